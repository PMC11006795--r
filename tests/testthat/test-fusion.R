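ns <- asNamespace("DIPK")

# hand-set attention parameters for a d_query x d_atom pool
handAttn <- function(d_query, d_atom, seed = 1) {
  withr::with_seed(seed, list(
    q = list(W = matrix(rnorm(d_query * d_atom), d_query, d_atom),
             b = matrix(rnorm(d_atom), 1)),
    k = list(W = matrix(rnorm(d_atom * d_atom), d_atom, d_atom),
             b = matrix(rnorm(d_atom), 1)),
    v = list(W = matrix(rnorm(d_atom * d_atom), d_atom, d_atom),
             b = matrix(rnorm(d_atom), 1)),
    o = list(W = matrix(rnorm(d_atom * d_atom), d_atom, d_atom),
             b = matrix(rnorm(d_atom), 1))))
}

test_that("attention pool over a single atom returns its mixed value projection", {
  prm <- handAttn(3, 4)
  atom <- matrix(rnorm(4), 1, 4)
  q <- rnorm(3)
  out <- attentionPool(q, atom, prm, heads = 1L)
  v <- atom %*% prm$v$W + prm$v$b
  expect_equal(out, (v %*% prm$o$W + prm$o$b)[1, ], tolerance = 1e-12)
})

test_that("identical keys and values give the query-independent average", {
  prm <- handAttn(3, 4, seed = 2)
  atom <- matrix(rnorm(4), 1, 4)
  two <- rbind(atom, atom)
  o1 <- attentionPool(rnorm(3), two, prm, heads = 1L)
  o2 <- attentionPool(rnorm(3), two, prm, heads = 2L)
  v <- atom %*% prm$v$W + prm$v$b
  expect_equal(o1, (v %*% prm$o$W + prm$o$b)[1, ], tolerance = 1e-12)
  expect_equal(o2, (v %*% prm$o$W + prm$o$b)[1, ], tolerance = 1e-12)
})

test_that("three-atom pool matches hand-computed scaled dot-product attention", {
  prm <- handAttn(2, 4, seed = 3)
  atoms <- matrix(rnorm(12), 3, 4)
  qf <- c(0.3, -1.2)
  out <- attentionPool(qf, atoms, prm, heads = 1L)

  Q <- matrix(qf, 1) %*% prm$q$W + prm$q$b
  K <- atoms %*% prm$k$W + matrix(prm$k$b, 3, 4, byrow = TRUE)
  V <- atoms %*% prm$v$W + matrix(prm$v$b, 3, 4, byrow = TRUE)
  s <- (Q %*% t(K)) / sqrt(4)          # d_k = atomic feature dimension
  a <- exp(s - max(s)); a <- a / sum(a)
  expect_equal(sum(a), 1, tolerance = 1e-12)
  pooled <- a %*% V
  expect_equal(out, (pooled %*% prm$o$W + prm$o$b)[1, ], tolerance = 1e-6)
})

test_that("micro fusion forward matches the hand-composed layer stack", {
  d_gene <- 2L; d_atom <- 3L
  cfg <- fusionConfig(variant = "DIPK", share_parameters = FALSE,
                      attention_heads = 1L, head_dims = c(5L, 2L, 1L),
                      seed = 1L)
  prm <- initFusionParams(cfg, d_cell = d_gene, d_atom = d_atom)
  fint <- c(0.5, -1); ftrn <- c(2, 0.25)
  atom <- matrix(c(0.1, -0.4, 0.9), 1, 3)
  got <- fusionForward(prm, cfg, fint, ftrn, atom)

  lin <- function(x, l) x %*% l$W + l$b
  pool <- function(qf, aset) {
    Q <- lin(qf, aset$q); K <- lin(atom, aset$k); V <- lin(atom, aset$v)
    # single atom: softmax == 1
    lin(V, aset$o)
  }
  ei_lin <- lin(matrix(fint, 1), prm$branch$int)
  et_lin <- lin(matrix(ftrn, 1), prm$branch$trn)
  mol <- pool(ei_lin, prm$attn$int) + pool(et_lin, prm$attn$trn)
  cell <- pmax(ei_lin, 0) + pmax(et_lin, 0)
  h <- cbind(mol, cell)
  h <- pmax(lin(h, prm$head[[1]]), 0)
  pred <- lin(h, prm$head[[2]])
  expect_equal(got, pred[1, 1], tolerance = 1e-6)
})

test_that("all-zero head weights predict exactly zero", {
  cfg <- fusionConfig(variant = "DIPK", share_parameters = TRUE,
                      attention_heads = 1L, head_dims = c(5L, 2L, 1L),
                      seed = 1L)
  prm <- initFusionParams(cfg, d_cell = 2L, d_atom = 3L)
  prm$head <- lapply(prm$head, function(l)
    list(W = l$W * 0, b = l$b * 0))
  out <- fusionForward(prm, cfg, c(1, 2), c(3, 4), matrix(rnorm(6), 2, 3))
  expect_identical(out, 0)
})

test_that("forward is invariant to atom permutation of the drug graph", {
  enc <- initDrugEncoder(microEncoderConfig(d_atom = 8L, steps = 2L,
                                            heads = 2L, seed = 5L))
  cfg <- fusionConfig(variant = "DIPK", share_parameters = TRUE,
                      attention_heads = 2L, head_dims = c(12L, 4L, 1L),
                      seed = 2L)
  prm <- initFusionParams(cfg, d_cell = 4L, d_atom = 8L)
  g <- smilesToGraph("quinoline", "c1ccc2ncccc2c1")
  X <- encodeDrug(g, enc)
  fint <- rnorm(4); ftrn <- rnorm(4)
  base <- fusionForward(prm, cfg, fint, ftrn, X)
  withr::with_seed(9, {
    for (r in 1:5) {
      perm <- sample(nrow(X))
      Xp <- encodeDrug(permuteGraph(g, perm), enc)
      expect_lt(abs(fusionForward(prm, cfg, fint, ftrn, Xp) - base), 1e-5)
    }
  })
})

test_that("parameter sharing removes exactly one linear and one attention layer", {
  mk <- function(share) fusionConfig(variant = "DIPK",
                                     share_parameters = share,
                                     attention_heads = 2L,
                                     head_dims = c(16L, 8L, 1L), seed = 1L)
  d_cell <- 8L; d_atom <- 8L
  shared <- countFusionParameters(mk(TRUE), d_cell, d_atom)
  distinct <- countFusionParameters(mk(FALSE), d_cell, d_atom)
  one_linear <- d_cell * d_cell + d_cell
  one_attention <- (d_cell * d_atom + d_atom) + 3L * (d_atom * d_atom + d_atom)
  expect_equal(distinct - shared, one_linear + one_attention)
})

test_that("training validates inputs and honours the zero-epoch contract", {
  profs <- tinyProfiles(6)
  genes <- geneIds(profs[[1]])
  tab <- geneEmbeddingTable(
    matrix(rnorm(30), 10, 3, dimnames = list(genes, NULL)))
  dae <- trainDAE(profs, daeConfig(hidden_dims = c(6L, 3L, 6L), epochs = 3L,
                                   learning_rate = 1e-3, seed = 1L))
  reps <- buildCellRepresentations(profs, tab, dae, k = 4)
  graphs <- list(d1 = smilesToGraph("d1", "CCO"),
                 d2 = smilesToGraph("d2", "c1ccccc1"))
  enc <- initDrugEncoder(microEncoderConfig(d_atom = 8L, steps = 1L,
                                            heads = 2L))
  resp <- expand.grid(cell_id = names(profs), drug_id = names(graphs),
                      stringsAsFactors = FALSE)
  resp$ln_ic50 <- rnorm(nrow(resp))

  bad <- rbind(resp, data.frame(cell_id = "ghost", drug_id = "d1",
                                ln_ic50 = 0))
  cfg <- fusionConfig(variant = "DIPK", attention_heads = 2L,
                      head_dims = c(11L, 4L, 1L), epochs = 1L, seed = 1L,
                      freeze_encoder = TRUE)
  expect_error(trainResponseModel(bad, reps, graphs, enc, cfg), "ghost")
  # head width must match d_atom + d_cell
  cfg_bad <- fusionConfig(variant = "DIPK", attention_heads = 2L,
                          head_dims = c(10L, 4L, 1L), epochs = 1L, seed = 1L,
                          freeze_encoder = TRUE)
  expect_error(trainResponseModel(resp, reps, graphs, enc, cfg_bad),
               "head_dims")

  m0 <- trainResponseModel(resp, reps, graphs, enc,
                           fusionConfig(variant = "DIPK",
                                        attention_heads = 2L,
                                        head_dims = c(11L, 4L, 1L),
                                        epochs = 0L, seed = 3L,
                                        freeze_encoder = TRUE))
  expect_length(lossHistory(m0), 0L)
  expect_equal(m0@params,
               initFusionParams(m0@config, d_cell = 3L, d_atom = 8L),
               tolerance = 1e-12)
})

test_that("prediction is deterministic, batch-independent and order-preserving", {
  profs <- tinyProfiles(5)
  genes <- geneIds(profs[[1]])
  tab <- geneEmbeddingTable(
    matrix(rnorm(30), 10, 3, dimnames = list(genes, NULL)))
  dae <- trainDAE(profs, daeConfig(hidden_dims = c(6L, 3L, 6L), epochs = 3L,
                                   learning_rate = 1e-3, seed = 1L))
  reps <- buildCellRepresentations(profs, tab, dae, k = 4)
  graphs <- list(d1 = smilesToGraph("d1", "CCO"),
                 d2 = smilesToGraph("d2", "c1ccncc1"))
  enc <- initDrugEncoder(microEncoderConfig(d_atom = 8L, steps = 1L,
                                            heads = 2L))
  resp <- expand.grid(cell_id = names(profs), drug_id = names(graphs),
                      stringsAsFactors = FALSE)
  resp$ln_ic50 <- rnorm(nrow(resp))
  model <- trainResponseModel(resp, reps, graphs, enc,
                              fusionConfig(variant = "DIPK",
                                           attention_heads = 2L,
                                           head_dims = c(11L, 4L, 1L),
                                           epochs = 2L, learning_rate = 1e-3,
                                           seed = 2L, freeze_encoder = TRUE))
  pairs <- resp[, c("cell_id", "drug_id")]
  p1 <- predictResponse(model, pairs, reps, graphs)
  p2 <- predictResponse(model, pairs, reps, graphs)
  expect_identical(p1, p2)

  single <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    predictResponse(model, pairs[i, , drop = FALSE], reps, graphs)))
  expect_equal(p1$predicted_ln_ic50, single$predicted_ln_ic50,
               tolerance = 1e-10)

  perm <- sample(nrow(pairs))
  pp <- predictResponse(model, pairs[perm, ], reps, graphs)
  expect_equal(pp$predicted_ln_ic50, p1$predicted_ln_ic50[perm],
               tolerance = 1e-12)
  expect_error(predictResponse(model, data.frame(cell_id = "nope",
                                                 drug_id = "d1"),
                               reps, graphs), "nope")
})

test_that("DEM drops the interactome branch and DIM accepts any gene count", {
  profs <- tinyProfiles(6, genes = sprintf("g%02d", 1:13))  # odd gene count
  genes <- geneIds(profs[[1]])
  tab <- geneEmbeddingTable(
    matrix(rnorm(13 * 3), 13, 3, dimnames = list(genes, NULL)))
  dae <- trainDAE(profs, daeConfig(hidden_dims = c(6L, 3L, 6L), epochs = 3L,
                                   learning_rate = 1e-3, seed = 1L))
  graphs <- list(d1 = smilesToGraph("d1", "CCO"))
  enc <- initDrugEncoder(microEncoderConfig(d_atom = 8L, steps = 1L,
                                            heads = 2L))
  resp <- data.frame(cell_id = names(profs), drug_id = "d1",
                     ln_ic50 = rnorm(6))

  reps <- buildCellRepresentations(profs, tab, dae, k = 4)
  dem <- trainResponseModel(resp, reps, graphs, enc,
                            fusionConfig(variant = "DEM",
                                         attention_heads = 2L,
                                         head_dims = c(11L, 4L, 1L),
                                         epochs = 2L, learning_rate = 1e-3,
                                         seed = 2L, freeze_encoder = TRUE))
  expect_s4_class(dem, "ResponseModel")
  expect_null(dem@params$branch$int)
  expect_identical(modelVariant(dem), "DEM")
  expect_equal(nrow(predictResponse(dem, resp, reps, graphs)), 6L)

  repsRaw <- buildCellRepresentations(profs, tab, k = 4,
                                      transcriptome = "raw")
  dim_model <- trainResponseModel(resp, repsRaw, graphs, enc,
                                  fusionConfig(variant = "DIM",
                                               attention_heads = 2L,
                                               head_dims = c(11L, 4L, 1L),
                                               epochs = 2L,
                                               learning_rate = 1e-3,
                                               seed = 2L,
                                               freeze_encoder = TRUE))
  pred <- predictResponse(dim_model, resp, repsRaw, graphs)
  expect_true(all(is.finite(pred$predicted_ln_ic50)))
})
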