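test_that("top-gene selection ranks by expression with lexicographic ties", {
  p <- expressionProfile("c1", c("g1", "g2", "g3", "g4"), c(5, 9, 9, 1))
  expect_identical(selectTopGenes(p, k = 2), c("g2", "g3"))
  # default k follows the published setting
  big <- expressionProfile("c2", sprintf("g%04d", 1:300), rnorm(300))
  expect_length(selectTopGenes(big), 256L)
  expect_error(selectTopGenes(p, k = 2, eligible = "absent"), "c1")
})

test_that("top-gene selection agrees with a full-sort oracle and is monotone", {
  withr::with_seed(3, {
    genes <- sprintf("g%03d", 1:60)
    for (i in 1:200) {
      v <- round(rnorm(60), 1)  # coarse values force ties
      p <- expressionProfile("c", genes, v)
      sel <- selectTopGenes(p, k = 16)
      ord <- order(-v, genes)
      expect_identical(sel, genes[ord][1:16])
      expect_true(all(sel %in% selectTopGenes(p, k = 17)))
    }
  })
})

test_that("interactome feature is the mean embedding of the selected genes", {
  emb <- rbind(g1 = c(1, 0), g2 = c(0, 1))
  tab <- geneEmbeddingTable(emb)
  p <- expressionProfile("c1", c("g1", "g2", "g3"), c(3, 2, 10))
  # g3 has no embedding: excluded before ranking
  expect_equal(unname(interactomeFeature(p, tab, k = 2)), c(0.5, 0.5))
  expect_equal(unname(interactomeFeature(p, tab, k = 1)), c(1, 0))

  withr::with_seed(4, {
    genes <- sprintf("g%03d", 1:80)
    m <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(genes, NULL))
    tab2 <- geneEmbeddingTable(m)
    for (i in 1:20) {
      v <- rnorm(80)
      prof <- expressionProfile("c", genes, v)
      sel <- genes[order(-v, genes)][1:20]
      expect_equal(interactomeFeature(prof, tab2, k = 20),
                   colMeans(m[sel, ]), tolerance = 1e-9)
      # invariance to storage order of profile and table
      perm <- sample(80)
      prof2 <- expressionProfile("c", genes[perm], v[perm])
      tab3 <- geneEmbeddingTable(m[sample(80), ])
      expect_equal(interactomeFeature(prof2, tab3, k = 20),
                   interactomeFeature(prof, tab2, k = 20), tolerance = 1e-9)
    }
  })
})

test_that("DAE configuration enforces the palindromic hidden stack", {
  expect_error(daeConfig(hidden_dims = c(64, 32)), "palindromic")
  expect_error(daeConfig(hidden_dims = c(64, 32, 16, 64)), "palindromic")
  cfg <- daeConfig()
  expect_equal(cfg$hidden_dims[(length(cfg$hidden_dims) + 1) %/% 2], 512L)
})

test_that("DAE training reduces reconstruction error on a low-rank fixture", {
  withr::with_seed(1, {
    G <- 120L; n <- 40L
    L <- matrix(rnorm(n * 3), n, 3)
    Fm <- matrix(rnorm(3 * G), 3, G)
    X <- L %*% Fm + matrix(rnorm(n * G, 0, 0.3), n, G)
    genes <- sprintf("g%03d", 1:G)
    profs <- lapply(1:n, function(i)
      expressionProfile(sprintf("c%02d", i), genes, X[i, ]))
  })
  dae <- trainDAE(profs, daeConfig(hidden_dims = c(64L, 16L, 64L),
                                   noise_sigma = 0, epochs = 100L,
                                   learning_rate = 1e-3, seed = 2L))
  h <- lossHistory(dae)
  expect_lt(h[length(h)], h[1])
  expect_equal(latentDim(dae), 16L)

  z1 <- encodeTranscriptome(profs[[1]], dae)
  expect_length(z1, 16L)
  expect_identical(z1, encodeTranscriptome(profs[[1]], dae))

  # hand-rolled forward pass from the exported weights
  x <- (profs[[1]]@values - dae@scaler$center) / dae@scaler$scale
  h1 <- pmax(x %*% dae@params[[1]]$W + dae@params[[1]]$b[1, ], 0)
  h2 <- pmax(h1 %*% dae@params[[2]]$W + dae@params[[2]]$b[1, ], 0)
  expect_equal(z1, h2[1, ], tolerance = 1e-6)
})

test_that("zero-epoch DAE returns the seeded initialisation unchanged", {
  profs <- tinyProfiles(4)
  cfg0 <- daeConfig(hidden_dims = c(8L, 4L, 8L), noise_sigma = 0,
                    epochs = 0L, seed = 7L)
  dae0 <- trainDAE(profs, cfg0)
  init <- withr::with_seed(7L, {
    dims <- c(10L, 8L, 4L, 8L, 10L)
    lapply(seq_len(4), function(k) {
      lim <- sqrt(6 / (dims[k] + dims[k + 1]))
      list(W = matrix(runif(dims[k] * dims[k + 1], -lim, lim),
                      dims[k], dims[k + 1]),
           b = matrix(0, 1, dims[k + 1]))
    })
  })
  expect_equal(dae0@params, init, tolerance = 1e-12)
})

test_that("profiles with mismatched gene lists are rejected with coordinates", {
  profs <- tinyProfiles(3)
  bad <- expressionProfile("cX", c("g01", "zz", sprintf("g%02d", 3:10)),
                           rnorm(10))
  expect_error(trainDAE(c(profs, list(bad)),
                        daeConfig(hidden_dims = c(4L), epochs = 1L)),
               "cX.*position 2")
  dae <- trainDAE(profs, daeConfig(hidden_dims = c(4L), epochs = 1L,
                                   learning_rate = 1e-3, seed = 1L))
  expect_error(encodeTranscriptome(bad, dae), "position 2")
})

test_that("cell representations assemble both features", {
  profs <- tinyProfiles(4)
  genes <- geneIds(profs[[1]])
  tab <- geneEmbeddingTable(
    matrix(rnorm(10 * 3), 10, 3, dimnames = list(genes, NULL)))
  dae <- trainDAE(profs, daeConfig(hidden_dims = c(8L, 3L, 8L), epochs = 5L,
                                   learning_rate = 1e-3, seed = 1L))
  reps <- buildCellRepresentations(profs, tab, dae, k = 4)
  expect_named(reps, names(profs))
  expect_length(reps[[1]]@interactome, 3L)
  expect_length(reps[[1]]@transcriptome, 3L)

  raw <- buildCellRepresentations(profs, tab, k = 4, transcriptome = "raw")
  expect_length(raw[[1]]@transcriptome, 10L)
})
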