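ns <- asNamespace("DIPK")

test_that("SMILES parsing yields attributed heavy-atom graphs", {
  m <- smilesToGraph("methane", "C")
  expect_equal(nrow(atomTable(m)), 1L)
  expect_equal(nrow(bondTable(m)), 0L)

  b <- smilesToGraph("benzene", "c1ccccc1")
  expect_equal(nrow(atomTable(b)), 6L)
  expect_equal(nrow(bondTable(b)), 6L)
  expect_true(all(atomTable(b)$aromatic))
  expect_true(all(bondTable(b)$type == "aromatic"))

  a <- smilesToGraph("aspirin", "CC(=O)Oc1ccccc1C(=O)O")
  expect_equal(nrow(atomTable(a)), 13L)
  expect_equal(sum(atomTable(a)$element == "O"), 4L)

  expect_error(smilesToGraph("salt", "C.C"), "disconnected")
  expect_error(smilesToGraph("bad", "C("), "bad")
  expect_error(smilesToGraph("ring", "c1ccc"), "malformed")
  # formal charge decoding
  ac <- smilesToGraph("acetate", "CC(=O)[O-]")
  expect_equal(sum(atomTable(ac)$charge), -1L)
})

test_that("atom vectors have the configured width and are deterministic", {
  enc <- initDrugEncoder(encoderConfig(seed = 1L))
  X <- encodeDrug(smilesToGraph("ethanol", "CCO"), enc)
  expect_equal(dim(X), c(3L, 768L))
  enc2 <- initDrugEncoder(microEncoderConfig())
  g <- smilesToGraph("pyridine", "c1ccncc1")
  expect_identical(encodeDrug(g, enc2), encodeDrug(g, enc2))
})

test_that("encoding is permutation-equivariant", {
  enc <- initDrugEncoder(microEncoderConfig(seed = 6L))
  withr::with_seed(8, {
    pool <- DIPK:::SMILES_POOL
    for (smi in sample(pool, 10)) {
      g <- smilesToGraph("mol", smi)
      n <- nrow(atomTable(g))
      if (n < 2) next
      X <- encodeDrug(g, enc)
      for (r in 1:3) {
        perm <- sample(n)
        Xp <- encodeDrug(permuteGraph(g, perm), enc)
        expect_lt(max(abs(Xp - X[perm, , drop = FALSE])), 1e-5)
      }
    }
  })
})

test_that("one message step on a two-atom path matches hand arithmetic", {
  cfg <- encoderConfig(d_atom = 4L, message_steps = 1L, attention_heads = 1L,
                       seed = 2L)
  enc <- initDrugEncoder(cfg)
  g <- smilesToGraph("ethane", "CC")
  X <- encodeDrug(g, enc)

  p <- enc@params
  elem <- match("C", DIPK:::ELEMENT_VOCAB)
  deg <- match(1L, DIPK:::DEGREE_VOCAB)
  chg <- match(0L, DIPK:::CHARGE_VOCAB)
  x0 <- p$emb_element[elem, ] + p$emb_degree[deg, ] + p$emb_charge[chg, ] +
    p$emb_aromatic[1, ]                       # both atoms identical
  ebond <- p$emb_bond[match("single", DIPK:::BOND_VOCAB), ]
  q <- x0 %*% p$attn$Wq
  k <- (x0 + ebond) %*% p$attn$Wk
  v <- (x0 + ebond) %*% p$attn$Wv
  # one neighbour: softmax weight is 1 regardless of the q.k score
  msg <- (v %*% p$attn$Wo)[1, ]
  gp <- p$gru
  r <- plogis(msg %*% gp$Wr + x0 %*% gp$Ur + gp$br)
  z <- plogis(msg %*% gp$Wz + x0 %*% gp$Uz + gp$bz)
  nn <- tanh(msg %*% gp$Wn + r * (x0 %*% gp$Un + gp$bn))
  h1 <- (1 - z) * nn + z * x0
  expect_equal(X[1, ], h1[1, ], tolerance = 1e-6)
  expect_equal(X[2, ], h1[1, ], tolerance = 1e-6)
})

test_that("neighbourhood attention weights sum to one per atom", {
  cfg <- microEncoderConfig(d_atom = 8L, steps = 1L, heads = 2L)
  enc <- initDrugEncoder(cfg)
  g <- smilesToGraph("toluene", "Cc1ccccc1")
  prep <- ns$prepGraph(g)
  p <- rapply(enc@params, ns$adConst, classes = c("matrix", "numeric", "array"),
              how = "replace")
  x <- ns$adAdd(ns$adAdd(ns$adRows(p$emb_element, prep$elem),
                         ns$adRows(p$emb_degree, prep$deg)),
                ns$adAdd(ns$adRows(p$emb_charge, prep$chg),
                         ns$adRows(p$emb_aromatic, prep$arom)))
  Q <- ns$adMatmul(x, p$attn$Wq)
  Kx <- ns$adMatmul(x, p$attn$Wk)
  scores <- ns$adMatmul(ns$adCols(Q, 1:4),
                        ns$adTranspose(ns$adCols(Kx, 1:4)))
  alpha <- ns$adMaskedSoftmax(ns$adScale(scores, 0.5), prep$support)$value
  expect_equal(rowSums(alpha), rep(1, nrow(atomTable(g))), tolerance = 1e-6)
})

test_that("half-graph discrimination is learnable on distinct molecules", {
  enc <- initDrugEncoder(microEncoderConfig(d_atom = 16L, steps = 2L,
                                            heads = 4L))
  gs <- list(smilesToGraph("alkane", "CCCCCCCC"),
             smilesToGraph("aromatic", "c1ccc2ccccc2c1"))
  enc2 <- pretrainPHD(gs, enc, epochs = 120L, learning_rate = 3e-3, seed = 7L)
  expect_gt(attr(enc2, "phd_accuracy"), 0.5)
  expect_false(identical(enc2@params, enc@params))

  # zero-epoch contract and small-graph exclusion
  expect_identical(pretrainPHD(gs, enc, epochs = 0L)@params, enc@params)
  small <- smilesToGraph("water", "O")
  expect_warning(
    expect_error(pretrainPHD(list(small, small), enc, epochs = 1L), ">= 2"),
    "excluded")
})

test_that("half-graph splits bipartition the atom set evenly", {
  g <- smilesToGraph("caffeine", "Cn1cnc2c1c(=O)n(C)c(=O)n2C")
  prep <- ns$prepGraph(g)
  withr::with_seed(3, {
    for (i in 1:20) {
      sp <- ns$.split_halves(prep)
      expect_length(intersect(sp$a, sp$b), 0L)
      expect_setequal(c(sp$a, sp$b), seq_len(prep$n))
      expect_lte(abs(length(sp$a) - length(sp$b)), 1L)
    }
  })
})

test_that("attribute masking masks floor(rate * atoms) and learns a trivial vocabulary", {
  g20 <- smilesToGraph("arachidic-ish", paste(rep("C", 20), collapse = ""))
  prep <- ns$prepGraph(g20)
  expect_equal(floor(0.15 * prep$n), 3)

  enc <- initDrugEncoder(microEncoderConfig(d_atom = 8L, steps = 1L,
                                            heads = 2L))
  alkanes <- list(smilesToGraph("c6", "CCCCCC"),
                  smilesToGraph("c8", "CCCCCCCC"),
                  g20)
  enc2 <- pretrainMask(alkanes, enc, mask_rate = 0.15, epochs = 40L,
                       learning_rate = 5e-3, seed = 4L)
  expect_equal(attr(enc2, "mask_accuracy"), 1)
  expect_identical(pretrainMask(alkanes, enc, mask_rate = 0.15,
                                epochs = 0L)@params, enc@params)
})
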