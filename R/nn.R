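# Shared neural-network plumbing: parameter containers (nested lists of
# matrices), Glorot initialisation, the Adam optimiser, and layer helpers
# (linear, GRU cell, multi-head attention) used by every model.

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

initLinear <- function(n_in, n_out) {
  list(W = glorot(n_in, n_out), b = matrix(0, 1L, n_out))
}

# apply a linear layer to a node (rows = examples)
linearOp <- function(x, lin) adAdd(adMatmul(x, lin$W), lin$b)

initGRU <- function(d_in, d_hidden) {
  list(
    Wr = glorot(d_in, d_hidden), Ur = glorot(d_hidden, d_hidden), br = matrix(0, 1L, d_hidden),
    Wz = glorot(d_in, d_hidden), Uz = glorot(d_hidden, d_hidden), bz = matrix(0, 1L, d_hidden),
    Wn = glorot(d_in, d_hidden), Un = glorot(d_hidden, d_hidden), bn = matrix(0, 1L, d_hidden)
  )
}

# one GRU step applied row-wise: h' = (1-z)*n + z*h
gruOp <- function(m, h, p) {
  r <- adSigmoid(adAdd(adAdd(adMatmul(m, p$Wr), adMatmul(h, p$Ur)), p$br))
  z <- adSigmoid(adAdd(adAdd(adMatmul(m, p$Wz), adMatmul(h, p$Uz)), p$bz))
  n <- adTanh(adAdd(adMatmul(m, p$Wn), adMul(r, adAdd(adMatmul(h, p$Un), p$bn))))
  adAdd(adMul(adSub(adConst(matrix(1, nrow(.val(z)), ncol(.val(z)))), z), n),
        adMul(z, h))
}

# -- nested parameter lists --------------------------------------------------

# wrap every matrix leaf of a nested list as a gradient-requiring node
wrapParams <- function(params) {
  rapply(params, adParam, classes = c("matrix", "numeric", "array"), how = "replace")
}

# extract gradients (zeros where a leaf was unused in the graph)
gradsOf <- function(nodes) {
  rapply(nodes, function(nd) {
    if (is.null(nd$grad)) matrix(0, nrow(nd$value), ncol(nd$value)) else nd$grad
  }, classes = "ad_node", how = "replace")
}

paramCount <- function(params) {
  sum(rapply(params, length, classes = c("matrix", "numeric", "array"), how = "unlist"))
}

# flatten a nested list of matrices to a single numeric vector (and back)
flattenParams <- function(params) {
  unlist(rapply(params, as.numeric, classes = c("matrix", "numeric", "array"), how = "unlist"))
}

# -- Adam --------------------------------------------------------------------

adamInit <- function(params) {
  zeros <- rapply(params, function(m) matrix(0, nrow(as.matrix(m)), ncol(as.matrix(m))),
                  classes = c("matrix", "numeric", "array"), how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

.adam_walk <- function(p, g, m, v, lr, b1, b2, eps, t) {
  if (is.list(p)) {
    upd <- Map(.adam_walk, p, g, m, v,
               MoreArgs = list(lr = lr, b1 = b1, b2 = b2, eps = eps, t = t))
    list(p = lapply(upd, `[[`, "p"), m = lapply(upd, `[[`, "m"),
         v = lapply(upd, `[[`, "v"))
  } else {
    m2 <- b1 * m + (1 - b1) * g
    v2 <- b2 * v + (1 - b2) * g^2
    mhat <- m2 / (1 - b1^t)
    vhat <- v2 / (1 - b2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
  }
}

adamStep <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  upd <- .adam_walk(params, grads, opt$m, opt$v, lr, beta1, beta2, eps, opt$t)
  opt$m <- upd$m
  opt$v <- upd$v
  list(params = upd$p, opt = opt)
}

# -- misc --------------------------------------------------------------------

# deterministic sub-seed derivation (kept below 2^31)
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 7919) %% 2147483629)
}
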