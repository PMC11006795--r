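# Reverse-mode automatic differentiation on dense matrices.
#
# Minimal tape-based engine: every value is a node (an environment holding a
# matrix, its parents and a backward closure). All networks in this package
# (graph auto-encoder, denoising auto-encoder, molecular message-passing
# encoder, fusion head) are expressed through these ops, so a single set of
# finite-difference gradient checks covers the whole training stack.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L

# restart node numbering; called at the start of every training step and by
# inference entry points so backward bookkeeping stays small
adResetTape <- function() {
  .ad$counter <- 0L
  invisible(NULL)
}

#' @keywords internal
adNode <- function(value, parents = list(), backfn = NULL, requires_grad = FALSE) {
  if (!is.matrix(value)) value <- as.matrix(value)
  node <- new.env(parent = emptyenv())
  id <- .ad$counter + 1L
  .ad$counter <- id
  node$id <- id
  node$value <- value
  node$parents <- parents
  node$backfn <- backfn
  if (!requires_grad)
    for (p in parents) if (p$requires_grad) { requires_grad <- TRUE; break }
  node$requires_grad <- requires_grad
  node$grad <- NULL
  class(node) <- "ad_node"
  node
}

adConst <- function(x) adNode(x)
adParam <- function(x) adNode(x, requires_grad = TRUE)

is_ad_node <- function(x) is.environment(x)
.as_node <- function(x) if (is.environment(x)) x else adConst(x)
.val <- function(x) if (is.environment(x)) x$value else as.matrix(x)

#' @export
print.ad_node <- function(x, ...) {
  cat(sprintf("<ad_node %dx%d%s>\n", nrow(x$value), ncol(x$value),
              if (x$requires_grad) " grad" else ""))
  invisible(x)
}

# -- elementary ops ----------------------------------------------------------

adMatmul <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  adNode(a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), crossprod(a$value, g))
  })
}

# a + b; b may be a 1 x n row vector broadcast over the rows of a (bias add)
adAdd <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  bcast <- nrow(b$value) == 1L && nrow(a$value) > 1L
  v <- if (bcast) sweep(a$value, 2L, b$value[1L, ], "+") else a$value + b$value
  adNode(v, list(a, b), function(g) {
    list(g, if (bcast) matrix(colSums(g), 1L) else g)
  })
}

adSub <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  adNode(a$value - b$value, list(a, b), function(g) list(g, -g))
}

adMul <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  adNode(a$value * b$value, list(a, b), function(g) {
    list(g * b$value, g * a$value)
  })
}

adScale <- function(a, s) {
  a <- .as_node(a)
  adNode(a$value * s, list(a), function(g) list(g * s))
}

adRelu <- function(a) {
  a <- .as_node(a)
  m <- a$value > 0
  adNode(a$value * m, list(a), function(g) list(g * m))
}

adSigmoid <- function(a) {
  a <- .as_node(a)
  s <- 1 / (1 + exp(-a$value))
  adNode(s, list(a), function(g) list(g * s * (1 - s)))
}

adTanh <- function(a) {
  a <- .as_node(a)
  s <- tanh(a$value)
  adNode(s, list(a), function(g) list(g * (1 - s^2)))
}

adTranspose <- function(a) {
  a <- .as_node(a)
  adNode(t(a$value), list(a), function(g) list(t(g)))
}

adSum <- function(a) {
  a <- .as_node(a)
  adNode(sum(a$value), list(a), function(g) {
    list(matrix(g[1L], nrow(a$value), ncol(a$value)))
  })
}

adMean <- function(a) {
  a <- .as_node(a)
  n <- length(a$value)
  adNode(mean(a$value), list(a), function(g) {
    list(matrix(g[1L] / n, nrow(a$value), ncol(a$value)))
  })
}

adRowSums <- function(a) {
  a <- .as_node(a)
  adNode(matrix(rowSums(a$value), ncol = 1L), list(a), function(g) {
    list(matrix(g[, 1L], nrow(a$value), ncol(a$value)))
  })
}

adRowMeans <- function(a) {
  a <- .as_node(a)
  k <- ncol(a$value)
  adNode(matrix(rowMeans(a$value), ncol = 1L), list(a), function(g) {
    list(matrix(g[, 1L] / k, nrow(a$value), ncol(a$value)))
  })
}

adColMeans <- function(a) {
  a <- .as_node(a)
  n <- nrow(a$value)
  adNode(matrix(colMeans(a$value), nrow = 1L), list(a), function(g) {
    list(matrix(g[1L, ] / n, nrow(a$value), ncol(a$value), byrow = TRUE))
  })
}

# row gather: a[idx, ]; backward scatter-adds into the source
adRows <- function(a, idx) {
  a <- .as_node(a)
  idx <- as.integer(idx)
  adNode(a$value[idx, , drop = FALSE], list(a), function(g) {
    acc <- rowsum(g, group = idx)
    out <- matrix(0, nrow(a$value), ncol(a$value))
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

adCols <- function(a, j) {
  a <- .as_node(a)
  j <- as.integer(j)
  adNode(a$value[, j, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$value), ncol(a$value))
    out[, j] <- g
    list(out)
  })
}

adCbind <- function(...) {
  nodes <- lapply(list(...), .as_node)
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  adNode(do.call(cbind, lapply(nodes, function(n) n$value)), nodes, function(g) {
    lapply(seq_along(nodes), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

adRbind <- function(...) {
  nodes <- lapply(list(...), .as_node)
  hs <- vapply(nodes, function(n) nrow(n$value), integer(1))
  ends <- cumsum(hs)
  starts <- c(1L, head(ends, -1L) + 1L)
  adNode(do.call(rbind, lapply(nodes, function(n) n$value)), nodes, function(g) {
    lapply(seq_along(nodes), function(k) g[starts[k]:ends[k], , drop = FALSE])
  })
}

# elementwise product with a constant mask matrix
adMaskMul <- function(a, mask) {
  a <- .as_node(a)
  adNode(a$value * mask, list(a), function(g) list(g * mask))
}

# broadcast a column vector v (n x 1) across columns, gated by a constant
# n x m mask: out[i, j] = mask[i, j] * v[i]
adRowBcastMask <- function(v, mask) {
  v <- .as_node(v)
  adNode(mask * v$value[, 1L], list(v), function(g) {
    list(matrix(rowSums(g * mask), ncol = 1L))
  })
}

# row-wise softmax restricted to a binary support mask (constant). Rows whose
# support is empty yield an all-zero row (no NaN); used for neighbourhood
# attention where isolated vertices receive no message.
adMaskedSoftmax <- function(scores, support) {
  scores <- .as_node(scores)
  s <- scores$value
  s[support == 0] <- -Inf
  mx <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  mx[!is.finite(mx)] <- 0
  e <- exp(s - mx) * support
  z <- rowSums(e)
  z[z == 0] <- 1
  a <- e / z
  adNode(a, list(scores), function(g) {
    list(a * (g - rowSums(g * a)))
  })
}

# -- losses ------------------------------------------------------------------

adMSELoss <- function(pred, target) {
  pred <- .as_node(pred)
  target <- .val(target)
  d <- pred$value - target
  n <- length(d)
  adNode(mean(d^2), list(pred), function(g) list(g[1L] * 2 * d / n))
}

# numerically stable binary cross-entropy on logits; labels in {0,1}
adBCEWithLogits <- function(logits, labels) {
  logits <- .as_node(logits)
  y <- .val(labels)
  l <- logits$value
  loss <- mean(pmax(l, 0) - l * y + log1p(exp(-abs(l))))
  p <- 1 / (1 + exp(-l))
  n <- length(l)
  adNode(loss, list(logits), function(g) list(g[1L] * (p - y) / n))
}

# mean softmax cross-entropy; labels are 1-based class indices per row
adSoftmaxCE <- function(logits, labels) {
  logits <- .as_node(logits)
  labels <- as.integer(labels)
  l <- logits$value
  mx <- apply(l, 1L, max)
  e <- exp(l - mx)
  p <- e / rowSums(e)
  n <- nrow(l)
  picked <- p[cbind(seq_len(n), labels)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  adNode(loss, list(logits), function(g) {
    gr <- p
    gr[cbind(seq_len(n), labels)] <- gr[cbind(seq_len(n), labels)] - 1
    list(g[1L] * gr / n)
  })
}

# -- backward pass -----------------------------------------------------------

#' @keywords internal
adBackward <- function(loss) {
  stopifnot(is_ad_node(loss), length(loss$value) == 1L)
  # collect the reachable subgraph; creation ids give the topological order
  visited <- logical(loss$id)
  nodes <- vector("list", 512L)
  ids <- integer(512L)
  cnt <- 0L
  stack <- vector("list", 256L)
  stack[[1L]] <- loss
  sp <- 1L
  while (sp > 0L) {
    nd <- stack[[sp]]
    sp <- sp - 1L
    id <- nd$id
    if (visited[id]) next
    visited[id] <- TRUE
    cnt <- cnt + 1L
    if (cnt > length(nodes)) {
      nodes <- c(nodes, vector("list", length(nodes)))
      ids <- c(ids, integer(length(ids)))
    }
    nodes[[cnt]] <- nd
    ids[cnt] <- id
    for (p in nd$parents) {
      if (p$requires_grad && !visited[p$id]) {
        sp <- sp + 1L
        if (sp > length(stack)) stack <- c(stack, vector("list", length(stack)))
        stack[[sp]] <- p
      }
    }
  }
  ord <- sort.list(ids[seq_len(cnt)], decreasing = TRUE, method = "radix")
  loss$grad <- matrix(1, 1L, 1L)
  for (k in ord) {
    nd <- nodes[[k]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    parents <- nd$parents
    for (j in seq_along(parents)) {
      p <- parents[[j]]
      if (!p$requires_grad || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(loss)
}
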