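# Graph auto-encoder over one or more gene interaction networks.
#
# A two-layer graph-convolution encoder (shared across networks) embeds the
# union gene set; per-gene embeddings are the mean of per-network encoder
# outputs. The inner-product decoder with a logistic link is trained with
# binary cross-entropy on observed edges against uniformly sampled
# non-edges. Node features are one-hot identity, so the first layer reduces
# to a learnable per-gene embedding smoothed over the graph.

#' Configuration for the gene-network auto-encoder
#'
#' @param dim embedding dimensionality (default 512).
#' @param epochs training epochs (>= 1).
#' @param learning_rate Adam learning rate.
#' @param seed RNG seed; training is deterministic given the seed.
#' @param negative_sampling_ratio non-edges sampled per observed edge.
#' @param weight_decay decoupled L2 weight decay; regularises the encoder
#'   so embeddings reflect community structure rather than memorising the
#'   observed edge list.
#' @return validated config list.
#' @export
gaeConfig <- function(dim = 512L, epochs = 200L, learning_rate = 0.05,
                      seed = 1L, negative_sampling_ratio = 1.0,
                      weight_decay = 1e-3) {
  stopifnot(dim >= 2L, epochs >= 1L, learning_rate > 0,
            negative_sampling_ratio > 0, weight_decay >= 0)
  list(dim = as.integer(dim), epochs = as.integer(epochs),
       learning_rate = learning_rate, seed = as.integer(seed),
       negative_sampling_ratio = negative_sampling_ratio,
       weight_decay = weight_decay)
}

# symmetric degree-normalised adjacency (self-loops added) over `genes`
.norm_adjacency <- function(network, genes) {
  n <- length(genes)
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  e <- edgeTable(network)
  if (nrow(e)) {
    ia <- match(e$gene_a, genes)
    ib <- match(e$gene_b, genes)
    A[cbind(ia, ib)] <- e$weight
    A[cbind(ib, ia)] <- e$weight
  }
  diag(A) <- diag(A) + 1
  d <- 1 / sqrt(rowSums(A))
  A * outer(d, d)
}

#' Train the gene embedder on interaction networks
#'
#' @param networks list of \linkS4class{GeneNetwork}.
#' @param config a \code{\link{gaeConfig}}.
#' @param extra_genes genes to embed even if absent from every network
#'   (isolated nodes; flagged with a warning).
#' @param verbose print per-epoch loss.
#' @return a \linkS4class{GeneEmbeddingTable} with attribute
#'   \code{history} (per-epoch reconstruction loss).
#' @export
trainGeneEmbedder <- function(networks, config = gaeConfig(),
                              extra_genes = character(), verbose = FALSE) {
  if (is(networks, "GeneNetwork")) networks <- list(networks)
  genes <- sort(unique(c(unlist(lapply(networks, networkGenes)),
                         as.character(extra_genes))))
  n_edges <- sum(vapply(networks, function(nw) nrow(edgeTable(nw)), integer(1)))
  if (length(genes) == 0L || n_edges == 0L)
    stop("need a non-empty union gene set with at least one edge", call. = FALSE)
  isolated <- setdiff(as.character(extra_genes),
                      unlist(lapply(networks, networkGenes)))
  if (length(isolated))
    warning(sprintf("%d gene(s) appear in no network; embedded as isolated nodes",
                    length(isolated)), call. = FALSE)
  n <- length(genes)
  adjs <- lapply(networks, .norm_adjacency, genes = genes)

  # union of observed edges as index pairs (i < j)
  pos <- unique(do.call(rbind, lapply(networks, function(nw) {
    e <- edgeTable(nw)
    ia <- match(e$gene_a, genes); ib <- match(e$gene_b, genes)
    cbind(pmin(ia, ib), pmax(ia, ib))
  })))
  pos_key <- pos[, 1L] + n * pos[, 2L]
  n_neg <- ceiling(config$negative_sampling_ratio * nrow(pos))

  # hidden width floored at 16 so ReLU units cannot all die at tiny dims
  h1 <- max(config$dim, 16L)
  withr::with_seed(config$seed, {
    params <- list(W1 = glorot(n, h1),
                   W2 = glorot(h1, config$dim))
    opt <- adamInit(params)
    history <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      adResetTape()
      # uniform non-edge sample, rejecting observed edges and self-pairs
      neg <- matrix(0L, 0L, 2L)
      while (nrow(neg) < n_neg) {
        i <- sample.int(n, n_neg, replace = TRUE)
        j <- sample.int(n, n_neg, replace = TRUE)
        a <- pmin(i, j); b <- pmax(i, j)
        ok <- a != b & !((a + n * b) %in% pos_key)
        neg <- rbind(neg, cbind(a[ok], b[ok]))
      }
      neg <- neg[seq_len(n_neg), , drop = FALSE]
      ii <- c(pos[, 1L], neg[, 1L])
      jj <- c(pos[, 2L], neg[, 2L])
      y <- matrix(c(rep(1, nrow(pos)), rep(0, n_neg)), ncol = 1L)

      nodes <- wrapParams(params)
      zs <- lapply(adjs, function(A) {
        H1 <- adRelu(adMatmul(adConst(A), nodes$W1))
        adMatmul(adMatmul(adConst(A), H1), nodes$W2)
      })
      Z <- zs[[1L]]
      if (length(zs) > 1L) {
        for (k in 2:length(zs)) Z <- adAdd(Z, zs[[k]])
        Z <- adScale(Z, 1 / length(zs))
      }
      logits <- adRowSums(adMul(adRows(Z, ii), adRows(Z, jj)))
      loss <- adBCEWithLogits(logits, y)
      adBackward(loss)
      history[ep] <- loss$value[1L]
      if (verbose) message(sprintf("GAE epoch %d: loss %.4f", ep, history[ep]))
      step <- adamStep(opt, params, gradsOf(nodes), config$learning_rate)
      params <- step$params; opt <- step$opt
      if (config$weight_decay > 0) {
        shrink <- 1 - config$learning_rate * config$weight_decay
        params <- rapply(params, function(m) m * shrink, classes = "matrix",
                         how = "replace")
      }
    }
    # final embeddings (no sampling involved)
    emb <- Reduce(`+`, lapply(adjs, function(A) {
      H1 <- pmax(A %*% params$W1, 0)
      (A %*% H1) %*% params$W2
    })) / length(adjs)
    rownames(emb) <- genes
    out <- geneEmbeddingTable(emb)
    attr(out, "history") <- history
    out
  })
}

#' Decoder scores for gene pairs
#'
#' Inner-product decoder through the logistic link:
#' \code{plogis(z_a . z_b)}, strictly inside (0, 1) and symmetric in the
#' pair.
#'
#' @param table a \linkS4class{GeneEmbeddingTable}.
#' @param pairs two-column matrix or data.frame of gene identifiers.
#' @return numeric vector of scores in (0, 1).
#' @export
scoreEdges <- function(table, pairs) {
  pairs <- as.matrix(pairs)
  m <- embeddingMatrix(table)
  unknown <- setdiff(unique(c(pairs)), rownames(m))
  if (length(unknown))
    stop(sprintf("unknown gene(s): %s", paste(head(unknown, 3L), collapse = ", ")),
         call. = FALSE)
  a <- m[pairs[, 1L], , drop = FALSE]
  b <- m[pairs[, 2L], , drop = FALSE]
  unname(stats::plogis(rowSums(a * b)))
}
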