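# Cell-line representations: the interactome feature (mean embedding of the
# most highly expressed genes) and the transcriptome feature (denoising
# auto-encoder latent vector over the standardized expression profile).

#' Select the most highly expressed genes of a profile
#'
#' Returns up to \code{k} genes, descending by expression with ties broken
#' by ascending gene identifier; only genes in \code{eligible} are
#' considered (genes without an embedding are excluded before ranking).
#'
#' @param profile an \linkS4class{ExpressionProfile}.
#' @param k number of genes to select (paper default 256).
#' @param eligible character vector of eligible gene identifiers.
#' @return ordered character vector of selected gene identifiers.
#' @export
selectTopGenes <- function(profile, k = 256L, eligible = geneIds(profile)) {
  stopifnot(k >= 1L, length(eligible) > 0L)
  v <- exprValues(profile)
  v <- v[names(v) %in% eligible]
  if (length(v) == 0L)
    stop(sprintf("no eligible gene present in profile of cell '%s'",
                 cellId(profile)), call. = FALSE)
  ord <- order(-v, names(v))
  names(v)[ord][seq_len(min(k, length(v)))]
}

#' Interactome feature of a cell line
#'
#' Element-wise mean of the embeddings of the top-\code{k} expressed genes
#' among those present in the embedding table.
#'
#' @param profile an \linkS4class{ExpressionProfile}.
#' @param table a \linkS4class{GeneEmbeddingTable}.
#' @param k number of genes averaged (paper default 256).
#' @return numeric vector of length \code{embeddingDim(table)}.
#' @export
interactomeFeature <- function(profile, table, k = 256L) {
  sel <- selectTopGenes(profile, k, eligible = geneIds(table))
  colMeans(embeddingMatrix(table)[sel, , drop = FALSE])
}

#' Configuration for the denoising auto-encoder
#'
#' @param hidden_dims hidden-layer widths; must be palindromic with odd
#'   length; the middle entry is the latent dimension (paper default
#'   \code{c(2048, 1024, 512, 1024, 2048)}).
#' @param noise_sigma std of the additive Gaussian corruption applied to
#'   the standardized inputs during training.
#' @param epochs training epochs (0 returns the seeded initialisation).
#' @param learning_rate Adam learning rate.
#' @param batch_size mini-batch size.
#' @param seed RNG seed.
#' @return validated config list.
#' @export
daeConfig <- function(hidden_dims = c(2048L, 1024L, 512L, 1024L, 2048L),
                      noise_sigma = 0.1, epochs = 100L, learning_rate = 1e-4,
                      batch_size = 64L, seed = 1L) {
  hidden_dims <- as.integer(hidden_dims)
  if (length(hidden_dims) %% 2L == 0L ||
      !identical(hidden_dims, rev(hidden_dims)))
    stop("hidden_dims must be palindromic with odd length", call. = FALSE)
  stopifnot(noise_sigma >= 0, epochs >= 0L, learning_rate > 0, batch_size >= 1L)
  list(hidden_dims = hidden_dims, noise_sigma = noise_sigma,
       epochs = as.integer(epochs), learning_rate = learning_rate,
       batch_size = as.integer(batch_size), seed = as.integer(seed))
}

.check_alignment <- function(profiles, genes) {
  for (p in profiles) {
    g <- geneIds(p)
    if (!identical(g, genes)) {
      i <- which(g != genes[seq_along(g)])[1L]
      if (is.na(i)) i <- min(length(g), length(genes)) + 1L
      stop(sprintf("gene list mismatch for cell '%s' at position %d ('%s' vs '%s')",
                   cellId(p), i,
                   if (i <= length(g)) g[i] else "<missing>",
                   if (i <= length(genes)) genes[i] else "<missing>"),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# MLP forward over node x; ReLU on all but the last layer
.mlp_forward <- function(x, layers) {
  nl <- length(layers)
  for (k in seq_len(nl)) {
    x <- linearOp(x, layers[[k]])
    if (k < nl) x <- adRelu(x)
  }
  x
}

#' Train the denoising auto-encoder on expression profiles
#'
#' Inputs are standardized per gene (z-score over the training cells; the
#' scaler is stored with the model). During training, Gaussian noise of
#' std \code{noise_sigma} corrupts the standardized input; the loss is the
#' MSE between the reconstruction and the clean standardized profile.
#'
#' @param profiles list of \linkS4class{ExpressionProfile} sharing one gene
#'   list (same order).
#' @param config a \code{\link{daeConfig}}.
#' @param verbose print per-epoch loss.
#' @return a \linkS4class{DenoisingAutoencoder}.
#' @export
trainDAE <- function(profiles, config = daeConfig(), verbose = FALSE) {
  stopifnot(length(profiles) >= 2L)
  genes <- geneIds(profiles[[1L]])
  .check_alignment(profiles, genes)
  X <- do.call(rbind, lapply(profiles, function(p) p@values))
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  G <- length(genes)
  dims <- c(G, config$hidden_dims, G)

  withr::with_seed(config$seed, {
    layers <- lapply(seq_len(length(dims) - 1L), function(k)
      initLinear(dims[k], dims[k + 1L]))
    opt <- adamInit(layers)
    history <- numeric(config$epochs)
    n <- nrow(Xs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        adResetTape()
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        clean <- Xs[idx, , drop = FALSE]
        noisy <- clean + if (config$noise_sigma > 0)
          matrix(stats::rnorm(length(clean), 0, config$noise_sigma),
                 nrow(clean)) else 0
        nodes <- wrapParams(layers)
        pred <- .mlp_forward(adConst(noisy), nodes)
        loss <- adMSELoss(pred, clean)
        adBackward(loss)
        ep_loss <- ep_loss + loss$value[1L] * length(idx)
        step <- adamStep(opt, layers, gradsOf(nodes), config$learning_rate)
        layers <- step$params; opt <- step$opt
      }
      history[ep] <- ep_loss / n
      if (verbose) message(sprintf("DAE epoch %d: MSE %.5f", ep, history[ep]))
    }
    new("DenoisingAutoencoder", params = layers,
        scaler = list(center = center, scale = scale), genes = genes,
        config = config, history = history)
  })
}

#' Encode a profile into the transcriptome latent vector
#'
#' Deterministic encoder pass (no noise): standardize with the stored
#' scaler, then apply layers up to and including the middle (latent) layer
#' with ReLU activations.
#'
#' @param profile an \linkS4class{ExpressionProfile}; its gene list must
#'   match the training gene list exactly.
#' @param dae a \linkS4class{DenoisingAutoencoder}.
#' @return numeric latent vector of length \code{latentDim(dae)}.
#' @export
encodeTranscriptome <- function(profile, dae) {
  .check_alignment(list(profile), dae@genes)
  x <- (profile@values - dae@scaler$center) / dae@scaler$scale
  mid <- (length(dae@config$hidden_dims) + 1L) %/% 2L
  h <- matrix(x, nrow = 1L)
  for (k in seq_len(mid)) {
    lin <- dae@params[[k]]
    h <- pmax(sweep(h %*% lin$W, 2L, lin$b[1L, ], "+"), 0)
  }
  h[1L, ]
}

#' Reconstruct a profile through the full auto-encoder (no noise)
#' @param profile an \linkS4class{ExpressionProfile}.
#' @param dae a \linkS4class{DenoisingAutoencoder}.
#' @return reconstructed standardized expression vector.
#' @export
reconstructTranscriptome <- function(profile, dae) {
  .check_alignment(list(profile), dae@genes)
  x <- (profile@values - dae@scaler$center) / dae@scaler$scale
  h <- matrix(x, nrow = 1L)
  nl <- length(dae@params)
  for (k in seq_len(nl)) {
    lin <- dae@params[[k]]
    h <- sweep(h %*% lin$W, 2L, lin$b[1L, ], "+")
    if (k < nl) h <- pmax(h, 0)
  }
  h[1L, ]
}

#' Build CellRepresentation objects for a set of profiles
#'
#' @param profiles list of \linkS4class{ExpressionProfile}.
#' @param table a \linkS4class{GeneEmbeddingTable}.
#' @param dae a trained \linkS4class{DenoisingAutoencoder}, or NULL when
#'   \code{transcriptome = "raw"}.
#' @param k top-gene count for the interactome feature.
#' @param transcriptome \code{"dae"} (latent vector) or \code{"raw"}
#'   (standardized expression, the DIM ablation).
#' @return named list of \linkS4class{CellRepresentation}.
#' @export
buildCellRepresentations <- function(profiles, table, dae = NULL, k = 256L,
                                     transcriptome = c("dae", "raw")) {
  transcriptome <- match.arg(transcriptome)
  if (transcriptome == "raw") {
    genes <- geneIds(profiles[[1L]])
    .check_alignment(profiles, genes)
    X <- do.call(rbind, lapply(profiles, function(p) p@values))
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[scale == 0] <- 1
  }
  out <- lapply(profiles, function(p) {
    trn <- if (transcriptome == "dae") encodeTranscriptome(p, dae)
           else (p@values - center) / scale
    new("CellRepresentation", cellId = cellId(p),
        interactome = interactomeFeature(p, table, k),
        transcriptome = as.numeric(trn))
  })
  names(out) <- vapply(profiles, cellId, character(1))
  out
}
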