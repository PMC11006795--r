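# Attention fusion of cell and drug representations, and the LN IC50
# regression head.
#
# Each cell feature (interactome, transcriptome) passes a ReLU linear layer
# preserving its dimensionality; the pre-activation linear output serves as
# the query of a multi-head attention pool over the drug's atom vectors
# (scaled by sqrt of the atomic feature dimension). The molecular feature is
# the sum of the two attention outputs, the cell summary the sum of the two
# ReLU outputs; their concatenation feeds the fully connected head. The DEM
# variant drops the interactome branch; the DIM variant feeds standardized
# raw expression instead of the auto-encoder latent.

#' Configuration for the fusion model
#'
#' @param variant \code{"DIPK"} (full model), \code{"DEM"} (no interactome
#'   branch) or \code{"DIM"} (raw standardized expression instead of the
#'   DAE latent).
#' @param share_parameters share weights between the two branch linear
#'   layers and between the two attention layers (the generalization
#'   setting); set FALSE for the learned-cells-and-drugs protocol.
#' @param attention_heads number of attention heads.
#' @param head_dims fully connected head widths; must start at
#'   \code{d_atom + d_cell} and end at 1 (paper default
#'   \code{c(1280, 512, 256, 128, 1)} = \code{c(768 + 512, ...)}).
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param seed RNG seed.
#' @param freeze_encoder if TRUE the drug encoder is not updated during
#'   response training.
#' @return validated config list.
#' @export
fusionConfig <- function(variant = c("DIPK", "DEM", "DIM"),
                         share_parameters = TRUE, attention_heads = 4L,
                         head_dims = c(1280L, 512L, 256L, 128L, 1L),
                         learning_rate = 1e-4, epochs = 100L,
                         batch_size = 64L, seed = 1L,
                         freeze_encoder = FALSE) {
  variant <- match.arg(variant)
  head_dims <- as.integer(head_dims)
  if (tail(head_dims, 1L) != 1L)
    stop("head_dims must end at 1", call. = FALSE)
  stopifnot(attention_heads >= 1L, learning_rate > 0, epochs >= 0L,
            batch_size >= 1L)
  list(variant = variant, share_parameters = isTRUE(share_parameters),
       attention_heads = as.integer(attention_heads), head_dims = head_dims,
       learning_rate = learning_rate, epochs = as.integer(epochs),
       batch_size = as.integer(batch_size), seed = as.integer(seed),
       freeze_encoder = isTRUE(freeze_encoder))
}

.attn_set <- function(d_query, d_atom) {
  list(q = initLinear(d_query, d_atom), k = initLinear(d_atom, d_atom),
       v = initLinear(d_atom, d_atom), o = initLinear(d_atom, d_atom))
}

#' Initialise fusion parameters
#'
#' @param config a \code{\link{fusionConfig}}.
#' @param d_cell branch output width (interactome / latent dimension).
#' @param d_atom atom feature width.
#' @param d_trn_in transcriptome input width (equals \code{d_cell} except
#'   for DIM, where it is the gene count).
#' @return nested parameter list.
#' @export
initFusionParams <- function(config, d_cell, d_atom, d_trn_in = d_cell) {
  if (config$head_dims[1L] != d_atom + d_cell)
    stop(sprintf("head_dims[1] must equal d_atom + d_cell (%d + %d)",
                 d_atom, d_cell), call. = FALSE)
  share_branch <- config$share_parameters && config$variant == "DIPK"
  share_attn <- config$share_parameters && config$variant != "DEM"
  withr::with_seed(config$seed, {
    branch <- if (config$variant == "DEM")
      list(trn = initLinear(d_trn_in, d_cell))
    else if (share_branch)
      list(shared = initLinear(d_cell, d_cell))
    else
      list(int = initLinear(d_cell, d_cell),
           trn = initLinear(d_trn_in, d_cell))
    attn <- if (config$variant == "DEM")
      list(trn = .attn_set(d_cell, d_atom))
    else if (share_attn)
      list(shared = .attn_set(d_cell, d_atom))
    else
      list(int = .attn_set(d_cell, d_atom), trn = .attn_set(d_cell, d_atom))
    hd <- config$head_dims
    head <- lapply(seq_len(length(hd) - 1L), function(k)
      initLinear(hd[k], hd[k + 1L]))
    list(branch = branch, attn = attn, head = head)
  })
}

.pick <- function(group, which) {
  if (!is.null(group$shared)) group$shared else group[[which]]
}

# multi-head attention pool for a group of queries against one atom matrix;
# K/V may be passed in precomputed (kv) to avoid recomputation across groups
.pool_group <- function(Qg, atoms, aset, heads, d_atom, kv = NULL) {
  K <- if (is.null(kv)) linearOp(atoms, aset$k) else kv$K
  V <- if (is.null(kv)) linearOp(atoms, aset$v) else kv$V
  dh <- d_atom %/% heads
  n <- nrow(.val(atoms))
  ones <- matrix(1, nrow(.val(Qg)), n)
  outs <- vector("list", heads)
  for (hh in seq_len(heads)) {
    cols <- ((hh - 1L) * dh + 1L):(hh * dh)
    scores <- adScale(adMatmul(adCols(Qg, cols), adTranspose(adCols(K, cols))),
                      1 / sqrt(d_atom))
    alpha <- adMaskedSoftmax(scores, ones)
    outs[[hh]] <- adMatmul(alpha, adCols(V, cols))
  }
  linearOp(do.call(adCbind, outs), aset$o)
}

# pooled attention output for a whole batch, grouped by drug
.pool_batch <- function(Q_all, drug_ids, drug_nodes, aset, heads, d_atom,
                        kv_cache = NULL) {
  groups <- split(seq_along(drug_ids), drug_ids)
  pooled <- vector("list", length(groups))
  order_idx <- integer(0)
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    pooled[[k]] <- .pool_group(adRows(Q_all, idx), drug_nodes[[names(groups)[k]]],
                               aset, heads, d_atom,
                               kv = kv_cache[[names(groups)[k]]])
    order_idx <- c(order_idx, idx)
  }
  stacked <- if (length(pooled) == 1L) pooled[[1L]] else do.call(adRbind, pooled)
  adRows(stacked, order(order_idx))
}

# full fusion forward on nodes; Fint may be NULL for DEM
.fusion_forward <- function(p, config, Fint, Ftrn, drug_ids, drug_nodes, d_atom) {
  H <- config$attention_heads
  aset_t <- .pick(p$attn, "trn")
  # K/V depend only on the atoms and the attention parameter set: compute
  # once per drug (and reuse across branches when the set is shared)
  kv_t <- lapply(drug_nodes, function(atoms)
    list(K = linearOp(atoms, aset_t$k), V = linearOp(atoms, aset_t$v)))
  et_lin <- linearOp(Ftrn, .pick(p$branch, "trn"))
  et <- adRelu(et_lin)
  Qt <- linearOp(et_lin, aset_t$q)
  pool_t <- .pool_batch(Qt, drug_ids, drug_nodes, aset_t, H, d_atom, kv_t)
  if (config$variant == "DEM") {
    mol <- pool_t
    cell <- et
  } else {
    aset_i <- .pick(p$attn, "int")
    kv_i <- if (!is.null(p$attn$shared)) kv_t else
      lapply(drug_nodes, function(atoms)
        list(K = linearOp(atoms, aset_i$k), V = linearOp(atoms, aset_i$v)))
    ei_lin <- linearOp(Fint, .pick(p$branch, "int"))
    ei <- adRelu(ei_lin)
    Qi <- linearOp(ei_lin, aset_i$q)
    pool_i <- .pool_batch(Qi, drug_ids, drug_nodes, aset_i, H, d_atom, kv_i)
    mol <- adAdd(pool_i, pool_t)
    cell <- adAdd(ei, et)
  }
  .mlp_forward(adCbind(mol, cell), p$head)
}

#' Multi-head attention pool of atom features for one query
#'
#' The query feature passes a linear layer (no activation) to form Q; K and
#' V come from two independent linear maps of the atom matrix. Per head,
#' \code{softmax(QK'/sqrt(d_k)) V} with \code{d_k} the atomic feature
#' dimension; heads are concatenated and linearly mixed.
#'
#' @param query numeric query feature vector.
#' @param atoms atom feature matrix (atoms x d_atom).
#' @param params list with linear layers \code{q}, \code{k}, \code{v},
#'   \code{o} (each \code{list(W, b)}).
#' @param heads number of attention heads.
#' @return numeric vector of length \code{d_atom}.
#' @export
attentionPool <- function(query, atoms, params, heads = 1L) {
  atoms <- as.matrix(atoms)
  d_atom <- ncol(atoms)
  if (ncol(params$q$W) != d_atom || nrow(params$k$W) != d_atom)
    stop("attention parameter shapes do not match the atom features",
         call. = FALSE)
  adResetTape()
  pn <- rapply(params, adConst, classes = c("matrix", "numeric", "array"),
               how = "replace")
  Qg <- linearOp(adConst(matrix(query, nrow = 1L)), pn$q)
  out <- .pool_group(Qg, adConst(atoms), pn, heads, d_atom)
  out$value[1L, ]
}

#' Single-pair fusion forward pass
#'
#' @param params fusion parameter list (see \code{\link{initFusionParams}}).
#' @param config a \code{\link{fusionConfig}}.
#' @param interactome interactome feature vector (ignored for DEM).
#' @param transcriptome transcriptome feature vector.
#' @param atoms atom feature matrix of the drug.
#' @return predicted LN IC50 (scalar).
#' @export
fusionForward <- function(params, config, interactome, transcriptome, atoms) {
  adResetTape()
  p <- rapply(params, adConst, classes = c("matrix", "numeric", "array"),
              how = "replace")
  out <- .fusion_forward(
    p, config,
    Fint = if (config$variant == "DEM") NULL else
      adConst(matrix(interactome, nrow = 1L)),
    Ftrn = adConst(matrix(transcriptome, nrow = 1L)),
    drug_ids = "drug", drug_nodes = list(drug = adConst(as.matrix(atoms))),
    d_atom = ncol(as.matrix(atoms)))
  out$value[1L, 1L]
}

.rep_matrix <- function(cell_reps, ids, slot) {
  do.call(rbind, lapply(cell_reps[ids], function(r)
    if (slot == "interactome") r@interactome else r@transcriptome))
}

#' Train the attention-fusion response model
#'
#' Minimises the mean squared error of the predicted against the observed
#' LN IC50 over mini-batches with Adam. Gradients flow into the drug
#' encoder unless \code{config$freeze_encoder} is TRUE (frozen encoders
#' have their atom features precomputed once).
#'
#' @param responses data.frame with \code{cell_id}, \code{drug_id},
#'   \code{ln_ic50}.
#' @param cell_reps named list of \linkS4class{CellRepresentation}.
#' @param drug_graphs named list of \linkS4class{MolecularGraph} keyed by
#'   drug id.
#' @param encoder a \linkS4class{DrugEncoder}.
#' @param config a \code{\link{fusionConfig}}.
#' @param verbose print per-epoch loss.
#' @return a \linkS4class{ResponseModel}.
#' @export
trainResponseModel <- function(responses, cell_reps, drug_graphs, encoder,
                               config = fusionConfig(), verbose = FALSE) {
  bad <- which(!(responses$cell_id %in% names(cell_reps)) |
                 !(responses$drug_id %in% names(drug_graphs)))
  if (length(bad))
    stop(sprintf("unresolvable response record (cell '%s', drug '%s')",
                 responses$cell_id[bad[1L]], responses$drug_id[bad[1L]]),
         call. = FALSE)
  d_atom <- encoder@config$d_atom
  r1 <- cell_reps[[1L]]
  d_cell <- if (config$variant == "DEM") length(r1@transcriptome)
            else length(r1@interactome)
  d_trn_in <- length(r1@transcriptome)
  if (config$variant %in% c("DIPK") && d_trn_in != d_cell)
    stop("DIPK requires interactome and transcriptome features of equal length",
         call. = FALSE)
  if (config$head_dims[1L] != d_atom + d_cell)
    stop(sprintf("head_dims[1] (%d) must equal d_atom + d_cell (%d + %d)",
                 config$head_dims[1L], d_atom, d_cell), call. = FALSE)

  used_drugs <- unique(responses$drug_id)
  preps <- lapply(drug_graphs[used_drugs], prepGraph)
  frozen_feats <- if (config$freeze_encoder)
    lapply(drug_graphs[used_drugs], encodeDrug, encoder = encoder)

  params <- initFusionParams(config, d_cell, d_atom, d_trn_in)
  enc_params <- encoder@params
  y <- matrix(responses$ln_ic50, ncol = 1L)
  n <- nrow(responses)
  history <- numeric(config$epochs)

  withr::with_seed(config$seed, {
    trainable <- if (config$freeze_encoder) list(fus = params)
                 else list(fus = params, enc = enc_params)
    opt <- adamInit(trainable)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        adResetTape()
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        nodes <- wrapParams(trainable)
        batch_drugs <- unique(responses$drug_id[idx])
        drug_nodes <- if (config$freeze_encoder)
          lapply(frozen_feats[batch_drugs], adConst)
        else
          lapply(preps[batch_drugs], .encode_graph_node, p = nodes$enc,
                 config = encoder@config)
        pred <- .fusion_forward(
          nodes$fus, config,
          Fint = if (config$variant == "DEM") NULL else
            adConst(.rep_matrix(cell_reps, responses$cell_id[idx], "interactome")),
          Ftrn = adConst(.rep_matrix(cell_reps, responses$cell_id[idx], "transcriptome")),
          drug_ids = responses$drug_id[idx], drug_nodes = drug_nodes,
          d_atom = d_atom)
        loss <- adMSELoss(pred, y[idx, , drop = FALSE])
        adBackward(loss)
        ep_loss <- ep_loss + loss$value[1L] * length(idx)
        step <- adamStep(opt, trainable, gradsOf(nodes), config$learning_rate)
        trainable <- step$params; opt <- step$opt
      }
      history[ep] <- ep_loss / n
      if (verbose) message(sprintf("fusion epoch %d: MSE %.5f", ep, history[ep]))
    }
    final_encoder <- if (config$freeze_encoder) encoder else
      new("DrugEncoder", params = trainable$enc, config = encoder@config,
          vocab = encoder@vocab)
    new("ResponseModel", params = trainable$fus, config = config,
        dims = list(d_cell = d_cell, d_atom = d_atom, d_trn_in = d_trn_in),
        encoder = final_encoder, history = history)
  })
}

#' Predict LN IC50 for (cell, drug) pairs
#'
#' Deterministic, order-preserving inference with no training-mode noise.
#'
#' @param model a \linkS4class{ResponseModel}.
#' @param pairs data.frame with columns \code{cell_id}, \code{drug_id}.
#' @param cell_reps named list of \linkS4class{CellRepresentation}.
#' @param drug_graphs named list of \linkS4class{MolecularGraph}.
#' @return data.frame with \code{cell_id}, \code{drug_id},
#'   \code{predicted_ln_ic50}.
#' @export
predictResponse <- function(model, pairs, cell_reps, drug_graphs) {
  unknown_c <- setdiff(pairs$cell_id, names(cell_reps))
  if (length(unknown_c))
    stop(sprintf("unknown cell id: %s", unknown_c[1L]), call. = FALSE)
  unknown_d <- setdiff(pairs$drug_id, names(drug_graphs))
  if (length(unknown_d))
    stop(sprintf("unknown drug id: %s", unknown_d[1L]), call. = FALSE)
  config <- model@config
  feats <- lapply(drug_graphs[unique(pairs$drug_id)], encodeDrug,
                  encoder = model@encoder)
  adResetTape()
  p <- rapply(model@params, adConst, classes = c("matrix", "numeric", "array"),
              how = "replace")
  out <- .fusion_forward(
    p, config,
    Fint = if (config$variant == "DEM") NULL else
      adConst(.rep_matrix(cell_reps, pairs$cell_id, "interactome")),
    Ftrn = adConst(.rep_matrix(cell_reps, pairs$cell_id, "transcriptome")),
    drug_ids = pairs$drug_id, drug_nodes = lapply(feats, adConst),
    d_atom = model@dims$d_atom)
  data.frame(cell_id = pairs$cell_id, drug_id = pairs$drug_id,
             predicted_ln_ic50 = out$value[, 1L], stringsAsFactors = FALSE)
}

#' @export
setGeneric("countParameters", function(x) standardGeneric("countParameters"))
#' @describeIn ResponseModel number of trainable fusion parameters
#' @param x object
#' @export
setMethod("countParameters", "ResponseModel", function(x) paramCount(x@params))
#' @export
setMethod("countParameters", "DrugEncoder", function(x) paramCount(x@params))
#' @export
setMethod("countParameters", "DenoisingAutoencoder", function(x) paramCount(x@params))

#' Count fusion parameters for a config without training
#' @param config a \code{\link{fusionConfig}}.
#' @param d_cell branch width.
#' @param d_atom atom feature width.
#' @param d_trn_in transcriptome input width.
#' @export
countFusionParameters <- function(config, d_cell, d_atom, d_trn_in = d_cell) {
  paramCount(initFusionParams(config, d_cell, d_atom, d_trn_in))
}
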