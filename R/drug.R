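# Molecular graphs and the neighbour-attention message-passing encoder.
#
# SMILES are parsed through ChemmineR/ChemmineOB (OpenBabel). The encoder
# follows the message-passing scheme: per step, each atom aggregates its
# neighbours' states plus bond-type embeddings through multi-head dot-product
# attention, and updates its state with a GRU cell whose initial hidden state
# is the atom's attribute embedding.

ELEMENT_VOCAB <- c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "As", "Se",
                   "Br", "I", "Zn", "Fe", "other", "<mask>")
DEGREE_VOCAB <- 0:6
CHARGE_VOCAB <- -2:2
BOND_VOCAB <- c("single", "double", "triple", "aromatic")

# V2000 old-style charge codes
.sdf_charge <- function(code) {
  c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2,
    `7` = -3)[as.character(code)]
}

# lexical sanity checks; OpenBabel silently repairs some malformed SMILES
.smiles_sanity <- function(drug_id, smiles) {
  s <- trimws(smiles)
  if (!nzchar(s))
    stop(sprintf("empty SMILES for drug '%s'", drug_id), call. = FALSE)
  if (grepl(".", s, fixed = TRUE))
    stop(sprintf("disconnected (multi-fragment) SMILES for drug '%s'; strip salts upstream",
                 drug_id), call. = FALSE)
  chars <- strsplit(s, "")[[1L]]
  depth <- 0L; bracket <- FALSE; rings <- integer()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (bracket) {
      if (ch == "]") bracket <- FALSE
    } else if (ch == "[") bracket <- TRUE
    else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) break
    } else if (grepl("[0-9]", ch)) {
      rings <- c(rings, as.integer(ch))
    } else if (ch == "%" && i + 2L <= length(chars)) {
      rings <- c(rings, as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 2L
    }
    i <- i + 1L
  }
  ring_ok <- all(table(rings) %% 2L == 0L)
  if (depth != 0L || bracket || !ring_ok)
    stop(sprintf("malformed SMILES for drug '%s'", drug_id), call. = FALSE)
  invisible(TRUE)
}

#' Convert a SMILES string to a MolecularGraph
#'
#' Heavy atoms only (hydrogens implicit); atoms carry element, heavy-atom
#' degree, formal charge and an aromatic flag; bonds carry
#' single/double/triple/aromatic types. Multi-fragment SMILES (salts) are
#' rejected.
#'
#' @param drug_id drug identifier used in error messages.
#' @param smiles SMILES string.
#' @return a \linkS4class{MolecularGraph}.
#' @export
smilesToGraph <- function(drug_id, smiles) {
  .smiles_sanity(drug_id, smiles)
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n")),
    error = function(e) "")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  if (length(lines) < 4L)
    stop(sprintf("cannot parse SMILES for drug '%s'", drug_id), call. = FALSE)
  counts <- lines[4L]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(n_atoms) || n_atoms < 1L)
    stop(sprintf("cannot parse SMILES for drug '%s'", drug_id), call. = FALSE)

  if (n_atoms == 1L) {
    # ChemmineR's container mishandles one-atom molecules; read the single
    # V2000 atom line directly.
    fields <- strsplit(trimws(lines[5L]), "\\s+")[[1L]]
    element <- fields[4L]
    charge <- .sdf_charge(fields[6L])
    chg_line <- grep("^M  CHG", lines, value = TRUE)
    if (length(chg_line)) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", chg_line[1L])),
                               "\\s+")[[1L]])
      charge <- f[3L]
    }
    atoms <- data.frame(element = element, degree = 0L,
                        charge = as.integer(charge), aromatic = FALSE,
                        stringsAsFactors = FALSE)
    bonds <- data.frame(a1 = integer(), a2 = integer(), type = character(),
                        stringsAsFactors = FALSE)
    return(new("MolecularGraph", drugId = as.character(drug_id),
               atoms = atoms, bonds = bonds))
  }

  parsed <- tryCatch({
    sdf <- suppressWarnings(ChemmineR::read.SDFset(lines))
    mol <- sdf[[1L]]
    list(mol = mol, ab = ChemmineR::atomblock(mol),
         bb = ChemmineR::bondblock(mol))
  }, error = function(e) NULL)
  if (is.null(parsed) || nrow(parsed$ab) != n_atoms)
    stop(sprintf("cannot parse SMILES for drug '%s'", drug_id), call. = FALSE)
  mol <- parsed$mol; ab <- parsed$ab; bb <- parsed$bb
  elements <- sub("_.*$", "", rownames(ab))
  charges <- if ("C6" %in% colnames(ab)) .sdf_charge(ab[, "C6"]) else
    rep(0, n_atoms)
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  for (cl in chg_lines) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "\\s+")[[1L]])
    np <- f[1L]
    for (k in seq_len(np)) charges[f[2L * k]] <- f[2L * k + 1L]
  }

  bonds <- data.frame(a1 = as.integer(bb[, 1L]), a2 = as.integer(bb[, 2L]),
                      order = as.integer(bb[, 3L]), stringsAsFactors = FALSE)

  # aromatic perception from ring analysis
  aromatic_atoms <- rep(FALSE, n_atoms)
  ring_bond_key <- character()
  if (n_bonds > 0L && n_atoms >= 3L) {
    ringinfo <- tryCatch(
      ChemmineR::rings(mol, type = "all", arom = TRUE, inner = FALSE),
      error = function(e) NULL)
    if (!is.null(ringinfo) && length(ringinfo$RINGS)) {
      for (rn in names(ringinfo$RINGS)) {
        if (!isTRUE(ringinfo$AROMATIC[[rn]])) next
        members <- as.integer(sub("^.*_", "", ringinfo$RINGS[[rn]]))
        aromatic_atoms[members] <- TRUE
        cyc <- cbind(members, c(members[-1L], members[1L]))
        ring_bond_key <- c(ring_bond_key,
                           paste(pmin(cyc[, 1L], cyc[, 2L]),
                                 pmax(cyc[, 1L], cyc[, 2L])))
      }
    }
  }
  bkey <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
  type <- c("single", "double", "triple")[pmin(bonds$order, 3L)]
  type[bkey %in% ring_bond_key] <- "aromatic"

  atoms <- data.frame(element = elements,
                      degree = as.integer(tabulate(c(bonds$a1, bonds$a2),
                                                   nbins = n_atoms)),
                      charge = as.integer(charges),
                      aromatic = aromatic_atoms, stringsAsFactors = FALSE)
  out <- tryCatch(
    new("MolecularGraph", drugId = as.character(drug_id), atoms = atoms,
        bonds = data.frame(a1 = bonds$a1, a2 = bonds$a2, type = type,
                           stringsAsFactors = FALSE)),
    error = function(e)
      stop(sprintf("invalid molecule for drug '%s': %s", drug_id,
                   conditionMessage(e)), call. = FALSE))
  out
}

#' Configuration for the drug encoder
#'
#' @param d_atom atom vector width (default 768).
#' @param message_steps number of message-passing steps (default 5).
#' @param attention_heads number of attention heads; must divide
#'   \code{d_atom}.
#' @param seed RNG seed for parameter initialisation.
#' @return validated config list.
#' @export
encoderConfig <- function(d_atom = 768L, message_steps = 5L,
                          attention_heads = 4L, seed = 1L) {
  stopifnot(d_atom >= 1L, message_steps >= 1L, attention_heads >= 1L)
  if (d_atom %% attention_heads != 0L)
    stop("d_atom must be divisible by attention_heads", call. = FALSE)
  list(d_atom = as.integer(d_atom), message_steps = as.integer(message_steps),
       attention_heads = as.integer(attention_heads), seed = as.integer(seed))
}

#' Initialise a DrugEncoder with random weights
#'
#' @param config an \code{\link{encoderConfig}}.
#' @return a \linkS4class{DrugEncoder}.
#' @export
initDrugEncoder <- function(config = encoderConfig()) {
  d <- config$d_atom
  vocab <- list(element = ELEMENT_VOCAB, degree = DEGREE_VOCAB,
                charge = CHARGE_VOCAB, bond = BOND_VOCAB)
  params <- withr::with_seed(config$seed, list(
    emb_element = glorot(length(ELEMENT_VOCAB), d),
    emb_degree = glorot(length(DEGREE_VOCAB), d),
    emb_charge = glorot(length(CHARGE_VOCAB), d),
    emb_aromatic = glorot(2L, d),
    emb_bond = glorot(length(BOND_VOCAB), d),
    attn = list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
                Wo = glorot(d, d)),
    gru = initGRU(d, d)
  ))
  new("DrugEncoder", params = params, config = config, vocab = vocab)
}

# categorical indices and constant masks used by the encoder forward pass
prepGraph <- function(graph, vocab = NULL) {
  a <- atomTable(graph)
  b <- bondTable(graph)
  n <- nrow(a)
  elem <- match(a$element, ELEMENT_VOCAB)
  elem[is.na(elem)] <- match("other", ELEMENT_VOCAB)
  deg <- match(pmin(a$degree, max(DEGREE_VOCAB)), DEGREE_VOCAB)
  chg <- match(pmax(pmin(a$charge, max(CHARGE_VOCAB)), min(CHARGE_VOCAB)),
               CHARGE_VOCAB)
  arom <- as.integer(a$aromatic) + 1L
  support <- matrix(0, n, n)
  type_masks <- lapply(BOND_VOCAB, function(tp) matrix(0, n, n))
  names(type_masks) <- BOND_VOCAB
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      i <- b$a1[k]; j <- b$a2[k]; tp <- b$type[k]
      support[i, j] <- support[j, i] <- 1
      type_masks[[tp]][i, j] <- type_masks[[tp]][j, i] <- 1
    }
  }
  list(n = n, elem = elem, deg = deg, chg = chg, arom = arom,
       support = support, type_masks = type_masks,
       has_bonds = nrow(b) > 0L)
}

# encoder forward pass on wrapped (node) params; returns n x d node
.encode_graph_node <- function(prep, p, config) {
  d <- config$d_atom
  H <- config$attention_heads
  dh <- d %/% H
  x <- adAdd(adAdd(adRows(p$emb_element, prep$elem),
                   adRows(p$emb_degree, prep$deg)),
             adAdd(adRows(p$emb_charge, prep$chg),
                   adRows(p$emb_aromatic, prep$arom)))
  for (t in seq_len(config$message_steps)) {
    if (prep$has_bonds) {
      Q <- adMatmul(x, p$attn$Wq)
      Kx <- adMatmul(x, p$attn$Wk)
      Ke <- adMatmul(p$emb_bond, p$attn$Wk)
      Vx <- adMatmul(x, p$attn$Wv)
      Ve <- adMatmul(p$emb_bond, p$attn$Wv)
      heads <- vector("list", H)
      for (hh in seq_len(H)) {
        cols <- ((hh - 1L) * dh + 1L):(hh * dh)
        Qh <- adCols(Q, cols); Kxh <- adCols(Kx, cols)
        Keh <- adCols(Ke, cols); Vxh <- adCols(Vx, cols)
        Veh <- adCols(Ve, cols)
        scores <- adMatmul(Qh, adTranspose(Kxh))
        QKe <- adMatmul(Qh, adTranspose(Keh))      # n x n_bond_types
        for (ci in seq_along(BOND_VOCAB)) {
          M <- prep$type_masks[[ci]]
          if (!any(M > 0)) next
          scores <- adAdd(scores, adRowBcastMask(adCols(QKe, ci), M))
        }
        scores <- adScale(scores, 1 / sqrt(dh))
        alpha <- adMaskedSoftmax(scores, prep$support)
        mh <- adMatmul(alpha, Vxh)
        for (ci in seq_along(BOND_VOCAB)) {
          M <- prep$type_masks[[ci]]
          if (!any(M > 0)) next
          rs <- adRowSums(adMaskMul(alpha, M))
          mh <- adAdd(mh, adMatmul(rs, adRows(Veh, ci)))
        }
        heads[[hh]] <- mh
      }
      m <- adMatmul(do.call(adCbind, heads), p$attn$Wo)
    } else {
      m <- adConst(matrix(0, prep$n, d))
    }
    x <- gruOp(m, x, p$gru)
  }
  x
}

#' Encode a molecular graph into per-atom feature vectors
#'
#' @param graph a \linkS4class{MolecularGraph}.
#' @param encoder a \linkS4class{DrugEncoder}.
#' @return numeric matrix (atoms x \code{d_atom}) with attribute
#'   \code{drug_id}.
#' @export
encodeDrug <- function(graph, encoder) {
  adResetTape()
  prep <- prepGraph(graph)
  p <- rapply(encoder@params, adConst,
              classes = c("matrix", "numeric", "array"), how = "replace")
  out <- .encode_graph_node(prep, p, encoder@config)$value
  attr(out, "drug_id") <- drugId(graph)
  out
}

# -- pairwise half-graph discrimination --------------------------------------

# BFS bipartition from a random seed atom, balanced within +-1 atom
.split_halves <- function(prep) {
  n <- prep$n
  start <- sample.int(n, 1L)
  order <- integer(0)
  visited <- rep(FALSE, n)
  queue <- start
  visited[start] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    nb <- which(prep$support[v, ] > 0 & !visited)
    visited[nb] <- TRUE
    queue <- c(queue, nb)
  }
  order <- c(order, which(!visited))   # safety; graphs are connected
  k <- n %/% 2L
  list(a = sort(order[seq_len(k)]), b = sort(order[(k + 1L):n]))
}

# constants for the subgraph induced by atom subset `keep`
.induce <- function(prep, keep) {
  map <- match(seq_len(prep$n), keep)
  sub <- prep
  sub$n <- length(keep)
  sub$elem <- prep$elem[keep]
  sub$deg <- prep$deg[keep]
  sub$chg <- prep$chg[keep]
  sub$arom <- prep$arom[keep]
  sub$support <- prep$support[keep, keep, drop = FALSE]
  sub$type_masks <- lapply(prep$type_masks, function(M)
    M[keep, keep, drop = FALSE])
  sub$has_bonds <- any(sub$support > 0)
  sub
}

# classifier head is a one-hidden-layer MLP: same-source discrimination is a
# similarity predicate (XOR-like in the concatenated halves), which a purely
# linear head cannot express
.phd_logit <- function(preps_pair, p, head, config) {
  za <- adColMeans(.encode_graph_node(preps_pair[[1L]], p, config))
  zb <- adColMeans(.encode_graph_node(preps_pair[[2L]], p, config))
  linearOp(adRelu(linearOp(adCbind(za, zb), head$h1)), head$h2)
}

.phd_batch <- function(preps) {
  nmol <- length(preps)
  splits <- lapply(preps, .split_halves)
  pairs <- list(); labels <- numeric(0)
  for (i in seq_len(nmol)) {
    pairs[[length(pairs) + 1L]] <- list(.induce(preps[[i]], splits[[i]]$a),
                                        .induce(preps[[i]], splits[[i]]$b))
    labels <- c(labels, 1)
    cand <- setdiff(seq_len(nmol), i)
    j <- if (length(cand) == 1L) cand else sample(cand, 1L)
    pairs[[length(pairs) + 1L]] <- list(.induce(preps[[i]], splits[[i]]$a),
                                        .induce(preps[[j]], splits[[j]]$b))
    labels <- c(labels, 0)
  }
  list(pairs = pairs, labels = labels)
}

#' Pre-train the drug encoder with pairwise half-graph discrimination
#'
#' Each molecule is split into two balanced half-graphs by breadth-first
#' traversal from a random seed atom; a classifier head on the concatenated
#' mean-pooled half encodings learns to tell same-molecule pairs from
#' cross-molecule pairs. The head is discarded; the updated encoder is
#' returned with the held-out pretext accuracy (measured on fresh splits)
#' attached as attribute \code{phd_accuracy}.
#'
#' @param graphs list of \linkS4class{MolecularGraph}; graphs with fewer
#'   than 4 atoms are excluded with a warning.
#' @param encoder a \linkS4class{DrugEncoder}.
#' @param epochs training epochs (0 returns the encoder unchanged).
#' @param learning_rate Adam learning rate.
#' @param seed RNG seed.
#' @return the updated \linkS4class{DrugEncoder}.
#' @export
pretrainPHD <- function(graphs, encoder, epochs = 50L, learning_rate = 1e-3,
                        seed = 1L) {
  sizes <- vapply(graphs, function(g) nrow(atomTable(g)), integer(1))
  if (any(sizes < 4L)) {
    warning(sprintf("excluded %d graph(s) with < 4 atoms", sum(sizes < 4L)),
            call. = FALSE)
    graphs <- graphs[sizes >= 4L]
  }
  if (length(graphs) < 2L) stop("need >= 2 graphs with >= 4 atoms", call. = FALSE)
  config <- encoder@config
  preps <- lapply(graphs, prepGraph)
  params <- encoder@params
  if (epochs == 0L) return(encoder)

  withr::with_seed(seed, {
    head <- list(h1 = initLinear(2L * config$d_atom, config$d_atom),
                 h2 = initLinear(config$d_atom, 1L))
    all <- list(enc = params, head = head)
    opt <- adamInit(all)
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      adResetTape()
      batch <- .phd_batch(preps)
      nodes <- wrapParams(all)
      logits <- do.call(adRbind, lapply(batch$pairs, .phd_logit,
                                        p = nodes$enc, head = nodes$head,
                                        config = config))
      loss <- adBCEWithLogits(logits, matrix(batch$labels, ncol = 1L))
      adBackward(loss)
      history[ep] <- loss$value[1L]
      step <- adamStep(opt, all, gradsOf(nodes), learning_rate)
      all <- step$params; opt <- step$opt
    }
    # held-out probe: fresh random splits never used for a gradient step
    correct <- 0L; total <- 0L
    nodesc <- rapply(all, adConst, classes = c("matrix", "numeric", "array"),
                     how = "replace")
    for (rep_i in 1:5) {
      batch <- .phd_batch(preps)
      for (k in seq_along(batch$pairs)) {
        lg <- .phd_logit(batch$pairs[[k]], nodesc$enc, nodesc$head, config)
        correct <- correct + as.integer((lg$value[1L] > 0) == (batch$labels[k] > 0.5))
        total <- total + 1L
      }
    }
    out <- new("DrugEncoder", params = all$enc, config = config,
               vocab = encoder@vocab)
    attr(out, "phd_accuracy") <- correct / total
    attr(out, "history") <- history
    out
  })
}

#' Pre-train the drug encoder with atom attribute masking
#'
#' A fraction \code{mask_rate} of atoms per graph (floor, at least one graph
#' must yield >= 1) have their element replaced by the reserved mask token;
#' a linear head predicts the true element from the final atom vector. The
#' head is discarded.
#'
#' @param graphs list of \linkS4class{MolecularGraph}.
#' @param encoder a \linkS4class{DrugEncoder}.
#' @param mask_rate fraction of atoms masked per graph, in (0, 1).
#' @param epochs training epochs (0 returns the encoder unchanged).
#' @param learning_rate Adam learning rate.
#' @param seed RNG seed.
#' @return updated \linkS4class{DrugEncoder} with attribute
#'   \code{mask_accuracy} (held-out mask prediction accuracy).
#' @export
pretrainMask <- function(graphs, encoder, mask_rate = 0.15, epochs = 50L,
                         learning_rate = 1e-3, seed = 1L) {
  stopifnot(mask_rate > 0, mask_rate < 1)
  config <- encoder@config
  preps <- lapply(graphs, prepGraph)
  nmask <- vapply(preps, function(pp) as.integer(floor(mask_rate * pp$n)),
                  integer(1))
  if (!any(nmask >= 1L))
    stop("mask_rate yields zero masked atoms for every graph", call. = FALSE)
  if (epochs == 0L) return(encoder)
  mask_idx <- match("<mask>", ELEMENT_VOCAB)

  withr::with_seed(seed, {
    head <- initLinear(config$d_atom, length(ELEMENT_VOCAB))
    all <- list(enc = encoder@params, head = head)
    opt <- adamInit(all)
    history <- numeric(epochs)
    draw_losses <- function(nodes, collect_acc = FALSE) {
      losses <- list(); acc <- c(0L, 0L)
      for (gi in seq_along(preps)) {
        if (nmask[gi] < 1L) next
        pp <- preps[[gi]]
        sel <- sample.int(pp$n, nmask[gi])
        truth <- pp$elem[sel]
        pp$elem[sel] <- mask_idx
        x <- .encode_graph_node(pp, nodes$enc, config)
        logits <- linearOp(adRows(x, sel), nodes$head)
        losses[[length(losses) + 1L]] <- adSoftmaxCE(logits, truth)
        if (collect_acc) {
          pred <- max.col(logits$value)
          acc <- acc + c(sum(pred == truth), length(truth))
        }
      }
      total <- losses[[1L]]
      if (length(losses) > 1L)
        for (k in 2:length(losses)) total <- adAdd(total, losses[[k]])
      list(loss = adScale(total, 1 / length(losses)), acc = acc)
    }
    for (ep in seq_len(epochs)) {
      adResetTape()
      nodes <- wrapParams(all)
      out <- draw_losses(nodes)
      adBackward(out$loss)
      history[ep] <- out$loss$value[1L]
      step <- adamStep(opt, all, gradsOf(nodes), learning_rate)
      all <- step$params; opt <- step$opt
    }
    nodesc <- rapply(all, adConst, classes = c("matrix", "numeric", "array"),
                     how = "replace")
    acc <- c(0L, 0L)
    for (rep_i in 1:5) acc <- acc + draw_losses(nodesc, collect_acc = TRUE)$acc
    out <- new("DrugEncoder", params = all$enc, config = config,
               vocab = encoder@vocab)
    attr(out, "mask_accuracy") <- acc[1L] / acc[2L]
    attr(out, "history") <- history
    out
  })
}
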