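#' @import methods
NULL

# ---------------------------------------------------------------------------
# Core data containers. Validity methods enforce the structural invariants
# that the rest of the pipeline relies on; use the constructor helpers and
# accessors rather than reaching into slots.
# ---------------------------------------------------------------------------

#' ExpressionProfile: one cell line's transcriptome
#'
#' Holds the gene identifiers and expression values of a single cell line,
#' in the order provided by the source matrix. Values are used as provided
#' (no internal log transform).
#'
#' @slot cellId single cell-line identifier.
#' @slot genes character vector of unique gene identifiers.
#' @slot values numeric vector of finite expression values, aligned to
#'   \code{genes}.
#' @exportClass ExpressionProfile
setClass("ExpressionProfile",
  representation(cellId = "character", genes = "character", values = "numeric"))

setValidity("ExpressionProfile", function(object) {
  msg <- character()
  if (length(object@cellId) != 1L || !nzchar(object@cellId))
    msg <- c(msg, "cellId must be a single non-empty string")
  if (anyDuplicated(object@genes))
    msg <- c(msg, sprintf("duplicated gene identifier: %s",
                          object@genes[duplicated(object@genes)][1L]))
  if (length(object@values) != length(object@genes))
    msg <- c(msg, "values and genes must have equal length")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "all expression values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionProfile
#'
#' @param cell_id cell-line identifier.
#' @param genes gene identifiers.
#' @param values expression values aligned to \code{genes}.
#' @return an \linkS4class{ExpressionProfile}.
#' @export
expressionProfile <- function(cell_id, genes, values) {
  new("ExpressionProfile", cellId = as.character(cell_id),
      genes = as.character(genes),
      values = stats::setNames(as.numeric(values), NULL))
}

setMethod("show", "ExpressionProfile", function(object) {
  cat(sprintf("ExpressionProfile '%s': %d genes\n",
              object@cellId, length(object@genes)))
})

#' GeneNetwork: a weighted undirected gene interaction network
#'
#' Edges are stored once per unordered pair with strictly positive finite
#' weights; self-loops are forbidden. Use \code{\link{readEdgeList}} or
#' \code{\link{geneNetwork}} to build one (both normalise direction,
#' merge duplicates by maximum weight and drop self-loops).
#'
#' @slot netName network name.
#' @slot edges data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{weight}.
#' @exportClass GeneNetwork
setClass("GeneNetwork",
  representation(netName = "character", edges = "data.frame"))

setValidity("GeneNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("gene_a", "gene_b", "weight") %in% names(e)))
    return("edges must have columns gene_a, gene_b, weight")
  if (nrow(e)) {
    if (any(e$gene_a == e$gene_b)) msg <- c(msg, "self-loops are not allowed")
    if (!all(is.finite(e$weight)) || any(e$weight <= 0))
      msg <- c(msg, "edge weights must be finite and > 0")
    key <- paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate undirected edges")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneNetwork from an edge table
#'
#' Normalises undirected duplicates (keeping the maximum weight) and drops
#' self-loops with a message.
#'
#' @param name network name.
#' @param edges data.frame with columns \code{gene_a}, \code{gene_b} and an
#'   optional \code{weight} (default 1).
#' @return a \linkS4class{GeneNetwork}.
#' @export
geneNetwork <- function(name, edges) {
  edges <- as.data.frame(edges)
  if (is.null(edges$weight)) edges$weight <- 1
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  edges$weight <- as.numeric(edges$weight)
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0, na.rm = TRUE))
    stop("edge weights must be finite and > 0", call. = FALSE)
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    message(sprintf("geneNetwork '%s': dropped %d self-loop(s)", name, sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges) == 0L)
    return(new("GeneNetwork", netName = as.character(name),
               edges = data.frame(gene_a = character(), gene_b = character(),
                                  weight = numeric())))
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  key <- paste(a, b, sep = "\r")
  w <- tapply(edges$weight, key, max)
  uk <- names(w)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  out <- data.frame(
    gene_a = vapply(parts, `[`, character(1), 1L),
    gene_b = vapply(parts, `[`, character(1), 2L),
    weight = as.numeric(w), stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  new("GeneNetwork", netName = as.character(name), edges = out)
}

setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf("GeneNetwork '%s': %d genes, %d edges\n", object@netName,
              length(networkGenes(object)), nrow(object@edges)))
})

#' GeneEmbeddingTable: dense per-gene embedding vectors
#'
#' One row per gene (rownames are gene identifiers); produced by
#' \code{\link{trainGeneEmbedder}} or loaded from file with
#' \code{\link{readGeneEmbeddingTable}}.
#'
#' @slot embeddings numeric matrix, genes x dimensions, finite entries,
#'   rownames are unique gene identifiers.
#' @exportClass GeneEmbeddingTable
setClass("GeneEmbeddingTable", representation(embeddings = "matrix"))

setValidity("GeneEmbeddingTable", function(object) {
  m <- object@embeddings
  msg <- character()
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msg <- c(msg, "embeddings must have unique gene rownames")
  if (!all(is.finite(m))) msg <- c(msg, "all embedding entries must be finite")
  if (ncol(m) < 1L) msg <- c(msg, "embedding dimension must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @export
geneEmbeddingTable <- function(embeddings) {
  new("GeneEmbeddingTable", embeddings = as.matrix(embeddings))
}

setMethod("show", "GeneEmbeddingTable", function(object) {
  cat(sprintf("GeneEmbeddingTable: %d genes x %d dimensions\n",
              nrow(object@embeddings), ncol(object@embeddings)))
})

#' MolecularGraph: heavy-atom graph of one drug molecule
#'
#' Atoms carry categorical attributes (element, heavy-atom degree, formal
#' charge, aromatic flag); bonds are undirected with a type in
#' single/double/triple/aromatic. Built from SMILES by
#' \code{\link{smilesToGraph}}.
#'
#' @slot drugId drug identifier.
#' @slot atoms data.frame with columns \code{element}, \code{degree},
#'   \code{charge}, \code{aromatic}.
#' @slot bonds data.frame with columns \code{a1}, \code{a2}, \code{type};
#'   indices 1-based into \code{atoms}.
#' @exportClass MolecularGraph
setClass("MolecularGraph",
  representation(drugId = "character", atoms = "data.frame", bonds = "data.frame"))

setValidity("MolecularGraph", function(object) {
  a <- object@atoms; b <- object@bonds
  msg <- character()
  if (nrow(a) < 1L) msg <- c(msg, "at least one heavy atom required")
  if (nrow(b)) {
    if (any(b$a1 < 1L | b$a1 > nrow(a) | b$a2 < 1L | b$a2 > nrow(a)))
      msg <- c(msg, "bond indices out of range")
    if (any(b$a1 == b$a2)) msg <- c(msg, "bond endpoints must differ")
    key <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate undirected bonds")
  }
  if (nrow(a) > 1L) {
    g <- igraph::graph_from_edgelist(cbind(b$a1, b$a2), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nrow(a) - igraph::vcount(g)))
    if (!igraph::is_connected(g)) msg <- c(msg, "molecular graph must be connected")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph '%s': %d atoms, %d bonds\n",
              object@drugId, nrow(object@atoms), nrow(object@bonds)))
})

#' ResponseDataset: profiles, drugs and response records
#'
#' @slot profiles named list of \linkS4class{ExpressionProfile} objects.
#' @slot drugs data.frame with columns \code{drug_id}, \code{smiles}.
#' @slot responses data.frame with columns \code{cell_id}, \code{drug_id},
#'   \code{ln_ic50}; every record must resolve to a profile and drug.
#' @exportClass ResponseDataset
setClass("ResponseDataset",
  representation(profiles = "list", drugs = "data.frame", responses = "data.frame"))

setValidity("ResponseDataset", function(object) {
  msg <- character()
  cells <- vapply(object@profiles, cellId, character(1))
  r <- object@responses
  if (nrow(r)) {
    if (!all(is.finite(r$ln_ic50))) msg <- c(msg, "ln_ic50 values must be finite")
    key <- paste(r$cell_id, r$drug_id, sep = "\r")
    if (anyDuplicated(key)) msg <- c(msg, "duplicate (cell_id, drug_id) pairs")
    bad_c <- setdiff(r$cell_id, cells)
    if (length(bad_c)) msg <- c(msg, sprintf("unresolved cell id(s): %s",
                                             paste(head(bad_c, 3L), collapse = ", ")))
    bad_d <- setdiff(r$drug_id, object@drugs$drug_id)
    if (length(bad_d)) msg <- c(msg, sprintf("unresolved drug id(s): %s",
                                             paste(head(bad_d, 3L), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' @export
responseDataset <- function(profiles, drugs, responses) {
  names(profiles) <- vapply(profiles, cellId, character(1))
  new("ResponseDataset", profiles = profiles, drugs = as.data.frame(drugs),
      responses = as.data.frame(responses))
}

setMethod("show", "ResponseDataset", function(object) {
  cat(sprintf("ResponseDataset: %d cells, %d drugs, %d responses\n",
              length(object@profiles), nrow(object@drugs), nrow(object@responses)))
})

#' CellRepresentation: the two fused cell-line features
#'
#' @slot cellId cell identifier.
#' @slot interactome mean embedding of the most highly expressed genes.
#' @slot transcriptome auto-encoder latent vector (or standardized raw
#'   expression for the DIM ablation).
#' @exportClass CellRepresentation
setClass("CellRepresentation",
  representation(cellId = "character", interactome = "numeric",
                 transcriptome = "numeric"))

setValidity("CellRepresentation", function(object) {
  if (!all(is.finite(object@interactome)) || !all(is.finite(object@transcriptome)))
    "feature vectors must be finite" else TRUE
})

setMethod("show", "CellRepresentation", function(object) {
  cat(sprintf("CellRepresentation '%s': interactome[%d], transcriptome[%d]\n",
              object@cellId, length(object@interactome), length(object@transcriptome)))
})

# ---------------------------------------------------------------------------
# Model containers
# ---------------------------------------------------------------------------

#' DenoisingAutoencoder: trained transcriptome compressor
#'
#' @slot params nested list of layer weights.
#' @slot scaler per-gene centering/scaling applied before the network.
#' @slot genes gene list (order matters) the model was trained on.
#' @slot config the \code{\link{daeConfig}} used.
#' @slot history per-epoch reconstruction MSE.
#' @exportClass DenoisingAutoencoder
setClass("DenoisingAutoencoder",
  representation(params = "list", scaler = "list", genes = "character",
                 config = "list", history = "numeric"))

setMethod("show", "DenoisingAutoencoder", function(object) {
  cat(sprintf("DenoisingAutoencoder: %d genes -> latent %d (%d epochs trained)\n",
              length(object@genes), latentDim(object), length(object@history)))
})

#' DrugEncoder: neighbour-attention message-passing molecular encoder
#'
#' @slot params nested list of weights (attribute embeddings, attention,
#'   GRU).
#' @slot config the \code{\link{encoderConfig}} used.
#' @slot vocab categorical attribute vocabularies.
#' @exportClass DrugEncoder
setClass("DrugEncoder",
  representation(params = "list", config = "list", vocab = "list"))

setMethod("show", "DrugEncoder", function(object) {
  cat(sprintf("DrugEncoder: d_atom=%d, %d message steps, %d heads\n",
              object@config$d_atom, object@config$message_steps,
              object@config$attention_heads))
})

#' ResponseModel: trained attention-fusion IC50 regressor
#'
#' @slot params nested list of fusion weights.
#' @slot config the \code{\link{fusionConfig}} used (includes the variant).
#' @slot dims input dimensions the model was built for.
#' @slot encoder the \linkS4class{DrugEncoder} used (possibly fine-tuned).
#' @slot history per-epoch training MSE.
#' @exportClass ResponseModel
setClass("ResponseModel",
  representation(params = "list", config = "list", dims = "list",
                 encoder = "ANY", history = "numeric"))

setMethod("show", "ResponseModel", function(object) {
  cat(sprintf("ResponseModel (%s): head [%s], %s parameters\n",
              object@config$variant,
              paste(object@config$head_dims, collapse = ", "),
              format(paramCount(object@params), big.mark = ",")))
})

# ---------------------------------------------------------------------------
# Generics and accessors
# ---------------------------------------------------------------------------

#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))
#' @describeIn ExpressionProfile cell identifier
#' @param x object
#' @export
setMethod("cellId", "ExpressionProfile", function(x) x@cellId)
#' @export
setMethod("cellId", "CellRepresentation", function(x) x@cellId)

#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @describeIn ExpressionProfile gene identifiers
#' @export
setMethod("geneIds", "ExpressionProfile", function(x) x@genes)
#' @export
setMethod("geneIds", "GeneEmbeddingTable", function(x) rownames(x@embeddings))

#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @describeIn ExpressionProfile named expression vector
#' @export
setMethod("exprValues", "ExpressionProfile", function(x)
  stats::setNames(x@values, x@genes))

#' Genes incident to at least one edge of a network
#' @param x a \linkS4class{GeneNetwork}
#' @export
networkGenes <- function(x) sort(unique(c(x@edges$gene_a, x@edges$gene_b)))

#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @describeIn GeneNetwork the normalised edge table
#' @param x object
#' @export
setMethod("edgeTable", "GeneNetwork", function(x) x@edges)

#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))
#' @describeIn GeneEmbeddingTable embedding dimensionality
#' @param x object
#' @export
setMethod("embeddingDim", "GeneEmbeddingTable", function(x) ncol(x@embeddings))

#' @export
setGeneric("embeddingMatrix", function(x) standardGeneric("embeddingMatrix"))
#' @describeIn GeneEmbeddingTable the genes x dim matrix
#' @export
setMethod("embeddingMatrix", "GeneEmbeddingTable", function(x) x@embeddings)

#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @describeIn MolecularGraph atom attribute table
#' @param x object
#' @export
setMethod("atomTable", "MolecularGraph", function(x) x@atoms)

#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))
#' @describeIn MolecularGraph bond table
#' @export
setMethod("bondTable", "MolecularGraph", function(x) x@bonds)

#' @export
setGeneric("drugId", function(x) standardGeneric("drugId"))
#' @describeIn MolecularGraph drug identifier
#' @export
setMethod("drugId", "MolecularGraph", function(x) x@drugId)

#' @export
setGeneric("latentDim", function(x) standardGeneric("latentDim"))
#' @describeIn DenoisingAutoencoder width of the latent (middle) layer
#' @param x object
#' @export
setMethod("latentDim", "DenoisingAutoencoder", function(x) {
  h <- x@config$hidden_dims
  h[(length(h) + 1L) %/% 2L]
})

#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))
#' @describeIn DenoisingAutoencoder per-epoch training loss
#' @export
setMethod("lossHistory", "DenoisingAutoencoder", function(x) x@history)
#' @export
setMethod("lossHistory", "ResponseModel", function(x) x@history)

#' @export
setGeneric("modelVariant", function(x) standardGeneric("modelVariant"))
#' @describeIn ResponseModel which variant (DIPK, DEM or DIM) was trained
#' @param x object
#' @export
setMethod("modelVariant", "ResponseModel", function(x) x@config$variant)

#' Profiles of a dataset
#' @param x a \linkS4class{ResponseDataset}
#' @export
datasetProfiles <- function(x) x@profiles
#' Drug table of a dataset
#' @param x a \linkS4class{ResponseDataset}
#' @export
datasetDrugs <- function(x) x@drugs
#' Response records of a dataset
#' @param x a \linkS4class{ResponseDataset}
#' @export
datasetResponses <- function(x) x@responses
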