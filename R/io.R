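# Readers and writers for the delimited formats the pipeline touches:
# expression matrices, network edge lists, SMILES tables, response tables,
# embedding tables and prediction output. Delimiter is auto-detected among
# tab and comma unless given.

detectDelim <- function(path) {
  line <- readLines(path, n = 1L)
  if (length(line) && grepl("\t", line)) "\t" else ","
}

.read_df <- function(path, delim = NULL, header = TRUE) {
  if (is.null(delim)) delim <- detectDelim(path)
  utils::read.table(path, header = header, sep = delim, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "")
}

#' Read an expression matrix into ExpressionProfile objects
#'
#' The file must be delimited text with one header row and one leading
#' identifier column. Depending on \code{orientation}, rows are cells and
#' columns genes, or vice versa. Gene order in the file is preserved.
#'
#' @param path file path.
#' @param orientation \code{"cells_as_rows"} (default) or
#'   \code{"genes_as_rows"}.
#' @param delim field delimiter; auto-detected among tab/comma when NULL.
#' @return named list of \linkS4class{ExpressionProfile}.
#' @export
readExpressionMatrix <- function(path,
                                 orientation = c("cells_as_rows", "genes_as_rows"),
                                 delim = NULL) {
  orientation <- match.arg(orientation)
  df <- .read_df(path, delim)
  ids <- as.character(df[[1L]])
  header <- colnames(df)[-1L]   # before subsetting: `[.data.frame` mangles
  body <- df[, -1L, drop = FALSE]                    # duplicated names
  if (orientation == "genes_as_rows") {
    genes <- ids
    cells <- header
    mat <- t(as.matrix(body))
  } else {
    genes <- header
    cells <- ids
    mat <- as.matrix(body)
  }
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop(sprintf("duplicated gene identifier: %s", dup[1L]), call. = FALSE)
  if (anyDuplicated(cells))
    stop(sprintf("duplicated cell identifier: %s",
                 cells[duplicated(cells)][1L]), call. = FALSE)
  suppressWarnings(storage.mode(mat) <- "double")
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing or non-numeric expression value for cell '%s', gene '%s'",
                 cells[idx[1L]], genes[idx[2L]]), call. = FALSE)
  }
  out <- lapply(seq_along(cells), function(i)
    expressionProfile(cells[i], genes, mat[i, ]))
  names(out) <- cells
  out
}

#' Write ExpressionProfile objects as a delimited matrix
#'
#' @param profiles list of \linkS4class{ExpressionProfile} sharing one gene
#'   list.
#' @param path output path.
#' @param delim field delimiter (default tab).
#' @export
writeExpressionMatrix <- function(profiles, path, delim = "\t") {
  genes <- geneIds(profiles[[1L]])
  for (p in profiles)
    if (!identical(geneIds(p), genes))
      stop("all profiles must share one gene list", call. = FALSE)
  mat <- do.call(rbind, lapply(profiles, function(p) p@values))
  df <- data.frame(cell_id = vapply(profiles, cellId, character(1)), mat,
                   check.names = FALSE)
  colnames(df) <- c("cell_id", genes)
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene interaction network from an edge list
#'
#' Expects columns \code{gene_a}, \code{gene_b} and an optional
#' \code{weight} (default 1). Self-loops are dropped with a message and
#' duplicate undirected edges merged keeping the maximum weight.
#'
#' @param path file path.
#' @param name network name.
#' @param delim field delimiter; auto-detected when NULL.
#' @return a \linkS4class{GeneNetwork}.
#' @export
readEdgeList <- function(path, name, delim = NULL) {
  df <- .read_df(path, delim)
  if (ncol(df) < 2L) stop("edge list needs at least two columns", call. = FALSE)
  names(df)[1:2] <- c("gene_a", "gene_b")
  if (ncol(df) >= 3L) {
    names(df)[3L] <- "weight"
    w <- suppressWarnings(as.numeric(df$weight))
    if (anyNA(w) || any(!is.finite(w)) || any(w <= 0))
      stop("edge weights must be positive finite numbers", call. = FALSE)
    df$weight <- w
  } else df$weight <- 1
  geneNetwork(name, df[, c("gene_a", "gene_b", "weight")])
}

#' Write a GeneNetwork as an edge list
#' @param network a \linkS4class{GeneNetwork}.
#' @param path output path.
#' @param delim field delimiter (default tab).
#' @export
writeEdgeList <- function(network, path, delim = "\t") {
  utils::write.table(edgeTable(network), path, sep = delim,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a drug table (drug_id, smiles) and validate every SMILES
#'
#' All SMILES are parsed; entries failing to parse (or parsing to a
#' disconnected or empty molecule) are collected and reported together.
#'
#' @param path file path.
#' @param delim field delimiter; auto-detected when NULL.
#' @return data.frame with columns \code{drug_id}, \code{smiles}.
#' @export
readSmilesTable <- function(path, delim = NULL) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(trimws(first))) {
    warning("empty drug table", call. = FALSE)
    return(data.frame(drug_id = character(), smiles = character(),
                      stringsAsFactors = FALSE))
  }
  df <- .read_df(path, delim)
  names(df)[1:2] <- c("drug_id", "smiles")
  df$drug_id <- as.character(df$drug_id)
  df$smiles <- as.character(df$smiles)
  if (anyDuplicated(df$drug_id))
    stop(sprintf("duplicated drug identifier: %s",
                 df$drug_id[duplicated(df$drug_id)][1L]), call. = FALSE)
  bad <- character()
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({
      smilesToGraph(df$drug_id[i], df$smiles[i])
      TRUE
    }, error = function(e) FALSE)
    if (!ok) bad <- c(bad, df$drug_id[i])
  }
  if (length(bad))
    stop(sprintf("invalid SMILES for drug id(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  df[, c("drug_id", "smiles")]
}

#' Read a response table (cell_id, drug_id, ln_ic50)
#'
#' @param path file path.
#' @param delim field delimiter; auto-detected when NULL.
#' @return data.frame with columns \code{cell_id}, \code{drug_id},
#'   \code{ln_ic50}.
#' @export
readResponseTable <- function(path, delim = NULL) {
  df <- .read_df(path, delim)
  names(df)[1:3] <- c("cell_id", "drug_id", "ln_ic50")
  df$cell_id <- as.character(df$cell_id)
  df$drug_id <- as.character(df$drug_id)
  v <- suppressWarnings(as.numeric(df$ln_ic50))
  if (anyNA(v) || any(!is.finite(v))) {
    i <- which(is.na(v) | !is.finite(v))[1L]
    stop(sprintf("non-finite ln_ic50 at row %d (cell '%s', drug '%s')",
                 i, df$cell_id[i], df$drug_id[i]), call. = FALSE)
  }
  df$ln_ic50 <- v
  key <- paste(df$cell_id, df$drug_id, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("duplicate response pair ('%s', '%s')",
                 df$cell_id[i], df$drug_id[i]), call. = FALSE)
  }
  df[, c("cell_id", "drug_id", "ln_ic50")]
}

#' Write response records
#' @param responses data.frame with cell_id, drug_id, ln_ic50.
#' @param path output path.
#' @param delim field delimiter (default tab).
#' @export
writeResponseTable <- function(responses, path, delim = "\t") {
  utils::write.table(responses, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene embedding table (gene id column then numeric columns)
#' @param path file path.
#' @param delim field delimiter; auto-detected when NULL.
#' @return a \linkS4class{GeneEmbeddingTable}.
#' @export
readGeneEmbeddingTable <- function(path, delim = NULL) {
  df <- .read_df(path, delim)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  geneEmbeddingTable(m)
}

#' Write a gene embedding table
#' @param table a \linkS4class{GeneEmbeddingTable}.
#' @param path output path.
#' @param delim field delimiter (default tab).
#' @export
writeGeneEmbeddingTable <- function(table, path, delim = "\t") {
  m <- embeddingMatrix(table)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("gene", paste0("d", seq_len(ncol(m))))
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write predictions (cell_id, drug_id, observed, predicted)
#'
#' @param predictions data.frame with columns \code{cell_id},
#'   \code{drug_id}, \code{predicted_ln_ic50} and optionally
#'   \code{observed_ln_ic50}.
#' @param path output path.
#' @param delim field delimiter (default tab).
#' @export
writePredictions <- function(predictions, path, delim = "\t") {
  obs <- if ("observed_ln_ic50" %in% names(predictions))
    predictions$observed_ln_ic50 else rep(NA_real_, nrow(predictions))
  df <- data.frame(cell_id = predictions$cell_id, drug_id = predictions$drug_id,
                   observed_ln_ic50 = obs,
                   predicted_ln_ic50 = predictions$predicted_ln_ic50)
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
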