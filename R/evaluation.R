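# Validation protocols: k-fold plans (random pairs, cell-disjoint,
# drug-disjoint, doubly disjoint), prediction averaging over folds, and the
# MSE / RMSE / PCC / R2 metric suite.

#' Build a cross-validation fold plan
#'
#' \code{random_pairs} partitions pairs uniformly. \code{disjoint_cells}
#' (resp. \code{disjoint_drugs}) partitions cell (drug) identifiers into
#' groups so no test cell (drug) occurs in its fold's training set.
#' \code{disjoint_both} independently partitions cells and drugs; fold i
#' tests pairs with cell-group i AND drug-group i and trains on pairs whose
#' cell and drug group both differ from i; remaining pairs are dropped for
#' that fold with a recorded count (the cold-start construction for novel
#' cells and drugs).
#'
#' @param responses data.frame with \code{cell_id}, \code{drug_id} columns
#'   (a \linkS4class{ResponseDataset} is also accepted).
#' @param n_folds number of folds.
#' @param mode one of \code{"random_pairs"}, \code{"disjoint_cells"},
#'   \code{"disjoint_drugs"}, \code{"disjoint_both"}.
#' @param seed RNG seed; the plan is deterministic given the seed.
#' @return a \code{FoldPlan}: list with \code{n_folds}, \code{mode},
#'   \code{seed}, \code{folds} (per fold: \code{train}, \code{test} row
#'   indices into \code{responses}, \code{dropped} count).
#' @export
makeFolds <- function(responses, n_folds, mode = c("random_pairs",
                                                   "disjoint_cells",
                                                   "disjoint_drugs",
                                                   "disjoint_both"),
                      seed = 1L) {
  mode <- match.arg(mode)
  if (is(responses, "ResponseDataset")) responses <- datasetResponses(responses)
  n <- nrow(responses)
  stopifnot(n_folds >= 2L, n >= n_folds)
  cells <- unique(responses$cell_id)
  drugs <- unique(responses$drug_id)
  if (mode %in% c("disjoint_cells", "disjoint_both") && length(cells) < n_folds)
    stop("n_folds exceeds the number of distinct cells", call. = FALSE)
  if (mode %in% c("disjoint_drugs", "disjoint_both") && length(drugs) < n_folds)
    stop("n_folds exceeds the number of distinct drugs", call. = FALSE)

  chunk <- function(ids) {
    ids <- sample(ids)
    split(ids, rep(seq_len(n_folds), length.out = length(ids))[order(seq_along(ids))])
  }
  folds <- withr::with_seed(seed, {
    if (mode == "random_pairs") {
      grp <- sample(rep(seq_len(n_folds), length.out = n))
      lapply(seq_len(n_folds), function(i)
        list(train = which(grp != i), test = which(grp == i), dropped = 0L))
    } else if (mode %in% c("disjoint_cells", "disjoint_drugs")) {
      key <- if (mode == "disjoint_cells") responses$cell_id else responses$drug_id
      ids <- if (mode == "disjoint_cells") cells else drugs
      groups <- chunk(ids)
      lapply(seq_len(n_folds), function(i) {
        test <- which(key %in% groups[[i]])
        list(train = setdiff(seq_len(n), test), test = test, dropped = 0L)
      })
    } else {
      cg <- chunk(cells)
      dg <- chunk(drugs)
      lapply(seq_len(n_folds), function(i) {
        cin <- responses$cell_id %in% cg[[i]]
        din <- responses$drug_id %in% dg[[i]]
        test <- which(cin & din)
        train <- which(!cin & !din)
        list(train = train, test = test,
             dropped = n - length(test) - length(train))
      })
    }
  })
  structure(list(n_folds = as.integer(n_folds), mode = mode,
                 seed = as.integer(seed), folds = folds),
            class = "FoldPlan")
}

#' @export
print.FoldPlan <- function(x, ...) {
  cat(sprintf("FoldPlan: %d folds, mode %s\n", x$n_folds, x$mode))
  for (i in seq_along(x$folds))
    cat(sprintf("  fold %d: %d train, %d test, %d dropped\n", i,
                length(x$folds[[i]]$train), length(x$folds[[i]]$test),
                x$folds[[i]]$dropped))
  invisible(x)
}

#' Average per-fold predictions over a common pair set
#'
#' All folds must have predicted the identical pair set (the protocol for
#' scoring a fixed external test set with each fold's model); the result is
#' the element-wise mean per pair.
#'
#' @param per_fold list of data.frames with \code{cell_id}, \code{drug_id},
#'   \code{predicted_ln_ic50}.
#' @return data.frame in the pair order of the first fold.
#' @export
averageFoldPredictions <- function(per_fold) {
  stopifnot(length(per_fold) >= 1L)
  ref <- per_fold[[1L]]
  key <- paste(ref$cell_id, ref$drug_id, sep = "\r")
  acc <- ref$predicted_ln_ic50
  if (length(per_fold) > 1L) {
    for (k in 2:length(per_fold)) {
      fk <- per_fold[[k]]
      kk <- paste(fk$cell_id, fk$drug_id, sep = "\r")
      if (!setequal(kk, key) || length(kk) != length(key)) {
        diffp <- c(setdiff(kk, key), setdiff(key, kk))[1L]
        parts <- strsplit(diffp, "\r", fixed = TRUE)[[1L]]
        stop(sprintf("fold %d predicted a different pair set (first difference: '%s', '%s')",
                     k, parts[1L], parts[2L]), call. = FALSE)
      }
      acc <- acc + fk$predicted_ln_ic50[match(key, kk)]
    }
  }
  data.frame(cell_id = ref$cell_id, drug_id = ref$drug_id,
             predicted_ln_ic50 = acc / length(per_fold),
             stringsAsFactors = FALSE)
}

#' Regression metric suite: MSE, RMSE, PCC, R2
#'
#' \code{r2 = 1 - SS_res / SS_tot}. With zero observed variance, PCC and R2
#' are reported as NA (MSE/RMSE still computed).
#'
#' @param observed numeric vector of observed LN IC50.
#' @param predicted numeric vector of predictions, same length.
#' @return a \code{MetricReport}: list with \code{mse}, \code{rmse},
#'   \code{pcc}, \code{r2}, \code{n}.
#' @export
computeMetrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  d <- observed - predicted
  mse <- mean(d^2)
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0) {
    pcc <- NA_real_; r2 <- NA_real_
  } else {
    pcc <- if (stats::sd(predicted) == 0) NA_real_ else
      stats::cor(observed, predicted)
    r2 <- 1 - sum(d^2) / sstot
  }
  structure(list(mse = mse, rmse = sqrt(mse), pcc = pcc, r2 = r2,
                 n = length(observed)), class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat(sprintf("MetricReport (n=%d): MSE %.4f, RMSE %.4f, PCC %s, R2 %s\n",
              x$n, x$mse, x$rmse,
              ifelse(is.na(x$pcc), "NA", sprintf("%.4f", x$pcc)),
              ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2))))
  invisible(x)
}

#' Per-cell or per-drug metric breakdown
#'
#' @param predictions data.frame with \code{cell_id}, \code{drug_id},
#'   \code{observed_ln_ic50}, \code{predicted_ln_ic50}.
#' @param by \code{"cell"} or \code{"drug"}.
#' @return tidy data.frame, one row per group with the metric suite.
#' @export
metricBreakdown <- function(predictions, by = c("cell", "drug")) {
  by <- match.arg(by)
  key <- if (by == "cell") predictions$cell_id else predictions$drug_id
  groups <- split(seq_len(nrow(predictions)), key)
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    m <- computeMetrics(predictions$observed_ln_ic50[idx],
                        predictions$predicted_ln_ic50[idx])
    data.frame(id = g, n = m$n, mse = m$mse, rmse = m$rmse, pcc = m$pcc,
               r2 = m$r2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- paste0(by, "_id")
  out
}
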