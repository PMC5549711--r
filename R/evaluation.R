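#' Confusion counts for binary predictions
#'
#' TP = interacting pairs predicted interacting; FN = interacting pairs
#' predicted non-interacting; FP = non-interacting pairs predicted
#' interacting; TN = non-interacting pairs predicted non-interacting.
#'
#' @param y_true,y_pred Binary vectors (0/1 or -1/+1), equal length.
#' @return Object of class `confusion_counts`: named integer vector
#'   `c(tp, fp, tn, fn)`.
#' @export
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  yt <- .to_pm1(y_true)
  yp <- .to_pm1(y_pred)
  out <- c(tp = sum(yt == 1 & yp == 1),
           fp = sum(yt == -1 & yp == 1),
           tn = sum(yt == -1 & yp == -1),
           fn = sum(yt == 1 & yp == -1))
  class(out) <- "confusion_counts"
  out
}

#' Binary classification metrics
#'
#' The five standard measures from a confusion table:
#' \deqn{ACC = \frac{TP+TN}{TP+FP+TN+FN}, \quad SN = \frac{TP}{TP+FN},
#'       \quad PPV = \frac{TP}{TP+FP}}
#' \deqn{F = \frac{2 \cdot SN \cdot PPV}{SN + PPV}, \quad
#'       MCC = \frac{TP \cdot TN - FP \cdot FN}
#'       {\sqrt{(TP+FN)(TN+FP)(TP+FP)(TN+FN)}}}
#' A metric whose denominator is zero (e.g. PPV when nothing is predicted
#' positive) is reported as `NA` and listed in the `undefined` attribute
#' rather than silently coerced to 0.
#'
#' @param counts A `confusion_counts` object, or a named vector with
#'   entries `tp`, `fp`, `tn`, `fn`.
#' @return Object of class `ppi_metrics`: named numeric vector
#'   `c(acc, sn, ppv, fscore, mcc)` with attribute `undefined` naming any
#'   metric whose denominator was zero.
#' @export
#' @examples
#' classification_metrics(c(tp = 40, fp = 20, tn = 30, fn = 10))
classification_metrics <- function(counts) {
  need <- c("tp", "fp", "tn", "fn")
  if (!all(need %in% names(counts))) {
    stop("counts must contain tp, fp, tn and fn", call. = FALSE)
  }
  tp <- as.numeric(counts[["tp"]]); fp <- as.numeric(counts[["fp"]])
  tn <- as.numeric(counts[["tn"]]); fn <- as.numeric(counts[["fn"]])
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- tp + fp + tn + fn
  if (n == 0) stop("empty confusion table", call. = FALSE)

  undefined <- character(0)
  acc <- (tp + tn) / n
  sn <- if (tp + fn > 0) tp / (tp + fn) else { undefined <- c(undefined, "sn"); NA_real_ }
  ppv <- if (tp + fp > 0) tp / (tp + fp) else { undefined <- c(undefined, "ppv"); NA_real_ }
  fscore <- if (!is.na(sn) && !is.na(ppv) && sn + ppv > 0) {
    2 * sn * ppv / (sn + ppv)
  } else {
    undefined <- c(undefined, "fscore"); NA_real_
  }
  mcc_den <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  mcc <- if (mcc_den > 0) {
    (tp * tn - fp * fn) / sqrt(mcc_den)
  } else {
    undefined <- c(undefined, "mcc"); NA_real_
  }
  structure(c(acc = acc, sn = sn, ppv = ppv, fscore = fscore, mcc = mcc),
            undefined = undefined, class = "ppi_metrics")
}

#' @export
print.ppi_metrics <- function(x, digits = 4, ...) {
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  print(round(v, digits))
  und <- attr(x, "undefined")
  if (length(und) > 0) cat("undefined (zero denominator):",
                           paste(und, collapse = ", "), "\n")
  invisible(x)
}

# stratified k-fold assignment: within each class, shuffled indices are
# dealt round-robin, so fold sizes differ by at most one per class
.stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  rng <- .with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
  rng
}

# evaluate expr with a temporary RNG state, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Stratified five-fold cross-validation of the PPI pipeline
#'
#' Randomly partitions the labeled pairs into `n_folds` stratified folds,
#' then for each fold trains a [gbdt()] classifier on the pair descriptor
#' vectors of the remaining folds and evaluates on the held-out fold.
#' Reports the five classification metrics per fold plus their mean and
#' sample (n-1) standard deviation, mirroring the usual
#' "Average +/- Std" presentation.
#'
#' @param pairs Data frame with columns `id_a`, `id_b`, `label`.
#' @param sequences Named character vector of residue strings.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed controlling the fold assignment.
#' @param tables Property tables for descriptor extraction.
#' @param max_lag Auto-covariance maximum lag.
#' @param ... Passed on to [gbdt()] (`n_trees`, `max_depth`, `shrinkage`,
#'   ...).
#' @return Object of class `ppi_cv`: list with `folds` (metrics matrix, one
#'   row per fold), `mean`, `sd`, `fold_assignment` and the calling
#'   configuration.
#' @export
cross_validate_ppi <- function(pairs, sequences, n_folds = 5L, seed = 1L,
                               tables = aa_property_tables(), max_lag = 30L,
                               ...) {
  if (nrow(pairs) < 2L * n_folds) {
    stop("need at least ", 2L * n_folds, " pairs for ", n_folds,
         "-fold cross-validation", call. = FALSE)
  }
  y <- as.integer(pairs$label)
  if (length(unique(y)) < 2L) {
    stop("both interaction classes must be present", call. = FALSE)
  }
  feats <- pair_feature_matrix(pairs, sequences, tables = tables,
                               max_lag = max_lag)
  fold <- .stratified_folds(y, n_folds, seed)
  rows <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    test <- fold == k
    y_train <- y[!test]
    if (length(unique(y_train)) < 2L || length(unique(y[test])) < 2L) {
      stop("fold ", k, " is single-class; use more pairs or fewer folds",
           call. = FALSE)
    }
    fit <- gbdt(feats$x[!test, , drop = FALSE], y_train, seed = seed, ...)
    pred <- predict(fit, feats$x[test, , drop = FALSE], type = "class")
    rows[[k]] <- unclass(classification_metrics(
      confusion_counts(y[test], pred)))
  }
  folds <- do.call(rbind, rows)
  rownames(folds) <- paste0("fold", seq_len(n_folds))
  structure(list(
    folds = folds,
    mean = colMeans(folds),
    sd = apply(folds, 2, stats::sd),
    fold_assignment = fold,
    n_folds = as.integer(n_folds),
    seed = as.integer(seed)
  ), class = "ppi_cv")
}

#' @export
print.ppi_cv <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold stratified cross-validation (seed %d)\n",
              x$n_folds, x$seed))
  tab <- rbind(x$folds, mean = x$mean, sd = x$sd)
  print(round(tab, digits))
  invisible(x)
}

#' Write a cross-validation report as CSV
#'
#' One row per fold plus `mean` and `sd` rows; columns are the five
#' classification metrics.
#'
#' @param cv A `ppi_cv` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  tab <- rbind(cv$folds, mean = cv$mean, sd = cv$sd)
  df <- data.frame(set = rownames(tab), round(tab, 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
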