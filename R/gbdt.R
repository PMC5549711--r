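#' Negative gradient of the two-class deviance
#'
#' For the binomial deviance \eqn{L(y, f) = \log(1 + e^{-2yf})} with labels
#' \eqn{y \in \{-1, +1\}}, the negative gradient (pseudo-residual) at the
#' current score f is \eqn{2y / (1 + e^{2yf})}. Each boosting round fits a
#' regression tree to these residuals.
#'
#' @param y Numeric vector of labels in -1/+1.
#' @param f Numeric vector of current model scores.
#' @return Numeric residual vector, same length as `y`.
#' @export
negative_gradient <- function(y, f) {
  if (length(y) != length(f)) stop("y and f must have equal length", call. = FALSE)
  if (!all(y %in% c(-1, 1))) stop("labels must be coded -1 / +1", call. = FALSE)
  2 * y / (1 + exp(2 * y * f))
}

# numerically stable mean deviance log(1 + exp(-2 y f))
.mean_deviance <- function(y, f) {
  z <- -2 * y * f
  mean(ifelse(z > 30, z, log1p(exp(pmin(z, 30)))))
}

#' Fit a least-squares regression tree
#'
#' Greedy CART: each node takes the axis-aligned split (feature, threshold)
#' minimizing the summed squared deviation of the targets from the child
#' means, with thresholds at midpoints between consecutive distinct sorted
#' feature values. Growth stops at `max_depth`, when a child would hold
#' fewer than `min_samples_leaf` rows, or at a pure node. Ties are broken
#' toward the lowest feature index, then the lowest threshold. Leaf values
#' are the mean target in the leaf.
#'
#' @param x Numeric matrix (rows = observations).
#' @param r Numeric targets.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param min_samples_leaf Minimum rows per leaf.
#' @param column_order Optional precomputed per-column row order (0-based)
#'   of `x`; the boosting loop supplies it so the design matrix is sorted
#'   only once per fit.
#' @return A `gbdt_tree` object: list of parallel node arrays (`feature`,
#'   0-based or -1 for leaves; `threshold`; `left`/`right` child ids,
#'   0-based; `value`; `n`) plus `row_leaf`, the 0-based leaf node of every
#'   training row.
#' @export
fit_regression_tree <- function(x, r, max_depth = 3L, min_samples_leaf = 5L,
                                column_order = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) == 0L) stop("cannot fit a tree on an empty matrix", call. = FALSE)
  if (is.null(column_order)) column_order <- .sort_columns_cpp(x)
  tree <- .fit_tree_cpp(x, as.numeric(r), column_order, as.integer(max_depth),
                        as.integer(min_samples_leaf))
  class(tree) <- "gbdt_tree"
  tree
}

# leaf node id (0-based) reached by each row of x
.tree_leaves <- function(tree, x) {
  .tree_leaf_cpp(tree$feature, tree$threshold, tree$left, tree$right, x)
}

#' Gradient boosting decision tree classifier
#'
#' Fits a stage-wise additive ensemble of regression trees for binary
#' classification. The model score is
#' \deqn{f_M(x) = f_0 + \nu \sum_{m=1}^{M} T_m(x)}
#' where \eqn{f_0 = \frac{1}{2}\log\frac{1+\bar y}{1-\bar y}} minimizes the
#' two-class deviance for a constant score, and each tree \eqn{T_m} is a
#' CART regression tree fit to the negative gradient of the deviance at the
#' previous model. Leaf values are re-optimized by a single Newton step
#' over the leaf members, \eqn{c = \sum R_i / \sum |R_i|(2 - |R_i|)}, the
#' standard approximation to the per-leaf argmin which has no closed form
#' under this loss. The shrinkage \eqn{\nu} damps each tree's contribution;
#' `shrinkage = 1` recovers the unregularized stage-wise update. The fit is
#' fully deterministic (no row or feature subsampling), so `seed` merely
#' records provenance.
#'
#' @param x Numeric feature matrix, one row per training example (e.g. the
#'   694-column pair descriptor matrix from [pair_feature_matrix()]).
#' @param y Labels: 0/1 or -1/+1; both classes must be present.
#' @param n_trees Number of boosting rounds M.
#' @param max_depth Depth of each regression tree.
#' @param min_samples_leaf Minimum training rows per leaf.
#' @param shrinkage Learning rate \eqn{\nu} in (0, 1].
#' @param seed Integer recorded in the model (the fit itself is
#'   deterministic).
#' @return An object of class `gbdt`: list with `f0`, `trees`, the
#'   configuration, the per-round mean training `deviance` trace and the
#'   final training scores `fitted_scores`.
#' @seealso [predict.gbdt()], [write_gbdt()]
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(80), ncol = 2)
#' y <- as.integer(x[, 1] + x[, 2] > 0)
#' fit <- gbdt(x, y, n_trees = 30)
#' mean(predict(fit, x, type = "class") == 2 * y - 1)
gbdt <- function(x, y, n_trees = 500L, max_depth = 3L, min_samples_leaf = 5L,
                 shrinkage = 0.1, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- .to_pm1(y)
  if (nrow(x) != length(y)) stop("x and y disagree on the number of examples",
                                 call. = FALSE)
  if (nrow(x) < 2L) stop("need at least two training examples", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training labels are single-class; the initial score is undefined",
         call. = FALSE)
  }
  if (n_trees < 1L) stop("n_trees must be >= 1", call. = FALSE)
  if (max_depth < 1L) stop("max_depth must be >= 1", call. = FALSE)
  if (shrinkage <= 0 || shrinkage > 1) stop("shrinkage must be in (0, 1]",
                                            call. = FALSE)

  n <- nrow(x)
  ybar <- mean(y)
  f0 <- 0.5 * log((1 + ybar) / (1 - ybar))
  f <- rep(f0, n)
  trees <- vector("list", n_trees)
  deviance <- numeric(n_trees)

  column_order <- .sort_columns_cpp(x)
  for (m in seq_len(n_trees)) {
    r <- negative_gradient(y, f)
    tree <- fit_regression_tree(x, r, max_depth = max_depth,
                                min_samples_leaf = min_samples_leaf,
                                column_order = column_order)
    # Newton re-optimization of each leaf value over its members
    leaf_ids <- sort(unique(tree$row_leaf))
    for (leaf in leaf_ids) {
      rows <- which(tree$row_leaf == leaf)
      rl <- r[rows]
      denom <- sum(abs(rl) * (2 - abs(rl)))
      tree$value[leaf + 1L] <- if (denom > 0) sum(rl) / denom else 0
    }
    f <- f + shrinkage * tree$value[tree$row_leaf + 1L]
    tree$row_leaf <- NULL
    trees[[m]] <- tree
    deviance[m] <- .mean_deviance(y, f)
  }

  structure(list(
    f0 = f0,
    trees = trees,
    n_trees = as.integer(n_trees),
    max_depth = as.integer(max_depth),
    min_samples_leaf = as.integer(min_samples_leaf),
    shrinkage = shrinkage,
    seed = as.integer(seed),
    loss = "deviance",
    n_features = ncol(x),
    feature_names = colnames(x),
    deviance = deviance,
    fitted_scores = f,
    y = y
  ), class = "gbdt")
}

# accept 0/1 or -1/+1 labels, return -1/+1 numeric
.to_pm1 <- function(y) {
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) y <- 2 * y - 1
  if (!all(y %in% c(-1, 1))) {
    stop("labels must be binary (0/1 or -1/+1)", call. = FALSE)
  }
  y
}

#' Predict from a gbdt model
#'
#' @param object A `gbdt` model.
#' @param newdata Numeric matrix (or single vector) with the training
#'   dimensionality.
#' @param type `"score"` for the raw additive score \eqn{f_M(x)},
#'   `"response"` for the interaction probability
#'   \eqn{1 / (1 + e^{-2 f_M(x)})}, or `"class"` for -1/+1 labels at the
#'   probability `threshold`.
#' @param threshold Classification threshold on the probability, in (0, 1).
#' @param ... Unused.
#' @return Numeric vector of scores, probabilities or -1/+1 labels.
#' @export
predict.gbdt <- function(object, newdata, type = c("response", "score", "class"),
                         threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$n_features) {
    stop("newdata has ", ncol(newdata), " features; the model was trained on ",
         object$n_features, call. = FALSE)
  }
  f <- rep(object$f0, nrow(newdata))
  for (tree in object$trees) {
    f <- f + object$shrinkage * tree$value[.tree_leaves(tree, newdata) + 1L]
  }
  if (type == "score") return(f)
  p <- 1 / (1 + exp(-2 * f))
  if (type == "response") return(p)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be strictly inside (0, 1)", call. = FALSE)
  }
  ifelse(p >= threshold, 1, -1)
}

#' @export
print.gbdt <- function(x, ...) {
  cat("Gradient boosting decision tree classifier\n")
  cat(sprintf("  trees: %d (depth %d, min leaf %d, shrinkage %.3g)\n",
              x$n_trees, x$max_depth, x$min_samples_leaf, x$shrinkage))
  cat(sprintf("  features: %d;  initial score f0 = %.4f\n", x$n_features, x$f0))
  cat(sprintf("  final training deviance: %.5f\n",
              x$deviance[length(x$deviance)]))
  invisible(x)
}

#' @export
summary.gbdt <- function(object, ...) {
  leaves <- vapply(object$trees, function(t) sum(t$feature < 0L), integer(1))
  used <- sort(unique(unlist(lapply(object$trees, function(t) {
    t$feature[t$feature >= 0L] + 1L
  }))))
  out <- list(
    n_trees = object$n_trees,
    max_depth = object$max_depth,
    shrinkage = object$shrinkage,
    f0 = object$f0,
    mean_leaves = mean(leaves),
    n_features_used = length(used),
    n_features = object$n_features,
    initial_deviance = object$deviance[1],
    final_deviance = object$deviance[length(object$deviance)]
  )
  class(out) <- "summary.gbdt"
  out
}

#' @export
print.summary.gbdt <- function(x, ...) {
  cat("Gradient boosting decision tree classifier\n")
  cat(sprintf("  %d trees, depth %d, shrinkage %.3g, f0 = %.4f\n",
              x$n_trees, x$max_depth, x$shrinkage, x$f0))
  cat(sprintf("  mean leaves per tree: %.1f\n", x$mean_leaves))
  cat(sprintf("  features used in splits: %d of %d\n",
              x$n_features_used, x$n_features))
  cat(sprintf("  training deviance: %.5f (round 1) -> %.5f (round %d)\n",
              x$initial_deviance, x$final_deviance, x$n_trees))
  invisible(x)
}

#' Plot the training deviance trace of a gbdt model
#'
#' @param x A `gbdt` model.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.gbdt <- function(x, ...) {
  graphics::plot(seq_along(x$deviance), x$deviance, type = "l",
                 xlab = "boosting round", ylab = "mean training deviance", ...)
  invisible(x)
}

#' @export
residuals.gbdt <- function(object, ...) {
  # pseudo-residuals (negative gradient) at the final fitted scores
  if (is.null(object$fitted_scores) || is.null(object$y)) {
    stop("model carries no training-time scores (was it read from disk?)",
         call. = FALSE)
  }
  negative_gradient(object$y, object$fitted_scores)
}

#' Serialize / restore a gbdt model
#'
#' Writes the model to a self-describing versioned JSON file (configuration,
#' initial score, tree structures and leaf values) and reads it back.
#'
#' @param model A `gbdt` object.
#' @param path File path.
#' @return `path` (write) or the restored `gbdt` model (read).
#' @export
write_gbdt <- function(model, path) {
  payload <- list(
    format = "ppiboost-gbdt",
    version = 1L,
    f0 = model$f0,
    n_trees = model$n_trees,
    max_depth = model$max_depth,
    min_samples_leaf = model$min_samples_leaf,
    shrinkage = model$shrinkage,
    seed = model$seed,
    loss = model$loss,
    n_features = model$n_features,
    feature_names = model$feature_names,
    trees = lapply(model$trees, function(t) {
      list(feature = t$feature, threshold = t$threshold,
           left = t$left, right = t$right, value = t$value, n = t$n)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gbdt
#' @export
read_gbdt <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "ppiboost-gbdt")) {
    stop("'", path, "' is not a ppiboost gbdt model file", call. = FALSE)
  }
  trees <- lapply(payload$trees, function(t) {
    out <- list(
      feature = as.integer(unlist(t$feature)),
      threshold = as.numeric(unlist(t$threshold)),
      left = as.integer(unlist(t$left)),
      right = as.integer(unlist(t$right)),
      value = as.numeric(unlist(t$value)),
      n = as.integer(unlist(t$n))
    )
    class(out) <- "gbdt_tree"
    out
  })
  structure(list(
    f0 = as.numeric(payload$f0),
    trees = trees,
    n_trees = as.integer(payload$n_trees),
    max_depth = as.integer(payload$max_depth),
    min_samples_leaf = as.integer(payload$min_samples_leaf),
    shrinkage = as.numeric(payload$shrinkage),
    seed = as.integer(payload$seed),
    loss = as.character(payload$loss),
    n_features = as.integer(payload$n_features),
    feature_names = if (is.null(payload$feature_names)) NULL else
      as.character(unlist(payload$feature_names)),
    deviance = numeric(0),
    fitted_scores = NULL,
    y = NULL
  ), class = "gbdt")
}
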