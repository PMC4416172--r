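# Weighted-instance decision tree used as the base classifier for both the
# multiple-instance wrapper and the single-instance baselines.

#' Base-classifier configuration
#'
#' The base learner is a weighted-instance CART decision tree (via
#' \pkg{rpart}) with Laplace-smoothed leaf probabilities. It stands in for
#' the C4.5 trees used historically in this problem: the comparison of
#' interest is multiple-instance vs single-instance learning and feature
#' models, not the tree dialect, so C4.5's gain-ratio splits and error-based
#' pruning are not replicated. The controls below are the usual CART knobs.
#' The defaults grow a deep, lightly constrained tree (tiny leaves, no
#' cost-complexity pruning), in the spirit of classic C4.5 defaults;
#' Laplace-smoothed leaves and bag-probability averaging supply the
#' stabilization that pruning would otherwise provide, and a deep tree is
#' what lets instance-level scores pinpoint individual binding sites.
#'
#' @param maxdepth Maximum tree depth (rpart limit is 30).
#' @param minsplit Minimum weighted observations in a node to attempt a
#'   split.
#' @param minbucket Minimum weighted observations in a leaf.
#' @param cp Complexity parameter; splits that do not improve the overall
#'   fit by `cp` are pruned.
#' @param laplace If `TRUE` (default) leaf class probabilities are
#'   add-one-smoothed on the leaf's weighted class counts, so no instance is
#'   ever scored exactly 0 or 1; this stabilizes bag-probability averaging
#'   and AUC ties.
#' @param seed Seed applied before fitting; CART fitting here is
#'   deterministic, but the seed is part of the recorded configuration so
#'   runs are reproducible end to end.
#' @return A list of class `tree_config`.
#' @export
tree_config <- function(maxdepth = 30L, minsplit = 4L, minbucket = 2L,
                        cp = 0, laplace = TRUE, seed = 0L) {
  structure(list(maxdepth = as.integer(maxdepth),
                 minsplit = as.integer(minsplit),
                 minbucket = as.integer(minbucket),
                 cp = as.numeric(cp), laplace = isTRUE(laplace),
                 seed = as.integer(seed)),
            class = "tree_config")
}

as_tree_config <- function(config) {
  if (inherits(config, "tree_config")) return(config)
  do.call(tree_config, as.list(config))
}

# Fit a weighted probabilistic classifier on a numeric feature matrix.
# labels: character/factor with values "negative"/"positive".
# weights are rescaled to mean 1 so Laplace counts keep their natural scale.
fit_weighted_tree <- function(x, labels, weights = NULL, config = tree_config()) {
  config <- as_tree_config(config)
  x <- as.matrix(x)
  y <- factor(as.character(labels), levels = c("negative", "positive"))
  if (anyNA(y)) stop("labels must be 'negative' or 'positive'", call. = FALSE)
  if (nlevels(droplevels(y)) < 2L) {
    stop("training data contains a single class; both positive and ",
         "negative examples are required", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, nrow(x))
  stopifnot(length(weights) == nrow(x), all(weights > 0))
  w <- weights * (length(weights) / sum(weights))
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  df <- data.frame(.y = y, x, check.names = FALSE)
  set.seed(config$seed)
  fit <- rpart::rpart(
    .y ~ ., data = df, weights = w, method = "class",
    control = rpart::rpart.control(maxdepth = min(config$maxdepth, 30L),
                                   minsplit = config$minsplit,
                                   minbucket = config$minbucket,
                                   cp = config$cp, xval = 0L))
  structure(list(fit = fit, n_features = ncol(x), config = config),
            class = "weighted_tree")
}

# Positive-class probability for each row of a feature matrix.
predict_tree_prob <- function(model, x) {
  stopifnot(inherits(model, "weighted_tree"))
  x <- as.matrix(x)
  if (ncol(x) != model$n_features) {
    stop("feature length mismatch: model expects ", model$n_features,
         " features, got ", ncol(x), call. = FALSE)
  }
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  one_row <- nrow(x) == 1L
  if (one_row) x <- rbind(x, x)  # predict.rpart(type = "matrix") needs >= 2 rows
  df <- as.data.frame(x)
  m <- predict(model$fit, newdata = df, type = "matrix")
  if (one_row) m <- m[1L, , drop = FALSE]
  # columns: fitted class, weighted count (neg, pos), prob (neg, pos), node mass
  n_neg <- m[, 2L]
  n_pos <- m[, 3L]
  if (model$config$laplace) {
    (n_pos + 1) / (n_neg + n_pos + 2)
  } else {
    n_pos / (n_neg + n_pos)
  }
}
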