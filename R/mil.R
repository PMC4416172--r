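# The wrapper-based multiple-instance learner: flatten bags for training,
# average instance probabilities for bag prediction, expose instance scores
# for binding-site localization.

#' Flatten bags into a weighted single-instance training set
#'
#' Each instance becomes one training row carrying its bag's label and its
#' initial weight `1 / bag size`, so every bag contributes total weight 1
#' regardless of probe length. Provenance (probe id, offset, k-mer) is kept
#' per row.
#'
#' @param bags Nonempty list of `mil_bag` with a common `k` and feature
#'   length.
#' @return List of class `flattened_bags`: `features` (matrix), `labels`,
#'   `weights`, `provenance` (data.frame `probe_id`, `offset`, `kmer`), `k`.
#' @export
flatten_bags <- function(bags) {
  stopifnot(is.list(bags), length(bags) > 0L)
  lapply(bags, function(b) stopifnot(inherits(b, "mil_bag")))
  ks <- vapply(bags, function(b) b$k, integer(1L))
  fl <- vapply(bags, function(b) ncol(b$features), integer(1L))
  if (length(unique(ks)) != 1L || length(unique(fl)) != 1L) {
    stop("bags are heterogeneous: all bags must share the same k and ",
         "feature length (found k in {", paste(unique(ks), collapse = ", "),
         "})", call. = FALSE)
  }
  features <- do.call(rbind, lapply(bags, function(b) b$features))
  labels <- unlist(lapply(bags, function(b) rep(b$label, length(b$kmers))))
  weights <- unlist(lapply(bags, function(b) b$weights))
  provenance <- data.frame(
    probe_id = unlist(lapply(bags, function(b) rep(b$probe_id, length(b$kmers)))),
    offset = unlist(lapply(bags, function(b) b$offsets)),
    kmer = unlist(lapply(bags, function(b) b$kmers)),
    stringsAsFactors = FALSE)
  structure(list(features = features, labels = labels, weights = weights,
                 provenance = provenance, k = ks[1L]),
            class = "flattened_bags")
}

#' Train a multiple-instance model on labeled bags
#'
#' The multiple-instance wrapper: bags are flattened to weighted,
#' bag-labeled single instances (see [flatten_bags()]) and the base
#' weighted-instance decision tree is fitted once on the flattened rows.
#' Training is single-pass; see [mil_train_iterative()] for the experimental
#' reweighting variant.
#'
#' @param bags List of `mil_bag` containing at least one positive and one
#'   negative bag.
#' @param config A [tree_config()].
#' @param table_source Provenance string of the structural table used to
#'   build the bags (recorded on the model).
#' @return Object of class `mil_model`: the fitted base classifier plus
#'   `feature_model = "mil3d_kmer"`, `k`, `config`, `table_source`.
#' @export
mil_train <- function(bags, config = tree_config(), table_source = "") {
  flat <- flatten_bags(bags)
  tree <- fit_weighted_tree(flat$features, flat$labels, flat$weights, config)
  structure(list(tree = tree, feature_model = "mil3d_kmer", k = flat$k,
                 feature_length = ncol(flat$features),
                 config = as_tree_config(config),
                 table_source = table_source),
            class = "mil_model")
}

#' Iteratively re-weighted multiple-instance training (experimental)
#'
#' After the single-pass fit, instance weights are replaced by the previous
#' model's instance probabilities (renormalized within each bag to sum to 1;
#' negative bags keep uniform weights) and the tree is refitted, for a fixed
#' number of rounds. This explores the idea that instance weights can be
#' sharpened as the model localizes the binding site. It is not part of the
#' benchmarked method and is off by default everywhere.
#'
#' @inheritParams mil_train
#' @param n_iter Number of reweighting rounds after the initial fit.
#' @return A `mil_model`.
#' @export
mil_train_iterative <- function(bags, config = tree_config(), n_iter = 2L,
                                table_source = "") {
  model <- mil_train(bags, config, table_source)
  flat <- flatten_bags(bags)
  bag_ids <- flat$provenance$probe_id
  for (i in seq_len(n_iter)) {
    p <- predict_tree_prob(model$tree, flat$features)
    w <- flat$weights
    pos_rows <- flat$labels == "positive"
    w[pos_rows] <- p[pos_rows]
    # renormalize so each bag still contributes total weight 1
    totals <- tapply(w, bag_ids, sum)
    w <- w / as.numeric(totals[bag_ids])
    tree <- fit_weighted_tree(flat$features, flat$labels, w, config)
    model$tree <- tree
  }
  model$iterative <- n_iter
  model
}

#' Predict the binding probability of one bag
#'
#' Each instance is scored by the base classifier; the bag probability is
#' the unweighted arithmetic mean of the instance probabilities. Training
#' weights play no role at prediction time.
#'
#' @param model A `mil_model`.
#' @param bag A `mil_bag` with the model's feature length.
#' @return List of class `bag_prediction`: `probe_id`, `bag_probability`,
#'   `instance_probabilities` (aligned with `bag$offsets`).
#' @export
predict_bag <- function(model, bag) {
  stopifnot(inherits(model, "mil_model"), inherits(bag, "mil_bag"))
  if (ncol(bag$features) != model$feature_length) {
    stop("feature length mismatch: model expects ", model$feature_length,
         ", bag has ", ncol(bag$features), call. = FALSE)
  }
  p <- predict_tree_prob(model$tree, bag$features)
  structure(list(probe_id = bag$probe_id, bag_probability = mean(p),
                 instance_probabilities = as.numeric(p)),
            class = "bag_prediction")
}

#' Predict binding probabilities for a list of bags
#'
#' @param model A `mil_model`.
#' @param bags List of `mil_bag`.
#' @return data.frame with `probe_id`, `label` (as carried by the bags) and
#'   `bag_probability`.
#' @export
predict_bags <- function(model, bags) {
  preds <- lapply(bags, function(b) predict_bag(model, b))
  data.frame(
    probe_id = vapply(preds, function(p) p$probe_id, character(1L)),
    label = vapply(bags, function(b) b$label, character(1L)),
    bag_probability = vapply(preds, function(p) p$bag_probability,
                             numeric(1L)),
    stringsAsFactors = FALSE)
}

#' Per-instance binding-site scores
#'
#' Extracts the positive-class probability of every instance in every bag —
#' the quantity used to localize putative binding sites within positive
#' probes. The result is sorted by probability descending, ties broken by
#' (probe_id, offset).
#'
#' @param model A `mil_model`.
#' @param bags List of `mil_bag` (may be empty).
#' @return data.frame with `probe_id`, `offset`, `kmer`, `probability`.
#' @export
instance_scores <- function(model, bags) {
  if (length(bags) == 0L) {
    return(data.frame(probe_id = character(), offset = integer(),
                      kmer = character(), probability = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(bags, function(b) {
    pred <- predict_bag(model, b)
    data.frame(probe_id = b$probe_id, offset = b$offsets, kmer = b$kmers,
               probability = pred$instance_probabilities,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$probability, out$probe_id, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.mil_model <- function(x, ...) {
  cat("Multiple-instance model (", x$feature_model, "), k =", x$k,
      ", feature length", x$feature_length, "\n")
  cat("structural table:", x$table_source, "\n")
  invisible(x)
}

#' Save / load a trained model
#'
#' Models are persisted as a small versioned archive (RDS) holding the
#' fitted classifier and the feature-model metadata needed to apply it.
#'
#' @param model A `mil_model` or `sil_model`.
#' @param path File path.
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mil_model") || inherits(model, "sil_model"))
  saveRDS(list(format = "milbind-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "milbind-model")) {
    stop("not a milbind model archive: ", path, call. = FALSE)
  }
  obj$model
}
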