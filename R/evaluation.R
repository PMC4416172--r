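# AUC scoring, benchmark reports, top-scoring k-mer tables and the
# gain-correlation analyses.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly drawn positive
#' outscores a uniformly drawn negative, with ties counting 1/2. Computed
#' from midranks, so it is exact and O(n log n).
#'
#' @param labels Logical vector, or anything coercible via
#'   `labels == positive_level`; both classes must be present.
#' @param scores Numeric scores, higher = more positive.
#' @param positive_level The label value treated as positive (default
#'   `"positive"`; ignored if `labels` is logical).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(labels, scores, positive_level = "positive") {
  if (!is.logical(labels)) labels <- labels == positive_level
  stopifnot(length(labels) == length(scores), !anyNA(labels), !anyNA(scores))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC is undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' GC content of a sequence
#'
#' @param sequence Nonempty DNA string.
#' @return Fraction of G or C bases, in \[0, 1\].
#' @export
gc_content <- function(sequence) {
  s <- normalize_dna(sequence)
  if (nchar(s) == 0L) stop("empty sequence", call. = FALSE)
  mean(strsplit(s, "")[[1L]] %in% c("G", "C"))
}

#' Pearson correlation with two-sided p-value
#'
#' Thin wrapper around [stats::cor.test()] returning just the sample
#' correlation and its two-sided t-distribution p-value.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r` and `p`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = unname(ct$p.value))
}

#' Two-sided paired t-test on matched score lists
#'
#' Used to compare per-TF AUCs of two models across a panel of transcription
#' factors.
#'
#' @param a,b Numeric vectors of equal length >= 2 (paired).
#' @return List with `t` and `p`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  if (stats::sd(a - b) == 0 && all(a == b)) {
    return(list(t = 0, p = 1))
  }
  if (stats::sd(a - b) == 0) {
    stop("degenerate paired t-test: differences have zero variance",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), p = unname(tt$p.value))
}

#' Table of the most frequent high-probability k-mers
#'
#' From per-instance scores (see [instance_scores()]) on positive probes,
#' keeps instances whose predicted binding probability meets the threshold,
#' counts occurrences of each distinct k-mer among them (one occurrence per
#' qualifying instance; a probe can contribute several), and returns the
#' `top_n` k-mers by count. A large total, or a few dominating k-mers,
#' indicates a strong consensus binding site. Count ties are broken by
#' lexicographic k-mer order.
#'
#' @param scored data.frame with at least `kmer` and `probability` columns.
#' @param threshold Minimum predicted probability (inclusive; default 0.85).
#' @param top_n Number of k-mers to keep (default 10).
#' @param tf_name Optional label carried on the result.
#' @return Object of class `kmer_frequency_table`: list with `tf_name`,
#'   `rows` (data.frame `kmer`, `count`, sorted by count descending),
#'   `probability_threshold` and `total` (sum of kept counts).
#' @export
top_kmers <- function(scored, threshold = 0.85, top_n = 10L, tf_name = "") {
  stopifnot(is.data.frame(scored),
            all(c("kmer", "probability") %in% names(scored)))
  qual <- scored[scored$probability >= threshold, , drop = FALSE]
  if (nrow(qual) == 0L) {
    rows <- data.frame(kmer = character(), count = integer(),
                       stringsAsFactors = FALSE)
  } else {
    tab <- table(qual$kmer)
    rows <- data.frame(kmer = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
    rows <- rows[order(-rows$count, rows$kmer), , drop = FALSE]
    rows <- utils::head(rows, top_n)
    rownames(rows) <- NULL
  }
  structure(list(tf_name = tf_name, rows = rows,
                 probability_threshold = threshold,
                 total = sum(rows$count)),
            class = "kmer_frequency_table")
}

#' @export
print.kmer_frequency_table <- function(x, ...) {
  cat("Top high-probability k-mers",
      if (nzchar(x$tf_name)) paste("for", x$tf_name) else "",
      "(probability >=", x$probability_threshold, ")\n")
  print(x$rows, row.names = FALSE)
  cat("Total", x$total, "\n")
  invisible(x)
}

# Canonical model-spec normalization: user-facing names are mil3d, sil3d,
# count, count345.
normalize_model_spec <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$name))
  name <- match.arg(spec$name, c("mil3d", "sil3d", "count", "count345"))
  k <- spec$k
  if (name == "mil3d" && is.null(k)) k <- 7L
  if (name == "count" && is.null(k)) k <- 5L
  if (name %in% c("sil3d", "count345")) k <- NA_integer_
  list(name = name, k = if (is.na(k)) NA_integer_ else as.integer(k),
       id = if (is.na(k)) name else paste0(name, "_k", k))
}

# Train one model spec and score the test set; returns label/score columns.
run_model <- function(spec, train, test, table, config) {
  if (spec$name == "mil3d") {
    train_bags <- build_bags(train, spec$k, table)
    test_bags <- build_bags(test, spec$k, table)
    model <- mil_train(train_bags, config, table_source = table$source_name)
    preds <- predict_bags(model, test_bags)
    list(model = model, labels = preds$label, scores = preds$bag_probability,
         test_bags = test_bags)
  } else {
    feature_model <- switch(spec$name, sil3d = "sil3d",
                            count = "kmer_counting",
                            count345 = "combined_counting")
    model <- sil_train(train, feature_model, k = spec$k, table = table,
                       config = config)
    test_probes <- rbind(test$positives, test$negatives)
    labels <- rep(c("positive", "negative"),
                  c(nrow(test$positives), nrow(test$negatives)))
    preds <- sil_predict(model, test_probes, table = table)
    list(model = model, labels = labels, scores = preds$probability,
         test_bags = NULL)
  }
}

#' Benchmark feature models on one transcription factor
#'
#' Trains every requested model on the training probe set, scores the
#' disjoint test set, and assembles per-model AUCs into a report. For
#' multiple-instance models the report also carries the top
#' high-probability k-mer table from the positive test probes and the mean
#' GC content of the positive test probes, the ingredients of the
#' gain-correlation analyses (see [gain_analysis()]). A model that errors is
#' recorded in `errors` without aborting the others.
#'
#' @param train,test `labeled_probes` sets built from different probe
#'   designs; their probe ids must not overlap.
#' @param models List of model specs, each `list(name =, k =)` with name in
#'   `"mil3d"`, `"sil3d"`, `"count"`, `"count345"`. Defaults to the standard
#'   four-way comparison: mil3d k = 7, sil3d, count k = 5, count345.
#' @param table A `structural_table`.
#' @param config A [tree_config()].
#' @param threshold,top_n Passed to [top_kmers()] for multiple-instance
#'   models.
#' @return Object of class `evaluation_report`: list with `tf_name`, `auc`
#'   (data.frame `model`, `k`, `auc`), `top_kmer_tables` (by model id),
#'   `mean_positive_gc`, `errors`.
#' @export
benchmark_tf <- function(train, test,
                         models = list(list(name = "mil3d", k = 7L),
                                       list(name = "sil3d"),
                                       list(name = "count", k = 5L),
                                       list(name = "count345")),
                         table = placeholder_structural_table(),
                         config = tree_config(),
                         threshold = 0.85, top_n = 10L) {
  stopifnot(inherits(train, "labeled_probes"), inherits(test, "labeled_probes"))
  train_ids <- c(train$positives$probe_id, train$negatives$probe_id)
  test_ids <- c(test$positives$probe_id, test$negatives$probe_id)
  if (length(intersect(train_ids, test_ids)) > 0L) {
    stop("train and test probe sets overlap; they must be disjoint",
         call. = FALSE)
  }
  specs <- lapply(models, normalize_model_spec)
  auc_rows <- list()
  top_tables <- list()
  errors <- list()
  for (spec in specs) {
    res <- tryCatch(run_model(spec, train, test, table, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[[spec$id]] <- conditionMessage(res)
      next
    }
    auc_rows[[spec$id]] <- data.frame(model = spec$name, k = spec$k,
                                      auc = auc_score(res$labels, res$scores),
                                      stringsAsFactors = FALSE)
    if (spec$name == "mil3d") {
      pos_bags <- Filter(function(b) b$label == "positive", res$test_bags)
      scored <- instance_scores(res$model, pos_bags)
      top_tables[[spec$id]] <- top_kmers(scored, threshold = threshold,
                                         top_n = top_n,
                                         tf_name = test$tf_name)
    }
  }
  auc <- if (length(auc_rows)) do.call(rbind, auc_rows) else
    data.frame(model = character(), k = integer(), auc = numeric())
  rownames(auc) <- NULL
  structure(list(tf_name = test$tf_name, auc = auc,
                 top_kmer_tables = top_tables,
                 mean_positive_gc = mean(vapply(test$positives$sequence,
                                                gc_content, numeric(1L))),
                 errors = errors),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Benchmark report for", x$tf_name, "\n")
  print(x$auc, row.names = FALSE)
  if (length(x$errors)) {
    cat("errors:\n")
    for (id in names(x$errors)) cat("  ", id, ": ", x$errors[[id]], "\n", sep = "")
  }
  invisible(x)
}

#' Gain-correlation and paired-test analysis across transcription factors
#'
#' Given one [benchmark_tf()] report per TF, computes, for a chosen model
#' pair, the per-TF AUC gain (model_a minus model_b) and its Pearson
#' correlation with (a) the total occurrence of the top high-probability
#' k-mers and (b) the mean GC content of the positive test probes, plus the
#' two-sided paired t-test on the per-TF AUCs. Large total k-mer occurrence
#' marks a strong sequence consensus; the structural multiple-instance model
#' is expected to gain most where that consensus is weak.
#'
#' @param reports List of `evaluation_report`, one per TF.
#' @param model_a,model_b Model ids as in the reports' AUC tables
#'   (e.g. `"mil3d_k7"`, `"count_k5"`); gain = AUC(a) - AUC(b).
#' @return List of class `gain_analysis`: per-TF data.frame and the
#'   correlation / paired-test results.
#' @export
gain_analysis <- function(reports, model_a = "mil3d_k7", model_b = "count_k5") {
  stopifnot(length(reports) >= 2L)
  get_auc <- function(rep, id) {
    tab <- rep$auc
    ids <- ifelse(is.na(tab$k), tab$model, paste0(tab$model, "_k", tab$k))
    hit <- which(ids == id)
    if (length(hit) != 1L) stop("model ", id, " missing from report for ",
                                rep$tf_name, call. = FALSE)
    tab$auc[hit]
  }
  per_tf <- do.call(rbind, lapply(reports, function(rep) {
    tot <- if (model_a %in% names(rep$top_kmer_tables))
      rep$top_kmer_tables[[model_a]]$total else NA_integer_
    data.frame(tf_name = rep$tf_name,
               auc_a = get_auc(rep, model_a), auc_b = get_auc(rep, model_b),
               top_kmer_total = tot, mean_positive_gc = rep$mean_positive_gc,
               stringsAsFactors = FALSE)
  }))
  per_tf$gain <- per_tf$auc_a - per_tf$auc_b
  rownames(per_tf) <- NULL
  cor_occ <- if (all(!is.na(per_tf$top_kmer_total)) &&
                 stats::sd(per_tf$top_kmer_total) > 0 &&
                 stats::sd(per_tf$gain) > 0)
    pearson_cor(per_tf$top_kmer_total, per_tf$gain) else NULL
  cor_gc <- if (stats::sd(per_tf$mean_positive_gc) > 0 &&
                stats::sd(per_tf$gain) > 0)
    pearson_cor(per_tf$mean_positive_gc, per_tf$gain) else NULL
  structure(list(model_a = model_a, model_b = model_b, per_tf = per_tf,
                 cor_gain_vs_kmer_total = cor_occ,
                 cor_gain_vs_gc = cor_gc,
                 paired = paired_ttest(per_tf$auc_a, per_tf$auc_b)),
            class = "gain_analysis")
}

#' Serialize / restore an evaluation report
#'
#' Reports are written as JSON with stable key order; AUC matrices can also
#' be exported as TSV via [write_auc_tsv()].
#'
#' @param report An `evaluation_report`.
#' @param path File path.
#' @return `read_report` returns the report; `write_report` returns `path`
#'   invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  obj <- list(tf_name = report$tf_name,
              auc = report$auc,
              top_kmer_tables = lapply(report$top_kmer_tables, function(t) {
                list(tf_name = t$tf_name, rows = t$rows,
                     probability_threshold = t$probability_threshold,
                     total = t$total)
              }),
              mean_positive_gc = report$mean_positive_gc,
              errors = report$errors)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  auc <- as.data.frame(obj$auc, stringsAsFactors = FALSE)
  auc$k <- as.integer(auc$k)
  tops <- lapply(obj$top_kmer_tables, function(t) {
    rows <- as.data.frame(t$rows, stringsAsFactors = FALSE)
    if (nrow(rows)) rows$count <- as.integer(rows$count)
    structure(list(tf_name = t$tf_name, rows = rows,
                   probability_threshold = t$probability_threshold,
                   total = as.integer(t$total)),
              class = "kmer_frequency_table")
  })
  structure(list(tf_name = obj$tf_name, auc = auc, top_kmer_tables = tops,
                 mean_positive_gc = obj$mean_positive_gc,
                 errors = as.list(obj$errors)),
            class = "evaluation_report")
}

#' Write the AUC matrix of one or more reports as TSV
#'
#' @param reports An `evaluation_report` or list of them.
#' @param path Output path.
#' @export
write_auc_tsv <- function(reports, path) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  rows <- do.call(rbind, lapply(reports, function(rep) {
    cbind(tf_name = rep$tf_name, rep$auc)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
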