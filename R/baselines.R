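# Single-instance comparison feature models: positional structural
# concatenation (SIL3D) and k-mer occurrence counting.

#' Positional structural feature vector of a whole probe (SIL3D)
#'
#' Concatenates the structural table rows of every overlapping trinucleotide
#' of the sequence in positional order — one feature vector per probe, used
#' with conventional single-instance learning. For the standard 35-mer probe
#' this gives `33 * 6 = 198` features. By construction this equals
#' [kmer_structural_vector()] applied to the full sequence.
#'
#' @param sequence DNA string, length >= 3.
#' @param table A `structural_table`.
#' @return Numeric vector of length `(nchar(sequence) - 2) * 6`.
#' @export
sil3d_features <- function(sequence, table) {
  kmer_structural_vector(sequence, table)
}

#' k-mer occurrence-count feature vector
#'
#' Counts overlapping occurrences of every possible k-mer on the forward
#' strand, indexed in lexicographic order (A < C < G < T). The counts sum to
#' `L - k + 1`.
#'
#' @param sequence DNA string with `nchar(sequence) >= k`.
#' @param k Word length (3-8 is the usual range; `4^k` features).
#' @return Named integer vector of length `4^k`.
#' @export
kmer_count_features <- function(sequence, k) {
  s <- normalize_dna(sequence)
  k <- as.integer(k)
  if (k < 1L) stop("k must be positive", call. = FALSE)
  L <- nchar(s)
  if (L < k) {
    stop("sequence length (", L, ") is smaller than k (", k, ")",
         call. = FALSE)
  }
  digits <- match(strsplit(s, "")[[1L]], c("A", "C", "G", "T")) - 1L
  pow <- 4L^((k - 1L):0L)
  idx <- vapply(seq_len(L - k + 1L), function(i) {
    sum(digits[i:(i + k - 1L)] * pow) + 1L
  }, numeric(1L))
  counts <- integer(4L^k)
  tab <- table(idx)
  counts[as.integer(names(tab))] <- as.integer(tab)
  names(counts) <- all_kmers(k)
  counts
}

#' Combined 3+4+5-mer counting features
#'
#' Concatenates the 3-mer, 4-mer and 5-mer occurrence-count vectors in that
#' order: `64 + 256 + 1024 = 1344` features.
#'
#' @param sequence DNA string of length >= 5.
#' @return Named integer vector of length 1344.
#' @export
combined_count_features <- function(sequence) {
  c(kmer_count_features(sequence, 3L),
    kmer_count_features(sequence, 4L),
    kmer_count_features(sequence, 5L))
}

# Feature matrix (one row per probe) for a single-instance feature model.
sil_feature_matrix <- function(sequences, feature_model, k = NULL,
                               table = NULL) {
  feature_model <- match.arg(feature_model,
                             c("sil3d", "kmer_counting", "combined_counting"))
  fv <- switch(feature_model,
    sil3d = {
      stopifnot(inherits(table, "structural_table"))
      lapply(sequences, sil3d_features, table = table)
    },
    kmer_counting = {
      stopifnot(!is.null(k))
      lapply(sequences, kmer_count_features, k = as.integer(k))
    },
    combined_counting = lapply(sequences, combined_count_features))
  lens <- vapply(fv, length, integer(1L))
  if (length(unique(lens)) != 1L) {
    stop("probes of differing length produce inconsistent ", feature_model,
         " feature vectors; use equal-length probes for this model",
         call. = FALSE)
  }
  do.call(rbind, fv)
}

#' Train a single-instance baseline model
#'
#' Fits the same base weighted-instance decision tree used by the
#' multiple-instance wrapper, but on one feature vector per probe (unit
#' weights). This is the conventional-learning arm of the benchmark.
#'
#' @param labeled A `labeled_probes` set.
#' @param feature_model One of `"sil3d"`, `"kmer_counting"`,
#'   `"combined_counting"`.
#' @param k Word length for `"kmer_counting"`; ignored otherwise.
#' @param table `structural_table`, required for `"sil3d"`.
#' @param config A [tree_config()].
#' @return Object of class `sil_model` with the fitted tree and feature-model
#'   metadata.
#' @export
sil_train <- function(labeled, feature_model, k = NULL, table = NULL,
                      config = tree_config()) {
  stopifnot(inherits(labeled, "labeled_probes"))
  sequences <- c(labeled$positives$sequence, labeled$negatives$sequence)
  labels <- rep(c("positive", "negative"),
                c(nrow(labeled$positives), nrow(labeled$negatives)))
  x <- sil_feature_matrix(sequences, feature_model, k = k, table = table)
  tree <- fit_weighted_tree(x, labels, weights = NULL, config = config)
  structure(list(tree = tree, feature_model = feature_model,
                 k = if (is.null(k)) NA_integer_ else as.integer(k),
                 feature_length = ncol(x),
                 config = as_tree_config(config),
                 table_source = if (inherits(table, "structural_table"))
                   table$source_name else ""),
            class = "sil_model")
}

#' Score probes with a single-instance baseline model
#'
#' @param model A `sil_model`.
#' @param probes data.frame with `probe_id` and `sequence` columns.
#' @param table `structural_table`; required when the model's feature model
#'   is `"sil3d"`.
#' @return data.frame with `probe_id` and `probability` (positive-class).
#' @export
sil_predict <- function(model, probes, table = NULL) {
  stopifnot(inherits(model, "sil_model"), is.data.frame(probes))
  x <- sil_feature_matrix(probes$sequence, model$feature_model,
                          k = model$k, table = table)
  if (ncol(x) != model$feature_length) {
    stop("feature length mismatch: model expects ", model$feature_length,
         ", probes give ", ncol(x), call. = FALSE)
  }
  data.frame(probe_id = probes$probe_id,
             probability = predict_tree_prob(model$tree, x),
             stringsAsFactors = FALSE)
}

#' @export
print.sil_model <- function(x, ...) {
  cat("Single-instance model (", x$feature_model, ")",
      if (!is.na(x$k)) paste0(", k = ", x$k) else "",
      ", feature length ", x$feature_length, "\n", sep = "")
  invisible(x)
}
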