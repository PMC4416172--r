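# Decomposing probes into bags of weighted k-mer instances.

#' Sliding-window decomposition of a sequence into k-mers
#'
#' Returns all `L - k + 1` overlapping windows of length `k`, step 1, left to
#' right. Offsets are 0-based; each window covers the half-open interval
#' `[offset, offset + k)`.
#'
#' @param sequence DNA string (A/C/G/T, any case).
#' @param k Window length, `3 <= k <= nchar(sequence)`.
#' @return data.frame with columns `offset` (integer) and `kmer` (character).
#' @export
decompose_kmers <- function(sequence, k) {
  s <- normalize_dna(sequence)
  k <- as.integer(k)
  L <- nchar(s)
  if (k < 3L) stop("k must be >= 3, got ", k, call. = FALSE)
  if (L < k) {
    stop("sequence length (", L, ") is smaller than k (", k, ")",
         call. = FALSE)
  }
  starts <- seq_len(L - k + 1L)
  data.frame(offset = starts - 1L,
             kmer = substring(s, starts, starts + k - 1L),
             stringsAsFactors = FALSE)
}

#' Build a bag of weighted structural instances from one probe
#'
#' The probe sequence is decomposed into its `L - k + 1` overlapping k-mers;
#' each k-mer becomes one instance whose feature vector is its trinucleotide
#' structural concatenation (length `(k-2)*6`, see
#' [kmer_structural_vector()]). Every instance gets the same initial weight
#' `1 / (L - k + 1)` — with no prior on where the binding site sits, all
#' windows are equally plausible — so a bag's weights always sum to 1.
#'
#' @param probe_id Probe identifier.
#' @param sequence Probe DNA string.
#' @param label `"positive"` or `"negative"`.
#' @param k Instance k-mer length (candidate binding-site length; 5-8 is the
#'   benchmarked range).
#' @param table A `structural_table`.
#' @param add_revcomp If `TRUE`, also instance the reverse-complement k-mers;
#'   the bag doubles in size and weights halve. Off by default: the mapping
#'   is strand-naive.
#' @return An object of class `mil_bag`: list with `probe_id`, `label`, `k`,
#'   `offsets`, `kmers`, `features` (matrix, one row per instance) and
#'   `weights`.
#' @export
build_bag <- function(probe_id, sequence, label, k, table,
                      add_revcomp = FALSE) {
  label <- match.arg(label, c("positive", "negative"))
  stopifnot(inherits(table, "structural_table"))
  win <- decompose_kmers(sequence, k)
  k <- as.integer(k)
  # windows share triplets: look up the probe's triplet rows once, then
  # slice; identical to per-window kmer_structural_vector
  s <- normalize_dna(sequence)
  rows <- table$values[sequence_triplets(s), , drop = FALSE]
  flat <- as.vector(t(rows))  # triplet-major, 6 values per triplet
  n_win <- nrow(win)
  width <- (k - 2L) * 6L
  feats <- t(vapply(seq_len(n_win), function(i) {
    flat[((i - 1L) * 6L + 1L):((i - 1L) * 6L + width)]
  }, numeric(width)))
  colnames(feats) <- paste0(rep(colnames(table$values), times = k - 2L),
                            ".", rep(seq_len(k - 2L), each = 6L))
  offsets <- win$offset
  kmers <- win$kmer
  if (add_revcomp) {
    rc <- unname(vapply(kmers, revcomp_dna, character(1L)))
    feats <- rbind(feats, t(vapply(rc, kmer_structural_vector,
                                   numeric(ncol(feats)), table = table)))
    offsets <- c(offsets, win$offset)
    kmers <- c(kmers, rc)
  }
  n <- length(kmers)
  rownames(feats) <- NULL
  structure(list(probe_id = as.character(probe_id), label = label,
                 k = as.integer(k), offsets = offsets, kmers = kmers,
                 features = feats, weights = rep(1 / n, n)),
            class = "mil_bag")
}

#' Build bags for a whole labeled probe set
#'
#' @param labeled A `labeled_probes` object from [label_by_signal()].
#' @param k Instance k-mer length.
#' @param table A `structural_table`.
#' @param add_revcomp See [build_bag()].
#' @return List of `mil_bag`, positives first.
#' @export
build_bags <- function(labeled, k, table, add_revcomp = FALSE) {
  stopifnot(inherits(labeled, "labeled_probes"))
  one_side <- function(df, label) {
    lapply(seq_len(nrow(df)), function(i) {
      build_bag(df$probe_id[i], df$sequence[i], label, k, table,
                add_revcomp = add_revcomp)
    })
  }
  c(one_side(labeled$positives, "positive"),
    one_side(labeled$negatives, "negative"))
}

#' Reverse complement of a DNA string
#'
#' @param sequence DNA string (A/C/G/T, any case).
#' @return Uppercase reverse complement.
#' @export
revcomp_dna <- function(sequence) {
  s <- normalize_dna(sequence)
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

#' @export
print.mil_bag <- function(x, ...) {
  cat("Bag", x$probe_id, "(", x$label, "):", length(x$kmers),
      "instances of k =", x$k, ", feature length", ncol(x$features), "\n")
  invisible(x)
}

#' Dump a bag as a TSV table (offset, kmer, weight, features)
#'
#' @param bag A `mil_bag`.
#' @param path Output path, or `""` for stdout.
#' @export
dump_bag <- function(bag, path = "") {
  stopifnot(inherits(bag, "mil_bag"))
  df <- data.frame(offset = bag$offsets, kmer = bag$kmers,
                   weight = bag$weights, bag$features, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
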