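# Reading PBM probe tables and labeling probes by binding signal.

#' Read a PBM probe table
#'
#' Expects a tab-separated file with columns `probe_id`, `sequence`, `signal`
#' (one probe per row). Sequences are uppercased; probes whose sequence
#' contains anything outside A/C/G/T are dropped with a warning giving the
#' count. Row order is preserved.
#'
#' @param path Path to the probe TSV.
#' @param header Whether the file has a header row (default `TRUE`).
#' @param strict_length If not `NULL`, require every kept sequence to have
#'   exactly this length (the standard universal-PBM design uses 35-mers).
#' @return A data.frame with columns `probe_id` (character), `sequence`
#'   (character, uppercase) and `signal` (numeric).
#' @export
read_probes <- function(path, header = TRUE, strict_length = NULL) {
  if (!file.exists(path)) {
    stop("probe file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, header = header, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L) {
    return(data.frame(probe_id = character(), sequence = character(),
                      signal = numeric(), stringsAsFactors = FALSE))
  }
  if (ncol(raw) < 3L) {
    stop("probe file must have 3 tab-separated columns ",
         "(probe_id, sequence, signal); found ", ncol(raw), call. = FALSE)
  }
  probe_id <- as.character(raw[[1L]])
  sequence <- toupper(as.character(raw[[2L]]))
  signal <- suppressWarnings(as.numeric(raw[[3L]]))
  bad_sig <- which(is.na(signal) | !is.finite(signal))
  if (length(bad_sig) > 0L) {
    stop("non-numeric signal in probe file at line ",
         bad_sig[1L] + as.integer(header), " (probe ",
         probe_id[bad_sig[1L]], ")", call. = FALSE)
  }
  keep <- !grepl("[^ACGT]", sequence) & nzchar(sequence)
  if (any(!keep)) {
    warning(sum(!keep), " probe(s) dropped: sequence contains non-ACGT ",
            "characters or is empty", call. = FALSE)
  }
  out <- data.frame(probe_id = probe_id[keep], sequence = sequence[keep],
                    signal = signal[keep], stringsAsFactors = FALSE)
  if (!is.null(strict_length)) {
    bad_len <- which(nchar(out$sequence) != strict_length)
    if (length(bad_len) > 0L) {
      stop("probe ", out$probe_id[bad_len[1L]], " has length ",
           nchar(out$sequence[bad_len[1L]]), "; expected ", strict_length,
           call. = FALSE)
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a probe table in the dialect [read_probes()] reads
#'
#' @param probes data.frame with `probe_id`, `sequence`, `signal`.
#' @param path Output path.
#' @export
write_probes <- function(probes, path) {
  stopifnot(all(c("probe_id", "sequence", "signal") %in% names(probes)))
  utils::write.table(probes[, c("probe_id", "sequence", "signal")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Label probes as bound / unbound by their binding signal
#'
#' Applies the top/bottom selection rule used for universal-PBM arrays: the
#' `n_pos` probes with the highest binding signals become positives and the
#' `n_neg` probes with the lowest become negatives; everything in between is
#' discarded. Ties at either cut are broken deterministically by probe id
#' (ascending), so the result does not depend on input order.
#'
#' @param probes data.frame from [read_probes()].
#' @param n_pos,n_neg Number of positive / negative probes (defaults 3000,
#'   the selection used with ~40,000-probe arrays).
#' @param tf_name Transcription-factor label carried into reports.
#' @param source Free-text provenance.
#' @return An object of class `labeled_probes`: list with data.frames
#'   `positives` and `negatives` (same columns as `probes`), plus `tf_name`
#'   and `source`.
#' @export
label_by_signal <- function(probes, n_pos = 3000L, n_neg = 3000L,
                            tf_name = "TF", source = "") {
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "sequence", "signal") %in% names(probes)))
  n_pos <- as.integer(n_pos); n_neg <- as.integer(n_neg)
  if (n_pos < 1L || n_neg < 1L) {
    stop("n_pos and n_neg must be positive", call. = FALSE)
  }
  if (n_pos + n_neg > nrow(probes)) {
    stop("n_pos + n_neg (", n_pos + n_neg, ") exceeds the number of probes (",
         nrow(probes), ")", call. = FALSE)
  }
  if (anyDuplicated(probes$probe_id)) {
    stop("duplicate probe_id(s) in probe table", call. = FALSE)
  }
  ord_desc <- order(-probes$signal, probes$probe_id)
  ord_asc <- order(probes$signal, probes$probe_id)
  pos <- probes[ord_desc[seq_len(n_pos)], , drop = FALSE]
  neg <- probes[ord_asc[seq_len(n_neg)], , drop = FALSE]
  rownames(pos) <- rownames(neg) <- NULL
  if (length(intersect(pos$probe_id, neg$probe_id)) > 0L) {
    stop("positive and negative selections overlap; n_pos + n_neg too large",
         call. = FALSE)
  }
  structure(list(positives = pos, negatives = neg,
                 tf_name = tf_name, source = source),
            class = "labeled_probes")
}

#' @export
print.labeled_probes <- function(x, ...) {
  cat("Labeled probe set for", x$tf_name, "-",
      nrow(x$positives), "positives,", nrow(x$negatives), "negatives\n")
  if (nzchar(x$source)) cat("source:", x$source, "\n")
  invisible(x)
}
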