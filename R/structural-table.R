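# Trinucleotide structural-parameter tables and k-mer feature vectors.

#' Names of the six base-step structural parameters, in canonical order
#'
#' Every structural table and every feature vector built from one uses this
#' fixed parameter order: shear, buckle, stretch, propeller, stagger, opening.
#'
#' @return Character vector of length 6.
#' @export
structural_parameters <- function() {
  c("shear", "buckle", "stretch", "propeller", "stagger", "opening")
}

#' All k-mers over the DNA alphabet in lexicographic order (A < C < G < T)
#'
#' @param k Word length (positive integer).
#' @return Character vector of length `4^k`.
#' @export
all_kmers <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1L)
  k <- as.integer(k)
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(rep(list(bases), k), stringsAsFactors = FALSE)[, k:1, drop = FALSE]
  sort(do.call(paste0, g))
}

#' Load a trinucleotide structural-parameter table
#'
#' Reads a tab-separated file with a header row
#' `kmer shear buckle stretch propeller stagger opening` and exactly one data
#' row for each of the 64 trinucleotides over A/C/G/T. Trinucleotides are
#' normalized to uppercase. The six real-valued parameters describe the
#' average 3-D conformation of the middle base pair of each triplet (units as
#' in the source molecular-dynamics study; treated as dimensionless here).
#'
#' @param path Path to the TSV file.
#' @param source_name Free-text provenance label stored on the returned table;
#'   defaults to the file's base name.
#' @return An object of class `structural_table`: a list with `values`
#'   (64 x 6 numeric matrix, rownames the trinucleotides, colnames the
#'   parameters) and `source_name`.
#' @seealso [placeholder_structural_table()] for the packaged synthetic table,
#'   [kmer_structural_vector()] to map k-mers to feature vectors.
#' @export
read_structural_table <- function(path, source_name = basename(path)) {
  if (!file.exists(path)) {
    stop("structural table file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  expected_cols <- c("kmer", structural_parameters())
  if (ncol(raw) != length(expected_cols)) {
    stop("structural table must have ", length(expected_cols),
         " tab-separated columns (", paste(expected_cols, collapse = ", "),
         "); found ", ncol(raw), call. = FALSE)
  }
  if (!identical(tolower(names(raw)), expected_cols)) {
    stop("structural table header must be: ",
         paste(expected_cols, collapse = "\t"), call. = FALSE)
  }
  kmers <- toupper(raw$kmer)
  expected <- all_kmers(3L)
  dup <- unique(kmers[duplicated(kmers)])
  if (length(dup) > 0L) {
    stop("duplicate 3-mer(s) in structural table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(expected, kmers)
  if (length(missing) > 0L) {
    stop("missing 3-mer(s) in structural table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(kmers, expected)
  if (length(extra) > 0L) {
    stop("invalid 3-mer(s) in structural table: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow = 64L, ncol = 6L,
                 dimnames = list(expected, structural_parameters()))
  for (j in seq_len(6L)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad) > 0L) {
      stop("non-numeric or non-finite value in structural table, row ",
           bad[1L] + 1L, " (3-mer ", kmers[bad[1L]], "), column '",
           structural_parameters()[j], "'", call. = FALSE)
    }
    vals[kmers, j] <- num
  }
  structure(list(values = vals, source_name = source_name),
            class = "structural_table")
}

#' The packaged placeholder structural table
#'
#' The real trinucleotide base-step parameters come from molecular-dynamics
#' simulations and are not redistributed here. This synthetic stand-in
#' contains fixed pseudo-random values drawn once, per parameter, from ranges
#' plausible for the corresponding base-step descriptor. It exercises every
#' code path identically to a real table; predictions made with it carry no
#' biophysical meaning. Supply a real table via [read_structural_table()] for
#' scientific use.
#'
#' @return A `structural_table` with `source_name = "placeholder-fixture"`.
#' @export
placeholder_structural_table <- function() {
  path <- system.file("extdata", "structural_3mer_placeholder_synthetic.tsv",
                      package = "milbind", mustWork = TRUE)
  read_structural_table(path, source_name = "placeholder-fixture")
}

#' @export
print.structural_table <- function(x, ...) {
  cat("Trinucleotide structural table (64 x 6), source:", x$source_name, "\n")
  print(utils::head(x$values, 4L))
  cat("...\n")
  invisible(x)
}

#' Symmetrize a structural table over base-complement pairs
#'
#' Replaces each triplet's parameter row by the average of its own row and
#' the row of its position-wise complement (A<->T, C<->G), so that
#' complementary triplets share identical parameters. The resulting table is
#' maximally structurally degenerate in sequence space: a sequence and its
#' position-wise complement have exactly the same structural feature vector
#' while sharing no k-mers. This mimics, in controlled form, the degeneracy
#' of real base-step parameter tables in which distinct triplets can adopt
#' near-identical conformations — the regime where structure-aware models
#' retain signal that word-counting models lose. Used by the weak-consensus
#' synthetic benchmarks; not part of the standard feature mapping, which is
#' strand-naive.
#'
#' @param table A `structural_table`.
#' @return A `structural_table` with averaged rows and a `"+comp-sym"`
#'   suffix on `source_name`.
#' @export
complement_symmetrize_table <- function(table) {
  stopifnot(inherits(table, "structural_table"))
  kmers <- rownames(table$values)
  comp <- chartr("ACGT", "TGCA", kmers)
  vals <- (table$values + table$values[comp, , drop = FALSE]) / 2
  rownames(vals) <- kmers
  structure(list(values = vals,
                 source_name = paste0(table$source_name, "+comp-sym")),
            class = "structural_table")
}

#' A synthetic structural table with controlled degeneracy
#'
#' Builds a table in which the 64 trinucleotides fall into `n_classes`
#' structural classes: every triplet in a class shares one prototype
#' parameter row. Real base-step parameter tables are degenerate in this
#' sense — conformationally similar triplets have near-identical parameters
#' even when their sequences are unrelated — and that degeneracy is
#' precisely what lets a structure-based model treat sequence-diverse
#' binding sites as one pattern. This controlled version makes the
#' degeneracy exact, so weak-consensus benchmark datasets can be built whose
#' planted sites are structural synonyms (see [generate_structural_pbm()]
#' with `radius = 0`). Class membership and prototype rows are pseudo-random
#' but fully determined by `seed`; prototypes are drawn from the same
#' plausible per-parameter ranges as the packaged placeholder table.
#'
#' @param n_classes Number of distinct structural classes (default 3; with a
#'   7-base motif this yields site ensembles of roughly a hundred sequences).
#' @param seed Integer seed fixing class membership and prototypes.
#' @return A `structural_table` with `source_name`
#'   `"degenerate-synthetic-<n_classes>"`.
#' @export
degenerate_structural_table <- function(n_classes = 3L, seed = 1L) {
  n_classes <- as.integer(n_classes)
  stopifnot(n_classes >= 2L, n_classes <= 64L)
  kmers <- all_kmers(3L)
  lo <- c(-0.6, -14, -0.30, -20, -0.55, -4.5)
  hi <- c(0.6, 14, 0.25, 4, 0.55, 5.5)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  classes <- sample(rep_len(seq_len(n_classes), 64L))
  proto <- vapply(seq_len(6L), function(j) {
    stats::runif(n_classes, lo[j], hi[j])
  }, numeric(n_classes))
  vals <- proto[classes, , drop = FALSE]
  dimnames(vals) <- list(kmers, structural_parameters())
  structure(list(values = vals,
                 source_name = paste0("degenerate-synthetic-", n_classes)),
            class = "structural_table")
}

# Uppercase a DNA string and reject anything outside A/C/G/T.
normalize_dna <- function(sequence, what = "sequence") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  if (grepl("[^ACGT]", s)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", s), "")[[1L]])
    stop("invalid ", what, ": contains non-ACGT character(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  s
}

# All overlapping 3-mers of a sequence, left to right.
sequence_triplets <- function(s) {
  n <- nchar(s)
  substring(s, seq_len(n - 2L), seq_len(n - 2L) + 2L)
}

#' Structural feature vector of a k-mer
#'
#' Maps a k-mer (k >= 3) to the concatenation, left to right, of the table
#' rows for each of its k-2 overlapping trinucleotides, giving a vector of
#' length `(k-2)*6`. A 7-mer therefore yields 30 features from its 5
#' triplets; a 3-mer yields exactly its own table row. Lookup is
#' case-insensitive.
#'
#' @param kmer DNA string of length >= 3, A/C/G/T only (any case).
#' @param table A `structural_table`.
#' @return Numeric vector of length `(nchar(kmer) - 2) * 6`, named
#'   `<parameter>.<triplet index>`.
#' @export
kmer_structural_vector <- function(kmer, table) {
  stopifnot(inherits(table, "structural_table"))
  s <- normalize_dna(kmer, "k-mer")
  k <- nchar(s)
  if (k < 3L) {
    stop("k-mer must have length >= 3, got ", k, call. = FALSE)
  }
  triplets <- sequence_triplets(s)
  m <- table$values[triplets, , drop = FALSE]
  out <- as.vector(t(m))
  names(out) <- paste0(rep(colnames(table$values), times = length(triplets)),
                       ".", rep(seq_along(triplets), each = 6L))
  out
}
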