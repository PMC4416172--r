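# Synthetic PBM-like data with planted binding sites, for end-to-end testing
# and benchmarking without any external array download.

SYNTH_PURPOSES <- c("sequence", "offsets", "variants", "mutations", "noise")

# One global seed drives a named substream per purpose, so adding a feature
# never perturbs the draws of existing streams.
substream_seed <- function(seed, purpose) {
  idx <- match(purpose, SYNTH_PURPOSES)
  stopifnot(!is.na(idx))
  as.integer((abs(as.numeric(seed)) * 31 + idx * 1000003) %% 2147483629)
}

with_substream <- function(seed, purpose, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substream_seed(seed, purpose))
  force(code)
}

#' Specification of a synthetic PBM dataset
#'
#' Describes a dataset of fixed-length probes with i.i.d. background bases at
#' a chosen GC level, a consensus binding site planted into positive probes,
#' and a real-valued binding signal whose ranking approximately recovers the
#' planted classes. Defaults mirror the universal-PBM setting this package
#' targets: 35-base probes and 3000 probes per class.
#'
#' @param motif Planted consensus site (DNA string, required;
#'   `nchar(motif) <= probe_length`).
#' @param n_pos,n_neg Number of positive / negative probes.
#' @param probe_length Probe length in bases (default 35).
#' @param motif_insert_probability Probability that a positive probe actually
#'   receives the site (default 1).
#' @param mutation_rate Per-base probability that a planted site base is
#'   replaced by a different random base (default 0).
#' @param background_gc Background GC fraction in (0, 1) (default 0.5, the
#'   array designs are near-uniform).
#' @param signal_effect Mean signal increment for probes carrying a site
#'   (arbitrary units; default 3).
#' @param signal_noise_sd Gaussian noise s.d. added to every signal
#'   (default 1; signal-vs-class AUC approaches 1 as this goes to 0).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(motif, n_pos = 3000L, n_neg = 3000L,
                           probe_length = 35L,
                           motif_insert_probability = 1,
                           mutation_rate = 0, background_gc = 0.5,
                           signal_effect = 3, signal_noise_sd = 1,
                           seed = 0L) {
  motif <- normalize_dna(motif, "motif")
  probe_length <- as.integer(probe_length)
  if (nchar(motif) > probe_length) {
    stop("motif (", nchar(motif), " bases) is longer than probe_length (",
         probe_length, ")", call. = FALSE)
  }
  stopifnot(n_pos >= 1L, n_neg >= 1L,
            motif_insert_probability > 0, motif_insert_probability <= 1,
            mutation_rate >= 0, mutation_rate < 1,
            background_gc > 0, background_gc < 1,
            signal_noise_sd >= 0)
  structure(list(motif = motif, n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg), probe_length = probe_length,
                 motif_insert_probability = motif_insert_probability,
                 mutation_rate = mutation_rate,
                 background_gc = background_gc,
                 signal_effect = signal_effect,
                 signal_noise_sd = signal_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

random_background <- function(n, L, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE, prob = p),
              nrow = n)
  apply(m, 1L, paste, collapse = "")
}

mutate_site <- function(site, flips, replacements) {
  if (!any(flips)) return(site)
  chars <- strsplit(site, "")[[1L]]
  for (i in which(flips)) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[i])
    chars[i] <- alt[replacements[i]]
  }
  paste(chars, collapse = "")
}

# site_per_positive: character vector length n_pos of consensus sites to
# plant (recycled motif by default; the twin generator alternates two).
generate_core <- function(spec, site_per_positive) {
  L <- spec$probe_length
  n <- spec$n_pos + spec$n_neg
  sequences <- with_substream(spec$seed, "sequence",
                              random_background(n, L, spec$background_gc))
  # ids carry the seed so datasets drawn with different seeds never collide
  probe_id <- c(sprintf("s%d_pos_%05d", spec$seed, seq_len(spec$n_pos)),
                sprintf("s%d_neg_%05d", spec$seed, seq_len(spec$n_neg)))

  site_len <- nchar(site_per_positive)
  ins <- with_substream(spec$seed, "offsets", {
    inserted <- stats::runif(spec$n_pos) <= spec$motif_insert_probability
    offset <- vapply(site_len, function(l) {
      sample.int(L - l + 1L, 1L) - 1L
    }, integer(1L))
    list(inserted = inserted, offset = offset)
  })
  planted <- with_substream(spec$seed, "mutations", {
    vapply(seq_len(spec$n_pos), function(i) {
      site <- site_per_positive[i]
      l <- nchar(site)
      flips <- stats::runif(l) < spec$mutation_rate
      replacements <- sample.int(3L, l, replace = TRUE)
      mutate_site(site, flips, replacements)
    }, character(1L))
  })
  offsets <- rep(NA_integer_, n)
  sites <- rep("", n)
  for (i in seq_len(spec$n_pos)) {
    if (!ins$inserted[i]) next
    off <- ins$offset[i]
    site <- planted[i]
    substr(sequences[i], off + 1L, off + nchar(site)) <- site
    offsets[i] <- off
    sites[i] <- site
  }
  signals <- with_substream(spec$seed, "noise", {
    has_site <- c(ifelse(ins$inserted, 1, 0), rep(0, spec$n_neg))
    spec$signal_effect * has_site + stats::rnorm(n, 0, spec$signal_noise_sd)
  })
  probes <- data.frame(probe_id = probe_id, sequence = sequences,
                       signal = signals, stringsAsFactors = FALSE)
  truth <- data.frame(probe_id = probe_id, offset = offsets,
                      site = sites, stringsAsFactors = FALSE)
  list(probes = probes, truth = truth, spec = spec)
}

#' Generate a synthetic PBM dataset
#'
#' Positive probes receive the (possibly mutated) consensus site at a
#' uniformly random offset with the specified probability; all backgrounds
#' are i.i.d. at the specified GC level; signals are base level plus a
#' site-presence effect plus Gaussian noise. The truth table records, for
#' every probe, the exact planted offset (`NA` when no site was planted) and
#' the planted site sequence after mutation.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `probes` (data.frame `probe_id`, `sequence`, `signal`),
#'   `truth` (data.frame `probe_id`, `offset`, `site`) and `spec`.
#' @export
generate_pbm <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  generate_core(spec, rep(spec$motif, spec$n_pos))
}

#' Generate a weak-consensus dataset using a structural twin motif
#'
#' Plants the spec's motif into half of the positive probes (odd indices)
#' and its structural twin — the different equal-length sequence whose
#' structural feature vector is closest to the motif's under `table`, see
#' [structural_twin_motif()] — into the other half. Sequence consensus
#' across positives is thereby weakened while the structural signal is
#' largely preserved: the regime in which structure-aware
#' multiple-instance learning is expected to hold its advantage over plain
#' k-mer counting.
#'
#' @param spec A [synthetic_spec()]; `spec$motif` is the primary site.
#' @param table A `structural_table` used to find the twin.
#' @return As [generate_pbm()], plus a `twin` element with the twin motif.
#' @export
generate_twin_pbm <- function(spec, table) {
  stopifnot(inherits(spec, "synthetic_spec"))
  twin <- structural_twin_motif(table, spec$motif)
  sites <- rep(c(spec$motif, twin), length.out = spec$n_pos)
  out <- generate_core(spec, sites)
  out$twin <- twin
  out
}

#' Generate a weak-consensus dataset from a structural site ensemble
#'
#' The structural-profile mode of the generator: instead of one consensus,
#' each positive probe receives a site drawn uniformly from the
#' `n_neighbors` sequences of the motif's length whose structural feature
#' vectors are closest (Euclidean) to the motif's, motif included
#' (exhaustive search; motif length <= 7). The planted population then has
#' a weak sequence consensus — its k-mer vocabulary is about `n_neighbors`
#' words — while remaining a tight cluster in structural feature space.
#' This is the regime in which structure-aware learning is expected to
#' out-generalize word counting. Pairing with a degenerate table (see
#' [complement_symmetrize_table()]) makes the vocabulary sequence-diverse
#' even at small neighborhood radii.
#'
#' @param spec A [synthetic_spec()]; `spec$motif` defines the structural
#'   target (length 3-7).
#' @param table A `structural_table` defining the structural metric.
#' @param n_neighbors Size of the site ensemble (default 64); ignored when
#'   `radius` is given.
#' @param radius If given, the ensemble is every candidate whose structural
#'   Euclidean distance to the motif is `<= radius`; `radius = 0` with a
#'   degenerate table (see [degenerate_structural_table()]) selects all
#'   exact structural synonyms of the motif.
#' @return As [generate_pbm()], plus `site_ensemble` (the candidate sites).
#' @export
generate_structural_pbm <- function(spec, table, n_neighbors = 64L,
                                    radius = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(table, "structural_table"))
  L <- nchar(spec$motif)
  if (L > 7L) {
    stop("structural-profile mode uses exhaustive search; motif length ",
         "must be <= 7", call. = FALSE)
  }
  target <- kmer_structural_vector(spec$motif, table)
  candidates <- all_kmers(L)
  d <- structural_sqdist(candidates, target, table)
  ensemble <- if (is.null(radius)) {
    candidates[order(d, candidates)][seq_len(n_neighbors)]
  } else {
    candidates[sqrt(d) <= radius]
  }
  sites <- with_substream(spec$seed, "variants", {
    sample(ensemble, spec$n_pos, replace = TRUE)
  })
  out <- generate_core(spec, sites)
  out$site_ensemble <- ensemble
  out
}

#' Write the truth table of a synthetic dataset
#'
#' @param truth data.frame with `probe_id` and `offset` (as produced by
#'   [generate_pbm()]).
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Squared structural distance from each candidate k-mer (character vector,
# all of length L) to a target feature vector, vectorized by triplet column.
structural_sqdist <- function(candidates, target, table) {
  L <- nchar(candidates[1L])
  d <- numeric(length(candidates))
  for (i in seq_len(L - 2L)) {
    trips <- substring(candidates, i, i + 2L)
    rows <- table$values[trips, , drop = FALSE]
    tgt <- target[((i - 1L) * 6L + 1L):(i * 6L)]
    d <- d + rowSums(sweep(rows, 2L, tgt)^2)
  }
  d
}

#' Structural twin of a motif
#'
#' Returns a different sequence of the same length whose structural feature
#' vector is closest (Euclidean distance) to the motif's. For motifs up to 7
#' bases the search is exhaustive over all `4^L` candidates; beyond that a
#' greedy per-position search is used. Ties are broken by lexicographic
#' order, so a degenerate table (all rows equal) yields the lexicographically
#' smallest sequence other than the motif itself.
#'
#' @param table A `structural_table`.
#' @param motif DNA string of length >= 3.
#' @return DNA string of the same length, never equal to `motif`.
#' @export
structural_twin_motif <- function(table, motif) {
  stopifnot(inherits(table, "structural_table"))
  motif <- normalize_dna(motif, "motif")
  L <- nchar(motif)
  if (L < 3L) stop("motif must have length >= 3", call. = FALSE)
  target <- kmer_structural_vector(motif, table)
  if (L <= 7L) {
    candidates <- all_kmers(L)  # lexicographic: ties resolve to smallest
    candidates <- candidates[candidates != motif]
    d <- structural_sqdist(candidates, target, table)
    return(candidates[which.min(d)])
  }
  # greedy: choose each base to minimize the distance of completed triplets
  bases <- c("A", "C", "G", "T")
  chosen <- character(L)
  for (pos in seq_len(L)) {
    best <- NULL
    best_d <- Inf
    for (b in bases) {
      trial <- chosen
      trial[pos] <- b
      d <- 0
      for (i in seq_len(max(0L, pos - 2L))) {
        trip <- paste(trial[i:(i + 2L)], collapse = "")
        tgt <- target[((i - 1L) * 6L + 1L):(i * 6L)]
        d <- d + sum((table$values[trip, ] - tgt)^2)
      }
      if (d < best_d) {
        best_d <- d
        best <- b
      }
    }
    chosen[pos] <- best
  }
  twin <- paste(chosen, collapse = "")
  if (twin != motif) return(twin)
  # greedy reproduced the motif; perturb the final base to the next-best
  pre <- chosen
  alt <- setdiff(bases, chosen[L])
  d_alt <- vapply(alt, function(b) {
    trial <- pre
    trial[L] <- b
    i <- L - 2L
    trip <- paste(trial[i:(i + 2L)], collapse = "")
    tgt <- target[((i - 1L) * 6L + 1L):(i * 6L)]
    sum((table$values[trip, ] - tgt)^2)
  }, numeric(1L))
  pre[L] <- alt[which.min(d_alt)]
  paste(pre, collapse = "")
}
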