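# Shared fixtures, built in code.

the_table <- placeholder_structural_table()

# Write a small probe TSV and return its path.
write_probe_file <- function(lines, header = TRUE) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  if (header) lines <- c("probe_id\tsequence\tsignal", lines)
  writeLines(lines, path)
  path
}

# Random DNA string of length L under a local seed.
random_dna <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# A small labeled synthetic train/test pair with a planted consensus.
# Cached per option set so several tests can share one expensive generation.
make_labeled_pair <- function(n_label = 100L, motif = "TGACGTA",
                              mutation_rate = 0, noise = 0.2,
                              seed = 101L) {
  gen <- function(s) {
    spec <- synthetic_spec(motif = motif, n_pos = n_label + 20L,
                           n_neg = n_label + 20L,
                           mutation_rate = mutation_rate,
                           signal_noise_sd = noise, seed = s)
    generate_pbm(spec)
  }
  train <- gen(seed)
  test <- gen(seed + 1000L)
  list(train = label_by_signal(train$probes, n_label, n_label,
                               tf_name = "synthTF"),
       test = label_by_signal(test$probes, n_label, n_label,
                              tf_name = "synthTF"),
       train_truth = train$truth, test_truth = test$truth)
}
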