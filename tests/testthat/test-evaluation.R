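# AUC, correlation and t-test oracles; top-k-mer tables; benchmark reports.

brute_auc <- function(labels, scores) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels != "positive"]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

test_that("AUC matches the exhaustive pairwise comparison", {
  expect_identical(auc_score(c(TRUE, TRUE, FALSE), c(0.9, 0.8, 0.1)), 1)
  withr::with_seed(31, {
    labels <- ifelse(stats::runif(50) < 0.4, "positive", "negative")
    labels[1:2] <- c("positive", "negative")
    scores <- round(stats::rnorm(50), 1)  # rounding forces some ties
    expect_equal(auc_score(labels, scores), brute_auc(labels, scores),
                 tolerance = 1e-12)
    # complement symmetry (ties absent)
    scores2 <- stats::rnorm(50)
    expect_equal(auc_score(labels, scores2) + auc_score(labels, -scores2), 1,
                 tolerance = 1e-12)
  })
})

test_that("AUC of scores independent of labels is near one half", {
  withr::with_seed(32, {
    labels <- rep(c("positive", "negative"), 2000)
    scores <- stats::rnorm(4000)
    expect_equal(auc_score(labels, scores), 0.5, tolerance = 0.05)
  })
  expect_error(auc_score(rep("positive", 5), 1:5), "both classes")
})

test_that("GC content is the G+C fraction", {
  expect_identical(gc_content("GGCC"), 1)
  expect_identical(gc_content("ATAT"), 0)
  expect_identical(gc_content("ACGT"), 0.5)
  expect_error(gc_content(""), "empty")
})

test_that("Pearson correlation matches the long-hand formula", {
  expect_equal(pearson_cor(1:10, 2 * (1:10) + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_cor(1:10, -(1:10))$r, -1, tolerance = 1e-12)
  withr::with_seed(33, {
    x <- stats::rnorm(10)
    y <- stats::rnorm(10)
    res <- pearson_cor(x, y)
    n <- 10
    r_hand <- (sum(x * y) - n * mean(x) * mean(y)) /
      sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
    t_stat <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
    p_hand <- 2 * stats::pt(-abs(t_stat), df = n - 2)
    expect_equal(res$r, r_hand, tolerance = 1e-10)
    expect_equal(res$p, p_hand, tolerance = 1e-10)
  })
  expect_error(pearson_cor(rep(1, 5), 1:5), "zero variance")
})

test_that("paired t-test equals the one-sample test on differences", {
  expect_identical(paired_ttest(c(1, 2, 3), c(1, 2, 3)), list(t = 0, p = 1))
  withr::with_seed(34, {
    a <- stats::rnorm(12)
    b <- a + 0.5 + stats::rnorm(12, 0, 0.01)
    res <- paired_ttest(a, b)
    one <- stats::t.test(a - b)
    expect_equal(res$t, unname(one$statistic), tolerance = 1e-12)
    expect_equal(res$p, unname(one$p.value), tolerance = 1e-12)
    expect_lt(res$p, 1e-6)
  })
  expect_error(paired_ttest(c(1, 2), c(2, 3)), "degenerate")
})

test_that("top k-mers filters by threshold and counts per qualifying instance", {
  scored <- data.frame(
    kmer = c(rep("AAA", 3), "CCC", rep("GGG", 9)),
    probability = c(rep(0.9, 3), 0.9, rep(0.5, 9)))
  tab <- top_kmers(scored, threshold = 0.85, top_n = 10)
  expect_identical(tab$rows$kmer, c("AAA", "CCC"))
  expect_identical(tab$rows$count, c(3L, 1L))
  expect_identical(tab$total, 4L)

  empty <- top_kmers(scored, threshold = 1.01)
  expect_identical(nrow(empty$rows), 0L)
  expect_identical(empty$total, 0L)
})

test_that("count ties resolve to the lexicographically smaller k-mer", {
  # every arrival order of the tied k-mers gives the same winner
  kmers <- c("TTT", "CCC", "GGG", "AAA")
  for (perm in list(1:4, 4:1, c(2, 4, 1, 3), c(3, 1, 4, 2))) {
    scored <- data.frame(kmer = kmers[perm], probability = rep(0.9, 4))
    tab <- top_kmers(scored, top_n = 1)
    expect_identical(tab$rows$kmer, "AAA")
  }
})

test_that("the benchmark trains all requested models and reports sane AUCs", {
  pair <- make_labeled_pair(n_label = 60L, seed = 601L)
  report <- benchmark_tf(pair$train, pair$test,
                         models = list(list(name = "mil3d", k = 7),
                                       list(name = "sil3d"),
                                       list(name = "count", k = 5),
                                       list(name = "count345")),
                         table = the_table)
  expect_s3_class(report, "evaluation_report")
  expect_identical(nrow(report$auc), 4L)
  expect_true(all(report$auc$auc >= 0 & report$auc$auc <= 1))
  expect_identical(length(report$errors), 0L)
  expect_true("mil3d_k7" %in% names(report$top_kmer_tables))
  expect_true(report$mean_positive_gc > 0 && report$mean_positive_gc < 1)

  # deterministic given identical inputs and seeds
  report2 <- benchmark_tf(pair$train, pair$test,
                          models = list(list(name = "mil3d", k = 7),
                                        list(name = "sil3d"),
                                        list(name = "count", k = 5),
                                        list(name = "count345")),
                          table = the_table)
  expect_equal(report$auc, report2$auc)
  expect_equal(report$top_kmer_tables[["mil3d_k7"]]$rows,
               report2$top_kmer_tables[["mil3d_k7"]]$rows)
})

test_that("benchmark refuses overlapping train/test and captures per-model errors", {
  pair <- make_labeled_pair(n_label = 30L, seed = 602L)
  expect_error(benchmark_tf(pair$train, pair$train), "disjoint")

  # a model that cannot run (sil3d on variable-length probes) is captured
  test2 <- pair$test
  test2$positives$sequence[1] <- substr(test2$positives$sequence[1], 1, 20)
  report <- benchmark_tf(pair$train, test2,
                         models = list(list(name = "sil3d"),
                                       list(name = "count", k = 3)),
                         table = the_table)
  expect_identical(nrow(report$auc), 1L)
  expect_true("sil3d" %in% names(report$errors))
})

test_that("reports serialize and round-trip losslessly", {
  pair <- make_labeled_pair(n_label = 40L, seed = 603L)
  report <- benchmark_tf(pair$train, pair$test,
                         models = list(list(name = "mil3d", k = 5),
                                       list(name = "count", k = 3)),
                         table = the_table)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(report, path)
  back <- read_report(path)
  expect_equal(back$auc, report$auc)
  expect_equal(back$tf_name, report$tf_name)
  expect_equal(back$mean_positive_gc, report$mean_positive_gc)
  expect_equal(back$top_kmer_tables[["mil3d_k5"]]$rows,
               report$top_kmer_tables[["mil3d_k5"]]$rows)
  expect_equal(back$top_kmer_tables[["mil3d_k5"]]$total,
               report$top_kmer_tables[["mil3d_k5"]]$total)
})

test_that("gain analysis assembles per-TF gains and compares model pairs", {
  reports <- lapply(1:4, function(i) {
    pair <- make_labeled_pair(n_label = 40L, seed = 700L + i,
                              motif = c("TGACGTA", "ACAAACA",
                                        "TTTCATT", "CACCTGG")[i])
    rep <- benchmark_tf(pair$train, pair$test,
                        models = list(list(name = "mil3d", k = 7),
                                      list(name = "count", k = 5)),
                        table = the_table)
    rep$tf_name <- paste0("TF", i)
    rep
  })
  ga <- gain_analysis(reports, "mil3d_k7", "count_k5")
  expect_identical(nrow(ga$per_tf), 4L)
  expect_equal(ga$per_tf$gain, ga$per_tf$auc_a - ga$per_tf$auc_b)
  expect_true(is.numeric(ga$paired$p))
  if (!is.null(ga$cor_gain_vs_gc)) {
    expect_true(abs(ga$cor_gain_vs_gc$r) <= 1)
  }
})
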