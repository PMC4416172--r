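# The multiple-instance wrapper: flattening, training, bag prediction and
# instance-level binding-site scores.

make_bag_set <- function(n_per_class = 2, L = 35, k = 7, seed = 3) {
  withr::with_seed(seed, {
    bags <- list()
    for (i in seq_len(n_per_class)) {
      bags[[length(bags) + 1L]] <-
        build_bag(paste0("pos", i), random_dna(L), "positive", k, the_table)
      bags[[length(bags) + 1L]] <-
        build_bag(paste0("neg", i), random_dna(L), "negative", k, the_table)
    }
    bags
  })
}

test_that("flattening copies labels, weights and provenance per instance", {
  bags <- make_bag_set(1)
  flat <- flatten_bags(bags)
  expect_identical(nrow(flat$features), 58L)  # 2 bags x 29 instances
  expect_equal(flat$weights, rep(1 / 29, 58))
  expect_identical(flat$labels,
                   rep(c("positive", "negative"), each = 29))
  expect_identical(flat$provenance$probe_id,
                   rep(c("pos1", "neg1"), each = 29))
  expect_identical(flat$provenance$offset, rep(0:28, 2))
  # per-bag weight totals
  expect_equal(as.numeric(tapply(flat$weights, flat$provenance$probe_id, sum)),
               c(1, 1))
})

test_that("a single one-instance bag flattens to one full-weight row", {
  bag <- build_bag("p", "ACGTACG", "positive", 7, the_table)
  flat <- flatten_bags(list(bag))
  expect_identical(nrow(flat$features), 1L)
  expect_identical(flat$weights, 1)
})

test_that("bags with mixed k are refused", {
  bags <- make_bag_set(1)
  bags[[3]] <- build_bag("x", strrep("ACGTA", 7), "positive", 5, the_table)
  expect_error(flatten_bags(bags), "heterogeneous")
})

test_that("training requires both classes", {
  bags <- Filter(function(b) b$label == "positive", make_bag_set(2))
  expect_error(mil_train(bags), "single class")
})

test_that("bag probability is the arithmetic mean of instance probabilities", {
  pair <- make_labeled_pair(n_label = 40L, seed = 301L)
  bags <- build_bags(pair$train, 7, the_table)
  model <- mil_train(bags, tree_config(), the_table$source_name)
  test_bags <- build_bags(pair$test, 7, the_table)
  withr::with_seed(11, {
    for (bag in sample(test_bags, 100, replace = TRUE)) {
      pred <- predict_bag(model, bag)
      # oracle: score each instance independently, one at a time, and average
      brute <- vapply(seq_along(bag$kmers), function(i) {
        milbind:::predict_tree_prob(model$tree,
                                    bag$features[i, , drop = FALSE])
      }, numeric(1))
      expect_equal(pred$instance_probabilities, brute, tolerance = 1e-12)
      expect_equal(pred$bag_probability, mean(brute), tolerance = 1e-12)
      expect_true(all(pred$instance_probabilities >= 0 &
                        pred$instance_probabilities <= 1))
    }
  })
})

test_that("bag prediction is invariant under instance permutation", {
  pair <- make_labeled_pair(n_label = 40L, seed = 301L)
  model <- mil_train(build_bags(pair$train, 7, the_table))
  bag <- build_bags(pair$test, 7, the_table)[[1]]
  p0 <- predict_bag(model, bag)$bag_probability
  withr::with_seed(13, {
    for (i in 1:5) {
      perm <- sample(length(bag$kmers))
      shuffled <- bag
      shuffled$kmers <- bag$kmers[perm]
      shuffled$offsets <- bag$offsets[perm]
      shuffled$features <- bag$features[perm, , drop = FALSE]
      expect_equal(predict_bag(model, shuffled)$bag_probability, p0,
                   tolerance = 1e-12)
    }
  })
})

test_that("raising one instance's probability cannot lower the bag probability", {
  pair <- make_labeled_pair(n_label = 40L, seed = 301L)
  model <- mil_train(build_bags(pair$train, 7, the_table))
  flat <- flatten_bags(build_bags(pair$train, 7, the_table))
  p_all <- milbind:::predict_tree_prob(model$tree, flat$features)
  best_row <- flat$features[which.max(p_all), , drop = FALSE]
  bag <- build_bags(pair$test, 7, the_table)[[5]]
  p0 <- predict_bag(model, bag)
  i <- which.min(p0$instance_probabilities)
  boosted <- bag
  boosted$features[i, ] <- best_row
  p1 <- predict_bag(model, boosted)
  expect_gte(p1$instance_probabilities[i], p0$instance_probabilities[i])
  expect_gte(p1$bag_probability, p0$bag_probability)
})

test_that("identical feature vectors across classes predict about the class prior", {
  flat_feats <- matrix(1, nrow = 20, ncol = 6)
  bags <- lapply(1:20, function(i) {
    structure(list(probe_id = paste0("b", i),
                   label = if (i <= 15) "positive" else "negative",
                   k = 3L, offsets = 0L, kmers = "AAA",
                   features = flat_feats[i, , drop = FALSE], weights = 1),
              class = "mil_bag")
  })
  model <- mil_train(bags)
  p <- predict_bag(model, bags[[1]])$bag_probability
  expect_equal(p, (15 + 1) / (20 + 2), tolerance = 1e-9)  # smoothed prior
})

test_that("a depth-1 stump still yields valid probabilities", {
  bags <- make_bag_set(5)
  model <- mil_train(bags, tree_config(maxdepth = 1))
  preds <- predict_bags(model, bags)
  expect_true(all(preds$bag_probability >= 0 & preds$bag_probability <= 1))
})

test_that("feature-length mismatches at prediction are refused", {
  bags <- make_bag_set(2)
  model <- mil_train(bags)
  bag5 <- build_bag("x", strrep("ACGTA", 7), "positive", 5, the_table)
  expect_error(predict_bag(model, bag5), "mismatch")
})

test_that("a model trained on separable planted-motif bags ranks held-out bags well", {
  pair <- make_labeled_pair(n_label = 400L, seed = 1L)
  model <- mil_train(build_bags(pair$train, 7, the_table))
  preds <- predict_bags(model, build_bags(pair$test, 7, the_table))
  expect_gt(auc_score(preds$label, preds$bag_probability), 0.9)
})

test_that("instance scores are sorted and locate planted sites in positive bags", {
  pair <- make_labeled_pair(n_label = 400L, seed = 1L)
  model <- mil_train(build_bags(pair$train, 7, the_table))
  truth <- pair$test_truth[!is.na(pair$test_truth$offset), ]
  seqs <- stats::setNames(
    c(pair$test$positives$sequence, pair$test$negatives$sequence),
    c(pair$test$positives$probe_id, pair$test$negatives$probe_id))
  truth <- truth[truth$probe_id %in% names(seqs), ]
  bags <- lapply(seq_len(nrow(truth)), function(i) {
    build_bag(truth$probe_id[i], seqs[[truth$probe_id[i]]], "positive", 7,
              the_table)
  })
  scored <- instance_scores(model, bags)
  expect_identical(names(scored),
                   c("probe_id", "offset", "kmer", "probability"))
  expect_true(!is.unsorted(rev(scored$probability)))
  # argmax instance recovers the planted offset in most bags
  hits <- vapply(seq_along(bags), function(i) {
    p <- predict_bag(model, bags[[i]])$instance_probabilities
    # membership in the argmax set: site windows and their overlaps can tie
    # at exactly equal leaf probabilities
    p[truth$offset[i] + 1L] >= max(p) - 1e-12
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # scoring an empty list of bags is a no-op
  empty <- instance_scores(model, list())
  expect_identical(nrow(empty), 0L)
})

test_that("negative-only bags still produce a scored list", {
  pair <- make_labeled_pair(n_label = 40L, seed = 301L)
  model <- mil_train(build_bags(pair$train, 7, the_table))
  neg <- lapply(seq_len(5), function(i) {
    build_bag(pair$test$negatives$probe_id[i],
              pair$test$negatives$sequence[i], "negative", 7, the_table)
  })
  scored <- instance_scores(model, neg)
  expect_identical(nrow(scored), 5L * 29L)
  expect_true(all(scored$probability >= 0 & scored$probability <= 1))
})

test_that("models survive a save/load round trip", {
  bags <- make_bag_set(2)
  model <- mil_train(bags)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(predict_bags(back, bags), predict_bags(model, bags))
  expect_error(load_model(write_probe_file("p\tACG\t1")))
})
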