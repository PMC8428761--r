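# Cross-validation, fusion, metrics.

test_that("the study-size partition gives 9- or 10-subject stratified subsets", {
  labels <- rep(c("group1_osteo", "group2_healthy"), c(27, 40))
  folds <- stratified_partition(labels, k = 7, seed = 3)
  sizes <- tabulate(folds$membership, 7)
  expect_identical(sort(sizes), c(9L, 9L, 9L, 10L, 10L, 10L, 10L))
  for (fold in 1:7) {
    in_fold <- folds$membership == fold
    expect_lte(abs(sum(in_fold & labels == "group1_osteo") - 27 / 7), 1)
    expect_lte(abs(sum(in_fold & labels == "group2_healthy") - 40 / 7), 1)
  }
})

test_that("partition invariants hold across random draws", {
  set.seed(77)
  for (rep in 1:500) {
    n <- sample(6:80, 1)
    n1 <- sample(2:(n - 2), 1)
    k <- sample(2:min(10, n), 1)
    labels <- sample(rep(c("group1_osteo", "group2_healthy"), c(n1, n - n1)))
    folds <- stratified_partition(labels, k = k, seed = rep)
    # total function onto 1..k
    expect_length(folds$membership, n)
    expect_true(all(folds$membership %in% seq_len(k)))
    sizes <- tabulate(folds$membership, k)
    expect_lte(diff(range(sizes)), 1)
    for (cl in c("group1_osteo", "group2_healthy")) {
      nc <- sum(labels == cl)
      counts <- tabulate(folds$membership[labels == cl], k)
      expect_true(all(abs(counts - nc / k) <= 1))
    }
  }
  expect_error(stratified_partition(rep("group1_osteo", 5), k = 2), "both classes")
  expect_error(stratified_partition(c("group1_osteo", "group2_healthy"), k = 3),
               "k must lie")
})

test_that("fusion matches an exhaustively enumerated truth table", {
  g1 <- "group1_osteo"; g2 <- "group2_healthy"
  truth <- rbind(
    # left, right, scheme, expected — written out case by case
    c(g1, g1, "keep_left", g1),    c(g1, g1, "keep_right", g1),
    c(g1, g1, "keep_osteo", g1),   c(g1, g1, "keep_healthy", g1),
    c(g2, g2, "keep_left", g2),    c(g2, g2, "keep_right", g2),
    c(g2, g2, "keep_osteo", g2),   c(g2, g2, "keep_healthy", g2),
    c(g1, g2, "keep_left", g1),    c(g1, g2, "keep_right", g2),
    c(g1, g2, "keep_osteo", g1),   c(g1, g2, "keep_healthy", g2),
    c(g2, g1, "keep_left", g2),    c(g2, g1, "keep_right", g1),
    c(g2, g1, "keep_osteo", g1),   c(g2, g1, "keep_healthy", g2))
  expect_equal(nrow(truth), 16)
  for (i in seq_len(nrow(truth))) {
    expect_identical(
      fuse_arm_predictions(truth[i, 1], truth[i, 2], truth[i, 3]),
      truth[i, 4])
  }
  expect_error(fuse_arm_predictions(g1, g2, "separate"), "fusion")
})

test_that("metrics agree with brute-force recounts from raw label pairs", {
  set.seed(55)
  for (rep in 1:1000) {
    tp <- sample(0:40, 1); fn <- sample(0:40, 1)
    tn <- sample(0:40, 1); fp <- sample(0:40, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    truth <- rep(c("group1_osteo", "group2_healthy"),
                 c(tp + fn, tn + fp))
    pred <- c(rep("group1_osteo", tp), rep("group2_healthy", fn),
              rep("group2_healthy", tn), rep("group1_osteo", fp))
    cc <- confusion_counts(pred, truth)
    expect_identical(unlist(unclass(cc)), c(tp = tp, fp = fp, tn = tn, fn = fn))
    m <- compute_metrics(cc)
    # independent recount straight from the pairs
    expect_equal(m$sensitivity,
                 sum(pred == "group1_osteo" & truth == "group1_osteo") /
                   sum(truth == "group1_osteo"))
    expect_equal(m$specificity,
                 sum(pred == "group2_healthy" & truth == "group2_healthy") /
                   sum(truth == "group2_healthy"))
    expect_equal(m$accuracy, mean(pred == truth))
    expect_equal(m$youden_j, m$sensitivity + m$specificity - 1)
  }
})

test_that("degenerate tallies are flagged, not silently zeroed", {
  expect_warning(m <- compute_metrics(tp = 0, fp = 2, tn = 3, fn = 0),
                 "sensitivity undefined")
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$youden_j))
  perfect <- compute_metrics(tp = 5, fp = 0, tn = 7, fn = 0)
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1,
                                  accuracy = 1, youden_j = 1))
  chance <- compute_metrics(tp = 4, fp = 6, tn = 6, fn = 4)
  expect_equal(chance$youden_j, 0)
})

test_that("run_cv keeps subjects intact across folds and counts every arm", {
  co <- simulate_cohort(sim_params(seed = 19, effect_amplitude = 0.4))
  cv <- run_cv(co, feature_recipe("complex_reim", "separate", TRUE),
               k = 7, seed = 19, classifier = fast_classifier)
  expect_named(cv$schemes, c("separate", "keep_left", "keep_right",
                             "keep_osteo", "keep_healthy"))
  sep <- cv$schemes$separate$per_fold
  # 134 arm-level predictions in total, two per validation subject per fold
  expect_equal(sum(sep$tp + sep$fp + sep$tn + sep$fn), 134)
  sizes <- tabulate(cv$folds$membership, 7)
  expect_equal(sep$tp + sep$fp + sep$tn + sep$fn, 2 * sizes)
  # fused schemes tally one decision per validation subject
  ko <- cv$schemes$keep_osteo$per_fold
  expect_equal(ko$tp + ko$fp + ko$tn + ko$fn, sizes)
  # fold means are the arithmetic means of the fold metrics
  expect_equal(cv$schemes$separate$mean$sensitivity, mean(sep$sensitivity))
})

test_that("averaged arm mode yields a single scheme block per subject", {
  co <- simulate_cohort(fast_sim(seed = 23))
  cv <- run_cv(co, feature_recipe("complex_reim", "average", TRUE),
               k = 3, seed = 23, classifier = fast_classifier)
  expect_named(cv$schemes, "average")
  pf <- cv$schemes$average$per_fold
  expect_equal(sum(pf$tp + pf$fp + pf$tn + pf$fn), 14)
})

test_that("leave-one-subject-out is the accepted boundary of the partition", {
  co <- simulate_cohort(fast_sim(seed = 29))
  n <- length(co$subjects)
  cv <- suppressWarnings(
    run_cv(co, feature_recipe("complex_reim", "separate", TRUE),
           k = n, seed = 29, classifier = fast_classifier))
  expect_equal(cv$folds$k, n)
  sep <- cv$schemes$separate$per_fold
  expect_equal(sep$tp + sep$fp + sep$tn + sep$fn, rep(2L, n))
})
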