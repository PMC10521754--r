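test_that("stratified folds partition the cohort and balance classes", {
  labels <- rep(c(1L, 0L), c(9, 15))
  plan <- stratified_kfold(labels, 3, seed = 4)
  expect_identical(sort(plan$index), 1:24)
  per_fold <- table(plan$fold, plan$label)
  expect_true(all(per_fold[, "1"] == 3))
  expect_true(all(per_fold[, "0"] == 5))
  expect_identical(stratified_kfold(labels, 3, seed = 4), plan)
  expect_error(stratified_kfold(labels, 30), "exceeds")
  expect_warning(stratified_kfold(rep(c(1L, 0L), c(1, 8)), 3, seed = 1),
                 "strat")
})

test_that("sampling weights invert class frequencies", {
  w <- make_sampling_weights(c(1L, 0L, 0L, 0L))
  expect_equal(w / min(w), c(3, 1, 1, 1), tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_error(make_sampling_weights(c(1L, 1L)), "single class")
})

test_that("training reduces the loss on separable bags and is deterministic", {
  sim <- make_gauss_bags(8, n_inst = 8, d = 4, shift = 2, seed = 30)
  bm <- matrix(runif(16 * 4), 16, 4)
  cfg <- mmil_config(input_dim = 4, image_repr_dim = 6, biomarker_repr_dim = 4,
                     seed = 30)
  fit <- mmil_train(sim$bags, bm, sim$labels, cfg, epochs = 15, seed = 30)
  expect_lt(tail(fit$training_log$loss, 1), fit$training_log$loss[1])
  fit2 <- mmil_train(sim$bags, bm, sim$labels, cfg, epochs = 15, seed = 30)
  expect_identical(fit$params, fit2$params)
  expect_setequal(fit$trained_on, purrr::map_chr(sim$bags, "bag_id"))
})

test_that("the fitted pipeline predicts a probability simplex per bag", {
  sim <- make_gauss_bags(8, n_inst = 8, d = 6, shift = 2, seed = 31)
  ids <- purrr::map_chr(sim$bags, "bag_id")
  bm <- make_bm_table(ids, sim$labels, seed = 31)
  pipe <- fit_mmil(sim$bags, bm, sim$labels, epochs = 12, seed = 31)
  pr <- predict(pipe, sim$bags, bm)
  expect_s3_class(pr, "tbl_df")
  expect_identical(names(pr), c("bag_id", "p_pos", "p_neg"))
  expect_identical(pr$bag_id, ids)
  expect_equal(pr$p_pos + pr$p_neg, rep(1, 16), tolerance = 1e-12)
  expect_true(all(pr$p_pos > 0 & pr$p_pos < 1))
  expect_gt(roc_auc(pr$p_pos, sim$labels), 0.9)   # training-set separation
  # transforms recorded the training ids
  expect_silent(leakage_audit(pipe, c("Z1", "Z2")))
  expect_error(leakage_audit(pipe, ids[1]), "held-out")
})

test_that("cross-validation scores every bag exactly once, leakage-free", {
  sim <- make_gauss_bags(9, n_inst = 8, d = 6, shift = 2, seed = 32)
  ids <- purrr::map_chr(sim$bags, "bag_id")
  bm <- make_bm_table(ids, sim$labels, seed = 32)
  cv <- cross_validate(sim$bags, bm, sim$labels, k = 3, seed = 32, epochs = 10)
  expect_s3_class(cv, "mmil_cv")
  expect_setequal(cv$predictions$bag_id, ids)
  expect_identical(nrow(cv$predictions), 18L)
  expect_identical(sort(unique(cv$predictions$fold)), 1:3)
  rep <- eval_report(cv, B = 200, seed = 32)
  expect_gt(rep$pooled_auc, 0.8)
  expect_identical(rep$n, 18L)
})

test_that("AUC matches hand-counted concordant pairs", {
  expect_identical(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_identical(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_identical(roc_auc(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  expect_identical(roc_auc(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0)
  expect_identical(roc_auc(c(5, 5), c(0, 1)), 0.5)   # pure tie
  # property: midrank formula equals the pair-counting estimator under ties
  set.seed(33)
  for (rep in 1:25) {
    s <- sample(seq(0, 1, 0.1), 30, replace = TRUE)
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    pos <- s[y == 1]; neg <- s[y == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(s, y), mean(pairs), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("the Youden cutoff maximises J, breaking ties toward lower values", {
  set.seed(34)
  for (rep in 1:20) {
    s <- round(runif(25), 2)
    y <- rbinom(25, 1, 0.5)
    if (length(unique(y)) < 2) next
    yc <- youden_cutoff(s, y)
    brute <- vapply(c(-Inf, sort(unique(s)), Inf), function(ct) {
      sum(s >= ct & y == 1) / sum(y == 1) + sum(s < ct & y == 0) / sum(y == 0) - 1
    }, numeric(1))
    expect_equal(yc$youden, max(brute), tolerance = 1e-12)
    # the reported operating point reproduces its own sensitivity/specificity
    expect_equal(sum(s >= yc$cutoff & y == 1) / sum(y == 1), yc$sensitivity,
                 tolerance = 1e-12)
    expect_equal(sum(s < yc$cutoff & y == 0) / sum(y == 0), yc$specificity,
                 tolerance = 1e-12)
  }
  expect_true(youden_cutoff(c(1, 1, 1), c(0, 1, 1))$degenerate)
})

test_that("rank-sum test reproduces exact and approximate references", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value, 1 / 3,
               tolerance = 1e-12)
  # tie-free small samples agree with the exact reference implementation
  set.seed(35)
  for (rep in 1:10) {
    a <- rnorm(5); b <- rnorm(6)
    ours <- wilcoxon_rank_sum(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_identical(ours$method, "exact")
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$statistic - 5 * 6 / 2, ref$statistic[[1]],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # large samples with ties agree with the corrected normal approximation
  set.seed(36)
  a <- sample(1:6, 18, replace = TRUE)
  b <- sample(2:8, 20, replace = TRUE)
  ours <- wilcoxon_rank_sum(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_identical(ours$method, "normal")
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  # identical samples are maximally non-significant
  expect_identical(wilcoxon_rank_sum(rep(1, 3), rep(1, 3))$p_value, 1)
})

test_that("bootstrap CI is deterministic, ordered and class-preserving", {
  set.seed(37)
  s <- c(runif(30, 0.4, 1), runif(30, 0, 0.6))
  y <- rep(c(1, 0), each = 30)
  ci <- bootstrap_ci(roc_auc, s, y, B = 200, seed = 7)
  expect_identical(bootstrap_ci(roc_auc, s, y, B = 200, seed = 7), ci)
  expect_lte(ci$lower, ci$upper)
  expect_equal(ci$point, roc_auc(s, y), tolerance = 1e-12)
  expect_gte(ci$point, ci$lower)
  expect_lte(ci$point, ci$upper)
  expect_error(bootstrap_ci(roc_auc, s, y, B = 50), "100")
})

test_that("evaluation reports tidy, glance and plot cleanly", {
  set.seed(38)
  preds <- tibble::tibble(
    bag_id = sprintf("P%02d", 1:40),
    fold = rep(1:4, each = 10),
    label = rep(c(1L, 0L), 20),
    p_pos = plogis(rnorm(40, mean = rep(c(1, -1), 20)))
  )
  rep <- eval_report(preds, B = 200, seed = 3)
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("pooled_auc", "sensitivity", "specificity") %in% td$metric))
  gl <- glance(rep)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n, 40L)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
  expect_output(print(rep), "pooled AUC")
})
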