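test_that("complete tables pass through imputation unchanged", {
  tb <- make_bm_table(sprintf("P%02d", 1:6), rep(0:1, 3), seed = 2)
  expect_identical(impute_mice_pmm(tb), tb)
})

test_that("single-donor PMM matches a hand-run regression oracle", {
  # 5-row table, one missing CEA; with k_donors = 1 the imputed value must be
  # the observed CEA whose OLS-predicted mean is nearest the missing row's.
  tb <- tibble::tibble(
    CEA    = c(2.0, 3.5, NA, 6.0, 4.5),
    CA125  = c(10, 12, 11, 15, 13),
    CA19_9 = c(5, 9, 7, 14, 10),
    AFP    = c(2.0, 2.5, 2.2, 3.0, 2.6)
  )
  out <- impute_mice_pmm(tb, k_donors = 1, seed = 9)
  obs <- c(1, 2, 4, 5)
  fit <- lm(CEA ~ CA125 + CA19_9 + AFP, data = tb[obs, ])
  pred_obs <- predict(fit, tb[obs, ])
  pred_mis <- predict(fit, tb[3, ])
  donor <- obs[which.min(abs(pred_obs - pred_mis))]
  expect_identical(out$CEA[3], tb$CEA[donor])
  # predictors were complete, so every sweep refits the same regression
  expect_identical(impute_mice_pmm(tb, k_donors = 1, seed = 1)$CEA[3],
                   out$CEA[3])
})

test_that("imputation preserves observed cells and the PMM support property", {
  set.seed(4)
  tb <- make_bm_table(sprintf("P%02d", 1:30), rep(0:1, 15), seed = 4)
  holed <- tb
  for (m in c("CEA", "CA125", "CA19_9", "AFP")) {
    holed[[m]][sample.int(30, 6)] <- NA
  }
  out <- impute_mice_pmm(holed, seed = 5)
  expect_false(anyNA(out[, c("CEA", "CA125", "CA19_9", "AFP")]))
  for (m in c("CEA", "CA125", "CA19_9", "AFP")) {
    was_obs <- !is.na(holed[[m]])
    expect_identical(out[[m]][was_obs], holed[[m]][was_obs])
    expect_true(all(out[[m]][!was_obs] %in% holed[[m]][was_obs]))
  }
  # determinism
  expect_identical(impute_mice_pmm(holed, seed = 5), out)
})

test_that("degenerate imputation inputs error informatively", {
  tb <- tibble::tibble(CEA = c(NA_real_, NA_real_), CA125 = c(1, 2),
                       CA19_9 = c(3, 4), AFP = c(5, 6))
  expect_error(impute_mice_pmm(tb), "CEA")
  tb2 <- tibble::tibble(CEA = c("a", "1"), CA125 = c(1, 2),
                        CA19_9 = c(3, 4), AFP = c(5, 6))
  expect_error(impute_mice_pmm(tb2), "non-numeric")
})

test_that("held-out rows are imputed from training donors only", {
  tb <- make_bm_table(sprintf("P%02d", 1:20), rep(0:1, 10), seed = 8)
  imp <- fit_imputer(tb, seed = 8)
  new <- make_bm_table(sprintf("Q%02d", 1:5), rep(1, 5), seed = 9)
  new$CA19_9[c(1, 3)] <- NA
  out <- impute_newdata(imp, new)
  expect_false(anyNA(out$CA19_9))
  expect_true(all(out$CA19_9[c(1, 3)] %in% tb$CA19_9))
  expect_identical(out$CA19_9[2], new$CA19_9[2])
})

test_that("min-max normalisation maps, clips and degenerates as specified", {
  train <- tibble::tibble(CEA = c(2, 4, 10), CA125 = c(5, 5, 5),
                          CA19_9 = c(1, 2, 3), AFP = c(0, 1, 2))
  prm <- fit_minmax(train)
  out <- apply_minmax(train, prm)
  expect_equal(out$CEA, c(0, 0.25, 1))
  expect_identical(out$CA125, c(0, 0, 0))   # constant marker
  expect_true(all(as.matrix(out[, c("CEA", "CA19_9", "AFP")]) >= 0 &
                  as.matrix(out[, c("CEA", "CA19_9", "AFP")]) <= 1))
  big <- apply_minmax(tibble::tibble(CEA = 100, CA125 = 5, CA19_9 = 2, AFP = 1),
                      prm)
  expect_identical(big$CEA, 1)              # clipped
  expect_error(apply_minmax(train, list(a = 1)), "fit_minmax")
  # inverse of un-clipped values recovers inputs
  inv <- out$CEA * (10 - 2) + 2
  expect_equal(inv, train$CEA, tolerance = 1e-12)
})
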