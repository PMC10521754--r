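MARKERS <- c("CEA", "CA125", "CA19_9", "AFP")

#' Impute missing biomarkers by chained equations with predictive mean matching
#'
#' Single-imputation variant of multivariate imputation by chained equations
#' (MICE): markers are swept in the fixed order CEA, CA125, CA19-9, AFP.
#' For each marker with missing cells, an ordinary least squares regression
#' of the marker on the other three is fitted on the rows where the marker is
#' observed (using current working values for the predictors); each missing
#' cell is then filled by predictive mean matching — the `k_donors` observed
#' rows with the nearest predicted mean are found and one donor's observed
#' value is copied uniformly at random.  Imputed values therefore always lie
#' in the observed support of that marker, observed cells are never altered,
#' and the result is deterministic given `seed`.
#'
#' @param data Tibble containing the marker columns (extra columns such as
#'   `patient_id` and `label` pass through untouched; the outcome never
#'   enters the imputation model).
#' @param markers Character vector of marker columns (default the four serum
#'   markers).
#' @param n_iterations Number of full sweeps, default 10.
#' @param k_donors Donor pool size for predictive mean matching, default 5.
#' @param seed Integer seed for donor draws and the random initial fill.
#' @return The completed tibble, same shape and row order.
#' @export
#' @examples
#' tb <- tibble::tibble(CEA = c(1, 2, NA, 4, 3), CA125 = c(9, 11, 10, 12, 8),
#'                      CA19_9 = c(5, 7, 6, 9, 8), AFP = c(2, 3, 2.5, 2, 4))
#' impute_mice_pmm(tb, seed = 1)
impute_mice_pmm <- function(data, markers = MARKERS, n_iterations = 10,
                            k_donors = 5, seed = 1) {
  assert_that(all(markers %in% names(data)),
              paste("data must contain columns:", paste(markers, collapse = ", ")))
  assert_that(is_count(n_iterations), "`n_iterations` must be a positive count")
  assert_that(is_count(k_donors), "`k_donors` must be a positive count")
  x <- as.data.frame(data[, markers])
  for (m in markers) {
    if (!is.numeric(x[[m]])) {
      bad <- which(!is.na(x[[m]]) & is.na(suppressWarnings(as.numeric(x[[m]]))))
      abort(sprintf("non-numeric values in marker %s (e.g. row %d)",
                    m, if (length(bad)) bad[1] else 1L))
    }
    if (all(is.na(x[[m]]))) {
      abort(sprintf("marker %s has zero observed values; cannot impute", m))
    }
  }
  miss <- is.na(x)
  if (!any(miss)) return(data)

  with_seed(seed, {
    # initial fill: random draws from each marker's observed values
    for (m in markers) {
      obs <- x[[m]][!miss[, m]]
      nmiss <- sum(miss[, m])
      if (nmiss > 0) {
        x[[m]][miss[, m]] <- sample(obs, nmiss, replace = TRUE)
      }
    }
    for (it in seq_len(n_iterations)) {
      for (m in markers) {
        idx_miss <- which(miss[, m])
        if (!length(idx_miss)) next
        others <- setdiff(markers, m)
        obs_rows <- which(!miss[, m])
        fit_df <- x[obs_rows, , drop = FALSE]
        fml <- stats::as.formula(paste(m, "~", paste(others, collapse = "+")))
        fit <- lm(fml, data = fit_df)
        pred_obs <- predict(fit, newdata = fit_df)
        pred_mis <- predict(fit, newdata = x[idx_miss, , drop = FALSE])
        donors_obs <- x[[m]][obs_rows]
        k <- min(k_donors, length(obs_rows))
        for (j in seq_along(idx_miss)) {
          d <- abs(pred_obs - pred_mis[j])
          donor_pool <- order(d)[seq_len(k)]
          pick <- if (k == 1) donor_pool else donor_pool[sample.int(k, 1)]
          x[[m]][idx_miss[j]] <- donors_obs[pick]
        }
      }
    }
  })
  out <- data
  out[, markers] <- tibble::as_tibble(x)
  out
}

#' Fit a reusable imputer on a training table
#'
#' Runs [impute_mice_pmm()] on the training rows and retains what is needed
#' to impute held-out rows without touching them during fitting: the
#' completed training table, the original missingness mask (so donor pools
#' stay restricted to genuinely observed values), and the settings.
#'
#' @inheritParams impute_mice_pmm
#' @return An `mmil_imputer`: list with `completed`, `observed_mask`,
#'   `markers`, `k_donors`, `n_iterations`, `seed`, `fitted_on`.
#' @export
fit_imputer <- function(data, markers = MARKERS, n_iterations = 10,
                        k_donors = 5, seed = 1) {
  completed <- impute_mice_pmm(data, markers, n_iterations, k_donors, seed)
  structure(list(
    completed = completed,
    observed_mask = !is.na(as.matrix(data[, markers])),
    markers = markers,
    k_donors = k_donors,
    n_iterations = n_iterations,
    seed = seed,
    fitted_on = if ("patient_id" %in% names(data)) data$patient_id else NULL
  ), class = "mmil_imputer")
}

#' Impute held-out rows with a fitted imputer
#'
#' Chained-equation PMM sweeps for new rows using only training
#' information: regressions are fitted on the completed training table,
#' donor pools are the training values originally observed for each marker,
#' and missing predictors are initialised at training medians.  Training
#' rows are never modified by new data.
#'
#' @param imputer An `mmil_imputer` from [fit_imputer()].
#' @param newdata Tibble with the marker columns (missing values allowed).
#' @param seed Seed for donor draws, default the imputer's.
#' @return `newdata` completed.
#' @export
impute_newdata <- function(imputer, newdata, seed = imputer$seed) {
  assert_that(inherits(imputer, "mmil_imputer"),
              "`imputer` must come from fit_imputer()")
  markers <- imputer$markers
  assert_that(all(markers %in% names(newdata)),
              "newdata must contain all marker columns")
  x <- as.data.frame(newdata[, markers])
  miss <- is.na(x)
  if (!any(miss)) return(newdata)
  train <- as.data.frame(imputer$completed[, markers])
  with_seed(seed, {
    for (m in markers) {
      x[[m]][miss[, m]] <- median(train[[m]])
    }
    for (it in seq_len(imputer$n_iterations)) {
      for (m in markers) {
        idx_miss <- which(miss[, m])
        if (!length(idx_miss)) next
        others <- setdiff(markers, m)
        fml <- stats::as.formula(paste(m, "~", paste(others, collapse = "+")))
        fit <- lm(fml, data = train)
        donor_rows <- which(imputer$observed_mask[, m])
        pred_donor <- predict(fit, newdata = train[donor_rows, , drop = FALSE])
        pred_new <- predict(fit, newdata = x[idx_miss, , drop = FALSE])
        donors <- train[[m]][donor_rows]
        k <- min(imputer$k_donors, length(donor_rows))
        for (j in seq_along(idx_miss)) {
          pool <- order(abs(pred_donor - pred_new[j]))[seq_len(k)]
          pick <- if (k == 1) pool else pool[sample.int(k, 1)]
          x[[m]][idx_miss[j]] <- donors[pick]
        }
      }
    }
  })
  out <- newdata
  out[, markers] <- tibble::as_tibble(x)
  out
}

#' Fit min-max normalisation parameters on a training table
#'
#' Records per-marker training minimum and maximum.  Fit only on training
#' rows: applying parameters fitted elsewhere to held-out data is the
#' leakage guard the evaluation protocol relies on.
#'
#' @param data Training tibble (post-imputation).
#' @param markers Marker columns.
#' @return A `minmax_params` tibble with columns `marker`, `min`, `max`.
#' @export
fit_minmax <- function(data, markers = MARKERS) {
  assert_that(all(markers %in% names(data)),
              "data must contain all marker columns")
  assert_that(!anyNA(data[, markers]),
              "impute before fitting normalisation")
  params <- tibble::tibble(
    marker = markers,
    min = purrr::map_dbl(markers, ~ min(data[[.x]])),
    max = purrr::map_dbl(markers, ~ max(data[[.x]]))
  )
  class(params) <- c("minmax_params", class(params))
  params
}

#' Apply min-max normalisation
#'
#' Maps `x` to `(x - min) / (max - min)`; values outside the training range
#' (as occur when a model trained on one centre is applied to another) are
#' clipped to `[0, 1]`; a marker constant in training maps to 0.
#'
#' @param data Tibble with marker columns.
#' @param params A `minmax_params` from [fit_minmax()].
#' @return Tibble with markers normalised, other columns untouched.
#' @export
apply_minmax <- function(data, params) {
  assert_that(inherits(params, "minmax_params"),
              "`params` must come from fit_minmax()")
  out <- data
  for (i in seq_len(nrow(params))) {
    m <- params$marker[i]
    rng <- params$max[i] - params$min[i]
    v <- if (rng == 0) rep(0, nrow(data)) else (data[[m]] - params$min[i]) / rng
    out[[m]] <- pmin(pmax(v, 0), 1)
  }
  out
}
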