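#' Area under the ROC curve
#'
#' Tie-corrected Mann-Whitney pair-counting statistic: the probability that
#' a random positive scores above a random negative, counting ties as 1/2.
#'
#' @param scores Numeric predictions (higher = more positive).
#' @param labels Integer 0/1 vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))  # 0.75
roc_auc <- function(scores, labels) {
  assert_that(length(scores) == length(labels), "scores/labels length mismatch")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  r <- rank(scores)  # midranks under ties
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' Sensitivity/specificity at every distinct threshold, for plotting and
#' threshold search.  Prediction rule: `score >= cutoff` is called positive.
#'
#' @inheritParams roc_auc
#' @return Tibble with `cutoff`, `sensitivity`, `specificity` ordered by
#'   decreasing cutoff; cutoffs are midpoints between adjacent distinct
#'   scores, flanked by `+/-Inf`.
#' @export
roc_points <- function(scores, labels) {
  u <- sort(unique(scores))
  cutoffs <- c(Inf, rev((u[-1] + u[-length(u)]) / 2), -Inf)
  if (length(u) == 1) cutoffs <- c(Inf, -Inf)
  purrr::map_dfr(cutoffs, function(ct) {
    pred <- scores >= ct
    tibble::tibble(
      cutoff = ct,
      sensitivity = sum(pred & labels == 1) / sum(labels == 1),
      specificity = sum(!pred & labels == 0) / sum(labels == 0)
    )
  })
}

#' Youden-optimal ROC cutoff
#'
#' Maximises the Youden index `J = sensitivity + specificity - 1` over all
#' candidate thresholds (midpoints between adjacent distinct scores plus the
#' two extremes).  Ties are broken toward the lower cutoff, i.e. higher
#' sensitivity.  With all scores equal, `J = 0` and the degenerate cutoff is
#' flagged.
#'
#' @inheritParams roc_auc
#' @return List with `cutoff`, `sensitivity`, `specificity`, `youden` and
#'   `degenerate` flag.
#' @export
youden_cutoff <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  pts <- roc_points(scores, labels)
  j <- pts$sensitivity + pts$specificity - 1
  best <- max(j)
  # finite candidates preferred; among ties take the lowest cutoff
  cand <- which(j >= best - 1e-12)
  cand <- cand[order(pts$cutoff[cand])]
  pick <- cand[is.finite(pts$cutoff[cand])][1]
  if (is.na(pick)) pick <- cand[1]
  list(cutoff = pts$cutoff[pick],
       sensitivity = pts$sensitivity[pick],
       specificity = pts$specificity[pick],
       youden = j[pick],
       degenerate = length(unique(scores)) == 1)
}

#' Stratified bootstrap percentile confidence interval
#'
#' Resamples within each class (so every resample retains both classes),
#' recomputes `metric` B times, and returns the percentile interval.
#' Deterministic given `seed`.
#'
#' @param metric Function `(scores, labels) -> scalar`, e.g. [roc_auc()].
#' @param scores,labels Data to resample.
#' @param B Bootstrap replicates, `>= 100`; default 1000.
#' @param level Confidence level, default 0.95.
#' @param seed Seed.
#' @return List with `lower`, `upper`, `point`, `level`, `B`.
#' @export
bootstrap_ci <- function(metric, scores, labels, B = 1000, level = 0.95,
                         seed = 1) {
  assert_that(is_count(B) && B >= 100, "`B` must be a count >= 100")
  assert_that(level > 0 && level < 1, "`level` must lie in (0, 1)")
  idx_pos <- which(labels == 1)
  idx_neg <- which(labels == 0)
  stats <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      ip <- sample(idx_pos, length(idx_pos), replace = TRUE)
      ineg <- sample(idx_neg, length(idx_neg), replace = TRUE)
      i <- c(ip, ineg)
      metric(scores[i], labels[i])
    }, numeric(1))
  })
  q <- quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2),
                names = FALSE, type = 7)
  list(lower = q[1], upper = q[2],
       point = metric(scores, labels), level = level, B = B)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test comparing two independent samples by midranks.  For
#' combined `n <= 20` the null distribution is enumerated exactly over all
#' `choose(n, n_a)` group assignments (valid under ties, since midranks are
#' permuted); larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b Numeric samples, both non-empty.
#' @return List with `statistic` (rank sum of `a`), `p_value`, `method`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value  # 1/3
wilcoxon_rank_sum <- function(a, b) {
  assert_that(length(a) > 0 && length(b) > 0, "both samples must be non-empty")
  n_a <- length(a)
  n <- n_a + length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n_a)])
  if (n <= 20) {
    combos <- utils::combn(n, n_a)
    null_w <- colSums(matrix(r[combos], nrow = n_a))
    eps <- 1e-9
    p <- 2 * min(mean(null_w <= W + eps), mean(null_w >= W - eps))
    list(statistic = W, p_value = min(1, p), method = "exact")
  } else {
    mu <- n_a * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n_a * length(b) / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      return(list(statistic = W, p_value = 1, method = "normal"))
    }
    zval <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    list(statistic = W, p_value = min(1, 2 * pnorm(-abs(zval))),
         method = "normal")
  }
}

#' Evaluation report for cross-validated (or held-out) predictions
#'
#' Computes per-fold and pooled AUC, the bootstrap CI of the pooled AUC, the
#' Youden-optimal cutoff and the sensitivity/specificity/accuracy it
#' implies.  Both the pooled-predictions AUC and the mean of per-fold AUCs
#' are reported, as the two conventions can differ.
#'
#' @param predictions Tibble with `label`, `p_pos` and optionally `fold`
#'   (e.g. from [cross_validate()]'s `$predictions`), or an `mmil_cv`.
#' @param B,level,seed Bootstrap settings, see [bootstrap_ci()].
#' @return An `eval_report` list: `pooled_auc`, `mean_fold_auc`, `fold_aucs`
#'   (tibble), `ci`, `cutoff`, `sensitivity`, `specificity`, `accuracy`,
#'   `youden`, `n`, and the per-fold score vectors.
#' @export
eval_report <- function(predictions, B = 1000, level = 0.95, seed = 1) {
  if (inherits(predictions, "mmil_cv")) predictions <- predictions$predictions
  assert_that(all(c("label", "p_pos") %in% names(predictions)),
              "predictions need `label` and `p_pos` columns")
  scores <- predictions$p_pos
  labels <- predictions$label
  pooled <- roc_auc(scores, labels)
  fold_aucs <- if ("fold" %in% names(predictions)) {
    predictions |>
      dplyr::group_by(.data$fold) |>
      dplyr::summarise(auc = tryCatch(roc_auc(.data$p_pos, .data$label),
                                      error = function(e) NA_real_),
                       n = dplyr::n(), .groups = "drop")
  } else {
    tibble::tibble(fold = 1L, auc = pooled, n = length(labels))
  }
  ci <- bootstrap_ci(roc_auc, scores, labels, B = B, level = level, seed = seed)
  yc <- youden_cutoff(scores, labels)
  pred_pos <- scores >= yc$cutoff
  acc <- mean(pred_pos == (labels == 1))
  structure(list(
    pooled_auc = pooled,
    mean_fold_auc = mean(fold_aucs$auc, na.rm = TRUE),
    fold_aucs = fold_aucs,
    ci = ci,
    cutoff = yc$cutoff,
    sensitivity = yc$sensitivity,
    specificity = yc$specificity,
    accuracy = acc,
    youden = yc$youden,
    n = length(labels),
    predictions = predictions
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    paste0("<eval_report> n = %d\n",
           "  pooled AUC %.3f (%d%% CI %.3f-%.3f), mean fold AUC %.3f\n",
           "  Youden cutoff %.3f: sens %.3f, spec %.3f, acc %.3f\n"),
    x$n, x$pooled_auc, round(100 * x$ci$level), x$ci$lower, x$ci$upper,
    x$mean_fold_auc, x$cutoff, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(
    metric = c("pooled_auc", "mean_fold_auc", "auc_ci_lower", "auc_ci_upper",
               "cutoff", "sensitivity", "specificity", "accuracy", "youden"),
    value = c(x$pooled_auc, x$mean_fold_auc, x$ci$lower, x$ci$upper,
              x$cutoff, x$sensitivity, x$specificity, x$accuracy, x$youden)
  )
}

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(n = x$n, pooled_auc = x$pooled_auc,
                 auc_ci_lower = x$ci$lower, auc_ci_upper = x$ci$upper,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 accuracy = x$accuracy)
}

#' @method tidy mmil_model
#' @export
tidy.mmil_model <- function(x, ...) {
  purrr::imap_dfr(x$params, function(v, nm) {
    tibble::tibble(parameter = nm, n_values = length(v),
                   mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_)
  })
}

#' @method glance mmil_model
#' @export
glance.mmil_model <- function(x, ...) {
  tibble::tibble(
    mode = x$config$mode,
    input_dim = x$config$input_dim,
    fused_dim = x$config$fused_dim,
    n_parameters = sum(purrr::map_int(x$params, length)),
    final_loss = if (!is.null(x$training_log)) {
      tail(x$training_log$loss, 1)
    } else {
      NA_real_
    }
  )
}

#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  pts <- roc_points(object$predictions$p_pos, object$predictions$label)
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC (AUC %.3f, %d%% CI %.3f-%.3f)",
                      object$pooled_auc, round(100 * object$ci$level),
                      object$ci$lower, object$ci$upper)) +
    ggplot2::theme_minimal()
}
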