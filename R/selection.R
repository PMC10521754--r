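#' Squared maximum mean discrepancy (biased V-statistic)
#'
#' Gaussian-kernel two-sample statistic
#' `MMD^2 = mean K(x,x') + mean K(y,y') - 2 mean K(x,y)` with
#' `K(a,b) = exp(-(a-b)^2 / (2 bw^2))`.  The biased (V-statistic) form is
#' used: it is non-negative and exactly zero for identical samples.
#' Optional weights turn each sample into a weighted empirical distribution
#' (weights are normalised to sum to one), which is how histogram-compressed
#' samples are scored in [select_feature_dims()].
#'
#' @param x,y Numeric vectors (non-empty).
#' @param bandwidth Kernel bandwidth; default is the median heuristic —
#'   the median of the nonzero pairwise absolute differences of the pooled
#'   sample (1 if all differences are zero).
#' @param wx,wy Optional non-negative weights, one per point.
#' @return Scalar statistic, `>= 0` up to float rounding.
#' @export
#' @examples
#' mmd_squared(0, 1, bandwidth = 1)  # 2 - 2*exp(-0.5)
mmd_squared <- function(x, y, bandwidth = NULL, wx = NULL, wy = NULL) {
  assert_that(length(x) > 0 && length(y) > 0, "both samples must be non-empty")
  if (is.null(bandwidth)) bandwidth <- median_bandwidth(c(x, y))
  assert_that(is.numeric(bandwidth) && bandwidth > 0,
              "`bandwidth` must be positive")
  wx <- if (is.null(wx)) rep(1 / length(x), length(x)) else wx / sum(wx)
  wy <- if (is.null(wy)) rep(1 / length(y), length(y)) else wy / sum(wy)
  k <- function(a, b) exp(-outer(a, b, "-")^2 / (2 * bandwidth^2))
  drop(wx %*% k(x, x) %*% wx + wy %*% k(y, y) %*% wy - 2 * wx %*% k(x, y) %*% wy)
}

median_bandwidth <- function(pooled) {
  d <- abs(as.vector(dist(pooled)))
  d <- d[d > 0]
  if (!length(d)) return(1)
  median(d)
}

#' Select discriminative feature dimensions by histogram-compressed MMD
#'
#' Weakly supervised selection: instance labels are unknown, only bag labels
#' are, so per feature dimension the instance values of all positive bags
#' are pooled against those of all negative bags.  Each pool is compressed
#' to an `n_hist_bins`-bin normalised histogram over the pooled range, and
#' the dimension is scored by the Gaussian-kernel MMD between the two
#' histograms (bin centers weighted by bin mass, shared median-heuristic
#' bandwidth).  The `n_keep` highest-scoring dimensions are kept.  The
#' procedure is deterministic and invariant to bag order and to instance
#' order within bags.
#'
#' @param pos_bags,neg_bags Lists of `feature_bag`s (or plain matrices) for
#'   the positive and negative class; at least one bag each.
#' @param n_keep Number of dimensions to keep, in `[1, feature_dim]`;
#'   default half of `feature_dim`.
#' @param n_hist_bins Histogram resolution, default 50.
#' @return A `selection_result`: list with `scores` (per-dimension),
#'   `kept_dims` (sorted 1-based indices of the top `n_keep`), `n_keep`,
#'   `n_hist_bins` and `bandwidths`.
#' @export
select_feature_dims <- function(pos_bags, neg_bags, n_keep = NULL,
                                n_hist_bins = 50) {
  as_mat <- function(b) if (inherits(b, "feature_bag")) b$features else as.matrix(b)
  assert_that(length(pos_bags) >= 1 && length(neg_bags) >= 1,
              "need at least one bag per class")
  pos <- do.call(rbind, lapply(pos_bags, as_mat))
  neg <- do.call(rbind, lapply(neg_bags, as_mat))
  assert_that(ncol(pos) == ncol(neg), "feature dimensions differ across classes")
  d <- ncol(pos)
  if (is.null(n_keep)) n_keep <- max(1L, d %/% 2L)
  if (n_keep < 1 || n_keep > d) {
    abort(sprintf("`n_keep` must lie in [1, %d]", d))
  }
  assert_that(is_count(n_hist_bins), "`n_hist_bins` must be a positive count")

  scores <- numeric(d)
  bandwidths <- rep(NA_real_, d)
  for (j in seq_len(d)) {
    pooled <- c(pos[, j], neg[, j])
    rng <- range(pooled)
    if (rng[1] == rng[2]) {
      scores[j] <- 0
      next
    }
    brks <- seq(rng[1], rng[2], length.out = n_hist_bins + 1)
    centers <- (brks[-1] + brks[-length(brks)]) / 2
    hp <- bin_masses(pos[, j], brks)
    hn <- bin_masses(neg[, j], brks)
    bw <- median_bandwidth(centers)
    bandwidths[j] <- bw
    keep <- hp > 0 | hn > 0
    scores[j] <- mmd_squared(centers[keep], centers[keep], bandwidth = bw,
                             wx = hp[keep], wy = hn[keep])
  }
  kept <- sort(order(scores, decreasing = TRUE)[seq_len(n_keep)])
  structure(list(scores = scores, kept_dims = kept, n_keep = as.integer(n_keep),
                 n_hist_bins = as.integer(n_hist_bins), bandwidths = bandwidths,
                 feature_dim = d),
            class = "selection_result")
}

bin_masses <- function(v, brks) {
  idx <- findInterval(v, brks, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, nbins = length(brks) - 1) / length(v)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> kept %d of %d dims; top score %.4g\n",
              x$n_keep, x$feature_dim, max(x$scores)))
  invisible(x)
}

#' Apply a feature-dimension selection to a bag
#'
#' @param bag A `feature_bag` (or matrix).
#' @param result A `selection_result` fitted on training bags.
#' @return The bag with columns subset to `result$kept_dims`; labels and
#'   coordinates untouched.
#' @export
apply_selection <- function(bag, result) {
  assert_that(inherits(result, "selection_result"),
              "`result` must come from select_feature_dims()")
  m <- if (inherits(bag, "feature_bag")) bag$features else as.matrix(bag)
  if (ncol(m) != result$feature_dim) {
    abort(sprintf("bag has %d dims but selection was fitted on %d",
                  ncol(m), result$feature_dim))
  }
  sub <- m[, result$kept_dims, drop = FALSE]
  if (inherits(bag, "feature_bag")) {
    out <- bag
    out$features <- sub
    out
  } else {
    sub
  }
}
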