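#' Score every tile of a bag with the trained model
#'
#' Tile-level LNM probabilities: each tile is run through the image channel
#' as a singleton bag with the patient's (normalised) biomarker vector held
#' fixed, and the positive-class probability recorded at the tile's grid
#' position.  Deterministic.  The alternative `"attention"` channel fills
#' the same map structure with the bag's attention weights instead.
#'
#' @param pipeline A fitted `mmil_pipeline`.
#' @param tile_bag The patient's `tile_bag` (raw tiles) — features are
#'   extracted with `spec` and must match the fingerprint the model was
#'   trained with.
#' @param biomarkers Tibble with `patient_id` + markers containing this
#'   patient, or `NULL` for the neutral-vector mode (pure-image map, all
#'   markers at 0.5).
#' @param spec The [backbone_spec()] used at training time.
#' @param channel `"probability"` (default) or `"attention"`.
#' @return A `tile_score_map`: list with `bag_id`, `entries` tibble
#'   (`grid_row`, `grid_col`, `probability`), `grid_shape`, `channel`.
#' @export
score_tiles <- function(pipeline, tile_bag, biomarkers = NULL,
                        spec = backbone_spec(),
                        channel = c("probability", "attention")) {
  channel <- match.arg(channel)
  assert_that(inherits(pipeline, "mmil_pipeline"),
              "`pipeline` must come from fit_mmil()")
  fb <- extract_features(tile_bag, spec)
  if (!is.na(pipeline$model$backbone_fingerprint) &&
      !identical(fb$backbone, pipeline$model$backbone_fingerprint)) {
    abort("backbone fingerprint mismatch between checkpoint and bag")
  }
  sel <- apply_selection(fb, pipeline$selection)
  bvec <- if (is.null(biomarkers)) {
    rep(0.5, 4)
  } else {
    bm <- dplyr::left_join(tibble::tibble(patient_id = tile_bag$bag_id),
                           biomarkers, by = "patient_id")
    bm <- impute_newdata(pipeline$imputer, bm)
    bm <- apply_minmax(bm, pipeline$minmax)
    as.numeric(bm[1, MARKERS])
  }
  if (channel == "attention") {
    pred <- mmil_predict_bag(pipeline$model, sel,
                             if (pipeline$mode == "image") NULL else bvec)
    prob <- pred$attention_weights
  } else {
    prob <- vapply(seq_len(nrow(sel$features)), function(i) {
      single <- sel$features[i, , drop = FALSE]
      p <- mmil_predict_bag(pipeline$model, single,
                            if (pipeline$mode == "image") NULL else bvec)
      p$class_probabilities[2]
    }, numeric(1))
  }
  entries <- tibble::tibble(
    grid_row = tile_bag$coords$grid_row,
    grid_col = tile_bag$coords$grid_col,
    probability = prob
  )
  structure(list(bag_id = tile_bag$bag_id, entries = entries,
                 grid_shape = c(max(entries$grid_row) + 1L,
                                max(entries$grid_col) + 1L),
                 channel = channel),
            class = "tile_score_map")
}

#' @export
print.tile_score_map <- function(x, ...) {
  cat(sprintf("<tile_score_map> %s: %d tiles on a %d x %d grid (%s)\n",
              x$bag_id, nrow(x$entries), x$grid_shape[1], x$grid_shape[2],
              x$channel))
  invisible(x)
}

#' Histogram of tile scores
#'
#' @param map A `tile_score_map`.
#' @param n_bins Number of uniform bins over `[0, 1]`, default 20.
#' @return Tibble with `bin_lower`, `bin_upper`, `count`; counts sum to the
#'   number of tiles.
#' @export
score_histogram <- function(map, n_bins = 20) {
  assert_that(is_count(n_bins), "`n_bins` must be a positive count")
  assert_that(nrow(map$entries) > 0, "empty score map")
  brks <- seq(0, 1, length.out = n_bins + 1)
  idx <- findInterval(map$entries$probability, brks,
                      rightmost.closed = TRUE, all.inside = TRUE)
  tibble::tibble(bin_lower = brks[-length(brks)], bin_upper = brks[-1],
                 count = tabulate(idx, nbins = n_bins))
}

# Monotone cold-to-hot colormap: probability 0 -> deep blue, 1 -> red.
# Each channel is monotone (R increasing, B decreasing) so rendered pixel
# values order exactly as probabilities do.
heat_rgb <- function(p) {
  cbind(r = 0.10 + 0.88 * p, g = rep(0.15, length(p)), b = 0.95 - 0.85 * p)
}

#' Render a tile score map as a heatmap PNG
#'
#' One coloured cell per retained tile at its grid position; grid cells with
#' no retained tile are fully transparent; a vertical legend strip (0 at the
#' bottom, 1 at the top) is embedded on the right.  Rendering is
#' deterministic, so re-rendering the same map gives a byte-identical file.
#'
#' @param map A `tile_score_map`.
#' @param out_path Output PNG path.
#' @param cell_px Pixels per grid cell, default 16.
#' @return Invisibly, `out_path`.
#' @export
render_heatmap <- function(map, out_path, cell_px = 16) {
  assert_that(nrow(map$entries) > 0, "empty score map")
  nr <- map$grid_shape[1]
  nc <- map$grid_shape[2]
  img <- array(0, c(nr * cell_px, (nc + 2) * cell_px, 4))
  cols <- heat_rgb(map$entries$probability)
  for (i in seq_len(nrow(map$entries))) {
    rr <- map$entries$grid_row[i] * cell_px + seq_len(cell_px)
    cc <- map$entries$grid_col[i] * cell_px + seq_len(cell_px)
    img[rr, cc, 1] <- cols[i, 1]
    img[rr, cc, 2] <- cols[i, 2]
    img[rr, cc, 3] <- cols[i, 3]
    img[rr, cc, 4] <- 1
  }
  # legend: rightmost column of cells, gradient top (1) to bottom (0)
  leg_rows <- nr * cell_px
  leg_p <- seq(1, 0, length.out = leg_rows)
  leg_cols <- heat_rgb(leg_p)
  cc <- (nc + 1) * cell_px + seq_len(cell_px)
  for (ch in 1:3) img[, cc, ch] <- matrix(leg_cols[, ch], leg_rows, cell_px)
  img[, cc, 4] <- 1
  ok <- tryCatch({
    png::writePNG(img, out_path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(sprintf("cannot write heatmap to %s", out_path))
  invisible(out_path)
}

#' @method autoplot tile_score_map
#' @export
autoplot.tile_score_map <- function(object, ...) {
  ggplot2::ggplot(object$entries,
                  ggplot2::aes(x = .data$grid_col, y = -.data$grid_row,
                               fill = .data$probability)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient(low = "#1a26f2", high = "#fa1905",
                                 limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("Tile LNM probability:", object$bag_id),
                  x = NULL, y = NULL, fill = "P(LNM+)") +
    ggplot2::theme_minimal()
}

# Otsu threshold on a [0,1] grayscale matrix (256-bin histogram maximising
# between-class variance).
otsu_threshold <- function(x, n_bins = 256) {
  h <- tabulate(pmin(n_bins, floor(x * n_bins) + 1L), nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sb <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, NA)
  k <- which.max(sb)
  if (!length(k) || all(is.na(sb))) return(NA_real_)
  # upper edge of bin k, so pixels falling in bin k stay below the cut
  # (class 0 = bins <= k)
  k / n_bins
}

# 4-connected component labelling; uses EBImage when available, otherwise a
# two-pass union-find in plain R.
label_components <- function(bw) {
  if (requireNamespace("EBImage", quietly = TRUE)) {
    return(matrix(as.integer(EBImage::bwlabel(bw)), nrow(bw), ncol(bw)))
  }
  lab <- matrix(0L, nrow(bw), ncol(bw))
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nxt <- 0L
  for (cc in seq_len(ncol(bw))) {
    for (rr in seq_len(nrow(bw))) {
      if (!bw[rr, cc]) next
      up <- if (rr > 1) lab[rr - 1, cc] else 0L
      left <- if (cc > 1) lab[rr, cc - 1] else 0L
      if (up == 0L && left == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[rr, cc] <- nxt
      } else if (up != 0L && left != 0L) {
        ru <- find(up); rl <- find(left)
        parent[max(ru, rl)] <- min(ru, rl)
        lab[rr, cc] <- min(ru, rl)
      } else {
        lab[rr, cc] <- max(up, left)
      }
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    remap <- match(roots, sort(unique(roots)))
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

# Area of the convex image (pixels of the bounding box inside the convex
# hull of the component's pixel centers), for solidity.
convex_area <- function(rows, cols) {
  pts <- unique(cbind(cols, rows))
  if (nrow(pts) <= 2) return(nrow(pts))
  hull <- grDevices::chull(pts)
  if (length(hull) <= 2) {
    # collinear: count pixels on the segment's bounding box diagonal
    return(nrow(pts))
  }
  hx <- pts[hull, 1]
  hy <- pts[hull, 2]
  grid <- expand.grid(x = min(cols):max(cols), y = min(rows):max(rows))
  inside <- rep(TRUE, nrow(grid))
  eps <- 1e-9
  nh <- length(hull)
  sgn <- 0
  for (e in seq_len(nh)) {
    x1 <- hx[e]; y1 <- hy[e]
    x2 <- hx[e %% nh + 1]; y2 <- hy[e %% nh + 1]
    cr <- (x2 - x1) * (grid$y - y1) - (y2 - y1) * (grid$x - x1)
    if (sgn == 0 && any(abs(cr) > eps)) sgn <- sign(cr[which.max(abs(cr))])
    inside <- inside & (sgn * cr >= -eps)
  }
  sum(inside)
}

# Haralick sum-average from the gray-level co-occurrence matrix: gray
# levels quantised to 1..n_gray, distance-1 offsets in 4 directions,
# symmetric and normalised, matrices averaged over directions.
haralick_sum_average <- function(gray, n_gray = 8) {
  q <- floor(gray * n_gray) + 1L
  q[q > n_gray] <- n_gray
  nr <- nrow(q); nc <- ncol(q)
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  P <- matrix(0, n_gray, n_gray)
  n_dir <- 0
  for (o in offs) {
    r1 <- max(1, 1 - o[1]):min(nr, nr - o[1])
    c1 <- max(1, 1 - o[2]):min(nc, nc - o[2])
    if (!length(r1) || !length(c1)) next
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + o[1], c1 + o[2], drop = FALSE]
    tab <- matrix(tabulate((a - 1L) * n_gray + b, nbins = n_gray^2),
                  n_gray, n_gray, byrow = TRUE)
    Pd <- (tab + t(tab))
    P <- P + Pd / sum(Pd)
    n_dir <- n_dir + 1
  }
  P <- P / n_dir
  ks <- 2:(2 * n_gray)
  pxy <- vapply(ks, function(k) {
    i <- max(1, k - n_gray):min(n_gray, k - 1)
    sum(P[cbind(i, k - i)])
  }, numeric(1))
  sum(ks * pxy)
}

#' Histomic characterisation of one tile
#'
#' Reduced nucleus-level feature set describing size, shape, texture and
#' spatial arrangement: nuclei are segmented by grayscale inversion (nuclei
#' are dark), Otsu thresholding, small-object removal and connected
#' components; features are the nucleus count, mean nucleus area (px^2),
#' mean solidity (component area over its convex-image area), the Haralick
#' sum-average texture statistic of the quantised grayscale tile, and the
#' mean first-nearest-neighbour distance between nucleus centroids (px).
#' A tile with no detected nuclei yields zero count and `NA` features
#' (flagged), not an error.
#'
#' @param tile H x W x 3 array in `[0, 1]` (or H x W grayscale).
#' @param min_size Minimum component size in pixels, default 5.
#' @param n_gray Gray levels for the co-occurrence matrix, default 8
#'   (suited to the low dynamic range of synthetic tiles; use 32 for real
#'   H&E).
#' @return One-row tibble: `nucleus_count`, `mean_nucleus_area`,
#'   `mean_solidity`, `haralick_sum_average`, `mean_first_neighbor_distance`,
#'   `undefined` flag.
#' @export
extract_histomic_features <- function(tile, min_size = 5, n_gray = 8) {
  gray <- if (length(dim(tile)) == 3) {
    0.299 * tile[, , 1] + 0.587 * tile[, , 2] + 0.114 * tile[, , 3]
  } else {
    tile
  }
  sa <- haralick_sum_average(gray, n_gray)
  inv <- 1 - gray
  th <- if (max(inv) - min(inv) < 1e-6) NA_real_ else otsu_threshold(inv)
  empty <- tibble::tibble(nucleus_count = 0L, mean_nucleus_area = NA_real_,
                          mean_solidity = NA_real_,
                          haralick_sum_average = sa,
                          mean_first_neighbor_distance = NA_real_,
                          undefined = TRUE)
  if (is.na(th)) return(empty)
  bw <- inv > th
  lab <- label_components(bw)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  if (!length(keep)) return(empty)
  areas <- numeric(length(keep))
  solidity <- numeric(length(keep))
  cent <- matrix(0, length(keep), 2)
  for (i in seq_along(keep)) {
    px <- which(lab == keep[i], arr.ind = TRUE)
    areas[i] <- nrow(px)
    solidity[i] <- min(1, areas[i] / convex_area(px[, 1], px[, 2]))
    cent[i, ] <- colMeans(px)
  }
  nnd <- if (length(keep) >= 2) {
    dm <- as.matrix(dist(cent))
    diag(dm) <- Inf
    mean(apply(dm, 1, min))
  } else {
    NA_real_
  }
  tibble::tibble(nucleus_count = length(keep),
                 mean_nucleus_area = mean(areas),
                 mean_solidity = mean(solidity),
                 haralick_sum_average = sa,
                 mean_first_neighbor_distance = nnd,
                 undefined = FALSE)
}

#' Compare histomic features of top-scoring tiles between classes
#'
#' Characterises the high-value regions: from every LNM+ bag the `q` tiles
#' with the highest LNM probability, and from every LNM- bag the `q` tiles
#' with the highest LNM- probability (lowest LNM+ score), are pooled and
#' each histomic feature is compared between the two pools with the
#' two-sided Wilcoxon rank-sum test.
#'
#' @param maps List of `tile_score_map`s, one per bag.
#' @param tile_bags List of the matching `tile_bag`s (same order; tile
#'   images are needed for feature extraction). Bag labels are read from
#'   the bags.
#' @param q Tiles taken per bag, default 5; clamped with a warning when a
#'   bag has fewer tiles.
#' @param ... Passed to [extract_histomic_features()].
#' @return Tibble with one row per histomic feature: `feature`,
#'   `median_pos`, `median_neg`, `statistic`, `p_value`.
#' @export
compare_top_tiles <- function(maps, tile_bags, q = 5, ...) {
  labels <- purrr::map_int(tile_bags, ~ as.integer(.x$label))
  assert_that(sum(labels == 1) >= 2 && sum(labels == 0) >= 2,
              "need at least 2 bags per class")
  collect <- function(which_bags, decreasing) {
    purrr::map_dfr(which_bags, function(i) {
      probs <- maps[[i]]$entries$probability
      qq <- q
      if (qq > length(probs)) {
        warn(sprintf("q = %d exceeds tiles in bag %s; clamping", q,
                     tile_bags[[i]]$bag_id))
        qq <- length(probs)
      }
      top <- order(probs, decreasing = decreasing)[seq_len(qq)]
      purrr::map_dfr(top, function(j) {
        extract_histomic_features(tile_bags[[i]]$tiles[[j]], ...)
      })
    })
  }
  feats_pos <- collect(which(labels == 1), decreasing = TRUE)
  feats_neg <- collect(which(labels == 0), decreasing = FALSE)
  feature_names <- c("nucleus_count", "mean_nucleus_area", "mean_solidity",
                     "haralick_sum_average", "mean_first_neighbor_distance")
  purrr::map_dfr(feature_names, function(fn) {
    a <- feats_pos[[fn]][!is.na(feats_pos[[fn]])]
    b <- feats_neg[[fn]][!is.na(feats_neg[[fn]])]
    if (!length(a) || !length(b)) {
      return(tibble::tibble(feature = fn, median_pos = NA_real_,
                            median_neg = NA_real_, statistic = NA_real_,
                            p_value = NA_real_))
    }
    wt <- wilcoxon_rank_sum(a, b)
    tibble::tibble(feature = fn, median_pos = median(a), median_neg = median(b),
                   statistic = wt$statistic, p_value = wt$p_value)
  })
}
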