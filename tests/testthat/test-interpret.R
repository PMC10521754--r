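test_that("Otsu threshold separates a bimodal image", {
  img <- matrix(c(rep(0.2, 60), rep(0.8, 40)), 10, 10)
  th <- mmil:::otsu_threshold(img)
  expect_gt(th, 0.2)
  expect_lt(th, 0.8)
  expect_identical(sum(img > th), 40L)
})

test_that("connected components and solidity behave on known shapes", {
  bw <- matrix(FALSE, 20, 20)
  bw[2:11, 2:11] <- TRUE       # 10x10 square
  bw[15:17, 15:17] <- TRUE     # separate 3x3 square
  lab <- mmil:::label_components(bw)
  expect_identical(max(lab), 2L)
  expect_setequal(tabulate(lab[lab > 0]), c(100L, 9L))
  expect_identical(lab[bw == FALSE], rep(0L, sum(!bw)))
  # a filled square is its own convex hull
  px <- which(lab == lab[2, 2], arr.ind = TRUE)
  expect_identical(mmil:::convex_area(px[, 1], px[, 2]), 100L)
  # an L-shape is strictly non-convex
  l <- matrix(FALSE, 10, 10)
  l[1:8, 1:2] <- TRUE
  l[7:8, 1:8] <- TRUE
  lp <- which(l, arr.ind = TRUE)
  expect_gt(mmil:::convex_area(lp[, 1], lp[, 2]), sum(l))
})

test_that("Haralick sum-average hits its closed forms", {
  # constant image: single co-occurrence pair (q, q) -> sum average 2q
  g <- matrix(0.5, 8, 8)   # level floor(0.5 * 8) + 1 = 5
  expect_equal(mmil:::haralick_sum_average(g, n_gray = 8), 10, tolerance = 1e-12)
  expect_equal(mmil:::haralick_sum_average(matrix(0, 5, 5), n_gray = 8), 2,
               tolerance = 1e-12)
  expect_equal(mmil:::haralick_sum_average(matrix(1, 5, 5), n_gray = 8), 16,
               tolerance = 1e-12)
  # brighter images score higher
  expect_gt(mmil:::haralick_sum_average(matrix(0.9, 6, 6)),
            mmil:::haralick_sum_average(matrix(0.3, 6, 6)))
})

test_that("histomic extraction counts planted nuclei and flags empty tiles", {
  tile <- array(0.9, c(48, 48, 3))
  put_disk <- function(t, cr, cc, rad) {
    for (r in seq_len(48)) for (c in seq_len(48)) {
      if ((r - cr)^2 + (c - cc)^2 <= rad^2) t[r, c, ] <- 0.1
    }
    t
  }
  tile <- put_disk(tile, 12, 12, 4)
  tile <- put_disk(tile, 12, 36, 4)
  tile <- put_disk(tile, 36, 24, 4)
  ft <- extract_histomic_features(tile)
  expect_identical(ft$nucleus_count, 3L)
  expect_false(ft$undefined)
  expect_gt(ft$mean_solidity, 0.85)           # disks are nearly convex
  expect_lte(ft$mean_solidity, 1)
  expect_equal(ft$mean_nucleus_area, 45, tolerance = 0.2)  # ~pi * 16 px
  # centroids at (12,12), (12,36), (36,24): nearest neighbour of each
  d12 <- 24; d3 <- sqrt(24^2 + 12^2)
  expect_equal(ft$mean_first_neighbor_distance,
               mean(c(d12, d12, d3)), tolerance = 0.1)

  blank <- array(0.9, c(16, 16, 3))
  fb <- extract_histomic_features(blank)
  expect_identical(fb$nucleus_count, 0L)
  expect_true(fb$undefined)
  expect_true(is.na(fb$mean_nucleus_area))
})

test_that("tile scoring produces a deterministic per-tile probability map", {
  co <- small_cohort()
  pipe <- small_pipeline()
  bag <- co$bags[[which(co$labels == 1)[1]]]
  map <- score_tiles(pipe, bag, co$biomarkers)
  expect_s3_class(map, "tile_score_map")
  expect_identical(nrow(map$entries), length(bag$tiles))
  expect_true(all(map$entries$probability >= 0 & map$entries$probability <= 1))
  expect_identical(score_tiles(pipe, bag, co$biomarkers)$entries, map$entries)
  # neutral-biomarker mode works without a table
  map0 <- score_tiles(pipe, bag)
  expect_identical(nrow(map0$entries), length(bag$tiles))
  # attention channel is a simplex over the bag
  att <- score_tiles(pipe, bag, co$biomarkers, channel = "attention")
  expect_equal(sum(att$entries$probability), 1, tolerance = 1e-12)
  # a backbone the model was not trained with is refused
  expect_error(score_tiles(pipe, bag, co$biomarkers,
                           spec = backbone_spec(seed = 99)), "fingerprint")
})

test_that("score histogram partitions all tiles", {
  map <- score_tiles(small_pipeline(), small_cohort()$bags[[1]])
  h <- score_histogram(map, n_bins = 10)
  expect_identical(nrow(h), 10L)
  expect_identical(sum(h$count), nrow(map$entries))
  expect_equal(h$bin_upper - h$bin_lower, rep(0.1, 10), tolerance = 1e-12)
})

test_that("heatmap rendering is byte-stable with a monotone colormap", {
  map <- score_tiles(small_pipeline(), small_cohort()$bags[[1]])
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_heatmap(map, f1, cell_px = 4)
  render_heatmap(map, f2, cell_px = 4)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  img <- png::readPNG(f1)
  expect_equal(dim(img), c(map$grid_shape[1] * 4, (map$grid_shape[2] + 2) * 4, 4))
  # higher probability -> strictly redder, bluer otherwise
  cols <- mmil:::heat_rgb(c(0.1, 0.9))
  expect_gt(cols[2, "r"], cols[1, "r"])
  expect_lt(cols[2, "b"], cols[1, "b"])
  expect_error(render_heatmap(map, "/nonexistent-dir/x.png"), "writ")
  p <- autoplot(map)
  expect_s3_class(p, "ggplot")
})

test_that("top-tile comparison contrasts pooled histomics between classes", {
  co <- small_cohort()
  pipe <- small_pipeline()
  maps <- lapply(co$bags, score_tiles, pipeline = pipe,
                 biomarkers = co$biomarkers)
  cmp <- compare_top_tiles(maps, co$bags, q = 3)
  expect_s3_class(cmp, "tbl_df")
  expect_identical(nrow(cmp), 5L)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1, na.rm = TRUE))
  expect_true("nucleus_count" %in% cmp$feature)
  # asking for more tiles than a bag holds clamps with a warning per bag
  w <- capture_warnings(compare_top_tiles(maps, co$bags, q = 50))
  expect_true(all(grepl("clamp", w)) && length(w) > 0)
})
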