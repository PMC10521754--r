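#' Tile bag constructor
#'
#' A bag is one patient's ordered collection of tiles together with grid
#' coordinates and the bag-level LNM label; tile order carries no semantic
#' meaning (the MIL pooling downstream is permutation invariant).
#'
#' @param bag_id Character id.
#' @param tiles List of H x W x 3 arrays in `[0, 1]`.
#' @param coords Tibble with `grid_row`, `grid_col` (0-based), one row per
#'   tile; an optional `roi_overlap` column records the ROI fraction.
#' @param label 0, 1, or `NA` when unknown.
#' @return A `tile_bag`.
#' @export
new_tile_bag <- function(bag_id, tiles, coords, label = NA_integer_) {
  assert_that(length(tiles) == nrow(coords),
              "`tiles` and `coords` must have matching lengths")
  structure(list(bag_id = bag_id, tiles = tiles,
                 coords = tibble::as_tibble(coords),
                 label = label),
            class = "tile_bag")
}

#' @export
print.tile_bag <- function(x, ...) {
  cat(sprintf("<tile_bag> %s: %d tiles, label = %s\n",
              x$bag_id, length(x$tiles), format(x$label)))
  invisible(x)
}

#' Enumerate the tile grid of an image
#'
#' Non-overlapping 512 px tiles are the convention for whole-slide images at
#' 20x magnification; the grid is enumerated row-major with 0-based,
#' half-open pixel bounding boxes.  Tiles whose box would exceed the image
#' are dropped rather than padded, so an image smaller than `tile_size`
#' yields an empty grid.
#'
#' @param image_shape Integer `(rows, cols)` of the image.
#' @param tile_size Tile side length in pixels.
#' @param stride Step between tile origins; defaults to `tile_size`
#'   (non-overlapping).
#' @return Tibble with `grid_row`, `grid_col`, `r0`, `r1`, `c0`, `c1`
#'   (half-open `[r0, r1) x [c0, c1)`).
#' @export
#' @examples
#' compute_tile_grid(c(1024, 1024), 512)
compute_tile_grid <- function(image_shape, tile_size, stride = tile_size) {
  assert_that(is_count(tile_size), "`tile_size` must be a positive count")
  assert_that(is_count(stride), "`stride` must be a positive count")
  assert_that(length(image_shape) >= 2 && all(image_shape >= 0),
              "`image_shape` must give (rows, cols)")
  r_starts <- seq(0L, by = as.integer(stride),
                  length.out = max(0L, (image_shape[1] - tile_size) %/% stride + 1))
  c_starts <- seq(0L, by = as.integer(stride),
                  length.out = max(0L, (image_shape[2] - tile_size) %/% stride + 1))
  if (image_shape[1] < tile_size) r_starts <- integer(0)
  if (image_shape[2] < tile_size) c_starts <- integer(0)
  grid <- tidyr::expand_grid(r0 = r_starts, c0 = c_starts)  # row-major
  tibble::tibble(
    grid_row = grid$r0 %/% as.integer(stride),
    grid_col = grid$c0 %/% as.integer(stride),
    r0 = grid$r0, r1 = grid$r0 + as.integer(tile_size),
    c0 = grid$c0, c1 = grid$c0 + as.integer(tile_size)
  )
}

#' Fraction of a tile covered by the region of interest
#'
#' Exact pixel-count ratio `|ROI intersect tile| / tile area` for a binary
#' mask on the same pixel grid as the image.
#'
#' @param tile_bbox Numeric `(r0, r1, c0, c1)`, 0-based half-open, or a
#'   one-row tibble from [compute_tile_grid()].
#' @param mask Binary matrix (0/1 or logical); nonzero means ROI.
#' @param image_shape Optional `(rows, cols)` to validate that the mask and
#'   image share a grid.
#' @return Overlap fraction in `[0, 1]`.
#' @export
compute_roi_overlap <- function(tile_bbox, mask, image_shape = NULL) {
  if (is.data.frame(tile_bbox)) {
    tile_bbox <- c(tile_bbox$r0[1], tile_bbox$r1[1],
                   tile_bbox$c0[1], tile_bbox$c1[1])
  }
  if (!is.null(image_shape) && !all(dim(mask)[1:2] == image_shape[1:2])) {
    abort("mask and image shapes differ")
  }
  r0 <- tile_bbox[1]; r1 <- tile_bbox[2]
  c0 <- tile_bbox[3]; c1 <- tile_bbox[4]
  assert_that(r0 >= 0 && c0 >= 0 && r1 <= nrow(mask) && c1 <= ncol(mask),
              "tile bbox falls outside the mask")
  sub <- mask[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
  sum(sub != 0) / length(sub)
}

#' Filter tiles by ROI overlap
#'
#' Keeps tiles whose `roi_overlap` is at least `min_overlap` — tiles with
#' less than 20% overlap with the annotated cancer region are excluded by
#' default, and a tile at exactly the threshold is kept.  Order is
#' preserved and the operation is idempotent.
#'
#' @param tiles Tibble with a `roi_overlap` column (e.g. an annotated grid),
#'   or a `tile_bag` whose `coords` carry `roi_overlap`.
#' @param min_overlap Inclusive threshold, default 0.2.
#' @return Same type as `tiles`, subset.
#' @export
filter_tiles <- function(tiles, min_overlap = 0.2) {
  assert_that(is_fraction(min_overlap), "`min_overlap` must lie in [0, 1]")
  if (inherits(tiles, "tile_bag")) {
    assert_that("roi_overlap" %in% names(tiles$coords),
                "tile_bag coords lack `roi_overlap`")
    keep <- tiles$coords$roi_overlap >= min_overlap
    return(new_tile_bag(tiles$bag_id, tiles$tiles[keep],
                        tiles$coords[keep, ], tiles$label))
  }
  assert_that("roi_overlap" %in% names(tiles), "`tiles` lack `roi_overlap`")
  tiles[tiles$roi_overlap >= min_overlap, ]
}

#' Tile a slide image into a MIL bag
#'
#' Full tiling pipeline for one slide: enumerate the grid, compute exact ROI
#' overlap per tile against the binary mask, drop tiles under the overlap
#' threshold, and crop the surviving tiles.
#'
#' @param image H x W x 3 array in `[0, 1]` (or H x W grayscale).
#' @param mask Binary H x W matrix, nonzero = ROI.
#' @param bag_id Identifier for the resulting bag.
#' @param tile_size,stride,min_overlap See [compute_tile_grid()] and
#'   [filter_tiles()].
#' @param label Optional bag label.
#' @return A `tile_bag`; its `coords` carry `roi_overlap`.
#' @export
tile_image <- function(image, mask, bag_id, tile_size = 512,
                       stride = tile_size, min_overlap = 0.2,
                       label = NA_integer_) {
  shp <- dim(image)[1:2]
  if (!all(dim(mask)[1:2] == shp)) abort("mask and image shapes differ")
  grid <- compute_tile_grid(shp, tile_size, stride)
  if (nrow(grid) == 0) {
    return(new_tile_bag(bag_id, list(),
                        tibble::tibble(grid_row = integer(), grid_col = integer(),
                                       roi_overlap = numeric()),
                        label))
  }
  grid$roi_overlap <- purrr::pmap_dbl(grid, function(r0, r1, c0, c1, ...) {
    compute_roi_overlap(c(r0, r1, c0, c1), mask)
  })
  kept <- filter_tiles(grid, min_overlap)
  tiles <- purrr::pmap(kept, function(r0, r1, c0, c1, ...) {
    if (length(dim(image)) == 3) {
      image[(r0 + 1):r1, (c0 + 1):c1, , drop = FALSE]
    } else {
      image[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
    }
  })
  new_tile_bag(bag_id, tiles,
               kept[, c("grid_row", "grid_col", "roi_overlap")], label)
}

#' Read an image and its ROI mask from PNG files
#'
#' @param image_path RGB (or grayscale) PNG/TIFF path.
#' @param mask_path Single-channel PNG path; pixel value 255 (1.0 after
#'   decoding) marks ROI.
#' @return List with `image` array and binary `mask` matrix.
#' @export
read_slide <- function(image_path, mask_path) {
  image <- png::readPNG(image_path)
  mask <- png::readPNG(mask_path)
  if (length(dim(mask)) == 3) mask <- mask[, , 1]
  list(image = image, mask = (mask > 0.5) * 1L)
}
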