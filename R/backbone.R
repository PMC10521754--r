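#' Backbone specification for tile feature extraction
#'
#' Registry of instance-level feature extractors.  `"smallconv"` is a fully
#' implemented three-conv-block network (3x3 valid convolutions with ReLU
#' and 2x2 max pooling, channels 8/16/32, global mean+max pooling over the
#' final maps, so `feature_dim = 64`), randomly He-initialised from a fixed
#' seed and used frozen — adequate as a deterministic texture encoder for
#' the synthetic tiles and for CPU test runs.  `"resnet18"` is registered
#' with the architecture's known embedding width (512, the channel count of
#' its final stage, exposed after removing the final fully connected layer);
#' extracting with it requires a weights file supplied by the user.
#'
#' @param name `"smallconv"` or `"resnet18"`.
#' @param input_size Expected tile side in pixels (tiles are resized to it).
#' @param seed Seed for the random initialisation of `"smallconv"`.
#' @param weights_path Optional path to pretrained weights (required for
#'   `"resnet18"`).
#' @return A `backbone_spec` with `name`, `feature_dim`, `input_size`,
#'   `fingerprint` and (for smallconv) the weights.
#' @export
backbone_spec <- function(name = c("smallconv", "resnet18"),
                          input_size = if (match.arg(name) == "resnet18") 224 else 64,
                          seed = 42, weights_path = NULL) {
  name <- match.arg(name)
  if (name == "resnet18") {
    spec <- list(name = name, feature_dim = 512L, input_size = as.integer(input_size),
                 pretrained = TRUE, weights_path = weights_path)
  } else {
    channels <- c(8L, 16L, 32L)
    weights <- with_seed(seed, {
      he <- function(fan_in, n) matrix(rnorm(fan_in * n, sd = sqrt(2 / fan_in)),
                                       fan_in, n)
      list(
        W1 = he(9 * 3, channels[1]),  b1 = rep(0, channels[1]),
        W2 = he(9 * channels[1], channels[2]), b2 = rep(0, channels[2]),
        W3 = he(9 * channels[2], channels[3]), b3 = rep(0, channels[3])
      )
    })
    spec <- list(name = name, feature_dim = 2L * channels[3],
                 input_size = as.integer(input_size), pretrained = FALSE,
                 seed = seed, channels = channels, weights = weights)
  }
  spec$fingerprint <- fingerprint(spec[setdiff(names(spec), "fingerprint")])
  structure(spec, class = "backbone_spec")
}

# Linear indices for im2col on an h x w image with k x k valid patches,
# cached per shape (the same shapes recur for every tile of a cohort).
.im2col_cache <- new.env(parent = emptyenv())
im2col_idx <- function(h, w, k) {
  key <- paste(h, w, k, sep = "x")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  oh <- h - k + 1; ow <- w - k + 1
  base <- outer(seq_len(oh), (seq_len(ow) - 1) * h, "+")
  off <- outer(seq_len(k) - 1, (seq_len(k) - 1) * h, "+")
  res <- list(idx = outer(as.vector(base), as.vector(off), "+"), oh = oh, ow = ow)
  .im2col_cache[[key]] <- res
  res
}

conv_relu <- function(x, W, b) {
  d <- dim(x)
  ic <- im2col_idx(d[1], d[2], 3)
  kk <- ncol(ic$idx)
  cin <- d[3]
  cols <- matrix(0, nrow(ic$idx), kk * cin)
  for (ch in seq_len(cin)) {
    cols[, ((ch - 1) * kk + 1):(ch * kk)] <- x[, , ch][ic$idx]
  }
  out <- sweep(cols %*% W, 2, b, "+")
  out[out < 0] <- 0
  array(out, c(ic$oh, ic$ow, ncol(W)))
}

maxpool2 <- function(x) {
  h <- dim(x)[1] %/% 2 * 2
  w <- dim(x)[2] %/% 2 * 2
  x <- x[seq_len(h), seq_len(w), , drop = FALSE]
  m <- pmax(x[seq(1, h, 2), , , drop = FALSE], x[seq(2, h, 2), , , drop = FALSE])
  pmax(m[, seq(1, w, 2), , drop = FALSE], m[, seq(2, w, 2), , drop = FALSE])
}

# Nearest-neighbour resize of an H x W x C array to side `s`.
resize_tile <- function(x, s) {
  d <- dim(x)
  if (length(d) == 2) x <- array(rep(x, 3), c(d, 3))
  d <- dim(x)
  if (d[1] == s && d[2] == s) return(x)
  ri <- pmin(d[1], pmax(1, round(seq(0.5, d[1] - 0.5, length.out = s) + 0.5)))
  ci <- pmin(d[2], pmax(1, round(seq(0.5, d[2] - 0.5, length.out = s) + 0.5)))
  x[ri, ci, , drop = FALSE]
}

# Per-channel standardisation constants applied before the backbone.  The
# values are fixed and recorded here so extraction is reproducible.
TILE_NORM_MEAN <- c(0.80, 0.72, 0.78)
TILE_NORM_SD <- c(0.20, 0.20, 0.20)

smallconv_forward <- function(x, spec) {
  for (ch in 1:3) x[, , ch] <- (x[, , ch] - TILE_NORM_MEAN[ch]) / TILE_NORM_SD[ch]
  w <- spec$weights
  a <- maxpool2(conv_relu(x, w$W1, w$b1))
  a <- maxpool2(conv_relu(a, w$W2, w$b2))
  a <- maxpool2(conv_relu(a, w$W3, w$b3))
  c(apply(a, 3, mean), apply(a, 3, max))
}

#' Extract instance features for a bag of tiles
#'
#' Maps each tile to a fixed-length feature row.  Deterministic for fixed
#' backbone weights (the backbone runs in evaluation mode; there is no
#' stochastic layer), so identical tiles yield identical rows.
#'
#' @param bag A `tile_bag`.
#' @param spec A [backbone_spec()].
#' @return A `feature_bag`: list with `bag_id`, `features`
#'   (n_tiles x feature_dim matrix), `label`, `coords`, and the backbone
#'   `fingerprint`.
#' @export
extract_features <- function(bag, spec = backbone_spec()) {
  assert_that(inherits(bag, "tile_bag"), "`bag` must be a tile_bag")
  assert_that(inherits(spec, "backbone_spec"), "`spec` must be a backbone_spec")
  if (length(bag$tiles) == 0) abort("cannot extract features from an empty bag")
  if (spec$name == "resnet18" && is.null(spec$weights_path)) {
    abort(paste("the resnet18 backbone needs pretrained weights;",
                "supply `weights_path` or use the smallconv backbone"))
  }
  rows <- lapply(bag$tiles, function(tl) {
    d <- dim(tl)
    if (length(d) == 3 && d[3] != 3 && d[3] != 1) {
      abort(sprintf("tile has %d channels; expected 1 or 3", d[3]))
    }
    x <- resize_tile(tl, spec$input_size)
    smallconv_forward(x, spec)
  })
  feats <- do.call(rbind, rows)
  if (any(!is.finite(feats))) abort("non-finite values in extracted features")
  new_feature_bag(bag$bag_id, feats, bag$label, bag$coords, spec$fingerprint)
}

#' Feature bag constructor
#'
#' @param bag_id Character id.
#' @param features n x d numeric matrix, row i belonging to tile i.
#' @param label Bag label (0/1 or NA).
#' @param coords Per-tile coordinate tibble carried through for heatmaps.
#' @param backbone Fingerprint of the extracting backbone.
#' @return A `feature_bag`.
#' @export
new_feature_bag <- function(bag_id, features, label = NA_integer_,
                            coords = NULL, backbone = NA_character_) {
  features <- as.matrix(features)
  assert_that(all(is.finite(features)), "features must be finite")
  if (is.null(coords)) {
    coords <- tibble::tibble(grid_row = seq_len(nrow(features)) - 1L,
                             grid_col = 0L)
  }
  structure(list(bag_id = bag_id, features = features, label = label,
                 coords = tibble::as_tibble(coords), backbone = backbone),
            class = "feature_bag")
}

#' @export
print.feature_bag <- function(x, ...) {
  cat(sprintf("<feature_bag> %s: %d x %d, label = %s\n", x$bag_id,
              nrow(x$features), ncol(x$features), format(x$label)))
  invisible(x)
}

#' Cache extracted features on disk
#'
#' One file per bag plus a JSON manifest recording dimensions and the
#' backbone fingerprint; [load_features()] verifies both.
#' [cache_features()] is incremental: bags already present under the same
#' fingerprint are not recomputed.
#'
#' @param bags List of `tile_bag`s.
#' @param path Cache directory.
#' @param spec Backbone to use for extraction.
#' @return Invisibly, the list of `feature_bag`s (loaded or extracted).
#' @export
cache_features <- function(bags, path, spec = backbone_spec()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  man_path <- file.path(path, "manifest.json")
  manifest <- if (file.exists(man_path)) {
    jsonlite::read_json(man_path, simplifyVector = TRUE)
  } else {
    list(feature_dim = spec$feature_dim, backbone = spec$fingerprint,
         bag_ids = character(0))
  }
  if (!identical(manifest$backbone, spec$fingerprint)) {
    abort("feature cache was built with a different backbone (stale cache)")
  }
  out <- vector("list", length(bags))
  for (i in seq_along(bags)) {
    bag <- bags[[i]]
    f <- file.path(path, paste0(bag$bag_id, ".rds"))
    if (file.exists(f) && bag$bag_id %in% manifest$bag_ids) {
      out[[i]] <- readRDS(f)
    } else {
      fb <- extract_features(bag, spec)
      saveRDS(fb, f)
      manifest$bag_ids <- union(manifest$bag_ids, bag$bag_id)
      out[[i]] <- fb
    }
  }
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Load cached features
#'
#' @param path Cache directory written by [cache_features()].
#' @param expected_dim Optional feature dimension to validate against the
#'   manifest.
#' @return List of `feature_bag`s in manifest order.
#' @export
load_features <- function(path, expected_dim = NULL) {
  man_path <- file.path(path, "manifest.json")
  assert_that(file.exists(man_path), paste("no feature cache at", path))
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (!is.null(expected_dim) && manifest$feature_dim != expected_dim) {
    abort(sprintf("cache feature_dim %d != expected %d (stale cache)",
                  manifest$feature_dim, expected_dim))
  }
  out <- lapply(manifest$bag_ids, function(id) {
    fb <- readRDS(file.path(path, paste0(id, ".rds")))
    if (ncol(fb$features) != manifest$feature_dim) {
      abort("cached bag dimension disagrees with manifest (stale cache)")
    }
    fb
  })
  stats::setNames(out, manifest$bag_ids)
}
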