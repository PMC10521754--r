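# Fixtures are generated in code; nothing is read from disk.

# Gaussian feature bags with a class shift on selected dimensions -- a fast
# stand-in for backbone features when the test targets the MIL/selection
# machinery rather than the image pipeline.
make_gauss_bags <- function(n_bags_per_class, n_inst = 8, d = 6,
                            shift_dims = 1, shift = 1, seed = 1,
                            prefix = "B") {
  set.seed(seed)
  labels <- rep(c(1L, 0L), each = n_bags_per_class)
  bags <- lapply(seq_along(labels), function(i) {
    m <- matrix(rnorm(n_inst * d), n_inst, d)
    if (labels[i] == 1L) {
      m[, shift_dims] <- m[, shift_dims, drop = FALSE] + shift
    }
    new_feature_bag(sprintf("%s%03d", prefix, i), m, labels[i])
  })
  list(bags = bags, labels = labels)
}

# Biomarker table with a CA19-9 class shift and no missingness, for pipeline
# tests that want deterministic tabular input.
make_bm_table <- function(ids, labels, seed = 1) {
  set.seed(seed)
  n <- length(ids)
  tibble::tibble(
    patient_id = ids,
    CEA = rlnorm(n, log(ifelse(labels == 1, 5, 3.5)), 0.3),
    CA125 = rlnorm(n, log(11), 0.3),
    CA19_9 = rlnorm(n, log(ifelse(labels == 1, 12, 8)), 0.3),
    AFP = rlnorm(n, log(2.5), 0.3)
  )
}

# Small synthetic cohort shared across tests (memoised per session).
.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- synthetic_config(n_patients = 12, tiles_per_bag = 6,
                            tile_size = 32, seed = 20)
    .fixture_env$cohort <- generate_cohort(cfg)
  }
  .fixture_env$cohort
}

# Feature bags extracted from the small cohort with the default backbone,
# and a pipeline trained on them (memoised; used by interpretation tests).
small_feature_bags <- function() {
  if (is.null(.fixture_env$fbags)) {
    .fixture_env$fbags <- lapply(small_cohort()$bags, extract_features,
                                 spec = backbone_spec())
  }
  .fixture_env$fbags
}

small_pipeline <- function() {
  if (is.null(.fixture_env$pipeline)) {
    co <- small_cohort()
    .fixture_env$pipeline <- fit_mmil(small_feature_bags(), co$biomarkers,
                                      co$labels, epochs = 10, seed = 2)
  }
  .fixture_env$pipeline
}
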