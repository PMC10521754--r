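test_that("cross-entropy matches frozen closed-form values", {
  # uniform binary predictions: -log(1/2)
  p_unif <- matrix(0.5, 2, 2)
  expect_equal(cross_entropy_loss(p_unif, c(0L, 1L)), log(2),
               tolerance = 1e-12)
  # (-log 0.8 - log 0.6) / 2
  p <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  expect_equal(cross_entropy_loss(p, c(0L, 1L)),
               -(log(0.8) + log(0.6)) / 2, tolerance = 1e-12)
  # perfect prediction -> 0; clamped zero probability warns and stays finite
  expect_equal(cross_entropy_loss(rbind(c(1, 0)), 0L), 0, tolerance = 1e-12)
  expect_warning(l0 <- cross_entropy_loss(rbind(c(0, 1)), 0L), "clamp")
  expect_true(is.finite(l0))
  expect_equal(l0, -log(1e-12), tolerance = 1e-6)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- mmil_config(input_dim = 5, image_repr_dim = 4, biomarker_repr_dim = 3,
                     attention_hidden_dim = 4, biomarker_hidden_dim = 4,
                     classifier_hidden_dim = 6, seed = 3)
  model <- mmil_init(cfg)
  set.seed(3)
  X <- matrix(rnorm(4 * 5), 4, 5)
  bm <- runif(4)
  y <- 1L
  loss_at <- function(m) {
    fw <- mmil:::mmil_forward_cached(m, X, bm)
    cross_entropy_loss(matrix(fw$head$probs, 1), y)
  }
  fw <- mmil:::mmil_forward_cached(model, X, bm)
  dlog <- mmil:::softmax_ce_grad_logits(fw$head$probs, y)
  gr <- mmil:::mmil_backward(model, fw, dlog)
  eps <- 1e-6
  for (nm in c("We", "V", "U", "w", "Wb1", "Wb2", "Wgz", "Wgm", "Wc1", "Wc2",
               "be", "bb1", "bc1")) {
    g <- gr[[nm]]
    flat <- sample(length(g), min(4, length(g)))
    for (i in flat) {
      m2 <- model; m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
      m3 <- model; m3$params[[nm]][i] <- m3$params[[nm]][i] - eps
      fd <- (loss_at(m2) - loss_at(m3)) / (2 * eps)
      expect_equal(g[i], fd, tolerance = 1e-5)
    }
  }
})

test_that("attention pooling is permutation invariant and duplication aware", {
  cfg <- mmil_config(input_dim = 6, seed = 11)
  model <- mmil_init(cfg)
  set.seed(11)
  X <- matrix(rnorm(7 * 6), 7, 6)
  bm <- runif(4)
  base <- mmil_predict_bag(model, X, bm)
  perm <- sample(7)
  shuffled <- mmil_predict_bag(model, X[perm, ], bm)
  expect_equal(shuffled$class_probabilities, base$class_probabilities,
               tolerance = 1e-12)
  expect_equal(shuffled$attention_weights, base$attention_weights[perm],
               tolerance = 1e-12)
  expect_equal(sum(base$attention_weights), 1, tolerance = 1e-12)
  expect_true(all(base$attention_weights >= 0))

  # duplicating one instance: copies share a weight, and all weights keep
  # their pairwise ratios (softmax renormalisation)
  Xd <- rbind(X, X[1, ])
  dup <- mmil_predict_bag(model, Xd, bm)
  expect_equal(dup$attention_weights[1], dup$attention_weights[8],
               tolerance = 1e-12)
  expected <- c(base$attention_weights, base$attention_weights[1])
  expect_equal(dup$attention_weights, expected / sum(expected),
               tolerance = 1e-12)

  # a singleton bag puts all attention on its only instance
  one <- mmil_predict_bag(model, X[2, , drop = FALSE], bm)
  expect_equal(one$attention_weights, 1, tolerance = 1e-12)
})

test_that("the fused representation follows the gated Kronecker contract", {
  cfg <- mmil_config(input_dim = 4, image_repr_dim = 3, biomarker_repr_dim = 2,
                     seed = 5)
  model <- mmil_init(cfg)
  set.seed(5)
  X <- matrix(rnorm(3 * 4), 3, 4)
  bm <- runif(4)
  out <- mmil_predict_bag(model, X, bm)
  expect_identical(length(out$fused_repr), (3L + 1L) * (2L + 1L))
  expect_equal(sum(out$class_probabilities), 1, tolerance = 1e-12)
  # the appended-one slot guarantees the final coordinate is exactly 1
  expect_equal(out$fused_repr[length(out$fused_repr)], 1, tolerance = 1e-12)

  # layout oracle: with gating off the tensor is a plain Kronecker product
  cfg2 <- mmil_config(input_dim = 4, image_repr_dim = 1, biomarker_repr_dim = 1,
                      gate_enabled = FALSE, seed = 5)
  m2 <- mmil_init(cfg2)
  fw <- mmil:::mmil_forward_cached(m2, X, bm)
  z1 <- c(fw$z, 1); m1 <- c(fw$m, 1)
  expect_equal(fw$fus$f, as.numeric(kronecker(z1, m1)), tolerance = 1e-12)
  expect_equal(as.numeric(kronecker(c(2, 1), c(3, 1))), c(6, 2, 3, 1))
})

test_that("oversized fusion dimensions are refused upfront", {
  expect_error(mmil_config(input_dim = 4, image_repr_dim = 200,
                           biomarker_repr_dim = 200), "fused")
})

test_that("unimodal ablations ignore the silenced channel", {
  set.seed(6)
  X <- matrix(rnorm(5 * 4), 5, 4)
  img_only <- mmil_init(mmil_config(input_dim = 4, mode = "image", seed = 6))
  a <- mmil_predict_bag(img_only, X, c(0.1, 0.2, 0.3, 0.4))
  b <- mmil_predict_bag(img_only, X, c(0.9, 0.8, 0.7, 0.6))
  expect_equal(a$class_probabilities, b$class_probabilities, tolerance = 1e-12)

  bio_only <- mmil_init(mmil_config(input_dim = 4, mode = "biomarker", seed = 6))
  bm <- c(0.5, 0.5, 0.5, 0.5)
  c1 <- mmil_predict_bag(bio_only, X, bm)
  c2 <- mmil_predict_bag(bio_only, matrix(rnorm(5 * 4), 5, 4), bm)
  expect_equal(c1$class_probabilities, c2$class_probabilities,
               tolerance = 1e-12)
})

test_that("biomarker encoding validates its input length", {
  model <- mmil_init(mmil_config(input_dim = 4, seed = 1))
  expect_error(mmil_predict_bag(model, matrix(rnorm(8), 2, 4), c(0.1, 0.2)),
               "4")
})
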