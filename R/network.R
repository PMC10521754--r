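#' Model configuration for the multimodal MIL network
#'
#' The network has three parts (two feature-extraction channels and an
#' information-fusion module): gated-attention MIL pooling of instance
#' features into an image representation; a feedforward encoder of the four
#' normalised biomarkers into a molecular representation; and fusion by
#' gating-based attention followed by a Kronecker tensor product (with an
#' appended constant 1 per modality so unimodal terms survive), feeding a
#' small classifier trained with categorical cross-entropy.
#'
#' Hidden sizes are deliberately modest — the bags are small and the fused
#' dimension grows as `(d1+1)(d2+1)`.
#'
#' @param input_dim Instance feature dimension entering the network (after
#'   selection).
#' @param image_repr_dim Image (bag) representation size d1, default 16.
#' @param biomarker_repr_dim Molecular representation size d2, default 8.
#' @param attention_hidden_dim Hidden size of the attention scorer, default 16.
#' @param biomarker_hidden_dim Hidden size of the biomarker encoder, default 16.
#' @param classifier_hidden_dim Hidden size of the classifier head, default 32.
#' @param n_classes Number of outcome categories C, default 2 (LNM-/LNM+).
#' @param gate_enabled Use gating-based attention before fusion, default TRUE
#'   (FALSE fixes both gates at 1).
#' @param gated_attention Use the gated form of attention pooling (tanh *
#'   sigmoid scorer); FALSE gives the plain tanh scorer.
#' @param dropout Dropout rate on the classifier hidden layer during
#'   training, default 0 (evaluation mode never applies dropout).
#' @param mode `"multimodal"`, `"image"` (biomarker channel replaced by a
#'   learned constant vector) or `"biomarker"` (image channel replaced by a
#'   learned constant vector) — the unimodal ablations.
#' @param fused_cap Guard on the fused dimension `(d1+1)(d2+1)`.
#' @param seed Seed for weight initialisation.
#' @return A `mmil_config`.
#' @export
mmil_config <- function(input_dim,
                        image_repr_dim = 16,
                        biomarker_repr_dim = 8,
                        attention_hidden_dim = 16,
                        biomarker_hidden_dim = 16,
                        classifier_hidden_dim = 32,
                        n_classes = 2,
                        gate_enabled = TRUE,
                        gated_attention = TRUE,
                        dropout = 0,
                        mode = c("multimodal", "image", "biomarker"),
                        fused_cap = 10000,
                        seed = 1) {
  mode <- match.arg(mode)
  dims <- c(input_dim, image_repr_dim, biomarker_repr_dim,
            attention_hidden_dim, biomarker_hidden_dim, classifier_hidden_dim)
  assert_that(all(vapply(dims, is_count, logical(1))),
              "all dimensions must be positive counts")
  assert_that(is_count(n_classes) && n_classes >= 2, "`n_classes` must be >= 2")
  assert_that(is_fraction(dropout) && dropout < 1, "`dropout` must lie in [0, 1)")
  fused_dim <- (image_repr_dim + 1) * (biomarker_repr_dim + 1)
  if (fused_dim > fused_cap) {
    abort(sprintf(
      "fused dimension (d1+1)(d2+1) = %d exceeds the cap %d; use smaller representation dims",
      fused_dim, fused_cap))
  }
  structure(list(
    input_dim = as.integer(input_dim),
    image_repr_dim = as.integer(image_repr_dim),
    biomarker_repr_dim = as.integer(biomarker_repr_dim),
    attention_hidden_dim = as.integer(attention_hidden_dim),
    biomarker_hidden_dim = as.integer(biomarker_hidden_dim),
    classifier_hidden_dim = as.integer(classifier_hidden_dim),
    n_classes = as.integer(n_classes),
    gate_enabled = isTRUE(gate_enabled),
    gated_attention = isTRUE(gated_attention),
    dropout = dropout,
    mode = mode,
    fused_dim = as.integer(fused_dim),
    seed = as.integer(seed)
  ), class = "mmil_config")
}

#' Initialise an MMIL model
#'
#' All weights are drawn from a seeded generator (Glorot-scaled normals,
#' zero biases), so initialisation is reproducible.
#'
#' @param config A [mmil_config()].
#' @return An `mmil_model`: list with `params`, `config`, and bookkeeping
#'   fields (`selection_fingerprint`, `trained_on`).
#' @export
mmil_init <- function(config) {
  assert_that(inherits(config, "mmil_config"), "`config` must be an mmil_config")
  g <- function(n_in, n_out) {
    matrix(rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
  }
  cf <- config
  params <- with_seed(cf$seed, list(
    We = g(cf$input_dim, cf$image_repr_dim),
    be = rep(0, cf$image_repr_dim),
    V = g(cf$image_repr_dim, cf$attention_hidden_dim),
    U = g(cf$image_repr_dim, cf$attention_hidden_dim),
    w = rnorm(cf$attention_hidden_dim, sd = sqrt(1 / cf$attention_hidden_dim)),
    Wb1 = g(4, cf$biomarker_hidden_dim),
    bb1 = rep(0, cf$biomarker_hidden_dim),
    Wb2 = g(cf$biomarker_hidden_dim, cf$biomarker_repr_dim),
    bb2 = rep(0, cf$biomarker_repr_dim),
    Wgz = g(cf$image_repr_dim + cf$biomarker_repr_dim, cf$image_repr_dim),
    bgz = rep(0, cf$image_repr_dim),
    Wgm = g(cf$image_repr_dim + cf$biomarker_repr_dim, cf$biomarker_repr_dim),
    bgm = rep(0, cf$biomarker_repr_dim),
    Wc1 = g(cf$fused_dim, cf$classifier_hidden_dim),
    bc1 = rep(0, cf$classifier_hidden_dim),
    Wc2 = g(cf$classifier_hidden_dim, cf$n_classes),
    bc2 = rep(0, cf$n_classes),
    img_const = rnorm(cf$image_repr_dim, sd = 0.1),
    bio_const = rnorm(cf$biomarker_repr_dim, sd = 0.1)
  ))
  structure(list(params = params, config = config,
                 selection_fingerprint = NA_character_,
                 backbone_fingerprint = NA_character_,
                 trained_on = character(0)),
            class = "mmil_model")
}

#' @export
print.mmil_model <- function(x, ...) {
  cf <- x$config
  cat(sprintf(
    "<mmil_model> mode = %s, input %d -> image %d + biomarker %d -> fused %d -> %d classes\n",
    cf$mode, cf$input_dim, cf$image_repr_dim, cf$biomarker_repr_dim,
    cf$fused_dim, cf$n_classes))
  invisible(x)
}

#' Gated-attention MIL pooling
#'
#' Embeds instances, scores each with the gated attention form
#' `score_k = w' (tanh(V' h_k) * sigmoid(U' h_k))`, softmax-normalises the
#' scores into weights on the simplex, and returns the weighted sum of
#' instance embeddings.  Weights are permutation equivariant and the bag
#' representation permutation invariant.
#'
#' @param features n x input_dim matrix (one row per instance, n >= 1).
#' @param model An `mmil_model` (its embedding and attention parameters are
#'   used).
#' @return List with `bag_repr` (length `image_repr_dim`) and `weights`
#'   (length n, summing to 1).
#' @export
attention_pool <- function(features, model) {
  features <- as.matrix(features)
  if (nrow(features) == 0) abort("cannot pool an empty bag")
  if (any(!is.finite(features))) abort("non-finite instance features")
  fw <- forward_image_channel(features, model$params, model$config)
  list(bag_repr = fw$z, weights = fw$a)
}

forward_image_channel <- function(X, p, cf) {
  Hpre <- sweep(X %*% p$We, 2, p$be, "+")
  H <- relu(Hpre)                                     # n x D
  Tt <- tanh(H %*% p$V)                               # n x A
  if (cf$gated_attention) {
    S <- sigmoid(H %*% p$U)
    G <- Tt * S
  } else {
    S <- NULL
    G <- Tt
  }
  s <- drop(G %*% p$w)                                # n
  a <- softmax(s)
  z <- drop(crossprod(H, a))                          # D
  list(X = X, Hpre = Hpre, H = H, Tt = Tt, S = S, G = G, s = s, a = a, z = z)
}

#' Encode a normalised biomarker vector
#'
#' Two-layer feedforward encoder of the 4 min-max-normalised markers into
#' the molecular representation.  Deterministic (no stochastic layer).
#'
#' @param biomarkers Numeric length-4 vector in `[0, 1]`
#'   (CEA, CA125, CA19-9, AFP order).
#' @param model An `mmil_model`.
#' @return Numeric vector of length `biomarker_repr_dim`.
#' @export
encode_biomarkers <- function(biomarkers, model) {
  if (length(biomarkers) != 4) {
    abort(sprintf("expected 4 biomarker values, got %d", length(biomarkers)))
  }
  forward_bio_channel(as.numeric(biomarkers), model$params)$m
}

forward_bio_channel <- function(xb, p) {
  h1pre <- drop(xb %*% p$Wb1) + p$bb1
  h1 <- relu(h1pre)
  m <- drop(h1 %*% p$Wb2) + p$bb2
  list(xb = xb, h1pre = h1pre, h1 = h1, m = m)
}

#' Gated Kronecker tensor fusion
#'
#' Each modality representation is rescaled by a sigmoid gate computed from
#' both modalities (`gate_m = sigmoid(A_m [z ; m] + b_m)`), a constant 1 is
#' appended to each gated vector so unimodal terms survive, and the fused
#' representation is the Kronecker product of the two augmented vectors —
#' length `(d1+1)(d2+1)`, laid out as `kron(c(z_gated, 1), c(m_gated, 1))`
#' so the image sub-block sits against the appended biomarker 1 and vice
#' versa.
#'
#' @param image_repr Length-d1 vector.
#' @param biomarker_repr Length-d2 vector.
#' @param model An `mmil_model` (gates read from its parameters; with
#'   `gate_enabled = FALSE` both gates are 1).
#' @return Fused numeric vector of length `(d1+1)(d2+1)`.
#' @export
gated_tensor_fuse <- function(image_repr, biomarker_repr, model) {
  assert_that(all(is.finite(image_repr)) && all(is.finite(biomarker_repr)),
              "representations must be finite")
  forward_fusion(as.numeric(image_repr), as.numeric(biomarker_repr),
                 model$params, model$config)$f
}

forward_fusion <- function(z, m, p, cf) {
  u <- c(z, m)
  if (cf$gate_enabled) {
    gz <- sigmoid(drop(u %*% p$Wgz) + p$bgz)
    gm <- sigmoid(drop(u %*% p$Wgm) + p$bgm)
  } else {
    gz <- rep(1, length(z))
    gm <- rep(1, length(m))
  }
  zt1 <- c(gz * z, 1)
  mt1 <- c(gm * m, 1)
  f <- as.vector(kronecker(zt1, mt1))
  list(u = u, gz = gz, gm = gm, zt1 = zt1, mt1 = mt1, f = f)
}

forward_head <- function(f, p, dropout_mask = NULL) {
  c1pre <- drop(f %*% p$Wc1) + p$bc1
  c1 <- relu(c1pre)
  c1d <- if (is.null(dropout_mask)) c1 else c1 * dropout_mask
  logits <- drop(c1d %*% p$Wc2) + p$bc2
  probs <- softmax(logits)
  list(f = f, c1pre = c1pre, c1 = c1, c1d = c1d,
       dropout_mask = dropout_mask, logits = logits, probs = probs)
}

# Full forward pass with intermediate caches (training use).
mmil_forward_cached <- function(model, features, biomarkers,
                                dropout_mask = NULL) {
  p <- model$params
  cf <- model$config
  img <- NULL
  if (cf$mode == "biomarker") {
    z <- p$img_const
  } else {
    img <- forward_image_channel(as.matrix(features), p, cf)
    z <- img$z
  }
  bio <- NULL
  if (cf$mode == "image") {
    m <- p$bio_const
  } else {
    if (length(biomarkers) != 4) abort("expected 4 biomarker values")
    bio <- forward_bio_channel(as.numeric(biomarkers), p)
    m <- bio$m
  }
  fus <- forward_fusion(z, m, p, cf)
  head <- forward_head(fus$f, p, dropout_mask)
  if (any(!is.finite(head$probs))) abort("NaN in classifier head output")
  list(img = img, bio = bio, fus = fus, head = head, z = z, m = m)
}

#' Predict one bag
#'
#' Runs the full forward pass in evaluation mode (no dropout) and returns
#' the bag-level prediction with its attention weights and intermediate
#' representations.
#'
#' @param model An `mmil_model`.
#' @param bag A `feature_bag` (feature selection already applied) or a plain
#'   instance matrix; ignored in biomarker-only mode (may be `NULL`).
#' @param biomarkers Normalised length-4 biomarker vector; ignored in
#'   image-only mode (may be `NULL`).
#' @return A `bag_prediction`: `class_probabilities` (simplex vector,
#'   strictly positive), `attention_weights` (simplex over instances, or
#'   `NULL` in biomarker-only mode), `image_repr`, `biomarker_repr`,
#'   `fused_repr`.
#' @export
mmil_predict_bag <- function(model, bag, biomarkers = NULL) {
  feats <- if (inherits(bag, "feature_bag")) bag$features else bag
  if (model$config$mode != "biomarker") {
    assert_that(!is.null(feats) && nrow(as.matrix(feats)) >= 1,
                "bag must be non-empty")
    if (ncol(as.matrix(feats)) != model$config$input_dim) {
      abort(sprintf("bag has %d feature dims but the model expects %d",
                    ncol(as.matrix(feats)), model$config$input_dim))
    }
  }
  fw <- mmil_forward_cached(model, feats, biomarkers)
  structure(list(
    bag_id = if (inherits(bag, "feature_bag")) bag$bag_id else NA_character_,
    class_probabilities = fw$head$probs,
    attention_weights = if (is.null(fw$img)) NULL else fw$img$a,
    image_repr = fw$z,
    biomarker_repr = fw$m,
    fused_repr = fw$fus$f
  ), class = "bag_prediction")
}

#' Categorical cross-entropy loss
#'
#' `L = -(1/N) sum_i sum_c delta(y_i = c) log P(y_i = c)`.  Probabilities of
#' the true class equal to zero are clamped at 1e-12 with a warning rather
#' than producing `-Inf`.
#'
#' @param probs N x C matrix of predicted probabilities (rows on the
#'   simplex), or a single length-C vector.
#' @param labels Integer vector of true classes in `0 .. C-1`.
#' @return Scalar loss, `>= 0`; 0 iff every true-class probability is 1.
#' @export
#' @examples
#' cross_entropy_loss(matrix(c(0.5, 0.5), 1), 0)  # log(2)
cross_entropy_loss <- function(probs, labels) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  n <- nrow(probs)
  assert_that(length(labels) == n, "one label per probability row required")
  assert_that(all(labels >= 0 & labels < ncol(probs)),
              "labels must lie in [0, C)")
  p_true <- probs[cbind(seq_len(n), labels + 1L)]
  if (any(p_true <= 0)) {
    warn("true-class probability of 0 clamped at 1e-12")
    p_true <- pmax(p_true, 1e-12)
  }
  -mean(log(p_true))
}

# Gradient of the mean cross-entropy w.r.t. the logits of one sample:
# (softmax(logits) - onehot(y)) / N.
softmax_ce_grad_logits <- function(probs, label, n_batch = 1) {
  g <- probs
  g[label + 1L] <- g[label + 1L] - 1
  g / n_batch
}

# Backward pass for one bag; returns the parameter-gradient list (same
# shapes as params).  `fw` is the cache from mmil_forward_cached();
# `dlogits` the upstream gradient at the logits.
mmil_backward <- function(model, fw, dlogits) {
  p <- model$params
  cf <- model$config
  gr <- lapply(p, function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x)))

  head <- fw$head
  gr$Wc2 <- outer(head$c1d, dlogits)
  gr$bc2 <- dlogits
  dc1d <- drop(p$Wc2 %*% dlogits)
  dc1 <- if (is.null(head$dropout_mask)) dc1d else dc1d * head$dropout_mask
  dc1pre <- dc1 * (head$c1pre > 0)
  gr$Wc1 <- outer(head$f, dc1pre)
  gr$bc1 <- dc1pre
  df <- drop(p$Wc1 %*% dc1pre)

  # fusion: f = kron(zt1, mt1); index (i,j) -> (i-1)*(d2+1)+j
  fus <- fw$fus
  d1p <- length(fus$zt1)
  d2p <- length(fus$mt1)
  Dfm <- matrix(df, nrow = d2p, ncol = d1p)   # column i holds block of zt1_i
  dzt1 <- drop(crossprod(Dfm, fus$mt1))       # length d1+1
  dmt1 <- drop(Dfm %*% fus$zt1)               # length d2+1
  d1 <- d1p - 1
  d2 <- d2p - 1
  dzt <- dzt1[seq_len(d1)]
  dmt <- dmt1[seq_len(d2)]
  z <- fw$z
  m <- fw$m
  if (cf$gate_enabled) {
    dgz <- dzt * z
    dgm <- dmt * m
    dz <- dzt * fus$gz
    dm <- dmt * fus$gm
    dpre_gz <- dgz * fus$gz * (1 - fus$gz)
    dpre_gm <- dgm * fus$gm * (1 - fus$gm)
    gr$Wgz <- outer(fus$u, dpre_gz)
    gr$bgz <- dpre_gz
    gr$Wgm <- outer(fus$u, dpre_gm)
    gr$bgm <- dpre_gm
    du <- drop(p$Wgz %*% dpre_gz) + drop(p$Wgm %*% dpre_gm)
    dz <- dz + du[seq_len(d1)]
    dm <- dm + du[d1 + seq_len(d2)]
  } else {
    dz <- dzt
    dm <- dmt
  }

  # biomarker channel
  if (cf$mode == "image") {
    gr$bio_const <- dm
  } else {
    bio <- fw$bio
    gr$Wb2 <- outer(bio$h1, dm)
    gr$bb2 <- dm
    dh1 <- drop(p$Wb2 %*% dm)
    dh1pre <- dh1 * (bio$h1pre > 0)
    gr$Wb1 <- outer(bio$xb, dh1pre)
    gr$bb1 <- dh1pre
  }

  # image channel
  if (cf$mode == "biomarker") {
    gr$img_const <- dz
  } else {
    img <- fw$img
    H <- img$H
    a <- img$a
    dH <- a %o% dz                             # from z = H'a
    da <- drop(H %*% dz)
    ds <- a * (da - sum(a * da))               # softmax backward
    dG <- ds %o% p$w
    gr$w <- drop(crossprod(img$G, ds))
    if (cf$gated_attention) {
      dT <- dG * img$S
      dS <- dG * img$Tt
      dpreS <- dS * img$S * (1 - img$S)
      gr$U <- crossprod(H, dpreS)
      dH <- dH + dpreS %*% t(p$U)
    } else {
      dT <- dG
    }
    dpreT <- dT * (1 - img$Tt^2)
    gr$V <- crossprod(H, dpreT)
    dH <- dH + dpreT %*% t(p$V)
    dHpre <- dH * (img$Hpre > 0)
    gr$We <- crossprod(img$X, dHpre)
    gr$be <- colSums(dHpre)
  }
  gr
}
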