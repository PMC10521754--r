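#' Stratified k-fold split plan
#'
#' Partitions bags into k folds, keeping per-fold positive counts within one
#' of proportionality.  With fewer members of a class than folds the split
#' degrades gracefully (some folds get none of that class) with a warning.
#'
#' @param labels Integer 0/1 vector.
#' @param k Fold count, `2 <= k <= n`.
#' @param seed Seed; the plan is deterministic given it.
#' @param stratified Stratify by class, default TRUE.
#' @return A `split_plan` tibble with columns `index`, `label`, `fold`.
#' @export
stratified_kfold <- function(labels, k, seed = 1, stratified = TRUE) {
  n <- length(labels)
  assert_that(is_count(k) && k >= 2, "`k` must be a count >= 2")
  if (k > n) abort(sprintf("k = %d exceeds the number of bags (%d)", k, n))
  fold <- integer(n)
  with_seed(seed, {
    if (stratified) {
      if (any(table(labels) < k)) {
        warn("a class has fewer members than folds; stratification is partial")
      }
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })
  plan <- tibble::tibble(index = seq_len(n), label = labels, fold = fold)
  class(plan) <- c("split_plan", class(plan))
  plan
}

#' Inverse-class-frequency sampling weights
#'
#' Weighted-random-sampler weights addressing class imbalance: each bag gets
#' weight proportional to `1 / (class frequency)`, so sampling with
#' replacement draws each class with expected probability 1/2.
#'
#' @param labels Integer 0/1 vector containing both classes.
#' @return Numeric weights summing to 1.
#' @export
make_sampling_weights <- function(labels) {
  counts <- table(factor(labels, levels = sort(unique(labels))))
  if (length(counts) < 2) {
    abort("training set contains a single class; cannot balance sampling")
  }
  w <- 1 / as.numeric(counts[as.character(labels)])
  w / sum(w)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the MMIL network
#'
#' Adam optimisation of the categorical cross-entropy with a weighted random
#' sampler (inverse class frequency) building each batch.  Deterministic
#' given `seed`.  Pass `fine_tune_from` to continue from an existing model's
#' weights (the transfer protocol for adapting to a new centre).
#'
#' @param bags List of `feature_bag`s with selection already applied.
#' @param biomarkers n x 4 matrix of normalised biomarkers, rows aligned
#'   with `bags` (ignored in image-only mode; may be NULL then).
#' @param labels Integer 0/1 vector aligned with `bags`.
#' @param config An [mmil_config()]; ignored when `fine_tune_from` is given.
#' @param epochs Training epochs, default 100.  The multimodal network is
#'   small but the fused layer is slow to converge; monitor
#'   `training_log` and extend if the loss has not plateaued.
#' @param lr Adam learning rate, default 5e-3.
#' @param batch_size Bags per batch, default 8.
#' @param seed Seed for sampling, dropout and initialisation.
#' @param fine_tune_from Optional `mmil_model` to start from.
#' @return A trained `mmil_model`; `$training_log` is a tibble
#'   (epoch, loss) and `$trained_on` records the bag ids seen.
#' @export
mmil_train <- function(bags, biomarkers, labels, config = NULL,
                       epochs = 100, lr = 5e-3, batch_size = 8, seed = 1,
                       fine_tune_from = NULL) {
  n <- length(bags)
  assert_that(length(labels) == n, "one label per bag required")
  assert_that(is_count(epochs) && is_count(batch_size), "bad hyperparameters")
  assert_that(lr > 0, "`lr` must be positive")
  if (!is.null(fine_tune_from)) {
    assert_that(inherits(fine_tune_from, "mmil_model"),
                "`fine_tune_from` must be an mmil_model")
    model <- fine_tune_from
  } else {
    assert_that(inherits(config, "mmil_config"), "`config` required")
    model <- mmil_init(config)
  }
  cf <- model$config
  feats <- lapply(bags, function(b) {
    m <- if (inherits(b, "feature_bag")) b$features else as.matrix(b)
    if (cf$mode != "biomarker" && ncol(m) != cf$input_dim) {
      abort(sprintf("bag has %d dims; model expects %d", ncol(m), cf$input_dim))
    }
    m
  })
  if (cf$mode != "image") {
    biomarkers <- as.matrix(biomarkers)
    assert_that(nrow(biomarkers) == n && ncol(biomarkers) == 4,
                "`biomarkers` must be an n x 4 matrix")
  }
  weights <- make_sampling_weights(labels)
  params <- model$params
  state <- adam_init(params)
  steps <- ceiling(n / batch_size)
  log <- numeric(epochs)

  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ep_loss <- 0
      for (st in seq_len(steps)) {
        idx <- sample.int(n, batch_size, replace = TRUE, prob = weights)
        grads <- NULL
        batch_loss <- 0
        for (i in idx) {
          mask <- if (cf$dropout > 0) {
            (runif(cf$classifier_hidden_dim) >= cf$dropout) / (1 - cf$dropout)
          } else {
            NULL
          }
          tmp_model <- model
          tmp_model$params <- params
          fw <- mmil_forward_cached(tmp_model, feats[[i]],
                                    if (cf$mode == "image") NULL else biomarkers[i, ],
                                    dropout_mask = mask)
          batch_loss <- batch_loss +
            cross_entropy_loss(fw$head$probs, labels[i]) / length(idx)
          dlogits <- softmax_ce_grad_logits(fw$head$probs, labels[i],
                                            n_batch = length(idx))
          g <- mmil_backward(tmp_model, fw, dlogits)
          grads <- if (is.null(grads)) g else {
            purrr::map2(grads, g, `+`)
          }
        }
        if (!is.finite(batch_loss)) {
          abort(sprintf("NaN loss at epoch %d step %d; aborting", ep, st))
        }
        upd <- adam_step(params, grads, state, lr)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + batch_loss / steps
      }
      log[ep] <- ep_loss
    }
  })
  model$params <- params
  model$training_log <- tibble::tibble(epoch = seq_len(epochs), loss = log)
  model$trained_on <- union(model$trained_on,
                            purrr::map_chr(bags, function(b) {
                              if (inherits(b, "feature_bag")) b$bag_id else NA_character_
                            }))
  model
}

#' Fit the full MMIL pipeline on a training cohort
#'
#' Fits, in order and on the training cohort only: the chained-equation PMM
#' imputer, min-max normalisation, the MMD feature-dimension selection, and
#' the MMIL network.  Every fitted transform records the patient ids it saw,
#' which [leakage_audit()] checks against held-out ids.
#'
#' @param bags List of `feature_bag`s (raw backbone dimensions).
#' @param biomarkers Tibble with `patient_id` and the four marker columns
#'   (missing values allowed).
#' @param labels Integer 0/1 vector aligned with `bags`.
#' @param mode `"multimodal"`, `"image"` or `"biomarker"` (ablations).
#' @param n_keep Dimensions kept by selection; default half.
#' @param epochs,lr,batch_size,seed Passed to [mmil_train()].
#' @param ... Further arguments to [mmil_config()].
#' @return An `mmil_pipeline`.
#' @export
fit_mmil <- function(bags, biomarkers, labels,
                     mode = "multimodal", n_keep = NULL,
                     epochs = 100, lr = 5e-3, batch_size = 8, seed = 1, ...) {
  n <- length(bags)
  ids <- purrr::map_chr(bags, "bag_id")
  bm <- dplyr::left_join(tibble::tibble(patient_id = ids),
                         biomarkers, by = "patient_id")
  imputer <- fit_imputer(bm, seed = seed)
  bm_complete <- imputer$completed
  minmax <- fit_minmax(bm_complete)
  attr(minmax, "fitted_on") <- ids
  bm_norm <- apply_minmax(bm_complete, minmax)

  pos <- bags[labels == 1]
  neg <- bags[labels == 0]
  selection <- select_feature_dims(pos, neg, n_keep = n_keep)
  selection$fitted_on <- ids
  sel_bags <- lapply(bags, apply_selection, result = selection)

  config <- mmil_config(input_dim = selection$n_keep, mode = mode,
                        seed = seed, ...)
  model <- mmil_train(sel_bags,
                      as.matrix(bm_norm[, MARKERS]),
                      labels, config,
                      epochs = epochs, lr = lr, batch_size = batch_size,
                      seed = seed)
  model$selection_fingerprint <- fingerprint(selection$kept_dims)
  model$backbone_fingerprint <- bags[[1]]$backbone
  structure(list(imputer = imputer, minmax = minmax, selection = selection,
                 model = model, mode = mode, train_ids = ids),
            class = "mmil_pipeline")
}

#' @export
print.mmil_pipeline <- function(x, ...) {
  cat(sprintf("<mmil_pipeline> mode = %s, %d training bags, %d/%d dims kept\n",
              x$mode, length(x$train_ids), x$selection$n_keep,
              x$selection$feature_dim))
  invisible(x)
}

#' Predict LNM probabilities for a cohort
#'
#' Applies the pipeline's frozen transforms (imputer, normalisation,
#' selection) and the trained network to new bags.
#'
#' @param object An `mmil_pipeline`.
#' @param bags List of `feature_bag`s (raw backbone dimensions).
#' @param biomarkers Tibble with `patient_id` + marker columns.
#' @param ... Unused.
#' @return Tibble with `bag_id`, `p_pos` (probability of LNM+), `p_neg`.
#' @export
predict.mmil_pipeline <- function(object, bags, biomarkers = NULL, ...) {
  ids <- purrr::map_chr(bags, "bag_id")
  if (object$mode != "image") {
    bm <- dplyr::left_join(tibble::tibble(patient_id = ids), biomarkers,
                           by = "patient_id")
    bm <- impute_newdata(object$imputer, bm)
    bm <- apply_minmax(bm, object$minmax)
    bmat <- as.matrix(bm[, MARKERS])
  }
  p_pos <- vapply(seq_along(bags), function(i) {
    sel <- apply_selection(bags[[i]], object$selection)
    pred <- mmil_predict_bag(object$model, sel,
                             if (object$mode == "image") NULL else bmat[i, ])
    pred$class_probabilities[2]
  }, numeric(1))
  tibble::tibble(bag_id = ids, p_pos = p_pos, p_neg = 1 - p_pos)
}

#' Fine-tune a fitted pipeline on a new cohort
#'
#' Continues network training from the pipeline's weights on bags from a new
#' centre, keeping the original imputer, normalisation and selection frozen
#' (the transfer protocol: a model developed on one centre is adapted with a
#' modest number of epochs on locally collected cases).
#'
#' @param pipeline A fitted `mmil_pipeline`.
#' @param bags,biomarkers,labels The fine-tuning cohort.
#' @param epochs Fine-tuning epochs, default 5.
#' @param lr Learning rate, default 1e-3 (lower than from-scratch training).
#' @param seed Seed.
#' @return The pipeline with updated model weights.
#' @export
fine_tune <- function(pipeline, bags, biomarkers, labels,
                      epochs = 5, lr = 1e-3, seed = 1) {
  ids <- purrr::map_chr(bags, "bag_id")
  bm <- dplyr::left_join(tibble::tibble(patient_id = ids), biomarkers,
                         by = "patient_id")
  bm <- impute_newdata(pipeline$imputer, bm)
  bm <- apply_minmax(bm, pipeline$minmax)
  sel_bags <- lapply(bags, apply_selection, result = pipeline$selection)
  model <- mmil_train(sel_bags, as.matrix(bm[, MARKERS]), labels,
                      epochs = epochs, lr = lr, seed = seed,
                      fine_tune_from = pipeline$model)
  pipeline$model <- model
  pipeline
}

#' Check fitted transforms never saw held-out bags
#'
#' @param pipeline An `mmil_pipeline`.
#' @param test_ids Character ids of held-out bags.
#' @return `TRUE` invisibly; errors naming the leaking transform otherwise.
#' @export
leakage_audit <- function(pipeline, test_ids) {
  seen <- list(
    imputer = pipeline$imputer$fitted_on,
    minmax = attr(pipeline$minmax, "fitted_on"),
    selection = pipeline$selection$fitted_on,
    model = pipeline$model$trained_on
  )
  for (nm in names(seen)) {
    leak <- intersect(seen[[nm]], test_ids)
    if (length(leak)) {
      abort(sprintf("transform '%s' was fitted on held-out bags: %s",
                    nm, paste(head(leak, 3), collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' Cross-validated evaluation of the MMIL pipeline
#'
#' Stratified k-fold protocol: for each fold, all transforms and the network
#' are fitted on the training folds only and predictions made on the test
#' fold; a leakage audit runs per fold.
#'
#' @param bags List of `feature_bag`s.
#' @param biomarkers Tibble with `patient_id` + markers.
#' @param labels Integer 0/1 vector.
#' @param k Folds.
#' @param seed Seed controlling the split and all fold fits.
#' @param ... Passed to [fit_mmil()].
#' @return An `mmil_cv`: list with `predictions` tibble
#'   (bag_id, fold, label, p_pos) and the split plan.
#' @export
cross_validate <- function(bags, biomarkers, labels, k = 6, seed = 1, ...) {
  plan <- stratified_kfold(labels, k, seed = seed)
  ids <- purrr::map_chr(bags, "bag_id")
  preds <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- plan$index[plan$fold != f]
    te <- plan$index[plan$fold == f]
    fit <- fit_mmil(bags[tr], biomarkers, labels[tr], seed = seed + f, ...)
    leakage_audit(fit, ids[te])
    p <- predict(fit, bags[te], biomarkers)
    tibble::tibble(bag_id = p$bag_id, fold = f, label = labels[te],
                   p_pos = p$p_pos)
  })
  structure(list(predictions = preds, plan = plan, k = k, seed = seed),
            class = "mmil_cv")
}
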