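# The mixed attention ensemble: base-model abstraction, weighted fusion and
# the training orchestration that produces a fitted `mae` object.

#' Specify a base model
#'
#' @param name Identifier used in reports.
#' @param backbone One of the bundled small CNN variants (`"tiny_cnn"`,
#'   `"tiny_cnn_wide"`, `"tiny_cnn_deep"`). The pretrained torch backbones of
#'   the original design (`"resnet18"`, `"mobilenetv3_small"`, `"googlenet"`,
#'   `"efficientnet_b0"`) are accepted here for completeness but raise an
#'   informative error at build time: they need a deep-learning runtime and
#'   published weights that this package does not bundle.
#' @param use_csae Insert the CSAE attention operator before the classifier?
#' @param num_classes Number of classes (>= 2, default 6).
#' @param pretrained Load published pretrained weights (only meaningful for
#'   the torch backbones; always `FALSE` for the tiny variants).
#' @param csae_kernel Odd kernel size of both CSAE 1D convolutions.
#' @return An object of class `"base_model_spec"`.
#' @export
base_model_spec <- function(name, backbone = "tiny_cnn", use_csae = TRUE,
                            num_classes = 6L, pretrained = FALSE,
                            csae_kernel = 3L) {
  known <- c(names(tiny_backbones), pretrained_backbones)
  if (!backbone %in% known) {
    stop(sprintf("unknown backbone '%s'; expected one of: %s", backbone,
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  stopifnot(is_scalar_number(num_classes), num_classes >= 2,
            is_scalar_number(csae_kernel), csae_kernel >= 1)
  if (as.integer(csae_kernel) %% 2L == 0L) {
    stop("`csae_kernel` must be odd", call. = FALSE)
  }
  structure(
    list(name = as.character(name), backbone = backbone,
         use_csae = isTRUE(use_csae), num_classes = as.integer(num_classes),
         pretrained = isTRUE(pretrained),
         csae_kernel = as.integer(csae_kernel)),
    class = "base_model_spec"
  )
}

build_base_model <- function(spec, seed) {
  stopifnot(inherits(spec, "base_model_spec"))
  net_init(spec$backbone, spec$num_classes, spec$use_csae,
           csae_kernel = spec$csae_kernel, seed = seed)
}

#' Class probabilities from one base model
#'
#' Runs backbone -> (CSAE) -> global average pool -> softmax classifier on a
#' batch of images.
#'
#' @param model A parameter list from a fitted [mae()] object
#'   (`fit$models[[k]]`), or a `base_model_spec` (then a freshly initialised,
#'   untrained model is used with `init_seed`).
#' @param images A list of H x W x 3 arrays on the 0..255 scale, all square
#'   and of equal size (at least 32 pixels).
#' @param init_seed Seed for initialisation when `model` is a spec.
#' @return An n x K matrix of softmax probability rows.
#' @export
forward_base <- function(model, images, init_seed = 1L) {
  if (inherits(model, "base_model_spec")) {
    model <- build_base_model(model, seed = init_seed)
  }
  if (is.array(images)) images <- list(images)
  inputs <- lapply(images, function(img) {
    stop_if_not_image(img)
    if (any(dim(img)[1:2] < 32L)) stop("images must be at least 32x32")
    prepare_input(img)
  })
  net_predict_probs(model, inputs)
}

#' Fuse per-model probabilities with ensemble weights
#'
#' `fused = sum_i w_i * probs_i`, argmax with lowest-index tie-break.
#'
#' @param per_model_probs An n x K matrix of per-model probability rows (one
#'   row per base model, for a single sample), or a list of such rows.
#' @param w Weight vector of length n.
#' @return A list of class `"ensemble_prediction"` with `per_model_probs`,
#'   `fused_probs` (length-K simplex vector) and `predicted_class` (index).
#' @export
#' @examples
#' p <- rbind(c(0.8, 0.2), c(0.2, 0.8))
#' fuse_predictions(p, c(0.5, 0.5))$predicted_class
fuse_predictions <- function(per_model_probs, w) {
  if (is.list(per_model_probs)) per_model_probs <- do.call(rbind, per_model_probs)
  stopifnot(is.matrix(per_model_probs))
  w <- as_weight_vector(w)
  if (nrow(per_model_probs) != length(w)) {
    stop("number of probability rows must match the weight length",
         call. = FALSE)
  }
  fused <- as.vector(t(per_model_probs) %*% w)
  structure(
    list(per_model_probs = per_model_probs, fused_probs = fused,
         predicted_class = argmax_first(fused)),
    class = "ensemble_prediction"
  )
}

# Batched fusion: `prob_list` holds one N x K matrix per model; returns the
# fused N x K matrix.
fuse_prob_matrices <- function(prob_list, w) {
  w <- as_weight_vector(w)
  stopifnot(length(prob_list) == length(w))
  Reduce(`+`, Map(function(P, wi) wi * P, prob_list, w))
}

ensemble_accuracy <- function(prob_list, w, y) {
  fused <- fuse_prob_matrices(prob_list, w)
  mean(max.col(fused, ties.method = "first") == y)
}

load_split_images <- function(manifest, split, image_size, images = NULL) {
  rows <- manifest[manifest$split == split, , drop = FALSE]
  if (nrow(rows) == 0L) stop(sprintf("empty %s split", split), call. = FALSE)
  imgs <- lapply(rows$path, function(p) {
    img <- if (!is.null(images) && !is.null(images[[p]])) {
      images[[p]]
    } else {
      read_image_png(p)
    }
    if (any(dim(img)[1:2] != image_size)) img <- resize_image(img, image_size)
    img
  })
  list(inputs = lapply(imgs, prepare_input),
       y = match(rows$label, hrem_classes()),
       labels = rows$label, paths = rows$path)
}

#' Fit a mixed attention ensemble
#'
#' Trains each base model independently (cross-entropy loss, minibatch Adam),
#' freezes them, then derives the ensemble weights on the validation split:
#' the four individual-voting passes and their exponential-accuracy blend
#' `W_i`, the group search `W_g`, and the mixed weight
#' `W = beta1 * W_g + (1 - beta1) * W_i` (or the weights dictated by
#' `voting_mode`). The test split is touched exactly once, at the end.
#'
#' @param manifest A split manifest ([stratified_split()]); augmented
#'   training rows are used as-is.
#' @param specs List of [base_model_spec()] objects (>= 2).
#' @param config An [mae_config()].
#' @param images Optional named list mapping manifest paths to in-memory
#'   H x W x 3 arrays (bypasses PNG reading).
#' @return An object of class `"mae"` with components `models` (trained
#'   parameters), `weights` (`per_primary` W_1..W_n, `alphas`, `individual`
#'   W_i, `group` W_g, `final` W), `history` (per-epoch validation accuracy
#'   per model), `val_accuracy`, `test_metrics`, `confusion`, `specs`,
#'   `config`.
#' @seealso [predict.mae()], [summary.mae()], [beta_sweep()]
#' @export
mae <- function(manifest, specs, config = mae_config(), images = NULL) {
  manifest <- as_manifest(manifest)
  stopifnot(inherits(config, "mae_config"))
  if (any(is.na(manifest$split))) {
    stop("manifest must have train/val/test splits", call. = FALSE)
  }
  if (!is.list(specs) || length(specs) < 2L) {
    stop("need at least two base model specs", call. = FALSE)
  }
  lapply(specs, function(s) stopifnot(inherits(s, "base_model_spec")))
  n <- length(specs)
  seed <- config$seed

  train <- load_split_images(manifest, "train", config$image_size, images)
  val <- load_split_images(manifest, "val", config$image_size, images)
  test <- load_split_images(manifest, "test", config$image_size, images)

  models <- vector("list", n)
  history <- matrix(NA_real_, config$epochs, n,
                    dimnames = list(NULL, vapply(specs, `[[`, "", "name")))
  val_probs <- vector("list", n)
  test_probs <- vector("list", n)
  for (k in seq_len(n)) {
    init <- build_base_model(specs[[k]],
                             seed = derive_seed(seed, paste("init", k)))
    fit_k <- net_train(init, train$inputs, train$y, val$inputs, val$y,
                       epochs = config$epochs, batch_size = config$batch_size,
                       lr = config$learning_rate,
                       seed = derive_seed(seed, paste("train", k)))
    models[[k]] <- fit_k$params
    history[, k] <- fit_k$val_acc
    val_probs[[k]] <- net_predict_probs(fit_k$params, val$inputs)
    test_probs[[k]] <- net_predict_probs(fit_k$params, test$inputs)
  }
  val_acc_final <- vapply(seq_len(n), function(k) {
    mean(max.col(val_probs[[k]], ties.method = "first") == val$y)
  }, numeric(1))

  scorer <- function(w) ensemble_accuracy(val_probs, w, val$y)

  per_primary <- lapply(seq_len(n), function(k) {
    fit_individual_weight_set(k, history, scorer = scorer)
  })
  alphas <- accuracy_coefficients(val_acc_final,
                                  temperature = config$temperature)
  w_individual <- combine_individual(per_primary, alphas)
  w_group <- group_search(history, scorer, restarts = config$restarts,
                          seed = derive_seed(seed, "group_search"))
  w_final <- switch(config$voting_mode,
    average = rep(1 / n, n),
    standard = as_weight_vector(val_acc_final, normalize = TRUE),
    individual = w_individual,
    group = as_weight_vector(as.vector(w_group)),
    mixed = mixed_combine(as.vector(w_group), w_individual,
                          beta1 = config$beta1)
  )

  fused_test <- fuse_prob_matrices(test_probs, w_final)
  test_pred <- max.col(fused_test, ties.method = "first")
  cm <- build_confusion(test$y, test_pred, labels = hrem_classes())
  metrics <- metrics_from_confusion(cm)

  structure(
    list(
      models = models,
      specs = specs,
      config = config,
      weights = list(
        per_primary = lapply(per_primary, as.numeric),
        alphas = alphas,
        individual = w_individual,
        group = as.vector(w_group),
        final = as.vector(w_final)
      ),
      history = history,
      val_accuracy = val_acc_final,
      val_probs = val_probs,
      test_probs = test_probs,
      test_y = test$y,
      val_y = val$y,
      confusion = cm,
      test_metrics = metrics
    ),
    class = "mae"
  )
}

#' @export
print.mae <- function(x, ...) {
  cat("Mixed attention ensemble\n")
  cat(sprintf("  base models: %s\n",
              paste(vapply(x$specs, `[[`, "", "name"), collapse = ", ")))
  cat(sprintf("  voting mode: %s (beta1 = %g)\n",
              x$config$voting_mode, x$config$beta1))
  cat(sprintf("  final weights W: (%s)\n",
              paste(sprintf("%.4f", x$weights$final), collapse = ", ")))
  cat(sprintf("  test accuracy: %.4f on %d samples\n",
              x$test_metrics$overall$accuracy, x$test_metrics$overall$n))
  invisible(x)
}

#' @export
summary.mae <- function(object, ...) {
  cat("Mixed attention ensemble\n\n")
  info <- data.frame(
    model = vapply(object$specs, `[[`, "", "name"),
    backbone = vapply(object$specs, `[[`, "", "backbone"),
    csae = vapply(object$specs, function(s) s$use_csae, logical(1)),
    val_accuracy = round(object$val_accuracy, 4),
    alpha = round(object$weights$alphas, 4),
    W_individual = round(object$weights$individual, 4),
    W_group = round(object$weights$group, 4),
    W = round(object$weights$final, 4)
  )
  print(info, row.names = FALSE)
  cat("\nTest performance:\n")
  print(object$test_metrics)
  invisible(object)
}

#' Ensemble weights of a fitted model
#'
#' @param object A fitted [mae()] object.
#' @param ... Unused.
#' @return The final mixed weight vector W.
#' @export
coef.mae <- function(object, ...) {
  setNames(object$weights$final, vapply(object$specs, `[[`, "", "name"))
}

#' Predict motility classes for new images
#'
#' @param object A fitted [mae()] object.
#' @param newdata A list of H x W x 3 arrays (0..255), a single array, or a
#'   manifest data.frame whose `path` column points at PNGs.
#' @param type `"class"` for labels, `"prob"` for the fused probability
#'   matrix.
#' @param ... Unused.
#' @return Factor of predicted labels, or an N x 6 probability matrix.
#' @export
predict.mae <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    newdata <- lapply(newdata$path, read_image_png)
  }
  if (is.array(newdata)) newdata <- list(newdata)
  newdata <- lapply(newdata, function(img) {
    if (any(dim(img)[1:2] != object$config$image_size)) {
      img <- resize_image(img, object$config$image_size)
    }
    img
  })
  prob_list <- lapply(object$models, forward_base, images = newdata)
  fused <- fuse_prob_matrices(prob_list, object$weights$final)
  colnames(fused) <- hrem_classes()
  if (type == "prob") return(fused)
  factor(hrem_classes()[max.col(fused, ties.method = "first")],
         levels = hrem_classes())
}

#' Plot per-epoch validation accuracy of the base models
#'
#' @param x A fitted [mae()] object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mae <- function(x, ...) {
  matplot(x$history, type = "l", lty = 1, lwd = 2,
          xlab = "epoch", ylab = "validation accuracy", ...)
  legend("bottomright", colnames(x$history), lty = 1, lwd = 2,
         col = seq_len(ncol(x$history)), bty = "n")
  invisible(x)
}

#' Parameter counts of the ensemble
#'
#' Exact integer parameter counts per model and in total, with serialised
#' sizes assuming 4 bytes per parameter. The CSAE operator adds exactly two
#' bias-free 1D filters of the configured kernel size (2k parameters) per
#' model.
#'
#' @param x A fitted [mae()] object or a list of [base_model_spec()]s.
#' @param init_seed Seed used to materialise models from bare specs.
#' @return A data.frame with columns `model`, `parameters`, `size_mb`, plus a
#'   total row.
#' @export
count_parameters <- function(x, init_seed = 1L) {
  models <- if (inherits(x, "mae")) {
    setNames(x$models, vapply(x$specs, `[[`, "", "name"))
  } else {
    stopifnot(is.list(x))
    setNames(
      lapply(seq_along(x), function(k) build_base_model(x[[k]], init_seed)),
      vapply(x, `[[`, "", "name")
    )
  }
  counts <- vapply(models, net_param_count, integer(1))
  out <- data.frame(
    model = c(names(models), "total"),
    parameters = c(counts, sum(counts)),
    size_mb = c(counts, sum(counts)) * 4 / 2^20,
    stringsAsFactors = FALSE
  )
  out
}
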