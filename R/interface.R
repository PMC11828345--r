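# Configuration, config-driven runs, beta sweeps and run reports.

#' Run configuration
#'
#' Defaults mirror the original training recipe (100 epochs, batch size 16,
#' learning rate 0.001, cross-entropy + Adam, beta1 = 0.2); tests and the
#' bundled examples scale `epochs`/`image_size` down for CPU runs.
#'
#' @param seed Master seed; every random stream (splits, augmentation,
#'   initialisation, weight search) uses a named sub-seed derived from it.
#' @param epochs,batch_size,learning_rate Training hyper-parameters.
#' @param beta1 Group-voting coefficient of the mixed blend, in \[0, 1\].
#' @param voting_mode One of `"average"` (uniform 1/n), `"standard"`
#'   (weights proportional to validation accuracy), `"individual"`,
#'   `"group"`, `"mixed"`.
#' @param use_csae Insert the CSAE operator in every base model.
#' @param image_size Square input side length fed to the backbones (>= 32).
#' @param restarts Random restarts of the group-voting search.
#' @param temperature Exponent scale of the accuracy coefficients.
#' @return An object of class `"mae_config"`.
#' @export
mae_config <- function(seed = 1L, epochs = 100L, batch_size = 16L,
                       learning_rate = 0.001, beta1 = 0.2,
                       voting_mode = c("mixed", "average", "standard",
                                       "individual", "group"),
                       use_csae = TRUE, image_size = 32L, restarts = 32L,
                       temperature = 1) {
  voting_mode <- match.arg(voting_mode)
  stopifnot(
    is_scalar_number(seed),
    is_scalar_number(epochs), epochs >= 1,
    is_scalar_number(batch_size), batch_size >= 1,
    is_scalar_number(learning_rate), learning_rate > 0,
    is_scalar_number(image_size), image_size >= 32,
    is_scalar_number(restarts), restarts >= 1,
    is_scalar_number(temperature), temperature > 0
  )
  if (!is_scalar_number(beta1) || beta1 < 0 || beta1 > 1) {
    stop("`beta1` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), learning_rate = learning_rate,
         beta1 = beta1, voting_mode = voting_mode, use_csae = isTRUE(use_csae),
         image_size = as.integer(image_size), restarts = as.integer(restarts),
         temperature = temperature),
    class = "mae_config"
  )
}

known_config_keys <- c(
  "seed", "epochs", "batch_size", "learning_rate", "beta1", "voting_mode",
  "use_csae", "image_size", "restarts", "temperature", "backbones",
  "data", "augment", "augmentation", "out_dir"
)

#' Run the full pipeline from a configuration file
#'
#' Reads a YAML (or JSON) configuration, prepares the data (synthetic
#' generation and/or split and optional augmentation), fits the ensemble with
#' [mae()] and evaluates it; writes a self-contained JSON report (config
#' echo, run id, all weight vectors, per-epoch accuracies, confusion matrix
#' and metrics) when `out_dir` is set. Unknown configuration keys are an
#' error, listed by name. Two runs with the same config are identical.
#'
#' Config keys: the [mae_config()] fields, plus `backbones` (list of entries
#' with `name`, `backbone`, optional `use_csae`), `data` (either
#' `synthetic: {n_per_class, dir, noise_level}` or `manifest: path`; a
#' manifest without splits is split with the master seed), `augment`
#' (logical), `augmentation` ([augmentation_policy()] overrides) and
#' `out_dir`.
#'
#' @param path Path to the YAML/JSON config file, or an equivalent named
#'   list.
#' @return The fitted `mae` object, with the report list attached as
#'   attribute `"report"`.
#' @export
run_from_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a mapping", call. = FALSE)
  unknown <- setdiff(names(cfg), known_config_keys)
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  base_keys <- intersect(names(cfg),
                         setdiff(known_config_keys,
                                 c("backbones", "data", "augment",
                                   "augmentation", "out_dir")))
  config <- do.call(mae_config, cfg[base_keys])

  if (is.null(cfg$data)) {
    stop("no dataset: provide `data: synthetic: ...` or `data: manifest: ...`",
         call. = FALSE)
  }
  if (!is.null(cfg$data$synthetic)) {
    sy <- cfg$data$synthetic
    dir <- sy$dir
    if (is.null(dir)) dir <- tempfile("hrem_synth_")
    manifest <- hrem_dataset(
      n_per_class = sy$n_per_class %||% 20L,
      seed = derive_seed(config$seed, "synthetic"),
      dir = dir,
      image_size = config$image_size,
      noise_level = sy$noise_level %||% 0.05
    )
  } else if (!is.null(cfg$data$manifest)) {
    manifest <- read_manifest(cfg$data$manifest)
  } else {
    stop("`data` must contain either `synthetic` or `manifest`", call. = FALSE)
  }
  if (all(is.na(manifest$split))) {
    manifest <- stratified_split(manifest, seed = derive_seed(config$seed, "split"))
  }
  if (isTRUE(cfg$augment)) {
    pol_args <- cfg$augmentation %||% list()
    pol_args$seed <- derive_seed(config$seed, "augment")
    policy <- do.call(augmentation_policy, pol_args)
    manifest <- expand_training_set(manifest, policy, write_images = TRUE)
  }

  backbones <- cfg$backbones %||% list(
    list(name = "tiny", backbone = "tiny_cnn"),
    list(name = "tiny_wide", backbone = "tiny_cnn_wide")
  )
  specs <- lapply(backbones, function(b) {
    base_model_spec(
      name = b$name %||% b$backbone,
      backbone = b$backbone %||% "tiny_cnn",
      use_csae = b$use_csae %||% config$use_csae
    )
  })

  fit <- mae(manifest, specs, config)
  report <- build_report(fit, cfg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    write_metrics(fit$test_metrics,
                  csv_path = file.path(cfg$out_dir, "metrics.csv"),
                  confusion_csv_path = file.path(cfg$out_dir, "confusion.csv"))
  }
  attr(fit, "report") <- report
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Serialisable run report: config echo, deterministic run id, weights,
# history and test metrics.
build_report <- function(fit, cfg_echo = NULL) {
  cfg <- fit$config
  id_material <- paste(
    cfg$seed, cfg$epochs, cfg$batch_size, cfg$learning_rate, cfg$beta1,
    cfg$voting_mode, cfg$use_csae, cfg$image_size, cfg$restarts,
    paste(vapply(fit$specs, `[[`, "", "backbone"), collapse = "+"),
    sep = "|"
  )
  run_id <- sprintf("run-%08x", derive_seed(0, id_material))
  list(
    run_id = run_id,
    config = unclass(cfg),
    config_file = cfg_echo,
    models = lapply(fit$specs, unclass),
    val_accuracy = fit$val_accuracy,
    history = apply(fit$history, 2L, identity, simplify = FALSE),
    weights = list(
      per_primary = lapply(fit$weights$per_primary, as.vector),
      alphas = fit$weights$alphas,
      individual = fit$weights$individual,
      group = fit$weights$group,
      final = fit$weights$final,
      beta1 = cfg$beta1
    ),
    test = list(
      accuracy = fit$test_metrics$overall$accuracy,
      error_rate = fit$test_metrics$overall$error_rate,
      n = fit$test_metrics$overall$n,
      per_class = fit$test_metrics$per_class,
      aggregate = fit$test_metrics$aggregate,
      confusion = unname(apply(fit$confusion, 1L, identity, simplify = FALSE))
    )
  )
}

#' Sweep the mixed-voting coefficient beta1
#'
#' Re-evaluates a fitted ensemble for each requested `beta1` on the frozen
#' per-model test probabilities -- no retraining. Row `beta1 = 0` equals the
#' pure individual-voting ensemble, row `beta1 = 1` the pure group-voting
#' ensemble.
#'
#' @param fit A fitted [mae()] object.
#' @param beta_values Nonempty numeric vector of values in \[0, 1\].
#' @return A data.frame with one row per `beta1`: accuracy and macro
#'   precision/recall/F1, plus the weight vector columns `w1..wn`.
#' @export
beta_sweep <- function(fit, beta_values) {
  stopifnot(inherits(fit, "mae"))
  if (length(beta_values) == 0L) {
    stop("`beta_values` must be nonempty", call. = FALSE)
  }
  rows <- lapply(beta_values, function(b) {
    w <- mixed_combine(fit$weights$group, fit$weights$individual, beta1 = b)
    fused <- fuse_prob_matrices(fit$test_probs, w)
    pred <- max.col(fused, ties.method = "first")
    m <- metrics_from_confusion(
      build_confusion(fit$test_y, pred, labels = hrem_classes())
    )
    macro <- m$aggregate[m$aggregate$average == "macro", ]
    cbind(
      data.frame(beta1 = b, accuracy = m$overall$accuracy,
                 precision_macro = macro$precision,
                 recall_macro = macro$recall, f1_macro = macro$f1),
      setNames(as.data.frame(t(w)), paste0("w", seq_along(w)))
    )
  })
  do.call(rbind, rows)
}
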