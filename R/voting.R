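# The mixed voting mechanism.
#
# All ensemble weights live on the probability simplex. "Individual" voting
# runs one pass per base model with that model as primary, evolving a
# primary-heavy prior by accuracy-proportional multiplicative updates, and
# blends the four resulting weight sets with exponential-accuracy
# coefficients alpha_i = exp(A_i) / sum_j exp(A_j). "Group" voting evolves
# randomly initialised simplex points by the same multiplicative update and
# keeps the trajectory point with the best validation accuracy. The final
# mixed weight is the convex blend W = beta1 * W_g + (1 - beta1) * W_i.

#' Validate a voting weight vector
#'
#' @param w Numeric vector, nonnegative, summing to 1 (tolerance 1e-9).
#' @param normalize If `TRUE`, rescale a nonnegative vector with positive sum
#'   onto the simplex instead of erroring.
#' @return The weight vector.
#' @export
as_weight_vector <- function(w, normalize = FALSE) {
  if (!is.numeric(w) || length(w) < 1L || any(!is.finite(w))) {
    stop("weights must be a nonempty finite numeric vector", call. = FALSE)
  }
  if (any(w < -1e-12)) stop("weights must be nonnegative", call. = FALSE)
  w <- as.numeric(pmax(w, 0)) # bare numeric: no stray attributes

  s <- sum(w)
  if (normalize) {
    if (s <= 0) stop("weights sum to zero; cannot normalize", call. = FALSE)
    return(w / s)
  }
  if (abs(s - 1) > 1e-9) {
    stop(sprintf("weights must sum to 1 (got %.12f)", s), call. = FALSE)
  }
  w
}

#' Exponential-accuracy mixing coefficients
#'
#' Computes `alpha_i = exp(a_i) / sum_j exp(a_j)` over per-model validation
#' accuracies, after converting to the fraction scale. A temperature scales
#' the exponents (`alpha_i` proportional to `exp(temperature * a_i)`);
#' `temperature = 1` is the plain rule. Computed with max-subtraction for
#' numerical stability.
#'
#' @param acc Numeric vector of accuracies.
#' @param scale `"fraction"` (values in \[0, 1\]) or `"percent"` (\[0, 100\],
#'   divided by 100 before exponentiation).
#' @param temperature Positive exponent scale.
#' @return A simplex vector of the same length.
#' @export
#' @examples
#' accuracy_coefficients(c(0.9804, 0.9696, 0.9674, 0.9718))
accuracy_coefficients <- function(acc, scale = c("fraction", "percent"),
                                  temperature = 1) {
  scale <- match.arg(scale)
  if (!is.numeric(acc) || length(acc) < 1L) {
    stop("`acc` must be a nonempty numeric vector", call. = FALSE)
  }
  if (scale == "percent") {
    if (any(acc < 0 | acc > 100)) stop("percent accuracies must lie in [0, 100]")
    acc <- acc / 100
  } else if (any(acc < 0 | acc > 1)) {
    stop("fraction accuracies must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(is_scalar_number(temperature), temperature > 0)
  softmax_vec(temperature * acc)
}

#' Convex combination of per-primary weight sets (individual voting)
#'
#' `W_i = alpha_1 W_1 + ... + alpha_n W_n`, elementwise.
#'
#' @param weight_sets List of n weight vectors of equal length.
#' @param alphas Simplex vector of length n.
#' @return A weight vector.
#' @export
combine_individual <- function(weight_sets, alphas) {
  stopifnot(is.list(weight_sets), length(weight_sets) >= 1L)
  alphas <- as_weight_vector(alphas)
  if (length(weight_sets) != length(alphas)) {
    stop("length mismatch between weight_sets and alphas", call. = FALSE)
  }
  len <- unique(vapply(weight_sets, length, integer(1)))
  if (length(len) != 1L) stop("weight sets have unequal lengths", call. = FALSE)
  w <- Reduce(`+`, Map(function(wk, ak) ak * as_weight_vector(wk),
                       weight_sets, alphas))
  as_weight_vector(w, normalize = TRUE)
}

#' Accuracy-proportional multiplicative weight update (group voting step)
#'
#' `w*_i = w_i * a_i / sum_j a_j`, renormalised onto the simplex (the uniform
#' rescale leaves the downstream argmax selection unchanged). Scale-invariant
#' in the accuracies.
#'
#' @param w A weight vector.
#' @param acc Nonnegative accuracies of the same length, with positive sum.
#' @return The updated weight vector.
#' @export
group_update <- function(w, acc) {
  w <- as_weight_vector(w)
  if (length(acc) != length(w)) stop("length mismatch", call. = FALSE)
  if (any(acc < 0)) stop("accuracies must be nonnegative", call. = FALSE)
  if (sum(acc) <= 0) stop("accuracies sum to zero", call. = FALSE)
  as_weight_vector(w * (acc / sum(acc)), normalize = TRUE)
}

#' Select the best candidate weight vector by validation accuracy
#'
#' Returns the candidate maximising `scorer` (a deterministic
#' weights-to-accuracy function, normally ensemble validation accuracy on
#' frozen per-model predictions); ties go to the lowest candidate index.
#'
#' @param candidates Nonempty list of weight vectors.
#' @param scorer Function mapping a weight vector to a score.
#' @return The winning weight vector, with the score and index as attributes.
#' @export
group_select <- function(candidates, scorer) {
  if (!is.list(candidates) || length(candidates) == 0L) {
    stop("`candidates` must be a nonempty list", call. = FALSE)
  }
  scores <- vapply(candidates, function(w) scorer(as_weight_vector(w)),
                   numeric(1))
  best <- which.max(scores) # first index on ties
  out <- as_weight_vector(candidates[[best]])
  attr(out, "score") <- scores[best]
  attr(out, "index") <- best
  out
}

#' Fit one individual-voting weight set
#'
#' Starting from a primary-heavy prior (0.55 on the primary model, the
#' remaining 0.45 split evenly), applies the accuracy-proportional
#' multiplicative update once per epoch of the accuracy stream and returns the
#' trajectory point (prior included) with the best ensemble validation
#' accuracy under `scorer`; without a scorer, the final point.
#'
#' @param primary_index Which model is primary (1-based).
#' @param accuracies_per_epoch Matrix with one row per epoch and one column
#'   per model (validation accuracies), or a list of accuracy vectors.
#' @param scorer Optional weights-to-accuracy function used to pick the best
#'   trajectory point (ties to the earliest epoch).
#' @param prior_primary Prior mass on the primary model (default 0.55).
#' @return A weight vector `W_k`.
#' @export
fit_individual_weight_set <- function(primary_index, accuracies_per_epoch,
                                      scorer = NULL, prior_primary = 0.55) {
  if (is.list(accuracies_per_epoch)) {
    accuracies_per_epoch <- do.call(rbind, accuracies_per_epoch)
  }
  stopifnot(is.matrix(accuracies_per_epoch))
  n <- ncol(accuracies_per_epoch)
  if (!is_scalar_number(primary_index) || primary_index < 1 ||
      primary_index > n) {
    stop(sprintf("`primary_index` must be in 1..%d", n), call. = FALSE)
  }
  stopifnot(is_scalar_number(prior_primary), prior_primary > 0,
            prior_primary < 1)
  w <- rep((1 - prior_primary) / (n - 1), n)
  w[primary_index] <- prior_primary
  trajectory <- list(w)
  for (ep in seq_len(nrow(accuracies_per_epoch))) {
    a <- accuracies_per_epoch[ep, ]
    if (sum(a) <= 0) {
      stop(sprintf("all-zero accuracies at epoch %d", ep), call. = FALSE)
    }
    w <- group_update(w, a)
    trajectory[[length(trajectory) + 1L]] <- w
  }
  if (is.null(scorer)) {
    return(as_weight_vector(trajectory[[length(trajectory)]]))
  }
  group_select(trajectory, scorer)
}

#' Mixed voting combination
#'
#' `W = beta1 * W_g + (1 - beta1) * W_i` (so `beta2 = 1 - beta1` weights the
#' individual part). `beta1 = 0` recovers pure individual voting and
#' `beta1 = 1` pure group voting; the default 0.2 is the coefficient selected
#' in the original ablation.
#'
#' @param w_group,w_individual Weight vectors of equal length.
#' @param beta1 Group-voting coefficient in \[0, 1\].
#' @return A weight vector.
#' @export
mixed_combine <- function(w_group, w_individual, beta1 = 0.2) {
  if (!is_scalar_number(beta1) || beta1 < 0 || beta1 > 1) {
    stop("`beta1` must lie in [0, 1]", call. = FALSE)
  }
  w_group <- as_weight_vector(w_group)
  w_individual <- as_weight_vector(w_individual)
  if (length(w_group) != length(w_individual)) {
    stop("length mismatch", call. = FALSE)
  }
  as_weight_vector(beta1 * w_group + (1 - beta1) * w_individual)
}

# R flat-Dirichlet simplex draws (exponential spacings), seeded.
random_simplex_points <- function(n, restarts, seed) {
  with_seed(seed, lapply(seq_len(restarts), function(i) {
    g <- -log(runif(n))
    g / sum(g)
  }))
}

#' Group-voting weight search
#'
#' Draws `restarts` random simplex points, evolves each through the per-epoch
#' accuracy stream with [group_update()], and selects the best trajectory
#' point (initial points included) by `scorer` via [group_select()].
#'
#' @param accuracies_per_epoch Epochs x models matrix of validation
#'   accuracies.
#' @param scorer Weights-to-accuracy function on frozen predictions.
#' @param restarts Number of random initialisations (default 32).
#' @param seed Integer seed for the draws.
#' @return The selected weight vector `W_g`.
#' @export
group_search <- function(accuracies_per_epoch, scorer, restarts = 32L,
                         seed = 1L) {
  if (is.list(accuracies_per_epoch)) {
    accuracies_per_epoch <- do.call(rbind, accuracies_per_epoch)
  }
  stopifnot(is.matrix(accuracies_per_epoch), restarts >= 1)
  n <- ncol(accuracies_per_epoch)
  starts <- random_simplex_points(n, restarts, seed)
  candidates <- list()
  for (w0 in starts) {
    w <- as_weight_vector(w0)
    candidates[[length(candidates) + 1L]] <- w
    for (ep in seq_len(nrow(accuracies_per_epoch))) {
      w <- group_update(w, accuracies_per_epoch[ep, ])
      candidates[[length(candidates) + 1L]] <- w
    }
  }
  group_select(candidates, scorer)
}
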