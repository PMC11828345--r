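test_that("exponential-accuracy coefficients match symmetry and the frozen oracle", {
  expect_equal(accuracy_coefficients(rep(0.9, 4)), rep(0.25, 4))
  expect_equal(accuracy_coefficients(0.73), 1)
  # high-precision (50-digit) evaluation of exp(a_i)/sum exp(a_j) for the
  # published base-model accuracies, frozen as the reference
  alpha <- accuracy_coefficients(c(0.9804, 0.9696, 0.9674, 0.9718))
  expect_equal(alpha,
               c(0.25203015838171643, 0.24932287829835530,
                 0.24877497088524265, 0.24987199243468563),
               tolerance = 1e-14)
  # percent scale is converted, not exponentiated raw
  expect_equal(accuracy_coefficients(c(98.04, 96.96, 96.74, 97.18),
                                     scale = "percent"),
               alpha, tolerance = 1e-14)
  expect_error(accuracy_coefficients(numeric(0)), "nonempty")
  expect_error(accuracy_coefficients(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("accuracy coefficients are strictly monotone in accuracy", {
  set.seed(1)
  for (i in 1:50) {
    a <- runif(4)
    alpha <- accuracy_coefficients(a)
    expect_equal(order(alpha), order(a))
    expect_true(all(diff(sort(a)) == 0 | diff(alpha[order(a)]) > 0))
  }
})

test_that("combine_individual is a convex combination with the stated identities", {
  sets <- list(c(1, 0), c(0, 1))
  expect_equal(combine_individual(sets, c(1, 0)), c(1, 0)) # one-hot selects
  expect_equal(combine_individual(sets, c(0.5, 0.5)), c(0.5, 0.5))
  same <- list(c(0.3, 0.7), c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(combine_individual(same, c(0.2, 0.3, 0.5)), c(0.3, 0.7))
  expect_error(combine_individual(sets, c(0.5, 0.25, 0.25)), "mismatch")
})

test_that("the multiplicative group update follows the hand-worked values", {
  expect_equal(group_update(c(0.25, 0.25, 0.25, 0.25), c(0.8, 0.4, 0.4, 0.4)),
               c(0.4, 0.2, 0.2, 0.2), tolerance = 1e-12)
  expect_equal(group_update(c(0.4, 0.3, 0.2, 0.1), c(1, 0, 0, 0)),
               c(1, 0, 0, 0))
  w <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(group_update(w, rep(0.7, 4)), w) # equal accuracies fix w
  expect_error(group_update(w, rep(0, 4)), "zero")
})

test_that("group update is scale-invariant in the accuracies", {
  set.seed(2)
  for (i in 1:50) {
    w <- as_weight_vector(runif(4), normalize = TRUE)
    a <- runif(4, 0.1, 1)
    for (c_ in c(0.01, 3, 100)) {
      expect_equal(group_update(w, c_ * a), group_update(w, a),
                   tolerance = 1e-12)
    }
  }
})

test_that("group_select maximises the scorer with lowest-index ties", {
  cands <- list(c(0.5, 0.5), c(0.9, 0.1), c(0.1, 0.9))
  scorer <- function(w) -abs(w[1] - 0.85) # brute-force optimum is candidate 2
  best_brute <- cands[[which.max(vapply(cands, scorer, numeric(1)))]]
  expect_equal(as.vector(group_select(cands, scorer)), best_brute)
  expect_equal(attr(group_select(cands, scorer), "index"), 2L)

  single <- list(c(0.3, 0.7))
  expect_equal(as.vector(group_select(single, function(w) 1)), c(0.3, 0.7))
  tied <- list(c(1, 0), c(0, 1))
  expect_equal(as.vector(group_select(tied, function(w) 0)), c(1, 0))
  expect_error(group_select(list(), function(w) 0), "nonempty")
})

test_that("individual weight sets start primary-heavy and follow the update", {
  # constant equal accuracies: every trajectory point equals the prior
  acc <- matrix(0.8, nrow = 5, ncol = 4)
  expect_equal(fit_individual_weight_set(2, acc),
               c(0.15, 0.55, 0.15, 0.15))
  # a perfect primary absorbs all mass in one epoch
  expect_equal(fit_individual_weight_set(1, matrix(c(1, 0, 0, 0), 1)),
               c(1, 0, 0, 0))
  # one hand-worked multiplicative step from the prior
  one <- fit_individual_weight_set(1, matrix(c(0.9, 0.9, 0.6, 0.6), 1))
  expect_equal(one, c(0.495, 0.135, 0.09, 0.09) / 0.81, tolerance = 1e-12)
  expect_error(fit_individual_weight_set(5, acc), "1\\.\\.4")
  expect_error(fit_individual_weight_set(1, matrix(0, 1, 4)), "all-zero")
})

test_that("a scorer picks the best trajectory point including the prior", {
  acc <- matrix(c(0.9, 0.1, 0.1, 0.1), nrow = 3, ncol = 4, byrow = TRUE)
  # scorer prefers balanced weights, so the prior beats the sharpened tail
  w <- fit_individual_weight_set(1, acc, scorer = function(w) -max(w))
  expect_equal(w, c(0.55, 0.15, 0.15, 0.15), ignore_attr = TRUE)
})

test_that("mixed_combine hits its endpoints and the beta = 0.2 oracle", {
  wg <- c(0.4, 0.3, 0.2, 0.1)
  wi <- c(0.25, 0.25, 0.25, 0.25)
  expect_equal(mixed_combine(wg, wi, beta1 = 0), wi)
  expect_equal(mixed_combine(wg, wi, beta1 = 1), wg)
  expect_equal(mixed_combine(wg, wi, beta1 = 0.2),
               c(0.28, 0.26, 0.24, 0.22), tolerance = 1e-12)
  expect_error(mixed_combine(wg, wi, beta1 = 1.2), "\\[0, 1\\]")
  expect_error(mixed_combine(wg, wi, beta1 = -0.1), "\\[0, 1\\]")
  expect_error(mixed_combine(wg, c(0.5, 0.5), 0.5), "mismatch")
})

test_that("every voting operation returns a simplex point", {
  set.seed(3)
  for (i in 1:250) {
    n <- sample(2:6, 1)
    a <- runif(n)
    w1 <- as_weight_vector(runif(n), normalize = TRUE)
    w2 <- as_weight_vector(runif(n), normalize = TRUE)
    outs <- list(
      accuracy_coefficients(a),
      group_update(w1, a + 0.01),
      mixed_combine(w1, w2, runif(1)),
      combine_individual(list(w1, w2), accuracy_coefficients(runif(2)))
    )
    for (w in outs) {
      expect_equal(sum(w), 1, tolerance = 1e-9)
      expect_true(all(w >= 0))
    }
  }
})

test_that("mixed_combine output lies elementwise between its inputs", {
  set.seed(4)
  for (i in 1:100) {
    n <- sample(2:5, 1)
    wg <- as_weight_vector(runif(n), normalize = TRUE)
    wi <- as_weight_vector(runif(n), normalize = TRUE)
    w <- mixed_combine(wg, wi, runif(1))
    expect_true(all(w >= pmin(wg, wi) - 1e-12))
    expect_true(all(w <= pmax(wg, wi) + 1e-12))
  }
})

test_that("group_search matches brute-force scoring of its own candidates", {
  set.seed(6)
  acc <- matrix(runif(8, 0.5, 1), nrow = 2, ncol = 4)
  scorer <- function(w) sum(w * c(0.6, 0.2, 0.9, 0.4)) # deterministic toy score
  got <- group_search(acc, scorer, restarts = 5, seed = 10)

  # rebuild the candidate trajectories independently and score exhaustively
  starts <- maensemble:::random_simplex_points(4, 5, 10)
  cands <- list()
  for (w0 in starts) {
    w <- w0
    cands[[length(cands) + 1]] <- w
    for (ep in 1:2) {
      w <- group_update(w, acc[ep, ])
      cands[[length(cands) + 1]] <- w
    }
  }
  brute <- cands[[which.max(vapply(cands, scorer, numeric(1)))]]
  expect_equal(as.vector(got), brute, tolerance = 1e-12)
})

test_that("the mixed pipeline favours a strictly better model (majority of seeds)", {
  # frozen two-model fixture: model 1 predicts the truth with 90% mass,
  # model 2 with 60%; all weight machinery runs on these fixed predictions
  n_val <- 60
  wins <- 0
  for (s in 1:10) {
    set.seed(s)
    y <- sample(1:6, n_val, replace = TRUE)
    make_probs <- function(p_true) {
      t(vapply(y, function(k) {
        p <- rep((1 - p_true) / 5, 6)
        p[k] <- p_true
        # mislabel some samples by swapping mass to a wrong class
        if (runif(1) > p_true) p <- p[c(2:6, 1)]
        p
      }, numeric(6)))
    }
    probs <- list(make_probs(0.9), make_probs(0.6))
    acc <- vapply(probs, function(P) mean(max.col(P) == y), numeric(1))
    scorer <- function(w) {
      fused <- w[1] * probs[[1]] + w[2] * probs[[2]]
      mean(max.col(fused, ties.method = "first") == y)
    }
    hist <- rbind(acc * 0.8, acc * 0.9, acc) # an improving accuracy stream
    sets <- lapply(1:2, fit_individual_weight_set,
                   accuracies_per_epoch = hist, scorer = scorer)
    wi <- combine_individual(sets, accuracy_coefficients(acc))
    wg <- group_search(hist, scorer, restarts = 8, seed = s)
    w <- mixed_combine(wg, wi, beta1 = 0.2)
    if (w[1] > w[2]) wins <- wins + 1
  }
  expect_gt(wins, 5)
})

test_that("weight vector validation enforces the simplex contract", {
  expect_error(as_weight_vector(c(0.5, 0.6)), "sum to 1")
  expect_error(as_weight_vector(c(-0.2, 1.2)), "nonnegative")
  expect_equal(as_weight_vector(c(2, 2), normalize = TRUE), c(0.5, 0.5))
  expect_error(as_weight_vector(numeric(0)), "nonempty")
})
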