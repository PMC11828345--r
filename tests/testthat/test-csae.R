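test_that("pooled descriptors follow the channel/spatial reductions", {
  const <- array(3.5, dim = c(4, 2, 3))
  d <- pool_descriptors(const)
  expect_equal(d$c_avg, rep(3.5, 4))
  expect_equal(d$c_max, rep(3.5, 6))

  f <- array(0, dim = c(2, 2, 2))
  f[2, , ] <- 1 # channel 1 all zero, channel 2 all one
  d2 <- pool_descriptors(f)
  expect_equal(d2$c_avg, c(0, 1))
  expect_equal(d2$c_max, rep(1, 4))

  px <- array(c(0.3, -1, 2), dim = c(3, 1, 1)) # single spatial position
  d3 <- pool_descriptors(px)
  expect_equal(d3$c_avg, c(0.3, -1, 2))
  expect_equal(d3$c_max, 2)
})

test_that("spatial flattening is row-major", {
  f <- array(0, dim = c(1, 2, 3)) # C=1, H=2, W=3
  f[1, 1, ] <- c(1, 2, 3)
  f[1, 2, ] <- c(4, 5, 6)
  expect_equal(pool_descriptors(f)$c_max, 1:6)
})

test_that("channel attention matches the closed-form softmax values", {
  # constant descriptor -> uniform weights regardless of the filter
  const <- pool_descriptors(array(7, dim = c(5, 2, 2)))
  set.seed(3)
  expect_equal(channel_attention(const, filter = rnorm(3)), rep(1 / 5, 5))

  f <- array(c(0, 0, 0, log(3)), dim = c(4, 1, 1))
  d <- pool_descriptors(f)
  expect_equal(channel_attention(d, filter = c(0, 1, 0)),
               c(1 / 6, 1 / 6, 1 / 6, 1 / 2), tolerance = 1e-12)

  w <- channel_attention(pool_descriptors(array(rnorm(4 * 9), c(4, 3, 3))), 3)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w > 0))
})

test_that("spatial attention mirrors the channel branch over c_max", {
  const <- pool_descriptors(array(-2, dim = c(3, 2, 2)))
  expect_equal(spatial_attention(const, 3), rep(1 / 4, 4))

  single <- pool_descriptors(array(c(1, 5), dim = c(2, 1, 1)))
  expect_equal(spatial_attention(single, 3), 1)

  f <- array(0, dim = c(1, 2, 2))
  f[1, 2, 1] <- log(2) # row-major position 3
  expect_equal(spatial_attention(pool_descriptors(f), c(0, 1, 0)),
               c(0.2, 0.2, 0.4, 0.2), tolerance = 1e-12)
})

test_that("even kernels and malformed filters are rejected", {
  d <- pool_descriptors(array(1:8 / 8, c(2, 2, 2)))
  expect_error(channel_attention(d, filter = 4L), "odd")
  expect_error(spatial_attention(d, filter = c(1, 2)), "odd")
})

test_that("csae_forward has the constant closed form and linearity at zero", {
  for (dims in list(c(3, 2, 2), c(5, 4, 4), c(2, 1, 7))) {
    v <- 1.7
    f <- array(v, dim = dims)
    expected <- v * (1 / dims[1] + 1 / (dims[2] * dims[3]))
    set.seed(dims[1])
    out <- csae_forward(f, filter_c = rnorm(3), filter_s = rnorm(5))
    expect_equal(out, array(expected, dims), tolerance = 1e-12)
  }
  zero <- array(0, dim = c(4, 3, 3))
  expect_equal(csae_forward(zero), zero)
  expect_error(csae_forward(array(c(NA, 1:7), c(2, 2, 2))), "finite")
})

test_that("csae_forward equals the naive loop oracle on random small maps", {
  set.seed(99)
  for (i in 1:50) {
    C <- sample(1:6, 1); H <- sample(1:5, 1); W <- sample(1:5, 1)
    f <- array(rnorm(C * H * W), dim = c(C, H, W))
    gc <- rnorm(3); gs <- rnorm(3)
    expect_equal(csae_forward(f, gc, gs), naive_csae(f, gc, gs),
                 tolerance = 1e-6)
  }
})

test_that("shapes are preserved and attention vectors stay on the simplex", {
  set.seed(5)
  for (i in 1:20) {
    C <- sample(1:8, 1); H <- sample(1:6, 1); W <- sample(1:6, 1)
    f <- array(rnorm(C * H * W, sd = 3), dim = c(C, H, W))
    fwd <- csae_forward_cache(f, rnorm(3), rnorm(3))
    expect_equal(dim(fwd$out), c(C, H, W))
    expect_equal(sum(fwd$w_c), 1, tolerance = 1e-9)
    expect_equal(sum(fwd$w_s), 1, tolerance = 1e-9)
    expect_true(all(fwd$w_c >= 0) && all(fwd$w_s >= 0))
  }
})

test_that("attention is invariant to constant shifts of the descriptor", {
  # with the identity (delta) filter, adding a constant to the feature map
  # shifts both descriptors uniformly, and softmax ignores the shift
  set.seed(11)
  f <- array(rnorm(3 * 4 * 4), dim = c(3, 4, 4))
  d0 <- pool_descriptors(f)
  d1 <- pool_descriptors(f + 5)
  expect_equal(channel_attention(d0, 3L), channel_attention(d1, 3L),
               tolerance = 1e-12)
  expect_equal(spatial_attention(d0, 3L), spatial_attention(d1, 3L),
               tolerance = 1e-12)
})

test_that("rescale_attention restores unit-mean attention", {
  set.seed(13)
  f <- array(rnorm(4 * 3 * 3), dim = c(4, 3, 3))
  plain <- csae_forward(f)
  scaled <- csae_forward(f, rescale_attention = TRUE)
  fwd <- csae_forward_cache(f, rescale_attention = TRUE)
  expect_equal(mean(4 * fwd$w_c), 1, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(plain, scaled)))
})

test_that("csae_backward matches numerical gradients", {
  set.seed(42)
  C <- 3; H <- 2; W <- 2
  f <- array(rnorm(C * H * W), dim = c(C, H, W))
  gc <- rnorm(3); gs <- rnorm(3)
  G <- array(rnorm(C * H * W), dim = c(C, H, W))
  loss <- function(f, gc, gs) sum(csae_forward(f, gc, gs) * G)
  bk <- csae_backward(csae_forward_cache(f, gc, gs), G)
  eps <- 1e-6
  num_df <- array(0, dim(f))
  for (i in seq_along(f)) {
    fp <- f; fm <- f
    fp[i] <- fp[i] + eps; fm[i] <- fm[i] - eps
    num_df[i] <- (loss(fp, gc, gs) - loss(fm, gc, gs)) / (2 * eps)
  }
  expect_equal(bk$df, num_df, tolerance = 1e-6)
  num_dgc <- vapply(seq_along(gc), function(j) {
    gp <- gc; gm <- gc
    gp[j] <- gp[j] + eps; gm[j] <- gm[j] - eps
    (loss(f, gp, gs) - loss(f, gm, gs)) / (2 * eps)
  }, numeric(1))
  expect_equal(bk$dgc, num_dgc, tolerance = 1e-6)
  num_dgs <- vapply(seq_along(gs), function(j) {
    gp <- gs; gm <- gs
    gp[j] <- gp[j] + eps; gm[j] <- gm[j] - eps
    (loss(f, gc, gp) - loss(f, gc, gm)) / (2 * eps)
  }, numeric(1))
  expect_equal(bk$dgs, num_dgs, tolerance = 1e-6)
})
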