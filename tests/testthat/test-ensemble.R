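test_that("base model specs validate their fields", {
  s <- base_model_spec("m", "tiny_cnn")
  expect_s3_class(s, "base_model_spec")
  expect_error(base_model_spec("m", "alexnet"), "unknown backbone")
  expect_error(base_model_spec("m", "tiny_cnn", num_classes = 1), "num_classes")
  expect_error(base_model_spec("m", "tiny_cnn", csae_kernel = 4), "odd")
  # the original pretrained backbones are recognised but not buildable here
  r18 <- base_model_spec("r18", "resnet18", pretrained = TRUE)
  expect_error(forward_base(r18, array(0, c(32, 32, 3))), "pretrained")
})

test_that("forward_base emits softmax rows with stable shapes", {
  spec <- base_model_spec("m", "tiny_cnn", use_csae = TRUE)
  imgs <- lapply(1:4, function(i) {
    hrem_image(hrem_spec(hrem_classes()[i], 32, seed = i))
  })
  probs <- forward_base(spec, imgs, init_seed = 5)
  expect_equal(dim(probs), c(4L, 6L))
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-9)
  expect_true(all(probs > 0))

  no_csae <- forward_base(base_model_spec("m", "tiny_cnn", use_csae = FALSE),
                          imgs, init_seed = 5)
  expect_equal(dim(no_csae), dim(probs))
  expect_false(isTRUE(all.equal(no_csae, probs)))

  expect_error(forward_base(spec, array(0, c(16, 16, 3))), "at least 32")
  expect_error(forward_base(spec, matrix(0, 32, 32)), "H x W x 3")
})

test_that("a frozen model is deterministic across fresh constructions", {
  img <- hrem_image(hrem_spec("EGJOO", 32, seed = 2))
  spec <- base_model_spec("m", "tiny_cnn")
  p1 <- forward_base(spec, img, init_seed = 11)
  p2 <- forward_base(spec, img, init_seed = 11)
  expect_identical(p1, p2)
  p3 <- forward_base(spec, img, init_seed = 12)
  expect_false(identical(p1, p3))
})

test_that("fuse_predictions mixes probability rows with the tie rule", {
  probs <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  half <- fuse_predictions(probs, c(0.5, 0.5))
  expect_equal(half$fused_probs, c(0.5, 0.5))
  expect_equal(half$predicted_class, 1L) # lowest-index tie-break

  onehot <- fuse_predictions(probs, c(0, 1))
  expect_equal(onehot$fused_probs, c(0.2, 0.8))

  same <- rbind(c(0.1, 0.6, 0.3), c(0.1, 0.6, 0.3))
  expect_equal(fuse_predictions(same, c(0.5, 0.5))$fused_probs,
               c(0.1, 0.6, 0.3))
  expect_error(fuse_predictions(probs, c(1, 0, 0) / 1), "match the weight")
})

test_that("network gradients match numerical differentiation", {
  params <- maensemble:::net_init("tiny_cnn", 6, use_csae = TRUE, seed = 3)
  set.seed(1)
  x <- array(rnorm(32 * 32 * 3, sd = 0.3), dim = c(32, 32, 3))
  yk <- 4L
  loss_fn <- function(p) -log(maensemble:::net_forward(p, x)$probs[yk])
  fwd <- maensemble:::net_forward(params, x, keep_cache = TRUE)
  dlog <- fwd$probs
  dlog[yk] <- dlog[yk] - 1
  gr <- maensemble:::net_backward(params, fwd, dlog)
  eps <- 1e-5
  for (nm in c("W1", "b2", "W3", "gc", "gs", "Wfc")) {
    p <- params[[nm]]
    idx <- sample(length(p), min(4, length(p)))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("parameter counts are exact and CSAE adds two filters", {
  # layer-by-layer arithmetic for tiny_cnn (channels 8, 16, 16, 6 classes):
  # conv1 27*8+8, conv2 72*16+16, conv3 144*16+16, classifier 16*6+6
  by_hand <- (27 * 8 + 8) + (72 * 16 + 16) + (144 * 16 + 16) + (16 * 6 + 6)
  specs_plain <- list(base_model_spec("a", "tiny_cnn", use_csae = FALSE))
  plain <- count_parameters(specs_plain)
  expect_equal(plain$parameters[plain$model == "a"], by_hand)
  expect_equal(plain$size_mb[plain$model == "total"], by_hand * 4 / 2^20)

  for (k in c(3L, 5L)) {
    with_csae <- count_parameters(list(
      base_model_spec("a", "tiny_cnn", use_csae = TRUE, csae_kernel = k)
    ))
    expect_equal(with_csae$parameters[with_csae$model == "a"],
                 by_hand + 2 * k)
  }

  wide <- count_parameters(list(base_model_spec("w", "tiny_cnn_wide",
                                                use_csae = FALSE)))
  expect_gt(wide$parameters[wide$model == "w"], by_hand) # wider => more
})

test_that("the fitted ensemble satisfies the mixed-voting contract", {
  fit <- tiny_fit()
  w <- fit$weights
  expect_equal(length(w$final), 2)
  expect_equal(sum(w$final), 1, tolerance = 1e-9)
  for (wk in w$per_primary) expect_equal(sum(wk), 1, tolerance = 1e-9)
  expect_equal(sum(w$individual), 1, tolerance = 1e-9)
  expect_equal(sum(w$group), 1, tolerance = 1e-9)
  # W = beta1 * W_g + (1 - beta1) * W_i, recomputed from the logged parts
  expect_equal(w$final,
               fit$config$beta1 * w$group + (1 - fit$config$beta1) * w$individual,
               tolerance = 1e-12)
  expect_equal(dim(fit$history), c(fit$config$epochs, 2L))
  expect_true(all(fit$history >= 0 & fit$history <= 1))
  expect_s3_class(fit$test_metrics, "mae_metrics")
  expect_equal(sum(fit$confusion), 12L) # 6 classes x 2 test images
})

test_that("ensemble S3 methods expose weights, predictions and summaries", {
  fit <- tiny_fit()
  expect_equal(unname(coef(fit)), fit$weights$final)
  expect_output(print(fit), "Mixed attention ensemble")
  expect_output(summary(fit), "Test performance")

  img <- hrem_image(hrem_spec("Normal", 32, seed = 400))
  probs <- predict(fit, img, type = "prob")
  expect_equal(dim(probs), c(1L, 6L))
  expect_equal(rowSums(probs), 1, tolerance = 1e-9, ignore_attr = TRUE)
  cls <- predict(fit, img)
  expect_s3_class(cls, "factor")
  expect_equal(levels(cls), hrem_classes())
  # manifest input resolves paths
  m <- tiny_manifest()
  two <- predict(fit, m[m$split == "test", ][1:2, ], type = "prob")
  expect_equal(dim(two), c(2L, 6L))
})

test_that("voting modes force the documented weight structures", {
  fit <- tiny_fit()
  manifest <- tiny_manifest()
  specs <- fit$specs
  refit <- function(mode) {
    cfg <- mae_config(seed = 7, epochs = 3, image_size = 32, restarts = 8,
                      voting_mode = mode)
    mae(manifest, specs, cfg)
  }
  avg <- refit("average")
  expect_equal(avg$weights$final, c(0.5, 0.5))
  std <- refit("standard")
  expect_equal(std$weights$final,
               std$val_accuracy / sum(std$val_accuracy), tolerance = 1e-12)
  grp <- refit("group")
  expect_equal(grp$weights$final, grp$weights$group, tolerance = 1e-12)
})

test_that("empty splits and bad inputs are rejected", {
  manifest <- tiny_manifest()
  no_val <- manifest[manifest$split != "val", ]
  specs <- list(base_model_spec("a", "tiny_cnn"),
                base_model_spec("b", "tiny_cnn_wide"))
  expect_error(mae(no_val, specs, mae_config(epochs = 1)), "empty val split")
  expect_error(mae(manifest, specs[1], mae_config(epochs = 1)),
               "at least two")
})
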