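# Independent oracles and small fixtures shared across tests. Everything here
# is written as plainly as possible (explicit loops, no reuse of package
# internals) so it can serve as a reference implementation.

# Naive CSAE: explicit loops over channels and positions, row-major spatial
# flattening, zero-padded 1D convolutions and textbook softmax.
naive_csae <- function(f, gc, gs) {
  C <- dim(f)[1]; H <- dim(f)[2]; W <- dim(f)[3]
  P <- H * W
  c_avg <- numeric(C)
  for (k in 1:C) c_avg[k] <- mean(f[k, , ])
  c_max <- numeric(P)
  for (h in 1:H) {
    for (w in 1:W) {
      p <- (h - 1) * W + w
      c_max[p] <- max(f[, h, w])
    }
  }
  conv1 <- function(x, g) {
    k <- length(g); pad <- (k - 1) / 2; n <- length(x)
    u <- numeric(n)
    for (t in 1:n) {
      for (j in 1:k) {
        src <- t + j - 1 - pad
        src <- min(max(src, 1), n) # edge replication
        u[t] <- u[t] + g[j] * x[src]
      }
    }
    u
  }
  sm <- function(u) exp(u - max(u)) / sum(exp(u - max(u)))
  w_c <- sm(conv1(c_avg, gc))
  w_s <- sm(conv1(c_max, gs))
  out <- array(0, dim(f))
  for (k in 1:C) {
    for (h in 1:H) {
      for (w in 1:W) {
        p <- (h - 1) * W + w
        out[k, h, w] <- w_c[k] * f[k, h, w] + w_s[p] * f[k, h, w]
      }
    }
  }
  out
}

# Independent multiclass metrics straight from label vectors (no confusion
# matrix): per-class precision/recall/F1 by direct counting.
naive_metrics <- function(truth, pred, K) {
  precision <- recall <- f1 <- numeric(K)
  for (k in 1:K) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    precision[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (precision[k] + recall[k] > 0) {
      2 * precision[k] * recall[k] / (precision[k] + recall[k])
    } else 0
  }
  list(accuracy = mean(truth == pred), precision = precision,
       recall = recall, f1 = f1)
}

# Unsplit manifest with fabricated paths, n[i] rows of class i.
fake_manifest <- function(n_per_class) {
  classes <- hrem_classes()
  rows <- lapply(seq_along(classes), function(i) {
    if (n_per_class[i] == 0) return(NULL)
    data.frame(
      path = sprintf("img_%d_%04d.png", i, seq_len(n_per_class[i])),
      label = classes[i], stringsAsFactors = FALSE
    )
  })
  as_manifest(do.call(rbind, rows))
}

# Confusion matrix of the published test run, reconstructed from the printed
# per-class test counts and the three described misclassifications.
paper_confusion <- function() {
  classes <- hrem_classes()
  test_counts <- c(35, 67, 48, 96, 20, 195)
  truth <- rep(classes, test_counts)
  pred <- truth
  flip <- function(pred, from, to, k) {
    idx <- which(pred == from)[seq_len(k)]
    pred[idx] <- to
    pred
  }
  pred <- flip(pred, "Achalasia II", "Normal", 1)
  pred <- flip(pred, "IEM", "DES", 1)
  pred <- flip(pred, "IEM", "Normal", 5)
  build_confusion(truth, pred, labels = classes)
}

# Shared tiny trained ensemble for contract tests (fit once per test run).
tiny_fit_cache <- new.env(parent = emptyenv())

tiny_fit <- function() {
  if (!is.null(tiny_fit_cache$fit)) return(tiny_fit_cache$fit)
  dir <- file.path(tempdir(), "maensemble_tiny_fixture")
  manifest <- hrem_dataset(12, seed = 101, dir = dir, image_size = 32,
                           noise_level = 0.05)
  manifest <- stratified_split(manifest, seed = 102)
  specs <- list(
    base_model_spec("m1", "tiny_cnn"),
    base_model_spec("m2", "tiny_cnn_wide")
  )
  cfg <- mae_config(seed = 7, epochs = 3, image_size = 32, restarts = 8)
  tiny_fit_cache$fit <- mae(manifest, specs, cfg)
  tiny_fit_cache$manifest <- manifest
  tiny_fit_cache$fit
}

tiny_manifest <- function() {
  tiny_fit()
  tiny_fit_cache$manifest
}
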