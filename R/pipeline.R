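# Dataset manifests, stratified splitting, resizing and augmentation.

manifest_columns <- c("path", "label", "split", "seed", "augmented_from")

#' Validate and normalise a dataset manifest
#'
#' A manifest is a data.frame with columns `path, label, split, seed,
#' augmented_from`; one row per image. Labels must come from [hrem_classes()],
#' paths must be unique, and any augmented record must point back to a
#' train-split original.
#'
#' @param manifest A data.frame.
#' @return The manifest, with missing optional columns added as `NA`.
#' @export
as_manifest <- function(manifest) {
  stopifnot(is.data.frame(manifest))
  if (!all(c("path", "label") %in% names(manifest))) {
    stop("a manifest needs at least `path` and `label` columns", call. = FALSE)
  }
  for (col in manifest_columns) {
    if (!col %in% names(manifest)) manifest[[col]] <- NA
  }
  manifest <- manifest[manifest_columns]
  # canonical column types regardless of construction route (CSV or code)
  for (col in c("path", "label", "split", "augmented_from")) {
    manifest[[col]] <- as.character(manifest[[col]])
  }
  manifest$seed <- as.integer(manifest$seed)
  rownames(manifest) <- NULL
  bad <- setdiff(unique(manifest$label), hrem_classes())
  if (length(bad)) {
    stop(sprintf("unknown class label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(manifest$path)) {
    stop("duplicated paths in manifest", call. = FALSE)
  }
  aug <- !is.na(manifest$augmented_from)
  if (any(aug)) {
    src_split <- manifest$split[match(manifest$augmented_from[aug], manifest$path)]
    if (any(is.na(src_split)) || any(src_split != "train")) {
      stop("every augmented record must derive from a train-split original",
           call. = FALSE)
    }
  }
  manifest
}

#' @rdname as_manifest
#' @export
write_manifest <- function(manifest, path) {
  write.csv(as_manifest(manifest), path, row.names = FALSE)
  invisible(path)
}

#' @rdname as_manifest
#' @param path CSV file path.
#' @export
read_manifest <- function(path) {
  as_manifest(read.csv(path, stringsAsFactors = FALSE,
                       colClasses = list(split = "character",
                                         augmented_from = "character")))
}

#' Stratified 6:2:2 train/validation/test split
#'
#' Within each class of size n, the validation and test sets each get
#' `floor(0.2 * n)` images and the training set the remainder
#' (`n - 2 * floor(0.2 * n)`) -- the floor rule under which a 6:2:2 split of
#' integer class counts is exact whenever n is a multiple of 5 and the training
#' set absorbs the remainder otherwise. Assignment within a class is random
#' given `seed`.
#'
#' @param manifest An unsplit manifest ([as_manifest()]).
#' @param seed Integer seed for the within-class shuffles.
#' @return The manifest with the `split` column filled in.
#' @export
#' @examples
#' m <- data.frame(path = sprintf("img%02d.png", 1:10), label = "Normal")
#' table(stratified_split(as_manifest(m), seed = 1)$split)
stratified_split <- function(manifest, seed) {
  manifest <- as_manifest(manifest)
  if (any(!is.na(manifest$split))) {
    stop("manifest already has split assignments", call. = FALSE)
  }
  counts <- table(manifest$label)
  small <- names(counts)[counts < 5]
  if (length(small)) {
    stop(sprintf("class(es) with fewer than 5 members: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  }
  for (cls in names(counts)) {
    idx <- which(manifest$label == cls)
    n <- length(idx)
    n_val <- floor(0.2 * n)
    n_test <- floor(0.2 * n)
    ord <- with_seed(derive_seed(seed, paste("split", cls)), sample.int(n))
    split <- rep("train", n)
    split[ord[seq_len(n_val)]] <- "val"
    split[ord[n_val + seq_len(n_test)]] <- "test"
    manifest$split[idx] <- split
  }
  manifest
}

#' Split sizes under the floor-based 6:2:2 rule
#'
#' @param n_per_class Integer vector of class sizes.
#' @return A data.frame with columns `train`, `val`, `test`, one row per input.
#' @export
#' @examples
#' split_counts(c(178, 339, 240, 483, 100, 975))
split_counts <- function(n_per_class) {
  n_val <- floor(0.2 * n_per_class)
  data.frame(train = n_per_class - 2L * n_val, val = n_val, test = n_val)
}

#' Resize an image with bilinear interpolation
#'
#' Square output; aspect ratio is not preserved. Sampling uses pixel-centre
#' alignment with edge clamping.
#'
#' @param img H x W x 3 numeric array (values on any scale).
#' @param target Output side length in pixels.
#' @return `target` x `target` x 3 array.
#' @export
resize_image <- function(img, target) {
  stop_if_not_image(img)
  stopifnot(is_scalar_number(target), target >= 1)
  target <- as.integer(target)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  sample_axis <- function(n_src, n_dst) {
    src <- (seq_len(n_dst) - 0.5) * n_src / n_dst + 0.5
    src <- pmin(pmax(src, 1), n_src)
    i0 <- pmin(floor(src), n_src - ifelse(n_src > 1, 1, 0))
    list(i0 = as.integer(i0), frac = src - i0)
  }
  ry <- sample_axis(h, target)
  rx <- sample_axis(w, target)
  out <- array(0, dim = c(target, target, 3L))
  y1 <- pmin(ry$i0 + 1L, h); x1 <- pmin(rx$i0 + 1L, w)
  fy <- matrix(ry$frac, target, target)
  fx <- matrix(rx$frac, target, target, byrow = TRUE)
  for (ch in 1:3) {
    p00 <- img[ry$i0, rx$i0, ch]
    p01 <- img[ry$i0, x1, ch]
    p10 <- img[y1, rx$i0, ch]
    p11 <- img[y1, x1, ch]
    out[, , ch] <- p00 * (1 - fy) * (1 - fx) + p01 * (1 - fy) * fx +
      p10 * fy * (1 - fx) + p11 * fy * fx
  }
  out
}

#' Augmentation policy
#'
#' The training-set expansion draws, for each augmented copy, exactly one
#' transform uniformly from \{brightness, contrast+saturation, rotation,
#' scaling, Gaussian noise, salt-and-pepper noise\} with its parameter sampled
#' uniformly from the corresponding range. Defaults: brightness 1.6-2.0x,
#' contrast/saturation 2.1-2.5x, rotation -10..10 degrees, scaling 0.5-0.9,
#' Gaussian sigma 0.02 and salt-and-pepper fraction 0.01 (noise magnitudes are
#' the package's own defaults). `copies_per_image = 7` gives the standard
#' eight-fold expansion (original + 7 copies).
#'
#' @param brightness_range,contrast_saturation_range,rotation_range,scale_range
#'   Length-2 numeric ranges.
#' @param gaussian_sigma Gaussian noise sd as a fraction of the dynamic range.
#' @param salt_pepper_fraction Fraction of pixels hit by salt-and-pepper noise.
#' @param copies_per_image Augmented copies per training original (>= 0).
#' @param compose If `TRUE`, apply all transforms in sequence instead of one
#'   chosen at random (off by default).
#' @param seed Integer seed for the augmentation stream.
#' @return An object of class `"augmentation_policy"`.
#' @export
augmentation_policy <- function(brightness_range = c(1.6, 2.0),
                                contrast_saturation_range = c(2.1, 2.5),
                                rotation_range = c(-10, 10),
                                scale_range = c(0.5, 0.9),
                                gaussian_sigma = 0.02,
                                salt_pepper_fraction = 0.01,
                                copies_per_image = 7L,
                                compose = FALSE,
                                seed = 1L) {
  stopifnot(
    length(brightness_range) == 2L, length(contrast_saturation_range) == 2L,
    length(rotation_range) == 2L, length(scale_range) == 2L,
    is_scalar_number(gaussian_sigma), gaussian_sigma >= 0,
    is_scalar_number(salt_pepper_fraction), salt_pepper_fraction >= 0
  )
  if (!is_scalar_number(copies_per_image) || copies_per_image < 0) {
    stop("`copies_per_image` must be >= 0", call. = FALSE)
  }
  structure(
    list(
      brightness_range = as.numeric(brightness_range),
      contrast_saturation_range = as.numeric(contrast_saturation_range),
      rotation_range = as.numeric(rotation_range),
      scale_range = as.numeric(scale_range),
      gaussian_sigma = gaussian_sigma,
      salt_pepper_fraction = salt_pepper_fraction,
      copies_per_image = as.integer(copies_per_image),
      compose = isTRUE(compose),
      seed = as.integer(seed)
    ),
    class = "augmentation_policy"
  )
}

# Affine resampling about the image centre with bilinear interpolation and
# border replication (edge clamp). Used by both rotation and scaling so that
# neither introduces black corners that would trivially separate classes.
affine_resample <- function(img, angle_deg = 0, zoom = 1) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- angle_deg * pi / 180
  Y <- matrix(seq_len(h), h, w) - cy
  X <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse map: rotate by -angle, scale by 1/zoom
  sy <- (cos(th) * Y - sin(th) * X) / zoom + cy
  sx <- (sin(th) * Y + cos(th) * X) / zoom + cx
  sy <- pmin(pmax(sy, 1), h)
  sx <- pmin(pmax(sx, 1), w)
  y0 <- pmin(floor(sy), h - 1); x0 <- pmin(floor(sx), w - 1)
  fy <- sy - y0; fx <- sx - x0
  out <- img
  i00 <- cbind(as.vector(y0), as.vector(x0))
  i01 <- cbind(as.vector(y0), as.vector(x0 + 1))
  i10 <- cbind(as.vector(y0 + 1), as.vector(x0))
  i11 <- cbind(as.vector(y0 + 1), as.vector(x0 + 1))
  for (ch in 1:3) {
    plane <- img[, , ch]
    v <- plane[i00] * (1 - fy) * (1 - fx) + plane[i01] * (1 - fy) * fx +
      plane[i10] * fy * (1 - fx) + plane[i11] * fy * fx
    out[, , ch] <- matrix(v, h, w)
  }
  out
}

apply_transform <- function(img, which, par, policy) {
  switch(which,
    brightness = clip255(img * par),
    contrast_saturation = {
      # contrast: scale deviations from the per-channel mean; saturation:
      # scale deviations from the grayscale image; same drawn factor for both
      gs <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
      out <- img
      for (ch in 1:3) {
        m <- mean(img[, , ch])
        contrasted <- m + (img[, , ch] - m) * par
        out[, , ch] <- gs + (contrasted - gs) * par
      }
      clip255(out)
    },
    rotation = affine_resample(img, angle_deg = par),
    scale = affine_resample(img, zoom = par),
    gaussian_noise = {
      clip255(img + array(rnorm(length(img), sd = policy$gaussian_sigma * 255),
                          dim = dim(img)))
    },
    salt_pepper = {
      n_px <- prod(dim(img)[1:2])
      n_hit <- round(policy$salt_pepper_fraction * n_px)
      out <- img
      if (n_hit > 0) {
        hit <- sample.int(n_px, n_hit)
        val <- sample(c(0, 255), n_hit, replace = TRUE)
        for (ch in 1:3) {
          plane <- out[, , ch]
          plane[hit] <- val
          out[, , ch] <- plane
        }
      }
      out
    },
    stop("unknown transform: ", which)
  )
}

augment_transforms <- c("brightness", "contrast_saturation", "rotation",
                        "scale", "gaussian_noise", "salt_pepper")

#' Apply one random augmentation draw to an image
#'
#' Selects one transform uniformly from the policy's six (or composes all six
#' in order when `policy$compose`), samples its parameter uniformly from the
#' policy range, applies it and clips to \[0, 255\]. Deterministic given
#' `draw_seed`.
#'
#' @param img H x W x 3 array, values in \[0, 255\].
#' @param policy An [augmentation_policy()].
#' @param draw_seed Integer seed for this single draw.
#' @return Augmented image, same shape.
#' @export
augment_image <- function(img, policy, draw_seed) {
  stop_if_not_image(img)
  stopifnot(inherits(policy, "augmentation_policy"))
  with_seed(draw_seed, {
    draw_par <- function(which) {
      switch(which,
        brightness = runif(1, policy$brightness_range[1], policy$brightness_range[2]),
        contrast_saturation = runif(1, policy$contrast_saturation_range[1],
                                    policy$contrast_saturation_range[2]),
        rotation = runif(1, policy$rotation_range[1], policy$rotation_range[2]),
        scale = runif(1, policy$scale_range[1], policy$scale_range[2]),
        gaussian_noise = NA_real_,
        salt_pepper = NA_real_
      )
    }
    if (policy$compose) {
      for (tr in augment_transforms) {
        img <- apply_transform(img, tr, draw_par(tr), policy)
      }
      img
    } else {
      tr <- augment_transforms[sample.int(length(augment_transforms), 1L)]
      apply_transform(img, tr, draw_par(tr), policy)
    }
  })
}

#' Expand the training split by augmentation
#'
#' Every train-split original contributes itself plus `policy$copies_per_image`
#' augmented copies (default 7, i.e. the training set grows to eight times its
#' original size); validation and test splits are untouched. Augmented records
#' carry `augmented_from` provenance. When `write_images` is `TRUE` the source
#' PNGs are read, augmented and written next to the originals with an `_augN`
#' suffix; otherwise only the manifest bookkeeping is produced (enough for
#' counting and planning).
#'
#' @param manifest A split manifest.
#' @param policy An [augmentation_policy()].
#' @param write_images Materialise augmented PNGs on disk?
#' @return The expanded manifest.
#' @export
expand_training_set <- function(manifest, policy = augmentation_policy(),
                                write_images = FALSE) {
  manifest <- as_manifest(manifest)
  stopifnot(inherits(policy, "augmentation_policy"))
  if (any(is.na(manifest$split))) {
    stop("manifest must have split assignments; run stratified_split() first",
         call. = FALSE)
  }
  train_idx <- which(manifest$split == "train" & is.na(manifest$augmented_from))
  k <- policy$copies_per_image
  if (k == 0L || length(train_idx) == 0L) return(manifest)
  new_rows <- vector("list", length(train_idx) * k)
  pos <- 0L
  for (i in train_idx) {
    src <- manifest[i, ]
    img <- if (write_images) read_image_png(src$path) else NULL
    for (j in seq_len(k)) {
      draw_seed <- derive_seed(policy$seed, paste("augment", src$path, j))
      aug_path <- sub("(\\.[A-Za-z]+)$", sprintf("_aug%d\\1", j), src$path)
      if (write_images) {
        write_image_png(augment_image(img, policy, draw_seed), aug_path)
      }
      pos <- pos + 1L
      new_rows[[pos]] <- data.frame(
        path = aug_path, label = src$label, split = "train",
        seed = draw_seed, augmented_from = src$path, stringsAsFactors = FALSE
      )
    }
  }
  as_manifest(rbind(manifest, do.call(rbind, new_rows)))
}
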