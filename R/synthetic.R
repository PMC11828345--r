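# Synthetic HREM-style pressure topography generator.
#
# Real HREM plots show pressure along the esophagus (vertical axis) over time
# (horizontal axis) as a colour map; the upper and lower esophageal sphincters
# (UES, LES/EGJ) appear as horizontal high-pressure bands and peristalsis as a
# slanted band running from just below the UES to just above the LES. Each of
# the six motility categories has a characteristic caricature of that anatomy,
# which is what the generator draws: these are deliberately stylised fixtures
# for testing the classification pipeline, not physiological simulations.

#' Class vocabulary for esophageal motility categories
#'
#' The six diagnostic categories handled throughout the package, in canonical
#' order. Achalasia is restricted to type II (panesophageal pressurization).
#'
#' @return Character vector of length 6.
#' @export
#' @examples
#' hrem_classes()
hrem_classes <- function() {
  c("Achalasia II", "DES", "EGJOO", "IEM", "Jackhammer", "Normal")
}

#' Per-class rendering parameters for the synthetic generator
#'
#' One editable table drives the whole generator. Columns, all on the latent
#' pressure scale in \[0, 1\]:
#' \describe{
#'   \item{les_amp}{amplitude of the LES/EGJ band (elevated in Achalasia II and
#'     EGJOO).}
#'   \item{wave_amp}{amplitude of the peristaltic diagonal band (absent in
#'     Achalasia II, faint in IEM, very high in DES/Jackhammer).}
#'   \item{wave_width}{Gaussian half-width of the diagonal band, as a fraction
#'     of image width.}
#'   \item{n_waves}{number of parallel diagonal bursts (3 for Jackhammer's
#'     repetitive hypercontractility).}
#'   \item{gate_segments}{0 for a continuous wave; k > 0 chops the wave into k
#'     on/off segments (broken contractions in DES, repeated bursts in
#'     Jackhammer).}
#'   \item{column_amp}{amplitude of a full-height uniform pressure column
#'     (Achalasia II panesophageal pressurization).}
#' }
#'
#' @return A data.frame with one row per class.
#' @export
hrem_class_params <- function() {
  data.frame(
    class = hrem_classes(),
    les_amp = c(0.95, 0.55, 0.95, 0.50, 0.60, 0.55),
    wave_amp = c(0.00, 0.90, 0.60, 0.15, 0.95, 0.60),
    wave_width = c(0.08, 0.07, 0.08, 0.10, 0.05, 0.08),
    n_waves = c(1L, 1L, 1L, 1L, 3L, 1L),
    gate_segments = c(0L, 4L, 0L, 0L, 6L, 0L),
    column_amp = c(0.80, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Specification for one synthetic HREM image
#'
#' @param class_label One of [hrem_classes()].
#' @param image_size Side length in pixels (square image), at least 32.
#' @param seed Integer seed; the image is a deterministic function of the spec.
#' @param noise_level Standard deviation of additive Gaussian noise on the
#'   latent pressure field, as a fraction of its dynamic range; in \[0, 0.2\].
#' @return An object of class `"hrem_spec"`.
#' @export
#' @examples
#' sp <- hrem_spec("Normal", image_size = 64, seed = 1)
hrem_spec <- function(class_label, image_size = 224L, seed = 1L,
                      noise_level = 0.05) {
  if (!is.character(class_label) || length(class_label) != 1L ||
      !(class_label %in% hrem_classes())) {
    stop(sprintf(
      "unknown class label '%s'; expected one of: %s",
      as.character(class_label)[1L], paste(hrem_classes(), collapse = ", ")
    ), call. = FALSE)
  }
  stopifnot(is_scalar_number(image_size), image_size >= 32)
  stopifnot(is_scalar_number(seed))
  if (!is_scalar_number(noise_level) || noise_level < 0 || noise_level > 0.2) {
    stop("`noise_level` must be in [0, 0.2]", call. = FALSE)
  }
  structure(
    list(
      class_label = class_label, image_size = as.integer(image_size),
      seed = as.integer(seed), noise_level = noise_level
    ),
    class = "hrem_spec"
  )
}

# Pressure-to-colour map: piecewise linear through three documented stops,
# blue (low) -> green (moderate) -> red (high), chosen so that grayscale
# luminance increases monotonically with pressure.
#   p = 0.0 -> (15, 20, 140)
#   p = 0.5 -> (20, 190, 60)
#   p = 1.0 -> (250, 40, 10)
hrem_colormap <- function(p) {
  p <- clip01(p)
  lo <- c(15, 20, 140)
  mid <- c(20, 190, 60)
  hi <- c(250, 40, 10)
  t1 <- pmin(p / 0.5, 1)
  t2 <- pmax((p - 0.5) / 0.5, 0)
  out <- array(0, dim = c(length(p), 3L))
  for (ch in 1:3) {
    low_part <- lo[ch] + (mid[ch] - lo[ch]) * t1
    out[, ch] <- ifelse(p <= 0.5, low_part, mid[ch] + (hi[ch] - mid[ch]) * t2)
  }
  out
}

# Latent pressure field for a class, before noise; values in [0, 1].
# Rows run top (pharynx/UES) to bottom (LES/EGJ), columns are time.
hrem_latent_field <- function(class_label, size) {
  pars <- hrem_class_params()
  p <- pars[pars$class == class_label, ]
  y <- (seq_len(size) - 0.5) / size # row fraction, 0 top
  x <- (seq_len(size) - 0.5) / size # column fraction
  Y <- matrix(y, nrow = size, ncol = size)
  X <- matrix(x, nrow = size, ncol = size, byrow = TRUE)

  edge <- function(t) 1 / (1 + exp(-t / 0.008)) # soft band edges
  band <- function(yy, lo, hi) edge(yy - lo) * edge(hi - yy)

  field <- matrix(0.05, size, size) # resting background
  field <- pmax(field, 0.85 * band(Y, 0.04, 0.12)) # UES band
  field <- pmax(field, p$les_amp * band(Y, 0.86, 0.94)) # LES/EGJ band

  # peristaltic diagonal: body progression u in [0,1] between the sphincters
  u <- (Y - 0.14) / 0.70
  in_body <- u > 0 & u < 1
  if (p$wave_amp > 0) {
    centre <- 0.15 + 0.70 * u
    gate <- if (p$gate_segments > 0) {
      (sin(pi * p$gate_segments * u + 0.7) > 0) * 1
    } else {
      1
    }
    offs <- if (p$n_waves > 1L) {
      seq(-0.18, 0.18, length.out = p$n_waves)
    } else {
      0
    }
    wave <- matrix(0, size, size)
    for (o in offs) {
      wave <- pmax(wave, exp(-((X - centre - o)^2) / (2 * p$wave_width^2)))
    }
    field <- pmax(field, p$wave_amp * gate * wave * in_body)
  }
  if (p$column_amp > 0) { # panesophageal pressurization column
    col_mask <- (X > 0.35 & X < 0.75) * in_body
    field <- pmax(field, p$column_amp * col_mask)
  }
  field
}

#' Generate one synthetic HREM-style image
#'
#' Renders the class-specific latent pressure field (see [hrem_class_params()]),
#' adds Gaussian noise of standard deviation `noise_level` on the latent scale,
#' clips to \[0, 1\] and colourises with the blue-green-red pressure map.
#' Deterministic given the spec (including its seed).
#'
#' @param spec An [hrem_spec()].
#' @return An `image_size` x `image_size` x 3 numeric array with values in
#'   \[0, 255\].
#' @export
#' @examples
#' img <- hrem_image(hrem_spec("Jackhammer", image_size = 64, seed = 3))
#' dim(img)
hrem_image <- function(spec) {
  stopifnot(inherits(spec, "hrem_spec"))
  size <- spec$image_size
  field <- hrem_latent_field(spec$class_label, size)
  if (spec$noise_level > 0) {
    noise <- with_seed(
      derive_seed(spec$seed, paste("hrem_image", spec$class_label, size)),
      matrix(rnorm(size * size, sd = spec$noise_level), size, size)
    )
    field <- field + noise
  }
  rgb <- hrem_colormap(as.vector(clip01(field)))
  array(rgb, dim = c(size, size, 3L))
}

#' Generate a labelled synthetic dataset on disk
#'
#' Writes `6 * n_per_class` PNG images plus a `manifest.csv` with columns
#' `path, label, split, seed, augmented_from`. Splits are left unassigned
#' (`NA`); use [stratified_split()]. Each image gets its own sub-seed derived
#' from `seed`, so the whole dataset is reproducible byte-for-byte.
#'
#' @param n_per_class Images per class, at least 1.
#' @param seed Master seed.
#' @param dir Output directory (created if missing).
#' @param image_size,noise_level Passed to [hrem_spec()].
#' @return The manifest data.frame, invisibly also written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
hrem_dataset <- function(n_per_class, seed, dir,
                         image_size = 224L, noise_level = 0.05) {
  stopifnot(is_scalar_number(n_per_class), n_per_class >= 1)
  n_per_class <- as.integer(n_per_class)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop(sprintf("cannot create directory '%s'", dir))
  rows <- list()
  for (cls in hrem_classes()) {
    slug <- gsub("[^A-Za-z0-9]+", "_", tolower(cls))
    cls_dir <- file.path(dir, slug)
    dir.create(cls_dir, showWarnings = FALSE)
    for (i in seq_len(n_per_class)) {
      img_seed <- derive_seed(seed, paste(cls, i))
      sp <- hrem_spec(cls, image_size = image_size, seed = img_seed,
                      noise_level = noise_level)
      img <- hrem_image(sp)
      path <- file.path(cls_dir, sprintf("%s_%04d.png", slug, i))
      write_image_png(img, path)
      rows[[length(rows) + 1L]] <- data.frame(
        path = path, label = cls, split = NA_character_,
        seed = img_seed, augmented_from = NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}

#' Read / write images as PNG
#'
#' Thin wrappers over the png package using the package-wide image convention:
#' an H x W x 3 numeric array with values in \[0, 255\].
#'
#' @param img Image array.
#' @param path File path.
#' @return `read_image_png` returns the image array; `write_image_png` returns
#'   `path` invisibly.
#' @export
write_image_png <- function(img, path) {
  stop_if_not_image(img)
  png::writePNG(clip255(img) / 255, target = path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE] # drop alpha
  a * 255
}
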