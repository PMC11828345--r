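# Internal helpers: seeding, numeric utilities, argument checks.

# Derive a named sub-seed from a master seed so that independent random streams
# (splits, augmentation draws, model inits, weight search) never share state.
# FNV-1a style fold over the stream name, kept exact in double precision and
# reduced mod 2^31 - 1 so the result is always a valid 32-bit seed.
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1
  h <- (abs(master) %% m)
  for (code in utf8ToInt(paste(stream, collapse = "/"))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 1L) + 1L)
}

# Run code with a local RNG state; the caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Numerically stable softmax of a vector.
softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Row-wise stable softmax of a matrix.
softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

# argmax with lowest-index tie-break (which.max's documented behaviour),
# wrapped for intent at call sites where the tie rule is part of the contract.
argmax_first <- function(x) which.max(x)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_if_not_image <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L) {
    stop(sprintf("`%s` must be an H x W x 3 numeric array", what), call. = FALSE)
  }
  if (any(dim(img)[1:2] == 0L)) {
    stop(sprintf("`%s` has a zero dimension", what), call. = FALSE)
  }
  invisible(img)
}
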