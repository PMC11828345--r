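# Channel-and-spatial attention enhancement (CSAE).
#
# Given a backbone feature map f (C x H x W), two pooled descriptors are
# formed: a per-channel average (length C, over the channel view) and a
# per-position maximum over channels (length H*W, over the spatial view).
# Each descriptor passes through a learnable bias-free 1D convolution
# (edge-replicate padded, length-preserving) and a softmax, yielding a channel attention
# vector w_c on the C-simplex and a spatial attention vector w_s on the
# (H*W)-simplex. The enhanced map is
#
#   f'[k, p] = w_c[k] * f[k, p] + w_s[p] * f[k, p]
#
# Spatial positions are flattened row-major (w fastest within each row h).
# Because softmax is applied literally, the mean attention weight shrinks as
# C or H*W grow; `rescale_attention` optionally multiplies w_c by C and w_s by
# H*W to restore unit mean (off by default).

#' Construct a feature map
#'
#' @param values Numeric array of dimension C x H x W (channels first), all
#'   finite.
#' @return The array, validated, with class `"feature_map"` prepended.
#' @export
feature_map <- function(values) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("a feature map must be a C x H x W array", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("non-finite values in feature map", call. = FALSE)
  class(values) <- c("feature_map", class(values))
  values
}

# C x H x W array -> C x P matrix with row-major spatial flattening
# (p = (h-1)*W + w), and back.
fmap_to_matrix <- function(f) {
  d <- dim(f)
  m <- aperm(unclass(f), c(1L, 3L, 2L)) # C, W, H
  dim(m) <- c(d[1L], d[2L] * d[3L])
  m
}

matrix_to_fmap <- function(m, dims) {
  a <- m
  dim(a) <- c(dims[1L], dims[3L], dims[2L]) # C, W, H
  aperm(a, c(1L, 3L, 2L))
}

#' Pooled channel and spatial descriptors
#'
#' `c_avg[k]` is the spatial mean of channel k (average pooling of the channel
#' view); `c_max[p]` is the maximum over channels at spatial position p (max
#' pooling of the spatial view), positions flattened row-major.
#'
#' @param f A C x H x W array (see [feature_map()]).
#' @return A list with `c_avg` (length C), `c_max` (length H*W), `argmax`
#'   (channel attaining each spatial max, first index on ties) and `dims`.
#' @export
pool_descriptors <- function(f) {
  if (!is.array(f) || length(dim(f)) != 3L) {
    stop("`f` must be a C x H x W array", call. = FALSE)
  }
  d <- dim(f)
  m <- fmap_to_matrix(f)
  arg <- max.col(t(m), ties.method = "first")
  structure(
    list(
      c_avg = rowMeans(m),
      c_max = m[cbind(arg, seq_len(ncol(m)))],
      argmax = arg,
      dims = d
    ),
    class = "csae_descriptor"
  )
}

# Resolve a filter argument: an odd-length numeric vector is taken as the
# filter weights; a single whole number k is taken as a kernel size and
# expanded to the identity (delta) filter of that size.
resolve_filter <- function(filter) {
  if (length(filter) == 1L && filter == round(filter) && filter >= 1) {
    k <- as.integer(filter)
    if (k %% 2L == 0L) stop("kernel size must be odd", call. = FALSE)
    g <- numeric(k)
    g[(k + 1L) / 2L] <- 1
    return(g)
  }
  if (length(filter) %% 2L == 0L) {
    stop("1D convolution filter must have odd length", call. = FALSE)
  }
  as.numeric(filter)
}

# Length-preserving 1D convolution (cross-correlation form) with
# edge-replicate padding: u[t] = sum_j g[j] * xp[t + j - 1], pad = (k-1)/2,
# xp = (x[1] repeated, x, x[n] repeated). Replicate padding makes the
# operator constant-preserving (a constant descriptor maps to a constant,
# hence uniform attention after softmax, whatever the filter) -- a property
# the attention closed forms rely on and which zero padding would break at
# the boundary.
conv1d_pad <- function(x, pad) {
  n <- length(x)
  c(rep(x[1L], pad), x, rep(x[n], pad))
}

conv1d_same <- function(x, g) {
  k <- length(g)
  pad <- (k - 1L) / 2L
  n <- length(x)
  if (pad == 0L) return(g * x)
  xp <- conv1d_pad(x, pad)
  u <- numeric(n)
  for (j in seq_len(k)) u <- u + g[j] * xp[j:(j + n - 1L)]
  u
}

# Gradients of conv1d_same. d/dx: full convolution of du with g on the
# padded axis, with the pad contributions folded back into the replicated
# border elements. d/dg[j] = sum_t du[t] * xp[t + j - 1].
conv1d_same_grad_x <- function(du, g) {
  k <- length(g)
  pad <- (k - 1L) / 2L
  n <- length(du)
  if (pad == 0L) return(g * du)
  dxp <- numeric(n + 2L * pad)
  for (j in seq_len(k)) {
    dxp[j:(j + n - 1L)] <- dxp[j:(j + n - 1L)] + g[j] * du
  }
  dx <- dxp[(pad + 1L):(pad + n)]
  dx[1L] <- dx[1L] + sum(dxp[seq_len(pad)])
  dx[n] <- dx[n] + sum(dxp[(pad + n + 1L):(n + 2L * pad)])
  dx
}

conv1d_same_grad_g <- function(du, x, k) {
  pad <- (k - 1L) / 2L
  n <- length(x)
  xp <- if (pad == 0L) x else conv1d_pad(x, pad)
  vapply(seq_len(k), function(j) sum(du * xp[j:(j + n - 1L)]), numeric(1))
}

#' Channel and spatial attention vectors
#'
#' `channel_attention` maps the pooled channel descriptor through a bias-free
#' length-preserving 1D convolution (edge-replicate padding, so constant
#' descriptors stay constant) and a softmax, returning a point on the
#' C-simplex. `spatial_attention` does the same over the spatial descriptor
#' `c_max`, returning a point on the (H*W)-simplex.
#'
#' @param d A descriptor from [pool_descriptors()].
#' @param filter Either an odd-length numeric vector of filter weights, or a
#'   single odd integer kernel size (expanded to the identity filter). In a
#'   trained model the weights are learnable parameters.
#' @return A nonnegative vector summing to 1.
#' @export
channel_attention <- function(d, filter = 3L) {
  stopifnot(inherits(d, "csae_descriptor"))
  softmax_vec(conv1d_same(d$c_avg, resolve_filter(filter)))
}

#' @rdname channel_attention
#' @export
spatial_attention <- function(d, filter = 3L) {
  stopifnot(inherits(d, "csae_descriptor"))
  softmax_vec(conv1d_same(d$c_max, resolve_filter(filter)))
}

#' Apply the CSAE operator to a feature map
#'
#' Computes `f'[k, p] = (w_c[k] + w_s[p]) * f[k, p]` with the attention
#' vectors of [channel_attention()] and [spatial_attention()]. Shape is
#' preserved. The operation is differentiable in `f` and both filters; use
#' [csae_forward_cache()] / [csae_backward()] inside training loops.
#'
#' @param f A C x H x W array with finite values.
#' @param filter_c,filter_s Filters (or odd kernel sizes) for the channel and
#'   spatial branches.
#' @param rescale_attention If `TRUE`, multiply `w_c` by C and `w_s` by H*W so
#'   each attention vector has unit mean.
#' @return A C x H x W array.
#' @export
#' @examples
#' f <- array(seq_len(2 * 3 * 3) / 18, dim = c(2, 3, 3))
#' out <- csae_forward(f)
#' dim(out)
csae_forward <- function(f, filter_c = 3L, filter_s = 3L,
                         rescale_attention = FALSE) {
  csae_forward_cache(f, filter_c, filter_s, rescale_attention)$out
}

#' CSAE forward pass with cache (for training)
#'
#' @inheritParams csae_forward
#' @return A list with `out` (C x H x W array), `w_c`, `w_s`, and the cached
#'   intermediates needed by [csae_backward()].
#' @export
csae_forward_cache <- function(f, filter_c = 3L, filter_s = 3L,
                               rescale_attention = FALSE) {
  if (!is.array(f) || length(dim(f)) != 3L) {
    stop("`f` must be a C x H x W array", call. = FALSE)
  }
  if (!all(is.finite(f))) stop("non-finite values in feature map", call. = FALSE)
  gc_ <- resolve_filter(filter_c)
  gs_ <- resolve_filter(filter_s)
  d <- pool_descriptors(f)
  C <- d$dims[1L]
  P <- d$dims[2L] * d$dims[3L]
  w_c <- softmax_vec(conv1d_same(d$c_avg, gc_))
  w_s <- softmax_vec(conv1d_same(d$c_max, gs_))
  sc <- if (rescale_attention) C else 1
  ss <- if (rescale_attention) P else 1
  m <- fmap_to_matrix(f)
  gain <- outer(sc * w_c, ss * w_s, "+") # C x P
  out_m <- gain * m
  list(
    out = matrix_to_fmap(out_m, d$dims),
    w_c = w_c, w_s = w_s,
    cache = list(m = m, d = d, gc = gc_, gs = gs_, w_c = w_c, w_s = w_s,
                 sc = sc, ss = ss, dims = d$dims)
  )
}

#' CSAE backward pass
#'
#' Back-propagates a gradient through [csae_forward_cache()], including the
#' paths through the pooled descriptors (mean for the channel branch,
#' subgradient through the argmax for the spatial branch) and the softmax.
#'
#' @param fwd The list returned by [csae_forward_cache()].
#' @param dout Gradient with respect to the output, C x H x W array.
#' @return A list with `df` (C x H x W), `dgc` and `dgs` (filter gradients).
#' @export
csae_backward <- function(fwd, dout) {
  cc <- fwd$cache
  G <- fmap_to_matrix(dout)
  m <- cc$m
  C <- cc$dims[1L]
  P <- ncol(m)
  gain_c <- cc$sc * cc$w_c
  gain_s <- cc$ss * cc$w_s
  df_m <- (outer(gain_c, gain_s, "+")) * G

  q_c <- cc$sc * rowSums(G * m) # dL/dw_c
  q_s <- cc$ss * colSums(G * m) # dL/dw_s
  du_c <- cc$w_c * (q_c - sum(cc$w_c * q_c)) # softmax backward
  du_s <- cc$w_s * (q_s - sum(cc$w_s * q_s))

  dgc <- conv1d_same_grad_g(du_c, cc$d$c_avg, length(cc$gc))
  dgs <- conv1d_same_grad_g(du_s, cc$d$c_max, length(cc$gs))

  dc_avg <- conv1d_same_grad_x(du_c, cc$gc)
  dc_max <- conv1d_same_grad_x(du_s, cc$gs)

  # c_avg[k] = mean_p f[k, p]; c_max[p] = f[argmax_p, p]
  df_m <- df_m + matrix(dc_avg / P, C, P)
  idx <- cbind(cc$d$argmax, seq_len(P))
  df_m[idx] <- df_m[idx] + dc_max

  list(df = matrix_to_fmap(df_m, cc$dims), dgc = dgc, dgs = dgs)
}
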