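#' Fixed bilinear upsampling kernel
#'
#' The separable triangular kernel that makes a stride-`factor` transposed
#' convolution perform bilinear interpolation. Side length is
#' `2*factor - (factor %% 2)`; for factor 2 the central 2x2 block equals
#' 0.75^2 = 0.5625. Used as a fixed (non-learned) filter in both network
#' families: learned upsampling kernels buy little accuracy for their cost.
#'
#' @param factor integer upsampling factor >= 1.
#' @return Square numeric matrix of bilinear weights.
#' @export
bilinear_kernel <- function(factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor)) {
    stop_suvseg("factor must be an integer >= 1", class = "suvseg_config_error")
  }
  f <- as.integer(factor)
  k <- 2L * f - f %% 2L
  og <- (2 * f - 1 - f %% 2) / (2 * f)
  w <- 1 - abs((seq_len(k) - 1) / f - og)
  outer(w, w)
}

#' Atrous (dilated) 2D convolution
#'
#' Cross-correlates `x` with `kernel` whose taps are spaced `rate` pixels
#' apart, enlarging the receptive field of a k x k kernel to
#' `(k-1)*rate + 1` without extra parameters. Same-padding keeps the
#' spatial size; rate 1 reduces to standard convolution.
#'
#' @param x numeric matrix.
#' @param kernel numeric matrix with odd side lengths.
#' @param rate integer dilation rate >= 1.
#' @return Matrix of the same dimensions as `x`.
#' @export
atrous_conv2d <- function(x, kernel, rate = 1L) {
  if (rate < 1 || rate != round(rate)) {
    stop_suvseg("rate must be an integer >= 1", class = "suvseg_config_error")
  }
  if (nrow(kernel) %% 2L == 0L || ncol(kernel) %% 2L == 0L) {
    stop_suvseg("kernel side lengths must be odd for same-padding",
                class = "suvseg_config_error")
  }
  xc <- array(as.numeric(x), c(nrow(x), ncol(x), 1L))
  W <- matrix(as.numeric(kernel), ncol = 1L)
  out <- cpp_conv2d_fwd(xc, W, 0, nrow(kernel), ncol(kernel), 1L,
                        as.integer(rate))
  out[, , 1]
}

#' Bilinear upsampling by fixed-kernel transposed convolution
#'
#' Applies a stride-`factor` transposed convolution with
#' [bilinear_kernel()] channel-wise; on interior pixels this equals direct
#' bilinear interpolation at source positions `(i + 0.5)/factor - 0.5`.
#'
#' @param x numeric matrix or (H, W, C) array.
#' @param factor integer upsampling factor >= 1.
#' @return Upsampled matrix/array with spatial dimensions scaled by
#'   `factor`.
#' @export
upsample_bilinear <- function(x, factor) {
  K <- bilinear_kernel(factor)
  was_mat <- is.matrix(x)
  if (was_mat) x <- array(x, c(dim(x), 1L))
  out <- cpp_upsample_fwd(x, K, as.integer(factor))
  if (was_mat) out[, , 1] else out
}

# ---- internal layer helpers -------------------------------------------------

conv_fwd <- function(x, p) {
  cpp_conv2d_fwd(x, p$W, p$b, p$kh, p$kw, p$stride, p$dil)
}

conv_bwd <- function(x, p, dout) {
  cpp_conv2d_bwd(x, p$W, dout, p$kh, p$kw, p$stride, p$dil)
}

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(x_pre, dout) {
  dout[x_pre <= 0] <- 0
  dout
}

# He-normal initialized conv parameter set; zero_init for score layers that
# must start as the identity contribution in skip fusion
conv_param <- function(kh, kw, cin, cout, stride = 1L, dil = 1L,
                       zero_init = FALSE) {
  n <- kh * kw * cin
  W <- if (zero_init) matrix(0, n, cout) else {
    matrix(stats::rnorm(n * cout, sd = sqrt(2 / n)), n, cout)
  }
  list(W = W, b = numeric(cout), kh = as.integer(kh), kw = as.integer(kw),
       cin = as.integer(cin), cout = as.integer(cout),
       stride = as.integer(stride), dil = as.integer(dil))
}
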