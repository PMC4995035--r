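#' Configuration for the filament enhancement chain
#'
#' Three filters applied in sequence to the fibers image: an isotropic
#' Gaussian smoothing (`gaussian_sigma`), a 3x3 Laplace-type sharpening
#' kernel scaled by `laplace_beta` (constrained to (0, 10\]), and a
#' directional Gaussian bank (`dg_sigma` along the filament axis, unit sigma
#' across, support size `r = 2 * ceiling(3 * dg_sigma)`), maximized over
#' `n_orientations` evenly spaced orientations.
#'
#' The printed Laplace kernel has center coefficient -4, making the scaled
#' kernel an all-negative smoother; with `laplace_abs = TRUE` (default) the
#' chain takes the magnitude of the Laplace output so that filament ridges
#' come out bright, which is what the subsequent line detector expects.
#' `laplace_center` can override the center coefficient (e.g. +4).
#'
#' @param gaussian_sigma smoothing sigma in px (default 1.0).
#' @param laplace_beta Laplace scale beta, 0 < beta <= 10 (default 10).
#' @param dg_sigma directional Gaussian long-axis sigma (default 10).
#' @param n_orientations orientation count (>= 4, default 12).
#' @param laplace_center center coefficient of the 3x3 kernel (default -4).
#' @param laplace_abs take the magnitude after the Laplace step (default TRUE).
#' @param dg_short_sigma cross-axis sigma of the directional Gaussian.
#' @return an `enhancement_config` list; `dg_filter_size` holds `r`.
#' @export
enhancement_config <- function(gaussian_sigma = 1.0, laplace_beta = 10.0,
                               dg_sigma = 10.0, n_orientations = 12L,
                               laplace_center = -4, laplace_abs = TRUE,
                               dg_short_sigma = 1.0) {
  if (laplace_beta <= 0 || laplace_beta > 10)
    ft_stop("laplace_beta must satisfy 0 < beta <= 10", "ft_invalid_argument")
  if (n_orientations < 4) ft_stop("n_orientations must be >= 4", "ft_invalid_argument")
  if (gaussian_sigma <= 0 || dg_sigma <= 0)
    ft_stop("sigmas must be positive", "ft_invalid_argument")
  structure(list(gaussian_sigma = gaussian_sigma, laplace_beta = laplace_beta,
                 dg_sigma = dg_sigma,
                 dg_filter_size = 2L * as.integer(ceiling(3 * dg_sigma)),
                 n_orientations = as.integer(n_orientations),
                 laplace_center = laplace_center, laplace_abs = laplace_abs,
                 dg_short_sigma = dg_short_sigma),
            class = "enhancement_config")
}

gaussian_kernel_1d <- function(sigma) {
  half <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing with mirror boundary
#'
#' @param img numeric matrix.
#' @param sigma kernel standard deviation in pixels (> 0).
#' @return smoothed matrix of the same size.
#' @export
gaussian_smooth <- function(img, sigma = 1.0) {
  check_gray_image(img)
  if (sigma <= 0) ft_stop("sigma must be > 0", "ft_invalid_argument")
  sep_conv_mirror(img, gaussian_kernel_1d(sigma))
}

#' Laplace-type sharpening kernel
#'
#' Convolves with `beta * [[0,-1,0],[-1,center,-1],[0,-1,0]]` (mirror
#' boundary). The default center of -4 follows the printed operator; note
#' that with it the response to a bright ridge is strongly negative -- the
#' enhancement chain compensates by taking the magnitude (see
#' [enhancement_config()]).
#'
#' @param img numeric matrix.
#' @param beta scale factor, 0 < beta <= 10.
#' @param center center coefficient (default -4).
#' @return filtered matrix.
#' @export
laplace_sharpen <- function(img, beta = 10.0, center = -4) {
  check_gray_image(img)
  if (beta <= 0 || beta > 10)
    ft_stop("beta must satisfy 0 < beta <= 10", "ft_invalid_argument")
  k <- beta * matrix(c(0, -1, 0, -1, center, -1, 0, -1, 0), 3, 3)
  conv2_mirror(img, k)
}

directional_gaussian_kernel <- function(angle_deg, dg_sigma, short_sigma = 1.0) {
  r <- 2L * as.integer(ceiling(3 * dg_sigma))
  # support size r; sampled on an (r+1)^2 grid so the anchor is a pixel center
  cs <- seq(-r / 2, r / 2)
  a <- angle_deg * pi / 180
  X <- matrix(cs, r + 1, r + 1, byrow = TRUE)
  Y <- matrix(cs, r + 1, r + 1)
  u <- X * cos(a) + Y * sin(a)     # along the filament axis
  v <- -X * sin(a) + Y * cos(a)
  k <- exp(-u^2 / (2 * dg_sigma^2) - v^2 / (2 * short_sigma^2))
  k / sum(k)
}

#' Directional Gaussian filter bank
#'
#' Convolves with anisotropic Gaussian kernels elongated along each of
#' `n_orientations` evenly spaced orientations in \[0, 180) and keeps the
#' per-pixel maximum, reinforcing intensity along locally straight
#' structures. Support size is `r = 2 * ceiling(3 * dg_sigma)`.
#'
#' @param img numeric matrix.
#' @param dg_sigma long-axis sigma (> 0).
#' @param n_orientations number of orientations (default 12).
#' @param short_sigma cross-axis sigma (default 1).
#' @return filtered matrix with attribute `filter_size` = r.
#' @export
directional_gaussian <- function(img, dg_sigma = 10.0, n_orientations = 12L,
                                 short_sigma = 1.0) {
  check_gray_image(img)
  if (dg_sigma <= 0) ft_stop("dg_sigma must be > 0", "ft_invalid_argument")
  angles <- seq(0, 180, length.out = n_orientations + 1L)[seq_len(n_orientations)]
  out <- matrix(-Inf, nrow(img), ncol(img))
  for (a in angles) {
    k <- directional_gaussian_kernel(a, dg_sigma, short_sigma)
    out <- pmax(out, conv2_mirror(img, k))
  }
  attr(out, "filter_size") <- 2L * as.integer(ceiling(3 * dg_sigma))
  out
}

#' Enhance a fibers image
#'
#' The full chain: Gaussian smoothing, Laplace sharpening (optionally
#' followed by a magnitude step), directional Gaussian reinforcement, then a
#' linear rescale to \[0, 1\] so downstream thresholds are scale-free.
#'
#' @param u_f fibers image (e.g. `mca_decompose(...)$fibers`).
#' @param cfg an [enhancement_config()].
#' @return the enhanced image `u_E` in \[0, 1\].
#' @export
enhance <- function(u_f, cfg = enhancement_config()) {
  check_gray_image(u_f, "u_f")
  x <- gaussian_smooth(u_f, cfg$gaussian_sigma)
  x <- laplace_sharpen(x, cfg$laplace_beta, cfg$laplace_center)
  if (isTRUE(cfg$laplace_abs)) x <- abs(x)
  x <- directional_gaussian(x, cfg$dg_sigma, cfg$n_orientations,
                            cfg$dg_short_sigma)
  rescale01(x)
}
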