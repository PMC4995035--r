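#' @keywords internal
"_PACKAGE"

#' @importFrom stats median rnorm runif sd fft nextn setNames quantile
#' @importFrom rlang abort warn
#' @importFrom tibble tibble as_tibble
NULL

# Images are plain numeric matrices m[row, col] with the first row at the top
# of the picture. Column index is the x (horizontal) axis, row index the y
# axis pointing downwards. Orientations are degrees in [0, 180) measured from
# the horizontal axis towards increasing y. External tables use 0-based pixel
# coordinates; everything internal is 1-based.

ft_stop <- function(msg, class) {
  rlang::abort(msg, class = c(class, "fibertrace_error"))
}

check_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    ft_stop(sprintf("`%s` must be a numeric matrix", arg), "ft_invalid_argument")
  }
  if (!all(is.finite(img))) {
    ft_stop(sprintf("`%s` contains non-finite pixels", arg), "ft_invalid_input")
  }
  invisible(img)
}

#' Rescale an image linearly onto [0, 1]
#'
#' Constant images map to all zeros (there is no contrast to preserve).
#'
#' @param img numeric matrix.
#' @return numeric matrix with values in \[0, 1\].
#' @export
rescale01 <- function(img) {
  rng <- range(img)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(1, abs(rng[2]))) {
    return(matrix(0, nrow(img), ncol(img)))
  }
  (img - rng[1]) / (rng[2] - rng[1])
}

# Reflect 1-based indices into 1..n (symmetric, edge pixel not repeated:
# ... 3 2 | 1 2 3 ... n | n-1 n-2 ...); whole-period reflection handles
# arbitrarily large offsets.
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  p <- 2L * (n - 1L)
  m <- ((idx - 1L) %% p + p) %% p
  ifelse(m >= n, p - m, m) + 1L
}

# Image translated so out[r, c] = img[r + dy, c + dx], mirror boundary.
shift_mirror <- function(img, dy, dx) {
  r <- reflect_index(seq_len(nrow(img)) + dy, nrow(img))
  c <- reflect_index(seq_len(ncol(img)) + dx, ncol(img))
  img[r, c, drop = FALSE]
}

# Mirror-pad by `pad` pixels on every side.
pad_mirror <- function(img, pad) {
  r <- reflect_index(seq_len(nrow(img) + 2 * pad) - pad, nrow(img))
  c <- reflect_index(seq_len(ncol(img) + 2 * pad) - pad, ncol(img))
  img[r, c, drop = FALSE]
}

crop_center <- function(img, nr, nc, pad) {
  img[pad + seq_len(nr), pad + seq_len(nc), drop = FALSE]
}

# 2-D correlation with mirror boundary. The kernel must have odd dimensions;
# its center is the anchor. Small kernels go through shift-and-add (exact),
# large ones through padded FFT.
conv2_mirror <- function(img, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  cy <- (kr + 1L) %/% 2L; cx <- (kc + 1L) %/% 2L
  if (kr * kc <= 81) {
    out <- matrix(0, nrow(img), ncol(img))
    for (i in seq_len(kr)) {
      for (j in seq_len(kc)) {
        w <- kernel[i, j]
        if (w != 0) out <- out + w * shift_mirror(img, i - cy, j - cx)
      }
    }
    return(out)
  }
  pad <- max(kr, kc) %/% 2L + 1L
  big <- pad_mirror(img, pad)
  n1 <- nextn(nrow(big), c(2, 3, 5)); n2 <- nextn(ncol(big), c(2, 3, 5))
  a <- matrix(0, n1, n2); a[seq_len(nrow(big)), seq_len(ncol(big))] <- big
  k <- matrix(0, n1, n2)
  # place kernel so that its center sits at (1, 1) modulo the torus
  ri <- ((seq_len(kr) - cy) %% n1) + 1L
  ci <- ((seq_len(kc) - cx) %% n2) + 1L
  k[ri, ci] <- kernel
  res <- Re(fft(fft(a) * fft(k), inverse = TRUE)) / (n1 * n2)
  res[pad + seq_len(nrow(img)), pad + seq_len(ncol(img)), drop = FALSE]
}

# Separable correlation with a symmetric 1-D kernel (odd length), mirror
# boundary, optionally with dilated ("a trous") taps.
sep_conv_mirror <- function(img, k1d, step = 1L) {
  half <- (length(k1d) - 1L) %/% 2L
  offs <- (seq_along(k1d) - 1L - half) * step
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(offs)) out <- out + k1d[i] * shift_mirror(img, offs[i], 0L)
  out2 <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(offs)) out2 <- out2 + k1d[i] * shift_mirror(out, 0L, offs[i])
  out2
}

# Box mean over a (2w+1) x (2w+1) window, mirror boundary.
box_mean_mirror <- function(img, w) {
  k <- rep(1 / (2 * w + 1), 2 * w + 1)
  sep_conv_mirror(img, k)
}

# Minimal circular difference between two orientations on the 180-degree axis.
angle_diff_180 <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Evaluate an expression with a private RNG stream seeded by `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
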