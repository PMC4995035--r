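# Transform dictionaries for the two-dictionary sparse decomposition.
#
# A dictionary is a list with `analysis` (image -> list of coefficient
# bands), `synthesis` (bands -> image), `thresholdable` (logical per band,
# bands excluded from thresholding carry the lowpass content), and `bands`
# (a tibble of band metadata). Both transforms here are tight (or exactly
# invertible) frames: synthesis(analysis(x)) == x to machine precision.

new_dictionary <- function(name, analysis, synthesis, thresholdable, bands) {
  structure(list(name = name, analysis = analysis, synthesis = synthesis,
                 thresholdable = thresholdable, bands = bands),
            class = "transform_dictionary")
}

#' @export
print.transform_dictionary <- function(x, ...) {
  cat("<transform_dictionary>", x$name, "-", nrow(x$bands), "bands\n")
  invisible(x)
}

# B3-spline refinement kernel of the "a trous" scheme.
.starlet_h <- c(1, 4, 6, 4, 1) / 16

#' Undecimated wavelet (starlet) dictionary
#'
#' Shift-invariant isotropic undecimated wavelet transform ("a trous" scheme
#' with the B3-spline kernel). Detail bands are differences of successive
#' smoothings, so synthesis is the plain sum of all bands and reconstruction
#' is exact. Smooth blob-like content concentrates in the coarse bands, which
#' is what makes this the artifacts dictionary of the decomposition.
#'
#' @param levels decomposition depth (>= 1). The image must satisfy
#'   `min(dim) >= 2^levels`.
#' @param wavelet kernel name; only `"b3spline"` is provided.
#' @return a `transform_dictionary`.
#' @export
udwt_dictionary <- function(levels = 4L, wavelet = "b3spline") {
  if (levels < 1) ft_stop("levels must be >= 1", "ft_invalid_argument")
  if (!identical(wavelet, "b3spline"))
    ft_stop("unsupported wavelet; available: b3spline", "ft_invalid_argument")
  levels <- as.integer(levels)
  analysis <- function(img) {
    check_gray_image(img)
    if (min(dim(img)) < 2^levels)
      ft_stop(sprintf("image too small for %d levels (need min dim >= %d)",
                      levels, 2^levels), "ft_invalid_argument")
    bands <- vector("list", levels + 1L)
    c_prev <- img
    for (j in seq_len(levels)) {
      c_j <- sep_conv_mirror(c_prev, .starlet_h, step = 2L^(j - 1L))
      bands[[j]] <- c_prev - c_j
      c_prev <- c_j
    }
    bands[[levels + 1L]] <- c_prev
    bands
  }
  synthesis <- function(bands) Reduce(`+`, bands)
  bands <- tibble::tibble(
    band = seq_len(levels + 1L),
    kind = c(rep("detail", levels), "coarse"),
    scale = c(seq_len(levels), levels)
  )
  new_dictionary("udwt", analysis, synthesis,
                 thresholdable = c(rep(TRUE, levels), FALSE), bands = bands)
}

# Raised-cosine lowpass radial profile: 1 for rho <= cut/2, 0 for rho >= cut.
.meyer_lowpass <- function(rho, cut) {
  t <- pmin(pmax(rho / cut, 0), 1)
  out <- numeric(length(t))
  out[t <= 0.5] <- 1
  mid <- t > 0.5 & t < 1
  out[mid] <- cos(pi * (t[mid] - 0.5))
  out
}

# Frequency-domain window stack for a curvelet-style directional tight frame.
build_wedge_windows <- function(nr, nc, scales, wedges) {
  fy <- c(seq(0, floor(nr / 2)), seq(-ceiling(nr / 2) + 1, -1)) / nr
  fx <- c(seq(0, floor(nc / 2)), seq(-ceiling(nc / 2) + 1, -1)) / nc
  FY <- matrix(fy, nr, nc); FX <- matrix(fx, nr, nc, byrow = TRUE)
  rho <- sqrt(FX^2 + FY^2) / 0.5              # 1 at Nyquist
  phi <- atan2(FY, FX) %% pi                  # orientation axis of the frequency
  n_dir <- scales - 1L
  lows <- lapply(seq_len(n_dir), function(j) .meyer_lowpass(rho, 2^(-j + 1)))
  windows <- list(); meta <- list()
  for (j in seq_len(n_dir)) {
    upper2 <- if (j == 1) matrix(1, nr, nc) else lows[[j - 1]]^2
    ring2 <- pmax(upper2 - lows[[j]]^2, 0)
    nw <- wedges[j]
    delta <- pi / nw
    for (l in seq_len(nw)) {
      alpha <- (l - 1) * delta
      d <- abs(phi - alpha); d <- pmin(d, pi - d)
      ang <- ifelse(d < delta, cos(pi * d / (2 * delta)), 0)
      windows[[length(windows) + 1L]] <- sqrt(ring2) * ang
      meta[[length(meta) + 1L]] <- tibble::tibble(
        scale = j, wedge = l,
        orientation_deg = (alpha * 180 / pi + 90) %% 180, kind = "wedge")
    }
  }
  windows[[length(windows) + 1L]] <- lows[[n_dir]]
  meta[[length(meta) + 1L]] <- tibble::tibble(scale = n_dir + 1L, wedge = NA_integer_,
                                              orientation_deg = NA_real_,
                                              kind = "coarse")
  list(windows = windows, meta = dplyr::bind_rows(meta))
}

#' Curvelet-style directional multiscale dictionary
#'
#' A tight frame of FFT-domain windows: Meyer-type radial rings split into
#' overlapping raised-cosine orientation wedges (opposite wedges fused so
#' coefficients describe an undirected orientation), plus one isotropic
#' lowpass band. The squared windows sum to one at every frequency, so
#' reconstruction is exact. Elongated atoms adapted to smooth curvilinear
#' edges make it the fibers dictionary of the decomposition; each wedge is
#' labelled with the spatial orientation (in degrees) of the structures it
#' responds to.
#'
#' Coefficient bands are full-size complex matrices; band metadata is in
#' `$bands` (`scale`, `wedge`, `orientation_deg`, `kind`).
#'
#' @param scales number of dyadic scales including the lowpass (>= 2).
#' @param angles_per_scale integer vector (recycled) of wedge counts per
#'   directional scale, finest first.
#' @return a `transform_dictionary`.
#' @export
curvelet_dictionary <- function(scales = 3L, angles_per_scale = c(12L, 8L)) {
  if (scales < 2) ft_stop("scales must be >= 2", "ft_invalid_argument")
  scales <- as.integer(scales)
  wedges <- rep_len(as.integer(angles_per_scale), scales - 1L)
  cache <- new.env(parent = emptyenv())
  get_windows <- function(nr, nc) {
    key <- paste(nr, nc, sep = "x")
    if (is.null(cache[[key]])) {
      if (min(nr, nc) < 2^(scales + 1))
        ft_stop(sprintf("image too small for %d scales (need min dim >= %d)",
                        scales, 2^(scales + 1)), "ft_invalid_argument")
      cache[[key]] <- build_wedge_windows(nr, nc, scales, wedges)
    }
    cache[[key]]
  }
  analysis <- function(img) {
    check_gray_image(img)
    ww <- get_windows(nrow(img), ncol(img))
    FI <- fft(img)
    lapply(ww$windows, function(w) fft(FI * w, inverse = TRUE) / length(img))
  }
  synthesis <- function(bands) {
    nr <- nrow(bands[[1]]); nc <- ncol(bands[[1]])
    ww <- get_windows(nr, nc)
    acc <- matrix(0 + 0i, nr, nc)
    for (b in seq_along(bands)) acc <- acc + fft(bands[[b]]) * ww$windows[[b]]
    Re(fft(acc, inverse = TRUE)) / (nr * nc)
  }
  meta <- build_wedge_windows(2^(scales + 1), 2^(scales + 1), scales, wedges)$meta
  new_dictionary("curvelet", analysis, synthesis,
                 thresholdable = rep(TRUE, nrow(meta)), bands = meta)
}

# Energy (sum of squared moduli) per coefficient band.
band_energies <- function(bands) {
  vapply(bands, function(b) sum(Mod(b)^2), numeric(1))
}
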