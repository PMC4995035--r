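# Independent brute-force oracles, written against the documented contracts
# only (no package internals).

# reflect a 1-based index into 1..n (symmetric boundary, edge not repeated)
oracle_reflect <- function(i, n) {
  if (n == 1) return(1L)
  while (i < 1 || i > n) {
    if (i < 1) i <- 2 - i
    if (i > n) i <- 2 * n - i
  }
  i
}

# dense spatial correlation with mirror boundary
oracle_conv2 <- function(img, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  cy <- (kr + 1) %/% 2; cx <- (kc + 1) %/% 2
  out <- matrix(0, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    acc <- 0
    for (i in seq_len(kr)) for (j in seq_len(kc)) {
      rr <- oracle_reflect(r + i - cy, nrow(img))
      cc <- oracle_reflect(c + j - cx, ncol(img))
      acc <- acc + kernel[i, j] * img[rr, cc]
    }
    out[r, c] <- acc
  }
  out
}

# nested-loop line response: mean over the s samples of the line element at
# angle theta minus the (2W+1)^2 window mean, mirror boundary
oracle_line_response <- function(u, x, y, theta_deg, s, W) {
  a <- theta_deg * pi / 180
  ks <- (seq_len(s) - 1) - (s - 1) / 2
  acc <- 0
  for (k in ks) {
    xx <- oracle_reflect(x + round(k * cos(a)), ncol(u))
    yy <- oracle_reflect(y + round(k * sin(a)), nrow(u))
    acc <- acc + u[yy, xx]
  }
  line_mean <- acc / s
  wacc <- 0
  for (dy in -W:W) for (dx in -W:W) {
    yy <- oracle_reflect(y + dy, nrow(u))
    xx <- oracle_reflect(x + dx, ncol(u))
    wacc <- wacc + u[yy, xx]
  }
  line_mean - wacc / (2 * W + 1)^2
}

# nested-loop multi-scale response, unscaled
oracle_multiscale <- function(u, W, angle_step, include_pixel_term) {
  angles <- seq(0, 180 - angle_step, by = angle_step)
  out <- matrix(0, nrow(u), ncol(u))
  for (r in seq_len(nrow(u))) for (c in seq_len(ncol(u))) {
    acc <- if (include_pixel_term) u[r, c] else 0
    for (s in seq_len(W)) {
      best <- -Inf
      for (th in angles)
        best <- max(best, oracle_line_response(u, c, r, th, s, W))
      acc <- acc + best
    }
    out[r, c] <- acc / (W + 1)
  }
  out
}

# pixel-set confusion counts by direct set comparison (tolerance 0)
oracle_confusion <- function(pred, truth) {
  p <- which(pred); t <- which(truth)
  TP <- length(intersect(p, t))
  FP <- length(setdiff(p, t))
  FN <- length(setdiff(t, p))
  c(TP = TP, FP = FP, TN = length(truth) - TP - FP - FN, FN = FN)
}

# pixels within distance w/2 of the segment from p0 to p1 (brute force)
oracle_stroke_mask <- function(shape, p0, p1, width) {
  m <- matrix(FALSE, shape[1], shape[2])
  v <- p1 - p0
  L2 <- sum(v^2)
  for (r in seq_len(shape[1])) for (c in seq_len(shape[2])) {
    t <- if (L2 == 0) 0 else ((c - p0[1]) * v[1] + (r - p0[2]) * v[2]) / L2
    t <- min(max(t, 0), 1)
    d <- sqrt((c - (p0[1] + t * v[1]))^2 + (r - (p0[2] + t * v[2]))^2)
    if (d <= width / 2) m[r, c] <- TRUE
  }
  m
}

make_line_image <- function(shape, angle_deg, length_px = 80, width_px = 2,
                            intensity = 1) {
  specs <- filament_specs(shape[2] / 2, shape[1] / 2, angle_deg, length_px,
                          width_px, intensity)
  rasterize_filaments(specs, shape)
}

# small standard scene used across tests
make_test_scene <- function(seed = 5, shape = c(128, 128), n = 4,
                            noise_sigma = 0.04, n_blobs = 3, ...) {
  specs <- random_filaments(n, shape = shape, length_range = c(50, 80),
                            min_sep = 14, seed = seed, ...)
  compose_scene(specs, shape, n_blobs = n_blobs, noise_sigma = noise_sigma,
                seed = seed + 100)
}
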