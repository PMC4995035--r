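#' Build a table of filament specifications
#'
#' A filament is a quasi-straight bright stroke: a centerline of given
#' orientation and length, with an optional small per-pixel angular drift
#' (`curvature_deg_px`) that bends it gently, rendered with a flat intensity
#' profile across its width. Stress fibers in phalloidin-stained micrographs
#' are piecewise compositions of such strokes.
#'
#' @param cx,cy centerline midpoint, 1-based pixel coordinates.
#' @param angle_deg orientation in \[0, 180) from the image horizontal axis.
#' @param length_px centerline length in pixels (>= 1).
#' @param width_px stroke width in pixels (>= 1).
#' @param intensity peak intensity in (0, 1\].
#' @param curvature_deg_px angular drift per pixel of arc length; limited so
#'   total drift over the filament stays within 20 degrees.
#' @return a `tbl_df` with one row per filament and class `filament_spec`.
#' @export
filament_specs <- function(cx, cy, angle_deg, length_px, width_px = 3,
                           intensity = 1, curvature_deg_px = 0) {
  spec <- tibble::tibble(
    id = seq_along(cx), cx = cx, cy = cy,
    angle_deg = angle_deg %% 180,
    length_px = length_px,
    width_px = rep_len(width_px, length(cx)),
    intensity = rep_len(intensity, length(cx)),
    curvature_deg_px = rep_len(curvature_deg_px, length(cx))
  )
  if (nrow(spec)) {
    if (any(spec$length_px < 1)) ft_stop("length_px must be >= 1", "ft_invalid_argument")
    if (any(spec$width_px < 1)) ft_stop("width_px must be >= 1", "ft_invalid_argument")
    if (any(spec$intensity <= 0 | spec$intensity > 1))
      ft_stop("intensity must lie in (0, 1]", "ft_invalid_argument")
    drift <- abs(spec$curvature_deg_px) * spec$length_px
    if (any(drift > 20))
      ft_stop("total angular drift exceeds 20 degrees; reduce curvature_deg_px",
              "ft_invalid_argument")
  }
  class(spec) <- c("filament_spec", class(spec))
  spec
}

# Dense sample points along one (possibly gently curved) centerline.
filament_polyline <- function(cx, cy, angle_deg, length_px, curvature_deg_px = 0,
                              step = 0.25) {
  ts <- seq(-length_px / 2, length_px / 2, by = step)
  if (curvature_deg_px == 0) {
    a <- angle_deg * pi / 180
    cbind(x = cx + ts * cos(a), y = cy + ts * sin(a))
  } else {
    # integrate heading theta(t) = angle + curvature * t from the midpoint out
    a <- (angle_deg + curvature_deg_px * ts) * pi / 180
    dx <- cos(a) * step; dy <- sin(a) * step
    mid <- which.min(abs(ts))
    x <- cumsum(dx) - sum(dx[seq_len(mid)]) + cx
    y <- cumsum(dy) - sum(dy[seq_len(mid)]) + cy
    cbind(x = x, y = y)
  }
}

#' Rasterize filaments into a ground-truth image and mask
#'
#' Renders each filament as an anti-aliased stroke whose intensity profile is
#' flat across the width (the downstream line detector assumes near-uniform
#' brightness over the stroke). The truth mask is the set of pixels whose
#' distance to a centerline is at most `width_px / 2`.
#'
#' @param specs a [filament_specs()] table (may be empty).
#' @param shape `c(nrow, ncol)` image dimensions.
#' @return list with `image` (numeric matrix in \[0,1\]) and `mask` (logical).
#' @export
rasterize_filaments <- function(specs, shape) {
  if (length(shape) != 2 || any(shape < 1))
    ft_stop("shape must be two positive integers", "ft_invalid_argument")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  img <- matrix(0, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  if (is.null(specs) || nrow(specs) == 0) return(list(image = img, mask = mask))

  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    pts <- filament_polyline(s$cx, s$cy, s$angle_deg, s$length_px,
                             s$curvature_deg_px)
    halfw <- s$width_px / 2
    reach <- ceiling(halfw + 1.5)
    # distance field on the filament's bounding box, stamped sample by sample
    r0 <- max(1L, floor(min(pts[, "y"]) - reach))
    r1 <- min(nr, ceiling(max(pts[, "y"]) + reach))
    c0 <- max(1L, floor(min(pts[, "x"]) - reach))
    c1 <- min(nc, ceiling(max(pts[, "x"]) + reach))
    if (r1 < r0 || c1 < c0) next
    bh <- r1 - r0 + 1L; bw <- c1 - c0 + 1L
    d2 <- matrix(Inf, bh, bw)
    win <- seq(-reach, reach)
    for (k in seq_len(nrow(pts))) {
      px <- pts[k, "x"]; py <- pts[k, "y"]
      rr <- round(py) + win - r0 + 1
      cc <- round(px) + win - c0 + 1
      ok_r <- rr >= 1 & rr <= bh; ok_c <- cc >= 1 & cc <= bw
      if (!any(ok_r) || !any(ok_c)) next
      yy <- (rr[ok_r] + r0 - 1) - py
      xx <- (cc[ok_c] + c0 - 1) - px
      local <- outer(yy^2, xx^2, `+`)
      sub <- d2[rr[ok_r], cc[ok_c], drop = FALSE]
      d2[rr[ok_r], cc[ok_c]] <- pmin(sub, local)
    }
    d <- sqrt(d2)
    cov <- pmin(pmax(halfw + 0.5 - d, 0), 1)      # anti-aliased flat profile
    img[r0:r1, c0:c1] <- pmax(img[r0:r1, c0:c1], s$intensity * cov)
    mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | (d <= halfw)
  }
  list(image = img, mask = mask)
}

#' Generate a smooth blob-like artifact image
#'
#' Background artifacts in cytoskeleton micrographs (out-of-focus haze,
#' staining deposits) lack the elongated geometry of fibers. They are
#' emulated as a sum of isotropic Gaussian blobs with standard deviations
#' drawn from `sigma_range`; the result carries no straight ridge of
#' appreciable length.
#'
#' @param shape `c(nrow, ncol)`.
#' @param n_blobs number of blobs (>= 0).
#' @param seed RNG seed (determinism contract).
#' @param sigma_range blob standard deviation range in pixels.
#' @param amplitude_range per-blob peak amplitude range.
#' @return numeric matrix, non-negative, clipped to \[0, 1\].
#' @export
generate_artifacts <- function(shape, n_blobs, seed = 1L,
                               sigma_range = c(5, 20),
                               amplitude_range = c(0.1, 0.4)) {
  if (n_blobs < 0) ft_stop("n_blobs must be >= 0", "ft_invalid_argument")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  img <- matrix(0, nr, nc)
  if (n_blobs == 0) return(img)
  with_seed(seed, {
    # rejection-sample centers so blobs stay clearly apart: summed
    # overlapping Gaussians would form elongated ridges, violating the
    # defining isotropic (non-fiber-like) geometry of these artifacts
    xs <- ys <- sg <- am <- numeric(0)
    tries <- 0L
    while (length(xs) < n_blobs && tries < 2000L) {
      tries <- tries + 1L
      x <- runif(1, 1, nc); y <- runif(1, 1, nr)
      s <- runif(1, sigma_range[1], sigma_range[2])
      if (length(xs) &&
          any(sqrt((xs - x)^2 + (ys - y)^2) < 1.5 * (sg + s))) next
      xs <- c(xs, x); ys <- c(ys, y); sg <- c(sg, s)
      am <- c(am, runif(1, amplitude_range[1], amplitude_range[2]))
    }
    n_blobs <- length(xs)
    for (b in seq_len(n_blobs)) {
      gy <- exp(-((seq_len(nr) - ys[b])^2) / (2 * sg[b]^2))
      gx <- exp(-((seq_len(nc) - xs[b])^2) / (2 * sg[b]^2))
      img <- img + am[b] * (gy %o% gx)
    }
  })
  pmin(img, 1)
}

#' Compose a ground-truthed synthetic scene
#'
#' Builds `composite = clip(u + v + eta, 0, 1)` where `u` is the rasterized
#' filament image, `v` a smooth blob artifact image and `eta` i.i.d. Gaussian
#' noise of standard deviation `noise_sigma` (the reference construction uses
#' sigma = 0.04). An optional Gaussian blur of `u` before composition
#' emulates out-of-focus filaments.
#'
#' @param specs [filament_specs()] table (may be empty).
#' @param shape image dimensions `c(nrow, ncol)`.
#' @param n_blobs number of artifact blobs.
#' @param noise_sigma Gaussian noise standard deviation (>= 0).
#' @param seed RNG seed controlling artifacts and noise.
#' @param blur_sigma optional defocus blur applied to `u` (0 = none).
#' @param background constant background level folded into the artifacts
#'   image (camera offset / diffuse fluorescence; default 0.1). It keeps the
#'   additive noise clear of the zero clip.
#' @param sigma_range,amplitude_range forwarded to [generate_artifacts()].
#' @return a `synthetic_scene` list: `composite`, `truth_image`,
#'   `artifacts_image`, `truth_mask`, `truth_fibers`, `noise_sigma`, `seed`.
#' @export
compose_scene <- function(specs, shape = c(256, 256), n_blobs = 6,
                          noise_sigma = 0.04, seed = 1L, blur_sigma = 0,
                          background = 0.1, sigma_range = c(5, 20),
                          amplitude_range = c(0.1, 0.4)) {
  if (noise_sigma < 0) ft_stop("noise_sigma must be >= 0", "ft_invalid_argument")
  ras <- rasterize_filaments(specs, shape)
  u <- ras$image
  if (blur_sigma > 0) u <- gaussian_smooth(u, blur_sigma)
  v <- generate_artifacts(shape, n_blobs, seed = seed,
                          sigma_range = sigma_range,
                          amplitude_range = amplitude_range)
  v <- pmin(v + background, 1)
  eta <- if (noise_sigma > 0) {
    with_seed(seed + 1L, matrix(rnorm(prod(shape), 0, noise_sigma),
                                shape[1], shape[2]))
  } else matrix(0, shape[1], shape[2])
  f <- pmin(pmax(u + v + eta, 0), 1)
  structure(list(
    composite = f, truth_image = u, artifacts_image = v,
    truth_mask = ras$mask,
    truth_fibers = if (is.null(specs)) filament_specs(numeric(), numeric(),
                                                      numeric(), numeric()) else specs,
    noise_sigma = noise_sigma, seed = seed
  ), class = "synthetic_scene")
}

#' Place n straight, well-separated filaments at random
#'
#' Convenience generator for recovery experiments: filaments are laid out
#' with rejection sampling so that centerlines keep at least `min_sep` pixels
#' apart, giving unambiguous one-to-one ground truth.
#'
#' @param n number of filaments.
#' @param shape image dimensions.
#' @param length_range,width_range,intensity_range per-filament draws.
#' @param min_sep minimal distance between any two centerline sample points.
#' @param seed RNG seed.
#' @param margin keep-out border in pixels.
#' @return a [filament_specs()] table.
#' @export
random_filaments <- function(n, shape = c(256, 256), length_range = c(60, 100),
                             width_range = c(2, 6), intensity_range = c(0.6, 1),
                             min_sep = 10, seed = 1L, margin = 12) {
  with_seed(seed, {
    placed <- list(); pts_all <- NULL; tries <- 0L
    while (length(placed) < n && tries < 4000L) {
      tries <- tries + 1L
      len <- runif(1, length_range[1], length_range[2])
      ang <- runif(1, 0, 180)
      wid <- runif(1, width_range[1], width_range[2])
      # center placement bounds; on small canvases long filaments may touch
      # the margin (the rasterizer clips at the domain)
      bx <- sort(c(margin + len / 2, shape[2] - margin - len / 2))
      by <- sort(c(margin + len / 2, shape[1] - margin - len / 2))
      cx <- runif(1, bx[1], bx[2])
      cy <- runif(1, by[1], by[2])
      pts <- filament_polyline(cx, cy, ang, len, 0, step = 2)
      if (!is.null(pts_all)) {
        dmin <- min(sqrt(outer(pts[, "y"], pts_all[, "y"], `-`)^2 +
                         outer(pts[, "x"], pts_all[, "x"], `-`)^2))
        if (dmin < min_sep) next
      }
      placed[[length(placed) + 1L]] <- c(cx, cy, ang, len, wid,
                                         runif(1, intensity_range[1], intensity_range[2]))
      pts_all <- rbind(pts_all, pts)
    }
    m <- do.call(rbind, placed)
    filament_specs(cx = m[, 1], cy = m[, 2], angle_deg = m[, 3],
                   length_px = m[, 4], width_px = m[, 5], intensity = m[, 6])
  })
}

#' Write a synthetic scene to disk
#'
#' Composite, truth and artifact images go out as 16-bit TIFF, the mask as
#' PNG, and the ground-truth fiber list as CSV.
#'
#' @param scene a [compose_scene()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, a named character vector of the written paths.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    composite = file.path(dir, "composite.tif"),
    truth = file.path(dir, "truth.tif"),
    artifacts = file.path(dir, "artifacts.tif"),
    mask = file.path(dir, "truth_mask.png"),
    fibers = file.path(dir, "truth_fibers.csv")
  )
  write_gray_image(scene$composite, paths["composite"])
  write_gray_image(scene$truth_image, paths["truth"])
  write_gray_image(scene$artifacts_image, paths["artifacts"])
  png::writePNG(scene$truth_mask * 1, paths["mask"])
  tf <- scene$truth_fibers
  utils::write.csv(
    data.frame(id = tf$id, cx = tf$cx - 1, cy = tf$cy - 1,
               angle_deg = tf$angle_deg, length_px = tf$length_px,
               width_px = tf$width_px, intensity = tf$intensity),
    paths["fibers"], row.names = FALSE)
  invisible(paths)
}
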