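test_that("rasterization handles the empty and degenerate cases", {
  r <- rasterize_filaments(filament_specs(numeric(), numeric(), numeric(),
                                          numeric()), c(128, 128))
  expect_equal(r$image, matrix(0, 128, 128))
  expect_false(any(r$mask))
  expect_error(rasterize_filaments(NULL, c(0, 10)), class = "ft_invalid_argument")
})

test_that("a horizontal stroke has the expected mask footprint", {
  r <- rasterize_filaments(filament_specs(64, 64, 0, 100, 3), c(128, 128))
  # oracle: pixels within 1.5 px of the centerline segment
  o <- oracle_stroke_mask(c(128, 128), c(64 - 50, 64), c(64 + 50, 64), 3)
  expect_lt(abs(sum(r$mask) - 300) / 300, 0.10)
  expect_equal(r$mask, o)
})

test_that("rotating a stroke by 90 degrees transposes the rasterization", {
  h <- rasterize_filaments(filament_specs(64, 64, 0, 100, 3), c(128, 128))
  v <- rasterize_filaments(filament_specs(64, 64, 90, 100, 3), c(128, 128))
  expect_identical(v$mask, t(h$mask))
  expect_equal(v$image, t(h$image))
})

test_that("filament spec validation enforces the quasi-straight contract", {
  expect_error(filament_specs(10, 10, 0, 0.5), class = "ft_invalid_argument")
  expect_error(filament_specs(10, 10, 0, 50, width_px = 0.5),
               class = "ft_invalid_argument")
  expect_error(filament_specs(10, 10, 0, 100, curvature_deg_px = 0.5),
               class = "ft_invalid_argument")  # 50 deg total drift
  expect_silent(filament_specs(64, 64, 10, 80, curvature_deg_px = 0.2))
})

test_that("artifact generation is deterministic, smooth and blob-like", {
  expect_equal(generate_artifacts(c(128, 128), 0), matrix(0, 128, 128))
  a1 <- generate_artifacts(c(128, 128), 5, seed = 42)
  a2 <- generate_artifacts(c(128, 128), 5, seed = 42)
  expect_identical(a1, a2)
  expect_true(all(a1 >= 0) && all(a1 <= 1))
  # no straight ridge longer than 10 px: skeletonize the thresholded blobs
  # and measure the longest branch
  th <- a1 > 0.5 * max(a1)
  skel <- thin_mask(th)
  chains <- skeletonize_and_trace(th)
  if (length(chains)) {
    longest <- max(vapply(chains, function(ch)
      sqrt(sum((ch[nrow(ch), ] - ch[1, ])^2)), numeric(1)))
    expect_lte(longest, 10)
  }
  expect_true(TRUE)
})

test_that("scene composition obeys the additive model", {
  specs <- filament_specs(c(40, 90), c(40, 90), c(30, 120), c(50, 50))
  sc0 <- compose_scene(specs, c(128, 128), n_blobs = 3, noise_sigma = 0,
                       seed = 3)
  raw <- sc0$truth_image + sc0$artifacts_image
  expect_equal(sc0$composite, pmin(pmax(raw, 0), 1))
  # where no clipping occurred the decomposition is exact
  ok <- raw > 0 & raw < 1
  expect_equal(sc0$composite[ok], raw[ok])

  sc <- compose_scene(specs, c(128, 128), n_blobs = 3, noise_sigma = 0.04,
                      seed = 3)
  eta <- sc$composite - sc$truth_image - sc$artifacts_image
  noclip <- sc$composite > 0 & sc$composite < 1
  expect_lt(abs(sd(eta[noclip]) - 0.04), 0.005)
  expect_error(compose_scene(specs, c(128, 128), noise_sigma = -1),
               class = "ft_invalid_argument")
})

test_that("an empty spec list with artifacts off gives pure noise", {
  sc <- compose_scene(filament_specs(numeric(), numeric(), numeric(), numeric()),
                      c(64, 64), n_blobs = 0, noise_sigma = 0.04,
                      background = 0, seed = 9)
  expect_false(any(sc$truth_mask))
  expect_equal(sc$truth_image, matrix(0, 64, 64))
  expect_gt(sd(sc$composite), 0.01)
})

test_that("scenes are byte-identical under a fixed seed", {
  specs <- random_filaments(5, c(128, 128), seed = 8)
  s1 <- compose_scene(specs, c(128, 128), seed = 4)
  s2 <- compose_scene(specs, c(128, 128), seed = 4)
  expect_identical(s1$composite, s2$composite)
})

test_that("truth angles agree with the principal axis of their own mask", {
  specs <- random_filaments(6, c(160, 160), seed = 21)
  for (i in seq_len(nrow(specs))) {
    r <- rasterize_filaments(specs[i, ], c(160, 160))
    idx <- which(r$mask, arr.ind = TRUE)
    xs <- idx[, 2] - mean(idx[, 2]); ys <- idx[, 1] - mean(idx[, 1])
    ang <- (0.5 * atan2(2 * sum(xs * ys), sum(xs^2) - sum(ys^2)) * 180 / pi) %% 180
    d <- abs(ang - specs$angle_deg[i]) %% 180
    expect_lt(min(d, 180 - d), 1)
  }
})

test_that("scene serialization writes the documented files", {
  specs <- random_filaments(3, c(96, 96), seed = 2)
  sc <- compose_scene(specs, c(96, 96), seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_scene(sc, dir)
  expect_true(all(file.exists(paths)))
  tf <- utils::read.csv(paths["fibers"])
  expect_equal(nrow(tf), 3)
  back <- read_gray_image(paths[["composite"]])
  expect_lt(max(abs(back - sc$composite)), 1 / 65535 + 1e-9)
})
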