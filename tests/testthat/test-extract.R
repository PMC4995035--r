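test_that("a filled bar traces to a single full-length chain", {
  mask <- matrix(FALSE, 40, 120)
  mask[19:21, 11:110] <- TRUE
  chains <- skeletonize_and_trace(mask)
  expect_equal(length(chains), 1)
  expect_lt(abs(nrow(chains[[1]]) - 100), 3 + 1)
  expect_identical(skeletonize_and_trace(matrix(FALSE, 16, 16)), list())
})

test_that("a plus sign splits into four branch chains at the junction", {
  mask <- matrix(FALSE, 61, 61)
  mask[30:32, 6:56] <- TRUE
  mask[6:56, 30:32] <- TRUE
  chains <- skeletonize_and_trace(mask)
  long <- Filter(function(ch) nrow(ch) >= 5, chains)
  expect_equal(length(long), 4)
  # chains are disjoint: no pixel in more than one chain
  all_px <- do.call(rbind, chains)
  expect_false(any(duplicated(all_px)))
})

test_that("segment fitting recovers straight chains and splits corners", {
  ch30 <- fibertrace:::filament_polyline(60, 60, 30, 100, step = 1)
  ch30 <- unique(round(ch30))
  segs <- fit_segments(ch30, L = 30)
  expect_equal(nrow(segs), 1)
  expect_lt(fibertrace:::angle_diff_180(segs$theta_deg, 30), 1)

  short <- cbind(x = 1:20, y = rep(5, 20))
  expect_equal(nrow(fit_segments(short, L = 30)), 0)

  elbow <- rbind(cbind(x = 10:59, y = 10),       # horizontal arm, 50 px
                 cbind(x = 60, y = 11:60))       # vertical arm, 50 px
  segs2 <- fit_segments(elbow, L = 30)
  expect_equal(nrow(segs2), 2)
  expect_lt(abs(fibertrace:::angle_diff_180(segs2$theta_deg[1], segs2$theta_deg[2]) - 90), 2)
})

test_that("segments respect the perpendicular error bound", {
  set.seed(5)
  # a gently curved chain must be split so each piece stays within 1 px
  ch <- fibertrace:::filament_polyline(80, 80, 20, 140, curvature_deg_px = 0.12, step = 1)
  ch <- unique(round(ch))
  segs <- fit_segments(ch, L = 30)
  expect_gt(nrow(segs), 0)
  for (i in seq_len(nrow(segs)))
    expect_lte(segs$max_fit_err[i], 1 + 1e-9)
})

test_that("endpoint overlap is symmetric and boundary inclusive", {
  a <- cbind(x = 1:30, y = 1)
  b <- cbind(x = 30:60, y = 1)
  expect_true(overlap_endpoints(a, b, 2))
  far <- cbind(x = 1:30, y = 51)
  expect_false(overlap_endpoints(a, far, 2))
  c2 <- cbind(x = 10:40, y = 3)     # endpoint of a at (30,1): distance 2 to b chain
  expect_true(overlap_endpoints(a, c2, 2))
  c3 <- cbind(x = 10:40, y = 4)
  expect_false(overlap_endpoints(a, c3, 2))
})

make_seg <- function(x, y, angle_deg, len, id = 1L) {
  px <- unique(round(fibertrace:::filament_polyline(x, y, angle_deg, len, step = 1)))
  fit_segments(px, L = 0.9 * len, chain_id = id)
}

test_that("collinear overlapping segments merge into one spanning fiber", {
  s1 <- make_seg(30, 40, 40, 40, 1L)
  s2 <- make_seg(60, 65, 40, 40, 2L)   # continues along the same line
  segs <- dplyr::bind_rows(s1, s2); segs$seg_id <- 1:2
  fib <- merge_fibers(segs, merge_config(T_theta = 0, overlap_tol_px = 3))
  expect_equal(nrow(fib), 1)
  expect_lt(fibertrace:::angle_diff_180(fib$theta_deg, 40), 1.5)
  span <- sqrt((fib$x1 - fib$x0)^2 + (fib$y1 - fib$y0)^2)
  expect_gt(span, 65)
})

test_that("the merged orientation is the delta-weighted mean", {
  # deltas 10 and 30 at 0 and 4 degrees -> (10*0 + 30*4)/40 = 3
  a <- cbind(x = seq(0, 10), y = 0)
  b_pts <- fibertrace:::filament_polyline(10 + 15 * cos(4 * pi / 180), 15 * sin(4 * pi / 180) + 0,
                             4, 30, step = 1)
  segs <- tibble::tibble(
    chain_id = 1:2, theta_deg = c(0, 4), length_px = c(10, 30),
    n_pixels = c(nrow(a), nrow(b_pts)),
    x0 = c(0, b_pts[1, 1]), y0 = c(0, b_pts[1, 2]),
    x1 = c(10, b_pts[nrow(b_pts), 1]), y1 = c(10, b_pts[nrow(b_pts), 2]),
    max_fit_err = 0, pixels = list(unname(a), unname(b_pts)), seg_id = 1:2)
  fib <- merge_fibers(segs, merge_config(T_theta = 4, overlap_tol_px = 3))
  expect_equal(nrow(fib), 1)
  expect_equal(fib$theta_deg, 3.0, tolerance = 1e-8)
})

test_that("segments beyond the angle tolerance stay separate", {
  s1 <- make_seg(30, 30, 0, 40, 1L)
  s2 <- make_seg(48, 32, 10, 40, 2L)
  segs <- dplyr::bind_rows(s1, s2); segs$seg_id <- 1:2
  fib <- merge_fibers(segs, merge_config(T_theta = 2, overlap_tol_px = 5))
  expect_equal(nrow(fib), 2)
})

test_that("merging is idempotent and monotone in the angle tolerance", {
  sc <- make_test_scene(seed = 23, shape = c(160, 160), n = 5,
                        n_blobs = 0, noise_sigma = 0)
  uB <- wellner_binarize(multiscale_response(enhance(sc$truth_image)))
  segs <- extract_segments(uB)
  n_prev <- Inf
  for (tt in c(0, 2, 5)) {
    fib <- merge_fibers(segs, merge_config(T_theta = tt))
    expect_lte(nrow(fib), n_prev)
    n_prev <- nrow(fib)
    again <- merge_fibers(fib, merge_config(T_theta = tt))
    expect_equal(nrow(again), nrow(fib))
    expect_equal(again$theta_deg, fib$theta_deg)
  }
})

test_that("fiber pixels originate from segments without duplication", {
  sc <- make_test_scene(seed = 29, shape = c(160, 160), n = 5,
                        n_blobs = 0, noise_sigma = 0)
  uB <- wellner_binarize(multiscale_response(enhance(sc$truth_image)))
  segs <- extract_segments(uB)
  fib <- merge_fibers(segs, merge_config(T_theta = 2))
  seg_px <- do.call(rbind, segs$pixels)
  fib_px <- do.call(rbind, fib$pixels)
  expect_false(any(duplicated(fib_px)))
  key <- function(m) paste(m[, 1], m[, 2])
  expect_true(all(key(fib_px) %in% key(seg_px)))
})

test_that("well-separated straight fibers are recovered one-to-one", {
  specs <- random_filaments(6, c(192, 192), length_range = c(70, 100),
                            min_sep = 16, seed = 31)
  sc <- compose_scene(specs, c(192, 192), n_blobs = 0, noise_sigma = 0,
                      seed = 31)
  uB <- wellner_binarize(multiscale_response(enhance(sc$composite)))
  fib <- merge_fibers(extract_segments(uB), merge_config())
  m <- match_fibers(fib, specs)
  expect_true(all(m$matched))
  expect_lt(max(m$angle_err_deg), 2)
})
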