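test_that("a constant image has zero line response everywhere", {
  u <- matrix(0.5, 24, 24)
  for (s in 1:4)
    expect_equal(line_response_R(u, 12, 12, 45, s, 4), 0)
  raw <- multiscale_response(u, line_response_config(include_pixel_term = FALSE),
                             rescale = FALSE)
  expect_equal(raw, matrix(0, 24, 24))
})

test_that("a bright line maximizes the response along its own angle", {
  img <- make_line_image(c(31, 31), 0, 21, 1)$image
  angles <- seq(0, 165, by = 15)
  rs <- vapply(angles, function(th)
    line_response_R(img, 16, 16, th, 4, 4), numeric(1))
  expect_equal(angles[which.max(rs)], 0)
})

test_that("the response field matches the nested-loop oracle to 1e-10", {
  set.seed(7)
  u <- matrix(runif(16 * 16), 16)
  cfg <- line_response_config(W = 3, angle_step_deg = 30)
  got <- multiscale_response(u, cfg, rescale = FALSE)
  want <- oracle_multiscale(u, 3, 30, TRUE)
  expect_lt(max(abs(got - want)), 1e-10)
  # single-point evaluator agrees with the oracle at every pixel/theta/s
  for (x in c(1, 7, 16)) for (y in c(1, 9, 16))
    for (th in c(0, 30, 150)) for (s in 1:3)
      expect_lt(abs(line_response_R(u, x, y, th, s, 3) -
                    oracle_line_response(u, x, y, th, s, 3)), 1e-10)
})

test_that("W = 1 reduces to the single-scale formula", {
  set.seed(8)
  u <- matrix(runif(20 * 20), 20)
  cfg <- line_response_config(W = 1, include_pixel_term = FALSE)
  got <- multiscale_response(u, cfg, rescale = FALSE)
  win <- oracle_conv2(u, matrix(1 / 9, 3, 3))
  expect_lt(max(abs(got - (u - win) / 2)), 1e-10)  # best theta is the pixel itself at s = 1
})

test_that("adaptive thresholding empties constants and keeps bright lines", {
  expect_false(any(wellner_binarize(matrix(0.5, 64, 64))))
  expect_false(any(wellner_binarize(matrix(0.5, 64, 64),
                                    threshold_config(b = 2))))
  img <- make_line_image(c(96, 96), 30, 60, 3)
  uG <- multiscale_response(enhance(img$image))
  mask <- wellner_binarize(uG)
  centre <- img$mask & fibertrace:::dist_to_mask(!img$mask) >= 1.5
  expect_gt(mean(mask[centre]), 0.95)          # line pixels retained
  far <- fibertrace:::dist_to_mask(img$mask) > 10
  expect_equal(sum(mask & far), 0)             # far background empty
})

test_that("lowering b retains monotonically more foreground", {
  sc <- make_test_scene(seed = 19, shape = c(96, 96), n = 3)
  uG <- multiscale_response(enhance(sc$truth_image))
  counts <- vapply(c(1, 0.5, 0.3, 0.1), function(b)
    sum(wellner_binarize(uG, threshold_config(b = b, min_component_px = 1L))),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("threshold configuration is validated", {
  expect_error(threshold_config(b = 0), class = "ft_invalid_argument")
  expect_error(threshold_config(median_window = 4), class = "ft_invalid_argument")
  expect_error(line_response_config(W = 0), class = "ft_invalid_argument")
  expect_error(line_response_config(angle_step_deg = 25),
               class = "ft_invalid_argument")
  expect_error(wellner_binarize(matrix(2, 8, 8)), class = "ft_invalid_argument")
})
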