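test_that("decomposing a zero image yields zero components", {
  d <- mca_decompose(matrix(0, 64, 64), cfg = mca_config(n_iter = 5))
  expect_equal(d$fibers, matrix(0, 64, 64))
  expect_equal(d$artifacts, matrix(0, 64, 64))
  expect_equal(d$residual, matrix(0, 64, 64))
})

test_that("components and residual reconstruct the input exactly", {
  sc <- make_test_scene(seed = 3, shape = c(96, 96))
  d <- mca_decompose(sc$composite, cfg = mca_config(n_iter = 10))
  expect_identical(sc$composite - d$fibers - d$artifacts, d$residual)
  expect_equal(d$fibers + d$artifacts + d$residual, sc$composite,
               tolerance = 1e-14)
  # bitwise reproducible
  d2 <- mca_decompose(sc$composite, cfg = mca_config(n_iter = 10))
  expect_identical(d$fibers, d2$fibers)
})

test_that("invalid decomposition inputs are rejected", {
  expect_error(mca_config(n_iter = 0), class = "ft_invalid_argument")
  expect_error(mca_config(p = 2), class = "ft_invalid_argument")
  bad <- matrix(0, 64, 64); bad[1, 1] <- NA
  expect_error(mca_decompose(bad, cfg = mca_config(n_iter = 2)),
               class = "ft_invalid_input")
})

test_that("a clean line image lands almost entirely in the fibers component", {
  sc <- compose_scene(random_filaments(3, c(96, 96), length_range = c(40, 60),
                                       seed = 4),
                      c(96, 96), n_blobs = 0, noise_sigma = 0, background = 0,
                      seed = 4)
  d <- mca_decompose(sc$composite, cfg = mca_config(n_iter = 50))
  e_in <- sum(sc$composite^2)
  expect_gt(sum(d$fibers^2) / e_in, 0.8)
  expect_lt(sum(d$artifacts^2) / e_in, 0.1)
})

test_that("decomposition improves correlation with the true line image", {
  sc <- make_test_scene(seed = 6, shape = c(128, 128), n = 5)
  d <- mca_decompose(sc$composite, cfg = mca_config(n_iter = 60))
  u <- as.vector(sc$truth_image)
  expect_gt(cor(as.vector(d$fibers), u), cor(as.vector(sc$composite), u))
})

test_that("swapping the dictionaries degrades the fibers estimate", {
  sc <- make_test_scene(seed = 6, shape = c(128, 128), n = 5)
  cfg <- mca_config(n_iter = 40)
  good <- mca_decompose(sc$composite, cfg = cfg)
  swapped <- mca_decompose(sc$composite, d_f = udwt_dictionary(),
                           d_a = curvelet_dictionary(), cfg = cfg)
  u <- as.vector(sc$truth_image)
  expect_gt(cor(as.vector(good$fibers), u), cor(as.vector(swapped$fibers), u))
})

test_that("iterating longer keeps removing blob content from u_f", {
  sc <- make_test_scene(seed = 9, shape = c(128, 128), n = 5)
  # blob territory: bright artifact regions well clear of any filament
  blob <- sc$artifacts_image > 0.2 & fibertrace:::dist_to_mask(sc$truth_mask) > 8
  expect_gt(sum(blob), 100)
  e_in <- sum(sc$composite[blob]^2)
  e_blob <- vapply(c(10L, 100L), function(it) {
    d <- mca_decompose(sc$composite, cfg = mca_config(n_iter = it))
    sum(d$fibers[blob]^2)
  }, numeric(1))
  # near-complete rejection of blob content, and no growth with iterations
  expect_lt(e_blob[2], 0.05 * e_in)
  expect_lte(e_blob[2], e_blob[1] * 1.05 + 1e-3 * e_in)
})

test_that("noise sigma estimation is calibrated and scale-equivariant", {
  expect_equal(estimate_noise_sigma(matrix(0, 64, 64)), 0)
  set.seed(11)
  noise <- matrix(rnorm(256 * 256, 0, 0.04), 256)
  s1 <- estimate_noise_sigma(noise)
  expect_gt(s1, 0.03); expect_lt(s1, 0.05)
  expect_lt(abs(estimate_noise_sigma(2 * noise) - 2 * s1), 1e-9)
})

test_that("tidy and glance summarize a decomposition", {
  sc <- make_test_scene(seed = 3, shape = c(96, 96))
  d <- mca_decompose(sc$composite, cfg = mca_config(n_iter = 5))
  td <- tidy(d)
  expect_equal(td$component, c("fibers", "artifacts", "residual"))
  expect_equal(sum(td$energy_fraction), 1)
  expect_equal(glance(d)$n_iter, 5L)
})
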