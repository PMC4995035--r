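test_that("confusion counts reduce to set comparison at zero tolerance", {
  set.seed(2)
  for (i in 1:5) {
    pred <- matrix(runif(48 * 64) < 0.2, 48, 64)
    truth <- matrix(runif(48 * 64) < 0.1, 48, 64)
    got <- confusion_counts(pred, truth)
    want <- oracle_confusion(pred, truth)
    expect_equal(c(TP = got$TP, FP = got$FP, TN = got$TN, FN = got$FN), want)
    expect_equal(got$TP + got$FP + got$TN + got$FN, 48 * 64)
  }
  expect_error(confusion_counts(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               class = "ft_invalid_argument")
})

test_that("identical and disjoint masks give the trivial counts", {
  m <- make_line_image(c(64, 64), 40, 40, 2)$mask
  cc <- confusion_counts(m, m)
  expect_equal(cc$FP, 0); expect_equal(cc$FN, 0)
  empty <- matrix(FALSE, 64, 64)
  cc2 <- confusion_counts(empty, m)
  expect_equal(cc2$TP, 0); expect_equal(cc2$FN, sum(m))
})

test_that("a one-pixel shift is forgiven only with tolerance", {
  truth <- matrix(FALSE, 32, 32); truth[16, 6:27] <- TRUE
  pred <- matrix(FALSE, 32, 32); pred[17, 6:27] <- TRUE
  strict <- confusion_counts(pred, truth, match_tol_px = 0)
  expect_equal(strict$FP, 22); expect_equal(strict$FN, 22)
  tol <- confusion_counts(pred, truth, match_tol_px = 1)
  expect_equal(tol$FP, 0); expect_equal(tol$FN, 0)
})

test_that("acc/sn/sp match their defining ratios on random tables", {
  c0 <- tibble::tibble(TP = 90, FN = 10, TN = 900, FP = 0)
  s0 <- acc_sn_sp(c0)
  expect_equal(s0$sensitivity, 0.90)
  expect_equal(s0$specificity, 1.0)
  expect_equal(s0$accuracy, 0.99)
  set.seed(9)
  for (i in 1:1000) {
    k <- as.list(stats::setNames(sample(0:500, 4, replace = TRUE),
                                 c("TP", "FP", "TN", "FN")))
    if (k$TP + k$FN == 0 || k$TN + k$FP == 0) next
    s <- acc_sn_sp(k)
    expect_identical(s$accuracy, (k$TP + k$TN) / (k$TP + k$TN + k$FP + k$FN))
    expect_identical(s$sensitivity, k$TP / (k$TP + k$FN))
    expect_identical(s$specificity, k$TN / (k$TN + k$FP))
  }
})

test_that("undefined metric ratios warn and return NA", {
  expect_warning(s <- acc_sn_sp(list(TP = 10, FP = 0, TN = 0, FN = 0)),
                 "specificity")
  expect_true(is.na(s$specificity))
  expect_equal(s$sensitivity, 1)
  expect_equal(s$accuracy, 1)
})

fiber_stub <- function(theta, len = 50) {
  tibble::tibble(fiber_id = seq_along(theta), theta_deg = theta,
                 length_px = rep_len(len, length(theta)))
}

test_that("the angular distribution is normalized by its mode", {
  h <- angular_distribution(fiber_stub(rep(80, 7)), 10)
  expect_equal(h$normalized[h$bin_start == 80], 1)
  expect_equal(sum(h$normalized), 1)
  h2 <- angular_distribution(fiber_stub(c(rep(15, 3), rep(125, 6))), 10)
  expect_equal(sort(unique(h2$normalized)), c(0, 0.5, 1))
  h3 <- angular_distribution(fiber_stub(seq(5, 175, by = 10)), 10)
  expect_true(all(h3$normalized == 1))
  expect_warning(h4 <- angular_distribution(fiber_stub(numeric())), "no fibers")
  expect_true(all(h4$count == 0))
  expect_error(angular_distribution(fiber_stub(10), 7),
               class = "ft_invalid_argument")
})

test_that("orientation statistics use the population convention", {
  s <- orientation_stats(fiber_stub(rep(90, 5)))
  expect_equal(s$mean_deg, 90); expect_equal(s$variance_deg2, 0)
  s2 <- orientation_stats(fiber_stub(c(80, 100)))
  expect_equal(s2$mean_deg, 90); expect_equal(s2$variance_deg2, 100)
  # unweighted stats ignore the lengths entirely
  f <- fiber_stub(c(80, 100)); f$length_px <- c(10, 90)
  expect_equal(orientation_stats(f)$variance_deg2, 100)
  expect_gt(orientation_stats(f, weighting = "length")$mean_deg, 90)
  expect_error(orientation_stats(fiber_stub(numeric())),
               class = "ft_undefined_metric")
})

test_that("aligned populations have far smaller variance than isotropic ones", {
  set.seed(33)
  aligned <- fiber_stub(80 + rnorm(200, 0, 3))
  isotropic <- fiber_stub(runif(200, 0, 180))
  va <- orientation_stats(aligned)$variance_deg2
  vi <- orientation_stats(isotropic)$variance_deg2
  expect_lt(va, vi / 10)
})
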