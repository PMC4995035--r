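#' Pixel confusion counts between a predicted and a truth mask
#'
#' With `match_tol_px = 0` this is the strict pixelwise comparison. With a
#' positive tolerance, a predicted-positive pixel counts as TP when a
#' truth-positive pixel lies within the tolerance (Euclidean), and a
#' truth-positive pixel with no predicted positive nearby counts as FN --
#' the usual allowance for the width ambiguity of filament masks.
#'
#' @param predicted,truth logical matrices of the same shape.
#' @param match_tol_px matching tolerance in pixels (default 0).
#' @return tibble with columns `TP`, `FP`, `TN`, `FN` (they sum to the pixel
#'   count).
#' @export
confusion_counts <- function(predicted, truth, match_tol_px = 0) {
  if (!all(dim(predicted) == dim(truth)))
    ft_stop("mask shapes differ", "ft_invalid_argument")
  n <- length(truth)
  if (match_tol_px <= 0) {
    TP <- sum(predicted & truth)
    FP <- sum(predicted & !truth)
    FN <- sum(!predicted & truth)
  } else {
    d_truth <- dist_to_mask(truth)
    d_pred <- dist_to_mask(predicted)
    TP <- sum(predicted & d_truth <= match_tol_px)
    FP <- sum(predicted & d_truth > match_tol_px)
    FN <- sum(truth & d_pred > match_tol_px)
  }
  tibble::tibble(TP = TP, FP = FP, TN = n - TP - FP - FN, FN = FN)
}

# Euclidean distance of every pixel to the nearest TRUE pixel.
dist_to_mask <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  inv <- matrix(1, nrow(mask), ncol(mask)); inv[mask] <- 0
  as.matrix(EBImage::distmap(inv, metric = "euclidean"))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `Acc = (TP+TN)/(TP+TN+FP+FN)`, `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`.
#' A zero denominator yields `NA` for that metric, with a warning -- an
#' undefined ratio is never silently reported as 0.
#'
#' @param counts one-row tibble (or list) with `TP`, `FP`, `TN`, `FN`.
#' @return tibble with `accuracy`, `sensitivity`, `specificity`.
#' @export
acc_sn_sp <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  ratio <- function(num, den, what) {
    if (den == 0) {
      rlang::warn(sprintf("%s undefined (zero denominator)", what))
      return(NA_real_)
    }
    num / den
  }
  tibble::tibble(
    accuracy = ratio(TP + TN, total, "accuracy"),
    sensitivity = ratio(TP, TP + FN, "sensitivity"),
    specificity = ratio(TN, TN + FP, "specificity")
  )
}

#' Normalized angular distribution of fiber orientations
#'
#' Counts fibers per orientation bin over \[0, 180) and divides by the
#' maximum bin count, the normalization used when comparing populations of
#' different sizes. The horizontal image axis is the reference direction.
#'
#' @param fibers an `ft_fibers` tibble (or any data frame with `theta_deg`).
#' @param bin_width_deg bin width; must divide 180 (default 10).
#' @return tibble of class `angular_histogram`: `bin_start`, `bin_end`,
#'   `count`, `normalized`. For an empty fiber list the normalized column is
#'   `NA` and the attribute `empty` is set.
#' @export
angular_distribution <- function(fibers, bin_width_deg = 10) {
  if (180 %% bin_width_deg != 0)
    ft_stop("bin_width_deg must divide 180", "ft_invalid_argument")
  edges <- seq(0, 180, by = bin_width_deg)
  theta <- fibers$theta_deg %% 180
  counts <- vapply(seq_len(length(edges) - 1L), function(i)
    sum(theta >= edges[i] & theta < edges[i + 1]), integer(1))
  res <- tibble::tibble(
    bin_start = edges[-length(edges)], bin_end = edges[-1], count = counts,
    normalized = if (any(counts > 0)) counts / max(counts) else NA_real_
  )
  if (!any(counts > 0)) {
    attr(res, "empty") <- TRUE
    rlang::warn("no fibers: normalized distribution undefined")
  }
  class(res) <- c("angular_histogram", class(res))
  res
}

#' Mean and variance of fiber orientations
#'
#' Linear (non-circular) statistics of the orientation angles in degrees on
#' \[0, 180), with the population (divide-by-n) variance convention;
#' optionally length-weighted. A circular (axial) alternative is available
#' but non-default, since reported orientation summaries in this field are
#' usually the linear ones.
#'
#' @param fibers an `ft_fibers` tibble (>= 1 row).
#' @param weighting `"none"` or `"length"`.
#' @param circular use axial circular statistics (doubled-angle mean;
#'   variance as circular variance scaled to deg^2 equivalents).
#' @return tibble with `mean_deg`, `variance_deg2`, `n`.
#' @export
orientation_stats <- function(fibers, weighting = c("none", "length"),
                              circular = FALSE) {
  weighting <- match.arg(weighting)
  theta <- fibers$theta_deg %% 180
  if (length(theta) == 0)
    ft_stop("orientation statistics undefined for an empty fiber list",
            "ft_undefined_metric")
  w <- if (weighting == "length") fibers$length_px else rep(1, length(theta))
  w <- w / sum(w)
  if (!circular) {
    mu <- sum(w * theta)
    v <- sum(w * (theta - mu)^2)
  } else {
    a <- 2 * theta * pi / 180
    C <- sum(w * cos(a)); S <- sum(w * sin(a))
    mu <- ((atan2(S, C) / 2) * 180 / pi) %% 180
    R <- sqrt(C^2 + S^2)
    v <- (1 - R) * (90 / pi)^2 * 2   # small-dispersion deg^2 equivalent
  }
  tibble::tibble(mean_deg = mu %% 180, variance_deg2 = v, n = length(theta))
}
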