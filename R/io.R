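#' Read a grayscale image
#'
#' Reads a TIFF or PNG (8- or 16-bit) into a numeric matrix normalized to
#' \[0, 1\]. RGB images are converted by Rec. 709 luminance unless a single
#' channel is selected (stained-channel micrographs often carry the signal
#' in one channel).
#'
#' @param path file path; format by extension (`.tif`/`.tiff`/`.png`).
#' @param channel `"luminance"`, `"red"`, `"green"`, `"blue"`, or `"gray"`
#'   (gray requires a single-channel file).
#' @return numeric matrix in \[0, 1\].
#' @export
read_gray_image <- function(path, channel = c("luminance", "red", "green",
                                              "blue", "gray")) {
  channel <- match.arg(channel)
  if (!file.exists(path))
    ft_stop(sprintf("file not found: %s", path), "ft_format_error")
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) ft_stop(
                        sprintf("unreadable TIFF %s: %s", path, conditionMessage(e)),
                        "ft_format_error"))
    if (length(pages) > 1)
      ft_stop(sprintf("multi-page TIFF not supported: %s", path), "ft_format_error")
    pages[[1]]
  } else if (ext == "png") {
    tryCatch(png::readPNG(path),
             error = function(e) ft_stop(
               sprintf("unreadable PNG %s: %s", path, conditionMessage(e)),
               "ft_format_error"))
  } else {
    ft_stop(sprintf("unsupported image format '%s' (use TIFF or PNG)", ext),
            "ft_format_error")
  }
  if (length(dim(img)) == 3) {
    if (channel == "gray")
      ft_stop("multi-channel image but channel = 'gray'", "ft_format_error")
    img <- switch(channel,
      luminance = 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3],
      red = img[, , 1], green = img[, , 2], blue = img[, , 3])
  }
  pmin(pmax(img, 0), 1)
}

#' Write a grayscale image
#'
#' @param img numeric matrix; values are clipped to \[0, 1\].
#' @param path output path; `.tif`/`.tiff` (16-bit by default) or `.png`.
#' @param bits bit depth for TIFF output (8 or 16).
#' @return invisibly, `path`.
#' @export
write_gray_image <- function(img, path, bits = 16L) {
  x <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x, path, bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    png::writePNG(x, path)
  } else {
    ft_stop(sprintf("unsupported output format '%s'", ext), "ft_format_error")
  }
  invisible(path)
}

#' Full pipeline configuration
#'
#' Collects the per-stage configurations with their reference defaults
#' (100 MCA iterations, p = 0, delta = 3; sigma = 1.0, beta = 10.0,
#' sigma_dg = 10.0; W = 4, b = 0.1; L = 30, T_theta = 2), dictionary
#' parameters, stage toggles and the RNG seed.
#'
#' @param mca,enhance,line,threshold,merge stage configs (see
#'   [mca_config()], [enhancement_config()], [line_response_config()],
#'   [threshold_config()], [merge_config()]).
#' @param curvelet_scales,curvelet_angles,udwt_levels,udwt_wavelet
#'   dictionary parameters.
#' @param stages named logical vector enabling stages (decomposition can be
#'   skipped for clean images).
#' @param channel input channel selection for [read_gray_image()].
#' @param seed RNG seed recorded in the manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mca = mca_config(),
                            enhance = enhancement_config(),
                            line = line_response_config(),
                            threshold = threshold_config(),
                            merge = merge_config(),
                            curvelet_scales = 3L,
                            curvelet_angles = c(12L, 8L),
                            udwt_levels = 4L, udwt_wavelet = "b3spline",
                            stages = c(decompose = TRUE, enhance = TRUE,
                                       detect = TRUE, extract = TRUE),
                            channel = "luminance", seed = 1L) {
  structure(list(mca = mca, enhance = enhance, line = line,
                 threshold = threshold, merge = merge,
                 curvelet_scales = as.integer(curvelet_scales),
                 curvelet_angles = as.integer(curvelet_angles),
                 udwt_levels = as.integer(udwt_levels),
                 udwt_wavelet = udwt_wavelet,
                 stages = stages, channel = channel, seed = as.integer(seed)),
            class = "pipeline_config")
}

# flat dotted-key representation (config file format)
flatten_config <- function(cfg) {
  list(
    "mca.n_iter" = cfg$mca$n_iter, "mca.p" = cfg$mca$p,
    "mca.delta" = cfg$mca$delta, "mca.gamma_init_k" = cfg$mca$gamma_init_k,
    "mca.gamma_final_k" = cfg$mca$gamma_final_k,
    "mca.tv_target" = cfg$mca$tv_target, "mca.pad" = cfg$mca$pad,
    "dict.curvelet.scales" = cfg$curvelet_scales,
    "dict.curvelet.angles" = paste(cfg$curvelet_angles, collapse = ","),
    "dict.udwt.levels" = cfg$udwt_levels,
    "dict.udwt.wavelet" = cfg$udwt_wavelet,
    "enh.sigma" = cfg$enhance$gaussian_sigma,
    "enh.beta" = cfg$enhance$laplace_beta,
    "enh.dg_sigma" = cfg$enhance$dg_sigma,
    "enh.n_orientations" = cfg$enhance$n_orientations,
    "enh.laplace_center" = cfg$enhance$laplace_center,
    "enh.laplace_abs" = cfg$enhance$laplace_abs,
    "line.W" = cfg$line$W, "line.angle_step" = cfg$line$angle_step_deg,
    "line.include_pixel_term" = cfg$line$include_pixel_term,
    "thr.b" = cfg$threshold$b,
    "thr.median_window" = cfg$threshold$median_window,
    "thr.min_component_px" = cfg$threshold$min_component_px,
    "merge.T_theta" = cfg$merge$T_theta,
    "merge.overlap_tol_px" = cfg$merge$overlap_tol_px,
    "merge.L" = cfg$merge$L,
    "stages" = paste(names(cfg$stages)[cfg$stages], collapse = ","),
    "channel" = cfg$channel, "seed" = cfg$seed
  )
}

#' Write / read a pipeline configuration file
#'
#' Flat dotted-key YAML; values round-trip losslessly through
#' [read_config()].
#'
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @return `write_config`: invisibly `path`; `read_config`: a
#'   `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(flatten_config(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  kv <- yaml::read_yaml(path)
  g <- function(key, default) if (!is.null(kv[[key]])) kv[[key]] else default
  all_stages <- c("decompose", "enhance", "detect", "extract")
  on <- strsplit(g("stages", paste(all_stages, collapse = ",")), ",")[[1]]
  pipeline_config(
    mca = mca_config(n_iter = g("mca.n_iter", 100L), p = g("mca.p", 0L),
                     delta = g("mca.delta", 3),
                     gamma_init_k = g("mca.gamma_init_k", 30),
                     gamma_final_k = g("mca.gamma_final_k", 3),
                     tv_target = g("mca.tv_target", "artifacts"),
                     pad = g("mca.pad", 16L)),
    enhance = enhancement_config(
      gaussian_sigma = g("enh.sigma", 1.0), laplace_beta = g("enh.beta", 10.0),
      dg_sigma = g("enh.dg_sigma", 10.0),
      n_orientations = g("enh.n_orientations", 12L),
      laplace_center = g("enh.laplace_center", -4),
      laplace_abs = g("enh.laplace_abs", TRUE)),
    line = line_response_config(W = g("line.W", 4L),
                                angle_step_deg = g("line.angle_step", 15),
                                include_pixel_term = g("line.include_pixel_term", TRUE)),
    threshold = threshold_config(b = g("thr.b", 0.1),
                                 median_window = g("thr.median_window", 15L),
                                 min_component_px = g("thr.min_component_px", 5L)),
    merge = merge_config(T_theta = g("merge.T_theta", 2),
                         overlap_tol_px = g("merge.overlap_tol_px", 2),
                         L = g("merge.L", 30)),
    curvelet_scales = g("dict.curvelet.scales", 3L),
    curvelet_angles = as.integer(strsplit(as.character(
      g("dict.curvelet.angles", "12,8")), ",")[[1]]),
    udwt_levels = g("dict.udwt.levels", 4L),
    udwt_wavelet = g("dict.udwt.wavelet", "b3spline"),
    stages = stats::setNames(all_stages %in% on, all_stages),
    channel = g("channel", "luminance"), seed = g("seed", 1L)
  )
}

checksum_of <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    return(unname(tools::md5sum(x)))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full fiber-extraction pipeline
#'
#' Decompose, enhance, detect (multi-scale response + binarization), extract
#' (skeletonize, fit fixed-length segments, merge into fibers), then
#' evaluate against ground truth when available. Any stage can be disabled
#' through `cfg$stages`; a disabled decomposition feeds the input image
#' directly to the enhancement chain.
#'
#' @param input a file path, a numeric matrix in \[0, 1\], or a
#'   `synthetic_scene` (its composite is processed and its truth used for
#'   evaluation).
#' @param cfg a [pipeline_config()].
#' @param output_dir if non-NULL, intermediate images (TIFF), segment/fiber
#'   tables and histogram (CSV), overlay (PNG) and the run manifest (JSON)
#'   are written there.
#' @param truth_mask optional logical matrix for pixel-level evaluation.
#' @return a `ft_pipeline_result` list: images (`u_f`, `v_a`, `u_E`, `u_G`,
#'   `u_B`), `segments`, `fibers`, `histogram`, `evaluation` (if truth
#'   given), `manifest`.
#' @export
run_pipeline <- function(input, cfg = pipeline_config(), output_dir = NULL,
                         truth_mask = NULL) {
  t_start <- Sys.time()
  scene <- NULL
  if (inherits(input, "synthetic_scene")) {
    scene <- input
    f <- scene$composite
    if (is.null(truth_mask)) truth_mask <- scene$truth_mask
    input_ref <- "synthetic_scene"
  } else if (is.character(input)) {
    f <- read_gray_image(input, channel = cfg$channel)
    input_ref <- input
  } else {
    check_gray_image(input, "input")
    f <- input
    input_ref <- "matrix"
  }
  stages <- cfg$stages
  log <- list()
  mark <- function(name, expr) {
    t0 <- Sys.time()
    val <- expr
    log[[name]] <<- list(elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))
    val
  }

  decomp <- NULL
  u_f <- f
  v_a <- matrix(0, nrow(f), ncol(f))
  if (isTRUE(stages[["decompose"]])) {
    decomp <- mark("decompose", mca_decompose(
      f,
      d_f = curvelet_dictionary(cfg$curvelet_scales, cfg$curvelet_angles),
      d_a = udwt_dictionary(cfg$udwt_levels, cfg$udwt_wavelet),
      cfg = cfg$mca))
    u_f <- decomp$fibers
    v_a <- decomp$artifacts
  }
  u_E <- if (isTRUE(stages[["enhance"]])) {
    mark("enhance", enhance(u_f, cfg$enhance))
  } else rescale01(u_f)
  u_G <- NULL; u_B <- NULL
  segments <- empty_segments(); fibers <- empty_fibers()
  if (isTRUE(stages[["detect"]])) {
    u_G <- mark("detect", multiscale_response(u_E, cfg$line))
    u_B <- wellner_binarize(u_G, cfg$threshold)
  }
  if (isTRUE(stages[["extract"]]) && !is.null(u_B)) {
    segments <- mark("extract", extract_segments(u_B, L = cfg$merge$L))
    fibers <- merge_fibers(segments, cfg$merge)
  }
  histogram <- suppressWarnings(angular_distribution(fibers))
  evaluation <- NULL
  if (!is.null(truth_mask) && !is.null(u_B)) {
    counts <- confusion_counts(u_B, truth_mask)
    evaluation <- dplyr::bind_cols(counts, suppressWarnings(acc_sn_sp(counts)))
  }

  manifest <- list(
    tool = "fibertrace", version = as.character(utils::packageVersion("fibertrace")),
    input = input_ref, input_checksum = checksum_of(if (is.character(input)) input else f),
    config = flatten_config(cfg),
    stages_run = names(stages)[vapply(stages, isTRUE, TRUE)],
    image_shape = dim(f),
    n_segments = nrow(segments), n_fibers = nrow(fibers),
    stage_log = log,
    elapsed_s = as.numeric(Sys.time() - t_start, units = "secs")
  )

  result <- structure(list(
    input = f, u_f = u_f, v_a = v_a, residual = if (!is.null(decomp)) decomp$residual,
    u_E = u_E, u_G = u_G, u_B = u_B,
    decomposition = decomp, segments = segments, fibers = fibers,
    histogram = histogram, evaluation = evaluation, manifest = manifest,
    scene = scene
  ), class = "ft_pipeline_result")

  if (!is.null(output_dir)) {
    manifest$outputs <- write_pipeline_outputs(result, output_dir)
    result$manifest <- manifest
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  result
}

# encode an ordered pixel chain as "x0,y0;x1,y1;..." (0-based)
encode_polyline <- function(pixels) {
  paste(sprintf("%d,%d", round(pixels[, 1]) - 1L, round(pixels[, 2]) - 1L),
        collapse = ";")
}

segments_to_table <- function(segments) {
  data.frame(
    seg_id = segments$seg_id, chain_id = segments$chain_id,
    theta_deg = segments$theta_deg, length_px = segments$length_px,
    x0 = segments$x0 - 1, y0 = segments$y0 - 1,
    x1 = segments$x1 - 1, y1 = segments$y1 - 1,
    n_pixels = segments$n_pixels,
    polyline = vapply(segments$pixels, encode_polyline, character(1))
  )
}

fibers_to_table <- function(fibers) {
  data.frame(
    fiber_id = fibers$fiber_id, theta_deg = fibers$theta_deg,
    length_px = fibers$length_px,
    x0 = fibers$x0 - 1, y0 = fibers$y0 - 1,
    x1 = fibers$x1 - 1, y1 = fibers$y1 - 1,
    n_pixels = fibers$n_pixels,
    source_segments = vapply(fibers$source_segments,
                             function(s) paste(s, collapse = ";"), character(1)),
    polyline = vapply(fibers$pixels, encode_polyline, character(1))
  )
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wimg <- function(img, name) {
    if (is.null(img)) return()
    p <- file.path(dir, name)
    write_gray_image(rescale01(img), p)
    paths[[name]] <<- p
  }
  wimg(result$u_f, "u_f.tif"); wimg(result$v_a, "v_a.tif")
  wimg(result$u_E, "u_E.tif"); wimg(result$u_G, "u_G.tif")
  if (!is.null(result$u_B)) {
    p <- file.path(dir, "u_B.png")
    png::writePNG(result$u_B * 1, p); paths[["u_B.png"]] <- p
  }
  utils::write.csv(segments_to_table(result$segments),
                   file.path(dir, "segments.csv"), row.names = FALSE)
  utils::write.csv(fibers_to_table(result$fibers),
                   file.path(dir, "fibers.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$histogram[, c("bin_start", "bin_end",
                                                      "count", "normalized")]),
                   file.path(dir, "histogram.csv"), row.names = FALSE)
  if (!is.null(result$evaluation))
    utils::write.csv(as.data.frame(result$evaluation),
                     file.path(dir, "evaluation.csv"), row.names = FALSE)
  ov <- render_overlay(result$input, result$fibers)
  png::writePNG(ov, file.path(dir, "overlay.png"))
  paths[["segments.csv"]] <- file.path(dir, "segments.csv")
  paths[["fibers.csv"]] <- file.path(dir, "fibers.csv")
  paths[["histogram.csv"]] <- file.path(dir, "histogram.csv")
  paths[["overlay.png"]] <- file.path(dir, "overlay.png")
  as.list(paths)
}

#' @export
print.ft_pipeline_result <- function(x, ...) {
  cat("<ft_pipeline_result>", paste(dim(x$input), collapse = "x"),
      "-", nrow(x$segments), "segments ->", nrow(x$fibers), "fibers\n")
  if (!is.null(x$evaluation)) {
    ev <- x$evaluation
    cat(sprintf("  Acc %.4f  Sn %.4f  Sp %.4f\n",
                ev$accuracy, ev$sensitivity, ev$specificity))
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x an `ft_pipeline_result`.
#' @param ... unused.
#' @method tidy ft_pipeline_result
#' @export
tidy.ft_pipeline_result <- function(x, ...) x$fibers

#' @rdname run_pipeline
#' @method glance ft_pipeline_result
#' @export
glance.ft_pipeline_result <- function(x, ...) {
  out <- tibble::tibble(
    n_segments = nrow(x$segments), n_fibers = nrow(x$fibers),
    total_fiber_length_px = sum(x$fibers$length_px),
    mean_theta_deg = if (nrow(x$fibers)) orientation_stats(x$fibers)$mean_deg else NA_real_,
    var_theta_deg2 = if (nrow(x$fibers)) orientation_stats(x$fibers)$variance_deg2 else NA_real_,
    elapsed_s = x$manifest$elapsed_s
  )
  if (!is.null(x$evaluation)) out <- dplyr::bind_cols(out, x$evaluation)
  out
}

#' Render fibers over an image, colored by orientation
#'
#' Colors are taken from a cyclic palette over \[0, 180) (HSV hue), so 0 and
#' 180 degrees share a color.
#'
#' @param image background image in \[0, 1\].
#' @param fibers an `ft_fibers` tibble.
#' @return an H x W x 3 RGB array.
#' @export
render_overlay <- function(image, fibers) {
  g <- pmin(pmax(image, 0), 1)
  rgb_arr <- array(rep(g, 3), dim = c(nrow(g), ncol(g), 3))
  if (nrow(fibers) > 0) {
    for (i in seq_len(nrow(fibers))) {
      col <- grDevices::col2rgb(grDevices::hsv(
        (fibers$theta_deg[i] %% 180) / 180, 1, 1)) / 255
      px <- fibers$pixels[[i]]
      rr <- round(px[, 2]); cc <- round(px[, 1])
      ok <- rr >= 1 & rr <= nrow(g) & cc >= 1 & cc <= ncol(g)
      idx <- cbind(rr[ok], cc[ok])
      for (ch in 1:3) {
        plane <- rgb_arr[, , ch]
        plane[idx] <- col[ch]
        rgb_arr[, , ch] <- plane
      }
    }
  }
  rgb_arr
}
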