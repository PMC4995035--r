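# Fixed-length segment extraction and fiber merging.
#
# Segments and fibers are tibbles with one row per object and a `pixels`
# list-column of ordered n x 2 matrices (columns x, y; 1-based). `theta_deg`
# is the orientation in [0, 180) from the horizontal axis, `length_px` the
# Euclidean distance between the two terminal pixels.

shift_zero <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dy):min(nr, nr + dy)
  cs <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(rs) && length(cs)) out[rs - dy, cs - dx] <- img[rs, cs]
  out
}

#' Thin a binary mask to a 1-pixel skeleton
#'
#' Zhang-Suen morphological thinning, iterated to stability. The binarized
#' filament network is several pixels wide; tracing operates on its skeleton.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same size.
#' @export
thin_mask <- function(mask) {
  img <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- shift_zero(img, -1L, 0L); p3 <- shift_zero(img, -1L, 1L)
      p4 <- shift_zero(img, 0L, 1L);  p5 <- shift_zero(img, 1L, 1L)
      p6 <- shift_zero(img, 1L, 0L);  p7 <- shift_zero(img, 1L, -1L)
      p8 <- shift_zero(img, 0L, -1L); p9 <- shift_zero(img, -1L, -1L)
      bn <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      an <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
            (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
            (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (pass == 1) {
        cond <- img == 1 & bn >= 2 & bn <= 6 & an == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- img == 1 & bn >= 2 & bn <= 6 & an == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { img[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img == 1L
}

neighbor_count <- function(img) {
  s <- matrix(0L, nrow(img), ncol(img))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    s <- s + shift_zero(img, dy, dx)
  }
  s
}

# crossing number: 0->1 transitions when walking the 8-neighborhood in
# order; 1 at line ends, 2 inside a curve, >= 3 at true branch points
# (plain neighbor counts misfire on diagonal staircases).
crossing_number <- function(img) {
  p2 <- shift_zero(img, -1L, 0L); p3 <- shift_zero(img, -1L, 1L)
  p4 <- shift_zero(img, 0L, 1L);  p5 <- shift_zero(img, 1L, 1L)
  p6 <- shift_zero(img, 1L, 0L);  p7 <- shift_zero(img, 1L, -1L)
  p8 <- shift_zero(img, 0L, -1L); p9 <- shift_zero(img, -1L, -1L)
  (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
    (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
    (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
}

#' Skeletonize a binary network and trace its pixel chains
#'
#' Thins the mask to one-pixel width, removes junction pixels (three or more
#' skeleton neighbors), and walks each remaining branch into an ordered
#' 8-connected chain. Every non-junction skeleton pixel lands in exactly one
#' chain.
#'
#' @param u_B logical matrix (binarized filament network).
#' @return list of ordered n x 2 matrices with columns `x`, `y`.
#' @export
skeletonize_and_trace <- function(u_B) {
  if (!any(u_B)) return(list())
  skel <- thin_mask(u_B)
  img <- matrix(as.integer(skel), nrow(skel), ncol(skel))
  cn <- crossing_number(img)
  junction <- skel & cn > 2
  branch <- skel & !junction
  if (!any(branch)) return(list())
  nr <- nrow(branch)
  idx_all <- which(branch)
  rs_all <- (idx_all - 1L) %% nr + 1L; cs_all <- (idx_all - 1L) %/% nr + 1L
  n_all <- length(idx_all)
  key_all <- paste(rs_all, cs_all)
  pos_all <- stats::setNames(seq_len(n_all), key_all)
  is_junc <- function(r, c) {
    r >= 1 && r <= nrow(junction) && c >= 1 && c <= ncol(junction) &&
      junction[r, c]
  }
  adj_all <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    nb <- integer(0)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      j <- pos_all[paste(rs_all[i] + dy, cs_all[i] + dx)]
      if (is.na(j)) next
      # a diagonal step must not shortcut through a junction cell: distinct
      # branches meeting at a removed junction would otherwise reconnect
      if (dy != 0 && dx != 0 &&
          (is_junc(rs_all[i], cs_all[i] + dx) ||
           is_junc(rs_all[i] + dy, cs_all[i]))) next
      nb <- c(nb, j)
    }
    adj_all[[i]] <- nb
  }
  # connected components on that adjacency
  comp_id <- integer(n_all)
  cur <- 0L
  for (s0 in seq_len(n_all)) {
    if (comp_id[s0] != 0L) next
    cur <- cur + 1L
    stack <- s0; comp_id[s0] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (q in adj_all[[p]]) if (comp_id[q] == 0L) {
        comp_id[q] <- cur; stack <- c(stack, q)
      }
    }
  }
  chains <- list()
  for (comp in seq_len(cur)) {
    sel <- which(comp_id == comp)
    rs <- rs_all[sel]; cs <- cs_all[sel]
    n <- length(sel)
    if (n == 1L) { chains[[length(chains) + 1L]] <- cbind(x = cs, y = rs); next }
    remap <- integer(n_all); remap[sel] <- seq_len(n)
    adj <- lapply(adj_all[sel], function(v) remap[v])
    # consume the component into maximal paths; a direction-momentum
    # preference keeps the walk straight through staircase double
    # adjacencies and spur attachment points
    visited <- logical(n)
    repeat {
      left <- which(!visited)
      if (!length(left)) break
      degs <- vapply(left, function(i) sum(!visited[adj[[i]]]), integer(1))
      start <- if (any(degs == 1)) left[which(degs == 1)[1]]
               else left[which.min(degs)]
      path <- integer(0)
      cur <- start
      heading <- c(0, 0)
      while (!is.na(cur)) {
        visited[cur] <- TRUE
        path <- c(path, cur)
        nxt <- adj[[cur]][!visited[adj[[cur]]]]
        if (length(nxt) == 0) break
        if (length(nxt) > 1) {
          dirs <- cbind(cs[nxt] - cs[cur], rs[nxt] - rs[cur])
          dirs <- dirs / sqrt(rowSums(dirs^2))
          score <- dirs %*% heading
          if (all(heading == 0)) score <- -abs(dirs[, 1] * dirs[, 2])  # prefer 4-conn
          nxt <- nxt[order(-score)]
        }
        step <- c(cs[nxt[1]] - cs[cur], rs[nxt[1]] - rs[cur])
        step <- step / sqrt(sum(step^2))
        heading <- if (all(heading == 0)) step else 0.7 * heading + step
        heading <- heading / sqrt(sum(heading^2))
        cur <- nxt[1]
      }
      chains[[length(chains) + 1L]] <- cbind(x = cs[path], y = rs[path])
    }
  }
  chains[order(-vapply(chains, nrow, 1L))]
}

# total-least-squares line through points; returns angle (deg in [0,180))
# and maximal perpendicular distance of the points from the fitted line.
tls_fit <- function(px, py) {
  mx <- mean(px); my <- mean(py)
  dx <- px - mx; dy <- py - my
  sxx <- sum(dx * dx); syy <- sum(dy * dy); sxy <- sum(dx * dy)
  ang <- 0.5 * atan2(2 * sxy, sxx - syy)      # principal axis
  ux <- cos(ang); uy <- sin(ang)
  perp <- abs(-uy * dx + ux * dy)
  list(theta_deg = (ang * 180 / pi) %% 180, max_err = max(perp),
       center = c(mx, my), dir = c(ux, uy))
}

segment_row <- function(pixels, chain_id, fit = NULL) {
  if (is.null(fit)) fit <- tls_fit(pixels[, 1], pixels[, 2])
  p0 <- pixels[1, ]; p1 <- pixels[nrow(pixels), ]
  tibble::tibble(
    chain_id = chain_id, theta_deg = fit$theta_deg,
    length_px = sqrt(sum((p1 - p0)^2)), n_pixels = nrow(pixels),
    x0 = p0[1], y0 = p0[2], x1 = p1[1], y1 = p1[2],
    max_fit_err = fit$max_err, pixels = list(unname(pixels))
  )
}

#' Fit fixed-length quasi-straight segments to a pixel chain
#'
#' Greedy total-least-squares growth: pixels are appended to the current
#' segment while the maximal perpendicular distance from the fitted line
#' stays within `max_err_px`; on violation the segment is closed and a new
#' one starts at the current pixel. Segments shorter than `L` (endpoint
#' distance) are discarded.
#'
#' @param chain ordered n x 2 matrix (columns x, y).
#' @param L minimum segment length in px (default 30).
#' @param max_err_px perpendicular error threshold (default 1).
#' @param chain_id identifier stored with the segments.
#' @return tibble of segments (possibly empty), class `ft_segments`.
#' @export
fit_segments <- function(chain, L = 30, max_err_px = 1, chain_id = 1L) {
  out <- list()
  n <- if (is.null(chain)) 0L else nrow(chain)
  i0 <- 1L
  while (i0 <= n - 1L) {
    fit <- NULL
    i <- i0 + 1L
    while (i <= n) {
      cand <- tls_fit(chain[i0:i, 1], chain[i0:i, 2])
      if (cand$max_err > max_err_px) break
      fit <- cand
      i <- i + 1L
    }
    last <- i - 1L                      # last pixel satisfying the error bound
    seg <- chain[i0:last, , drop = FALSE]
    if (sqrt(sum((seg[nrow(seg), ] - seg[1, ])^2)) >= L)
      out[[length(out) + 1L]] <- segment_row(seg, chain_id, fit)
    if (i > n) break
    i0 <- i                             # restart at the violating pixel
  }
  res <- if (length(out)) dplyr::bind_rows(out) else empty_segments()
  res$seg_id <- seq_len(nrow(res)) + 0L
  class(res) <- c("ft_segments", class(tibble::tibble()))
  res
}

empty_segments <- function() {
  tibble::tibble(chain_id = integer(), theta_deg = numeric(),
                 length_px = numeric(), n_pixels = integer(),
                 x0 = numeric(), y0 = numeric(), x1 = numeric(), y1 = numeric(),
                 max_fit_err = numeric(), pixels = list())
}

#' Extract fixed-length segments from a binary network
#'
#' Convenience wrapper: [skeletonize_and_trace()] then [fit_segments()] on
#' every chain.
#'
#' @param u_B logical matrix.
#' @inheritParams fit_segments
#' @return tibble of segments, class `ft_segments`.
#' @export
extract_segments <- function(u_B, L = 30, max_err_px = 1) {
  chains <- skeletonize_and_trace(u_B)
  segs <- lapply(seq_along(chains), function(i)
    fit_segments(chains[[i]], L = L, max_err_px = max_err_px, chain_id = i))
  res <- if (length(segs)) dplyr::bind_rows(segs) else empty_segments()
  if (nrow(res)) res$seg_id <- seq_len(nrow(res))
  class(res) <- c("ft_segments", class(tibble::tibble()))
  res
}

#' Do two segments overlap at their endpoints?
#'
#' TRUE iff the minimum distance between an endpoint of one segment and the
#' pixel set of the other is at most `overlap_tol_px` (boundary inclusive).
#'
#' @param pixels_a,pixels_b n x 2 pixel matrices.
#' @param overlap_tol_px tolerance in pixels (default 2).
#' @return logical scalar.
#' @export
overlap_endpoints <- function(pixels_a, pixels_b, overlap_tol_px = 2) {
  ends_a <- pixels_a[c(1, nrow(pixels_a)), , drop = FALSE]
  ends_b <- pixels_b[c(1, nrow(pixels_b)), , drop = FALSE]
  d1 <- min(outer(ends_a[, 1], pixels_b[, 1], `-`)^2 +
            outer(ends_a[, 2], pixels_b[, 2], `-`)^2)
  d2 <- min(outer(ends_b[, 1], pixels_a[, 1], `-`)^2 +
            outer(ends_b[, 2], pixels_a[, 2], `-`)^2)
  sqrt(min(d1, d2)) <= overlap_tol_px
}

#' Merge configuration for fiber extraction
#'
#' @param T_theta angle merging tolerance in degrees (default 2).
#' @param overlap_tol_px endpoint overlap tolerance (default 2).
#' @param L minimum segment length (default 30).
#' @return a `merge_config` list.
#' @export
merge_config <- function(T_theta = 2, overlap_tol_px = 2, L = 30) {
  if (T_theta < 0 || overlap_tol_px < 0)
    ft_stop("tolerances must be >= 0", "ft_invalid_argument")
  structure(list(T_theta = T_theta, overlap_tol_px = overlap_tol_px, L = L),
            class = "merge_config")
}

# intersection of the two fitted lines; near-parallel lines fall back to the
# midpoint of the closest endpoint pair.
connection_point <- function(a, b) {
  if (angle_diff_180(a$theta, b$theta) >= 0.5) {
    ca <- colMeans(a$pixels); cb <- colMeans(b$pixels)
    ta <- a$theta * pi / 180; tb <- b$theta * pi / 180
    da <- c(cos(ta), sin(ta)); db <- c(cos(tb), sin(tb))
    # solve ca + t*da = cb + s*db
    M <- cbind(da, -db)
    rhs <- cb - ca
    sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (!is.null(sol)) return(ca + sol[1] * da)
  }
  ea <- a$pixels[c(1, nrow(a$pixels)), , drop = FALSE]
  eb <- b$pixels[c(1, nrow(b$pixels)), , drop = FALSE]
  d <- outer(seq_len(2), seq_len(2), Vectorize(function(i, j)
    sum((ea[i, ] - eb[j, ])^2)))
  ij <- which(d == min(d), arr.ind = TRUE)[1, ]
  (ea[ij[1], ] + eb[ij[2], ]) / 2
}

# keep the part of an ordered chain on the far side of the connection point,
# walking from its far end up to (and including) the pixel nearest beyond cp.
clip_chain <- function(pixels, cp) {
  theta <- tls_fit(pixels[, 1], pixels[, 2])
  u <- theta$dir
  t_pix <- (pixels[, 1] - cp[1]) * u[1] + (pixels[, 2] - cp[2]) * u[2]
  ends_t <- t_pix[c(1, length(t_pix))]
  far_sign <- sign(ends_t[which.max(abs(ends_t))])
  if (far_sign == 0) far_sign <- 1
  keep <- t_pix * far_sign >= 0
  if (!any(keep)) keep[which.min(abs(t_pix))] <- TRUE
  kept <- pixels[keep, , drop = FALSE]
  # order from connection point outwards
  tk <- t_pix[keep] * far_sign
  kept[order(tk), , drop = FALSE]
}

#' Merge fixed-length segments into individual fibers
#'
#' The tolerance sweep: for each integer tolerance `xi = 0..T_theta`, each
#' live segment `i` is merged into the first later segment `k` whose
#' orientation differs by at most `xi` degrees (circularly, on the 180
#' degree axis) and whose endpoints overlap within `overlap_tol_px`. The
#' surviving segment keeps the length-weighted mean orientation
#' `(d_k * theta_k + d_i * theta_i) / (d_k + d_i)` and the union of pixels
#' with everything beyond the connection (intersection) point discarded.
#'
#' @param segments an `ft_segments` tibble (or a fiber table from a previous
#'   merge; the sweep is then a refinement pass).
#' @param cfg a [merge_config()].
#' @return tibble of fibers, class `ft_fibers`: `fiber_id`, `theta_deg`,
#'   `length_px`, `n_pixels`, endpoints, `source_segments`, `pixels`.
#' @export
merge_fibers <- function(segments, cfg = merge_config()) {
  n <- nrow(segments)
  if (n == 0) return(empty_fibers())
  live <- rep(TRUE, n)
  objs <- lapply(seq_len(n), function(i) list(
    pixels = segments$pixels[[i]], theta = segments$theta_deg[i],
    delta = segments$length_px[i],
    sources = if ("source_segments" %in% names(segments))
      segments$source_segments[[i]] else segments$seg_id[i]))

  for (xi in 0:floor(cfg$T_theta)) {
    for (i in seq_len(n)) {
      if (!live[i]) next
      k_found <- 0L
      for (k in seq_len(n)) {
        if (k <= i || !live[k]) next
        if (angle_diff_180(objs[[k]]$theta, objs[[i]]$theta) > xi) next
        if (!overlap_endpoints(objs[[k]]$pixels, objs[[i]]$pixels,
                               cfg$overlap_tol_px)) next
        k_found <- k
        break
      }
      if (k_found == 0L) next
      k <- k_found
      a <- objs[[k]]; b <- objs[[i]]
      cp <- connection_point(list(theta = a$theta, pixels = a$pixels),
                             list(theta = b$theta, pixels = b$pixels))
      ka <- clip_chain(a$pixels, cp)
      kb <- clip_chain(b$pixels, cp)
      merged <- rbind(kb[rev(seq_len(nrow(kb))), , drop = FALSE], ka)
      merged <- merged[!duplicated(merged), , drop = FALSE]
      theta_new <- (a$delta * a$theta + b$delta * b$theta) / (a$delta + b$delta)
      objs[[k]] <- list(pixels = merged, theta = theta_new %% 180,
                        delta = sqrt(sum((merged[nrow(merged), ] - merged[1, ])^2)),
                        sources = c(a$sources, b$sources))
      live[i] <- FALSE
    }
  }
  rows <- lapply(which(live), function(i) {
    o <- objs[[i]]
    p0 <- o$pixels[1, ]; p1 <- o$pixels[nrow(o$pixels), ]
    tibble::tibble(theta_deg = o$theta, length_px = o$delta,
                   n_pixels = nrow(o$pixels),
                   x0 = p0[1], y0 = p0[2], x1 = p1[1], y1 = p1[2],
                   source_segments = list(o$sources), pixels = list(o$pixels))
  })
  res <- dplyr::bind_rows(rows)
  res$fiber_id <- seq_len(nrow(res))
  res <- res[, c("fiber_id", setdiff(names(res), "fiber_id"))]
  class(res) <- c("ft_fibers", class(tibble::tibble()))
  res
}

empty_fibers <- function() {
  res <- tibble::tibble(fiber_id = integer(), theta_deg = numeric(),
                        length_px = numeric(), n_pixels = integer(),
                        x0 = numeric(), y0 = numeric(), x1 = numeric(),
                        y1 = numeric(), source_segments = list(),
                        pixels = list())
  class(res) <- c("ft_fibers", class(tibble::tibble()))
  res
}

#' Match extracted fibers to ground-truth filaments
#'
#' Greedy one-to-one assignment: each truth filament claims the nearest
#' unmatched extracted fiber, where nearness is the distance from the truth
#' centerline midpoint to the fiber's pixel chain; matches farther than
#' `max_dist_px` are rejected. Orientation and length errors are reported
#' per match.
#'
#' @param fibers an `ft_fibers` tibble.
#' @param truth a [filament_specs()] table.
#' @param max_dist_px maximal center-to-chain distance for a valid match.
#' @return tibble with one row per truth filament: `matched`,
#'   `angle_err_deg`, `length_err_rel`, `fiber_id`.
#' @export
match_fibers <- function(fibers, truth, max_dist_px = 5) {
  out <- tibble::tibble(truth_id = truth$id, matched = FALSE,
                        fiber_id = NA_integer_, angle_err_deg = NA_real_,
                        length_err_rel = NA_real_)
  if (nrow(fibers) == 0 || nrow(truth) == 0) return(out)
  used <- rep(FALSE, nrow(fibers))
  chain_dist <- function(t, j) {
    px <- fibers$pixels[[j]]
    min(sqrt((px[, 1] - truth$cx[t])^2 + (px[, 2] - truth$cy[t])^2))
  }
  for (t in seq_len(nrow(truth))) {
    d <- vapply(seq_len(nrow(fibers)), function(j)
      if (used[j]) Inf else chain_dist(t, j), numeric(1))
    j <- which.min(d)
    if (!is.finite(d[j]) || d[j] > max_dist_px) next
    used[j] <- TRUE
    out$matched[t] <- TRUE
    out$fiber_id[t] <- fibers$fiber_id[j]
    out$angle_err_deg[t] <- angle_diff_180(fibers$theta_deg[j], truth$angle_deg[t])
    out$length_err_rel[t] <- abs(fibers$length_px[j] - truth$length_px[t]) /
      truth$length_px[t]
  }
  out
}
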