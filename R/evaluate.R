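#' Automatically placed stitch-edge fiducials
#'
#' For each of the four stitch edges of the reference reconstruction, the
#' inner endpoint, outer endpoint, and midpoint of the facing best-fit
#' lines (averaged over the two adjacent quadrants) are anchors.  Inner
#' endpoints closer than `merge_tol` px collapse to their centroid; the
#' retained set is truncated to `n_asf` anchors, outermost endpoints
#' first, then midpoints, then inner points.
#'
#' @param ref_ts reference `transform_set`.
#' @param qs `quadrant_set` with detected edges (detected on demand).
#' @param n_asf number of anchors to keep.
#' @param merge_tol merge tolerance for coincident central endpoints (px).
#' @return data.frame: `x`, `y` (reference frame px), `kind`, `label_a`,
#'   `label_b`.
#' @export
place_asf_fiducials <- function(ref_ts, qs, n_asf = 10, merge_tol = 2) {
  qs <- ensure_edges(qs)
  rows <- list()
  for (ab in ADJACENT_PAIRS) {
    key <- facing_edge(ab[1], ab[2])
    ea <- qs[[ab[1]]]$edges$edges[[key]]
    eb <- qs[[ab[2]]]$edges$edges[[key]]
    pa <- transform_points(ref_ts$transforms[[ab[1]]],
                           rbind(ea$C_in, ea$C_out))
    pb <- transform_points(ref_ts$transforms[[ab[2]]],
                           rbind(eb$C_in, eb$C_out))
    ain <- (pa[1, ] + pb[1, ]) / 2
    aout <- (pa[2, ] + pb[2, ]) / 2
    rows[[length(rows) + 1]] <- data.frame(
      x = c(aout[1], (ain[1] + aout[1]) / 2, ain[1]),
      y = c(aout[2], (ain[2] + aout[2]) / 2, ain[2]),
      kind = c("outer", "mid", "inner"),
      label_a = ab[1], label_b = ab[2])
  }
  an <- do.call(rbind, rows)
  inner <- an[an$kind == "inner", ]
  keep <- an[an$kind != "inner", ]
  # merge coincident central endpoints
  while (nrow(inner) > 0) {
    d <- sqrt((inner$x - inner$x[1])^2 + (inner$y - inner$y[1])^2)
    cl <- d <= merge_tol
    merged <- inner[1, ]
    merged$x <- mean(inner$x[cl]); merged$y <- mean(inner$y[cl])
    keep <- rbind(keep, merged)
    inner <- inner[!cl, , drop = FALSE]
  }
  ord <- order(match(keep$kind, c("outer", "mid", "inner")))
  keep <- keep[ord, , drop = FALSE]
  utils::head(keep, n_asf)
}

ensure_edges <- function(qs) {
  for (lb in QUADRANT_LABELS)
    if (is.null(qs[[lb]]$edges))
      qs[[lb]] <- detect_corners_and_edges(qs[[lb]])
  qs
}

#' Mean fiducial distance, absolute and normalized
#'
#' @param pairs data.frame/matrix with columns `xa, ya, xb, yb`
#'   (pixel coordinates of each pair in a common frame).
#' @param scale_um_per_px physical pixel size.
#' @param ref_size_um `(width, height)` of the reference reconstruction in
#'   micrometres (normalizer: average of length and width).
#' @return list: `mean_um`, `pct`.
#' @export
fiducial_error <- function(pairs, scale_um_per_px, ref_size_um) {
  pairs <- as.matrix(pairs[, 1:4])
  if (nrow(pairs) < 1) stop("fiducial_error: no fiducial pairs")
  d <- sqrt((pairs[, 1] - pairs[, 3])^2 + (pairs[, 2] - pairs[, 4])^2)
  mean_um <- mean(d) * scale_um_per_px
  list(mean_um = mean_um, pct = 100 * mean_um / mean(ref_size_um))
}

#' ASF error of a test reconstruction against a reference
#'
#' Anchors from [place_asf_fiducials()] are carried into each adjacent
#' quadrant's local frame through the reference transforms and re-mapped
#' through the test transforms; the error is the mean distance between the
#' two re-mapped copies of each anchor.
#'
#' @param ref_ts,test_ts reference and test `transform_set`s.
#' @param qs `quadrant_set`.
#' @param scale_um_per_px physical pixel size.
#' @param ref_size_um reference reconstruction `(width, height)` in um.
#' @param n_asf anchor count.
#' @return list: `mean_um`, `pct`, `pairs` (per-anchor distances).
#' @export
asf_error <- function(ref_ts, test_ts, qs, scale_um_per_px, ref_size_um,
                      n_asf = 10) {
  qs <- ensure_edges(qs)
  an <- place_asf_fiducials(ref_ts, qs, n_asf = n_asf)
  map_through <- function(lb, p) {
    loc <- transform_points(invert_transform(ref_ts$transforms[[lb]]),
                            p)
    transform_points(test_ts$transforms[[lb]], loc)
  }
  pa <- t(vapply(seq_len(nrow(an)), function(i)
    map_through(an$label_a[i], c(an$x[i], an$y[i])), numeric(2)))
  pb <- t(vapply(seq_len(nrow(an)), function(i)
    map_through(an$label_b[i], c(an$x[i], an$y[i])), numeric(2)))
  fe <- fiducial_error(cbind(pa, pb), scale_um_per_px, ref_size_um)
  fe$pairs <- cbind(an, dist_px = sqrt(rowSums((pa - pb)^2)))
  fe
}

## dense 1-px-spaced chain around the convex hull of a mask
hull_chain <- function(bits, spacing = 1) {
  idx <- which(bits != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("hull_chain: empty mask")
  pts <- cbind(idx[, 2], idx[, 1])
  h <- grDevices::chull(pts)
  poly <- pts[c(h, h[1]), , drop = FALSE]
  seg <- sqrt(rowSums(diff(poly)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  s <- seq(0, L, by = spacing)
  s <- s[s < L]
  cbind(stats::approx(cum, poly[, 1], xout = s)$y,
        stats::approx(cum, poly[, 2], xout = s)$y)
}

#' Symmetric Hausdorff distance between two point chains
#' @param a,b `n x 2` coordinate matrices.
#' @return distance in the chains' units.
#' @export
hausdorff_dist <- function(a, b) {
  cpp_hausdorff(a[, 1], a[, 2], b[, 1], b[, 2])
}

golden_section <- function(f, lo, hi, tol = 0.05) {
  gr <- (sqrt(5) - 1) / 2
  c_ <- hi - gr * (hi - lo); d_ <- lo + gr * (hi - lo)
  fc <- f(c_); fd <- f(d_)
  while (abs(hi - lo) > tol) {
    if (fc < fd) { hi <- d_; d_ <- c_; fd <- fc
      c_ <- hi - gr * (hi - lo); fc <- f(c_)
    } else { lo <- c_; c_ <- d_; fc <- fd
      d_ <- lo + gr * (hi - lo); fd <- f(d_) }
  }
  (lo + hi) / 2
}

#' Hausdorff distance between aligned convex hulls
#'
#' Both tissue masks are reduced to convex hulls resampled at `spacing`-px
#' arc length.  Hull B is aligned onto hull A by centroid translation, a
#' rotation grid search over 360 degrees at 0.5-degree steps (run on
#' subsampled chains), and local refinement (golden-section on the angle,
#' coordinate descent on the translation, 0.1-px convergence); the
#' symmetric Hausdorff distance of the aligned full chains is reported.
#'
#' @param maskA,maskB `tissue_mask` objects (A is the reference).
#' @param scale_um_per_px physical pixel size.
#' @param ref_size_um optional normalizer `(width, height)` in um;
#'   defaults to the bounding-box size of `maskA`.
#' @param spacing chain resampling interval (px).
#' @return list: `hausdorff_um`, `pct`, `hausdorff_px`, `alignment`
#'   (angle in degrees and translation of B), `unaligned_px`.
#' @export
hull_hausdorff <- function(maskA, maskB, scale_um_per_px = 1,
                           ref_size_um = NULL, spacing = 1) {
  a <- hull_chain(if (inherits(maskA, "tissue_mask")) maskA$bits else maskA,
                  spacing)
  b <- hull_chain(if (inherits(maskB, "tissue_mask")) maskB$bits else maskB,
                  spacing)
  ca <- colMeans(a); cb <- colMeans(b)
  b0 <- sweep(b, 2, cb)          # B about its centroid
  a_c <- sweep(a, 2, ca)
  pose_chain <- function(ang, dt, chain) {
    R <- rotation_matrix(ang)
    sweep(chain %*% t(R), 2, dt, "+")
  }
  hd_at <- function(ang, dt, bb, aa)
    cpp_hausdorff(aa[, 1], aa[, 2],
                  pose_chain(ang, dt, bb)[, 1], pose_chain(ang, dt, bb)[, 2])

  # coarse grid on subsampled chains
  sub <- function(m, k) m[seq(1, nrow(m), by = k), , drop = FALSE]
  k <- max(1L, floor(nrow(a) / 400))
  as_ <- sub(a_c, k); bs_ <- sub(b0, k)
  angles <- seq(0, 359.5, by = 0.5)
  hs <- vapply(angles, function(ang) hd_at(ang, c(0, 0), bs_, as_),
               numeric(1))
  ang <- angles[which.min(hs)]
  # refinement on the full chains
  dt <- c(0, 0)
  for (it in 1:4) {
    ang <- golden_section(function(x) hd_at(x, dt, b0, a_c),
                          ang - 1, ang + 1, tol = 0.02)
    dx <- golden_section(function(x) hd_at(ang, c(x, dt[2]), b0, a_c),
                         dt[1] - 3, dt[1] + 3, tol = 0.1)
    dy <- golden_section(function(y) hd_at(ang, c(dx, y), b0, a_c),
                         dt[2] - 3, dt[2] + 3, tol = 0.1)
    if (max(abs(c(dx - dt[1], dy - dt[2]))) < 0.1) { dt <- c(dx, dy); break }
    dt <- c(dx, dy)
  }
  h_aligned <- hd_at(ang, dt, b0, a_c)
  h_unaligned <- hd_at(0, c(0, 0), b0, a_c)
  if (h_unaligned < h_aligned) { ang <- 0; dt <- c(0, 0)
    h_aligned <- h_unaligned }
  if (is.null(ref_size_um)) {
    ref_size_um <- c(diff(range(a[, 1])) + 1, diff(range(a[, 2])) + 1) *
      scale_um_per_px
  }
  h_um <- h_aligned * scale_um_per_px
  list(hausdorff_um = h_um, pct = 100 * h_um / mean(ref_size_um),
       hausdorff_px = h_aligned,
       alignment = list(angle_deg = ang,
                        translation = ca - cb + dt),
       unaligned_px = h_unaligned)
}

#' Full evaluation report of a test reconstruction against a reference
#'
#' Computes the ASF error, optionally the MSF error from supplied fiducial
#' pairs, and the aligned convex-hull Hausdorff distance, each absolute
#' (um) and normalized by the average of the reference reconstruction's
#' width and height (%).
#'
#' @param ref_ts,test_ts reference and test `transform_set`s.
#' @param qs the `quadrant_set`.
#' @param msf optional MSF pairs: a CSV path or data.frame with columns
#'   `ref_x, ref_y, test_x, test_y` (px; each row one fiducial, its
#'   position per the reference and per the test reconstruction).
#' @param n_asf ASF anchor count.
#' @return class `eval_report`: `asf_um`, `asf_pct`, `msf_um`, `msf_pct`,
#'   `hausdorff_um`, `hausdorff_pct`, `ref_width_um`, `ref_height_um`,
#'   `n_fiducials`.
#' @export
evaluate_reconstruction <- function(ref_ts, test_ts, qs, msf = NULL,
                                    n_asf = 10) {
  if (inherits(ref_ts, "stitch_result")) ref_ts <- ref_ts$transforms
  if (inherits(test_ts, "stitch_result")) test_ts <- test_ts$transforms
  qs <- ensure_edges(qs)
  scale <- qs$ul$image$scale_um_per_px
  ref_c <- composite_section(qs, ref_ts)
  test_c <- composite_section(qs, test_ts)
  bb <- mask_bbox(ref_c$mask$bits)
  ref_size_um <- c(bb$x1 - bb$x0 + 1, bb$y1 - bb$y0 + 1) * scale

  asf <- asf_error(ref_ts, test_ts, qs, scale, ref_size_um, n_asf = n_asf)
  hh <- hull_hausdorff(ref_c$mask, test_c$mask, scale, ref_size_um)

  msf_um <- msf_pct <- NA_real_
  n_msf <- 0L
  if (!is.null(msf)) {
    if (is.character(msf)) msf <- utils::read.csv(msf)
    need <- c("ref_x", "ref_y", "test_x", "test_y")
    if (!all(need %in% names(msf)))
      stop("evaluate_reconstruction: MSF table needs columns ",
           paste(need, collapse = ", "))
    fe <- fiducial_error(msf[, need], scale, ref_size_um)
    msf_um <- fe$mean_um; msf_pct <- fe$pct
    n_msf <- nrow(msf)
  }
  structure(list(asf_um = asf$mean_um, asf_pct = asf$pct,
                 msf_um = msf_um, msf_pct = msf_pct,
                 hausdorff_um = hh$hausdorff_um,
                 hausdorff_pct = hh$pct,
                 ref_width_um = ref_size_um[1],
                 ref_height_um = ref_size_um[2],
                 n_fiducials = n_asf + n_msf),
            class = "eval_report")
}

#' MSF fiducial table from synthetic ground-truth landmarks
#'
#' Each landmark (both members of every straddling pair) is mapped through
#' the reference and the test transforms of its owning quadrant, yielding
#' one row of the MSF table.
#'
#' @param landmarks landmark data.frame from [fragment_phantom()].
#' @param ref_ts,test_ts `transform_set`s.
#' @return data.frame with columns `ref_x, ref_y, test_x, test_y`.
#' @export
landmarks_to_msf <- function(landmarks, ref_ts, test_ts) {
  one <- function(lb, x, y) {
    loc <- cbind(x, y)
    list(ref = transform_points(ref_ts$transforms[[lb]], loc),
         test = transform_points(test_ts$transforms[[lb]], loc))
  }
  rows <- list()
  for (i in seq_len(nrow(landmarks))) {
    for (side in c("a", "b")) {
      lb <- landmarks[[paste0("label_", side)]][i]
      p <- one(lb, landmarks[[paste0("local_x", side)]][i],
               landmarks[[paste0("local_y", side)]][i])
      rows[[length(rows) + 1]] <- data.frame(
        ref_x = p$ref[1], ref_y = p$ref[2],
        test_x = p$test[1], test_y = p$test[2])
    }
  }
  do.call(rbind, rows)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> ASF %.1f um (%.2f%%)", x$asf_um, x$asf_pct))
  if (!is.na(x$msf_um))
    cat(sprintf("  MSF %.1f um (%.2f%%)", x$msf_um, x$msf_pct))
  cat(sprintf("  Hausdorff %.1f um (%.2f%%)\n",
              x$hausdorff_um, x$hausdorff_pct))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(asf_um = x$asf_um, asf_pct = x$asf_pct, msf_um = x$msf_um,
             msf_pct = x$msf_pct, hausdorff_um = x$hausdorff_um,
             hausdorff_pct = x$hausdorff_pct,
             ref_width_um = x$ref_width_um,
             ref_height_um = x$ref_height_um,
             n_fiducials = x$n_fiducials)
}

#' Write an evaluation report as JSON
#' @param report an `eval_report`.
#' @param path output path.
#' @export
write_eval_report <- function(report, path) {
  writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                              digits = NA, na = "null"), path)
  invisible(path)
}

#' Read an evaluation report written by [write_eval_report()]
#' @param path JSON path.
#' @export
read_eval_report <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj[vapply(obj, is.null, logical(1))] <- NA_real_
  structure(obj, class = "eval_report")
}
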