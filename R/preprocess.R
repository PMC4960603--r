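#' Standardize a raw fragment image
#'
#' Applies the preprocessing contract: down-sampling so that the larger
#' dimension equals `target_max_dim` (images already at or below the target
#' are left unchanged), user-specified flips, grayscale conversion (done at
#' read time) and rescaling of intensities to `[0, 1]`.
#'
#' @param x path to a PNG/TIFF file, or a `gray_image`.
#' @param flip_h,flip_v mirror about the vertical / horizontal axis.
#' @param target_max_dim working resolution in pixels.
#' @param scale_um_per_px physical pixel size of the *input* image.
#' @return a `gray_image` at working resolution.
#' @export
standardize <- function(x, flip_h = FALSE, flip_v = FALSE,
                        target_max_dim = 1024, scale_um_per_px = 1) {
  if (is.character(x)) x <- read_gray_image(x, scale_um_per_px)
  stopifnot(inherits(x, "gray_image"))
  if (target_max_dim < 1) stop("standardize: target_max_dim must be >= 1")
  px <- x$pixels
  cur <- max(dim(px))
  scale <- x$scale_um_per_px
  if (cur > target_max_dim) {
    ratio <- target_max_dim / cur
    w <- max(1L, round(ncol(px) * ratio))
    h <- max(1L, round(nrow(px) * ratio))
    r <- EBImage::resize(EBImage::Image(t(px)), w = w, h = h,
                         antialias = TRUE)
    px <- t(EBImage::imageData(r))
    px <- pmin(pmax(px, 0), 1)
    scale <- scale / ratio
  }
  if (flip_h) px <- px[, rev(seq_len(ncol(px))), drop = FALSE]
  if (flip_v) px <- px[rev(seq_len(nrow(px))), , drop = FALSE]
  gray_image(px, scale_um_per_px = scale)
}

#' Segment the tissue foreground from background
#'
#' Tissue is darker than the (near-white) background: Otsu's threshold is
#' taken on the inverted intensity, followed by morphological closing,
#' hole filling, and retention of the largest connected component.
#'
#' @param img a `gray_image`.
#' @param closing_radius_px radius of the closing disc.
#' @param threshold `"auto"` (Otsu) or a numeric threshold on the inverted
#'   intensity in `[0, 1]`.
#' @return a `tissue_mask`.
#' @export
segment_tissue <- function(img, closing_radius_px = 5, threshold = "auto") {
  stopifnot(inherits(img, "gray_image"))
  inv <- 1 - img$pixels
  if (diff(range(inv)) < 1e-9)
    stop("segment_tissue: image has no intensity variation; ",
         "supply an explicit threshold override")
  thr <- if (identical(threshold, "auto")) {
    EBImage::otsu(EBImage::Image(t(inv)))
  } else as.numeric(threshold)
  bw <- EBImage::Image(t(inv > thr))
  if (closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius_px + 1, shape = "disc")
    bw <- EBImage::closing(bw, brush)
  }
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  if (length(tab) == 0 || max(tab) == 0)
    stop("segment_tissue: empty foreground; ",
         "supply an explicit threshold override")
  keep <- which.max(tab)
  tissue_mask(t(EBImage::imageData(lab) == keep))
}

#' Minimum-area bounding box of a tissue mask
#'
#' Rotating calipers over the convex hull of foreground pixel centers; the
#' reported area counts whole pixels (extent of centers plus one).
#'
#' @param mask a `tissue_mask`.
#' @return list with `corners` (4 x 2 matrix of `(x, y)`, ordered around
#'   the rectangle), `area` (px^2) and `angle` (degrees of the long side).
#' @export
min_area_bbox <- function(mask) {
  bits <- if (inherits(mask, "tissue_mask")) mask$bits else mask
  idx <- which(bits != 0, arr.ind = TRUE)
  if (nrow(idx) < 3)
    stop("min_area_bbox: need at least 3 foreground pixels")
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  n <- nrow(hull)
  best <- list(area = Inf)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d <- hull[j, ] - hull[i, ]
    ang <- atan2(d[2], d[1])
    R <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2, 2)
    rot <- hull %*% t(R)
    xr <- range(rot[, 1]); yr <- range(rot[, 2])
    area <- (diff(xr) + 1) * (diff(yr) + 1)
    if (area < best$area) {
      corners_rot <- cbind(xr[c(1, 2, 2, 1)], yr[c(1, 1, 2, 2)])
      best <- list(area = area,
                   corners = corners_rot %*% R,
                   angle = ang * 180 / pi)
    }
  }
  list(corners = unname(best$corners), area = best$area, angle = best$angle)
}

#' Theil-Sen robust line fit
#'
#' Slope is the median over all pairwise slopes, intercept the median of
#' `y - slope * x`.  Edges longer than `max_points` are subsampled on a
#' deterministic stride before slope enumeration.  A perfectly vertical
#' point set is refit with axes swapped (`swapped = TRUE`; the fit is then
#' `x = slope * y + intercept`).
#'
#' @param pts `n x 2` matrix of `(x, y)` points (n >= 2).
#' @param swap fit with axes swapped (used for vertical-facing edges).
#' @param max_points subsample cap for the O(n^2) slope enumeration.
#' @return list with `slope`, `intercept`, `swapped`.
#' @export
theil_sen <- function(pts, swap = FALSE, max_points = 500) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (nrow(pts) < 2) stop("theil_sen: need at least 2 points")
  if (all(pts[, 1] == pts[1, 1]) && all(pts[, 2] == pts[1, 2]))
    stop("theil_sen: all points identical")
  if (swap) pts <- pts[, 2:1, drop = FALSE]
  if (nrow(pts) > max_points) {
    keep <- unique(round(seq(1, nrow(pts), length.out = max_points)))
    pts <- pts[keep, , drop = FALSE]
  }
  x <- pts[, 1]; y <- pts[, 2]
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  use <- upper.tri(dx) & dx != 0
  if (!any(use)) {
    # vertical in these axes: fit with axes swapped
    fit <- theil_sen(pts[, 2:1, drop = FALSE], swap = FALSE,
                     max_points = max_points)
    fit$swapped <- !swap
    return(fit)
  }
  slope <- stats::median(dy[use] / dx[use])
  intercept <- stats::median(y - slope * x)
  list(slope = slope, intercept = intercept, swapped = swap)
}

## project points onto a fitted line and return the two extreme endpoints
line_endpoints <- function(pts, fit) {
  if (fit$swapped) {
    p0 <- c(fit$intercept, 0); d <- c(fit$slope, 1)
  } else {
    p0 <- c(0, fit$intercept); d <- c(1, fit$slope)
  }
  d <- d / sqrt(sum(d^2))
  tv <- (pts[, 1] - p0[1]) * d[1] + (pts[, 2] - p0[2]) * d[2]
  rbind(p0 + min(tv) * d, p0 + max(tv) * d)
}

## which endpoint points toward the section interior, by anatomic label
assign_inner_outer <- function(endpts, orientation, label) {
  if (orientation == "horizontal") {
    inner_is_max <- label %in% c("ul", "ll")   # interior lies at larger x
    key <- endpts[, 1]
  } else {
    inner_is_max <- label %in% c("ul", "ur")   # interior lies at larger y
    key <- endpts[, 2]
  }
  i_in <- if (inner_is_max) which.max(key) else which.min(key)
  list(C_in = endpts[i_in, ], C_out = endpts[3 - i_in, ])
}

## resample an ordered point chain at uniform arc length (keeps order)
resample_chain <- function(pts, spacing = 1) {
  if (nrow(pts) < 3) return(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (L < spacing) return(pts)
  s <- seq(0, L, by = spacing)
  cbind(stats::approx(cum, pts[, 1], xout = s)$y,
        stats::approx(cum, pts[, 2], xout = s)$y)
}

## perpendicular distance of points to a fitted (possibly axis-swapped)
## line
line_distance <- function(pts, fit) {
  if (fit$swapped) {
    abs(pts[, 1] - fit$slope * pts[, 2] - fit$intercept) /
      sqrt(1 + fit$slope^2)
  } else {
    abs(pts[, 2] - fit$slope * pts[, 1] - fit$intercept) /
      sqrt(1 + fit$slope^2)
  }
}

make_edge <- function(pixels, orientation, label, corridor_px = 8,
                      trim_px = 2) {
  # uniform 1-px arc-length spacing so that facing parallel edges pair
  # one-to-one under projection correspondence
  pixels <- resample_chain(matrix(as.numeric(pixels), ncol = 2))
  # keep the longest contiguous run inside a corridor around the cut:
  # first a wide corridor around the robust straight fit, then a tight
  # corridor around a flexible robust fit that follows the cut's
  # waviness.  The chain then ends where the contour departs from the
  # cut itself -- shared geometry -- so facing edges end at consistent
  # positions instead of at independently detected corners
  longest_run <- function(pixels, inside) {
    r <- rle(inside)
    if (!any(r$values)) return(pixels)
    len <- r$lengths; ends <- cumsum(len)
    runs <- which(r$values)
    best <- runs[which.max(len[runs])]
    keep <- (ends[best] - len[best] + 1):ends[best]
    if (length(keep) >= 10) pixels[keep, , drop = FALSE] else pixels
  }
  fit0 <- theil_sen(pixels, swap = orientation == "vertical")
  pixels <- longest_run(pixels, line_distance(pixels, fit0) <= corridor_px)
  if (nrow(pixels) >= 30) {
    sw <- orientation == "vertical"
    xv <- if (sw) pixels[, 2] else pixels[, 1]
    yv <- if (sw) pixels[, 1] else pixels[, 2]
    lo <- try(suppressWarnings(
      stats::loess(yv ~ xv, span = 0.5, degree = 2,
                   family = "symmetric",
                   control = stats::loess.control(surface = "direct"))),
      silent = TRUE)
    if (!inherits(lo, "try-error")) {
      resid <- abs(yv - stats::predict(lo, xv))
      pixels <- longest_run(pixels, resid <= max(3, corridor_px / 2.5))
    }
  }
  n <- nrow(pixels)
  if (n > 4 * trim_px && trim_px > 0)
    pixels <- pixels[(trim_px + 1):(n - trim_px), , drop = FALSE]
  fit <- theil_sen(pixels, swap = orientation == "vertical")
  ep <- line_endpoints(pixels, fit)
  io <- assign_inner_outer(ep, orientation, label)
  structure(list(pixels = pixels, line_slope = fit$slope,
                 line_intercept = fit$intercept, swapped = fit$swapped,
                 orientation = orientation, C_in = io$C_in,
                 C_out = io$C_out),
            class = "stitch_edge")
}

## ordered outer boundary contour of the largest object, 1-based (x, y)
contour_cycle <- function(bits) {
  oc <- EBImage::ocontour(EBImage::Image(t(bits)))
  if (length(oc) == 0) stop("contour_cycle: empty mask")
  len <- vapply(oc, nrow, integer(1))
  ct <- oc[[which.max(len)]] + 1L
  colnames(ct) <- c("x", "y")
  ct
}

#' Detect cut-edge geometry of a quadrant
#'
#' The minimum-area bounding box has one corner external to the prostate
#' (chosen by anatomic label); contour points nearest the other three box
#' corners are the "corner points", and the two contour runs between them
#' that face the section interior are the stitch edges.  Each edge gets a
#' Theil-Sen best-fit line with inner (`C_in`) and outer (`C_out`)
#' endpoints.
#'
#' @param q a `quadrant` with a segmented mask.
#' @return the `quadrant` with its `edges` field set to an `edge_geometry`
#'   (fields `bbox_corners`, `corner_points`, `external_corner`, `edges`
#'   with elements `h` and `v`).
#' @export
detect_corners_and_edges <- function(q) {
  stopifnot(inherits(q, "quadrant"))
  ct <- contour_cycle(q$mask$bits)
  if (nrow(ct) < 10)
    stop("detect_corners_and_edges: contour shorter than 10 px")
  bb <- min_area_bbox(q$mask)
  sc <- switch(q$label,
               ul = -(bb$corners[, 1] + bb$corners[, 2]),
               ur = bb$corners[, 1] - bb$corners[, 2],
               ll = bb$corners[, 2] - bb$corners[, 1],
               lr = bb$corners[, 1] + bb$corners[, 2])
  ext <- which.max(sc)
  nearest_idx <- function(p) {
    which.min((ct[, 1] - p[1])^2 + (ct[, 2] - p[2])^2)
  }
  corner_idx <- vapply(seq_len(4)[-ext], function(i)
    nearest_idx(bb$corners[i, ]), integer(1))
  if (length(unique(corner_idx)) < 3)
    stop("detect_corners_and_edges: degenerate corner detection")
  ext_near <- nearest_idx(bb$corners[ext, ])

  n <- nrow(ct)
  ord <- sort(corner_idx)
  arcs <- list(c(ord[1], ord[2]), c(ord[2], ord[3]), c(ord[3], ord[1]))
  # extend arcs past the detected corner points; the corridor filter in
  # make_edge finds the true cut ends, so corner detection only needs to
  # be approximate
  arc_ext <- 15L
  arc_pixels <- lapply(arcs, function(a) {
    a2 <- if (a[1] <= a[2]) a[2] else a[2] + n
    idx <- ((a[1] - arc_ext):(a2 + arc_ext) - 1L) %% n + 1L
    ct[idx, , drop = FALSE]
  })
  contains_ext <- vapply(arcs, function(a) {
    if (a[1] <= a[2]) ext_near >= a[1] && ext_near <= a[2]
    else ext_near >= a[1] || ext_near <= a[2]
  }, logical(1))
  edge_arcs <- arc_pixels[!contains_ext]
  if (length(edge_arcs) != 2)
    stop("detect_corners_and_edges: could not isolate two interior edges")
  spreads <- vapply(edge_arcs, function(p)
    diff(range(p[, 1])) - diff(range(p[, 2])), numeric(1))
  h_first <- spreads[1] >= spreads[2]
  e_h <- make_edge(edge_arcs[[if (h_first) 1 else 2]], "horizontal", q$label)
  e_v <- make_edge(edge_arcs[[if (h_first) 2 else 1]], "vertical", q$label)
  q$edges <- structure(
    list(bbox_corners = bb$corners,
         corner_points = ct[ord, , drop = FALSE],
         external_corner = bb$corners[ext, ],
         edges = list(h = e_h, v = e_v)),
    class = "edge_geometry")
  q
}

## rigidly move an edge and refit its line/endpoints
transform_edge <- function(edge, t, label) {
  make_edge(transform_points(t, edge$pixels), edge$orientation, label)
}

mask_centroid <- function(bits) {
  idx <- which(bits != 0, arr.ind = TRUE)
  c(mean(idx[, 2]), mean(idx[, 1]))
}

## occupancy keys of a transformed mask (rounded pixel coordinates)
occupancy_keys <- function(bits, t) {
  idx <- which(bits != 0, arr.ind = TRUE)
  p <- transform_points(t, cbind(idx[, 2], idx[, 1]))
  unique(round(p[, 1]) * 1e5 + round(p[, 2]))
}

edge_mid <- function(edge) (edge$C_in + edge$C_out) / 2

#' Low-resolution initial reconstruction
#'
#' Each quadrant is rotated so its horizontal-facing cut edge is level and
#' its vertical-facing edge upright (the two per-edge estimates are
#' averaged; rotation acts about the tissue centroid).  Quadrants are then
#' translated so facing best-fit lines coincide: the normal offset comes
#' from the line difference over the overlapping span, the tangential
#' offset from the chain span midpoints; finally quadrants are pushed
#' apart along the facing normal until mask overlap is at most
#' `max_overlap` of the smaller quadrant.  The result is re-expressed
#' relative to the fixed `ul` quadrant and returned in base-resolution
#' units.
#'
#' @param qs a `quadrant_set` (segmented; edges need not be present).
#' @param coarse_factor integer downsample factor at which alignment runs.
#' @param max_overlap allowed pairwise overlap fraction.
#' @return a `transform_set` (base-resolution px / deg, fixed = ul).
#' @export
initial_align <- function(qs, coarse_factor = 4, max_overlap = 0.01) {
  stopifnot(inherits(qs, "quadrant_set"))
  f <- as.integer(coarse_factor)
  coarse <- lapply(QUADRANT_LABELS, function(lb) {
    lev <- build_pyramid(qs[[lb]], factors = if (f > 1) c(f, 1L) else 1L)[[1]]
    detect_corners_and_edges(quadrant(lb, lev$image, lev$mask))
  })
  names(coarse) <- QUADRANT_LABELS

  g <- list()   # per-quadrant transform into the internal aligned frame
  rot_edges <- list()
  occ <- list()
  for (lb in QUADRANT_LABELS) {
    q <- coarse[[lb]]
    eh <- q$edges$edges$h
    ev <- q$edges$edges$v
    s_h <- if (eh$swapped) 1 / eh$line_slope else eh$line_slope
    # both edges estimate the same quadrant rotation: the horizontal edge
    # must become level and the vertical edge upright
    th_h <- -atan(s_h) * 180 / pi
    th_v <- if (ev$swapped) atan(ev$line_slope) * 180 / pi
            else atan(1 / ev$line_slope) * 180 / pi
    theta <- (th_h + th_v) / 2
    ctr <- mask_centroid(q$mask$bits)
    g[[lb]] <- rigid_transform(0, 0, theta, center = ctr)
    rot_edges[[lb]] <- list(
      h = transform_edge(q$edges$edges$h, g[[lb]], lb),
      v = transform_edge(q$edges$edges$v, g[[lb]], lb))
  }

  shift_t <- function(t, dt) rigid_transform(t$tx + dt[1], t$ty + dt[2],
                                             t$theta, t$center, t$flip_h)
  occ_of <- function(lb) occupancy_keys(coarse[[lb]]$mask$bits, g[[lb]])
  overlap_frac <- function(a, b) {
    length(intersect(a, b)) / min(length(a), length(b))
  }
  push_until_clear <- function(lb, others, dir, max_iter = 300) {
    dir <- dir / sqrt(sum(dir^2))
    it <- 0
    while (it < max_iter) {
      a <- occ_of(lb)
      ov <- max(vapply(others, function(o) overlap_frac(a, occ[[o]]),
                       numeric(1)))
      if (ov <= max_overlap) break
      g[[lb]] <<- shift_t(g[[lb]], dir)
      it <- it + 1
    }
  }
  place <- function(lb, dt) {
    g[[lb]] <<- shift_t(g[[lb]], dt)
    rot_edges[[lb]] <<- list(
      h = transform_edge(coarse[[lb]]$edges$edges$h, g[[lb]], lb),
      v = transform_edge(coarse[[lb]]$edges$edges$v, g[[lb]], lb))
  }

  # normal offset between two nearly parallel facing edges: difference of
  # their best-fit lines evaluated over the overlap of their spans
  line_offset <- function(eA, eB, orientation) {
    fA <- theil_sen(eA$pixels, swap = orientation == "vertical")
    fB <- theil_sen(eB$pixels, swap = orientation == "vertical")
    i <- if (orientation == "vertical") 2 else 1   # span coordinate
    lo <- max(min(eA$pixels[, i]), min(eB$pixels[, i]))
    hi <- min(max(eA$pixels[, i]), max(eB$pixels[, i]))
    if (hi <= lo) { lo <- min(eA$pixels[, i]); hi <- max(eA$pixels[, i]) }
    tgrid <- seq(lo, hi, length.out = 25)
    ev <- function(fit) if (fit$swapped == (orientation == "vertical"))
      fit$slope * tgrid + fit$intercept
    else stop("initial_align: inconsistent edge fit axes")
    mean(ev(fA) - ev(fB))
  }

  occ$ul <- occ_of("ul")
  # ur right of ul, facing vertical edges: tangential (y) from the chain
  # span midpoints, normal (x) from the best-fit lines
  place("ur", c(0, edge_mid(rot_edges$ul$v)[2] -
                  edge_mid(rot_edges$ur$v)[2]))
  place("ur", c(line_offset(rot_edges$ul$v, rot_edges$ur$v, "vertical"), 0))
  push_until_clear("ur", "ul", c(1, 0))
  occ$ur <- occ_of("ur")
  # ll below ul, facing horizontal edges
  place("ll", c(edge_mid(rot_edges$ul$h)[1] -
                  edge_mid(rot_edges$ll$h)[1], 0))
  place("ll", c(0, line_offset(rot_edges$ul$h, rot_edges$ll$h,
                               "horizontal")))
  push_until_clear("ll", "ul", c(0, 1))
  occ$ll <- occ_of("ll")
  # lr: both constraints are normal offsets -- x from ll's vertical edge,
  # y from ur's horizontal edge
  place("lr", c(edge_mid(rot_edges$ll$v)[1] - edge_mid(rot_edges$lr$v)[1],
                edge_mid(rot_edges$ur$h)[2] - edge_mid(rot_edges$lr$h)[2]))
  place("lr", c(line_offset(rot_edges$ll$v, rot_edges$lr$v, "vertical"),
                line_offset(rot_edges$ur$h, rot_edges$lr$h, "horizontal")))
  push_until_clear("lr", c("ul", "ur", "ll"), c(1, 1))

  # re-express relative to ul, scale to base resolution, recenter on the
  # base-resolution tissue centroids
  g_ul_inv <- invert_transform(g$ul)
  out <- list()
  for (lb in QUADRANT_LABELS) {
    rel <- compose_transforms(g_ul_inv, g[[lb]])
    base <- scale_transform(rel, f)
    ctr <- mask_centroid(qs[[lb]]$mask$bits)
    a <- transform_affine(base)
    out[[lb]] <- affine_to_rigid(a$R, a$v, ctr)
  }
  out$ul <- rigid_transform(0, 0, 0, center = mask_centroid(qs$ul$mask$bits))
  transform_set(out, fixed = "ul")
}
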