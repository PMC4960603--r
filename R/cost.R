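#' Cost-function configuration
#'
#' Defaults are the empirically optimal values: `w1 = 0.989` (dissimilarity
#' weight, `w2 = 1 - w1`), `w3 = 0.4` (inner-point weight, `w4 = 1 - w3`),
#' patch side `p = 81` px at base resolution, `b = 16` histogram bins.  The
#' maximum dissimilarity `phi` is 2 between normalized histograms and 1
#' between single intensities; it is derived from the patch size at each
#' resolution level and is not a free parameter.
#'
#' @param w1 weight of the dissimilarity component (`w2 = 1 - w1` weights
#'   misalignment).
#' @param w3 weight of the inner corner-point pair (`w4 = 1 - w3` the
#'   outer pair).
#' @param patch_px square patch side in base-resolution px (odd).
#' @param bins number of histogram bins (>= 2).
#' @param tau_px correspondence distance threshold in current-level px;
#'   `NULL` means the patch radius at the current level.
#' @param normal_cone_deg half-angle (degrees) of the cone about the edge
#'   normal within which a match displacement must lie for two edge
#'   pixels to count as facing each other across the cut; 90 (the
#'   default) disables the test, leaving overhang handling to the
#'   projection rule alone.
#' @return an object of class `cost_config`.
#' @export
cost_config <- function(w1 = 0.989, w3 = 0.4, patch_px = 81, bins = 16,
                        tau_px = NULL, normal_cone_deg = 90) {
  if (w1 < 0 || w1 > 1 || w3 < 0 || w3 > 1)
    stop("cost_config: weights must lie in [0, 1]")
  patch_px <- as.integer(patch_px)
  if (patch_px < 1 || patch_px %% 2 == 0)
    stop("cost_config: patch_px must be odd and >= 1")
  if (bins < 2) stop("cost_config: bins must be >= 2")
  structure(list(w1 = w1, w2 = 1 - w1, w3 = w3, w4 = 1 - w3,
                 p = patch_px, b = as.integer(bins), tau_px = tau_px,
                 min_cos = if (normal_cone_deg >= 90) -1
                           else cos(normal_cone_deg * pi / 180)),
            class = "cost_config")
}

## patch side at a pyramid level; a patch of constant physical size spans a
## single pixel at the lowest resolution
patch_at_level <- function(p, factor) max(1L, as.integer(round(p / factor)))

phi_for <- function(p_level) if (p_level > 1) 2 else 1

tau_for <- function(cfg, factor) {
  p_level <- patch_at_level(cfg$p, factor)
  tau_level <- if (is.null(cfg$tau_px)) max(1, p_level / 2) else cfg$tau_px
  tau_level * factor   # in base-resolution px
}

## which edges face each other for a pair of adjacent labels:
## vertically split pairs share vertical edges, horizontally split pairs
## share horizontal edges
facing_edge <- function(labelA, labelB) {
  if (substr(labelA, 1, 1) == substr(labelB, 1, 1)) "v" else "h"
}

ADJACENT_PAIRS <- list(c("ul", "ur"), c("ur", "lr"), c("lr", "ll"),
                       c("ll", "ul"))

## unit normal of an edge's best-fit line after a rigid transform
edge_normal <- function(edge, t) {
  u <- edge$C_in - edge$C_out
  u <- as.numeric(rotation_matrix(t$theta) %*% u)
  n <- c(-u[2], u[1])
  n / sqrt(sum(n^2))
}

#' Corresponding edge pixels between two adjacent quadrants
#'
#' Both facing-edge pixel lists are mapped into the common frame; a pixel
#' of one edge corresponds to the facing edge's pixel nearest the foot of
#' its projection onto that edge's polyline, provided the foot is
#' interior (no overhang past the edge ends), the distance is at most
#' `tau`, and the displacement lies within the normal cone of the edge
#' (the pair faces each other across the cut).  Partners are claimed
#' injectively so the matching cannot collapse many-to-one.  Edge pixels
#' of either quadrant left unmatched are non-corresponding.
#'
#' @param qA,qB `quadrant`s with detected edges.
#' @param tA,tB their `rigid_transform`s into the common frame.
#' @param tau correspondence distance threshold (common-frame px).
#' @param min_cos cosine of the normal-cone half-angle (<= 0 disables).
#' @return an object of class `correspondence_set`: `pairs` (n x 4 matrix
#'   `x1, y1, x2, y2`), `match` (per-A-pixel 1-based index into B, 0 if
#'   none), `n`, `m`.
#' @export
find_correspondences <- function(qA, qB, tA, tB, tau,
                                 min_cos = cos(pi / 4)) {
  if (is.null(qA$edges) || is.null(qB$edges))
    stop("find_correspondences: edge geometry missing; run ",
         "detect_corners_and_edges() first")
  key <- facing_edge(qA$label, qB$label)
  ea <- qA$edges$edges[[key]]
  pa <- transform_points(tA, ea$pixels)
  pb <- transform_points(tB, qB$edges$edges[[key]]$pixels)
  nrm <- edge_normal(ea, tA)
  match <- cpp_proj_match(pa[, 1], pa[, 2], pb[, 1], pb[, 2], tau,
                          nrm[1], nrm[2], min_cos)
  hit <- match > 0
  n <- sum(hit)
  structure(list(
    pairs = cbind(pa[hit, , drop = FALSE], pb[match[hit], , drop = FALSE]),
    match = match, n = n,
    m = (nrow(pa) - n) + (nrow(pb) - n)),
    class = "correspondence_set")
}

#' Intensity histogram (or single intensity) of a square patch
#'
#' Tissue pixels inside the `p x p` window centred on `center` are binned
#' into `b` uniform bins on `[0, 1]` and normalized to a discrete
#' probability density.  With `p = 1` the raw intensity is returned
#' (pixel mode).  A window containing no tissue yields an empty marker.
#'
#' @param img a `gray_image`.
#' @param mask its `tissue_mask`.
#' @param center integer `(x, y)` patch centre.
#' @param p patch side at the current resolution (odd).
#' @param b histogram bin count.
#' @return class `intensity_histogram`: `bins` (length `b`, or length 1 in
#'   pixel mode), `mode`, `empty`.
#' @export
patch_vector <- function(img, mask, center, p, b) {
  px <- img$pixels; bits <- mask$bits
  cx <- as.integer(round(center[1])); cy <- as.integer(round(center[2]))
  if (cx < 1 || cx > ncol(px) || cy < 1 || cy > nrow(px))
    stop("patch_vector: center outside image")
  if (p == 1) {
    if (bits[cy, cx] == 0)
      return(structure(list(bins = NA_real_, mode = "pixel", empty = TRUE),
                       class = "intensity_histogram"))
    return(structure(list(bins = px[cy, cx], mode = "pixel", empty = FALSE),
                     class = "intensity_histogram"))
  }
  r <- cpp_patch_hist(px, bits, cx, cy, as.integer(p), as.integer(b))
  structure(list(bins = as.numeric(r$V[, 1]), mode = "histogram",
                 empty = r$empty[1]),
            class = "intensity_histogram")
}

#' L1 dissimilarity between two patch vectors
#'
#' Sum of absolute bin differences (histogram mode) or absolute intensity
#' difference (pixel mode).  Bounded by 2 for normalized histograms and by
#' 1 for intensities in `[0, 1]`.
#'
#' @param V1,V2 `intensity_histogram` objects of the same mode and size.
#' @export
l1_dissimilarity <- function(V1, V2) {
  if (!identical(V1$mode, V2$mode) ||
      length(V1$bins) != length(V2$bins))
    stop("l1_dissimilarity: mode or bin-count mismatch")
  sum(abs(V1$bins - V2$bins))
}

## core pair dissimilarity given precomputed per-edge patch matrices
## (columns = non-empty edge pixels, base-resolution coords)
pair_dissim_core <- function(pa, pb, Va, Vb, tau, phi, n_empty,
                             nrm = c(0, 0), min_cos = -1) {
  cpp_pair_dissim(pa[, 1], pa[, 2], pb[, 1], pb[, 2], Va, Vb,
                  tau, phi, as.integer(n_empty), nrm[1], nrm[2], min_cos)
}

## patch matrix for all pixels of one edge; edge pixels are given in
## base-resolution coordinates and sampled from the level image (so the
## geometry is resolution-independent while the appearance term follows
## the pyramid).  Returns base coordinates of non-empty pixels and their
## patch vectors.
edge_patch_matrix <- function(img, mask, edge_pixels_base, factor, p_level,
                              b) {
  lvl <- (edge_pixels_base - 0.5) / factor + 0.5   # exact center map
  cx <- as.integer(round(lvl[, 1])); cy <- as.integer(round(lvl[, 2]))
  cx <- pmin(pmax(cx, 1L), ncol(img)); cy <- pmin(pmax(cy, 1L), nrow(img))
  if (p_level == 1) {
    vals <- img[cbind(cy, cx)]
    empty <- mask[cbind(cy, cx)] == 0L
    V <- matrix(vals[!empty], nrow = 1)
  } else {
    r <- cpp_patch_hist(img, mask, cx, cy, p_level, as.integer(b))
    empty <- as.logical(r$empty)
    V <- r$V[, !empty, drop = FALSE]
  }
  list(xy = edge_pixels_base[!empty, , drop = FALSE], V = V,
       n_empty = sum(empty))
}

#' Pair dissimilarity between two adjacent quadrants
#'
#' Mean L1 dissimilarity over corresponding patch pairs, with every
#' non-corresponding edge pixel contributing the maximum dissimilarity
#' `phi`: `D = (sum_k L1(V1_k, V2_k) + m * phi) / (n + m)`.
#'
#' @param qA,qB `quadrant`s with detected edges (base resolution).
#' @param tA,tB transforms into the common frame.
#' @param cfg a `cost_config`.
#' @param factor downsample factor at which patch appearance is sampled
#'   (sets patch size, mode, and `tau`); edge geometry stays at base
#'   resolution.
#' @param imgA,imgB,maskA,maskB optional level-resolution pixel/mask
#'   matrices to sample patches from (default: the quadrants' own).
#' @return list: `d_pair`, `n`, `m`.
#' @export
pair_dissimilarity <- function(qA, qB, tA, tB, cfg = cost_config(),
                               factor = 1, imgA = NULL, imgB = NULL,
                               maskA = NULL, maskB = NULL) {
  key <- facing_edge(qA$label, qB$label)
  p_level <- patch_at_level(cfg$p, factor)
  phi <- phi_for(p_level)
  tau <- tau_for(cfg, factor)
  if (is.null(imgA)) { imgA <- qA$image$pixels; maskA <- qA$mask$bits }
  if (is.null(imgB)) { imgB <- qB$image$pixels; maskB <- qB$mask$bits }
  ea <- edge_patch_matrix(imgA, maskA, qA$edges$edges[[key]]$pixels,
                          factor, p_level, cfg$b)
  eb <- edge_patch_matrix(imgB, maskB, qB$edges$edges[[key]]$pixels,
                          factor, p_level, cfg$b)
  pa <- transform_points(tA, ea$xy); pb <- transform_points(tB, eb$xy)
  nrm <- edge_normal(qA$edges$edges[[key]], tA)
  r <- pair_dissim_core(pa, pb, ea$V, eb$V, tau, phi,
                        ea$n_empty + eb$n_empty, nrm, cfg$min_cos)
  list(d_pair = r$d_pair, n = r$n, m = r$m)
}

#' Pair misalignment between two adjacent quadrants
#'
#' Weighted sum of the Euclidean distances between the transformed inner
#' and outer best-fit-line endpoints of the facing edges:
#' `M = w3 * |C_in^1 - C_in^2| + w4 * |C_out^1 - C_out^2|`, in
#' base-resolution pixels.
#'
#' @param edgeA,edgeB `stitch_edge` objects (facing edges, base px).
#' @param tA,tB transforms into the common frame.
#' @param cfg a `cost_config`.
#' @export
pair_misalignment <- function(edgeA, edgeB, tA, tB, cfg = cost_config()) {
  if (is.null(edgeA$C_in) || is.null(edgeB$C_in))
    stop("pair_misalignment: edge endpoints missing")
  ein <- transform_points(tA, rbind(edgeA$C_in, edgeA$C_out))
  ein2 <- transform_points(tB, rbind(edgeB$C_in, edgeB$C_out))
  d_in <- sqrt(sum((ein[1, ] - ein2[1, ])^2))
  d_out <- sqrt(sum((ein[2, ] - ein2[2, ])^2))
  cfg$w3 * d_in + cfg$w4 * d_out
}

#' Total reconstruction cost
#'
#' Dissimilarity and misalignment are evaluated on the four adjacent pairs
#' (ul, ur), (ur, lr), (lr, ll), (ll, ul); `D_tot` and `M_tot` are their
#' means and the cost is `w1 * D_tot + w2 * M_tot`.
#'
#' @param qs a `quadrant_set` with detected edges (base resolution).
#' @param ts a `transform_set`.
#' @param cfg a `cost_config`.
#' @param factor downsample factor at which patch appearance is sampled.
#' @return list: `cost`, `d_tot`, `m_tot`, and per-pair values.
#' @export
total_cost <- function(qs, ts, cfg = cost_config(), factor = 1) {
  d <- m <- numeric(4)
  for (i in seq_along(ADJACENT_PAIRS)) {
    ab <- ADJACENT_PAIRS[[i]]
    qa <- qs[[ab[1]]]; qb <- qs[[ab[2]]]
    ta <- ts$transforms[[ab[1]]]; tb <- ts$transforms[[ab[2]]]
    key <- facing_edge(ab[1], ab[2])
    d[i] <- pair_dissimilarity(qa, qb, ta, tb, cfg, factor)$d_pair
    m[i] <- pair_misalignment(qa$edges$edges[[key]],
                              qb$edges$edges[[key]], ta, tb, cfg)
  }
  list(cost = cfg$w1 * mean(d) + cfg$w2 * mean(m),
       d_tot = mean(d), m_tot = mean(m), d_pair = d, m_pair = m)
}
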