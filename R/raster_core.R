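#' @useDynLib quadstitch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

QUADRANT_LABELS <- c("ul", "ur", "ll", "lr")

#' Grayscale image with physical pixel size
#'
#' Pixels are stored as a numeric `Y x X` matrix (rows = y, columns = x,
#' y increasing downward) with intensities in `[0, 1]`; pixel centers sit at
#' integer coordinates `(x, y)`, 1-based.
#'
#' @param pixels numeric matrix of intensities in `[0, 1]`.
#' @param scale_um_per_px physical size of one pixel in micrometres.
#' @return An object of class `gray_image` with fields `pixels` and
#'   `scale_um_per_px`.
#' @export
gray_image <- function(pixels, scale_um_per_px = 1) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (nrow(pixels) < 1 || ncol(pixels) < 1)
    stop("gray_image: dimensions must be at least 1 x 1")
  if (!is.numeric(scale_um_per_px) || scale_um_per_px <= 0)
    stop("gray_image: scale_um_per_px must be > 0")
  rng <- range(pixels)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("gray_image: intensities must lie in [0, 1]")
  structure(list(pixels = pmin(pmax(pixels, 0), 1),
                 scale_um_per_px = scale_um_per_px),
            class = "gray_image")
}

#' Binary tissue mask
#'
#' @param bits matrix of 0/1 (or logical); foreground = tissue.
#' @return An object of class `tissue_mask` with field `bits`
#'   (integer matrix).
#' @export
tissue_mask <- function(bits) {
  stopifnot(is.matrix(bits))
  bits <- matrix(as.integer(bits != 0), nrow(bits), ncol(bits))
  structure(list(bits = bits), class = "tissue_mask")
}

#' Rigid-body transform (3 DOF)
#'
#' Maps a point `p = (x, y)` to `R(theta) (p - center) + center + (tx, ty)`
#' where `R` is the rotation matrix `[[cos, -sin], [sin, cos]]` (degrees,
#' counter-clockwise on screen with y pointing down).  `flip_h` records a
#' pre-applied mirror and takes no part in the mapping.
#'
#' @param tx,ty translation in base-resolution pixels.
#' @param theta rotation in degrees about `center`.
#' @param center rotation center `(x, y)`; by convention the quadrant's
#'   tissue centroid.
#' @param flip_h logical bookkeeping flag.
#' @export
rigid_transform <- function(tx = 0, ty = 0, theta = 0, center = c(0, 0),
                            flip_h = FALSE) {
  stopifnot(length(center) == 2, is.finite(tx), is.finite(ty),
            is.finite(theta))
  structure(list(tx = tx, ty = ty, theta = theta,
                 center = as.numeric(center), flip_h = isTRUE(flip_h)),
            class = "rigid_transform")
}

rotation_matrix <- function(theta_deg) {
  a <- theta_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Apply a rigid transform to points
#'
#' @param t a `rigid_transform`.
#' @param pts `n x 2` matrix of `(x, y)` coordinates.
#' @return Transformed `n x 2` matrix.
#' @export
transform_points <- function(t, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  R <- rotation_matrix(t$theta)
  ctr <- t$center
  out <- sweep(pts, 2, ctr) %*% t(R)
  sweep(out, 2, ctr + c(t$tx, t$ty), "+")
}

## 2x3 affine [R | v] with p' = R p + v
transform_affine <- function(t) {
  R <- rotation_matrix(t$theta)
  v <- t$center + c(t$tx, t$ty) - R %*% t$center
  list(R = R, v = as.numeric(v))
}

## Express an affine rigid map as a rigid_transform about `center`
affine_to_rigid <- function(R, v, center, flip_h = FALSE) {
  theta <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  tr <- as.numeric(v) - center + as.numeric(R %*% center)
  rigid_transform(tr[1], tr[2], theta, center = center, flip_h = flip_h)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return The inverse transform, expressed about the same center.
#' @export
invert_transform <- function(t) {
  a <- transform_affine(t)
  Ri <- t(a$R)
  vi <- -Ri %*% a$v
  affine_to_rigid(Ri, vi, t$center, flip_h = t$flip_h)
}

#' Compose two rigid transforms
#'
#' Returns the transform applying `t1` first, then `t2`.
#'
#' @param t2,t1 `rigid_transform` objects.
#' @param center rotation center of the result (default `t1$center`).
#' @export
compose_transforms <- function(t2, t1, center = t1$center) {
  a1 <- transform_affine(t1); a2 <- transform_affine(t2)
  R <- a2$R %*% a1$R
  v <- a2$R %*% a1$v + a2$v
  affine_to_rigid(R, v, center, flip_h = xor(t1$flip_h, t2$flip_h))
}

#' Rescale a rigid transform between resolutions
#'
#' If `t` acts on coordinates at one resolution, `scale_transform(t, s)`
#' acts identically on coordinates multiplied by `s` (rotation unchanged,
#' translation and center scaled).
#'
#' @param t a `rigid_transform`.
#' @param s scale factor.
#' @export
scale_transform <- function(t, s) {
  rigid_transform(t$tx * s, t$ty * s, t$theta, center = t$center * s,
                  flip_h = t$flip_h)
}

#' Tissue quadrant
#'
#' @param label one of `"ul"`, `"ur"`, `"ll"`, `"lr"`.
#' @param image a `gray_image`.
#' @param mask a `tissue_mask` congruent with `image`.
#' @param edges optional `edge_geometry` (see [detect_corners_and_edges()]).
#' @export
quadrant <- function(label, image, mask, edges = NULL) {
  label <- match.arg(label, QUADRANT_LABELS)
  stopifnot(inherits(image, "gray_image"), inherits(mask, "tissue_mask"))
  if (!identical(dim(image$pixels), dim(mask$bits)))
    stop("quadrant: image and mask dimensions differ")
  structure(list(label = label, image = image, mask = mask, edges = edges),
            class = "quadrant")
}

#' Set of four quadrants (one per anatomic label)
#' @param ul,ur,ll,lr `quadrant` objects carrying the matching labels.
#' @export
quadrant_set <- function(ul, ur, ll, lr) {
  qs <- list(ul = ul, ur = ur, ll = ll, lr = lr)
  for (lb in QUADRANT_LABELS) {
    if (!inherits(qs[[lb]], "quadrant") || qs[[lb]]$label != lb)
      stop("quadrant_set: argument '", lb, "' must be a quadrant labeled '",
           lb, "'")
  }
  structure(qs, class = "quadrant_set")
}

#' Set of per-quadrant transforms with one fixed reference quadrant
#'
#' @param transforms named list of `rigid_transform`s, one per label.
#' @param fixed label of the reference quadrant; its transform must be the
#'   identity.
#' @export
transform_set <- function(transforms, fixed = "ul") {
  fixed <- match.arg(fixed, QUADRANT_LABELS)
  if (!setequal(names(transforms), QUADRANT_LABELS))
    stop("transform_set: need exactly the labels ul, ur, ll, lr")
  tf <- transforms[[fixed]]
  if (abs(tf$tx) > 1e-9 || abs(tf$ty) > 1e-9 || abs(tf$theta) > 1e-9)
    stop("transform_set: transform of fixed quadrant '", fixed,
         "' must be the identity")
  structure(list(fixed = fixed, transforms = transforms[QUADRANT_LABELS]),
            class = "transform_set")
}

#' Resample a quadrant onto a canvas under a rigid transform
#'
#' Intensities are sampled with bilinear interpolation, the mask with
#' nearest-neighbour; pixels mapping outside the source get `background`
#' intensity and mask 0.  Canvas pixel `(x, y)` represents common-frame
#' coordinate `(x + origin[1] - 1, y + origin[2] - 1)`.
#'
#' @param q a `quadrant`.
#' @param t a `rigid_transform` (source-to-common frame).
#' @param canvas integer `c(Y, X)` canvas dimensions.
#' @param origin common-frame coordinate of canvas pixel (1, 1).
#' @param background intensity for unpainted pixels.
#' @return list with `image` (`gray_image`), `mask` (`tissue_mask`), and
#'   `origin`.
#' @export
apply_transform <- function(q, t, canvas, origin = c(1, 1), background = 0) {
  stopifnot(inherits(q, "quadrant"), length(canvas) == 2)
  Yc <- as.integer(canvas[1]); Xc <- as.integer(canvas[2])
  src <- q$image$pixels; msk <- q$mask$bits
  Y <- nrow(src); X <- ncol(src)

  idx <- which(msk != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("apply_transform: empty mask")
  pts <- cbind(idx[, 2], idx[, 1])
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  tc <- transform_points(t, hull)
  lim_x <- origin[1] + c(0, Xc - 1); lim_y <- origin[2] + c(0, Yc - 1)
  over <- c(lim_x[1] - min(tc[, 1]), max(tc[, 1]) - lim_x[2],
            lim_y[1] - min(tc[, 2]), max(tc[, 2]) - lim_y[2])
  if (any(over > 0.5)) {
    side <- c("left", "right", "top", "bottom")[which.max(over)]
    stop(sprintf(
      "apply_transform: canvas too small; mask overflows %s edge by %.1f px",
      side, max(over)))
  }

  ti <- invert_transform(t)
  gx <- origin[1] + seq_len(Xc) - 1
  gy <- origin[2] + seq_len(Yc) - 1
  pts <- cbind(rep(gx, each = Yc), rep(gy, times = Xc))
  sp <- transform_points(ti, pts)
  sx <- sp[, 1]; sy <- sp[, 2]

  # nearest-neighbour mask lookup
  ix <- round(sx); iy <- round(sy)
  ok <- ix >= 1 & ix <= X & iy >= 1 & iy <= Y
  mv <- integer(length(sx))
  mv[ok] <- msk[cbind(iy[ok], ix[ok])]

  # bilinear intensity lookup
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  iv <- rep(background, length(sx))
  okb <- x0 >= 1 & x0 + 1 <= X & y0 >= 1 & y0 + 1 <= Y
  if (any(okb)) {
    xo <- x0[okb]; yo <- y0[okb]; fxo <- fx[okb]; fyo <- fy[okb]
    v00 <- src[cbind(yo, xo)];     v10 <- src[cbind(yo, xo + 1)]
    v01 <- src[cbind(yo + 1, xo)]; v11 <- src[cbind(yo + 1, xo + 1)]
    iv[okb] <- v00 * (1 - fxo) * (1 - fyo) + v10 * fxo * (1 - fyo) +
      v01 * (1 - fxo) * fyo + v11 * fxo * fyo
  }
  # border pixels (within half a pixel of the frame): nearest sample
  okn <- !okb & ok
  if (any(okn)) iv[okn] <- src[cbind(iy[okn], ix[okn])]

  list(image = gray_image(matrix(iv, Yc, Xc),
                          scale_um_per_px = q$image$scale_um_per_px),
       mask = tissue_mask(matrix(mv, Yc, Xc)),
       origin = as.numeric(origin))
}

mask_bbox <- function(bits) {
  idx <- which(bits != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask_bbox: empty mask")
  list(x0 = min(idx[, 2]), x1 = max(idx[, 2]),
       y0 = min(idx[, 1]), y1 = max(idx[, 1]))
}

#' Composite four transformed quadrants into one section image
#'
#' The canvas is auto-sized to the union of the transformed mask bounding
#' boxes plus `margin`.  Where tissue masks overlap, the later-drawn
#' quadrant wins under the fixed order ul, ur, ll, lr.
#'
#' @param qs a `quadrant_set`.
#' @param ts a `transform_set`.
#' @param margin canvas margin in pixels.
#' @param background intensity of unpainted canvas.
#' @return list of class `pwmhs`: `image`, `mask`, `origin`.
#' @export
composite_section <- function(qs, ts, margin = 8, background = 1) {
  stopifnot(inherits(qs, "quadrant_set"), inherits(ts, "transform_set"))
  lo <- c(Inf, Inf); hi <- c(-Inf, -Inf)
  for (lb in QUADRANT_LABELS) {
    bb <- mask_bbox(qs[[lb]]$mask$bits)
    corners <- cbind(c(bb$x0, bb$x1, bb$x1, bb$x0),
                     c(bb$y0, bb$y0, bb$y1, bb$y1))
    tc <- transform_points(ts$transforms[[lb]], corners)
    lo <- pmin(lo, apply(tc, 2, min)); hi <- pmax(hi, apply(tc, 2, max))
  }
  origin <- floor(lo) - margin
  canvas <- c(ceiling(hi[2]) + margin - origin[2] + 1,
              ceiling(hi[1]) + margin - origin[1] + 1)
  img <- matrix(background, canvas[1], canvas[2])
  msk <- matrix(0L, canvas[1], canvas[2])
  scale <- qs$ul$image$scale_um_per_px
  for (lb in QUADRANT_LABELS) {
    r <- apply_transform(qs[[lb]], ts$transforms[[lb]], canvas,
                         origin = origin, background = background)
    on <- r$mask$bits == 1L
    img[on] <- r$image$pixels[on]
    msk[on] <- 1L
  }
  structure(list(image = gray_image(img, scale_um_per_px = scale),
                 mask = tissue_mask(msk), origin = as.numeric(origin)),
            class = "pwmhs")
}

## exact block mean by aggregation matrix; edge blocks average what exists
aggregation_matrix <- function(n, f) {
  n2 <- ceiling(n / f)
  A <- matrix(0, n2, n)
  for (i in seq_len(n2)) {
    j <- ((i - 1) * f + 1):min(i * f, n)
    A[i, j] <- 1 / length(j)
  }
  A
}

downsample_matrix <- function(m, f) {
  if (f == 1) return(m)
  Ay <- aggregation_matrix(nrow(m), f)
  Ax <- aggregation_matrix(ncol(m), f)
  Ay %*% m %*% t(Ax)
}

#' Multi-resolution pyramid of a quadrant
#'
#' Intensities are reduced by exact block averaging (anti-aliased for
#' integer factors); the mask by block majority vote.
#'
#' @param q a `quadrant`.
#' @param factors strictly decreasing integer downsample factors, last = 1
#'   (coarsest first).
#' @return list of class `pyramid`; each level has `image`, `mask`,
#'   `factor`.
#' @export
build_pyramid <- function(q, factors = c(8, 2, 1)) {
  stopifnot(inherits(q, "quadrant"))
  factors <- as.integer(factors)
  if (any(diff(factors) >= 0) || factors[length(factors)] != 1L)
    stop("build_pyramid: factors must be strictly decreasing and end at 1")
  levels <- lapply(factors, function(f) {
    img <- downsample_matrix(q$image$pixels, f)
    mk <- (downsample_matrix(q$mask$bits + 0, f) >= 0.5) + 0L
    list(image = gray_image(img, q$image$scale_um_per_px * f),
         mask = tissue_mask(matrix(mk, nrow(img), ncol(img))),
         factor = f)
  })
  structure(levels, class = "pyramid")
}

#' Read a raster file as a grayscale image
#'
#' PNG and TIFF, 8- or 16-bit, RGB or gray.  RGB is converted with the
#' Rec. 601 luminance weights (0.299, 0.587, 0.114).
#'
#' @param path file path.
#' @param scale_um_per_px physical pixel size to record.
#' @return a `gray_image`.
#' @export
read_gray_image <- function(path, scale_um_per_px = 1) {
  if (!file.exists(path)) stop("read_gray_image: no such file: ", path)
  img <- try(EBImage::readImage(path), silent = TRUE)
  if (inherits(img, "try-error"))
    stop("read_gray_image: cannot read raster file: ", path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3) {
    nch <- dim(a)[3]
    a <- if (nch >= 3) {
      0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else a[, , 1]
  }
  a <- pmin(pmax(a, 0), 1)
  gray_image(t(a), scale_um_per_px = scale_um_per_px)  # EBImage is [x, y]
}

#' Write a grayscale image to PNG or TIFF
#' @param img a `gray_image` (or plain matrix in `[0, 1]`).
#' @param path output path; format chosen by extension.
#' @export
write_gray_image <- function(img, path) {
  px <- if (inherits(img, "gray_image")) img$pixels else img
  EBImage::writeImage(EBImage::Image(t(px)), path)
  invisible(path)
}

#' Serialize a transform set to JSON
#'
#' Schema: `{"fixed": "ul", "transforms": {"ul": {"tx", "ty", "theta",
#' "center", "flip_h"}, ...}, "units": {"translation": "px_base",
#' "rotation": "deg"}}`.
#'
#' @param ts a `transform_set`.
#' @param path output path.
#' @export
write_transform_set <- function(ts, path) {
  obj <- list(
    fixed = ts$fixed,
    transforms = lapply(ts$transforms, function(t)
      list(tx = t$tx, ty = t$ty, theta = t$theta, center = t$center,
           flip_h = t$flip_h)),
    units = list(translation = "px_base", rotation = "deg"))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a transform set from JSON written by [write_transform_set()]
#' @param path input path.
#' @return a `transform_set`.
#' @export
read_transform_set <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  tr <- lapply(obj$transforms, function(t)
    rigid_transform(t$tx, t$ty, t$theta,
                    center = if (!is.null(t$center)) t$center else c(0, 0),
                    flip_h = isTRUE(t$flip_h)))
  transform_set(tr, fixed = obj$fixed)
}

#' Intersection-over-union of two binary masks
#' @param a,b `tissue_mask` objects or 0/1 matrices of equal size.
#' @export
mask_iou <- function(a, b) {
  a <- if (inherits(a, "tissue_mask")) a$bits else a
  b <- if (inherits(b, "tissue_mask")) b$bits else b
  stopifnot(identical(dim(a), dim(b)))
  inter <- sum(a == 1L & b == 1L)
  uni <- sum(a == 1L | b == 1L)
  if (uni == 0) return(1)
  inter / uni
}

#' @export
print.quadrant <- function(x, ...) {
  d <- dim(x$image$pixels)
  cat(sprintf("<quadrant %s> %d x %d px, %.3g um/px, tissue %d px%s\n",
              x$label, d[2], d[1], x$image$scale_um_per_px,
              sum(x$mask$bits), if (is.null(x$edges)) "" else ", edges set"))
  invisible(x)
}

#' @export
print.transform_set <- function(x, ...) {
  cat("<transform_set> fixed =", x$fixed, "\n")
  for (lb in QUADRANT_LABELS) {
    t <- x$transforms[[lb]]
    cat(sprintf("  %s: tx %8.2f  ty %8.2f  theta %7.2f deg\n",
                lb, t$tx, t$ty, t$theta))
  }
  invisible(x)
}
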