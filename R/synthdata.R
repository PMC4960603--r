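#' Specification of a pseudo-histology phantom
#'
#' The phantom emulates the intensity statistics the dissimilarity term
#' exploits: a dark textured tissue ellipse carrying bright elliptical
#' blobs (gland lumina, spatially clustered so local intensity histograms
#' vary across the section) on a near-white background.
#'
#' @param seed RNG seed.
#' @param canvas `(X, Y)` canvas size in px.
#' @param axes `(a, b)` tissue ellipse semi-axes in px.
#' @param axis_jitter relative jitter applied to each semi-axis.
#' @param gland_density gland blobs per 10^4 px^2 of tissue.
#' @param gland_radius `(min, max)` blob radius in px.
#' @param background background intensity.
#' @param tissue_intensity tissue base intensity.
#' @param noise_sd Gaussian texture noise s.d.
#' @param scale_um_per_px physical pixel size.
#' @export
phantom_spec <- function(seed = 1, canvas = c(512, 448),
                         axes = c(215, 180), axis_jitter = 0.04,
                         gland_density = 6, gland_radius = c(2, 11),
                         background = 0.95, tissue_intensity = 0.45,
                         noise_sd = 0.05, scale_um_per_px = 80) {
  stopifnot(all(canvas > 0), all(axes > 0), gland_density >= 0)
  structure(list(seed = as.integer(seed), canvas = as.integer(canvas),
                 axes = axes, axis_jitter = axis_jitter,
                 gland_density = gland_density,
                 gland_radius = gland_radius, background = background,
                 tissue_intensity = tissue_intensity, noise_sd = noise_sd,
                 scale_um_per_px = scale_um_per_px),
            class = "phantom_spec")
}

#' Specification of phantom fragmentation
#'
#' Two wavy cuts through the tissue centroid quarter the phantom; a
#' kerf-wide band of tissue is destroyed along each cut; each quadrant is
#' independently perturbed by a random rigid transform (and optionally
#' mirrored or bitten), with the inverse recorded as ground truth.
#'
#' @param seed RNG seed.
#' @param waviness_amp,waviness_freq amplitude (px) and frequency (cycles
#'   per section) of the cut waviness.
#' @param kerf width of destroyed tissue along each cut (px).
#' @param trans_range,rot_range perturbation half-ranges (px, deg).
#' @param flip_prob probability of a horizontal mirror per quadrant.
#' @param bite_n,bite_radius extra tissue-loss bites along the cuts.
#' @export
fragment_spec <- function(seed = 1, waviness_amp = 6, waviness_freq = 2,
                          kerf = 0, trans_range = 5, rot_range = 3,
                          flip_prob = 0, bite_n = 0, bite_radius = 15) {
  stopifnot(kerf >= 0, trans_range >= 0, rot_range >= 0)
  structure(list(seed = as.integer(seed), waviness_amp = waviness_amp,
                 waviness_freq = waviness_freq, kerf = kerf,
                 trans_range = trans_range, rot_range = rot_range,
                 flip_prob = flip_prob, bite_n = as.integer(bite_n),
                 bite_radius = bite_radius),
            class = "fragment_spec")
}

#' Difficulty presets for synthetic fixtures
#'
#' `easy`: lossless cuts (kerf 0), perturbations within 5 px / 3 deg.
#' `medium`: kerf 5 px, within 10 px / 8 deg.
#' `hard`: kerf 12 px plus bites, within 20 px / 15 deg.
#'
#' @param preset one of `"easy"`, `"medium"`, `"hard"`.
#' @param seed RNG seed for the fragment stage.
#' @return a `fragment_spec`.
#' @export
preset_fragment_spec <- function(preset = c("easy", "medium", "hard"),
                                 seed = 1) {
  preset <- match.arg(preset)
  switch(preset,
         easy = fragment_spec(seed, kerf = 0, trans_range = 5,
                              rot_range = 3),
         medium = fragment_spec(seed, kerf = 5, trans_range = 10,
                                rot_range = 8),
         hard = fragment_spec(seed, kerf = 12, trans_range = 20,
                              rot_range = 15, bite_n = 3,
                              bite_radius = 18))
}

quantize8 <- function(px) round(pmin(pmax(px, 0), 1) * 255) / 255

#' Generate a pseudo-tissue phantom
#'
#' @param spec a `phantom_spec`.
#' @return list: `image` (`gray_image`), `mask` (`tissue_mask`).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  X <- spec$canvas[1]; Y <- spec$canvas[2]
  set.seed(spec$seed)
  a <- spec$axes[1] * (1 + stats::runif(1, -spec$axis_jitter,
                                        spec$axis_jitter))
  b <- spec$axes[2] * (1 + stats::runif(1, -spec$axis_jitter,
                                        spec$axis_jitter))
  if (2 * a >= X - 4 || 2 * b >= Y - 4)
    stop("generate_phantom: tissue ellipse larger than canvas")
  cx <- (X + 1) / 2; cy <- (Y + 1) / 2
  xg <- matrix(rep(seq_len(X), each = Y), Y, X)
  yg <- matrix(rep(seq_len(Y), times = X), Y, X)
  tissue <- ((xg - cx) / a)^2 + ((yg - cy) / b)^2 <= 1

  img <- matrix(spec$background, Y, X) +
    matrix(stats::rnorm(Y * X, 0, 0.01), Y, X)
  # very slow regional intensity drift: wavelengths exceed the section so
  # patches straddling a cut keep near-identical intensity distributions
  drift <- 0
  for (k in 1:3) {
    fx <- stats::runif(1, 0.3, 0.8) * 2 * pi / X
    fy <- stats::runif(1, 0.3, 0.8) * 2 * pi / Y
    ph <- stats::runif(2, 0, 2 * pi)
    drift <- drift + 0.012 * cos(fx * xg + ph[1]) * cos(fy * yg + ph[2])
  }
  # concentric zonal banding (elliptical rings around the section
  # center, as in prostate zonal anatomy): intensity varies with radius
  # at a few tens of px but is constant tangentially.  The quartering
  # cuts run radially, so patches facing each other across a cut sample
  # the same bands (low dissimilarity at the true pose) while patches
  # displaced along a cut sample different bands -- the structure the
  # histogram dissimilarity needs in order to localize tangentially.
  rho <- sqrt(((xg - cx) / a)^2 + ((yg - cy) / b)^2) * (a + b) / 2
  rings <- 0
  for (k in 1:4) {
    lam <- stats::runif(1, 20, 45)
    phk <- stats::runif(1, 0, 2 * pi)
    rings <- rings + 0.06 * cos(2 * pi * rho / lam + phk)
  }
  base <- spec$tissue_intensity + drift + rings +
    matrix(stats::rnorm(Y * X, 0, spec$noise_sd), Y, X)
  img[tissue] <- base[tissue]

  n_gland <- round(spec$gland_density * sum(tissue) / 1e4)
  if (n_gland > 0) {
    n_parent <- max(3L, ceiling(n_gland / 12))
    repeat {
      px_ <- stats::runif(n_parent, cx - a, cx + a)
      py_ <- stats::runif(n_parent, cy - b, cy + b)
      ok <- ((px_ - cx) / (0.85 * a))^2 + ((py_ - cy) / (0.85 * b))^2 <= 1
      if (sum(ok) >= 3) { px_ <- px_[ok]; py_ <- py_[ok]; break }
    }
    for (i in seq_len(n_gland)) {
      j <- sample.int(length(px_), 1)
      gx <- px_[j] + stats::rnorm(1, 0, 25)
      gy <- py_[j] + stats::rnorm(1, 0, 25)
      r <- stats::runif(1, spec$gland_radius[1], spec$gland_radius[2])
      rx <- r * stats::runif(1, 0.7, 1.3)
      inside <- ((xg - gx) / rx)^2 + ((yg - gy) / r)^2 <= 1
      img[inside & tissue] <- stats::runif(1, 0.82, 0.93)
    }
  }
  img <- quantize8(img)
  list(image = gray_image(img, scale_um_per_px = spec$scale_um_per_px),
       mask = tissue_mask(tissue))
}

## affine composition helpers on (R, v) pairs
aff_compose <- function(a2, a1)
  list(R = a2$R %*% a1$R, v = as.numeric(a2$R %*% a1$v + a2$v))
aff_invert <- function(a)
  list(R = t(a$R), v = as.numeric(-t(a$R) %*% a$v))
aff_apply <- function(a, pts)
  sweep(matrix(pts, ncol = 2) %*% t(a$R), 2, a$v, "+")
aff_translate <- function(d) list(R = diag(2), v = as.numeric(d))

#' Fragment a phantom into four quadrants with known ground truth
#'
#' @param img phantom `gray_image`.
#' @param mask phantom `tissue_mask`.
#' @param spec a `fragment_spec`.
#' @return list: `quadrants` (a `quadrant_set` of perturbed local
#'   fragments) and `ground_truth` (class `ground_truth`: true
#'   `transforms` relative to ul, cut polylines, landmark pairs, the
#'   pre-cut phantom, per-quadrant local-to-phantom affines, flips).
#' @export
fragment_phantom <- function(img, mask, spec = fragment_spec()) {
  stopifnot(inherits(img, "gray_image"), inherits(mask, "tissue_mask"))
  X <- ncol(img$pixels); Y <- nrow(img$pixels)
  set.seed(spec$seed + 1L)
  ctr <- mask_centroid(mask$bits)
  ph <- stats::runif(2, 0, 2 * pi)
  hcut <- function(x) ctr[2] + spec$waviness_amp *
    sin(2 * pi * spec$waviness_freq * x / X + ph[1])
  vcut <- function(y) ctr[1] + spec$waviness_amp *
    sin(2 * pi * spec$waviness_freq * y / Y + ph[2])

  xg <- matrix(rep(seq_len(X), each = Y), Y, X)
  yg <- matrix(rep(seq_len(Y), times = X), Y, X)
  HC <- matrix(hcut(seq_len(X)), Y, X, byrow = TRUE)
  VC <- matrix(vcut(seq_len(Y)), Y, X)
  top <- yg < HC; left <- xg < VC
  keep <- mask$bits == 1L
  if (spec$kerf > 0)
    keep <- keep & abs(yg - HC) >= spec$kerf / 2 &
      abs(xg - VC) >= spec$kerf / 2
  if (spec$bite_n > 0) {
    for (i in seq_len(spec$bite_n)) {
      if (stats::runif(1) < 0.5) {
        bx <- stats::runif(1, ctr[1] - X / 4, ctr[1] + X / 4)
        bp <- c(bx, hcut(bx))
      } else {
        by <- stats::runif(1, ctr[2] - Y / 4, ctr[2] + Y / 4)
        bp <- c(vcut(by), by)
      }
      r <- spec$bite_radius * stats::runif(1, 0.6, 1)
      keep <- keep & ((xg - bp[1])^2 + (yg - bp[2])^2 > r^2)
    }
  }
  sides <- list(ul = top & left, ur = top & !left,
                ll = !top & left, lr = !top & !left)

  bgv <- quantize8(0.95)
  quads <- list(); affines <- list(); flips <- list()
  for (lb in QUADRANT_LABELS) {
    qm <- keep & sides[[lb]]
    if (sum(qm) < 500)
      stop("fragment_phantom: quadrant ", lb,
           " vanished (kerf/bites too large)")
    idx <- which(qm, arr.ind = TRUE)
    m <- 6L
    y0 <- max(1L, min(idx[, 1]) - m); y1 <- min(Y, max(idx[, 1]) + m)
    x0 <- max(1L, min(idx[, 2]) - m); x1 <- min(X, max(idx[, 2]) + m)
    crop_img <- img$pixels[y0:y1, x0:x1]
    crop_msk <- qm[y0:y1, x0:x1]
    crop_img[!crop_msk] <- bgv
    q0 <- quadrant(lb, gray_image(crop_img, img$scale_um_per_px),
                   tissue_mask(crop_msk))

    dth <- stats::runif(1, -spec$rot_range, spec$rot_range)
    dtr <- stats::runif(2, -spec$trans_range, spec$trans_range)
    tp <- rigid_transform(dtr[1], dtr[2], dth,
                          center = mask_centroid(q0$mask$bits))
    bb <- mask_bbox(q0$mask$bits)
    corners <- cbind(c(bb$x0, bb$x1, bb$x1, bb$x0),
                     c(bb$y0, bb$y0, bb$y1, bb$y1))
    tc <- transform_points(tp, corners)
    org <- floor(apply(tc, 2, min)) - m
    cv <- c(ceiling(max(tc[, 2])) + m - org[2] + 1,
            ceiling(max(tc[, 1])) + m - org[1] + 1)
    rnd <- apply_transform(q0, tp, cv, origin = org, background = bgv)
    loc_img <- quantize8(rnd$image$pixels)
    loc_msk <- rnd$mask$bits

    # local -> phantom affine: undo render origin, undo perturbation,
    # undo crop
    a_loc <- aff_compose(aff_translate(c(x0 - 1, y0 - 1)),
                         aff_compose(transform_affine(invert_transform(tp)),
                                     aff_translate(org - 1)))
    flip_h <- stats::runif(1) < spec$flip_prob
    if (flip_h)
      loc_img <- loc_img[, rev(seq_len(ncol(loc_img))), drop = FALSE]
    if (flip_h)
      loc_msk <- loc_msk[, rev(seq_len(ncol(loc_msk))), drop = FALSE]
    quads[[lb]] <- quadrant(lb, gray_image(loc_img, img$scale_um_per_px),
                            tissue_mask(loc_msk))
    affines[[lb]] <- a_loc
    flips[[lb]] <- flip_h
  }

  # ground-truth transforms relative to the fixed ul quadrant (on the
  # unflipped local frames)
  a_ul_inv <- aff_invert(affines$ul)
  tr <- list()
  for (lb in QUADRANT_LABELS) {
    B <- aff_compose(a_ul_inv, affines[[lb]])
    ctr_l <- mask_centroid(if (flips[[lb]]) {
      quads[[lb]]$mask$bits[, rev(seq_len(ncol(quads[[lb]]$mask$bits))),
                            drop = FALSE]
    } else quads[[lb]]$mask$bits)
    tr[[lb]] <- affine_to_rigid(B$R, B$v, ctr_l)
  }
  tr$ul <- rigid_transform(0, 0, 0, center = tr$ul$center)

  landmarks <- sample_landmarks(keep, sides, hcut, vcut, spec, affines,
                                X, Y)
  cut_h <- data.frame(x = seq_len(X), y = hcut(seq_len(X)))
  cut_v <- data.frame(x = vcut(seq_len(Y)), y = seq_len(Y))

  list(quadrants = quadrant_set(quads$ul, quads$ur, quads$ll, quads$lr),
       ground_truth = structure(
         list(transforms = transform_set(tr, fixed = "ul"),
              cut_h = cut_h, cut_v = cut_v, landmarks = landmarks,
              phantom_image = img, phantom_mask = mask,
              affines = affines, flips = flips,
              fragment_mask = tissue_mask(matrix((keep) + 0L, Y, X))),
         class = "ground_truth"))
}

## >= 9 corresponding point pairs straddling each cut, in phantom and in
## local coordinates of the owning quadrants
sample_landmarks <- function(keep, sides, hcut, vcut, spec, affines, X, Y) {
  off <- spec$kerf / 2 + 2
  rows <- list()
  try_pair <- function(pa, pb, la, lb_, cut) {
    ia <- round(pa); ib <- round(pb)
    if (any(ia < 1) || any(ib < 1) || ia[1] > X || ib[1] > X ||
        ia[2] > Y || ib[2] > Y) return(NULL)
    oka <- keep[ia[2], ia[1]] && sides[[la]][ia[2], ia[1]]
    okb <- keep[ib[2], ib[1]] && sides[[lb_]][ib[2], ib[1]]
    if (!oka || !okb) return(NULL)
    qa <- aff_apply(aff_invert(affines[[la]]), pa)
    qb <- aff_apply(aff_invert(affines[[lb_]]), pb)
    data.frame(cut = cut, label_a = la, label_b = lb_,
               phantom_xa = pa[1], phantom_ya = pa[2],
               phantom_xb = pb[1], phantom_yb = pb[2],
               local_xa = qa[1], local_ya = qa[2],
               local_xb = qb[1], local_yb = qb[2])
  }
  for (x in seq(0.1 * X, 0.9 * X, length.out = 40)) {
    y <- hcut(x)
    la <- if (x < vcut(y - off)) "ul" else "ur"
    lb_ <- if (x < vcut(y + off)) "ll" else "lr"
    rows[[length(rows) + 1]] <-
      try_pair(c(x, y - off), c(x, y + off), la, lb_, "h")
  }
  for (y in seq(0.1 * Y, 0.9 * Y, length.out = 40)) {
    x <- vcut(y)
    la <- if (y < hcut(x - off)) "ul" else "ll"
    lb_ <- if (y < hcut(x + off)) "ur" else "lr"
    rows[[length(rows) + 1]] <-
      try_pair(c(x - off, y), c(x + off, y), la, lb_, "v")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || sum(out$cut == "h") < 9 || sum(out$cut == "v") < 9)
    stop("sample_landmarks: could not place 9 landmark pairs per cut")
  out
}

#' Generate a complete synthetic fixture
#'
#' @param preset difficulty preset (see [preset_fragment_spec()]).
#' @param seed seed controlling both phantom and fragmentation.
#' @param out optional directory; when given the fixture is written via
#'   [write_fixture()].
#' @param pspec,fspec optional explicit specs overriding the preset.
#' @return list: `quadrants`, `ground_truth`, `preset`, `seed`.
#' @export
simulate_fixture <- function(preset = "easy", seed = 1, out = NULL,
                             pspec = NULL, fspec = NULL) {
  if (is.null(pspec)) pspec <- phantom_spec(seed = seed)
  if (is.null(fspec)) fspec <- preset_fragment_spec(preset, seed = seed)
  ph <- generate_phantom(pspec)
  fr <- fragment_phantom(ph$image, ph$mask, fspec)
  fx <- list(quadrants = fr$quadrants, ground_truth = fr$ground_truth,
             preset = preset, seed = seed,
             scale_um_per_px = pspec$scale_um_per_px)
  if (!is.null(out)) write_fixture(out, fx)
  fx
}

#' Write a synthetic fixture to disk
#'
#' Writes the four quadrant PNGs (plus their true masks), the ground-truth
#' transforms JSON, the landmark CSV, the phantom PNG/mask, and a metadata
#' JSON.  Images are 8-bit; pixel arrays round-trip exactly.
#'
#' @param dir output directory (created if missing).
#' @param fx a fixture from [simulate_fixture()].
#' @export
write_fixture <- function(dir, fx) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  qs <- fx$quadrants; gt <- fx$ground_truth
  for (lb in QUADRANT_LABELS) {
    write_gray_image(qs[[lb]]$image, file.path(dir, paste0(lb, ".png")))
    write_gray_image(qs[[lb]]$mask$bits + 0,
                     file.path(dir, paste0(lb, "_mask.png")))
  }
  write_transform_set(gt$transforms, file.path(dir, "truth_transforms.json"))
  utils::write.csv(gt$landmarks, file.path(dir, "landmarks.csv"),
                   row.names = FALSE)
  write_gray_image(gt$phantom_image, file.path(dir, "phantom.png"))
  write_gray_image(gt$phantom_mask$bits + 0,
                   file.path(dir, "phantom_mask.png"))
  meta <- list(preset = fx$preset, seed = fx$seed,
               scale_um_per_px = fx$scale_um_per_px,
               flips = lapply(gt$flips, isTRUE))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "metadata.json"))
  invisible(dir)
}

#' Read a fixture written by [write_fixture()]
#' @param dir fixture directory.
#' @return list with `quadrants`, `truth_transforms`, `landmarks`,
#'   `phantom_image`, `phantom_mask`, `metadata`.
#' @export
read_fixture <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"))
  s <- meta$scale_um_per_px
  quads <- lapply(QUADRANT_LABELS, function(lb) {
    im <- read_gray_image(file.path(dir, paste0(lb, ".png")), s)
    mk <- read_gray_image(file.path(dir, paste0(lb, "_mask.png")), s)
    quadrant(lb, im, tissue_mask(mk$pixels > 0.5))
  })
  names(quads) <- QUADRANT_LABELS
  list(quadrants = quadrant_set(quads$ul, quads$ur, quads$ll, quads$lr),
       truth_transforms =
         read_transform_set(file.path(dir, "truth_transforms.json")),
       landmarks = utils::read.csv(file.path(dir, "landmarks.csv")),
       phantom_image = read_gray_image(file.path(dir, "phantom.png"), s),
       phantom_mask = tissue_mask(
         read_gray_image(file.path(dir, "phantom_mask.png"), s)$pixels > 0.5),
       metadata = meta)
}

#' Pose discrepancy between two transform sets
#'
#' For each moving quadrant, the rotation difference (degrees) and the
#' displacement of the tissue centroid between the two maps.
#'
#' @param ts_a,ts_b `transform_set`s sharing the fixed quadrant.
#' @param qs the `quadrant_set` the transforms act on.
#' @return data.frame: `label`, `rot_deg`, `trans_px`.
#' @export
compare_transform_sets <- function(ts_a, ts_b, qs) {
  out <- lapply(MOVING_LABELS, function(lb) {
    ta <- ts_a$transforms[[lb]]; tb <- ts_b$transforms[[lb]]
    dth <- (ta$theta - tb$theta + 180) %% 360 - 180
    ctr <- mask_centroid(qs[[lb]]$mask$bits)
    d <- sqrt(sum((transform_points(ta, ctr) -
                     transform_points(tb, ctr))^2))
    data.frame(label = lb, rot_deg = abs(dth), trans_px = d)
  })
  do.call(rbind, out)
}
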