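# Shared fixtures (cached per session) and independent reference
# implementations used as oracles.

.fx_cache <- new.env(parent = emptyenv())

cached_fixture <- function(preset = "easy", seed = 1, pspec = NULL,
                           fspec = NULL) {
  key <- paste(preset, seed, is.null(pspec), is.null(fspec), sep = "|")
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- simulate_fixture(preset, seed, pspec = pspec,
                                         fspec = fspec)
  .fx_cache[[key]]
}

cached_edges <- function(preset = "easy", seed = 1) {
  key <- paste("edges", preset, seed, sep = "|")
  if (is.null(.fx_cache[[key]])) {
    fx <- cached_fixture(preset, seed)
    qs <- fx$quadrants
    for (lb in c("ul", "ur", "ll", "lr"))
      qs[[lb]] <- detect_corners_and_edges(qs[[lb]])
    .fx_cache[[key]] <- qs
  }
  .fx_cache[[key]]
}

# a small phantom for fast pipeline/CLI tests
small_fixture <- function(seed = 1, preset = "easy") {
  key <- paste("small", preset, seed, sep = "|")
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- simulate_fixture(
      preset, seed,
      pspec = phantom_spec(seed = seed, canvas = c(320, 288),
                           axes = c(130, 108)))
  .fx_cache[[key]]
}

# quadrant with hand-set edge geometry, for correspondence tests
stub_quadrant <- function(label, edge_key, pixels, dim = c(40, 40)) {
  q <- quadrant(label,
                gray_image(matrix(0.5, dim[1], dim[2])),
                tissue_mask(matrix(1L, dim[1], dim[2])))
  ep <- pixels[c(1, nrow(pixels)), , drop = FALSE]
  edge <- structure(
    list(pixels = pixels, line_slope = 0, line_intercept = 0,
         swapped = edge_key == "v",
         orientation = if (edge_key == "v") "vertical" else "horizontal",
         C_in = ep[1, ], C_out = ep[2, ]),
    class = "stitch_edge")
  q$edges <- structure(list(edges = setNames(list(edge), edge_key)),
                       class = "edge_geometry")
  q
}

identity_t <- function() rigid_transform(0, 0, 0)

# -- independent reference implementations (oracles) ----------------------

# Theil-Sen by explicit enumeration of all pairwise slopes
oracle_theil_sen <- function(x, y) {
  n <- length(x)
  slopes <- c()
  for (i in 1:(n - 1))
    for (j in (i + 1):n)
      if (x[j] != x[i]) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
  s <- stats::median(slopes)
  list(slope = s, intercept = stats::median(y - s * x))
}

# symmetric Hausdorff by naive double loop
oracle_hausdorff <- function(a, b) {
  da <- apply(a, 1, function(p) min(sqrt((b[, 1] - p[1])^2 +
                                           (b[, 2] - p[2])^2)))
  db <- apply(b, 1, function(p) min(sqrt((a[, 1] - p[1])^2 +
                                           (a[, 2] - p[2])^2)))
  max(max(da), max(db))
}

# pair dissimilarity by naive loops implementing the stated
# correspondence rule (projection onto the facing polyline, interior foot
# with half-pixel slack, distance <= tau, injective claims with +-2
# fallback) and the pooling formula (sum of matched L1 + m*phi) / (n + m)
oracle_pair_dissim <- function(pa, pb, Va, Vb, tau, phi, extra_m = 0) {
  na <- nrow(pa); nb <- nrow(pb)
  used <- rep(FALSE, nb)
  match <- integer(na)
  for (i in seq_len(na)) {
    best <- Inf; bj <- -1; bt <- 0; btraw <- 0
    for (j in seq_len(nb - 1)) {
      e <- pb[j + 1, ] - pb[j, ]
      len2 <- sum(e^2)
      traw <- if (len2 > 0) sum((pa[i, ] - pb[j, ]) * e) / len2 else 0
      t <- min(max(traw, 0), 1)
      f <- pb[j, ] + t * e
      d2 <- sum((pa[i, ] - f)^2)
      if (d2 < best) { best <- d2; bj <- j; bt <- t; btraw <- traw }
    }
    if (best > tau^2) next
    if ((bj == 1 && btraw < -0.5) || (bj == nb - 1 && btraw > 1.5)) next
    partner <- if (bt >= 0.5) bj + 1 else bj
    if (used[partner]) {
      found <- NA
      for (off in 1:2) {
        if (partner + off <= nb && !used[partner + off]) {
          found <- partner + off; break
        } else if (partner - off >= 1 && !used[partner - off]) {
          found <- partner - off; break
        }
      }
      if (is.na(found)) next
      partner <- found
    }
    used[partner] <- TRUE
    match[i] <- partner
  }
  n <- sum(match > 0)
  sumd <- 0
  for (i in which(match > 0))
    sumd <- sumd + sum(abs(Va[, i] - Vb[, match[i]]))
  m <- (na - n) + (nb - n) + extra_m
  list(d_pair = if (n + m > 0) (sumd + m * phi) / (n + m) else phi,
       n = n, m = m)
}

# four quadrants cut from a textured rectangle with axis-aligned straight
# cuts; optional per-quadrant rotations (degrees).  Returns the quadrant
# set plus the true relative transforms (zero-rotation case) or the true
# relative rotations.
rect_quadrants <- function(thetas = c(ul = 0, ur = 0, ll = 0, lr = 0)) {
  X <- 360L; Y <- 280L; cx <- 180L; cy <- 140L; pad <- 8L
  set.seed(99)
  img <- matrix(runif(Y * X, 0.35, 0.65), Y, X)
  crops <- list(ul = list(rows = 1:cy, cols = 1:cx),
                ur = list(rows = 1:cy, cols = (cx + 1):X),
                ll = list(rows = (cy + 1):Y, cols = 1:cx),
                lr = list(rows = (cy + 1):Y, cols = (cx + 1):X))
  quads <- list(); offs <- list()
  for (lb in names(crops)) {
    r <- crops[[lb]]
    h <- length(r$rows); w <- length(r$cols)
    px <- matrix(1, h + 2 * pad, w + 2 * pad)
    mk <- matrix(0L, h + 2 * pad, w + 2 * pad)
    px[pad + (1:h), pad + (1:w)] <- img[r$rows, r$cols]
    mk[pad + (1:h), pad + (1:w)] <- 1L
    q0 <- quadrant(lb, gray_image(px), tissue_mask(mk))
    offs[[lb]] <- c(min(r$cols) - 1 - pad, min(r$rows) - 1 - pad)
    if (thetas[[lb]] != 0) {
      ctr <- c((w + 2 * pad + 1) / 2, (h + 2 * pad + 1) / 2)
      t <- rigid_transform(0, 0, thetas[[lb]], center = ctr)
      d <- dim(mk) + 80L
      rr <- apply_transform(q0, t, d, origin = c(-40, -40), background = 1)
      q0 <- quadrant(lb, rr$image, rr$mask)
    }
    quads[[lb]] <- q0
  }
  truth <- list()
  for (lb in names(crops)) {
    d <- offs[[lb]] - offs$ul
    ctr <- colMeans(which(quads[[lb]]$mask$bits == 1, arr.ind = TRUE))[2:1]
    truth[[lb]] <- rigid_transform(d[1], d[2], 0, center = ctr)
  }
  truth$ul <- rigid_transform(0, 0, 0, center = truth$ul$center)
  list(qs = quadrant_set(quads$ul, quads$ur, quads$ll, quads$lr),
       truth = transform_set(truth, fixed = "ul"),
       thetas = thetas)
}
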