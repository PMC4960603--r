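test_that("standardize leaves conforming images alone and applies flips", {
  px <- round(matrix(runif(400), 20, 20) * 255) / 255
  gi <- gray_image(px, scale_um_per_px = 8)
  out <- standardize(gi, target_max_dim = 20)
  expect_equal(out$pixels, px)

  f1 <- standardize(gi, flip_h = TRUE, target_max_dim = 20)
  f2 <- standardize(f1, flip_h = TRUE, target_max_dim = 20)
  expect_equal(f2$pixels, px)

  small <- standardize(gi, target_max_dim = 10)
  expect_equal(max(dim(small$pixels)), 10)
  expect_equal(small$scale_um_per_px, 16)
})

test_that("RGB rasters convert with Rec. 601 luminance weights", {
  f <- tempfile(fileext = ".png")
  arr <- array(0, c(6, 6, 3)); arr[, , 1] <- 1   # pure red
  EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), f)
  g <- read_gray_image(f)
  expect_equal(unique(round(as.vector(g$pixels), 3)), 0.299)
})

test_that("segment_tissue recovers a dark ellipse on white background", {
  X <- 160; Y <- 120
  xg <- matrix(rep(1:X, each = Y), Y, X)
  yg <- matrix(rep(1:Y, times = X), Y, X)
  truth <- ((xg - 80) / 55)^2 + ((yg - 60) / 40)^2 <= 1
  px <- matrix(1, Y, X); px[truth] <- 0.3
  set.seed(1)
  px <- pmin(pmax(px + matrix(rnorm(Y * X, 0, 0.02), Y, X), 0), 1)
  m <- segment_tissue(gray_image(px))
  expect_gt(mask_iou(m$bits, truth + 0L), 0.98)

  expect_error(segment_tissue(gray_image(matrix(0.5, 20, 20))),
               "variation")

  # a 3-px speck away from the ellipse is dropped (largest component)
  px2 <- px; px2[5:7, 5] <- 0.2
  m2 <- segment_tissue(gray_image(px2))
  expect_identical(sum(m2$bits[1:10, 1:10]), 0L)
})

test_that("min_area_bbox matches analytic and brute-force areas", {
  rect <- matrix(0L, 80, 100); rect[20:59, 25:84] <- 1L  # 40 x 60
  bb <- min_area_bbox(tissue_mask(rect))
  expect_lt(abs(bb$area - 40 * 60), 1)

  # rotate the rectangle 30 degrees and compare to a brute-force search
  idx <- which(rect == 1L, arr.ind = TRUE)
  pts <- cbind(idx[, 2], idx[, 1])
  a <- 30 * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  rot <- round(sweep(sweep(pts, 2, colMeans(pts)) %*% t(R), 2, c(90, 70),
                     "+"))
  mk <- matrix(0L, 180, 180); mk[rot[, 2:1]] <- 1L
  bb2 <- min_area_bbox(tissue_mask(mk))
  brute <- min(vapply(seq(0, 90, by = 0.1), function(deg) {
    aa <- deg * pi / 180
    Rb <- matrix(c(cos(aa), sin(aa), -sin(aa), cos(aa)), 2, 2)
    p <- rot %*% Rb
    (diff(range(p[, 1])) + 1) * (diff(range(p[, 2])) + 1)
  }, numeric(1)))
  expect_lt(abs(bb2$area - brute) / brute, 0.02)
  expect_lt(abs(bb2$area - 40 * 60) / (40 * 60), 0.05)

  # disk: the square circumscribes the circle
  dg <- matrix(0L, 90, 90)
  dgx <- matrix(rep(1:90, each = 90), 90, 90)
  dgy <- matrix(rep(1:90, times = 90), 90, 90)
  dg[(dgx - 45)^2 + (dgy - 45)^2 <= 30^2] <- 1L
  bb3 <- min_area_bbox(tissue_mask(dg))
  expect_lt(abs(bb3$area - 4 * 30^2) / (4 * 30^2), 0.05)

  expect_error(min_area_bbox(tissue_mask(matrix(0L, 5, 5))), "foreground")
})

test_that("theil_sen matches exhaustive pairwise-slope enumeration", {
  f <- theil_sen(cbind(0:2, 0:2))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)

  pts <- cbind(c(0, 1, 2, 3), c(0, 1, 2, 10))
  f2 <- theil_sen(pts)
  o2 <- oracle_theil_sen(pts[, 1], pts[, 2])
  expect_identical(f2$slope, o2$slope)
  expect_identical(f2$intercept, o2$intercept)

  set.seed(4)
  x <- runif(50, 0, 10); y <- 2 * x + 1 + rnorm(50, 0, 0.05)
  xo <- runif(10, 0, 10); yo <- rep(100, 10)
  pts3 <- cbind(c(x, xo), c(y, yo))
  f3 <- theil_sen(pts3)
  o3 <- oracle_theil_sen(pts3[, 1], pts3[, 2])
  expect_identical(f3$slope, o3$slope)
  expect_lt(abs(f3$slope - 2), 0.05)

  # invariant to ordering and to duplicating the whole set
  perm <- pts3[sample(nrow(pts3)), ]
  expect_equal(theil_sen(perm)$slope, f3$slope)
  expect_equal(theil_sen(rbind(pts3, pts3))$slope, f3$slope)

  expect_error(theil_sen(cbind(rep(1, 5), rep(2, 5))), "identical")
  fv <- theil_sen(cbind(rep(3, 10), 1:10))
  expect_true(fv$swapped)
})

test_that("detected edges of a filled square face the section interior", {
  sq <- matrix(0L, 100, 100); sq[21:80, 21:80] <- 1L
  base <- quadrant("ul", gray_image(matrix(0.4, 100, 100)),
                   tissue_mask(sq))
  qul <- detect_corners_and_edges(base)
  expect_length(qul$edges$edges, 2)
  expect_equal(nrow(qul$edges$corner_points), 3)
  # ul: interior is to the lower right, so edges are the right and
  # bottom sides
  expect_lt(abs(mean(qul$edges$edges$v$pixels[, 1]) - 80), 2)
  expect_lt(abs(mean(qul$edges$edges$h$pixels[, 2]) - 80), 2)

  qlr <- detect_corners_and_edges(quadrant("lr", base$image, base$mask))
  expect_lt(abs(mean(qlr$edges$edges$v$pixels[, 1]) - 21), 2)
  expect_lt(abs(mean(qlr$edges$edges$h$pixels[, 2]) - 21), 2)

  tiny <- matrix(0L, 10, 10); tiny[5:6, 5] <- 1L
  expect_error(detect_corners_and_edges(
    quadrant("ul", gray_image(matrix(0.4, 10, 10)), tissue_mask(tiny))))
})

test_that("detected edges follow the true cut lines of a fixture", {
  fx <- cached_fixture("easy", 3)
  qs <- cached_edges("easy", 3)
  for (lb in c("ul", "lr")) {
    aff <- fx$ground_truth$affines[[lb]]
    for (key in c("h", "v")) {
      cut <- if (key == "h") fx$ground_truth$cut_h else fx$ground_truth$cut_v
      e <- qs[[lb]]$edges$edges[[key]]$pixels
      ph <- sweep(e %*% t(aff$R), 2, aff$v, "+")
      d <- vapply(seq_len(nrow(ph)), function(i)
        min(sqrt((cut$x - ph[i, 1])^2 + (cut$y - ph[i, 2])^2)), numeric(1))
      expect_lt(mean(d), 2)   # kerf 0 on the easy preset
    }
  }
})

test_that("initial_align recovers an unperturbed straight-cut rectangle", {
  rq <- rect_quadrants()
  ts0 <- initial_align(rq$qs)
  cmp <- compare_transform_sets(ts0, rq$truth, rq$qs)
  expect_true(all(cmp$trans_px <= 2))
  expect_true(all(cmp$rot_deg <= 1))

  # after alignment, facing horizontal edges are nearly level
  for (lb in c("ul", "ur")) {
    q <- detect_corners_and_edges(rq$qs[[lb]])
    e <- q$edges$edges$h
    p <- transform_points(ts0$transforms[[lb]], e$pixels)
    fit <- theil_sen(p)
    expect_lt(abs(fit$slope), tan(2 * pi / 180))
  }
})

test_that("initial_align corrects quadrant rotations within 2 degrees", {
  rq <- rect_quadrants(thetas = c(ul = 8, ur = -10, ll = 10, lr = -7))
  ts0 <- initial_align(rq$qs)
  # recovering quadrant q means undoing its rotation relative to ul
  for (lb in c("ur", "ll", "lr")) {
    truth_rel <- rq$thetas[["ul"]] - rq$thetas[[lb]]
    expect_lt(abs(ts0$transforms[[lb]]$theta - truth_rel), 2)
  }

  # an ellipse fixture with rotated quadrants also comes back level
  fx <- cached_fixture(
    "easy", 6,
    fspec = fragment_spec(seed = 6, kerf = 0, trans_range = 0,
                          rot_range = 10, waviness_amp = 2))
  ts1 <- initial_align(fx$quadrants)
  cmp <- compare_transform_sets(ts1, fx$ground_truth$transforms,
                                fx$quadrants)
  expect_true(all(cmp$rot_deg <= 2))
})

test_that("initial_align leaves at most a kerf-sized gap along cuts", {
  kerf <- 5
  fx <- cached_fixture(
    "medium", 8,
    fspec = fragment_spec(seed = 8, kerf = kerf, trans_range = 0,
                          rot_range = 0, waviness_amp = 2))
  qs <- fx$quadrants
  for (lb in c("ul", "ur", "ll", "lr"))
    qs[[lb]] <- detect_corners_and_edges(qs[[lb]])
  ts0 <- initial_align(qs)
  pa <- transform_points(ts0$transforms$ul, qs$ul$edges$edges$v$pixels)
  pb <- transform_points(ts0$transforms$ur, qs$ur$edges$edges$v$pixels)
  gap <- stats::median(vapply(seq_len(nrow(pa)), function(i)
    min(sqrt((pb[, 1] - pa[i, 1])^2 + (pb[, 2] - pa[i, 2])^2)),
    numeric(1)))
  expect_lte(gap, kerf + 2)
})
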