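test_that("gray_image and tissue_mask validate their invariants", {
  expect_error(gray_image(matrix(1.5, 2, 2)), "intensities")
  expect_error(gray_image(matrix(0.5, 2, 2), scale_um_per_px = 0), "scale")
  gi <- gray_image(matrix(runif(12), 3, 4), scale_um_per_px = 8)
  expect_s3_class(gi, "gray_image")
  tm <- tissue_mask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
  expect_identical(sort(unique(as.vector(tm$bits))), c(0L, 1L))
  expect_error(quadrant("ul", gi, tissue_mask(matrix(1, 2, 2))),
               "dimensions")
})

test_that("rigid transforms compose, invert, and rescale exactly", {
  t1 <- rigid_transform(5, -3, 32, center = c(10, 7))
  inv <- invert_transform(t1)
  rt <- compose_transforms(inv, t1)
  expect_lt(abs(rt$tx), 1e-9)
  expect_lt(abs(rt$ty), 1e-9)
  expect_lt(abs(rt$theta), 1e-9)

  pts <- cbind(runif(20, 0, 50), runif(20, 0, 50))
  expect_equal(transform_points(rigid_transform(0, 0, 0), pts), pts)
  t2 <- rigid_transform(-2, 4, -15, center = c(3, 3))
  both <- transform_points(compose_transforms(t2, t1), pts)
  seq_ <- transform_points(t2, transform_points(t1, pts))
  expect_equal(both, seq_, tolerance = 1e-12)

  s <- scale_transform(t1, 4)
  expect_equal(transform_points(s, pts * 4), 4 * transform_points(t1, pts),
               tolerance = 1e-9)
})

test_that("transform round trip preserves the mask", {
  fx <- cached_fixture("easy", 1)
  q <- fx$quadrants$ul
  t <- rigid_transform(6, -4, 11,
                       center = colMeans(which(q$mask$bits == 1,
                                               arr.ind = TRUE))[2:1])
  d <- dim(q$mask$bits) + 80
  r1 <- apply_transform(q, t, d, origin = c(-40, -40))
  # canvas pixel (x, y) holds common-frame coordinate (x - 41, y - 41),
  # so fold that shift into the transform before inverting
  shifted <- rigid_transform(t$tx + 41, t$ty + 41, t$theta, t$center)
  back <- apply_transform(quadrant(q$label, r1$image, r1$mask),
                          invert_transform(shifted), dim(q$mask$bits))
  expect_gt(mask_iou(back$mask, q$mask), 0.98)
})

test_that("apply_transform handles identity, full turns, and quarter turns", {
  px <- matrix(runif(900), 30, 30)
  mk <- matrix(0L, 30, 30); mk[8:24, 6:27] <- 1L
  q <- quadrant("ul", gray_image(px), tissue_mask(mk))

  r <- apply_transform(q, rigid_transform(0, 0, 0), c(30, 30))
  expect_equal(r$image$pixels, px, tolerance = 1e-12)
  expect_identical(r$mask$bits, mk)

  r360 <- apply_transform(q, rigid_transform(0, 0, 360, center = c(15, 15)),
                          c(30, 30))
  expect_equal(r360$image$pixels, px, tolerance = 1e-6)

  # +90 degrees about (2, 2) on a 3x3 grid vs analytic coordinate rotation
  g <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9), 3, 3)
  q3 <- quadrant("ul", gray_image(g), tissue_mask(matrix(1L, 3, 3)))
  r90 <- apply_transform(q3, rigid_transform(0, 0, 90, center = c(2, 2)),
                         c(3, 3))
  expected <- matrix(0, 3, 3)
  Rinv <- matrix(c(0, -1, 1, 0), 2, 2)  # rotation by -90
  for (x in 1:3) for (y in 1:3) {
    src <- Rinv %*% (c(x, y) - c(2, 2)) + c(2, 2)
    expected[y, x] <- g[src[2], src[1]]
  }
  expect_equal(r90$image$pixels, expected, tolerance = 1e-9)
})

test_that("apply_transform rejects canvases that cannot hold the mask", {
  q <- quadrant("ul", gray_image(matrix(0.5, 20, 20)),
                tissue_mask(matrix(1L, 20, 20)))
  expect_error(apply_transform(q, rigid_transform(30, 0, 0), c(20, 20)),
               "overflows")
})

test_that("composite_section unions masks with the fixed draw order", {
  blk <- function(lb) quadrant(lb, gray_image(matrix(0.2, 10, 10)),
                               tissue_mask(matrix(1L, 10, 10)))
  ts <- transform_set(list(
    ul = rigid_transform(0, 0, 0), ur = rigid_transform(10, 0, 0),
    ll = rigid_transform(0, 10, 0), lr = rigid_transform(10, 10, 0)))
  qs <- quadrant_set(blk("ul"), blk("ur"), blk("ll"), blk("lr"))
  comp <- composite_section(qs, ts)
  expect_identical(sum(comp$mask$bits), 400L)

  # overlapping identical quadrants leave the union area unchanged
  ts0 <- transform_set(list(ul = rigid_transform(0, 0, 0),
                            ur = rigid_transform(0, 0, 0),
                            ll = rigid_transform(0, 0, 0),
                            lr = rigid_transform(0, 0, 0)))
  comp0 <- composite_section(qs, ts0)
  expect_identical(sum(comp0$mask$bits), 100L)

  # union area never exceeds the sum of quadrant areas
  fx <- cached_fixture("easy", 1)
  compt <- composite_section(fx$quadrants, fx$ground_truth$transforms)
  total <- sum(vapply(c("ul", "ur", "ll", "lr"),
                      function(lb) sum(fx$quadrants[[lb]]$mask$bits), 0L))
  expect_lte(sum(compt$mask$bits), total)
})

test_that("ground-truth compositing reproduces the phantom shape", {
  fx <- cached_fixture(
    "easy", 7,
    fspec = fragment_spec(seed = 7, kerf = 0, trans_range = 0,
                          rot_range = 0, waviness_amp = 0))
  comp <- composite_section(fx$quadrants, fx$ground_truth$transforms,
                            margin = 4)
  # overlay composited mask on the phantom mask through the ul affine
  aff <- fx$ground_truth$affines$ul
  idx <- which(comp$mask$bits == 1L, arr.ind = TRUE)
  pts <- cbind(idx[, 2] + comp$origin[1] - 1, idx[, 1] + comp$origin[2] - 1)
  ph <- round(sweep(pts %*% t(aff$R), 2, aff$v, "+"))
  pm <- fx$ground_truth$phantom_mask$bits
  ok <- ph[, 1] >= 1 & ph[, 1] <= ncol(pm) & ph[, 2] >= 1 & ph[, 2] <= nrow(pm)
  inter <- sum(pm[cbind(ph[ok, 2], ph[ok, 1])])
  union <- nrow(ph) + sum(pm) - inter
  expect_gt(inter / union, 0.95)
})

test_that("pyramids have the right sizes and conserve intensity", {
  fx <- cached_fixture("easy", 1)
  q <- fx$quadrants$ul
  pyr <- build_pyramid(q, c(4, 2, 1))
  d <- dim(q$image$pixels)
  expect_equal(dim(pyr[[1]]$image$pixels), ceiling(d / 4))
  expect_equal(dim(pyr[[2]]$image$pixels), ceiling(d / 2))
  expect_equal(dim(pyr[[3]]$image$pixels), d)
  for (lev in pyr)
    expect_lt(abs(mean(lev$image$pixels) - mean(q$image$pixels)), 0.02)

  expect_error(build_pyramid(q, c(2, 4, 1)), "decreasing")
  one <- build_pyramid(q, 1)
  expect_equal(one[[1]]$image$pixels, q$image$pixels)

  const <- quadrant("ul", gray_image(matrix(0.7, 64, 64)),
                    tissue_mask(matrix(1L, 64, 64)))
  pc <- build_pyramid(const, c(4, 2, 1))
  for (lev in pc)
    expect_equal(range(lev$image$pixels), c(0.7, 0.7), tolerance = 1e-12)
})

test_that("transform sets serialize to JSON and back losslessly", {
  ts <- transform_set(list(
    ul = rigid_transform(0, 0, 0, center = c(5, 6)),
    ur = rigid_transform(101.25, -3.5, -2.125, center = c(50, 40)),
    ll = rigid_transform(1.5, 98, 3, center = c(45, 55)),
    lr = rigid_transform(99, 97, -1, center = c(52, 48))))
  f <- tempfile(fileext = ".json")
  write_transform_set(ts, f)
  ts2 <- read_transform_set(f)
  for (lb in c("ul", "ur", "ll", "lr")) {
    expect_equal(ts$transforms[[lb]]$tx, ts2$transforms[[lb]]$tx,
                 tolerance = 0)
    expect_equal(ts$transforms[[lb]]$theta, ts2$transforms[[lb]]$theta,
                 tolerance = 0)
    expect_equal(ts$transforms[[lb]]$center, ts2$transforms[[lb]]$center,
                 tolerance = 0)
  }
  expect_error(transform_set(list(ul = rigid_transform(1, 0, 0),
                                  ur = rigid_transform(0, 0, 0),
                                  ll = rigid_transform(0, 0, 0),
                                  lr = rigid_transform(0, 0, 0))),
               "identity")
})

test_that("image files round-trip through PNG", {
  px <- round(matrix(runif(600), 20, 30) * 255) / 255
  f <- tempfile(fileext = ".png")
  write_gray_image(gray_image(px), f)
  back <- read_gray_image(f)
  expect_equal(back$pixels, px, tolerance = 1e-12)
  expect_error(read_gray_image(tempfile()), "no such file")
})
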