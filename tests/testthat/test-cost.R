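test_that("cost_config enforces the weight and size invariants", {
  cfg <- cost_config()
  expect_equal(cfg$w1 + cfg$w2, 1)
  expect_equal(cfg$w3 + cfg$w4, 1)
  expect_identical(cfg$p, 81L)
  expect_identical(cfg$b, 16L)
  expect_error(cost_config(w1 = 1.2), "weights")
  expect_error(cost_config(patch_px = 80), "odd")
  expect_error(cost_config(bins = 1), "bins")
  # a patch of constant physical size collapses to one pixel at the
  # lowest resolution, where intensities replace histograms
  expect_identical(quadstitch:::patch_at_level(81, 81), 1L)
  expect_identical(quadstitch:::phi_for(1), 1)
  expect_identical(quadstitch:::phi_for(10), 2)
})

test_that("l1_dissimilarity attains its analytic extremes", {
  h <- function(v) structure(list(bins = v, mode = "histogram",
                                  empty = FALSE),
                             class = "intensity_histogram")
  p <- function(v) structure(list(bins = v, mode = "pixel", empty = FALSE),
                             class = "intensity_histogram")
  expect_identical(l1_dissimilarity(h(c(0.25, 0.75)), h(c(0.25, 0.75))), 0)
  expect_identical(l1_dissimilarity(h(c(1, rep(0, 15))),
                                    h(c(rep(0, 15), 1))), 2)
  expect_identical(l1_dissimilarity(p(0), p(1)), 1)
  expect_error(l1_dissimilarity(h(c(1, 0)), p(0.5)), "mismatch")
})

test_that("l1_dissimilarity is a metric on random histogram triples", {
  set.seed(9)
  h <- function(v) structure(list(bins = v, mode = "histogram",
                                  empty = FALSE),
                             class = "intensity_histogram")
  for (i in 1:100) {
    tri <- lapply(1:3, function(k) {
      v <- runif(16); h(v / sum(v))
    })
    ab <- l1_dissimilarity(tri[[1]], tri[[2]])
    ba <- l1_dissimilarity(tri[[2]], tri[[1]])
    ac <- l1_dissimilarity(tri[[1]], tri[[3]])
    cb <- l1_dissimilarity(tri[[3]], tri[[2]])
    expect_identical(ab, ba)
    expect_lte(ab, ac + cb + 1e-12)
    expect_lte(ab, 2)
  }
})

test_that("patch_vector bins tissue pixels and honours pixel mode", {
  img <- gray_image(matrix(0.5, 21, 21))
  msk <- tissue_mask(matrix(1L, 21, 21))
  v <- patch_vector(img, msk, c(11, 11), p = 9, b = 4)
  expect_equal(v$bins, c(0, 0, 1, 0))

  img2 <- gray_image(matrix(0.73, 5, 5))
  v2 <- patch_vector(img2, tissue_mask(matrix(1L, 5, 5)), c(3, 3),
                     p = 1, b = 4)
  expect_identical(v2$mode, "pixel")
  expect_equal(v2$bins, 0.73)

  half <- matrix(0.1, 20, 21); half[11:20, ] <- 0.9
  v3 <- patch_vector(gray_image(half), tissue_mask(matrix(1L, 20, 21)),
                     c(11, 10), p = 19, b = 2)
  # window rows 1..19: ten rows of 0.1 and nine of 0.9
  expect_equal(v3$bins, c(10, 9) / 19, tolerance = 1e-12)

  v4 <- patch_vector(img, tissue_mask(matrix(0L, 21, 21)), c(11, 11),
                     p = 9, b = 4)
  expect_true(v4$empty)
  expect_error(patch_vector(img, msk, c(50, 50), p = 9, b = 4), "outside")
})

test_that("find_correspondences pairs facing parallel edges", {
  mk_edge <- function(x, ys) cbind(rep(x, length(ys)), ys)
  qa <- stub_quadrant("ul", "v", mk_edge(10, 1:20))
  qb <- stub_quadrant("ur", "v", mk_edge(11, 1:20))
  cs <- find_correspondences(qa, qb, identity_t(), identity_t(), tau = 3)
  expect_identical(cs$n, 20L)
  expect_identical(cs$m, 0L)

  qb10 <- stub_quadrant("ur", "v", mk_edge(20, 1:20))
  cs10 <- find_correspondences(qa, qb10, identity_t(), identity_t(),
                               tau = 3)
  expect_identical(cs10$n, 0L)
  expect_identical(cs10$m, 40L)

  qa20 <- stub_quadrant("ul", "v", mk_edge(10, 1:20))
  qb30 <- stub_quadrant("ur", "v", mk_edge(11, 1:30))
  cs23 <- find_correspondences(qa20, qb30, identity_t(), identity_t(),
                               tau = 3)
  expect_identical(cs23$n, 20L)
  expect_identical(cs23$m, 10L)

  expect_error(find_correspondences(
    quadrant("ul", gray_image(matrix(0.5, 4, 4)),
             tissue_mask(matrix(1L, 4, 4))),
    qb, identity_t(), identity_t(), 3), "edge geometry")
})

test_that("pair dissimilarity pools matched L1 and phi-weighted leftovers", {
  # n = 2 with dissimilarities 0.2 and 0.4, one non-corresponding pixel,
  # phi = 2: (0.2 + 0.4 + 2) / 3
  pa <- cbind(c(0, 0, 0), c(1, 2, 4))
  pb <- cbind(c(1, 1), c(1, 2))
  Va <- cbind(c(0.6, 0.4), c(1, 0), c(0.5, 0.5))
  Vb <- cbind(c(0.5, 0.5), c(0.8, 0.2))
  r <- quadstitch:::pair_dissim_core(pa, pb, Va, Vb, tau = 1.5, phi = 2,
                                     n_empty = 0)
  expect_identical(r$n, 2L)
  expect_identical(r$m, 1L)
  expect_equal(r$d_pair, (0.2 + 0.4 + 2) / 3, tolerance = 1e-12)

  # fully unmatched adjacency saturates at phi
  r2 <- quadstitch:::pair_dissim_core(pa, pb + 100, Va, Vb, tau = 1.5,
                                      phi = 2, n_empty = 0)
  expect_equal(r2$d_pair, 2)
})

test_that("identical abutting quadrants have near-zero dissimilarity", {
  fx <- cached_fixture("easy", 1)
  q <- detect_corners_and_edges(fx$quadrants$ul)
  # pair the quadrant's own edge against itself shifted one pixel
  qb <- q; qb$label <- "ur"
  d <- pair_dissimilarity(q, qb, identity_t(),
                          rigid_transform(1, 0, 0), cost_config())
  expect_lt(d$d_pair, 0.1)
  expect_equal(pair_dissimilarity(q, qb, identity_t(), identity_t(),
                                  cost_config())$d_pair, 0,
               tolerance = 1e-9)
})

test_that("pair_dissimilarity agrees exactly with a naive double loop", {
  fx <- cached_fixture("easy", 2)
  qs <- cached_edges("easy", 2)
  gt <- fx$ground_truth$transforms
  cfg <- cost_config()
  tau <- quadstitch:::tau_for(cfg, 1)
  for (ab in list(c("ul", "ur"), c("ll", "ul"))) {
    key <- quadstitch:::facing_edge(ab[1], ab[2])
    qa <- qs[[ab[1]]]; qb <- qs[[ab[2]]]
    ea <- quadstitch:::edge_patch_matrix(qa$image$pixels, qa$mask$bits,
                                         qa$edges$edges[[key]]$pixels, 1,
                                         81L, 16L)
    eb <- quadstitch:::edge_patch_matrix(qb$image$pixels, qb$mask$bits,
                                         qb$edges$edges[[key]]$pixels, 1,
                                         81L, 16L)
    pa <- transform_points(gt$transforms[[ab[1]]], ea$xy)
    pb <- transform_points(gt$transforms[[ab[2]]], eb$xy)
    fast <- quadstitch:::pair_dissim_core(pa, pb, ea$V, eb$V, tau, 2,
                                          ea$n_empty + eb$n_empty)
    slow <- oracle_pair_dissim(pa, pb, ea$V, eb$V, tau, 2,
                               ea$n_empty + eb$n_empty)
    expect_identical(fast$n, slow$n)
    expect_identical(fast$m, slow$m)
    expect_equal(fast$d_pair, slow$d_pair, tolerance = 1e-12)
  }
})

test_that("pair_misalignment weights inner and outer endpoint distances", {
  mk <- function(cin, cout) structure(
    list(C_in = cin, C_out = cout, orientation = "vertical"),
    class = "stitch_edge")
  e1 <- mk(c(0, 0), c(0, 100))
  cfg <- cost_config()
  expect_equal(pair_misalignment(e1, e1, identity_t(), identity_t(), cfg),
               0)
  e2 <- mk(c(20, 0), c(10, 100))
  m <- pair_misalignment(e1, e2, identity_t(), identity_t(), cfg)
  expect_equal(m, 0.4 * 20 + 0.6 * 10)
  e3 <- mk(c(40, 0), c(20, 100))
  expect_equal(pair_misalignment(e1, e3, identity_t(), identity_t(), cfg),
               2 * m)
  expect_error(pair_misalignment(mk(NULL, NULL), e1, identity_t(),
                                 identity_t(), cfg), "endpoints")
})

test_that("total_cost blends the components and prefers the true pose", {
  fx <- cached_fixture("easy", 1)
  qs <- cached_edges("easy", 1)
  gt <- fx$ground_truth$transforms
  r <- total_cost(qs, gt, cost_config())
  expect_equal(r$cost, 0.989 * r$d_tot + 0.011 * r$m_tot)
  expect_equal(total_cost(qs, gt, cost_config(w1 = 1))$cost, r$d_tot)
  expect_equal(total_cost(qs, gt, cost_config(w1 = 0))$cost, r$m_tot)
  expect_true(all(r$d_pair >= 0 & r$d_pair <= 2))
  expect_true(all(r$m_pair >= 0))

  shifted <- gt
  t <- shifted$transforms$lr
  shifted$transforms$lr <- rigid_transform(t$tx + 10, t$ty, t$theta,
                                           t$center)
  expect_lt(r$cost, total_cost(qs, shifted, cost_config())$cost)
})

test_that("total_cost is invariant under a global rigid motion", {
  fx <- cached_fixture("easy", 1)
  qs <- cached_edges("easy", 1)
  gt <- fx$ground_truth$transforms
  g <- rigid_transform(17, -23, 12, center = c(100, 100))
  moved <- lapply(gt$transforms, function(t)
    compose_transforms(g, t, center = t$center))
  ts2 <- structure(list(fixed = "ul", transforms = moved),
                   class = "transform_set")
  c1 <- total_cost(qs, gt, cost_config())$cost
  c2 <- total_cost(qs, ts2, cost_config())$cost
  expect_equal(c1, c2, tolerance = 1e-6)
})
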