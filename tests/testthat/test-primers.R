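test_that("disc and annulus memberships follow the signed distance", {
  d <- shape_spec("disc", center_x = 0, center_y = 0, radius = 10)
  expect_equal(shape_membership(d, 0, 0), 1)      # interior
  expect_equal(shape_membership(d, 10.01, 0), 0)  # exterior
  # soft edge: smoothstep midpoint sits on the contour
  ds <- shape_spec("disc", center_x = 0, center_y = 0, radius = 10,
                   edge_width = 2)
  expect_equal(shape_membership(ds, 10, 0), 0.5)
  expect_equal(shape_membership(ds, 9, 0), 1)     # inner edge of the ramp
  expect_equal(shape_membership(ds, 11, 0), 0)    # outer edge of the ramp
  a <- shape_spec("annulus", center_x = 0, center_y = 0,
                  inner_radius = 5, outer_radius = 10)
  expect_equal(shape_membership(a, 3, 0), 0)      # the hole
  expect_equal(shape_membership(a, 7, 0), 1)
  expect_equal(shape_membership(a, 12, 0), 0)
  expect_error(shape_spec("annulus", inner_radius = 3, outer_radius = 2))
})

test_that("hard edges are the pointwise limit of soft edges", {
  shapes <- list(
    shape_spec("disc", 0, 0, radius = 7),
    shape_spec("rectangle", 0, 0, width = 8, height = 4, angle = 0.3))
  pts <- cbind(x = c(0, 3, 5, 9, -6, 2.2), y = c(0, 1, -2, 4, 0, -1.4))
  for (s in shapes) {
    soft <- s; soft$edge_width <- 1e-6
    hard <- shape_membership(s, pts[, 1], pts[, 2])
    near <- shape_membership(soft, pts[, 1], pts[, 2])
    expect_equal(near, hard, tolerance = 1e-5)
  }
})

test_that("polygons use the even-odd rule and rotated rectangles work", {
  sq <- shape_spec("polygon",
                   vertices = rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)))
  expect_equal(shape_membership(sq, 2, 2), 1)
  expect_equal(shape_membership(sq, 5, 2), 0)
  # self-intersecting bow-tie: the crossing center is outside by even-odd
  bow <- shape_spec("polygon",
                    vertices = rbind(c(0, 0), c(4, 4), c(4, 0), c(0, 4)))
  expect_equal(shape_membership(bow, 1, 2), 1)    # left triangle
  expect_equal(shape_membership(bow, 2, 0.5), 0)  # between the lobes
  r <- shape_spec("rectangle", 0, 0, width = 10, height = 2,
                  angle = pi / 2)
  expect_equal(shape_membership(r, 0, 4), 1)      # rotated onto the y axis
  expect_equal(shape_membership(r, 4, 0), 0)
  expect_error(shape_spec("polygon", vertices = rbind(c(0, 0), c(1, 1))),
               "3 vertices")
})

test_that("bezier regions flatten to a polygon approximating the curve", {
  # four cubic segments approximating a circle of radius 10 (kappa trick)
  k <- 10 * 0.5522847498
  cp <- rbind(c(10, 0), c(10, k), c(k, 10), c(0, 10),
              c(-k, 10), c(-10, k), c(-10, 0),
              c(-10, -k), c(-k, -10), c(0, -10),
              c(k, -10), c(10, -k), c(10, 0))
  b <- shape_spec("bezier_region", center_x = 0, center_y = 0,
                  control_points = cp)
  expect_equal(shape_membership(b, 0, 0), 1)
  expect_equal(shape_membership(b, 9.2, 0), 1)
  expect_equal(shape_membership(b, 10.5, 0), 0)
  expect_error(shape_spec("bezier_region",
                          control_points = rbind(c(0, 0), c(1, 1))),
               "3k \\+ 1")
})

test_that("membership combinators satisfy the De Morgan identities", {
  set.seed(4)
  a <- matrix(runif(64), 8, 8)
  b <- matrix(runif(64), 8, 8)
  expect_identical(membership_complement(membership_union(a, b)),
                   membership_intersect(membership_complement(a),
                                        membership_complement(b)))
  expect_identical(membership_complement(membership_intersect(a, b)),
                   membership_union(membership_complement(a),
                                    membership_complement(b)))
  expect_identical(membership_difference(a, b),
                   membership_intersect(a, membership_complement(b)))
})

test_that("gratings follow the stated trigonometric forms", {
  p <- pattern_spec("sine_grating", spatial_frequency = 0.1,
                    orientation = 0, phase = 0, mean = 0.4,
                    amplitude = 0.3)
  # zero-phase line: sin(0) = 0 -> mean
  expect_equal(eval_pattern(p, 0, 5), rep(0.4, 3))
  # quarter period along x: sin(pi/2) = 1
  expect_equal(eval_pattern(p, 2.5, 0), rep(0.7, 3))
  sq <- pattern_spec("square_grating", spatial_frequency = 0.1,
                     orientation = 0, phase = 0, mean = 0.4,
                     amplitude = 0.3)
  # ties (sin = 0) go to the high level
  expect_equal(eval_pattern(sq, 0, 0), rep(0.7, 3))
  expect_equal(eval_pattern(sq, 6, 0), rep(0.1, 3))
  expect_error(pattern_spec("sine_grating", mean = 0.2, amplitude = 0.5),
               "amplitude")
})

test_that("grating spatial mean over integer periods equals `mean`", {
  geo <- field_geometry(100, 50)
  cc <- pixel_centers(geo)
  for (kind in c("sine_grating", "square_grating")) {
    p <- pattern_spec(kind, spatial_frequency = 0.1, orientation = 0,
                      mean = 0.5, amplitude = 0.4)   # 10 periods across
    v <- eval_pattern(p, cc$x, cc$y)
    expect_equal(mean(v), 0.5, tolerance = 1e-3)
  }
})

test_that("the frequency/contrast chart hits its stated anchors", {
  p <- pattern_spec("campbell_robson", freq_start = 0.01, freq_end = 0.5,
                    contrast_start = 1, contrast_end = 0,
                    extent_x = 100, extent_y = 100)
  # contrast-zero edge: whole row at mid-gray
  expect_equal(eval_pattern(p, seq(0, 100, by = 7), rep(100, 15))[, 1],
               rep(0.5, 15))
  # x = 0: phase 0 -> 0.5 regardless of contrast
  expect_equal(eval_pattern(p, 0, 0)[1], 0.5)
  # values stay within [0, 1] for max contrast
  cc <- pixel_centers(field_geometry(50, 50, um_per_px = 2))
  v <- eval_pattern(p, cc$x, cc$y)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("image primers sample bilinearly from the asset", {
  img <- array(0, dim = c(2, 2, 3))
  img[1, 1, ] <- 0; img[1, 2, ] <- 1; img[2, 1, ] <- 1; img[2, 2, ] <- 0
  p <- pattern_spec("image", image = img, extent_x = 2, extent_y = 2)
  # pixel centers reproduce the asset
  expect_equal(eval_pattern(p, 0.5, 0.5)[1], 0)
  expect_equal(eval_pattern(p, 1.5, 0.5)[1], 1)
  # midpoint between the four pixels: bilinear average
  expect_equal(eval_pattern(p, 1, 1)[1], 0.5)
})

test_that("grid layouts generate the documented vertex geometry", {
  r <- grid_vertices("rectangular", rows = 3, cols = 4, spacing = 5)
  expect_equal(nrow(r), 12)
  expect_equal(r$x[1:4], c(0, 5, 10, 15))
  # hexagonal: odd rows (0-based) shifted by s/2, pitch s*sqrt(3)/2
  h <- grid_vertices("hexagonal", rows = 2, cols = 3, spacing = 4)
  expect_equal(h$x, c(0, 4, 8, 2, 6, 10))
  expect_equal(h$y, c(0, 0, 0, rep(4 * sqrt(3) / 2, 3)))
  # random layout is seeded and reproducible
  a <- grid_vertices("random", n = 10, extent_x = 50, extent_y = 30,
                     seed = 4)
  b <- grid_vertices("random", n = 10, extent_x = 50, extent_y = 30,
                     seed = 4)
  expect_identical(a, b)
  expect_true(all(a$x >= 0 & a$x <= 50 & a$y >= 0 & a$y <= 30))
  expect_error(grid_vertices("random", n = 3), "seed")
  expect_error(grid_vertices("rectangular", rows = 2, cols = 1,
                             labels = c("a", "a")), "duplicate")
})

test_that("grid_points repeats the base shape at each vertex by maximum", {
  base <- shape_spec("disc", center_x = 0, center_y = 0, radius = 2)
  # singleton: identical to the base translated to the vertex
  g1 <- grid_points(base, grid_vertices("explicit",
                                        vertices = rbind(c(10, 20))))
  xs <- seq(5, 25, by = 0.5)
  expect_equal(shape_membership(g1, xs, rep(20, length(xs))),
               shape_membership(base, xs - 10, rep(0, length(xs))))
  # overlapping copies combine by maximum
  soft <- shape_spec("disc", center_x = 0, center_y = 0, radius = 2,
                     edge_width = 2)
  g2 <- grid_points(soft, grid_vertices("explicit",
                                        vertices = rbind(c(0, 0), c(2, 0))))
  m2 <- shape_membership(g2, 1, 0)
  expect_equal(m2, pmax(shape_membership(soft, 1, 0),
                        shape_membership(soft, -1, 0)))
  expect_equal(nrow(grid_points(base, rows = 2, cols = 2,
                                layout = "rectangular")$vertices), 4)
})
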