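test_that("field geometry validates and exposes pixel centers", {
  geo <- field_geometry(4, 3, frame_rate_hz = 60, um_per_px = 2)
  cc <- pixel_centers(geo)
  expect_equal(dim(cc$x), c(3, 4))
  expect_equal(cc$x[1, ], c(1, 3, 5, 7))   # (j - 0.5) * um_per_px
  expect_equal(cc$y[, 1], c(1, 3, 5))
  expect_error(field_geometry(0, 4))
  expect_error(field_geometry(4, 4, frame_rate_hz = 0))
})

test_that("a constant primer renders to a constant frame at any t", {
  geo <- field_geometry(16, 12)
  st <- gray_stimulus(0.5, frames = 10)
  ctx <- render_context(geo)
  for (t in c(0, 3, 9))
    expect_equal(render_frame(st, t, ctx), const_frame(geo, 0.5))
  expect_error(render_frame(st, 10, ctx), "out of range")
  expect_error(render_frame(st, -1, ctx), "out of range")
})

test_that("single-primer rendering equals direct pointwise evaluation", {
  geo <- field_geometry(24, 24)
  st <- stimulus(list(component("primer", "disc",
                                list(center_x = 12, center_y = 12,
                                     radius = 6, edge_width = 3,
                                     fill_color = 0.9,
                                     background_color = 0.1))), 1)
  got <- render_frame(st, 0, render_context(geo))
  cc <- pixel_centers(geo)
  m <- shape_membership(shape_spec("disc", 12, 12, radius = 6,
                                   edge_width = 3), cc$x, cc$y)
  for (ch in 1:3)
    expect_equal(got[, , ch], m * 0.9 + (1 - m) * 0.1)
})

test_that("identity warp and unit modulation change no pixel", {
  geo <- field_geometry(20, 20)
  base <- stimulus(list(component("primer", "sine_grating",
                                  list(spatial_frequency = 0.1))), 4)
  decorated <- stimulus(list(component("primer", "sine_grating",
                                       list(spatial_frequency = 0.1)),
                             component("warp", "identity"),
                             component("modulation", "constant",
                                       list(value = 1)),
                             component("motion", "static")), 4)
  expect_identical(render_frame(base, 2, render_context(geo)),
                   render_frame(decorated, 2, render_context(geo)))
})

test_that("a DoG-filtered homogeneous region is zero before renorming", {
  geo <- field_geometry(48, 48)
  st <- stimulus(list(component("primer", "disc",
                                list(radius = 18, fill_color = 0.8,
                                     background_color = 0.8)),
                      component("spatial_filter", "dog",
                                list(sigma_center = 1,
                                     sigma_surround = 2))), 1)
  fr <- render_frame(st, 0, render_context(geo))
  # disc fill equals background: the whole field is homogeneous, so the
  # zero-integral filter nulls the interior (borders feel the zero padding)
  expect_lt(max(abs(fr[10:38, 10:38, ])), 1e-12)
})

test_that("same stimulus and seed render bit-identical frame stacks", {
  geo <- field_geometry(24, 24)
  build <- function() stimulus(list(
    component("prng", "xorshift128", list(rows = 12, cols = 12)),
    component("primer", "checkerboard", list(mode = "grayscale")),
    component("spatial_filter", "gaussian", list(sigma = 1)),
    component("temporal_filter", "exponential", list(length = 5, a = 0.6)),
    component("tonemap", "renorm")), 4)
  render_all <- function() {
    ctx <- render_context(geo, seed = 99)
    lapply(0:3, function(t) render_frame(build(), t, ctx))
  }
  expect_identical(render_all(), render_all())
})

test_that("stateful stimuli must be rendered sequentially", {
  geo <- field_geometry(8, 8)
  st <- stimulus(list(component("prng", "xorshift128",
                                list(rows = 4, cols = 4)),
                      component("primer", "checkerboard")), 5)
  ctx <- render_context(geo, seed = 1)
  render_frame(st, 0, ctx)
  expect_error(render_frame(st, 3, ctx), "sequentially")
})

test_that("mixing interpolates foreground and background under the mask", {
  geo <- field_geometry(6, 6)
  fg <- const_frame(geo, 1)
  bg <- const_frame(geo, 0)
  expect_equal(compose_mix(fg, bg, matrix(1, 6, 6)), fg)
  expect_equal(compose_mix(fg, bg, matrix(0, 6, 6)), bg)
  expect_equal(compose_mix(fg, bg, matrix(0.25, 6, 6)),
               const_frame(geo, 0.25))
  expect_error(compose_mix(fg, const_frame(field_geometry(5, 5), 0),
                           matrix(1, 6, 6)), "mismatch")
  expect_error(compose_mix(fg, bg, matrix(1.5, 6, 6)), "\\[0, 1\\]")
})

test_that("crossfade ramps the mask linearly from a to b", {
  geo <- field_geometry(8, 8)
  a <- component("primer", "fullfield", list(intensity = 0))
  b <- component("primer", "fullfield", list(intensity = 1))
  # duration 2: endpoints only
  cf2 <- crossfade(a, b, 2)
  expect_equal(render_frame(cf2, 0, render_context(geo)),
               const_frame(geo, 0))
  expect_equal(render_frame(cf2, 1, render_context(geo)),
               const_frame(geo, 1))
  # duration 3: midpoint frame is the average
  cf3 <- crossfade(a, b, 3)
  expect_equal(render_frame(cf3, 1, render_context(geo)),
               const_frame(geo, 0.5))
  # duration 1: the single frame is pure b
  cf1 <- crossfade(a, b, 1)
  expect_equal(render_frame(cf1, 0, render_context(geo)),
               const_frame(geo, 1))
  expect_error(crossfade(a, b, 0))
})

test_that("post-processing stages run in their listed order", {
  geo <- field_geometry(24, 24)
  mk <- function(first, second) stimulus(list(
    component("primer", "sine_grating", list(spatial_frequency = 0.1)),
    component(first[[1]], first[[2]], first[[3]]),
    component(second[[1]], second[[2]], second[[3]])), 1)
  dog <- list("spatial_filter", "dog",
              list(sigma_center = 1, sigma_surround = 2))
  str <- list("tonemap", "stretch", list(lo = 0.25, hi = 0.75))
  f_ds <- render_frame(mk(dog, str), 0, render_context(geo))
  f_sd <- render_frame(mk(str, dog), 0, render_context(geo))
  expect_gt(max(abs(f_ds - f_sd)), 1e-3)   # order matters
  # golden: listed order equals the hand-built pipeline
  base <- render_frame(stimulus(list(component("primer", "sine_grating",
                                               list(spatial_frequency = 0.1))),
                                1), 0, render_context(geo))
  k <- make_spatial_kernel("dog", sigma_center = 1, sigma_surround = 2)
  manual <- tone_map(convolve_direct(base, k),
                     tonemap_spec("stretch", lo = 0.25, hi = 0.75))
  expect_equal(f_ds, manual, tolerance = 1e-12)
})

test_that("component validation rejects unknown names and parameters", {
  expect_error(component("primer", "no_such_shape"), "unknown primer")
  expect_error(component("primer", "disc", list(radim = 3)),
               "unknown parameter")
  expect_error(component("composition", "mix", list(foreground = 1)),
               "missing required")
  expect_error(stimulus(list(component("primer", "fullfield"),
                             component("gamma", "power"),
                             component("gamma", "power")), 2),
               "at most one gamma")
  expect_error(stimulus(list(component("motion", "linear",
                                       list(velocity_x = 1))), 2),
               "at least one primer")
})

test_that("warped checkerboards and mixing compose into masked noise", {
  geo <- field_geometry(32, 32)
  st <- stimulus(list(
    component("prng", "xorshift128", list(rows = 16, cols = 16)),
    component("primer", "checkerboard"),
    component("primer", "fullfield", list(intensity = 0.5)),
    component("primer", "annulus",
              list(inner_radius = 5, outer_radius = 12,
                   fill_color = 1, background_color = 0)),
    component("composition", "mix",
              list(foreground = 1, background = 2, mask = 3))), 2)
  ctx <- render_context(geo, seed = 5)
  fr <- render_frame(st, 0, ctx)
  # outside the annulus: the gray background; inside: binary noise
  expect_equal(fr[16, 2, 1], 0.5)
  inside <- as.numeric(fr[16, 22:26, 1])   # 5 < r < 12 from the center
  expect_true(all(inside %in% c(0, 1)))
})
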