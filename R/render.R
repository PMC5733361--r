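#' Stimulus specification
#'
#' A stimulus is an ordered list of [component()] specs rendered for a fixed
#' number of frames.  Primers create image layers; motion, modulation and
#' warp components decorate the most recently listed primer; a `mix`
#' composition combines three primers in the foreground/mask/background
#' template; post-processing components (spatial filter, temporal filter,
#' tone map, gamma) apply to the composed image in their listed order.
#'
#' @param components list of [component()] specs.
#' @param duration_frames number of frames (>= 1).
#' @param label a short identifying name.
#' @return object of class `stimulus_spec`.
#' @examples
#' stim <- stimulus(list(component("primer", "fullfield",
#'                                 list(intensity = 0.5))), 60, "gray")
#' @export
stimulus <- function(components, duration_frames, label = "stimulus") {
  stopifnot(.is_count(duration_frames), duration_frames >= 1)
  if (inherits(components, "component_spec")) components <- list(components)
  if (!length(components)) stop("stimulus needs at least one component")
  if (!all(vapply(components, inherits, TRUE, "component_spec")))
    stop("components must be component_spec objects")
  types <- vapply(components, `[[`, "", "sbc_type")
  if (sum(types == "temporal_filter") > 1)
    stop("at most one temporal_filter per stimulus")
  if (sum(types == "gamma") > 1) stop("at most one gamma per stimulus")
  if (sum(types == "composition") > 1)
    stop("at most one composition per stimulus")
  if (!any(types == "primer")) stop("stimulus needs at least one primer")
  structure(list(components = components,
                 duration_frames = as.integer(duration_frames),
                 label = label),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec> '%s': %d frames, %d components\n", x$label,
              x$duration_frames, length(x$components)))
  invisible(x)
}

#' Per-stimulus render context
#'
#' The context is the single mutable carrier across the frames of one
#' stimulus: it owns the PRNG stream state, the temporal-filter state
#' (ring buffer or LTI state), optional pre-measured global statistics for
#' static tone mapping, and the frame cursor.  Stateful stimuli must be
#' rendered sequentially from frame 0 with one `render_frame()` call per
#' frame.
#'
#' @param geometry a [field_geometry()].
#' @param seed global seed used by components that do not carry their own.
#' @param global_stats optional [measure_histogram()] report for static
#'   (non-dynamic) tone mapping.
#' @param record_randoms keep every generated random grid in
#'   `ctx$random_log` for later [export_randoms()].
#' @return an environment of class `render_context`.
#' @export
render_context <- function(geometry, seed = 1, global_stats = NULL,
                           record_randoms = FALSE) {
  stopifnot(inherits(geometry, "field_geometry"))
  ctx <- new.env(parent = emptyenv())
  ctx$geometry <- geometry
  ctx$seed <- seed
  ctx$global_stats <- global_stats
  ctx$record_randoms <- isTRUE(record_randoms)
  ctx$random_log <- list()
  ctx$cursor <- 0L
  ctx$plan <- NULL
  class(ctx) <- c("render_context", "environment")
  ctx
}

#' Per-pixel linear mixing of two frames under a mask
#'
#' `out = mask * foreground + (1 - mask) * background`, per pixel and per
#' channel — the foreground/mask/background template that covers most
#' masked stimuli.
#'
#' @param foreground,background frames of identical geometry.
#' @param mask interpolation weights in `[0, 1]`: a matrix (shared across
#'   channels) or a frame.
#' @return mixed frame.
#' @export
compose_mix <- function(foreground, background, mask) {
  .check_frame(foreground)
  if (!identical(dim(foreground), dim(background)))
    stop("foreground/background geometry mismatch")
  md <- if (is.matrix(mask)) dim(mask) else dim(mask)[1:2]
  if (!identical(md, dim(foreground)[1:2]))
    stop("mask geometry mismatch")
  if (min(mask) < 0 || max(mask) > 1) stop("mask values must be in [0, 1]")
  if (is.matrix(mask)) mask <- .gray_frame(mask)
  mask * foreground + (1 - mask) * background
}

#' Cross-fade between two primers
#'
#' Builds a stimulus that fades from primer `a` to primer `b` over the given
#' duration: the mask is a fullfield primer under linear modulation rising
#' 0 to 1, with the ramp convention `mask(t) = t / (duration_frames - 1)`
#' (and `mask == 1` for a single frame).  Frame 0 therefore shows pure `a`
#' and the final frame pure `b`.
#'
#' @param primer_a,primer_b primer [component()] specs.
#' @param duration_frames fade length in frames (>= 1).
#' @return a [stimulus()].
#' @export
crossfade <- function(primer_a, primer_b, duration_frames) {
  stopifnot(inherits(primer_a, "component_spec"),
            inherits(primer_b, "component_spec"),
            primer_a$sbc_type == "primer", primer_b$sbc_type == "primer",
            .is_count(duration_frames), duration_frames >= 1)
  mask_mod <- if (duration_frames == 1)
    component("modulation", "constant", list(value = 1))
  else
    component("modulation", "linear",
              list(start = 0, end = 1,
                   duration_frames = duration_frames))
  stimulus(list(primer_a, primer_b,
                component("primer", "fullfield", list(intensity = 1)),
                mask_mod,
                component("composition", "mix",
                          list(foreground = 2L, background = 1L,
                               mask = 3L))),
           duration_frames, label = "crossfade")
}

#' Render one frame of a stimulus
#'
#' Runs the per-frame workflow: prerequisites (random-grid advance), core
#' rendering (primers composed under motion/modulation/warp, then mixing),
#' and post-processing stages in their listed order (spatial filter,
#' temporal filter, tone map, gamma compensation).  The context's PRNG and
#' temporal state advance exactly once per call, so stateful stimuli must be
#' rendered with consecutive `t_frame` values starting at 0.
#'
#' @param stim a [stimulus()].
#' @param t_frame frame index, `0 <= t_frame < duration_frames`.
#' @param ctx a [render_context()].
#' @param .stop_before internal: run only post stages with position smaller
#'   than this (used for global-measurement prepasses).
#' @return the rendered `H x W x 3` frame.
#' @export
render_frame <- function(stim, t_frame, ctx, .stop_before = Inf) {
  stopifnot(inherits(stim, "stimulus_spec"),
            inherits(ctx, "render_context"))
  if (!(.is_count(t_frame) && t_frame >= 0 &&
        t_frame < stim$duration_frames))
    stop("t_frame out of range [0, ", stim$duration_frames - 1, "]")
  if (is.null(ctx$plan) || !identical(ctx$stim_label_cache, list(stim))) {
    ctx$plan <- .compile_stimulus(stim, ctx$geometry, ctx$seed)
    ctx$stim_label_cache <- list(stim)
    ctx$cursor <- 0L
    .init_states(ctx)
  }
  plan <- ctx$plan
  stateful <- !is.null(plan$prng) || !is.null(plan$temporal)
  if (stateful && t_frame != ctx$cursor)
    stop("stateful stimulus must be rendered sequentially; expected frame ",
         ctx$cursor, ", got ", t_frame)
  ctx$cursor <- t_frame + 1L
  t_s <- t_frame / ctx$geometry$frame_rate_hz

  # --- prerequisites: advance random grids ---------------------------------
  if (!is.null(plan$prng)) .advance_prng(ctx, t_frame)

  # --- core rendering ------------------------------------------------------
  frame <- tryCatch(.render_core(plan, t_frame, t_s, ctx),
                    error = function(e)
                      stop("core rendering failed: ", conditionMessage(e),
                           call. = FALSE))
  # --- post processing, in listed order ------------------------------------
  for (i in seq_along(plan$post)) {
    if (i >= .stop_before) break
    st <- plan$post[[i]]
    frame <- tryCatch(.apply_post_stage(st, frame, ctx),
                      error = function(e)
                        stop("stage ", st$comp$sbc_type, "/", st$comp$name,
                             " failed: ", conditionMessage(e),
                             call. = FALSE))
  }
  frame
}

# ---- compilation -----------------------------------------------------------

.compile_stimulus <- function(stim, geometry, global_seed) {
  layers <- list()
  prng <- NULL
  composition <- NULL
  post <- list()
  need_layer <- function(what) {
    if (!length(layers))
      stop(what, " component must follow a primer")
  }
  for (comp in stim$components) {
    switch(comp$sbc_type,
      primer = {
        layers[[length(layers) + 1L]] <-
          list(primer = comp, motion = NULL, shake = NULL,
               modulation = NULL, warp = NULL)
      },
      motion = {
        need_layer("motion")
        i <- length(layers)
        if (comp$name == "shake") {
          layers[[i]]$shake <- comp
        } else {
          if (!is.null(layers[[i]]$motion))
            stop("layer already has a motion component")
          layers[[i]]$motion <- comp
        }
      },
      modulation = {
        need_layer("modulation")
        layers[[length(layers)]]$modulation <- comp
      },
      warp = {
        need_layer("warp")
        layers[[length(layers)]]$warp <- comp
      },
      prng = {
        if (!is.null(prng)) stop("at most one prng component")
        prng <- comp
      },
      composition = composition <- comp,
      # post stages keep their listed order
      spatial_filter = ,
      temporal_filter = ,
      tonemap = ,
      gamma = post[[length(post) + 1L]] <- list(comp = comp)
    )
  }
  dur_s <- stim$duration_frames / geometry$frame_rate_hz
  layers <- lapply(layers, .compile_layer, geometry = geometry,
                   global_seed = global_seed, dur_s = dur_s,
                   n_frames = stim$duration_frames)
  uses_cb <- any(vapply(layers, function(l) l$kind == "checkerboard", TRUE))
  if (uses_cb && is.null(prng))
    stop("checkerboard primers require a prng component")
  if (!is.null(prng)) {
    p <- prng$params
    if (is.null(p$seed)) p$seed <- global_seed
    if (is.null(p$streams)) {
      color_cb <- any(vapply(layers, function(l)
        l$kind == "checkerboard" && identical(l$comp$params$mode, "color"),
        TRUE))
      p$streams <- if (color_cb) 3L else 1L
    }
    if (!p$update %in% c("refresh", "shift"))
      stop("prng update must be 'refresh' or 'shift'")
    prng <- list(comp = prng, params = p)
  }
  if (!is.null(composition)) {
    idx <- unlist(composition$params[c("foreground", "background", "mask")])
    if (any(idx < 1 | idx > length(layers)))
      stop("composition references a non-existent primer")
  }
  temporal <- NULL
  gamma_lut <- NULL
  for (i in seq_along(post)) {
    comp <- post[[i]]$comp
    if (comp$sbc_type == "spatial_filter")
      post[[i]]$kernel <- .build_spatial(comp)
    if (comp$sbc_type == "temporal_filter") {
      temporal <- .build_temporal(comp, geometry)
      post[[i]]$temporal <- TRUE
    }
    if (comp$sbc_type == "tonemap")
      post[[i]]$spec <- .build_tonemap(comp)
    if (comp$sbc_type == "gamma") {
      gamma_lut <- .build_gamma(comp)
      post[[i]]$lut <- gamma_lut
    }
  }
  list(layers = layers, prng = prng, composition = composition,
       post = post, temporal = temporal, gamma_lut = gamma_lut,
       duration_frames = stim$duration_frames)
}

.field_center <- function(geometry) {
  c(geometry$width_px * geometry$um_per_px / 2,
    geometry$height_px * geometry$um_per_px / 2)
}

.compile_layer <- function(layer, geometry, global_seed, dur_s, n_frames) {
  comp <- layer$primer
  p <- comp$params
  ctr <- .field_center(geometry)
  cx <- p$center_x %||% ctr[1]
  cy <- p$center_y %||% ctr[2]
  out <- list(comp = comp, kind = comp$name)
  shape_kinds <- c("disc", "annulus", "rectangle", "polygon",
                   "bezier_region")
  if (comp$name %in% shape_kinds) {
    out$shape <- shape_spec(comp$name, center_x = cx, center_y = cy,
                            radius = p$radius %||% 1,
                            inner_radius = p$inner_radius %||% 0.5,
                            outer_radius = p$outer_radius %||% 1,
                            width = p$width %||% 1,
                            height = p$height %||% 1,
                            angle = p$angle %||% 0,
                            vertices = p$vertices,
                            control_points = p$control_points,
                            edge_width = p$edge_width,
                            fill_color = p$fill_color,
                            background_color = p$background_color)
    out$kind <- "shape"
  } else if (comp$name == "grid_points") {
    base <- component("primer", p$base_name, p$base_params)
    if (!base$name %in% shape_kinds)
      stop("grid_points base must be a shape primer")
    bp <- base$params
    bshape <- shape_spec(base$name,
                         center_x = bp$center_x %||% 0,
                         center_y = bp$center_y %||% 0,
                         radius = bp$radius %||% 1,
                         inner_radius = bp$inner_radius %||% 0.5,
                         outer_radius = bp$outer_radius %||% 1,
                         width = bp$width %||% 1, height = bp$height %||% 1,
                         angle = bp$angle %||% 0, vertices = bp$vertices,
                         control_points = bp$control_points,
                         edge_width = bp$edge_width,
                         fill_color = bp$fill_color,
                         background_color = bp$background_color)
    verts <- if (!is.null(p$vertices))
      grid_vertices("explicit", vertices = p$vertices, labels = p$labels)
    else
      grid_vertices(p$layout, rows = p$rows, cols = p$cols,
                    spacing = p$spacing, origin_x = p$origin_x,
                    origin_y = p$origin_y, n = p$n,
                    extent_x = p$extent_x %||%
                      (geometry$width_px * geometry$um_per_px),
                    extent_y = p$extent_y %||%
                      (geometry$height_px * geometry$um_per_px),
                    seed = p$seed %||% global_seed, labels = p$labels)
    out$shape <- grid_points(bshape, verts)
    out$kind <- "shape"
  } else if (comp$name %in% c("sine_grating", "square_grating",
                              "campbell_robson")) {
    out$pattern <- pattern_spec(comp$name,
                                spatial_frequency = p$spatial_frequency %||% 0.05,
                                orientation = p$orientation %||% 0,
                                phase = p$phase %||% 0,
                                mean = p$mean %||% 0.5,
                                amplitude = p$amplitude %||% 0.5,
                                freq_start = p$freq_start %||% 0.005,
                                freq_end = p$freq_end %||% 0.25,
                                contrast_start = p$contrast_start %||% 1,
                                contrast_end = p$contrast_end %||% 0)
    out$kind <- "pattern"
  } else if (comp$name == "image") {
    img <- p$image %||% p$path
    if (is.null(img)) stop("image primer needs 'path' or 'image'")
    out$pattern <- pattern_spec("image", image = img)
    out$kind <- "pattern"
  } else if (comp$name == "fullfield") {
    out$color <- if (!is.null(p$color)) .as_rgb(p$color)
                 else .as_rgb(p$intensity)
  } else if (comp$name == "checkerboard") {
    if (!p$mode %in% c("binary", "grayscale", "color"))
      stop("checkerboard mode must be binary, grayscale or color")
    out$low <- .as_rgb(p$low); out$high <- .as_rgb(p$high)
  }
  if (!is.null(layer$motion)) {
    mp <- layer$motion$params
    out$motion <- switch(layer$motion$name,
      static = motion_spec("static"),
      linear = {
        vel <- if (!is.null(mp$velocity_x) || !is.null(mp$velocity_y))
          c(mp$velocity_x %||% 0, mp$velocity_y %||% 0) else NULL
        motion_spec("linear", velocity = vel,
                    crossing_time = mp$crossing_time,
                    direction = mp$direction %||% 0)
      },
      path = motion_spec("path", control_points = mp$control_points))
    out$shape_extent <- mp$shape_extent %||% 0
  }
  if (!is.null(layer$shake)) {
    sp <- layer$shake$params
    out$shake <- shake_offsets(sp$seed %||% 1, n_frames, sp$amplitude)
  }
  if (!is.null(layer$modulation)) {
    md <- layer$modulation$params
    nm <- layer$modulation$name
    if (nm == "linear" && !is.null(md$duration_frames)) {
      md$duration_s <- max(md$duration_frames - 1, 1e-9) /
        (n_frames / dur_s)
    }
    out$modulation <- switch(nm,
      constant = modulation_spec("constant", value = md$value),
      linear = modulation_spec("linear", start = md$start, end = md$end,
                               duration_s = md$duration_s %||% dur_s),
      sine = ,
      square = modulation_spec(nm, mean = md$mean,
                               amplitude_start = md$amplitude_start,
                               amplitude_end = md$amplitude_end,
                               frequency_start = md$frequency_start,
                               frequency_end = md$frequency_end,
                               phase = md$phase,
                               duration_s = md$duration_s %||% dur_s),
      multi_component = modulation_spec("multi_component",
                                        components = md$components))
  }
  if (!is.null(layer$warp)) {
    wp <- layer$warp$params
    out$warp <- switch(layer$warp$name,
      identity = warp_spec("identity"),
      "repeat" = warp_spec("repeat", period_x = wp$period_x,
                           period_y = wp$period_y),
      polar = warp_spec("polar", center_x = wp$center_x %||% ctr[1],
                        center_y = wp$center_y %||% ctr[2],
                        angle_scale = wp$angle_scale),
      pinch_twist = warp_spec("pinch_twist",
                              center_x = wp$center_x %||% ctr[1],
                              center_y = wp$center_y %||% ctr[2],
                              radius = wp$radius %||% (min(ctr) ),
                              strength = wp$strength, twist = wp$twist),
      custom = {
        tab <- wp$table
        if (!is.null(wp$table_path))
          tab <- read.table(wp$table_path, header = TRUE)
        warp_spec("custom", fn = wp$fn, table = tab)
      })
  }
  out
}

.build_spatial <- function(comp) {
  p <- comp$params
  switch(comp$name,
    median = list(median = TRUE, window = p$window),
    gaussian = list(kernel = make_spatial_kernel("gaussian",
                                                 sigma = p$sigma),
                    method = p$method),
    dog = list(kernel = make_spatial_kernel("dog",
                                            sigma_center = p$sigma_center,
                                            sigma_surround = p$sigma_surround,
                                            gain_center = p$gain_center,
                                            gain_surround = p$gain_surround),
               method = p$method),
    gabor = list(kernel = make_spatial_kernel("gabor", sigma = p$sigma,
                                              frequency = p$frequency,
                                              orientation = p$orientation,
                                              phase = p$phase,
                                              gain = p$gain),
                 method = p$method),
    freq_lowpass = list(kernel = make_spatial_kernel("freq_lowpass",
                                                     cutoff = p$cutoff),
                        method = "fft"),
    freq_highpass = list(kernel = make_spatial_kernel("freq_highpass",
                                                      cutoff = p$cutoff),
                         method = "fft"),
    freq_bandpass = list(kernel = make_spatial_kernel("freq_bandpass",
                                                      low = p$low,
                                                      high = p$high),
                         method = "fft"),
    freq_custom = list(kernel = make_spatial_kernel("freq_custom",
                                                    transfer = p$transfer),
                       method = "fft"))
}

.build_temporal <- function(comp, geometry) {
  p <- comp$params
  if (comp$name == "lti") {
    sys <- lti_system(p$poles, p$coefs, p$direct %||% 0)
    list(kind = "lti", system = sys, geometry = geometry)
  } else {
    kern <- switch(comp$name,
      rectangular = ,
      triangular = ,
      hamming = ,
      hann = make_temporal_kernel(comp$name, length = p$length),
      exponential = make_temporal_kernel("exponential", length = p$length,
                                         a = p$a),
      cell_dog = make_temporal_kernel("cell_dog", length = p$length,
                                      mu1 = p$mu1, sigma1 = p$sigma1,
                                      w1 = p$w1, mu2 = p$mu2,
                                      sigma2 = p$sigma2, w2 = p$w2))
    list(kind = "convolve", kernel = kern,
         prestimulus = p$prestimulus %||% "zero")
  }
}

.build_tonemap <- function(comp) {
  p <- comp$params
  switch(comp$name,
    stretch = tonemap_spec("stretch", lo = p$lo, hi = p$hi,
                           dynamic = p$dynamic %||% TRUE),
    sigmoid = tonemap_spec("sigmoid", center = p$center, slope = p$slope),
    equalize = tonemap_spec("equalize", n_bins = p$n_bins,
                            dynamic = p$dynamic %||% TRUE),
    renorm = tonemap_spec("renorm", dynamic = p$dynamic %||% TRUE))
}

.build_gamma <- function(comp) {
  p <- comp$params
  if (comp$name == "power") {
    v <- seq(0, 1, length.out = 33)
    gamma_build(cbind(v, v^p$exponent), n_entries = p$n_entries)
  } else {
    s <- p$samples
    if (!is.null(p$samples_path)) s <- as.matrix(read.table(p$samples_path))
    if (is.null(s)) stop("gamma lut needs 'samples' or 'samples_path'")
    gamma_build(s, n_entries = p$n_entries)
  }
}

# ---- per-frame state -------------------------------------------------------

.init_states <- function(ctx) {
  plan <- ctx$plan
  if (!is.null(plan$prng)) {
    p <- plan$prng$params
    ctx$prng_states <- lapply(seq_len(p$streams) - 1L,
                              function(k) seed_state(p$seed + k))
    ctx$prng_grids <- NULL
  }
  if (!is.null(plan$temporal)) {
    tp <- plan$temporal
    ctx$temporal <- if (tp$kind == "lti")
      lti_state(tp$system, ctx$geometry)
    else temporal_state(tp$kernel, tp$prestimulus)
  }
  ctx$random_log <- list()
}

.advance_prng <- function(ctx, t_frame) {
  p <- ctx$plan$prng$params
  for (k in seq_len(p$streams)) {
    if (p$update == "refresh" || is.null(ctx$prng_grids)) {
      if (is.null(ctx$prng_grids)) ctx$prng_grids <- vector("list", p$streams)
      r <- fill_grid(ctx$prng_states[[k]], p$rows, p$cols)
    } else {
      r <- shift_grid(ctx$prng_grids[[k]], p$dx, p$dy, ctx$prng_states[[k]])
    }
    ctx$prng_grids[[k]] <- r$grid
    ctx$prng_states[[k]] <- r$state
  }
  if (ctx$record_randoms)
    ctx$random_log[[length(ctx$random_log) + 1L]] <-
      if (p$streams == 1L) ctx$prng_grids[[1]] else ctx$prng_grids
}

# ---- core rendering --------------------------------------------------------

.render_core <- function(plan, t_frame, t_s, ctx) {
  geometry <- ctx$geometry
  if (is.null(ctx$coords)) ctx$coords <- pixel_centers(geometry)
  if (is.null(plan$composition)) {
    canvas <- NULL
    for (l in plan$layers)
      canvas <- .blend_layer(canvas, l, t_frame, t_s, ctx)
    canvas
  } else {
    idx <- plan$composition$params
    vals <- lapply(plan$layers, function(l) NULL)
    for (i in unique(unlist(idx[c("foreground", "background", "mask")])))
      vals[[i]] <- .blend_layer(NULL, plan$layers[[i]], t_frame, t_s, ctx)
    mask <- vals[[idx$mask]]
    mask_m <- (mask[, , 1] + mask[, , 2] + mask[, , 3]) / 3
    compose_mix(vals[[idx$foreground]], vals[[idx$background]], mask_m)
  }
}

# Blend one layer over the canvas (NULL canvas: the layer's own background
# fills first).  Shapes with finite support are evaluated only inside their
# (motion-shifted) bounding box, which keeps many-shape stimuli cheap.
.blend_layer <- function(canvas, l, t_frame, t_s, ctx) {
  geometry <- ctx$geometry
  off <- c(0, 0)
  if (!is.null(l$motion))
    off <- motion_offset(l$motion, t_s, geometry, l$shape_extent %||% 0)
  if (!is.null(l$shake)) off <- off + l$shake[t_frame + 1L, ]
  m <- if (!is.null(l$modulation)) modulation_value(l$modulation, t_s) else 1

  if (l$kind == "shape" && is.null(l$warp)) {
    bg <- l$shape$background_color
    if (is.null(canvas)) canvas <- new_frame(geometry, bg)
    bb <- .shape_bbox(l$shape, off, geometry)
    if (is.null(bb)) return(canvas)      # fully outside the field
    xs <- ctx$coords$x[bb$ri, bb$rj, drop = FALSE]
    ys <- ctx$coords$y[bb$ri, bb$rj, drop = FALSE]
    a <- shape_membership(l$shape, xs - off[1], ys - off[2])
    fill <- l$shape$fill_color * m
    for (ch in 1:3)
      canvas[bb$ri, bb$rj, ch] <- a * fill[ch] +
        (1 - a) * canvas[bb$ri, bb$rj, ch]
    return(canvas)
  }

  xs <- ctx$coords$x; ys <- ctx$coords$y
  if (!is.null(l$warp)) {
    w <- warp_coords(l$warp, xs, ys)
    xs <- w$x; ys <- w$y
  }
  xs <- xs - off[1]; ys <- ys - off[2]
  val <- switch(l$kind,
    fullfield = new_frame(geometry, l$color * m),
    shape = {
      a <- shape_membership(l$shape, xs, ys)
      fill <- l$shape$fill_color * m
      bg <- l$shape$background_color
      out <- array(0, dim = c(dim(a), 3))
      base <- if (is.null(canvas)) lapply(bg, function(b)
        matrix(b, nrow(a), ncol(a))) else
        lapply(1:3, function(ch) canvas[, , ch])
      for (ch in 1:3) out[, , ch] <- a * fill[ch] + (1 - a) * base[[ch]]
      return(out)
    },
    pattern = eval_pattern(l$pattern, xs, ys, t_s, geometry) * m,
    checkerboard = .eval_checkerboard(l, xs, ys, ctx) * m,
    stop("unhandled primer kind '", l$kind, "'"))
  val
}

# Pointwise checkerboard lookup: the grid spans the field; warped or shifted
# coordinates index into it with clamping.
.eval_checkerboard <- function(l, xs, ys, ctx) {
  if (is.null(ctx$prng_grids)) stop("checkerboard has no random grids")
  grids <- ctx$prng_grids
  p <- ctx$plan$prng$params
  geometry <- ctx$geometry
  cw <- geometry$width_px * geometry$um_per_px / p$cols
  chh <- geometry$height_px * geometry$um_per_px / p$rows
  jj <- pmin(pmax(floor(xs / cw) + 1, 1), p$cols)
  ii <- pmin(pmax(floor(ys / chh) + 1, 1), p$rows)
  mode <- l$comp$params$mode
  out <- array(0, dim = c(nrow(xs), ncol(xs), 3))
  pick <- function(g) {
    u <- matrix(unclass(g)[cbind(c(ii), c(jj))] / 2^32, nrow(xs), ncol(xs))
    u
  }
  if (mode == "color") {
    if (length(grids) < 3L) stop("color checkerboard needs 3 grids")
    for (ch in 1:3) {
      u <- pick(grids[[ch]])
      out[, , ch] <- l$low[ch] + u * (l$high[ch] - l$low[ch])
    }
  } else {
    u <- pick(grids[[1]])
    if (mode == "binary") {
      b <- u >= 0.5
      for (ch in 1:3) out[, , ch] <- ifelse(b, l$high[ch], l$low[ch])
    } else {
      for (ch in 1:3) out[, , ch] <- l$low[ch] + u * (l$high[ch] - l$low[ch])
    }
  }
  out
}

# Bounding box (row/col index ranges) of a shape's support, soft edge
# included, after displacement; NULL when it misses the field entirely.
.shape_bbox <- function(shape, off, geometry) {
  if (inherits(shape, "grid_shape")) {
    vb <- shape$vertices
    sub <- .shape_extent_box(shape$base)
    box <- c(min(vb$x) + sub[1], max(vb$x) + sub[2],
             min(vb$y) + sub[3], max(vb$y) + sub[4])
  } else {
    box <- .shape_extent_box(shape)
  }
  if (any(!is.finite(box))) {
    ri <- seq_len(geometry$height_px); rj <- seq_len(geometry$width_px)
    return(list(ri = ri, rj = rj))
  }
  box <- box + c(off[1], off[1], off[2], off[2])
  u <- geometry$um_per_px
  j0 <- max(1L, floor(box[1] / u) + 1L)
  j1 <- min(geometry$width_px, ceiling(box[2] / u))
  i0 <- max(1L, floor(box[3] / u) + 1L)
  i1 <- min(geometry$height_px, ceiling(box[4] / u))
  if (j0 > j1 || i0 > i1) return(NULL)
  list(ri = i0:i1, rj = j0:j1)
}

# (xmin, xmax, ymin, ymax) of the membership support, edge margin included.
.shape_extent_box <- function(s) {
  e <- s$edge_width / 2
  switch(s$kind,
    fullfield = rep(Inf, 4) * c(-1, 1, -1, 1),
    disc = c(s$center_x - s$radius - e, s$center_x + s$radius + e,
             s$center_y - s$radius - e, s$center_y + s$radius + e),
    annulus = c(s$center_x - s$outer_radius - e,
                s$center_x + s$outer_radius + e,
                s$center_y - s$outer_radius - e,
                s$center_y + s$outer_radius + e),
    rectangle = {
      hd <- sqrt(s$width^2 + s$height^2) / 2 + e
      c(s$center_x - hd, s$center_x + hd, s$center_y - hd, s$center_y + hd)
    },
    polygon = ,
    bezier_region = {
      v <- s$vertices
      c(s$center_x + min(v[, 1]) - e, s$center_x + max(v[, 1]) + e,
        s$center_y + min(v[, 2]) - e, s$center_y + max(v[, 2]) + e)
    },
    rep(Inf, 4) * c(-1, 1, -1, 1))
}

.apply_post_stage <- function(st, frame, ctx) {
  comp <- st$comp
  switch(comp$sbc_type,
    spatial_filter = {
      if (isTRUE(st$kernel$median))
        return(median_filter(frame, st$kernel$window))
      k <- st$kernel$kernel
      method <- st$kernel$method %||% "auto"
      if (k$domain == "frequency") return(convolve_fft(frame, k))
      if (method == "direct" ||
          (method == "auto" && max(dim(k$weights)) <= 9))
        convolve_direct(frame, k)
      else convolve_fft(frame, k)
    },
    temporal_filter = {
      r <- if (inherits(ctx$temporal$system, "lti_system"))
        lti_step(ctx$temporal, frame)
      else temporal_convolve(ctx$temporal, frame)
      ctx$temporal <- r$state
      r$frame
    },
    tonemap = {
      spec <- st$spec
      report <- if (spec$dynamic) NULL else {
        if (is.null(ctx$global_stats))
          stop("static tone mapping needs ctx$global_stats ",
               "(run a global measurement prepass)")
        ctx$global_stats
      }
      tone_map(frame, spec, report)
    },
    gamma = gamma_apply(frame, st$lut))
}
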