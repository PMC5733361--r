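#' Motion specification
#'
#' Motions displace a primer across the field as a function of time.
#'
#' * `static`: no displacement.
#' * `linear`: constant velocity.  Either `velocity` (a 2-vector, units per
#'   second) or `crossing_time` is given; with `crossing_time` the speed is
#'   `(field extent along the motion direction + shape_extent) /
#'   crossing_time`, so the shape enters on one side and has fully left on
#'   the other when the time elapses.
#' * `path`: free-form motion interpolated by cubic Hermite segments through
#'   `(time, position, velocity)` control points; times before the first or
#'   after the last control point clamp to the endpoint positions.
#'
#' Random shaking is superimposed separately (see [shake_offsets()]) so that
#' any smooth motion can be decorated with seeded per-frame jitter.
#'
#' @param kind `"static"`, `"linear"` or `"path"`.
#' @param velocity numeric 2-vector `(vx, vy)`, units/second.
#' @param crossing_time seconds for the shape to cross the field (used when
#'   `velocity` is absent; mutually exclusive with it).
#' @param direction motion direction in radians (with `crossing_time`).
#' @param control_points data.frame/matrix with columns
#'   `t, x, y, vx, vy`, strictly increasing in `t`, >= 2 rows.
#' @return object of class `motion_spec`.
#' @export
motion_spec <- function(kind = c("static", "linear", "path"),
                        velocity = NULL, crossing_time = NULL, direction = 0,
                        control_points = NULL) {
  kind <- match.arg(kind)
  if (kind == "linear") {
    if (is.null(velocity) == is.null(crossing_time))
      stop("linear motion needs exactly one of velocity / crossing_time")
    if (!is.null(velocity)) stopifnot(length(velocity) == 2L)
    if (!is.null(crossing_time)) stopifnot(crossing_time > 0)
  }
  if (kind == "path") {
    cp <- as.data.frame(as.matrix(control_points))
    names(cp) <- c("t", "x", "y", "vx", "vy")[seq_len(ncol(cp))]
    if (nrow(cp) < 2L) stop("path needs >= 2 control points")
    if (any(diff(cp$t) <= 0)) stop("control times must strictly increase")
    control_points <- cp
  }
  structure(list(kind = kind, velocity = velocity,
                 crossing_time = crossing_time, direction = direction,
                 control_points = control_points),
            class = "motion_spec")
}

#' Displacement of a motion at time t
#'
#' @param motion a [motion_spec()].
#' @param t time in seconds (>= 0).
#' @param geometry [field_geometry()] (needed to derive speed from
#'   `crossing_time`).
#' @param shape_extent size of the moving shape along the motion direction
#'   (added to the field extent for the crossing rule).
#' @return numeric 2-vector `(dx, dy)`.
#' @export
motion_offset <- function(motion, t, geometry = NULL, shape_extent = 0) {
  stopifnot(inherits(motion, "motion_spec"), t >= 0)
  switch(motion$kind,
    static = c(0, 0),
    linear = {
      v <- motion$velocity
      if (is.null(v)) {
        th <- motion$direction
        ext <- abs(cos(th)) * geometry$width_px * geometry$um_per_px +
          abs(sin(th)) * geometry$height_px * geometry$um_per_px
        speed <- (ext + shape_extent) / motion$crossing_time
        v <- speed * c(cos(th), sin(th))
      }
      v * t
    },
    path = .hermite_path(motion$control_points, t)
  )
}

# Piecewise cubic Hermite through (t, pos, vel) control points.
.hermite_path <- function(cp, t) {
  if (t <= cp$t[1]) return(c(cp$x[1], cp$y[1]))
  n <- nrow(cp)
  if (t >= cp$t[n]) return(c(cp$x[n], cp$y[n]))
  k <- findInterval(t, cp$t)
  h <- cp$t[k + 1] - cp$t[k]
  s <- (t - cp$t[k]) / h
  h00 <- 2 * s^3 - 3 * s^2 + 1
  h10 <- s^3 - 2 * s^2 + s
  h01 <- -2 * s^3 + 3 * s^2
  h11 <- s^3 - s^2
  c(h00 * cp$x[k] + h10 * h * cp$vx[k] + h01 * cp$x[k + 1] +
      h11 * h * cp$vx[k + 1],
    h00 * cp$y[k] + h10 * h * cp$vy[k] + h01 * cp$y[k + 1] +
      h11 * h * cp$vy[k + 1])
}

#' Seeded random shake offsets
#'
#' Per-frame jitter superimposed on a smooth motion: uniform offsets in
#' `[-amplitude, amplitude]^2` drawn from a dedicated xorshift stream (two
#' draws per frame, x then y), independent of any checkerboard noise so that
#' shaking a stimulus never perturbs its random-grid stream.
#'
#' @param seed stream seed.
#' @param n_frames number of frames.
#' @param amplitude jitter half-range (same units as coordinates); 0 gives
#'   exact zeros.
#' @return `n_frames x 2` matrix of offsets.
#' @export
shake_offsets <- function(seed, n_frames, amplitude) {
  stopifnot(.is_count(n_frames), n_frames >= 0, amplitude >= 0)
  if (n_frames == 0) return(matrix(numeric(0), 0, 2))
  if (amplitude == 0) return(matrix(0, n_frames, 2))
  r <- draw_u32(seed_state(seed), 2 * n_frames)
  u <- r$words / 2^32
  matrix((2 * u - 1) * amplitude, ncol = 2, byrow = TRUE)
}

#' Temporal modulation specification
#'
#' Modulations return a scalar in `[0, 1]` as a function of time which
#' multiplies a primer's intensity.
#'
#' * `constant`: fixed value.
#' * `linear`: ramp from `start` to `end` over `duration_s`, clamped after.
#' * `sine`: `mean + a(t) * sin(phi(t) + phase)` with amplitude `a(t)`
#'   interpolated linearly between its initial and final values and
#'   continuous phase `phi(t) = 2*pi * integral of f`, the frequency swept
#'   linearly between its initial and final values (a linear chirp); output
#'   clamped to `[0, 1]`.
#' * `square`: two-level thresholding of the same phase (high for
#'   `sin >= 0`).
#' * `multi_component`: `0.5 + 0.5 * sum(a_i sin(2 pi f_i t + ph_i)) /
#'   sum(a_i)`, i.e. a normalized sum of sinusoids shifted into `[0, 1]`.
#'
#' @param kind modulation kind.
#' @param value constant value.
#' @param start,end linear ramp endpoints.
#' @param mean sine/square offset level.
#' @param amplitude_start,amplitude_end amplitude sweep endpoints.
#' @param frequency_start,frequency_end frequency sweep endpoints, Hz
#'   (>= 0).
#' @param phase phase offset, radians.
#' @param duration_s sweep duration in seconds (amplitude/frequency reach
#'   their final values here; beyond it they hold).
#' @param components for `multi_component`: matrix/data.frame with columns
#'   `frequency, amplitude, phase`.
#' @return object of class `modulation_spec`.
#' @export
modulation_spec <- function(kind = c("constant", "linear", "sine", "square",
                                     "multi_component"),
                            value = 1, start = 0, end = 1,
                            mean = 0.5, amplitude_start = 0.5,
                            amplitude_end = 0.5,
                            frequency_start = 1, frequency_end = 1,
                            phase = 0, duration_s = 1, components = NULL) {
  kind <- match.arg(kind)
  stopifnot(frequency_start >= 0, frequency_end >= 0, duration_s > 0)
  if (kind == "multi_component") {
    cm <- as.data.frame(as.matrix(components))
    names(cm) <- c("frequency", "amplitude", "phase")[seq_len(ncol(cm))]
    if (is.null(cm$phase)) cm$phase <- 0
    stopifnot(nrow(cm) >= 1, all(cm$frequency >= 0), sum(cm$amplitude) > 0)
    components <- cm
  }
  structure(list(kind = kind, value = value, start = start, end = end,
                 mean = mean, amplitude_start = amplitude_start,
                 amplitude_end = amplitude_end,
                 frequency_start = frequency_start,
                 frequency_end = frequency_end, phase = phase,
                 duration_s = duration_s, components = components),
            class = "modulation_spec")
}

#' Modulation value at time t
#'
#' @param mod a [modulation_spec()].
#' @param t time in seconds (vectorized).
#' @return values in `[0, 1]`, same length as `t`.
#' @export
modulation_value <- function(mod, t) {
  stopifnot(inherits(mod, "modulation_spec"), all(t >= 0))
  D <- mod$duration_s
  out <- switch(mod$kind,
    constant = rep(mod$value, length(t)),
    linear = mod$start + (mod$end - mod$start) * pmin(t / D, 1),
    sine = ,
    square = {
      tc <- pmin(t, D)
      f0 <- mod$frequency_start; f1 <- mod$frequency_end
      # continuous-phase linear chirp; frequency holds at f1 past D
      phi <- 2 * pi * (f0 * tc + (f1 - f0) * tc^2 / (2 * D) +
                         f1 * pmax(t - D, 0))
      a <- mod$amplitude_start +
        (mod$amplitude_end - mod$amplitude_start) * pmin(t / D, 1)
      s <- sin(phi + mod$phase)
      if (mod$kind == "sine") mod$mean + a * s
      else mod$mean + a * ifelse(s >= 0, 1, -1)
    },
    multi_component = {
      cm <- mod$components
      s <- 0
      for (i in seq_len(nrow(cm)))
        s <- s + cm$amplitude[i] *
          sin(2 * pi * cm$frequency[i] * t + cm$phase[i])
      0.5 + 0.5 * s / sum(cm$amplitude)
    })
  .clamp01(out)
}

#' Coordinate warp specification
#'
#' Warps remap the coordinates a primer is evaluated at, before motion is
#' applied:
#'
#' * `identity`: no change.
#' * `repeat`: coordinates modulo `(period_x, period_y)` — tiles the primer.
#' * `polar`: `(x, y) -> (r, angle * angle_scale)` about a center, producing
#'   fan/ring versions of Cartesian patterns.
#' * `pinch_twist`: inside radius `R` about the center, the point is rotated
#'   by `twist * (1 - r/R)^2` and its radius rescaled to `(r/R)^strength *
#'   R`; the identity outside, continuous at the rim.
#' * `custom`: a user function `f(x, y) -> list(x, y)`, or a coarse lookup
#'   table (columns `x, y, xp, yp` on a rectangular grid) interpolated
#'   bilinearly.
#'
#' @param kind warp kind.
#' @param period_x,period_y repeat periods (> 0).
#' @param center_x,center_y warp center.
#' @param radius pinch-twist support radius `R` (> 0).
#' @param strength radial exponent (> 0; 1 = no radial change).
#' @param twist maximal rotation at the center, radians.
#' @param angle_scale polar angular scale factor.
#' @param fn custom mapping function.
#' @param table custom lookup table.
#' @return object of class `warp_spec`.
#' @export
warp_spec <- function(kind = c("identity", "repeat", "polar", "pinch_twist",
                               "custom"),
                      period_x = 1, period_y = 1,
                      center_x = 0, center_y = 0,
                      radius = 1, strength = 1, twist = 0, angle_scale = 1,
                      fn = NULL, table = NULL) {
  kind <- match.arg(kind)
  if (kind == "repeat" && (period_x <= 0 || period_y <= 0))
    stop("repeat periods must be positive")
  if (kind == "pinch_twist") stopifnot(radius > 0, strength > 0)
  if (kind == "custom" && is.null(fn) && is.null(table))
    stop("custom warp needs fn or table")
  if (!is.null(table)) {
    table <- as.data.frame(as.matrix(table))
    names(table) <- c("x", "y", "xp", "yp")[seq_len(ncol(table))]
  }
  structure(list(kind = kind, period_x = period_x, period_y = period_y,
                 center_x = center_x, center_y = center_y, radius = radius,
                 strength = strength, twist = twist,
                 angle_scale = angle_scale, fn = fn, table = table),
            class = "warp_spec")
}

#' Apply a warp to coordinates
#'
#' @param warp a [warp_spec()].
#' @param x,y coordinate vectors/matrices.
#' @return list with warped `x` and `y` of the same shape.
#' @export
warp_coords <- function(warp, x, y) {
  stopifnot(inherits(warp, "warp_spec"))
  out <- switch(warp$kind,
    identity = list(x = x, y = y),
    "repeat" = list(x = x %% warp$period_x, y = y %% warp$period_y),
    polar = {
      dx <- x - warp$center_x; dy <- y - warp$center_y
      list(x = sqrt(dx^2 + dy^2),
           y = atan2(dy, dx) * warp$angle_scale)
    },
    pinch_twist = {
      dx <- x - warp$center_x; dy <- y - warp$center_y
      r <- sqrt(dx^2 + dy^2)
      inside <- r < warp$radius & r > 0
      rn <- ifelse(inside, r / warp$radius, 1)
      ang <- warp$twist * (1 - rn)^2
      rr <- ifelse(inside, rn^warp$strength * warp$radius, r)
      ca <- cos(ang); sa <- sin(ang)
      sc <- ifelse(r > 0, rr / r, 1)
      list(x = warp$center_x + sc * (dx * ca - dy * sa),
           y = warp$center_y + sc * (dx * sa + dy * ca))
    },
    custom = {
      if (!is.null(warp$fn)) warp$fn(x, y) else .table_warp(warp$table, x, y)
    })
  if (is.matrix(x)) { dim(out$x) <- dim(x); dim(out$y) <- dim(x) }
  out
}

# Bilinear interpolation of a warp lookup table defined on a rectangular
# grid of (x, y) source points.
.table_warp <- function(tab, x, y) {
  xs <- sort(unique(tab$x)); ys <- sort(unique(tab$y))
  nx <- length(xs); ny <- length(ys)
  if (nx * ny != nrow(tab)) stop("warp table must cover a rectangular grid")
  o <- order(tab$y, tab$x)
  xp <- matrix(tab$xp[o], ny, nx, byrow = TRUE)
  yp <- matrix(tab$yp[o], ny, nx, byrow = TRUE)
  ix <- pmin(pmax(findInterval(x, xs), 1), nx - 1)
  iy <- pmin(pmax(findInterval(y, ys), 1), ny - 1)
  fx <- (x - xs[ix]) / (xs[ix + 1] - xs[ix])
  fy <- (y - ys[iy]) / (ys[iy + 1] - ys[iy])
  fx <- .clamp01(fx); fy <- .clamp01(fy)
  lerp <- function(m) {
    m[cbind(c(iy), c(ix))] * (1 - fx) * (1 - fy) +
      m[cbind(c(iy), c(ix + 1))] * fx * (1 - fy) +
      m[cbind(c(iy + 1), c(ix))] * (1 - fx) * fy +
      m[cbind(c(iy + 1), c(ix + 1))] * fx * fy
  }
  list(x = lerp(xp), y = lerp(yp))
}
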