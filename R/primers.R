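#' Shape specification
#'
#' Shapes are defined implicitly: every pixel center is tested against the
#' shape's signed distance, which yields a membership value in `[0, 1]`.
#' With `edge_width = 0` the membership is hard (1 inside, 0 outside); with
#' `edge_width > 0` it ramps smoothly (a cubic smoothstep of the signed
#' distance) across a band of that total width centered on the contour, which
#' is also the anti-aliasing mechanism of pointwise rendering.
#'
#' @param kind one of `"fullfield"`, `"disc"`, `"annulus"`, `"rectangle"`,
#'   `"polygon"`, `"bezier_region"`.
#' @param center_x,center_y shape center (same units as field coordinates).
#' @param radius disc radius; `inner_radius`/`outer_radius` for an annulus.
#' @param inner_radius,outer_radius annulus radii (`inner < outer`).
#' @param width,height,angle rectangle extents and rotation (radians,
#'   counter-clockwise).
#' @param vertices two-column matrix of polygon vertices (>= 3 rows);
#'   self-intersecting polygons are resolved by the even-odd rule.
#' @param control_points for `bezier_region`: two-column matrix of cubic
#'   Bezier control points, `3k + 1` rows, describing a closed piecewise
#'   curve (the last point is joined back to the first); flattened to a
#'   polygon at a chord tolerance of 0.25 px before testing.
#' @param edge_width softening length (>= 0).
#' @param fill_color,background_color RGB triples or gray scalars.
#' @return object of class `shape_spec`.
#' @export
shape_spec <- function(kind = c("fullfield", "disc", "annulus", "rectangle",
                                "polygon", "bezier_region"),
                       center_x = 0, center_y = 0, radius = 1,
                       inner_radius = 0.5, outer_radius = 1,
                       width = 1, height = 1, angle = 0,
                       vertices = NULL, control_points = NULL,
                       edge_width = 0, fill_color = 1, background_color = 0) {
  kind <- match.arg(kind)
  stopifnot(.is_num1(edge_width), edge_width >= 0)
  if (kind == "disc") stopifnot(.is_num1(radius), radius > 0)
  if (kind == "annulus") {
    stopifnot(.is_num1(inner_radius), .is_num1(outer_radius),
              inner_radius >= 0)
    if (inner_radius >= outer_radius)
      stop("annulus requires inner_radius < outer_radius")
  }
  if (kind == "rectangle") stopifnot(width > 0, height > 0)
  if (kind == "polygon") {
    vertices <- .as_vertex_matrix(vertices)
    if (nrow(vertices) < 3L) stop("polygon needs at least 3 vertices")
  }
  if (kind == "bezier_region") {
    control_points <- .as_vertex_matrix(control_points)
    if (nrow(control_points) < 4L || (nrow(control_points) - 1L) %% 3L != 0L)
      stop("bezier_region needs 3k + 1 control points")
    vertices <- .flatten_bezier(control_points, tol = 0.25)
  }
  structure(list(kind = kind, center_x = center_x, center_y = center_y,
                 radius = radius, inner_radius = inner_radius,
                 outer_radius = outer_radius, width = width, height = height,
                 angle = angle, vertices = vertices,
                 edge_width = edge_width,
                 fill_color = .as_rgb(fill_color),
                 background_color = .as_rgb(background_color)),
            class = "shape_spec")
}

.as_vertex_matrix <- function(v) {
  if (is.null(v)) stop("vertices/control points required")
  if (is.list(v) && !is.data.frame(v))
    v <- do.call(rbind, lapply(v, as.numeric))
  v <- as.matrix(v)
  storage.mode(v) <- "double"
  if (ncol(v) != 2L) stop("vertices must be a 2-column matrix")
  v
}

# Flatten closed piecewise-cubic Bezier to a polygon: each segment is
# subdivided uniformly until the chord error bound (max control point
# deviation from the chord) falls below tol.
.flatten_bezier <- function(cp, tol = 0.25) {
  nseg <- (nrow(cp) - 1L) %/% 3L
  pts <- NULL
  for (s in seq_len(nseg)) {
    p <- cp[(3 * (s - 1) + 1):(3 * (s - 1) + 4), , drop = FALSE]
    chord <- p[4, ] - p[1, ]
    cl <- sqrt(sum(chord^2))
    dev <- function(q) {
      if (cl < 1e-12) return(sqrt(sum((q - p[1, ])^2)))
      abs((q[1] - p[1, 1]) * chord[2] - (q[2] - p[1, 2]) * chord[1]) / cl
    }
    err <- max(dev(p[2, ]), dev(p[3, ]))
    n <- max(2L, ceiling(sqrt(err / tol) * 8))
    tt <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
    b <- outer((1 - tt)^3, p[1, ]) + outer(3 * tt * (1 - tt)^2, p[2, ]) +
      outer(3 * tt^2 * (1 - tt), p[3, ]) + outer(tt^3, p[4, ])
    pts <- rbind(pts, b)
  }
  pts
}

#' Soft shape membership
#'
#' Evaluates the shape's fuzzy membership at the given coordinates: 1
#' strictly inside, 0 strictly outside, and a smoothstep ramp of total width
#' `edge_width` across the boundary (value 0.5 exactly on the contour).
#'
#' @param shape a [shape_spec()].
#' @param x,y coordinate vectors/matrices (recycled to a common shape).
#' @return membership values in `[0, 1]`, same shape as `x`.
#' @export
shape_membership <- function(shape, x, y) UseMethod("shape_membership")

# Signed distance: negative inside, positive outside, zero on the contour.
.signed_distance <- function(shape, x, y) {
  cx <- x - shape$center_x
  cy <- y - shape$center_y
  switch(shape$kind,
    fullfield = rep(-Inf, length(x)),
    disc = sqrt(cx^2 + cy^2) - shape$radius,
    annulus = {
      rr <- sqrt(cx^2 + cy^2)
      pmax(shape$inner_radius - rr, rr - shape$outer_radius)
    },
    rectangle = {
      a <- shape$angle
      xr <- cx * cos(a) + cy * sin(a)
      yr <- -cx * sin(a) + cy * cos(a)
      qx <- abs(xr) - shape$width / 2
      qy <- abs(yr) - shape$height / 2
      sqrt(pmax(qx, 0)^2 + pmax(qy, 0)^2) + pmin(pmax(qx, qy), 0)
    },
    polygon = ,
    bezier_region = .polygon_sdf(shape$vertices, x, y)
  )
}

# Even-odd interiority + unsigned distance to the closest edge.
.polygon_sdf <- function(v, x, y) {
  n <- nrow(v)
  xx <- as.numeric(x); yy <- as.numeric(y)
  inside <- rep(FALSE, length(xx))
  dist2 <- rep(Inf, length(xx))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > yy) != (yj > yy)) &
      (xx < (xj - xi) * (yy - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    ex <- xj - xi; ey <- yj - yi
    len2 <- ex^2 + ey^2
    t <- if (len2 > 0) .clamp01(((xx - xi) * ex + (yy - yi) * ey) / len2)
         else rep(0, length(xx))
    dist2 <- pmin(dist2, (xx - (xi + t * ex))^2 + (yy - (yi + t * ey))^2)
    j <- i
  }
  sqrt(dist2) * ifelse(inside, -1, 1)
}

#' Membership set operations
#'
#' Fuzzy set combinators over memberships in `[0, 1]`: union is the pointwise
#' maximum, intersection the minimum, complement `1 - m`, difference
#' `min(a, 1 - b)`.  These satisfy the De Morgan identities exactly.
#'
#' @param a,b,m membership arrays.
#' @name membership-ops
#' @export
membership_union <- function(a, b) pmax(a, b)

#' @rdname membership-ops
#' @export
membership_intersect <- function(a, b) pmin(a, b)

#' @rdname membership-ops
#' @export
membership_complement <- function(m) 1 - m

#' @rdname membership-ops
#' @export
membership_difference <- function(a, b) pmin(a, 1 - b)

#' Pattern specification
#'
#' Spatial patterns evaluated pointwise: sinusoidal and square gratings, a
#' frequency/contrast-gradient (Campbell-Robson style) chart, and image
#' assets sampled bilinearly.
#'
#' Gratings: `sine` returns
#' `mean + amplitude * sin(2*pi*f*(x*cos(th) + y*sin(th)) + phase)`;
#' `square` returns `mean + amplitude` where that sine is `>= 0` (ties go to
#' the high level) and `mean - amplitude` otherwise.  The chart returns
#' `0.5 + c(y) * 0.5 * sin(2*pi*phi(x))` with the spatial frequency
#' interpolated geometrically (log-linearly) along `x` between
#' `freq_start`/`freq_end` using the continuous-phase integral `phi`, and the
#' contrast interpolated geometrically along `y` (linearly if an endpoint is
#' zero).
#'
#' @param kind `"sine_grating"`, `"square_grating"`, `"campbell_robson"`, or
#'   `"image"`.
#' @param spatial_frequency cycles per unit length (> 0).
#' @param orientation grating orientation, radians.
#' @param phase phase offset, radians.
#' @param mean,amplitude intensity mean and amplitude;
#'   `amplitude <= min(mean, 1 - mean)` keeps output inside `[0, 1]`.
#' @param freq_start,freq_end,contrast_start,contrast_end chart gradients.
#' @param extent_x,extent_y chart extent (defaults to the field size at
#'   evaluation time).
#' @param image an `H x W x 3` array in `[0, 1]`, or a PNG file path.  Values
#'   are mapped linearly from the container's integer range; no sRGB decoding
#'   is applied (linear-light assumption).
#' @return object of class `pattern_spec`.
#' @export
pattern_spec <- function(kind = c("sine_grating", "square_grating",
                                  "campbell_robson", "image"),
                         spatial_frequency = 0.1, orientation = 0, phase = 0,
                         mean = 0.5, amplitude = 0.5,
                         freq_start = 0.01, freq_end = 0.5,
                         contrast_start = 1, contrast_end = 0,
                         extent_x = NULL, extent_y = NULL, image = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("sine_grating", "square_grating")) {
    stopifnot(spatial_frequency > 0, amplitude >= 0)
    if (amplitude > min(mean, 1 - mean) + 1e-12)
      stop("amplitude must be <= min(mean, 1 - mean)")
  }
  if (kind == "campbell_robson") stopifnot(freq_start > 0, freq_end > 0)
  if (kind == "image") {
    if (is.character(image)) image <- .load_image(image)
    if (!(is.array(image) && length(dim(image)) %in% c(2L, 3L)))
      stop("image must be an array or a file path")
    if (length(dim(image)) == 2L) image <- .gray_frame(image)
    if (dim(image)[3] > 3L) image <- image[, , 1:3]
  }
  structure(list(kind = kind, spatial_frequency = spatial_frequency,
                 orientation = orientation, phase = phase, mean = mean,
                 amplitude = amplitude, freq_start = freq_start,
                 freq_end = freq_end, contrast_start = contrast_start,
                 contrast_end = contrast_end, extent_x = extent_x,
                 extent_y = extent_y, image = image),
            class = "pattern_spec")
}

.load_image <- function(path) {
  if (!file.exists(path)) stop("image asset not found: ", path)
  png::readPNG(path)
}

#' Evaluate a pattern at coordinates
#'
#' @param pattern a [pattern_spec()].
#' @param x,y coordinate matrices.
#' @param t time in seconds (reserved for time-varying patterns; the shipped
#'   patterns are static and time enters through modulation/motion SBCs).
#' @param geometry optional [field_geometry()] supplying the chart/image
#'   extent when the spec leaves it `NULL`.
#' @return `H x W x 3` array (for matrix input) of intensities.
#' @export
eval_pattern <- function(pattern, x, y, t = 0, geometry = NULL) {
  stopifnot(inherits(pattern, "pattern_spec"))
  ex <- pattern$extent_x %||%
    (if (!is.null(geometry)) geometry$width_px * geometry$um_per_px else
       max(x) + min(x))
  ey <- pattern$extent_y %||%
    (if (!is.null(geometry)) geometry$height_px * geometry$um_per_px else
       max(y) + min(y))
  lum <- switch(pattern$kind,
    sine_grating = {
      ph <- 2 * pi * pattern$spatial_frequency *
        (x * cos(pattern$orientation) + y * sin(pattern$orientation)) +
        pattern$phase
      pattern$mean + pattern$amplitude * sin(ph)
    },
    square_grating = {
      ph <- 2 * pi * pattern$spatial_frequency *
        (x * cos(pattern$orientation) + y * sin(pattern$orientation)) +
        pattern$phase
      pattern$mean + pattern$amplitude * ifelse(sin(ph) >= 0, 1, -1)
    },
    campbell_robson = {
      f0 <- pattern$freq_start; f1 <- pattern$freq_end
      # integrated geometric frequency sweep: continuous phase along x
      phi <- if (abs(f1 - f0) < 1e-15) f0 * x else
        f0 * ex / log(f1 / f0) * ((f1 / f0)^(x / ex) - 1)
      c0 <- pattern$contrast_start; c1 <- pattern$contrast_end
      cc <- if (min(c0, c1) <= 0) c0 + (c1 - c0) * y / ey else
        c0 * (c1 / c0)^(y / ey)
      0.5 + cc * 0.5 * sin(2 * pi * phi)
    },
    image = return(.pattern_shape(.sample_image(pattern$image, x, y,
                                                ex, ey), x))
  )
  .pattern_shape(list(lum, lum, lum), x)
}

# Assemble per-channel values into the output shape implied by the input
# coordinates: H x W x 3 array for matrices, RGB triple for a single point,
# n x 3 matrix for coordinate vectors.
.pattern_shape <- function(channels, x) {
  if (is.matrix(x)) {
    out <- array(0, dim = c(nrow(x), ncol(x), 3))
    for (ch in 1:3) out[, , ch] <- channels[[ch]]
    return(out)
  }
  if (length(x) == 1L) return(vapply(channels, `[`, numeric(1), 1L))
  vapply(channels, as.numeric, numeric(length(x)))
}

# Bilinear sampling: the image spans [0, ex] x [0, ey]; coordinates outside
# are clamped to the border (replication).
.sample_image <- function(img, x, y, ex, ey) {
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- pmin(pmax(x / ex * w - 0.5, 0), w - 1)
  py <- pmin(pmax(y / ey * h - 0.5, 0), h - 1)
  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0; fy <- py - y0
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  lapply(1:3, function(ch) {
    m <- img[, , ch]
    idx <- function(r, c) m[cbind(as.numeric(r) + 1, as.numeric(c) + 1)]
    v <- idx(y0, x0) * (1 - fx) * (1 - fy) + idx(y0, x1) * fx * (1 - fy) +
      idx(y1, x0) * (1 - fx) * fy + idx(y1, x1) * fx * fy
    if (is.matrix(x)) dim(v) <- dim(x)
    v
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate grid vertex layouts
#'
#' Produces labeled vertex positions for repeating a primer at preset
#' locations: rectangular and hexagonal lattices, seeded uniform-random
#' scatters, or explicit lists.  In the hexagonal layout, odd rows (0-based)
#' are offset by `spacing / 2` and the vertical pitch is
#' `spacing * sqrt(3) / 2`.
#'
#' @param layout `"rectangular"`, `"hexagonal"`, `"random"`, `"explicit"`.
#' @param rows,cols lattice dimensions.
#' @param spacing lattice constant (center-to-center distance within a row).
#' @param origin_x,origin_y position of the first (top-left) vertex.
#' @param n number of random vertices.
#' @param extent_x,extent_y random-scatter region `[0, extent]`.
#' @param seed seed for the random layout (required).
#' @param vertices explicit two-column matrix.
#' @param labels optional character labels, unique; defaults to
#'   `"v1", "v2", ...` in generation order.
#' @return data.frame with columns `label`, `x`, `y`.
#' @export
grid_vertices <- function(layout = c("rectangular", "hexagonal", "random",
                                     "explicit"),
                          rows = 1, cols = 1, spacing = 1,
                          origin_x = 0, origin_y = 0,
                          n = 1, extent_x = 1, extent_y = 1, seed = NULL,
                          vertices = NULL, labels = NULL) {
  layout <- match.arg(layout)
  pos <- switch(layout,
    rectangular = {
      g <- expand.grid(j = seq_len(cols) - 1L, i = seq_len(rows) - 1L)
      cbind(origin_x + g$j * spacing, origin_y + g$i * spacing)
    },
    hexagonal = {
      g <- expand.grid(j = seq_len(cols) - 1L, i = seq_len(rows) - 1L)
      cbind(origin_x + g$j * spacing + (g$i %% 2) * spacing / 2,
            origin_y + g$i * spacing * sqrt(3) / 2)
    },
    random = {
      if (is.null(seed)) stop("random layout requires a seed")
      st <- seed_state(seed)
      r <- draw_u32(st, 2 * n)
      u <- r$words / 2^32
      cbind(u[seq_len(n) * 2 - 1] * extent_x, u[seq_len(n) * 2] * extent_y)
    },
    explicit = .as_vertex_matrix(vertices)
  )
  if (nrow(pos) < 1L) stop("at least one vertex required")
  if (is.null(labels)) labels <- paste0("v", seq_len(nrow(pos)))
  if (anyDuplicated(labels)) stop("duplicate vertex labels")
  if (length(labels) != nrow(pos)) stop("labels length mismatch")
  data.frame(label = labels, x = pos[, 1], y = pos[, 2],
             stringsAsFactors = FALSE)
}

#' Repeat a shape primer at grid vertices
#'
#' Returns a composite shape whose membership at `(x, y)` is the maximum
#' over copies of the base shape translated by each vertex (overlapping
#' copies combine by maximum).  Vertices are retrievable by label through the
#' attached `vertices` data.frame.
#'
#' @param shape a [shape_spec()] (defined around its own center).
#' @param vertices a data.frame from [grid_vertices()], or arguments passed
#'   through to it via `...`.
#' @param ... forwarded to [grid_vertices()] when `vertices` is missing.
#' @return object of class `grid_shape` (also a valid membership source for
#'   [shape_membership()] via its own method).
#' @export
grid_points <- function(shape, vertices = NULL, ...) {
  stopifnot(inherits(shape, "shape_spec"))
  if (is.null(vertices)) vertices <- grid_vertices(...)
  stopifnot(is.data.frame(vertices), nrow(vertices) >= 1)
  structure(list(base = shape, vertices = vertices,
                 fill_color = shape$fill_color,
                 background_color = shape$background_color),
            class = "grid_shape")
}

#' @export
shape_membership.grid_shape <- function(shape, x, y) {
  m <- 0
  for (k in seq_len(nrow(shape$vertices)))
    m <- pmax(m, shape_membership.shape_spec(
      shape$base, x - shape$vertices$x[k], y - shape$vertices$y[k]))
  m
}

#' @export
shape_membership.shape_spec <- function(shape, x, y) {
  d <- .signed_distance(shape, x, y)
  e <- shape$edge_width
  if (e == 0) {
    m <- as.numeric(d <= 0)
  } else {
    s <- .clamp01((d + e / 2) / e)
    m <- 1 - (3 * s^2 - 2 * s^3)
  }
  if (is.matrix(x)) dim(m) <- dim(x)
  m
}
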