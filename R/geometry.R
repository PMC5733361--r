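#' Display field geometry
#'
#' Describes the rendering field: pixel dimensions, physical scale and the
#' display refresh rate.  Every stimulus frame is an `height_px x width_px x 3`
#' array of linear-light RGB intensities; the frame shown at index `t` covers
#' the time interval starting at `t / frame_rate_hz` seconds.
#'
#' Pixel `(i, j)` (row `i`, column `j`, both 1-based) samples the continuous
#' point `x = (j - 0.5) * um_per_px`, `y = (i - 0.5) * um_per_px`, with the
#' origin at the field's top-left corner.  All shape and pattern formulas are
#' evaluated at these pixel centers (one sample per pixel; anti-aliasing is
#' available only through soft shape edges).
#'
#' @param width_px,height_px field size in pixels (integers, >= 1).
#' @param frame_rate_hz display refresh rate in frames per second (> 0).
#' @param um_per_px physical scale, micrometers per pixel (default 1, i.e.
#'   coordinates are in pixels).
#' @return An object of class `field_geometry`.
#' @examples
#' geo <- field_geometry(64, 48, frame_rate_hz = 60)
#' @export
field_geometry <- function(width_px, height_px, frame_rate_hz = 60,
                           um_per_px = 1) {
  stopifnot(.is_count(width_px), width_px >= 1,
            .is_count(height_px), height_px >= 1,
            .is_num1(frame_rate_hz), frame_rate_hz > 0,
            .is_num1(um_per_px), um_per_px > 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 frame_rate_hz = frame_rate_hz,
                 um_per_px = um_per_px),
            class = "field_geometry")
}

#' @export
print.field_geometry <- function(x, ...) {
  cat(sprintf("<field_geometry> %d x %d px, %g um/px, %g Hz\n",
              x$width_px, x$height_px, x$um_per_px, x$frame_rate_hz))
  invisible(x)
}

#' Pixel-center coordinate matrices
#'
#' @param geometry a [field_geometry()].
#' @return list with `x` and `y`: `height_px x width_px` matrices of the
#'   physical coordinates of every pixel center.
#' @export
pixel_centers <- function(geometry) {
  stopifnot(inherits(geometry, "field_geometry"))
  xs <- (seq_len(geometry$width_px) - 0.5) * geometry$um_per_px
  ys <- (seq_len(geometry$height_px) - 0.5) * geometry$um_per_px
  list(x = matrix(xs, geometry$height_px, geometry$width_px, byrow = TRUE),
       y = matrix(ys, geometry$height_px, geometry$width_px))
}

#' Construct a constant frame
#'
#' @param geometry a [field_geometry()].
#' @param value a single intensity or an RGB triple.
#' @return `height_px x width_px x 3` numeric array.
#' @export
new_frame <- function(geometry, value = 0) {
  stopifnot(inherits(geometry, "field_geometry"))
  rgb <- .as_rgb(value)
  arr <- array(0, dim = c(geometry$height_px, geometry$width_px, 3))
  for (ch in 1:3) arr[, , ch] <- rgb[ch]
  arr
}

# Accept a scalar gray level or an RGB triple.
.as_rgb <- function(value) {
  v <- as.numeric(value)
  if (length(v) == 1L) v <- rep(v, 3)
  if (length(v) != 3L || any(!is.finite(v)))
    stop("color must be a finite scalar or RGB triple")
  v
}

.check_frame <- function(frame, geometry = NULL) {
  if (!(is.array(frame) && length(dim(frame)) == 3L && dim(frame)[3] == 3L))
    stop("frame must be an H x W x 3 array")
  if (!is.null(geometry) &&
      !identical(dim(frame)[1:2],
                 c(geometry$height_px, geometry$width_px)))
    stop("frame geometry mismatch")
  invisible(frame)
}

# Build an RGB frame from one matrix (replicated) or three.
.gray_frame <- function(m) {
  array(c(m, m, m), dim = c(nrow(m), ncol(m), 3))
}
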