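#' Measure the intensity histogram of a frame sequence
#'
#' In-silico measurement of the intensity distribution over one frame
#' (`scope = "per_frame"`) or over a whole stimulus (`scope = "global"`),
#' together with the minimum, maximum, mean and variance.  The binning range
#' is auto-detected and always covers at least `[0, 1]`; mass lying outside
#' the displayable unit interval (as arises after zero-integral filtering)
#' is reported separately so it can be flagged.
#'
#' @param frames a single frame or a list of frames.
#' @param n_bins number of histogram bins (default 256).
#' @param scope `"per_frame"` (first/only frame) or `"global"` (all frames).
#' @return object of class `histogram_report`: list with `breaks`, `counts`,
#'   `min`, `max`, `mean`, `variance`, `n_values`, `frac_below`, `frac_above`
#'   and `scope`.
#' @export
measure_histogram <- function(frames, n_bins = 256,
                              scope = c("per_frame", "global")) {
  scope <- match.arg(scope)
  if (is.array(frames) || is.matrix(frames)) frames <- list(frames)
  if (!is.list(frames) || length(frames) == 0L) stop("no frames supplied")
  if (scope == "per_frame") frames <- frames[1]
  v <- unlist(lapply(frames, as.numeric), use.names = FALSE)
  if (any(!is.finite(v))) stop("non-finite intensities")
  lo <- min(0, min(v)); hi <- max(1, max(v))
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- .bin_counts(v, breaks)
  structure(list(breaks = breaks, counts = counts,
                 min = min(v), max = max(v), mean = mean(v),
                 variance = if (length(v) > 1) var(v) else 0,
                 n_values = length(v),
                 frac_below = mean(v < 0), frac_above = mean(v > 1),
                 scope = scope),
            class = "histogram_report")
}

.bin_counts <- function(v, breaks) {
  n_bins <- length(breaks) - 1L
  idx <- findInterval(v, breaks, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n_bins)
  tabulate(idx, nbins = n_bins)
}

#' @export
print.histogram_report <- function(x, ...) {
  cat(sprintf(
    "<histogram_report> %s: %d values in %d bins\n  min %.4g  max %.4g  mean %.4g  var %.4g",
    x$scope, x$n_values, length(x$counts), x$min, x$max, x$mean, x$variance))
  if (x$frac_below + x$frac_above > 0)
    cat(sprintf("\n  outside [0,1]: %.2f%% below, %.2f%% above",
                100 * x$frac_below, 100 * x$frac_above))
  cat("\n")
  invisible(x)
}

#' Write a histogram report as TSV
#'
#' Columns `bin_left`, `bin_right`, `count`, preceded by a `#` summary line.
#'
#' @param report a [measure_histogram()] result.
#' @param path output path.
#' @export
write_histogram_tsv <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# min %.12g max %.12g mean %.12g variance %.12g",
                     report$min, report$max, report$mean, report$variance),
             con)
  df <- data.frame(bin_left = head(report$breaks, -1),
                   bin_right = tail(report$breaks, -1),
                   count = report$counts)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tone-mapping specification
#'
#' @param kind `"stretch"` (linear contrast stretch between `lo` and `hi`),
#'   `"sigmoid"` (logistic transfer), `"equalize"` (histogram equalization),
#'   or `"renorm"` (affine map of the measured `[min, max]` onto `[0, 1]`,
#'   the standard way to squeeze post-filtering intensities back into the
#'   displayable range).
#' @param lo,hi stretch bounds (`lo < hi`); when `NULL` they are taken from
#'   the measured report (min/max).
#' @param center,slope sigmoid parameters (`slope > 0`).
#' @param n_bins equalization CDF resolution.
#' @param dynamic if `TRUE` the transfer function is re-measured per frame;
#'   if `FALSE` one global measurement is used for every frame of the
#'   stimulus.
#' @return object of class `tonemap_spec`.
#' @export
tonemap_spec <- function(kind = c("stretch", "sigmoid", "equalize", "renorm"),
                         lo = NULL, hi = NULL, center = 0.5, slope = 10,
                         n_bins = 256, dynamic = TRUE) {
  kind <- match.arg(kind)
  if (!is.null(lo) && !is.null(hi) && lo >= hi) stop("requires lo < hi")
  stopifnot(slope > 0, .is_count(n_bins), n_bins >= 1)
  structure(list(kind = kind, lo = lo, hi = hi, center = center,
                 slope = slope, n_bins = n_bins, dynamic = isTRUE(dynamic)),
            class = "tonemap_spec")
}

#' Apply a tone map to a frame
#'
#' Monotone transfer functions mapping intensities into the unit interval:
#'
#' * stretch: `v -> (v - lo) / (hi - lo)` clamped to `[0, 1]`;
#' * sigmoid: `v -> 1 / (1 + exp(-slope * (v - center)))`;
#' * equalize: `v -> (cdf(v) - cdf_min) / (1 - cdf_min)` via an
#'   `n_bins`-bin CDF (identity when a single bin is occupied);
#' * renorm: the unique affine map sending the measured `[min, max]` to
#'   `[0, 1]` (identity when `min == max`).
#'
#' @param frame the frame to map.
#' @param spec a [tonemap_spec()].
#' @param report a [measure_histogram()] report supplying measured bounds /
#'   CDF; required for `renorm`, for `stretch` with `NULL` bounds, and for
#'   static (`dynamic = FALSE`) equalization.  With `dynamic = TRUE` the
#'   frame itself is measured when no report is given.
#' @return mapped frame with values in `[0, 1]`.
#' @export
tone_map <- function(frame, spec, report = NULL) {
  stopifnot(inherits(spec, "tonemap_spec"))
  needs_report <- spec$kind == "renorm" ||
    (spec$kind == "stretch" && (is.null(spec$lo) || is.null(spec$hi))) ||
    spec$kind == "equalize"
  if (needs_report && is.null(report)) {
    if (!spec$dynamic)
      stop("static tone mapping needs a pre-measured global report")
    report <- measure_histogram(frame, n_bins = spec$n_bins)
  }
  switch(spec$kind,
    stretch = {
      lo <- spec$lo %||% report$min
      hi <- spec$hi %||% report$max
      if (lo >= hi) stop("requires lo < hi")
      .clamp01((frame - lo) / (hi - lo))
    },
    sigmoid = 1 / (1 + exp(-spec$slope * (frame - spec$center))),
    equalize = {
      counts <- report$counts
      breaks <- report$breaks
      occupied <- sum(counts > 0)
      if (occupied <= 1L) return(.clamp01(frame))
      # continuous (interpolated) CDF: piecewise linear through the
      # cumulative counts at the bin edges, so the transfer is a smooth
      # monotone map rather than an n_bins-level staircase
      cdf_edges <- c(0, cumsum(counts)) / sum(counts)
      cdf <- function(v) approx(breaks, cdf_edges, xout = v, rule = 2)$y
      cdf_min <- cdf(report$min)
      out <- (cdf(as.numeric(frame)) - cdf_min) / (1 - cdf_min)
      dim(out) <- dim(frame)
      .clamp01(out)
    },
    renorm = {
      rng <- report$max - report$min
      if (rng <= 0) return(.clamp01(frame))
      .clamp01((frame - report$min) / rng)
    })
}

#' Per-frame statistics
#'
#' Luminance is the unweighted per-pixel channel mean (computations are in
#' linear RGB).  Michelson contrast is `(Lmax - Lmin) / (Lmax + Lmin)` (0
#' when the denominator vanishes), RMS contrast is `sd(L) / mean(L)` (0 for
#' zero mean), and entropy is `-sum(p log2 p)` over 256 equal luminance bins
#' spanning `[0, 1]` (extended if values exceed it).
#'
#' @param frame an `H x W x 3` frame (or a plain luminance matrix).
#' @return list with `michelson`, `rms_contrast`, `entropy_bits`, `mean`,
#'   `variance`.
#' @export
frame_stats <- function(frame) {
  L <- if (is.matrix(frame)) frame else
    (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3
  if (any(!is.finite(L))) stop("non-finite intensities")
  lmax <- max(L); lmin <- min(L)
  michelson <- if (lmax + lmin == 0) 0 else (lmax - lmin) / (lmax + lmin)
  mu <- mean(L)
  # population (not sample) spread: a frame is the full population of pixels
  sdev <- sqrt(mean((L - mu)^2))
  rms <- if (mu == 0) 0 else sdev / mu
  breaks <- seq(min(0, lmin), max(1, lmax), length.out = 257L)
  p <- .bin_counts(as.numeric(L), breaks) / length(L)
  p <- p[p > 0]
  list(michelson = michelson, rms_contrast = rms,
       entropy_bits = -sum(p * log2(p)), mean = mu, variance = sdev^2)
}

#' Convert colors from CMYK, HSV, or XYZ to linear RGB
#'
#' Standard conversions: CMYK uses `red = (1-c)(1-k)` etc.; HSV follows the
#' hexcone model; XYZ is mapped through the fixed sRGB/D65 primaries matrix
#' (without the sRGB transfer curve — outputs stay linear-light).  Outputs
#' are clamped to `[0, 1]`.
#'
#' @param value numeric vector of components (CMYK: 4; HSV: hue in degrees
#'   `[0, 360)`, s, v in `[0, 1]`; XYZ: 3, Y normalized so white is 1).
#' @param from_space `"CMYK"`, `"HSV"`, or `"XYZ"`.
#' @return RGB triple in `[0, 1]`.
#' @export
color_convert <- function(value, from_space = c("CMYK", "HSV", "XYZ")) {
  from_space <- match.arg(from_space)
  v <- as.numeric(value)
  out <- switch(from_space,
    CMYK = {
      stopifnot(length(v) == 4, all(v >= 0 & v <= 1))
      c((1 - v[1]) * (1 - v[4]),
        (1 - v[2]) * (1 - v[4]),
        (1 - v[3]) * (1 - v[4]))
    },
    HSV = {
      stopifnot(length(v) == 3, v[1] >= 0, v[1] < 360,
                all(v[2:3] >= 0 & v[2:3] <= 1))
      h <- v[1] / 60; s <- v[2]; val <- v[3]
      i <- floor(h) %% 6
      f <- h - floor(h)
      p <- val * (1 - s); q <- val * (1 - s * f); t <- val * (1 - s * (1 - f))
      switch(as.character(i),
             "0" = c(val, t, p), "1" = c(q, val, p), "2" = c(p, val, t),
             "3" = c(p, q, val), "4" = c(t, p, val), "5" = c(val, p, q))
    },
    XYZ = {
      stopifnot(length(v) == 3)
      m <- matrix(c(3.2406, -1.5372, -0.4986,
                    -0.9689, 1.8758, 0.0415,
                    0.0557, -0.2040, 1.0570), 3, 3, byrow = TRUE)
      as.numeric(m %*% v)
    })
  .clamp01(out)
}

#' Build a gamma-compensation lookup table
#'
#' Display devices apply a nonlinear input-to-luminance curve; scientific
#' stimulation assumes strict linearity, so software intensities must be
#' pre-distorted by the inverse of the measured curve.  The device curve
#' `D(v)` is interpolated piecewise-linearly through the supplied
#' photometer samples (rescaled so luminance spans `[0, 1]`), and the
#' compensation `C = D^{-1}` is tabulated at `n_entries` points.  By
#' construction `C(0) = 0` and `C(1) = 1`.
#'
#' @param samples two-column matrix/data.frame of `(input value, measured
#'   luminance)` pairs, at least 2, strictly increasing in both coordinates
#'   after sorting by input.
#' @param n_entries number of LUT entries (default 256).
#' @return object of class `gamma_lut`: list with `input`, `luminance`
#'   (the normalized device samples) and `comp_x`, `comp_y` (the tabulated
#'   compensation curve).
#' @export
gamma_build <- function(samples, n_entries = 256) {
  s <- as.matrix(samples)
  if (nrow(s) < 2 || ncol(s) < 2) stop("need >= 2 (input, luminance) samples")
  s <- s[order(s[, 1]), 1:2, drop = FALSE]
  dv <- diff(s[, 1]); dl <- diff(s[, 2])
  if (any(dv <= 0)) stop("non-monotone input values at sample index ",
                         which(dv <= 0)[1] + 1L)
  if (any(dl <= 0)) stop("non-monotone luminance at sample index ",
                         which(dl <= 0)[1] + 1L)
  inp <- (s[, 1] - s[1, 1]) / (s[nrow(s), 1] - s[1, 1])
  lum <- (s[, 2] - s[1, 2]) / (s[nrow(s), 2] - s[1, 2])
  # tabulate the compensation at the device-curve values of an input grid
  # (plus the sample nodes): this is the exact piecewise-linear inverse of
  # the interpolated device curve, so C(D(v)) = v to float precision.  A
  # grid uniform in luminance would lose accuracy where the curve is steep.
  vg <- sort(unique(c(seq(0, 1, length.out = n_entries), inp)))
  comp_x <- approx(inp, lum, xout = vg)$y
  comp_y <- vg
  structure(list(input = inp, luminance = lum,
                 comp_x = comp_x, comp_y = comp_y),
            class = "gamma_lut")
}

#' Evaluate the device curve of a gamma LUT
#'
#' @param lut a [gamma_build()] result.
#' @param v input values in `[0, 1]`.
#' @return simulated device luminance.
#' @export
gamma_device <- function(lut, v) {
  approx(lut$input, lut$luminance, xout = v, rule = 2)$y
}

#' Apply gamma compensation to a frame
#'
#' Per-channel lookup with linear interpolation.  Apply after the final tone
#' mapping: input values outside `[0, 1]` are clamped with a warning.
#'
#' @param frame frame in `[0, 1]`.
#' @param lut a [gamma_build()] result.
#' @return compensated frame in `[0, 1]`.
#' @export
gamma_apply <- function(frame, lut) {
  stopifnot(inherits(lut, "gamma_lut"))
  if (min(frame) < 0 || max(frame) > 1) {
    warning("frame values outside [0, 1] clamped before gamma compensation")
    frame <- .clamp01(frame)
  }
  out <- approx(lut$comp_x, lut$comp_y, xout = as.numeric(frame),
                rule = 2)$y
  dim(out) <- dim(frame)
  out
}
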