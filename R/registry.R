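# Registry of stimulus building components (SBCs).  Each entry records the
# component's parameter names with documented defaults; `component()`
# validates names and resolves defaults against it.  `register_sbc()` is the
# extension hook for user-defined components.

.sbc_registry <- new.env(parent = emptyenv())

#' Register a stimulus building component
#'
#' Adds (or replaces) an SBC definition in the registry, making it available
#' to [component()] and to declarative configurations.
#'
#' @param sbc_type one of `"primer"`, `"prng"`, `"motion"`, `"modulation"`,
#'   `"warp"`, `"composition"`, `"spatial_filter"`, `"temporal_filter"`,
#'   `"tonemap"`, `"gamma"`.
#' @param name the concrete SBC name.
#' @param defaults named list of all accepted parameters with their default
#'   values (`NULL` marks context-resolved defaults such as the field
#'   center).
#' @param required character vector of parameters that must be supplied.
#' @export
register_sbc <- function(sbc_type, name, defaults = list(),
                         required = character()) {
  stopifnot(sbc_type %in% .sbc_types(), is.character(name), nzchar(name))
  key <- paste(sbc_type, name, sep = "/")
  assign(key, list(type = sbc_type, name = name, defaults = defaults,
                   required = required), envir = .sbc_registry)
  invisible(key)
}

.sbc_types <- function() c("primer", "prng", "motion", "modulation", "warp",
                           "composition", "spatial_filter",
                           "temporal_filter", "tonemap", "gamma")

#' List registered SBCs
#'
#' @return data.frame with columns `type` and `name`.
#' @export
list_sbcs <- function() {
  keys <- sort(ls(.sbc_registry))
  parts <- strsplit(keys, "/", fixed = TRUE)
  data.frame(type = vapply(parts, `[`, "", 1),
             name = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Construct a component specification
#'
#' A `component_spec` names one SBC with its fully resolved parameter set:
#' unknown parameter names are rejected, missing ones take the registered
#' defaults.  Components are combined into stimuli with [stimulus()].
#'
#' @param sbc_type the SBC category (see [register_sbc()]).
#' @param name the registered SBC name.
#' @param params named list of parameters.
#' @return object of class `component_spec`.
#' @examples
#' component("primer", "fullfield", list(intensity = 0.5))
#' @export
component <- function(sbc_type, name, params = list()) {
  if (!sbc_type %in% .sbc_types())
    stop("unknown SBC type '", sbc_type, "'")
  key <- paste(sbc_type, name, sep = "/")
  if (!exists(key, envir = .sbc_registry))
    stop("unknown ", sbc_type, " component '", name, "'")
  def <- get(key, envir = .sbc_registry)
  if (is.null(params)) params <- list()
  if (length(params) && (is.null(names(params)) || any(!nzchar(names(params)))))
    stop("component parameters must be named")
  unknown <- setdiff(names(params), names(def$defaults))
  if (length(unknown))
    stop("unknown parameter(s) for ", sbc_type, " '", name, "': ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(def$required, names(params))
  if (length(missing))
    stop("missing required parameter(s) for ", sbc_type, " '", name, "': ",
         paste(missing, collapse = ", "))
  structure(list(sbc_type = sbc_type, name = name,
                 params = modifyList(def$defaults, params,
                                     keep.null = TRUE)),
            class = "component_spec")
}

#' @export
print.component_spec <- function(x, ...) {
  cat(sprintf("<component_spec> %s/%s\n", x$sbc_type, x$name))
  invisible(x)
}

# ---- built-in component registrations --------------------------------------

.register_builtins <- function() {
  reg <- register_sbc

  shape_common <- list(center_x = NULL, center_y = NULL, edge_width = 0,
                       fill_color = 1, background_color = 0)
  reg("primer", "fullfield", list(intensity = 0.5, color = NULL))
  reg("primer", "disc", c(shape_common, list(radius = 10)))
  reg("primer", "annulus",
      c(shape_common, list(inner_radius = 5, outer_radius = 10)))
  reg("primer", "rectangle",
      c(shape_common, list(width = 10, height = 10, angle = 0)))
  reg("primer", "polygon", c(shape_common, list(vertices = NULL)),
      required = "vertices")
  reg("primer", "bezier_region",
      c(shape_common, list(control_points = NULL)),
      required = "control_points")
  grating <- list(spatial_frequency = 0.05, orientation = 0, phase = 0,
                  mean = 0.5, amplitude = 0.5)
  reg("primer", "sine_grating", grating)
  reg("primer", "square_grating", grating)
  reg("primer", "campbell_robson",
      list(freq_start = 0.005, freq_end = 0.25,
           contrast_start = 1, contrast_end = 0))
  reg("primer", "image", list(path = NULL, image = NULL))
  reg("primer", "checkerboard",
      list(mode = "binary", low = 0, high = 1))
  reg("primer", "grid_points",
      list(base_name = "disc", base_params = list(),
           layout = "rectangular", rows = 1, cols = 1, spacing = 10,
           origin_x = 0, origin_y = 0, n = 1,
           extent_x = NULL, extent_y = NULL, seed = NULL, labels = NULL,
           vertices = NULL))

  reg("prng", "xorshift128",
      list(seed = NULL, rows = 16, cols = 16,
           update = "refresh", dx = 0, dy = 0, streams = NULL))

  reg("motion", "static", list())
  reg("motion", "linear",
      list(velocity_x = NULL, velocity_y = NULL, crossing_time = NULL,
           direction = 0, shape_extent = 0))
  reg("motion", "path", list(control_points = NULL),
      required = "control_points")
  reg("motion", "shake", list(amplitude = 0, seed = 1))

  reg("modulation", "constant", list(value = 1))
  reg("modulation", "linear",
      list(start = 0, end = 1, duration_s = NULL, duration_frames = NULL))
  wave <- list(mean = 0.5, amplitude_start = 0.5, amplitude_end = 0.5,
               frequency_start = 1, frequency_end = 1, phase = 0,
               duration_s = NULL)
  reg("modulation", "sine", wave)
  reg("modulation", "square", wave)
  reg("modulation", "multi_component", list(components = NULL),
      required = "components")

  reg("warp", "identity", list())
  reg("warp", "repeat", list(period_x = 32, period_y = 32))
  reg("warp", "polar",
      list(center_x = NULL, center_y = NULL, angle_scale = 10))
  reg("warp", "pinch_twist",
      list(center_x = NULL, center_y = NULL, radius = NULL,
           strength = 1, twist = pi / 2))
  reg("warp", "custom", list(fn = NULL, table = NULL, table_path = NULL))

  reg("composition", "mix",
      list(foreground = NULL, background = NULL, mask = NULL),
      required = c("foreground", "background", "mask"))

  reg("spatial_filter", "gaussian", list(sigma = 2, method = "auto"))
  reg("spatial_filter", "dog",
      list(sigma_center = 1, sigma_surround = 2, gain_center = 1,
           gain_surround = 1, method = "auto"))
  reg("spatial_filter", "gabor",
      list(sigma = 4, frequency = 0.1, orientation = 0, phase = 0,
           gain = 1, method = "auto"))
  reg("spatial_filter", "median", list(window = 3))
  reg("spatial_filter", "freq_lowpass", list(cutoff = 0.05))
  reg("spatial_filter", "freq_highpass", list(cutoff = 0.05))
  reg("spatial_filter", "freq_bandpass", list(low = 0.02, high = 0.2))
  reg("spatial_filter", "freq_custom", list(transfer = NULL),
      required = "transfer")

  tw <- list(length = 5, prestimulus = "zero")
  reg("temporal_filter", "rectangular", tw)
  reg("temporal_filter", "triangular", tw)
  reg("temporal_filter", "hamming", tw)
  reg("temporal_filter", "hann", tw)
  reg("temporal_filter", "exponential",
      list(length = 20, a = 0.85, prestimulus = "zero"))
  reg("temporal_filter", "cell_dog",
      list(length = 16, mu1 = 2, sigma1 = 1, w1 = 1,
           mu2 = 6, sigma2 = 2, w2 = 0.5, prestimulus = "zero"))
  reg("temporal_filter", "lti",
      list(poles = NULL, coefs = NULL, direct = 0),
      required = c("poles", "coefs"))

  reg("tonemap", "stretch", list(lo = NULL, hi = NULL, dynamic = TRUE))
  reg("tonemap", "sigmoid", list(center = 0.5, slope = 10))
  reg("tonemap", "equalize", list(n_bins = 256, dynamic = TRUE))
  reg("tonemap", "renorm", list(dynamic = TRUE))

  reg("gamma", "power", list(exponent = 2.2, n_entries = 256))
  reg("gamma", "lut",
      list(samples = NULL, samples_path = NULL, n_entries = 256))
}

.onLoad <- function(libname, pkgname) {
  .register_builtins()
}
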