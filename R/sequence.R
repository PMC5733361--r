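#' Sequence specification
#'
#' A sequence concatenates stimuli under one field geometry and one global
#' seed.  Two signalling channels are always present: `"stim"` rises on each
#' stimulus's first frame and falls on its last, and `"stop"` pulses on the
#' final frame of the sequence — the software stand-in for hardware
#' synchronisation voltages.
#'
#' @param geometry a [field_geometry()].
#' @param stimuli list of [stimulus()] objects (>= 1).
#' @param seed global seed (used by components without their own).
#' @param label sequence name.
#' @return object of class `sequence_spec`.
#' @export
sequence_spec <- function(geometry, stimuli, seed = 1, label = "sequence") {
  stopifnot(inherits(geometry, "field_geometry"))
  if (inherits(stimuli, "stimulus_spec")) stimuli <- list(stimuli)
  if (!length(stimuli)) stop("sequence needs at least one stimulus")
  if (!all(vapply(stimuli, inherits, TRUE, "stimulus_spec")))
    stop("stimuli must be stimulus_spec objects")
  structure(list(geometry = geometry, stimuli = stimuli, seed = seed,
                 label = label,
                 total_frames = sum(vapply(stimuli, `[[`, 1L,
                                           "duration_frames"))),
            class = "sequence_spec")
}

#' @export
print.sequence_spec <- function(x, ...) {
  cat(sprintf("<sequence_spec> '%s': %d stimuli, %d frames @ %g Hz\n",
              x$label, length(x$stimuli), x$total_frames,
              x$geometry$frame_rate_hz))
  invisible(x)
}

#' Parse a declarative sequence configuration
#'
#' Reads a YAML configuration with a `geometry` block, an optional `seed`,
#' and a `stimuli` list; each stimulus gives `label`, `duration_frames` and
#' a `components` list of `{type, name, params}` entries.  Unknown component
#' names or parameters fail fast with the stimulus and component position
#' named; all defaults are resolved into the returned spec so that the
#' normalized ("resolved") configuration can be echoed for provenance.
#'
#' @param path configuration file path.
#' @return a [sequence_spec()] with attribute `"resolved"` holding the
#'   fully resolved configuration list.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$geometry)) stop("config: missing 'geometry' block")
  g <- cfg$geometry
  for (k in c("width_px", "height_px"))
    if (is.null(g[[k]])) stop("config: geometry lacks '", k, "'")
  geometry <- field_geometry(g$width_px, g$height_px,
                             frame_rate_hz = g$frame_rate_hz %||% 60,
                             um_per_px = g$um_per_px %||% 1)
  if (is.null(cfg$stimuli) || !length(cfg$stimuli))
    stop("config: empty stimulus list")
  stimuli <- vector("list", length(cfg$stimuli))
  resolved <- list(geometry = list(width_px = geometry$width_px,
                                   height_px = geometry$height_px,
                                   frame_rate_hz = geometry$frame_rate_hz,
                                   um_per_px = geometry$um_per_px),
                   seed = cfg$seed %||% 1, stimuli = list())
  for (i in seq_along(cfg$stimuli)) {
    s <- cfg$stimuli[[i]]
    where <- sprintf("config stimulus %d", i)
    if (is.null(s$duration_frames))
      stop(where, ": missing duration_frames")
    if (is.null(s$components) || !length(s$components))
      stop(where, ": missing components")
    comps <- vector("list", length(s$components))
    rcomps <- list()
    for (j in seq_along(s$components)) {
      c0 <- s$components[[j]]
      if (is.null(c0$type) || is.null(c0$name))
        stop(where, " component ", j, ": needs 'type' and 'name'")
      comps[[j]] <- tryCatch(
        component(c0$type, c0$name, .yaml_params(c0$params)),
        error = function(e)
          stop(where, " component ", j, " (", c0$type, "/", c0$name,
               "): ", conditionMessage(e), call. = FALSE))
      rcomps[[j]] <- list(type = c0$type, name = c0$name,
                          params = .printable_params(comps[[j]]$params))
    }
    stimuli[[i]] <- tryCatch(
      stimulus(comps, s$duration_frames, s$label %||% sprintf("stim%d", i)),
      error = function(e) stop(where, ": ", conditionMessage(e),
                               call. = FALSE))
    resolved$stimuli[[i]] <- list(label = stimuli[[i]]$label,
                                  duration_frames = s$duration_frames,
                                  components = rcomps)
  }
  spec <- sequence_spec(geometry, stimuli, seed = cfg$seed %||% 1,
                        label = cfg$label %||% "sequence")
  attr(spec, "resolved") <- resolved
  spec
}

# YAML gives nested lists; coerce obvious numeric tables (vertices,
# control_points, components) into matrices.
.yaml_params <- function(p) {
  if (is.null(p)) return(list())
  for (k in c("vertices", "control_points", "components")) {
    if (!is.null(p[[k]]) && is.list(p[[k]]))
      p[[k]] <- do.call(rbind, lapply(p[[k]], as.numeric))
  }
  p
}

.printable_params <- function(p) {
  lapply(p, function(v) {
    if (is.matrix(v)) apply(v, 1, as.numeric, simplify = FALSE)
    else if (is.function(v)) "<function>"
    else v
  })
}

#' Render a full sequence to disk
#'
#' Renders every frame in order (one shared [render_context()] per
#' stimulus), writes the frames, the frame-accurate event log, the resolved
#' configuration, optional random-grid exports, and a render-time budget
#' report (frames whose render wall time exceeded the frame interval are
#' flagged — informational only, the output is never altered).
#'
#' Stimuli containing a static (`dynamic = FALSE`) tone map are rendered
#' twice: a measurement prepass up to that stage feeds the global histogram
#' that fixes the transfer function, then the real pass renders with it.
#'
#' @param spec a [sequence_spec()] (or [parse_config()] result).
#' @param out_dir output directory (created if needed).
#' @param format `"png16"` or `"raw_stack"`.
#' @param write_frames write frame files (disable for measurement-only runs).
#' @param record_randoms export random grids to `randoms.txt`.
#' @return invisibly, a list with `event_log` (data.frame), `files`,
#'   `stats` (per-frame [frame_stats()] rows) and `budget` (per-frame wall
#'   times and flagged indices).
#' @export
run_sequence <- function(spec, out_dir, format = c("png16", "raw_stack"),
                         write_frames = TRUE, record_randoms = FALSE) {
  format <- match.arg(format)
  stopifnot(inherits(spec, "sequence_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geometry <- spec$geometry
  rate <- geometry$frame_rate_hz
  events <- list()
  files <- character()
  stats <- list()
  times <- numeric(spec$total_frames)
  raw_frames <- if (format == "raw_stack") vector("list", spec$total_frames)
  global_t <- 0L
  random_log <- list()
  for (si in seq_along(spec$stimuli)) {
    stim <- spec$stimuli[[si]]
    ctx <- render_context(geometry, seed = spec$seed,
                          record_randoms = record_randoms)
    static_stage <- .static_tonemap_stage(stim, geometry, spec$seed)
    if (!is.null(static_stage)) {
      pre_ctx <- render_context(geometry, seed = spec$seed)
      pre <- lapply(seq_len(stim$duration_frames) - 1L, function(t)
        render_frame(stim, t, pre_ctx, .stop_before = static_stage))
      ctx$global_stats <- measure_histogram(pre, scope = "global")
    }
    events[[length(events) + 1L]] <-
      data.frame(frame = global_t, channel = "stim", edge = "rise")
    for (t in seq_len(stim$duration_frames) - 1L) {
      t0 <- proc.time()[["elapsed"]]
      fr <- render_frame(stim, t, ctx)
      times[global_t + 1L] <- proc.time()[["elapsed"]] - t0
      stats[[global_t + 1L]] <- c(frame = global_t,
                                  unlist(frame_stats(fr)))
      if (write_frames) {
        if (format == "png16") {
          f <- file.path(out_dir, sprintf("frame_%06d.png", global_t))
          write_png16(fr, f)
          files <- c(files, f)
        } else raw_frames[[global_t + 1L]] <- fr
      }
      global_t <- global_t + 1L
    }
    events[[length(events) + 1L]] <-
      data.frame(frame = global_t - 1L, channel = "stim", edge = "fall")
    if (record_randoms && length(ctx$random_log))
      random_log[[stim$label]] <- ctx$random_log
  }
  events[[length(events) + 1L]] <-
    data.frame(frame = global_t - 1L, channel = "stop", edge = "pulse")
  log <- do.call(rbind, events)
  log$time_s <- log$frame / rate
  log <- log[order(log$frame, log$channel), c("frame", "time_s",
                                              "channel", "edge")]
  rownames(log) <- NULL
  if (write_frames && format == "raw_stack") {
    f <- file.path(out_dir, "frames.raw")
    write_raw_stack(raw_frames, f, rate)
    files <- c(files, f, paste0(f, ".json"))
  }
  ev_path <- file.path(out_dir, "events.tsv")
  write_event_log(log, ev_path)
  files <- c(files, ev_path)
  resolved <- attr(spec, "resolved")
  if (!is.null(resolved)) {
    rc <- file.path(out_dir, "resolved_config.yaml")
    yaml::write_yaml(resolved, rc)
    files <- c(files, rc)
  }
  if (length(random_log)) {
    rp <- file.path(out_dir, "randoms.txt")
    flat <- list(); fi <- integer()
    for (lbl in names(random_log)) for (k in seq_along(random_log[[lbl]])) {
      g <- random_log[[lbl]][[k]]
      if (is.list(g)) for (gg in g) {            # color: 3 grids per frame
        flat[[length(flat) + 1L]] <- gg; fi <- c(fi, k - 1L)
      } else {
        flat[[length(flat) + 1L]] <- g; fi <- c(fi, k - 1L)
      }
    }
    export_randoms(flat, rp, frame_indices = fi)
    files <- c(files, rp)
  }
  st <- as.data.frame(do.call(rbind, stats))
  budget <- list(frame_s = times, budget_s = 1 / rate,
                 flagged = which(times > 1 / rate) - 1L)
  invisible(list(event_log = log, files = files, stats = st,
                 budget = budget))
}

# Position (1-based, within the post-stage list) of the first static tone
# map, or NULL.  Compiled once here so the prepass knows where to stop.
.static_tonemap_stage <- function(stim, geometry, seed) {
  plan <- .compile_stimulus(stim, geometry, seed)
  for (i in seq_along(plan$post)) {
    comp <- plan$post[[i]]$comp
    if (comp$sbc_type == "tonemap" &&
        !isTRUE(plan$post[[i]]$spec$dynamic))
      return(i)
  }
  NULL
}

#' Write a list of frames to disk
#'
#' `png16` writes one 16-bit-per-channel PNG per frame, named
#' `frame_%06d.png` (see [write_png16()] for the quantization rule);
#' `raw_stack` writes a single little-endian float32 stack with a JSON
#' sidecar.  Both round-trip within quantization error (the raw stack
#' exactly, at float32 precision).
#'
#' @param frames list of frames with values in `[0, 1]`.
#' @param out_dir output directory (created if needed).
#' @param format `"png16"` or `"raw_stack"`.
#' @param start_index index of the first frame file (default 0).
#' @param frame_rate_hz recorded in the raw-stack sidecar.
#' @return character vector of the files written, invisibly.
#' @export
write_frames <- function(frames, out_dir, format = c("png16", "raw_stack"),
                         start_index = 0L, frame_rate_hz = 60) {
  format <- match.arg(format)
  if (is.array(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "png16") {
    files <- vapply(seq_along(frames), function(i) {
      f <- file.path(out_dir, sprintf("frame_%06d.png",
                                      start_index + i - 1L))
      write_png16(frames[[i]], f)
      f
    }, character(1))
    return(invisible(files))
  }
  f <- file.path(out_dir, "frames.raw")
  write_raw_stack(frames, f, frame_rate_hz)
  invisible(c(f, paste0(f, ".json")))
}

#' Write frames as a raw float stack
#'
#' Little-endian 32-bit floats, frame-major (each frame stored in R's native
#' column-major `[H, W, 3]` order), with a JSON sidecar (`<path>.json`)
#' recording dimensions, frame count and rate.  Lossless for float32 data.
#'
#' @param frames list of frames.
#' @param path output path.
#' @param frame_rate_hz recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_raw_stack <- function(frames, path, frame_rate_hz = 60) {
  stopifnot(length(frames) >= 1)
  d <- dim(frames[[1]])
  con <- file(path, "wb")
  on.exit(close(con))
  for (fr in frames) {
    if (min(fr) < 0 || max(fr) > 1)
      stop("frame values outside [0, 1]; tone-map before writing")
    writeBin(as.numeric(fr), con, size = 4, endian = "little")
  }
  jsonlite::write_json(
    list(height_px = d[1], width_px = d[2], channels = 3L,
         n_frames = length(frames), frame_rate_hz = frame_rate_hz,
         dtype = "float32", byte_order = "little",
         layout = "frame-major; column-major [H, W, 3] within frame"),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a raw float stack
#'
#' @param path path written by [write_raw_stack()].
#' @return list of frames.
#' @export
read_raw_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$height_px * meta$width_px * meta$channels
  con <- file(path, "rb")
  on.exit(close(con))
  lapply(seq_len(meta$n_frames), function(i) {
    v <- readBin(con, numeric(), n = n, size = 4, endian = "little")
    array(v, dim = c(meta$height_px, meta$width_px, meta$channels))
  })
}

#' Write the event log as TSV
#'
#' Columns `frame`, `time_s` (printed with 6 decimals, computed exactly as
#' `frame / frame_rate` so there is no cumulative drift), `channel`, `edge`.
#'
#' @param log event data.frame (`frame`, `time_s`, `channel`, `edge`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(all(c("frame", "time_s", "channel", "edge") %in% names(log)))
  out <- data.frame(frame = log$frame,
                    time_s = sprintf("%.6f", log$time_s),
                    channel = log$channel, edge = log$edge)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event log written by [write_event_log()]
#'
#' @param path TSV path.
#' @return data.frame with `frame`, `time_s`, `channel`, `edge`.
#' @export
read_event_log <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  df$time_s <- as.numeric(df$time_s)
  df
}
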