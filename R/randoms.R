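#' Seed an xorshift128 generator state
#'
#' Grid noise (random checkerboards, random shape motion) is driven by a
#' 128-bit xorshift generator.  The state consists of four 32-bit unsigned
#' words `(x, y, z, w)` which must never be all zero; a zero seed is remapped
#' to 1 to enforce this.  The three fixed companion words are the classic
#' reference constants, so that `seed_state(123456789)` reproduces the
#' generator's published test state and the stream can be cross-checked
#' against any independent transliteration.
#'
#' @param seed non-negative integer seed.
#' @return object of class `xs128_state`: numeric vector `(x, y, z, w)` of
#'   exact 32-bit unsigned values.
#' @references Marsaglia, G. (2003) Xorshift RNGs. J. Stat. Software 8(14).
#' @seealso [next_u32()], [fill_grid()]
#' @export
seed_state <- function(seed) {
  stopifnot(.is_count(seed), seed >= 0, seed < 2^32)
  x <- if (seed == 0) 1 else seed
  structure(c(x = x, y = 362436069, z = 521288629, w = 88675123),
            class = "xs128_state")
}

.check_state <- function(state) {
  if (!inherits(state, "xs128_state") || length(state) != 4L)
    stop("not an xs128_state")
  if (all(state == 0)) stop("all-zero xorshift state is invalid")
  invisible(state)
}

#' Draw the next 32-bit word
#'
#' One xorshift128 update: `t = x XOR (x << 11); t = t XOR (t >> 8)`, the
#' state words shift down, and `w <- (w XOR (w >> 19)) XOR t` becomes the
#' output.  All operations act on 32-bit unsigned words.
#'
#' @param state an `xs128_state`.
#' @return list with `word` (the new `w`, as a double in `[0, 2^32)`) and
#'   `state` (the advanced state).
#' @export
next_u32 <- function(state) {
  .check_state(state)
  r <- .xs128_fill(unclass(state), 1)
  list(word = r$words[1],
       state = structure(r$state, names = c("x", "y", "z", "w"),
                         class = "xs128_state"))
}

#' Draw a block of words from the stream
#'
#' @param state an `xs128_state`.
#' @param n number of draws.
#' @return list with `words` (numeric vector of u32 values) and `state`.
#' @export
draw_u32 <- function(state, n) {
  .check_state(state)
  stopifnot(.is_count(n), n >= 0)
  r <- .xs128_fill(unclass(state), n)
  list(words = r$words,
       state = structure(r$state, names = c("x", "y", "z", "w"),
                         class = "xs128_state"))
}

#' Fill a 2D grid of random words
#'
#' Fills a `rows x cols` grid in row-major order (row 1 left-to-right, then
#' row 2, ...) with successive generator draws.  The documented fill order
#' makes the stream position a pure function of the number of cells, so any
#' re-implementation (including a parallel one) can be compared cell by cell.
#'
#' @param state an `xs128_state`.
#' @param rows,cols grid dimensions (>= 1).
#' @return list with `grid` (a `random_grid`: `rows x cols` numeric matrix of
#'   u32 words) and `state` advanced by `rows * cols` draws.
#' @export
fill_grid <- function(state, rows, cols) {
  .check_state(state)
  stopifnot(.is_count(rows), rows >= 1, .is_count(cols), cols >= 1)
  r <- draw_u32(state, rows * cols)
  g <- matrix(r$words, nrow = rows, ncol = cols, byrow = TRUE)
  class(g) <- c("random_grid", class(g))
  list(grid = g, state = r$state)
}

#' Shift a random grid, refreshing only the vacated border
#'
#' Translates the existing words by `(dx, dy)` grid cells (positive `dx`
#' moves content right, positive `dy` moves it down) and fills only the
#' vacated cells with fresh draws, in row-major order over the vacated
#' region.  This is the economical update for drifting random patterns:
#' exactly `rows*|dx| + (cols-|dx|)*|dy|` new words are consumed.
#'
#' @param grid a `random_grid`.
#' @param dx,dy shift in cells; `|dx| < cols`, `|dy| < rows`.
#' @param state an `xs128_state`.
#' @return list with `grid` and `state`.
#' @export
shift_grid <- function(grid, dx, dy, state) {
  stopifnot(inherits(grid, "random_grid"),
            .is_count(dx), .is_count(dy))
  .check_state(state)
  nr <- nrow(grid); nc <- ncol(grid)
  if (abs(dx) >= nc || abs(dy) >= nr)
    stop("shift magnitude must be smaller than the grid")
  if (dx == 0 && dy == 0) return(list(grid = grid, state = state))
  out <- matrix(NA_real_, nr, nc)
  src_rows <- seq_len(nr) - dy
  src_cols <- seq_len(nc) - dx
  ok_r <- src_rows >= 1 & src_rows <= nr
  ok_c <- src_cols >= 1 & src_cols <= nc
  out[ok_r, ok_c] <- grid[src_rows[ok_r], src_cols[ok_c]]
  vac <- which(t(is.na(out)))           # row-major order over vacated cells
  if (length(vac)) {
    r <- draw_u32(state, length(vac))
    tout <- t(out)
    tout[vac] <- r$words
    out <- t(tout)
    state <- r$state
  }
  class(out) <- c("random_grid", class(out))
  list(grid = out, state = state)
}

#' Map a random grid to a checkerboard frame
#'
#' Each word is first spread to the unit interval as `u = word / 2^32`
#' (half-open).  `binary` colors a cell `high` when `u >= 0.5` and `low`
#' otherwise; `grayscale` maps linearly, `low + u * (high - low)`;
#' `color` uses three independent grids, one per RGB channel.  Each grid
#' cell covers a `cell_px x cell_px` block of pixels.
#'
#' @param grid a `random_grid`, or for `mode = "color"` a list of three.
#' @param mode one of `"binary"`, `"grayscale"`, `"color"`.
#' @param low,high cell colors (scalars or RGB triples).
#' @param cell_px pixels per grid cell (>= 1).
#' @return a frame of size `(rows*cell_px) x (cols*cell_px) x 3`.
#' @export
grid_to_checkerboard <- function(grid, mode = c("binary", "grayscale", "color"),
                                 low = 0, high = 1, cell_px = 1) {
  mode <- match.arg(mode)
  stopifnot(.is_count(cell_px), cell_px >= 1)
  lo <- .as_rgb(low); hi <- .as_rgb(high)
  expand <- function(m) {
    m[rep(seq_len(nrow(m)), each = cell_px),
      rep(seq_len(ncol(m)), each = cell_px), drop = FALSE]
  }
  if (mode == "color") {
    if (!(is.list(grid) && length(grid) == 3L))
      stop("color mode needs a list of three grids")
    us <- lapply(grid, function(g) expand(unclass(g) / 2^32))
    arr <- array(0, dim = c(nrow(us[[1]]), ncol(us[[1]]), 3))
    for (ch in 1:3) arr[, , ch] <- lo[ch] + us[[ch]] * (hi[ch] - lo[ch])
    return(arr)
  }
  u <- expand(unclass(grid) / 2^32)
  arr <- array(0, dim = c(nrow(u), ncol(u), 3))
  if (mode == "binary") {
    b <- u >= 0.5
    for (ch in 1:3) arr[, , ch] <- ifelse(b, hi[ch], lo[ch])
  } else {
    for (ch in 1:3) arr[, , ch] <- lo[ch] + u * (hi[ch] - lo[ch])
  }
  arr
}

#' Export random grids as text
#'
#' Writes one block per frame: a header line `frame <k> rows <r> cols <c>`
#' followed by `r` lines of `c` space-separated decimal 32-bit words.  The
#' format round-trips losslessly through [read_randoms()] so a stimulus's
#' noise stream can be handed to analysis software.
#'
#' @param grids a list of `random_grid` objects (frame order).
#' @param path output file path.
#' @param frame_indices optional integer frame labels (default `0:(n-1)`).
#' @return `path`, invisibly.
#' @export
export_randoms <- function(grids, path, frame_indices = NULL) {
  if (!is.list(grids) || length(grids) == 0L)
    stop("grids must be a non-empty list")
  if (is.null(frame_indices)) frame_indices <- seq_along(grids) - 1L
  stopifnot(length(frame_indices) == length(grids))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(grids)) {
    g <- grids[[i]]
    writeLines(sprintf("frame %d rows %d cols %d",
                       frame_indices[i], nrow(g), ncol(g)), con)
    writeLines(apply(format(unclass(g), scientific = FALSE, trim = TRUE),
                     1, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Read grids written by [export_randoms()]
#'
#' @param path file path.
#' @return list of `random_grid` matrices, with frame indices as names.
#' @export
read_randoms <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  out <- list(); idx <- character()
  i <- 1L
  while (i <= length(lines)) {
    h <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(h) != 6L || h[1] != "frame")
      stop("malformed randoms header at line ", i)
    r <- as.integer(h[4]); cl <- as.integer(h[6])
    block <- lines[(i + 1L):(i + r)]
    m <- matrix(as.numeric(unlist(strsplit(trimws(block), "\\s+"))),
                nrow = r, ncol = cl, byrow = TRUE)
    class(m) <- c("random_grid", class(m))
    out[[length(out) + 1L]] <- m
    idx <- c(idx, h[2])
    i <- i + r + 1L
  }
  names(out) <- idx
  out
}
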