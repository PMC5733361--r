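# 16-bit PNG output.  Frames are written as RGB, 16 bits per channel,
# quantized as q = round(v * 65535) with halves rounded away from zero.
# The IDAT payload is the zlib (RFC 1950) stream produced by memCompress;
# chunk CRCs come from the package's CRC-32.

# big-endian u32 from a double (values up to 2^32 - 1, beyond int range)
.u32_be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 2^24 %% 256, x %/% 2^16 %% 256, x %/% 2^8 %% 256,
           x %% 256))
}

.png_chunk <- function(type, data) {
  td <- c(charToRaw(type), data)
  c(.u32_be(length(data)), td, .u32_be(.crc32(td)))
}

#' Write a frame as a 16-bit-per-channel PNG
#'
#' Quantization is `q = round(v * 65535)` with ties rounded away from zero
#' (so 0.5 maps to 32768), clamped to the valid range.  Files round-trip
#' through `png::readPNG` within quantization error (1/65535).
#'
#' @param frame `H x W x 3` frame with values in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_png16 <- function(frame, path) {
  .check_frame(frame)
  if (min(frame) < 0 || max(frame) > 1)
    stop("frame values outside [0, 1]; tone-map before writing")
  h <- dim(frame)[1]; w <- dim(frame)[2]
  q <- floor(frame * 65535 + 0.5)           # round-half-away-from-zero
  q <- pmin(pmax(q, 0), 65535)
  # interleave to R,G,B per pixel, row by row, 16-bit big-endian
  samp <- aperm(q, c(3, 2, 1))              # [channel, col, row]
  by <- writeBin(as.integer(samp), raw(), size = 2, endian = "big")
  dim(by) <- c(2L * 3L * w, h)
  scan <- rbind(as.raw(0L), by)             # filter byte 0 per scanline
  z <- memCompress(as.raw(scan), "gzip")
  if (z[1] != as.raw(0x78))
    stop("compressor did not produce a zlib stream")   # defensive
  ihdr <- c(.u32_be(w), .u32_be(h),
            as.raw(c(16L, 2L, 0L, 0L, 0L)))
  out <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
           .png_chunk("IHDR", ihdr),
           .png_chunk("IDAT", z),
           .png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read a frame written by [write_png16()]
#'
#' Thin wrapper over `png::readPNG` returning an `H x W x 3` array.
#'
#' @param path PNG path.
#' @return frame array in `[0, 1]`.
#' @export
read_png16 <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- .gray_frame(img)
  img[, , 1:3, drop = FALSE]
}
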