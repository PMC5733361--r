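# Independent scalar transliteration of the xorshift128 update, written
# directly from the published pseudocode.  Works on doubles holding exact
# 32-bit unsigned values; 32-bit XOR is done on 16-bit halves to stay within
# R's integer range.  This is the oracle the package's C++ stream is checked
# against — it deliberately shares no code with the implementation.
xs_ref_xor32 <- function(a, b) {
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi * 65536 + lo
}

xs_ref_step <- function(s) {
  t <- xs_ref_xor32(s[1], (s[1] * 2048) %% 4294967296)
  t <- xs_ref_xor32(t, t %/% 256)
  w <- xs_ref_xor32(xs_ref_xor32(s[4], s[4] %/% 524288), t)
  c(s[2], s[3], s[4], w)
}

xs_ref_stream <- function(seed, n) {
  s <- c(if (seed == 0) 1 else seed, 362436069, 521288629, 88675123)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- xs_ref_step(s)
    out[i] <- s[4]
  }
  out
}

# tiny helpers used across test files
const_frame <- function(geo, v) new_frame(geo, v)

rand_frame <- function(geo, seed = 1) {
  set.seed(seed)
  array(runif(geo$height_px * geo$width_px * 3),
        dim = c(geo$height_px, geo$width_px, 3))
}

gray_stimulus <- function(v, frames = 1) {
  stimulus(list(component("primer", "fullfield", list(intensity = v))),
           frames)
}
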