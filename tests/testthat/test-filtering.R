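test_that("kernel constructors enforce their normalizations", {
  g <- make_spatial_kernel("gaussian", sigma = 1.5)
  expect_equal(sum(g$weights), 1, tolerance = 1e-12)
  expect_true(all(dim(g$weights) %% 2 == 1))
  d <- make_spatial_kernel("dog", sigma_center = 1, sigma_surround = 2.5,
                           gain_center = 2, gain_surround = 1.2)
  expect_lt(abs(sum(d$weights)), 1e-12)
  expect_error(make_spatial_kernel("dog", sigma_center = 2,
                                   sigma_surround = 1), "surround")
  expect_error(make_spatial_kernel("gaussian", sigma = 0))
  # frequency kernels: DC behavior
  lp <- make_spatial_kernel("freq_lowpass", cutoff = 0.1)
  expect_equal(lp$transfer(0, 0), 1)
  hp <- make_spatial_kernel("freq_highpass", cutoff = 0.1)
  expect_equal(hp$transfer(0, 0), 0)
})

test_that("direct convolution matches impulse/identity expectations", {
  geo <- field_geometry(16, 16)
  x <- rand_frame(geo, 2)
  expect_equal(convolve_direct(x, matrix(1, 1, 1)), x)
  # 3x3 box stamped at a one-hot location
  oh <- matrix(0, 16, 16); oh[8, 9] <- 1
  box <- matrix(1, 3, 3)
  y <- convolve_direct(oh, box)
  expect_equal(y[7:9, 8:10], matrix(1, 3, 3))
  expect_equal(sum(y), 9)
  # zero-integral DoG maps a homogeneous region to zero wherever the
  # kernel support lies fully inside the field (zero padding rules the rim)
  d <- make_spatial_kernel("dog", sigma_center = 1, sigma_surround = 2)
  r <- max(dim(d$weights)) %/% 2
  geo48 <- field_geometry(48, 48)
  cf <- convolve_direct(const_frame(geo48, 0.6), d)
  interior <- cf[(r + 1):(48 - r), (r + 1):(48 - r), ]
  expect_lt(max(abs(interior)), 1e-12)
  expect_error(convolve_direct(x, make_spatial_kernel("freq_lowpass")),
               "spatial-domain")
})

test_that("FFT convolution equals direct convolution (oracle property)", {
  set.seed(11)
  for (i in 1:10) {
    h <- sample(12:40, 1); w <- sample(12:40, 1)
    kh <- sample(c(3, 5, 7, 9), 1); kw <- sample(c(3, 5, 7, 9), 1)
    x <- matrix(runif(h * w), h, w)
    k <- matrix(runif(kh * kw) - 0.3, kh, kw)
    expect_lt(max(abs(convolve_fft(x, k) - convolve_direct(x, k))), 1e-10)
  }
})

test_that("frequency-specified kernels act on the spectrum", {
  geo <- field_geometry(24, 24)
  x <- rand_frame(geo, 3)
  ident <- make_spatial_kernel("freq_custom",
                               transfer = function(fx, fy) 1 + 0 * fx)
  expect_lt(max(abs(convolve_fft(x, ident) - x)), 1e-12)
  lp <- make_spatial_kernel("freq_lowpass", cutoff = 0.03)
  y <- convolve_fft(x, lp)
  expect_lt(var(as.numeric(y)), var(as.numeric(x)))
  # DC is preserved by an all-pass-at-zero filter (cyclic mean invariance)
  expect_equal(mean(y), mean(x), tolerance = 1e-12)
})

test_that("linear filters superpose and commute with translation", {
  set.seed(5)
  k <- make_spatial_kernel("gabor", sigma = 1.2, frequency = 0.2)
  x <- matrix(runif(400), 20, 20)
  y <- matrix(runif(400), 20, 20)
  expect_equal(convolve_fft(2 * x + 3 * y, k),
               2 * convolve_fft(x, k) + 3 * convolve_fft(y, k),
               tolerance = 1e-10)
  # shift invariance, checked where neither the padded top row nor the
  # dropped bottom row can reach the kernel window
  xs <- rbind(matrix(0, 1, 20), x[-20, ])      # shift down by one
  ys <- convolve_direct(xs, k)
  y0 <- convolve_direct(x, k)
  r <- nrow(k$weights) %/% 2
  expect_equal(ys[(r + 2):(19 - r), (r + 1):(20 - r)],
               y0[(r + 1):(18 - r), (r + 1):(20 - r)], tolerance = 1e-12)
})

test_that("median filtering removes outliers and respects windows", {
  geo <- field_geometry(12, 12)
  f <- const_frame(geo, 0.5)
  expect_equal(median_filter(f, 1), f)
  f2 <- f; f2[6, 6, ] <- 1
  expect_equal(median_filter(f2, 3), f)
  expect_equal(median_filter(f, 5), f)
  expect_error(median_filter(f, 4), "window")
})

test_that("temporal kernels follow the standard window formulas", {
  expect_equal(as.numeric(make_temporal_kernel("rectangular", 4)),
               rep(0.25, 4))
  # hann over 3 taps is (0, 1, 0) before normalization
  expect_equal(as.numeric(make_temporal_kernel("hann", 3)), c(0, 1, 0))
  hm <- make_temporal_kernel("hamming", 5)
  raw <- 0.54 - 0.46 * cos(2 * pi * (0:4) / 4)
  expect_equal(as.numeric(hm), raw / sum(raw))
  tri <- make_temporal_kernel("triangular", 5)
  expect_equal(sum(tri), 1)
  ex <- make_temporal_kernel("exponential", 6, a = 0.5)
  expect_equal(as.numeric(ex), 0.5^(0:5))
  expect_error(make_temporal_kernel("exponential", 6, a = 1.2), "\\(0, 1\\)")
  cd <- make_temporal_kernel("cell_dog", 16)
  expect_lt(abs(sum(cd)), 1e-12)
  expect_gt(cd[3], 0)          # positive lobe near mu1 = 2
  expect_lt(cd[7], 0)          # negative lobe near mu2 = 6
})

test_that("temporal convolution is causal with zero (or held) prehistory", {
  geo <- field_geometry(4, 4)
  delta <- c(1, 0, 0)
  st <- temporal_state(delta)
  frames <- lapply(1:5, function(i) const_frame(geo, i / 10))
  for (fr in frames) {
    r <- temporal_convolve(st, fr)
    st <- r$state
    expect_identical(r$frame, fr)        # delta kernel: identity stream
  }
  # unit-sum rectangular window on a constant-1 stream reaches 1 at t >= L-1
  st <- temporal_state(make_temporal_kernel("rectangular", 3))
  outs <- numeric(5)
  for (t in 1:5) {
    r <- temporal_convolve(st, const_frame(geo, 1))
    st <- r$state
    outs[t] <- r$frame[1, 1, 1]
  }
  expect_equal(outs, c(1 / 3, 2 / 3, 1, 1, 1))
  # step through an (unnormalized) exponential kernel: partial geometric sums
  a <- 0.6; L <- 8
  st <- temporal_state(make_temporal_kernel("exponential", L, a = a))
  outs <- numeric(12)
  for (t in 1:12) {
    r <- temporal_convolve(st, const_frame(geo, 1))
    st <- r$state
    outs[t] <- r$frame[1, 1, 1]
  }
  expected <- vapply(1:12, function(t)
    sum(a^(0:(min(t - 1, L - 1)))), numeric(1))
  expect_equal(outs, expected, tolerance = 1e-12)
  # hold-first prehistory: constant stream is a fixed point from frame 0
  st <- temporal_state(make_temporal_kernel("rectangular", 4), "hold")
  r <- temporal_convolve(st, const_frame(geo, 0.7))
  expect_equal(r$frame, const_frame(geo, 0.7))
})

test_that("output at frame t never depends on later frames", {
  geo <- field_geometry(4, 4)
  kern <- make_temporal_kernel("exponential", 5, a = 0.7)
  run <- function(values) {
    st <- temporal_state(kern)
    out <- list()
    for (v in values) {
      r <- temporal_convolve(st, const_frame(geo, v))
      st <- r$state
      out[[length(out) + 1L]] <- r$frame
    }
    out
  }
  a <- run(c(0.1, 0.9, 0.4, 0.0, 0.0))
  b <- run(c(0.1, 0.9, 0.4, 1.0, 0.3))   # perturb only frames 3 and 4
  for (t in 1:3) expect_identical(a[[t]], b[[t]])
})

test_that("the recursive LTI system realizes its impulse response", {
  geo <- field_geometry(3, 3)
  sys <- lti_system(0.5 + 0i, 1 + 0i, direct = 0)
  st <- lti_state(sys, geo)
  imp <- c(1, rep(0, 5))
  outs <- numeric(6)
  for (t in 1:6) {
    r <- lti_step(st, const_frame(geo, imp[t]))
    st <- r$state
    outs[t] <- r$frame[1, 1, 1]
  }
  expect_equal(outs, c(0, 0.5, 0.25, 0.125, 0.0625, 0.03125))
  expect_equal(outs, lti_impulse_response(sys, 6))
  # zero input -> zero output
  st <- lti_state(sys, geo)
  for (t in 1:4) {
    r <- lti_step(st, const_frame(geo, 0))
    st <- r$state
    expect_true(all(r$frame == 0))
  }
  expect_error(lti_system(1.01, 1), "unstable")
})

test_that("LTI filtering equals direct convolution for exponential kernels", {
  geo <- field_geometry(16, 16)
  # kernel taps are exactly a sum of the system's exponentials
  a1 <- 0.5; a2 <- 0.3; L <- 40
  taps <- c(0.2, 0.7 * a1^(1:(L - 1)) + 0.3 * a2^(1:(L - 1)))
  # poles/coefs chosen so h_k = 0.7 a1^k + 0.3 a2^k for k >= 1
  sys <- lti_system(c(a1, a2), c(0.7, 0.3), direct = 0.2)
  expect_equal(lti_impulse_response(sys, L), taps, tolerance = 1e-12)
  st_c <- temporal_state(taps)
  st_l <- lti_state(sys, geo)
  set.seed(8)
  worst <- 0
  for (t in 1:60) {
    x <- rand_frame(geo, seed = t)
    rc <- temporal_convolve(st_c, x); st_c <- rc$state
    rl <- lti_step(st_l, x); st_l <- rl$state
    # beyond L frames the truncated convolution drops only the tiny tail
    worst <- max(worst, max(abs(rc$frame - rl$frame)))
  }
  expect_lt(worst, 1e-8)
})

test_that("Prony fitting recovers exponential kernels and reports misfit", {
  k1 <- make_temporal_kernel("exponential", 20, a = 0.8)
  f1 <- fit_exponentials(k1, 1)
  expect_equal(Re(f1$system$poles), 0.8, tolerance = 1e-9)
  expect_lt(f1$residual, 1e-8)
  # sum of two real exponentials
  taps <- 1.5 * 0.7^(0:19) + 0.5 * 0.2^(0:19)
  f2 <- fit_exponentials(taps, 2)
  expect_lt(f2$residual, 1e-6)
  expect_equal(sort(Re(f2$system$poles)), c(0.2, 0.7), tolerance = 1e-6)
  # the rectangular window is not representable by decaying exponentials:
  # linear prediction lands on the unit circle and the system is rejected
  expect_error(fit_exponentials(make_temporal_kernel("rectangular", 12), 1),
               "rejected")
  # a truncated-but-decaying misfit case: one pole cannot carry two decays
  f3 <- fit_exponentials(taps, 1)
  expect_gt(f3$residual, 1e-6)
  expect_error(fit_exponentials(k1, 12))   # L > 2 * n_poles violated
})
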