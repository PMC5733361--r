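#' Construct a spatial filter kernel
#'
#' Spatial-domain kernels (`gaussian`, `dog`, `gabor`) are materialized as
#' odd-sized weight matrices whose support is auto-sized to a 4-sigma
#' truncation radius of the widest Gaussian involved.  The Gaussian is
#' normalized to unit sum; the difference-of-Gaussians has its surround lobe
#' rescaled so the discrete sum is exactly zero (a zero-integral band-pass,
#' so homogeneous regions map to zero).  Frequency-domain kernels
#' (`freq_lowpass`, `freq_highpass`, `freq_bandpass`, `freq_custom`) are
#' stored as radial transfer functions and realized on the FFT grid of the
#' frame they are applied to; they act with cyclic convolution semantics.
#'
#' @param kind kernel kind.
#' @param sigma Gaussian/Gabor envelope width (> 0), pixels.
#' @param sigma_center,sigma_surround DoG widths (`center < surround`).
#' @param gain_center,gain_surround DoG lobe gains.
#' @param frequency Gabor carrier frequency, cycles/pixel.
#' @param orientation,phase Gabor carrier orientation and phase, radians.
#' @param gain overall Gabor gain.
#' @param cutoff low/high-pass cutoff, cycles/pixel in `(0, 0.5]`.
#' @param low,high band-pass edges, cycles/pixel.
#' @param transfer for `freq_custom`: `function(fx, fy)` returning the
#'   transfer value at signed frequency coordinates (cycles/pixel).
#' @return object of class `spatial_kernel` with fields `domain`
#'   (`"spatial"` or `"frequency"`), `weights`, `kind`, `params`.
#' @export
make_spatial_kernel <- function(kind = c("gaussian", "dog", "gabor",
                                         "freq_lowpass", "freq_highpass",
                                         "freq_bandpass", "freq_custom"),
                                sigma = 1,
                                sigma_center = 1, sigma_surround = 2,
                                gain_center = 1, gain_surround = 1,
                                frequency = 0.1, orientation = 0, phase = 0,
                                gain = 1, cutoff = 0.1, low = 0.05,
                                high = 0.2, transfer = NULL) {
  kind <- match.arg(kind)
  if (startsWith(kind, "freq_")) {
    tf <- switch(kind,
      freq_lowpass = function(fx, fy) as.numeric(sqrt(fx^2 + fy^2) <= cutoff),
      freq_highpass = function(fx, fy) as.numeric(sqrt(fx^2 + fy^2) > cutoff),
      freq_bandpass = function(fx, fy) {
        fr <- sqrt(fx^2 + fy^2)
        as.numeric(fr >= low & fr <= high)
      },
      freq_custom = {
        if (is.null(transfer)) stop("freq_custom needs a transfer function")
        transfer
      })
    return(structure(list(domain = "frequency", kind = kind, weights = NULL,
                          transfer = tf,
                          params = list(cutoff = cutoff, low = low,
                                        high = high)),
                     class = "spatial_kernel"))
  }
  gauss2d <- function(s, r) {
    v <- seq(-r, r)
    g <- exp(-outer(v^2, v^2, "+") / (2 * s^2))
    g / sum(g)
  }
  w <- switch(kind,
    gaussian = {
      stopifnot(sigma > 0)
      gauss2d(sigma, max(1L, ceiling(4 * sigma)))
    },
    dog = {
      stopifnot(sigma_center > 0, sigma_surround > 0)
      if (sigma_surround <= sigma_center)
        stop("dog requires sigma_surround > sigma_center")
      r <- max(1L, ceiling(4 * sigma_surround))
      g1 <- gain_center * gauss2d(sigma_center, r)
      g2 <- gain_surround * gauss2d(sigma_surround, r)
      g1 - g2 * (sum(g1) / sum(g2))    # exact zero integral
    },
    gabor = {
      stopifnot(sigma > 0, frequency > 0)
      r <- max(1L, ceiling(4 * sigma))
      v <- seq(-r, r)
      xx <- matrix(v, 2 * r + 1, 2 * r + 1, byrow = TRUE)
      yy <- matrix(v, 2 * r + 1, 2 * r + 1)
      env <- exp(-(xx^2 + yy^2) / (2 * sigma^2))
      gain * env * cos(2 * pi * frequency *
                         (xx * cos(orientation) + yy * sin(orientation)) +
                         phase)
    })
  structure(list(domain = "spatial", kind = kind, weights = w,
                 transfer = NULL,
                 params = list(sigma = sigma, sigma_center = sigma_center,
                               sigma_surround = sigma_surround)),
            class = "spatial_kernel")
}

#' Direct spatial convolution
#'
#' Per-channel 2D linear convolution with zero padding outside the field;
#' the output has the same size as the input.  Values may leave `[0, 1]`
#' (e.g. after zero-integral band-pass filtering); renorm tone mapping is
#' the intended follow-up.  Efficient for small kernels.
#'
#' @param frame `H x W x 3` frame (a plain matrix is also accepted).
#' @param kernel a spatial-domain [make_spatial_kernel()], or a raw odd-sized
#'   weight matrix.
#' @return filtered frame, same shape.
#' @export
convolve_direct <- function(frame, kernel) {
  k <- .kernel_weights(kernel)
  .apply_channels(frame, function(m) .conv2_direct(m, k))
}

.kernel_weights <- function(kernel) {
  if (is.matrix(kernel)) k <- kernel
  else {
    stopifnot(inherits(kernel, "spatial_kernel"))
    if (kernel$domain != "spatial")
      stop("direct convolution requires a spatial-domain kernel")
    k <- kernel$weights
  }
  if (any(dim(k) %% 2 == 0)) stop("spatial kernels must have odd dimensions")
  k
}

.apply_channels <- function(frame, f) {
  if (is.matrix(frame)) return(f(frame))
  .check_frame(frame)
  out <- frame
  for (ch in 1:3) out[, , ch] <- f(frame[, , ch])
  out
}

# Sum of shifted copies; zero padding outside. Flipped-kernel convolution:
# y[i,j] = sum_{a,b} k[a,b] * x[i - (a - ca), j - (b - cb)].
.conv2_direct <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  kh <- nrow(k); kw <- ncol(k)
  ca <- (kh + 1L) %/% 2L; cb <- (kw + 1L) %/% 2L
  out <- matrix(0, h, w)
  for (a in seq_len(kh)) for (b in seq_len(kw)) {
    wt <- k[a, b]
    if (wt == 0) next
    oi <- a - ca; oj <- b - cb
    ri <- max(1, 1 + oi):min(h, h + oi)
    rj <- max(1, 1 + oj):min(w, w + oj)
    out[ri, rj] <- out[ri, rj] + wt * x[ri - oi, rj - oj, drop = FALSE]
  }
  out
}

#' FFT-domain spatial filtering
#'
#' For spatial-domain kernels this computes the identical zero-padded linear
#' convolution as [convolve_direct()] (padded FFT, cropped back to size);
#' it is the efficient route for large kernels.  Frequency-specified kernels
#' multiply the frame's spectrum directly, which implies cyclic boundary
#' semantics (there is no spatial support to pad with).
#'
#' @inheritParams convolve_direct
#' @param kernel any [make_spatial_kernel()].
#' @return filtered frame.
#' @export
convolve_fft <- function(frame, kernel) {
  if (is.matrix(kernel) ||
      (inherits(kernel, "spatial_kernel") && kernel$domain == "spatial")) {
    k <- .kernel_weights(kernel)
    return(.apply_channels(frame, function(m) .conv2_fft(m, k)))
  }
  stopifnot(inherits(kernel, "spatial_kernel"))
  .apply_channels(frame, function(m) .filter_freq(m, kernel$transfer))
}

.conv2_fft <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  kh <- nrow(k); kw <- ncol(k)
  ph <- h + kh - 1L; pw <- w + kw - 1L
  xp <- matrix(0, ph, pw); xp[1:h, 1:w] <- x
  kp <- matrix(0, ph, pw); kp[1:kh, 1:kw] <- k
  full <- Re(fft(fft(xp) * fft(kp), inverse = TRUE)) / (ph * pw)
  ca <- (kh + 1L) %/% 2L; cb <- (kw + 1L) %/% 2L
  full[ca:(ca + h - 1L), cb:(cb + w - 1L)]
}

# Multiply the spectrum by a transfer function sampled on the FFT grid
# (signed frequencies in cycles/pixel, DC at [1, 1]).
.filter_freq <- function(x, tf) {
  h <- nrow(x); w <- ncol(x)
  fy <- (seq_len(h) - 1) / h; fy[fy >= 0.5] <- fy[fy >= 0.5] - 1
  fx <- (seq_len(w) - 1) / w; fx[fx >= 0.5] <- fx[fx >= 0.5] - 1
  FX <- matrix(fx, h, w, byrow = TRUE)
  FY <- matrix(fy, h, w)
  tr <- tf(FX, FY)
  dim(tr) <- c(h, w)
  Re(fft(fft(x) * tr, inverse = TRUE)) / (h * w)
}

#' Moving-median filter
#'
#' Nonlinear de-noising filter: per-channel moving median over an odd
#' square window, with edge-replicated borders.
#'
#' @inheritParams convolve_direct
#' @param window odd window size (>= 1).
#' @return filtered frame.
#' @export
median_filter <- function(frame, window) {
  stopifnot(.is_count(window), window >= 1, window %% 2 == 1)
  if (window == 1) return(frame)
  r <- (window - 1L) %/% 2L
  .apply_channels(frame, function(m) {
    h <- nrow(m); w <- ncol(m)
    k <- window^2
    stack <- array(0, dim = c(h, w, k))
    s <- 1L
    for (di in -r:r) for (dj in -r:r) {
      ri <- pmin(pmax(seq_len(h) + di, 1), h)
      rj <- pmin(pmax(seq_len(w) + dj, 1), w)
      stack[, , s] <- m[ri, rj]
      s <- s + 1L
    }
    mid <- (k + 1L) %/% 2L
    apply(stack, c(1, 2), function(v) sort(v, partial = mid)[mid])
  })
}

#' Construct a causal temporal kernel
#'
#' Temporal filtering treats each pixel's value across frames as a discrete
#' time signal; only past frames enter the filter (filtering that would need
#' future frames is obtained by adding a presentation delay).  Tap 0 weights
#' the current frame.
#'
#' Window kernels (`rectangular`, `triangular`, `hamming`, `hann`) use the
#' standard window formulas over `length` taps and are normalized to unit
#' sum.  `exponential` is the raw attenuation `a^k` (unnormalized, so a unit
#' step converges to the geometric sum `1/(1-a)`).  `cell_dog` is a
#' difference of two Gaussians in time — a positive lobe followed by a
#' negative lobe, the usual coarse model of a retinal cell's biphasic
#' temporal response — rescaled to exactly zero sum.
#'
#' @param kind kernel kind.
#' @param length number of taps `L >= 1`.
#' @param a exponential decay factor, in `(0, 1)`.
#' @param mu1,sigma1,w1 first (positive) temporal Gaussian: center tap,
#'   width, weight.
#' @param mu2,sigma2,w2 second (negative) lobe.
#' @return object of class `temporal_kernel` (numeric taps with attributes).
#' @export
make_temporal_kernel <- function(kind = c("rectangular", "triangular",
                                          "hamming", "hann", "exponential",
                                          "cell_dog"),
                                 length = 5,
                                 a = 0.85,
                                 mu1 = 2, sigma1 = 1, w1 = 1,
                                 mu2 = 6, sigma2 = 2, w2 = 0.5) {
  kind <- match.arg(kind)
  L <- length
  stopifnot(.is_count(L), L >= 1)
  k <- seq_len(L) - 1
  h <- switch(kind,
    rectangular = rep(1, L),
    triangular = if (L == 1) 1 else 1 - abs(2 * k / (L - 1) - 1),
    hamming = if (L == 1) 1 else 0.54 - 0.46 * cos(2 * pi * k / (L - 1)),
    hann = if (L == 1) 1 else 0.5 * (1 - cos(2 * pi * k / (L - 1))),
    exponential = {
      if (!(a > 0 && a < 1)) stop("exponential decay a must be in (0, 1)")
      a^k
    },
    cell_dog = {
      stopifnot(sigma1 > 0, sigma2 > 0, w1 > 0, w2 > 0)
      g1 <- w1 * exp(-(k - mu1)^2 / (2 * sigma1^2))
      g2 <- w2 * exp(-(k - mu2)^2 / (2 * sigma2^2))
      g1 - g2 * (sum(g1) / sum(g2))
    })
  if (kind %in% c("rectangular", "triangular", "hamming", "hann"))
    h <- h / sum(h)
  structure(h, class = "temporal_kernel", kind = kind)
}

#' Initialize temporal-convolution state
#'
#' @param kernel a [make_temporal_kernel()] (or plain numeric taps).
#' @param prestimulus how frames before the stimulus start are treated:
#'   `"zero"` (default) or `"hold"` (replicate the first frame).
#' @return mutable state for [temporal_convolve()].
#' @export
temporal_state <- function(kernel, prestimulus = c("zero", "hold")) {
  prestimulus <- match.arg(prestimulus)
  taps <- as.numeric(kernel)
  stopifnot(length(taps) >= 1)
  list(taps = taps, buffer = list(), prestimulus = prestimulus)
}

#' One step of causal temporal convolution
#'
#' Computes `y_t = sum_k h_k * frame_{t-k}` over the kernel's taps, treating
#' frames before the stimulus start as zero (or as held copies of the first
#' frame), and advances the ring buffer.
#'
#' @param state from [temporal_state()] (or returned by a previous call).
#' @param new_frame the current frame.
#' @return list with `frame` (the filtered output) and `state`.
#' @export
temporal_convolve <- function(state, new_frame) {
  taps <- state$taps
  L <- length(taps)
  if (length(state$buffer) == 0L && state$prestimulus == "hold" && L > 1L)
    state$buffer <- rep(list(new_frame), L - 1L)
  out <- taps[1] * new_frame
  nb <- length(state$buffer)
  if (L > 1L) for (k in 2:L) {
    if (k - 1L <= nb) out <- out + taps[k] * state$buffer[[k - 1L]]
  }
  if (L > 1L) {
    state$buffer <- c(list(new_frame), state$buffer)
    if (length(state$buffer) > L - 1L)
      state$buffer <- state$buffer[seq_len(L - 1L)]
  }
  list(frame = out, state = state)
}

#' Linear time-invariant recursive temporal filter
#'
#' A diagonal complex-exponential state system applied pointwise: per pixel
#' `y = d * x + sum_j Re(s_j)` followed by the update
#' `s_j <- z_j * (s_j + c_j * x)`.  Its impulse response is
#' `h_0 = d`, `h_k = sum_j Re(c_j * z_j^k)` for `k >= 1`, so memory per
#' pixel is constant regardless of the effective kernel length.
#'
#' @param poles complex vector `z_j`, all `|z_j| < 1`.
#' @param coefs complex vector `c_j`, same length.
#' @param direct real direct-path gain `d` (tap 0).
#' @return object of class `lti_system`.
#' @export
lti_system <- function(poles, coefs, direct = 0) {
  poles <- as.complex(poles); coefs <- as.complex(coefs)
  stopifnot(length(poles) == length(coefs), length(poles) >= 1)
  if (any(Mod(poles) >= 1)) stop("unstable system: |z| >= 1")
  structure(list(poles = poles, coefs = coefs, direct = direct),
            class = "lti_system")
}

#' Impulse response of an LTI system
#'
#' @param system an [lti_system()].
#' @param n number of taps to return.
#' @return numeric vector `h_0 .. h_{n-1}`.
#' @export
lti_impulse_response <- function(system, n) {
  k <- seq_len(n) - 1
  h <- vapply(k, function(kk) {
    if (kk == 0) system$direct
    else sum(Re(system$coefs * system$poles^kk))
  }, numeric(1))
  h
}

#' Initialize per-pixel LTI state
#'
#' @param system an [lti_system()].
#' @param geometry a [field_geometry()] (state covers every pixel/channel).
#' @return mutable state for [lti_step()].
#' @export
lti_state <- function(system, geometry) {
  stopifnot(inherits(system, "lti_system"))
  J <- length(system$poles)
  dims <- c(geometry$height_px, geometry$width_px, 3, J)
  list(system = system,
       s = array(complex(real = 0, imaginary = 0), dim = dims))
}

#' One step of the recursive LTI temporal filter
#'
#' @param state from [lti_state()] (or a previous call).
#' @param new_frame the current frame.
#' @return list with `frame` and `state`.
#' @export
lti_step <- function(state, new_frame) {
  sys <- state$system
  J <- length(sys$poles)
  out <- sys$direct * new_frame
  for (j in seq_len(J)) out <- out + Re(state$s[, , , j])
  for (j in seq_len(J))
    state$s[, , , j] <- sys$poles[j] *
      (state$s[, , , j] + sys$coefs[j] * new_frame)
  list(frame = out, state = state)
}

#' Fit an LTI system to a temporal kernel (Prony's method)
#'
#' Approximates kernel taps `h_1 .. h_{L-1}` by a sum of complex
#' exponentials: the poles come from a least-squares linear-prediction fit
#' (the taps are regressed on their own lags and the poles are the roots of
#' the prediction polynomial), the coefficients from a subsequent linear
#' solve against the exponential basis, and the direct term absorbs tap 0
#' exactly.  Smooth kernels (exponential decays, damped oscillations) are
#' represented essentially exactly; discontinuous ones (e.g. a rectangular
#' window) leave a residual, which is reported so the caller can decide
#' whether the recursive form is acceptable.
#'
#' @param kernel a [make_temporal_kernel()] or numeric taps, `L > 2*n_poles`.
#' @param n_poles number of exponential components (>= 1).
#' @return list with `system` (an [lti_system()]) and `residual` (max
#'   absolute fit error over the taps).  Unstable fitted poles
#'   (`|z| >= 1`) are an error: the system is rejected.
#' @export
fit_exponentials <- function(kernel, n_poles) {
  h <- as.numeric(kernel)
  L <- length(h)
  p <- n_poles
  stopifnot(.is_count(p), p >= 1, L > 2 * p)
  hk <- h[-1]                       # taps k = 1 .. L-1
  n <- length(hk)
  # linear prediction: hk[t] = sum_i a_i hk[t - i]
  y <- hk[(p + 1):n]
  X <- sapply(seq_len(p), function(i) hk[(p + 1 - i):(n - i)])
  X <- matrix(X, ncol = p)
  a <- qr.solve(X, y)
  z <- polyroot(c(-rev(a), 1))
  if (any(Mod(z) >= 1))
    stop("fit_exponentials: unstable fitted poles (|z| >= 1); ",
         "system rejected")
  # coefficients: least squares on the exponential basis over k = 1..L-1
  k <- seq_len(n)
  V <- sapply(seq_len(p), function(j) z[j]^k)
  V <- matrix(V, ncol = p)
  cj <- qr.solve(Conj(t(V)) %*% V, Conj(t(V)) %*% hk)
  fit <- Re(V %*% cj)
  sys <- lti_system(z, as.vector(cj), direct = h[1])
  list(system = sys, residual = max(abs(fit - hk)))
}
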