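## Velocity spectra and the forced damped harmonic oscillator fit.

#' Amplitude spectrum of a velocity trace
#'
#' Computes a one-sided, sine-amplitude-normalized velocity spectrum: a
#' pure sine of amplitude \eqn{v_0} occupying one bin yields a bin value
#' of \eqn{v_0}. Long traces are estimated Welch-style (Hann window, 50\%
#' overlap, power-averaged across segments) when at least 8 segments of at
#' least 64 samples fit; shorter traces fall back to a single full-length
#' rectangular-window FFT. The equivalent noise bandwidth per bin
#' (\code{enbw}, Hz) is recorded so that stochastic bin amplitudes can be
#' converted to spectral densities downstream.
#'
#' @param trace A [simulate_free_fluctuation()] result, or any list with
#'   numeric \code{samples} and scalar \code{dt}.
#' @param method "auto" (default, Welch when the trace allows),
#'   "welch", or "fft".
#' @param max_frequency Upper frequency limit of the returned grid, Hz
#'   (default 10 kHz); truncated at Nyquist.
#'
#' @return An \code{"amplitude_spectrum"} object: \code{frequencies} (Hz,
#'   uniform, DC excluded), \code{amplitude} (m/s per bin), \code{df}
#'   (grid spacing, Hz), \code{enbw} (Hz), \code{method},
#'   \code{n_segments}.
#' @export
#' @examples
#' fs <- 2e4; t <- seq(0, 1 - 1 / fs, by = 1 / fs)
#' tr <- list(samples = 3e-3 * sin(2 * pi * 200 * t), dt = 1 / fs)
#' sp <- compute_spectrum(tr, method = "fft")
#' sp$amplitude[which.max(sp$amplitude)] # ~3e-3 at 200 Hz
compute_spectrum <- function(trace, method = c("auto", "welch", "fft"),
                             max_frequency = 1e4) {
  method <- match.arg(method)
  x <- trace$samples
  dt <- trace$dt
  if (is.null(x) || is.null(dt)) {
    stop("`trace` must have `samples` and `dt`", call. = FALSE)
  }
  .check_scalar(dt, "dt", positive = TRUE)
  if (length(x) < 2L) stop("trace length must be >= 2", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("trace samples must all be finite (non-uniform or gappy sampling is not supported)",
         call. = FALSE)
  }
  n <- length(x)
  fs <- 1 / dt

  seg_len <- .welch_segment_length(n)
  use_welch <- switch(method,
    auto = !is.null(seg_len),
    welch = {
      if (is.null(seg_len)) {
        stop("trace too short for Welch estimation (needs >= 8 segments of >= 64 samples)",
             call. = FALSE)
      }
      TRUE
    },
    fft = FALSE)

  if (use_welch) {
    w <- 0.5 * (1 - cos(2 * pi * (0:(seg_len - 1)) / seg_len)) # periodic Hann
    hop <- seg_len %/% 2L
    starts <- seq(1L, n - seg_len + 1L, by = hop)
    acc <- numeric(seg_len %/% 2L)
    for (s in starts) {
      seg <- x[s:(s + seg_len - 1L)] * w
      xf <- stats::fft(seg)
      amp <- 2 * Mod(xf[2:(seg_len %/% 2L + 1L)]) / sum(w)
      acc <- acc + amp^2
    }
    amp <- sqrt(acc / length(starts))
    df <- fs / seg_len
    enbw <- fs * sum(w^2) / sum(w)^2
    n_segments <- length(starts)
    nb <- seg_len %/% 2L
  } else {
    xf <- stats::fft(x)
    nb <- n %/% 2L
    amp <- 2 * Mod(xf[2:(nb + 1L)]) / n
    if (n %% 2L == 0L) amp[nb] <- sqrt(2) * Mod(xf[nb + 1L]) / n # Nyquist bin
    df <- fs / n
    enbw <- df
    n_segments <- 1L
  }

  freq <- df * seq_len(nb)
  keep <- freq <= min(max_frequency, fs / 2)
  structure(
    list(frequencies = freq[keep], amplitude = amp[keep], df = df,
         enbw = enbw, method = if (use_welch) "welch" else "fft",
         n_segments = n_segments, dt = dt),
    class = "amplitude_spectrum")
}

## largest power-of-two segment length allowing >= 8 half-overlapping
## segments of >= 64 samples; NULL when the trace is too short
.welch_segment_length <- function(n) {
  l <- 2^floor(log2(n / 4.5))
  while (l >= 64) {
    if (floor((n - l / 2) / (l / 2)) >= 8) return(as.integer(l))
    l <- l / 2
  }
  NULL
}

#' @export
print.amplitude_spectrum <- function(x, ...) {
  cat(sprintf(
    "<amplitude_spectrum> %d bins, %.3g-%.4g Hz (df = %.3g Hz, ENBW = %.3g Hz), %s (%d segment%s)\n",
    length(x$frequencies), min(x$frequencies), max(x$frequencies),
    x$df, x$enbw, x$method, x$n_segments, if (x$n_segments > 1) "s" else ""))
  invisible(x)
}

## velocity-amplitude model of a thermally forced damped harmonic
## oscillator: displacement Lorentzian times frequency
.dho_velocity_model <- function(f, a, f0, q, floor = 0) {
  a * f * f0^2 / sqrt((f0^2 - f^2)^2 + (f0 * f / q)^2) + floor
}

#' Fit a forced damped harmonic oscillator to an amplitude spectrum
#'
#' Least-squares fit of
#' \deqn{V(f) = A f f_0^2 / \sqrt{(f_0^2 - f^2)^2 + (f_0 f / Q)^2}}
#' (optionally plus an additive white noise floor) to the spectrum bins
#' inside \code{fit_band}, the restriction reflecting heavy low-frequency
#' measurement noise in vibrometry recordings. Initialization follows the
#' band amplitude argmax for \eqn{f_0}; a small deterministic grid of
#' starting \eqn{Q} values guards against the wide dynamic range of
#' receiver tuning (passive \eqn{Q < 1} up to SSO \eqn{Q} in the
#' thousands). Bounded search keeps \eqn{f_0} inside the band and
#' \eqn{Q \in [0.1, 10^5]}.
#'
#' @param spectrum An [compute_spectrum()] result.
#' @param fit_band Length-2 numeric, Hz. Default \code{c(101, 1000)}.
#' @param noise_floor Logical; include an additive noise-floor term
#'   (default \code{FALSE}).
#' @param r2_floor Fits with \eqn{R^2} below this are flagged invalid
#'   (default 0.5).
#'
#' @return An \code{"oscillator_fit"} object: \code{f0} (Hz), \code{q},
#'   \code{amplitude} (the scale \eqn{A}), \code{noise_floor},
#'   \code{r_squared}, \code{fit_band}, \code{valid}, \code{n_bins},
#'   \code{bin_bandwidth} (ENBW carried from the spectrum, Hz).
#' @export
fit_oscillator <- function(spectrum, fit_band = c(101, 1000),
                           noise_floor = FALSE, r2_floor = 0.5) {
  stopifnot(inherits(spectrum, "amplitude_spectrum"))
  if (length(fit_band) != 2L || fit_band[1] >= fit_band[2]) {
    stop("`fit_band` must be an increasing length-2 numeric", call. = FALSE)
  }
  sel <- spectrum$frequencies >= fit_band[1] &
    spectrum$frequencies <= fit_band[2]
  if (sum(sel) < 10L) {
    stop("need >= 10 spectrum bins inside `fit_band`", call. = FALSE)
  }
  f <- spectrum$frequencies[sel]
  y <- spectrum$amplitude[sel]

  ss_tot <- sum((y - mean(y))^2)
  if (max(y) <= 0 || ss_tot <= .Machine$double.eps * max(y)^2 * length(y)) {
    return(.new_oscillator_fit(NA, NA, NA, NA, NA_real_, fit_band, FALSE,
                               sum(sel), spectrum$enbw,
                               reason = "flat or empty spectrum"))
  }

  f0_init <- f[which.max(y)]
  peak <- max(y)
  floor0 <- if (noise_floor) stats::median(y) / 10 else 0

  lower <- c(-745, fit_band[1], log(0.1))
  upper <- c(709, fit_band[2], log(1e5))
  if (noise_floor) {
    lower <- c(lower, -745); upper <- c(upper, log(10 * peak))
  }
  obj <- function(par) {
    if (any(par < lower) || any(par > upper)) return(1e300) # box for NM
    a <- exp(par[1]); f0 <- par[2]; q <- exp(par[3])
    fl <- if (noise_floor) exp(par[4]) else 0
    r <- y - .dho_velocity_model(f, a, f0, q, fl)
    sum(r * r)
  }

  best <- NULL
  for (q0 in c(0.5, 2, 20, 200)) {
    start <- c(log(peak / (f0_init * q0)), f0_init, log(q0))
    if (noise_floor) start <- c(start, log(max(floor0, peak * 1e-6)))
    fit <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    return(.new_oscillator_fit(NA, NA, NA, NA, NA_real_, fit_band, FALSE,
                               sum(sel), spectrum$enbw,
                               reason = "optimizer failure"))
  }
  ## derivative-free polish; cheap and helps when L-BFGS-B stalls at a bound
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000,
                                      reltol = .Machine$double.eps^0.9))

  a <- exp(best$par[1]); f0 <- best$par[2]; q <- exp(best$par[3])
  fl <- if (noise_floor) exp(best$par[4]) else 0
  r2 <- 1 - best$value / ss_tot
  valid <- is.finite(r2) && r2 >= r2_floor &&
    f0 > fit_band[1] && f0 < fit_band[2]
  .new_oscillator_fit(f0, q, a, fl, r2, fit_band, valid, sum(sel),
                      spectrum$enbw,
                      reason = if (valid) NULL else "low r-squared or f0 at band edge")
}

.new_oscillator_fit <- function(f0, q, amplitude, noise_floor, r2, band,
                                valid, n_bins, enbw, reason = NULL) {
  structure(
    list(f0 = f0, q = q, amplitude = amplitude, noise_floor = noise_floor,
         r_squared = r2, fit_band = band, valid = valid, n_bins = n_bins,
         bin_bandwidth = enbw, invalid_reason = reason),
    class = "oscillator_fit")
}

#' Construct an oscillator fit record directly
#'
#' Builds an \code{"oscillator_fit"} object from known parameter values,
#' e.g. for [check_recovery()] comparisons of externally stored fits or
#' for evaluating the model via [fluctuation_power()].
#'
#' @param f0 Best frequency, Hz.
#' @param q Quality factor.
#' @param amplitude Amplitude scale \eqn{A} of the velocity model.
#' @param bin_bandwidth Spectral bin bandwidth the amplitude refers to, Hz.
#' @param r_squared,fit_band,noise_floor Optional metadata.
#' @return An \code{"oscillator_fit"} object (marked valid).
#' @export
oscillator_fit <- function(f0, q, amplitude, bin_bandwidth,
                           r_squared = 1, fit_band = c(101, 1000),
                           noise_floor = 0) {
  .check_scalar(f0, "f0", positive = TRUE)
  .check_scalar(q, "q", positive = TRUE)
  .check_scalar(amplitude, "amplitude", positive = TRUE)
  .check_scalar(bin_bandwidth, "bin_bandwidth", positive = TRUE)
  .new_oscillator_fit(f0, q, amplitude, noise_floor, r_squared, fit_band,
                      TRUE, NA_integer_, bin_bandwidth)
}

#' @export
print.oscillator_fit <- function(x, ...) {
  if (!isTRUE(x$valid)) {
    cat(sprintf("<oscillator_fit> INVALID (%s)\n",
                x$invalid_reason %||% "unknown"))
    return(invisible(x))
  }
  cat(sprintf(
    "<oscillator_fit> f0 = %.2f Hz, Q = %.4g, A = %.3g, R^2 = %.4f (band %g-%g Hz)\n",
    x$f0, x$q, x$amplitude, x$r_squared, x$fit_band[1], x$fit_band[2]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Baseline-vs-final recording recovery check
#'
#' Recordings bracketing an experiment (e.g. before and after CO2
#' sedation) are compared via their free-fluctuation fits; the preparation
#' counts as recovered when both the best frequency and the velocity
#' amplitude changed by less than \code{threshold} (default 20\%) relative
#' to baseline.
#'
#' @param baseline,final Valid \code{"oscillator_fit"} objects.
#' @param threshold Maximum tolerated relative change (default 0.20).
#' @return A \code{"recovery_check"} object with \code{relative_changes}
#'   (named: \code{f0}, \code{amplitude}) and \code{passed}.
#' @export
#' @examples
#' b <- oscillator_fit(300, 1.2, 1e-6, 1)
#' f <- oscillator_fit(355, 1.2, 1e-6, 1)
#' check_recovery(b, f)$passed # 18.3% change: recovered
check_recovery <- function(baseline, final, threshold = 0.20) {
  for (fit in list(baseline, final)) {
    if (!inherits(fit, "oscillator_fit") || !isTRUE(fit$valid)) {
      stop("`baseline` and `final` must be valid oscillator fits",
           call. = FALSE)
    }
  }
  .check_scalar(threshold, "threshold", positive = TRUE)
  changes <- c(f0 = abs(final$f0 - baseline$f0) / baseline$f0,
               amplitude = abs(final$amplitude - baseline$amplitude) /
                 baseline$amplitude)
  structure(
    list(baseline = baseline, final = final,
         relative_changes = changes, threshold = threshold,
         passed = all(changes < threshold)),
    class = "recovery_check")
}

#' @export
print.recovery_check <- function(x, ...) {
  cat(sprintf(
    "<recovery_check> delta f0 = %.1f%%, delta amplitude = %.1f%% (threshold %.0f%%): %s\n",
    100 * x$relative_changes["f0"], 100 * x$relative_changes["amplitude"],
    100 * x$threshold, if (x$passed) "recovered" else "NOT recovered"))
  invisible(x)
}
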