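## Seeded simulators for every input the analysis chain consumes.

#' Simulate free fluctuations of a flagellar receiver
#'
#' Integrates the Langevin equation
#' \eqn{m\ddot x + \gamma\dot x + kx = \sqrt{2\gamma k_B T_{\mathrm{eff}}}\,\xi(t)}
#' with \eqn{T_{\mathrm{eff}} = T(1 + \code{active\_boost})} and unit white
#' noise \eqn{\xi}, using a semi-implicit (symplectic) Euler--Maruyama
#' scheme with per-step thermal-force standard deviation
#' \eqn{\sqrt{2\gamma k_B T_{\mathrm{eff}}/dt}}. The scheme's stationary
#' displacement variance satisfies equipartition,
#' \eqn{\langle x^2\rangle = k_B T_{\mathrm{eff}}/k}, to O((\eqn{f_0 dt})^2).
#'
#' If the parameters carry an SSO configuration, a van-der-Pol limit cycle
#' with the requested amplitude and frequency is integrated alongside and
#' superposed on the thermal motion, mimicking the autonomous
#' self-sustained oscillations of male receivers.
#'
#' A burn-in of \code{burn_in_periods} resonance periods (default
#' \eqn{10Q}) is integrated and discarded before the returned samples so
#' the trace is stationary; the burn-in is skipped for noise-free
#' (deterministic ringdown) runs started from \code{initial_displacement}.
#'
#' @param params An [oscillator_params()] object.
#' @param duration Trace duration after burn-in, s.
#' @param dt Sampling interval, s. Must satisfy \code{dt < 1/(20 * f0)}.
#' @param seed Integer seed; identical seeds give bit-identical traces.
#'   \code{NULL} uses (and advances) the global RNG stream.
#' @param initial_displacement Starting displacement, m (default 0).
#' @param initial_velocity Starting velocity, m/s (default 0).
#' @param burn_in_periods Number of resonance periods integrated and
#'   discarded before recording. Default \code{10 * Q} when thermal forcing
#'   is present, 0 otherwise.
#'
#' @return A \code{"velocity_trace"} object: list with \code{samples}
#'   (velocity, m/s), \code{displacement} (m), \code{dt},
#'   \code{state_label} ("active" or "passive"), \code{oscillation_label}
#'   ("SSO", "quiescent" or "n/a"), \code{seed}, and \code{params}.
#' @export
#' @examples
#' p <- oscillator_params(mass = 77.45e-12, natural_frequency = 220.03,
#'                        quality_factor = 1.19)
#' tr <- simulate_free_fluctuation(p, duration = 0.5, dt = 5e-5, seed = 1)
#' var(tr$displacement) # approaches kB * T / k for long traces
simulate_free_fluctuation <- function(params, duration, dt, seed = NULL,
                                      initial_displacement = 0,
                                      initial_velocity = 0,
                                      burn_in_periods = NULL) {
  stopifnot(inherits(params, "oscillator_params"))
  .check_scalar(duration, "duration", positive = TRUE)
  .check_scalar(dt, "dt", positive = TRUE)
  seed <- .check_seed(seed)
  f0 <- params$natural_frequency
  if (dt >= 1 / (20 * f0)) {
    stop(sprintf(
      "`dt` = %g is too coarse for f0 = %g Hz; integration requires dt < 1/(20*f0) = %g s",
      dt, f0, 1 / (20 * f0)), call. = FALSE)
  }

  m <- params$mass; k <- params$stiffness; g <- params$damping
  t_eff <- params$temperature * (1 + params$active_boost)
  thermal <- t_eff > 0

  if (is.null(burn_in_periods)) {
    burn_in_periods <- if (thermal) 10 * params$quality_factor else 0
  }
  n_out <- max(2L, as.integer(round(duration / dt)))
  n_burn <- as.integer(ceiling(burn_in_periods / (f0 * dt)))
  n_tot <- n_out + n_burn + 1L

  force_sd <- if (thermal) sqrt(2 * g * .kB * t_eff / dt) else 0
  forces <- .with_seed(seed, {
    f <- if (thermal) stats::rnorm(n_tot, sd = force_sd) else numeric(n_tot)
    sso <- if (!is.null(params$sso)) {
      .vdp_limit_cycle(params$sso$amplitude, params$sso$frequency, n_tot, dt)
    }
    list(f = f, sso = sso)
  })

  ## semi-implicit Euler (v updated first, then x) collapses to a linear
  ## two-term recursion in x, evaluated at C speed by stats::filter
  a1 <- 2 - dt^2 * k / m - dt * g / m
  a2 <- dt * g / m - 1
  drive <- dt^2 / m * forces$f
  x1 <- initial_displacement + dt * initial_velocity
  x <- stats::filter(drive, filter = c(a1, a2), method = "recursive",
                     init = c(x1, initial_displacement))
  x <- as.numeric(x)
  v <- diff(c(initial_displacement, x)) / dt

  idx <- (n_burn + 2L):(n_burn + 1L + n_out)
  x <- x[idx]; v <- v[idx]
  if (!is.null(forces$sso)) {
    x <- x + forces$sso$x[idx]
    v <- v + forces$sso$v[idx]
  }

  structure(
    list(samples = v, displacement = x, dt = dt,
         state_label = if (params$active_boost > 0 ||
                           !is.null(params$sso)) "active" else "passive",
         oscillation_label = if (!is.null(params$sso)) "SSO"
                             else if (thermal) "quiescent" else "n/a",
         seed = seed, params = params),
    class = "velocity_trace")
}

## van der Pol oscillator settled on a limit cycle of the requested
## displacement amplitude and frequency; weak nonlinearity (mu) keeps the
## cycle near-sinusoidal
.vdp_limit_cycle <- function(amplitude, frequency, n, dt, mu = 0.05) {
  ws <- 2 * pi * frequency
  a <- amplitude / 2 # standard vdP scaling: limit cycle amplitude = 2a
  x <- numeric(n); v <- numeric(n)
  xi <- amplitude; vi <- 0
  for (i in seq_len(n)) {
    vi <- vi + dt * (mu * ws * (1 - (xi / a)^2) * vi - ws^2 * xi)
    xi <- xi + dt * vi
    x[i] <- xi; v[i] <- vi
  }
  list(x = x, v = v)
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf("<velocity_trace> %d samples @ dt = %g s (%.3g s), %s/%s\n",
              length(x$samples), x$dt, length(x$samples) * x$dt,
              x$state_label, x$oscillation_label))
  invisible(x)
}

#' Simulate a frequency-sweep stimulation trial
#'
#' Produces the forced displacement response of the receiver to a linear
#' frequency sweep, plus a compound-action-potential (CAP) trace modelled
#' as a saturating sigmoid of the displacement envelope weighted by a
#' Gaussian electrical tuning curve. The displacement trace tracks the
#' steady-state transfer function at the instantaneous stimulus frequency;
#' both traces receive additive Gaussian noise.
#'
#' The returned \code{truth} element records, from the noise-free forward
#' model, the planted mechanical best frequency (argmax of the
#' displacement envelope over the swept band) and the planted electrical
#' best frequency (argmax of the CAP envelope).
#'
#' @param params An [oscillator_params()] object for the receiver.
#' @param stimulus A [sweep_stimulus()] object; \code{amplitude} is read
#'   as the force amplitude in newtons.
#' @param electrical_tuning Numeric length-2: centre (Hz) and width (Hz,
#'   Gaussian sd) of the nerve's frequency tuning.
#' @param cap_saturation List with \code{max} (uV), \code{midpoint} (nm)
#'   and \code{slope} (nm) of the sigmoidal CAP-vs-displacement curve.
#' @param noise_level Additive noise standard deviation as a fraction of
#'   the peak noise-free envelope (displacement trace) or of
#'   \code{cap_saturation$max} (CAP trace). With a zero-amplitude stimulus
#'   the displacement noise floor is 1 nm.
#' @param dt Sampling interval, s.
#' @param seed Integer seed for reproducibility.
#'
#' @return A \code{"sweep_trial"} object: \code{stimulus},
#'   \code{displacement} (nm), \code{cap} (uV), \code{dt}, \code{truth}.
#' @export
simulate_sweep_trial <- function(params, stimulus,
                                 electrical_tuning = c(220, 120),
                                 cap_saturation = list(max = 50,
                                                       midpoint = 400,
                                                       slope = 150),
                                 noise_level = 0.01, dt = 5e-5,
                                 seed = NULL) {
  stopifnot(inherits(params, "oscillator_params"),
            inherits(stimulus, "sweep_stimulus"))
  .check_scalar(noise_level, "noise_level")
  if (noise_level < 0) stop("`noise_level` must be >= 0", call. = FALSE)
  .check_scalar(dt, "dt", positive = TRUE)
  seed <- .check_seed(seed)
  nyq <- 1 / (2 * dt)
  if (max(stimulus$f_start, stimulus$f_end) >= nyq) {
    stop("stimulus frequencies must lie below the Nyquist frequency",
         call. = FALSE)
  }

  n <- as.integer(round(stimulus$duration / dt))
  tt <- (seq_len(n) - 1L) * dt
  finst <- stimulus$f_start +
    (stimulus$f_end - stimulus$f_start) * tt / stimulus$duration
  phase <- 2 * pi * (stimulus$f_start * tt +
    (stimulus$f_end - stimulus$f_start) * tt^2 / (2 * stimulus$duration))

  gain_m <- .displacement_gain_modulus(params, finst)      # m per N
  env_nm <- stimulus$amplitude * gain_m * 1e9
  disp0 <- env_nm * sin(phase)

  tune <- exp(-(finst - electrical_tuning[1])^2 /
                (2 * electrical_tuning[2]^2))
  ## baseline-subtracted sigmoid: zero displacement gives zero CAP
  cap_sig <- function(env) {
    s <- 1 / (1 + exp(-(env - cap_saturation$midpoint) /
                        cap_saturation$slope))
    s0 <- 1 / (1 + exp(cap_saturation$midpoint / cap_saturation$slope))
    cap_saturation$max * (s - s0) / (1 - s0)
  }
  cap0 <- cap_sig(env_nm) * tune * sin(phase)

  band <- sort(c(stimulus$f_start, stimulus$f_end))
  fgrid <- seq(band[1], band[2], length.out = 20000L)
  g <- .displacement_gain_modulus(params, fgrid)
  mech_bf <- fgrid[which.max(g)]
  cap_truth <- cap_sig(stimulus$amplitude * g * 1e9) *
    exp(-(fgrid - electrical_tuning[1])^2 / (2 * electrical_tuning[2]^2))
  elec_bf <- fgrid[which.max(cap_truth)]

  disp_sd <- noise_level * max(max(env_nm), 1)
  cap_sd <- noise_level * cap_saturation$max
  noise <- .with_seed(seed, list(d = stats::rnorm(n, sd = disp_sd),
                                 c = stats::rnorm(n, sd = cap_sd)))

  structure(
    list(stimulus = stimulus,
         displacement = disp0 + noise$d,
         cap = cap0 + noise$c,
         dt = dt,
         truth = list(mechanical_bf = mech_bf, electrical_bf = elec_bf,
                      peak_displacement_nm = max(env_nm)),
         seed = seed),
    class = "sweep_trial")
}

## |x(f)/F| of the damped harmonic oscillator, m per N
.displacement_gain_modulus <- function(params, f) {
  f0 <- params$natural_frequency
  q <- params$quality_factor
  1 / (params$mass * (2 * pi)^2 *
         sqrt((f0^2 - f^2)^2 + (f0 * f / q)^2))
}

#' @export
print.sweep_trial <- function(x, ...) {
  cat(sprintf(
    "<sweep_trial> %s %g->%g Hz, %g s @ dt = %g s; planted mech BF %.1f Hz, elec BF %.1f Hz\n",
    x$stimulus$direction, x$stimulus$f_start, x$stimulus$f_end,
    x$stimulus$duration, x$dt,
    x$truth$mechanical_bf, x$truth$electrical_bf))
  invisible(x)
}

#' Simulate a force-step gating-compliance experiment
#'
#' Generates steady-state force/displacement/CAP triples from the
#' two-state single-population transducer model (see
#' [gating_force_model()]). Forces are applied in logarithmic steps of
#' both signs, mimicking the 20-intensity step protocol; the steady
#' displacement for each commanded force solves the model
#' force--displacement relation and is then perturbed by multiplicative
#' Gaussian noise. CAP amplitudes follow a saturating sigmoid of the
#' absolute displacement.
#'
#' @param truth A [gating_fit()] object holding the generating parameters.
#' @param n_steps Number of force intensities per sign (default 20).
#' @param displacement_noise Multiplicative noise fraction on
#'   displacements (sd of the relative perturbation).
#' @param seed Integer seed.
#' @param max_force Largest commanded force magnitude, N. Default: the
#'   model force at +2.5 um, so the +/-2000 nm analysis window is covered.
#' @param force_decades Decades spanned by the log-spaced step magnitudes.
#' @param cap_params List with \code{max} (uV), \code{midpoint} (nm),
#'   \code{slope} (nm) for the CAP dose-response.
#'
#' @return A \code{"gating_experiment"} object: \code{forces} (N),
#'   \code{displacements} (m), \code{cap_amplitudes} (uV), \code{truth}.
#' @export
simulate_gating_experiment <- function(truth = gating_fit(),
                                       n_steps = 20,
                                       displacement_noise = 0.01,
                                       seed = NULL,
                                       max_force = NULL,
                                       force_decades = 2,
                                       cap_params = list(max = 40,
                                                         midpoint = 500,
                                                         slope = 200)) {
  stopifnot(inherits(truth, "gating_fit"))
  if (n_steps < 4) stop("`n_steps` must be >= 4", call. = FALSE)
  .check_scalar(displacement_noise, "displacement_noise")
  if (displacement_noise < 0) {
    stop("`displacement_noise` must be >= 0", call. = FALSE)
  }
  seed <- .check_seed(seed)
  if (!.gating_stable(truth)) {
    stop("truth parameters give non-positive total stiffness", call. = FALSE)
  }
  if (is.null(max_force)) {
    max_force <- abs(gating_force_model(truth, 2.5e-6) - truth$force_offset)
  }

  mags <- 10^seq(log10(max_force) - force_decades, log10(max_force),
                 length.out = n_steps)
  forces <- c(-rev(mags), mags)
  x <- vapply(forces, function(f) .gating_inverse(truth, f), numeric(1))
  noise <- .with_seed(seed, stats::rnorm(length(x), sd = displacement_noise))
  x_obs <- x * (1 + noise)
  x_nm <- abs(x_obs) * 1e9
  cap <- cap_params$max /
    (1 + exp(-(x_nm - cap_params$midpoint) / cap_params$slope))

  structure(
    list(forces = forces, displacements = x_obs, cap_amplitudes = cap,
         truth = truth, seed = seed),
    class = "gating_experiment")
}

## invert F(x) = f for the (strictly increasing) two-state model
.gating_inverse <- function(fit, f) {
  g <- function(x) gating_force_model(fit, x) - f
  span <- max(abs(f - fit$force_offset) / fit$asymptotic_stiffness,
              1e-7) * 4 + abs(fit$set_point) +
    fit$n_transducers * fit$gating_force / fit$asymptotic_stiffness
  stats::uniroot(g, lower = -span, upper = span, tol = 1e-15)$root
}

#' @export
print.gating_experiment <- function(x, ...) {
  cat(sprintf(
    "<gating_experiment> %d force steps, |F| in [%.3g, %.3g] N, |x| up to %.0f nm\n",
    length(x$forces), min(abs(x$forces)), max(abs(x$forces)),
    max(abs(x$displacements)) * 1e9))
  invisible(x)
}

#' Simulate a mechanical sensitivity curve with a planted displacement gain
#'
#' Generates per-intensity mechanical sensitivities (peak displacement per
#' unit stimulus) following a three-parameter sigmoid in log10 intensity,
#' scaled so that the ratio of the curve's values at the lowest and
#' highest tested intensities equals \code{gain}. Compressive receivers
#' are most sensitive at low intensities, so the curve decreases with
#' intensity. Multiplicative Gaussian noise is applied.
#'
#' @param gain Planted displacement gain (max/min sensitivity over the
#'   tested range), \eqn{\ge 1}. \code{gain = 1} gives a constant curve.
#' @param n_intensities Number of tested intensities (default 10).
#' @param intensity_range Length-2 positive numeric; intensities are
#'   log-spaced across this range.
#' @param max_sensitivity Sensitivity at the most sensitive end
#'   (arbitrary displacement/stimulus units).
#' @param noise Multiplicative noise fraction.
#' @param seed Integer seed.
#'
#' @return A [sensitivity_curve()] object with a \code{truth} attribute
#'   recording the planted gain.
#' @export
simulate_sensitivity_curve <- function(gain, n_intensities = 10,
                                       intensity_range = c(1, 1000),
                                       max_sensitivity = 100,
                                       noise = 0, seed = NULL) {
  .check_scalar(gain, "gain")
  if (gain < 1) stop("`gain` must be >= 1", call. = FALSE)
  .check_scalar(noise, "noise")
  if (noise < 0) stop("`noise` must be >= 0", call. = FALSE)
  seed <- .check_seed(seed)

  intens <- 10^seq(log10(intensity_range[1]), log10(intensity_range[2]),
                   length.out = n_intensities)
  lx <- log10(intens)
  if (gain == 1) {
    y <- rep(max_sensitivity, n_intensities)
  } else {
    ## decreasing logistic in log-intensity; for a centred midpoint the
    ## endpoint ratio is exp(span / (2b)), so b follows from the gain
    span <- diff(range(lx))
    b <- span / (2 * log(gain))
    x0 <- mean(range(lx))
    raw <- 1 / (1 + exp((lx - x0) / b))
    y <- max_sensitivity * raw / max(raw)
  }
  mult <- .with_seed(seed, 1 + stats::rnorm(n_intensities, sd = noise))
  curve <- sensitivity_curve(intens, y * mult)
  attr(curve, "truth") <- list(gain = gain)
  curve
}
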