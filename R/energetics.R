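## Equipartition energetics: total fluctuation power, apparent mass,
## active-vs-passive power gain.

#' Total fluctuation power of a fitted receiver
#'
#' Converts the fitted velocity-amplitude model to displacement via
#' \eqn{x(\omega) = v(\omega)/\omega} and integrates
#' \eqn{\langle x^2\rangle = \int_0^\infty x^2(\omega)\,d\omega} over the
#' whole positive axis. Bin amplitudes relate to spectral density through
#' the bin bandwidth \eqn{B} recorded in the fit
#' (\eqn{E[V^2]/2 = S_v(f)\,B}), which gives the closed form
#' \deqn{\langle x^2\rangle = A^2 f_0 Q / (16\pi B).}
#' The default uses this closed form; \code{method = "numeric"}
#' integrates the same density on a fine grid over \code{band} instead
#' (useful as a sensitivity check for band-limited integration).
#'
#' For a passive receiver in thermal equilibrium the result equals
#' \eqn{k_B T / k} (equipartition).
#'
#' @param fit A valid \code{"oscillator_fit"}.
#' @param method "analytic" (default) or "numeric".
#' @param band Length-2 numeric, Hz; integration band for the numeric
#'   method. Default \code{c(f0/20, 20 f0)}.
#' @return A \code{"fluctuation_power"} object: \code{x2_total} (m^2),
#'   \code{method}, \code{integration_domain} (rad/s).
#' @export
fluctuation_power <- function(fit, method = c("analytic", "numeric"),
                              band = NULL) {
  method <- match.arg(method)
  if (!inherits(fit, "oscillator_fit") || !isTRUE(fit$valid)) {
    stop("`fit` must be a valid oscillator_fit", call. = FALSE)
  }
  b <- fit$bin_bandwidth
  if (!is.finite(b) || b <= 0) {
    stop("fit carries no bin bandwidth; cannot scale amplitudes to density",
         call. = FALSE)
  }
  if (method == "analytic") {
    x2 <- fit$amplitude^2 * fit$f0 * fit$q / (16 * pi * b)
    domain <- c(0, Inf)
  } else {
    if (is.null(band)) band <- c(fit$f0 / 20, 20 * fit$f0)
    fgrid <- exp(seq(log(band[1]), log(band[2]), length.out = 100000L))
    v <- .dho_velocity_model(fgrid, fit$amplitude, fit$f0, fit$q)
    dens <- v^2 / (2 * b * (2 * pi * fgrid)^2) # displacement PSD, m^2/Hz
    x2 <- sum(diff(fgrid) * (dens[-1] + dens[-length(dens)]) / 2)
    domain <- 2 * pi * band
  }
  if (!is.finite(x2) || x2 <= 0) {
    stop("fluctuation power must be positive", call. = FALSE)
  }
  structure(list(x2_total = x2, method = method,
                 integration_domain = domain),
            class = "fluctuation_power")
}

#' @export
print.fluctuation_power <- function(x, ...) {
  cat(sprintf("<fluctuation_power> <x^2> = %.4g m^2 (%s)\n",
              x$x2_total, x$method))
  invisible(x)
}

#' Apparent antennal mass by equipartition
#'
#' Estimates the effective inertia of the receiver from passive thermal
#' fluctuations: \eqn{m = k_B T / (\omega_0^2 \langle x^2\rangle)} with
#' \eqn{\omega_0 = 2\pi f_0} from the passive-state oscillator fit and
#' \eqn{\langle x^2\rangle} the total fluctuation power. Valid only for
#' the passive (sedated) state, where equipartition holds.
#'
#' @param fit Passive-state \code{"oscillator_fit"}.
#' @param power Matching [fluctuation_power()] result.
#' @param temperature Absolute temperature, K (default 293).
#' @return An \code{"apparent_mass"} object with \code{mass} (kg),
#'   \code{mass_ng}, \code{temperature}, and the sources.
#' @export
#' @examples
#' fit <- oscillator_fit(337.52, 0.69, 1e-5, 1)
#' pw <- structure(list(x2_total = 1.161e-17, method = "analytic",
#'                      integration_domain = c(0, Inf)),
#'                 class = "fluctuation_power")
#' apparent_mass(fit, pw)$mass_ng # ~77.5 ng
apparent_mass <- function(fit, power, temperature = 293) {
  if (!inherits(fit, "oscillator_fit") || !isTRUE(fit$valid)) {
    stop("`fit` must be a valid oscillator_fit", call. = FALSE)
  }
  if (!inherits(power, "fluctuation_power") || power$x2_total <= 0) {
    stop("`power` must be a fluctuation_power with positive x2_total",
         call. = FALSE)
  }
  .check_scalar(temperature, "temperature", positive = TRUE)
  omega0 <- 2 * pi * fit$f0
  m <- .kB * temperature / (omega0^2 * power$x2_total)
  structure(
    list(mass = m, mass_ng = m * 1e12, temperature = temperature,
         boltzmann = .kB, source_fit = fit, source_power = power),
    class = "apparent_mass")
}

#' @export
print.apparent_mass <- function(x, ...) {
  cat(sprintf("<apparent_mass> m = %.4g kg (%.2f ng) at T = %.1f K\n",
              x$mass, x$mass_ng, x$temperature))
  invisible(x)
}

#' Active-hearing power gain
#'
#' The fractional excess of active-state fluctuation energy over the
#' passive state,
#' \deqn{\mathrm{gain} = (E_a - E_p)/E_p
#'   = \omega_a^2\langle x_a^2\rangle / (\omega_p^2\langle x_p^2\rangle) - 1,}
#' with natural frequencies from the respective oscillator fits. Energies
#' enter only through \eqn{\omega^2\langle x^2\rangle} products, so the
#' (shared) mass cancels. A value of 0 means no energy injection; the
#' gain is bounded below by -1.
#'
#' @param active_fit,passive_fit Valid \code{"oscillator_fit"} objects for
#'   the active and passive states of the same individual.
#' @param active_power,passive_power Matching [fluctuation_power()]
#'   results.
#' @return A \code{"power_gain"} object with \code{gain} and the
#'   \code{active}/\code{passive} (\eqn{\omega}, \eqn{\langle x^2\rangle})
#'   pairs.
#' @export
power_gain <- function(active_fit, active_power,
                       passive_fit, passive_power) {
  for (fit in list(active_fit, passive_fit)) {
    if (!inherits(fit, "oscillator_fit") || !isTRUE(fit$valid)) {
      stop("fits must be valid oscillator_fit objects", call. = FALSE)
    }
  }
  for (pw in list(active_power, passive_power)) {
    if (!inherits(pw, "fluctuation_power") || pw$x2_total <= 0) {
      stop("powers must be fluctuation_power objects with positive x2_total",
           call. = FALSE)
    }
  }
  wa <- 2 * pi * active_fit$f0
  wp <- 2 * pi * passive_fit$f0
  gain <- (wa^2 * active_power$x2_total) /
    (wp^2 * passive_power$x2_total) - 1
  structure(
    list(gain = gain,
         active = c(omega = wa, x2 = active_power$x2_total),
         passive = c(omega = wp, x2 = passive_power$x2_total)),
    class = "power_gain")
}

#' @export
print.power_gain <- function(x, ...) {
  cat(sprintf("<power_gain> gain = %.4g (E_a/E_p = %.4g)\n",
              x$gain, x$gain + 1))
  invisible(x)
}
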