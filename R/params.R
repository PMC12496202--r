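#' Mechanical parameters of a flagellar receiver
#'
#' Describes the flagellum as a damped harmonic oscillator
#' \eqn{m\ddot x + \gamma\dot x + kx = F(t)} in thermal contact with a bath
#' at temperature \code{temperature}. Parameters can be given either as
#' \code{(mass, stiffness, damping)} or as \code{(mass, natural_frequency,
#' quality_factor)}; the missing pair is derived from
#' \eqn{f_0 = \sqrt{k/m}/2\pi} and \eqn{Q = \sqrt{mk}/\gamma}.
#'
#' The active (energy-injecting) state of the hearing organ is modelled as
#' an effective-temperature boost: thermal forcing at
#' \eqn{T_{\mathrm{eff}} = T (1 + \code{active\_boost})}. Self-sustained
#' oscillations (SSO), the autonomous large-amplitude vibrations of male
#' receivers, are modelled as a separate additive limit cycle configured
#' via \code{sso}.
#'
#' @param mass Apparent mass of the receiver, kg.
#' @param stiffness Spring constant \eqn{k}, N/m. Give either
#'   \code{stiffness} + \code{damping} or \code{natural_frequency} +
#'   \code{quality_factor}.
#' @param damping Damping coefficient \eqn{\gamma}, N s/m.
#' @param natural_frequency Resonance frequency \eqn{f_0}, Hz.
#' @param quality_factor Dimensionless tuning sharpness \eqn{Q}.
#' @param temperature Bath temperature, K. Default 293 K, the approximate
#'   temperature of the recording room.
#' @param active_boost Dimensionless energy-injection factor \eqn{\ge 0};
#'   0 gives the passive (e.g. sedated) receiver.
#' @param sso Either \code{NULL} (no limit cycle) or a list with elements
#'   \code{amplitude} (displacement amplitude of the limit cycle, m) and
#'   \code{frequency} (Hz).
#'
#' @return An object of class \code{"oscillator_params"}: a list with
#'   fields \code{mass}, \code{stiffness}, \code{damping},
#'   \code{natural_frequency}, \code{quality_factor}, \code{temperature},
#'   \code{active_boost}, \code{sso}.
#' @export
#' @examples
#' ## a female receiver in the active state (best frequency 220 Hz, Q 1.19)
#' oscillator_params(mass = 77.45e-12, natural_frequency = 220.03,
#'                   quality_factor = 1.19)
oscillator_params <- function(mass,
                              stiffness = NULL,
                              damping = NULL,
                              natural_frequency = NULL,
                              quality_factor = NULL,
                              temperature = 293,
                              active_boost = 0,
                              sso = NULL) {
  .check_scalar(mass, "mass", positive = TRUE)
  .check_scalar(temperature, "temperature")
  if (temperature < 0) stop("`temperature` must be >= 0", call. = FALSE)
  .check_scalar(active_boost, "active_boost")
  if (active_boost < 0) stop("`active_boost` must be >= 0", call. = FALSE)

  have_kg <- !is.null(stiffness) && !is.null(damping)
  have_fq <- !is.null(natural_frequency) && !is.null(quality_factor)
  if (have_kg == have_fq) {
    stop(paste0("give exactly one of (stiffness, damping) or ",
                "(natural_frequency, quality_factor)"), call. = FALSE)
  }
  if (have_fq) {
    .check_scalar(natural_frequency, "natural_frequency", positive = TRUE)
    .check_scalar(quality_factor, "quality_factor", positive = TRUE)
    omega0 <- 2 * pi * natural_frequency
    stiffness <- mass * omega0^2
    damping <- mass * omega0 / quality_factor
  } else {
    .check_scalar(stiffness, "stiffness", positive = TRUE)
    .check_scalar(damping, "damping", positive = TRUE)
    natural_frequency <- sqrt(stiffness / mass) / (2 * pi)
    quality_factor <- sqrt(mass * stiffness) / damping
  }
  if (!is.finite(natural_frequency) || !is.finite(quality_factor) ||
      natural_frequency <= 0 || quality_factor <= 0) {
    stop("derived f0 and Q must be finite and positive", call. = FALSE)
  }

  if (!is.null(sso)) {
    if (!is.list(sso) || is.null(sso$amplitude) || is.null(sso$frequency)) {
      stop("`sso` must be a list with `amplitude` and `frequency`",
           call. = FALSE)
    }
    .check_scalar(sso$amplitude, "sso$amplitude", positive = TRUE)
    .check_scalar(sso$frequency, "sso$frequency", positive = TRUE)
  }

  structure(
    list(mass = mass, stiffness = stiffness, damping = damping,
         natural_frequency = natural_frequency,
         quality_factor = quality_factor,
         temperature = temperature, active_boost = active_boost,
         sso = sso),
    class = "oscillator_params")
}

#' @export
print.oscillator_params <- function(x, ...) {
  cat("<oscillator_params>\n")
  cat(sprintf("  f0 = %.2f Hz, Q = %.3g  (m = %.3g kg, k = %.3g N/m, gamma = %.3g N s/m)\n",
              x$natural_frequency, x$quality_factor,
              x$mass, x$stiffness, x$damping))
  cat(sprintf("  T = %.1f K, active boost = %.3g%s\n",
              x$temperature, x$active_boost,
              if (is.null(x$sso)) "" else
                sprintf(", SSO %.3g m @ %.1f Hz",
                        x$sso$amplitude, x$sso$frequency)))
  invisible(x)
}
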