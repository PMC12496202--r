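## Plain-text interchange: trace TSV + JSON sidecar, fit-result JSON.

#' Write / read a velocity trace as TSV with a JSON sidecar
#'
#' Traces are stored as two-column tab-separated text (\code{time_s},
#' \code{value}) next to a \code{<path>.json} sidecar holding units,
#' state labels, the seed and - for simulated traces - the generating
#' oscillator parameters.
#'
#' @param trace A \code{"velocity_trace"} object.
#' @param path Output TSV path; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @param sidecar Write the JSON sidecar (default \code{TRUE}).
#' @return \code{write_trace_tsv}: the path, invisibly.
#'   \code{read_trace_tsv}: a \code{"velocity_trace"} object (labels
#'   restored from the sidecar when present).
#' @export
write_trace_tsv <- function(trace, path, sidecar = TRUE) {
  stopifnot(inherits(trace, "velocity_trace"))
  n <- length(trace$samples)
  df <- data.frame(time_s = (seq_len(n) - 1L) * trace$dt,
                   value = trace$samples)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (sidecar) {
    meta <- list(units = "m/s", dt_s = trace$dt,
                 state_label = trace$state_label,
                 oscillation_label = trace$oscillation_label,
                 seed = trace$seed)
    if (!is.null(trace$params)) {
      meta$truth <- list(
        natural_frequency_hz = trace$params$natural_frequency,
        quality_factor = trace$params$quality_factor,
        mass_kg = trace$params$mass,
        stiffness_n_per_m = trace$params$stiffness,
        temperature_k = trace$params$temperature,
        active_boost = trace$params$active_boost)
    }
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  df <- utils::read.delim(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("trace TSV must have columns time_s and value", call. = FALSE)
  }
  dts <- diff(df$time_s)
  if (length(dts) < 1L || any(abs(dts - dts[1]) > 1e-9 * dts[1])) {
    stop("trace is not uniformly sampled", call. = FALSE)
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  structure(
    list(samples = df$value, displacement = NULL, dt = dts[1],
         state_label = meta$state_label %||% "unknown",
         oscillation_label = meta$oscillation_label %||% "n/a",
         seed = meta$seed, params = NULL, truth = meta$truth),
    class = "velocity_trace")
}

#' Write an oscillator fit as a JSON record
#'
#' @param fit An \code{"oscillator_fit"}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "oscillator_fit"))
  jsonlite::write_json(
    list(f0_hz = fit$f0, q = fit$q, amplitude = fit$amplitude,
         noise_floor = fit$noise_floor, r2 = fit$r_squared,
         band_hz = fit$fit_band, bin_bandwidth_hz = fit$bin_bandwidth,
         valid = isTRUE(fit$valid)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
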