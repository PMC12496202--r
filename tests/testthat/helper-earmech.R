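## shared fixtures, all built in code

kB <- boltzmann_constant()

## exact model amplitude spectrum on a uniform grid
model_spectrum <- function(f0, q, a = 2e-9, df = 0.5,
                           fmax = 2000, noise = 0, seed = NULL) {
  f <- seq(df, fmax, by = df)
  y <- a * f * f0^2 / sqrt((f0^2 - f^2)^2 + (f0 * f / q)^2)
  if (noise > 0) {
    y <- earmech:::.with_seed(seed, y * (1 + rnorm(length(y), sd = noise)))
    y <- pmax(y, 0)
  }
  structure(list(frequencies = f, amplitude = y, df = df, enbw = df,
                 method = "fft", n_segments = 1L, dt = NA_real_),
            class = "amplitude_spectrum")
}

## amplitude scale that makes the velocity model the exact thermal PSD of
## a passive oscillator (one-sided, bin width df), so that the analytic
## fluctuation power equals kB*T/k
thermal_amplitude <- function(mass, f0, q, temperature = 293, df = 1) {
  gamma <- mass * 2 * pi * f0 / q
  sqrt(8 * gamma * kB * temperature * df / (mass^2 * (2 * pi)^2 * f0^4))
}

## female passive receiver (apparent mass and tuning from the passive
## free-fluctuation medians)
female_passive <- function(...) {
  oscillator_params(mass = 77.45e-12, natural_frequency = 337.52,
                    quality_factor = 0.69, ...)
}

## one-row DE tables for truth-table enumeration
one_row_tables <- function(mvf, ivf, mvi) {
  mk <- function(v) data.frame(transcript_id = "t1", log2fc = v[1],
                               padj = v[2])
  list(mvf = mk(mvf), ivf = mk(ivf), mvi = mk(mvi))
}

## independent truth-table oracle for the subset classifier: a transcript
## up in MvF is split by the significance pattern of (IvF, MvI); "up"
## means padj < thr and positive fold change (direction "up")
oracle_label <- function(mvf, ivf, mvi, thr = 0.05) {
  sig <- function(v) !is.na(v[2]) && v[2] < thr
  if (!(sig(mvf) && mvf[1] > 0)) return("not_male_upregulated")
  if (sig(ivf)) {
    if (sig(mvi)) "partial_recovery" else "full_recovery"
  } else {
    if (sig(mvi)) "male_independent" else "mvf_only"
  }
}
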