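---
title: "Models and methods behind earmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind earmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earmech)
```

## The scientific problem

Mosquitoes hear with their antennae: the flagellum acts as a sound
receiver whose vibrations are transduced by the Johnston's organ (JO) in
the pedicel. The male ear is strongly sexually dimorphic — sharper
mechanical tuning, active amplification (energy injection by the JO),
and spontaneous self-sustained oscillations (SSO) of the flagellum.
`earmech` implements the quantitative analysis chain used to
characterize these properties from laser-Doppler-vibrometry (LDV) style
recordings, together with the intersectional classification of ear
RNA-seq results used to dissect the transcriptomic basis of "auditory
maleness" in *Anopheles gambiae* doublesex (*dsxF*) mutants. Because the
original vibrometry recordings are not publicly deposited, the package
ships seeded simulators for every input, with recorded ground truth, so
the whole chain is testable end to end.

## Free fluctuations: the damped harmonic oscillator model

An unstimulated flagellum in thermal equilibrium obeys the Langevin
equation

$$m\ddot x + \gamma \dot x + kx = \sqrt{2\gamma k_B T}\,\xi(t),$$

with apparent mass $m$, damping $\gamma$, stiffness $k$ and unit white
noise $\xi$. Its velocity amplitude spectrum is fitted with

$$V(f) = \frac{A\, f\, f_0^2}{\sqrt{(f_0^2-f^2)^2 + (f_0 f/Q)^2}},$$

the displacement Lorentzian multiplied by frequency, where
$f_0 = \sqrt{k/m}/2\pi$ is the best frequency and
$Q = \sqrt{mk}/\gamma$ the tuning sharpness. The exact fit function is a
package choice (the protocol literature cites prior work without
printing it); the convention is pinned by self-consistency tests that
recover planted $(f_0, Q)$ to 0.1% from noiseless model curves.

Key parameter choices:

* **Fit band 101–1000 Hz** (default): low-frequency bins of real LDV
  recordings are dominated by ambient noise, so the fit excludes them.
* **Spectrum estimation**: Welch averaging (periodic Hann window, 50%
  overlap) whenever at least 8 segments of at least 64 samples fit,
  otherwise a single rectangular-window FFT. Amplitudes are
  sine-normalized (a pure sine of amplitude $v_0$ gives a bin value
  $v_0$), and the equivalent noise bandwidth (ENBW) of a bin is stored
  so stochastic bin amplitudes can be converted to spectral densities.
  Averaging matters twice: it smooths the spectrum for stable fits, and
  it removes the Rayleigh small-sample bias that would otherwise make
  amplitude fits (and hence fluctuation powers) systematically low.
* **Optimizer**: bounded quasi-Newton from a deterministic grid of
  starting $Q$ values (the dynamic range of real receivers spans
  passive $Q<1$ to SSO $Q$ in the thousands, so the upper bound is
  $10^5$), followed by a derivative-free polish confined to the same
  box. Fits with $R^2$ below a configurable floor (default 0.5), or
  with $f_0$ pinned at a band edge, carry `valid = FALSE`.

## Equipartition energetics

The total fluctuation power is
$\langle x^2\rangle = \int_0^\infty x^2(\omega)\,d\omega$ with
$x(\omega) = v(\omega)/\omega$. For the fitted model the integral has a
closed form: with bin bandwidth $B$,

$$\langle x^2\rangle = \frac{A^2 f_0 Q}{16\pi B},$$

which for a passive receiver equals $k_BT/k$ (equipartition) — the
package's central numerical oracle. The apparent antennal mass follows
as

$$m = \frac{k_B T}{\omega_0^2 \langle x^2\rangle},$$

computed from passive-state (sedated) recordings only, with
$T = 293\,\mathrm{K}$ by default (configurable). The active-hearing
power gain compares active and passive fluctuation energies,

$$\mathrm{gain} = \frac{\omega_a^2\langle x_a^2\rangle}
{\omega_p^2\langle x_p^2\rangle} - 1,$$

in which the (shared) mass cancels, so no assumption about active-state
mass is needed. Integration is performed over the whole positive axis
via the closed form (the formula demands total power even though the
fit uses a finite band); a numeric band-limited alternative exists for
sensitivity analysis and agrees with the closed form to ~1.5% for a
$(f_0/20, 20f_0)$ band at intersex-like $Q \approx 2$ (heavily damped
receivers put several percent of their fluctuation power below
$f_0/20$, which is why the analytic route is the default).

## The synthetic oscillator traces

`simulate_free_fluctuation()` integrates the Langevin equation with a
*semi-implicit* (symplectic) Euler–Maruyama scheme — velocity updated
first, thermal force standard deviation $\sqrt{2\gamma k_B T/dt}$ per
step — which collapses to a linear two-term recursion evaluated at C
speed. The explicit variant was rejected because it injects energy at
$O(\omega_0 dt)$ and fails the equipartition test at the working step
size; the semi-implicit scheme is the simplest one whose stationary
variance matches $k_BT/k$ (verified at 10% tolerance on 10 s traces).
Choices:

* **Active state** is an effective-temperature boost,
  $T_\mathrm{eff} = T(1+\mathrm{boost})$, rather than negative damping:
  the power-gain formula compares fluctuation powers, not linewidths, so
  energy injection is the property that must be planted.
* **SSO** is a separate additive van-der-Pol limit cycle (amplitude and
  frequency configurable), since SSO is treated as a distinct receiver
  state rather than a continuation of quiescent amplification.
* **Burn-in** of $10Q$ resonance periods is integrated and discarded so
  returned traces are stationary; deterministic zero-temperature
  ringdown runs skip it.
* **Stability guard**: `dt` must be below $1/(20 f_0)$.

The generator does *not* emulate real trace morphology (harmonic
distortion, efferent modulation dynamics, measurement noise spectra —
the protocol gives no LDV noise model, so measurement noise is a free
parameter). A green round-trip test therefore establishes that the
analysis chain is self-consistent and unbiased for
thermally-driven-oscillator data, not that it is robust to every
artefact of laboratory recordings.

## Transducer gating: the two-state model

Force steps probe mechanotransducer gating. A single population of $N$
two-state channels with gating force $z$ in an elastic suspension of
asymptotic stiffness $K_\infty$ gives the force–displacement relation

$$F(x) = K_\infty x - N z\, p_\mathrm{open}(x) + F_0, \qquad
p_\mathrm{open}(x) = \frac{1}{1+e^{-z(x-x_0)/k_BT}},$$

whose signature is a gating-compliance dip of depth $Nz^2/4k_BT$ in the
local stiffness at the set point. Only displacements within ±2000 nm
enter the fit (the most sensitive transducers). Design notes:

* **Residual metric.** The protocol commands forces and measures
  displacements, with error proportional to displacement. Naive
  force-domain least squares is dominated by the few largest steps and
  leaves $N$ poorly determined; the fitter instead minimizes the
  first-order errors-in-variables objective — force residual divided by
  local slope, relative to $\max(|x|, 20\,\mathrm{nm})$ — which matches
  the generative error model.
* **Identifiability.** $N$ and $z$ enter as $Nz$ (asymptote offset) and
  $Nz^2$ (dip); the fitter works in $(K_\infty, Nz, z, x_0, F_0)$ and
  derives $N$. A deterministic multi-start (starting $z \in \{1, 10,
  100\}$ fN crossed with three gating-strength starts) covers the
  curved valley of this landscape. Even so, $N$ is statistically weakly
  identified when the dip is small: at a 10% dip and 1% displacement
  noise the per-experiment spread of $\hat N$ is tens of percent — an
  information limit, not an optimizer defect (fitted optima beat the
  truth's residual sum). The simulator's default truth
  ($N = 1000$, $z = 10$ fN, $K_\infty = 20\,\mu$N/m, a 31% dip)
  therefore describes a receiver with pronounced gating compliance, the
  regime these experiments target.
* **Degenerate gating.** Data linear to machine precision, or for which
  the gating terms fail a partial F-test against a straight line at the
  1% level, are flagged `degenerate_gating` and reported with their
  Hookean parameters. Fits pinned at the stiffness-positivity
  constraint $K_\infty > Nz^2/4k_BT$ are flagged unstable.

CAP (compound action potential) dose–response curves are fitted with a
monotone three-parameter sigmoid in $|x|$; the forward model for nerve
responses in the sweep simulator (sigmoid of the displacement envelope,
weighted by a Gaussian electrical tuning curve, baseline-subtracted so
zero displacement gives zero CAP) is likewise an artifact choice — the
protocol specifies no forward model for CAPs.

## Sweep analysis

Sweeps are pure tones whose frequency moves linearly between 1 and
1000 Hz in 1 s. Processing follows: DC removal → trial averaging →
envelope extraction → peak localization → the linear time-to-frequency
map $f(t^*) = f_\mathrm{start} + (f_\mathrm{end}-f_\mathrm{start})
t^*/\mathrm{duration}$.

* **DC removal** subtracts an exponential moving average with
  $\tau = 0.015$ s, weight $\alpha = 1-e^{-dt/\tau}$, so a unit step
  decays exactly as $e^{-t/\tau}$ (corner frequency ≈ 10.6 Hz; 200 Hz
  passes at >99%).
* **Envelope**: local maxima of the rectified trace, linearly
  interpolated, smoothed over a 20 ms centred window. The envelope's
  native resolution is the rectified-peak spacing (half a carrier
  period), which bounds the noise-free localization error.
* **Direction averaging**: a resonant receiver rings after the sweep
  passes its resonance, biasing single-direction estimates in the sweep
  direction, so the package reports forward/backward estimates and
  their mean.
* **Displacement gain**: mechanical sensitivities (peak displacement per
  stimulus unit) are fitted with $y = a/(1+e^{-(x-x_0)/b})$ against
  $x=\log_{10}$(intensity) — intensities are graded in logarithmic
  steps, so the log abscissa is the natural scale. The gain is the
  ratio of the fitted curve's values at the extreme tested intensities;
  a constant curve yields exactly 1. Fits with $R^2 < 0.9$ are flagged
  and should be excluded from group summaries, mirroring the protocol's
  $R^2 \ge 0.9$ acceptance rule. The "intensity" axis is treated as an
  abstract monotone stimulus magnitude; whether it is force, voltage or
  an index does not affect the gain.

## Differential-expression subsets

Three DESeq2-style result tables (transcript, log2 fold change, FDR-
adjusted p) from the comparisons male-vs-female (MvF),
intersex-vs-female (IvF) and male-vs-intersex (MvI) are intersected.
Within the gate "up in MvF" (padj < 0.05 and positive fold change) the
four subsets are the 2×2 significance pattern of (IvF, MvI):

| IvF significant | MvI significant | label | interpretation |
|---|---|---|---|
| yes | no  | `full_recovery`    | male-level expression restored in the intersex mutant |
| no  | yes | `male_independent` | male-biased expression untouched by the mutation |
| yes | yes | `partial_recovery` | intersex expression between female and male |
| no  | no  | `mvf_only`         | male-biased, mutation effect below significance |

"Not differentially expressed" means padj ≥ threshold regardless of
sign, and significance is strict (`padj < threshold`). The sign-aware
definitions ("upregulated in both…") coincide with this significance
split for sign-concordant data; splitting by significance keeps the four
labels an exhaustive partition of the MvF-up set even for discordant
patterns, which the set-sum bookkeeping requires. Missing adjusted
p-values count as non-significant (with a reported count); transcripts
absent from any table are dropped with a warning. The DE fit itself
(normalization, dispersion, testing) is out of scope — the package
consumes exported result tables.

The DE simulator plants the *decision pattern* directly: significant
comparisons draw padj uniformly below a tenth of the threshold,
non-significant ones uniformly above it. Drawing null padj uniformly on
(0,1) would plant false positives and make exact recovery of the
planted partition impossible; that behaviour is available via
`spurious_nulls = TRUE` for partition-property testing, but the default
states exactly the planted world.

## Statistical decision tree

Group comparisons follow the protocol's tree: Shapiro–Wilk screening at
α = 0.05 per group; independent designs use Welch's t-test when both
groups pass and a Mann–Whitney test otherwise; paired designs use the
Wilcoxon signed-rank test. All tests are two-sided (sidedness is not
specified by the protocol), Bonferroni-corrected by a caller-supplied
family size (the protocol does not enumerate family definitions per
figure). An optional Kruskal–Wallis omnibus annotates, but does not
gate, pairwise results, since pairwise p-values are the primary report.
All differences of identical paired samples being zero is reported as
p = 1. Test internals are delegated to `stats`; the package's contract
is the routing, correction and report.

## Numerical conventions and edge cases

* Boltzmann constant: exact SI value, 1.380649e-23 J/K.
* Temperature default 293 K everywhere, configurable.
* Angular-frequency convention: integrals over $\omega$ in rad/s;
  frequency grids in Hz are converted with $2\pi$ — pinned by the
  equipartition oracle.
* Flat spectra, all-zero CAPs, flat sweep responses, and constant
  sensitivity curves return flagged results (invalid / no-response /
  no-peak / gain 1) rather than errors.
* Seeded determinism: every simulator accepts an integer seed, restores
  the caller's RNG state, and returns bit-identical output for equal
  seeds.

## Known limitations

* The simulators are linear-response idealizations: no harmonic
  distortion, no efferent feedback, no intensity-dependent tuning
  shifts within a single sweep, no raw-read simulation for RNA-seq.
* Reproducing the study's published subset counts from real data
  additionally depends on the deposited GEO counts and DE software
  version; it is outside the tested scope.
* $N$ from gating fits should be treated as order-of-magnitude unless
  the gating dip is a substantial fraction of the stiffness (see
  above); $z$ and $K_\infty$ are robust.
* The sweep "intensity" axis is unitless by design.
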