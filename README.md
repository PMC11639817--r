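# amaresr

Time-domain AMARES fitting of magnetic resonance spectroscopy (MRS) data in R.

## The problem

In vivo MRS quantifies metabolites — phosphocreatine, ATP, inorganic
phosphate in ³¹P spectra; choline, creatine, NAA in ¹H spectra; dissolved
¹²⁹Xe or ²H compartments — from the complex free induction decay (FID)
recorded after excitation. AMARES (advanced method for accurate, robust and
efficient spectral fitting) is the workhorse time-domain approach for
X-nuclei spectra: it fits the FID directly as a sum of exponentially damped
sinusoids, with *prior knowledge* — initial values, box bounds, and
algebraic ties between peak parameters — constraining the fit so that
J-coupled multiplets keep their known splittings, amplitude ratios,
linewidths and phases. Because the model is fitted in the time domain, no
subjective spectral phasing is needed, which matters for data acquired with
long receiver dead times.

`amaresr` is aimed at spectroscopists who want scriptable, reproducible
AMARES quantification inside R pipelines: tibbles in, tibbles out,
broom-style `tidy()`/`glance()` accessors and `ggplot2::autoplot()`
figures.

## The model

The FID is modelled as

```
y_n = Σ_k  a_k · exp(j φ_k) · exp( −d_k [(1 − g_k) + g_k t_n] t_n ) · exp(j 2π f_k t_n)
```

for `n = 0 … N−1` at times `t_n = dead_time + n · dwell_time`, where each
spectral line `k` has amplitude `a_k` (a.u.), frequency `f_k` (Hz offset
from the carrier; user-facing chemical shifts in ppm), damping `d_k` (s⁻¹;
user-facing linewidth in Hz via `d = π·LW`), phase `φ_k` (degrees), and
lineshape `g_k ∈ [0, 1]` interpolating between Lorentzian (`g = 0`) and
Gaussian (`g = 1`) decay. Any parameter may be fitted, fixed, or tied to an
earlier peak's parameter through the prior-knowledge spreadsheet grammar
(`BATP/2` for an amplitude ratio, `BATP-15Hz` for a J-coupling offset, a
bare name for an identity tie). Fitting is bounded nonlinear least squares
(Levenberg–Marquardt, optionally preceded by an unconstrained LM
initializer that can recover from starting values ~100 Hz off); parameter
uncertainty is reported as the Cramér–Rao lower bound (CRLB) propagated
through the linear ties, with per-peak SNR defined as the fitted amplitude
per standard deviation of the time-domain noise.

Beyond conventional AMARES the package provides Hankel-SVD (HSVD) black-box
decomposition to fit spectra *without* prior knowledge, frequency-selective
fitting (band-pass FIR extraction of a region of interest, or a
frequency-masked objective), metabolite-residual removal for macromolecule
(MM) spectra, parallel batch fitting of dynamic series or MRSI voxels, and
a Monte-Carlo validation harness.

## Worked example

Fit a noisy synthetic 7T ³¹P brain spectrum against the packaged
prior-knowledge table (β-ATP triplet + α-ATP doublet, five peaks of which
only 7 parameters are free — the rest are tied or fixed by the multiplet
constraints):

```r
library(amaresr)

prior_path <- system.file("extdata", "prior_31p_brain.csv", package = "amaresr")
pk     <- parse_prior_knowledge(prior_path, carrier_mhz = 120.66)
params <- compile_parameters(pk)
params
#> <amares_params> 5 peaks | 7 free, 13 tied, 5 fixed parameters
#> free: BATP.amplitude, BATP.chemicalshift, BATP.linewidth, BATP.phase,
#>       AATP.amplitude, AATP.chemicalshift, AATP.linewidth

truth <- eval_full_params(params)
set.seed(42)
fid <- synthesize_fid(
  data.frame(name = rownames(truth), amplitude = truth[, "amplitude"],
             chemicalshift = truth[, "chemicalshift"],
             linewidth = truth[, "linewidth"], phase = truth[, "phase"],
             g = truth[, "g"]),
  n_points = 2048, sw_hz = 10000, carrier_mhz = 120.66)
fid$samples <- fid$samples + complex(real = rnorm(2048, 0, 0.05),
                                     imaginary = rnorm(2048, 0, 0.05))

fit <- fit_amares(fid, params, method = "trr+init")
tidy(fit)
#> # A tibble: 5 × 8
#>   name  amplitude chemicalshift linewidth  phase     g crlb_pct   snr
#> 1 BATP      1.41         -16.2       57.5 -0.169     0    0.486  28.8
#> 2 BATP2     0.705        -16.3       57.5 -0.169     0    0.486  14.4
#> 3 BATP3     0.705        -16.0       57.5 -0.169     0    0.486  14.4
#> 4 AATP      1.56          -7.49      32.4 -0.169     0    0.346  31.7
#> 5 AATP2     1.56          -7.62      32.4 -0.169     0    0.346  31.7

assemble_results(fit)$result_sum[, c("name", "peaks", "amplitude",
                                     "crlb_pct", "snr", "reliable")]
#> # A tibble: 2 × 6
#>   name  peaks            amplitude crlb_pct   snr reliable
#> 1 BATP  BATP+BATP2+BATP3      2.82    0.486  57.5 TRUE
#> 2 AATP  AATP+AATP2            3.11    0.346  63.4 TRUE

autoplot(fit)   # original / fitted / residual spectra + components
```

Reading this output: the fitted `BATP` amplitude 1.41 matches the
generating value; its subpeaks hold the tied `BATP/2` ratio exactly; the
`result_sum` table sums the β-ATP triplet to 2.82 with a propagated
amplitude CRLB of 0.49 % — far below the conventional 20 % reliability
threshold, so the row is flagged reliable (green in the HTML report written
by `render_report()`).

Other entry points: `hsvd_decompose()` / `hsvd_to_prior()` (fitting
without prior knowledge), `mpfir_extract()` and
`objective_spec("frequency_masked", ...)` (frequency-selective fitting),
`quarter_sine_weights()` + `subtract_fitted()` (macromolecule residual
removal), `fit_batch()` (parallel dynamic-series/MRSI fitting),
`simulate_dataset()` / `evaluate_recovery()` (Monte-Carlo validation), and
`run_pipeline()` / `inst/cli/amares.R` (end-to-end runs from files).

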