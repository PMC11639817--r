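---
title: "AMARES fitting in amaresr: model, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AMARES fitting in amaresr: model, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the science and the engineering conventions behind
`amaresr`: the signal model and its assumptions, the prior-knowledge
grammar, the optimization and uncertainty machinery, the numerical choices
that had to be pinned down for reproducibility, and what the synthetic
validation data do and do not establish about real spectra.

## The signal model

An FID acquired after excitation is modelled as a sum of K damped
sinusoids,

$$y_n = \sum_{k=1}^{K} a_k\, e^{j\varphi_k}\,
  e^{-d_k\left[(1-g_k) + g_k t_n\right] t_n}\, e^{j 2\pi f_k t_n},
  \qquad t_n = t_{\mathrm{dead}} + n\,\Delta t,$$

with amplitude $a_k$ (arbitrary units, proportional to metabolite
concentration and to the integrated spectral area under this model),
frequency $f_k$ in Hz offset from the carrier, damping $d_k$ in s⁻¹, phase
$\varphi_k$ in degrees (converted to radians internally), and lineshape
$g_k \in [0,1]$. The envelope exponent interpolates linearly between a
Lorentzian decay ($\propto t$, $g=0$) and a Gaussian decay ($\propto t^2$,
$g=1$) sharing the single coefficient $d_k$; intermediate $g$ gives a
Voigt-like line.

Assumptions inherited from this model: the signal is a finite sum of
well-separated exponentially damped components; the noise is additive,
circular Gaussian, and white in the time domain; and the acquisition is
characterized fully by dwell time, dead time, spectrometer frequency and
reference shift. The time axis *includes* the dead time, so a nonzero
dead time produces the physical frequency-dependent phase ramp in the
spectrum rather than being absorbed into fitted phases.

### Units and the linewidth bijection

Users work in field units: chemical shift in ppm
($\mathrm{ppm} = \mathrm{ref} + \mathrm{Hz}/\mathrm{MHz}$), linewidth in
Hz, phase in degrees. The linewidth column maps to the damping coefficient
by the Lorentzian-equivalent bijection $d = \pi \cdot \mathrm{LW}$ for
*every* $g$. For $g > 0$ the true FWHM of the line is therefore a derived
quantity, computed numerically from a densely zero-filled spectrum when
needed; the package deliberately does not invent a closed-form Voigt FWHM.
This single, documented bijection keeps the map between the spreadsheet
and the optimizer's parameter space bijective and the fit well posed. The
test suite verifies that for a pure Lorentzian the absorption-mode FWHM
measured on a 64-fold zero-filled spectrum agrees with the nominal
linewidth to well under 1 % once the dwell time is fine relative to the
decay (the discrete-time spectrum of a sampled exponential deviates from
the continuous Lorentzian at first order in $d\,\Delta t$).

### DFT convention

`fid_to_spectrum()` uses the unnormalized forward DFT, reordered so the
frequency axis runs uniformly over $[-SW/2, SW/2)$ with the carrier at
0 Hz; Parseval then reads $\sum_n |y_n|^2 = \frac{1}{M}\sum_m |Y_m|^2$.
First-order phase is parameterized as a time delay $\tau$ (s), applied as
$e^{j 2\pi f \tau}$, matching dead-time physics. Any consistent convention
would work; this one is pinned so that tests can be exact.

## Prior knowledge

The spreadsheet dialect has an `Index` row naming peaks (columns ordered
left to right), an `Initial Values` block and a `Bounds` block with the
five rows `amplitude`, `chemicalshift`, `linewidth`, `phase`, `g`, and
`#`-comment lines. Bounds use bracket syntax (`"(0,"` = positive with no
upper limit; a bare number = fixed). Initial-value cells are numbers or
single-operation tie expressions referencing a peak to the left: identity
(`BATP`), ratio (`BATP/2`, `BATP*2`), Hz offset (`BATP-15Hz`, converted to
ppm through the spectrometer frequency when applied to a chemical shift),
or unsuffixed ppm offset (chemical-shift row only).

Three semantic decisions were genuinely open and are resolved as follows:

* **Ties are hard constraints.** An expression in the initial-values block
  makes that parameter tied for the *entire* fit, not merely initialized:
  multiplet amplitude ratios and J-splittings are exact at every iteration
  and at the solution, and the CRLB machinery treats them as zero-variance
  linear constraints. This is what makes a triplet behave as one
  concentration parameter.
* **`g = 0` pins the lineshape.** A numeric initial `g` of exactly 0 fixes
  the peak as Lorentzian regardless of the g bounds row; a positive
  initial `g` (e.g. 0.1) is fitted within its bounds. This mirrors how
  lineshapes are specified in practice — Lorentzian by default, Voigt
  opt-in — and reproduces the intended free-parameter count of the
  packaged ³¹P example (7 free parameters for 5 peaks).
* **Expressions in the Bounds block are rejected** with a clear message
  rather than guessed at; no printed example exists to fix their meaning.

Classification is exhaustive: every (peak, field) cell compiles to exactly
one of free (bare number + range bound), tied (expression), or fixed (bare
number with no bound or a single-value bound). Free initial values are
clipped into their bounds before fitting.

## Initializers

* **HSVD.** The FID is arranged into an $L \times (N-L+1)$ Hankel matrix
  ($L = \lfloor N/2 \rfloor$ by default), its SVD truncated to rank K, and
  the signal poles estimated from the row-shifted truncated left-singular
  subspace by least squares; complex amplitudes follow from a Vandermonde
  least-squares solve, back-referenced to the excitation time when a dead
  time is present. When K is not given it is chosen by the largest
  relative singular-value gap, capped at 25 — a documented default, and
  overridable. Components with negative damping (growing exponentials,
  typically noise artifacts) are flagged and dropped. `hsvd_to_prior()`
  turns retained components into a wide-bounds prior, enabling fitting of
  spectra with no prior knowledge at all.
* **LM initializer.** An *unconstrained* Levenberg–Marquardt pass on the
  free parameters (ties still exact), clipped into bounds afterwards.
  Being unconstrained is the point: a starting chemical shift ~100 Hz off
  can travel to the true line without being stopped at a box edge. The
  refined values are guaranteed never to worsen the objective — if they
  would, the input values are returned.

## Fitting

The bounded solver behind the `"trr"` and `"trr+init"` methods is
`minpack.lm::nls.lm` — Levenberg–Marquardt with box projection — rather
than a hand-written trust-region-reflective algorithm; the method names
keep the terms the field uses for "bounded fit" and "bounded fit with LM
initialization". `"lm"` runs unconstrained and clips the solution into the
bounds afterwards. Jacobians are numerical (the package never requires
analytic derivatives, which keeps user-defined objectives unrestricted).
Convergence tolerances default to $10^{-8}$ on the objective and the
parameters with at most 3000 function evaluations, all overridable via
`control`. The fitter is deterministic given identical inputs; all
stochasticity lives in the simulation harness under explicit seeds.

Objectives:

* `time_domain` (default): concatenated real and imaginary parts of
  (model − data), optionally weighted per sample (this is how quarter-sine
  weighting enters a fit: weighting the residual is equivalent to
  weighting both model and data).
* `frequency_masked`: both model and data are transformed at the data
  length (no extra zero-fill, so mask bins are well defined) and the same
  real/imaginary construction is restricted to bins whose chemical shift
  lies in `ppm_range`. The complex spectrum is compared in-mask — not just
  the real part — so the objective stays insensitive to phasing.
* `user_hook`: any function of (free values, FID, compiled parameters)
  returning a numeric residual vector, with optional declared length that
  is validated on every call.

### Frequency-selective extraction

`mpfir_extract()` convolves the FID with a complex band-pass FIR: a
linear-phase windowed-design (Hamming) low-pass prototype modulated to the
band centre, with the constant group delay trimmed. Two numerical choices
matter. First, the user's `filter_order` (default 50) is a floor — the
order is raised automatically until the transition band is no wider than
half the passband, because a short filter against a narrow band otherwise
has several percent of passband droop. Second, the prototype is normalized
to unity gain at the band centre. The design contract — out-of-band tones
suppressed by ≥ 40 dB, in-band amplitudes preserved within 2 % — is
asserted by the tests. A passband covering the whole spectral window is
treated as an all-pass (the input is returned unchanged). The extraction
route and the masked-objective route are independent implementations of
frequency-selective fitting and are checked against each other and against
a full multi-peak fit.

## Uncertainty

The noise convention: $\sigma$ is the standard deviation per
real/imaginary channel of the time-domain samples, estimated by default as
the pooled SD over the trailing eighth of the raw FID (robust to fit bias;
requires the signal to have decayed there, and at least 128 samples) or
optionally from the fit residual. The Fisher information is
$F = J^\top J / \sigma^2$ with $J$ the numerical Jacobian of the
concatenated real/imaginary model vector with respect to the *free*
parameters only — ties folded in by the chain rule — so
$\mathrm{CRLB}_i = \sqrt{(F^{-1})_{ii}}$, and with this convention the
one-free-amplitude case has the exact closed form
$\mathrm{CRLB}_a = \sigma / \lVert m \rVert_2$, which the tests verify to
numerical precision. Rank-deficient information matrices are flagged with
their condition number and pseudo-inverted, with unidentifiable parameters
reported as infinite. Per-peak amplitude CRLBs and multiplet
summed-amplitude CRLBs come from the linear combination $w^\top \Sigma w$
of the amplitude covariance block; a consequence worth knowing is that a
scale-tied subpeak has exactly the CRLB% of its source. SNR is the fitted
amplitude divided by $\sigma$; rows whose amplitude CRLB% is below the
threshold (default 20 %) are flagged reliable, and the HTML report colors
them green.

## Macromolecule-residual removal

For short-echo ¹H spectra the broad mobile-macromolecule (MM) background
decays within the first few milliseconds. The workflow: weight the first
20 points with the quarter-sine ramp
$w_i = \sin\!\big(i\pi / (2(M{-}1))\big)$ — anchored so $w_0 = 0$ and
$w_{M-1} = 1$, a pinned choice since the window's sampling alignment is
not standardized — fit only the narrow metabolite lines with those weights
in the objective, then subtract the fitted metabolites from the
*unweighted* FID. What remains is the MM spectrum.
`shift_fid_to_reference()` supports the companion alignment step (e.g.
moving the water line to 4.70 ppm) by time-domain modulation, which
shifts the spectrum without altering its shape.

## Batch fitting

`fit_batch()` compiles the prior once and fits each FID independently,
optionally across forked worker processes. Because the fitter is
deterministic, results are identical bit-for-bit at any worker count, and
output order always matches input order; a failure on one FID (e.g.
corrupt samples) is logged against its index without aborting the batch.

## The synthetic-data generator

`simulate_dataset()` draws, per replicate, a truth perturbed uniformly on
± the stated half-widths (additive in Hz for frequency and degrees for
phase; multiplicative for amplitude and linewidth — the uniform
distribution is a documented choice, as is the ±100 Hz frequency
half-width used in the singlet robustness benchmark and the <5 %
multiplicative perturbations used for multi-peak scenarios), synthesizes
the noiseless FID, and adds i.i.d. Gaussian noise per channel at
$\sigma = \max_k a_k / \mathrm{SNR}$ — SNR is anchored to the largest true
amplitude, a convention that must be pinned because "SNR" alone is
ambiguous. Replicates are seeded individually from a base seed, so every
dataset is exactly reproducible. The default SNR grid
$\{2, 5, 10, 20\}$ spans what practitioners would call low to high SNR
for single-shot X-nuclei spectra.

What the generator emulates: model-consistent spectra with parameter
scatter and white complex noise — exactly the regime in which bias, CRLB
consistency and initializer robustness are well-defined quantities. What
it does not emulate: baseline distortions, eddy-current and lineshape
distortions beyond the Voigt family, correlated or non-Gaussian noise,
residual water, motion, and frequency drift within an acquisition.
Passing the validation suite therefore demonstrates correctness of the
estimator under its own model assumptions, not performance on pathological
in vivo data; on real spectra the user remains responsible for
preprocessing (the package deliberately performs none) and for priors
that reflect the acquisition.

## Validation problem sizes

The shipped validation uses: 200 replicates per SNR level
$\{5, 10, 20\}$ for the perturbed-singlet benchmark (512 points, 5 kHz
bandwidth); 20 random mixtures of up to three damped sinusoids for the
HSVD construct-and-recover oracle; a 1024-point two-peak scenario for the
frequency-selective equivalence; a 1024-point, 2.5 kHz three-metabolite +
two-MM scenario for residual removal; and a 366-spectrum dynamic series at
256 points for batch fitting. These sizes were chosen as the smallest at
which the quantities of interest are estimated stably.

## Known limitations

* Only single-operation ties are supported — no general arithmetic, no
  cross-field ties (e.g. phase tied to a linewidth).
* The bounded solver is projected Levenberg–Marquardt, not a true interior
  trust-region-reflective method; on fits where many bounds are active the
  two can differ in path (not, in our testing, in solution quality).
* CRLBs assume the model is correct and the noise white Gaussian; they are
  lower bounds, not posterior intervals.
* No vendor raw-data readers and no preprocessing (coil combination,
  apodization, eddy-current correction) — convert and preprocess with a
  dedicated tool, then hand the FID and its four acquisition numbers to
  this package.
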