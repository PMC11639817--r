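#' Complex FID time-domain signal
#'
#' Container for a free induction decay (FID): the complex time-domain MR
#' signal acquired after excitation, together with the acquisition metadata
#' needed to interpret it (dwell time, dead time, spectrometer frequency,
#' reference chemical shift).
#'
#' The time axis includes the dead time: `t_n = dead_time + n * dwell_time`
#' for `n = 0 .. N-1`, so the model is always evaluated at true
#' post-excitation times.
#'
#' @param samples Complex vector of FID samples (arbitrary units). A real
#'   vector is promoted to complex.
#' @param sw_hz Spectral width (sampling bandwidth) in Hz. Exactly one of
#'   `sw_hz` and `dwell_time` must be given.
#' @param dwell_time Dwell time in seconds (`1 / sw_hz`).
#' @param dead_time Delay in seconds between the RF excitation and the first
#'   acquired sample. Default 0.
#' @param carrier_mhz Spectrometer frequency in MHz (must be positive).
#' @param ref_ppm Chemical shift (ppm) assigned to 0 Hz offset. Default 0.
#'
#' @return An object of class `fid_signal`.
#' @export
#' @examples
#' fid <- fid_signal(complex(real = rnorm(256), imaginary = rnorm(256)),
#'                   sw_hz = 5000, carrier_mhz = 120.7)
#' fid
fid_signal <- function(samples, sw_hz = NULL, dwell_time = NULL,
                       dead_time = 0, carrier_mhz, ref_ppm = 0) {
  if (is.null(dwell_time) && is.null(sw_hz)) {
    stop("supply either `sw_hz` or `dwell_time`")
  }
  if (is.null(dwell_time)) dwell_time <- 1 / sw_hz
  samples <- as.complex(samples)
  n <- length(samples)
  if (n < 2L) stop("an FID needs at least 2 samples")
  if (!is.numeric(dwell_time) || dwell_time <= 0) stop("`dwell_time` must be > 0")
  if (dead_time < 0) stop("`dead_time` must be >= 0")
  if (!is.numeric(carrier_mhz) || carrier_mhz <= 0) stop("`carrier_mhz` must be > 0")
  structure(
    list(samples = samples, dwell_time = dwell_time, dead_time = dead_time,
         carrier_mhz = carrier_mhz, ref_ppm = ref_ppm),
    class = "fid_signal"
  )
}

#' @export
print.fid_signal <- function(x, ...) {
  cat(sprintf(
    "<fid_signal> %d complex points | SW %.6g Hz | dwell %.6g s | dead time %.6g s | %.6g MHz | ref %.6g ppm\n",
    n_points(x), sw_hz(x), x$dwell_time, x$dead_time, x$carrier_mhz, x$ref_ppm))
  invisible(x)
}

#' Number of points, spectral width and time axis of an FID
#'
#' @param fid A [fid_signal].
#' @return `n_points()`: integer count; `sw_hz()`: the spectral width in Hz;
#'   `fid_times()`: the time axis `dead_time + n * dwell_time` in seconds.
#' @export
n_points <- function(fid) length(fid$samples)

#' @rdname n_points
#' @export
sw_hz <- function(fid) 1 / fid$dwell_time

#' @rdname n_points
#' @export
fid_times <- function(fid) {
  fid$dead_time + (seq_len(n_points(fid)) - 1) * fid$dwell_time
}

# ---- unit conversions -------------------------------------------------------

#' Convert between Hz offsets and ppm chemical shifts
#'
#' The chemical-shift convention is `ppm = ref_ppm + hz / carrier_mhz`: a
#' frequency offset in Hz divided by the spectrometer frequency in MHz gives
#' the field-independent shift in parts per million, anchored at the reference
#' shift assigned to 0 Hz.
#'
#' @param hz,ppm Value(s) to convert.
#' @param carrier_mhz Spectrometer frequency in MHz (> 0).
#' @param ref_ppm Chemical shift assigned to 0 Hz offset.
#' @return Converted numeric vector.
#' @export
#' @examples
#' hz_to_ppm(78.125, carrier_mhz = 35.3)  # ~2.21 ppm
hz_to_ppm <- function(hz, carrier_mhz, ref_ppm = 0) {
  if (!is.numeric(carrier_mhz) || any(carrier_mhz <= 0)) stop("`carrier_mhz` must be > 0")
  ref_ppm + hz / carrier_mhz
}

#' @rdname hz_to_ppm
#' @export
ppm_to_hz <- function(ppm, carrier_mhz, ref_ppm = 0) {
  if (!is.numeric(carrier_mhz) || any(carrier_mhz <= 0)) stop("`carrier_mhz` must be > 0")
  (ppm - ref_ppm) * carrier_mhz
}

#' Convert between user-facing linewidth (Hz) and model damping (1/s)
#'
#' The model's decay envelope is `exp(-d * ((1 - g) + g * t) * t)`: the
#' lineshape parameter `g` linearly mixes a Lorentzian (exponent proportional
#' to `t`) and a Gaussian (proportional to `t^2`) decay sharing a single
#' coefficient `d`. The user-facing linewidth column maps to `d` through the
#' Lorentzian-equivalent bijection `d = pi * linewidth` for every `g`; for
#' `g > 0` the true full width at half maximum is a derived quantity and is
#' computed numerically where reported.
#'
#' @param linewidth Linewidth in Hz (>= 0).
#' @param damping Damping coefficient in 1/s (>= 0).
#' @param g Lineshape parameter in `[0, 1]` (0 Lorentzian, 1 Gaussian).
#'   Accepted for interface symmetry; the bijection does not depend on it.
#' @return Damping in 1/s, or linewidth in Hz for the inverse.
#' @export
linewidth_to_damping <- function(linewidth, g = 0) {
  if (any(linewidth < 0, na.rm = TRUE)) stop("`linewidth` must be >= 0")
  if (any(g < 0 | g > 1, na.rm = TRUE)) stop("`g` must lie in [0, 1]")
  pi * linewidth
}

#' @rdname linewidth_to_damping
#' @export
damping_to_linewidth <- function(damping, g = 0) {
  if (any(damping < 0, na.rm = TRUE)) stop("`damping` must be >= 0")
  damping / pi
}

# ---- peak tables ------------------------------------------------------------

# Normalize a peak table to model units: one row per spectral line with
# amplitude (a.u.), frequency (Hz offset from carrier), damping (1/s),
# phase (degrees), g in [0, 1]. User-unit columns chemicalshift (ppm) and
# linewidth (Hz) are converted when the model-unit columns are absent.
normalize_peaks <- function(peaks, carrier_mhz = 1, ref_ppm = 0) {
  peaks <- tibble::as_tibble(peaks)
  if (nrow(peaks) == 0L) stop("peak table is empty")
  if (!"amplitude" %in% names(peaks)) stop("peak table needs an `amplitude` column")
  if (!"frequency" %in% names(peaks)) {
    if (!"chemicalshift" %in% names(peaks)) {
      stop("peak table needs a `frequency` (Hz) or `chemicalshift` (ppm) column")
    }
    peaks$frequency <- ppm_to_hz(peaks$chemicalshift, carrier_mhz, ref_ppm)
  }
  if (!"g" %in% names(peaks)) peaks$g <- 0
  if (!"damping" %in% names(peaks)) {
    if (!"linewidth" %in% names(peaks)) {
      stop("peak table needs a `damping` (1/s) or `linewidth` (Hz) column")
    }
    peaks$damping <- linewidth_to_damping(peaks$linewidth, peaks$g)
  }
  if (!"phase" %in% names(peaks)) peaks$phase <- 0
  if (!"name" %in% names(peaks)) peaks$name <- paste0("Peak", seq_len(nrow(peaks)))
  out <- peaks[, c("name", "amplitude", "frequency", "damping", "phase", "g")]
  for (col in c("amplitude", "frequency", "damping", "phase", "g")) {
    if (!all(is.finite(out[[col]]))) {
      bad <- out$name[!is.finite(out[[col]])][1]
      stop(sprintf("non-finite `%s` for peak %s", col, bad))
    }
  }
  if (any(out$g < 0 | out$g > 1)) stop("`g` must lie in [0, 1]")
  if (any(out$damping < 0)) stop("`damping` must be >= 0")
  out
}

# Inverse of normalize_peaks: model units -> user units (ppm, Hz linewidth).
peaks_to_user <- function(peaks, carrier_mhz, ref_ppm = 0) {
  tibble::tibble(
    name = peaks$name,
    amplitude = peaks$amplitude,
    chemicalshift = hz_to_ppm(peaks$frequency, carrier_mhz, ref_ppm),
    linewidth = damping_to_linewidth(peaks$damping, peaks$g),
    phase = peaks$phase,
    g = peaks$g
  )
}

# ---- model synthesis --------------------------------------------------------

# Evaluate the damped-sinusoid model at times t (seconds) for model-unit peaks.
model_eval <- function(peaks, t) {
  y <- complex(length(t))
  for (k in seq_len(nrow(peaks))) {
    a <- peaks$amplitude[k]; f <- peaks$frequency[k]; d <- peaks$damping[k]
    phi <- peaks$phase[k] * pi / 180; g <- peaks$g[k]
    envelope <- exp(-d * ((1 - g) + g * t) * t)
    y <- y + a * exp(1i * phi) * envelope * exp(2i * pi * f * t)
  }
  y
}

#' Synthesize an FID from a table of spectral lines
#'
#' Evaluates the sum-of-damped-sinusoids model
#' \deqn{y_n = \sum_k a_k e^{j\varphi_k} e^{-d_k[(1-g_k)+g_k t_n] t_n}
#'   e^{j 2\pi f_k t_n}}
#' at `t_n = dead_time + n * dwell_time`. Each row of `peaks` is one line
#' with amplitude `a` (a.u.), frequency `f` (Hz offset; or `chemicalshift` in
#' ppm), damping `d` (1/s; or `linewidth` in Hz, converted by
#' [linewidth_to_damping()]), `phase` (degrees) and lineshape `g` in `[0, 1]`.
#' Synthesis is additive over peaks.
#'
#' @param peaks Data frame of peaks; see Details for recognized columns.
#' @param n_points Number of samples to generate.
#' @param sw_hz,dwell_time Spectral width in Hz or dwell time in s (one of).
#' @param dead_time,carrier_mhz,ref_ppm Acquisition metadata (see
#'   [fid_signal()]).
#' @param like A [fid_signal] to copy all metadata (and length) from.
#' @return A [fid_signal] of length `n_points`.
#' @export
#' @examples
#' fid <- synthesize_fid(
#'   data.frame(amplitude = 1, frequency = 250, damping = 30, phase = 0, g = 0),
#'   n_points = 512, sw_hz = 5000, carrier_mhz = 120.7)
synthesize_fid <- function(peaks, n_points = NULL, sw_hz = NULL,
                           dwell_time = NULL, dead_time = 0,
                           carrier_mhz = 1, ref_ppm = 0, like = NULL) {
  if (!is.null(like)) {
    stopifnot(inherits(like, "fid_signal"))
    if (is.null(n_points)) n_points <- n_points(like)
    dwell_time <- like$dwell_time; dead_time <- like$dead_time
    carrier_mhz <- like$carrier_mhz; ref_ppm <- like$ref_ppm
    sw_hz <- NULL
  }
  if (is.null(n_points) || n_points < 2) stop("`n_points` must be >= 2")
  if (is.null(dwell_time)) {
    if (is.null(sw_hz)) stop("supply `sw_hz`, `dwell_time`, or `like`")
    dwell_time <- 1 / sw_hz
  }
  pk <- normalize_peaks(peaks, carrier_mhz, ref_ppm)
  t <- dead_time + (seq_len(n_points) - 1) * dwell_time
  fid_signal(model_eval(pk, t), dwell_time = dwell_time, dead_time = dead_time,
             carrier_mhz = carrier_mhz, ref_ppm = ref_ppm)
}

# ---- Fourier transform ------------------------------------------------------

#' Fourier transform an FID into a frequency-domain spectrum
#'
#' Forward DFT (no 1/N scaling) of the optionally zero-filled FID, with the
#' output reordered so the frequency axis runs uniformly over
#' `[-SW/2, SW/2)` and the carrier sits at 0 Hz. Optional zero-order phase
#' (degrees) and first-order phase expressed as a time delay in seconds
#' (applied as `exp(j 2 pi f tau)`, matching dead-time physics) are applied
#' multiplicatively in the frequency domain.
#'
#' @param fid A [fid_signal].
#' @param zero_fill Output length; must be `>= n_points(fid)`. Default: no
#'   zero filling.
#' @param phase0 Zero-order phase in degrees (default 0).
#' @param phase1 First-order phase as a time delay in seconds (default 0).
#' @return A tibble of class `mrs_spectrum` with columns `freq_hz`, `ppm`
#'   and complex `intensity`, ordered by increasing frequency.
#' @export
fid_to_spectrum <- function(fid, zero_fill = NULL, phase0 = 0, phase1 = 0) {
  stopifnot(inherits(fid, "fid_signal"))
  n <- n_points(fid)
  m <- if (is.null(zero_fill)) n else as.integer(zero_fill)
  if (m < n) stop("`zero_fill` must be >= n_points(fid)")
  y <- c(fid$samples, complex(m - n))
  Y <- stats::fft(y)
  sw <- sw_hz(fid)
  freq_unordered <- c(seq(0, ceiling(m / 2) - 1), seq(-floor(m / 2), -1)) * sw / m
  ord <- order(freq_unordered)
  freq <- freq_unordered[ord]
  Y <- Y[ord]
  if (phase0 != 0 || phase1 != 0) {
    Y <- Y * exp(1i * (phase0 * pi / 180 + 2 * pi * freq * phase1))
  }
  out <- tibble::tibble(
    freq_hz = freq,
    ppm = hz_to_ppm(freq, fid$carrier_mhz, fid$ref_ppm),
    intensity = Y
  )
  class(out) <- c("mrs_spectrum", class(out))
  attr(out, "zero_fill") <- m
  attr(out, "sw_hz") <- sw
  out
}

# ---- FID post-processing ----------------------------------------------------

#' Quarter-sine weights for the leading FID samples
#'
#' The first `n_weighted` samples are multiplied by the rising quarter of a
#' sine wave, `w_i = sin(i * pi / (2 * (n_weighted - 1)))` for
#' `i = 0 .. n_weighted - 1`, so `w_0 = 0` and `w_{n_weighted-1} = 1`; all
#' later samples are left untouched. This de-emphasizes the earliest points,
#' where rapidly decaying broad (macromolecule) components dominate.
#'
#' @param fid A [fid_signal].
#' @param n_points Total length of the returned weight vector.
#' @param n_weighted Number of leading samples on the ramp (default 20); must
#'   be at least 2 and less than the FID length.
#' @return `quarter_sine_weights()`: a numeric weight vector;
#'   `quarter_sine_weight()`: the weighted [fid_signal].
#' @export
quarter_sine_weights <- function(n_points, n_weighted = 20) {
  if (n_weighted <= 1) stop("`n_weighted` must be > 1")
  if (n_weighted >= n_points) stop("`n_weighted` must be < n_points")
  i <- seq_len(n_points) - 1
  ifelse(i < n_weighted, sin(i * pi / (2 * (n_weighted - 1))), 1)
}

#' @rdname quarter_sine_weights
#' @export
quarter_sine_weight <- function(fid, n_weighted = 20) {
  stopifnot(inherits(fid, "fid_signal"))
  w <- quarter_sine_weights(n_points(fid), n_weighted)
  fid$samples <- fid$samples * w
  fid
}

#' Shift an FID so an observed peak lands at a target chemical shift
#'
#' Multiplies the samples by `exp(-j 2 pi df t_n)` with
#' `df = (observed_peak_ppm - target_ppm) * carrier_mhz`, which circularly
#' shifts the magnitude spectrum so the observed peak moves to `target_ppm`
#' (e.g. aligning the water resonance to 4.7 ppm before macromolecule
#' analysis).
#'
#' @param fid A [fid_signal].
#' @param observed_peak_ppm Chemical shift where the landmark peak currently
#'   appears.
#' @param target_ppm Chemical shift where it should appear.
#' @return The shifted [fid_signal].
#' @export
shift_fid_to_reference <- function(fid, observed_peak_ppm, target_ppm) {
  stopifnot(inherits(fid, "fid_signal"))
  df <- ppm_to_hz(observed_peak_ppm - target_ppm, fid$carrier_mhz)
  if (abs(df) >= sw_hz(fid) / 2) {
    stop("requested shift exceeds half the spectral width")
  }
  fid$samples <- fid$samples * exp(-2i * pi * df * fid_times(fid))
  fid
}

#' Subtract synthesized peaks from an FID
#'
#' Re-synthesizes the named subset of fitted peaks on the FID's own time axis
#' and subtracts it sample-wise. Subtracting all fitted metabolite lines from
#' a short-echo spectrum isolates the mobile-macromolecule (MM) background.
#'
#' @param fid A [fid_signal].
#' @param peaks Fitted peak table (as returned in `tidy()` of a fit, or any
#'   table [synthesize_fid()] accepts, with a `name` column).
#' @param subset Character vector of peak names to subtract; `NULL` (default)
#'   subtracts every peak; `character(0)` returns the input unchanged.
#' @return The residual [fid_signal].
#' @export
subtract_fitted <- function(fid, peaks, subset = NULL) {
  stopifnot(inherits(fid, "fid_signal"))
  pk <- normalize_peaks(peaks, fid$carrier_mhz, fid$ref_ppm)
  if (is.null(subset)) subset <- pk$name
  if (length(subset) == 0L) return(fid)
  unknown <- setdiff(subset, pk$name)
  if (length(unknown)) {
    stop("unknown peak name(s): ", paste(unknown, collapse = ", "))
  }
  model <- synthesize_fid(pk[pk$name %in% subset, , drop = FALSE], like = fid)
  fid$samples <- fid$samples - model$samples
  fid
}
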