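#' Hankel SVD decomposition of an FID into damped sinusoids
#'
#' Black-box (prior-knowledge-free) decomposition: the FID is arranged into
#' an L x M Hankel matrix, its SVD truncated to rank `k`, and the signal
#' poles `z = exp((-d + j 2 pi f) * dwell)` estimated from the row-shifted
#' truncated left-singular subspace by least squares (state-space Hankel SVD
#' estimation); complex amplitudes then follow from a linear least-squares
#' solve against the pole basis. Components with negative damping are flagged
#' and dropped by default. Amplitude and phase are referenced to the true
#' excitation time, i.e. corrected for the dead time.
#'
#' @param fid A [fid_signal].
#' @param k Model order (number of components). Default: chosen by the
#'   largest relative singular-value gap, capped at 25.
#' @param hankel_rows Number of Hankel rows L (default `floor(N/2)`).
#' @param drop_negative_damping Drop components whose damping is negative
#'   (beyond numerical tolerance)? Default `TRUE`.
#' @return A tibble of class `hsvd_components`, one row per retained
#'   component sorted by frequency, with columns `name`, `amplitude`,
#'   `frequency` (Hz), `damping` (1/s), `phase` (deg), `g` (all 0);
#'   attributes `k`, `singular_values` and `dropped` (components removed by
#'   the damping filter).
#' @export
#' @examples
#' fid <- synthesize_fid(
#'   data.frame(amplitude = 1.5, frequency = 250, damping = 30, phase = 30),
#'   n_points = 512, sw_hz = 5000, carrier_mhz = 120.7)
#' hsvd_decompose(fid, k = 1)
hsvd_decompose <- function(fid, k = NULL, hankel_rows = NULL,
                           drop_negative_damping = TRUE) {
  stopifnot(inherits(fid, "fid_signal"))
  y <- fid$samples
  n <- length(y)
  L <- if (is.null(hankel_rows)) n %/% 2L else as.integer(hankel_rows)
  if (L < 2 || L > n - 1) stop("`hankel_rows` must lie in [2, N-1]")
  M <- n - L + 1L
  kmax <- min(L - 1L, M)
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 1 || k > kmax) {
      stop(sprintf("`k` must lie in [1, %d] for this Hankel geometry", kmax))
    }
  }
  H <- matrix(0 + 0i, L, M)
  for (i in seq_len(L)) H[i, ] <- y[i:(i + M - 1L)]
  sv <- svd(H, nu = min(kmax + 1L, L), nv = 0)
  s <- sv$d
  if (is.null(k)) {
    ncand <- min(25L, kmax, length(s) - 1L)
    gaps <- s[seq_len(ncand)] / pmax(s[seq_len(ncand) + 1L], .Machine$double.xmin)
    k <- which.max(gaps)
  }

  U <- sv$u[, seq_len(k), drop = FALSE]
  Z <- tryCatch(qr.solve(U[seq_len(L - 1L), , drop = FALSE],
                         U[2:L, , drop = FALSE]),
                error = function(e) NULL)
  empty <- tibble::tibble(name = character(), amplitude = numeric(),
                          frequency = numeric(), damping = numeric(),
                          phase = numeric(), g = numeric())
  finish <- function(comp, dropped) {
    comp <- comp[order(comp$frequency), , drop = FALSE]
    if (nrow(comp)) comp$name <- paste0("Peak", seq_len(nrow(comp)))
    structure(comp, class = c("hsvd_components", class(comp)),
              k = k, singular_values = s, dropped = dropped)
  }
  if (is.null(Z)) {
    warning("ill-conditioned pole solve; no components estimated")
    return(finish(empty, empty))
  }
  z <- eigen(Z, only.values = TRUE)$values
  lz <- log(z)
  ok <- is.finite(lz) & Mod(z) > 0
  z <- z[ok]; lz <- lz[ok]
  if (length(z) == 0L) return(finish(empty, empty))

  dwell <- fid$dwell_time
  damping <- -Re(lz) / dwell
  # clamp tiny negative dampings arising from roundoff on undamped tones
  damping[abs(damping) < 1e-8 * sw_hz(fid)] <- pmax(
    damping[abs(damping) < 1e-8 * sw_hz(fid)], 0)
  frequency <- Im(lz) / (2 * pi * dwell)
  B <- exp(outer(seq_len(n) - 1L, lz))
  camp <- tryCatch(qr.solve(B, y), error = function(e) {
    warning("ill-conditioned amplitude solve; components flagged zero")
    complex(length(z))
  })
  # refer amplitude/phase back to t = 0 (excitation), not the first sample
  camp <- camp * exp((damping - 2i * pi * frequency) * fid$dead_time)
  comp <- tibble::tibble(
    name = character(length(z)),
    amplitude = Mod(camp),
    frequency = frequency,
    damping = damping,
    phase = Arg(camp) * 180 / pi,
    g = 0
  )
  dropped <- empty
  if (drop_negative_damping && any(comp$damping < 0)) {
    dropped <- comp[comp$damping < 0, , drop = FALSE]
    comp <- comp[comp$damping >= 0, , drop = FALSE]
  }
  finish(comp, dropped)
}

#' Reconstruct an FID from HSVD components
#'
#' @param components A `hsvd_components` tibble.
#' @param like A [fid_signal] providing the acquisition grid.
#' @return A [fid_signal] synthesized from the components.
#' @export
hsvd_reconstruct <- function(components, like) {
  if (nrow(components) == 0L) {
    like$samples <- complex(n_points(like))
    return(like)
  }
  synthesize_fid(components, like = like)
}

#' Generate prior knowledge from HSVD components
#'
#' Builds a prior-knowledge object with one peak per retained component,
#' named `Peak1..PeakK` in frequency order: amplitude, chemical shift,
#' linewidth and phase are free with wide default bounds (amplitude > 0,
#' chemical shift within the spectral window, linewidth > 0, phase in
#' (-180, 180]); `g` is fixed at 0 (Lorentzian). This enables AMARES fitting
#' of spectra for which no prior knowledge is available.
#'
#' @param components A `hsvd_components` tibble with at least one row.
#' @param fid The [fid_signal] the components came from (supplies the
#'   spectral window, spectrometer frequency, and reference shift).
#' @return A `prior_knowledge` object.
#' @export
hsvd_to_prior <- function(components, fid) {
  stopifnot(inherits(fid, "fid_signal"))
  if (nrow(components) == 0L) stop("no HSVD components to build a prior from")
  carrier <- fid$carrier_mhz; ref <- fid$ref_ppm
  half_ppm <- sw_hz(fid) / 2 / carrier
  num <- function(x) sprintf("%.17g", x)
  cs <- hz_to_ppm(components$frequency, carrier, ref)
  lw <- damping_to_linewidth(components$damping)
  ph <- ((components$phase + 180) %% 360) - 180
  rows <- list(
    c("Index", components$name),
    c("Initial Values", rep("", nrow(components))),
    c("amplitude", num(components$amplitude)),
    c("chemicalshift", num(cs)),
    c("linewidth", num(lw)),
    c("phase", num(ph)),
    c("g", rep("0", nrow(components))),
    c("Bounds", rep("", nrow(components))),
    c("amplitude", rep("(0,", nrow(components))),
    c("chemicalshift", rep(sprintf("(%s, %s)", num(ref - half_ppm), num(ref + half_ppm)),
                           nrow(components))),
    c("linewidth", rep("(0,", nrow(components))),
    c("phase", rep("(-180, 180)", nrow(components))),
    c("g", rep("(0, 1)", nrow(components)))
  )
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  parse_prior_knowledge(df, carrier_mhz = carrier, ref_ppm = ref)
}
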