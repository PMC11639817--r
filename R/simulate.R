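#' Design of a Monte-Carlo recovery study
#'
#' Describes how synthetic spectra are generated: the true peak table, the
#' number of replicates, the SNR grid, per-parameter perturbation
#' half-widths, the acquisition grid, and the base seed. SNR is defined as
#' the largest true peak amplitude divided by the per-channel time-domain
#' noise SD. With all perturbation half-widths 0 every replicate shares the
#' same truth (only the noise differs); perturbations are drawn uniformly
#' on +/- the half-width — additive in Hz for frequency and in degrees for
#' phase, multiplicative (fractional) for amplitude and linewidth.
#'
#' @param peaks True peak table (any form [synthesize_fid()] accepts).
#' @param n_replicates Replicates per SNR level (default 500).
#' @param snr Numeric vector of SNR levels (all > 0); default
#'   `c(2, 5, 10, 20)` spans low to high SNR.
#' @param perturbation List with any of `frequency_hz`, `amplitude_frac`,
#'   `linewidth_frac`, `phase_deg` (all default 0).
#' @param n_points,sw_hz,dead_time,carrier_mhz,ref_ppm Acquisition grid.
#' @param seed Base seed; replicate r at SNR level s uses
#'   `seed + (s - 1) * n_replicates + r`.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(peaks, n_replicates = 500,
                              snr = c(2, 5, 10, 20),
                              perturbation = list(),
                              n_points = 512, sw_hz = 5000, dead_time = 0,
                              carrier_mhz = 1, ref_ppm = 0,
                              seed = 20240001) {
  if (any(snr <= 0)) stop("all SNR levels must be > 0")
  pert <- list(frequency_hz = 0, amplitude_frac = 0,
               linewidth_frac = 0, phase_deg = 0)
  unknown <- setdiff(names(perturbation), names(pert))
  if (length(unknown)) stop("unknown perturbation field(s): ",
                            paste(unknown, collapse = ", "))
  pert[names(perturbation)] <- perturbation
  truth <- normalize_peaks(peaks, carrier_mhz, ref_ppm)
  structure(list(truth = truth, n_replicates = as.integer(n_replicates),
                 snr = snr, perturbation = pert,
                 n_points = as.integer(n_points), sw_hz = sw_hz,
                 dead_time = dead_time, carrier_mhz = carrier_mhz,
                 ref_ppm = ref_ppm, seed = as.integer(seed)),
            class = "simulation_design")
}

#' Simulate a Monte-Carlo dataset of noisy FIDs
#'
#' For each SNR level and replicate: draws a perturbed truth uniformly
#' within the design's half-widths, synthesizes the noiseless FID, and adds
#' i.i.d. Gaussian noise per real/imaginary channel at
#' `sigma = max(amplitude) / SNR`. Fully reproducible from the design's
#' seed (each replicate re-seeds deterministically).
#'
#' @param design A [simulation_design()].
#' @return A tibble with one row per replicate: `snr`, `replicate`,
#'   `sigma`, list-columns `fid` ([fid_signal]) and `truth` (the perturbed
#'   model-unit peak table).
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  pert <- design$perturbation
  out <- vector("list", length(design$snr) * design$n_replicates)
  row <- 0L
  for (s in seq_along(design$snr)) {
    snr <- design$snr[s]
    for (r in seq_len(design$n_replicates)) {
      seed_r <- design$seed + (s - 1L) * design$n_replicates + r
      set.seed(seed_r)
      truth <- design$truth
      k <- nrow(truth)
      truth$frequency <- truth$frequency +
        stats::runif(k, -pert$frequency_hz, pert$frequency_hz)
      truth$amplitude <- truth$amplitude *
        (1 + stats::runif(k, -pert$amplitude_frac, pert$amplitude_frac))
      truth$damping <- truth$damping *
        (1 + stats::runif(k, -pert$linewidth_frac, pert$linewidth_frac))
      truth$phase <- truth$phase +
        stats::runif(k, -pert$phase_deg, pert$phase_deg)
      fid <- synthesize_fid(truth, n_points = design$n_points,
                            sw_hz = design$sw_hz, dead_time = design$dead_time,
                            carrier_mhz = design$carrier_mhz,
                            ref_ppm = design$ref_ppm)
      sigma <- max(truth$amplitude) / snr
      fid$samples <- fid$samples +
        complex(real = stats::rnorm(design$n_points, 0, sigma),
                imaginary = stats::rnorm(design$n_points, 0, sigma))
      row <- row + 1L
      out[[row]] <- tibble::tibble(snr = snr, replicate = r, sigma = sigma,
                                   seed = seed_r,
                                   fid = list(fid), truth = list(truth))
    }
  }
  dplyr::bind_rows(out)
}

#' Recovery metrics of fitted estimates against simulated truths
#'
#' Compares per-peak fitted parameters with the generating truths across
#' replicates, per parameter: relative bias
#' (`100 * mean((est - truth)/truth)` in percent; flagged `NA` when any
#' truth is 0, with the absolute bias always reported), empirical SD, mean
#' reported amplitude CRLB, CRLB coverage (fraction of replicates with
#' `|est - truth| <= 1.96 * CRLB`), and Pearson correlation of estimates
#' against truths (`NA` when the truth does not vary).
#'
#' @param fits List of `amares_fit` objects (or tibbles as from [tidy()]),
#'   aligned with `truths`.
#' @param truths List of model-unit truth peak tables (as produced by
#'   [simulate_dataset()]).
#' @return A tibble with one row per (peak, parameter).
#' @export
evaluate_recovery <- function(fits, truths) {
  stopifnot(length(fits) == length(truths))
  carrier <- NULL; ref <- NULL
  long <- purrr::map_dfr(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (inherits(f, "amares_fit")) {
      est <- f$peaks
      carrier <<- f$fid$carrier_mhz; ref <<- f$fid$ref_ppm
      crlb <- if (!is.null(f$uncertainty)) f$uncertainty$peaks else NULL
    } else {
      est <- tibble::as_tibble(f)
      crlb <- NULL
    }
    tr <- tibble::as_tibble(truths[[i]])
    if (!"chemicalshift" %in% names(tr) && !is.null(carrier)) {
      tr <- peaks_to_user(tr, carrier, ref)
    }
    fields <- intersect(c("amplitude", "chemicalshift", "linewidth", "phase"),
                        intersect(names(est), names(tr)))
    purrr::map_dfr(fields, function(fl) {
      j <- match(est$name, tr$name)
      crlb_col <- if (fl == "amplitude" && !is.null(crlb)) {
        crlb$crlb_abs[match(est$name, crlb$name)]
      } else rep(NA_real_, nrow(est))
      tibble::tibble(
        replicate = i, name = est$name, field = fl,
        est = est[[fl]], truth = tr[[fl]][j], crlb_abs = crlb_col
      )
    })
  })
  long <- long[stats::complete.cases(long[, c("est", "truth")]), ]
  dplyr::summarise(
    dplyr::group_by(long, .data$name, .data$field),
    n = dplyr::n(),
    rel_bias_pct = if (any(.data$truth == 0)) NA_real_ else
      100 * mean((.data$est - .data$truth) / .data$truth),
    abs_bias = mean(.data$est - .data$truth),
    sd_emp = stats::sd(.data$est),
    mean_crlb = mean(.data$crlb_abs),
    coverage = mean(abs(.data$est - .data$truth) <= 1.96 * .data$crlb_abs),
    pearson_r = if (dplyr::n() < 2 || stats::sd(.data$truth) == 0) NA_real_ else
      stats::cor(.data$est, .data$truth),
    .groups = "drop"
  )
}
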