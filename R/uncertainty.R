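#' Estimate the time-domain noise standard deviation
#'
#' The noise convention throughout the package: `sigma` is the standard
#' deviation per real/imaginary channel of the time-domain samples. In
#' `"fid_tail"` mode it is the pooled SD of the real and imaginary parts
#' over the trailing fraction of the raw FID (robust to fit bias, assuming
#' the signal has decayed there); in `"residual"` mode it is pooled over the
#' whole supplied residual series.
#'
#' @param x A [fid_signal] or a complex/numeric vector.
#' @param fraction Trailing fraction used in tail mode (default 1/8).
#' @param source `"fid_tail"` (default; requires at least 128 samples) or
#'   `"residual"`.
#' @return An object of class `noise_estimate`: list with `sigma`, `source`
#'   and `n_samples_used` (at least 16, enforced).
#' @export
estimate_noise_sd <- function(x, fraction = 1 / 8,
                              source = c("fid_tail", "residual")) {
  source <- match.arg(source)
  y <- if (inherits(x, "fid_signal")) x$samples else as.complex(x)
  n <- length(y)
  if (source == "fid_tail") {
    if (n < 128) stop("tail-mode noise estimation needs at least 128 samples")
    use <- y[(n - floor(n * fraction) + 1):n]
  } else {
    use <- y
  }
  if (length(use) < 16) stop("fewer than 16 usable samples for noise estimation")
  sigma <- sqrt((stats::var(Re(use)) + stats::var(Im(use))) / 2)
  structure(list(sigma = sigma, source = source, n_samples_used = length(use)),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate> sigma = %.6g per channel (%s, %d samples)\n",
              x$sigma, x$source, x$n_samples_used))
  invisible(x)
}

#' Per-peak signal-to-noise ratio
#'
#' SNR is defined as the fitted amplitude divided by one standard deviation
#' of the time-domain noise (per real/imaginary channel).
#'
#' @param amplitude Fitted amplitude(s), arbitrary units.
#' @param sigma A `noise_estimate` or a positive number.
#' @return Numeric SNR (infinite, with a warning, when `sigma` is 0).
#' @export
compute_snr <- function(amplitude, sigma) {
  s <- if (inherits(sigma, "noise_estimate")) sigma$sigma else sigma
  if (s == 0) {
    warning("sigma is 0; SNR is infinite")
    return(ifelse(amplitude == 0, NaN, Inf * sign(amplitude)))
  }
  amplitude / s
}

#' Cramer-Rao lower bounds with propagation through linear parameter ties
#'
#' Builds the Fisher information `F = (1/sigma^2) * t(J) %*% J`, where `J`
#' is the numerical Jacobian of the concatenated real/imaginary model vector
#' with respect to the **free** parameters only — linear ties are exact
#' (zero-variance) constraints folded in by the chain rule, so a tied
#' subpeak contributes information to its source parameter rather than
#' carrying uncertainty of its own. `CRLB_i = sqrt((F^-1)_ii)`; the
#' covariance is the pseudo-inverse when `F` is rank-deficient, in which
#' case the report is flagged with the condition number and unidentifiable
#' parameters get infinite CRLBs. Per-peak amplitude CRLBs and multiplet
#' summed-amplitude CRLBs follow from the linear combination of the
#' amplitude covariance block (`w' Sigma w`).
#'
#' @param fit An `amares_fit` (converged, or evaluation-only with free
#'   parameters).
#' @param sigma A `noise_estimate` or positive number; defaults to the
#'   fit's own estimate.
#' @return An object of class `uncertainty_report` with tibbles
#'   `parameters` (per free parameter: estimate, `crlb_abs`, `crlb_pct`),
#'   `peaks` (per peak: amplitude CRLB% and SNR) and `groups` (per
#'   multiplet: summed amplitude, propagated CRLB%, SNR), plus `sigma` and
#'   the Fisher condition number.
#' @export
compute_crlb <- function(fit, sigma = fit$sigma) {
  stopifnot(inherits(fit, "amares_fit"))
  s <- if (inherits(sigma, "noise_estimate")) sigma$sigma else sigma
  if (is.null(s) || !is.finite(s) || s <= 0) stop("`sigma` must be > 0")
  params <- fit$params
  free_hat <- fit$free
  if (length(free_hat) == 0L) stop("no free parameters to bound")

  model_vec <- function(free) {
    m <- model_fid_from_free(stats::setNames(free, names(free_hat)),
                             fit$fid, params)$samples
    c(Re(m), Im(m))
  }
  J <- pracma::jacobian(model_vec, as.numeric(free_hat))
  FI <- crossprod(J) / s^2
  kappa_f <- tryCatch(kappa(FI, exact = TRUE), error = function(e) Inf)
  singular <- !is.finite(kappa_f) || kappa_f > 1e12
  Sigma <- if (singular) {
    warning(sprintf("Fisher information ill-conditioned (condition number %.3g); using pseudo-inverse",
                    kappa_f))
    pracma::pinv(FI)
  } else {
    solve(FI)
  }
  vars <- diag(Sigma)
  unident <- vars < 0 | !is.finite(vars)
  crlb_abs <- sqrt(pmax(vars, 0))
  crlb_abs[unident] <- Inf
  est <- as.numeric(free_hat)
  crlb_pct <- ifelse(est == 0, NA_real_, 100 * crlb_abs / abs(est))

  split_names <- strsplit(names(free_hat), ".", fixed = TRUE)
  parameters <- tibble::tibble(
    parameter = names(free_hat),
    peak = vapply(split_names, `[`, "", 1),
    field = vapply(split_names, `[`, "", 2),
    estimate = est,
    crlb_abs = crlb_abs,
    crlb_pct = crlb_pct
  )

  # amplitude of every peak as a (linear) function of the free parameters
  amp_fun <- function(free) {
    eval_full_params(params, stats::setNames(free, names(free_hat)))[, "amplitude"]
  }
  A <- pracma::jacobian(amp_fun, as.numeric(free_hat))
  amps <- stats::setNames(amp_fun(as.numeric(free_hat)), params$peaks)
  amp_var <- rowSums((A %*% Sigma) * A)
  amp_crlb <- sqrt(pmax(amp_var, 0))
  peaks <- tibble::tibble(
    name = params$peaks,
    amplitude = as.numeric(unname(amps)),
    crlb_abs = as.numeric(unname(amp_crlb)),
    crlb_pct = as.numeric(ifelse(amps == 0, NA_real_,
                                 100 * unname(amp_crlb) / abs(unname(amps)))),
    snr = compute_snr(as.numeric(unname(amps)), s)
  )

  groups <- purrr::map_dfr(names(params$groups), function(gname) {
    members <- params$groups[[gname]]
    w <- colSums(A[match(members, params$peaks), , drop = FALSE])
    v <- drop(t(w) %*% Sigma %*% w)
    total <- sum(amps[members])
    tibble::tibble(
      name = gname, peaks = paste(members, collapse = "+"),
      amplitude = total,
      crlb_abs = sqrt(max(v, 0)),
      crlb_pct = ifelse(total == 0, NA_real_, 100 * sqrt(max(v, 0)) / abs(total)),
      snr = compute_snr(total, s)
    )
  })

  structure(list(parameters = parameters, peaks = peaks, groups = groups,
                 sigma = s, fisher_condition = kappa_f, singular = singular),
            class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat(sprintf("<uncertainty_report> sigma = %.6g | Fisher condition %.3g%s\n",
              x$sigma, x$fisher_condition,
              if (x$singular) " (flagged singular)" else ""))
  print(x$peaks)
  invisible(x)
}
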