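#' Objective specification for AMARES fitting
#'
#' @param mode `"time_domain"` (default): the residual is the concatenation
#'   of the real and imaginary parts of model minus data over the whole FID,
#'   optionally weighted per sample. `"frequency_masked"`: both model and
#'   data are Fourier transformed (at the data length, no extra zero fill)
#'   and the same construction is restricted to frequency bins whose
#'   chemical shift lies in `ppm_range`; the complex spectrum (real and
#'   imaginary parts) is compared in-mask. `"user_hook"`: `hook` computes
#'   the residual itself.
#' @param ppm_range Length-2 numeric `(low, high)` in ppm; required for
#'   `frequency_masked`.
#' @param weights Optional non-negative per-sample weight vector of FID
#'   length (time-domain mode), e.g. [quarter_sine_weights()].
#' @param hook Function `(free_values, fid, params)` returning a numeric
#'   residual vector; required for `user_hook`.
#' @param residual_length Optional declared length of the hook's residual,
#'   validated on every call.
#' @return An object of class `objective_spec`.
#' @export
objective_spec <- function(mode = c("time_domain", "frequency_masked", "user_hook"),
                           ppm_range = NULL, weights = NULL, hook = NULL,
                           residual_length = NULL) {
  mode <- match.arg(mode)
  if (mode == "frequency_masked") {
    if (is.null(ppm_range) || length(ppm_range) != 2 || !all(is.finite(ppm_range))) {
      stop("`frequency_masked` requires a finite length-2 `ppm_range`")
    }
    ppm_range <- sort(as.numeric(ppm_range))
  }
  if (!is.null(weights)) {
    if (any(weights < 0) || !all(is.finite(weights))) {
      stop("`weights` must be finite and non-negative")
    }
  }
  if (mode == "user_hook" && !is.function(hook)) {
    stop("`user_hook` requires a `hook` function")
  }
  structure(list(mode = mode, ppm_range = ppm_range, weights = weights,
                 hook = hook, residual_length = residual_length),
            class = "objective_spec")
}

#' Real residual vector for a free-parameter vector
#'
#' Evaluates the model on the FID's acquisition grid (ties applied exactly)
#' and returns the real residual the least-squares minimizer sees, according
#' to the [objective_spec()].
#'
#' @param free Named numeric vector of free-parameter values.
#' @param fid The measured [fid_signal].
#' @param params Compiled `amares_params`.
#' @param objective An [objective_spec()].
#' @return Numeric residual vector.
#' @export
build_residual <- function(free, fid, params,
                           objective = objective_spec()) {
  stopifnot(inherits(fid, "fid_signal"), inherits(params, "amares_params"))
  if (objective$mode == "user_hook") {
    r <- objective$hook(free, fid, params)
    if (!is.numeric(r) || length(r) == 0L) {
      stop("user objective hook must return a non-empty numeric vector")
    }
    if (!is.null(objective$residual_length) &&
        length(r) != objective$residual_length) {
      stop(sprintf("user objective hook returned length %d, expected %d",
                   length(r), objective$residual_length))
    }
    return(r)
  }
  model <- model_fid_from_free(free, fid, params)
  if (objective$mode == "time_domain") {
    d <- model$samples - fid$samples
    w <- objective$weights
    if (!is.null(w)) {
      if (length(w) != n_points(fid)) stop("`weights` must have FID length")
      d <- d * w
    }
    return(c(Re(d), Im(d)))
  }
  # frequency_masked
  sm <- fid_to_spectrum(model)
  sd_ <- fid_to_spectrum(fid)
  mask <- sd_$ppm >= objective$ppm_range[1] & sd_$ppm <= objective$ppm_range[2]
  if (!any(mask)) stop("`ppm_range` selects no frequency bins")
  d <- sm$intensity[mask] - sd_$intensity[mask]
  c(Re(d), Im(d))
}

objective_value <- function(free, fid, params, objective) {
  r <- build_residual(free, fid, params, objective)
  sum(r * r)
}

clip_to_bounds <- function(free, params) {
  pmin(pmax(free, params$lower), params$upper)
}

lm_control <- function(control) {
  defaults <- list(ftol = 1e-8, ptol = 1e-8, maxfev = 3000)
  defaults[names(control)] <- control
  minpack.lm::nls.lm.control(ftol = defaults$ftol, ptol = defaults$ptol,
                             maxfev = defaults$maxfev)
}

#' Levenberg-Marquardt refinement of starting values
#'
#' Runs an unconstrained Levenberg-Marquardt least-squares pass on the free
#' parameters (ties respected exactly at every step) and clips the result
#' into the declared bounds. Because the pass is unconstrained, it can
#' travel across large initial errors (e.g. a chemical shift off by 100 Hz)
#' that a box-bounded solver would stop at. The refined values never worsen
#' the objective relative to the input initial values: if they would, the
#' input is returned unchanged (with a warning on non-convergence).
#'
#' @param fid The measured [fid_signal].
#' @param params Compiled `amares_params`.
#' @param objective An [objective_spec()].
#' @param control Optional list overriding `ftol`, `ptol`, `maxfev`.
#' @return `params` with its free initial values (`free_init`) refined.
#' @export
lm_initialize <- function(fid, params, objective = objective_spec(),
                          control = list()) {
  stopifnot(inherits(params, "amares_params"))
  if (length(params$free_init) == 0L) return(params)
  f0 <- params$free_init
  obj0 <- objective_value(f0, fid, params, objective)
  ans <- tryCatch(
    minpack.lm::nls.lm(par = f0, fn = build_residual, fid = fid,
                       params = params, objective = objective,
                       control = lm_control(control)),
    error = function(e) NULL)
  if (is.null(ans)) {
    warning("LM initializer failed to converge; keeping input values")
    return(params)
  }
  refined <- clip_to_bounds(stats::setNames(ans$par, names(f0)), params)
  obj1 <- objective_value(refined, fid, params, objective)
  if (!is.finite(obj1) || obj1 > obj0) {
    return(params)
  }
  params$free_init <- refined
  attr(params, "initializer_objective") <- obj1
  params
}

# HSVD-based refinement: match decomposed components to peaks with a free
# chemical shift by nearest frequency and copy over the free fields.
hsvd_refine <- function(fid, params, k = NULL) {
  comp <- hsvd_decompose(fid, k = if (is.null(k)) length(params$peaks) else k)
  if (nrow(comp) == 0L) return(params)
  free <- params$free_init
  full <- eval_full_params(params, free)
  cs_user <- hz_to_ppm(comp$frequency, params$carrier_mhz, params$ref_ppm)
  take <- function(peak, field, value) {
    key <- paste(peak, field, sep = ".")
    if (key %in% names(free)) free[key] <<- value
  }
  used <- rep(FALSE, nrow(comp))
  for (p in params$peaks) {
    if (!paste(p, "chemicalshift", sep = ".") %in% names(free)) next
    f_hz <- ppm_to_hz(full[p, "chemicalshift"], params$carrier_mhz, params$ref_ppm)
    cand <- which(!used)
    if (!length(cand)) break
    j <- cand[which.min(abs(comp$frequency[cand] - f_hz))]
    used[j] <- TRUE
    take(p, "chemicalshift", cs_user[j])
    take(p, "amplitude", comp$amplitude[j])
    take(p, "linewidth", damping_to_linewidth(comp$damping[j]))
    take(p, "phase", comp$phase[j])
  }
  params$free_init <- clip_to_bounds(free, params)
  params
}

#' Fit an FID by AMARES
#'
#' Bounded nonlinear least-squares fitting of the damped-sinusoid model
#' under prior knowledge. Methods: `"trr+init"` (default) refines the
#' starting values with an unconstrained Levenberg-Marquardt pass
#' ([lm_initialize()]) and then minimizes with box bounds enforced;
#' `"trr"` minimizes with box bounds from the raw initial values; `"lm"`
#' minimizes unconstrained and clips the solution into the bounds
#' afterwards. Tied parameters satisfy their expressions exactly at every
#' step; the returned objective never exceeds the objective at the starting
#' point (otherwise the start is returned and the fit flagged
#' non-convergent). The fit is deterministic given identical inputs.
#'
#' @param fid The measured [fid_signal].
#' @param prior A `prior_knowledge` object or compiled `amares_params`.
#' @param method `"trr+init"`, `"trr"` or `"lm"`.
#' @param objective An [objective_spec()].
#' @param initializer Optional extra starting-value refinement applied
#'   before the method: `"none"` (default), `"lm"`, or `"hsvd"` (match
#'   black-box components to peaks).
#' @param crlb Compute the uncertainty report (CRLBs, SNR) on the result?
#'   Default `TRUE`.
#' @param noise_from `"fid_tail"` (default; trailing eighth of the raw FID)
#'   or `"residual"` for the noise SD used by CRLB and SNR.
#' @param control Optional list overriding `ftol`, `ptol`, `maxfev`
#'   (defaults 1e-8, 1e-8, 3000).
#' @return An object of class `amares_fit`: fitted peak table (user units),
#'   free-parameter estimates, complex time-domain residual, objective
#'   value, convergence diagnostics, noise estimate and (if requested)
#'   the uncertainty report. Use [tidy()], [glance()], [autoplot()] and
#'   [assemble_results()] on it.
#' @export
fit_amares <- function(fid, prior, method = c("trr+init", "trr", "lm"),
                       objective = objective_spec(),
                       initializer = c("none", "lm", "hsvd"),
                       crlb = TRUE, noise_from = c("fid_tail", "residual"),
                       control = list()) {
  method <- match.arg(method)
  initializer <- match.arg(initializer)
  noise_from <- match.arg(noise_from)
  stopifnot(inherits(fid, "fid_signal"))
  if (!all(is.finite(Re(fid$samples))) || !all(is.finite(Im(fid$samples)))) {
    stop("FID contains non-finite samples")
  }
  params <- if (inherits(prior, "prior_knowledge")) {
    compile_parameters(prior)
  } else if (inherits(prior, "amares_params")) {
    prior
  } else stop("`prior` must be a prior_knowledge or amares_params object")

  n_free <- length(params$free_init)
  msg <- character()
  converged <- TRUE
  niter <- 0L

  if (n_free == 0L) {
    warning("all parameters fixed or tied; returning evaluation-only result")
    free_hat <- params$free_init
    msg <- "evaluation only: no free parameters"
  } else {
    if (initializer == "lm") params <- lm_initialize(fid, params, objective, control)
    if (initializer == "hsvd") params <- hsvd_refine(fid, params)
    if (method == "trr+init") params <- lm_initialize(fid, params, objective, control)
    f0 <- clip_to_bounds(params$free_init, params)
    obj0 <- objective_value(f0, fid, params, objective)
    if (!is.finite(obj0)) stop("objective is non-finite at the starting values")

    if (method == "lm") {
      ans <- minpack.lm::nls.lm(par = f0, fn = build_residual, fid = fid,
                                params = params, objective = objective,
                                control = lm_control(control))
      free_hat <- clip_to_bounds(stats::setNames(ans$par, names(f0)), params)
    } else {
      ans <- minpack.lm::nls.lm(par = f0, fn = build_residual, fid = fid,
                                params = params, objective = objective,
                                lower = params$lower, upper = params$upper,
                                control = lm_control(control))
      free_hat <- clip_to_bounds(stats::setNames(ans$par, names(f0)), params)
    }
    niter <- ans$niter
    obj1 <- objective_value(free_hat, fid, params, objective)
    if (!is.finite(obj1) || obj1 > obj0) {
      free_hat <- f0
      converged <- FALSE
      msg <- c(msg, "no improvement over starting values; start returned")
    }
    if (ans$info %in% c(0, 5, 9)) {
      converged <- FALSE
      msg <- c(msg, paste0("solver: ", ans$message))
    }
    tol <- 1e-9 * pmax(1, abs(free_hat))
    at_lower <- is.finite(params$lower) & (free_hat - params$lower) <= tol
    at_upper <- is.finite(params$upper) & (params$upper - free_hat) <= tol
    if (any(at_lower | at_upper)) {
      msg <- c(msg, paste0("active bounds: ",
                           paste(names(free_hat)[at_lower | at_upper], collapse = ", ")))
    }
  }

  model <- model_fid_from_free(free_hat, fid, params)
  residual <- fid
  residual$samples <- fid$samples - model$samples
  obj_final <- objective_value(free_hat, fid, params, objective)

  sigma <- tryCatch({
    if (noise_from == "fid_tail" && n_points(fid) >= 128) {
      estimate_noise_sd(fid, source = "fid_tail")
    } else {
      estimate_noise_sd(residual$samples, source = "residual")
    }
  }, error = function(e) NULL)

  fit <- structure(
    list(peaks = params_to_peaks(params, free_hat),
         free = free_hat, params = params, fid = fid,
         model = model, residual = residual,
         objective = objective, objective_value = obj_final,
         converged = converged,
         message = if (length(msg)) paste(msg, collapse = "; ") else "converged",
         method = method, initializer = initializer,
         niter = niter, sigma = sigma, uncertainty = NULL),
    class = "amares_fit")

  if (crlb && n_free > 0L && !is.null(sigma) && sigma$sigma > 0) {
    fit$uncertainty <- tryCatch(compute_crlb(fit, sigma),
                                warning = function(w) {
                                  suppressWarnings(compute_crlb(fit, sigma))
                                },
                                error = function(e) NULL)
  }
  fit
}

#' @export
print.amares_fit <- function(x, ...) {
  cat(sprintf("<amares_fit> method %s (initializer %s) | %d peaks, %d free parameters\n",
              x$method, x$initializer, nrow(x$peaks), length(x$free)))
  cat(sprintf("  objective %.6g | %s\n", x$objective_value, x$message))
  print(tidy(x))
  invisible(x)
}
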