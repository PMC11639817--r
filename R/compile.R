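#' Compile prior knowledge into a parameter map
#'
#' Classifies every (peak, parameter) cell of the prior knowledge exactly
#' once as **free** (a bare number with a range bound — optimized within box
#' bounds), **tied** (a tie expression — a pure function of an earlier peak's
#' parameter, enforced exactly throughout the fit), or **fixed** (a bare
#' number with no bound or with a single-value bound; or an initial `g` of
#' exactly 0, which pins the lineshape to Lorentzian). Free initial values
#' are clipped into their bounds.
#'
#' @param pk A `prior_knowledge` object from [parse_prior_knowledge()].
#' @return An object of class `amares_params` holding the classification
#'   table, the free-parameter vector (`PEAK.field` names) with its bounds,
#'   tie evaluators, multiplet groups and acquisition context.
#' @export
#' @examples
#' path <- system.file("extdata", "prior_31p_brain.csv", package = "amaresr")
#' params <- compile_parameters(parse_prior_knowledge(path, carrier_mhz = 120.66))
#' params
compile_parameters <- function(pk) {
  stopifnot(inherits(pk, "prior_knowledge"))
  cells <- pk$cells
  n <- nrow(cells)
  type <- character(n); value <- rep(NA_real_, n)
  lower <- rep(-Inf, n); upper <- rep(Inf, n)
  for (r in seq_len(n)) {
    init <- cells$init[[r]]; bound <- cells$bound[[r]]
    if (inherits(init, "amares_expr")) {
      type[r] <- "tied"
    } else if (cells$field[r] == "g" && init == 0) {
      type[r] <- "fixed"; value[r] <- 0
    } else if (is.null(bound)) {
      type[r] <- "fixed"; value[r] <- init
    } else if (bound$type == "fixed") {
      type[r] <- "fixed"; value[r] <- bound$fixed
    } else {
      type[r] <- "free"
      value[r] <- min(max(init, bound$lower), bound$upper)
      lower[r] <- bound$lower; upper[r] <- bound$upper
    }
  }
  entries <- tibble::tibble(
    peak = cells$peak, field = cells$field, type = type,
    value = value, lower = lower, upper = upper, expr = cells$init
  )
  isfree <- entries$type == "free"
  free_names <- paste(entries$peak[isfree], entries$field[isfree], sep = ".")
  obj <- structure(
    list(peaks = pk$peaks, entries = entries,
         free_names = free_names,
         free_init = stats::setNames(entries$value[isfree], free_names),
         lower = stats::setNames(entries$lower[isfree], free_names),
         upper = stats::setNames(entries$upper[isfree], free_names),
         groups = pk$groups,
         carrier_mhz = pk$carrier_mhz, ref_ppm = pk$ref_ppm),
    class = "amares_params"
  )
  # evaluate ties once to assert the left-to-right rule yields no cycles and
  # to fill display values for tied entries
  full <- eval_full_params(obj, obj$free_init)
  tied <- entries$type == "tied"
  obj$entries$value[tied] <- full[cbind(entries$peak[tied], entries$field[tied])]
  obj
}

#' @export
print.amares_params <- function(x, ...) {
  tab <- table(factor(x$entries$type, levels = c("free", "tied", "fixed")))
  cat(sprintf("<amares_params> %d peaks | %d free, %d tied, %d fixed parameters\n",
              length(x$peaks), tab["free"], tab["tied"], tab["fixed"]))
  if (length(x$free_names)) cat("free:", paste(x$free_names, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the full parameter set from the free-parameter vector
#'
#' Applies fixed values and tie evaluators (left to right across peaks) to
#' produce every peak's five parameters in user units — amplitude,
#' chemicalshift (ppm), linewidth (Hz), phase (deg), g. Tie semantics:
#' identity copies the source's same parameter; scale multiplies it;
#' `offset_hz` adds a Hz offset (converted to ppm through the spectrometer
#' frequency when applied to a chemical shift); `offset_ppm` adds a ppm
#' offset.
#'
#' @param params An `amares_params` object.
#' @param free Named numeric vector of free-parameter values (defaults to
#'   the compiled initial values).
#' @return A numeric matrix with one row per peak and columns
#'   `amplitude`, `chemicalshift`, `linewidth`, `phase`, `g`.
#' @export
eval_full_params <- function(params, free = params$free_init) {
  stopifnot(inherits(params, "amares_params"))
  if (length(free) != length(params$free_names)) {
    stop("`free` must have length ", length(params$free_names))
  }
  free <- stats::setNames(as.numeric(free), params$free_names)
  m <- matrix(NA_real_, nrow = length(params$peaks), ncol = length(pk_fields),
              dimnames = list(params$peaks, pk_fields))
  e <- params$entries
  for (p in params$peaks) {
    for (f in pk_fields) {
      r <- which(e$peak == p & e$field == f)
      m[p, f] <- switch(e$type[r],
        free = free[paste(p, f, sep = ".")],
        fixed = e$value[r],
        tied = {
          ex <- e$expr[[r]]
          src <- m[ex$ref, ex$field]
          if (is.na(src)) stop("tie cycle detected at ", p, ".", f)
          switch(ex$op,
            identity = src,
            scale = src * ex$operand,
            offset_hz = if (f == "chemicalshift") {
              src + ex$operand / params$carrier_mhz
            } else src + ex$operand,
            offset_ppm = src + ex$operand)
        })
    }
  }
  m
}

# Full parameter matrix -> user-unit peak tibble.
params_to_peaks <- function(params, free = params$free_init) {
  m <- eval_full_params(params, free)
  tibble::tibble(
    name = rownames(m),
    amplitude = unname(m[, "amplitude"]),
    chemicalshift = unname(m[, "chemicalshift"]),
    linewidth = unname(m[, "linewidth"]),
    phase = unname(m[, "phase"]),
    g = unname(m[, "g"])
  )
}

# Model FID for a free-parameter vector on a given acquisition grid.
# Deliberately lenient: an unconstrained minimizer pass may probe negative
# linewidths or g outside [0, 1]; the model stays evaluable there (a growing
# exponential), and bounds are enforced by the solver or by clipping.
model_fid_from_free <- function(free, fid, params) {
  m <- eval_full_params(params, free)
  peaks <- tibble::tibble(
    name = rownames(m),
    amplitude = m[, "amplitude"],
    frequency = ppm_to_hz(m[, "chemicalshift"], fid$carrier_mhz, fid$ref_ppm),
    damping = pi * m[, "linewidth"],
    phase = m[, "phase"],
    g = m[, "g"]
  )
  out <- fid
  samples <- model_eval(peaks, fid_times(fid))
  # keep the objective finite if the search probes an exploding envelope
  bad <- !is.finite(Re(samples)) | !is.finite(Im(samples))
  if (any(bad)) samples[bad] <- 1e12 + 0i
  out$samples <- samples
  out
}
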