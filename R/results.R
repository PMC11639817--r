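#' Assemble the per-peak and per-multiplet result tables
#'
#' Builds the two standard output tables of an AMARES fit:
#' `result_multiplet` has one row per spectral line (including every subpeak
#' of a J-coupled multiplet) with its fitted parameters, amplitude CRLB%
#' and SNR; `result_sum` has one row per multiplet group with the summed
#' amplitude (area), the CRLB% propagated through the summed-amplitude
#' variance, and the group SNR. Rows whose amplitude CRLB% is below
#' `threshold` are flagged reliable.
#'
#' @param fit An `amares_fit`.
#' @param report An `uncertainty_report`; defaults to the one attached to
#'   the fit (may be `NULL`, in which case CRLB/SNR columns are `NA`).
#' @param groups Multiplet map (named list root -> member peak names);
#'   defaults to the fit's compiled groups.
#' @param threshold Reliability threshold on amplitude CRLB% (default 20).
#' @return An object of class `amares_results` with tibbles
#'   `result_multiplet` and `result_sum`.
#' @export
assemble_results <- function(fit, report = fit$uncertainty,
                             groups = fit$params$groups, threshold = 20) {
  stopifnot(inherits(fit, "amares_fit"))
  peaks <- fit$peaks
  missing <- setdiff(unlist(groups), peaks$name)
  if (length(missing)) {
    stop("multiplet group references missing peak(s): ",
         paste(missing, collapse = ", "))
  }
  rm_tbl <- peaks
  if (!is.null(report)) {
    rm_tbl <- dplyr::left_join(rm_tbl,
      dplyr::select(report$peaks, "name", "crlb_pct", "snr"), by = "name")
  } else {
    rm_tbl$crlb_pct <- NA_real_; rm_tbl$snr <- NA_real_
  }
  rm_tbl$reliable <- !is.na(rm_tbl$crlb_pct) & rm_tbl$crlb_pct < threshold

  rs_tbl <- purrr::map_dfr(names(groups), function(gname) {
    members <- groups[[gname]]
    sub <- rm_tbl[match(members, rm_tbl$name), , drop = FALSE]
    main <- sub[1, ]
    tibble::tibble(
      name = gname,
      peaks = paste(members, collapse = "+"),
      amplitude = sum(sub$amplitude),
      chemicalshift = main$chemicalshift,
      linewidth = main$linewidth,
      phase = main$phase,
      g = main$g,
      crlb_pct = NA_real_, snr = NA_real_
    )
  })
  if (!is.null(report)) {
    j <- match(rs_tbl$name, report$groups$name)
    rs_tbl$crlb_pct <- report$groups$crlb_pct[j]
    rs_tbl$snr <- report$groups$snr[j]
  }
  rs_tbl$reliable <- !is.na(rs_tbl$crlb_pct) & rs_tbl$crlb_pct < threshold

  structure(list(result_multiplet = rm_tbl, result_sum = rs_tbl,
                 threshold = threshold),
            class = "amares_results")
}

#' @export
print.amares_results <- function(x, ...) {
  cat("result_sum (threshold", x$threshold, "% CRLB):\n")
  print(x$result_sum)
  invisible(x)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

results_html <- function(tbl, threshold) {
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, digits = 6, format = "g") else html_escape(as.character(v))
  }
  head_cells <- paste0("<th>", html_escape(names(tbl)), "</th>", collapse = "")
  rows <- vapply(seq_len(nrow(tbl)), function(i) {
    color <- if (isTRUE(tbl$reliable[i])) "#c8e6c9" else "#ffcdd2"
    cells <- paste0("<td>", vapply(tbl[i, ], function(v) fmt(v[[1]]), ""), "</td>",
                    collapse = "")
    sprintf('<tr style="background-color:%s">%s</tr>', color, cells)
  }, "")
  paste0("<html><body><table border='1' cellspacing='0' cellpadding='4'>\n",
         "<tr>", head_cells, "</tr>\n", paste(rows, collapse = "\n"),
         "\n</table>\n<p>green: amplitude CRLB &lt; ", threshold,
         "% (reliable); red: otherwise</p></body></html>\n")
}

#' Write result tables to CSV (and optionally HTML)
#'
#' Always writes `result_multiplet.csv` and `result_sum.csv`; with the
#' `"html"` format also writes `result_sum.html`, in which reliable rows
#' (amplitude CRLB% below the threshold) are colored green and the rest
#' red.
#'
#' @param results An `amares_results` object.
#' @param dir Output directory (created if missing).
#' @param formats Subset of `c("csv", "html")`.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(results, dir, formats = c("csv", "html")) {
  stopifnot(inherits(results, "amares_results"))
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  if ("csv" %in% formats) {
    p1 <- file.path(dir, "result_multiplet.csv")
    p2 <- file.path(dir, "result_sum.csv")
    utils::write.csv(results$result_multiplet, p1, row.names = FALSE)
    utils::write.csv(results$result_sum, p2, row.names = FALSE)
    paths <- c(paths, p1, p2)
  }
  if ("html" %in% formats) {
    p3 <- file.path(dir, "result_sum.html")
    writeLines(results_html(results$result_sum, results$threshold), p3)
    paths <- c(paths, p3)
  }
  invisible(paths)
}

# ---- broom-style accessors --------------------------------------------------

#' Tidy an AMARES fit into a per-peak tibble
#'
#' @param x An `amares_fit`.
#' @param ... Unused.
#' @return One row per peak: fitted `amplitude`, `chemicalshift` (ppm),
#'   `linewidth` (Hz), `phase` (deg), `g`, amplitude `crlb_pct` and `snr`.
#' @method tidy amares_fit
#' @export
tidy.amares_fit <- function(x, ...) {
  out <- x$peaks
  if (!is.null(x$uncertainty)) {
    out <- dplyr::left_join(out,
      dplyr::select(x$uncertainty$peaks, "name", "crlb_pct", "snr"), by = "name")
  } else {
    out$crlb_pct <- NA_real_; out$snr <- NA_real_
  }
  out
}

#' One-row summary of an AMARES fit
#'
#' @param x An `amares_fit`.
#' @param ... Unused.
#' @return A tibble with the objective value, convergence flag and message,
#'   method, initializer, free-parameter count, iteration count and noise
#'   SD.
#' @method glance amares_fit
#' @export
glance.amares_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective_value,
    converged = x$converged,
    message = x$message,
    method = x$method,
    initializer = x$initializer,
    n_peaks = nrow(x$peaks),
    n_free = length(x$free),
    n_iter = x$niter,
    sigma = if (is.null(x$sigma)) NA_real_ else x$sigma$sigma
  )
}

#' Frequency-domain arrays of a fit for plotting
#'
#' Fourier transforms the original FID, the fitted model, the residual and
#' each fitted component on a common frequency axis. The plotted residual
#' equals original minus fitted bin-wise, and the component spectra sum to
#' the fitted spectrum (linearity of the transform).
#'
#' @param fit An `amares_fit`.
#' @param zero_fill Optional output length for the transforms.
#' @param ifphase Apply phase correction from the fit (zero-order from the
#'   strongest peak's fitted phase, first-order from the dead time) for
#'   display? Default `FALSE`.
#' @param components Include per-peak component spectra? Default `TRUE`.
#' @return A tibble with columns `component`, `freq_hz`, `ppm`, complex
#'   `intensity` and its real part `real`.
#' @export
spectrum_tables <- function(fit, zero_fill = NULL, ifphase = FALSE,
                            components = TRUE) {
  stopifnot(inherits(fit, "amares_fit"))
  ph0 <- 0; ph1 <- 0
  if (ifphase) {
    main <- which.max(fit$peaks$amplitude)
    ph0 <- -fit$peaks$phase[main]
    ph1 <- -fit$fid$dead_time
  }
  spec_of <- function(f, label) {
    s <- fid_to_spectrum(f, zero_fill = zero_fill, phase0 = ph0, phase1 = ph1)
    tibble::tibble(component = label, freq_hz = s$freq_hz, ppm = s$ppm,
                   intensity = s$intensity, real = Re(s$intensity))
  }
  out <- dplyr::bind_rows(
    spec_of(fit$fid, "original"),
    spec_of(fit$model, "fitted"),
    spec_of(fit$residual, "residual")
  )
  if (components) {
    for (nm in fit$peaks$name) {
      comp <- synthesize_fid(fit$peaks[fit$peaks$name == nm, ], like = fit$fid)
      out <- dplyr::bind_rows(out, spec_of(comp, nm))
    }
  }
  out
}

#' Plot an AMARES fit
#'
#' Draws the original spectrum, the fitted spectrum and the residual (real
#' part) against chemical shift, with the ppm axis reversed in the NMR
#' convention, and the individual fitted components in a lower panel.
#'
#' @param object An `amares_fit`.
#' @param zero_fill,ifphase Passed to [spectrum_tables()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot amares_fit
#' @export
autoplot.amares_fit <- function(object, zero_fill = NULL, ifphase = FALSE, ...) {
  dat <- spectrum_tables(object, zero_fill = zero_fill, ifphase = ifphase)
  dat$panel <- ifelse(dat$component %in% c("original", "fitted", "residual"),
                      "fit", "components")
  dat$panel <- factor(dat$panel, levels = c("fit", "components"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ppm, y = .data$real,
                                    color = .data$component)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity (a.u.)",
                  color = NULL) +
    ggplot2::theme_minimal()
}
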