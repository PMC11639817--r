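#' Read and write FID files
#'
#' The interchange formats are deliberately simple: a CSV with header
#' `real,imag` and one complex sample per row, or a packed little-endian
#' binary array of interleaved real/imaginary doubles (extension `.bin`).
#' Acquisition metadata travels in a JSON sidecar or an R list with keys
#' `carrier_mhz`, `sw_hz`, `dead_time_s` (optional, default 0) and
#' `ref_ppm` (optional, default 0). Vendor raw formats are out of scope;
#' convert with a dedicated reader first.
#'
#' @param path FID file path (`.csv` or `.bin`).
#' @param meta Metadata: named list, or path to a JSON file.
#' @return A [fid_signal].
#' @export
read_fid <- function(path, meta) {
  if (!file.exists(path)) stop("FID file not found: ", path)
  if (is.character(meta) && length(meta) == 1) {
    if (!file.exists(meta)) stop("metadata file not found: ", meta)
    meta <- jsonlite::read_json(meta, simplifyVector = TRUE)
  }
  for (key in c("carrier_mhz", "sw_hz")) {
    if (is.null(meta[[key]])) stop("missing metadata key: ", key)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "bin") {
    sz <- file.info(path)$size
    raw <- readBin(path, "double", n = sz / 8, size = 8, endian = "little")
    if (length(raw) %% 2 != 0) stop("binary FID has an odd number of doubles")
    samples <- complex(real = raw[c(TRUE, FALSE)], imaginary = raw[c(FALSE, TRUE)])
  } else {
    df <- utils::read.csv(path, colClasses = "character")
    if (!all(c("real", "imag") %in% names(df))) {
      stop("FID CSV must have columns `real` and `imag`")
    }
    re <- suppressWarnings(as.numeric(df$real))
    im <- suppressWarnings(as.numeric(df$imag))
    bad <- which(is.na(re) | is.na(im) | !is.finite(re) | !is.finite(im))
    if (length(bad)) {
      stop(sprintf("non-numeric or non-finite FID sample at row %d", bad[1]))
    }
    samples <- complex(real = re, imaginary = im)
  }
  fid_signal(samples, sw_hz = meta$sw_hz,
             dead_time = if (is.null(meta$dead_time_s)) 0 else meta$dead_time_s,
             carrier_mhz = meta$carrier_mhz,
             ref_ppm = if (is.null(meta$ref_ppm)) 0 else meta$ref_ppm)
}

#' @rdname read_fid
#' @param fid A [fid_signal] to write.
#' @param meta_path Optional path for the JSON metadata sidecar.
#' @export
write_fid <- function(fid, path, meta_path = NULL) {
  stopifnot(inherits(fid, "fid_signal"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "bin") {
    inter <- as.numeric(rbind(Re(fid$samples), Im(fid$samples)))
    writeBin(inter, path, size = 8, endian = "little")
  } else {
    utils::write.csv(
      data.frame(real = sprintf("%.17g", Re(fid$samples)),
                 imag = sprintf("%.17g", Im(fid$samples))),
      path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(meta_path)) {
    jsonlite::write_json(
      list(carrier_mhz = fid$carrier_mhz, sw_hz = sw_hz(fid),
           dead_time_s = fid$dead_time, ref_ppm = fid$ref_ppm),
      meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' Merges (in decreasing precedence) explicit arguments, a JSON config
#' file, and the package defaults, and validates the result. The merged
#' configuration is what gets hashed into the run manifest.
#'
#' @param ... Configuration fields: `fid`, `meta` (list or JSON path),
#'   `prior`, `method`, `objective` (`"time"` or `"mask"`), `ppm_range`,
#'   `initializer`, `mpfir_range`, `crlb_threshold`, `out`, `seed`,
#'   `zero_fill`.
#' @param file Optional JSON config file.
#' @return A `run_config` list.
#' @export
run_config <- function(..., file = NULL) {
  defaults <- list(fid = NULL, meta = NULL, prior = NULL,
                   method = "trr+init", objective = "time",
                   ppm_range = NULL, initializer = "none",
                   mpfir_range = NULL, crlb_threshold = 20,
                   out = "amares_out", seed = 1L, zero_fill = NULL)
  cfg <- defaults
  if (!is.null(file)) {
    fromfile <- jsonlite::read_json(file, simplifyVector = TRUE)
    cfg[names(fromfile)] <- fromfile
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (!is.null(cfg$crlb_threshold) && cfg$crlb_threshold <= 0) {
    stop("`crlb_threshold` must be > 0")
  }
  structure(cfg, class = "run_config")
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the end-to-end AMARES pipeline
#'
#' Load FID and prior knowledge, optionally extract a frequency region
#' (FIR) or restrict the objective to a chemical-shift mask, fit, compute
#' CRLBs, and write `result_multiplet.csv`, `result_sum.csv`,
#' `result_sum.html`, the spectrum arrays (`fit_arrays.csv`: original,
#' fitted, residual and component spectra on a common axis) and a
#' machine-readable `manifest.json` (package and R versions, seed, merged
#' config and its hash) into the output directory. Re-running an identical
#' configuration reproduces the outputs exactly.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `status` (0 on success), the fit, the
#'   result tables, and the file paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  fid <- pipeline_stage("load_fid", {
    if (inherits(config$fid, "fid_signal")) config$fid
    else read_fid(config$fid, config$meta)
  })
  pk <- pipeline_stage("load_prior", {
    if (inherits(config$prior, "prior_knowledge")) config$prior
    else {
      meta <- config$meta
      if (is.character(meta)) meta <- jsonlite::read_json(meta, simplifyVector = TRUE)
      parse_prior_knowledge(config$prior, carrier_mhz = fid$carrier_mhz,
                            ref_ppm = fid$ref_ppm)
    }
  })
  if (!is.null(config$mpfir_range)) {
    fid <- pipeline_stage("mpfir", mpfir_extract(fid, config$mpfir_range))
  }
  objective <- pipeline_stage("objective", {
    if (identical(config$objective, "mask")) {
      objective_spec("frequency_masked", ppm_range = config$ppm_range)
    } else objective_spec("time_domain")
  })
  fit <- pipeline_stage("fit", {
    fit_amares(fid, pk, method = config$method, objective = objective,
               initializer = config$initializer)
  })
  results <- pipeline_stage("report", {
    assemble_results(fit, threshold = config$crlb_threshold)
  })
  out <- config$out
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  files <- pipeline_stage("write", {
    paths <- render_report(results, out)
    arrays <- spectrum_tables(fit, zero_fill = config$zero_fill)
    arrays$intensity_re <- Re(arrays$intensity)
    arrays$intensity_im <- Im(arrays$intensity)
    arrays$intensity <- NULL
    pa <- file.path(out, "fit_arrays.csv")
    utils::write.csv(arrays, pa, row.names = FALSE)
    serializable <- config
    serializable$fid <- if (is.character(config$fid)) config$fid else "<in-memory fid>"
    serializable$prior <- if (is.character(config$prior)) config$prior else "<in-memory prior>"
    manifest <- list(
      package = "amaresr",
      package_version = as.character(utils::packageVersion("amaresr")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      config = unclass(serializable),
      config_hash = rlang::hash(unclass(serializable)),
      log = list(n_points = n_points(fid), sw_hz = sw_hz(fid),
                 dead_time = fid$dead_time,
                 n_free = length(fit$free), method = fit$method,
                 converged = fit$converged,
                 sigma = if (is.null(fit$sigma)) NA else fit$sigma$sigma)
    )
    pm <- file.path(out, "manifest.json")
    jsonlite::write_json(manifest, pm, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    c(paths, pa, pm)
  })
  invisible(list(status = 0L, fit = fit, results = results, files = files))
}
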