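# Shared fixture builders: everything is generated in code at test time.

# Build a prior-knowledge table in the spreadsheet dialect from row vectors.
prior_df <- function(...) {
  as.data.frame(rbind(...), stringsAsFactors = FALSE)
}

# One-peak prior with wide bounds; chemical shifts in ppm at `carrier` MHz.
singlet_prior <- function(cs_init = 0.5, amp_init = 0.8, lw_init = 15,
                          phase_init = 0, carrier = 120, ref = 0,
                          cs_bounds = "(-20.8, 20.8)",
                          lw_bounds = "(0.1, 100)",
                          phase_bounds = "(-180, 180)",
                          name = "PCR") {
  df <- prior_df(
    c("Index", name), c("Initial Values", ""),
    c("amplitude", sprintf("%.10g", amp_init)),
    c("chemicalshift", sprintf("%.10g", cs_init)),
    c("linewidth", sprintf("%.10g", lw_init)),
    c("phase", sprintf("%.10g", phase_init)),
    c("g", "0"),
    c("Bounds", ""),
    c("amplitude", "(0,"),
    c("chemicalshift", cs_bounds),
    c("linewidth", lw_bounds),
    c("phase", phase_bounds),
    c("g", "(0, 1)"))
  parse_prior_knowledge(df, carrier_mhz = carrier, ref_ppm = ref)
}

# The packaged 31P brain multiplet prior (beta/alpha-ATP) at 7T.
brain_pk <- function(carrier = 120.66) {
  parse_prior_knowledge(
    system.file("extdata", "prior_31p_brain.csv", package = "amaresr"),
    carrier_mhz = carrier)
}

brain_truth_peaks <- function(params) {
  m <- eval_full_params(params)
  data.frame(name = rownames(m), amplitude = m[, "amplitude"],
             chemicalshift = m[, "chemicalshift"], linewidth = m[, "linewidth"],
             phase = m[, "phase"], g = m[, "g"])
}

# Noiseless (or noisy) synthetic spectrum from the brain prior's own values.
brain_fid <- function(params, n = 2048, sw = 10000, sigma = 0, seed = NULL) {
  fid <- synthesize_fid(brain_truth_peaks(params), n_points = n, sw_hz = sw,
                        carrier_mhz = params$carrier_mhz,
                        ref_ppm = params$ref_ppm)
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    fid$samples <- fid$samples +
      complex(real = rnorm(n, 0, sigma), imaginary = rnorm(n, 0, sigma))
  }
  fid
}

# Short-echo 1H scenario: three narrow metabolite lines over two broad
# macromolecule (MM) components; phases all zero.
mm_scenario <- function(n = 1024, sw = 2500, carrier = 400, ref = 2.5) {
  met <- data.frame(name = c("NAA", "CR", "CHO"),
                    amplitude = c(1.0, 0.8, 1.2),
                    chemicalshift = c(1.0, 2.0, 3.0),
                    linewidth = c(8, 10, 12), phase = 0, g = 0)
  mm <- data.frame(name = c("MMA", "MMB"), amplitude = c(3, 4),
                   chemicalshift = c(0.9, 2.2),
                   linewidth = c(300, 450), phase = 0, g = 0)
  pk <- parse_prior_knowledge(prior_df(
    c("Index", "NAA", "CR", "CHO"), c("Initial Values", "", "", ""),
    c("amplitude", "0.9", "0.9", "0.9"),
    c("chemicalshift", "1.02", "1.98", "3.03"),
    c("linewidth", "10", "10", "10"),
    c("phase", "0", "0", "0"),
    c("g", "0", "0", "0"),
    c("Bounds", "", "", ""),
    c("amplitude", "(0,", "(0,", "(0,"),
    c("chemicalshift", "(0.8, 1.2)", "(1.8, 2.2)", "(2.8, 3.2)"),
    c("linewidth", "(1, 50)", "(1, 50)", "(1, 50)"),
    c("phase", "0", "0", "0"),
    c("g", "(0, 1)", "(0, 1)", "(0, 1)")),
    carrier_mhz = carrier, ref_ppm = ref)
  fid_all <- synthesize_fid(rbind(met, mm), n_points = n, sw_hz = sw,
                            carrier_mhz = carrier, ref_ppm = ref)
  fid_mm <- synthesize_fid(mm, n_points = n, sw_hz = sw,
                           carrier_mhz = carrier, ref_ppm = ref)
  list(met = met, mm = mm, pk = pk, fid_all = fid_all, fid_mm = fid_mm,
       n = n, sw = sw, carrier = carrier, ref = ref)
}

# Random damped-sinusoid mixtures with well-separated frequencies, for the
# HSVD construct-and-recover oracle.
random_tone_peaks <- function(k, min_sep = 150) {
  repeat {
    f <- sort(runif(k, -2000, 2000))
    if (k == 1 || min(diff(f)) >= min_sep) break
  }
  data.frame(name = paste0("T", seq_len(k)),
             amplitude = runif(k, 0.5, 2),
             frequency = f,
             damping = runif(k, 5, 80),
             phase = runif(k, -170, 170), g = 0)
}

# Small batch of noisy singlet FIDs with a slow amplitude trend.
batch_fids <- function(n_fids = 8, n = 256, seed = 50) {
  set.seed(seed)
  lapply(seq_len(n_fids), function(i) {
    amp <- 0.8 + 0.05 * i
    fid <- synthesize_fid(data.frame(amplitude = amp, chemicalshift = 0.5,
                                     linewidth = 8, phase = 0, g = 0),
                          n_points = n, sw_hz = 5000, carrier_mhz = 120)
    fid$samples <- fid$samples +
      complex(real = rnorm(n, 0, 0.02), imaginary = rnorm(n, 0, 0.02))
    fid
  })
}

spectral_rms <- function(a, b) {
  sqrt(mean(Mod(a$intensity - b$intensity)^2))
}
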