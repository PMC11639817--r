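singlet_fid <- function(cs = 0.5, amp = 1, lw = 10, phase = 0, n = 512,
                        sw = 5000, carrier = 120, sigma = 0, seed = NULL) {
  fid <- synthesize_fid(data.frame(amplitude = amp, chemicalshift = cs,
                                   linewidth = lw, phase = phase, g = 0),
                        n_points = n, sw_hz = sw, carrier_mhz = carrier)
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    fid$samples <- fid$samples +
      complex(real = rnorm(n, 0, sigma), imaginary = rnorm(n, 0, sigma))
  }
  fid
}

test_that("the time-domain residual is zero at a perfect fit and has norm^2 = sum|model-data|^2", {
  fid <- singlet_fid()
  params <- compile_parameters(singlet_prior(cs_init = 0.5, amp_init = 1,
                                             lw_init = 10))
  r <- build_residual(params$free_init, fid, params)
  expect_equal(length(r), 2 * 512)
  expect_lt(max(abs(r)), 1e-12)

  off <- params$free_init; off["PCR.amplitude"] <- 1.3
  r <- build_residual(off, fid, params)
  model <- synthesize_fid(data.frame(amplitude = 1.3, chemicalshift = 0.5,
                                     linewidth = 10, phase = 0, g = 0),
                          like = fid)
  expect_equal(sum(r^2), sum(Mod(model$samples - fid$samples)^2))
})

test_that("a full-window frequency mask reproduces the time-domain minimizer outcome", {
  fid <- singlet_fid()
  params <- compile_parameters(singlet_prior(cs_init = 0.5 + 20 / 120))
  ft <- fit_amares(fid, params, method = "trr", crlb = FALSE)
  fm <- fit_amares(fid, params, method = "trr", crlb = FALSE,
                   objective = objective_spec("frequency_masked",
                                              ppm_range = c(-21, 21)))
  expect_lt(max(abs(ft$free - fm$free) / pmax(1, abs(ft$free))), 1e-6)
  expect_error(build_residual(params$free_init, fid, params,
                              objective_spec("frequency_masked",
                                             ppm_range = c(50, 60))),
               "no frequency bins")
})

test_that("the 5-peak 31P spectrum initialized at truth fits to numerical zero", {
  params <- compile_parameters(brain_pk())
  fid <- brain_fid(params)
  fit <- fit_amares(fid, params, method = "trr", crlb = FALSE)
  expect_lt(sqrt(sum(Mod(fit$residual$samples)^2)) /
              sqrt(sum(Mod(fid$samples)^2)), 1e-8)
  expect_lt(max(abs(fit$free - params$free_init) / abs(params$free_init + 1e-12)),
            1e-6)
})

test_that("tied parameters satisfy their expressions exactly at any solution", {
  params <- compile_parameters(brain_pk())
  fid <- brain_fid(params, sigma = 0.01, seed = 5)
  fit <- fit_amares(fid, params, method = "trr+init", crlb = FALSE)
  est <- fit$peaks
  g <- function(nm, col) est[[col]][est$name == nm]
  expect_identical(g("BATP2", "amplitude"), g("BATP", "amplitude") / 2)
  expect_identical(g("BATP3", "amplitude"), g("BATP", "amplitude") / 2)
  expect_identical(g("AATP2", "amplitude"), g("AATP", "amplitude"))
  expect_identical(g("BATP2", "linewidth"), g("BATP", "linewidth"))
  expect_identical(g("AATP2", "phase"), g("BATP", "phase"))
  expect_equal(g("BATP2", "chemicalshift"), g("BATP", "chemicalshift") - 15 / 120.66)
})

test_that("a truth outside a deliberately wrong bound lands on the bound and is reported", {
  fid <- singlet_fid(amp = 2)
  params <- compile_parameters(singlet_prior(cs_init = 0.5, amp_init = 1,
                                             lw_init = 10))
  params$upper["PCR.amplitude"] <- 1.5      # truth amplitude 2 excluded
  fit <- fit_amares(fid, params, method = "trr", crlb = FALSE)
  expect_equal(unname(fit$free[["PCR.amplitude"]]), 1.5)
  expect_match(fit$message, "active bounds.*PCR.amplitude")
})

test_that("the objective never increases relative to the starting point", {
  set.seed(9)
  for (i in 1:5) {
    fid <- singlet_fid(sigma = 0.1, seed = 100 + i)
    params <- compile_parameters(singlet_prior(cs_init = 0.5 + runif(1, -0.5, 0.5)))
    for (method in c("lm", "trr", "trr+init")) {
      fit <- fit_amares(fid, params, method = method, crlb = FALSE)
      start_obj <- sum(build_residual(params$free_init, fid, params)^2)
      expect_lte(fit$objective_value, start_obj + 1e-12)
    }
  }
})

test_that("permuting independent peak groups leaves fitted values unchanged", {
  # two multiplet groups with no cross-group ties, so both column orders obey
  # the left-to-right dependency rule
  two_groups <- function(first_b = TRUE) {
    b <- list(c("BATP", "BATP2"), c("amplitude", "1.41", "BATP/2"),
              c("chemicalshift", "-16.15", "BATP-15Hz"),
              c("linewidth", "58.12", "BATP"), c("phase", "0", "BATP"),
              c("g", "0", "0"))
    a <- list(c("AATP", "AATP2"), c("amplitude", "1.545", "AATP"),
              c("chemicalshift", "-7.49", "AATP-16Hz"),
              c("linewidth", "32.28", "AATP"), c("phase", "10", "AATP"),
              c("g", "0", "0"))
    bb <- list(c("(0,", "(0,"), c("(-16.30, -16.00)", "(-16.30, -16.00)"),
               c("(54, 62)", "(54, 62)"), c("(-180, 180)", "(-180, 180)"),
               c("(0, 1)", "(0, 1)"))
    ba <- list(c("(0,", "(0,"), c("(-7.72, -7.42)", "(-7.72, -7.42)"),
               c("(31, 34)", "(31, 34)"), c("(-180, 180)", "(-180, 180)"),
               c("(0, 1)", "(0, 1)"))
    g1 <- if (first_b) b else a; g2 <- if (first_b) a else b
    bb1 <- if (first_b) bb else ba; bb2 <- if (first_b) ba else bb
    rows <- list(c("Index", g1[[1]], g2[[1]]), c("Initial Values", rep("", 4)))
    for (i in 2:6) rows[[length(rows) + 1]] <- c(g1[[i]][1], g1[[i]][-1], g2[[i]][-1])
    rows[[length(rows) + 1]] <- c("Bounds", rep("", 4))
    for (i in 1:5) {
      rows[[length(rows) + 1]] <- c(c("amplitude", "chemicalshift", "linewidth",
                                      "phase", "g")[i], bb1[[i]], bb2[[i]])
    }
    parse_prior_knowledge(as.data.frame(do.call(rbind, rows)),
                          carrier_mhz = 120.66)
  }
  pk1 <- two_groups(TRUE); pk2 <- two_groups(FALSE)
  p1 <- compile_parameters(pk1)
  fid <- synthesize_fid(brain_truth_peaks(p1), n_points = 2048, sw_hz = 10000,
                        carrier_mhz = 120.66)
  set.seed(31)
  fid$samples <- fid$samples +
    complex(real = rnorm(2048, 0, 0.02), imaginary = rnorm(2048, 0, 0.02))
  fit1 <- fit_amares(fid, p1, method = "trr", crlb = FALSE)
  fit2 <- fit_amares(fid, compile_parameters(pk2), method = "trr", crlb = FALSE)
  j <- match(fit1$peaks$name, fit2$peaks$name)
  for (col in c("amplitude", "chemicalshift", "linewidth", "phase")) {
    expect_lt(max(abs(fit1$peaks[[col]] - fit2$peaks[[col]][j]) /
                    pmax(1, abs(fit1$peaks[[col]]))), 1e-6)
  }
})

test_that("an all-fixed prior yields an evaluation-only result with a warning", {
  df <- prior_df(
    c("Index", "REF"), c("Initial Values", ""),
    c("amplitude", "1"), c("chemicalshift", "0.5"),
    c("linewidth", "10"), c("phase", "0"), c("g", "0"),
    c("Bounds", ""), c("amplitude", ""), c("chemicalshift", ""),
    c("linewidth", ""), c("phase", ""), c("g", ""))
  pk <- parse_prior_knowledge(df, carrier_mhz = 120)
  fid <- singlet_fid()
  expect_warning(fit <- fit_amares(fid, pk, crlb = FALSE), "evaluation-only")
  expect_lt(max(Mod(fit$residual$samples)), 1e-12)
})

test_that("user objective hooks are called and validated", {
  fid <- singlet_fid()
  params <- compile_parameters(singlet_prior(cs_init = 0.5, amp_init = 1,
                                             lw_init = 10))
  hook <- function(free, fid, params) {
    build_residual(free, fid, params, objective_spec())[1:100]
  }
  obj <- objective_spec("user_hook", hook = hook, residual_length = 100)
  fit <- fit_amares(fid, params, method = "trr", objective = obj, crlb = FALSE)
  expect_true(fit$converged)
  bad <- objective_spec("user_hook", hook = hook, residual_length = 99)
  expect_error(build_residual(params$free_init, fid, params, bad),
               "length 100, expected 99")
  expect_error(objective_spec("user_hook"), "hook")
  expect_error(objective_spec("frequency_masked"), "ppm_range")
  expect_error(objective_spec(weights = c(-1, rep(1, 511))), "non-negative")
})

test_that("non-finite FIDs are rejected", {
  fid <- singlet_fid()
  fid$samples[5] <- NaN + 0i
  expect_error(fit_amares(fid, singlet_prior(), crlb = FALSE), "non-finite")
})
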