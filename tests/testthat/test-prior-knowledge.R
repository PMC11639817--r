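test_that("bound cells parse ranges, one-sided limits and fixed values", {
  b <- parse_bound("(−180, 180)")   # Unicode minus
  expect_equal(b[c("type", "lower", "upper")], list(type = "range", lower = -180, upper = 180))
  b <- parse_bound("(0,")
  expect_equal(b[c("lower", "upper")], list(lower = 0, upper = Inf))
  b <- parse_bound(", 180)")
  expect_equal(b[c("lower", "upper")], list(lower = -Inf, upper = 180))
  b <- parse_bound("180)")
  expect_equal(b[c("lower", "upper")], list(lower = -Inf, upper = 180))
  b <- parse_bound("0")
  expect_equal(b[c("type", "fixed")], list(type = "fixed", fixed = 0))
  expect_equal(parse_bound("(0, 1)")$upper, 1)
  expect_error(parse_bound("(5, 2)"), "lower >= upper")
  expect_error(parse_bound("(a, b)", where = "row 'phase'"), "phase")
  expect_error(parse_bound(""), "empty")
})

test_that("tie expressions parse ratios, Hz offsets and identity references", {
  e <- parse_expression("BATP/2", "amplitude", "BATP")
  expect_s3_class(e, "amares_expr")
  expect_equal(e[c("ref", "op", "operand")],
               list(ref = "BATP", op = "scale", operand = 0.5))
  e <- parse_expression("BATP*1.5", "amplitude", "BATP")
  expect_equal(e$operand, 1.5)
  e <- parse_expression("BATP-15Hz", "chemicalshift", "BATP")
  expect_equal(e[c("op", "operand")], list(op = "offset_hz", operand = -15))
  e <- parse_expression("BATP+15Hz", "chemicalshift", "BATP")
  expect_equal(e$operand, 15)
  e <- parse_expression("AATP", "amplitude", c("BATP", "AATP"))
  expect_equal(e$op, "identity")
  e <- parse_expression("NAA-0.1", "chemicalshift", "NAA")
  expect_equal(e[c("op", "operand")], list(op = "offset_ppm", operand = -0.1))
  expect_equal(parse_expression("−1.5", "amplitude", character(0)), -1.5)

  # references must point left; names may carry digits only as a suffix
  expect_error(parse_expression("BATP2", "amplitude", character(0)), "must precede")
  expect_error(parse_expression("B2ATP/2", "amplitude", "B2ATP"), "cannot parse|trailing")
  expect_error(parse_expression("NAA-5Hz", "phase", "NAA"), "chemicalshift or linewidth")
  expect_error(parse_expression("NAA-5", "amplitude", "NAA"), "chemicalshift")
})

test_that("the 31P brain table parses into 5 peaks with 2 multiplet groups", {
  pk <- brain_pk()
  expect_equal(pk$peaks, c("BATP", "BATP2", "BATP3", "AATP", "AATP2"))
  expect_equal(pk$groups,
               list(BATP = c("BATP", "BATP2", "BATP3"), AATP = c("AATP", "AATP2")))
  # comment lines are dropped without affecting the peak count
  df <- write_prior_knowledge(pk)
  df2 <- rbind(c("# a leading comment", rep("", ncol(df) - 1)), df)
  pk2 <- parse_prior_knowledge(df2, carrier_mhz = 120.66)
  expect_equal(pk2$peaks, pk$peaks)
})

test_that("dependency order, duplicates and malformed schemas are rejected", {
  # BATP2 placed left of BATP: forward reference
  df <- prior_df(
    c("Index", "BATP2", "BATP"), c("Initial Values", "", ""),
    c("amplitude", "BATP/2", "1.41"), c("chemicalshift", "-16.2", "-16.15"),
    c("linewidth", "58", "58"), c("phase", "0", "0"), c("g", "0", "0"),
    c("Bounds", "", ""), c("amplitude", "(0,", "(0,"),
    c("chemicalshift", "(-17, -16)", "(-17, -16)"),
    c("linewidth", "(1, 100)", "(1, 100)"),
    c("phase", "(-180, 180)", "(-180, 180)"), c("g", "(0, 1)", "(0, 1)"))
  expect_error(parse_prior_knowledge(df, carrier_mhz = 120), "must precede")

  df <- prior_df(
    c("Index", "PCR", "PCR"), c("Initial Values", "", ""),
    c("amplitude", "1", "1"), c("chemicalshift", "0", "0"),
    c("linewidth", "5", "5"), c("phase", "0", "0"), c("g", "0", "0"),
    c("Bounds", "", ""), c("amplitude", "(0,", "(0,"),
    c("chemicalshift", "(-1, 1)", "(-1, 1)"), c("linewidth", "(1, 9)", "(1, 9)"),
    c("phase", "(-180, 180)", "(-180, 180)"), c("g", "(0, 1)", "(0, 1)"))
  expect_error(parse_prior_knowledge(df, carrier_mhz = 120), "duplicate")

  # missing linewidth row in the bounds block
  pkdf <- write_prior_knowledge(brain_pk())
  broken <- pkdf[-11, ]
  expect_error(parse_prior_knowledge(broken, carrier_mhz = 120), "linewidth")

  # expressions inside the bounds block are rejected, not guessed
  pkdf2 <- write_prior_knowledge(brain_pk())
  pkdf2[10, 3] <- "BATP"
  expect_error(parse_prior_knowledge(pkdf2, carrier_mhz = 120), "Bounds block")
})

test_that("compilation classifies the 31P brain table into exactly 7 free parameters", {
  params <- compile_parameters(brain_pk())
  expect_equal(sort(params$free_names),
               sort(c("BATP.amplitude", "BATP.chemicalshift", "BATP.linewidth",
                      "BATP.phase", "AATP.amplitude", "AATP.chemicalshift",
                      "AATP.linewidth")))
  e <- params$entries
  expect_true(all(e$type[e$field == "g"] == "fixed"))
  expect_true(all(e$value[e$field == "g"] == 0))
  # every cell classified exactly once
  expect_equal(nrow(e), 25)
  expect_true(all(e$type %in% c("free", "tied", "fixed")))
})

test_that("tie evaluators reproduce their defining expressions exactly", {
  params <- compile_parameters(brain_pk())
  # amplitude ratio at the printed initial value
  m <- eval_full_params(params)
  expect_equal(m["BATP2", "amplitude"], 1.41 / 2)
  expect_equal(m["BATP3", "amplitude"], 1.41 / 2)
  expect_equal(m["AATP2", "amplitude"], m["AATP", "amplitude"])
  # J-coupling offsets in Hz, converted through the carrier
  expect_equal(m["BATP2", "chemicalshift"], m["BATP", "chemicalshift"] - 15 / 120.66)
  expect_equal(m["BATP3", "chemicalshift"], m["BATP", "chemicalshift"] + 15 / 120.66)
  expect_equal(m["AATP2", "chemicalshift"], m["AATP", "chemicalshift"] - 16 / 120.66)

  # property: at random free-parameter draws the ties still hold exactly
  set.seed(11)
  for (i in 1:20) {
    free <- params$free_init * runif(7, 0.5, 1.5)
    m <- eval_full_params(params, free)
    expect_identical(m["BATP2", "amplitude"], unname(free["BATP.amplitude"]) / 2)
    expect_identical(m["BATP2", "linewidth"], unname(free["BATP.linewidth"]))
    expect_identical(m["AATP2", "phase"], unname(free["BATP.phase"]))
    expect_equal(m["BATP2", "chemicalshift"],
                 unname(free["BATP.chemicalshift"]) - 15 / 120.66)
  }
})

test_that("a peak of bare numbers with no bound entries compiles fully fixed", {
  df <- prior_df(
    c("Index", "REF"), c("Initial Values", ""),
    c("amplitude", "2.5"), c("chemicalshift", "1.1"),
    c("linewidth", "12"), c("phase", "30"), c("g", "0"),
    c("Bounds", ""), c("amplitude", ""), c("chemicalshift", ""),
    c("linewidth", ""), c("phase", ""), c("g", ""))
  params <- compile_parameters(parse_prior_knowledge(df, carrier_mhz = 120))
  expect_equal(length(params$free_names), 0)
  expect_true(all(params$entries$type == "fixed"))
  m <- eval_full_params(params)
  expect_equal(unname(m["REF", ]), c(2.5, 1.1, 12, 30, 0))
})

test_that("serialization round-trips to an identical structure", {
  pk <- brain_pk()
  tmp <- tempfile(fileext = ".csv")
  write_prior_knowledge(pk, tmp)
  pk2 <- parse_prior_knowledge(tmp, carrier_mhz = 120.66)
  expect_equal(pk2$peaks, pk$peaks)
  expect_equal(pk2$groups, pk$groups)
  expect_equal(pk2$cells$init_text, pk$cells$init_text)
  expect_equal(pk2$cells$bound_text, pk$cells$bound_text)
  p1 <- compile_parameters(pk); p2 <- compile_parameters(pk2)
  expect_identical(p1$free_init, p2$free_init)
  expect_identical(eval_full_params(p1), eval_full_params(p2))
})

test_that("an initial g of 0 pins the lineshape; a positive g is fitted", {
  pk <- singlet_prior()
  pk$cells$init[[which(pk$cells$field == "g")]] <- 0.1
  pk$cells$init_text[which(pk$cells$field == "g")] <- "0.1"
  params <- compile_parameters(pk)
  expect_true("PCR.g" %in% params$free_names)
  params0 <- compile_parameters(singlet_prior())
  expect_false("PCR.g" %in% params0$free_names)
})
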