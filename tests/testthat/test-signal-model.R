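test_that("model synthesis matches the damped-sinusoid equation in limit cases", {
  # a=1, f=d=phi=0: the model collapses to a constant 1
  fid <- synthesize_fid(data.frame(amplitude = 1, frequency = 0, damping = 0,
                                   phase = 0, g = 0),
                        n_points = 64, sw_hz = 5000, carrier_mhz = 120)
  expect_equal(fid$samples, rep(1 + 0i, 64))

  # first point is a * exp(j phi): a=2, phi=90deg -> 0+2i
  fid <- synthesize_fid(data.frame(amplitude = 2, frequency = 0, damping = 0,
                                   phase = 90, g = 0),
                        n_points = 16, sw_hz = 5000, carrier_mhz = 120)
  expect_equal(fid$samples[1], 0 + 2i)

  # modulus is the pure exponential envelope for g = 0
  d <- 182.6
  fid <- synthesize_fid(data.frame(amplitude = 1.3, frequency = 400,
                                   damping = d, phase = 25, g = 0),
                        n_points = 256, sw_hz = 5000, carrier_mhz = 120)
  expect_equal(Mod(fid$samples), 1.3 * exp(-d * fid_times(fid)))
})

test_that("synthesis is additive over peaks and linear in amplitude", {
  p1 <- data.frame(amplitude = 1.2, frequency = 300, damping = 40, phase = 10, g = 0)
  p2 <- data.frame(amplitude = 0.7, frequency = -800, damping = 15, phase = -60, g = 0.3)
  mk <- function(p) synthesize_fid(p, n_points = 256, sw_hz = 5000, carrier_mhz = 120)
  expect_equal(mk(rbind(p1, p2))$samples, mk(p1)$samples + mk(p2)$samples)
  p3 <- p1; p3$amplitude <- 3 * p1$amplitude
  expect_equal(mk(p3)$samples, 3 * mk(p1)$samples)
})

test_that("adding 360 degrees of phase leaves the signal unchanged", {
  base <- data.frame(amplitude = 1, frequency = 123, damping = 20, phase = 47, g = 0.2)
  shifted <- base; shifted$phase <- base$phase + 360
  mk <- function(p) synthesize_fid(p, n_points = 128, sw_hz = 5000, carrier_mhz = 120)
  expect_equal(mk(shifted)$samples, mk(base)$samples)
})

test_that("invalid peaks and axes are rejected with informative errors", {
  expect_error(synthesize_fid(data.frame(amplitude = NA_real_, frequency = 0,
                                         damping = 0, phase = 0, g = 0),
                              n_points = 16, sw_hz = 5000, carrier_mhz = 120),
               "amplitude")
  expect_error(synthesize_fid(data.frame(amplitude = numeric(0)),
                              n_points = 16, sw_hz = 5000, carrier_mhz = 120),
               "empty")
  expect_error(fid_signal(1 + 0i, sw_hz = 5000, carrier_mhz = 120), "2 samples")
  expect_error(fid_signal(c(1, 2), sw_hz = 5000, carrier_mhz = -1), "carrier")
})

test_that("spectrum transform has the documented convention", {
  # impulse at n=0: flat magnitude across bins
  fid <- fid_signal(c(1 + 0i, rep(0 + 0i, 63)), sw_hz = 5000, carrier_mhz = 120)
  sp <- fid_to_spectrum(fid)
  expect_equal(Mod(sp$intensity), rep(1, 64))

  # all-ones FID: magnitude maximal at the 0 Hz bin
  fid <- fid_signal(rep(1 + 0i, 64), sw_hz = 5000, carrier_mhz = 120)
  sp <- fid_to_spectrum(fid)
  expect_equal(sp$freq_hz[which.max(Mod(sp$intensity))], 0)

  # Parseval under the unnormalized forward DFT
  set.seed(42)
  y <- complex(real = rnorm(128), imaginary = rnorm(128))
  fid <- fid_signal(y, sw_hz = 5000, carrier_mhz = 120)
  sp <- fid_to_spectrum(fid)
  expect_equal(sum(Mod(y)^2), sum(Mod(sp$intensity)^2) / 128)

  # frequency axis spans [-SW/2, SW/2) uniformly; ppm derived from it
  expect_equal(sp$freq_hz[1], -2500)
  expect_equal(diff(sp$freq_hz), rep(5000 / 128, 127))
  expect_equal(sp$ppm, sp$freq_hz / 120)
  expect_error(fid_to_spectrum(fid, zero_fill = 64), "zero_fill")
})

test_that("a noiseless singlet peaks at the bin nearest its frequency", {
  for (f in c(-1234.5, 0, 777)) {
    fid <- synthesize_fid(data.frame(amplitude = 1, frequency = f, damping = 30,
                                     phase = 0, g = 0),
                          n_points = 512, sw_hz = 5000, carrier_mhz = 120)
    sp <- fid_to_spectrum(fid)
    fmax <- sp$freq_hz[which.max(Mod(sp$intensity))]
    expect_lt(abs(fmax - f), 5000 / 512)
  }
})

test_that("Hz/ppm conversion reproduces the printed spectral resolutions", {
  # 20 kHz bandwidth over 256 points at 35.3 MHz
  expect_equal(round(20000 / 256), 78)
  expect_equal(round(hz_to_ppm(20000 / 256, carrier_mhz = 35.3), 2), 2.21)
  # 5 kHz over 1024 points at 51.72 MHz
  expect_equal(round(5000 / 1024), 5)
  expect_equal(round(hz_to_ppm(5000 / 1024, carrier_mhz = 51.72), 2), 0.09)
  # reference point maps to 0 Hz; round trip is exact
  expect_equal(ppm_to_hz(4.7, 300, ref_ppm = 4.7), 0)
  x <- seq(-3000, 3000, length.out = 11)
  expect_equal(ppm_to_hz(hz_to_ppm(x, 120.66, 1.2), 120.66, 1.2), x)
  expect_error(hz_to_ppm(10, carrier_mhz = 0), "carrier")
})

test_that("linewidth/damping bijection is pi*LW and matches the measured FWHM", {
  expect_equal(linewidth_to_damping(58.12), pi * 58.12)
  expect_equal(damping_to_linewidth(linewidth_to_damping(58.12)), 58.12)
  expect_equal(linewidth_to_damping(0, g = 0.7), 0)
  lws <- c(1, 10, 58.12, 200)
  expect_true(all(diff(linewidth_to_damping(lws, g = 0.4)) > 0))
  expect_error(linewidth_to_damping(-1), ">= 0")

  # numeric FWHM oracle: absorption-mode width of a densely sampled pure
  # Lorentzian singlet equals the nominal linewidth within 0.5%
  lw <- 58.12
  n <- 5120; sw <- 50000
  fid <- synthesize_fid(data.frame(amplitude = 1, frequency = 0,
                                   damping = linewidth_to_damping(lw),
                                   phase = 0, g = 0),
                        n_points = n, sw_hz = sw, carrier_mhz = 120)
  sp <- fid_to_spectrum(fid, zero_fill = n * 64)
  re <- Re(sp$intensity); half <- max(re) / 2; f <- sp$freq_hz
  above <- which(re >= half)
  lo <- min(above); hi <- max(above)
  cross <- function(i1, i2) f[i1] + (half - re[i1]) * (f[i2] - f[i1]) / (re[i2] - re[i1])
  fwhm <- cross(hi, hi + 1) - cross(lo, lo - 1)
  expect_lt(abs(fwhm - lw) / lw, 0.005)
})

test_that("dead time enters the time axis and phases the spectrum", {
  dead <- 2e-3
  fid <- synthesize_fid(data.frame(amplitude = 1, frequency = 200, damping = 30,
                                   phase = 0, g = 0),
                        n_points = 256, sw_hz = 5000, dead_time = dead,
                        carrier_mhz = 120)
  expect_equal(fid_times(fid)[1], dead)
  # first sample already attenuated and rotated by the dead-time evolution
  expect_equal(fid$samples[1], exp((-30 + 2i * pi * 200) * dead))
})
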