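# Band-pass design, discretization, response evaluation, fitting, filtering.

half_power_db <- -10 * log10(2)

test_that("Butterworth band-pass has half-power edges and unit peak", {
  cases <- list(c(0.305, 1.615, 4), c(1, 2, 2), c(0.2, 3, 6))
  for (cs in cases) {
    f <- design_butterworth_bandpass(cs[1], cs[2], cs[3])
    resp <- frequency_response(f, c(cs[1], sqrt(cs[1] * cs[2]), cs[2]))
    expect_equal(resp$magnitude_db[c(1, 3)], rep(half_power_db, 2),
                 tolerance = 0.01 / 3)
    expect_equal(resp$magnitude_db[2], 0, tolerance = 0.01)
    expect_equal(half_power_freqs(f), c(cs[1], cs[2]), tolerance = 1e-6)
  }
})

test_that("band-pass design rejects bad arguments", {
  expect_error(design_butterworth_bandpass(0, 1.6, 4), "band edges")
  expect_error(design_butterworth_bandpass(1.6, 0.3, 4), "band edges")
  expect_error(design_butterworth_bandpass(0.3, 1.6, 3), "even")
  expect_error(frequency_response(default_modifiable_filter(), c(2, 1)),
               "increasing")
})

test_that("analog magnitude response matches per-point polynomial oracle", {
  f <- default_modifiable_filter()
  grid <- exp(seq(log(0.01), log(16.15), length.out = 1000))
  resp <- frequency_response(f, grid)
  oracle <- vapply(grid, function(fr)
    20 * log10(oracle_mag_analog(f$num, f$den, fr)), numeric(1))
  expect_equal(resp$magnitude_db, oracle, tolerance = 1e-10)
})

test_that("bilinear discretization keeps the band-pass character", {
  f <- default_modifiable_filter()
  for (fs in c(30, 100)) {
    d <- discretize(f, fs)
    expect_s3_class(d, "digital_bandpass")
    expect_length(d$b, length(d$a))
    expect_equal(d$a[1], 1)
    # DC rejection: |H(z = 1)| = 0
    expect_equal(sum(d$b) / sum(d$a), 0, tolerance = 1e-9)
    expect_true(all(Mod(polyroot(rev(d$a))) < 1))
  }
  d100 <- discretize(f, 100)
  expect_equal(half_power_freqs(d100), c(0.305, 1.615), tolerance = 0.01)
})

test_that("digital magnitude matches a unit-circle evaluation oracle", {
  d <- discretize(default_modifiable_filter(), 30)
  for (fr in c(0.1, 1.0, 2.5))
    expect_equal(frequency_response(d, fr)$magnitude_db,
                 20 * log10(oracle_mag_digital(d$b, d$a, fr, 30)),
                 tolerance = 1e-10)
})

test_that("analog and digital responses agree inside the band", {
  f <- default_modifiable_filter()
  grid30 <- seq(0.05, 1.5, by = 0.05)
  diff30 <- frequency_response(discretize(f, 30), grid30)$magnitude_db -
    frequency_response(f, grid30)$magnitude_db
  expect_lt(max(abs(diff30)), 0.1)
  grid100 <- seq(0.05, 3, by = 0.05)
  diff100 <- frequency_response(discretize(f, 100), grid100)$magnitude_db -
    frequency_response(f, grid100)$magnitude_db
  expect_lt(max(abs(diff100)), 0.1)
})

test_that("prewarped discretization is exact at the matched frequency", {
  f <- default_modifiable_filter()
  d <- discretize(f, 30, prewarp_hz = 1.615)
  expect_equal(frequency_response(d, 1.615)$magnitude_db,
               frequency_response(f, 1.615)$magnitude_db, tolerance = 1e-9)
})

test_that("discretization rejects sampling rates too close to the band", {
  expect_error(discretize(default_modifiable_filter(), 12), "too low")
  expect_error(frequency_response(discretize(default_modifiable_filter(), 30),
                                  c(14, 16)), "Nyquist")
})

test_that("fit recovers a representable order-4 band-pass", {
  target <- design_butterworth_bandpass(0.305, 1.615, 4)
  ref <- frequency_response(target, exp(seq(log(0.05), log(5),
                                            length.out = 80)))
  fit <- fit_bandpass_to_reference(ref, order = 4, seed = 11)
  expect_lt(attr(fit, "objective"), 0.01)
  hp <- half_power_freqs(fit)
  expect_equal(hp[1], 0.305, tolerance = 0.01)
  expect_equal(hp[2], 1.615, tolerance = 0.01)
  # objective at the true parameters of a member of the family is zero
  obj <- wearcounts:::fit_objective(ref, 4)
  theta_true <- wearcounts:::filter_to_theta(target)
  expect_lt(obj(theta_true), 1e-18)
})

test_that("fit is bit-reproducible for a fixed seed", {
  ref <- frequency_response(design_butterworth_bandpass(0.4, 1.2, 4),
                            exp(seq(log(0.05), log(6), length.out = 60)))
  f1 <- fit_bandpass_to_reference(ref, order = 4, seed = 5)
  f2 <- fit_bandpass_to_reference(ref, order = 4, seed = 5)
  expect_identical(f1$num, f2$num)
  expect_identical(f1$den, f2$den)
})

test_that("default fixed filter matches the packaged reference at 30 Hz", {
  ff <- default_fixed_filter()
  expect_equal(ff$order, 8L)
  ref <- read_reference_response(
    system.file("extdata", "synthetic_reference_response.csv",
                package = "wearcounts"))
  sel <- ref$freq_hz >= 0.25 & ref$freq_hz <= 2.5
  dig <- discretize(ff, 30)
  got <- frequency_response(dig, ref$freq_hz[sel])$magnitude_db
  expect_lt(max(abs(got - ref$magnitude_db[sel])), 0.5)
})

test_that("every designed, fitted or discretized filter is stable", {
  filts <- list(design_butterworth_bandpass(0.2, 1.0, 4),
                design_butterworth_bandpass(0.305, 1.615, 8),
                default_fixed_filter())
  for (f in filts) {
    expect_true(all(Re(polyroot(rev(f$den))) < 0))
    for (fs in c(30, 100))
      expect_true(all(Mod(polyroot(rev(discretize(f, fs)$a))) < 1))
  }
})

test_that("apply_filter is causal, rejects DC and has the predicted gain", {
  d <- discretize(default_modifiable_filter(), 100)
  expect_equal(apply_filter(rep(0, 500), d), rep(0, 500))
  y <- apply_filter(rep(1, 100 * 90), d)
  expect_lt(max(abs(utils::tail(y, 30 * 100))), 1e-6)
  # steady-state sinusoid amplitude equals |H| at that frequency
  x <- sin(2 * pi * 1 * (0:(100 * 120 - 1)) / 100)
  ss <- utils::tail(apply_filter(x, d), 60 * 100)
  gain_pred <- 10^(frequency_response(d, 1)$magnitude_db / 20)
  expect_equal(max(abs(ss)), gain_pred, tolerance = 0.005)
})

test_that("apply_filter matches a naive direct-form recursion", {
  d <- discretize(default_modifiable_filter(), 30)
  set.seed(42)
  x <- rnorm(400)
  expect_equal(apply_filter(x, d), oracle_iir(d$b, d$a, x),
               tolerance = 1e-10)
})

test_that("apply_filter enforces sampling-rate agreement", {
  d <- discretize(default_modifiable_filter(), 30)
  expect_error(apply_filter(rnorm(10), d, fs = 100), "30")
  raw <- gen_sinusoid(1, 0.2, fs = 100, duration_s = 2)
  expect_error(apply_filter(raw, d), "30")
})

test_that("filters round-trip through JSON", {
  f <- default_modifiable_filter()
  f2 <- filter_from_json(filter_to_json(f))
  expect_equal(f2$num, f$num)
  expect_equal(f2$den, f$den)
  expect_equal(f2$band, c(0.305, 1.615))
  d <- discretize(f, 30)
  path <- withr::local_tempfile(fileext = ".json")
  filter_to_json(d, path)
  d2 <- filter_from_json(path)
  expect_equal(d2$b, d$b, tolerance = 1e-12)
  expect_equal(d2$fs, 30)
})

test_that("unstable or non-band-pass coefficient sets are rejected", {
  expect_error(analog_bandpass(c(1, 0), c(1, -3, 2)), "unstable")
  expect_error(analog_bandpass(c(1, 1), c(1, 2, 2)), "DC")
  expect_error(digital_bandpass(c(1, 0), c(1, -1.5), fs = 30), "unstable")
})
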