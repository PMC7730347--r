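# The eight-step count quantification pipeline.

test_that("unit conversion reproduces the count pipeline's constant pairs", {
  r <- raw_accel(9.8, 20.874, 0.6664, fs = 100, units = "m/s2")
  g <- to_g(r)
  expect_equal(g$ax, 1.0)
  expect_equal(g$ay, 2.13)
  expect_equal(g$az, 0.068)
  # idempotent on g input
  expect_identical(to_g(g), g)
  r2 <- raw_accel(0.0163072, 0, 0, fs = 30, units = "m/s2")
  expect_equal(to_g(r2)$ax, 0.001664)
})

test_that("elementwise stages match loop oracles and their conventions", {
  set.seed(7)
  x <- abs(rnorm(300, sd = 1.2))
  expect_equal(rectify(c(-1, 0, 2)), c(1, 0, 2))
  expect_equal(rectify(x), vapply(x, abs, numeric(1)))
  expect_equal(saturate(3.0), 2.13)
  expect_equal(saturate(1.0), 1.0)
  expect_equal(saturate(x), vapply(x, function(v) min(v, 2.13), numeric(1)))
  expect_equal(deadband(0.05), 0)
  expect_equal(deadband(0.068), 0.068)  # boundary kept
  expect_equal(deadband(x),
               vapply(x, function(v) if (v < 0.068) 0 else v, numeric(1)))
  expect_equal(scale_to_counts(0.001664), 1)
  expect_equal(scale_to_counts(0), 0)
  expect_equal(scale_to_counts(0.0049, quantize = TRUE),
               floor(0.0049 / 0.001664))
  expect_error(saturate(1, limit = -1), "positive")
  expect_error(scale_to_counts(1, count_scale_g = 0), "positive")
})

test_that("epoch aggregation divides epoch sums by the sampling rate", {
  expect_equal(epoch_aggregate(rep(1, 100), fs = 100), 1.0)
  expect_length(epoch_aggregate(rep(1, 250), fs = 100), 2L)
  expect_length(epoch_aggregate(numeric(0), fs = 30), 0L)
  set.seed(3)
  x <- runif(300)
  got <- epoch_aggregate(x, fs = 30)
  want <- vapply(1:10, function(e) sum(x[((e - 1) * 30 + 1):(e * 30)]) / 30,
                 numeric(1))
  expect_equal(got, want)
})

test_that("vm3 is the Euclidean norm of the per-axis counts", {
  expect_equal(vm3(3, 4, 0), 5)
  expect_equal(vm3(0, 0, 0), 0)
  expect_equal(vm3(1, 1, 1), sqrt(3))
  cs <- count_series(c(1, 2), c(2, 3), c(2, 6))
  expect_equal(cs$vm3, sqrt(cs$sx^2 + cs$sy^2 + cs$sz^2))
})

test_that("zero and gravity-only signals produce zero counts", {
  z <- raw_accel(rep(0, 1800), rep(0, 1800), rep(0, 1800), fs = 30)
  cz <- compute_counts(z)
  expect_equal(cz$vm3, rep(0, 60))
  grav <- raw_accel(rep(0, 3600), rep(0, 3600), rep(1, 3600), fs = 30)
  cg <- compute_counts(grav)
  # DC is rejected; after a settling prefix the residual is below deadband
  expect_equal(cg$vm3[-(1:10)], rep(0, length(cg$vm3) - 10))
})

test_that("the pipeline equals a naive straight-line reference", {
  cfg <- pipeline_config("modifiable")
  filt <- discretize(default_modifiable_filter(), 30)
  set.seed(12)
  for (rep_i in 1:3) {
    n <- 300
    raw <- raw_accel(rnorm(n, sd = 0.4), rnorm(n, sd = 0.4),
                     1 + rnorm(n, sd = 0.4), fs = 30)
    got <- compute_counts(raw, cfg)
    for (ax in c("ax", "ay", "az")) {
      want <- oracle_axis_counts(raw[[ax]], filt$b, filt$a, fs = 30,
                                 gain = 0.96)
      field <- c(ax = "sx", ay = "sy", az = "sz")[ax]
      expect_equal(got[[field]], want, tolerance = 1e-9)
    }
    expect_equal(got$vm3, sqrt(got$sx^2 + got$sy^2 + got$sz^2))
  }
})

test_that("steady sinusoid counts match the step-by-step reference", {
  raw <- gen_sinusoid(1, 0.5, fs = 100, duration_s = 60)
  cfg <- pipeline_config("modifiable")
  got <- compute_counts(raw, cfg)
  filt <- discretize(default_modifiable_filter(), 100)
  want <- oracle_axis_counts(raw$ax, filt$b, filt$a, fs = 100, gain = 0.96)
  expect_equal(got$sx, want, tolerance = 1e-9)
  expect_gt(mean(got$sx[-(1:5)]), 0)
})

test_that("counts scale linearly inside the deadband-saturation corridor", {
  # amplitudes well above the deadband and below saturation, so the
  # thresholds clip only a negligible sliver of each cycle
  c1 <- compute_counts(gen_sinusoid(1, 1.0, fs = 100, duration_s = 90))
  c2 <- compute_counts(gen_sinusoid(1, 2.0, fs = 100, duration_s = 90))
  steady <- 11:90
  expect_equal(c2$vm3[steady] / c1$vm3[steady], rep(2, length(steady)),
               tolerance = 0.01)
})

test_that("counts rise monotonically with amplitude and then plateau", {
  amps <- c(0.1, 0.3, 0.6, 1.2, 2.5, 20, 50, 80)
  means <- vapply(amps, function(a) {
    cs <- compute_counts(gen_sinusoid(1, a, fs = 100, duration_s = 30))
    mean(cs$vm3[-(1:10)])
  }, numeric(1))
  expect_true(all(diff(means) >= -1e-9))
  # saturation caps the per-sample contribution, so counts flatten out
  expect_equal(means[8] / means[7], 1, tolerance = 0.02)
})

test_that("quantized counts are integer multiples of the gain", {
  raw <- gen_sinusoid(1, 0.5, fs = 100, duration_s = 30)
  cfg <- pipeline_config("modifiable", quantize = TRUE, gain = 1,
                         epoch_s = 1)
  cs <- compute_counts(raw, cfg)
  per_sample_sums <- cs$sx * 100  # epoch value * fs = sum of integer counts
  expect_equal(per_sample_sums, round(per_sample_sums), tolerance = 1e-9)
  expect_true(all(cs$vm3 >= 0))
})

test_that("pipeline validates its inputs", {
  expect_error(raw_accel(1:3, 1:2, 1:3, fs = 30), "identical length")
  expect_error(raw_accel(1, 1, 1, fs = 30, units = "furlong"))
  low <- raw_accel(rep(0, 100), rep(0, 100), rep(0, 100), fs = 10)
  expect_error(compute_counts(low), "30 Hz")
  expect_error(pipeline_config(deadband_g = 3), "below saturation_g")
  expect_error(pipeline_config("custom"), "requires a filter")
  d30 <- discretize(default_modifiable_filter(), 30)
  raw100 <- gen_sinusoid(1, 0.2, fs = 100, duration_s = 2)
  expect_error(compute_counts(raw100, pipeline_config("custom", filter = d30)),
               "bound to fs")
})

test_that("m/s2 input gives the same counts as the equivalent g input", {
  raw_g <- gen_sinusoid(1.2, 0.4, fs = 100, duration_s = 20)
  raw_si <- raw_accel(raw_g$ax * 9.8, raw_g$ay * 9.8, raw_g$az * 9.8,
                      fs = 100, units = "m/s2")
  expect_equal(compute_counts(raw_si)$vm3, compute_counts(raw_g)$vm3,
               tolerance = 1e-12)
})
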