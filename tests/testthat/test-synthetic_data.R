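test_that("analytic RI hits the archetype anchor values", {
  expect_equal(true_ri(archetype_spec("power_law", gamma = 0)), 1)
  expect_equal(true_ri(archetype_spec("power_law", gamma = 1)), 0)
  expect_equal(true_ri(archetype_spec("power_law", gamma = 3)), -0.5)
  # independent hand formulas for the other families
  sat <- archetype_spec("saturation", rmax = 1, K = 25)
  a_c <- 1 * (100 - 25 * log(1 + 100 / 25))
  expect_equal(true_ri(sat), a_c / (0.8 * 100 / 2) - 1)
  pc <- archetype_spec("pcrit_regulator", pcrit_pct = 25)
  expect_equal(true_ri(pc), 1 - 25 / 100)
  sup <- archetype_spec("suppressor", threshold_pct = 70,
                        suppression_fraction = 0.25)
  expect_equal(true_ri(sup), -(1 - 0.25) * 70^2 / 100^2)
})

test_that("windowed analytic RI matches brute-force quadrature of the geometry", {
  specs <- list(archetype_spec("power_law", rmax = 2, gamma = 2),
                archetype_spec("saturation", rmax = 1.5, K = 40),
                archetype_spec("pcrit_regulator", rmax = 2, pcrit_pct = 30),
                archetype_spec("suppressor", rmax = 2, threshold_pct = 60,
                               suppression_fraction = 0.3))
  for (spec in specs) for (win in list(c(0, 100), c(5, 90), c(35, 80))) {
    lo <- win[1]; hi <- win[2]
    x <- seq(lo, hi, length.out = 4e5 + 1)
    y <- archetype_rate(spec, x)
    a_c <- sum((y[-1] + y[-length(y)]) / 2 * diff(x))
    y_hi <- archetype_rate(spec, hi)
    a_f <- y_hi / hi * (hi^2 - lo^2) / 2
    a_r <- max(y) * (hi - lo)
    oracle <- if (a_c >= a_f) (a_c - a_f) / (a_r - a_f) else (a_c - a_f) / a_f
    # 1e-5: the suppressor's jump limits trapezoid convergence at the step
    expect_equal(true_ri(spec, lo, hi), oracle, tolerance = 1e-5,
                 label = paste(spec$kind, lo, hi))
  }
})

test_that("sampled profiles are seeded-deterministic and oracle-consistent", {
  spec <- archetype_spec("power_law", rmax = 2, gamma = 1)
  p1 <- sample_rate_profile(spec, 50, noise_model(rate_sd = 0.1, seed = 99))
  p2 <- sample_rate_profile(spec, 50, noise_model(rate_sd = 0.1, seed = 99))
  expect_identical(p1, p2)
  p3 <- sample_rate_profile(spec, 50, noise_model(rate_sd = 0.1, seed = 100))
  expect_false(identical(p1$rate_mlO2_h_gww, p3$rate_mlO2_h_gww))
  clean <- sample_rate_profile(spec, 200)
  expect_equal(compute_ri(clean)$ri, 0, tolerance = 0.01)
})

test_that("noisy conformer replicates centre on RI = 0", {
  spec <- archetype_spec("power_law", rmax = 2, gamma = 1)
  set.seed(31)
  ris <- vapply(1:20, function(i) {
    p <- sample_rate_profile(spec, 60,
                             noise_model(rate_sd = 0.1,
                                         seed = sample.int(1e6, 1)))
    compute_ri(p, smooth = TRUE, span = 0.5)$ri
  }, numeric(1))
  expect_lt(abs(median(ris)), 0.05)
})

test_that("constant-rate chambers desaturate linearly at -R W / V", {
  spec <- archetype_spec("power_law", rmax = 2, gamma = 0)
  meta <- trace_metadata("lin", temperature_C = 10, salinity_psu = 35,
                         chamber_volume_mL = 20, weight_mg = 20,
                         sampling_interval_s = 15)
  tr <- simulate_trace(spec, meta, duration_h = 2)
  ctx <- unit_context(10, 35)
  slope_ml_per_h <- 2 * 0.02 / 0.02          # rmax * W(g) / V(L), mL/L/h
  slope_pct_per_s <- slope_ml_per_h / o2_saturation(ctx, "mlO2_per_L") *
    100 / 3600
  expected <- 100 - slope_pct_per_s * tr$time_s
  expect_equal(tr$do_pct_airsat, expected, tolerance = 1e-9)
})

test_that("conformer chambers decay exponentially to 0.1%", {
  spec <- archetype_spec("power_law", rmax = 2, gamma = 1)
  meta <- trace_metadata("exp", temperature_C = 10, salinity_psu = 35,
                         chamber_volume_mL = 20, weight_mg = 20,
                         sampling_interval_s = 15)
  tr <- simulate_trace(spec, meta, duration_h = 3)
  ctx <- unit_context(10, 35)
  k_per_h <- 2 * 0.02 / 0.02 / o2_saturation(ctx, "mlO2_per_L")
  expected <- 100 * exp(-k_per_h * tr$time_s / 3600)
  expect_lt(max(abs(tr$do_pct_airsat / expected - 1)), 0.001)
})

test_that("blank chambers show pure background drift", {
  meta <- trace_metadata("bl", temperature_C = 10, is_blank = TRUE,
                         sampling_interval_s = 15)
  spec <- archetype_spec("power_law")
  tr <- simulate_trace(spec, meta, noise_model(blank_slope_pct_per_h = 0.8),
                       duration_h = 2)
  expect_equal(tr$do_pct_airsat, 100 - 0.8 * tr$time_s / 3600,
               tolerance = 1e-9)
  still <- simulate_trace(spec, meta, duration_h = 1)
  expect_equal(unique(still$do_pct_airsat), 100)
})

test_that("oxygen consumed equals the time-integral of the specified rate", {
  spec <- archetype_spec("saturation", rmax = 2, K = 30)
  meta <- trace_metadata("cons", temperature_C = 10, salinity_psu = 35,
                         chamber_volume_mL = 20, weight_mg = 20,
                         sampling_interval_s = 15)
  tr <- simulate_trace(spec, meta, duration_h = 6)
  ctx <- unit_context(10, 35)
  c_sat <- o2_saturation(ctx, "mlO2_per_L")
  consumed_ml <- (tr$do_pct_airsat[1] - tr$do_pct_airsat[length(tr$time_s)]) /
    100 * c_sat * 0.02
  rates_ml_per_h <- archetype_rate(spec, tr$do_pct_airsat) * 0.02
  n <- length(tr$time_s)
  integral_ml <- sum((rates_ml_per_h[-1] + rates_ml_per_h[-n]) / 2 *
                       diff(tr$time_s) / 3600)
  expect_equal(consumed_ml, integral_ml, tolerance = 0.01)
})

test_that("halving the Euler step changes the trace by less than 0.1%", {
  spec <- archetype_spec("power_law", rmax = 2, gamma = 1)
  meta <- trace_metadata("cv", temperature_C = 10, chamber_volume_mL = 20,
                         weight_mg = 20, sampling_interval_s = 15)
  t1 <- simulate_trace(spec, meta, duration_h = 3)
  t2 <- simulate_trace(spec, meta, duration_h = 3, euler_substeps = 2L)
  expect_lt(max(abs(t1$do_pct_airsat / t2$do_pct_airsat - 1)), 0.001)
})

test_that("truncation floors the trace instead of going anoxic", {
  spec <- archetype_spec("power_law", rmax = 4, gamma = 0)
  meta <- trace_metadata("tr", temperature_C = 10, chamber_volume_mL = 20,
                         weight_mg = 50, sampling_interval_s = 15)
  expect_message(tr <- simulate_trace(spec, meta, duration_h = 6,
                                      floor_pct = 1), "truncated")
  expect_gte(min(tr$do_pct_airsat), 1)
  expect_lt(max(tr$time_s), 6 * 3600)
})

test_that("make_study produces traces plus a matching truth table", {
  design <- list(
    reg = list(spec = archetype_spec("pcrit_regulator", rmax = 2,
                                     pcrit_pct = 25), n = 5),
    conf = list(spec = archetype_spec("power_law", rmax = 2, gamma = 1),
                n = 5, duration_h = 10),
    sup = list(spec = archetype_spec("suppressor", rmax = 2), n = 5,
               duration_h = 10))
  study <- suppressMessages(make_study(design, noise_model(seed = 4)))
  expect_length(study$traces, 15)
  expect_equal(nrow(study$truth), 15)
  expect_setequal(study$truth$trace_id, names(study$traces))
  expect_equal(study$truth$true_ri[study$truth$group == "conf"], rep(0, 5))
  # same seed reproduces the same study byte for byte
  study2 <- suppressMessages(make_study(design, noise_model(seed = 4)))
  expect_identical(study$traces, study2$traces)
  blanks <- suppressMessages(
    make_study(design["reg"], noise_model(seed = 4), n_blanks = 2))
  expect_length(blanks$traces, 7)
  expect_true(blanks$traces$reg_blank01$metadata$is_blank)
})
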