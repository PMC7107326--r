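make_trace <- function(minutes, do_fn, dt = 15, id = "t") {
  t <- seq(0, minutes * 60, by = dt)
  respirometry_trace(t, do_fn(t),
                     trace_metadata(id, temperature_C = 10, weight_mg = 20,
                                    sampling_interval_s = dt))
}

test_that("acclimation trim discards the initial segment and re-zeroes time", {
  tr <- make_trace(60, function(t) 100 - t / 3600 * 30)
  out <- trim_acclimation(tr, 30)
  expect_equal(max(out$time_s), 30 * 60)
  expect_equal(out$time_s[1], 0)
  expect_equal(out$do_pct_airsat[1], 85)          # oxygen at the 30-min mark
  expect_identical(trim_acclimation(tr, 0), tr)   # trim 0 is the identity
  expect_error(trim_acclimation(make_trace(20, function(t) 100 - t / 1e4), 30),
               "shorter than")
})

test_that("oxygen unit conversions match published solubility values", {
  ctx <- unit_context(10, 35, 1)
  # frozen from an independent transcription of the Benson-Krause and
  # Green-Carritt equations at 10 degC, 35 psu, 1 atm
  expect_equal(o2_saturation(ctx, "mg_per_L"), 9.0243, tolerance = 1e-4)
  expect_equal(o2_saturation(ctx, "mlO2_per_L"), 6.3149, tolerance = 1e-4)
  expect_equal(convert_oxygen_units(100, "pct_airsat", "kPa", ctx),
               20.9715, tolerance = 1e-4)
  expect_equal(convert_oxygen_units(100, "pct_airsat", "mg_per_L", ctx),
               9.0243, tolerance = 1e-4)
})

test_that("unit conversion is a consistent invertible mapping", {
  ctx <- unit_context(15, 34)
  units <- c("pct_airsat", "kPa", "mlO2_per_L", "mg_per_L")
  for (u in units) {
    expect_equal(convert_oxygen_units(76, u, u, ctx), 76)   # identity
    expect_equal(convert_oxygen_units(0, "pct_airsat", u, ctx), 0)
    for (v in units) {
      x <- convert_oxygen_units(76, u, v, ctx)
      expect_equal(convert_oxygen_units(x, v, u, ctx), 76,
                   tolerance = 1e-9)
    }
  }
  expect_error(convert_oxygen_units(1, "torr", "kPa", ctx), "unknown unit")
  expect_error(convert_oxygen_units(-1, "kPa", "kPa", ctx), ">= 0")
})

test_that("paper-scale oxygen equivalences are reproduced", {
  # 76% air saturation is about 16 kPa in cold seawater
  ctx <- unit_context(2, 35)
  expect_equal(convert_oxygen_units(76, "pct_airsat", "kPa", ctx), 16,
               tolerance = 0.02)
})

test_that("sliding OLS recovers exact slopes on noiseless traces", {
  lin <- make_trace(60, function(t) 100 - 50 * t / 3600)
  w <- derive_rates(lin, window_s = 300)
  expect_true(all(abs(w$slope_pct_per_s + 50 / 3600) < 1e-12))
  flat <- make_trace(60, function(t) rep(80, length(t)))
  expect_true(all(abs(derive_rates(flat)$slope_pct_per_s) < 1e-12))
})

test_that("windowed slopes reproduce a piecewise decline away from the break", {
  # fast (-0.02 %/s) for 30 min, then slow (-0.005 %/s)
  brk <- 1800
  fn <- function(t) 100 - ifelse(t <= brk, 0.02 * t,
                                 0.02 * brk + 0.005 * (t - brk))
  w <- derive_rates(make_trace(60, fn), window_s = 300)
  early <- w$t_mid_s < brk - 150
  late <- w$t_mid_s > brk + 150
  expect_true(all(abs(w$slope_pct_per_s[early] + 0.02) < 1e-10))
  expect_true(all(abs(w$slope_pct_per_s[late] + 0.005) < 1e-10))
})

test_that("rate derivation tracks a known smooth response within 1%", {
  spec <- archetype_spec("power_law", rmax = 2, gamma = 1)
  meta <- trace_metadata("cf", temperature_C = 10, weight_mg = 20,
                         sampling_interval_s = 15)
  tr <- simulate_trace(spec, meta, duration_h = 6)
  w <- derive_rates(tr, window_s = 300)
  prof <- to_mass_specific(w, meta, unit_context(10, 35))
  interior <- seq_along(prof$do_pct_airsat)
  interior <- interior[-c(1, length(interior))]
  rel_err <- abs(prof$rate_mlO2_h_gww[interior] /
                   archetype_rate(spec, prof$do_pct_airsat[interior]) - 1)
  expect_lt(max(rel_err), 0.01)
})

test_that("blank correction subtracts interpolated background demand", {
  w <- data.frame(t_mid_s = c(100, 200, 300), do_mid_pct = c(90, 80, 70),
                  slope_pct_per_s = c(-0.010, -0.010, -0.010), n_points = 20)
  expect_equal(blank_correct(w, constant_blank_slope = 0)$slope_pct_per_s,
               w$slope_pct_per_s)
  expect_equal(blank_correct(w, constant_blank_slope = -0.002)$slope_pct_per_s,
               rep(-0.008, 3))
  b1 <- data.frame(t_mid_s = c(0, 400), do_mid_pct = c(99, 98),
                   slope_pct_per_s = c(-0.002, -0.002), n_points = 20)
  b2 <- data.frame(t_mid_s = c(0, 400), do_mid_pct = c(99, 98),
                   slope_pct_per_s = c(-0.004, -0.004), n_points = 20)
  expect_equal(blank_correct(w, list(b1, b2))$slope_pct_per_s,
               rep(-0.007, 3))
  # over-correction capped at zero (oxygen cannot be produced)
  expect_message(
    out <- blank_correct(w, constant_blank_slope = -0.02), "capped")
  expect_equal(out$slope_pct_per_s, rep(0, 3))
  expect_error(blank_correct(w), "no blanks")
  expect_equal(blank_correct(w, disabled = TRUE), w)
})

test_that("mass-specific conversion follows the chamber arithmetic", {
  ctx <- unit_context(10, 35)
  ml_per_pct <- o2_saturation(ctx, "mlO2_per_L") / 100
  # decline of 2.5 mL O2 / L over one hour, 20 mL chamber, 0.1 g animal
  slope <- -(2.5 / ml_per_pct) / 3600
  w <- data.frame(t_mid_s = 1:3 * 100, do_mid_pct = c(90, 80, 70),
                  slope_pct_per_s = rep(slope, 3), n_points = 20)
  meta <- trace_metadata("m", chamber_volume_mL = 20, weight_mg = 100)
  prof <- to_mass_specific(w, meta, ctx)
  expect_equal(prof$rate_mlO2_h_gww, rep(0.5, 3))
  w0 <- w; w0$slope_pct_per_s <- 0
  expect_equal(to_mass_specific(w0, meta, ctx)$rate_mlO2_h_gww, rep(0, 3))
  meta250 <- trace_metadata("m", chamber_volume_mL = 250, weight_mg = 100)
  expect_equal(to_mass_specific(w, meta250, ctx)$rate_mlO2_h_gww,
               rep(0.5 * 12.5, 3))
  meta_na <- trace_metadata("m", is_blank = TRUE)
  expect_error(to_mass_specific(w, meta_na, ctx), "missing weight")
})

test_that("mass-specific rate is invariant to volume-doubling with slope-halving", {
  ctx <- unit_context(10, 35)
  w <- data.frame(t_mid_s = 100, do_mid_pct = 90,
                  slope_pct_per_s = -0.01, n_points = 20)
  w2 <- w; w2$slope_pct_per_s <- -0.005
  m1 <- trace_metadata("a", chamber_volume_mL = 20, weight_mg = 50)
  m2 <- trace_metadata("a", chamber_volume_mL = 40, weight_mg = 50)
  expect_equal(to_mass_specific(w, m1, ctx)$rate_mlO2_h_gww,
               to_mass_specific(w2, m2, ctx)$rate_mlO2_h_gww)
})

test_that("dry-to-wet conversion is configuration-driven", {
  expect_equal(dry_to_wet(10, list(form = "identity")), 10,
               ignore_attr = TRUE)
  expect_equal(dry_to_wet(10, list(form = "ratio", dry_fraction = 0.25)), 40,
               ignore_attr = TRUE)
  expect_equal(dry_to_wet(100, list(form = "loglinear", a = 0.6, b = 1)),
               10^0.6 * 100, ignore_attr = TRUE)
  expect_error(dry_to_wet(10), "no dry-to-wet coefficients")
  expect_error(dry_to_wet(10, list(form = "ratio")), "dry_fraction")
})

test_that("QC passes only profiles whose oxygen halves, inclusively", {
  p <- function(lo) rate_profile("q", c(100, 75, lo), c(1, 1, 1))
  expect_true(qc_filter(p(40))$qc_pass)
  expect_false(qc_filter(p(60))$qc_pass)
  expect_match(qc_filter(p(60))$qc_reason, "dropped")
  expect_true(qc_filter(p(50))$qc_pass)   # <= is inclusive
})

test_that("QC depends only on the min/start ratio, not the scale", {
  for (s in c(0.5, 1, 7)) {
    p <- rate_profile("q", s * c(100, 70, 49), c(1, 1, 1))
    expect_true(qc_filter(p)$qc_pass)
    p2 <- rate_profile("q", s * c(100, 70, 51), c(1, 1, 1))
    expect_false(qc_filter(p2)$qc_pass)
  }
})
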