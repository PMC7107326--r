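#' Unit context for oxygen conversions
#'
#' Physical conditions needed to move between oxygen units: temperature,
#' salinity and barometric pressure.
#'
#' @param temperature_C Water temperature, degrees Celsius, in \[-2, 40\].
#' @param salinity_psu Practical salinity, in \[0, 42\].
#' @param pressure_atm Barometric pressure in atmospheres (default 1).
#' @return A `unit_context` list.
#' @export
unit_context <- function(temperature_C, salinity_psu = 35, pressure_atm = 1) {
  if (!is.finite(temperature_C) || temperature_C < -2 || temperature_C > 40)
    stop("temperature_C must be in [-2, 40]", call. = FALSE)
  if (!is.finite(salinity_psu) || salinity_psu < 0 || salinity_psu > 42)
    stop("salinity_psu must be in [0, 42]", call. = FALSE)
  structure(list(temperature_C = temperature_C, salinity_psu = salinity_psu,
                 pressure_atm = pressure_atm), class = "unit_context")
}

# Saturated water vapor pressure over seawater (atm); Green & Carritt form.
.vapor_pressure_atm <- function(temperature_C, salinity_psu) {
  TK <- temperature_C + 273.15
  exp(24.4543 - 67.4509 * (100 / TK) - 4.8489 * log(TK / 100) -
        0.000544 * salinity_psu)
}

#' Oxygen solubility at 100% air saturation
#'
#' Benson-Krause equilibrium oxygen concentration of water in contact with
#' water-saturated air, with salinity term, corrected to the stated
#' barometric pressure. Used as the bridge between percent air saturation
#' and concentration units.
#'
#' @param ctx A [unit_context()].
#' @param unit `"mg_per_L"` or `"mlO2_per_L"`.
#' @return Saturation concentration in the requested unit.
#' @export
o2_saturation <- function(ctx, unit = c("mg_per_L", "mlO2_per_L")) {
  unit <- match.arg(unit)
  TK <- ctx$temperature_C + 273.15
  S <- ctx$salinity_psu
  lnC <- -139.34411 + 1.575701e5 / TK - 6.642308e7 / TK^2 +
    1.2438e10 / TK^3 - 8.621949e11 / TK^4 -
    S * (0.017674 - 10.754 / TK + 2140.7 / TK^2)
  c_mg <- exp(lnC)  # mg/L at 1 atm moist air
  pv <- .vapor_pressure_atm(ctx$temperature_C, S)
  t <- ctx$temperature_C
  theta <- 0.000975 - 1.426e-5 * t + 6.436e-8 * t^2
  P <- ctx$pressure_atm
  fp <- P * (1 - pv / P) * (1 - theta * P) / ((1 - pv) * (1 - theta))
  c_mg <- c_mg * fp
  if (unit == "mg_per_L") c_mg else c_mg / 1.42905
}

# Partial pressure of O2 (kPa) at 100% air saturation: mole fraction of O2
# in dry air times (barometric - vapor) pressure.
.po2_saturation_kPa <- function(ctx) {
  pv_kPa <- .vapor_pressure_atm(ctx$temperature_C, ctx$salinity_psu) * 101.325
  0.20946 * (ctx$pressure_atm * 101.325 - pv_kPa)
}

#' Convert dissolved-oxygen values between units
#'
#' Supported units: percent air saturation, kPa partial pressure, mL O2 per
#' litre and mg per litre. All conversions pass through the saturation value
#' of each unit at the context's temperature, salinity and pressure, so
#' round-trips are exact to machine precision.
#'
#' @param value Non-negative oxygen value(s).
#' @param from_unit,to_unit One of `"pct_airsat"`, `"kPa"`, `"mlO2_per_L"`,
#'   `"mg_per_L"`.
#' @param ctx A [unit_context()].
#' @return The converted value(s).
#' @export
convert_oxygen_units <- function(value, from_unit, to_unit, ctx) {
  units <- c("pct_airsat", "kPa", "mlO2_per_L", "mg_per_L")
  if (!from_unit %in% units) stop("unknown unit: ", from_unit, call. = FALSE)
  if (!to_unit %in% units) stop("unknown unit: ", to_unit, call. = FALSE)
  if (any(value < 0)) stop("oxygen value must be >= 0", call. = FALSE)
  if (from_unit == to_unit) return(value)
  sat <- function(u) switch(u,
    pct_airsat = 100,
    kPa = .po2_saturation_kPa(ctx),
    mlO2_per_L = o2_saturation(ctx, "mlO2_per_L"),
    mg_per_L = o2_saturation(ctx, "mg_per_L"))
  value / sat(from_unit) * sat(to_unit)
}

#' Discard the acclimation period of a trace
#'
#' Removes the initial chamber-acclimation segment (default the first 30
#' minutes) and re-zeroes time to the first retained sample.
#'
#' @param trace A [respirometry_trace()].
#' @param trim_min Minutes to discard from the start.
#' @return The trimmed trace.
#' @export
trim_acclimation <- function(trace, trim_min = 30) {
  stopifnot(inherits(trace, "respirometry_trace"))
  if (trim_min == 0) return(trace)
  cut_s <- trim_min * 60
  dur <- trace$time_s[length(trace$time_s)] - trace$time_s[1]
  if (dur <= cut_s)
    stop("validation error: trace '", trace$metadata$trace_id,
         "' shorter than the ", trim_min, "-min trim window", call. = FALSE)
  keep <- trace$time_s - trace$time_s[1] >= cut_s
  respirometry_trace(trace$time_s[keep] - trace$time_s[keep][1],
                     trace$do_pct_airsat[keep], trace$metadata)
}

#' Derive oxygen-decline slopes in sliding windows
#'
#' Estimates the instantaneous oxygen decline by ordinary-least-squares
#' regression of oxygen on time within a sliding window. This is the
#' standard way to obtain point respiration rates from densely sampled
#' closed-chamber optode traces.
#'
#' @param trace A (trimmed) [respirometry_trace()].
#' @param window_s Window width in seconds (default 300 = 5 min); must cover
#'   at least 3 sampling intervals.
#' @param step_s Advance between windows (default `window_s / 2`).
#' @return A data frame of rate windows: `t_mid_s`, `do_mid_pct`,
#'   `slope_pct_per_s`, `n_points`. Windows with fewer than 3 samples are
#'   skipped with a message.
#' @export
derive_rates <- function(trace, window_s = 300, step_s = window_s / 2) {
  stopifnot(inherits(trace, "respirometry_trace"))
  dt <- trace$metadata$sampling_interval_s
  if (window_s < 3 * dt)
    stop("window_s must cover at least 3 sampling intervals", call. = FALSE)
  t <- trace$time_s
  o <- trace$do_pct_airsat
  starts <- seq(t[1], t[length(t)] - window_s, by = step_s)
  if (length(starts) == 0) starts <- t[1]
  rows <- lapply(starts, function(s) {
    in_win <- t >= s & t <= s + window_s
    n <- sum(in_win)
    if (n < 3) {
      message("skipping window at t=", s, " s (", n, " points)")
      return(NULL)
    }
    tw <- t[in_win]; ow <- o[in_win]
    tc <- tw - mean(tw)
    slope <- sum(tc * ow) / sum(tc^2)
    data.frame(t_mid_s = mean(tw), do_mid_pct = mean(ow),
               slope_pct_per_s = slope, n_points = n)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no window contained 3 or more points", call. = FALSE)
  out
}

#' Subtract background (blank) oxygen demand
#'
#' Corrects animal-chamber decline slopes for bacterial oxygen demand
#' measured in animal-free blank chambers. The blank slope is interpolated
#' in time (blanks and animals desaturate at different speeds, so matching
#' is done on the clock, not on oxygen). When several blank window sets are
#' given their interpolated slopes are averaged. Corrected slopes are capped
#' at 0 from above: a chamber cannot produce oxygen, and cap events are
#' reported via a message.
#'
#' @param windows Rate-window data frame from [derive_rates()].
#' @param blank_windows One blank window data frame, a list of them, or
#'   `NULL` when `constant_blank_slope` is used.
#' @param constant_blank_slope A single blank slope (%/s) applied uniformly,
#'   as an alternative to measured blanks.
#' @param disabled Set `TRUE` to pass slopes through uncorrected.
#' @return The windows with corrected `slope_pct_per_s`.
#' @export
blank_correct <- function(windows, blank_windows = NULL,
                          constant_blank_slope = NULL, disabled = FALSE) {
  if (disabled) return(windows)
  if (is.null(blank_windows) && is.null(constant_blank_slope))
    stop("no blanks and no configured blank rate; set disabled = TRUE to ",
         "skip correction", call. = FALSE)
  if (!is.null(constant_blank_slope)) {
    bl <- rep(constant_blank_slope, nrow(windows))
  } else {
    if (is.data.frame(blank_windows)) blank_windows <- list(blank_windows)
    per_blank <- vapply(blank_windows, function(bw) {
      stats::approx(bw$t_mid_s, bw$slope_pct_per_s, xout = windows$t_mid_s,
                    rule = 2)$y
    }, numeric(nrow(windows)))
    bl <- rowMeans(matrix(per_blank, nrow = nrow(windows)))
  }
  corrected <- windows$slope_pct_per_s - bl
  capped <- corrected > 0
  if (any(capped)) {
    message(sum(capped), " corrected slope(s) > 0 capped at 0")
    corrected[capped] <- 0
  }
  windows$slope_pct_per_s <- corrected
  windows
}

#' Convert decline slopes to a mass-specific rate profile
#'
#' Turns oxygen-decline slopes (% air saturation per second) into
#' mass-specific respiration rates in mL O2 h^-1 g wet weight^-1:
#' `rate = (-slope in mL O2 L^-1 s^-1) * chamber volume (L) * 3600 / wet
#' weight (g)`. The oxygen axis stays in % air saturation.
#'
#' @param windows Rate-window data frame (blank-corrected).
#' @param meta [trace_metadata()] with chamber volume and wet weight.
#' @param ctx [unit_context()] used for the % air saturation to
#'   concentration conversion.
#' @return A [rate_profile()].
#' @export
to_mass_specific <- function(windows, meta, ctx) {
  if (!is.finite(meta$weight_mg))
    stop("missing weight for trace '", meta$trace_id, "'", call. = FALSE)
  if (meta$weight_basis != "wet")
    stop("weight basis is '", meta$weight_basis,
         "'; convert with dry_to_wet() first", call. = FALSE)
  ml_per_pct <- o2_saturation(ctx, "mlO2_per_L") / 100
  slope_ml_L_s <- windows$slope_pct_per_s * ml_per_pct
  rate <- (-slope_ml_L_s) * (meta$chamber_volume_mL / 1000) * 3600 /
    (meta$weight_mg / 1000)
  rate_profile(meta$trace_id, windows$do_mid_pct, rate,
               species = meta$species, temperature_C = meta$temperature_C)
}

#' Convert dry weight to wet weight
#'
#' Applies a configured dry-to-wet conversion; the coefficients come from
#' the study configuration, never from a built-in constant. Supported forms:
#' `identity` (wet = dry), `ratio` (wet = dry / dry_fraction), and
#' `loglinear` (log10 wet = a + b log10 dry, weights in mg).
#'
#' @param weight_dry_mg Dry weight in mg.
#' @param coeff Named list: `form` plus `dry_fraction` (ratio) or `a`, `b`
#'   (loglinear).
#' @return Wet weight in mg, with the coefficient provenance attached as
#'   attribute `"conversion"`.
#' @export
dry_to_wet <- function(weight_dry_mg, coeff) {
  if (missing(coeff) || is.null(coeff) || is.null(coeff$form))
    stop("dry-basis weight present but no dry-to-wet coefficients ",
         "configured; supply coeff = list(form = ..., ...)", call. = FALSE)
  wet <- switch(coeff$form,
    identity = weight_dry_mg,
    ratio = {
      if (is.null(coeff$dry_fraction))
        stop("ratio form needs dry_fraction", call. = FALSE)
      weight_dry_mg / coeff$dry_fraction
    },
    loglinear = {
      if (is.null(coeff$a) || is.null(coeff$b))
        stop("loglinear form needs a and b", call. = FALSE)
      10^(coeff$a + coeff$b * log10(weight_dry_mg))
    },
    stop("unknown conversion form: ", coeff$form, call. = FALSE))
  attr(wet, "conversion") <- coeff
  wet
}

#' Flag profiles whose oxygen range is too shallow
#'
#' A profile enters the Regulation Index statistics only when the
#' experimental oxygen concentration dropped to at or below a fraction
#' (default 50%) of the run's starting concentration. The check depends
#' only on the min/start ratio, never on absolute units. Failing profiles
#' are retained (flagged), not dropped; enforcement happens downstream.
#'
#' @param profile A [rate_profile()].
#' @param max_min_frac Highest admissible min/start oxygen ratio
#'   (inclusive; default 0.5).
#' @return The profile with `qc_pass` and `qc_reason` set.
#' @export
qc_filter <- function(profile, max_min_frac = 0.5) {
  stopifnot(inherits(profile, "rate_profile"))
  start <- max(profile$do_pct_airsat)
  lo <- min(profile$do_pct_airsat)
  if (lo <= max_min_frac * start) {
    profile$qc_pass <- TRUE
    profile$qc_reason <- ""
  } else {
    profile$qc_pass <- FALSE
    profile$qc_reason <- sprintf(
      "oxygen only dropped to %.1f%% of start (threshold %.0f%%)",
      100 * lo / start, 100 * max_min_frac)
  }
  profile
}
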