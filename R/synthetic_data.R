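#' Parametric respiration-response archetype
#'
#' Formalises the verbal strategy taxonomy (oxyconformity, oxyregulation,
#' metabolic suppression) as parametric rate-vs-oxygen shapes with
#' analytically known Regulation Index, for use as simulation ground truth:
#' \itemize{
#'   \item `power_law`: rate = rmax (DO/do_max)^gamma. gamma = 0 is a
#'     perfect regulator (RI = 1), gamma = 1 a perfect conformer (RI = 0),
#'     gamma > 1 bends below the conformity line (RI < 0).
#'   \item `saturation`: rate = rmax DO / (K + DO), a hyperbolic
#'     oxyregulator.
#'   \item `pcrit_regulator`: rate = rmax above `pcrit_pct`, declining
#'     proportionally to zero below it - the classic breakpoint regulator.
#'   \item `suppressor`: rate on the conformity line above `threshold_pct`,
#'     dropped to `suppression_fraction` of that line below it - active
#'     metabolic suppression, guaranteeing a negative RI.
#' }
#'
#' @param kind Archetype name.
#' @param rmax Maximum mass-specific rate, mL O2 h^-1 g wet weight^-1.
#' @param gamma,K,pcrit_pct,threshold_pct,suppression_fraction Kind-specific
#'   shape parameters (see above); oxygen thresholds in % air saturation.
#' @param do_max Oxygen value where the response reaches `rmax`
#'   (% air saturation, default 100).
#' @return An `archetype_spec` list.
#' @export
archetype_spec <- function(kind = c("power_law", "saturation",
                                    "pcrit_regulator", "suppressor"),
                           rmax = 1, gamma = 1, K = 25, pcrit_pct = 25,
                           threshold_pct = 70, suppression_fraction = 0.25,
                           do_max = 100) {
  kind <- match.arg(kind)
  stopifnot(rmax > 0, do_max > 0)
  if (kind == "power_law" && gamma < 0) stop("gamma must be >= 0")
  if (kind == "saturation" && K <= 0) stop("K must be > 0")
  if (kind == "pcrit_regulator" &&
      !(pcrit_pct > 0 && pcrit_pct < do_max))
    stop("pcrit_pct must be in (0, do_max)")
  if (kind == "suppressor" &&
      !(threshold_pct > 0 && threshold_pct < do_max &&
          suppression_fraction > 0 && suppression_fraction < 1))
    stop("need 0 < threshold_pct < do_max and suppression_fraction in (0,1)")
  structure(list(kind = kind, rmax = rmax, gamma = gamma, K = K,
                 pcrit_pct = pcrit_pct, threshold_pct = threshold_pct,
                 suppression_fraction = suppression_fraction,
                 do_max = do_max),
            class = "archetype_spec")
}

#' Evaluate an archetype's rate response
#'
#' @param spec An [archetype_spec()].
#' @param do_pct Oxygen values, % air saturation.
#' @return Mass-specific rates at `do_pct`.
#' @export
archetype_rate <- function(spec, do_pct) {
  with(spec, switch(kind,
    power_law = rmax * (pmax(do_pct, 0) / do_max)^gamma,
    saturation = rmax * do_pct / (K + do_pct),
    pcrit_regulator = ifelse(do_pct >= pcrit_pct, rmax,
                             rmax * do_pct / pcrit_pct),
    suppressor = {
      conf <- rmax * do_pct / do_max
      ifelse(do_pct >= threshold_pct, conf, suppression_fraction * conf)
    }))
}

# Exact integral of the archetype response over [lo, hi] (piecewise closed
# forms; the oracle must stay independent of the quadrature it checks).
.archetype_auc <- function(spec, lo, hi) {
  with(spec, switch(kind,
    power_law = rmax / do_max^gamma * (hi^(gamma + 1) - lo^(gamma + 1)) /
      (gamma + 1),
    saturation = rmax * ((hi - lo) - K * log((K + hi) / (K + lo))),
    pcrit_regulator = {
      seg_lo <- function(a, b) rmax * (b^2 - a^2) / (2 * pcrit_pct)
      if (hi <= pcrit_pct) seg_lo(lo, hi)
      else if (lo >= pcrit_pct) rmax * (hi - lo)
      else seg_lo(lo, pcrit_pct) + rmax * (hi - pcrit_pct)
    },
    suppressor = {
      seg <- function(a, b, f) f * rmax * (b^2 - a^2) / (2 * do_max)
      if (hi <= threshold_pct) seg(lo, hi, suppression_fraction)
      else if (lo >= threshold_pct) seg(lo, hi, 1)
      else seg(lo, threshold_pct, suppression_fraction) +
        seg(threshold_pct, hi, 1)
    }))
}

#' Analytic Regulation Index of an archetype
#'
#' Closed-form RI of the archetype response over an oxygen window
#' `[lo, hi]`, using exactly the geometry of the RI definition: conformity
#' line through the origin anchored at the response value at `hi`,
#' regulation line at the response maximum over the window, areas by exact
#' integration, branch by the sign of the net area. With the default full
#' window `[0, do_max]` the familiar closed forms emerge, e.g.
#' `2/(gamma+1) - 1` for the power-law family.
#'
#' @param spec An [archetype_spec()].
#' @param lo,hi Oxygen window, % air saturation (defaults 0 and
#'   `spec$do_max`).
#' @return The analytic RI.
#' @export
true_ri <- function(spec, lo = 0, hi = spec$do_max) {
  stopifnot(lo >= 0, hi > lo)
  a_c <- .archetype_auc(spec, lo, hi)
  y_hi <- archetype_rate(spec, hi)
  a_f <- y_hi / hi * (hi^2 - lo^2) / 2
  # all archetypes are nondecreasing in oxygen, so the window max is at hi;
  # except pcrit/suppressor plateaus which equal rmax at hi anyway
  level <- max(archetype_rate(spec, c(lo, hi)))
  a_r <- level * (hi - lo)
  if (a_c >= a_f) (a_c - a_f) / (a_r - a_f) else (a_c - a_f) / a_f
}

#' Measurement noise model
#'
#' Where randomness enters the simulator: additive Gaussian noise on oxygen
#' sensor readings, a background (bacterial) oxygen drift in the chamber,
#' and - for directly sampled rate profiles - additive Gaussian noise on
#' rates. All randomness flows from the one `seed`.
#'
#' @param sensor_sd_pct SD of sensor noise on oxygen readings, % air
#'   saturation.
#' @param blank_slope_pct_per_h Background oxygen consumption, % air
#'   saturation per hour (applied to traces, including blanks).
#' @param rate_sd SD of additive rate noise used by
#'   [sample_rate_profile()], mL O2 h^-1 g^-1.
#' @param seed Integer RNG seed.
#' @return A `noise_model` list.
#' @export
noise_model <- function(sensor_sd_pct = 0, blank_slope_pct_per_h = 0,
                        rate_sd = 0, seed = 1L) {
  stopifnot(sensor_sd_pct >= 0, rate_sd >= 0)
  structure(list(sensor_sd_pct = sensor_sd_pct,
                 blank_slope_pct_per_h = blank_slope_pct_per_h,
                 rate_sd = rate_sd, seed = as.integer(seed)),
            class = "noise_model")
}

#' Sample a rate profile directly from an archetype
#'
#' Draws (oxygen, rate) points on a descending oxygen grid from the
#' archetype response plus seeded Gaussian rate noise - the profile-level
#' shortcut past the trace simulation.
#'
#' @param spec An [archetype_spec()].
#' @param n_points Number of points (>= 3).
#' @param noise A [noise_model()]; `rate_sd` and `seed` are used.
#' @param floor_pct Lowest oxygen on the grid (default 0).
#' @param trace_id Identifier for the resulting profile.
#' @param species,temperature_C Group labels.
#' @return A [rate_profile()].
#' @export
sample_rate_profile <- function(spec, n_points, noise = noise_model(),
                                floor_pct = 0, trace_id = "synthetic",
                                species = NA_character_,
                                temperature_C = NA_real_) {
  stopifnot(n_points >= 3)
  do <- seq(spec$do_max, floor_pct, length.out = n_points)
  rate <- archetype_rate(spec, do)
  if (noise$rate_sd > 0) {
    set.seed(noise$seed)
    rate <- rate + stats::rnorm(n_points, sd = noise$rate_sd)
    rate <- pmax(rate, 0)  # physical non-negativity, as enforced upstream
  }
  rate_profile(trace_id, do, rate, species = species,
               temperature_C = temperature_C)
}

#' Simulate a closed-chamber respirometry trace
#'
#' Forward-Euler integration of the chamber oxygen balance
#' `dC/dt = -R(C) W / V - drift`, with `C` the oxygen concentration
#' (mL O2 per L, converted to % air saturation for output), `R` the
#' archetype's mass-specific rate at the current saturation, `W` the wet
#' weight and `V` the chamber volume. The step is the sensor sampling
#' interval. The trace starts at `start_pct` and includes the initial
#' acclimation segment that [trim_acclimation()] later discards; seeded
#' sensor noise is added to the readings. If oxygen would fall below
#' `floor_pct` the trace is truncated there with a message.
#'
#' @param spec An [archetype_spec()]; ignored for blank chambers.
#' @param meta [trace_metadata()] (volume, weight, sampling interval,
#'   temperature, salinity; `is_blank` simulates an animal-free chamber).
#' @param noise A [noise_model()].
#' @param duration_h Run length in hours.
#' @param start_pct Initial oxygen, % air saturation.
#' @param floor_pct Truncation floor, % air saturation.
#' @param euler_substeps Euler substeps per sampling interval (default 1;
#'   raise to check convergence).
#' @return A [respirometry_trace()].
#' @export
simulate_trace <- function(spec, meta, noise = noise_model(),
                           duration_h = 8, start_pct = 100,
                           floor_pct = 0.5, euler_substeps = 1L) {
  stopifnot(inherits(meta, "trace_metadata"))
  ctx <- unit_context(
    temperature_C = if (is.finite(meta$temperature_C)) meta$temperature_C
                    else 10,
    salinity_psu = if (is.finite(meta$salinity_psu)) meta$salinity_psu
                   else 35)
  c_sat <- o2_saturation(ctx, "mlO2_per_L")
  dt <- meta$sampling_interval_s
  n <- floor(duration_h * 3600 / dt) + 1
  w_g <- if (meta$is_blank) 0 else meta$weight_mg / 1000
  v_l <- meta$chamber_volume_mL / 1000
  drift_ml_per_s <- noise$blank_slope_pct_per_h * c_sat / 100 / 3600
  time_s <- (seq_len(n) - 1) * dt
  pct <- numeric(n)
  pct[1] <- start_pct
  C <- start_pct / 100 * c_sat
  h <- dt / euler_substeps
  truncated_at <- n
  for (i in seq_len(n - 1)) {
    for (s in seq_len(euler_substeps)) {
      r_animal <- if (w_g > 0)
        archetype_rate(spec, C / c_sat * 100) * w_g / v_l / 3600 else 0
      C <- C - h * (r_animal + drift_ml_per_s)
    }
    if (C / c_sat * 100 < floor_pct) {
      truncated_at <- i
      message("trace '", meta$trace_id, "' truncated at t = ",
              time_s[i], " s (oxygen floor)")
      break
    }
    pct[i + 1] <- C / c_sat * 100
  }
  time_s <- time_s[seq_len(truncated_at)]
  pct <- pct[seq_len(truncated_at)]
  if (noise$sensor_sd_pct > 0) {
    set.seed(noise$seed)
    pct <- pct + stats::rnorm(length(pct), sd = noise$sensor_sd_pct)
  }
  pct <- pmin(pmax(pct, 0), 110)
  respirometry_trace(time_s, pct, meta)
}

#' Generate a full synthetic study with known truth
#'
#' Builds a multi-group study shaped like a comparative respirometry
#' design: for each group, `n` individual traces simulated from the group's
#' archetype, plus optional blank chambers, and a truth table holding every
#' individual's analytic RI (full-range closed form) and designed strategy.
#'
#' @param design Named list of groups, each a list with elements `spec`
#'   (an [archetype_spec()]), `n` (individuals), and optionally `species`,
#'   `temperature_C`, `weight_mg`, `chamber_volume_mL`, `duration_h`.
#' @param noise A [noise_model()]; per-individual seeds are derived from
#'   its `seed`.
#' @param n_blanks Blank chambers simulated per group.
#' @param sampling_interval_s Sensor interval for all traces.
#' @return List with `traces` (named list of traces, blanks flagged in
#'   metadata) and `truth` (data frame: `trace_id`, `group`, `species`,
#'   `temperature_C`, `kind`, `true_ri`).
#' @export
make_study <- function(design, noise = noise_model(), n_blanks = 0,
                       sampling_interval_s = 15) {
  stopifnot(length(design) >= 1)
  set.seed(noise$seed)
  traces <- list()
  truth <- list()
  for (g in names(design)) {
    d <- design[[g]]
    species <- d$species %||% g
    temp <- d$temperature_C %||% 10
    for (i in seq_len(d$n)) {
      id <- sprintf("%s_%02d", g, i)
      meta <- trace_metadata(id, species = species, temperature_C = temp,
                             chamber_volume_mL = d$chamber_volume_mL %||% 20,
                             weight_mg = d$weight_mg %||% 20,
                             sampling_interval_s = sampling_interval_s)
      sub <- noise
      sub$seed <- sample.int(.Machine$integer.max, 1)
      traces[[id]] <- simulate_trace(d$spec, meta, sub,
                                     duration_h = d$duration_h %||% 8)
      truth[[id]] <- data.frame(trace_id = id, group = g, species = species,
                                temperature_C = temp, kind = d$spec$kind,
                                true_ri = true_ri(d$spec),
                                stringsAsFactors = FALSE)
    }
    for (b in seq_len(n_blanks)) {
      id <- sprintf("%s_blank%02d", g, b)
      meta <- trace_metadata(id, species = species, temperature_C = temp,
                             chamber_volume_mL = d$chamber_volume_mL %||% 20,
                             is_blank = TRUE,
                             sampling_interval_s = sampling_interval_s)
      sub <- noise
      sub$seed <- sample.int(.Machine$integer.max, 1)
      traces[[id]] <- simulate_trace(d$spec, meta, sub,
                                     duration_h = d$duration_h %||% 8)
    }
  }
  list(traces = traces,
       truth = do.call(rbind, c(unname(truth), list(make.row.names = FALSE))))
}
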