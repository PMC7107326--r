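#!/usr/bin/env Rscript
# Stage 1: simulate a comparative hypoxia-tolerance study.
#
# Ten species x temperature groups (141 individuals in total, the scale of
# a multi-region euphausiid campaign) are drawn from respiration-response
# archetypes with analytically known Regulation Index: breakpoint and
# hyperbolic oxyregulators, power-law conformers, and metabolic
# suppressors. Every chamber run gets sensor noise and a bacterial
# background drift; one blank chamber per group records that drift.
#
# Outputs: bulky chamber traces under scratch/ (regenerated on demand),
# the per-individual truth table under results/.

library(regindex)

dir.create("scratch/synthetic_study", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

design <- list(
  polar_reg      = list(spec = archetype_spec("pcrit_regulator", rmax = 0.8,
                                              pcrit_pct = 20),
                        species = "polar_regulator", temperature_C = 2,
                        n = 10, duration_h = 9, weight_mg = 350,
                        chamber_volume_mL = 250),
  arctic_reg     = list(spec = archetype_spec("pcrit_regulator", rmax = 1.2,
                                              pcrit_pct = 25),
                        species = "arctic_regulator", temperature_C = 6,
                        n = 22, duration_h = 6, weight_mg = 25),
  temperate_sat  = list(spec = archetype_spec("saturation", rmax = 2.5,
                                              K = 30),
                        species = "temperate_hyperbolic", temperature_C = 10,
                        n = 10, duration_h = 7, weight_mg = 20),
  temperate_low  = list(spec = archetype_spec("saturation", rmax = 2, K = 50),
                        species = "temperate_weak_regulator",
                        temperature_C = 10, n = 10, duration_h = 8,
                        weight_mg = 20),
  neritic_conf   = list(spec = archetype_spec("power_law", rmax = 2,
                                              gamma = 1),
                        species = "neritic_conformer", temperature_C = 10,
                        n = 12, duration_h = 10, weight_mg = 20),
  tropical_conf  = list(spec = archetype_spec("power_law", rmax = 3,
                                              gamma = 1),
                        species = "tropical_conformer", temperature_C = 20,
                        n = 12, duration_h = 10, weight_mg = 8),
  subtrop_reg    = list(spec = archetype_spec("pcrit_regulator", rmax = 2,
                                              pcrit_pct = 30),
                        species = "subtropical_regulator",
                        temperature_C = 10, n = 22, duration_h = 5,
                        weight_mg = 20),
  subtrop_mid    = list(spec = archetype_spec("power_law", rmax = 2,
                                              gamma = 0.5),
                        species = "subtropical_intermediate",
                        temperature_C = 15, n = 15, duration_h = 8,
                        weight_mg = 20),
  omz_supp       = list(spec = archetype_spec("suppressor", rmax = 1.5,
                                              threshold_pct = 70,
                                              suppression_fraction = 0.25),
                        species = "omz_suppressor", temperature_C = 8,
                        n = 18, duration_h = 10, weight_mg = 25),
  deep_supp      = list(spec = archetype_spec("suppressor", rmax = 1.2,
                                              threshold_pct = 60,
                                              suppression_fraction = 0.35),
                        species = "deep_suppressor", temperature_C = 5,
                        n = 10, duration_h = 10, weight_mg = 30))

stopifnot(sum(vapply(design, `[[`, numeric(1), "n")) == 141)

noise <- noise_model(sensor_sd_pct = 0.5, blank_slope_pct_per_h = 0.3,
                     seed = 20260923)
study <- make_study(design, noise, n_blanks = 1, sampling_interval_s = 30)

# long trace table + sidecar metadata, the shape a sensor export would have
long <- do.call(rbind, lapply(study$traces, function(tr)
  data.frame(trace_id = tr$metadata$trace_id, time = tr$time_s,
             oxygen = tr$do_pct_airsat)))
meta <- do.call(rbind, lapply(study$traces, function(tr)
  as.data.frame(tr$metadata[c("trace_id", "species", "temperature_C",
                              "chamber_volume_mL", "weight_mg",
                              "weight_basis", "is_blank",
                              "sampling_interval_s")])))
write.csv(long, "scratch/synthetic_study/traces_long.csv", row.names = FALSE)
write.csv(meta, "scratch/synthetic_study/trace_metadata.csv",
          row.names = FALSE)
write_results(study$truth, "results/simulated_truth.csv")

cat(sprintf("simulated %d chamber runs (%d animals + %d blanks), %d groups\n",
            length(study$traces), nrow(study$truth),
            sum(meta$is_blank), length(design)))
cat("traces -> scratch/synthetic_study/, truth -> results/simulated_truth.csv\n")
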