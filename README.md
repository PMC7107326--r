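# regindex

Hypoxia-tolerance analysis for closed-chamber respirometry: from raw
oxygen-decline traces to per-individual **Regulation Index (RI)** values,
group-level respiration-strategy labels, and nonparametric group
comparison. Written for comparative ecophysiologists working on aquatic
ectotherms — zooplankton crossing oxygen minimum zones in particular —
whose rate-vs-oxygen responses lack the clean breakpoint a critical
oxygen tension (P~crit~) needs.

## The statistic

For a mass-specific respiration response *f(c)* observed over dissolved
oxygen *c* ∈ [c_lo, c_hi] (% air saturation), draw two reference lines:
the **perfect-conformity** line through the origin reaching *f(c_hi)* at
the highest observed oxygen, and the **perfect-regulation** horizontal
line at max *f*. With A_c the area under the response (natural cubic
spline through the points, adaptive quadrature), A_f under the conformity
line and A_r under the regulation line:

    RI = (A_c − A_f) / (A_r − A_f)   if A_c ≥ A_f
    RI = (A_c − A_f) / A_f           otherwise

so a perfect regulator scores 1, a perfect conformer 0, and a response
suppressed below even the conformity expectation goes negative — down to
−1 for rates pinned at zero. Negative RI reads as hypoxia sensitivity or
active metabolic suppression. No parametric model is fitted at any point.

Around the statistic the package provides the full pipeline: trace
ingestion (long/wide delimited text, configurable columns), 30-min
acclimation trimming, sliding-OLS rate derivation, blank (background)
correction, oxygen unit conversion (% air saturation / kPa / mL L⁻¹ /
mg L⁻¹ via Benson–Krause solubility), wet-weight normalisation, a ≤50%
oxygen-depth QC rule, median/quartile strategy classification,
Kruskal–Wallis + rank post-hoc with significance letters, and a
closed-chamber simulator with analytically known RI for validation.

## Worked example

Score a noisy hyperbolic regulator (Michaelis-type response,
rate = 2·DO/(30+DO) mL O₂ h⁻¹ g⁻¹, sensor noise SD 0.1) and summarise a
group of twelve:

```r
library(regindex)
set.seed(42)
spec <- archetype_spec("saturation", rmax = 2, K = 30)
prof <- sample_rate_profile(spec, 40, noise_model(rate_sd = 0.1, seed = 42),
                            trace_id = "krill_01", species = "demo_krill",
                            temperature_C = 10)
compute_ri(qc_filter(prof), smooth = TRUE, span = 0.5)
#>   trace_id    ri auc_curve auc_conformity auc_regulation branch
#> 1 krill_01 0.427       112           78.3            157  mixed
true_ri(spec)
#> [1] 0.456

ris <- replicate(12, compute_ri(sample_rate_profile(spec, 40,
         noise_model(rate_sd = 0.1, seed = sample.int(1e6, 1))),
         smooth = TRUE, span = 0.5)$ri)
summarize_group(ris, species = "demo_krill", temperature_C = 10)
#>      species  n ri_median ri_q1 ri_q3          strategy
#> 1 demo_krill 12     0.451 0.428 0.491 low_oxyregulation
```

The individual scores RI = 0.43 against an analytic archetype value of
0.456: the curve sits 43% of the way from its conformity line to its
regulation line (areas 112 vs 78.3 and 157; `branch = "mixed"` flags that
noise carries the spline across the conformity line somewhere). The group
median 0.45 with quartiles above 0.25 classifies as a low degree of
oxyregulation.

## Analysis workflow

`analysis/` holds the numbered study scripts, each a thin driver over the
package (run from the repository root, in order):

| script | does | writes |
|---|---|---|
| `01_simulate_study.R` | 141 simulated chamber runs, 10 groups, blanks, noise | `scratch/` traces, `results/simulated_truth.csv` |
| `02_derive_rates.R` | trim → OLS slopes → blank correction → mass-specific profiles, QC | `results/qc_summary.csv` |
| `03_regulation_index.R` | RI per individual, recovery vs analytic truth | `results/ri_results.csv` |
| `04_classify.R` | group summaries + strategies, both rule modes | `results/group_summaries_*.csv` |
| `05_group_stats.R` | Kruskal–Wallis, rank post hoc, letters, boxplot numbers | `results/kruskal_wallis.csv`, … |

`run_pipeline()` performs the same chain in one call from a config list
or YAML file; `euphausiid_ri_table()` carries the seventeen published
euphausiid group summaries used as a classification regression fixture.

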