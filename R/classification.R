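#' Summarise Regulation Index values for one group
#'
#' Median and quartiles of per-individual RI within a species x temperature
#' group, using linear-interpolation quantiles (R's default type 7), plus
#' the respiration-strategy label from [classify_strategy()].
#'
#' @param ri_values Numeric vector of per-individual RI values.
#' @param species,temperature_C Group labels.
#' @param mode Classification mode, see [classify_strategy()].
#' @param quantile_type Quantile algorithm (passed to [stats::quantile()]);
#'   default 7, linear interpolation between order statistics.
#' @return One-row data frame: `species`, `temperature_C`, `n`,
#'   `ri_median`, `ri_q1`, `ri_q3`, `strategy`, `rule_trace`.
#' @export
summarize_group <- function(ri_values, species = NA_character_,
                            temperature_C = NA_real_,
                            mode = c("literal", "table2_compat"),
                            quantile_type = 7) {
  mode <- match.arg(mode)
  ri_values <- ri_values[is.finite(ri_values)]
  if (length(ri_values) == 0)
    stop("empty group: no finite RI values", call. = FALSE)
  q <- stats::quantile(ri_values, probs = c(0.25, 0.5, 0.75),
                       type = quantile_type, names = FALSE)
  cls <- classify_strategy(q[2], q[1], q[3], mode = mode)
  data.frame(species = species, temperature_C = temperature_C,
             n = length(ri_values), ri_median = q[2], ri_q1 = q[1],
             ri_q3 = q[3], strategy = cls$strategy,
             rule_trace = cls$rule_trace, stringsAsFactors = FALSE)
}

#' Assign a respiration strategy from group RI median and quartiles
#'
#' Strategies are group-level constructs defined on the RI median and the
#' first/third quartiles (Q1, Q3):
#' \itemize{
#'   \item metabolic_suppression: median, Q1 and Q3 all below 0;
#'   \item high_oxyregulation: 0.5 <= median < 1 and (Q1 > 0.25 or
#'     Q3 > 0.75);
#'   \item low_oxyregulation: 0.25 < median < 0.5;
#'   \item conformity_regulation: median in (0, 0.5) with Q1 < 0 and
#'     Q3 > 0.25 - a hybrid box straddling both regimes;
#'   \item conformity: |median| <= 0.25 with Q1 < 0 and Q3 > 0 (the
#'     operational reading of "median about zero");
#'   \item unclassified otherwise.
#' }
#' Clauses are evaluated in that fixed order; suppression is checked first
#' because the definitions are not mutually exclusive near zero, and the
#' hybrid clause precedes plain conformity so a box reaching well into the
#' regulation range is not collapsed onto conformity. In `table2_compat`
#' mode the median is rounded to one decimal before the high-oxyregulation
#' clause, matching how published summary tables present medians (0.48
#' prints as a high regulator when its quartiles support it).
#'
#' @param median,q1,q3 Group RI median and quartiles, `q1 <= median <= q3`.
#' @param mode `"literal"` or `"table2_compat"`.
#' @return List with `strategy` (label) and `rule_trace` (which clause
#'   fired, and the mode).
#' @export
classify_strategy <- function(median, q1, q3,
                              mode = c("literal", "table2_compat")) {
  mode <- match.arg(mode)
  if (!(q1 <= median && median <= q3))
    stop("need q1 <= median <= q3", call. = FALSE)
  m_high <- if (mode == "table2_compat") round(median, 1) else median
  fired <- NULL
  strategy <-
    if (median < 0 && q1 < 0 && q3 < 0) {
      fired <- "suppression: median, Q1, Q3 < 0"
      "metabolic_suppression"
    } else if (m_high >= 0.5 && m_high < 1 && (q1 > 0.25 || q3 > 0.75)) {
      fired <- sprintf("high: 0.5 <= median(%s) < 1 & (Q1 > 0.25 | Q3 > 0.75)",
                       format(m_high))
      "high_oxyregulation"
    } else if (median > 0.25 && median < 0.5) {
      fired <- "low: 0.25 < median < 0.5"
      "low_oxyregulation"
    } else if (median > 0 && median < 0.5 && q1 < 0 && q3 > 0.25) {
      fired <- "hybrid: 0 < median < 0.5 & Q1 < 0 & Q3 > 0.25"
      "conformity_regulation"
    } else if (abs(median) <= 0.25 && q1 < 0 && q3 > 0) {
      fired <- "conformity: |median| <= 0.25 & Q1 < 0 & Q3 > 0"
      "conformity"
    } else {
      fired <- "no clause matched"
      "unclassified"
    }
  list(strategy = strategy,
       rule_trace = paste0(fired, " [mode=", mode, "]"))
}

#' Group summaries and strategies for a batch of RI results
#'
#' Splits RI results by species x temperature and summarises each group.
#'
#' @param ri_results Data frame from [ri_batch()] (columns `species`,
#'   `temperature_C`, `ri`).
#' @param mode,quantile_type Passed to [summarize_group()].
#' @return Data frame with one row per group, ordered by species then
#'   temperature.
#' @export
classify_groups <- function(ri_results, mode = c("literal", "table2_compat"),
                            quantile_type = 7) {
  mode <- match.arg(mode)
  key <- interaction(ri_results$species, ri_results$temperature_C,
                     drop = TRUE)
  rows <- lapply(split(ri_results, key), function(g)
    summarize_group(g$ri, species = g$species[1],
                    temperature_C = g$temperature_C[1], mode = mode,
                    quantile_type = quantile_type))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$species, out$temperature_C), , drop = FALSE]
}

#' Published euphausiid group RI summaries
#'
#' The 17 species x temperature group summaries (RI median, quartiles and
#' strategy label) published for 10 euphausiid species from polar, upwelling
#' and tropical regions, as printed in the source study's summary table.
#' Used as a regression fixture for [classify_strategy()]'s
#' `table2_compat` mode.
#'
#' @return Data frame: `species`, `temperature_C`, `ri_median`, `ri_q1`,
#'   `ri_q3`, `strategy`.
#' @export
euphausiid_ri_table <- function() {
  tab <- rbind(
    c("Euphausia superba",     "4",   0.48,  0.29,  0.58, "high_oxyregulation"),
    c("Thysanoessa inermis",   "2",   0.34,  0.32,  0.46, "low_oxyregulation"),
    c("Thysanoessa inermis",   "2-6", 0.48,  0.35,  0.60, "high_oxyregulation"),
    c("Thysanoessa inermis",   "6",   0.66,  0.60,  0.72, "high_oxyregulation"),
    c("Thysanoessa inermis",   "8",   0.43,  0.17,  0.54, "low_oxyregulation"),
    c("Thysanoessa inermis",   "10",  0.49,  0.30,  0.60, "high_oxyregulation"),
    c("Euphausia pacifica",    "10",  0.36,  0.16,  0.55, "low_oxyregulation"),
    c("Thysanoessa spinifera", "10",  0.07, -0.31,  0.24, "conformity"),
    c("Euphausia distinguenda","20", -0.19, -0.26, -0.03, "metabolic_suppression"),
    c("Euphausia lamelligera", "20", -0.03, -0.04,  0.14, "conformity"),
    c("Euphausia hanseni",     "5",  -0.38, -0.50, -0.15, "metabolic_suppression"),
    c("Euphausia hanseni",     "10",  0.50,  0.29,  0.69, "high_oxyregulation"),
    c("Euphausia hanseni",     "15",  0.25, -0.11,  0.58, "conformity_regulation"),
    c("Euphausia hanseni",     "20",  0.74,  0.59,  0.79, "high_oxyregulation"),
    c("Nematoscelis megalops", "10",  0.52,  0.37,  0.67, "high_oxyregulation"),
    c("Nyctiphanes capensis",  "10",  0.59,  0.16,  0.78, "high_oxyregulation"),
    c("Euphausia mucronata",   "8",  -0.26, -0.40, -0.15, "metabolic_suppression"))
  data.frame(species = tab[, 1], temperature_C = tab[, 2],
             ri_median = as.numeric(tab[, 3]), ri_q1 = as.numeric(tab[, 4]),
             ri_q3 = as.numeric(tab[, 5]), strategy = tab[, 6],
             stringsAsFactors = FALSE)
}
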