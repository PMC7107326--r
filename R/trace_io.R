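#' Construct trace metadata
#'
#' Metadata describing one respirometry chamber run: the animal, the chamber
#' and the sensor settings. Weights may be on a wet or dry basis; dry weights
#' must be converted with [dry_to_wet()] before rates are mass-normalised.
#'
#' @param trace_id Character identifier, unique within a study.
#' @param species Species name (free text).
#' @param temperature_C Water temperature in degrees Celsius.
#' @param chamber_volume_mL Chamber volume in mL (> 0).
#' @param weight_mg Animal weight in mg (> 0 unless `is_blank`).
#' @param weight_basis `"wet"` or `"dry"`.
#' @param is_blank `TRUE` for an animal-free blank chamber.
#' @param sampling_interval_s Sensor sampling interval in seconds.
#' @param salinity_psu Salinity in practical salinity units (for oxygen unit
#'   conversion); may be `NA` when no conversion is needed.
#' @return A `trace_metadata` list.
#' @export
trace_metadata <- function(trace_id, species = NA_character_,
                           temperature_C = NA_real_, chamber_volume_mL = 20,
                           weight_mg = NA_real_, weight_basis = c("wet", "dry"),
                           is_blank = FALSE, sampling_interval_s = 15,
                           salinity_psu = NA_real_) {
  weight_basis <- match.arg(weight_basis)
  if (!is.finite(chamber_volume_mL) || chamber_volume_mL <= 0)
    stop("chamber_volume_mL must be > 0", call. = FALSE)
  # NA weight is allowed at ingestion (caught when rates are normalised);
  # a known non-positive weight is rejected outright
  if (!is_blank && is.finite(weight_mg) && weight_mg <= 0)
    stop("weight_mg must be > 0 for non-blank traces", call. = FALSE)
  if (!is.finite(sampling_interval_s) || sampling_interval_s <= 0)
    stop("sampling_interval_s must be > 0", call. = FALSE)
  structure(list(trace_id = as.character(trace_id), species = species,
                 temperature_C = temperature_C,
                 chamber_volume_mL = chamber_volume_mL,
                 weight_mg = weight_mg, weight_basis = weight_basis,
                 is_blank = isTRUE(is_blank),
                 sampling_interval_s = sampling_interval_s,
                 salinity_psu = salinity_psu),
            class = "trace_metadata")
}

#' Construct a respirometry trace
#'
#' An oxygen-vs-time series for one closed chamber. Time must be strictly
#' increasing; dissolved oxygen is in percent air saturation (sensor
#' overshoot tolerated up to 110).
#'
#' @param time_s Numeric vector of sample times in seconds.
#' @param do_pct_airsat Numeric vector of dissolved oxygen, % air saturation.
#' @param metadata A [trace_metadata()] object.
#' @return A `respirometry_trace` list.
#' @export
respirometry_trace <- function(time_s, do_pct_airsat, metadata) {
  if (!inherits(metadata, "trace_metadata"))
    stop("metadata must be a trace_metadata object", call. = FALSE)
  time_s <- as.numeric(time_s)
  do_pct_airsat <- as.numeric(do_pct_airsat)
  if (length(time_s) != length(do_pct_airsat))
    stop("time and oxygen vectors differ in length", call. = FALSE)
  if (length(time_s) < 3)
    stop("a trace needs at least 3 samples", call. = FALSE)
  if (anyNA(time_s) || anyNA(do_pct_airsat))
    stop("non-numeric or missing cells in trace '", metadata$trace_id, "'",
         call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("time not strictly increasing in trace '", metadata$trace_id, "'",
         call. = FALSE)
  if (any(do_pct_airsat < 0 | do_pct_airsat > 110))
    stop("oxygen outside [0, 110] %% air saturation in trace '",
         metadata$trace_id, "'", call. = FALSE)
  structure(list(metadata = metadata, time_s = time_s,
                 do_pct_airsat = do_pct_airsat),
            class = "respirometry_trace")
}

#' @export
print.respirometry_trace <- function(x, ...) {
  cat(sprintf("<respirometry_trace> %s: %d samples, %.1f min, DO %.1f -> %.1f %%airsat\n",
              x$metadata$trace_id, length(x$time_s),
              diff(range(x$time_s)) / 60,
              x$do_pct_airsat[1], x$do_pct_airsat[length(x$do_pct_airsat)]))
  invisible(x)
}

#' Construct a rate-vs-oxygen profile
#'
#' Paired (dissolved oxygen, mass-specific respiration rate) points for one
#' individual; the unit of Regulation Index computation. Rates are in
#' mL O2 h^-1 g wet weight^-1, oxygen in % air saturation.
#'
#' @param trace_id Identifier of the source trace.
#' @param do_pct_airsat Oxygen values, % air saturation.
#' @param rate_mlO2_h_gww Mass-specific rates (same length).
#' @param species,temperature_C Group labels carried through the pipeline.
#' @param qc_pass Logical quality-control flag (see [qc_filter()]).
#' @param qc_reason Reason recorded when `qc_pass` is `FALSE`.
#' @return A `rate_profile` list, points ordered by descending oxygen.
#' @export
rate_profile <- function(trace_id, do_pct_airsat, rate_mlO2_h_gww,
                         species = NA_character_, temperature_C = NA_real_,
                         qc_pass = TRUE, qc_reason = "") {
  do_pct_airsat <- as.numeric(do_pct_airsat)
  rate_mlO2_h_gww <- as.numeric(rate_mlO2_h_gww)
  if (length(do_pct_airsat) != length(rate_mlO2_h_gww))
    stop("oxygen and rate vectors differ in length", call. = FALSE)
  if (any(do_pct_airsat < 0))
    stop("negative oxygen in profile '", trace_id, "'", call. = FALSE)
  if (any(!is.finite(rate_mlO2_h_gww)))
    stop("non-finite rates in profile '", trace_id, "'", call. = FALSE)
  ord <- order(do_pct_airsat, decreasing = TRUE)
  structure(list(trace_id = as.character(trace_id), species = species,
                 temperature_C = temperature_C,
                 do_pct_airsat = do_pct_airsat[ord],
                 rate_mlO2_h_gww = rate_mlO2_h_gww[ord],
                 qc_pass = isTRUE(qc_pass), qc_reason = qc_reason),
            class = "rate_profile")
}

#' @export
print.rate_profile <- function(x, ...) {
  cat(sprintf("<rate_profile> %s (%s, %s degC): %d points, DO [%.1f, %.1f], QC %s\n",
              x$trace_id, x$species, format(x$temperature_C),
              length(x$do_pct_airsat),
              min(x$do_pct_airsat), max(x$do_pct_airsat),
              if (x$qc_pass) "pass" else paste0("FAIL (", x$qc_reason, ")")))
  invisible(x)
}

# Resolve a logical column through a user column_map, falling back to the
# canonical name. Errors name the missing column.
.resolve_col <- function(df, role, column_map, default, required = TRUE) {
  name <- if (!is.null(column_map[[role]])) column_map[[role]] else default
  if (!name %in% names(df)) {
    if (required)
      stop("format error: required column '", name, "' (", role,
           ") not found", call. = FALSE)
    return(NULL)
  }
  name
}

.read_delim <- function(path, sep = ",", dec = ".") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Read respirometry traces from a delimited text table
#'
#' Two dialects are supported. `long`: one row per sample with columns for
#' trace id, time and oxygen. `wide`: one time column plus one oxygen column
#' per chamber, the column headers becoming trace ids. Metadata may be given
#' per trace through `metadata`, either a data frame keyed by `trace_id` or a
#' single [trace_metadata()] template applied to all traces.
#'
#' @param path Path to a delimited text file.
#' @param dialect `"long"` or `"wide"`.
#' @param column_map Named list mapping roles (`trace_id`, `time`, `oxygen`)
#'   to actual column headers; defaults are the role names.
#' @param metadata `NULL`, a data frame with a `trace_id` column plus
#'   metadata fields, or a `trace_metadata` template.
#' @param sep,dec Field delimiter and decimal separator.
#' @return A named list of [respirometry_trace()] objects.
#' @export
read_trace_table <- function(path, dialect = c("long", "wide"),
                             column_map = list(), metadata = NULL,
                             sep = ",", dec = ".") {
  dialect <- match.arg(dialect)
  df <- .read_delim(path, sep, dec)
  if (dialect == "long") {
    id_col <- .resolve_col(df, "trace_id", column_map, "trace_id")
    t_col <- .resolve_col(df, "time", column_map, "time")
    o_col <- .resolve_col(df, "oxygen", column_map, "oxygen")
    ids <- unique(as.character(df[[id_col]]))
    traces <- lapply(ids, function(id) {
      sub <- df[as.character(df[[id_col]]) == id, , drop = FALSE]
      tt <- suppressWarnings(as.numeric(sub[[t_col]]))
      oo <- suppressWarnings(as.numeric(sub[[o_col]]))
      if (anyNA(tt) || anyNA(oo))
        stop("non-numeric cells in trace '", id, "'", call. = FALSE)
      ord <- order(tt)
      tt <- tt[ord]; oo <- oo[ord]
      if (anyDuplicated(tt))
        stop("validation error: duplicated timestamps in trace '", id, "'",
             call. = FALSE)
      respirometry_trace(tt, oo, .meta_for(id, metadata))
    })
    names(traces) <- ids
  } else {
    t_col <- .resolve_col(df, "time", column_map, "time")
    o_cols <- setdiff(names(df), t_col)
    if (length(o_cols) == 0)
      stop("format error: required column 'oxygen' not found", call. = FALSE)
    tt <- suppressWarnings(as.numeric(df[[t_col]]))
    if (anyNA(tt)) stop("non-numeric cells in time column", call. = FALSE)
    ord <- order(tt)
    traces <- lapply(o_cols, function(id) {
      oo <- suppressWarnings(as.numeric(df[[id]]))[ord]
      if (anyNA(oo))
        stop("non-numeric cells in trace '", id, "'", call. = FALSE)
      if (anyDuplicated(tt[ord]))
        stop("validation error: duplicated timestamps in trace '", id, "'",
             call. = FALSE)
      respirometry_trace(tt[ord], oo, .meta_for(id, metadata))
    })
    names(traces) <- o_cols
  }
  traces
}

# Build a trace_metadata for id from NULL / template / keyed data frame.
.meta_for <- function(id, metadata) {
  if (is.null(metadata))
    return(trace_metadata(id))  # placeholder; weight supplied later
  if (inherits(metadata, "trace_metadata")) {
    m <- metadata
    m$trace_id <- as.character(id)
    return(m)
  }
  if (is.data.frame(metadata)) {
    row <- metadata[metadata$trace_id == id, , drop = FALSE]
    if (nrow(row) == 0)
      stop("no metadata row for trace '", id, "'", call. = FALSE)
    row <- as.list(row[1, ])
    return(trace_metadata(
      trace_id = id,
      species = row$species %||% NA_character_,
      temperature_C = row$temperature_C %||% NA_real_,
      chamber_volume_mL = row$chamber_volume_mL %||% 20,
      weight_mg = row$weight_mg %||% NA_real_,
      weight_basis = row$weight_basis %||% "wet",
      is_blank = isTRUE(row$is_blank %||% FALSE),
      sampling_interval_s = row$sampling_interval_s %||% 15,
      salinity_psu = row$salinity_psu %||% NA_real_))
  }
  stop("metadata must be NULL, a trace_metadata or a data frame",
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Read pre-derived rate-vs-oxygen profiles
#'
#' Entry point for deposited data that is already rate-vs-oxygen (one row per
#' point). Requires columns for trace id, oxygen and rate; optional `species`
#' and `temperature_C` columns are carried as group labels.
#'
#' @inheritParams read_trace_table
#' @return A named list of [rate_profile()] objects, points ordered by
#'   descending oxygen. An empty file yields an empty list with a warning.
#' @export
read_rate_profiles <- function(path, column_map = list(), sep = ",",
                               dec = ".") {
  df <- .read_delim(path, sep, dec)
  if (nrow(df) == 0) {
    warning("no data rows in ", path)
    return(list())
  }
  id_col <- .resolve_col(df, "trace_id", column_map, "trace_id")
  o_col <- .resolve_col(df, "oxygen", column_map, "oxygen")
  r_col <- .resolve_col(df, "rate", column_map, "rate")
  sp_col <- .resolve_col(df, "species", column_map, "species", required = FALSE)
  tc_col <- .resolve_col(df, "temperature_C", column_map, "temperature_C",
                         required = FALSE)
  oo_all <- suppressWarnings(as.numeric(df[[o_col]]))
  if (any(oo_all < 0, na.rm = TRUE))
    stop("validation error: negative oxygen values", call. = FALSE)
  ids <- unique(as.character(df[[id_col]]))
  profiles <- lapply(ids, function(id) {
    sub <- df[as.character(df[[id_col]]) == id, , drop = FALSE]
    rate_profile(id,
                 do_pct_airsat = as.numeric(sub[[o_col]]),
                 rate_mlO2_h_gww = as.numeric(sub[[r_col]]),
                 species = if (is.null(sp_col)) NA_character_ else
                   as.character(sub[[sp_col]][1]),
                 temperature_C = if (is.null(tc_col)) NA_real_ else
                   as.numeric(sub[[tc_col]][1]))
  })
  names(profiles) <- ids
  profiles
}

#' Write result tables to delimited text
#'
#' Writes RI results or group summaries with a stable column order: numeric
#' columns are serialized at full precision and each gets a companion
#' `<name>_2dp` display column rounded to 2 decimals.
#'
#' @param results A data frame (e.g. from [ri_batch()] or
#'   [classify_groups()]), or a list of `rate_profile` objects.
#' @param path Output file path.
#' @param allow_empty Permit an empty table (header-only file).
#' @param sep Field delimiter.
#' @return Invisibly, the data frame as written.
#' @export
write_results <- function(results, path, allow_empty = FALSE, sep = ",") {
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, logical(1), "rate_profile"))) {
    results <- profiles_to_table(results)
  }
  if (!is.data.frame(results))
    stop("results must be a data frame or a list of rate_profiles",
         call. = FALSE)
  if (nrow(results) == 0 && !allow_empty)
    stop("refusing to write an empty table (set allow_empty = TRUE)",
         call. = FALSE)
  out <- results
  num <- names(out)[vapply(out, is.numeric, logical(1))]
  for (nm in num) out[[paste0(nm, "_2dp")]] <- round(results[[nm]], 2)
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(out)
}

#' Flatten rate profiles to a long table
#'
#' One row per (oxygen, rate) point, suitable for [write_results()] and
#' re-ingestion by [read_rate_profiles()].
#'
#' @param profiles List of `rate_profile` objects.
#' @return A data frame with columns `trace_id`, `species`, `temperature_C`,
#'   `oxygen`, `rate`, `qc_pass`, `qc_reason`.
#' @export
profiles_to_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    data.frame(trace_id = p$trace_id, species = p$species,
               temperature_C = p$temperature_C,
               oxygen = p$do_pct_airsat, rate = p$rate_mlO2_h_gww,
               qc_pass = p$qc_pass, qc_reason = p$qc_reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
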