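#' Fit the continuous respiration-response curve of a profile
#'
#' Interpolating natural cubic spline through the (oxygen, rate) points,
#' sorted ascending in oxygen, with duplicate oxygen values mean-aggregated
#' first (interpolation needs strictly increasing abscissae). No parametric
#' model is fitted: the curve follows the data, which keeps the Regulation
#' Index free of model-choice interpretation. Optional local-regression
#' pre-smoothing can be enabled for noisy sensor data; the spline is then
#' drawn through the smoothed values at the observed oxygen points.
#'
#' @param profile A [rate_profile()] passing QC, with at least 3 distinct
#'   oxygen values.
#' @param smooth Apply loess pre-smoothing before interpolation.
#' @param span Loess span when `smooth = TRUE`.
#' @return A function of oxygen (% air saturation), evaluable on the
#'   observed range, with attributes `do_lo` and `do_hi`.
#' @export
fit_response_curve <- function(profile, smooth = FALSE, span = 0.75) {
  stopifnot(inherits(profile, "rate_profile"))
  x <- profile$do_pct_airsat
  y <- profile$rate_mlO2_h_gww
  if (anyDuplicated(x)) {
    agg <- tapply(y, x, mean)
    x <- as.numeric(names(agg))
    y <- as.numeric(agg)
  }
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  if (length(x) < 3)
    stop("degenerate profile: fewer than 3 distinct oxygen values",
         call. = FALSE)
  if (smooth) {
    fit <- stats::loess(y ~ x, span = span,
                        control = stats::loess.control(surface = "direct"))
    y <- stats::predict(fit, newdata = data.frame(x = x))
  }
  f <- stats::splinefun(x, y, method = "natural")
  attr(f, "do_lo") <- x[1]
  attr(f, "do_hi") <- x[length(x)]
  attr(f, "smooth") <- smooth
  f
}

#' Reference lines for the Regulation Index geometry
#'
#' The perfect-oxyconformity reference is the line through the origin (zero
#' rate at 0% air saturation) anchored at the fitted curve's value at the
#' highest observed oxygen: a conformer with the same normoxic rate. The
#' perfect-oxyregulation reference is the horizontal line at the maximum of
#' the fitted curve over the observed range, located on a dense grid.
#'
#' @param curve Function from [fit_response_curve()].
#' @param do_lo,do_hi Observed oxygen range (% air saturation).
#' @param grid_n Grid size for the maximum search (default 512).
#' @return List with `conformity_slope` (rate per % air sat) and
#'   `regulation_level` (max rate).
#' @export
build_reference_lines <- function(curve, do_lo = attr(curve, "do_lo"),
                                  do_hi = attr(curve, "do_hi"),
                                  grid_n = 512) {
  y_hi <- curve(do_hi)
  if (y_hi < 0)
    stop("curve is negative at the highest observed oxygen; rates must be ",
         "non-negative upstream", call. = FALSE)
  grid <- seq(do_lo, do_hi, length.out = grid_n)
  list(conformity_slope = y_hi / do_hi,
       regulation_level = max(curve(grid)))
}

#' Area under a curve by adaptive quadrature
#'
#' @param f Function of one variable, finite on `[lo, hi]`.
#' @param lo,hi Integration bounds, `lo < hi`.
#' @param method `"adaptive"` (default, `stats::integrate`) or
#'   `"trapezoid"` (dense-grid trapezoidal rule).
#' @param n Grid size for the trapezoid method.
#' @return The integral.
#' @export
integrate_auc <- function(f, lo, hi, method = c("adaptive", "trapezoid"),
                          n = 1e5) {
  method <- match.arg(method)
  if (!(lo < hi)) stop("lo must be < hi", call. = FALSE)
  if (method == "adaptive") {
    fx <- f(c(lo, hi))
    if (any(!is.finite(fx)))
      stop("non-finite curve evaluation on the integration range",
           call. = FALSE)
    res <- stats::integrate(f, lo, hi, subdivisions = 500L,
                            rel.tol = 1e-9, abs.tol = 1e-12,
                            stop.on.error = FALSE)
    if (!is.finite(res$value))
      stop("non-finite integral", call. = FALSE)
    res$value
  } else {
    x <- seq(lo, hi, length.out = n)
    y <- f(x)
    if (any(!is.finite(y)))
      stop("non-finite curve evaluation on the integration range",
           call. = FALSE)
    sum((y[-1] + y[-n]) / 2 * diff(x))
  }
}

#' Compute the Regulation Index of one rate profile
#'
#' The Regulation Index (RI) locates a respiration response between perfect
#' oxyconformity and perfect oxyregulation by areas under curves over the
#' observed oxygen range `[do_lo, do_hi]`. With `A_c` the area under the
#' fitted response curve, `A_f` the area under the conformity line and
#' `A_r` the area under the regulation line:
#' \itemize{
#'   \item positive branch (`A_c >= A_f`): `RI = (A_c - A_f) / (A_r - A_f)`,
#'     so a constant-rate regulator scores 1 and a proportional conformer 0;
#'   \item negative branch (`A_c < A_f`): `RI = (A_c - A_f) / A_f`, the
#'     deficit relative to the area between the conformity line and the
#'     zero-rate floor, so a response pinned at zero scores -1. Negative RI
#'     indicates rates below even the conformity expectation - hypoxia
#'     sensitivity or metabolic suppression.
#' }
#' When the curve crosses the conformity line the branch is decided by the
#' net area (the only rule continuous in the data) and flagged `"mixed"`.
#' RI is clamped to `[-1, 1]`; clamping is reported via a message.
#'
#' @param profile A [rate_profile()]; must pass QC.
#' @param smooth,span Passed to [fit_response_curve()].
#' @param grid_n Grid size for the maximum search and crossing detection.
#' @param quadrature `"adaptive"` or `"trapezoid"`, see [integrate_auc()].
#' @return One-row data frame: `trace_id`, `species`, `temperature_C`, `ri`,
#'   `auc_curve`, `auc_conformity`, `auc_regulation`, `do_lo_pct`,
#'   `do_hi_pct`, `branch`, `n_points`.
#' @export
compute_ri <- function(profile, smooth = FALSE, span = 0.75, grid_n = 512,
                       quadrature = c("adaptive", "trapezoid")) {
  quadrature <- match.arg(quadrature)
  stopifnot(inherits(profile, "rate_profile"))
  if (!profile$qc_pass)
    stop("profile '", profile$trace_id, "' failed QC: ", profile$qc_reason,
         call. = FALSE)
  curve <- fit_response_curve(profile, smooth = smooth, span = span)
  lo <- attr(curve, "do_lo"); hi <- attr(curve, "do_hi")
  refs <- build_reference_lines(curve, lo, hi, grid_n = grid_n)
  a_c <- integrate_auc(curve, lo, hi, method = quadrature)
  a_f <- refs$conformity_slope * (hi^2 - lo^2) / 2
  a_r <- refs$regulation_level * (hi - lo)
  if (isTRUE(all.equal(a_r, a_f)) && isTRUE(all.equal(a_f, 0)))
    stop("degenerate geometry: conformity and regulation references ",
         "coincide at zero", call. = FALSE)
  grid <- seq(lo, hi, length.out = grid_n)
  yg <- curve(grid)
  resid <- yg - refs$conformity_slope * grid
  tol <- 1e-6 * max(abs(yg), .Machine$double.eps)  # fp noise, not crossing
  crosses <- any(resid > tol) && any(resid < -tol)
  if (a_c >= a_f) {
    if (a_r - a_f <= 0)
      stop("degenerate geometry: regulation area does not exceed ",
           "conformity area", call. = FALSE)
    ri <- (a_c - a_f) / (a_r - a_f)
    branch <- "positive"
  } else {
    if (a_f <= 0)
      stop("degenerate geometry: conformity area is zero", call. = FALSE)
    ri <- (a_c - a_f) / a_f
    branch <- "negative"
  }
  if (crosses) branch <- "mixed"
  if (ri > 1 || ri < -1) {
    message("RI ", signif(ri, 4), " clamped to [-1, 1] for trace '",
            profile$trace_id, "'")
    ri <- max(-1, min(1, ri))
  }
  data.frame(trace_id = profile$trace_id, species = profile$species,
             temperature_C = profile$temperature_C, ri = ri,
             auc_curve = a_c, auc_conformity = a_f, auc_regulation = a_r,
             do_lo_pct = lo, do_hi_pct = hi, branch = branch,
             n_points = length(unique(profile$do_pct_airsat)),
             stringsAsFactors = FALSE)
}

#' Regulation Index for a batch of profiles
#'
#' Computes RI for every profile that passes QC. Failures (QC or geometry)
#' are recorded in the skip table, never silently dropped.
#'
#' @param profiles List of [rate_profile()] objects.
#' @param ... Passed to [compute_ri()].
#' @return Data frame of RI results with attribute `"skipped"`: a data
#'   frame of `trace_id`, `reason` for profiles not scored.
#' @export
ri_batch <- function(profiles, ...) {
  results <- list(); skipped <- list()
  for (p in profiles) {
    if (!p$qc_pass) {
      skipped[[length(skipped) + 1]] <-
        data.frame(trace_id = p$trace_id,
                   reason = paste0("QC: ", p$qc_reason),
                   stringsAsFactors = FALSE)
      next
    }
    res <- tryCatch(compute_ri(p, ...), error = function(e)
      data.frame(trace_id = p$trace_id, reason = conditionMessage(e),
                 stringsAsFactors = FALSE))
    if ("ri" %in% names(res)) results[[length(results) + 1]] <- res
    else skipped[[length(skipped) + 1]] <- res
  }
  out <- if (length(results)) do.call(rbind, results) else
    data.frame(trace_id = character(), species = character(),
               temperature_C = numeric(), ri = numeric(),
               auc_curve = numeric(), auc_conformity = numeric(),
               auc_regulation = numeric(), do_lo_pct = numeric(),
               do_hi_pct = numeric(), branch = character(),
               n_points = integer(), stringsAsFactors = FALSE)
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(trace_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  out
}
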