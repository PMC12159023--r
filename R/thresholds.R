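# Loess response curves along the burrow-density gradient, peak extraction,
# the conservative threshold-adoption rule, and relative change rates.

#' Fit a loess response curve of a metric against burrow density
#'
#' Classical locally weighted polynomial regression (tricube weights, no
#' robustness iterations), evaluated on a uniform grid over the observed
#' density range.  Fitting uses the exact ("direct") surface so that
#' noiseless polynomials of degree at most `degree` are reproduced to
#' numerical precision.
#'
#' @param x Burrow densities, effective holes/ha.
#' @param y Metric values.
#' @param span Smoothing fraction in `(0, 1]` (default 0.75).
#' @param degree Local polynomial degree: 0, 1 or 2 (default 2).
#' @param grid_size Evaluation grid resolution (default 512).
#' @return A `loess_fit`: list with `model`, `x`, `y`, `span`, `degree`,
#'   `grid`, `fitted`.
#' @export
loess_fit <- function(x, y, span = 0.75, degree = 2, grid_size = 512) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (!degree %in% 0:2) stop("degree must be 0, 1 or 2", call. = FALSE)
  if (span <= 0 || span > 1) stop("span must be in (0, 1]", call. = FALSE)
  if (length(unique(x)) < degree + 2)
    stop("need at least degree + 2 distinct x values", call. = FALSE)
  if (ceiling(span * length(x)) < degree + 1)
    stop("span * n too small for a degree-", degree, " local fit",
         call. = FALSE)
  model <- stats::loess(y ~ x, span = span, degree = degree,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
  grid <- seq(min(x), max(x), length.out = grid_size)
  fitted <- unname(stats::predict(model, newdata = data.frame(x = grid)))
  if (!all(is.finite(fitted)))
    stop("loess produced non-finite fitted values on the grid",
         call. = FALSE)
  structure(list(model = model, x = x, y = y, span = span, degree = degree,
                 grid = grid, fitted = fitted), class = "loess_fit")
}

#' Locate the fitted response peak
#'
#' Returns the grid density at which the loess curve is maximal; ties break
#' toward the lowest density (the protective choice).  A peak on the grid
#' boundary is flagged: a maximum at the minimum density means no interior
#' optimum exists (monotone-declining response).
#'
#' @param fit A `loess_fit`.
#' @return List with `peak` (holes/ha), `value` (fitted metric at the peak)
#'   and `at_boundary` (logical).
#' @export
find_peak <- function(fit) {
  stopifnot(inherits(fit, "loess_fit"))
  i <- which.max(fit$fitted)  # which.max takes the first (lowest-density) tie
  list(peak = fit$grid[i], value = fit$fitted[i],
       at_boundary = i == 1L || i == length(fit$grid))
}

#' Adopt a management threshold from candidate peak densities
#'
#' Given one candidate peak density per diversity metric, adopts the minimum
#' — the conservative threshold that safeguards every metric before its
#' decline begins.  When all candidates agree to within `tolerance`
#' (relative range `(max - min)/max`), the choice is reported as driven by a
#' negligible difference rather than conservatism.
#'
#' @param candidates Named numeric vector of candidate densities, holes/ha;
#'   all positive.
#' @param tolerance Relative-difference cutoff for "negligible" (default
#'   0.005, i.e. 0.5%).
#' @param grassland_type Optional type label carried into the result.
#' @return A `threshold_decision`: list with `candidates`, `adopted`,
#'   `principle` (`"conservative"` or `"negligible-difference"`),
#'   `relative_difference`, `tolerance`, `grassland_type`.
#' @export
adopt_threshold <- function(candidates, tolerance = 0.005,
                            grassland_type = NA_character_) {
  if (length(candidates) == 0 || any(!is.finite(candidates)) ||
      any(candidates <= 0))
    stop("candidates must be a nonempty set of positive densities",
         call. = FALSE)
  rel <- (max(candidates) - min(candidates)) / max(candidates)
  structure(list(candidates = candidates, adopted = min(candidates),
                 principle = if (rel < tolerance) "negligible-difference"
                             else "conservative",
                 relative_difference = rel, tolerance = tolerance,
                 grassland_type = grassland_type),
            class = "threshold_decision")
}

#' @export
print.threshold_decision <- function(x, ...) {
  cat("Threshold decision", if (!is.na(x$grassland_type))
    paste0("(", x$grassland_type, ")"), "\n")
  cat("  candidates:", paste(names(x$candidates), round(x$candidates, 1),
                             collapse = ", "), "\n")
  cat("  adopted:", round(x$adopted, 1), "holes/ha  [", x$principle, "]\n")
  invisible(x)
}

#' Relative change rate of a metric
#'
#' Percentage change of a metric at the highest disturbance relative to the
#' lowest-disturbance state: `100 * (value - baseline) / baseline`.
#'
#' @param baseline Metric value in the lowest-disturbance state (nonzero).
#' @param value Metric value under the highest burrow density.
#' @return Percent change (negative = decline).
#' @export
relative_change_rate <- function(baseline, value) {
  if (any(baseline == 0))
    stop("undefined change: baseline is zero", call. = FALSE)
  100 * (value - baseline) / baseline
}

#' Relative change rates of all indicators, by grassland type
#'
#' For each type, the baseline is the mean over level-I (no significant
#' disturbance) plots and the comparison value the mean over plots in the top
#' burrow-density stratum (above the `top_quantile` within-type quantile of
#' effective holes).  Metrics follow the conventional abbreviations SW, SR,
#' AB, CH, VC, HB.
#'
#' @param indicators Plot-indicator data frame (with `type` and
#'   `effective_holes`).
#' @param levels Factor of disturbance levels aligned to `indicators` rows.
#' @param top_quantile Quantile defining the highest-density stratum
#'   (default 0.9).
#' @return Data frame: one row per type, one column per metric, in percent.
#' @export
change_table <- function(indicators, levels, top_quantile = 0.9) {
  mets <- indicator_columns()[c("SW", "SR", "AB", "CH", "VC", "HB")]
  out <- lapply(unique(indicators$type), function(ty) {
    sel <- indicators$type == ty
    base_rows <- sel & levels == "I"
    top_rows <- sel & indicators$effective_holes >=
      stats::quantile(indicators$effective_holes[sel], top_quantile)
    if (!any(base_rows) || !any(top_rows))
      stop("empty group for type ", ty, ": ",
           if (!any(base_rows)) "no level-I plots " else "",
           if (!any(top_rows)) "no top-density plots" else "",
           call. = FALSE)
    ch <- vapply(mets, function(col) relative_change_rate(
      mean(indicators[base_rows, col]), mean(indicators[top_rows, col])),
      numeric(1))
    data.frame(type = ty, t(ch), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  names(out) <- c("type", names(mets))
  out
}

#' Extract diversity-density thresholds for one grassland type
#'
#' Fits loess curves of Shannon diversity and species richness against
#' burrow density, locates each fitted peak, and applies the conservative
#' adoption rule.
#'
#' @param indicators Plot-indicator rows of a single grassland type.
#' @param span,degree,grid_size Passed to [loess_fit()].
#' @param tolerance Passed to [adopt_threshold()].
#' @param metrics Named map of candidate metrics to indicator columns
#'   (default Shannon and richness).
#' @return A `threshold_decision` with a `peaks` attribute carrying the
#'   per-metric [find_peak()] results.
#' @export
extract_thresholds <- function(indicators, span = 0.75, degree = 2,
                               grid_size = 512, tolerance = 0.005,
                               metrics = c(SW = "shannon", SR = "richness")) {
  stopifnot(length(unique(indicators$type)) == 1L)
  peaks <- lapply(metrics, function(col) {
    find_peak(loess_fit(indicators$effective_holes, indicators[[col]],
                        span = span, degree = degree,
                        grid_size = grid_size))
  })
  cand <- vapply(peaks, `[[`, numeric(1), "peak")
  dec <- adopt_threshold(cand, tolerance = tolerance,
                         grassland_type = indicators$type[1])
  attr(dec, "peaks") <- peaks
  dec
}
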