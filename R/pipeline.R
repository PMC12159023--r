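# End-to-end orchestration: survey -> indicators -> health index / levels ->
# level summaries -> thresholds and change rates -> Mantel screen.

#' Pipeline configuration
#'
#' @param generator A [generator_config()] (used unless `input_dir` is set).
#' @param input_dir Optional directory of `plots.csv`/`quadrats.csv` to read
#'   instead of generating.
#' @param k Number of disturbance levels (>= 2).
#' @param span,degree,grid_size Loess settings for threshold extraction.
#' @param tolerance Negligible-difference cutoff for threshold adoption.
#' @param top_quantile Highest-density stratum quantile for change rates.
#' @param n_permutations Mantel permutations (>= 99).
#' @param seed Master seed for all stochastic stages.
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(generator = generator_config(),
                            input_dir = NULL, k = 4, span = 0.75,
                            degree = 2, grid_size = 512, tolerance = 0.005,
                            top_quantile = 0.9, n_permutations = 999,
                            seed = 1L, out_dir = NULL) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (n_permutations < 99) stop("need at least 99 permutations",
                                call. = FALSE)
  if (seed != round(seed)) stop("seed must be an integer", call. = FALSE)
  structure(list(generator = generator, input_dir = input_dir, k = k,
                 span = span, degree = degree, grid_size = grid_size,
                 tolerance = tolerance, top_quantile = top_quantile,
                 n_permutations = n_permutations, seed = as.integer(seed),
                 out_dir = out_dir), class = "pipeline_config")
}

#' Per-level metric summaries
#'
#' For every (grassland type, disturbance level, metric): sample size, mean
#' and standard error, plus a flag marking the level at which each metric's
#' mean peaks within a type.  The SE of a single-plot level is reported as
#' `NA`.
#'
#' @param indicators Plot-indicator data frame.
#' @param levels Factor of disturbance levels aligned to `indicators`.
#' @return Long data frame: `type`, `level`, `metric`, `n`, `mean`, `se`,
#'   `is_peak_level`.
#' @export
level_summary <- function(indicators, levels) {
  mets <- indicator_columns()[c("SW", "SR", "AB", "CH", "VC", "HB")]
  rows <- list()
  for (ty in unique(indicators$type)) {
    sel <- indicators$type == ty
    for (met in names(mets)) {
      v <- indicators[sel, mets[[met]]]
      lv <- droplevels(levels[sel])
      means <- tapply(v, lv, mean)
      ns <- tapply(v, lv, length)
      ses <- tapply(v, lv, function(z)
        if (length(z) > 1) stats::sd(z) / sqrt(length(z)) else NA_real_)
      peak_level <- names(means)[which.max(means)]
      rows[[paste(ty, met)]] <- data.frame(
        type = ty, level = names(means), metric = met,
        n = as.integer(ns), mean = as.numeric(means), se = as.numeric(ses),
        is_peak_level = names(means) == peak_level,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$type, out$metric, out$level), ]
}

analyse_type <- function(ind_ty, cfg) {
  g <- ghi_analysis(ind_ty, k = cfg$k)
  dec <- extract_thresholds(ind_ty, span = cfg$span, degree = cfg$degree,
                            grid_size = cfg$grid_size,
                            tolerance = cfg$tolerance)
  geo <- geodesic_distance_matrix(ind_ty$lat, ind_ty$lon, ind_ty$plot_id)
  mem <- dbmem(geo)
  preds <- list(MEM = mem, EH = ind_ty$effective_holes)
  for (cv in intersect(c("amt", "ap", "toc", "ph"), names(ind_ty)))
    preds[[toupper(cv)]] <- ind_ty[[cv]]
  mt <- lapply(c(SW = "shannon", SR = "richness"), function(col) {
    mantel_screen(scalar_distance_matrix(ind_ty[[col]], ind_ty$plot_id),
                  preds, n_permutations = cfg$n_permutations,
                  seed = substream_seed(cfg$seed, ind_ty$type[1], col))
  })
  mantel_tab <- do.call(rbind, lapply(names(mt), function(rn)
    cbind(response = rn, mt[[rn]])))
  list(ghi = g, thresholds = dec, mem = mem, mantel = mantel_tab)
}

#' Run the full disturbance-response pipeline
#'
#' Generates (or reads) the survey, computes plot indicators, and then —
#' independently per grassland type — builds the health index and
#' disturbance levels, summarises metrics by level, extracts the
#' diversity-density thresholds, computes the relative change-rate table,
#' and screens spatial/climate/soil/disturbance predictors of diversity by
#' Mantel tests.  Identical config (and seed) reproduces the report exactly;
#' when `out_dir` is set all intermediate tables are written as CSV plus a
#' `report.json`.
#'
#' @param config A [pipeline_config()].
#' @return A `pika_report` list: `indicators`, per-type `ghi` results,
#'   `levels`, `level_summary`, `thresholds`, `change_rates`, `mantel`,
#'   `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  survey <- if (!is.null(config$input_dir)) read_survey(config$input_dir)
            else generate_survey(config$generator)
  ind <- plot_indicators(survey)
  types <- unique(ind$type)
  per_type <- lapply(types, function(ty)
    analyse_type(ind[ind$type == ty, , drop = FALSE], config))
  names(per_type) <- types
  levels_all <- factor(rep(NA_character_, nrow(ind)),
                       levels = levels(per_type[[1]]$ghi$levels))
  for (ty in types)
    levels_all[ind$type == ty] <- per_type[[ty]]$ghi$levels
  report <- structure(list(
    indicators = ind,
    ghi = lapply(per_type, `[[`, "ghi"),
    levels = levels_all,
    level_summary = level_summary(ind, levels_all),
    thresholds = lapply(per_type, `[[`, "thresholds"),
    change_rates = change_table(ind, levels_all,
                                top_quantile = config$top_quantile),
    mantel = do.call(rbind, lapply(types, function(ty)
      cbind(type = ty, per_type[[ty]]$mantel))),
    mem = lapply(per_type, `[[`, "mem"),
    provenance = list(seed = config$seed, k = config$k, span = config$span,
                      degree = config$degree,
                      n_permutations = config$n_permutations,
                      generated = is.null(config$input_dir),
                      version = as.character(utils::packageVersion("pikathresh")))),
    class = "pika_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir, survey)
  report
}

#' Serialize a pipeline report
#'
#' Writes `plot_indicators.csv`, `ghi_scores.csv`, `ghi_model.json`,
#' `thresholds.csv`, `change_rates.csv`, `mantel_results.csv`,
#' `level_summary.csv`, `mem_basis.csv` and a machine-readable
#' `report.json` under `dir`.
#'
#' @param report A `pika_report`.
#' @param dir Output directory.
#' @param survey Optional survey to write alongside (via [write_survey()]).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, survey = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(survey)) write_survey(survey, file.path(dir, "survey"))
  w <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                        row.names = FALSE)
  w(report$indicators, "plot_indicators.csv")
  scores <- do.call(rbind, lapply(names(report$ghi), function(ty) {
    g <- report$ghi[[ty]]
    data.frame(plot_id = names(g$scores), type = ty, ghi = unname(g$scores),
               level = as.character(g$levels), stringsAsFactors = FALSE)
  }))
  w(scores, "ghi_scores.csv")
  thr <- do.call(rbind, lapply(report$thresholds, function(d)
    data.frame(type = d$grassland_type,
               metric = names(d$candidates), peak = unname(d$candidates),
               adopted = d$adopted, principle = d$principle,
               stringsAsFactors = FALSE)))
  w(thr, "thresholds.csv")
  w(report$change_rates, "change_rates.csv")
  w(report$mantel, "mantel_results.csv")
  w(report$level_summary, "level_summary.csv")
  mem_tab <- do.call(rbind, lapply(names(report$mem), function(ty) {
    v <- report$mem[[ty]]$vectors
    data.frame(plot_id = rownames(v), type = ty, axis = rep(colnames(v),
               each = nrow(v)), value = as.vector(v),
               stringsAsFactors = FALSE)
  }))
  w(mem_tab, "mem_basis.csv")
  model <- lapply(report$ghi, function(g) list(
    weights = as.list(g$weights), kmo = g$kmo,
    bartlett = g$bartlett,
    orientations = as.list(g$indicator_matrix$orientations),
    eigenvalues = g$pca$eigenvalues, retained = g$pca$retained))
  jsonlite::write_json(model, file.path(dir, "ghi_model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report_to_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# lossless-enough plain-list view of a report for JSON round-tripping
report_to_list <- function(report) {
  list(
    provenance = report$provenance,
    ghi = lapply(report$ghi, function(g) list(
      weights = as.list(g$weights), kmo = g$kmo, bartlett = g$bartlett,
      scores = as.list(g$scores),
      levels = as.character(g$levels))),
    thresholds = lapply(report$thresholds, function(d) list(
      type = d$grassland_type, candidates = as.list(d$candidates),
      adopted = d$adopted, principle = d$principle,
      relative_difference = d$relative_difference)),
    change_rates = report$change_rates,
    level_summary = report$level_summary,
    mantel = report$mantel)
}

#' @export
print.pika_report <- function(x, ...) {
  cat("Pika disturbance-response report:", nrow(x$indicators), "plots (",
      paste(names(x$ghi), collapse = ", "), ")\n")
  for (ty in names(x$thresholds)) {
    d <- x$thresholds[[ty]]
    cat("  ", ty, ": adopted threshold ", round(d$adopted, 1),
        " holes/ha [", d$principle, "]\n", sep = "")
  }
  cat("Change rates (%):\n")
  print(cbind(x$change_rates[1], round(x$change_rates[-1], 2)))
  invisible(x)
}
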