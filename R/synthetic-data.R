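# Seeded synthetic plot/quadrat survey generator.
#
# The generator emulates the statistical structure of a two-type alpine
# grassland survey: 30 alpine meadow (AM) and 26 alpine steppe (AS) plots of
# 1 ha, three quadrats each, with seven disturbance-related community metrics
# responding to an effective-burrow-density gradient.  Diversity metrics
# follow rise-then-fall (Gaussian bump) curves with type-specific peak
# locations; community height declines monotonically.  It simulates survey
# tables only — no pika population dynamics or soil processes.

#' Expected metric value under a rise-then-fall disturbance response
#'
#' Gaussian-bump response curve used by the synthetic survey generator:
#' `baseline + amplitude * exp(-(density - peak)^2 / (2 * width^2))`.
#' The maximum is attained exactly at `density = peak`, encoding the
#' hump-shaped (intermediate-disturbance) pattern of diversity along a
#' burrow-density gradient.
#'
#' @param density Burrow-entrance density, effective holes/ha (vectorised).
#' @param baseline Metric value far from the peak, in metric units.
#' @param amplitude Height of the bump above baseline, in metric units.
#' @param peak Density at which the response is maximal, holes/ha.
#' @param width Gaussian width of the bump, holes/ha; must be positive.
#' @return Expected metric value, same length as `density`.
#' @examples
#' hump_response(300, baseline = 1, amplitude = 2, peak = 300, width = 120)
#' @export
hump_response <- function(density, baseline, amplitude, peak, width) {
  stopifnot_scalar_number(width, "width", min = 0, strict = TRUE)
  baseline + amplitude * exp(-(density - peak)^2 / (2 * width^2))
}

# Monotone logistic decline: ~ baseline + amplitude at zero density, decaying
# to baseline; `peak` is reused as the inflection midpoint.
decline_response <- function(density, baseline, amplitude, peak, width) {
  stopifnot_scalar_number(width, "width", min = 0, strict = TRUE)
  baseline + amplitude * stats::plogis(-(density - peak) / width)
}

response_value <- function(par, density) {
  f <- if (identical(par$direction, "monotone-decreasing")) decline_response
       else hump_response
  f(density, par$baseline, par$amplitude, par$peak, par$width)
}

resp <- function(baseline, amplitude, peak, width, noise_sd,
                 direction = "rise-then-fall") {
  list(baseline = baseline, amplitude = amplitude, peak = peak,
       width = width, noise_sd = noise_sd, direction = direction)
}

#' Configuration for the synthetic survey generator
#'
#' Defaults mirror the field design the package targets: 30 AM + 26 AS plots
#' of 1 ha with at least 1 km spacing within a grassland type, three quadrats
#' per plot, and an effective-burrow-density gradient spanning 0-1200
#' holes/ha.  Default response curves place the AS diversity peaks
#' (Shannon ~217, richness ~307 holes/ha) well below the AM peaks (~680,
#' ~683), with height declining monotonically in both types.
#'
#' @param n_plots_AM,n_plots_AS Plot counts per grassland type.
#' @param quadrats_per_plot Quadrats surveyed per plot.
#' @param density_range Length-2 gradient of effective holes/ha.
#' @param responses Nested list `responses$AM$shannon` etc.; each entry a list
#'   with `baseline`, `amplitude`, `peak`, `width`, `noise_sd`, `direction`
#'   (`"rise-then-fall"` or `"monotone-decreasing"`).  Metrics: `shannon`,
#'   `richness`, `biomass`, `height`, `cover`, `edible`.
#' @param species_pool_size Size of the per-type species pool.
#' @param edible_fraction Probability that a pool species is edible forage.
#' @param spatial_extent Side of the square sampling region, km.
#' @param min_spacing Minimum within-type distance between plots, km.
#' @param individuals_per_quadrat Multinomial total per quadrat (counted
#'   individuals); controls sampling noise on Shannon.
#' @param seed Master seed; every draw uses a sub-stream hashed from it.
#' @return A `pika_config` list.
#' @export
generator_config <- function(n_plots_AM = 30L,
                             n_plots_AS = 26L,
                             quadrats_per_plot = 3L,
                             density_range = c(0, 1200),
                             responses = default_responses(),
                             species_pool_size = 120L,
                             edible_fraction = 0.5,
                             spatial_extent = 60,
                             min_spacing = 1,
                             individuals_per_quadrat = 250L,
                             seed = 1L) {
  for (nm in c("n_plots_AM", "n_plots_AS", "quadrats_per_plot"))
    stopifnot_scalar_number(get(nm), nm, min = 1)
  if (length(density_range) != 2L || any(density_range < 0) ||
      diff(density_range) <= 0)
    stop("`density_range` must be an ordered nonnegative interval",
         call. = FALSE)
  stopifnot_scalar_number(edible_fraction, "edible_fraction", min = 0)
  if (edible_fraction > 1) stop("`edible_fraction` must be in [0, 1]",
                                call. = FALSE)
  stopifnot_scalar_number(min_spacing, "min_spacing", min = 0, strict = TRUE)
  stopifnot_scalar_number(spatial_extent, "spatial_extent", min = 0,
                          strict = TRUE)
  for (ty in c("AM", "AS")) for (m in names(responses[[ty]])) {
    p <- responses[[ty]][[m]]
    if (p$width <= 0 || p$noise_sd < 0)
      stop("invalid response parameters for ", ty, "/", m, call. = FALSE)
  }
  structure(list(
    n_plots_AM = as.integer(n_plots_AM), n_plots_AS = as.integer(n_plots_AS),
    quadrats_per_plot = as.integer(quadrats_per_plot),
    density_range = as.numeric(density_range), responses = responses,
    species_pool_size = as.integer(species_pool_size),
    edible_fraction = edible_fraction, spatial_extent = spatial_extent,
    min_spacing = min_spacing,
    individuals_per_quadrat = as.integer(individuals_per_quadrat),
    seed = as.integer(seed)), class = "pika_config")
}

#' Default per-type response curves
#'
#' Encodes the qualitative study conditions: AS diversity peaks near 217
#' (Shannon) and 307 (richness) holes/ha, AM near 680/683; biomass peaks at
#' moderate disturbance; height declines monotonically; AM cover is maximal
#' undisturbed while AS cover peaks at low disturbance.
#'
#' @return Nested list of response parameter sets, `$AM`/`$AS` by metric.
#' @export
default_responses <- function() {
  list(
    AM = list(
      shannon  = resp(1.60, 0.60, 680, 250, 0.08),
      richness = resp(12.0, 6.00, 683, 250, 0.00),
      biomass  = resp(180., 120., 600, 250, 20.0),
      height   = resp(4.00, 12.0, 500, 150, 1.00, "monotone-decreasing"),
      cover    = resp(0.55, 0.40, 500, 200, 0.05, "monotone-decreasing"),
      edible   = resp(0.35, 0.25, 250, 200, 0.05)),
    AS = list(
      shannon  = resp(0.90, 0.50, 217, 120, 0.08),
      richness = resp(6.00, 4.00, 307, 130, 0.00),
      biomass  = resp(60.0, 40.0, 300, 150, 8.00),
      height   = resp(2.00, 7.00, 300, 100, 0.80, "monotone-decreasing"),
      cover    = resp(0.25, 0.15, 150, 150, 0.04),
      edible   = resp(0.30, 0.20, 300, 150, 0.05)))
}

#' Rejection-sample plot coordinates with a minimum spacing
#'
#' Draws `n` points uniformly in a lat/lon box of side `extent_km` anchored at
#' (`origin_lat`, `origin_lon`), rejecting candidates closer than
#' `min_spacing` km (haversine) to any accepted point.  Deterministic given
#' `seed`; each point is bounded at `max_attempts` rejections.
#'
#' @param n Number of points.
#' @param origin_lat,origin_lon South-west corner, decimal degrees (WGS84).
#' @param extent_km Box side length, km.
#' @param min_spacing Minimum pairwise distance, km.
#' @param seed Integer seed.
#' @param max_attempts Rejection budget per point.
#' @return Data frame with columns `lat`, `lon`.
#' @export
generate_coordinates <- function(n, origin_lat = 34, origin_lon = 102,
                                 extent_km = 60, min_spacing = 1, seed = 1L,
                                 max_attempts = 10000L) {
  stopifnot_scalar_number(n, "n", min = 1)
  # necessary packing condition: n disks of radius spacing/2 must fit the box
  if (n * pi * (min_spacing / 2)^2 > extent_km^2)
    stop("cannot place ", n, " points at ", min_spacing, " km spacing in a ",
         extent_km, " km box", call. = FALSE)
  dlat <- extent_km / 111.19493
  dlon <- extent_km / (111.19493 * cos(origin_lat * pi / 180))
  with_substream(substream_seed(seed, "coords"), {
    lat <- numeric(0); lon <- numeric(0)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        la <- origin_lat + stats::runif(1) * dlat
        lo <- origin_lon + stats::runif(1) * dlon
        if (i == 1L || all(haversine_km(la, lo, lat, lon) >= min_spacing)) {
          lat <- c(lat, la); lon <- c(lon, lo); ok <- TRUE; break
        }
      }
      if (!ok) stop("coordinate capacity: failed to place point ", i,
                    " after ", max_attempts, " attempts", call. = FALSE)
    }
    data.frame(lat = lat, lon = lon)
  })
}

haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

# Symmetric-Dirichlet concentration whose expected entropy matches `target`
# nats for S species: E[H] = digamma(S*a + 1) - digamma(a + 1).
dirichlet_alpha_for_entropy <- function(S, target) {
  if (S <= 1L) return(1)
  hmax <- log(S)
  target <- min(max(target, 1e-6), 0.985 * hmax)
  f <- function(a) digamma(S * a + 1) - digamma(a + 1) - target
  if (f(1e-4) >= 0) return(1e-4)
  if (f(5e4) <= 0) return(5e4)
  stats::uniroot(f, c(1e-4, 5e4), tol = 1e-10)$root
}

#' Generate a complete synthetic survey dataset
#'
#' Produces the plot table (coordinates, grassland type, effective burrow
#' density, climate/soil covariates) and the long-format quadrat table
#' (per-species abundances with edibility flags plus cover, height and
#' biomass).  Burrow densities are stratified-uniform across
#' `density_range` within each type so the gradient is always covered.
#' Quadrat communities are drawn species-first: richness ~ truncated Poisson
#' around its response curve, relative abundances ~ Dirichlet with the
#' concentration solved so expected Shannon entropy matches its curve, then
#' multinomial counts; edible relative abundance is tilted to its curve.
#' Identical config (including seed) gives an identical dataset, and each
#' type's draws are independent sub-streams.
#'
#' @param config A [generator_config()] list.
#' @return A `pika_survey` list with elements `plots`, `quadrats`, `config`.
#' @export
generate_survey <- function(config = generator_config()) {
  if (!inherits(config, "pika_config"))
    stop("`config` must come from generator_config()", call. = FALSE)
  origins <- list(AM = c(lat = 33.8, lon = 102.0),
                  AS = c(lat = 38.5, lon = 95.5))
  covariate_means <- list(  # type means for AMT (deg C), AP (mm), TOC, pH
    AM = c(amt = 1.05, ap = 660.7, toc = 4.69, ph = 6.69),
    AS = c(amt = -1.90, ap = 154.9, toc = 1.31, ph = 6.70))
  covariate_sd <- c(amt = 0.6, ap = 30, toc = 0.8, ph = 0.3)

  plots <- list(); quads <- list()
  for (ty in c("AM", "AS")) {
    n <- if (ty == "AM") config$n_plots_AM else config$n_plots_AS
    rs <- config$responses[[ty]]
    ids <- sprintf("%s%02d", ty, seq_len(n))
    xy <- generate_coordinates(n, origins[[ty]]["lat"], origins[[ty]]["lon"],
                               config$spatial_extent, config$min_spacing,
                               seed = substream_seed(config$seed, ty))
    dr <- config$density_range
    holes <- with_substream(substream_seed(config$seed, ty, "holes"),
      dr[1] + (seq_len(n) - stats::runif(n)) / n * diff(dr))
    covs <- with_substream(substream_seed(config$seed, ty, "covariates"), {
      m <- covariate_means[[ty]]
      data.frame(amt = stats::rnorm(n, m["amt"], covariate_sd["amt"]),
                 ap  = pmax(0, stats::rnorm(n, m["ap"], covariate_sd["ap"])),
                 toc = pmax(0.05, stats::rnorm(n, m["toc"],
                                               covariate_sd["toc"])),
                 ph  = stats::rnorm(n, m["ph"], covariate_sd["ph"]))
    })
    plots[[ty]] <- data.frame(plot_id = ids, type = ty,
                              lat = xy$lat, lon = xy$lon,
                              effective_holes = holes, covs,
                              stringsAsFactors = FALSE)
    pool_edible <- with_substream(substream_seed(config$seed, ty, "pool"),
      stats::runif(config$species_pool_size) < config$edible_fraction)
    for (i in seq_len(n)) {
      # per-plot species pool sized to the richness curve, so that pooling
      # the quadrats recovers approximately the configured plot richness
      mu_sr <- max(response_value(rs$richness, holes[i]), 0.5)
      pool_n <- min(config$species_pool_size, max(1L, round(1.05 * mu_sr)))
      plot_pool <- with_substream(substream_seed(config$seed, ty, ids[i],
                                                 "plotpool"),
        sample.int(config$species_pool_size, pool_n))
      for (q in seq_len(config$quadrats_per_plot)) {
        quads[[paste(ids[i], q)]] <- simulate_quadrat(
          config, ty, ids[i], sprintf("Q%d", q), holes[i], rs, pool_edible,
          plot_pool)
      }
    }
  }
  structure(list(plots = do.call(rbind, c(plots, make.row.names = FALSE)),
                 quadrats = do.call(rbind, c(quads, make.row.names = FALSE)),
                 config = config),
            class = "pika_survey")
}

simulate_quadrat <- function(config, ty, plot_id, quadrat_id, d, rs,
                             pool_edible, plot_pool) {
  ss <- function(what) substream_seed(config$seed, ty, plot_id, quadrat_id,
                                      what)
  clamp01 <- function(x) pmin(1, pmax(0, x))
  cover <- with_substream(ss("cover"), clamp01(
    response_value(rs$cover, d) + stats::rnorm(1, 0, rs$cover$noise_sd)))
  height <- with_substream(ss("height"), pmax(0,
    response_value(rs$height, d) + stats::rnorm(1, 0, rs$height$noise_sd)))
  biomass <- with_substream(ss("biomass"), pmax(0,
    response_value(rs$biomass, d) + stats::rnorm(1, 0, rs$biomass$noise_sd)))

  # species composition: richness, then evenness-tuned relative abundances;
  # quadrat richness targets ~0.7 of the plot curve so the pooled union of
  # the quadrats lands near the configured plot-level richness
  mu_sr <- max(response_value(rs$richness, d), 0.5)
  S <- with_substream(ss("richness"),
                      max(1L, stats::rpois(1, 0.7 * mu_sr)))
  S <- min(S, length(plot_pool))
  species <- with_substream(ss("species"), {
    ix <- sample.int(length(plot_pool), S)
    plot_pool[ix]
  })
  h_target <- with_substream(ss("shannon"), max(0,
    response_value(rs$shannon, d) + stats::rnorm(1, 0, rs$shannon$noise_sd)))
  alpha <- dirichlet_alpha_for_entropy(S, h_target)
  p <- with_substream(ss("dirichlet"), {
    g <- stats::rgamma(S, shape = alpha)
    if (all(g == 0)) g <- rep(1, S)
    g / sum(g)
  })
  # tilt edible relative abundance toward its response curve
  e_target <- with_substream(ss("edible"), clamp01(
    response_value(rs$edible, d) + stats::rnorm(1, 0, rs$edible$noise_sd)))
  ed <- pool_edible[species]
  m <- sum(p[ed])
  if (m > 0 && m < 1) {
    e_target <- min(max(e_target, 0.02), 0.98)
    p[ed] <- p[ed] * e_target / m
    p[!ed] <- p[!ed] * (1 - e_target) / (1 - m)
  }
  counts <- with_substream(ss("counts"), as.vector(
    stats::rmultinom(1, config$individuals_per_quadrat, p)))
  if (all(counts == 0)) counts[1] <- 1L
  keep <- counts > 0
  data.frame(plot_id = plot_id, quadrat_id = quadrat_id,
             species_id = sprintf("sp%03d", species[keep]),
             abundance = counts[keep], edible = ed[keep],
             cover = cover, height_cm = height, biomass_g_m2 = biomass,
             stringsAsFactors = FALSE)
}

#' Write a survey to plain-text files
#'
#' Writes `plots.csv`, `quadrats.csv` and `provenance.json` (config echo and
#' seed) under `dir`.
#'
#' @param survey A `pika_survey` from [generate_survey()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "pika_survey"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(survey$plots, file.path(dir, "plots.csv"),
                   row.names = FALSE)
  utils::write.csv(survey$quadrats, file.path(dir, "quadrats.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(survey$config),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a survey written by [write_survey()]
#'
#' @param dir Directory containing `plots.csv` and `quadrats.csv`.
#' @return A `pika_survey` list (config echoed from `provenance.json` when
#'   present).
#' @export
read_survey <- function(dir) {
  plots <- utils::read.csv(file.path(dir, "plots.csv"),
                           stringsAsFactors = FALSE)
  quadrats <- utils::read.csv(file.path(dir, "quadrats.csv"),
                              stringsAsFactors = FALSE)
  cfg <- NULL
  pj <- file.path(dir, "provenance.json")
  if (file.exists(pj))
    cfg <- jsonlite::read_json(pj, simplifyVector = TRUE)
  structure(list(plots = plots, quadrats = quadrats, config = cfg),
            class = "pika_survey")
}
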