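# Per-quadrat community metrics and their plot-level aggregation.

#' Shannon-Wiener diversity index
#'
#' `H = -sum(p_i * ln p_i)` over species with positive abundance, where
#' `p_i` is the relative abundance of species i.  Reported in nats
#' (natural log); `H = 0` for a monoculture and `H = ln(S)` for a perfectly
#' even community of S species.
#'
#' @param abundances Nonnegative species abundances (counts or densities).
#' @return Shannon index H in nats.
#' @examples
#' shannon_wiener(c(5, 5, 5, 5))  # log(4)
#' @export
shannon_wiener <- function(abundances) {
  if (length(abundances) == 0 || any(abundances < 0) || !all(is.finite(abundances)))
    stop("abundances must be finite and nonnegative", call. = FALSE)
  tot <- sum(abundances)
  if (tot == 0) stop("empty community: all abundances are zero", call. = FALSE)
  p <- abundances[abundances > 0] / tot
  -sum(p * log(p))
}

#' Species richness
#'
#' Number of species with positive abundance.
#'
#' @inheritParams shannon_wiener
#' @return Integer count (0 for an empty vector).
#' @export
species_richness <- function(abundances) {
  sum(abundances > 0)
}

#' Proportion of edible forage
#'
#' Relative abundance of species flagged as edible forage:
#' `sum(abundances[edible]) / sum(abundances)`.
#'
#' @inheritParams shannon_wiener
#' @param edible_flags Logical vector, same length as `abundances`.
#' @return Proportion in `[0, 1]`.
#' @export
edible_proportion <- function(abundances, edible_flags) {
  if (length(abundances) != length(edible_flags))
    stop("`abundances` and `edible_flags` must have the same length",
         call. = FALSE)
  tot <- sum(abundances)
  if (length(abundances) == 0 || tot == 0)
    stop("empty community: cannot compute an edible proportion",
         call. = FALSE)
  sum(abundances[edible_flags]) / tot
}

#' Aggregate one plot's quadrats into plot-level indicators
#'
#' Continuous metrics (cover, height, biomass, Shannon H, edible proportion)
#' are arithmetic means over the plot's quadrats; richness is the number of
#' distinct species pooled across quadrats (the community species total, not
#' a mean).  Burrow density is plot-level metadata passed through.
#'
#' @param quadrats Long-format quadrat rows for a single plot: columns
#'   `plot_id`, `quadrat_id`, `species_id`, `abundance`, `edible`, `cover`,
#'   `height_cm`, `biomass_g_m2`.
#' @param effective_holes Effective burrow-entrance density, holes/ha.
#' @param type Grassland type label (`"AM"` or `"AS"`).
#' @return One-row data frame of plot indicators.
#' @export
aggregate_plot <- function(quadrats, effective_holes, type = NA_character_) {
  if (nrow(quadrats) == 0) stop("no quadrat rows supplied", call. = FALSE)
  if (length(unique(quadrats$plot_id)) != 1L)
    stop("quadrats span multiple plot_ids: ",
         paste(unique(quadrats$plot_id), collapse = ", "), call. = FALSE)
  per_q <- lapply(split(quadrats, quadrats$quadrat_id), function(q) {
    data.frame(shannon = shannon_wiener(q$abundance),
               edible_proportion = edible_proportion(q$abundance, q$edible),
               cover = q$cover[1], height = q$height_cm[1],
               biomass = q$biomass_g_m2[1])
  })
  per_q <- do.call(rbind, per_q)
  data.frame(plot_id = quadrats$plot_id[1], type = type,
             shannon = mean(per_q$shannon),
             richness = length(unique(quadrats$species_id[quadrats$abundance > 0])),
             biomass = mean(per_q$biomass), height = mean(per_q$height),
             cover = mean(per_q$cover),
             edible_proportion = mean(per_q$edible_proportion),
             effective_holes = effective_holes,
             stringsAsFactors = FALSE)
}

#' Plot-level indicator table for a whole survey
#'
#' Applies [aggregate_plot()] to every plot, joining in coordinates, type,
#' burrow density and any covariates from the plot table.
#'
#' @param survey A `pika_survey` (see [generate_survey()] / [read_survey()]).
#' @return Data frame with one row per plot: the seven health-index
#'   indicators plus `lat`, `lon` and covariate columns.
#' @export
plot_indicators <- function(survey) {
  stopifnot(inherits(survey, "pika_survey"))
  plots <- survey$plots
  rows <- lapply(seq_len(nrow(plots)), function(i) {
    q <- survey$quadrats[survey$quadrats$plot_id == plots$plot_id[i], ,
                         drop = FALSE]
    aggregate_plot(q, plots$effective_holes[i], plots$type[i])
  })
  ind <- do.call(rbind, rows)
  extra <- setdiff(names(plots), c("type", "effective_holes"))
  merge(ind, plots[, extra, drop = FALSE], by = "plot_id", sort = TRUE)
}
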