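# Grassland health index: min-max standardization, sampling-adequacy
# diagnostics, PCA-derived weights, composite scores and disturbance levels.

#' Default indicator orientations for the health index
#'
#' All indicators are "higher is healthier" except effective burrow density
#' (`EH`), which is reversed: more active burrow entrances mean a more
#' disturbed, less healthy plot.
#'
#' @return Named character vector, `"positive"` or `"reverse"` per indicator
#'   (VC, AB, EH, CH, SR, HB, SW).
#' @export
default_orientations <- function() {
  c(VC = "positive", AB = "positive", EH = "reverse", CH = "positive",
    SR = "positive", HB = "positive", SW = "positive")
}

# canonical column-abbreviation <-> indicator-column mapping
indicator_columns <- function() {
  c(SW = "shannon", SR = "richness", AB = "biomass", CH = "height",
    VC = "cover", HB = "edible_proportion", EH = "effective_holes")
}

#' Min-max standardize an indicator matrix
#'
#' Positively oriented columns map `x -> (x - min) / (max - min)`; reversed
#' columns map `x -> (max - x) / (max - min)`, so that after standardization
#' every column lies in `[0, 1]` with 1 = healthiest.  Zero-variance columns
#' cannot be scaled and are dropped with a warning.
#'
#' @param raw Numeric matrix or data frame, rows = plots.
#' @param orientations Named character vector (`"positive"`/`"reverse"`)
#'   covering every column of `raw`; see [default_orientations()].
#' @return An `indicator_matrix`: list with `values` (matrix in `[0,1]`),
#'   `orientations`, and `dropped` (names of zero-variance columns).
#' @export
min_max_standardize <- function(raw, orientations) {
  raw <- as.matrix(raw)
  if (nrow(raw) < 2) stop("need at least 2 plots to standardize",
                          call. = FALSE)
  if (!all(colnames(raw) %in% names(orientations)))
    stop("missing orientation for: ",
         paste(setdiff(colnames(raw), names(orientations)), collapse = ", "),
         call. = FALSE)
  rng <- apply(raw, 2, range)
  flat <- rng[2, ] - rng[1, ] == 0
  if (any(flat))
    warning("dropping zero-variance indicator(s): ",
            paste(colnames(raw)[flat], collapse = ", "), call. = FALSE)
  keep <- which(!flat)
  vals <- sapply(keep, function(j) {
    v <- (raw[, j] - rng[1, j]) / (rng[2, j] - rng[1, j])
    if (orientations[[colnames(raw)[j]]] == "reverse") 1 - v else v
  })
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(rownames(raw), colnames(raw)[keep]))
  structure(list(values = vals,
                 orientations = orientations[colnames(vals)],
                 dropped = colnames(raw)[flat]),
            class = "indicator_matrix")
}

cor_from <- function(x, R = NULL) {
  if (!is.null(R)) return(as.matrix(R))
  x <- if (inherits(x, "indicator_matrix")) x$values else as.matrix(x)
  stats::cor(x)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO: `sum(r_ij^2) / (sum(r_ij^2) + sum(q_ij^2))` over off-diagonal
#' pairs, where `r` are simple correlations and `q` the anti-image partial
#' correlations `-S_ij / sqrt(S_ii S_jj)` from `S = R^{-1}`.  Values near 1
#' indicate data well suited to factoring/PCA; 0.5 is the floor attained by
#' any two-variable dataset.
#'
#' @param x Data matrix (rows = observations) or an `indicator_matrix`.
#'   Ignored when `R` is given.
#' @param R Optional correlation matrix supplied directly.
#' @return KMO statistic in `[0, 1]`.
#' @export
kmo <- function(x, R = NULL) {
  R <- cor_from(x, R)
  if (nrow(R) < 2) stop("KMO needs at least 2 variables", call. = FALSE)
  S <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is singular (near-collinear indicators: ",
         paste(colnames(R), collapse = ", "), ")", call. = FALSE))
  q <- -S / sqrt(diag(S) %o% diag(S))
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(q[off]^2))
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is an identity (no shared structure):
#' `chi2 = -(n - 1 - (2p + 5)/6) * ln det(R)` on `p(p-1)/2` degrees of
#' freedom.
#'
#' @param x Data matrix or `indicator_matrix`; ignored when `R` is given.
#' @param R Optional correlation matrix (requires `n`).
#' @param n Number of observations (taken from `x` when omitted).
#' @return List with `chi2`, `df`, `p`.
#' @export
bartlett_sphericity <- function(x, R = NULL, n = NULL) {
  if (is.null(n)) {
    xm <- if (inherits(x, "indicator_matrix")) x$values else as.matrix(x)
    n <- nrow(xm)
  }
  R <- cor_from(x, R)
  p <- ncol(R)
  if (n <= p) stop("need more observations than variables", call. = FALSE)
  detR <- det(R)
  if (detR <= 0)
    stop("correlation matrix is not positive definite", call. = FALSE)
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' PCA-derived indicator weights
#'
#' Eigendecomposes the correlation matrix of the standardized indicators,
#' retains components with eigenvalue above `eigenvalue_threshold` (Kaiser
#' rule; at least one component always retained), and weights each indicator
#' by the variance-explained-weighted sum of its absolute loadings over the
#' retained components, normalized to sum to 1.
#'
#' @param im An `indicator_matrix` (or plain numeric matrix).
#' @param eigenvalue_threshold Retention cutoff on eigenvalues (default 1).
#' @return List with `weights` (named, nonnegative, summing to 1),
#'   `eigenvalues`, `loadings`, `retained` (component indices), and
#'   `variance_explained`.
#' @export
pca_weights <- function(im, eigenvalue_threshold = 1) {
  v <- if (inherits(im, "indicator_matrix")) im$values else as.matrix(im)
  if (ncol(v) < 2) stop("need at least 2 indicators", call. = FALSE)
  if (nrow(v) < 3) stop("need at least 3 plots", call. = FALSE)
  R <- stats::cor(v)
  e <- eigen(R, symmetric = TRUE)
  lambda <- e$values
  retained <- which(lambda > eigenvalue_threshold)
  if (length(retained) == 0) retained <- 1L
  loadings <- e$vectors %*% diag(sqrt(pmax(lambda, 0)))
  dimnames(loadings) <- list(colnames(v), paste0("PC", seq_along(lambda)))
  varexp <- lambda / sum(lambda)
  w <- as.vector(abs(loadings[, retained, drop = FALSE]) %*% varexp[retained])
  w <- w / sum(w)
  names(w) <- colnames(v)
  list(weights = w, eigenvalues = lambda, loadings = loadings,
       retained = retained, variance_explained = varexp)
}

#' Composite grassland health index scores
#'
#' `GHI = sum_i v_i w_i`: the weighted sum of the standardized indicators.
#' With weights summing to 1 and indicators in `[0, 1]`, scores lie in
#' `[0, 1]` (1 = healthiest).
#'
#' @param im An `indicator_matrix`.
#' @param weights Named weight vector aligned to the retained columns.
#' @return Named numeric vector of per-plot scores.
#' @export
ghi_score <- function(im, weights) {
  v <- if (inherits(im, "indicator_matrix")) im$values else as.matrix(im)
  if (length(weights) != ncol(v) ||
      (!is.null(names(weights)) && !identical(names(weights), colnames(v))))
    stop("weights are not aligned to the indicator columns", call. = FALSE)
  drop(v %*% weights)
}

#' Classify plots into disturbance levels I-IV
#'
#' Ward (`ward.D2`) agglomerative clustering of the one-dimensional health
#' scores (Euclidean distance), cut at `k` clusters; clusters are labelled
#' `I..IV` in order of decreasing mean score, so level I is the healthiest
#' ("no significant disturbance") and level IV the most heavily disturbed.
#'
#' @param scores Numeric health-index scores.
#' @param k Number of levels (default 4).
#' @return Factor of roman-numeral levels, one per plot, with attribute
#'   `"hclust"` carrying the linkage object.
#' @export
classify_disturbance <- function(scores, k = 4) {
  if (length(unique(scores)) < k)
    stop("fewer than k = ", k, " distinct scores; use a smaller k",
         call. = FALSE)
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  means <- tapply(scores, cl, mean)
  ord <- order(-means, as.integer(names(means)))  # ties -> lower cluster id
  lab <- as.roman(seq_len(k))
  levels_out <- factor(as.character(lab[match(cl, as.integer(names(means))[ord])]),
                       levels = as.character(lab))
  attr(levels_out, "hclust") <- hc
  levels_out
}

#' Full health-index analysis for one set of plots
#'
#' Standardizes the seven indicators, computes KMO and Bartlett diagnostics,
#' derives PCA weights, scores every plot and classifies disturbance levels.
#'
#' @param indicators Plot-indicator data frame (see [plot_indicators()]).
#' @param orientations See [default_orientations()].
#' @param k Number of disturbance levels.
#' @param eigenvalue_threshold Kaiser retention cutoff for [pca_weights()].
#' @return A `ghi_result` list: `indicator_matrix`, `weights`, `kmo`,
#'   `bartlett`, `scores`, `levels`, `pca`.
#' @export
ghi_analysis <- function(indicators, orientations = default_orientations(),
                         k = 4, eigenvalue_threshold = 1) {
  cols <- indicator_columns()
  raw <- as.matrix(indicators[, cols])
  colnames(raw) <- names(cols)
  rownames(raw) <- indicators$plot_id
  im <- min_max_standardize(raw, orientations)
  pw <- pca_weights(im, eigenvalue_threshold)
  scores <- ghi_score(im, pw$weights)
  levels <- classify_disturbance(scores, k = k)
  structure(list(indicator_matrix = im, weights = pw$weights,
                 kmo = kmo(im), bartlett = bartlett_sphericity(im),
                 scores = scores, levels = levels, pca = pw),
            class = "ghi_result")
}

#' @export
print.ghi_result <- function(x, ...) {
  cat("Grassland health index (", length(x$scores), " plots)\n", sep = "")
  cat("  KMO =", round(x$kmo, 3),
      " Bartlett chi2 =", round(x$bartlett$chi2, 2),
      " (p =", format.pval(x$bartlett$p, digits = 3), ")\n")
  cat("  weights:\n")
  print(round(x$weights, 4))
  print(table(levels = x$levels))
  invisible(x)
}
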