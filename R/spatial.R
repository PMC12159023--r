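# Spatial and permutation statistics: haversine distances, distance-based
# Moran's eigenvector maps, Moran's I, seeded Mantel tests, Wilcoxon
# rank-sum comparisons.

#' Geodesic (haversine) distance matrix in km
#'
#' Great-circle distances between plots on a sphere of radius 6371 km
#' (WGS84 decimal-degree coordinates).
#'
#' @param lat,lon Latitudes and longitudes, decimal degrees.
#' @param labels Optional plot ids for the dimnames.
#' @return Symmetric matrix of distances in km with zero diagonal.
#' @export
geodesic_distance_matrix <- function(lat, lon, labels = NULL) {
  if (length(lat) != length(lon)) stop("lat/lon lengths differ",
                                       call. = FALSE)
  if (any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("coordinates outside valid latitude/longitude ranges",
         call. = FALSE)
  d <- geosphere::distm(cbind(lon, lat),
                        fun = function(a, b)
                          geosphere::distHaversine(a, b, r = 6371000)) / 1000
  dimnames(d) <- list(labels, labels)
  d
}

#' Distance-based Moran's eigenvector maps (dbMEM)
#'
#' The classical principal-coordinates-of-neighbour-matrices construction:
#' the truncation distance is the longest edge of the minimum spanning tree
#' of the plot distance matrix; distances beyond it are replaced by four
#' times the truncation distance; the truncated matrix is Gower
#' double-centered as `-d^2/2`; its eigenvectors with eigenvalues above
#' `1e-9` of the largest are the MEM spatial variables, ordered by
#' decreasing eigenvalue (broad to fine spatial scales).
#'
#' @param D Distance matrix (km), as from [geodesic_distance_matrix()].
#' @param truncation Optional truncation distance override; defaults to the
#'   longest MST edge.
#' @return A `mem_basis`: list with `vectors` (plots x axes, orthonormal and
#'   centered, columns `MEM1..`), `values` (eigenvalues, decreasing) and
#'   `truncation`.
#' @export
dbmem <- function(D, truncation = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("dbMEM needs at least 3 plots", call. = FALSE)
  if (is.null(truncation)) {
    mst <- vegan::spantree(stats::as.dist(D))
    truncation <- max(mst$dist)
  }
  Dt <- D
  Dt[Dt > truncation] <- 4 * truncation
  diag(Dt) <- 0
  A <- -0.5 * Dt^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- which(e$values > 1e-9 * max(e$values))
  vectors <- e$vectors[, keep, drop = FALSE]
  dimnames(vectors) <- list(rownames(D), paste0("MEM", seq_along(keep)))
  structure(list(vectors = vectors, values = e$values[keep],
                 truncation = truncation), class = "mem_basis")
}

#' Moran's I spatial autocorrelation coefficient
#'
#' `I = (n / sum(W)) * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2`.  Positive values indicate spatial clustering of
#' similar values; the null expectation is `-1/(n - 1)`.
#'
#' @param values Numeric vector with nonzero variance.
#' @param W Nonnegative spatial weights matrix with zero diagonal.
#' @return Moran's I.
#' @export
morans_i <- function(values, W) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values", call. = FALSE)
  if (stats::var(values) == 0) stop("values have zero variance",
                                    call. = FALSE)
  W <- as.matrix(W)
  if (any(W < 0) || any(diag(W) != 0))
    stop("weights must be nonnegative with a zero diagonal", call. = FALSE)
  z <- values - mean(values)
  (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Mantel test between two distance matrices
#'
#' Correlates the strict upper triangles of two distance matrices and builds
#' the permutation null by simultaneously permuting the rows and columns of
#' the second matrix.  One-sided (positive-association) p by default:
#' `p = (1 + #{r_perm >= r_obs}) / (1 + n_permutations)`.  With
#' `exhaustive = TRUE` all `n!` relabelings are enumerated (n <= 8) and the
#' p-value is the exact proportion with `r_perm >= r_obs` (the identity
#' included).  Deterministic given `seed`.
#'
#' @param dist_a,dist_b Conformable distance matrices (or `dist` objects).
#' @param n_permutations Number of random permutations (default 999).
#' @param method `"pearson"` or `"spearman"`.
#' @param seed Integer seed for the permutation stream.
#' @param exhaustive Enumerate all relabelings instead of sampling.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A `mantel_result`: list with `r`, `p`, `n_permutations`, `method`,
#'   `seed`, `exhaustive`.
#' @export
mantel <- function(dist_a, dist_b, n_permutations = 999,
                   method = c("pearson", "spearman"), seed = 1L,
                   exhaustive = FALSE,
                   alternative = c("greater", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  A <- as.matrix(dist_a); B <- as.matrix(dist_b)
  if (!all(dim(A) == dim(B)))
    stop("distance matrices have different sizes", call. = FALSE)
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("distance matrices have different labels", call. = FALSE)
  n <- nrow(A)
  if (n < 4) stop("Mantel test needs at least 4 plots", call. = FALSE)
  ut <- upper.tri(A)
  stat <- function(Bp) stats::cor(A[ut], Bp[ut], method = method)
  r_obs <- stat(B)
  score <- function(r) if (alternative == "greater") r else abs(r)
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8",
                    call. = FALSE)
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1, function(ix) stat(B[ix, ix]))
    p <- mean(score(r_perm) >= score(r_obs) - 1e-12)
    n_permutations <- nrow(perms)
  } else {
    r_perm <- with_substream(substream_seed(seed, "mantel"), {
      vapply(seq_len(n_permutations), function(i) {
        ix <- sample.int(n)
        stat(B[ix, ix])
      }, numeric(1))
    })
    p <- (1 + sum(score(r_perm) >= score(r_obs) - 1e-12)) /
      (1 + n_permutations)
  }
  structure(list(r = r_obs, p = p, n_permutations = n_permutations,
                 method = method, seed = seed, exhaustive = exhaustive),
            class = "mantel_result")
}

#' Euclidean distance matrix from one or more plain variables
#'
#' @param x Numeric vector, matrix or data frame (rows = plots).
#' @param labels Optional row labels.
#' @return Symmetric distance matrix.
#' @export
scalar_distance_matrix <- function(x, labels = NULL) {
  d <- as.matrix(stats::dist(as.matrix(x)))
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  d
}

#' Mantel screen of several predictors against one response
#'
#' Runs one Mantel test per predictor distance matrix against the response
#' distance matrix.  Predictors given as plain vectors/matrices are converted
#' to Euclidean distance matrices; a `mem_basis` predictor is converted to
#' Euclidean distance in its retained MEM coordinates.  Significance is
#' binned (`p < 0.01`, `p < 0.05`, `ns`) without multiple-testing
#' correction.
#'
#' @param response_dist Response distance matrix.
#' @param predictors Named list of distance matrices, numeric variables, or
#'   `mem_basis` objects.
#' @param n_permutations,method,seed Passed to [mantel()]; each predictor
#'   gets its own seeded sub-stream.
#' @return Data frame: `predictor`, `r`, `p`, `sig`, `n_permutations`.
#' @export
mantel_screen <- function(response_dist, predictors, n_permutations = 999,
                          method = "pearson", seed = 1L) {
  labels <- rownames(as.matrix(response_dist))
  rows <- lapply(names(predictors), function(nm) {
    p <- predictors[[nm]]
    pd <- if (inherits(p, "mem_basis"))
            scalar_distance_matrix(p$vectors, labels)
          else if (is.matrix(p) && nrow(p) == ncol(p) &&
                   isTRUE(all.equal(unname(p), unname(t(p))))) p
          else scalar_distance_matrix(p, labels)
    m <- mantel(response_dist, pd, n_permutations = n_permutations,
                method = method, seed = substream_seed(seed, nm))
    data.frame(predictor = nm, r = m$r, p = m$p,
               sig = if (m$p < 0.01) "p<0.01" else if (m$p < 0.05) "p<0.05"
                     else "ns",
               n_permutations = m$n_permutations, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Wilcoxon rank-sum test
#'
#' `W` is the rank sum of the first sample (midranks under ties).  The
#' two-sided p-value is exact (full enumeration) when the pooled sample size
#' is at most `exact_limit` and tie-free, and otherwise uses the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Nonempty numeric samples.
#' @param exact_limit Largest pooled size for the exact p-value (default 16).
#' @return List with `W`, `p`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 16) {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be nonempty", call. = FALSE)
  r <- rank(c(x, y))
  W <- sum(r[seq_along(x)])
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_limit && !ties
  p <- if (exact)
    stats::wilcox.test(x, y, exact = TRUE)$p.value
  else
    suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  list(W = W, p = p, exact = exact)
}
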