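# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own code paths.

# All permutations of 1:n as rows (n small).
perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
}

# Exact two-sided Wilcoxon rank-sum p-value by enumerating every assignment
# of m of the m+n pooled ranks to the first sample (tie-free data only).
wilcoxon_enum_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(m)])
  combos <- utils::combn(length(pooled), m)
  Ws <- apply(combos, 2, function(ix) sum(r[ix]))
  mu <- m * (length(pooled) + 1) / 2
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}

# Mantel r for a permutation of the second matrix (plain arithmetic).
mantel_r_perm <- function(A, B, ix) {
  ut <- upper.tri(A)
  Bp <- B[ix, ix]
  stats::cor(A[ut], Bp[ut])
}

# Greedy Ward agglomeration on 1-D points: repeatedly merge the pair of
# clusters with the smallest within-cluster sum-of-squares increase.
# Returns the list of partitions (membership vectors) from n clusters to 1.
ward_greedy_partitions <- function(x) {
  members <- as.list(seq_along(x))
  partitions <- list()
  repeat {
    memb <- integer(length(x))
    for (i in seq_along(members)) memb[members[[i]]] <- i
    partitions[[length(members)]] <- memb
    if (length(members) == 1) break
    best <- c(Inf, NA, NA)
    for (a in seq_along(members)) for (b in seq_len(a - 1)) {
      na <- length(members[[a]]); nb <- length(members[[b]])
      d <- na * nb / (na + nb) *
        (mean(x[members[[a]]]) - mean(x[members[[b]]]))^2
      if (d < best[1]) best <- c(d, b, a)
    }
    members[[best[2]]] <- c(members[[best[2]]], members[[best[3]]])
    members[[best[3]]] <- NULL
  }
  partitions
}

# Do two membership vectors describe the same partition?
same_partition <- function(a, b) {
  identical(unname(split(seq_along(a), a)[order(sapply(split(seq_along(a), a), min))]),
            unname(split(seq_along(b), b)[order(sapply(split(seq_along(b), b), min))]))
}

# Leading eigenpairs of a symmetric matrix by power iteration + deflation.
power_eigen <- function(M, k = nrow(M), iters = 10000, tol = 1e-12) {
  vals <- numeric(0); vecs <- NULL
  A <- M
  for (j in seq_len(k)) {
    v <- rep(1, nrow(A)) / sqrt(nrow(A))
    for (i in seq_len(iters)) {
      v2 <- A %*% v
      nv <- sqrt(sum(v2^2))
      if (nv < tol) break
      v2 <- v2 / nv
      if (sum(abs(v2 - v)) < tol || sum(abs(v2 + v)) < tol) { v <- v2; break }
      v <- v2
    }
    lam <- drop(t(v) %*% A %*% v)
    vals <- c(vals, lam); vecs <- cbind(vecs, v)
    A <- A - lam * v %*% t(v)
  }
  list(values = vals, vectors = vecs)
}

# Small survey config used when test speed matters more than realism.
tiny_config <- function(seed = 1L, ...) {
  generator_config(n_plots_AM = 8L, n_plots_AS = 7L, spatial_extent = 30,
                   seed = seed, ...)
}
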