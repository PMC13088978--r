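# Independent brute-force oracles used to validate the package's optimized
# implementations on small instances. These are written as plain loops over
# first principles and share no code path with the functions they check.

# Greedy MaxMin by exhaustive recomputation of all pairwise min-distances at
# every step; ties broken by smallest id.
oracle_maxmin <- function(fps, k, first_index) {
  ids <- rownames(fps)
  n <- nrow(fps)
  picked <- first_index
  while (length(picked) < k) {
    best <- NULL
    best_d <- -1
    for (i in setdiff(seq_len(n), picked)) {
      di <- min(vapply(picked, function(p) {
        a <- fps[i, ] > 0
        b <- fps[p, ] > 0
        u <- sum(a | b)
        if (u == 0) 0 else 1 - sum(a & b) / u
      }, numeric(1)))
      if (di > best_d ||
          (di == best_d && ids[i] < ids[best])) {
        best <- i
        best_d <- di
      }
    }
    picked <- c(picked, best)
  }
  ids[picked]
}

# Exhaustive sphere-exclusion clustering: neighbor counts from the full
# pairwise distance matrix, centroids in order of descending neighbor count
# (ties by id), each absorbing its unassigned neighbors.
oracle_sphere_exclusion <- function(fps, cutoff) {
  ids <- rownames(fps)
  n <- nrow(fps)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- fps[i, ] > 0
      b <- fps[j, ] > 0
      u <- sum(a | b)
      d[i, j] <- if (u == 0) 0 else 1 - sum(a & b) / u
    }
  }
  neighbors <- lapply(seq_len(n), function(i) {
    setdiff(which(d[i, ] <= cutoff), i)
  })
  counts <- lengths(neighbors)
  ord <- order(-counts, ids, method = "radix")
  assigned <- rep(0L, n)
  cl <- 0L
  for (i in ord) {
    if (assigned[i] > 0) next
    cl <- cl + 1L
    members <- c(i, neighbors[[i]][assigned[neighbors[[i]]] == 0])
    assigned[members] <- cl
  }
  stats::setNames(assigned, ids)
}

# Inflection of a noiseless logistic melt model from a dense (0.01 degC)
# grid: the midpoint of the steepest discrete rise.
oracle_dense_tm <- function(tm_true, amplitude = 1, baseline = 0, width = 2,
                            lo = 25, hi = 95) {
  t <- seq(lo, hi, by = 0.01)
  f <- baseline + amplitude / (1 + exp(-(t - tm_true) / width))
  i <- which.max(diff(f))
  (t[i] + t[i + 1]) / 2
}

# Random 0/1 fingerprint matrix with rownames.
random_fps <- function(n, bits, density = 0.3, prefix = "F") {
  m <- matrix(rbinom(n * bits, 1, density), n, bits)
  rownames(m) <- sprintf("%s%03d", prefix, seq_len(n))
  m
}

# A small abstract two-motif campaign for loop tests (fast; n defaults low).
small_campaign <- function(seed = 1, n = 400, ...) {
  generate_library(synth_config(n_compounds = n, seed = seed, ...))
}
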