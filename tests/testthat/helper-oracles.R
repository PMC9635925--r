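# Independent oracle implementations used by unit and acceptance tests.
# These deliberately re-derive the algorithms from their definitions and
# must stay independent of the package internals they check.

# Alternating median sweeps (rows first, effect medians folded into the
# overall term), stopping when no effect moves more than tol.
brute_force_polish <- function(y, tol = 1e-9, max_iter = 500) {
  nr <- nrow(y)
  nc <- ncol(y)
  z <- y
  overall <- 0
  ro <- numeric(nr)
  co <- numeric(nc)
  for (k in seq_len(max_iter)) {
    old <- c(overall, ro, co)
    rm_ <- apply(z, 1, median)
    z <- z - rm_
    ro <- ro + rm_
    d <- median(co); co <- co - d; overall <- overall + d
    cm_ <- apply(z, 2, median)
    z <- sweep(z, 2, cm_)
    co <- co + cm_
    d <- median(ro); ro <- ro - d; overall <- overall + d
    if (max(abs(c(overall, ro, co) - old)) <= tol) break
  }
  list(overall = overall, row = ro, col = co, residuals = z)
}

# Greedy sphere-exclusion by direct enumeration over a similarity matrix:
# repeatedly pick the lexicographically first unassigned compound with the
# most unassigned neighbours at >= cutoff.
brute_force_butina <- function(sim, cutoff) {
  ids <- rownames(sim)
  ord <- order(ids)
  sim <- sim[ord, ord]
  ids <- ids[ord]
  unassigned <- ids
  clusters <- list()
  while (length(unassigned)) {
    counts <- vapply(unassigned, function(i) {
      sum(sim[i, setdiff(unassigned, i)] >= cutoff)
    }, numeric(1))
    centroid <- sort(unassigned[counts == max(counts)])[1]
    members <- c(centroid,
                 setdiff(unassigned[sim[centroid, unassigned] >= cutoff],
                         centroid))
    clusters[[length(clusters) + 1L]] <- list(centroid = centroid,
                                              members = sort(members))
    unassigned <- setdiff(unassigned, members)
  }
  clusters
}

# Random symmetric similarity matrix with unit diagonal.
random_sim <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(letters[1:n], letters[1:n])
  m
}
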