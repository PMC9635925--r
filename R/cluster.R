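#' Sphere-exclusion (Butina) clustering of hit structures
#'
#' Groups compounds by fingerprint similarity with the greedy
#' sphere-exclusion rule: build neighbour lists at Tanimoto similarity
#' `>= cutoff`, then repeatedly take the unassigned compound with the most
#' unassigned neighbours as a cluster centroid and assign it together with
#' those neighbours. Ties on neighbour count break lexicographically on
#' compound id, which makes the result independent of input order. Every
#' member of a cluster has similarity `>= cutoff` to its centroid.
#'
#' Clusters smaller than `min_report_size` are retained in the full
#' membership table but reported as unclustered in the summary view — the
#' convention used when reporting "major" clusters of screening hits.
#'
#' @param x A `fingerprint_set` from [fingerprint_compounds()], or a
#'   symmetric similarity matrix with compound ids as dimnames.
#' @param cutoff Similarity threshold for neighbourhood (default 0.6).
#' @param min_report_size Minimum members for a cluster to count as major
#'   (default 3, inclusive).
#' @return A `cluster_set`: tibble with columns `compound_id`, `cluster`
#'   (integer, in order of extraction), `is_centroid`, `sim_to_centroid`,
#'   `is_major`; attributes hold `cutoff` and `min_report_size`. Use
#'   [glance.cluster_set()] for the summary counts and
#'   [tidy.cluster_set()] for per-cluster rows.
#' @examples
#' sim <- diag(4)
#' dimnames(sim) <- list(letters[1:4], letters[1:4])
#' sim["a", "b"] <- sim["b", "a"] <- 0.8
#' cluster_butina(sim, cutoff = 0.6)
#' @export
cluster_butina <- function(x, cutoff = 0.6, min_report_size = 3L) {
  sim <- if (inherits(x, "fingerprint_set")) tanimoto_matrix(x) else as.matrix(x)
  if (nrow(sim) != ncol(sim)) abort("Similarity matrix must be square.")
  ids <- rownames(sim) %||% as.character(seq_len(nrow(sim)))
  if (anyDuplicated(ids)) abort("Compound ids must be unique.")
  n <- nrow(sim)
  # canonical processing order: lexicographic on id
  ord <- order(ids)
  sim <- sim[ord, ord, drop = FALSE]
  ids <- ids[ord]
  neighbours <- lapply(seq_len(n), function(i) {
    which(sim[i, ] >= cutoff & seq_len(n) != i)
  })
  assigned <- rep(FALSE, n)
  cluster <- rep(NA_integer_, n)
  centroid <- rep(FALSE, n)
  sim_to_centroid <- rep(NA_real_, n)
  k <- 0L
  while (any(!assigned)) {
    counts <- vapply(seq_len(n), function(i) {
      if (assigned[i]) -1L else length(neighbours[[i]][!assigned[neighbours[[i]]]])
    }, integer(1))
    c_i <- which.max(counts)   # first max = lexicographically smallest id
    k <- k + 1L
    members <- c(c_i, neighbours[[c_i]][!assigned[neighbours[[c_i]]]])
    assigned[members] <- TRUE
    cluster[members] <- k
    centroid[c_i] <- TRUE
    sim_to_centroid[members] <- sim[c_i, members]
    sim_to_centroid[c_i] <- 1
  }
  out <- tibble::tibble(
    compound_id = ids, cluster = cluster, is_centroid = centroid,
    sim_to_centroid = sim_to_centroid
  )
  sizes <- table(out$cluster)
  out$is_major <- as.vector(sizes[as.character(out$cluster)]) >= min_report_size
  out <- dplyr::arrange(out, .data$cluster, dplyr::desc(.data$is_centroid),
                        .data$compound_id)
  structure(out, class = c("cluster_set", class(out)),
            cutoff = cutoff, min_report_size = as.integer(min_report_size))
}

#' @export
#' @method tidy cluster_set
#' @rdname cluster_butina
#' @param ... Unused.
tidy.cluster_set <- function(x, ...) {
  x |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      centroid = .data$compound_id[.data$is_centroid],
      n_members = dplyr::n(),
      is_major = .data$is_major[1L],
      mean_sim_to_centroid = mean(.data$sim_to_centroid),
      members = list(.data$compound_id),
      .groups = "drop"
    )
}

#' @export
#' @method glance cluster_set
#' @rdname cluster_butina
glance.cluster_set <- function(x, ...) {
  per <- tidy.cluster_set(x)
  tibble::tibble(
    n_compounds = nrow(x),
    n_clusters = nrow(per),
    n_major_clusters = sum(per$is_major),
    n_in_major = sum(per$n_members[per$is_major]),
    n_unclustered = sum(per$n_members[!per$is_major]),
    cutoff = attr(x, "cutoff"),
    min_report_size = attr(x, "min_report_size")
  )
}
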