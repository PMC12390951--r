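# Cluster-based permutation tests ----------------------------------------
#
# Nonparametric family-wise control for time courses (temporal clusters:
# contiguous supra-threshold samples) and channel maps (spatial clusters:
# connected components of the channel neighbour graph). The null is built
# by participant-level sign flips of the paired differences, the exact
# permutation scheme for a within-subject contrast; cluster mass is the
# sum of pointwise t values and the permutation p compares observed mass
# against the null distribution of the maximal mass.

#' Cluster-test configuration
#'
#' @param n_permutations Sign-flip draws (default 5000).
#' @param alpha_cluster_forming Pointwise threshold for cluster membership.
#' @param alpha_final Significance level for cluster p values.
#' @param min_neighbors Neighbour-definition parameter of the spatial
#'   test; 1 permits singleton clusters (set `min_cluster_size = 2` to
#'   require company).
#' @param min_cluster_size Minimum members for a reported cluster.
#' @param neighbor_radius_mm Radius of the channel neighbour graph; NULL
#'   uses [default_neighbor_radius()] of the montage at hand.
#' @param exhaustive "auto" enumerates all 2^n sign patterns when that is
#'   no more than `n_permutations` (n <= 12); "never"/"always" force it.
#' @param seed RNG seed for sampled permutations.
#' @return A `cluster_config`.
#' @export
cluster_config <- function(n_permutations = 5000L,
                           alpha_cluster_forming = 0.05,
                           alpha_final = 0.05,
                           min_neighbors = 1L,
                           min_cluster_size = 1L,
                           neighbor_radius_mm = NULL,
                           exhaustive = c("auto", "never", "always"),
                           seed = 1L) {
  stopifnot(n_permutations >= 1,
            alpha_cluster_forming > 0, alpha_cluster_forming < 1,
            alpha_final > 0, alpha_final < 1)
  structure(list(n_permutations = as.integer(n_permutations),
                 alpha_cluster_forming = alpha_cluster_forming,
                 alpha_final = alpha_final,
                 min_neighbors = as.integer(min_neighbors),
                 min_cluster_size = as.integer(min_cluster_size),
                 neighbor_radius_mm = neighbor_radius_mm,
                 exhaustive = match.arg(exhaustive),
                 seed = as.integer(seed)),
            class = "cluster_config")
}

# NA-aware pointwise one-sample t on rows = permutations
# d: n x p matrix of differences; flips: m x n of +-1
flip_t <- function(d, flips) {
  ok <- !is.na(d)
  d0 <- ifelse(ok, d, 0)
  n_eff <- colSums(ok)
  msq <- colSums(d0^2) / n_eff
  m <- (flips %*% d0) / rep(n_eff, each = nrow(flips))
  v <- (rep(msq, each = nrow(flips)) - m^2) * rep(n_eff / (n_eff - 1),
                                                  each = nrow(flips))
  m / sqrt(v / rep(n_eff, each = nrow(flips)))
}

sign_flip_matrix <- function(n, config) {
  exhaustive <- switch(config$exhaustive,
                       always = TRUE,
                       never = FALSE,
                       auto = n <= 12 && 2^n <= config$n_permutations)
  if (exhaustive) {
    m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    dimnames(m) <- NULL
    m
  } else {
    set.seed(config$seed)
    matrix(sample(c(-1, 1), config$n_permutations * n, replace = TRUE),
           config$n_permutations, n)
  }
}

# contiguous same-sign supra-threshold runs; returns list of index vectors
temporal_clusters <- function(tval, tcrit) {
  state <- ifelse(is.na(tval), 0L, ifelse(tval > tcrit, 1L,
                                          ifelse(tval < -tcrit, -1L, 0L)))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values != 0), function(k) starts[k]:ends[k])
}

max_cluster_mass <- function(tval, tcrit, clusterer, ...) {
  cl <- clusterer(tval, tcrit, ...)
  if (!length(cl)) return(0)
  max(vapply(cl, function(idx) abs(sum(tval[idx])), 0))
}

#' Temporal cluster-based permutation test
#'
#' Pointwise paired t (or one-sample vs `mu`) across participants, runs of
#' contiguous same-sign supra-threshold samples as clusters, summed t as
#' cluster mass, and a participant-level sign-flip null of the maximal
#' mass. With `y = NULL` the test contrasts `x` against the constant `mu`
#' (for baseline-corrected averages, the baseline mean of 0).
#'
#' @param x Participant x time matrix.
#' @param y Optional matching matrix for a paired contrast.
#' @param mu Null value for the one-sample form (default 0).
#' @param config A `cluster_config`.
#' @return A `cluster_result`: `t_map`, `threshold`, `clusters` (data
#'   frame: start, end, n_members, t_sum, p), `null_max`, `n_permutations`.
#' @export
temporal_cluster_test <- function(x, y = NULL, mu = 0,
                                  config = cluster_config()) {
  d <- if (is.null(y)) x - mu else x - y
  n <- nrow(d)
  if (n < 2) stop("need at least 2 participants")
  flips <- sign_flip_matrix(n, config)
  tmat <- flip_t(d, flips)
  n_eff <- colSums(!is.na(d))
  tcrit <- stats::qt(1 - config$alpha_cluster_forming / 2, n_eff - 1)
  t_obs <- flip_t(d, matrix(1, 1, n))[1, ]
  null_max <- vapply(seq_len(nrow(flips)), function(i)
    max_cluster_mass(tmat[i, ], tcrit, temporal_clusters), 0)
  cl <- temporal_clusters(t_obs, tcrit)
  cl <- cl[lengths(cl) >= config$min_cluster_size]
  clusters <- data.frame(start = integer(), end = integer(),
                         n_members = integer(), t_sum = numeric(),
                         p = numeric())
  for (idx in cl) {
    mass <- sum(t_obs[idx])
    p <- (1 + sum(null_max >= abs(mass))) / (1 + length(null_max))
    clusters <- rbind(clusters,
                      data.frame(start = min(idx), end = max(idx),
                                 n_members = length(idx), t_sum = mass,
                                 p = p))
  }
  structure(list(t_map = t_obs, threshold = tcrit, clusters = clusters,
                 null_max = null_max, n_permutations = nrow(flips)),
            class = "cluster_result")
}

# connected components of the supra-threshold subgraph, split by t sign
spatial_clusters <- function(tval, tcrit, adj) {
  comp_of <- function(nodes) {
    comps <- list()
    seen <- logical(length(tval))
    for (s in nodes) {
      if (seen[s]) next
      queue <- s
      seen[s] <- TRUE
      members <- integer(0)
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        members <- c(members, v)
        nb <- intersect(which(adj[v, ]), nodes)
        nb <- nb[!seen[nb]]
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
      comps[[length(comps) + 1L]] <- sort(members)
    }
    comps
  }
  pos <- which(!is.na(tval) & tval > tcrit)
  neg <- which(!is.na(tval) & tval < -tcrit)
  c(comp_of(pos), comp_of(neg))
}

#' Spatial cluster-based permutation test on channel maps
#'
#' Per-channel paired t between two participant x channel matrices
#' (e.g. rising slopes under the two conditions), clusters as connected
#' components of supra-threshold channels on the montage neighbour graph
#' (singletons allowed with min_neighbors = 1), sign-flip null of maximal
#' cluster mass. Channels with fewer than `min_n` contributing
#' participants are dropped from the map.
#'
#' @param a,b Participant x channel matrices (NAs allowed).
#' @param montage An `fnirs_montage` (defines the neighbour graph).
#' @param config A `cluster_config`.
#' @param min_n Minimum participants per channel (default 4).
#' @return A `cluster_result` with `clusters` (members as channel ids),
#'   `t_map`, `threshold`, `null_max`.
#' @export
spatial_cluster_test <- function(a, b, montage, config = cluster_config(),
                                 min_n = 4L) {
  stopifnot(dim(a) == dim(b))
  d <- a - b
  n <- nrow(d)
  if (n < 2) stop("need at least 2 participants")
  usable <- colSums(!is.na(d)) >= max(2L, min_n)
  d[, !usable] <- NA
  adj <- neighbor_matrix(montage, config$neighbor_radius_mm)
  flips <- sign_flip_matrix(n, config)
  tmat <- flip_t(d, flips)
  n_eff <- colSums(!is.na(d))
  tcrit <- stats::qt(1 - config$alpha_cluster_forming / 2,
                     pmax(n_eff - 1, 1))
  t_obs <- flip_t(d, matrix(1, 1, n))[1, ]
  null_max <- vapply(seq_len(nrow(flips)), function(i)
    max_cluster_mass(tmat[i, ], tcrit, spatial_clusters, adj), 0)
  cl <- spatial_clusters(t_obs, tcrit, adj)
  cl <- cl[lengths(cl) >= config$min_cluster_size]
  clusters <- data.frame()
  for (idx in cl) {
    mass <- sum(t_obs[idx])
    p <- (1 + sum(null_max >= abs(mass))) / (1 + length(null_max))
    clusters <- rbind(clusters,
                      data.frame(members = I(list(idx)),
                                 n_members = length(idx),
                                 t_sum = mass, p = p))
  }
  structure(list(t_map = t_obs, threshold = tcrit, clusters = clusters,
                 null_max = null_max, n_permutations = nrow(flips)),
            class = "cluster_result")
}

#' Significant clusters of a result
#' @param result A `cluster_result`.
#' @param alpha Significance level (default the 0.05 final threshold).
#' @return Subset of `result$clusters`.
#' @export
significant_clusters <- function(result, alpha = 0.05) {
  if (nrow(result$clusters) == 0) return(result$clusters)
  result$clusters[result$clusters$p < alpha, , drop = FALSE]
}
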