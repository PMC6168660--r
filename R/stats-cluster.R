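#' Cluster-based permutation test on paired channel differences
#'
#' One-sample topographic test in the Maris-Oostenveld style: a
#' per-channel one-sample t statistic is computed on the subject x
#' channel difference matrix; channels with |t| above the critical
#' value at \code{cluster_alpha} (df = n - 1) are grouped into
#' same-sign clusters connected under a distance-based adjacency graph;
#' each cluster's mass is the sum of its |t| values. The null
#' distribution of the maximum cluster mass is built from
#' \code{n_perm} seeded random sign flips of whole subjects, and each
#' observed cluster's p value is the proportion of the null at or
#' above its mass (with the +1 permutation convention, so p is in
#' (0, 1\]).
#'
#' @param diff Numeric matrix, subjects x channels, of paired
#'   condition differences (n >= 5 subjects).
#' @param positions channels x 3 electrode positions (see
#'   \code{\link{montage_positions}}).
#' @param alpha Cluster significance level (default 0.05).
#' @param cluster_alpha Channel inclusion threshold (default 0.05).
#' @param n_perm Number of sign-flip permutations (>= 500; default
#'   5000).
#' @param seed RNG seed for the permutations.
#' @param adjacency_prop Neighborhood radius as a fraction of the
#'   maximum inter-electrode distance (default 0.4).
#' @return An object of class \code{topography_result}: list with
#'   \code{t} (per-channel t values), \code{mean_diff},
#'   \code{clusters} (data.frame: cluster, sign, mass, p, significant,
#'   channels as a comma-joined label string), \code{cluster_channels}
#'   (list of integer vectors), \code{adjacency}, \code{alpha},
#'   \code{n_perm}.
#' @export
cluster_permutation_test <- function(diff, positions, alpha = 0.05,
                                     cluster_alpha = 0.05, n_perm = 5000,
                                     seed = 1, adjacency_prop = 0.4) {
  diff <- as.matrix(diff)
  n <- nrow(diff); n_ch <- ncol(diff)
  if (n < 5) stop("need at least 5 subjects")
  if (n_perm < 500) stop("precision error: need n_perm >= 500")
  if (nrow(positions) != n_ch)
    stop("channel error: positions must cover every channel")

  adj <- channel_adjacency(positions, prop = adjacency_prop)
  comps_all <- connected_components(seq_len(n_ch), adj)
  if (length(comps_all) > 1)
    warning("electrode montage is disconnected under the adjacency rule")

  tcrit <- qt(1 - cluster_alpha / 2, df = n - 1)
  ss <- colSums(diff^2) # invariant under sign flips

  t_of_means <- function(mn) {
    v <- (ss - n * mn^2) / (n - 1)
    v[v <= 0] <- NA # constant column after flip; treat as no evidence
    tt <- mn / sqrt(v / n)
    tt[!is.finite(tt)] <- 0
    tt
  }

  max_cluster_mass <- function(tt) {
    out <- 0
    for (sgn in c(1, -1)) {
      supra <- which(sgn * tt > tcrit)
      if (length(supra) == 0) next
      for (comp in connected_components(supra, adj)) {
        mass <- sum(abs(tt[comp]))
        if (mass > out) out <- mass
      }
    }
    out
  }

  t_obs <- t_of_means(colMeans(diff))

  clusters <- list()
  chans <- list()
  for (sgn in c(1, -1)) {
    supra <- which(sgn * t_obs > tcrit)
    if (length(supra) == 0) next
    for (comp in connected_components(supra, adj)) {
      clusters[[length(clusters) + 1L]] <-
        data.frame(sign = sgn, mass = sum(abs(t_obs[comp])))
      chans[[length(chans) + 1L]] <- comp
    }
  }

  null_max <- with_rng(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), nrow = n_perm)
    M <- (S %*% diff) / n
    vapply(seq_len(n_perm), function(i) max_cluster_mass(t_of_means(M[i, ])),
           numeric(1))
  })

  if (length(clusters)) {
    cl <- do.call(rbind, clusters)
    cl$p <- vapply(cl$mass,
                   function(ms) (1 + sum(null_max >= ms)) / (1 + n_perm),
                   numeric(1))
    cl$significant <- cl$p < alpha
    labs <- rownames(positions)
    cl$channels <- vapply(chans, function(ix) {
      if (is.null(labs)) paste(ix, collapse = ",")
      else paste(labs[ix], collapse = ",")
    }, character(1))
    cl <- cbind(cluster = seq_len(nrow(cl)), cl)
  } else {
    cl <- data.frame(cluster = integer(0), sign = numeric(0),
                     mass = numeric(0), p = numeric(0),
                     significant = logical(0), channels = character(0))
  }

  structure(list(t = t_obs, mean_diff = colMeans(diff), clusters = cl,
                 cluster_channels = chans, adjacency = adj,
                 alpha = alpha, cluster_alpha = cluster_alpha,
                 n_perm = n_perm),
            class = "topography_result")
}

#' @export
print.topography_result <- function(x, ...) {
  cat(sprintf("<topography_result> %d channels, %d cluster(s), %d permutations\n",
              length(x$t), nrow(x$clusters), x$n_perm))
  if (nrow(x$clusters)) {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %d (%s): mass %.2f, p = %.4f%s\n",
                  i, if (x$clusters$sign[i] > 0) "+" else "-",
                  x$clusters$mass[i], x$clusters$p[i],
                  if (x$clusters$significant[i]) " *" else ""))
  } else cat("  no supra-threshold channels\n")
  invisible(x)
}
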