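# Dominant-node identification: cosine similarity between per-scale
# diffusion profiles and the maturation map (spin-tested), the cross-scale
# conjunction map, and the rank-based alternative.

#' Dominance likelihood: cosine similarity of diffusion profiles to a map
#'
#' For node i and scale m, the cosine similarity between row i of the
#' symmetrized scale-m diffusion matrix (self entry included) and the
#' full maturation map. Vectors are used raw (uncentered); `centered = TRUE`
#' gives the Pearson-correlation variant.
#'
#' @param profiles a `diffusion_profiles`.
#' @param map numeric nodal map, not all zero.
#' @param centered center vectors before the cosine (correlation variant).
#' @param drop_self zero the self entry of each profile row first.
#' @return matrix nodes x scales of similarities in `[-1, 1]`.
#' @export
dominance_likelihood <- function(profiles, map, centered = FALSE,
                                 drop_self = FALSE) {
  v <- map_values(map)
  if (all(v == 0)) stop("map must not be all zero")
  n <- nrow(profiles$P)
  stopifnot(length(v) == n)
  out <- matrix(NA_real_, n, profiles$M)
  for (m in seq_len(profiles$M)) {
    x <- profiles$S_m[[m]]
    if (drop_self) diag(x) <- 0
    if (centered) {
      x <- x - rowMeans(x)
      vm <- v - mean(v)
    } else vm <- v
    rn <- sqrt(rowSums(x^2))
    if (any(rn == 0)) stop("zero-norm profile row encountered")
    out[, m] <- as.vector(x %*% vm) / (rn * sqrt(sum(vm^2)))
  }
  out
}

#' Dominant nodes by spin-tested dominance likelihood
#'
#' Per node and scale, compares the observed cosine similarity with
#' similarities recomputed against spin-surrogate maps (one shared spin
#' ensemble) and masks nodes at one-sided `p_spin < alpha`. The conjunction
#' map is the per-node fraction of scales at which the node is dominant.
#'
#' @param profiles a `diffusion_profiles`.
#' @param map numeric nodal map.
#' @param parcellation a `parcellation`.
#' @param n_spin number of spin surrogates.
#' @param alpha per-scale significance level.
#' @param seed integer RNG seed.
#' @param spin_assign optional precomputed [spin_assignments()].
#' @param centered,drop_self passed to [dominance_likelihood()].
#' @return object of class `dominance_result`: list with `likelihood`
#'   (nodes x scales), `p_spin`, `dominant_mask`, `conjunction`, `method`.
#' @export
dominant_nodes <- function(profiles, map, parcellation = profiles$parcellation,
                           n_spin = 1000, alpha = 0.05, seed = 1,
                           spin_assign = NULL, centered = FALSE,
                           drop_self = FALSE) {
  v <- map_values(map)
  lik <- dominance_likelihood(profiles, v, centered, drop_self)
  if (is.null(spin_assign))
    spin_assign <- spin_assignments(parcellation, n_spin, seed = seed)
  n_surr <- nrow(spin_assign)
  n <- nrow(lik)
  p <- matrix(NA_real_, n, profiles$M)
  vs <- apply(spin_assign, 1, function(a) {
    vv <- v[a]
    if (centered) vv - mean(vv) else vv
  })                                      # nodes x surrogates
  for (m in seq_len(profiles$M)) {
    x <- profiles$S_m[[m]]
    if (drop_self) diag(x) <- 0
    if (centered) x <- x - rowMeans(x)
    rn <- sqrt(rowSums(x^2))
    # null similarities for all nodes x surrogates in one product
    null_sim <- (x %*% vs) / (rn %o% sqrt(colSums(vs^2)))
    p[, m] <- (rowSums(null_sim >= lik[, m]) + 1) / (n_surr + 1)
  }
  mask <- p < alpha
  structure(list(likelihood = lik, p_spin = p, dominant_mask = mask,
                 conjunction = conjunction_map(mask),
                 method = "diffusion_cosine", alpha = alpha),
            class = "dominance_result")
}

#' Cross-scale conjunction map
#'
#' Per node, the fraction of neighboring scales at which the node is
#' dominant.
#'
#' @param masks logical matrix nodes x scales.
#' @return numeric vector in `[0, 1]`.
#' @export
conjunction_map <- function(masks) rowMeans(masks)

#' @export
print.dominance_result <- function(x, ...) {
  cat("dominance (", x$method, "): ", nrow(x$likelihood), " nodes x ",
      ncol(x$likelihood), " scales; ",
      sum(x$conjunction == 1), " node(s) dominant at every scale\n", sep = "")
  invisible(x)
}

#' Rank-based dominant-node identification
#'
#' Ranks the map and the neighbor-mean map in ascending order (average rank
#' for ties); the likelihood is the mean of the two ranks per node, so nodes
#' that are high both in their own maturation and their neighbors' lead. The
#' spin test recomputes mean ranks on surrogate maps; the mask keeps nodes
#' with one-sided `p_spin < alpha`.
#'
#' @param map numeric nodal map.
#' @param connectome a `connectome`.
#' @param parcellation a `parcellation`.
#' @param n_spin number of spin surrogates.
#' @param alpha significance level.
#' @param seed integer RNG seed.
#' @param spin_assign optional precomputed [spin_assignments()].
#' @return a `dominance_result` with method `"rank_based"` (single scale).
#' @export
rank_based_dominance <- function(map, connectome,
                                 parcellation = connectome$parcellation,
                                 n_spin = 1000, alpha = 0.05, seed = 1,
                                 spin_assign = NULL) {
  v <- map_values(map)
  mean_rank <- function(vv) {
    est <- neighbor_mean_estimate(vv, connectome)
    (ascending_rank(vv) + ascending_rank(est)) / 2
  }
  lik <- mean_rank(v)
  if (is.null(spin_assign))
    spin_assign <- spin_assignments(parcellation, n_spin, seed = seed)
  null_lik <- apply(spin_assign, 1, function(a) mean_rank(v[a]))  # n x n_surr
  p <- (rowSums(null_lik >= lik) + 1) / (ncol(null_lik) + 1)
  mask <- matrix(p < alpha, ncol = 1)
  structure(list(likelihood = matrix(lik, ncol = 1),
                 p_spin = matrix(p, ncol = 1), dominant_mask = mask,
                 conjunction = conjunction_map(mask),
                 method = "rank_based", alpha = alpha),
            class = "dominance_result")
}
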