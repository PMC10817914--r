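# Neighbor-constraint statistics: neighbor-mean maturation estimates and
# their correlation with the observed map, with confound-control variants
# and significance against spin and rewired nulls.

#' Neighbor-mean maturation estimate
#'
#' For each node, the mean map value over its directly connected graph
#' neighbors. Degree-0 nodes get NA and are flagged for exclusion downstream.
#'
#' @param map numeric nodal map (or `maturation_map`/`effect_map`).
#' @param connectome a `connectome` sharing the map's node order.
#' @return numeric vector of estimates, NA at degree-0 nodes.
#' @export
neighbor_mean_estimate <- function(map, connectome) {
  v <- map_values(map)
  a <- connectome$adjacency
  stopifnot(length(v) == nrow(a))
  deg <- rowSums(a)
  if (all(deg == 0)) stop("all nodes have degree 0")
  est <- as.vector(a %*% v) / deg
  est[deg == 0] <- NA_real_
  est
}

#' Constraint correlation between a map and its neighbor-mean estimate
#'
#' Pearson correlation between the observed nodal map and the neighbor-mean
#' estimate. Variants: `"excluded"` recomputes the estimate over graph
#' neighbors that are not spatial neighbors (nodes left without such a
#' neighbor are dropped); `"regressed"` residualizes the estimate on each
#' node's mean Euclidean distance to its graph neighbors before correlating.
#'
#' @param map numeric nodal map.
#' @param connectome a `connectome`.
#' @param variant one of "plain", "excluded", "regressed".
#' @param parcellation parcellation supplying the spatial-adjacency relation
#'   (required for "excluded"; defaults to the connectome's).
#' @return list with `r`, `estimate`, `used` (logical inclusion mask),
#'   `n_used`, `variant`.
#' @export
constraint_correlation <- function(map, connectome,
                                   variant = c("plain", "excluded", "regressed"),
                                   parcellation = NULL) {
  variant <- match.arg(variant)
  v <- map_values(map)
  if (is.null(parcellation)) parcellation <- connectome$parcellation
  a <- connectome$adjacency
  if (variant == "excluded") {
    if (is.null(parcellation)) stop("variant 'excluded' requires a parcellation")
    a <- a * (1 - 1 * parcellation$adjacency)
    diag(a) <- 0
  }
  deg <- rowSums(a)
  est <- as.vector(a %*% v) / pmax(deg, 1)
  est[deg == 0] <- NA_real_
  used <- deg > 0
  if (sum(used) < 10)
    stop("fewer than 10 usable nodes after neighbor exclusion")
  if (variant == "regressed") {
    full_deg <- rowSums(connectome$adjacency)
    md <- rowSums(connectome$adjacency * connectome$distance) / pmax(full_deg, 1)
    x <- md[used]
    if (var(x) < 1e-14) {
      est[used] <- est[used] - mean(est[used])
    } else {
      est[used] <- resid(lm(est[used] ~ x))
    }
  }
  r <- cor(v[used], est[used])
  list(r = r, estimate = est, used = used, n_used = sum(used),
       variant = variant)
}

#' Constraint correlation with spin and rewired significance
#'
#' Computes the observed constraint correlation and one-sided empirical
#' p-values against (1) spin surrogate maps (estimate recomputed from each
#' spun map) and (2) degree-preserving rewired surrogate networks (estimate
#' recomputed from the observed map on each surrogate network). The test
#' side follows the sign of the observed correlation.
#'
#' @param map numeric nodal map.
#' @param connectome a `connectome`.
#' @param parcellation a `parcellation`.
#' @param variant as in [constraint_correlation()].
#' @param n_spin,n_rewired surrogate counts (0 skips that null).
#' @param n_bins length bins for rewiring.
#' @param seed integer RNG seed.
#' @param spin_assign optional precomputed [spin_assignments()] matrix.
#' @param rewired optional precomputed [rewired_surrogates()] list.
#' @return list with `r`, `variant`, `n_used`, `p_spin`, `p_rewired`, and
#'   the null correlation vectors.
#' @export
constraint_test <- function(map, connectome, parcellation = connectome$parcellation,
                            variant = "plain", n_spin = 1000, n_rewired = 1000,
                            n_bins = 10, seed = 1, spin_assign = NULL,
                            rewired = NULL) {
  v <- map_values(map)
  obs <- constraint_correlation(v, connectome, variant, parcellation)
  side <- if (obs$r >= 0) "greater" else "less"
  null_spin <- null_rew <- NULL
  p_spin <- p_rew <- NA_real_
  if (n_spin > 0 || !is.null(spin_assign)) {
    if (is.null(spin_assign))
      spin_assign <- spin_assignments(parcellation, n_spin, seed = seed)
    null_spin <- apply(spin_assign, 1, function(a)
      constraint_correlation(v[a], connectome, variant, parcellation)$r)
    p_spin <- empirical_p(obs$r, null_spin, side)
  }
  if (n_rewired > 0 || !is.null(rewired)) {
    if (is.null(rewired))
      rewired <- rewired_surrogates(connectome, n_bins = n_bins, n = n_rewired,
                                    seed = seed + 1)
    null_rew <- vapply(rewired, function(cs)
      constraint_correlation(v, cs, variant, parcellation)$r, numeric(1))
    p_rew <- empirical_p(obs$r, null_rew, side)
  }
  list(r = obs$r, variant = variant, n_used = obs$n_used,
       p_spin = p_spin, p_rewired = p_rew,
       null_spin = null_spin, null_rewired = null_rew)
}
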