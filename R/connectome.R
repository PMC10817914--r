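# Binary structural connectomes: synthetic distance-dependent generation,
# the distance-binned consensus backbone, and nodal graph metrics.

#' Pairwise Euclidean distances between parcel centroids
#'
#' @param parcellation a `parcellation` object.
#' @return symmetric n x n matrix of Euclidean centroid distances.
#' @export
euclidean_distance_matrix <- function(parcellation) {
  as.matrix(dist(parcellation$centroids))
}

#' Construct a connectome from a binary adjacency matrix
#'
#' Validating constructor shared by the generators and readers; also handy
#' for building toy graphs.
#'
#' @param adjacency symmetric binary matrix with zero diagonal.
#' @param distance optional symmetric distance matrix.
#' @param parcellation optional `parcellation` (supplies distances).
#' @return a `connectome`.
#' @export
as_connectome <- function(adjacency, distance = NULL, parcellation = NULL) {
  adjacency <- 1 * (adjacency != 0)
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency must have a zero diagonal")
  if (is.null(distance) && !is.null(parcellation))
    distance <- euclidean_distance_matrix(parcellation)
  structure(list(adjacency = adjacency, distance = distance,
                 parcellation = parcellation),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$adjacency)
  e <- sum(x$adjacency) / 2
  cat("connectome:", n, "nodes,", e, "edges, density",
      round(2 * e / (n * (n - 1)), 4), "\n")
  invisible(x)
}

connectome_graph <- function(x) {
  igraph::graph_from_adjacency_matrix(x$adjacency, mode = "undirected")
}

stop_if_disconnected <- function(x, what = "this operation") {
  comp <- igraph::components(connectome_graph(x))
  if (comp$no > 1) {
    smallest <- which(comp$membership == which.min(comp$csize))
    stop(sprintf("graph is disconnected; %s requires a connected graph (smallest component: nodes %s)",
                 what, paste(smallest - 1L, collapse = ", ")))
  }
  invisible(x)
}

#' Generate a synthetic distance-dependent binary connectome
#'
#' Samples edges with probability proportional to
#' `exp(-d_ij / length_scale) * (1 + within_system_bonus * same_system)`,
#' scaled so the expected edge count matches `target_density`, then adds the
#' Euclidean minimum spanning tree so the graph is connected.
#'
#' @param parcellation a `parcellation`.
#' @param target_density edge density in (0, 1).
#' @param length_scale exponential decay length of wiring probability with
#'   Euclidean distance (same units as centroid coordinates).
#' @param within_system_bonus multiplicative preference for within-system
#'   edges (0 = none).
#' @param seed integer RNG seed.
#' @return a `connectome` with distances and the parcellation attached.
#' @export
gen_connectome <- function(parcellation, target_density = 0.08,
                           length_scale = 0.5, within_system_bonus = 4,
                           seed = 1) {
  stopifnot(target_density > 0, target_density < 1)
  if (length_scale <= 0) stop("length_scale must be positive")
  if (within_system_bonus < 0) stop("within_system_bonus must be >= 0")
  n <- parcellation$n
  d <- euclidean_distance_matrix(parcellation)
  same <- outer(parcellation$system, parcellation$system, "==")
  w <- exp(-d / length_scale) * (1 + within_system_bonus * same)
  ut <- upper.tri(w)
  wv <- w[ut]
  if (!any(wv > 0)) stop("no candidate edges: wiring weights are all zero")
  m_target <- round(target_density * sum(ut))
  # scale weights into clipped Bernoulli probabilities matching the target
  f <- function(cc) sum(pmin(1, cc * wv)) - m_target
  hi <- 1
  while (f(hi) < 0 && hi < 1e12) hi <- hi * 2
  cc <- uniroot(f, c(0, hi), tol = 1e-10)$root
  p <- pmin(1, cc * wv)
  with_seed(seed, {
    adj <- matrix(0, n, n)
    adj[ut] <- rbinom(length(p), 1, p)
    adj <- adj + t(adj)
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    mst <- igraph::as_edgelist(igraph::mst(g), names = FALSE)
    in_mst <- matrix(FALSE, n, n)
    for (k in seq_len(nrow(mst))) {
      adj[mst[k, 1], mst[k, 2]] <- adj[mst[k, 2], mst[k, 1]] <- 1
      in_mst[mst[k, 1], mst[k, 2]] <- in_mst[mst[k, 2], mst[k, 1]] <- TRUE
    }
    # the spanning tree pushes the count above target; trim non-tree edges
    excess <- sum(adj[ut]) - m_target
    if (excess > 0) {
      removable <- which(ut & adj == 1 & !in_mst)
      drop <- sample(removable, min(excess, length(removable)))
      adj[drop] <- 0
      adj[lower.tri(adj)] <- 0
      adj <- adj + t(adj)
    }
    as_connectome(adj, d, parcellation)
  })
}

# largest-remainder apportionment of `total` proportional to `weights`
apportion <- function(total, weights) {
  if (total == 0 || sum(weights) == 0) return(integer(length(weights)))
  raw <- total * weights / sum(weights)
  out <- floor(raw)
  rem <- total - sum(out)
  if (rem > 0) {
    take <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[take] <- out[take] + 1
  }
  as.integer(out)
}

# equal-frequency bin membership (1..n_bins) for lengths, given break vector
length_bins <- function(lengths, n_bins) {
  if (n_bins == 1) return(list(bin = rep(1L, length(lengths)),
                               breaks = c(-Inf, Inf)))
  br <- quantile(lengths, probs = seq(0, 1, length.out = n_bins + 1))
  br[1] <- -Inf; br[length(br)] <- Inf
  br <- unique(br)
  bin <- findInterval(lengths, br, left.open = TRUE, rightmost.closed = TRUE)
  list(bin = pmax(1L, as.integer(bin)), breaks = br)
}

#' Distance-binned consensus backbone of individual binary connectomes
#'
#' Builds a group-level binary network whose edge count equals the rounded
#' mean individual edge count and whose edge-length distribution matches the
#' individuals': candidate edges (present in at least one individual) are
#' partitioned into equal-frequency Euclidean-length bins, each bin receives
#' a quota equal to the mean individual edge count in that bin, and the
#' most-frequently-occurring edges fill each quota (ties broken by shorter
#' length, then lexicographic node pair). When hemisphere labels are
#' available, intra- and inter-hemispheric edge pools are binned separately.
#'
#' @param individuals list of symmetric binary adjacency matrices sharing a
#'   node order.
#' @param distances symmetric matrix of inter-node Euclidean distances.
#' @param n_bins number of equal-frequency length bins per pool.
#' @param hemispheres optional factor/character of per-node hemisphere labels.
#' @param split_hemispheres bin intra- and inter-hemispheric pools separately
#'   (default: yes whenever `hemispheres` is given).
#' @param parcellation optional `parcellation` to attach (supplies
#'   hemispheres and distances if missing).
#' @return a `connectome`; per-pool bin quotas are attached as
#'   `attr(, "bin_summary")`.
#' @export
consensus_backbone <- function(individuals, distances = NULL, n_bins = 10,
                               hemispheres = NULL, split_hemispheres = NULL,
                               parcellation = NULL) {
  if (length(individuals) < 2) stop("need at least 2 individual networks")
  if (!is.null(parcellation)) {
    if (is.null(distances)) distances <- euclidean_distance_matrix(parcellation)
    if (is.null(hemispheres)) hemispheres <- parcellation$hemisphere
  }
  if (n_bins < 1) stop("n_bins must be >= 1")
  n <- nrow(individuals[[1]])
  for (a in individuals) {
    if (!all(dim(a) == n)) stop("individual networks must share one shape")
    if (any(diag(a) != 0) || !isTRUE(all.equal(1 * (a != 0), t(1 * (a != 0)))))
      stop("individual networks must be symmetric with zero diagonal")
  }
  if (is.null(split_hemispheres)) split_hemispheres <- !is.null(hemispheres)
  if (split_hemispheres && is.null(hemispheres))
    stop("split_hemispheres requires hemisphere labels")

  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  freq <- Reduce(`+`, lapply(individuals, function(a) 1 * (a[upper.tri(a)] != 0)))
  cand <- which(freq > 0)
  if (length(cand) == 0) stop("empty candidate edge set")
  if (is.null(distances)) stop("distances are required")
  len <- distances[upper.tri(distances)]
  if (any(!is.finite(len[cand]))) stop("distances missing for a candidate edge")

  pool <- if (split_hemispheres) {
    ifelse(hemispheres[ut[, 1]] == hemispheres[ut[, 2]], "intra", "inter")
  } else rep("all", nrow(ut))

  n_subj <- length(individuals)
  subj_edges <- lapply(individuals, function(a) which(a[upper.tri(a)] != 0))
  total_target <- round(mean(lengths(subj_edges)))

  pools <- unique(pool[cand])
  pool_mean <- vapply(pools, function(pl) {
    mean(vapply(subj_edges, function(e) sum(pool[e] == pl), numeric(1)))
  }, numeric(1))
  pool_target <- apportion(total_target, pool_mean)

  keep <- integer(0)
  bin_summary <- list()
  for (pi in seq_along(pools)) {
    pl <- pools[pi]
    pc <- cand[pool[cand] == pl]
    lb <- length_bins(len[pc], n_bins)
    nb <- length(lb$breaks) - 1
    # mean individual edge count per bin (same breaks)
    bin_mean <- rep(0, nb)
    for (e in subj_edges) {
      ep <- e[pool[e] == pl]
      b <- findInterval(len[ep], lb$breaks, left.open = TRUE, rightmost.closed = TRUE)
      tb <- tabulate(pmax(1L, b), nbins = nb)
      bin_mean <- bin_mean + tb / n_subj
    }
    quota <- apportion(pool_target[pi], bin_mean)
    chosen <- integer(0)
    leftover <- 0
    for (b in seq_len(nb)) {
      eb <- pc[lb$bin == b]
      ord <- eb[order(-freq[eb], len[eb], ut[eb, 1], ut[eb, 2])]
      take <- min(quota[b], length(ord))
      leftover <- leftover + quota[b] - take
      chosen <- c(chosen, ord[seq_len(take)])
    }
    if (leftover > 0) {  # refill from best unselected candidates in this pool
      rest <- setdiff(pc, chosen)
      ord <- rest[order(-freq[rest], len[rest], ut[rest, 1], ut[rest, 2])]
      chosen <- c(chosen, ord[seq_len(min(leftover, length(ord)))])
    }
    keep <- c(keep, chosen)
    bin_summary[[pl]] <- data.frame(bin = seq_len(nb), quota = quota,
                                    candidates = tabulate(lb$bin, nb))
  }

  adj <- matrix(0, n, n)
  adj[cbind(ut[keep, 1], ut[keep, 2])] <- 1
  adj <- adj + t(adj)
  out <- as_connectome(adj, distances, parcellation)
  attr(out, "bin_summary") <- bin_summary
  out
}

#' Unweighted graph diameter
#'
#' Maximum over node pairs of the unweighted shortest-path length.
#'
#' @param connectome a connected `connectome`.
#' @return integer diameter.
#' @export
graph_diameter <- function(connectome) {
  stop_if_disconnected(connectome, "graph_diameter")
  as.integer(igraph::diameter(connectome_graph(connectome), weights = NA))
}

#' Nodal efficiency
#'
#' For node i, the mean over j != i of the inverse shortest-path length.
#'
#' @param connectome a `connectome`.
#' @return numeric vector, one value per node.
#' @export
nodal_efficiency <- function(connectome) {
  d <- igraph::distances(connectome_graph(connectome), weights = NA)
  diag(d) <- Inf
  rowSums(1 / d) / (nrow(d) - 1)
}

#' Nodal mean first passage time
#'
#' For node i, the mean over source nodes j != i of the expected number of
#' unbiased random-walk steps from j until first reaching i, obtained by
#' solving the first-step linear system (I - Q) h = 1 with the target state
#' removed.
#'
#' @param connectome a connected `connectome`.
#' @return numeric vector, one value per node.
#' @export
mean_first_passage_time <- function(connectome) {
  stop_if_disconnected(connectome, "mean_first_passage_time")
  p <- transition_matrix(connectome)
  n <- nrow(p)
  out <- numeric(n)
  for (i in seq_len(n)) {
    q <- p[-i, -i, drop = FALSE]
    h <- solve(diag(n - 1) - q, rep(1, n - 1))
    out[i] <- mean(h)
  }
  out
}

#' Participation coefficient
#'
#' `PC_i = 1 - sum_s (k_is / k_i)^2` over systems s, where `k_is` counts
#' edges from node i into system s. Degree-0 nodes return 0.
#'
#' @param connectome a `connectome`.
#' @param system_labels integer/factor of per-node system labels (defaults to
#'   the attached parcellation's systems).
#' @return numeric vector in `[0, 1 - 1/K]`.
#' @export
participation_coefficient <- function(connectome, system_labels = NULL) {
  if (is.null(system_labels)) system_labels <- connectome$parcellation$system
  if (is.null(system_labels)) stop("system labels are required")
  a <- connectome$adjacency
  deg <- rowSums(a)
  systems <- sort(unique(system_labels))
  ks <- sapply(systems, function(s) rowSums(a[, system_labels == s, drop = FALSE]))
  pc <- 1 - rowSums((ks / pmax(deg, 1))^2)
  pc[deg == 0] <- 0
  pc
}
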