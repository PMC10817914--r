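# Surrogate families: spherical spin permutations of nodal maps,
# degree-preserving length-binned network rewiring, and empirical p-values.

# uniform random rotation matrix from a unit quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Spin-test node assignments
#'
#' For each surrogate, draws one uniform 3-D rotation, applies it to the
#' left-hemisphere centroids and its x-mirrored twin to the right-hemisphere
#' centroids, and assigns to every original parcel the index of the nearest
#' rotated parcel of the same hemisphere (duplicates permitted). The
#' resulting index rows permute-with-replacement any nodal map while
#' preserving its spatial autocorrelation.
#'
#' @param parcellation a `parcellation` with unit-norm centroids.
#' @param n number of surrogates.
#' @param seed integer RNG seed.
#' @param rotations optional list of n 3x3 rotation matrices (testing hook;
#'   identity rotations reproduce the input map).
#' @param unique_assignment `TRUE` assigns each rotated parcel to at most one
#'   original parcel (greedy nearest-available matching), making every
#'   surrogate a true permutation; the default `FALSE` is the plain
#'   nearest-parcel projection with duplicates permitted. The projection
#'   variant slightly inflates surrogate smoothness on coarse parcellations
#'   (a conservative bias); the matching variant deflates it (an
#'   anti-conservative bias), so the conservative projection is the default.
#' @return integer matrix (n x nodes); row s maps original node i to source
#'   node `assign[s, i]`.
#' @export
spin_assignments <- function(parcellation, n = length(rotations), seed = 1,
                             rotations = NULL, unique_assignment = FALSE) {
  if (!is.null(rotations)) n <- length(rotations)
  cen <- parcellation$centroids
  if (max(abs(sqrt(rowSums(cen^2)) - 1)) > 1e-6)
    stop("spin test requires unit-sphere centroids")
  mirror <- diag(c(-1, 1, 1))
  idx_h <- split(seq_len(parcellation$n), parcellation$hemisphere)
  run <- function() {
    out <- matrix(NA_integer_, n, parcellation$n)
    for (s in seq_len(n)) {
      rot <- if (is.null(rotations)) random_rotation() else rotations[[s]]
      for (h in names(idx_h)) {
        idx <- idx_h[[h]]
        rh <- if (h == "left") rot else mirror %*% rot %*% mirror
        rotated <- cen[idx, , drop = FALSE] %*% t(rh)
        # nearest rotated parcel on the sphere = max inner product
        sim <- cen[idx, , drop = FALSE] %*% t(rotated)
        if (unique_assignment) {
          k <- length(idx)
          ord <- order(-sim)  # all (original, rotated) pairs, closest first
          orig_free <- rep(TRUE, k)
          rot_free <- rep(TRUE, k)
          assigned <- integer(k)
          left <- k
          for (pair in ord) {
            i <- (pair - 1) %% k + 1
            j <- (pair - 1) %/% k + 1
            if (orig_free[i] && rot_free[j]) {
              assigned[i] <- j
              orig_free[i] <- rot_free[j] <- FALSE
              left <- left - 1
              if (left == 0) break
            }
          }
          out[s, idx] <- idx[assigned]
        } else {
          out[s, idx] <- idx[max.col(sim, ties.method = "first")]
        }
      }
    }
    out
  }
  if (is.null(rotations)) with_seed(seed, run()) else run()
}

#' Spin surrogate maps
#'
#' Applies [spin_assignments()] to a nodal map; every surrogate value is an
#' element of the original value multiset.
#'
#' @param map numeric nodal map (or `maturation_map`/`effect_map`).
#' @param parcellation a `parcellation`.
#' @param n number of surrogate maps.
#' @param seed integer RNG seed.
#' @param assignments optional precomputed assignment matrix (shared across
#'   maps for comparable p-values).
#' @param rotations optional forced rotations (see [spin_assignments()]).
#' @return matrix (n x nodes) of surrogate maps.
#' @export
spin_surrogates <- function(map, parcellation, n = 1000, seed = 1,
                            assignments = NULL, rotations = NULL) {
  v <- map_values(map)
  if (length(v) != parcellation$n) stop("map length must equal node count")
  if (!is.null(rotations)) n <- length(rotations)
  if (is.null(assignments))
    assignments <- spin_assignments(parcellation, n, seed, rotations)
  t(apply(assignments, 1, function(a) v[a]))
}

#' Degree-preserving, length-binned rewired surrogate networks
#'
#' Assigns edges to equal-frequency Euclidean-length bins and performs
#' degree-preserving double-edge swaps within each bin, rejecting swaps that
#' would create self-loops or multi-edges or move an edge out of its length
#' bin. Every surrogate retains the exact degree sequence and exact per-bin
#' edge counts. Bins with fewer than 2 edges are left unswapped.
#'
#' @param connectome a connected `connectome` with distances.
#' @param n_bins number of equal-frequency length bins.
#' @param n number of surrogates.
#' @param n_swap_factor swap attempts per bin = factor x bin edge count.
#' @param seed integer RNG seed.
#' @param require_connected redraw surrogates that come out disconnected
#'   (needed when surrogates feed the diffusion model).
#' @return list of `connectome` surrogates (distances shared with source).
#' @export
rewired_surrogates <- function(connectome, n_bins = 10, n = 100,
                               n_swap_factor = 10, seed = 1,
                               require_connected = FALSE) {
  stopifnot(n_bins >= 1)
  stop_if_disconnected(connectome, "rewired_surrogates")
  a0 <- connectome$adjacency
  d <- connectome$distance
  if (is.null(d)) stop("rewiring requires a distance matrix")
  nn <- nrow(a0)
  ep <- which(upper.tri(a0) & a0 != 0, arr.ind = TRUE)
  lens <- d[ep]
  lb <- length_bins(lens, n_bins)
  breaks <- lb$breaks

  rewire_once <- function() {
    adj <- a0
    edges <- ep  # rows mutate in place
    for (b in unique(lb$bin)) {
      rows <- which(lb$bin == b)
      if (length(rows) < 2) next
      lo <- breaks[b]; hi <- breaks[b + 1]
      n_try <- ceiling(n_swap_factor * length(rows))
      pick <- matrix(sample(rows, 2 * n_try, replace = TRUE), ncol = 2)
      flip <- runif(n_try) < 0.5
      for (t in seq_len(n_try)) {
        e1 <- pick[t, 1]; e2 <- pick[t, 2]
        if (e1 == e2) next
        a <- edges[e1, 1]; bb <- edges[e1, 2]
        c2 <- edges[e2, 1]; d2 <- edges[e2, 2]
        # proposal: (a,b),(c,d) -> (a,d),(c,b)  or  (a,c),(b,d)
        if (flip[t]) { new1 <- c(a, d2); new2 <- c(c2, bb) }
        else { new1 <- c(a, c2); new2 <- c(bb, d2) }
        if (new1[1] == new1[2] || new2[1] == new2[2]) next
        if (adj[new1[1], new1[2]] != 0 || adj[new2[1], new2[2]] != 0) next
        l1 <- d[new1[1], new1[2]]; l2 <- d[new2[1], new2[2]]
        if (l1 <= lo || l1 > hi || l2 <= lo || l2 > hi) next
        adj[a, bb] <- adj[bb, a] <- 0
        adj[c2, d2] <- adj[d2, c2] <- 0
        adj[new1[1], new1[2]] <- adj[new1[2], new1[1]] <- 1
        adj[new2[1], new2[2]] <- adj[new2[2], new2[1]] <- 1
        edges[e1, ] <- sort(new1)
        edges[e2, ] <- sort(new2)
      }
    }
    adj
  }

  with_seed(seed, {
    out <- vector("list", n)
    for (s in seq_len(n)) {
      adj <- rewire_once()
      if (require_connected) {
        tries <- 0
        while (igraph::components(igraph::graph_from_adjacency_matrix(
          adj, mode = "undirected"))$no > 1 && tries < 50) {
          adj <- rewire_once()
          tries <- tries + 1
        }
        if (tries == 50) stop("could not draw a connected rewired surrogate")
      }
      out[[s]] <- as_connectome(adj, d, connectome$parcellation)
    }
    out
  })
}

#' Empirical one-sided p-value against a null distribution
#'
#' `(#{null >= observed} + 1) / (n + 1)` for `side = "greater"` (mirrored for
#' `side = "less"`). The +1 guard avoids p = 0; `plus_one = FALSE` gives the
#' plain fraction.
#'
#' @param observed observed statistic.
#' @param null_values numeric vector of null statistics.
#' @param side "greater" or "less".
#' @param plus_one use the (k+1)/(n+1) convention (default).
#' @return empirical p-value.
#' @export
empirical_p <- function(observed, null_values, side = c("greater", "less"),
                        plus_one = TRUE) {
  side <- match.arg(side)
  k <- if (side == "greater") sum(null_values >= observed) else sum(null_values <= observed)
  n <- length(null_values)
  if (plus_one) (k + 1) / (n + 1) else k / n
}
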