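# Synthetic spherical parcellations: quasi-uniform parcel centroids on two
# unit hemispheres, contiguous system labels, laminar bands and a
# Delaunay-based spatial-adjacency relation.

# Fibonacci lattice on the hemisphere x > 0 (n points, unit norm)
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n)
  x <- (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - x^2))
  golden <- pi * (3 - sqrt(5))
  theta <- golden * i
  cbind(x = x, y = r * cos(theta), z = r * sin(theta))
}

# Spherical Delaunay within one hemisphere via stereographic projection from
# the opposite pole (circle-preserving, so the planar triangulation is the
# spherical one restricted to the hemisphere).
hemisphere_delaunay <- function(centroids, pole_sign) {
  # pole_sign +1: hemisphere x > 0, project from (-1,0,0)
  denom <- 1 + pole_sign * centroids[, 1]
  u <- centroids[, 2] / denom
  v <- centroids[, 3] / denom
  tri <- deldir::deldir(u, v, suppressMsge = TRUE)
  cbind(tri$delsgs$ind1, tri$delsgs$ind2)
}

#' Generate a synthetic spherical parcellation
#'
#' Places `n_nodes/2` parcels quasi-uniformly (Fibonacci lattice, seeded
#' random rotation about the left-right axis) on each unit hemisphere, with
#' mirror-symmetric centroids, spatially contiguous system labels
#' (nearest-seed partition, each system contained in one hemisphere so it is
#' connected under the per-hemisphere adjacency), laminar labels as four
#' equal-frequency superior-inferior bands, and a spatial-adjacency relation
#' from a per-hemisphere spherical Delaunay triangulation.
#'
#' @param n_nodes even integer >= 20, total number of parcels.
#' @param n_systems integer >= 2 and <= `n_nodes/2`, number of systems.
#' @param seed integer RNG seed.
#' @return object of class `parcellation`: list with `n`, `hemisphere`
#'   (factor left/right), `centroids` (n x 3, unit rows), `system`,
#'   `laminar`, and `adjacency` (n x n logical).
#' @examples
#' p <- gen_parcellation(40, 4, seed = 1)
#' table(p$hemisphere)
#' @export
gen_parcellation <- function(n_nodes, n_systems = 7, seed = 1) {
  if (n_nodes %% 2 != 0) stop("n_nodes must be even")
  if (n_nodes < 20) stop("n_nodes must be >= 20")
  if (n_systems < 2) stop("n_systems must be >= 2")
  if (n_systems > n_nodes / 2) stop("n_systems must be <= n_nodes/2")
  with_seed(seed, {
    n_half <- n_nodes / 2
    right <- fibonacci_hemisphere(n_half)
    # seeded rotation about the x axis keeps hemisphere membership and the
    # left/right mirror symmetry while decorrelating lattices across seeds
    ang <- runif(1, 0, 2 * pi)
    rot <- cbind(right[, 2] * cos(ang) - right[, 3] * sin(ang),
                 right[, 2] * sin(ang) + right[, 3] * cos(ang))
    right <- cbind(right[, 1], rot)
    left <- right
    left[, 1] <- -left[, 1]
    centroids <- rbind(left, right)
    colnames(centroids) <- c("x", "y", "z")
    hemisphere <- factor(rep(c("left", "right"), each = n_half),
                         levels = c("left", "right"))

    adjacency <- matrix(FALSE, n_nodes, n_nodes)
    idx_l <- which(hemisphere == "left")
    idx_r <- which(hemisphere == "right")
    seg_l <- hemisphere_delaunay(centroids[idx_l, , drop = FALSE], -1)
    seg_r <- hemisphere_delaunay(centroids[idx_r, , drop = FALSE], +1)
    for (s in seq_len(nrow(seg_l))) {
      a <- idx_l[seg_l[s, 1]]; b <- idx_l[seg_l[s, 2]]
      adjacency[a, b] <- adjacency[b, a] <- TRUE
    }
    for (s in seq_len(nrow(seg_r))) {
      a <- idx_r[seg_r[s, 1]]; b <- idx_r[seg_r[s, 2]]
      adjacency[a, b] <- adjacency[b, a] <- TRUE
    }

    # contiguous systems: nearest-seed partition, seeds split across
    # hemispheres, assignment restricted to the seed's hemisphere
    k_left <- ceiling(n_systems / 2)
    k_right <- n_systems - k_left
    seeds <- c(sample(idx_l, k_left), if (k_right > 0) sample(idx_r, k_right))
    system <- integer(n_nodes)
    for (h in list(idx_l, idx_r)) {
      h_seeds <- intersect(seeds, h)
      d2 <- outer(seq_along(h), seq_along(h_seeds), function(i, j) {
        rowSums((centroids[h[i], , drop = FALSE] - centroids[h_seeds[j], , drop = FALSE])^2)
      })
      system[h] <- match(h_seeds, seeds)[max.col(-d2, ties.method = "first")]
    }

    # laminar bands: equal-frequency bands of z, mirror-symmetric by design
    zq <- quantile(centroids[, "z"], probs = c(0.25, 0.5, 0.75))
    laminar <- findInterval(centroids[, "z"], zq) + 1L

    structure(list(n = n_nodes, hemisphere = hemisphere, centroids = centroids,
                   system = system, laminar = laminar, adjacency = adjacency,
                   seed = seed),
              class = "parcellation")
  })
}

#' @export
print.parcellation <- function(x, ...) {
  cat("parcellation:", x$n, "nodes (", sum(x$hemisphere == "left"), "left /",
      sum(x$hemisphere == "right"), "right ),",
      length(unique(x$system)), "systems,",
      length(unique(x$laminar)), "laminar bands\n")
  cat("spatial adjacency: mean degree",
      round(mean(rowSums(x$adjacency)), 2), "\n")
  invisible(x)
}
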