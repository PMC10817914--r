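# Random-walk diffusion model: one-step transition matrix, m-step
# propagation up to the network diameter, symmetrized diffusion profiles and
# system-level diffusion summaries.

#' One-step random-walk transition matrix
#'
#' `P = D^-1 A` for binary adjacency A and degree diagonal D: the probability
#' of a walker at node i moving to neighbor j in one step is `A_ij / d_i`.
#'
#' @param connectome a `connectome` with no degree-0 nodes.
#' @return row-stochastic n x n matrix.
#' @export
transition_matrix <- function(connectome) {
  a <- connectome$adjacency
  deg <- rowSums(a)
  if (any(deg == 0))
    stop("degree-0 node(s): ", paste(which(deg == 0) - 1L, collapse = ", "))
  a / deg
}

#' Multiscale random-walk diffusion profiles
#'
#' Computes the m-step walker distribution matrices `P_m = P^m` (initial
#' distribution = identity, so row i is the distribution of a walker started
#' at node i) for m = 1..M, and their symmetrized versions
#' `S_m = (P_m + P_m') / 2` representing bidirectional diffusion between node
#' pairs. M defaults to the graph diameter.
#'
#' @param connectome a connected `connectome`.
#' @param max_scale maximum neighboring scale M; default the graph diameter.
#' @return object of class `diffusion_profiles`: list with `P`, `P_m` (list
#'   of length M), `S_m` (list of length M), and `M`.
#' @export
diffusion_profiles <- function(connectome, max_scale = NULL) {
  stop_if_disconnected(connectome, "diffusion_profiles")
  p <- transition_matrix(connectome)
  m_max <- if (is.null(max_scale)) graph_diameter(connectome) else as.integer(max_scale)
  stopifnot(m_max >= 1)
  p_m <- vector("list", m_max)
  s_m <- vector("list", m_max)
  cur <- p
  for (m in seq_len(m_max)) {
    p_m[[m]] <- cur
    s_m[[m]] <- (cur + t(cur)) / 2
    if (m < m_max) cur <- cur %*% p
  }
  structure(list(P = p, P_m = p_m, S_m = s_m, M = m_max,
                 parcellation = connectome$parcellation),
            class = "diffusion_profiles")
}

#' @export
print.diffusion_profiles <- function(x, ...) {
  cat("diffusion profiles:", nrow(x$P), "nodes, scales 1..", x$M, "\n")
  invisible(x)
}

#' Within- and between-system diffusion mass per scale
#'
#' For each node and scale m, sums the symmetrized diffusion profile mass
#' landing in the node's own system (within) and elsewhere (between), and
#' averages across nodes. Also returns the mean system-pair mass matrix per
#' scale.
#'
#' @param profiles a `diffusion_profiles`.
#' @param system_labels per-node system labels (defaults to the attached
#'   parcellation's).
#' @return list with `overall` (data.frame scale/within/between) and `pairs`
#'   (list of K x K matrices, mean row mass from system a nodes into system b).
#' @export
system_diffusion_summary <- function(profiles, system_labels = NULL) {
  if (is.null(system_labels)) system_labels <- profiles$parcellation$system
  if (is.null(system_labels)) stop("system labels are required")
  systems <- sort(unique(system_labels))
  k <- length(systems)
  overall <- data.frame(scale = seq_len(profiles$M), within = NA_real_,
                        between = NA_real_)
  pairs <- vector("list", profiles$M)
  member <- sapply(systems, function(s) 1 * (system_labels == s))  # n x k
  for (m in seq_len(profiles$M)) {
    s_mat <- profiles$S_m[[m]]
    mass <- s_mat %*% member                      # n x k: mass into each system
    own <- mass[cbind(seq_len(nrow(mass)), match(system_labels, systems))]
    tot <- rowSums(s_mat)
    overall$within[m] <- mean(own)
    overall$between[m] <- mean(tot - own)
    pm <- matrix(NA_real_, k, k, dimnames = list(systems, systems))
    for (a in seq_len(k)) pm[a, ] <- colMeans(mass[system_labels == systems[a], , drop = FALSE])
    pairs[[m]] <- pm
  }
  list(overall = overall, pairs = pairs)
}
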