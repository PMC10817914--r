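# Shared fixtures, built once per test run. All synthetic, all seeded.

fix_parc <- gen_parcellation(100, 7, seed = 3)
fix_conn <- gen_connectome(fix_parc, seed = 2)
fix_prof <- diffusion_profiles(fix_conn)

fix_parc_small <- gen_parcellation(40, 4, seed = 5)
fix_conn_small <- gen_connectome(fix_parc_small, target_density = 0.12, seed = 6)
fix_prof_small <- diffusion_profiles(fix_conn_small)

# toy graphs (adjacency only; distances where needed)
toy_path3 <- as_connectome(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
toy_path4 <- as_connectome(outer(1:4, 1:4, function(i, j) 1 * (abs(i - j) == 1)))
toy_k3 <- as_connectome(1 - diag(3))
toy_star4 <- as_connectome(rbind(c(0, 1, 1, 1), c(1, 0, 0, 0),
                                 c(1, 0, 0, 0), c(1, 0, 0, 0)))
toy_cycle6 <- as_connectome(outer(1:6, 1:6, function(i, j) {
  d <- abs(i - j); 1 * (d == 1 | d == 5)
}))

# ring connectome with regular polygon geometry (constant neighbor distance)
toy_ring <- local({
  n <- 12
  th <- 2 * pi * (seq_len(n) - 1) / n
  cen <- cbind(cos(th), sin(th), 0)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    d <- abs(i - j); 1 * (d == 1 | d == n - 1)
  })
  as_connectome(adj, as.matrix(dist(cen)))
})

# planted study map: mixture of diffusion-profile rows + moderate noise
make_planted <- function(seed, n_dom = 2, noise_frac = 0.5, m = 3,
                         prof = fix_prof, parc = fix_parc) {
  set.seed(seed)
  dn <- sample(nrow(prof$P), n_dom)
  clean <- gen_effect_map(prof, dn, m, rep(1, n_dom), noise_sd = 0, seed = seed,
                          parcellation = parc)
  eff <- gen_effect_map(prof, dn, m, rep(1, n_dom),
                        noise_sd = noise_frac * sd(clean$beta), seed = seed,
                        parcellation = parc)
  list(map = eff$beta, dominant = dn, m = m, clean = clean$beta)
}

# Monte-Carlo mean-first-passage oracle: mean hitting time of `target` from
# sources cycled uniformly over the other nodes (vectorized random walk)
mc_mfpt_nodal <- function(connectome, target, n_walks = 1e5, max_steps = 1e4) {
  a <- connectome$adjacency
  n <- nrow(a)
  nbrs <- apply(a, 1, function(r) which(r != 0), simplify = FALSE)
  deg <- lengths(nbrs)
  nbr_mat <- matrix(0L, n, max(deg))
  for (i in seq_len(n)) nbr_mat[i, seq_len(deg[i])] <- nbrs[[i]]
  cur <- rep_len(setdiff(seq_len(n), target), n_walks)
  steps <- numeric(n_walks)
  alive <- seq_len(n_walks)
  s <- 0
  while (length(alive) > 0 && s < max_steps) {
    s <- s + 1
    pick <- floor(runif(length(alive)) * deg[cur[alive]]) + 1
    cur[alive] <- nbr_mat[cbind(cur[alive], pick)]
    hit <- cur[alive] == target
    steps[alive[hit]] <- s
    alive <- alive[!hit]
  }
  if (length(alive) > 0) stop("walks did not absorb")
  mean(steps)
}
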