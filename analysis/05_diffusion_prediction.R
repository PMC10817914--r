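#!/usr/bin/env Rscript
# Stage 5 — the random-walk diffusion model: per-scale profiles up to the
# network diameter, within/between-system diffusion mass per scale, and
# cross-validated linear-SVR prediction of the t map from each scale's
# profiles, with spin and rewired significance (99 surrogates each).

suppressPackageStartupMessages(library(wmconstraint))
parc <- read_node_table("results/data/nodes.csv")
backbone <- read_edge_list("results/backbone_edges.tsv", parcellation = parc)
map1 <- read.csv("results/maturation_model1.csv")$t

profiles <- diffusion_profiles(backbone)
sysd <- system_diffusion_summary(profiles, parc$system)
write.csv(sysd$overall, "results/diffusion_system_mass.csv", row.names = FALSE)
message(sprintf("diffusion: M = %d scales; within-system mass %.2f at scale 1, %.2f at scale M",
                profiles$M, sysd$overall$within[1],
                sysd$overall$within[profiles$M]))

# demonstration-scale ensembles and cost grid: the significance step
# re-runs the identical cross-validation once per surrogate and scale
spins <- spin_surrogates(map1, parc, n = 49, seed = 9)
rewired <- rewired_surrogates(backbone, n_bins = 10, n = 49, seed = 10,
                              require_connected = TRUE)

pred <- lapply(seq_len(profiles$M), function(m) {
  res <- svr_predict_scale(profiles, map1, m, k_folds = 5, c_grid = 2^(0:4),
                           inner_folds = 3, seed = 11)
  sig <- prediction_significance(res, profiles, map1, spin_maps = spins,
                                 rewired = rewired)
  message(sprintf("scale %d: accuracy r = %.3f, p_spin = %.2f, p_rewired = %.2f",
                  m, res$accuracy_r, sig$p_spin, sig$p_rewired))
  contrib <- feature_contributions(res)
  write.csv(data.frame(node_id = seq_len(parc$n) - 1L, contribution = contrib),
            sprintf("results/svr_contributions_scale%d.csv", m),
            row.names = FALSE)
  data.frame(scale = m, accuracy_r = res$accuracy_r,
             p_spin = sig$p_spin, p_rewired = sig$p_rewired)
})
write.csv(do.call(rbind, pred), "results/prediction.csv", row.names = FALSE)
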