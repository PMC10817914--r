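#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic study: a 100-node spherical parcellation,
# 20 individual distance- and community-dependent connectomes, a planted
# two-node effect map, a discovery-style longitudinal thickness roster, and
# a developmental gene panel. Everything downstream reads these files.

suppressPackageStartupMessages(library(wmconstraint))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

parc <- gen_parcellation(100, 7, seed = 1)
write_node_table(parc, "results/data/nodes.csv")
message("parcellation: ", parc$n, " nodes, mean spatial degree ",
        round(mean(rowSums(parc$adjacency)), 1))

for (i in 1:20) {
  cn <- gen_connectome(parc, seed = 100 + i)
  write_edge_list(cn, sprintf("results/data/individual_%02d.tsv", i))
}
message("wrote 20 individual connectomes (target density 0.08)")

# backbone is rebuilt in stage 2; here we only need profiles to plant from
ind <- lapply(1:20, function(i)
  read_edge_list(sprintf("results/data/individual_%02d.tsv", i),
                 parcellation = parc)$adjacency)
backbone <- consensus_backbone(ind, parcellation = parc)
profiles <- diffusion_profiles(backbone)
set.seed(2)
dominant <- sample(parc$n, 2)
effect <- gen_effect_map(profiles, dominant, scale_m = 3, weights = c(-3, -3),
                         noise_sd = 0.005, seed = 3)
write.csv(data.frame(node_id = seq_len(parc$n) - 1L, beta = effect$beta,
                     planted = seq_len(parc$n) %in% dominant),
          "results/data/effect_map.csv", row.names = FALSE)
message("planted thinning at nodes ", paste(dominant - 1L, collapse = ", "),
        " (scale 3, -3 mm per unit profile mass)")

scans <- gen_longitudinal_ct(parc, effect, 158, 105, 51, seed = 4)
write_scan_table(scans, "results/data/scan_meta.csv", "results/data/scan_ct.csv")
message("roster: ", nrow(scans$meta), " scans from ",
        length(unique(scans$meta$subject_id)), " subjects; ",
        length(split_scan_pairs(scans)), " consecutive scan pairs")

panel <- gen_gene_panel(n_genes = 300, gene_sets = c(axon = 25, myelination = 25,
                                                     dendrite = 25, synapse = 25),
                        region_categories = setNames(
                          rep(c("dominant", "non_dominant"), c(5, 6)),
                          sprintf("area%02d", 1:11)),
                        ages = seq(4, 16, by = 1),
                        divergence = c(axon = -1.2, myelination = -1.2,
                                       dendrite = 1.2, synapse = 1.2),
                        noise_sd = 0.4, seed = 5)
write_gene_panel(panel, "results/data/gene_panel.csv",
                 "results/data/gene_sets.json")
message("gene panel: ", nrow(panel$expression), " samples x ",
        ncol(panel$expression), " genes, 4 maturation sets")
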