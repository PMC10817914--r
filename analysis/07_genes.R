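#!/usr/bin/env Rscript
# Stage 7 — transcriptomic contrasts: per-set PC1 contrast between dominant
# and non-dominant regions against a gene-resampling null, and the
# dominance-likelihood vs per-gene expression-map correlation with spin +
# Benjamini-Hochberg FDR.

suppressPackageStartupMessages(library(wmconstraint))
parc <- read_node_table("results/data/nodes.csv")
panel <- read_gene_panel("results/data/gene_panel.csv",
                         "results/data/gene_sets.json")

contrasts <- lapply(names(panel$gene_sets), function(s) {
  res <- dominant_contrast(panel, panel$gene_sets[[s]], n_resamples = 999,
                           seed = 14)
  message(sprintf("%-12s PC1 difference = %+.2f (dominant - non-dominant), p = %.3f",
                  s, res$difference, res$p))
  list(set = s, difference = res$difference, p = res$p,
       direction = res$direction)
})
jsonlite::write_json(contrasts, "results/gene_contrasts.json",
                     auto_unbox = TRUE, digits = NA)

# region x gene maps: mean expression per region aligned to the first
# length(regions) parcels (synthetic stand-in for an atlas-aligned matrix)
likelihood <- read.csv("results/dominance_cosine.csv")$likelihood_scale1
regions <- sort(unique(panel$region))
gm <- t(vapply(regions, function(r)
  colMeans(panel$expression[panel$region == r, , drop = FALSE]),
  numeric(ncol(panel$expression))))
# broadcast each region's expression to its parcel block so the gene maps
# live on the full parcellation
block <- rep(seq_along(regions), length.out = parc$n)
gm_full <- gm[block, , drop = FALSE]
res <- map_gene_correlation(likelihood, gm_full, parc, n_spin = 999,
                            fdr_alpha = 0.05, seed = 15)
write.csv(res$table, "results/gene_map_correlation.csv", row.names = FALSE)
message(sprintf("map-gene correlation: %d positive and %d negative genes at FDR 0.05",
                length(res$positive), length(res$negative)))
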