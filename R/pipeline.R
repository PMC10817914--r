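# End-to-end orchestration: a config-driven run of the full synthetic
# analysis with explicit per-stage seeds and a reproducible manifest.

#' Default pipeline configuration
#'
#' Every stochastic stage has its own explicit seed; [run_full_pipeline()]
#' refuses configs with a missing seed before doing any computation.
#'
#' @param out_dir output directory.
#' @param seed base seed; stage seeds default to consecutive offsets.
#' @return named list accepted by [run_full_pipeline()].
#' @export
default_config <- function(out_dir = "results/pipeline", seed = 1) {
  list(out_dir = out_dir,
       n_nodes = 100, n_systems = 7,
       n_subjects = c(single = 40, double = 25, triple = 12),
       target_density = 0.08, length_scale = 0.5, within_system_bonus = 4,
       n_individual_networks = 20, consensus_bins = 10,
       dominant_nodes = 2, effect_scale = 2, effect_weight = -0.3,
       effect_noise_sd = 0.01,
       subject_sd = 0.1, noise_sd = 0.05,
       n_null = 99, null_bins = 10,
       k_folds = 10, c_grid = default_c_grid(),
       n_genes = 150, gene_set_size = 20, divergence = 1,
       seeds = list(parcellation = seed, connectome = seed + 1,
                    effect = seed + 2, scans = seed + 3, nulls = seed + 4,
                    prediction = seed + 5, genes = seed + 6))
}

stage_seed <- function(config, stage) {
  s <- config$seeds[[stage]]
  if (is.null(s)) stop("config is missing a seed for stage '", stage, "'")
  s
}

#' Run the full synthetic analysis pipeline
#'
#' Sequences simulation, consensus backbone, maturation mapping (Model I),
#' neighbor-constraint testing, diffusion profiling, SVR prediction,
#' dominance mapping and the gene contrast, writing stage outputs and a
#' manifest (package version, seeds, file hashes) under `config$out_dir`.
#'
#' @param config list from [default_config()] (possibly modified).
#' @return the manifest, invisibly; side effect: files under `out_dir`.
#' @export
run_full_pipeline <- function(config = default_config()) {
  for (stage in c("parcellation", "connectome", "effect", "scans", "nulls",
                  "prediction", "genes"))
    stage_seed(config, stage)  # validate all seeds before any computation
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  parc <- run_stage("simulate", gen_parcellation(
    config$n_nodes, config$n_systems, seed = stage_seed(config, "parcellation")))
  write_node_table(parc, out("nodes.csv"))

  individuals <- run_stage("simulate", lapply(seq_len(config$n_individual_networks),
    function(i) gen_connectome(parc, config$target_density, config$length_scale,
                               config$within_system_bonus,
                               seed = stage_seed(config, "connectome") + i)$adjacency))
  backbone <- run_stage("backbone", consensus_backbone(
    individuals, n_bins = config$consensus_bins, parcellation = parc))
  write_edge_list(backbone, out("backbone_edges.tsv"))

  profiles <- run_stage("diffuse", diffusion_profiles(backbone))
  eff <- run_stage("simulate", {
    dn <- order(-rowSums(backbone$adjacency))[seq_len(config$dominant_nodes)]
    gen_effect_map(profiles, dn, scale_m = config$effect_scale,
                   weights = rep(config$effect_weight, length(dn)),
                   noise_sd = config$effect_noise_sd,
                   seed = stage_seed(config, "effect"))
  })
  scans <- run_stage("simulate", gen_longitudinal_ct(
    parc, eff, config$n_subjects["single"], config$n_subjects["double"],
    config$n_subjects["triple"], subject_sd = config$subject_sd,
    noise_sd = config$noise_sd, seed = stage_seed(config, "scans")))
  write_scan_table(scans, out("scan_meta.csv"), out("scan_ct.csv"))

  map1 <- run_stage("maturation", model1_group_t(scans))
  write.csv(data.frame(node_id = seq_len(parc$n) - 1L, value = map1$value,
                       p = map1$p, mask = map1$mask),
            out("maturation_model1.csv"), row.names = FALSE)

  null_seed <- stage_seed(config, "nulls")
  spin_assign <- spin_assignments(parc, config$n_null, seed = null_seed)
  rewired <- rewired_surrogates(backbone, n_bins = config$null_bins,
                                n = config$n_null, seed = null_seed + 1)
  constraint <- run_stage("constraint", constraint_test(
    map1$value, backbone, parc, spin_assign = spin_assign, rewired = rewired))
  jsonlite::write_json(
    list(r = constraint$r, variant = constraint$variant,
         n_used = constraint$n_used, p_spin = constraint$p_spin,
         p_rewired = constraint$p_rewired),
    out("constraint.json"), auto_unbox = TRUE, digits = NA)

  pred <- run_stage("predict", lapply(seq_len(profiles$M), function(m)
    svr_predict_scale(profiles, map1$value, m, k_folds = config$k_folds,
                      c_grid = config$c_grid,
                      seed = stage_seed(config, "prediction"))))
  write.csv(data.frame(scale = seq_len(profiles$M),
                       accuracy_r = vapply(pred, `[[`, numeric(1), "accuracy_r")),
            out("prediction.csv"), row.names = FALSE)

  dom <- run_stage("dominance", dominant_nodes(
    profiles, map1$value, parc, spin_assign = spin_assign))
  write.csv(data.frame(node_id = seq_len(parc$n) - 1L,
                       conjunction = dom$conjunction,
                       likelihood_scale1 = dom$likelihood[, 1]),
            out("dominance.csv"), row.names = FALSE)

  genes_seed <- stage_seed(config, "genes")
  region_cat <- setNames(ifelse(dom$conjunction[seq_len(min(8, parc$n))] >=
                                  median(dom$conjunction), "dominant", "non_dominant"),
                         paste0("region", seq_len(min(8, parc$n))))
  if (length(unique(region_cat)) < 2) region_cat[1:2] <- c("dominant", "non_dominant")
  panel <- run_stage("genes", gen_gene_panel(
    n_genes = config$n_genes, gene_sets = c(maturation = config$gene_set_size),
    region_categories = region_cat, divergence = config$divergence,
    seed = genes_seed))
  contrast <- run_stage("genes", dominant_contrast(
    panel, panel$gene_sets$maturation, n_resamples = config$n_null,
    seed = genes_seed + 1))
  jsonlite::write_json(list(difference = contrast$difference, p = contrast$p,
                            direction = contrast$direction),
                       out("gene_contrast.json"), auto_unbox = TRUE, digits = NA)

  files <- c("nodes.csv", "backbone_edges.tsv", "scan_meta.csv", "scan_ct.csv",
             "maturation_model1.csv", "constraint.json", "prediction.csv",
             "dominance.csv", "gene_contrast.json")
  manifest <- list(package = "wmconstraint",
                   version = as.character(utils::packageVersion("wmconstraint")),
                   seeds = config$seeds,
                   hashes = setNames(as.list(unname(tools::md5sum(out(files)))),
                                     files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
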