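test_that("noiseless single-node effect maps equal the planted profile row", {
  eff <- gen_effect_map(fix_prof_small, 4, scale_m = 2, weights = 1,
                        noise_sd = 0, seed = 1)
  expect_equal(eff$beta, fix_prof_small$S_m[[2]][4, ])
  expect_identical(eff$dominant_truth, 4)
  expect_identical(eff$provenance, "planted_from_diffusion")
})

test_that("zero-weight effect maps are pure smoothed noise with empty truth", {
  eff <- gen_effect_map(fix_prof_small, integer(0), scale_m = 1,
                        weights = numeric(0), noise_sd = 0.1, seed = 2)
  expect_length(eff$dominant_truth, 0)
  expect_identical(eff$provenance, "autocorrelated_null")
  expect_gt(sd(eff$beta), 0)
  # smoothing imparts positive spatial autocorrelation
  expect_gt(morans_i(eff$beta, fix_parc_small$adjacency), 0)
})

test_that("planted nodes out-rank non-planted nodes in profile similarity", {
  set.seed(3)
  dn <- sample(100, 2)
  eff <- gen_effect_map(fix_prof, dn, scale_m = 2, weights = c(1, 1),
                        noise_sd = 0, seed = 3)
  sims <- vapply(seq_len(100), function(k)
    sum(eff$beta * fix_prof$S_m[[2]][k, ]) /
      sqrt(sum(eff$beta^2) * sum(fix_prof$S_m[[2]][k, ]^2)), numeric(1))
  cutoff <- quantile(sims[-dn], 0.95)
  expect_true(all(sims[dn] > cutoff))
})

test_that("the discovery-design roster yields the printed scan and pair counts", {
  scans <- gen_longitudinal_ct(fix_parc_small, NULL, 158, 105, 51, seed = 1)
  expect_equal(nrow(scans$meta), 521)
  expect_length(split_scan_pairs(scans), 207)
})

test_that("noise-free rosters reproduce planted group effects exactly", {
  eff <- gen_effect_map(fix_prof_small, 3, scale_m = 1, weights = -2,
                        noise_sd = 0, seed = 1)
  scans <- gen_longitudinal_ct(fix_parc_small, eff, 30, 20, 10,
                               subject_sd = 0, noise_sd = 0, sex_effect = 0,
                               seed = 4)
  adol <- scans$meta$group == "adolescent"
  expect_gt(sum(adol), 0)
  diff <- colMeans(scans$ct[adol, , drop = FALSE]) -
    colMeans(scans$ct[!adol, , drop = FALSE])
  expect_lt(max(abs(diff - eff$beta)), 1e-10)
})

test_that("rosters are reproducible, age-ordered, and validated", {
  a <- gen_longitudinal_ct(fix_parc_small, NULL, 10, 5, 3, seed = 7)
  b <- gen_longitudinal_ct(fix_parc_small, NULL, 10, 5, 3, seed = 7)
  expect_identical(a, b)
  for (s in unique(a$meta$subject_id))
    expect_true(all(diff(a$meta$age[a$meta$subject_id == s]) > 0))
  expect_identical(a$meta$group, ifelse(a$meta$age >= 10, "adolescent", "child"))
  expect_true(all(is.finite(a$ct)) && all(a$ct > 0))
  expect_error(gen_longitudinal_ct(fix_parc_small, NULL, 0, 0, 0), "zero")
  expect_error(gen_longitudinal_ct(fix_parc_small, NULL, 5, 0, 0,
                                   age_range = c(2, 12)), "age_range")
})

test_that("gene panels diverge by category only when divergence is planted", {
  diffs <- vapply(1:50, function(s) {
    pan <- gen_gene_panel(n_genes = 60, gene_sets = c(set1 = 15),
                          divergence = 0, seed = s)
    sc <- geneset_pc1(pan, pan$gene_sets$set1)
    mean(sc[pan$category == "dominant"]) - mean(sc[pan$category == "non_dominant"])
  }, numeric(1))
  expect_lt(abs(mean(diffs) / (sd(diffs) / sqrt(50))), 3)

  signs <- vapply(1:50, function(s) {
    pan <- gen_gene_panel(n_genes = 60, gene_sets = c(set1 = 15),
                          divergence = 2, noise_sd = 0.2, seed = s)
    sc <- geneset_pc1(pan, pan$gene_sets$set1)
    mean(sc[pan$category == "dominant"]) - mean(sc[pan$category == "non_dominant"])
  }, numeric(1))
  expect_gte(mean(signs > 0), 0.95)
})

test_that("gene panels are reproducible from the seed", {
  expect_identical(gen_gene_panel(seed = 12), gen_gene_panel(seed = 12))
})
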