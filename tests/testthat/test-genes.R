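test_that("PC1 recovers a planted rank-1 latent and the single-gene case", {
  set.seed(16)
  latent <- rnorm(40)
  loadings <- runif(10, 0.5, 2)
  expr <- outer(latent, loadings) + matrix(rnorm(400, 0, 1e-3), 40, 10)
  colnames(expr) <- sprintf("g%02d", 1:10)
  sc <- geneset_pc1(expr, colnames(expr))
  expect_gte(abs(cor(sc, latent)), 0.999)
  single <- geneset_pc1(expr, "g03")
  expect_equal(single, as.vector(scale(expr[, "g03"])))
  # zero-variance genes are dropped with a warning
  expr2 <- cbind(expr, flat = 1)
  expect_warning(sc2 <- geneset_pc1(expr2, c("g01", "flat")), "zero-variance")
  expect_equal(sc2, as.vector(scale(expr2[, "g01"])))
  expect_error(geneset_pc1(expr, "nope"), "not in panel")
})

test_that("the category contrast is zero for identical categories and is
          direction-aware", {
  pan <- gen_gene_panel(n_genes = 50, gene_sets = c(set1 = 10),
                        divergence = 1, seed = 17)
  # make the non-dominant samples exact copies of dominant ones
  dom_rows <- which(pan$category == "dominant")
  nod_rows <- which(pan$category == "non_dominant")
  k <- min(length(dom_rows), length(nod_rows))
  pan$expression[nod_rows[seq_len(k)], ] <- pan$expression[dom_rows[seq_len(k)], ]
  pan2 <- pan
  pan2$expression <- pan$expression[c(dom_rows[seq_len(k)], nod_rows[seq_len(k)]), ]
  pan2$category <- pan$category[c(dom_rows[seq_len(k)], nod_rows[seq_len(k)])]
  pan2$age <- pan$age[c(dom_rows[seq_len(k)], nod_rows[seq_len(k)])]
  res <- dominant_contrast(pan2, pan2$gene_sets$set1, n_resamples = 19,
                           seed = 1)
  expect_equal(res$difference, 0)
  expect_error(dominant_contrast(pan2, colnames(pan2$expression)[1:30],
                                 n_resamples = 9, seed = 1), "remaining")
})

test_that("planted set divergence is detected against the resampling null", {
  ps <- vapply(1:20, function(s) {
    pan <- gen_gene_panel(n_genes = 120, gene_sets = c(set1 = 20),
                          divergence = 1.5, noise_sd = 0.4, seed = 40 + s)
    dominant_contrast(pan, pan$gene_sets$set1, n_resamples = 99,
                      seed = s)$p
  }, numeric(1))
  expect_gte(mean(ps <= 0.05), 0.9)
})

test_that("the contrast p-value is calibrated when no divergence is planted", {
  # calibration requires (i) a side fixed a priori — the observed-direction
  # p lives on (0, 0.5) — and (ii) a target set exchangeable with the
  # resampling pool, i.e. a background-gene set (the competitive null is
  # not calibrated for internally correlated sets, divergent or not)
  ps <- vapply(1:100, function(s) {
    pan <- gen_gene_panel(n_genes = 60, gene_sets = c(set1 = 10),
                          divergence = 0, seed = 200 + s)
    background <- setdiff(colnames(pan$expression), pan$gene_sets$set1)
    set.seed(s)
    target <- sample(background, 10)
    res <- dominant_contrast(pan, target, n_resamples = 99, seed = s)
    empirical_p(res$difference, res$null, "greater")
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("contrast is invariant to sample order", {
  pan <- gen_gene_panel(n_genes = 60, gene_sets = c(set1 = 10),
                        divergence = 1, seed = 18)
  res <- dominant_contrast(pan, pan$gene_sets$set1, n_resamples = 29, seed = 2)
  set.seed(19)
  ord <- sample(nrow(pan$expression))
  pan_s <- pan
  pan_s$expression <- pan$expression[ord, ]
  pan_s$category <- pan$category[ord]
  pan_s$age <- pan$age[ord]
  pan_s$region <- pan$region[ord]
  res_s <- dominant_contrast(pan_s, pan$gene_sets$set1, n_resamples = 29,
                             seed = 2)
  expect_equal(res_s$difference, res$difference)
})

test_that("map-gene correlations hit the exact-match and antisymmetry cases", {
  pl <- make_planted(10, prof = fix_prof_small, parc = fix_parc_small, m = 2)
  set.seed(20)
  gm <- matrix(rnorm(fix_parc_small$n * 5), fix_parc_small$n, 5,
               dimnames = list(NULL, sprintf("g%d", 1:5)))
  gm[, 1] <- pl$map
  res <- map_gene_correlation(pl$map, gm, fix_parc_small, n_spin = 49,
                              seed = 3)
  expect_equal(res$table$r[1], 1)
  expect_equal(res$table$p_spin[1], 1 / 50)
  gm_neg <- gm
  gm_neg[, 2] <- -gm[, 2]
  res_neg <- map_gene_correlation(pl$map, gm_neg, fix_parc_small, n_spin = 49,
                                  seed = 3)
  expect_equal(res_neg$table$r[2], -res$table$r[2])
  expect_equal(res_neg$table$p_spin[2], res$table$p_spin[2])
  gm_flat <- cbind(gm, flat = 1)
  expect_warning(map_gene_correlation(pl$map, gm_flat, fix_parc_small,
                                      n_spin = 9, seed = 3), "constant")
})

test_that("false discoveries stay controlled for independent gene maps", {
  fdp <- vapply(1:20, function(s) {
    pl <- make_planted(60 + s, prof = fix_prof_small, parc = fix_parc_small,
                       m = 2)
    set.seed(s)
    gm <- matrix(rnorm(fix_parc_small$n * 200), fix_parc_small$n, 200,
                 dimnames = list(NULL, sprintf("g%03d", 1:200)))
    res <- map_gene_correlation(pl$map, gm, fix_parc_small, n_spin = 99,
                                seed = s)
    n_sig <- sum(res$table$significant)
    if (n_sig == 0) 0 else 1  # every discovery is false here
  }, numeric(1))
  expect_lte(mean(fdp), 0.10)
})
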