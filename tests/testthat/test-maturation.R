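make_single_scan_roster <- function(n_subj, n_nodes, seed, beta = NULL) {
  # one scan per subject, half child half adolescent
  set.seed(seed)
  age <- c(runif(n_subj / 2, 6, 9.9), runif(n_subj / 2, 10.1, 14))
  sex <- rbinom(n_subj, 1, 0.5)
  grp <- ifelse(age >= 10, "adolescent", "child")
  ct <- matrix(rnorm(n_subj * n_nodes, 2.5, 0.1), n_subj, n_nodes)
  if (!is.null(beta)) ct <- ct + outer(grp == "adolescent", beta, `*`)
  structure(list(meta = data.frame(subject_id = sprintf("s%03d", seq_len(n_subj)),
                                   scan_index = 1L, age = age, sex = sex,
                                   group = grp, site = "site1"),
                 ct = ct), class = "scan_table")
}

test_that("group t equals the ordinary-least-squares oracle for single scans", {
  scans <- make_single_scan_roster(40, 6, seed = 1)
  m1 <- model1_group_t(scans)
  for (j in 1:6) {
    d <- data.frame(y = scans$ct[, j],
                    group = factor(scans$meta$group,
                                   levels = c("child", "adolescent")),
                    sex = scans$meta$sex)
    cf <- summary(lm(y ~ group + sex, data = d))$coefficients
    expect_lt(abs(m1$value[j] - (-cf["groupadolescent", "t value"])), 1e-6)
    expect_lt(abs(m1$p[j] - cf["groupadolescent", "Pr(>|t|)"]), 1e-6)
  }
})

test_that("planted thinning yields positive significant t at affected nodes", {
  eff <- gen_effect_map(fix_prof_small, 5, scale_m = 2, weights = -3,
                        noise_sd = 0, seed = 1)  # strong thinning, mm
  scans <- gen_longitudinal_ct(fix_parc_small, eff, 30, 20, 10,
                               subject_sd = 0.02, noise_sd = 0.02, seed = 2)
  m1 <- model1_group_t(scans)
  affected <- which(abs(eff$beta) > 0.1)
  expect_true(all(m1$value[affected] > 0))
  expect_true(all(m1$mask[affected]))
  expect_equal(m1$alpha_corrected, 0.05 / fix_parc_small$n)
})

test_that("group t is invariant to adding a constant to a node's thickness", {
  scans <- gen_longitudinal_ct(fix_parc_small, NULL, 12, 8, 4, seed = 3)
  m_a <- model1_group_t(scans)
  scans$ct[, 2] <- scans$ct[, 2] + 5
  m_b <- model1_group_t(scans)
  expect_equal(m_a$value[2], m_b$value[2], tolerance = 1e-8)
})

test_that("model I rejects degenerate inputs", {
  scans <- gen_longitudinal_ct(fix_parc_small, NULL, 10, 5, 2, seed = 4)
  young <- scans$meta$group == "child"
  one_group <- structure(list(meta = scans$meta[young, ],
                              ct = scans$ct[young, , drop = FALSE]),
                         class = "scan_table")
  expect_error(model1_group_t(one_group), "both groups")
  flat <- scans
  flat$ct[, 1] <- 2.5
  expect_error(model1_group_t(flat), "zero CT variance")
})

test_that("null-model p-values are uniform under repeated simulation", {
  pvals <- unlist(lapply(1:200, function(s)
    model1_group_t(make_single_scan_roster(40, 5, seed = s))$p))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("spline-model maturation rates recover planted age trends", {
  n_subj <- 80
  set.seed(5)
  age <- runif(n_subj, 6, 14)
  base <- data.frame(subject_id = sprintf("s%03d", 1:n_subj), scan_index = 1L,
                     age = age, sex = rbinom(n_subj, 1, 0.5),
                     group = ifelse(age >= 10, "adolescent", "child"),
                     site = "site1")
  ct <- cbind(3.2 - 0.1 * age,                 # linear thinning -0.1 mm/y
              rep(2.8, n_subj),                # constant
              2.5 + 0.01 * (age - 10)^2)       # vertex at age 10
  ct <- ct + matrix(rnorm(n_subj * 3, 0, 0.01), n_subj, 3)
  scans <- structure(list(meta = base, ct = ct), class = "scan_table")
  fit <- model2_gam(scans, eval_ages = c(8, 10, 12))
  for (i in 1:3) {
    expect_lt(abs(fit$maps[[i]]$value[1] - (-0.1)), 0.02)
    expect_lt(abs(fit$maps[[i]]$value[2]), 0.01)
  }
  expect_lt(fit$maps[[1]]$value[3], 0)   # before the vertex: thinning
  expect_gt(fit$maps[[3]]$value[3], 0)   # after the vertex: thickening
  expect_error(model2_gam(scans, eval_ages = 20), "age range")
})

test_that("individual rates follow the annualized-change arithmetic", {
  pair <- structure(list(
    meta = data.frame(subject_id = c("s1", "s1"), scan_index = 1:2,
                      age = c(8, 9), sex = 0, group = "child", site = "site1"),
    ct = rbind(c(3.0, 2.5), c(2.8, 2.6))), class = "scan_table")
  rate <- model3_individual_rate(pair)
  expect_equal(rate$value, c(-0.2, 0.1))
  # identical scans -> zero everywhere
  pair$ct[2, ] <- pair$ct[1, ]
  expect_equal(model3_individual_rate(pair)$value, c(0, 0))
  # half-year gap doubles the rate
  pair2 <- pair
  pair2$meta$age <- c(8, 8.5)
  pair2$ct <- rbind(c(2.5, 2.5), c(2.6, 2.5))
  expect_equal(model3_individual_rate(pair2)$value, c(0.2, 0))
  # antisymmetry under swapping the two scans
  pair3 <- structure(list(meta = pair$meta, ct = rbind(c(3, 2), c(2.9, 2.2))),
                     class = "scan_table")
  r_fwd <- model3_individual_rate(pair3)$value
  pair3$ct <- pair3$ct[2:1, ]
  expect_equal(model3_individual_rate(pair3)$value, -r_fwd)
  bad <- pair
  bad$meta$age <- c(9, 9)
  expect_error(model3_individual_rate(bad), "age gap")
})

test_that("pair splitting yields consecutive pairs only", {
  scans <- gen_longitudinal_ct(fix_parc_small, NULL, 5, 0, 1, seed = 6)
  pairs <- split_scan_pairs(scans)
  expect_length(pairs, 2)  # the triple-scan subject gives (1,2) and (2,3)
  expect_equal(pairs[[1]]$meta$scan_index, 1:2)
  expect_equal(pairs[[2]]$meta$scan_index, 2:3)
  singles <- gen_longitudinal_ct(fix_parc_small, NULL, 6, 0, 0, seed = 7)
  expect_length(split_scan_pairs(singles), 0)
})

test_that("system enrichment z-scores behave under degenerate and planted maps", {
  spins <- spin_surrogates(rep(1, fix_parc$n), fix_parc, n = 50, seed = 1)
  ws <- capture_warnings(out <- system_enrichment(rep(1, fix_parc$n),
                                                  fix_parc$system, spins))
  expect_true(length(ws) >= 1 && all(grepl("degenerate", ws)))
  expect_true(all(out$z == 0))
  # indicator of one system is strongly enriched there
  v <- 1 * (fix_parc$system == 3)
  spins <- spin_surrogates(v, fix_parc, n = 1000, seed = 2)
  out <- suppressWarnings(system_enrichment(v, fix_parc$system, spins))
  expect_gt(out$z[out$system == 3], 3)
  # size-weighted mean over systems equals the global mean in every surrogate
  sizes <- table(factor(fix_parc$system, levels = 1:7))
  for (s in c(1, 10)) {
    per_sys <- vapply(1:7, function(k) mean(spins[s, fix_parc$system == k]),
                      numeric(1))
    expect_equal(sum(per_sys * as.numeric(sizes)) / fix_parc$n,
                 mean(spins[s, ]))
  }
})
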