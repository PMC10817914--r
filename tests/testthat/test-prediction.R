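test_that("a noiseless linear target is predicted almost perfectly", {
  set.seed(14)
  w <- rnorm(fix_parc$n)
  y <- as.vector(fix_prof$S_m[[2]] %*% w) + 0.3
  res <- svr_predict_scale(fix_prof, y, m = 2, k_folds = 10,
                           seed = 1, inner_folds = 3, epsilon = 0.01)
  expect_gte(res$accuracy_r, 0.99)
})

test_that("permuted targets give chance-level accuracy", {
  pl <- make_planted(4, prof = fix_prof_small, parc = fix_parc_small, m = 2)
  rs <- vapply(1:100, function(s) {
    set.seed(s)
    svr_predict_scale(fix_prof_small, sample(pl$map), m = 2, k_folds = 5,
                      c_grid = 1, seed = s)$accuracy_r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("the CV pipeline is reproducible and the degenerate grid is honored", {
  pl <- make_planted(5, prof = fix_prof_small, parc = fix_parc_small, m = 2)
  a <- svr_predict_scale(fix_prof_small, pl$map, m = 2, k_folds = 5,
                         c_grid = 1, seed = 3)
  b <- svr_predict_scale(fix_prof_small, pl$map, m = 2, k_folds = 5,
                         c_grid = 1, seed = 3)
  expect_identical(a, b)
  expect_true(all(a$chosen_cost == 1))
  expect_error(svr_predict_scale(fix_prof_small, rep(1, fix_parc_small$n),
                                 m = 1), "constant")
})

test_that("contributions single out the generating feature", {
  y <- fix_prof_small$S_m[[1]][, 7] * 10
  res <- svr_predict_scale(fix_prof_small, y, m = 1, k_folds = 5,
                           c_grid = 2^(0:4), seed = 2, inner_folds = 3)
  contrib <- feature_contributions(res)
  expect_true(all(contrib >= 0))
  expect_identical(which.max(contrib), 7L)
})

test_that("accuracy degrades monotonically with target noise", {
  pl <- make_planted(6, prof = fix_prof_small, parc = fix_parc_small,
                     m = 2, noise_frac = 0)
  acc <- function(noise_sd, s) {
    set.seed(s)
    y <- pl$clean + rnorm(length(pl$clean), 0, noise_sd)
    svr_predict_scale(fix_prof_small, y, m = 2, k_folds = 5, c_grid = 1,
                      seed = s)$accuracy_r
  }
  sd0 <- sd(pl$clean)
  lo <- vapply(1:20, function(s) acc(0.2 * sd0, s), numeric(1))
  hi <- vapply(1:20, function(s) acc(2 * sd0, s), numeric(1))
  expect_gt(median(lo), median(hi))
})

test_that("prediction significance uses both null families correctly", {
  pl <- make_planted(7, prof = fix_prof_small, parc = fix_parc_small, m = 2)
  res <- svr_predict_scale(fix_prof_small, pl$map, m = 2, k_folds = 5,
                           c_grid = 2^(0:4), seed = 4, inner_folds = 3)
  spins <- spin_surrogates(pl$map, fix_parc_small, n = 19, seed = 5)
  rw <- rewired_surrogates(fix_conn_small, n_bins = 1, n = 19, seed = 6,
                           require_connected = TRUE)
  sig <- prediction_significance(res, fix_prof_small, pl$map,
                                 spin_maps = spins, rewired = rw)
  expect_gte(sig$p_spin, 1 / 20)
  expect_gte(sig$p_rewired, 1 / 20)
  expect_lte(sig$p_spin, 1)
  expect_length(sig$null_spin, 19)
  expect_length(sig$null_rewired, 19)
  expect_lte(sig$p_spin, 0.1)  # planted relation beats 19 spun targets
})
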