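# Cross-validated linear support-vector regression of a nodal map from
# per-scale diffusion profiles, with nested cost selection, per-feature
# contributions, and significance against spin and rewired nulls.

#' The default SVR cost grid: the 16 powers of two from 2^-5 to 2^10
#' @return numeric vector of length 16.
#' @export
default_c_grid <- function() 2^(-5:10)

make_folds <- function(n, k, seed) {
  with_seed(seed, {
    idx <- sample(n)
    split(idx, rep_len(seq_len(k), n))
  })
}

standardize_train <- function(x_tr, x_te) {
  mu <- colMeans(x_tr)
  sdv <- apply(x_tr, 2, sd)
  sdv[sdv == 0] <- 1
  list(tr = sweep(sweep(x_tr, 2, mu), 2, sdv, "/"),
       te = sweep(sweep(x_te, 2, mu), 2, sdv, "/"))
}

# target standardized with training statistics so the epsilon tube is in
# target-sd units; predictions are mapped back to the original scale
svr_fit_predict <- function(x_tr, y_tr, x_te, cost, epsilon) {
  mu <- mean(y_tr)
  sdv <- sd(y_tr)
  if (sdv == 0) sdv <- 1
  fit <- e1071::svm(x = x_tr, y = (y_tr - mu) / sdv, type = "eps-regression",
                    kernel = "linear", cost = cost, epsilon = epsilon,
                    scale = FALSE, fitted = FALSE)
  if (fit$tot.nSV == 0) {  # every training point inside the epsilon tube
    return(list(pred = rep(mu, nrow(x_te)), w = numeric(ncol(x_tr))))
  }
  w <- as.vector(t(fit$coefs) %*% fit$SV)
  list(pred = mu + sdv * as.vector(predict(fit, x_te)), w = w)
}

#' Predict a maturation map from scale-m diffusion profiles with linear SVR
#'
#' Nodes are samples and the rows of the (symmetrized) scale-m diffusion
#' matrix are features. The model is trained with k-fold cross-validation;
#' features are standardized with training-fold statistics only, and the SVR
#' cost parameter is chosen per outer fold by inner cross-validation over
#' `c_grid` (lowest inner RMSE). Out-of-fold predictions are assembled and
#' scored once against the observed map by Pearson correlation.
#'
#' @param profiles a `diffusion_profiles`.
#' @param map numeric nodal map (the prediction target).
#' @param m neighboring scale to use.
#' @param k_folds outer folds (default 10).
#' @param c_grid cost grid (default the 16 powers of two, 2^-5..2^10).
#' @param seed integer seed for the fold shuffle.
#' @param inner_folds inner folds for cost selection.
#' @param epsilon epsilon-insensitive loss width.
#' @param use_symmetrized use `S_m` rows (default) or raw `P_m` rows.
#' @param drop_self drop the self (return-probability) feature column.
#' @return object of class `prediction_result`: list with `m`, `accuracy_r`,
#'   `predictions`, `folds`, `chosen_cost` (per outer fold), `contributions`
#'   (per-feature mean |weight| on the standardized scale).
#' @export
svr_predict_scale <- function(profiles, map, m, k_folds = 10,
                              c_grid = default_c_grid(), seed = 1,
                              inner_folds = 5, epsilon = 0.1,
                              use_symmetrized = TRUE, drop_self = FALSE) {
  stopifnot(k_folds >= 2, length(c_grid) >= 1, m >= 1, m <= profiles$M)
  y <- map_values(map)
  x <- if (use_symmetrized) profiles$S_m[[m]] else profiles$P_m[[m]]
  if (drop_self) diag(x) <- 0
  n <- length(y)
  stopifnot(nrow(x) == n)
  if (sd(y) == 0) stop("prediction target is constant; accuracy undefined")
  folds <- make_folds(n, k_folds, seed)
  preds <- numeric(n)
  chosen <- numeric(k_folds)
  w_mat <- matrix(NA_real_, k_folds, ncol(x))
  for (f in seq_len(k_folds)) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(n), te)
    best_c <- c_grid[1]
    if (length(c_grid) > 1) {
      inner <- split(tr, rep_len(seq_len(inner_folds), length(tr)))
      rmse <- sapply(c_grid, function(cc) {
        errs <- unlist(lapply(inner, function(ite) {
          itr <- setdiff(tr, ite)
          std <- standardize_train(x[itr, , drop = FALSE], x[ite, , drop = FALSE])
          svr_fit_predict(std$tr, y[itr], std$te, cc, epsilon)$pred - y[ite]
        }))
        sqrt(mean(errs^2))
      })
      best_c <- c_grid[which.min(rmse)]
    }
    chosen[f] <- best_c
    std <- standardize_train(x[tr, , drop = FALSE], x[te, , drop = FALSE])
    fit <- svr_fit_predict(std$tr, y[tr], std$te, best_c, epsilon)
    preds[te] <- fit$pred
    w_mat[f, ] <- fit$w
  }
  structure(list(m = m, accuracy_r = cor(y, preds), predictions = preds,
                 folds = folds, chosen_cost = chosen,
                 contributions = colMeans(abs(w_mat)),
                 k_folds = k_folds, c_grid = c_grid, seed = seed,
                 inner_folds = inner_folds, epsilon = epsilon,
                 use_symmetrized = use_symmetrized, drop_self = drop_self),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("SVR prediction at scale", x$m, ": accuracy r =",
      round(x$accuracy_r, 3), "(", x$k_folds, "folds )\n")
  invisible(x)
}

#' Per-feature contributions of a fitted SVR prediction
#'
#' Mean over outer folds of the absolute fitted linear weight per feature,
#' on the standardized feature scale.
#'
#' @param result a `prediction_result`.
#' @return nonnegative numeric vector, one value per feature.
#' @export
feature_contributions <- function(result) result$contributions

#' Significance of SVR prediction accuracy against spin and rewired nulls
#'
#' Re-runs the identical cross-validation procedure (same folds, grid and
#' seed) on each spin-surrogate target map (empirical features), and on
#' features recomputed from each rewired surrogate network (empirical
#' target), then compares the observed accuracy by one-sided empirical p.
#'
#' @param result a `prediction_result`.
#' @param profiles the `diffusion_profiles` used for the observed fit.
#' @param map the observed target map.
#' @param spin_maps matrix of spin surrogate maps (surrogates x nodes), or
#'   NULL to skip.
#' @param rewired list of rewired surrogate `connectome`s (connected), or
#'   NULL to skip.
#' @return list with `p_spin`, `p_rewired` and the null accuracy vectors.
#' @export
prediction_significance <- function(result, profiles, map, spin_maps = NULL,
                                    rewired = NULL) {
  y <- map_values(map)
  rerun <- function(prof, target) {
    svr_predict_scale(prof, target, result$m, k_folds = result$k_folds,
                      c_grid = result$c_grid, seed = result$seed,
                      inner_folds = result$inner_folds,
                      epsilon = result$epsilon,
                      use_symmetrized = result$use_symmetrized,
                      drop_self = result$drop_self)$accuracy_r
  }
  null_spin <- null_rew <- NULL
  p_spin <- p_rew <- NA_real_
  if (!is.null(spin_maps)) {
    null_spin <- apply(spin_maps, 1, function(v) rerun(profiles, v))
    p_spin <- empirical_p(result$accuracy_r, null_spin, "greater")
  }
  if (!is.null(rewired)) {
    null_rew <- vapply(rewired, function(cs) {
      prof <- diffusion_profiles(cs, max_scale = result$m)
      rerun(prof, y)
    }, numeric(1))
    p_rew <- empirical_p(result$accuracy_r, null_rew, "greater")
  }
  list(p_spin = p_spin, p_rewired = p_rew,
       null_spin = null_spin, null_rewired = null_rew)
}
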