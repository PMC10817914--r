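# Per-node cortical-thickness maturation maps under three statistical
# models, pair splitting for individual-level analysis, and system-level
# enrichment against a spin null.

maturation_map <- function(value, model, p = NULL, mask = NULL,
                           alpha_corrected = NULL) {
  stopifnot(all(is.finite(value)))
  structure(list(value = value, model = model, p = p, mask = mask,
                 alpha_corrected = alpha_corrected),
            class = "maturation_map")
}

#' @export
print.maturation_map <- function(x, ...) {
  cat("maturation map (", x$model, "): ", length(x$value), " nodes, range [",
      paste(round(range(x$value), 3), collapse = ", "), "]",
      if (!is.null(x$mask)) paste0(", ", sum(x$mask), " significant"), "\n", sep = "")
  invisible(x)
}

map_values <- function(map) if (inherits(map, "maturation_map")) map$value else
  if (inherits(map, "effect_map")) map$beta else as.numeric(map)

# vectorized OLS t for the group contrast across all nodes at once
ols_group_t <- function(x_mat, ct, term) {
  fit <- lm.fit(x_mat, ct)
  dfree <- nrow(x_mat) - ncol(x_mat)
  sigma2 <- colSums(fit$residuals^2) / dfree
  xtx_inv <- chol2inv(chol(crossprod(x_mat)))
  j <- match(term, colnames(x_mat))
  se <- sqrt(sigma2 * xtx_inv[j, j])
  tval <- fit$coefficients[j, ] / se
  list(t = tval, p = 2 * pt(-abs(tval), dfree))
}

#' Model I: mixed-effects group contrast of cortical thickness
#'
#' Per node, fits thickness on group (child vs adolescent, assigned per scan
#' at the age-10 cut) and sex, with a per-subject random intercept and — when
#' identifiable — a per-subject random group slope (falling back to the
#' intercept-only random structure on non-convergence or a singular fit).
#' Site enters as a fixed covariate when more than one site is present.
#' When every subject has a single scan the random intercept is confounded
#' with the residual and the model reduces to ordinary least squares, which
#' is fit directly.
#'
#' The returned t statistic is the child-minus-adolescent contrast, so
#' cortical thinning with development is positive. Significance is
#' Bonferroni-masked at `alpha / n_nodes` (two-sided).
#'
#' @param scans a `scan_table`.
#' @param alpha family-wise error level before Bonferroni division.
#' @return a `maturation_map` (`model1_t`) with per-node `value` (t), `p`,
#'   `mask` and `alpha_corrected`; per-node random-slope fallback flags in
#'   `attr(, "fallback")`.
#' @export
model1_group_t <- function(scans, alpha = 0.05) {
  meta <- scans$meta
  ct <- scans$ct
  n_nodes <- ncol(ct)
  group <- factor(meta$group, levels = c("child", "adolescent"))
  if (nlevels(droplevels(group)) < 2) stop("both groups must be present")
  for (g in levels(group)) {
    if (length(unique(meta$subject_id[group == g])) < 2)
      stop("need at least 2 subjects per group")
  }
  v <- apply(ct, 2, var)
  if (any(v == 0)) stop("node(s) with zero CT variance: ",
                        paste(which(v == 0) - 1L, collapse = ", "))
  use_site <- !is.null(meta$site) && length(unique(meta$site)) > 1
  single_scan <- all(tabulate(factor(meta$subject_id)) == 1)

  if (single_scan) {
    fml <- if (use_site) ~ group + sex + site else ~ group + sex
    dd <- data.frame(group = group, sex = meta$sex)
    if (use_site) dd$site <- factor(meta$site)
    x_mat <- model.matrix(fml, data = dd)
    res <- ols_group_t(x_mat, ct, "groupadolescent")
    tval <- -res$t
    pval <- res$p
    fallback <- rep(NA, n_nodes)
  } else {
    gnum <- as.numeric(group == "adolescent")
    subject <- factor(meta$subject_id)
    slope_identifiable <- any(tapply(gnum, subject, function(g) length(unique(g)) > 1))
    tval <- pval <- numeric(n_nodes)
    fallback <- logical(n_nodes)
    base_terms <- if (use_site) "group + sex + site" else "group + sex"
    f_slope <- as.formula(paste("y ~", base_terms, "+ (1 + gnum | subject)"))
    f_int <- as.formula(paste("y ~", base_terms, "+ (1 | subject)"))
    for (j in seq_len(n_nodes)) {
      d <- data.frame(y = ct[, j], group = group, gnum = gnum,
                      sex = meta$sex, subject = subject)
      if (use_site) d$site <- factor(meta$site)
      fit <- NULL
      if (slope_identifiable) {
        fit <- tryCatch(suppressMessages(suppressWarnings(
          lmerTest::lmer(f_slope, data = d))), error = function(e) NULL)
        if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-5)) fit <- NULL
      }
      if (is.null(fit)) {
        fallback[j] <- TRUE
        fit <- suppressMessages(suppressWarnings(lmerTest::lmer(f_int, data = d)))
      }
      cf <- summary(fit)$coefficients
      tval[j] <- -cf["groupadolescent", "t value"]
      pval[j] <- cf["groupadolescent", "Pr(>|t|)"]
    }
  }
  alpha_corr <- alpha / n_nodes
  out <- maturation_map(tval, "model1_t", p = pval, mask = pval < alpha_corr,
                        alpha_corrected = alpha_corr)
  attr(out, "fallback") <- fallback
  out
}

#' Model II: penalized-spline age trajectories and maturation rates
#'
#' Per node, fits a thin-plate regression spline of thickness on age
#' (basis dimension `k`) with sex as a linear covariate and a per-subject
#' random intercept, smoothing parameter by REML. The maturation rate at
#' each evaluation age is the first derivative of the fitted age smooth by
#' central finite difference.
#'
#' @param scans a `scan_table` with at least 8 distinct scan ages.
#' @param eval_ages ages (years) at which to evaluate the rate; must lie
#'   within the observed age range.
#' @param k spline basis dimension.
#' @param deriv_step central finite-difference step in years.
#' @param n_grid grid size of the returned fitted curves.
#' @return list with `maps` (one `model2_rate` maturation map per eval age,
#'   mm/y), `eval_ages`, `curves` (list: `age` grid, `fitted` nodes x grid),
#'   and `p_age` (per-node smooth-term p-value).
#' @export
model2_gam <- function(scans, eval_ages, k = 5, deriv_step = 0.01,
                       n_grid = 50) {
  meta <- scans$meta
  ct <- scans$ct
  if (length(unique(meta$age)) < 8) stop("need at least 8 distinct scan ages")
  rng <- range(meta$age)
  if (any(eval_ages < rng[1] | eval_ages > rng[2]))
    stop("eval ages must lie within the observed age range [",
         round(rng[1], 2), ", ", round(rng[2], 2), "]")
  n_nodes <- ncol(ct)
  subject <- factor(meta$subject_id)
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  rates <- matrix(NA_real_, n_nodes, length(eval_ages))
  fitted <- matrix(NA_real_, n_nodes, n_grid)
  p_age <- numeric(n_nodes)
  sex_ref <- mean(meta$sex)
  newd <- function(a) data.frame(age = a, sex = sex_ref, subject = subject[1])
  for (j in seq_len(n_nodes)) {
    d <- data.frame(y = ct[, j], age = meta$age, sex = meta$sex, subject = subject)
    fit <- mgcv::gam(y ~ s(age, bs = "tp", k = k) + sex + s(subject, bs = "re"),
                     data = d, method = "REML")
    hi <- predict(fit, newd(eval_ages + deriv_step / 2), exclude = "s(subject)")
    lo <- predict(fit, newd(eval_ages - deriv_step / 2), exclude = "s(subject)")
    rates[j, ] <- (hi - lo) / deriv_step
    fitted[j, ] <- predict(fit, newd(grid), exclude = "s(subject)")
    p_age[j] <- summary(fit)$s.table["s(age)", "p-value"]
  }
  maps <- lapply(seq_along(eval_ages), function(i)
    maturation_map(rates[, i], "model2_rate"))
  names(maps) <- paste0("age", eval_ages)
  list(maps = maps, eval_ages = eval_ages,
       curves = list(age = grid, fitted = fitted), p_age = p_age)
}

#' Split a roster into consecutive scan pairs
#'
#' Subjects with k scans yield k - 1 consecutive pair-scan samples;
#' single-scan subjects yield none.
#'
#' @param scans a `scan_table`.
#' @return list of two-row `scan_table` objects.
#' @export
split_scan_pairs <- function(scans) {
  meta <- scans$meta
  out <- list()
  for (s in unique(meta$subject_id)) {
    rows <- which(meta$subject_id == s)
    rows <- rows[order(meta$age[rows])]
    if (length(rows) < 2) next
    for (i in seq_len(length(rows) - 1)) {
      pick <- rows[c(i, i + 1)]
      out[[length(out) + 1]] <- structure(
        list(meta = meta[pick, , drop = FALSE],
             ct = scans$ct[pick, , drop = FALSE]),
        class = "scan_table")
    }
  }
  out
}

#' Model III: individual annualized maturation rate
#'
#' Per node, `(CT_second - CT_first) / (age_second - age_first)` in mm/y for
#' one consecutive scan pair. Negative values are cortical thinning.
#'
#' @param scan_pair a two-row `scan_table` from [split_scan_pairs()].
#' @return a `maturation_map` (`model3_rate`).
#' @export
model3_individual_rate <- function(scan_pair) {
  meta <- scan_pair$meta
  if (nrow(meta) != 2) stop("a scan pair must contain exactly two scans")
  if (meta$subject_id[1] != meta$subject_id[2])
    stop("both scans must come from the same subject")
  gap <- meta$age[2] - meta$age[1]
  if (gap <= 0) stop("age gap must be positive")
  maturation_map((scan_pair$ct[2, ] - scan_pair$ct[1, ]) / gap, "model3_rate")
}

#' System-level enrichment of a nodal map against a spin null
#'
#' Expresses each system's observed mean map value as a z score relative to
#' the per-system means of spin-surrogate maps, with a one-sided empirical p
#' for positive enrichment.
#'
#' @param map a `maturation_map` or numeric vector.
#' @param labels per-node system labels.
#' @param spin_ensemble matrix of surrogate maps (surrogates x nodes), e.g.
#'   from [spin_surrogates()].
#' @return data.frame with system, size, observed mean, z and p.
#' @export
system_enrichment <- function(map, labels, spin_ensemble) {
  v <- map_values(map)
  stopifnot(ncol(spin_ensemble) == length(v), length(labels) == length(v))
  systems <- sort(unique(labels))
  out <- data.frame(system = systems,
                    size = as.integer(table(factor(labels, levels = systems))),
                    observed = NA_real_, z = NA_real_, p = NA_real_)
  for (i in seq_along(systems)) {
    sel <- labels == systems[i]
    obs <- mean(v[sel])
    null_means <- rowMeans(spin_ensemble[, sel, drop = FALSE])
    s <- sd(null_means)
    if (s == 0) {
      warning("degenerate null sd for system ", systems[i], "; z set to 0")
      out$z[i] <- 0
      out$p[i] <- 1
    } else {
      out$z[i] <- (obs - mean(null_means)) / s
      out$p[i] <- empirical_p(obs, null_means, "greater")
    }
    out$observed[i] <- obs
  }
  out
}
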