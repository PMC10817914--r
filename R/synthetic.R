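# Synthetic study data: effect maps planted from diffusion profiles,
# longitudinal cortical-thickness rosters and developmental gene panels.

#' Plant a group-effect map from diffusion profiles
#'
#' Builds a per-node group effect (mm) as a weighted sum of the symmetrized
#' scale-m diffusion profile rows of chosen "dominant" nodes, plus spatially
#' smoothed Gaussian noise (one adjacency-averaging pass over iid noise).
#' With empty weights the map is pure smoothed noise.
#'
#' @param profiles a `diffusion_profiles`.
#' @param dominant_nodes integer node indices (1-based) of planted dominant
#'   nodes; may be empty.
#' @param scale_m neighboring scale whose profiles are planted.
#' @param weights numeric weights, one per dominant node (negative weights
#'   plant thinning).
#' @param noise_sd standard deviation of the iid noise before smoothing (mm).
#' @param seed integer RNG seed.
#' @param parcellation parcellation supplying the smoothing adjacency
#'   (defaults to the one attached to `profiles`).
#' @return object of class `effect_map`: list with `beta`, `provenance`,
#'   `dominant_truth`.
#' @export
gen_effect_map <- function(profiles, dominant_nodes = integer(0),
                           scale_m = 1, weights = numeric(0), noise_sd = 0,
                           seed = 1, parcellation = NULL) {
  if (is.null(parcellation)) parcellation <- profiles$parcellation
  stopifnot(length(dominant_nodes) == length(weights))
  stopifnot(scale_m >= 1, scale_m <= profiles$M)
  n <- nrow(profiles$P)
  beta <- numeric(n)
  effective <- dominant_nodes[weights != 0]
  for (k in seq_along(dominant_nodes))
    beta <- beta + weights[k] * profiles$S_m[[scale_m]][dominant_nodes[k], ]
  if (noise_sd > 0) {
    noise <- with_seed(seed, rnorm(n, 0, noise_sd))
    adj <- parcellation$adjacency
    beta <- beta + (noise + as.vector(adj %*% noise)) / (1 + rowSums(adj))
  }
  structure(list(beta = beta,
                 provenance = if (length(effective)) "planted_from_diffusion" else "autocorrelated_null",
                 dominant_truth = effective, scale_m = scale_m),
            class = "effect_map")
}

#' Generate isotropic spatially autocorrelated nodal maps
#'
#' Draws nodal maps from a Gaussian process with a squared-exponential
#' kernel on inter-centroid Euclidean distances. Because the kernel is
#' isotropic, these maps are exchangeable under sphere rotations, which
#' makes them the appropriate network-independent null for spin-test
#' calibration (adjacency-smoothed noise, by contrast, is smooth with
#' respect to the very graph scale under test).
#'
#' @param parcellation a `parcellation`.
#' @param length_scale kernel length scale (same units as centroids).
#' @param n number of maps.
#' @param seed integer RNG seed.
#' @return numeric vector (n = 1) or n x nodes matrix.
#' @export
gen_autocorrelated_map <- function(parcellation, length_scale = 0.3, n = 1,
                                   seed = 1) {
  d <- euclidean_distance_matrix(parcellation)
  k <- exp(-d^2 / (2 * length_scale^2)) + 1e-8 * diag(parcellation$n)
  l <- t(chol(k))
  out <- with_seed(seed,
    t(l %*% matrix(rnorm(parcellation$n * n), parcellation$n, n)))
  if (n == 1) out[1, ] else out
}

#' Generate a longitudinal cortical-thickness scan roster
#'
#' Emulates an accelerated longitudinal design: `n_single`, `n_double` and
#' `n_triple` subjects with 1, 2 and 3 scans, first-scan ages uniform over
#' `age_range`, repeat scans spaced about one year apart. Per-scan per-node
#' thickness is
#' `baseline + beta * 1[adolescent] + sex_effect * sex + subject intercept + noise`,
#' with group assigned from the scan age at the 10-year cut (age >= 10 is
#' adolescent).
#'
#' @param parcellation a `parcellation`.
#' @param effect_map an `effect_map` (its `beta`, mm, is added for
#'   adolescent-group scans), or NULL for no group effect.
#' @param n_single,n_double,n_triple subject counts by number of scans.
#' @param age_range first-scan age range in years, within (4, 16).
#' @param subject_sd sd of the per-subject random intercept (mm).
#' @param noise_sd sd of iid scan noise (mm).
#' @param sex_effect additive effect of sex = 1 (mm).
#' @param baseline per-node baseline thickness (mm); scalar or length-n
#'   vector. Default 2.5 mm plus a fixed spatial gradient.
#' @param age_cut group cut in years (default 10).
#' @param seed integer RNG seed.
#' @return object of class `scan_table`: list with `meta` (data.frame:
#'   subject_id, scan_index, age, sex, group, site) and `ct` (scans x nodes
#'   matrix, mm).
#' @export
gen_longitudinal_ct <- function(parcellation, effect_map = NULL,
                                n_single = 158, n_double = 105, n_triple = 51,
                                age_range = c(6, 13), subject_sd = 0.1,
                                noise_sd = 0.05, sex_effect = 0.02,
                                baseline = NULL, age_cut = 10, seed = 1) {
  stopifnot(n_single >= 0, n_double >= 0, n_triple >= 0)
  if (n_single + n_double + n_triple == 0) stop("all subject counts are zero")
  if (age_range[1] < 4 || age_range[2] > 16 || age_range[1] >= age_range[2])
    stop("age_range must be an increasing interval within (4, 16)")
  n <- parcellation$n
  beta <- if (is.null(effect_map)) numeric(n) else effect_map$beta
  stopifnot(length(beta) == n)
  if (is.null(baseline)) baseline <- 2.5 + 0.2 * parcellation$centroids[, "z"]
  baseline <- rep(baseline, length.out = n)
  with_seed(seed, {
    n_scans_per <- rep(c(1L, 2L, 3L), c(n_single, n_double, n_triple))
    n_subj <- length(n_scans_per)
    sex <- rbinom(n_subj, 1, 0.5)
    intercept <- if (subject_sd > 0) rnorm(n_subj, 0, subject_sd) else numeric(n_subj)
    first_age <- runif(n_subj, age_range[1], age_range[2])
    meta <- do.call(rbind, lapply(seq_len(n_subj), function(i) {
      gaps <- if (n_scans_per[i] > 1) runif(n_scans_per[i] - 1, 0.8, 1.2) else numeric(0)
      ages <- first_age[i] + cumsum(c(0, gaps))
      data.frame(subject_id = sprintf("sub%04d", i),
                 scan_index = seq_len(n_scans_per[i]),
                 age = ages, sex = sex[i],
                 group = ifelse(ages >= age_cut, "adolescent", "child"),
                 site = "site1", stringsAsFactors = FALSE)
    }))
    rownames(meta) <- NULL
    n_rows <- nrow(meta)
    subj_idx <- match(meta$subject_id, sprintf("sub%04d", seq_len(n_subj)))
    ct <- matrix(rep(baseline, each = n_rows), n_rows, n)
    ct <- ct + outer(meta$group == "adolescent", beta, `*`)
    ct <- ct + sex_effect * meta$sex
    ct <- ct + intercept[subj_idx]
    if (noise_sd > 0) ct <- ct + matrix(rnorm(n_rows * n, 0, noise_sd), n_rows, n)
    if (any(!is.finite(ct)) || any(ct <= 0))
      stop("generated thickness must be finite and positive; reduce effect or noise sizes")
    structure(list(meta = meta, ct = ct), class = "scan_table")
  })
}

#' @export
print.scan_table <- function(x, ...) {
  cat("scan table:", nrow(x$meta), "scans,",
      length(unique(x$meta$subject_id)), "subjects,",
      ncol(x$ct), "nodes; age",
      paste(round(range(x$meta$age), 2), collapse = "-"), "y\n")
  invisible(x)
}

#' Generate a developmental gene-expression panel
#'
#' Samples are region x age tissue measurements with a dominant /
#' non-dominant category per region. Genes in a target set share a latent
#' age trajectory whose level differs between categories by `divergence`
#' (in latent units; positive means higher in dominant regions); background
#' genes are iid standard normal noise.
#'
#' @param n_genes total gene count (sets plus background).
#' @param gene_sets named integer vector of set sizes, e.g.
#'   `c(axon = 30, myelination = 30)`.
#' @param region_categories named character vector mapping region name to
#'   "dominant" or "non_dominant".
#' @param ages numeric vector of sample ages (years) per region.
#' @param divergence scalar or named (per set) latent category offset.
#' @param noise_sd residual expression noise sd.
#' @param seed integer RNG seed.
#' @return object of class `gene_panel`: list with `expression`
#'   (samples x genes), `region`, `category`, `age`, `gene_sets` (named list
#'   of gene ids).
#' @export
gen_gene_panel <- function(n_genes = 200,
                           gene_sets = c(set1 = 20),
                           region_categories = c(r1 = "dominant", r2 = "dominant",
                                                 r3 = "non_dominant", r4 = "non_dominant"),
                           ages = seq(4, 16, by = 2),
                           divergence = 1, noise_sd = 0.5, seed = 1) {
  stopifnot(sum(gene_sets) <= n_genes, all(gene_sets >= 1))
  if (is.null(names(gene_sets))) names(gene_sets) <- paste0("set", seq_along(gene_sets))
  div <- if (is.null(names(divergence))) setNames(rep(divergence, length.out = length(gene_sets)),
                                                 names(gene_sets)) else divergence
  regions <- names(region_categories)
  with_seed(seed, {
    samp <- expand.grid(region = regions, age = ages, stringsAsFactors = FALSE)
    category <- unname(region_categories[samp$region])
    n_samp <- nrow(samp)
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    expr <- matrix(rnorm(n_samp * n_genes, 0, 1), n_samp, n_genes,
                   dimnames = list(NULL, gene_ids))
    sets <- list()
    offset <- 0
    for (s in names(gene_sets)) {
      idx <- offset + seq_len(gene_sets[[s]])
      sets[[s]] <- gene_ids[idx]
      offset <- offset + gene_sets[[s]]
      # shared increasing latent age trajectory, category-shifted
      latent <- scale(samp$age)[, 1] + div[[s]] * (category == "dominant")
      loading <- runif(length(idx), 0.5, 1.5)
      expr[, idx] <- outer(latent, loading) +
        matrix(rnorm(n_samp * length(idx), 0, noise_sd), n_samp, length(idx))
    }
    structure(list(expression = expr, region = samp$region,
                   category = category, age = samp$age, gene_sets = sets),
              class = "gene_panel")
  })
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("gene panel:", nrow(x$expression), "samples x", ncol(x$expression),
      "genes;", length(x$gene_sets), "gene set(s);",
      sum(x$category == "dominant"), "dominant samples\n")
  invisible(x)
}
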