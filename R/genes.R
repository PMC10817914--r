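# Gene-expression contrasts: gene-set first-principal-component scores,
# dominant vs non-dominant category contrasts with a gene-resampling null,
# and dominance-map x gene-map correlations with spin + FDR.

#' First-principal-component score of a gene set
#'
#' Projects samples onto the first principal axis of the column-standardized
#' expression submatrix of the set, fit jointly over all samples.
#' Zero-variance genes are dropped with a warning. The sign is fixed so the
#' mean loading is nonnegative.
#'
#' @param panel a `gene_panel` (or a samples x genes matrix with column
#'   names).
#' @param gene_set character vector of gene ids (subset of panel genes).
#' @return numeric per-sample score vector.
#' @export
geneset_pc1 <- function(panel, gene_set) {
  expr <- if (inherits(panel, "gene_panel")) panel$expression else panel
  stopifnot(length(gene_set) >= 1, nrow(expr) >= 3)
  missing <- setdiff(gene_set, colnames(expr))
  if (length(missing)) stop("gene(s) not in panel: ", paste(missing, collapse = ", "))
  x <- expr[, gene_set, drop = FALSE]
  v <- apply(x, 2, sd)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance gene(s)")
    x <- x[, v > 0, drop = FALSE]
    if (ncol(x) == 0) stop("gene set empty after dropping zero-variance genes")
  }
  x <- scale(x)
  sv <- svd(x, nu = 1, nv = 1)
  loading <- sv$v[, 1]
  if (mean(loading) < 0) loading <- -loading
  as.vector(x %*% loading)
}

#' Dominant vs non-dominant gene-set expression contrast
#'
#' Difference between the mean gene-set PC1 score of dominant-category and
#' non-dominant-category samples within an age window, tested against a
#' null distribution obtained by resampling same-size gene sets from the
#' remaining panel genes (sample categories unchanged). The p-value is
#' one-sided in the observed direction.
#'
#' @param panel a `gene_panel`.
#' @param gene_set character vector of gene ids.
#' @param age_window inclusive age window in years (default 6-14,
#'   childhood to adolescence).
#' @param n_resamples number of resampled null gene sets.
#' @param seed integer RNG seed.
#' @return list with `difference`, `p`, `direction`, `n_samples`, `null`.
#' @export
dominant_contrast <- function(panel, gene_set, age_window = c(6, 14),
                              n_resamples = 1000, seed = 1) {
  keep <- panel$age >= age_window[1] & panel$age <= age_window[2]
  if (!any(panel$category[keep] == "dominant") ||
      !any(panel$category[keep] == "non_dominant"))
    stop("both categories must be present within the age window")
  sub <- list(expression = panel$expression[keep, , drop = FALSE])
  cat_keep <- panel$category[keep]
  contrast_of <- function(genes) {
    sc <- suppressWarnings(geneset_pc1(sub$expression, genes))
    mean(sc[cat_keep == "dominant"]) - mean(sc[cat_keep == "non_dominant"])
  }
  obs <- contrast_of(gene_set)
  remaining <- setdiff(colnames(panel$expression), gene_set)
  if (length(remaining) < length(gene_set))
    stop("fewer remaining genes than the target set size")
  null <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i)
      contrast_of(sample(remaining, length(gene_set))), numeric(1))
  })
  direction <- if (obs >= 0) "greater" else "less"
  list(difference = obs, p = empirical_p(obs, null, direction),
       direction = direction, n_samples = sum(keep), null = null)
}

#' Correlate a dominance-likelihood map with per-gene expression maps
#'
#' Per gene, the Pearson correlation across regions between the likelihood
#' map and the gene's expression map; two-sided significance from one shared
#' spin ensemble of the likelihood map, Benjamini-Hochberg corrected across
#' genes. Constant gene maps are skipped with a warning.
#'
#' @param likelihood_map numeric per-region map.
#' @param gene_maps regions x genes expression matrix (column names = gene
#'   ids) aligned to the same regions.
#' @param parcellation a `parcellation` whose nodes match the regions.
#' @param n_spin number of spin surrogates.
#' @param fdr_alpha FDR level for the significant gene lists.
#' @param seed integer RNG seed.
#' @param spin_assign optional precomputed [spin_assignments()].
#' @return list with `table` (gene, r, p_spin, q_fdr, significant),
#'   `positive`, `negative` (significant gene id vectors).
#' @export
map_gene_correlation <- function(likelihood_map, gene_maps, parcellation,
                                 n_spin = 1000, fdr_alpha = 0.05, seed = 1,
                                 spin_assign = NULL) {
  v <- map_values(likelihood_map)
  stopifnot(nrow(gene_maps) == length(v))
  ok <- apply(gene_maps, 2, sd) > 0
  if (!all(ok)) warning("skipping ", sum(!ok), " constant gene map(s)")
  gm <- gene_maps[, ok, drop = FALSE]
  if (is.null(spin_assign))
    spin_assign <- spin_assignments(parcellation, n_spin, seed = seed)
  surr <- t(apply(spin_assign, 1, function(a) v[a]))  # surrogates x regions
  r_obs <- as.vector(cor(v, gm))
  r_null <- cor(t(surr), gm)                          # surrogates x genes
  p <- (colSums(abs(r_null) >= matrix(abs(r_obs), nrow(r_null),
                                      length(r_obs), byrow = TRUE)) + 1) /
    (nrow(r_null) + 1)
  q <- p.adjust(p, "BH")
  tab <- data.frame(gene = colnames(gm), r = r_obs, p_spin = p, q_fdr = q,
                    significant = q < fdr_alpha, stringsAsFactors = FALSE)
  list(table = tab,
       positive = tab$gene[tab$significant & tab$r > 0],
       negative = tab$gene[tab$significant & tab$r < 0])
}
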