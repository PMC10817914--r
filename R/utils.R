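#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor lm coef pt quantile rnorm runif sd var prcomp
#'   p.adjust predict rbinom resid setNames uniroot dist model.matrix lm.fit
#'   chol2inv as.formula median
#' @importFrom utils read.csv write.csv read.delim write.table head
NULL

# cosine similarity between two vectors; errors on zero norm
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero-norm vector")
  sum(a * b) / (na * nb)
}

# set the RNG reproducibly; all exported generators funnel through this
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# average rank with ties, ascending
ascending_rank <- function(x) rank(x, ties.method = "average")

#' Moran's I spatial autocorrelation
#'
#' Computes Moran's I of a nodal map under a binary spatial weight matrix.
#' Used to verify that spin surrogates preserve the spatial autocorrelation
#' of the input map.
#'
#' @param values numeric vector, one value per node.
#' @param adjacency symmetric binary (or logical) spatial weight matrix.
#' @return scalar Moran's I.
#' @export
morans_i <- function(values, adjacency) {
  w <- 1 * (adjacency != 0)
  diag(w) <- 0
  n <- length(values)
  z <- values - mean(values)
  s0 <- sum(w)
  if (s0 == 0 || sum(z^2) == 0) stop("Moran's I undefined (no weights or constant map)")
  (n / s0) * sum(w * outer(z, z)) / sum(z^2)
}
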