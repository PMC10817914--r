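# Plain-text readers and writers for the pipeline's data products.
# Conventions: node ids are 0-based in all files (1-based inside R),
# thickness in mm, age in years, edge lists are tab-separated with i < j.

#' Write / read a node table (parcellation) CSV
#'
#' Columns: node_id, hemi, x, y, z, system, laminar; node_id is 0-based.
#'
#' @param parcellation a `parcellation`.
#' @param path CSV path.
#' @return `read_node_table` returns a `parcellation` without an adjacency
#'   relation unless `rebuild_adjacency = TRUE` (per-hemisphere Delaunay).
#' @export
write_node_table <- function(parcellation, path) {
  df <- data.frame(node_id = seq_len(parcellation$n) - 1L,
                   hemi = as.character(parcellation$hemisphere),
                   x = parcellation$centroids[, "x"],
                   y = parcellation$centroids[, "y"],
                   z = parcellation$centroids[, "z"],
                   system = parcellation$system,
                   laminar = parcellation$laminar)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_node_table
#' @param path CSV path.
#' @param rebuild_adjacency recompute the spatial adjacency from centroids.
#' @export
read_node_table <- function(path, rebuild_adjacency = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("node_id", "hemi", "x", "y", "z", "system", "laminar")
  if (!identical(names(df)[seq_along(need)], need))
    stop("node table must have header: ", paste(need, collapse = ","))
  if (!identical(df$node_id, seq_len(nrow(df)) - 1L))
    stop("node_id must be 0..N-1 in order")
  n <- nrow(df)
  centroids <- cbind(x = df$x, y = df$y, z = df$z)
  hemisphere <- factor(df$hemi, levels = c("left", "right"))
  adjacency <- matrix(FALSE, n, n)
  if (rebuild_adjacency) {
    for (h in c("left", "right")) {
      idx <- which(hemisphere == h)
      if (length(idx) >= 3) {
        seg <- hemisphere_delaunay(centroids[idx, , drop = FALSE],
                                   if (h == "left") -1 else +1)
        for (s in seq_len(nrow(seg))) {
          a <- idx[seg[s, 1]]; b <- idx[seg[s, 2]]
          adjacency[a, b] <- adjacency[b, a] <- TRUE
        }
      }
    }
  }
  structure(list(n = n, hemisphere = hemisphere, centroids = centroids,
                 system = df$system, laminar = df$laminar,
                 adjacency = adjacency, seed = NA),
            class = "parcellation")
}

#' Write / read a binary edge list TSV (0-based, i < j)
#'
#' @param connectome a `connectome` (or binary adjacency matrix).
#' @param path TSV path.
#' @export
write_edge_list <- function(connectome, path) {
  a <- if (inherits(connectome, "connectome")) connectome$adjacency else connectome
  e <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  df <- data.frame(i = e[, 1] - 1L, j = e[, 2] - 1L)
  df <- df[order(df$i, df$j), ]
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param n_nodes node count of the adjacency to build.
#' @param parcellation optional `parcellation` to attach (supplies n_nodes
#'   and distances).
#' @export
read_edge_list <- function(path, n_nodes = NULL, parcellation = NULL) {
  df <- read.delim(path)
  if (!identical(names(df), c("i", "j"))) stop("edge list must have header i<TAB>j")
  if (is.null(n_nodes)) {
    if (!is.null(parcellation)) n_nodes <- parcellation$n
    else n_nodes <- max(df$i, df$j) + 1L
  }
  # normalize to i < j, 1-based
  a <- pmin(df$i, df$j) + 1L
  b <- pmax(df$i, df$j) + 1L
  if (any(a == b)) stop("self-loop in edge list")
  key <- paste(a, b)
  if (anyDuplicated(key)) stop("duplicate edge(s) in edge list")
  adj <- matrix(0, n_nodes, n_nodes)
  adj[cbind(a, b)] <- 1
  adj <- adj + t(adj)
  as_connectome(adj, parcellation = parcellation)
}

#' Write / read a scan table (metadata CSV + thickness matrix CSV)
#'
#' The thickness matrix row order equals the metadata row order; columns are
#' nodes (`node0...`). Ages must be strictly increasing within subject.
#'
#' @param scans a `scan_table`.
#' @param meta_path,ct_path CSV paths.
#' @export
write_scan_table <- function(scans, meta_path, ct_path) {
  write.csv(scans$meta, meta_path, row.names = FALSE)
  ct <- as.data.frame(scans$ct)
  names(ct) <- paste0("node", seq_len(ncol(ct)) - 1L)
  write.csv(ct, ct_path, row.names = FALSE)
  invisible(meta_path)
}

#' @rdname write_scan_table
#' @export
read_scan_table <- function(meta_path, ct_path) {
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  ct <- as.matrix(read.csv(ct_path))
  if (nrow(meta) != nrow(ct))
    stop("metadata and thickness matrix row counts differ")
  for (s in unique(meta$subject_id)) {
    ages <- meta$age[meta$subject_id == s]
    if (any(diff(ages) <= 0))
      stop("scan ages must be strictly increasing within subject ", s)
  }
  if (any(!is.finite(ct)) || any(ct <= 0))
    stop("thickness values must be finite and positive")
  dimnames(ct) <- NULL
  structure(list(meta = meta, ct = ct), class = "scan_table")
}

#' Write / read a gene panel (expression CSV + gene-set JSON)
#'
#' The CSV carries region, category and age sample columns followed by one
#' column per gene; the JSON maps set names to gene-id lists.
#'
#' @param panel a `gene_panel`.
#' @param expr_path,sets_path file paths.
#' @export
write_gene_panel <- function(panel, expr_path, sets_path) {
  df <- cbind(data.frame(region = panel$region, category = panel$category,
                         age = panel$age, stringsAsFactors = FALSE),
              as.data.frame(panel$expression))
  write.csv(df, expr_path, row.names = FALSE)
  jsonlite::write_json(panel$gene_sets, sets_path)
  invisible(expr_path)
}

#' @rdname write_gene_panel
#' @export
read_gene_panel <- function(expr_path, sets_path) {
  df <- read.csv(expr_path, stringsAsFactors = FALSE)
  expr <- as.matrix(df[, -(1:3), drop = FALSE])
  if (any(!is.finite(expr))) stop("missing expression values after loading")
  sets <- lapply(jsonlite::read_json(sets_path), function(s)
    vapply(s, as.character, character(1)))
  bad <- unlist(sets)[!unlist(sets) %in% colnames(expr)]
  if (length(bad)) stop("gene set member(s) not in panel: ",
                        paste(unique(bad), collapse = ", "))
  structure(list(expression = expr, region = df$region,
                 category = df$category, age = df$age, gene_sets = sets),
            class = "gene_panel")
}
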