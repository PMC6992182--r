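#' Build the species-by-index matrix for clustering
#'
#' Turns a [nutritional_indices()] table into a numeric matrix with species
#' as rows, optionally z-scoring each index column (mean 0, sample SD 1).
#' Standardization is on by default because the five indices live on
#' different scales (the n-6/n-3 ratio spans roughly 0.1–0.5 while HH spans
#' 0.6–1.4 in typical marine fish), and unscaled Euclidean distances would
#' be dominated by the widest column.
#'
#' @param indices a `"nutritional_indices"` data frame (or any data frame
#'   with a `species` column and numeric index columns).
#' @param scale logical; z-score each column.
#' @return A numeric matrix of class `"index_matrix"` with species row
#'   names and attribute `"scaled"`.
#' @examples
#' m <- index_matrix(nutritional_indices(load_study_fixture()))
#' round(colMeans(m), 10)
#' @export
index_matrix <- function(indices, scale = TRUE) {
  stopifnot(is.data.frame(indices), "species" %in% names(indices),
            nrow(indices) >= 2)
  m <- as.matrix(indices[, setdiff(names(indices), "species"), drop = FALSE])
  rownames(m) <- indices$species
  if (scale) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      stop("cannot z-score zero-variance column(s): ",
           paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
    }
    m <- base::scale(m)
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
  }
  structure(m, scaled = scale, class = c("index_matrix", class(m)))
}

#' Hierarchical clustering of species on the index matrix
#'
#' Agglomerative clustering of species with Euclidean distances on the
#' (usually z-scored) five-index matrix, cut into `k` groups. Groups are
#' renumbered 1..k by increasing composite nutritional quality — the mean
#' z-score of the favourable indices (HH, P/S) minus the mean z-score of
#' the unfavourable ones (IA, IT, n-6/n-3) — so group k always holds the
#' nutritionally most desirable species. Agglomeration is deterministic;
#' ties in merge distance are resolved by the lowest cluster index pair.
#'
#' @param x an [index_matrix()].
#' @param linkage `"complete"`, `"average"` or `"ward"` (Ward D2).
#' @param k number of groups to cut (>= 2).
#' @return An object of class `"species_clusters"`: list with elements
#'   `hclust` (the merge tree), `leaf_order` (species in dendrogram order),
#'   `k`, `groups` (named integer vector of group ids) and `linkage`.
#' @examples
#' cl <- cluster_species(index_matrix(nutritional_indices(load_study_fixture())))
#' table(cl$groups)
#' @export
cluster_species <- function(x, linkage = c("complete", "average", "ward"),
                            k = 4) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(x, "index_matrix"))
  if (nrow(x) < 2) stop("clustering needs at least 2 species", call. = FALSE)
  k <- as.integer(k)
  if (k < 1 || k > nrow(x)) {
    stop("k must lie between 1 and the number of species", call. = FALSE)
  }
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::dist(unclass(x), method = "euclidean"),
                      method = method)
  raw <- stats::cutree(hc, k = k)
  groups <- .renumber_by_quality(x, raw)
  structure(list(hclust = hc, leaf_order = hc$labels[hc$order], k = k,
                 groups = groups, linkage = linkage),
            class = "species_clusters")
}

# Relabel cluster ids 1..k in order of increasing group-mean composite
# quality score (mean z of hh, ps minus mean z of ia, it, n6_n3). Columns
# are matched by name; any extra columns count as favourable.
.renumber_by_quality <- function(x, raw) {
  z <- base::scale(unclass(x))  # idempotent if already z-scored
  bad <- intersect(colnames(z), c("ia", "it", "n6_n3"))
  good <- setdiff(colnames(z), bad)
  score <- rowMeans(z[, good, drop = FALSE]) -
    (if (length(bad)) rowMeans(z[, bad, drop = FALSE]) else 0)
  means <- tapply(score, raw, mean)
  relab <- stats::setNames(rank(means, ties.method = "first"), names(means))
  out <- as.integer(relab[as.character(raw)])
  stats::setNames(out, names(raw))
}

#' @export
print.species_clusters <- function(x, ...) {
  cat(sprintf("Hierarchical clustering (%s linkage, Euclidean), k = %d\n",
              x$linkage, x$k))
  for (g in sort(unique(x$groups))) {
    cat(sprintf("  group %d: %s\n", g,
                paste(names(x$groups)[x$groups == g], collapse = ", ")))
  }
  invisible(x)
}

#' @export
plot.species_clusters <- function(x, ...) {
  plot(x$hclust, main = "Species clustered on nutritional quality indices",
       xlab = "", sub = "", ...)
  invisible(x)
}

#' Export the clustered index matrix as a heatmap table
#'
#' Writes the index matrix with rows reordered to the dendrogram leaf order
#' as tab-separated text (the testable artifact behind a heatmap figure),
#' and optionally renders a raster heatmap through the pheatmap package
#' when it is installed.
#'
#' @param x an [index_matrix()].
#' @param clusters a `"species_clusters"` from [cluster_species()] on the
#'   same species.
#' @param path destination for the TSV (columns: `species`, then one column
#'   per index; full precision).
#' @param image optional path for a PNG heatmap; ignored with a message if
#'   pheatmap is not installed.
#' @return Invisibly, `path`.
#' @export
export_heatmap <- function(x, clusters, path, image = NULL) {
  stopifnot(inherits(x, "index_matrix"), inherits(clusters, "species_clusters"))
  if (!setequal(rownames(x), names(clusters$groups))) {
    stop("matrix and clustering cover different species", call. = FALSE)
  }
  ord <- clusters$leaf_order
  out <- data.frame(species = ord, unclass(x)[ord, , drop = FALSE],
                    row.names = NULL, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(image)) {
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      pheatmap::pheatmap(unclass(x), cluster_rows = clusters$hclust,
                         cluster_cols = FALSE, filename = image)
    } else {
      message("pheatmap not installed; skipping raster heatmap")
    }
  }
  invisible(path)
}
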