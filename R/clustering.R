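#' Hierarchical clustering of samples (1 - Pearson distance)
#'
#' Agglomerative clustering of sample expression profiles restricted to the
#' signature genes, using `d(a, b) = 1 - cor(a, b)` as distance and average
#' (UPGMA) linkage by default. The distance is invariant to positive affine
#' transforms of a profile, so duplicated or rescaled samples merge at
#' height 0.
#'
#' @param x numeric matrix, genes x samples (typically centred VST values
#'   restricted to a [select_signature()] set).
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return An [stats::hclust] dendrogram over samples.
#' @export
hcluster_samples <- function(x, linkage = "average") {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need >= 2 samples", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0] %||% which(sds == 0)
    stop(sprintf("zero-variance profile for sample(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(x))
  stats::hclust(d, method = linkage)
}

#' Hierarchical clustering of genes (Euclidean distance)
#'
#' Same linkage as the sample clustering, but with Euclidean distance over
#' samples, the study's choice for the gene axis.
#'
#' @param x numeric matrix, genes x samples.
#' @param linkage agglomeration method.
#' @return An [stats::hclust] dendrogram over genes.
#' @export
hcluster_genes <- function(x, linkage = "average") {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need >= 2 genes", call. = FALSE)
  stats::hclust(stats::dist(x), method = linkage)
}

#' Co-clustering purity of a query group with a reference group
#'
#' Cuts the sample dendrogram into `k` flat clusters (the cut below the
#' k - 1 highest merges) and returns the fraction of query-group samples
#' assigned to the flat cluster holding the majority of reference-group
#' samples. Used to quantify "tumor samples cluster with early embryos".
#'
#' @param dend an [stats::hclust] over samples (labels = sample ids).
#' @param meta data frame with `sample` and `group` columns.
#' @param k number of flat clusters (<= number of samples).
#' @param query_group,reference_group group labels present in `meta`.
#' @return Purity in `[0, 1]`.
#' @export
co_cluster_purity <- function(dend, meta, k, query_group, reference_group) {
  if (!inherits(dend, "hclust")) stop("`dend` must be an hclust", call. = FALSE)
  n <- length(dend$labels)
  if (k > n) stop("`k` cannot exceed the number of samples", call. = FALSE)
  grp <- meta$group[match(dend$labels, meta$sample)]
  for (g in c(query_group, reference_group)) {
    if (!g %in% grp) stop(sprintf("group '%s' not present", g), call. = FALSE)
  }
  cl <- stats::cutree(dend, k = k)
  ref_counts <- table(cl[grp == reference_group])
  top <- max(ref_counts)
  winners <- names(ref_counts)[ref_counts == top]
  if (length(winners) > 1L) {
    stop(sprintf(
      "reference group '%s' has no majority cluster (tied clusters: %s)",
      reference_group, paste(winners, collapse = ", ")), call. = FALSE)
  }
  mean(cl[grp == query_group] == as.integer(winners))
}

#' Export a dendrogram as Newick
#'
#' Writes an [stats::hclust] tree with branch lengths equal to merge-height
#' differences, via [ape::as.phylo()].
#'
#' @param dend an [stats::hclust] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dend, path) {
  ape::write.tree(ape::as.phylo(dend), file = path)
  invisible(path)
}

#' Signature clustering in one step
#'
#' Convenience wrapper running the study's clustering recipe on a count
#' matrix: size factors, simplified VST, per-gene centring, restriction to
#' the signature genes, then sample clustering (1 - Pearson) and gene
#' clustering (Euclidean).
#'
#' @param counts count matrix, genes x samples.
#' @param signature character vector of signature gene ids.
#' @param linkage agglomeration method for both dendrograms.
#' @return List with `samples` and `genes` (both [stats::hclust]) and the
#'   centred signature `matrix`.
#' @export
cluster_signature <- function(counts, signature, linkage = "average") {
  missing_genes <- setdiff(signature, rownames(counts))
  if (length(missing_genes) > 0L) {
    stop(sprintf("signature genes absent from the matrix: %s",
                 paste(utils::head(missing_genes, 5), collapse = ", ")),
         call. = FALSE)
  }
  v <- vst_counts(counts)
  cen <- center_rows(v)[signature, , drop = FALSE]
  list(samples = hcluster_samples(cen, linkage = linkage),
       genes = hcluster_genes(cen, linkage = linkage),
       matrix = cen)
}
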