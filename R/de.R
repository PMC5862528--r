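#' Negative-binomial Wald differential expression (two groups)
#'
#' A lightweight two-group DE test used to select signature genes on
#' synthetic counts. Per gene, group means are taken on
#' median-of-ratios-normalised counts; the per-gene NB dispersion is
#' estimated by method of moments on the pooled within-group residuals
#' (`alpha = max(0, (s^2 - m) / m^2)`) and moderated by the across-genes
#' median (per-gene estimates below the median are raised to it, guarding
#' against the strong downward noise of moment estimates at a few samples
#' per group); the Wald statistic is the log2 fold change over its
#' delta-method standard error
#' (`Var(log2 m-hat) = (m + alpha m^2) / (n m^2 ln(2)^2)` per group), with
#' two-sided normal p-values; raw p-values are Benjamini-Hochberg adjusted. This is a declared stand-in,
#' not a reimplementation of a full DE framework.
#'
#' @param counts count matrix, genes x samples.
#' @param group character/factor of length `ncol(counts)` with exactly two
#'   levels, each with >= 2 samples.
#' @param alpha adjusted-p cutoff for the DE flag (default 0.01, the
#'   study's signature threshold).
#' @param pseudocount added to group means before taking the fold change.
#' @return Object of class `de_result`: data frame with `gene`,
#'   `base_mean`, `log2fc`, `se`, `stat`, `pvalue`, `padj`, `direction`
#'   (up/down relative to the second group level vs the first), `de`.
#' @export
simple_de <- function(counts, group, alpha = 0.01, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L) stop("exactly two groups required", call. = FALSE)
  if (any(table(group) < 2L)) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, `/`)
  g1 <- group == levels(group)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  # pooled within-group moments
  v1 <- apply(norm[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, g2, drop = FALSE], 1, stats::var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  m <- (n1 * m1 + n2 * m2) / (n1 + n2)
  disp <- ifelse(m > 0, pmax(0, (s2 - m) / m^2), 0)
  expressed <- m > 1
  if (any(expressed)) {
    disp <- pmax(disp, stats::median(disp[expressed]))
  }
  lfc <- log2((m2 + pseudocount) / (m1 + pseudocount))
  var_log2_mean <- function(mm, nn) {
    ifelse(mm > 0, (mm + disp * mm^2) / (nn * mm^2 * log(2)^2), Inf)
  }
  se <- sqrt(var_log2_mean(m1, n1) + var_log2_mean(m2, n2))
  stat <- ifelse(is.finite(se) & se > 0, lfc / se, 0)
  pvalue <- 2 * stats::pnorm(-abs(stat))
  padj <- stats::p.adjust(pvalue, method = "BH")
  res <- data.frame(
    gene = rownames(counts) %||% sprintf("gene_%d", seq_len(nrow(counts))),
    base_mean = m, log2fc = lfc, se = se, stat = stat,
    pvalue = pvalue, padj = padj,
    direction = ifelse(lfc >= 0, "up", "down"),
    de = padj <= alpha & is.finite(stat) & stat != 0,
    stringsAsFactors = FALSE)
  attr(res, "alpha") <- alpha
  attr(res, "contrast") <- sprintf("%s vs %s", levels(group)[2],
                                   levels(group)[1])
  class(res) <- c("de_result", "data.frame")
  res
}

#' Select the TF-signature gene set
#'
#' Intersects the DE genes with an annotation set (e.g. transcription
#' factor-encoding genes), mirroring the study's restriction of the
#' signature to differentially expressed genes involved in transcriptional
#' regulation. Order is stable by gene id.
#'
#' @param de a [simple_de()] result.
#' @param tf_annotation character vector of annotated gene ids (non-empty).
#' @return Object of class `signature_gene_set`: sorted character vector of
#'   gene ids with `provenance` attribute (alpha, annotation size).
#' @export
select_signature <- function(de, tf_annotation) {
  if (length(tf_annotation) == 0L) {
    stop("`tf_annotation` must be non-empty", call. = FALSE)
  }
  sig <- sort(intersect(de$gene[de$de], tf_annotation))
  if (length(sig) == 0L) {
    stop("no DE gene is in the annotation set; clustering impossible",
         call. = FALSE)
  }
  structure(sig, provenance = list(alpha = attr(de, "alpha"),
                                   n_de = sum(de$de),
                                   n_annotation = length(tf_annotation)),
            class = c("signature_gene_set", "character"))
}
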