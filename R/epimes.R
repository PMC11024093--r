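# Epithelial-mesenchymal (EPI-MES) tumor signature scoring: per-gene
# z-scoring of log2 expression, correlation-threshold signature
# refinement, EPI minus MES score, quintile stratification, per-stratum
# marker correlation panels and correlation-matrix clustering.

#' Packaged epithelial / mesenchymal / subtype-marker gene lists
#'
#' Returns the curated marker lists shipped with the package (plain-text
#' resource under `extdata`). The raw resource preserves the source
#' list order, including one duplicated epithelial symbol (*KRT5*);
#' loading deduplicates so every gene appears exactly once.
#'
#' @return List with character vectors `epithelial` (25 genes),
#'   `mesenchymal` (15) and `subtype_markers` (9).
#' @export
epimes_gene_lists <- function() {
  path <- system.file("extdata", "epimes_gene_lists.tsv",
                      package = "calshape", mustWork = TRUE)
  df <- utils::read.delim(path)
  list(epithelial = unique(df$gene[df$list == "epithelial"]),
       mesenchymal = unique(df$gene[df$list == "mesenchymal"]),
       subtype_markers = unique(df$gene[df$list == "subtype_marker"]))
}

#' Per-gene z-scores across tumors
#'
#' Standardises each gene (column) of a tumors x genes log2 expression
#' matrix to zero mean and unit standard deviation (n - 1 denominator)
#' across tumors. Genes with zero cross-tumor variance, or with any
#' missing value, cannot be scored and are dropped with a warning.
#'
#' @param expr Tumors x genes numeric matrix of log2 expression, gene
#'   symbols as column names.
#' @return Tumors x genes matrix of z-scores (possibly fewer columns).
#' @export
zscore_genes <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2) stop("need at least two tumors", call. = FALSE)
  if (is.null(colnames(expr)))
    stop("'expr' must have gene symbols as column names", call. = FALSE)
  has_na <- colSums(is.na(expr)) > 0
  if (any(has_na)) {
    warning(sprintf("dropping %d gene(s) with missing values: %s",
                    sum(has_na),
                    paste(utils::head(colnames(expr)[has_na], 5),
                          collapse = ", ")))
    expr <- expr[, !has_na, drop = FALSE]
  }
  sds <- apply(expr, 2, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warning(sprintf("dropping %d zero-variance gene(s): %s", sum(flat),
                    paste(utils::head(colnames(expr)[flat], 5),
                          collapse = ", ")))
    expr <- expr[, !flat, drop = FALSE]
    sds <- sds[!flat]
  }
  scale(expr, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Refine a signature by correlation with its own average z-score
#'
#' Retains the genes of `genes` whose cross-tumor Pearson correlation
#' with the unweighted mean z-score of the full list (the gene itself
#' included) is strictly greater than `threshold`.
#'
#' @param z Tumors x genes z-score matrix from [zscore_genes()].
#' @param genes Character vector: the full signature list.
#' @param threshold Correlation cutoff (strict), default 0.5.
#' @return Character vector: the refined signature (a subset of `genes`).
#' @export
refine_signature <- function(z, genes, threshold = 0.5) {
  missing <- setdiff(genes, colnames(z))
  if (length(missing))
    stop("signature genes absent from the z matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  avg <- rowMeans(z[, genes, drop = FALSE])
  r <- as.numeric(stats::cor(z[, genes, drop = FALSE], avg))
  refined <- genes[r > threshold]
  if (length(refined) == 0)
    stop("no gene exceeds the correlation threshold; signature is empty",
         call. = FALSE)
  refined
}

#' EPI-MES score and quintile stratification
#'
#' Each tumor's epithelial z-score is the unweighted mean z over the
#' refined epithelial genes, likewise for mesenchymal; the EPI-MES score
#' is their difference (negative = mesenchymal-high, positive =
#' epithelial-high). Tumors are ranked by score and cut into five
#' equal-count ordered strata: H-MES, L-MES, Ambig, L-EPI, H-EPI
#' (lowest to highest score; sizes balanced within one tumor, ties broken
#' by input order).
#'
#' @param z Tumors x genes z-score matrix.
#' @param refined_epi,refined_mes Refined signatures (see
#'   [refine_signature()]).
#' @return Data frame with `tumor`, `epi_z`, `mes_z`, `score` and ordered
#'   factor `quintile`.
#' @export
score_and_stratify <- function(z, refined_epi, refined_mes) {
  if (length(refined_epi) == 0 || length(refined_mes) == 0)
    stop("refined signatures must be non-empty", call. = FALSE)
  if (nrow(z) < 5)
    stop("quintile stratification needs at least five tumors",
         call. = FALSE)
  epi_z <- rowMeans(z[, refined_epi, drop = FALSE])
  mes_z <- rowMeans(z[, refined_mes, drop = FALSE])
  score <- epi_z - mes_z
  labels <- c("H-MES", "L-MES", "Ambig", "L-EPI", "H-EPI")
  rk <- rank(score, ties.method = "first")
  q <- ceiling(rk * 5 / length(score))
  data.frame(tumor = rownames(z) %||% sprintf("tumor_%d", seq_along(score)),
             epi_z = epi_z, mes_z = mes_z, score = score,
             quintile = factor(labels[q], levels = labels, ordered = TRUE),
             row.names = NULL)
}

#' Per-stratum correlations of a target gene with a marker panel
#'
#' Pearson correlation (with two-sided p-value, no multiplicity
#' adjustment) of the target gene's expression with each marker gene,
#' computed separately within each stratum (e.g. the EPI-MES quintiles).
#' Strata with fewer than three tumors are reported as not computable
#' (`NA`).
#'
#' @param expr Tumors x genes log2 expression matrix.
#' @param target Target gene symbol.
#' @param markers Character vector of marker gene symbols.
#' @param strata Stratum label per tumor (length `nrow(expr)`).
#' @return Data frame with `stratum`, `marker`, `n`, `r`, `p`.
#' @export
marker_correlations <- function(expr, target, markers, strata) {
  if (!target %in% colnames(expr))
    stop("target gene absent from the matrix", call. = FALSE)
  missing <- setdiff(markers, colnames(expr))
  if (length(missing))
    stop("marker genes absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(strata) != nrow(expr))
    stop("'strata' must have one label per tumor", call. = FALSE)
  out <- list(); k <- 0L
  for (s in unique(strata)) {
    sel <- strata == s
    for (m in markers) {
      k <- k + 1L
      if (sum(sel) < 3) {
        out[[k]] <- data.frame(stratum = s, marker = m, n = sum(sel),
                               r = NA_real_, p = NA_real_)
        next
      }
      ct <- stats::cor.test(expr[sel, target], expr[sel, m],
                            method = "pearson")
      out[[k]] <- data.frame(stratum = s, marker = m, n = sum(sel),
                             r = unname(ct$estimate), p = ct$p.value)
    }
  }
  do.call(rbind, out)
}

#' Cluster a gene-gene correlation matrix
#'
#' Hierarchical clustering with average linkage on Manhattan distances
#' between the rows of the correlation matrix, cut into `k` groups -
#' the standard way to organise a marker correlation heatmap into blocks
#' of co-varying genes.
#'
#' @param cor_mat Square symmetric correlation matrix with gene names.
#' @param k Number of groups to cut the tree into.
#' @return List with `order` (gene names in dendrogram order), `groups`
#'   (named integer vector of group assignments) and `hclust` (the tree).
#' @export
cluster_correlation_matrix <- function(cor_mat, k) {
  cor_mat <- as.matrix(cor_mat)
  if (nrow(cor_mat) != ncol(cor_mat) ||
      !isTRUE(all.equal(cor_mat, t(cor_mat), tolerance = 1e-8)))
    stop("'cor_mat' must be square and symmetric", call. = FALSE)
  if (k > nrow(cor_mat))
    stop("'k' cannot exceed the number of genes", call. = FALSE)
  hc <- stats::hclust(stats::dist(cor_mat, method = "manhattan"),
                      method = "average")
  groups <- stats::cutree(hc, k = k)
  list(order = rownames(cor_mat)[hc$order], groups = groups, hclust = hc)
}

#' Comparative-Ct relative quantification
#'
#' Converts a delta-delta-Ct value to the relative fold change
#' `2^(-ddCt)`, the percent of transcript remaining (fold x 100) and the
#' log2-scale relative mRNA value `-ddCt`.
#'
#' @param delta_delta_ct Numeric vector of ddCt values.
#' @return Data frame with `delta_delta_ct`, `fold_change`,
#'   `percent_remaining`, `relative_mrna`.
#' @examples
#' ddct_quantitation(c(0, 1, -2))  # fold 1, 0.5, 4
#' @export
ddct_quantitation <- function(delta_delta_ct) {
  if (!is.numeric(delta_delta_ct) || any(!is.finite(delta_delta_ct)))
    stop("'delta_delta_ct' must be finite numeric", call. = FALSE)
  fold <- 2^(-delta_delta_ct)
  data.frame(delta_delta_ct = delta_delta_ct, fold_change = fold,
             percent_remaining = 100 * fold,
             relative_mrna = -delta_delta_ct)
}
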