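#' Preprocess a probe-level expression matrix
#'
#' Removes probes whose log2 expression is below the background level in at
#' least \code{background_fraction} of samples (boundary inclusive), then
#' collapses multi-probe genes by their median expression.
#'
#' @param matrix probes x samples numeric matrix of log2 intensities.
#' @param probe_gene named character vector, probe -> gene symbol.
#' @param background background noise level on the log2 scale.
#' @param background_fraction fraction of samples below background that
#'   removes a probe (default 0.8).
#' @return genes x samples matrix.
#' @export
preprocessExpression <- function(matrix, probe_gene, background,
                                 background_fraction = 0.8) {
  stopifnot(all(rownames(matrix) %in% names(probe_gene)))
  frac_low <- rowMeans(matrix < background)
  keep <- frac_low < background_fraction   # >= fraction below => removed
  m <- matrix[keep, , drop = FALSE]
  if (!nrow(m)) stop("no probes left after background filtering")
  gene <- probe_gene[rownames(m)]
  collapsed <- apply(m, 2, function(col) tapply(col, gene, stats::median))
  if (is.null(dim(collapsed)))   # single gene edge case
    collapsed <- matrix(collapsed, 1,
                        dimnames = list(unique(gene), colnames(m)))
  collapsed
}

#' Remove batch effects by per-batch mean centering
#'
#' For each gene, subtracts the batch mean and adds back the grand mean —
#' the fixed-effect special case of linear-model batch correction. After
#' correction the per-gene batch means coincide; for batch-balanced group
#' designs, group contrasts are unchanged.
#'
#' @param matrix genes x samples matrix.
#' @param batch character/factor of batch labels, one per sample.
#' @return corrected matrix. A single batch returns the input unchanged;
#'   single-sample batches are allowed (message).
#' @export
removeBatchEffects <- function(matrix, batch) {
  batch <- as.character(batch)
  stopifnot(length(batch) == ncol(matrix))
  if (length(unique(batch)) < 2) return(matrix)
  sizes <- table(batch)
  if (any(sizes == 1))
    message("batch(es) with a single sample: ",
            paste(names(sizes)[sizes == 1], collapse = ", "))
  grand <- rowMeans(matrix)
  out <- matrix
  for (b in unique(batch)) {
    j <- batch == b
    out[, j] <- matrix[, j, drop = FALSE] -
      rowMeans(matrix[, j, drop = FALSE]) + grand
  }
  out
}

#' Differential expression by Welch's t-test
#'
#' Per-gene Welch t-test on log2 values between two sample groups, BH
#' adjustment, and a signed linear fold change
#' \code{FC = 2^d} when the log2 mean difference \code{d >= 0}, else
#' \code{-2^(-d)}, so the usual "FC >= 1.5 or <= -1.5" selection rule reads
#' directly. Genes with zero variance in both groups and equal means get
#' p = 1.
#'
#' @param matrix genes x samples matrix of log2 expression.
#' @param group_a,group_b column names (or indices) of the two groups
#'   (>= 2 each); the difference is mean(A) - mean(B).
#' @param fc_threshold,adj_p_threshold selection cutoffs (defaults 1.5 and
#'   0.01).
#' @return list: \code{table} (gene, log2_diff, fold_change, p_value,
#'   adj_p, selected) and \code{selected} (gene list).
#' @export
differentialExpression <- function(matrix, group_a, group_b,
                                   fc_threshold = 1.5,
                                   adj_p_threshold = 0.01) {
  a <- matrix[, group_a, drop = FALSE]
  b <- matrix[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2 || nb < 2) stop("need >= 2 samples per group")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  d <- ma - mb
  t_stat <- ifelse(se2 > 0, d / sqrt(se2), NA_real_)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t_stat), df),
              ifelse(d == 0, 1, 0))
  adj <- stats::p.adjust(p, "BH")
  fc <- ifelse(d >= 0, 2^d, -2^(-d))
  selected <- (fc >= fc_threshold | fc <= -fc_threshold) &
    adj < adj_p_threshold
  tab <- data.frame(gene = rownames(matrix), log2_diff = d,
                    fold_change = fc, p_value = p, adj_p = adj,
                    selected = selected,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, selected = tab$gene[selected])
}

# Internal: hierarchical co-clustering of patients and cell lines on a
# feature x sample matrix; a cell line is labeled 1 iff its cluster holds
# the majority of the non-responder samples.
coclusterCore <- function(m, nonresponders, cell_lines, k = 2,
                          linkage = "average") {
  if (k > ncol(m)) stop("k exceeds the number of samples")
  cc <- suppressWarnings(stats::cor(m))
  cc[is.na(cc)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - cc), method = linkage)
  cl <- stats::cutree(hc, k = k)
  nr_counts <- table(factor(cl[nonresponders], levels = seq_len(k)))
  nr_cluster <- as.integer(which.max(nr_counts))
  stats::setNames(as.integer(cl[cell_lines] == nr_cluster), cell_lines)
}

#' Co-clustering similarity labels on DEG expression
#'
#' Hierarchically clusters patients and cell lines together — average
#' linkage on (1 - Pearson) sample distance, cut into \code{k} clusters —
#' on the matrix restricted to the differentially expressed genes. A cell
#' line is labeled 1 iff it falls in the cluster containing the majority of
#' the non-responder samples.
#'
#' @param matrix genes x samples matrix (patients and cell lines),
#'   restricted to the DEG list by the caller.
#' @param nonresponders,cell_lines sample name vectors.
#' @param k number of clusters (default 2).
#' @param linkage hclust linkage (default "average").
#' @return named integer vector of 0/1 labels per cell line.
#' @export
coclusterLabels <- function(matrix, nonresponders, cell_lines, k = 2,
                            linkage = "average") {
  coclusterCore(matrix, nonresponders, cell_lines, k, linkage)
}

#' Top variable genes across cell lines
#'
#' The \code{n} genes with the largest standard deviation across the
#' cell-line panel; ties broken deterministically by gene name.
#'
#' @param matrix genes x cell lines matrix.
#' @param n number of genes (default 2000).
#' @return character vector of gene names, most variable first.
#' @export
topVariableGenes <- function(matrix, n = 2000) {
  if (n > nrow(matrix)) stop("n exceeds the number of genes")
  sds <- apply(matrix, 1, stats::sd)
  ord <- order(-sds, rownames(matrix))
  rownames(matrix)[ord][seq_len(n)]
}

#' Spearman representativeness of cell lines
#'
#' For each cell line, the mean Spearman correlation — over the
#' non-responder samples, on the supplied gene list — summarizes its
#' similarity to the poor-responder population; cell lines are ranked by
#' this average (descending) and labeled 1 when ranked within
#' \code{top_rank}. Constant expression vectors make a correlation
#' undefined; such terms are excluded from the mean (message).
#'
#' @param cellline_matrix genes x cell lines matrix.
#' @param nonresponder_matrix genes x non-responder samples matrix.
#' @param genes gene list present in both matrices.
#' @param top_rank rank cutoff for the similarity label (default 100).
#' @return data.frame: cell_line, avg_spearman, rank, label.
#' @export
spearmanRepresentativeness <- function(cellline_matrix, nonresponder_matrix,
                                       genes, top_rank = 100) {
  stopifnot(all(genes %in% rownames(cellline_matrix)),
            all(genes %in% rownames(nonresponder_matrix)))
  cl <- cellline_matrix[genes, , drop = FALSE]
  nr <- nonresponder_matrix[genes, , drop = FALSE]
  rho <- suppressWarnings(stats::cor(cl, nr, method = "spearman"))
  if (anyNA(rho))
    message("undefined Spearman correlation(s) from constant vectors ",
            "excluded from the average")
  avg <- rowMeans(rho, na.rm = TRUE)
  rk <- rank(-avg, ties.method = "first")
  data.frame(cell_line = colnames(cl),
             avg_spearman = as.numeric(avg),
             rank = as.integer(rk),
             label = as.integer(rk <= top_rank),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Co-clustering labels on ssGSEA pathway scores
#'
#' As [coclusterLabels()], but on a gene set x sample enrichment-score
#' matrix (see [ssgseaScores()]): pathway-level similarity instead of
#' gene-level.
#'
#' @param ssgsea gene sets x samples score matrix.
#' @inheritParams coclusterLabels
#' @return named integer vector of 0/1 labels per cell line.
#' @export
ssgseaCoclusterLabels <- function(ssgsea, nonresponders, cell_lines, k = 2,
                                  linkage = "average") {
  coclusterCore(ssgsea, nonresponders, cell_lines, k, linkage)
}

#' Overall representativeness ranking
#'
#' Sums the three binary similarity labels (DEG co-clustering, Spearman
#' top-rank, ssGSEA co-clustering) per cell line and ranks by the sum,
#' descending, breaking ties by the average Spearman correlation.
#'
#' @param label_cluster,label_spearman,label_ssgsea named 0/1 vectors over
#'   the same cell lines.
#' @param avg_spearman named numeric vector (tie-break).
#' @return data.frame: cell_line, the three labels, avg_spearman,
#'   overall_score (0..3), overall_rank (1-based).
#' @export
overallRepresentativeness <- function(label_cluster, label_spearman,
                                      label_ssgsea, avg_spearman) {
  cl <- names(label_cluster)
  for (v in list(label_spearman, label_ssgsea, avg_spearman)) {
    miss <- setdiff(cl, names(v))
    if (length(miss) || length(setdiff(names(v), cl)))
      stop("missing label for cell line(s): ",
           paste(union(miss, setdiff(names(v), cl)), collapse = ", "))
  }
  score <- label_cluster[cl] + label_spearman[cl] + label_ssgsea[cl]
  ord <- order(-score, -avg_spearman[cl])
  rk <- integer(length(cl)); rk[ord] <- seq_along(cl)
  data.frame(cell_line = cl,
             label_cluster = as.integer(label_cluster[cl]),
             label_spearman = as.integer(label_spearman[cl]),
             label_ssgsea = as.integer(label_ssgsea[cl]),
             avg_spearman = as.numeric(avg_spearman[cl]),
             overall_score = as.integer(score),
             overall_rank = rk,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full three-analysis representativeness framework
#'
#' Orchestrates: differential expression (non-responders vs responders,
#' Welch t + BH), DEG co-clustering, top-variable-gene Spearman ranking
#' against the non-responders, ssGSEA pathway co-clustering, and the
#' sum-of-labels overall ranking.
#'
#' @param expr a \code{SummarizedExperiment} as produced by
#'   [simulateTranscriptomeCohort()] (assay \code{"exprs"}, colData
#'   \code{kind}, \code{response}, \code{batch}).
#' @param gene_sets named list of gene sets for the ssGSEA analysis.
#' @param n_top_genes top-variable-gene count (capped at the universe).
#' @param top_rank Spearman label rank cutoff.
#' @param fc_threshold,adj_p_threshold DEG selection cutoffs.
#' @return list: \code{deg} (DE result), \code{report} (the
#'   [overallRepresentativeness()] table, ranked) and the per-analysis
#'   labels.
#' @export
runRepresentativeness <- function(expr, gene_sets, n_top_genes = 2000,
                                  top_rank = 100, fc_threshold = 1.5,
                                  adj_p_threshold = 0.01) {
  m <- assay(expr, "exprs")
  cd <- colData(expr)
  pats <- rownames(cd)[cd$kind == "patient"]
  cells <- rownames(cd)[cd$kind == "cell_line"]
  nr <- rownames(cd)[!is.na(cd$response) & cd$response == "non_responder"]
  rs <- rownames(cd)[!is.na(cd$response) & cd$response == "responder"]
  pm <- m[, pats, drop = FALSE]
  if (length(unique(stats::na.omit(cd[pats, "batch"]))) > 1)
    pm <- removeBatchEffects(pm, cd[pats, "batch"])
  de <- differentialExpression(pm, nr, rs, fc_threshold, adj_p_threshold)
  degs <- de$selected
  corrected <- cbind(pm, m[, cells, drop = FALSE])
  lab_cluster <- if (length(degs) >= 2)
    coclusterLabels(corrected[degs, , drop = FALSE], nr, cells)
  else stats::setNames(rep(0L, length(cells)), cells)
  tv <- topVariableGenes(m[, cells, drop = FALSE],
                         min(n_top_genes, nrow(m)))
  sp <- spearmanRepresentativeness(m[, cells, drop = FALSE],
                                   m[, nr, drop = FALSE], tv, top_rank)
  lab_spearman <- stats::setNames(sp$label, sp$cell_line)
  es <- ssgseaScores(corrected, gene_sets)
  lab_ssgsea <- ssgseaCoclusterLabels(es, nr, cells)
  report <- overallRepresentativeness(
    lab_cluster, lab_spearman, lab_ssgsea,
    stats::setNames(sp$avg_spearman, sp$cell_line))
  list(deg = de,
       report = report[order(report$overall_rank), , drop = FALSE],
       labels = list(cluster = lab_cluster, spearman = lab_spearman,
                     ssgsea = lab_ssgsea))
}
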