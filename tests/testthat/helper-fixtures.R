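# Fixture builders and independent oracles shared across the suite.

suppressPackageStartupMessages(library(SummarizedExperiment))

makeLibrary <- function(n_genes, guides_per_gene = 3, n_safe = 0,
                        gene_prefix = "G") {
  n_t <- n_genes * guides_per_gene
  GuideLibrary(
    guide_id = c(sprintf("g%04d", seq_len(n_t)),
                 if (n_safe) sprintf("s%02d", seq_len(n_safe))),
    gene = c(rep(sprintf("%s%03d", gene_prefix, seq_len(n_genes)),
                 each = guides_per_gene),
             rep(SAFE_GENE, n_safe)),
    role = c(rep("targeting", n_t), rep("safe", n_safe)))
}

# the desk-scale CDKO scenario: 40 genes x 3 guides + 4 safe
makeCdkoScenario <- function(n_planted = 20, gamma = -2, seed = 99) {
  lib <- makeLibrary(40, 3, 4)
  dual <- buildDualDesign(lib)
  genes <- targetGenes(lib)
  set.seed(seed)
  planted <- character(0)
  while (length(planted) < n_planted) {
    planted <- unique(c(planted,
                        paste(sort(sample(genes, 2)), collapse = "__")))
  }
  planted <- planted[seq_len(n_planted)]
  list(lib = lib, dual = dual, planted = planted,
       gamma = stats::setNames(rep(gamma, n_planted), planted))
}

safeSafeConstructs <- function(dual) {
  ct <- constructTable(dual)
  ct$construct_id[ct$gene1 == SAFE_GENE & ct$gene2 == SAFE_GENE]
}

# normalize -> LFC -> fitness -> four scores, in one call
runCdkoScores <- function(sim, dual, lib, pseudocount = 1, ...) {
  norm <- normalizeCounts(sim$counts, safeSafeConstructs(dual))
  lfc <- constructLfc(norm, dual, pseudocount = pseudocount)
  fitness <- singleGeneFitness(lfc, dual, lib)
  slScores(lfc, fitness, dual, ...)
}

writeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

simpleDesign <- function(n_t0 = 1, n_tend = 1, condition = "control") {
  data.frame(
    sample_id = c(sprintf("T0_%d", seq_len(n_t0)),
                  sprintf("Tend_%d", seq_len(n_tend))),
    timepoint = c(rep("T0", n_t0), rep("Tend", n_tend)),
    condition = condition,
    replicate = c(seq_len(n_t0), seq_len(n_tend)),
    stringsAsFactors = FALSE)
}

# brute-force pairwise-difference Gini oracle
giniBrute <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# explicit two-step-walk ssGSEA oracle for a single sample
ssgseaBruteSample <- function(values, members, alpha = 0.25) {
  r <- unname(rank(values, ties.method = "average"))
  ord <- order(-r)
  inset <- names(values)[ord] %in% members
  n <- length(values); m <- sum(inset)
  denom_in <- sum((r[ord]^alpha)[inset])
  p_in <- 0; p_out <- 0; es <- 0
  for (i in seq_len(n)) {
    if (inset[i]) p_in <- p_in + r[ord][i]^alpha / denom_in
    else if (m < n) p_out <- p_out + 1 / (n - m)
    es <- es + (p_in - p_out)
  }
  es
}

# explicit min-over-order-statistics rho oracle for one pair
rraRhoBrute <- function(percentiles) {
  r <- sort(percentiles)
  vals <- numeric(length(r))
  for (k in seq_along(r))
    vals[k] <- stats::pbeta(r[k], k, length(r) - k + 1)
  min(vals)
}
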