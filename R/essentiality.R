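#' Control-guide median-ratio normalization
#'
#' Per-sample size factors are the median, over the control guides, of the
#' ratio of that guide's count to its geometric mean across samples (the
#' median-of-ratios estimator restricted to non-targeting controls); each
#' sample is divided by its factor. When no control list is supplied the
#' estimator falls back to all guides, with a warning.
#'
#' @param counts a [ScreenCountSet-class].
#' @param control_guides character vector of control guide ids present in
#'   the table; \code{NULL} for the all-guide fallback.
#' @return a [ScreenCountSet-class] with real-valued normalized counts; the
#'   size factors are kept in \code{metadata(x)$size_factors}.
#' @export
normalizeCounts <- function(counts, control_guides = NULL) {
  stopifnot(is(counts, "ScreenCountSet"))
  m <- assay(counts, "counts")
  if (is.null(control_guides) || !length(control_guides)) {
    warning("no control guides supplied; falling back to all-guide median-ratio")
    ref <- m
  } else {
    missing <- setdiff(control_guides, rownames(m))
    if (length(missing))
      stop("control guides absent from count table: ",
           paste(utils::head(missing, 5), collapse = ", "))
    ref <- m[control_guides, , drop = FALSE]
    all_zero <- colSums(ref) == 0
    if (any(all_zero))
      stop("all control guides are zero in sample(s): ",
           paste(colnames(m)[all_zero], collapse = ", "))
  }
  gm <- exp(rowMeans(log(ref)))      # 0 when any sample has a zero
  usable <- is.finite(gm) & gm > 0
  if (!any(usable))
    stop("no control guide has positive counts in every sample")
  ratios <- ref[usable, , drop = FALSE] / gm[usable]
  sf <- apply(ratios, 2, stats::median)
  if (any(sf <= 0))
    stop("non-positive size factor in sample(s): ",
         paste(colnames(m)[sf <= 0], collapse = ", "))
  out <- ScreenCountSet(sweep(m, 2, sf, "/"), screenDesign(counts))
  S4Vectors::metadata(out)$size_factors <- sf
  out
}

#' Guide-level log2 fold changes Tend vs T0
#'
#' The T0 reference is the mean of the (normalized) T0 replicates — a
#' single pooled baseline, matching a screen design in which T0 precedes
#' the branching into treatment arms. Each Tend replicate is compared
#' against it: \code{lfc = log2(tend + pc) - log2(t0_ref + pc)}.
#'
#' @param counts a (normalized) [ScreenCountSet-class].
#' @param pseudocount added inside both logs (default 1).
#' @return data.frame with \code{guide_id}, \code{condition},
#'   \code{replicate}, \code{lfc}.
#' @export
guideLfc <- function(counts, pseudocount = 1) {
  stopifnot(is(counts, "ScreenCountSet"))
  m <- assay(counts, "counts")
  des <- screenDesign(counts)
  t0 <- des$timepoint == "T0"
  if (!any(t0)) stop("no T0 samples present")
  tend <- which(des$timepoint == "Tend")
  if (!length(tend)) stop("no Tend samples present")
  t0_ref <- rowMeans(m[, t0, drop = FALSE])
  ref_log <- log2(t0_ref + pseudocount)
  out <- lapply(tend, function(j) {
    data.frame(guide_id = rownames(m),
               condition = des$condition[j],
               replicate = des$replicate[j],
               lfc = log2(m[, j] + pseudocount) - ref_log,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gene essentiality (beta) scores with permutation p-values
#'
#' The beta score of a gene in a condition is the mean, over the gene's
#' guides, of the replicate-averaged guide log2 fold change — a log2-scale
#' depletion/enrichment score sharing the sign convention of
#' maximum-likelihood screen scorers (negative = knockout depleted =
#' essential). Two-sided permutation p-values come from
#' \code{n_permutations} random same-size guide sets drawn from all
#' targeting guides of the condition; FDR is Benjamini-Hochberg within
#' condition.
#'
#' @param lfc a [guideLfc()] table.
#' @param library the [GuideLibrary-class] (safe guides are excluded from
#'   gene scoring and from the permutation pool).
#' @param n_permutations permutations per guide-count stratum
#'   (default 10000; < 100 warns).
#' @param seed integer RNG seed.
#' @return data.frame: \code{gene}, \code{condition}, \code{n_guides},
#'   \code{beta}, \code{p_value}, \code{fdr}.
#' @export
geneBeta <- function(lfc, library, n_permutations = 10000, seed = 1L) {
  stopifnot(is(library, "GuideLibrary"))
  if (n_permutations < 100)
    warning("n_permutations < 100 gives very coarse p-values")
  gmap <- guideGeneMap(library)
  roles <- guideRoles(library)
  set.seed(seed)
  res <- list()
  for (cond in unique(lfc$condition)) {
    sub <- lfc[lfc$condition == cond, , drop = FALSE]
    avg <- tapply(sub$lfc, sub$guide_id, mean)      # replicate-averaged
    keep <- names(avg)[roles[names(avg)] == "targeting" &
                         !is.na(roles[names(avg)])]
    avg <- avg[keep]
    gene <- gmap[keep]
    beta <- tapply(avg, gene, mean)
    sizes <- tapply(avg, gene, length)
    p <- rep(NA_real_, length(beta))
    pool <- as.numeric(avg)
    # each gene gets its own permutation null (chunked to bound memory)
    for (k in sort(unique(sizes))) {
      sel <- which(sizes == k)
      chunk <- max(1L, as.integer(5e6 / (n_permutations * k)))
      for (start in seq(1, length(sel), by = chunk)) {
        genes_i <- sel[start:min(start + chunk - 1, length(sel))]
        g <- length(genes_i)
        draws <- matrix(pool[sample.int(length(pool),
                                        n_permutations * g * k,
                                        replace = TRUE)],
                        nrow = n_permutations * g, ncol = k)
        null_means <- matrix(rowMeans(draws), n_permutations, g)
        obs <- abs(beta[genes_i])
        ge <- colSums(abs(null_means) >=
                        rep(obs, each = n_permutations) - 1e-12)
        p[genes_i] <- (1 + ge) / (n_permutations + 1)
      }
    }
    res[[cond]] <- data.frame(gene = names(beta), condition = cond,
                              n_guides = as.integer(sizes),
                              beta = as.numeric(beta),
                              p_value = p,
                              fdr = stats::p.adjust(p, "BH"),
                              row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Select chemotherapy re-sensitizer genes
#'
#' Genes tolerated (or enriched) in the untreated arm but depleted under
#' drug: \code{beta[control] > thr_control} and
#' \code{beta[drug] < thr_drug}. Defaults implement the literal
#' "higher than 1 in control, less than -1 under drug" rule; both
#' thresholds are configurable (e.g. \code{thr_control = -1} for a
#' "not essential" reading).
#'
#' @param beta a [geneBeta()] table.
#' @param control_condition,drug_condition condition labels present in
#'   \code{beta}.
#' @param thr_control,thr_drug score thresholds (defaults 1 and -1).
#' @return data.frame of selected genes sorted by drug beta ascending, with
#'   both scores.
#' @export
selectResensitizers <- function(beta, control_condition = "control",
                                drug_condition, thr_control = 1,
                                thr_drug = -1) {
  for (cond in c(control_condition, drug_condition))
    if (!cond %in% beta$condition)
      stop("condition absent from beta table: ", cond)
  bc <- beta[beta$condition == control_condition, c("gene", "beta")]
  bd <- beta[beta$condition == drug_condition, c("gene", "beta")]
  m <- merge(bc, bd, by = "gene", suffixes = c("_control", "_drug"))
  sel <- m[m$beta_control > thr_control & m$beta_drug < thr_drug, ,
           drop = FALSE]
  sel[order(sel$beta_drug), , drop = FALSE]
}

#' Overlap of two gene lists
#'
#' @param list_a,list_b character vectors.
#' @return list with \code{genes} (intersection, in \code{list_a} order)
#'   and \code{count}.
#' @export
overlapGenes <- function(list_a, list_b) {
  g <- list_a[list_a %in% list_b]
  g <- g[!duplicated(g)]
  list(genes = g, count = length(g))
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric tail \eqn{P(X \ge k)} per set, against a
#' user-supplied universe; BH correction across sets. Set members outside
#' the universe are ignored (the count is reported via a message).
#'
#' @param gene_list character vector, a subset of \code{universe}.
#' @param sets named list of member vectors (see [readGeneSetsGmt()]).
#' @param universe character vector of all testable genes.
#' @return data.frame: set, set_size (in-universe), overlap, p_value, fdr,
#'   members (comma-separated overlap).
#' @export
hypergeometricEnrichment <- function(gene_list, sets, universe) {
  if (!all(gene_list %in% universe))
    stop("gene_list must be a subset of the universe")
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  dropped <- sum(vapply(sets, function(s) sum(!s %in% universe), numeric(1)))
  if (dropped > 0)
    message(dropped, " set member(s) absent from the universe were ignored")
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    K <- length(s)
    hits <- intersect(gene_list, s)
    k <- length(hits)
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p_value = p,
               members = paste(hits, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, "BH")
  out[, c("set", "set_size", "overlap", "p_value", "fdr", "members")]
}

#' Drug-combination additivity t-test
#'
#' Compares the observed combination effect against the replicate-wise sum
#' of the two single-agent effects (inhibition fractions) with a two-sided
#' Welch t-test. A combination significantly above its additive expectation
#' is synergistic; significantly below, antagonistic; otherwise additive.
#'
#' @param effect_a,effect_b,effect_combo numeric vectors of replicate
#'   inhibition fractions (>= 2 each; a and b paired by replicate index).
#' @param alpha significance level for the verdict (default 0.05).
#' @return list: \code{expected_additive_mean}, \code{t_statistic},
#'   \code{p_value}, \code{verdict}.
#' @export
additivityTest <- function(effect_a, effect_b, effect_combo, alpha = 0.05) {
  if (length(effect_a) != length(effect_b))
    stop("effect_a and effect_b must be paired by replicate index")
  if (length(effect_a) < 2 || length(effect_combo) < 2)
    stop("need >= 2 replicates per group")
  expected <- effect_a + effect_b
  if (stats::var(expected) == 0 && stats::var(effect_combo) == 0) {
    diff <- mean(effect_combo) - mean(expected)
    if (diff == 0) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- list(statistic = sign(diff) * Inf, p.value = 0)
    }
  } else {
    ht <- stats::t.test(effect_combo, expected, var.equal = FALSE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  diff <- mean(effect_combo) - mean(expected)
  verdict <- if (tt$p.value < alpha && diff > 0) "synergistic"
             else if (tt$p.value < alpha && diff < 0) "antagonistic"
             else "additive"
  list(expected_additive_mean = mean(expected),
       t_statistic = tt$statistic,
       p_value = tt$p.value,
       verdict = verdict)
}
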