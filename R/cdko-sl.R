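#' Replicate-averaged construct log2 fold changes
#'
#' Per replicate, \code{log2((tend + pc) / (t0_ref + pc))} with the T0
#' reference the mean of the (normalized) T0 replicates; replicates are
#' then averaged. Constructs present in the design but missing from the
#' count table are treated as zero count (reported via a message). Depth
#' normalization is expected upstream (see [normalizeCounts()], typically
#' with the safe-safe constructs as controls).
#'
#' @param counts a (normalized) [ScreenCountSet-class].
#' @param dual a [DualDesign-class].
#' @param pseudocount added inside both logs.
#' @return named numeric vector of LFCs, one per design construct.
#' @export
constructLfc <- function(counts, dual, pseudocount = 1) {
  stopifnot(is(counts, "ScreenCountSet"), is(dual, "DualDesign"))
  m <- assay(counts, "counts")
  ids <- constructIds(dual)
  missing <- setdiff(ids, rownames(m))
  if (length(missing)) {
    message(length(missing),
            " design construct(s) missing from counts; treated as zero")
    add <- matrix(0, length(missing), ncol(m),
                  dimnames = list(missing, colnames(m)))
    m <- rbind(m, add)
  }
  m <- m[ids, , drop = FALSE]
  des <- screenDesign(counts)
  t0 <- des$timepoint == "T0"
  tend <- des$timepoint == "Tend"
  if (!any(t0) || !any(tend)) stop("need both T0 and Tend samples")
  ref <- log2(rowMeans(m[, t0, drop = FALSE]) + pseudocount)
  per_rep <- log2(m[, tend, drop = FALSE] + pseudocount) - ref
  rowMeans(per_rep)
}

#' Single-guide and single-gene fitness from safe pairings
#'
#' Pairing a guide with safe-harbor guides measures its single-knockout
#' fitness inside the dual library: \code{f_guide} is the mean LFC of the
#' guide's safe-paired constructs over both cassette positions, and
#' \code{f_gene} the median of the gene's guide fitness values. The SAFE
#' pseudo-gene's fitness (from safe-safe constructs) estimates the assay
#' background. Guides with no safe pairing are excluded (message).
#'
#' @param lfc a [constructLfc()] vector.
#' @param dual a [DualDesign-class].
#' @param library the [GuideLibrary-class].
#' @return list with \code{f_guide} and \code{f_gene} named vectors.
#' @export
singleGeneFitness <- function(lfc, dual, library) {
  stopifnot(is(dual, "DualDesign"), is(library, "GuideLibrary"))
  ct <- constructTable(dual)
  x <- lfc[ct$construct_id]
  safe1 <- ct$gene1 == SAFE_GENE
  safe2 <- ct$gene2 == SAFE_GENE
  # guide at position 1 with safe partner at position 2, and vice versa
  vals <- c(x[safe2], x[safe1])
  who <- c(ct$guide1[safe2], ct$guide2[safe1])
  f_guide <- tapply(vals, who, mean)
  absent <- setdiff(guideIds(library), names(f_guide))
  if (length(absent))
    message(length(absent), " guide(s) without safe pairings excluded: ",
            paste(utils::head(absent, 5), collapse = ", "))
  gmap <- guideGeneMap(library)
  f_gene <- tapply(as.numeric(f_guide), gmap[names(f_guide)], stats::median)
  list(f_guide = stats::setNames(as.numeric(f_guide), names(f_guide)),
       f_gene = stats::setNames(as.numeric(f_gene), names(f_gene)))
}

# Internal: per-construct interaction deltas at gene- and guide-level
# fitness resolution, for targeting pairs with two distinct genes and for
# the safe-safe background, plus the pair grouping.
pairDeltas <- function(lfc, fitness, dual) {
  ct <- constructTable(dual)
  x <- unname(lfc[ct$construct_id])
  fg <- fitness$f_gene
  fu <- fitness$f_guide
  keep <- ct$gene1 != SAFE_GENE & ct$gene2 != SAFE_GENE &
    ct$gene1 != ct$gene2 &
    ct$guide1 %in% names(fu) & ct$guide2 %in% names(fu)
  ss <- ct$gene1 == SAFE_GENE & ct$gene2 == SAFE_GENE
  list(pair = ct$pair_unordered[keep],
       orientation = ct$pair_ordered[keep],
       delta_gene = x[keep] - unname(fg[ct$gene1[keep]] + fg[ct$gene2[keep]]),
       delta_guide = x[keep] - unname(fu[ct$guide1[keep]] + fu[ct$guide2[keep]]),
       ss_delta_gene = x[ss] - 2 * unname(fg[SAFE_GENE]),
       ss_delta_guide = x[ss] -
         unname(fu[ct$guide1[ss]] + fu[ct$guide2[ss]]))
}

#' Horlbeck-style genetic interaction score
#'
#' Per construct, the interaction delta is the observed LFC minus the
#' additive single-gene expectation \code{f_gene[i] + f_gene[j]}; the pair
#' score is the mean delta over all guide combinations and both cassette
#' orientations (up to 3 x 3 x 2 constructs). Negative = depletion beyond
#' additivity = synthetic lethal.
#'
#' @param lfc a [constructLfc()] vector.
#' @param fitness a [singleGeneFitness()] result.
#' @param dual a [DualDesign-class].
#' @return data.frame: pair, n_constructs, score.
#' @export
slScoreHorlbeck <- function(lfc, fitness, dual) {
  pd <- pairDeltas(lfc, fitness, dual)
  score <- tapply(pd$delta_gene, pd$pair, mean)
  data.frame(pair = names(score),
             n_constructs = as.integer(table(pd$pair)[names(score)]),
             score = as.numeric(score),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Median genetic interaction score (B/NB)
#'
#' Median of the gene-level interaction deltas per pair. With
#' \code{background_normalize} (the "B" variant) each delta is first
#' reduced by the median delta of the safe-safe background constructs,
#' making the score invariant to global LFC shifts.
#'
#' @inheritParams slScoreHorlbeck
#' @param background_normalize logical (B variant when \code{TRUE}).
#' @return data.frame: pair, n_constructs, score.
#' @export
slScoreMedian <- function(lfc, fitness, dual, background_normalize = TRUE) {
  pd <- pairDeltas(lfc, fitness, dual)
  bg <- if (background_normalize) stats::median(pd$ss_delta_gene) else 0
  score <- tapply(pd$delta_gene - bg, pd$pair, stats::median)
  data.frame(pair = names(score),
             n_constructs = as.integer(table(pd$pair)[names(score)]),
             score = as.numeric(score),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' sgRNA-derived genetic interaction score (B/NB)
#'
#' Deltas are computed against guide-level fitness,
#' \code{LFC - (f_guide[i] + f_guide[j])}, which corrects guide-efficiency
#' outliers that a gene-median fitness retains; the pair score is the mean
#' of the two per-orientation mean deltas. The "B" variant subtracts the
#' mean guide-level delta of the safe-safe constructs.
#'
#' @inheritParams slScoreMedian
#' @return data.frame: pair, n_constructs, score.
#' @export
slScoreSgrnaDerived <- function(lfc, fitness, dual,
                                background_normalize = TRUE) {
  pd <- pairDeltas(lfc, fitness, dual)
  bg <- if (background_normalize) mean(pd$ss_delta_guide) else 0
  d <- pd$delta_guide - bg
  by_orient <- tapply(d, pd$orientation, mean)
  # map each orientation back to its unordered pair, then average the
  # (one or two) orientation means
  o2p <- tapply(pd$pair, pd$orientation, `[`, 1)
  score <- tapply(as.numeric(by_orient), o2p[names(by_orient)], mean)
  data.frame(pair = names(score),
             n_constructs = as.integer(table(pd$pair)[names(score)]),
             score = as.numeric(score),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank-aggregation SL score (RRA-style rho statistic)
#'
#' Guide-level interaction deltas are converted to ascending percentile
#' ranks among all targeting-pair constructs (most depleted = smallest
#' rank). For a pair with n constructs holding sorted percentiles
#' r_(1) <= ... <= r_(n), the rho statistic is the minimum over k of the
#' Beta(k, n - k + 1) CDF at r_(k) — small when the pair's constructs sit
#' unusually low in the overall ranking. Optional permutation p-values
#' shuffle the construct-to-pair assignment.
#'
#' @inheritParams slScoreHorlbeck
#' @param n_permutations permutations for the p-value (0 = skip; < 100
#'   warns when positive).
#' @param seed integer RNG seed (used when permuting).
#' @return data.frame: pair, n_constructs, rho (smaller = stronger SL) and,
#'   when permuted, p_value.
#' @export
slScoreRankAgg <- function(lfc, fitness, dual, n_permutations = 0,
                           seed = 1L) {
  pd <- pairDeltas(lfc, fitness, dual)
  if (n_permutations > 0 && n_permutations < 100)
    warning("n_permutations < 100 gives very coarse p-values")
  n_all <- length(pd$delta_guide)
  pct <- rank(pd$delta_guide, ties.method = "average") / n_all
  pairs <- sort(unique(pd$pair))
  rhoOf <- function(percentiles, grp) {
    as.numeric(tapply(percentiles, grp, function(r) {
      r <- sort(r)
      k <- seq_along(r)
      min(stats::pbeta(r, k, length(r) - k + 1))
    })[pairs])
  }
  rho <- rhoOf(pct, pd$pair)
  out <- data.frame(pair = pairs,
                    n_constructs = as.integer(table(pd$pair)[pairs]),
                    rho = rho,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (n_permutations > 0) {
    set.seed(seed)
    hits <- numeric(length(pairs))
    for (b in seq_len(n_permutations)) {
      perm_rho <- rhoOf(sample(pct), pd$pair)
      hits <- hits + (perm_rho <= rho + 1e-15)
    }
    out$p_value <- (1 + hits) / (n_permutations + 1)
  }
  out
}

#' All SL scores for a dual-knockout screen
#'
#' Convenience wrapper computing the four scoring methods on a shared
#' delta decomposition: Horlbeck (mean, gene-level), median (B/NB),
#' sgRNA-derived (B/NB) and the rank-aggregation rho.
#'
#' @inheritParams slScoreRankAgg
#' @param background_normalize use the background-normalized (B) variants
#'   of the median and sgRNA-derived scores.
#' @param min_constructs pairs observed with fewer constructs are flagged
#'   \code{low_confidence} (not dropped).
#' @return data.frame with one row per unordered gene pair and columns
#'   \code{horlbeck}, \code{median}, \code{sgrna}, \code{rra} (rho).
#' @export
slScores <- function(lfc, fitness, dual, background_normalize = TRUE,
                     min_constructs = 4, n_permutations = 0, seed = 1L) {
  h <- slScoreHorlbeck(lfc, fitness, dual)
  md <- slScoreMedian(lfc, fitness, dual, background_normalize)
  sg <- slScoreSgrnaDerived(lfc, fitness, dual, background_normalize)
  rr <- slScoreRankAgg(lfc, fitness, dual, n_permutations, seed)
  stopifnot(identical(h$pair, md$pair), identical(h$pair, sg$pair),
            identical(h$pair, rr$pair))
  out <- data.frame(pair = h$pair, n_constructs = h$n_constructs,
                    horlbeck = h$score, median = md$score,
                    sgrna = sg$score, rra = rr$rho,
                    low_confidence = h$n_constructs < min_constructs,
                    stringsAsFactors = FALSE)
  if (!is.null(rr$p_value)) out$rra_p <- rr$p_value
  out
}

#' Top-decile consensus over SL scoring methods
#'
#' Per method, the \code{ceiling(top_fraction * n_pairs)} most synthetic
#' lethal pairs are flagged (most negative score; smallest rho for the
#' rank-aggregation column). The consensus keeps pairs flagged by at least
#' \code{min_methods} methods; counts per method-subset (Venn regions) are
#' reported alongside.
#'
#' @param scores a data.frame with a \code{pair} column and one numeric
#'   column per method (as from [slScores()]).
#' @param top_fraction fraction of pairs flagged per method, in (0, 1].
#' @param min_methods minimum number of flagging methods for consensus.
#' @param methods character vector of score columns; defaults to the four
#'   standard columns present in \code{scores}.
#' @param ascending character vector of methods whose score is
#'   smallest-is-strongest (default \code{"rra"}); all others take the most
#'   negative tail.
#' @return list: \code{table} (scores + per-method flags, n_methods_hit,
#'   consensus), \code{consensus} (pair labels), \code{venn} (named counts
#'   per non-empty method subset).
#' @export
consensusSlPairs <- function(scores, top_fraction = 0.10, min_methods = 3,
                             methods = intersect(c("horlbeck", "median",
                                                   "sgrna", "rra"),
                                                 colnames(scores)),
                             ascending = "rra") {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must lie in (0, 1]")
  if (length(methods) < min_methods)
    stop("need at least min_methods score columns")
  n <- nrow(scores)
  n_flag <- ceiling(top_fraction * n)
  flags <- sapply(methods, function(mth) {
    v <- scores[[mth]]
    ord <- order(v)  # ascending: most negative / smallest rho first
    sel <- logical(n)
    sel[ord[seq_len(n_flag)]] <- TRUE
    sel
  })
  colnames(flags) <- paste0("hit_", methods)
  n_hit <- rowSums(flags)
  consensus <- n_hit >= min_methods
  subset_label <- apply(flags, 1, function(f)
    paste(methods[f], collapse = "&"))
  venn <- table(subset_label[n_hit > 0])
  out <- cbind(scores, as.data.frame(flags),
               n_methods_hit = as.integer(n_hit),
               consensus = consensus)
  list(table = out,
       consensus = scores$pair[consensus],
       venn = stats::setNames(as.integer(venn), names(venn)))
}

#' Candidate-gene selection for a dual-knockout library
#'
#' Three criteria: membership in the cell-death hallmark list, expression
#' above \code{expr_threshold} read counts, and non-essentiality in the
#' genome-wide screen (\code{|beta[control]| <= essentiality_band}, the
#' null band of the essentiality score).
#'
#' @param hallmark_genes character vector of hallmark genes.
#' @param expression_counts named numeric vector, gene -> read counts.
#' @param beta a [geneBeta()] table.
#' @param expr_threshold expression cutoff (strictly above; default 50).
#' @param essentiality_band half-width of the non-essential beta band.
#' @param control_condition condition holding the essentiality scores.
#' @return list: \code{genes} (the three-way intersection) and \code{venn}
#'   (counts of the 7 regions over the gene union).
#' @export
selectCdkoCandidates <- function(hallmark_genes, expression_counts, beta,
                                 expr_threshold = 50, essentiality_band = 1,
                                 control_condition = "control") {
  if (!length(hallmark_genes) || !length(expression_counts) || !nrow(beta))
    stop("all three inputs must be non-empty")
  bc <- beta[beta$condition == control_condition, , drop = FALSE]
  universe <- unique(c(hallmark_genes, names(expression_counts), bc$gene))
  in_hallmark <- universe %in% hallmark_genes
  expr <- expression_counts[universe]
  in_expr <- !is.na(expr) & expr > expr_threshold
  b <- stats::setNames(bc$beta, bc$gene)[universe]
  in_noness <- !is.na(b) & abs(b) <= essentiality_band
  key <- paste0(ifelse(in_hallmark, "hallmark", ""),
                ifelse(in_expr, "+expressed", ""),
                ifelse(in_noness, "+nonessential", ""))
  key <- sub("^\\+", "", key)
  venn <- table(key[key != ""])
  list(genes = universe[in_hallmark & in_expr & in_noness],
       venn = stats::setNames(as.integer(venn), names(venn)))
}

#' SL network and hub genes
#'
#' Builds the undirected simple graph of consensus SL pairs; hubs are
#' genes incident to at least \code{hub_threshold} partners.
#'
#' @param pairs character vector of pair labels (\code{"A__B"}) or a
#'   two-column data.frame of gene pairs.
#' @param hub_threshold minimum degree for a hub (default 10).
#' @return list: \code{graph} (igraph), \code{degrees} (named), \code{hubs}
#'   (character), \code{edges} (two-column data.frame).
#' @export
slNetworkHubs <- function(pairs, hub_threshold = 10) {
  edges <- if (is.character(pairs)) {
    if (!length(pairs)) data.frame(gene1 = character(), gene2 = character())
    else {
      sp <- strsplit(pairs, "__", fixed = TRUE)
      data.frame(gene1 = vapply(sp, `[[`, "", 1),
                 gene2 = vapply(sp, `[[`, "", 2),
                 stringsAsFactors = FALSE)
    }
  } else as.data.frame(pairs)[, 1:2]
  g <- igraph::simplify(igraph::graph_from_data_frame(edges, directed = FALSE))
  deg <- igraph::degree(g)
  list(graph = g, degrees = deg,
       hubs = names(deg)[deg >= hub_threshold],
       edges = edges)
}
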