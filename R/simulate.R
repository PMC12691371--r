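#' Simulation truth parameters for pooled screens
#'
#' Bundles the generative parameters of the negative-binomial screen
#' simulators: guide abundance skew, sequencing depth, NB dispersion
#' (\code{size}; variance = mu + mu^2/dispersion, Poisson as
#' dispersion -> Inf), per-gene essentiality effects, guide-level jitter,
#' and (for dual-knockout screens) pairwise interaction effects and
#' construct-level noise.
#'
#' Defaults are chosen so that a null screen reproduces the quality-control
#' profile of a well-executed pooled screen: mean depth of a few hundred
#' reads per guide and a log-normal abundance spread (\code{sigma_log})
#' calibrated so the library Gini index sits near 0.05.
#'
#' @param beta named list per condition of named numeric vectors
#'   (gene -> log2 essentiality effect); genes absent default to 0.
#' @param gamma named numeric vector, unordered pair label
#'   (\code{"A__B"}, sorted) -> log2 interaction effect; absent pairs are 0.
#' @param depth mean reads per guide/construct and sample (> 0).
#' @param dispersion NB size parameter (> 0; \code{Inf} = Poisson).
#' @param sigma_log log-normal sd of baseline guide abundance.
#' @param tau sd of the guide-level jitter around the gene effect.
#' @param gene_fitness_sd sd of random per-gene fitness in CDKO screens.
#' @param sigma_construct sd of construct-level noise in CDKO screens.
#' @param count_noise logical; \code{FALSE} yields the noiseless limit in
#'   which counts equal their (real-valued) expectations exactly.
#' @return a list of class \code{"ScreenTruth"}.
#' @export
screenTruth <- function(beta = list(), gamma = numeric(0), depth = 500,
                        dispersion = 1000, sigma_log = 0.07, tau = 0.2,
                        gene_fitness_sd = 0.3, sigma_construct = 0.25,
                        count_noise = TRUE) {
  if (depth <= 0) stop("depth must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  structure(list(beta = beta, gamma = gamma, depth = depth,
                 dispersion = dispersion, sigma_log = sigma_log, tau = tau,
                 gene_fitness_sd = gene_fitness_sd,
                 sigma_construct = sigma_construct,
                 count_noise = count_noise),
            class = "ScreenTruth")
}

# NB draw in the size/dispersion parameterization; Poisson at Inf;
# exact expectations when count_noise is off.
rNbCounts <- function(mu, dispersion, count_noise) {
  if (!count_noise) return(mu)
  if (is.infinite(dispersion)) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = dispersion)
}

#' Simulate a genome-wide pooled CRISPR screen
#'
#' Baseline (T0) counts are negative-binomial around a log-normal guide
#' abundance profile scaled to the target depth; end-point counts have mean
#' \code{T0 mean * 2^(beta[gene, condition] + jitter)}, with guide-level
#' jitter ~ Normal(0, tau). Safe (non-targeting control) guides have effect
#' exactly 0 by construction. Deterministic given \code{seed}.
#'
#' @param library a [GuideLibrary-class].
#' @param design data.frame with \code{sample_id}, \code{timepoint}
#'   (T0/Tend), \code{condition}, \code{replicate}; T0 and Tend required.
#' @param truth a [screenTruth()] object.
#' @param seed integer RNG seed.
#' @return list with \code{counts} (a [ScreenCountSet-class]) and
#'   \code{truth} (input truth plus the realized per-guide effects).
#' @export
simulateGenomeScreen <- function(library, design, truth = screenTruth(),
                                 seed = 1L) {
  stopifnot(is(library, "GuideLibrary"), inherits(truth, "ScreenTruth"))
  design <- as.data.frame(design)
  if (!any(design$timepoint == "T0") || !any(design$timepoint == "Tend"))
    stop("design needs both T0 and Tend samples")
  set.seed(seed)
  ids <- guideIds(library)
  gmap <- guideGeneMap(library)
  roles <- guideRoles(library)
  n <- length(ids)
  ab <- stats::rlnorm(n, 0, truth$sigma_log)
  mu0 <- truth$depth * ab / mean(ab)

  conditions <- unique(design$condition[design$timepoint == "Tend"])
  eff <- matrix(0, n, length(conditions), dimnames = list(ids, conditions))
  for (cond in conditions) {
    b <- truth$beta[[cond]]
    gene_eff <- if (is.null(b)) rep(0, n) else {
      v <- b[gmap[ids]]; v[is.na(v)] <- 0; unname(v)
    }
    jitter <- if (truth$tau > 0) stats::rnorm(n, 0, truth$tau) else 0
    e <- gene_eff + jitter
    e[roles[ids] == "safe"] <- 0
    eff[, cond] <- e
  }

  cts <- matrix(0, n, nrow(design),
                dimnames = list(ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    mu <- if (design$timepoint[j] == "T0") mu0
          else mu0 * 2^eff[, design$condition[j]]
    cts[, j] <- rNbCounts(mu, truth$dispersion, truth$count_noise)
  }
  truth$guide_effect <- eff
  truth$mu0 <- stats::setNames(mu0, ids)
  list(counts = ScreenCountSet(cts, design), truth = truth)
}

#' Simulate a dual-knockout (CDKO) pooled screen
#'
#' Each construct's log2 fold change has mean
#' \code{f_i + f_j + gamma[pair] + eps}, with per-guide fitness
#' \code{f = f_gene + Normal(0, tau)} for targeting guides and exactly 0
#' for safe guides, pair interactions \code{gamma} planted on unordered
#' gene-pair labels (both orientations are generated), and construct-level
#' noise \code{eps ~ Normal(0, sigma_construct)}. Counts are NB around the
#' implied expectations at the target depth. Deterministic given
#' \code{seed}.
#'
#' @param dual a [DualDesign-class] built from a library with safe guides.
#' @param library the [GuideLibrary-class] behind \code{dual}.
#' @param truth a [screenTruth()] object; \code{truth$f_gene} may supply
#'   fixed per-gene fitness, otherwise it is drawn
#'   Normal(0, gene_fitness_sd).
#' @param n_replicates replicates per timepoint (>= 1).
#' @param seed integer RNG seed.
#' @return list with \code{counts} ([ScreenCountSet-class]) and
#'   \code{truth} augmented with realized \code{f_gene}, \code{f_guide} and
#'   per-construct expected \code{lfc}.
#' @export
simulateCdkoScreen <- function(dual, library, truth = screenTruth(depth = 200),
                               n_replicates = 3L, seed = 1L) {
  stopifnot(is(dual, "DualDesign"), is(library, "GuideLibrary"),
            inherits(truth, "ScreenTruth"))
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (!length(safeGuides(library)))
    stop("CDKO simulation needs >= 1 safe guide in the library")
  set.seed(seed)
  genes <- targetGenes(library)
  f_gene <- truth$f_gene %||%
    stats::setNames(stats::rnorm(length(genes), 0, truth$gene_fitness_sd), genes)
  roles <- guideRoles(library)
  ids <- guideIds(library)
  gmap <- guideGeneMap(library)
  f_guide <- stats::setNames(numeric(length(ids)), ids)
  tg <- roles[ids] == "targeting"
  f_guide[tg] <- f_gene[gmap[ids[tg]]] +
    (if (truth$tau > 0) stats::rnorm(sum(tg), 0, truth$tau) else 0)

  ct <- constructTable(dual)
  gam <- truth$gamma[ct$pair_unordered]
  gam[is.na(gam)] <- 0
  eps <- if (truth$sigma_construct > 0)
    stats::rnorm(nrow(ct), 0, truth$sigma_construct) else 0
  lfc <- unname(f_guide[ct$guide1] + f_guide[ct$guide2]) + unname(gam) + eps

  nc <- nrow(ct)
  ab <- stats::rlnorm(nc, 0, truth$sigma_log)
  mu0 <- truth$depth * ab / mean(ab)
  design <- data.frame(
    sample_id = c(paste0("T0_", seq_len(n_replicates)),
                  paste0("Tend_", seq_len(n_replicates))),
    timepoint = rep(c("T0", "Tend"), each = n_replicates),
    condition = "control",
    replicate = rep(seq_len(n_replicates), 2),
    stringsAsFactors = FALSE)
  cts <- matrix(0, nc, nrow(design),
                dimnames = list(ct$construct_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    mu <- if (design$timepoint[j] == "T0") mu0 else mu0 * 2^lfc
    cts[, j] <- rNbCounts(mu, truth$dispersion, truth$count_noise)
  }
  truth$f_gene <- f_gene
  truth$f_guide <- f_guide
  truth$lfc <- stats::setNames(lfc, ct$construct_id)
  list(counts = ScreenCountSet(cts, design), truth = truth)
}

#' Simulation truth for a transcriptome cohort
#'
#' @param deg named numeric vector: gene -> log2 shift in non-responders.
#' @param batch_offsets named numeric vector: batch -> additive offset.
#' @param lambda numeric in [0, 1] per cell line: similarity to the
#'   non-responder centroid (1 = identical in expectation).
#' @param sigma residual noise sd for patients (> 0).
#' @param sigma_cellline residual noise sd for cell lines.
#' @param independent_sd sd of the independent per-cell-line centroid.
#' @return list of class \code{"CohortTruth"}.
#' @export
cohortTruth <- function(deg = numeric(0),
                        batch_offsets = c(batch1 = 0, batch2 = 1),
                        lambda = c(0.9, 0.7, 0.5, 0.2, 0.0),
                        sigma = 0.5, sigma_cellline = 0.5,
                        independent_sd = 1) {
  if (any(lambda < 0 | lambda > 1)) stop("lambda must lie in [0, 1]")
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(deg = deg, batch_offsets = batch_offsets, lambda = lambda,
                 sigma = sigma, sigma_cellline = sigma_cellline,
                 independent_sd = independent_sd),
            class = "CohortTruth")
}

#' Simulate a patient + cell-line transcriptome cohort
#'
#' Patient expression = per-gene baseline + response-group shift (the
#' planted log2 differences on DEGs, applied to non-responders) + batch
#' offset + Normal(0, sigma). Cell line c = lambda_c * (non-responder
#' centroid) + (1 - lambda_c) * (its own independent centroid) + noise, so
#' lambda tunes how representative a line is of the non-responder
#' population. Group sizes default to the 29 non-responder : 15 responder
#' baseline comparison. Deterministic given \code{seed}.
#'
#' @param truth a [cohortTruth()]; when \code{truth$deg} is empty,
#'   \code{n_deg} genes get alternating +/- \code{delta} shifts.
#' @param n_nonresponders,n_responders patient group sizes (>= 2).
#' @param n_genes gene universe size.
#' @param n_deg,delta planted DEG count and |log2 shift| used when
#'   \code{truth$deg} is empty.
#' @param seed integer RNG seed.
#' @return list with \code{expr} (a \code{SummarizedExperiment}; assay
#'   \code{"exprs"} of log2 values; colData \code{kind}, \code{response},
#'   \code{batch}) and \code{truth} augmented with the realized DEG shifts,
#'   baseline and non-responder centroid.
#' @export
simulateTranscriptomeCohort <- function(truth = cohortTruth(),
                                        n_nonresponders = 29,
                                        n_responders = 15,
                                        n_genes = 2000,
                                        n_deg = 150, delta = 1.5,
                                        seed = 1L) {
  stopifnot(inherits(truth, "CohortTruth"))
  if (n_nonresponders < 2 || n_responders < 2)
    stop("need >= 2 samples per patient group")
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  if (!length(truth$deg)) {
    deg_genes <- sample(genes, n_deg)
    truth$deg <- stats::setNames(delta * rep_len(c(1, -1), n_deg), deg_genes)
  }
  if (!all(names(truth$deg) %in% genes))
    stop("DEG list must be a subset of the gene universe")
  shift <- stats::setNames(numeric(n_genes), genes)
  shift[names(truth$deg)] <- truth$deg

  baseline <- stats::rnorm(n_genes, 7, 1)
  n_pat <- n_nonresponders + n_responders
  response <- c(rep("non_responder", n_nonresponders),
                rep("responder", n_responders))
  batches <- names(truth$batch_offsets)
  batch <- rep_len(batches, n_pat)  # interleaved => batch-balanced groups
  pat <- matrix(stats::rnorm(n_genes * n_pat, 0, truth$sigma), n_genes, n_pat)
  pat <- pat + baseline +
    outer(shift, as.numeric(response == "non_responder"))
  pat <- sweep(pat, 2, truth$batch_offsets[batch], "+")
  colnames(pat) <- sprintf("patient%02d", seq_len(n_pat))

  nr_centroid <- baseline + shift
  n_cl <- length(truth$lambda)
  cl <- matrix(0, n_genes, n_cl)
  for (i in seq_len(n_cl)) {
    indep <- baseline + stats::rnorm(n_genes, 0, truth$independent_sd)
    cl[, i] <- truth$lambda[i] * nr_centroid +
      (1 - truth$lambda[i]) * indep +
      stats::rnorm(n_genes, 0, truth$sigma_cellline)
  }
  colnames(cl) <- sprintf("cellline%02d", seq_len(n_cl))

  m <- cbind(pat, cl)
  rownames(m) <- genes
  cd <- DataFrame(
    kind = c(rep("patient", n_pat), rep("cell_line", n_cl)),
    response = c(response, rep(NA_character_, n_cl)),
    batch = c(batch, rep(NA_character_, n_cl)),
    row.names = colnames(m))
  truth$baseline <- stats::setNames(baseline, genes)
  truth$nr_centroid <- stats::setNames(nr_centroid, genes)
  names(truth$lambda) <- colnames(cl)
  list(expr = SummarizedExperiment(assays = list(exprs = m), colData = cd),
       truth = truth)
}
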