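#' Mapping ratio of a sequenced screen sample
#'
#' Percentage of reads mappable to the sgRNA library, half-up rounded to
#' two decimals as reported in screen sequencing-statistics tables.
#'
#' @param total_reads total sequenced reads (> 0).
#' @param mapped_reads reads mapping to the library (0..total).
#' @return percentage with two decimals.
#' @examples
#' mappingRatio(9272549, 8159448)  # 88.00
#' @export
mappingRatio <- function(total_reads, mapped_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  if (any(mapped_reads < 0) || any(mapped_reads > total_reads))
    stop("mapped_reads must lie in [0, total_reads]")
  roundHalfUp(100 * mapped_reads / total_reads, 2)
}

#' Missed-guide (zero-count) statistics per sample
#'
#' Guides with zero reads are "missed"; rows absent from the table count as
#' missed too, hence the explicit library size.
#'
#' @param counts a [ScreenCountSet-class].
#' @param library_size total guides/constructs in the library
#'   (>= rows observed).
#' @return data.frame with per-sample \code{zero_count} and
#'   \code{zero_pct} (two decimals).
#' @export
missedGuideStats <- function(counts, library_size) {
  stopifnot(is(counts, "ScreenCountSet"))
  m <- assay(counts, "counts")
  if (library_size < nrow(m))
    stop("library_size (", library_size, ") smaller than observed rows (",
         nrow(m), ")")
  absent <- library_size - nrow(m)
  zc <- colSums(m == 0) + absent
  data.frame(sample_id = colnames(m),
             zero_count = as.integer(zc),
             zero_pct = roundHalfUp(100 * zc / library_size, 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Guides at or above a read-count threshold, per sample
#'
#' @param counts a [ScreenCountSet-class].
#' @param threshold minimum reads (>= 1); default 10.
#' @param library_size total guides in the library (denominator).
#' @return data.frame with per-sample \code{above_count} and
#'   \code{above_pct} (two decimals).
#' @export
aboveThresholdStats <- function(counts, threshold = 10, library_size = nrow(counts)) {
  stopifnot(is(counts, "ScreenCountSet"))
  if (threshold < 1) stop("threshold must be >= 1")
  m <- assay(counts, "counts")
  ac <- colSums(m >= threshold)
  data.frame(sample_id = colnames(m),
             above_count = as.integer(ac),
             above_pct = roundHalfUp(100 * ac / library_size, 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gini index of a read-count distribution
#'
#' Population form over all ordered pairs,
#' \deqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x),}
#' computed on raw counts including zeros. Rising values indicate
#' selective guide dropout / unevenness of the pool.
#'
#' @param x non-negative numeric vector, length >= 2, not all zero.
#' @return Gini index in [0, 1).
#' @examples
#' giniIndex(c(5, 5, 5, 5))  # 0
#' giniIndex(c(0, 0, 0, 1))  # 0.75
#' @export
giniIndex <- function(x) {
  if (length(x) < 2) stop("need at least 2 values")
  if (any(!is.finite(x)) || any(x < 0)) stop("x must be finite and non-negative")
  if (all(x == 0)) stop("Gini index undefined for an all-zero vector")
  n <- length(x)
  xs <- sort(x)
  # identity: sum_ij |xi-xj| = 2 * sum_i (2i - n - 1) * x_(i)
  g <- sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * mean(x))
  unname(g)
}

#' Pairwise replicate correlations on log counts
#'
#' Pearson correlation of log2(count + pseudocount) sample profiles, with a
#' per-group summary: mean correlation within each (timepoint, condition)
#' group and mean correlation between timepoints. Constant sample vectors
#' yield \code{NA} (undefined), never a silent zero.
#'
#' @param counts a [ScreenCountSet-class] with >= 2 samples.
#' @param pseudocount added before log2 (default 1).
#' @return list with \code{correlations} (symmetric matrix, unit diagonal)
#'   and \code{groups} (data.frame of group-level mean correlations).
#' @export
replicateCorrelations <- function(counts, pseudocount = 1) {
  stopifnot(is(counts, "ScreenCountSet"))
  m <- logCounts(assay(counts, "counts"), pseudocount)
  if (ncol(m) < 2) stop("need >= 2 samples")
  sds <- apply(m, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(m))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc) <- 1
  des <- screenDesign(counts)
  grp <- paste(des$timepoint, des$condition, sep = "/")
  pairs <- which(upper.tri(cc), arr.ind = TRUE)
  lab <- ifelse(grp[pairs[, 1]] == grp[pairs[, 2]],
                paste0("within ", grp[pairs[, 1]]),
                ifelse(des$timepoint[pairs[, 1]] != des$timepoint[pairs[, 2]],
                       "between timepoints", "between conditions"))
  vals <- cc[pairs]
  groups <- stats::aggregate(list(mean_correlation = vals),
                             by = list(group = lab),
                             FUN = function(v) mean(v, na.rm = TRUE))
  list(correlations = cc, groups = groups)
}

#' PCA summary of sample count profiles
#'
#' PCA on centered log2(count + pseudocount) sample profiles.
#'
#' @param counts a [ScreenCountSet-class].
#' @param n_components number of components to report (<= samples).
#' @param pseudocount added before log2.
#' @return list with \code{coordinates} (samples x components) and
#'   \code{variance_explained} (non-increasing fractions, all components).
#' @export
pcaSummary <- function(counts, n_components = 3, pseudocount = 1) {
  stopifnot(is(counts, "ScreenCountSet"))
  m <- logCounts(assay(counts, "counts"), pseudocount)
  if (n_components > ncol(m))
    stop("n_components exceeds the number of samples")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  list(coordinates = pc$x[, seq_len(k), drop = FALSE],
       variance_explained = ve)
}

#' Per-sample screen QC report
#'
#' Combines mapping ratio, missed-guide, above-threshold and Gini
#' statistics into one table per sample, mirroring the sequencing-statistics
#' tables screen studies publish (Reads, Mapped, Mapped%, Zero_Counts,
#' Zero_Counts%, Gini_Index, Above_Threshold, Above_Threshold%).
#'
#' @param counts a [ScreenCountSet-class].
#' @param total_reads,mapped_reads optional named integer vectors (per
#'   sample); when absent the read columns are omitted.
#' @param library_size library size (default: observed rows).
#' @param threshold above-threshold read cutoff (default 10).
#' @return data.frame, one row per sample.
#' @export
qcReport <- function(counts, total_reads = NULL, mapped_reads = NULL,
                     library_size = nrow(counts), threshold = 10) {
  stopifnot(is(counts, "ScreenCountSet"))
  m <- assay(counts, "counts")
  zero <- missedGuideStats(counts, library_size)
  above <- aboveThresholdStats(counts, threshold, library_size)
  out <- data.frame(sample_id = colnames(m),
                    zero_count = zero$zero_count,
                    zero_pct = zero$zero_pct,
                    gini_index = roundHalfUp(apply(m, 2, giniIndex), 2),
                    above_count = above$above_count,
                    above_pct = above$above_pct,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(total_reads) && !is.null(mapped_reads)) {
    tr <- total_reads[out$sample_id]
    mr <- mapped_reads[out$sample_id]
    out <- cbind(out[1],
                 data.frame(reads = unname(tr), mapped = unname(mr),
                            mapped_pct = mappingRatio(tr, mr)),
                 out[-1])
  }
  out
}
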