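#' Single-sample gene set enrichment (ssGSEA) scores
#'
#' Per sample, genes are ranked by expression (average ranks for ties,
#' highest expression = rank N). Walking the ranked list from the top, the
#' enrichment score of a set is the sum over all positions of the
#' difference between the weighted in-set empirical CDF — weight
#' \code{rank^alpha} — and the unweighted out-of-set ECDF:
#' \deqn{ES = \sum_i [ P_{in}^w(i) - P_{out}(i) ].}
#' Scores are optionally normalized by the global max - min across the
#' whole score matrix, the usual single-sample convention.
#'
#' @param matrix genes x samples expression matrix (any monotone scale).
#' @param sets named list of member gene vectors; sets with no member in
#'   the matrix are dropped with a warning.
#' @param alpha rank weighting exponent (default 0.25).
#' @param normalize divide by the global max - min of the raw scores.
#' @return gene sets x samples numeric matrix of enrichment scores.
#' @export
ssgseaScores <- function(matrix, sets, alpha = 0.25, normalize = TRUE) {
  present <- vapply(sets, function(s) any(s %in% rownames(matrix)), logical(1))
  if (any(!present)) {
    warning("dropping set(s) with no member in the matrix: ",
            paste(names(sets)[!present], collapse = ", "))
    sets <- sets[present]
  }
  if (!length(sets)) stop("no usable gene sets")
  n <- nrow(matrix)
  es <- matrix(0, length(sets), ncol(matrix),
               dimnames = list(names(sets), colnames(matrix)))
  member <- lapply(sets, function(s) rownames(matrix) %in% s)
  for (j in seq_len(ncol(matrix))) {
    r <- rank(matrix[, j], ties.method = "average")   # N = most expressed
    ord <- order(-r)                                   # walk top-down
    w <- r[ord]^alpha
    for (si in seq_along(sets)) {
      inset <- member[[si]][ord]
      m <- sum(inset)
      win <- w * inset
      p_in <- cumsum(win) / sum(win)
      p_out <- if (m == n) rep(0, n) else cumsum(!inset) / (n - m)
      es[si, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  es
}
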