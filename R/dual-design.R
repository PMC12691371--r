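#' Build the full two-position dual-knockout design
#'
#' Crosses every guide with every guide over the two cassette positions, so
#' a library of \eqn{m} guides yields \eqn{m^2} constructs. Construct ids
#' join the two guide ids with \code{separator}. Each construct carries an
#' ordered gene-pair label (cassette order) and an unordered alias
#' (lexicographically sorted), the latter being what synthetic-lethality
#' scoring aggregates over. Safe guides enter the cross but are excluded
#' from targeted-pair counting.
#'
#' @param library a [GuideLibrary-class].
#' @param separator string joining the two guide ids (default \code{"~"}).
#' @return a [DualDesign-class].
#' @examples
#' lib <- GuideLibrary(c("a1", "b1", "s1"), c("A", "B", "SAFE"),
#'                     c("targeting", "targeting", "safe"))
#' dd <- buildDualDesign(lib)
#' designCounts(dd)
#' @export
buildDualDesign <- function(library, separator = "~") {
  stopifnot(is(library, "GuideLibrary"))
  ids <- guideIds(library)
  if (!length(ids)) stop("guide library is empty")
  gmap <- guideGeneMap(library)
  cross <- expand.grid(guide2 = ids, guide1 = ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g1 <- cross$guide1
  g2 <- cross$guide2
  gene1 <- unname(gmap[g1])
  gene2 <- unname(gmap[g2])
  lo <- pmin(gene1, gene2)
  hi <- pmax(gene1, gene2)
  d <- DataFrame(construct_id = paste0(g1, separator, g2),
                 guide1 = g1, guide2 = g2,
                 gene1 = gene1, gene2 = gene2,
                 pair_ordered = paste0(gene1, "__", gene2),
                 pair_unordered = paste0(lo, "__", hi))
  new("DualDesign", constructs = d, separator = separator)
}

#' DualDesign accessors
#'
#' \code{constructIds} returns the construct identifiers;
#' \code{pairLabels} the gene-pair label of every construct (ordered by
#' cassette position, or the sorted unordered alias);
#' \code{constructTable} the per-construct annotation as a data.frame;
#' \code{designCounts} the design's summary counts: constructs, distinct
#' ordered targeted-gene pair labels (safe pairings excluded), distinct
#' unordered targeted pairs with two distinct genes, and safe-safe
#' background constructs.
#'
#' @param x a [DualDesign-class].
#' @param ordered logical; ordered (cassette-position) or unordered labels.
#' @param ... ignored.
#' @name DualDesign-accessors
NULL

#' @rdname DualDesign-accessors
setMethod("constructIds", "DualDesign", function(x) x@constructs$construct_id)

#' @rdname DualDesign-accessors
setMethod("pairLabels", "DualDesign", function(x, ordered = TRUE) {
  if (ordered) x@constructs$pair_ordered else x@constructs$pair_unordered
})

#' @rdname DualDesign-accessors
setMethod("constructTable", "DualDesign", function(x)
  as.data.frame(x@constructs))

#' @rdname DualDesign-accessors
setMethod("designCounts", "DualDesign", function(x) {
  d <- x@constructs
  targeted <- d$gene1 != SAFE_GENE & d$gene2 != SAFE_GENE
  distinct <- targeted & d$gene1 != d$gene2
  list(n_constructs = nrow(d),
       n_ordered_pairs = length(unique(d$pair_ordered[targeted])),
       n_unordered_pairs = length(unique(d$pair_unordered[distinct])),
       n_safe_safe = sum(d$gene1 == SAFE_GENE & d$gene2 == SAFE_GENE))
})

setMethod("show", "DualDesign", function(object) {
  dc <- designCounts(object)
  cat("DualDesign:", dc$n_constructs, "constructs,",
      dc$n_ordered_pairs, "ordered targeted pair labels,",
      dc$n_unordered_pairs, "unordered screened pairs,",
      dc$n_safe_safe, "safe-safe constructs\n")
})
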