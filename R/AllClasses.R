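#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Sentinel gene symbol for safe-harbor guides
#'
#' Safe-harbor guides target non-functional genomic regions and carry no
#' gene symbol; they are normalized to this pseudo-gene so that they can be
#' carried through the dual-design machinery while being excluded from
#' gene-pair counting and synthetic-lethality scoring.
#'
#' @export
SAFE_GENE <- "SAFE"

#' GuideLibrary: annotated sgRNA library
#'
#' Holds one row per guide with its target gene and role. Targeting guides
#' must carry a gene symbol; safe-harbor guides carry the \code{SAFE_GENE}
#' sentinel. Guide identifiers are unique.
#'
#' @slot guides a \code{DataFrame} with columns \code{guide_id},
#'   \code{gene}, \code{role} (\code{"targeting"} or \code{"safe"}) and,
#'   optionally, \code{sequence}.
#'
#' @seealso [readGuideLibrary()], [buildDualDesign()]
#' @export
setClass("GuideLibrary", slots = c(guides = "DataFrame"))

setValidity("GuideLibrary", function(object) {
  g <- object@guides
  msgs <- character()
  needed <- c("guide_id", "gene", "role")
  if (!all(needed %in% colnames(g)))
    return(paste("guides must have columns", paste(needed, collapse = ", ")))
  if (anyDuplicated(g$guide_id)) {
    dup <- unique(g$guide_id[duplicated(g$guide_id)])
    msgs <- c(msgs, paste0("duplicated guide_id: ", paste(dup, collapse = ", ")))
  }
  bad_role <- setdiff(unique(g$role), c("targeting", "safe"))
  if (length(bad_role))
    msgs <- c(msgs, paste0("unknown role value: ", paste(bad_role, collapse = ", ")))
  tg <- g$role == "targeting"
  if (any(tg & (is.na(g$gene) | g$gene == "" | g$gene == SAFE_GENE)))
    msgs <- c(msgs, "every targeting guide needs a non-empty gene symbol distinct from the SAFE sentinel")
  if (any(!tg & g$role == "safe" & g$gene != SAFE_GENE))
    msgs <- c(msgs, "safe guides must carry the SAFE sentinel, not a gene symbol")
  if (length(msgs)) msgs else TRUE
})

#' DualDesign: two-position dual-knockout construct design
#'
#' The full cross of a guide library over two cassette positions. Each
#' construct knocks out (up to) two genes; the ordered gene-pair label keeps
#' cassette order while the unordered label (lexicographically sorted) is
#' what synthetic-lethality scoring aggregates over.
#'
#' @slot constructs a \code{DataFrame} with columns \code{construct_id},
#'   \code{guide1}, \code{guide2}, \code{gene1}, \code{gene2},
#'   \code{pair_ordered}, \code{pair_unordered}.
#' @slot separator the string joining the two guide ids into a construct id.
#'
#' @seealso [buildDualDesign()]
#' @export
setClass("DualDesign",
         slots = c(constructs = "DataFrame", separator = "character"))

setValidity("DualDesign", function(object) {
  d <- object@constructs
  needed <- c("construct_id", "guide1", "guide2", "gene1", "gene2",
              "pair_ordered", "pair_unordered")
  if (!all(needed %in% colnames(d)))
    return(paste("constructs must have columns", paste(needed, collapse = ", ")))
  if (anyDuplicated(d$construct_id))
    return("construct_id values must be unique")
  expect <- paste0(d$guide1, object@separator, d$guide2)
  if (!all(d$construct_id == expect))
    return("construct_id must equal guide1 <sep> guide2")
  TRUE
})

#' ScreenCountSet: pooled-screen count container
#'
#' A \linkS4class{SummarizedExperiment} whose \code{"counts"} assay holds
#' non-negative per-guide (or per-construct) read counts and whose
#' \code{colData} carries the screen design: \code{timepoint}
#' (\code{"T0"}/\code{"Tend"}), \code{condition} and \code{replicate}.
#' Counts read from disk are integral; normalized counts are real-valued and
#' live in the same container.
#'
#' @seealso [ScreenCountSet()], [readCountTable()], [normalizeCounts()]
#' @export
#' @import SummarizedExperiment
setClass("ScreenCountSet", contains = "SummarizedExperiment")

setValidity("ScreenCountSet", function(object) {
  if (!"counts" %in% assayNames(object))
    return("assay 'counts' is required")
  cts <- assay(object, "counts")
  if (any(!is.finite(cts)) || any(cts < 0))
    return("counts must be finite and non-negative")
  cd <- colData(object)
  needed <- c("timepoint", "condition", "replicate")
  if (!all(needed %in% colnames(cd)))
    return(paste("colData must have columns", paste(needed, collapse = ", ")))
  bad_tp <- setdiff(unique(cd$timepoint), c("T0", "Tend"))
  if (length(bad_tp))
    return(paste0("unknown timepoint: ", paste(bad_tp, collapse = ", ")))
  if (!any(cd$timepoint == "T0"))
    return("at least one T0 sample is required")
  if (anyDuplicated(rownames(object)))
    return("row ids must be unique")
  TRUE
})

#' Construct a ScreenCountSet from a count matrix and a screen design
#'
#' @param counts numeric matrix, rows = guides or constructs, columns =
#'   samples; non-negative.
#' @param design data.frame with columns \code{sample_id}, \code{timepoint},
#'   \code{condition}, \code{replicate}; one row per count column.
#' @return a validated [ScreenCountSet-class] with samples ordered as in
#'   \code{design}.
#' @examples
#' cts <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
#' des <- data.frame(sample_id = c("a", "b"),
#'                   timepoint = c("T0", "Tend"),
#'                   condition = "control", replicate = 1L)
#' ScreenCountSet(cts, des)
#' @export
ScreenCountSet <- function(counts, design) {
  design <- as.data.frame(design)
  needed <- c("sample_id", "timepoint", "condition", "replicate")
  if (!all(needed %in% colnames(design)))
    stop("design needs columns ", paste(needed, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("design sample_id values must be unique")
  if (is.null(colnames(counts)))
    stop("counts must have sample column names")
  extra <- setdiff(colnames(counts), design$sample_id)
  if (length(extra))
    stop("samples absent from design: ", paste(extra, collapse = ", "))
  missing <- setdiff(design$sample_id, colnames(counts))
  if (length(missing))
    stop("design samples missing from counts: ", paste(missing, collapse = ", "))
  counts <- counts[, design$sample_id, drop = FALSE]
  cd <- DataFrame(design[, c("timepoint", "condition", "replicate")],
                  row.names = design$sample_id)
  new("ScreenCountSet",
      SummarizedExperiment(assays = list(counts = counts), colData = cd))
}
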