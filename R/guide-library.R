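#' Read an sgRNA library table
#'
#' Parses a tab-separated guide annotation file with header columns
#' \code{guide_id}, \code{gene} and \code{role}. Safe-harbor guides
#' (\code{role == "safe"}) are normalized to the \code{SAFE_GENE} sentinel
#' whatever the file's gene column says.
#'
#' @param path path to a TSV file.
#' @return a validated [GuideLibrary-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("guide_id\tgene\trole",
#'              "g1\tTP53\ttargeting",
#'              "s1\t\tsafe"), tf)
#' lib <- readGuideLibrary(tf)
#' nGenes(lib)
#' @export
readGuideLibrary <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("guide_id", "gene", "role")
  if (!all(needed %in% colnames(tab)))
    stop("guide library file needs header columns ",
         paste(needed, collapse = ", "))
  if (anyDuplicated(tab$guide_id)) {
    dup <- unique(tab$guide_id[duplicated(tab$guide_id)])
    stop("duplicated guide_id in library: ", paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(tab$role), c("targeting", "safe"))
  if (length(bad))
    stop("unknown role value: ", paste(bad, collapse = ", "))
  tab$gene[tab$role == "safe"] <- SAFE_GENE
  GuideLibrary(tab$guide_id, tab$gene, tab$role,
               sequence = if ("sequence" %in% colnames(tab)) tab$sequence else NULL)
}

#' Construct a GuideLibrary from vectors
#'
#' @param guide_id,gene,role character vectors of equal length.
#' @param sequence optional character vector of spacer sequences.
#' @return a validated [GuideLibrary-class].
#' @export
GuideLibrary <- function(guide_id, gene, role, sequence = NULL) {
  g <- DataFrame(guide_id = as.character(guide_id),
                 gene = as.character(gene),
                 role = as.character(role))
  if (!is.null(sequence)) g$sequence <- as.character(sequence)
  new("GuideLibrary", guides = g)
}

#' GuideLibrary accessors
#'
#' \code{guideIds}, \code{targetGenes} (targeted genes, SAFE excluded),
#' \code{guideRoles}, \code{safeGuides}, \code{nGuides} and \code{nGenes}.
#'
#' @param x a [GuideLibrary-class].
#' @name GuideLibrary-accessors
NULL

#' @rdname GuideLibrary-accessors
setMethod("guideIds", "GuideLibrary", function(x) x@guides$guide_id)

#' @rdname GuideLibrary-accessors
setMethod("targetGenes", "GuideLibrary", function(x)
  unique(x@guides$gene[x@guides$role == "targeting"]))

#' @rdname GuideLibrary-accessors
setMethod("guideRoles", "GuideLibrary", function(x)
  stats::setNames(x@guides$role, x@guides$guide_id))

#' @rdname GuideLibrary-accessors
setMethod("safeGuides", "GuideLibrary", function(x)
  x@guides$guide_id[x@guides$role == "safe"])

#' @rdname GuideLibrary-accessors
setMethod("nGuides", "GuideLibrary", function(x) nrow(x@guides))

#' @rdname GuideLibrary-accessors
setMethod("nGenes", "GuideLibrary", function(x) length(targetGenes(x)))

#' Map guide ids to genes
#'
#' @param x a [GuideLibrary-class].
#' @return named character vector, guide_id -> gene (safe guides map to the
#'   SAFE sentinel).
#' @export
guideGeneMap <- function(x) {
  stopifnot(is(x, "GuideLibrary"))
  stats::setNames(x@guides$gene, x@guides$guide_id)
}

setMethod("show", "GuideLibrary", function(object) {
  cat("GuideLibrary with", nGuides(object), "guides:",
      sum(object@guides$role == "targeting"), "targeting",
      paste0("(", nGenes(object), " genes),"),
      length(safeGuides(object)), "safe\n")
})
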