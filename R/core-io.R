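#' Read a count table aligned to a screen design
#'
#' Tab-separated file, first column the row (guide/construct) id, remaining
#' columns per-sample read counts. Cells must be non-negative integers;
#' violations are reported with their row/sample coordinates. Samples in
#' the file must match the design exactly.
#'
#' @param path path to a TSV count file.
#' @param design data.frame with columns \code{sample_id}, \code{timepoint},
#'   \code{condition}, \code{replicate}.
#' @return a [ScreenCountSet-class].
#' @seealso [writeCountTable()]
#' @export
readCountTable <- function(path, design) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2) stop("count table needs an id column and >= 1 sample")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicated row ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (any(is.na(m)))
    stop("missing cells in count table")
  storage.mode(m) <- "double"
  bad <- which(m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("non-integer or negative count at row '%s', sample '%s': %s",
                 ids[i], colnames(m)[j], format(m[i, j])))
  }
  rownames(m) <- ids
  ScreenCountSet(m, design)
}

#' Write a ScreenCountSet's counts as TSV
#'
#' Inverse of [readCountTable()]: writing then re-reading yields an
#' identical table.
#'
#' @param x a [ScreenCountSet-class] with integral counts.
#' @param path output path.
#' @param id_column name of the first (row id) column.
#' @return \code{path}, invisibly.
#' @export
writeCountTable <- function(x, path, id_column = "id") {
  stopifnot(is(x, "ScreenCountSet"))
  m <- assay(x, "counts")
  out <- data.frame(rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out)[1] <- id_column
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the screen design from a ScreenCountSet
#'
#' @param x a [ScreenCountSet-class].
#' @return data.frame with sample_id, timepoint, condition, replicate.
#' @export
screenDesign <- function(x) {
  stopifnot(is(x, "ScreenCountSet"))
  cd <- colData(x)
  data.frame(sample_id = rownames(cd),
             timepoint = cd$timepoint,
             condition = cd$condition,
             replicate = cd$replicate,
             stringsAsFactors = FALSE)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene symbols, all
#' tab-separated. Duplicate members within a set are removed.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (members per set), with the
#'   per-set descriptions in \code{attr(, "descriptions")}.
#' @export
readGeneSetsGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm))
    stop("duplicated set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  if (any(!lengths(sets))) stop("GMT set with empty member list")
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(desc, nm)
  sets
}
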