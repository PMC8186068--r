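#' Gene set collection
#'
#' A named list of gene sets (character vectors of unique gene ids) with a
#' free-text description per set, as read from GMT files.  Any collection —
#' GO terms, KEGG pathways or custom lists — can be supplied; the testing
#' functions require no size filtering, though [filterBySize()] mirrors the
#' common 5–5000 gene protocol of other methods.
#'
#' @slot sets named list; element names are set ids, elements are unique
#'   gene-id character vectors.
#' @slot descriptions character vector parallel to \code{sets}.
#' @seealso [readGMT()], [writeGMT()], [filterBySize()], [testGeneSets()]
#' @export
setClass("GeneSetCollection",
         slots = c(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character(0)
  ids <- names(object@sets)
  if (is.null(ids) || any(!nzchar(ids)))
    msg <- c(msg, "every gene set must have a non-empty id")
  else if (anyDuplicated(ids))
    msg <- c(msg, "duplicate set id(s)")
  if (any(vapply(object@sets, anyDuplicated, 0L) > 0))
    msg <- c(msg, "genes within a set must be unique")
  if (length(object@descriptions) != length(object@sets))
    msg <- c(msg, "descriptions must parallel sets")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneSetCollection-class
#' @param sets named list of gene-id character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  new("GeneSetCollection", sets = sets,
      descriptions = as.character(descriptions))
}

#' @rdname GeneSetCollection-class
#' @param x a `GeneSetCollection`
#' @export
setIds <- function(x) names(x@sets)

#' @rdname GeneSetCollection-class
#' @export
setDescriptions <- function(x) setNames(x@descriptions, names(x@sets))

#' @rdname GeneSetCollection-class
#' @export
geneSetList <- function(x) x@sets

#' @describeIn GeneSetCollection-class number of sets
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection-class extract one set's genes by id or index
#' @param i set id or index
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

#' @describeIn GeneSetCollection-class subset the collection
#' @export
setMethod("[", "GeneSetCollection", function(x, i) {
  if (is.character(i)) i <- match(i, names(x@sets))
  new("GeneSetCollection", sets = x@sets[i],
      descriptions = x@descriptions[i])
})

setMethod("show", "GeneSetCollection", function(object) {
  sz <- lengths(object@sets)
  cat("GeneSetCollection with", length(object@sets), "sets")
  if (length(sz))
    cat(sprintf(" (sizes %d-%d, median %.0f)", min(sz), max(sz),
                stats::median(sz)))
  cat("\n")
  invisible(object)
})

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: each line is \code{set_id<TAB>description<TAB>
#' gene1<TAB>gene2...}.  Duplicate genes within a line are removed with a
#' warning; a line with fewer than three fields is a format error reported
#' with its line number.
#'
#' @param path GMT file path.
#' @return a [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("malformed GMT line ", which(keep)[short[1]], " in ", path,
         ": fewer than 3 tab-separated fields")
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate set id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  dup <- vapply(genes, anyDuplicated, 0L) > 0
  if (any(dup))
    warning("duplicate genes within set(s) ",
            paste(utils::head(ids[dup], 5), collapse = ", "),
            "; duplicates removed")
  GeneSetCollection(setNames(genes, ids), desc)
}

#' Write gene sets to a GMT file
#'
#' Inverse of [readGMT()]; \code{readGMT(writeGMT(x, f))} reproduces the
#' collection exactly.
#'
#' @param x a [GeneSetCollection-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(x, path) {
  lines <- vapply(seq_along(x@sets), function(i)
    paste(c(names(x@sets)[i], x@descriptions[i], x@sets[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter gene sets by size
#'
#' Drops sets with fewer than \code{minSize} or more than \code{maxSize}
#' genes; when a \code{universe} is given, the size is measured after
#' intersecting each set with it.  The Wallenius-based tests require no such
#' filtering — this mirrors the comparison protocol of methods that do
#' (minimum 5, maximum 5000 genes).
#'
#' @param x a [GeneSetCollection-class].
#' @param minSize,maxSize inclusive size bounds.
#' @param universe optional character vector of gene ids (e.g.
#'   [geneUniverse()]).
#' @return the filtered collection; the number dropped is reported via
#'   [message()].
#' @export
filterBySize <- function(x, minSize = 5, maxSize = 5000, universe = NULL) {
  if (minSize > maxSize) stop("'minSize' must not exceed 'maxSize'")
  sz <- if (is.null(universe)) lengths(x@sets)
        else vapply(x@sets, function(g) sum(g %in% universe), 0L)
  keep <- sz >= minSize & sz <= maxSize
  message(sum(!keep), " of ", length(keep),
          " gene sets dropped by size filter [", minSize, ", ", maxSize, "]")
  x[which(keep)]
}
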