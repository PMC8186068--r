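#' Read differentially methylated regions from BED or CSV
#'
#' Regions are returned as a [GenomicRanges::GRanges] (1-based closed
#' coordinates, the Bioconductor convention).  BED input (0-based,
#' half-open) is converted on import via [rtracklayer::import()]; CSV input
#' declares its convention through \code{coords} and may carry the optional
#' \code{no_cpgs} (number of CpGs underlying the region) and
#' \code{mean_delta_beta} (mean methylation difference, in [-1, 1]) columns
#' used by [filterRegions()].  Strand is ignored throughout: methylation
#' arrays are unstranded at this level.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"bed"} or \code{"csv"}.
#' @param coords CSV coordinate convention: \code{"one-based"} (inclusive,
#'   the default emitted by most DMR tools) or \code{"zero-based"}
#'   (half-open, BED-like).
#' @param columns named list mapping \code{chrom}, \code{start}, \code{end}
#'   and optionally \code{no_cpgs}, \code{mean_delta_beta} to CSV column
#'   names.
#' @return a \code{GRanges}; duplicated regions are allowed but flagged
#'   with a warning.
#' @export
readRegions <- function(path, format = c("auto", "bed", "csv"),
                        coords = c("one-based", "zero-based"),
                        columns = list(chrom = "chrom", start = "start",
                                       end = "end", no_cpgs = "no_cpgs",
                                       mean_delta_beta = "mean_delta_beta")) {
  format <- match.arg(format)
  coords <- match.arg(coords)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "bed") "bed" else "csv"
  if (format == "bed") {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e)
                     stop("malformed BED file ", path, ": ",
                          conditionMessage(e), call. = FALSE))
    if (any(GenomicRanges::width(gr) < 1))
      stop("region(s) with start >= end in ", path, " (first at ",
           as.character(GenomicRanges::seqnames(gr))[
             which(GenomicRanges::width(gr) < 1)[1]], ")")
  } else {
    dt <- data.table::fread(path, showProgress = FALSE)
    need <- unlist(columns[c("chrom", "start", "end")])
    miss <- setdiff(need, names(dt))
    if (length(miss))
      stop("region file ", path, " lacks required column(s): ",
           paste(miss, collapse = ", "))
    start <- as.numeric(dt[[columns$start]])
    end <- as.numeric(dt[[columns$end]])
    bad <- if (coords == "one-based") which(end < start | start < 1)
           else which(end <= start | start < 0)
    if (length(bad))
      stop("invalid region coordinates in ", path, " at data line(s) ",
           paste(utils::head(bad, 3), collapse = ", "))
    if (coords == "zero-based") start <- start + 1
    gr <- GenomicRanges::GRanges(
      seqnames = as.character(dt[[columns$chrom]]),
      ranges = IRanges::IRanges(start = start, end = end))
    if (!is.null(columns$no_cpgs) && columns$no_cpgs %in% names(dt))
      gr$no_cpgs <- as.integer(dt[[columns$no_cpgs]])
    if (!is.null(columns$mean_delta_beta) &&
        columns$mean_delta_beta %in% names(dt))
      gr$mean_delta_beta <- as.numeric(dt[[columns$mean_delta_beta]])
  }
  GenomicRanges::strand(gr) <- "*"
  if (anyDuplicated(gr) > 0)
    warning("duplicated region(s) in ", path)
  gr
}

#' Filter DMRs on support and effect size
#'
#' Keeps regions with at least \code{minCpGs} underlying CpGs and a mean
#' absolute methylation difference of at least \code{minAbsDeltaBeta}
#' (boundary inclusive: regions are removed only when strictly below a
#' threshold).  Either filter is disabled by passing \code{NULL}; region
#' tables from some experiments are deliberately tested unfiltered.
#'
#' @param regions a \code{GRanges}, e.g. from [readRegions()].
#' @param minCpGs minimum CpG support (uses metadata column
#'   \code{no_cpgs}), or \code{NULL} to disable.
#' @param minAbsDeltaBeta minimum |mean delta-beta| (metadata column
#'   \code{mean_delta_beta}), or \code{NULL} to disable.
#' @return the filtered \code{GRanges}.
#' @export
filterRegions <- function(regions, minCpGs = 3, minAbsDeltaBeta = 0.1) {
  keep <- rep(TRUE, length(regions))
  mc <- S4Vectors::mcols(regions)
  if (!is.null(minCpGs)) {
    if (is.null(mc$no_cpgs))
      stop("CpG-support filter is active but regions carry no 'no_cpgs' ",
           "column")
    if (anyNA(mc$no_cpgs))
      stop("CpG-support filter is active but 'no_cpgs' is missing",
           .regionHint(regions, is.na(mc$no_cpgs)))
    keep <- keep & mc$no_cpgs >= minCpGs
  }
  if (!is.null(minAbsDeltaBeta)) {
    if (is.null(mc$mean_delta_beta))
      stop("delta-beta filter is active but regions carry no ",
           "'mean_delta_beta' column")
    if (anyNA(mc$mean_delta_beta))
      stop("delta-beta filter is active but 'mean_delta_beta' is missing",
           .regionHint(regions, is.na(mc$mean_delta_beta)))
    keep <- keep & abs(mc$mean_delta_beta) >= minAbsDeltaBeta
  }
  regions[keep]
}

.regionHint <- function(regions, bad) {
  i <- which(bad)[1]
  if (is.na(i) || !length(i)) return("")
  paste0(" (first offending region: ",
         as.character(GenomicRanges::seqnames(regions))[i], ":",
         GenomicRanges::start(regions)[i], "-",
         GenomicRanges::end(regions)[i], ")")
}

#' CpGs underlying a set of regions
#'
#' Overlaps region intervals with the single-basepair CpG coordinates of
#' the array and returns the deduplicated set of CpG ids whose position
#' falls inside any region (>= 1 bp overlap at probe resolution; strand
#' ignored).
#'
#' @param regions a \code{GRanges}.
#' @param annot a [CpGAnnotation-class].
#' @return character vector of CpG ids, in array order.
#' @export
regionsToCpGs <- function(regions, annot) {
  hits <- GenomicRanges::findOverlaps(cpgRanges(annot), regions,
                                      ignore.strand = TRUE)
  ids <- cpgIds(annot)[sort(unique(S4Vectors::queryHits(hits)))]
  if (!length(ids))
    stop("no CpG on the array underlies any of the supplied regions; ",
         "check coordinates and chromosome naming")
  ids
}

#' Gene set testing of differentially methylated regions
#'
#' Region-based front end to the bias-corrected over-representation test:
#' the CpGs underlying the regions are identified with [regionsToCpGs()]
#' and passed, unchanged, to [testGeneSets()].  Because region detection is
#' driven by probe density, genes with more measured CpGs are more likely
#' to contain a region; delegating to the Wallenius machinery corrects this
#' the same way as for probe-wise input.  Filtering (e.g. by CpG support
#' and effect size) is the caller's choice via [filterRegions()] before
#' this call.
#'
#' @param regions a \code{GRanges} of DMRs.
#' @param annot a [CpGAnnotation-class].
#' @param sets a [GeneSetCollection-class].
#' @inheritParams testGeneSets
#' @return the [testGeneSets()] result data.frame.
#' @export
goregion <- function(regions, annot, sets,
                     method = c("GOmeth", "HGT-mod", "HGT"),
                     span = 0.5, adjust = c("BH", "Holm")) {
  if (!length(regions)) stop("empty region set")
  testGeneSets(regionsToCpGs(regions, annot), annot, sets,
               method = method, span = span, adjust = adjust)
}
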