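#' CpG-to-gene annotation table
#'
#' Container for an array manifest abstraction: every measured CpG site with
#' its genomic coordinate, and the (possibly empty) set of genes each CpG is
#' annotated to, with transcript-level feature labels (\code{TSS1500},
#' \code{TSS200}, \code{5'UTR}, \code{1stExon}, \code{Body}, \code{3'UTR},
#' ...).  Gene links are stored deduplicated: a gene listed for several
#' transcripts of the same CpG appears once, carrying the union of its
#' feature labels.
#'
#' @slot sites data.frame with columns \code{cpg_id} (unique), \code{chrom},
#'   \code{pos} (1-based basepair, >= 1); one row per CpG on the array,
#'   including unannotated CpGs.
#' @slot links data.frame with columns \code{cpg_id}, \code{gene},
#'   \code{features} (semicolon-joined labels); one row per unique
#'   (CpG, gene) pair.
#' @seealso [readAnnotation()], [cpgWeights()], [buildGeneIndex()],
#'   [restrictByFeature()], [compositionSummary()]
#' @export
setClass("CpGAnnotation",
         slots = c(sites = "data.frame", links = "data.frame"))

setValidity("CpGAnnotation", function(object) {
  s <- object@sites
  l <- object@links
  msg <- character(0)
  need <- c("cpg_id", "chrom", "pos")
  if (!all(need %in% names(s)))
    msg <- c(msg, "sites must have columns cpg_id, chrom, pos")
  else {
    if (anyDuplicated(s$cpg_id))
      msg <- c(msg, "duplicate cpg_id in annotation")
    if (nrow(s) && any(s$pos < 1))
      msg <- c(msg, "positions must be >= 1")
  }
  if (!all(c("cpg_id", "gene", "features") %in% names(l)))
    msg <- c(msg, "links must have columns cpg_id, gene, features")
  else if (nrow(l)) {
    if (!all(l$cpg_id %in% s$cpg_id))
      msg <- c(msg, "links refer to CpGs absent from sites")
    if (anyDuplicated(l[, c("cpg_id", "gene")]))
      msg <- c(msg, "duplicate (cpg_id, gene) link")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CpGAnnotation from site and link tables
#'
#' @param sites data.frame of CpG sites (\code{cpg_id}, \code{chrom},
#'   \code{pos}).
#' @param links data.frame of gene links (\code{cpg_id}, \code{gene},
#'   optional \code{features}); duplicate (CpG, gene) rows are collapsed and
#'   their feature labels merged.
#' @return a [CpGAnnotation-class] object.
#' @export
CpGAnnotation <- function(sites, links = data.frame(cpg_id = character(0),
                                                    gene = character(0),
                                                    features = character(0))) {
  sites <- data.frame(cpg_id = as.character(sites$cpg_id),
                      chrom = as.character(sites$chrom),
                      pos = as.integer(sites$pos))
  if (is.null(links$features)) links$features <- ""
  links <- data.frame(cpg_id = as.character(links$cpg_id),
                      gene = as.character(links$gene),
                      features = as.character(links$features))
  if (nrow(links) && anyDuplicated(links[, c("cpg_id", "gene")])) {
    dt <- data.table::as.data.table(links)
    links <- as.data.frame(dt[, list(
      features = paste(unique(unlist(strsplit(features, ";", fixed = TRUE))),
                       collapse = ";")), by = c("cpg_id", "gene")])
  }
  new("CpGAnnotation", sites = sites, links = links)
}

#' @describeIn CpGAnnotation-class number of CpG sites on the array
#' @param x,object a \code{CpGAnnotation}
#' @export
nCpGs <- function(x) nrow(x@sites)

#' @describeIn CpGAnnotation-class CpG identifiers
#' @export
cpgIds <- function(x) x@sites$cpg_id

#' @describeIn CpGAnnotation-class site table (one row per CpG)
#' @export
cpgSites <- function(x) x@sites

#' @describeIn CpGAnnotation-class link table (one row per CpG-gene pair)
#' @export
geneLinks <- function(x) x@links

#' @describeIn CpGAnnotation-class CpG coordinates as a width-1
#'   [GenomicRanges::GRanges], named by CpG id, for interval overlap
#' @export
cpgRanges <- function(x) {
  s <- x@sites
  gr <- GenomicRanges::GRanges(
    seqnames = s$chrom,
    ranges = IRanges::IRanges(start = s$pos, width = 1L))
  names(gr) <- s$cpg_id
  gr$cpg_id <- s$cpg_id
  gr
}

setMethod("show", "CpGAnnotation", function(object) {
  cs <- compositionSummary(object)
  cat("CpGAnnotation with", nrow(object@sites), "CpG sites,",
      nrow(object@links), "gene links,", cs$nGenes, "genes\n")
  cat(sprintf("  annotated fraction: %.3f; multi-gene fraction: %.3f\n",
              cs$fracAnnotated, cs$fracMultiGene))
  invisible(object)
})

#' Default and Illumina manifest column mappings
#'
#' Column-name mappings used by [readAnnotation()].  `annotationColumns()`
#' is the generic dialect (the one written by [writeAnnotation()]);
#' `illuminaColumns()` matches CSV exports of Illumina 450K/EPIC manifest
#' annotation (\code{Name}/\code{CHR}/\code{MAPINFO}/
#' \code{UCSC_RefGene_Name}/\code{UCSC_RefGene_Group}).
#'
#' @param cpg,chrom,pos,genes,features column names in the file.
#' @return named list of column names.
#' @export
annotationColumns <- function(cpg = "cpg_id", chrom = "chrom", pos = "pos",
                              genes = "genes", features = "features") {
  list(cpg = cpg, chrom = chrom, pos = pos, genes = genes,
       features = features)
}

#' @rdname annotationColumns
#' @export
illuminaColumns <- function() {
  annotationColumns(cpg = "Name", chrom = "CHR", pos = "MAPINFO",
                    genes = "UCSC_RefGene_Name",
                    features = "UCSC_RefGene_Group")
}

#' Read a CpG annotation table from CSV/TSV
#'
#' Parses a manifest-like file with one row per CpG: id, chromosome, 1-based
#' position, semicolon-separated gene symbols and a parallel
#' semicolon-separated feature-label field.  Gene symbols repeated for
#' several transcripts of one CpG are collapsed to a single link whose
#' feature labels are the union of the repeated entries.
#'
#' @param path file path (separator sniffed by [data.table::fread()]).
#' @param columns column-name mapping, see [annotationColumns()].
#' @return a [CpGAnnotation-class].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("cpg_id,chrom,pos,genes,features",
#'              "cg0001,chr1,100,GENEA,Body",
#'              "cg0002,chr1,200,GENEA;GENEA;GENEB,TSS200;Body;Body",
#'              "cg0003,chr1,300,,"), tf)
#' ann <- readAnnotation(tf)
#' geneLinks(ann)
#' @export
readAnnotation <- function(path, columns = annotationColumns()) {
  hdr <- names(data.table::fread(path, nrows = 0, showProgress = FALSE))
  charCols <- intersect(
    unlist(columns[c("cpg", "chrom", "genes", "features")]), hdr)
  dt <- data.table::fread(path, colClasses = list(character = charCols),
                          showProgress = FALSE)
  miss <- setdiff(unlist(columns), names(dt))
  if (length(miss))
    stop("annotation file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  cpg <- as.character(dt[[columns$cpg]])
  if (anyDuplicated(cpg))
    stop("duplicate CpG id(s) in ", path, ": ",
         paste(utils::head(unique(cpg[duplicated(cpg)]), 3), collapse = ", "))
  genes <- as.character(dt[[columns$genes]])
  feats <- as.character(dt[[columns$features]])
  genes[is.na(genes)] <- ""
  feats[is.na(feats)] <- ""
  gs <- strsplit(genes, ";", fixed = TRUE)
  fs <- strsplit(feats, ";", fixed = TRUE)
  ng <- lengths(gs)
  nf <- lengths(fs)
  bad <- which(ng != nf & ng > 0 & nf > 0 | (ng == 0) != (nf == 0))
  if (length(bad))
    stop("gene/feature field length mismatch for CpG(s): ",
         paste(utils::head(cpg[bad], 3), collapse = ", "))
  has <- ng > 0
  links <- data.frame(cpg_id = rep(cpg[has], ng[has]),
                      gene = unlist(gs[has]),
                      features = unlist(fs[has]))
  links <- links[nzchar(links$gene), , drop = FALSE]
  sites <- data.frame(cpg_id = cpg,
                      chrom = as.character(dt[[columns$chrom]]),
                      pos = as.integer(dt[[columns$pos]]))
  CpGAnnotation(sites, links)
}

#' Write a CpG annotation table as CSV
#'
#' Emits the generic dialect read back by [readAnnotation()] (columns
#' \code{cpg_id,chrom,pos,genes,features}), with one row per CpG and
#' semicolon-joined gene/feature fields.  A link whose feature union holds
#' several labels is expanded so the gene and feature fields stay parallel.
#'
#' @param annot a [CpGAnnotation-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotation <- function(annot, path) {
  l <- annot@links
  out <- data.table::as.data.table(annot@sites)
  if (nrow(l)) {
    fl <- strsplit(l$features, ";", fixed = TRUE)
    nf <- pmax(lengths(fl), 1L)
    expanded <- data.table::data.table(
      cpg_id = rep(l$cpg_id, nf),
      gene = rep(l$gene, nf),
      feature = unlist(lapply(fl, function(f) if (length(f)) f else "")))
    joined <- expanded[, list(genes = paste(gene, collapse = ";"),
                              features = paste(feature, collapse = ";")),
                       by = "cpg_id"]
    out <- merge(out, joined, by = "cpg_id", all.x = TRUE, sort = FALSE)
  } else {
    out$genes <- ""
    out$features <- ""
  }
  out$genes[is.na(out$genes)] <- ""
  out$features[is.na(out$features)] <- ""
  data.table::setcolorder(out, c("cpg_id", "chrom", "pos", "genes",
                                 "features"))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Multi-gene CpG weights
#'
#' Assigns each gene-annotated CpG the weight \eqn{w = 1/k}, where \eqn{k}
#' is the number of unique genes the CpG is annotated to, so that one CpG
#' distributes a total annotation mass of 1 across its genes.  Unannotated
#' CpGs carry no weight and are absent from the result.
#'
#' @param annot a [CpGAnnotation-class].
#' @return named numeric vector of weights in (0, 1], one entry per
#'   gene-annotated CpG.
#' @export
cpgWeights <- function(annot) {
  l <- data.table::as.data.table(annot@links)
  if (!nrow(l)) return(setNames(numeric(0), character(0)))
  k <- l[, list(k = .N), by = "cpg_id"]
  setNames(1 / k$k, k$cpg_id)
}

#' Per-gene equivalent CpG counts and weighted CpG lists
#'
#' For each annotated gene \eqn{j}, sums the multi-gene weights of its CpGs
#' into the equivalent CpG count \eqn{N_j = \sum_i w_{ij}}.  When no CpG is
#' shared between genes, \eqn{N_j} equals the integer number of probes
#' measured across the gene.  The gene universe is the set of genes with at
#' least one link.
#'
#' @slot links data.frame (\code{cpg_id}, \code{gene}, \code{w}), one row
#'   per (gene, CpG) pair.
#' @slot genes data.frame (\code{gene}, \code{N}, \code{nCpGs}) ordered by
#'   gene id; \code{nCpGs} is the raw integer probe count.
#' @export
setClass("GeneIndex", slots = c(links = "data.frame", genes = "data.frame"))

setValidity("GeneIndex", function(object) {
  msg <- character(0)
  if (!all(c("cpg_id", "gene", "w") %in% names(object@links)))
    msg <- c(msg, "links must have columns cpg_id, gene, w")
  if (!all(c("gene", "N", "nCpGs") %in% names(object@genes)))
    msg <- c(msg, "genes must have columns gene, N, nCpGs")
  else if (anyDuplicated(object@genes$gene))
    msg <- c(msg, "duplicate gene in index")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneIndex-class
#' @param annot a [CpGAnnotation-class].
#' @param weights CpG weights, normally from [cpgWeights()] on the same
#'   annotation.
#' @return `buildGeneIndex()` returns a `GeneIndex`.
#' @export
buildGeneIndex <- function(annot, weights = cpgWeights(annot)) {
  l <- data.table::as.data.table(annot@links)
  if (!nrow(l)) {
    return(new("GeneIndex",
               links = data.frame(cpg_id = character(0), gene = character(0),
                                  w = numeric(0)),
               genes = data.frame(gene = character(0), N = numeric(0),
                                  nCpGs = integer(0))))
  }
  l <- l[, list(cpg_id, gene)]
  l[, "w" := weights[match(cpg_id, names(weights))]]
  genes <- l[, list(N = sum(w), nCpGs = .N), by = "gene"]
  data.table::setorder(genes, gene)
  new("GeneIndex", links = as.data.frame(l), genes = as.data.frame(genes))
}

#' @rdname GeneIndex-class
#' @param x a `GeneIndex`
#' @export
geneUniverse <- function(x) x@genes$gene

#' @rdname GeneIndex-class
#' @export
equivalentCounts <- function(x) setNames(x@genes$N, x@genes$gene)

#' @rdname GeneIndex-class
#' @export
rawCounts <- function(x) setNames(x@genes$nCpGs, x@genes$gene)

setMethod("show", "GeneIndex", function(object) {
  cat("GeneIndex:", nrow(object@genes), "genes,", nrow(object@links),
      "CpG-gene links\n")
  invisible(object)
})

#' Restrict annotation to genomic features
#'
#' Keeps only the gene links whose feature-label set intersects
#' \code{features} (e.g. \code{c("TSS1500", "TSS200", "Body")}).  CpGs left
#' without links remain on the array as unannotated sites.  Weights and gene
#' index must be recomputed from the restricted table; a retained CpG's
#' weight can only grow, since dropping links lowers its gene count.
#'
#' @param annot a [CpGAnnotation-class].
#' @param features non-empty character vector of feature labels to keep.
#'   Labels absent from the annotation trigger a warning, not an error
#'   (annotation dialects vary).
#' @return the restricted [CpGAnnotation-class].
#' @export
restrictByFeature <- function(annot, features) {
  if (!length(features)) stop("'features' must be a non-empty character vector")
  l <- annot@links
  fl <- strsplit(l$features, ";", fixed = TRUE)
  seen <- unique(unlist(fl))
  unknown <- setdiff(features, seen)
  if (length(unknown))
    warning("feature label(s) not present in annotation: ",
            paste(unknown, collapse = ", "))
  keep <- vapply(fl, function(f) any(f %in% features), logical(1))
  kept <- l[keep, , drop = FALSE]
  if (nrow(kept)) {
    kf <- strsplit(kept$features, ";", fixed = TRUE)
    kept$features <- vapply(kf, function(f)
      paste(intersect(f, features), collapse = ";"), character(1))
  }
  new("CpGAnnotation", sites = annot@sites, links = kept)
}

#' Composition summary of an annotation
#'
#' Reports the array composition statistics that drive both biases corrected
#' by the Wallenius test: the CpGs-per-gene distribution (probe-number bias)
#' and the fraction of gene-annotated CpGs mapped to two or more genes
#' (multi-gene bias), plus the fraction of CpGs annotated at all.
#'
#' @param annot a [CpGAnnotation-class].
#' @return one-row data.frame with columns \code{nCpGs}, \code{nGenes},
#'   \code{fracAnnotated}, \code{fracMultiGene}, \code{minCpGsPerGene},
#'   \code{medianCpGsPerGene}, \code{maxCpGsPerGene},
#'   \code{modeCpGsPerGene}.  Distribution fields are \code{NA} and
#'   fractions 0 for an empty universe.
#' @export
compositionSummary <- function(annot) {
  l <- annot@links
  ncpg <- nrow(annot@sites)
  if (!nrow(l)) {
    return(data.frame(nCpGs = ncpg, nGenes = 0L, fracAnnotated = 0,
                      fracMultiGene = 0, minCpGsPerGene = NA_real_,
                      medianCpGsPerGene = NA_real_, maxCpGsPerGene = NA_real_,
                      modeCpGsPerGene = NA_real_))
  }
  dt <- data.table::as.data.table(l)
  perGene <- dt[, list(k = .N), by = "gene"]$k
  perCpG <- dt[, list(k = .N), by = "cpg_id"]$k
  cnt <- table(perGene)
  mode_ <- as.integer(names(cnt)[which.max(cnt)])
  data.frame(nCpGs = ncpg,
             nGenes = length(perGene),
             fracAnnotated = length(perCpG) / ncpg,
             fracMultiGene = mean(perCpG >= 2),
             minCpGsPerGene = min(perGene),
             medianCpGsPerGene = stats::median(as.numeric(perGene)),
             maxCpGsPerGene = max(perGene),
             modeCpGsPerGene = mode_)
}
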