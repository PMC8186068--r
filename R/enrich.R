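#' Per-gene differential methylation scores
#'
#' Maps a set of significant CpGs onto genes with multi-gene weighting.
#' Gene \eqn{j}'s score is \eqn{S_j = \min(\sum_i 1[CpG_{ij} \in A]
#' w_{ij},\ 1)}: the sum of the weights of its significant CpGs, capped at
#' 1, so that no gene contributes more than one "count" to any overlap
#' statistic however many significant probes it carries.  \eqn{S_j = 0} iff
#' the gene has no significant CpG; \eqn{S_j < 1} only when all its
#' significant CpGs are shared with other genes.
#'
#' @param sig character vector of significant CpG ids (the set \eqn{A}).
#'   Ids absent from the index (including unannotated CpGs) contribute to no
#'   gene; their count is attached as attribute \code{nUnannotated}.
#' @param index a [GeneIndex-class].
#' @return named numeric vector of scores in [0, 1] over the full gene
#'   universe (zeros retained).
#' @export
geneScores <- function(sig, index) {
  sig <- unique(as.character(sig))
  if (!length(sig))
    warning("empty significant CpG set; all gene scores are zero")
  genes <- index@genes$gene
  l <- data.table::as.data.table(index@links)
  hit <- l[l$cpg_id %in% sig, ]
  S <- setNames(numeric(length(genes)), genes)
  if (nrow(hit)) {
    agg <- hit[, list(S = min(sum(w), 1)), by = "gene"]
    S[match(agg$gene, genes)] <- agg$S
  }
  attr(S, "nUnannotated") <- sum(!(sig %in% l$cpg_id))
  S
}

#' Probability weighting function
#'
#' Estimates the empirical probability that a gene is called differentially
#' methylated as a function of how many CpGs it carries (probe-number bias).
#' The binary indicator \eqn{dm_j = 1[S_j > 0]} is ordered by the gene's
#' CpG count — equivalent (multi-gene-weighted) counts \eqn{N_j} for the
#' fully corrected test, raw integer counts for the probe-number-only
#' variant — and smoothed with a tricube moving average
#' ([limma::tricubeMovingAverage()]), a least-squares loess-like smoother of
#' degree zero with edge truncation and weight renormalisation.  The window
#' covers a \code{span} fraction of the universe (odd width, default span
#' 0.5).
#'
#' @param scores gene scores from [geneScores()].
#' @param index a [GeneIndex-class] built from the same annotation.
#' @param span moving-average span in (0, 1].
#' @param biasCounts \code{"equivalent"} to order by \eqn{N_j},
#'   \code{"raw"} to order by integer probe counts.
#' @return data.frame (\code{gene}, \code{N}, \code{dm}, \code{pwf}) sorted
#'   by ascending \code{N} with stable gene-id tie-breaking; \code{pwf} in
#'   [0, 1].
#' @export
estimatePWF <- function(scores, index, span = 0.5,
                        biasCounts = c("equivalent", "raw")) {
  biasCounts <- match.arg(biasCounts)
  if (span <= 0 || span > 1) stop("'span' must be in (0, 1]")
  genes <- index@genes$gene
  if (!length(genes)) stop("empty gene universe")
  N <- if (biasCounts == "equivalent") index@genes$N
       else as.numeric(index@genes$nCpGs)
  dm <- as.numeric(scores[match(genes, names(scores))] > 0)
  if (anyNA(dm)) stop("scores do not cover the gene universe")
  ord <- order(N, genes)
  pwf <- limma::tricubeMovingAverage(dm[ord], span = span)
  data.frame(gene = genes[ord], N = N[ord], dm = dm[ord],
             pwf = pmin(pmax(pwf, 0), 1))
}

#' Expected enrichment odds of a gene set
#'
#' Ratio of the mean probability weighting function over the genes in the
#' set to the mean over the rest of the array universe:
#' \deqn{ODDS_g = mean(PWF(in\ set)) / mean(PWF(not\ in\ set)).}
#' Values above 1 mean the set's genes are more likely to be called
#' differentially methylated for composition reasons alone, and the
#' Wallenius test discounts their overlap accordingly.
#'
#' @param pwf PWF table from [estimatePWF()].
#' @param geneSet character vector of gene ids; intersected with the
#'   universe, which must leave a non-empty proper subset.
#' @return positive scalar; capped at 1e6 (with a warning) in the
#'   degenerate case of an all-zero out-of-set PWF.
#' @export
setOdds <- function(pwf, geneSet) {
  inSet <- pwf$gene %in% geneSet
  if (!any(inSet))
    stop("gene set does not intersect the array universe; untestable")
  if (all(inSet))
    stop("gene set covers the whole array universe; untestable")
  mIn <- mean(pwf$pwf[inSet])
  mOut <- mean(pwf$pwf[!inSet])
  if (mOut == 0) {
    warning("out-of-set mean PWF is zero; odds capped at 1e6")
    return(1e6)
  }
  mIn / mOut
}

#' Weighted enrichment statistic of a gene set
#'
#' \eqn{ES_g = \sum_{j \in g} S_j}, the multi-gene-weighted overlap between
#' significant genes and the set; each gene contributes at most 1, so a
#' single significant CpG shared by many co-clustered genes cannot inflate
#' the overlap beyond one count.
#'
#' @param scores gene scores from [geneScores()].
#' @param geneSet character vector of gene ids.
#' @return non-negative scalar, at most the set's universe intersection
#'   size.
#' @export
enrichmentScore <- function(scores, geneSet) {
  sum(scores[names(scores) %in% geneSet])
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg or Holm adjustment of a p-value vector (wraps
#' [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method \code{"BH"} (default) or \code{"Holm"}.
#' @return adjusted p-values, monotone and capped at 1.
#' @export
adjustPValues <- function(p, method = c("BH", "Holm")) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = c(BH = "BH", Holm = "holm")[[method]])
}

#' Gene set over-representation tests for significant CpGs
#'
#' Tests every gene set for over-representation of the genes hit by a
#' significant-CpG list, with three variants:
#' \describe{
#'   \item{\code{GOmeth}}{corrects probe-number and multi-gene bias:
#'     \eqn{x = \lfloor ES_g \rfloor} from the weighted scores, odds from
#'     the equivalent-count PWF, one-sided Wallenius noncentral
#'     hypergeometric p-value.}
#'   \item{\code{HGT-mod}}{corrects probe-number bias only: integer count of
#'     significant genes in the set, odds from the raw-count PWF.}
#'   \item{\code{HGT}}{plain hypergeometric test (odds 1), integer counts.}
#' }
#' The urn for set \eqn{g} is \eqn{m_1 = J_g} (genes in the set on the
#' array), \eqn{m_2} the rest of the universe, and \eqn{n} the total number
#' of genes with at least one significant CpG.
#'
#' @param sig character vector of significant CpG ids.
#' @param annot a [CpGAnnotation-class].
#' @param sets a [GeneSetCollection-class].
#' @param method one of \code{"GOmeth"}, \code{"HGT-mod"}, \code{"HGT"}.
#' @param span PWF smoother span, see [estimatePWF()].
#' @param adjust multiple-testing adjustment, see [adjustPValues()].
#' @return data.frame with one row per set, sorted by p-value (ties broken
#'   by set id): \code{set_id}, \code{set_name}, \code{J},
#'   \code{n_sig_genes}, \code{ES}, \code{odds}, \code{p}, \code{p_adj},
#'   \code{method}.  Attributes \code{universeSize}, \code{nSigGenes} and
#'   \code{nUnannotatedSig} summarise the run.
#' @examples
#' ann <- syntheticAnnotation(nGenes = 300, seed = 7)
#' sets <- syntheticGeneSets(ann, nSets = 20, sizeRange = c(5, 40), seed = 8)
#' sig <- sampleNullCpGs(ann, 100, seed = 9)
#' head(testGeneSets(sig, ann, sets, method = "GOmeth"))
#' @export
testGeneSets <- function(sig, annot, sets,
                         method = c("GOmeth", "HGT-mod", "HGT"),
                         span = 0.5, adjust = c("BH", "Holm")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  prep <- .prepareEnrichment(annot, sets)
  res <- .testPrepared(prep, sig, methods = method, span = span)[[method]]
  .finishResult(res, prep, adjust)
}

#' Write an enrichment result table as TSV
#'
#' @param res result data.frame from [testGeneSets()] or [goregion()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(res, path) {
  data.table::fwrite(res, path, sep = "\t")
  invisible(path)
}

# Precompute everything that depends only on (annotation, sets):
# the gene index, both bias orderings, and per-set membership indices.
.prepareEnrichment <- function(annot, sets, index = buildGeneIndex(annot)) {
  stopifnot(is(annot, "CpGAnnotation"), is(sets, "GeneSetCollection"))
  if (length(sets) == 0) stop("gene set collection is empty")
  genes <- index@genes$gene
  if (length(genes) < 2)
    stop("gene universe has fewer than 2 genes; nothing to test")
  N <- index@genes$N
  rawN <- as.numeric(index@genes$nCpGs)
  links <- data.table::data.table(
    cpg_id = index@links$cpg_id,
    gi = match(index@links$gene, genes),
    w = index@links$w)
  data.table::setkey(links, cpg_id)
  members <- lapply(sets@sets, function(g) which(genes %in% g))
  list(index = index, genes = genes, U = length(genes),
       N = N, rawN = rawN,
       ordEquiv = order(N, genes), ordRaw = order(rawN, genes),
       links = links, members = members, J = lengths(members),
       setIds = names(sets@sets), setNames = sets@descriptions)
}

# Score a significant-CpG set against a prepared universe and compute the
# requested method variants.  Returns a named list of raw result
# data.frames (unsorted, unadjusted).
.testPrepared <- function(prep, sig, methods = "GOmeth", span = 0.5) {
  sig <- unique(as.character(sig))
  hit <- prep$links[list(sig), nomatch = NULL]
  S <- numeric(prep$U)
  if (nrow(hit)) {
    agg <- hit[, list(S = min(sum(w), 1)), by = "gi"]
    S[agg$gi] <- agg$S
  }
  dm <- S > 0
  n <- sum(dm)
  if (n == 0)
    warning("no significant CpG maps to any gene in the universe; ",
            "all p-values are 1")
  ES <- vapply(prep$members, function(ix) sum(S[ix]), numeric(1))
  xInt <- vapply(prep$members, function(ix) sum(dm[ix]), numeric(1))
  J <- prep$J
  m2 <- prep$U - J
  dmNum <- as.numeric(dm)

  oddsFor <- function(ord) {
    pwf <- numeric(prep$U)
    pwf[ord] <- pmin(pmax(
      limma::tricubeMovingAverage(dmNum[ord], span = span), 0), 1)
    tot <- sum(pwf)
    sIn <- vapply(prep$members, function(ix) sum(pwf[ix]), numeric(1))
    odds <- rep(1, length(J))
    ok <- J > 0 & J < prep$U
    mIn <- sIn[ok] / J[ok]
    mOut <- (tot - sIn[ok]) / (prep$U - J[ok])
    o <- ifelse(mOut == 0, 1e6, mIn / mOut)
    if (any(mOut == 0 & mIn > 0))
      warning("out-of-set mean PWF is zero for some set(s); odds capped ",
              "at 1e6")
    odds[ok] <- o
    odds
  }

  out <- list()
  for (method in methods) {
    if (method == "GOmeth") {
      x <- floor(ES)
      odds <- oddsFor(prep$ordEquiv)
      es <- ES
    } else if (method == "HGT-mod") {
      x <- xInt
      odds <- oddsFor(prep$ordRaw)
      es <- xInt
    } else if (method == "HGT") {
      x <- xInt
      odds <- rep(1, length(J))
      es <- xInt
    } else stop("unknown method: ", method)
    p <- numeric(length(J))
    testable <- J > 0
    if (method == "HGT") {
      # odds = 1: exact central hypergeometric
      p[testable] <- stats::phyper(x[testable] - 1, J[testable],
                                   m2[testable], n, lower.tail = FALSE)
    } else {
      p[testable] <- walleniusUpperTail(x[testable], J[testable],
                                        m2[testable], n, odds[testable])
    }
    p[!testable] <- 1
    out[[method]] <- data.frame(
      set_id = prep$setIds, set_name = prep$setNames, J = as.integer(J),
      n_sig_genes = as.integer(xInt), ES = es, odds = odds, p = p,
      method = method, nSigGenes = n,
      nUnannotatedSig = sum(!(sig %in% prep$links$cpg_id)))
  }
  out
}

# Sort, adjust, and attach run summaries.
.finishResult <- function(res, prep, adjust) {
  n <- res$nSigGenes[1]
  nUn <- res$nUnannotatedSig[1]
  res <- res[, setdiff(names(res), c("nSigGenes", "nUnannotatedSig"))]
  res$p_adj <- adjustPValues(res$p, adjust)
  res <- res[order(res$p, res$set_id), ]
  res <- res[, c("set_id", "set_name", "J", "n_sig_genes", "ES", "odds",
                 "p", "p_adj", "method")]
  rownames(res) <- NULL
  attr(res, "universeSize") <- prep$U
  attr(res, "nSigGenes") <- n
  attr(res, "nUnannotatedSig") <- nUn
  res
}
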