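# Synthetic methylation-array generators.  The defaults emulate the
# composition of a modern Illumina-style array: a heavy-tailed
# CpGs-per-gene distribution (median ~20, tail into the hundreds), ~9% of
# gene-annotated CpGs shared between two genomically adjacent genes, and
# ~30% of CpGs with no gene annotation.  Everything is a pure function of
# its seed.

# Evaluate expr under a local RNG seed, restoring global RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Negative-binomial mu whose 1 + NB(size, mu) median is the target:
# binary search on the monotone discrete quantile, centred on the plateau
# of mu values whose median equals the target.
.calibrateNBMu <- function(medianTarget, size) {
  edge <- function(m) {
    lo <- 0.01
    hi <- 10
    while (stats::qnbinom(0.5, size = size, mu = hi) < m) hi <- hi * 2
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (stats::qnbinom(0.5, size = size, mu = mid) >= m) hi <- mid
      else lo <- mid
    }
    hi
  }
  m <- medianTarget - 1L
  (edge(m) + edge(m + 1L)) / 2
}

#' Generate a synthetic CpG annotation
#'
#' Builds an annotation table with the composition structure of a real
#' methylation array: genes laid out in genomic order over
#' \code{nChroms} chromosomes, per-gene CpG counts drawn from a
#' negative-binomial (shifted to a minimum of 1) calibrated so the median is
#' \code{medianCpGsPerGene}, a configurable fraction of gene-annotated CpGs
#' shared between genomically adjacent genes (multi-gene bias), and a
#' fraction of CpGs with no gene link at all.  CpG positions are strictly
#' increasing within a chromosome, with unannotated CpGs interspersed at
#' random ranks, so interval overlap behaves like real coordinates.
#'
#' @param nGenes number of genes.
#' @param cpgsPerGene optional integer vector of fixed per-gene CpG counts
#'   (recycled to \code{nGenes}); overrides the negative-binomial draw.
#' @param medianCpGsPerGene target median of the CpGs-per-gene
#'   distribution.
#' @param dispersion negative-binomial size parameter; smaller is
#'   heavier-tailed.
#' @param multiGeneFraction target fraction of gene-annotated CpGs linked
#'   to two genes, in [0, 1).
#' @param sharedCpGs optional exact number of shared CpGs, overriding
#'   \code{multiGeneFraction} (useful for small fixed layouts).
#' @param unannotatedFraction target fraction of all CpGs with no gene
#'   link, in [0, 1).
#' @param nChroms number of synthetic chromosomes (\code{chr1}, ...).
#' @param seed integer; output is a pure function of the configuration and
#'   this seed.
#' @return a [CpGAnnotation-class].
#' @examples
#' # two genes with 3 and 8 CpGs, one of them shared:
#' ann <- syntheticAnnotation(nGenes = 2, cpgsPerGene = c(3, 8),
#'                            sharedCpGs = 1, unannotatedFraction = 0,
#'                            seed = 1)
#' equivalentCounts(buildGeneIndex(ann))  # 2.5 and 7.5
#' @export
syntheticAnnotation <- function(nGenes = 10000, cpgsPerGene = NULL,
                                medianCpGsPerGene = 20, dispersion = 1.2,
                                multiGeneFraction = 0.09, sharedCpGs = NULL,
                                unannotatedFraction = 0.30, nChroms = 22,
                                seed = 1) {
  if (multiGeneFraction < 0 || multiGeneFraction >= 1)
    stop("'multiGeneFraction' must be in [0, 1)")
  if (unannotatedFraction < 0 || unannotatedFraction >= 1)
    stop("'unannotatedFraction' must be in [0, 1)")
  # keep at least two genes per chromosome so adjacent-pair sharing is
  # feasible for small layouts
  nChroms <- max(1L, min(nChroms, nGenes %/% 2L))
  .withSeed(seed, {
    cnt <- if (is.null(cpgsPerGene)) {
      mu <- .calibrateNBMu(medianCpGsPerGene, dispersion)
      1L + stats::rnbinom(nGenes, size = dispersion, mu = mu)
    } else rep_len(as.integer(cpgsPerGene), nGenes)
    genes <- sprintf("G%05d", seq_len(nGenes))
    chrom <- sort(rep_len(seq_len(nChroms), nGenes))

    # shared CpGs between adjacent same-chromosome gene pairs
    sh <- integer(max(nGenes - 1, 0))
    if (nGenes > 1) {
      pairOK <- chrom[-nGenes] == chrom[-1]
      cap <- pmin(cnt[-nGenes], cnt[-1])
      cap[!pairOK] <- 0L
      target <- if (!is.null(sharedCpGs)) as.integer(sharedCpGs)
                else round(multiGeneFraction / (1 + multiGeneFraction) *
                           sum(cnt))
      if (target > sum(cap))
        stop("infeasible sharing fraction: ", target,
             " shared CpGs requested but adjacent-pair capacity is ",
             sum(cap))
      if (target > 0) {
        sh <- pmin(floor(target * cap / sum(cap)), cap)
        deficit <- target - sum(sh)
        while (deficit > 0) {
          room <- which(sh < cap)
          if (!length(room)) break
          add <- room[seq_len(min(deficit, length(room)))]
          sh[add] <- sh[add] + 1L
          deficit <- target - sum(sh)
        }
        # a gene cannot donate more CpGs than it has to both neighbours
        for (j in seq_len(nGenes)) {
          left <- if (j > 1) sh[j - 1] else 0L
          right <- if (j < nGenes) sh[j] else 0L
          over <- left + right - cnt[j]
          if (over > 0) {
            cut <- min(over, right)
            if (j < nGenes) sh[j] <- sh[j] - cut
            over <- over - cut
            if (over > 0 && j > 1) sh[j - 1] <- sh[j - 1] - min(over, left)
          }
        }
      }
    }
    own <- cnt - c(0L, sh) - c(sh, 0L)

    # distinct annotated CpGs in genomic order: gene j's own CpGs, then the
    # CpGs it shares with gene j+1
    rec <- data.table::data.table(
      g = c(rep(seq_len(nGenes), own),
            rep(seq_len(max(nGenes - 1, 0)), sh)),
      shared = c(rep(FALSE, sum(own)), rep(TRUE, sum(sh))),
      sub = c(rep(1L, sum(own)), rep(2L, sum(sh))))
    data.table::setorder(rec, g, sub)
    nA <- nrow(rec)
    chromA <- chrom[rec$g]

    nU <- round(nA * unannotatedFraction / (1 - unannotatedFraction))
    aPerChrom <- tabulate(chromA, nChroms)
    chromU <- if (nU > 0)
      sample(seq_len(nChroms), nU, replace = TRUE,
             prob = aPerChrom + 1) else integer(0)

    # annotated CpGs keep their genomic rank; unannotated CpGs get a
    # uniform random rank among them
    keyA <- as.numeric(unlist(lapply(aPerChrom, seq_len), use.names = FALSE))
    keyU <- stats::runif(nU, 0, aPerChrom[chromU] + 1)
    all <- data.table::data.table(
      chromIdx = c(chromA, chromU),
      gidx = c(rec$g, rep(NA_integer_, nU)),
      shared = c(rec$shared, rep(FALSE, nU)),
      ordkey = c(keyA, keyU))
    data.table::setorder(all, chromIdx, ordkey)
    all[, "pos" := cumsum(sample(30:3000, .N, replace = TRUE)),
        by = "chromIdx"]
    all[, "cpg_id" := sprintf("cg%07d", seq_len(nrow(all)))]

    sites <- data.frame(cpg_id = all$cpg_id,
                        chrom = paste0("chr", all$chromIdx),
                        pos = all$pos)
    ann <- all[!is.na(all$gidx), ]
    featLabels <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")
    featProbs <- c(0.12, 0.10, 0.08, 0.05, 0.55, 0.10)
    l1 <- data.frame(cpg_id = ann$cpg_id, gene = genes[ann$gidx])
    shr <- ann[ann$shared, ]
    l2 <- data.frame(cpg_id = shr$cpg_id, gene = genes[shr$gidx + 1L])
    links <- rbind(l1, l2)
    links$features <- sample(featLabels, nrow(links), replace = TRUE,
                             prob = featProbs)
    CpGAnnotation(sites, links)
  })
}

#' Generate synthetic gene sets
#'
#' Draws gene sets with log-uniform sizes.  A fraction of the sets is built
#' around a contiguous block of genes in genomic order, emulating
#' functionally related gene clusters (such as the protocadherin family)
#' whose members share multi-gene CpGs; the remaining members, and all
#' members of the other sets, are sampled uniformly.  Clustered sets are
#' what turns shared CpGs into a false-positive mechanism for uncorrected
#' overlap tests.
#'
#' @param x a [CpGAnnotation-class] (gene order inferred from link order,
#'   which is genomic for [syntheticAnnotation()]) or a character vector of
#'   gene ids in genomic order.
#' @param nSets number of sets.
#' @param sizeRange inclusive set size bounds; sizes are log-uniform.
#' @param clusteredFraction fraction of sets containing a genomic block.
#' @param blockFraction fraction of a clustered set's genes taken from the
#'   block.
#' @param seed integer seed.
#' @return a [GeneSetCollection-class] with ids \code{SET0001}, ...
#' @export
syntheticGeneSets <- function(x, nSets = 300, sizeRange = c(10, 500),
                              clusteredFraction = 0.3, blockFraction = 0.5,
                              seed = 1) {
  genes <- if (is(x, "CpGAnnotation")) unique(x@links$gene)
           else as.character(x)
  nG <- length(genes)
  if (nG < 2) stop("need at least two genes to build sets")
  sizeRange <- pmin(pmax(sizeRange, 1), nG)
  .withSeed(seed, {
    sizes <- pmin(pmax(round(exp(stats::runif(
      nSets, log(sizeRange[1]), log(sizeRange[2])))), sizeRange[1]),
      sizeRange[2])
    clustered <- seq_len(nSets) <= round(clusteredFraction * nSets)
    sets <- lapply(seq_len(nSets), function(i) {
      sz <- sizes[i]
      if (clustered[i]) {
        b <- min(max(2, round(blockFraction * sz)), sz)
        start <- sample.int(nG - b + 1, 1)
        block <- genes[start:(start + b - 1)]
        rest <- sample(setdiff(genes, block), sz - b)
        c(block, rest)
      } else sample(genes, sz)
    })
    GeneSetCollection(setNames(sets, sprintf("SET%04d", seq_len(nSets))),
                      descriptions = ifelse(clustered, "clustered",
                                            "random"))
  })
}

#' Sample a null set of significant CpGs
#'
#' Uniform sample without replacement over all CpGs on the array —
#' annotated or not — designating them "significant" under the null.
#'
#' @param annot a [CpGAnnotation-class].
#' @param nSig number of CpGs to draw.
#' @param seed integer seed.
#' @return character vector of CpG ids.
#' @export
sampleNullCpGs <- function(annot, nSig, seed = 1) {
  ids <- cpgIds(annot)
  if (nSig > length(ids))
    stop("'nSig' exceeds the number of CpGs on the array (",
         length(ids), ")")
  .withSeed(seed, sample(ids, nSig))
}

#' Null two-group comparison with top-ranked CpG selection
#'
#' Emulates selecting the "most differentially methylated" CpGs from a
#' comparison of two groups drawn from the same distribution: every sample's
#' value at CpG \eqn{i} comes from one shared per-CpG normal model (no group
#' effect), CpGs are ranked by the magnitude of the ordinary two-sample
#' t-statistic, and the top \code{topN} are returned as the significant
#' set.  Because the null is exact, the selection is uniform over CpGs in
#' distribution, but mirrors the ranked-input workflow used on real data.
#'
#' @param annot a [CpGAnnotation-class].
#' @param nPerGroup samples per group (>= 2).
#' @param topN number of top-ranked CpGs to return.
#' @param seed integer seed.
#' @return character vector of \code{topN} CpG ids.
#' @export
simulateNullTwoGroup <- function(annot, nPerGroup = 10, topN = 1000,
                                 seed = 1) {
  if (nPerGroup < 2) stop("'nPerGroup' must be at least 2")
  ids <- cpgIds(annot)
  nc <- length(ids)
  if (topN > nc) stop("'topN' exceeds the number of CpGs (", nc, ")")
  .withSeed(seed, {
    mu <- stats::rnorm(nc)
    sdv <- 0.05 * exp(0.3 * stats::rnorm(nc))
    g <- 2L * nPerGroup
    X <- matrix(stats::rnorm(nc * g), nc, g) * sdv + mu
    i1 <- seq_len(nPerGroup)
    m1 <- rowMeans(X[, i1, drop = FALSE])
    m2 <- rowMeans(X[, -i1, drop = FALSE])
    ss <- rowSums((X[, i1, drop = FALSE] - m1)^2) +
      rowSums((X[, -i1, drop = FALSE] - m2)^2)
    tstat <- (m1 - m2) / sqrt(ss / (g - 2) * (2 / nPerGroup))
    ids[order(-abs(tstat))[seq_len(topN)]]
  })
}

#' Null type-I error experiment
#'
#' For each significant-set size and replicate, draws a uniform random CpG
#' set with [sampleNullCpGs()], runs the requested test variants against
#' the gene set collection, and records the fraction of sets reaching
#' \code{p < alpha}.  Under the null a calibrated test keeps this fraction
#' at or below \code{alpha}; the uncorrected hypergeometric test does not,
#' and its excess grows with the significant-set size.
#'
#' @param annot a [CpGAnnotation-class].
#' @param sets a [GeneSetCollection-class].
#' @param sizes significant-set sizes to simulate.
#' @param reps replicates per size.
#' @param alpha nominal significance threshold.
#' @param methods test variants to evaluate (see [testGeneSets()]).
#' @param span PWF smoother span.
#' @param seed integer seed for the whole experiment.
#' @return list with \code{replicates} (data.frame: \code{size},
#'   \code{rep}, \code{method}, \code{fracSig}) and \code{summary}
#'   (data.frame per size and method: mean, median, q25, q75 of the
#'   fraction).
#' @export
typeIErrorExperiment <- function(annot, sets,
                                 sizes = c(50, 100, 500, 1000, 5000, 10000),
                                 reps = 100, alpha = 0.05,
                                 methods = c("HGT", "HGT-mod", "GOmeth"),
                                 span = 0.5, seed = 1) {
  methods <- match.arg(methods, c("HGT", "HGT-mod", "GOmeth"),
                       several.ok = TRUE)
  ids <- cpgIds(annot)
  if (max(sizes) > length(ids))
    stop("largest size exceeds the number of CpGs on the array")
  prep <- .prepareEnrichment(annot, sets)
  rows <- vector("list", length(sizes) * reps)
  k <- 0L
  .withSeed(seed, {
    for (size in sizes) {
      for (r in seq_len(reps)) {
        sig <- sample(ids, size)
        res <- .testPrepared(prep, sig, methods = methods, span = span)
        k <- k + 1L
        rows[[k]] <- data.frame(
          size = size, rep = r, method = methods,
          fracSig = vapply(methods, function(m) mean(res[[m]]$p < alpha),
                           numeric(1)))
      }
    }
  })
  replicates <- do.call(rbind, rows)
  rownames(replicates) <- NULL
  dt <- data.table::as.data.table(replicates)
  summary <- as.data.frame(dt[, list(
    mean = mean(fracSig), median = stats::median(fracSig),
    q25 = stats::quantile(fracSig, 0.25, names = FALSE),
    q75 = stats::quantile(fracSig, 0.75, names = FALSE)),
    by = c("size", "method")])
  list(replicates = replicates, summary = summary)
}
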