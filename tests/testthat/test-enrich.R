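test_that("gene scores cap at one and weight shared CpGs fractionally", {
  ann <- tinyAnnotation()
  idx <- buildGeneIndex(ann)
  # one significant private CpG: S = 1
  S <- geneScores("cg01", idx)
  expect_equal(S[["GENEA"]], 1)
  expect_equal(S[["GENEB"]], 0)
  # only significant CpG shared between two genes: S = 0.5 each
  S2 <- geneScores("cg02", idx)
  expect_equal(S2[["GENEA"]], 0.5)
  expect_equal(S2[["GENEB"]], 0.5)
  # several significant CpGs with summed weight above one: capped
  S3 <- geneScores(c("cg01", "cg02", "cg03"), idx)
  expect_equal(S3[["GENEA"]], 1)   # 1 + 0.5 -> capped
  expect_equal(S3[["GENEB"]], 1)   # 0.5 + 1 -> capped
  expect_true(all(S3 >= 0 & S3 <= 1))
  # unannotated significant CpGs are counted but score nothing
  S4 <- geneScores(c("cg01", "cg04", "nonexistent"), idx)
  expect_equal(attr(S4, "nUnannotated"), 2)
  expect_warning(geneScores(character(0), idx), "empty")
})

test_that("PWF smoothing preserves constants and matches direct kernel arithmetic", {
  ann <- tinyAnnotation()
  idx <- buildGeneIndex(ann)
  none <- suppressWarnings(geneScores(character(0), idx))
  expect_true(all(estimatePWF(none, idx)$pwf == 0))
  allSig <- geneScores(c("cg01", "cg02", "cg03", "cg05", "cg06", "cg07"),
                       idx)
  expect_true(all(estimatePWF(allSig, idx)$pwf == 1))
  expect_error(estimatePWF(allSig, idx, span = 0), "span")
  expect_error(estimatePWF(allSig, idx, span = 1.5), "span")

  # five genes, single spike, full-width window: compare against explicit
  # tricube weights
  five <- CpGAnnotation(
    data.frame(cpg_id = sprintf("cg%d", 1:15), chrom = "chr1", pos = 1:15),
    data.frame(cpg_id = sprintf("cg%d", 1:15),
               gene = rep(sprintf("G%d", 1:5), times = c(1, 2, 3, 4, 5)),
               features = "Body"))
  idx5 <- buildGeneIndex(five)
  # G3 (the middle gene once ordered by count) carries the only signal
  S <- geneScores("cg4", idx5)   # cg4 belongs to G3
  pwf <- estimatePWF(S, idx5, span = 1)
  expect_equal(pwf$dm, c(0, 0, 1, 0, 0))
  expect_equal(pwf$pwf, tricubeOracle(c(0, 0, 1, 0, 0)), tolerance = 1e-12)
})

test_that("PWF ordering uses equivalent or raw counts as requested", {
  # shared CpGs push equivalent counts below raw counts and can reorder
  ann <- syntheticAnnotation(nGenes = 50, multiGeneFraction = 0.2,
                             seed = 5)
  idx <- buildGeneIndex(ann)
  S <- geneScores(sampleNullCpGs(ann, 100, seed = 6), idx)
  pe <- estimatePWF(S, idx, biasCounts = "equivalent")
  pr <- estimatePWF(S, idx, biasCounts = "raw")
  expect_equal(sort(pe$gene), sort(pr$gene))
  expect_true(all(diff(pe$N) >= 0))
  expect_true(all(diff(pr$N) >= 0))
  expect_true(all(pr$N == round(pr$N)))   # raw counts are integers
})

test_that("set odds are PWF mean ratios with guarded degenerate cases", {
  pwf <- data.frame(gene = c("A", "B", "C", "D"), N = 1:4,
                    dm = c(0, 0, 1, 1), pwf = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(setOdds(pwf, c("A", "B")), (0.15) / (0.35))
  # constant PWF: odds exactly 1
  pwfc <- transform(pwf, pwf = 0.25)
  expect_equal(setOdds(pwfc, c("A", "C")), 1)
  # set holding the largest PWF values beats the rest
  expect_gt(setOdds(pwf, c("C", "D")), 1)
  expect_error(setOdds(pwf, c("zz")), "intersect")
  expect_error(setOdds(pwf, pwf$gene), "whole")
  pwf0 <- transform(pwf, pwf = c(0.5, 0.5, 0, 0))
  expect_warning(o <- setOdds(pwf0, c("A", "B")), "capped")
  expect_equal(o, 1e6)
})

test_that("enrichment statistic sums capped scores over the set", {
  S <- c(A = 1, B = 1, C = 0, D = 0.5)
  expect_equal(enrichmentScore(S, c("A", "B", "C")), 2)
  expect_equal(enrichmentScore(S, character(0)), 0)
  # 22 genes sharing one significant CpG contribute 22 * (1/22) = 1
  fx <- clusterFixture()
  idx <- buildGeneIndex(fx$annotation)
  S22 <- geneScores(fx$shared, idx)
  expect_equal(enrichmentScore(S22, fx$clusterGenes), 1)
})

test_that("p-value adjustment matches the textbook procedures", {
  expect_equal(adjustPValues(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjustPValues(0.2, "BH"), 0.2)
  expect_equal(adjustPValues(c(1, 1), "Holm"), c(1, 1))
  expect_error(adjustPValues(c(0.5, 1.2)), "0, 1")
})

test_that("the hypergeometric variant matches the textbook tail when no bias exists", {
  ann <- noBiasAnnotation(120)
  set.seed(42)
  sets <- GeneSetCollection(list(
    S1 = sample(sprintf("G%04d", 1:120), 15),
    S2 = sample(sprintf("G%04d", 1:120), 30),
    S3 = sample(sprintf("G%04d", 1:120), 8)))
  sig <- sample(cpgIds(ann), 25)
  res <- testGeneSets(sig, ann, sets, method = "HGT")
  n <- attr(res, "nSigGenes")
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p[i],
                 phyper(res$n_sig_genes[i] - 1, res$J[i], 120 - res$J[i],
                        n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("methods coincide when their corrections have nothing to correct", {
  ann <- noBiasAnnotation(60)
  sets <- GeneSetCollection(list(S1 = sprintf("G%04d", 1:10),
                                 S2 = sprintf("G%04d", 25:44)))
  # no multi-gene CpGs: weighted and integer counts agree for any input
  sig <- sprintf("cg%04d", c(1:5, 30:37))
  rG <- testGeneSets(sig, ann, sets, method = "GOmeth")
  rM <- testGeneSets(sig, ann, sets, method = "HGT-mod")
  expect_equal(rG$ES, rM$ES)
  expect_equal(rG$n_sig_genes, rM$n_sig_genes)
  # every gene significant: the PWF is constant 1, so all three variants
  # collapse onto the central hypergeometric
  allSig <- cpgIds(ann)
  ps <- lapply(c("GOmeth", "HGT-mod", "HGT"), function(m)
    testGeneSets(allSig, ann, sets, method = m)$p)
  expect_equal(ps[[1]], ps[[2]], tolerance = 1e-10)
  expect_equal(ps[[1]], ps[[3]], tolerance = 1e-10)
})

test_that("annotation outside the tested sets cannot move a set's statistic", {
  ann <- tinyAnnotation()
  sets <- GeneSetCollection(list(S1 = c("GENEA", "GENEB")))
  sig <- c("cg01", "cg02")
  es0 <- testGeneSets(sig, ann, sets, method = "GOmeth")$ES
  # add a nonsignificant CpG to GENED (outside S1)
  sites <- rbind(cpgSites(ann),
                 data.frame(cpg_id = "cg99", chrom = "chr2", pos = 999))
  links <- rbind(geneLinks(ann),
                 data.frame(cpg_id = "cg99", gene = "GENED",
                            features = "Body"))
  ann2 <- CpGAnnotation(sites, links)
  es1 <- testGeneSets(sig, ann2, sets, method = "GOmeth")$ES
  expect_equal(es1, es0)
})

test_that("GOmeth with no signal returns p = 1 and results sort stably", {
  ann <- tinyAnnotation()
  sets <- GeneSetCollection(list(
    B1 = c("GENEA", "GENEB"), A1 = c("GENEC", "GENED")))
  res <- suppressWarnings(testGeneSets("cg08", ann, sets,
                                       method = "GOmeth"))
  expect_true(all(res$p == 1))
  # equal p-values break ties by set id
  expect_equal(res$set_id, c("A1", "B1"))
  expect_true(all(res$ES <= res$J))
})

test_that("a single shared CpG cannot drive a cluster set to significance under GOmeth", {
  fx <- clusterFixture()
  rH <- testGeneSets(fx$shared, fx$annotation, fx$sets, method = "HGT")
  rG <- testGeneSets(fx$shared, fx$annotation, fx$sets, method = "GOmeth")
  h <- rH[rH$set_id == "CLUSTER", ]
  g <- rG[rG$set_id == "CLUSTER", ]
  # naive overlap counts all 22 genes; the weighted statistic counts 1
  expect_equal(h$n_sig_genes, 22)
  expect_equal(g$ES, 1)
  expect_equal(floor(g$ES), 1)
  expect_gt(g$p, h$p)
  expect_lt(h$p, 1e-6)
})
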