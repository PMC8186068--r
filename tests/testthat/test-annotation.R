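test_that("annotation parsing handles single links, transcript dedup and unannotated probes", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cpg_id,chrom,pos,genes,features",
               "cg0001,chr1,100,GENEA,Body",
               "cg0002,chr1,200,GENEA;GENEA;GENEB,TSS200;Body;Body",
               "cg0003,chr1,300,,"), tf)
  ann <- readAnnotation(tf)
  expect_equal(nCpGs(ann), 3)
  l <- geneLinks(ann)
  expect_equal(l$gene[l$cpg_id == "cg0001"], "GENEA")
  # GENEA listed for two transcripts collapses to one link with the union
  # of its labels; GENEB keeps its single label
  la <- l[l$cpg_id == "cg0002", ]
  expect_setequal(la$gene, c("GENEA", "GENEB"))
  expect_setequal(strsplit(la$features[la$gene == "GENEA"], ";")[[1]],
                  c("TSS200", "Body"))
  expect_equal(la$features[la$gene == "GENEB"], "Body")
  # cg0003 stays on the array with no links
  expect_true("cg0003" %in% cpgIds(ann))
  expect_false("cg0003" %in% l$cpg_id)
})

test_that("annotation format and validation errors are reported", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cpg_id,chrom,pos,genes",
               "cg0001,chr1,100,GENEA"), tf)
  expect_error(readAnnotation(tf), "features")
  writeLines(c("cpg_id,chrom,pos,genes,features",
               "cg0001,chr1,100,GENEA,Body",
               "cg0001,chr1,200,GENEB,Body"), tf)
  expect_error(readAnnotation(tf), "duplicate CpG")
  writeLines(c("cpg_id,chrom,pos,genes,features",
               "cg0001,chr1,100,GENEA;GENEB,Body"), tf)
  expect_error(readAnnotation(tf), "mismatch")
})

test_that("annotation round-trips through its CSV writer", {
  ann <- tinyAnnotation()
  tf <- withr::local_tempfile(fileext = ".csv")
  writeAnnotation(ann, tf)
  back <- readAnnotation(tf)
  expect_equal(cpgSites(back), cpgSites(ann))
  ord <- function(l) l[order(l$cpg_id, l$gene), ]
  lb <- ord(geneLinks(back))
  la <- ord(geneLinks(ann))
  rownames(lb) <- rownames(la) <- NULL
  expect_equal(lb, la)
})

test_that("multi-gene weights are reciprocal unique gene counts", {
  ann <- tinyAnnotation()
  w <- cpgWeights(ann)
  expect_equal(w[["cg01"]], 1)      # single gene
  expect_equal(w[["cg02"]], 0.5)    # shared between two genes
  expect_false("cg04" %in% names(w))  # unannotated absent
  # a CpG annotated to 22 genes gets weight 1/22
  many <- CpGAnnotation(
    data.frame(cpg_id = "cgX", chrom = "chr1", pos = 1),
    data.frame(cpg_id = "cgX", gene = sprintf("P%02d", 1:22),
               features = "Body"))
  expect_equal(unname(cpgWeights(many)), 1 / 22)
})

test_that("equivalent CpG counts sum weights per gene", {
  ann <- tinyAnnotation()
  idx <- buildGeneIndex(ann)
  N <- equivalentCounts(idx)
  expect_equal(N[["GENEA"]], 1.5)   # one private + half a shared CpG
  expect_equal(N[["GENEC"]], 2)     # two private CpGs
  # gene with 3 CpGs sharing one with an 8-CpG gene: N = 2.5 / 7.5
  fig <- syntheticAnnotation(nGenes = 2, cpgsPerGene = c(3, 8),
                             sharedCpGs = 1, unannotatedFraction = 0,
                             seed = 1)
  expect_equal(unname(sort(equivalentCounts(buildGeneIndex(fig)))),
               c(2.5, 7.5))
  # gene whose 4 CpGs are all shared with one other gene: N = 2
  sh <- CpGAnnotation(
    data.frame(cpg_id = sprintf("cg%d", 1:4), chrom = "chr1", pos = 1:4),
    data.frame(cpg_id = rep(sprintf("cg%d", 1:4), each = 2),
               gene = rep(c("A", "B"), 4), features = "Body"))
  expect_equal(unname(equivalentCounts(buildGeneIndex(sh))), c(2, 2))
})

test_that("weight mass is conserved and the index ignores row order", {
  ann <- syntheticAnnotation(nGenes = 400, seed = 11)
  idx <- buildGeneIndex(ann)
  # every gene-annotated CpG distributes exactly weight 1 across its genes
  expect_equal(sum(equivalentCounts(idx)),
               length(unique(geneLinks(ann)$cpg_id)))
  # permuting site and link rows changes nothing
  set.seed(1)
  shuf <- CpGAnnotation(cpgSites(ann)[sample(nCpGs(ann)), ],
                        geneLinks(ann)[sample(nrow(geneLinks(ann))), ])
  idx2 <- buildGeneIndex(shuf)
  expect_equal(idx2@genes, idx@genes)
})

test_that("feature restriction drops links, recomputes weights upward and warns on unknown labels", {
  ann <- tinyAnnotation()
  # cg02 links (GENEA, Body), (GENEB, Body); restricting to TSS labels
  # keeps only TSS-linked CpGs
  r <- restrictByFeature(ann, c("TSS200", "TSS1500"))
  l <- geneLinks(r)
  expect_setequal(l$cpg_id, c("cg01", "cg05"))
  # restriction to Body: cg02 keeps both genes, weight still 0.5; cg01
  # loses its only link
  rb <- restrictByFeature(ann, "Body")
  wb <- cpgWeights(rb)
  expect_equal(wb[["cg02"]], 0.5)
  expect_false("cg01" %in% names(wb))
  # retained CpG weights never decrease
  w0 <- cpgWeights(ann)
  shared <- intersect(names(w0), names(wb))
  expect_true(all(wb[shared] >= w0[shared]))
  # restricting to every label present is the identity on links
  allLabs <- unique(unlist(strsplit(geneLinks(ann)$features, ";")))
  expect_equal(nrow(geneLinks(restrictByFeature(ann, allLabs))),
               nrow(geneLinks(ann)))
  expect_warning(restrictByFeature(ann, c("Body", "NoSuchLabel")),
                 "NoSuchLabel")
  # restriction matching nothing empties the universe; testing refuses
  empty <- suppressWarnings(restrictByFeature(ann, "ExonBnd"))
  expect_equal(nrow(geneLinks(empty)), 0)
  sets <- GeneSetCollection(list(S1 = c("GENEA", "GENEB")))
  expect_error(testGeneSets("cg01", empty, sets), "universe")
})

test_that("composition summary reports the bias-relevant fractions", {
  two <- CpGAnnotation(
    data.frame(cpg_id = sprintf("cg%02d", 1:10), chrom = "chr1",
               pos = 1:10),
    data.frame(cpg_id = sprintf("cg%02d", 1:10),
               gene = rep(c("A", "B"), each = 5), features = "Body"))
  cs <- compositionSummary(two)
  expect_equal(cs$medianCpGsPerGene, 5)
  expect_equal(cs$fracMultiGene, 0)
  expect_equal(cs$fracAnnotated, 1)
  # the 3+8-CpG two-gene layout has 10 distinct annotated CpGs, 1 shared
  fig <- syntheticAnnotation(nGenes = 2, cpgsPerGene = c(3, 8),
                             sharedCpGs = 1, unannotatedFraction = 0,
                             seed = 1)
  expect_equal(compositionSummary(fig)$fracMultiGene, 1 / 10)
  # degenerate empty table
  empty <- CpGAnnotation(data.frame(cpg_id = character(0),
                                    chrom = character(0),
                                    pos = integer(0)))
  cs0 <- compositionSummary(empty)
  expect_equal(cs0$nGenes, 0)
  expect_true(is.na(cs0$medianCpGsPerGene))
})
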