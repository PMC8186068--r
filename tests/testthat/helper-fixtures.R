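# Fixtures and independent oracles shared across the suite.
# Everything is built in code; nothing is read from disk unless a test
# writes it first.

# Hand-built annotation: 4 genes on two chromosomes, one CpG shared by
# GENEA/GENEB, one unannotated CpG.
tinyAnnotation <- function() {
  sites <- data.frame(
    cpg_id = sprintf("cg%02d", 1:8),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr2",
              "chr2"),
    pos = c(100, 200, 300, 400, 150, 250, 350, 450))
  links <- data.frame(
    cpg_id = c("cg01", "cg02", "cg02", "cg03", "cg05", "cg06", "cg07"),
    gene = c("GENEA", "GENEA", "GENEB", "GENEB", "GENEC", "GENEC",
             "GENED"),
    features = c("TSS200", "Body", "Body", "Body", "TSS1500", "Body",
                 "5'UTR"))
  CpGAnnotation(sites, links)   # cg04, cg08 unannotated
}

# The gene-cluster scenario: one CpG annotated to all 22 clustered genes
# (each also carrying a few private CpGs), plus background genes, and one
# gene set holding exactly the cluster.
clusterFixture <- function(nCluster = 22, nBackground = 200,
                           privateCpGs = 3, backgroundCpGs = 5) {
  clusterGenes <- sprintf("CL%02d", seq_len(nCluster))
  bgGenes <- sprintf("BG%03d", seq_len(nBackground))
  sites <- list()
  links <- list()
  k <- 0
  addCpG <- function(chrom, pos, genes) {
    k <<- k + 1
    id <- sprintf("cg%05d", k)
    sites[[k]] <<- data.frame(cpg_id = id, chrom = chrom, pos = pos)
    if (length(genes))
      links[[k]] <<- data.frame(cpg_id = id, gene = genes, features = "Body")
    id
  }
  pos <- 0
  sharedId <- addCpG("chr1", pos <- pos + 100, clusterGenes)
  for (g in clusterGenes)
    for (i in seq_len(privateCpGs))
      addCpG("chr1", pos <- pos + 100, g)
  for (g in bgGenes)
    for (i in seq_len(backgroundCpGs))
      addCpG("chr2", pos <- pos + 100, g)
  ann <- CpGAnnotation(do.call(rbind, sites), do.call(rbind, links))
  sets <- GeneSetCollection(list(
    CLUSTER = clusterGenes,
    RANDOM1 = bgGenes[1:30],
    RANDOM2 = bgGenes[31:80]))
  list(annotation = ann, sets = sets, shared = sharedId,
       clusterGenes = clusterGenes)
}

# Annotation in which every gene owns exactly one CpG (no probe-number or
# multi-gene bias possible).
noBiasAnnotation <- function(nGenes = 200) {
  sites <- data.frame(cpg_id = sprintf("cg%04d", seq_len(nGenes)),
                      chrom = "chr1", pos = seq_len(nGenes) * 100)
  links <- data.frame(cpg_id = sites$cpg_id,
                      gene = sprintf("G%04d", seq_len(nGenes)),
                      features = "Body")
  CpGAnnotation(sites, links)
}

# Direct tricube-kernel arithmetic for a full-width window over a short
# vector: weights (1 - |u|^3)^3 at u = seq(-1, 1, length = w) * w/(w + 1),
# normalised, with edge truncation and renormalisation.
tricubeOracle <- function(x, width = length(x)) {
  n <- length(x)
  u <- seq(-1, 1, length.out = width) * width / (width + 1)
  wt <- (1 - abs(u)^3)^3
  wt <- wt / sum(wt)
  half <- (width - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    js <- (i - half):(i + half)
    ok <- js >= 1 & js <= n
    out[i] <- sum(x[js[ok]] * wt[ok]) / sum(wt[ok])
  }
  out
}

# Enumerated full Wallenius pmf (oracle route) for tail cross-checks.
walleniusPmfOracle <- function(m1, m2, n, odds) {
  methylORA:::.walleniusPmfEnum(m1, m2, n, odds)
}
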