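# Shared fixtures, built in code at test time.

# A small valid summary-statistics data.frame; z/p derived from beta/se so
# all record invariants hold by construction.
makeSumstatsDF <- function(n = 20, seed = 1, chr = "1",
                           alleles = c("A", "C")) {
  set.seed(seed)
  beta <- rnorm(n, 0, 0.1)
  se <- runif(n, 0.02, 0.08)
  z <- beta / se
  data.frame(snp = sprintf("rs%03d", seq_len(n)),
             chr = chr, bp = 1000L * seq_len(n),
             a1 = alleles[1], a2 = alleles[2],
             beta = beta, se = se, z = z, p = zToP(z),
             n = 500L, stringsAsFactors = FALSE)
}

makeSumstats <- function(n = 20, seed = 1, traitName = "t1",
                         traitKind = "quantitative", ...) {
  SummaryStats(makeSumstatsDF(n = n, seed = seed, ...),
               traitMeta(traitName, traitKind))
}

# Gene intervals as a GRanges, 1-based inclusive.
makeGenes <- function(starts, ends, ids = sprintf("G%02d", seq_along(starts)),
                      chr = "1") {
  gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(starts, ends))
  S4Vectors::mcols(gr)$gene_id <- ids
  gr
}

# Aligned pair of SummaryStats over the same variants with prescribed
# z-scores (se = 1, beta = z), ready for runJointScan.
makeAlignedPair <- function(z1, z2, chr = "1", bpStep = 1000L) {
  n <- length(z1)
  base <- data.frame(snp = sprintf("rs%05d", seq_len(n)),
                     chr = chr, bp = bpStep * seq_len(n),
                     a1 = "A", a2 = "C", se = 1, n = 1000L,
                     stringsAsFactors = FALSE)
  d1 <- base; d1$beta <- z1; d1$z <- z1; d1$p <- zToP(z1)
  d2 <- base; d2$beta <- z2; d2$z <- z2; d2$p <- zToP(z2)
  list(SummaryStats(d1, traitMeta("t1", "quantitative")),
       SummaryStats(d2, traitMeta("t2", "quantitative")))
}
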