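# Synthetic cohort generator: determinism, calibration, architecture.

test_that("invalid configurations fail before any sampling", {
  expect_error(simConfig(nSharedCausal = 80, nCausalA = 60, nCausalB = 60,
                         nVariants = 100),
               "nSharedCausal")
  expect_error(simConfig(prevalence = 1.2), "prevalence")
  expect_error(simConfig(mafRange = c(0.2, 0.6)), "mafRange")
})

test_that("identical seeds give bit-identical cohorts and annotations", {
  cfg <- simConfig(nIndividuals = 150, nVariants = 80, nCausalA = 20,
                   nCausalB = 20, nSharedCausal = 10, nGenes = 10,
                   nPathways = 5, seed = 99)
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_identical(dosages(c1), dosages(c2))
  expect_identical(phenotypes(c1), phenotypes(c2))
  expect_identical(truthTable(c1), truthTable(c2))
  a1 <- simulateAnnotation(cfg)
  a2 <- simulateAnnotation(cfg)
  expect_identical(a1$pathways, a2$pathways)
  expect_identical(a1$ppi, a2$ppi)
  expect_identical(S4Vectors::mcols(a1$genes)$gene_id,
                   S4Vectors::mcols(a2$genes)$gene_id)
  # different cohort ids share the architecture but not the data
  c3 <- simulateCohort(cfg, cohortId = 1)
  expect_identical(truthTable(c3)$effectA, truthTable(c1)$effectA)
  expect_false(identical(dosages(c3), dosages(c1)))
})

test_that("dosage frequencies and case fraction match their targets", {
  cfg <- simConfig(nIndividuals = 3000, nVariants = 200, seed = 17)
  coh <- simulateCohort(cfg)
  maf <- variantTable(coh)$maf
  obs <- colMeans(dosages(coh)) / 2
  se <- sqrt(maf * (1 - maf) / (2 * 3000))
  expect_gt(mean(abs(obs - maf) <= 3 * se), 0.98)
  # prevalence 0.5 with zero genetic effect: symmetric threshold
  cfg2 <- simConfig(nIndividuals = 4000, nVariants = 50, nCausalA = 0,
                    nCausalB = 0, nSharedCausal = 0, prevalence = 0.5,
                    covariateEffects = c(0, 0, 0), seed = 18)
  coh2 <- simulateCohort(cfg2)
  caseFrac <- mean(phenotypes(coh2)$pheno_bin)
  expect_lt(abs(caseFrac - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("perfectly correlated shared effects are exactly proportional", {
  cfg <- simConfig(nVariants = 100, nCausalA = 20, nCausalB = 20,
                   nSharedCausal = 10, sharedEffectCorr = 1,
                   effectSdA = 0.1, effectSdB = 0.1, seed = 5)
  arch <- simulateArchitecture(cfg)
  sh <- arch$shared
  expect_equal(arch$effectA[sh], arch$effectB[sh], tolerance = 1e-12)
  # unequal SDs: proportional with ratio sdB/sdA
  cfg2 <- simConfig(nVariants = 100, nCausalA = 20, nCausalB = 20,
                    nSharedCausal = 10, sharedEffectCorr = 1,
                    effectSdA = 0.1, effectSdB = 0.3, seed = 5)
  arch2 <- simulateArchitecture(cfg2)
  expect_equal(arch2$effectB[arch2$shared] / arch2$effectA[arch2$shared],
               rep(3, 10), tolerance = 1e-9)
})

test_that("null scans are calibrated: uniform p and nominal type-I error", {
  # no causal variants anywhere: per-variant scan P-values are uniform
  cfg <- simConfig(nIndividuals = 400, nVariants = 5000, nCausalA = 0,
                   nCausalB = 0, nSharedCausal = 0,
                   covariateEffects = c(0.2, 0.01, 0.1), seed = 23)
  coh <- simulateCohort(cfg)
  ss <- scanSummaryStats(coh, "quant")
  p <- statsTable(ss)$p
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  # fraction below 0.05 within 3 binomial SEs of 0.05
  frac <- mean(p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 5000))
})

test_that("a noise-free single-variant fit recovers the slope exactly", {
  cfg <- simConfig(nIndividuals = 6, nVariants = 1, nCausalA = 0,
                   nCausalB = 0, nSharedCausal = 0, seed = 3)
  coh <- simulateCohort(cfg)
  # overwrite with the analytic fixture: phenotype equal to dosage
  coh@dosages <- matrix(c(0L, 1L, 2L, 0L, 1L, 2L), ncol = 1,
                        dimnames = list(rownames(coh@dosages), "rs00001"))
  coh@phenoQuant <- as.numeric(coh@dosages[, 1])
  ss <- scanSummaryStats(coh, "quant", covariates = FALSE)
  expect_equal(statsTable(ss)$beta, 1, tolerance = 1e-10)
  expect_equal(statsTable(ss)$se, 0, tolerance = 1e-8)
})

test_that("monomorphic variants are flagged null records", {
  cfg <- simConfig(nIndividuals = 50, nVariants = 5, nCausalA = 0,
                   nCausalB = 0, nSharedCausal = 0, seed = 4)
  coh <- simulateCohort(cfg)
  coh@dosages[, 2] <- 0L
  ss <- scanSummaryStats(coh, "quant")
  row <- statsTable(ss)[statsTable(ss)$snp == "rs00002", ]
  expect_true(row$monomorphic)
  expect_identical(row$z, 0)
  expect_identical(row$p, 1)
})

test_that("logistic scan matches glm() on a single variant", {
  cfg <- simConfig(nIndividuals = 500, nVariants = 20, nCausalA = 5,
                   nCausalB = 5, nSharedCausal = 3, seed = 29)
  coh <- simulateCohort(cfg)
  ss <- scanSummaryStats(coh, "binary")
  j <- 7
  dat <- data.frame(y = phenotypes(coh)$pheno_bin, g = dosages(coh)[, j],
                    sex = phenotypes(coh)$sex, age = phenotypes(coh)$age,
                    study = factor(phenotypes(coh)$study))
  fit <- glm(y ~ sex + age + study + g, data = dat, family = binomial())
  co <- summary(fit)$coefficients["g", ]
  row <- statsTable(ss)[j, ]
  expect_equal(row$beta, unname(co[1]), tolerance = 1e-8)
  expect_equal(row$se, unname(co[2]), tolerance = 1e-8)
})

test_that("realized liability-scale heritability matches theory", {
  h2real <- h2theory <- numeric(10)
  for (s in 1:10) {
    cfg <- simConfig(nIndividuals = 20000, nVariants = 300, nCausalA = 60,
                     nCausalB = 60, nSharedCausal = 30, seed = 300 + s)
    arch <- simulateArchitecture(cfg)
    coh <- simulateCohort(cfg, arch = arch)
    maf <- arch$variants$maf
    varG <- sum(2 * maf * (1 - maf) * arch$effectA^2)
    h2theory[s] <- varG / (varG + 1)
    Gc <- sweep(dosages(coh), 2, 2 * maf)
    gA <- drop(Gc %*% arch$effectA)
    h2real[s] <- var(gA) / (var(gA) + 1)
  }
  expect_lt(abs(mean(h2real) - mean(h2theory)) / mean(h2theory), 0.10)
})

test_that("a strong shared causal variant dominates the joint overlap scan", {
  # effect 0.5 SD at MAF 0.3, n = 2000: smallest joint overlap P in
  # >= 95% of 20 seeded replicates
  hits <- 0L
  for (s in 1:20) {
    cfg <- simConfig(nIndividuals = 2000, nVariants = 120, nCausalA = 1,
                     nCausalB = 1, nSharedCausal = 1, seed = 5000 + s)
    arch <- simulateArchitecture(cfg)
    j <- arch$shared[1]
    arch$variants$maf[j] <- 0.3
    arch$effectA[j] <- 0.5
    arch$effectB[j] <- 0.5
    coh <- simulateCohort(cfg, arch = arch)
    sb <- scanSummaryStats(coh, "binary", "A")
    coh2 <- simulateCohort(cfg, cohortId = 1, arch = arch)
    sq <- scanSummaryStats(coh2, "quant", "B")
    h <- harmonizeSumstats(sb, sq)
    scan <- runJointScan(list(h$a, h$b))
    res <- statsTable(scan)
    if (res$snp[which.min(res$joint_p)] == arch$variants$snp[j])
      hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("annotation structure: coverage, fit errors, empty PPI", {
  cfg <- simConfig(nIndividuals = 50, nVariants = 100, nCausalA = 10,
                   nCausalB = 10, nSharedCausal = 5, nGenes = 76,
                   nPathways = 8, ppiEdgeProb = 0, seed = 33)
  # gaps forced to 0 with genes tiling past the last variant: full coverage
  ann <- simulateAnnotation(cfg, gapRange = c(0, 0),
                            geneLengthRange = c(20000, 20000))
  arch <- simulateArchitecture(cfg)
  mapped <- mapSnpToGene(arch$variants$chr, arch$variants$bp, ann$genes,
                         flank = 0)
  expect_false(any(is.na(mapped)))
  # requesting more genes than fit errors
  cfgBig <- simConfig(nIndividuals = 50, nVariants = 20, nCausalA = 5,
                      nCausalB = 5, nSharedCausal = 2, nGenes = 100,
                      seed = 33)
  expect_error(simulateAnnotation(cfgBig, gapRange = c(50000, 50000)),
               "more genes")
  # ppiEdgeProb = 0 and no within-pathway bonus: empty graph
  expect_identical(nrow(ann$ppi), 0L)
})

test_that("a causally enriched pathway tops downstream enrichment", {
  hits <- 0L
  for (s in 1:20) {
    cfg <- simConfig(nIndividuals = 100, nVariants = 400, nCausalA = 40,
                     nCausalB = 40, nSharedCausal = 30, nGenes = 40,
                     nPathways = 10, seed = 700 + s)
    arch <- simulateArchitecture(cfg)
    ann <- simulateAnnotation(cfg, arch = arch, causalEnrichment = 10,
                              enrichedPathways = 1L,
                              pathwaySizeRange = c(8, 12))
    if (length(ann$causalGenes) < 4) next
    # candidate gene list: the causal genes themselves (the generator's
    # truth), tested against the simulated pathways
    ref <- S4Vectors::mcols(ann$genes)$gene_id
    enr <- hypergeomEnrich(ann$causalGenes, ann$pathways, ref,
                           minListGenes = 3)
    if (nrow(enr) && enr$pathway[1] == "PW001") hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
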