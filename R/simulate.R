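## Synthetic pleiotropic study generator.
##
## Two traits are simulated over one linear pseudo-chromosome of independent
## variants (no LD): trait A is binary under a liability-threshold model,
## trait B quantitative. A configurable subset of causal variants is shared
## between the traits with correlated effect sizes. The "architecture"
## (variant positions/alleles/MAFs, causal sets, true effects) is drawn from
## the config seed alone, so several cohorts can be sampled from one
## architecture -- emulating genetically correlated traits measured in
## different samples.

# Ordered non-complementary allele pairs; palindromic (A/T, C/G) pairs are
# excluded so harmonization of scans over one simulated universe is lossless.
.ALLELE_PAIRS <- matrix(c("A","C", "A","G", "C","A", "C","T",
                          "G","A", "G","T", "T","C", "T","G"),
                        ncol = 2, byrow = TRUE)

.VARIANT_SPACING <- 15000L  # bp between adjacent simulated variants

.cohortSeed <- function(config, cohortId) {
  as.integer((as.double(config@seed) + 104729 * (cohortId + 1)) %%
             .Machine$integer.max)
}

#' Draw the genetic architecture of a synthetic two-trait study
#'
#' Uses only `config@seed`, so the same architecture can back several
#' cohorts. Variants are placed every 2 kb on one pseudo-chromosome with
#' MAFs uniform on `mafRange` and non-palindromic allele pairs (15 kb
#' spacing, so gene/flank structure is on a human-like scale). Causal sets
#' are drawn for both traits with the configured overlap; effects at shared
#' causal variants are bivariate normal with correlation
#' `sharedEffectCorr`, non-shared effects independent normal.
#'
#' @param config a [SimConfig-class].
#' @return a list with `variants` (data.frame: snp, chr, bp, a1, a2, maf),
#'   `causalA`, `causalB`, `shared` (variant indices), and `effectA`,
#'   `effectB` (length-nVariants true effect vectors, zero off the causal
#'   sets).
#' @export
simulateArchitecture <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  v <- config@nVariants
  maf <- runif(v, config@mafRange[1], config@mafRange[2])
  pair <- .ALLELE_PAIRS[sample.int(nrow(.ALLELE_PAIRS), v, replace = TRUE), ,
                        drop = FALSE]
  variants <- data.frame(snp = sprintf("rs%05d", seq_len(v)),
                         chr = "1",
                         bp = .VARIANT_SPACING * seq_len(v),
                         a1 = pair[, 1], a2 = pair[, 2],
                         maf = maf, stringsAsFactors = FALSE)
  causalA <- sort(sample.int(v, config@nCausalA))
  shared <- sort(sample(causalA, config@nSharedCausal))
  pool <- setdiff(seq_len(v), causalA)
  extraB <- config@nCausalB - config@nSharedCausal
  causalB <- sort(c(shared, sample(pool, extraB)))
  effectA <- numeric(v); effectB <- numeric(v)
  rho <- config@sharedEffectCorr
  x1 <- rnorm(config@nSharedCausal)
  x2 <- rnorm(config@nSharedCausal)
  effectA[shared] <- config@effectSdA * x1
  effectB[shared] <- config@effectSdB * (rho * x1 + sqrt(1 - rho^2) * x2)
  onlyA <- setdiff(causalA, shared)
  onlyB <- setdiff(causalB, shared)
  effectA[onlyA] <- rnorm(length(onlyA), 0, config@effectSdA)
  effectB[onlyB] <- rnorm(length(onlyB), 0, config@effectSdB)
  list(variants = variants, causalA = causalA, causalB = causalB,
       shared = shared, effectA = effectA, effectB = effectB)
}

#' Simulate a cohort under a liability-threshold / additive model
#'
#' Genotypes are drawn per variant binomially under Hardy-Weinberg at the
#' architecture MAFs. The quantitative trait is the centered-dosage genetic
#' value of trait B plus sex/age/study covariate terms plus unit-variance
#' residual. The binary trait follows a liability-threshold model: latent
#' liability = trait-A genetic value + unit-variance normal residual, and an
#' individual is a case when liability exceeds the theoretical
#' (1 - prevalence) quantile of the liability distribution.
#'
#' Identical `config@seed` and `cohortId` give bit-identical cohorts.
#'
#' @param config a [SimConfig-class].
#' @param cohortId non-negative integer; cohorts with different ids drawn
#'   from the same architecture share true effects but nothing else.
#' @param arch optional architecture from [simulateArchitecture()]; drawn
#'   from `config` when NULL.
#' @return a [Cohort-class].
#' @export
simulateCohort <- function(config, cohortId = 0L, arch = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)  # invalid configs fail before any sampling
  if (is.null(arch)) arch <- simulateArchitecture(config)
  cohortId <- as.integer(cohortId)
  set.seed(.cohortSeed(config, cohortId))
  n <- config@nIndividuals
  v <- config@nVariants
  maf <- arch$variants$maf
  D <- matrix(rbinom(n * v, 2L, rep(maf, each = n)), nrow = n, ncol = v)
  iid <- sprintf("c%d_i%05d", cohortId, seq_len(n))
  dimnames(D) <- list(iid, arch$variants$snp)
  sex <- rbinom(n, 1L, 0.5)
  age <- sample(18:70, n, replace = TRUE)
  study <- sample(1:3, n, replace = TRUE)
  ce <- config@covariateEffects
  Gc <- sweep(D, 2L, 2 * maf)  # centered dosages -> mean-zero genetic values
  gB <- drop(Gc %*% arch$effectB)
  phenoQuant <- gB + ce[1] * sex + ce[2] * (age - 44) + ce[3] * (study - 2) +
    rnorm(n)
  gA <- drop(Gc %*% arch$effectA)
  liability <- gA + rnorm(n)
  varG <- sum(2 * maf * (1 - maf) * arch$effectA^2)
  threshold <- qnorm(1 - config@prevalence, mean = 0, sd = sqrt(varG + 1))
  phenoBinary <- as.integer(liability > threshold)
  truth <- data.frame(snp = arch$variants$snp,
                      causalA = seq_len(v) %in% arch$causalA,
                      causalB = seq_len(v) %in% arch$causalB,
                      shared = seq_len(v) %in% arch$shared,
                      effectA = arch$effectA,
                      effectB = arch$effectB,
                      stringsAsFactors = FALSE)
  new("Cohort", dosages = D, phenoQuant = phenoQuant,
      phenoBinary = phenoBinary,
      covariates = data.frame(iid = iid, sex = sex, age = age, study = study,
                              stringsAsFactors = FALSE),
      variants = arch$variants, truth = truth,
      config = config, cohortId = cohortId)
}

# Covariate design without intercept: sex, age, study indicator columns.
.covariateDesign <- function(covariates) {
  study <- factor(covariates$study)
  out <- cbind(sex = covariates$sex, age = covariates$age)
  if (nlevels(study) > 1L) {
    dm <- stats::model.matrix(~study)[, -1, drop = FALSE]
    out <- cbind(out, dm)
  }
  out
}

#' Per-variant association scan of a simulated cohort
#'
#' Runs a simple per-variant regression of phenotype on effect-allele
#' dosage with sex, age and study covariates: ordinary least squares for
#' the quantitative trait, maximum-likelihood logistic regression (beta =
#' log odds ratio) for the binary trait. `z = beta/se` and `p` from the
#' two-sided normal tail. Monomorphic variants are emitted with `z = 0`,
#' `p = 1` and flagged in the `monomorphic` column.
#'
#' @param cohort a [Cohort-class].
#' @param trait `"quant"` or `"binary"`.
#' @param traitName label stored in the result's metadata.
#' @param covariates include sex/age/study covariates (default TRUE).
#' @return a [SummaryStats-class] object.
#' @export
scanSummaryStats <- function(cohort, trait = c("quant", "binary"),
                             traitName = NULL, covariates = TRUE) {
  stopifnot(is(cohort, "Cohort"))
  trait <- match.arg(trait)
  if (is.null(traitName))
    traitName <- if (trait == "quant") "trait_quant" else "trait_binary"
  D <- cohort@dosages
  n <- nrow(D); v <- ncol(D)
  C <- if (covariates) .covariateDesign(cohort@covariates) else
    matrix(numeric(0), nrow = n, ncol = 0)
  mono <- apply(D, 2L, function(g) length(unique(g)) == 1L)
  beta <- numeric(v); se <- rep(Inf, v); z <- numeric(v); p <- rep(1, v)
  if (trait == "quant") {
    y <- cohort@phenoQuant
    X0 <- cbind(1, C)
    qr0 <- qr(X0)
    ry <- qr.resid(qr0, y)
    rG <- qr.resid(qr0, D)
    df <- n - ncol(X0) - 1L
    sxx <- colSums(rG^2)
    syy <- sum(ry^2)
    ok <- which(!mono & sxx > 0)
    b <- colSums(rG[, ok, drop = FALSE] * ry) / sxx[ok]
    rss <- syy - b^2 * sxx[ok]
    s2 <- pmax(rss, 0) / df
    beta[ok] <- b
    # a residual-free fit gives se = 0; keep it strictly positive so the
    # record invariants hold (z then saturates and p hits the floor)
    se[ok] <- pmax(sqrt(s2 / sxx[ok]), 1e-300)
    zk <- ifelse(se[ok] > 0, beta[ok] / se[ok], 0)
    z[ok] <- zk
    p[ok] <- zToP(zk)
  } else {
    y <- cohort@phenoBinary
    X0 <- cbind(`(Intercept)` = 1, C)
    k <- ncol(X0) + 1L
    for (j in which(!mono)) {
      fit <- suppressWarnings(glm.fit(cbind(X0, g = D[, j]), y,
                                      family = binomial()))
      R <- qr.R(fit$qr)
      piv <- fit$qr$pivot
      covm <- tryCatch(chol2inv(R), error = function(e) NULL)
      if (is.null(covm) || fit$rank < k) next  # leave flagged-null record
      sePiv <- sqrt(diag(covm))
      seAll <- sePiv[match(seq_len(k), piv)]
      beta[j] <- fit$coefficients[k]
      se[j] <- seAll[k]
      z[j] <- beta[j] / se[j]
      p[j] <- zToP(z[j])
    }
  }
  df <- data.frame(snp = cohort@variants$snp,
                   chr = cohort@variants$chr,
                   bp = cohort@variants$bp,
                   a1 = cohort@variants$a1,
                   a2 = cohort@variants$a2,
                   beta = beta, se = se, z = z, p = p,
                   n = n, monomorphic = mono,
                   stringsAsFactors = FALSE)
  meta <- traitMeta(traitName,
                    traitKind = if (trait == "quant") "quantitative" else "binary")
  SummaryStats(df, meta)
}

#' Simulate gene, pathway and PPI annotations for a synthetic study
#'
#' Genes are tiled left to right over the simulated pseudo-chromosome with
#' lengths and inter-gene gaps drawn uniformly from the supplied ranges, so
#' under the defaults some variants fall inside genes, some within the
#' 50-kb flank, and some beyond. Pathways are gene subsets sampled with an
#' optional enrichment weight on "causal" genes (genes containing a shared
#' causal variant). The PPI network is an Erdos-Renyi graph over all genes
#' with an optional extra within-pathway edge probability.
#'
#' @param config a [SimConfig-class].
#' @param arch optional architecture from [simulateArchitecture()].
#' @param causalEnrichment sampling-weight multiplier for causal genes in
#'   pathway membership draws (1 = no enrichment).
#' @param enrichedPathways indices of pathways receiving the enrichment
#'   weight (default: the first pathway when `causalEnrichment > 1`).
#' @param withinPathwayEdgeProb extra PPI edge probability for gene pairs
#'   co-occurring in a pathway.
#' @param geneLengthRange,gapRange uniform sampling ranges (bp) for gene
#'   lengths and inter-gene gaps.
#' @param pathwaySizeRange uniform integer range of pathway sizes.
#' @return list with `genes` (GRanges with `gene_id`), `pathways` (named
#'   list of gene-id vectors), `ppi` (data.frame `from`/`to`), and
#'   `causalGenes` (ids of genes containing shared causal variants).
#' @export
simulateAnnotation <- function(config, arch = NULL,
                               causalEnrichment = 1,
                               enrichedPathways = NULL,
                               withinPathwayEdgeProb = 0,
                               geneLengthRange = c(10000, 50000),
                               gapRange = c(0, 150000),
                               pathwaySizeRange = c(5, 30)) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (is.null(arch)) arch <- simulateArchitecture(config)
  set.seed(as.integer((as.double(config@seed) + 7) %% .Machine$integer.max))
  chromLength <- max(arch$variants$bp) + .VARIANT_SPACING
  nG <- config@nGenes
  lens <- round(runif(nG, geneLengthRange[1], geneLengthRange[2]))
  gaps <- round(runif(nG, gapRange[1], gapRange[2]))
  starts <- 1 + cumsum(c(0, lens[-nG] + gaps[-nG]))
  ends <- starts + lens - 1
  if (any(starts > chromLength))
    stop("more genes requested than fit on the simulated chromosome (",
         nG, " genes, ", chromLength, " bp)")
  ends <- pmin(ends, chromLength)
  geneIds <- sprintf("GENE%04d", seq_len(nG))
  genes <- GRanges("1", IRanges(starts, ends))
  mcols(genes)$gene_id <- geneIds

  sharedPos <- arch$variants$bp[arch$shared]
  hitIdx <- vapply(sharedPos, function(pos) {
    hit <- which(starts <= pos & ends >= pos)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  causalGenes <- unique(geneIds[hitIdx[!is.na(hitIdx)]])

  nP <- config@nPathways
  if (is.null(enrichedPathways))
    enrichedPathways <- if (causalEnrichment > 1) 1L else integer(0)
  sizes <- sample(pathwaySizeRange[1]:pathwaySizeRange[2], nP, replace = TRUE)
  sizes <- pmin(sizes, nG)
  pathways <- lapply(seq_len(nP), function(i) {
    w <- rep(1, nG)
    if (i %in% enrichedPathways)
      w[geneIds %in% causalGenes] <- causalEnrichment
    sort(sample(geneIds, sizes[i], prob = w))
  })
  names(pathways) <- sprintf("PW%03d", seq_len(nP))

  g <- igraph::sample_gnp(nG, config@ppiEdgeProb)
  igraph::V(g)$name <- geneIds
  if (withinPathwayEdgeProb > 0) {
    for (pw in pathways) {
      if (length(pw) < 2) next
      prs <- utils::combn(pw, 2)
      draw <- runif(ncol(prs)) < withinPathwayEdgeProb
      if (any(draw))
        g <- igraph::add_edges(g, as.vector(prs[, draw, drop = FALSE]))
    }
    g <- igraph::simplify(g)
  }
  el <- igraph::as_edgelist(g)
  ppi <- data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
  list(genes = genes, pathways = pathways, ppi = ppi,
       causalGenes = causalGenes)
}
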