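#' TraitMeta: trait-level metadata for a summary-statistics table
#'
#' Records the trait name, whether the trait is binary or quantitative, and
#' the scale of the per-variant effect estimates. Binary traits must carry
#' log-odds effects and quantitative traits linear effects.
#'
#' @slot traitName single character, trait label.
#' @slot traitKind `"binary"` or `"quantitative"`.
#' @slot effectScale `"log_odds"` or `"linear"`.
#' @export
setClass("TraitMeta",
  representation(traitName = "character",
                 traitKind = "character",
                 effectScale = "character"))

setValidity("TraitMeta", function(object) {
  msg <- character()
  if (length(object@traitName) != 1L || !nzchar(object@traitName))
    msg <- c(msg, "traitName must be a single non-empty string")
  if (!identical(length(object@traitKind), 1L) ||
      !object@traitKind %in% c("binary", "quantitative"))
    msg <- c(msg, "traitKind must be 'binary' or 'quantitative'")
  if (!identical(length(object@effectScale), 1L) ||
      !object@effectScale %in% c("log_odds", "linear"))
    msg <- c(msg, "effectScale must be 'log_odds' or 'linear'")
  if (length(msg) == 0L) {
    if ((object@traitKind == "binary") != (object@effectScale == "log_odds"))
      msg <- c(msg, "binary traits must use log_odds effects and quantitative traits linear effects")
  }
  if (length(msg)) msg else TRUE
})

#' Construct trait metadata
#'
#' @param traitName trait label.
#' @param traitKind `"binary"` or `"quantitative"`.
#' @param effectScale effect scale; defaults to the scale implied by
#'   `traitKind` (`"log_odds"` for binary, `"linear"` for quantitative).
#' @return a [TraitMeta-class] object.
#' @examples
#' traitMeta("scz", "binary")
#' @export
traitMeta <- function(traitName, traitKind = c("quantitative", "binary"),
                      effectScale = NULL) {
  traitKind <- match.arg(traitKind)
  if (is.null(effectScale))
    effectScale <- if (traitKind == "binary") "log_odds" else "linear"
  new("TraitMeta", traitName = as.character(traitName),
      traitKind = traitKind, effectScale = effectScale)
}

#' SummaryStats: per-variant GWAS association results for one trait
#'
#' Container for one trait's summary statistics. Each row holds a variant's
#' association result: identifier, position, allele pair, effect size (beta;
#' log odds ratio for binary traits), its standard error, the signed Z
#' statistic and two-sided P-value, and the sample size. Rows are sorted by
#' (chromosome, position); chromosome labels are normalized ("chr" prefix
#' stripped, X encoded as 23). Validity enforces p in (0, 1], se > 0,
#' distinct alleles, sign agreement between z and beta, and z/p consistency
#' under the normal tail.
#'
#' @slot stats data.frame with columns `snp`, `chr`, `bp`, `a1` (effect
#'   allele), `a2`, `beta`, `se`, `z`, `p`, `n` (extra columns allowed).
#' @slot meta a [TraitMeta-class].
#' @seealso [readSumstats()], [harmonizeSumstats()]
#' @export
setClass("SummaryStats",
  representation(stats = "data.frame", meta = "TraitMeta"))

.SUMSTAT_COLS <- c("snp", "chr", "bp", "a1", "a2", "beta", "se", "z", "p", "n")

setValidity("SummaryStats", function(object) {
  df <- object@stats
  msg <- character()
  missing_cols <- setdiff(.SUMSTAT_COLS, names(df))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (anyDuplicated(df$snp))
    msg <- c(msg, paste("duplicate variant id(s):",
                        paste(unique(df$snp[duplicated(df$snp)]), collapse = ", ")))
  if (any(!is.finite(df$p) | df$p <= 0 | df$p > 1))
    msg <- c(msg, "p must lie in (0, 1]")
  if (any(is.na(df$se) | df$se <= 0))  # Inf allowed (monomorphic records)
    msg <- c(msg, "se must be > 0")
  if (any(df$a1 == df$a2))
    msg <- c(msg, "effect and other allele must differ")
  both <- is.finite(df$z) & is.finite(df$beta) & df$z != 0 & df$beta != 0
  if (any(sign(df$z[both]) != sign(df$beta[both])))
    msg <- c(msg, "sign(z) must equal sign(beta)")
  # z/p mutual consistency through the normal tail (skip floored tails)
  chk <- is.finite(df$z) & is.finite(df$p) & df$p > 1e-290
  if (any(chk)) {
    pref <- zToP(df$z[chk])
    rel <- abs(df$p[chk] - pref) / pref
    if (any(rel > 1e-6))
      msg <- c(msg, "z and p are inconsistent under the two-sided normal tail")
  }
  key <- order(chromOrderKey(df$chr), df$bp)
  if (is.unsorted(key) && !identical(key, seq_len(nrow(df))))
    msg <- c(msg, "records must be sorted by (chr, bp)")
  if (length(msg)) msg else TRUE
})

#' Construct a SummaryStats object from a data.frame
#'
#' Normalizes chromosome labels, sorts by (chromosome, position), fills in a
#' missing `z` from `beta`/`se` and a missing `p` from `z`, and validates.
#'
#' @param stats data.frame with (at least) columns `snp`, `chr`, `bp`, `a1`,
#'   `a2`, `beta`, `se`, `n`; `z` and `p` may be absent or NA and are then
#'   reconstructed.
#' @param meta a [TraitMeta-class] object.
#' @return a validated [SummaryStats-class] object.
#' @export
SummaryStats <- function(stats, meta) {
  stopifnot(is.data.frame(stats), is(meta, "TraitMeta"))
  df <- as.data.frame(stats, stringsAsFactors = FALSE)
  if (is.null(df$z)) df$z <- NA_real_
  if (is.null(df$p)) df$p <- NA_real_
  need <- setdiff(.SUMSTAT_COLS, names(df))
  if (length(need))
    stop("missing required column(s): ", paste(need, collapse = ", "))
  if (anyDuplicated(df$snp))
    stop("duplicate variant id(s): ",
         paste(unique(df$snp[duplicated(df$snp)]), collapse = ", "))
  df$chr <- normalizeChrom(df$chr)
  df$bp <- as.integer(df$bp)
  df$n <- as.integer(df$n)
  fillz <- !is.finite(df$z)
  df$z[fillz] <- df$beta[fillz] / df$se[fillz]
  fillp <- !is.finite(df$p)
  df$p[fillp] <- zToP(df$z[fillp])
  df <- df[order(chromOrderKey(df$chr), df$bp), , drop = FALSE]
  rownames(df) <- NULL
  new("SummaryStats", stats = df, meta = meta)
}

#' SimConfig: parameters of the synthetic pleiotropic-cohort generator
#'
#' Describes the simulated study: cohort and variant counts, the allele
#' frequency range, the genetic architecture of two traits (trait A binary
#' under a liability-threshold model, trait B quantitative) including how
#' many causal variants they share and how correlated the shared effects
#' are, covariate effects on the quantitative trait, and annotation sizes.
#'
#' @slot nIndividuals,nVariants cohort dimensions.
#' @slot mafRange length-2 numeric in (0, 0.5], uniform sampling range for
#'   minor allele frequencies.
#' @slot nCausalA,nCausalB,nSharedCausal causal-variant counts for the two
#'   traits and their overlap (shared <= both).
#' @slot effectSdA,effectSdB SD of per-allele effect sizes.
#' @slot sharedEffectCorr correlation of effect pairs at shared causal
#'   variants, in [-1, 1].
#' @slot prevalence population prevalence of the binary trait, in (0, 1).
#' @slot covariateEffects length-3 numeric: additive effects of sex (0/1),
#'   centered age (per year) and centered study index on the quantitative
#'   trait.
#' @slot nGenes,nPathways annotation sizes.
#' @slot ppiEdgeProb background edge probability of the simulated PPI graph.
#' @slot seed integer RNG seed; identical seeds give bit-identical output.
#' @export
setClass("SimConfig",
  representation(nIndividuals = "integer", nVariants = "integer",
                 mafRange = "numeric",
                 nCausalA = "integer", nCausalB = "integer",
                 nSharedCausal = "integer",
                 effectSdA = "numeric", effectSdB = "numeric",
                 sharedEffectCorr = "numeric",
                 prevalence = "numeric",
                 covariateEffects = "numeric",
                 nGenes = "integer", nPathways = "integer",
                 ppiEdgeProb = "numeric",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  pos1 <- function(x) length(x) == 1L && is.finite(x) && x > 0
  if (!pos1(object@nIndividuals)) msg <- c(msg, "nIndividuals must be positive")
  if (!pos1(object@nVariants)) msg <- c(msg, "nVariants must be positive")
  if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
      any(object@mafRange > 0.5) || object@mafRange[1] > object@mafRange[2])
    msg <- c(msg, "mafRange must be an increasing interval within (0, 0.5]")
  if (object@nCausalA < 0L || object@nCausalB < 0L || object@nSharedCausal < 0L)
    msg <- c(msg, "causal counts must be non-negative")
  if (object@nSharedCausal > min(object@nCausalA, object@nCausalB))
    msg <- c(msg, "nSharedCausal must be <= both causal counts")
  if (object@nCausalA > object@nVariants || object@nCausalB > object@nVariants)
    msg <- c(msg, "causal counts must be <= nVariants")
  if (object@nCausalA + object@nCausalB - object@nSharedCausal >
      object@nVariants)
    msg <- c(msg, "combined causal sets exceed nVariants")
  if (!pos1(object@effectSdA) || !pos1(object@effectSdB))
    msg <- c(msg, "effect SDs must be > 0")
  if (abs(object@sharedEffectCorr) > 1)
    msg <- c(msg, "sharedEffectCorr must lie in [-1, 1]")
  if (object@prevalence <= 0 || object@prevalence >= 1)
    msg <- c(msg, "prevalence must lie in (0, 1)")
  if (length(object@covariateEffects) != 3L)
    msg <- c(msg, "covariateEffects must have length 3 (sex, age, study)")
  if (!pos1(object@nGenes)) msg <- c(msg, "nGenes must be positive")
  if (!pos1(object@nPathways)) msg <- c(msg, "nPathways must be positive")
  if (object@ppiEdgeProb < 0 || object@ppiEdgeProb > 1)
    msg <- c(msg, "ppiEdgeProb must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic-study configuration
#'
#' Defaults describe a desk-scale pleiotropic study: 2,000 individuals,
#' 1,000 independent variants, 60 causal variants per trait of which 30 are
#' shared with effect correlation 0.8, binary-trait prevalence 0.25, and
#' modest sex/age/study covariate effects.
#'
#' @param nIndividuals,nVariants cohort dimensions.
#' @param mafRange MAF sampling interval within (0, 0.5].
#' @param nCausalA,nCausalB,nSharedCausal causal counts (A = binary trait,
#'   B = quantitative trait) and their overlap.
#' @param effectSdA,effectSdB per-allele effect SDs.
#' @param sharedEffectCorr effect correlation at shared causal variants.
#' @param prevalence binary-trait prevalence in (0, 1).
#' @param covariateEffects length-3 numeric (sex, per-year age, study).
#' @param nGenes,nPathways,ppiEdgeProb annotation sizes.
#' @param seed integer RNG seed.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nIndividuals = 200, nVariants = 50, seed = 7)
#' @export
simConfig <- function(nIndividuals = 2000L, nVariants = 1000L,
                      mafRange = c(0.05, 0.5),
                      nCausalA = 60L, nCausalB = 60L, nSharedCausal = 30L,
                      effectSdA = 0.12, effectSdB = 0.12,
                      sharedEffectCorr = 0.8,
                      prevalence = 0.25,
                      covariateEffects = c(sex = 0.2, age = 0.01, study = 0.15),
                      nGenes = 100L, nPathways = 25L, ppiEdgeProb = 0.02,
                      seed = 1L) {
  new("SimConfig",
      nIndividuals = as.integer(nIndividuals),
      nVariants = as.integer(nVariants),
      mafRange = as.numeric(mafRange),
      nCausalA = as.integer(nCausalA), nCausalB = as.integer(nCausalB),
      nSharedCausal = as.integer(nSharedCausal),
      effectSdA = as.numeric(effectSdA), effectSdB = as.numeric(effectSdB),
      sharedEffectCorr = as.numeric(sharedEffectCorr),
      prevalence = as.numeric(prevalence),
      covariateEffects = as.numeric(covariateEffects),
      nGenes = as.integer(nGenes), nPathways = as.integer(nPathways),
      ppiEdgeProb = as.numeric(ppiEdgeProb),
      seed = as.integer(seed))
}

#' Cohort: simulated individual-level data with recorded truth
#'
#' Holds hard-call dosages, both phenotypes, covariates, per-variant
#' metadata (positions, alleles, generating MAFs) and the generating truth
#' (causal flags and true effects for both traits).
#'
#' @slot dosages integer matrix (individuals x variants) of 0/1/2 counts of
#'   the effect allele, dimnames = (iid, snp).
#' @slot phenoQuant numeric vector, quantitative trait.
#' @slot phenoBinary integer 0/1 vector, binary trait.
#' @slot covariates data.frame with `iid`, `sex`, `age`, `study`.
#' @slot variants data.frame with `snp`, `chr`, `bp`, `a1`, `a2`, `maf`.
#' @slot truth data.frame with `snp`, `causalA`, `causalB`, `shared`,
#'   `effectA`, `effectB`.
#' @slot config the generating [SimConfig-class].
#' @slot cohortId integer tag distinguishing cohorts drawn from one
#'   architecture.
#' @export
setClass("Cohort",
  representation(dosages = "matrix", phenoQuant = "numeric",
                 phenoBinary = "integer", covariates = "data.frame",
                 variants = "data.frame", truth = "data.frame",
                 config = "SimConfig", cohortId = "integer"))

setValidity("Cohort", function(object) {
  msg <- character()
  n <- nrow(object@dosages); v <- ncol(object@dosages)
  if (!all(object@dosages %in% 0:2)) msg <- c(msg, "dosages must be 0/1/2")
  if (length(object@phenoQuant) != n) msg <- c(msg, "phenoQuant length mismatch")
  if (length(object@phenoBinary) != n) msg <- c(msg, "phenoBinary length mismatch")
  if (!all(object@phenoBinary %in% 0:1)) msg <- c(msg, "phenoBinary must be 0/1")
  if (nrow(object@covariates) != n) msg <- c(msg, "covariates row mismatch")
  if (nrow(object@variants) != v) msg <- c(msg, "variants row mismatch")
  if (nrow(object@truth) != v) msg <- c(msg, "truth row mismatch")
  if (length(msg)) msg else TRUE
})

#' JointScanResult: output of the weakest-link joint scan
#'
#' @slot results data.frame, one row per harmonized variant: `snp`, `chr`,
#'   `bp`, per-trait `z_*` and background-adjusted `p_adj_*` columns, the
#'   overlap statistic `r` (max of per-trait adjusted P-values), the overlap
#'   P-value `joint_p`, and the Benjamini-Hochberg `q`.
#' @slot loci data.frame of merged significant loci (lead variant, span,
#'   marker count, nearest-gene label).
#' @slot candidates data.frame of variants passing the relaxed candidate
#'   q-value cutoff used for pathway work.
#' @slot lambda named numeric, genomic-control inflation factor per trait.
#' @slot params list of scan options.
#' @export
setClass("JointScanResult",
  representation(results = "data.frame", loci = "data.frame",
                 candidates = "data.frame", lambda = "numeric",
                 params = "list"))

## ------------------------------------------------------------------------
## Generics and accessors

#' @describeIn SummaryStats-class number of variant records.
#' @param x,object a SummaryStats object.
#' @export
setMethod("length", "SummaryStats", function(x) nrow(x@stats))

#' Accessors for pleioscan containers
#'
#' `statsTable()` returns the per-variant table of a [SummaryStats-class] or
#' the per-variant results of a [JointScanResult-class]; `traitName()` and
#' `traitKind()` return trait metadata; `dosages()`, `phenotypes()` and
#' `truthTable()` extract the parts of a [Cohort-class]; `lociTable()`,
#' `candidateTable()` and `lambdaValues()` extract [JointScanResult-class]
#' components.
#'
#' @param x a pleioscan container object.
#' @return the extracted component (data.frame, matrix or vector).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("statsTable", function(x) standardGeneric("statsTable"))
#' @rdname accessors
#' @export
setMethod("statsTable", "SummaryStats", function(x) x@stats)
#' @rdname accessors
#' @export
setMethod("statsTable", "JointScanResult", function(x) x@results)

#' @rdname accessors
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))
#' @rdname accessors
#' @export
setMethod("traitName", "TraitMeta", function(x) x@traitName)
#' @rdname accessors
#' @export
setMethod("traitName", "SummaryStats", function(x) x@meta@traitName)

#' @rdname accessors
#' @export
setGeneric("traitKind", function(x) standardGeneric("traitKind"))
#' @rdname accessors
#' @export
setMethod("traitKind", "TraitMeta", function(x) x@traitKind)
#' @rdname accessors
#' @export
setMethod("traitKind", "SummaryStats", function(x) x@meta@traitKind)

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setMethod("dosages", "Cohort", function(x) x@dosages)

#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))
#' @rdname accessors
#' @export
setMethod("phenotypes", "Cohort", function(x) {
  data.frame(iid = x@covariates$iid,
             pheno_quant = x@phenoQuant,
             pheno_bin = x@phenoBinary,
             sex = x@covariates$sex,
             age = x@covariates$age,
             study = x@covariates$study,
             stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setMethod("truthTable", "Cohort", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))
#' @rdname accessors
#' @export
setMethod("variantTable", "Cohort", function(x) x@variants)

#' @rdname accessors
#' @export
setGeneric("lociTable", function(x) standardGeneric("lociTable"))
#' @rdname accessors
#' @export
setMethod("lociTable", "JointScanResult", function(x) x@loci)

#' @rdname accessors
#' @export
setGeneric("candidateTable", function(x) standardGeneric("candidateTable"))
#' @rdname accessors
#' @export
setMethod("candidateTable", "JointScanResult", function(x) x@candidates)

#' @rdname accessors
#' @export
setGeneric("lambdaValues", function(x) standardGeneric("lambdaValues"))
#' @rdname accessors
#' @export
setMethod("lambdaValues", "JointScanResult", function(x) x@lambda)

setMethod("show", "TraitMeta", function(object) {
  cat("TraitMeta:", object@traitName,
      sprintf("(%s, %s effects)\n", object@traitKind, object@effectScale))
})

setMethod("show", "SummaryStats", function(object) {
  cat(sprintf("SummaryStats for trait '%s' (%s): %d variants on %d chromosome(s)\n",
              object@meta@traitName, object@meta@traitKind,
              nrow(object@stats), length(unique(object@stats$chr))))
  if (nrow(object@stats)) {
    cat("  min p:", format(min(object@stats$p)), "\n")
  }
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d individuals x %d variants, seed %d\n",
              object@nIndividuals, object@nVariants, object@seed))
  cat(sprintf("  causal A/B/shared: %d/%d/%d, effect corr %.2f, prevalence %.2f\n",
              object@nCausalA, object@nCausalB, object@nSharedCausal,
              object@sharedEffectCorr, object@prevalence))
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort %d: %d individuals x %d variants, %d cases (%.1f%%)\n",
              object@cohortId, nrow(object@dosages), ncol(object@dosages),
              sum(object@phenoBinary),
              100 * mean(object@phenoBinary)))
})

setMethod("show", "JointScanResult", function(object) {
  cat(sprintf("JointScanResult: %d variants, %d loci at q <= %g, %d candidates at q <= %g\n",
              nrow(object@results), nrow(object@loci),
              object@params$qLoci, nrow(object@candidates),
              object@params$qCandidates))
  cat("  lambda:", paste(sprintf("%s=%.3f", names(object@lambda), object@lambda),
                         collapse = ", "), "\n")
})
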