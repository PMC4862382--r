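## Polygenic risk scoring and reciprocal cross-trait prediction.

# The five standard P-value inclusion thresholds.
.PRS_THRESHOLDS <- c(5e-5, 5e-4, 5e-3, 5e-2, 5e-1)

#' Compute thresholded, normalized polygenic risk scores
#'
#' For each threshold T, an individual's score is the dosage-weighted sum of
#' effect sizes over all weight variants with `p <= T` that are present in
#' the dosage matrix, normalized to the average-per-allele scale:
#' \deqn{score_i = \sum_{j: p_j \le T} d_{ij} w_j / (2 M_i)}
#' where \eqn{w_j} is the effect size (log odds ratio for a binary source
#' trait) and \eqn{M_i} the number of non-missing markers for individual i
#' at T. Negative-effect variants contribute with their sign preserved
#' (equivalently, via the other allele). Missing dosages drop the marker
#' from both the numerator and \eqn{M_i} for that individual. The
#' normalization is an affine rescaling, so downstream regression
#' statistics and r-squared are unaffected by its exact convention.
#'
#' Weights must already be harmonized to the dosage matrix's allele coding
#' (see [harmonizeSumstats()]).
#'
#' @param weights a [SummaryStats-class] of the source trait.
#' @param dosageMatrix numeric matrix, individuals x variants, effect-allele
#'   counts 0/1/2 (NA allowed), colnames = variant ids.
#' @param thresholds numeric vector of P-value cutoffs in (0, 1]; default
#'   the five standard values 5e-5 ... 5e-1.
#' @return data.frame with columns `iid`, `threshold`, `score`,
#'   `n_markers` (markers passing the threshold and present in the dosage
#'   data) and `defined` (FALSE when no markers pass, in which case `score`
#'   is NA and downstream regression should skip the threshold).
#' @export
computeRiskScores <- function(weights, dosageMatrix,
                              thresholds = .PRS_THRESHOLDS) {
  stopifnot(is(weights, "SummaryStats"), is.matrix(dosageMatrix))
  if (any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must lie in (0, 1]")
  w <- weights@stats
  ids <- colnames(dosageMatrix)
  if (is.null(ids)) stop("dosage matrix must have variant-id colnames")
  w <- w[w$snp %in% ids, , drop = FALSE]
  iid <- rownames(dosageMatrix)
  if (is.null(iid)) iid <- as.character(seq_len(nrow(dosageMatrix)))
  out <- vector("list", length(thresholds))
  for (k in seq_along(thresholds)) {
    T <- thresholds[k]
    sel <- w[w$p <= T, , drop = FALSE]
    if (nrow(sel) == 0L) {
      out[[k]] <- data.frame(iid = iid, threshold = T, score = NA_real_,
                             n_markers = 0L, defined = FALSE,
                             stringsAsFactors = FALSE)
      next
    }
    D <- dosageMatrix[, sel$snp, drop = FALSE]
    wt <- sel$beta
    miss <- is.na(D)
    Dz <- D; Dz[miss] <- 0
    num <- drop(Dz %*% wt)
    M <- nrow(sel) - rowSums(miss)
    score <- ifelse(M > 0, num / (2 * M), NA_real_)
    out[[k]] <- data.frame(iid = iid, threshold = T, score = score,
                           n_markers = nrow(sel), defined = TRUE,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Nagelkerke's R-squared for a fitted logistic model
#'
#' Likelihood-based coefficient of determination rescaled to [0, 1]:
#' \deqn{R^2 = \frac{1 - (L_0/L_1)^{2/n}}{1 - L_0^{2/n}}}
#' with \eqn{L_0} the likelihood of the reference (here covariates-only)
#' model and \eqn{L_1} the full model.
#'
#' @param llFull,llNull log-likelihoods of the full and reference models.
#' @param n number of observations.
#' @return numeric in [0, 1].
#' @export
nagelkerkeR2 <- function(llFull, llNull, n) {
  cs <- 1 - exp((2 / n) * (llNull - llFull))  # Cox-Snell
  denom <- 1 - exp((2 / n) * llNull)
  r2 <- if (denom > 0) cs / denom else 0
  min(max(r2, 0), 1)
}

#' Regress a phenotype on polygenic scores, one model per threshold
#'
#' Joins scores to the phenotype table by individual id and fits, per
#' threshold, phenotype ~ score + sex + age + factor(study). For a
#' quantitative trait the reported `r2` is the incremental R-squared of the
#' full linear model over the covariates-only model and `stat` is the score
#' term's t statistic. For a binary trait the model is logistic, `stat` the
#' Wald Z, and `r2` Nagelkerke's R-squared of the full model relative to
#' the covariates-only model. A constant score column yields `r2 = 0` with
#' NA effect estimates; complete separation is flagged (`reliable = FALSE`,
#' `r2 = 1`).
#'
#' @param scores data.frame from [computeRiskScores()].
#' @param pheno data.frame with `iid`, the phenotype column, and `sex`,
#'   `age`, `study`.
#' @param traitKind `"quantitative"` or `"binary"`.
#' @param phenoColumn name of the phenotype column; defaults to
#'   `pheno_quant` / `pheno_bin` according to `traitKind`.
#' @param covariates include sex/age/study covariates (default TRUE).
#' @return data.frame with one row per defined threshold: `threshold`,
#'   `beta`, `se`, `stat`, `p`, `r2`, `n_markers`, `n_individuals`,
#'   `reliable`.
#' @export
predictTrait <- function(scores, pheno,
                         traitKind = c("quantitative", "binary"),
                         phenoColumn = NULL, covariates = TRUE) {
  traitKind <- match.arg(traitKind)
  if (is.null(phenoColumn))
    phenoColumn <- if (traitKind == "binary") "pheno_bin" else "pheno_quant"
  stopifnot(phenoColumn %in% names(pheno), "iid" %in% names(pheno))
  thresholds <- unique(scores$threshold)
  rows <- vector("list", length(thresholds))
  for (k in seq_along(thresholds)) {
    T <- thresholds[k]
    sc <- scores[scores$threshold == T, , drop = FALSE]
    if (!any(sc$defined)) next  # scores undefined at this threshold
    m <- merge(sc, pheno, by = "iid")
    m <- m[complete.cases(m[, c("score", phenoColumn)]), , drop = FALSE]
    if (nrow(m) < 10L) next
    y <- m[[phenoColumn]]
    covForm <- if (covariates) "sex + age + factor(study)" else "1"
    fullForm <- stats::as.formula(paste("y ~ score +", covForm))
    nullForm <- stats::as.formula(paste("y ~", covForm))
    dat <- data.frame(y = y, score = m$score, sex = m$sex, age = m$age,
                      study = m$study)
    constScore <- stats::var(m$score) == 0
    if (traitKind == "quantitative") {
      if (constScore) {
        rows[[k]] <- data.frame(threshold = T, beta = NA_real_, se = NA_real_,
                                stat = NA_real_, p = NA_real_, r2 = 0,
                                n_markers = sc$n_markers[1],
                                n_individuals = nrow(m), reliable = TRUE)
        next
      }
      fit <- lm(fullForm, data = dat)
      fit0 <- lm(nullForm, data = dat)
      co <- summary(fit)$coefficients["score", ]
      r2 <- max(summary(fit)$r.squared - summary(fit0)$r.squared, 0)
      rows[[k]] <- data.frame(threshold = T, beta = co[1], se = co[2],
                              stat = co[3], p = co[4], r2 = r2,
                              n_markers = sc$n_markers[1],
                              n_individuals = nrow(m), reliable = TRUE)
    } else {
      if (constScore) {
        rows[[k]] <- data.frame(threshold = T, beta = NA_real_, se = NA_real_,
                                stat = NA_real_, p = NA_real_, r2 = 0,
                                n_markers = sc$n_markers[1],
                                n_individuals = nrow(m), reliable = TRUE)
        next
      }
      sep <- FALSE
      fit <- withCallingHandlers(
        glm(fullForm, data = dat, family = binomial()),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
            sep <<- TRUE
          invokeRestart("muffleWarning")
        })
      # glm does not always warn under separation; saturated fitted
      # probabilities are the reliable symptom
      if (!fit$converged ||
          any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8))
        sep <- TRUE
      fit0 <- suppressWarnings(glm(nullForm, data = dat, family = binomial()))
      co <- summary(fit)$coefficients["score", ]
      r2 <- nagelkerkeR2(as.numeric(logLik(fit)), as.numeric(logLik(fit0)),
                         nrow(m))
      if (sep) r2 <- 1  # separation: likelihood saturates, p unreliable
      rows[[k]] <- data.frame(threshold = T, beta = co[1], se = co[2],
                              stat = co[3], p = co[4], r2 = r2,
                              n_markers = sc$n_markers[1],
                              n_individuals = nrow(m), reliable = !sep)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(threshold = numeric(), beta = numeric(),
                      se = numeric(), stat = numeric(), p = numeric(),
                      r2 = numeric(), n_markers = integer(),
                      n_individuals = integer(), reliable = logical())
  rownames(res) <- NULL
  res
}

#' Reciprocal polygenic risk-score analysis between two traits
#'
#' Runs both prediction directions: trait A's summary statistics score the
#' trait-B cohort and predict its phenotype, and vice versa. Each direction
#' yields one row per threshold with a significance flag at p < 0.05.
#'
#' @param sumstatsA,sumstatsB [SummaryStats-class] weight sources for the
#'   two traits.
#' @param dosagesB,phenoB dosage matrix and phenotype table of the cohort
#'   scored with trait-A weights (phenotype kind taken from `sumstatsB`'s
#'   trait kind is NOT assumed; see `kindB`).
#' @param dosagesA,phenoA cohort scored with trait-B weights.
#' @param kindB,kindA trait kind of the predicted phenotype in each
#'   direction (`"quantitative"` or `"binary"`).
#' @param thresholds P-value cutoffs (default the five standard values).
#' @return list with data.frames `aToB` and `bToA`, each with a
#'   `significant` flag at p < 0.05.
#' @export
reciprocalAnalysis <- function(sumstatsA, dosagesB, phenoB,
                               sumstatsB, dosagesA, phenoA,
                               kindB = "quantitative", kindA = "binary",
                               thresholds = .PRS_THRESHOLDS) {
  scB <- computeRiskScores(sumstatsA, dosagesB, thresholds)
  aToB <- predictTrait(scB, phenoB, traitKind = kindB)
  scA <- computeRiskScores(sumstatsB, dosagesA, thresholds)
  bToA <- predictTrait(scA, phenoA, traitKind = kindA)
  aToB$significant <- !is.na(aToB$p) & aToB$p < 0.05
  bToA$significant <- !is.na(bToA$p) & bToA$p < 0.05
  list(aToB = aToB, bToA = bToA)
}
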