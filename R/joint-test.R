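## Weakest-link joint ("overlap") testing across traits.
##
## At each variant the overlap statistic is the LARGEST of the per-trait
## (background-adjusted) P-values, so a signal must be supported by every
## trait; under independent null tests the overlap P-value is r^m. This
## makes the test robust to an extreme signal in a single trait: even with
## one trait's p -> 0, the other trait must independently reach
## alpha^(1/m) (2.2e-4 for alpha = 5e-8, m = 2).

# Median of the chi-square(1) distribution, the genomic-control null median.
.CHISQ1_MEDIAN <- qchisq(0.5, df = 1)

#' Genomic-control style background-enrichment adjustment
#'
#' Estimates the inflation factor \eqn{\lambda} = median(z^2) / 0.4549
#' (the chi-square-1 median), divides each squared statistic by
#' max(\eqn{\lambda}, 1) -- deflation below 1 is never applied -- and
#' returns P-values from the chi-square-1 upper tail. With fewer than 100
#' variants the adjustment is skipped with a warning (lambda is unreliable
#' at that size) and unadjusted tail P-values are returned.
#'
#' @param z numeric vector of signed per-variant statistics for one trait.
#' @return list with `p` (adjusted two-sided P-values, floored at 1e-300),
#'   `lambda` (estimated inflation; NA when skipped) and `lambdaApplied`
#'   (the max(lambda, 1) actually used).
#' @export
backgroundAdjust <- function(z) {
  stopifnot(is.numeric(z))
  chisq <- z^2
  if (length(z) < 100L) {
    warning("fewer than 100 variants: background adjustment skipped")
    p <- pmax(pchisq(chisq, df = 1, lower.tail = FALSE), .P_FLOOR)
    return(list(p = p, lambda = NA_real_, lambdaApplied = 1))
  }
  lambda <- median(chisq) / .CHISQ1_MEDIAN
  lambdaApplied <- max(lambda, 1)
  p <- exp(pchisq(chisq / lambdaApplied, df = 1, lower.tail = FALSE,
                  log.p = TRUE))
  p <- pmax(pmin(p, 1), .P_FLOOR)
  list(p = p, lambda = lambda, lambdaApplied = lambdaApplied)
}

#' Weakest-link overlap statistic
#'
#' The overlap statistic at a variant is the largest of its per-trait
#' P-values: small only when every trait shows association.
#'
#' @param pMatrix numeric matrix (variants x traits) of P-values in (0, 1],
#'   m >= 2 columns; a plain numeric vector is treated as one variant.
#' @return numeric vector, r = row-wise max.
#' @export
overlapStatistic <- function(pMatrix) {
  if (is.vector(pMatrix)) pMatrix <- matrix(pMatrix, nrow = 1)
  if (ncol(pMatrix) < 2L) stop("need P-values for at least two traits")
  if (any(!is.finite(pMatrix) | pMatrix <= 0 | pMatrix > 1))
    stop("all P-values must lie in (0, 1]")
  do.call(pmax, as.data.frame(pMatrix))
}

#' Overlap P-value for the weakest-link statistic
#'
#' Under independent trait tests, \eqn{P(R \le r) = \prod_j P(P_j \le r)}.
#' With all traits null-uniform this simplifies to \eqn{r^m} (computed in
#' log space). The `empirical` option instead evaluates each trait's term
#' from the empirical CDF of that trait's genome-wide adjusted P-values.
#'
#' @param r numeric vector of overlap statistics in (0, 1].
#' @param m number of traits (>= 2).
#' @param null `"uniform"` (default) or `"empirical"`.
#' @param traitPs list of per-trait P-value vectors, required for the
#'   empirical null.
#' @return numeric vector of overlap P-values.
#' @export
overlapPvalue <- function(r, m, null = c("uniform", "empirical"),
                          traitPs = NULL) {
  null <- match.arg(null)
  if (any(!is.finite(r) | r <= 0 | r > 1)) stop("r must lie in (0, 1]")
  if (m < 2L) stop("m must be >= 2")
  if (null == "uniform") return(pmax(exp(m * log(r)), .P_FLOOR))
  if (is.null(traitPs) || length(traitPs) != m)
    stop("empirical null requires per-trait P-value collections (traitPs)")
  out <- rep(1, length(r))
  for (ps in traitPs) {
    Fj <- stats::ecdf(ps)
    out <- out * pmax(Fj(r), .P_FLOOR)
  }
  pmax(out, .P_FLOOR)
}

#' Per-trait P-value threshold implied by an overall significance level
#'
#' For a significant weakest-link signal at overall level alpha across m
#' traits, every trait's P-value must fall below \eqn{\alpha^{1/m}}: e.g.
#' 2.2e-4 for alpha = 5e-8 with two traits.
#'
#' @param alpha overall significance level in (0, 1).
#' @param m number of traits (>= 1).
#' @return the per-trait threshold \eqn{\alpha^{1/m}}.
#' @export
perTraitThreshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha^(1 / m)
}

#' Worst-case per-variant false-positive rate of the overlap test
#'
#' With m - 1 traits carrying an extreme signal (p -> 0) and one null
#' trait, the overlap test rejects at level alpha exactly when the null
#' trait's uniform P-value falls below \eqn{\alpha^{1/m}} -- the worst-case
#' per-variant false-positive probability.
#'
#' @inheritParams perTraitThreshold
#' @return the bound \eqn{\alpha^{1/m}}.
#' @export
worstCaseFpr <- function(alpha, m) {
  perTraitThreshold(alpha, m)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values \eqn{q_{(i)} = \min_{k \ge i} n p_{(k)} / k}, clipped
#' to 1 and mapped back to input order (delegates to
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p numeric vector of P-values in (0, 1].
#' @return numeric vector of q-values in the input order; empty input
#'   yields empty output.
#' @export
fdrQvalues <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1)) stop("P-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' q-value cutoff corresponding to an AIC penalty
#'
#' An AIC penalty of `penalty` in a 1-df likelihood-ratio chi-square test
#' corresponds to the chi-square-1 upper-tail probability at that value;
#' the result is rounded to two decimals for reporting. A factor of 2 gives
#' 0.16, the candidate-marker cutoff used ahead of pathway analyses.
#'
#' @param penalty AIC factor, > 0 (0 allowed, giving 1).
#' @param digits decimals for reporting (default 2); use NULL for the
#'   unrounded tail probability.
#' @return the q-value cutoff.
#' @export
aicQvalueCutoff <- function(penalty, digits = 2) {
  stopifnot(penalty >= 0)
  q <- pchisq(penalty, df = 1, lower.tail = FALSE)
  if (is.null(digits)) q else round(q, digits)
}

#' Chain significant variants into loci
#'
#' Variants with `q <= qCutoff` are merged by proximity: consecutive
#' significant variants on the same chromosome within `mergeWindow` bp of
#' the previous member join one locus. Each locus reports its lead variant
#' (smallest overlap P-value, ties broken toward the smaller position), its
#' span, member count, and (when `genes` is supplied) the lead variant's
#' nearest-gene label under the 50-kb flank rule.
#'
#' @param results data.frame with columns `snp`, `chr`, `bp`, `joint_p`,
#'   `q`, sorted by (chr, bp).
#' @param qCutoff q-value cutoff (default 0.05).
#' @param mergeWindow chaining window in bp (default 250000).
#' @param genes optional `GRanges` with `gene_id` for lead annotation.
#' @param flank flank for gene annotation (default 50000).
#' @return data.frame with `lead_snp`, `chr`, `start`, `end`, `n_markers`,
#'   `gene`.
#' @export
selectLoci <- function(results, qCutoff = 0.05, mergeWindow = 250000,
                       genes = NULL, flank = 50000) {
  stopifnot(all(c("snp", "chr", "bp", "joint_p", "q") %in% names(results)))
  empty <- data.frame(lead_snp = character(), chr = character(),
                      start = integer(), end = integer(),
                      n_markers = integer(), gene = character(),
                      stringsAsFactors = FALSE)
  sig <- results[results$q <= qCutoff, , drop = FALSE]
  if (nrow(sig) == 0L) return(empty)
  sig <- sig[order(chromOrderKey(sig$chr), sig$bp), , drop = FALSE]
  newChain <- c(TRUE, diff(sig$bp) > mergeWindow |
                  sig$chr[-1] != sig$chr[-nrow(sig)])
  locusId <- cumsum(newChain)
  out <- lapply(split(seq_len(nrow(sig)), locusId), function(ix) {
    mem <- sig[ix, , drop = FALSE]
    lead <- mem[order(mem$joint_p, mem$bp), , drop = FALSE][1, ]
    gene <- NA_character_
    if (!is.null(genes))
      gene <- mapSnpToGene(lead$chr, lead$bp, genes, flank = flank)
    data.frame(lead_snp = lead$snp, chr = lead$chr,
               start = min(mem$bp), end = max(mem$bp),
               n_markers = nrow(mem), gene = gene,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full weakest-link joint scan
#'
#' Pipeline over two or more harmonized summary-statistics tables:
#' per-trait genomic-control background adjustment, the weakest-link
#' overlap statistic, overlap P-values, Benjamini-Hochberg q-values, locus
#' selection at `qLoci`, and the relaxed candidate set at `qCandidates`
#' for pathway work. All inputs must cover the identical variant set in the
#' identical order (use [harmonizeSumstats()] first); trait order does not
#' affect any output.
#'
#' @param statsList list of >= 2 aligned [SummaryStats-class] objects.
#' @param gcAdjust apply the background adjustment (default TRUE).
#' @param null `"uniform"` or `"empirical"` overlap null.
#' @param qLoci q-value cutoff for locus selection (default 0.05).
#' @param qCandidates q-value cutoff for the candidate set (default 0.16).
#' @param mergeWindow locus chaining window in bp (default 250000).
#' @param genes optional `GRanges` for lead-variant gene labels.
#' @param statistic `"max"` (weakest link, default) or `"min"` (an
#'   alternative strongest-link variant, exposed for completeness; its
#'   overlap P-value is \eqn{1-(1-r)^m}).
#' @return a [JointScanResult-class].
#' @export
runJointScan <- function(statsList, gcAdjust = TRUE,
                         null = c("uniform", "empirical"),
                         qLoci = 0.05, qCandidates = 0.16,
                         mergeWindow = 250000, genes = NULL,
                         statistic = c("max", "min")) {
  null <- match.arg(null)
  statistic <- match.arg(statistic)
  stopifnot(is.list(statsList), length(statsList) >= 2L)
  lapply(statsList, function(x) stopifnot(is(x, "SummaryStats")))
  snp0 <- statsList[[1]]@stats$snp
  for (x in statsList[-1])
    if (!identical(x@stats$snp, snp0))
      stop("summary statistics are not aligned; harmonize them first")
  m <- length(statsList)
  nms <- vapply(statsList, traitName, character(1))
  if (anyDuplicated(nms)) nms <- make.unique(nms)

  lambda <- setNames(rep(NA_real_, m), nms)
  pAdj <- matrix(NA_real_, nrow = length(snp0), ncol = m,
                 dimnames = list(NULL, nms))
  zMat <- pAdj
  for (j in seq_len(m)) {
    z <- statsList[[j]]@stats$z
    zMat[, j] <- z
    if (gcAdjust) {
      adj <- backgroundAdjust(z)
      pAdj[, j] <- adj$p
      lambda[j] <- adj$lambda
    } else {
      pAdj[, j] <- statsList[[j]]@stats$p
    }
  }
  r <- if (statistic == "max") do.call(pmax, as.data.frame(pAdj)) else
    do.call(pmin, as.data.frame(pAdj))
  if (statistic == "max") {
    jp <- overlapPvalue(r, m, null = null,
                        traitPs = if (null == "empirical")
                          lapply(seq_len(m), function(j) pAdj[, j]) else NULL)
  } else {
    jp <- pmax(1 - exp(m * log1p(-pmin(r, 1 - 1e-16))), .P_FLOOR)
  }
  q <- fdrQvalues(jp)

  res <- data.frame(snp = snp0,
                    chr = statsList[[1]]@stats$chr,
                    bp = statsList[[1]]@stats$bp,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) res[[paste0("z_", nms[j])]] <- zMat[, j]
  for (j in seq_len(m)) res[[paste0("p_adj_", nms[j])]] <- pAdj[, j]
  res$r <- r
  res$joint_p <- jp
  res$q <- q
  loci <- selectLoci(res, qCutoff = qLoci, mergeWindow = mergeWindow,
                     genes = genes)
  candidates <- res[res$q <= qCandidates, , drop = FALSE]
  rownames(candidates) <- NULL
  new("JointScanResult", results = res, loci = loci,
      candidates = candidates, lambda = lambda,
      params = list(gcAdjust = gcAdjust, null = null, qLoci = qLoci,
                    qCandidates = qCandidates, mergeWindow = mergeWindow,
                    statistic = statistic))
}
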