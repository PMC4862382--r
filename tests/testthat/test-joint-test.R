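# Weakest-link overlap testing, background adjustment, FDR and loci.

test_that("overlap statistic is the per-variant maximum P-value", {
  expect_identical(overlapStatistic(c(0.3, 0.01)), 0.3)
  for (x in c(1e-8, 0.25, 1))
    expect_identical(overlapStatistic(c(x, x, x)), x)
  # brute-force oracle at m = 5: sort and take the last element
  set.seed(11)
  P <- matrix(runif(200 * 5), ncol = 5)
  oracle <- apply(P, 1, function(p) sort(p)[5])
  expect_identical(overlapStatistic(P), oracle)
  expect_error(overlapStatistic(c(0, 0.5)), "\\(0, 1\\]")
  expect_error(overlapStatistic(matrix(0.5, 2, 1)), "two traits")
})

test_that("overlap P-value follows r^m and the empirical option", {
  expect_identical(overlapPvalue(1, 2), 1)
  expect_identical(overlapPvalue(1, 5), 1)
  expect_equal(overlapPvalue(0.1, 2), 0.01, tolerance = 1e-12)
  # log-space evaluation survives tiny r
  expect_equal(log(overlapPvalue(1e-100, 2)), 2 * log(1e-100) ,
               tolerance = 1e-9)
  # Monte-Carlo oracle: P(max(U1, U2) <= 0.3) = 0.09
  set.seed(21)
  nmc <- 1e6
  r <- pmax(runif(nmc), runif(nmc))
  phat <- mean(r <= 0.3)
  se <- sqrt(0.09 * 0.91 / nmc)
  expect_lt(abs(phat - overlapPvalue(0.3, 2)), 3 * se)
  # empirical null: uniform ECDFs recover ~ r^m
  set.seed(22)
  tp <- list(runif(20000), runif(20000))
  expect_equal(overlapPvalue(0.3, 2, null = "empirical", traitPs = tp),
               0.09, tolerance = 0.01)
  expect_error(overlapPvalue(0.3, 2, null = "empirical"), "traitPs")
})

test_that("per-trait threshold and worst-case FPR equal alpha^(1/m)", {
  # the two-trait genome-wide configuration: sqrt(5e-8) ~ 2.2e-4
  expect_equal(signif(perTraitThreshold(5e-8, 2), 2), 2.2e-4)
  expect_equal(perTraitThreshold(5e-8, 2), sqrt(5e-8), tolerance = 1e-12)
  expect_identical(perTraitThreshold(0.3, 1), 0.3)
  expect_equal(perTraitThreshold(0.25, 2), 0.5, tolerance = 1e-12)
  expect_equal(worstCaseFpr(5e-8, 2), 2.236068e-4, tolerance = 1e-6)
  expect_identical(worstCaseFpr(0.05, 1), 0.05)
})

test_that("background adjustment estimates and applies lambda correctly", {
  # median(z^2) exactly at the chi-square(1) median -> lambda = 1, p unchanged
  z <- sqrt(qchisq(0.5, 1)) * rep(c(-1, 1), 100)
  adj <- backgroundAdjust(z)
  expect_equal(adj$lambda, 1, tolerance = 1e-12)
  expect_equal(adj$p, pchisq(z^2, 1, lower.tail = FALSE), tolerance = 1e-12)

  # scale equivariance: z * sqrt(2) doubles lambda, adjusted p's unchanged
  set.seed(31)
  z <- rnorm(5000)
  a1 <- backgroundAdjust(z * sqrt(2))
  a0 <- backgroundAdjust(z)
  expect_equal(a1$lambda, 2 * a0$lambda, tolerance = 1e-12)
  # lambda floor: a0's lambda ~ 1 but may dip below; compare to floored
  z2 <- z * sqrt(2)
  expect_equal(a1$p, pchisq(z2^2 / a1$lambdaApplied, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # simulated inflation 1.3 recovered within 5% over 10 seeds
  lams <- vapply(1:10, function(s) {
    set.seed(100 + s)
    backgroundAdjust(rnorm(20000, 0, sqrt(1.3)))$lambda
  }, numeric(1))
  expect_lt(abs(mean(lams) - 1.3), 0.05 * 1.3)

  # deflation is never applied
  set.seed(32)
  zd <- rnorm(1000, 0, 0.5)
  ad <- backgroundAdjust(zd)
  expect_lt(ad$lambda, 1)
  expect_equal(ad$p, pchisq(zd^2, 1, lower.tail = FALSE), tolerance = 1e-12)

  expect_warning(backgroundAdjust(rnorm(50)), "skipped")
})

test_that("BH q-values match the hand-computed step-up", {
  # all five p's give n*p/k = 0.05 -> every q = 0.05
  expect_equal(fdrQvalues(c(0.01, 0.02, 0.03, 0.04, 0.05)),
               rep(0.05, 5), tolerance = 1e-12)
  expect_identical(fdrQvalues(0.3), 0.3)
  expect_identical(fdrQvalues(numeric(0)), numeric(0))
  # step-up monotonicity in p-rank, preserved through input reordering
  set.seed(41)
  p <- runif(50)
  q <- fdrQvalues(p)
  expect_true(!is.unsorted(q[order(p)]))
  # independent hand implementation
  stepUp <- function(p) {
    n <- length(p); o <- order(p)
    q <- rev(cummin(rev(n * p[o] / seq_len(n))))
    pmin(q, 1)[order(o)]
  }
  expect_equal(q, stepUp(p), tolerance = 1e-12)
})

test_that("AIC penalty maps to the chi-square q-value cutoff", {
  expect_identical(aicQvalueCutoff(2), 0.16)
  expect_equal(aicQvalueCutoff(2, digits = NULL), 0.1572992, tolerance = 1e-6)
  expect_identical(aicQvalueCutoff(0), 1)
  expect_equal(aicQvalueCutoff(3.841, digits = NULL), 0.05, tolerance = 1e-3)
})

test_that("locus selection chains significant variants within the window", {
  mk <- function(chr, bp, jp, q) {
    data.frame(snp = sprintf("v%03d", seq_along(bp)), chr = chr, bp = bp,
               joint_p = jp, q = q, stringsAsFactors = FALSE)
  }
  # singleton
  r <- mk("1", c(100L, 500000L), c(1e-6, 0.5), c(0.01, 0.9))
  loci <- selectLoci(r)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$n_markers, 1L)
  # two significant 10 bp apart chain into one locus
  r <- mk("1", c(1000L, 1010L), c(1e-6, 1e-5), c(0.01, 0.02))
  loci <- selectLoci(r, mergeWindow = 250000)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$n_markers, 2L)
  expect_identical(loci$lead_snp, "v001")
  # tie on joint_p -> smaller position leads
  r <- mk("1", c(2000L, 1000L)[order(c(2000, 1000))], c(1e-6, 1e-6),
          c(0.01, 0.01))
  expect_identical(selectLoci(r)$lead_snp, r$snp[1])
  # chromosomes never chain together
  r <- mk(c("1", "2"), c(1000L, 1100L), c(1e-6, 1e-6), c(0.01, 0.01))
  expect_identical(nrow(selectLoci(r)), 2L)
})

test_that("locus chaining matches a union-find components oracle", {
  set.seed(51)
  win <- 250000
  bp <- sort(sample.int(5e6, 50))
  r <- data.frame(snp = sprintf("v%03d", 1:50), chr = "1", bp = bp,
                  joint_p = runif(50, 1e-9, 1e-6), q = 0.01,
                  stringsAsFactors = FALSE)
  loci <- selectLoci(r, qCutoff = 0.05, mergeWindow = win)
  # oracle: union-find over all pairs within the window
  parent <- seq_len(50)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in 1:49) for (j in (i + 1):50)
    if (abs(bp[i] - bp[j]) <= win) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  comp <- vapply(1:50, find, integer(1))
  oracleSizes <- sort(as.integer(table(comp)))
  expect_identical(sort(loci$n_markers), oracleSizes)
  expect_identical(nrow(loci), length(unique(comp)))
})

test_that("joint scan output is monotone, symmetric and candidate-tiered", {
  set.seed(61)
  n <- 500
  z1 <- rnorm(n); z2 <- rnorm(n)
  z1[5] <- 7; z2[5] <- 7.5
  pair <- makeAlignedPair(z1, z2)
  scan <- runJointScan(pair, gcAdjust = FALSE)
  res <- statsTable(scan)
  expect_equal(res$r, pmax(zToP(z1), zToP(z2)), tolerance = 1e-12)
  expect_equal(res$joint_p, res$r^2, tolerance = 1e-12)
  expect_equal(res$q, p.adjust(res$joint_p, "BH"), tolerance = 1e-12)

  # symmetry: permuting trait order leaves r/joint_p/q unchanged
  scan2 <- runJointScan(pair[c(2, 1)], gcAdjust = FALSE)
  res2 <- statsTable(scan2)
  expect_equal(res2$r, res$r, tolerance = 1e-15)
  expect_equal(res2$q, res$q, tolerance = 1e-15)

  # monotonicity: shrinking one trait's p never increases r, joint_p or q
  z2b <- z2; z2b[10] <- z2[10] + 5
  scanB <- runJointScan(makeAlignedPair(z1, z2b), gcAdjust = FALSE)
  resB <- statsTable(scanB)
  expect_lte(resB$r[10], res$r[10])
  expect_lte(resB$joint_p[10], res$joint_p[10])
  expect_lte(resB$q[10], res$q[10])

  # candidate tier is a superset of the locus tier
  expect_true(all(res$snp[res$q <= 0.05] %in% candidateTable(scan)$snp))
  expect_error(runJointScan(list(pair[[1]], makeSumstats(10))), "harmonize")
})

test_that("an extreme single-trait signal is excluded by the weakest link", {
  # genome-wide significant in trait 1 (p = 1e-15) but p = 0.2 in trait 2:
  # r = 0.2, joint_p = 0.04, never selected at q <= 0.05 given >= 100 tests
  set.seed(71)
  n <- 500
  z1 <- rnorm(n); z2 <- rnorm(n)
  z1[1] <- zFromP(1e-15); z2[1] <- zFromP(0.2)
  scan <- runJointScan(makeAlignedPair(z1, z2), gcAdjust = FALSE)
  res <- statsTable(scan)
  expect_equal(res$r[1], 0.2, tolerance = 1e-9)
  expect_equal(res$joint_p[1], 0.04, tolerance = 1e-9)
  expect_gt(res$q[1], 0.05)
  expect_false(res$snp[1] %in% lociTable(scan)$lead_snp)
})
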