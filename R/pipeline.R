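## End-to-end orchestration: simulate -> scan -> PRS -> joint test ->
## pathways -> crosstalk, driven by one flat key = value configuration.

.PIPELINE_DEFAULTS <- list(
  seed = 1L,
  # stage toggles
  run_simulate = TRUE, run_prs = TRUE, run_joint = TRUE,
  run_pathways = TRUE,
  # simulation
  n_individuals = 1500L, n_variants = 600L,
  maf_low = 0.05, maf_high = 0.5,
  n_causal_a = 50L, n_causal_b = 50L, n_shared_causal = 25L,
  effect_sd_a = 0.12, effect_sd_b = 0.12, shared_effect_corr = 0.8,
  prevalence = 0.25, n_genes = 55L, n_pathways = 20L,
  ppi_edge_prob = 0.02, n_nd_traits = 3L,
  # analysis constants (package defaults mirror the standard values)
  thresholds = c(5e-5, 5e-4, 5e-3, 5e-2, 5e-1),
  q_loci = 0.05, q_candidates = 0.16,
  flank = 50000L, merge_window = 250000L,
  min_traits = 2L, n_perm = 1000L, crosstalk_alpha = 0.05,
  # optional external inputs (generated when empty and run_simulate = TRUE)
  genes_file = "", gmt_file = "", ppi_file = "")

#' Read a flat pipeline configuration file
#'
#' The configuration is a plain text file of `key = value` lines (`#`
#' comments allowed). Unknown keys are an error; missing keys take the
#' package defaults, which equal the standard analysis constants (five PRS
#' thresholds 5e-5..5e-1, loci at q <= 0.05, candidates at q <= 0.16,
#' 50-kb flank, 250-kb merge window, enrichment at adjusted P < 0.05,
#' crosstalk edges at permutation P < 0.05). `thresholds` is
#' comma-separated. Values given as `overrides` (e.g. from CLI flags) win
#' over file values.
#'
#' @param path path to the config file, or NULL for pure defaults.
#' @param overrides named list of values overriding the file.
#' @return named list of validated configuration values.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- .PIPELINE_DEFAULTS
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) < 2) stop("malformed config line: ", ln)
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      if (!key %in% names(cfg)) stop("unknown config key: ", key)
      cfg[[key]] <- .coerceConfigValue(key, val, cfg[[key]])
    }
  }
  for (key in names(overrides)) {
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cfg[[key]] <- overrides[[key]]
  }
  cfg
}

.coerceConfigValue <- function(key, val, template) {
  if (key == "thresholds")
    return(as.numeric(strsplit(val, ",")[[1]]))
  if (is.logical(template))
    return(toupper(val) %in% c("TRUE", "T", "YES", "1"))
  if (is.integer(template)) return(as.integer(val))
  if (is.numeric(template)) return(as.numeric(val))
  val
}

.validateRunConfig <- function(cfg) {
  if (any(cfg$thresholds <= 0 | cfg$thresholds > 1))
    stop("thresholds must lie in (0, 1]")
  for (key in c("genes_file", "gmt_file", "ppi_file")) {
    if (nzchar(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("config references a missing file: ", key, " = ", cfg[[key]])
  }
  if (!cfg$run_simulate && (cfg$run_prs || cfg$run_joint))
    stop("run_prs/run_joint require run_simulate in this release")
  if (cfg$run_pathways && !cfg$run_joint)
    stop("run_pathways requires run_joint (it consumes the candidate sets)")
  invisible(cfg)
}

.pipeWrite <- function(obj, path, manifest, writer = NULL) {
  if (is.null(writer)) {
    write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writer(obj, path)
  }
  rbind(manifest, data.frame(file = basename(path),
                             md5 = unname(tools::md5sum(path)),
                             stringsAsFactors = FALSE))
}

#' Run the full pleiotropy pipeline
#'
#' Executes the enabled stages in dependency order with deterministic
#' seeding, writing every output table as TSV under `outDir` and recording
#' each written file with an MD5 checksum in `manifest.tsv`. Identical
#' configuration and seed give byte-identical outputs. A stage failure
#' aborts downstream stages with an error naming the stage. Per-stage
#' counts (variants, loci, merged genes, enriched pathways, crosstalk
#' edges) are logged via `message()`.
#'
#' Stage layout: one binary-trait source cohort plus `n_nd_traits`
#' quantitative-trait cohorts sharing a single genetic architecture are
#' simulated and scanned; reciprocal PRS prediction uses disjoint weight
#' and target cohorts; each quantitative trait is joint-tested against the
#' binary trait; candidate genes (q <= `q_candidates`) are merged across
#' quantitative traits (>= `min_traits` support), HLA-filtered, tested for
#' pathway enrichment, and the significant pathways scored for crosstalk.
#'
#' @param config named list from [readRunConfig()] (or NULL for defaults).
#' @param outDir output directory, created if needed.
#' @return invisibly, a list with `manifest` (data.frame of file, md5) and
#'   `counts` (named list of per-stage tallies).
#' @export
runPipeline <- function(config = NULL, outDir = tempfile("pleioscan_run_")) {
  cfg <- if (is.null(config)) .PIPELINE_DEFAULTS else config
  .validateRunConfig(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(file = character(), md5 = character(),
                         stringsAsFactors = FALSE)
  counts <- list()
  stage <- "none"
  tryCatch({
    if (!any(unlist(cfg[c("run_simulate", "run_prs", "run_joint",
                          "run_pathways")]))) {
      .pipeWriteManifest(manifest, outDir)
      message("pipeline: all stages disabled, nothing to do")
      return(invisible(list(manifest = manifest, counts = counts)))
    }

    scz <- NULL; ndScans <- list(); cohorts <- list(); ann <- NULL
    if (cfg$run_simulate) {
      stage <- "simulate"
      simCfg <- simConfig(
        nIndividuals = cfg$n_individuals, nVariants = cfg$n_variants,
        mafRange = c(cfg$maf_low, cfg$maf_high),
        nCausalA = cfg$n_causal_a, nCausalB = cfg$n_causal_b,
        nSharedCausal = cfg$n_shared_causal,
        effectSdA = cfg$effect_sd_a, effectSdB = cfg$effect_sd_b,
        sharedEffectCorr = cfg$shared_effect_corr,
        prevalence = cfg$prevalence, nGenes = cfg$n_genes,
        nPathways = cfg$n_pathways, ppiEdgeProb = cfg$ppi_edge_prob,
        seed = cfg$seed)
      arch <- simulateArchitecture(simCfg)
      nCoh <- cfg$n_nd_traits + 1L
      cohorts <- lapply(seq_len(nCoh) - 1L, function(id)
        simulateCohort(simCfg, cohortId = id, arch = arch))
      scz <- scanSummaryStats(cohorts[[1]], "binary", traitName = "disease")
      ndNames <- sprintf("nd%d", seq_len(cfg$n_nd_traits))
      ndScans <- lapply(seq_len(cfg$n_nd_traits), function(t)
        scanSummaryStats(cohorts[[t + 1L]], "quant", traitName = ndNames[t]))
      ann <- simulateAnnotation(simCfg, arch = arch, causalEnrichment = 8,
                                withinPathwayEdgeProb = 0.15)
      manifest <- .pipeWrite(scz, file.path(outDir, "sumstats_disease.tsv"),
                             manifest, writeSumstats)
      for (t in seq_along(ndScans))
        manifest <- .pipeWrite(ndScans[[t]],
                               file.path(outDir,
                                         sprintf("sumstats_nd%d.tsv", t)),
                               manifest, writeSumstats)
      manifest <- .pipeWrite(phenotypes(cohorts[[1]]),
                             file.path(outDir, "pheno_cohort0.tsv"), manifest,
                             writePhenotypes)
      manifest <- .pipeWrite(ann$genes, file.path(outDir, "genes.bed"),
                             manifest, writeGeneAnnotation)
      manifest <- .pipeWrite(ann$pathways, file.path(outDir, "pathways.gmt"),
                             manifest, function(x, p) writeGmt(x, p))
      manifest <- .pipeWrite(ann$ppi, file.path(outDir, "ppi.edges"),
                             manifest, writePpiEdges)
      counts$n_variants <- length(scz)
      message(sprintf("simulate: %d cohorts x %d variants", nCoh,
                      length(scz)))
    }

    if (cfg$run_prs) {
      stage <- "prs"
      rec <- reciprocalAnalysis(
        sumstatsA = scz, dosagesB = dosages(cohorts[[2]]),
        phenoB = phenotypes(cohorts[[2]]),
        sumstatsB = ndScans[[1]], dosagesA = dosages(cohorts[[1]]),
        phenoA = phenotypes(cohorts[[1]]),
        thresholds = cfg$thresholds)
      prsTab <- rbind(cbind(direction = "disease_to_nd", rec$aToB),
                      cbind(direction = "nd_to_disease", rec$bToA))
      manifest <- .pipeWrite(prsTab, file.path(outDir, "prs_results.tsv"),
                             manifest)
      counts$prs_significant <- sum(prsTab$significant)
      message(sprintf("prs: %d/%d threshold models significant at p < 0.05",
                      sum(prsTab$significant), nrow(prsTab)))
    }

    scans <- list(); geneLists <- list()
    if (cfg$run_joint) {
      stage <- "joint"
      for (t in seq_along(ndScans)) {
        h <- harmonizeSumstats(scz, ndScans[[t]])
        scan <- runJointScan(list(h$a, h$b), qLoci = cfg$q_loci,
                             qCandidates = cfg$q_candidates,
                             mergeWindow = cfg$merge_window,
                             genes = if (!is.null(ann)) ann$genes else NULL)
        scans[[t]] <- scan
        manifest <- .pipeWrite(statsTable(scan),
                               file.path(outDir, sprintf("joint_nd%d.tsv", t)),
                               manifest)
        manifest <- .pipeWrite(lociTable(scan),
                               file.path(outDir, sprintf("loci_nd%d.tsv", t)),
                               manifest)
        cand <- candidateTable(scan)
        gl <- unique(mapSnpToGene(cand$chr, cand$bp, ann$genes,
                                  flank = cfg$flank))
        geneLists[[t]] <- gl[!is.na(gl)]
        message(sprintf(
          "joint nd%d: %d loci at q <= %g, %d candidates at q <= %g, %d genes",
          t, nrow(lociTable(scan)), cfg$q_loci, nrow(cand),
          cfg$q_candidates, length(geneLists[[t]])))
      }
      counts$n_loci <- sum(vapply(scans, function(s) nrow(lociTable(s)),
                                  integer(1)))
    }

    if (cfg$run_pathways) {
      stage <- "pathways"
      genesGr <- if (nzchar(cfg$genes_file))
        readGeneAnnotation(cfg$genes_file) else ann$genes
      pathways <- if (nzchar(cfg$gmt_file))
        readGmt(cfg$gmt_file) else ann$pathways
      ppi <- if (nzchar(cfg$ppi_file)) readPpiEdges(cfg$ppi_file) else ann$ppi
      merged <- mergeTraitGenes(geneLists, minTraits = cfg$min_traits)
      flt <- filterHla(merged)
      counts$n_merged_genes <- length(merged)
      counts$n_genes_after_hla <- length(flt$genes)
      message(sprintf("pathways: %d merged genes, %d after HLA filter",
                      length(merged), length(flt$genes)))
      writeLines(flt$genes, file.path(outDir, "merged_genes.txt"))
      manifest <- rbind(manifest,
                        data.frame(file = "merged_genes.txt",
                                   md5 = unname(tools::md5sum(
                                     file.path(outDir, "merged_genes.txt"))),
                                   stringsAsFactors = FALSE))
      reference <- mcols(genesGr)$gene_id
      enr <- hypergeomEnrich(intersect(flt$genes, reference), pathways,
                             reference)
      manifest <- .pipeWrite(enr, file.path(outDir, "enrichment.tsv"),
                             manifest)
      counts$n_enriched <- sum(enr$significant)
      message(sprintf("pathways: %d/%d tested pathways enriched at adj p < 0.05",
                      sum(enr$significant), nrow(enr)))
      sig <- enr[enr$significant, , drop = FALSE]
      if (nrow(sig) >= 2) {
        stage <- "crosstalk"
        sets <- setNames(strsplit(sig$genes, ","), sig$pathway)
        net <- crosstalkNetwork(sets, ppi, nPerm = cfg$n_perm,
                                alpha = cfg$crosstalk_alpha,
                                seed = cfg$seed + 101L)
        counts$n_crosstalk_edges <- sum(net$retained)
        message(sprintf("crosstalk: %d/%d pairs retained at perm p < %g",
                        sum(net$retained), nrow(net), cfg$crosstalk_alpha))
      } else {
        net <- data.frame(pathway_a = character(), pathway_b = character(),
                          score = integer(), perm_p = numeric(),
                          retained = logical(), stringsAsFactors = FALSE)
        counts$n_crosstalk_edges <- 0L
      }
      manifest <- .pipeWrite(net, file.path(outDir, "crosstalk.tsv"),
                             manifest)
    }

    .pipeWriteManifest(manifest, outDir)
    invisible(list(manifest = manifest, counts = counts))
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

.pipeWriteManifest <- function(manifest, outDir) {
  write.table(manifest, file.path(outDir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
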