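## SNP -> gene mapping, cross-trait gene merging, hypergeometric pathway
## enrichment, and the permutation pathway-crosstalk network.

# The seven HLA-region gene symbols removed by default before pathway work
# (long-range LD makes their joint appearance uninformative).
.HLA_GENES <- c("HLA-B", "HLA-C", "HLA-DOA", "HLA-DQA1", "HLA-DQB1",
                "HLA-DRB1", "HLA-G")

#' Map variant positions to genes with a flanking window
#'
#' A variant inside a gene is assigned to that gene (containment wins over
#' proximity; among several containing genes, the one with the smaller
#' start). Otherwise it is assigned to the nearest gene whose boundary lies
#' within `flank` bp on either side; equidistant ties break toward the gene
#' with the smaller start coordinate. Variants beyond the flank of every
#' gene are unmapped (NA).
#'
#' @param chrom character vector of chromosome labels (normalized
#'   internally).
#' @param pos integer vector of 1-based positions.
#' @param genes `GRanges` with `mcols()$gene_id`, 1-based inclusive.
#' @param flank flanking distance in bp (default 50000). The boundary is
#'   inclusive: a variant exactly `flank` bp from a gene edge maps to it.
#' @return character vector of gene ids (NA where unmapped).
#' @export
mapSnpToGene <- function(chrom, pos, genes, flank = 50000) {
  stopifnot(is(genes, "GRanges"), !is.null(mcols(genes)$gene_id))
  chrom <- normalizeChrom(chrom)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  query <- GRanges(chrom, IRanges(pos, pos))
  out <- rep(NA_character_, n)
  gstart <- start(genes)
  gend <- end(genes)
  gid <- mcols(genes)$gene_id

  # one pass: all genes whose body lies within flank bp of the variant
  # (findOverlaps gaps are exclusive, hence maxgap = flank - 1; containment
  # has distance 0 and therefore always beats proximity)
  ov <- suppressWarnings(
    findOverlaps(query, genes, maxgap = max(flank - 1L, 0L)))
  if (length(ov)) {
    oq <- queryHits(ov); os <- subjectHits(ov)
    d <- pmax(gstart[os] - pos[oq], pos[oq] - gend[os], 0L)
    keepHit <- d <= flank
    oq <- oq[keepHit]; os <- os[keepHit]; d <- d[keepHit]
    ord <- order(oq, d, gstart[os])  # distance, then smaller gene start
    first <- !duplicated(oq[ord])
    out[oq[ord][first]] <- gid[os[ord][first]]
  }
  out
}

#' Merge per-trait gene lists by minimum trait support
#'
#' Keeps genes appearing in at least `minTraits` of the supplied lists
#' (each list counted once per gene), deduplicated and sorted.
#'
#' @param geneLists list of >= 1 character vectors of gene ids sharing one
#'   namespace.
#' @param minTraits minimum number of lists a gene must appear in
#'   (default 2).
#' @return sorted character vector of merged gene ids.
#' @export
mergeTraitGenes <- function(geneLists, minTraits = 2) {
  stopifnot(is.list(geneLists), length(geneLists) >= 1L)
  if (minTraits > length(geneLists))
    stop("minTraits (", minTraits, ") exceeds the number of gene lists (",
         length(geneLists), ")")
  counts <- table(unlist(lapply(geneLists, unique)))
  as.character(sort(names(counts)[counts >= minTraits]))
}

#' Remove HLA-region genes from a gene list
#'
#' Exact-match removal of the supplied identifiers (default: the seven
#' classical HLA symbols HLA-B, HLA-C, HLA-DOA, HLA-DQA1, HLA-DQB1,
#' HLA-DRB1, HLA-G), motivated by the strong linkage disequilibrium of the
#' region.
#'
#' @param genes character vector of gene ids.
#' @param hlaIds identifiers to remove.
#' @return list with `genes` (the filtered vector, order preserved) and
#'   `removed` (count removed).
#' @export
filterHla <- function(genes, hlaIds = .HLA_GENES) {
  drop <- genes %in% hlaIds
  list(genes = genes[!drop], removed = sum(drop))
}

#' Hypergeometric pathway over-representation test
#'
#' For each pathway, tests whether the gene list is over-represented among
#' the pathway's genes within a finite reference universe of N genes:
#' raw P = \eqn{P(X \ge k)} for X hypergeometric with K pathway genes, n
#' list genes. Pathway gene sets are intersected with the reference before
#' testing. Pathways with fewer than `minListGenes` list genes or more than
#' `maxPathwayGenes` reference genes are excluded before multiplicity
#' adjustment; Benjamini-Hochberg adjustment is applied over the tested
#' pathways only, with significance flagged at adjusted P < 0.05.
#'
#' @param geneList character vector of n candidate genes, all present in
#'   `reference` (a missing gene is an error naming it).
#' @param pathways named list of character vectors (e.g. from
#'   [readGmt()]).
#' @param reference character vector, the N-gene reference universe.
#' @param minListGenes minimum list genes in a pathway (default 3).
#' @param maxPathwayGenes maximum reference genes in a pathway
#'   (default 300).
#' @return data.frame sorted by raw P-value with columns `pathway`,
#'   `genes_in_pathway` (K), `genes_observed` (k), `genes_expected`
#'   (nK/N), `ratio` (k/expected), `raw_p`, `adj_p`, `significant`, and
#'   `genes` (comma-separated observed genes).
#' @export
hypergeomEnrich <- function(geneList, pathways, reference,
                            minListGenes = 3, maxPathwayGenes = 300) {
  geneList <- unique(geneList)
  reference <- unique(reference)
  missing <- setdiff(geneList, reference)
  if (length(missing))
    stop("gene(s) absent from the reference universe: ",
         paste(missing, collapse = ", "))
  N <- length(reference)
  n <- length(geneList)
  rows <- lapply(names(pathways), function(pw) {
    pwGenes <- intersect(unique(pathways[[pw]]), reference)
    K <- length(pwGenes)
    obs <- intersect(geneList, pwGenes)
    k <- length(obs)
    if (k < minListGenes || K > maxPathwayGenes) return(NULL)
    expected <- n * K / N
    rawP <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, genes_in_pathway = K, genes_observed = k,
               genes_expected = expected,
               ratio = if (expected > 0) k / expected else NA_real_,
               raw_p = rawP,
               genes = paste(sort(obs), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(pathway = character(), genes_in_pathway = integer(),
                      genes_observed = integer(), genes_expected = numeric(),
                      ratio = numeric(), raw_p = numeric(),
                      adj_p = numeric(), significant = logical(),
                      genes = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$adj_p <- p.adjust(res$raw_p, method = "BH")
  res$significant <- res$adj_p < 0.05
  res <- res[order(res$raw_p, res$pathway),
             c("pathway", "genes_in_pathway", "genes_observed",
               "genes_expected", "ratio", "raw_p", "adj_p", "significant",
               "genes")]
  rownames(res) <- NULL
  res
}
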