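#' Read a GWAS summary-statistics table
#'
#' Reads the tab-separated dialect with header
#' `SNP CHR BP A1 A2 BETA SE Z P N` (A1 = effect allele). `Z` and `P` may be
#' missing or NA: a missing Z is reconstructed as beta/se and a missing P
#' from Z via the two-sided normal tail. Records are validated (p in (0,1],
#' se > 0, unique ids, z/p consistency) and returned sorted by
#' (chromosome, position).
#'
#' @param path path to the TSV file.
#' @param meta a [TraitMeta-class] describing the trait.
#' @return a [SummaryStats-class] object.
#' @seealso [writeSumstats()], [harmonizeSumstats()]
#' @export
readSumstats <- function(path, meta) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = TRUE,
                    stringsAsFactors = FALSE, na.strings = c("NA", "", "."),
                    quote = "", comment.char = "")
  need <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "Z", "P", "N")
  absent <- setdiff(need, names(raw))
  if (length(absent))
    stop("header is missing required column(s): ",
         paste(absent, collapse = ", "))
  numify <- function(col) {
    x <- raw[[col]]
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad))
      stop(sprintf("malformed value '%s' in column %s at line %d",
                   x[bad[1]], col, bad[1] + 1L))  # +1 for the header line
    v
  }
  df <- data.frame(snp = raw$SNP, chr = raw$CHR,
                   bp = numify("BP"),
                   a1 = toupper(raw$A1), a2 = toupper(raw$A2),
                   beta = numify("BETA"), se = numify("SE"),
                   z = numify("Z"), p = numify("P"), n = numify("N"),
                   stringsAsFactors = FALSE)
  noz <- !is.finite(df$z) & (!is.finite(df$beta) | !is.finite(df$se))
  if (any(noz))
    stop("row at line ", which(noz)[1] + 1L,
         " has no z and no beta/se to reconstruct it from")
  badp <- is.finite(df$p) & (df$p <= 0 | df$p > 1)
  if (any(badp))
    stop("p outside (0, 1] at line ", which(badp)[1] + 1L)
  SummaryStats(df, meta)
}

#' Write a summary-statistics table
#'
#' Emits the same tab-separated dialect that [readSumstats()] accepts, with
#' full double precision so that a write/read round trip reproduces all
#' numeric fields to better than 1e-12 relative.
#'
#' @param x a [SummaryStats-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(x, path) {
  stopifnot(is(x, "SummaryStats"))
  df <- x@stats
  out <- data.frame(SNP = df$snp, CHR = df$chr, BP = df$bp,
                    A1 = df$a1, A2 = df$a2,
                    BETA = formatC(df$beta, digits = 17, format = "g"),
                    SE = formatC(df$se, digits = 17, format = "g"),
                    Z = formatC(df$z, digits = 17, format = "g"),
                    P = formatC(df$p, digits = 17, format = "g"),
                    N = df$n, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.isPalindromic <- function(a1, a2) {
  ok <- a1 %in% names(.COMPLEMENT) & a2 %in% names(.COMPLEMENT)
  ok & unname(.COMPLEMENT[a1]) == a2
}

#' Harmonize two traits' summary statistics onto shared variants
#'
#' Restricts both tables to variants present in both traits (matched by id)
#' and aligns trait B's effect direction to trait A's allele coding. If B's
#' alleles are swapped relative to A, B's beta and z are negated and its
#' alleles swapped; strand flips (A<->T, C<->G complements) are reconciled,
#' including flipped-and-swapped pairs. Strand-ambiguous palindromic
#' variants (A/T or C/G in either trait) are dropped and counted, since
#' their orientation cannot be resolved without allele frequencies.
#' Irreconcilable allele pairs are dropped with a logged reason rather than
#' raising an error.
#'
#' Harmonization is symmetric up to sign bookkeeping: swapping the roles of
#' A and B yields the same retained variant set.
#'
#' @param a,b [SummaryStats-class] objects for the two traits.
#' @return a list with elements `a` and `b` (aligned [SummaryStats-class]
#'   objects over the identical, identically ordered variant set),
#'   `dropped` (data.frame of `snp`, `reason`), and `nAmbiguous` (count of
#'   palindromic exclusions).
#' @export
harmonizeSumstats <- function(a, b) {
  stopifnot(is(a, "SummaryStats"), is(b, "SummaryStats"))
  da <- a@stats; db <- b@stats
  shared <- intersect(da$snp, db$snp)
  da <- da[da$snp %in% shared, , drop = FALSE]
  db <- db[match(da$snp, db$snp), , drop = FALSE]
  dropped <- data.frame(snp = character(), reason = character(),
                        stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(da))
  flip <- rep(FALSE, nrow(da))

  pal <- .isPalindromic(da$a1, da$a2) | .isPalindromic(db$a1, db$a2)
  nAmbiguous <- sum(pal)
  if (nAmbiguous) {
    dropped <- rbind(dropped, data.frame(snp = da$snp[pal],
                                         reason = "strand_ambiguous",
                                         stringsAsFactors = FALSE))
    keep[pal] <- FALSE
  }
  idx <- which(keep)
  if (length(idx)) {
    a1a <- da$a1[idx]; a2a <- da$a2[idx]
    a1b <- db$a1[idx]; a2b <- db$a2[idx]
    c1b <- unname(.COMPLEMENT[a1b]); c2b <- unname(.COMPLEMENT[a2b])
    c1b[is.na(c1b)] <- "?"; c2b[is.na(c2b)] <- "?"
    same    <- a1b == a1a & a2b == a2a
    swapped <- a1b == a2a & a2b == a1a
    flp     <- c1b == a1a & c2b == a2a
    flpswp  <- c1b == a2a & c2b == a1a
    bad <- !(same | swapped | flp | flpswp)
    if (any(bad)) {
      dropped <- rbind(dropped,
                       data.frame(snp = da$snp[idx[bad]],
                                  reason = "allele_mismatch",
                                  stringsAsFactors = FALSE))
      keep[idx[bad]] <- FALSE
    }
    flip[idx] <- (swapped | flpswp) & !bad
  }

  da <- da[keep, , drop = FALSE]
  db <- db[keep, , drop = FALSE]
  flip <- flip[keep]
  if (any(flip)) {
    db$beta[flip] <- -db$beta[flip]
    db$z[flip] <- -db$z[flip]
  }
  # after alignment B adopts A's allele coding and coordinates, so both
  # tables describe the identical variant set identically ordered
  db$a1 <- da$a1; db$a2 <- da$a2
  db$chr <- da$chr; db$bp <- da$bp
  rownames(da) <- rownames(db) <- NULL
  list(a = SummaryStats(da, a@meta),
       b = SummaryStats(db, b@meta),
       dropped = dropped,
       nAmbiguous = nAmbiguous)
}

## ------------------------------------------------------------------------
## Auxiliary annotation formats

#' Read gene intervals from a BED file
#'
#' Reads a 4+ column BED file (chrom, start, end, gene id) and returns a
#' `GRanges` in 1-based inclusive coordinates (the on-disk 0-based half-open
#' convention is converted on read), with the gene identifier in
#' `mcols()$gene_id` and chromosome labels normalized.
#'
#' @param path path to the BED file.
#' @return a `GRanges` sorted by (chromosome, start).
#' @export
readGeneAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  gene_id <- mcols(gr)$name
  gr2 <- GRanges(normalizeChrom(as.character(seqnames(gr))),
                 IRanges(start(gr), end(gr)))
  mcols(gr2)$gene_id <- gene_id
  gr2[order(chromOrderKey(as.character(seqnames(gr2))), start(gr2))]
}

#' Write gene intervals to a BED file
#'
#' @param genes `GRanges` with `mcols()$gene_id`, 1-based inclusive.
#' @param path output path (written 0-based half-open).
#' @return `path`, invisibly.
#' @export
writeGeneAnnotation <- function(genes, path) {
  stopifnot(is(genes, "GRanges"), !is.null(mcols(genes)$gene_id))
  df <- data.frame(chrom = as.character(seqnames(genes)),
                   start = start(genes) - 1L,  # to 0-based half-open
                   end = end(genes),
                   name = mcols(genes)$gene_id,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read pathway gene sets from a GMT file
#'
#' @param path path to a GMT file (pathway id, description, then member
#'   gene ids, tab-separated).
#' @return named list of character vectors of gene ids.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fgsea::gmtPathways(path)
}

#' Write pathway gene sets to a GMT file
#'
#' @param pathways named list of character vectors of gene ids.
#' @param path output path.
#' @param descriptions optional character vector of descriptions (defaults
#'   to the pathway names).
#' @return `path`, invisibly.
#' @export
writeGmt <- function(pathways, path, descriptions = names(pathways)) {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  lines <- vapply(seq_along(pathways), function(i) {
    paste(c(names(pathways)[i], descriptions[i], pathways[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected PPI edge list
#'
#' @param path two-column whitespace/tab-separated file of gene-id pairs.
#' @return data.frame with columns `from`, `to` (self-loops removed,
#'   duplicate undirected edges collapsed).
#' @export
readPpiEdges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("from", "to"),
                   colClasses = c("character", "character"))
  df <- df[df$from != df$to, , drop = FALSE]
  key <- ifelse(df$from < df$to, paste(df$from, df$to), paste(df$to, df$from))
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write an undirected PPI edge list
#'
#' @param edges data.frame with columns `from`, `to`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePpiEdges <- function(edges, path) {
  write.table(edges[, c("from", "to")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a dosage matrix
#'
#' TSV dialect: first column `iid`, remaining columns one per variant id,
#' values 0/1/2 effect-allele counts.
#'
#' @param path file path.
#' @return integer matrix with rownames = individual ids and colnames =
#'   variant ids.
#' @export
readDosageMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname readDosageMatrix
#' @param dosages integer matrix (individuals x variants).
#' @export
writeDosageMatrix <- function(dosages, path) {
  df <- data.frame(iid = rownames(dosages), dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a phenotype + covariate table
#'
#' TSV with columns `iid`, `pheno_quant`, `pheno_bin`, `sex`, `age`,
#' `study`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPhenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(iid = "character"))
  need <- c("iid", "pheno_quant", "pheno_bin", "sex", "age", "study")
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop("phenotype table is missing column(s): ",
         paste(absent, collapse = ", "))
  df
}

#' @rdname readPhenotypes
#' @param pheno data.frame as returned by `phenotypes()` on a Cohort.
#' @export
writePhenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
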