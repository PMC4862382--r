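## Permutation pathway-crosstalk network.
##
## Crosstalk between two enriched pathways is scored as the number of PPI
## edges with one endpoint in each pathway's observed gene set (a gene
## shared by both sets contributes through its incident edges; self-pairs
## of a pathway with itself are never formed). The null rescoring draws,
## for each permutation, two random gene sets of the same sizes from the
## PPI node universe.

# Count edges (u, v) with u in A, v in B or vice versa; u == v impossible
# in a simple graph.
.crossEdgeCount <- function(from, to, setA, setB) {
  inA1 <- from %in% setA; inB1 <- from %in% setB
  inA2 <- to %in% setA; inB2 <- to %in% setB
  sum((inA1 & inB2) | (inB1 & inA2))
}

#' Permutation-based pathway crosstalk network
#'
#' For every pair of enriched pathways, scores the protein-protein
#' interaction between their observed gene sets and assesses it against a
#' size-matched permutation null: `nPerm` times, two random gene sets of
#' the same sizes (after intersection with the PPI node universe) are
#' drawn from the PPI nodes and rescored. The permutation P-value is
#' `(1 + #{null >= observed}) / (nPerm + 1)`; pairs with
#' `perm_p < alpha` are retained as network edges. Pathway genes absent
#' from the PPI simply contribute no edges.
#'
#' @param pathwayGenes named list (one element per enriched pathway) of
#'   observed gene-id vectors, typically the `genes` column of
#'   [hypergeomEnrich()] output restricted to significant rows.
#' @param ppi data.frame with columns `from`, `to` (undirected edges), as
#'   from [readPpiEdges()].
#' @param nPerm number of permutations (default 1000).
#' @param alpha retention cutoff on the permutation P-value (default
#'   0.05).
#' @param seed optional integer seed for the permutation draws.
#' @return data.frame with `pathway_a`, `pathway_b`, `score`, `perm_p`,
#'   `retained`, one row per unordered pathway pair (no self-pairs).
#'   Results are invariant to pathway input order and reproducible under a
#'   fixed seed.
#' @export
crosstalkNetwork <- function(pathwayGenes, ppi, nPerm = 1000, alpha = 0.05,
                             seed = NULL) {
  stopifnot(is.list(pathwayGenes), !is.null(names(pathwayGenes)))
  if (length(pathwayGenes) < 2L)
    stop("need at least two enriched pathways")
  stopifnot(all(c("from", "to") %in% names(ppi)))
  if (!is.null(seed)) set.seed(seed)
  # canonical order: output independent of input pathway order
  pathwayGenes <- pathwayGenes[order(names(pathwayGenes))]
  nodes <- unique(c(ppi$from, ppi$to))
  from <- ppi$from; to <- ppi$to
  sets <- lapply(pathwayGenes, function(g) intersect(unique(g), nodes))
  nms <- names(pathwayGenes)
  pairs <- utils::combn(seq_along(sets), 2)
  rows <- vector("list", ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    obs <- .crossEdgeCount(from, to, sets[[i]], sets[[j]])
    na <- length(sets[[i]]); nb <- length(sets[[j]])
    exceed <- 0L
    if (na > 0L && nb > 0L && length(nodes) >= max(na, nb)) {
      for (b in seq_len(nPerm)) {
        sa <- sample(nodes, na)
        sb <- sample(nodes, nb)
        if (.crossEdgeCount(from, to, sa, sb) >= obs) exceed <- exceed + 1L
      }
    } else {
      exceed <- nPerm  # degenerate pair: nothing to score
    }
    permP <- (1 + exceed) / (nPerm + 1)
    rows[[c]] <- data.frame(pathway_a = nms[i], pathway_b = nms[j],
                            score = obs, perm_p = permP,
                            retained = permP < alpha,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
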