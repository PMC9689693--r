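#' Map loci or regions to nearby genes
#'
#' A gene is hit by a locus (or region) when the gene interval extended by
#' \code{flank} bases on each side (clipped at position 1) contains the locus
#' position (or intersects the region). The boundary is inclusive: a gene
#' edge exactly \code{flank} bases away is a hit. Overlap testing goes
#' through \pkg{GenomicRanges}.
#'
#' @param loci data.frame with \code{chrom} and either \code{pos} (point
#'   loci, 1-based) or \code{start}/\code{end} (regions; 0-based half-open as
#'   produced by \code{\link{link_regions}}).
#' @param genes gene models from \code{\link{read_genes}} (1-based inclusive).
#' @param flank flank in bp on each side; default 50000 (50 kb). With
#'   \code{flank = 0} this is plain interval overlap.
#' @return data.frame of hits: \code{gene_id}, \code{anchor} (row index into
#'   \code{loci}), \code{chrom}, \code{distance_bp} (0 when overlapping the
#'   unextended gene, else the gap to the nearest gene edge). Duplicate
#'   (gene, anchor) hits are deduplicated.
#' @export
genes_near_loci <- function(loci, genes, flank = 50000) {
  empty <- data.frame(gene_id = character(), anchor = integer(),
                      chrom = character(), distance_bp = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(loci) || !nrow(genes)) return(empty)
  if (!is.null(loci$pos)) {
    ls <- loci$pos; le <- loci$pos
  } else {
    ls <- loci$start + 1  # BED-like to 1-based inclusive
    le <- loci$end
  }
  lgr <- GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(ls, le))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(pmax(1, genes$start - flank),
                                                 genes$end + flank))
  ov <- GenomicRanges::findOverlaps(lgr, ggr)
  if (!length(ov)) return(empty)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  gap <- pmax(0, pmax(genes$start[si] - le[qi], ls[qi] - genes$end[si]))
  out <- data.frame(gene_id = genes$gene_id[si], anchor = qi,
                    chrom = genes$chrom[si], distance_bp = gap,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("gene_id", "anchor")]), , drop = FALSE]
  out <- out[order(out$anchor, out$distance_bp, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of each term's overlap with a gene list
#' against a background universe, with Benjamini-Hochberg adjustment across
#' the tested terms. Terms with no background genes or no hits are skipped.
#'
#' @param gene_list character vector of candidate genes (must be a subset of
#'   \code{background}).
#' @param term_map data.frame with columns \code{term_id}, \code{term_name},
#'   \code{gene_id} (one row per term-gene assignment), or a path to such a
#'   TSV.
#' @param background character vector: the gene universe.
#' @return data.frame: \code{term_id}, \code{term_name}, \code{k} (hits in
#'   list), \code{K} (term size in background), \code{n} (list size),
#'   \code{N} (background size), \code{p_value}, \code{q_value}; sorted by
#'   p-value.
#' @export
enrich <- function(gene_list, term_map, background) {
  if (is.character(term_map) && length(term_map) == 1L)
    term_map <- utils::read.table(term_map, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  stopifnot(all(c("term_id", "gene_id") %in% names(term_map)))
  if (is.null(term_map$term_name)) term_map$term_name <- term_map$term_id
  background <- unique(background)
  if (!length(background)) stop("empty background gene universe")
  gene_list <- unique(gene_list)
  extra <- setdiff(gene_list, background)
  if (length(extra))
    stop("gene_list not a subset of background: ", extra[1])
  term_map <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(gene_list)
  terms <- split(term_map, term_map$term_id)
  rows <- lapply(terms, function(tm) {
    gs <- unique(tm$gene_id)
    K <- length(gs)
    k <- length(intersect(gs, gene_list))
    if (K == 0L || k == 0L) return(NULL)
    data.frame(term_id = tm$term_id[1], term_name = tm$term_name[1],
               k = k, K = K, n = n, N = N,
               p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(), q_value = numeric()))
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Unique-gene counts per comparison and method
#'
#' Tabulates unique gene hits per (comparison, method) cell; a gene hit by
#' several methods is counted once in each method's cell (per-cell, not
#' global, deduplication).
#'
#' @param hits_by_comparison nested list:
#'   \code{hits_by_comparison[[comparison]][[method]]} is a character vector
#'   of gene ids.
#' @return data.frame with one row per comparison and one column per method.
#' @export
report_gene_counts <- function(hits_by_comparison) {
  comps <- names(hits_by_comparison)
  methods <- unique(unlist(lapply(hits_by_comparison, names)))
  out <- data.frame(comparison = comps, stringsAsFactors = FALSE)
  for (m in methods)
    out[[m]] <- vapply(comps, function(cmp) {
      g <- hits_by_comparison[[cmp]][[m]]
      if (is.null(g)) NA_integer_ else length(unique(g))
    }, 1L)
  out
}
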