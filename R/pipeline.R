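#' Pipeline run configuration
#'
#' Bundles the analysis parameters with their conventional defaults: MAF
#' cutoff 0.05, top 1\% Fst outliers, 10 kb rIBD bins, 2-sd significance,
#' 50 kb gene-mapping flanks.
#'
#' @param vcf path to the phased cohort VCF.
#' @param pops path to the two-column population map.
#' @param genes optional gene-model file (GFF3/BED).
#' @param ibd_file optional precomputed IBD segment file; when given the
#'   detector is skipped.
#' @param maf MAF threshold (default 0.05).
#' @param fst_fraction outlier tail fraction (default 0.01).
#' @param bin_size rIBD bin size in bp (default 10000).
#' @param sd_threshold rIBD significance threshold in sd units (default 2).
#' @param flank gene-mapping flank in bp (default 50000).
#' @param min_snps,min_bp IBD detector minima (defaults 100 / 100000).
#' @param mode rIBD standardization mode (default "pooled").
#' @param seed integer seed recorded in the manifest (default 1).
#' @param outdir output directory (default "introscan_out").
#' @return A \code{run_config} list.
#' @export
run_config <- function(vcf, pops, genes = NULL, ibd_file = NULL,
                       maf = 0.05, fst_fraction = 0.01, bin_size = 10000,
                       sd_threshold = 2.0, flank = 50000,
                       min_snps = 100, min_bp = 100000, mode = "pooled",
                       seed = 1, outdir = "introscan_out") {
  structure(list(vcf = vcf, pops = pops, genes = genes, ibd_file = ibd_file,
                 maf = maf, fst_fraction = fst_fraction, bin_size = bin_size,
                 sd_threshold = sd_threshold, flank = flank,
                 min_snps = min_snps, min_bp = min_bp, mode = mode,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
}

load_inputs <- function(cfg) {
  hs <- stage("read_vcf", read_vcf(cfg$vcf, cfg$pops))
  n_raw <- nrow(hs$variants)
  hs <- stage("filter_maf", filter_maf(hs, cfg$maf))
  genes <- NULL
  if (!is.null(cfg$genes)) {
    if (file.exists(cfg$genes)) genes <- stage("read_genes", read_genes(cfg$genes))
    else warning("gene file not found; gene mapping skipped: ", cfg$genes)
  }
  list(hs = hs, genes = genes, n_raw = n_raw)
}

write_manifest <- function(cfg, outdir, extra = list()) {
  inputs <- list()
  for (f in c("vcf", "pops", "genes", "ibd_file"))
    if (!is.null(cfg[[f]]) && file.exists(cfg[[f]]))
      inputs[[f]] <- list(path = cfg[[f]],
                          md5 = unname(tools::md5sum(cfg[[f]])))
  manifest <- c(list(package = "introscan",
                     version = as.character(utils::packageVersion("introscan")),
                     parameters = unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)],
                     inputs = inputs), extra)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the Fst selection-signature pipeline
#'
#' MAF filter, per-site Fst of the hybrid against each parent, top-fraction
#' outlier selection, gene mapping with flanks, and a per-comparison gene
#' count table. Writes Manhattan TSVs, a gene-hit TSV, a counts TSV and a
#' manifest into \code{cfg$outdir}.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return The \code{\link{fst_scan}} object, invisibly, with the gene hits
#'   attached as attribute \code{"gene_hits"}.
#' @export
run_fst_pipeline <- function(cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_inputs(cfg)
  scan <- stage("fst_scan", fst_scan(inp$hs, fraction = cfg$fst_fraction))
  hits_by <- list(); gene_hits <- list()
  for (nm in names(scan$results)) {
    r <- scan$results[[nm]]
    manhattan_table(r, file.path(cfg$outdir, paste0("fst_", nm, ".tsv")))
    if (!is.null(inp$genes)) {
      loci <- r[r$is_outlier, c("chrom", "pos")]
      h <- stage("genes_near_loci",
                 genes_near_loci(loci, inp$genes, flank = cfg$flank))
      gene_hits[[nm]] <- h
      hits_by[[nm]] <- list(fst = unique(h$gene_id))
    } else hits_by[[nm]] <- list(fst = NULL)
  }
  counts <- report_gene_counts(hits_by)
  utils::write.table(counts, file.path(cfg$outdir, "fst_gene_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(gene_hits)) {
    all_hits <- do.call(rbind, Map(function(nm, h)
      cbind(comparison = nm, h), names(gene_hits), gene_hits))
    utils::write.table(all_hits, file.path(cfg$outdir, "fst_gene_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(cfg, cfg$outdir,
                 list(stage = "fst", n_sites_raw = inp$n_raw,
                      n_sites_maf = nrow(inp$hs$variants)))
  attr(scan, "gene_hits") <- gene_hits
  attr(scan, "gene_counts") <- counts
  invisible(scan)
}

#' Run the rIBD introgression pipeline
#'
#' IBD detection (or import), 10 kb binning, nIBD/rIBD, genome-wide
#' standardization and significance calling, region linking and gene
#' mapping. Writes the per-bin TSV, region BED, summary JSON and a manifest
#' into \code{cfg$outdir}.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return The \code{\link{ribd_scan}} object, invisibly.
#' @export
run_ribd_pipeline <- function(cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_inputs(cfg)
  segments <- NULL
  if (!is.null(cfg$ibd_file))
    segments <- stage("import_ibd", import_ibd(cfg$ibd_file, cfg$pops))
  scan <- stage("ribd_scan",
                ribd_scan(inp$hs, bin_size = cfg$bin_size,
                          sd_threshold = cfg$sd_threshold,
                          min_snps = cfg$min_snps, min_bp = cfg$min_bp,
                          segments = segments, mode = cfg$mode,
                          genes = inp$genes, flank = cfg$flank))
  write_ribd_outputs(scan, cfg$outdir)
  write_manifest(cfg, cfg$outdir,
                 list(stage = "ribd", n_sites_raw = inp$n_raw,
                      n_sites_maf = nrow(inp$hs$variants),
                      n_segments = nrow(scan$segments)))
  invisible(scan)
}

#' Run both pipelines
#'
#' @param cfg a \code{\link{run_config}}.
#' @return list with elements \code{fst} and \code{ribd}, invisibly.
#' @export
run_all <- function(cfg) {
  fst <- run_fst_pipeline(cfg)
  ribd <- run_ribd_pipeline(cfg)
  invisible(list(fst = fst, ribd = ribd))
}

#' Jaccard overlap between called regions and a truth interval
#'
#' Utility for simulation studies: Jaccard index between a truth interval
#' and the union of called regions of the given direction on the truth
#' chromosome.
#'
#' @param regions region data.frame from \code{\link{link_regions}}.
#' @param truth_chrom,truth_start,truth_end the planted interval (0-based
#'   half-open).
#' @param direction which regions to consider (default "PARENT_A").
#' @return Jaccard index in [0, 1].
#' @export
region_jaccard <- function(regions, truth_chrom, truth_start, truth_end,
                           direction = "PARENT_A") {
  r <- regions[regions$direction == direction & regions$chrom == truth_chrom, ,
               drop = FALSE]
  if (!nrow(r)) return(0)
  inter <- sum(pmax(0, pmin(r$end, truth_end) - pmax(r$start, truth_start)))
  union <- sum(r$end - r$start) + (truth_end - truth_start) - inter
  inter / union
}
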