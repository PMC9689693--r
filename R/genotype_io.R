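POP_LEVELS <- c("HYBRID", "PARENT_A", "PARENT_B")

#' Construct a haplotype set
#'
#' A \code{haplotype_set} holds phased biallelic genotypes for a three-labelled
#' cohort: a hybrid (composite) population and its two parental populations.
#' Alleles are stored as a 0/1 integer matrix with one row per haplotype (two
#' per diploid sample) and one column per variant; variants are sorted by
#' (chromosome, position) and positions are strictly increasing within a
#' chromosome.
#'
#' @param variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{id}, \code{ref}, \code{alt}; one row per biallelic SNP.
#' @param alleles integer matrix in \{0,1\}, \code{2 * n_samples} rows,
#'   \code{nrow(variants)} columns. Row \code{2i-1} and \code{2i} are the two
#'   haplotypes of sample \code{i}.
#' @param samples character vector of sample identifiers.
#' @param pop_labels named character vector mapping every sample to one of
#'   \code{"HYBRID"}, \code{"PARENT_A"}, \code{"PARENT_B"}.
#' @return An object of class \code{haplotype_set}.
#' @export
haplotype_set <- function(variants, alleles, samples, pop_labels) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos") %in% names(variants)))
  if (is.null(variants$id))  variants$id  <- paste0(variants$chrom, "_", variants$pos)
  if (is.null(variants$ref)) variants$ref <- "A"
  if (is.null(variants$alt)) variants$alt <- "C"
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != 2L * length(samples))
    stop("haplotype count must be 2 x sample count")
  if (ncol(alleles) != nrow(variants))
    stop("allele matrix has ", ncol(alleles), " columns but ", nrow(variants), " variants")
  if (anyNA(alleles))
    stop("allele matrix contains missing values; phased, imputed input is required")
  if (!all(alleles %in% c(0L, 1L)))
    stop("allele matrix must contain only 0/1")
  miss <- setdiff(samples, names(pop_labels))
  if (length(miss))
    stop("samples missing from population map: ", paste(miss, collapse = ", "))
  pop_labels <- pop_labels[samples]
  bad <- setdiff(unique(pop_labels), POP_LEVELS)
  if (length(bad))
    stop("unknown population label(s) ", paste(bad, collapse = ", "),
         "; allowed labels: ", paste(POP_LEVELS, collapse = ", "))
  # enforce variant ordering invariants
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  alleles <- alleles[, o, drop = FALSE]
  dup <- duplicated(variants[c("chrom", "pos")])
  if (any(dup))
    stop("duplicate (chrom, pos): ", variants$chrom[dup][1], ":", variants$pos[dup][1])
  rownames(variants) <- NULL
  rownames(alleles) <- paste0(rep(samples, each = 2L), "_", rep(1:2, length(samples)))
  structure(list(variants = variants, alleles = alleles,
                 samples = samples, pop_labels = pop_labels),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", length(x$samples), "samples (",
      paste(sprintf("%s=%d", POP_LEVELS, vapply(POP_LEVELS, function(p)
        sum(x$pop_labels == p), 1L)), collapse = ", "), ")\n")
  cat("  ", nrow(x$variants), "biallelic SNPs on",
      length(unique(x$variants$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.haplotype_set <- function(x) dim(x$alleles)

# haplotype row indices of a population
hap_rows <- function(hs, pop) {
  idx <- which(hs$pop_labels == pop)
  sort(c(2L * idx - 1L, 2L * idx))
}

# diploid sample names of a population
pop_samples <- function(hs, pop) hs$samples[hs$pop_labels == pop]

#' Read a two-column population map
#'
#' @param path whitespace-delimited text, two columns: sample id, population
#'   label (\code{HYBRID}, \code{PARENT_A} or \code{PARENT_B}). Accepts gzip.
#' @return Named character vector sample -> population.
#' @export
read_pop_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("sample", "pop"))
  bad <- setdiff(unique(df$pop), POP_LEVELS)
  if (length(bad))
    stop("unknown population label(s) in ", path, ": ",
         paste(bad, collapse = ", "), "; allowed labels: ",
         paste(POP_LEVELS, collapse = ", "))
  stats::setNames(df$pop, df$sample)
}

#' Read phased genotypes from a VCF
#'
#' Parses a VCF 4.x file (optionally gzipped) into a \code{\link{haplotype_set}}.
#' Only biallelic SNPs are retained; multiallelic records and indels are
#' skipped with a reported count. Genotypes must be phased (\code{|}
#' separator) and complete: the first unphased or missing genotype is an
#' error, because downstream IBD detection operates on haplotypes.
#'
#' @param path VCF file.
#' @param pop_map either a path to a two-column population map (see
#'   \code{\link{read_pop_map}}) or an already-parsed named vector.
#' @return A \code{haplotype_set}.
#' @export
read_vcf <- function(path, pop_map) {
  if (is.character(pop_map) && length(pop_map) == 1L && file.exists(pop_map))
    pop_map <- read_pop_map(pop_map)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  unknown <- setdiff(samples, names(pop_map))
  if (length(unknown))
    stop("sample(s) absent from population map: ", paste(unknown, collapse = ", "))

  snp <- fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped)
    message("read_vcf: skipped ", n_skipped, " multiallelic/non-SNP record(s)")
  fix <- fix[snp, , drop = FALSE]
  gt <- gt[snp, , drop = FALSE]

  if (anyNA(gt)) {
    i <- which(is.na(gt), arr.ind = TRUE)[1, ]
    stop("missing genotype at ", fix$CHROM[i[1]], ":", fix$POS[i[1]],
         " sample ", samples[i[2]], "; imputed input is a precondition")
  }
  unphased <- matrix(!grepl("|", gt, fixed = TRUE), nrow = nrow(gt))
  if (any(unphased)) {
    i <- which(unphased, arr.ind = TRUE)[1, ]
    stop("unphased genotype '", gt[i[1], i[2]], "' at ", fix$CHROM[i[1]], ":",
         fix$POS[i[1]], " sample ", samples[i[2]],
         "; phased GT (| separator) is required")
  }
  # gt is sites x samples; expand to haplotypes x sites
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  if (!all(a1 %in% c("0", "1")) || !all(a2 %in% c("0", "1")))
    stop("non-biallelic allele code in GT field")
  n_site <- nrow(gt)
  alleles <- matrix(0L, nrow = 2L * length(samples), ncol = n_site)
  alleles[seq(1L, by = 2L, length.out = length(samples)), ] <- t(a1 == "1")
  alleles[seq(2L, by = 2L, length.out = length(samples)), ] <- t(a2 == "1")
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                     paste0(fix$CHROM, "_", fix$POS), fix$ID),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  hs <- haplotype_set(variants, alleles, samples, pop_map)
  attr(hs, "n_skipped") <- n_skipped
  hs
}

#' Write a haplotype set as a phased VCF
#'
#' @param hs a \code{haplotype_set}.
#' @param path output file; \code{.gz} suffix writes gzip.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(hs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=introscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", hs$samples), collapse = "\t")), con)
  n_s <- length(hs$samples)
  h1 <- hs$alleles[seq(1L, by = 2L, length.out = n_s), , drop = FALSE]
  h2 <- hs$alleles[seq(2L, by = 2L, length.out = n_s), , drop = FALSE]
  gt <- matrix(paste0(t(h1), "|", t(h2)), nrow = ncol(hs$alleles))
  v <- hs$variants
  lines <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                 apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Pooled minor allele frequency per site
#'
#' @param hs a \code{haplotype_set}.
#' @return Numeric vector, \code{min(p, 1 - p)} of the pooled alternate-allele
#'   fraction \code{p} at each site.
#' @export
maf <- function(hs) {
  p <- colMeans(hs$alleles)
  pmin(p, 1 - p)
}

#' Filter sites by minor allele frequency
#'
#' Retains exactly the sites whose pooled MAF (all populations together) is
#' greater than or equal to \code{threshold}; sites with MAF strictly below
#' the threshold are discarded. The default 0.05 is the conventional
#' chip-data cutoff.
#'
#' @param hs a \code{haplotype_set}.
#' @param threshold MAF cutoff in \code{[0, 0.5]}.
#' @return Filtered \code{haplotype_set}.
#' @export
filter_maf <- function(hs, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  keep <- maf(hs) >= threshold
  if (!any(keep))
    stop("no sites pass MAF >= ", threshold, "; lower the threshold")
  haplotype_set(hs$variants[keep, , drop = FALSE],
                hs$alleles[, keep, drop = FALSE],
                hs$samples, hs$pop_labels)
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 input keeps features of type \code{gene} (1-based inclusive as-is);
#' BED input (0-based half-open) is converted to 1-based inclusive
#' coordinates. Both are read through \pkg{rtracklayer}.
#'
#' @param path file ending in \code{.gff3}, \code{.gff}, \code{.bed}
#'   (optionally \code{.gz}).
#' @return data.frame with columns \code{gene_id}, \code{name}, \code{chrom},
#'   \code{start}, \code{end}, sorted by (chrom, start).
#' @export
read_genes <- function(path) {
  base <- sub("\\.gz$", "", path)
  ext <- tolower(tools::file_ext(base))
  if (ext %in% c("gff3", "gff")) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$type) & gr$type == "gene"]
    if (length(gr) == 0L) {
      warning("no 'gene' features in ", path)
      return(data.frame(gene_id = character(), name = character(),
                        chrom = character(), start = integer(), end = integer()))
    }
    id <- if (!is.null(gr$ID)) gr$ID else paste0("gene", seq_along(gr))
    nm <- if (!is.null(gr$Name)) gr$Name else rep("", length(gr))
    df <- data.frame(gene_id = as.character(id),
                     name = ifelse(is.na(nm), "", as.character(nm)),
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")  # converts to 1-based inclusive
    id <- if (!is.null(gr$name)) as.character(gr$name) else paste0("gene", seq_along(gr))
    df <- data.frame(gene_id = id, name = id,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
  } else {
    stop("unknown gene-model format '.", ext, "'; accepted: .gff3/.gff, .bed")
  }
  stopifnot(all(df$start <= df$end))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}
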