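#' Detect IBD segments between hybrid and parental haplotypes
#'
#' Deterministic exact-match detector: for every cross-population haplotype
#' pair (hybrid x parent-A and hybrid x parent-B) it reports all maximal runs
#' of identical alleles spanning at least \code{min_snps} variants and at
#' least \code{min_bp} bases. Segment coordinates are the positions of the
#' first and last matching variant (1-based inclusive); the base-pair span is
#' \code{end - start + 1}. Intended for error-free phased input (e.g. the
#' package simulator, or imputed chip data); probabilistic detectors' output
#' can be substituted via \code{\link{import_ibd}}.
#'
#' @param hs a \code{\link{haplotype_set}} containing all three populations.
#' @param min_snps minimum variants per segment (>= 2); default 100.
#' @param min_bp minimum base-pair span; default 100000. The defaults
#'   suppress short chance matches at chip-like SNP densities.
#' @return data.frame of segments: \code{chrom}, \code{start}, \code{end},
#'   \code{n_snps}, \code{sample1}, \code{hap1}, \code{sample2}, \code{hap2},
#'   \code{pop_pair} ("HYBRID_PARENT_A" or "HYBRID_PARENT_B"). sample1 is
#'   always the hybrid.
#' @export
detect_ibd <- function(hs, min_snps = 100, min_bp = 100000) {
  stopifnot(min_snps >= 2)
  hyb_idx <- which(hs$pop_labels == "HYBRID")
  if (!length(hyb_idx)) stop("no HYBRID samples")
  out <- vector("list", 0L)
  for (ch in unique(hs$variants$chrom)) {
    sel <- which(hs$variants$chrom == ch)
    if (length(sel) < 2L)
      stop("chromosome ", ch, " has a single variant; cannot detect segments")
    pos <- hs$variants$pos[sel]
    A <- hs$alleles[, sel, drop = FALSE]
    for (par in c("PARENT_A", "PARENT_B")) {
      par_idx <- which(hs$pop_labels == par)
      if (!length(par_idx)) next
      prow <- sort(c(2L * par_idx - 1L, 2L * par_idx))
      P <- A[prow, , drop = FALSE]
      psample <- hs$samples[(prow + 1L) %/% 2L]
      phap <- 2L - (prow %% 2L)
      for (i in hyb_idx) {
        for (hp in 1:2) {
          hrow <- A[2L * i - 2L + hp, ]
          mism <- P != matrix(hrow, nrow(P), length(hrow), byrow = TRUE)
          for (j in seq_len(nrow(P))) {
            segs <- match_runs(which(mism[j, ]), pos, min_snps, min_bp)
            if (is.null(segs)) next
            segs$sample1 <- hs$samples[i]; segs$hap1 <- hp
            segs$sample2 <- psample[j]; segs$hap2 <- phap[j]
            segs$pop_pair <- paste0("HYBRID_", par)
            segs$chrom <- ch
            out[[length(out) + 1L]] <- segs
          }
        }
      }
    }
  }
  if (!length(out)) return(empty_segments())
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start, df$end), c("chrom", "start", "end",
          "n_snps", "sample1", "hap1", "sample2", "hap2", "pop_pair")]
  rownames(df) <- NULL
  df
}

# maximal match runs between consecutive mismatch indices
match_runs <- function(mm, pos, min_snps, min_bp) {
  n <- length(pos)
  bnd <- c(0L, mm, n + 1L)
  from <- bnd[-length(bnd)] + 1L
  to <- bnd[-1] - 1L
  len <- to - from + 1L
  keep <- len >= min_snps
  if (!any(keep)) return(NULL)
  from <- from[keep]; to <- to[keep]
  span <- pos[to] - pos[from] + 1L
  keep2 <- span >= min_bp
  if (!any(keep2)) return(NULL)
  data.frame(start = pos[from[keep2]], end = pos[to[keep2]],
             n_snps = (to - from + 1L)[keep2])
}

empty_segments <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             n_snps = integer(), sample1 = character(), hap1 = integer(),
             sample2 = character(), hap2 = integer(), pop_pair = character(),
             stringsAsFactors = FALSE)
}

#' Import IBD segments from an external detector
#'
#' Reads a tab-delimited segment file in the common refined-IBD/hap-IBD
#' column order: sample1, hap1, sample2, hap2, chrom, start, end and an
#' optional score column. Cross-population pairs are retained (segments
#' involving the hybrid are oriented hybrid-first); within-population
#' segments are dropped with a reported count.
#'
#' @param path segment file (gzip accepted).
#' @param pop_map named vector sample -> population, or a path to one.
#' @return Segment data.frame as from \code{\link{detect_ibd}}
#'   (\code{n_snps} is \code{NA} for imported segments without one).
#' @export
import_ibd <- function(path, pop_map) {
  if (is.character(pop_map) && length(pop_map) == 1L && file.exists(pop_map))
    pop_map <- read_pop_map(pop_map)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 7L) stop("expected >= 7 columns: sample1 hap1 sample2 hap2 chrom start end")
  names(df)[1:7] <- c("sample1", "hap1", "sample2", "hap2", "chrom", "start", "end")
  for (col in c("sample1", "sample2")) {
    unk <- setdiff(df[[col]], names(pop_map))
    if (length(unk)) stop("unknown sample in segment file: ", unk[1])
  }
  bad <- df$end <= df$start
  if (any(bad))
    stop("malformed segment (end <= start) at line ", which(bad)[1])
  if (any(df$sample1 == df$sample2))
    stop("segment pairing a sample with itself at line ",
         which(df$sample1 == df$sample2)[1])
  p1 <- pop_map[df$sample1]; p2 <- pop_map[df$sample2]
  within <- p1 == p2
  if (any(within))
    message("import_ibd: dropped ", sum(within), " within-population segment(s)")
  df <- df[!within, , drop = FALSE]
  p1 <- p1[!within]; p2 <- p2[!within]
  # orient hybrid first where a hybrid is involved
  flip <- p2 == "HYBRID"
  if (any(flip)) {
    tmp_s <- df$sample1[flip]; tmp_h <- df$hap1[flip]
    df$sample1[flip] <- df$sample2[flip]; df$hap1[flip] <- df$hap2[flip]
    df$sample2[flip] <- tmp_s; df$hap2[flip] <- tmp_h
    t <- p1[flip]; p1[flip] <- p2[flip]; p2[flip] <- t
  }
  pair <- paste(pmin(p1, p2), pmax(p1, p2), sep = "_")
  pair[p1 == "HYBRID"] <- paste0("HYBRID_", p2[p1 == "HYBRID"])
  out <- data.frame(chrom = as.character(df$chrom), start = as.integer(df$start),
                    end = as.integer(df$end), n_snps = NA_integer_,
                    sample1 = df$sample1, hap1 = as.integer(df$hap1),
                    sample2 = df$sample2, hap2 = as.integer(df$hap2),
                    pop_pair = pair, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count IBD sharing per genomic bin
#'
#' Divides each chromosome into half-open bins \code{[k*bin_size,
#' (k+1)*bin_size)} (0-based) and, for each bin and each hybrid-parent
#' comparison, counts cIBD: the number of distinct (hybrid sample, parent
#' sample) pairs having at least one IBD segment overlapping the bin (a pair
#' is counted at most once per bin regardless of how many of its segments or
#' haplotype combinations overlap). tIBD is the total number of pairs,
#' \code{n_hybrid * n_parent}, constant across bins; nIBD = cIBD / tIBD.
#'
#' @param segments segment data.frame (\code{\link{detect_ibd}} or
#'   \code{\link{import_ibd}}).
#' @param sample_sizes named vector with elements \code{HYBRID},
#'   \code{PARENT_A}, \code{PARENT_B} (diploid counts, all > 0).
#' @param bin_size bin length in bp; default 10000 (10 kb).
#' @param chrom_lengths named vector of chromosome lengths in bp; defaults to
#'   the largest segment end per chromosome. Bins with no sharing are kept
#'   (they carry cIBD = 0 and enter the genome-wide standardization).
#' @param count segment-level counting (\code{"segments"}) is available as a
#'   sensitivity mode: cIBD then counts overlapping segments rather than
#'   distinct pairs and nIBD may exceed 1. Default \code{"pairs"}.
#' @return data.frame (one row per bin): \code{chrom}, \code{bin_start},
#'   \code{bin_end}, \code{cIBD_A}, \code{cIBD_B}, \code{tIBD_A},
#'   \code{tIBD_B}, \code{nIBD_A}, \code{nIBD_B}.
#' @export
bin_counts <- function(segments, sample_sizes, bin_size = 10000,
                       chrom_lengths = NULL, count = c("pairs", "segments")) {
  count <- match.arg(count)
  for (p in POP_LEVELS)
    if (is.na(sample_sizes[p]) || sample_sizes[p] <= 0)
      stop("sample size for ", p, " must be positive")
  tA <- unname(sample_sizes["HYBRID"] * sample_sizes["PARENT_A"])
  tB <- unname(sample_sizes["HYBRID"] * sample_sizes["PARENT_B"])
  if (is.null(chrom_lengths)) {
    if (!nrow(segments)) stop("no segments and no chrom_lengths given")
    chrom_lengths <- tapply(segments$end, segments$chrom, max)
  }
  chroms <- names(chrom_lengths)
  bins <- do.call(rbind, lapply(chroms, function(ch) {
    nb <- ceiling(chrom_lengths[[ch]] / bin_size)
    data.frame(chrom = ch, bin_start = as.numeric(bin_size) * (seq_len(nb) - 1L),
               stringsAsFactors = FALSE)
  }))
  bins$bin_end <- bins$bin_start + bin_size
  key <- paste(bins$chrom, bins$bin_start)

  count_one <- function(pp) {
    seg <- segments[segments$pop_pair == pp, , drop = FALSE]
    cnt <- integer(nrow(bins))
    if (!nrow(seg)) return(cnt)
    # expand each segment into the bin indices it overlaps
    b0 <- (seg$start - 1L) %/% bin_size
    b1 <- (seg$end - 1L) %/% bin_size
    nb <- b1 - b0 + 1L
    rep_i <- rep(seq_len(nrow(seg)), nb)
    bin_i <- unlist(lapply(seq_len(nrow(seg)), function(k) b0[k]:b1[k]),
                    use.names = FALSE)
    ids <- if (count == "pairs")
      paste(seg$sample1[rep_i], seg$sample2[rep_i]) else rep_i
    gi <- match(paste(seg$chrom[rep_i], as.numeric(bin_i) * bin_size), key)
    ok <- !is.na(gi)  # segments may extend past declared chrom length
    dedup <- !duplicated(paste(gi[ok], ids[ok]))
    tab <- tabulate(gi[ok][dedup], nbins = nrow(bins))
    cnt + tab
  }
  bins$cIBD_A <- count_one("HYBRID_PARENT_A")
  bins$cIBD_B <- count_one("HYBRID_PARENT_B")
  bins$tIBD_A <- tA
  bins$tIBD_B <- tB
  bins$nIBD_A <- bins$cIBD_A / tA
  bins$nIBD_B <- bins$cIBD_B / tB
  rownames(bins) <- NULL
  bins
}

#' Relative IBD per bin
#'
#' rIBD = nIBD(hybrid, parent A) - nIBD(hybrid, parent B). Positive values
#' indicate local haplotype sharing with parent A in excess of parent B,
#' i.e. introgression from parent A into the hybrid.
#'
#' @param bins output of \code{\link{bin_counts}}.
#' @return \code{bins} with an added \code{ribd} column.
#' @export
ribd_track <- function(bins) {
  stopifnot(all(c("nIBD_A", "nIBD_B") %in% names(bins)))
  if (anyNA(bins$nIBD_A) || anyNA(bins$nIBD_B))
    stop("nIBD tracks incomplete: bin mismatch between comparisons")
  bins$ribd <- bins$nIBD_A - bins$nIBD_B
  bins
}

#' Standardize rIBD and call significant bins
#'
#' Default mode (\code{"pooled"}): the signed rIBD track is z-scored once
#' genome-wide, \code{z = (ribd - mean) / sd} with the population sd
#' (divisor N, deterministic), and the two introgression directions are
#' called from the two tails: \code{z > sd_threshold} is parent-A-ward,
#' \code{z < -sd_threshold} parent-B-ward. Mode \code{"separate"} z-scores
#' the nIBD_A and nIBD_B tracks separately and takes \code{z = z_A - z_B},
#' the alternative reading of per-group standardization.
#'
#' @param bins output of \code{\link{ribd_track}}.
#' @param sd_threshold significance threshold in sd units; default 2.
#' @param mode \code{"pooled"} (default) or \code{"separate"}.
#' @return \code{bins} with \code{z}, \code{significant}, \code{direction}
#'   (\code{"PARENT_A"}, \code{"PARENT_B"} or \code{"none"}) columns.
#' @export
standardize_and_call <- function(bins, sd_threshold = 2.0,
                                 mode = c("pooled", "separate")) {
  mode <- match.arg(mode)
  if (nrow(bins) < 2L) stop("need >= 2 bins to standardize")
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  if (mode == "pooled") {
    s <- sd_pop(bins$ribd)
    if (s == 0) stop("rIBD track is constant; cannot standardize")
    bins$z <- (bins$ribd - mean(bins$ribd)) / s
  } else {
    sA <- sd_pop(bins$nIBD_A); sB <- sd_pop(bins$nIBD_B)
    if (sA == 0 || sB == 0) stop("an nIBD track is constant; cannot standardize")
    bins$z <- (bins$nIBD_A - mean(bins$nIBD_A)) / sA -
      (bins$nIBD_B - mean(bins$nIBD_B)) / sB
  }
  bins$significant <- abs(bins$z) > sd_threshold
  bins$direction <- ifelse(!bins$significant, "none",
                           ifelse(bins$z > 0, "PARENT_A", "PARENT_B"))
  bins
}

#' Link significant bins into introgression regions
#'
#' Merges maximal runs of genomically adjacent significant bins sharing the
#' same direction into regions. Region coordinates are 0-based half-open
#' (BED-like): start of the first bin to end of the last, so
#' \code{length_bp = end - start = n_bins * bin_size}. Runs never cross a
#' chromosome boundary, and adjacent bins of opposite direction start a new
#' region.
#'
#' @param bins output of \code{\link{standardize_and_call}}, sorted by
#'   (chrom, bin_start).
#' @return data.frame of regions: \code{chrom}, \code{start}, \code{end},
#'   \code{n_bins}, \code{length_bp}, \code{direction}, \code{mean_z}.
#' @export
link_regions <- function(bins) {
  bins <- bins[order(bins$chrom, bins$bin_start), , drop = FALSE]
  sig <- bins[bins$significant, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_bins = integer(), length_bp = numeric(),
                      direction = character(), mean_z = numeric(),
                      stringsAsFactors = FALSE))
  bin_size <- bins$bin_end[1] - bins$bin_start[1]
  new_run <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                 sig$bin_start[-1] != sig$bin_end[-nrow(sig)] |
                 sig$direction[-1] != sig$direction[-nrow(sig)])
  grp <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(sig, grp), function(g) {
    data.frame(chrom = g$chrom[1], start = g$bin_start[1],
               end = g$bin_end[nrow(g)], n_bins = nrow(g),
               length_bp = g$bin_end[nrow(g)] - g$bin_start[1],
               direction = g$direction[1], mean_z = mean(g$z),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-direction region summary
#'
#' @param regions output of \code{\link{link_regions}}.
#' @return list keyed by direction with \code{n_regions} and
#'   \code{total_bases}.
#' @export
region_summary <- function(regions) {
  out <- list()
  for (d in c("PARENT_A", "PARENT_B")) {
    r <- regions[regions$direction == d, , drop = FALSE]
    out[[d]] <- list(n_regions = nrow(r), total_bases = sum(r$length_bp))
  }
  out
}

#' rIBD introgression scan
#'
#' End-to-end relative-IBD analysis of a hybrid population against its two
#' parents: IBD segment detection (or import), 10 kb binning of pair-level
#' sharing, nIBD/rIBD computation, genome-wide z-standardization with a
#' 2-sd significance call, and linking of consecutive significant bins into
#' introgression regions.
#'
#' @param hs a \code{\link{haplotype_set}}.
#' @param bin_size bin length in bp (default 10000).
#' @param sd_threshold significance threshold in sd units (default 2).
#' @param min_snps,min_bp IBD detector settings (see \code{\link{detect_ibd}}).
#' @param segments optional precomputed segment data.frame (e.g. from
#'   \code{\link{import_ibd}}); skips the detector.
#' @param chrom_lengths optional named chromosome lengths (bp); defaults to
#'   the last variant position per chromosome.
#' @param mode standardization mode, see \code{\link{standardize_and_call}}.
#' @param genes optional gene models (\code{\link{read_genes}}) used to list
#'   genes per region with \code{flank}.
#' @param flank gene-mapping flank in bp (default 50000).
#' @return Object of class \code{ribd_scan}: list with \code{segments},
#'   \code{bins}, \code{regions}, \code{summary} and the parameters used.
#' @export
ribd_scan <- function(hs, bin_size = 10000, sd_threshold = 2.0,
                      min_snps = 100, min_bp = 100000, segments = NULL,
                      chrom_lengths = NULL, mode = "pooled",
                      genes = NULL, flank = 50000) {
  if (is.null(segments))
    segments <- detect_ibd(hs, min_snps = min_snps, min_bp = min_bp)
  sizes <- vapply(POP_LEVELS, function(p) sum(hs$pop_labels == p), 1L)
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(hs$variants$pos, hs$variants$chrom, max)
  bins <- bin_counts(segments, sizes, bin_size = bin_size,
                     chrom_lengths = chrom_lengths)
  bins <- standardize_and_call(ribd_track(bins), sd_threshold = sd_threshold,
                               mode = mode)
  regions <- link_regions(bins)
  smry <- region_summary(regions)
  if (!is.null(genes) && nrow(regions)) {
    hits <- genes_near_loci(regions, genes, flank = flank)
    regions$genes <- vapply(seq_len(nrow(regions)), function(i)
      paste(sort(unique(hits$gene_id[hits$anchor == i])), collapse = ","), "")
    for (d in c("PARENT_A", "PARENT_B"))
      smry[[d]]$n_genes <- length(unique(unlist(
        strsplit(regions$genes[regions$direction == d], ",", fixed = TRUE))))
  }
  structure(list(segments = segments, bins = bins, regions = regions,
                 summary = smry, sample_sizes = sizes,
                 params = list(bin_size = bin_size, sd_threshold = sd_threshold,
                               min_snps = min_snps, min_bp = min_bp,
                               mode = mode, flank = flank)),
            class = "ribd_scan")
}

#' @export
print.ribd_scan <- function(x, ...) {
  cat("rIBD scan:", nrow(x$segments), "IBD segments,", nrow(x$bins),
      "bins of", x$params$bin_size, "bp\n")
  for (d in c("PARENT_A", "PARENT_B")) {
    s <- x$summary[[d]]
    cat(sprintf("  %s -> HYBRID: %d region(s), %s bases%s\n", d, s$n_regions,
                format(s$total_bases, big.mark = ","),
                if (!is.null(s$n_genes)) paste0(", ", s$n_genes, " gene(s)") else ""))
  }
  invisible(x)
}

#' @export
summary.ribd_scan <- function(object, ...) object$summary

#' Genome-wide rIBD track plot
#'
#' @param x a \code{ribd_scan}.
#' @param ... passed to \code{plot}.
#' @export
plot.ribd_scan <- function(x, ...) {
  b <- x$bins
  chroms <- unique(b$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch) max(b$bin_end[b$chrom == ch]), 0)))
  gx <- b$bin_start + offs[match(b$chrom, chroms)]
  graphics::plot(gx, b$ribd, type = "h",
                 col = ifelse(b$significant, "firebrick", "grey60"),
                 xlab = "genome position (bp)", ylab = "rIBD",
                 main = "relative IBD (positive: parent A -> hybrid)", ...)
  graphics::abline(h = 0)
  invisible(x)
}

#' Write rIBD scan outputs
#'
#' Writes the per-bin TSV, a BED of called regions and a JSON summary.
#'
#' @param x a \code{ribd_scan}.
#' @param dir output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_ribd_outputs <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bins_f <- file.path(dir, "ribd_bins.tsv")
  utils::write.table(format(x$bins, scientific = FALSE, trim = TRUE),
                     bins_f, sep = "\t", quote = FALSE, row.names = FALSE)
  bed_f <- file.path(dir, "ribd_regions.bed")
  r <- x$regions
  bed <- data.frame(chrom = r$chrom, start = format(r$start, scientific = FALSE, trim = TRUE),
                    end = format(r$end, scientific = FALSE, trim = TRUE),
                    name = r$direction, score = round(r$mean_z, 3))
  utils::write.table(bed, bed_f, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  json_f <- file.path(dir, "ribd_summary.json")
  jsonlite::write_json(x$summary, json_f, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(bins = bins_f, regions = bed_f, summary = json_f))
}
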