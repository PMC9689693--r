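#' Simulation configuration
#'
#' Parameters of the synthetic three-population cohort: two parental
#' populations diverged under the Balding-Nichols model to a target Fst, and
#' a hybrid whose haplotypes are recombinant mosaics copied from actual
#' parental haplotypes, optionally with planted regions of excess
#' single-parent ancestry.
#'
#' @param n_parentA,n_parentB,n_hybrid diploid sample counts (default 30 each).
#' @param n_snps SNPs per chromosome (default 5000).
#' @param n_chrom number of chromosomes (default 2).
#' @param chrom_len chromosome length in bp (default 1e7).
#' @param fst_target Balding-Nichols divergence parameter F in (0, 1)
#'   (default 0.2); the expected Fst between the parents.
#' @param admix_prop expected parent-A ancestry fraction of hybrid
#'   haplotypes, in (0, 1) (default 0.5, a balanced composite).
#' @param tract_mean_bp mean ancestry-tract length in bp (default 1e6).
#' @param planted optional data.frame of planted introgression intervals:
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open bp),
#'   \code{direction} ("PARENT_A"/"PARENT_B"), \code{ancestry_prob} —
#'   the probability that a hybrid tract inside the interval carries the
#'   stated parent's ancestry.
#' @param seed integer RNG seed (default 1).
#' @return Object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_parentA = 30, n_parentB = 30, n_hybrid = 30,
                       n_snps = 5000, n_chrom = 2, chrom_len = 1e7,
                       fst_target = 0.2, admix_prop = 0.5,
                       tract_mean_bp = 1e6, planted = NULL, seed = 1) {
  stopifnot(n_parentA > 0, n_parentB > 0, n_hybrid > 0, n_snps > 1,
            n_chrom > 0, chrom_len > 0, tract_mean_bp > 0)
  if (fst_target <= 0 || fst_target >= 1)
    stop("fst_target must be in (0, 1)")
  if (admix_prop <= 0 || admix_prop >= 1)
    stop("admix_prop must be in (0, 1)")
  chroms <- paste0("chr", seq_len(n_chrom))
  if (!is.null(planted)) {
    planted <- as.data.frame(planted, stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "start", "end", "direction", "ancestry_prob")
                  %in% names(planted)))
    if (!all(planted$chrom %in% chroms))
      stop("planted region on unknown chromosome")
    if (any(planted$start < 0 | planted$end > chrom_len | planted$start >= planted$end))
      stop("planted region outside chromosome bounds")
    stopifnot(all(planted$direction %in% c("PARENT_A", "PARENT_B")),
              all(planted$ancestry_prob >= 0 & planted$ancestry_prob <= 1))
  }
  structure(list(n_parentA = n_parentA, n_parentB = n_parentB,
                 n_hybrid = n_hybrid, n_snps = n_snps, n_chrom = n_chrom,
                 chrom_len = chrom_len, chroms = chroms,
                 fst_target = fst_target, admix_prop = admix_prop,
                 tract_mean_bp = tract_mean_bp, planted = planted,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_hybrid, "hybrid +", x$n_parentA, "+", x$n_parentB,
      "parent diploids;", x$n_chrom, "x", format(x$chrom_len, big.mark = ","),
      "bp,", x$n_snps, "SNPs/chrom\n")
  cat("  F target", x$fst_target, "| admix", x$admix_prop, "| tract mean",
      format(x$tract_mean_bp, big.mark = ","), "bp | seed", x$seed, "\n")
  if (!is.null(x$planted)) cat("  planted regions:", nrow(x$planted), "\n")
  invisible(x)
}

#' Simulate the two parental populations
#'
#' Balding-Nichols divergence: per SNP an ancestral frequency
#' \code{p0 ~ Uniform(0.05, 0.95)}; each parental population's frequency is
#' drawn from \code{Beta(p0 (1-F)/F, (1-p0)(1-F)/F)}, which has mean
#' \code{p0} and variance \code{F p0 (1-p0)}, giving expected Fst F between
#' the populations. Haplotype alleles are independent Bernoulli draws at the
#' population frequency (no background LD; see the package vignette for why
#' this is acceptable here). Deterministic under \code{cfg$seed}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{hs} (a \code{\link{haplotype_set}} of the two
#'   parental populations) and \code{freqs} (per-chromosome matrices of
#'   p0/pA/pB, the realized truth).
#' @export
simulate_parents <- function(cfg) {
  set.seed(cfg$seed)
  F <- cfg$fst_target
  nA <- cfg$n_parentA; nB <- cfg$n_parentB
  samples <- c(sprintf("PA_%03d", seq_len(nA)), sprintf("PB_%03d", seq_len(nB)))
  pops <- stats::setNames(rep(c("PARENT_A", "PARENT_B"), c(nA, nB)), samples)
  var_l <- list(); all_l <- list(); frq_l <- list()
  for (ch in cfg$chroms) {
    pos <- sort(sample.int(cfg$chrom_len, cfg$n_snps))
    p0 <- stats::runif(cfg$n_snps, 0.05, 0.95)
    pA <- stats::rbeta(cfg$n_snps, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
    pB <- stats::rbeta(cfg$n_snps, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
    hapA <- matrix(stats::rbinom(2L * nA * cfg$n_snps, 1L, rep(pA, each = 2L * nA)),
                   nrow = 2L * nA)
    hapB <- matrix(stats::rbinom(2L * nB * cfg$n_snps, 1L, rep(pB, each = 2L * nB)),
                   nrow = 2L * nB)
    var_l[[ch]] <- data.frame(chrom = ch, pos = pos,
                              id = paste0(ch, "_", pos), ref = "A", alt = "C",
                              stringsAsFactors = FALSE)
    all_l[[ch]] <- rbind(hapA, hapB)
    frq_l[[ch]] <- cbind(p0 = p0, pA = pA, pB = pB)
  }
  hs <- haplotype_set(do.call(rbind, var_l), do.call(cbind, all_l),
                      samples, pops)
  list(hs = hs, freqs = frq_l)
}

#' Simulate the hybrid population as parental-haplotype mosaics
#'
#' Each hybrid haplotype is a recombinant mosaic: tract boundaries follow an
#' exponential (Poisson breakpoint) process with mean tract length
#' \code{tract_mean_bp}, with additional forced breakpoints at planted-region
#' edges so planted intervals are exactly respected. Each tract is labelled
#' parent-A ancestry with probability \code{admix_prop} (or the planted
#' \code{ancestry_prob} inside a planted interval) and copies the alleles of
#' one uniformly chosen parental haplotype of that ancestry — so the hybrid
#' carries genuine long-range IBD with individual parents, the signal the
#' rIBD scan detects.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param parents output of \code{\link{simulate_parents}}.
#' @return list with \code{hs} (hybrid-only \code{haplotype_set}) and
#'   \code{truth}: data.frame of ancestry tracts (\code{hap_id},
#'   \code{sample}, \code{chrom}, \code{start}, \code{end} 0-based half-open,
#'   \code{ancestry}, \code{source_hap} row index into the parents' allele
#'   matrix).
#' @export
simulate_hybrid <- function(cfg, parents) {
  set.seed(cfg$seed + 1000003L)
  nH <- cfg$n_hybrid
  samples <- sprintf("HYB_%03d", seq_len(nH))
  pops <- stats::setNames(rep("HYBRID", nH), samples)
  phs <- parents$hs
  rowsA <- hap_rows(phs, "PARENT_A")
  rowsB <- hap_rows(phs, "PARENT_B")
  alleles <- matrix(0L, nrow = 2L * nH, ncol = nrow(phs$variants))
  truth <- vector("list", 0L)
  for (ch in cfg$chroms) {
    sel <- which(phs$variants$chrom == ch)
    pos <- phs$variants$pos[sel]
    planted <- cfg$planted[cfg$planted$chrom == ch, , drop = FALSE]
    forced <- if (!is.null(planted) && nrow(planted))
      sort(unique(c(planted$start, planted$end))) else numeric(0)
    for (hrow in seq_len(2L * nH)) {
      # breakpoints: Poisson process + forced planted edges
      bp <- numeric(0); at <- 0
      repeat {
        at <- at + stats::rexp(1, rate = 1 / cfg$tract_mean_bp)
        if (at >= cfg$chrom_len) break
        bp <- c(bp, at)
      }
      bnd <- sort(unique(c(0, bp, forced, cfg$chrom_len)))
      t_start <- bnd[-length(bnd)]
      t_end <- bnd[-1]
      mid <- (t_start + t_end) / 2
      pA <- rep(cfg$admix_prop, length(mid))
      if (!is.null(planted) && nrow(planted)) {
        for (k in seq_len(nrow(planted))) {
          inside <- mid >= planted$start[k] & mid < planted$end[k]
          pA[inside] <- if (planted$direction[k] == "PARENT_A")
            planted$ancestry_prob[k] else 1 - planted$ancestry_prob[k]
        }
      }
      lab <- ifelse(stats::runif(length(mid)) < pA, "A", "B")
      src <- ifelse(lab == "A",
                    rowsA[sample.int(length(rowsA), length(mid), replace = TRUE)],
                    rowsB[sample.int(length(rowsB), length(mid), replace = TRUE)])
      for (t in seq_along(mid)) {
        in_tract <- sel[pos > t_start[t] & pos <= t_end[t]]
        if (length(in_tract))
          alleles[hrow, in_tract] <- phs$alleles[src[t], in_tract]
      }
      truth[[length(truth) + 1L]] <- data.frame(
        hap_id = paste0(samples[(hrow + 1L) %/% 2L], "_", 2L - hrow %% 2L),
        sample = samples[(hrow + 1L) %/% 2L], chrom = ch,
        start = t_start, end = t_end, ancestry = lab, source_hap = src,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(hs = haplotype_set(phs$variants, alleles, samples, pops),
       truth = truth)
}

#' Simulate a full three-population cohort
#'
#' Runs \code{\link{simulate_parents}} and \code{\link{simulate_hybrid}} and
#' merges them into one cohort.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return Object of class \code{sim_cohort}: list with \code{hs} (merged
#'   \code{haplotype_set}), \code{truth} (hybrid ancestry tracts),
#'   \code{freqs}, \code{config}.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  parents <- simulate_parents(cfg)
  hyb <- simulate_hybrid(cfg, parents)
  samples <- c(hyb$hs$samples, parents$hs$samples)
  pops <- c(hyb$hs$pop_labels, parents$hs$pop_labels)
  alleles <- rbind(hyb$hs$alleles, parents$hs$alleles)
  hs <- haplotype_set(parents$hs$variants, alleles, samples, pops)
  structure(list(hs = hs, truth = hyb$truth, freqs = parents$freqs,
                 config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  print(x$config)
  print(x$hs)
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits one merged phased VCF, the population map, a BED of the true hybrid
#' ancestry tracts, a BED of planted regions (possibly empty) and a JSON echo
#' of the configuration.
#'
#' @param cohort a \code{sim_cohort}.
#' @param outdir output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(outdir, "cohort.vcf")
  write_vcf(cohort$hs, vcf)
  pops <- file.path(outdir, "pops.tsv")
  utils::write.table(data.frame(sample = cohort$hs$samples,
                                pop = unname(cohort$hs$pop_labels)),
                     pops, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  truth <- file.path(outdir, "truth_tracts.bed")
  tt <- cohort$truth
  utils::write.table(data.frame(tt$chrom,
                                format(tt$start, scientific = FALSE, trim = TRUE),
                                format(tt$end, scientific = FALSE, trim = TRUE),
                                paste0(tt$hap_id, ":", tt$ancestry)),
                     truth, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  planted <- file.path(outdir, "planted.bed")
  pl <- cohort$config$planted
  if (is.null(pl))
    pl <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     direction = character(), ancestry_prob = numeric())
  utils::write.table(data.frame(pl$chrom,
                                format(pl$start, scientific = FALSE, trim = TRUE),
                                format(pl$end, scientific = FALSE, trim = TRUE),
                                pl$direction, pl$ancestry_prob),
                     planted, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  cfgf <- file.path(outdir, "sim_config.json")
  cfg <- unclass(cohort$config)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)], cfgf,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(vcf = vcf, pops = pops, truth = truth, planted = planted,
              config = cfgf))
}

#' Realized parent-A ancestry fraction from truth tracts
#'
#' @param truth truth-tract data.frame from \code{\link{simulate_cohort}}.
#' @return Fraction of hybrid genome (bp-weighted, across haplotypes) with
#'   parent-A ancestry.
#' @export
ancestry_fraction <- function(truth) {
  len <- truth$end - truth$start
  sum(len[truth$ancestry == "A"]) / sum(len)
}
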