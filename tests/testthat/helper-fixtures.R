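# Small fixtures and independent oracle implementations used across tests.
# Oracles are deliberately scalar / brute-force and share no code with the
# package's vectorized paths.

# build a haplotype_set from an explicit haplotype matrix
make_hs <- function(alleles, pops, pos = NULL, chrom = "chr1") {
  n_s <- nrow(alleles) / 2L
  samples <- sprintf("S%02d", seq_len(n_s))
  if (is.null(pos)) pos <- seq_len(ncol(alleles)) * 1000L
  haplotype_set(data.frame(chrom = chrom, pos = pos),
                alleles, samples, stats::setNames(pops, samples))
}

# scalar Weir & Cockerham (1984) variance components from per-pop summaries:
# n diploids, alt frequency p, observed heterozygote frequency h
oracle_wc_theta <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# brute-force maximal identical-run scan between two haplotypes
oracle_match_runs <- function(x, y, pos, min_snps, min_bp) {
  n <- length(x)
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (x[i] == y[i]) {
      j <- i
      while (j < n && x[j + 1L] == y[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_snps && pos[j] - pos[i] + 1L >= min_bp)
        segs[[length(segs) + 1L]] <- c(start = pos[i], end = pos[j],
                                       n_snps = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(segs)) return(NULL)
  as.data.frame(do.call(rbind, segs))
}

# exact hypergeometric upper tail by direct combinatorial evaluation
oracle_hyper_upper <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# brute-force per-bin pair counting: O(bins x segments) double loop
oracle_bin_counts <- function(segments, pop_pair, n_bins, bin_size, chrom) {
  cnt <- integer(n_bins)
  seg <- segments[segments$pop_pair == pop_pair & segments$chrom == chrom, ]
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) * bin_size  # 0-based half-open bin
    hi <- b * bin_size
    pairs <- character(0)
    for (s in seq_len(nrow(seg)))
      if (seg$start[s] <= hi && seg$end[s] > lo)  # 1-based seg vs bin overlap
        pairs <- c(pairs, paste(seg$sample1[s], seg$sample2[s]))
    cnt[b] <- length(unique(pairs))
  }
  cnt
}

# write a minimal phased VCF by hand (independent of write_vcf)
write_test_vcf <- function(path, chrom, pos, gts, samples,
                           ref = "A", alt = "C") {
  hdr <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_along(pos), function(i)
    paste(c(chrom, pos[i], ".", ref, alt, ".", ".", ".", "GT", gts[[i]]),
          collapse = "\t"), "")
  writeLines(c(hdr, rows), path)
  path
}
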