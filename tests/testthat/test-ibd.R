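# one hybrid + one parent-A sample whose haplotype rows are given explicitly
pair_hs <- function(hyb_hap, par_hap, pos) {
  alleles <- rbind(hyb_hap, hyb_hap, par_hap, par_hap)
  make_hs(alleles, c("HYBRID", "PARENT_A"), pos = pos)
}

test_that("detect_ibd finds full-identity and mismatch-split segments", {
  n <- 1000
  pos <- seq_len(n) * 100L
  hap <- rep(c(0L, 1L), length.out = n)
  hs <- pair_hs(hap, hap, pos)
  segs <- detect_ibd(hs, min_snps = 10, min_bp = 10)
  # all 4 haplotype combinations of the identical pair share one full segment
  expect_equal(nrow(segs), 4L)
  expect_equal(unique(segs$start), pos[1])
  expect_equal(unique(segs$end), pos[n])
  expect_equal(unique(segs$n_snps), n)
  expect_equal(unique(segs$pop_pair), "HYBRID_PARENT_A")

  # single mismatch at variant 500 splits into exactly two segments
  hap2 <- hap
  hap2[500] <- 1L - hap2[500]
  hs2 <- pair_hs(hap, hap2, pos)
  segs2 <- unique(detect_ibd(hs2, min_snps = 100, min_bp = 10)[c("start", "end", "n_snps")])
  expect_equal(nrow(segs2), 2L)
  expect_equal(segs2$start, c(pos[1], pos[501]))
  expect_equal(segs2$end, c(pos[499], pos[1000]))

  # mismatch every 10th variant with min_snps = 100 -> nothing qualifies
  hap3 <- hap
  hap3[seq(10, n, by = 10)] <- 1L - hap3[seq(10, n, by = 10)]
  expect_equal(nrow(detect_ibd(pair_hs(hap, hap3, pos), min_snps = 100,
                               min_bp = 10)), 0L)

  # single-variant chromosome is an error
  expect_error(detect_ibd(pair_hs(0L, 0L, 1000L), min_snps = 2), "single variant")
})

test_that("detect_ibd agrees with the brute-force maximal-run oracle", {
  set.seed(21)
  for (rep in 1:200) {
    n <- 500
    pos <- sort(sample.int(5e5, n))
    # correlated haplotypes so runs of varied length occur
    x <- rbinom(n, 1, 0.5)
    y <- ifelse(rbinom(n, 1, 0.95) == 1, x, 1 - x)
    min_snps <- sample(c(3, 5, 10, 25), 1)
    min_bp <- sample(c(1, 1000, 20000), 1)
    hs <- pair_hs(as.integer(x), as.integer(y), pos)
    got <- detect_ibd(hs, min_snps = min_snps, min_bp = min_bp)
    got <- got[got$hap1 == 1 & got$hap2 == 1, c("start", "end", "n_snps")]
    rownames(got) <- NULL
    want <- oracle_match_runs(x, y, pos, min_snps, min_bp)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got, data.frame(start = want$start, end = want$end,
                                   n_snps = as.integer(want$n_snps)))
    }
  }
})

test_that("import_ibd retains cross-population segments and validates input", {
  pm <- c(H1 = "HYBRID", H2 = "HYBRID", A1 = "PARENT_A", B1 = "PARENT_B")
  f <- tempfile()
  writeLines(c("H1\t1\tA1\t2\tchr1\t100\t5000",
               "A1\t1\tH2\t1\tchr1\t200\t9000",   # hybrid listed second
               "H1\t2\tB1\t1\tchr2\t50\t700"), f)
  segs <- import_ibd(f, pm)
  expect_equal(nrow(segs), 3L)
  expect_true(all(segs$sample1 %in% c("H1", "H2")))  # hybrid oriented first
  expect_setequal(segs$pop_pair, c("HYBRID_PARENT_A", "HYBRID_PARENT_B"))

  # within-population line dropped with a message
  writeLines(c("H1\t1\tA1\t2\tchr1\t100\t5000",
               "H1\t1\tH2\t1\tchr1\t100\t5000",
               "A1\t1\tB1\t2\tchr1\t100\t5000"), f)
  expect_message(segs2 <- import_ibd(f, pm), "dropped 1")
  expect_equal(nrow(segs2), 2L)

  writeLines("H1\t1\tZZ\t2\tchr1\t100\t5000", f)
  expect_error(import_ibd(f, pm), "ZZ")
  writeLines("H1\t1\tA1\t2\tchr1\t5000\t100", f)
  expect_error(import_ibd(f, pm), "end <= start")
})

test_that("bin_counts deduplicates pairs and matches the double-loop oracle", {
  sizes <- c(HYBRID = 2, PARENT_A = 3, PARENT_B = 2)
  # all 6 hybrid x parent-A pairs share IBD across the first bin -> nIBD 1
  segs <- expand.grid(s1 = c("H1", "H2"), s2 = c("A1", "A2", "A3"),
                      stringsAsFactors = FALSE)
  segs <- data.frame(chrom = "chr1", start = 1L, end = 9000L, n_snps = 10L,
                     sample1 = segs$s1, hap1 = 1L, sample2 = segs$s2,
                     hap2 = 1L, pop_pair = "HYBRID_PARENT_A")
  bins <- bin_counts(segs, sizes, bin_size = 10000,
                     chrom_lengths = c(chr1 = 20000))
  expect_equal(bins$nIBD_A, c(1, 0))
  expect_equal(bins$tIBD_A, c(6, 6))
  expect_equal(bins$tIBD_B, c(4, 4))

  # a pair with two overlapping segments in one bin counts once
  two <- segs[c(1, 1), ]
  two$start <- c(1L, 4000L); two$end <- c(5000L, 9500L)
  b2 <- bin_counts(two, sizes, bin_size = 10000, chrom_lengths = c(chr1 = 10000))
  expect_equal(b2$cIBD_A, 1L)
  # ...but twice in segment-counting sensitivity mode
  b2s <- bin_counts(two, sizes, bin_size = 10000,
                    chrom_lengths = c(chr1 = 10000), count = "segments")
  expect_equal(b2s$cIBD_A, 2L)

  expect_error(bin_counts(segs, c(HYBRID = 2, PARENT_A = 0, PARENT_B = 2)),
               "positive")

  # random segment sets match the O(bins x segments) oracle
  set.seed(31)
  for (rep in 1:10) {
    n_seg <- 60
    start <- sample.int(490000, n_seg)
    rs <- data.frame(chrom = "chr1", start = start,
                     end = start + sample.int(60000, n_seg), n_snps = 5L,
                     sample1 = sample(c("H1", "H2"), n_seg, TRUE), hap1 = 1L,
                     sample2 = sample(c("A1", "A2", "A3"), n_seg, TRUE),
                     hap2 = 1L, pop_pair = "HYBRID_PARENT_A",
                     stringsAsFactors = FALSE)
    got <- bin_counts(rs, sizes, bin_size = 10000,
                      chrom_lengths = c(chr1 = 500000))
    expect_equal(got$cIBD_A,
                 oracle_bin_counts(rs, "HYBRID_PARENT_A", 50, 10000, "chr1"))
  }
})

test_that("ribd_track differences the nIBD tracks elementwise", {
  bins <- data.frame(chrom = "chr1", bin_start = (0:9) * 1e4,
                     bin_end = (1:10) * 1e4,
                     nIBD_A = seq(0, 0.9, by = 0.1),
                     nIBD_B = rep(c(0.2, 0), 5))
  out <- ribd_track(bins)
  expect_equal(out$ribd, bins$nIBD_A - bins$nIBD_B)
  # equal tracks give zero everywhere; unit bounds behave
  bins$nIBD_B <- bins$nIBD_A
  expect_equal(ribd_track(bins)$ribd, rep(0, 10))
  one <- data.frame(chrom = "chr1", bin_start = 0, bin_end = 1e4,
                    nIBD_A = 1, nIBD_B = 0)
  expect_equal(ribd_track(one)$ribd, 1)
})

test_that("standardize_and_call z-scores genome-wide and calls both tails", {
  # constant-plus-spike: only the spike is significant
  bins <- data.frame(chrom = "chr1", bin_start = (0:99) * 1e4,
                     bin_end = (1:100) * 1e4,
                     nIBD_A = c(rep(0.1, 99), 0.9), nIBD_B = 0.1)
  out <- standardize_and_call(ribd_track(bins), 2)
  expect_equal(which(out$significant), 100L)
  expect_equal(out$direction[100], "PARENT_A")

  # degenerate constant track errors
  flat <- data.frame(chrom = "chr1", bin_start = (0:9) * 1e4,
                     bin_end = (1:10) * 1e4, nIBD_A = 0.3, nIBD_B = 0.1)
  expect_error(standardize_and_call(ribd_track(flat)), "constant")

  # z equals brute-force two-pass statistics with population sd
  set.seed(41)
  big <- data.frame(chrom = "chr1", bin_start = (0:999) * 1e4,
                    bin_end = (1:1000) * 1e4,
                    nIBD_A = runif(1000), nIBD_B = runif(1000))
  got <- standardize_and_call(ribd_track(big), 2)
  r <- big$nIBD_A - big$nIBD_B
  mu <- sum(r) / 1000
  sd_pop <- sqrt(sum((r - mu)^2) / 1000)
  expect_equal(got$z, (r - mu) / sd_pop, tolerance = 1e-12)
  expect_equal(got$significant, abs(got$z) > 2)
  expect_equal(got$direction[got$z > 2], rep("PARENT_A", sum(got$z > 2)))
  expect_equal(got$direction[got$z < -2], rep("PARENT_B", sum(got$z < -2)))

  # separate mode standardizes each nIBD track before differencing
  sep <- standardize_and_call(ribd_track(big), 2, mode = "separate")
  zA <- (big$nIBD_A - mean(big$nIBD_A)) / sqrt(mean((big$nIBD_A - mean(big$nIBD_A))^2))
  zB <- (big$nIBD_B - mean(big$nIBD_B)) / sqrt(mean((big$nIBD_B - mean(big$nIBD_B))^2))
  expect_equal(sep$z, zA - zB, tolerance = 1e-12)
})

test_that("link_regions merges same-direction runs within chromosomes", {
  mk <- function(idx_sig, dir, chrom = "chr1", n = 12) {
    b <- data.frame(chrom = chrom, bin_start = (seq_len(n) - 1) * 1e4,
                    bin_end = seq_len(n) * 1e4, z = 0,
                    significant = FALSE, direction = "none",
                    stringsAsFactors = FALSE)
    b$significant[idx_sig] <- TRUE
    b$direction[idx_sig] <- dir
    b$z[idx_sig] <- ifelse(dir == "PARENT_A", 3, -3)
    b
  }
  # bins 4,5,6 and 10 (1-based) -> regions of 30 kb and 10 kb
  r <- link_regions(mk(c(4, 5, 6, 10), "PARENT_A"))
  expect_equal(nrow(r), 2L)
  expect_equal(r$length_bp, c(30000, 10000))
  expect_equal(r$n_bins, c(3L, 1L))
  expect_equal(r$start, c(30000, 90000))
  expect_equal(r$end, c(60000, 100000))

  # adjacent but opposite directions never merge
  b <- mk(3:4, "PARENT_A")
  b$direction[4] <- "PARENT_B"; b$z[4] <- -3
  expect_equal(nrow(link_regions(b)), 2L)

  # adjacency does not cross chromosomes
  b2 <- rbind(mk(12, "PARENT_A", "chr1"), mk(1, "PARENT_A", "chr2"))
  expect_equal(nrow(link_regions(b2)), 2L)

  # conservation: summed region length = bin_size x significant bins per direction
  set.seed(51)
  b3 <- mk(sample(1:12, 6), "PARENT_A")
  r3 <- link_regions(b3)
  expect_equal(sum(r3$length_bp), 6 * 1e4)
  smry <- region_summary(r3)
  expect_equal(smry$PARENT_A$total_bases, 60000)
  expect_equal(smry$PARENT_B$n_regions, 0L)
})

test_that("parent relabeling negates rIBD and z and swaps directions", {
  planted <- data.frame(chrom = "chr1", start = 4e6, end = 4.5e6,
                        direction = "PARENT_A", ancestry_prob = 1)
  co <- simulate_cohort(sim_config(seed = 13, n_chrom = 1, planted = planted))
  scan <- ribd_scan(co$hs)
  # swap PARENT_A <-> PARENT_B labels
  pl <- co$hs$pop_labels
  pl[pl == "PARENT_A"] <- "tmp"
  pl[pl == "PARENT_B"] <- "PARENT_A"
  pl[pl == "tmp"] <- "PARENT_B"
  hs_sw <- haplotype_set(co$hs$variants, co$hs$alleles, co$hs$samples, pl)
  scan_sw <- ribd_scan(hs_sw)
  expect_equal(scan_sw$bins$ribd, -scan$bins$ribd, tolerance = 1e-12)
  expect_equal(scan_sw$bins$z, -scan$bins$z, tolerance = 1e-12)
  dir_map <- c(PARENT_A = "PARENT_B", PARENT_B = "PARENT_A", none = "none")
  expect_equal(unname(dir_map[scan$bins$direction]), scan_sw$bins$direction)
  expect_equal(scan_sw$summary$PARENT_B$n_regions, scan$summary$PARENT_A$n_regions)
  expect_equal(scan_sw$summary$PARENT_B$total_bases, scan$summary$PARENT_A$total_bases)
  # and the basic track bounds hold throughout
  expect_true(all(scan$bins$nIBD_A >= 0 & scan$bins$nIBD_A <= 1))
  expect_true(all(scan$bins$nIBD_B >= 0 & scan$bins$nIBD_B <= 1))
  expect_true(all(abs(scan$bins$ribd) <= 1))
})
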