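#' Per-site Fst between two populations
#'
#' Computes the Weir & Cockerham (1984) moment estimator theta-hat at every
#' biallelic site from the two populations' allele and heterozygote counts
#' (r = 2 subpopulations). The variance components are
#' \deqn{a = \bar n / n_c [ s^2 - (\bar p(1-\bar p) - s^2/2 - \bar h/4)/(\bar n - 1) ]}
#' \deqn{b = \bar n/(\bar n - 1) [ \bar p(1-\bar p) - s^2/2 - (2\bar n - 1)\bar h/(4\bar n) ]}
#' \deqn{c = \bar h / 2}
#' with theta-hat = a / (a + b + c). Sites where the denominator is zero
#' (monomorphic across both populations) are reported with \code{fst = 0} and
#' flagged \code{undefined}. Negative estimates are reported as-is, not
#' clamped.
#'
#' The Hudson estimator (Bhatia et al. 2013 formulation) is available via
#' \code{estimator = "hudson"} for sensitivity analysis.
#'
#' @param hs a \code{\link{haplotype_set}}.
#' @param popA,popB population labels, each with >= 2 diploid samples.
#' @param estimator \code{"wc"} (default) or \code{"hudson"}.
#' @return data.frame: \code{chrom}, \code{pos}, \code{id}, \code{fst},
#'   \code{undefined} (logical), plus per-site variance components \code{a}
#'   and \code{denom} used by the ratio-of-sums genome-wide estimate.
#' @references Weir BS, Cockerham CC (1984). Estimating F-statistics for the
#'   analysis of population structure. Evolution 38:1358-1370.
#' @export
fst_per_site <- function(hs, popA = "PARENT_A", popB = "PARENT_B",
                         estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  for (p in c(popA, popB))
    if (sum(hs$pop_labels == p) < 2L)
      stop("population ", p, " has fewer than 2 diploid samples")
  cntA <- pop_site_counts(hs, popA)
  cntB <- pop_site_counts(hs, popB)
  out <- hs$variants[c("chrom", "pos", "id")]
  if (estimator == "wc") {
    wc <- wc_theta(cntA$n, cntB$n, cntA$p, cntB$p, cntA$h, cntB$h)
    out$fst <- wc$theta
    out$undefined <- wc$undefined
    out$a <- wc$a
    out$denom <- wc$denom
  } else {
    hu <- hudson_fst(2 * cntA$n, 2 * cntB$n, cntA$p, cntB$p)
    out$fst <- hu$fst
    out$undefined <- hu$undefined
    out$a <- hu$num
    out$denom <- hu$den
  }
  out
}

# per-population per-site summaries: n diploids, alt freq p, observed het freq h
pop_site_counts <- function(hs, pop) {
  idx <- which(hs$pop_labels == pop)
  h1 <- hs$alleles[2L * idx - 1L, , drop = FALSE]
  h2 <- hs$alleles[2L * idx, , drop = FALSE]
  n <- length(idx)
  p <- (colSums(h1) + colSums(h2)) / (2 * n)
  h <- colMeans(h1 != h2)
  list(n = n, p = p, h = h)
}

# vectorized W&C (1984) variance components for r = 2 populations
wc_theta <- function(n1, n2, p1, p2, h1, h2) {
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - s2 / 2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  undefined <- denom == 0
  theta <- ifelse(undefined, 0, a / denom)
  list(theta = theta, a = a, denom = denom, undefined = undefined)
}

# Hudson estimator, haplotype sample sizes m1/m2 (Bhatia et al. 2013, eq. 10)
hudson_fst <- function(m1, m2, p1, p2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (m1 - 1) - p2 * (1 - p2) / (m2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  undefined <- den == 0
  list(fst = ifelse(undefined, 0, num / den), num = num, den = den,
       undefined = undefined)
}

#' Genome-wide Fst by ratio of sums
#'
#' The ratio-of-sums (not mean-of-ratios) combination of per-site variance
#' components, the standard multi-locus W&C estimate.
#'
#' @param fst_df output of \code{\link{fst_per_site}}.
#' @return A single number, \code{sum(a) / sum(denom)}.
#' @export
fst_global <- function(fst_df) sum(fst_df$a) / sum(fst_df$denom)

#' Select top-quantile Fst outliers
#'
#' Ranks all sites in descending Fst and flags as outliers every site whose
#' Fst is at least the empirical upper quantile cut value, using the
#' nearest-rank definition: the cut is the \code{ceiling(fraction * n)}-th
#' largest value. Ties at the cut are all included, so slightly more than
#' \code{fraction * n} sites may be returned. Non-positive estimates are
#' never outliers.
#'
#' @param results data.frame from \code{\link{fst_per_site}}.
#' @param fraction upper tail fraction in (0, 1]; default 0.01 (top 1\%).
#' @return \code{results} with added \code{rank} (descending, ties broken by
#'   position order) and \code{is_outlier} columns, original row order.
#' @export
select_top <- function(results, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  if (nrow(results) == 0L) stop("empty Fst results")
  k <- ceiling(fraction * nrow(results))
  ord <- sort(results$fst, decreasing = TRUE)
  cut <- ord[k]
  results$rank <- rank(-results$fst, ties.method = "first")
  results$is_outlier <- results$fst >= cut & results$fst > 0
  attr(results, "cut_value") <- cut
  results
}

#' Write a Manhattan-style per-site report
#'
#' @param results data.frame from \code{\link{select_top}} (must carry
#'   \code{rank} and \code{is_outlier}).
#' @param path output TSV; rows sorted by (chrom, pos). Optional.
#' @return The sorted data.frame, invisibly if \code{path} given.
#' @export
manhattan_table <- function(results, path = NULL) {
  cols <- c("chrom", "pos", "fst", "rank", "is_outlier")
  stopifnot(all(cols %in% names(results)))
  tab <- results[order(results$chrom, results$pos), cols, drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Fst selection-signature scan
#'
#' Runs the per-site Weir & Cockerham scan of the hybrid population against
#' each parental population and flags the top-quantile outliers, the standard
#' two-step used to nominate candidate loci under selection.
#'
#' @param hs a \code{\link{haplotype_set}} (already MAF-filtered).
#' @param pairs list of two-element character vectors of population labels;
#'   default compares HYBRID against each parent.
#' @param fraction outlier tail fraction (default 0.01).
#' @param estimator see \code{\link{fst_per_site}}.
#' @return Object of class \code{fst_scan}: a list with one ranked result
#'   table per pair, plus the global ratio-of-sums Fst of each pair.
#' @export
fst_scan <- function(hs, pairs = list(c("HYBRID", "PARENT_A"),
                                      c("HYBRID", "PARENT_B")),
                     fraction = 0.01, estimator = "wc") {
  res <- lapply(pairs, function(pr) {
    select_top(fst_per_site(hs, pr[1], pr[2], estimator = estimator),
               fraction = fraction)
  })
  names(res) <- vapply(pairs, paste, "", collapse = "_vs_")
  structure(list(results = res,
                 global_fst = vapply(res, fst_global, 0),
                 fraction = fraction, estimator = estimator,
                 n_sites = nrow(hs$variants)),
            class = "fst_scan")
}

#' @export
print.fst_scan <- function(x, ...) {
  cat("Fst scan (", x$estimator, " estimator), ", x$n_sites, " sites, top ",
      100 * x$fraction, "% outliers\n", sep = "")
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %-22s global Fst %.4f  outliers %d  cut %.4f\n", nm,
                x$global_fst[[nm]], sum(r$is_outlier), attr(r, "cut_value")))
  }
  invisible(x)
}

#' @export
summary.fst_scan <- function(object, ...) {
  do.call(rbind, lapply(names(object$results), function(nm) {
    r <- object$results[[nm]]
    data.frame(pair = nm, n_sites = nrow(r),
               global_fst = object$global_fst[[nm]],
               cut_value = attr(r, "cut_value"),
               n_outliers = sum(r$is_outlier),
               max_fst = max(r$fst), stringsAsFactors = FALSE)
  }))
}

#' Manhattan plot of an Fst scan
#'
#' @param x an \code{fst_scan}.
#' @param pair which comparison to draw (index or name); default 1.
#' @param ... passed to \code{plot}.
#' @export
plot.fst_scan <- function(x, pair = 1, ...) {
  r <- x$results[[pair]]
  cut <- attr(r, "cut_value")
  r <- r[order(r$chrom, r$pos), ]
  chroms <- unique(r$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch) max(r$pos[r$chrom == ch]), 0)))
  gx <- r$pos + offs[match(r$chrom, chroms)]
  col <- ifelse(r$is_outlier, "firebrick",
                c("grey40", "grey70")[1 + match(r$chrom, chroms) %% 2])
  graphics::plot(gx, r$fst, pch = 20, cex = 0.4, col = col,
                 xlab = "genome position (bp)", ylab = expression(F[st]),
                 main = names(x$results)[[pair]], ...)
  graphics::abline(h = cut, lty = 2)
  invisible(x)
}
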