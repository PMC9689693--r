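---
title: "Selection-signature and introgression scans: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection-signature and introgression scans: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

`introscan` analyzes a three-population design: a composite (admixed)
population, here always labelled `HYBRID`, and the two purebred populations
it was bred from, `PARENT_A` and `PARENT_B`. This vignette is the package's
account of the statistics it computes, the choices that were genuinely open
when it was designed, and what the validation on synthetic cohorts does and
does not demonstrate.

## Input model

The unit of input is a `haplotype_set`: phased, biallelic, missing-free
genotypes (a 0/1 matrix with two haplotype rows per diploid sample) plus a
sample-to-population map. Phasing and imputation are declared
*preconditions*, not package functionality — in practice they come from
tools like BEAGLE upstream — because the IBD detector operates directly on
haplotypes and treats every allele as observed. Missing genotypes are a
hard error rather than being imputed or dropped silently.

Sites are filtered on pooled minor allele frequency across all three
populations in one pass (default threshold 0.05, the conventional chip
cutoff; *strictly below* the threshold is removed). Pooled rather than
per-population filtering mirrors the single-pass quality control used in
merged-cohort pipelines and keeps the site set identical across
comparisons. Internal coordinates are 1-based inclusive (VCF convention);
BED input is converted at the boundary, and the 0-based half-open
convention reappears only where it is idiomatic (bins and region/BED
output).

## The F~st~ scan

Per site, the package computes the Weir & Cockerham (1984) moment estimator
for r = 2 subpopulations. With diploid sample sizes $n_1, n_2$, alternate
allele frequencies $p_1, p_2$ and observed heterozygote frequencies
$h_1, h_2$, and writing $\bar n$, $n_c$, $\bar p$, $s^2$, $\bar h$ for the
usual averages, the variance components are

$$a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}\left(\bar p(1-\bar p) - \tfrac{1}{2}s^2 - \tfrac{1}{4}\bar h\right)\right]$$
$$b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) - \tfrac{1}{2}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right], \qquad c = \tfrac{1}{2}\bar h$$

and $\hat\theta = a/(a+b+c)$. Design notes:

- **Estimator choice.** Weir & Cockerham is the de facto standard of
  PLINK-era pipelines and is what a practitioner reaching for "F~st~"
  almost always means; a Hudson option (`estimator = "hudson"`, Bhatia et
  al. 2013 form) is provided because the two can diverge under unequal
  sample sizes, and comparing them is a cheap robustness check.
- **Negative estimates** (expected at undifferentiated sites) are reported
  unclamped — clamping at zero would distort the empirical outlier
  quantile — but are never flagged as outliers.
- **Monomorphic sites** have $a+b+c = 0$; they are reported with
  `fst = 0` and an `undefined` flag rather than NaN, so downstream ranking
  stays total.
- **Outlier threshold.** "Top 1%" is implemented as the nearest-rank
  empirical quantile: the cut is the `ceiling(0.01 n)`-th largest value and
  every site at or above it is an outlier, so ties at the cut are all
  included. The threshold is applied genome-wide (jointly across
  chromosomes), not per chromosome.
- The genome-wide estimate is the ratio of sums
  $\sum a / \sum(a+b+c)$, which is the consistent multi-locus combination
  (a mean of per-site ratios is biased at low-information sites).

## The rIBD introgression scan

The question rIBD answers is directional: *locally, which parent do the
hybrid's haplotypes come from?* The pipeline is:

1. **IBD segments.** Between every hybrid×parent haplotype pair, maximal
   runs of identical alleles spanning at least `min_snps = 100` variants
   and `min_bp = 100000` bases are segments. This detector is exact and
   deterministic, which is appropriate for error-free phased input (the
   simulator) and for imputed chip data; it deliberately replaces
   stochastic HMM detectors. Their output (refined-IBD/hap-IBD-style
   tab-delimited files) can be injected via `import_ibd()`, so the rest of
   the pipeline is detector-agnostic. The defaults are conservative
   chip-density settings chosen to suppress short chance matches
   (at 1 SNP / 2 kb, 100 SNPs ≈ 200 kb); both are configurable and should
   be scaled with marker density.
2. **Binning.** Bins are 0-based half-open windows of `bin_size = 10000`
   bp; a segment overlaps a bin if the intervals share ≥ 1 bp. cIBD counts
   *distinct sample pairs*, not segments: tIBD is defined as the pair
   count $n_\mathrm{hyb} \times n_\mathrm{par}$, and only pair-level
   counting makes nIBD = cIBD/tIBD a proper fraction in [0, 1]. (A
   segment-level mode, `count = "segments"`, is kept for sensitivity
   analysis.) Bins with no sharing stay in the track — removing them would
   bias the standardization below.
3. **rIBD and significance.** rIBD = nIBD~A~ − nIBD~B~ per bin, positive
   meaning parent-A-ward sharing. The signed track is z-scored once
   genome-wide and bins with |z| > 2 are significant, the two directions
   being the two tails. An alternative reading of "standardize per group" —
   z-scoring nIBD~A~ and nIBD~B~ separately and differencing
   (`mode = "separate"`) — is implemented; the pooled mode is the default
   because it standardizes the quantity that is actually thresholded and
   guarantees exact antisymmetry under relabelling of the parents. The sd
   is the population form (divisor N), a deterministic choice that matters
   only in the third decimal at genome scale.
4. **Regions.** Maximal runs of adjacent significant bins with the same
   direction merge into regions (never across chromosomes, never across a
   direction flip); per direction the scan reports region count and summed
   bases. Region coordinates are BED-like, so `length = end − start =
   n_bins × bin_size` exactly.

## Gene mapping and enrichment

A gene is associated with a locus or region when its interval extended by
`flank = 50000` bp on each side contains the locus (inclusive boundary: an
edge exactly 50 kb away counts). The flank applies to both F~st~ loci and
rIBD regions — whether a flank belongs on region-level anchors is less
settled than for point loci, so it is a parameter, and `flank = 0` gives
plain overlap. Enrichment is a generic upper-tail hypergeometric test over
a user-supplied term→gene map with BH adjustment; raw p-values are retained
so fixed-threshold conventions (e.g. GO at p < 0.01, KEGG at p < 0.05) can
be applied verbatim. Annotation databases are inputs, not bundled: their
versions drift, and bundling one would fake reproducibility the package
cannot guarantee.

## The simulator and what validation shows

`simulate_cohort()` generates: (i) parental populations under the
Balding–Nichols model — ancestral frequency $p_0 \sim U(0.05, 0.95)$ per
SNP, population frequencies $\sim \mathrm{Beta}(p_0(1-F)/F,
(1-p_0)(1-F)/F)$, haplotypes Bernoulli — chosen over coalescent simulation
because the closed-form relation E[F~st~] = F makes estimator recovery an
exact target; and (ii) hybrid haplotypes as mosaics of *actual parental
haplotypes*, with exponential tract lengths (mean `tract_mean_bp`),
parent-A tract probability `admix_prop`, and forced tract boundaries at
planted-interval edges so a planted region with `ancestry_prob = 1` is
exactly parent-A in every hybrid haplotype. Copying real haplotypes (not
drawing from frequencies) is what makes hybrid–parent IBD genuine,
long-range and detectable — the property the rIBD stage needs.

Default scale, chosen once as a realistic desk-scale emulation of a
chip-genotyped cohort: 2 chromosomes × 10 Mb, 5,000 SNPs per chromosome
(1 SNP / 2 kb, chip-like), 30/30/30 diploids (tens of samples per
population), F = 0.2 (well-separated breeds), `admix_prop = 0.5` (a
balanced composite), tract mean 1 Mb (a few generations of recombination
after admixture). The full pipeline on this cohort runs in seconds;
the acceptance experiments use 20k SNPs and 50+50 samples where estimator
recovery is the point, and 20 seeded replicates for planted-region
recovery.

What the simulator does **not** emulate — and therefore what passing tests
do not show about real data: background linkage disequilibrium within
parents (sites are independent given frequencies; chance IBD is rarer than
in real genomes, so the detector's false-positive behaviour on real data is
untested here), genotyping error and missingness (the exact-match detector
would fragment segments; use an error-tolerant external detector and
`import_ibd()`), chip ascertainment bias, sex chromosomes, and pedigree
structure within populations.

## Numerical and degenerate-input conventions

- Ranking ties in the F~st~ table are broken by position order so ranks are
  a permutation (the outlier rule itself is tie-inclusive and unaffected).
- A constant rIBD track (zero sd) is an error, not a silent all-zero
  z-track; likewise empty result sets where a quantile or standardization
  is undefined.
- All randomness flows from explicit integer seeds (`sim_config(seed=)`),
  and the pipeline manifest records parameters and input MD5 sums, so any
  run can be reproduced bit-identically.
- Haplotype-level IBD hits from the same sample pair are deduplicated per
  bin by construction; the same pair sharing both haplotypes still counts
  once, which caps nIBD at 1 by definition rather than by clamping.

## Known limitations

The exact-match IBD detector is O(pairs × sites) and intended for cohorts
of tens of samples and 10^4–10^5 SNPs; hundreds of samples at sequencing
density call for an external detector plus `import_ibd()`. The enrichment
test treats genes as exchangeable (no length or LD correction), which is
the standard but known-imperfect practice for locus-derived gene lists.
The 2-sd rule calibrates significance to the genome-wide empirical
distribution of rIBD — under strong, widespread introgression the
background itself shifts and the threshold becomes conservative.
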