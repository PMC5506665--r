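---
title: "Spike-in-free depth calibration for ChIP-seq with global signal loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in-free depth calibration for ChIP-seq with global signal loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipscale)
```

## Why depth normalization fails for global changes

A ChIP-seq coverage track confounds three multiplicative quantities: the
local abundance of the mark, the IP efficiency, and the sequencing depth
of the library. Comparing two conditions therefore requires putting both
tracks on a common scale. The usual choice — scaling to equal total
coverage (CPM and relatives) — is correct only if the *total* amount of
the mark is equal in both conditions. For a treatment that removes a
large fraction of a broad mark genome-wide (the motivating case is the
loss of H3K9me2, a repressive mark organised in large chromosomal
domains, in naïve mouse ES cells), equal-total scaling is exactly wrong:
it absorbs the biology into the normalization and the rescaled tracks
look unchanged.

`chipscale` implements an internal calibration that does not assume
equal totals. Aligned libraries contain bins of extreme coverage caused
by alignment artifacts — collapsed repeats and other loci missing or
mis-assembled in the reference, which soak up mis-mapped reads. Three
properties make them usable as an internal standard:

1. their coverage is far above anything enrichment produces;
2. they appear in IP and input libraries with very similar profiles,
   because their signal is an alignment phenomenon, not a chromatin one;
3. for libraries with the same read and fragment-length characteristics,
   their coverage scales with sequencing depth only.

The ratio of treated to untreated coverage at these bins therefore
estimates the depth ratio, uncontaminated by the biological change.

## The estimator

Coverage is computed as mean per-base fragment depth in fixed bins
(`bin_genome()`, `bin_coverage()`). With $U_b$ and $T_b$ the untreated
and treated values, and $O$ the $k$ bins with the largest $U_b$
(`select_outlier_bins()`, ties broken by ascending genomic index):

$$\widehat{d} = \mathrm{median}_{\,b \in O,\; U_b, T_b > 0}\; T_b / U_b,
\qquad \text{factor} = 1 / \widehat{d},$$

and the treated track is multiplied by the factor
(`scale_coverage()`). The median over the per-bin ratio distribution is
the primary aggregate; the mean is reported as a diagnostic only. Bins
with zero coverage in either track are excluded and counted rather than
pseudocounted — pseudocounts would bias ratios precisely at the
extreme-value bins the method depends on. In practice zero outlier bins
essentially never occur, since outliers are by construction the
highest-coverage loci.

Two diagnostics accompany the estimate:

* `check_input_consistency()` compares, for a library pair, the fold
  change of the **total** genomic coverage with the **outlier-bin
  median** fold change. For input libraries the two must agree (default
  tolerance: |log2 gap| ≤ 0.1, exposed as a parameter and reported in
  the output); for the IP of a globally lost mark they must not — the
  outlier bins follow depth while the total follows depth × loss. The
  outlier set used for the input check is the one selected on the
  untreated IP track, so IP and input are probed at the same loci.
* `sweep_outlier_k()` repeats the estimate over a range of $k$ (default
  50–500) and reports the relative spread (max − min over median) of the
  factors.

### Properties relied on downstream

The estimator is exactly scale-equivariant (estimating on $c\,T$ gives
factor$/c$), self-normalizing (after applying the factor, the outlier
median ratio is 1 to floating-point accuracy), and strictly monotone in
the treated outlier values. These are unit-tested as properties, not
spot checks.

## Downstream comparisons

* `bin_fold_change()` — per-bin treated/untreated ratios on the rescaled
  tracks; bins with zero untreated coverage are flagged, not dropped.
* `coverage_cor()` — Pearson correlation over bins nonzero in at least
  one track. The default correlates raw bin values; a `log2p1` transform
  is available. Since Pearson correlation is invariant to positive
  rescaling, it isolates the question "is the *distribution* preserved?"
  from the level change.
* `promoter_windows()` / `window_signal()` /
  `promoter_fold_change()` — symmetric TSS ± 2 kb windows (TSS from the
  annotation strand: interval start for `+`, end for `-`; strand is used
  only to locate the TSS), window means computed from bin values
  weighted by overlap length, fold changes formed on the window means
  (not as averages of per-bin ratios) and sorted descending. The
  fraction of promoters with fold change < 1 summarises how generalized
  a loss is.
* `call_domains()` / `region_overlap()` — a deliberately simple
  threshold-and-merge caller for broad domains: bins with IP/input ≥
  `min_ratio` (default 1.5) are marked, runs gapped by ≤ `merge_gap`
  (default 1000 bp) merged, merged runs < `min_len` (default 2000 bp)
  dropped. Bins with zero input use the genome-wide mean input as
  denominator, flagged in the output — this avoids infinite ratios
  without masking artifact bins, which are high in input too. The
  defaults are tuned to broad, domain-forming marks and all exposed.
  Overlap is reported as a base-pair three-way partition with Jaccard
  (primary) plus region counts, since either can be the Venn unit.

## The PTM summary module

Mass-spectrometry relative abundances (fraction of a residue's peptide
pool per modification state) arrive as a tidy table; the per-(site,
condition, replicate) sum-to-one invariant is enforced on load with a
0.01 tolerance. `compare_ptm()` reports, per state, the log2 ratio of
condition means (the mean of per-replicate log2 ratios is also emitted),
a two-sided Welch t-test across replicates, and a rank by |log2 ratio|.
The Welch variant was chosen because replicate variances need not be
equal and nothing about the design guarantees it; the choice is recorded
in the result's metadata. p-values are reported uncorrected, matching
per-mark significance testing practice for small PTM panels, with a
Benjamini–Hochberg column added for transparency.

A note on precision: with biological triplicates and absolute replicate
noise of sd 0.01 on an abundance of 0.3 dropping 2.6-fold, the log2
ratio-of-means estimator has a sampling sd of about 0.07. Single-table
estimates of the ratio therefore scatter visibly around the planted
value even when the generator is exactly unbiased (a 300-replicate
check of `sim_ptm_table()` gives mean −1.383 against the planted
−1.379); tolerances on a single draw must be read with that in mind.

## What the synthetic generator emulates

`simulate_chip()` produces the four libraries (IP/input ×
untreated/treated) as fragment sets plus a truth record. Expected
fragment count in bin $b$ is

$$\lambda_b = d \cdot \big(\text{bio}_b\,[\times r \text{ in treated IP}] + \text{art}_b\big) \cdot \rho\, w_b$$

with $d$ the library depth factor, $\rho$ the background rate
(fragments/bp), $w_b$ the bin width, $\text{bio}_b$ = 1 in background,
`domain_fold` in domains, `promoter_fold` in promoter windows, and
$\text{art}_b$ the artifact fold. Defaults and rationale:

* **Genome: 2 × 5 Mb, 500 bp bins (20,000 bins).** Large enough that
  median-of-150 estimates are stable to well under 1%, small enough that
  a full four-library experiment simulates in a few seconds; this is
  also the problem size used by the package's end-to-end tests and the
  reproduction script.
* **Artifact population: 1000 bins, Pareto-tailed folds (shape 2, scale
  15× background; `artifact_shape = Inf` gives constant intensity).**
  Real artifact bins are not a fixed small set: ranking bins by coverage
  in real data walks down a heavy tail of artifact loci, which is what
  makes the estimator insensitive to the exact cutoff. A population
  larger than any reasonable $k$, with folds spanning ~15× to several
  hundred ×, reproduces that regime at desk scale, while keeping the
  artifact share of total coverage realistic enough that the IP-side
  total-vs-outlier gap remains diagnostic.
* **Artifact signal replaces local signal** at artifact bins (the `bio`
  term is zeroed there, in IP and input alike, and the reduction $r$
  never applies): mis-mapped reads swamp whatever the locus truly
  carries, which is precisely why IP and input profiles coincide there
  and why the bins read out pure depth. An additive mixture would leak
  the biological reduction into artifact bins sitting inside enriched
  domains and contradict both the IP/input similarity and the
  depth-only-ratio property the method is built on.
* **Biology: 20 domains of 100–500 kb at 5×, 400 promoters at 3×
  (TSS ± 2 kb), background 0.02 fragments/bp, fragment length 200 bp,
  $r = 0.4$ applied uniformly to all non-artifact signal in the treated
  IP** — a broad-domain mark losing 60% of its level genome-wide, with
  the loss preserving the distribution.
* **Depths: IP 1 vs 1.75, input 1 vs 1.3.** The treated IP is deeper,
  so naive equal-depth comparison would mask the loss; the inputs differ
  by an unrelated factor, exercising the consistency check.
* **Noise: Poisson per bin** (negative binomial with configurable
  dispersion available; `"none"` uses rounded expected counts with
  deterministic placement). Fragments are placed wholly inside their
  generating bin, which makes the noise-free law exact — realized
  coverage equals the configured expectation — and keeps planted
  structure bin-sharp. Cross-bin fragments are a property of real data
  that the *binning code* must handle, and its tests exercise straddling
  and sequence-end-clipping fragments explicitly; the generator does not
  need them to emulate the statistical structure the calibration relies
  on.

What passing the synthetic suite does **not** show: robustness to
mappability and GC structure in the background, to fragment-length
differences between libraries (which perturb artifact-bin profiles and
are an assumption of the method, not a tested property), to artifact
populations that differ between IP and input, or to marks whose loss is
regional rather than uniform. On real data the scatter of the outlier
fold-change distribution and the input-consistency gap are the
diagnostics that must be inspected before trusting the factor.

## Numerical conventions and degenerate inputs

Coordinates are 0-based half-open (BED) throughout; bins tile each
sequence with the terminal bin kept at its true length (its mean uses
the true length as denominator, avoiding edge inflation). Fragments past
a sequence end are clipped with a warning; fragments on unknown
sequences are errors naming the sequence. bedGraph output is
zero-suppressed; reading restores zeros and rejects records that do not
coincide with a grid bin. Top-$k$ selection requires at least $k$
positive bins; correlation requires ≥ 2 informative bins with nonzero
variance; an all-dropped outlier set, zero-total input tracks and empty
promoter sets are errors rather than NaNs. No mappability or blacklist
masking is applied anywhere — extreme bins are the method's signal, not
noise to remove.

One bookkeeping caveat: published bin totals for a given assembly (e.g.
~5.46 million 500 bp bins for mouse) depend on which scaffolds are
included and how terminal bins are counted, so the package documents its
tiling rule (`ceiling(length / bin_size)` per sequence) rather than
asserting any assembly-specific count.

## Session info

```{r}
sessionInfo()
```
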