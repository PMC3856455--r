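---
title: "Methods: copy-number discovery from tiling aCGH in ricecnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number discovery from tiling aCGH in ricecnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricecnv)
```

## The problem and the data model

Two-channel array comparative genomic hybridization (aCGH) co-hybridizes
a test genome and a reference genome, each labelled with a different
dye, onto a tiling array of 50--75-mer oligonucleotide probes. For each
probe the quantity of interest is the log2 ratio of test to reference
intensity: near 0 for two copies, strongly negative over a deletion,
positive over a duplication. A copy number variant (CNV) is a segment of
at least 1 kb whose copy number differs from the reference; overlapping
CNV calls from different samples are consolidated into copy-number
variable regions (CNVRs), the cross-sample unit over which population
statistics are computed.

`ricecnv` implements the complete desk-scale analysis: a synthetic-data
generator standing in for real scans, two normalization stages,
least-squares segmentation, a stringent call filter cascade, CNVR
consolidation and probe re-validation, population genetics over
{normal, loss, gain} genotypes, annotation overlap accounting, and GO
enrichment.

## The synthetic world

The generator's defaults describe one fixed stated world, chosen once:

* **Genome**: 12 chromosomes of 1 Mb (a desk-scale stand-in for the
  12-chromosome rice genome). Configurable.
* **Probes**: jittered tiling with start-to-start gaps uniform on
  [0.5, 1.5] x 500 bp, so the median spacing is the requested ~500 bp
  while realistic gaps occur; probe lengths uniform on 50--75 bp.
  Probes map onto a near-square array grid in genome order and the
  assignment is then shuffled, so array-spatial structure is
  statistically independent of genomic position.
* **Planted events**: 10 per sample over a 20-cultivar panel (two
  subspecies, six groups), lengths uniform on 1--10 kb (real panels put
  ~98.5% of CNV lengths under 10 kb), 90% losses (losses dominate real
  calls roughly 9:1). Copy ratios -2.5 (loss) and +1.2 (gain) clear the
  -2/+1 calling thresholds with margin.
* **Artifacts**, layered in this order: a smooth low-order polynomial
  surface in grid coordinates added to the test channel (amplitude 0.1,
  log2 units) -- the position-dependent non-uniformity the LOESS stage
  must remove; a monotone intensity-dependent distortion of the
  reference channel (`u + 0.2 * tanh(u - mu)` on the log2 scale) -- the
  dye bias the q-spline stage must undo; and Gaussian noise.
* **Noise**: the published study reports no noise magnitude for its
  arrays; `noise_sd = 0.15` was chosen for testability (events at -2.5
  clear the -2 threshold by >3 per-probe standard deviations) rather
  than fitted to any real scan. Noise is split equally between the two
  channels (sd `noise_sd/sqrt(2)` each) so the ratio noise SD is
  exactly `noise_sd` *and* both channels share a marginal intensity
  distribution. The alternative -- noise on the test channel only --
  makes the test channel strictly wider than the reference, and
  quantile matching then necessarily inflates the ratio SD above
  `noise_sd`, which would contradict the self--self pipeline invariant;
  the symmetric split is also the physically sensible reading (both
  dyes are noisy).

What the simulator does **not** model: sequence-dependent probe
response (GC, cross-hybridization, SNP-in-probe effects), spatially
correlated defects (scratches, edge gradients beyond the smooth
surface), and copy-number states other than one discrete shift per
event. A green recovery test therefore establishes that the pipeline
recovers idealized planted signals under Gaussian noise and removable
artifacts -- not that it matches any real array's error process.

## Normalization

Stage order is spatial correction first, then dye normalization,
matching how array vendors apply them.

**Spatial LOESS.** A degree-1 locally weighted regression of the log2
ratio on array grid coordinates, span 0.3 (fraction of probes per local
fit), tricube weights, robust `"symmetric"` family so the sparse true
CNV probes do not drag the surface. The method is named in the source
protocol without settings; these are standard choices and are
configurable. The fitted surface is recentred to mean zero before
subtraction, so the global ratio level is untouched. The correction is
applied to the test-channel log intensity and the ratio recomputed,
keeping both channels available downstream. Whether the original
vendor software smoothed each channel separately or the ratio is not
recoverable; we correct the ratio (equivalently, one channel) and note
the alternative. The robust family degenerates when residuals are
exactly zero (noiseless input); the implementation falls back to plain
least squares in that case.

**q-spline.** Dye bias is removed by quantile matching: a monotone
cubic interpolant (Hyman-filtered spline) through 100 matched quantiles
of the log2 test and reference intensities maps the reference channel
onto the test channel's scale; ratios are recomputed. The cited method
is parameter-free in the source; 100 evenly spaced quantile knots keep
the mapping smooth at array sizes of 10^3--10^6 probes. Because the
knots span quantiles 0 to 1, no extrapolation occurs and monotonicity
(hence within-channel rank preservation) is guaranteed.

One caveat verified by the test suite: quantile matching slightly
attenuates planted signal when the fraction of aberrant probes is
comparable to the knot spacing (~1%). At the default world (~0.5% of
probes inside events) the attenuation is a few hundredths of a log2
unit; fixtures with several percent of probes in events show
attenuation up to ~0.1, which is why the segment-recovery tests are run
at realistic event density.

## Segmentation

Each chromosome's ordered ratios are partitioned by exact dynamic
programming minimizing

    sum over segments of within-segment SSE  +  penalty * (#segments).

The vendor algorithm this replaces (segMNT) is proprietary and
undocumented; penalized least-squares change-point optimization is the
documented algorithm class with the same pipeline role, and equivalence
is claimed at the level of pipeline behaviour (planted-event recovery,
self--self nulls), not per-breakpoint identity. Design choices:

* **Penalty**: default `2 * sigma^2 * log(n)` (BIC-like), with `sigma`
  estimated robustly from the median absolute successive difference,
  `median(|diff(x)|) / (sqrt(2) * 0.6745)`, which ignores the sparse
  true jumps. A floor of 1e-6 keeps the penalty positive on noiseless
  input. Any fixed penalty can be passed instead.
* **Ties**: costs equal within relative tolerance 1e-9 are ties
  (floating-point SSE of a constant run is not exactly zero); ties are
  broken toward fewer segments, then leftmost boundaries. This makes
  the noiseless case exact: a constant vector is one segment at any
  penalty >= 0.
* **Complexity**: O(n^2) with a vectorized inner loop; chromosomes are
  independent, so results do not depend on processing order. An
  optional `max_segments` cap uses the O(k n^2) constrained recursion.

The test suite proves global optimality against exhaustive enumeration
of all breakpoint placements for n <= 12 (600 random instances), and
checks refinement monotonicity (smaller penalty never yields fewer
segments) and signal conservation (probe-weighted mean of segment means
equals the input mean).

## Calling: the stringent filter cascade

A segment becomes a CNV call only if it survives all of:

1. **Mean threshold** (inclusive): mean log2 <= -2 (loss) or >= +1
   (gain). The source protocol phrases the filter as removing segments
   whose average ratio is "> -2 or < 1"; read literally that removes
   everything, so it is interpreted as defining the neutral band to
   remove -- the only reading consistent with the call definitions that
   follow it.
2. **100% of probes**: every member probe individually meets the
   directional cut-off. One outlying probe disqualifies the whole
   segment (no trimming; whether the original manual review trimmed or
   removed is unknowable, and removal is the stringent choice).
   Single-probe segments are rejected outright.
3. **>= 5 probes**: the source states a five-probe minimum only for
   CNVRs; the same value is borrowed per call, since a per-call minimum
   is implied by the single-outlier rule but never quantified.
4. **>= 1 kb**, the definitional CNV minimum.

All four are configurable in `calling_config()`; every rejection is
logged with a reason. Stringency is monotone by construction: raising
any threshold can only remove calls, which the suite asserts.

The practical consequence of rule 2, measured by the acceptance suite:
losses at -2.5 (margin 0.5 ~ 3.3 noise SDs per probe) are recovered at
>98% recall with zero false positives, while gains at +1.2 (margin 0.2
~ 1.3 SDs) are rejected often -- exactly the loss-dominated behaviour
real stringent aCGH call sets show. Recovery statistics are therefore
reported over events whose planted ratio clears its threshold by at
least 0.3, the calling contract's own definition of a callable event.

## CNVRs

Calls from all samples are merged into CNVRs as connected components of
the >= 1 bp interval-overlap graph (transitive chaining, union extent).
The criterion in the source is only "similar criteria as described
previously"; single-base overlap with transitive closure is the
simplest published CNVR convention and is what the implementation
freezes. A CNVR is `both` if it contains calls of both signs; such
complex regions are carried in the genotype matrix but excluded from
population statistics. Probe re-validation mimics re-mapping the array
to a newer assembly: a supplied per-probe perfect-match count strikes
non-unique probes, CNVRs left with fewer than five probes are dropped,
and CNVRs overlapping any user-declared assembly gap are dropped --
"large gap" is deliberately left to the gap file, since no size
threshold is defined in the source. Coordinates are 1-based inclusive
in memory and BED half-open on disk.

## Population genetics

Genotypes are the three categories normal/loss/gain treated as alleles
of a triallelic locus.

* **Gene diversity**: plain Nei `He = 1 - sum(p^2)` without
  small-sample correction -- the printed formula style; bounds
  `0 <= He <= 1 - 1/k` are asserted.
* **Fst** `= 1 - Hs/Ht` with `Hs` the *unweighted* mean of
  within-subspecies He (the source says "average" without weights; a
  size-weighted option exists) and `Ht` the He of the size-weighted
  pooled frequency vector (total-population definition; the
  mean-of-frequencies alternative is a flag). `Fst = 0` when `Ht = 0`.
* **Polymorphism criterion**: any non-monomorphic column (no minor
  frequency floor is stated in the source; none is imposed).
* **Subspecies-specific screen**: a CNVR is X-only iff all carriers are
  subspecies X; single-carrier CNVRs are flagged unique.
* **Group screen**: per-group carrier frequencies; default reporting
  threshold 0.8 on the largest pairwise difference ("high frequency
  difference" is never quantified in the source; the threshold is
  configurable and recorded in the output).
* **Clustering**: UPGMA (average linkage over original pairwise
  distances) on uncentered correlation distance
  `1 - sum(uv)/(||u|| ||v||)`, the metric named by the source protocol.
  Ties merge the earliest-created pair. Output is a standard `hclust`
  object; newick export goes through `ape`.
* **ANOVA**: classic one-way fixed-effects F; all-identical input
  returns F = 0 by convention rather than erroring.

## Annotation and enrichment

Gene/SD/repeat interval algebra is delegated to IRanges/GenomicRanges.
Containment is non-strict (a gene exactly coterminous with a CNVR is
wholly contained). Repeat masking unions overlapping repeat features
before counting, so masked bp never exceeds region bp. Per-class repeat
tallies are reported both as regions-containing-a-class and as
feature counts, covering both readings of published per-class tables.
The RepeatMasker `.out` reader handles the classic 3-header-line
whitespace dialect with a BED fallback.

Enrichment is one-sided hypergeometric over-representation with
Benjamini--Hochberg q-values. Following the source's bookkeeping, only
genes with at least one GO annotation enter the study size `n` and
background size `N`. Annotations are used exactly as given -- no
GO-graph ancestor propagation (the original tool's handling is not
described); this typically makes leaf terms look sparser than a
propagated analysis would.

## Numerical conventions

* Printed percentages and table means use **half-up** rounding
  (`floor(x * 10^d + 0.5)/10^d`), not R's banker's rounding -- banker's
  flips published edge cases such as 12.5% -> 12.
* DP tie tolerance 1e-9 (relative); SSE values are clamped at >= 0.
* The self--self invariant "ratio SD <= noise_sd after normalization"
  is tested with a `3/sqrt(2n)` sampling allowance at small fixture
  sizes; at the 24k-probe desk scale the bound is met without it.
* All randomness flows from explicit integer seeds; per-sample seeds
  are derived from the base seed by fixed offsets, and a pipeline rerun
  with the same config reproduces every artifact byte for byte
  (asserted on file contents in the suite).

## Known limitations

* Breakpoints are probe-resolution only; no sub-probe refinement.
* No joint multi-sample segmentation; each scan is segmented alone.
* The probe re-validation table is an input; the package does not
  re-align probe sequences.
* The simulator's q-spline attenuation caveat above: benchmark fixtures
  should keep planted-event probe fraction below ~1%, as real panels
  do.
* Headline counts from the motivating real-data study (12,224 CNVs,
  2886 CNVRs, etc.) depend on that study's raw arrays and a manual
  review step and are not reproduction targets at desk scale; the
  package reproduces the study's *arithmetic* and its *properties*
  (null behaviour, recovery, closed forms), which is what the
  acceptance suite asserts.
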