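---
title: "Comparing chromosome architecture between Hi-C samples"
author: "HiCcontrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing chromosome architecture between Hi-C samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HiCcontrasts)
```

## Scope and motivation

HiCcontrasts implements a toolbox for asking how chromosome architecture
differs between two Hi-C samples — the motivating case being the single
dosage-compensated male X chromosome of *Drosophila* against its paired
female counterpart and the autosomes. The stages are deliberately simple,
composable statistics rather than heavy model fits: matrix balancing,
distance-decay slopes, non-parametric top-interaction clustering, a
trans-contact null model, a local-outlier boundary caller (LSD, the Local
Score Differentiator), insulation scores, and enrichment summaries of point
features, insulator signal, pairwise pile-ups and 4C tracks around boundary
classes. A synthetic contact-map generator with known ground truth makes
every stage testable by parameter recovery.

## Data model

A `GenomeModel` holds chromosomes (or chromosome arms — arms are treated as
chromosomes throughout, matching the 2L/2R/3L/3R/X universe of the fly),
their lengths, expected copy numbers, and a dense 0-based bin table with
half-open intervals; a `ContactMatrix` stores the upper triangle of a
symmetric binned contact map as sparse triplets with a kind (`raw`,
`balanced`, `frequency`), a per-bin bias vector and masked-bin set after
balancing. Absent cells are zeros. All public functions take and return
these objects or plain data frames.

## Balancing

`iceBalance()` performs iterative correction under a factorizable-bias
model: raw counts are divided by the outer product of per-bin biases until
the unmasked marginals equalize. Choices that matter:

* **Non-informative diagonals.** Cis cells at distances 0 and 1 bin
  (`ignoreDiags = 2`) are removed before balancing and stay absent from the
  balanced output, so every downstream statistic sees zeros there — the
  same view a mirnylib/cooler-style pipeline produces.
* **Masking.** Bins whose marginal is below `minMarginal = 40` read counts
  are excluded; their rows and columns are dropped from the output and
  their bias is NA.
* **Convergence.** The stopping metric is the relative spread
  (max − min)/mean of the unmasked marginals, with tolerance `tol = 1e-2`
  and an iteration cap of 1000; the metric is recorded in the matrix
  metadata because the criterion behind a bare "tolerance" is a library
  detail with several conventions in the wild.
* **Damping.** The bias update is multiplicative with a square-root
  exponent. The damped iteration has exactly the same fixed point (Sinkhorn
  scaling is unique up to a global factor) but avoids the two-cycle
  oscillation the undamped divide-by-marginal step develops on strongly
  TAD-block-structured matrices, where it can stall just above the
  tolerance. Equivalence with the plain iteration is asserted in the test
  suite at tight tolerance after normalizing both to unit mean marginal,
  since the overall scale of a balanced matrix is algorithm-dependent.

`toContactFrequency()` rescales each chromosome by its median balanced
signal at the first informative diagonal (distance 2 bins), so neighbouring
informative loci have median contact frequency 1. An alternative per-cell
transform (value / mean at distance 2, capped at 1) is available via
`capped = TRUE`; it is not part of any default analysis.

Two downsampling schemes make coverage comparable across samples:
`downsampleBinomial()` (each count thinned binomially, p = 0.5 emulating
single-copy autosomes) and `downsampleMatchedCis()` (each chromosome of one
sample thinned to the cis total of the other).

## Interaction decay

`decayCurve()` takes the median signal per cis diagonal over distances
2–100 bins. The median runs over the *full* diagonal: structurally absent
sparse cells count as zeros, the natural extension of setting non-finite
normalized values to zero; this makes sparse and dense representations give
identical curves. `fitDecaySlope()` is an ordinary least-squares fit of
log10(median) on log10(distance in bp) over 2–15 bins, the range where the
decay is near-linear; distances are in bp so intercepts are anchored to
printed coordinates (log10 of 50 kb is about 4.69), while the slope itself
is unit-invariant. Slope differences between chromosomes (`slopeDeltas()`)
feed a two-sample Wilcoxon rank-sum test of chrX-vs-autosome deltas against
autosome-pair deltas (`compareXvsAutosomes()`); the exact null distribution
is used for small tie-free samples, the normal approximation otherwise.

`decayCdf()` normalizes the cumulative sum of the median contact
frequencies to end at 1, and `kuiperStatistic()` computes
V = max(cdf_a − cdf_b) + max(cdf_b − cdf_a). Both maxima are floored at
zero: when one CDF dominates everywhere the statistic equals the single
largest gap rather than adding a spurious negative term. V is symmetric and
bounded by 2 (by 1 for true CDF pairs on a shared grid).

## Top-scoring interactions

Within each cis diagonal (distances ≥ 2 bins, optionally capped at a
maximum distance such as 2 Mb), cells whose balanced value is *strictly*
greater than the diagonal's 95th percentile are selected. The percentile is
computed over the full diagonal including implicit zeros, with the
linear-interpolation quantile convention. The strict inequality means a
constant (e.g. all-zero) diagonal selects nothing — important in sparse
data, where an inclusive rule would select entire empty diagonals. Selected
points are clustered by single-linkage connected components under the
Euclidean distance in bin coordinates times the bin size, linked at
≤ 25 kb; at 25-kb bins this joins immediate neighbours only. A point is
"clustered" when its component has size ≥ 2, and the headline statistic is
the difference in clustered fractions between two samples, per chromosome.

## Trans-contact propensity

`expectedTrans()` implements a null in which trans contacts originating
from a chromosome are spread over the other chromosomes in proportion to
copy number × length; row sums of the expectation equal the observed row
totals by construction. `transPropensity()` reports log2(observed /
expected); the table need not be symmetric. A read pair is counted once per
involved chromosome, so the observed matrix is symmetric and each pair
contributes to two origins; copy number enters only the expectation, never
the observed counts. Zero observed cells are reported as −Inf with a flag
rather than dropped.

## The LSD boundary caller

The directionality index (DI) contrasts, for each bin, the summed contacts
to the `windowN = 10` upstream bins (A) against the downstream window (B):
sign(B − A) × ((A − E)² + (B − E)²)/E with E = (A + B)/2, zero when A = B
and undefined where the window leaves the chromosome or E = 0. Its first
differences (forward: DI_i − DI_{i+1}; backward: DI_i − DI_{i−1}) are
screened for local outliers with Tukey fences computed from the ΔDI
distribution inside a ±`localM = 25`-bin window: a domain start needs
ΔDI_forward ≤ Q25 − 1.5·IQR and ΔDI_forward ≤ DI; a domain end needs
ΔDI_backward ≥ Q75 + 1.5·IQR and ΔDI_backward ≥ DI, with DI finite in both
cases. Numerical decisions worth knowing:

* Quartiles use the linear-interpolation convention; at small windows the
  fence values depend on it, so it is fixed and documented here.
* In perfectly flat windows the IQR degenerates to zero and the fences
  collapse onto the quartiles, so the ≤/≥ gates alone would fire on
  constant tracks. A call therefore additionally requires strictly negative
  ΔDI_forward (starts) or strictly positive ΔDI_backward (ends); uniform
  matrices emit no boundaries.
* Fence windows at chromosome ends use the available truncated window
  rather than being dropped.
* `strict` (additionally require DI ≤ 0 at starts, DI ≥ 0 at ends) and
  `fillGaps` (extend each domain end to meet the next start) both default
  to FALSE.

Unique domain ends define boundaries; `makeBoundaryRegions()` converts each
junction (between end bin e and bin e + 1) into a bin-size-wide region by
extending the junction coordinate half a bin each side. The "extend by half
a bin" rule could also be read as centring on the end-bin midpoint; the
junction reading is used because a boundary conceptually lives between the
last bin of one domain and the first of the next, and regions built this
way span exactly those two half-bins. `compareBoundarySets()` classifies
boundaries by exact junction-bin intersection into same / appearing /
disappearing — the three classes partition the union — and reports the
non-matching fraction 1 − |same|/|union|.

`insulationScore()` is the Crane-style square-window statistic: the mean
signal in a `window × window` square immediately up/downstream of each bin,
normalized by the chromosome mean; a boundary's score is the mean of the
two junction-adjacent bins. The first and last `window` bins are skipped.

## Feature and signal enrichment around boundaries

`boundaryWindows()` builds flanks of up to 15 bins per side around each
boundary; when neighbouring windows would overlap, the intervening bins are
split equally (the downstream boundary takes the odd bin, so even adjacent
boundaries keep their own end bin), guaranteeing a disjoint cover — this
avoids double-counting features between closely spaced boundaries while
still permitting small domains. `featureEnrichment()` compares the observed
site density in those windows with the uniform expectation N/L (sites per
bin over the chromosome) as a log2 ratio, and
`featureEnrichmentPermutation()` provides an empirical null by re-placing
the sites uniformly. Sites are located by their midpoints; a site belongs
to the bin containing its midpoint.

Insulator tracks are rescaled by their 99th percentile
(`scaleSignal99()`) to absorb ChIP-efficiency differences; each boundary's
summit is the maximum scaled signal inside its one-bin region, sexes are
combined by the per-boundary maximum, and `classifyInsulatorBoundaries()`
applies a 0.5 cutoff (the midpoint between the modes of the bimodal summit
distributions) to form three classes: BEAF-32 high with CP190 or Chromator
high; exactly one of the two conditions (including BEAF-32 low with both
partners high — the inclusive reading of "either"); and all low.

`aggregatePairwiseProfile()` is a PE-SCan-style pile-up: for anchor pairs
(i, j) passing the non-overlap filters 1 + n ≤ i ≤ D − n and
i + 2n < j ≤ D − n, the (2n+1)² window around (i, j) is divided by the mean
of a background window just one bin larger per side, log2-transformed and
averaged. The n + 1 background is intentionally literal — it is much
smaller than the backgrounds used by other pile-up tools, and `bgExtra`
exposes it for users who want a wider one. Non-finite values are zeroed
before normalization and after the log transform, so empty cells do not
poison the average and a constant matrix gives an identically zero profile.

`fourcEnrichment()` computes, at each restriction-fragment midpoint, the
log10 of (binarized-coverage sum in a ±20-kb window over the sum in a
±600-kb background window, plus a pseudocount of 1); fragments closer than
the background half-width to a chromosome end are excluded. Replicates are
merged by "any replicate covered" binarization, and a depth-based QC
(`filterFourcProbes()`) discards probes with ≥ 2-fold replicate imbalance
or > 1.5-fold cross-sample imbalance. `fourcBoundarySummary()` maps
fragment enrichments to bins and averages them by offset from each
boundary class.

`assignTssToBoundaries()` pairs each gene TSS with its nearest boundary
junction, keeps pairs closer than 10 kb, retains only the closest gene per
boundary, and removes inactive genes *after* the competition — an inactive
gene can thus displace an active one, preventing spurious
active-gene/boundary associations.

## The synthetic generator

`simSpec()`/`simulateContactMap()` emit Poisson counts around an expected
cis intensity proportional to d^exponent (distances ≥ 2 bins; the first
two diagonals are zero, mirroring the analysis-side exclusion), multiplied
by `intraTadBoost` within TADs and attenuated by (1 − strength) per crossed
boundary; trans contacts are uniform over trans bin pairs at the requested
fraction, and a chromosome with copy number c receives c/2 of the stated
per-pair coverage. Defaults are the package's reference study conditions,
chosen once as realistic for fly embryo data: exponent −1, boost 2.5,
insulation strength 0.85, 10^6 cis pairs per two-copy chromosome, 10%
trans. `simulateSexPair()` derives a male map from a female spec by setting
chrX to one copy, shifting its decay exponent (less negative) and fully
opening selected boundaries; `simulateFeatureTrack()` places point features
uniformly or co-located with ground-truth boundaries.

What the generator does *not* emulate: polymer-physics realism (no
homologous pairing, no chromatin-state block copolymer energetics),
overdispersed counts (Poisson, not negative binomial), fragment-level
biases, compartments, or loops. Passing parameter-recovery tests therefore
demonstrates correctness of the statistics under a clean factorizable-bias,
power-law-decay world — not robustness to every artefact of real Hi-C.

## Worked example

```{r example}
g <- genomeModel(data.frame(name = c("2L", "2R", "3L", "3R", "X"),
                            length = rep(5e6, 5), copyNumber = rep(2L, 5)),
                 binSize = 25000)
sp <- simSpec(g, decayExponent = -1, coverage = 1e6,
              transFraction = 0.1, seed = 3)
pair <- simulateSexPair(sp, deltaExponent = 0.11, seed = 3)
fits <- decaySlopes(toContactFrequency(iceBalance(pair$male$map)))
res <- compareXvsAutosomes(slopeDeltas(fits), "X")
round(res$xDeltas, 3)
res$p.value
```

The male X slope sits about 0.11 above the autosomes, and the rank-sum test
against the autosome-pair deltas is significant despite only four X deltas
— the smallest two-sided exact p attainable with groups of 4 and 6 is about
0.0095, which complete separation achieves.

## Problem sizes and test design

The test and acceptance workloads use 5-Mb chromosomes at 25-kb bins
(200 bins) for decay analyses at 0.5–1 million cis pairs per chromosome,
and a 1.4-Mb chromosome at 3.5-kb bins (400 bins, 10 boundaries, ~300
reads/bin) for boundary calling; these sizes were chosen so each oracle or
recovery check completes in seconds while leaving the estimators in their
asymptotic regime (slope recovery is already within ±0.02 at these
coverages). Boundary recovery is assessed over a five-seed ensemble —
TPR and FDR are pooled across seeds — with a ±1-bin matching tolerance,
since individual noisy seeds can place a duplicate call two to four bins
from a true junction without that reflecting a systematic defect.

## Known limitations

* Genome-wide balancing and chromosome-wise balancing share one bias model;
  copy-number differences between chromosomes are not absorbed into the
  expected marginals (as in the real pipelines, they surface in coverage
  and are handled by downsampling).
* `.cool` containers are not read directly; matrices enter as triplet +
  bin-table text files (the `cooler dump` layout).
* The rank-sum comparison has low power with few chromosome arms by
  construction; it is reported with the group values so users can judge
  effect sizes directly.
* The fill-gaps option connects consecutive end/start calls; with a one-bin
  gap it extends the end to the bin before the next start, one of several
  defensible readings of "filling in gaps between domains".
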