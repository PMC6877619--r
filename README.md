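# HiCcontrasts

Comparative analysis of chromosome architecture from binned Hi-C contact
maps, built around the question of how a chromosome's 3D organisation
differs between two samples — the motivating case being the single,
dosage-compensated male X of *Drosophila melanogaster* against the paired
female X and the autosome arms (2L, 2R, 3L, 3R).

The package provides, as composable functions over S4 containers
(`GenomeModel`, `ContactMatrix`, `BoundarySet`):

* **Balancing & coverage matching** — iterative correction (ICE) with
  low-coverage masking (marginal ≥ 40), exclusion of the first two
  diagonals and a 1e-2 marginal-spread tolerance; binomial downsampling
  (p = 0.5) and per-chromosome matched-cis downsampling.
* **Interaction decay** — per-diagonal median curves (distances 2–100
  bins), contact-frequency normalisation by the distance-2 median, OLS
  slopes of log10(median) vs log10(distance) over 2–15 bins, pairwise
  slope deltas Δ(a,b) = slope_a − slope_b, Wilcoxon rank-sum comparison of
  chrX-vs-autosome deltas against autosome pairs, decay CDFs and the
  Kuiper statistic V = max(cdf_a − cdf_b) + max(cdf_b − cdf_a).
* **Top-scoring interactions** — per-diagonal top-5% selection (strict
  percentile, implicit zeros included), single-linkage clustering at
  Euclidean bin distance ≤ 25 kb, and the clustered-fraction difference
  between samples.
* **Trans propensity** — the uniform null
  E(a,b) = (c_b·l_b)/Σ_{b′≠a}(c_{b′}·l_{b′}) · T_a with copy-number and
  length weighting, reported as log2 observed/expected.
* **LSD boundary calling** — directionality index on a 10-bin window,
  forward/backward ΔDI, local Tukey fences (Q25 − 1.5·IQR / Q75 + 1.5·IQR
  in a ±25-bin window), one-bin boundary regions at domain-end junctions,
  exact-match boundary classes (same / appearing / disappearing) and
  Crane-style insulation scores.
* **Feature context** — disjoint ±15-bin boundary windows with equal
  splitting of shared territory, log2 obs/exp site enrichment against a
  uniform null with a permutation envelope, 99th-percentile signal
  scaling, combinatorial insulator classes (BEAF-32 × CP190/Chromator at a
  0.5 summit cutoff), PE-SCan-style pairwise pile-ups, 4C fragment
  enrichment E = log10(Σ±20kb / Σ±600kb + 1), and TSS-to-boundary
  assignment (< 10 kb, closest gene per boundary).
* **Synthetic maps with ground truth** — Poisson contact maps with a
  power-law decay exponent, TAD blocks with per-boundary insulation
  strengths, copy-number-scaled coverage, uniform trans contacts, and
  male/female map pairs with a shifted chrX exponent and weakened
  boundaries, so every stage above is testable by parameter recovery.

## Worked example

```r
library(HiCcontrasts)

g  <- genomeModel(data.frame(name = c("2L", "2R", "3L", "3R", "X"),
                             length = rep(5e6, 5), copyNumber = rep(2L, 5)),
                  binSize = 25000)
sp   <- simSpec(g, decayExponent = -1, coverage = 1e6,
                transFraction = 0.1, seed = 3)
pair <- simulateSexPair(sp, deltaExponent = 0.11, seed = 3)

fits <- decaySlopes(toContactFrequency(iceBalance(pair$male$map)))
res  <- compareXvsAutosomes(slopeDeltas(fits), "X")
round(res$xDeltas, 3)
#>    2L    2R    3L    3R
#> 0.109 0.111 0.114 0.113
res$p.value
#> [1] 0.00952381
```

The four chrX-vs-autosome slope deltas recover the simulated +0.11 shift
in the male X decay exponent (a less negative slope means relatively more
mid/long-range contacts), and the rank-sum test against the six
autosome-pair deltas (all within ±0.005 of zero here) reaches the smallest
two-sided exact p attainable at these group sizes.

A thin command-line front end wraps the same functions:

```sh
exec/hiccontrasts simulate --out-prefix sim --nbins 400 --boundaries 10 --seed 1
exec/hiccontrasts balance  --contacts sim.contacts.tsv --bins sim.bins.tsv \
                           --out sim.bal.tsv --bias sim.bias.tsv
exec/hiccontrasts lsd      --contacts sim.bal.tsv --bins sim.bins.tsv \
                           --out sim.boundaries.tsv
```

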