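---
title: "Inferring centric fusions from linkage disequilibrium: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring centric fusions from linkage disequilibrium: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Some species carry submetacentric chromosomes that arose as centric
(Robertsonian) fusions of two acrocentric chromosomes of a related species —
the water buffalo's five submetacentrics relative to cattle are the textbook
case. When a SNP panel for the derived species is annotated on the ancestral,
split reference, markers that are physically adjacent across a fusion
junction end up on two different "chromosomes" of the map. Linkage
disequilibrium does not care about the annotation: marker pairs flanking the
junction still show high r², and that signal identifies which chromosomes
fused, at which ends, and in which orientation. `ldfusion` implements this
inference end to end:

1. genotype QC (call rate, MAF, exact Hardy–Weinberg test);
2. pairwise r² between all markers, intra- and inter-chromosomal;
3. counting inter-chromosomal pairs with r² > 0.2 per chromosome pair and
   calling fusions against a robust background;
4. localizing the joined ends from the positions of the supporting markers;
5. building an exact, invertible rearrangement plan and lifting the marker
   map onto fused coordinates;
6. diagnostics on the result: decay-adjusted windowed LD, windowed haplotype
   diversity, map-vs-map regression, misplaced-marker and
   translocated-segment flags, and an imputation-accuracy contrast.

A seeded forward simulator of fused-chromosome genotype panels provides the
ground-truth test bed for all of it.

## Pairwise r²

For two biallelic loci, r² = D²/(p_A q_A p_B q_B), with D the deviation of
the AB haplotype frequency from independence. Genotypes are unphased, so
haplotype frequencies are estimated by maximum likelihood with an EM
iteration over the double-heterozygote phase (the default, and the default
of the common LD tools); a composite estimator (squared Pearson correlation
of allele counts) is available and is substituted automatically for the rare
pairs where EM has not converged within 100 iterations at tolerance 1e-8.
Missing genotypes are handled by pairwise deletion; a pair whose
complete-case subset is monomorphic at either locus is skipped and tallied.
Both estimators are invariant to allele relabeling and sample order, and
thresholds are strict everywhere: a pair at exactly r² = 0.2 is not counted.

The EM and composite estimators are *not* interchangeable: the composite is
the correlation of genotype dosages and differs from the ML haplotype r²
whenever genotype frequencies depart from Hardy–Weinberg pairing. What is
exactly true — and what the test suite asserts — is that without double
heterozygotes the EM solution equals direct haplotype counting.

## Calling fusions

The evidence matrix counts, for every chromosome pair, the marker pairs with
r² > 0.2. True fusion pairs stand far above the diffuse inter-chromosomal
background, so candidates are pairs exceeding
`max(min_count, median + k · MAD)` of all inter-chromosomal counts
(defaults `min_count = 20`, `k = 10`), accepted greedily by descending count
with each chromosome used at most once — a centric fusion consumes both
partners. The joined end of each partner is `begin` or `end` according to
whether the median position of its supporting markers falls in the first or
last quarter (`terminal_fraction = 0.25`) of the chromosome; medians in the
middle are reported as unresolvable rather than silently placed.

## The coordinate transform

The fused chromosome is laid out with position 0 at the short-arm telomere
and the junction (centromere) at `junction_bp` = short-arm length, so a
short-arm marker at split position p maps to `junction − p`. Two conventions
are supported for the long arm:

* `junction_forward` (default): the long arm runs forward from the junction
  (`junction + p` when its joined end is its beginning). This places the
  junction between the two arms' centromeric ends and is the convention
  under which the arranged assembly shows its LD peak at the junction.
* `paper_literal`: the transform `short_len + (long_len − p)` applied to
  every long-arm position. It is retained verbatim as a switchable mode; it
  anchors the long arm's far end at the junction side, which contradicts the
  junction-peak behavior, and the package does not guess which convention
  the original analysis actually used.

Either way the transform is an exact integer bijection per arm;
`invert_plan()` reverses it, and the round trip is tested to zero
mismatches on every simulated map.

## Windowed diagnostics

**Decay-adjusted LD.** Raw mean r² per window is confounded by the window's
marker spacing, so each 4 Mb window (sliding by 1 Mb) is summarized by
fitting the Hill–Weir drift expectation

E(r²) = [(10 + C) / ((2 + C)(11 + C))] ·
[1 + ((3 + C)(12 + 12C + C²)) / (n (2 + C)(11 + C))],

with C = beta · distance, by bounded one-dimensional least squares (20-point
multi-start on the log10 scale plus the beta = 0 boundary, then local
refinement; noiseless recovery is exact to 1e-8 relative error). The window
statistic is the fitted curve evaluated at a fixed reference distance
`d_ref = 100 kb`, reported alongside the raw mean. Windows with fewer than
`min_pairs = 10` pairs, or a single distinct distance, are emitted as
undefined rather than extrapolated.

**Haplotype diversity.** Per 1 Mb window (0.5 Mb step), complete window
haplotypes define classes with frequencies p_i and
H = (M/(M−1))(1 − Σ p_i²). M defaults to the number of haplotype
observations (2N for N diploids), the standard unbiased estimator; a literal
mode with M = N is switchable since the verbal definition of the source
method reads that way. H is 0 iff the window is haplotypically monomorphic
and exactly 1 when all haplotypes are distinct.

**Centromere profile and fusion age.** Around a junction, the profile's
peak, far-window baseline (median beyond 10 Mb) and half-maximum extent are
extracted. Ranking several fused chromosomes by apparent fusion age is a
heuristic with three selectable keys; the default reads smaller extent as
older with peak as tie-break. In the rising-LD regime that forward
simulation at desk scale reaches (fusion age below ~2Ne), the junction peak
carries essentially all of the age signal and the half-maximum extent is
window-quantization noise, so the `higher_peak` key is the one that
recovers staggered fusion times in the package's own simulations (10/10
seeds, vs 7/10 for the extent-primary key). The output is annotated as a
heuristic in all cases.

## Imputation-accuracy design

Masking scenarios retain 10–30% of markers, equidistant in map order from a
seeded random offset. Reference/target splits default to disjoint 4-fold
cross-validation (349 samples give 262/87-sized complements, matching the
design this reproduces); independent random splits of a fixed ratio are
available since the original description does not state which was used.
Accuracy is scored as r²a (squared Pearson correlation of true vs imputed
allele counts, pooled over cells by default, per-marker mean switchable) and
PERC (proportion of correctly imputed alleles, a het-vs-hom discrepancy
counting one of two alleles correct). Group contrasts between map variants
use one-way ANOVA on per-fold means plus Tukey HSD compact letters at
alpha = 0.05.

The built-in imputer is deliberately a baseline, not a reimplementation of
any external imputation software: each masked genotype is the sum of the two
reference haplotypes that best match the target's flanking window (nearest
`near_k = 10` retained markers per side), the first by Hamming-type distance
|h − g/2|, the second by the diplotype residual |h − (g − h1)|, ties broken
by window-haplotype frequency then row index — fully deterministic. Because
heterozygous flank sites tie across haplotypes, even imputing a sample
against its own haplotypes is only near-perfect (r²a ≈ 0.94, PERC ≈ 0.98 in
the suite's check), which is a property of any flank-matching rule, not a
defect of the metrics; exactness holds when the flanks determine the masked
site.

## The simulator

Forward Wright–Fisher diploids with founder variation only: founder alleles
are drawn per marker at frequencies Uniform(0.1, 0.9) (a Beta option
exists), and each generation every offspring receives two gametes from
random parents, with strand switches sampled exactly per inter-marker
interval (probability rate × length, capped at 0.5; 0.5 between
chromosomes). A fusion's junction interval recombines freely before the
fusion's time and at the suppressed rate afterwards; intervals within the
suppression radius of any centromere — the junction of a fused chromosome,
the coordinate start of an acrocentric — are multiplied by the suppression
factor throughout. Marker coordinates are expressed both on the true fused
genome and on the split ancestral reference (the exact inverse of the
rearrangement the pipeline infers), and panel ascertainment drops markers
at or below sample MAF 0.05.

Standard scenario (the package's study conditions): six split chromosomes
of 40, 100, 50, 60, 70 and 80 Mb, the first two being the arms of one
centric fusion; 300 sampled diploids from a constant population of
Ne = 600; 600 generations with the fusion present throughout; 1 cM/Mb;
suppression factor 0.01 within 1 Mb of each centromere; ~4,800 requested
markers (12/Mb) of which ~3,000 survive ascertainment. The drift ratio
t/2Ne = 0.5 is the controlling quantity: it is large enough for the
junction to accumulate strong cross-arm LD and for the pericentromeric
signature to be established, while keeping most panel markers segregating.
An earlier draft used Ne = t = 300; that history made within-arm LD (4Nec
for adjacent markers ≈ 1.3) almost as strong as the junction signal, which
is the wrong regime for a fusion that, in the real system, predates the
species — scaling Ne and t together fixes the regime without changing any
drift-dependent calibration.

Planted misassemblies for the detectors: individual misplacements are
sourced from decoy-chromosome centromeres (a pericentromeric marker has an
unambiguous high-LD home; a junction-region marker has partners on *both*
arms, so its "correct" alternative chromosome is intrinsically ambiguous),
and the planted translocated segment relocates a run of junction-flanking
markers into a decoy interior, vacating the native markers of the target
interval — the interval is foreign sequence, and interleaved native markers
would artificially break the consecutive-marker run the detector requires.

### What the simulator does and does not emulate

It reproduces: panel-like allele-frequency spectra, distance-decaying LD on
arms, strong junction LD with suppressed recombination, reduced junction
haplotype diversity relative to the arm *median*, misassembly signatures,
and the imputation advantage of the correct marker order at the centromere.

It does not include mutation, selection, gene conversion, population
structure or sex chromosomes, and its fusions are at most as old as the
simulated history. One consequence deserves emphasis: with founder
variation only and ascertainment at MAF > 0.05, the junction's windowed
haplotype diversity has a floor — surviving junction markers necessarily
tag the few remaining intermediate-frequency lineage blocks, so H at the
junction settles around 0.4–0.7 while occasional arm windows drift to
0.1–0.4. The junction is therefore reliably *below the arm median* but is
rarely the *global minimum* of the scan, unlike in real data where ancient
centromeres are maintained at low diversity by the mutation–recombination
balance. Passing tests show the directional contrast, not the global
argmin; the acceptance suite records the argmin version of the check
honestly failing under these dynamics.

## Numerical and interface choices

* Positions are 1-based inclusive externally (PLINK/VCF convention); the
  internal window arithmetic is half-open and converted at the boundary.
  Lifted maps may legitimately contain position 0 (the short-arm telomere).
* ped/map files carry no allele roles; the reader recovers them by the
  convention allele_a < allele_b, so only maps following that convention
  round-trip ped exactly (bim and VCF round-trip roles verbatim).
* Multi-allelic VCF records are rejected — the method is biallelic by
  construction.
* The PLINK bed codec is the v1.00 SNP-major layout, written and read
  natively (no installed R package provides it).
* Equal arm lengths take the lexicographically smaller label as short arm,
  with a message.
* `detect_fusions` background: median + 10 · MAD with a floor of 20 pairs;
  the MAD of an all-equal background is widened to machine epsilon so the
  z-scores stay finite.
* Problem sizes in the test suite: the standard scenario at 20 seeds for
  recovery rates, 10 seeds for the planted-misassembly rates, with smaller
  populations (60–150 diploids) for distributional unit checks. The
  acceptance script reruns the same computations at 10/5/5 seeds.

## Known limitations

* The r² engine evaluates all marker pairs in chunks; output, not input,
  dominates memory, but an unthresholded all-pairs table over tens of
  thousands of markers is still large — threshold or restrict scope at that
  scale.
* The fusion caller assumes at most one fusion per chromosome (greedy
  matching); nested or serial rearrangements of the same chromosome are out
  of scope, as are inversions and fissions beyond the translocated-segment
  detector.
* The imputation harness scores the built-in baseline; imported external
  imputations can be scored with the same metrics, but absolute accuracies
  of specialized software are not reproduced.
* The fusion-age ranking is a qualitative staging heuristic; with only
  window-level profiles it cannot separate ages beyond the rising-LD phase.
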