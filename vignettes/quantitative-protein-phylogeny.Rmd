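---
title: "Methods: quantitative protein phylogeny from physico-chemical profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative protein phylogeny from physico-chemical profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantphylo)
```

## The model

Protein evolution proceeds by mutation and by selection. Mismatch counting
over aligned letters sees only the former; the physico-chemical footprint
of a substitution — how much volume, charge, or hydrophobicity it changes —
is where selection leaves its trace. `quantphylo` therefore converts each
aligned protein sequence into a *number string*: residue i becomes the
measured value of one physical property of its amino acid, and alignment
gaps become exactly 0. Twelve properties are embedded (molecular mass Da,
solvent-accessible surface Å², volume Å³, hydropathy index, normalized
hydrophobicity, solubility g/kg H₂O, octanol–interface / octanol /
interface transfer free energies kcal/mol, isoelectric point at 25 °C, and
the two backbone pKa values). The default analysis set is five of them —
volume, hydropathy index, solubility, octanol–interface, pI — chosen to
span size, hydrophobic, solvation and charge axes; the box-counting
dimension defaults to volume, pI and solubility.

Two deliberate encoding caveats are worth stating. First, the gap code 0
collides with arginine's normalized hydrophobicity of exactly 0, so
hydrophobicity encoding is not invertible and is excluded from the default
set. Second, isoleucine and leucine share identical volume (166.7 Å³) and
molecular mass (131.175 Da), so those columns are not invertible either;
among the embedded columns only solubility assigns 20 distinct values, and
`decode_sequence()` documents this.

Input letters are upper-cased, `.` is accepted as a gap synonym for `-`,
and any other symbol (including B, J, O, U, X, Z, `*`) is an error that
reports its position: ambiguity codes have no measured physical value, so
silently imputing one would corrupt every downstream statistic.

## Sum-difference trees

For one property, the distance between two taxa is the L1 distance
Σᵢ |xᵢ − yᵢ| (“sum-difference”), with gap positions contributing the full
|value − 0|. Tree construction is agglomerative: find the pair of current
profiles with the smallest sum-difference, record that distance on the new
internal node, replace the pair by the *unweighted* position-wise mean of
the two profiles, repeat. The unweighted average (WPGMA-like, not
centroid-weighted) is intrinsic to the method — a merged profile is itself
a number string, so later distances remain physical quantities. When only a
distance matrix is available (e.g. correlation-derived distances through
`similarity_to_distance()`, d = 1 − r), the same loop runs with merged
distances taken as the arithmetic mean of the members' distances (WPGMA);
`stats::hclust(method = "mcquitty")` serves as an independent cross-check
of that variant in the test suite.

Numerical policies:

- **Tie-breaking.** Equal minimal distances resolve to the lowest
  (row, column) pair in the current ordering. With real-valued property
  sums, exact ties are essentially impossible, but determinism must not
  depend on that.
- **Branch lengths.** The raw merge distance d is stored verbatim on each
  internal node; for rendering and Newick output the node is placed at
  height d/2 and a child edge is the height difference, floored at 0.
  Sum-difference merge sequences are not guaranteed monotone (an averaged
  profile can sit closer to a third cluster than its parents did), and the
  floor keeps the serialized tree well-formed while the stored distances
  preserve the raw values for proportional labelling.
- Per-property trees are built independently; no cross-property composite
  tree is computed.

## Relatedness measures

**Correlation.** The autocorrelation statistic
R_m = Σ_{t=1}^{N−m}(xₜ−x̄)(xₜ₊ₘ−x̄) / Σ_{t=1}^{N}(xₜ−x̄)² is implemented
exactly as written (shared overall mean; the 1/N factors cancel). Applied
pairwise *between* taxa at lag 0 it is the Pearson correlation, which is
what `pair_correlation()` computes and what the relatedness tables
aggregate; the within-string lag-m form remains available as
`lag_autocorrelation()`. Both interpretations are provided because the
statistic is defined as an autocorrelation but deployed pairwise; lag-0
Pearson is the only reading that yields one number per taxon pair.

**Average mutual information.** MI = H(X) + H(Y) − H(X,Y) with plug-in
empirical entropies, each distinct encoded value (including the 0 gap code)
treated as an exact categorical symbol — the strings carry at most 21
distinct values, so interval binning would only blur them. Units are nats
by default with a bits option; the unit convention for published AMI
values of this kind is not standardized, which matters when comparing
absolute numbers across studies. The estimator is the plain plug-in; no
bias correction (Miller–Madow, shrinkage) is attempted.

**Box-counting dimension.** The points (xᵢ, yᵢ) are binned on a single
10 × 10 grid whose axes both span the common range [min, max] of the two
strings (half-open bins, last bin closed); the dimension is
log₁₀(occupied cells), i.e. estimated at that single scale rather than by
multi-scale regression — the definition is the 10 × 10 grid. A degenerate
zero range returns 0 with a warning. Grid placement quantization error is
acknowledged: an optional mode (`offsets = TRUE`) averages the occupancy
count over a 5 × 5 set of sub-cell grid offsets; it is off by default so
the reference behaviour stays the plain anchored grid.

**Aggregation.** For each taxon pair the measure is computed per property
and reported as mean ± sample (n−1) standard deviation across properties —
the small-sample ± convention.

All three measures retain gap positions: gaps are data (the 0 encoding is
what lets indels contribute to distance at all), and every statistic
consumes the same strings the trees do.

## Bivariate wavelet analysis

The position axis is treated as a spatial series with unit spacing. The
continuous Morlet transform uses the standard FFT formulation: central
frequency ω₀ = 6 (Fourier period ≈ 1.033 × scale — the community default),
zero padding to the next power of two, a dyadic scale grid from
`period_min` = 2 to `period_max` = 256 positions at 20 voices per octave,
and a cone of influence from the √2·scale e-folding length. Cross-spectrum
W_xy = W_x · conj(W_y) gives cross-power |W_xy| and phase arg(W_xy);
phases in (−π/2, π/2) classify as in-phase (conserved), the rest as
out-of-phase.

Coherence is |S(W_xy/s)|² / (S(|W_x|²/s) · S(|W_y|²/s)), clipped to
[0, 1], where S smooths with a boxcar over position (window length
proportional to scale) and over scale (fixed 0.6-octave window) — standard
cross-wavelet practice; without S the quantity is identically 1, and the
test suite asserts the smoothing is active.

Significance is Monte-Carlo: `n_surrogates` (default 100) surrogate pairs
matching the originals' lengths, means and variances. The default null is
white noise — amino-acid property strings have no agreed autoregressive
null — with an AR(1) option (`surrogate_model = "ar1"`). A coherence cell
inside the cone is significant at `sig_level_local` (default 0.05) when it
exceeds the corresponding quantile of surrogate coherence pooled per scale
across in-cone positions (thinned to ≤ 25 positions per scale per
surrogate to bound memory; coherence is heavily smoothed, so thinning
sacrifices little information). Per-period average cross-power is tested
at `sig_level_avg` (default 0.1) against the surrogate distribution of the
same average. All stochastic steps take an explicit seed (default 1), and
identical seeds give identical masks.

Known limitations: significance thresholds are pooled per scale rather
than cell-wise (cell-wise nulls at this resolution would need orders of
magnitude more memory or surrogates for no practical gain); agreement with
published wavelet figures is qualitative — band locations and phase
structure — since the original analysis does not specify its wavelet
software, smoothing windows or surrogate model; and only the Morlet family
is offered.

## The simulator

`evolve_family()` generates the ground-truth families used throughout
validation: a uniformly random root sequence walked down a user-given
binary topology, each branch receiving a stated number of substitutions
(positions uniform outside protected blocks, sampled without replacement
per branch; replacement residue uniform over the other 19), then per-taxon
gap blocks applied after substitution so an indel fully masks the
underlying residues. The default study conditions mirror the analysis
setting: 356-position alignments, and the standard validation quartet
((A,B),(C,D)) with 5 substitutions per leaf branch versus 60 per internal
branch, so within-pair and cross-pair distances are cleanly separated.

What the simulator deliberately does not model: empirical exchangeability
matrices (substitutions are uniform), rate heterogeneity beyond protected
blocks, and indel evolution (gap blocks are assigned, not evolved).
Passing tests therefore demonstrate that the pipeline recovers planted
structure under a neutral, clean-signal regime; they do not certify
performance on real families where substitution biases and alignment
uncertainty interact with the encoding.

## Validation design and problem sizes

The test suite checks every measure against an independently coded
brute-force oracle (direct evaluation of the defining formula, or an
alternative identity: MI is cross-checked through its Kullback–Leibler
form, the Morlet FFT route against periodized time-domain convolution,
box counting against a `cut()`-based binning) to 1e−12 relative tolerance
on random fixtures, plus property-style invariants (metric axioms on
random triples, symmetry, bounds, monotone degradation of correlation with
substitution load over {0, 5, 20, 80} substitutions). Topology recovery is
measured over 100 simulated quartets per property; the wavelet type-I rate
uses 200 surrogates and 10 independent white-noise pairs on 356-position
series with periods 2–64 at 6 voices per octave — sizes at which the whole
suite completes in well under a minute while Monte-Carlo error stays far
inside the tolerance bands. `scripts/acceptance.R` recomputes the headline
quantities from scratch at the same sizes.

One validation target is external: reproduction of published relatedness
matrices for the Osteopontin consensus alignments requires the source
publication's supplementary alignment file, which is third-party data not
distributed here. The corresponding test looks for a user-installed
`extdata/FS1_osteopontin_consensus.fasta` and reports a failure until it
is supplied; the shipped `synthetic_family.fasta` is a clearly-labelled
synthetic stand-in for examples only.

## Consensus and I/O policies

Consensus construction is per-column majority with the gap symbol voting
(a mostly-gap column yields a gap — indel stretches in group consensus
sequences must be producible). Ties resolve deterministically: a residue
beats the gap, and the alphabetically first residue wins among tied
residues; the source procedure is silent on ties, so this is a
reproducibility policy, flagged as such. Positions are 1-based everywhere.
Aligned FASTA parsing goes through `seqinr`; the Clustal reader is a small
tolerant parser written here because both installed Clustal readers
(`seqinr`, `Biostrings`) reject common single-block Clustal Omega output
(one requires repeated name blocks, the other a double blank line after
the header).
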