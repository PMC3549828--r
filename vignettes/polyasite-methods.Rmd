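---
title: "A minimal-feature model of polyadenylation sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal-feature model of polyadenylation sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyasite)
```

## The problem

Nearly every eukaryotic mRNA is cleaved at its 3' end and polyadenylated.
The sequence around a cleavage site is only loosely constrained: most
mammalian sites carry an A-rich hexamer (the poly(A) signal, canonically
AWUAAA) roughly 20 nt upstream, a CA-like dinucleotide at the cut itself,
and a U/GU-rich downstream element (DSE); plants and invertebrates often
lack the DSE entirely, and within one genome almost no two sites look
alike. `polyasite` implements a deliberately small model of this anatomy —
four scalar features per candidate site — that can be trained on one
species' sites and applied to another's, together with the machinery to
localize the cis-elements in the first place, to generate realistic null
sequences, and to quantify cross-species transfer.

## Coordinates

All positions are anchored at the cleavage point: `-1` is the last
transcribed base before the cut, `+1` the first base after it, and there is
no position 0. The onset convention follows from how the cleavage-site
dinucleotide is observed to straddle the cut (its two bases sit at `-1` and
`+1`); a zero position would make "the dinucleotide across the cleavage
site" ambiguous. Regions are signed intervals written `"<-N,+M>"`; the
modelling windows are `<-100,+100>` for sequence features and
`<-300,+300>` for occupancy. In R, indices are 1-based, so `pa_to_index()`
maps `-N` to 1.

## Cis-element localization by PCA

The position-by-kmer matrix counts, for every kmer start position, how many
sequences carry each of the `4^k` kmers there. Rows (positions) are near
identical wherever the sequence is unconstrained, so after column centring
a PCA of this matrix pushes constrained positions away from the origin; the
loadings of the same components show which kmers drive each excursion, and
reading score and loading directions together (a biplot) assigns oligos to
the distal-upstream (DUR), proximal-upstream (PUR), cleavage-site (CS) and
downstream (DR) regions.

Choices we made where the procedure is genuinely open:

* **Covariance, not correlation.** All columns are counts on one scale, and
  rescaling rare kmers to unit variance would amplify noise; an option
  (`scale. = TRUE`) is provided.
* **Sign normalization.** Eigenvectors are defined up to sign; we flip
  components so that the farthest-from-origin position has nonnegative
  coordinates, making results identical across eigensolvers.
* **Peak grouping.** Positions at or above a threshold fraction (default
  0.5) of the maximum origin distance are merged into contiguous groups; a
  gap of more than 2 positions starts a new group. Group oligos are those
  whose loading direction lies within 45° of the group's distance-weighted
  mean score direction.
* **Element onset.** A kmer window overlapping an element anywhere along
  its length is perturbed, so the localization signal of an element
  smears downstream of its start; `pa_signal_position()` therefore
  reports the *onset* of the above-half-max run inside a search window
  (default `<-60,-6>`, which excludes the cleavage-site element) as the
  element-start estimate, rather than the argmax.

## Position score matrices

The PSM for kmer size `k` over region `<-100,+100>` is a
`4^k x (l-k+1)` matrix whose entry for kmer `w` at start position `n` is
the log2 fold difference of observing `w` at `n` in real versus false
site sequences. A raw count ratio is undefined at zero counts and depends
on dataset sizes, so entries are computed from Laplace-smoothed
per-class frequencies:

$$v(w,n) = \log_2 \frac{(c_{\mathrm{real}}(w,n)+\alpha)/(R+\alpha 4^k)}
{(c_{\mathrm{false}}(w,n)+\alpha)/(F+\alpha 4^k)}$$

with `alpha = 1` by default (`alpha = 0` is allowed only when no entry
would be infinite). A sequence's score over a subregion is the sum of
entries for every kmer lying *entirely* inside the subregion — the
boundary rule that gives 98 trimers for `<-100,-1>`, 48 for `<+1,+50>`
and 19 dimers for `<-10,+10>`. One PSM per kmer size is built over the
full `<-100,+100>` window and subregion scores are sums over its columns,
rather than building separate per-subregion matrices.

## Nucleosome occupancy and the NOM

Real sites show depleted predicted nucleosome occupancy around the
cleavage point while Markov-generated negatives stay flat, so the fourth
feature scores a per-position occupancy track (probabilities in `[0,1]`
over `<-300,+300>`) against a nucleosome occupancy matrix (NOM). The NOM
is the PSM construction with occupancy bins playing the role of kmers:
`B = 20` equal-width probability bins, the same smoothing, and scoring by
lookup-and-sum. The alternative reading — a single per-position log-ratio
of mean occupancies scored by inner product — is available as
`mode = "profile"`; the binned form is the default because it makes
scoring a new track exactly parallel to PSM scoring. Both bin count and
pseudocount are package choices, not values fixed by the underlying
method description.

Occupancy can come from any genome-wide track via `pa_read_track()`
(bedGraph/fixed-step WIG). For sequence-only workflows,
`pa_predict_occupancy()` supplies a deterministic composition-based
surrogate — a logistic transform of the 147-nt running GC fraction minus
an A/T-homopolymer penalty, with 200 positions trimmed from each end of a
`<-500,+500>` window because the running window is unreliable there. This
stand-in is *not* a trained nucleosome model; its contract is determinism,
range and monotone sensitivity to composition, and real analyses should
supply genuine tracks.

## Markov negatives

False sites are sampled from a homogeneous 2nd-order Markov chain fitted
to the real sequences over `<-300,+300>`: transition probabilities are
pooled trinucleotide counts with Laplace smoothing (`alpha = 1`, so every
transition remains sampleable from small training sets), and the initial
dinucleotide law is smoothed the same way. Position-homogeneity is
essential — a position-specific chain would reproduce the very positional
signal the negatives must lack. Negatives are generated once per dataset
(600 nt, so both modelling windows can be cut from one negative), at a
1:1 ratio by default, before any cross-validation fold assignment.

## Classifiers and evaluation

Each site is summarized by four standardized features (upstream trimer
PSM `<-100,-1>`, downstream trimer PSM `<+1,+50>`, cleavage-site dimer PSM
`<-10,+10>`, NOM score `<-300,+300>`). Standardization uses means and
standard deviations of the pooled real + false training set. During
cross-validation the standardizer is refitted on each training split so no
test statistics leak into training; `paper_standardization = TRUE`
restores whole-dataset standardization for comparability with analyses
that standardized up front.

Logistic regression is fitted by maximum likelihood (IRLS via
`stats::glm`, capped at 100 iterations so perfectly separable data
converges with a warning rather than diverging). LDA is implemented from
the shared-covariance Gaussian formulation — class means, pooled
within-class covariance (ridge-repaired only if singular), class-frequency
priors — and validated in the test suite against both a brute-force
density evaluation and an independent implementation. Both classifiers
emit a positive-class probability; the default decision threshold is 0.5
(a threshold sweep, `pa_roc()`, reports the Youden optimum) and ties are
called positive. Class-frequency priors coincide with equal priors at the
default 1:1 negative ratio.

Performance is reported as sensitivity, specificity (percent) and the
Matthews correlation coefficient, with MCC defined as 0 whenever a
denominator factor vanishes. The headline evaluation design is 20
repetitions of stratified 10-fold cross-validation (200 fits), averaging
the 20 repetition-level results.

## Cross-species transfer

A model bundle travels with its matrices: applying species A's model to
species B's real sites means extracting B's features with A's PSMs, NOM
and standardizer, and reporting the fraction predicted positive
(sensitivity). The reciprocal sensitivity of a pair is the arithmetic mean
of the two directed sensitivities — the definition was fixed by verifying
that all 21 published pair values equal the mean of the corresponding
directed entries, which the test suite re-checks exactly. Distances from
marker-gene phylogenies are consumed as an input table (shipped as a
fixture for seven eukaryotes), and their association with reciprocal
sensitivity is summarized by Pearson correlation (the published analysis
names only "correlation coefficients"; Pearson is our reading, and the
shipped table reproduces the published values of about −0.87, −0.50 and
−0.77 for GAPDH, 18S and CPSF3).

## Sliding-window scanning

`pa_scan()` slides a 600-nt window (step 1 nt by default) along a long
sequence, scoring each window as if its centre were a cleavage point.
Candidate sites are local probability maxima at or above the threshold;
calls within 25 nt are merged keeping the strongest. The merge radius is
wider than the biological cleavage precision (about ±5 nt) on purpose, to
suppress shoulder calls from adjacent overlapping windows.

## The synthetic generator

`pa_simulate()` emulates the site anatomy the model assumes: background
sequence (iid bases, AT-rich as in 3' UTRs, or a supplied Markov chain),
a signal hexamer planted at a start position drawn from a rounded normal
(defaults: AATAAA with weight 0.66 and ATTAAA with 0.16 — the canonical
mammalian usage — with the remaining 18% of sites left signal-less; mean
start −21, sd 3), a CA-dominant cleavage dinucleotide straddling `-1/+1`,
an optional U/GU-rich element over `+5..+30`, and occupancy tracks with a
Gaussian dip (depth 0.3, FWHM 150 nt, baseline 0.6) for real sites versus
flat tracks for false ones, both with clipped per-position Gaussian noise
(sd 0.05, the simplest noise satisfying the track contract).
`pa_divergent_profiles()` interpolates a profile toward an alternate
hexamer set with a shifted signal position and weakened DSE, emulating
species whose site architecture has drifted.

What the generator does *not* emulate — genome heterogeneity, alternative
polyadenylation, multi-site genes, compositional isochores, real
nucleosome positioning — bounds what green tests mean: they demonstrate
that the implementation recovers planted structure of the stated kind and
strength, not that the model attains any particular accuracy on real
genomes.

## Numerical and degenerate-input choices

* Pseudocounts default to 1 everywhere; `alpha = 0` is accepted only when
  finite.
* Ambiguous bases (N and other IUPAC codes) are kept in sequences but
  excluded from kmer counting and contribute 0 to scores; records with
  more than 10% ambiguous bases are rejected as a quality floor.
* RNA input (U) is silently normalized to DNA (T).
* Zero-variance features, single-class training sets, empty datasets,
  windows outside their regions and uncovered track positions are errors,
  not silent degradation.
* All sampling functions take explicit seeds; equal seeds give identical
  output.

## Problem sizes

The packaged validation study uses 2000 real plus 2000 negative sites for
training and cross-validation (20 × 10-fold, 200 fits per classifier),
2000 sites for PCA localization, and 500 synthetic 2000-nt sequences for
scanning — sizes at which every stage completes in well under a minute on
one CPU while the measured properties (accuracy ≥ 85%, signal onset
within ±2 nt, ≥ 95% of planted sites recovered within ±10 nt) are stable
across seeds.

## Known limitations

The occupancy stand-in is a composition heuristic, not a nucleosome
model; cross-species conclusions from synthetic "species" are qualitative;
the classifier assumes pre-extracted, cleavage-anchored windows and does
not discover poly(A) sites from transcript evidence (EST/cDNA mapping is
upstream of this package); and kmer sizes above 8 are unsupported (the
hexamer-versus-trimer comparison is the only intended use of sizes above
3).
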