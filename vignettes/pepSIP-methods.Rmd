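---
title: "pepSIP: models and methods for protein-SIP with de novo peptide databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pepSIP: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepSIP)
```

# The problem

Protein stable isotope probing reads substrate assimilation off the
isotopologue envelopes of peptides measured by mass spectrometry. When a
community is fed a heavy-isotope substrate, active members incorporate
the label into newly synthesized protein; the fraction of heavy atoms in
a peptide's element pool — its relative isotope abundance (RIA, in atom
percent) — shifts the envelope toward higher nominal masses. pepSIP
implements the full analysis path for the case where the search database
is assembled from *de novo* sequencing of unlabeled samples rather than
from a (meta)genome, covering database assembly, validation, RIA and
labeling-ratio quantification, peptide-centric taxonomy and function,
and an audit for labeled populations the reference cannot explain.

# Isotopologue envelopes

A peptide's elemental composition is the residue sum plus one water;
fixed cysteine carbamidomethylation can be applied as a composition
delta (the standard iodoacetamide adduct, +C2H3NO per cysteine). The
packaged isotope table fixes natural heavy-isotope abundances at
1.07 atom% ¹³C, 0.0115% ²H, 0.205% ¹⁸O and 0.364% ¹⁵N; sulfur is
carried through the same machinery with natural abundances only, since
none of the supported labeling schemes targets it.

Envelopes live in nominal mass-shift space: each isotope contributes its
integer shift relative to the element's lightest isotope, and the
envelope is the convolution of per-element multinomial distributions,
computed exactly by direct (non-FFT) convolution with binary
exponentiation over atom counts. Labeling at RIA $a$ replaces the label
isotope's abundance with $a/100$ and rescales the element's remaining
isotopes proportionally, so RIA equal to the natural abundance
reproduces the natural envelope identically. Aggregated nominal-mass
resolution is deliberate: the downstream pattern windows operate on
aggregated peaks, and fine isotopic structure is invisible at the MS2
resolutions these experiments use. Trailing peaks are truncated once
cumulative probability reaches $1 - 10^{-6}$, which bounds envelope
length for nearly fully labeled peptides; the truncation tolerance is a
parameter wherever exactness matters (the test suite's enumeration
oracle runs at tolerance 0).

# RIA and labeling-ratio estimation

Quantification operates per feature: a peptide, a charge and ordered
peak intensities aligned to shifts $+0 \ldots +K$. An alignment helper
maps raw (m/z, intensity) pairs to bins of width $1/z$ Da with a ±10 ppm
anchor tolerance, mirroring the precursor tolerance used during
identification.

The estimator is a grid search with greedy residual fitting:

1. Theoretical envelopes are computed on an RIA grid from the natural
   abundance to 100 atom%, at 0.5 atom% steps for ¹³C/¹⁸O and 0.1 for ²H
   (²H windows are tighter throughout because its natural abundance and
   attainable enrichments are far smaller).
2. The template best correlated (Pearson) with the current residual is
   accepted while its correlation reaches `minCorrelation` (default
   0.7). Correlation is evaluated over the template's own support window
   (positions carrying ≥ 1% of its maximum, padded to ≥ 3 points): a
   narrow, heavily labeled template would otherwise be judged against
   positions where it is structurally zero.
3. After each acceptance the observed vector is refit by non-negative
   least squares (NNLS) on the accepted set and the residual updated.
   This is what resolves mixtures: the dominant component is explained
   first, and the minor component's correlation emerges in the residual.
   A plain local-maxima scan of the raw correlation curve fails here —
   the dominant peak suppresses the Pearson correlation of the minor
   template over the full vector — which is why the greedy residual form
   was chosen.
4. Final intensity shares are the NNLS coefficients renormalized to
   sum 1. Weights below a 2% share floor are dropped: grid
   discretization otherwise surfaces sub-percent satellite weights next
   to a true component.

Because detection compares the observed envelope against computed
templates, no unlabeled reference feature is required — a deliberate
divergence from tools that detect enrichment relative to a measured
light pattern.

Weights within the isotope-specific merge window (±1.5 atom% ²H, ±5.0
¹³C/¹⁸O) are merged single-linkage: share-weighted mean RIA, summed
shares, maximum correlation. A peptide is **labeled** when any merged
weight lies outside the natural window (natural ± merge window); purely
natural peptides are reported with `labeled = FALSE`, not suppressed.
The labeling ratio of a weight is its intensity share; `lrLabeled` sums
the shares of non-natural weights. Features with fewer than 3 peaks, or
no intensity beyond the monoisotopic peak, or no template passing the
correlation gate are reported unassigned rather than forced to natural.

At the peptide level, a peptide counts as labeled when it is labeled in
at least `minSamples` (default 2) distinct samples, and its
representative RIA is the share-weighted mean of its non-natural weights
(natural weights if unlabeled).

# Validation: FDR and entrapment FDP

Decoys are whole-sequence reversals (database entries are peptides, so
no enzymatic terminus is preserved); palindromic collisions fall back to
seeded shuffling. At each score threshold the FDR estimate is
#decoys/#targets among passing PSMs, ties broken decoy-first, and the
q-value is the running minimum toward looser thresholds. The +1
correction is off by default and recorded in the output metadata; it is
a toggle, not a behavioural fork.

The entrapment construction appends sequences foreign to the sample:
for peptide databases, an entrapment proteome digested into tryptic
peptides of 6–100 residues with up to two missed cleavages,
target-colliding peptides removed, then a seeded sample sized to the
entrapment-to-target ratio $r$. The estimator

$$\widehat{\mathrm{FDP}} = \frac{N_E\,(1 + 1/r)}{N_T + N_E}$$

counts identified entrapment peptides $N_E$ as known false positives and
extrapolates $N_E/r$ expected false positives inside the target portion.
Interpreted against the false proportion among *original-target*
identifications it is conservative by roughly a factor $(1+r)$, which is
the property the simulation suite checks (coverage ≥ 95% over seeded
runs with planted truth).

A note on calibration testing: the q-value procedure accepts the
largest PSM set whose estimated FDR sits below the threshold, which
imparts a small positive selection bias on the realized false
proportion (about +0.0005 at the 1% level in our simulations,
essentially unchanged by the +1 correction). Calibration is therefore
asserted per seeded run against that run's binomial sampling interval,
with the across-run pass count compared to nominal 95% coverage.

# Taxonomy, GO slims and group statistics

Unipept-style peptide taxonomy is re-implemented locally for
determinism and offline use: reference proteins (each carrying a taxon
id) are digested under configurable rules and indexed by I/L-collapsed
peptide key, since leucine and isoleucine are isobaric and
indistinguishable by mass. A query peptide's taxon is the lowest common
ancestor (LCA) of all taxa holding its key. "Advanced missed-cleavage
handling" is interpreted as: an unmatched query is split at internal K/R
sites, and assignment requires all fully tryptic fragments to match,
taking the LCA over taxa common to every fragment (per-fragment LCAs
when no taxon holds all fragments). Unassigned is a value, not an error
— such peptides feed the BLAST export.

GO terms propagate from source proteins to peptides as a multiset;
slim rollup maps each term to its ancestors-or-self within the slim via
the is_a graph of a minimal OBO reader (id, name, is_a, obsolete — all
that rollup needs), dropping terms with no slim ancestor and counting a
term once under each slim ancestor it reaches.

Grouped RIA comparisons use the pooled-variance two-sample t-test
(`t.test(var.equal = TRUE)`) with stars at p < 0.05/0.01/0.001 and no
multiple-testing correction by default, mirroring common reporting
practice in this field; Benjamini–Hochberg is available behind a flag.
Group filters default to ≥ 3 peptides per group and ≥ 2 samples per
peptide. Rank summaries use the fixed 7-rank ladder
(domain…species); peptides whose LCA is shallower than the requested
rank are excluded from that rank's table, so counts are conserved
monotonically toward finer ranks.

# Drop-off auditing

Drop-off rates describe the decline in taxon-specific peptide counts
from general to specific ranks along a focal lineage. The theoretical
profile digests the focal taxon's expressed proteins into 7–15 residue
tryptic peptides, applies a pluggable detectability predicate (default:
accept all; a naive length/hydrophobicity heuristic is bundled for
demonstrations), draws a seeded sample (3,500 by default), and assigns
each peptide through the index. The observed profile tallies labeled
peptides' LCAs on the same lineage. Profiles are expressed as fractions
of the domain-level total, cumulative from species upward — so the
domain fraction is 1 and fractions are non-increasing toward species —
and profiles are compared per rank in absolute percentage points, with
the maximum deviation as the headline statistic. This fraction
definition is a design choice recorded in the output metadata. A
sequence-randomization control (within-peptide shuffles, preserving
length and composition; 10 rounds by default) estimates the
false-positive assignment expectation per rank.

The trypsin rule is cleavage C-terminal of K/R except before proline
(toggleable); one consequence worth knowing is that under the no-P
convention a tryptic product can never begin with P.

# The synthetic community

The simulator is first-class, seeded code, and its defaults are the
study conditions the rest of the package is validated under: five taxa,
two labeled — one near-completely labeled at 95.7 atom% ¹³C (the
long-incubation, sole-carbon-source regime) and one at 50 atom% (an
intermediate enrichment) — three at natural abundance; equal
abundances; 30 proteins per taxon with average-proteome residue
frequencies and log-normal lengths; sister species sharing 30% of
proteins verbatim, which manufactures genus-level non-specific
peptides. Features add 2% multiplicative log-normal peak noise, a small
additive uniform baseline, and dropout below a relative-intensity floor
— the simplest noise model that degrades envelope fits realistically
without simulating raw spectra. De novo reads carry independent
per-residue substitutions (mass-plausible swaps preferred; no
insertions/deletions, so truth alignment stays trivial) with
quality scores from a high-mean Beta component for error-free reads and
a lower-mean component otherwise. PSM score sets draw true targets from
a shifted normal and false targets and decoys i.i.d. from the null —
the equal-null assumption of target-decoy competition, made literal.

What the simulation does **not** emulate: chromatographic peak shapes,
charge-envelope interference, co-eluting isobaric contamination,
spectrum-level noise, real score distributions of any particular engine,
and realistic proteome homology structure. Passing tests therefore
demonstrate correctness of the algorithms under the stated noise model,
not performance on any particular instrument or community.

# Problem sizes and numerical choices

The validation suite runs at desk scale by construction: envelope
enumeration oracles up to 25 atoms; 200-node random trees with 1,000
LCA queries; ≥ 200 unlabeled features for the natural-abundance
calibration (median estimated RIA within ±0.3 atom% of the natural
1.07); 1,000 noisy natural features for the ≤ 1% false-labeling bound;
20 seeded runs of 10,000 PSMs for FDR calibration; 200 seeded
entrapment simulations for the FDP upper-bound property. Grid
templates are cached per (composition, element, step, length), which
makes replicate features of one peptide cheap. All randomness flows
through explicit seeds via a local RNG wrapper that never perturbs the
caller's `.Random.seed`, so every generator and every pipeline run is
rerun-identical.

# Known limitations

- Quantification assumes the supplied sequence string reflects the
  peptide's composition; variable modifications affect identification
  (out of scope here) rather than envelope math, and only fixed
  cysteine carbamidomethylation is applied as a delta.
- One label element per experiment; no joint multi-element fitting.
- The RIA grid bounds resolution at half the grid step; sub-grid
  refinement was judged unnecessary against the ±1.5/±5 merge windows.
- LCA fidelity is to the definition, not to any external service's
  byte-level output; protein inference is deliberately avoided
  (peptide-centric throughout).
- The de novo error model omits insertions/deletions, so database
  contamination by length-shifted reads is not simulated.
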