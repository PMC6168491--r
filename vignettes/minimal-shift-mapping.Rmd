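---
title: "Minimal chemical-shift mapping and SID discovery with CSPmap"
author: "CSPmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal chemical-shift mapping and SID discovery with CSPmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CSPmap)
```

## The problem

Chemical shift perturbation (CSP) is the workhorse NMR experiment for
protein–ligand interaction mapping: a ¹⁵N-labelled protein is titrated
with an unlabelled partner and the movement of its ¹⁵N-HSQC cross peaks
reports where and how strongly the partner binds. When backbone
assignments are available, per-residue CSPs localise the interface.
Very often, however — mutant panels, screening settings, or simply
unassigned spectra — no assignments exist. *Minimal chemical-shift
mapping* replaces the per-residue analysis with an assignment-free one:
peaks of two spectra are placed in one-to-one correspondence by a
minimal-distance criterion, and the comparison is summarised by the
average minimal shift over all matched peaks. Because every peak is
matched to the *nearest* plausible counterpart, the statistic is a lower
bound on the true average perturbation; it can understate an effect but
not invent one, which makes it a conservative, robust score for ranking
a series of complexes (for instance wild-type against point mutants of
an interaction motif).

CSPmap implements this analysis chain end to end, together with the
sequence-analysis steps used to find the interaction motif in the first
place: helical-wheel geometry, hydrophobic moments, a short/long
hydrophobic pair motif characteristic of Sin3-interaction domains
(SIDs), and alignment conservation. The motivating system is the
interaction between the PAH1 domain of the transcriptional corepressor
Sin3A — a four-helix bundle presenting a hydrophobic cleft — and the
short amphipathic SID helix of the DNA dioxygenase Tet1, whose
hydrophobic face (A893, I894, A896, L897, L900) docks into that cleft.

## The minimal-shift statistic

Peak distances combine both dimensions with the common 7:1 ¹H:¹⁵N
weighting,

$$\Delta\delta = \sqrt{\Delta\delta_H^2 + (\Delta\delta_N / 7)^2},$$

so that a ¹⁵N shift of 7 ppm counts as much as a ¹H shift of 1 ppm
(`weightedDistance()`, divisor configurable). Between two peak lists
$A$ and $B$, `matchPeaks()` builds the full weighted distance matrix
and establishes a one-to-one matching of size $\min(|A|,|B|)$. Two
readings of "minimal distance matching" exist in practice, and the
package provides both:

* **optimal** (default): the matching minimising the *total* weighted
  distance — the linear assignment problem, solved exactly by a
  Jonker–Volgenant shortest-augmenting-path algorithm. For lists of up
  to six peaks the unit tests verify the solution against exhaustive
  enumeration over all permutations; the solver is exact at any size.
* **greedy**: repeatedly pair the globally closest unmatched peaks.
  This is what simple in-house scripts typically do; it can lock in a
  locally attractive pair and force a long detour later. The optimal
  total is never larger, and results record which mode produced them.

The comparison statistic is then

$$\Delta\delta_{\min} = \frac{1}{N}\sum_{\text{matched pairs}} \Delta\delta,$$

the summed difference over all matched peaks divided by the number of
matched peaks (`minimalShiftSummary()`). Unmatched peaks (unequal list
sizes, or pairs dropped by the optional `max_distance` gate) are
reported but never averaged. Useful identities, all enforced by tests:
$\Delta\delta_{\min}(A,A)=0$ exactly; for equal sizes the optimal mode
is symmetric in its arguments; and with a known true correspondence the
optimal matched total never exceeds the true total — the
underestimation property above.

`compareSeries()` ranks many comparisons against one reference. Both
conventions of a mutant-series analysis are reached by choosing the
reference: complexes against the apo spectrum measure the magnitude of
the binding effect; mutant complexes against the wild-type complex
measure how much the mutated residue contributed to complex formation.

Asn/Gln side-chain NH₂ peaks do not report on backbone conformation and
are excluded before matching (`excludeSidechainNH2()`). Annotated peaks
are removed by flag; for unannotated lists an optional heuristic removes
peak pairs sharing a ¹⁵N shift within 0.2 ppm with both ¹H shifts in
6.4–7.8 ppm — the geminal NH₂ doublet signature. The thresholds are
package choices; peaks annotated as backbone amides are never touched.

## Peak picking

`pickPeaks()` reproduces the standard automatic picking step applied to
processed 2D spectra: local maxima (8-connected, strict, with the
lowest-index cell winning on exact plateaus) above a threshold of 1.4
times the spectrum noise level, the factor conventionally used for
HSQC picking. "Noise level" is not standardised across processing
software; CSPmap defines it as the scaled median absolute deviation
(MAD × 1.4826) of all grid intensities (`estimateNoise()`), which stays
anchored to the baseline even on signal-rich spectra — a single large
spike leaves it unchanged. The threshold factor is a parameter
precisely because different software applies its factor to different
base levels. Apex positions are refined by 3-point parabolic
interpolation per axis, clipped to half a grid step; overlapping peaks
are *not* deconvolved — picked positions are apex estimates, nothing
more. Note that at 1.4σ Gaussian noise alone produces spurious local
maxima at a rate of about 6% of interior grid cells
($\int_{1.4}^{\infty}\phi(x)\Phi(x)^8\,dx$); the original workflow
handled these by manual curation, which the package represents by
`removePeaks()`.

## Sequence discovery of SID candidates

The SID search combines four signals per sliding window
(`scanSID()`, default window 11 residues — the length of the minimal
Tet1-SID; the wider 15-residue window used in some analyses is one
parameter away):

* **Helical wheel**: ideal α-helix geometry at 3.6 residues/turn, i.e.
  100° per residue (`wheelAngles()`); angles depend only on position.
* **Hydrophobic moment**: the Eisenberg moment of the window
  (`hydrophobicMoment()`), with the consensus scale as default. The
  scale is centred before summing, making the moment invariant under
  adding any constant; `X` contributes the mean, i.e. nothing. Moment
  scoring stands in for secondary-structure prediction, which would
  require an external service.
* **Hydrophobic face**: residues with positive centred hydrophobicity
  whose wheel angles fit inside a minimal covering arc of at most 180°
  (`hydrophobicFace()`). The Tet1-SID window 893–900 puts A893, I894,
  A896, L897 and L900 on one 160° face.
* **Pair motif**: small hydrophobic (A, G, S, C) at offsets $i$ and
  $i+3$, large hydrophobic (L, I, V, M, F) at $i+4$ and $i+7$
  (`sidMotifMatch()`) — the lock-and-key arrangement Tet1 realises as
  A893/A896 + L897/L900. The small/large alphabets are package
  definitions generalising the named instances.
* **Conservation**: per-column $1 - H/\log 21$, Shannon entropy over
  the 20 amino acids plus gap (`columnConservation()`), averaged over
  the window when an alignment is supplied.

The combined score is a weighted sum (default weights 1:1:1) of the
z-scored moment, the z-scored window conservation and a motif bonus.
Z-scoring *both* continuous terms is a deliberate design choice: the
moment is unbounded while conservation lives in $[0,1]$, and in early
testing raw conservation was routinely swamped by moment outliers such
as charge-clustered windows, which carry large Eisenberg moments
without being interaction motifs. On a common scale, a window must be
jointly unusual in amphipathy and conservation (plus motif-positive) to
rank first. No claim is made that any weighting reproduces expert
visual inspection of an alignment; the weights are parameters.

Since the full Tet1 sequence is not bundled, tests and examples encode
exactly the residues named for the Tet1-SID (A893, I894, A896, L897,
T898, L900, E902) with neutral hydrophilic placeholders elsewhere;
real-sequence scans expect user-supplied FASTA
(`Biostrings::readAAStringSet()`).

## The synthetic-data model

No experimental peak lists are bundled, so `makeApoPeakList()`,
`makeComplexSeries()` and `renderGrid()` generate data with the
statistical structure the analysis assumes, plus known ground truth.

* **Apo spectrum**: `n = 90` backbone amides uniform over ¹H 6.5–10.5,
  ¹⁵N 103–133 ppm with a minimum pairwise weighted separation of
  0.05 ppm (rejection sampling) — a well-dispersed small domain. The
  90-peak default represents a PAH-domain-sized protein.
* **Binding**: slow exchange at 1:1 stoichiometry is modelled as fully
  shifted peaks — each list shows one peak per amide at its bound
  position. (True slow-exchange titrations show apo and bound peaks
  coexisting at sub-stoichiometric ratios; that doubling is outside the
  default scenarios.) A fixed interface fraction (default 0.3 — the
  true interface size of a PAH1-type complex is not known, this is a
  flagged guess) of peaks is displaced. Each interface peak gets one
  base displacement: weighted magnitude Gamma(shape 2) with mean
  `mean_shift`, direction uniform in weighted space. Gamma gives
  positive, right-skewed magnitudes, as CSPs are.
* **Mutants**: each label scales the *same* base displacements by an
  effect multiplier — a weaker-binding mutant moves the same peaks in
  the same directions, only less. Everything receives isotropic
  weighted-space jitter (default σ = 0.005 ppm, a typical peak-position
  uncertainty), including a regenerated apo list.
* **Calibration**: the built-in `tet1MutantScenario()` uses multipliers
  (WT 1, L897A 0.07, L900A 0.42, I894A 0.52, T898E 0.70, T898A 0.795)
  chosen once from the ratios of published average-minimal-shift values
  for a Tet1-SID mutant panel, so the mutant-vs-WT comparisons are
  ordered L897A > L900A > I894A > T898E > T898A — the published
  residue-importance ordering. `mean_shift = 0.48` ppm was calibrated
  once so the measured apo-vs-WT $\Delta\delta_{\min}$ of the default
  scenario lands near the 0.127 ppm anchor; the measured value sits a
  few percent below `interface_fraction × mean_shift` because optimal
  matching slightly underestimates large displacements. Note the
  shared-vector model is deliberately simple: published mutant-vs-apo
  and mutant-vs-WT values are not simultaneously representable by any
  scaling along one line (they do not sum to the apo-vs-WT value), so
  only the ordering and the apo-vs-WT magnitude are emulated.
* **Alignment generator**: `makeSidAlignment()` plants a fully
  conserved amphipathic, motif-positive 11-mer (`AIEALTELQES`) inside a
  200-residue background mutated at 50% per row and column. Background
  residues follow a disorder-like composition (polar/charged/small
  enriched, large hydrophobics rare), emulating the low-complexity
  regions that flank short linear motifs; a uniform composition would
  scatter spuriously amphipathic windows through the background, which
  real disordered sequence does not.

What passing tests on these data do **not** show: performance on
crowded real spectra (peak overlap, intensity loss from exchange
broadening, appearing/disappearing peaks), referencing errors between
spectrometers, or SID discovery in globular (hydrophobic-rich)
backgrounds where moment and motif signals are weaker discriminators.

## Structure comparison

`readStructure()` parses one model of a PDB file (first ensemble member
by default, blank/'A' altlocs kept) along with its HELIX records;
`superposeRmsd()` pairs atoms by (segment order, residue offset, atom
name), superposes them by the Kabsch SVD solution restricted to proper
rotations, and reports RMSD. "Backbone" defaults to N, CA, C — adding O
is one argument away. `comparePah1Helices()` wraps the whole workflow
for comparing two PAH-domain structures over their four helices, e.g.
the deposited PAH1:Sap25-SID and PAH1:REST ensembles (PDB 2RMS and
2CZY), which users can download and compare directly; segments of
unequal length are compared over their common offsets. Pairing by
offset rather than by sequence alignment is a simplification; explicit
segment selections let users impose alignment-derived residue ranges
when the default pairing is off by a turn.

## Numerical choices and degenerate inputs

* Assignment solver: exact, $O(n^2 m)$, pure R; a 90×90 matching runs
  in ~20 ms. Greedy ties are broken lexicographically by id pair, so
  results are deterministic.
* Peak picking: strict local maxima; exact plateaus resolved to the
  lowest column-major index; borders never picked; grids smaller than
  3×3 are errors. Decreasing ppm axes are normalised on construction.
* Moments: scale centred; the Eisenberg consensus scale is itself
  zero-mean, so centring is a no-op there. Homopolymer windows spanning
  whole turns (e.g. length 18 = 5 turns) have moment 0 to machine
  precision.
* Minimal covering arc: 360° minus the largest circular gap between
  sorted angles; a single residue has arc 0.
* Superposition: reflections are excluded by sign-correcting the SVD;
  fewer than 3 paired atoms is an error.
* All generators restore the caller's RNG state and are fully
  determined by their `seed` argument.

## Problem sizes used by the test suite

The packaged tests and the acceptance script run entirely on generated
data at sizes chosen to exercise the methods well while keeping the
suite quick: 90-peak lists for the mutant-series emulation (50
replicate seeds), 200 random list pairs against the enumeration oracle
(n ≤ 6), 1000 pairs for the optimal-vs-greedy bound, 20 rendered
256×256 spectra for picking recall/precision, and 50 planted-SID
alignments (6 × 200 residues). A full run takes well under a minute.

## Known limitations

* $\Delta\delta_{\min}$ is a lower bound; strongly moved peaks can be
  matched to the wrong neighbour, deflating large perturbations — and
  two spectra differing by a *permutation* of peak positions would
  score spuriously low. The statistic ranks comparable spectra; it is
  not an absolute perturbation measure.
* Peaks appearing or disappearing between spectra become unmatched
  peaks only when list sizes differ; with equal sizes they silently
  pair with something else.
* The motif and face definitions assume ideal helical geometry; kinked
  or 3₁₀ segments shift the angles.
* No Kd estimation, no per-residue mapping onto structure, no
  exchange-regime classification: those need assignments or titration
  series the package does not model.
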