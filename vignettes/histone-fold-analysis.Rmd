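---
title: "Quantifying histone dimer folding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone dimer folding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histonefold)
```

## The scientific problem

Histones — the proteins that package DNA in both Eukarya and Archaea —
share the histone fold: three α-helices (α1, α2, α3) joined by two
loops.  Two histone-fold monomers dimerise in an intertwined,
head-to-tail "handshake".  Isolated monomers are disordered at the
tertiary level; stable structure appears only upon binding the partner
("folding upon binding").  Simulations of this process also find an
*inverted* non-native dimer in which α1 of one monomer packs against
the partner's α3; with each α2 helix assigned an N→C direction vector,
the α2–α2 crossing angle of the inverted arrangement is approximately
complementary (180° minus) to the native one.  A relic head-tail
sequence symmetry — hydrophobic positions of one histone recurring at
the reversed positions of its partner — makes the inverted packing
chemically plausible.

`histonefold` implements the quantitative layer of such a study as
reusable, tested operations: structural-similarity order parameters,
trajectory geometry, free-energy reconstruction from umbrella sampling,
polymer scaling, and the reversed-sequence symmetry statistic.  It does
**not** contain a force field or sampler for real proteins; molecular
ensembles are either supplied by the user (multi-MODEL PDB) or emulated
by the synthetic-data module with known ground truth.

## The Q order parameter

Structural similarity to a reference ("native") structure is measured
by

$$Q = \frac{1}{N}\sum_{\text{pairs}} \exp\!\left[-\frac{(r_{ij} - r_{ij}^{N})^2}{2\sigma_{ij}^2}\right],$$

the average over a fixed pair list of Gaussian agreements between the
instantaneous Cα distance $r_{ij}$ and its native value $r_{ij}^N$.
Q is 1 on the native structure, decays towards 0 with increasing
distortion, and depends only on internal distances, so it is exactly
invariant under rigid motion.

Choices that the formula leaves open, and how this package fixes them
(all exposed in `q_spec()`):

* **Pair list.** Intra-chain pairs require sequence separation
  $j - i \ge 3$ (`min_separation`, the conventional "$i < j - 2$"
  rule), in the contiguous internal index — author-numbering gaps in
  PDB files never enter separations.  `monomer` mode uses intra-chain
  pairs; `dimer` adds every inter-chain pair; `interface` uses
  inter-chain pairs only.
* **Pair widths.** $\sigma_{ij} = \sigma_0 (1 + |i-j|)^{0.15}$ Å for
  intra-chain pairs, the growth law customary for this order parameter
  in coarse-grained folding work; inter-chain pairs use the constant
  $\sigma_0 (1 + 3)^{0.15}$ because $|i-j|$ is meaningless across
  chains.  $\sigma_0$ defaults to 1 Å.
* **Interface pair set.** Unrestricted inter-chain Q is dominated by
  long, uninformative distances, so `interface` mode keeps pairs with
  native distance ≤ 9.5 Å by default; set
  `interface_native_cutoff = Inf` for the literal all-pairs variant.
  The signature of "folded monomers, wrong interface" — monomer Q near
  1 with interface Q near 0 — is exercised in the test suite.
* **Homodimers.** Chain labelling is ambiguous for two identical
  chains; `q_score_max()` maximises over the label bijections from
  `enumerate_chain_pairings()`.

`fraction_native_contacts()` is the discrete cousin: native contacts
are pairs (separation ≥ 3, plus all inter-chain pairs) with native Cα
distance ≤ 8 Å, counted as formed below 1.2 × the cutoff.  Both knobs
are configurable; they are stated in every report because contact
criteria are conventions, not measurements.

## Geometry

Superposition uses the Kabsch algorithm via SVD with the usual sign
correction on the smallest singular vector, so the returned rotation
always has determinant +1 — mirror solutions are never accepted, and a
chiral set superposed on its mirror image keeps a strictly positive
RMSD.  Weighted superposition is available; RMSD/RMSF and the pairwise
RMSD matrix are built on it.  RMSF aligns all frames either to the
first frame or (default) to an iterated mean structure (two passes);
for a rigidly moving but internally static body the profile is zero.
Note one finite-size effect quantified in the tests: alignment absorbs
six rigid degrees of freedom, so for an $n$-residue structure under
isotropic per-coordinate noise $s$ the per-residue RMSF approaches
$s\sqrt{3}$ only as $n$ grows (within 2 % at $n = 60$).

Helix axes are fitted as the dominant principal axis of the segment's
Cα coordinates, oriented so the direction points from the N- to the
C-terminal end.  Plain PCA on a short helix is biased by the helical
wobble whenever the segment spans a non-integer number of turns (about
2.3° for 12 residues), so the direction is computed from a one-turn
(window-4) moving average of the trace; straight traces are unaffected
and the reported `fit_rms` is still the raw-point scatter.  A
`method = "termini"` variant (normalised last-minus-first Cα vector) is
provided because published crossing angles do not always state the
axis definition; results should name the mode used.  The crossing
angle `interhelix_angle()` is reported on [0, 180°] *without* folding
to [0, 90°]: orientation is the signal.  Flipping one axis maps θ to
180° − θ exactly — the native/inverted complementarity.

Residue ranges for the α2 helices are deliberately explicit user input
(`segment_spec()`, author or internal numbering): published structures
do not agree on helix boundaries and silently guessing them would move
the angle by several degrees.

Conformational heterogeneity ("no consensus structure" statements) is
assessed by average-linkage agglomerative clustering of the pairwise
superposed-RMSD matrix, cut at a configurable height (default 4 Å),
with medoids as representatives.  The method and cutoff are
conventions; both are recorded in the output.

## WHAM free-energy reconstruction

Umbrella windows carry samples of a reaction coordinate $q$ (here
typically Q) collected under a harmonic bias.  The bias convention is
fixed once and echoed in window-file headers:

$$U_\text{bias}(q) = \tfrac{1}{2}\,k\,(q - q_0)^2,$$

i.e. the spring constant does **not** absorb the ½ — the form in which
harmonic restraints are usually quoted in molecular simulation.  The
1D solver iterates the standard self-consistent equations for the
window free-energy constants $f_w$ and the unbiased bin probabilities,
converging on the maximum change of the $f_w$ (tolerance
$10^{-7}$ kcal/mol, cap $10^5$ iterations; the first window is gauged
to $f = 0$).  $F(q) = -k_\mathrm{B}T\ln p(q)$ is anchored so its
sampled minimum is 0, with `Inf` in empty bins; a zero-count gap inside
the sampled range raises a connectivity warning because the two sides
are then only internally comparable.  $k_\mathrm{B}T$ defaults to
0.593 kcal/mol (≈ 300 K).  Bins are left-closed/right-open with the
last bin closed; out-of-range samples are dropped and counted.

2D surfaces such as $F(Q, \text{α2–α2 angle})$ are built by
reweighting: each sample's weight is the inverse of its total biased
density $\sum_w N_w \exp[\beta(f_w - U_w(q_s))]$, histogrammed on
(q, aux).  Only the primary coordinate is biased; the auxiliary one
rides along.  `barrier_height()` reads a 1D profile: locate the
minimum inside each declared basin range and return the highest
sampled F between them, from the first basin's minimum; an unsampled
gap makes the barrier undefined (error), and identical basins give 0.

The solver is validated against analytic truth from the synthetic
module: Boltzmann inversion is reproduced bin-wise to 10⁻⁹ for a
single unbiased window, a harmonic potential is recovered with RMS
error well under 0.15 kcal/mol (12 windows × 5000 samples), and a
double well with an exact 3 kT barrier is recovered within 0.3 kT.
Free energies are compared after removing the one free additive
constant (mean offset over counted bins).  Autocorrelation estimation
(statistical inefficiency, MBAR) is out of scope; samples are treated
as given, with thinning available at generation time.

## Polymer scaling

`fit_power_law()` fits $R_g = R_0 N^{\nu}$ by least squares in
(log N, log Rg); `reference_deviation()` reports the natural-log-space
residual of a query from a reference line, and `scaling_table()` does
this for batches of structures using Cα-only $R_g$ (stated in the
output — some published curves use all atoms) and, for dimers, the
total residue count over both chains.  The default reference
($R_0 = 2.2$ Å, $\nu = 0.38$) is a generic globular-monomer stand-in,
*not* a survey value: any quantitative use should supply the survey
parameters relevant to the comparison.

## Reversed-sequence hydrophobic symmetry

The analysis formalises the shaded-column observation of reversed
sequence alignments: reverse the partner (C→N), align globally, and
score hydrophobic coincidence.

* **Aligner.** Needleman–Wunsch with affine gaps (Gotoh), implemented
  in C++.  A gap of length $L$ costs `gap_open` + $(L-1)$ ·
  `gap_extend` (defaults −5/−1, with match +2 / mismatch −1; a full
  substitution matrix, e.g. BLOSUM62 from Biostrings, may be supplied
  instead).  Traceback ties break deterministically diagonal > up >
  left, so identical inputs always yield identical alignments.  The
  implementation is checked against exhaustive enumeration of every
  alignment on short pairs.
* **Score.** Over residue–residue alignment columns with a hydrophobic
  residue on at least one side, the fraction where both sides are
  hydrophobic.  Columns against gaps carry no positional-symmetry
  information and are excluded from both counts; this is what makes
  the score exactly 1 for any pair of all-hydrophobic sequences.  The
  hydrophobic set defaults to {A, V, L, I, M, F, W, C} — tyrosine
  excluded, a deliberate, configurable convention echoed in every
  report, since published figures rarely state their set.
* **Null.** Composition-preserving shuffles of the partner, re-scored
  through the full pipeline (reversal + alignment), with the add-one
  estimator $p = (1 + \#\{\text{null} \ge \text{obs}\})/(B + 1)$: it
  can never return 0 and is valid by exchangeability.  Because the
  score is a ratio of small column counts it ties frequently under the
  null (roughly a fifth of draws), which makes the add-one estimator
  noticeably conservative.  For calibration work the
  `ties = "randomized"` variant returns the tie-smoothed randomized
  p-value $(\#\{>\} + U(1 + \#\{=\}))/(B+1)$, the estimator for which
  null uniformity holds; the conservative default remains what the
  package reports for data.
* **Multiple sequences** are handled as all-pairs pairwise reports
  (`symmetry_report_table()`), not a true multiple alignment — a
  stated limitation relative to MSA-based figures, traded for a
  well-defined, testable statistic.

## The synthetic-data module

Every input the pipeline consumes can be generated with known ground
truth, which is what the test suite leans on:

* **Ideal helices** at canonical α geometry (rise 1.5 Å, radius
  2.3 Å, 100°/residue) along any axis; consecutive Cα distances come
  out at the physical ≈ 3.8 Å.
* **Two-helix dimers** at a prescribed crossing angle (placement
  guarantees ≥ 4 Å inter-chain clearance) — fixtures for the
  native-like (140°) and inverted-like (40°) geometries.
* **Perturbed ensembles**: i.i.d. isotropic Gaussian displacement per
  atom per frame — the reference case for Q decay, RMSD/RMSF closed
  forms and planted clustering.
* **Metropolis samples** from analytic potentials (harmonic, double
  well with exact barrier, separable 2D, and a two-basin 2D fixture
  with minima at (0.8, 140°) and (0.35, 40°) mimicking a
  native/inverted free-energy topology) under umbrella biases.  The
  proposal step is tuned during burn-in (first 10 % of the effort,
  minimum 500 steps) towards 30–50 % acceptance; runs below 1 %
  acceptance abort with a diagnostic.
* **Symmetric sequence pairs** with planted head-tail hydrophobic
  symmetry.  With probability `strength` a hydrophobic position of
  `a` is mirrored (same residue) at the reversed position of `b`;
  non-mirrored positions avoid the hydrophobic alphabet with
  probability `strength` and are uniform over all 20 letters
  otherwise.  The pair thus interpolates between an independent
  uniform partner (strength 0) and a perfect mirror whose symmetry
  score is exactly 1 (strength 1), and the generator returns the
  realised planted fraction as ground truth for the alignment-based
  score.

All generators are pure functions of their configuration and seed.

What the synthetic data does **not** emulate: chain connectivity
constraints and excluded volume in perturbed ensembles, correlated
(collective) motions, realistic contact energetics, sequence
composition of real histones, or sampling autocorrelation beyond the
Metropolis chain itself.  Passing tests therefore demonstrate the
correctness of the *statistics*, not the biology of any particular
system; conclusions about real histones require user-supplied
structures and trajectories.

## Problem sizes and numerical choices

The shipped validation uses sizes chosen to exercise each method well
inside a laptop budget: 12–13 umbrella windows × 5000 Metropolis
samples for the free-energy round trips, 500 replicates for null
calibration (99 permutations each) and 50 for power (999 permutations,
planted strength 0.8, length 60), 100 random pairs against the
exhaustive alignment oracle (lengths ≤ 6, where enumeration is exact),
and grid-refined rotation search to 10⁻³ Å agreement for the
superposition oracle.  Degenerate inputs fail loudly rather than
silently: empty chains, all-coincident points, missing residues under
a contact reference, non-overlapping windows, unsampled barriers and
sub-99 permutation counts are all errors or flagged warnings.

## Known limitations

* Cα-only throughout; side-chain contact definitions and
  secondary-structure assignment are out of scope.
* The interface pair set and σ-law are conventions (declared, not
  derived); comparisons across software must align these choices.
* WHAM assumes uncorrelated samples within windows.
* The symmetry statistic is pairwise; evolutionary interpretation
  across many sequences needs a proper MSA upstream.
* The reference scaling line must come from the user for quantitative
  claims.
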