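# histonefold

Quantitative analysis of histone (and histone-like) dimer folding at
the Cα level.

Histone-fold proteins — three α-helices (α1, α2, α3) joined by two
loops — are disordered as monomers and acquire tertiary structure only
by dimerising into an intertwined head-to-tail "handshake".  Folding
simulations of such dimers also find an *inverted* non-native
arrangement (α1 of one monomer against the partner's α3) whose α2–α2
crossing angle, with each helix axis oriented N→C, is roughly
complementary (180° −) to the native one; a relic head-tail symmetry of
hydrophobic sequence positions makes that packing chemically sensible.
This package provides the statistics such a study runs on its
ensembles, as tested, reusable operations:

* **Order parameters** — the structural-similarity measure
  *Q* = (1/N) Σ<sub>pairs</sub> exp[−(r<sub>ij</sub> − r<sub>ij</sub><sup>N</sup>)² / 2σ<sub>ij</sub>²]
  over native pair lists (monomer / dimer / interface variants,
  homodimer chain-pairing maximisation), and the fraction of native
  contacts.
* **Geometry** — Kabsch superposition (always a proper rotation),
  RMSD series, RMSF profiles, radius of gyration, helix-axis fitting
  and the α2–α2 crossing angle on [0°, 180°], pairwise-RMSD
  conformational clustering.
* **Free energies** — 1D WHAM over harmonically biased umbrella
  windows (bias U = ½ k (q − q₀)²), reweighting onto 2D surfaces such
  as F(Q, angle), and basin-to-basin barrier heights.
* **Polymer scaling** — R<sub>g</sub> = R₀ N<sup>ν</sup> fits and
  deviations from a monomeric-protein reference line.
* **Sequence symmetry** — reversed-sequence global alignment
  (affine-gap Needleman–Wunsch), a hydrophobic-symmetry score and a
  composition-preserving permutation test.
* **Synthetic data** — ideal helices and two-helix dimers at a set
  crossing angle, noisy ensembles, Metropolis samples from analytic
  potentials under umbrella biases, and sequence pairs with planted
  head-tail symmetry; every generator is deterministic given its seed
  and carries analytic ground truth.

Structures come in as (multi-MODEL) PDB, sequences as FASTA, umbrella
windows as plain columnar text with a TSV manifest; results leave as
TSV.  A subcommand CLI (`inst/scripts/histonefold`, or
`histonefold::main()` from R) wires the pieces into shell pipelines
with a manifest written per run.

## A worked example

```r
library(histonefold)

# a synthetic native-like handshake surrogate: two helices crossing at 140°
dimer <- make_two_helix_dimer(140)
dimer
#> <ca_structure 'two_helix_140deg' frame 0: 2 chain(s), 40 residues>
#>   chain A: 20 residues [1..20]
#>   chain B: 20 residues [1..20]

# Q of a noisy ensemble about it (1 Å per-coordinate jitter)
ref <- build_contact_reference(dimer, q_spec("dimer"))
frames <- perturb_ensemble(dimer, 5, 1.0, generator_config(seed = 42))
round(q_series(frames, ref), 3)
#> [1] 0.690 0.732 0.694 0.680 0.627

# native vs inverted crossing angle
axA <- fit_helix_axis(dimer$chains$A$ca_coords)
axB <- fit_helix_axis(dimer$chains$B$ca_coords)
interhelix_angle(axA, axB)          # 140
inv <- make_two_helix_dimer(40)
interhelix_angle(fit_helix_axis(inv$chains$A$ca_coords),
                 fit_helix_axis(inv$chains$B$ca_coords))  # 40

# WHAM round trip on a double well with an exact 3 kT barrier
pot  <- potential_spec("double_well")
wins <- data.frame(center = seq(0.1, 0.9, length.out = 13), spring = 1000)
uw   <- sample_potential(pot, wins, 5000, generator_config(seed = 11))
prof <- solve_wham_1d(uw, wham_config(n_bins = 60, range = c(0.05, 0.95)))
prof
#> <fe_profile: 60 bins on [0.05, 0.95], converged after 1115 iteration(s)>
barrier_height(prof, c(0.2, 0.42), c(0.58, 0.8)) / 0.593
#> [1] 3.18        # kT; analytic value 3

# planted head-tail hydrophobic symmetry, detected by permutation test
pair <- make_symmetric_pair(60, 0.8, generator_config(seed = 7))
permutation_pvalue(pair$a, pair$b, n_perm = 999, seed = 1)
#> <symmetry_report: score 0.722 over 18 hydrophobic-bearing columns; p = 0.001 (999 permutations)>
#> hydrophobic set: AVLIMFWC
```

Reading the numbers: Q near 1 means native-like internal distances
(here ~0.7 under 1 Å jitter); the crossing angles recover the built
geometries to fractions of a degree, and 140°/40° are the native-like
and inverted-like arrangements; the reconstructed free-energy barrier
agrees with the analytic 3 kT to within sampling error; the symmetry
score is the fraction of hydrophobic-bearing aligned columns that are
hydrophobic on both sides, and p = 0.001 is the smallest value 999
permutations can resolve.

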