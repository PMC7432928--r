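---
title: "Methods: scoring missense mutations in protein-RNA complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring missense mutations in protein-RNA complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priddg)
```

## The prediction problem

Given the 3D structure of a protein-RNA complex and a single amino-acid
substitution in the protein, `priddg` estimates the binding free-energy
change ΔΔG (kcal·mol⁻¹).  The sign convention is that positive ΔΔG means
the mutation weakens binding.  The estimator is a multiple linear
regression over 11 features; linearity is a deliberate choice: with only
a few hundred training mutations available in this field, a small linear
model with interpretable, physically motivated features generalizes
better than high-capacity learners and exposes each feature's
contribution per mutation.

## Pipeline per mutation

1. **Load** the complex (first NMR model, or the biological-assembly
   file for crystal structures), strip waters and hydrogens, resolve
   alternate locations to the highest-occupancy copy (ties to the first
   altLoc code), and assign partner 1 = protein chains, partner 2 = RNA
   chains.  Known modified residues are mapped to their parent type with
   a warning; complexes with a modified residue *at the interface* are
   rejected, mirroring the training-data curation rule.  Complexes whose
   nucleic partner is not pure RNA are rejected rather than guessed at.
2. **Complete** missing heavy side-chain atoms from ideal-geometry
   templates (backbone-superposed, existing CB and chi-1 orientation
   preserved when present).
3. **Minimize** the wild-type complex: L-BFGS on the bundled force
   field with harmonic positional restraints (default
   5 kcal·mol⁻¹·Å⁻², the protocol's value) on all backbone atoms,
   1000 steps by default, 12 Å nonbonded cutoff inside the minimizer.
   A fixed step count, not a convergence test, terminates minimization.
4. **Build the mutant** from the unminimized wild type by replacing the
   side chain with an ideal-geometry template of the mutant residue:
   the backbone is kept, CB is kept when both residue types have one,
   and the template is rotated about CA-CB to match the wild-type chi-1
   direction.  No rotamer search is performed — a single deterministic
   placement followed by restrained minimization stands in for the
   external model-building tools used in the original protocol.
5. **Minimize the mutant** the same way, then compute the 11 features.

## The force field

The bundled parameter set is a heavy-atom (united-atom style) set:
Lennard-Jones well depths and radii per atom class, and partial charges
per (residue, atom) with hydrogen charges folded into their parent heavy
atoms.  Neutral residues sum to exactly 0 e, Asp/Glu to −1, Lys/Arg to
+1, and each nucleotide carries −1 on its phosphate group, as
appropriate for neutral pH with default charge states.  Hydrogens are
never built; this keeps every energy term well-defined without a
topology engine, at the cost of dropping explicit hydrogen-bond
directionality from the minimization (an acceptable trade for a
restrained, fixed-step relaxation whose purpose is to relieve clashes
introduced by side-chain replacement).  The tables ship as plain-text
TSVs (`inst/extdata/ff_params.tsv`, `lj_types.tsv`) and can be swapped
by the user.

Energy conventions: Lorentz-Berthelot combination for LJ; Coulomb
constant 332.0716 kcal·Å·mol⁻¹·e⁻², relative dielectric 1 (gas phase).
Feature energies use **no cutoff** — the interaction sets themselves
(cross-partner pairs, site-vs-RNA pairs, site-vs-contact pairs within
the explicit 10 Å contact rule) define each sum; the 12 Å cutoff applies
only inside minimization.  The minimizer's bonded terms are harmonic
bond and 1-3 distance restraints toward the input covalent geometry;
bonds are detected from the input coordinates (< 1.85 Å, 2.25 Å around
S/P), and 1-2/1-3 pairs are excluded from the nonbonded sum.

## Feature definitions and choices that were genuinely open

- **Contact sets for ΔΔE_elec** are recomputed independently for the
  wild-type and mutant structures (the alternative — freezing the
  wild-type contact set — was rejected because a larger mutant side
  chain can genuinely gain contacts; the tests assert this behaviour).
- **Glycine at the mutated site** has no side-chain heavy atoms; its
  "side-chain atom" set for the contact and repulsion rules is {CA}, so
  the sets are never empty.
- **Interface membership** compares a residue's SASA in the rigidly
  extracted unbound partner with its SASA in the complex.  The rule is a
  strict inequality in principle; numerically we require the difference
  to exceed 0.1 Å² to suppress lattice noise.  N_inter counts protein
  residues only ("number of amino acids"), never nucleotides.
- **Exposure** divides the residue's SASA in the complex by a
  per-residue-type maximum-ASA reference (theoretical Gly-X-Gly extended
  tripeptide values, bundled as `max_asa.tsv`); a ratio above 0.25
  counts as exposed.  The reference-state table is the standard
  interpretation of "SASA in solvent".
- **SASA** is Shrake-Rupley over heavy atoms with Bondi-style element
  radii (C 1.70 Å — the value the isolated-sphere checks are written
  against — N 1.55, O 1.52, S/P 1.80) and a 1.4 Å probe, sampled on a
  fixed golden-section spiral lattice (default 960 points per atom), so
  results are deterministic.  Points landing exactly on a neighbour's
  expanded sphere (degenerate overlaps) are claimed by the earlier atom.
- **Secondary structure** is a re-implementation of the hydrogen-bond
  based assignment collapsed to three classes: Kabsch-Sander
  electrostatic H-bond criterion (virtual amide H rebuilt from the
  backbone, bond when E < −0.5 kcal·mol⁻¹), consecutive 4-turns giving
  helix (3- and 5-turns likewise, at lower priority), bridge patterns
  giving strand, everything else coil.  Only the 3-class collapse is
  consumed downstream.
- **The residue interaction network** spans *all* protein chains of
  partner 1 (configurable down to single chains); nodes are Cα atoms,
  edges strictly below 6 Å.  Closeness uses hop distances; on
  disconnected graphs each node is scored within its component and
  scaled by (component size − 1)/(n − 1), the convention of the network
  library the original work used, which reduces exactly to the plain
  formula on connected graphs.  Isolated nodes score 0.
- **Sequence features** are computed on the mutated chain's sequence *as
  resolved in the structure* (not the full-length UniProt sequence),
  keeping every feature structure-derived.  The OMH hydrophobicity scale
  is bundled verbatim from its original publication.

## Fitting and evaluation

Ordinary least squares in natural units (no standardization), so
coefficients have physical units per feature; importance is reported as
|t|, collinearity as VIF.  Rank-deficient designs are rejected naming
the collinear columns.  Repeated measurements of one mutation are
averaged when their spread is below 1 kcal·mol⁻¹ and rejected otherwise;
the other curation filters (protein < 20 aa, RNA < 5 nt, metal-site
mutations, modified interface residues, RNA-sequence identity < 80%
between structure and assay, by global alignment) run in that order with
per-row rejection reasons.  The 80% rule's alignment method is not
dictated anywhere; we use Needleman-Wunsch global identity
(matches / alignment length) and expose the threshold.

Cross-validation: CV1 and CV2 are repeated random 50/50 and 80/20
mutation splits (100 rounds by default) aggregated as the mean per-round
R and RMSE; CV3 is leave-one-complex-out, aggregated as metrics on the
pooled out-of-fold predictions — the most literal reading of how the
three protocols are reported.  Splits are unstratified and seeded.
Classification of "highly decreasing" mutations (experimental
ΔΔG ≥ 1 kcal·mol⁻¹) uses a threshold sweep over the predictions:
trapezoidal ROC AUC, step-interpolated PR AUC, and the maximum MCC over
all distinct thresholds (MCC defined as 0 when a confusion-matrix factor
vanishes).

## What the synthetic data emulate — and what they do not

`make_synthetic_dataset()` draws 11-feature vectors with realistic
spreads (complex-level centres plus mutation-level scatter, so
leave-one-complex-out is a real generalization test) and generates
ΔΔG = linear model + Gaussian noise.  Its defaults are the emulated
study conditions: 50 complexes, ~5 mutations each, residual
σ = 0.76 kcal·mol⁻¹, and generative coefficients scaled so the
true-model signal standard deviation is ≈ 0.8 kcal·mol⁻¹ — the
signal-to-noise regime in which a training correlation around 0.7 is
expected, matching the regime the curated experimental set reports.
Passing tests on these data show that the regression, cross-validation
and classification machinery is correct and unbiased; they do **not**
show that the 11 features predict real experimental ΔΔG — that claim
requires the real curated structures and measurements, which are not
bundled.  The shipped `s248_synthetic.tsv` is a labelled synthetic
stand-in reproducing only set-level bookkeeping (248 mutations, 50
complexes, 124 at or above 1 kcal·mol⁻¹).

`make_toy_complex()` builds ideal-geometry peptides (helix, extended, or
a two-strand antiparallel hairpin whose placement realizes genuine
cross-strand backbone hydrogen bonds) docked against an idealized
single-stranded A-form-like RNA at a controlled separation.  The toys
are deliberately not folded proteins: they exercise every geometric and
energetic code path (interfaces, burial, networks, clashes) with exact
knowledge of what the answer should be, which folded-protein realism
would only obscure.

## Numerical choices and degenerate inputs

- Minimization uses `optim`'s L-BFGS-B with the step count as the
  iteration budget; `n_steps = 0` returns the input unchanged, and the
  result is never accepted if its objective exceeds the input's.
  Problem sizes in the tests (toy complexes of ~150-300 atoms, 30-200
  steps) keep the full suite in a few minutes while the default 1000
  steps remain the production setting.
- Chains shorter than 3 residues are assigned all-coil; residues without
  Cα are excluded from the network with a warning; an empty partner, a
  zero-variance metric input, a single-class label vector, and a CV3
  fold leaving fewer than 13 training rows are all hard errors rather
  than silent answers.
- All randomness (sequence draws, synthetic datasets, CV splits) is
  behind explicit seeds; structures, SASA, minimization and features are
  fully deterministic.

## Known limitations

Single mutations only (multiple substitutions are not additive and are
out of scope); no explicit solvent, ions or pKa-dependent protonation;
side-chain placement uses one ideal rotamer rather than a rotamer
search; the built-in minimizer is a simplified potential intended for
clash relief, not a replacement for a full molecular-mechanics stack
(the mutant-modelling step is a pluggable contract, so an external
engine can stand behind it); and prediction quality on real complexes
depends on a user-supplied training table — no pretrained coefficients
are shipped, because the original fitted coefficients were never
published.
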