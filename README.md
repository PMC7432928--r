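# priddg — protein–RNA binding affinity changes upon missense mutations

`priddg` predicts how a single amino-acid substitution in an RNA-binding
protein changes the binding free energy of its protein–RNA complex
(ΔΔG, kcal·mol⁻¹; positive values mean the mutation weakens binding).
It is aimed at structural bioinformaticians who have a protein–RNA
complex structure (PDB format) and want quantitative, interpretable
per-mutation scores — for mutation scanning of binding interfaces,
prioritizing candidate disease variants, or studying binding hot spots.

## The model

The score is a multiple linear regression over 11 features of the
wild-type and mutant complexes:

    ΔΔG = β₀ + β₁·ΔΔE_vdw + β₂·ΔΔE_vdw.re + β₃·ΔΔE_elec + β₄·N_inter
              + β₅·R_L/SA + β₆·C(u) + β₇·ΔSA + β₈·P_coil
              + β₉·ΔOMH + β₁₀·ΔP_FWY + β₁₁·ΔP_KR−DE

Structure-based features (computed on minimized wild-type and mutant
complexes; the mutant is built by ideal-template side-chain replacement
followed by backbone-restrained minimization):

- **ΔΔE_vdw** — change in the cross-partner Lennard-Jones interaction
  energy (complex minus unbound partners, mutant minus wild type);
- **ΔΔE_vdw.re** — change in the r⁻¹² repulsion between the mutated
  residue and the RNA;
- **ΔΔE_elec** — change in the Coulomb energy between the mutated
  residue and its contact residues/nucleotides (any side-chain/base atom
  within 10 Å of a side-chain atom of the site);
- **N_inter** — number of protein residues at the binding interface
  (residues whose SASA in the unbound protein exceeds their SASA in the
  complex);
- **R_L/SA** — protein length divided by the unbound protein's solvent
  accessible surface area;
- **C(u)** — closeness centrality of the mutated site in the residue
  interaction network (Cα nodes, edges below 6 Å);
- **ΔSA** — change in the mutated residue's SASA in the unbound protein;
- **P_coil** — fraction of the mutated chain's residues that are both
  solvent-exposed (relative accessibility > 0.25) and in coil.

Sequence-based features: **ΔOMH** (optimal-matching-hydrophobicity
difference), **ΔP_FWY** and **ΔP_KR−DE** (aromatic and net-charge-class
composition changes of the mutated chain).

The coefficients are fitted by ordinary least squares on a user-supplied
training table of experimental ΔΔG values; the package reports
per-coefficient p-values, |t| importance and variance inflation factors,
and evaluates models by repeated 50/50 and 80/20 splits (CV1/CV2),
leave-one-complex-out validation (CV3), and ROC / precision–recall /
maximum-MCC analysis of "highly decreasing" mutations
(ΔΔG ≥ 1 kcal·mol⁻¹).

## Worked example

```r
library(priddg)

# a deterministic toy complex: 12-residue helix docked on a 6-nt RNA
cx <- make_toy_complex(n_res = 12, n_nt = 6, geometry = "helix",
                       separation = 4, seed = 1)
chain_sequence(cx, "A")
#> [1] "DEARLFYVAIFI"

# fit a scoring function on a synthetic training table
train <- make_synthetic_dataset(seed = 1)
model <- fit_ddg_model(train)

# score two mutations (features + prediction per row)
res <- run_predict(cx, mutations = c("A:L5A", "A:F6A"), model = model)
res[, c("mutation", "ddg", "interface", "n_inter", "closeness", "status")]
#>   mutation      ddg interface n_inter closeness status
#> 1    A:L5A 3.086693        no       1    0.6875     ok
#> 2    A:F6A 5.565487        no       1    0.6875     ok
```

Each row reports the predicted ΔΔG (kcal·mol⁻¹, positive =
binding-weakening), whether the mutated site lies at the protein–RNA
interface, and all 11 feature values.  Failures (e.g. a wrong wild-type
residue) are isolated per mutation in the `status` column.

A command-line front end with `predict`, `fit`, `cv`, `curate` and
`fixtures` subcommands is installed at
`system.file("cli", "priddg.R", package = "priddg")`.

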