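# VarStab

Stability-driven classification of non-synonymous protein variants from
3D structure.

A single amino-acid substitution can cause disease by changing the folded
protein's stability — most often by destabilizing it, but sometimes by
*over*-stabilizing it and freezing out function. VarStab is an R package
for structural bioinformaticians who want to score and classify such
variants on stability grounds, and to study how far stability alone
explains deleteriousness. It provides the whole chain from structures to
cross-validated classifiers, with no external data dependencies: every
input it needs can be generated synthetically.

## What it computes

**Statistical mean-force potentials.** From a reference set of PDB
structures, for any combination E of sequence/structure elements
(amino-acid type *s*, solvent-accessibility bin *a*, backbone torsion
domain *t*, side-chain center distance bin *d*):

    ΔW(E) = −k_B T Σ_{∅≠S⊆E} (−1)^{|E|−|S|} log P̂(S)

which reduces to −k_B T log[P(s,c)/(P(s)P(c))] for pairs and the
corresponding ratio for triples. Thirteen configurable potentials span
the distance, accessibility and torsion classes. Per substitution the
package derives ΔΔW_i (positive = destabilizing), the Heaviside volume
split ΔV± = θ(±ΔV)|ΔV|, and the relative accessibility A (%).

**Classifiers.**

* Accessibility-gated linear stability models — every weight is a sigmoid
  α(A) = ω/(1+e^(−ν(A−ξ))) + φ — for folding free-energy changes
  (ΔΔG, 13 potentials + ΔV± + intercept; deleterious above a threshold)
  and melting-temperature changes (ΔT_m, 9 potentials inside a
  1/(aN_r+b) size prefactor; deleterious below a threshold).
* A sign-split gated index
  I = Σ_i φ_i⁺(A) ΔΔW_i⁺ + Σ_i φ_i⁻(A) ΔΔW_i⁻ + φ₁₂(A)ΔV₊ + φ₁₃(A)ΔV₋
  that can flag stabilizing *and* destabilizing substitutions, trained by
  least squares against 0/1 labels with a balanced-accuracy-optimal
  threshold ψ.
* A probabilistic neural network: per-sample diagonal Gaussian kernels
  with per-feature bandwidths, class densities P_D, P_N weighted by
  η₁, η₂; deleterious iff P_D > P_N.
* A meta-combiner J = γ₁ + γ₂ I + γ₃ PRO with an external
  evolutionary-conservation score, plus high-confidence bands J ≥ J_D
  (call deleterious) and J ≤ J_N (call neutral).

**Evaluation.** Balanced accuracy
BACC = TP/(2(TP+FN)) + TN/(2(TN+FP)),
sensitivity/specificity/PPV/NPV, rank-based AUROC, exhaustive
threshold optimization, and 5-fold cross-validation at the mutation or
the protein level (proteins are never split across folds). Dataset
curation filters (X-ray ≤ 2.5 Å; ≥ 10 Å inter-Cα from extra mutations;
conflicting annotations discarded) are provided as generic table
operations.

**Synthetic fixtures.** A generator for small PDB-format structures
(ideal helices, strands, coils, and a packed bundle with genuinely buried
residues) and labeled variant tables with a planted, recoverable
stability→deleteriousness signal.

## Worked example

End to end on synthetic data — generate structures, derive potentials,
plant a labeled variant set, and cross-validate the combined classifier:

```r
library(VarStab)
cfg <- defaultConfig()
docs <- makeStructures(6, 50, "mixed", seed = 7)
structs <- lapply(names(docs), function(id)
  computeDescriptors(readStructure(docs[[id]], pdbId = id), cfg))
names(structs) <- names(docs)

tabs <- derivePotentials(structs, cfg)
tabs[["sd"]]
#> PotentialTable sd (code sd, kT = 0.593 kcal/mol, sigma = 1)
#>    20 x 25 element tuples; energy range [-0.599, 0.811] kcal/mol

vt <- makeVariantTable(structs, tabs, nVariants = 1000,
                       labelNoise = 0.05, config = cfg, seed = 1)
table(vt$label)
#> deleterious     neutral
#>         722         278

crossValidate(combinerTrainer(cfg), vt, k = 5, level = "mutation",
              seed = 1)
#> EvalReport: 5 -fold CV at the mutation level
#>   Sens 0.962  Spec 0.849  PPV 0.943  NPV 0.894  BACC 0.905  AUROC 0.915 (pooled 0.914)
```

The potential table reports pseudo-energies in kcal/mol for each
(amino acid, distance-bin) tuple — negative values mark favourable
sequence–structure associations. The variant table realises roughly the
75 % deleterious composition typical of curated disease-variant sets.
The evaluation row reads like a benchmark table: with a planted signal
whose best achievable balanced accuracy is about 0.91 (5 % label flips),
the combiner recovers BACC 0.905 with pooled AUROC 0.914, and its
high positive predictive value (0.943) reflects that deleterious calls
are the reliable direction for a stability-based classifier.

A thin command-line front-end over the same functions is installed at
`inst/cli/varstab` (subcommands `make-fixtures`, `derive-potentials`,
`train-ann`, `train-pnn`, `train-combiner`, `predict`, `evaluate`; see
`?runPipeline`).

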