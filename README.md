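# stabvar

Protein stability change and missense variant pathogenicity.

Missense mutations in monogenic disease genes frequently act by
destabilizing the folded protein. Two sequence-computable physical
quantities track this: the predicted folding free-energy change of a
substitution (ΔΔG, kcal/mol; negative = destabilizing here) and the
relative solvent accessibility of the mutated site (RSA ∈ [0,1]; low =
buried). `stabvar` is for researchers who have per-variant ΔΔG and RSA
columns (from any external predictor) and want to quantify — and exploit —
their association with pathogenicity:

- **curate** ClinVar-style variant tables into a strict
  (benign/pathogenic) and an extended (plus likely calls) dataset via
  conflict exclusion, an allele-frequency filter at 0.01 and a per-gene
  10% rule, with a reconciling audit report;
- **annotate** substitutions on four chemistry axes
  (hydrophobic/polar, small/large, aromatic/aliphatic, positive/negative);
- **evaluate** any score with ROC/AUC computed two independent ways
  (trapezoidal sweep ≡ Mann–Whitney concordance,
  AUC = P(random pathogenic variant outscores a random benign one, ties ½)),
  MCC-optimal threshold calibration
  (MCC = (tp·tn − fp·fn)/√((tp+fp)(tp+fn)(tn+fp)(tn+fn))),
  balanced N+N resampling, and stratified AUC tables;
- **classify** with a two-feature L2 logistic model
  (penalty ‖w‖²/(2c), c selected by repeated stratified 5-fold CV on a
  balanced 80/20 split);
- **scan** whole proteins in silico: all 19·L substitutions through a
  pluggable ΔΔG scorer, flagged pathogenic at ΔΔG ≤ −1.1 kcal/mol by
  default;
- **simulate** all of the above: a seeded generator with label-conditional
  Gaussians for ΔΔG (analytic AUC = Φ((μ_b−μ_p)/√(σ_b²+σ_p²))), Beta RSA,
  correlated predictor columns and allele frequencies straddling the filter
  — so every stage is testable with known ground truth.

External ΔΔG/RSA predictors are out of scope by design; they enter only as
numeric columns or through the scorer contract.

## Worked example

```r
library(stabvar)

cfg <- generator_config(seed = 42)          # pathogenic ddG N(-1.5,1.5^2), benign N(-0.3,1)
d   <- generate_annotated_variants(cfg, 1500, 1500)

auc_concordance(d$ddg_p1, d$label)          # 0.747  (analytic: 0.747)
optimal_threshold(d$ddg_p1, d$label)        # cutoff -1.49 kcal/mol, MCC 0.413
fraction_destabilizing(d$ddg_p1[d$label == 1])  # 0.845

fit <- fit_pathogenicity(d, ddg = c("ddg_p1", "ddg_p3"), rsa = TRUE,
                         protocol = split_protocol(repeats = 3,
                                                   c_grid = c(0.01, 0.1, 1, 10, 100),
                                                   seed = 42))
fit
#> Two-feature pathogenicity classifier (L2 logistic regression)
#>   ddG feature: mean of ddg_p1, ddg_p3; RSA included
#>   selected c = 100 (5-fold CV x 3)
#>   portion    n  auc   mcc
#> 1   train 2400 0.85 0.543
#> 2    test  600 0.85 0.553
```

Reading: a single simulated ΔΔG predictor separates pathogenic from benign
variants with AUC 0.747 (matching the generator's closed form); the
MCC-optimal decision threshold lands at −1.49 kcal/mol; 84.5% of pathogenic
variants are destabilizing (ΔΔG < 0); and combining ΔΔG with RSA lifts the
held-out AUC to 0.85.

The full pipeline — generate/curate/annotate/evaluate/classify/saturate with
all reports written to a run directory — is one call:

```r
run_pipeline(run_config(seed = 7), "runs/demo")
```

or from a shell, `Rscript inst/scripts/run_pipeline.R --seed 7 --out runs/demo`.

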