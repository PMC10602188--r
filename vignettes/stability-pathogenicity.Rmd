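---
title: "Folding stability, solvent accessibility and variant pathogenicity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Folding stability, solvent accessibility and variant pathogenicity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabvar)
```

## The scientific question

Missense mutations in monogenic disease genes often act by destabilizing the
folded protein. Two cheap, sequence-computable physical quantities track this:
the predicted folding free-energy change of the substitution
($\Delta\Delta G$, kcal/mol; this package uses the convention that negative
values are destabilizing) and the relative solvent accessibility of the
mutated site (RSA $\in [0,1]$; low values are buried). Pathogenic variants
tend to be more destabilizing and more buried than benign ones, so either
quantity is a weak classifier on its own and the two together form a simple,
physically interpretable predictor.

stabvar implements the full evaluation chain for this idea: curating a
ClinVar-style variant table into analysis datasets, annotating the chemistry
of each substitution, measuring how well a score separates pathogenic from
benign variants, calibrating decision thresholds, fitting a two-feature
logistic classifier, and scanning whole proteins in silico. External
$\Delta\Delta G$ and RSA predictors are deliberately out of scope: they enter
only as numeric columns, and a pluggable scorer contract plus a synthetic
generator with known ground truth stand in for them so that every stage of
the pipeline is verifiable.

## Curation model

Raw records carry a gene, a protein position, wild-type and mutant residues,
one of six significance classes (benign, likely benign, pathogenic, likely
pathogenic, uncertain, conflicting) and an optional population allele
frequency. `build_datasets()` applies three rules in a fixed order:

1. records with conflicting interpretations are removed;
2. an allele-frequency plausibility filter at 0.01: benign-side variants
   rarer than 1% and pathogenic-side variants commoner than 1% are removed;
3. a per-gene 10% rule: a gene enters the strict dataset (dataset 1) when
   its fraction of definitive benign/pathogenic calls among all its
   surviving variants strictly exceeds 10%, and the extended dataset
   (dataset 2, a superset) when the fraction including likely calls does.

Three points here were genuinely open and are fixed as package decisions.
The denominator of the 10% rule is the gene's total variant count reaching
stage 3 (all significance classes) — the rule's natural reading, and
configurable via `min_fraction` only in the sense that the threshold itself
can be moved. Boundary cases are literal: exactly 10% fails the strict
inequality, and an allele frequency of exactly 0.01 is retained on both
sides because the filter removes only "below"/"above". Records with a
missing frequency are retained by default (`retain_missing_af = FALSE`
flips this), since the filter can only speak to observed frequencies. The
filter order itself is not derivable from first principles; the
`curation_report` records counts removed at each stage so the order is
auditable, and the report must reconcile exactly
(input = removed + retained at every stage), which the tests enforce.

Dataset 1 maps benign → 0, pathogenic → 1; dataset 2 additionally maps the
likely classes to the same labels. Uncertain variants never reach an output.

## Evaluation mathematics

Scores are oriented so that *lower* means more pathogenic ($\Delta\Delta G$:
more destabilizing; RSA: more buried), and classification uses the
`pathogenic_if_le` rule with a closed boundary: a score equal to the
threshold is called pathogenic. ROC/AUC is computed by two independent
routes that must agree exactly — a threshold sweep over all unique scores
with trapezoidal integration (`roc_curve()`), and the Mann–Whitney pairwise
concordance estimator with ties counted 1/2 (`auc_concordance()`). The
equality is an algebraic identity, and the test suite asserts it to 1e-12 on
random tied instances; it is the package's built-in oracle for the ROC code.

Threshold calibration maximizes the Matthews correlation coefficient by an
exhaustive scan over the midpoints of consecutive sorted unique scores plus
below-minimum and above-maximum sentinels; this candidate set realizes every
achievable confusion table. MCC uses the convention that a zero denominator
factor yields 0. Ties in the scan are broken toward the smallest
$|\mathrm{threshold}|$, then the smaller threshold — a deterministic and
scale-symmetric choice.

The balanced resampling assessment draws, per repeat, $N$ benign and $N$
pathogenic variants without replacement with
$N = \lfloor 0.5 \cdot \min(n_\mathrm{benign}, n_\mathrm{pathogenic})\rfloor$
(floor, an explicit decision), computes TPR/FPR/FNR/accuracy per repeat and
reports means and standard deviations over 100 repeats by default. The
MCC-optimal threshold is calibrated once on the full dataset and then reused
inside the resampling; this mild information leakage mirrors the original
protocol of threshold-then-resample studies and is documented rather than
silently repaired. Stratified AUC tables (by substitution-category axis or
functional class) keep only groups whose size strictly exceeds
`min_count = 100` and that contain both labels.

An absolute-magnitude analysis ($|\Delta\Delta G|$ with `pathogenic_if_ge`)
is available simply by transforming the score column and flipping the rule
argument; no dedicated code path exists for it.

## The two-feature classifier

`fit_pathogenicity()` fits an L2-regularized logistic regression on the
ensemble-averaged $\Delta\Delta G$ and (optionally) RSA. The objective is
the negative log-likelihood plus $\frac{1}{2c}\lVert w\rVert^2$ with the
intercept unpenalized; $c$ is the usual inverse regularization strength.
The solver is damped Newton/IRLS, converged when the largest coefficient
update falls below 1e-10 (capped at 100 iterations), so the fit is
deterministic given the data and $c$. The unpenalized limit reproduces
`glm(..., family = binomial)` and the penalized fit matches an independent
ridge implementation; both identities are asserted in the tests rather than
assumed.

The surrounding protocol: classes are balanced by a seeded subsample of the
majority class (how balance is achieved is an open choice; subsampling
without replacement is the least invasive), the balanced data are split
80/20 stratified by label, and $c$ is selected on the training portion by
stratified 5-fold cross-validation repeated with reshuffled folds,
maximizing mean validation AUC with ties going to the smaller $c$ (stronger
regularization). The default grid is 13 points log-spaced over
$[10^{-3}, 10^{3}]$ and the default repeat count is 100; both are
`split_protocol()` parameters. Features are standardized using
training-portion statistics only — $\Delta\Delta G$ lives in kcal/mol and
RSA in $[0,1]$, and a shared ridge penalty is only meaningful on a common
scale. Reported metrics are AUC (concordance of predicted probabilities)
and MCC at probability threshold 0.5 for both portions; train and test are
computed independently and never forced to agree.

## Saturation mutagenesis

`enumerate_substitutions()` produces the $19L$ single-residue substitutions
of a length-$L$ sequence (positions 1-based, mutants alphabetical);
`saturation_scan()` scores them through a scorer satisfying the contract
*f(sequence, position, wt, mut) → finite kcal/mol, deterministic,
vectorized* and flags pathogenicity at $\Delta\Delta G \le$ cutoff, default
−1.1 kcal/mol. Non-canonical residues abort by default; `skip_noncanonical`
records-and-skips instead. `scan_fasta()` streams rows to a TSV protein by
protein so a proteome-scale run never holds all rows in memory.
`synthetic_scorer()` is a deterministic integer-hash scorer mapped to
$[-3.5, 1.5]$ kcal/mol — its values carry no biophysical meaning and it
exists so the scan machinery can be exercised and recounted exactly.

## The synthetic generator: what it emulates and what it does not

`generator_config()` fixes the study conditions. Per label, the three
simulated predictor columns are drawn from Gaussians coupled by a common
latent factor: $x_k = \mu_k + \sigma_k(\sqrt{\rho}\,Z_0 +
\sqrt{1-\rho}\,Z_k)$, giving exact marginals and pairwise correlation
$\rho$ — a deliberately simple construction that suffices for the package's
tests and avoids a full covariance parameterization. RSA is Beta per label;
allele frequencies are log-uniform within class ranges chosen to straddle
the 0.01 filter in both directions; gene significance mixes are tilted
per-gene between the configured mix and a VUS-only mix so the 10% rule sees
both outcomes; uncertain and conflicting records receive $\Delta\Delta G$
and RSA too, so that *failing to drop them is detectable*. Wild-type
residues are drawn Arg-heavy by default, mirroring the residue-usage skew
of curated disease-variant sets. All draws descend from one master seed
with fixed per-operation offsets (raw +1, annotated +2, sequences +3) on
R's default Mersenne–Twister generator, so a seed fixes every byte of
output.

Default distribution parameters, chosen once: pathogenic
$\Delta\Delta G \sim N(-1.5, 1.5^2)$, benign $N(-0.3, 1.0^2)$ (single
predictor population AUC $\Phi(1.2/\sqrt{3.25}) \approx 0.747$), $\rho =
0.6$, RSA pathogenic Beta(2, 3.2), benign Beta(3, 2) (population AUC
$\approx 0.78$, the scale reported for RSA on real curated data). These are
free parameters of the emulation — they are plausibility choices, not
estimates of any real dataset. The closed form
$\mathrm{AUC} = \Phi\!\big((\mu_b-\mu_p)/\sqrt{\sigma_b^2+\sigma_p^2}\big)$
(`analytic_auc()`) is the ground truth for recovery tests.

What the generator does **not** emulate: evolutionary conservation,
structural context, per-gene phenotypes, predictor biases correlated with
residue identity, or any dependence between $\Delta\Delta G$ and RSA beyond
their shared label. Consequently, passing tests demonstrate that the
pipeline's mathematics and bookkeeping are correct under known conditions —
they do not certify performance numbers on real variant sets, where the
feature distributions are neither Gaussian nor independent.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design:
distributional recovery at 4000 variants per class, null checks at 1000 per
class, resampling at 100 repeats, classifier fits with a reduced
cross-validation budget (3 repeats over a 5-point $c$ grid) that leaves the
selection protocol intact, and saturation scans of ten 300–500-residue
proteins. Degenerate inputs are contracts, not accidents: single-class
inputs to AUC/threshold code raise errors, empty curation inputs return
zeroed reports, a zero balanced-sample size raises an error, and
`mcc` returns 0 on degenerate margins.

## Known limitations

Curation assumes one record per variant; cross-source duplicate
reconciliation beyond the conflicting-class flag is out of scope, as are
live database queries and isoform selection. The classifier is intentionally
the simplest member of its family — no interaction terms, no calibration
analysis, no comparison tests between AUCs. The resampling standard
deviations describe resampling variability around one fixed dataset, not
sampling variability of the underlying cohort.
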