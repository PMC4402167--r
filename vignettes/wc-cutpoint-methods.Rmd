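---
title: "Metabolic phenotyping and waist-circumference cutpoint selection: methods"
author: "metabocut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic phenotyping and waist-circumference cutpoint selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabocut)
```

## The problem

Waist circumference (WC) is the standard anthropometric screen for abdominal
obesity, but its cutoff points are population-specific. The usual way to
derive them — an ROC curve of WC against a "metabolically sick" label defined
by preset criteria — is contaminated by two atypical phenotypes that
anthropometry cannot see: metabolically obese normal-weight subjects (MONW:
lean but insulin-resistant) and metabolically healthy obese subjects (MHO:
obese but insulin-sensitive). Both sit on the wrong side of any WC threshold
and act as label noise, dragging down the sensitivity and specificity of the
selected cutpoint.

`metabocut` implements the alternative workflow evaluated on the Maracaibo
City Metabolic Syndrome Prevalence Study (MMSPS) cohort: discover the
metabolic phenotypes first by cluster analysis of biochemical variables
within gender × BMI strata, then build WC ROC curves under stepwise exclusion
of the atypical phenotypes, and read the cutpoint off the cleanest contrast
(healthy normal weight vs. metabolically disturbed obese). Because the
original per-subject data were never deposited, the package ships a synthetic
cohort generator parameterised from the study's published summary tables;
every stage of the pipeline is exercised and tested against that generator.

## The synthetic cohort

`default_cohort_spec()` encodes the published summaries (`mmsps_reference()`):

* six phenotypes (HNW, MONW, healthy/sick overweight, MHO, MDO) with
  per-gender prevalences equal to the published healthy/sick counts divided
  by the gender totals (e.g. 28/992 MONW in women);
* per-phenotype, per-gender mean/SD for WC (cm), HOMA2-IR, TAG, HDL-C
  (mg/dL) and MAP (mmHg);
* pooled per-gender parameters for variables not reported per phenotype
  (fasting glucose, HOMA2-%B, age, insulin, total cholesterol) — these
  columns are therefore *phenotype-uninformative* in synthetic data, a known
  and deliberate limitation;
* defaults n = 1902 subjects, 52.15% women — the published analysis sample.

Distribution families: WC, MAP, HDL-C, HOMA2-%B, glucose, age and total
cholesterol are truncated normals (floors at physiologic minima, e.g.
WC > 40 cm); HOMA2-IR, TAG and insulin are right-skewed and drawn log-normal
with parameters solved from the target mean/SD by moment matching, so sample
moments converge to the published values. HOMA2-S is the definitional
reciprocal 100/HOMA2-IR, and SBP/DBP are reconstructed from the drawn MAP
and an independent pulse pressure (42 ± 8 mmHg, floored at 20) so that
MAP = DBP + (SBP − DBP)/3 holds exactly. BMI is drawn uniformly inside each
phenotype's WHO band; the obese phenotypes are split across classes I–III
with weights equal to the published per-class counts, which makes the
per-class sick fractions come out right by construction.

Variables are independent within phenotype by default (no published
covariance exists). A Gaussian-copula correlation knob is available for
sensitivity analyses; it changes no marginal.

What the generator does *not* emulate: age structure, ethnicity, hs-CRP,
any within-subject correlation between biochemical variables, and — most
importantly — the published per-phenotype tables are *cluster-conditional*
summaries of the real data, which we reuse as *generative* components. The
components overlap: for instance ~23% of generated MDO subjects fall below
the HOMA2-IR 2.00 cutpoint, so no classifier keyed to HOMA2-IR can reach
100% phenotype recovery; the practical ceiling on the default spec is about
92%. Passing tests therefore demonstrate that the pipeline recovers the
structure the generator encodes, not that it would perform identically on
the real cohort.

## Preprocessing

Derived quantities follow the study's conventions: MAP = DBP + (SBP−DBP)/3;
WHO BMI classes on left-closed intervals (underweight < 18.5 ≤ normal < 25 ≤
overweight < 30 ≤ obese I < 35 ≤ obese II < 40 ≤ obese III); Friedewald
LDL/VLDL (invalid above TAG 400 mg/dL — such rows are flagged, not
estimated); non-HDL-C and the TAG/HDL ratio. Exclusions remove subjects with
missing insulin or a recorded diabetes diagnosis. A diagnosis *flag* is
required rather than a glucose rule, because a fasting-glucose threshold
would misclassify treated-free hyperglycemic subjects the study retained.

Normality is assessed by Geary's test: the ratio of the mean absolute
deviation to the population SD, which converges to √(2/π) ≈ 0.7979 under
normality with asymptotic null SD 0.2123/√n (the classical formulation; the
study names the test without printing the statistic). Skewed variables are
log-transformed and normality re-tested — with teeth: if the transform moves
the Geary statistic *away* from its normal value (as it does for the
left-truncated HOMA2-%B), the transform is reverted. The transform decision
is made once at cohort level so that every stratum, and both halves of the
cross-validation split, work on the same scale. The default alpha is 0.05
(the study does not state one; it is a configurable argument).

## Two-step clustering

The clustering engine is the sequential two-step procedure: CF-tree
preclustering followed by hierarchical agglomeration under the
log-likelihood distance, with automatic selection of the cluster count.

**Preclustering** (`build_cf_tree()`). Records are absorbed one at a time
into leaf entries holding sufficient statistics (n, per-variable sum and
sum of squares). A record joins its nearest leaf when the log-likelihood
distance is within the current threshold (initially 0, so only duplicates
merge) and opens a new leaf otherwise; when the leaf count passes 512 the
threshold grows to at least the median nearest-neighbour distance and the
leaves are re-inserted. The nearest leaf is found by exact vectorised
search rather than a fixed-fan-out tree descent — with vectorised
arithmetic the exact search is as cheap as a descent and removes one source
of insertion-order dependence. Insertion order is still order-dependent in
principle; it is shuffled by a named sub-seed of the pipeline seed.

**Distance.** For entries \(a, b\): \(d(a,b) = \xi_a + \xi_b - \xi_{a\cup b}\)
with \(\xi_v = -N_v \sum_j \tfrac12 \log(\hat\sigma_j^2 +
\hat\sigma_{v,j}^2)\), where \(\hat\sigma_j^2\) is the pooled variance of
predictor \(j\) and \(\hat\sigma^2_{v,j}\) the within-entry variance. The
pooled term regularises singleton entries. Predictors are standardized per
stratum before clustering (they live on incommensurate scales). Merging adds
sufficient statistics exactly, so cluster means and variances are exact at
every dendrogram level; ties in the closest pair are broken by lowest
(i, j) index pair.

**Cluster-count selection** (`select_k()`). The dendrogram's candidate
partitions (k = 1..k_max) are scored as diagonal Gaussian mixtures *on the
records*: starting from the partition's weights/means/variances — and, to
guard against wrong-axis local optima, also from an equal-quantile
partition along each predictor — bounded EM refines the parameters and the
best log-likelihood is kept. Two variance structures are fitted and
compared by penalized likelihood: shared-across-components (which prevents
a narrow-bulk/wide-tail solution from out-fitting a genuine two-component
structure) and free per-component variances (needed when components truly
differ in spread); the freer model must earn its extra parameters. The
selected k minimises \(-2\ell(k) + m_k c_n\); by default \(c_n = \max(2,
2\log\log n)\) (Hannan–Quinn), which in simulation recovers k = 1 on single
Gaussians and k = 2/3 on 8-SD-separated mixtures in ≥ 19/20 seeds, while
still splitting the weakly separated (≈ 2.2 SD) healthy/sick structures the
phenotype strata exhibit. The AIC and BIC weights are selectable; the
cross-validation module uses BIC, where consistency of the selected k
across the two halves is what the exercise measures.

An earlier design scored candidates by the merge-cost BIC with a
merge-distance-ratio refinement. It was abandoned after simulation showed
the null and alternative ratio distributions overlap (a structureless
Gaussian yields ratios up to ~2.7; a genuine 8-SD split only ~3.4), making
k = 1 undetectable.

**Final membership.** Cases are assigned to the maximum-posterior component
of the selected, EM-refined mixture (which the model also stores for later
centroid assignment). This matters under unbalanced prevalences: the raw
dendrogram boundary sits near the unweighted equal-density point, which
misplaces ~8% of a 92/8 stratum; the posterior boundary accounts for the
weights.

Cluster quality is summarised by the mean silhouette on standardized
predictors (singleton clusters take cohesion a = 0, so two far-apart
singletons score 1), and predictor importance by the per-predictor one-way
F statistic normalized to the maximum.

## Phenotyping

Each gender is stratified into normal weight, overweight and obese (the
obese WHO sub-classes are clustered as one pooled group per gender — the
published analysis found the sub-classes behaved alike, and at sub-class
sample sizes the mixture fits are unstable), and each stratum is clustered
on its published predictor set: HOMA2-IR + HOMA2-%B for women
(normal/overweight), plus TAG for men, HOMA2-IR alone for the obese. WC is
never a predictor, being the variable under evaluation. A cluster is
metabolically healthy iff its raw-scale mean HOMA2-IR is strictly below
2.00, the population-specific insulin-resistance cutpoint; stratum × health
then maps onto the six phenotypes. Underweight subjects (no defined
phenotype) are excluded with a logged count.

## Cross-validation

`crossval_clustering()` reproduces the published validation protocol: split
the cohort in half (seeded, optionally gender-stratified), cluster the
training half, then cluster the validation half twice — once through the
frozen training model (same transform, scaling and mixture; maximum
posterior), once independently from scratch — align the label sets by the
diagonal-maximizing permutation, and compute Cohen's kappa with the Fleiss
large-sample null variance. The default predictor is HOMA2-IR, the one
predictor shared by every stratified analysis, with the consistency-oriented
BIC weight for k: on the default cohort this yields a stable k = 2 in both
halves and kappa around 0.9, mirroring the published pooled validation
(kappa 0.902 over three clusters of the 951-subject testing half). Pooled
2-predictor validation including HOMA2-%B is available but less stable on
synthetic data, where HOMA2-%B carries no phenotype signal.

## ROC construction and cutpoint selection

`build_roc()` uses every midpoint between consecutive distinct WC values as
a threshold (±∞ sentinels complete the curve), calling WC ≥ threshold
positive — higher WC indicates sickness. The AUC is the trapezoid area and
is verified against the rank-statistic (Mann–Whitney) formulation to 1e-10
on every call. Printed cutpoints such as 91.25 or 98.15 cm are data
midpoints of this kind, never hard-coded values.

Scenarios: `six_group` keeps all phenotypes; `four_group` removes MONW and
MHO; `two_group` keeps HNW vs MDO only. (A published table footnote
describes the four-phenotype set inconsistently with the running text; the
text's definition — drop MONW and MHO, keep the overweight groups and MDO —
is implemented, the footnote treated as an erratum.) The outcome is
membership of the metabolically sick phenotypes among those retained.

Cutpoint indices: Youden J = sens + spec − 1; the distance to the (0, 1)
corner; LR+ = sens/(1 − spec) (+∞ at spec = 1). The default selection
policy mirrors the study's stated preference for sensitivity: among
thresholds within 0.005 of the maximal J, take the most sensitive, then the
lowest threshold. Strict-Youden and closest-to-(0,1) policies are
selectable. Reported tables round half-up to 2 decimals; raw values are
retained.

AUC comparisons use DeLong's test on placement values. Because the
stepwise exclusions change the subject set, the two-sample (unpaired) form
is the default: var = var(V10_A)/m_A + var(V01_A)/n_A + (same for B).
Identical subsets short-circuit to z = 0, p = 1. The unpaired test's type-I
error is verified by simulation to sit near its nominal 5%.

## Reproducibility and problem sizes

All randomness flows from one integer seed through named substreams
(synthesis, CF-tree shuffle, split), so `run_pipeline()` with the same
configuration reproduces its JSON report byte for byte. The test-suite
problem sizes are chosen to exercise each claim at meaningful power while
staying desk-scale: moment recovery at n = 20,000; phenotype recovery on
n = 5,000 cohorts over 10 seeds; cross-validation and AUC-ordering on the
default n = 1,902 cohort over 20 seeds; k-selection on n = 300 mixtures
over 20 seeds; DeLong size over 1,000 null replicates at 200 subjects per
arm.

## Known limitations

* The published per-phenotype summaries are treated as generative
  parameters; real within-phenotype distributions and correlations are
  unknown. Headline numbers of the original study (91.50/98.15 cm and their
  sensitivity/specificity) are therefore *not* exactly reproducible — the
  pipeline reproduces the qualitative structure: the stepwise AUC ordering,
  a near-0.9 validation kappa, and two-group cutpoints near the
  equal-likelihood boundary of the WC components.
* Only continuous predictors are supported; the study used none other.
* No outlier/noise-cluster handling; the study did not use that option.
* Phenotype-uninformative synthetic columns (glucose, HOMA2-%B) mean
  predictor-importance rankings on synthetic data understate those
  variables by construction.
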