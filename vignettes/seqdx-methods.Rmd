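---
title: "Models and methods in seqdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in seqdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqdx)
```

## What seqdx models

In routine breast-cancer management, treatment decisions hinge on a small
set of biomarkers — estrogen receptor (ER), progesterone receptor (PR),
HER2, the proliferation marker Ki-67 — and on the Nottingham Histologic
Grade (NHG), itself a sum of three morphological subcomponents (mitotic
count, nuclear atypia, tubular formation). All of these are assayed by
immunohistochemistry or by a pathologist's reading of a slide, which is
semi-quantitative and observer-dependent. seqdx implements the molecular
counterpart: predicting each routine biomarker from bulk RNA-seq
expression, reducing the uninformative middle grade to a binary
transcriptomic grade, calling intrinsic molecular subtypes, reading gene
amplifications out of low-pass whole-genome copy-number profiles, and
matching called alterations to an actionability knowledge base.

Because clinical cohorts with linked expression, clinical and sequencing
data cannot be redistributed, the package carries a synthetic cohort
generator that reproduces the *statistical structure* these methods rely
on. All simulation-based tests run against it.

## Marker models

ER, PR and HER2 status are each modelled by a univariable logistic
regression of status on the log2 expression of the corresponding gene
(ESR1, PGR, ERBB2):

$$\operatorname{logit} P(\text{positive}) = \beta_0 + \beta_1 x_{\text{gene}}.$$

The fit is plain maximum likelihood via iteratively reweighted least
squares, with one numerical safeguard: a ridge penalty of `1e-8` on the
slope, so that perfectly separable inputs (common in small or simulated
data, where positive and negative tumors do not overlap in marker
expression) still yield finite, monotone estimates. The predictor is
centred during fitting so the safeguard acts only on the slope direction;
on degenerate constant predictors the model collapses exactly to an
intercept at the logit of the prevalence.

Ki-67 is recorded as a percentage, so it is modelled as a *linear* elastic
net over all genes; predictions are evaluated as a classifier against the
20% high-proliferation rule through the same ROC machinery as the binary
markers.

### Elastic net and penalty selection

All penalized models use the elastic net with the L1/L2 mixing weight
fixed at $\alpha = 0.5$. The penalty strength $\lambda$ is chosen on a
grid of 50 values, log-spaced from $\lambda_{\max}$ (the smallest value
that zeroes every coefficient, taken from the start of the glmnet path)
down by a factor $10^{-4}$, by minimizing the mean inner cross-validation
deviance (squared error for linear models). glmnet performs the path
fitting; grid construction, fold assignment and selection are the
package's own, so the procedure is reproducible from a single seed.

### Nested cross-validation

Reported performance always comes from nested cross-validation: 5 outer
folds estimate performance, 5 inner folds (on outer-training data only)
tune $\lambda$. Folds are stratified by class and derived
deterministically from the seed. Every sample is scored exactly once by a
model that never saw it during fitting *or* tuning. The fold counts are a
package default; they balance bias against the small class sizes that
stratification must accommodate.

### ROC analysis and decision boundaries

`roc_points()` places thresholds at distinct score values (ties collapse
into a single step), `auc_score()` integrates the curve by the trapezoid
rule — numerically identical to the probability that a random positive
outscores a random negative, with half credit for ties. Decision
boundaries are set at the curve point with minimal Euclidean distance to
the top-left corner, $\sqrt{\mathrm{fpr}^2 + (1-\mathrm{tpr})^2}$, ties
resolved toward the lower false-positive rate. AUC variances, confidence
intervals and the two-cohort comparison use DeLong placement values; the
two-cohort test is unpaired (independent cohorts), a two-sided normal
z-test on the AUC difference. Reported confidence intervals are
DeLong-based, and labelled as such.

## Transcriptomic grade

The composite transcriptomic grade (TG) model fits one *binomial* elastic
net per NHG subcomponent, trained only on tumors scored 1 or 3 for that
subcomponent (event = score 3); score-2 tumors are excluded from fitting
and their count is kept in an audit record. The per-sample TG score is the
sum of the three predicted probabilities,

$$\mathrm{TG} = \hat y_{\text{mitotic}} + \hat y_{\text{nuclearity}} +
\hat y_{\text{tubularity}} \in [0, 3],$$

and the low/high boundary on this sum is placed by the top-left-corner
rule on **nested-CV** scores of overall grade 1 vs grade 3 tumors — not on
refit scores, so the boundary inherits no optimism from the fit. Binomial
component models were chosen (over linear ones on the 1/3 scores) because
probabilities are bounded and comparable across components, making the sum
a well-defined score on [0, 3]. Ties at the boundary classify as *low*:
conservative toward the lower grade. Grade-2 tumors, which carry no
actionable information of their own, are then reclassified by the fitted
boundary.

The genes a fitted TG model selects are a property of the training cohort;
no fixed gene list is shipped or assumed.

## Molecular subtyping

Subtypes (Basal-like, Luminal A, Luminal B, HER2-enriched; the Normal-like
class is deliberately not modelled) are called by a nearest shrunken
centroid classifier over a 50-gene panel. Standardized class-vs-overall
differences

$$d_{ik} = \frac{\bar x_{ik} - \bar x_i}{m_k\,(s_i + s_0)},
\qquad m_k = \sqrt{1/n_k + 1/n},$$

are soft-thresholded by $\Delta$ ($d'_{ik} = \mathrm{sign}(d_{ik})
\max(|d_{ik}|-\Delta, 0)$) and centroids reconstructed from $d'_{ik}$.
$s_i$ is the pooled within-class standard deviation and $s_0$ its median
across genes. Classification minimizes

$$\delta_k(x) = \sum_i \frac{(x_i - \bar x'_{ik})^2}{(s_i+s_0)^2}
- 2\log \pi_k ,$$

with ties broken by the fixed class order (Basal, LumA, LumB, Her2). The
$m_k = \sqrt{1/n_k + 1/n}$ form follows the published description of the
classifier; the $\sqrt{1/n_k - 1/n}$ variant used by some implementations
is available behind the `norm_constant` switch. Priors default to
empirical class frequencies, and $\Delta$ defaults to 0 (no shrinkage):
published centroid parameters are not redistributable, so the package
trains on whatever reference cohort the user supplies (the pipeline uses
the simulated truth labels as a stand-in reference).

## Copy-number calls

Low-pass whole-genome sequencing (~0.5x) is summarized as counts in 1-Mb
bins. The per-bin ratio is the library-size-normalized tumor count over
the matched baseline count; zero-baseline bins are flagged and excluded.
Gene-level calls average bin ratios over the gene's region, weighted by
overlap length, and categorize the mean with half-open thresholds:

| mean ratio | category |
|---|---|
| < 0.6 | deep_deletion |
| [0.6, 1.8) | neutral |
| [1.8, 3.0) | low_amp |
| >= 3.0 | high_amp |

The 1.8/3.0 cut-points encode the qualitative distinction between
low-grade amplification ("ratio close to two" — the regime seen at the
ERBB2 locus in discordant HER2 cases) and high-grade amplification; no
published numeric cutoffs exist for this distinction, so these are package
choices. No tumor-purity correction and no segmentation are applied: calls
come from raw bin ratios against a matched bin grid.

## Clinical rules and re-examination concordance

The routine rules are encoded exactly: ER/PR positive at >= 10% stained
cells by IHC (or > 0.05 fmol/ug DNA by radioimmunoassay, IHC preferred
when both exist); HER2 positive if in-situ hybridization shows
amplification, otherwise only at IHC grade 3+; Ki-67 high at >= 20%
(the threshold is taken as inclusive; a boundary value of exactly 20% is
*high*). `reexam_concordance()` implements the re-examination bookkeeping:
per marker, a patient counts as reclassified-and-concordant when **any**
re-examined tumor piece changed status relative to the medical record
*and* agrees with the sequencing-based call; patients with several pieces
count once, and denominators are distinct re-examined patients. The
any-piece rule matters: a patient whose two pieces disagree after
re-examination is still counted through the piece that moved toward the
sequencing call. The packaged `table1_reexam.csv` fixture is a verbatim
transcription of a published re-examination table, including its missing
cells.

## Actionability matching

Somatic SNVs, indels, amplifications and deep deletions are matched to
knowledge-base entries on (gene, alteration class); germline events are
never matched (they are handled only by the BRCA1/2 flagging rule). Under
the breast-only scope the ERBB2 amplification is excluded, since its
therapy is already standard practice for HER2-positive disease. Each
patient is counted once, at the highest-priority match
(approved > late phase > early phase; ties broken lexicographically by
gene then therapy). Composite entries that additionally require
HER2-positive status are supported via an optional
`requires_her2_positive` column; such entries match only when the
patient's HER2 status is known positive. The shipped 15-entry knowledge
base is schema-true but illustrative — it stands in for curated databases
that cannot be redistributed.

## The synthetic cohort generator

`generate_cohort()` draws, per tumor: receptor/Ki-67 truth states
(independent Bernoulli at configurable prevalences: ER 0.80, PR 0.70,
HER2 0.15, Ki-67-high 0.40), an intrinsic subtype (mixture 0.12/0.50/0.25/0.13
over Basal/LumA/LumB/Her2), and three grade subcomponents (a latent
tendency drawn 20/45/35 over grades, jittered per subcomponent); the
overall grade is the Elston–Ellis-style binning of the subcomponent sum
(3–5 → 1, 6–7 → 2, 8–9 → 3). Expression is simulated on the log2 scale as
Gaussian noise (sd 1.0) around per-gene baselines, with structural shifts:
each marker gene moves by `marker_shift` (default 2.0 log2 units) with
positive status; each subcomponent has a disjoint 30-gene program moving
by `grade_effect` per unit of score; panel genes carry subtype centroid
structure. Values are exponentiated to raw abundances, so the
normalization path (log2 counts-per-million with a +1 offset — the
standard, monotone choice when the upstream quantification units are
unspecified) is exercised end to end.

Ki-67 percent is a logistic transform of the proliferation signal scaled
to [0, 100]; its 20%-rule dichotomy defines the Ki-67 truth label.
Recorded clinical labels equal truth except for a `discordance_rate`
fraction (default 0.05, in line with the ~5% ER discordance seen in
practice) flipped uniformly at random. HER2-positive tumors carry
ERBB2-overlapping bins at `erbb2_amp_ratio` (default 2.0 — the low-grade
amplification regime); bin counts are Poisson with mean 5000 per bin,
which is the arithmetic of ~0.5x coverage at 1-Mb bins. The option
`grade2_mixture` makes recorded-grade-2 tumors carry latent grade-1-like
or grade-3-like expression programs in equal proportion, for testing
grade-2 reclassification against a known substrate.

All randomness flows from one master seed through named per-stage streams,
so any stage reproduces on its own and two runs with equal configuration
are byte-identical.

**What the generator does not emulate:** gene–gene correlation beyond the
block programs, subtype–receptor dependence (ER status and subtype are
drawn independently, unlike real cohorts where Luminal tumors are mostly
ER-positive), library-size variation, batch structure, mutational
signatures, and read-level noise. Passing the simulation-recovery tests
therefore demonstrates that the estimators recover the structure they
assume — not that real-cohort performance figures would be reproduced.
At the default conditions the single-gene marker AUCs land around
0.80–0.87 (label discordance alone caps them near 0.9), below the >= 0.95
figures reported for real cohorts where marker expression is more
bimodal; with discordance removed and the spec'd strong-signal settings
the models recover AUC >= 0.9, which is what the tests assert.

## Numerical choices and degenerate inputs

* Logistic separation guard: ridge `1e-8` on the (centred) slope.
* glmnet is run at `thresh = 1e-12` for the final refit so the
  no-penalty limit agrees with least squares to ~1e-4.
* ROC threshold convention: a sample is called positive at score >=
  threshold; the curve always carries its (0,0) and (1,1) endpoints.
* Boundary ties: lower fpr (ROC), low grade (TG), fixed class order
  (NSC), gene-then-therapy lexicographic (actionability).
* Zero-total expression samples, single-class labels, mismatched bin
  grids, missing model genes and unknown enumeration values are all hard
  errors naming the offending sample/gene/interval — never silently
  imputed.
* Fisher's exact test and the Welch t-test are delegated to base R
  (`fisher.test`, `t.test`); the test suite checks both against full
  enumeration and the textbook formula respectively.

## Problem sizes used by the test suite

The simulation-recovery tests run at n = 400 tumors x 1000 genes for the
marker models (the scale at which binomial noise on an AUC is ~0.02), at
n = 660 for the grade-2 mixture split (yielding ~200 grade-2 tumors, so a
50% split has standard error ~3.5%), 1000 replicates for the DeLong size
check, and 100 seeded replicates at 1000 bins for CNV recovery. These
sizes are the package's choices for stable assertions at desk scale.

## Known limitations

* The single-gene marker models are deliberately univariable; multivariate
  marker models would likely dominate on real data but are out of scope.
* Subtype calling requires a training cohort; shipped published centroids
  are not available.
* CNV calling has no segmentation, purity or ploidy model; it is a
  bin-ratio summarizer adequate for strong focal events like ERBB2.
* The knowledge base is a toy; real deployments must supply a curated one
  in the same schema.
* p-values produced by the pipeline are unadjusted for multiplicity and
  are labelled as such in the report.
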