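# seqdx

Sequencing-based breast-cancer diagnostic models in R.

Routine breast-cancer diagnostics rest on four immunohistochemistry
biomarkers — estrogen receptor (ER), progesterone receptor (PR), HER2 and
Ki-67 — plus the Nottingham Histologic Grade read from morphology. seqdx
implements their sequencing-based counterparts for analysts evaluating
whether molecular profiling can stand in for (and extend) routine
pathology:

* **Marker models** — univariable logistic regression of ER/PR/HER2 status
  on log2 expression of the marker gene (ESR1, PGR, ERBB2), and a linear
  elastic net (α = 0.5) for the Ki-67 percentage. Performance is always
  estimated by nested cross-validation (outer folds for performance,
  inner folds for penalty tuning), with ROC curves, trapezoidal AUC,
  DeLong variance/CIs, an unpaired two-cohort DeLong test, and decision
  boundaries at the ROC point closest to the top-left corner,
  argmin √(fpr² + (1 − tpr)²).
* **Transcriptomic grade (TG)** — one binomial elastic net per grade
  subcomponent (mitotic count, nuclear atypia, tubular formation), each
  trained on tumors scored 1 or 3; the TG score is the sum of the three
  predicted probabilities, ŷ_mitotic + ŷ_nuclearity + ŷ_tubularity ∈ [0, 3],
  dichotomized at a boundary placed on nested-CV scores of grade 1 vs 3
  tumors. Grade-2 tumors are reclassified into low/high TG.
* **Molecular subtyping** — a nearest shrunken centroid classifier over a
  50-gene panel (Basal, LumA, LumB, Her2; Normal-like excluded), with
  soft-thresholded standardized centroid differences
  d'ᵢₖ = sign(dᵢₖ)·max(|dᵢₖ| − Δ, 0).
* **Copy-number calls** — per-bin tumor/baseline ratios from low-pass WGS
  counts, and overlap-weighted gene-level calls (deep_deletion / neutral /
  low_amp / high_amp); a ratio near two at the ERBB2 locus is the
  low-grade amplification regime.
* **Clinical rules** — the ER (≥10% IHC, >0.05 fmol/ug RIA), HER2
  (ISH-amplified, else IHC 3+) and Ki-67 (≥20%) status rules, and the
  re-examination concordance bookkeeping for discordant cases, with a
  packaged transcription of the published re-examination table.
* **Actionability** — matching somatic alterations to a knowledge base by
  gene and alteration class, one match per patient at the highest priority
  (approved > late > early), BRCA1/2 and ERBB2-mutant/HER2-negative flags.
* **Synthetic cohorts** — `generate_cohort()` simulates expression with
  bimodal marker genes, grade-correlated gene programs, subtype centroid
  structure, ERBB2-amplified bins in HER2-positives, and configurable
  label discordance, so the whole pipeline is testable without any
  clinical data.

See `vignettes/seqdx-methods.Rmd` for the models, assumptions, numerical
choices and limitations.

## Worked example

```r
library(seqdx)

cfg <- cohort_config(n_samples = 120, n_genes = 400, seed = 42)
cohort <- generate_cohort(cfg)
print(cohort)
#> <synthetic_cohort> 120 samples, 400 genes
#>   ER+ 98 | PR+ 79 | HER2+ 16 | Ki67-high 66 (truth)
#>   grades 1/2/3: 37/38/45; 126 alterations; 1000 CNV bins/sample

bundle <- run_pipeline(list(simulate = list(n_samples = 120, n_genes = 400,
                                            seed = 42), seed = 42))
print(bundle)
#> <report_bundle> seed 42
#>   ER    nested-CV AUC 0.808 (95% CI 0.702-0.914), boundary 0.872
#>   PR    nested-CV AUC 0.890 (95% CI 0.829-0.950), boundary 0.588
#>   HER2  nested-CV AUC 0.757 (95% CI 0.615-0.900), boundary 0.241
#>   Ki-67 nested-CV AUC 0.772 (95% CI 0.687-0.857)
#>   TG: grade 1 vs 3 AUC 1.000, boundary 2.154
#>      tg
#> grade low high
#>     1  37    0
#>     2  13   25
#>     3   0   45
#> grade 2: 13 (34%) low TG, 25 (66%) high TG of 38
#>   subtype calls:
#>
#> Basal  Her2  LumA  LumB
#>    19    15    60    26
#>   actionable: 41 patients (34%)
```

Reading the output: each marker line is the out-of-fold AUC of the
corresponding model with its DeLong 95% CI and the probability (for Ki-67:
percent) decision boundary chosen on the ROC curve. The TG block shows the
grade 1 vs 3 discrimination of the summed subcomponent score, the chosen
score boundary on [0, 3], and the cross-tabulation of histological grade
against low/high TG — at this small simulated size every grade-1 tumor is
low TG, every grade-3 tumor high TG, and the 38 grade-2 tumors split
13/25. The subtype table counts shrunken-centroid calls, and the
actionability line is the fraction of patients with at least one
knowledge-base match (breast-only scope, one match per patient at the
highest study phase).

The status rules are available directly:

```r
er_status(ihc_percent = 20)                     # "positive"
her2_status(ihc_grade = "1+", ish_result = "amplified")  # "positive"
ki67_status(20)                                 # "high"
```

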