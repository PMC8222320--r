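# grslife

Gene–environment interaction analysis of body fat mass (BFM) change, as a
tested, reusable R pipeline.

**For whom:** biostatisticians and genetic epidemiologists analysing short
lifestyle-intervention cohorts — a baseline period, then ~12 weeks in one
of four modification arms (low-carbohydrate diet, low-fat diet, moderate-
or intense-intensity exercise) — with SNP-array genotypes, daily diet and
activity diaries, and pre/post anthropometry.

**What it computes.** For each SNP $i$ (minor-allele dosage
$G_i \in \{0,1,2\}$), two interaction regressions:

```
ΔBFM = β0 + βs·sex + βa·age + βa2·age² + βg·G + β1·ΔC + β2·ΔF + βC·ΔC×G + βF·ΔF×G   (diet arms)
ΔBFM = β0 + βs·sex + βa·age + βa2·age² + βg·G + β3·ΔE + βE·ΔE×G                      (exercise arms)
```

where ΔC, ΔF (g/day) and ΔE (kcal/day) are observation-minus-baseline
changes in mean daily carbohydrate intake, fat intake and exercise energy
expenditure extracted from the diaries. The fitted interaction
coefficients weight three genetic risk scores,
`GRS-X = Σ β̂X,i · Gi` over fixed-size panels (37/19/25 SNPs for C/F/E),
so each score predicts how strongly that person's BFM responds to a unit
of the matching lifestyle change. Scores are stratified high/low at the
cutoff maximizing the between-class difference in mean ΔBFM (minimum
class size enforced), compared by Welch t-test with Benjamini–Hochberg
FDR across the three scores, and crossed with an active/inactive
(median-split compliance) classification in a four-group one-way ANOVA.

Upstream, the package provides SNP-level QC (call rate < 0.99, MAF < 0.01,
exact-test HWE p < 1e-5, indel and non-autosomal exclusion, single-fate
accounting), VCF v4.2 / PLINK `.traw` readers and writers with
minor-allele dosage orientation, and a synthetic-cohort generator with
planted interaction effects that makes the whole pipeline testable with no
external data.

## Worked example

```r
library(grslife)

cfg    <- cohort_config(seed = 7)          # 259 participants, 120 SNPs
cohort <- synthesize_cohort(cfg)
qc     <- apply_qc(cohort$genotypes)

win    <- study_windows(cfg)
deltas <- compute_lifestyle_delta(cohort$diet, cohort$activity,
                                  win$baseline, win$observation)
cov      <- covariate_rows(cohort$phenotypes, deltas)
diet_cov <- cov[cov$group %in% c("low_carb", "low_fat"), ]
ex_cov   <- cov[cov$group %in% c("moderate_exercise", "intense_exercise"), ]

dw <- fit_interaction_models(qc$genotypes, diet_cov, "diet")
ew <- fit_interaction_models(qc$genotypes, ex_cov,  "exercise")
panels <- build_panels(dw, ew, c(C = 37, F = 19, E = 25), qc$genotypes$snps)
scores <- grs_score_all(qc$genotypes, panels)

deltas$activity_class <- classify_activity(
  deltas, cohort$phenotypes[, c("participant_id", "group")])$activity_class
res <- analyze_scores(scores, deltas, cohort$phenotypes)
print(res$stratification, digits = 3)
```

prints

```
  grs_type  cutoff n_high n_low mean_dbfm_high mean_dbfm_low    t p_value q_value
C        C  0.0182    225    34          0.588        -1.112 2.43 0.01950  0.0293
F        F -0.0983    233    26          0.511        -0.950 1.53 0.13673  0.1367
E        E  0.1284    181    78          0.817        -0.684 2.83 0.00536  0.0161
```

Each row is one GRS: the chosen cutoff, class sizes, the mean BFM change
(kg, post − pre, reductions negative) in the high- and low-GRS classes,
and the Welch t-test with its BH q-value across the three comparisons.
The four-group view for the carbohydrate score,

```r
print(res$results$four_group$C)
#> <four_group_result>
#>   high-active    n=15   mean dBFM -8.136
#>   high-inactive  n=14   mean dBFM -1.175
#>   low-active     n=6    mean dBFM -6.014
#>   low-inactive   n=6    mean dBFM -1.142
#>   ANOVA F(3, 37) = 11.055, p = 2.527e-05
```

shows the planted structure in this synthetic world: within the low-carb
arm, high-GRS participants who actually complied (active) lost the most
body fat, and compliance without genetic susceptibility (low-active) beat
susceptibility without compliance (high-inactive).

One-shot equivalent, and the CLI:

```r
run_pipeline(run_config(out_dir = "results/demo", seed = 7))
```

```sh
Rscript inst/cli/grslife.R run --config run.json
Rscript inst/cli/grslife.R qc --genotypes in.vcf --format vcf --out qcdir/
# subcommands: run, simulate, qc, lifelog, fit, score, analyze
```

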