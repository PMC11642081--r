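# comorbinet

Comorbidity-pattern analysis for periodontitis cohorts: prevalence
accounting, two-step clustering of patients by binary disease indicators,
covariate-adjusted between-cluster prevalence comparison, and a hypergraph
disease co-occurrence network with eigenvector centrality.

## The problem

Periodontitis (PD) patients frequently carry systemic comorbidities —
cardiometabolic disease, respiratory/allergic disease, endocrine disorders —
and the *patterns* in which those diseases co-occur matter for treatment
planning and referral policy. Given a patient-level table with demographics
(age, sex, socioeconomic-position score, smoking), periodontal metrics
(teeth, pockets ≥ 6 mm, bleeding on probing, PISA), and 26 binary disease
indicators from a medical-history questionnaire, this package answers:

* How prevalent are comorbidity (≥ 1 systemic disease) and multimorbidity
  (≥ 2)?
* Do comorbid patients fall into distinct disease-pattern clusters, and do
  the clusters differ in disease prevalence after adjusting for age, sex,
  SEP, and smoking?
* Which diseases sit centrally in the co-occurrence network of multimorbid
  patients?

Because clinical cohorts of this kind cannot be shared, the package ships a
calibrated synthetic-cohort generator so every stage is testable end to end.

## Methods at the core

**Two-step clustering.** Patients are clustered on the 26 binary indicators
with the classic two-stage design for categorical data: a leader pass
condenses records into homogeneous leaves, then hierarchical agglomeration
merges the closest pair under the log-likelihood (entropy) distance. For a
cluster *v* with *N<sub>v</sub>* members, the cost is
ξ<sub>v</sub> = N<sub>v</sub> Σ<sub>k</sub> Ê<sub>vk</sub> (summed attribute
entropies, natural log), the distance is the pooling increase
d(a,b) = ξ<sub>⟨a,b⟩</sub> − ξ<sub>a</sub> − ξ<sub>b</sub>, and
BIC(J) = 2 Σ ξ<sub>v</sub> + J·K·ln N guides a two-stage choice of the
cluster count (BIC-improvement ratio, refined by the ratio of closest-pair
distances).

**Adjusted comparison.** Each disease (and each ICD-11-adapted disease
group) is regressed on cluster membership by binomial logistic regression
(IRLS) with age, sex, SEP, and smoking as covariates; the cluster effect is
reported as an odds ratio with Wald 95% CI and two-sided p-value, with
explicit flags for separation and untestable (zero-count) outcomes.

**Hypergraph co-occurrence network.** For multimorbid patients the
incidence matrix **M** (diseases × patients) defines a hypergraph whose
hyperedges are each patient's disease combination. The adjacency
**A** = **MM**ᵀ − **D**<sub>n</sub>, with **D**<sub>n</sub> = diag(**MM**ᵀ),
counts pairwise co-occurrences with zero diagonal; disease centrality is
the principal (Perron) eigenvector of **A**, computed by shifted power
iteration. Hyperedges with ≥ 8 occurrences are kept for visual export.

**Synthetic cohorts.** A three-class mixture — disease-free,
respiratory/allergy, cardiometabolic — with class-conditional Bernoulli
indicators (independent within class) and class-conditional demographic and
periodontal distributions. The comorbid classes are rejection-sampled to
≥ 1 disease, with raw rates deflated so within-class prevalences match the
calibration targets in expectation.

## Worked example

```r
library(comorbinet)

gen <- generate_cohort(default_spec(n = 3171, seed = 42))
gen$cohort
#> A periodontitis cohort: 3171 patients, 26 disease indicators
#>   with comorbidity (>=1 disease): 1487 (46.9%)

counts <- disease_counts(gen$cohort)
sub <- cohort(gen$cohort$records[counts >= 1, ], gen$cohort$codebook)
model <- fit_twostep(sub, shuffle_seed = 42)
model
#> Two-step clustering: 2 cluster(s) over 1487 records (364 leaves)
#>   sizes: 671, 816

round(model$profiles[, c("hypertension", "allergic_rhinitis", "allergy")], 3)
#>   hypertension allergic_rhinitis allergy
#> 1        0.003             0.462   0.544
#> 2        0.419             0.107   0.225
```

Nearly half the synthetic cohort is comorbid, and the comorbid subset
splits into a smaller respiratory/allergy cluster (cluster 1: rhinitis 46%,
allergy 54%, almost no hypertension) and a larger cardiometabolic cluster
(cluster 2: hypertension 42%). The adjusted comparison confirms the
enrichment after covariate correction:

```r
disease_cluster_comparison(sub, model$assignments, "hypertension")
#>        outcome  or ci_low ci_high  p_value direction
#> 1 hypertension 234   57.9     945 1.85e-14  cluster2
```

and the co-occurrence network puts the same diseases at its centre:

```r
M <- build_incidence(gen$cohort)          # multimorbid patients only
sc <- centrality(cooccurrence_adjacency(M))
head(round(sort(sc$scores, decreasing = TRUE), 3), 5)
#>           allergy allergic_rhinitis      hypertension            asthma
#>             0.547             0.457             0.417             0.276
#> diabetes_mellitus
#>             0.199
```

`run_pipeline(pipeline_config(seed = 1))` chains all stages and writes
`table1.csv`, `table2.csv`, `figure2.csv`, `clusters.csv`, `bic.csv`,
`adjusted_comparisons.csv`, the hypergraph exports, and a run manifest.

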