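# gscin

Copy-number-based GS/CIN subtyping and survival stratification of gastric
cancer.

## What problem this solves

TCGA recognizes four molecular subgroups of gastric cancer; the two that
cover EBV-negative, microsatellite-stable disease — genomically stable (GS)
and chromosomally instable (CIN) — were defined by unsupervised clustering
of a whole cohort, so there was no rule for assigning an *individual* tumor.
`gscin` implements such a rule for anyone working with shallow-WGS
copy-number profiles of gastric tumors: it classifies single samples into
GS/CIN, computes the genome instability index (GII), combines the molecular
call with Lauren histology into four prognostic strata (GS-intestinal,
GS-diffuse, CIN-intestinal, CIN-diffuse), and provides the survival and
association statistics used to establish those strata.

## The method

Given a segmented log2 copy-number profile on 100-kbp bins and a tumor
purity estimate *p*, observed ratios are corrected by inverting the
admixture model 2^r = p·2^q + (1 − p):

    q = log2( max(2^-10, (2^r − (1 − p)) / p) )

Corrected segmented values are averaged (length-weighted) over the autosomal
GISTIC peak regions (107 of the 114 published peaks; the 7 on chromosome X
are excluded), giving one feature vector per sample. Per-cluster mean
vectors over a labeled reference cohort define the GS and CIN centroids,
and a sample takes the label of the nearer centroid in Euclidean distance,
over the peak dimensions observed in that sample.

GII is the percentage of the called genome with a non-neutral five-level
call; `max_sel_cutpoint()` dichotomizes it at the value maximizing the
standardized two-group log-rank statistic (maximally selected rank
statistic, minimum group proportion 0.1). The statistical battery includes
Kaplan–Meier curves with 10%-at-risk display truncation, log-rank tests,
Cox models (Efron ties) with stepwise backward selection at p < 0.10, a
simplified log-rank survival tree, Fisher r×c and one-way ANOVA association
tests, and permutation-based comparison of regional gain/loss frequencies
between subgroups with a permutation FDR. A fully seeded synthetic-cohort
generator (`sim_config()` / `simulate_cohort()`) emulates binned profiles,
purity admixture, five-level calls, Table-1-like covariates and
stratum-specific exponential survival, so the whole pipeline runs and is
tested without patient data.

See `vignettes/gscin-methods.Rmd` for the model, its assumptions, and every
numerical choice.

## Worked example

```r
library(gscin)

cfg    <- sim_config(seed = 1)          # defaults = the study conditions
cohort <- simulate_cohort(cfg)

# samples-by-peaks matrix of purity-corrected segmented log2 values
pm  <- summarize_peaks(cohort$profiles, cfg$peaks, cfg$grid)

# fit centroids on the labeled reference panel, classify the cohort
fit <- gscin_fit(cohort$reference$matrix, cohort$reference$labels)
fit
#> GS/CIN nearest-centroid classifier
#>   peaks: 24   reference: n(GS) = 83 , n(CIN) = 210
#>   inter-centroid distance: 2.805
calls <- predict(fit, pm)

# apply the cohort exclusions and stratify by TCGA x Lauren
fc  <- filter_cohort(cohort$clinical)
fc
#> cohort filter: 371 -> 309 analyzable ( 39 'other' histology, 23 insufficient DNA excluded )
dat <- merge(calls, fc$clinical, by = "sample_id")
stratify(dat[, c("sample_id", "label")], setNames(dat$lauren, dat$sample_id))
#> TCGA x Lauren stratification (309 samples)
#>         stratum   n percent
#>   GS-intestinal  24     7.8
#>      GS-diffuse  57    18.4
#>  CIN-intestinal 142    46.0
#>     CIN-diffuse  86    27.8
```

Every simulated tumor is classified back to its generating subtype here, so
the strata reproduce the configured 24/57/142/86 split and the percentages
(7.8/18.4/46.0/27.8) are the four-subgroup composition of the cohort.
Five-year cancer-related survival per stratum follows from the fitted
Kaplan–Meier curves:

```r
km <- km_fit(dat$time_months, dat$event,
             paste(dat$label, ifelse(dat$lauren == "mixed", "diffuse", dat$lauren),
                   sep = "-"))
survival_at(km, 60)
#>            group time      surv     lower     upper beyond_followup
#> 1    CIN-diffuse   60 0.3015188 0.2078211 0.4374609           FALSE
#> 2 CIN-intestinal   60 0.4842738 0.3948717 0.5939173           FALSE
#> 3     GS-diffuse   60 0.5204121 0.3863192 0.7010494           FALSE
#> 4  GS-intestinal   60 0.7491639 0.5772333 0.9723045           FALSE
```

i.e. the estimated five-year survival ranges from 30% (CIN-diffuse) to 75%
(GS-intestinal) in this cohort, around the generator's calibration of
31.5%–61.4%. A command-line front end over the same functions lives at
`inst/cli/gscin.R` (subcommands `simulate`, `classify`, `gii`, `cutpoint`,
`stratify`, `analyze`, `compare-regions`, `run-all`).

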