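# miomet

Analysis pipeline for joint gut-microbiome / urine-metabolome cohort
studies: who produces what, which urinary metabolites mark a diverse gut
community, and whether those metabolites carry the health associations of
microbial diversity.

`miomet` is aimed at statistical analysts of population cohorts with
paired 16S rRNA genus count tables and targeted (e.g. NMR) urine
metabolite panels. It implements, as tested and reusable components:

* **Dilution normalisation** — probabilistic quotient estimation of each
  sample's urine dilution on the log scale, followed by per-metabolite
  regression on a restricted cubic spline of that factor (4 knots at the
  5/33/66/95 percentiles) and a single-pass 4-SD outlier rule;
* **Association screens** — linear mixed models of each normalised
  metabolite on genus abundance, genus presence, or alpha diversity
  (Shannon entropy, richness), with spline-coded covariate adjustment in
  two tiers, a sequencing-batch random intercept, Benjamini–Hochberg FDR
  per screen, full-adjustment re-testing of hits, and a within-batch
  case-resampling bootstrap sensitivity p-value;
* **Microbiome-based prediction scores** — the elastic-net objective

  ```
  Q = 1/(2n) Σᵢ (yᵢ − β₀ − xᵢ'β)² + λ Σⱼ [ (1−α)/2 βⱼ² + α|βⱼ| ]
  ```

  solved by coordinate descent (C++, warm-started λ paths, active sets),
  with a 10-fold cross-validated grid search over α ∈ {0, 0.1, …, 1} and
  100 λ values per α, reporting out-of-sample R² and per-sample scores;
* **Mediation analysis** — product-of-coefficients decomposition of
  diversity → health-marker effects through a metabolite or its
  microbiome-based score, with percentile-bootstrap CIs on the proportion
  mediated (which may exceed 100% when direct and total effects have
  opposite signs);
* **Functional annotation** — reaction abundances of communities mapped
  onto a genome-scale reconstruction summary (sum of carrier relative
  abundances), per-phylum secretion capability, and fractional-logit
  regressions of reaction abundances on diversity with robust SEs;
* **A synthetic cohort generator** with planted genus–metabolite effects,
  dilution confounding, batch structure and mediated marker effects, so
  every stage has a recoverable ground truth.

## Worked example

```r
library(miomet)

cfg <- sim_config(n_samples = 951, seed = 1)   # 50 genera, 60-metabolite panel
cohort <- simulate_cohort(cfg)

prep <- prepare_panel(cohort$panel)
prep$panel
#> <metabolite_panel> 951 samples x 42 metabolites, state = normalised
#>   missing cells: 2039; masked outliers: 11

screen <- run_screen(prep$panel, cohort$abundance, cohort$covariates,
                     mode = "abundance")
head(screen[order(screen$q), c("predictor", "response", "b", "q", "tier")], 3)
#>      predictor  response         b             q  tier
#> 53    genus_03 succinate  7.808788  0.000000e+00 basic
#> 2101  genus_03 succinate  7.814527  0.000000e+00  full
#> 110   genus_10   formate -6.118863 2.774949e-237 basic
```

The screen recovers the generator's planted effects (slopes 8 and −6 on
those pairs), and re-tests the hits under the full covariate tier.
Fitting the microbiome-based score for the diversity-driven focal
metabolite and mediating a health-marker effect through it:

```r
vals <- panel_values(prep$panel)
rel <- relative_abundance(cohort$abundance)
keep <- !is.na(vals[, "hippurate"])
fit <- enet_cv(vals[keep, "hippurate"], rel[keep, ], seed = 1)
round(fit$r2_oos, 3)
#> [1] 0.011

div <- diversity_vector(cohort$abundance)
round(cor(fit$score, div$shannon[keep]), 2)
#> [1] 0.5
```

The out-of-sample R² is small by design — batch offsets and host factors
dominate the urinary signal, as they do for most urinary metabolites —
yet the genus-based score still tracks alpha diversity strongly, because
the score concentrates exactly the diversity-driven component of the
metabolite. Mediating a marker effect through the metabolite:

```r
med <- mediate(setNames(div$shannon, div$sample_id),
               vals[, "hippurate"],
               setNames(log(cohort$markers$ggt), rownames(cohort$markers)),
               covariates = cohort$covariates, n_boot = 1000, seed = 1)
med
#> <mediation_result> n = 896, 1000 bootstrap replicates
#>   total -0.4778, direct -0.0869, indirect -0.3910
#>   proportion mediated: 81.8% (95% CI 61.9%, 113.5%)
```

The planted mediated fraction in this generator is 78%; the estimate and
its interval are the pipeline's recovery of it.

An end-to-end run (simulate → normalise → diversity → screens → score →
mediation → annotation), persisting every intermediate plus a run
manifest, is one call:

```r
cfg <- pipeline_config(out_dir = "run1", seed = 1, sim = list(n_samples = 500))
run_pipeline(cfg)
```

or from a shell via the thin dispatcher:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "miomet.R", package = "miomet"))') \
    pipeline --out run1 --seed 1
```

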