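# tilquant

Machine scoring of tumor-infiltrating lymphocytes (TILs) on
hematoxylin-and-eosin image tiles, with the statistics needed to validate
such scores — and a synthetic-data generator that makes the whole
pipeline testable with no image downloads.

TILs are prognostic in melanoma, but pathologist-read scores (TIL-WG
stromal percentages, Clark brisk/nonbrisk/sparse grades) vary
substantially between observers. A machine pipeline replaces the
subjective read with reproducible computation:

1. **Stain normalization** — Beer–Lambert optical density
   (OD = −log₁₀(I/I₀)), Macenko-style stain-vector estimation
   (eigenplane of foreground OD + extreme-angle percentiles), and
   re-rendering of every tile through one fixed reference stain model.
2. **Cell detection and classification** — Gaussian smoothing and
   thresholding of the hematoxylin channel, watershed splitting,
   distance-limited Voronoi cell expansion, a fixed morphometric +
   chromatic feature schema, and a one-hidden-layer MLP over
   {tumor, stromal, immune, other}, scored by per-class
   precision/recall/F1 with greedy centroid matching.
3. **The five electronic TIL variables** within an annotated region
   (counts *n*, cell areas *a* in mm², region area *A*):

   | score | definition |
   |---|---|
   | eTILs%  | 100·n_immune / (n_immune + n_tumor) |
   | etTILs% | 100·n_immune / (n_immune + n_tumor + n_stromal + n_other) |
   | esTILs% | 100·n_immune / (n_immune + n_stromal) |
   | eaTILs  | a_immune / A |
   | easTILs% | 100·a_immune / (A − a_tumor) |

   plus cohort QC (exclude area < 0.5 mm² or tumor fraction < 50%) and
   cutoff dichotomization (median, 16.6, 10%, 30%; high iff ≥ cutoff).
4. **Validation statistics** — ICC (all six Shrout–Fleiss forms with
   F-based CIs; default ICC(2,1)), tie-corrected Kendall's W,
   coefficient of variation, reliability bands, Kaplan–Meier + log-rank,
   Cox proportional hazards (Efron ties, stage-I-referenced adjustment
   set), and Schoenfeld proportional-hazards checks.
5. **Synthetic data** — Beer–Lambert H&E tiles with class-distinct cell
   morphologies and exact ground truth, dense two-stain phantoms,
   operator score matrices with a target ICC, ordinal Clark matrices,
   and survival cohorts with a known hazard ratio.

See `vignettes/tilquant-methods.Rmd` for models, parameters and design
choices.

## Worked example

Simulate two cases, run the full pipeline (reference fitting,
normalization, detection, classifier training on ground-truth-labeled
tiles, scoring), then the concordance and survival statistics:

```r
library(tilquant)

cfg <- pipeline_config(seed = 1,
                       sim = sim_config(seed = 1, field_width_um = 350,
                                        field_height_um = 350),
                       n_cases = 2)
res <- run_pipeline(cfg)   # add out_dir = "run1" to write artifacts
res$panels
#>   case n_tumor n_stromal n_immune n_other eTILs_pct etTILs_pct esTILs_pct
#> 1    1      36        45       63      27    63.636     36.842     58.333
#> 2    2      43        41       50      19    53.763     32.680     54.945
#>   eaTILs easTILs_pct
#> 1  0.123      14.373
#> 2  0.104      12.672

# operator concordance of a simulated 60-case x 38-rater score matrix
icc(log_transform(simulate_score_matrix(sim_config(seed = 1))))
#> ICC2 = 0.9226 (95% CI, 0.8933-0.9474)  [excellent]  n_cases = 60, n_raters = 38

# prognostic association in a simulated testing cohort (n = 111, true HR 0.45)
co <- simulate_survival_cohort(sim_config(seed = 1))
km_logrank(co)$p
#> log-rank chi-square 7.53, p = 0.0061
cox_fit(co, c("group", "sex", "age", "stage"))[1, ]
#>        term    hr lower upper       p
#> 1 grouphigh 0.435 0.243 0.778 0.00504
```

Each panel row gives the per-class cell counts inside the scored region
and the five TIL scores; here roughly a third of all cells are immune,
so eTILs% (immune vs tumor) sits near 60 and etTILs% (immune vs all
cells) near 35. The ICC of 0.92 on the simulated operator matrix lands
in the "excellent" reliability band, and the high-TIL group of the
simulated cohort shows the protective hazard ratio it was generated
with (0.435, true value 0.45).

A thin command-line front end over the same functions lives at
`inst/cli/tilquant.R` (subcommands `simulate`, `fit-reference`,
`normalize`, `score`, `concord`, `survive`, `run`).

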