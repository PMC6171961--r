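# ordgwas

GWAS of ordinal (rater-scored) traits across multiple cohorts, end to end:
genotype QC, LD pruning and PCA covariates, additive and conditional linear
association scans, trans-ethnic meta-analysis with Cochran's Q / I²
heterogeneity, approximate-Bayes-factor credible-set fine-mapping, and a
battery of positive-selection tests — haplotype-based iHS scans, pairwise
log-odds selection-difference tests, and a polygenic-score divergence
(Qx-style) test against a drift null built from frequency-matched neutral
variants.

The intended user is a statistical geneticist who wants the full analysis
chain of a multi-cohort scan of a trait rated on an ordered categorical
scale (e.g. a 3-level photo-numeric score averaged over raters) as tested,
reusable building blocks — including a forward Wright–Fisher simulator with
selection, recombination and population splits plus an ordinal
genotype→phenotype generator, so every stage can be validated on
truth-tagged synthetic cohorts without access to restricted cohort data.

## Core statistics

* **Scan** — per variant, OLS of the (averaged) score on dosage +
  covariates; genomic control λ = median χ² / 0.45494.
* **Meta** — METAL-style sample-size-weighted `Z = Σ√nᵢzᵢ/√Σnᵢ` and
  inverse-variance fixed effects; `Q = Σwᵢ(βᵢ−β̂)²`,
  `I² = max(0, (Q−(k−1))/Q)·100`; DerSimonian–Laird random effects.
* **Fine-mapping** — per-variant approximate Bayes factor
  `BF = √(V/(V+W))·exp(z²W/2(V+W))`, posterior = BF/ΣBF over the ±500 kb
  locus, 99% credible set by ranked cumulative posterior.
* **iHS** — EHH via `Σ C(n_h,2)/C(n_c,2)` out to EHH < 0.05, trapezoidal
  iHH, `iHS = ln(iHH_A/iHH_D)` standardized in 0.05 frequency bins;
  Gaussian p-values and empirical top-0.1% cutoffs.
* **Selection differences** — `d = logit(p_A) − logit(p_B)` with a
  genome-wide, frequency-binned robust null SD.
* **Qx** — scores `Z_m = 2Σβ_l p_ml` tested against a multivariate-normal
  drift null `4·V_A·F` with matched-set empirical resampling.

See `vignettes/methods.Rmd` for models, parameter defaults and design
rationale.

## Worked example

A published-numbers check plus a two-cohort synthetic run:

```r
library(ordgwas)
set.seed(42)

# Heterogeneity arithmetic from a printed Q over four cohorts:
heterogeneity(q = 16.284, k = 4)$i2        # 81.58 (%)

# Sample-size-weighted meta of three cohort rows (all effects positive):
m <- meta_fixed_ss(p = c(1.46e-4, 3.42e-3, 3.54e-6),
                   direction = c(1, 1, 1), n = c(2961, 721, 2301))
# m$z = 6.563, m$p = 5.26e-11, m$n_total = 5983, directions "+++"

# Two synthetic cohorts sharing one causal variant (beta = 0.4 latent):
p0 <- runif(120, 0.1, 0.9); p0[60] <- 0.5
sim  <- sim_config(n_diploid = c(400, 400), n_sites = 120,
                   sequence_length = 5e6, generations = 80,
                   split_generation = 40, init_freq = p0,
                   require_segregating = 60L)
arch <- trait_architecture(causal = data.frame(id = "sv00060", beta = 0.4))
cfg  <- pipeline_config(sim, arch, cohort_n = c(1500, 1500),
                        selection_battery = FALSE)
res  <- run_pipeline(cfg, seed = 42)
res$loci
#> [1] "sv00060"
res$meta[match(res$loci, res$meta$ID),
         c("ID", "BETA_FIXED", "SE_FIXED", "P_SS", "I2", "DIRECTIONS", "N")]
#>       ID BETA_FIXED  SE_FIXED         P_SS I2 DIRECTIONS    N
#>  sv00060  0.1827573 0.0200166 8.312255e-20  0         ++ 3000
head(res$credible_sets[["sv00060"]], 2)[, c("id", "posterior", "in_credible_set")]
#>       id   posterior in_credible_set
#>  sv00060 1.00000e+00            TRUE
#>  sv00051 1.18387e-15           FALSE
```

The meta scan recovers the planted variant genome-wide significantly
(P ≈ 8.3e-20 at n = 3000; the latent β = 0.4 appears as ≈ 0.18 on the
averaged 1–3 rating scale because thresholding and rater noise attenuate
it), with no heterogeneity between the two cohorts (I² = 0), and the 99%
credible set is the causal variant alone. Phenotype-quality metrics on the
same run give inter-rater Cohen's κ = 0.587 and a Gini diversity of the
rating distribution of 0.618:

```r
ph <- res$cohorts$cohort1$phenotypes
cohens_kappa(ph$rater1, ph$rater2)$kappa   # 0.587
gini_diversity(ph$rater1)$d                # 0.618
```

## Command line

Every stage is also a CLI subcommand (`simulate`, `qc`, `gwas`, `meta`,
`finemap`, `ihs`, `seldiff`, `qx`, `phenostats`), driven by a YAML config
and writing a JSON run manifest:

```sh
Rscript -e 'ordgwas::run_cli()' simulate --config sim.yaml --seed 7 --out run/
# or, from an installed tree: <library>/ordgwas/exec/ordgwas simulate ...
```

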