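# kinherit

Heritability and single-variant mixed-model association for quantitative
traits measured in extended families, using either the expected kinship
computed from genealogy or an empirical genetic relationship matrix (GRM)
estimated from genome-wide SNP dosages.

The package is aimed at analysts of family-based cohorts (the motivating
design is a multi-generation lipid study with triglyceride and HDL-C
measured at two visits before and two after a drug intervention) who want
to (1) estimate narrow-sense heritability under interchangeable kinship
models, (2) screen their pedigrees for sample swaps and relationship
errors before trusting either, and (3) scan SNPs for association while
accounting for relatedness.

## The model

The engine is the two-component polygenic model

    y ~ N(X beta, sigma2_g * K + sigma2_e * I),
    h2 = sigma2_g / (sigma2_g + sigma2_e)

with K a relatedness matrix on the 2Φ scale (Φ the kinship coefficient).
K can be:

- **pedigree-derived** — `pedigree_kinship()` runs the classical
  recursion Φ(i,j) = ½[Φ(fi,j) + Φ(mi,j)], Φ(i,i) = ½[1 + Φ(fi,mi)];
- **empirical** — `grm()` computes the allelic-correlation estimator
  K(i,j) = (1/m) Σs (gis − 2ps)(gjs − 2ps) / 2ps(1−ps), and
  `postprocess_kinship()` applies the conventional repairs (zero the
  negative entries, rescale each entry by 1/√(Kii·Kjj) so the diagonal
  is exactly 1); or
- **imported** — `import_kinship()` reads matrices computed elsewhere.

`fit_polygenic()` maximizes the likelihood through a single symmetric
eigendecomposition plus a one-dimensional profile search in h² on [0, 1];
`lrt_h2()` tests h² > 0 against the boundary-corrected ½χ²₀ + ½χ²₁ null.
`mga_scan()` performs measured genotype analysis — each SNP dosage enters
the same model as a fixed covariate — with genome-wide suggestive
(p ≤ 1e−5) and Bonferroni (α/m) flags. Around the engine sit pedigree
parsing/validation, SNP QC (Hardy-Weinberg filter, windowed LD pruning),
method-of-moments IBD relationship inference with a pedigree-discordance
report, trait preparation (visit averaging, founder-based PCA covariates,
covariate residualization, rank-based inverse-normal transform), and a
gene-dropping simulator that generates pedigrees, genotypes and traits
with specified heritability.

## Worked example

```r
library(kinherit)

# a 30-family, three-generation study; trait heritability 0.55
cfg   <- sim_config(n_families = 30, n_snps = 5000, true_h2 = 0.55, seed = 7)
study <- simulate_study(cfg)

# visit averaging -> covariate residualization -> inverse-normalization
hdl <- prepare_trait(study$pheno, "trait", phase = "pre")

# heritability under the pedigree kinship
fit_polygenic(hdl, study$kinship)
#> <polygenic_fit> h2 = 0.621 (SE 0.083), p = 9.42e-15, n = 420 [pedigree kinship]
#>   sigma2_g = 0.6273, sigma2_e = 0.3823, logL = -566.13 (null -595.45)

# heritability under a postprocessed empirical GRM
grm_rep <- grm(study$genotypes)
grm_rep
#> <empirical_kinship_report> allelic-correlation, 5000 SNPs used (0 excluded)
#>   raw diagonal: min 0.854 max 1.063 mean 0.995 sd 0.025
k_emp <- postprocess_kinship(grm_rep$kinship)
fit_polygenic(hdl, k_emp)
#> <polygenic_fit> h2 = 0.640 (SE 0.082), p = 5.04e-15, n = 420 [empirical kinship]
#>   sigma2_g = 0.6483, sigma2_e = 0.3652, logL = -565.51 (null -595.45)

compare_kinships(study$kinship, k_emp)
#> <kinship_comparison> 420 common samples
#>   off-diagonal: r = 0.9931, RMSE = 0.0063, mean diff = -0.0021

# mixed-model association scan with plot-ready output
scan <- mga_scan(hdl, study$genotypes, study$kinship, method = "fast")
plot_data(scan)
#> <mga_plot_data> 5000 SNPs, lambda = 1.026
```

Reading the output: both kinship models recover an h² estimate within one
standard error of the generating value 0.55, with strongly significant
boundary-corrected LRT p-values; the two estimates differ by 0.02,
illustrating the near-equivalence of pedigree and empirical kinship when
there is no hidden relatedness. The GRM report shows the raw
self-relatedness diagonal spread around 1 before postprocessing fixes it
at exactly 1. The null association scan (no QTL was planted) is
calibrated: genomic inflation λ ≈ 1.03.

Relationship screening before analysis:

```r
pruned <- qc_snps(study$genotypes)          # HWE filter + LD pruning
calls  <- relationship_calls(study$ped, pruned)
pedigree_discordance(study$ped, calls)      # swap candidates, if any
```

A thin command-line front end over the same functions is installed at
`inst/cli/kinherit` (subcommands `simulate`, `kinship`, `grm`, `h2`,
`relcheck`, `mga`).

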