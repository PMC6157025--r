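---
title: "Heritability and association with pedigree and empirical kinships: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritability and association with pedigree and empirical kinships: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinherit)
```

## The problem

In family studies of quantitative traits — here modelled on lipid phenotypes
(triglycerides, HDL-C) measured in multi-generation pedigrees before and
after a drug intervention — two questions recur:

1. **How heritable is the trait?** What fraction of its variance is
   attributable to additive genetic effects (narrow-sense heritability,
   $h^2$)?
2. **Which individual variants are associated with it**, once the
   non-independence of relatives is accounted for?

Both questions hinge on a relatedness matrix. It can come from genealogy
(the *expected* kinship implied by the recorded pedigree) or from
genome-wide SNP data (*empirical* kinship, a genetic relationship matrix).
`kinherit` implements both routes, the quality-control screens that
protect them from sample-handling errors, and a gene-dropping simulator
that lets every stage be validated end to end without access to any real
cohort.

## The polygenic model

The core model is the standard two-component variance decomposition

$$ y \sim N(X\beta,\; \sigma^2_g K + \sigma^2_e I), \qquad
   h^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_e}, $$

where $K$ is a relatedness matrix on the $2\Phi$ scale ($\Phi$ the kinship
coefficient: diagonal $1+F$, 0.5 for parent–offspring pairs).
`fit_polygenic()` eigendecomposes $K = UDU'$ once, rotates $y$ and $X$ by
$U'$, and profiles out $\beta$ and the total variance, leaving a
one-dimensional likelihood in $h^2$ on $[0,1]$ maximized by Brent search.
This needs no starting values and cannot fail to converge; estimates
within $10^{-6}$ of an endpoint are reported as exactly 0 or 1 with a
boundary flag.

**Scale convention.** $K$ is normalized internally to unit mean diagonal
(division by $\mathrm{tr}(K)/n$). Consequently $h^2$, the
likelihood-ratio statistic, its p-value *and* the reported variance
components are all invariant to a global rescaling of $K$ — in particular
to whether a matrix was supplied as $\Phi$ or $2\Phi$ — and the identity
$h^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$ holds exactly on the reported
scale. This is what makes pedigree-derived matrices and empirical
matrices scaled to unit diagonal directly exchangeable.

**Testing $h^2 > 0$.** The null $\sigma^2_g = 0$ sits on the boundary of
the parameter space, so the LRT statistic follows the
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture: `lrt_h2()` returns
$p = \tfrac12 P(\chi^2_1 \ge \Lambda)$, with $p = 1$ at $\Lambda = 0$.

**ML vs REML.** Maximum likelihood is the default, matching the classic
variance-components LRT framework. Its boundary test is mildly
*conservative* at desk scale: with 30–60 simulated families we measure
empirical type-I error around 0.03–0.04 at nominal 0.05, because ML does
not account for fixed-effect estimation (and the traits here are
pre-residualized on about ten estimated covariate coefficients). The
restricted likelihood (`reml = TRUE`) corrects exactly this and is
calibrated (≈0.05 in the same simulations); the acceptance suite uses it
for the calibration check and reports both rates. Conservatism never
inflates false positives, so the default is safe for screening.

**Standard errors** come from the curvature of the profile likelihood at
the optimum (numerical second derivative). At a boundary optimum the
delta method is invalid and the SE is `NA` by design. In the recovery
simulations below, the empirical SD of $\hat h^2$ and the mean reported
SE agree within ~5%.

**Degenerate inputs.** Indefinite matrices (a side effect of
postprocessing, below) are handled by clipping eigenvalues at $10^{-8}$;
the clip count is reported. A kinship matrix numerically equal to the
identity carries no relatedness information and raises an
unidentifiability error rather than returning an arbitrary $h^2$.

## Pedigree kinship

`pedigree_kinship()` implements the classical recursion
$\Phi(i,j) = \tfrac12[\Phi(f_i,j)+\Phi(m_i,j)]$ (for $j$ not a descendant
of $i$) and $\Phi(i,i) = \tfrac12[1+\Phi(f_i,m_i)]$, with founders
mutually unrelated and non-inbred; individuals are processed in
topological (parents-first) order, ties broken by input order, so output
is deterministic. Entries are exact rationals represented as doubles;
inbreeding (e.g. diagonal 1.25 for the child of a full-sib mating) falls
out of the recursion.

The independent check is `mc_kinship()`: uniquely labelled founder
alleles are dropped through the pedigree tens of thousands of times and
pairwise identity-by-descent is averaged. Agreement is assessed
entrywise in Monte-Carlo standard errors; with ~1,500 matrix entries
across ten random pedigrees a handful of 3-SE exceedances is the
expected multiplicity, so the suite requires ≥99% of entries within 3 SE
and none beyond 5.

## Empirical kinship

`grm()` is the allelic-correlation (VanRaden-type) estimator,
$K_{ij} = m^{-1}\sum_s (g_{is}-2p_s)(g_{js}-2p_s)/2p_s(1-p_s)$, with
frequencies computed from the analyzed samples, a MAF floor (default
0.01) to keep denominators stable, and mean imputation of missing
dosages. Its off-diagonal expectation equals $2\Phi$, verified against
gene-dropped sib, parent–offspring and unrelated pairs. LD-weighted or
HMM-based estimators are deliberately not re-implemented;
`import_kinship()` accepts externally computed matrices so the usual
three-way comparison workflow (pedigree vs two empirical estimators)
still runs.

`postprocess_kinship()` applies the two conventional repairs, in this
order: strictly negative entries are set to zero ("removing" an entry of
a matrix can only mean zeroing it), then each entry is rescaled by
$1/\sqrt{K_{ii}K_{jj}}$ so the diagonal equals exactly 1. Per-pair
rescaling is required — raw self-relatedness estimates spread widely
around 1, so no single global divisor could fix the diagonal. The
operation is idempotent and sign-preserving; note that with a spread
diagonal it can permute the *ordering* of entries within a row (each
column is divided by a different factor), and zeroing negatives can make
the matrix indefinite — which is why the minimum eigenvalue is recorded
and the polygenic fitter clips.

## Relationship screening

`moment_ibd()`/`ibd_estimates()` implement the method-of-moments IBD
estimator on identity-by-state counts (the PLINK `--genome` approach):
expected IBS given each IBD state is computed from allele frequencies,
the moment system is solved, and raw estimates are projected onto the
simplex by truncation and renormalization. Allele frequencies are
treated as known (they come from hundreds of samples), so the
small-sample bias corrections of the original estimator are omitted.
This is a deliberate substitution for likelihood-based relationship
tests: the screening purpose — flagging sample swaps and unexpected
relatedness — needs only degree-level accuracy, which the moment
estimator delivers at ≥95% on pruned 10k-SNP panels. Inference should
use the LD/HWE-pruned marker set (`qc_snps()`): the moment estimator
assumes independent markers.

Classification uses kinship intervals with edges at powers of two
(0.354, 0.177, 0.0884, 0.0442), splitting the 1st-degree band into
parent–offspring vs full siblings by $\hat{\mathrm{IBD}}_0 < 0.1$.

`pedigree_discordance()` compares inferred classes with the
pedigree-expected ones. A swapped sample contradicts essentially *all*
of its within-family pairs, while each innocent relative contradicts
only the single pair involving the swapped sample. The report therefore
lists every individual with at least one discordance (with counts), but
*proposes for exclusion* only individuals discordant in more than half
of their within-family pairs — on a planted swap this recovers exactly
the two swapped samples. Cross-pedigree pairs above the 3rd-degree
kinship bound are listed as corroborating evidence (the swapped-in
genotype shows up as related to its true family).

## Trait preparation

- `average_visits()`: the two visit replicates within a phase are
  averaged; a single available measurement is used as-is.
- `founder_pca()`: stratification PCs are fit on pedigree founders only
  (so family structure cannot masquerade as ancestry) and projected to
  all samples; founders' projected scores equal their fit scores by
  construction.
- `residualize()`: OLS on the full fixed covariate set — age, sex,
  age×sex, age², age²×sex, study center, smoking, PCs 1–4 — always all
  included, never selected by significance, for determinism.
  Rank-deficient designs are an error naming the collinear columns.
- `inverse_normal()`: rank-based transform with the Blom offset
  $(r-0.375)/(n+0.25)$, average ranks for ties, then exact
  standardization to mean 0, SD 1. Monotone and affine-invariant.

The order — residualize, then inverse-normalize — follows standard
variance-components practice.

## Measured genotype association

`mga_scan()` adds each SNP's dosage (0/1/2, missing mean-imputed per
SNP) as a fixed covariate in the polygenic model, reusing one
eigendecomposition of $K$ for the whole scan. The default `"exact"` mode
re-estimates the variance components under every SNP model and tests by
1-df LRT against the no-SNP fit; the `"fast"` mode fixes the variance
components at their null estimates and uses a GLS Wald chi-square — the
two agree on $-\log_{10}p$ to within 0.1 on null scans, and the fast
mode is what makes replicate power studies cheap. SNPs below 1% MAF or
above 10% missingness are skipped with logged reasons (SE estimates
become unstable below that). Significance flags follow the genome-wide
conventions: suggestive at $p \le 10^{-5}$ (a fixed convention, not
$\alpha/m$-derived), significant at Bonferroni $\alpha/m$. With
$\alpha = 0.05$ and the 718,407-SNP panel this is
$6.96\times10^{-8}$ — printed as $6.9\times10^{-8}$ in truncated
two-figure form. `plot_data()` produces Manhattan/Q-Q series and the
genomic inflation factor $\lambda$ (median $\chi^2$ over 0.4549).

With an identity $K$ the whole machinery reduces to ordinary
linear-regression LRTs (verified to $10^{-6}$), and flipping the dosage
coding flips $\hat\beta$'s sign without changing its magnitude — allele
labels are carried through so the effect allele is never ambiguous.

## The simulator and what it does (not) emulate

`simulate_study()` generates the study conditions every claim above is
tested under:

- **Pedigrees**: 60 three-generation families by default — two
  grandparents, three adult children with married-in spouses, two
  grandchildren per couple; 14 members each, 840 individuals, the scale
  of a large family-based lipid cohort.
- **Genotypes**: `gene_drop()` draws founder haplotypes from
  Hardy-Weinberg proportions at uniform(0.05, 0.5) frequencies and
  transmits one uniformly chosen allele per parent per SNP; 10,000
  independent markers by default. Markers segregate independently (no
  linkage map); an optional Markov haplotype-copying mode creates block
  LD for testing the pruner, and a Balding–Nichols two-subpopulation
  mode creates founder stratification for testing the PCA. A
  `planted_swap` exchanges two individuals' genotype rows only,
  emulating a sample-handling error.
- **Traits**: fixed covariate effects (age slope 0.02/yr, sex difference
  0.3, center offset 0.2, smoking 0.2 — modest effects on a unit-variance
  trait, removed again by residualization), an optional single QTL with a
  stated variance fraction, a polygenic value sampled through the
  symmetric eigen square root of any PSD kinship matrix (so empirical
  matrices work too, unlike recursive Mendelian sampling), an individual
  environmental deviate, and independent per-visit noise (SD 0.5) on two
  pre- and two post-intervention visits.

**Heritability convention**: `true_h2` is the heritability of the
*phase-averaged* phenotype. The variance budget is
$\sigma^2_g = h^2(1-q)$,
$\sigma^2_{e,\mathrm{ind}} = (1-h^2)(1-q) - \sigma^2_{\mathrm{visit}}/2$
(with $q$ the QTL fraction), so averaging the two visit replicates
yields genetic fraction exactly $h^2$; an infeasible budget (visit noise
exceeding the environmental variance) is an error. Every generator is a
pure function of (configuration, seed).

What the simulator does **not** emulate: realistic LD and recombination
maps, ascertainment, genotyping error, pharmacodynamic response to the
intervention, or trait non-normality beyond what the covariates induce.
Passing tests therefore demonstrate correctness of the estimators under
the model's own assumptions — unbiasedness on real cohort data with
cryptic structure, batch effects, or informative missingness is a
separate question the package's QC tools help probe but cannot settle.

## Problem sizes and numerical choices

The validation suite uses: 100 replicates per heritability level
(0.2, 0.42, 0.55, 0.8 — the middle two chosen to match reported
pedigree-based estimates for pre-intervention triglycerides and HDL-C)
on the 840-person design; 1,000 null replicates for LRT calibration; 50
replicates for the pedigree-vs-GRM comparison (10,000 SNPs each) and for
QTL power (5% variance QTL, n = 840); a 5,000-SNP exact-mode null scan
for $\lambda$; 20,000 Monte-Carlo drops for the kinship oracle. These
sizes put Monte-Carlo error comfortably inside the asserted tolerances
while keeping a full run in minutes on one core.

Numerical details collected in one place: eigenvalue clip $10^{-8}$;
Brent tolerance $10^{-8}$ on $h^2$; boundary snap at $10^{-6}$;
kinship-matrix symmetry tolerance $10^{-8}$ (matrices are symmetrized by
averaging); LD-prune tie-breaks remove the lower-MAF member, then the
later marker in map order; HWE uses the 1-df chi-square (not the exact
test) for speed, with monomorphic markers returning $p = 1$; window
units for pruning are marker counts, the convention when no kb suffix is
given.

## Known limitations

- Half-specified parentage is rejected rather than imputed; X-linked
  kinship, pedigree loops requiring likelihood-based loop-breaking, and
  dominance/household variance components are out of scope.
- The moment IBD estimator reports degree-level classes only; it is a
  screen, not a likelihood-based relationship test.
- Exact-mode MGA refits variance components per SNP and is meant for
  panels up to ~10^5 SNPs at desk scale; genome-scale scans should use
  the fast mode (or the exact mode on the suggestive subset).
- The ML boundary LRT is finite-sample conservative (see above); REML is
  provided and used for calibration claims.
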