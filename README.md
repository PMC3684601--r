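# famkernel

Region-based kernel (SKAT-type) association testing of quantitative traits
in samples of **related individuals**, for statistical geneticists analysing
pedigree or family-cohort data (exome regions, sliding marker windows) who
want to keep using kernel machinery built for unrelated samples.

## The method

Kernel region tests sum weighted per-marker score statistics,
`Q = Σ_m w_m T_m`, and compare `Q` with a mixture-of-χ²₁ null.  With
relatives the trait covariance is `V = σ²_g R + σ²_e I` (`R` = relationship
matrix, twice the kinship), and the unrelated-sample null is wrong: inflated
type I error on the raw trait, conservative on BLUP-subtracted residuals.

`famkernel` fits the null polygenic model `y = Xα + u + e` by REML (one
eigendecomposition of `R`, closed-form profiling over heritability) and
applies the **GRAMMAR+ transformation**

    y⁺ = (σ̂² / √γ̄) · V̂⁻¹ (y − Xα̂),
    γ̄  = σ̂² · tr(V̂⁻¹HRH) / tr(HRH)     (H = centering projector)

after which simple-regression scores on `y⁺` approximate the exact
mixed-model scores `T_m = (g̃ᵀV̂⁻¹ỹ)²/(g̃ᵀV̂⁻¹g̃)` — exactly so for
unrelated samples — and the standard kernel pipeline applies unchanged:
beta(MAF)-density weights, χ²-mixture P values (Imhof inversion with a
moment-matched fallback) or residual-permutation P values.  A
small-N exact related-sample kernel oracle, a pedigree/genomic relationship
builder, VCF/pedigree/phenotype/GRM readers, a gene-dropping simulator and a
calibration/power study harness round out the package.

## Worked example

```r
library(famkernel)

ped <- sim_pedigree(n_families = 20, generations = 3, offspring = 2, seed = 1)
eg  <- relmat_eigen(pedigree_relmat(ped))
y   <- sim_phenotype(eg, h2 = 0.5, sigma2 = 1, seed = 2)

fit <- polygenic(y, relmat = eg)
fit
#> Polygenic mixed model (REML)
#>   n = 200, h2 = 0.4836, sigma2_g = 0.552, sigma2_e = 0.5895
#>   logLik = -289.3632
#>   fixed effects:
#> (Intercept)
#>      0.0432

yp <- transform_trait(fit, "grammar_plus")
G  <- gene_drop(ped, sim_mafs(20, seed = 3), seed = 4)
kernel_test(yp, genotype_region(G), weights = c(1, 25))
#>     Region-based weighted kernel association test
#>
#> chrom 0, positions 1-20, 17 polymorphic markers, weights beta(1,25)
#> trait presentation: grammar_plus
#> Q = 5394.7807, mixture P = 0.07514 (imhof)
```

`h2` is the REML heritability of the polygenic background; `Q` is the
weighted score sum over the region's polymorphic markers and the mixture
`P` is its tail probability under the unrelated-sample null that the
transformation makes (approximately) valid.  A null region, as here, gives
an unremarkable P value; the same pipeline on the raw `y` inflates the 5%
type I error to ≈ 0.3 in this design (see the study harness below).
Transformed traits can be written out with `write_phenotypes()` for any
external kernel software.  A thin CLI over the same functions lives at
`inst/exec/famkernel.R` (`transform`, `test`, `study` subcommands).

The methods vignette (`vignettes/famkernel-methods.Rmd`) documents the
model, the gamma-factor approximation, the weight and P-value conventions,
the simulator's scope, and known limitations.

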