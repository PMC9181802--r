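# spatialglsm

Predicting spatial expression patterns of **unmeasured genes** in
image-based spatial transcriptomics (seqFISH, STARmap, osmFISH, MERFISH)
by integrating paired single-cell RNA-seq from the same tissue.  Imaging
panels measure counts for a limited set of genes at single-cell spatial
resolution; scRNA-seq measures the whole transcriptome but loses space.
`spatialglsm` bridges the two for analysts who have both modalities and
want spatial patterns for genes outside the imaging panel.

## The model

For one gene at a time, spatial counts are modelled directly (no
normalization of the response):

```
y_i ~ Poisson(N_i * lambda_i)
log(lambda_i) = alpha + x_i * beta + g_i + e_i
g ~ MVN(0, sigma^2 h^2 K)        # spatial random effect
e ~ MVN(0, sigma^2 (1 - h^2) I)  # independent nugget (overdispersion)
```

where `N_i` is the pixel's total count (offset), `x_i` is the average
expression of the gene in the cell type mapped to pixel `i` (mapping by
Pearson correlation between pixel profiles and cell-type centers), and
`K` is a spatial kernel — Gaussian, or the conditional autoregressive
(CAR) covariance `(D - alpha_s W)^(-1)` on a pixel adjacency graph.
Fitting is penalized quasi-likelihood: Gaussian working data from a
second-order expansion, variance components by average-information REML,
fixed effects by GLS, random effects by BLUP, and a Wald test of
`H0: beta = 0`.  Genes with a significant covariate form a **reference
set**; an unmeasured target gene is predicted by applying the fitted
parameters of its most sc-correlated reference:
`log(lambda_hat) = alpha_hat + x_un * beta_hat + g_hat + e_hat`.

## Worked example

```r
library(spatialglsm)

sim <- simulate_paired_datasets(n_pixels = 400, n_genes = 100,
                                n_cells = 500, n_types = 5, seed = 1)
sim$paired
#> Paired data: 400 pixels x 100 spatial genes; 500 cells x 100 sc genes; 100 shared genes

centers    <- cell_type_centers(sim$paired$sc)
assignment <- assign_pixels(sim$paired$spatial, centers, sim$paired$shared_genes)
kernel     <- make_kernel(sim$paired$spatial$coords,
                          list(kind = "car", alpha_s = 0.5))

fit <- glsm(sim$paired$spatial$counts[, "gene001"], assignment$x[, "gene001"],
            kernel, offset = sim$paired$spatial$size_factors)
summary(fit)
#> Fixed effects:
#>       Estimate Std. Error z value Pr(>|z|)
#> alpha -8.95335    0.24263  -36.90   <2e-16 ***
#> beta   1.33526    0.07825   17.06   <2e-16 ***
#>
#> Variance components: sigma2 = 0.5106, h2 = 0 (spatial share)
#> n = 400 pixels, kernel = car (alpha_s = 0.5); converged in 7 iterations
```

`beta` is the log-scale effect of the mapped cell-type expression on the
gene's spatial rate (here strongly significant: the single-cell centers
explain this gene's pattern), `sigma2` the residual log-scale variance,
and `h2` its spatially structured share.  Hold-out validation over the
shared genes:

```r
cv <- leave_n_genes_out(sim$paired, n_test = 20,
                        kernel = list(kind = "car", alpha_s = 0.5), seed = 1)
cv
#> Leave-20-genes-out CV (seed 1): mean r = 0.319 (se 0.089), range [-0.020, 0.985], 20 scored / 0 excluded

head(cv$per_gene[order(-cv$per_gene$cor), c("gene", "cor", "reference", "ref_cor_sc")], 5)
#>      gene       cor reference ref_cor_sc
#> 8 gene043 0.9852628   gene018  0.8546843
#> 5 gene034 0.9741690   gene004  0.6256751
#> 6 gene037 0.9505202   gene012  0.8242891
#> 4 gene021 0.9500431   gene011  0.6774185
#> 1 gene001 0.8632766   gene011  0.5272189
```

Each held-out gene is scored by the Pearson correlation between its
observed and predicted counts; `ref_cor_sc` is the single-cell
correlation with the chosen reference gene.  Genes simulated with a real
covariate effect and a well-correlated reference are recovered at
`r = 0.86–0.99`; the overall mean is pulled down by the half of the genes
that are pure-noise nulls by construction.  `downsampling_experiment()`
and `kernel_sensitivity()` rerun the same split under smaller training
sets and other kernels.

A command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "spatialglsm.R", package = "spatialglsm"))')" \
    cv --spatial-counts counts.tsv --coords coords.tsv \
       --sc-counts sc_counts.tsv --cell-types cell_types.tsv \
       --kernel car --alpha-s 0.5 --n-test 20 --seed 1 --out cv.tsv
```

Subcommands: `validate`, `simulate`, `fit`, `predict`, `cv`; all outputs
are byte-deterministic given identical inputs and seeds.

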