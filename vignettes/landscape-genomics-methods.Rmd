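---
title: "Methods and design notes for individual-based landscape genomics with landgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landgen)
```

`landgen` implements an individual-based landscape genomics workflow: the
inputs are a VCF of biallelic SNPs and one sampling coordinate per
individual, and the outputs are population-structure maps, genetic-diversity
rasters, isolation-by-distance/environment models and genotype–environment
association scans. This vignette explains each model, the tunable parameters
that matter, the numerical choices made where the design was genuinely open,
and what the synthetic-data generator does and does not emulate.

## Genotype representation and preprocessing

Genotypes are stored as **dosages**: the count (0/1/2) of the ALT allele at
each biallelic SNP. We count the ALT rather than the minor allele because
the ALT label is fixed by the variant file, so dosages are stable when the
dataset is subset; minor-allele identity can flip.

**LD pruning** scans sliding windows defined in locus-index units (default
window 50 loci, step 5) and removes one locus of any retained pair whose
squared Pearson correlation exceeds the threshold (default 0.2). Windows in
index units rather than base pairs match the common
sliding-window-of-SNPs convention and keep the operation well defined for
reduced-representation data with sparse physical coverage. Which locus to
drop is not dictated by any convention we know of; we remove the one with
the lower minor-allele frequency (ties: the higher column index), on the
grounds that low-MAF loci carry less information downstream. Monomorphic
loci have undefined correlation; they are never removed on correlation
grounds and a warning points them out.

**Imputation** comes in two flavours. Per-locus median imputation rounds a
.5 median up so dosages stay integral; the rounding direction is arbitrary
and its bias is negligible at realistic missingness, but median imputation
as such will inflate downstream test statistics when missingness is not
random, which is why it is not the recommended default for association
scans. Structure-aware imputation factorizes the one-hot-encoded genotype
matrix (rank `k`, multiplicative updates, at most 200 iterations, relative
loss tolerance 1e-6) with missing cells excluded from the loss, and fills
each missing cell with the genotype class of highest reconstructed score.
It is deterministic given a seed and never alters observed cells.

## Spatially regularized ancestry estimation

Dosages divided by 2 give a matrix `X` in [0,1], which we factorize as
`X ≈ QG` with `Q` (individuals × K) on the probability simplex and `G`
(K × loci) in [0,1], interpretable as cluster allele frequencies. The loss

```
||X − QG||²_F + λ · tr(QᵀLQ)
```

adds a smoothness penalty through the graph Laplacian `L` of a Gaussian
spatial kernel on great-circle distances. The kernel bandwidth defaults to
the mean nearest-neighbour distance — the smallest scale at which the data
can express spatial structure — and `λ` defaults to 1, a mild pull that
leaves well-separated clusters untouched while stabilizing assignments of
spatially intermediate individuals. Optimization is by blockwise projected
gradient steps with step size 1/L (the gradient Lipschitz constant per
block), which guarantees a monotone loss; convergence is declared when the
relative loss change falls below 1e-6 or after 200 outer iterations.
Initialization uses k-means on principal-component scores with
deterministic farthest-point seeding, so results are reproducible and
permuting individuals merely permutes the rows of `Q`. Simplex projection
is the standard sort-based algorithm.

`select_k()` hides 5% of genotype cells (3 replicates), refits, and scores
the root-mean-square error of `2·QG` against the hidden dosages. The
automatic rule picks the elbow: the smallest K whose relative improvement
to K+1 falls below 5%. Automatic selection is intended for simulation
studies and meta-analyses; for a real dataset the cross-validation table
should be inspected manually, which is the command-line default.

Ancestry surfaces are interpolated by ordinary kriging: an empirical
variogram (12 bins to half the maximum distance) is fitted by weighted
least squares against exponential, spherical and Gaussian models, the best
model by summed squared error wins, and a failure of all three falls back
to inverse-distance weighting with a message. Kriged ancestry values are
clamped to [0,1] and renormalized across the K layers cell-wise; the
dominant-cluster map takes the arg-max with ties resolved to the lowest
cluster index.

## Moving-window diversity

Each individual is assigned to its grid cell; a window of `wdim × wdim`
cells (default 3, must be odd) pools individuals around each focal cell and
computes observed heterozygosity (fraction of dosage-1 calls), nucleotide
diversity `π` per locus as `2·c₀·c₁ / (m(m−1))` with `m` non-missing gene
copies — the unbiased pairwise-difference form, defined from two copies
upward — or allelic richness (observed allele count, 1 or 2). Windows with
fewer than `min_n` individuals (default 2) are nodata. Rarefaction uses the
hypergeometric expectation of the allele count in `g` gene copies (default
`2·min_n`); missing calls are excluded per locus before rarefying, and the
unit is gene copies (two per diploid individual) rather than individuals so
loci with partial missingness are still comparable. A companion raster
records the per-window sample count, and the same kriging/IDW machinery can
fill unobserved cells, optionally masked to the convex hull of the samples.

## Isolation by distance, environment and resistance

Distance matrices feed two regression frameworks. Genetic distances are
Euclidean over dosages, Euclidean in a truncated principal-component space,
or 1 − proportion of shared alleles; all three are valid for
individual-based sampling. Geographic distances are haversine great-circle
distances with the IUGG mean Earth radius 6371.0088 km (no reference names
a geodesic for this purpose; the haversine form is standard and the radius
choice moves distances by well under 0.5%). Resistance distances are
commute distances on the 8-connected cell graph of a user-supplied
resistance raster: edge conductance is the mean of the two cell
conductances with diagonal edges scaled by 1/√2 (the standard circuit-
theory raster convention), and `C(i,j) = vol(G)·R_eff(i,j)` comes from the
graph Laplacian. Averaging conductances rather than resistances keeps the
parallel-paths interpretation of circuit theory. Note that on a finite
uniform lattice commute distance is monotone in straight-line distance only
approximately (boundary and anisotropy effects), which is expected
behaviour, not error. Environmental distances standardize each variable to
unit variance first so that regression coefficients are comparable across
variables with incommensurate units.

**MMRR** unfolds the strict lower triangle of each matrix, standardizes to
zero mean and unit variance, and fits OLS. Because pairwise distances are
not independent, significance comes from jointly permuting rows and columns
of the response matrix (999 permutations by default) and comparing |t| per
coefficient and F for the model; `p = (#{perm ≥ obs}+1)/(n_perm+1)` never
returns zero. Backwards elimination drops the least significant predictor
above `alpha` (default 0.05) and refits until all survivors are
significant.

**GDM** models dissimilarity as `1 − exp(−η)` with
`η = a₀ + Σ_p |f_p(x_i) − f_p(x_j)|` and each `f_p` a non-negative
combination of three monotone I-splines (quadratic, knots at the minimum,
median and maximum of the predictor; geographic distance enters through
splines on the pairwise distance itself). We fit by non-negative least
squares on the link scale `η = −log(1−d)` rather than by iteratively
reweighted GLM: the NNLS formulation is a single convex problem, guarantees
the monotone non-negative structure by construction, and coincides with the
GLM solution on noiseless data; the difference on real data is a weighting
of pairs, which we accept for robustness and simplicity. Genetic distances
must be pre-scaled to [0,1] (divide by the observed maximum; `rescale_dist`
records the factor), and exact 1s are clamped to 1−1e-6 so the link is
finite. Deviance explained is computed on the link scale against the
intercept-only model; a zero response is reported as 100% trivially.
Predictor importance — not defined by any single convention in the GDM
literature — is the mean drop in deviance explained when that predictor's
site values are permuted (10 permutations, seeded). The fitted transforms
applied to raster layers, followed by a PCA of the transformed cells with
the first three components rescaled to 0–255, give the familiar RGB
turnover map; with fewer than three predictors the channels repeat.

## Genotype–environment association

**RDA** centers genotype columns, standardizes predictors, projects the
genotype matrix onto the predictor space by OLS and takes the SVD of the
fitted values; with covariates both sides are residualized first (partial
RDA). Adjusted R² uses the Ezekiel correction. Outliers are flagged two
ways: standardized axis loadings beyond `z` standard deviations (default
3), or Mahalanobis distances in the leading-axes loading space. The
Mahalanobis version uses median/MAD standardization per axis rather than a
minimum-covariance-determinant estimator: at the scale of loading matrices
this is deterministic, fast, and adequate because the axes are nearly
uncorrelated by construction. Distances are recalibrated by the genomic
inflation factor `gif = median(D²)/median(χ²_k)` before conversion to
upper-tail χ² p-values; the gif is reported so users can judge and redo the
calibration. Multiple testing uses Benjamini–Hochberg throughout. Variance
partitioning reports the full-model adjusted R², each block's independent
fraction (its partial RDA conditioned on all other blocks) and the
confounded remainder; small negative adjusted fractions are reported as
computed, as is conventional.

**LFMM** estimates `Y ≈ UVᵀ + XBᵀ` by alternating a top-K SVD of the
genotype matrix minus the current environmental component with a ridge
regression of the genotypes on the environment. Genotype columns are
standardized inside the model so the ridge penalty is comparable across
datasets; the default `lambda = 5` was chosen by calibration simulation
during development: in the near-zero-penalty limit the variance that is
confounded between environment and population structure is attributed to
the environment and the per-locus tests inflate, while a moderate penalty
shifts that confounded variance onto the latent factors and brings the
genomic inflation factor close to 1 without losing power on strongly
associated loci. Per-locus tests regress each locus on the environment plus
the estimated factors; raw p-values come from the t distribution (with
`k = 0` they equal plain per-locus OLS p-values exactly), and the default
reported p-values are gif-calibrated χ² values. Both are returned.

Four rules choose the number of latent factors: sequential Tracy–Widom
tests of the leading eigenvalues of the Patterson-normalized genotype
covariance against tabulated TW1 critical values (default alpha 0.01,
conservative); a "quick elbow" that takes the smallest K whose next
eigenvalue falls below 8% of the leading one (the elbow rule has no
standard quantitative definition, so the fraction is explicit
configuration); the clustering cross-validation above; and k-means with
BIC over principal-component scores. On data with `D` demes, values of
`D` or `D−1` are both defensible (the mean structure has rank `D−1` after
centering), and both are accepted in our recovery tests.

## Synthetic data: what it does and does not emulate

The generator draws Gaussian-random-field environmental layers
(kernel-smoothed white noise; the stated autocorrelation range is the
distance at which correlation decays to 0.05), uniform sampling coordinates,
and genotypes from a hierarchical model: ancestral frequencies
Uniform(0.1, 0.9); Balding–Nichols Beta drift per deme with
`F = deme_divergence` (demes occupy contiguous longitudinal blocks so
cluster maps have a known geography); a low-rank distance-decaying spatial
perturbation of logit frequencies (8 smooth basis fields with random locus
weights) scaled by `ibd_strength`; and for adaptive loci a logit shift of
`adaptive_effect ×` the standardized first environmental layer. Genotypes
are Binomial(2, p) — Hardy–Weinberg within locality — with frequencies
clamped to (1e-4, 1−1e-4), and missingness is completely at random.

Defaults (60 individuals, 500 loci, 2 demes, `F = 0.3`, `ibd_strength =
0.5`, 10 adaptive loci of effect 1.5, 20×20 grid, range 6 cells) describe a
modest reduced-representation dataset of a species with moderate structure.
The recovery analyses use explicit scenario settings: clustering and
imputation scenarios use `F = 0.5` (well-separated demes, 300 loci);
the association scenario uses 1000 loci with 10 loci of effect 3 on the
logit scale — a strong, sweep-like signal — and no additional continuous
IBD beyond the deme structure, matching the scenario the latent factors are
designed to absorb. Problem sizes throughout (tens of individuals, hundreds
of loci, 5 seeds for recovery medians, 200 null replicates for calibration)
are chosen so the whole suite runs on a laptop in minutes while keeping
Monte-Carlo error well inside the test margins.

What the generator does **not** emulate: linkage (loci are exchangeable, so
LD pruning is exercised only by planted duplicated columns in tests),
coalescent variance and allele-frequency spectra of real demographies,
informative missingness (the median-imputation bias it causes is therefore
not visible in our tests), selection through time, and non-equilibrium
range dynamics. Passing recovery tests demonstrates internal correctness
of the estimators under the stated model, not robustness to every feature
of real data.

## Degenerate inputs and numerical tie-breaks

Monomorphic loci: never LD-pruned, zero-variance guarded in scaling (their
z-scores are 0, never NaN). Constant environmental variables or layers are
errors wherever standardization is required. Collinearity is detected by
condition number (> 1e10) with the offending pair named. Kriging with
fewer than 5 points is refused for ancestry maps and falls back to IDW for
surface interpolation (with a warning), since a variogram cannot be fitted.
Dominant-cluster ties take the lowest cluster index; `which.max` semantics
make this deterministic. The commute-distance graph reports infinite
distances with a warning when samples occupy disconnected components.
Permutation p-values are lower-bounded at `1/(n_perm+1)`.

## Known limitations

Coordinates are always lon/lat WGS84; projected CRS support is deferred.
Interpolation operates on planar degree coordinates, adequate at study
extents of a few degrees but increasingly distorted at continental scales.
Raster I/O uses the ESRI ASCII grid format — universally readable but
uncompressed. Windows for LD pruning are index-based, not base-pair-based,
so chromosome boundaries are not respected. GDM site-pair weighting and
Bayesian LFMM variants are out of scope.
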