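---
title: "Training-set design for multi-environment genomic selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training-set design for multi-environment genomic selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metgs)
```

## The design problem

A genomic-selection program predicts the genetic merit of a large
candidate panel from a smaller phenotyped training set. In a
multi-environment trial (MET) the design space is richer than in a single
trial: each environment gets its own subset of lines, subsets may overlap,
and genotype-by-environment (G×E) interaction couples the environments.
`metgs` scores and optimizes such designs before any phenotype exists.

## Model

### Marker data and kinship

Markers are biallelic SNPs coded −1 (minor homozygote), 0 (heterozygote),
+1 (major homozygote) — the natural coding for inbred panels, where
heterozygotes are rare. Input coded as 0/1/2 allele dosages is re-oriented
per marker so that +1 is the homozygote of the more frequent allele; a
50/50 frequency tie keeps the file orientation. Files declared as −1/0/+1
are trusted as already oriented.

Columns are standardized with the sample standard deviation (denominator
n−1). This makes two identities exact, and the test suite asserts both to
1e−8: `trace(K) = n − 1` and `K 1 = 0` for `K = W W'/p`. Monomorphic
columns carry no information and are dropped with a warning rather than an
error, since the usual pipeline (MAF filter first) removes them anyway.
MAF is computed from the scores as `(2·#(−1) + #(0)) / (2n)`.

### The multi-environment mixed model

For a design S₁,…,S_T with sizes n₁,…,n_T, training phenotypes follow

y = μ + g + e,

with fixed environment means μ_j, genetic values `g ~ MVN(0, G_tr)` and
independent residuals with per-environment variances σ²_Ej. The genetic
covariance is compound-symmetric across environments: block (j,j) of
`G_tr` is σ²_{G×j}·K[S_j,S_j] and block (j,j′) is τ₀·K[S_j,S_j′]. The
per-environment genetic variance σ²_{G×j} pools the main additive variance
and the environment-specific interaction variance; only the pooled value
and the common covariance τ₀ are identifiable from MET phenotypes, so
those are what the package represents. The implied genetic correlation
between environments, ρ = τ₀/√(σ²_{G×j}σ²_{G×j′}), is exposed by
`genetic_correlation()`; ρ = 1 means no G×E.

Fixed means are never estimated explicitly in prediction: the residual
precision is replaced by the centering projection
`M_tr = blockdiag((1/σ²_Ej)(I − J/n_j))`, which annihilates
per-environment constants. The BLUPs are

g-hat = G_tr (M_tr G_tr + I)⁻¹ M_tr y,
h-hat = G_cp.tr (M_tr G_tr + I)⁻¹ M_tr y,

where `G_cp.tr` extends the training covariance to all candidates in all
environments. All flat vectors are environment-major: candidate i in
environment j sits at position (j−1)·n_cp + i. The prediction covariance

A = G_cp.tr (M_tr G_tr + I)⁻¹ M_tr G_cp.tr′

equals both Var(h-hat) and Cov(h, h-hat); the test suite verifies the
identity by Monte Carlo. A is data-free — it depends only on K, the design
and the variance components — which is what makes pre-phenotyping design
optimization possible.

## Design criteria

With `B = Ω_G ⊗ K` the candidate prior, the coefficient of determination
of one candidate-environment pair is `A(l,l)/B(l,l)`, the squared
correlation between its true and predicted genotypic value.

* `cdmean_v2()` sums this ratio over all N = T·n_cp pairs.
* `cdmean_met()` sums, over candidates, the ratio of environment-pair
  aggregates `A_i*/B_i*` — the squared correlation of environment-averaged
  values (the 1/T² averaging factors cancel).

Both are printed as sums and reported as means on request
(`report_mean = TRUE`, dividing by N or n_cp); the two forms rank designs
identically, so the optimizer uses the sum and reports typically show the
mean. For T = 1 the criteria coincide exactly.

Criterion variance components are nominal, not estimated: the defaults fix
every σ²_{G×j} and σ²_Ej at 1 and τ₀ at 0.5. CD-based ranking of designs
is insensitive to this choice; the test suite checks that rankings of
random designs under τ₀ ∈ {0.2, 0.8} and unequal-variance settings stay
rank-concordant (Spearman > 0.9) with the default.

Degenerate cases: a design whose every environment holds a single record
has zero information after centering, scores 0 and warns. Candidates with
`B(l,l) = 0` (possible only for a degenerate K) are excluded from the sum
with a warning.

## The genetic algorithm

The search space — one subset per environment — is explored by an elitist
generational GA:

| setting | default | role |
|---|---|---|
| population_size | 50 | designs per generation |
| min_iterations | 12,000 | floor before stopping rules apply |
| patience | 500 | non-improving iterations that end the run |
| elite_count | 1 | incumbents copied unchanged |
| tournament_size | 3 | selection pressure |
| mutation_rate | 0.1 | per-environment swap probability |

Crossover samples each child subset from the union of the two parents'
subsets for that environment; mutation swaps one selected index for an
unselected one. Elitism makes the best-score trace non-decreasing, and the
whole search is deterministic given the seed. The 12,000-iteration floor
is a conservative default for real panels, where the criterion landscape
has many near-optimal plateaus; the package's own tests use floors of a
few hundred iterations on small panels, which enumeration shows is already
enough to reach the global optimum there (784-design instances are checked
exhaustively).

## REML

`fit_reml()` estimates the 2T+1 components (σ²_{G×1..T}, τ₀, σ²_{E1..T})
by maximizing the restricted likelihood with fixed environment means.
Numerical choices:

* variances are optimized on the log scale;
* τ₀ = tanh(z)·√(product of the two smallest genetic variances). For
  T = 2 this cap is exactly the positive-semidefiniteness boundary of the
  genetic covariance matrix, so every proposal is feasible; an earlier cap
  at the smallest variance alone was abandoned because it pins τ₀ to a
  ridge whenever one genetic variance shrinks, stalling the optimizer. For
  T ≥ 3 an explicit eigenvalue check rejects non-PSD proposals;
* a Nelder-Mead pass from a method-of-moments start (half of each
  environment's phenotypic variance to each side, moderate positive
  correlation) is polished by BFGS; convergence is the optimizer's
  relative-tolerance criterion on the log-likelihood (default 1e−6);
* estimates falling below 1e−6 of the phenotypic variance are pinned at
  that floor and the fit is still reported (flagged, not raised);
* environment means are reported as the mean phenotype minus the mean
  training BLUP per environment.

The restricted log-likelihood itself
(`restricted_loglik()`) is exposed so users can compare fits; it was
verified against an independent contrast-space computation (identical up
to the data-independent ½·log|X′X| constant).

A caveat that matters for interpreting single-dataset estimates: with one
record per genotype-environment, genetic and residual variances separate
only through the spread of the kinship eigenvalues. On a weakly structured
panel (K close to the identity) the two are nearly confounded and REML
point estimates scatter widely even at 150 records per environment —
the restricted likelihood at the estimate still dominates the truth, but
the maximizer is far away. Family- or subpopulation-structured panels,
and designs that phenotype the same lines in several environments (which
identify τ₀ directly), are what make the components well-estimated. The
package's REML tests therefore use a family-structured panel and a
complete-overlap design.

## Simulation engine and ranking metrics

`simulate_truth()` draws genotypic values `h ~ MVN(0, Ω_G ⊗ K)` through an
eigendecomposition square root (negative eigenvalues, numerical noise of a
rank-deficient K, are clipped at zero), adds fixed means to give TBVs, and
adds independent residuals for phenotypes. Residual variances derive from
genomic heritability as σ²_E = σ²_G(1−h²)/h² when not given directly.
Replicate r uses seed `master_seed + r`, so any replicate is reproducible
in isolation.

`run_experiment()` evaluates named designs over replicates: training
records are extracted per design, candidate values predicted (true
variance components by default; per-replicate REML on request, with a
known-truth fallback counted on non-convergence), and rankings scored in
each environment plus the "overall" context (environment-averaged TBV vs
environment-averaged prediction). Environment means are constants within a
context and cannot change a ranking, so predicted values omit them; TBVs
retain them because NDCG gains are TBVs.

Metrics at k = ⌊0.05·n_cp⌋ (at least 1):

* **NDCG@k** — discounted gain ratio with linear gain f(v) = v and
  discount 1/log2(i+1). Gains must be positive; with means like 100–200
  and genetic variances ≤ 30 this holds essentially always, but a guard
  shifts all gains by 1 − min(TBV) (with a warning) if not.
* **SRC@k** — Pearson correlation of (i, π_i), i ≤ k, where π is the
  permutation mapping predicted positions to true ranks. Needs k ≥ 2 and
  is reported NA at k = 1.
* **RS_ratio@k** — ideal rank sum over achieved rank sum; equal to 1
  exactly when the predicted top-k set is the true top-k set.

Ties in either ranking break by ascending candidate index — an arbitrary
but deterministic rule that the metrics need for reproducibility.

Because NDCG mixes the large environment means into its gains, its
replicate-to-replicate spread is much smaller than that of the rank-based
metrics; the test suite asserts this qualitative ordering.

## The synthetic panel generator

`simulate_marker_matrix()` stands in for real genotype panels so that
everything runs offline. Per marker, an ancestral minor-allele frequency
is uniform on `maf_range` (default 0.05–0.5); with subpopulations,
per-subpopulation frequencies follow a Balding–Nichols Beta around the
ancestral value with differentiation `fst`; genotypes are drawn with
heterozygosity at 5% of its Hardy–Weinberg expectation, emulating inbred
elite lines, and each marker is oriented to the major allele after the
draw.

What it does and does not emulate: it reproduces allele-frequency spectra,
population structure and inbreeding — the features that drive kinship
structure and hence criterion behaviour. It has no linkage disequilibrium,
no chromosomes, no selection history and no pedigree beyond the
subpopulation blocks. Tests passing on these panels therefore validate
the algebra and the optimizer on realistic kinship spectra, not the
biology of any particular crop panel.

## Problem sizes used in the tests

The package's own evaluation runs at desk scale, chosen so the full suite
completes in minutes: Monte-Carlo verification of the prediction
covariance and the CD criteria on an 8-line, 2-environment instance with
200,000 replicates; exhaustive-enumeration checks of the GA on 784-design
instances; REML recovery on a 300-line family-structured panel with 150
lines per environment; and the optimized-versus-random comparison on a
120-line panel with 30 lines per environment, 100 replicates, across
genetic correlations 0.707, 0.5 and 0.408. A full-size study (panels of
several hundred lines, 2,000 REML replicates per scenario, 12,000-iteration
GA floors) uses the same functions with larger settings.

## Known limitations

* The genetic covariance across environments is compound-symmetric; an
  unstructured or factor-analytic Ω_G, dominance and epistasis terms, and
  heterogeneous genetic architectures are out of scope.
* No block, row-column or spatial field effects: phenotypes are assumed to
  be adjusted means.
* Optimization is untargeted — the criteria integrate over the whole
  candidate panel rather than a named testing set.
* The GA is a local search; the enumeration guarantee exists only at toy
  sizes. Longer floors and multiple seeds are the practical safeguard.
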