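# eigenphase

SVD eigen-phase synthesis of multi-omics time courses from oscillatory
biological systems, built around the yeast metabolic cycle (YMC): the
periodic oscillation of oxygen consumption, transcripts, histone
modifications and metabolites in continuous yeast culture.

## The problem and the approach

Time-course omics experiments on the YMC produce one molecule-by-sample
matrix per assay — transcriptome, per-mark histone ChIP signal, metabolome
— each sampled on its own clock, over one to three cycles. This package
implements a synthesis of such datasets in four stages:

1. **Stratification.** Each log-scale matrix `A` (m molecules × n samples)
   is decomposed by SVD, `A = Σ_k λ_k u_k v_kᵀ`, into ranked
   eigen-components ("levels"). After normalization, the level with the
   largest singular value has nearly constant sample loadings,
   `v_0 ≈ (1/√n) 1`, and carries the per-molecule average
   `λ_0 u_0 ≈ √n μ`; it is indexed 0 and treated as the baseline. For
   k ≥ 1, `λ_k²` is the variance of `Ā = A − λ_0 u_0 v_0ᵀ` along `v_k`,
   `Σ_{k≥1} λ_k² = ‖Ā‖²_F`, and the ratios `p_k = λ_k²/Σλ_k²` give each
   level's relative contribution. The Shannon entropy of the `p_k`
   ("eigen-entropy") measures how concentrated the variance is.

2. **Eigen-phases.** The signs of the sample loadings at the top two
   levels define four overlapping half-cycle windows — eigen-phases 1A/1B
   (level 1) and 2A/2B (level 2) — which cycle in the order
   1B → 2A → 1A → 2B. Each molecule's cyclic signal decomposes as
   `a(i,t) = μ(i) + λ₁u₁(i)·v₁(t−τ) + λ₂u₂(i)·v₂(t−τ) + ε(i,t)`,
   with a per-dataset time lag τ.

3. **Timeline and lags.** Datasets are placed on a unified timeline by
   derivative dynamic time warping (DDTW) of their dissolved-oxygen
   indicator curves; inter-omics time differences
   `Δτ(l₁,l₂) = τ(l₁) − τ(l₂)` are then estimated as the lag of maximum
   cross-correlation between natural-spline-resampled (0.001 h grid)
   sample-eigenvector loading curves, averaged over levels 1 and 2, with
   95% confidence intervals from Gaussian perturbations (sd = 10% of each
   series' sd).

4. **Interpretation.** Molecule-eigenvectors are read as weighted
   differential profiles: gene sets are scored by Wilcoxon rank-sum
   enrichment per pole (BH-adjusted), marker molecules by a randomization
   null built from random unit sample-vectors orthogonal to the leading
   eigenvectors (`u_kʳ = A v_kʳ/‖A v_kʳ‖`, sign-split p-values with a +1
   correction), and a signal matrix's contribution to each eigen-phase by
   the bilinear forms `u_k^±ᵀ A v_k^±` with the normalized non-negative
   eigenvector parts as weights, summarized by their CV.

A synthetic-data module generates multi-omics studies obeying exactly this
decomposition model — planted baselines, orthonormal molecule-eigenvector
shapes, quadrature periodic functions, per-omics lags, calibrated noise,
oxygen curves with optional clock distortions, and a marker block — so
every stage is validated by parameter recovery without any downloads.

## Worked example

```r
library(eigenphase)

truth <- generate_truth(seed = 1)          # planted ground truth
set.seed(10001)
study <- simulate_study(truth)             # three omics + oxygen curves

dec <- stratify(study$matrices$transcriptome)
relative_contributions(dec)$top2
#>         1
#> 0.5655935
call_phases(dec)
#> <phase_calls> 48 samples; cyclic order: 1A -> 2A -> 1B -> 2B

est <- estimate_pair_lag(stratify(study$matrices$epigenome), dec,
                         max_lag = 1.5)
est
#> <lag_estimate> epigenome vs transcriptome: lag = -0.0530 h (-3.18 min), mean |rho*| = 0.998
#>  level    lag       rho flipped
#>      1 -0.051 0.9990439   FALSE
#>      2 -0.055 0.9965449   FALSE
```

The top two levels carry ~57% of the non-baseline transcriptome variance;
the four eigen-phases cycle in the planted order (the A/B letters are a
label convention — see the methods vignette); and the epigenome is
estimated to run ~3.2 min ahead of the transcriptome, recovering the
planted 3-min lag. The printed cyclic order `1A -> 2A -> 1B -> 2B` is the
same cycle as `1B, 2A, 1A, 2B` after the arbitrary level-1 sign flip.

The `analysis/` directory holds the same workflow as numbered scripts
(simulate → decompose → align → lags → interpret), each writing its tables
under `results/`:

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_decompose.R
Rscript analysis/03_align.R
Rscript analysis/04_lags.R 1
Rscript analysis/05_interpret.R 1
```

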