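---
title: "Information dynamics of EEG cortical sources: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information dynamics of EEG cortical sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eeginfodyn)
```

## The problem

Scalp EEG electrodes do not observe cortical sources directly: each
electrode records a near-instantaneous superposition of several sources
(volume conduction). Any lag-based directed-connectivity measure applied
straight to the scalp channels therefore mixes genuine time-lagged
interactions with purely instantaneous cross-talk, and routinely reports
directed links between channels whose underlying sources do not interact at
all. `eeginfodyn` implements a two-class source-level analysis that models
both effects jointly and computes linear-Gaussian information dynamics —
information storage, information transfer, and statistically significant
directed links — at the level of the reconstructed sources.

## Model

The scalp process is modeled as an instantaneous linear mixture
`x_n = M s_n` of `Q` cortical sources, and the sources as a stable VAR(p)

    s_n = sum_{k=1..p} B_k s_{n-k} + e_n,

with independent, non-Gaussian (super-Gaussian) innovations `e_n` with
diagonal covariance. Non-Gaussianity is what makes the instantaneous mixing
identifiable by ICA; the VAR part captures every time-lagged dependency so
that the fitted residuals carry only the zero-lag mixing.

Estimation proceeds in seven steps, all exposed as package functions:

1. **CSP** (`class_covariances`, `csp_filters`, `select_filters`):
   trace-normalized class covariance matrices are jointly diagonalized by
   the generalized eigenproblem `P_h1 c = lambda (P_h1 + P_h2) c`. Filters
   are ranked by their fractional contribution
   `delta_j = ln^2(lambda_j/(1-lambda_j)) / sum_i ln^2(lambda_i/(1-lambda_i))`
   to the affine-invariant Riemannian distance between the two class
   covariances, and the smallest prefix covering a set fraction of the
   total distance (default 90%) is retained. The squared *natural*
   logarithm is used: it is the metric under which the distance between two
   SPD matrices decomposes over generalized eigenvalues; a base-2 logarithm
   would only rescale every `delta_j` by the same constant and leave the
   fractions unchanged, so the choice is inconsequential for selection but
   is stated here for definiteness.
2. **VAR on the reduced components** (`select_order`, `fit_var`): per-trial
   multivariate least squares `A-hat = Y Z'(Z Z')^-1`; order chosen by the
   Schwarz Bayesian Criterion `ln det(Sigma_p) + p Q^2 ln(n')/n'` evaluated
   on a common effective sample so all candidate orders see identical data.
   Residual whiteness is checked with the multivariate Li–McLeod
   portmanteau statistic (chi-square with `Q^2 (h - p)` df; default lag
   budget `h = 20`).
3. **ICA on the residuals** (`concatenate_residuals`, `estimate_ica`):
   residual blocks of all trials and both classes are concatenated
   (stationary-mixing assumption) and decomposed by a natural-gradient
   Infomax ICA (logistic nonlinearity, suited to super-Gaussian sources).
   Because the objective is non-convex, the algorithm restarts from 10
   seeded random orthogonal initializations and keeps the run whose
   components have the largest mean absolute excess kurtosis; a
   near-Gaussian warning is raised when all component kurtoses are within
   0.1 of zero, where the mixing is not identifiable.
4. **Unmixing** (`assemble_unmixing`, `reconstruct_sources`):
   `U = W^-1 C` maps scalp signals to sources, `s = U x`.
5. **Source-domain parameters** (`transform_parameters`):
   `B_k = W^-1 A_k W`, `Sigma_e = W^-1 Sigma_r W^-T` — an exact similarity
   transform, so no second model fit is needed and the eigen-spectrum of
   the dynamics is preserved.
6. **Inverse Yule–Walker solution** (`yule_walker_inverse`): the lag
   covariances `Gamma_0..Gamma_{p-1}` solve a discrete-time Lyapunov
   equation on the companion form (solved by vectorization for state
   dimension up to 70, by Smith doubling beyond), and
   `Gamma_k = sum_l B_l Gamma_{k-l}` extends the sequence to the sub-model
   lag `q` (default 10).
7. **Information measures** (`partial_variance`, `information_measures`):
   partial variances are Schur complements of the stacked lag-covariance
   matrix, and

        S_j       = 1/2 ln(Sigma_j / Sigma_j|j)
        T_j       = 1/2 ln(Sigma_j|j / Sigma_j|ijk)
        T_i->j|k  = 1/2 ln(Sigma_j|jk / Sigma_j|ijk)

   in nats. Each ordered pair is tested with the F statistic of the nested
   regressions, `F = ((Sigma_j|jk - Sigma_j|ijk)/q) /
   (Sigma_j|ijk/(N_eff - Q q))` with `(q, N_eff - Q q)` degrees of freedom.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `csp_coverage` | 0.90 | fraction of the Riemannian distance retained filters must cover; 1.0 disables pruning |
| `p_min`, `p_max` | 1, 10 | SBC candidate order range |
| `q` | 10 | past lags in the information sub-models |
| `alpha` | 0.05 | level of the link F-test |
| `ica_restarts` | 10 | seeded Infomax restarts |
| `whiteness_h` | 20 | Li–McLeod lag budget |
| `ftest_n` | "n-p" | effective sample for the F-test denominator |

Two of these deserve comment.

**Effective sample size.** The F-test denominator uses `N - p` (the samples
actually entering the regression) rather than `N`; both are supported via
`ftest_n` because the distinction is below resolution for typical `N` but
matters in principle.

**Sub-model lag `q` versus fitted order `p`.** The partial variances are
computed from the covariance sequence *implied by the fitted model*, so
only `p` of the `q` lags of an ordered pair carry estimated cross
coefficients. When `q > p` the F statistic spreads at most `p` degrees of
estimation noise over `q` numerator degrees of freedom and the link test
becomes conservative (empirical null rejection near 0 at `q = 10`,
`p = 2`); when `q = p` it is exactly calibrated (empirical rate 0.049 at
the 0.05 level over 10,000 null pairs). Recommendation: keep `q` at or
below the fitted order for calibrated link counts; the default `q = 10`
reflects typical EEG orders of 25–30, where the condition holds
automatically. Conservativeness does not impair detection of strong
couplings: the simulated causal chain below is recovered at `q = 10` in
every trial.

## The synthetic benchmark

`generate_dataset()` builds the two-condition study used throughout the
tests: five sources, VAR(2) at 125 Hz, 10 trials of 1000 samples per
condition. Diagonal AR(2) blocks place complex-conjugate poles at
`2 rho cos(2 pi f/fs)` and `-rho^2`; condition 1 has autonomous alpha
rhythms (10 Hz) on sources 1, 4, 5 and beta rhythms (23 Hz) on 2, 3, with
no coupling; condition 2 has alpha on source 1, beta elsewhere, and a
causal chain `s1 -> s2 -> s3 -> s4 -> s5` with lag-1 coefficients 0.5.
Innovations are super-Gaussian (`sign(w)|w|^g`, `g ~ U[1.2, 2]`, rescaled
analytically to unit variance), and the sources are mixed by a symmetric
tridiagonal matrix (1 on the diagonal, 0.5 off) spreading each source over
two or three electrodes.

Values the design leaves open were fixed once: pole radii
`rho_alpha = 0.9` (narrowband) and `rho_beta = 0.7` (broadband), which give
clearly peaked versus damped spectra at the stated center frequencies;
identity innovation variances; and full filter retention
(`csp_coverage = 1`) in the square `D = Q = 5` benchmark, where pruning is
not the object of study. `theoretical_measures()` returns the exact
measures implied by the true parameters — the ground truth against which
estimates are judged.

What the generator does *not* emulate: measurement noise on the
electrodes, non-stationarity within or across trials, artifacts, more
sources than channels, and realistic head-volume forward models. Passing
the benchmark therefore demonstrates correctness of the estimation
machinery under the model's own assumptions, not robustness to their
violation on clinical recordings.

```{r benchmark, eval = FALSE}
sim <- generate_dataset(seed = 0)
cfg <- analysis_config(csp_coverage = 1, p_min = 1, p_max = 5, seed = 0)
src <- run_source_analysis(sim$dataset, cfg)
head(src$summary)
```

## Numerical choices

* **Eigenvalue clamping.** CSP eigenvalues are clamped to
  `[1e-9, 1 - 1e-9]` before the log-odds distances; exactly
  indiscriminable classes (all log-odds below 1e-5 in magnitude, i.e.
  eigenvalues within 2.5e-6 of 0.5) raise a degenerate-classes error.
* **Ridge.** `gamma tr(P)/D I` with `gamma = 1e-8` is added to
  `P_h1 + P_h2` before the eigensolve; configurable, and zero is accepted
  when the sum is known to be well-conditioned.
* **Ties.** Equal fractional distances are broken by ascending original
  filter index, making pruning deterministic.
* **ICA convergence.** The natural-gradient iteration adapts its step size
  (gentle growth while the gradient norm shrinks, back-off when it grows)
  and declares non-convergence above a 1e-4 gradient norm; a restart that
  fails is simply dropped. Scale/sign indeterminacy is fixed by unit-norm
  mixing columns with positive dominant entry, which makes same-seed runs
  bit-identical. The information measures themselves are invariant to any
  positive rescaling of the sources.
* **Covariance divisor.** Residual covariances divide by `N - p`
  (switchable to the per-equation-corrected `N - p - pQ`).
* **Partial-variance jitter.** A near-singular regressor covariance gets a
  symmetric jitter of `1e-10 tr/dim` once; condition numbers above 1e10
  raise instead of silently regularizing.
* **Negative measures.** Log-ratios within `-1e-10` of zero are clipped to
  0; anything more negative signals an inconsistent covariance sequence
  and raises.
* **Common VAR order.** Within a source run the order is the maximum of the
  per-trial SBC picks, so all residual blocks entering the pooled ICA have
  the same structure.

## Problem sizes used in the validation suite

The test suite exercises the full pipeline on the 10-trials-per-condition,
1000-sample benchmark; oracle equivalence compares the analytic measures
with explicit least-squares regressions on a single 10^6-sample
realization; null calibration of the link F-test uses 500 simulated
uncoupled trials (10,000 ordered pairs) and the Li–McLeod null uses 500
white-noise draws. These sizes give Monte-Carlo standard errors comfortably
inside the asserted bands while keeping a full run under a minute.

## Known limitations

* The VAR/ICA decomposition assumes stationary mixing across trials and
  conditions; slowly varying volume conduction violates it.
* Gaussian (or near-Gaussian) residuals make the mixing unidentifiable;
  the package warns but cannot fix this.
* Source labels are arbitrary across runs (ICA permutation); network
  results are therefore summarized as node averages, or matched to a
  reference by `match_sources()` when one exists (as in simulation).
* Linear-Gaussian information measures capture only second-order
  structure; nonlinear coupling is invisible to them.
* Real-data input is delimited-text matrices plus a JSON manifest; EDF
  files must be converted upstream.
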