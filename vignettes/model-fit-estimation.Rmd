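---
title: "Estimating Bayesian model fit: cross-validation, wAIC and sequential importance sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating Bayesian model fit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Given `n` exchangeable observations `X = (X_1, ..., X_n)` (in phylogenetics,
the columns of a protein alignment) and a Bayesian model with parameter
`theta`, prior `p(theta)` and likelihood `p(X | theta)`, how well does the
model fit — and which of several candidate models fits best?  Two families of
answers coexist:

* **Marginal likelihoods / Bayes factors.**  The per-site log marginal
  likelihood `m = (1/n) ln p(X)` integrates the likelihood over the prior.
  It penalizes a model by the *total* work of moving from prior to
  posterior, which makes it acutely sensitive to the width of vague priors
  (the Jeffreys–Lindley effect): widening a prior that has virtually no
  effect on the posterior can reverse a model choice.
* **Predictive scores.**  Cross-validation (CV) and the widely applicable
  information criterion (wAIC) score the model by how well the posterior
  predicts *new* observations.  They depend on the prior only through the
  posterior, and track estimation accuracy.

All of these are special cases of one quantity: the expected predictive fit
`C(q, r) = (1/r) E[ln p(Y_r | Y_q)]` of a training set of size `q` on an
independent validation set of size `r`.  Joint k-fold CV estimates
`C((1-f)n, fn)`, site-wise k-fold CV estimates `C((1-f)n, 1)`, leave-one-out
CV (LOO-CV) estimates `C(n-1, 1)`, the wAIC targets `C(n, 1)`, and the
per-site log marginal likelihood is `C(0, n)`.  This package implements the
Monte Carlo estimators of all of them, their diagnostics and bias
corrections, an exactly solvable multivariate-normal testbed on which every
estimator can be checked against closed-form truth, and a minimal
fixed-topology amino-acid phylogenetic model on which they can be exercised
in their natural habitat.

# Estimators

All estimators consume a **site log-likelihood matrix** (`bcv_sitell`):
entry `(i, t)` is `ln p(X_i | theta_t)` for posterior draw `theta_t`.

* `cv_joint()` — naive importance sampling (nIS) for joint k-fold CV:
  per replicate, `ln` of the arithmetic mean over draws of the *joint*
  validation likelihood.  Its importance weights degenerate when the
  validation likelihood is much more peaked than the training posterior —
  which is exactly what happens in high dimension; the per-replicate joint
  effective sample size (ESS) is reported as the warning signal.
* `cv_sitewise()` — the same posterior average done independently per
  validation item.  Single-observation likelihoods are far flatter, so the
  weights behave and the estimator is stable.
* `loo_cpo()` — LOO-CV via cross-predictive ordinates: the harmonic-mean
  identity `1/p(X_i|X_(i)) = E_post[1/p(X_i|theta)]` turns a single
  full-data posterior sample into all `n` leave-one-out scores.
* `loo_pareto_smoothed()` — the stabilized variant: per site, a generalized
  Pareto distribution is fitted to the top 20% of the inverse-likelihood
  weights (empirical-Bayes profile fit, posterior-mean shape) and those tail
  weights are replaced by expected order statistics of the fit.  The fitted
  shape `kappa-hat` flags unreliable sites at `kappa-hat > 0.7`; a
  degenerate constant tail reports `kappa-hat = 0` and no smoothing.
* `waic()` — per site, `ln E_post[p(X_i|theta)] - V_post[ln p(X_i|theta)]`
  (unbiased sample variance, so two draws suffice formally), reported per
  observation, higher is better; the variance penalty is returned separately.
* `two_step_cv()` — site-wise CV with training on an *independent* dataset
  of equal size: a direct, numerically stable estimator of `C(n, 1)` with a
  bias of opposite sign to CPO, useful as a cross-check when a large data
  pool is available.
* `sis_run()` / `sis_marginal()` / `sis_kfold()` — sequential importance
  sampling (sIS): the marginal likelihood telescopes into one-observation
  conditionals `p(X_i | X_1:i-1)`, each estimated by averaging the next
  item's likelihood over a short MCMC run under the current partial
  posterior.  Summing all increments gives `ln p(X)`; summing the last
  `r = fn` increments of a permuted run gives the joint k-fold score, and
  every `f <= 1/2` can be read off the same run.

## The reference bridge

The early sIS steps sample near the prior, where the increments have high
variance.  A normalized reference family `p_eps` interpolates between a
distribution fitted to a preliminary posterior sample (`eps = 0`) and the
prior (`eps = 1`) on the schedule `eps_i = min(1, 2(i-1)/n)`, reaching the
prior halfway so that every k-fold validation segment lies under the
original prior.  We use geometric bridges of exponential-family fits, which
stay normalized and evaluable for every `eps`: a moment-matched Gaussian for
the normal model, and a product of moment-matched Dirichlet (frequencies,
exchangeabilities) and gamma (branch lengths) distributions for the
phylogenetic model.  Each increment includes the density-ratio correction
`p_{eps_{i+1}}(theta)/p_{eps_i}(theta)`; without it the telescoped product
is not the marginal likelihood.  This identity is verified against the
normal model's closed-form marginal in the test suite.  With an improper
prior the marginal likelihood is infinite and `sis_run()` refuses to run
with the reference disabled.

## Diagnostics, quality thresholds and bias correction

ESS is Kong's `(sum w)^2 / sum(w^2)` on self-normalized weights.  A site is
*bad* when its ESS is at most 10 or its `kappa-hat` exceeds 0.7.  The
verdict is **good** when the mean ESS across sites is at least 500 and at
most 5% of sites are bad, **reasonable** at mean ESS at least 50 and at most
10% bad, **fail** otherwise.

Every estimator log-transforms an unbiased likelihood average, which biases
the score: downward for arithmetic means (nIS, sIS, the wAIC self-fit),
upward for the harmonic-mean CPO.  When the Monte Carlo variance is small,
the absolute bias is approximately half the variance of the estimated
per-site log score, which two independent runs estimate as
`(a_i - b_i)^2 / 2` per site (`bias_correct()`, `debias_fits()`).  Two
caveats are deliberate design choices:

* joint k-fold CV reports no bias estimate — its variance is far too large
  for the two-run estimate to mean anything;
* the half-variance rule assumes the between-run variance comes from
  likelihood-scale averaging noise.  With short, slowly mixing chains (e.g.
  a 190-dimensional GTR exchangeability walk at a few hundred cycles) the
  between-run variance is dominated by chain-level noise that is additive on
  the log scale, and the rule then *over*-corrects.  The asymptotic
  agreement check between LOO-CV and wAIC in the test suite therefore uses
  raw same-matrix scores, whose shared Monte Carlo noise largely cancels in
  the difference.

# The normal testbed

Observations are i.i.d. `N_p(theta*, sigma^2 I)`.  M1 fixes the mean at
`theta0 = 0`; M2 places a `N(0, delta^2 I)` prior on it.  Everything
factorizes over coordinates and every expected score has a closed form
built from one function: `g(m)`, the expected log predictive density of one
new observation after training on `m` observations, with
`C(q, r) = (1/r) * sum_{j=q}^{q+r-1} g(j)` because the log joint predictive
telescopes into one-observation conditionals.  `analytic_fit()` evaluates
these exactly; `realized_scores()` conditions on an actual simulated dataset
(the per-dataset truth used to benchmark the estimators); `asymptotic_fit()`
implements the first-order expansions (the Bayes-factor penalty decays as
`ln(n)/n` with a `-2 ln(delta^2/sigma^2)` prior-width term, the CV penalties
as `1/n` with prefactors `1/(1-f)` for site-wise and `|ln(1-f)|/f` for joint
k-fold, and LOO-CV equals the relative quadratic risk to first order);
`crossover()` bisects the exact curves for the smallest `n` at which M2
overtakes M1.  The closed forms were derived from conjugate Gaussian
identities and are validated in the tests against brute-force quadrature
(one-dimensional posterior and predictive integrals) and against Monte
Carlo averages over thousands of simulated dataset pairs — the oracle chain
the estimator checks rest on.

Under the paper-style conditions (`p = 300`, `sigma^2 = 10`,
`theta* = 0.1`), the exact curves place the accuracy tipping point at
`n = 1000` while Bayes factors only switch to M2 near `n = 8000`
(`delta^2 = 10`) or beyond `n = 10000` (`delta^2 = 1000`) — inside that
window the model chosen by the Bayes factor is up to several times less
accurate, and the CV crossovers sit at the tipping point regardless of
`delta^2`.

# The phylogenetic model

A deliberately minimal, fully i.i.d. fixed-topology model: amino-acid
substitution with `Q_ab ∝ rho_ab * pi_b` normalized to one expected
substitution per unit branch length; Poisson (equal exchangeabilities),
empirical (LG/WAG/JTT shipped in PAML layout and parsed by
`read_paml_matrix()`), and GTR (uniform Dirichlet prior on the 190
renormalized exchangeabilities) variants; pruning likelihood with
conditional scaling (gaps and unknowns marginalized); and a
Metropolis–Hastings sampler whose cycle sweeps multiplicative branch-length
proposals (i.i.d. exponential prior, mean 0.1) and Dirichlet-walk plus
pair-transfer proposals on the simplex parameters.  Matrix exponentials use
the symmetric eigendecomposition of `diag(pi)^{1/2} Q diag(pi)^{-1/2}`,
cached per draw.  Amino acids follow the PAML order everywhere.

Design choices worth knowing:

* No rate-across-sites heterogeneity: a uniform-rate model keeps the
  observation-level i.i.d. structure that all the estimators assume.
* Empirical-matrix models fix both `rho` and `pi` from the file by default
  (`free_pi = TRUE` frees the frequencies under a uniform Dirichlet prior).
* Proposal scales are fixed defaults tuned for moderate acceptance on small
  trees (roughly 20–65% in the shipped settings), not adaptive.
* The MCMC is a compact R implementation meant for the moderate problem
  sizes of the validation experiments (up to ~6 taxa and a few thousand
  sites), not a general-purpose phylogenetic engine: topology is fixed and
  mixing over the 190-simplex is slow, so GTR runs use longer thinning.

# What the synthetic data do and do not show

The generators simulate exactly the processes the models assume: spherical
Gaussian vectors, and alignments evolved site-independently under a
reversible substitution model on a fixed tree (`simulate_alignment()` draws
the root from the stationary frequencies and evolves along branches).  They
emulate the dimensional structure that breaks naive importance sampling and
the data-size scaling that drives every asymptotic statement.  They do not
emulate real alignments: no rate heterogeneity across sites, no
site-specific amino-acid preferences, no alignment error, no non-stationary
composition.  Passing tests therefore validate the *estimators* (against
exact oracles) and the qualitative orderings the theory predicts, not any
claim about empirical datasets.

# Numerical choices

* `log_mean_exp()` uses a max shift; ESS is computed on shifted weights.
* The generalized-Pareto tail fit is the empirical-Bayes profile method
  (location at the 20% tail threshold, shape by posterior mean over a
  profile grid), robust at tail sizes of ~0.2T and requiring `T >= 25`;
  a constant tail short-circuits to `kappa-hat = 0`.
* k-fold splits use `r = round(f n)` floored at 1; replicates are
  independent random splits (not a systematic rotation), unstratified.
  A single global seed expands to per-replicate seeds by a counter-based
  derivation, so runs are reproducible end to end.
* `crossover()` returns the smallest integer `n` with a positive difference
  (bisection to a width of 1) and `NA` with a warning when there is no sign
  change in the range.
* Adaptive sIS step lengths: `T_i = clamp(ceil(var_pilot / target_se^2),
  T, 100T)`, so constant sites get the floor and difficult sites more
  cycles.

# Problem sizes used in the shipped checks

The validation experiments are sized for a single CPU: oracle-equivalence
runs use `p in {3, 10}`, `n in {100, 1000}`, `T = 10^4` draws; the
high-dimensional failure mode of joint-k-fold nIS is demonstrated at
`p = 2000`, `n = 1200`, `f = 0.5`, with the nIS draw count matched to the
total sIS cycle budget (`T = 24000`); the LOO-CV/wAIC convergence experiment
uses one LG-simulated 6-taxon alignment subsampled to
`{200, 1000, 5000}` sites with `T = 100` saved draws (thinning 2 for
Poisson, 6 for GTR).  These choices are stated here because they are the
package's own study conditions; all of them can be scaled up by the user.

# Known limitations

* The wAIC's variance penalty and the CPO weights come from the same draws;
  at very small `T` both estimators are noisy and only the two-run debiased
  versions should be compared across models.
* The bias rule's small-variance assumption (above) makes debiasing
  counterproductive for poorly mixing chains; check acceptance rates and
  ESS first.
* sIS with the MCMC kernel re-equilibrates from the previous step's state;
  for strongly multimodal posteriors the quasi-static assumption (a few
  cycles per added observation) can fail silently — the between-permutation
  spread of `sis_marginal()` is the practical diagnostic.
* The phylogenetic model deliberately omits the site-heterogeneous mixture
  models whose comparison motivates these tools in practice; it is the
  minimal i.i.d. model sufficient to exercise every estimator.
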