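# Sequential importance sampling (sIS) over data points.
#
# The marginal likelihood telescopes into one-observation conditionals,
# p(X_1:n) = prod_i p(X_i | X_1:i-1); each factor is estimated by averaging
# the next item's likelihood over draws from the current partial posterior,
# along a quasi-static run that adds items one at a time.  A normalized
# reference family p_eps bridging a fitted posterior approximation (eps = 0)
# to the prior (eps = 1) over the first half of the items reduces the
# variance of the early, prior-dominated steps; each increment then carries
# the correction factor p_{eps_{i+1}}/p_{eps_i} so the telescoped product
# still equals the marginal likelihood.  Summing the last r increments of a
# permuted run gives the joint k-fold CV score.

#' Configuration of a sequential importance sampling run
#'
#' @param B burn-in cycles per step (>= 0).
#' @param T baseline sampling cycles per step (>= 1); with `adaptive = TRUE`
#'   this is the per-step floor.
#' @param adaptive tune the number of cycles per step from a pilot variance
#'   estimate (see [tune_step_cycles()]).
#' @param pilot_T pilot cycles used for the variance probe.
#' @param target_se desired per-step Monte Carlo standard error (> 0).
#' @param permutation_seed seed for the item permutation.
#' @param use_reference enable the reference-distribution bridge.
#' @return Object of class `bcv_sis_config`.
#' @export
sis_config <- function(B = 3L, T = 10L, adaptive = FALSE, pilot_T = 10L,
                       target_se = 0.1, permutation_seed = 1L,
                       use_reference = TRUE) {
  stopifnot(B >= 0L, T >= 1L, target_se > 0)
  structure(list(B = as.integer(B), T = as.integer(T), adaptive = adaptive,
                 pilot_T = as.integer(pilot_T), target_se = target_se,
                 permutation_seed = as.integer(permutation_seed),
                 use_reference = use_reference),
            class = "bcv_sis_config")
}

#' Epsilon schedule of the reference bridge
#'
#' `eps_i = min(1, 2(i-1)/n)`: the bridge starts at the fitted posterior
#' approximation, reaches the prior midway and stays there, so every
#' validation segment of a k-fold score (training fraction >= 1/2) lies
#' entirely under the original prior.  With the reference disabled the
#' schedule is identically 1.
#'
#' @param n number of items.
#' @param use_reference logical.
#' @return Numeric vector of length `n + 1` (the final entry, used by the
#'   last step's correction factor, is always 1).
#' @export
eps_schedule <- function(n, use_reference = TRUE) {
  if (!use_reference) return(rep(1, n + 1L))
  c(pmin(1, 2 * (seq_len(n) - 1L) / n), 1)
}

#' Per-step cycle count from a pilot variance estimate
#'
#' `T_i = clamp(ceil(pilot_variance / target_se^2), T_min, 100 * T_min)`
#' with `T_min = config$T`: low-variance items (e.g. constant alignment
#' columns) get the floor, high-variance items get more cycles.
#'
#' @param pilot_variance nonnegative pilot estimate of the variance of the
#'   per-step log term.
#' @param config a [sis_config()].
#' @return Integer cycle count.
#' @export
tune_step_cycles <- function(pilot_variance, config) {
  stopifnot(pilot_variance >= 0)
  T_min <- config$T
  as.integer(min(max(ceiling(pilot_variance / config$target_se^2), T_min),
                 100L * T_min))
}

#' Run sequential importance sampling
#'
#' Adds the items of `data` one at a time in a random permutation; at step
#' `i` the model's kernel equilibrates for `B` cycles and yields `T_i` states
#' under the partial target `p(X_1:i-1 | theta) * p_{eps_i}(theta)`, and the
#' step increment is recorded as
#' `ln R_i = ln (1/T) sum_t p(X_{(i)} | theta_t) * p_{eps_{i+1}}(theta_t) / p_{eps_i}(theta_t)`
#' (the density ratio is 1 when eps does not change or the reference is
#' disabled).
#'
#' The model must be a [bcv_sampler()] extended with a `sis_kernel` function
#' `(prefix_ids, epsilon, n_cycles, seed, state)` returning
#' `list(states = <list of states>, state = <last state>)` whose chain leaves
#' the partial target invariant, and — when the reference is enabled — a
#' `log_ref(state, eps)` function evaluating the normalized bridge density.
#' [normal_sis_model()] and [phylo_sis_model()] build such objects.
#'
#' @param model sIS-capable sampler (see above).
#' @param data a [bcv_dataset()] (only `n` and the item ids are used here;
#'   the model closure holds the observations).
#' @param config a [sis_config()].
#' @return Object of class `bcv_sis_trace` with `increments`, `epsilons`,
#'   `cycles_used` and `permutation` (0-based item order).
#' @export
sis_run <- function(model, data, config = sis_config()) {
  n <- data$n
  if (is.null(model$sis_kernel))
    stop("model does not expose a sequential-importance-sampling kernel",
         call. = FALSE)
  if (config$use_reference && is.null(model$log_ref))
    stop("reference bridge requested but the model has no normalized reference family",
         call. = FALSE)
  if (!config$use_reference && isTRUE(model$improper_prior))
    stop(paste("improper prior: the marginal likelihood is infinite;",
               "sIS requires the reference bridge for this model"),
         call. = FALSE)
  set.seed(derive_seed(config$permutation_seed, 0L))
  perm <- sample(data$item_ids, n, replace = FALSE)
  eps <- eps_schedule(n, config$use_reference)
  increments <- numeric(n)
  cycles <- integer(n)
  state <- NULL
  for (i in seq_len(n)) {
    prefix <- if (i == 1L) integer(0) else perm[seq_len(i - 1L)]
    step_seed <- derive_seed(config$permutation_seed, i)
    Ti <- config$T
    if (config$adaptive) {
      pil <- model$sis_kernel(prefix, eps[i], config$B + config$pilot_T,
                              step_seed, state)
      logterms <- vapply(pil$states, function(th)
        step_logterm(model, perm[i], th, eps[i + 1L], eps[i]), numeric(1))
      drop_n <- min(config$B, length(logterms) - 1L)
      keep <- if (drop_n > 0L) logterms[-seq_len(drop_n)] else logterms
      pv <- if (length(keep) >= 2L) stats::var(keep) else 0
      Ti <- tune_step_cycles(pv, config)
      state <- pil$state
    }
    out <- model$sis_kernel(prefix, eps[i], config$B + Ti,
                            derive_seed(step_seed, 1L), state)
    states <- out$states[(length(out$states) - Ti + 1L):length(out$states)]
    logterms <- vapply(states, function(th)
      step_logterm(model, perm[i], th, eps[i + 1L], eps[i]), numeric(1))
    increments[i] <- log_mean_exp(logterms)
    if (!is.finite(increments[i]))
      stop(sprintf("non-finite sIS increment at step %d (item %d)", i, perm[i]),
           call. = FALSE)
    cycles[i] <- Ti
    state <- out$state
  }
  structure(list(increments = increments, epsilons = eps[seq_len(n)],
                 cycles_used = cycles, permutation = perm,
                 use_reference = config$use_reference),
            class = "bcv_sis_trace")
}

step_logterm <- function(model, item_id, state, eps_next, eps_cur) {
  lt <- model$loglik(item_id, state)
  if (eps_next != eps_cur)
    lt <- lt + model$log_ref(state, eps_next) - model$log_ref(state, eps_cur)
  lt
}

#' Per-site log marginal likelihood from a sIS trace
#'
#' `m = (1/n) sum_i ln R_i`; two traces with independent seeds can be fed to
#' [bias_correct()] (direction `"negative"`).
#'
#' @param trace a `bcv_sis_trace`.
#' @param n expected number of items (guards against truncated traces).
#' @return The per-site log marginal likelihood.
#' @export
sis_marginal <- function(trace, n) {
  if (length(trace$increments) != n)
    stop("incomplete trace: expected one increment per item", call. = FALSE)
  mean(trace$increments)
}

#' Joint k-fold CV score from sIS traces
#'
#' Each permutation is one replicate: its last `r = round(f * n)` increments
#' sum to the log joint predictive of a random validation set given the
#' complementary training set, so
#' `CVj = (1/L) sum_l (1/r) sum_{i=q+1}^{n} ln R_i^(l)`.
#' Requires `f <= 1/2` so the validation segment lies where the bridge has
#' reached the prior.
#'
#' @param traces list of `bcv_sis_trace` over independent permutations.
#' @param f set-aside fraction (<= 0.5).
#' @param n number of items.
#' @return A `bcv_fit` report (method tag `"CVj-sIS"`); per-replicate scores
#'   in `replicate_scores`.
#' @export
sis_kfold <- function(traces, f, n) {
  if (f > 0.5)
    stop("f > 0.5: validation segment would overlap the reference bridge",
         call. = FALSE)
  r <- max(1L, as.integer(round(f * n)))
  rep_scores <- vapply(traces, function(tr) {
    if (length(tr$increments) != n)
      stop("incomplete trace: expected one increment per item", call. = FALSE)
    sum(tr$increments[(n - r + 1L):n]) / r
  }, numeric(1))
  per_site <- unlist(lapply(traces, function(tr)
    tr$increments[(n - r + 1L):n]))
  new_fit(mean(rep_scores), per_site, NULL, "CVj-sIS",
          replicate_scores = rep_scores)
}

#' sIS-capable sampler for the normal model
#'
#' Under the normal testbed every partial target — prefix likelihood times
#' the geometric bridge of the Gaussian reference and the Gaussian prior —
#' is itself Gaussian, so the "kernel" samples exactly (each call returns
#' independent draws from the target).  The reference `p0` is a Gaussian
#' moment-matched to a preliminary posterior sample of the full data.
#'
#' @param spec a [normal_spec()] (M2; the parameter-free M1 needs no sIS).
#' @param data a dataset from [normal_simulate()].
#' @param ref_T size of the preliminary posterior sample used to fit `p0`
#'   (0 fits the exact full-data posterior moments).
#' @param ref_seed seed of the preliminary run.
#' @return A [bcv_sampler()] extended with `sis_kernel` and `log_ref`.
#' @export
normal_sis_model <- function(spec, data, ref_T = 1000L, ref_seed = 1L) {
  s <- normal_sampler(spec, data, "M2")
  s2 <- spec$sigma2; p <- spec$p
  post <- normal_posterior(spec, data)
  if (ref_T > 0L) {
    set.seed(ref_seed)
    th <- matrix(stats::rnorm(ref_T * p, sd = sqrt(post$var)), ref_T, p)
    th <- sweep(th, 2L, post$mean, `+`)
    mu0 <- colMeans(th)
    v0 <- mean(apply(th, 2L, stats::var))
  } else {
    mu0 <- post$mean; v0 <- post$var
  }
  # geometric bridge of N(mu0, v0) and the prior N(0, delta2) is Gaussian
  bridge <- function(eps) {
    if (!is.finite(spec$delta2)) {
      tau <- (1 - eps) / v0
      if (tau <= 0) stop("improper prior: bridge degenerates at eps = 1",
                         call. = FALSE)
      return(list(mean = mu0, var = 1 / tau))
    }
    tau <- (1 - eps) / v0 + eps / spec$delta2
    list(mean = ((1 - eps) * mu0 / v0) / tau, var = 1 / tau)
  }
  s$log_ref <- function(state, eps) {
    b <- bridge(eps)
    sum(stats::dnorm(state, b$mean, sqrt(b$var), log = TRUE))
  }
  s$sis_kernel <- function(prefix_ids, epsilon, n_cycles, seed, state) {
    b <- bridge(epsilon)
    m <- length(prefix_ids)
    tau <- m / s2 + 1 / b$var
    mu <- if (m == 0L) b$mean * (1 / b$var) / tau else
      (m * colMeans(data$items[prefix_ids + 1L, , drop = FALSE]) / s2 +
         b$mean / b$var) / tau
    set.seed(seed)
    th <- matrix(stats::rnorm(n_cycles * p, sd = sqrt(1 / tau)), n_cycles, p)
    th <- sweep(th, 2L, mu, `+`)
    states <- lapply(seq_len(n_cycles), function(t) th[t, ])
    list(states = states, state = states[[n_cycles]])
  }
  s$improper_prior <- !is.finite(spec$delta2)
  s
}
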