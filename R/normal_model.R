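# Multivariate-normal testbed with closed-form truth.
#
# Observations are i.i.d. N_p(theta*, sigma^2 I).  Model M1 fixes the mean at
# theta0; model M2 places a N(0, delta^2 I) prior on it.  Everything
# factorizes over the p coordinates, so every expected score is p times a
# one-dimensional Gaussian quantity.  The central identity: with
#
#   g(m) = E[ ln p(Y_new | training set of size m) ]
#
# the expected predictive fit C(q, r) = (1/r) * sum_{j=q}^{q+r-1} g(j),
# because the log joint predictive telescopes into one-observation
# conditionals whose conditioning sets are themselves i.i.d. population
# draws.  The per-site marginal likelihood is C(0, n), site-wise k-fold CV is
# C((1-f)n, 1), joint k-fold CV is C((1-f)n, fn), LOO-CV is C(n-1, 1) and
# the wAIC target is C(n, 1).

#' Specify the normal M1/M2 comparison problem
#'
#' @param p dimension of each observation.
#' @param sigma2 known observation variance (> 0).
#' @param theta_star true per-coordinate mean; a scalar is replicated over
#'   all coordinates, a length-`p` vector is used as-is.
#' @param theta0 M1's fixed mean (scalar replicated, default 0).
#' @param delta2 M2's prior variance (> 0; `Inf` marks the improper-limit
#'   flag, allowed for posterior-only computations).
#' @return Object of class `bcv_normal_spec`.
#' @export
normal_spec <- function(p, sigma2, theta_star, theta0 = 0, delta2 = 1000) {
  stopifnot(p >= 1, sigma2 > 0, delta2 > 0)
  theta_star <- if (length(theta_star) == 1L) rep(theta_star, p) else theta_star
  theta0 <- if (length(theta0) == 1L) rep(theta0, p) else theta0
  stopifnot(length(theta_star) == p, length(theta0) == p)
  structure(list(p = as.integer(p), sigma2 = sigma2, theta_star = theta_star,
                 theta0 = theta0, delta2 = delta2),
            class = "bcv_normal_spec")
}

#' Simulate a dataset from the true normal source
#'
#' @param spec a [normal_spec()].
#' @param n number of observations.
#' @param seed integer seed (same seed, same data).
#' @return A [bcv_dataset()] whose `items` is an `n x p` matrix.
#' @export
normal_simulate <- function(spec, n, seed = 1L) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * spec$p, sd = sqrt(spec$sigma2)), n, spec$p,
              byrow = TRUE)
  x <- sweep(x, 2L, spec$theta_star, `+`)
  bcv_dataset(x)
}

#' Conjugate posterior of the mean under M2
#'
#' Per coordinate, training on `m` observations with sample mean `xbar` gives
#' posterior variance `v = sigma2 * delta2 / (m * delta2 + sigma2)` and mean
#' `xbar * m * delta2 / (m * delta2 + sigma2)` (the prior for an empty
#' subset).  `delta2 = Inf` gives the flat-prior limit.
#'
#' @param spec a [normal_spec()].
#' @param data a dataset from [normal_simulate()].
#' @param subset_ids 0-based ids to condition on (may be empty).
#' @return List with `mean` (length-`p`) and `var` (scalar, same for all
#'   coordinates).
#' @export
normal_posterior <- function(spec, data, subset_ids = data$item_ids) {
  m <- length(subset_ids)
  if (m == 0L) {
    if (!is.finite(spec$delta2))
      return(list(mean = rep(0, spec$p), var = Inf))
    return(list(mean = rep(0, spec$p), var = spec$delta2))
  }
  xbar <- colMeans(data$items[subset_ids + 1L, , drop = FALSE])
  if (!is.finite(spec$delta2))
    return(list(mean = xbar, var = spec$sigma2 / m))
  shrink <- m * spec$delta2 / (m * spec$delta2 + spec$sigma2)
  list(mean = xbar * shrink,
       var = spec$sigma2 * spec$delta2 / (m * spec$delta2 + spec$sigma2))
}

# log N(x; mu, s2) summed over coordinates, vectorized over rows of x
.mvn_logdens <- function(x, mu, s2) {
  x <- matrix(x, ncol = length(mu))
  -0.5 * ncol(x) * log(2 * pi * s2) -
    rowSums(sweep(x, 2L, mu, `-`)^2) / (2 * s2)
}

#' Posterior sampler contract for the normal models
#'
#' Wraps M1 (no free parameter: every draw is `theta0`) or M2 (exact
#' conjugate draws, no MCMC) behind the [bcv_sampler()] contract.
#'
#' @param spec a [normal_spec()].
#' @param data a dataset from [normal_simulate()].
#' @param model `"M1"` or `"M2"`.
#' @return A [bcv_sampler()].
#' @export
normal_sampler <- function(spec, data, model = c("M2", "M1")) {
  model <- match.arg(model)
  X <- data$items
  p <- spec$p; s2 <- spec$sigma2
  draw_posterior <- function(training_ids, T, seed) {
    set.seed(seed)
    if (model == "M1") {
      th <- matrix(spec$theta0, T, p, byrow = TRUE)
    } else {
      post <- normal_posterior(spec, data, training_ids)
      th <- matrix(stats::rnorm(T * p, sd = sqrt(post$var)), T, p)
      th <- sweep(th, 2L, post$mean, `+`)
    }
    th
  }
  loglik_matrix <- function(item_ids, draws) {
    xs <- X[item_ids + 1L, , drop = FALSE]
    cross <- xs %*% t(draws)
    q_x <- rowSums(xs^2)
    q_t <- rowSums(draws^2)
    (-p / 2) * log(2 * pi * s2) -
      (outer(q_x, q_t, `+`) - 2 * cross) / (2 * s2)
  }
  loglik <- function(item_id, draw) {
    .mvn_logdens(X[item_id + 1L, ], draw, s2)[1L]
  }
  log_prior <- function(draw) {
    if (model == "M1") return(0)
    if (!is.finite(spec$delta2))
      stop("improper prior: log prior density unavailable", call. = FALSE)
    sum(stats::dnorm(draw, 0, sqrt(spec$delta2), log = TRUE))
  }
  s <- bcv_sampler(draw_posterior = function(training_ids, T, seed) {
    th <- draw_posterior(training_ids, T, seed)
    lapply(seq_len(T), function(t) th[t, ])
  }, loglik = loglik,
  loglik_matrix = function(item_ids, draws) {
    loglik_matrix(item_ids, do.call(rbind, draws))
  }, log_prior = log_prior, tag = paste0("normal-", model))
  s$spec <- spec; s$data <- data; s$model <- model
  s
}

# Expected log predictive of one new observation after training on m items
# (M2), summed over coordinates; exact, vectorized over m >= 0.
.g2 <- function(spec, m) {
  sigma2 <- spec$sigma2; delta2 <- spec$delta2; p <- spec$p
  ts2 <- sum(spec$theta_star^2)
  if (!is.finite(delta2)) {
    if (any(m == 0L)) stop("improper prior: C(0, .) undefined", call. = FALSE)
    v <- sigma2 / m; shr <- 1; vmu <- sigma2 / m
  } else {
    v <- sigma2 * delta2 / (m * delta2 + sigma2)
    shr <- m * delta2 / (m * delta2 + sigma2)
    vmu <- ifelse(m > 0L, shr^2 * sigma2 / pmax(m, 1L), 0)
  }
  s2 <- sigma2 + v
  p * (-0.5 * log(2 * pi * s2) - (sigma2 + vmu) / (2 * s2)) -
    (1 - shr)^2 * ts2 / (2 * s2)
}

.g1 <- function(spec) {
  sum(-0.5 * log(2 * pi * spec$sigma2) -
        (spec$sigma2 + (spec$theta_star - spec$theta0)^2) / (2 * spec$sigma2))
}

# C(q, r) under M2: mean of g over training sizes q .. q+r-1
.C2 <- function(spec, q, r) {
  mean(.g2(spec, q:(q + r - 1L)))
}

#' Exact expected fit scores and risks
#'
#' Closed-form expected per-site scores under both models and their
#' difference (M2 minus M1), plus the frequentist risk (expected squared
#' error of the point estimate: posterior mean for M2, `theta0` for M1).
#' All quantities are exact Gaussian integrals; M1's scores are independent
#' of `q`, `r` and `delta2`.
#'
#' @param spec a [normal_spec()].
#' @param n data size.
#' @param which one of `"marginal"` (per-site log marginal likelihood,
#'   C(0, n)), `"CVj"` (joint k-fold, C((1-f)n, fn)), `"CVs"` (site-wise
#'   k-fold, C((1-f)n, 1)), `"CVl"` (leave-one-out, C(n-1, 1)), `"waic"`
#'   (the target C(n, 1)) or `"risk"`.
#' @param f set-aside fraction for the k-fold variants.
#' @return List with components `M1`, `M2` and `delta` (= M2 - M1).
#' @export
analytic_fit <- function(spec, n,
                         which = c("marginal", "CVj", "CVs", "CVl", "waic",
                                   "risk"),
                         f = 0.2) {
  which <- match.arg(which)
  stopifnot(n >= 1)
  if (which == "marginal" && !is.finite(spec$delta2))
    stop("improper prior: the marginal likelihood is infinite", call. = FALSE)
  if (which == "risk") {
    m1 <- sum((spec$theta0 - spec$theta_star)^2)
    if (!is.finite(spec$delta2)) {
      m2 <- spec$p * spec$sigma2 / n
    } else {
      shr <- n * spec$delta2 / (n * spec$delta2 + spec$sigma2)
      m2 <- sum(shr^2 * spec$sigma2 / n + (1 - shr)^2 * spec$theta_star^2)
    }
    return(list(M1 = m1, M2 = m2, delta = m2 - m1))
  }
  m1 <- .g1(spec)
  r <- max(1L, as.integer(round(f * n)))
  q <- n - r
  m2 <- switch(which,
    marginal = .C2(spec, 0L, n),
    CVj = .C2(spec, q, r),
    CVs = .g2(spec, q),
    CVl = { if (n < 2L) stop("CVl needs n >= 2", call. = FALSE)
            .g2(spec, n - 1L) },
    waic = .g2(spec, n))
  list(M1 = m1, M2 = m2, delta = m2 - m1)
}

#' First-order asymptotic fit differences
#'
#' The leading-order expansions of the exact M2-minus-M1 expected scores:
#' \deqn{\Delta BF \approx \frac{p\theta^{*2}}{2\sigma^2}
#'   - \frac{p \ln n}{2n}
#'   + \frac{p}{2n}\Big(1 - \frac{\theta^{*2}}{\sigma^2}
#'   - 2\ln\frac{\delta^2}{\sigma^2}\Big)}
#' \deqn{\Delta CV_s \approx \frac{p\theta^{*2}}{2\sigma^2} - \frac{p}{2(1-f)n},\quad
#'   \Delta CV_j \approx \frac{p\theta^{*2}}{2\sigma^2} - \frac{p}{2n}\frac{|\ln(1-f)|}{f},\quad
#'   \Delta CV_l \approx \frac{p\theta^{*2}}{2\sigma^2} - \frac{p}{2n}}
#' and the relative risk (difference in quadratic error, normalized by
#' `2 sigma2`) equals the CVl expansion to this order.
#'
#' @param spec a [normal_spec()] (scalar `theta_star` assumed).
#' @param n data size (>= 2).
#' @param f set-aside fraction.
#' @param which one of `"BF"`, `"CVs"`, `"CVj"`, `"CVl"`, `"risk"`.
#' @return The first-order M2-minus-M1 value.
#' @export
asymptotic_fit <- function(spec, n, f = 0.2,
                           which = c("BF", "CVs", "CVj", "CVl", "risk")) {
  which <- match.arg(which)
  stopifnot(n >= 2)
  p <- spec$p; s2 <- spec$sigma2; ts2 <- mean(spec$theta_star^2)
  lead <- p / 2 * ts2 / s2
  switch(which,
    BF = lead - p / 2 * log(n) / n +
      p / (2 * n) * (1 - ts2 / s2 - 2 * log(spec$delta2 / s2)),
    CVs = lead - p / (2 * (1 - f) * n),
    CVj = lead - p / (2 * n) * abs(log(1 - f)) / f,
    CVl = lead - p / (2 * n),
    risk = lead - p / (2 * n))
}

#' Crossover data size of a fit or risk difference
#'
#' Smallest integer `n` in `n_range` at which the exact M2-minus-M1
#' difference of the chosen score becomes positive (for `"risk"`: at which
#' M2's expected quadratic error drops below M1's), located by bisection on
#' the exact analytic curves.
#'
#' @param spec a [normal_spec()].
#' @param score one of `"risk"`, `"BF"` (per-site log Bayes factor),
#'   `"CVl"`, `"CVs"`, `"CVj"`.
#' @param n_range length-2 integer range to search.
#' @param f set-aside fraction for the k-fold scores.
#' @return The crossover `n`, or `NA` (with a warning) when the difference
#'   does not change sign over `n_range`.
#' @export
crossover <- function(spec, score = c("risk", "BF", "CVl", "CVs", "CVj"),
                      n_range = c(100L, 20000L), f = 0.2) {
  score <- match.arg(score)
  dif <- function(n) {
    switch(score,
      risk = { a <- analytic_fit(spec, n, "risk"); a$M1 - a$M2 },
      BF = analytic_fit(spec, n, "marginal")$delta,
      CVl = analytic_fit(spec, n, "CVl")$delta,
      CVs = analytic_fit(spec, n, "CVs", f = f)$delta,
      CVj = analytic_fit(spec, n, "CVj", f = f)$delta)
  }
  lo <- as.integer(n_range[1L]); hi <- as.integer(n_range[2L])
  if (dif(lo) > 0) return(lo)
  if (dif(hi) <= 0) {
    warning("no sign change over n_range", call. = FALSE)
    return(NA_integer_)
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (dif(mid) > 0) hi <- mid else lo <- mid
  }
  hi
}

#' Exact realized scores for a given simulated dataset
#'
#' Closed-form predictive Gaussians conditioned on the actual data: the
#' per-dataset truth against which the Monte Carlo estimators are
#' benchmarked.  For M1 every score is the mean log-density under `theta0`.
#'
#' @param spec a [normal_spec()].
#' @param data a dataset from [normal_simulate()].
#' @param which `"marginal"`, `"CVl"`, `"CVs"` or `"CVj"`; the k-fold
#'   variants require `splits`.
#' @param splits list of `bcv_split` (for `"CVs"`/`"CVj"`).
#' @param model `"M2"` (default) or `"M1"`.
#' @return Exact per-site realized score (a number).
#' @export
realized_scores <- function(spec, data,
                            which = c("marginal", "CVl", "CVs", "CVj"),
                            splits = NULL, model = "M2") {
  which <- match.arg(which)
  X <- data$items; n <- data$n; s2 <- spec$sigma2
  if (model == "M1")
    return(mean(.mvn_logdens(X, spec$theta0, s2)))
  pred1 <- function(train_ids, item_ids) {
    post <- normal_posterior(spec, data, train_ids)
    .mvn_logdens(X[item_ids + 1L, , drop = FALSE], post$mean, s2 + post$var)
  }
  joint_pred <- function(train_ids, val_ids) {
    # telescoped: condition on train plus already-scored validation items
    tot <- 0
    cur <- train_ids
    for (i in val_ids) {
      tot <- tot + pred1(cur, i)
      cur <- c(cur, i)
    }
    tot
  }
  switch(which,
    marginal = {
      if (!is.finite(spec$delta2))
        stop("improper prior: the marginal likelihood is infinite", call. = FALSE)
      joint_pred(integer(0), data$item_ids) / n
    },
    CVl = {
      if (n < 2L) stop("CVl needs n >= 2", call. = FALSE)
      mean(vapply(data$item_ids, function(i)
        pred1(setdiff(data$item_ids, i), i), numeric(1)))
    },
    CVs = {
      stopifnot(!is.null(splits))
      mean(vapply(splits, function(sp)
        mean(pred1(sp$training_ids, sp$validation_ids)), numeric(1)))
    },
    CVj = {
      stopifnot(!is.null(splits))
      mean(vapply(splits, function(sp)
        joint_pred(sp$training_ids, sp$validation_ids) /
          length(sp$validation_ids), numeric(1)))
    })
}

#' Benchmark Monte Carlo estimators against the analytic truth
#'
#' For each dimension `p` and Monte Carlo sample size `T`, simulates a
#' dataset, computes the exact realized M2-minus-M1 score, runs each
#' requested estimator twice (independent seeds), and reports the estimate,
#' two-run debiased estimate, true and estimated bias, raw and debiased
#' error, and the diagnostic ESS.
#'
#' @param p_list integer vector of dimensions.
#' @param n data size.
#' @param T_list integer vector of Monte Carlo sample sizes.
#' @param methods subset of `c("CVj", "CVs", "CVl", "waic")`.
#' @param seed integer seed.
#' @param sigma2,theta_star,delta2 testbed parameters.
#' @param f set-aside fraction; `L` replicate count for the k-fold methods.
#' @return A data.frame, one row per (method, p, T).
#' @export
benchmark_table <- function(p_list = c(100L, 300L), n = 100L,
                            T_list = c(100L, 1000L),
                            methods = c("CVj", "CVs", "CVl", "waic"),
                            seed = 1L, sigma2 = 10, theta_star = 0.1,
                            delta2 = 10, f = 0.2, L = 5L) {
  rows <- list()
  for (p in p_list) {
    spec <- normal_spec(p, sigma2, theta_star, delta2 = delta2)
    data <- normal_simulate(spec, n, seed = derive_seed(seed, p))
    splits <- make_kfold_splits(n, f = f, L = L, seed = derive_seed(seed, p + 1L))
    m1 <- realized_scores(spec, data, "CVl", model = "M1")  # same for all
    truth <- list(
      CVj = realized_scores(spec, data, "CVj", splits = splits) - m1,
      CVs = realized_scores(spec, data, "CVs", splits = splits) - m1,
      CVl = realized_scores(spec, data, "CVl") - m1,
      waic = realized_scores(spec, data, "CVl") - m1)
    for (T in T_list) {
      for (meth in methods) {
        fits <- lapply(1:2, function(run) {
          sa <- normal_sampler(spec, data, "M2")
          run_estimator(meth, sa, data$n, splits, T,
                        seed = derive_seed(seed, 1000L * run + T + p))
        })
        est <- fits[[1L]]$raw_score - m1
        deb <- if (meth == "CVj") NA_real_ else
          debias_fits(fits[[1L]], fits[[2L]])$debiased_score - m1
        rows[[length(rows) + 1L]] <- data.frame(
          method = meth, p = p, T = T, true = truth[[meth]], est = est,
          deb = deb, true_bias = est - truth[[meth]],
          est_bias = if (meth == "CVj") NA_real_ else
            debias_fits(fits[[1L]], fits[[2L]])$bias_estimate,
          raw_error = abs(est - truth[[meth]]),
          deb_error = abs(deb - truth[[meth]]),
          ess = fits[[1L]]$diagnostics$mean_ess)
      }
    }
  }
  do.call(rbind, rows)
}

# dispatch a named estimator on a sampler (M1 scores are deterministic so the
# M2-minus-M1 difference only needs the M2 runs)
run_estimator <- function(method, sampler, n, splits, T, seed) {
  switch(method,
    CVj = ,
    CVs = {
      mats <- lapply(seq_along(splits), function(l)
        score_matrix(sampler, n, splits[[l]], T = T,
                     seed = derive_seed(seed, l)))
      if (method == "CVj") cv_joint(mats, splits) else cv_sitewise(mats, splits)
    },
    CVl = loo_cpo(score_matrix(sampler, n, NULL, T = T, seed = seed)),
    psloo = loo_pareto_smoothed(score_matrix(sampler, n, NULL, T = T, seed = seed)),
    waic = waic(score_matrix(sampler, n, NULL, T = T, seed = seed)),
    stop("unknown method: ", method, call. = FALSE))
}
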