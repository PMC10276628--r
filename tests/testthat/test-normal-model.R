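test_that("simulation is reproducible and matches the source moments", {
  sp <- normal_spec(3, 10, 0.1)
  a <- normal_simulate(sp, 20, seed = 5)
  b <- normal_simulate(sp, 20, seed = 5)
  expect_identical(a$items, b$items)
  tiny <- normal_spec(2, 1e-12, 0.1)
  x <- normal_simulate(tiny, 10, seed = 1)
  expect_lt(max(abs(x$items - 0.1)), 1e-4)
  big <- normal_simulate(sp, 1e5, seed = 2)
  expect_lt(max(abs(colMeans(big$items) - 0.1)), 4 * sqrt(10 / 1e5))
  expect_lt(max(abs(apply(big$items, 2, var) - 10)), 0.5)
})

test_that("conjugate posterior matches quadrature and its limits", {
  sp <- normal_spec(1, 4, 0.2, delta2 = 9)
  dat <- normal_simulate(sp, 12, seed = 3)
  expect_equal(normal_posterior(sp, dat, integer(0)),
               list(mean = 0, var = 9))
  # flat-prior limit: posterior mean equals the single observation
  flat <- normal_spec(1, 4, 0.2, delta2 = Inf)
  p1 <- normal_posterior(flat, dat, 0L)
  expect_equal(p1$mean, dat$items[1, 1])
  expect_equal(p1$var, 4)
  # shrinkage formula against brute-force numerical integration (p = 1)
  sub <- 0:4
  post <- normal_posterior(sp, dat, sub)
  x <- dat$items[sub + 1, 1]
  lik <- function(th) vapply(th, function(t)
    prod(dnorm(x, t, 2)) * dnorm(t, 0, 3), numeric(1))
  quad <- function(f) integrate(f, -20, 20, rel.tol = 1e-12)$value
  z <- quad(lik)
  m_quad <- quad(function(th) th * lik(th)) / z
  v_quad <- quad(function(th) th^2 * lik(th)) / z - m_quad^2
  expect_equal(post$mean, m_quad, tolerance = 1e-6)
  expect_equal(post$var, v_quad, tolerance = 1e-6)
})

test_that("the one-step predictive density matches quadrature", {
  sp <- normal_spec(1, 4, 0.2, delta2 = 9)
  dat <- normal_simulate(sp, 12, seed = 3)
  post <- normal_posterior(sp, dat, 0:6)
  y <- 1.23
  pred_quad <- integrate(function(th)
    dnorm(y, th, 2) * dnorm(th, post$mean, sqrt(post$var)), -20, 20)$value
  expect_equal(bayescv:::.mvn_logdens(y, post$mean, sp$sigma2 + post$var),
               log(pred_quad), tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("expected scores match a Monte Carlo oracle over dataset pairs", {
  # the independent oracle: average realized predictive scores over many
  # simulated training/validation pairs
  sp <- normal_spec(2, 4, 0.3, delta2 = 5)
  q <- 5L; r <- 2L
  set.seed(41)
  reps <- 4000
  cvs_mc <- numeric(reps); cvj_mc <- numeric(reps); mar_mc <- numeric(reps)
  for (i in seq_len(reps)) {
    dat <- normal_simulate(sp, q + r, seed = sample.int(2^30, 1))
    spl <- bayescv:::new_split(0:(q - 1L), q:(q + r - 1L), 1L)
    cvs_mc[i] <- realized_scores(sp, dat, "CVs", splits = list(spl))
    cvj_mc[i] <- realized_scores(sp, dat, "CVj", splits = list(spl))
    mar_mc[i] <- realized_scores(sp, dat, "marginal")
  }
  f <- r / (q + r)
  cvs_an <- analytic_fit(sp, q + r, "CVs", f = f)$M2
  cvj_an <- analytic_fit(sp, q + r, "CVj", f = f)$M2
  mar_an <- analytic_fit(sp, q + r, "marginal")$M2
  expect_lt(abs(mean(cvs_mc) - cvs_an), 3 * sd(cvs_mc) / sqrt(reps))
  expect_lt(abs(mean(cvj_mc) - cvj_an), 3 * sd(cvj_mc) / sqrt(reps))
  expect_lt(abs(mean(mar_mc) - mar_an), 3 * sd(mar_mc) / sqrt(reps))
})

test_that("M1 expected score is the Gaussian cross-entropy, independent of q, r and delta", {
  sp <- normal_spec(7, 3, 0.25, theta0 = 0.1, delta2 = 50)
  want <- -7 / 2 * log(2 * pi * 3) - 7 * (3 + 0.15^2) / (2 * 3)
  for (w in c("marginal", "CVj", "CVs", "CVl", "waic"))
    expect_equal(analytic_fit(sp, 100, w)$M1, want)
  sp2 <- normal_spec(7, 3, 0.25, theta0 = 0.1, delta2 = 5000)
  expect_equal(analytic_fit(sp2, 100, "CVl")$M1, want)
})

test_that("the improper prior is refused exactly where the math demands it", {
  sp <- normal_spec(2, 4, 0.1, delta2 = Inf)
  expect_error(analytic_fit(sp, 50, "marginal"), "improper")
  dat <- normal_simulate(sp, 10, seed = 1)
  expect_error(realized_scores(sp, dat, "marginal"), "improper")
  expect_silent(analytic_fit(sp, 50, "CVl"))
})

test_that("asymptotic expansions hit the tipping point and match the risk identity", {
  sp <- normal_spec(300, 10, 0.1, delta2 = 10)
  expect_equal(asymptotic_fit(sp, 1000, which = "CVl"), 0)
  for (n in c(500, 2000, 10000))
    expect_identical(asymptotic_fit(sp, n, which = "risk"),
                     asymptotic_fit(sp, n, which = "CVl"))
  # small-f penalty ordering: CVs >= CVj >= CVl
  for (f in c(0.1, 0.2)) {
    lead <- 300 / 2 * 0.01 / 10
    pen <- function(w) lead - asymptotic_fit(sp, 1000, f = f, which = w)
    expect_gte(pen("CVs"), pen("CVj"))
    expect_gte(pen("CVj"), pen("CVl"))
  }
})

test_that("exact and asymptotic scores converge as n grows", {
  sp <- normal_spec(300, 10, 0.1, delta2 = 10)
  for (w in c("BF", "CVs", "CVj", "CVl")) {
    which_exact <- if (w == "BF") "marginal" else w
    gap <- vapply(c(1e3, 1e4, 1e5), function(n)
      abs(analytic_fit(sp, as.integer(n), which_exact)$delta -
            asymptotic_fit(sp, as.integer(n), which = w)), numeric(1))
    expect_true(all(diff(gap) < 0))
    expect_lt(gap[3], 1e-4)
  }
})

test_that("crossover solvers reproduce the printed tipping points", {
  sp10 <- normal_spec(300, 10, 0.1, delta2 = 10)
  sp1000 <- normal_spec(300, 10, 0.1, delta2 = 1000)
  expect_equal(crossover(sp1000, "risk", c(10L, 100000L)), 1000)
  bf10 <- crossover(sp10, "BF", c(100L, 50000L))
  expect_gt(bf10, 7600); expect_lt(bf10, 8400)
  expect_gt(crossover(sp1000, "BF", c(100L, 50000L)), 10000)
  # CV crossovers sit at the accuracy tipping point, insensitive to delta
  expect_lt(abs(crossover(sp10, "CVl", c(10L, 100000L)) - 1000), 20)
  expect_lt(abs(crossover(sp1000, "CVl", c(10L, 100000L)) - 1000), 20)
  expect_warning(out <- crossover(sp10, "BF", c(100L, 200L)), "no sign change")
  expect_true(is.na(out))
})

test_that("CV scores are insensitive to the prior width while the Bayes factor is not", {
  n <- 1000L
  d10 <- normal_spec(300, 10, 0.1, delta2 = 10)
  d1000 <- normal_spec(300, 10, 0.1, delta2 = 1000)
  for (w in c("CVl", "CVs", "CVj"))
    expect_lt(abs(analytic_fit(d10, n, w)$delta -
                    analytic_fit(d1000, n, w)$delta), 1e-3)
  expect_gt(abs(analytic_fit(d10, n, "marginal")$delta -
                  analytic_fit(d1000, n, "marginal")$delta), 0.05)
})

test_that("realized scores converge to expected scores and to estimator limits", {
  sp <- normal_spec(2, 10, 0.1, delta2 = 10)
  dat <- normal_simulate(sp, 50, seed = 61)
  expect_equal(realized_scores(sp, dat, "CVl", model = "M1"),
               mean(bayescv:::.mvn_logdens(dat$items, sp$theta0, sp$sigma2)))
  # leave-one-out realized truth is the large-T limit of the CPO estimator
  sa <- normal_sampler(sp, dat)
  est <- loo_cpo(score_matrix(sa, 50, NULL, T = 1e5, seed = 3))$raw_score
  expect_lt(abs(est - realized_scores(sp, dat, "CVl")), 1e-2)
  # realized concentrates around the expectation as n grows
  sp3 <- normal_spec(3, 10, 0.1, delta2 = 10)
  devs <- vapply(c(100L, 4000L), function(n) {
    r <- vapply(1:8, function(s)
      realized_scores(sp3, normal_simulate(sp3, n, seed = 100 + s), "CVl"),
      numeric(1))
    mean(abs(r - analytic_fit(sp3, n, "CVl")$M2))
  }, numeric(1))
  expect_lt(devs[2], devs[1])
})

test_that("a posterior-insensitive likelihood collapses matched estimators to one value", {
  # huge observation variance: the likelihood barely depends on theta, so
  # every estimator sharing a scope must coincide
  sp <- normal_spec(2, 1e8, 0.01, delta2 = 10)
  dat <- normal_simulate(sp, 40, seed = 71)
  sa <- normal_sampler(sp, dat)
  m <- score_matrix(sa, 40, NULL, T = 500, seed = 1)
  full_scope <- c(loo_cpo(m)$raw_score, waic(m)$raw_score,
                  loo_pareto_smoothed(m)$raw_score)
  expect_lt(max(full_scope) - min(full_scope), 1e-3)
  splits <- make_kfold_splits(40, 0.2, 2, seed = 2)
  mats <- lapply(seq_along(splits), function(l)
    score_matrix(sa, 40, splits[[l]], T = 500, seed = 10 + l))
  expect_lt(abs(cv_sitewise(mats, splits)$raw_score -
                  cv_joint(mats, splits)$raw_score), 1e-3)
})

test_that("the benchmark table has the advertised layout", {
  tab <- benchmark_table(p_list = 3L, n = 30L, T_list = 50L,
                         methods = c("CVs", "CVl"), seed = 2)
  expect_s3_class(tab, "data.frame")
  expect_setequal(tab$method, c("CVs", "CVl"))
  expect_true(all(c("true", "est", "deb", "true_bias", "est_bias",
                    "raw_error", "deb_error", "ess") %in% names(tab)))
  expect_true(all(is.finite(tab$est)))
})
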