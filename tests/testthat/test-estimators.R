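test_that("log_mean_exp is exact on closed forms and stable", {
  expect_identical(log_mean_exp(rep(3.7, 5)), 3.7)
  expect_equal(log_mean_exp(c(0, log(3))), log(2))
  expect_identical(log_mean_exp(c(1000, 1000)), 1000)
  expect_error(log_mean_exp(numeric(0)), "empty")
})

test_that("ess matches closed forms and stays in [1, T]", {
  expect_equal(ess(rep(0, 100)), 100)
  expect_lt(ess(c(0, -50, -50)), 1.01)
  expect_equal(ess(log(c(2, 1, 1))), 16 / 6)
  for (s in 1:20) {
    lw <- rnorm(37, sd = runif(1, 0.1, 5))
    e <- ess(lw)
    expect_gte(e, 1); expect_lte(e, 37)
  }
  expect_error(ess(numeric(0)), "empty")
})

make_split_matrix <- function(vals, split) {
  bcv_sitell(vals, split$validation_ids, split$training_ids)
}

test_that("site-wise CV reduces to closed forms", {
  sp1 <- bayescv:::new_split(1:4, 0L, 1L)
  m1 <- make_split_matrix(matrix(-1.3, 1, 8), sp1)
  expect_equal(cv_sitewise(list(m1), list(sp1))$raw_score, -1.3)
  # two replicates with scores a and b average to (a+b)/2
  sp2 <- bayescv:::new_split(c(0L, 2:4), 1L, 2L)
  m2 <- make_split_matrix(matrix(-2.1, 1, 8), sp2)
  fit <- cv_sitewise(list(m1, m2), list(sp1, sp2))
  expect_equal(fit$raw_score, (-1.3 - 2.1) / 2)
  expect_identical(fit$method_tag, "CVs")
})

test_that("joint CV reduces to site-wise for singleton validation sets and to sums at T=1", {
  sp1 <- bayescv:::new_split(1:4, 0L, 1L)
  vals <- matrix(rnorm(6), 1, 6)
  m <- make_split_matrix(vals, sp1)
  expect_equal(cv_joint(list(m), list(sp1))$raw_score,
               cv_sitewise(list(m), list(sp1))$raw_score)
  sp3 <- bayescv:::new_split(3:9, 0:2, 1L)
  m3 <- make_split_matrix(matrix(c(-1, -2, -3), 3, 1), sp3)
  expect_equal(cv_joint(list(m3), list(sp3))$raw_score, mean(c(-1, -2, -3)))
})

test_that("provenance mismatches between matrix and split are caught", {
  sp <- bayescv:::new_split(1:4, 0L, 1L)
  wrong <- bcv_sitell(matrix(-1, 1, 3), 2L, c(0L, 1L, 3L, 4L))
  expect_error(cv_sitewise(list(wrong), list(sp)), "provenance")
  expect_error(cv_joint(list(wrong), list(sp)), "provenance")
})

test_that("CPO leave-one-out matches the harmonic-mean closed form", {
  m <- bcv_sitell(matrix(rep(-0.7, 6), 1, 6), 0L, 0L)
  expect_equal(loo_cpo(m)$raw_score, -0.7)
  m2 <- bcv_sitell(matrix(c(0, log(3)), 1, 2), 0L, 0L)
  expect_equal(loo_cpo(m2)$raw_score, log(3 / 2))
})

test_that("wAIC separates self-fit and penalty with the unbiased variance", {
  m <- bcv_sitell(matrix(rep(-1.2, 8), 2, 4), 0:1, 0:1)
  f <- waic(m)
  expect_equal(f$raw_score, -1.2)
  expect_equal(f$penalty, 0)
  m2 <- bcv_sitell(matrix(c(0, log(3)), 1, 2), 0L, 0L)
  f2 <- waic(m2)
  expect_equal(f2$lppd, log(2))
  expect_equal(f2$penalty, log(3)^2 / 2)
  expect_equal(f2$raw_score, log(2) - log(3)^2 / 2)
  expect_error(waic(bcv_sitell(matrix(-1, 2, 1), 0:1, 0:1)), "two draws")
})

test_that("Jensen ordering holds site by site: CPO score <= lppd, penalty >= 0", {
  set.seed(11)
  for (rep in 1:10) {
    vals <- matrix(rnorm(30 * 40, sd = runif(1, 0.2, 3)), 30, 40)
    m <- bcv_sitell(vals, 0:29, 0:29)
    cpo <- loo_cpo(m)$per_site_scores
    w <- waic(m)
    lppd <- w$lppd_per_site
    expect_true(all(cpo <= lppd + 1e-12))
    expect_true(all(w$penalty_per_site >= 0))
    expect_lte(w$raw_score, w$lppd)
  }
})

test_that("Pareto smoothing leaves constant rows alone and calibrates kappa", {
  m <- bcv_sitell(matrix(rep(-0.4, 50), 1, 50), 0L, 0L)
  ps <- loo_pareto_smoothed(m)
  expect_equal(ps$raw_score, loo_cpo(m)$raw_score)
  expect_equal(ps$diagnostics$kappa_per_site, 0)
  expect_error(loo_pareto_smoothed(bcv_sitell(matrix(-1, 1, 10), 0L, 0L)),
               "25 draws")
  # shape recovery on exceedances drawn from a generalized Pareto
  set.seed(21)
  ks <- replicate(100, bayescv:::gpd_fit((runif(2000)^(-0.4) - 1) / 0.4)$k)
  expect_lt(abs(median(ks) - 0.4), 0.1)
})

test_that("smoothed and plain CPO agree on well-behaved sites", {
  sp <- normal_spec(4, 10, 0.1, delta2 = 10)
  dat <- normal_simulate(sp, 40, seed = 31)
  sa <- normal_sampler(sp, dat)
  m1 <- score_matrix(sa, 40, NULL, T = 2000, seed = 1)
  m2 <- score_matrix(sa, 40, NULL, T = 2000, seed = 2)
  ps <- loo_pareto_smoothed(m1)
  cpo1 <- loo_cpo(m1)$per_site_scores
  cpo2 <- loo_cpo(m2)$per_site_scores
  ok <- which(ps$diagnostics$kappa_per_site < 0.5)
  expect_gt(length(ok), 10)
  gap <- abs(ps$per_site_scores - cpo1)[ok]
  run2run <- abs(cpo1 - cpo2)[ok]
  expect_lte(median(gap), median(run2run) + 1e-6)
})

test_that("two-step CV scores items under an independent training posterior", {
  sa <- constant_sampler(-3)
  split <- bayescv:::new_split(0:4, 5:9, 1L)
  m <- score_matrix(sa, 10, split, T = 6, seed = 1)
  expect_equal(two_step_cv(m)$raw_score, -3)
  overlap <- bcv_sitell(matrix(-1, 2, 3), 0:1, 0:5)
  expect_error(two_step_cv(overlap), "disjoint")
})

test_that("two-run bias estimation follows the half-variance rule", {
  same <- bias_correct(c(1, 2), c(1, 2), "negative")
  expect_equal(same$bias_estimate, 0)
  expect_equal(same$debiased_score, same$raw_score)
  bc <- bias_correct(1.0, 0.6, "negative")
  expect_equal(bc$bias_estimate, -0.04)
  expect_equal(bc$debiased_score, 0.84)
  pos <- bias_correct(1.0, 0.6, "positive")
  expect_equal(pos$bias_estimate, 0.04)
  expect_equal(pos$debiased_score, 0.76)
  expect_error(bias_correct(1:3, 1:2, "negative"), "mismatch")
})

test_that("debias_fits pools runs with the method's bias direction", {
  m1 <- bcv_sitell(matrix(c(0, log(3)), 1, 2), 0L, 0L)
  m2 <- bcv_sitell(matrix(c(log(2), log(2)), 1, 2), 0L, 0L)
  a <- loo_cpo(m1); b <- loo_cpo(m2)
  d <- debias_fits(a, b)
  expect_gt(d$bias_estimate, 0)       # CPO bias is positive
  expect_equal(d$debiased_score, d$raw_score - d$bias_estimate)
  aw <- waic(m1); bw <- waic(m2)
  dw <- debias_fits(aw, bw)
  expect_lt(dw$bias_estimate, 0)      # arithmetic-mean bias is negative
  expect_error(debias_fits(a, bw), "different methods")
})

test_that("quality verdicts follow the ESS and kappa thresholds", {
  good <- make_diag(c(rep(606, 99), 5))
  expect_identical(quality_check(good), "good")
  reasonable <- make_diag(c(rep(64.3, 92), rep(8, 8)))
  expect_identical(quality_check(reasonable), "reasonable")
  expect_identical(quality_check(make_diag(rep(40, 100))), "fail")
  # high kappa counts toward the bad-site fraction even with high ESS
  kap <- make_diag(rep(1000, 100), kappa = c(rep(0.9, 8), rep(0.1, 92)))
  expect_identical(quality_check(kap), "reasonable")
})

test_that("model comparison is paired, antisymmetric and zero on identity", {
  m <- bcv_sitell(matrix(rnorm(200), 20, 10), 0:19, 0:19)
  a <- loo_cpo(m)
  expect_equal(compare_models(a, a)$delta, 0)
  m2 <- bcv_sitell(m$values + 0.3, 0:19, 0:19)
  b <- loo_cpo(m2)
  ab <- compare_models(a, b); ba <- compare_models(b, a)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$per_site_delta, -ba$per_site_delta)
  expect_equal(ab$delta, 0.3)
  wrong <- loo_cpo(bcv_sitell(m$values[1:10, ], 0:9, 0:19))
  expect_error(compare_models(a, wrong), "different site sets")
})

test_that("fit reports serialize to TSV plus key=value summary", {
  m <- bcv_sitell(matrix(rnorm(60), 6, 10), 0:5, 0:5)
  f <- loo_cpo(m)
  path <- tempfile(fileext = ".tsv")
  write_fit_report(f, path)
  lines <- readLines(path)
  expect_identical(strsplit(lines[1], "\t")[[1]][1:3], c("site", "score", "ess"))
  expect_length(grep("^#", lines), 1)
  kv <- readLines(paste0(path, ".summary"))
  expect_true(any(grepl("^method=CVl$", kv)))
  expect_true(any(grepl("^verdict=", kv)))
})
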