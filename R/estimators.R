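# Non-sequential fit scores computed from site log-likelihood matrices:
# joint and site-wise k-fold CV, CPO leave-one-out CV (plain and
# Pareto-smoothed), wAIC, two-step CV, Monte Carlo bias correction and
# importance-sampling diagnostics.
#
# All scores are per observation in natural-log units; higher is better.

#' Numerically stable log of an arithmetic mean of exponentials
#'
#' Computes `ln((1/T) * sum(exp(v)))` with a max shift, exact for constant
#' input and overflow-free for large values.
#'
#' @param values nonempty finite numeric vector.
#' @return A single number.
#' @export
log_mean_exp <- function(values) {
  if (length(values) == 0L) stop("empty vector", call. = FALSE)
  m <- max(values)
  m + log(mean(exp(values - m)))
}

log_sum_exp <- function(values) {
  m <- max(values)
  m + log(sum(exp(values - m)))
}

#' Effective sample size of importance weights
#'
#' Kong's estimator `(sum w)^2 / sum(w^2)` on self-normalized weights
#' `w_t` proportional to `exp(logweights_t)`; always in `[1, T]`, equal to
#' `T` iff all weights are equal.
#'
#' @param logweights nonempty finite numeric vector of log weights.
#' @return A single number in `[1, length(logweights)]`.
#' @export
ess <- function(logweights) {
  if (length(logweights) == 0L) stop("empty vector", call. = FALSE)
  lw <- logweights - max(logweights)
  w <- exp(lw)
  sum(w)^2 / sum(w^2)
}

new_diag <- function(ess_per_site, kappa_per_site = NULL, T = NA_integer_) {
  fl <- mean(ess_per_site <= 10)
  fk <- if (is.null(kappa_per_site)) NA_real_ else
    mean(kappa_per_site > 0.7, na.rm = TRUE)
  d <- structure(list(ess_per_site = ess_per_site,
                      mean_ess = mean(ess_per_site),
                      frac_low_ess = fl,
                      kappa_per_site = kappa_per_site,
                      frac_high_kappa = fk,
                      T = T, verdict = NA_character_),
                 class = "bcv_diag")
  d$verdict <- quality_check(d)
  d
}

new_fit <- function(raw_score, per_site_scores, diagnostics, method_tag,
                    bias_estimate = 0, site_ids = NULL, replicate_scores = NULL,
                    extra = list()) {
  structure(c(list(score_per_site = raw_score - bias_estimate,
                   raw_score = raw_score,
                   bias_estimate = bias_estimate,
                   debiased_score = raw_score - bias_estimate,
                   per_site_scores = per_site_scores,
                   site_ids = site_ids,
                   replicate_scores = replicate_scores,
                   diagnostics = diagnostics,
                   method_tag = method_tag),
              extra),
            class = "bcv_fit")
}

#' @export
print.bcv_fit <- function(x, ...) {
  cat(sprintf("%s fit report\n", x$method_tag))
  cat(sprintf("  raw score      : %.6f per site\n", x$raw_score))
  cat(sprintf("  bias estimate  : %.6f\n", x$bias_estimate))
  cat(sprintf("  debiased score : %.6f per site\n", x$debiased_score))
  d <- x$diagnostics
  if (!is.null(d)) {
    cat(sprintf("  mean ESS       : %.1f (frac ESS<=10: %.3f)\n",
                d$mean_ess, d$frac_low_ess))
    if (!is.na(d$frac_high_kappa))
      cat(sprintf("  frac kappa>0.7 : %.3f\n", d$frac_high_kappa))
    cat(sprintf("  verdict        : %s\n", d$verdict))
  }
  invisible(x)
}

check_split_matrix <- function(mat, split) {
  if (!setequal(mat$row_ids, split$validation_ids) ||
      !setequal(mat$training_ids, split$training_ids))
    stop("matrix provenance does not match split (training/validation ids differ)",
         call. = FALSE)
}

#' Site-wise k-fold cross-validation score
#'
#' Per replicate, averages each validation item's likelihood over the
#' training posterior independently, log-transforms, and averages over items
#' and replicates:
#' `CVs = (1/r)(1/L) sum_l sum_{i in I_lv} ln((1/T) sum_t L_it)`.
#' ESS is computed per site on the likelihood weights themselves.
#'
#' @param matrices list of [bcv_sitell()], one per split, rows covering the
#'   split's validation items and draws conditioned on its training items.
#' @param splits list of `bcv_split` of equal length.
#' @return A `bcv_fit` report (method tag `"CVs"`).
#' @export
cv_sitewise <- function(matrices, splits) {
  stopifnot(length(matrices) == length(splits))
  per_site <- numeric(0); ids <- integer(0); esss <- numeric(0)
  rep_scores <- numeric(length(splits))
  for (l in seq_along(splits)) {
    check_split_matrix(matrices[[l]], splits[[l]])
    v <- matrices[[l]]$values
    s <- apply(v, 1L, log_mean_exp)
    e <- apply(v, 1L, ess)
    per_site <- c(per_site, s); ids <- c(ids, matrices[[l]]$row_ids)
    esss <- c(esss, e)
    rep_scores[l] <- mean(s)
  }
  new_fit(mean(rep_scores), per_site,
          new_diag(esss, T = ncol(matrices[[1L]]$values)),
          "CVs", site_ids = ids, replicate_scores = rep_scores)
}

#' Joint k-fold cross-validation score (naive importance sampling)
#'
#' Per replicate, averages the joint likelihood of the whole validation set
#' over the training posterior:
#' `CVj = (1/r)(1/L) sum_l ln((1/T) sum_t prod_{i in I_lv} L_it)`.
#' The reported ESS is the per-replicate joint ESS (the diagnostic that
#' collapses in high dimension), averaged over replicates.
#'
#' @inheritParams cv_sitewise
#' @return A `bcv_fit` report (method tag `"CVj"`).  The Monte Carlo bias of
#'   this estimator cannot be usefully estimated from two runs (its variance
#'   is too large), so `bias_estimate` is `NA`.
#' @export
cv_joint <- function(matrices, splits) {
  stopifnot(length(matrices) == length(splits))
  rep_scores <- numeric(length(splits)); joint_ess <- numeric(length(splits))
  for (l in seq_along(splits)) {
    check_split_matrix(matrices[[l]], splits[[l]])
    v <- matrices[[l]]$values
    r <- nrow(v)
    joint_lw <- colSums(v)
    rep_scores[l] <- log_mean_exp(joint_lw) / r
    joint_ess[l] <- ess(joint_lw)
  }
  f <- new_fit(mean(rep_scores), rep_scores,
               new_diag(joint_ess, T = ncol(matrices[[1L]]$values)),
               "CVj", replicate_scores = rep_scores)
  f$bias_estimate <- NA_real_
  f$debiased_score <- NA_real_
  f
}

#' Leave-one-out CV via cross-predictive ordinates
#'
#' Uses the harmonic-mean identity
#' `1/p(X_i | X_(i)) = E_post[1/p(X_i | theta)]`
#' on a full-data posterior sample: per site,
#' `CPO_i = -ln((1/T) sum_t 1/L_it)`, and `CVl = (1/n) sum_i CPO_i`.
#' ESS is computed on the inverse-likelihood weights.
#'
#' @param matrix a [bcv_sitell()] scored on all items with draws conditioned
#'   on all items.
#' @return A `bcv_fit` report (method tag `"CVl"`).
#' @export
loo_cpo <- function(matrix) {
  v <- matrix$values
  per_site <- -apply(-v, 1L, log_mean_exp)
  esss <- apply(-v, 1L, ess)
  new_fit(mean(per_site), per_site, new_diag(esss, T = ncol(v)), "CVl",
          site_ids = matrix$row_ids)
}

# --- generalized Pareto tail fit (empirical-Bayes profile posterior mean,
#     Zhang & Stephens 2009) on exceedances over a threshold ---------------
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 2L || x[n] <= 0 || x[n] - x[1L] < 1e-30 * max(1, abs(x[n])))
    return(list(k = 0, sigma = NA_real_))
  m <- 30L + floor(sqrt(n))
  quart <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (3 * quart)
  k_j <- vapply(theta, function(th) -mean(log1p(-th * x)), numeric(1))
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(l_j - l_j[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))        # profile estimate of the shape
  sigma <- -k / theta_hat
  list(k = k, sigma = sigma)              # k is the shape xi (kappa-hat)
}

qgpd <- function(p, mu, sigma, xi) {
  if (abs(xi) < 1e-12) mu - sigma * log1p(-p)
  else mu + sigma * expm1(-xi * log1p(-p)) / xi
}

#' Pareto-smoothed leave-one-out CV
#'
#' Stabilized CPO: per site, a generalized Pareto distribution is fitted to
#' the right tail (largest 20%) of the inverse-likelihood weights
#' `w_t = 1/L_it`, and those tail weights are replaced by expected order
#' statistics of the fitted distribution before recomputing the harmonic-mean
#' score.  The fitted shape `kappa-hat` is reported per site; values above
#' 0.7 flag unreliable sites.  A degenerate (constant) tail yields
#' `kappa-hat = 0` and no smoothing.
#'
#' @inheritParams loo_cpo
#' @return A `bcv_fit` report (method tag `"PS-CVl"`) whose diagnostics carry
#'   `kappa_per_site`.
#' @export
loo_pareto_smoothed <- function(matrix) {
  v <- matrix$values
  T <- ncol(v)
  if (T < 25L)
    stop("Pareto smoothing needs at least 25 draws for a stable tail fit",
         call. = FALSE)
  M <- ceiling(0.2 * T)
  n <- nrow(v)
  per_site <- numeric(n); esss <- numeric(n); kappas <- numeric(n)
  for (i in seq_len(n)) {
    lw <- -v[i, ]                       # log inverse-likelihood weights
    lw <- lw - max(lw)                  # scale-free: harmonic mean refactored
    ord <- order(lw)
    tail_idx <- ord[(T - M + 1L):T]
    w <- exp(lw)
    thr <- exp(lw[ord[T - M]])          # threshold: largest non-tail weight
    fit <- gpd_fit(w[tail_idx] - thr)
    kappas[i] <- fit$k
    if (!is.na(fit$sigma) && is.finite(fit$sigma) && fit$sigma > 0) {
      repl <- qgpd((seq_len(M) - 0.5) / M, thr, fit$sigma, fit$k)
      w[tail_idx[order(w[tail_idx])]] <- pmin(repl, max(w))
    }
    per_site[i] <- -(max(-v[i, ]) + log(mean(w)))
    esss[i] <- sum(w)^2 / sum(w^2)
  }
  new_fit(mean(per_site), per_site, new_diag(esss, kappas, T = T), "PS-CVl",
          site_ids = matrix$row_ids)
}

#' Widely applicable information criterion (wAIC)
#'
#' Per-site convention, higher is better:
#' `wAIC = (1/n) sum_i [ ln E_post p(X_i|theta) - V_post ln p(X_i|theta) ]`,
#' with the posterior expectation and variance replaced by their Monte Carlo
#' counterparts over a full-data posterior sample (unbiased sample variance).
#' The penalty `(1/n) sum_i V_i` is reported separately.
#'
#' @inheritParams loo_cpo
#' @return A `bcv_fit` report (method tag `"wAIC"`) with elements `lppd`
#'   (self-fit term) and `penalty`.
#' @export
waic <- function(matrix) {
  v <- matrix$values
  if (ncol(v) < 2L)
    stop("wAIC needs at least two draws (posterior variance undefined)",
         call. = FALSE)
  lppd_i <- apply(v, 1L, log_mean_exp)
  p_i <- apply(v, 1L, stats::var)
  per_site <- lppd_i - p_i
  esss <- apply(v, 1L, ess)
  new_fit(mean(per_site), per_site, new_diag(esss, T = ncol(v)), "wAIC",
          site_ids = matrix$row_ids,
          extra = list(lppd = mean(lppd_i), penalty = mean(p_i),
                       lppd_per_site = lppd_i, penalty_per_site = p_i))
}

#' Two-step cross-validation
#'
#' Site-wise CV with a single replicate in which the model is trained on an
#' independent dataset of the same size and validated on every item of the
#' dataset of interest; a direct estimator of the ideal target C(n, 1).
#'
#' @param matrix a [bcv_sitell()] whose rows cover the full dataset of
#'   interest and whose draws are conditioned on a disjoint training dataset.
#' @return A `bcv_fit` report (method tag `"two-step"`).
#' @export
two_step_cv <- function(matrix) {
  if (length(intersect(matrix$row_ids, matrix$training_ids)) > 0L)
    stop("two-step CV requires training data disjoint from validation data",
         call. = FALSE)
  v <- matrix$values
  per_site <- apply(v, 1L, log_mean_exp)
  esss <- apply(v, 1L, ess)
  new_fit(mean(per_site), per_site, new_diag(esss, T = ncol(v)), "two-step",
          site_ids = matrix$row_ids)
}

#' Monte Carlo bias estimation from two independent runs
#'
#' The log transform of an unbiased likelihood average biases every estimator
#' here; to good approximation the absolute bias is half the variance of the
#' averaged log score.  That variance is estimated per site from two
#' independent runs as `(a_i - b_i)^2 / 2`, giving
#' `|bias| = (1/2n) sum_i var-hat_i`.  The sign is negative for
#' arithmetic-mean estimators (nIS, sIS, the wAIC self-fit) and positive for
#' the harmonic-mean CPO.
#'
#' @param per_site_a,per_site_b per-site score estimates from two independent
#'   runs of the same method on the same data.
#' @param direction `"negative"` or `"positive"` (sign of the bias).
#' @return List with `bias_estimate`, `debiased_score` (mean of the two runs
#'   minus the bias) and `raw_score` (mean of the two runs).
#' @export
bias_correct <- function(per_site_a, per_site_b,
                         direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  if (length(per_site_a) != length(per_site_b))
    stop("mismatched site sets between the two runs", call. = FALSE)
  var_i <- (per_site_a - per_site_b)^2 / 2
  mag <- mean(var_i) / 2
  bias <- if (direction == "negative") -mag else mag
  raw <- mean((per_site_a + per_site_b) / 2)
  list(bias_estimate = bias, debiased_score = raw - bias, raw_score = raw)
}

#' Apply two-run bias correction to a pair of fit reports
#'
#' Convenience wrapper around [bias_correct()] using each method's known bias
#' direction (positive for CPO-based scores, negative otherwise).
#'
#' @param fit_a,fit_b `bcv_fit` reports from two independent runs.
#' @return A `bcv_fit` with pooled raw score and filled bias fields.
#' @export
debias_fits <- function(fit_a, fit_b) {
  if (fit_a$method_tag != fit_b$method_tag)
    stop("cannot pool reports from different methods", call. = FALSE)
  if (!identical(fit_a$site_ids, fit_b$site_ids))
    stop("mismatched site sets between the two runs", call. = FALSE)
  dir <- if (fit_a$method_tag %in% c("CVl", "PS-CVl")) "positive" else "negative"
  bc <- bias_correct(fit_a$per_site_scores, fit_b$per_site_scores, dir)
  out <- fit_a
  out$per_site_scores <- (fit_a$per_site_scores + fit_b$per_site_scores) / 2
  out$raw_score <- bc$raw_score
  out$bias_estimate <- bc$bias_estimate
  out$debiased_score <- bc$debiased_score
  out$score_per_site <- bc$debiased_score
  out
}

#' Quality verdict from importance-sampling diagnostics
#'
#' A site is flagged bad when its ESS is at most 10 or its fitted Pareto
#' shape exceeds 0.7.  The verdict is `"good"` when the mean ESS across sites
#' is at least 500 and at most 5% of sites are bad, `"reasonable"` when the
#' mean ESS is at least 50 and at most 10% are bad, `"fail"` otherwise.
#'
#' @param diag a diagnostics object (`bcv_diag`) from a fit report.
#' @return `"good"`, `"reasonable"` or `"fail"`.
#' @export
quality_check <- function(diag) {
  bad <- diag$ess_per_site <= 10
  if (!is.null(diag$kappa_per_site))
    bad <- bad | (diag$kappa_per_site > 0.7)
  frac_bad <- mean(bad)
  if (diag$mean_ess >= 500 && frac_bad <= 0.05) "good"
  else if (diag$mean_ess >= 50 && frac_bad <= 0.10) "reasonable"
  else "fail"
}

#' Compare two fit reports site by site
#'
#' Computes the per-site score difference `b - a` (a per-site log Bayes
#' factor when the scores are marginal likelihoods), its mean on debiased
#' scores, the paired per-site standard error and, when both reports carry
#' replicate scores, the replicate SD of the difference.
#'
#' @param report_a,report_b `bcv_fit` reports for two models on the same
#'   data with the same method family.
#' @return List with `delta` (debiased mean difference), `delta_raw`,
#'   `per_site_delta`, `se` and `replicate_sd`.
#' @export
compare_models <- function(report_a, report_b) {
  if (!identical(report_a$site_ids, report_b$site_ids))
    stop("reports cover different site sets", call. = FALSE)
  d <- report_b$per_site_scores - report_a$per_site_scores
  se <- stats::sd(d) / sqrt(length(d))
  rsd <- if (!is.null(report_a$replicate_scores) &&
             !is.null(report_b$replicate_scores) &&
             length(report_a$replicate_scores) ==
             length(report_b$replicate_scores)) {
    stats::sd(report_b$replicate_scores - report_a$replicate_scores)
  } else NA_real_
  da <- if (is.na(report_a$debiased_score)) report_a$raw_score else report_a$debiased_score
  db <- if (is.na(report_b$debiased_score)) report_b$raw_score else report_b$debiased_score
  list(delta = db - da,
       delta_raw = report_b$raw_score - report_a$raw_score,
       per_site_delta = d, se = se, replicate_sd = rsd)
}

#' Write a fit report to plain text
#'
#' One TSV row per site (1-based site, score, ESS, kappa-hat when available)
#' followed by a '#'-prefixed summary block, plus a flat `key=value` summary
#' file at `paste0(path, ".summary")`.
#'
#' @param fit a `bcv_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  d <- fit$diagnostics
  ids <- if (is.null(fit$site_ids)) seq_along(fit$per_site_scores) - 1L else fit$site_ids
  kap <- if (is.null(d$kappa_per_site)) rep(NA_real_, length(ids)) else d$kappa_per_site
  tab <- data.frame(site = ids + 1L, score = fit$per_site_scores,
                    ess = d$ess_per_site, kappa = kap)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(names(tab), collapse = "\t"), con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("# method=%s score=%.8f bias=%.8f debiased=%.8f verdict=%s",
                     fit$method_tag, fit$raw_score, fit$bias_estimate,
                     fit$debiased_score, d$verdict), con)
  kv <- c(paste0("method=", fit$method_tag),
          paste0("raw_score=", format(fit$raw_score, digits = 12)),
          paste0("bias_estimate=", format(fit$bias_estimate, digits = 12)),
          paste0("debiased_score=", format(fit$debiased_score, digits = 12)),
          paste0("mean_ess=", format(d$mean_ess, digits = 8)),
          paste0("frac_low_ess=", format(d$frac_low_ess, digits = 8)),
          paste0("verdict=", d$verdict))
  writeLines(kv, paste0(path, ".summary"))
  invisible(path)
}
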