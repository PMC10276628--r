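# Metropolis-Hastings MCMC for the fixed-topology amino-acid models, the
# posterior-sampler contract built on it, the sIS adapter with its
# Dirichlet/gamma reference bridge, and the jackknife data-size scaling
# experiment.
#
# Priors: i.i.d. exponential (mean 0.1) on branch lengths, uniform Dirichlet
# on frequencies and (for GTR) exchangeabilities.  A cycle is a sweep of
# multiplicative branch-length proposals plus Dirichlet-walk proposals on the
# free simplex parameters; proposal scales are fixed defaults chosen to give
# moderate acceptance on small trees.

BL_PRIOR_RATE <- 10      # exponential prior with mean 0.1

ldirichlet <- function(x, alpha) {
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g <- pmax(g, 1e-300)
  g / sum(g)
}

# one Dirichlet-walk proposal on a simplex vector; returns the proposal and
# the Hastings log-ratio
dirwalk <- function(x, conc) {
  eps <- 1e-8
  a_fwd <- conc * x + eps
  y <- rdirichlet1(a_fwd)
  a_rev <- conc * y + eps
  list(value = y, lhr = ldirichlet(x, a_rev) - ldirichlet(y, a_fwd))
}

phylo_state_init <- function(kind, nedge, fixed, seed) {
  set.seed(seed)
  list(bl = stats::rexp(nedge, rate = BL_PRIOR_RATE),
       pi = if (is.null(fixed$pi)) rep(1 / 20, 20L) else fixed$pi,
       rho = if (kind == "gtr") rep(1 / 190, 190L) else fixed$rho)
}

# symmetric pair-transfer move on a simplex: shift mass between two random
# coordinates; out-of-support proposals are rejected upstream (NULL)
pair_move <- function(x, frac = 0.3) {
  ij <- sample.int(length(x), 2L)
  s <- frac * (x[ij[1L]] + x[ij[2L]])
  d <- stats::runif(1, -s, s)
  y <- x
  y[ij[1L]] <- x[ij[1L]] + d
  y[ij[2L]] <- x[ij[2L]] - d
  if (any(y[ij] <= 1e-12)) return(NULL)
  list(value = y, lhr = 0)
}

# log prior under the (possibly bridged) reference; bridge = NULL means the
# model prior itself
phylo_log_prior <- function(state, kind, free_pi, bridge = NULL) {
  if (is.null(bridge)) {
    lp <- sum(stats::dexp(state$bl, rate = BL_PRIOR_RATE, log = TRUE))
    if (free_pi) lp <- lp + ldirichlet(state$pi, rep(1, 20L))
    if (kind == "gtr") lp <- lp + ldirichlet(state$rho, rep(1, 190L))
  } else {
    lp <- sum(stats::dgamma(state$bl, shape = bridge$bl_shape,
                            rate = bridge$bl_rate, log = TRUE))
    if (free_pi) lp <- lp + ldirichlet(state$pi, bridge$pi_alpha)
    if (kind == "gtr") lp <- lp + ldirichlet(state$rho, bridge$rho_alpha)
  }
  lp
}

# run `cycles` MCMC cycles; target = sum of site log-likelihoods over
# `sites` (may be empty: prior sampling) plus the (bridged) prior.
# Returns the chain of states, per-cycle log-likelihood vectors over
# `score_sites`, and acceptance statistics.
phylo_mcmc_cycles <- function(aln, tree, kind, free_pi, fixed, state, cycles,
                              sites, seed, bridge = NULL, score_sites = NULL,
                              save_from = 1L, thin = 1L) {
  set.seed(seed)
  te <- tree_edges(tree, aln$taxa)
  nedge <- nrow(te$edge)
  # cache the eigendecomposition across branch-length proposals: it changes
  # only when the simplex parameters move
  cache <- new.env(parent = emptyenv())
  cache$rho <- NULL; cache$pi <- NULL; cache$model <- NULL
  model_of <- function(st) {
    if (is.null(cache$model) || !identical(st$rho, cache$rho) ||
        !identical(st$pi, cache$pi)) {
      cache$model <- subst_model(kind, rho = st$rho, freqs = st$pi)
      cache$rho <- st$rho; cache$pi <- st$pi
    }
    cache$model
  }
  ll_of <- function(st) {
    if (length(sites) == 0L) return(0)
    sum(phylo_sitell(model_of(st), tree, aln, sites = sites, bl = st$bl))
  }
  if (is.null(state)) state <- phylo_state_init(kind, nedge, fixed,
                                                derive_seed(seed, 999L))
  cur_ll <- ll_of(state)
  cur_lp <- phylo_log_prior(state, kind, free_pi, bridge)
  acc <- c(bl = 0, pi = 0, rho = 0); prop <- c(bl = 0, pi = 0, rho = 0)
  saved <- list(); sitells <- list()
  for (cy in seq_len(cycles)) {
    # branch-length sweep (multiplicative proposals)
    for (e in seq_len(nedge)) {
      cand <- state
      mult <- exp(0.8 * (stats::runif(1) - 0.5))
      cand$bl[e] <- state$bl[e] * mult
      cll <- ll_of(cand)
      clp <- phylo_log_prior(cand, kind, free_pi, bridge)
      prop["bl"] <- prop["bl"] + 1
      if (log(stats::runif(1)) < cll - cur_ll + clp - cur_lp + log(mult)) {
        state <- cand; cur_ll <- cll; cur_lp <- clp
        acc["bl"] <- acc["bl"] + 1
      }
    }
    # frequency moves: one Dirichlet walk plus pair transfers
    if (free_pi) {
      pi_props <- c(list(dirwalk(state$pi, 2000)),
                    lapply(1:3, function(z) pair_move(state$pi)))
      for (pw in pi_props) {
        prop["pi"] <- prop["pi"] + 1
        if (is.null(pw)) next
        cand <- state
        cand$pi <- pw$value
        cll <- ll_of(cand)
        clp <- phylo_log_prior(cand, kind, free_pi, bridge)
        if (log(stats::runif(1)) < cll - cur_ll + clp - cur_lp + pw$lhr) {
          state <- cand; cur_ll <- cll; cur_lp <- clp
          acc["pi"] <- acc["pi"] + 1
        }
      }
    }
    # exchangeability moves (GTR): gentle walk plus pair transfers
    if (kind == "gtr") {
      rho_props <- c(list(dirwalk(state$rho, 50000)),
                     lapply(1:5, function(z) pair_move(state$rho)))
      for (rw in rho_props) {
        prop["rho"] <- prop["rho"] + 1
        if (is.null(rw)) next
        cand <- state
        cand$rho <- rw$value
        cll <- ll_of(cand)
        clp <- phylo_log_prior(cand, kind, free_pi, bridge)
        if (log(stats::runif(1)) < cll - cur_ll + clp - cur_lp + rw$lhr) {
          state <- cand; cur_ll <- cll; cur_lp <- clp
          acc["rho"] <- acc["rho"] + 1
        }
      }
    }
    if (cy >= save_from && (cy - save_from) %% thin == 0L) {
      saved[[length(saved) + 1L]] <- state
      if (!is.null(score_sites))
        sitells[[length(sitells) + 1L]] <-
          phylo_sitell(model_of(state), tree, aln, sites = score_sites,
                       bl = state$bl)
    }
  }
  rates <- ifelse(prop > 0, acc / prop, NA_real_)
  if (any(prop > 0 & acc == 0))
    warning("zero acceptance for move type(s): ",
            paste(names(prop)[prop > 0 & acc == 0], collapse = ", "),
            call. = FALSE)
  list(states = saved, sitells = sitells, state = state,
       acceptance = rates)
}

#' Run the phylogenetic MCMC
#'
#' Fixed-topology Metropolis-Hastings sampler.  A cycle sweeps multiplicative
#' proposals over all branch lengths and Dirichlet-walk proposals over the
#' free simplex parameters (frequencies; exchangeabilities for GTR); one
#' draw is saved per `thin` cycles after `burnin`, together with the per-site
#' log-likelihood vector over all alignment sites.
#'
#' @param aln a [bcv_alignment()].
#' @param tree an `ape::phylo` tree (topology held fixed).
#' @param kind `"poisson"`, `"empirical"` or `"gtr"`.
#' @param cycles post-burn-in cycles.
#' @param burnin burn-in cycles.
#' @param thin save one draw per `thin` cycles.
#' @param seed integer seed (same seed, same chain).
#' @param sites 1-based site indices conditioned on (default all; a k-fold
#'   training run conditions on the training sites only).
#' @param exch fixed exchangeabilities/frequencies (list with `rho`, `pi`)
#'   for `kind = "empirical"`, e.g. from [read_paml_matrix()].
#' @param free_pi estimate frequencies even under an empirical matrix.
#' @return List with `draws` (list of states), `sitell` (matrix, all sites x
#'   draws), `acceptance` and the run's settings.
#' @export
mcmc_run <- function(aln, tree, kind = c("poisson", "empirical", "gtr"),
                     cycles = 500L, burnin = 100L, thin = 1L, seed = 1L,
                     sites = NULL, exch = NULL, free_pi = NULL) {
  kind <- match.arg(kind)
  if (kind == "empirical" && is.null(exch))
    stop("empirical model needs exchangeabilities (see read_paml_matrix)",
         call. = FALSE)
  if (is.null(free_pi)) free_pi <- kind != "empirical"
  fixed <- switch(kind,
    poisson = list(rho = rep(1 / 190, 190L), pi = NULL),
    empirical = list(rho = exch$rho, pi = if (free_pi) NULL else exch$pi),
    gtr = list(rho = NULL, pi = NULL))
  if (is.null(sites)) sites <- seq_len(aln$n)
  out <- phylo_mcmc_cycles(aln, tree, kind, free_pi, fixed, NULL,
                           cycles = burnin + cycles, sites = sites,
                           seed = seed, score_sites = seq_len(aln$n),
                           save_from = burnin + 1L, thin = thin)
  list(draws = out$states,
       sitell = do.call(cbind, out$sitells),
       acceptance = out$acceptance,
       kind = kind, sites = sites, seed = seed)
}

#' Posterior-sampler contract for the phylogenetic models
#'
#' Adapts [mcmc_run()] to the [bcv_sampler()] contract used by
#' [score_matrix()]: `draw_posterior` runs a fresh chain conditioned on the
#' training sites, and each returned draw carries its per-site
#' log-likelihood vector over all sites so scoring is a lookup.
#'
#' @param aln a [bcv_alignment()].
#' @param tree an `ape::phylo` tree.
#' @param kind model kind (see [mcmc_run()]).
#' @param burnin,thin MCMC settings per [mcmc_run()].
#' @param exch,free_pi see [mcmc_run()].
#' @return A [bcv_sampler()].
#' @export
phylo_sampler <- function(aln, tree, kind = "poisson", burnin = 100L,
                          thin = 2L, exch = NULL, free_pi = NULL) {
  force(aln); force(tree)
  draw_posterior <- function(training_ids, T, seed) {
    run <- mcmc_run(aln, tree, kind, cycles = T * thin, burnin = burnin,
                    thin = thin, seed = seed, sites = training_ids + 1L,
                    exch = exch, free_pi = free_pi)
    lapply(seq_along(run$draws), function(t)
      c(run$draws[[t]], list(sitell = run$sitell[, t])))
  }
  bcv_sampler(
    draw_posterior = draw_posterior,
    loglik = function(item_id, draw) draw$sitell[item_id + 1L],
    loglik_matrix = function(item_ids, draws)
      vapply(draws, function(d) d$sitell[item_ids + 1L],
             numeric(length(item_ids))),
    log_prior = NULL,
    tag = paste0("phylo-", kind))
}

#' sIS-capable sampler for the phylogenetic models
#'
#' Exposes the Metropolis-Hastings kernel over partial targets
#' `p(columns 1..i-1 | theta) * p_eps(theta)` required by [sis_run()].  The
#' reference family is a geometric bridge between the model prior and a
#' moment-matched fit to a preliminary full-data posterior run: independent
#' gamma distributions on branch lengths and Dirichlet distributions on the
#' free simplex parameters, all closed under the bridge.
#'
#' @inheritParams phylo_sampler
#' @param ref_cycles,ref_burnin preliminary run used to fit the reference.
#' @param ref_seed seed of the preliminary run.
#' @return A sampler usable by [sis_run()].
#' @export
phylo_sis_model <- function(aln, tree, kind = "poisson", exch = NULL,
                            free_pi = NULL, ref_cycles = 200L,
                            ref_burnin = 50L, ref_seed = 1L) {
  kind <- match.arg(kind, c("poisson", "empirical", "gtr"))
  if (is.null(free_pi)) free_pi <- kind != "empirical"
  fixed <- switch(kind,
    poisson = list(rho = rep(1 / 190, 190L), pi = NULL),
    empirical = list(rho = exch$rho, pi = if (free_pi) NULL else exch$pi),
    gtr = list(rho = NULL, pi = NULL))
  pre <- mcmc_run(aln, tree, kind, cycles = ref_cycles, burnin = ref_burnin,
                  seed = ref_seed, exch = exch, free_pi = free_pi)
  # moment-matched exponential-family fits to the preliminary posterior
  bls <- do.call(rbind, lapply(pre$draws, `[[`, "bl"))
  mb <- pmax(colMeans(bls), 1e-8)
  vb <- pmax(apply(bls, 2L, stats::var), 1e-12)
  bl_shape0 <- mb^2 / vb
  bl_rate0 <- mb / vb
  dir_fit <- function(draws_mat) {
    m <- colMeans(draws_mat)
    v <- apply(draws_mat, 2L, stats::var)
    s <- stats::median(m * (1 - m) / pmax(v, 1e-12) - 1)
    pmax(s, 1) * m + 0.01
  }
  pi_alpha0 <- if (free_pi)
    dir_fit(do.call(rbind, lapply(pre$draws, `[[`, "pi"))) else NULL
  rho_alpha0 <- if (kind == "gtr")
    dir_fit(do.call(rbind, lapply(pre$draws, `[[`, "rho"))) else NULL
  bridge_at <- function(eps) {
    list(bl_shape = (1 - eps) * bl_shape0 + eps * 1,
         bl_rate = (1 - eps) * bl_rate0 + eps * BL_PRIOR_RATE,
         pi_alpha = if (free_pi) (1 - eps) * pi_alpha0 + eps * 1 else NULL,
         rho_alpha = if (kind == "gtr") (1 - eps) * rho_alpha0 + eps * 1 else NULL)
  }
  s <- phylo_sampler(aln, tree, kind, exch = exch, free_pi = free_pi)
  s$log_ref <- function(state, eps) {
    phylo_log_prior(state, kind, free_pi, bridge_at(eps))
  }
  s$loglik <- function(item_id, state) {
    m <- subst_model(kind, rho = state$rho, freqs = state$pi)
    phylo_sitell(m, tree, aln, sites = item_id + 1L, bl = state$bl)[1L]
  }
  s$sis_kernel <- function(prefix_ids, epsilon, n_cycles, seed, state) {
    out <- phylo_mcmc_cycles(aln, tree, kind, free_pi, fixed, state,
                             cycles = n_cycles, sites = prefix_ids + 1L,
                             seed = seed, bridge = bridge_at(epsilon))
    list(states = out$states, state = out$state)
  }
  s$improper_prior <- FALSE
  s
}

#' Jackknife data-size scaling experiment
#'
#' Randomly subsamples alignment columns at each requested size, fits each
#' model by MCMC on each subsample, computes the requested scores and reports
#' their mean and standard deviation across replicates.
#'
#' @param aln a [bcv_alignment()].
#' @param tree an `ape::phylo` tree.
#' @param sizes integer vector of column counts (each <= `aln$n`).
#' @param replicates jackknife replicates per size.
#' @param models named list of model argument lists, each with `kind` and
#'   optionally `exch`, `free_pi` (names label the output).
#' @param methods subset of `c("CVl", "waic")`.
#' @param seed integer seed.
#' @param T posterior draws per fit; `burnin`, `thin` MCMC settings.
#' @return A data.frame with one row per (size, model, method, replicate)
#'   plus `score`; aggregate with the returned `summary` attribute (mean and
#'   SD across replicates).
#' @export
jackknife_scaling <- function(aln, tree, sizes, replicates = 2L, models,
                              methods = c("CVl", "waic"), seed = 1L,
                              T = 100L, burnin = 100L, thin = 2L) {
  if (any(sizes > aln$n))
    stop("jackknife size exceeds the number of alignment columns",
         call. = FALSE)
  rows <- list()
  for (sz in sizes) for (rep_i in seq_len(replicates)) {
    set.seed(derive_seed(seed, 7919L * sz + rep_i))
    cols <- sort(sample.int(aln$n, sz, replace = FALSE))
    sub <- bcv_alignment(aln$taxa, aln$states[, cols, drop = FALSE])
    for (mn in names(models)) {
      args <- models[[mn]]
      sampler <- phylo_sampler(sub, tree, kind = args$kind, burnin = burnin,
                               thin = thin, exch = args$exch,
                               free_pi = args$free_pi)
      mat <- score_matrix(sampler, sub$n, NULL, T = T,
                          seed = derive_seed(seed, 13L * sz + rep_i))
      for (meth in methods) {
        fit <- switch(meth, CVl = loo_cpo(mat), waic = waic(mat),
                      stop("unknown method: ", meth, call. = FALSE))
        rows[[length(rows) + 1L]] <- data.frame(
          size = sz, model = mn, method = meth, replicate = rep_i,
          score = fit$raw_score, mean_ess = fit$diagnostics$mean_ess)
      }
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(score ~ size + model + method, out,
                          function(x) c(mean = mean(x), sd = stats::sd(x)))
  attr(out, "summary") <- agg
  out
}
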