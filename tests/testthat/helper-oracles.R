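# Shared test oracles and utilities.

# Exhaustive-enumeration site likelihood: sums over all internal-node state
# assignments; independent of the pruning recursion.
brute_site_loglik <- function(model, tree, column, taxa) {
  te <- bayescv:::tree_edges(tree, taxa)
  Ps <- lapply(seq_len(nrow(te$edge)), function(k)
    bayescv:::aa_transition(model$decomp, te$length[k]))
  internal <- setdiff(seq_len(te$nnode), seq_len(te$ntip))
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  asg <- matrix(NA_integer_, nrow(grid), te$nnode)
  for (tip in seq_len(te$ntip)) asg[, tip] <- column[te$tip_map[tip]]
  asg[, internal] <- grid
  pr <- model$pi[asg[, te$root]]
  for (k in seq_len(nrow(te$edge)))
    pr <- pr * Ps[[k]][cbind(asg[, te$edge[k, 1L]], asg[, te$edge[k, 2L]])]
  log(sum(pr))
}

# Delta-method Monte Carlo standard error of log_mean_exp(v)
lme_se <- function(v) {
  w <- exp(v - max(v))
  stats::sd(w) / (sqrt(length(v)) * mean(w))
}

# aggregate SE for a mean of independent log-mean-exp terms
agg_se <- function(se_vec) sqrt(sum(se_vec^2)) / length(se_vec)

# standard 6-taxon test tree (unrooted, trifurcating root)
test_tree6 <- function() {
  ape::read.tree(text =
    "((A:0.3,B:0.2):0.1,(C:0.25,(D:0.15,E:0.4):0.1):0.05,F:0.35);")
}

test_tree4 <- function() {
  ape::read.tree(text = "(A:0.2,B:0.35,(C:0.4,D:0.08):0.3);")
}

make_diag <- function(ess, kappa = NULL) {
  structure(list(ess_per_site = ess, mean_ess = mean(ess),
                 frac_low_ess = mean(ess <= 10), kappa_per_site = kappa,
                 frac_high_kappa = if (is.null(kappa)) NA_real_ else
                   mean(kappa > 0.7)),
            class = "bcv_diag")
}

# constant-likelihood sampler: loglik(i, theta) == const for every draw
constant_sampler <- function(const = -2) {
  bcv_sampler(
    draw_posterior = function(training_ids, T, seed) as.list(seq_len(T)),
    loglik = function(item_id, draw) const,
    tag = "constant")
}
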