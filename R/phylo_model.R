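# Minimal fixed-topology amino-acid substitution model: rate matrices
# (Poisson, empirical, GTR), pruning likelihood with per-node scaling,
# alignment simulation, and the exchangeability-RMSD accuracy metric.
#
# Amino acids follow the PAML order throughout, the layout in which the
# empirical matrices (LG, WAG, JTT) are distributed.

#' PAML amino-acid ordering
#' @return Character vector of the 20 amino-acid one-letter codes.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Construct an amino-acid alignment
#'
#' @param taxa character vector of taxon names.
#' @param states integer matrix (`length(taxa) x n` sites) of amino-acid
#'   indices in PAML order, `NA` for gap/unknown; or a character matrix of
#'   one-letter codes.
#' @return Object of class `bcv_alignment` with elements `taxa`, `states`
#'   and `n`.
#' @export
bcv_alignment <- function(taxa, states) {
  if (is.character(states)) {
    idx <- match(toupper(states), aa_alphabet())
    idx[toupper(states) %in% c("-", "?", "X")] <- NA_integer_
    bad <- is.na(idx) & !(toupper(states) %in% c("-", "?", "X"))
    if (any(bad))
      stop("invalid amino-acid symbol(s): ",
           paste(unique(states[bad]), collapse = " "), call. = FALSE)
    states <- matrix(idx, nrow = nrow(states))
  }
  stopifnot(nrow(states) == length(taxa), ncol(states) >= 1L)
  structure(list(taxa = taxa, states = states, n = ncol(states)),
            class = "bcv_alignment")
}

#' Substitution model over the 20 amino acids
#'
#' Builds the reversible rate matrix `Q_ab = rho_ab * pi_b` (a != b) from
#' exchangeabilities `rho` (lower-triangular 190-vector, normalized to the
#' simplex) and stationary frequencies `pi`, normalized so the expected
#' number of substitutions per unit branch length at stationarity is one.
#'
#' @param kind `"poisson"` (all exchangeabilities equal), `"empirical"`
#'   (fixed `rho` and `pi`, e.g. from a PAML file) or `"gtr"` (free `rho`).
#' @param rho 190-vector of exchangeabilities (required for `"empirical"`
#'   and as the current value for `"gtr"`; ignored for `"poisson"`).
#' @param freqs 20-vector of stationary frequencies (default uniform).
#' @param name free-text label.
#' @return Object of class `bcv_substmodel` with `rho`, `pi`, `Q` and the
#'   cached symmetric eigendecomposition used for matrix exponentials.
#' @export
subst_model <- function(kind = c("poisson", "empirical", "gtr"),
                        rho = NULL, freqs = NULL, name = NULL) {
  kind <- match.arg(kind)
  if (kind == "poisson" || is.null(rho)) rho <- rep(1, 190L)
  if (is.null(freqs)) freqs <- rep(1 / 20, 20L)
  stopifnot(length(rho) == 190L, all(rho >= 0), length(freqs) == 20L,
            all(freqs > 0))
  rho <- rho / sum(rho)
  freqs <- freqs / sum(freqs)
  dec <- aa_decompose(rho, freqs)
  structure(list(kind = kind, rho = rho, pi = freqs, Q = dec$Q,
                 decomp = dec, name = if (is.null(name)) kind else name),
            class = "bcv_substmodel")
}

# symmetric matrix S from the lower-triangular exchangeability vector
rho_to_S <- function(rho) {
  S <- matrix(0, 20L, 20L)
  S[lower.tri(S)] <- rho
  S + t(S)
}

# rate matrix + eigendecomposition of diag(sqrt(pi)) Q diag(1/sqrt(pi))
aa_decompose <- function(rho, pi) {
  S <- rho_to_S(rho)
  Q <- S * rep(pi, each = 20L)       # Q_ab = S_ab * pi_b
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  sp <- sqrt(pi)
  B <- Q * (sp / rep(sp, each = 20L))  # B_ab = sqrt(pi_a) Q_ab / sqrt(pi_b)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(Q = Q, values = e$values,
       U = e$vectors / sp,                 # diag(1/sqrt(pi)) V
       Uinv = t(e$vectors) * rep(sp, each = 20L))  # V' diag(sqrt(pi))
}

# transition probability matrix P(t) = exp(Qt)
aa_transition <- function(decomp, t) {
  P <- decomp$U %*% (exp(decomp$values * t) * decomp$Uinv)
  P[P < 0] <- 0
  P
}

# edge table in postorder from an ape tree; validates against taxa
tree_edges <- function(tree, taxa) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object",
                                     call. = FALSE)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must carry nonnegative branch lengths", call. = FALSE)
  if (!setequal(tree$tip.label, taxa))
    stop("tree leaf set does not match alignment taxa", call. = FALSE)
  tr <- stats::reorder(tree, "postorder")
  list(edge = tr$edge, length = tr$edge.length,
       ntip = length(tr$tip.label),
       nnode = max(tr$edge),
       root = tr$edge[nrow(tr$edge), 1L],
       tip_map = match(tr$tip.label, taxa))
}

#' Per-site log-likelihoods by pruning
#'
#' Felsenstein's pruning algorithm with per-node log scaling; gap/unknown
#' states contribute all-ones conditional partials (marginalized out).
#'
#' @param model a [subst_model()].
#' @param tree an `ape::phylo` tree with branch lengths, leaves matching the
#'   alignment taxa.
#' @param aln a [bcv_alignment()].
#' @param sites optional 1-based site indices to score (default all).
#' @param bl optional replacement branch lengths in the postorder edge order
#'   (used by the MCMC, which holds the tree fixed).
#' @return Numeric vector of per-site log-likelihoods.
#' @export
phylo_sitell <- function(model, tree, aln, sites = NULL, bl = NULL) {
  te <- tree_edges(tree, aln$taxa)
  if (is.null(sites)) sites <- seq_len(aln$n)
  S <- length(sites)
  states <- aln$states[, sites, drop = FALSE]
  lens <- if (is.null(bl)) te$length else bl
  partial <- vector("list", te$nnode)
  logscale <- numeric(S)
  done <- logical(te$nnode)
  leaf_partial <- function(node) {
    row <- states[te$tip_map[node], ]
    Pm <- matrix(0, 20L, S)
    obs <- !is.na(row)
    Pm[cbind(row[obs], which(obs))] <- 1
    Pm[, !obs] <- 1
    Pm
  }
  for (k in seq_len(nrow(te$edge))) {
    par <- te$edge[k, 1L]; chi <- te$edge[k, 2L]
    cp <- if (chi <= te$ntip) leaf_partial(chi) else partial[[chi]]
    contrib <- aa_transition(model$decomp, lens[k]) %*% cp
    if (!done[par]) {
      partial[[par]] <- contrib
      done[par] <- TRUE
    } else {
      pp <- partial[[par]] * contrib
      cs <- .colSums(pp, 20L, S)
      if (min(cs) < 1e-200) {   # rescale only when underflow threatens
        cs[cs <= 0] <- 1
        pp <- pp / rep(cs, each = 20L)
        logscale <- logscale + log(cs)
      }
      partial[[par]] <- pp
    }
  }
  drop(log(model$pi %*% partial[[te$root]])) + logscale
}

#' Log-likelihood of a single alignment column
#'
#' @inheritParams phylo_sitell
#' @param column integer vector of amino-acid indices (PAML order, `NA` for
#'   gap/unknown), one entry per taxon in `aln`-free usage; here a length-
#'   `ntaxa` vector paired with `taxa`.
#' @param taxa taxon names matching the tree's leaves.
#' @return The site log-likelihood (a number).
#' @export
site_loglik <- function(model, tree, column, taxa) {
  aln <- bcv_alignment(taxa, matrix(column, ncol = 1L))
  phylo_sitell(model, tree, aln)[1L]
}

#' Simulate an alignment under a substitution model on a tree
#'
#' The root state of each site is drawn from the stationary frequencies and
#' evolved along every branch with the model's transition probabilities.
#'
#' @param model a [subst_model()].
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param n number of sites.
#' @param seed integer seed (same seed, same alignment).
#' @return A [bcv_alignment()] over the tree's tip labels.
#' @export
simulate_alignment <- function(model, tree, n, seed = 1L) {
  taxa <- tree$tip.label
  te <- tree_edges(tree, taxa)
  set.seed(seed)
  node_states <- matrix(NA_integer_, te$nnode, n)
  node_states[te$root, ] <- sample.int(20L, n, replace = TRUE,
                                       prob = model$pi)
  # preorder = reversed postorder edges
  for (k in rev(seq_len(nrow(te$edge)))) {
    par <- te$edge[k, 1L]; chi <- te$edge[k, 2L]
    P <- aa_transition(model$decomp, te$length[k])
    P[P < 0] <- 0
    from <- node_states[par, ]
    node_states[chi, ] <- vapply(from, function(a)
      sample.int(20L, 1L, prob = P[a, ]), integer(1))
  }
  bcv_alignment(taxa, node_states[seq_len(te$ntip), , drop = FALSE])
}

#' Root-mean-square deviation between exchangeability vectors
#'
#' `sqrt(mean((a - b)^2))` over the 190 amino-acid pairs, both vectors
#' normalized to the simplex first.
#'
#' @param rho_a,rho_b 190-vectors of exchangeabilities.
#' @return A nonnegative number.
#' @export
rmsd_exchangeabilities <- function(rho_a, rho_b) {
  if (length(rho_a) != 190L || length(rho_b) != 190L)
    stop("exchangeability vectors must have length 190", call. = FALSE)
  a <- rho_a / sum(rho_a); b <- rho_b / sum(rho_b)
  sqrt(mean((a - b)^2))
}
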