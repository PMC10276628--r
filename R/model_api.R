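# Data-splitting machinery and the sampler contract shared by all estimators.
#
# Observations are identified by stable 0-based integer ids so that splits
# remain meaningful after any reordering of the data; printed output uses
# 1-based site numbers (phylogenetic convention).

#' Construct a dataset of exchangeable observations
#'
#' A thin container pairing an ordered collection of observations with stable
#' integer identifiers.  The observations themselves are opaque to the
#' estimators: only the model's log-likelihood function ever looks inside.
#'
#' @param items ordered collection (list, or matrix with one observation per
#'   row) of `n` exchangeable observations.
#' @return An object of class `bcv_dataset` with elements `items`, `n` and
#'   `item_ids` (0-based).
#' @export
bcv_dataset <- function(items) {
  n <- if (is.matrix(items)) nrow(items) else length(items)
  if (n < 1L) stop("dataset must contain at least one observation", call. = FALSE)
  structure(list(items = items, n = as.integer(n),
                 item_ids = seq_len(n) - 1L),
            class = "bcv_dataset")
}

# Counter-based seed derivation: one global seed expands to independent
# per-replicate seeds.  Kept below 2^31 so the result is a valid R seed.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed %% 2147483647L) * 48271 + counter) %% 2147483647)
}

new_split <- function(training_ids, validation_ids, replicate_index) {
  structure(list(training_ids = as.integer(training_ids),
                 validation_ids = as.integer(validation_ids),
                 replicate_index = as.integer(replicate_index)),
            class = "bcv_split")
}

#' Random k-fold style data splits
#'
#' Generates `L` independent random splits of `n` observations, each setting
#' aside a fraction `f` for validation (`r = round(f * n)`, floored at one
#' item) and training on the complement.  Replicates are independent random
#' splits rather than a systematic rotation of k subsets, so `L` is arbitrary.
#'
#' @param n number of observations (>= 2).
#' @param f set-aside fraction in (0, 1); `f = 1/k` corresponds to k-fold CV.
#' @param L number of replicates.
#' @param seed integer seed; splits are reproducible from `(n, f, L, seed)`.
#' @return List of `L` `bcv_split` objects with 0-based ids.
#' @export
make_kfold_splits <- function(n, f = 0.2, L = 10L, seed = 1L) {
  if (!is.numeric(f) || f <= 0 || f >= 1)
    stop("set-aside fraction f must lie strictly between 0 and 1", call. = FALSE)
  if (n < 2L) stop("need at least two observations to split", call. = FALSE)
  r <- max(1L, as.integer(round(f * n)))
  ids <- seq_len(n) - 1L
  lapply(seq_len(L), function(l) {
    set.seed(derive_seed(seed, l))
    v <- sort(sample(ids, r, replace = FALSE))
    new_split(setdiff(ids, v), v, l)
  })
}

#' Leave-one-out data splits
#'
#' One split per observation: split `i` validates on item `i` alone and
#' trains on the remaining `n - 1` items.
#'
#' @param n number of observations (>= 2).
#' @return List of `n` `bcv_split` objects.
#' @export
make_loo_splits <- function(n) {
  if (n < 2L) stop("leave-one-out requires at least two observations", call. = FALSE)
  ids <- seq_len(n) - 1L
  lapply(ids, function(i) new_split(setdiff(ids, i), i, i + 1L))
}

#' Construct a posterior-sampler contract
#'
#' Wraps a Bayesian model behind the behavioural contract the estimators
#' consume.  `draw_posterior(training_ids, T, seed)` must return a list of
#' `T` opaque parameter states approximately distributed as the posterior
#' given the training items (identical output for identical seeds);
#' `loglik(item_id, state)` returns the log-likelihood of one observation
#' under one state.  `loglik_matrix`, if supplied, must return the
#' `length(item_ids) x T` matrix of log-likelihoods in one call and is used
#' as a fast path.  `log_prior(state)` is required only by sequential
#' importance sampling.
#'
#' @param draw_posterior,loglik functions as described above.
#' @param loglik_matrix optional vectorized scorer `(item_ids, states)`.
#' @param log_prior optional log prior density of a state.
#' @param tag free-text model tag recorded in score matrices.
#' @return An object of class `bcv_sampler`.
#' @export
bcv_sampler <- function(draw_posterior, loglik, loglik_matrix = NULL,
                        log_prior = NULL, tag = "model") {
  structure(list(draw_posterior = draw_posterior, loglik = loglik,
                 loglik_matrix = loglik_matrix, log_prior = log_prior,
                 tag = tag),
            class = "bcv_sampler")
}

#' Construct a site log-likelihood matrix
#'
#' The common currency of all estimators: entry `(i, t)` holds
#' `ln p(X_i | theta_t)` for scored item `i` and posterior draw `t`.
#'
#' @param values numeric matrix, rows = scored items, columns = draws.
#' @param row_ids 0-based ids of the scored items.
#' @param training_ids 0-based ids the draws were conditioned on.
#' @param model_tag,run_tag free-text provenance.
#' @return Object of class `bcv_sitell`.
#' @export
bcv_sitell <- function(values, row_ids, training_ids,
                       model_tag = "model", run_tag = "run") {
  values <- as.matrix(values)
  if (ncol(values) < 1L) stop("need at least one posterior draw", call. = FALSE)
  if (nrow(values) != length(row_ids))
    stop("row_ids must label every row of the matrix", call. = FALSE)
  if (any(!is.finite(values)))
    stop("non-finite log-likelihood entries in site matrix", call. = FALSE)
  structure(list(values = unname(values), row_ids = as.integer(row_ids),
                 training_ids = as.integer(training_ids),
                 model_tag = model_tag, run_tag = run_tag),
            class = "bcv_sitell")
}

#' Score items under posterior draws
#'
#' Draws `T` posterior states from `model` conditioned on the split's
#' training items (or on all items when `split` is `NULL`) and evaluates the
#' log-likelihood of every requested item under every draw.
#'
#' @param model a [bcv_sampler()].
#' @param n total number of observations.
#' @param split a `bcv_split`, or `NULL` for full-data conditioning (the
#'   LOO/wAIC setting, where every item is both trained on and scored).
#' @param T number of posterior draws.
#' @param seed integer seed (same seed, same matrix).
#' @param run_tag free-text run label.
#' @return A [bcv_sitell()] whose rows cover the split's validation items
#'   (or all items for full-data conditioning).
#' @export
score_matrix <- function(model, n, split = NULL, T = 1000L, seed = 1L,
                         run_tag = "run") {
  if (T < 1L) stop("need at least one draw", call. = FALSE)
  all_ids <- seq_len(n) - 1L
  if (is.null(split)) {
    training_ids <- all_ids
    row_ids <- all_ids
  } else {
    training_ids <- split$training_ids
    row_ids <- split$validation_ids
  }
  draws <- model$draw_posterior(training_ids, T, seed)
  vals <- if (!is.null(model$loglik_matrix)) {
    model$loglik_matrix(row_ids, draws)
  } else {
    vapply(draws, function(th) vapply(row_ids, model$loglik, numeric(1), th),
           numeric(length(row_ids)))
  }
  vals <- matrix(vals, nrow = length(row_ids))
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite log-likelihood for item %d under draw %d",
                 row_ids[bad[1L]], bad[2L]), call. = FALSE)
  }
  bcv_sitell(vals, row_ids, training_ids, model_tag = model$tag,
             run_tag = run_tag)
}

#' Write / read a site log-likelihood matrix as TSV
#'
#' Plain-text serialization: '#'-prefixed header lines carry the provenance
#' (model tag, run tag, training ids), then one row per site with a 1-based
#' site column followed by `draw_1 .. draw_T`.
#'
#' @param x a `bcv_sitell`.
#' @param path file path.
#' @return `write_sitell` returns `path` invisibly; `read_sitell` returns the
#'   reconstructed `bcv_sitell`.
#' @export
write_sitell <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#model_tag=", x$model_tag),
               paste0("#run_tag=", x$run_tag),
               paste0("#training_ids=", paste(x$training_ids, collapse = ","))),
             con)
  hdr <- c("site", paste0("draw_", seq_len(ncol(x$values))))
  writeLines(paste(hdr, collapse = "\t"), con)
  tab <- cbind(x$row_ids + 1L, format(x$values, digits = 17, trim = TRUE))
  writeLines(apply(tab, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_sitell
#' @export
read_sitell <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getf <- function(key) sub(paste0("^#", key, "="), "",
                            grep(paste0("^#", key, "="), hdr, value = TRUE)[1L])
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.delim(text = body, header = TRUE, check.names = FALSE)
  tr <- getf("training_ids")
  tr <- if (nzchar(tr) && !is.na(tr)) as.integer(strsplit(tr, ",")[[1L]]) else integer(0)
  bcv_sitell(as.matrix(tab[, -1L, drop = FALSE]), as.integer(tab$site) - 1L,
             tr, model_tag = getf("model_tag"), run_tag = getf("run_tag"))
}
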