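#' Balanced cross-validation folds
#'
#' Random partition of `n` items into `n_folds` folds whose sizes differ
#' by at most one, so each sequence is tested once and used for training
#' `n_folds - 1` times.  Seeded independently of the sampler.
#'
#' @param n number of items
#' @param n_folds number of folds (default 5)
#' @param seed fold seed
#' @return integer vector of fold labels in 1..n_folds
#' @export
make_folds <- function(n, n_folds = 5L, seed = 1L) {
  n <- stop_if_not_scalar_count(n, "n")
  n_folds <- stop_if_not_scalar_count(n_folds, "n_folds")
  if (n < n_folds) stop("need at least as many sequences as folds")
  withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
}

#' Cross-validated held-out likelihood of one model structure
#'
#' For each fold, fits the model on the remaining four fifths — one
#' chain per restart, each retained state refined to its local mode with
#' [polish_state()], keeping the best refined state — and scores the
#' held-out fifth with the marginal mixture likelihood (held-out labels
#' are unknown, so architectures are integrated out against the
#' estimated weights).
#'
#' @param X a [seq_matrix()]
#' @param structure a [model_structure()]
#' @param prior a [prior_spec()]
#' @param config a [sampler_config()]; fold f uses sampler seed
#'   `config$seed + f`
#' @param folds optional precomputed fold labels from [make_folds()]
#' @param n_folds number of folds when `folds` is NULL
#' @param fold_seed fold seed when `folds` is NULL
#' @return list with `per_fold` held-out log-likelihoods, their `mean`,
#'   the fold-trained `models`, and the `folds` used
#' @export
cross_validate <- function(X, structure, prior = prior_spec(),
                           config = sampler_config(), folds = NULL,
                           n_folds = 5L, fold_seed = 1L) {
  n <- nrow(X$data)
  folds <- folds %||% make_folds(n, n_folds, fold_seed)
  if (length(folds) != n) stop("`folds` must label every sequence")
  ids <- sort(unique(folds))
  per_fold <- numeric(length(ids))
  models <- vector("list", length(ids))
  for (f in seq_along(ids)) {
    test <- folds == ids[f]
    cfg <- config
    cfg$seed <- config$seed + f
    tr <- X[!test, ]
    fit <- search_best_state(tr, structure, prior, cfg)
    models[[f]] <- estimate_parameters(
      fit$state, prior, tss_offset = X$tss_offset,
      score = fit$score, seed = cfg$seed, drop_empty = TRUE
    )
    per_fold[f] <- dataset_log_likelihood(X[test, ], models[[f]], "marginal")
  }
  list(per_fold = per_fold, mean = mean(per_fold), models = models,
       folds = folds)
}

#' Structure search by cross-validated likelihood
#'
#' Evaluates every (k, p) cell of the grid with the same folds, selects
#' the cell with the highest mean held-out log-likelihood (ties broken
#' towards the smallest k, then the smallest p), and refits the selected
#' structure on the full dataset with a fresh restart budget.
#'
#' @param X a [seq_matrix()]
#' @param k_values integer vector of architecture counts to try
#' @param p_values integer vector of important-position counts (applied
#'   uniformly to all architectures of a model)
#' @param prior a [prior_spec()]
#' @param config a [sampler_config()] for the fold fits; cell c uses
#'   sampler seed `config$seed + 997 * (c - 1)`
#' @param n_folds number of folds (default 5)
#' @param fold_seed seed for the fold partition
#' @param refit_config optional [sampler_config()] for the final full-data
#'   refit (defaults to `config`)
#' @param keep_models keep the fold-trained models in the report
#' @return an object of class `cv_report`: `table` (one row per grid cell
#'   with per-fold and mean held-out log-likelihoods and a `selected`
#'   flag), `selected` (k, p), `final_model`, `folds`, and optionally
#'   `cells` with fold models
#' @export
select_model <- function(X, k_values, p_values, prior = prior_spec(),
                         config = sampler_config(), n_folds = 5L,
                         fold_seed = 1L, refit_config = NULL,
                         keep_models = FALSE) {
  if (!length(k_values) || !length(p_values)) stop("the search grid is empty")
  l <- ncol(X$data)
  if (any(p_values > l)) stop("`p_values` must not exceed the window length")
  grid <- expand.grid(p = sort(unique(as.integer(p_values))),
                      k = sort(unique(as.integer(k_values))))[, c("k", "p")]
  grid <- grid[order(grid$k, grid$p), , drop = FALSE]
  folds <- make_folds(nrow(X$data), n_folds, fold_seed)
  rows <- vector("list", nrow(grid))
  cells <- if (keep_models) vector("list", nrow(grid))
  for (cell in seq_len(nrow(grid))) {
    cfg <- config
    cfg$seed <- config$seed + 997L * (cell - 1L)
    cv <- cross_validate(X, model_structure(grid$k[cell], grid$p[cell]),
                         prior, cfg, folds = folds)
    rows[[cell]] <- data.frame(
      k = grid$k[cell], p = grid$p[cell], t(cv$per_fold),
      mean_heldout_loglik = cv$mean
    )
    if (keep_models) cells[[cell]] <- cv
  }
  tab <- do.call(rbind, rows)
  names(tab)[3:(2 + n_folds)] <- sprintf("fold_%d", seq_len(n_folds))
  best <- which.max(tab$mean_heldout_loglik)  # grid sorted: ties -> smallest k, p
  tab$selected <- seq_len(nrow(tab)) == best
  refit_config <- refit_config %||% config
  final_model <- fit_model(X, tab$k[best], tab$p[best], prior, refit_config)
  structure(
    list(table = tab, selected = list(k = tab$k[best], p = tab$p[best]),
         final_model = final_model, folds = folds,
         cells = if (keep_models) cells),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d grid cells; selected k = %d, p = %d\n",
              nrow(x$table), x$selected$k, x$selected$p))
  print(x$table[, c("k", "p", "mean_heldout_loglik", "selected")],
        row.names = FALSE)
  invisible(x)
}

#' Export a cross-validation report as TSV
#'
#' Long format: one row per (k, p, fold) with the fold's held-out
#' log-likelihood, the cell mean, and a 0/1 selected flag.
#'
#' @param report a `cv_report` from [select_model()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  tab <- report$table
  fold_cols <- grep("^fold_", names(tab))
  long <- do.call(rbind, lapply(seq_len(nrow(tab)), function(r) {
    data.frame(
      k = tab$k[r], p = tab$p[r], fold = seq_along(fold_cols),
      heldout_loglik = as.numeric(tab[r, fold_cols]),
      mean_heldout_loglik = tab$mean_heldout_loglik[r],
      selected = as.integer(tab$selected[r])
    )
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
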