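#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement (Hubert-Arabie) computed from the label
#' contingency table: 1 for identical partitions (up to relabeling), 0 in
#' expectation for independent random groupings.  Labels may come from
#' arbitrary alphabets.
#'
#' @param labels_a,labels_b equal-length label vectors
#' @return a single numeric index (at most 1)
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("the two label vectors must have the same length")
  }
  if (length(labels_a) < 2L) stop("need at least two items")
  if (length(unique(labels_a)) == 1L && length(unique(labels_b)) == 1L) {
    return(1)  # both trivial one-cluster partitions: identical
  }
  as.numeric(mclust::adjustedRandIndex(labels_a, labels_b))
}

#' Held-out likelihood versus partition recovery across a structure grid
#'
#' For every (k, p) grid cell: the mean cross-validated held-out
#' log-likelihood, and the adjusted Rand index of each fold-trained
#' model's full-data MAP assignment against the ground-truth partition,
#' averaged over folds.  The likelihood axis is what model selection
#' sees; the ARI axis is what it would need the truth to compute.
#'
#' @param X a [seq_matrix()]
#' @param truth a `simulation_truth` (or any vector of true labels)
#' @param k_values,p_values structure grid
#' @param prior a [prior_spec()]
#' @param config a [sampler_config()]
#' @param n_folds number of folds
#' @param fold_seed fold seed
#' @return data frame with columns k, p, mean_heldout_loglik, mean_ari
#' @export
likelihood_vs_ari_table <- function(X, truth, k_values, p_values,
                                    prior = prior_spec(),
                                    config = sampler_config(),
                                    n_folds = 5L, fold_seed = 1L) {
  true_labels <- if (inherits(truth, "simulation_truth")) truth$labels else truth
  if (length(true_labels) != nrow(X$data)) {
    stop("truth labels must cover every sequence")
  }
  grid <- expand.grid(p = sort(unique(as.integer(p_values))),
                      k = sort(unique(as.integer(k_values))))[, c("k", "p")]
  grid <- grid[order(grid$k, grid$p), , drop = FALSE]
  folds <- make_folds(nrow(X$data), n_folds, fold_seed)
  rows <- lapply(seq_len(nrow(grid)), function(cell) {
    cfg <- config
    cfg$seed <- config$seed + 997L * (cell - 1L)
    cv <- cross_validate(X, model_structure(grid$k[cell], grid$p[cell]),
                         prior, cfg, folds = folds)
    aris <- vapply(cv$models, function(m) {
      adjusted_rand_index(assign_architectures(m, X)$map, true_labels)
    }, numeric(1))
    data.frame(k = grid$k[cell], p = grid$p[cell],
               mean_heldout_loglik = cv$mean, mean_ari = mean(aris))
  })
  do.call(rbind, rows)
}
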