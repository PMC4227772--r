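#' Sampler configuration
#'
#' @param n_iterations Gibbs sweeps per restart (each sweep holds out every
#'   sequence in turn, resamples its architecture, then resamples the
#'   important positions of that architecture)
#' @param n_restarts independent random restarts; the overall best-scoring
#'   state across restarts is reported
#' @param seed master seed; restart r uses a stream derived from (seed, r)
#'   only, so results never depend on other restarts
#' @param record_trace record per-iteration collapsed scores
#' @return an object of class `sampler_config`
#' @export
sampler_config <- function(n_iterations = 300L, n_restarts = 10L, seed = 1L,
                           record_trace = FALSE) {
  n_iterations <- stop_if_not_scalar_count(n_iterations, "n_iterations")
  n_restarts <- stop_if_not_scalar_count(n_restarts, "n_restarts")
  structure(
    list(n_iterations = n_iterations, n_restarts = n_restarts,
         seed = as.integer(seed), record_trace = isTRUE(record_trace)),
    class = "sampler_config"
  )
}

#' Run the collapsed Gibbs sampler
#'
#' Initializes labels uniformly and each important-position set as a
#' uniform random subset, then iterates: hold out each sequence, draw its
#' architecture from the exact collapsed conditional, and run one
#' cardinality-preserving swap sweep over the important positions of the
#' architecture just sampled.  After every sweep the collapsed joint score
#' is recorded and the first-reached maximum-score state is retained;
#' across restarts the overall best is returned.
#'
#' @param X a [seq_matrix()]
#' @param structure a [model_structure()]
#' @param prior a [prior_spec()]
#' @param config a [sampler_config()]
#' @param .record_states internal: also return the per-iteration latent
#'   states (single-restart, small problems only)
#' @return an object of class `chain_result` with elements `best_state`
#'   (a [model_state()]), `best_score`, `score_trace` (data frame when
#'   recorded), and `final` (end-of-chain internal tables, for audits)
#' @export
run_chain <- function(X, structure, prior = prior_spec(),
                      config = sampler_config(), .record_states = FALSE) {
  stopifnot(inherits(X, "seq_matrix"), inherits(structure, "model_structure"))
  l <- ncol(X$data)
  if (any(structure$p > l)) stop("important-position count exceeds window length")
  res <- cpp_run_chain(
    X$data, structure$k, structure$p, prior$pseudocount,
    config$n_iterations, config$n_restarts, config$seed,
    config$record_trace, .record_states
  )
  best_state <- model_state(X, res$best_y, res$best_I)
  out <- list(
    best_state = best_state,
    best_score = res$best_score,
    score_trace = if (config$record_trace) {
      data.frame(restart = res$trace[, 1L], iteration = res$trace[, 2L],
                 posterior_score = res$trace[, 3L])
    },
    final = res[c("final_y", "final_I", "final_counts", "final_bgc",
                  "final_bgtot", "final_sizes", "final_score")]
  )
  if (.record_states && !is.null(res$y_trace)) {
    out$y_trace <- res$y_trace
    out$imp_trace <- res$imp_trace
  }
  class(out) <- "chain_result"
  out
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf("<chain_result> best collapsed score %.4f, k = %d\n",
              x$best_score, x$best_state$k))
  invisible(x)
}

#' Fit a model of fixed structure
#'
#' Convenience wrapper: one chain per restart, each retained state
#' refined to its local mode with [polish_state()], the best refined
#' state estimated with [estimate_parameters()].
#'
#' @inheritParams run_chain
#' @param k number of architectures
#' @param p important positions per architecture (scalar or length-k)
#' @return a `promarch_model`
#' @export
fit_model <- function(X, k, p, prior = prior_spec(),
                      config = sampler_config()) {
  fit <- search_best_state(X, model_structure(k, p), prior, config)
  estimate_parameters(fit$state, prior, tss_offset = X$tss_offset,
                      score = fit$score, seed = config$seed,
                      drop_empty = TRUE)
}

#' Exact collapsed conditional for one sequence's architecture
#'
#' Probability vector `P(y_i = u | y_{-i}, I, X)` with sequence `i` held
#' out of all count tables, computed from the Dirichlet-multinomial
#' predictive.  Exposed for audit; [run_chain()] draws from exactly this
#' conditional.
#'
#' @param X a [seq_matrix()]
#' @param y full label vector (entry `i` is ignored)
#' @param I list of important-position sets
#' @param i sequence index
#' @param prior a [prior_spec()]
#' @return numeric vector of k probabilities summing to 1
#' @export
assignment_conditional <- function(X, y, I, i, prior = prior_spec()) {
  stopifnot(inherits(X, "seq_matrix"))
  cpp_assignment_probs(X$data, as.integer(y), lapply(I, as.integer),
                       as.integer(i), prior$pseudocount)
}

#' Collapsed score log-ratio of a position swap
#'
#' Log ratio of the collapsed joint scores after versus before moving
#' position `j_out` out of, and `j_in` into, the important set of
#' architecture `u`.  The swap sweep inside [run_chain()] accepts each
#' proposal with probability `1 / (1 + exp(-delta))`.
#'
#' @inheritParams assignment_conditional
#' @param u architecture index
#' @param j_in position to include (currently unimportant for `u`)
#' @param j_out position to exclude (currently important for `u`)
#' @return a single numeric log-ratio
#' @export
swap_log_ratio <- function(X, y, I, u, j_in, j_out, prior = prior_spec()) {
  stopifnot(inherits(X, "seq_matrix"))
  cpp_swap_delta(X$data, as.integer(y), lapply(I, as.integer),
                 as.integer(u), as.integer(j_in), as.integer(j_out),
                 prior$pseudocount)
}
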