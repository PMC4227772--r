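#' Symmetric Dirichlet prior specification
#'
#' One pseudocount applied symmetrically to the mixture weights and to
#' every positional nucleotide distribution (architecture-specific and
#' background alike).
#'
#' @param pseudocount positive real, default 1
#' @return an object of class `prior_spec`
#' @export
prior_spec <- function(pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      is.na(pseudocount) || pseudocount <= 0) {
    stop("`pseudocount` must be a single positive number")
  }
  structure(list(pseudocount = as.numeric(pseudocount)), class = "prior_spec")
}

#' Model structure: number of architectures and important-position counts
#'
#' @param k number of architectures (>= 1)
#' @param p important-position count per architecture; a single value is
#'   recycled to all `k` architectures
#' @return an object of class `model_structure`
#' @export
model_structure <- function(k, p) {
  k <- stop_if_not_scalar_count(k, "k")
  p <- as.integer(p)
  if (length(p) == 1L) p <- rep(p, k)
  if (length(p) != k) stop("`p` must have length 1 or k")
  if (anyNA(p) || any(p < 0L)) stop("`p` entries must be >= 0")
  structure(list(k = k, p = p), class = "model_structure")
}

#' Sufficient-statistic state of the collapsed model
#'
#' Builds the count tables implied by a complete latent configuration:
#' labels `y` and important-position sets `I`.  `arch_counts[[u]]` holds
#' the 4 x p_u nucleotide counts of architecture `u` at its important
#' positions; `bg_counts` holds, per position, the counts contributed by
#' every sequence whose architecture does not deem that position
#' important.
#'
#' @param X a [seq_matrix()]
#' @param y integer labels in 1..k, one per sequence
#' @param I list of k integer vectors of important positions (1-based
#'   column indices)
#' @return an object of class `model_state`
#' @export
model_state <- function(X, y, I) {
  stopifnot(inherits(X, "seq_matrix"))
  n <- nrow(X$data); l <- ncol(X$data); k <- length(I)
  y <- as.integer(y)
  if (length(y) != n) stop("`y` must have one label per sequence")
  if (n > 0L && (anyNA(y) || any(y < 1L) || any(y > k))) {
    stop("labels must lie in 1..k")
  }
  I <- lapply(I, function(iu) {
    iu <- as.integer(sort(iu))
    if (anyNA(iu) || any(iu < 1L) || any(iu > l) || anyDuplicated(iu)) {
      stop("important positions must be distinct column indices in 1..l")
    }
    iu
  })
  size_counts <- tabulate(y, nbins = k)
  arch_counts <- vector("list", k)
  member_cols <- vector("list", k)  # 4 x l counts over members, all positions
  for (u in seq_len(k)) {
    rows <- which(y == u)
    cc <- matrix(0L, 4L, l, dimnames = list(NUC, NULL))
    if (length(rows)) {
      for (b in 0:3) {
        cc[b + 1L, ] <- colSums(X$data[rows, , drop = FALSE] == b)
      }
    }
    member_cols[[u]] <- cc
    arch_counts[[u]] <- cc[, I[[u]], drop = FALSE]
    colnames(arch_counts[[u]]) <- I[[u]]
  }
  col_tot <- matrix(0L, 4L, l, dimnames = list(NUC, NULL))
  for (b in 0:3) col_tot[b + 1L, ] <- colSums(X$data == b)
  bg_counts <- col_tot
  bg_n <- rep(n, l)
  for (u in seq_len(k)) {
    if (length(I[[u]])) {
      bg_counts[, I[[u]]] <- bg_counts[, I[[u]]] -
        member_cols[[u]][, I[[u]], drop = FALSE]
      bg_n[I[[u]]] <- bg_n[I[[u]]] - size_counts[u]
    }
  }
  structure(
    list(y = y, I = I, arch_counts = arch_counts, bg_counts = bg_counts,
         size_counts = size_counts, n = n, l = l, k = k),
    class = "model_state"
  )
}

# Integrity check used by the collapsed score: per-position contributions
# (architecture tables where important + background elsewhere) must account
# for every sequence exactly once.
check_state_consistency <- function(state) {
  with(state, {
    if (sum(size_counts) != n) stop("size counts do not sum to n")
    contrib <- colSums(bg_counts)
    for (u in seq_len(k)) {
      if (length(I[[u]])) {
        if (!all(colSums(arch_counts[[u]]) == size_counts[u])) {
          stop("architecture count table inconsistent with its occupancy")
        }
        contrib[I[[u]]] <- contrib[I[[u]]] + size_counts[u]
      }
    }
    if (!all(contrib == n)) {
      stop("architecture + background contributions do not sum to n at every position")
    }
  })
  invisible(TRUE)
}

# log Dirichlet-multinomial marginal of one count vector under a symmetric
# Dirichlet(a) prior.
dirmult_log <- function(counts, a) {
  counts <- as.numeric(counts)
  d <- length(counts)
  lgamma(d * a) - lgamma(sum(counts) + d * a) +
    sum(lgamma(counts + a)) - d * lgamma(a)
}

#' Collapsed joint posterior score of a latent configuration
#'
#' Returns `log P(X, y, I | structure)` with all categorical parameters
#' integrated out under the symmetric Dirichlet prior: the sum of
#' Dirichlet-multinomial marginal log-likelihoods of the occupancy vector,
#' of every architecture-specific positional count table, and of every
#' background positional count table.  (The uniform prior over
#' position-set choices is a structure constant and omitted.)  This is the
#' quantity the sampler maximises when retaining its best state.
#'
#' @param state a [model_state()]
#' @param prior a [prior_spec()]
#' @return a single numeric log score (0 for empty data)
#' @export
posterior_score <- function(state, prior = prior_spec()) {
  stopifnot(inherits(state, "model_state"))
  check_state_consistency(state)
  a <- prior$pseudocount
  sc <- dirmult_log(state$size_counts, a)
  for (u in seq_len(state$k)) {
    ac <- state$arch_counts[[u]]
    if (ncol(ac)) {
      for (j in seq_len(ncol(ac))) sc <- sc + dirmult_log(ac[, j], a)
    }
  }
  for (j in seq_len(state$l)) {
    sc <- sc + dirmult_log(state$bg_counts[, j], a)
  }
  sc
}

#' Point estimates from a collapsed state: the fitted model
#'
#' Posterior-mean estimates under the symmetric Dirichlet prior (never
#' maximum likelihood), so no probability is ever zero and log-odds are
#' always finite: mixture weights `(size_u + a) / (n + k a)` and
#' nucleotide probabilities `(count + a) / (total + 4 a)`.  An empty
#' architecture falls back to the prior mean (uniform).
#'
#' With `drop_empty = TRUE` (used by the fitting wrappers), architectures
#' that ended up with no member sequences are removed before estimation
#' and the mixture weights are computed over the realized architectures
#' only: an unoccupied slot carries no data support and is not part of
#' the reported model, so a fit whose extra slot stays empty yields
#' exactly the same fitted model as the smaller structure on the same
#' partition.
#'
#' @param state a [model_state()]
#' @param prior a [prior_spec()]
#' @param tss_offset 1-based TSS column of the windows the model was fit to
#' @param score optional collapsed score to record with the model
#' @param seed optional RNG seed provenance to record
#' @param drop_empty remove unoccupied architectures before estimation
#' @return an object of class `promarch_model`
#' @export
estimate_parameters <- function(state, prior = prior_spec(), tss_offset = 1L,
                                score = NA_real_, seed = NA_integer_,
                                drop_empty = FALSE) {
  stopifnot(inherits(state, "model_state"))
  if (isTRUE(drop_empty) && any(state$size_counts == 0L) &&
      any(state$size_counts > 0L)) {
    occ <- which(state$size_counts > 0L)
    # an empty architecture contributes no counts anywhere, so dropping
    # it only subsets the per-architecture tables and relabels y
    state$y <- match(state$y, occ)
    state$I <- state$I[occ]
    state$arch_counts <- state$arch_counts[occ]
    state$size_counts <- state$size_counts[occ]
    state$k <- length(occ)
  }
  a <- prior$pseudocount
  n <- state$n; k <- state$k; l <- state$l
  gamma_hat <- (state$size_counts + a) / (n + k * a)
  labs <- tss_labels(l, tss_offset)
  phi_arch <- vector("list", k)
  for (u in seq_len(k)) {
    ac <- state$arch_counts[[u]]
    ph <- sweep(ac + a, 2L, colSums(ac) + 4 * a, "/")
    dimnames(ph) <- list(NUC, labs[state$I[[u]]])
    phi_arch[[u]] <- ph
  }
  bg_n <- colSums(state$bg_counts)
  phi_bg <- sweep(state$bg_counts + a, 2L, bg_n + 4 * a, "/")
  dimnames(phi_bg) <- list(NUC, labs)
  structure(
    list(
      structure = model_structure(k, lengths(state$I)),
      gamma_hat = gamma_hat,
      phi_arch = phi_arch,
      phi_bg = phi_bg,
      I = state$I,
      tss_offset = as.integer(tss_offset),
      prior = prior,
      score = score,
      seed = seed,
      state = state
    ),
    class = "promarch_model"
  )
}

#' @export
print.promarch_model <- function(x, ...) {
  cat(sprintf(
    "<promarch_model> k = %d architectures over %d positions (TSS at column %d)\n",
    x$structure$k, ncol(x$phi_bg), x$tss_offset
  ))
  cat("  important positions per architecture:",
      paste(x$structure$p, collapse = ", "), "\n")
  cat("  mixture weights:",
      paste(sprintf("%.3f", x$gamma_hat), collapse = ", "), "\n")
  if (is.finite(x$score)) cat(sprintf("  collapsed score: %.3f\n", x$score))
  invisible(x)
}

# Full 4 x l log-probability matrix of architecture u: architecture columns
# at important positions, shared background elsewhere.
log_prob_matrix <- function(model, u) {
  lp <- log(model$phi_bg)
  iu <- model$I[[u]]
  if (length(iu)) lp[, iu] <- log(model$phi_arch[[u]])
  lp
}

# n x k matrix of per-sequence, per-architecture log-likelihoods.
loglik_matrix <- function(model, X) {
  xd <- if (inherits(X, "seq_matrix")) X$data else X
  if (ncol(xd) != ncol(model$phi_bg)) {
    stop("sequence length does not match the model window length")
  }
  n <- nrow(xd); l <- ncol(xd); k <- model$structure$k
  idx <- cbind(as.vector(xd) + 1L, rep(seq_len(l), each = n))
  out <- matrix(0, n, k)
  for (u in seq_len(k)) {
    lp <- log_prob_matrix(model, u)
    out[, u] <- rowSums(matrix(lp[idx], n, l))
  }
  out
}

# Per-sequence marginal (mixture) log-likelihood under a fitted model.
sequence_marginal_ll <- function(model, X) {
  ll <- loglik_matrix(model, X)
  row_logsumexp(sweep(ll, 2L, log(model$gamma_hat), "+"))
}

#' Log-likelihood of one sequence under one architecture
#'
#' Product of categorical probabilities: architecture-specific
#' distributions at the important positions, the shared background at all
#' others, on the log scale.  `-Inf` is permitted when a probability is
#' exactly zero (cannot occur with posterior-mean estimates).
#'
#' @param x an encoded sequence (integer codes 0..3) or a single DNA string
#' @param u architecture index in 1..k
#' @param model a `promarch_model`
#' @return a single numeric log-likelihood
#' @export
sequence_log_likelihood <- function(x, u, model) {
  if (is.character(x)) x <- encode_sequences(x)$data[1L, ]
  if (inherits(x, "seq_matrix")) x <- x$data[1L, ]
  x <- as.integer(x)
  l <- ncol(model$phi_bg)
  if (length(x) != l) stop("sequence length does not match the model window length")
  u <- as.integer(u)
  if (u < 1L || u > model$structure$k) stop("architecture index out of range")
  lp <- log_prob_matrix(model, u)
  sum(lp[cbind(x + 1L, seq_len(l))])
}

#' Log-likelihood of a dataset under a fitted model
#'
#' With explicit labels, the sum of per-sequence architecture-conditional
#' terms.  With `assignments = "marginal"` (the default, and the form used
#' for held-out scoring), architectures are integrated out against the
#' estimated mixture weights: `sum_i log sum_u gamma_u P(X_i | u)`.
#'
#' @param X a [seq_matrix()] (or bare coded matrix)
#' @param model a `promarch_model`
#' @param assignments `"marginal"` or an integer label vector in 1..k
#' @return a single numeric log-likelihood
#' @export
dataset_log_likelihood <- function(X, model, assignments = "marginal") {
  ll <- loglik_matrix(model, X)
  if (identical(assignments, "marginal")) {
    return(sum(row_logsumexp(sweep(ll, 2L, log(model$gamma_hat), "+"))))
  }
  lab <- as.integer(assignments)
  if (length(lab) != nrow(ll)) stop("need one label per sequence")
  if (anyNA(lab) || any(lab < 1L) || any(lab > model$structure$k)) {
    stop("labels must lie in 1..k")
  }
  sum(ll[cbind(seq_len(nrow(ll)), lab)])
}
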