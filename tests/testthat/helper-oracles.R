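# Independent oracles used across the suite.  All are written from first
# principles (sequential chain-rule predictives, exhaustive enumeration,
# O(n^2) pairwise counts) and never call the code paths they check.

# Collapsed joint score log P(X, y, I) via the chain rule: process
# sequences one at a time, multiplying Dirichlet-categorical predictive
# probabilities and updating counts.  By exchangeability this equals the
# closed-form Dirichlet-multinomial product the package computes with
# lgamma, but shares no code with it.
oracle_collapsed_score <- function(xd, y, I, a = 1) {
  n <- nrow(xd); l <- ncol(xd); k <- length(I)
  size <- rep(0, k)
  ac <- lapply(seq_len(k), function(u) matrix(0, 4, l))
  bg <- matrix(0, 4, l)
  bgn <- rep(0, l)
  logp <- 0
  for (i in seq_len(n)) {
    u <- y[i]
    logp <- logp + log((size[u] + a) / (i - 1 + k * a))
    for (j in seq_len(l)) {
      b <- xd[i, j] + 1
      if (j %in% I[[u]]) {
        logp <- logp + log((ac[[u]][b, j] + a) / (size[u] + 4 * a))
      } else {
        logp <- logp + log((bg[b, j] + a) / (bgn[j] + 4 * a))
      }
    }
    size[u] <- size[u] + 1
    for (j in seq_len(l)) {
      b <- xd[i, j] + 1
      if (j %in% I[[u]]) {
        ac[[u]][b, j] <- ac[[u]][b, j] + 1
      } else {
        bg[b, j] <- bg[b, j] + 1
        bgn[j] <- bgn[j] + 1
      }
    }
  }
  logp
}

# Exhaustive assignment conditional: enumerate the k completions of y[i]
# and normalise their collapsed scores.
oracle_assignment_probs <- function(xd, y, I, i, a = 1) {
  k <- length(I)
  sc <- vapply(seq_len(k), function(u) {
    yy <- y
    yy[i] <- u
    oracle_collapsed_score(xd, yy, I, a)
  }, numeric(1))
  w <- exp(sc - max(sc))
  w / sum(w)
}

# Exhaustive position-set posterior for architecture u with |I_u| = p,
# holding all other architectures' sets and all labels fixed.
oracle_position_set_probs <- function(xd, y, I, u, p, a = 1) {
  l <- ncol(xd)
  sets <- utils::combn(l, p, simplify = FALSE)
  sc <- vapply(sets, function(s) {
    II <- I
    II[[u]] <- s
    oracle_collapsed_score(xd, y, II, a)
  }, numeric(1))
  w <- exp(sc - max(sc))
  list(sets = sets, probs = w / sum(w))
}

# AUC by exhaustive pairwise comparison (Mann-Whitney, ties counted half).
oracle_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Hubert-Arabie adjusted Rand index from a hand-built contingency table.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_nij <- sum(ch2(tab))
  sum_ai <- sum(ch2(rowSums(tab)))
  sum_bj <- sum(ch2(colSums(tab)))
  ntot <- ch2(length(a))
  expected <- sum_ai * sum_bj / ntot
  (sum_nij - expected) / ((sum_ai + sum_bj) / 2 - expected)
}

# Small random dataset helper.
random_seq_matrix <- function(n, l, seed = 1) {
  withr::with_seed(seed,
    seq_matrix(matrix(sample.int(4L, n * l, replace = TRUE) - 1L, n, l)))
}

# Random valid latent configuration for a given structure.
random_config <- function(n, l, k, p, seed = 1) {
  withr::with_seed(seed, list(
    y = sample.int(k, n, replace = TRUE),
    I = lapply(seq_len(k), function(u) sort(sample.int(l, p)))
  ))
}
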