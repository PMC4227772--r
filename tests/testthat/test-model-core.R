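test_that("sequence log-likelihood matches a naive per-position product", {
  l <- 5
  X <- random_seq_matrix(6, l, seed = 11)
  cfg <- random_config(6, l, k = 2, p = 2, seed = 12)
  st <- model_state(X, cfg$y, cfg$I)
  model <- estimate_parameters(st)
  for (u in 1:2) {
    for (i in 1:6) {
      x <- X$data[i, ]
      naive <- 0
      for (j in seq_len(l)) {
        ph <- if (j %in% cfg$I[[u]]) {
          model$phi_arch[[u]][, match(j, cfg$I[[u]])]
        } else {
          model$phi_bg[, j]
        }
        naive <- naive + log(unname(ph[x[j] + 1]))
      }
      expect_equal(sequence_log_likelihood(x, u, model), naive,
                   tolerance = 1e-12)
    }
  }
})

test_that("uniform background gives l * log(1/4); sure important base costs nothing", {
  X <- encode_sequences("ACG")
  st <- model_state(X, 1L, list(integer(0)))
  model <- estimate_parameters(st)
  model$phi_bg[] <- 0.25
  expect_equal(sequence_log_likelihood(c(0L, 1L, 2L), 1, model), 3 * log(0.25))
  # one important position carrying the observed base with certainty
  model2 <- model
  model2$I <- list(2L)
  model2$structure$p <- 1L
  model2$phi_arch <- list(matrix(c(0, 1, 0, 0), 4, 1,
                                 dimnames = list(c("A", "C", "G", "T"), "2")))
  expect_equal(sequence_log_likelihood(c(0L, 1L, 2L), 1, model2),
               2 * log(0.25))
})

test_that("dataset log-likelihood is additive over rows with explicit labels", {
  X <- random_seq_matrix(8, 6, seed = 21)
  cfg <- random_config(8, 6, k = 3, p = 2, seed = 22)
  st <- model_state(X, cfg$y, cfg$I)
  model <- estimate_parameters(st)
  lab <- cfg$y
  by_row <- sum(vapply(seq_len(8), function(i) {
    sequence_log_likelihood(X$data[i, ], lab[i], model)
  }, numeric(1)))
  expect_equal(dataset_log_likelihood(X, model, lab), by_row,
               tolerance = 1e-12)
  expect_error(dataset_log_likelihood(X, model, rep(4L, 8)), "1\\.\\.k")
})

test_that("marginal likelihood over identical architectures collapses to k = 1", {
  X <- random_seq_matrix(5, 4, seed = 31)
  st1 <- model_state(X, rep(1L, 5), list(integer(0)))
  m1 <- estimate_parameters(st1)
  # duplicate the single architecture into a symmetric k = 2 mixture
  m2 <- m1
  m2$structure <- model_structure(2, c(0L, 0L))
  m2$gamma_hat <- c(0.5, 0.5)
  m2$phi_arch <- list(m1$phi_arch[[1]], m1$phi_arch[[1]])
  m2$I <- list(integer(0), integer(0))
  expect_equal(dataset_log_likelihood(X, m2, "marginal"),
               dataset_log_likelihood(X, m1, "marginal"), tolerance = 1e-10)
  # explicit mixture summation oracle
  ll <- vapply(seq_len(5), function(i) {
    lls <- vapply(1:2, function(u) {
      sequence_log_likelihood(X$data[i, ], u, m2)
    }, numeric(1))
    log(sum(0.5 * exp(lls)))
  }, numeric(1))
  expect_equal(dataset_log_likelihood(X, m2, "marginal"), sum(ll),
               tolerance = 1e-10)
})

test_that("collapsed score matches the chain-rule oracle on small instances", {
  for (shape in list(c(n = 2, l = 2, k = 1, p = 1), c(n = 3, l = 2, k = 2, p = 1),
                     c(n = 4, l = 3, k = 2, p = 1), c(n = 4, l = 3, k = 2, p = 0))) {
    X <- random_seq_matrix(shape["n"], shape["l"], seed = 40 + shape["n"])
    cfg <- random_config(shape["n"], shape["l"], shape["k"], shape["p"],
                         seed = 50 + shape["n"])
    st <- model_state(X, cfg$y, cfg$I)
    expect_equal(posterior_score(st),
                 oracle_collapsed_score(X$data, cfg$y, cfg$I), tolerance = 1e-8)
  }
})

test_that("collapsed score closed form on a single background-only sequence", {
  X <- encode_sequences("ACGTA")
  st <- model_state(X, 1L, list(integer(0)))
  expect_equal(posterior_score(st), 5 * log(1 / 4), tolerance = 1e-12)
})

test_that("corrupted count tables fail the integrity check", {
  X0 <- seq_matrix(matrix(0L, 1, 2))
  st <- model_state(X0, 1L, list(integer(0)))
  st$size_counts <- c(2L)  # corrupt
  expect_error(posterior_score(st), "sum to n")
  st2 <- model_state(X0, 1L, list(1L))
  st2$arch_counts[[1]][1, 1] <- 5L  # corrupt
  expect_error(posterior_score(st2), "inconsistent")
})

test_that("posterior-mean estimates match direct arithmetic and prior means", {
  # 4 sequences showing A,C,G,T at an important position: phi = 2/8 each
  X <- encode_sequences(c("AA", "CA", "GA", "TA"))
  st <- model_state(X, rep(1L, 4), list(1L))
  m <- estimate_parameters(st)
  expect_equal(unname(m$phi_arch[[1]][, 1]), rep(2 / 8, 4))
  expect_equal(m$gamma_hat, (4 + 1) / (4 + 1))
  # arbitrary counts: (c + 1) / (sum + 4)
  cfgX <- random_seq_matrix(7, 3, seed = 61)
  cfg <- random_config(7, 3, k = 2, p = 1, seed = 62)
  st2 <- model_state(cfgX, cfg$y, cfg$I)
  m2 <- estimate_parameters(st2)
  u_sizes <- tabulate(cfg$y, 2)
  for (u in 1:2) {
    j <- cfg$I[[u]][1]
    counts <- vapply(0:3, function(b) {
      sum(cfgX$data[cfg$y == u, j] == b)
    }, numeric(1))
    expect_equal(unname(m2$phi_arch[[u]][, 1]),
                 (counts + 1) / (u_sizes[u] + 4))
  }
  expect_equal(m2$gamma_hat, (u_sizes + 1) / (7 + 2))
  # empty architecture: prior-mean uniform at its important positions
  st3 <- model_state(cfgX, rep(1L, 7), list(1L, 2L))
  m3 <- estimate_parameters(st3)
  expect_equal(unname(m3$phi_arch[[2]][, 1]), rep(0.25, 4))
})

test_that("background column of an everywhere-unimportant position holds all n counts", {
  X <- random_seq_matrix(9, 4, seed = 71)
  st <- model_state(X, sample(rep(1:2, len = 9)), list(2L, 2L))
  for (j in c(1, 3, 4)) {
    expect_equal(unname(st$bg_counts[, j]),
                 vapply(0:3, function(b) sum(X$data[, j] == b), numeric(1)))
  }
  expect_equal(sum(st$bg_counts[, 2]), 0)
})

test_that("model JSON round trip is bit-stable and preserves likelihoods", {
  X <- random_seq_matrix(12, 6, seed = 81)
  cfg <- random_config(12, 6, k = 2, p = 2, seed = 82)
  st <- model_state(X, cfg$y, cfg$I)
  m <- estimate_parameters(st, tss_offset = 3, score = -12.5, seed = 7L)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_model(m, f1)
  m2 <- read_model(f1)
  write_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(m2$gamma_hat, m$gamma_hat)
  expect_equal(unname(m2$phi_bg), unname(m$phi_bg))
  expect_identical(m2$I, m$I)
  expect_equal(dataset_log_likelihood(X, m2), dataset_log_likelihood(X, m))
})
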