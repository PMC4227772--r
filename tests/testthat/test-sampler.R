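test_that("assignment conditionals match exhaustive enumeration on tiny instances", {
  shapes <- expand.grid(n = 2:4, l = 1:3, k = 1:2, p = 0:1)
  shapes <- shapes[shapes$p <= shapes$l, ]
  for (r in seq_len(nrow(shapes))) {
    n <- shapes$n[r]; l <- shapes$l[r]; k <- shapes$k[r]; p <- shapes$p[r]
    X <- random_seq_matrix(n, l, seed = 100 + r)
    cfg <- random_config(n, l, k, p, seed = 200 + r)
    for (i in c(1L, n)) {
      got <- assignment_conditional(X, cfg$y, cfg$I, i)
      want <- oracle_assignment_probs(X$data, cfg$y, cfg$I, i)
      expect_equal(got, want, tolerance = 1e-8,
                   info = sprintf("shape n=%d l=%d k=%d p=%d i=%d", n, l, k, p, i))
    }
  }
})

test_that("assignment conditional is uniform with no training counts", {
  X <- seq_matrix(matrix(c(0L, 2L, 1L), 1, 3))
  # three empty architectures: remove the only sequence -> prior only
  probs <- assignment_conditional(X, 1L, list(1L, 2L, 3L), 1L)
  expect_equal(probs, rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("a matching important position raises the assignment probability", {
  # two architectures identical except architecture 1 has seen only A at
  # its important position; query sequence carries an A there
  X <- encode_sequences(c("AAAA", "AAAA", "CAAA", "AAAA"))
  y <- c(1L, 1L, 2L, 2L)
  I <- list(1L, 1L)
  probs <- assignment_conditional(X, y, I, 4L)
  expect_gt(probs[1], probs[2])
})

test_that("swap log-ratios equal collapsed-score differences", {
  for (r in 1:6) {
    n <- 3 + (r %% 2); l <- 3; k <- 1 + (r %% 2); p <- 1
    X <- random_seq_matrix(n, l, seed = 300 + r)
    cfg <- random_config(n, l, k, p, seed = 400 + r)
    for (u in seq_len(k)) {
      j_out <- cfg$I[[u]][1]
      for (j_in in setdiff(seq_len(l), cfg$I[[u]])) {
        got <- swap_log_ratio(X, cfg$y, cfg$I, u, j_in, j_out)
        I2 <- cfg$I
        I2[[u]] <- sort(c(setdiff(I2[[u]], j_out), j_in))
        want <- oracle_collapsed_score(X$data, cfg$y, I2) -
          oracle_collapsed_score(X$data, cfg$y, cfg$I)
        expect_equal(got, want, tolerance = 1e-8)
      }
    }
  }
})

test_that("chains are deterministic under a fixed seed and restart-stable", {
  X <- random_seq_matrix(30, 8, seed = 501)
  st <- model_structure(2, 2)
  cfg <- sampler_config(20, 3, seed = 9, record_trace = TRUE)
  r1 <- run_chain(X, st, config = cfg)
  r2 <- run_chain(X, st, config = cfg)
  expect_identical(r1$best_state$y, r2$best_state$y)
  expect_identical(r1$best_state$I, r2$best_state$I)
  expect_identical(r1$best_score, r2$best_score)
  expect_identical(r1$score_trace, r2$score_trace)
  # restart r depends only on (seed, r): the first restart of a 3-restart
  # run equals a 1-restart run with the same seed
  r_single <- run_chain(X, st, config = sampler_config(20, 1, seed = 9,
                                                       record_trace = TRUE))
  tr1 <- subset(r1$score_trace, restart == 1)$posterior_score
  expect_identical(tr1, r_single$score_trace$posterior_score)
})

test_that("best state attains the maximum recorded score, recomputable from scratch", {
  X <- random_seq_matrix(40, 10, seed = 601)
  res <- run_chain(X, model_structure(3, 3),
                   config = sampler_config(30, 2, seed = 4, record_trace = TRUE))
  expect_equal(res$best_score, max(res$score_trace$posterior_score))
  expect_true(all(res$best_score >= res$score_trace$posterior_score))
  # the collapsed score of the returned state, recomputed in R from
  # (X, y, I) alone, equals the sampler's retained score
  expect_equal(posterior_score(res$best_state), res$best_score,
               tolerance = 1e-8)
})

test_that("incremental count tables survive thousands of moves intact", {
  # 40 sequences x 30 iterations = 1200 assignment moves plus swap sweeps;
  # the end-of-chain internal tables must equal tables rebuilt from scratch
  X <- random_seq_matrix(40, 6, seed = 701)
  res <- run_chain(X, model_structure(3, 2), config = sampler_config(30, 1, seed = 8))
  st <- model_state(X, res$final$final_y, res$final$final_I)
  expect_identical(unname(res$final$final_sizes), st$size_counts)
  for (u in 1:3) {
    iu <- sort(res$final$final_I[[u]])
    got <- res$final$final_counts[, iu, u, drop = FALSE]
    expect_equal(unname(got[, , 1]), unname(st$arch_counts[[u]]))
  }
  expect_equal(unname(res$final$final_bgc), unname(st$bg_counts))
  expect_equal(posterior_score(st), res$final$final_score, tolerance = 1e-8)
})

test_that("p = 0 and p = l position sweeps are no-ops", {
  X <- random_seq_matrix(10, 4, seed = 801)
  r0 <- run_chain(X, model_structure(2, 0), config = sampler_config(10, 1, seed = 2))
  expect_identical(lengths(r0$best_state$I), c(0L, 0L))
  rl <- run_chain(X, model_structure(2, 4), config = sampler_config(10, 1, seed = 2))
  expect_identical(lapply(rl$best_state$I, as.integer), list(1:4, 1:4))
  expect_error(run_chain(X, model_structure(2, 5)), "exceeds")
})

test_that("long-run state frequencies match the enumerated collapsed posterior", {
  # tiny instance: n = 2, l = 2, k = 1, p = 1 -> state is the important
  # position of the single architecture (2 possibilities)
  X <- seq_matrix(matrix(c(0L, 0L, 1L, 3L), 2, 2))
  iters <- 60000
  res <- run_chain(X, model_structure(1, 1),
                   config = sampler_config(iters, 1, seed = 31),
                   .record_states = TRUE)
  freq_pos1 <- mean(res$imp_trace[, 1] == 1L)
  en <- oracle_position_set_probs(X$data, c(1L, 1L), list(1L), 1, 1)
  want <- en$probs[vapply(en$sets, function(s) s[1] == 1, logical(1))]
  se <- sqrt(want * (1 - want) / iters) * 3
  # autocorrelation inflates the Monte-Carlo error; allow a wide 3 sigma
  expect_lt(abs(freq_pos1 - want), max(20 * se, 0.02))

  # and for assignments: n = 2, l = 1, k = 2, p = 0 -> state is (y1, y2)
  X2 <- seq_matrix(matrix(c(0L, 3L), 2, 1))
  res2 <- run_chain(X2, model_structure(2, 0),
                    config = sampler_config(iters, 1, seed = 32),
                    .record_states = TRUE)
  same <- mean(res2$y_trace[, 1] == res2$y_trace[, 2])
  sc_same1 <- oracle_collapsed_score(X2$data, c(1L, 1L), list(integer(0), integer(0)))
  sc_same2 <- oracle_collapsed_score(X2$data, c(2L, 2L), list(integer(0), integer(0)))
  sc_diff1 <- oracle_collapsed_score(X2$data, c(1L, 2L), list(integer(0), integer(0)))
  sc_diff2 <- oracle_collapsed_score(X2$data, c(2L, 1L), list(integer(0), integer(0)))
  w <- exp(c(sc_same1, sc_same2, sc_diff1, sc_diff2))
  want_same <- (w[1] + w[2]) / sum(w)
  expect_lt(abs(same - want_same), 0.02)
})
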