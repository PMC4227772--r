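# shared small fitted models for classification tests
make_two_models <- function() {
  simA <- simulate_architecture_mixture(n = 150, l = 20, sizes = c(4, 4),
                                        weights = c(0.6, 0.4), seed = 41)
  simB <- simulate_architecture_mixture(n = 150, l = 20, sizes = c(4, 4),
                                        weights = c(0.6, 0.4), seed = 42)
  cfg <- sampler_config(40, 3, seed = 5)
  list(
    A = fit_model(simA$X, 2, 4, config = cfg),
    B = fit_model(simB$X, 2, 4, config = cfg),
    simA = simA, simB = simB
  )
}

test_that("log-odds is exactly the difference of the two marginals", {
  mm <- make_two_models()
  X <- mm$simA$X[1:20]
  lo <- log_odds(X, mm$A, mm$B)
  want <- vapply(seq_len(20), function(i) {
    dataset_log_likelihood(X[i], mm$A) - dataset_log_likelihood(X[i], mm$B)
  }, numeric(1))
  expect_equal(lo, want, tolerance = 1e-10)
  expect_equal(log_odds(X, mm$A, mm$A), rep(0, 20))
})

test_that("sequences favour the model they were simulated from", {
  mm <- make_two_models()
  loA <- log_odds(mm$simA$X, mm$A, mm$B)
  loB <- log_odds(mm$simB$X, mm$A, mm$B)
  expect_gt(mean(loA > 0), 0.5)
  expect_gt(mean(loB < 0), 0.5)
  # rank-sum direction check
  expect_gt(wilcox.test(loA, loB, alternative = "greater")$statistic,
            length(loA) * length(loB) / 2)
})

test_that("responsibilities are a proper posterior and MAP attains their max", {
  mm <- make_two_models()
  asg <- assign_architectures(mm$A, mm$simA$X)
  expect_equal(rowSums(asg$responsibilities), rep(1, 150), tolerance = 1e-9)
  expect_identical(asg$map, max.col(asg$responsibilities, ties.method = "first"))
  st1 <- model_state(mm$simA$X, rep(1L, 150), list(integer(0)))
  m1 <- estimate_parameters(st1)
  asg1 <- assign_architectures(m1, mm$simA$X)
  expect_equal(asg1$responsibilities[, 1], rep(1, 150))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_assignments(mm$A, mm$simA$X, f)
  tab <- read.delim(f)
  expect_equal(rowSums(tab[, c("resp_1", "resp_2")]), rep(1, 150),
               tolerance = 1e-6)
})

test_that("genome scans recover a planted window and match per-window likelihoods", {
  sim <- simulate_architecture_mixture(n = 200, l = 15, sizes = c(5, 5),
                                       weights = c(0.5, 0.5), seed = 61)
  model <- fit_model(sim$X, 2, 5, config = sampler_config(40, 3, seed = 6))
  # plant the consensus of the dominant fitted architecture: the
  # single strongest instance the model can encounter
  u_star <- which.max(model$gamma_hat)
  lp <- promarch:::log_prob_matrix(model, u_star)
  plant <- paste(c("A", "C", "G", "T")[apply(lp, 2, which.max)],
                 collapse = "")
  contig <- withr::with_seed(99, paste(sample(c("A", "C", "G", "T"), 2000,
                                              replace = TRUE), collapse = ""))
  plant_at <- 700L
  substr(contig, plant_at, plant_at + 14) <- plant
  scan <- scan_genome(c(chr1 = contig), model, strand = "plus")
  sc <- scan$scores
  expect_identical(nrow(scan$skipped), 0L)
  expect_identical(sc$window_start[which.max(sc$score)], plant_at)
  # definitional: score at a position equals the window's marginal loglik
  i <- 123
  w <- substr(contig, i, i + 14)
  expect_equal(sc$score[sc$window_start == i],
               dataset_log_likelihood(encode_sequences(w), model),
               tolerance = 1e-9)
  # a contig of exactly window length yields one plus-strand window
  one <- scan_genome(c(tiny = w), model, strand = "plus")
  expect_identical(nrow(one$scores), 1L)
  expect_warning(scan_genome(c(short = "ACGT"), model), "shorter")
})

test_that("ambiguous windows are skipped and flagged, never scored", {
  sim <- simulate_uniform_null(n = 50, l = 10, seed = 71)
  model <- fit_model(sim$X, 1, 0, config = sampler_config(5, 1, seed = 1))
  contig <- paste0(strrep("ACGT", 10), "N", strrep("ACGT", 10))
  scan <- scan_genome(c(c1 = contig), model, strand = "plus")
  expect_identical(nrow(scan$skipped), 10L)  # windows overlapping the N
  expect_false(any(scan$scores$window_start %in% scan$skipped$window_start))
})

test_that("strand-symmetric scans yield identical score multisets", {
  sim <- simulate_architecture_mixture(n = 100, l = 12, sizes = c(4, 4),
                                       weights = c(0.5, 0.5), seed = 81)
  model <- fit_model(sim$X, 2, 4, config = sampler_config(30, 2, seed = 3))
  contig <- withr::with_seed(7, paste(sample(c("A", "C", "G", "T"), 500,
                                             replace = TRUE), collapse = ""))
  rc <- promarch:::revcomp_chr(contig)
  fwd <- scan_genome(c(g = contig), model, strand = "both")
  rev <- scan_genome(c(g = rc), model, strand = "both")
  expect_equal(sort(fwd$scores$score), sort(rev$scores$score),
               tolerance = 1e-10)
  # plus scan of the reverse complement equals the minus scan
  expect_equal(sort(subset(rev$scores, strand == "+")$score),
               sort(subset(fwd$scores, strand == "-")$score),
               tolerance = 1e-10)
})

test_that("best region position is the scan argmax, leftmost on ties", {
  sim <- simulate_architecture_mixture(n = 150, l = 12, sizes = c(4, 4),
                                       weights = c(0.5, 0.5), seed = 91)
  model <- fit_model(sim$X, 2, 4, config = sampler_config(30, 2, seed = 3))
  region <- withr::with_seed(5, paste(sample(c("A", "C", "G", "T"), 80,
                                             replace = TRUE), collapse = ""))
  bp <- best_position_in_region(region, model)
  scan <- scan_genome(c(r = region), model, strand = "plus")
  expect_equal(bp$score, max(scan$scores$score))
  expect_identical(bp$offset, scan$scores$window_start[which.max(scan$scores$score)] - 1L)
  # region of exactly window length -> offset 0
  exact <- best_position_in_region(substr(region, 1, 12), model)
  expect_identical(exact$offset, 0L)
  expect_error(best_position_in_region("ACGT", model), "shorter")
})

test_that("planted TSSs are localised within two nucleotides in most trials", {
  sim <- simulate_architecture_mixture(n = 400, l = 15, sizes = c(8, 8),
                                       weights = c(0.5, 0.5), alpha = 0.05,
                                       seed = 111)
  model <- fit_model(sim$X, 2, 8, config = sampler_config(50, 3, seed = 4))
  hits <- 0; trials <- 25
  for (t in seq_len(trials)) {
    row <- which(sim$truth$labels == 1)[t]
    plant <- decode_sequences(sim$X[row])[[1]]
    region <- withr::with_seed(1000 + t,
      paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = ""))
    at <- 50
    substr(region, at, at + 14) <- plant
    bp <- best_position_in_region(region, model)
    if (abs(bp$offset + 1L - at) <= 2) hits <- hits + 1
  }
  expect_gte(hits / trials, 0.6)
})

test_that("AUC equals the exhaustive pairwise count and handles edge shapes", {
  withr::with_seed(121, {
    pos <- c(rnorm(15, 1), 0.5, 0.5)   # include ties across lists
    neg <- c(rnorm(12, 0), 0.5)
  })
  r <- roc_auc(pos, neg)
  expect_equal(r$auc, oracle_auc(pos, neg), tolerance = 1e-12)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  expect_true(all(r$fpr >= 0 & r$fpr <= 1 & r$tpr >= 0 & r$tpr <= 1))
  # perfectly separated and identical distributions
  expect_equal(roc_auc(2:4, -(1:3))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  expect_error(roc_auc(numeric(0), 1), "nonempty")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_roc(r, f)
  first <- readLines(f, n = 1)
  expect_match(first, "^# AUC")
})

test_that("matched multi-architecture models outrank single-architecture scans", {
  # plant-vs-background discrimination, paired over simulation replicates
  wins <- 0; reps <- 10
  for (rep in seq_len(reps)) {
    sim <- simulate_architecture_mixture(n = 240, l = 12,
                                         sizes = c(4, 4, 4),
                                         weights = c(0.5, 0.3, 0.2),
                                         seed = 3000 + rep)
    cfg <- sampler_config(40, 3, seed = rep)
    multi <- fit_model(sim$X, 3, 4, config = cfg)
    single <- fit_model(sim$X, 1, 4, config = cfg)
    neg <- simulate_uniform_null(n = 60, l = 12, seed = 5000 + rep)
    auc_multi <- roc_auc(promarch:::sequence_marginal_ll(multi, sim$X),
                         promarch:::sequence_marginal_ll(multi, neg$X))$auc
    auc_single <- roc_auc(promarch:::sequence_marginal_ll(single, sim$X),
                          promarch:::sequence_marginal_ll(single, neg$X))$auc
    if (auc_multi > auc_single) wins <- wins + 1
  }
  expect_gt(wins, reps / 2)
})
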