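#' Architecture assignment of sequences under a fitted model
#'
#' Posterior responsibilities `r_iu` proportional to
#' `gamma_u * P(X_i | u)`, the MAP architecture per sequence, and the
#' marginal log-likelihood of each sequence.
#'
#' @param model a `promarch_model`
#' @param X a [seq_matrix()]
#' @return list with `map` (labels), `responsibilities` (n x k), `loglik`
#'   (marginal per-sequence log-likelihoods)
#' @export
assign_architectures <- function(model, X) {
  ll <- loglik_matrix(model, X)
  lg <- sweep(ll, 2L, log(model$gamma_hat), "+")
  marg <- row_logsumexp(lg)
  resp <- exp(lg - marg)
  list(map = max.col(lg, ties.method = "first"), responsibilities = resp,
       loglik = marg)
}

#' Write per-sequence assignments as TSV
#'
#' One row per sequence: id, MAP architecture, per-architecture posterior
#' responsibilities, and marginal log-likelihood.
#'
#' @param model a `promarch_model`
#' @param X a [seq_matrix()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_assignments <- function(model, X, path) {
  asg <- assign_architectures(model, X)
  resp <- as.data.frame(asg$responsibilities)
  names(resp) <- sprintf("resp_%d", seq_len(ncol(resp)))
  out <- cbind(data.frame(id = X$ids, map_architecture = asg$map), resp,
               data.frame(loglik = asg$loglik))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log-odds score between two fitted models
#'
#' Marginal log-likelihood under `m1` minus under `m2` for each query
#' sequence.  A higher score implies a better fit with `m1`, a lower
#' score a better fit with `m2`.
#'
#' @param x a [seq_matrix()], a coded matrix, or a character vector of DNA
#'   strings
#' @param m1,m2 fitted `promarch_model` objects over the same window length
#' @return numeric vector of per-sequence log-odds
#' @export
log_odds <- function(x, m1, m2) {
  if (is.character(x)) x <- encode_sequences(x)
  if (ncol(m1$phi_bg) != ncol(m2$phi_bg)) {
    stop("the two models must share the same window length")
  }
  sequence_marginal_ll(m1, x) - sequence_marginal_ll(m2, x)
}

# Score all windows of one contig string under the model's marginal
# mixture likelihood.  Returns window starts, scores, and a validity mask
# (windows containing non-ACGT bases are flagged invalid, never scored).
score_contig <- function(s, model) {
  l <- ncol(model$phi_bg)
  codes <- match(strsplit(toupper(s), "", fixed = TRUE)[[1L]], NUC) - 1L
  len <- length(codes)
  if (len < l) return(NULL)
  npos <- len - l + 1L
  bad <- is.na(codes)
  codes0 <- ifelse(bad, 0L, codes)
  k <- model$structure$k
  lg <- log(model$gamma_hat)
  per_u <- matrix(0, npos, k)
  for (u in seq_len(k)) {
    lp <- log_prob_matrix(model, u)
    acc <- numeric(npos)
    for (j in seq_len(l)) {
      acc <- acc + lp[cbind(codes0[j:(j + npos - 1L)] + 1L, j)]
    }
    per_u[, u] <- acc + lg[u]
  }
  score <- row_logsumexp(per_u)
  nbad <- c(0L, cumsum(bad))
  valid <- (nbad[seq_len(npos) + l] - nbad[seq_len(npos)]) == 0L
  list(start = seq_len(npos), score = score, valid = valid)
}

#' Slide a fitted model across a genome
#'
#' Scores every window of the model's length on the requested strand(s)
#' with the marginal mixture log-likelihood.  Scores are anchored at the
#' TSS column of the window (not the window start); minus-strand windows
#' are reverse-complemented before scoring and reported at the
#' TSS-equivalent genomic coordinate.  Windows containing non-ACGT bases
#' are skipped and flagged; contigs shorter than the window yield a
#' warning and no scores.
#'
#' @param genome a named character vector of contig sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file
#' @param model a `promarch_model`
#' @param strand `"both"`, `"plus"`, or `"minus"`
#' @return an object of class `scan_result`: `scores` (data frame with
#'   chrom, tss, strand, score, window_start) and `skipped` (flagged
#'   ambiguous windows)
#' @export
scan_genome <- function(genome, model, strand = c("both", "plus", "minus")) {
  strand <- match.arg(strand)
  contigs <- as_contig_strings(genome)
  l <- ncol(model$phi_bg)
  t_off <- model$tss_offset
  scores <- list()
  skipped <- list()
  for (nm in names(contigs)) {
    s <- contigs[[nm]]
    len <- nchar(s)
    if (len < l) {
      warning(sprintf("contig '%s' (%d bp) is shorter than the window (%d bp)",
                      nm, len, l))
      next
    }
    if (strand %in% c("both", "plus")) {
      sc <- score_contig(s, model)
      tss <- sc$start + t_off - 1L
      scores[[length(scores) + 1L]] <- data.frame(
        chrom = nm, tss = tss[sc$valid], strand = "+",
        score = sc$score[sc$valid], window_start = sc$start[sc$valid]
      )
      if (any(!sc$valid)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          chrom = nm, window_start = sc$start[!sc$valid], strand = "+"
        )
      }
    }
    if (strand %in% c("both", "minus")) {
      rc <- revcomp_chr(s)
      sc <- score_contig(rc, model)
      # rc index r maps to genomic coordinate len - r + 1
      tss <- len - (sc$start + t_off - 1L) + 1L
      gstart <- len - (sc$start + l - 1L) + 1L
      scores[[length(scores) + 1L]] <- data.frame(
        chrom = nm, tss = tss[sc$valid], strand = "-",
        score = sc$score[sc$valid], window_start = gstart[sc$valid]
      )
      if (any(!sc$valid)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          chrom = nm, window_start = gstart[!sc$valid], strand = "-"
        )
      }
    }
  }
  empty_sc <- data.frame(chrom = character(0), tss = integer(0),
                         strand = character(0), score = numeric(0),
                         window_start = integer(0))
  empty_sk <- data.frame(chrom = character(0), window_start = integer(0),
                         strand = character(0))
  structure(
    list(
      scores = if (length(scores)) do.call(rbind, scores) else empty_sc,
      skipped = if (length(skipped)) do.call(rbind, skipped) else empty_sk
    ),
    class = "scan_result"
  )
}

#' Write scan scores as BED6
#'
#' One line per scored window, at the single TSS base in 0-based
#' half-open coordinates.
#'
#' @param scan a `scan_result` from [scan_genome()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_scan_bed <- function(scan, path) {
  stopifnot(inherits(scan, "scan_result"))
  sc <- scan$scores
  bed <- data.frame(
    chrom = sc$chrom, start = sc$tss - 1L, end = sc$tss,
    name = sprintf("%s:%d%s", sc$chrom, sc$tss, sc$strand),
    score = sc$score, strand = sc$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Best TSS position within a candidate region
#'
#' Evaluates the marginal likelihood of every position within the region
#' for being a TSS and returns the highest-scoring one (ties go to the
#' leftmost).  The returned `offset` is the 0-based window start;
#' `tss_position` is the 1-based coordinate of the implied TSS base
#' within the region.
#'
#' @param region a single DNA string (length >= the model window)
#' @param model a `promarch_model`
#' @return list with `offset`, `score`, and `tss_position`
#' @export
best_position_in_region <- function(region, model) {
  stopifnot(is.character(region), length(region) == 1L)
  l <- ncol(model$phi_bg)
  if (nchar(region) < l) stop("region is shorter than the model window")
  sc <- score_contig(region, model)
  if (!any(sc$valid)) stop("no window in the region is free of ambiguous bases")
  sc$score[!sc$valid] <- -Inf
  best <- which.max(sc$score)
  list(offset = best - 1L, score = sc$score[best],
       tss_position = best - 1L + model$tss_offset)
}

#' ROC curve and AUC from positive and negative score lists
#'
#' Standard threshold-sweep ROC; the area under the curve equals the
#' Mann-Whitney probability that a positive outscores a negative (ties
#' counted half).
#'
#' @param scores_pos scores of true positives
#' @param scores_neg scores of negatives
#' @return an object of class `roc_result` with `thresholds`, `tpr`,
#'   `fpr`, and `auc`
#' @export
roc_auc <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg)) {
    stop("both score lists must be nonempty")
  }
  r <- pROC::roc(
    response = c(rep(1L, length(scores_pos)), rep(0L, length(scores_neg))),
    predictor = c(scores_pos, scores_neg),
    levels = c(0L, 1L), direction = "<", quiet = TRUE
  )
  ord <- order(1 - r$specificities, r$sensitivities)
  structure(
    list(thresholds = r$thresholds[ord], tpr = r$sensitivities[ord],
         fpr = (1 - r$specificities)[ord], auc = as.numeric(r$auc)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f over %d thresholds\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' Write a ROC curve as TSV
#'
#' First line is a `# AUC` summary comment, then (threshold, fpr, tpr)
#' rows.
#'
#' @param roc a `roc_result`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_roc <- function(roc, path) {
  stopifnot(inherits(roc, "roc_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# AUC\t%.17g", roc$auc), con)
  utils::write.table(
    data.frame(threshold = roc$thresholds, fpr = roc$fpr, tpr = roc$tpr),
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
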