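`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log-sum-exp
#' @param x numeric vector of log-scale values
#' @return log(sum(exp(x)))
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix (n x k), used for mixture marginals.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  fin <- is.finite(mx)
  out <- mx
  if (any(fin)) {
    out[fin] <- mx[fin] + log(rowSums(exp(m[fin, , drop = FALSE] - mx[fin])))
  }
  out
}

#' Draw one Dirichlet vector, robust to very small concentrations
#'
#' Uses the shape-boosted gamma representation `G(a) = G(a + 1) * U^(1/a)`
#' on the log scale, so draws at concentrations as small as 1e-3 never
#' underflow to an all-zero vector.
#'
#' @param alpha vector of positive concentration parameters
#' @return a probability vector of the same length
#' @keywords internal
rdirichlet1 <- function(alpha) {
  stopifnot(all(alpha > 0))
  lg <- log(stats::rgamma(length(alpha), shape = alpha + 1)) +
    log(stats::runif(length(alpha))) / alpha
  lg <- lg - max(lg)
  w <- exp(lg)
  w / sum(w)
}

# Reverse complement of a plain character string (ACGT, case preserved as
# upper case).
revcomp_chr <- function(s) {
  chartr("ACGTacgt", "TGCAtgca", vapply(s, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

stop_if_not_scalar_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 1 || x != as.integer(x)) {
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}
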