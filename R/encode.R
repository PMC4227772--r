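NUC <- c("A", "C", "G", "T")

#' TSS-aligned sequence matrix
#'
#' Container for a set of equal-length DNA windows aligned on the
#' transcription start site (TSS).  Bases are integer coded
#' (0 = A, 1 = C, 2 = G, 3 = T); `tss_offset` is the 1-based column index
#' at which the TSS base sits in every window.
#'
#' @param data integer matrix (n x l) of codes in 0..3
#' @param ids character vector of n sequence identifiers
#' @param tss_offset 1-based column index of the TSS within each window
#' @return an object of class `seq_matrix`
#' @export
seq_matrix <- function(data, ids = NULL, tss_offset = 1L) {
  if (!is.matrix(data) || nrow(data) < 1L || ncol(data) < 1L) {
    stop("`data` must be a matrix with at least one row and one column")
  }
  storage.mode(data) <- "integer"
  dimnames(data) <- NULL
  if (anyNA(data) || any(data < 0L) || any(data > 3L)) {
    stop("sequence codes must all lie in 0..3 (A, C, G, T)")
  }
  tss_offset <- as.integer(tss_offset)
  if (tss_offset < 1L || tss_offset > ncol(data)) {
    stop("`tss_offset` must be a column index of the window")
  }
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_len(nrow(data)))
  if (length(ids) != nrow(data)) stop("`ids` must have one entry per sequence")
  structure(
    list(data = data, ids = as.character(ids), tss_offset = tss_offset),
    class = "seq_matrix"
  )
}

#' Encode DNA strings into a TSS-aligned sequence matrix
#'
#' All strings must be the same length and contain only A, C, G, T
#' (case-insensitive).  Windows containing ambiguous bases such as N are
#' rejected outright: callers that tolerate them should filter first (see
#' [extract_windows()], which logs rejections instead of failing).
#'
#' @param raw character vector of DNA strings
#' @param ids optional identifiers; defaults to `names(raw)` or `seq_i`
#' @param tss_offset 1-based TSS column within the window
#' @return a [seq_matrix()]
#' @export
#' @examples
#' encode_sequences(c(p1 = "ACGT", p2 = "TTGA"))$data
encode_sequences <- function(raw, ids = NULL, tss_offset = 1L) {
  if (length(raw) < 1L) stop("need at least one sequence")
  ids <- ids %||% names(raw) %||% sprintf("seq_%d", seq_along(raw))
  lens <- nchar(raw)
  if (length(unique(lens)) != 1L) {
    stop("sequences must all have the same length (found lengths ",
         paste(sort(unique(lens)), collapse = ", "), ")")
  }
  chars <- strsplit(toupper(raw), "", fixed = TRUE)
  codes <- lapply(chars, function(x) match(x, NUC) - 1L)
  bad <- which(vapply(codes, anyNA, logical(1)))
  if (length(bad)) {
    stop(sprintf(
      "sequence '%s' contains a character outside A/C/G/T (e.g. ambiguous N)",
      ids[bad[1L]]
    ))
  }
  seq_matrix(do.call(rbind, codes), ids = ids, tss_offset = tss_offset)
}

#' Decode a sequence matrix back into DNA strings
#' @param x a [seq_matrix()]
#' @return named character vector
#' @export
decode_sequences <- function(x) {
  stopifnot(inherits(x, "seq_matrix"))
  out <- apply(x$data, 1L, function(r) paste(NUC[r + 1L], collapse = ""))
  names(out) <- x$ids
  out
}

#' Subset rows of a sequence matrix
#' @param x a [seq_matrix()]
#' @param i row index
#' @param ... ignored
#' @return a [seq_matrix()] with the selected rows
#' @export
`[.seq_matrix` <- function(x, i, ...) {
  seq_matrix(x$data[i, , drop = FALSE], ids = x$ids[i],
             tss_offset = x$tss_offset)
}

#' @export
dim.seq_matrix <- function(x) dim(x$data)

#' @export
print.seq_matrix <- function(x, ...) {
  cat(sprintf(
    "<seq_matrix> %d sequences x %d positions, TSS at column %d (%s)\n",
    nrow(x$data), ncol(x$data), x$tss_offset,
    paste(range(tss_labels(ncol(x$data), x$tss_offset)), collapse = " .. ")
  ))
  invisible(x)
}

#' TSS-relative position labels for window columns
#'
#' User-facing positions are reported relative to the TSS with no
#' position 0: the TSS base is +1 and the base before it is -1.
#'
#' @param l window length
#' @param tss_offset 1-based TSS column
#' @return integer vector of length `l`
#' @export
tss_labels <- function(l, tss_offset) {
  d <- seq_len(l) - as.integer(tss_offset)
  ifelse(d >= 0L, d + 1L, d)
}

# Inverse of tss_labels: map a TSS-relative label to a column index.
label_to_col <- function(label, l, tss_offset) {
  lab <- tss_labels(l, tss_offset)
  idx <- match(as.integer(label), lab)
  if (anyNA(idx)) stop("TSS-relative position outside the window")
  idx
}
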