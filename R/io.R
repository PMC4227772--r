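# Normalize a genome argument (path, DNAStringSet, or named character
# vector) to a named character vector of contig strings.
as_contig_strings <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "XStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      names(genome) <- sprintf("contig_%d", seq_along(genome))
    }
    return(genome)
  }
  stop("`genome` must be a FASTA path, a DNAStringSet, or named strings")
}

#' Read TSS-aligned windows from a FASTA file
#'
#' All records must have the same length; records containing ambiguous
#' bases are rejected with an error naming the offending sequence (see
#' [extract_windows()] for tolerant extraction with a rejection log).
#'
#' @param path FASTA file
#' @param tss_offset 1-based TSS column within each window
#' @return a [seq_matrix()]
#' @export
read_fasta_windows <- function(path, tss_offset = 1L) {
  ss <- Biostrings::readDNAStringSet(path)
  encode_sequences(as.character(ss), ids = sub("\\s.*$", "", names(ss)),
                   tss_offset = tss_offset)
}

#' Write sequences to FASTA
#'
#' @param x a [seq_matrix()] or a named character vector of sequences
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_fasta <- function(x, path) {
  s <- if (inherits(x, "seq_matrix")) decode_sequences(x) else x
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(s), path)
  invisible(path)
}

#' Window geometry around the TSS
#'
#' A window covers `upstream` bases before the TSS, the TSS base itself,
#' and `downstream` bases after it, giving length
#' `upstream + downstream + 1` with the TSS at column `upstream + 1`.
#' The bacterial convention is upstream 45 / downstream 5 (51 bp); the
#' eukaryotic one upstream 45 / downstream 45 (91 bp).
#'
#' @param upstream bases before the TSS (>= 0)
#' @param downstream bases after the TSS (>= 0)
#' @return an object of class `window_spec`
#' @export
window_spec <- function(upstream = 45L, downstream = 5L) {
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  if (is.na(upstream) || is.na(downstream) || upstream < 0L || downstream < 0L) {
    stop("`upstream` and `downstream` must be >= 0")
  }
  structure(list(upstream = upstream, downstream = downstream,
                 length = upstream + downstream + 1L,
                 tss_offset = upstream + 1L),
            class = "window_spec")
}

#' Read a table of TSS records
#'
#' Two dialects, never guessed: BED6 (0-based half-open single-base
#' intervals; the `score` column is taken as the tag count) or a 1-based
#' TSV with header columns `chrom, pos, strand, id` and optional
#' `tag_count`.
#'
#' @param path input file
#' @param format `"bed"` or `"tsv"`
#' @return data frame with columns chrom, pos (1-based TSS base), strand,
#'   id, tag_count
#' @export
read_tss_table <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (format == "bed") {
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 6L) stop("BED input must have 6 columns")
    names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
    if (any(bed$end - bed$start != 1L)) {
      stop("BED records must be single-base intervals encoding the TSS")
    }
    out <- data.frame(chrom = bed$chrom, pos = bed$start + 1L,
                      strand = bed$strand, id = bed$name,
                      tag_count = suppressWarnings(as.numeric(bed$score)),
                      stringsAsFactors = FALSE)
  } else {
    tsv <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "strand", "id")
    if (!all(need %in% names(tsv))) {
      stop("TSV input needs header columns chrom, pos, strand, id")
    }
    out <- data.frame(chrom = tsv$chrom, pos = as.integer(tsv$pos),
                      strand = tsv$strand, id = tsv$id,
                      tag_count = if ("tag_count" %in% names(tsv))
                        as.numeric(tsv$tag_count) else NA_real_,
                      stringsAsFactors = FALSE)
  }
  if (any(out$pos < 1L)) stop("TSS positions must be >= 1")
  if (!all(out$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  out
}

#' Extract TSS-aligned windows from a genome
#'
#' Plus-strand records yield bases `(pos - upstream)..(pos + downstream)`;
#' minus-strand records yield the reverse complement of
#' `(pos - downstream)..(pos + upstream)`, so the TSS base sits at the
#' same within-window column for every record.  Records on unknown
#' chromosomes, windows overrunning contig ends, and windows containing
#' non-ACGT bases are rejected per record and logged, never aborting the
#' extraction.  Soft-masked (lower-case) bases are uppercased by default;
#' `drop_masked = TRUE` rejects windows overlapping them instead.
#'
#' @param genome a FASTA path, `DNAStringSet`, or named contig strings
#' @param tss a data frame of TSS records from [read_tss_table()] (or with
#'   the same columns)
#' @param spec a [window_spec()]
#' @param drop_masked reject windows overlapping soft-masked bases
#' @return list with `X` (a [seq_matrix()], TSS at column
#'   `spec$tss_offset`) and `rejected` (data frame id, reason)
#' @export
extract_windows <- function(genome, tss, spec = window_spec(),
                            drop_masked = FALSE) {
  contigs <- as_contig_strings(genome)
  kept <- character(0); kept_ids <- character(0)
  rej_id <- character(0); rej_why <- character(0)
  for (r in seq_len(nrow(tss))) {
    id <- as.character(tss$id[r]); chrom <- as.character(tss$chrom[r])
    pos <- tss$pos[r]; strand <- tss$strand[r]
    if (!chrom %in% names(contigs)) {
      rej_id <- c(rej_id, id); rej_why <- c(rej_why, "unknown_chromosome")
      next
    }
    clen <- nchar(contigs[[chrom]])
    rng <- if (strand == "+") {
      c(pos - spec$upstream, pos + spec$downstream)
    } else {
      c(pos - spec$downstream, pos + spec$upstream)
    }
    if (rng[1] < 1L || rng[2] > clen) {
      rej_id <- c(rej_id, id); rej_why <- c(rej_why, "outside_contig")
      next
    }
    w <- substr(contigs[[chrom]], rng[1], rng[2])
    if (drop_masked && grepl("[a-z]", w)) {
      rej_id <- c(rej_id, id); rej_why <- c(rej_why, "soft_masked")
      next
    }
    w <- toupper(w)
    if (strand == "-") w <- revcomp_chr(w)
    if (grepl("[^ACGT]", w)) {
      rej_id <- c(rej_id, id); rej_why <- c(rej_why, "ambiguous_base")
      next
    }
    kept <- c(kept, w); kept_ids <- c(kept_ids, id)
  }
  rejected <- data.frame(id = rej_id, reason = rej_why,
                         stringsAsFactors = FALSE)
  if (!length(kept)) {
    return(list(X = NULL, rejected = rejected))
  }
  list(X = encode_sequences(kept, ids = kept_ids,
                            tss_offset = spec$tss_offset),
       rejected = rejected)
}

#' Keep one primary TSS per gene
#'
#' Per gene id, keeps the record with the maximum tag count; ties go to
#' the most upstream record (smallest position on `+`, largest on `-`).
#' Distinct gene ids sharing a genomic coordinate are kept separately,
#' with a warning.
#'
#' @param tss a TSS data frame (see [read_tss_table()])
#' @return the reduced data frame, one row per gene id
#' @export
reduce_primary <- function(tss) {
  if (anyNA(tss$tag_count)) {
    stop("`tag_count` is required to reduce to primary TSSs")
  }
  picks <- lapply(split(seq_len(nrow(tss)), tss$id), function(idx) {
    sub <- tss[idx, , drop = FALSE]
    best <- sub$tag_count == max(sub$tag_count)
    cand <- sub[best, , drop = FALSE]
    ord <- if (all(cand$strand == "-")) order(-cand$pos) else order(cand$pos)
    idx[best][ord[1L]]
  })
  out <- tss[sort(unlist(picks)), , drop = FALSE]
  key <- paste(out$chrom, out$pos, out$strand)
  if (anyDuplicated(key)) {
    warning("distinct gene ids share a TSS coordinate; all kept")
  }
  rownames(out) <- NULL
  out
}

#' Export per-architecture PWMs in MEME minimal motif format
#'
#' One motif per architecture over its full window: architecture-specific
#' probabilities at important positions, the shared background elsewhere.
#' `which = "posterior"` (default) uses the pseudocount-smoothed
#' posterior-mean tables stored in the model; `which = "raw"` recomputes
#' raw count frequencies (requires the in-memory fitting state; intended
#' for sequence-logo rendering).  A comment line records the TSS-relative
#' position label of every column.
#'
#' @param model a `promarch_model`
#' @param path output file path
#' @param which `"posterior"` or `"raw"`
#' @return `path`, invisibly
#' @export
export_pwms <- function(model, path, which = c("posterior", "raw")) {
  which <- match.arg(which)
  l <- ncol(model$phi_bg); k <- model$structure$k
  labs <- tss_labels(l, model$tss_offset)
  mats <- lapply(seq_len(k), function(u) {
    if (which == "posterior") {
      m <- model$phi_bg
      if (length(model$I[[u]])) m[, model$I[[u]]] <- model$phi_arch[[u]]
    } else {
      if (is.null(model$state)) {
        stop("raw-frequency export needs a model with its fitting state ",
             "(models reloaded from JSON carry only posterior means)")
      }
      st <- model$state
      bg_n <- colSums(st$bg_counts)
      m <- sweep(st$bg_counts, 2L, pmax(bg_n, 1L), "/")
      m[, bg_n == 0L] <- 0.25
      iu <- st$I[[u]]
      if (length(iu)) {
        ac <- st$arch_counts[[u]]
        if (st$size_counts[u] > 0L) {
          m[, iu] <- ac / st$size_counts[u]
        } else {
          m[, iu] <- 0.25
        }
      }
    }
    dimnames(m) <- list(NUC, labs)
    m
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (u in seq_len(k)) {
    nsites <- if (!is.null(model$state)) model$state$size_counts[u] else 20L
    writeLines(sprintf("MOTIF arch_%d", u), con)
    writeLines(paste("# TSS-relative positions:", paste(labs, collapse = " ")),
               con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0", l,
      max(nsites, 1L)), con)
    writeLines(apply(mats[[u]], 2L, function(col) {
      paste(sprintf("%.8f", col), collapse = " ")
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs written by [export_pwms()]
#'
#' @param path a MEME minimal motif file
#' @return named list of 4 x w probability matrices, columns labeled by
#'   TSS-relative position when the file records them
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  out <- list()
  for (s in starts) {
    name <- sub("^MOTIF\\s+(\\S+).*$", "\\1", lines[s])
    labs <- NULL
    i <- s + 1L
    while (i <= length(lines) && !grepl("^letter-probability matrix", lines[i])) {
      if (grepl("^# TSS-relative positions:", lines[i])) {
        labs <- strsplit(sub("^# TSS-relative positions:\\s*", "", lines[i]),
                         "\\s+")[[1L]]
      }
      i <- i + 1L
    }
    if (i > length(lines)) break
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[i]))
    rows <- lines[(i + 1L):(i + w)]
    m <- vapply(strsplit(trimws(rows), "\\s+"),
                function(x) as.numeric(x), numeric(4))
    dimnames(m) <- list(NUC, labs)
    out[[name]] <- m
  }
  out
}
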