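#' Save a fitted model as JSON
#'
#' Writes the model structure, mixture weights, and all positional
#' probability tables (keyed by TSS-relative position, no position 0) with
#' full decimal precision (17 significant digits), so that a save/load
#' round trip is bit-stable.  Count tables are not serialized; a reloaded
#' model supports every likelihood-based operation but not raw-frequency
#' PWM export.
#'
#' @param model a `promarch_model`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "promarch_model"))
  labs <- colnames(model$phi_bg)
  doc <- list(
    format = "promarch_model",
    package_version = as.character(utils::packageVersion("promarch")),
    structure = list(k = model$structure$k, p = model$structure$p),
    tss_offset = model$tss_offset,
    prior = list(pseudocount = model$prior$pseudocount),
    seed = model$seed,
    score = model$score,
    gamma_hat = model$gamma_hat,
    phi_bg = stats::setNames(
      lapply(seq_along(labs), function(j) unname(model$phi_bg[, j])), labs
    ),
    phi_arch = lapply(model$phi_arch, function(ph) {
      cl <- colnames(ph)
      stats::setNames(lapply(seq_along(cl), function(j) unname(ph[, j])), cl)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       always_decimal = TRUE)
  invisible(path)
}

#' Load a fitted model saved by [write_model()]
#'
#' @param path path to a model JSON file
#' @return a `promarch_model`
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "promarch_model")) {
    stop("not a promarch model file: ", path)
  }
  k <- as.integer(doc$structure$k)
  p <- as.integer(unlist(doc$structure$p))
  tss_offset <- as.integer(doc$tss_offset)
  bg_labs <- names(doc$phi_bg)
  l <- length(bg_labs)
  phi_bg <- vapply(doc$phi_bg, function(v) as.numeric(unlist(v)), numeric(4))
  dimnames(phi_bg) <- list(NUC, bg_labs)
  labs <- tss_labels(l, tss_offset)
  phi_arch <- vector("list", k)
  I <- vector("list", k)
  for (u in seq_len(k)) {
    au <- doc$phi_arch[[u]]
    if (length(au)) {
      ph <- vapply(au, function(v) as.numeric(unlist(v)), numeric(4))
      dimnames(ph) <- list(NUC, names(au))
      phi_arch[[u]] <- ph
      I[[u]] <- match(as.integer(names(au)), labs)
    } else {
      phi_arch[[u]] <- matrix(numeric(0), 4L, 0L, dimnames = list(NUC, NULL))
      I[[u]] <- integer(0)
    }
  }
  structure(
    list(
      structure = model_structure(k, p),
      gamma_hat = as.numeric(unlist(doc$gamma_hat)),
      phi_arch = phi_arch,
      phi_bg = phi_bg,
      I = I,
      tss_offset = tss_offset,
      prior = prior_spec(as.numeric(doc$prior$pseudocount)),
      score = as.numeric(doc$score %||% NA_real_),
      seed = doc$seed %||% NA_integer_,
      state = NULL
    ),
    class = "promarch_model"
  )
}
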