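# Internal helpers shared across modules.

#' Run code with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds it, evaluates `code`, and restores the
#' state, so seeded package functions do not perturb user-level randomness.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific seed from a master seed
#'
#' Each pipeline stage consumes its own seed, derived deterministically from
#' the master seed and the stage name, so any stage can be re-run in isolation
#' and reproduce the full-pipeline result. The derived value is kept inside
#' the 32-bit integer range R requires.
#'
#' @param master_seed integer master seed.
#' @param stage character stage label, e.g. `"cohort"`, `"tuning:stm"`.
#' @return a single integer seed.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(length(master_seed) == 1, is.finite(master_seed),
            is.character(stage), length(stage) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(master_seed)) * 7919 + h * 104729) %% 2147483647)
}

#' Normalise a feature name for cross-table matching
#'
#' Lower-cases, trims, and collapses runs of whitespace and punctuation to a
#' single space, so spelling variants of the same metabolite (for example
#' "Sphingosine 1-phosphate" vs "sphingosine 1 phosphate") compare equal.
#' An optional synonym map (named character vector, `old = new`) is applied
#' after normalisation.
#'
#' @param x character vector of feature names.
#' @param synonyms optional named character vector mapping normalised
#'   spellings to a canonical normalised spelling.
#' @return normalised character vector.
#' @export
normalize_feature_name <- function(x, synonyms = NULL) {
  out <- tolower(trimws(x))
  out <- gsub("[[:space:][:punct:]]+", " ", out)
  out <- trimws(out)
  if (!is.null(synonyms)) {
    hit <- out %in% names(synonyms)
    out[hit] <- unname(synonyms[out[hit]])
  }
  out
}

# stop() with a consistent prefix-free message built by sprintf
abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
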