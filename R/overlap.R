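# Cross-model reporting: coefficient tables in long format, sign partitions
# of each model's support, and Venn-style overlap regions across the
# mortality, PECAM and sTM models. Feature names are matched after
# case/punctuation normalisation (published metabolite rosters mix
# spellings), with an optional synonym map.

#' Partition a fit's support by coefficient sign
#'
#' @param fit a `lasso_fit` or named coefficient vector.
#' @param model model label.
#' @param synonyms optional synonym map for [normalize_feature_name()].
#' @return object of class `model_support`: `model`, `positives`,
#'   `negatives` (normalised feature names).
#' @export
sign_partition <- function(fit, model = "model", synonyms = NULL) {
  w <- if (inherits(fit, "lasso_fit")) fit$w else fit
  if (is.null(names(w))) abort_fmt("coefficients must be named")
  nm <- normalize_feature_name(names(w), synonyms)
  structure(list(model = model,
                 positives = sort(unique(nm[w > 0])),
                 negatives = sort(unique(nm[w < 0]))),
            class = "model_support")
}

#' Venn regions of model supports, per sign
#'
#' For each sign, every exclusive region of the Venn partition across the
#' models: the key `"a&b"` holds features in models a and b and in no other
#' model. Region contents are invariant to the order the supports are given
#' in (keys use sorted model names).
#'
#' @param supports list of `model_support` objects with distinct model names.
#' @return list with elements `positive` and `negative`, each a named list
#'   of feature vectors keyed by the region's model combination.
#' @export
support_overlap <- function(supports) {
  if (!length(supports)) abort_fmt("need at least one support")
  models <- vapply(supports, `[[`, character(1), "model")
  if (anyDuplicated(models)) abort_fmt("duplicate model names")
  one_sign <- function(field) {
    sets <- setNames(lapply(supports, `[[`, field), models)
    feats <- sort(unique(unlist(sets)))
    if (!length(feats)) return(setNames(list(), character(0)))
    membership <- vapply(sets, function(s) feats %in% s,
                         logical(length(feats)))
    membership <- matrix(membership, nrow = length(feats),
                         dimnames = list(feats, models))
    key <- apply(membership, 1, function(m)
      paste(sort(models[m]), collapse = "&"))
    split(feats, key)
  }
  list(positive = one_sign("positives"), negative = one_sign("negatives"))
}

#' Features shared by all models, per sign
#'
#' Convenience wrapper over the full intersection (e.g. metabolites
#' positively associated with mortality and with both endothelial markers).
#'
#' @inheritParams support_overlap
#' @return list with `positive` and `negative` character vectors.
#' @export
support_in_all <- function(supports) {
  list(positive = Reduce(intersect, lapply(supports, `[[`, "positives")),
       negative = Reduce(intersect, lapply(supports, `[[`, "negatives")))
}

#' Long-format coefficient table across models
#'
#' One row per nonzero coefficient: `model`, `metabolite`, `coefficient`,
#' sorted by model then decreasing absolute coefficient.
#'
#' @param fits named list of `lasso_fit` objects (or named coefficient
#'   vectors); list names are the model labels.
#' @return a data frame.
#' @export
coefficient_table <- function(fits) {
  if (is.null(names(fits))) abort_fmt("fits must be a named list")
  rows <- lapply(names(fits), function(m) {
    w <- if (inherits(fits[[m]], "lasso_fit")) fits[[m]]$w else fits[[m]]
    w <- w[w != 0]
    if (!length(w))
      return(data.frame(model = character(0), metabolite = character(0),
                        coefficient = numeric(0)))
    data.frame(model = m, metabolite = names(w), coefficient = unname(w),
               row.names = NULL)[order(-abs(w)), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write/read a coefficient table with lossless round-trip
#'
#' Coefficients are serialised with 17 significant digits so that
#' write -> read reproduces them bit-for-bit.
#'
#' @param table a coefficient table.
#' @param path CSV path.
#' @export
write_coefficient_table <- function(table, path) {
  tab <- table
  tab$coefficient <- sprintf("%.17g", tab$coefficient)
  write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_coefficient_table
#' @export
read_coefficient_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(model = "character",
                                 metabolite = "character",
                                 coefficient = "character"))
  out$coefficient <- as.numeric(out$coefficient)
  out
}

#' Venn-region size summary across supports
#'
#' @inheritParams support_overlap
#' @return list (suitable for JSON) with per-sign region sizes and members.
#' @export
overlap_summary <- function(supports) {
  ov <- support_overlap(supports)
  lapply(ov, function(sign_regions)
    lapply(sign_regions, function(r) list(n = length(r), members = r)))
}
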