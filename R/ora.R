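# Over-representation analysis of the penalised model's selected metabolites
# against pathway sets supplied in GMT format. Raw p is the upper-tail
# hypergeometric probability of the observed overlap; the enrichment score is
# -log10(raw p); adjusted p-values use Benjamini-Hochberg across tested
# pathways.

#' Read a pathway collection from a GMT file
#'
#' Tab-separated, one set per line: column 1 = set id, column 2 =
#' description, columns 3+ = member identifiers. Members are trimmed,
#' matched case-insensitively (stored normalised via
#' [normalize_feature_name()]) and deduplicated within each set. The
#' universe is the union of all members.
#'
#' @param path GMT file path.
#' @return object of class `pathway_collection`: `sets` (named list of
#'   member vectors), `descriptions`, `universe`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_fmt("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort_fmt("GMT file is empty: %s", path)
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      abort_fmt("GMT parse error at line %d: fewer than 3 columns", i)
    id <- trimws(f[1])
    members <- unique(normalize_feature_name(f[-(1:2)]))
    members <- members[nzchar(members)]
    sets[[id]] <- members
    desc[id] <- trimws(f[2])
  }
  structure(list(sets = sets, descriptions = desc,
                 universe = sort(unique(unlist(sets)))),
            class = "pathway_collection")
}

#' Select features from a penalised fit
#'
#' Default rule: every feature with a nonzero coefficient (the model's
#' support). Alternative: the `top_k` features by absolute coefficient.
#'
#' @param fit a `lasso_fit`, or a named coefficient vector.
#' @param rule `"nonzero"` (default) or `"top_k"`.
#' @param k number of features for `"top_k"`.
#' @return character vector of selected feature names.
#' @export
select_features <- function(fit, rule = c("nonzero", "top_k"), k = NULL) {
  rule <- match.arg(rule)
  w <- if (inherits(fit, "lasso_fit")) fit$w else fit
  if (is.null(names(w))) abort_fmt("coefficients must be named")
  nz <- w[w != 0]
  if (rule == "nonzero") return(names(nz))
  if (is.null(k)) abort_fmt("rule 'top_k' requires k")
  names(nz)[order(abs(nz), decreasing = TRUE)][seq_len(min(k, length(nz)))]
}

#' Hypergeometric over-representation test
#'
#' For each pathway with at least `min_size` members in the universe, the
#' raw p-value is the upper-tail hypergeometric probability
#' `P(X >= overlap)` of drawing `|selected|` features from a universe
#' containing `pathway size` members of the pathway. The enrichment score is
#' `-log10(raw p)`; adjusted p-values are Benjamini-Hochberg across the
#' tested pathways. Feature names are matched after
#' [normalize_feature_name()].
#'
#' @param selected character vector of selected feature identifiers (must
#'   map into the universe).
#' @param pathways a `pathway_collection` (or named list of member vectors).
#' @param universe optional universe override (e.g. all measured, mappable
#'   metabolites); defaults to the collection's universe.
#' @param min_size smallest in-universe pathway tested (default 2).
#' @return data frame of class `ora_table`: `pathway`, `description`,
#'   `pathway_size`, `overlap`, `raw_p`, `ora_score`, `adjusted_p`, sorted
#'   by raw p.
#' @export
ora_test <- function(selected, pathways, universe = NULL, min_size = 2L) {
  if (inherits(pathways, "pathway_collection")) {
    sets <- pathways$sets; desc <- pathways$descriptions
    if (is.null(universe)) universe <- pathways$universe
  } else {
    sets <- lapply(pathways, normalize_feature_name)
    desc <- setNames(names(sets), names(sets))
    if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  }
  universe <- unique(normalize_feature_name(universe))
  selected <- unique(normalize_feature_name(selected))
  unmapped <- setdiff(selected, universe)
  if (length(unmapped))
    abort_fmt("selected features not in the universe: %s",
              paste(unmapped, collapse = ", "))
  sets <- lapply(sets, intersect, universe)
  sizes <- lengths(sets)
  keep <- sizes >= min_size
  if (!any(keep)) abort_fmt("no pathway has >= min_size members in the universe")
  sets <- sets[keep]; sizes <- sizes[keep]

  Nuniv <- length(universe); ndraw <- length(selected)
  rows <- lapply(names(sets), function(id) {
    ov <- length(intersect(selected, sets[[id]]))
    p <- if (ndraw == 0L) 1 else
      phyper(ov - 1L, sizes[[id]], Nuniv - sizes[[id]], ndraw,
             lower.tail = FALSE)
    data.frame(pathway = id,
               description = unname(desc[id]),
               pathway_size = sizes[[id]],
               overlap = ov,
               raw_p = p,
               ora_score = -log10(p),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- p.adjust(out$raw_p, method = "BH")
  out <- out[order(out$raw_p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ora_table", "data.frame")
  out
}
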