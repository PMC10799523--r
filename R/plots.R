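# Diagnostic plots (ggplot2, Suggests): penalty-selection histogram, ROC
# overlay, ORA dot plot. Each returns a ggplot object; callers decide where
# to write it.

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    abort_fmt("ggplot2 is required for plotting")
}

#' Histogram of per-bootstrap selected penalties
#' @param search a `lambda_search`.
#' @return a ggplot object.
#' @export
plot_lambda_histogram <- function(search) {
  need_ggplot2()
  df <- data.frame(lambda = search$per_bootstrap_lambda)
  ggplot2::ggplot(df, ggplot2::aes(x = log10(lambda))) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = log10(search$median_lambda),
                        linetype = "dashed") +
    ggplot2::labs(x = "log10(selected lambda)", y = "bootstrap count",
                  title = sprintf("Median lambda = %.4g over %d bootstraps",
                                  search$median_lambda, search$B))
}

#' Overlayed ROC curves
#' @param rocs named list of `roc_curve` objects.
#' @return a ggplot object.
#' @export
plot_roc_overlay <- function(rocs) {
  need_ggplot2()
  df <- do.call(rbind, lapply(names(rocs), function(m) {
    p <- rocs[[m]]$points
    data.frame(model = sprintf("%s (AUC %.2f)", m, rocs[[m]]$auc),
               fpr = 1 - p$specificity, tpr = p$sensitivity)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = fpr, y = tpr, colour = model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity")
}

#' ORA dot plot
#'
#' Pathways positioned by -log10 of the BH-adjusted p-value, point size by
#' enrichment score.
#' @param tables named list of `ora_table` objects (one per model).
#' @param max_p show pathways with adjusted p below this (default 0.05).
#' @return a ggplot object.
#' @export
plot_ora_dotplot <- function(tables, max_p = 0.05) {
  need_ggplot2()
  df <- do.call(rbind, lapply(names(tables), function(m) {
    t <- tables[[m]]
    t <- t[t$adjusted_p < max_p, , drop = FALSE]
    if (!nrow(t)) return(NULL)
    data.frame(model = m, pathway = t$pathway,
               neglog_adj = -log10(pmax(t$adjusted_p, 1e-16)),
               score = t$ora_score)
  }))
  if (is.null(df) || !nrow(df)) abort_fmt("no pathway passes max_p")
  ggplot2::ggplot(df, ggplot2::aes(x = model, y = pathway,
                                   colour = neglog_adj, size = score)) +
    ggplot2::geom_point() +
    ggplot2::labs(colour = "-log10 adj. p", size = "ORA score")
}
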