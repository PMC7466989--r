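## Optional ggplot2 figures ------------------------------------------------

#' Bar-with-interval plot of strain-level predictions
#'
#' Bars are the predicted strain (or strain-by-treatment) deviations in
#' ascending order; vertical segments are the prediction intervals.
#' Requires ggplot2.
#'
#' @param blups A [compute_blups()] result.
#' @param effect Which random effect to display.
#' @return A ggplot object.
#' @export
plot_blups <- function(blups, effect = "strain") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    rix_abort("ggplot2 is required for plotting", "rixmm_dependency_error")
  }
  d <- as.data.frame(blups[blups$effect == effect, ])
  if (nrow(d) == 0L) {
    rix_abort(sprintf("no '%s' predictions in this blup_result", effect),
              "rixmm_schema_error")
  }
  d$level <- factor(d$level, levels = d$level[order(d$blup)])
  ggplot2::ggplot(d, ggplot2::aes(x = level, y = blup)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = lower, ymax = upper),
                           width = 0.3) +
    ggplot2::labs(x = NULL, y = "predicted deviation",
                  title = sprintf("%s predictions (%s)",
                                  effect, attr(blups, "endpoint"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Correlogram of cross-phenotype strain-effect correlations
#'
#' @param corr A [strain_effect_correlations()] result.
#' @return A ggplot object (tile heat map with printed coefficients).
#' @export
plot_correlogram <- function(corr) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    rix_abort("ggplot2 is required for plotting", "rixmm_dependency_error")
  }
  cm <- corr$correlation
  d <- expand.grid(x = rownames(cm), y = colnames(cm),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$r <- as.vector(cm)
  ggplot2::ggplot(d, ggplot2::aes(x = x, y = y, fill = r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", r)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "firebrick",
                                  mid = "white", high = "navy") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("strain-effect correlations (%s)", corr$effect)) +
    ggplot2::theme_minimal()
}
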