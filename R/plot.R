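#' Boxplot of overall and pairwise CCA across scenarios
#'
#' One panel summarising a scenario sweep: scenarios on the vertical axis
#' (1 at the top), CCA percentage on the horizontal axis, a labelled point
#' for the overall CCA of each scenario and a box for the distribution of
#' its defined pairwise CCA values. A dashed line separates the
#' overview-level scenarios (1--8) from the outcome-level ones (9--16).
#' Undefined scenarios simply leave gaps; they are never drawn as zeros.
#'
#' @param sweep a [SweepResult-class].
#' @param title optional plot title.
#' @return a `ggplot` object.
#' @examples
#' ds <- generateOverview(generatorConfig(seed = 4))
#' plotSweep(runScenarioSweep(ds))
#' @export
plotSweep <- function(sweep, title = NULL) {
  stopifnot(methods::is(sweep, "SweepResult"))
  rec <- as.data.frame(sweep@records)
  rec$scenarioF <- factor(rec$scenario, levels = rev(1:16))

  pairLong <- do.call(rbind, lapply(seq_len(16L), function(k) {
    res <- sweep@results[[k]]
    if (is.null(res) || !length(res@pairwise)) return(NULL)
    v <- res@pairwise[upper.tri(res@pairwise)]
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    data.frame(scenario = k, cca = v)
  }))

  g <- ggplot2::ggplot()
  if (!is.null(pairLong)) {
    pairLong$scenarioF <- factor(pairLong$scenario, levels = rev(1:16))
    g <- g + ggplot2::geom_boxplot(
      data = pairLong,
      ggplot2::aes(x = .data$cca, y = .data$scenarioF),
      outlier.size = 0.6, linewidth = 0.3, fill = "grey90")
  }
  ov <- rec[!is.na(rec$overall_cca), ]
  g + ggplot2::geom_point(
        data = ov,
        ggplot2::aes(x = .data$overall_cca, y = .data$scenarioF),
        size = 1.8) +
    ggplot2::geom_text(
      data = ov,
      ggplot2::aes(x = .data$overall_cca, y = .data$scenarioF,
                   label = sprintf("%.1f", .data$overall_cca)),
      hjust = -0.4, size = 2.8) +
    ggplot2::geom_hline(yintercept = 8.5, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_x_continuous(limits = c(0, NA),
                                expand = ggplot2::expansion(mult = c(0.02, 0.12))) +
    ggplot2::labs(x = "CCA (%)", y = "Scenario", title = title,
                  caption = "point: overall CCA; box: pairwise CCA; dashed line: overview- vs outcome-level scenarios") +
    ggplot2::theme_minimal(base_size = 10)
}
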