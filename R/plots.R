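#' @include sbml.R
NULL

#' Plot selected species time courses
#' @param traj a Trajectory.
#' @param species species ids to plot.
#' @param normalize divide each series by its stimulus-start value.
#' @return a ggplot object.
#' @export
plotTrajectory <- function(traj, species, normalize = TRUE) {
  df <- trajectoryToDataFrame(traj, species)
  if (normalize) {
    base <- stimulusBaseline(traj)
    df$amount <- df$amount / base[df$species]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amount,
                                   color = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = traj@phaseMarks$time,
                        linetype = "dashed", color = "grey60") +
    ggplot2::labs(x = "time (h)",
                  y = if (normalize) "fold of baseline" else "amount") +
    ggplot2::theme_minimal()
}

#' Plot proliferation/damage/cell-function scores over time
#' @param score a ScoreSeries.
#' @return a ggplot object.
#' @export
plotScoreSeries <- function(score) {
  df <- data.frame(time = rep(score@times, 3),
                   value = c(score@proliferation, score@damage,
                             score@cellFunction),
                   score = rep(c("proliferation", "damage", "cell function"),
                               each = length(score@times)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   color = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "score (log scale)") +
    ggplot2::theme_minimal()
}

#' Heatmap of an OGD x reoxygenation phenotype grid
#' @param grid a PhenotypeGrid.
#' @return a ggplot object.
#' @export
plotPhenotypeGrid <- function(grid) {
  df <- gridToDataFrame(grid)
  df$condition <- sprintf("%gh re-%gh", df$ogd_h, df$reox_h)
  df$condition <- factor(df$condition, levels = unique(df$condition))
  df$marker <- factor(df$marker, levels = rev(grid@markers))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$marker,
                                   fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "OGD / reoxygenation condition", y = NULL,
                  fill = "log2 FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Tornado plot of PRCC values for one output
#' @param result a SensitivityResult.
#' @param outputId output to plot.
#' @param topK number of parameters shown.
#' @return a ggplot object.
#' @export
plotSensitivity <- function(result, outputId, topK = 15) {
  j <- match(outputId, result@outputIds)
  if (is.na(j)) stop("unknown output id: ", outputId)
  df <- data.frame(parameter = result@parameterIds,
                   prcc = result@prcc[, j])
  df <- df[order(-abs(df$prcc)), ][seq_len(min(topK, nrow(df))), ]
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prcc, y = .data$parameter)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "PRCC", y = NULL, title = outputId) +
    ggplot2::theme_minimal()
}

#' Histogram of cohort cell-function fold changes
#' @param summary output of \code{\link{summarizeCohort}}.
#' @return a ggplot object.
#' @export
plotCohortSummary <- function(summary) {
  df <- data.frame(fc = summary$fold_changes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fc)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue",
                            color = "white") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "CF fold change (treated / control)", y = "cells") +
    ggplot2::theme_minimal()
}
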