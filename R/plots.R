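#' Normed likelihood curves with prediction-interval threshold
#'
#' One panel per stage group: the normed likelihood over age, the horizontal
#' line at the level's normed-likelihood cutoff (0.1465 for 95 percent) whose
#' crossings delimit the prediction interval, a dashed vertical line at the
#' legal age threshold of 18 years, and a solid vertical line at the point
#' prediction of interior groups.
#'
#' @param object a fitted `transition_model`.
#' @param level prediction-interval level.
#' @param age_min,age_max,step age grid for the curves.
#' @param threshold_age legal age threshold drawn as a dashed line.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.transition_model <- function(object, level = 0.95, age_min = 13,
                                      age_max = 25, step = 0.01,
                                      threshold_age = 18, ...) {
  curves <- likelihood_curve(object, age_min = age_min, age_max = age_max,
                             step = step)
  preds <- age_predictions(object, level = level,
                           sample_age_min = age_min,
                           sample_age_max = age_max, step = step)
  mla <- dplyr::filter(preds, !.data$terminal) |>
    dplyr::mutate(stage_group = factor(.data$stage_group,
                                       levels = object$groups))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$age_years,
                               y = .data$normed_likelihood)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = normed_threshold(level),
                        linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = threshold_age, linetype = "dashed") +
    ggplot2::geom_vline(data = mla, ggplot2::aes(xintercept = .data$mla)) +
    ggplot2::facet_wrap(~stage_group) +
    ggplot2::labs(x = "Age (years)", y = "Normed likelihood") +
    ggplot2::theme_bw()
}

#' Age-by-stage box plots, by side
#'
#' @param observations per-clavicle observation tibble.
#' @return a ggplot object: chronological age against stage, one box per
#'   (stage, side).
#' @export
plot_stage_ages <- function(observations) {
  df <- dplyr::mutate(observations,
                      stage = factor(.data$stage, levels = stage_levels()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$age_years,
                                   fill = .data$side)) +
    ggplot2::geom_boxplot(outlier.shape = 16, position = "dodge") +
    ggplot2::labs(x = "Ossification stage", y = "Chronological age (years)",
                  fill = "Side") +
    ggplot2::theme_bw()
}

#' Pairwise rater-agreement bubble plot
#'
#' For every rater pair, the cross-tabulation of assigned stages as a bubble
#' grid: dots on the identity diagonal are complete agreement, dot size the
#' frequency of the stage combination; `"NE"` is shown as its own category.
#'
#' @param ratings tibble of rating records ([read_ratings()]).
#' @return a ggplot object faceted by rater pair.
#' @export
plot_agreement_pairs <- function(ratings) {
  mat <- rater_matrix(ratings, include_not_evaluable = TRUE)
  cats <- order_categories(mat)
  pairs <- utils::combn(colnames(mat), 2, simplify = FALSE)
  df <- purrr::map_dfr(pairs, function(pr) {
    tibble::tibble(pair = paste(pr, collapse = " vs "),
                   a = factor(mat[, pr[1]], levels = cats),
                   b = factor(mat[, pr[2]], levels = cats))
  }) |>
    dplyr::count(.data$pair, .data$a, .data$b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   size = .data$n)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "Stage (first rater)", y = "Stage (second rater)",
                  size = "Count") +
    ggplot2::theme_bw()
}
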