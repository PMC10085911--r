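#' Normed-likelihood cutoff for a prediction interval
#'
#' Inverting the normed likelihood by Wilks' theorem, ages whose normed
#' likelihood exceeds exp(-q/2) — q the `level` quantile of chi-squared with
#' one degree of freedom — form the level-prediction interval. For
#' level = 0.95 the cutoff is 0.1465.
#'
#' @param level confidence level in (0, 1).
#' @return the cutoff in (0, 1).
#' @examples
#' normed_threshold(0.95)
#' @export
normed_threshold <- function(level) {
  stopifnot(is.numeric(level), level > 0, level < 1)
  exp(-stats::qchisq(level, df = 1) / 2)
}

#' Normed likelihood curves over an age grid
#'
#' For each stage group, P(group | age) evaluated on a regular age grid and
#' divided by its grid maximum, so every curve peaks at exactly 1. Interior
#' groups give unimodal curves; the lowest and highest groups are monotone
#' over realistic age windows.
#'
#' @param model a fitted [fit_transition_model()] object.
#' @param groups stage-group labels to include (default: all fitted groups).
#' @param age_min,age_max age window in years (default 13-25).
#' @param step grid step in years.
#' @return a tibble: `stage_group`, `age_years`, `normed_likelihood`.
#' @export
likelihood_curve <- function(model, groups = NULL, age_min = 13,
                             age_max = 25, step = 0.01) {
  stopifnot(inherits(model, "transition_model"), step > 0,
            age_max > age_min)
  if (is.null(groups)) groups <- model$groups
  stopifnot(all(groups %in% model$groups))
  grid <- seq(age_min, age_max, by = step)
  p <- group_prob_matrix(model, grid)
  purrr::map_dfr(groups, function(g) {
    lk <- p[, g]
    tibble::tibble(stage_group = g, age_years = grid,
                   normed_likelihood = lk / max(lk))
  }) |>
    dplyr::mutate(stage_group = factor(.data$stage_group, levels = groups))
}

#' Point prediction (maximum likelihood age) for one stage group
#'
#' The age maximising the stage-group likelihood. The lowest and highest
#' groups have no interior maximum (their likelihood is monotone), so by
#' convention their point prediction is substituted by the sample minimum
#' and maximum age respectively, and flagged as terminal.
#'
#' @param curve one group's rows of a [likelihood_curve()] tibble.
#' @param terminal `"none"`, `"lowest"` or `"highest"`: is this the terminal
#'   group at either end of the scale?
#' @param sample_age_min,sample_age_max observed age range of the sample,
#'   used as the substitution values for terminal groups.
#' @return a one-row tibble: `mla` (years), `terminal` (logical).
#' @export
point_prediction <- function(curve, terminal = "none",
                             sample_age_min = NULL, sample_age_max = NULL) {
  stopifnot(terminal %in% c("none", "lowest", "highest"))
  if (terminal == "lowest") {
    stopifnot(!is.null(sample_age_min))
    return(tibble::tibble(mla = sample_age_min, terminal = TRUE))
  }
  if (terminal == "highest") {
    stopifnot(!is.null(sample_age_max))
    return(tibble::tibble(mla = sample_age_max, terminal = TRUE))
  }
  tibble::tibble(mla = curve$age_years[which.max(curve$normed_likelihood)],
                 terminal = FALSE)
}

#' Prediction interval from a normed likelihood curve
#'
#' The smallest and largest ages whose normed likelihood reaches
#' [normed_threshold()] for the requested level, with the crossing refined by
#' linear interpolation between grid points and the bounds clipped to the
#' grid window. For terminal groups the curve is monotone, so the interval
#' end at the monotone side sits on the window bound — reflecting the
#' sample's minimum (lowest group) or maximum (highest group) age.
#'
#' @param curve one group's rows of a [likelihood_curve()] tibble.
#' @param level confidence level in (0, 1), default 0.95.
#' @return a one-row tibble: `pi_low`, `pi_high` (years).
#' @export
prediction_interval <- function(curve, level = 0.95) {
  thr <- normed_threshold(level)
  a <- curve$age_years
  lk <- curve$normed_likelihood
  above <- which(lk >= thr)
  stopifnot(length(above) > 0)  # the maximum is 1 > thr by construction
  lo_i <- min(above); hi_i <- max(above)
  lo <- if (lo_i == 1) a[1] else
    interp_crossing(a[lo_i - 1], a[lo_i], lk[lo_i - 1], lk[lo_i], thr)
  hi <- if (hi_i == length(a)) a[length(a)] else
    interp_crossing(a[hi_i], a[hi_i + 1], lk[hi_i], lk[hi_i + 1], thr)
  tibble::tibble(pi_low = lo, pi_high = hi)
}

interp_crossing <- function(a0, a1, l0, l1, thr) {
  a0 + (thr - l0) / (l1 - l0) * (a1 - a0)
}

#' Per-group age predictions with prediction intervals
#'
#' The prediction report of a transition analysis: for every fitted stage
#' group, the maximum likelihood age (MLA; terminal groups substituted by the
#' sample age extremes), the level-prediction interval from the normed
#' likelihood curve, and the group's sample count.
#'
#' @inheritParams likelihood_curve
#' @param level confidence level for the prediction interval.
#' @param sample_age_min,sample_age_max observed age range; default the
#'   fitted data's range, rounded outward to 2 decimals.
#' @return a tibble, one row per group: `stage_group`, `n`, `mla`,
#'   `pi_low`, `pi_high`, `terminal`.
#' @export
age_predictions <- function(model, level = 0.95, sample_age_min = NULL,
                            sample_age_max = NULL, step = 0.01) {
  stopifnot(inherits(model, "transition_model"))
  if (is.null(model$data) &&
      (is.null(sample_age_min) || is.null(sample_age_max))) {
    stop("model carries no data: supply sample_age_min and sample_age_max",
         call. = FALSE)
  }
  if (is.null(sample_age_min)) sample_age_min <- min(model$data$age_years)
  if (is.null(sample_age_max)) sample_age_max <- max(model$data$age_years)
  curves <- likelihood_curve(model, age_min = sample_age_min,
                             age_max = sample_age_max, step = step)
  counts <- if (!is.null(model$data)) {
    tabulate(as.integer(model$data$stage_group), model$J)
  } else {
    rep(NA_integer_, model$J)
  }
  purrr::map_dfr(seq_along(model$groups), function(j) {
    g <- model$groups[j]
    cv <- dplyr::filter(curves, .data$stage_group == g)
    terminal <- if (j == 1) "lowest" else if (j == model$J) "highest" else
      "none"
    pp <- point_prediction(cv, terminal, sample_age_min, sample_age_max)
    pi <- prediction_interval(cv, level)
    tibble::tibble(stage_group = g, n = counts[j], mla = pp$mla,
                   pi_low = pi$pi_low, pi_high = pi$pi_high,
                   terminal = pp$terminal)
  })
}

#' Minor/adult classification by point prediction
#'
#' The legal question behind the analysis: is the individual at least 18?
#' The rule classifies as adult exactly when the point prediction (MLA) is
#' at or above the threshold; ties at exactly 18.0 count as adult.
#'
#' @param mla numeric vector of point predictions in years.
#' @param threshold legal age threshold, default 18.
#' @return a factor with levels `minor`, `adult`.
#' @export
classify_adult <- function(mla, threshold = 18) {
  factor(ifelse(mla >= threshold, "adult", "minor"),
         levels = c("minor", "adult"))
}

#' Accuracy, specificity and sensitivity of minor/adult classification
#'
#' Accuracy is the percentage of correctly classified individuals,
#' specificity the percentage of true minors classified as minors, and
#' sensitivity the percentage of true adults classified as adults.
#' Components undefined for the sample at hand (no minors, or no adults) are
#' reported as `NA`, never as 0.
#'
#' @param predicted_adult logical (or `classify_adult()` factor): classified
#'   as adult?
#' @param true_adult logical: actually 18 or older?
#' @return a one-row tibble: `n`, `accuracy`, `specificity`, `sensitivity`
#'   (percentages in [0, 100]).
#' @export
classification_metrics <- function(predicted_adult, true_adult) {
  if (is.factor(predicted_adult)) {
    predicted_adult <- predicted_adult == "adult"
  }
  stopifnot(length(predicted_adult) == length(true_adult))
  n <- length(true_adult)
  pct <- function(x) if (length(x) == 0) NA_real_ else 100 * mean(x)
  tibble::tibble(
    n = n,
    accuracy = pct(predicted_adult == true_adult),
    specificity = pct(!predicted_adult[!true_adult]),
    sensitivity = pct(predicted_adult[true_adult])
  )
}
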