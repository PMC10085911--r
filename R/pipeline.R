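#' Per-subject observations using the highest (or lowest) reached stage
#'
#' For the detailed model every subject with at least one staged clavicle
#' contributes one row carrying the more advanced of the available stages
#' (`which.max`), the convention under which the best-performing
#' constellation is refitted on all assessable cases.
#'
#' @param observations per-clavicle observation tibble
#'   ([stage_observations()]).
#' @param pick `which.max` (default) or `which.min` of the stage rank.
#' @return a tibble with one row per subject: `subject_id`, `stage`,
#'   `stage_group`, `age_years`, `adult`.
#' @export
max_stage_observations <- function(observations, pick = which.max) {
  observations |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::slice(pick(.data$stage_rank)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("subject_id", "stage", "stage_group",
                                  "age_years", "adult")))
}

#' Run the complete staging-to-validation pipeline
#'
#' Reads the ratings and subject files, resolves consensus stages, and
#' writes the full set of report files to `out_dir`:
#' \describe{
#'   \item{descriptives.csv}{age summaries per stage and side}
#'   \item{side_comparison.csv}{left-right concordance counts and the paired
#'     Wilcoxon test}
#'   \item{agreement.csv}{inter-rater agreement panel (and, when a re-read
#'     table is supplied, `intra_rater.csv`)}
#'   \item{validation.csv}{MAE/RMSE over the seven constellations}
#'   \item{transition_model.json}{the final max-stage model dump}
#'   \item{predictions.csv}{per-group MLA and prediction intervals}
#'   \item{diagnostics.csv}{LM fit test, pseudo R-squared and minor/adult
#'     classification metrics of the final model}
#'   \item{curves.csv}{normed likelihood curves (age, normed likelihood)}
#'   \item{likelihood_curves.pdf}{the curve figure (unless `plots = FALSE`)}
#' }
#' The final model follows the max-stage convention: every subject with at
#' least one staged clavicle enters with the highest reached stage.
#'
#' @param ratings_path,subjects_path input files (see [read_ratings()] and
#'   [read_subjects()]).
#' @param out_dir output directory, created if missing.
#' @param reread_path optional CSV with columns `rater_id`, `first_pass`,
#'   `second_pass` for intra-rater agreement.
#' @param adjudicator rater deciding three-way splits.
#' @param transform age transform of the transition model.
#' @param level prediction-interval level.
#' @param k,seed cross-validation folds and seed.
#' @param delim input field delimiter.
#' @param plots write the likelihood-curve figure?
#' @return invisibly, a list with the key result tables and the paths
#'   written.
#' @export
run_pipeline <- function(ratings_path, subjects_path, out_dir,
                         reread_path = NULL, adjudicator = "R3",
                         transform = "log", level = 0.95, k = 10,
                         seed = 20221219, delim = ",", plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  ratings <- read_ratings(ratings_path, delim = delim)
  subjects <- read_subjects(subjects_path, delim = delim)
  consensus <- consensus_ratings(ratings, adjudicator = adjudicator)
  obs <- stage_observations(consensus, subjects)

  desc <- descriptive_table(obs)
  readr::write_csv(desc, p("descriptives.csv"))

  side <- dplyr::bind_cols(
    side_concordance(obs),
    dplyr::select(paired_side_test(obs), -"n_pairs")
  )
  readr::write_csv(side, p("side_comparison.csv"))

  agree <- agreement_report(ratings)
  readr::write_csv(agree, p("agreement.csv"))
  intra <- NULL
  if (!is.null(reread_path)) {
    reread <- readr::read_csv(reread_path, show_col_types = FALSE)
    intra <- reread |>
      dplyr::group_by(.data$rater_id) |>
      dplyr::group_modify(function(df, key) {
        dplyr::bind_rows(
          intra_rater_agreement(df$first_pass, df$second_pass,
                                include_not_evaluable = TRUE),
          intra_rater_agreement(df$first_pass, df$second_pass,
                                include_not_evaluable = FALSE)
        )
      }) |>
      dplyr::ungroup()
    readr::write_csv(intra, p("intra_rater.csv"))
  }

  validation <- validate_constellations(obs, k = k, seed = seed,
                                        transform = transform)
  readr::write_csv(validation, p("validation.csv"))

  final_data <- max_stage_observations(obs)
  model <- fit_transition_model(final_data, transform = transform)
  write_transition_model(model, p("transition_model.json"))

  preds <- age_predictions(model, level = level)
  readr::write_csv(preds, p("predictions.csv"))

  mla <- stats::setNames(preds$mla, preds$stage_group)
  classified <- classify_adult(mla[as.character(final_data$stage_group)])
  metrics <- classification_metrics(classified, final_data$adult)
  diag <- dplyr::bind_cols(fit_diagnostics(model), metrics)
  readr::write_csv(diag, p("diagnostics.csv"))

  curves <- likelihood_curve(model,
                             age_min = min(final_data$age_years),
                             age_max = max(final_data$age_years))
  readr::write_csv(curves, p("curves.csv"))
  if (plots) {
    ggplot2::ggsave(p("likelihood_curves.pdf"),
                    autoplot(model, level = level,
                             age_min = min(final_data$age_years),
                             age_max = max(final_data$age_years)),
                    width = 8, height = 5)
  }

  invisible(list(
    observations = obs, descriptives = desc, side_comparison = side,
    agreement = agree, intra_rater = intra, validation = validation,
    model = model, predictions = preds, diagnostics = diag,
    out_dir = out_dir
  ))
}
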