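#' Constellation names for cross-validation and test-set validation
#'
#' Seven constellations probe how the model generalises: 10-fold
#' cross-validation on each side alone, on the merged whole set (each
#' subject contributing both clavicles), and on the per-subject half sets
#' carrying the more (`halfmax`) or less (`halfmin`) advanced of the two
#' stages; plus the two cross-side designs training on one side and testing
#' on the other. All constellations use only subjects with both sides
#' staged.
#'
#' @return character vector of the seven names.
#' @export
constellation_names <- function() {
  c("right_cv", "left_cv", "whole_cv", "right_train_left_test",
    "left_train_right_test", "halfmax_cv", "halfmin_cv")
}

#' Build the train/test datasets of one validation constellation
#'
#' @param observations per-clavicle observation tibble
#'   ([stage_observations()]); only subjects with both sides staged are
#'   used.
#' @param name one of [constellation_names()].
#' @return a list: `train`, `test` (tibbles with `subject_id`,
#'   `stage_group`, `age_years`, `adult`), `folds` (`TRUE` when the
#'   constellation is cross-validated, `FALSE` for the cross-side designs
#'   where train and test are different sides).
#' @export
build_constellation <- function(observations, name) {
  if (!name %in% constellation_names()) {
    stop("unknown constellation ", sQuote(name), "; expected one of ",
         paste(constellation_names(), collapse = ", "), call. = FALSE)
  }
  cols <- c("subject_id", "stage_group", "age_years", "adult")
  paired_ids <- intersect(
    observations$subject_id[observations$side == "L"],
    observations$subject_id[observations$side == "R"]
  )
  obs <- dplyr::filter(observations, .data$subject_id %in% paired_ids)
  side_set <- function(s) obs[obs$side == s, cols]
  half_set <- function(which_fun) {
    obs |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::slice(which_fun(.data$stage_rank)) |>
      dplyr::ungroup() |>
      dplyr::select(dplyr::all_of(cols))
  }
  switch(name,
    right_cv = list(train = side_set("R"), test = side_set("R"),
                    folds = TRUE),
    left_cv = list(train = side_set("L"), test = side_set("L"),
                   folds = TRUE),
    whole_cv = list(train = obs[, cols], test = obs[, cols], folds = TRUE),
    right_train_left_test = list(train = side_set("R"),
                                 test = side_set("L"), folds = FALSE),
    left_train_right_test = list(train = side_set("L"),
                                 test = side_set("R"), folds = FALSE),
    halfmax_cv = list(train = half_set(which.max),
                      test = half_set(which.max), folds = TRUE),
    halfmin_cv = list(train = half_set(which.min),
                      test = half_set(which.min), folds = TRUE)
  )
}

# subject-level fold assignment, stratified by the subject's highest stage
# group so that no training fold loses a whole group unnecessarily
assign_folds <- function(data, k, seed) {
  strata <- data |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(stratum = max(as.integer(.data$stage_group)),
                     .groups = "drop")
  with_seed(seed, {
    folds <- strata |>
      dplyr::group_by(.data$stratum) |>
      dplyr::mutate(fold = sample(rep_len(seq_len(k), dplyr::n()))) |>
      dplyr::ungroup()
  })
  folds$fold[match(data$subject_id, folds$subject_id)]
}

# MLA per group of a fitted model, with fold-local terminal substitution
mla_lookup <- function(model, age_min, age_max, step = 0.01) {
  preds <- age_predictions(model, sample_age_min = age_min,
                           sample_age_max = age_max, step = step)
  stats::setNames(preds$mla, preds$stage_group)
}

pooled_errors <- function(err) {
  tibble::tibble(
    n_test = length(err),
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2))
  )
}

#' k-fold cross-validated age-prediction error
#'
#' Subjects are assigned to folds (all rows of a subject share a fold, so
#' the whole-set constellation never sees a subject on both sides of a
#' split), stratified by stage group. Each fold's model is fitted on the
#' remaining folds, every test clavicle receives the MLA of its stage group
#' (terminal groups substituted by the training fold's age extremes), and
#' the absolute and squared errors (chronological age minus point
#' prediction) are pooled over all folds into one MAE and RMSE. Test rows
#' whose stage group is absent from the training fold cannot be predicted
#' and are counted in `n_skipped`.
#'
#' @param data tibble with `subject_id`, `stage_group`, `age_years`.
#' @param k number of folds (default 10).
#' @param seed integer seed governing the fold assignment.
#' @param transform age transform passed to [fit_transition_model()].
#' @return a one-row tibble: `n_test`, `mae`, `rmse` (years), `n_skipped`.
#' @export
cross_validate <- function(data, k = 10, seed = 20221219,
                           transform = "log") {
  stopifnot(k >= 2, nrow(data) >= k)
  fold <- assign_folds(data, k, seed)
  errs <- numeric(0)
  skipped <- 0L
  for (f in seq_len(k)) {
    train <- data[fold != f, ]
    test <- data[fold == f, ]
    if (nrow(test) == 0) next
    model <- fit_transition_model(train, transform = transform)
    mla <- mla_lookup(model, min(train$age_years), max(train$age_years))
    pred <- mla[as.character(test$stage_group)]
    skipped <- skipped + sum(is.na(pred))
    ok <- !is.na(pred)
    errs <- c(errs, test$age_years[ok] - pred[ok])
  }
  dplyr::mutate(pooled_errors(errs), n_skipped = skipped)
}

#' Train/test age-prediction error
#'
#' Single fit on the training set, single evaluation on the test set, same
#' error metrics as [cross_validate()].
#'
#' @param train,test tibbles with `stage_group` and `age_years`.
#' @inheritParams cross_validate
#' @return a one-row tibble: `n_test`, `mae`, `rmse`, `n_skipped`.
#' @export
train_test <- function(train, test, transform = "log") {
  if (nrow(test) == 0) stop("empty test set", call. = FALSE)
  model <- fit_transition_model(train, transform = transform)
  mla <- mla_lookup(model, min(train$age_years), max(train$age_years))
  pred <- mla[as.character(test$stage_group)]
  ok <- !is.na(pred)
  dplyr::mutate(pooled_errors(test$age_years[ok] - pred[ok]),
                n_skipped = sum(!ok))
}

#' Validation report over all (or selected) constellations
#'
#' @inheritParams build_constellation
#' @param names constellations to run (default: all seven).
#' @inheritParams cross_validate
#' @return a tibble, one row per constellation: `constellation`, `n_train`,
#'   `n_test`, `mae`, `rmse`, `n_skipped`.
#' @export
validate_constellations <- function(observations,
                                    names = constellation_names(),
                                    k = 10, seed = 20221219,
                                    transform = "log") {
  purrr::map_dfr(names, function(nm) {
    cst <- build_constellation(observations, nm)
    rep <- if (cst$folds) {
      cross_validate(cst$train, k = k, seed = seed, transform = transform)
    } else {
      train_test(cst$train, cst$test, transform = transform)
    }
    dplyr::bind_cols(
      tibble::tibble(constellation = nm, n_train = nrow(cst$train)),
      rep
    )
  })
}
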