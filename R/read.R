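#' Read a multi-rater stage ratings file
#'
#' The ratings file is delimited text with one row per (subject, side, rater)
#' and columns `subject_id`, `side` (L/R), `rater_id`, `stage`,
#' `exclusion_reason` and `adjudicated_stage`. `stage` is a 9-level code or
#' `"NE"`; `exclusion_reason` (`motion` or `shape_variant`) must be present
#' exactly when the stage is `"NE"`; `adjudicated_stage` is consulted only
#' when all three raters disagree.
#'
#' @param path path to the delimited file (UTF-8, header row required).
#' @param delim field delimiter, default comma.
#' @return a tibble of rating records with canonicalised stage codes.
#' @seealso [consensus_ratings()], [read_subjects()]
#' @export
read_ratings <- function(path, delim = ",") {
  stopifnot(file.exists(path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  required <- c("subject_id", "side", "rater_id", "stage")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("ratings file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"exclusion_reason" %in% names(raw)) raw$exclusion_reason <- NA_character_
  if (!"adjudicated_stage" %in% names(raw)) raw$adjudicated_stage <- NA_character_

  side <- toupper(trimws(raw$side))
  if (!all(side %in% c("L", "R"))) {
    stop("side must be 'L' or 'R'; offending value: ",
         sQuote(setdiff(unique(side), c("L", "R"))[1]), call. = FALSE)
  }
  stage <- parse_stage(raw$stage)
  adjudicated <- parse_stage(raw$adjudicated_stage, allow_ne = TRUE)

  reason <- trimws(raw$exclusion_reason)
  reason[!is.na(reason) & reason == ""] <- NA_character_
  ok_reason <- is.na(reason) | reason %in% c("motion", "shape_variant")
  if (!all(ok_reason)) {
    stop("unknown exclusion_reason: ",
         sQuote(reason[!ok_reason][1]), call. = FALSE)
  }
  is_ne <- !is.na(stage) & stage == not_evaluable()
  if (any(is_ne & is.na(reason))) {
    stop("row ", which(is_ne & is.na(reason))[1],
         ": stage 'NE' requires an exclusion_reason", call. = FALSE)
  }
  if (any(!is_ne & !is.na(reason))) {
    stop("row ", which(!is_ne & !is.na(reason))[1],
         ": exclusion_reason given for an evaluable stage", call. = FALSE)
  }

  tibble::tibble(
    subject_id = as.character(raw$subject_id),
    side = side,
    rater_id = as.character(raw$rater_id),
    stage = stage,
    exclusion_reason = reason,
    adjudicated_stage = adjudicated
  )
}

#' Read a subject table
#'
#' Columns: `subject_id`, `age_years` (decimal chronological age) and
#' optionally `adult` (0/1). When `adult` is absent it is derived as
#' `age_years >= 18`.
#'
#' @inheritParams read_ratings
#' @return a tibble with columns `subject_id`, `age_years`, `adult` (logical).
#' @export
read_subjects <- function(path, delim = ",") {
  stopifnot(file.exists(path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  required <- c("subject_id", "age_years")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("subjects file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  age <- suppressWarnings(as.numeric(raw$age_years))
  if (any(is.na(age) | age <= 0)) {
    stop("age_years must be a positive decimal age; offending row ",
         which(is.na(age) | age <= 0)[1], call. = FALSE)
  }
  adult <- if ("adult" %in% names(raw)) {
    as.integer(raw$adult) == 1L
  } else {
    age >= 18
  }
  tibble::tibble(subject_id = as.character(raw$subject_id),
                 age_years = age, adult = adult)
}
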