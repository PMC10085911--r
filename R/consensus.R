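#' Consensus stage from three raters by majority vote with adjudication
#'
#' The final stage of a clavicle is the stage assigned by at least two of the
#' three raters ("not evaluable" counts as an ordinary vote category, so two
#' NE votes exclude the clavicle). When all three raters disagree, the
#' adjudicating rater re-evaluates the case knowing all assignments and that
#' re-evaluated stage — supplied in the `adjudicated` argument — decides.
#'
#' @param votes character vector of exactly three stage codes (9-level codes
#'   or `"NE"`), one per rater, in any order.
#' @param adjudicated the adjudicator's re-evaluated stage; consulted only on
#'   a three-way split, where it must be present.
#' @return a single stage code (possibly `"NE"`).
#' @examples
#' consensus_stage(c("3a", "3a", "3b"))
#' consensus_stage(c("2a", "3a", "4"), adjudicated = "3a")
#' @export
consensus_stage <- function(votes, adjudicated = NA_character_) {
  votes <- parse_stage(votes)
  if (length(votes) != 3 || any(is.na(votes))) {
    stop("exactly three non-missing votes are required per clavicle",
         call. = FALSE)
  }
  tab <- table(votes)
  if (max(tab) >= 2) {
    return(names(tab)[which.max(tab)])
  }
  adjudicated <- parse_stage(adjudicated)
  if (is.na(adjudicated)) {
    stop("three-way split but no adjudicated stage supplied", call. = FALSE)
  }
  adjudicated
}

#' Resolve consensus stages for a whole ratings table
#'
#' Applies [consensus_stage()] per (subject, side). Each clavicle must carry
#' exactly one rating from each of the three configured raters. On three-way
#' splits the `adjudicated_stage` recorded on the adjudicator's row is used.
#' For clavicles excluded by consensus (two or more NE votes) the modal
#' exclusion reason among the NE votes is reported.
#'
#' @param ratings a tibble of rating records as returned by [read_ratings()].
#' @param adjudicator the `rater_id` whose re-evaluated stage decides
#'   three-way splits.
#' @return a tibble with one row per clavicle: `subject_id`, `side`,
#'   `stage` (consensus code, possibly `"NE"`), `exclusion_reason`,
#'   `three_way_split` (logical).
#' @export
consensus_ratings <- function(ratings, adjudicator = "R3") {
  raters <- sort(unique(ratings$rater_id))
  if (length(raters) != 3) {
    stop("expected ratings from exactly 3 raters, found ", length(raters),
         call. = FALSE)
  }
  if (!adjudicator %in% raters) {
    stop("adjudicator ", sQuote(adjudicator), " is not among the raters",
         call. = FALSE)
  }
  counts <- dplyr::count(ratings, .data$subject_id, .data$side, .data$rater_id)
  if (any(counts$n != 1) ||
      nrow(counts) != 3 * nrow(dplyr::distinct(ratings, .data$subject_id,
                                               .data$side))) {
    stop("each clavicle must carry exactly one rating per rater",
         call. = FALSE)
  }

  ratings |>
    dplyr::group_by(.data$subject_id, .data$side) |>
    dplyr::group_modify(function(df, key) {
      split3 <- length(unique(df$stage)) == 3
      adj <- df$adjudicated_stage[df$rater_id == adjudicator]
      stage <- consensus_stage(df$stage, adjudicated = adj)
      reason <- NA_character_
      if (stage == not_evaluable()) {
        rs <- df$exclusion_reason[df$stage == not_evaluable()]
        rs <- rs[!is.na(rs)]
        if (length(rs) > 0) reason <- names(which.max(table(rs)))
      }
      tibble::tibble(stage = stage, exclusion_reason = reason,
                     three_way_split = split3)
    }) |>
    dplyr::ungroup()
}

#' Join consensus stages to subject ages
#'
#' Drops clavicles excluded as not evaluable, joins the chronological age and
#' adult status, and attaches the 9-level rank and the collapsed stage group,
#' yielding the per-clavicle observation table every downstream analysis
#' consumes (one row per evaluable clavicle).
#'
#' @param consensus output of [consensus_ratings()] (or any tibble with
#'   `subject_id`, `side`, `stage`).
#' @param subjects output of [read_subjects()].
#' @return a tibble: `subject_id`, `side`, `stage`, `stage_rank`,
#'   `stage_group`, `age_years`, `adult`.
#' @export
stage_observations <- function(consensus, subjects) {
  obs <- consensus |>
    dplyr::filter(.data$stage != not_evaluable()) |>
    dplyr::inner_join(subjects, by = "subject_id")
  if (anyDuplicated(obs[, c("subject_id", "side")]) > 0) {
    stop("more than one observation for the same clavicle", call. = FALSE)
  }
  stopifnot(all(obs$age_years > 0))
  obs |>
    dplyr::transmute(
      .data$subject_id, .data$side, .data$stage,
      stage_rank = stage_rank(.data$stage),
      stage_group = collapse_stage(.data$stage),
      .data$age_years, .data$adult
    )
}
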