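#' The 9-level clavicle ossification stage scale
#'
#' The medial clavicular epiphysis is staged on the 5-stage scheme of
#' Schmeling with the Kellinghaus substages of stages 2 and 3, giving the
#' ordered scale 1 < 2a < 2b < 2c < 3a < 3b < 3c < 4 < 5. Clavicles that
#' cannot be staged (motion artefacts, anatomical shape variants) carry the
#' distinguished code `"NE"` ("not evaluable"), which is never part of the
#' ordinal scale.
#'
#' @return `stage_levels()` returns the nine stage codes in developmental
#'   order; `stage_group_levels()` the six analysis-group labels
#'   (`1, 2, 3a, 3b, 3c, 4/5`) used for transition analysis.
#' @examples
#' stage_levels()
#' stage_group_levels()
#' @export
stage_levels <- function() {
  c("1", "2a", "2b", "2c", "3a", "3b", "3c", "4", "5")
}

#' @rdname stage_levels
#' @export
stage_group_levels <- function() {
  c("1", "2", "3a", "3b", "3c", "4/5")
}

#' @rdname stage_levels
#' @export
not_evaluable <- function() "NE"

#' Convert between stage codes and developmental ranks
#'
#' Ranks are 0-based integers consistent with developmental order
#' (stage 1 has rank 0, stage 5 rank 8), so rank differences count substage
#' steps on the full 9-level scale. The mapping round-trips losslessly.
#'
#' @param stage character vector of stage codes.
#' @param rank integer vector of ranks in 0..8.
#' @return `stage_rank()` an integer vector (NA for `"NE"` or `NA` input);
#'   `stage_from_rank()` a character vector of stage codes.
#' @examples
#' stage_rank(c("1", "2c", "5"))
#' stage_from_rank(0:8)
#' @export
stage_rank <- function(stage) {
  out <- match(as.character(stage), stage_levels()) - 1L
  bad <- !is.na(stage) & as.character(stage) != not_evaluable() & is.na(out)
  if (any(bad)) {
    stop("unknown stage code(s): ", paste(unique(stage[bad]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @rdname stage_rank
#' @export
stage_from_rank <- function(rank) {
  stopifnot(all(rank %in% 0:8 | is.na(rank)))
  stage_levels()[rank + 1L]
}

#' Parse stage codes with validation
#'
#' @param x character vector of raw stage codes (possibly with whitespace).
#' @param allow_ne should the `"NE"` marker be accepted?
#' @return a character vector of canonical stage codes (`NA` stays `NA`).
#' @keywords internal
parse_stage <- function(x, allow_ne = TRUE) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  ok <- is.na(x) | x %in% stage_levels() | (allow_ne & x == not_evaluable())
  if (!all(ok)) {
    bad <- which(!ok)
    stop("unparseable stage code ", sQuote(x[bad[1]]), " (row ", bad[1],
         " of the stage column)", call. = FALSE)
  }
  x
}

#' Collapse substages into transition-analysis stage groups
#'
#' Because substages 2a-c are rare and stage 5 is scarce in cohorts capped at
#' 25 years, transition analysis is run on collapsed groups: 2a/2b/2c merge
#' into group 2 and stages 4 and 5 into group 4/5, leaving the six ordered
#' groups 1 < 2 < 3a < 3b < 3c < 4/5. The map is total and order-preserving
#' on the 9-level scale.
#'
#' @param stage character vector of 9-level stage codes (no `"NE"`).
#' @return a factor with levels `stage_group_levels()`.
#' @examples
#' collapse_stage(c("1", "2b", "3c", "5"))
#' @export
collapse_stage <- function(stage) {
  stage <- as.character(stage)
  if (any(stage == not_evaluable(), na.rm = TRUE)) {
    stop("cannot collapse a 'not evaluable' marker into a stage group",
         call. = FALSE)
  }
  rk <- stage_rank(stage)
  grp <- stage_group_levels()[c(1L, 2L, 2L, 2L, 3L, 4L, 5L, 6L, 6L)[rk + 1L]]
  factor(grp, levels = stage_group_levels())
}

#' @rdname collapse_stage
#' @param group factor or character of stage-group labels.
#' @return `stage_group_rank()` an integer vector in 0..5.
#' @export
stage_group_rank <- function(group) {
  out <- match(as.character(group), stage_group_levels()) - 1L
  bad <- !is.na(group) & is.na(out)
  if (any(bad)) {
    stop("unknown stage group label(s): ",
         paste(unique(group[bad]), collapse = ", "), call. = FALSE)
  }
  out
}
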