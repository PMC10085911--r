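#' Build an items-by-raters matrix from long rating records
#'
#' One row per clavicle (subject x side), one column per rater. With
#' `include_not_evaluable = TRUE` the `"NE"` marker is kept as an extra
#' category; otherwise NE ratings become missing cells.
#'
#' @param ratings tibble of rating records (see [read_ratings()]).
#' @param include_not_evaluable keep `"NE"` as a category?
#' @return a character matrix, rownames `subject_id:side`, colnames rater ids.
#' @export
rater_matrix <- function(ratings, include_not_evaluable = TRUE) {
  wide <- ratings |>
    dplyr::mutate(item = paste(.data$subject_id, .data$side, sep = ":")) |>
    dplyr::select(dplyr::all_of(c("item", "rater_id", "stage"))) |>
    tidyr::pivot_wider(names_from = "rater_id", values_from = "stage")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$item
  if (!include_not_evaluable) mat[mat == not_evaluable()] <- NA_character_
  mat
}

# categories in developmental order, NE (if present) ranked last
order_categories <- function(x) {
  vals <- unique(stats::na.omit(as.character(x)))
  out <- c(intersect(stage_levels(), vals),
           sort(setdiff(vals, c(stage_levels(), not_evaluable()))))
  if (not_evaluable() %in% vals) out <- c(out, not_evaluable())
  out
}

# linear agreement weights w_jk = 1 - |j - k|/(K - 1) on the ordered set
linear_weights <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  1 - d / (k - 1)
}

# items x categories count matrix (robust to K = 1)
count_matrix <- function(mat, categories) {
  out <- matrix(0L, nrow(mat), length(categories))
  for (j in seq_along(categories)) {
    out[, j] <- rowSums(mat == categories[j], na.rm = TRUE)
  }
  out
}

agreement_result <- function(scheme, estimate, n_items, n_raters,
                             statistic = NA_real_, p_value = NA_real_) {
  tibble::tibble(scheme = scheme, n_items = n_items, n_raters = n_raters,
                 estimate = estimate, statistic = statistic,
                 p_value = p_value)
}

#' Fleiss' kappa for three (or more) raters
#'
#' Chance-corrected multi-rater agreement. Unweighted: classic Fleiss kappa,
#' observed versus chance mean pairwise agreement, with the large-sample
#' normal test of kappa = 0. Weighted: the mean-pairwise-weighted-agreement
#' generalisation with linear ordinal weights over the category set in use,
#' crediting near-miss disagreements; each pairwise sub-computation then
#' coincides with weighted Cohen agreement. Items with missing cells must be
#' filtered beforehand (agreement is defined over complete items only).
#'
#' @param mat items x raters matrix (see [rater_matrix()]); no missing cells.
#' @param weights `"none"` or `"linear"`. Linear weights require an ordinal
#'   category set, so `"NE"` must not be present.
#' @param categories optional ordered category vector; defaults to the stage
#'   scale order of the values present.
#' @return an agreement tibble (`scheme`, `n_items`, `n_raters`, `estimate`,
#'   `statistic`, `p_value`). The p-value uses the large-sample normal
#'   approximation (unweighted only).
#' @export
fleiss_kappa <- function(mat, weights = c("none", "linear"),
                         categories = NULL) {
  weights <- match.arg(weights)
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing cells: pre-filter items rated by all raters",
                       call. = FALSE)
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop("need at least 2 items and 2 raters", call. = FALSE)
  }
  if (is.null(categories)) categories <- order_categories(mat)
  if (weights == "linear" && not_evaluable() %in% mat) {
    stop("linear weights need an ordinal scale: exclude 'NE' items first",
         call. = FALSE)
  }
  N <- nrow(mat); n <- ncol(mat); K <- length(categories)
  # counts n_ij: raters assigning category j to item i
  cnt <- count_matrix(mat, categories)
  p <- colSums(cnt) / (N * n)

  if (weights == "none") {
    pe <- sum(p^2)
    if (1 - pe < .Machine$double.eps^0.5) {
      warning("expected agreement is 1; kappa undefined", call. = FALSE)
      return(agreement_result("fleiss_unweighted", NA_real_, N, n))
    }
    po <- mean((rowSums(cnt^2) - n) / (n * (n - 1)))
    kap <- (po - pe) / (1 - pe)
    q <- 1 - p
    se <- sqrt(2 / (N * n * (n - 1))) *
      sqrt(sum(p * q)^2 - sum(p * q * (q - p))) / sum(p * q)
    z <- kap / se
    return(agreement_result("fleiss_unweighted", kap, N, n,
                            statistic = z,
                            p_value = 2 * stats::pnorm(-abs(z))))
  }

  w <- linear_weights(K)
  # sum of w over ordered rater pairs within an item, from category counts
  pair_w <- rowSums((cnt %*% w) * cnt) - n  # subtract self-pairs (w_jj = 1)
  po <- mean(pair_w / (n * (n - 1)))
  pe <- c(p %*% w %*% p)
  if (1 - pe < .Machine$double.eps^0.5) {
    warning("expected weighted agreement is 1; kappa undefined",
            call. = FALSE)
    return(agreement_result("fleiss_linear_weighted", NA_real_, N, n))
  }
  agreement_result("fleiss_linear_weighted", (po - pe) / (1 - pe), N, n)
}

#' Cohen's kappa for two raters, unweighted or linearly weighted
#'
#' kappa = (p_o - p_e) / (1 - p_e), with the weighted generalisation using
#' linear ordinal weights; the p-value tests kappa = 0 with the large-sample
#' normal approximation (Fleiss-Cohen-Everitt null variance, of which the
#' classic unweighted formula is the identity-weight special case).
#'
#' @param r1,r2 paired category vectors of equal length (one per rater).
#' @inheritParams fleiss_kappa
#' @return an agreement tibble as in [fleiss_kappa()].
#' @examples
#' cohen_kappa(rep(c("1", "4"), c(50, 50)),
#'             rep(c("1", "4", "1", "4"), c(45, 5, 5, 45)))
#' @export
cohen_kappa <- function(r1, r2, weights = c("none", "linear"),
                        categories = NULL) {
  weights <- match.arg(weights)
  keep <- !is.na(r1) & !is.na(r2)
  r1 <- as.character(r1)[keep]; r2 <- as.character(r2)[keep]
  n <- length(r1)
  if (n < 2) stop("need at least 2 paired ratings", call. = FALSE)
  if (is.null(categories)) categories <- order_categories(c(r1, r2))
  if (weights == "linear" &&
      not_evaluable() %in% c(r1, r2)) {
    stop("linear weights need an ordinal scale: exclude 'NE' items first",
         call. = FALSE)
  }
  K <- length(categories)
  scheme <- if (weights == "none") "cohen_unweighted" else
    "cohen_linear_weighted"
  w <- if (weights == "none") diag(K) else linear_weights(K)

  conf <- table(factor(r1, categories), factor(r2, categories)) / n
  prow <- rowSums(conf); pcol <- colSums(conf)
  po <- sum(conf * w)
  pe <- c(prow %*% w %*% pcol)
  if (1 - pe < .Machine$double.eps^0.5) {
    warning("no variation in either rater; kappa undefined", call. = FALSE)
    return(agreement_result(scheme, NA_real_, n, 2))
  }
  kap <- (po - pe) / (1 - pe)
  # null variance of weighted kappa (identity weights give Cohen's formula)
  wbar_row <- c(w %*% pcol)   # E[w | row category i]
  wbar_col <- c(prow %*% w)   # E[w | column category j]
  dev <- w - outer(wbar_row, rep(1, K)) - outer(rep(1, K), wbar_col)
  var0 <- (sum(outer(prow, pcol) * dev^2) - pe^2) / (n * (1 - pe)^2)
  z <- kap / sqrt(var0)
  agreement_result(scheme, kap, n, 2, statistic = z,
                   p_value = 2 * stats::pnorm(-abs(z)))
}

#' Krippendorff's alpha with missing ratings
#'
#' alpha = 1 - D_o / D_e from the coincidence matrix of pairable values;
#' items with fewer than two ratings drop out and missing cells are simply
#' absent from the coincidences. The difference function defaults to ordinal
#' (squared marginal-rank distance), matching the ordered staging scale;
#' nominal is available.
#'
#' @param mat items x raters matrix, `NA` allowed.
#' @param metric `"ordinal"` or `"nominal"` difference function.
#' @inheritParams fleiss_kappa
#' @return an agreement tibble; `n_items` counts items with >= 2 ratings.
#' @export
krippendorff_alpha <- function(mat, metric = c("ordinal", "nominal"),
                               categories = NULL) {
  metric <- match.arg(metric)
  mat <- as.matrix(mat)
  if (is.null(categories)) categories <- order_categories(mat)
  if (metric == "ordinal" && not_evaluable() %in% mat) {
    stop("ordinal metric needs an ordinal scale: exclude 'NE' first (or use
         metric = 'nominal')", call. = FALSE)
  }
  K <- length(categories)
  cnt <- count_matrix(mat, categories)
  m <- rowSums(cnt)
  cnt <- cnt[m >= 2, , drop = FALSE]
  m <- m[m >= 2]
  if (length(m) == 0) {
    warning("no item carries two or more ratings; alpha undefined",
            call. = FALSE)
    return(agreement_result(paste0("krippendorff_", metric), NA_real_, 0L,
                            ncol(mat)))
  }
  # coincidence matrix o_ck = sum_u n_uc n_uk - delta_ck n_uc, / (m_u - 1)
  o <- matrix(0, K, K)
  for (u in seq_along(m)) {
    nu <- cnt[u, ]
    o <- o + (outer(nu, nu) - diag(nu, K)) / (m[u] - 1)
  }
  nc <- rowSums(o)
  ntot <- sum(nc)
  delta2 <- switch(metric,
    nominal = 1 - diag(K),
    ordinal = {
      d <- matrix(0, K, K)
      for (c in 1:(K - 1)) for (k in (c + 1):K) {
        d[c, k] <- (sum(nc[c:k]) - (nc[c] + nc[k]) / 2)^2
        d[k, c] <- d[c, k]
      }
      d
    })
  De <- sum(outer(nc, nc) * delta2) / 2  # unordered pairs; diagonal is 0
  Do <- sum(o * delta2) / 2
  if (De <= 0) {
    warning("no expected disagreement; alpha undefined", call. = FALSE)
    return(agreement_result(paste0("krippendorff_", metric), NA_real_,
                            length(m), ncol(mat)))
  }
  alpha <- 1 - (ntot - 1) * Do / De
  agreement_result(paste0("krippendorff_", metric), alpha, length(m),
                   ncol(mat))
}

#' Intra-rater agreement between two reading passes
#'
#' Mirrors the two standard computations for a rater re-reading the same
#' cases: with `include_not_evaluable = TRUE`, unweighted Cohen's kappa over
#' the stage categories plus `"NE"` (all re-read cases); with the flag off,
#' linearly weighted Cohen's kappa restricted to cases where both passes
#' assigned a real stage.
#'
#' @param first_pass,second_pass one rater's stage codes for the same items,
#'   in the same item order.
#' @param include_not_evaluable keep `"NE"` as a category (unweighted) or
#'   drop those cases (weighted)?
#' @return an agreement tibble as in [cohen_kappa()].
#' @export
intra_rater_agreement <- function(first_pass, second_pass,
                                  include_not_evaluable = FALSE) {
  stopifnot(length(first_pass) == length(second_pass))
  if (include_not_evaluable) {
    cohen_kappa(first_pass, second_pass, weights = "none")
  } else {
    keep <- first_pass != not_evaluable() & second_pass != not_evaluable()
    cohen_kappa(first_pass[keep], second_pass[keep], weights = "linear",
                categories = order_categories(c(first_pass[keep],
                                                second_pass[keep])))
  }
}

#' Inter-rater agreement report
#'
#' The full agreement panel for a three-rater staging study: unweighted
#' Fleiss' kappa over all clavicles with `"NE"` as an extra category,
#' linearly weighted Fleiss' kappa and ordinal Krippendorff's alpha over
#' clavicles staged by all three raters, and pairwise linearly weighted
#' Cohen's kappa per rater pair over clavicles both raters staged.
#'
#' @param ratings tibble of rating records (see [read_ratings()]).
#' @return a long tibble: `scheme`, `rater_1`, `rater_2` (NA for multi-rater
#'   schemes), `n`, `estimate`, `statistic`, `p_value`.
#' @export
agreement_report <- function(ratings) {
  mat_all <- rater_matrix(ratings, include_not_evaluable = TRUE)
  mat_staged <- rater_matrix(ratings, include_not_evaluable = FALSE)
  complete <- stats::complete.cases(mat_staged)

  multi <- dplyr::bind_rows(
    fleiss_kappa(mat_all, weights = "none"),
    fleiss_kappa(mat_staged[complete, , drop = FALSE], weights = "linear"),
    krippendorff_alpha(mat_staged, metric = "ordinal")
  ) |>
    dplyr::mutate(rater_1 = NA_character_, rater_2 = NA_character_)

  raters <- colnames(mat_staged)
  pairs <- utils::combn(raters, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    a <- mat_staged[, pr[1]]; b <- mat_staged[, pr[2]]
    keep <- !is.na(a) & !is.na(b)
    cohen_kappa(a[keep], b[keep], weights = "linear") |>
      dplyr::mutate(rater_1 = pr[1], rater_2 = pr[2])
  })

  dplyr::bind_rows(multi, pairwise) |>
    dplyr::select(dplyr::all_of(c("scheme", "rater_1", "rater_2")),
                  n = "n_items", dplyr::all_of(c("estimate", "statistic",
                                                 "p_value")))
}
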