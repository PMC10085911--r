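#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted transition model
#'
#' One row per parameter: the latent cutpoints (with the transition age each
#' implies, in years) and the slope.
#'
#' @param x a fitted `transition_model`.
#' @param ... unused.
#' @return a tibble: `term`, `estimate`, `transition_age`.
#' @export
tidy.transition_model <- function(x, ...) {
  ta <- transition_ages(x)
  tibble::tibble(
    term = c(names(x$cutpoints), "beta"),
    estimate = unname(c(x$cutpoints, x$slope)),
    transition_age = c(unname(ta), NA_real_)
  )
}

#' One-row model summary
#'
#' @param x a fitted `transition_model`.
#' @param ... unused.
#' @return a tibble: `n`, `n_groups`, `transform`, `logLik`, `pseudo_r2`,
#'   `converged`, `flagged`.
#' @export
glance.transition_model <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_groups = x$J, transform = x$transform, logLik = x$loglik,
    pseudo_r2 = if (!is.null(x$data)) pseudo_r2(x) else NA_real_,
    converged = x$converged, flagged = x$flagged
  )
}
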