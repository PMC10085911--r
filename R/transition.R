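#' Cumulative probit log-likelihood
#'
#' Transition analysis models the ordinal stage group as a coarsening of a
#' latent developmental scale: P(group <= j | age) = Phi(tau_j - beta t(age))
#' with ordered cutpoints tau_1 < ... < tau_{J-1}, slope beta > 0 and an age
#' transform t (log by default). This evaluates the log-likelihood of a
#' sample directly from parameter values; [fit_transition_model()] maximises
#' it.
#'
#' @param cutpoints numeric vector of J-1 strictly increasing cutpoints on
#'   the latent scale.
#' @param slope positive slope per unit transformed age.
#' @param age numeric vector of chronological ages in years.
#' @param group integer group index in 1..J (or a factor whose level order is
#'   the developmental order).
#' @param transform `"log"` or `"identity"` age transform.
#' @return the log-likelihood (a single number).
#' @export
cumprobit_loglik <- function(cutpoints, slope, age, group,
                             transform = c("log", "identity")) {
  transform <- match.arg(transform)
  y <- if (is.factor(group)) as.integer(group) else as.integer(group)
  J <- length(cutpoints) + 1L
  stopifnot(all(y >= 1L & y <= J), slope > 0,
            all(diff(cutpoints) > 0) || J == 2L)
  t <- transform_age(age, transform)
  tau <- c(-Inf, cutpoints, Inf)
  p <- stats::pnorm(tau[y + 1L] - slope * t) - stats::pnorm(tau[y] - slope * t)
  sum(log(pmax(p, 1e-300)))
}

transform_age <- function(age, transform) {
  switch(transform, log = {
    stopifnot(all(age > 0))
    log(age)
  }, identity = age)
}

inverse_transform_age <- function(t, transform) {
  switch(transform, log = exp(t), identity = t)
}

# loglik and analytic gradient in the unconstrained parameterisation
# theta = (tau_1, log gaps, log beta); returns list(value, gradient)
cumprobit_objective <- function(theta, t, y, J) {
  gaps <- exp(theta[seq_len(J - 2L) + 1L])
  tau <- cumsum(c(theta[1L], gaps))
  beta <- exp(theta[J])
  taue <- c(-Inf, tau, Inf)
  u <- taue[y + 1L] - beta * t
  l <- taue[y] - beta * t
  p <- pmax(stats::pnorm(u) - stats::pnorm(l), 1e-300)
  du <- stats::dnorm(u); dl <- stats::dnorm(l)
  # d loglik / d tau_j, accumulated over observations
  gtau <- numeric(J - 1L)
  wu <- du / p; wl <- dl / p
  for (j in seq_len(J - 1L)) {
    gtau[j] <- sum(wu[y == j]) - sum(wl[y == j + 1L])
  }
  gbeta <- -sum(t * (du - dl) / p)
  grad <- numeric(J)
  grad[1L] <- sum(gtau)
  if (J > 2L) {
    for (m in seq_len(J - 2L)) {
      grad[m + 1L] <- gaps[m] * sum(gtau[(m + 1L):(J - 1L)])
    }
  }
  grad[J] <- beta * gbeta
  list(value = sum(log(p)), gradient = grad)
}

#' Fit the cumulative probit transition-analysis model
#'
#' Maximum-likelihood fit of stage group on (transformed) age. Cutpoint
#' ordering and slope positivity are enforced by optimising over
#' (tau_1, log cutpoint gaps, log beta); starting cutpoints come from
#' probit-transformed empirical cumulative group frequencies anchored at the
#' mean transformed age, with beta = 1. BFGS is followed by Newton polishing
#' until the gradient max-norm falls below `tol`, with three deterministic
#' perturbed restarts before a fit is declared unconverged. Runaway parameter
#' magnitudes (complete separation) flag the fit with a warning instead of
#' failing silently.
#'
#' @param data a data frame with one row per clavicle observation, carrying
#'   the collapsed stage group and the chronological age.
#' @param transform `"log"` (default; standard in the transition-analysis
#'   literature) or `"identity"` age transform.
#' @param group,age names of the stage-group and age columns.
#' @param tol convergence tolerance on the gradient max-norm.
#' @return an object of class `transition_model`: cutpoints, slope,
#'   transform, group levels, log-likelihood, n, convergence flags, and the
#'   fitting data (for diagnostics).
#' @examples
#' obs <- simulate_observations(300, seed = 1)
#' fit <- fit_transition_model(obs)
#' fit
#' @export
fit_transition_model <- function(data, transform = c("log", "identity"),
                                 group = "stage_group", age = "age_years",
                                 tol = 1e-6) {
  transform <- match.arg(transform)
  g <- data[[group]]
  if (!is.factor(g)) g <- factor(g, levels = stage_group_levels())
  g <- droplevels(g)
  stopifnot(!anyNA(g), !anyNA(data[[age]]))
  J <- nlevels(g)
  if (J < 2) stop("need at least 2 distinct stage groups", call. = FALSE)
  y <- as.integer(g)
  t <- transform_age(data[[age]], transform)
  n <- length(y)

  # starting values: probit of empirical cumulative frequencies at mean age
  cf <- cumsum(tabulate(y, J) / n)[seq_len(J - 1L)]
  cf <- pmin(pmax(cf, 1 / (2 * n)), 1 - 1 / (2 * n))
  cf <- cummax(cf + seq_len(J - 1L) * 1e-9)  # strict increase even with ties
  tau0 <- stats::qnorm(cf) + mean(t)
  gaps0 <- pmax(diff(tau0), 1e-3)
  theta0 <- c(tau0[1L], log(gaps0), 0)

  fit1 <- NULL
  perturb <- list(0, c(0.3, -0.2), c(-0.5, 0.4), c(1, 0.7))
  for (k in seq_along(perturb)) {
    start <- theta0 + rep_len(perturb[[k]], length(theta0))
    res <- polish_fit(start, t, y, J, tol)
    if (is.null(fit1) || res$value > fit1$value) fit1 <- res
    if (fit1$converged) break
  }
  if (!fit1$converged) {
    warning("transition model fit did not reach gradient tolerance (", tol,
            "); max |gradient| = ", signif(fit1$grad_norm, 3), call. = FALSE)
  }

  theta <- fit1$theta
  cutpoints <- cumsum(c(theta[1L], exp(theta[seq_len(J - 2L) + 1L])))
  slope <- exp(theta[J])
  flagged <- max(abs(cutpoints)) > 1e4 || slope > 1e4 || slope < 1e-6
  if (flagged) {
    warning("parameter magnitudes suggest complete separation; ",
            "fit is flagged", call. = FALSE)
  }

  structure(list(
    cutpoints = stats::setNames(cutpoints,
                                paste0("tau_", seq_len(J - 1L))),
    slope = slope,
    transform = transform,
    groups = levels(g),
    J = J,
    loglik = fit1$value,
    n = n,
    converged = fit1$converged,
    flagged = flagged,
    grad_norm = fit1$grad_norm,
    data = tibble::tibble(age_years = data[[age]], stage_group = g)
  ), class = "transition_model")
}

# BFGS then Newton polishing on the unconstrained scale
polish_fit <- function(theta0, t, y, J, tol) {
  nll <- function(th) -cumprobit_objective(th, t, y, J)$value
  ngr <- function(th) -cumprobit_objective(th, t, y, J)$gradient
  opt <- stats::optim(theta0, nll, ngr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-13))
  theta <- opt$par
  for (it in seq_len(30)) {
    ob <- cumprobit_objective(theta, t, y, J)
    gn <- max(abs(ob$gradient))
    if (gn <= tol) break
    H <- pracma::hessian(nll, theta)
    step <- tryCatch(solve(H, ob$gradient), error = function(e) NULL)
    if (is.null(step)) break
    improved <- FALSE
    for (h in 0:10) {  # halving line search on the Newton step
      cand <- theta + step / 2^h
      cob <- cumprobit_objective(cand, t, y, J)
      # near the optimum the value plateaus at machine precision, so a
      # shrinking gradient norm also counts as progress
      if (cob$value >= ob$value || max(abs(cob$gradient)) < gn) {
        improved <- TRUE
        break
      }
    }
    if (!improved) break
    theta <- cand
  }
  ob <- cumprobit_objective(theta, t, y, J)
  list(theta = theta, value = ob$value,
       grad_norm = max(abs(ob$gradient)),
       converged = max(abs(ob$gradient)) <= tol)
}

#' Assemble a transition model from known parameters
#'
#' Builds the same object [fit_transition_model()] returns, from parameter
#' values instead of data — for prediction from a reloaded or theoretical
#' (true) model, e.g. in coverage studies.
#'
#' @param cutpoints strictly increasing latent cutpoints (length J-1).
#' @param slope positive latent slope.
#' @param transform `"log"` or `"identity"`.
#' @param groups J ordered group labels.
#' @return an object of class `transition_model` (no data, no likelihood).
#' @export
transition_model <- function(cutpoints, slope,
                             transform = c("log", "identity"),
                             groups = stage_group_levels()) {
  transform <- match.arg(transform)
  stopifnot(length(groups) == length(cutpoints) + 1L,
            all(diff(cutpoints) > 0) || length(cutpoints) == 1L,
            slope > 0)
  structure(list(
    cutpoints = stats::setNames(cutpoints,
                                paste0("tau_", seq_along(cutpoints))),
    slope = slope, transform = transform, groups = groups,
    J = length(groups), loglik = NA_real_, n = NA_integer_,
    converged = TRUE, flagged = FALSE, grad_norm = NA_real_, data = NULL
  ), class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("Cumulative probit transition model (", x$transform, "-age)\n",
      sep = "")
  cat("  groups:", paste(x$groups, collapse = " < "), "\n")
  cat("  n =", x$n, " log-likelihood =", format(x$loglik, digits = 6), "\n")
  cat("  slope beta =", format(x$slope, digits = 4), "\n")
  ta <- transition_ages(x)
  cat("  transition ages (y):",
      paste(format(ta, digits = 4), collapse = ", "), "\n")
  if (!x$converged) cat("  [not converged]\n")
  if (x$flagged) cat("  [flagged: possible separation]\n")
  invisible(x)
}

#' @export
coef.transition_model <- function(object, ...) {
  c(object$cutpoints, beta = object$slope)
}

#' @export
logLik.transition_model <- function(object, ...) {
  structure(object$loglik, df = object$J, nobs = object$n, class = "logLik")
}

#' Ages at which the model transitions between adjacent stage groups
#'
#' The latent mean crosses cutpoint tau_j at transformed age tau_j / beta;
#' back-transforming gives the (strictly increasing) mean transition ages in
#' years between group j and group j+1.
#'
#' @param model a fitted [fit_transition_model()] object.
#' @return a named numeric vector of J-1 ages in years.
#' @export
transition_ages <- function(model) {
  stopifnot(inherits(model, "transition_model"))
  ages <- inverse_transform_age(model$cutpoints / model$slope,
                                model$transform)
  stats::setNames(ages, paste(model$groups[-model$J],
                              model$groups[-1L], sep = "|"))
}

#' Stage-group probabilities over age
#'
#' @param object a fitted `transition_model`.
#' @param newdata data frame with an `age_years` column (defaults to the
#'   training data).
#' @param ... unused.
#' @return a tibble in long form: `age_years`, `stage_group`, `probability`.
#'   Probabilities sum to one at every age.
#' @export
predict.transition_model <- function(object, newdata = NULL, ...) {
  age <- if (is.null(newdata)) object$data$age_years else newdata$age_years
  p <- group_prob_matrix(object, age)
  tibble::tibble(
    age_years = rep(age, times = object$J),
    stage_group = factor(rep(object$groups, each = length(age)),
                         levels = object$groups),
    probability = as.vector(p)
  )
}

# n x J matrix of P(group | age)
group_prob_matrix <- function(model, age) {
  t <- transform_age(age, model$transform)
  taue <- c(-Inf, model$cutpoints, Inf)
  eta <- outer(-model$slope * t, taue, "+")
  p <- stats::pnorm(eta[, -1L, drop = FALSE]) -
    stats::pnorm(eta[, -(model$J + 1L), drop = FALSE])
  colnames(p) <- model$groups
  p
}

#' Lagrange multiplier (score) test of the common-slope restriction
#'
#' The fitted model constrains every cutpoint equation to share one slope
#' (one latent scale). The score test evaluates, at the restricted MLE, the
#' gradient and observed information of the relaxed alternative
#' P(group <= j) = Phi(tau_j - beta_j t(age)) with a slope per cutpoint;
#' under the restriction the statistic is asymptotically chi-squared with
#' J - 2 degrees of freedom. A small p-value signals that one latent scale
#' does not fit the stage-age pattern.
#'
#' @param model a fitted `transition_model`.
#' @return a one-row tibble: `lm_statistic`, `df`, `lm_p`, `testable`
#'   (`FALSE` when the information matrix is numerically singular).
#' @export
lm_fit_test <- function(model) {
  stopifnot(inherits(model, "transition_model"))
  J <- model$J
  if (J < 3) {
    return(tibble::tibble(lm_statistic = NA_real_, df = 0L, lm_p = NA_real_,
                          testable = FALSE))
  }
  tt <- transform_age(model$data$age_years, model$transform)
  y <- as.integer(model$data$stage_group)
  ll_h1 <- function(psi) {
    tau <- psi[seq_len(J - 1L)]
    beta <- psi[J - 1L + seq_len(J - 1L)]
    # cumulative at level j uses its own (tau_j, beta_j)
    cu <- ifelse(y == J, Inf,
                 tau[pmin(y, J - 1L)] - beta[pmin(y, J - 1L)] * tt)
    cl <- ifelse(y == 1L, -Inf,
                 tau[pmax(y - 1L, 1L)] - beta[pmax(y - 1L, 1L)] * tt)
    sum(log(pmax(stats::pnorm(cu) - stats::pnorm(cl), 1e-300)))
  }
  psi0 <- unname(c(model$cutpoints, rep(model$slope, J - 1L)))
  g <- pracma::grad(ll_h1, psi0)
  H <- pracma::hessian(ll_h1, psi0)
  info <- -H
  stat <- tryCatch(drop(crossprod(g, solve(info, g))),
                   error = function(e) NA_real_)
  if (!is.finite(stat) || stat < 0) {
    return(tibble::tibble(lm_statistic = NA_real_, df = J - 2L,
                          lm_p = NA_real_, testable = FALSE))
  }
  tibble::tibble(lm_statistic = stat, df = J - 2L,
                 lm_p = stats::pchisq(stat, df = J - 2L, lower.tail = FALSE),
                 testable = TRUE)
}

#' Cragg-Uhler (Nagelkerke) pseudo R-squared
#'
#' [1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)] with L1 the fitted likelihood and L0
#' the intercept-only (marginal multinomial) likelihood on the same data: 0
#' when age explains nothing, approaching 1 under deterministic separation.
#'
#' @param model a fitted `transition_model`.
#' @return a single value in [0, 1].
#' @export
pseudo_r2 <- function(model) {
  stopifnot(inherits(model, "transition_model"))
  n <- model$n
  cnt <- tabulate(as.integer(model$data$stage_group), model$J)
  ll0 <- sum(cnt[cnt > 0] * log(cnt[cnt > 0] / n))
  ll1 <- model$loglik
  if (ll1 < ll0 - 1e-8) {
    stop("fitted log-likelihood below intercept-only log-likelihood: ",
         "optimizer failure", call. = FALSE)
  }
  (1 - exp(2 / n * (ll0 - ll1))) / (1 - exp(2 / n * ll0))
}

#' Fit diagnostics in one row
#'
#' @param model a fitted `transition_model`.
#' @return a one-row tibble: `lm_statistic`, `df`, `lm_p`, `pseudo_r2`.
#' @export
fit_diagnostics <- function(model) {
  lm <- lm_fit_test(model)
  dplyr::mutate(lm, pseudo_r2 = pseudo_r2(model))
}

#' Save or reload a fitted transition model as plain text
#'
#' The dump (JSON) carries the transform, group levels, cutpoints, slope,
#' log-likelihood and n — enough to reload and predict without refitting
#' (the training data itself is not stored).
#'
#' @param model a fitted `transition_model`.
#' @param path file path for the JSON dump.
#' @return `write_transition_model()` the path, invisibly;
#'   `read_transition_model()` a `transition_model` object (without data;
#'   diagnostics needing the data are unavailable on a reloaded model).
#' @export
write_transition_model <- function(model, path) {
  stopifnot(inherits(model, "transition_model"))
  x <- model[c("cutpoints", "slope", "transform", "groups", "J", "loglik",
               "n", "converged", "flagged")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transition_model
#' @export
read_transition_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$cutpoints <- stats::setNames(as.numeric(x$cutpoints),
                                 paste0("tau_", seq_along(x$cutpoints)))
  x$data <- NULL
  structure(x, class = "transition_model")
}
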