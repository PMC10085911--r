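fit_default <- function(n = 400, seed = 101) {
  fit_transition_model(simulate_observations(n, seed = seed))
}

test_that("fitted models define a proper probability model over age", {
  m <- fit_default()
  expect_true(all(diff(m$cutpoints) > 0))
  expect_gt(m$slope, 0)
  grid <- seq(13, 25, by = 0.25)
  p <- predict(m, tibble::tibble(age_years = grid))
  sums <- tapply(p$probability, p$age_years, sum)
  expect_equal(as.numeric(sums), rep(1, length(grid)), tolerance = 1e-12)
  # mean predicted group rank nondecreasing in age (slope > 0)
  mean_rank <- tapply(p$probability * as.integer(p$stage_group),
                      p$age_years, sum)
  expect_true(all(diff(mean_rank) >= -1e-10))
})

test_that("transition ages back-transform cutpoints and stay monotone", {
  m <- transition_model(cutpoints = c(0, 1), slope = 1,
                        transform = "identity", groups = c("a", "b", "c"))
  expect_equal(unname(transition_ages(m)), c(0, 1))
  m2 <- transition_model(cutpoints = 1 * log(18), slope = 1,
                         transform = "log", groups = c("a", "b"))
  expect_equal(unname(transition_ages(m2)), 18)
  for (seed in 1:3) {
    m3 <- fit_default(seed = 200 + seed)
    expect_true(all(diff(transition_ages(m3)) > 0))
  }
})

test_that("the MLE matches MASS::polr on identity-transform data", {
  skip_if_not_installed("MASS")
  obs <- simulate_observations(800, transition_ages = c(15.5, 18, 21),
                               slope = 1.1, transform = "identity",
                               groups = c("g1", "g2", "g3", "g4"),
                               seed = 77)
  m <- fit_transition_model(obs, transform = "identity")
  pol <- suppressWarnings(
    MASS::polr(stage_group ~ age_years, data = obs, method = "probit")
  )
  expect_equal(unname(m$cutpoints), unname(pol$zeta), tolerance = 1e-4)
  expect_equal(m$slope, unname(coef(pol)), tolerance = 1e-4)
  expect_equal(m$loglik, as.numeric(logLik(pol)), tolerance = 1e-8)
})

test_that("optimum beats a local grid search and order of rows is irrelevant", {
  obs <- simulate_observations(300, seed = 301)
  m <- fit_transition_model(obs)
  base <- cumprobit_loglik(m$cutpoints, m$slope, obs$age_years,
                           obs$stage_group)
  expect_equal(base, m$loglik, tolerance = 1e-9)
  # coordinate-wise 0.05-step perturbations around the optimum never win
  for (j in seq_along(m$cutpoints)) {
    for (d in c(-0.1, -0.05, 0.05, 0.1)) {
      cp <- m$cutpoints; cp[j] <- cp[j] + d
      if (any(diff(cp) <= 0)) next
      expect_lte(cumprobit_loglik(cp, m$slope, obs$age_years,
                                  obs$stage_group), base + 1e-8)
    }
  }
  for (d in c(-0.1, -0.05, 0.05, 0.1)) {
    expect_lte(cumprobit_loglik(m$cutpoints, m$slope + d, obs$age_years,
                                obs$stage_group), base + 1e-8)
  }

  perm <- sample(nrow(obs))
  m2 <- fit_transition_model(obs[perm, ])
  expect_equal(m$cutpoints, m2$cutpoints, tolerance = 1e-7)
  expect_equal(m$slope, m2$slope, tolerance = 1e-7)
})

test_that("a sharp split between two groups localises the transition age", {
  # tiny latent noise relative to the slope: transition age -> the split
  obs <- simulate_observations(1500, transition_ages = 18, slope = 120,
                               groups = c("lo", "hi"), seed = 42)
  # near-deterministic data: the fit may warn that the gradient stalls on
  # the flat likelihood shelf, which is exactly the designed signal
  m <- suppressWarnings(fit_transition_model(obs))
  expect_equal(unname(transition_ages(m)), 18, tolerance = 0.1)
  expect_gt(pseudo_r2(m), 0.9)  # near-deterministic separation
})

test_that("recovered transition ages tighten as n grows", {
  truth <- true_group_ages()
  err_at <- function(n) {
    mean(vapply(1:3, function(s) {
      m <- fit_transition_model(simulate_observations(n, seed = 400 + s))
      mean(abs(transition_ages(m) - truth))
    }, 0))
  }
  e150 <- err_at(150); e2400 <- err_at(2400)
  expect_lt(e2400, e150)
  expect_lt(e2400, 0.15)
})

test_that("score test is nonnegative and detects slope heterogeneity", {
  m <- fit_default(seed = 501)
  lt <- lm_fit_test(m)
  expect_true(lt$testable)
  expect_gte(lt$lm_statistic, 0)
  expect_equal(lt$df, 4L)
  expect_true(lt$lm_p >= 0 && lt$lm_p <= 1)

  # power: data whose cutpoints carry very different slopes
  ages_b <- true_group_ages()
  betas <- c(7, 10, 14, 18, 22)
  taus <- betas * log(ages_b)
  set.seed(502)
  age <- runif(1200, 13, 25)
  cum <- cbind(0, vapply(seq_along(taus), function(j) {
    pnorm(taus[j] - betas[j] * log(age))
  }, numeric(length(age))), 1)
  pr <- t(apply(cum, 1, function(r) pmax(diff(r), 0)))
  y <- apply(pr, 1, function(p) sample.int(6, 1, prob = p))
  d <- tibble::tibble(
    age_years = age,
    stage_group = factor(stage_group_levels()[y],
                         levels = stage_group_levels())
  )
  lt2 <- lm_fit_test(fit_transition_model(d))
  expect_lt(lt2$lm_p, 0.01)
})

test_that("pseudo R-squared follows its likelihood formula", {
  m <- fit_default(seed = 601)
  # independent recomputation from the two log-likelihoods
  cnt <- table(m$data$stage_group)
  ll0 <- sum(cnt * log(cnt / m$n))
  r2_direct <- (1 - exp(2 / m$n * (ll0 - m$loglik))) /
    (1 - exp(2 / m$n * ll0))
  expect_equal(pseudo_r2(m), r2_direct, tolerance = 1e-10)
  expect_true(pseudo_r2(m) >= 0 && pseudo_r2(m) <= 1)
})

test_that("model dumps reload and predict identically", {
  m <- fit_default(seed = 701)
  f <- withr::local_tempfile(fileext = ".json")
  write_transition_model(m, f)
  m2 <- read_transition_model(f)
  expect_equal(unname(m2$cutpoints), unname(m$cutpoints))
  expect_equal(m2$slope, m$slope)
  ages <- tibble::tibble(age_years = c(14, 18, 23))
  expect_equal(predict(m2, ages)$probability, predict(m, ages)$probability)
})

test_that("tidy and glance summarise the fit", {
  m <- fit_default(seed = 801)
  td <- tidy(m)
  expect_equal(td$term, c(paste0("tau_", 1:5), "beta"))
  expect_equal(td$transition_age[1:5], unname(transition_ages(m)))
  gl <- glance(m)
  expect_equal(gl$n, m$n)
  expect_true(gl$converged)
})
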