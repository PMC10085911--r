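test_that("perfect agreement scores 1 under every scheme", {
  mat <- cbind(rep(stage_levels(), 2), rep(stage_levels(), 2),
               rep(stage_levels(), 2))
  expect_equal(fleiss_kappa(mat, "none")$estimate, 1)
  expect_equal(fleiss_kappa(mat, "linear")$estimate, 1)
  expect_equal(cohen_kappa(mat[, 1], mat[, 2], "none")$estimate, 1)
  expect_equal(cohen_kappa(mat[, 1], mat[, 2], "linear")$estimate, 1)
  expect_equal(krippendorff_alpha(mat, "ordinal")$estimate, 1)
  expect_equal(intra_rater_agreement(mat[, 1], mat[, 2])$estimate, 1)
})

test_that("independent uniform raters give kappa near zero", {
  set.seed(11)
  mat <- matrix(sample(stage_levels()[1:4], 3 * 2000, replace = TRUE),
                ncol = 3)
  # SE of kappa under the null at this size is well below 0.02
  expect_lt(abs(fleiss_kappa(mat, "none")$estimate), 0.06)
  expect_lt(abs(fleiss_kappa(mat, "linear")$estimate), 0.06)
  expect_gt(fleiss_kappa(mat, "none")$p_value, 1e-4)
})

test_that("kappas match brute-force pairwise oracles on small tables", {
  tab <- rbind(c("1", "1", "2a"),
               c("3a", "3a", "3a"),
               c("2a", "2b", "2c"),
               c("4", "5", "4"))
  cats <- c("1", "2a", "2b", "2c", "3a", "4", "5")
  expect_equal(fleiss_kappa(tab, "none")$estimate,
               oracle_fleiss(tab, cats, weighted = FALSE))
  expect_equal(fleiss_kappa(tab, "linear")$estimate,
               oracle_fleiss(tab, cats, weighted = TRUE))

  set.seed(21)
  for (rep in 1:5) {
    r1 <- sample(stage_levels()[1:5], 10, replace = TRUE)
    r2 <- sample(stage_levels()[1:5], 10, replace = TRUE)
    cats <- stage_levels()[1:5]
    expect_equal(cohen_kappa(r1, r2, "none", categories = cats)$estimate,
                 oracle_cohen(r1, r2, cats, weighted = FALSE))
    expect_equal(cohen_kappa(r1, r2, "linear", categories = cats)$estimate,
                 oracle_cohen(r1, r2, cats, weighted = TRUE))
  }
})

test_that("Cohen's kappa reproduces the closed-form 2x2 example", {
  # [[45, 5], [5, 45]]: p_o = 0.9, p_e = 0.5, kappa = 0.8
  r1 <- rep(c("1", "1", "4", "4"), c(45, 5, 5, 45))
  r2 <- rep(c("1", "4", "1", "4"), c(45, 5, 5, 45))
  res <- cohen_kappa(r1, r2, "none")
  expect_equal(res$estimate, 0.8)
  expect_lt(res$p_value, 1e-10)

  # maximally discordant ordinal vectors: negative under linear weights
  lo_hi <- cohen_kappa(rep(c("1", "5"), 20), rep(c("5", "1"), 20), "linear",
                       categories = stage_levels())
  expect_lt(lo_hi$estimate, 0)
})

test_that("alpha reproduces the canonical missing-data example and oracle", {
  mat <- t(rbind(
    c(1, 2, 3, 3, 2, 1, 4, 1, 2, NA, NA, NA),
    c(1, 2, 3, 3, 2, 2, 4, 1, 2, 5, NA, 3),
    c(NA, 3, 3, 3, 2, 3, 4, 2, 2, 5, 1, NA),
    c(1, 2, 3, 3, 2, 4, 4, 1, 2, 5, 1, NA)
  ))
  mat <- matrix(as.character(mat), ncol = 4)
  cats <- as.character(1:5)
  # frozen reference values from an independent coincidence computation
  expect_equal(krippendorff_alpha(mat, "nominal", cats)$estimate, 0.743421,
               tolerance = 1e-6)
  expect_equal(krippendorff_alpha(mat, "ordinal", cats)$estimate, 0.815388,
               tolerance = 1e-6)
  expect_equal(krippendorff_alpha(mat, "ordinal", cats)$estimate,
               oracle_alpha(mat, cats, "ordinal"))

  # random tables with missing cells agree with the pair-enumeration oracle
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(sample(c(stage_levels()[1:4], NA), 30, replace = TRUE),
                ncol = 3)
    if (sum(rowSums(!is.na(m)) >= 2) < 2) next
    cats <- intersect(stage_levels(), m)
    expect_equal(krippendorff_alpha(m, "ordinal", cats)$estimate,
                 oracle_alpha(m, cats, "ordinal"))
  }

  # one item, two raters, different categories: alpha <= 0
  one <- matrix(c("1", "2a"), nrow = 1)
  expect_lte(krippendorff_alpha(one, "ordinal", c("1", "2a"))$estimate, 0)
})

test_that("estimates are permutation-invariant and bounded", {
  set.seed(41)
  mat <- matrix(sample(stage_levels()[1:5], 60, replace = TRUE), ncol = 3)
  perm <- sample(nrow(mat))
  for (w in c("none", "linear")) {
    expect_equal(fleiss_kappa(mat, w)$estimate,
                 fleiss_kappa(mat[perm, ], w)$estimate)
  }
  expect_equal(krippendorff_alpha(mat, "ordinal")$estimate,
               krippendorff_alpha(mat[perm, ], "ordinal")$estimate)
  vals <- c(fleiss_kappa(mat, "none")$estimate,
            fleiss_kappa(mat, "linear")$estimate,
            cohen_kappa(mat[, 1], mat[, 2], "linear")$estimate,
            krippendorff_alpha(mat, "ordinal")$estimate)
  expect_true(all(vals >= -1 & vals <= 1))
})

test_that("intra-rater agreement follows the two-computation convention", {
  first <- c("3a", "3b", "NE", "2a", "4")
  second <- c("3a", "3b", "NE", "2a", "4")
  expect_equal(intra_rater_agreement(first, second, TRUE)$estimate, 1)

  # passes differing only where one is NE: dropped under the weighted rule
  second2 <- c("3a", "3b", "3a", "2a", "4")
  res <- intra_rater_agreement(first, second2, FALSE)
  expect_equal(res$estimate, 1)
  expect_equal(res$n_items, 4)

  # 50-item synthetic re-read matches the direct formula oracle
  set.seed(51)
  rk <- sample(0:8, 50, replace = TRUE)
  flip <- function(r) {
    hit <- runif(50) < 0.2
    pmin(pmax(r + ifelse(hit, sample(c(-1, 1), 50, TRUE), 0), 0), 8)
  }
  p1 <- stage_from_rank(flip(rk))
  p2 <- stage_from_rank(flip(rk))
  cats <- intersect(stage_levels(), c(p1, p2))
  expect_equal(intra_rater_agreement(p1, p2, FALSE)$estimate,
               oracle_cohen(p1, p2, cats, weighted = TRUE))
})

test_that("degenerate one-category tables are signalled, not scored", {
  expect_warning(res <- cohen_kappa(rep("1", 5), rep("1", 5)), "undefined")
  expect_true(is.na(res$estimate))
  expect_warning(fleiss_kappa(matrix("3a", 4, 3)), "undefined")
})

test_that("the agreement report covers the published panel layout", {
  p <- simulation_params(n_subjects = 80)
  rat <- simulate_raters(simulate_cohort(p), p)
  rep <- agreement_report(rat)
  expect_setequal(
    rep$scheme,
    c("fleiss_unweighted", "fleiss_linear_weighted", "krippendorff_ordinal",
      rep("cohen_linear_weighted", 3))
  )
  # unweighted runs on all clavicles, weighted only on fully staged ones
  n_all <- rep$n[rep$scheme == "fleiss_unweighted"]
  n_staged <- rep$n[rep$scheme == "fleiss_linear_weighted"]
  expect_lte(n_staged, n_all)
  expect_equal(sum(rep$scheme == "cohen_linear_weighted"), 3)
  expect_true(all(rep$estimate >= -1 & rep$estimate <= 1))
})
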