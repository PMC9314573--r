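test_that("signed-rank test matches full enumeration on small samples", {
  set.seed(71)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    a <- runif(n)
    b <- runif(n)
    got <- wilcoxon_signed_rank(a, b)
    ref <- oracle_signed_rank(a, b)
    expect_equal(got$statistic, ref$statistic)
    expect_equal(got$p_value, ref$p_value)
  }
  # the worked example: differences 1, -2, 3, 4, 5, 6
  b <- rep(0, 6)
  a <- c(1, -2, 3, 4, 5, 6)
  got <- wilcoxon_signed_rank(a, b)
  ref <- oracle_signed_rank(a, b)
  expect_equal(got$statistic, 2) # the lone negative difference has rank 2
  expect_equal(got$p_value, ref$p_value)
})

test_that("signed-rank edge cases and symmetry", {
  a <- c(5, 6, 7, 8, 9)
  b <- c(1, 2, 3, 4, 5)
  w <- wilcoxon_signed_rank(a, b)
  expect_equal(w$statistic, 0) # all a > b
  expect_equal(w$direction, 1)
  sw <- wilcoxon_signed_rank(b, a)
  expect_equal(sw$statistic, w$statistic)
  expect_equal(sw$p_value, w$p_value)
  expect_equal(sw$direction, -1)
  expect_error(wilcoxon_signed_rank(a, a), "tied")

  # ties among |d| still enumerate exactly
  a2 <- c(2, 2, 0, 3, 3)
  w2 <- wilcoxon_signed_rank(a2, rep(0, 5))
  expect_equal(w2$n, 4L)
  expect_equal(w2$p_value, oracle_signed_rank(a2, rep(0, 5))$p_value)

  # large-sample path stays symmetric and sane
  set.seed(72)
  a3 <- rnorm(40)
  b3 <- rnorm(40)
  w3 <- wilcoxon_signed_rank(a3, b3)
  expect_equal(w3$method, "normal approximation")
  expect_equal(w3$p_value, wilcoxon_signed_rank(b3, a3)$p_value)
  expect_true(w3$p_value >= 0 && w3$p_value <= 1)
})

test_that("mixed model reproduces generating values in the noise-free limit", {
  st <- generate_study(smoke_config(12, seed = 81))
  ind <- st$deltas[st$deltas$level == "individual", ]
  cfg <- smoke_config(12, seed = 81, group_intercept_sd = 0, residual_sd = 0,
                      cohesion_beta = 0.4)
  coh <- generate_cohesion(st$groups, ind, cfg)
  fit <- suppressWarnings(fit_cohesion_model(coh, ind, include_interaction = FALSE))
  expect_equal(unname(fit$coefficients["delta"]), 0.4, tolerance = 1e-6)
  # grand mean under sum contrasts = gamma00 + average condition effect
  expect_equal(unname(fit$coefficients["(Intercept)"]),
               cfg$cohesion_mean + mean(cfg$condition_effects),
               tolerance = 1e-6)
  expect_equal(unname(fit$varcomp["residual"]), 0, tolerance = 1e-8)
  expect_gt(fit$r2_marginal, 0.99)
})

test_that("F table uses between-within denominator dfs", {
  st <- default_study()
  grp <- st$deltas[st$deltas$level == "group", ]
  ind <- st$deltas[st$deltas$level == "individual", ]
  coh <- st$cohesion
  fg <- suppressWarnings(fit_cohesion_model(coh, grp))
  an <- fg$anova
  # all terms of the group-level model are group-constant: df = 87 - 7 - 1
  expect_equal(an$den_df, rep(79, 3))
  expect_equal(an$num_df[an$term == "condition"], 3)
  expect_true(all(an$p >= 0 & an$p <= 1))

  fi <- suppressWarnings(fit_cohesion_model(coh, ind))
  ai <- fi$anova
  expect_equal(ai$den_df[ai$term == "delta"], 261 - 87 - 4)
  expect_equal(ai$den_df[ai$term == "condition"], 87 - 3 - 1)
  expect_true(all(fg$varcomp >= 0))
})

test_that("level comparison: collinear predictor adds nothing, LRT is non-negative", {
  st <- default_study()
  ind <- st$deltas[st$deltas$level == "individual", ]
  grp <- st$deltas[st$deltas$level == "group", ]
  coh <- st$cohesion

  # exact duplicate: group delta broadcast as the individual predictor
  dup <- ind
  dup$delta <- grp$delta[match(dup$group_id, grp$group_id)]
  cmp <- compare_levels(coh, dup, grp)
  expect_lt(abs(cmp$chi_square), 1e-6)
  expect_equal(cmp$df, 0L)

  cmp2 <- compare_levels(coh, ind, grp)
  expect_gte(cmp2$chi_square, -1e-6)
  expect_equal(cmp2$df, 1L)
  expect_true(cmp2$p_value >= 0 && cmp2$p_value <= 1)
})

test_that("level comparison rejects at ~alpha when cohesion ignores the group level", {
  st <- default_study()
  ind <- st$deltas[st$deltas$level == "individual", ]
  grp <- st$deltas[st$deltas$level == "group", ]
  pv <- vapply(1:200, function(i) {
    coh <- generate_cohesion(st$groups, ind, st$config, seed = 50000L + i)
    compare_levels(coh, ind, grp)$p_value
  }, numeric(1))
  rej <- mean(pv < 0.05)
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.10)
})

test_that("run_contrasts reports the three planned comparisons", {
  st <- generate_study(smoke_config(8, seed = 91))
  sur <- false_pair_surrogates(st$groups, seed = 92)
  stab <- sync_table(sur, st$params$dyad, st$params$triad, levels = "group")
  ct <- run_contrasts(st$sync, stab)
  expect_equal(ct$contrast,
               c("task real vs surrogate", "task vs baseline (real)",
                 "baseline real vs surrogate"))
  expect_true(all(ct$p_value >= 0 & ct$p_value <= 1))
  expect_true(all(ct$n <= 8))
  # degenerate: identical scores leave no informative pairs
  fake <- st$sync[st$sync$level == "group", ]
  fake$is_surrogate <- TRUE
  fake$unit_id <- sprintf("s%03d", match(fake$group_id, unique(fake$group_id)))
  expect_error(run_contrasts(st$sync, fake), "tied")
})
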