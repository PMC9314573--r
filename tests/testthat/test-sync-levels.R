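test_that("group-level sync scales exactly for identical members and ignores order", {
  set.seed(23)
  v <- rnorm(120, 0.8, 0.05)
  g_same <- make_group(list(v, v, v))
  pt <- embedding_params("triad", radius = 0.3)
  # identical members: joint distances are sqrt(3) times the univariate ones,
  # so the triad plot equals the single-member plot at radius r / sqrt(3)
  expect_equal(group_level_sync(g_same, pt, "task")$rec_pct,
               mdrqa(v, m = 7, d = 2, r = 0.3 / sqrt(3))$rec_pct)
  # and a perfectly still, identical triad saturates
  g_const <- make_group(list(rep(0.8, 50), rep(0.8, 50), rep(0.8, 50)))
  expect_equal(group_level_sync(g_const, pt, "task")$rec_pct, 100)

  g <- make_group(list(rnorm(120, 0.8, 0.05), rnorm(130, 0.85, 0.05),
                       rnorm(125, 0.9, 0.05)))
  perm <- c(3, 1, 2)
  g_perm <- make_group(lapply(perm, function(i) g$members[[i]]$baseline),
                       lapply(perm, function(i) g$members[[i]]$task))
  m1 <- group_level_sync(g, pt, "task")
  m2 <- group_level_sync(g_perm, pt, "task")
  expect_equal(m1[, c("rec_pct", "lam_pct", "mean_v", "max_v")],
               m2[, c("rec_pct", "lam_pct", "mean_v", "max_v")])
})

test_that("individual scores are the mean of each member's two dyads", {
  set.seed(24)
  g <- make_group(list(rnorm(100, 0.8, 0.05), rnorm(110, 0.85, 0.05),
                       rnorm(105, 0.9, 0.05)))
  pd <- embedding_params("dyad", radius = 0.25)
  ind <- individual_level_sync(g, pd, "task")
  pairs <- assemble_level_inputs(g, "dyad", "task")
  dy <- lapply(pairs, function(x) unlist(mdrqa(x, pd)))
  expect_equal(unlist(ind[1, c("rec_pct", "lam_pct", "mean_v", "max_v")]),
               (dy[["1-2"]] + dy[["1-3"]]) / 2, ignore_attr = TRUE)
  expect_equal(unlist(ind[2, c("rec_pct", "lam_pct", "mean_v", "max_v")]),
               (dy[["1-2"]] + dy[["2-3"]]) / 2, ignore_attr = TRUE)
  # each dyad counted twice across members: member sum == dyad sum
  expect_equal(sum(ind$rec_pct), sum(vapply(dy, `[[`, 1, "rec_pct")))
})

test_that("vertical_sync_composite standardises within level x phase", {
  base <- data.frame(
    unit_id = c("a", "b"), group_id = c("a", "b"), member_id = NA,
    study = 1, condition = "A", level = "group", phase = "task",
    is_surrogate = FALSE,
    rec_pct = c(2, 3), lam_pct = c(50, 60), mean_v = c(2, 4), max_v = c(5, 9)
  )
  out <- vertical_sync_composite(base)
  # two units: composites are antisymmetric
  expect_equal(out$vertical_sync, c(-1, 1) * out$vertical_sync[2])
  expect_lt(abs(mean(out$vertical_sync)), 1e-10)

  # a unit sitting at the stratum mean gets composite 0
  tri <- rbind(base, base[1, ])
  tri$unit_id <- c("a", "b", "c")
  tri[3, c("lam_pct", "mean_v", "max_v")] <- c(55, 3, 7)
  out3 <- vertical_sync_composite(tri)
  expect_equal(out3$vertical_sync[3], 0)
  expect_lt(abs(mean(out3$vertical_sync)), 1e-10)

  # location invariance of z-scores
  shifted <- base
  shifted$lam_pct <- shifted$lam_pct + 17
  expect_equal(vertical_sync_composite(shifted)$vertical_sync,
               out$vertical_sync)

  flat <- base
  flat$mean_v <- 2
  expect_error(vertical_sync_composite(flat), "mean_v")
  expect_error(vertical_sync_composite(base[1, ]), ">= 2 real units")
})

test_that("surrogates are scored against the real-unit scale", {
  st <- default_study()
  sur <- false_pair_surrogates(st$groups, n_surrogates = 20, seed = 31)
  tab <- rbind(
    st$sync[, setdiff(names(st$sync), "vertical_sync")],
    sync_table(sur, st$params$dyad, st$params$triad, levels = "group")
  )
  out <- vertical_sync_composite(tab)
  real <- out$level == "group" & out$phase == "task" & !out$is_surrogate
  expect_lt(abs(mean(out$vertical_sync[real])), 1e-10)
  # real-unit composites unchanged by the presence of surrogates
  ref <- st$sync[st$sync$level == "group" & st$sync$phase == "task", ]
  expect_equal(out$vertical_sync[real], ref$vertical_sync)
})

test_that("delta_sync subtracts baseline from task per unit", {
  st <- generate_study(smoke_config(4, seed = 21))
  task <- st$sync[st$sync$phase == "task", ]
  base <- st$sync[st$sync$phase == "baseline", ]
  d <- delta_sync(task, base)
  expect_equal(d$delta, task$vertical_sync - base$vertical_sync[
    match(paste(task$unit_id, task$level), paste(base$unit_id, base$level))])
  # identical phases give all-zero deltas
  d0 <- delta_sync(task, task)
  expect_true(all(d0$delta == 0) && all(d0$d_rec == 0))
  # simple arithmetic
  t1 <- task[1, ]; b1 <- base[base$unit_id == t1$unit_id &
                                base$level == t1$level, ]
  t1$vertical_sync <- 1.2; b1$vertical_sync <- 0.5
  expect_equal(delta_sync(t1, b1)$delta, 0.7)
  expect_error(delta_sync(task[-1, ], base), "unmatched")
})

test_that("false-pair surrogates draw members from distinct groups, reproducibly", {
  st <- generate_study(smoke_config(6, seed = 41))
  sur1 <- false_pair_surrogates(st$groups, seed = 99)
  sur2 <- false_pair_surrogates(st$groups, seed = 99)
  expect_length(sur1, 6L)
  expect_identical(sur1, sur2)
  for (s in sur1) {
    expect_true(s$is_surrogate)
    src <- attr(s, "sources")
    expect_length(unique(src$source_group), 3L)
    # series are copied intact from their sources
    src_rec <- st$groups[[match(src$source_group[1],
                                vapply(st$groups, `[[`, "", "group_id"))]]
    expect_identical(s$members[[1]]$task,
                     src_rec$members[[src$source_member[1]]]$task)
  }
  expect_error(false_pair_surrogates(st$groups[1:2]), "at least 3")
})

test_that("individual- and group-level delta synchrony are positively correlated", {
  st <- default_study()
  ind <- st$deltas[st$deltas$level == "individual", ]
  grp <- st$deltas[st$deltas$level == "group", ]
  gi <- grp$delta[match(ind$group_id, grp$group_id)]
  ct <- suppressWarnings(cor.test(ind$delta, gi, method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("coupled triads out-recur uncoupled ones during the task", {
  n <- 60
  cfg_c <- smoke_config(n, seed = 61) # kappa_task = 0.15
  cfg_u <- smoke_config(n, seed = 61, coupling_task = 0)
  gc <- lapply(1:n, function(i) generate_triad(cfg_c, i))
  gu <- lapply(1:n, function(i) generate_triad(cfg_u, i))
  r <- calibrate_threshold(c(level_datasets(gc, "triad", "task"),
                             level_datasets(gu, "triad", "task")), d = 2, m = 7)
  pt <- embedding_params("triad", radius = as.numeric(r))
  rec_c <- vapply(gc, function(g) group_level_sync(g, pt, "task")$rec_pct, 1)
  rec_u <- vapply(gu, function(g) group_level_sync(g, pt, "task")$rec_pct, 1)
  expect_gt(mean(rec_c), mean(rec_u))
  n_pos <- sum(rec_c > rec_u) # paired by index: a sign test
  expect_lt(stats::pbinom(n - n_pos, n, 0.5), 0.01)
})
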