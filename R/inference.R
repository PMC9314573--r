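#' Wilcoxon signed-rank test for paired samples
#'
#' Paired signed-rank test reporting the classical `T` statistic -- the
#' *smaller* of the positive and negative rank sums -- and a two-sided p-value.
#' Zero differences are dropped before ranking; ties among the absolute
#' differences receive average ranks. For fewer than 26 informative pairs the
#' null distribution of the positive rank sum is computed exactly by
#' convolving the per-pair generating functions (equivalent to enumerating all
#' `2^n` sign assignments, ties included); beyond that a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return List with `statistic` (T), `p_value`, `n` (informative pairs),
#'   `w_plus`, `w_minus`, `direction` (+1 when `a` tends to exceed `b`) and
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all pairs tied (zero differences); test undefined")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  t_stat <- min(w_plus, w_minus)
  if (n < 26L) {
    # exact: distribution of W+ over all sign assignments, half-ranks doubled
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)
    f[1L] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), f[seq_len(total + 1L - rk)])
      f <- f + shifted
    }
    f <- f / 2^n
    t2 <- as.integer(round(2 * t_stat))
    p <- min(1, 2 * sum(f[seq_len(t2 + 1L)]))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (t_stat - mu + 0.5) / sigma # continuity correction toward the mean
    p <- min(1, 2 * pnorm(z))
    method <- "normal approximation"
  }
  list(
    statistic = t_stat, p_value = p, n = n,
    w_plus = w_plus, w_minus = w_minus,
    direction = sign(w_plus - w_minus),
    method = method
  )
}

# ---------------------------------------------------------------------------

#' Mixed-effects model predicting cohesion from delta synchrony
#'
#' Fits, by REML via \pkg{lme4},
#' `cohesion ~ delta + condition (+ delta:condition) + (1 | group_id)`,
#' i.e. a grand mean, a fixed slope for delta synchrony, fixed condition
#' offsets (single 4-level factor pooling both studies), optionally their
#' interaction, and a random intercept per group. Condition uses sum-to-zero
#' contrasts so the marginal (type-III style) F tests are well defined with
#' the interaction present. F tests use between-within (containment)
#' denominator degrees of freedom: terms constant within groups are tested
#' against the group stratum, terms varying within groups against the residual
#' stratum.
#'
#' @param cohesion Data frame with `group_id`, `member_id`, `condition`,
#'   `cohesion` (e.g. from [generate_cohesion()] or `cohesion.csv`).
#' @param deltas Per-unit delta-synchrony table (one level) from
#'   [delta_sync()]; group-level deltas join by `group_id`, individual-level
#'   by `group_id` + `member_id`.
#' @param include_interaction Include `delta:condition` (default `TRUE`).
#' @param random Random-intercept grouping: `"group"` (default) or `"study"`.
#' @return Object of class `cohesion_fit`: list with `coefficients` (fixed
#'   effects), `anova` (term, F, numerator/denominator df, p), `varcomp`
#'   (random-intercept and residual variances), `r2_marginal`, `level`,
#'   and `model` (the underlying `lmerMod`).
#' @export
fit_cohesion_model <- function(cohesion, deltas, include_interaction = TRUE,
                               random = c("group", "study")) {
  random <- match.arg(random)
  level <- unique(deltas$level)
  if (length(level) != 1L) stop("deltas must contain a single level")
  df <- join_deltas(cohesion, deltas, level)
  df$condition <- factor(df$condition)
  contrasts(df$condition) <- contr.sum(nlevels(df$condition))
  df$.grp <- factor(if (random == "group") df$group_id else df$study)

  fixed <- if (include_interaction) cohesion ~ delta * condition
           else cohesion ~ delta + condition
  form <- stats::update.formula(fixed, . ~ . + (1 | .grp))
  fit <- lme4::lmer(form, data = df, REML = TRUE)
  if (lme4::isSingular(fit)) {
    warning("singular fit: random-intercept variance estimated at 0")
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == ".grp"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]

  beta <- lme4::fixef(fit)
  vcv <- as.matrix(stats::vcov(fit))
  X <- model.matrix(fixed, data = df)
  stopifnot(ncol(X) == length(beta))
  asn <- attr(X, "assign")
  term_labels <- attr(terms(fixed), "term.labels")

  n_grp <- nlevels(factor(df$group_id))
  n_obs <- nrow(df)
  is_between <- vapply(seq_along(term_labels), function(ti) {
    cols <- which(asn == ti)
    all(vapply(cols, function(j) {
      all(tapply(X[, j], df$group_id, function(v) max(v) - min(v)) == 0)
    }, logical(1)))
  }, logical(1))
  p_between <- sum(vapply(which(is_between), function(ti) sum(asn == ti), integer(1)))
  p_within <- sum(vapply(which(!is_between), function(ti) sum(asn == ti), integer(1)))
  df_between <- max(n_grp - p_between - 1L, 1L)
  df_within <- max(n_obs - n_grp - p_within, 1L)

  an <- do.call(rbind, lapply(seq_along(term_labels), function(ti) {
    cols <- which(asn == ti)
    bi <- beta[cols]
    Vi <- vcv[cols, cols, drop = FALSE]
    Fval <- as.numeric(crossprod(bi, solve(Vi, bi))) / length(cols)
    ddf <- if (is_between[ti]) df_between else df_within
    data.frame(
      term = term_labels[ti], F = Fval, num_df = length(cols), den_df = ddf,
      p = stats::pf(Fval, length(cols), ddf, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  }))

  fitted_fixed <- as.numeric(X %*% beta)
  r2m <- var(fitted_fixed) / (var(fitted_fixed) + tau2 + sigma2)

  out <- list(
    coefficients = beta,
    vcov = vcv,
    anova = an,
    varcomp = c(group_intercept = tau2, residual = sigma2),
    r2_marginal = r2m,
    level = level,
    n_obs = n_obs,
    n_groups = n_grp,
    model = fit
  )
  class(out) <- "cohesion_fit"
  out
}

join_deltas <- function(cohesion, deltas, level) {
  if (level == "group") {
    idx <- match(cohesion$group_id, deltas$group_id)
  } else {
    idx <- match(paste(cohesion$group_id, cohesion$member_id),
                 paste(deltas$group_id, deltas$member_id))
  }
  if (anyNA(idx)) {
    stop("no delta synchrony for participant(s): ",
         paste(head(paste(cohesion$group_id, cohesion$member_id)[is.na(idx)], 5L),
               collapse = ", "))
  }
  cbind(cohesion, delta = deltas$delta[idx])
}

#' @export
print.cohesion_fit <- function(x, ...) {
  cat(sprintf("Mixed model on cohesion (%s-level delta synchrony), %d obs / %d groups\n",
              x$level, x$n_obs, x$n_groups))
  print(x$anova, row.names = FALSE, digits = 4)
  cat(sprintf("Random intercept var = %.4f, residual var = %.4f, marginal R^2 = %.3f\n",
              x$varcomp[["group_intercept"]], x$varcomp[["residual"]],
              x$r2_marginal))
  invisible(x)
}

#' Likelihood-ratio comparison of individual- vs group-level predictors
#'
#' Refits, by maximum likelihood, the cohesion model containing the
#' individual-level delta synchrony (with condition and interaction) and the
#' same model with the group-level delta added, and returns the likelihood
#' ratio test of the added term. When the group-level predictor is collinear
#' with the individual-level one it contributes no parameter and the statistic
#' is ~0.
#'
#' @param cohesion Cohesion data frame (see [fit_cohesion_model()]).
#' @param individual_delta,group_delta [delta_sync()] tables at the two levels.
#' @param include_interaction Include `ind_delta:condition` in both models.
#' @return List with `chi_square`, `df`, `p_value`, and the two ML fits.
#' @export
compare_levels <- function(cohesion, individual_delta, group_delta,
                           include_interaction = TRUE) {
  df <- join_deltas(cohesion, individual_delta, "individual")
  names(df)[names(df) == "delta"] <- "ind_delta"
  idx <- match(df$group_id, group_delta$group_id)
  if (anyNA(idx)) stop("group-level delta missing for some groups")
  df$grp_delta <- group_delta$delta[idx]
  df$condition <- factor(df$condition)
  contrasts(df$condition) <- contr.sum(nlevels(df$condition))
  df$.grp <- factor(df$group_id)

  f1 <- if (include_interaction) {
    cohesion ~ ind_delta * condition + (1 | .grp)
  } else {
    cohesion ~ ind_delta + condition + (1 | .grp)
  }
  f2 <- stats::update.formula(f1, . ~ . + grp_delta)
  m1 <- lme4::lmer(f1, data = df, REML = FALSE)
  m2 <- suppressMessages(lme4::lmer(f2, data = df, REML = FALSE,
                                    control = lme4::lmerControl(check.rankX = "silent.drop.cols")))
  df_added <- length(lme4::fixef(m2)) - length(lme4::fixef(m1))
  chi <- max(0, 2 * (as.numeric(logLik(m2)) - as.numeric(logLik(m1))))
  p <- if (df_added > 0L) stats::pchisq(chi, df_added, lower.tail = FALSE) else NA_real_
  list(chi_square = chi, df = df_added, p_value = p, fit_individual = m1,
       fit_both = m2)
}

#' Signed-rank contrasts of real vs surrogate recurrence rates
#'
#' The three planned comparisons of group-level %REC: task-phase real vs
#' surrogate, task vs baseline within real groups, and baseline-phase real vs
#' surrogate. Real and surrogate units are paired by enumeration order, phases
#' by group id.
#'
#' @param real_scores Score table ([sync_table()]) of the real groups at the
#'   group level, both phases.
#' @param surrogate_scores Score table of the surrogate groups at the group
#'   level, both phases (same number of units as real groups).
#' @return Data frame with one row per contrast: `contrast`, `statistic` (T),
#'   `p_value`, `n`, `direction` (+1 when the first-named member of the
#'   contrast is larger).
#' @export
run_contrasts <- function(real_scores, surrogate_scores) {
  pick <- function(df, phase, surrogate) {
    out <- df[df$level == "group" & df$phase == phase &
                df$is_surrogate == surrogate, ]
    out[order(out$unit_id), ]
  }
  real_task <- pick(real_scores, "task", FALSE)
  real_base <- pick(real_scores, "baseline", FALSE)
  sur_task <- pick(surrogate_scores, "task", TRUE)
  sur_base <- pick(surrogate_scores, "baseline", TRUE)
  if (nrow(real_task) != nrow(sur_task)) {
    stop("real and surrogate tables must contain the same number of groups")
  }
  one <- function(label, a, b) {
    w <- wilcoxon_signed_rank(a, b)
    data.frame(
      contrast = label, statistic = w$statistic, p_value = w$p_value,
      n = w$n, direction = w$direction, stringsAsFactors = FALSE
    )
  }
  rbind(
    one("task real vs surrogate", real_task$rec_pct, sur_task$rec_pct),
    one("task vs baseline (real)", real_task$rec_pct,
        real_base$rec_pct[match(real_task$group_id, real_base$group_id)]),
    one("baseline real vs surrogate", real_base$rec_pct, sur_base$rec_pct)
  )
}
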