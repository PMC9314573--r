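#' Group-level synchrony score of one triad
#'
#' Runs MdRQA on the 3-column multivariate series of the whole triad (members
#' trimmed to the group-wide shortest length) at the triad-level embedding
#' parameters.
#'
#' @param group A `group_record`.
#' @param params_triad [embedding_params()] for the triad level.
#' @param phase `"baseline"` or `"task"`.
#' @return One-row data frame with columns `unit_id`, `group_id`, `member_id`
#'   (`NA`), `study`, `condition`, `level`, `phase`, `is_surrogate`, `rec_pct`,
#'   `lam_pct`, `mean_v`, `max_v`.
#' @export
group_level_sync <- function(group, params_triad, phase = c("baseline", "task")) {
  phase <- match.arg(phase)
  x <- assemble_level_inputs(group, "triad", phase)
  meas <- mdrqa(x, params_triad)
  sync_row(group, member_id = NA_integer_, level = "group", phase = phase, meas)
}

#' Individual-level synchrony scores of one triad
#'
#' Computes all three dyadic recurrence analyses of the triad at the dyad-level
#' parameters (each pair trimmed within itself) and scores each member as the
#' measure-by-measure arithmetic mean of that member's two dyads: member A
#' averages dyads (A,B) and (A,C), and so on.
#'
#' @param group A `group_record`.
#' @param params_dyad [embedding_params()] for the dyad level.
#' @param phase `"baseline"` or `"task"`.
#' @return Three-row data frame (one per member), same columns as
#'   [group_level_sync()].
#' @export
individual_level_sync <- function(group, params_dyad,
                                  phase = c("baseline", "task")) {
  phase <- match.arg(phase)
  pairs <- assemble_level_inputs(group, "dyad", phase)
  dyad <- lapply(pairs, function(x) unlist(mdrqa(x, params_dyad)))
  member_dyads <- list(c("1-2", "1-3"), c("1-2", "2-3"), c("1-3", "2-3"))
  do.call(rbind, lapply(1:3, function(i) {
    meas <- as.list((dyad[[member_dyads[[i]][1]]] + dyad[[member_dyads[[i]][2]]]) / 2)
    sync_row(group, member_id = i, level = "individual", phase = phase, meas)
  }))
}

sync_row <- function(group, member_id, level, phase, meas) {
  data.frame(
    unit_id = if (is.na(member_id)) group$group_id else
      paste0(group$group_id, "/", member_id),
    group_id = group$group_id,
    member_id = member_id,
    study = group$study,
    condition = group$condition,
    level = level,
    phase = phase,
    is_surrogate = group$is_surrogate,
    rec_pct = meas$rec_pct, lam_pct = meas$lam_pct,
    mean_v = meas$mean_v, max_v = meas$max_v,
    stringsAsFactors = FALSE
  )
}

#' Synchrony score table for a sample of groups
#'
#' Convenience wrapper computing [group_level_sync()] and/or
#' [individual_level_sync()] for every group and phase.
#'
#' @param groups List of `group_record`s (real or surrogate).
#' @param params_dyad,params_triad [embedding_params()] per level.
#' @param levels Levels to compute (default both).
#' @param phases Phases to compute (default both).
#' @return Data frame of per-unit scores (see [group_level_sync()]).
#' @export
sync_table <- function(groups, params_dyad = embedding_params("dyad"),
                       params_triad = embedding_params("triad"),
                       levels = c("individual", "group"),
                       phases = PHASES) {
  rows <- list()
  for (g in groups) {
    for (p in phases) {
      if ("group" %in% levels) {
        rows[[length(rows) + 1L]] <- group_level_sync(g, params_triad, p)
      }
      if ("individual" %in% levels) {
        rows[[length(rows) + 1L]] <- individual_level_sync(g, params_dyad, p)
      }
    }
  }
  do.call(rbind, rows)
}

#' Vertical Synchrony composite
#'
#' Adds the composite synchrony score used as the primary vertical measure:
#' within each stratum (level x phase), `lam_pct`, `mean_v` and `max_v` are
#' z-scored across the *real* (non-surrogate) units and the three z-scores are
#' averaged per unit. Surrogate units in the same stratum are standardised
#' against the real-unit mean and SD, keeping them on the same scale.
#'
#' @param sync_df Score table from [sync_table()].
#' @return `sync_df` with an added numeric column `vertical_sync`.
#' @export
vertical_sync_composite <- function(sync_df) {
  sync_df$vertical_sync <- NA_real_
  measures <- c("lam_pct", "mean_v", "max_v")
  for (lv in unique(sync_df$level)) {
    for (ph in unique(sync_df$phase)) {
      in_stratum <- sync_df$level == lv & sync_df$phase == ph
      real <- in_stratum & !sync_df$is_surrogate
      if (sum(real) < 2L) {
        stop(sprintf("stratum %s/%s needs >= 2 real units to standardise", lv, ph))
      }
      z <- sapply(measures, function(mv) {
        mu <- mean(sync_df[[mv]][real])
        s <- sd(sync_df[[mv]][real])
        if (s == 0) {
          stop(sprintf("zero variance in %s within stratum %s/%s", mv, lv, ph))
        }
        (sync_df[[mv]][in_stratum] - mu) / s
      })
      sync_df$vertical_sync[in_stratum] <- rowMeans(z)
    }
  }
  sync_df
}

#' Delta synchrony: task minus baseline
#'
#' Pairs each unit's task and baseline scores and returns the change in the
#' Vertical Synchrony composite (`delta`) together with the per-measure raw
#' changes.
#'
#' @param task_scores,baseline_scores Rows of a composite-filled score table
#'   (see [vertical_sync_composite()]) for the two phases; units must match.
#' @return Data frame with columns `unit_id`, `group_id`, `member_id`, `study`,
#'   `condition`, `level`, `is_surrogate`, `delta` and `d_rec`, `d_lam`,
#'   `d_mean_v`, `d_max_v`.
#' @export
delta_sync <- function(task_scores, baseline_scores) {
  if (is.null(task_scores$vertical_sync) || is.null(baseline_scores$vertical_sync)) {
    stop("scores lack a vertical_sync column; run vertical_sync_composite() first")
  }
  tkey <- paste(task_scores$unit_id, task_scores$level)
  bkey <- paste(baseline_scores$unit_id, baseline_scores$level)
  idx <- match(tkey, bkey)
  unmatched <- c(tkey[is.na(idx)], setdiff(bkey, tkey))
  if (length(unmatched)) {
    stop("unmatched unit(s) across phases: ", paste(unmatched, collapse = ", "))
  }
  b <- baseline_scores[idx, ]
  data.frame(
    unit_id = task_scores$unit_id,
    group_id = task_scores$group_id,
    member_id = task_scores$member_id,
    study = task_scores$study,
    condition = task_scores$condition,
    level = task_scores$level,
    is_surrogate = task_scores$is_surrogate,
    delta = task_scores$vertical_sync - b$vertical_sync,
    d_rec = task_scores$rec_pct - b$rec_pct,
    d_lam = task_scores$lam_pct - b$lam_pct,
    d_mean_v = task_scores$mean_v - b$mean_v,
    d_max_v = task_scores$max_v - b$max_v,
    stringsAsFactors = FALSE
  )
}

#' False-pair surrogate groups
#'
#' Builds pseudo-triads by randomly partnering participants' time series with
#' members of *different* real groups: each pseudo-triad draws its three
#' members from three distinct source groups (without replacement within the
#' pseudo-triad, with replacement across pseudo-triads), keeping each
#' participant's baseline and task series intact. Trimming is re-applied
#' within each pseudo-group when it is analysed, and the same embedding
#' parameters as for real groups should be used, so surrogate scores estimate
#' chance-level recurrence.
#'
#' @param groups List of at least 3 real `group_record`s.
#' @param n_surrogates Number of pseudo-triads (default: one per real group,
#'   so real-vs-surrogate contrasts pair 1:1 by enumeration order).
#' @param seed Optional integer seed for the assignment.
#' @return List of `group_record`s with `is_surrogate = TRUE`, ids `"s001"`,
#'   ... and attribute `sources` on each record (data frame of source group
#'   and member ids).
#' @export
false_pair_surrogates <- function(groups, n_surrogates = length(groups),
                                  seed = NULL) {
  if (length(groups) < 3L) stop("need at least 3 real groups to build surrogates")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_surrogates), function(k) {
    src_groups <- sample(length(groups), 3L, replace = FALSE)
    src_members <- sample(3L, 3L, replace = TRUE)
    members <- lapply(1:3, function(i) {
      groups[[src_groups[i]]]$members[[src_members[i]]]
    })
    rec <- new_group_record(
      group_id = sprintf("s%03d", k),
      study = NA, condition = "surrogate",
      members = members, is_surrogate = TRUE
    )
    attr(rec, "sources") <- data.frame(
      source_group = vapply(src_groups, function(j) groups[[j]]$group_id, character(1)),
      source_member = src_members
    )
    rec
  })
}
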