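#' Load a long-format IBI table into group records
#'
#' Reads an `ibi.csv`-style file (columns `group_id`, `member_id`, `study`,
#' `condition`, `phase`, `beat_index`, `ibi_s`) and assembles one
#' `group_record` per complete group. Groups without exactly 3 members, or
#' with a member missing one of the two phases, are excluded with a warning
#' (mirroring the exclusion of triads with incomplete physiological data);
#' their ids are attached as attribute `excluded`.
#'
#' @param path Path to the CSV file.
#' @return List of `group_record`s (possibly empty), with attribute
#'   `excluded` (character vector of dropped group ids).
#' @export
load_ibi_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("empty IBI table: ", path)
    return(structure(list(), excluded = character(0)))
  }
  group_records_from_long(df)
}

#' Assemble group records from a long-format IBI data frame
#'
#' @param df Data frame with the `ibi.csv` schema (see [load_ibi_table()]).
#' @return List of `group_record`s with attribute `excluded`.
#' @export
group_records_from_long <- function(df) {
  needed <- c("group_id", "member_id", "phase", "beat_index", "ibi_s")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("malformed IBI table, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"study" %in% names(df)) df$study <- NA
  if (!"condition" %in% names(df)) df$condition <- NA_character_
  bad <- which(!is.finite(df$ibi_s) | df$ibi_s <= 0 | !df$phase %in% PHASES)
  if (length(bad)) {
    stop(sprintf("malformed IBI row(s) at line(s) %s (non-positive ibi_s or unknown phase)",
                 paste(head(bad + 1L, 5L), collapse = ", ")))
  }
  records <- list()
  excluded <- character(0)
  for (gid in unique(df$group_id)) {
    sub <- df[df$group_id == gid, ]
    member_ids <- sort(unique(sub$member_id))
    complete <- length(member_ids) == 3L &&
      all(vapply(member_ids, function(mid) {
        all(PHASES %in% sub$phase[sub$member_id == mid])
      }, logical(1)))
    if (!complete) {
      excluded <- c(excluded, as.character(gid))
      next
    }
    members <- lapply(member_ids, function(mid) {
      out <- list()
      for (p in PHASES) {
        seg <- sub[sub$member_id == mid & sub$phase == p, ]
        seg <- seg[order(seg$beat_index), ]
        if (!identical(as.integer(seg$beat_index), seq_len(nrow(seg)) - 1L)) {
          stop(sprintf("group %s member %s phase %s: beat_index not contiguous from 0",
                       gid, mid, p))
        }
        out[[p]] <- seg$ibi_s
      }
      out
    })
    records[[length(records) + 1L]] <- new_group_record(
      group_id = gid, study = sub$study[1], condition = sub$condition[1],
      members = members
    )
  }
  if (length(excluded)) {
    warning("excluded incomplete group(s): ", paste(excluded, collapse = ", "))
  }
  attr(records, "excluded") <- excluded
  records
}

#' Trim series to the shortest length
#'
#' Equalises the lengths of two or more series by removing the excess data
#' points at the end of the longer ones, so that all series have the length of
#' the shortest. Values are never modified, only dropped from the tail; input
#' order is preserved and the operation is idempotent.
#'
#' @param series List of numeric vectors (at least 2, each non-empty).
#' @return List of numeric vectors, all of the minimum input length.
#' @export
trim_to_shortest <- function(series) {
  if (!is.list(series) || length(series) < 2L) {
    stop("need a list of at least 2 series")
  }
  lens <- lengths(series)
  if (any(lens == 0L)) stop("cannot trim: empty series present")
  n <- min(lens)
  lapply(series, function(v) v[seq_len(n)])
}

#' Assemble the multivariate inputs for one analysis level
#'
#' For the triad level, returns the single 3-column multivariate series of the
#' group (members trimmed to the group-wide shortest). For the dyad level,
#' returns the three 2-column pair series (A,B), (A,C), (B,C), each trimmed
#' within its own pair -- pairwise, not to the triad-wide minimum.
#'
#' @param group A `group_record`.
#' @param level `"triad"` or `"dyad"`.
#' @param phase `"baseline"` or `"task"`.
#' @return For `"triad"`: one numeric matrix (`L x 3`). For `"dyad"`: a named
#'   list of three matrices (`"1-2"`, `"1-3"`, `"2-3"`).
#' @export
assemble_level_inputs <- function(group, level = c("triad", "dyad"),
                                  phase = c("baseline", "task")) {
  stopifnot(inherits(group, "group_record"))
  level <- match.arg(level)
  phase <- match.arg(phase)
  series <- lapply(group$members, `[[`, phase)
  if (level == "triad") {
    do.call(cbind, trim_to_shortest(series))
  } else {
    pairs <- list(`1-2` = c(1L, 2L), `1-3` = c(1L, 3L), `2-3` = c(2L, 3L))
    lapply(pairs, function(idx) do.call(cbind, trim_to_shortest(series[idx])))
  }
}

# All multivariate datasets of one level/phase across groups: triad -> one per
# group; dyad -> three per group.
level_datasets <- function(groups, level, phase) {
  out <- lapply(groups, function(g) {
    x <- assemble_level_inputs(g, level, phase)
    if (level == "triad") list(x) else x
  })
  unlist(out, recursive = FALSE)
}
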