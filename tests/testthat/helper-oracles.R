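# Independent brute-force oracles used to validate the fast implementations.

# Naive RQA: explicit embedding, double-loop distances, inclusive threshold,
# per-definition %LAM (vertical neighbour check per recurrent cell) and an
# explicit per-column run scan for the line measures.
oracle_measures <- function(x, m, d, r, min_line = 2) {
  x <- as.matrix(x)
  n <- nrow(x)
  len <- n - (m - 1) * d
  pts <- lapply(seq_len(len), function(t) {
    out <- c()
    for (k in 0:(m - 1)) out <- c(out, x[t + k * d, ])
    out
  })
  M <- matrix(FALSE, len, len)
  for (i in seq_len(len)) {
    for (j in seq_len(len)) {
      M[i, j] <- sqrt(sum((pts[[i]] - pts[[j]])^2)) <= r
    }
  }
  ones <- sum(M)
  has_neigh <- 0L
  for (j in seq_len(len)) {
    for (i in seq_len(len)) {
      if (M[i, j] && ((i > 1 && M[i - 1, j]) || (i < len && M[i + 1, j]))) {
        has_neigh <- has_neigh + 1L
      }
    }
  }
  runs <- integer(0)
  for (j in seq_len(len)) {
    cnt <- 0L
    for (i in seq_len(len + 1L)) {
      on <- i <= len && M[i, j]
      if (on) cnt <- cnt + 1L
      else {
        if (cnt >= min_line) runs <- c(runs, cnt)
        cnt <- 0L
      }
    }
  }
  list(
    rec_pct = 100 * ones / len^2,
    lam_pct = if (ones > 0) 100 * has_neigh / ones else 0,
    mean_v = if (length(runs)) mean(runs) else 0,
    max_v = if (length(runs)) as.numeric(max(runs)) else 0
  )
}

# Exact signed-rank test by full enumeration of the 2^n sign assignments.
oracle_signed_rank <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  t_stat <- min(w_plus, sum(r) - w_plus)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  list(statistic = t_stat, p_value = min(1, 2 * mean(w_all <= t_stat)))
}

# The worked toy series: three members, four beats each.
toy_series <- function() {
  cbind(c(1, 1, 2, 25), c(1, 1, 3, 40), c(1, 1, 1, 99))
}

# group_record built directly from member series (both phases alike unless
# task series are given).
make_group <- function(baseline, task = baseline, group_id = "g001",
                       study = 1, condition = "A") {
  rqasync:::new_group_record(
    group_id = group_id, study = study, condition = condition,
    members = lapply(1:3, function(i) list(baseline = baseline[[i]],
                                           task = task[[i]]))
  )
}

# Small design for fast end-to-end runs.
smoke_config <- function(n_groups = 8, seed = 11, ...) {
  per <- n_groups %/% 4
  layout <- data.frame(
    study = c(1, 1, 2, 2), condition = c("A", "B", "C", "D"),
    n_groups = c(per, per, per, n_groups - 3 * per)
  )
  sim_config(n_groups = n_groups, condition_layout = layout, seed = seed, ...)
}

# The default 87-triad study is expensive (~6 s); build it once per test run.
.rqasync_cache <- new.env(parent = emptyenv())
default_study <- function() {
  if (is.null(.rqasync_cache$study)) {
    .rqasync_cache$study <- generate_study(sim_config(seed = 101))
  }
  .rqasync_cache$study
}
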