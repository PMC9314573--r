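#' Time-delay embedding of a multivariate series
#'
#' Reconstructs a phase-space trajectory from an `N x D` multivariate series by
#' concatenating `m` delayed copies of the rows. Point `t` of the trajectory is
#' `c(x[t, ], x[t + d, ], ..., x[t + (m - 1) * d, ])`, so the trajectory has
#' `N - (m - 1) * d` points in `D * m` dimensions. With `m = 1` the trajectory
#' is the series itself, whatever `d`.
#'
#' @param series Numeric matrix (`N x D`) or vector (treated as `N x 1`). Rows
#'   are time points, columns are signal dimensions (e.g. the members of a
#'   group).
#' @param m Embedding dimension (positive integer).
#' @param d Embedding delay in samples (positive integer).
#' @return Numeric matrix with `N - (m - 1) * d` rows and `D * m` columns, with
#'   attributes `m`, `d` and `source_dims`.
#' @examples
#' x <- cbind(c(1, 1, 2, 25), c(1, 1, 3, 40), c(1, 1, 1, 99))
#' delay_embed(x, m = 1, d = 1)  # the four joint phase-space coordinates
#' @export
delay_embed <- function(series, m, d) {
  x <- as_mv_series(series)
  stopifnot(length(m) == 1L, length(d) == 1L)
  m <- as.integer(m)
  d <- as.integer(d)
  if (is.na(m) || m < 1L) stop("embedding dimension `m` must be a positive integer")
  if (is.na(d) || d < 1L) stop("delay `d` must be a positive integer")
  n <- nrow(x)
  len <- n - (m - 1L) * d
  if (len < 1L) {
    stop(sprintf(
      "series too short for embedding: need at least %d rows for m = %d, d = %d (got %d)",
      (m - 1L) * d + 1L, m, d, n
    ))
  }
  traj <- do.call(cbind, lapply(seq_len(m) - 1L, function(k) {
    x[(1L + k * d):(k * d + len), , drop = FALSE]
  }))
  attr(traj, "m") <- m
  attr(traj, "d") <- d
  attr(traj, "source_dims") <- ncol(x)
  traj
}

#' Euclidean distance matrix of a phase-space trajectory
#'
#' @param traj Numeric matrix of trajectory points (rows), e.g. from
#'   [delay_embed()].
#' @return Symmetric numeric matrix of pairwise Euclidean distances with a zero
#'   main diagonal.
#' @export
distance_matrix <- function(traj) {
  traj <- as_mv_series(traj)
  if (nrow(traj) < 1L) stop("trajectory must contain at least one point")
  dm <- as.matrix(dist(traj, method = "euclidean"))
  dimnames(dm) <- NULL
  dm
}

#' Threshold a distance matrix into a recurrence plot
#'
#' Two time points are recurrent when their phase-space distance is at most the
#' radius `r` (inclusive comparison). The main diagonal (line of identity) is
#' therefore always recurrent and is deliberately kept: all measures in this
#' package include it, the convention that reproduces the package's worked toy
#' example and retains auto-recurrence information.
#'
#' @param dist Square numeric matrix of distances.
#' @param r Recurrence radius (threshold), positive, same units as `dist`.
#' @return Square logical matrix of class `recurrence_plot` with attribute
#'   `radius`.
#' @export
recurrence_matrix <- function(dist, r) {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist)) {
    stop("`dist` must be a square matrix")
  }
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("radius `r` must be a single positive number")
  }
  rp <- dist <= r
  attr(rp, "radius") <- r
  class(rp) <- c("recurrence_plot", class(rp))
  rp
}

# Maximal vertical runs of TRUE in each column of a binary matrix, fully
# vectorized: pad with FALSE above/below, run starts are FALSE->TRUE edges and
# ends TRUE->FALSE edges; within each column starts and ends pair up in order,
# and which() returns column-major order, so the k-th start matches the k-th
# end globally.
column_run_lengths <- function(m) {
  n <- nrow(m)
  pad <- rbind(FALSE, m, FALSE)
  cur <- pad[-1L, , drop = FALSE]
  prev <- pad[-(n + 2L), , drop = FALSE]
  starts <- which(cur & !prev)
  ends <- which(!cur & prev)
  as.integer(ends - starts)
}

#' Lengths of vertical recurrence lines
#'
#' Extracts the maximal vertical runs of recurrent points in each column of a
#' recurrence plot and keeps those of length at least `min_line`. Isolated
#' recurrent points (runs of length 1) are not lines.
#'
#' @param rp Square logical/binary matrix (see [recurrence_matrix()]).
#' @param min_line Minimum run length counted as a line (default 2).
#' @return Integer vector of line lengths (possibly empty), in column order.
#' @export
vertical_line_lengths <- function(rp, min_line = 2L) {
  rp <- as_binary_plot(rp)
  len <- column_run_lengths(rp)
  len[len >= min_line]
}

#' Recurrence measures of a recurrence plot
#'
#' Computes the vertical-line measures used for interbeat-interval synchrony:
#' \describe{
#'   \item{rec_pct (%REC)}{percentage of recurrent cells in the plot,
#'     `100 * ones / N^2`.}
#'   \item{lam_pct (%LAM)}{percentage of recurrent cells having at least one
#'     vertically adjacent recurrent cell; 0 when the plot is empty.}
#'   \item{mean_v (meanV)}{mean vertical line length (runs `>= min_line`), in
#'     beats; 0 when no lines exist.}
#'   \item{max_v (maxV)}{maximum vertical line length; 0 when no lines exist.}
#' }
#' The main diagonal participates like any other cell (no Theiler window).
#'
#' @inheritParams vertical_line_lengths
#' @return Object of class `recurrence_measures`: a named list with fields
#'   `rec_pct`, `lam_pct`, `mean_v`, `max_v`.
#' @examples
#' x <- cbind(c(1, 1, 2, 25), c(1, 1, 3, 40), c(1, 1, 1, 99))
#' rp <- recurrence_matrix(distance_matrix(delay_embed(x, 1, 1)), r = 3)
#' unlist(recurrence_measures(rp))  # 62.5, 90, 3, 3
#' @export
recurrence_measures <- function(rp, min_line = 2L) {
  rp <- as_binary_plot(rp)
  measures_from_runs(sum(rp), nrow(rp), column_run_lengths(rp), min_line)
}

measures_from_runs <- function(ones, n, run_lengths, min_line = 2L) {
  # %LAM counts points with a vertical neighbour, i.e. points in runs >= 2,
  # independent of min_line (which only defines what counts as a line).
  neighbour_pts <- sum(run_lengths[run_lengths >= 2L])
  v <- run_lengths[run_lengths >= min_line]
  out <- list(
    rec_pct = 100 * ones / n^2,
    lam_pct = if (ones > 0L) 100 * neighbour_pts / ones else 0,
    mean_v = if (length(v)) mean(v) else 0,
    max_v = if (length(v)) as.numeric(max(v)) else 0
  )
  class(out) <- "recurrence_measures"
  out
}

#' @export
print.recurrence_measures <- function(x, ...) {
  cat(sprintf(
    "%%REC = %.3f, %%LAM = %.3f, meanV = %.3f, maxV = %g\n",
    x$rec_pct, x$lam_pct, x$mean_v, x$max_v
  ))
  invisible(x)
}

#' Multidimensional RQA of one multivariate series
#'
#' End-to-end recurrence quantification: delay-embeds the series, thresholds
#' pairwise Euclidean distances at the radius and returns the vertical-line
#' recurrence measures. This is the fast path used by the synchrony pipeline;
#' squared distances are computed via cross-products (BLAS) rather than
#' materialising [distance_matrix()], which is numerically equivalent.
#'
#' @param series Numeric matrix (`N x D`) or vector; e.g. the trimmed IBI
#'   series of the members of a dyad or triad, one column per member.
#' @param params An [embedding_params()] object (delay, dimension, radius), or
#'   `NULL` to pass `m`, `d`, `r` directly.
#' @param m,d,r Embedding dimension, delay and radius (used when `params` is
#'   `NULL`).
#' @param min_line Minimum vertical line length (default 2).
#' @return `recurrence_measures` object.
#' @export
mdrqa <- function(series, params = NULL, m = NULL, d = NULL, r = NULL,
                  min_line = 2L) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "embedding_params"))
    m <- params$dim
    d <- params$delay
    r <- params$radius
    if (isTRUE(params$normalize_input)) {
      series <- scale(as_mv_series(series))
    }
  }
  if (!is.numeric(r) || length(r) != 1L || r <= 0) {
    stop("radius `r` must be a single positive number")
  }
  tr <- delay_embed(series, m, d)
  rp <- squared_dist(tr) <= r * r
  measures_from_runs(sum(rp), nrow(rp), column_run_lengths(rp), min_line)
}

# Squared Euclidean distances via the Gram matrix; clamped at 0 so that exact
# repeats cannot go slightly negative in floating point.
squared_dist <- function(tr) {
  g <- tcrossprod(tr)
  sq <- diag(g)
  d2 <- outer(sq, sq, "+") - 2 * g
  d2[d2 < 0] <- 0
  d2
}

# Coerce vector/matrix input to a numeric matrix with rows as time points.
as_mv_series <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1L)
  if (!is.numeric(x)) stop("series must be numeric")
  if (anyNA(x)) stop("series contains missing values")
  x
}

as_binary_plot <- function(rp) {
  if (!is.matrix(rp) || nrow(rp) != ncol(rp)) stop("recurrence plot must be a square matrix")
  if (is.logical(rp)) return(rp)
  if (!all(rp %in% c(0, 1))) stop("recurrence plot must be binary")
  rp == 1
}
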