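#' MdRQA embedding parameters
#'
#' Container for the parameters of a recurrence analysis: delay `d`, embedding
#' dimension `m`, radius `r`, norm and analysis level. The defaults are the
#' fixed sample-wide parameters used for IBI synchrony: delay 2, embedding
#' dimension 7 for both levels, Euclidean norm, no input normalisation, and
#' radii 0.457 (dyads) / 0.51 (triads) in seconds of the embedded space.
#'
#' @param level `"dyad"` or `"triad"` (selects the default radius).
#' @param delay Positive integer delay in samples.
#' @param dim Positive integer embedding dimension.
#' @param radius Positive radius, or `NA` to mark it as "to be calibrated"
#'   (see [calibrate_threshold()]).
#' @param norm Distance norm; only `"euclidean"` is supported.
#' @param normalize_input Should the series be z-scored before analysis?
#'   Default `FALSE` (IBI data are analysed in raw seconds).
#' @return Object of class `embedding_params`.
#' @export
embedding_params <- function(level = c("dyad", "triad"),
                             delay = 2L,
                             dim = 7L,
                             radius = NULL,
                             norm = "euclidean",
                             normalize_input = FALSE) {
  level <- match.arg(level)
  if (is.null(radius)) radius <- if (level == "dyad") 0.457 else 0.51
  delay <- as.integer(delay)
  dim <- as.integer(dim)
  if (delay < 1L) stop("delay must be >= 1")
  if (dim < 1L) stop("embedding dimension must be >= 1")
  if (!is.na(radius) && radius <= 0) stop("radius must be > 0")
  norm <- match.arg(norm, "euclidean")
  out <- list(level = level, delay = delay, dim = dim, radius = radius,
              norm = norm, normalize_input = isTRUE(normalize_input))
  class(out) <- "embedding_params"
  out
}

#' @export
print.embedding_params <- function(x, ...) {
  cat(sprintf("<embedding_params %s: d=%d m=%d r=%s norm=%s%s>\n",
              x$level, x$delay, x$dim,
              if (is.na(x$radius)) "NA (calibrate)" else format(x$radius),
              x$norm, if (x$normalize_input) " normalized" else ""))
  invisible(x)
}

#' Multivariate average mutual information by lag
#'
#' Estimates, for each lag `0..max_lag`, the mutual information between each
#' column of the series and its lag-shifted copy via an equal-width joint
#' histogram, and averages across columns. Used to pick the embedding delay as
#' the first local minimum of this curve.
#'
#' @param series Numeric matrix (`N x D`) or vector.
#' @param max_lag Largest lag examined; requires `N > max_lag + 1`.
#' @param n_bins Number of histogram bins per axis (default
#'   `ceiling(sqrt(N))`).
#' @return Numeric vector of length `max_lag + 1` (lags 0..max_lag), in nats.
#' @export
multivariate_ami <- function(series, max_lag = 50L, n_bins = NULL) {
  x <- as_mv_series(series)
  n <- nrow(x)
  max_lag <- as.integer(max_lag)
  if (n <= max_lag + 1L) stop("series too short for max_lag")
  if (is.null(n_bins)) n_bins <- ceiling(sqrt(n))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  rngs <- apply(x, 2L, range)
  if (any(rngs[2, ] - rngs[1, ] == 0)) {
    stop("constant series: mutual information undefined (zero entropy)")
  }
  # precompute bin index per column over the full series; lagged segments reuse it
  bin_idx <- vapply(seq_len(ncol(x)), function(j) {
    b <- seq(rngs[1, j], rngs[2, j], length.out = n_bins + 1L)
    findInterval(x[, j], b, rightmost.closed = TRUE, all.inside = TRUE)
  }, integer(n))
  vapply(0:max_lag, function(lag) {
    len <- n - lag
    mean(vapply(seq_len(ncol(x)), function(j) {
      hist_mi(bin_idx[seq_len(len), j], bin_idx[(1L + lag):n, j], n_bins)
    }, numeric(1)))
  }, numeric(1))
}

hist_mi <- function(ix, iy, n_bins) {
  joint <- tabulate((iy - 1L) * n_bins + ix, nbins = n_bins * n_bins)
  joint <- joint / sum(joint)
  px <- rowSums(matrix(joint, n_bins, n_bins))
  py <- colSums(matrix(joint, n_bins, n_bins))
  nz <- joint > 0
  outer_p <- as.vector(outer(px, py))
  sum(joint[nz] * log(joint[nz] / outer_p[nz]))
}

#' First local minimum of a curve
#'
#' Returns the smallest index `i >= 1` (0-based, i.e. skipping the first
#' element) such that `curve[i] <= curve[i-1]` and `curve[i] <= curve[i+1]`;
#' ties break toward the smaller lag. If no local minimum exists the index of
#' the global minimum over `i >= 1` is returned with a warning.
#'
#' @param curve Numeric vector of length at least 3, indexed from lag 0.
#' @return Positive integer lag (position in `curve` minus 1).
#' @export
first_local_minimum <- function(curve) {
  if (length(curve) < 3L) stop("curve must have length >= 3")
  for (i in 2:(length(curve) - 1L)) {
    if (curve[i] <= curve[i - 1L] && curve[i] <= curve[i + 1L]) return(i - 1L)
  }
  warning("no local minimum found; returning global minimum over lags >= 1")
  which.min(curve[-1L])
}

#' Multivariate false-nearest-neighbour fractions by dimension
#'
#' For each candidate embedding dimension `m = 1..max_dim`, finds every
#' point's nearest neighbour in the `m`-embedded multivariate space (Euclidean
#' norm, brute-force search) and classifies it as false when the extra
#' coordinates added by going to `m + 1` inflate the pair's distance beyond
#' the Kennel criteria: distance-ratio `> rtol`, or new distance larger than
#' `atol` times the attractor size (the SD of the pooled series values).
#'
#' @param series Numeric matrix (`N x D`) or vector.
#' @param delay Embedding delay `d`.
#' @param max_dim Largest dimension examined.
#' @param rtol Relative distance-increase tolerance (default 10).
#' @param atol Absolute tolerance in attractor-size units (default 2).
#' @return Numeric vector of FNN fractions in `[0, 1]`, one per dimension
#'   `1..max_dim`.
#' @export
multivariate_fnn <- function(series, delay, max_dim = 10L, rtol = 10,
                             atol = 2) {
  x <- as_mv_series(series)
  n <- nrow(x)
  delay <- as.integer(delay)
  max_dim <- as.integer(max_dim)
  if (n - max_dim * delay < 10L) {
    stop(sprintf("series too short: need length >= %d for max_dim = %d, delay = %d",
                 max_dim * delay + 10L, max_dim, delay))
  }
  r_attr <- sd(as.vector(x))
  if (r_attr == 0) stop("constant series")
  vapply(seq_len(max_dim), function(m) {
    # points that also exist in the (m+1)-embedding
    len <- n - m * delay
    tr <- delay_embed(x, m, delay)[seq_len(len), , drop = FALSE]
    extra <- x[(1L + m * delay):n, , drop = FALSE] # coordinates added at m+1
    d2 <- squared_dist(tr)
    diag(d2) <- Inf
    nn <- max.col(-d2, ties.method = "first")
    dm <- sqrt(d2[cbind(seq_len(len), nn)])
    add2 <- rowSums((extra - extra[nn, , drop = FALSE])^2)
    dm1 <- sqrt(dm^2 + add2)
    false_ratio <- ifelse(dm > 0, sqrt(add2) / dm, Inf)
    mean(false_ratio > rtol | dm1 / r_attr > atol)
  }, numeric(1))
}

#' Select the embedding dimension where the FNN curve bottoms out
#'
#' Returns the smallest dimension `m` at which either the decrease of the FNN
#' fraction from `m` to `m + 1` is at most `drop_tolerance`, or the fraction
#' itself has fallen below 0.05, whichever comes first. A curve that never
#' satisfies either rule yields its last dimension.
#'
#' @param fnn_curve Numeric vector of FNN fractions for dimensions `1..K`.
#' @param drop_tolerance Maximum decrease still considered "flat"
#'   (default 0.01).
#' @return Positive integer dimension.
#' @export
select_dimension <- function(fnn_curve, drop_tolerance = 0.01) {
  k <- length(fnn_curve)
  if (k == 0L) stop("empty FNN curve")
  eps <- 1e-9 # guards the boundary case decrease == drop_tolerance
  for (m in seq_len(k)) {
    if (fnn_curve[m] < 0.05) return(m)
    if (m < k && (fnn_curve[m] - fnn_curve[m + 1L]) <= drop_tolerance + eps) {
      return(m)
    }
  }
  k
}

#' Pool per-group embedding estimates across the sample
#'
#' Component-wise mean of the per-group (delay, dimension) estimates, rounded
#' to the nearest *higher* integer (ceiling), so every data set can be analysed
#' with one common, sufficiently large parameter pair.
#'
#' @param estimates Data frame or matrix with columns `d` and `m` (one row per
#'   group), or a list of `c(d, m)` pairs.
#' @return Named integer vector `c(d = ..., m = ...)`.
#' @export
pool_parameters <- function(estimates) {
  if (is.list(estimates) && !is.data.frame(estimates)) {
    estimates <- do.call(rbind, estimates)
  }
  estimates <- as.matrix(estimates)
  if (nrow(estimates) == 0L) stop("no estimates to pool")
  if (ncol(estimates) != 2L) stop("estimates must have two columns (d, m)")
  out <- as.integer(ceiling(colMeans(estimates)))
  names(out) <- c("d", "m")
  out
}

#' @rdname calibrate_threshold
#' @export
default_r_grid <- function() seq(0.05, 1.0, by = 0.005)

#' Calibrate the recurrence radius to the 1-5% mean recurrence band
#'
#' Computes, for every radius in an ascending grid, the mean recurrence rate
#' (%REC) across all supplied data sets at the given embedding, and returns
#' the smallest grid radius whose mean %REC lands in `[band[1], band[2]]`
#' (percent). Distances are computed once per data set, so the grid sweep is
#' cheap. Errors if no grid value lands in the band, reporting the bracketing
#' grid values.
#'
#' @param datasets List of numeric matrices (multivariate series), e.g. from
#'   all dyads or all triads of a study.
#' @param d,m Embedding delay and dimension.
#' @param r_grid Ascending numeric grid of candidate radii.
#' @param band Target band for the across-dataset mean %REC (default
#'   `c(1, 5)`).
#' @return The selected radius, with attributes `mean_rec` (achieved mean
#'   %REC) and `curve` (mean %REC over the whole grid).
#' @export
calibrate_threshold <- function(datasets, d, m, r_grid = default_r_grid(),
                                band = c(1, 5)) {
  if (!length(datasets)) stop("no datasets supplied")
  if (is.unsorted(r_grid, strictly = TRUE)) stop("r_grid must be strictly ascending")
  curves <- vapply(datasets, function(x) {
    tr <- delay_embed(x, m, d)
    n <- nrow(tr)
    dv <- sort(sqrt(squared_dist(tr)[upper.tri(matrix(0, n, n))]))
    # #pairs with distance <= r, via one pass over the sorted distances
    counts <- findInterval(r_grid, dv)
    100 * (2 * counts + n) / n^2
  }, numeric(length(r_grid)))
  mean_rec <- rowMeans(curves)
  ok <- which(mean_rec >= band[1] & mean_rec <= band[2])
  if (!length(ok)) {
    below <- max(which(mean_rec < band[1]), 0L)
    msg <- sprintf(
      "no grid radius gives mean %%REC in [%g, %g]: grid jumps from %s to %s",
      band[1], band[2],
      if (below >= 1L) sprintf("%.1f%% at r=%g", mean_rec[below], r_grid[below]) else "start",
      if (below < length(r_grid)) sprintf("%.1f%% at r=%g", mean_rec[below + 1L], r_grid[below + 1L]) else "end"
    )
    stop(msg)
  }
  r <- r_grid[ok[1L]]
  attr(r, "mean_rec") <- mean_rec[ok[1L]]
  attr(r, "curve") <- mean_rec
  r
}

#' Estimate embedding parameters for a sample of groups
#'
#' Per-group delay (first local minimum of the multivariate AMI) and dimension
#' (FNN bottoming-out) estimates, pooled across the sample by mean-then-ceiling.
#' Estimation uses task-phase data by default.
#'
#' @param groups List of `group_record`s.
#' @param level `"dyad"` or `"triad"`.
#' @param phase Phase used for estimation (default `"task"`).
#' @param max_lag,max_dim Search ranges.
#' @param ... Passed on to [multivariate_fnn()].
#' @return Named integer vector `c(d = ..., m = ...)` with attribute
#'   `per_group` (the per-dataset estimates).
#' @export
estimate_embedding <- function(groups, level = c("triad", "dyad"),
                               phase = "task", max_lag = 50L, max_dim = 10L,
                               ...) {
  level <- match.arg(level)
  datasets <- level_datasets(groups, level, phase)
  per <- t(vapply(datasets, function(x) {
    dd <- first_local_minimum(multivariate_ami(x, max_lag = max_lag))
    mm <- select_dimension(multivariate_fnn(x, delay = dd, max_dim = max_dim, ...))
    c(d = dd, m = mm)
  }, numeric(2)))
  out <- pool_parameters(per)
  attr(out, "per_group") <- per
  out
}
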