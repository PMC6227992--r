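#' Cluster-length permutation test specification
#'
#' Sample-wise paired t-statistics over 120-sample curves are thresholded at
#' the two-tailed critical value for `n - 1` degrees of freedom (2.201 for
#' the study's 12 participants at alpha 0.05); supra-threshold run lengths
#' are compared against an empirical null built by participant-wise
#' sign-flipping over `n_permutations` iterations.
#'
#' @param n_participants Number of paired participants.
#' @param alpha_samplewise Two-tailed sample-wise alpha.
#' @param n_permutations Number of permutation iterations.
#' @param seed Seed for the permutation stream.
#' @return An object of class `imk_cluster_spec` with the derived `df` and
#'   `t_crit`.
#' @export
cluster_spec <- function(n_participants = 12L, alpha_samplewise = 0.05,
                         n_permutations = 10000L, seed = 1L) {
  stopifnot(n_participants >= 3, n_permutations >= 1)
  df <- n_participants - 1L
  structure(list(n_participants = as.integer(n_participants),
                 alpha_samplewise = alpha_samplewise, df = df,
                 t_crit = stats::qt(1 - alpha_samplewise / 2, df),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "imk_cluster_spec")
}

#' Sample-wise paired t time-series
#'
#' At each of the 120 curve samples, the paired t across participants of
#' the difference between condition A and condition B participant-mean
#' curves.
#'
#' @param cellA,cellB Numeric matrices, participants x samples, same
#'   participant order.
#' @return Numeric vector of t values, one per sample.
#' @export
paired_t_series <- function(cellA, cellB) {
  cellA <- as.matrix(cellA); cellB <- as.matrix(cellB)
  if (!all(dim(cellA) == dim(cellB)))
    stop("cells must have identical dimensions", call. = FALSE)
  n <- nrow(cellA)
  if (n < 3) stop("need at least 3 participants", call. = FALSE)
  d <- cellA - cellB
  m <- colMeans(d)
  s2 <- pmax((colSums(d^2) - n * m^2) / (n - 1), 0)
  t <- m / sqrt(s2 / n)
  # zero-variance differences: t is 0 for a zero mean, +/-Inf otherwise
  degenerate <- s2 == 0
  t[degenerate] <- sign(m[degenerate]) * Inf
  t[degenerate & m == 0] <- 0
  t
}

#' Maximal supra-threshold runs of a t series
#'
#' Maximal consecutive index ranges where `|t|` strictly exceeds the
#' critical value.
#'
#' @param t_series Numeric t values.
#' @param t_crit Critical value.
#' @return Data frame with columns `start`, `end`, `length` (empty when no
#'   sample exceeds the threshold).
#' @export
find_runs <- function(t_series, t_crit) {
  if (any(is.na(t_series))) stop("t series must be finite", call. = FALSE)
  above <- abs(t_series) > t_crit
  if (!any(above))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

# maximum supra-threshold run length of each row of a matrix of |t| values
max_run_lengths <- function(tmat, t_crit) {
  apply(abs(tmat) > t_crit, 1L, function(row) {
    if (!any(row)) return(0L)
    r <- rle(row)
    max(r$lengths[r$values])
  })
}

#' Permutation null distribution of supra-threshold run lengths
#'
#' On each iteration every participant's condition labels are independently
#' flipped (sign-flip of the paired difference — the exchangeable null for a
#' paired design), the t series is recomputed exactly as for the observed
#' data, and the maximum supra-threshold run length is recorded (0 when no
#' sample exceeds the threshold). Deterministic under the spec's seed.
#'
#' @param cellA,cellB Participant x sample matrices as in
#'   [paired_t_series()].
#' @param spec An `imk_cluster_spec`.
#' @return Integer vector of `n_permutations` maximum run lengths.
#' @export
permutation_null <- function(cellA, cellB, spec) {
  d <- as.matrix(cellA) - as.matrix(cellB)
  n <- nrow(d)
  set.seed(spec$seed)
  signs <- matrix(sample(c(-1, 1), n * spec$n_permutations, replace = TRUE),
                  spec$n_permutations, n)
  null_t <- flip_t_matrix(d, signs)
  max_run_lengths(null_t, spec$t_crit)
}

# t series for every row of a sign matrix, vectorized:
# with flipped differences s_i * d_ij, (s_i d_ij)^2 = d_ij^2, so only the
# flipped means vary across permutations.
flip_t_matrix <- function(d, signs) {
  n <- nrow(d)
  m <- (signs %*% d) / n                      # permutations x samples
  ss <- matrix(colSums(d^2), nrow(signs), ncol(d), byrow = TRUE)
  s2 <- (ss - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  t <- m / sqrt(s2 / n)
  t[!is.finite(t)] <- 0
  t
}

#' Permutation p-value of an observed run
#'
#' `p = (1 + #\{null >= observed length\}) / (n_permutations + 1)` — the
#' add-one tail proportion, bounded below by `1/(n_permutations + 1)`; an
#' observed length of 0 gives p = 1.
#'
#' @param run_length Observed supra-threshold run length.
#' @param null_lengths Integer vector from [permutation_null()].
#' @return Permutation p-value.
#' @export
run_p_value <- function(run_length, null_lengths) {
  if (run_length <= 0) return(1)
  (1 + sum(null_lengths >= run_length)) / (length(null_lengths) + 1)
}

#' Cluster-length permutation test
#'
#' The full inference: observed paired t series, supra-threshold runs,
#' permutation null of maximum run lengths, and per-run p-values.
#'
#' @param cellA,cellB Participant x sample matrices.
#' @param spec An `imk_cluster_spec`; its `n_participants` must match the
#'   rows of the cells.
#' @return An object of class `imk_cluster_result`: list with `t_series`,
#'   `runs` (with a `p` column), `null_lengths`, `t_crit`.
#' @export
cluster_test <- function(cellA, cellB, spec = cluster_spec(nrow(cellA))) {
  if (spec$n_participants != nrow(as.matrix(cellA)))
    stop("spec n_participants does not match the data", call. = FALSE)
  t_series <- paired_t_series(cellA, cellB)
  runs <- find_runs(t_series, spec$t_crit)
  null_lengths <- permutation_null(cellA, cellB, spec)
  runs$p <- vapply(runs$length, run_p_value, numeric(1),
                   null_lengths = null_lengths)
  structure(list(t_series = t_series, runs = runs,
                 null_lengths = null_lengths, t_crit = spec$t_crit),
            class = "imk_cluster_result")
}

#' @export
print.imk_cluster_result <- function(x, ...) {
  cat(sprintf("<imk_cluster_result> %d supra-threshold run(s), |t| > %.3f\n",
              nrow(x$runs), x$t_crit))
  if (nrow(x$runs)) print(x$runs)
  invisible(x)
}

#' Plot a t-statistic time-series with its critical bounds
#'
#' Base-graphics plot of the sample-wise paired t series with horizontal
#' lines at plus/minus the critical value and supra-threshold runs shaded.
#'
#' @param x An `imk_cluster_result`.
#' @param ... Passed to [plot()].
#' @export
plot.imk_cluster_result <- function(x, ...) {
  graphics::plot(x$t_series, type = "l", xlab = "resampled time (samples)",
                 ylab = "paired t", ...)
  graphics::abline(h = c(-x$t_crit, x$t_crit), lty = 2)
  if (nrow(x$runs))
    for (i in seq_len(nrow(x$runs)))
      graphics::rect(x$runs$start[i], graphics::par("usr")[3],
                     x$runs$end[i], graphics::par("usr")[4],
                     col = grDevices::adjustcolor("red", 0.15), border = NA)
  invisible(x)
}

#' Label a run's overlap with the peak-kinematic phases
#'
#' Partitions the grand-mean resampled curve into an acceleration phase, the
#' period covering peak velocity (the contiguous samples within
#' `plateau_frac` of the curve maximum), and a deceleration phase. A run is
#' labelled with every phase it intersects.
#'
#' @param run A row of a runs data frame (`start`, `end`).
#' @param grand_mean_curve Numeric 120-sample mean curve.
#' @param plateau_frac Fraction of the maximum defining the PV period
#'   (default 0.9: samples within 10% of the peak).
#' @return Character vector among `"acceleration"`, `"PV"`,
#'   `"deceleration"`.
#' @export
overlap_with_peaks <- function(run, grand_mean_curve, plateau_frac = 0.9) {
  top <- which(grand_mean_curve >= plateau_frac * max(grand_mean_curve))
  pk <- which.max(grand_mean_curve)
  # contiguous plateau containing the argmax
  lo <- top[1]; hi <- top[length(top)]
  if (any(diff(top) != 1)) {
    runs_top <- split(top, cumsum(c(TRUE, diff(top) != 1)))
    blk <- runs_top[[which(vapply(runs_top, function(b) pk %in% b,
                                  logical(1)))[1]]]
    lo <- blk[1]; hi <- blk[length(blk)]
  }
  labs <- character(0)
  if (run$start < lo) labs <- c(labs, "acceleration")
  if (run$start <= hi && run$end >= lo) labs <- c(labs, "PV")
  if (run$end > hi) labs <- c(labs, "deceleration")
  labs
}
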