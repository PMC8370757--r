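# Between-replicate kinetic heterogeneity: replicate curves interpolated
# onto a common grid, the coefficient-of-variation (SD over mean) profile,
# and the two-sample t-test used for condition contrasts.

#' Align replicate time series onto a common grid
#'
#' Linear interpolation of each replicate onto the grid points falling inside
#' the replicates' overlapping time span; no extrapolation is performed.
#'
#' @param series_list list of data.frames with columns `time` and `value`
#'   (a `rheology_trace` or a speed-profile table can be passed after
#'   renaming), at least two.
#' @param grid numeric vector of target times.
#' @return numeric matrix, one row per replicate, one column per retained
#'   grid point; grid times in the `"time"` attribute.
#' @export
align_replicates <- function(series_list, grid) {
  if (length(series_list) < 2L)
    stop("need at least two replicates", call. = FALSE)
  series_list <- lapply(series_list, function(d) {
    d <- as.data.frame(d)
    stopifnot(all(c("time", "value") %in% names(d)))
    d[order(d$time), ]
  })
  lo <- max(vapply(series_list, function(d) min(d$time), numeric(1)))
  hi <- min(vapply(series_list, function(d) max(d$time), numeric(1)))
  if (lo > hi) stop("replicate time spans are disjoint", call. = FALSE)
  keep <- grid >= lo & grid <= hi
  if (!any(keep)) stop("no grid points inside the overlapping span",
                       call. = FALSE)
  g <- grid[keep]
  m <- t(vapply(series_list, function(d)
    approx(d$time, d$value, xout = g)$y, numeric(length(g))))
  attr(m, "time") <- g
  m
}

#' Coefficient-of-variation profile across replicates
#'
#' Per-column sample statistics over the replicate matrix: mean, sample SD
#' (n - 1 denominator, appropriate for the 3-6 replicates typical here) and
#' CoV = SD/mean. Columns whose |mean| falls below `mean_floor` are masked:
#' CoV is numerically unstable where the measured quantity is near zero, and
#' masked points are excluded from the summaries.
#'
#' @param mat replicate-by-time matrix, e.g. from [align_replicates()].
#' @param mean_floor absolute mean below which a column is masked; default
#'   5% of the global maximum of `mat`.
#' @param cov_threshold level defining the "high heterogeneity" time span
#'   summary.
#' @return a `heterogeneity_profile`: list with `profile` (data.frame `time`,
#'   `mean`, `sd`, `cov`, `masked`), `max_cov`, `time_span_above` (hours/
#'   units of the grid with CoV above `cov_threshold`).
#' @export
cov_profile <- function(mat, mean_floor = NULL, cov_threshold = 0.5) {
  if (is.null(dim(mat)) || nrow(mat) < 2L)
    stop("need at least two replicates", call. = FALSE)
  tt <- attr(mat, "time") %||% seq_len(ncol(mat))
  mean_floor <- mean_floor %||% (0.05 * max(abs(mat)))
  mu <- colMeans(mat)
  sdv <- apply(mat, 2, sd)
  masked <- abs(mu) < mean_floor
  cv <- ifelse(masked, NA_real_, sdv / mu)
  prof <- data.frame(time = tt, mean = mu, sd = sdv, cov = cv,
                     masked = masked)
  rownames(prof) <- NULL
  ok <- !masked & is.finite(cv)
  dt <- if (length(tt) > 1) median(diff(tt)) else 1
  structure(list(profile = prof,
                 max_cov = if (any(ok)) max(cv[ok]) else NA_real_,
                 time_span_above = sum(ok & cv > cov_threshold) * dt,
                 mean_floor = mean_floor,
                 cov_threshold = cov_threshold),
            class = "heterogeneity_profile")
}

#' Two-sample t-test (Welch or pooled)
#'
#' A thin, convention-fixing wrapper around [stats::t.test()]: Welch by
#' default, pooled variance on request, always two-sided. The degenerate
#' case of two zero-variance samples with equal means returns p = 1 (t = 0)
#' with a flag instead of erroring; with different means it returns p = 0
#' (infinite t), flagged.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param variant `"welch"` or `"pooled"`.
#' @return list `t`, `df`, `p`, `variant`, `flag`.
#' @export
two_sample_t <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (sd(a) == 0 && sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2,
                p = if (eq) 1 else 0,
                variant = variant, flag = "zero-variance"))
  }
  ht <- t.test(a, b, var.equal = (variant == "pooled"),
               alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, variant = variant, flag = NA_character_)
}
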