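# Hydrogelation kinetics from oscillatory rheology: lag time, growth rate,
# plateau and tan delta from time sweeps; the gel criterion (G' > G'' with
# frequency-independent moduli) from frequency sweeps.

# Centered moving average; width in hours converted to an odd point count.
smooth_ma <- function(y, dt, width_h) {
  k <- max(1L, round(width_h / dt))
  if (k %% 2 == 0) k <- k + 1L
  if (k <= 1) return(y)
  half <- (k - 1L) %/% 2L
  n <- length(y)
  out <- numeric(n)
  cs <- cumsum(c(0, y))
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

# Lag / rate / plateau for one modulus channel. Returns NAs and ok = FALSE
# for a never-rising channel.
extract_channel <- function(tt, y, baseline_window, smooth_width, mad_mult,
                            lag_persistence) {
  dt <- tt[2] - tt[1]
  n_base_max <- max(5L, sum(tt <= tt[1] + baseline_window))
  ys <- smooth_ma(y, dt, smooth_width)

  # provisional baseline/threshold over an adaptive initial stretch: the
  # stretch with minimal MAD, so a lag shorter than the declared window
  # (which would contaminate the window with rise points and inflate the
  # MAD) still yields a clean baseline
  cand <- unique(pmin(n_base_max, c(5L, 7L, 10L, 15L, n_base_max)))
  mads <- vapply(cand, function(n) mad(y[seq_len(n)]), numeric(1))
  n_base <- cand[max(which(mads <= min(mads) + 1e-12))]
  base0 <- median(y[seq_len(n_base)])
  mad0 <- mad(y[seq_len(n_base)])
  eps <- 1e-9 + 1e-6 * max(diff(range(y)), 0)
  thr <- base0 + max(mad_mult * mad0, eps)
  need <- max(1L, round(lag_persistence / dt))
  above <- y > thr
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  cross <- NA_integer_
  for (r in seq_along(run$values)) {
    if (run$values[r] && (run$lengths[r] >= need || ends[r] == length(y))) {
      cross <- starts[r]; break
    }
  }
  if (is.na(cross))
    return(list(ok = FALSE, lag = NA_real_, rate = NA_real_,
                plateau = NA_real_, plateau_onset = NA_real_,
                plateau_idx = integer(), baseline = base0))

  base <- base0

  # plateau scale from the record tail, then the central 15-85% of the rise
  plat0 <- mean(y[tt >= tt[length(tt)] - max(2 * smooth_width, 10 * dt)])
  lo_lvl <- base + 0.15 * (plat0 - base)
  hi_lvl <- base + 0.85 * (plat0 - base)
  i_lo <- which(ys >= lo_lvl)[1]
  i_hi <- which(ys >= hi_lvl)[1]
  if (is.na(i_lo)) i_lo <- cross
  if (is.na(i_hi)) i_hi <- length(y)
  if (i_hi - i_lo < 1L) {           # step-like rise: use the bracketing pair
    i_lo <- max(1L, i_hi - 1L)
  }
  fit <- lm(y[i_lo:i_hi] ~ tt[i_lo:i_hi])
  rate <- unname(coef(fit)[2])
  if (!is.finite(rate) || rate <= 0)
    return(list(ok = FALSE, lag = NA_real_, rate = NA_real_,
                plateau = NA_real_, plateau_onset = NA_real_,
                plateau_idx = integer(), baseline = base))

  # lag: rise line back-projected onto the baseline level, bounded by the
  # threshold crossing; the baseline is then re-estimated over the pre-lag
  # points (a longer, still uncontaminated stretch) and the back-projection
  # repeated once
  lag <- unname((base - coef(fit)[1]) / rate)
  lag <- min(max(lag, tt[1]), tt[cross])
  pre <- which(tt <= lag)
  if (length(pre) >= 5L) {
    base <- median(y[pre])
    lag <- min(max(unname((base - coef(fit)[1]) / rate), tt[1]), tt[cross])
  }

  # plateau: trailing region of near-zero smoothed derivative
  dy <- c(diff(ys) / dt, 0)
  flat <- abs(dy) < 0.05 * rate
  i <- length(y)
  while (i > 1L && flat[i - 1L]) i <- i - 1L
  plateau_idx <- i:length(y)
  if (length(plateau_idx) < 2L) plateau_idx <- (length(y) - 1L):length(y)
  plateau <- mean(y[plateau_idx])

  # plateau onset: first sustained entry into +/-5% of the plateau
  tol <- 0.05 * max(plateau - base, eps)
  inband <- ys >= plateau - tol
  rb <- rle(inband)
  ends_b <- cumsum(rb$lengths); starts_b <- ends_b - rb$lengths + 1L
  onset_i <- NA_integer_
  for (r in seq_along(rb$values)) {
    if (rb$values[r] && ends_b[r] == length(y)) { onset_i <- starts_b[r]; break }
  }
  plateau_onset <- if (is.na(onset_i)) tt[plateau_idx[1]] else tt[onset_i]

  list(ok = TRUE, lag = lag, rate = rate, plateau = plateau,
       plateau_onset = max(plateau_onset, lag + dt), plateau_idx = plateau_idx,
       baseline = base)
}

#' Extract hydrogelation features from a rheology time sweep
#'
#' The lag time is located by a threshold-persistence rule (first sustained
#' exceedance of baseline + `mad_mult` x MAD for at least `lag_persistence`
#' hours) and then refined by back-projecting a least-squares fit of the
#' central rise (15-85% of the baseline-to-plateau span, located on a
#' centered moving average of width `smooth_width`) onto the baseline level.
#' The rate is that fit's slope; the plateau is the mean over the trailing
#' segment where the smoothed derivative is below 5% of the rate. A trace
#' that never rises is flagged (`regime = "none"`) rather than reported as
#' zeros.
#'
#' @param trace a `rheology_trace` (see [simulate_rheology_trace()]), or a
#'   data.frame with `time_h`, `g_prime_pa`, `g_double_prime_pa`.
#' @param baseline_window initial span used for the provisional baseline,
#'   hours.
#' @param smooth_width centered moving-average width, hours.
#' @param mad_mult MAD multiplier of the lag threshold.
#' @param lag_persistence minimum sustained exceedance, hours.
#' @return a `gelation_features` list: `lag_h`, `rate_gp_pa_h`,
#'   `rate_gpp_pa_h`, `plateau_gp_pa`, `plateau_onset_h`,
#'   `tan_delta_at_plateau`, `regime`.
#' @export
extract_gelation_features <- function(trace, baseline_window = 1,
                                      smooth_width = 0.5, mad_mult = 5,
                                      lag_persistence = 0.25) {
  df <- as.data.frame(trace)
  stopifnot(all(c("time_h", "g_prime_pa", "g_double_prime_pa") %in% names(df)))
  tt <- df$time_h
  if (length(tt) < 5L) stop("trace too short", call. = FALSE)
  if (max(tt) - min(tt) <= baseline_window)
    stop("trace must span more than the baseline window", call. = FALSE)
  gp <- extract_channel(tt, df$g_prime_pa, baseline_window, smooth_width,
                        mad_mult, lag_persistence)
  gpp <- extract_channel(tt, df$g_double_prime_pa, baseline_window,
                         smooth_width, mad_mult, lag_persistence)
  feats <- list(
    lag_h = gp$lag,
    rate_gp_pa_h = gp$rate,
    rate_gpp_pa_h = gpp$rate,
    plateau_gp_pa = gp$plateau,
    plateau_onset_h = gp$plateau_onset,
    tan_delta_at_plateau = if (gp$ok)
      mean(df$g_double_prime_pa[gp$plateau_idx] /
             df$g_prime_pa[gp$plateau_idx]) else NA_real_,
    regime = if (!gp$ok) "none" else NA_character_)
  if (gp$ok) feats$regime <- classify_regime(feats$rate_gp_pa_h)
  class(feats) <- "gelation_features"
  feats
}

#' Classify the kinetic regime from the G' growth rate
#'
#' Boundaries default to 0.45 and 2.0 Pa/h, induced from the observed regime
#' rates (slow 0.28-0.36, intermediate 0.50-1.12, fast 4.7 Pa/h); both are
#' configurable.
#'
#' @param features a `gelation_features`, or a single numeric rate in Pa/h.
#' @param boundaries slow/intermediate and intermediate/fast cuts, Pa/h.
#' @return one of `"slow"`, `"intermediate"`, `"fast"`, `"none"`.
#' @export
classify_regime <- function(features, boundaries = c(0.45, 2.0)) {
  rate <- if (inherits(features, "gelation_features"))
    features$rate_gp_pa_h else features
  if (inherits(features, "gelation_features") &&
      identical(features$regime, "none")) return("none")
  if (is.null(rate) || is.na(rate)) return("none")
  stopifnot(length(boundaries) == 2L, boundaries[1] < boundaries[2])
  if (rate < boundaries[1]) "slow"
  else if (rate <= boundaries[2]) "intermediate"
  else "fast"
}

#' Frequency sweep constructor
#'
#' @param omega_rad_s angular frequencies, strictly increasing.
#' @param g_prime_pa,g_double_prime_pa moduli at each frequency.
#' @return a `frequency_sweep` data.frame.
#' @export
frequency_sweep <- function(omega_rad_s, g_prime_pa, g_double_prime_pa) {
  if (is.unsorted(omega_rad_s, strictly = TRUE))
    stop("omega must be strictly increasing", call. = FALSE)
  structure(data.frame(omega_rad_s = omega_rad_s, g_prime_pa = g_prime_pa,
                       g_double_prime_pa = g_double_prime_pa),
            class = c("frequency_sweep", "data.frame"))
}

#' Gel-state verdict from a frequency sweep
#'
#' A system is scored as a gel when the storage modulus dominates the loss
#' modulus at every frequency tested (tan delta < 1 throughout) and G' is
#' frequency independent: the slope of log G' versus log omega is below
#' `slope_tol` in magnitude.
#'
#' @param sweep a `frequency_sweep` with at least 3 frequency points.
#' @param slope_tol allowed |d log G' / d log omega|.
#' @return list `gel` (logical), `tan_delta_mean`, `tan_delta_max`,
#'   `loglog_slope`.
#' @export
assess_gel_state <- function(sweep, slope_tol = 0.1) {
  df <- as.data.frame(sweep)
  stopifnot(all(c("omega_rad_s", "g_prime_pa", "g_double_prime_pa") %in%
                  names(df)))
  if (nrow(df) < 3L) stop("need at least 3 frequency points", call. = FALSE)
  if (any(df$g_prime_pa <= 0) || any(df$g_double_prime_pa <= 0))
    stop("moduli must be positive", call. = FALSE)
  tan_d <- df$g_double_prime_pa / df$g_prime_pa
  slope <- unname(coef(lm(log(df$g_prime_pa) ~ log(df$omega_rad_s)))[2])
  list(gel = all(df$g_prime_pa > df$g_double_prime_pa) &&
         abs(slope) < slope_tol,
       tan_delta_mean = mean(tan_d), tan_delta_max = max(tan_d),
       loglog_slope = slope)
}
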