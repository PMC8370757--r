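# Particle detection, trajectory linking, flow-subtracted speeds and the
# mobility-arrest estimate of the gelation time.
#
# The paper's pipeline for this stage used commercial tracking software; here
# the equivalent steps are implemented directly so the whole chain is open
# and testable: intensity-weighted sub-pixel centroids over thresholded local
# maxima, greedy mutual-nearest-neighbour frame-to-frame linking, global
# mean-flow subtraction, and a threshold-persistence rule for the end of
# aggregate mobility.

#' Detect particles in an image stack
#'
#' Thresholded 3x3 local maxima refined to sub-pixel accuracy by an
#' intensity-weighted centroid over a window of +/- 2 spot sigma; detections
#' closer than one spot sigma are merged (averaged).
#'
#' @param stack an `image_stack` (see [render_image_stack()]).
#' @param min_intensity absolute intensity threshold on the 0..1 scale.
#' @param spot_sigma_px expected spot sd in pixels (sets the centroid window
#'   and the duplicate-merge radius).
#' @return data.frame `frame`, `time_h`, `x_um`, `y_um`, `intensity`. Frames
#'   with no detections contribute no rows (a valid outcome); an empty stack
#'   is an error.
#' @export
detect_particles <- function(stack, min_intensity = 0.25, spot_sigma_px = 2) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack) == 0L) stop("empty image stack", call. = FALSE)
  px <- attr(stack, "pixel_size_um")
  dt <- attr(stack, "frame_interval")
  w <- ceiling(2 * spot_sigma_px)
  out <- vector("list", length(stack))
  for (f in seq_along(stack)) {
    m <- stack[[f]]
    ny <- nrow(m); nx <- ncol(m)
    if (ny < 3 || nx < 3) stop("frames must be at least 3x3", call. = FALSE)
    core <- m[2:(ny - 1), 2:(nx - 1)]
    is_max <- core >= min_intensity
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      is_max <- is_max & core >= m[2:(ny - 1) + di, 2:(nx - 1) + dj]
    }
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    bg <- median(m)
    peaks <- cbind(idx[, 1] + 1L, idx[, 2] + 1L)
    cx <- numeric(nrow(peaks)); cy <- numeric(nrow(peaks))
    ival <- numeric(nrow(peaks))
    for (k in seq_len(nrow(peaks))) {
      ic <- peaks[k, 1]; jc <- peaks[k, 2]
      is <- max(1L, ic - w):min(ny, ic + w)
      js <- max(1L, jc - w):min(nx, jc + w)
      wts <- pmax(m[is, js] - bg, 0)
      s <- sum(wts)
      if (s <= 0) { cx[k] <- NA; next }
      cx[k] <- sum(t(wts) * (js - 0.5)) / s   # pixel units, origin at corner
      cy[k] <- sum(wts * (is - 0.5)) / s
      ival[k] <- m[ic, jc]
    }
    ok <- !is.na(cx)
    cx <- cx[ok]; cy <- cy[ok]; ival <- ival[ok]
    if (!length(cx)) next
    # merge duplicates within one spot sigma (plateaued maxima)
    keep <- rep(TRUE, length(cx))
    for (k in seq_along(cx)) {
      if (!keep[k]) next
      close <- which(keep & sqrt((cx - cx[k])^2 + (cy - cy[k])^2) <=
                       spot_sigma_px)
      if (length(close) > 1L) {
        cx[k] <- mean(cx[close]); cy[k] <- mean(cy[close])
        ival[k] <- max(ival[close])
        keep[setdiff(close, k)] <- FALSE
      }
    }
    out[[f]] <- data.frame(frame = f - 1L,
                           time_h = (f - 1L) * dt / 60,
                           x_um = cx[keep] * px, y_um = cy[keep] * px,
                           intensity = ival[keep])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(), time_h = numeric(),
                      x_um = numeric(), y_um = numeric(),
                      intensity = numeric())
  attr(res, "frame_interval") <- dt
  attr(res, "field_size") <- attr(stack, "field_size")
  res
}

#' Link detections into trajectories
#'
#' Greedy mutual-nearest-neighbour linking: in each frame, a detection and an
#' active track are linked when each is the other's nearest admissible
#' candidate (distance at most `max_disp` per elapsed frame); rounds repeat
#' among the unlinked until no mutual pair remains. Tracks may bridge up to
#' `gap_frames` missed frames; unlinked detections start new trajectories.
#'
#' @param detections data.frame with `frame`, `x_um`, `y_um` (as returned by
#'   [detect_particles()]), sorted by frame.
#' @param max_disp maximum displacement per frame step, um; must be positive.
#' @param gap_frames number of missed frames a track may bridge.
#' @param frame_interval minutes per frame (taken from `detections` if
#'   attached).
#' @param field_size field extent, um (taken from `detections` if attached).
#' @return a `replicate_series` whose trajectory table carries the assigned
#'   `particle_id`.
#' @export
link_trajectories <- function(detections, max_disp, gap_frames = 0,
                              frame_interval = NULL, field_size = NULL) {
  check_number(max_disp, "max_disp", positive = TRUE)
  frame_interval <- frame_interval %||% attr(detections, "frame_interval")
  field_size <- field_size %||% attr(detections, "field_size")
  if (is.null(frame_interval))
    stop("frame_interval not given and not attached to detections",
         call. = FALSE)
  det <- as.data.frame(detections)
  det <- det[order(det$frame), , drop = FALSE]
  det$particle_id <- NA_integer_
  track_last <- data.frame(id = integer(), frame = integer(),
                           x = numeric(), y = numeric())
  next_id <- 1L
  for (f in sort(unique(det$frame))) {
    rows <- which(det$frame == f)
    cand <- track_last[f - track_last$frame <= 1L + gap_frames, , drop = FALSE]
    unlinked <- rows
    if (nrow(cand)) {
      free_tracks <- seq_len(nrow(cand))
      repeat {
        if (!length(unlinked) || !length(free_tracks)) break
        dx <- outer(cand$x[free_tracks], det$x_um[unlinked], "-")
        dy <- outer(cand$y[free_tracks], det$y_um[unlinked], "-")
        dd <- sqrt(dx^2 + dy^2)
        lim <- max_disp * (f - cand$frame[free_tracks])
        dd[dd > lim] <- Inf
        if (!any(is.finite(dd))) break
        # mutual nearest neighbours among the remaining candidates
        best_det <- apply(dd, 1, which.min)     # per track
        best_trk <- apply(dd, 2, which.min)     # per detection
        took_t <- integer(); took_d <- integer()
        for (ti in seq_along(free_tracks)) {
          di <- best_det[ti]
          if (is.finite(dd[ti, di]) && best_trk[di] == ti) {
            trk_row <- free_tracks[ti]
            det_row <- unlinked[di]
            det$particle_id[det_row] <- cand$id[trk_row]
            track_last[track_last$id == cand$id[trk_row],
                       c("frame", "x", "y")] <-
              list(f, det$x_um[det_row], det$y_um[det_row])
            took_t <- c(took_t, ti); took_d <- c(took_d, di)
          }
        }
        if (!length(took_t)) break
        unlinked <- unlinked[-took_d]
        free_tracks <- free_tracks[-took_t]
      }
    }
    for (r in unlinked) {
      det$particle_id[r] <- next_id
      track_last <- rbind(track_last,
                          data.frame(id = next_id, frame = f,
                                     x = det$x_um[r], y = det$y_um[r]))
      next_id <- next_id + 1L
    }
  }
  traj <- det[order(det$particle_id, det$frame), , drop = FALSE]
  if (is.null(traj$time_h)) traj$time_h <- traj$frame * frame_interval / 60
  if (is.null(traj$z_um)) traj$z_um <- 0
  rownames(traj) <- NULL
  new_replicate_series(
    traj[, c("frame", "time_h", "particle_id", "x_um", "y_um", "z_um",
             intersect("intensity", names(traj)))],
    frame_interval,
    field_size %||% c(max(traj$x_um), max(traj$y_um)),
    max(traj$time_h), "linked")
}

#' Flow-subtracted speed profile of a replicate
#'
#' For every consecutive frame pair the mean flow is the arithmetic mean
#' displacement vector of the particles present in both frames; each
#' particle's flow-subtracted speed is the magnitude of its residual
#' displacement divided by the frame interval. The replicate time course is
#' the per-pair mean of those speeds, timestamped at the pair midpoint.
#' Frame pairs sharing no particle are kept as masked (`NA`) rows.
#'
#' @param series a `replicate_series`.
#' @return a `speed_profile`: list with `profile` (per-pair data.frame:
#'   `frame_a`, `time_h`, `n_shared`, `flow_x_um_min`, `flow_y_um_min`,
#'   `mean_speed_um_min`) and `speeds` (per-particle long table).
#' @export
compute_speed_profile <- function(series) {
  stopifnot(inherits(series, "replicate_series"))
  tr <- series$trajectories
  dt <- series$frame_interval
  spans <- tapply(tr$frame, tr$particle_id, function(f) length(f) >= 2L)
  if (!length(spans) || !any(unlist(spans)))
    stop("need at least one trajectory spanning two frames", call. = FALSE)
  frames <- min(tr$frame):max(tr$frame)
  by_frame <- split(tr[, c("particle_id", "x_um", "y_um")], tr$frame)
  prof <- vector("list", length(frames) - 1L)
  spd <- vector("list", length(frames) - 1L)
  for (i in seq_len(length(frames) - 1L)) {
    fa <- as.character(frames[i]); fb <- as.character(frames[i + 1L])
    a <- by_frame[[fa]]; b <- by_frame[[fb]]
    shared <- if (!is.null(a) && !is.null(b))
      intersect(a$particle_id, b$particle_id) else integer()
    t_mid <- pair_time_h(frames[i], dt)
    if (length(shared) < 1L) {
      prof[[i]] <- data.frame(frame_a = frames[i], time_h = t_mid,
                              n_shared = 0L, flow_x_um_min = NA_real_,
                              flow_y_um_min = NA_real_,
                              mean_speed_um_min = NA_real_)
      next
    }
    ia <- match(shared, a$particle_id); ib <- match(shared, b$particle_id)
    ddx <- b$x_um[ib] - a$x_um[ia]
    ddy <- b$y_um[ib] - a$y_um[ia]
    fx <- mean(ddx); fy <- mean(ddy)
    sp <- sqrt((ddx - fx)^2 + (ddy - fy)^2) / dt
    prof[[i]] <- data.frame(frame_a = frames[i], time_h = t_mid,
                            n_shared = length(shared),
                            flow_x_um_min = fx / dt, flow_y_um_min = fy / dt,
                            mean_speed_um_min = mean(sp))
    spd[[i]] <- data.frame(frame_a = frames[i], time_h = t_mid,
                           particle_id = shared, speed_um_min = sp)
  }
  structure(list(profile = do.call(rbind, prof),
                 speeds = do.call(rbind, spd),
                 frame_interval = dt,
                 replicate_id = series$replicate_id),
            class = "speed_profile")
}

#' Estimate the gelation time as the end of aggregate mobility
#'
#' The gelation time is the earliest profile time at which the replicate mean
#' flow-subtracted speed has fallen to or below an adaptive threshold and
#' stays there for the rest of the record, with at least `persistence_h`
#' hours of quiescent record as evidence. The threshold is
#' `threshold_frac` times the 90th percentile of the mean speed over the
#' first quarter of the record, floored at `noise_floor`.
#'
#' @param profile a `speed_profile`.
#' @param threshold_frac fraction of the early-mobility scale; default 0.1.
#' @param persistence_h minimum quiescent span required, hours.
#' @param noise_floor absolute lower bound on the threshold, um/min.
#' @return a `gelation_estimate`: list with `gelled` (logical),
#'   `gelation_time_h` (`NA` when not gelled; 0 when mobility was never
#'   observed), `threshold_um_min` and `mobility_duration_h` (alias of the
#'   gelation time).
#' @export
estimate_gelation_time <- function(profile, threshold_frac = 0.1,
                                   persistence_h = 0.5, noise_floor = 0.05) {
  stopifnot(inherits(profile, "speed_profile"))
  p <- profile$profile
  if (nrow(p) == 0L) stop("empty speed profile", call. = FALSE)
  span <- max(p$time_h) - min(p$time_h)
  if (span < persistence_h)
    stop("record shorter than the persistence window", call. = FALSE)
  early <- p$time_h <= min(p$time_h) + 0.25 * span
  scale90 <- quantile(p$mean_speed_um_min[early], 0.9, na.rm = TRUE,
                      names = FALSE)
  if (!is.finite(scale90)) scale90 <- 0
  thr <- max(threshold_frac * scale90, noise_floor)
  # small relative guard so exact threshold equality is not lost to rounding
  below <- is.na(p$mean_speed_um_min) |
    p$mean_speed_um_min <= thr * (1 + 1e-9)
  res <- list(gelled = FALSE, gelation_time_h = NA_real_,
              threshold_um_min = thr, mobility_duration_h = NA_real_)
  last_above <- if (any(!below)) max(which(!below)) else 0L
  if (last_above >= nrow(p)) {
    class(res) <- "gelation_estimate"
    return(res)
  }
  i0 <- last_above + 1L
  t0 <- if (last_above == 0L) 0 else p$time_h[i0]
  if (max(p$time_h) - p$time_h[i0] < persistence_h) {
    class(res) <- "gelation_estimate"
    return(res)
  }
  res$gelled <- TRUE
  res$gelation_time_h <- t0
  res$mobility_duration_h <- t0
  class(res) <- "gelation_estimate"
  res
}

#' @export
print.gelation_estimate <- function(x, ...) {
  if (x$gelled)
    cat(sprintf("<gelation_estimate> gelled at %.3f h (threshold %.3g um/min)\n",
                x$gelation_time_h, x$threshold_um_min))
  else
    cat(sprintf("<gelation_estimate> not gelled (threshold %.3g um/min)\n",
                x$threshold_um_min))
  invisible(x)
}
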