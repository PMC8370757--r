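# Synthetic particle-field and rheology generator with known ground truth.
#
# The generator emulates what time-lapse confocal imaging of a
# phase-separating amyloid system shows at the air-water interface (AWI):
# aggregates accumulate over time, members of an aggregate cluster share a
# local flow (a common drift) plus independent localisation jitter, scheduled
# cluster pairs drift into contact and progressively unify their motion
# (fusion), and the whole field undergoes progressive mobility arrest
# (hydrogelation) at a configurable time.  Every stochastic draw is governed
# by a single seed, so equal seeds give bit-identical output.

#' Configuration for a synthetic particle-field simulation
#'
#' Collects and validates all parameters of [simulate_particle_field()].
#' Units follow imaging conventions: the field is in micrometres, frame
#' interval in minutes, durations and gelation time in hours.
#'
#' @param seed integer seed; equal seeds give bit-identical simulations.
#' @param duration record length in hours.
#' @param frame_interval time between frames in minutes. 3 min resolves
#'   gelation-scale runs; 0.2 min resolves fusion events of ~1 min.
#' @param field_size field extent in micrometres, `c(x, y)`. The default
#'   matches a 1417 x 1417 um^2 confocal field of view.
#' @param n_clusters number of aggregate clusters seeded at t = 0.
#' @param n_initial aggregates per cluster at t = 0.
#' @param nucleation_rate new aggregates per cluster per hour (Poisson);
#'   accumulation stops at the gelation time.
#' @param flow_amplitude magnitude of each cluster's local flow, um/min.
#' @param jitter_sd per-frame, per-axis Gaussian localisation jitter, um.
#' @param gelation_time time of complete mobility arrest, hours. May be `Inf`
#'   for a never-gelling record; finite values must lie in `[0, duration]`.
#' @param arrest_ramp width of the linear speed ramp down to zero, hours.
#'   Arrest is progressive: speeds scale by `(gelation_time - t)/arrest_ramp`
#'   over the ramp and are exactly zero from `gelation_time` on.
#' @param fusion_schedule `NULL` or a data.frame with columns `cluster_a`,
#'   `cluster_b`, `onset_min`, `duration_min`. Each scheduled pair is placed
#'   on converging paths that reach contact distance at `onset_min`; the
#'   contact aggregate adopts the partner's flow at onset and the remainder
#'   of the cluster at `onset_min + duration_min`. Pairs must be disjoint and
#'   onsets strictly increasing.
#' @param regime_mixture probability that an associated kinetic parameter set
#'   is drawn from the 'fast' regime (used by [simulate_regime_ensemble()]).
#' @param cluster_radius radius of the disc on which cluster members are
#'   placed, um.
#' @param contact_distance centre-to-centre distance of a fusing pair at
#'   onset, um.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              duration = 7,
                              frame_interval = 3,
                              field_size = c(1417, 1417),
                              n_clusters = 5,
                              n_initial = 4,
                              nucleation_rate = 2,
                              flow_amplitude = 3,
                              jitter_sd = 0.3,
                              gelation_time = 4.29,
                              arrest_ramp = 0.25,
                              fusion_schedule = NULL,
                              regime_mixture = 0.5,
                              cluster_radius = 40,
                              contact_distance = 60) {
  check_number(duration, "duration", positive = TRUE)
  check_number(frame_interval, "frame_interval", positive = TRUE)
  stopifnot(length(field_size) == 2L, all(field_size > 0))
  check_number(n_clusters, "n_clusters", nonneg = TRUE)
  check_number(n_initial, "n_initial", positive = TRUE)
  check_number(nucleation_rate, "nucleation_rate", nonneg = TRUE)
  check_number(flow_amplitude, "flow_amplitude", nonneg = TRUE)
  check_number(jitter_sd, "jitter_sd", nonneg = TRUE)
  check_number(gelation_time, "gelation_time", nonneg = TRUE, finite = FALSE)
  if (is.finite(gelation_time) && gelation_time > duration)
    stop("gelation_time must lie within [0, duration] (or be Inf)",
         call. = FALSE)
  check_number(arrest_ramp, "arrest_ramp", nonneg = TRUE)
  if (regime_mixture < 0 || regime_mixture > 1)
    stop("regime_mixture must be a probability in [0, 1]", call. = FALSE)

  if (!is.null(fusion_schedule)) {
    fs <- as.data.frame(fusion_schedule)
    need <- c("cluster_a", "cluster_b", "onset_min", "duration_min")
    if (!all(need %in% names(fs)))
      stop("fusion_schedule needs columns ",
           paste(need, collapse = ", "), call. = FALSE)
    ids <- c(fs$cluster_a, fs$cluster_b)
    if (any(ids < 1 | ids > n_clusters | ids != round(ids)))
      stop("fusion_schedule names unknown clusters", call. = FALSE)
    if (anyDuplicated(ids))
      stop("fusion_schedule pairs must be disjoint (one fusion per cluster)",
           call. = FALSE)
    if (any(fs$cluster_a == fs$cluster_b))
      stop("a cluster cannot fuse with itself", call. = FALSE)
    if (is.unsorted(fs$onset_min, strictly = TRUE))
      stop("fusion onsets must be strictly increasing", call. = FALSE)
    if (any(fs$onset_min < 0) || any(fs$duration_min <= 0))
      stop("fusion onsets must be >= 0 and durations > 0", call. = FALSE)
    if (any(fs$onset_min + fs$duration_min > duration * 60))
      stop("fusion events must complete within the record", call. = FALSE)
    fusion_schedule <- fs
  }

  structure(list(
    seed = as.integer(seed), duration = duration,
    frame_interval = frame_interval, field_size = field_size,
    n_clusters = as.integer(n_clusters), n_initial = as.integer(n_initial),
    nucleation_rate = nucleation_rate, flow_amplitude = flow_amplitude,
    jitter_sd = jitter_sd, gelation_time = gelation_time,
    arrest_ramp = arrest_ramp, fusion_schedule = fusion_schedule,
    regime_mixture = regime_mixture, cluster_radius = cluster_radius,
    contact_distance = contact_distance
  ), class = "simulation_config")
}

# Effective mobile time E(t) = integral_0^t s(tau) dtau in minutes, where the
# arrest multiplier s is 1 before the ramp, falls linearly over
# [g - ramp, g] and is 0 from g on (all in minutes here).
effective_time <- function(t_min, gel_min, ramp_min) {
  if (!is.finite(gel_min)) return(t_min)
  if (ramp_min <= 0) return(pmin(t_min, gel_min))
  a <- gel_min - ramp_min
  ifelse(t_min <= a, t_min,
    ifelse(t_min >= gel_min,
      gel_min - ramp_min / 2,
      a + ramp_min / 2 - (gel_min - t_min)^2 / (2 * ramp_min)))
}

# rotate the unit vector of angle `phi` (radians) into cartesian components
unit_vec <- function(phi) c(cos(phi), sin(phi))

#' Simulate a particle field with known ground truth
#'
#' Generates a replicate's worth of aggregate trajectories under the model
#' described in [simulation_config()]: clusters of co-moving aggregates with
#' independent jitter, Poisson accumulation of new aggregates, scheduled
#' cluster fusion and progressive mobility arrest at the gelation time.
#'
#' @param config a [simulation_config()].
#' @param replicate_id label stored with the series.
#' @return a list with components `series` (a `replicate_series`: trajectory
#'   table plus frame geometry) and `truth` (a `ground_truth`: true gelation
#'   time, scheduled fusion events, per-particle origin cluster).
#' @export
simulate_particle_field <- function(config, replicate_id = "rep1") {
  stopifnot(inherits(config, "simulation_config"))
  dt <- config$frame_interval
  n_frames <- floor(config$duration * 60 / dt) + 1L
  t_min <- (seq_len(n_frames) - 1) * dt
  g_min <- config$gelation_time * 60
  ramp_min <- config$arrest_ramp * 60
  E <- effective_time(t_min, g_min, ramp_min)
  Efun <- function(t) effective_time(t, g_min, ramp_min)

  empty <- data.frame(frame = integer(), time_h = numeric(),
                      particle_id = integer(), x_um = numeric(),
                      y_um = numeric(), z_um = numeric(),
                      cluster_id = integer())
  truth_events <- data.frame(cluster_a = integer(), cluster_b = integer(),
                             onset_min = numeric(), completion_min = numeric())
  if (config$n_clusters == 0L) {
    series <- new_replicate_series(empty, dt, config$field_size,
                                   config$duration, replicate_id)
    truth <- structure(list(gelation_time_h = config$gelation_time,
                            fusion_events = truth_events,
                            particles = data.frame(),
                            config = config), class = "ground_truth")
    return(list(series = series, truth = truth))
  }

  sched <- config$fusion_schedule
  n_pairs <- if (is.null(sched)) 0L else nrow(sched)
  fusing <- if (n_pairs) c(sched$cluster_a, sched$cluster_b) else integer()
  free <- setdiff(seq_len(config$n_clusters), fusing)
  n_units <- n_pairs + length(free)

  with_seed(config$seed, {
    # one grid cell per unit (a free cluster or a fusing pair)
    ncell <- max(1L, ceiling(sqrt(n_units)))
    cw <- config$field_size / ncell
    cell_idx <- seq_len(n_units) - 1L
    cell_centre <- cbind((cell_idx %% ncell + 0.5) * cw[1],
                         (cell_idx %/% ncell + 0.5) * cw[2])

    # per-cluster kinematics: start centre, drift before/after a switch time
    clus <- vector("list", config$n_clusters)
    mk <- function(centre0, u_pre, u_post = u_pre, switch_min = Inf) {
      list(centre0 = centre0, u_pre = u_pre, u_post = u_post,
           switch_min = switch_min)
    }
    centre_at <- function(cl, t) {
      e_pre <- Efun(pmin(t, cl$switch_min))
      e_post <- pmax(0, Efun(t) - Efun(cl$switch_min))
      cl$centre0 + cl$u_pre * e_pre + cl$u_post * e_post
    }

    unit <- 0L
    # spread free-cluster headings apart so local flows are distinct
    if (length(free)) {
      base_phi <- runif(1, 0, 2 * pi)
      for (i in seq_along(free)) {
        unit <- unit + 1L
        phi <- base_phi + 2 * pi * (i - 1) / max(1L, length(free)) +
          runif(1, -0.2, 0.2)
        u <- config$flow_amplitude * unit_vec(phi)
        e_end <- Efun(max(t_min))
        start <- cell_centre[unit, ] - u * e_end / 2   # path midpoint in cell
        clus[[free[i]]] <- mk(start, u)
      }
    }
    if (n_pairs) {
      for (k in seq_len(n_pairs)) {
        unit <- unit + 1L
        a <- sched$cluster_a[k]; b <- sched$cluster_b[k]
        onset <- sched$onset_min[k]
        compl <- onset + sched$duration_min[k]
        phi_a <- runif(1, 0, 2 * pi)
        u_a <- config$flow_amplitude * unit_vec(phi_a)
        # partner heading 135 deg off: approaching pair reads as
        # anti-directional (cos ~ -0.71), and a window-averaged vector
        # rotating between the two headings can never sit inside both
        # +/-60 deg co-direction cones at once
        sgn <- sample(c(-1, 1), 1)
        u_b <- config$flow_amplitude * unit_vec(phi_a + sgn * 3 * pi / 4)
        w <- u_b - u_a
        perp <- c(-w[2], w[1]) / sqrt(sum(w^2))
        # at onset the centres sit `contact_distance` apart, perpendicular to
        # the relative velocity: closest approach is exactly at onset
        ca_on <- cell_centre[unit, ] - perp * config$contact_distance / 2
        cb_on <- cell_centre[unit, ] + perp * config$contact_distance / 2
        clus[[a]] <- mk(ca_on - u_a * Efun(onset), u_a)
        clus[[b]] <- mk(cb_on - u_b * Efun(onset), u_b, u_post = u_a,
                        switch_min = compl)
        truth_events <- rbind(truth_events, data.frame(
          cluster_a = a, cluster_b = b, onset_min = onset,
          completion_min = compl))
      }
    }

    # particle roster: initial members plus Poisson accumulation
    roster <- list()
    pid <- 0L
    nuc_end <- min(max(t_min), g_min)
    for (ci in seq_len(config$n_clusters)) {
      cl <- clus[[ci]]
      n_new <- if (config$nucleation_rate > 0 && nuc_end > 0)
        rpois(1, config$nucleation_rate * nuc_end / 60) else 0L
      t_app <- c(rep(0, config$n_initial),
                 if (n_new) sort(runif(n_new, 0, nuc_end)) else numeric())
      app_frame <- pmin(ceiling(t_app / dt), n_frames - 1L)
      for (j in seq_along(t_app)) {
        pid <- pid + 1L
        r <- config$cluster_radius * sqrt(runif(1))
        th <- runif(1, 0, 2 * pi)
        af <- app_frame[j]
        p_app <- centre_at(cl, af * dt) + r * unit_vec(th)
        roster[[pid]] <- list(id = pid, cluster = ci, app_frame = af,
                              p_app = p_app)
      }
    }

    # the fusing cluster's contact member: member of b closest to a at onset
    # switches drift already at onset (first contact / first co-alignment)
    if (n_pairs) {
      for (k in seq_len(n_pairs)) {
        a <- sched$cluster_a[k]; b <- sched$cluster_b[k]
        onset <- sched$onset_min[k]
        ca <- centre_at(clus[[a]], onset)
        members_b <- Filter(function(p) p$cluster == b &&
                              p$app_frame * dt <= onset, roster)
        if (length(members_b)) {
          d <- vapply(members_b, function(p) {
            pos <- p$p_app +
              clus[[b]]$u_pre * (Efun(onset) - Efun(p$app_frame * dt))
            sqrt(sum((pos - ca)^2))
          }, numeric(1))
          roster[[members_b[[which.min(d)]]$id]]$switch_min <- onset
        }
      }
    }

    # assemble trajectories
    rows <- vector("list", length(roster))
    for (p in roster) {
      cl <- clus[[p$cluster]]
      sw <- p$switch_min %||% cl$switch_min
      frames <- p$app_frame:(n_frames - 1L)
      tt <- t_min[frames + 1L]
      e_app <- Efun(p$app_frame * dt)
      # members born before the switch accrue pre-drift up to the switch;
      # afterwards (or if born after it) they accrue the unified drift
      e_pre <- pmax(0, Efun(pmin(tt, sw)) - e_app)
      e_post <- pmax(0, Efun(tt) - Efun(max(sw, p$app_frame * dt)))
      jit <- if (config$jitter_sd > 0)
        matrix(rnorm(2 * length(tt), 0, config$jitter_sd), ncol = 2)
      else matrix(0, length(tt), 2)
      x <- p$p_app[1] + cl$u_pre[1] * e_pre + cl$u_post[1] * e_post + jit[, 1]
      y <- p$p_app[2] + cl$u_pre[2] * e_pre + cl$u_post[2] * e_post + jit[, 2]
      rows[[p$id]] <- data.frame(frame = frames, time_h = tt / 60,
                                 particle_id = p$id, x_um = x, y_um = y,
                                 z_um = 0, cluster_id = p$cluster)
    }
    traj <- do.call(rbind, rows)
    traj <- traj[order(traj$particle_id, traj$frame), , drop = FALSE]
    rownames(traj) <- NULL

    series <- new_replicate_series(traj, dt, config$field_size,
                                   config$duration, replicate_id)
    particles <- do.call(rbind, lapply(roster, function(p) data.frame(
      particle_id = p$id, cluster_id = p$cluster, appear_frame = p$app_frame,
      switch_min = p$switch_min %||% clus[[p$cluster]]$switch_min)))
    truth <- structure(list(gelation_time_h = config$gelation_time,
                            fusion_events = truth_events,
                            particles = particles,
                            config = config), class = "ground_truth")
    list(series = series, truth = truth)
  })
}

new_replicate_series <- function(trajectories, frame_interval, field_size,
                                 duration, replicate_id) {
  stopifnot(is.data.frame(trajectories))
  structure(list(trajectories = trajectories,
                 frame_interval = frame_interval,
                 field_size = field_size,
                 duration = duration,
                 replicate_id = replicate_id),
            class = "replicate_series")
}

#' @export
print.replicate_series <- function(x, ...) {
  cat(sprintf(
    "<replicate_series '%s'> %d particles, %d frames @ %.3g min, field %g x %g um\n",
    x$replicate_id, length(unique(x$trajectories$particle_id)),
    length(unique(x$trajectories$frame)), x$frame_interval,
    x$field_size[1], x$field_size[2]))
  invisible(x)
}

#' Render a particle series as a synthetic image stack
#'
#' Each detection is drawn as an isotropic Gaussian spot on a 16-bit-range
#' grey-scale frame; optional additive Gaussian noise emulates camera noise
#' (photon statistics are out of scope).
#'
#' @param series a `replicate_series`.
#' @param spot_sigma_px spot standard deviation in pixels.
#' @param pixel_size_um pixel size in micrometres; must be positive.
#' @param noise_sd additive Gaussian noise sd on the 0..1 intensity scale.
#' @param amplitude peak spot intensity above baseline (0..1 scale).
#' @param baseline constant background level.
#' @param seed seed for the noise draws.
#' @return an `image_stack`: list of frame matrices (values in 0..1,
#'   quantised to 16 bits) with pixel/frame geometry attributes.
#' @export
render_image_stack <- function(series, spot_sigma_px = 2, pixel_size_um = 2,
                               noise_sd = 0, amplitude = 0.6, baseline = 0.1,
                               seed = 1L) {
  stopifnot(inherits(series, "replicate_series"))
  check_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  check_number(spot_sigma_px, "spot_sigma_px", positive = TRUE)
  nx <- max(1L, ceiling(series$field_size[1] / pixel_size_um))
  ny <- max(1L, ceiling(series$field_size[2] / pixel_size_um))
  tr <- series$trajectories
  if (nrow(tr) && (any(tr$x_um < 0 | tr$x_um > series$field_size[1]) ||
                   any(tr$y_um < 0 | tr$y_um > series$field_size[2])))
    stop("particle positions fall outside the field", call. = FALSE)
  frames <- if (nrow(tr)) 0:max(tr$frame) else 0L
  w <- ceiling(4 * spot_sigma_px)
  with_seed(seed, {
    stack <- lapply(frames, function(f) {
      m <- matrix(baseline, nrow = ny, ncol = nx)
      sub <- tr[tr$frame == f, , drop = FALSE]
      if (nrow(sub)) {
        for (i in seq_len(nrow(sub))) {
          cx <- sub$x_um[i] / pixel_size_um   # pixel units, origin at corner
          cy <- sub$y_um[i] / pixel_size_um
          jc <- round(cx + 0.5); ic <- round(cy + 0.5)
          js <- max(1L, jc - w):min(nx, jc + w)
          is <- max(1L, ic - w):min(ny, ic + w)
          gx <- exp(-((js - 0.5) - cx)^2 / (2 * spot_sigma_px^2))
          gy <- exp(-((is - 0.5) - cy)^2 / (2 * spot_sigma_px^2))
          m[is, js] <- m[is, js] + amplitude * outer(gy, gx)
        }
      }
      if (noise_sd > 0) m <- m + rnorm(length(m), 0, noise_sd)
      m <- pmin(pmax(m, 0), 1)
      # quantise to the 16-bit dynamic range of the emulated camera
      round(m * 65535) / 65535
    })
    structure(stack, class = "image_stack",
              pixel_size_um = pixel_size_um,
              frame_interval = series$frame_interval,
              field_size = series$field_size)
  })
}

#' Write / read an image stack as multi-page TIFF
#'
#' @param stack an `image_stack`.
#' @param path output file.
#' @return `write_image_stack` returns `path` invisibly; `read_image_stack`
#'   returns an `image_stack`.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  tiff::writeTIFF(unclass(stack), path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_stack
#' @param pixel_size_um,frame_interval geometry to attach on read (TIFF tags
#'   do not carry them).
#' @export
read_image_stack <- function(path, pixel_size_um, frame_interval) {
  frames <- tiff::readTIFF(path, all = TRUE)
  structure(frames, class = "image_stack",
            pixel_size_um = pixel_size_um,
            frame_interval = frame_interval,
            field_size = c(ncol(frames[[1]]) * pixel_size_um,
                           nrow(frames[[1]]) * pixel_size_um))
}

#' Simulate an oscillatory rheology time sweep
#'
#' Piecewise-linear storage/loss modulus kinetics: a flat baseline up to the
#' lag time, a linear rise at the given rate, and a plateau, plus optional
#' Gaussian noise. The loss modulus G'' rises at its own rate to
#' `plateau_gp * gpp_ratio`.
#'
#' @param lag lag time before moduli increase, hours.
#' @param rate_gp G' growth rate, Pa/h; must be positive.
#' @param plateau_gp terminal G', Pa; must be positive.
#' @param rate_gpp G'' growth rate, Pa/h.
#' @param gpp_ratio plateau of G'' as a fraction of `plateau_gp`.
#' @param noise_sd Gaussian noise sd, Pa.
#' @param dt,duration time grid, hours.
#' @param baseline pre-lag modulus level, Pa.
#' @param seed RNG seed for the noise.
#' @return a `rheology_trace`: data.frame `time_h`, `g_prime_pa`,
#'   `g_double_prime_pa` with measurement metadata attributes.
#' @export
simulate_rheology_trace <- function(lag, rate_gp, plateau_gp,
                                    rate_gpp = 0.3 * rate_gp,
                                    gpp_ratio = 0.3, noise_sd = 0,
                                    dt = 0.1, duration = 24,
                                    baseline = 0.02, seed = 1L) {
  check_number(rate_gp, "rate_gp", positive = TRUE)
  check_number(plateau_gp, "plateau_gp", positive = TRUE)
  check_number(lag, "lag", nonneg = TRUE)
  if (lag + plateau_gp / rate_gp > duration)
    stop("trace would not reach its plateau within `duration`", call. = FALSE)
  tt <- seq(0, duration, by = dt)
  ramp <- function(rate, plat) pmin(baseline + rate * pmax(tt - lag, 0), plat)
  gp <- ramp(rate_gp, plateau_gp)
  gpp <- ramp(rate_gpp, plateau_gp * gpp_ratio)
  if (noise_sd > 0) {
    with_seed(seed, {
      gp <- gp + rnorm(length(tt), 0, noise_sd)
      gpp <- gpp + rnorm(length(tt), 0, noise_sd)
    })
  }
  new_rheology_trace(data.frame(time_h = tt, g_prime_pa = gp,
                                g_double_prime_pa = gpp))
}

new_rheology_trace <- function(df, displacement_rad = 5e-3,
                               frequency_hz = 0.5, temperature_c = 25) {
  stopifnot(all(c("time_h", "g_prime_pa", "g_double_prime_pa") %in% names(df)))
  if (is.unsorted(df$time_h, strictly = TRUE))
    stop("trace times must be strictly increasing", call. = FALSE)
  structure(df, class = c("rheology_trace", "data.frame"),
            displacement_rad = displacement_rad,
            frequency_hz = frequency_hz, temperature_c = temperature_c)
}

#' Simulate an ensemble of rheology replicates from a kinetic-regime mixture
#'
#' Each replicate draws the 'fast' parameter set with probability `prob_fast`
#' and the 'slow' set otherwise, emulating the two-regime kinetics seen in
#' un-crowded hydrogelation; pass `prob_fast = 1` and identical sets for a
#' homogeneous ensemble.
#'
#' @param n number of replicates.
#' @param prob_fast probability of the fast parameter set.
#' @param fast,slow named lists with `lag`, `rate_gp`, `plateau_gp` (and
#'   optionally `rate_gpp`).
#' @param noise_frac Gaussian noise sd as a fraction of each trace's plateau.
#' @param dt,duration time grid, hours.
#' @param seed RNG seed.
#' @return list with `traces` (list of `rheology_trace`) and `regimes`
#'   (character vector "fast"/"slow").
#' @export
simulate_regime_ensemble <- function(n, prob_fast = 0.5,
                                     fast = list(lag = 0.5, rate_gp = 4.7,
                                                 plateau_gp = 3.6,
                                                 rate_gpp = 2.3),
                                     slow = list(lag = 2, rate_gp = 0.28,
                                                 plateau_gp = 3.6,
                                                 rate_gpp = 0.08),
                                     noise_frac = 0.02, dt = 0.1,
                                     duration = 24, seed = 1L) {
  stopifnot(n >= 1, prob_fast >= 0, prob_fast <= 1)
  with_seed(seed, {
    regimes <- ifelse(runif(n) < prob_fast, "fast", "slow")
    sub_seeds <- sample.int(.Machine$integer.max, n)
    traces <- lapply(seq_len(n), function(i) {
      p <- if (regimes[i] == "fast") fast else slow
      simulate_rheology_trace(
        lag = p$lag, rate_gp = p$rate_gp, plateau_gp = p$plateau_gp,
        rate_gpp = p$rate_gpp %||% (0.3 * p$rate_gp),
        noise_sd = noise_frac * p$plateau_gp, dt = dt, duration = duration,
        seed = sub_seeds[i])
    })
    list(traces = traces, regimes = regimes)
  })
}
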