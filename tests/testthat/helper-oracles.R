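# Independent oracles used by the tests: deliberately naive implementations
# that share no code with the package internals.

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# optimal one-to-one assignment between two point sets (same size) by
# exhaustive enumeration; returns the permutation minimising total distance
brute_assignment <- function(ax, ay, bx, by, max_dist = Inf) {
  n <- length(ax)
  per <- all_perms(n)
  cost <- apply(per, 1, function(p) {
    d <- sqrt((ax - bx[p])^2 + (ay - by[p])^2)
    if (any(d > max_dist)) Inf else sum(d)
  })
  per[which.min(cost), ]
}

# O(n^2) pairwise co-direction classifier
brute_codirection <- function(v, radius, cth, floor) {
  out <- NULL
  n <- nrow(v)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    d <- sqrt((v$x_um[i] - v$x_um[j])^2 + (v$y_um[i] - v$y_um[j])^2)
    if (d > radius) next
    si <- sqrt(v$vx_um_min[i]^2 + v$vy_um_min[i]^2)
    sj <- sqrt(v$vx_um_min[j]^2 + v$vy_um_min[j]^2)
    if (si < floor || sj < floor) next
    cs <- (v$vx_um_min[i] * v$vx_um_min[j] +
           v$vy_um_min[i] * v$vy_um_min[j]) / (si * sj)
    lab <- if (cs >= cth) "connected" else if (cs <= -cth) "non-connected"
           else next
    out <- rbind(out, data.frame(id_a = v$particle_id[i],
                                 id_b = v$particle_id[j], label = lab))
  }
  out
}

# connected components by explicit depth-first search
dfs_components <- function(ids, edge_a, edge_b) {
  adj <- lapply(setNames(vector("list", length(ids)), as.character(ids)),
                identity)
  for (k in seq_along(edge_a)) {
    a <- as.character(edge_a[k]); b <- as.character(edge_b[k])
    adj[[a]] <- c(adj[[a]], edge_b[k])
    adj[[b]] <- c(adj[[b]], edge_a[k])
  }
  seen <- setNames(rep(FALSE, length(ids)), as.character(ids))
  comps <- list()
  for (v in ids) {
    if (seen[as.character(v)]) next
    stack <- v; comp <- integer()
    while (length(stack)) {
      u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (seen[as.character(u)]) next
      seen[as.character(u)] <- TRUE
      comp <- c(comp, u)
      stack <- c(stack, adj[[as.character(u)]])
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

# build a replicate_series directly from a trajectory table
make_series <- function(traj, frame_interval = 1, field = c(500, 500)) {
  if (is.null(traj$time_h)) traj$time_h <- traj$frame * frame_interval / 60
  if (is.null(traj$z_um)) traj$z_um <- rep(0, nrow(traj))
  gelkin:::new_replicate_series(traj, frame_interval, field,
                                if (nrow(traj)) max(traj$time_h) else 0,
                                "test")
}

# default two-event fusion simulation used by several tests
fusion_sim <- function(seed) {
  sched <- data.frame(cluster_a = c(1, 3), cluster_b = c(2, 4),
                      onset_min = c(9, 16), duration_min = c(0.8, 2.4))
  cfg <- simulation_config(seed = seed, duration = 0.6, frame_interval = 0.2,
                           n_clusters = 5, gelation_time = Inf,
                           fusion_schedule = sched, n_initial = 8,
                           nucleation_rate = 2)
  simulate_particle_field(cfg)
}
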