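# Co-movement connectivity: aggregates moving in the same direction within a
# neighbourhood are "connected" (the red lines of a connectivity overlay),
# anti-directional neighbours are "non-connected"; connected components of
# the co-direction graph are the clusters of connected aggregates.

#' Per-particle displacement vectors over a frame window
#'
#' The vector is the end-minus-start position difference divided by the
#' window duration, for particles detected at both window ends; all other
#' particles are omitted (the contract, not an error).
#'
#' @param series a `replicate_series`.
#' @param start_frame first frame of the window (0-based).
#' @param window window length in frame pairs (>= 1).
#' @return data.frame `particle_id`, `x_um`, `y_um` (start position),
#'   `vx_um_min`, `vy_um_min`, `speed_um_min`, with window timing attributes
#'   (`t_mid_min` is the window midpoint in minutes).
#' @export
displacement_vectors <- function(series, start_frame = 0L, window = 5L) {
  stopifnot(inherits(series, "replicate_series"))
  if (window < 1L) stop("window must span at least one frame pair",
                        call. = FALSE)
  tr <- series$trajectories
  end_frame <- start_frame + window
  a <- tr[tr$frame == start_frame, , drop = FALSE]
  b <- tr[tr$frame == end_frame, , drop = FALSE]
  shared <- intersect(a$particle_id, b$particle_id)
  ia <- match(shared, a$particle_id); ib <- match(shared, b$particle_id)
  dt_win <- window * series$frame_interval
  out <- data.frame(
    particle_id = shared,
    x_um = a$x_um[ia], y_um = a$y_um[ia],
    vx_um_min = (b$x_um[ib] - a$x_um[ia]) / dt_win,
    vy_um_min = (b$y_um[ib] - a$y_um[ia]) / dt_win)
  out$speed_um_min <- sqrt(out$vx_um_min^2 + out$vy_um_min^2)
  attr(out, "t_start_min") <- start_frame * series$frame_interval
  attr(out, "t_mid_min") <- (start_frame + window / 2) * series$frame_interval
  attr(out, "window") <- window
  out
}

#' Build the co-direction (connectedness) graph
#'
#' Every particle pair within `neighbour_radius` whose speeds both exceed a
#' minimum-motion floor is classified by the cosine similarity of its
#' displacement vectors: at or above `+cos_threshold` the pair is
#' "connected", at or below `-cos_threshold` "non-connected", otherwise no
#' edge. Edges are symmetric and self-edges impossible.
#'
#' @param vectors output of [displacement_vectors()].
#' @param neighbour_radius maximum pair separation, um.
#' @param cos_threshold cosine cut in (0, 1]; the default 0.5 corresponds to
#'   +/- 60 degree cones.
#' @param min_speed minimum-motion floor, um/min, below which a particle
#'   cannot carry edges (keeps stationary pairs unclassified).
#' @return a `connectivity_graph`: list with `nodes` (the vectors table) and
#'   `edges` (`id_a`, `id_b`, `cos`, `dist_um`, `label`).
#' @export
build_codirection_graph <- function(vectors, neighbour_radius = 150,
                                    cos_threshold = 0.5, min_speed = 0.1) {
  if (cos_threshold <= 0 || cos_threshold > 1)
    stop("cos_threshold must lie in (0, 1]", call. = FALSE)
  if (nrow(vectors) < 2L)
    stop("need at least two displacement vectors", call. = FALSE)
  n <- nrow(vectors)
  id <- vectors$particle_id
  ij <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  d <- sqrt((vectors$x_um[j] - vectors$x_um[i])^2 +
            (vectors$y_um[j] - vectors$y_um[i])^2)
  si <- vectors$speed_um_min[i]; sj <- vectors$speed_um_min[j]
  ok <- d <= neighbour_radius & si >= min_speed & sj >= min_speed
  cs <- rep(NA_real_, length(i))
  cs[ok] <- (vectors$vx_um_min[i[ok]] * vectors$vx_um_min[j[ok]] +
             vectors$vy_um_min[i[ok]] * vectors$vy_um_min[j[ok]]) /
            (si[ok] * sj[ok])
  lab <- ifelse(cs >= cos_threshold, "connected",
                ifelse(cs <= -cos_threshold, "non-connected",
                       NA_character_))
  keep <- ok & !is.na(lab)
  edges <- data.frame(id_a = id[i[keep]], id_b = id[j[keep]],
                      cos = cs[keep], dist_um = d[keep],
                      label = lab[keep])
  structure(list(nodes = vectors, edges = edges,
                 neighbour_radius = neighbour_radius,
                 cos_threshold = cos_threshold, min_speed = min_speed,
                 t_mid_min = attr(vectors, "t_mid_min")),
            class = "connectivity_graph")
}

#' Extract clusters of connected aggregates
#'
#' Connected components over "connected" edges only; isolated nodes remain
#' singleton clusters. Clusters are ordered by decreasing size, ties broken
#' by smallest member id, and numbered in that order.
#'
#' @param graph a `connectivity_graph`.
#' @return an `aggregate_clusters` object: list with `membership`
#'   (`particle_id`, `cluster_id`) and `clusters` (`cluster_id`, `size`,
#'   `centroid_x_um`, `centroid_y_um`).
#' @export
extract_clusters <- function(graph) {
  stopifnot(inherits(graph, "connectivity_graph"))
  nodes <- graph$nodes
  conn <- graph$edges[graph$edges$label == "connected", , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(conn$id_a),
                   to = as.character(conn$id_b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$particle_id)))
  comp <- igraph::components(g)
  membership <- data.frame(particle_id = nodes$particle_id,
                           comp = comp$membership[
                             as.character(nodes$particle_id)])
  sizes <- table(membership$comp)
  min_id <- tapply(membership$particle_id, membership$comp, min)
  ord <- order(-as.integer(sizes[names(min_id)]), as.integer(min_id))
  relabel <- setNames(seq_along(ord), names(min_id)[ord])
  membership$cluster_id <- as.integer(relabel[as.character(membership$comp)])
  membership$comp <- NULL
  cl <- lapply(sort(unique(membership$cluster_id)), function(k) {
    m <- membership$particle_id[membership$cluster_id == k]
    i <- match(m, nodes$particle_id)
    data.frame(cluster_id = k, size = length(m),
               centroid_x_um = mean(nodes$x_um[i]),
               centroid_y_um = mean(nodes$y_um[i]))
  })
  structure(list(membership = membership[order(membership$cluster_id,
                                               membership$particle_id), ],
                 clusters = do.call(rbind, cl),
                 t_mid_min = graph$t_mid_min),
            class = "aggregate_clusters")
}

#' Cluster time course over sliding windows
#'
#' Runs [displacement_vectors()], [build_codirection_graph()] and
#' [extract_clusters()] for every window start (stride 1 frame) and collects
#' the per-window cluster member sets and edge tables used by lineage
#' tracking and fusion detection.
#'
#' @inheritParams displacement_vectors
#' @inheritParams build_codirection_graph
#' @return a `cluster_timecourse`: list of windows, each with `t_mid_min`,
#'   `members` (list of member-id vectors in cluster order) and `edges`.
#' @export
cluster_timecourse <- function(series, window = 5L, neighbour_radius = 150,
                               cos_threshold = 0.5, min_speed = 0.1) {
  stopifnot(inherits(series, "replicate_series"))
  tr <- series$trajectories
  max_start <- max(tr$frame) - window
  if (max_start < 0) stop("record shorter than one window", call. = FALSE)
  wins <- lapply(0:max_start, function(f) {
    v <- displacement_vectors(series, f, window)
    t_mid <- (f + window / 2) * series$frame_interval
    if (nrow(v) < 2L)
      return(list(t_mid_min = t_mid, members = list(),
                  edges = NULL))
    g <- build_codirection_graph(v, neighbour_radius, cos_threshold,
                                 min_speed)
    cl <- extract_clusters(g)
    members <- lapply(split(cl$membership$particle_id,
                            cl$membership$cluster_id), sort)
    list(t_mid_min = t_mid, members = unname(members), edges = g$edges)
  })
  structure(list(windows = wins, window = window,
                 frame_interval = series$frame_interval,
                 replicate_id = series$replicate_id),
            class = "cluster_timecourse")
}
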