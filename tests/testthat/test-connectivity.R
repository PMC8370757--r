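make_vectors <- function(x, y, vx, vy, ids = seq_along(x)) {
  v <- data.frame(particle_id = ids, x_um = x, y_um = y,
                  vx_um_min = vx, vy_um_min = vy)
  v$speed_um_min <- sqrt(vx^2 + vy^2)
  v
}

test_that("displacement vectors are endpoint differences over the window", {
  traj <- rbind(
    data.frame(frame = 0:5, particle_id = 1, x_um = 50, y_um = 50),
    data.frame(frame = 0:5, particle_id = 2, x_um = 100 + 0:5, y_um = 80))
  v <- displacement_vectors(make_series(traj, frame_interval = 0.2),
                            start_frame = 0, window = 5)
  expect_equal(v$vx_um_min[v$particle_id == 1], 0)
  expect_equal(v$vy_um_min[v$particle_id == 1], 0)
  # +5 um in x over a 1-minute window
  expect_equal(v$vx_um_min[v$particle_id == 2], 5)
  expect_equal(v$vy_um_min[v$particle_id == 2], 0)

  # particles absent at either end are omitted, not zero-filled
  part <- data.frame(frame = 2:4, particle_id = 3, x_um = 1, y_um = 1)
  v2 <- displacement_vectors(make_series(rbind(traj, part), 0.2), 0, 5)
  expect_false(3 %in% v2$particle_id)
  expect_error(displacement_vectors(make_series(traj, 0.2), 0, 0), "window")
})

test_that("random-walk vectors equal an independent recomputation", {
  sim <- simulate_particle_field(simulation_config(
    seed = 17, duration = 0.2, frame_interval = 0.2, n_clusters = 3,
    gelation_time = Inf))
  tr <- sim$series$trajectories
  v <- displacement_vectors(sim$series, start_frame = 10, window = 5)
  a <- tr[tr$frame == 10, ]; b <- tr[tr$frame == 15, ]
  for (k in seq_len(nrow(v))) {
    id <- v$particle_id[k]
    expect_equal(v$vx_um_min[k],
                 (b$x_um[b$particle_id == id] -
                    a$x_um[a$particle_id == id]) / 1)
  }
})

test_that("nearby pairs are classified by cosine similarity", {
  v <- make_vectors(x = c(0, 50, 60), y = c(0, 0, 40),
                    vx = c(2, 2, -2), vy = c(0, 0.1, 0.05))
  g <- build_codirection_graph(v, neighbour_radius = 150,
                               cos_threshold = 0.5)
  lab <- function(a, b) g$edges$label[(g$edges$id_a == a & g$edges$id_b == b)]
  expect_equal(lab(1, 2), "connected")      # parallel
  expect_equal(lab(1, 3), "non-connected")  # antiparallel
  # out-of-radius pairs carry no edge
  far <- make_vectors(x = c(0, 500), y = c(0, 0), vx = c(1, 1), vy = c(0, 0))
  expect_equal(nrow(build_codirection_graph(far)$edges), 0L)
  # stationary particles are below the minimum-motion floor
  still <- make_vectors(x = c(0, 10), y = c(0, 0), vx = c(0, 1), vy = c(0, 0))
  expect_equal(nrow(build_codirection_graph(still, min_speed = 0.1)$edges), 0L)
  expect_error(build_codirection_graph(v, cos_threshold = 0), "cos_threshold")
  expect_error(build_codirection_graph(v, cos_threshold = 1.2),
               "cos_threshold")
  expect_error(build_codirection_graph(v[1, ]), "two")
})

test_that("the edge set matches an O(n^2) brute-force classifier", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 12
    v <- make_vectors(x = runif(n, 0, 300), y = runif(n, 0, 300),
                      vx = rnorm(n), vy = rnorm(n))
    g <- build_codirection_graph(v, neighbour_radius = 150,
                                 cos_threshold = 0.5, min_speed = 0.1)
    o <- brute_codirection(v, 150, 0.5, 0.1)
    got <- g$edges[order(g$edges$id_a, g$edges$id_b),
                   c("id_a", "id_b", "label")]
    want <- o[order(o$id_a, o$id_b), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("the edge set is invariant under a common rotation", {
  set.seed(8)
  n <- 15
  v <- make_vectors(x = runif(n, 0, 200), y = runif(n, 0, 200),
                    vx = rnorm(n), vy = rnorm(n))
  th <- 1.1
  vr <- v
  vr$vx_um_min <- cos(th) * v$vx_um_min - sin(th) * v$vy_um_min
  vr$vy_um_min <- sin(th) * v$vx_um_min + cos(th) * v$vy_um_min
  vr$speed_um_min <- sqrt(vr$vx_um_min^2 + vr$vy_um_min^2)
  e1 <- build_codirection_graph(v)$edges
  e2 <- build_codirection_graph(vr)$edges
  expect_equal(e1[, c("id_a", "id_b", "label")],
               e2[, c("id_a", "id_b", "label")])
})

test_that("edge labels are invariant under node reordering", {
  set.seed(12)
  n <- 10
  v <- make_vectors(x = runif(n, 0, 120), y = runif(n, 0, 120),
                    vx = rnorm(n), vy = rnorm(n))
  perm <- sample(n)
  key <- function(e) {
    k <- paste(pmin(e$id_a, e$id_b), pmax(e$id_a, e$id_b), e$label)
    sort(k)
  }
  expect_equal(key(build_codirection_graph(v)$edges),
               key(build_codirection_graph(v[perm, ])$edges))
})

test_that("clusters are components over connected edges only", {
  # two disjoint triangles, all co-moving internally
  v <- make_vectors(x = c(0, 10, 5, 200, 210, 205),
                    y = c(0, 0, 8, 200, 200, 208),
                    vx = c(1, 1, 1, -1, -1, -1),
                    vy = c(0, 0, 0, 0.2, 0.2, 0.2))
  cl <- extract_clusters(build_codirection_graph(v))
  expect_equal(cl$clusters$size, c(3, 3))
  expect_equal(cl$membership$cluster_id, c(1, 1, 1, 2, 2, 2))

  # only anti-directional edges: everyone is a singleton
  v2 <- make_vectors(x = c(0, 10), y = c(0, 0), vx = c(1, -1), vy = c(0, 0))
  cl2 <- extract_clusters(build_codirection_graph(v2))
  expect_equal(cl2$clusters$size, c(1, 1))
})

test_that("components agree with a depth-first-search oracle", {
  set.seed(33)
  for (rep in 1:3) {
    n <- 30
    v <- make_vectors(x = runif(n, 0, 250), y = runif(n, 0, 250),
                      vx = rnorm(n), vy = rnorm(n))
    g <- build_codirection_graph(v)
    cl <- extract_clusters(g)
    conn <- g$edges[g$edges$label == "connected", ]
    want <- dfs_components(v$particle_id, conn$id_a, conn$id_b)
    got <- lapply(split(cl$membership$particle_id,
                        cl$membership$cluster_id), sort)
    got <- unname(got[order(vapply(got, min, numeric(1)))])
    expect_equal(got, want)
  }
})
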