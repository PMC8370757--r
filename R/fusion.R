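# Cluster identity over time and fusion-event quantitation: lineages are
# clusters matched window-to-window by Jaccard overlap; a many-to-one match
# is a merge. A fusion event's onset is the first co-directional contact
# between the two parent clusters and its completion the first time their
# members move as one stable cluster.

#' Track cluster lineages across windows
#'
#' Consecutive-window clusters are matched by Jaccard overlap of their member
#' sets: a one-to-one match at or above `overlap_threshold` continues a
#' lineage, several lineages matching one cluster record a merge (the parents
#' end, a child lineage starts), and unmatched clusters found new lineages.
#'
#' @param timecourse a `cluster_timecourse` (see [cluster_timecourse()]).
#' @param overlap_threshold Jaccard cut in (0, 1].
#' @return `cluster_lineages`: list with `lineages` (per lineage: id, birth
#'   and end window, parents, per-window member sets) and `merges`
#'   (`window`, `t_mid_min`, `child`, `parents` list-column).
#' @export
track_lineages <- function(timecourse, overlap_threshold = 0.3) {
  stopifnot(inherits(timecourse, "cluster_timecourse"))
  if (overlap_threshold <= 0 || overlap_threshold > 1)
    stop("overlap_threshold must lie in (0, 1]", call. = FALSE)
  lineages <- list()
  alive <- integer()      # lineage ids currently alive
  nxt <- 1L
  merges <- list()
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  for (k in seq_along(timecourse$windows)) {
    win <- timecourse$windows[[k]]
    cl <- win$members
    if (!length(cl)) next
    chosen <- rep(NA_integer_, length(alive))   # cluster index per lineage
    if (length(alive)) {
      for (li in seq_along(alive)) {
        cur <- lineages[[alive[li]]]$members_now
        js <- vapply(cl, jaccard, numeric(1), b = cur)
        best <- which.max(js)
        if (length(best) && js[best] >= overlap_threshold)
          chosen[li] <- best
      }
    }
    new_alive <- integer()
    for (ci in seq_along(cl)) {
      claimants <- alive[which(chosen == ci)]
      if (length(claimants) == 0L) {
        lineages[[nxt]] <- list(id = nxt, birth = k, end = NA_integer_,
                                parents = integer(),
                                members_now = cl[[ci]],
                                history = list())
        lineages[[nxt]]$history[[as.character(k)]] <- cl[[ci]]
        new_alive <- c(new_alive, nxt)
        nxt <- nxt + 1L
      } else if (length(claimants) == 1L) {
        lineages[[claimants]]$members_now <- cl[[ci]]
        lineages[[claimants]]$history[[as.character(k)]] <- cl[[ci]]
        new_alive <- c(new_alive, claimants)
      } else {
        for (p in claimants) lineages[[p]]$end <- k - 1L
        lineages[[nxt]] <- list(id = nxt, birth = k, end = NA_integer_,
                                parents = claimants,
                                members_now = cl[[ci]],
                                history = list())
        lineages[[nxt]]$history[[as.character(k)]] <- cl[[ci]]
        merges[[length(merges) + 1L]] <-
          list(window = k, t_mid_min = win$t_mid_min, child = nxt,
               parents = claimants)
        new_alive <- c(new_alive, nxt)
        nxt <- nxt + 1L
      }
    }
    for (li in setdiff(alive[is.na(chosen)], new_alive))
      lineages[[li]]$end <- k - 1L
    alive <- new_alive
  }
  for (li in alive)
    lineages[[li]]$end <- length(timecourse$windows)
  structure(list(lineages = lineages, merges = merges,
                 timecourse = timecourse),
            class = "cluster_lineages")
}

#' Detect fusion events from lineage merges
#'
#' For every merge of two or more substantive parent lineages the onset is
#' the time of the first "connected" edge between members of different
#' parents (membership taken at the window before the edge appears, since
#' the first co-aligning aggregate is reassigned in the same window its
#' contact edge arises); completion is the first window from which all
#' parent members move as one cluster for at least `persistence` consecutive
#' windows. A merge with no prior contact edge falls back to the merge time
#' and is flagged.
#'
#' @param lineages a `cluster_lineages`.
#' @param persistence number of consecutive single-cluster windows required
#'   for completion.
#' @param min_parent_size parents smaller than this at merge time are treated
#'   as cluster growth (e.g. a newly nucleated aggregate joining), not
#'   fusion.
#' @param min_parent_age parents alive for fewer windows than this are
#'   ignored: a sub-cluster that flickers into existence while two clusters
#'   unify is part of that fusion, not a fusing cluster itself. Defaults to
#'   `persistence`, mirroring the stability demanded of a completed fusion.
#' @return data.frame of `fusion_event`s sorted by onset: `parent_a`,
#'   `parent_b`, `onset_min`, `completion_min`, `completion_duration_min`,
#'   `merge_min`, `flagged`.
#' @export
detect_fusion_events <- function(lineages, persistence = 5L,
                                 min_parent_size = 2L,
                                 min_parent_age = persistence) {
  stopifnot(inherits(lineages, "cluster_lineages"))
  tc <- lineages$timecourse
  wins <- tc$windows
  members_at <- function(li, k) {
    h <- lineages$lineages[[li]]$history
    ks <- as.integer(names(h))
    ok <- ks[ks <= k]
    if (!length(ok)) return(integer())
    h[[as.character(max(ok))]]
  }
  # membership blurred over the direction-window timescale: an aggregate
  # whose heading is rotating between clusters can briefly belong to neither
  members_recent <- function(li, k) {
    h <- lineages$lineages[[li]]$history
    ks <- as.integer(names(h))
    ok <- ks[ks <= k & ks >= k - tc$window]
    if (!length(ok)) return(members_at(li, k))
    unique(unlist(h[as.character(ok)]))
  }
  out <- list()
  emitted_unions <- list()
  for (m in lineages$merges) {
    par_sizes <- vapply(m$parents, function(p)
      length(members_at(p, m$window - 1L)), integer(1))
    par_ages <- vapply(m$parents, function(p)
      m$window - lineages$lineages[[p]]$birth, integer(1))
    parents <- m$parents[par_sizes >= min_parent_size &
                           par_ages >= min_parent_age]
    if (length(parents) < 2L) next
    p1 <- parents[1L]; p2 <- parents[2L]
    union_members <- unique(unlist(lapply(parents, members_at,
                                          k = m$window - 1L)))
    # a merge adding less than a cluster's worth of members beyond an
    # earlier event's union is that same fusion re-observed after a
    # transient split (possibly with a few newly nucleated aggregates),
    # not a new event
    if (any(vapply(emitted_unions, function(u)
      length(setdiff(union_members, u)) < min_parent_size,
      logical(1)))) next
    emitted_unions[[length(emitted_unions) + 1L]] <- union_members
    birth <- max(vapply(parents, function(p) lineages$lineages[[p]]$birth,
                        integer(1)))
    # onset: first inter-parent connected edge, membership lagged one window
    onset_win <- NA_integer_
    for (k in max(2L, birth):m$window) {
      ed <- wins[[k]]$edges
      if (is.null(ed) || !nrow(ed)) next
      ma <- members_recent(p1, k - 1L); mb <- members_recent(p2, k - 1L)
      conn <- ed[ed$label == "connected", , drop = FALSE]
      hit <- (conn$id_a %in% ma & conn$id_b %in% mb) |
             (conn$id_a %in% mb & conn$id_b %in% ma)
      if (any(hit)) { onset_win <- k; break }
    }
    flagged <- is.na(onset_win)
    if (flagged) onset_win <- m$window
    # completion: union moves as a single cluster, stably
    single_at <- function(k) {
      mem <- wins[[k]]$members
      if (!length(mem)) return(FALSE)
      present <- intersect(union_members, unlist(mem))
      if (!length(present)) return(FALSE)
      hits <- vapply(mem, function(s) any(present %in% s), logical(1))
      sum(hits) == 1L && all(present %in% mem[[which(hits)]])
    }
    comp_win <- NA_integer_
    for (k in onset_win:length(wins)) {
      if (!single_at(k)) next
      horizon <- min(length(wins), k + persistence - 1L)
      if (all(vapply(k:horizon, single_at, logical(1)))) { comp_win <- k; break }
    }
    if (is.na(comp_win)) comp_win <- m$window
    onset <- wins[[onset_win]]$t_mid_min
    compl <- wins[[comp_win]]$t_mid_min
    out[[length(out) + 1L]] <- data.frame(
      parent_a = p1, parent_b = p2,
      onset_min = onset, completion_min = compl,
      completion_duration_min = compl - onset,
      merge_min = m$t_mid_min, flagged = flagged)
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(parent_a = integer(), parent_b = integer(),
                         onset_min = numeric(), completion_min = numeric(),
                         completion_duration_min = numeric(),
                         merge_min = numeric(), flagged = logical())
  res[order(res$onset_min), , drop = FALSE]
}

#' Direction-flagged fold change between condition means
#'
#' Fold changes are reported as ratios at or above 1 with a direction flag:
#' a condition mean below the control is an acceleration (control/condition),
#' above it a delay (condition/control). The rounded fold uses half-up
#' rounding to one decimal, as such tables are conventionally printed; the
#' raw ratio is retained.
#'
#' @param control_mean,condition_mean the two means being compared (same
#'   units).
#' @return list `raw` (ratio >= 1), `fold` (one decimal, half-up),
#'   `direction` ("acceleration", "delay" or "none").
#' @export
fold_change <- function(control_mean, condition_mean) {
  check_number(control_mean, "control_mean", positive = TRUE)
  check_number(condition_mean, "condition_mean", positive = TRUE)
  if (condition_mean < control_mean) {
    raw <- control_mean / condition_mean; dir <- "acceleration"
  } else if (condition_mean > control_mean) {
    raw <- condition_mean / control_mean; dir <- "delay"
  } else {
    raw <- 1; dir <- "none"
  }
  list(raw = raw, fold = round_half_up(raw, 1), direction = dir)
}

#' Summarise fusion events by replicate and condition
#'
#' Replicate means, condition grand means (mean of replicate means) with SEM
#' computed over replicate means, within-replicate SDs, and direction-flagged
#' fold changes of each condition versus the control.
#'
#' @param events data.frame with columns `condition`, `replicate`,
#'   `onset_min`, `completion_duration_min` (one row per fusion event).
#' @param control the control condition label; must be present.
#' @return a `fusion_summary`: list of data.frames `replicates`,
#'   `conditions`, `folds`.
#' @export
summarize_fusion <- function(events, control) {
  stopifnot(is.data.frame(events),
            all(c("condition", "replicate", "onset_min",
                  "completion_duration_min") %in% names(events)))
  if (!control %in% events$condition)
    stop("control condition '", control, "' not present", call. = FALSE)
  reps <- do.call(rbind, lapply(
    split(events, list(events$condition, events$replicate), drop = TRUE),
    function(d) data.frame(
      condition = d$condition[1], replicate = d$replicate[1],
      n_events = nrow(d),
      mean_onset_min = mean(d$onset_min),
      sd_onset_min = if (nrow(d) > 1) sd(d$onset_min) else NA_real_,
      mean_completion_min = mean(d$completion_duration_min),
      sd_completion_min = if (nrow(d) > 1) sd(d$completion_duration_min)
                          else NA_real_)))
  rownames(reps) <- NULL
  conds <- do.call(rbind, lapply(split(reps, reps$condition), function(d) {
    data.frame(
      condition = d$condition[1], n_replicates = nrow(d),
      mean_onset_min = mean(d$mean_onset_min),
      sem_onset_min = if (nrow(d) > 1)
        sd(d$mean_onset_min) / sqrt(nrow(d)) else NA_real_,
      within_sd_onset_min = mean(d$sd_onset_min, na.rm = TRUE),
      mean_completion_min = mean(d$mean_completion_min),
      sem_completion_min = if (nrow(d) > 1)
        sd(d$mean_completion_min) / sqrt(nrow(d)) else NA_real_,
      within_sd_completion_min = mean(d$sd_completion_min, na.rm = TRUE))
  }))
  rownames(conds) <- NULL
  ctrl <- conds[conds$condition == control, ]
  folds <- do.call(rbind, lapply(
    split(conds[conds$condition != control, ], seq_len(sum(conds$condition != control))),
    function(d) {
      fo <- fold_change(ctrl$mean_onset_min, d$mean_onset_min)
      fc <- fold_change(ctrl$mean_completion_min, d$mean_completion_min)
      data.frame(condition = d$condition,
                 onset_fold = fo$fold, onset_raw = fo$raw,
                 onset_direction = fo$direction,
                 completion_fold = fc$fold, completion_raw = fc$raw,
                 completion_direction = fc$direction)
    }))
  if (!is.null(folds)) rownames(folds) <- NULL
  structure(list(replicates = reps, conditions = conds,
                 folds = folds %||% data.frame(), control = control),
            class = "fusion_summary")
}
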