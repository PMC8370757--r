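# Plain-text interchange formats: trajectory / edge / event tables as CSV,
# configs as YAML or JSON, reports as JSON.

#' Write and read trajectory tables
#'
#' Schema: `frame`, `time_h`, `particle_id`, `x_um`, `y_um`, `z_um`,
#' optionally `cluster_id`. Frame geometry travels in a `# key: value`
#' comment header so a series round-trips.
#'
#' @param series a `replicate_series`.
#' @param path CSV file path.
#' @return `write_trajectories` returns `path` invisibly;
#'   `read_trajectories` a `replicate_series`.
#' @export
write_trajectories <- function(series, path) {
  stopifnot(inherits(series, "replicate_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# replicate_id: %s", series$replicate_id),
    sprintf("# frame_interval_min: %.10g", series$frame_interval),
    sprintf("# field_x_um: %.10g", series$field_size[1]),
    sprintf("# field_y_um: %.10g", series$field_size[2]),
    sprintf("# duration_h: %.10g", series$duration)), con)
  write.csv(series$trajectories, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get <- function(key, default = NA) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(default)
    sub(paste0("^# ", key, ": *"), "", ln[1])
  }
  df <- read.csv(path, comment.char = "#")
  new_replicate_series(
    df,
    frame_interval = as.numeric(get("frame_interval_min", 1)),
    field_size = c(as.numeric(get("field_x_um", max(df$x_um))),
                   as.numeric(get("field_y_um", max(df$y_um)))),
    duration = as.numeric(get("duration_h", max(df$time_h))),
    replicate_id = get("replicate_id", "imported"))
}

#' Write a rheology trace or frequency sweep as CSV
#'
#' Time sweeps use columns `time_h`, `g_prime_pa`, `g_double_prime_pa`;
#' frequency sweeps `omega_rad_s`, `g_prime_pa`, `g_double_prime_pa`.
#'
#' @param x a `rheology_trace` or `frequency_sweep`.
#' @param path CSV file path.
#' @export
write_rheology <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rheology
#' @export
read_rheology <- function(path) {
  df <- read.csv(path)
  if ("time_h" %in% names(df)) new_rheology_trace(df)
  else frequency_sweep(df$omega_rad_s, df$g_prime_pa, df$g_double_prime_pa)
}

#' Write connectivity edges as CSV
#'
#' Columns: `frame_start`, `frame_end`, `id_a`, `id_b`, `label`.
#'
#' @param timecourse a `cluster_timecourse`.
#' @param path CSV file path.
#' @export
write_edges <- function(timecourse, path) {
  stopifnot(inherits(timecourse, "cluster_timecourse"))
  w <- timecourse$window
  rows <- lapply(seq_along(timecourse$windows), function(k) {
    ed <- timecourse$windows[[k]]$edges
    if (is.null(ed) || !nrow(ed)) return(NULL)
    data.frame(frame_start = k - 1L, frame_end = k - 1L + w,
               id_a = ed$id_a, id_b = ed$id_b, label = ed$label)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(frame_start = integer(), frame_end = integer(),
                      id_a = integer(), id_b = integer(),
                      label = character())
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return the configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
}
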