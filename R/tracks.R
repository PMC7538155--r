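#' Nuclear track tables
#'
#' Tracks are stored as a plain data frame with one row per (nucleus, frame):
#' columns `track_id`, `parent_id` (-1 for founders), `t_min`, `x_um`,
#' `y_um`, `z_um`. Within each track, times are strictly increasing with a
#' uniform frame interval. This mirrors the output of 3-D nuclear tracking
#' pipelines (sequentially connected nuclear center coordinates plus lineage).
#'
#' @name tracks
NULL

track_columns <- c("track_id", "parent_id", "t_min", "x_um", "y_um", "z_um")

#' Validate a track table
#'
#' Checks column presence, per-track strictly increasing uniformly spaced
#' times, and lineage integrity (every non-missing `parent_id` refers to an
#' existing track; a parent is referenced by exactly two daughters).
#'
#' @param tracks a track data frame (see [tracks]).
#' @param check_divisions if `TRUE`, require that any referenced parent has
#'   exactly two daughters.
#' @return `tracks`, invisibly; errors name the offending record.
#' @export
validate_tracks <- function(tracks, check_divisions = TRUE) {
  missing_cols <- setdiff(track_columns, names(tracks))
  if (length(missing_cols)) {
    stop("track table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(tracks) == 0L) {
    return(invisible(tracks))
  }
  if (anyNA(tracks[track_columns])) stop("track table contains NA values")
  ids <- unique(tracks$track_id)
  by_id <- split(tracks$t_min, tracks$track_id)
  for (id in names(by_id)) {
    dt <- diff(sort(by_id[[id]]))
    if (length(dt) && any(dt <= 0)) {
      stop("track ", id, ": non-monotone time stamps")
    }
    if (length(dt) > 1L && diff(range(dt)) > 1e-6 * mean(dt)) {
      stop("track ", id, ": non-uniform frame interval")
    }
  }
  first <- tracks[!duplicated(tracks$track_id), , drop = FALSE]
  parents <- first$parent_id[first$parent_id >= 0]
  dangling <- setdiff(parents, ids)
  if (length(dangling)) {
    stop("dangling parent_id: ", paste(dangling, collapse = ", "))
  }
  if (check_divisions && length(parents)) {
    tab <- table(parents)
    bad <- names(tab)[tab != 2L]
    if (length(bad)) {
      stop(
        "parent track(s) with a daughter count other than two: ",
        paste(bad, collapse = ", ")
      )
    }
  }
  invisible(tracks)
}

#' Write nuclear tracks to CSV
#'
#' Header `track_id,parent_id,t_min,x_um,y_um,z_um`; missing parent encoded
#' as -1; UTF-8. Coordinates are written with enough digits for a bit-exact
#' round trip at 1e-6 µm.
#'
#' @param tracks a validated track table.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  validate_tracks(tracks, check_divisions = FALSE)
  out <- tracks[track_columns]
  for (col in c("t_min", "x_um", "y_um", "z_um")) {
    out[[col]] <- formatC(out[[col]], format = "g", digits = 12)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read nuclear tracks from CSV
#'
#' @param path file written by [write_tracks()] (or any file with the same
#'   header).
#' @param check_divisions passed to [validate_tracks()].
#' @return A validated track data frame.
#' @export
read_tracks <- function(path, check_divisions = FALSE) {
  tracks <- utils::read.csv(path, fileEncoding = "UTF-8")
  validate_tracks(tracks, check_divisions = check_divisions)
  tracks[order(tracks$track_id, tracks$t_min), , drop = FALSE]
}
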