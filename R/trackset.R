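#' Construct a single-particle trajectory
#'
#' A trajectory is the time-stamped 2D path of one tracked particle
#' (a chromosomal locus or an mRNP spot), with positions in micrometres
#' and a uniform frame interval.
#'
#' @param id Integer label, unique within a [trackset()].
#' @param times Numeric vector of acquisition times in seconds; strictly
#'   increasing with uniform spacing.
#' @param x,y Numeric vectors of positions in micrometres, same length as
#'   `times`.
#' @return An object of class `trajectory`: a data frame with columns
#'   `t_s`, `x_um`, `y_um` and attributes `id` and `dt`.
#' @export
trajectory <- function(id, times, x, y) {
  id <- as.integer(id)
  stopifnot(length(id) == 1L, !is.na(id))
  n <- length(times)
  if (n < 2L)
    stop("a trajectory needs at least 2 time points")
  if (length(x) != n || length(y) != n)
    stop("times, x and y must have equal length")
  if (!all(is.finite(times)) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("trajectory coordinates and times must be finite")
  dts <- diff(times)
  if (any(dts <= 0))
    stop("times must be strictly increasing")
  if (max(dts) - min(dts) > 1e-9)
    stop("time spacing must be uniform to within 1e-9 s")
  out <- data.frame(t_s = as.numeric(times), x_um = as.numeric(x),
                    y_um = as.numeric(y))
  attr(out, "id") <- id
  attr(out, "dt") <- mean(dts)
  class(out) <- c("trajectory", "data.frame")
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %d: %d frames, dt = %g s>\n",
              attr(x, "id"), nrow(x), attr(x, "dt")))
  invisible(x)
}

#' Construct a set of trajectories sharing one acquisition
#'
#' @param trajectories List of [trajectory()] objects with unique ids and a
#'   common frame interval.
#' @param frame_interval Frame interval in seconds.
#' @param pixel_size Pixel size in micrometres per pixel (used only when
#'   rendering to, or reading from, images).
#' @param condition_label Free-text condition label (e.g. `"+glucose"`).
#' @return An object of class `trackset`.
#' @export
trackset <- function(trajectories, frame_interval, pixel_size = 0.1067,
                     condition_label = "") {
  stopifnot(is.list(trajectories), length(trajectories) >= 1L)
  ids <- vapply(trajectories, function(tr) attr(tr, "id"), integer(1))
  if (anyDuplicated(ids))
    stop("trajectory ids must be unique within a trackset")
  dts <- vapply(trajectories, function(tr) attr(tr, "dt"), numeric(1))
  if (any(abs(dts - frame_interval) > 1e-9))
    stop("all trajectories must share the trackset frame_interval")
  structure(
    list(trajectories = trajectories,
         frame_interval = frame_interval,
         pixel_size = pixel_size,
         condition_label = condition_label),
    class = "trackset")
}

#' @export
print.trackset <- function(x, ...) {
  lens <- vapply(x$trajectories, nrow, integer(1))
  cat(sprintf("<trackset '%s': %d trajectories, %d-%d frames, dt = %g s>\n",
              x$condition_label, length(x$trajectories),
              min(lens), max(lens), x$frame_interval))
  invisible(x)
}

#' @export
length.trackset <- function(x) length(x$trajectories)

#' Flatten a trackset to a long data frame
#'
#' @param x A `trackset`.
#' @param ... Unused.
#' @return Data frame with columns `track_id,frame,t_s,x_um,y_um` (frames are
#'   0-based).
#' @export
as.data.frame.trackset <- function(x, ...) {
  do.call(rbind, lapply(x$trajectories, function(tr) {
    data.frame(track_id = attr(tr, "id"),
               frame = seq_len(nrow(tr)) - 1L,
               t_s = tr$t_s, x_um = tr$x_um, y_um = tr$y_um)
  }))
}

#' Write trajectories to CSV
#'
#' Uses the interchange schema `track_id,frame,t_s,x_um,y_um`.
#'
#' @param tracks A `trackset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read trajectories from CSV
#'
#' @param path CSV with columns `track_id,frame,t_s,x_um,y_um`.
#' @param pixel_size,condition_label Metadata for the resulting `trackset`.
#' @return A `trackset`.
#' @export
read_tracks <- function(path, pixel_size = 0.1067, condition_label = "") {
  df <- utils::read.csv(path)
  need <- c("track_id", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns track_id,frame,t_s,x_um,y_um")
  trs <- lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$t_s), ]
    trajectory(d$track_id[1], d$t_s, d$x_um, d$y_um)
  })
  names(trs) <- NULL
  dt <- attr(trs[[1]], "dt")
  trackset(trs, frame_interval = dt, pixel_size = pixel_size,
           condition_label = condition_label)
}
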