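#' Construct a pose time series
#'
#' A `pose_series` holds one person's tracked upper-body keypoints over time:
#' a `T x 7 x 2` coordinate array (pixels, image convention: y increases
#' downward) and a `T x 7` confidence matrix with values in `[0, 1]`.
#' Joints follow the canonical order of [dyad_joints()].
#'
#' Samples with confidence 0 encode "keypoint not detected in this frame";
#' their coordinates are ignored by downstream measures.
#'
#' @param coords numeric array `T x 7 x 2` (x then y on the third axis).
#' @param conf numeric matrix `T x 7`, entries in `[0, 1]`.
#' @param fps frames per second (default 60; never inferred from data).
#' @param person_id label for the tracked person.
#' @return An object of class `pose_series`.
#' @export
pose_series <- function(coords, conf, fps = 60, person_id = "p") {
  coords <- unname(coords)
  conf <- unname(as.matrix(conf))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 7 || dim(coords)[3] != 2)
    stop_dyadsync("coords must be a T x 7 x 2 array")
  if (!all(dim(conf) == dim(coords)[1:2]))
    stop_dyadsync("conf must be a T x 7 matrix matching coords")
  if (dim(coords)[1] < 1) stop_dyadsync("a pose series needs at least one frame (T >= 1)")
  if (!is.numeric(fps) || fps <= 0) stop_dyadsync("fps must be > 0")
  if (any(conf < 0 | conf > 1, na.rm = TRUE))
    stop_dyadsync("confidences must lie in [0, 1]")
  bad <- conf > 0 & (!is.finite(coords[, , 1]) | !is.finite(coords[, , 2]))
  if (any(bad)) stop_dyadsync("coordinates must be finite wherever confidence > 0")
  structure(
    list(coords = coords, conf = conf, fps = fps, person_id = person_id,
         joints = DYADSYNC_JOINTS, smoothed = FALSE),
    class = "pose_series"
  )
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf("<pose_series> person '%s': %d frames @ %g fps, 7 joints%s\n",
              x$person_id, n_frames(x), x$fps,
              if (isTRUE(x$smoothed)) " (smoothed)" else ""))
  invisible(x)
}

#' Number of frames in a pose series or dyad recording
#' @param x a `pose_series` or `dyad_recording`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.pose_series <- function(x) dim(x$coords)[1]

#' @export
n_frames.dyad_recording <- function(x) dim(x$series_a$coords)[1]

#' Construct a dyad recording
#'
#' Two aligned single-person pose series plus metadata about the dyad and
#' the task it performed: `"mirroring"` (the mirror game, high synchrony) or
#' `"observing"` (one partner watches the other move, low synchrony).
#'
#' @param series_a,series_b `pose_series` objects of equal length and fps.
#'   By convention `series_a` is the left-hand figure.
#' @param dyad_id,leader_id identifier labels.
#' @param condition `"mirroring"` or `"observing"`.
#' @return An object of class `dyad_recording`.
#' @export
dyad_recording <- function(series_a, series_b, dyad_id = "dyad",
                           leader_id = "leader",
                           condition = c("mirroring", "observing")) {
  condition <- match.arg(condition)
  if (!inherits(series_a, "pose_series") || !inherits(series_b, "pose_series"))
    stop_dyadsync("series_a and series_b must be pose_series objects")
  if (n_frames(series_a) != n_frames(series_b))
    stop_dyadsync("the two series must have the same number of frames")
  if (series_a$fps != series_b$fps)
    stop_dyadsync("the two series must share a frame rate")
  structure(
    list(dyad_id = dyad_id, leader_id = leader_id, condition = condition,
         series_a = series_a, series_b = series_b),
    class = "dyad_recording"
  )
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat(sprintf("<dyad_recording> '%s' (leader '%s', %s): %d frames @ %g fps\n",
              x$dyad_id, x$leader_id, x$condition, n_frames(x), x$series_a$fps))
  invisible(x)
}
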