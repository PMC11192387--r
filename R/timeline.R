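#' Acquisition timeline of a time-lapse movie
#'
#' Holds the mapping between frame indices, clock time and experiment days.
#' The defaults mirror a common confocal protocol: one picture every
#' 10 minutes over 3 days, i.e. 144 frames per day and 432 frames in total.
#'
#' @param frame_interval_min Minutes between consecutive frames (default 10).
#' @param frames_per_day Frames in one day; defaults to
#'   `round(24 * 60 / frame_interval_min)`.
#' @param total_frames Last frame index of the movie (default 432). Usually
#'   set to the forest's final frame when analysing a file.
#' @return A `timeline` object (list with `frame_interval_min`,
#'   `frames_per_day`, `total_frames`, `n_days`).
#' @examples
#' timeline()                       # 10 min, 144 frames/day, 432 frames
#' timeline(frame_interval_min = 15)
#' @export
timeline <- function(frame_interval_min = 10,
                     frames_per_day = NULL,
                     total_frames = 432L) {
  if (!is.numeric(frame_interval_min) || frame_interval_min <= 0) {
    abort("frame_interval_min must be a positive number", class = "cladotrace_error")
  }
  if (is.null(frames_per_day)) {
    frames_per_day <- as.integer(round(24 * 60 / frame_interval_min))
  }
  frames_per_day <- as.integer(frames_per_day)
  total_frames <- as.integer(total_frames)
  if (frames_per_day <= 0L) {
    abort("frames_per_day must be a positive integer", class = "cladotrace_error")
  }
  if (total_frames < 0L) {
    abort("total_frames must be non-negative", class = "cladotrace_error")
  }
  structure(
    list(frame_interval_min = frame_interval_min,
         frames_per_day = frames_per_day,
         total_frames = total_frames,
         n_days = max(1L, as.integer(ceiling(total_frames / frames_per_day)))),
    class = "timeline")
}

default_timeline <- function(total_frames) timeline(total_frames = total_frames)

#' @export
print.timeline <- function(x, ...) {
  cat(sprintf("<timeline> %g min/frame, %d frames/day, %d frames (%d day(s), %g h)\n",
              x$frame_interval_min, x$frames_per_day, x$total_frames,
              x$n_days, frames_to_hours(x, x$total_frames)))
  invisible(x)
}

#' Convert a frame count to hours
#'
#' @param timeline A [timeline()].
#' @param n_frames Non-negative frame count(s).
#' @return Hours (`n_frames * frame_interval_min / 60`), vectorised.
#' @examples
#' frames_to_hours(timeline(), 432)  # 72
#' @export
frames_to_hours <- function(timeline, n_frames) {
  stopifnot(inherits(timeline, "timeline"))
  if (any(n_frames < 0)) abort("n_frames must be non-negative", class = "cladotrace_error")
  n_frames * timeline$frame_interval_min / 60
}

#' Day index of a frame
#'
#' Days are half-open frame windows `[k*fpd, (k+1)*fpd)`, 1-based; the
#' terminal frame is assigned to the last day so end-of-movie events remain
#' countable.
#'
#' @param timeline A [timeline()].
#' @param frame Frame index (vectorised), `0 <= frame <= total_frames`.
#' @return Integer day index in `1..n_days`.
#' @examples
#' day_of_frame(timeline(), c(0, 287, 432))  # 1, 2, 3
#' @export
day_of_frame <- function(timeline, frame) {
  stopifnot(inherits(timeline, "timeline"))
  if (any(frame < 0 | frame > timeline$total_frames)) {
    abort(sprintf("frame out of range [0, %d]", timeline$total_frames),
          class = "cladotrace_error")
  }
  pmin(as.integer(frame %/% timeline$frames_per_day) + 1L, timeline$n_days)
}
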