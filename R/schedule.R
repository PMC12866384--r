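#' Frame schedules for dynamic acquisitions
#'
#' A frame schedule lists acquisition frames as `(start_min, duration_min)`
#' pairs relative to tracer injection (injection time = 0). Frames must not
#' overlap, durations must be positive and starts non-decreasing.
#'
#' @param start_min numeric vector of frame start times, minutes post-injection.
#' @param duration_min numeric vector of frame durations, minutes.
#' @return A `frame_schedule` object (a data.frame with columns `start`,
#'   `duration`, `mid`, `end`).
#' @examples
#' sch <- frame_schedule(c(0, 1, 2), c(1, 1, 1))
#' frame_midpoints(sch)
#' @export
frame_schedule <- function(start_min, duration_min) {
  if (length(start_min) != length(duration_min) || length(start_min) < 1L)
    stop("start_min and duration_min must be equal-length, non-empty vectors")
  if (any(duration_min <= 0)) stop("frame durations must be > 0")
  if (is.unsorted(start_min)) stop("frame starts must be non-decreasing")
  end <- start_min + duration_min
  if (any(utils::head(end, -1L) > utils::tail(start_min, -1L) + 1e-9))
    stop("frames must not overlap")
  out <- data.frame(start = start_min, duration = duration_min,
                    mid = start_min + duration_min / 2, end = end)
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' Default acquisition frame schedule
#'
#' Reproduces the acquisition structure of the emulated protocol: a 5-min
#' dynamic scan (20 x 15 s) starting at injection, a 55-min dynamic scan
#' (11 x 5 min) from 10 to 65 min, and 15-min static frames at 90 and
#' 150 min. The gap (5, 10) min contains no frames (patient repositioning).
#'
#' @return A [frame_schedule()] with 33 frames.
#' @export
default_frame_schedule <- function() {
  frame_schedule(
    start_min    = c(seq(0, 4.75, by = 0.25), seq(10, 60, by = 5), 90, 150),
    duration_min = c(rep(0.25, 20),           rep(5, 11),          15, 15)
  )
}

#' @rdname frame_schedule
#' @param schedule a `frame_schedule`.
#' @export
frame_midpoints <- function(schedule) schedule$mid

#' Split a frame schedule into contiguous segments
#'
#' Segments are maximal runs of frames with no temporal gap between them
#' (end of one frame equals start of the next). The default schedule splits
#' into four segments: 0--5, 10--65, 90--105 and 150--165 min.
#'
#' @param schedule a `frame_schedule`.
#' @return integer vector of segment indices, one per frame.
#' @export
schedule_segments <- function(schedule) {
  n <- nrow(schedule)
  if (n == 1L) return(1L)
  gap <- schedule$start[-1L] - schedule$end[-n] > 1e-9
  cumsum(c(TRUE, gap))
}

#' @export
print.frame_schedule <- function(x, ...) {
  seg <- schedule_segments(x)
  cat(sprintf("Frame schedule: %d frames in %d segment(s), %.4g-%.4g min\n",
              nrow(x), max(seg), min(x$start), max(x$end)))
  invisible(x)
}
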