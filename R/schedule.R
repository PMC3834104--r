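#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule records the start time and duration of every scan frame,
#' in minutes. Frames must be contiguous (each frame starts where the
#' previous one ends) and have positive duration. Model predictions and
#' simulated time-activity curves are evaluated at the frame mid-times.
#'
#' @param start numeric vector of frame start times (minutes), first >= 0.
#' @param duration numeric vector of frame durations (minutes), all > 0.
#' @return An object of class `"frame_schedule"`: a list with elements
#'   `start`, `duration` and the derived `mid` (mid-frame times).
#' @seealso [pib_schedule()] for the standard 19-frame/90-min protocol.
#' @export
#' @examples
#' sch <- frame_schedule(c(0, 1, 2), c(1, 1, 2))
#' mid_times(sch)
frame_schedule <- function(start, duration) {
  start <- as.numeric(start)
  duration <- as.numeric(duration)
  if (length(start) != length(duration) || length(start) == 0L)
    stop("'start' and 'duration' must be non-empty vectors of equal length")
  if (anyNA(start) || anyNA(duration) || any(!is.finite(start)) ||
      any(!is.finite(duration)))
    stop("frame times must be finite")
  if (any(duration <= 0))
    stop("all frame durations must be positive")
  if (start[1L] < 0)
    stop("first frame must not start before time 0")
  n <- length(start)
  if (n > 1L) {
    gap <- start[-1L] - (start[-n] + duration[-n])
    if (any(abs(gap) > 1e-9)) {
      bad <- which(abs(gap) > 1e-9)[1L]
      stop(sprintf("frames must be contiguous: frame %d ends at %.6g but frame %d starts at %.6g",
                   bad, start[bad] + duration[bad], bad + 1L, start[bad + 1L]))
    }
  }
  structure(list(start = start, duration = duration,
                 mid = start + duration / 2),
            class = "frame_schedule")
}

#' Standard 19-frame, 90-minute PIB acquisition schedule
#'
#' The dynamic protocol used throughout the simulation studies:
#' 3 x 20 s, 3 x 40 s, 1 x 1 min, 2 x 3 min, 5 x 6 min and 5 x 10 min,
#' spanning 90 min in total. The first 14 frames span the first 40 min,
#' which is the default fit window of the short-scan analyses.
#'
#' @return A [frame_schedule()] with 19 frames.
#' @export
pib_schedule <- function() {
  duration <- c(rep(1 / 3, 3), rep(2 / 3, 3), 1, rep(3, 2), rep(6, 5),
                rep(10, 5))
  frame_schedule(start = cumsum(c(0, duration[-length(duration)])),
                 duration = duration)
}

#' Frame mid-times of a schedule
#' @param schedule a [frame_schedule()].
#' @return Numeric vector of mid-frame times in minutes.
#' @export
mid_times <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  schedule$mid
}

#' @export
print.frame_schedule <- function(x, ...) {
  n <- length(x$start)
  cat(sprintf("PET frame schedule: %d frames, %.4g to %.4g min\n",
              n, x$start[1L], x$start[n] + x$duration[n]))
  invisible(x)
}

#' @export
length.frame_schedule <- function(x) length(x$start)

#' @export
as.data.frame.frame_schedule <- function(x, ...) {
  data.frame(frame_start = x$start, frame_duration = x$duration,
             frame_mid = x$mid)
}
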