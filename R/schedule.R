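#' Burst-phase DCE-MRI acquisition schedule
#'
#' Describes an acquisition in which short bursts ("phases") of
#' `frames_per_phase` images are acquired over `phase_duration` seconds each.
#' The default reproduces a liver protocol with ten phases: one pre-contrast
#' burst, one hepatic arterial-dominant burst, and bursts starting 60, 120,
#' 180, 240, 330, 420, 510 and 600 s after contrast injection. Time zero is
#' the moment of injection; pre-contrast frames carry negative times.
#'
#' The arterial-dominant phase has no protocol-fixed absolute time (it is set
#' per patient by a monitoring scan in practice); the default places it at
#' 20-50 s post-injection so that a bolus arriving at ~20 s peaks inside it.
#'
#' @param phase_starts start time (s, relative to injection) of each burst.
#' @param frames_per_phase number of frames per burst.
#' @param phase_duration burst duration in seconds.
#' @return An object of class `acq_schedule` with the derived `frame_times`
#'   (frame midpoints, strictly increasing).
#' @examples
#' sched <- acq_schedule()
#' length(sched$frame_times) # 50 frames
#' @export
acq_schedule <- function(phase_starts = c(-30, 20, 60, 120, 180, 240, 330, 420, 510, 600),
                         frames_per_phase = 5L,
                         phase_duration = 30) {
  if (is.unsorted(phase_starts, strictly = TRUE))
    dce_validation_error("phase_starts must be strictly increasing")
  if (frames_per_phase < 1L || phase_duration <= 0)
    dce_validation_error("frames_per_phase and phase_duration must be positive")
  frame_dt <- phase_duration / frames_per_phase
  mids <- (seq_len(frames_per_phase) - 0.5) * frame_dt
  frame_times <- as.vector(outer(mids, phase_starts, `+`))
  if (is.unsorted(frame_times, strictly = TRUE))
    dce_validation_error("phases overlap: frame times are not strictly increasing")
  structure(
    list(phase_starts = phase_starts,
         frames_per_phase = as.integer(frames_per_phase),
         phase_duration = phase_duration,
         frame_times = frame_times),
    class = "acq_schedule")
}

#' Number of pre-contrast (baseline) frames in a schedule
#'
#' @param schedule an [acq_schedule()].
#' @return Count of frames acquired before injection (time < 0).
#' @export
n_baseline_frames <- function(schedule) {
  stopifnot(inherits(schedule, "acq_schedule"))
  sum(schedule$frame_times < 0)
}

#' @export
print.acq_schedule <- function(x, ...) {
  cat("<acq_schedule> ", length(x$phase_starts), " phases x ",
      x$frames_per_phase, " frames (", x$phase_duration, " s each); ",
      n_baseline_frames(x), " pre-contrast frames\n", sep = "")
  invisible(x)
}
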