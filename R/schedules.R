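#' Saturation schedules
#'
#' A saturation schedule describes one CEST-type acquisition: the ordered
#' saturation offsets (in ppm relative to water), any far-off-resonance
#' reference offsets used for normalization, and the continuous-wave
#' saturation pulse (amplitude in microtesla, duration in seconds).
#'
#' @param offsets_ppm Strictly monotone numeric vector of saturation offsets
#'   (ppm relative to water).
#' @param reference_offsets_ppm Numeric vector of reference offsets (ppm),
#'   e.g. `c(-1000, 1000)`; must lie outside the sampled offset range.
#' @param b1_amplitude Saturation amplitude in microtesla (>= 0).
#' @param sat_duration Saturation duration in seconds (> 0).
#'
#' @return An object of class `saturation_schedule`.
#' @seealso [make_offset_schedule()], [cest_schedule()], [wassr_schedule()]
#' @export
saturation_schedule <- function(offsets_ppm, reference_offsets_ppm = numeric(),
                                b1_amplitude, sat_duration) {
  if (!is.numeric(offsets_ppm) || length(offsets_ppm) < 1L || !all(is.finite(offsets_ppm)))
    stopf("offsets_ppm must be a non-empty finite numeric vector")
  d <- diff(offsets_ppm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stopf("offsets_ppm must be strictly monotone")
  if (!is_number(b1_amplitude) || b1_amplitude < 0)
    stopf("b1_amplitude must be a single number >= 0 (microtesla)")
  if (!is_number(sat_duration) || sat_duration <= 0)
    stopf("sat_duration must be a single positive number (seconds)")
  if (length(reference_offsets_ppm)) {
    rng <- range(offsets_ppm)
    inside <- reference_offsets_ppm >= rng[1] & reference_offsets_ppm <= rng[2]
    if (any(inside))
      stopf("reference offsets must lie outside the sampled range [%g, %g] ppm",
            rng[1], rng[2])
  }
  structure(
    list(offsets_ppm = as.numeric(offsets_ppm),
         reference_offsets_ppm = as.numeric(reference_offsets_ppm),
         b1_amplitude = b1_amplitude,
         sat_duration = sat_duration),
    class = "saturation_schedule")
}

#' Build a linearly spaced saturation schedule
#'
#' Offsets run from `start_ppm` to `stop_ppm` inclusive in steps of
#' `step_ppm`; reference offsets are appended to the schedule's frame list
#' but kept separate from the sampled range.
#'
#' @param start_ppm,stop_ppm First and last sampled offset (ppm); requires
#'   `stop_ppm >= start_ppm`.
#' @param step_ppm Step size in ppm (> 0).
#' @param reference_offsets Numeric vector of reference offsets (ppm).
#' @param b1 Saturation amplitude (microtesla).
#' @param duration Saturation duration (seconds).
#'
#' @return A [saturation_schedule()].
#' @examples
#' sched <- make_offset_schedule(1.2, 6.6, 0.1, c(-1000, 1000), 1.5, 4)
#' n_frames(sched)  # 57: 55 sampled offsets plus 2 references
#' @export
make_offset_schedule <- function(start_ppm, stop_ppm, step_ppm,
                                 reference_offsets = numeric(),
                                 b1, duration) {
  if (!is_number(step_ppm) || step_ppm <= 0) stopf("step_ppm must be > 0")
  if (!is_number(start_ppm) || !is_number(stop_ppm) || stop_ppm < start_ppm)
    stopf("stop_ppm must be >= start_ppm")
  n <- round((stop_ppm - start_ppm) / step_ppm) + 1L
  offsets <- start_ppm + step_ppm * (seq_len(n) - 1L)
  saturation_schedule(offsets, reference_offsets, b1, duration)
}

#' Number of frames acquired under a schedule (sampled offsets + references)
#' @param schedule A [saturation_schedule()].
#' @return Integer frame count.
#' @export
n_frames <- function(schedule) {
  stopifnot(inherits(schedule, "saturation_schedule"))
  length(schedule$offsets_ppm) + length(schedule$reference_offsets_ppm)
}

#' Default CEST saturation schedule
#'
#' 1.2 to 6.6 ppm in 0.1-ppm steps (55 offsets) plus -1000/+1000 ppm
#' reference frames; continuous-wave saturation at 1.5 uT for 4 s.
#' @return A [saturation_schedule()].
#' @export
cest_schedule <- function() {
  make_offset_schedule(1.2, 6.6, 0.1, c(-1000, 1000), b1 = 1.5, duration = 4)
}

#' Default WASSR saturation schedule
#'
#' 41 linearly spaced offsets from -0.6 to +0.6 ppm (0.03-ppm steps),
#' low-power saturation at 0.2 uT for 100 ms, no reference frames:
#' WASSR stacks are normalized against the reference image of the
#' companion CEST acquisition (see [normalize_by_reference()]).
#' @return A [saturation_schedule()].
#' @export
wassr_schedule <- function() {
  make_offset_schedule(-0.6, 0.6, 0.03, numeric(), b1 = 0.2, duration = 0.1)
}

#' @export
print.saturation_schedule <- function(x, ...) {
  cat(sprintf("<saturation_schedule> %d offsets [%g, %g] ppm, %d reference(s), B1 = %g uT, t_sat = %g s\n",
              length(x$offsets_ppm), min(x$offsets_ppm), max(x$offsets_ppm),
              length(x$reference_offsets_ppm), x$b1_amplitude, x$sat_duration))
  invisible(x)
}
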