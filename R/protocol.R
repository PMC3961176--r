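# Time-dependent stimulus protocols: square pulse, pulse train, constant.

#' Stimulus protocols
#'
#' A protocol maps time (minutes) to a stimulus value: `baseline` outside
#' pulses and `amplitude` inside.  A pulse occupies the half-open window
#' `[start, start + pulse_duration)`.  For pulse trains the
#' `interstimulus_interval` is, by default, the gap between the end of one
#' pulse and the onset of the next (`"offset_to_onset"`); set
#' `interval_semantics = "onset_to_onset"` to interpret it as the pulse
#' period instead.
#'
#' @param amplitude Stimulus value inside pulses; must be `>= baseline`.
#' @param baseline Stimulus value outside pulses (default 0); must be `>= 0`.
#' @param onset Time of the first pulse onset, minutes (default 0).
#' @param duration,pulse_duration Pulse width in minutes; must be positive.
#' @param n_pulses Number of pulses (`>= 1`).
#' @param interstimulus_interval Interval between pulses, minutes; see above.
#' @param interval_semantics `"offset_to_onset"` (gap, default) or
#'   `"onset_to_onset"` (period).
#' @param level Constant stimulus value.
#' @return An object of class `stimulus_protocol`.
#' @examples
#' p <- square_pulse(amplitude = 1, duration = 10)
#' protocol_value(p, c(-1, 0, 5, 9.99, 10, 11))
#' @name stimulus_protocol
NULL

.new_protocol <- function(kind, baseline, amplitude, onset, duration,
                          n_pulses, gap, interval_semantics) {
  stopifnot(is.numeric(baseline), is.numeric(amplitude))
  if (duration <= 0) stop("pulse_duration must be positive")
  if (n_pulses < 1) stop("n_pulses must be >= 1")
  if (baseline < 0) stop("baseline must be >= 0")
  if (amplitude < baseline) stop("amplitude must be >= baseline")
  if (gap < 0) stop("interstimulus gap must be >= 0 (for onset_to_onset ",
                    "semantics the interval must exceed the pulse duration)")
  structure(list(kind = kind, baseline = baseline, amplitude = amplitude,
                 onset = onset, pulse_duration = duration,
                 n_pulses = as.integer(n_pulses), gap = gap,
                 interval_semantics = interval_semantics),
            class = "stimulus_protocol")
}

#' @rdname stimulus_protocol
#' @export
square_pulse <- function(amplitude, duration = 10, onset = 0, baseline = 0) {
  .new_protocol("square_pulse", baseline, amplitude, onset, duration,
                1L, 0, "offset_to_onset")
}

#' @rdname stimulus_protocol
#' @export
pulse_train <- function(amplitude, baseline = 0, n_pulses, pulse_duration,
                        interstimulus_interval, onset = 0,
                        interval_semantics = c("offset_to_onset",
                                               "onset_to_onset")) {
  interval_semantics <- match.arg(interval_semantics)
  gap <- if (interval_semantics == "offset_to_onset") interstimulus_interval
         else interstimulus_interval - pulse_duration
  .new_protocol("pulse_train", baseline, amplitude, onset, pulse_duration,
                n_pulses, gap, interval_semantics)
}

#' @rdname stimulus_protocol
#' @export
constant_stimulus <- function(level) {
  structure(list(kind = "constant", baseline = level, amplitude = level,
                 onset = 0, pulse_duration = 1, n_pulses = 0L, gap = 0,
                 interval_semantics = "offset_to_onset"),
            class = "stimulus_protocol")
}

# Pack for the C++ cores: c(base, amp, onset, dur, n, gap).
.proto_vec <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  c(protocol$baseline, protocol$amplitude, protocol$onset,
    protocol$pulse_duration, protocol$n_pulses, protocol$gap)
}

#' @rdname stimulus_protocol
#' @param protocol A `stimulus_protocol`.
#' @param t Numeric vector of times (minutes).
#' @export
protocol_value <- function(protocol, t) {
  .protocol_value_cpp(.proto_vec(protocol), as.numeric(t))
}

#' Total span of a protocol (onset of first pulse to offset of last), minutes
#' @param protocol A `stimulus_protocol`.
#' @export
protocol_span <- function(protocol) {
  if (protocol$n_pulses == 0L) return(0)
  protocol$onset + protocol$n_pulses * protocol$pulse_duration +
    (protocol$n_pulses - 1L) * protocol$gap
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  if (x$kind == "constant") {
    cat("Constant stimulus, level", x$baseline, "\n")
  } else {
    cat(sprintf("%s: %d pulse(s) of %g min, amplitude %g (baseline %g)",
                x$kind, x$n_pulses, x$pulse_duration, x$amplitude,
                x$baseline))
    if (x$n_pulses > 1L)
      cat(sprintf(", %g min offset-to-onset gap", x$gap))
    if (x$onset != 0) cat(sprintf(", onset %g min", x$onset))
    cat("\n")
  }
  invisible(x)
}
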