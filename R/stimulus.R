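# Piecewise stimulus waveforms S(t). A protocol is an ordered set of
# non-overlapping segments on half-open intervals [start, end); each segment
# is linear in t (squares/holds are constant, ramps interpolate s0 -> s1).
# S(t) = 0 outside all segments, and evaluation at a boundary takes the
# right-side value, so abutting pulses never double-count.

#' Construct a stimulus protocol from raw segments
#'
#' @param segments `data.frame` with columns `start`, `end` (s) and `s0`, `s1`
#'   (stimulus level at the segment's start/end; dimensionless, relative to
#'   the reference magnitude alpha = 1).
#' @return An `ash_protocol` (the validated, sorted segment table).
#' @export
ash_protocol <- function(segments) {
  if (nrow(segments)) {
    stopifnot(all(c("start", "end", "s0", "s1") %in% names(segments)))
    if (any(segments$end <= segments$start)) stop("segment duration must be > 0")
    if (any(segments$s0 < 0) || any(segments$s1 < 0)) stop("stimulus must be >= 0")
    segments <- segments[order(segments$start), , drop = FALSE]
    if (nrow(segments) > 1 &&
        any(segments$start[-1] < segments$end[-nrow(segments)] - 1e-12)) {
      stop("stimulus segments overlap")
    }
  }
  rownames(segments) <- NULL
  structure(segments, class = c("ash_protocol", "data.frame"))
}

#' @export
print.ash_protocol <- function(x, ...) {
  cat(sprintf("Stimulus protocol: %d segment(s), span %.6g s\n",
              nrow(x), if (nrow(x)) max(x$end) else 0))
  print.data.frame(x, ...)
  invisible(x)
}

#' Evaluate a stimulus protocol
#'
#' @param protocol An `ash_protocol`.
#' @param t Numeric vector of times (s).
#' @return `S(t)` for each time; 0 outside every segment.
#' @export
eval_stimulus <- function(protocol, t) {
  S <- numeric(length(t))
  for (i in seq_len(nrow(protocol))) {
    seg <- protocol[i, ]
    inside <- t >= seg$start & t < seg$end
    if (any(inside)) {
      frac <- (t[inside] - seg$start) / (seg$end - seg$start)
      S[inside] <- seg$s0 + (seg$s1 - seg$s0) * frac
    }
  }
  S
}

# Times where the waveform is non-smooth; integration restarts here.
protocol_breaks <- function(protocol) {
  sort(unique(c(protocol$start, protocol$end)))
}

#' Closed-form integral of a protocol over its span
#' @param protocol An `ash_protocol`.
#' @return Total area (s, in stimulus units), summed per segment as
#'   trapezoids.
#' @export
protocol_area <- function(protocol) {
  if (!nrow(protocol)) return(0)
  sum((protocol$end - protocol$start) * (protocol$s0 + protocol$s1) / 2)
}

#' Square stimulus pulse
#'
#' @param start Onset time (s).
#' @param duration Pulse duration (s), > 0.
#' @param magnitude Stimulus strength (dimensionless), >= 0.
#' @return An `ash_protocol` with `S = magnitude` on `[start, start+duration)`.
#' @export
stim_square <- function(start = 0, duration = 30, magnitude = 1) {
  if (duration <= 0) stop("duration must be > 0")
  if (magnitude < 0) stop("magnitude must be >= 0")
  ash_protocol(data.frame(start = start, end = start + duration,
                          s0 = magnitude, s1 = magnitude))
}

#' Train of square pulses
#'
#' @param pulses `data.frame` (or list coercible to one) with columns `start`,
#'   `duration`, `magnitude`; pulses must not overlap.
#' @return An `ash_protocol` superposing the squares.
#' @export
stim_train <- function(pulses) {
  pulses <- as.data.frame(pulses)
  if (!nrow(pulses)) return(ash_protocol(data.frame(start = numeric(), end = numeric(),
                                                    s0 = numeric(), s1 = numeric())))
  ash_protocol(data.frame(start = pulses$start, end = pulses$start + pulses$duration,
                          s0 = pulses$magnitude, s1 = pulses$magnitude))
}

#' Flickering (pulse-train) stimulus
#'
#' `n` equal square pulses of width `duty * period` at the start of each
#' period. Shrinking the duty cycle tenfold while boosting the magnitude
#' tenfold preserves the area under each pulse.
#'
#' @param n Number of pulses.
#' @param period Cycle length (s).
#' @param duty Fraction of each period the stimulus is on, in `(0, 1]`.
#' @param magnitude Stimulus strength.
#' @param start Onset of the first pulse (s).
#' @return An `ash_protocol`.
#' @export
stim_flicker <- function(n, period, duty, magnitude = 1, start = 0) {
  if (duty <= 0 || duty > 1) stop("duty must be in (0, 1]")
  starts <- start + (seq_len(n) - 1) * period
  stim_train(data.frame(start = starts, duration = duty * period,
                        magnitude = magnitude))
}

#' Ramp, triangle, and stepped-triangle stimuli
#'
#' @param shape `"rising"` (0 -> peak), `"falling"` (peak -> 0), `"triangle"`
#'   (0 -> peak -> 0), or `"stepped_triangle"` (a staircase with the same area
#'   as the continuous triangle).
#' @param span Total duration (s).
#' @param peak Peak stimulus strength.
#' @param start Onset (s).
#' @param n_steps Number of steps per side for `"stepped_triangle"`.
#' @return An `ash_protocol`.
#' @export
stim_ramp <- function(shape = c("rising", "falling", "triangle", "stepped_triangle"),
                      span, peak, start = 0, n_steps = 10) {
  shape <- match.arg(shape)
  if (span <= 0) stop("span must be > 0")
  if (peak < 0) stop("peak must be >= 0")
  if (shape == "rising") {
    return(ash_protocol(data.frame(start = start, end = start + span, s0 = 0, s1 = peak)))
  }
  if (shape == "falling") {
    return(ash_protocol(data.frame(start = start, end = start + span, s0 = peak, s1 = 0)))
  }
  half <- span / 2
  if (shape == "triangle") {
    return(ash_protocol(data.frame(start = c(start, start + half),
                                   end = c(start + half, start + span),
                                   s0 = c(0, peak), s1 = c(peak, 0))))
  }
  # stepped triangle: midpoint-height staircase on each side conserves area
  if (n_steps < 1) stop("n_steps must be >= 1")
  w <- half / n_steps
  up_lv <- peak * (seq_len(n_steps) - 0.5) / n_steps
  lv <- c(up_lv, rev(up_lv))
  st <- start + (seq_len(2 * n_steps) - 1) * w
  ash_protocol(data.frame(start = st, end = st + w, s0 = lv, s1 = lv))
}

#' Read a stimulus protocol from a one-segment-per-line text file
#'
#' Lines are `square <start> <duration> <magnitude>` or
#' `ramp <start> <duration> <start_level> <end_level>`; blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path File path.
#' @return An `ash_protocol`.
#' @export
read_protocol <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  segs <- lapply(lines, function(ln) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    kind <- tok[1]
    v <- suppressWarnings(as.numeric(tok[-1]))
    if (kind == "square" && length(v) == 3 && !anyNA(v)) {
      data.frame(start = v[1], end = v[1] + v[2], s0 = v[3], s1 = v[3])
    } else if (kind == "ramp" && length(v) == 4 && !anyNA(v)) {
      data.frame(start = v[1], end = v[1] + v[2], s0 = v[3], s1 = v[4])
    } else {
      stop("malformed protocol line: ", ln)
    }
  })
  ash_protocol(do.call(rbind, segs))
}

#' Write a stimulus protocol to the line-based text format
#' @param protocol An `ash_protocol`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  lines <- vapply(seq_len(nrow(protocol)), function(i) {
    seg <- protocol[i, ]
    if (seg$s0 == seg$s1) {
      sprintf("square %.15g %.15g %.15g", seg$start, seg$end - seg$start, seg$s0)
    } else {
      sprintf("ramp %.15g %.15g %.15g %.15g", seg$start, seg$end - seg$start, seg$s0, seg$s1)
    }
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
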