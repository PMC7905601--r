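#' Short-time RMS amplitude envelope
#'
#' RMS over a sliding window, returned in dB relative to full scale (dBFS).
#' This is the envelope behind [detect_events()] and [count_elements()].
#'
#' @param audio numeric samples, full scale `[-1, 1]`.
#' @param sample_rate sampling frequency, Hz.
#' @param win_ms window length, ms.
#' @param hop_ms hop between successive windows, ms.
#' @return list with `db` (envelope, dBFS), `t` (window-center times, s),
#'   `win_s`, `hop_s`.
#' @export
amplitude_envelope <- function(audio, sample_rate, win_ms = 5, hop_ms = 1) {
  if (length(audio) == 0L) ss_stop("invalid_argument", "audio is empty")
  win <- max(1L, round(win_ms * sample_rate / 1000))
  hop <- max(1L, round(hop_ms * sample_rate / 1000))
  n <- length(audio)
  if (n < win) {
    starts <- 1L
    win <- n
  } else {
    starts <- seq(1L, n - win + 1L, by = hop)
  }
  csum <- c(0, cumsum(audio^2))
  ms <- (csum[starts + win] - csum[starts]) / win
  list(db = 10 * log10(pmax(ms, .Machine$double.xmin)),
       t = (starts - 1 + win / 2) / sample_rate,
       win_s = win / sample_rate, hop_s = hop / sample_rate)
}

# Run-length segments of a logical vector: data.frame(start, end) of TRUE runs
# (indices, inclusive).
true_runs <- function(active) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Merge runs separated by fewer than gap_frames inactive frames.
merge_runs <- function(runs, gap_frames) {
  if (nrow(runs) <= 1L) return(runs)
  keep_start <- runs$start[1]
  out <- list()
  for (i in seq_len(nrow(runs) - 1L)) {
    gap <- runs$start[i + 1L] - runs$end[i] - 1L
    if (gap >= gap_frames) {
      out[[length(out) + 1L]] <- c(keep_start, runs$end[i])
      keep_start <- runs$start[i + 1L]
    }
  }
  out[[length(out) + 1L]] <- c(keep_start, runs$end[nrow(runs)])
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Detect sound events with an amplitude trigger
#'
#' Finds contiguous regions where the short-time RMS envelope exceeds a
#' trigger level; regions separated by less than `min_gap_ms` of silence are
#' merged into one event, which keeps multi-note syllables (e.g. trills with
#' very short internal gaps) together. Event boundaries are corrected for the
#' half-window bias of the envelope, so with a low trigger they land within
#' about one hop of the true sound edges.
#'
#' @param audio numeric samples, full scale.
#' @param sample_rate sampling frequency, Hz.
#' @param trigger_db trigger level in dBFS (user-set in the original
#'   workflow; default -40).
#' @param min_gap_ms minimum silence that separates two events, ms.
#' @param min_dur_ms events shorter than this are discarded (noise blips).
#' @return data frame of class `sound_events`, one row per event:
#'   `onset_s`, `offset_s` (half-open `[onset, offset)`), `peak_db`.
#'   All-silent input yields zero rows.
#' @export
detect_events <- function(audio, sample_rate, trigger_db = -40, min_gap_ms = 10,
                          min_dur_ms = 5) {
  if (length(audio) == 0L) ss_stop("invalid_argument", "audio is empty")
  if (min_gap_ms <= 0) ss_stop("invalid_argument", "min_gap_ms must be > 0")
  env <- amplitude_envelope(audio, sample_rate)
  active <- env$db > trigger_db
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0), peak_db = numeric(0))
  class(empty) <- c("sound_events", "data.frame")
  if (!any(active)) return(empty)
  runs <- true_runs(active)
  gap_frames <- max(1L, round(min_gap_ms / 1000 / env$hop_s))
  runs <- merge_runs(runs, gap_frames)
  # the first active window is the first touching the sound, so its trailing
  # edge sits just past the true onset; centering by half a hop removes the
  # discretization bias (symmetric for offsets)
  onset <- pmax(env$t[runs$start] + env$win_s / 2 - env$hop_s / 2, 0)
  offset <- env$t[runs$end] - env$win_s / 2 + env$hop_s / 2
  peak <- vapply(seq_len(nrow(runs)),
                 function(i) max(env$db[runs$start[i]:runs$end[i]]), numeric(1))
  keep <- (offset - onset) >= min_dur_ms / 1000
  ev <- data.frame(onset_s = onset[keep], offset_s = offset[keep], peak_db = peak[keep])
  class(ev) <- c("sound_events", "data.frame")
  ev
}

#' Count elements with a relative threshold and hold time
#'
#' Counts excursions of the envelope above `peak + threshold_db`, where
#' sub-threshold dips shorter than `hold_time_ms` do not split an element
#' (the automatic single-element separation rule: threshold -20 dB, hold
#' time 5 ms). Trills whose internal gaps are shorter than the hold time
#' therefore count as one element.
#'
#' @param audio numeric samples.
#' @param sample_rate sampling frequency, Hz.
#' @param threshold_db threshold relative to the envelope peak, dB (negative).
#' @param hold_time_ms dips shorter than this do not split an element, ms.
#' @return integer element count.
#' @export
count_elements <- function(audio, sample_rate, threshold_db = -20, hold_time_ms = 5) {
  if (length(audio) == 0L) ss_stop("invalid_argument", "audio is empty")
  env <- amplitude_envelope(audio, sample_rate)
  active <- env$db > max(env$db) + threshold_db
  if (!any(active)) return(0L)
  runs <- true_runs(active)
  hold_frames <- max(1L, round(hold_time_ms / 1000 / env$hop_s))
  runs <- merge_runs(runs, hold_frames)
  nrow(runs)
}

#' Parse a strophe into parts A, B and C
#'
#' Part B is identified as the event immediately following the longest
#' internal gap (the A-B pause), provided that gap exceeds `min_pause_s` and
#' the candidate event is atonal: its mean per-frame Wiener entropy must
#' exceed `atonality_threshold` (entropy near 0 means noise-like, strongly
#' negative means tonal). Events before B are labeled A, events after are C.
#'
#' @param events a `sound_events` data frame from [detect_events()].
#' @param audio the samples the events were detected in.
#' @param sample_rate sampling frequency, Hz.
#' @param min_pause_s smallest admissible A-B pause, s.
#' @param atonality_threshold Wiener-entropy floor for part B (dimensionless,
#'   `<= 0`).
#' @return an object of class `song_strophe`: list with `events` (the input
#'   plus a `part` column), `pause_ab_s`, `durations` (named vector with
#'   `A`, `B`, `C`, `total`, seconds), `b_entropy`.
#'   Unparseable strophes (too few events, no long-enough gap, or a tonal
#'   B candidate) raise a `seasong_unparseable` error carrying diagnostics.
#' @export
parse_strophe <- function(events, audio, sample_rate, min_pause_s = 0.1,
                          atonality_threshold = -2) {
  if (nrow(events) < 3L) {
    ss_stop("unparseable", sprintf("need >= 3 events to parse a strophe, got %d", nrow(events)),
            list(n_events = nrow(events)))
  }
  n <- nrow(events)
  gaps <- events$onset_s[-1] - events$offset_s[-n]
  j <- which.max(gaps)
  if (gaps[j] < min_pause_s) {
    ss_stop("unparseable",
            sprintf("longest internal gap (%.3f s) is below the minimum pause (%.3f s)",
                    gaps[j], min_pause_s),
            list(gaps = gaps))
  }
  if (j + 1L == n) {
    ss_stop("unparseable", "candidate part B is the last event; part C would be empty",
            list(gaps = gaps))
  }
  b_idx <- j + 1L
  b_audio <- audio[max(1, round(events$onset_s[b_idx] * sample_rate)):
                     min(length(audio), round(events$offset_s[b_idx] * sample_rate))]
  b_entropy <- mean_frame_entropy(b_audio, sample_rate)
  if (b_entropy < atonality_threshold) {
    ss_stop("unparseable",
            sprintf("candidate part B fails the atonality check (entropy %.2f < %.2f)",
                    b_entropy, atonality_threshold),
            list(b_entropy = b_entropy, gaps = gaps))
  }
  part <- c(rep("A", j), "B", rep("C", n - b_idx))
  events$part <- part
  dur_part <- function(p) {
    idx <- which(part == p)
    events$offset_s[max(idx)] - events$onset_s[min(idx)]
  }
  structure(
    list(events = events,
         pause_ab_s = gaps[j],
         durations = c(A = dur_part("A"), B = dur_part("B"), C = dur_part("C"),
                       total = events$offset_s[n] - events$onset_s[1]),
         b_entropy = b_entropy),
    class = "song_strophe"
  )
}

#' @export
print.song_strophe <- function(x, ...) {
  tab <- table(factor(x$events$part, levels = c("A", "B", "C")))
  cat(sprintf("<song_strophe> A: %d elements, B: %d, C: %d | pause A-B %.3f s, total %.3f s\n",
              tab["A"], tab["B"], tab["C"], x$pause_ab_s, x$durations["total"]))
  invisible(x)
}
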