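#' Spectrogram presets
#'
#' Two short-time Fourier parameterizations are used in practice: a display
#' preset (512-point FFT, Hanning window, 70% overlap) for visualization and
#' spectral measurements, and a measurement preset (256-point FFT, Hamming
#' window, 50% overlap) matching the sonograms used for syllable features.
#'
#' @param name `"display"` or `"measure"`.
#' @return list with `fft_size`, `window`, `overlap`.
#' @export
spectrogram_preset <- function(name = c("display", "measure")) {
  switch(match.arg(name),
         display = list(fft_size = 512L, window = "hanning", overlap = 0.7),
         measure = list(fft_size = 256L, window = "hamming", overlap = 0.5))
}

window_vector <- function(window, n) {
  switch(window,
         hamming = signal::hamming(n),
         hanning = signal::hanning(n),
         rectangular = rep(1, n),
         ss_stop("invalid_argument", sprintf("unknown window '%s'", window)))
}

#' Compute a magnitude spectrogram
#'
#' One-sided magnitude short-time Fourier transform. Frames advance by
#' `fft_size * (1 - overlap)` samples; frame times are window centers; bin
#' frequencies are `k * sample_rate / fft_size`.
#'
#' @param audio numeric samples.
#' @param sample_rate sampling frequency, Hz.
#' @param fft_size FFT length (power of two).
#' @param window window name: `"hamming"`, `"hanning"`, `"rectangular"`.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return an object of class `spectrogram`: list with `mag` (frames x bins
#'   magnitude matrix), `t` (frame-center times, s), `f` (bin frequencies,
#'   Hz), and `params`.
#' @export
compute_spectrogram <- function(audio, sample_rate, fft_size = 512,
                                window = "hamming", overlap = 0.5) {
  if (bitwAnd(fft_size, fft_size - 1L) != 0L || fft_size < 8L) {
    ss_stop("invalid_argument", "fft_size must be a power of two >= 8")
  }
  if (overlap < 0 || overlap >= 1) ss_stop("invalid_argument", "overlap must be in [0, 1)")
  n <- length(audio)
  if (n < fft_size) {
    ss_stop("invalid_argument",
            sprintf("audio (%d samples) is shorter than fft_size (%d)", n, fft_size))
  }
  hop <- max(1L, round(fft_size * (1 - overlap)))
  starts <- seq(1L, n - fft_size + 1L, by = hop)
  w <- window_vector(window, fft_size)
  frames <- vapply(starts, function(s) audio[s:(s + fft_size - 1L)] * w,
                   numeric(fft_size))
  spec <- stats::mvfft(frames)             # fft_size x n_frames
  n_bins <- fft_size %/% 2L + 1L
  mag <- t(Mod(spec[seq_len(n_bins), , drop = FALSE]))
  structure(
    list(mag = mag,
         t = (starts - 1 + fft_size / 2) / sample_rate,
         f = (seq_len(n_bins) - 1) * sample_rate / fft_size,
         params = list(fft_size = as.integer(fft_size), window = window,
                       overlap = overlap, sample_rate = sample_rate, hop = hop)),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d frames x %d bins | fft %d, %s, overlap %.0f%%, fs %g Hz\n",
              nrow(x$mag), ncol(x$mag), x$params$fft_size, x$params$window,
              100 * x$params$overlap, x$params$sample_rate))
  invisible(x)
}

#' Band limits of a time interval
#'
#' Over all frames whose centers fall in `interval`, the maximum frequency is
#' the highest bin whose magnitude (in any frame) exceeds the interval's peak
#' magnitude plus `rel_threshold_db`; the minimum frequency is the analogous
#' lowest bin. Because the criterion is relative to the peak, the result is
#' invariant to scaling the waveform.
#'
#' @param spg a [compute_spectrogram()] result.
#' @param interval numeric `c(start, end)`, seconds, half-open.
#' @param rel_threshold_db threshold relative to the interval peak, dB.
#' @return named numeric: `min_freq`, `max_freq`, `bandwidth` (Hz).
#' @export
band_limits <- function(spg, interval, rel_threshold_db = -20) {
  stopifnot(inherits(spg, "spectrogram"), length(interval) == 2L)
  in_frames <- spg$t >= interval[1] & spg$t < interval[2]
  if (!any(in_frames)) {
    ss_stop("measurement_failed", "interval overlaps no spectrogram frame",
            list(interval = interval))
  }
  m <- spg$mag[in_frames, , drop = FALSE]
  peak <- max(m)
  thr <- peak * db_to_amp(rel_threshold_db)
  above <- apply(m, 2, max) > thr
  if (!any(above)) {
    ss_stop("measurement_failed", "no bin above the relative threshold (silent interval?)",
            list(interval = interval))
  }
  f_above <- spg$f[above]
  c(min_freq = min(f_above), max_freq = max(f_above),
    bandwidth = max(f_above) - min(f_above))
}

#' Spectral measurements of a parsed strophe
#'
#' Applies [band_limits()] to each part (A, B, C) and to the whole strophe,
#' and assembles part durations, the A-B pause and the total duration from
#' the parse boundaries. A part whose measurement fails (e.g. silent) is
#' reported as `NA` without blocking the others.
#'
#' @param strophe a [parse_strophe()] result.
#' @param spg a [compute_spectrogram()] of the same audio.
#' @param rel_threshold_db threshold handed to [band_limits()].
#' @return one-row data frame of class `strophe_spectral_measures`:
#'   `{min,max}_freq_{A,B,C}`, `bandwidth_{A,B,C}`, `duration_{A,B,C}`,
#'   `pause_ab_s`, `total_duration_s`, `overall_min_freq`,
#'   `overall_max_freq`, `overall_bandwidth`.
#' @export
measure_strophe_spectra <- function(strophe, spg, rel_threshold_db = -20) {
  stopifnot(inherits(strophe, "song_strophe"))
  ev <- strophe$events
  part_band <- function(p) {
    idx <- which(ev$part == p)
    iv <- c(ev$onset_s[min(idx)], ev$offset_s[max(idx)])
    tryCatch(band_limits(spg, iv, rel_threshold_db),
             seasong_measurement_failed = function(e) {
               c(min_freq = NA_real_, max_freq = NA_real_, bandwidth = NA_real_)
             })
  }
  bands <- lapply(c(A = "A", B = "B", C = "C"), part_band)
  # whole-strophe band: union of the per-part bands, so a loud part cannot
  # push a quieter part's content below the relative threshold
  overall <- c(min_freq = suppressWarnings(min(vapply(bands, `[[`, numeric(1), "min_freq"),
                                              na.rm = TRUE)),
               max_freq = suppressWarnings(max(vapply(bands, `[[`, numeric(1), "max_freq"),
                                              na.rm = TRUE)))
  overall <- c(overall, bandwidth = unname(overall["max_freq"] - overall["min_freq"]))
  if (!is.finite(overall[["min_freq"]])) overall[] <- NA_real_
  out <- data.frame(
    min_freq_A = bands$A[["min_freq"]], max_freq_A = bands$A[["max_freq"]],
    bandwidth_A = bands$A[["bandwidth"]],
    min_freq_B = bands$B[["min_freq"]], max_freq_B = bands$B[["max_freq"]],
    bandwidth_B = bands$B[["bandwidth"]],
    min_freq_C = bands$C[["min_freq"]], max_freq_C = bands$C[["max_freq"]],
    bandwidth_C = bands$C[["bandwidth"]],
    duration_A = unname(strophe$durations["A"]),
    duration_B = unname(strophe$durations["B"]),
    duration_C = unname(strophe$durations["C"]),
    pause_ab_s = strophe$pause_ab_s,
    total_duration_s = unname(strophe$durations["total"]),
    overall_min_freq = overall[["min_freq"]],
    overall_max_freq = overall[["max_freq"]],
    overall_bandwidth = overall[["bandwidth"]]
  )
  class(out) <- c("strophe_spectral_measures", "data.frame")
  out
}
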