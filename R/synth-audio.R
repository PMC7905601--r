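#' Describe a syllable type
#'
#' A syllable spec is the ground-truth recipe for one syllable type: a
#' frequency contour (pure tone, linear sweep, trill of repeated sub-sweeps,
#' or atonal broadband noise), its duration and relative amplitude. Trills
#' consist of `n_subelements` sub-sweeps separated by sub-gaps shorter than
#' the element counter's hold time, so a trill is counted as one element.
#'
#' @param type_id integer label identifying the type.
#' @param contour one of `"tone"`, `"sweep"`, `"trill"`, `"atonal-noise"`.
#' @param f_start,f_end contour start/end frequency in Hz (ignored and set to
#'   `NA` for atonal noise).
#' @param duration_ms syllable duration in milliseconds.
#' @param n_subelements number of sub-sweeps for trills (>= 1).
#' @param amplitude peak amplitude relative to full scale, in (0, 1].
#' @return an object of class `syllable_spec`.
#' @export
syllable_spec <- function(type_id, contour = c("tone", "sweep", "trill", "atonal-noise"),
                          f_start = NA_real_, f_end = NA_real_,
                          duration_ms = 100, n_subelements = 1L, amplitude = 0.7) {
  contour <- match.arg(contour)
  if (!is_count(type_id)) ss_stop("invalid_spec", "type_id must be an integer")
  if (!is.numeric(duration_ms) || duration_ms <= 0) {
    ss_stop("invalid_spec", "duration_ms must be > 0")
  }
  if (!is_count(n_subelements) || n_subelements < 1) {
    ss_stop("invalid_spec", "n_subelements must be an integer >= 1")
  }
  if (amplitude <= 0 || amplitude > 1) ss_stop("invalid_spec", "amplitude must be in (0, 1]")
  if (contour == "atonal-noise") {
    f_start <- NA_real_
    f_end <- NA_real_
  } else {
    if (!is.finite(f_start) || !is.finite(f_end) || f_start <= 0 || f_end <= 0) {
      ss_stop("invalid_spec", "tonal contours need positive f_start and f_end")
    }
    if (contour == "tone" && f_start != f_end) {
      ss_stop("invalid_spec", "a tone must have f_start == f_end")
    }
  }
  structure(
    list(type_id = as.integer(type_id), contour = contour,
         f_start = f_start, f_end = f_end, duration_ms = duration_ms,
         n_subelements = as.integer(n_subelements), amplitude = amplitude),
    class = "syllable_spec"
  )
}

#' @export
print.syllable_spec <- function(x, ...) {
  cat(sprintf("<syllable_spec> type %d: %s %s, %.0f ms\n", x$type_id, x$contour,
              if (is.na(x$f_start)) "broadband" else sprintf("%.0f->%.0f Hz", x$f_start, x$f_end),
              x$duration_ms))
  invisible(x)
}

# Raised-cosine onset/offset ramp to avoid spectral splatter at edges.
apply_ramp <- function(x, sample_rate, ramp_ms = 2) {
  n <- length(x)
  nr <- min(round(ramp_ms * sample_rate / 1000), n %/% 2)
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / (nr + 1)))
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[n - nr + seq_len(nr)] <- x[n - nr + seq_len(nr)] * rev(ramp)
  }
  x
}

# Linear chirp from f0 to f1 over n samples.
chirp_samples <- function(f0, f1, n, sample_rate) {
  t <- (seq_len(n) - 1) / sample_rate
  dur <- n / sample_rate
  phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * dur))
  sin(phase)
}

#' Synthesize one syllable
#'
#' Renders a [syllable_spec()] to PCM samples. Trill sub-sweeps are separated
#' by 3-ms silent sub-gaps (shorter than the default 5-ms hold time, so a
#' trill registers as a single element). Output is deterministic given
#' `seed` — only atonal noise consumes random numbers.
#'
#' @param spec a [syllable_spec()].
#' @param sample_rate sampling frequency in Hz (22050 or 44100).
#' @param seed integer seed for the noise generator.
#' @return numeric vector of `round(duration_ms * sample_rate / 1000)` samples.
#' @export
synth_syllable <- function(spec, sample_rate = 22050, seed = 1L) {
  stopifnot(inherits(spec, "syllable_spec"))
  if (!sample_rate %in% c(22050, 44100)) {
    ss_stop("invalid_spec", "sample_rate must be 22050 or 44100 Hz")
  }
  nyq <- sample_rate / 2
  if (spec$contour != "atonal-noise" && (spec$f_start >= nyq || spec$f_end >= nyq)) {
    ss_stop("invalid_spec", sprintf("contour frequencies must be below Nyquist (%g Hz)", nyq))
  }
  n <- round(spec$duration_ms * sample_rate / 1000)
  x <- switch(
    spec$contour,
    tone = apply_ramp(chirp_samples(spec$f_start, spec$f_start, n, sample_rate), sample_rate),
    sweep = apply_ramp(chirp_samples(spec$f_start, spec$f_end, n, sample_rate), sample_rate),
    trill = {
      k <- spec$n_subelements
      gap_n <- round(3 * sample_rate / 1000)          # 3 ms sub-gaps, < hold time
      sub_n <- (n - (k - 1) * gap_n) %/% k
      if (sub_n < 8) ss_stop("invalid_spec", "trill too short for its sub-element count")
      out <- numeric(n)
      pos <- 0L
      for (i in seq_len(k)) {
        sub <- apply_ramp(chirp_samples(spec$f_start, spec$f_end, sub_n, sample_rate),
                          sample_rate, ramp_ms = 1)
        out[pos + seq_len(sub_n)] <- sub
        pos <- pos + sub_n + gap_n
      }
      out[seq_len(n)]
    },
    `atonal-noise` = with_seed(seed, apply_ramp(rnorm(n), sample_rate) / 3)
  )
  x <- x / max(abs(x))
  x * spec$amplitude
}

#' Describe a three-part strophe
#'
#' A strophe is part A (a series of elements), a pause, part B (exactly one
#' atonal element), then part C (a second element series). The pause must be
#' longer than every inter-element gap, which is what lets the parser find it.
#'
#' @param partA,partC lists of [syllable_spec()] objects, in singing order.
#' @param partB a single [syllable_spec()] with contour `"atonal-noise"`.
#' @param pause_ab_ms pause between the end of part A and part B, ms.
#' @param gap_ms silent gap between consecutive elements within a part, ms;
#'   must exceed 10 ms so elements remain separable.
#' @return an object of class `strophe_spec`.
#' @export
strophe_spec <- function(partA, partB, partC, pause_ab_ms = 250, gap_ms = 20) {
  if (length(partA) == 0L) ss_stop("invalid_spec", "part A must contain at least one element")
  if (length(partC) == 0L) ss_stop("invalid_spec", "part C must contain at least one element")
  ok <- function(l) all(vapply(l, inherits, logical(1), "syllable_spec"))
  if (!ok(partA) || !ok(partC) || !inherits(partB, "syllable_spec")) {
    ss_stop("invalid_spec", "parts must be built from syllable_spec objects")
  }
  if (partB$contour != "atonal-noise") {
    ss_stop("invalid_spec", "part B must be a single atonal-noise element")
  }
  if (gap_ms <= 10) ss_stop("invalid_spec", "gap_ms must exceed 10 ms")
  if (pause_ab_ms <= gap_ms) {
    ss_stop("invalid_spec", "pause_ab_ms must exceed the inter-element gap")
  }
  structure(
    list(partA = partA, partB = partB, partC = partC,
         pause_ab_ms = pause_ab_ms, gap_ms = gap_ms),
    class = "strophe_spec"
  )
}

#' Synthesize a strophe with ground truth
#'
#' Concatenates the part-A elements, the A-B pause, part B, and the part-C
#' elements, pads 60 ms of margin on both sides, and adds white Gaussian
#' noise at `snr_db` relative to the RMS of the clean strophe.
#'
#' @param spec a [strophe_spec()].
#' @param snr_db signal-to-noise ratio in dB (`Inf` for noiseless).
#' @param sample_rate sampling frequency, Hz.
#' @param seed integer seed; drives noise and any atonal syllables.
#' @return list with `audio` (numeric samples), `sample_rate`, and `truth`,
#'   a data frame with one row per element: `element`, `part`, `type_id`,
#'   `onset_sample`, `offset_sample` (half-open, 1-based onset), `onset_s`,
#'   `offset_s`.
#' @export
synth_strophe <- function(spec, snr_db = 40, sample_rate = 22050, seed = 1L) {
  stopifnot(inherits(spec, "strophe_spec"))
  if (!is.finite(snr_db) && !identical(snr_db, Inf)) {
    ss_stop("invalid_spec", "snr_db must be finite or Inf")
  }
  gap_n <- round(spec$gap_ms * sample_rate / 1000)
  pause_n <- round(spec$pause_ab_ms * sample_rate / 1000)
  pad_n <- round(0.060 * sample_rate)

  elems <- c(spec$partA, list(spec$partB), spec$partC)
  parts <- c(rep("A", length(spec$partA)), "B", rep("C", length(spec$partC)))
  # gap before each element (first element: leading pad handled separately)
  pre_gap <- c(0L, rep(gap_n, length(spec$partA) - 1L), pause_n,
               gap_n, rep(gap_n, length(spec$partC) - 1L))

  audio <- numeric(0)
  truth <- vector("list", length(elems))
  pos <- pad_n
  for (i in seq_along(elems)) {
    pos <- pos + pre_gap[i]
    syl <- synth_syllable(elems[[i]], sample_rate, seed = seed + i)
    audio <- c(audio, numeric(pre_gap[i]), syl)
    truth[[i]] <- data.frame(
      element = i, part = parts[i], type_id = elems[[i]]$type_id,
      onset_sample = pos + 1L, offset_sample = pos + length(syl)
    )
    pos <- pos + length(syl)
  }
  audio <- c(numeric(pad_n), audio, numeric(pad_n))
  if (is.finite(snr_db)) {
    noise_sd <- rms(audio[audio != 0]) * 10^(-snr_db / 20)
    noise <- with_seed(seed, rnorm(length(audio), sd = noise_sd))
    audio <- audio + noise
  }
  peak <- max(abs(audio))
  if (peak > 1) audio <- audio / (peak * 1.01)
  truth <- do.call(rbind, truth)
  truth$onset_s <- (truth$onset_sample - 1L) / sample_rate
  truth$offset_s <- truth$offset_sample / sample_rate
  list(audio = audio, sample_rate = sample_rate, truth = truth)
}

#' Synthesize a recording session for one individual
#'
#' Writes `n_strophes` WAV files (the number of best-quality strophes
#' analyzed per bird; default 20) drawn from the individual's song types,
#' plus one ground-truth CSV sidecar indexing every element of every file.
#'
#' @param song_types list of [strophe_spec()] objects; each strophe is drawn
#'   uniformly (cycling deterministically through types first so each type
#'   appears at least once when `n_strophes >= length(song_types)`).
#' @param out_dir output directory (created if needed).
#' @param n_strophes number of strophes to write (>= 1).
#' @param snr_db signal-to-noise ratio for every strophe.
#' @param sample_rate sampling frequency, Hz.
#' @param seed integer seed; identical seeds give identical file contents.
#' @param individual label used in file names.
#' @return invisibly, a list with `wav_paths`, `truth_path`, and the combined
#'   `truth` data frame (columns `file`, `strophe`, `song_type`, plus the
#'   per-element columns of [synth_strophe()]).
#' @export
synth_session <- function(song_types, out_dir, n_strophes = 20, snr_db = 40,
                          sample_rate = 22050, seed = 1L, individual = "bird01") {
  if (!is_count(n_strophes) || n_strophes < 1) {
    ss_stop("invalid_spec", "n_strophes must be an integer >= 1")
  }
  stopifnot(length(song_types) >= 1)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    ss_stop("io", sprintf("cannot create output directory '%s'", out_dir))
  }
  type_idx <- with_seed(seed, {
    base <- rep_len(seq_along(song_types), n_strophes)
    if (n_strophes > length(song_types)) {
      extra <- seq(length(song_types) + 1L, n_strophes)
      base[extra] <- sample.int(length(song_types), length(extra), replace = TRUE)
    }
    base
  })
  wav_paths <- character(n_strophes)
  truths <- vector("list", n_strophes)
  for (s in seq_len(n_strophes)) {
    st <- synth_strophe(song_types[[type_idx[s]]], snr_db = snr_db,
                        sample_rate = sample_rate, seed = seed * 1000L + s)
    path <- file.path(out_dir, sprintf("%s_strophe%02d.wav", individual, s))
    write_wav(st$audio, sample_rate, path)
    wav_paths[s] <- path
    tr <- st$truth
    tr$file <- basename(path)
    tr$strophe <- s
    tr$song_type <- type_idx[s]
    truths[[s]] <- tr
  }
  truth <- do.call(rbind, truths)
  truth <- truth[, c("file", "strophe", "song_type", "element", "part", "type_id",
                     "onset_sample", "offset_sample", "onset_s", "offset_s")]
  truth_path <- file.path(out_dir, sprintf("%s_truth.csv", individual))
  utils::write.csv(truth, truth_path, row.names = FALSE)
  invisible(list(wav_paths = wav_paths, truth_path = truth_path, truth = truth))
}
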