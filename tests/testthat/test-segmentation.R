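# Pulse train: bursts of a 3-kHz tone separated by silences (durations in ms).
pulse_train <- function(burst_ms, gap_ms, fs = 22050, n = 5, amp = 0.5) {
  burst <- amp * sin(2 * pi * 3000 * seq_len(round(burst_ms * fs / 1000)) / fs)
  gap <- numeric(round(gap_ms * fs / 1000))
  pad <- numeric(round(0.05 * fs))
  c(pad, rep(c(burst, gap), n - 1), burst, pad)
}

test_that("events separated by more than the minimum gap stay separate; shorter gaps merge", {
  fs <- 22050
  expect_equal(nrow(detect_events(pulse_train(30, 15), fs)), 5)
  expect_equal(nrow(detect_events(pulse_train(30, 8), fs)), 1)
  expect_equal(nrow(detect_events(numeric(1000) + 1e-6, fs)), 0)
  expect_error(detect_events(numeric(0), fs), class = "seasong_invalid_argument")
})

test_that("event detection matches a sample-wise thresholding oracle on clean audio", {
  fs <- 22050
  x <- pulse_train(40, 25, n = 4)
  ev <- detect_events(x, fs, trigger_db = -45)
  # oracle: exhaustive scan for runs of |x| above the trigger amplitude,
  # closing gaps shorter than min_gap
  thr <- 10^(-45 / 20)
  active <- abs(x) > thr
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- starts[r$values]
  off <- ends[r$values]
  keep <- c(TRUE, (on[-1] - off[-length(off)]) / fs >= 10 / 1000)
  grp <- cumsum(keep)
  on_m <- tapply(on, grp, min) / fs
  off_m <- tapply(off, grp, max) / fs
  expect_equal(nrow(ev), length(on_m))
  expect_true(all(abs(ev$onset_s - on_m) < 0.002))
  expect_true(all(abs(ev$offset_s - off_m) < 0.002))
})

test_that("merging is monotone in min_gap and voiced time is monotone in trigger level", {
  fs <- 22050
  x <- pulse_train(25, 12, n = 6)
  gaps <- c(2, 5, 8, 11, 14, 20)
  counts <- vapply(gaps, function(g) nrow(detect_events(x, fs, min_gap_ms = g)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  voiced <- vapply(c(-60, -45, -30, -20), function(tr) {
    ev <- detect_events(x, fs, trigger_db = tr)
    sum(ev$offset_s - ev$onset_s)
  }, numeric(1))
  expect_true(all(diff(voiced) <= 1e-9))
})

test_that("the element counter honors the -20 dB / 5 ms hold-time rule", {
  fs <- 22050
  expect_equal(count_elements(pulse_train(20, 3, n = 2), fs), 1)   # dip < hold time
  expect_equal(count_elements(pulse_train(20, 10, n = 2), fs), 2)  # gap >= 10 ms splits
  # a trill's sub-gaps (< 5 ms) never split it
  trill <- synth_syllable(syllable_spec(1, "trill", 3000, 4000, 200, n_subelements = 5), fs)
  expect_equal(count_elements(trill, fs), 1)
  # a 7-ms dip is held together at the default hold time but splits at 1 ms
  expect_equal(count_elements(pulse_train(20, 7, n = 2), fs), 1)
  expect_equal(count_elements(pulse_train(20, 7, n = 2), fs, hold_time_ms = 1), 2)
})

test_that("strophe parsing recovers parts, pause and durations from fixtures", {
  st <- synth_strophe(fixture_strophe_spec(), snr_db = 60, seed = 11)
  ev <- detect_events(st$audio, st$sample_rate)
  ps <- parse_strophe(ev, st$audio, st$sample_rate)
  expect_s3_class(ps, "song_strophe")
  expect_equal(ps$events$part, st$truth$part)
  expect_lt(abs(ps$pause_ab_s - 0.25), 0.002)
  expect_lt(abs(ps$durations[["total"]] - (st$truth$offset_s[10] - st$truth$onset_s[1])),
            0.004)
})

test_that("unparseable strophes raise diagnostic errors instead of guessing", {
  fs <- 22050
  two <- detect_events(pulse_train(30, 15, n = 2), fs)
  expect_error(parse_strophe(two, pulse_train(30, 15, n = 2), fs),
               class = "seasong_unparseable")
  # uniform gaps, all below the minimum pause
  x <- pulse_train(30, 20, n = 5)
  ev <- detect_events(x, fs)
  expect_error(parse_strophe(ev, x, fs, min_pause_s = 0.1), class = "seasong_unparseable")
  # longest gap present but the candidate B is tonal, not atonal
  ty <- fixture_types()
  tonal_b <- strophe_spec(list(ty$a1, ty$a2), ty$b, list(ty$c1, ty$c2))
  st <- synth_strophe(tonal_b, snr_db = 60, seed = 2)
  # splice a tone over part B's samples to break atonality
  b_row <- which(st$truth$part == "B")
  idx <- st$truth$onset_sample[b_row]:st$truth$offset_sample[b_row]
  st$audio[idx] <- 0.5 * sin(2 * pi * 3000 * seq_along(idx) / 22050)
  ev <- detect_events(st$audio, 22050)
  expect_error(parse_strophe(ev, st$audio, 22050), class = "seasong_unparseable")
})
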