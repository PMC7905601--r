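#' Segment, parse and measure one strophe recording
#'
#' Runs the bioacoustic chain on one recording: event detection, A/B/C
#' parsing, spectral measurements on the display spectrogram, and the
#' nine-feature syllable descriptors on the measurement sonogram.
#'
#' @param audio numeric samples (or use `wav` to read a file).
#' @param sample_rate sampling frequency, Hz.
#' @param wav optional path to a WAV file (overrides `audio`).
#' @param trigger_db amplitude trigger, dBFS.
#' @param min_gap_ms minimum inter-event silence, ms.
#' @param strophe_id identifier carried into the feature table.
#' @return list with `events`, `strophe` ([parse_strophe()]), `measures`
#'   ([measure_strophe_spectra()]), `features`
#'   ([syllable_feature_table()]).
#' @export
process_strophe <- function(audio = NULL, sample_rate = NULL, wav = NULL,
                            trigger_db = -40, min_gap_ms = 10, strophe_id = 1L) {
  if (!is.null(wav)) {
    w <- read_wav(wav)
    audio <- w$samples
    sample_rate <- w$sample_rate
  }
  stopifnot(!is.null(audio), !is.null(sample_rate))
  events <- detect_events(audio, sample_rate, trigger_db = trigger_db,
                          min_gap_ms = min_gap_ms)
  strophe <- parse_strophe(events, audio, sample_rate)
  preset <- spectrogram_preset("display")
  spg <- compute_spectrogram(audio, sample_rate, fft_size = preset$fft_size,
                             window = preset$window, overlap = preset$overlap)
  measures <- measure_strophe_spectra(strophe, spg)
  features <- syllable_feature_table(audio, sample_rate, strophe$events,
                                     strophe_id = strophe_id)
  list(events = events, strophe = strophe, measures = measures, features = features)
}

#' Repertoire analysis of a recording session
#'
#' Processes every WAV of one individual's session, pools the syllable
#' features, clusters them by incremental-split k-means and summarizes the
#' repertoire. Strophes that cannot be parsed are skipped and reported.
#'
#' @param wav_paths character vector of strophe WAV files.
#' @param k_max maximum cluster count.
#' @param seed clustering seed.
#' @param trigger_db amplitude trigger, dBFS.
#' @return list with `features` (pooled table), `clustering`, `summary`
#'   ([summarize_repertoire()]), `measures` (per-strophe spectral table),
#'   `skipped` (unparseable files).
#' @export
analyze_session <- function(wav_paths, k_max = 30, seed = 1L, trigger_db = -40) {
  feats <- list()
  meas <- list()
  skipped <- character(0)
  for (i in seq_along(wav_paths)) {
    res <- tryCatch(process_strophe(wav = wav_paths[i], trigger_db = trigger_db,
                                    strophe_id = i),
                    seasong_unparseable = function(e) NULL)
    if (is.null(res)) {
      skipped <- c(skipped, wav_paths[i])
      next
    }
    feats[[length(feats) + 1L]] <- res$features
    m <- res$measures
    m$strophe_id <- i
    meas[[length(meas) + 1L]] <- m
  }
  if (length(feats) == 0L) ss_stop("unparseable", "no strophe could be parsed")
  features <- do.call(rbind, feats)
  feature_cols <- c("avg_f", "modal_f", "fund_f", "wentropy", "duration",
                    "sd_avg_f", "sd_modal_f", "sd_fund_f", "sd_went")
  # part B is a single atonal element: it is identified by the parser and
  # excluded from the repertoire, so only A/C syllables are clustered
  # (spectral peak locations of broadband noise are arbitrary and would
  # scatter B across clusters)
  ac <- features$part != "B"
  clustering <- cluster_syllables(features[ac, feature_cols], k_max = k_max, seed = seed)
  summary <- summarize_repertoire(clustering, features$part[ac], features$strophe_id[ac])
  list(features = features, clustering = clustering, summary = summary,
       measures = do.call(rbind, meas), skipped = skipped)
}

#' Seasonal statistics over a stage table
#'
#' Applies the study's statistics layer to one stage table: stage linear
#' models for the non-vocal behaviors (time in the 5-m radius
#' square-root-transformed, closest approach log-transformed) and
#' testosterone, a Poisson model for song rate, and stage-by-area mixed
#' models for AR, ARO and ER in the hypothalamic areas and for AR in the
#' song system (HVC and lMAN).
#'
#' @param table a `stage_table` (synthetic or real, same schema).
#' @return list with `results` — a tidy data frame (`response`, `family`,
#'   `term`, `statistic`, `df`, `p`) — and `models`, the underlying
#'   `model_result` objects.
#' @export
run_seasonal_study <- function(table) {
  models <- list(
    latency = fit_stage_lm(table, "latency_s"),
    time5m = fit_stage_lm(table, "time5m_s", transform = "sqrt"),
    nodding = fit_stage_lm(table, "nodding"),
    closest = fit_stage_lm(table, "closest_m", transform = "log"),
    testosterone = fit_stage_lm(table, "testosterone_pgml"),
    songrate = fit_poisson_glm(table, "songrate"),
    ar_hypo = fit_stage_area_lmm(stage_table_long(table, c("ar_poa", "ar_h"),
                                                  c("POA", "H"))),
    aro_hypo = fit_stage_area_lmm(stage_table_long(table, c("aro_poa", "aro_h"),
                                                   c("POA", "H"))),
    er_hypo = fit_stage_area_lmm(stage_table_long(table, c("er_poa", "er_h"),
                                                  c("POA", "H"))),
    ar_song = fit_stage_area_lmm(stage_table_long(table, c("ar_hvc", "ar_lman"),
                                                  c("HVC", "lMAN")))
  )
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    t <- m$tests
    stat_col <- intersect(c("statistic", "chisq", "deviance"), names(t))[1]
    df_col <- if ("df" %in% names(t)) t$df else t$df1
    data.frame(response = nm, family = m$family, term = t$term,
               statistic = t[[stat_col]], df = df_col, p = t$p)
  })
  list(results = do.call(rbind, rows), models = models)
}
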