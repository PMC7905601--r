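#' Wiener entropy of a power spectrum
#'
#' Log ratio of the geometric to the arithmetic mean of spectral power:
#' 0 for a perfectly flat (noise-like) spectrum, strongly negative for
#' concentrated (tonal) spectra. To keep the geometric mean finite, power is
#' floored at `1e-12` of the spectral peak. Invariant to scaling the
#' spectrum.
#'
#' @param power_spectrum non-negative numeric vector, not all zero.
#' @return Wiener entropy (dimensionless, `<= 0`).
#' @export
wiener_entropy <- function(power_spectrum) {
  if (length(power_spectrum) == 0L || any(power_spectrum < 0) ||
      any(!is.finite(power_spectrum))) {
    ss_stop("undefined_input", "power spectrum must be non-negative and finite")
  }
  peak <- max(power_spectrum)
  if (peak == 0) ss_stop("undefined_input", "all-zero power spectrum")
  p <- pmax(power_spectrum, peak * 1e-12)
  min(mean(log(p)) - log(mean(p)), 0)
}

# Mean per-frame Wiener entropy of a sound, on the 256-point measurement
# sonogram. Used by the strophe parser's atonality check.
mean_frame_entropy <- function(audio, sample_rate, fft_size = 256) {
  while (length(audio) < fft_size && fft_size > 32L) fft_size <- fft_size %/% 2L
  spg <- compute_spectrogram(audio, sample_rate, fft_size = fft_size,
                             window = "hamming", overlap = 0.5)
  pw <- spg$mag^2
  energy <- rowSums(pw)
  keep <- energy > max(energy) * 1e-6
  mean(apply(pw[keep, , drop = FALSE], 1, wiener_entropy))
}

# First spectral peak above f_min and above floor_db of the spectrum peak
# (power dB). Falls back to the strongest bin above f_min if no local
# maximum qualifies.
first_peak_freq <- function(power, freq, f_min = 500, floor_db = -25) {
  thr <- max(power) * 10^(floor_db / 10)
  n <- length(power)
  cand <- which(freq >= f_min & power > thr)
  for (i in cand) {
    left <- if (i == 1L) 0 else power[i - 1L]
    right <- if (i == n) 0 else power[i + 1L]
    if (power[i] > left && power[i] >= right) return(freq[i])
  }
  eligible <- which(freq >= f_min)
  freq[eligible[which.max(power[eligible])]]
}

#' Sonogram feature descriptor of one syllable
#'
#' Computes the per-syllable descriptor used for repertoire clustering:
#' average frequency (magnitude-weighted mean), modal frequency (peak bin of
#' the time-averaged spectrum), fundamental frequency (first spectral peak
#' above `f_min`), Wiener entropy, duration, and the frame-wise standard
#' deviations of the four spectral quantities — nine features in all.
#' Near-silent frames (60 dB below the loudest frame) are excluded.
#'
#' @param audio samples of one extracted sound event.
#' @param sample_rate sampling frequency, Hz.
#' @param fft_size sonogram FFT length (default 256).
#' @param overlap fractional frame overlap.
#' @param f_min floor for the fundamental-frequency search, Hz.
#' @param fund_floor_db level below the spectral peak under which bins are
#'   ignored by the fundamental search, dB.
#' @param frame_floor_db frames whose energy is more than this below the
#'   loudest frame are treated as unvoiced and skipped, dB.
#' @param duration_s duration to report; defaults to `length(audio) /
#'   sample_rate` (pass the event's trigger boundaries when available).
#' @param spectrum `"frames"` (default) computes modal and fundamental
#'   frequency per frame and averages them, which is stable for
#'   frequency-modulated syllables; `"averaged"` takes them from the
#'   time-averaged spectrum, whose single peak is ill-defined for sweeps
#'   and trills.
#' @return one-row data frame of class `syllable_features` with columns
#'   `avg_f`, `modal_f`, `fund_f`, `wentropy`, `duration`, `sd_avg_f`,
#'   `sd_modal_f`, `sd_fund_f`, `sd_went`.
#' @export
extract_features <- function(audio, sample_rate, fft_size = 256, overlap = 0.5,
                             f_min = 500, fund_floor_db = -25, duration_s = NULL,
                             spectrum = c("frames", "averaged"), frame_floor_db = -30) {
  spectrum <- match.arg(spectrum)
  if (length(audio) < fft_size) {
    ss_stop("invalid_argument",
            sprintf("event too short for feature extraction (%d < %d samples)",
                    length(audio), fft_size))
  }
  spg <- compute_spectrogram(audio, sample_rate, fft_size = fft_size,
                             window = "hamming", overlap = overlap)
  mag <- spg$mag
  pw <- mag^2
  energy <- rowSums(pw)
  keep <- which(energy > max(energy) * 10^(frame_floor_db / 10))
  mag <- mag[keep, , drop = FALSE]
  pw <- pw[keep, , drop = FALSE]
  f <- spg$f

  avg_t <- as.numeric(mag %*% f) / rowSums(mag)
  modal_t <- f[max.col(mag, ties.method = "first")]
  fund_t <- apply(pw, 1, first_peak_freq, freq = f, f_min = f_min,
                  floor_db = fund_floor_db)
  went_t <- apply(pw, 1, wiener_entropy)

  # frame statistics are energy-weighted: low-energy edge frames (syllable
  # boundaries, trill sub-gaps) otherwise flip in and out of the frame set
  # with sub-hop alignment, quantizing the descriptor
  w <- energy[keep] / sum(energy[keep])
  wmean <- function(x) sum(w * x)
  wsd <- function(x) sqrt(max(sum(w * (x - sum(w * x))^2), 0))

  mean_spec <- colMeans(pw)
  out <- data.frame(
    avg_f = sum(colSums(mag) * f) / sum(mag),
    modal_f = if (spectrum == "frames") wmean(modal_t) else f[which.max(mean_spec)],
    fund_f = if (spectrum == "frames") wmean(fund_t) else {
      first_peak_freq(mean_spec, f, f_min, fund_floor_db)
    },
    wentropy = wmean(went_t),
    duration = duration_s %||% (length(audio) / sample_rate),
    sd_avg_f = wsd(avg_t),
    sd_modal_f = wsd(modal_t),
    sd_fund_f = wsd(fund_t),
    sd_went = wsd(went_t)
  )
  out[is.na(out)] <- 0
  class(out) <- c("syllable_features", "data.frame")
  out
}

#' Feature table for all events of a recording
#'
#' Convenience wrapper: runs [extract_features()] on each detected event and
#' returns one row per syllable with its identifiers attached.
#'
#' @param audio samples of the recording.
#' @param sample_rate sampling frequency, Hz.
#' @param events a `sound_events` data frame (optionally with a `part`
#'   column from [parse_strophe()]).
#' @param strophe_id identifier stored in the `strophe_id` column.
#' @param ... passed to [extract_features()].
#' @return data frame: `syllable_id`, `strophe_id`, `part` (NA when events
#'   are unlabeled) plus the nine feature columns.
#' @export
syllable_feature_table <- function(audio, sample_rate, events, strophe_id = 1L, ...) {
  rows <- lapply(seq_len(nrow(events)), function(i) {
    i0 <- max(1L, round(events$onset_s[i] * sample_rate))
    i1 <- min(length(audio), round(events$offset_s[i] * sample_rate))
    fe <- extract_features(audio[i0:i1], sample_rate,
                           duration_s = events$offset_s[i] - events$onset_s[i], ...)
    cbind(data.frame(syllable_id = i, strophe_id = strophe_id,
                     part = if ("part" %in% names(events)) events$part[i] else NA_character_),
          fe)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Gaussian classification BIC of a k-means partition with a diagonal,
# cluster-pooled covariance (per-feature within-cluster variance); smaller
# is better. A diagonal model is used rather than a spherical one because
# within-type measurement noise is strongly anisotropic (e.g. entropy
# jitter dwarfs frequency jitter), and a spherical score keeps paying to
# split along the noisiest feature.
kmeans_bic <- function(X, labels, centers) {
  n <- nrow(X)
  d <- ncol(X)
  k <- nrow(centers)
  resid <- X - centers[labels, , drop = FALSE]
  sigma2 <- pmax(colSums(resid^2) / max(n - k, 1L), 1e-12)
  n_i <- tabulate(labels, nbins = k)
  loglik <- sum(n_i * log(pmax(n_i, 1) / n)) -
    n / 2 * sum(log(2 * pi * sigma2)) - d * (n - k) / 2
  p <- k * d + d + (k - 1)
  -2 * loglik + p * log(n)
}

#' Cluster syllables by incremental-split k-means
#'
#' Starts from two clusters and splits new clusters off one at a time: at
#' each step the cluster with the largest within-cluster sum of squares is
#' bisected by a local 2-means, its two sub-centroids seed a global k-means
#' refinement, and the step is kept only while a spherical-Gaussian BIC
#' improves (or until `k_max`). The original workflow stopped by visual
#' inspection; the BIC rule is a reproducible surrogate and can be
#' overridden by forcing `k`. Features are z-scored per column before
#' clustering, so affine rescaling of any raw feature leaves the partition
#' unchanged.
#'
#' @param features numeric matrix or data frame, one row per syllable.
#' @param k_max largest cluster count considered.
#' @param seed integer seed making the procedure deterministic.
#' @param k force exactly `k` clusters (skips the BIC stopping rule).
#' @return an object of class `repertoire_clustering`: list with `labels`
#'   (integer in `1..k`), `centroids` (standardized space), `k`, `bic`,
#'   `split_history` (data frame `k`, `bic`, `accepted`), `flags`
#'   (`no_structure`, `degenerate`), `scaling`, `features_std`, `seed`,
#'   `edit_log`.
#' @export
cluster_syllables <- function(features, k_max = 30, seed = 1L, k = NULL) {
  X <- as.matrix(as.data.frame(features)[, vapply(as.data.frame(features), is.numeric,
                                                  logical(1)), drop = FALSE])
  n <- nrow(X)
  if (n < 2L) ss_stop("invalid_argument", "need at least 2 syllables to cluster")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  n_distinct <- nrow(unique(Xs))
  k_cap <- min(k_max, n_distinct)
  flags <- list(no_structure = FALSE, degenerate = n_distinct < n)

  res <- with_seed(seed, {
    if (!is.null(k)) {
      kk <- min(k, k_cap)
      if (kk < k) flags$degenerate <- TRUE
      km <- stats::kmeans(Xs, centers = kk, nstart = 10, iter.max = 100)
      list(km = km, history = data.frame(k = kk, bic = kmeans_bic(Xs, km$cluster, km$centers),
                                         accepted = TRUE))
    } else {
      km <- stats::kmeans(Xs, centers = min(2L, k_cap), nstart = 10, iter.max = 100)
      bic <- kmeans_bic(Xs, km$cluster, km$centers)
      history <- data.frame(k = nrow(km$centers), bic = bic, accepted = TRUE)
      while (nrow(km$centers) < k_cap) {
        # split the cluster with the largest within-cluster sum of squares;
        # its two sub-centroids seed a global refinement, and the step is
        # kept only while the BIC improves
        cand <- NULL
        for (ci in order(km$withinss, decreasing = TRUE)) {
          pts <- Xs[km$cluster == ci, , drop = FALSE]
          if (nrow(unique(pts)) < 2L) next     # unsplittable; try the next
          sub <- stats::kmeans(pts, centers = 2, nstart = 5, iter.max = 100)
          cand <- rbind(km$centers[-ci, , drop = FALSE], sub$centers)
          break
        }
        if (is.null(cand)) break
        km_new <- stats::kmeans(Xs, centers = cand, iter.max = 100)
        bic_new <- kmeans_bic(Xs, km_new$cluster, km_new$centers)
        accept <- bic_new < bic
        history <- rbind(history, data.frame(k = nrow(km_new$centers), bic = bic_new,
                                             accepted = accept))
        if (!accept) break
        km <- km_new
        bic <- bic_new
      }
      list(km = km, history = history)
    }
  })
  km <- res$km
  k_final <- nrow(km$centers)
  if (is.null(k) && k_final == 2L) {
    centers1 <- matrix(colMeans(Xs), nrow = 1)
    bic1 <- kmeans_bic(Xs, rep(1L, n), centers1)
    if (bic1 < res$history$bic[1]) flags$no_structure <- TRUE
  }
  structure(
    list(labels = as.integer(km$cluster), centroids = km$centers, k = k_final,
         bic = utils::tail(res$history$bic[res$history$accepted], 1),
         split_history = res$history, flags = flags,
         scaling = list(center = ctr, scale = scl),
         features_std = Xs, seed = seed, edit_log = list()),
    class = "repertoire_clustering"
  )
}

#' @export
print.repertoire_clustering <- function(x, ...) {
  cat(sprintf("<repertoire_clustering> %d syllables in %d types (BIC %.1f)%s%s\n",
              length(x$labels), x$k, x$bic,
              if (x$flags$no_structure) " [no structure]" else "",
              if (x$flags$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Recompute centroids and compact labels to 1..k.
rebuild_clustering <- function(cl, labels, edit) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  centroids <- do.call(rbind, lapply(seq_len(k), function(i) {
    colMeans(cl$features_std[labels == i, , drop = FALSE])
  }))
  cl$labels <- labels
  cl$centroids <- centroids
  cl$k <- k
  cl$edit_log <- c(cl$edit_log, list(edit))
  cl
}

#' Apply manual corrections to a clustering
#'
#' The original workflow reviewed every cluster and fixed mistakes by eye;
#' this is the programmatic equivalent. Each edit is a list with an `op`
#' field: `list(op = "relabel", id, label)` moves one syllable,
#' `list(op = "merge", a, b)` merges two clusters, and
#' `list(op = "split", cluster, ids)` moves `ids` out of `cluster` into a
#' new one. Centroids and `k` are recomputed and the edit log retained.
#'
#' @param clustering a [cluster_syllables()] result.
#' @param edits list of edit descriptions (may be empty: identity).
#' @return the corrected `repertoire_clustering`.
#' @export
apply_corrections <- function(clustering, edits) {
  stopifnot(inherits(clustering, "repertoire_clustering"))
  cl <- clustering
  for (e in edits) {
    labels <- cl$labels
    op <- e$op %||% ss_stop("invalid_argument", "each edit needs an 'op' field")
    if (op == "relabel") {
      if (!is_count(e$id) || e$id < 1 || e$id > length(labels)) {
        ss_stop("invalid_argument", sprintf("relabel: no syllable with id %s", e$id))
      }
      if (!is_count(e$label) || e$label < 1 || e$label > cl$k + 1) {
        ss_stop("invalid_argument", "relabel: label must be an existing cluster or k + 1")
      }
      labels[e$id] <- e$label
    } else if (op == "merge") {
      if (!all(c(e$a, e$b) %in% labels)) {
        ss_stop("invalid_argument", "merge: both clusters must exist")
      }
      labels[labels == e$b] <- e$a
    } else if (op == "split") {
      ids <- e$ids
      if (!all(ids >= 1 & ids <= length(labels)) || !all(labels[ids] == e$cluster)) {
        ss_stop("invalid_argument", "split: ids must all belong to the named cluster")
      }
      if (length(ids) == sum(labels == e$cluster)) {
        ss_stop("invalid_argument", "split: cannot move every member out of a cluster")
      }
      labels[ids] <- max(labels) + 1L
    } else {
      ss_stop("invalid_argument", sprintf("unknown edit op '%s'", op))
    }
    cl <- rebuild_clustering(cl, labels, e)
  }
  cl
}

# A sequence repeated in full collapses to one period.
collapse_full_repeats <- function(s) {
  n <- length(s)
  for (p in seq_len(n %/% 2)) {
    if (n %% p == 0L && all(s == rep_len(s[seq_len(p)], n))) return(s[seq_len(p)])
  }
  s
}

#' Count song types from per-strophe label sequences
#'
#' A song type is a stereotyped sequence of syllable labels; a strophe that
#' repeats a full sequence verbatim still shows one type. Under the
#' `"exact"` rule, distinct sequences are distinct types; under `"edit1"`,
#' sequences within Levenshtein distance 1 are pooled (transitively).
#'
#' @param sequences list of integer vectors, one per strophe, in singing
#'   order.
#' @param rule `"exact"` or `"edit1"`.
#' @return integer number of song types.
#' @export
count_song_types <- function(sequences, rule = c("exact", "edit1")) {
  rule <- match.arg(rule)
  if (length(sequences) == 0L) ss_stop("invalid_argument", "need at least one strophe")
  seqs <- lapply(sequences, collapse_full_repeats)
  keys <- vapply(seqs, function(s) paste(s, collapse = ","), character(1))
  uniq <- unique(keys)
  if (rule == "exact" || length(uniq) == 1L) return(length(uniq))
  # encode each label as one character so adist measures label edits
  labs <- sort(unique(unlist(seqs)))
  enc <- vapply(seqs[match(uniq, keys)], function(s) {
    intToUtf8(256L + match(s, labs))
  }, character(1))
  d <- utils::adist(enc)
  # union-find over sequences within edit distance 1
  parent <- seq_along(enc)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(enc)) for (j in seq_len(i - 1L)) {
    if (d[i, j] <= 1L) parent[find(i)] <- find(j)
  }
  length(unique(vapply(seq_along(enc), find, integer(1))))
}

#' Summarize a repertoire
#'
#' Derives the repertoire summary from a clustering plus the part label and
#' strophe membership of every syllable: distinct syllable types overall
#' (part B excluded — it is always a single atonal element), per part A and
#' part C, the number of song types, and the mean number of syllables per
#' song.
#'
#' @param clustering a [cluster_syllables()] result (possibly corrected).
#' @param parts character vector (`"A"`, `"B"`, `"C"`), one per syllable.
#' @param strophe_ids vector assigning each syllable to its strophe;
#'   syllables must be ordered within strophes.
#' @param rule song-type equality rule, see [count_song_types()].
#' @return list of class `repertoire_summary`: `n_song_types`,
#'   `repertoire_size_total`, `repertoire_size_A`, `repertoire_size_C`,
#'   `syllables_per_song`.
#' @export
summarize_repertoire <- function(clustering, parts, strophe_ids, rule = "exact") {
  stopifnot(inherits(clustering, "repertoire_clustering"))
  labels <- clustering$labels
  if (length(parts) != length(labels) || anyNA(parts)) {
    ss_stop("invalid_argument", "every syllable needs a part label")
  }
  if (length(strophe_ids) != length(labels)) {
    ss_stop("invalid_argument", "every syllable needs a strophe id")
  }
  sequences <- split(labels, strophe_ids)
  structure(
    list(n_song_types = count_song_types(sequences, rule = rule),
         repertoire_size_total = length(unique(labels[parts != "B"])),
         repertoire_size_A = length(unique(labels[parts == "A"])),
         repertoire_size_C = length(unique(labels[parts == "C"])),
         syllables_per_song = mean(lengths(sequences))),
    class = "repertoire_summary"
  )
}

#' @export
print.repertoire_summary <- function(x, ...) {
  cat(sprintf(paste0("<repertoire_summary> %d song types | repertoire %d",
                     " (A: %d, C: %d) | %.1f syllables/song\n"),
              x$n_song_types, x$repertoire_size_total, x$repertoire_size_A,
              x$repertoire_size_C, x$syllables_per_song))
  invisible(x)
}
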