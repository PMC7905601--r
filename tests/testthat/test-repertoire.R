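fs <- 22050

test_that("Wiener entropy is zero for flat spectra, negative for concentrated ones", {
  expect_equal(wiener_entropy(rep(3.7, 64)), 0)
  one_hot <- c(1, rep(1e-9, 63))
  expect_lt(wiener_entropy(one_hot), -10)
  # strictly decreasing along a parametric concentration family
  conc <- vapply(c(0, 0.5, 1, 2, 4), function(a) {
    wiener_entropy(exp(-a * (0:63)))
  }, numeric(1))
  expect_true(all(diff(conc) < 0))
  # scaling invariance
  p <- stats::runif(128)
  expect_equal(wiener_entropy(p), wiener_entropy(p * 1e6))
  expect_error(wiener_entropy(numeric(64)), class = "seasong_undefined_input")
})

test_that("noise frames average near zero entropy, tonal frames are strongly negative", {
  noise_vals <- vapply(1:10, function(s) {
    mean_frame_entropy(synth_syllable(syllable_spec(1, "atonal-noise", duration_ms = 80),
                                      fs, seed = s), fs)
  }, numeric(1))
  expect_gt(mean(noise_vals), -1)
  tone_val <- mean_frame_entropy(synth_syllable(syllable_spec(2, "tone", 4000, 4000, 80), fs), fs)
  expect_lt(tone_val, -3)
})

test_that("feature extraction recovers design values for tones and harmonic stacks", {
  tone <- synth_syllable(syllable_spec(1, "tone", 4000, 4000, 100), fs)
  f <- extract_features(tone, fs)
  bin <- fs / 256
  expect_lt(abs(f$avg_f - 4000), 1.5 * bin)
  expect_lt(abs(f$modal_f - 4000), bin)
  expect_lt(abs(f$fund_f - 4000), bin)
  expect_equal(f$duration, 0.1)
  expect_lt(f$sd_modal_f, 1e-9)
  # fundamental stays at f0 when a strong 2nd harmonic is present
  t <- seq_len(2205) / fs
  two <- 0.5 * sin(2 * pi * 4000 * t) + 0.45 * sin(2 * pi * 8000 * t)
  f2 <- extract_features(two, fs)
  expect_lt(abs(f2$fund_f - 4000), bin)
  expect_gt(f2$avg_f, 4000 + bin)
  expect_lt(f2$avg_f, 8000 - bin)
  expect_error(extract_features(tone[1:100], fs), class = "seasong_invalid_argument")
})

test_that("atonal syllables separate from tonal ones in entropy", {
  noise <- extract_features(synth_syllable(syllable_spec(1, "atonal-noise", duration_ms = 80),
                                           fs, seed = 3), fs)
  tone <- extract_features(synth_syllable(syllable_spec(2, "tone", 3000, 3000, 80), fs), fs)
  expect_gt(noise$wentropy - tone$wentropy, 2)
})

test_that("incremental-split k-means recovers well-separated blobs and flags no structure", {
  set.seed(42)
  X <- rbind(matrix(stats::rnorm(200, 0), ncol = 2),
             matrix(stats::rnorm(200, 10), ncol = 2),
             cbind(stats::rnorm(100, 0), stats::rnorm(100, 20)))
  cl <- cluster_syllables(X, k_max = 10, seed = 5)
  expect_equal(cl$k, 3)
  expect_equal(ari(cl$labels, rep(1:3, each = 100)), 1.0)
  # single blob: floor of two clusters, flagged
  cl1 <- cluster_syllables(matrix(stats::rnorm(240), ncol = 3), k_max = 10, seed = 5)
  expect_equal(cl1$k, 2)
  expect_true(cl1$flags$no_structure)
  expect_false(cl$flags$no_structure)
  expect_error(cluster_syllables(X[1, , drop = FALSE]), class = "seasong_invalid_argument")
})

test_that("clustering is invariant to affine feature rescaling and point order", {
  set.seed(7)
  X <- rbind(matrix(stats::rnorm(120, 0), ncol = 3),
             matrix(stats::rnorm(120, 8), ncol = 3))
  cl <- cluster_syllables(X, seed = 9)
  Xr <- X
  Xr[, 1] <- X[, 1] * 1000 - 52     # affine rescale of one column
  clr <- cluster_syllables(Xr, seed = 9)
  expect_equal(ari(cl$labels, clr$labels), 1.0)
  perm <- sample(nrow(X))
  clp <- cluster_syllables(X[perm, ], seed = 9)
  expect_equal(ari(cl$labels[perm], clp$labels), 1.0)
})

test_that("duplicate-point degeneracy yields fewer clusters with a flag, not an error", {
  X <- matrix(rep(c(0, 0, 5, 5), each = 10), ncol = 2)  # only 2 distinct points
  cl <- cluster_syllables(X, k_max = 10, seed = 1)
  expect_lte(cl$k, 2)
  expect_true(cl$flags$degenerate)
})

test_that("manual corrections merge, split, relabel and round-trip", {
  set.seed(3)
  X <- do.call(rbind, lapply(c(0, 6, 12, 18, 24), function(m) {
    matrix(stats::rnorm(40, m, 0.3), ncol = 2)
  }))
  cl <- cluster_syllables(X, k_max = 10, seed = 2)
  expect_equal(cl$k, 5)
  merged <- apply_corrections(cl, list(list(op = "merge", a = 2, b = 3)))
  expect_equal(merged$k, 4)
  expect_length(merged$edit_log, 1)
  expect_identical(apply_corrections(cl, list()), cl)
  # relabel one syllable into a new cluster, then merge back: same partition
  victim <- which(cl$labels == 1)[1]
  out <- apply_corrections(cl, list(list(op = "relabel", id = victim, label = cl$k + 1)))
  back <- apply_corrections(out, list(list(op = "merge", a = out$labels[victim],
                                           b = unique(out$labels[setdiff(which(cl$labels == 1), victim)]))))
  expect_equal(ari(back$labels, cl$labels), 1.0)
  expect_error(apply_corrections(cl, list(list(op = "relabel", id = 1e6, label = 1))),
               class = "seasong_invalid_argument")
})

test_that("song types count distinct stereotyped sequences", {
  expect_equal(count_song_types(list(c(1, 1, 2, 9, 3, 4), c(1, 1, 2, 9, 3, 4),
                                     c(1, 2, 9, 3, 5))), 2)
  expect_equal(count_song_types(rep(list(c(1, 2, 3)), 20)), 1)
  # a full verbatim repeat is still one type
  expect_equal(count_song_types(list(c(1, 2, 9), c(1, 2, 9, 1, 2, 9))), 1)
  # edit-1 rule pools near-identical sequences
  expect_equal(count_song_types(list(c(1, 2, 3, 4), c(1, 2, 3, 5), c(7, 7, 7, 7)),
                                rule = "edit1"), 2)
})

test_that("repertoire summaries follow set semantics with part B excluded", {
  labels <- c(1, 2, 3, 9, 4, 5, 6, 7, 8,
              1, 2, 3, 9, 4, 5, 6, 7, 8)
  parts <- rep(c("A", "A", "A", "B", "C", "C", "C", "C", "C"), 2)
  strophes <- rep(1:2, each = 9)
  cl <- structure(list(labels = as.integer(labels), k = 9L), class = "repertoire_clustering")
  s <- summarize_repertoire(cl, parts, strophes)
  expect_equal(s$repertoire_size_total, 8)
  expect_equal(s$repertoire_size_A, 3)
  expect_equal(s$repertoire_size_C, 5)
  expect_equal(s$n_song_types, 1)
  expect_equal(s$syllables_per_song, 9)
  # a type shared between parts counts once in the total
  labels2 <- c(1, 2, 9, 1, 4)
  s2 <- summarize_repertoire(structure(list(labels = as.integer(labels2), k = 4L),
                                       class = "repertoire_clustering"),
                             c("A", "A", "B", "C", "C"), rep(1, 5))
  expect_equal(s2$repertoire_size_total, 3)
  expect_equal(s2$repertoire_size_A + s2$repertoire_size_C, 4)
  expect_error(summarize_repertoire(cl, parts[-1], strophes),
               class = "seasong_invalid_argument")
})
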