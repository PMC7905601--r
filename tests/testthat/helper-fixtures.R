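# Shared fixtures: a small pool of well-separated syllable types and strophe
# specs mirroring the three-part song (A - pause - atonal B - C).

fixture_types <- function() {
  list(
    a1 = syllable_spec(1, "tone", 2500, 2500, 90),
    a2 = syllable_spec(2, "sweep", 3000, 5000, 120),
    a3 = syllable_spec(3, "trill", 4000, 4600, 160, n_subelements = 4),
    b  = syllable_spec(9, "atonal-noise", duration_ms = 80),
    c1 = syllable_spec(4, "tone", 6000, 6000, 80),
    c2 = syllable_spec(5, "sweep", 7000, 4500, 110),
    c3 = syllable_spec(6, "trill", 2000, 2400, 150, n_subelements = 3),
    c4 = syllable_spec(7, "sweep", 1500, 3500, 140),
    c5 = syllable_spec(8, "tone", 4300, 4300, 60)
  )
}

# One strophe spec drawing on the fixture pool: A uses 3 types, C uses 5.
fixture_strophe_spec <- function(pause_ab_ms = 250, gap_ms = 20) {
  ty <- fixture_types()
  strophe_spec(
    partA = list(ty$a1, ty$a1, ty$a2, ty$a3),
    partB = ty$b,
    partC = list(ty$c1, ty$c2, ty$c3, ty$c4, ty$c5),
    pause_ab_ms = pause_ab_ms, gap_ms = gap_ms
  )
}

# Three song types over the same 8-type pool (3 in A, 5 in C), used for
# repertoire-recovery fixtures: each orders/choses elements differently but
# the union of types per part is fixed.
fixture_song_types <- function() {
  ty <- fixture_types()
  list(
    strophe_spec(list(ty$a1, ty$a1, ty$a2, ty$a3), ty$b,
                 list(ty$c1, ty$c2, ty$c3, ty$c4, ty$c5)),
    strophe_spec(list(ty$a2, ty$a3, ty$a1), ty$b,
                 list(ty$c3, ty$c1, ty$c5, ty$c2, ty$c4)),
    strophe_spec(list(ty$a3, ty$a1, ty$a2, ty$a1), ty$b,
                 list(ty$c5, ty$c4, ty$c1, ty$c3, ty$c2, ty$c1))
  )
}

feature_cols <- c("avg_f", "modal_f", "fund_f", "wentropy", "duration",
                  "sd_avg_f", "sd_modal_f", "sd_fund_f", "sd_went")

# Adjusted Rand index oracle (mclust) guarded for suggests.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
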