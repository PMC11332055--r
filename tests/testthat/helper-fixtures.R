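# Small shared fixtures, all built in code.

tiny_config <- function(seed = 7L, n_phase1 = 24L, n_phase2 = 32L,
                        lexicon_size_per_emotion = 10L, ...) {
  generator_config(n_phase1 = n_phase1, n_phase2 = n_phase2,
                   lexicon_size_per_emotion = lexicon_size_per_emotion,
                   seed = seed, ...)
}

tiny_dataset <- function(seed = 7L, ...) {
  generate_dataset(tiny_config(seed = seed, ...))
}

tiny_encoder <- function(config = tiny_config(), dim = 32L, seed = 5L) {
  mock_encoder(build_lexicons(config), dim = dim, seed = seed)
}

# A hand-assembled record tibble with given words (list of character(5))
# and default in-range scale items.
make_records <- function(words, phase = 1L, emotion = "depression",
                         control_passed = TRUE) {
  n <- length(words)
  out <- tibble::tibble(
    record_id = sprintf("r%02d", seq_len(n)),
    phase = rep_len(phase, n),
    role = "control",
    narrative_id = sprintf("n%02d", seq_len(n)),
    true_emotion = rep_len(emotion, n)
  )
  wm <- t(vapply(words, function(w) {
    c(w, rep(NA_character_, 5 - length(w)))
  }, character(5)))
  for (j in 1:5) out[[paste0("word", j)]] <- wm[, j]
  for (s in names(scale_layout())) {
    lay <- scale_layout()[[s]]
    for (k2 in seq_len(lay$items)) out[[sprintf("%s_%d", s, k2)]] <- lay$lo
    out[[paste0(s, "_total")]] <- lay$lo * lay$items
  }
  out$control_passed <- rep_len(control_passed, n)
  out
}
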