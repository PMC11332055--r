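test_that("lexicon overlap is controlled within each confusable pair", {
  # zero overlap: four disjoint lists
  lex0 <- build_lexicons(generator_config(lexicon_overlap = 0,
                                          lexicon_size_per_emotion = 10))
  expect_true(all(lengths(lex0) == 10))
  expect_length(intersect(lex0$depression, lex0$anxiety), 0)
  expect_length(intersect(lex0$satisfaction, lex0$harmony), 0)

  # full overlap: confusable pairs share the whole lexicon
  lex1 <- build_lexicons(generator_config(lexicon_overlap = 1,
                                          lexicon_size_per_emotion = 10))
  expect_setequal(lex1$depression, lex1$anxiety)
  expect_setequal(lex1$satisfaction, lex1$harmony)

  # fractional overlap: round(0.4 * 10) = 4 shared words per pair
  lex <- build_lexicons(generator_config(lexicon_overlap = 0.4,
                                         lexicon_size_per_emotion = 10,
                                         seed = 7))
  expect_length(intersect(lex$depression, lex$anxiety), 4)
  expect_length(intersect(lex$satisfaction, lex$harmony), 4)

  # never across valences
  for (neg in c("depression", "anxiety")) {
    for (pos in c("harmony", "satisfaction")) {
      expect_length(intersect(lex[[neg]], lex[[pos]]), 0)
    }
  }
  expect_error(generator_config(lexicon_overlap = 1.2),
               class = "qcla_config_error")
})

test_that("sampled words respect the word-noise rate", {
  cfg <- generator_config(lexicon_size_per_emotion = 10)
  lex <- build_lexicons(cfg)

  withr::with_seed(1, {
    w0 <- sample_words("depression", lex, word_noise = 0)
    expect_length(w0, 5)
    expect_true(all(w0 %in% lex$depression))
    w1 <- sample_words("depression", lex, word_noise = 1)
    expect_false(any(w1 %in% lex$depression))
  })

  # Monte-Carlo: off-lexicon rate tracks word_noise (0.20 +/- 0.01)
  withr::with_seed(1, {
    draws <- replicate(2000, sample_words("harmony", lex, word_noise = 0.2))
    off_rate <- mean(!(draws %in% lex$harmony))
    expect_equal(off_rate, 0.2, tolerance = 0.05)
    expect_lt(abs(off_rate - 0.2), 0.01)
  })
})

test_that("scale items respect ranges and the latent copula correlation", {
  cfg <- generator_config(seed = 3)
  withr::with_seed(3, {
    draw <- sample_scale_items("depression", cfg, n = 5000)
  })
  lay <- scale_layout()
  for (s in names(lay)) {
    expect_true(all(draw$items[[s]] >= lay[[s]]$lo))
    expect_true(all(draw$items[[s]] <= lay[[s]]$hi))
    expect_equal(rowSums(draw$items[[s]]), unname(draw$totals[, s]))
  }
  # empirical PHQ-9 / GAD-7 total correlation tracks the 0.85 latent entry
  r <- cor(draw$totals[, "phq9"], draw$totals[, "gad7"])
  expect_gte(r, 0.80)
  expect_lte(r, 0.90)

  # identity latent correlation: totals essentially uncorrelated
  cfg_id <- generator_config(scale_corr = diag(4) + 0,
                             seed = 3)
  dimnames(cfg_id$scale_corr) <- dimnames(default_scale_corr())
  withr::with_seed(4, {
    d0 <- sample_scale_items("harmony", cfg_id, n = 5000)
  })
  expect_lt(abs(cor(d0$totals[, "phq9"], d0$totals[, "gad7"])), 0.05)

  # means far below the floor drive totals to the floor
  low <- matrix(-100, 4, 4, dimnames = dimnames(default_scale_mean_profile()))
  cfg_low <- generator_config(scale_mean_profile = low)
  withr::with_seed(5, {
    dl <- sample_scale_items("anxiety", cfg_low, n = 50)
  })
  expect_true(all(dl$totals[, "phq9"] == 0))
  expect_true(all(dl$totals[, "swls"] == 5))

  # non-positive-definite correlation is a configuration error
  bad <- matrix(1, 4, 4)
  expect_error(generator_config(scale_corr = bad),
               class = "qcla_config_error")
})

test_that("empirical total-score correlation matrix converges to scale_corr", {
  # mid-range mean profile: no floor/ceiling censoring, so the totals'
  # correlation matrix must converge to the latent one (profiles near a
  # scale's floor attenuate the affected entries, as bounded instruments do)
  mid <- matrix(rep(c(13.5, 10.5, 20, 20), each = 4), 4, 4,
                dimnames = dimnames(default_scale_mean_profile()))
  cfg <- generator_config(scale_mean_profile = mid, seed = 11)
  withr::with_seed(11, {
    draw <- sample_scale_items("satisfaction", cfg, n = 5000)
  })
  dev <- abs(cor(draw$totals) - cfg$scale_corr)
  expect_lt(max(dev), 0.05)
})

test_that("generated datasets are balanced, paired, and deterministic", {
  d <- tiny_dataset(seed = 7)
  d1 <- d[d$phase == 1, ]
  d2 <- d[d$phase == 2, ]

  counts <- table(d1$true_emotion)
  expect_lte(max(counts) - min(counts), 1)

  expect_true(all(d2$narrative_id %in% d1$narrative_id))
  reads <- table(d2$narrative_id)
  expect_true(all(reads %in% 1:2))
  expect_equal(sum(reads), nrow(d2))

  # each phase-2 record carries its narrative's emotion
  emo1 <- setNames(d1$true_emotion, d1$narrative_id)
  expect_equal(d2$true_emotion, unname(emo1[d2$narrative_id]))

  # n_phase2 == n_phase1: every narrative read exactly once
  done_once <- generate_dataset(generator_config(n_phase1 = 8, n_phase2 = 8,
                                                 seed = 1))
  expect_true(all(table(done_once$narrative_id[done_once$phase == 2]) == 1))

  # study-sized pairing: read counts only 1 or 2, summing to 434
  big <- generate_dataset(generator_config(n_phase1 = 297, n_phase2 = 434,
                                           seed = 2, word_noise = 0))
  r2 <- table(big$narrative_id[big$phase == 2])
  expect_true(all(r2 %in% 1:2))
  expect_equal(sum(r2), 434)

  # determinism: same config and seed, byte-identical output
  expect_identical(tiny_dataset(seed = 7), d)
  # pairing bounds enforced
  expect_error(generate_dataset(generator_config(n_phase1 = 10,
                                                 n_phase2 = 21)),
               class = "qcla_config_error")
  expect_error(generate_dataset(generator_config(n_phase1 = 10,
                                                 n_phase2 = 9)),
               class = "qcla_config_error")
})

test_that("item scores and totals always stay within the instrument bounds", {
  d <- generate_dataset(generator_config(n_phase1 = 150, n_phase2 = 250,
                                         seed = 13))
  expect_true(all(d$phq9_total >= 0 & d$phq9_total <= 27))
  expect_true(all(d$gad7_total >= 0 & d$gad7_total <= 21))
  expect_true(all(d$swls_total >= 5 & d$swls_total <= 35))
  expect_true(all(d$hils_total >= 5 & d$hils_total <= 35))
  expect_false(any(grepl("\\s", as.matrix(d[paste0("word", 1:5)]))))
})
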