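#' Default per-emotion mean profile of rating-scale totals
#'
#' Mean total scores the generator aims at for each emotion (rows) and scale
#' (columns: phq9, gad7, swls, hils). The two within-valence pairs are close
#' on purpose: raters score a depression narrative almost as high on the
#' anxiety scale as on the depression scale (and vice versa), which is what
#' makes the rating scales confusable. The negative-valence pair is made
#' tighter than the positive-valence pair so that most rating-scale errors
#' land in the depression/anxiety block.
#'
#' @return 4x4 numeric matrix, rows named by emotion, columns by scale.
#' @export
default_scale_mean_profile <- function() {
  m <- rbind(
    harmony      = c(3, 3, 23, 28),
    satisfaction = c(3, 3, 28, 23),
    depression   = c(17, 13, 11, 11),
    anxiety      = c(15, 14, 11, 11)
  )
  colnames(m) <- names(SCALES)
  m
}

#' Default latent correlation matrix for the four rating scales
#'
#' Correlations of the latent (pre-discretization) scale scores, order
#' phq9, gad7, swls, hils. Depression and anxiety scales correlate 0.85,
#' the two well-being scales 0.80, and the valences correlate -0.60.
#'
#' @return 4x4 positive-definite correlation matrix.
#' @export
default_scale_corr <- function() {
  m <- rbind(
    c(1.00, 0.85, -0.60, -0.60),
    c(0.85, 1.00, -0.60, -0.60),
    c(-0.60, -0.60, 1.00, 0.80),
    c(-0.60, -0.60, 0.80, 1.00)
  )
  dimnames(m) <- list(names(SCALES), names(SCALES))
  m
}

#' Configuration for the synthetic two-phase study generator
#'
#' @param n_phase1 Number of Phase-1 records (narrative authors). Default 297,
#'   the study size the generator emulates.
#' @param n_phase2 Number of Phase-2 records (narrative readers). Must lie in
#'   `[n_phase1, 2 * n_phase1]` so every narrative is read at least once but
#'   no more than twice. Default 434.
#' @param lexicon_size_per_emotion Words per emotion lexicon (>= 5).
#' @param lexicon_overlap Fraction in \[0, 1\] of each lexicon shared within a
#'   confusable pair (depression/anxiety, satisfaction/harmony). Cross-valence
#'   overlap is always zero.
#' @param word_noise Probability that a sampled descriptive word comes from
#'   another emotion's lexicon instead of the true one.
#' @param scale_mean_profile 4x4 matrix of target mean totals
#'   (emotion x scale); see [default_scale_mean_profile()].
#' @param scale_corr 4x4 latent correlation matrix (symmetric positive
#'   definite, unit diagonal); see [default_scale_corr()].
#' @param item_noise_sd Standard deviation of per-item latent noise around the
#'   scale-level latent score (latent units; the latent has unit variance).
#' @param professional_fraction Fraction of Phase-2 raters flagged as
#'   healthcare professionals. Default 34/434.
#' @param seed Master integer seed; all generator randomness derives from it.
#' @return A `qcla_generator_config` list.
#' @export
#' @examples
#' cfg <- generator_config(n_phase1 = 8, n_phase2 = 10, seed = 1)
generator_config <- function(n_phase1 = 297L,
                             n_phase2 = 434L,
                             lexicon_size_per_emotion = 40L,
                             lexicon_overlap = 0.2,
                             word_noise = 0.2,
                             scale_mean_profile = default_scale_mean_profile(),
                             scale_corr = default_scale_corr(),
                             item_noise_sd = 0.3,
                             professional_fraction = 34 / 434,
                             seed = 1L) {
  if (n_phase1 < 1 || n_phase2 < 1 || lexicon_size_per_emotion < 1) {
    stop_config("counts must be positive")
  }
  if (lexicon_size_per_emotion < 5) {
    stop_config("lexicon_size_per_emotion must be at least 5")
  }
  for (p in c(lexicon_overlap, word_noise, professional_fraction)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop_config("probabilities must lie in [0, 1]")
    }
  }
  stopifnot(is.matrix(scale_mean_profile),
            all(dim(scale_mean_profile) == c(4, 4)))
  check_corr_matrix(scale_corr)
  structure(
    list(
      n_phase1 = as.integer(n_phase1),
      n_phase2 = as.integer(n_phase2),
      lexicon_size_per_emotion = as.integer(lexicon_size_per_emotion),
      lexicon_overlap = lexicon_overlap,
      word_noise = word_noise,
      scale_mean_profile = scale_mean_profile,
      scale_corr = scale_corr,
      item_noise_sd = item_noise_sd,
      professional_fraction = professional_fraction,
      seed = as.integer(seed)
    ),
    class = "qcla_generator_config"
  )
}

check_corr_matrix <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(4, 4)) ||
      max(abs(m - t(m))) > 1e-10 || max(abs(diag(m) - 1)) > 1e-10) {
    stop_config("scale_corr must be a symmetric 4x4 matrix with unit diagonal")
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop_config("scale_corr must be positive definite")
  }
  invisible(m)
}

# Hand-picked seed vocabulary: words the study's word clouds single out as
# indicative of each state, plus shared words for the confusable pairs.
seed_vocabulary <- function() {
  list(
    unique = list(
      harmony      = c("calm", "peaceful", "serene", "balanced"),
      satisfaction = c("hopeful", "fulfilled", "pleased", "grateful"),
      depression   = c("sad", "depressed", "empty", "hopeless"),
      anxiety      = c("anxious", "worried", "nervous", "tense")
    ),
    shared = list(
      positive = c("happy", "content"),
      negative = c("overwhelmed", "distressed")
    )
  )
}

#' Build the four emotion lexicons
#'
#' Deterministic construction: each lexicon starts from a small seed
#' vocabulary of emotion-indicative English words and is padded with
#' synthetic tokens (`"dep_07"` style). Within each confusable pair
#' (depression/anxiety and satisfaction/harmony) a `lexicon_overlap`
#' fraction of words is shared; lexicons never overlap across valences.
#'
#' @param config A [generator_config()].
#' @return Named list of four character vectors (one per emotion).
#' @export
#' @examples
#' lex <- build_lexicons(generator_config(lexicon_overlap = 0.4,
#'                                        lexicon_size_per_emotion = 10))
#' length(intersect(lex$depression, lex$anxiety))  # 4
build_lexicons <- function(config) {
  stopifnot(inherits(config, "qcla_generator_config"))
  size <- config$lexicon_size_per_emotion
  n_shared <- as.integer(round(config$lexicon_overlap * size))
  vocab <- seed_vocabulary()
  pad <- function(words, prefix, n) {
    if (n <= 0) return(character(0))
    c(words, sprintf("%s_%03d", prefix, seq_len(max(0, n - length(words)))))[seq_len(n)]
  }
  shared <- list(
    positive = pad(vocab$shared$positive, "pos_shared", n_shared),
    negative = pad(vocab$shared$negative, "neg_shared", n_shared)
  )
  valence <- c(harmony = "positive", satisfaction = "positive",
               depression = "negative", anxiety = "negative")
  prefix <- c(harmony = "har", satisfaction = "sat",
              depression = "dep", anxiety = "anx")
  out <- lapply(setNames(EMOTIONS, EMOTIONS), function(e) {
    unique_part <- pad(vocab$unique[[e]], prefix[[e]], size - n_shared)
    c(unique_part, shared[[valence[[e]]]])
  })
  out
}

#' Sample five descriptive words for one response
#'
#' Each of the five words comes from the true emotion's lexicon with
#' probability `1 - word_noise`, otherwise from the union of the other
#' emotions' lexicons excluding any word also in the true lexicon. Words are
#' sampled without replacement within a response. Uses the current RNG
#' stream; seed control belongs to the caller (see [generate_dataset()]).
#'
#' @param emotion One of [emotions()].
#' @param lexicons Output of [build_lexicons()].
#' @param word_noise Off-lexicon probability in \[0, 1\].
#' @param n_words Number of words per response (default 5).
#' @return Character vector of `n_words` single tokens.
#' @export
sample_words <- function(emotion, lexicons, word_noise, n_words = 5L) {
  stopifnot(emotion %in% EMOTIONS)
  own <- lexicons[[emotion]]
  off_pool <- setdiff(unlist(lexicons[setdiff(EMOTIONS, emotion)],
                             use.names = FALSE), own)
  n_off <- rbinom(1L, n_words, word_noise)
  if (n_off > 0 && length(off_pool) == 0) {
    stop_config("word_noise > 0 requires off-lexicon words to exist")
  }
  words <- c(
    if (n_off < n_words) sample(own, n_words - n_off) else character(0),
    if (n_off > 0) sample(off_pool, n_off) else character(0)
  )
  words[sample.int(n_words)]
}

#' Sample rating-scale item responses via a latent-Gaussian copula
#'
#' For `n` raters of narratives with a given true emotion, draws a latent
#' 4-vector from a multivariate normal with correlation `scale_corr`, then
#' discretizes per item: each item equals the per-item mean implied by the
#' emotion's target total plus `slope * (latent + item noise)`, rounded and
#' clipped to the legal item range. Totals are item sums, so the empirical
#' correlation of totals across raters approaches `scale_corr` (the per-item
#' noise and the discretization error largely average out over items).
#'
#' @param emotion One of [emotions()].
#' @param config A [generator_config()].
#' @param n Number of independent raters to draw.
#' @return List with `items` (named list of n x k integer matrices, one per
#'   scale) and `totals` (n x 4 integer matrix, columns phq9, gad7, swls,
#'   hils). Uses the current RNG stream.
#' @export
sample_scale_items <- function(emotion, config, n = 1L) {
  stopifnot(emotion %in% EMOTIONS)
  check_corr_matrix(config$scale_corr)
  L <- chol(config$scale_corr)
  z <- matrix(rnorm(n * 4L), n, 4L) %*% L   # n x 4 latent scale scores
  items <- vector("list", length(SCALES))
  names(items) <- names(SCALES)
  totals <- matrix(0L, n, length(SCALES),
                   dimnames = list(NULL, names(SCALES)))
  for (j in seq_along(SCALES)) {
    s <- SCALES[[j]]
    mu_item <- config$scale_mean_profile[emotion, j] / s$items
    eps <- matrix(rnorm(n * s$items, sd = config$item_noise_sd), n, s$items)
    x <- mu_item + s$slope * (z[, j] + eps)
    it <- pmin(pmax(round(x), s$lo), s$hi)
    storage.mode(it) <- "integer"
    items[[j]] <- it
    totals[, j] <- as.integer(rowSums(it))
  }
  list(items = items, totals = totals)
}

#' Generate a complete synthetic two-phase dataset
#'
#' Phase 1: `n_phase1` authors, one narrative each, emotion labels balanced
#' across the four states (within one record). Phase 2: `n_phase2` readers;
#' every Phase-1 narrative is read at least once and at most twice, with the
#' second reads assigned at random. A configurable fraction of Phase-2
#' readers is flagged as healthcare professionals. Words and scale items are
#' drawn conditional on the narrative's true emotion. Fully reproducible
#' from `config$seed`; each generation stage uses its own derived stream.
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per response record: `record_id`, `phase`,
#'   `role`, `narrative_id`, `true_emotion`, `word1`..`word5`, all scale
#'   items (`phq9_1`..`hils_5`), the four totals, and `control_passed`.
#' @export
#' @examples
#' d <- generate_dataset(generator_config(n_phase1 = 8, n_phase2 = 10,
#'                                        seed = 7))
#' table(d$phase)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "qcla_generator_config"))
  n1 <- config$n_phase1
  n2 <- config$n_phase2
  if (n2 < n1 || n2 > 2L * n1) {
    stop_config("n_phase2 must lie in [n_phase1, 2 * n_phase1] ",
                "so each narrative is read once or twice")
  }
  lexicons <- build_lexicons(config)

  labels1 <- withr::with_seed(child_seed(config$seed, 101L), {
    sample(rep(EMOTIONS, length.out = n1))
  })
  narrative_ids <- sprintf("n%04d", seq_len(n1))

  # Phase-2 pairing: every narrative once, plus n2 - n1 random second reads.
  read_idx <- withr::with_seed(child_seed(config$seed, 202L), {
    extra <- if (n2 > n1) sample.int(n1, n2 - n1) else integer(0)
    sample(c(seq_len(n1), extra))
  })
  roles2 <- withr::with_seed(child_seed(config$seed, 303L), {
    r <- rep("control", n2)
    n_prof <- as.integer(round(config$professional_fraction * n2))
    if (n_prof > 0) r[sample.int(n2, n_prof)] <- "professional"
    r
  })

  phase <- c(rep(1L, n1), rep(2L, n2))
  role <- c(rep("control", n1), roles2)
  narr <- c(narrative_ids, narrative_ids[read_idx])
  label <- c(labels1, labels1[read_idx])

  n <- n1 + n2
  words <- withr::with_seed(child_seed(config$seed, 404L), {
    t(vapply(label, function(e) {
      sample_words(e, lexicons, config$word_noise)
    }, character(5L)))
  })

  totals <- matrix(0L, n, 4L, dimnames = list(NULL, names(SCALES)))
  item_cols <- lapply(SCALES, function(s) matrix(0L, n, s$items))
  withr::with_seed(child_seed(config$seed, 505L), {
    for (e in EMOTIONS) {
      idx <- which(label == e)
      if (!length(idx)) next
      draw <- sample_scale_items(e, config, n = length(idx))
      totals[idx, ] <- draw$totals
      for (s in names(SCALES)) item_cols[[s]][idx, ] <- draw$items[[s]]
    }
  })

  out <- tibble::tibble(
    record_id = sprintf("r%04d", seq_len(n)),
    phase = phase,
    role = role,
    narrative_id = narr,
    true_emotion = label
  )
  for (w in 1:5) out[[paste0("word", w)]] <- words[, w]
  for (s in names(SCALES)) {
    for (k in seq_len(SCALES[[s]]$items)) {
      out[[sprintf("%s_%d", s, k)]] <- item_cols[[s]][, k]
    }
  }
  for (s in names(SCALES)) out[[paste0(s, "_total")]] <- totals[, s]
  out$control_passed <- TRUE
  out
}
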