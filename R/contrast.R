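#' Aggregate embeddings into one unit-length semantic representation
#'
#' Sums the rows of an embedding matrix and normalizes the sum to Euclidean
#' length one.
#'
#' @param embeddings Matrix with one embedding per row (or a single vector).
#' @return Unit-length numeric vector.
#' @export
aggregate_unit_vector <- function(embeddings) {
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, nrow = 1)
  if (nrow(embeddings) < 1L) stop("need at least one embedding")
  s <- colSums(embeddings)
  n <- sqrt(sum(s^2))
  if (n == 0) stop("aggregate is the zero vector")
  s / n
}

#' Difference vector between two aggregate representations
#'
#' @param target_agg,other_agg Unit-length aggregate vectors.
#' @return `(target - other)` normalized to length one. Identical inputs
#'   (zero difference) are an error.
#' @export
difference_vector <- function(target_agg, other_agg) {
  d <- target_agg - other_agg
  n <- sqrt(sum(d^2))
  if (n == 0) stop("difference vector is zero (identical aggregates)")
  d / n
}

#' Similarity of a word to a difference vector
#'
#' The word vector is normalized to unit length, then the dot product with
#' the (unit) difference vector is taken - equivalently, the cosine of the
#' angle between them.
#'
#' @param word_vec Embedding of the word.
#' @param diff_vec Unit difference vector.
#' @return Scalar in \[-1, 1\].
#' @export
word_similarity <- function(word_vec, diff_vec) {
  sum(unit(word_vec) * diff_vec)
}

one_sample_t <- function(x) {
  n <- length(x)
  if (n < 2L) return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  m <- mean(x)
  s <- sd(x)
  if (s == 0) {
    # zero-variance convention: +/-Inf t, p in {0, 1}; all-zero scores give
    # the null result t = 0, p = 0.5
    t <- if (m > 0) Inf else if (m < 0) -Inf else 0
    p <- if (m > 0) 0 else if (m < 0) 1 else 0.5
    return(list(t = t, df = n - 1, p = p))
  }
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = pt(t, n - 1, lower.tail = FALSE))
}

#' Semantic t-test of every word against each emotion
#'
#' For one target emotion, all word occurrences attributed to it are summed
#' into a unit aggregate and contrasted with the aggregate of the other
#' three emotions via a unit difference vector; every unique word is scored
#' by the dot product of its unit embedding with that difference vector.
#' A 10-fold leave-out scheme makes the difference vector independent of
#' the measured occurrences: occurrences are split into `k` folds, and the
#' occurrences of the measured word in a fold are removed from the
#' aggregates before that fold's similarities are computed. A one-sample,
#' one-sided t-test then asks whether the word's per-occurrence
#' similarities exceed zero, with Bonferroni correction over the number of
#' unique words tested for that emotion's contrast.
#'
#' @param words Character vector of word occurrences (one entry per word
#'   per response).
#' @param labels Emotion label of the response each occurrence came from.
#' @param encoder A `qcla_encoder`.
#' @param k Number of leave-out folds, default 10.
#' @param seed Integer seed for the fold split.
#' @param min_count Minimum occurrences for a word to be tested (default 2;
#'   singletons are reported with `NA` statistics).
#' @return Tibble with one row per (emotion, unique word): `emotion`,
#'   `word`, `frequency`, `similarity` (mean over occurrences), `t`, `df`,
#'   `p_value`, `p_bonferroni`.
#' @export
semantic_t_test <- function(words, labels, encoder, k = 10L, seed = 1L,
                            min_count = 2L) {
  stopifnot(length(words) == length(labels),
            all(labels %in% EMOTIONS))
  n <- length(words)
  vocab <- sort(unique(words))
  V <- t(vapply(vocab, function(w) encode_word(encoder, w),
                numeric(encoder$dim)))
  Vu <- V / sqrt(rowSums(V^2))
  widx <- match(words, vocab)

  fold <- withr::with_seed(as.integer(seed), {
    sample(rep(seq_len(k), length.out = n))
  })

  # per-emotion occurrence-weighted sums of embeddings
  emo_sum <- sapply(EMOTIONS, function(e) {
    colSums(V[widx[labels == e], , drop = FALSE])
  })  # dim x 4
  total_sum <- rowSums(emo_sum)

  tested <- vocab[tabulate(widx, length(vocab)) >= min_count]
  n_tested <- length(tested)

  rows <- vector("list", length(EMOTIONS) * length(vocab))
  r <- 0L
  for (e in EMOTIONS) {
    in_e <- labels == e
    s_t_full <- emo_sum[, e]
    s_o_full <- total_sum - s_t_full
    for (wi in seq_along(vocab)) {
      occ <- which(widx == wi)
      freq <- length(occ)
      v_w <- V[wi, ]
      vu_w <- Vu[wi, ]
      sims <- numeric(freq)
      for (oi in seq_along(occ)) {
        f <- fold[occ[oi]]
        same_fold <- occ[fold[occ] == f]
        c_t <- sum(in_e[same_fold])
        c_o <- length(same_fold) - c_t
        s_t <- s_t_full - c_t * v_w
        s_o <- s_o_full - c_o * v_w
        a_t <- s_t / sqrt(sum(s_t^2))
        a_o <- s_o / sqrt(sum(s_o^2))
        dv <- difference_vector(a_t, a_o)
        sims[oi] <- sum(vu_w * dv)
      }
      tt <- one_sample_t(sims)
      r <- r + 1L
      rows[[r]] <- tibble::tibble(
        emotion = e, word = vocab[wi], frequency = freq,
        similarity = mean(sims), t = tt$t, df = tt$df, p_value = tt$p,
        p_bonferroni = if (is.na(tt$p)) NA_real_ else {
          min(1, tt$p * n_tested)
        }
      )
    }
  }
  do.call(rbind, rows[seq_len(r)])
}

#' Word-cloud tables: top words per emotion
#'
#' Keeps, for each emotion, the (at most) `k` words with the highest
#' t-values among those significant after Bonferroni correction; the
#' `frequency` column is the word-cloud weight.
#'
#' @param results Output of [semantic_t_test()].
#' @param k Maximum words per emotion, default 25.
#' @param alpha Significance level on the Bonferroni-corrected p, default
#'   0.05.
#' @return Tibble sorted by emotion then decreasing t.
#' @export
top_words <- function(results, k = 25L, alpha = 0.05) {
  keep <- !is.na(results$t) & !is.na(results$p_bonferroni) &
    results$p_bonferroni < alpha
  res <- results[keep, , drop = FALSE]
  out <- lapply(EMOTIONS, function(e) {
    sub <- res[res$emotion == e, , drop = FALSE]
    sub <- sub[order(-sub$t), , drop = FALSE]
    head(sub, k)
  })
  do.call(rbind, out)
}

#' Export word-cloud tables as TSV
#'
#' @param cloud Output of [top_words()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_word_cloud_tsv <- function(cloud, path) {
  cols <- c("emotion", "word", "t", "p_bonferroni", "frequency", "similarity")
  write.table(as.data.frame(cloud)[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
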