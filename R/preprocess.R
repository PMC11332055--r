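#' Clean one descriptive-word response
#'
#' Applies, in order: whitespace trimming and lowercasing; removal of
#' multi-token entries (responses were restricted to single words); removal
#' of "n/a"-style placeholders; optional dictionary-based spelling
#' correction; collapsing of successively repeated words (adjacent
#' duplicates only). Spell correction replaces a word only when exactly one
#' dictionary entry is at edit distance 1; otherwise the original form is
#' retained.
#'
#' @param words Character vector of raw word entries (NAs allowed).
#' @param dictionary Optional character vector of known-correct words
#'   enabling the spelling pass. Default `NULL` (off).
#' @return List with `words` (cleaned tokens, possibly empty), `n_removed`,
#'   `n_corrected`, and `codes` (rule codes for each removal/correction:
#'   `"multi_token"`, `"na_token"`, `"repeat"`, `"spell"`).
#' @export
#' @examples
#' clean_words(c("Sad", "sad", "calm", "calm", "happy"))$words
clean_words <- function(words, dictionary = NULL) {
  codes <- character(0)
  w <- tolower(trimws(as.character(words)))
  w <- w[!is.na(w) & nzchar(w)]

  multi <- grepl("\\s", w)
  codes <- c(codes, rep("multi_token", sum(multi)))
  w <- w[!multi]

  na_like <- w %in% c("n/a", "na")
  codes <- c(codes, rep("na_token", sum(na_like)))
  w <- w[!na_like]

  n_corrected <- 0L
  if (!is.null(dictionary) && length(w)) {
    dictionary <- tolower(dictionary)
    for (i in seq_along(w)) {
      if (w[i] %in% dictionary) next
      d <- adist(w[i], dictionary)
      hit <- which(d == 1L)
      if (length(hit) == 1L) {
        w[i] <- dictionary[hit]
        n_corrected <- n_corrected + 1L
        codes <- c(codes, "spell")
      }
    }
  }

  if (length(w) > 1) {
    keep <- c(TRUE, w[-1] != w[-length(w)])
    codes <- c(codes, rep("repeat", sum(!keep)))
    w <- w[keep]
  }

  list(words = w,
       n_removed = sum(codes %in% c("multi_token", "na_token", "repeat")),
       n_corrected = n_corrected,
       codes = codes)
}

#' Clean the word responses of a record table
#'
#' Runs [clean_words()] on every record, drops records flagged as failing
#' the embedded control questions, and drops records left with no surviving
#' word. Cleaning is idempotent: cleaning an already-clean table changes
#' nothing.
#'
#' @param records Record tibble as produced by [generate_dataset()] or
#'   [read_records()].
#' @param dictionary Optional dictionary for the spelling pass; default off.
#' @return List with `records` (cleaned tibble; `word1`..`word5` updated,
#'   removed slots set to `NA`) and `report`, a cleaning report list:
#'   `n_input`, `n_retained`, `n_dropped_records`, `n_removed_words`,
#'   `n_corrected_words`, and `reasons` (record_id -> rule codes, including
#'   the drop reasons `"control_failed"` and `"no_words_left"`).
#' @export
clean_records <- function(records, dictionary = NULL) {
  word_cols <- paste0("word", 1:5)
  stopifnot(all(word_cols %in% names(records)))
  n_input <- nrow(records)
  reasons <- list()
  n_removed <- 0L
  n_corrected <- 0L
  keep <- rep(TRUE, n_input)
  wmat <- as.matrix(records[word_cols])

  control <- if ("control_passed" %in% names(records)) {
    records$control_passed
  } else {
    rep(TRUE, n_input)
  }

  for (i in seq_len(n_input)) {
    rid <- records$record_id[i]
    if (!isTRUE(control[i])) {
      keep[i] <- FALSE
      reasons[[rid]] <- "control_failed"
      next
    }
    cl <- clean_words(wmat[i, ], dictionary = dictionary)
    n_removed <- n_removed + cl$n_removed
    n_corrected <- n_corrected + cl$n_corrected
    if (length(cl$codes)) reasons[[rid]] <- cl$codes
    if (length(cl$words) < 1L) {
      keep[i] <- FALSE
      reasons[[rid]] <- c(reasons[[rid]], "no_words_left")
      next
    }
    wmat[i, ] <- c(cl$words, rep(NA_character_, 5L - length(cl$words)))
  }

  out <- records
  out[word_cols] <- as.data.frame(wmat, stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  report <- list(
    n_input = n_input,
    n_retained = sum(keep),
    n_dropped_records = sum(!keep),
    n_removed_words = n_removed,
    n_corrected_words = n_corrected,
    reasons = reasons
  )
  list(records = out, report = report)
}

#' Flag forbidden target words
#'
#' Phase-1 participants were instructed not to use the name of their own
#' condition ("depression" in the depression condition, and so on). This
#' flags - but never deletes - exact matches of the condition word among a
#' Phase-1 record's descriptive words. Phase-2 records are never flagged:
#' readers did not know the condition and were free to use any word, and a
#' condition word was also allowed in Phase 1 under a different condition.
#'
#' @param records Record tibble.
#' @return Logical vector, one flag per record.
#' @export
forbid_target_word <- function(records) {
  word_cols <- paste0("word", 1:5)
  wmat <- as.matrix(records[word_cols])
  vapply(seq_len(nrow(records)), function(i) {
    records$phase[i] == 1L &&
      records$true_emotion[i] %in% tolower(wmat[i, ])
  }, logical(1))
}

#' Extract the surviving words of each record
#'
#' @param records Record tibble.
#' @return List of character vectors (non-missing words per record).
#' @export
record_words <- function(records) {
  wmat <- as.matrix(records[paste0("word", 1:5)])
  lapply(seq_len(nrow(records)), function(i) {
    w <- wmat[i, ]
    unname(w[!is.na(w) & nzchar(w)])
  })
}
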