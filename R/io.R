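record_columns <- function() {
  c("record_id", "phase", "role", "narrative_id", "true_emotion",
    paste0("word", 1:5),
    unlist(lapply(names(SCALES), function(s) {
      sprintf("%s_%d", s, seq_len(SCALES[[s]]$items))
    })),
    paste0(names(SCALES), "_total"),
    "control_passed")
}

#' Write the canonical record TSV
#'
#' Tab-delimited, UTF-8, header row; one row per response record. When a
#' generator configuration is supplied it is written alongside as a JSON
#' sidecar (`<path>.config.json`).
#'
#' @param records Record tibble.
#' @param path Output TSV path.
#' @param config Optional [generator_config()] to record as provenance.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, config = NULL) {
  write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$scale_mean_profile <- as.data.frame(cfg$scale_mean_profile)
    cfg$scale_corr <- as.data.frame(cfg$scale_corr)
    jsonlite::write_json(cfg, paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read and validate a canonical record TSV
#'
#' Parses the tab-delimited record file, checks the schema and every
#' row's value ranges (phase in {1, 2}, known roles and emotions, item
#' scores within each instrument's legal range, totals equal to item sums),
#' and reports all offending rows with their line numbers rather than
#' silently dropping them.
#'
#' @param path Path to a TSV written by [write_records()].
#' @return Validated record tibble. Any invalid row raises an error listing
#'   the problems.
#' @export
read_records <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                    fileEncoding = "UTF-8")
  missing_cols <- setdiff(record_columns(), names(tab))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  problems <- character(0)
  bad <- function(rows, what) {
    if (length(rows)) {
      # +1 for the header row: report physical file line numbers
      sprintf("line %d: %s", rows + 1L, what)
    } else character(0)
  }
  problems <- c(problems,
                bad(which(!tab$phase %in% c(1L, 2L)), "phase must be 1 or 2"),
                bad(which(!tab$role %in% c("control", "professional")),
                    "unknown role"),
                bad(which(!tab$true_emotion %in% EMOTIONS),
                    "unknown emotion label"))
  for (s in names(SCALES)) {
    sc <- SCALES[[s]]
    items <- as.matrix(tab[sprintf("%s_%d", s, seq_len(sc$items))])
    out_of_range <- which(apply(items, 1L, function(r) {
      anyNA(r) || any(r < sc$lo) || any(r > sc$hi)
    }))
    problems <- c(problems,
                  bad(out_of_range,
                      sprintf("%s item out of range [%d, %d]",
                              s, sc$lo, sc$hi)))
    mismatch <- which(rowSums(items) != tab[[paste0(s, "_total")]])
    problems <- c(problems,
                  bad(setdiff(mismatch, out_of_range),
                      sprintf("%s_total does not equal the item sum", s)))
  }
  if (length(problems)) {
    stop("invalid record file:\n  ",
         paste(head(problems, 20L), collapse = "\n  "),
         if (length(problems) > 20L) sprintf("\n  ... and %d more",
                                             length(problems) - 20L))
  }
  tibble::as_tibble(tab)
}

#' Configuration of a full experiment run
#'
#' @param generator A [generator_config()] used to simulate the data, or
#'   `NULL` when `input` is given.
#' @param input Optional path to a canonical record TSV to analyze instead
#'   of simulating.
#' @param feature_sets Feature sets to run, subset of
#'   `c("words", "scales", "combined", "items")`.
#' @param encoder `"mock"` or a ready-made `qcla_encoder`.
#' @param k Outer folds, default 10.
#' @param seed Master seed for all stages.
#' @param phase_filter `"all"`, `1`, or `2`.
#' @param role_filter `"all"`, `"control"`, or `"professional"`.
#' @param contrast Run the semantic t-test and word-cloud export?
#' @param output_dir Optional directory for the report artifacts.
#' @return A `qcla_run_config` list.
#' @export
run_config <- function(generator = generator_config(),
                       input = NULL,
                       feature_sets = c("words", "scales"),
                       encoder = "mock",
                       k = 10L,
                       seed = 1L,
                       phase_filter = "all",
                       role_filter = "all",
                       contrast = TRUE,
                       output_dir = NULL) {
  stopifnot(all(feature_sets %in% c("words", "scales", "combined", "items")))
  if (!is.null(input) && !file.exists(input)) {
    stop_config("input path does not exist: ", input)
  }
  structure(
    list(generator = generator, input = input, feature_sets = feature_sets,
         encoder = encoder, k = as.integer(k), seed = as.integer(seed),
         phase_filter = phase_filter, role_filter = role_filter,
         contrast = contrast, output_dir = output_dir),
    class = "qcla_run_config"
  )
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full words-versus-scales experiment
#'
#' Pipeline: obtain records (simulate or read), clean the word responses,
#' build each requested feature matrix, run the narrative-grouped
#' cross-validated categorization, compute the confusion matrix and
#' per-class accuracy/precision, compare the words and scales feature sets
#' with a two-proportion chi-square (with bootstrap phi interval), and
#' optionally run the semantic t-test word contrast. All randomness derives
#' from `config$seed`; with the mock encoder a rerun reproduces the report
#' bit for bit. Stage progress and timings go to the message stream; the
#' JSON report itself contains no timings, so it is byte-stable.
#'
#' @param config A [run_config()].
#' @return Report bundle (list): `config_echo`, `cleaning`, one entry per
#'   feature set (`percent_correct`, `selected_dims`, `confusion`,
#'   `accuracy_precision`, `coefficient_correlations`), `comparison`, and
#'   `cloud` when contrast is enabled. Written to `output_dir` as
#'   `report.json`, `confusion_<set>.tsv` and `word_cloud.tsv` when set.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "qcla_run_config"))
  t0 <- Sys.time()
  records <- if (!is.null(config$input)) {
    stage_log("data", "reading %s", config$input)
    read_records(config$input)
  } else {
    stage_log("data", "simulating study (seed %d)", config$generator$seed)
    generate_dataset(config$generator)
  }
  if (!identical(config$phase_filter, "all")) {
    records <- records[records$phase == as.integer(config$phase_filter), ]
  }
  if (!identical(config$role_filter, "all")) {
    records <- records[records$role == config$role_filter, ]
  }
  stage_log("data", "%d records after filtering", nrow(records))

  cleaned <- clean_records(records)
  records <- cleaned$records
  stage_log("clean", "%d retained, %d dropped, %d words removed",
            cleaned$report$n_retained, cleaned$report$n_dropped_records,
            cleaned$report$n_removed_words)

  encoder <- config$encoder
  if (identical(encoder, "mock")) {
    lex <- if (!is.null(config$generator)) {
      build_lexicons(config$generator)
    } else NULL
    encoder <- mock_encoder(lexicons = lex,
                            seed = child_seed(config$seed, 77L))
  }

  bundle <- list(
    config_echo = list(
      feature_sets = config$feature_sets, k = config$k, seed = config$seed,
      encoder = if (inherits(encoder, "qcla_encoder")) encoder$name else encoder,
      phase_filter = as.character(config$phase_filter),
      role_filter = config$role_filter,
      n_records = nrow(records)
    ),
    cleaning = cleaned$report[c("n_input", "n_retained", "n_dropped_records",
                                "n_removed_words", "n_corrected_words")]
  )

  results <- list()
  for (fs in config$feature_sets) {
    t1 <- Sys.time()
    feats <- build_feature_matrix(records, fs, encoder = encoder)
    cv <- cross_validated_categorize(feats, k = config$k,
                                     seed = child_seed(config$seed, 900L))
    cm <- confusion(cv$truth, cv$predicted)
    cc <- coefficient_correlations(
      do.call(rbind, lapply(cv$coefficients, function(b) b[-1, , drop = FALSE]))
    )
    results[[fs]] <- list(
      percent_correct = cv$percent_correct,
      selected_dims = cv$selected_dims,
      confusion = unclass(cm),
      accuracy_precision = class_accuracy_precision(cm),
      coefficient_correlations = cc$r,
      cv = cv
    )
    stage_log(fs, "%.1f%% correct (%.1fs)", cv$percent_correct,
              as.numeric(difftime(Sys.time(), t1, units = "secs")))
  }
  bundle$results <- results

  if (all(c("words", "scales") %in% names(results))) {
    n <- bundle$config_echo$n_records
    cmp <- two_proportion_chi2(results$words$percent_correct / 100,
                               results$scales$percent_correct / 100, n)
    bundle$comparison <- c(
      unclass(cmp)[c("p1", "p2", "N", "chi2", "df", "p_value", "phi")],
      list(phi_ci = phi_ci(cmp$p1, cmp$p2, n,
                           seed = child_seed(config$seed, 555L)))
    )
    stage_log("compare", "words %.1f%% vs scales %.1f%%: X2 = %.2f",
              100 * cmp$p1, 100 * cmp$p2, cmp$chi2)
  }

  if (isTRUE(config$contrast)) {
    wl <- record_words(records)
    occ <- unlist(wl, use.names = FALSE)
    lab <- rep(records$true_emotion, lengths(wl))
    res <- semantic_t_test(occ, lab, encoder,
                           seed = child_seed(config$seed, 333L))
    bundle$cloud <- top_words(res)
    stage_log("contrast", "%d unique words tested",
              length(unique(res$word)))
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    report <- bundle
    report$results <- lapply(report$results, function(r) {
      r$cv <- NULL
      r$confusion <- as.data.frame(r$confusion)
      r$accuracy_precision <- as.data.frame(r$accuracy_precision)
      r$coefficient_correlations <- as.data.frame(r$coefficient_correlations)
      r
    })
    if (!is.null(report$cloud)) report$cloud <- as.data.frame(report$cloud)
    jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (fs in names(results)) {
      write.table(results[[fs]]$confusion,
                  file.path(config$output_dir,
                            sprintf("confusion_%s.tsv", fs)),
                  sep = "\t", quote = FALSE)
    }
    if (!is.null(bundle$cloud)) {
      write_word_cloud_tsv(bundle$cloud,
                           file.path(config$output_dir, "word_cloud.tsv"))
    }
  }
  stage_log("done", "total %.1fs",
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(bundle)
}
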