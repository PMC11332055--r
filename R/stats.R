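#' Confusion matrix of emotion categorizations
#'
#' @param true_labels,predicted_labels Equal-length vectors of emotion
#'   labels (each must be one of [emotions()]).
#' @return A `qcla_confusion`: 4x4 integer matrix, rows = empirical
#'   (true) emotion, columns = predicted emotion.
#' @export
confusion <- function(true_labels, predicted_labels) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  stopifnot(length(true_labels) == length(predicted_labels))
  bad <- setdiff(unique(c(true_labels, predicted_labels)), EMOTIONS)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  cm <- table(factor(true_labels, levels = EMOTIONS),
              factor(predicted_labels, levels = EMOTIONS))
  m <- matrix(as.integer(cm), 4, 4, dimnames = list(EMOTIONS, EMOTIONS))
  structure(m, class = c("qcla_confusion", class(m)))
}

#' Percent correct of a confusion matrix
#' @param cm A `qcla_confusion`.
#' @return `100 * trace / total`.
#' @export
percent_correct <- function(cm) {
  100 * sum(diag(cm)) / sum(cm)
}

#' Per-class accuracy and precision
#'
#' Accuracy of a class is (TP + TN) / total; precision is TP / (TP + FP),
#' both as percentages. Precision is `NA` (reported missing) for a class
#' that is never predicted.
#'
#' @param cm A `qcla_confusion`.
#' @return 2x4 numeric matrix, rows `accuracy` and `precision`, columns the
#'   four emotions.
#' @export
class_accuracy_precision <- function(cm) {
  total <- sum(cm)
  out <- sapply(EMOTIONS, function(e) {
    tp <- cm[e, e]
    fp <- sum(cm[, e]) - tp
    fn <- sum(cm[e, ]) - tp
    tn <- total - tp - fp - fn
    c(accuracy = 100 * (tp + tn) / total,
      precision = if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp))
  })
  out
}

#' Two-proportion chi-square with phi effect size
#'
#' Compares two proportions measured on equal groups of size `N / 2` with
#' the closed form `chi2 = N * (p1 - p2)^2 / (4 * pbar * (1 - pbar))`,
#' `pbar = (p1 + p2) / 2`, on one degree of freedom; this equals the
#' cell-wise Pearson chi-square of the corresponding 2x2 table whenever the
#' implied counts are integral. The effect size is `phi = sqrt(chi2 / N)`.
#'
#' @param p1,p2 Proportions in \[0, 1\].
#' @param N Total count over both groups.
#' @return A `qcla_comparison`: list with `p1`, `p2`, `N`, `chi2`, `df`,
#'   `p_value` (upper tail of chi-square on 1 df), `phi`.
#' @export
#' @examples
#' two_proportion_chi2(0.64, 0.44, 400)  # chi2 = 16.10, phi = 0.20
two_proportion_chi2 <- function(p1, p2, N) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, N > 0)
  pbar <- (p1 + p2) / 2
  if (pbar <= 0 || pbar >= 1) {
    stop("degenerate pooled proportion (0 or 1)")
  }
  chi2 <- N * (p1 - p2)^2 / (4 * pbar * (1 - pbar))
  structure(
    list(p1 = p1, p2 = p2, N = N, chi2 = chi2, df = 1L,
         p_value = pchisq(chi2, 1L, lower.tail = FALSE),
         phi = sqrt(chi2 / N)),
    class = "qcla_comparison"
  )
}

#' @export
print.qcla_comparison <- function(x, ...) {
  cat(sprintf("X2(1, %d) = %.2f, p = %.4f, phi = %.2f\n",
              as.integer(x$N), x$chi2, x$p_value, x$phi))
  invisible(x)
}

#' Bootstrap confidence interval for phi
#'
#' Reconstructs the 2x2 table implied by the two proportions on equal
#' groups of size `N / 2`, resamples the two success counts binomially, and
#' returns the percentile interval of the signed phi
#' `(p1 - p2) / (2 * sqrt(pbar * (1 - pbar)))` (signed so that intervals of
#' near-zero effects straddle zero).
#'
#' @param p1,p2,N As in [two_proportion_chi2()].
#' @param confidence Coverage, default 0.95.
#' @param B Number of bootstrap resamples, default 2000.
#' @param seed Integer seed.
#' @return Numeric `c(lower, upper)`.
#' @export
phi_ci <- function(p1, p2, N, confidence = 0.95, B = 2000L, seed = 1L) {
  n1 <- floor(N / 2)
  n2 <- N - n1
  a <- round(p1 * n1)
  b <- round(p2 * n2)
  withr::with_seed(as.integer(seed), {
    p1s <- rbinom(B, n1, a / n1) / n1
    p2s <- rbinom(B, n2, b / n2) / n2
    pbar <- (p1s + p2s) / 2
    phis <- ifelse(pbar <= 0 | pbar >= 1, 0,
                   (p1s - p2s) / (2 * sqrt(pbar * (1 - pbar))))
    alpha <- (1 - confidence) / 2
    unname(quantile(phis, c(alpha, 1 - alpha)))
  })
}

#' Fisher-z confidence interval for a Pearson correlation
#'
#' @param r Pearson correlation.
#' @param n Sample size (> 3).
#' @param confidence Coverage, default 0.95.
#' @return Numeric `c(lower, upper)`.
#' @export
fisher_ci <- function(r, n, confidence = 0.95) {
  stopifnot(n > 3, abs(r) <= 1)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - confidence) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Pairwise correlations of per-class coefficient vectors
#'
#' Pearson correlations between the multinomial coefficient vectors of the
#' four classes, with Fisher-z 95% confidence intervals - high absolute
#' correlations indicate a model that confuses the classes.
#'
#' @param coef_by_class Numeric matrix, one column of coefficients per
#'   class (>= 2 rows).
#' @return List with `r` (4x4 symmetric matrix), `ci_lower`, `ci_upper`
#'   (same shape), `n` (number of coefficients per vector). Constant
#'   columns yield `NA` correlations with a warning.
#' @export
coefficient_correlations <- function(coef_by_class) {
  m <- as.matrix(coef_by_class)
  stopifnot(nrow(m) >= 2)
  if (any(apply(m, 2L, sd) == 0)) {
    warning("constant coefficient vector: correlations undefined")
  }
  r <- suppressWarnings(cor(m))
  lo <- hi <- r
  for (i in seq_len(ncol(m))) {
    for (j in seq_len(ncol(m))) {
      if (i == j || is.na(r[i, j]) || nrow(m) <= 3 || abs(r[i, j]) == 1) {
        lo[i, j] <- hi[i, j] <- NA_real_
      } else {
        ci <- fisher_ci(r[i, j], nrow(m))
        lo[i, j] <- ci[1]
        hi[i, j] <- ci[2]
      }
    }
  }
  list(r = r, ci_lower = lo, ci_upper = hi, n = nrow(m))
}

#' Inter-rater agreement over multiply-rated narratives
#'
#' Over all unordered pairs of categorizations of the same narrative:
#' `agreement` is the percentage of pairs with identical labels and
#' `correct` the percentage of pairs that are identical and equal to the
#' narrative's true label.
#'
#' @param narrative_ids Narrative id per categorization.
#' @param categorizations Assigned emotion label per categorization.
#' @param true_labels True emotion label per categorization.
#' @return List with `agreement`, `correct` (percentages) and `n_pairs`.
#' @export
interrater_agreement <- function(narrative_ids, categorizations,
                                 true_labels) {
  stopifnot(length(narrative_ids) == length(categorizations),
            length(narrative_ids) == length(true_labels))
  total <- agree <- correct <- 0
  for (id in unique(narrative_ids)) {
    idx <- which(narrative_ids == id)
    m <- length(idx)
    if (m < 2L) next
    labs <- as.character(categorizations[idx])
    truth <- unique(as.character(true_labels[idx]))
    stopifnot(length(truth) == 1L)
    total <- total + choose(m, 2)
    cnt <- table(labs)
    agree <- agree + sum(choose(cnt, 2))
    correct <- correct + choose(sum(labs == truth), 2)
  }
  if (total == 0) stop("no narrative was categorized more than once")
  list(agreement = 100 * agree / total,
       correct = 100 * correct / total,
       n_pairs = as.integer(total))
}

#' Matched-narrative correlations with a Fisher r-to-z contrast
#'
#' For one rating scale, correlates the Phase-1 score of each narrative
#' with (a) the matched Phase-2 rating-scale score and (b) the matched
#' Phase-2 word-based regression prediction of that score, then tests
#' whether the two correlations differ via the Fisher r-to-z transform,
#' `z = (atanh(r2) - atanh(r1)) / sqrt(2 / (n - 3))`, two-sided.
#'
#' @param phase1 Phase-1 rating-scale scores (one per matched narrative).
#' @param phase2_scale Matched Phase-2 rating-scale scores.
#' @param phase2_predicted Matched Phase-2 word-based predictions of the
#'   scale.
#' @return List with `r_scale`, `r_words`, their Fisher-z 95% CIs, `n`,
#'   `z`, and `p_value`.
#' @export
matched_correlations <- function(phase1, phase2_scale, phase2_predicted) {
  n <- length(phase1)
  stopifnot(length(phase2_scale) == n, length(phase2_predicted) == n)
  if (n <= 3) stop("need more than 3 matched narratives")
  r1 <- cor(phase1, phase2_scale)
  r2 <- cor(phase1, phase2_predicted)
  z <- (atanh(r2) - atanh(r1)) / sqrt(2 / (n - 3))
  list(r_scale = r1, r_words = r2,
       ci_scale = fisher_ci(r1, n), ci_words = fisher_ci(r2, n),
       n = n, z = z, p_value = 2 * pnorm(-abs(z)))
}
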