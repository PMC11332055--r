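test_that("confusion matrices tally correctly", {
  emo <- emotions()
  # perfect prediction: diagonal
  cm <- confusion(emo, emo)
  expect_equal(sum(diag(cm)), 4L)
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  expect_equal(percent_correct(cm), 100)

  # everything predicted depression: one nonzero column
  cm2 <- confusion(rep(emo, 2), rep("depression", 8))
  expect_equal(unname(colSums(cm2)), c(0L, 0L, 8L, 0L))

  # hand-built 12-record tally
  truth <- c(rep("harmony", 3), rep("satisfaction", 3),
             rep("depression", 3), rep("anxiety", 3))
  pred <- c("harmony", "harmony", "satisfaction",
            "satisfaction", "harmony", "satisfaction",
            "depression", "anxiety", "anxiety",
            "anxiety", "depression", "depression")
  cm3 <- confusion(truth, pred)
  expect_equal(cm3["harmony", "harmony"], 2L)
  expect_equal(cm3["harmony", "satisfaction"], 1L)
  expect_equal(cm3["depression", "anxiety"], 2L)
  expect_equal(cm3["anxiety", "depression"], 2L)
  expect_equal(unname(rowSums(cm3)), rep(3L, 4))
  expect_equal(percent_correct(cm3), 100 * 6 / 12)

  expect_error(confusion(c("joy"), c("harmony")), "unknown")
})

test_that("per-class accuracy and precision match manual arithmetic", {
  emo <- emotions()
  cm <- confusion(emo, emo)
  ap <- class_accuracy_precision(cm)
  expect_true(all(ap["accuracy", ] == 100))
  expect_true(all(ap["precision", ] == 100))

  truth <- c(rep("harmony", 4), rep("satisfaction", 4),
             rep("depression", 4), rep("anxiety", 4))
  pred <- c("harmony", "harmony", "harmony", "depression",
            "satisfaction", "satisfaction", "harmony", "harmony",
            "depression", "depression", "depression", "depression",
            "depression", "anxiety", "anxiety", "anxiety")
  cm2 <- confusion(truth, pred)
  ap2 <- class_accuracy_precision(cm2)
  # harmony: TP=3, FP=2, FN=1, TN=10
  expect_equal(ap2["accuracy", "harmony"], 100 * 13 / 16)
  expect_equal(ap2["precision", "harmony"], 100 * 3 / 5)
  # satisfaction: TP=2, FP=0 -> precision 100
  expect_equal(ap2["precision", "satisfaction"], 100)
  # a never-predicted class has missing precision
  cm3 <- confusion(emo, rep("depression", 4))
  expect_true(is.na(class_accuracy_precision(cm3)["precision", "harmony"]))
  expect_equal(dim(ap2), c(2L, 4L))
})

test_that("the two-proportion chi-square reproduces the closed form", {
  # equal proportions: no effect
  eq <- two_proportion_chi2(0.5, 0.5, 200)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$phi, 0)
  expect_equal(eq$p_value, 1)

  expect_error(two_proportion_chi2(0, 0, 100), "degenerate")

  # equivalence with the cell-wise Pearson chi-square on all integral
  # 2x2 tables with group sizes (margins) up to 30
  for (n in c(4L, 9L, 17L, 30L)) {
    for (a in 0:n) {
      for (b in 0:n) {
        if ((a + b) %in% c(0L, 2L * n)) next
        tab <- rbind(c(a, n - a), c(b, n - b))
        ref <- suppressWarnings(
          chisq.test(tab, correct = FALSE)$statistic
        )
        got <- two_proportion_chi2(a / n, b / n, 2L * n)$chi2
        expect_equal(got, unname(ref), tolerance = 1e-10)
      }
    }
  }
})

test_that("bootstrap phi intervals behave sensibly", {
  ci <- phi_ci(0.64, 0.44, 400, seed = 2)
  est <- two_proportion_chi2(0.64, 0.44, 400)$phi
  expect_lte(ci[1], est)
  expect_gte(ci[2], est)
  expect_lt(ci[1], ci[2])

  # null effect: interval straddles zero
  ci0 <- phi_ci(0.5, 0.5, 400, seed = 2)
  expect_lt(ci0[1], 0)
  expect_gt(ci0[2], 0)

  # width shrinks as N grows
  widths <- sapply(c(100, 400, 1600, 6400), function(N) {
    diff(phi_ci(0.6, 0.45, N, seed = 3))
  })
  expect_true(all(diff(widths) < 0))

  # reproducible
  expect_identical(phi_ci(0.64, 0.44, 400, seed = 2), ci)
})

test_that("coefficient correlations match the textbook Pearson oracle", {
  withr::with_seed(12, m <- matrix(rnorm(5 * 4), 5,
                                   dimnames = list(NULL, emotions())))
  cc <- coefficient_correlations(m)
  # identical vectors correlate 1; a vector and its negation -1
  same <- coefficient_correlations(cbind(a = m[, 1], b = m[, 1]))
  expect_equal(same$r["a", "b"], 1)
  neg <- coefficient_correlations(cbind(a = m[, 1], b = -m[, 1]))
  expect_equal(neg$r["a", "b"], -1)

  # manual Pearson on one pair
  x <- m[, 1]; y <- m[, 2]
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cc$r[1, 2], r_manual, tolerance = 1e-12)
  expect_true(all(cc$ci_lower <= cc$r | is.na(cc$ci_lower)))
  expect_true(all(cc$ci_upper >= cc$r | is.na(cc$ci_upper)))
  expect_warning(coefficient_correlations(cbind(m[, 1], rep(1, 5))),
                 "constant")
})

test_that("inter-rater agreement counts unordered pairs exactly", {
  # two raters per narrative, always identical and correct
  ids <- rep(c("n1", "n2"), each = 2)
  truth <- rep(c("harmony", "anxiety"), each = 2)
  agree <- interrater_agreement(ids, truth, truth)
  expect_equal(agree$agreement, 100)
  expect_equal(agree$correct, 100)
  expect_equal(agree$n_pairs, 2L)

  # identical but always wrong: agreement 100, correct 0
  wrong <- rep(c("depression", "harmony"), each = 2)
  agree2 <- interrater_agreement(ids, wrong, truth)
  expect_equal(agree2$agreement, 100)
  expect_equal(agree2$correct, 0)

  # hand-enumerated 3-narrative mix: n1 has raters (H, H, S) -> 3 pairs,
  # 1 agreeing and correct; n2 has (D, A) -> 1 pair, 0 agreeing;
  # n3 has a single rater -> no pairs
  ids3 <- c("n1", "n1", "n1", "n2", "n2", "n3")
  cats <- c("harmony", "harmony", "satisfaction",
            "depression", "anxiety", "harmony")
  tr3 <- c(rep("harmony", 3), rep("anxiety", 2), "harmony")
  a3 <- interrater_agreement(ids3, cats, tr3)
  expect_equal(a3$n_pairs, 4L)
  expect_equal(a3$agreement, 100 * 1 / 4)
  expect_equal(a3$correct, 100 * 1 / 4)
  expect_lte(a3$correct, a3$agreement)

  expect_error(interrater_agreement("n1", "harmony", "harmony"),
               "more than once")
})

test_that("matched correlations and the Fisher r-to-z contrast work", {
  # equal correlations: z = 0, p = 1 (same vector twice)
  withr::with_seed(30, {
    x <- rnorm(50)
    y <- x + rnorm(50)
  })
  mc0 <- matched_correlations(x, y, y)
  expect_equal(mc0$z, 0)
  expect_equal(mc0$p_value, 1)

  # textbook Pearson oracle on a small set
  x5 <- c(1, 2, 3, 4, 5); y5 <- c(2, 1, 4, 3, 6)
  mc5 <- matched_correlations(x5, y5, y5)
  r_manual <- sum((x5 - 3) * (y5 - mean(y5))) /
    sqrt(sum((x5 - 3)^2) * sum((y5 - mean(y5))^2))
  expect_equal(mc5$r_scale, r_manual, tolerance = 1e-12)
  expect_error(matched_correlations(1:3, 1:3, 1:3), "more than 3")

  # Fisher CI contains r and has roughly nominal coverage
  cover <- withr::with_seed(77, {
    mean(replicate(600, {
      z <- matrix(rnorm(200 * 2), ncol = 2)
      z[, 2] <- 0.5 * z[, 1] + sqrt(1 - 0.25) * z[, 2]
      ci <- fisher_ci(cor(z[, 1], z[, 2]), 200)
      ci[1] <= 0.5 && 0.5 <= ci[2]
    }))
  })
  expect_gt(cover, 0.91)
  expect_lt(cover, 0.99)
})
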