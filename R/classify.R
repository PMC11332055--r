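#' The dimension ladder
#'
#' The fixed sequence of leading-component counts tried during inner model
#' selection: 1, 2, 3, 5, 7, 10, 14, 19, 26, 35, 46, 61, 80, 105, 137, 179,
#' 234, 305, 397, 517, 768, truncated at the feature dimensionality `d`
#' (with `d` itself appended, so 4-dimensional scale features yield
#' 1, 2, 3, 4).
#'
#' @param d Number of feature columns.
#' @return Strictly increasing integer vector with maximum `d`.
#' @export
#' @examples
#' dimension_ladder(4)
#' dimension_ladder(26)
dimension_ladder <- function(d) {
  base <- c(1L, 2L, 3L, 5L, 7L, 10L, 14L, 19L, 26L, 35L, 46L, 61L, 80L,
            105L, 137L, 179L, 234L, 305L, 397L, 517L, 768L)
  d <- as.integer(d)
  if (d < 1) stop("d must be positive")
  unique(c(base[base < d], d))
}

#' Narrative-grouped fold assignment
#'
#' Assigns records to `k` folds such that all records of the same narrative
#' share a fold (no narrative can appear in both a training and a test
#' split). Narratives are shuffled, then greedily placed - largest
#' multiplicity first - into the currently smallest fold, so fold sizes are
#' as even as the multiplicities allow.
#'
#' @param narrative_ids Character vector, one entry per record.
#' @param k Number of folds (default 10).
#' @param seed Optional integer seed; when supplied the plan is reproducible
#'   and the caller's RNG state is untouched.
#' @return A `qcla_fold_plan`: list with `assignments` (fold index per
#'   record), `k`, and `narrative_fold` (named vector).
#' @export
make_group_folds <- function(narrative_ids, k = 10L, seed = NULL) {
  ids <- unique(narrative_ids)
  if (length(ids) < k) {
    stop("need at least k = ", k, " unique narratives, got ", length(ids))
  }
  shuffle <- function() {
    ord <- sample(ids)
    cnt <- as.integer(table(narrative_ids)[ord])
    o <- order(-cnt)                       # stable: ties keep shuffled order
    ord <- ord[o]
    cnt <- cnt[o]
    sizes <- numeric(k)
    fold <- integer(length(ord))
    for (i in seq_along(ord)) {
      f <- which.min(sizes)
      fold[i] <- f
      sizes[f] <- sizes[f] + cnt[i]
    }
    setNames(fold, ord)
  }
  nf <- if (is.null(seed)) shuffle() else {
    withr::with_seed(as.integer(seed), shuffle())
  }
  plan <- structure(
    list(assignments = unname(nf[narrative_ids]), k = as.integer(k),
         narrative_fold = nf),
    class = "qcla_fold_plan"
  )
  assert_no_leakage(plan, narrative_ids)
  plan
}

#' Assert that a fold plan leaks no narrative across folds
#'
#' @param plan A `qcla_fold_plan`.
#' @param narrative_ids The narrative ids the plan was built for.
#' @return `TRUE` invisibly; errors if any narrative spans two folds or any
#'   record is unassigned.
#' @export
assert_no_leakage <- function(plan, narrative_ids) {
  stopifnot(length(plan$assignments) == length(narrative_ids),
            !anyNA(plan$assignments))
  spans <- tapply(plan$assignments, narrative_ids,
                  function(f) length(unique(f)))
  if (any(spans > 1L)) {
    stop("fold plan leaks narratives across folds: ",
         paste(names(spans)[spans > 1L], collapse = ", "))
  }
  invisible(TRUE)
}

#' Fit an SVD compressor on training rows
#'
#' Decomposes the training matrix so that leading components carry the most
#' variance; new rows are projected onto the first `m` right singular
#' vectors. No column centering by default (configurable).
#'
#' @param X Training matrix (rows >= 2, not all zero).
#' @param center Center columns before decomposition? Default `FALSE`.
#' @return A `qcla_svd` object with fields `v`, `d` (singular values,
#'   decreasing), `center`, and `rank`.
#' @export
fit_svd <- function(X, center = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least two rows to fit the compressor")
  ctr <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2L, ctr)
  if (all(Xc == 0)) stop("degenerate all-zero matrix")
  s <- svd(Xc, nu = 0)
  tol <- max(dim(Xc)) * .Machine$double.eps * s$d[1]
  structure(
    list(v = s$v, d = s$d, center = ctr, rank = sum(s$d > tol)),
    class = "qcla_svd"
  )
}

#' Project rows onto leading components
#'
#' @param object A `qcla_svd` compressor.
#' @param newdata Matrix with the same columns the compressor was fitted on.
#' @param m Number of leading components (defaults to the full rank).
#' @param ... Unused.
#' @return `nrow(newdata)` x `m` score matrix.
#' @export
predict.qcla_svd <- function(object, newdata, m = object$rank, ...) {
  stopifnot(m >= 1, m <= ncol(object$v))
  sweep(as.matrix(newdata), 2L, object$center) %*%
    object$v[, seq_len(m), drop = FALSE]
}

# ---- multinomial logistic regression (full-softmax, tiny ridge) ----------

#' Fit multinomial logistic regression by penalized maximum likelihood
#'
#' Full-softmax parameterization (one coefficient column per class, made
#' identifiable by a tiny ridge penalty on all coefficients), optimized with
#' L-BFGS on the exact negative log-likelihood and its gradient. Columns
#' are standardized internally for conditioning; with the default penalty
#' the fit is in effect the maximum-likelihood solution.
#'
#' @param X Numeric design matrix (no intercept column; one is added).
#' @param y Factor of class labels; its level order is kept and also breaks
#'   argmax ties at prediction.
#' @param lambda Ridge weight, default `1e-6`.
#' @param maxit Maximum L-BFGS iterations.
#' @param init Optional warm-start coefficient matrix from a fit on the
#'   leading columns of the same data (rows are padded with zeros).
#' @return A `qcla_multinom` with `coefficients` ((d+1) x K, standardized
#'   scale), `levels`, `center`, `scale`.
#' @export
fit_multinomial <- function(X, y, lambda = 1e-6, maxit = 150L, init = NULL) {
  X <- as.matrix(X)
  y <- as.factor(y)
  lev <- levels(y)
  K <- length(lev)
  n <- nrow(X)
  stopifnot(n == length(y), K >= 2)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Z <- cbind(1, sweep(sweep(X, 2L, ctr), 2L, scl, "/"))
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  p <- ncol(Z)

  b0 <- matrix(0, p, K)
  if (!is.null(init)) {
    r <- min(nrow(init), p)
    b0[seq_len(r), ] <- init[seq_len(r), ]
  }

  negll <- function(beta) {
    B <- matrix(beta, p, K)
    A <- Z %*% B
    M <- apply(A, 1L, max)
    lse <- M + log(rowSums(exp(A - M)))
    -(sum(A * Y) - sum(lse)) + lambda / 2 * sum(B^2)
  }
  grad <- function(beta) {
    B <- matrix(beta, p, K)
    A <- Z %*% B
    A <- A - apply(A, 1L, max)
    P <- exp(A)
    P <- P / rowSums(P)
    as.numeric(crossprod(Z, P - Y) + lambda * B)
  }
  opt <- optim(as.numeric(b0), negll, grad, method = "L-BFGS-B",
               control = list(maxit = maxit))
  structure(
    list(coefficients = matrix(opt$par, p, K,
                               dimnames = list(NULL, lev)),
         levels = lev, center = ctr, scale = scl,
         lambda = lambda, value = opt$value,
         convergence = opt$convergence),
    class = "qcla_multinom"
  )
}

#' Predict classes from a fitted multinomial model
#'
#' @param object A `qcla_multinom`.
#' @param newdata Matrix with the columns used at fit time.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted classes (ties broken toward the first level
#'   in the canonical order) or a probability matrix.
#' @export
predict.qcla_multinom <- function(object, newdata, type = c("class", "prob"),
                                  ...) {
  type <- match.arg(type)
  Z <- cbind(1, sweep(sweep(as.matrix(newdata), 2L, object$center),
                      2L, object$scale, "/"))
  A <- Z %*% object$coefficients
  if (type == "class") {
    return(factor(object$levels[max.col(A, ties.method = "first")],
                  levels = object$levels))
  }
  A <- A - apply(A, 1L, max)
  P <- exp(A)
  P / rowSums(P)
}

# ---- dimension selection -------------------------------------------------

#' Select the compression dimensionality on training data only
#'
#' Runs a narrative-grouped inner cross-validation inside the training
#' partition: for every ladder value `m`, a multinomial model is fitted on
#' the first `m` compressed dimensions of the inner-training rows and its
#' miscategorizations counted on the inner-validation rows. The `m` with
#' the fewest total miscategorizations wins; ties go to the smallest `m`.
#'
#' @param scores Compressed training score matrix (records x components).
#' @param y Factor of training labels.
#' @param ladder Candidate dimension counts (values beyond `ncol(scores)`
#'   are dropped; an empty ladder is an error).
#' @param groups Narrative ids of the training records.
#' @param inner_k Number of inner folds, default 5.
#' @param seed Integer seed for the inner fold plan.
#' @param lambda,maxit Passed to [fit_multinomial()].
#' @return List with `m` (the winner) and `errors` (named miscategorization
#'   counts per ladder value).
#' @export
select_dimensions <- function(scores, y, ladder, groups, inner_k = 5L,
                              seed = 1L, lambda = 1e-6, maxit = 150L) {
  ladder <- ladder[ladder <= ncol(scores)]
  if (!length(ladder)) stop("dimension ladder is empty after truncation")
  inner_k <- min(inner_k, length(unique(groups)))
  plan <- make_group_folds(groups, k = inner_k, seed = seed)
  errs <- setNames(numeric(length(ladder)), ladder)
  for (f in seq_len(inner_k)) {
    tr <- plan$assignments != f
    te <- !tr
    warm <- NULL
    for (j in seq_along(ladder)) {
      m <- ladder[j]
      fit <- fit_multinomial(scores[tr, seq_len(m), drop = FALSE], y[tr],
                             lambda = lambda, maxit = maxit, init = warm)
      warm <- fit$coefficients
      pred <- predict(fit, scores[te, seq_len(m), drop = FALSE])
      errs[j] <- errs[j] + sum(pred != y[te])
    }
  }
  list(m = ladder[which.min(errs)], errors = errs)
}

select_dimensions_lm <- function(scores, tgt, ladder, groups, inner_k = 5L,
                                 seed = 1L, lambda = 1e-6) {
  ladder <- ladder[ladder <= ncol(scores)]
  if (!length(ladder)) stop("dimension ladder is empty after truncation")
  inner_k <- min(inner_k, length(unique(groups)))
  plan <- make_group_folds(groups, k = inner_k, seed = seed)
  sse <- setNames(numeric(length(ladder)), ladder)
  for (f in seq_len(inner_k)) {
    tr <- plan$assignments != f
    te <- !tr
    for (j in seq_along(ladder)) {
      m <- ladder[j]
      fit <- ridge_ls(scores[tr, seq_len(m), drop = FALSE], tgt[tr], lambda)
      pred <- cbind(1, scores[te, seq_len(m), drop = FALSE]) %*% fit
      sse[j] <- sse[j] + sum((tgt[te] - pred)^2)
    }
  }
  list(m = ladder[which.min(sse)], errors = sse)
}

ridge_ls <- function(S, tgt, lambda = 1e-6) {
  Z <- cbind(1, S)
  G <- crossprod(Z) + diag(lambda, ncol(Z))
  solve(G, crossprod(Z, tgt))
}

# ---- cross-validated drivers ---------------------------------------------

#' Narrative-grouped 10-fold cross-validated emotion categorization
#'
#' For each outer fold: the SVD compressor is fitted on the 90% training
#' rows only, the number of leading dimensions is chosen by inner grouped
#' cross-validation over the dimension ladder, a multinomial logistic model
#' is fitted on the compressed training features, and the held-out 10% is
#' predicted. Every record is predicted exactly once, by a model that never
#' saw its narrative.
#'
#' @param features A `qcla_features` object (see [build_feature_matrix()]).
#' @param k Number of outer folds, default 10.
#' @param seed Master seed: outer folds, inner folds and everything below
#'   derive from it.
#' @param inner_k Inner folds for dimension selection, default 5.
#' @param lambda Ridge weight for the multinomial fits.
#' @param ladder Dimension ladder; defaults to
#'   `dimension_ladder(ncol(features$X))`.
#' @param center Center columns in the SVD step? Default `FALSE`.
#' @param maxit Maximum optimizer iterations per fit.
#' @return A `qcla_cv` object: `predicted` and `truth` (factors),
#'   `percent_correct`, `selected_dims` (per fold), `coefficients` (per-fold
#'   (m+1) x 4 matrices on the compressed, standardized scale), `fold_plan`,
#'   `feature_set`, `seed`.
#' @export
cross_validated_categorize <- function(features, k = 10L, seed = 1L,
                                       inner_k = 5L, lambda = 1e-6,
                                       ladder = NULL, center = FALSE,
                                       maxit = 150L) {
  stopifnot(inherits(features, "qcla_features"))
  X <- features$X
  y <- features$label
  narr <- features$narrative_id
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop("need at least two classes present")
  }
  ladder <- ladder %||% dimension_ladder(ncol(X))
  plan <- make_group_folds(narr, k = k, seed = child_seed(seed, 11L))
  pred <- factor(rep(NA_character_, nrow(X)), levels = levels(y))
  dims <- integer(k)
  coefs <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- plan$assignments != f
    te <- !tr
    missing_class <- setdiff(unique(as.character(y)), as.character(y[tr]))
    if (length(missing_class)) {
      stop(sprintf("fold %d: class '%s' absent from the training split",
                   f, missing_class[1]))
    }
    comp <- fit_svd(X[tr, , drop = FALSE], center = center)
    lad <- ladder[ladder <= comp$rank]
    if (!length(lad)) stop(sprintf("fold %d: ladder empty after truncation", f))
    mmax <- max(lad)
    Str <- predict(comp, X[tr, , drop = FALSE], m = mmax)
    Ste <- predict(comp, X[te, , drop = FALSE], m = mmax)
    sel <- select_dimensions(Str, y[tr], lad, groups = narr[tr],
                             inner_k = inner_k,
                             seed = child_seed(seed, 100L + f),
                             lambda = lambda, maxit = maxit)
    m <- sel$m
    fit <- fit_multinomial(Str[, seq_len(m), drop = FALSE], y[tr],
                           lambda = lambda, maxit = maxit)
    pred[te] <- predict(fit, Ste[, seq_len(m), drop = FALSE])
    dims[f] <- m
    coefs[[f]] <- fit$coefficients
  }
  stopifnot(!anyNA(pred))
  structure(
    list(predicted = pred, truth = y,
         percent_correct = 100 * mean(pred == y),
         selected_dims = dims, coefficients = coefs,
         fold_plan = plan, feature_set = features$feature_set,
         seed = seed),
    class = "qcla_cv"
  )
}

#' @export
print.qcla_cv <- function(x, ...) {
  cat(sprintf("<qcla_cv '%s': %d records, %d folds, %.1f%% correct>\n",
              x$feature_set, length(x$predicted), x$fold_plan$k,
              x$percent_correct))
  cat("selected dimensions per fold:",
      paste(x$selected_dims, collapse = " "), "\n")
  invisible(x)
}

#' Cross-validated regression of continuous rating-scale scores
#'
#' Predicts each of the four rating-scale totals from the feature matrix
#' with multiple linear regression, using the same protocol as
#' [cross_validated_categorize()]: per-fold SVD compression and an inner
#' grouped cross-validation over the dimension ladder with squared error as
#' the selection criterion. Every record receives one out-of-fold
#' prediction per scale.
#'
#' @param features A `qcla_features` object.
#' @param targets Numeric matrix of targets (records x scales), e.g., the
#'   four totals.
#' @param k,seed,inner_k,lambda,ladder,center As in
#'   [cross_validated_categorize()].
#' @return List with `predicted` (records x scales matrix of out-of-fold
#'   predictions), `selected_dims` (folds x scales), `fold_plan`.
#' @export
regress_scale_scores <- function(features, targets, k = 10L, seed = 1L,
                                 inner_k = 5L, lambda = 1e-6,
                                 ladder = NULL, center = FALSE) {
  stopifnot(inherits(features, "qcla_features"))
  targets <- as.matrix(targets)
  X <- features$X
  narr <- features$narrative_id
  stopifnot(nrow(targets) == nrow(X))
  ladder <- ladder %||% dimension_ladder(ncol(X))
  for (j in seq_len(ncol(targets))) {
    if (sd(targets[, j]) == 0) {
      warning("target column ", j, " is constant; downstream correlations ",
              "are undefined")
    }
  }
  plan <- make_group_folds(narr, k = k, seed = child_seed(seed, 11L))
  pred <- matrix(NA_real_, nrow(X), ncol(targets),
                 dimnames = list(rownames(X), colnames(targets)))
  dims <- matrix(NA_integer_, k, ncol(targets))
  for (f in seq_len(k)) {
    tr <- plan$assignments != f
    te <- !tr
    comp <- fit_svd(X[tr, , drop = FALSE], center = center)
    lad <- ladder[ladder <= comp$rank]
    if (!length(lad)) stop(sprintf("fold %d: ladder empty after truncation", f))
    mmax <- max(lad)
    Str <- predict(comp, X[tr, , drop = FALSE], m = mmax)
    Ste <- predict(comp, X[te, , drop = FALSE], m = mmax)
    for (j in seq_len(ncol(targets))) {
      sel <- select_dimensions_lm(Str, targets[tr, j], lad,
                                  groups = narr[tr], inner_k = inner_k,
                                  seed = child_seed(seed, 1000L + 10L * f + j),
                                  lambda = lambda)
      m <- sel$m
      fit <- ridge_ls(Str[, seq_len(m), drop = FALSE], targets[tr, j], lambda)
      pred[te, j] <- cbind(1, Ste[, seq_len(m), drop = FALSE]) %*% fit
      dims[f, j] <- m
    }
  }
  list(predicted = pred, selected_dims = dims, fold_plan = plan, seed = seed)
}
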