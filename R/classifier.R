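#' Model specification for the activity classifier
#'
#' Bundles the hyperparameters of the repeated-split, cross-validated
#' L2-regularized logistic regression used to predict bicistronic reporter
#' activity from TL features: a 10-point log-spaced regularization grid over
#' `[1e-4, 1e4]`, 10-fold CV for strength selection, 100 random 80/20
#' train/test splits, min-max feature scaling and column-mean imputation.
#'
#' @param l2_grid Strictly positive penalty strengths (the coefficient of
#'   `||beta||^2 / 2` in the penalized log-likelihood).
#' @param cv_folds Folds for strength selection.
#' @param n_repeats Number of random train/test splits.
#' @param test_fraction Held-out fraction per split.
#' @param seed Integer seed; every random choice derives from it.
#' @param fit_intercept Include an (unpenalized) intercept.
#' @param leak_safe Refit imputation and scaling inside each training split
#'   instead of once on the full table (default FALSE, matching the usual
#'   scale-then-classify order).
#' @param stratified_split Stratify the 80/20 splits by label (default
#'   FALSE: simple random splits).
#' @return A list of class `tl_model_spec`.
#' @export
model_spec <- function(l2_grid = 10^seq(-4, 4, length.out = 10),
                       cv_folds = 10, n_repeats = 100, test_fraction = 0.2,
                       seed = 1L, fit_intercept = TRUE, leak_safe = FALSE,
                       stratified_split = FALSE) {
  stopifnot(all(l2_grid > 0), test_fraction > 0, test_fraction < 1,
            cv_folds >= 2, n_repeats >= 1)
  structure(list(l2_grid = sort(l2_grid), cv_folds = cv_folds,
                 n_repeats = n_repeats, test_fraction = test_fraction,
                 seed = as.integer(seed), fit_intercept = fit_intercept,
                 leak_safe = leak_safe, stratified_split = stratified_split),
            class = "tl_model_spec")
}

#' Min-max scale a numeric column
#'
#' `(x - min) / (max - min)` over non-missing values; a constant column maps
#' to all zeros. Missing cells stay missing.
#'
#' @param column Numeric vector with at least one non-missing value.
#' @return Scaled vector with non-missing range `[0, 1]`.
#' @export
minmax_scale <- function(column) {
  v <- column[!is.na(column)]
  if (length(v) == 0) abort("minmax_scale: all-missing column")
  rng <- range(v)
  if (rng[1] == rng[2]) return(ifelse(is.na(column), NA_real_, 0))
  (column - rng[1]) / (rng[2] - rng[1])
}

#' Mean-impute missing cells of a column
#'
#' @param column Numeric vector with at least one non-missing value.
#' @return Column with `NA` replaced by the mean of the observed values.
#' @export
impute_mean <- function(column) {
  v <- column[!is.na(column)]
  if (length(v) == 0) abort("impute_mean: all-missing column")
  column[is.na(column)] <- mean(v)
  column
}

# Feature matrix + response from a labeled feature table.
prepare_xy <- function(table) {
  x <- table |> filter(.data$label %in% c("active", "nonactive"))
  if (length(unique(x$label)) < 2) abort("classifier: need both labels")
  drop <- c("tl_id", "label", "hyperconserved")
  feats <- setdiff(names(x), drop)
  keep <- vapply(feats, function(f) is.numeric(x[[f]]) || is.logical(x[[f]]),
                 logical(1))
  feats <- feats[keep]
  feats <- feats[vapply(feats, function(f) any(!is.na(x[[f]])), logical(1))]
  X <- vapply(feats, function(f) as.numeric(x[[f]]), numeric(nrow(x)))
  X <- matrix(X, nrow = nrow(x), dimnames = list(NULL, feats))
  list(X = X, y = as.integer(x$label == "active"))
}

process_columns <- function(X) {
  apply(X, 2, function(col) minmax_scale(impute_mean(col)))
}

log1pexp <- function(eta) ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))

#' Fit an L2-penalized logistic regression by Newton/IRLS
#'
#' Maximizes `sum(loglik) - strength/2 * ||beta||^2` (intercept unpenalized)
#' with Newton steps and step-halving; the objective is strictly convex for
#' `strength > 0`, so the optimum is unique and the fit deterministic.
#' Convergence requires the gradient norm to drop to `tol`; otherwise an
#' error reports the final gradient norm.
#'
#' @param X Numeric feature matrix (no missing values).
#' @param y Binary 0/1 response.
#' @param strength Positive L2 penalty strength.
#' @param tol Gradient-norm convergence threshold.
#' @param max_iter Maximum Newton iterations.
#' @param fit_intercept Include an unpenalized intercept.
#' @param beta_init Optional start (length `ncol(X) + fit_intercept`);
#'   defaults to zero. The optimum does not depend on it.
#' @return List: `coefficients` (named), `intercept`, `loss`, `n_iter`,
#'   `grad_norm`.
#' @export
fit_logistic_l2 <- function(X, y, strength, tol = 1e-8, max_iter = 200,
                            fit_intercept = TRUE, beta_init = NULL) {
  stopifnot(is.matrix(X), !anyNA(X), all(y %in% c(0, 1)), strength >= 0)
  Xa <- if (fit_intercept) cbind(`(Intercept)` = 1, X) else X
  p_all <- ncol(Xa)
  pen <- rep(strength, p_all)
  if (fit_intercept) pen[1] <- 0
  beta <- if (is.null(beta_init)) rep(0, p_all) else as.numeric(beta_init)
  stopifnot(length(beta) == p_all)
  obj <- function(b) {
    eta <- drop(Xa %*% b)
    sum(log1pexp(eta) - y * eta) + sum(pen * b^2) / 2
  }
  f <- obj(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% beta)
    p <- plogis(eta)
    grad <- drop(crossprod(Xa, p - y)) + pen * beta
    gnorm <- sqrt(sum(grad^2))
    if (gnorm <= tol) {
      names(beta) <- colnames(Xa)
      return(list(
        coefficients = if (fit_intercept) beta[-1] else beta,
        intercept = if (fit_intercept) unname(beta[1]) else 0,
        loss = f, n_iter = it - 1L, grad_norm = gnorm
      ))
    }
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Xa, Xa * w) + diag(pen, p_all)
    step <- tryCatch(solve(H, grad),
                     error = function(e) solve(H + diag(1e-8, p_all), grad))
    t_step <- 1
    repeat {
      cand <- beta - t_step * step
      f_cand <- obj(cand)
      if (f_cand <= f + 1e-12 || t_step < 1e-10) break
      t_step <- t_step / 2
    }
    beta <- cand
    f <- f_cand
  }
  abort(sprintf("fit_logistic_l2: no convergence after %d iterations (gradient norm %.3g)",
                max_iter, gnorm))
}

make_stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Select the penalty strength by stratified 10-fold CV
#'
#' Fits every grid strength on each training fold and picks the strength
#' with the highest mean held-out accuracy; ties break toward the larger
#' penalty (more regularization for equal fit). Folds are stratified by
#' label; if a fold assignment leaves a training fold with one class, it is
#' redrawn (up to 10 attempts).
#'
#' @param X,y Processed feature matrix and 0/1 response.
#' @param spec A [model_spec()].
#' @param seed Optional integer; when given, fold shuffling derives from it.
#' @return The selected strength (scalar).
#' @export
select_strength_cv <- function(X, y, spec = model_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- spec$cv_folds
  if (length(y) < k) abort("select_strength_cv: fewer observations than folds")
  for (attempt in 1:10) {
    fold <- make_stratified_folds(y, k)
    ok <- all(vapply(seq_len(k), function(f) length(unique(y[fold != f])) == 2,
                     logical(1)))
    if (ok) break
    if (attempt == 10) abort("select_strength_cv: could not build folds with both classes")
  }
  acc <- matrix(NA_real_, nrow = length(spec$l2_grid), ncol = k)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (!any(!tr)) next
    for (g in seq_along(spec$l2_grid)) {
      fit <- fit_logistic_l2(X[tr, , drop = FALSE], y[tr], spec$l2_grid[g],
                             fit_intercept = spec$fit_intercept)
      eta <- drop(X[!tr, , drop = FALSE] %*% fit$coefficients) + fit$intercept
      acc[g, f] <- mean((eta > 0) == (y[!tr] == 1))
    }
  }
  mean_acc <- rowMeans(acc, na.rm = TRUE)
  best <- which(mean_acc >= max(mean_acc) - 1e-12)
  spec$l2_grid[max(best)]
}

#' Repeated 80/20 evaluation of the activity classifier
#'
#' The full modeling procedure: per repeat, a random 80/20 train/test split;
#' mean imputation and min-max scaling (on the full table by default, inside
#' the training split when `spec$leak_safe`); CV strength selection on the
#' training set; an L2 logistic fit; and held-out accuracy. Coefficients and
#' the selected strength are recorded per repeat. Fully reproducible from
#' `spec$seed`.
#'
#' @param table Feature-table tibble with `label` in active/nonactive
#'   (unlabeled rows are dropped).
#' @param spec A [model_spec()].
#' @return An object of class `tl_model` with elements `repeats` (tibble:
#'   `repeat_id`, `accuracy`, `strength`), `coefficients` (repeats x
#'   features matrix), `summary` (per-feature median and sign consistency),
#'   `mean_accuracy`, `max_accuracy`, `spec`.
#' @seealso [tidy.tl_model()], [glance.tl_model()], [autoplot.tl_model()],
#'   [coefficient_significance()]
#' @export
evaluate_repeated <- function(table, spec = model_spec()) {
  xy <- prepare_xy(table)
  n <- length(xy$y)
  n_test <- max(1L, round(n * spec$test_fraction))
  if (n - n_test < spec$cv_folds) abort("evaluate_repeated: too few rows for CV folds")
  X_full <- if (spec$leak_safe) xy$X else process_columns(xy$X)
  set.seed(spec$seed)
  p <- ncol(xy$X)
  coefs <- matrix(NA_real_, nrow = spec$n_repeats, ncol = p,
                  dimnames = list(NULL, colnames(xy$X)))
  accuracy <- strength <- numeric(spec$n_repeats)
  for (r in seq_len(spec$n_repeats)) {
    repeat {
      test_idx <- if (spec$stratified_split) {
        unlist(lapply(split(seq_len(n), xy$y),
                      function(ix) sample(ix, max(1L, round(length(ix) * spec$test_fraction)))))
      } else {
        sample(n, n_test)
      }
      if (length(unique(xy$y[-test_idx])) == 2) break
    }
    if (spec$leak_safe) {
      tr_raw <- xy$X[-test_idx, , drop = FALSE]
      means <- colMeans(tr_raw, na.rm = TRUE)
      mins <- apply(tr_raw, 2, min, na.rm = TRUE)
      maxs <- apply(tr_raw, 2, max, na.rm = TRUE)
      transform <- function(M) {
        for (j in seq_len(ncol(M))) {
          col <- M[, j]
          col[is.na(col)] <- means[j]
          rng <- maxs[j] - mins[j]
          M[, j] <- if (rng > 0) (col - mins[j]) / rng else 0
        }
        M
      }
      Xtr <- transform(xy$X[-test_idx, , drop = FALSE])
      Xte <- transform(xy$X[test_idx, , drop = FALSE])
    } else {
      Xtr <- X_full[-test_idx, , drop = FALSE]
      Xte <- X_full[test_idx, , drop = FALSE]
    }
    ytr <- xy$y[-test_idx]; yte <- xy$y[test_idx]
    strength[r] <- select_strength_cv(Xtr, ytr, spec,
                                      seed = sample.int(.Machine$integer.max, 1))
    fit <- fit_logistic_l2(Xtr, ytr, strength[r], fit_intercept = spec$fit_intercept)
    coefs[r, ] <- fit$coefficients
    eta <- drop(Xte %*% fit$coefficients) + fit$intercept
    accuracy[r] <- mean((eta > 0) == (yte == 1))
  }
  summary <- tibble(
    term = colnames(coefs),
    estimate = apply(coefs, 2, median),
    sign_consistency = apply(coefs, 2, function(b) max(mean(b > 0), mean(b < 0)))
  )
  structure(list(
    repeats = tibble(repeat_id = seq_len(spec$n_repeats),
                     accuracy = accuracy, strength = strength),
    coefficients = coefs,
    summary = summary,
    mean_accuracy = mean(accuracy),
    max_accuracy = max(accuracy),
    n_obs = n,
    spec = spec
  ), class = "tl_model")
}

#' @export
print.tl_model <- function(x, ...) {
  cat(sprintf("TL activity classifier: %d repeats on %d TLs\n",
              nrow(x$repeats), x$n_obs))
  cat(sprintf("  mean accuracy %.3f, max accuracy %.3f\n",
              x$mean_accuracy, x$max_accuracy))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Permutation significance of classifier coefficients
#'
#' Builds a null distribution for each coefficient by refitting the
#' (imputed, scaled) model on label-permuted data; scaling precedes the
#' permutation only through the feature matrix, so the p-values are
#' invariant to feature rescaling. The penalty strength is selected once by
#' CV on the observed labels and held fixed across permutations. Two-sided
#' `p = (1 + #{|null| >= |observed|}) / (1 + n_perm)`.
#'
#' @param table Feature-table tibble.
#' @param spec A [model_spec()].
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @return Tibble: `term`, `estimate` (observed coefficient), `p_value`.
#' @export
coefficient_significance <- function(table, spec = model_spec(), n_perm = 1000,
                                     seed = 1L) {
  xy <- prepare_xy(table)
  X <- process_columns(xy$X)
  set.seed(seed)
  strength <- select_strength_cv(X, xy$y, spec,
                                 seed = sample.int(.Machine$integer.max, 1))
  obs <- fit_logistic_l2(X, xy$y, strength,
                         fit_intercept = spec$fit_intercept)$coefficients
  null <- matrix(NA_real_, nrow = n_perm, ncol = length(obs))
  for (b in seq_len(n_perm)) {
    yp <- sample(xy$y)
    null[b, ] <- fit_logistic_l2(X, yp, strength,
                                 fit_intercept = spec$fit_intercept)$coefficients
  }
  p <- vapply(seq_along(obs), function(j) {
    (1 + sum(abs(null[, j]) >= abs(obs[j]))) / (1 + n_perm)
  }, numeric(1))
  tibble(term = names(obs), estimate = unname(obs), p_value = p,
         n_perm = n_perm)
}

#' Tidy the per-feature coefficient summary of a fitted classifier
#'
#' @param x A `tl_model` from [evaluate_repeated()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (median coefficient across
#'   repeats) and `sign_consistency` (fraction of repeats agreeing with the
#'   majority sign).
#' @export
tidy.tl_model <- function(x, ...) x$summary

#' One-row model summary
#'
#' @param x A `tl_model`.
#' @param ... Unused.
#' @return Tibble with mean/max/sd of held-out accuracy, repeat count and
#'   cohort size.
#' @export
glance.tl_model <- function(x, ...) {
  tibble(mean_accuracy = x$mean_accuracy,
         max_accuracy = x$max_accuracy,
         sd_accuracy = sd(x$repeats$accuracy),
         n_repeats = nrow(x$repeats),
         n_obs = x$n_obs)
}
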