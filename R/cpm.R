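#' CPM feature selection by phenotype correlation
#'
#' Correlates every feature (column) with the phenotype across subjects
#' (Pearson, two-sided p from the t distribution) and retains features
#' with p below the threshold, split by correlation sign. Zero-variance
#' features are excluded and counted.
#'
#' @param features subjects x P numeric matrix.
#' @param phenotype numeric vector, one value per subject.
#' @param p_threshold selection threshold (default 0.01).
#' @return list with logical masks `positive` and `negative` (disjoint),
#'   `r` and `p` per feature, and `n_excluded` (zero-variance count).
#' @export
cpm_select_features <- function(features, phenotype, p_threshold = 0.01) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(phenotype) == n, n >= 10)
  if (anyNA(features) || anyNA(phenotype)) stop("missing values not allowed")
  sds <- apply(features, 2, stats::sd)
  ok <- sds > 0 & stats::sd(phenotype) > 0
  r <- rep(NA_real_, ncol(features))
  r[ok] <- suppressWarnings(
    as.vector(stats::cor(features[, ok, drop = FALSE], phenotype)))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  sel <- !is.na(p) & p < p_threshold
  list(positive = sel & r > 0,
       negative = sel & r < 0,
       r = r, p = p,
       n_excluded = sum(!ok))
}

#' Summarize selected features into one score per subject
#'
#' The default "difference" score is the sum over positive-mask features
#' minus the sum over negative-mask features; "positive" and "negative"
#' use one mask only.
#'
#' @param features subjects x P numeric matrix.
#' @param masks list with `positive` and `negative` logical masks (from
#'   [cpm_select_features()]).
#' @param mode `"difference"` (default), `"positive"`, or `"negative"`.
#' @return numeric vector, one score per subject.
#' @export
cpm_summarize <- function(features, masks,
                          mode = c("difference", "positive", "negative")) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  pos <- masks$positive
  neg <- masks$negative
  used <- switch(mode, difference = sum(pos) + sum(neg),
                 positive = sum(pos), negative = sum(neg))
  if (used == 0) stop("no features selected")
  pos_sum <- rowSums(features[, pos, drop = FALSE])
  neg_sum <- rowSums(features[, neg, drop = FALSE])
  switch(mode,
         difference = pos_sum - neg_sum,
         positive = pos_sum,
         negative = neg_sum)
}

#' Deterministic fold assignments for repeated k-fold cross-validation
#'
#' Fold splits are a pure function of (seed, repeat index): a per-repeat
#' seed stream is derived once from the master seed, so the same splits
#' can be replayed for different feature sets and the per-repeat
#' performances compared pairwise.
#'
#' @param n_subjects number of subjects.
#' @param k folds (default 10).
#' @param n_repeats repeats.
#' @param seed master integer seed.
#' @return integer matrix (n_repeats x n_subjects) of fold labels 1..k.
#' @export
cpm_folds <- function(n_subjects, k = 10, n_repeats = 1, seed = 1) {
  stopifnot(n_subjects >= k, k >= 2)
  set.seed(seed)
  repeat_seeds <- sample.int(.Machine$integer.max - 1L, n_repeats)
  folds <- matrix(0L, n_repeats, n_subjects)
  base <- rep_len(seq_len(k), n_subjects)
  for (r in seq_len(n_repeats)) {
    set.seed(repeat_seeds[r])
    folds[r, ] <- sample(base)
  }
  folds
}

#' Repeated k-fold cross-validated CPM
#'
#' For every repeat and fold: select features on the training subjects
#' only, summarize them into a scalar score, fit a linear regression of
#' the phenotype on the score, and predict the held-out fold. Each
#' subject is predicted exactly once per repeat; performance is the
#' Pearson correlation between predicted and observed phenotype over all
#' subjects. Folds where no feature passes selection fall back to the
#' training-set mean prediction (counted in `n_fallback_folds`).
#'
#' @param features subjects x P numeric matrix (e.g., aligned eAC/eMC
#'   vectors).
#' @param phenotype numeric vector per subject.
#' @param k folds (default 10).
#' @param n_repeats repeats of the full cross-validation (default 1000).
#' @param seed master seed for the fold stream.
#' @param p_threshold feature-selection threshold (default 0.01).
#' @param mode summary-score mode, see [cpm_summarize()].
#' @return object of class `cpm_result`: list with `predictions`
#'   (n_repeats x subjects), `performance` (Pearson r per repeat),
#'   `folds` (the fold matrix), `n_repeats`, `k`, `seed`, `p_threshold`,
#'   `mode`, `n_fallback_folds`.
#' @export
cpm_cross_validate <- function(features, phenotype, k = 10, n_repeats = 1000,
                               seed = 1, p_threshold = 0.01,
                               mode = "difference") {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(phenotype) == n, n >= k)
  folds <- cpm_folds(n, k, n_repeats, seed)
  predictions <- matrix(NA_real_, n_repeats, n)
  performance <- numeric(n_repeats)
  n_fallback <- 0L
  for (r in seq_len(n_repeats)) {
    fold_of <- folds[r, ]
    pred <- numeric(n)
    for (f in seq_len(k)) {
      test <- fold_of == f
      train <- !test
      masks <- cpm_select_features(features[train, , drop = FALSE],
                                   phenotype[train], p_threshold)
      score_test <- tryCatch({
        score_train <- cpm_summarize(features[train, , drop = FALSE],
                                     masks, mode)
        fit <- stats::lm.fit(cbind(1, score_train), phenotype[train])
        cbind(1, cpm_summarize(features[test, , drop = FALSE],
                               masks, mode)) %*% fit$coefficients
      }, error = function(e) NULL)
      if (is.null(score_test)) {
        n_fallback <- n_fallback + 1L
        pred[test] <- mean(phenotype[train])
      } else {
        pred[test] <- score_test
      }
    }
    predictions[r, ] <- pred
    performance[r] <- if (stats::sd(pred) > 0)
      stats::cor(pred, phenotype) else 0
  }
  if (n_fallback > 0) {
    message(n_fallback, " fold(s) had no selected features; ",
            "training-mean predictions used")
  }
  structure(list(predictions = predictions, performance = performance,
                 folds = folds, n_repeats = n_repeats, k = k, seed = seed,
                 p_threshold = p_threshold, mode = mode,
                 n_fallback_folds = n_fallback),
            class = "cpm_result")
}

#' @exportS3Method base::print
print.cpm_result <- function(x, ...) {
  cat(sprintf("cpm_result: %d repeats of %d-fold CV over %d subjects\n",
              x$n_repeats, x$k, ncol(x$predictions)))
  cat(sprintf("  performance r: median %.3f [%.3f, %.3f]\n",
              stats::median(x$performance),
              stats::quantile(x$performance, 0.025),
              stats::quantile(x$performance, 0.975)))
  invisible(x)
}

#' Paired comparison of two CPM feature sets
#'
#' Both results must come from the same phenotype and identical fold
#' splits (same seed/k/n_repeats) so the per-repeat performances are
#' paired. Returns the one-sided p-value for "a predicts better than b":
#' the proportion of repeats where r_a <= r_b.
#'
#' @param result_a,result_b [cpm_cross_validate()] results sharing folds.
#' @return a single p-value in [0, 1].
#' @export
cpm_compare <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "cpm_result"), inherits(result_b, "cpm_result"))
  if (!identical(dim(result_a$folds), dim(result_b$folds)) ||
      !identical(result_a$folds, result_b$folds)) {
    stop("fold splits differ between the two results; rerun both with ",
         "the same seed, k, and n_repeats")
  }
  mean(result_a$performance <= result_b$performance)
}
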