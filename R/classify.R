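#' Describe a classifier
#'
#' @param family `"svm"`, `"knn"` or `"random_forest"`.
#' @param kernel SVM kernel: `"linear"`, `"polynomial"` or `"rbf"` (the
#'   radial basis / Gaussian kernel, the default).
#' @param cost SVM soft-margin cost C.
#' @param gamma RBF / polynomial kernel width; `NULL` = `1 / n_features`.
#' @param degree Polynomial kernel degree.
#' @param k_neighbors kNN neighborhood size (default 1).
#' @param n_trees Random-forest ensemble size (default 500).
#' @param seed Integer seed used when fitting (random forest bootstrap, kNN
#'   tie-breaks); makes training deterministic.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm", "knn", "random_forest"),
                            kernel = c("rbf", "linear", "polynomial"),
                            cost = 1, gamma = NULL, degree = 3,
                            k_neighbors = 1, n_trees = 500, seed = 1) {
  family <- match.arg(family)
  kernel <- match.arg(kernel)
  structure(list(family = family, kernel = kernel, cost = cost,
                 gamma = gamma, degree = degree,
                 k_neighbors = as.integer(k_neighbors),
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train a classifier on a normalized feature matrix
#'
#' SVMs are fitted through LIBSVM (via e1071) with `scale = FALSE` — feature
#' scaling is the normalizer's job and must be fitted on training data only.
#' The fitted object exposes decision scores for ROC analysis: SVM decision
#' values (oriented so that larger = more positive), kNN positive-vote
#' fraction, or random-forest positive-class probability.
#'
#' @param spec A [classifier_spec()].
#' @param x Numeric training matrix (samples x features), already normalized.
#' @param labels `"positive"` / `"negative"` per row.
#' @return An object of class `glutapred_fit`.
#' @export
train_classifier <- function(spec, x, labels) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as_feature_values(x)
  y <- factor(normalize_labels(labels), levels = c("negative", "positive"))
  if (length(unique(y)) < 2L) stop("training data has a single class",
                                   call. = FALSE)
  fit <- switch(spec$family,
    svm = {
      kern <- c(rbf = "radial", linear = "linear",
                polynomial = "polynomial")[[spec$kernel]]
      gamma <- if (is.null(spec$gamma)) 1 / ncol(x) else spec$gamma
      with_seed(spec$seed,
        e1071::svm(x = x, y = y, kernel = kern, cost = spec$cost,
                   gamma = gamma, degree = spec$degree, scale = FALSE))
    },
    knn = list(train = x, cl = y, k = spec$k_neighbors),
    random_forest = with_seed(spec$seed,
      randomForest::randomForest(x = x, y = y, ntree = spec$n_trees)))
  structure(list(spec = spec, fit = fit, feature_names = colnames(x)),
            class = "glutapred_fit")
}

#' Predict classes and decision scores for new samples
#'
#' @param object A [train_classifier()] fit.
#' @param newdata Matrix with the same feature columns as the training data.
#' @param ... Unused.
#' @return Data frame with columns `predicted` (class label) and `score`
#'   (larger = more positive).
#' @export
predict.glutapred_fit <- function(object, newdata, ...) {
  x <- as_feature_values(newdata)
  if (!identical(colnames(x), object$feature_names)) {
    stop("feature columns do not match the fitted model", call. = FALSE)
  }
  spec <- object$spec
  if (spec$family == "svm") {
    pr <- predict(object$fit, x, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # LIBSVM labels the decision column "first/second"; positive values vote
    # for the first-named class. Orient so larger = more "positive".
    first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    score <- if (first == "positive") dv[, 1] else -dv[, 1]
    pred <- as.character(pr)
  } else if (spec$family == "knn") {
    pr <- with_seed(spec$seed,
      class::knn(train = object$fit$train, test = x, cl = object$fit$cl,
                 k = object$fit$k, prob = TRUE))
    win <- attr(pr, "prob")  # fraction of votes for the winning class
    pred <- as.character(pr)
    score <- ifelse(pred == "positive", win, 1 - win)
  } else {
    prob <- predict(object$fit, x, type = "prob")[, "positive"]
    pred <- ifelse(prob >= 0.5, "positive", "negative")
    score <- prob
  }
  data.frame(predicted = unname(pred), score = unname(score),
             stringsAsFactors = FALSE)
}

#' Stratified fold assignment
#'
#' @param labels Class labels.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..folds`; per-fold class
#'   proportions are within one sample of the global proportions.
#' @export
stratified_folds <- function(labels, folds = 5, seed = 1) {
  y <- normalize_labels(labels)
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  assign <- integer(length(y))
  with_seed(seed, {
    cursor <- 0L
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      # continue dealing from where the previous class stopped, so overall
      # fold sizes also stay within one sample of each other
      assign[idx] <- (cursor + seq_along(idx) - 1L) %% folds + 1L
      cursor <- (cursor + length(idx)) %% folds
    }
  })
  assign
}

#' Leakage-safe stratified cross-validation of the full pipeline
#'
#' For each fold, the bi-profile matrix (when the scheme needs one), the
#' min-max normalizer, the t-test feature ranking and the classifier are all
#' fitted on the training part only; the held-out part is encoded and scored
#' with those frozen objects. Pooled metrics are computed from the
#' concatenated out-of-fold predictions; per-fold metrics are also returned.
#'
#' @param windows Window data frame from [extract_windows()] (or
#'   [generate_dataset()] + extraction); both classes must be present.
#' @param scheme Encoding scheme name (see [encode_windows()]).
#' @param spec A [classifier_spec()].
#' @param n_features Number of top-ranked features kept (capped at the
#'   scheme dimensionality); default from [default_selected_k()].
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for the fold split.
#' @param pseudocount Bi-profile smoothing (biprofile_bayes scheme only).
#' @param properties Property table (physchem scheme only).
#' @param tune Logical; if `TRUE`, SVM cost/gamma are chosen per fold by an
#'   inner stratified cross-validation over `tune_grid` before the outer
#'   model is fitted (nested CV, so tuning never sees held-out data).
#' @param tune_grid Data frame of candidate `cost` / `gamma` values; default
#'   a coarse LIBSVM-style log2 grid.
#' @return An object of class `cv_result`: list with `pooled`
#'   (a `metrics_report` incl. AUC/ROC), `per_fold` (list of
#'   `metrics_report`), `fold_assign`, `predictions` (per-sample out-of-fold
#'   label, prediction, score, fold), and the call configuration.
#' @export
crossvalidate <- function(windows, scheme, spec = classifier_spec(),
                          n_features = NULL, folds = 5, seed = 1,
                          pseudocount = 0, properties = NULL,
                          tune = FALSE, tune_grid = NULL) {
  y <- normalize_labels(windows$label)
  if (length(unique(y)) < 2L) stop("dataset has a single class",
                                   call. = FALSE)
  fold_assign <- stratified_folds(y, folds = folds, seed = seed)
  for (f in seq_len(folds)) {
    if (length(unique(y[fold_assign != f])) < 2L) {
      stop("fold ", f, " leaves a single-class training set; ",
           "use fewer folds or a different seed", call. = FALSE)
    }
  }
  if (is.null(n_features)) n_features <- default_selected_k()[[scheme]]
  pred <- data.frame(label = y, predicted = NA_character_,
                     score = NA_real_, fold = fold_assign,
                     stringsAsFactors = FALSE)
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- windows[fold_assign != f, , drop = FALSE]
    te <- windows[fold_assign == f, , drop = FALSE]
    profile <- NULL
    if (scheme == "biprofile_bayes") {
      profile <- fit_biprofile(tr$peptide, tr$label,
                               pseudocount = pseudocount)
    }
    xtr <- encode_windows(tr, scheme, profile = profile,
                          properties = properties)
    xte <- encode_windows(te, scheme, profile = profile,
                          properties = properties)
    norm <- fit_normalizer(xtr)
    xtr_n <- apply_normalizer(norm, xtr)
    xte_n <- apply_normalizer(norm, xte)
    ranking <- rank_features(xtr_n, tr$label)
    keep <- select_top_k(ranking, min(n_features, nrow(ranking)))
    xtr_k <- xtr_n[, keep, drop = FALSE]
    xte_k <- xte_n[, keep, drop = FALSE]
    fold_spec <- spec
    if (tune && spec$family == "svm") {
      fold_spec <- tune_svm(spec, xtr_k, tr$label, grid = tune_grid,
                            seed = seed + f)
    }
    fit <- train_classifier(fold_spec, xtr_k, tr$label)
    out <- predict(fit, xte_k)
    pred$predicted[fold_assign == f] <- out$predicted
    pred$score[fold_assign == f] <- out$score
    per_fold[[f]] <- evaluate_predictions(te$label, out$predicted, out$score)
  }
  pooled <- evaluate_predictions(pred$label, pred$predicted, pred$score)
  structure(list(pooled = pooled, per_fold = per_fold,
                 fold_assign = fold_assign, predictions = pred,
                 scheme = scheme, spec = spec, n_features = n_features,
                 folds = folds, seed = seed),
            class = "cv_result")
}

# inner stratified CV over a coarse cost/gamma grid; returns the spec with
# the best mean held-out accuracy (ties: first grid row, deterministic)
tune_svm <- function(spec, x, labels, grid = NULL, seed = 1,
                     inner_folds = 3) {
  if (is.null(grid)) {
    grid <- expand.grid(cost = 2 ^ c(-5, 0, 5, 10, 15),
                        gamma = 2 ^ c(-15, -11, -7, -3, 1))
  }
  y <- normalize_labels(labels)
  assign <- stratified_folds(y, folds = inner_folds, seed = seed)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    cand <- spec
    cand$cost <- grid$cost[g]
    if (!is.null(grid$gamma)) cand$gamma <- grid$gamma[g]
    hits <- 0L
    for (f in seq_len(inner_folds)) {
      if (length(unique(y[assign != f])) < 2L) return(0)
      fit <- train_classifier(cand, x[assign != f, , drop = FALSE],
                              y[assign != f])
      out <- predict(fit, x[assign == f, , drop = FALSE])
      hits <- hits + sum(out$predicted == y[assign == f])
    }
    hits / length(y)
  }, numeric(1))
  best <- which.max(acc)
  spec$cost <- grid$cost[best]
  if (!is.null(grid$gamma)) spec$gamma <- grid$gamma[best]
  spec
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold CV, scheme=%s, classifier=%s, seed=%d\n",
              x$folds, x$scheme, x$spec$family, x$seed))
  cat("pooled: ")
  print(x$pooled)
  invisible(x)
}

#' Summarize a cross-validation result as a data frame
#'
#' One row per fold plus a pooled row, columns AUC / Spe / Pre / Sen / F1 /
#' MCC / ACC.
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return Data frame.
#' @export
summary.cv_result <- function(object, ...) {
  row <- function(m, name) {
    data.frame(fold = name, AUC = m$auc, Spe = m$spe, Pre = m$pre,
               Sen = m$sen, F1 = m$f1, MCC = m$mcc, ACC = m$acc,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_along(object$per_fold), function(f)
    row(object$per_fold[[f]], as.character(f)))
  do.call(rbind, c(rows, list(row(object$pooled, "pooled"))))
}

#' Write a cross-validation summary (and ROC points) as TSV
#'
#' @param cv A `cv_result`.
#' @param path Output TSV path for the per-fold + pooled metric table.
#' @param roc_path Optional path for the pooled ROC points (two-column TSV).
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(cv, path, roc_path = NULL) {
  write.table(summary(cv), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(roc_path) && !is.null(cv$pooled$roc)) {
    write.table(cv$pooled$roc, roc_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Cross-validate across a range of window sizes
#'
#' Re-extracts the windows at each odd size (discarding terminal windows,
#' which makes the sample set size-dependent) and runs [crossvalidate()]
#' with the same seed at every size, so results are comparable.
#'
#' @param proteins Named character vector of sequences.
#' @param sites Validated annotation data frame.
#' @param sizes Odd window widths (default 9, 11, ..., 21).
#' @param ... Passed to [crossvalidate()] (`scheme`, `spec`, `seed`, ...).
#' @return List with `summary` (data frame: size, n_windows, pooled metrics)
#'   and `results` (named list of `cv_result`).
#' @export
sweep_window_sizes <- function(proteins, sites, sizes = seq(9, 21, by = 2),
                               ...) {
  for (s in sizes) check_window_size(s)
  results <- list()
  rows <- list()
  for (s in sizes) {
    win <- suppressWarnings(extract_windows(proteins, sites, w = s))
    cv <- crossvalidate(win, ...)
    results[[as.character(s)]] <- cv
    m <- cv$pooled
    rows[[as.character(s)]] <- data.frame(
      size = s, n_windows = nrow(win), AUC = m$auc, Spe = m$spe, Pre = m$pre,
      Sen = m$sen, F1 = m$f1, MCC = m$mcc, ACC = m$acc)
  }
  list(summary = do.call(rbind, rows), results = results)
}
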