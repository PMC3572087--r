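test_that("confusion metrics match the closed forms", {
  perfect <- confusion_metrics(tp = 75, fp = 0, tn = 158, fn = 0)
  for (m in c("sen", "spe", "pre", "f1", "mcc", "acc")) {
    expect_equal(perfect[[m]], 1)
  }

  r <- confusion_metrics(tp = 3, fp = 1, tn = 4, fn = 2)
  expect_equal(r$pre, 0.75)
  expect_equal(r$sen, 0.6)
  expect_equal(r$spe, 0.8)
  expect_equal(r$acc, 0.7)
  expect_equal(r$f1, 2 / 3, tolerance = 1e-12)
  expect_equal(r$mcc, 10 / sqrt(600), tolerance = 1e-12)

  # degenerate predictor: no positive calls -> Pre = F1 = 0 by convention
  z <- confusion_metrics(tp = 0, fp = 0, tn = 5, fn = 5)
  expect_equal(z$pre, 0)
  expect_equal(z$f1, 0)
  expect_equal(z$mcc, 0)
  expect_error(confusion_metrics(-1, 0, 0, 0), "non-negative")
})

test_that("metrics agree with independent recomputation on random confusion matrices", {
  withr_seed(41)
  for (i in 1:200) {
    cm <- sample(0:50, 4, replace = TRUE)
    tp <- cm[1]; fp <- cm[2]; tn <- cm[3]; fn <- cm[4]
    r <- confusion_metrics(tp, fp, tn, fn)
    safe <- function(num, den) if (den == 0) 0 else num / den
    expect_equal(r$sen, safe(tp, tp + fn), tolerance = 1e-12)
    expect_equal(r$spe, safe(tn, tn + fp), tolerance = 1e-12)
    expect_equal(r$pre, safe(tp, tp + fp), tolerance = 1e-12)
    expect_equal(r$acc, safe(tp + tn, sum(cm)), tolerance = 1e-12)
    pre <- safe(tp, tp + fp); sen <- safe(tp, tp + fn)
    expect_equal(r$f1, safe(2 * pre * sen, pre + sen), tolerance = 1e-12)
    den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    expect_equal(r$mcc, if (den == 0) 0 else (tp * tn - fp * fn) / den,
                 tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC equals the pairwise U-statistic oracle, ties half-credited", {
  labels <- rep(c("positive", "negative"), each = 5)
  expect_equal(roc_auc(c(rep(1, 5), rep(0, 5)), labels)$auc, 1)
  expect_equal(roc_auc(rep(0.3, 10), labels)$auc, 0.5)

  withr_seed(42)
  for (i in 1:20) {
    n <- 200
    y <- rep(c("positive", "negative"), each = n / 2)
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
    got <- roc_auc(scores, y)
    expect_equal(got$auc, auc_oracle(scores, y), tolerance = 1e-12)
    expect_true(all(diff(got$roc$fpr) >= 0))
    expect_true(all(diff(got$roc$tpr) >= 0))
  }
  expect_error(roc_auc(1:3, rep("positive", 3)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr_seed(43)
  y <- rep(c(1, 0), each = 100)
  s <- rnorm(200) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(roc_auc(s, ifelse(y == 1, "positive", "negative"))$auc, ref,
               tolerance = 1e-12)
})

test_that("classifiers separate easy data, and RBF beats linear on XOR", {
  withr_seed(44)
  x <- cbind(a = c(rnorm(30, 0), rnorm(30, 5)),
             b = c(rnorm(30, 0), rnorm(30, 5))) / 6
  y <- rep(c("negative", "positive"), each = 30)
  for (family in c("svm", "knn", "random_forest")) {
    fit <- train_classifier(classifier_spec(family, seed = 4), x, y)
    pr <- predict(fit, x)
    expect_equal(mean(pr$predicted == y), 1)
    expect_gt(roc_auc(pr$score, y)$auc, 0.99)
  }

  # XOR pattern: linear kernel cannot exceed chance-level structure
  withr_seed(45)
  n <- 50
  xx <- cbind(a = runif(4 * n), b = runif(4 * n))
  cls <- ifelse(xor(xx[, 1] > 0.5, xx[, 2] > 0.5), "positive", "negative")
  rbf <- train_classifier(classifier_spec("svm", "rbf", cost = 100,
                                          gamma = 10, seed = 1), xx, cls)
  lin <- train_classifier(classifier_spec("svm", "linear", cost = 100,
                                          seed = 1), xx, cls)
  acc_rbf <- mean(predict(rbf, xx)$predicted == cls)
  acc_lin <- mean(predict(lin, xx)$predicted == cls)
  expect_gte(acc_rbf, 0.95)
  expect_lte(acc_lin, 0.75)
})

test_that("training and prediction are deterministic for a fixed seed", {
  withr_seed(46)
  x <- matrix(runif(80 * 10), 80, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- rep(c("positive", "negative"), 40)
  for (family in c("svm", "knn", "random_forest")) {
    f1 <- train_classifier(classifier_spec(family, seed = 7), x, y)
    f2 <- train_classifier(classifier_spec(family, seed = 7), x, y)
    expect_identical(predict(f1, x), predict(f2, x))
  }
})

test_that("stratified folds balance size and class ratio", {
  labels <- c(rep("positive", 23), rep("negative", 61))
  f <- stratified_folds(labels, folds = 5, seed = 3)
  expect_identical(sort(unique(f)), 1:5)
  sizes <- table(f)
  expect_lte(max(sizes) - min(sizes), 1)
  pos_per_fold <- table(f[labels == "positive"])
  expect_lte(max(pos_per_fold) - min(pos_per_fold), 1)
  # deterministic given the seed
  expect_identical(f, stratified_folds(labels, folds = 5, seed = 3))
})

test_that("cross-validation pools every sample exactly once and is reproducible", {
  wd <- signal_windows(seed = 2, n_proteins = 12, n_positive = 24)
  cv <- crossvalidate(wd, "binary_profile",
                      classifier_spec("svm", "rbf", seed = 1),
                      folds = 5, seed = 11)
  m <- cv$pooled
  expect_identical(m$tp + m$tn + m$fp + m$fn, nrow(wd))
  expect_identical(nrow(cv$predictions), nrow(wd))
  expect_false(anyNA(cv$predictions$score))

  cv2 <- crossvalidate(wd, "binary_profile",
                       classifier_spec("svm", "rbf", seed = 1),
                       folds = 5, seed = 11)
  expect_identical(cv$predictions, cv2$predictions)
  expect_identical(summary(cv), summary(cv2))
})

test_that("label permutation collapses the pooled AUC to chance", {
  wd <- signal_windows(seed = 3)
  withr_seed(47)
  wd$label <- sample(wd$label)
  cv <- crossvalidate(wd, "reduced_triplet_aa",
                      classifier_spec("svm", "rbf", seed = 1), seed = 5)
  expect_lt(abs(cv$pooled$auc - 0.5), 0.08)
})

test_that("window-size sweep reruns the pipeline at each size", {
  cfg <- synth_config(n_proteins = 12, n_positive_sites = 24,
                      signal = strong_signal(), seed = 6)
  ds <- generate_dataset(cfg)
  sites <- validate_sites(ds$sites, ds$proteins)
  sw <- suppressWarnings(
    sweep_window_sizes(ds$proteins, sites, sizes = c(9, 13),
                       scheme = "biprofile_bayes",
                       spec = classifier_spec("svm", "rbf", seed = 1),
                       seed = 9))
  expect_identical(sw$summary$size, c(9, 13))
  expect_identical(nrow(sw$summary), 2L)
  expect_true(all(c("AUC", "Spe", "Pre", "Sen", "F1", "MCC", "ACC")
                  %in% names(sw$summary)))
  expect_error(sweep_window_sizes(ds$proteins, sites, sizes = 10), "odd")
})
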