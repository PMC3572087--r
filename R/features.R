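#' Fit a min-max feature normalizer on training data
#'
#' Stores the per-feature minimum and maximum over the training samples so
#' that every training value maps into \[0, 1\] — the standard rescaling for
#' LIBSVM-style classifiers, whose kernels are sensitive to feature scale.
#' Constant features map to 0.
#'
#' @param x Numeric samples x features matrix, or a `feature_matrix`.
#' @return An object of class `minmax_normalizer` (per-feature `min`, `max`).
#' @export
fit_normalizer <- function(x) {
  x <- as_feature_values(x)
  if (nrow(x) == 0L) stop("cannot fit a normalizer on 0 samples",
                          call. = FALSE)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max),
                 feature_names = colnames(x)),
            class = "minmax_normalizer")
}

#' Apply a fitted min-max normalizer
#'
#' Transforms each feature as `(x - min) / (max - min)` with training min and
#' max, clipping held-out values to \[0, 1\]; constant training features map
#' to 0.
#'
#' @param model A [fit_normalizer()] object.
#' @param x Matrix (or `feature_matrix`) with the same columns as the
#'   training data.
#' @return Normalized numeric matrix.
#' @export
apply_normalizer <- function(model, x) {
  stopifnot(inherits(model, "minmax_normalizer"))
  x <- as_feature_values(x)
  if (!identical(colnames(x), model$feature_names)) {
    stop("feature columns do not match the fitted normalizer", call. = FALSE)
  }
  rng <- model$max - model$min
  out <- sweep(x, 2, model$min, "-")
  scale_by <- ifelse(rng > 0, rng, 1)
  out <- sweep(out, 2, scale_by, "/")
  out[, rng == 0] <- 0
  pmin(pmax(out, 0), 1)
}

as_feature_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$features else as.matrix(x)
}

#' Two-sample pooled-variance Student's t statistic
#'
#' Classic Student's t with pooled variance and `n1 + n2 - 2` degrees of
#' freedom, two-sided p-value. When the pooled variance is zero the feature
#' carries no usable signal and `t = 0`, `p = 1` by convention.
#'
#' @param values_pos,values_neg Numeric vectors, each of length >= 2.
#' @return Named vector `c(t = ..., p = ...)`.
#' @examples
#' t_statistic(c(1, 2, 3), c(4, 5, 6))
#' @export
t_statistic <- function(values_pos, values_neg) {
  n1 <- length(values_pos); n2 <- length(values_neg)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 values", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(values_pos) +
            (n2 - 1) * stats::var(values_neg)) / (n1 + n2 - 2)
  if (sp2 <= 0) return(c(t = 0, p = 1))
  t <- (mean(values_pos) - mean(values_neg)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  c(t = t, p = 2 * stats::pt(-abs(t), df = n1 + n2 - 2))
}

#' Rank features by the Student's t-test
#'
#' Computes the pooled-variance t statistic of every feature between the
#' positive and negative samples and ranks features by decreasing |t| (ties
#' broken by column index, so the ranking is deterministic). The t statistic
#' is invariant under per-feature affine rescaling, so ranking before or
#' after normalization is equivalent.
#'
#' @param x Samples x features matrix, or `feature_matrix`.
#' @param labels `"positive"` / `"negative"` per sample (taken from the
#'   `feature_matrix` if omitted).
#' @return An object of class `feature_ranking`: data frame with columns
#'   `feature`, `t`, `p`, `rank`, ordered by rank.
#' @export
rank_features <- function(x, labels = NULL) {
  if (inherits(x, "feature_matrix") && is.null(labels)) labels <- x$labels
  x <- as_feature_values(x)
  if (is.null(labels)) stop("labels required", call. = FALSE)
  pos <- x[labels == "positive", , drop = FALSE]
  neg <- x[labels == "negative", , drop = FALSE]
  n1 <- nrow(pos); n2 <- nrow(neg)
  if (n1 < 2L || n2 < 2L) stop("each class needs >= 2 samples", call. = FALSE)
  m1 <- colMeans(pos); m2 <- colMeans(neg)
  v1 <- apply(pos, 2, stats::var); v2 <- apply(neg, 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t <- ifelse(sp2 > 0, (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2)), 0)
  p <- ifelse(sp2 > 0, 2 * stats::pt(-abs(t), df = n1 + n2 - 2), 1)
  ord <- order(-abs(t), seq_along(t))
  out <- data.frame(feature = colnames(x)[ord], t = unname(t[ord]),
                    p = unname(p[ord]), rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Select the top-k ranked features
#'
#' @param ranking A [rank_features()] result.
#' @param k Number of features to keep, `1 <= k <=` number of features.
#' @return Character vector of the first `k` feature names, in rank order.
#' @export
select_top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (k < 1L || k > nrow(ranking)) {
    stop("k must be in 1..", nrow(ranking), call. = FALSE)
  }
  ranking$feature[seq_len(k)]
}

#' Write a feature ranking as TSV
#' @param ranking A [rank_features()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
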