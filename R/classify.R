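# Cross-validated classification of events from their fitted parameters.

#' Classify events into conditions from fitted parameters
#'
#' Stratified k-fold cross-validation (each fold holds out ~1/folds of
#' every class, so after all folds each sample has been left out exactly
#' once; with 10 folds each model trains on 90% of the data). Features are
#' log10-transformed (strictly positive parameters span decades) and
#' standardized using training-fold statistics only. Two classifier
#' presets: `"knn"` (k = 10 nearest neighbours, standardized Euclidean
#' distance) and `"svm-quadratic"` (max-margin classifier with a degree-2
#' polynomial kernel).
#'
#' @param features data frame/tibble of numeric features (events x
#'   parameters), e.g. the ten parameter columns of a fit table.
#' @param labels class labels (2 or 3 classes, at least 20 events each).
#' @param method `"knn"` or `"svm-quadratic"`.
#' @param folds number of cross-validation folds.
#' @param k neighbours for the KNN preset.
#' @param log_transform log10-transform strictly positive columns first?
#' @param seed RNG seed for the fold assignment.
#' @return An object of class `ipsc_cv`: list with `accuracy` (mean
#'   held-out accuracy), `fold_accuracy`, `confusion` (table of truth x
#'   prediction), `method`, `folds`.
#' @export
cross_validated_classify <- function(features, labels,
                                     method = c("knn", "svm-quadratic"),
                                     folds = 10, k = 10,
                                     log_transform = TRUE, seed = 1) {
  method <- match.arg(method)
  X <- as.data.frame(features)
  stopifnot(all(vapply(X, is.numeric, logical(1))))
  y <- factor(labels)
  if (nlevels(y) < 2 || nlevels(y) > 3)
    stop("labels must form 2 or 3 classes", call. = FALSE)
  if (any(table(y) < 20))
    stop("class too small: need at least 20 events per class",
         call. = FALSE)
  if (log_transform) {
    pos <- vapply(X, function(col) all(col > 0), logical(1))
    X[pos] <- lapply(X[pos], log10)
  }
  n <- nrow(X)
  fold_id <- integer(n)
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  truth <- character(0); pred <- character(0)
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr_i <- which(fold_id != f)
    te_i <- which(fold_id == f)
    mu <- vapply(X[tr_i, , drop = FALSE], mean, numeric(1))
    sg <- vapply(X[tr_i, , drop = FALSE], stats::sd, numeric(1))
    sg[sg == 0] <- 1
    scale_df <- function(d) as.data.frame(
      mapply(function(col, m, s) (col - m) / s, d, mu, sg,
             SIMPLIFY = FALSE))
    Xtr <- scale_df(X[tr_i, , drop = FALSE])
    Xte <- scale_df(X[te_i, , drop = FALSE])
    ph <- switch(method,
      "knn" = as.character(class::knn(Xtr, Xte, y[tr_i], k = k)),
      "svm-quadratic" = {
        m <- e1071::svm(x = as.matrix(Xtr), y = y[tr_i],
                        kernel = "polynomial", degree = 2, coef0 = 1,
                        scale = FALSE)
        as.character(stats::predict(m, as.matrix(Xte)))
      })
    truth <- c(truth, as.character(y[te_i]))
    pred <- c(pred, ph)
    fold_acc[f] <- mean(ph == as.character(y[te_i]))
  }
  conf <- table(truth = factor(truth, levels(y)),
                prediction = factor(pred, levels(y)))
  structure(list(accuracy = mean(truth == pred),
                 fold_accuracy = fold_acc, confusion = conf,
                 method = method, folds = folds, n = n),
            class = "ipsc_cv")
}

#' @export
print.ipsc_cv <- function(x, ...) {
  cat(sprintf("<ipsc_cv> %s, %d-fold CV on %d events: accuracy %.1f%%\n",
              x$method, x$folds, x$n, 100 * x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Write a classification report as JSON
#'
#' @param cv an `ipsc_cv` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classification_report <- function(cv, path) {
  jsonlite::write_json(
    list(method = cv$method, folds = cv$folds, n = cv$n,
         accuracy = cv$accuracy, fold_accuracy = cv$fold_accuracy,
         confusion = as.data.frame(cv$confusion)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
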