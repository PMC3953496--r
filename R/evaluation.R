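#' Classification accuracy percentage
#'
#' \eqn{100 \times \mathrm{correct} / \mathrm{total}}. Reports format this
#' to one decimal with half-up rounding.
#'
#' @param correct number of correctly classified samples.
#' @param total total number of samples (> 0).
#' @return accuracy in percent (full precision).
#' @export
accuracy <- function(correct, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(correct < 0 | correct > total)) stop("need 0 <= correct <= total")
  100 * correct / total
}

#' Per-class accuracy aggregated over folds
#'
#' For each class, the correctly predicted counts are summed over all
#' folds and divided by the summed original counts, then scaled to
#' percent.
#'
#' @param original folds x classes matrix of original sample counts.
#' @param predicted folds x classes matrix of correctly predicted counts.
#' @return named numeric vector of per-class accuracies in percent.
#' @export
per_class_accuracy <- function(original, predicted) {
  original <- as.matrix(original); predicted <- as.matrix(predicted)
  if (!all(dim(original) == dim(predicted)))
    stop("original and predicted count tables must have matching shape")
  if (any(predicted > original))
    stop("predicted-correct counts cannot exceed original counts")
  tot <- colSums(original)
  if (any(tot == 0)) stop("a class has zero original samples across folds")
  out <- 100 * colSums(predicted) / tot
  names(out) <- colnames(original)
  out
}

#' Random train/test splits for k-fold evaluation
#'
#' Draws \code{k} independent random splits: each fold samples
#' \code{test_frac} of the rows (without replacement) as the test set and
#' uses the rest for training. Folds are resampled independently, so the
#' per-fold class counts vary from fold to fold.
#'
#' @param labels class label vector for the dataset rows.
#' @param k number of folds (default 5).
#' @param test_frac test fraction per fold (default 0.2).
#' @param seed RNG seed.
#' @return list of \code{k} lists with integer row indices \code{train}
#'   and \code{test}.
#' @export
make_folds <- function(labels, k = 5L, test_frac = 0.2, seed = NULL) {
  n <- length(labels)
  if (n == 0L) stop("empty dataset")
  if (test_frac <= 0 || test_frac >= 1) stop("test_frac must be in (0, 1)")
  if (any(table(labels) < 2))
    stop("every class needs at least 2 rows to appear in train and test splits")
  n_test <- max(1L, floor(n * test_frac))
  with_seed(seed, lapply(seq_len(k), function(f) {
    test <- sort(sample.int(n, n_test))
    list(fold = f, train = setdiff(seq_len(n), test), test = test)
  }))
}

# Assemble a cross-validation report from per-fold count tables
# (folds x classes): original and correctly-predicted counts for the
# train and test partitions. Used both by run_crossval() and to replay
# externally tabulated counts through the same arithmetic.
#' Build a fold report from count tables
#'
#' Computes every accuracy figure of the five-fold protocol from four
#' folds-by-classes count matrices: per-fold train/test accuracy (total
#' correct over fold size), per-class accuracies aggregated over folds,
#' and overall train/test accuracy as the unweighted mean of the per-fold
#' accuracies. All reported accuracies are rounded half-up to one decimal.
#'
#' @param orig_train,pred_train,orig_test,pred_test folds x classes count
#'   matrices (original and correctly-predicted, training and testing).
#' @return object of class \code{"manfis_cv"} with the count tables and
#'   all accuracy aggregates.
#' @export
fold_report <- function(orig_train, pred_train, orig_test, pred_test) {
  m <- lapply(list(orig_train = orig_train, pred_train = pred_train,
                   orig_test = orig_test, pred_test = pred_test), as.matrix)
  fold_train <- accuracy(rowSums(m$pred_train), rowSums(m$orig_train))
  fold_test <- accuracy(rowSums(m$pred_test), rowSums(m$orig_test))
  rep <- list(
    counts = m,
    fold_train_accuracy = round_half_up(fold_train, 1),
    fold_test_accuracy = round_half_up(fold_test, 1),
    class_train_accuracy = round_half_up(
      per_class_accuracy(m$orig_train, m$pred_train), 1),
    class_test_accuracy = round_half_up(
      per_class_accuracy(m$orig_test, m$pred_test), 1),
    overall_train_accuracy = round_half_up(mean(fold_train), 1),
    overall_test_accuracy = round_half_up(mean(fold_test), 1)
  )
  class(rep) <- "manfis_cv"
  rep
}

#' Five-fold cross-validation of the MANFIS classifier
#'
#' Trains a fresh [manfis()] model on each fold's training partition,
#' predicts both partitions, tallies original and correctly predicted
#' counts per class, and aggregates them with [fold_report()].
#'
#' @param features labelled feature table (six feature columns plus
#'   \code{label}).
#' @param k number of folds (default 5).
#' @param test_frac test fraction per fold (default 0.2).
#' @param seed seed for the fold sampling (also passed to each fold's
#'   model).
#' @param ... training arguments passed to [manfis()] (epochs, n_mf, ...).
#' @return \code{"manfis_cv"} report; also carries the fold index lists
#'   as attribute \code{"folds"}.
#' @export
run_crossval <- function(features, k = 5L, test_frac = 0.2, seed = 1L, ...) {
  lev <- cell_classes()
  if (!"label" %in% names(features)) stop("features must have a label column")
  labels <- factor(as.character(features$label), levels = lev)
  folds <- make_folds(labels, k = k, test_frac = test_frac, seed = seed)
  count_tab <- function(truth, pred) {
    ok <- pred == truth
    rbind(orig = table(truth), pred = table(truth[ok]))
  }
  tabs <- lapply(folds, function(fd) {
    fit <- tryCatch(
      manfis(label ~ ., data = features[fd$train, ], seed = seed, ...),
      error = function(e) stop("fold ", fd$fold, ": ", conditionMessage(e)))
    pr_tr <- predict(fit, features[fd$train, ])$class
    pr_te <- predict(fit, features[fd$test, ])$class
    list(train = count_tab(labels[fd$train], pr_tr),
         test = count_tab(labels[fd$test], pr_te))
  })
  grab <- function(part, row) t(vapply(tabs, function(tb) tb[[part]][row, ],
                                       numeric(length(lev))))
  rep <- fold_report(grab("train", "orig"), grab("train", "pred"),
                     grab("test", "orig"), grab("test", "pred"))
  attr(rep, "folds") <- folds
  rep
}

#' @export
print.manfis_cv <- function(x, ...) {
  lev <- colnames(x$counts$orig_train)
  if (is.null(lev)) lev <- cell_classes()
  k <- nrow(x$counts$orig_train)
  fmt <- function(v) formatC(v, format = "f", digits = 1)
  cat("Original sample counts per fold (train | test):\n")
  orig <- cbind(x$counts$orig_train, x$counts$orig_test)
  colnames(orig) <- rep(lev, 2)
  rownames(orig) <- paste("Fold", seq_len(k))
  print(orig)
  cat("\nCorrectly predicted counts and accuracy per fold:\n")
  pred <- cbind(x$counts$pred_train, x$counts$pred_test,
                train = fmt(x$fold_train_accuracy),
                test = fmt(x$fold_test_accuracy))
  rownames(pred) <- paste("Fold", seq_len(k))
  print(pred, quote = FALSE)
  cat("\nPer-class accuracy  (train):",
      paste(lev, fmt(x$class_train_accuracy), collapse = "  "), "\n")
  cat("Per-class accuracy  (test) :",
      paste(lev, fmt(x$class_test_accuracy), collapse = "  "), "\n")
  cat("Overall accuracy: train", fmt(x$overall_train_accuracy),
      " test", fmt(x$overall_test_accuracy), "\n")
  invisible(x)
}
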