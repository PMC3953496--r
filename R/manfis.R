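#' Fit a multiple adaptive neuro-fuzzy inference system (MANFIS)
#'
#' Fits a three-class MANFIS classifier: one first-order Sugeno ANFIS
#' sub-model per class (normal, LSIL, HSIL), arranged in parallel over the
#' same six inputs, each trained one-vs-rest with target 1 for its own
#' class and 0 otherwise. Each sub-model uses \code{n_mf} generalized bell
#' membership functions per input and a full grid-partition rule base
#' (\code{n_mf^d} rules). Training is the hybrid rule: per epoch a ridge
#' least-squares solve of all linear consequent coefficients with the
#' premises fixed, then one backpropagation (gradient-descent) step on the
#' bell parameters, with learning-rate halving whenever a step increases
#' the training error. Inputs are min-max normalized to [0, 1] using
#' bounds fitted on the training data only.
#'
#' @param x a formula such as \code{label ~ .}, or a numeric feature
#'   matrix/data.frame.
#' @param ... passed between methods.
#' @return an object of class \code{"manfis"}; see Details.
#' @details The fitted object carries \code{submodels} (one per class),
#'   \code{levels}, the normalization \code{bounds}, the training
#'   \code{config}, per-sub-model SSE traces, and fitted training labels.
#'   Methods: \code{print}, \code{summary}, \code{coef} (consequent
#'   matrices), \code{predict} (class labels and the three class scores)
#'   and \code{plot} (membership functions).
#' @examples
#' feats <- generate_feature_dataset(c(30, 30, 30), seed = 1)
#' fit <- manfis(label ~ ., data = feats, epochs = 5, seed = 1)
#' predict(fit, feats[1:3, ])
#' @export
manfis <- function(x, ...) UseMethod("manfis")

#' @rdname manfis
#' @param formula model formula with the class label on the left.
#' @param data data.frame holding the six features and the label.
#' @export
manfis.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- mf[, -1L, drop = FALSE]
  fit <- manfis.default(X, y, ...)
  fit$call <- match.call()
  fit
}

# Accept either interface: manfis(label ~ ., data) and manfis(X, y).
#' @rdname manfis
#' @export
manfis.data.frame <- function(x, y, ...) manfis.default(x, y, ...)

#' @rdname manfis
#' @param y class labels (factor or character with levels
#'   normal/LSIL/HSIL).
#' @param n_mf membership functions per input (default 2).
#' @param epochs hybrid training epochs (default 50).
#' @param lr initial premise learning rate (default 0.01).
#' @param lambda ridge penalty of the consequent solve (default 1e-6).
#' @param seed RNG seed recorded with the model; training itself is
#'   deterministic.
#' @export
manfis.default <- function(x, y, n_mf = 2L, epochs = 50L, lr = 0.01,
                           lambda = 1e-6, seed = 1L, ...) {
  X <- as.matrix(as.data.frame(x))
  if (!is.numeric(X)) stop("features must be numeric")
  if (anyNA(X)) stop("features contain missing values")
  lev <- cell_classes()
  y <- as.character(y)
  if (!all(y %in% lev))
    stop("unknown class labels: ", paste(setdiff(unique(y), lev), collapse = ", "),
         " (allowed: ", paste(lev, collapse = ", "), ")")
  y <- factor(y, levels = lev)
  missing_cls <- lev[!(lev %in% y)]
  if (length(missing_cls))
    stop("class absent from training data: ", paste(missing_cls, collapse = ", "))
  if (n_mf < 2L || epochs < 1L) stop("need n_mf >= 2 and epochs >= 1")
  d <- ncol(X)

  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1   # constant feature: maps to 0, harmless
  Z <- sweep(sweep(X, 2, lo), 2, rng, "/")

  submodels <- with_seed(seed, lapply(lev, function(cls) {
    target <- as.numeric(y == cls)
    anfis_train(anfis_init(d, n_mf), Z, target, epochs = epochs,
                lr = lr, lambda = lambda)
  }))
  names(submodels) <- lev

  fit <- structure(list(
    submodels = submodels, levels = lev,
    bounds = list(lo = lo, hi = lo + rng),
    features = colnames(X),
    config = list(n_mf = n_mf, epochs = epochs, lr = lr, lambda = lambda,
                  seed = seed),
    call = match.call()
  ), class = "manfis")
  pr <- predict(fit, X)
  fit$fitted <- pr$class
  fit$train_accuracy <- accuracy(sum(pr$class == y), length(y))
  fit
}

# Normalize raw features with the stored training bounds, clipping to [0,1].
manfis_normalize <- function(object, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$bounds$lo))
    stop("newdata has ", ncol(X), " feature columns; model expects ",
         length(object$bounds$lo))
  rng <- object$bounds$hi - object$bounds$lo
  Z <- sweep(sweep(X, 2, object$bounds$lo), 2, rng, "/")
  pmin(pmax(Z, 0), 1)
}

#' Predict classes with a fitted MANFIS
#'
#' Runs the three parallel sub-models and assigns the class with the
#' largest score; exact ties go to the earlier class in the fixed order
#' (normal, LSIL, HSIL).
#'
#' @param object fitted [manfis()] model.
#' @param newdata data.frame or matrix of the six features (label column,
#'   if present, is ignored).
#' @param ... unused.
#' @return list with \code{class} (factor) and \code{scores} (n x 3
#'   matrix of sub-model outputs).
#' @export
predict.manfis <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    keep <- setdiff(names(newdata), "label")
    newdata <- newdata[, keep, drop = FALSE]
  }
  Z <- manfis_normalize(object, newdata)
  scores <- vapply(object$submodels,
                   function(m) anfis_forward_full(m, Z)$f,
                   numeric(nrow(Z)))
  scores <- matrix(scores, nrow = nrow(Z),
                   dimnames = list(NULL, object$levels))
  idx <- max.col(scores, ties.method = "first")
  list(class = factor(object$levels[idx], levels = object$levels),
       scores = scores)
}

#' @export
print.manfis <- function(x, ...) {
  cat("MANFIS classifier:", length(x$submodels), "parallel ANFIS sub-models\n")
  cat("  classes :", paste(x$levels, collapse = ", "), "\n")
  cat("  inputs  :", length(x$bounds$lo), "features;",
      x$config$n_mf, "bell MFs each;",
      nrow(x$submodels[[1]]$rules), "rules per sub-model\n")
  cat("  training:", x$config$epochs, "epochs, training accuracy",
      sprintf("%.1f%%", round_half_up(x$train_accuracy, 1)), "\n")
  invisible(x)
}

#' @export
summary.manfis <- function(object, ...) {
  sse <- vapply(object$submodels, `[[`, numeric(1), "sse")
  out <- list(config = object$config, final_sse = sse,
              train_accuracy = object$train_accuracy,
              bounds = object$bounds)
  class(out) <- "summary.manfis"
  out
}

#' @export
print.summary.manfis <- function(x, ...) {
  cat("MANFIS summary\n")
  cat("  config: n_mf =", x$config$n_mf, ", epochs =", x$config$epochs,
      ", lr =", x$config$lr, ", lambda =", x$config$lambda, "\n")
  cat("  final training SSE per sub-model:\n")
  print(round(x$final_sse, 4))
  cat("  training accuracy:", sprintf("%.1f%%", round_half_up(x$train_accuracy, 1)), "\n")
  invisible(x)
}

#' @export
coef.manfis <- function(object, ...) {
  lapply(object$submodels, `[[`, "P")
}

#' Plot MANFIS membership functions
#'
#' Draws the fitted generalized bell membership functions of each input of
#' one sub-model over the normalized [0, 1] feature range.
#'
#' @param x fitted [manfis()] model.
#' @param submodel class name or index of the sub-model to plot.
#' @param ... passed to \code{matplot}.
#' @export
plot.manfis <- function(x, submodel = 1L, ...) {
  m <- x$submodels[[submodel]]
  z <- seq(0, 1, length.out = 201)
  op <- graphics::par(mfrow = c(2, ceiling(m$d / 2)), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(m$d)) {
    mf <- vapply(seq_len(m$n_mf), function(j)
      bell_membership(z, m$a[i, j], m$b[i, j], m$c[i, j]), numeric(length(z)))
    graphics::matplot(z, mf, type = "l", lty = 1, ylim = c(0, 1),
                      xlab = "", ylab = "membership",
                      main = if (!is.null(x$features)) x$features[i] else
                        paste("input", i), ...)
  }
  invisible(x)
}
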