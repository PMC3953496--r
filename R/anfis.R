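# Single-output first-order Sugeno ANFIS building blocks.
#
# A sub-model over d normalized inputs holds, per input i, M_f generalized
# bell membership functions (parameters a[i,m], b[i,m], c[i,m]), a full
# grid-partition rule base (M_f^d rules; `rules[r, i]` is the MF index of
# input i in rule r), and per rule a linear consequent: columns of the
# (d+1) x R matrix P are (slope_1..slope_d, intercept).

#' Generalized bell membership function
#'
#' \eqn{\mu(x) = 1 / (1 + ((x - c)/a)^{2b})}: peak 1 at \eqn{x = c}, value
#' exactly 0.5 at \eqn{x = c \pm a} for any \eqn{b > 0}; \eqn{b} controls
#' the shoulder steepness.
#'
#' @param x input value(s).
#' @param a half-width at half-maximum (> 0).
#' @param b slope parameter (> 0).
#' @param c centre.
#' @return membership degree(s) in (0, 1].
#' @export
bell_membership <- function(x, a, b, c) {
  if (any(a <= 0)) stop("bell parameter a must be positive")
  if (any(b <= 0)) stop("bell parameter b must be positive")
  1 / (1 + (((x - c) / a)^2)^b)
}

# Fresh sub-model: MF centres equally spaced over [0, 1], half-widths
# covering the gap so neighbouring bells cross at degree 0.5, b = 2.
anfis_init <- function(d = 6L, n_mf = 2L) {
  if (n_mf < 2L) stop("need at least 2 membership functions per input")
  centres <- seq(0, 1, length.out = n_mf)
  a0 <- (centres[2] - centres[1]) / 2
  rules <- as.matrix(expand.grid(rep(list(seq_len(n_mf)), d)))
  dimnames(rules) <- NULL
  list(d = d, n_mf = n_mf,
       a = matrix(a0, d, n_mf),
       b = matrix(2, d, n_mf),
       c = matrix(rep(centres, each = d), d, n_mf),
       rules = rules,
       P = matrix(0, d + 1L, nrow(rules)))
}

# Layer-by-layer forward pass over an n x d matrix of normalized inputs.
# Returns memberships, rule firings W, normalized firings wbar, rule
# linear outputs G and the model output f.
anfis_forward_full <- function(model, X) {
  X <- as.matrix(X)
  n <- nrow(X); d <- model$d
  mu <- lapply(seq_len(d), function(i)
    vapply(seq_len(model$n_mf), function(m)
      bell_membership(X[, i], model$a[i, m], model$b[i, m], model$c[i, m]),
      numeric(n)))
  mu <- lapply(mu, function(mi) matrix(mi, nrow = n))
  R <- nrow(model$rules)
  W <- matrix(1, n, R)
  for (i in seq_len(d)) W <- W * mu[[i]][, model$rules[, i], drop = FALSE]
  S <- rowSums(W)
  if (any(S <= 0) || any(!is.finite(S)))
    stop("all rule firings vanished for some input; cannot normalize")
  wbar <- W / S
  G <- cbind(X, 1) %*% model$P
  f <- rowSums(wbar * G)
  list(mu = mu, W = W, S = S, wbar = wbar, G = G, f = f)
}

#' Forward pass of a single ANFIS sub-model
#'
#' @param model an ANFIS sub-model (as stored in a fitted [manfis()]
#'   object's \code{submodels}).
#' @param x a length-d numeric vector or n x d matrix of normalized inputs.
#' @return list with \code{f} (output), \code{w} (rule firing strengths)
#'   and \code{wbar} (normalized firing strengths, summing to 1 per row).
#' @export
anfis_forward <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  fw <- anfis_forward_full(model, x)
  list(f = fw$f, w = fw$W, wbar = fw$wbar)
}

#' Least-squares estimate of the consequent coefficients
#'
#' Solves for all linear consequent coefficients with the premise
#' parameters held fixed, minimizing the ridge-penalized squared error.
#' Design column \eqn{(r-1)(d+1)+k} pairs rule r's normalized firing
#' strength with regressor k of \eqn{(x_1, ..., x_d, 1)}. The tiny ridge
#' penalty keeps the solve well-posed when there are more coefficients
#' than samples (minimum-norm-like solution).
#'
#' @param model ANFIS sub-model.
#' @param X n x d matrix of normalized inputs.
#' @param y length-n target vector.
#' @param lambda ridge penalty, default 1e-6.
#' @return the model with updated consequent matrix \code{P}.
#' @export
anfis_lse <- function(model, X, y, lambda = 1e-6) {
  X <- as.matrix(X)
  fw <- anfis_forward_full(model, X)
  d1 <- model$d + 1L
  R <- nrow(model$rules)
  Xa <- cbind(X, 1)
  D <- fw$wbar[, rep(seq_len(R), each = d1), drop = FALSE] *
    Xa[, rep(seq_len(d1), times = R), drop = FALSE]
  A <- crossprod(D) + lambda * diag(ncol(D))
  p <- solve(A, crossprod(D, y))
  model$P <- matrix(p, d1, R)
  model
}

#' Gradient of the training error with respect to the premise parameters
#'
#' Analytic gradient of \eqn{SSE = \sum_j (f(x_j) - y_j)^2} with respect
#' to every generalized-bell parameter (a, b, c), returned as d x n_mf
#' matrices. Matches central finite differences to high accuracy.
#'
#' @inheritParams anfis_lse
#' @return list of matrices \code{a}, \code{b}, \code{c}.
#' @export
anfis_premise_gradient <- function(model, X, y) {
  X <- as.matrix(X)
  fw <- anfis_forward_full(model, X)
  d <- model$d; n_mf <- model$n_mf
  # dE/dW_r = 2 (f - y) (G_r - f) / S
  A <- (2 * (fw$f - y) / fw$S) * (fw$G - fw$f)
  TW <- A * fw$W
  ga <- gb <- gc <- matrix(0, d, n_mf)
  for (i in seq_len(d)) {
    for (m in seq_len(n_mf)) {
      cols <- which(model$rules[, i] == m)
      mu_im <- fw$mu[[i]][, m]
      B <- rowSums(TW[, cols, drop = FALSE]) / mu_im
      u <- (X[, i] - model$c[i, m]) / model$a[i, m]
      u2 <- u^2
      b_ <- model$b[i, m]
      t_ <- u2^b_
      mu2 <- mu_im^2
      dmu_da <- 2 * b_ * t_ * mu2 / model$a[i, m]
      u2bm1 <- ifelse(u2 > 0, u2^(b_ - 1), 0)
      dmu_dc <- 2 * b_ * mu2 * u2bm1 * u / model$a[i, m]
      dmu_db <- ifelse(u2 > 0, -mu2 * t_ * log(u2), 0)
      ga[i, m] <- sum(B * dmu_da)
      gb[i, m] <- sum(B * dmu_db)
      gc[i, m] <- sum(B * dmu_dc)
    }
  }
  list(a = ga, b = gb, c = gc)
}

#' One backpropagation step on the premise parameters
#'
#' Gradient-descent update of all bell parameters; \code{a} and \code{b}
#' are kept strictly positive by clipping.
#'
#' @param model ANFIS sub-model.
#' @param grad gradient from [anfis_premise_gradient()].
#' @param lr learning rate (> 0 descends; 0 leaves the model unchanged).
#' @return updated model.
#' @export
anfis_premise_step <- function(model, grad, lr) {
  model$a <- pmax(model$a - lr * grad$a, 1e-3)
  model$b <- pmax(model$b - lr * grad$b, 0.1)
  model$c <- model$c - lr * grad$c
  model
}

anfis_sse <- function(model, X, y) {
  f <- anfis_forward_full(model, X)$f
  sum((f - y)^2)
}

# Hybrid training of one sub-model: per epoch, an exact (ridge) LSE solve
# of the consequents followed by one backpropagation step on the premises,
# with the learning rate halved (and the step reverted) whenever it
# increases the training SSE.
anfis_train <- function(model, X, y, epochs = 50L, lr = 0.01, lambda = 1e-6) {
  sse_trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    model <- anfis_lse(model, X, y, lambda)
    sse0 <- anfis_sse(model, X, y)
    grad <- anfis_premise_gradient(model, X, y)
    if (!all(vapply(grad, function(g) all(is.finite(g)), logical(1))))
      stop("non-finite premise gradient at epoch ", e, "; training diverged")
    cand <- anfis_premise_step(model, grad, lr)
    sse1 <- anfis_sse(cand, X, y)
    if (sse1 > sse0) {
      lr <- lr / 2
    } else {
      model <- cand
      sse0 <- sse1
    }
    sse_trace[e] <- sse0
  }
  model <- anfis_lse(model, X, y, lambda)
  model$sse <- anfis_sse(model, X, y)
  model$sse_trace <- sse_trace
  model$lr_final <- lr
  model
}
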