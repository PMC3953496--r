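test_that("generalized bell has the right peak, half-width and formula", {
  expect_equal(bell_membership(0.4, a = 0.2, b = 3, c = 0.4), 1.0)
  for (b in c(0.5, 1, 2, 7)) {
    expect_equal(bell_membership(0.6, a = 0.2, b = b, c = 0.4), 0.5)
    expect_equal(bell_membership(0.2, a = 0.2, b = b, c = 0.4), 0.5)
  }
  set.seed(5)
  for (i in 1:50) {
    x <- runif(1, -2, 2); a <- runif(1, 0.1, 2)
    b <- runif(1, 0.3, 4); cc <- runif(1, -1, 1)
    expect_equal(bell_membership(x, a, b, cc),
                 1 / (1 + abs((x - cc) / a)^(2 * b)), tolerance = 1e-12)
  }
  expect_error(bell_membership(0, a = 0, b = 1, c = 0), "positive")
})

test_that("forward pass matches a layer-by-layer scalar recomputation", {
  # single-rule model with constant consequent
  m1 <- list(d = 1L, n_mf = 1L, a = matrix(0.5), b = matrix(2),
             c = matrix(0.5), rules = matrix(1L, 1, 1),
             P = matrix(c(0, 3.7), 2, 1))
  for (x in c(0, 0.3, 1)) expect_equal(anfis_forward(m1, x)$f, 3.7)

  # two symmetric rules, symmetric input
  m2 <- cellafe:::anfis_init(1L, 2L)
  fw <- anfis_forward(m2, 0.5)
  expect_equal(as.vector(fw$wbar), c(0.5, 0.5))
  expect_equal(sum(fw$wbar), 1)

  m <- toy_anfis(d = 2, n_mf = 2, seed = 3)
  set.seed(4)
  for (i in 1:20) {
    x <- runif(2)
    expect_equal(anfis_forward(m, x)$f, oracle_anfis_forward(m, x),
                 tolerance = 1e-10)
  }
})

test_that("normalized firing strengths always sum to one", {
  m <- toy_anfis(d = 3, n_mf = 2, seed = 9)
  set.seed(10)
  X <- matrix(runif(300), 100, 3)
  fw <- anfis_forward(m, X)
  expect_equal(rowSums(fw$wbar), rep(1, 100))
  expect_true(all(is.finite(fw$f)))
})

test_that("LSE recovers known consequents and matches the normal equations", {
  m <- toy_anfis(d = 2, n_mf = 2, seed = 7)
  set.seed(8)
  X <- matrix(runif(200), 100, 2)
  y <- anfis_forward(m, X)$f          # targets generated by the true P
  m0 <- m; m0$P <- matrix(0, 3, 4)
  fit <- anfis_lse(m0, X, y, lambda = 1e-12)
  expect_equal(fit$P, m$P, tolerance = 1e-8)

  # constant targets, single rule: intercept k, zero slope
  m1 <- list(d = 1L, n_mf = 1L, a = matrix(0.5), b = matrix(2),
             c = matrix(0.5), rules = matrix(1L, 1, 1),
             P = matrix(0, 2, 1))
  X1 <- matrix(seq(0, 1, length.out = 20), 20, 1)
  f1 <- anfis_lse(m1, X1, rep(4.2, 20), lambda = 1e-12)
  expect_equal(as.vector(f1$P), c(0, 4.2), tolerance = 1e-6)

  # residual equals an explicit normal-equations solve on the same design
  yn <- y + rnorm(100, 0, 0.3)
  fit2 <- anfis_lse(m0, X, yn, lambda = 1e-6)
  wbar <- anfis_forward(m0, X)$wbar
  D <- matrix(0, 100, 12)
  for (r in 1:4) for (k in 1:3)
    D[, (r - 1) * 3 + k] <- wbar[, r] * (if (k == 3) 1 else X[, k])
  p <- solve(t(D) %*% D + 1e-6 * diag(12), t(D) %*% yn)
  expect_equal(sum((anfis_forward(fit2, X)$f - yn)^2),
               sum((D %*% p - yn)^2), tolerance = 1e-10)
})

test_that("premise gradients match central finite differences", {
  m <- toy_anfis(d = 2, n_mf = 2, seed = 13)
  set.seed(14)
  X <- matrix(runif(60), 30, 2)
  y <- rnorm(30)
  grad <- anfis_premise_gradient(m, X, y)
  eps <- 1e-6
  sse_at <- function(mod) sum((anfis_forward(mod, X)$f - y)^2)
  for (par in c("a", "b", "c")) {
    for (i in 1:2) for (j in 1:2) {
      mp <- m; mp[[par]][i, j] <- mp[[par]][i, j] + eps
      mm <- m; mm[[par]][i, j] <- mm[[par]][i, j] - eps
      fd <- (sse_at(mp) - sse_at(mm)) / (2 * eps)
      expect_lt(abs(grad[[par]][i, j] - fd) / max(abs(fd), 1e-8), 1e-4)
    }
  }
})

test_that("backpropagation descends and lr = 0 is a no-op", {
  m <- cellafe:::anfis_init(1L, 2L)
  m$c <- matrix(c(0.3, 0.9), 1, 2)   # deliberately mis-centred
  set.seed(15)
  X <- matrix(runif(40), 40, 1)
  y <- bell_membership(X[, 1], 0.25, 2, 0.5)
  m <- anfis_lse(m, X, y)
  grad <- anfis_premise_gradient(m, X, y)
  expect_identical(anfis_premise_step(m, grad, 0), m)
  sse0 <- sum((anfis_forward(m, X)$f - y)^2)
  sse1 <- sum((anfis_forward(anfis_premise_step(m, grad, 1e-4), X)$f - y)^2)
  expect_lt(sse1, sse0)
})

test_that("hybrid LSE step never increases the training error within an epoch", {
  tab <- generate_feature_dataset(c(25, 25, 25), seed = 30)
  X <- as.matrix(tab[, 1:6])
  Z <- apply(X, 2, function(v) (v - min(v)) / (max(v) - min(v)))
  y <- as.numeric(tab$label == "normal")
  m <- toy_anfis(d = 6, n_mf = 2, seed = 31)
  m$c <- cellafe:::anfis_init(6L, 2L)$c   # valid premise layout
  for (i in 1:3) {
    sse_before <- sum((anfis_forward(m, Z)$f - y)^2)
    m <- anfis_lse(m, Z, y)
    sse_after <- sum((anfis_forward(m, Z)$f - y)^2)
    expect_lte(sse_after, sse_before + 1e-6 * (1 + sse_before))
    grad <- anfis_premise_gradient(m, Z, y)
    m <- anfis_premise_step(m, grad, 0.005)
  }
})

test_that("training separates noiseless classes perfectly and is reproducible", {
  sep <- generate_feature_dataset(c(15, 15, 15),
                                  class_sds = matrix(0, 3, 6), seed = 1)
  fit <- manfis(label ~ ., data = sep, epochs = 3, seed = 1)
  expect_equal(fit$train_accuracy, 100)

  tab <- generate_feature_dataset(c(30, 20, 20), seed = 17)
  f1 <- manfis(label ~ ., data = tab, epochs = 4, seed = 2)
  f2 <- manfis(label ~ ., data = tab, epochs = 4, seed = 2)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$submodels$normal$a, f2$submodels$normal$a)

  expect_error(manfis(label ~ ., data = sep[sep$label != "HSIL", ]),
               "absent")
})

test_that("trained MANFIS generalizes on held-out simulated cells", {
  tab <- generate_feature_dataset(c(120, 60, 45), seed = 23)
  idx <- seq_len(nrow(tab)) %% 3 == 0
  fit <- manfis(label ~ ., data = tab[!idx, ], epochs = 10, seed = 3)
  pr <- predict(fit, tab[idx, ])
  acc <- accuracy(sum(pr$class == tab$label[idx]), sum(idx))
  expect_gte(acc, 90)
})

test_that("prediction takes the argmax with ties broken toward earlier classes", {
  const_sub <- function(k) list(d = 6L, n_mf = 1L,
                                a = matrix(0.5, 6, 1), b = matrix(2, 6, 1),
                                c = matrix(0.5, 6, 1),
                                rules = matrix(1L, 1, 6),
                                P = matrix(c(rep(0, 6), k), 7, 1))
  fake <- structure(list(
    submodels = list(normal = const_sub(0.9), LSIL = const_sub(0.2),
                     HSIL = const_sub(0.1)),
    levels = cell_classes(),
    bounds = list(lo = rep(0, 6), hi = rep(1, 6)),
    config = list()), class = "manfis")
  x <- matrix(0.5, 1, 6)
  expect_equal(as.character(predict(fake, x)$class), "normal")

  fake$submodels$normal <- const_sub(0.5)
  fake$submodels$LSIL <- const_sub(0.5)
  expect_equal(as.character(predict(fake, x)$class), "normal")
  fake$submodels$normal <- const_sub(0.4)
  expect_equal(as.character(predict(fake, x)$class), "LSIL")
})

test_that("batch prediction equals per-sample prediction", {
  tab <- generate_feature_dataset(c(20, 15, 15), seed = 44)
  fit <- manfis(label ~ ., data = tab, epochs = 3, seed = 5)
  new <- generate_feature_dataset(c(20, 15, 15), seed = 45)
  batch <- predict(fit, new)
  for (i in seq(1, 50, by = 7)) {
    single <- predict(fit, new[i, ])
    expect_equal(as.character(batch$class[i]), as.character(single$class))
    expect_equal(batch$scores[i, ], single$scores[1, ])
  }
})
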