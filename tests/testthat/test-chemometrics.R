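test_that("scaling is exact and exactly invertible", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 20, 40))
  s <- scaleMatrix(X, "uv")
  expect_equal(colMeans(s$X), c(a = 0, b = 0))
  expect_equal(apply(s$X, 2, sd), c(a = 1, b = 1))
  expect_equal(unscaleMatrix(s$X, s$center, s$scale), X,
               tolerance = 1e-12)
  ## pareto leaves variance equal to the original SD
  p <- scaleMatrix(X, "pareto")
  expect_equal(unname(apply(p$X, 2, var)), unname(apply(X, 2, sd)),
               tolerance = 1e-12)
  Xc <- cbind(a = c(1, 2, 3), flat = c(5, 5, 5))
  expect_error(scaleMatrix(Xc, "uv"), "flat")
})

test_that("NIPALS PLS matches closed forms and stays orthogonal", {
  set.seed(201)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- X %*% rnorm(6) + rnorm(40) * 0.2
  ## one component: weights proportional to X'y on the scaled data
  m1 <- fitPLS(X, y, 1, scale = "center")
  w_ref <- crossprod(scale(X, scale = FALSE), y - mean(y))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_equal(abs(sum(m1@weights[, 1] * w_ref)), 1, tolerance = 1e-10)

  ## full rank reproduces least squares
  mf <- fitPLS(X, y, 6, scale = "center")
  ls <- lm.fit(cbind(1, X), y)
  expect_equal(as.vector(predict(mf, X)), unname(ls$fitted.values),
               tolerance = 1e-8)

  ## score orthogonality over random fixtures
  for (s in 1:5) {
    set.seed(s)
    Xr <- matrix(rnorm(25 * 8), 25, 8)
    Yr <- matrix(rnorm(50), 25, 2)
    mr <- fitPLS(Xr, Yr, 4)
    G <- crossprod(mr@scores)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  }

  ## response orthogonal to X carries (almost) no explained variance
  set.seed(202)
  Xo <- matrix(rnorm(30 * 5), 30, 5)
  yo <- residuals(lm(rnorm(30) ~ Xo))
  expect_lt(fitPLS(Xo, yo, 2)@R2Y, 0.01)
})

test_that("PLS predictions agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(203)
  X <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(NULL, paste0("x", 1:8)))
  Y <- X %*% matrix(rnorm(16), 8, 2) + 0.3 * matrix(rnorm(60), 30, 2)
  colnames(Y) <- c("y1", "y2")
  Xn <- matrix(rnorm(5 * 8), 5, 8, dimnames = list(NULL, colnames(X)))
  ref <- mixOmics::pls(X, Y, ncomp = 3, mode = "regression", scale = FALSE)
  got <- fitPLS(X, Y, 3, scale = "center")
  expect_equal(unname(predict(ref, Xn)$predict[, , 3]),
               unname(predict(got, Xn)), tolerance = 1e-8)
})

test_that("VIP satisfies its normalization identities", {
  set.seed(204)
  X <- matrix(rnorm(20 * 7), 20, 7)
  y <- rnorm(20)
  m <- fitPLS(X, y, 3)
  v <- vip(m)
  expect_equal(mean(v^2), 1, tolerance = 1e-10)
  ## p = 1 forces VIP = 1
  m1 <- fitPLS(matrix(rnorm(20), 20, 1), y, 1, scale = "center")
  expect_equal(unname(vip(m1)), 1, tolerance = 1e-12)
  ## informative variables rise above the noise floor
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    cls <- rep(c(0, 1), each = 10)
    Xs <- cbind(matrix(rnorm(40), 20, 2) + 3 * cls,
                matrix(rnorm(40), 20, 2))
    vs <- vip(fitPLS(Xs, cls, 2))
    all(vs[1:2] > 1) && all(vs[3:4] < 1)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("OSC removes response-orthogonal structure only", {
  set.seed(205)
  n <- 30
  ## X carries a dominant component built to be orthogonal to y
  y <- rnorm(n)
  t_conf <- residuals(lm(rnorm(n) ~ y))
  X <- tcrossprod(t_conf, rep(3, 5)) + matrix(rnorm(n * 5), n, 5) * 0.3
  Xs <- scaleMatrix(X, "uv")$X
  osc <- oscFilter(Xs, y, 1)
  for (j in 1:1) {
    r <- abs(cor(osc@osc_scores[, j], y))
    expect_lt(r, 1e-6)
  }
  ## the planted confound is the first PC; its share of variance is removed
  pc_share <- svd(Xs)$d[1]^2 / sum(Xs^2)
  expect_equal(osc@removed_variance_fraction, pc_share, tolerance = 0.1)
  ## applying the stored correction to the training data strips the same
  ## confounded variance (the prediction weights are a least-squares
  ## surrogate for the orthogonalized score, so agreement is approximate)
  redone <- oscApply(osc, Xs)
  expect_lt(sum(redone^2), sum(Xs^2))
  expect_gt(cor(as.vector(redone), as.vector(osc@X_filtered)), 0.95)
})

test_that("OSC preprocessing can only help a response-aligned model", {
  set.seed(206)
  n <- 40
  y <- rnorm(n)
  noise_dir <- residuals(lm(rnorm(n) ~ y))
  X <- tcrossprod(y, rnorm(8)) + 4 * tcrossprod(noise_dir, rnorm(8)) +
    0.5 * matrix(rnorm(n * 8), n, 8)
  Xs <- scaleMatrix(X, "uv")$X
  q2_raw <- crossValidateQ2(Xs, y, 2, seed = 1,
                            fit_fun = function(X, Y, nc)
                              fitPLS(X, Y, nc, scale = "center"))
  Xo <- oscFilter(Xs, y, 1)@X_filtered
  q2_osc <- crossValidateQ2(Xo, y, 2, seed = 1,
                            fit_fun = function(X, Y, nc)
                              fitPLS(X, Y, nc, scale = "center"))
  expect_gt(q2_osc, q2_raw)
})

test_that("linear-kernel KPLS coincides with linear PLS", {
  set.seed(207)
  for (s in 1:5) {
    X <- matrix(rnorm(25 * 6), 25, 6)
    Y <- X %*% matrix(rnorm(12), 6, 2) + 0.5 * matrix(rnorm(50), 25, 2)
    Xn <- matrix(rnorm(8 * 6), 8, 6)
    a <- predict(fitPLS(X, Y, 3), Xn)
    b <- predict(fitKPLS(X, Y, 3, kernel = "linear"), Xn)
    expect_lt(max(abs(a - b)) / max(abs(a)), 1e-6)
  }
})

test_that("the Gaussian kernel matrix matches hand arithmetic", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 2))
  K <- riliMetab:::.kernel_matrix(X, X, "gaussian", gamma = 1)
  ## squared distances by hand: 1, 4, 5
  Kref <- rbind(c(1, exp(-1), exp(-4)),
                c(exp(-1), 1, exp(-5)),
                c(exp(-4), exp(-5), 1))
  expect_equal(K, Kref, tolerance = 1e-12)
  expect_error(fitKPLS(X, 1:3, 1, kernel = "gaussian", gamma = -1),
               "gamma")
})

test_that("Gaussian KPLS solves XOR where linear PLS cannot", {
  set.seed(208)
  centers <- rbind(c(0, 0), c(4, 4), c(0, 4), c(4, 0))
  lab <- c(0, 0, 1, 1)
  idx <- rep(1:4, each = 15)
  X <- centers[idx, ] + 0.3 * matrix(rnorm(120), 60, 2)
  y <- lab[idx]
  kp <- fitKPLSDA(X, y, ncomp = 2, kernel = "gaussian")
  acc_k <- mean(predict(kp, X, type = "class") == as.character(y))
  lp <- fitPLSDA(X, y, ncomp = 2)
  acc_l <- mean(predict(lp, X, type = "class") == as.character(y))
  expect_equal(acc_k, 1)
  expect_lte(acc_l, 0.75)
})

test_that("cross-validated Q2 behaves at its limits", {
  set.seed(209)
  X <- matrix(rnorm(35 * 5), 35, 5)
  y_exact <- X %*% rnorm(5)
  expect_gt(crossValidateQ2(X, y_exact, 4, seed = 1), 0.99)
  ## Q2 never beats the training fit
  for (s in 1:5) {
    set.seed(s)
    Xr <- matrix(rnorm(30 * 6), 30, 6)
    yr <- Xr %*% rnorm(6) + rnorm(30)
    q2 <- crossValidateQ2(Xr, yr, 2, seed = s)
    expect_lte(q2, fitPLS(Xr, yr, 2)@R2Y)
  }
  ## pure-noise responses cross-validate at or below zero almost always
  q2_null <- vapply(1:10, function(s) {
    set.seed(s + 500)
    crossValidateQ2(matrix(rnorm(30 * 10), 30, 10), rnorm(30), 2,
                    seed = s)
  }, numeric(1))
  expect_gte(mean(q2_null <= 0), 0.9)
  expect_error(crossValidateQ2(X, y_exact, 2, folds = 100), "fold")
})

test_that("permutation test certifies a strong planted signal", {
  set.seed(210)
  cls <- rep(c(0, 1), each = 20)
  X <- cbind(matrix(rnorm(40 * 5), 40, 5) + 3 * cls,
             matrix(rnorm(40 * 25), 40, 25))
  rep <- permutationTest(X, cls, 2, n_perm = 50, seed = 3)
  expect_equal(rep@empirical_p_Q2, 1 / 51)
  expect_gt(rep@observed_Q2, max(rep@permuted_Q2))
  ## single permutation with a fixed seed is reproducible
  r1 <- permutationTest(X, cls, 2, n_perm = 1, seed = 9)
  r2 <- permutationTest(X, cls, 2, n_perm = 1, seed = 9)
  expect_identical(r1@permuted_Q2, r2@permuted_Q2)
  expect_identical(r1@permuted_R2Y, r2@permuted_R2Y)
})

test_that("KPLS score projections are consistent between train and test", {
  set.seed(211)
  X <- matrix(rnorm(30 * 5), 30, 5)
  Y <- X %*% matrix(rnorm(10), 5, 2) + 0.2 * matrix(rnorm(60), 30, 2)
  m <- fitKPLS(X, Y, 2, kernel = "gaussian")
  ## projecting the training samples through the prediction path must give
  ## scores whose induced predictions equal the fitted values
  Tn <- kplsScores(m, X)
  expect_equal(dim(Tn), c(30, 2))
  expect_equal(predict(m, X),
               sweep((diag(30) - matrix(1 / 30, 30, 30)) %*% m@K %*%
                       (diag(30) - matrix(1 / 30, 30, 30)) %*% m@dual_coef,
                     2, -m@y_center), tolerance = 1e-10)
})
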