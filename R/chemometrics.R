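#' Column scaling for multivariate models
#'
#' Mean-centers each column and divides by its SD ("uv", unit variance), by
#' the square root of its SD ("pareto"), or by nothing ("center"). Missing
#' cells are mean-imputed first (multivariate models only; the flag is
#' propagated on the result). The stored vectors give an exact inverse.
#'
#' @param X numeric matrix; no all-missing column.
#' @param method "uv", "pareto" or "center".
#' @return list with \code{X} (scaled matrix), \code{center}, \code{scale}
#'   and \code{imputed} (logical).
#' @export
scaleMatrix <- function(X, method = c("uv", "pareto", "center")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  imputed <- anyNA(X)
  if (imputed) {
    for (j in seq_len(ncol(X))) {
      v <- X[, j]
      if (all(is.na(v))) stop("all-missing column: ", colnames(X)[j])
      if (anyNA(v)) X[is.na(v), j] <- mean(v, na.rm = TRUE)
    }
  }
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  scl <- switch(method,
                uv = sds,
                pareto = sqrt(sds),
                center = rep(1, ncol(X)))
  if (method %in% c("uv", "pareto") && any(sds == 0)) {
    bad <- colnames(X)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance column under ", method, " scaling: ",
         paste(bad, collapse = ", "))
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  list(X = Xs, center = ctr, scale = scl, imputed = imputed)
}

#' Invert scaleMatrix
#' @param Xs scaled matrix.
#' @param center,scale vectors stored by [scaleMatrix()].
#' @return the original-scale matrix.
#' @export
unscaleMatrix <- function(Xs, center, scale) {
  sweep(sweep(Xs, 2, scale, "*"), 2, center, "+")
}

.apply_scaling <- function(Xnew, center, scale) {
  Xnew <- as.matrix(Xnew)
  if (anyNA(Xnew)) {  # unseen missing cells fall back to the training mean
    for (j in seq_len(ncol(Xnew)))
      Xnew[is.na(Xnew[, j]), j] <- center[j]
  }
  sweep(sweep(Xnew, 2, center), 2, scale, "/")
}

.first_informative_col <- function(Y) {
  ss <- colSums(Y^2)
  j <- which(ss > .Machine$double.eps)[1]
  if (is.na(j)) stop("response has no variance left")
  j
}

#' NIPALS partial least squares
#'
#' Fits A components by the NIPALS algorithm with X and Y deflation.
#' Initialization is deterministic: a univariate response starts the inner
#' loop directly, a multivariate response starts at the exact fixed point
#' of the two-block relation (dominant eigenvector of Y'XX'Y), so the
#' iteration converges in a few passes regardless of the eigengap.
#' Convergence tolerance 1e-10 on the relative score change, at most 500
#' inner iterations per component. X columns are scaled per \code{scale};
#' Y is mean-centered.
#'
#' @param X n x p predictor matrix (missing cells mean-imputed, flagged).
#' @param Y n x c numeric response (a vector is treated as one column).
#' @param ncomp number of components, at most \code{min(n - 1, p)}.
#' @param scale X scaling: "uv" (default), "pareto" or "center".
#' @return a \linkS4class{LatentModel}.
#' @export
fitPLS <- function(X, Y, ncomp, scale = "uv") {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (nrow(X) != nrow(Y)) stop("X and Y must be row-matched")
  if (ncomp > min(nrow(X) - 1, ncol(X)))
    stop("ncomp exceeds min(n - 1, p)")
  sx <- scaleMatrix(X, scale)
  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2, y_center)
  Xd <- sx$X
  Yd <- Yc
  n <- nrow(Xd); p <- ncol(Xd); cc <- ncol(Yc)
  ssx0 <- sum(Xd^2); ssy0 <- sum(Yc^2)
  Tm <- matrix(0, n, ncomp); W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp); Q <- matrix(0, cc, ncomp)
  ssy <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    u <- Yd[, .first_informative_col(Yd)]
    if (ncol(Yd) > 1) {
      ## start at the exact fixed point of the two-block relation (the
      ## dominant eigenvector of Yd'XdXd'Yd); the iteration then converges
      ## in a couple of passes even when the eigengap is tiny
      Z <- crossprod(Xd, Yd)
      M <- crossprod(Z)
      av <- eigen((M + t(M)) / 2, symmetric = TRUE)$vectors[, 1]
      if (av[which.max(abs(av))] < 0) av <- -av
      u0 <- Yd %*% av
      if (sum(u0^2) > .Machine$double.eps) u <- u0
    }
    t_old <- rep(0, n)
    conv <- FALSE
    for (it in seq_len(500)) {
      w <- crossprod(Xd, u)
      w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      q <- crossprod(Yd, tt) / sum(tt^2)
      ## a response (numerically) orthogonal to X leaves q at rounding
      ## noise; amplifying it would iterate on garbage -- accept the
      ## component as explaining nothing
      if (sum(q^2) * sum(tt^2) <= 1e-24 * max(ssy0, .Machine$double.xmin)) {
        conv <- TRUE
        break
      }
      u <- Yd %*% q / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) < 1e-10 * max(sqrt(sum(tt^2)),
                                                  .Machine$double.eps)) {
        conv <- TRUE
        break
      }
      t_old <- tt
    }
    if (!conv) stop("NIPALS did not converge at component ", a)
    pp <- crossprod(Xd, tt) / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, pp)
    Yd <- Yd - tcrossprod(tt, q)
    Tm[, a] <- tt; W[, a] <- w; P[, a] <- pp; Q[, a] <- q
    ssy[a] <- sum(tt^2) * sum(q^2)
  }
  colnames(Tm) <- colnames(W) <- colnames(P) <- colnames(Q) <-
    paste0("comp", seq_len(ncomp))
  rownames(W) <- rownames(P) <- colnames(X)
  new("LatentModel", ncomp = as.integer(ncomp), scores = Tm, weights = W,
      xloadings = P, yloadings = Q, ssy = ssy,
      x_center = sx$center, x_scale = sx$scale, y_center = y_center,
      R2X = 1 - sum(Xd^2) / ssx0, R2Y = 1 - sum(Yd^2) / ssy0,
      Q2 = NA_real_, y_levels = character(0), imputed = sx$imputed)
}

#' Fit a PLS-DA model
#'
#' One-hot encodes the class labels and fits [fitPLS()]; predicted class is
#' the argmax of the predicted indicator columns.
#'
#' @param X predictor matrix.
#' @param classes factor (or coercible) of class labels.
#' @param ncomp number of components (default 2).
#' @param scale X scaling (default "uv").
#' @return a \linkS4class{LatentModel} carrying \code{y_levels}.
#' @export
fitPLSDA <- function(X, classes, ncomp = 2, scale = "uv") {
  classes <- factor(classes)
  Y <- stats::model.matrix(~ 0 + classes)
  colnames(Y) <- levels(classes)
  m <- fitPLS(X, Y, ncomp, scale)
  m@y_levels <- levels(classes)
  m
}

#' Predict from a fitted PLS model
#'
#' @param object a \linkS4class{LatentModel}.
#' @param Xnew new samples (columns as in training; missing cells fall back
#'   to the training mean).
#' @param type "response" (numeric Y) or "class" (PLS-DA argmax).
#' @param ... ignored.
#' @return predicted Y matrix, or a character vector of classes.
#' @export
setMethod("predict", "LatentModel",
          function(object, Xnew, type = c("response", "class"), ...) {
  type <- match.arg(type)
  Xs <- .apply_scaling(Xnew, object@x_center, object@x_scale)
  B <- object@weights %*%
    solve(crossprod(object@xloadings, object@weights)) %*%
    t(object@yloadings)
  Yhat <- sweep(Xs %*% B, 2, object@y_center, "+")
  colnames(Yhat) <- names(object@y_center)
  if (type == "class") {
    if (!length(object@y_levels)) stop("model was not fitted as PLS-DA")
    return(object@y_levels[max.col(Yhat, ties.method = "first")])
  }
  Yhat
})

setMethod("show", "LatentModel", function(object) {
  cat(sprintf("LatentModel: %d components, R2X %.3f, R2Y %.3f%s\n",
              object@ncomp, object@R2X, object@R2Y,
              if (is.na(object@Q2)) "" else sprintf(", Q2 %.3f",
                                                    object@Q2)))
  if (length(object@y_levels))
    cat("  PLS-DA classes:", paste(object@y_levels, collapse = ", "), "\n")
})

#' Variable importance in projection
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}}
#' with \eqn{SSY_a = \|q_a\|^2 t_a' t_a}. The mean of VIP^2 over variables
#' is exactly 1.
#'
#' @param model a fitted \linkS4class{LatentModel}.
#' @return numeric vector of VIP scores, named by variable.
#' @export
vip <- function(model) {
  stopifnot(is(model, "LatentModel"))
  if (all(model@ssy <= 0)) stop("degenerate model: no explained Y variance")
  W <- model@weights
  p <- nrow(W)
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  v <- sqrt(p * as.vector(wn2 %*% model@ssy) / sum(model@ssy))
  names(v) <- rownames(W)
  v
}

#' Orthogonal signal correction
#'
#' Removes from a scaled X matrix the dominant variation orthogonal to the
#' response, by Wold's iterative algorithm: each component starts at the
#' fixed point of the iteration (the dominant eigenvector of X'(I - P_Y)X),
#' is orthogonalized to Y (including an intercept, so correlations vanish
#' exactly), re-estimated through a PLS inner relation until the relative
#' score change falls below 1e-6 (at most 500 iterations), then deflated
#' from X.
#'
#' @param X scaled (at least centered) n x p matrix.
#' @param Y response matrix or vector (class indicators or doses).
#' @param n_osc number of OSC components to remove (default 1).
#' @return an \linkS4class{OSCResult}; each removed score has absolute
#'   Pearson correlation below 1e-6 with every Y column.
#' @export
oscFilter <- function(X, Y, n_osc = 1) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (n_osc < 1) stop("n_osc must be >= 1")
  qrY <- qr(cbind(1, Y))
  n <- nrow(X); p <- ncol(X)
  X0ss <- sum(X^2)
  Ts <- matrix(0, n, n_osc); Ps <- matrix(0, p, n_osc)
  Ws <- matrix(0, p, n_osc)
  Xd <- X
  for (a in seq_len(n_osc)) {
    ## start at the exact fixed point: w is the dominant eigenvector of
    ## X'(I - P_Y)X, so the Wold iteration below converges immediately
    S <- crossprod(Xd, qr.resid(qrY, Xd))
    S <- (S + t(S)) / 2
    w0 <- eigen(S, symmetric = TRUE)$vectors[, 1]
    tt <- Xd %*% w0
    conv <- FALSE
    for (it in seq_len(500)) {
      t_orth <- qr.resid(qrY, tt)
      w <- crossprod(Xd, t_orth)
      w <- w / sqrt(sum(w^2))
      t_new <- Xd %*% w
      if (sqrt(sum((t_new - tt)^2)) <
          1e-6 * max(sqrt(sum(t_new^2)), .Machine$double.eps)) {
        tt <- t_new
        conv <- TRUE
        break
      }
      tt <- t_new
    }
    if (!conv) stop("OSC did not converge at component ", a)
    t_final <- qr.resid(qrY, tt)  # exact orthogonality to Y (and centered)
    ## prediction weights: least-squares direction reproducing the
    ## orthogonalized score from X, so that new samples are deflated
    ## without touching the response-predictive (class-mean) structure
    w_pred <- qr.coef(qr(Xd), t_final)
    w_pred[is.na(w_pred)] <- 0
    pp <- crossprod(Xd, t_final) / sum(t_final^2)
    Xd <- Xd - tcrossprod(t_final, pp)
    Ts[, a] <- t_final; Ps[, a] <- pp; Ws[, a] <- w_pred
  }
  new("OSCResult", X_filtered = Xd, osc_scores = Ts, osc_loadings = Ps,
      osc_weights = Ws,
      removed_variance_fraction = 1 - sum(Xd^2) / X0ss)
}

#' Apply a fitted OSC correction to new samples
#'
#' @param osc an \linkS4class{OSCResult}.
#' @param Xnew new samples on the same (scaled) coordinates as the training
#'   X.
#' @return the corrected matrix.
#' @export
oscApply <- function(osc, Xnew) {
  stopifnot(is(osc, "OSCResult"))
  Xnew <- as.matrix(Xnew)
  for (a in seq_len(ncol(osc@osc_weights))) {
    tt <- Xnew %*% osc@osc_weights[, a, drop = FALSE]
    Xnew <- Xnew - tcrossprod(tt, osc@osc_loadings[, a, drop = FALSE])
  }
  Xnew
}

.median_gamma <- function(X) {
  d2 <- as.vector(stats::dist(X))^2
  d2 <- d2[d2 > 0]
  if (!length(d2)) return(1)
  1 / stats::median(d2)
}

.kernel_matrix <- function(A, B, kernel, gamma) {
  if (kernel == "linear") return(tcrossprod(A, B))
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Kernel partial least squares
#'
#' Kernel-space PLS with deflation. The training kernel matrix (Gaussian
#' \eqn{K_{ij} = \exp(-\gamma \|x_i - x_j\|^2)}, default
#' \eqn{\gamma = 1/\mathrm{median}} of the pairwise squared distances, or
#' linear \eqn{XX'}) is double-centered; score/weight vectors are extracted
#' with deflation of both K and Y, and predictions for new samples use the
#' centered cross-kernel. With a linear kernel, predictions coincide with
#' [fitPLS()].
#'
#' @param X n x p predictors.
#' @param Y numeric response (vector or matrix).
#' @param ncomp number of components.
#' @param kernel "gaussian" (default) or "linear".
#' @param gamma Gaussian width; median-distance heuristic when \code{NULL}.
#' @param scale X scaling before the kernel (default "uv").
#' @return a \linkS4class{KPLSModel}.
#' @export
fitKPLS <- function(X, Y, ncomp, kernel = c("gaussian", "linear"),
                    gamma = NULL, scale = "uv") {
  kernel <- match.arg(kernel)
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (nrow(X) != nrow(Y)) stop("X and Y must be row-matched")
  sx <- scaleMatrix(X, scale)
  Xs <- sx$X
  n <- nrow(Xs)
  if (kernel == "gaussian") {
    if (is.null(gamma)) gamma <- .median_gamma(Xs)
    if (gamma <= 0) stop("gamma must be positive")
  } else gamma <- NA_real_
  K <- .kernel_matrix(Xs, Xs, kernel, gamma)
  H <- diag(n) - matrix(1 / n, n, n)
  Kc <- H %*% K %*% H
  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2, y_center)
  Kd <- Kc; Yd <- Yc
  Tm <- matrix(0, n, ncomp); U <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    ## exact solution of the two-block fixed point t ~ Kd Yd Yd' t: the
    ## dominant eigenvector of the small c x c matrix Yd' Kd Yd gives the
    ## response-space direction (deterministic, no iteration)
    S <- crossprod(Yd, Kd %*% Yd)
    S <- (S + t(S)) / 2
    es <- eigen(S, symmetric = TRUE)
    avec <- es$vectors[, 1]
    j <- which.max(abs(avec))
    if (avec[j] < 0) avec <- -avec  # fixed sign convention
    u <- Yd %*% avec
    un <- sqrt(sum(u^2))
    if (un <= .Machine$double.eps)
      stop("kernel PLS: degenerate response at component ", a)
    u <- u / un
    tt <- Kd %*% u
    tn <- sqrt(sum(tt^2))
    if (tn <= .Machine$double.eps)
      stop("kernel PLS: degenerate kernel score at component ", a)
    tt <- tt / tn
    Tm[, a] <- tt; U[, a] <- u
    Pr <- diag(n) - tcrossprod(tt)
    Kd <- Pr %*% Kd %*% Pr
    Yd <- Yd - tcrossprod(tt, crossprod(Yd, tt))
  }
  M <- crossprod(Tm, Kc %*% U)
  dual <- U %*% solve(M, crossprod(Tm, Yc))
  new("KPLSModel", kernel = kernel, gamma = gamma, Xtrain = Xs,
      x_center = sx$center, x_scale = sx$scale, K = K, Tmat = Tm, U = U,
      dual_coef = dual, y_center = y_center, y_levels = character(0),
      ncomp = as.integer(ncomp))
}

#' Fit a kernel PLS-DA model
#' @inheritParams fitKPLS
#' @param classes factor of class labels (one-hot encoded internally).
#' @return a \linkS4class{KPLSModel} carrying \code{y_levels}.
#' @export
fitKPLSDA <- function(X, classes, ncomp = 2, kernel = "gaussian",
                      gamma = NULL, scale = "uv") {
  classes <- factor(classes)
  Y <- stats::model.matrix(~ 0 + classes)
  colnames(Y) <- levels(classes)
  m <- fitKPLS(X, Y, ncomp, kernel, gamma, scale)
  m@y_levels <- levels(classes)
  m
}

#' Predict from a fitted kernel PLS model
#'
#' @param object a \linkS4class{KPLSModel}.
#' @param Xnew new samples on the original variable scale.
#' @param type "response" or "class".
#' @param ... ignored.
#' @export
setMethod("predict", "KPLSModel",
          function(object, Xnew, type = c("response", "class"), ...) {
  type <- match.arg(type)
  Xs <- .apply_scaling(Xnew, object@x_center, object@x_scale)
  n <- nrow(object@Xtrain)
  Kt <- .kernel_matrix(Xs, object@Xtrain, object@kernel, object@gamma)
  H <- diag(n) - matrix(1 / n, n, n)
  ones <- matrix(1 / n, nrow(Kt), n)
  Ktc <- (Kt - ones %*% object@K) %*% H
  Yhat <- sweep(Ktc %*% object@dual_coef, 2, object@y_center, "+")
  colnames(Yhat) <- names(object@y_center)
  if (type == "class") {
    if (!length(object@y_levels)) stop("model was not fitted as KPLS-DA")
    return(object@y_levels[max.col(Yhat, ties.method = "first")])
  }
  Yhat
})

#' Latent scores of new samples under a kernel PLS model
#'
#' Projects new samples into the model's score space via the centered
#' cross-kernel: \code{t_new = Kc_new U (T' Kc U)^{-1}}.
#'
#' @param model a \linkS4class{KPLSModel}.
#' @param Xnew new samples on the original variable scale (\code{NULL}
#'   returns the training scores).
#' @return matrix of scores, one row per sample.
#' @export
kplsScores <- function(model, Xnew = NULL) {
  stopifnot(is(model, "KPLSModel"))
  if (is.null(Xnew)) return(model@Tmat)
  Xs <- .apply_scaling(Xnew, model@x_center, model@x_scale)
  n <- nrow(model@Xtrain)
  H <- diag(n) - matrix(1 / n, n, n)
  Kc <- H %*% model@K %*% H
  Kt <- .kernel_matrix(Xs, model@Xtrain, model@kernel, model@gamma)
  Ktc <- (Kt - matrix(1 / n, nrow(Kt), n) %*% model@K) %*% H
  Ktc %*% model@U %*% solve(crossprod(model@Tmat, Kc %*% model@U))
}

setMethod("show", "KPLSModel", function(object) {
  cat(sprintf("KPLSModel: %s kernel, %d components%s\n", object@kernel,
              object@ncomp,
              if (object@kernel == "gaussian")
                sprintf(", gamma %.4g", object@gamma) else ""))
})

#' Cross-validated Q2 of a PLS (or kernel PLS) model
#'
#' Venetian-blind fold assignment (sample i goes to fold
#' \code{(i - 1 + offset) mod folds + 1}, offset drawn from the seed);
#' within each fold, the model is refit on the remaining samples and the
#' held-out responses are predicted. \deqn{Q^2 = 1 - PRESS / SSY,} where SSY
#' sums squared deviations of held-out Y from the training-fold means.
#'
#' @param X,Y data matrices.
#' @param ncomp number of components.
#' @param folds number of folds (default 7).
#' @param seed integer seed for the fold offset.
#' @param fit_fun fitter: [fitPLS()] (default) or a wrapper around
#'   [fitKPLS()] with matching signature \code{function(X, Y, ncomp)}.
#' @return Q2 (a scalar, at most 1; can be negative).
#' @export
crossValidateQ2 <- function(X, Y, ncomp, folds = 7, seed = 1,
                            fit_fun = fitPLS) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (folds < 2) stop("folds must be >= 2")
  if (folds > n) stop("a fold would hold < 1 sample")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  offset <- sample.int(folds, 1) - 1L
  fold <- ((seq_len(n) - 1L + offset) %% folds) + 1L
  press <- 0; ssy <- 0
  for (f in seq_len(folds)) {
    test <- fold == f
    m <- fit_fun(X[!test, , drop = FALSE], Y[!test, , drop = FALSE], ncomp)
    Yhat <- predict(m, X[test, , drop = FALSE])
    press <- press + sum((Y[test, , drop = FALSE] - Yhat)^2)
    ybar <- colMeans(Y[!test, , drop = FALSE])
    ssy <- ssy + sum(sweep(Y[test, , drop = FALSE], 2, ybar)^2)
  }
  1 - press / ssy
}

#' Response permutation test
#'
#' Permutes the rows of Y \code{n_perm} times (200 by default), refits the
#' model and recomputes R2Y and cross-validated Q2 for each permutation.
#' \deqn{p = (1 + \#\{Q^2_{perm} \ge Q^2_{obs}\}) / (n_{perm} + 1).}
#'
#' @param X,Y data matrices.
#' @param ncomp number of components.
#' @param n_perm number of permutations.
#' @param seed integer seed (permutations and CV folds).
#' @param folds CV folds for Q2.
#' @return a \linkS4class{PermutationReport}.
#' @export
permutationTest <- function(X, Y, ncomp, n_perm = 200, seed = 1, folds = 7) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- fitPLS(X, Y, ncomp)
  obs_q2 <- crossValidateQ2(X, Y, ncomp, folds = folds, seed = seed)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  pr2 <- pq2 <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(nrow(Y))
    Yp <- Y[idx, , drop = FALSE]
    pr2[b] <- fitPLS(X, Yp, ncomp)@R2Y
    pq2[b] <- crossValidateQ2(X, Yp, ncomp, folds = folds,
                              seed = seed + b)
  }
  new("PermutationReport", n_perm = as.integer(n_perm),
      observed_R2Y = obs@R2Y, observed_Q2 = obs_q2,
      permuted_R2Y = pr2, permuted_Q2 = pq2,
      empirical_p_Q2 = (1 + sum(pq2 >= obs_q2)) / (n_perm + 1))
}

setMethod("show", "PermutationReport", function(object) {
  cat(sprintf(paste0("PermutationReport: %d permutations; observed R2Y ",
                     "%.3f, Q2 %.3f; empirical p(Q2) = %.4g\n"),
              object@n_perm, object@observed_R2Y, object@observed_Q2,
              object@empirical_p_Q2))
})
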