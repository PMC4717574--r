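#' Restricted log-likelihood of the univariate GRM model
#'
#' Evaluates, by dense Cholesky factorization, the restricted log-likelihood
#' \deqn{\ell = -\tfrac12 [\log|V| + \log|X'V^{-1}X| + y'Py]}
#' with \eqn{V = A\sigma_g^2 + I\sigma_e^2} and
#' \eqn{P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}}. Constant terms are
#' dropped; the same convention is used throughout the package, so
#' likelihoods are comparable across fits on the same data.
#'
#' @param sigmaG2,sigmaE2 variance components.
#' @param y numeric response.
#' @param X fixed-effects design matrix including the intercept.
#' @param A GRM as a \linkS4class{GRMatrix} or plain symmetric matrix.
#' @return restricted log-likelihood (scalar).
#' @export
remlLogLik <- function(sigmaG2, sigmaE2, y, X, A) {
  if (is(A, "GRMatrix")) A <- grmMatrix(A)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(A) == n, nrow(X) == n)
  V <- A * sigmaG2 + diag(sigmaE2, n)
  R <- tryCatch(chol(V), error = function(e)
    stop("V is not positive definite", call. = FALSE))
  logdetV <- 2 * sum(log(diag(R)))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_X <- backsolve(R, forwardsolve(t(R), X))
  XtViX <- crossprod(X, Vi_X)
  Rx <- tryCatch(chol(XtViX), error = function(e)
    stop("X'V^{-1}X is singular", call. = FALSE))
  logdetX <- 2 * sum(log(diag(Rx)))
  XtViy <- crossprod(X, Vi_y)
  b <- backsolve(Rx, forwardsolve(t(Rx), XtViy))
  yPy <- sum(y * Vi_y) - sum(XtViy * b)
  -0.5 * (logdetV + logdetX + yPy)
}

# REML internals on the eigenbasis of A.
#
# With A = U diag(lam) U', rotating y and X by U' turns V into the diagonal
# D = lam * sigmaG2 + sigmaE2, so each likelihood, gradient, EM and AI
# evaluation costs O(n L^2) instead of O(n^3). This is an exact
# reparameterization of the dense problem (identical restricted likelihood),
# not an approximation; the eigendecomposition is paid once per fit.
.remlRotated <- function(sg2, se2, lam, ys, Xs) {
  d <- lam * sg2 + se2
  if (any(d <= 0)) return(NULL)
  W <- Xs / d
  XtViX <- crossprod(Xs, W)
  Rx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(Rx)) return(NULL)
  Viy <- ys / d
  Xty <- crossprod(Xs, Viy)
  beta <- backsolve(Rx, forwardsolve(t(Rx), Xty))
  Py <- drop(Viy - W %*% beta)
  yPy <- sum(ys * Py)
  ll <- -0.5 * (sum(log(d)) + 2 * sum(log(diag(Rx))) + yPy)
  list(d = d, W = W, Rx = Rx, Py = Py, beta = drop(beta), ll = ll)
}

# P %*% v in the rotated basis
.applyP <- function(st, Xs, v) {
  u <- v / st$d
  drop(u - st$W %*% backsolve(st$Rx, forwardsolve(t(st$Rx), crossprod(Xs, u))))
}

# tr(P B) for B = diag(w) in the rotated basis:
#   tr(D^-1 B) - tr((X'V^-1X)^-1 X' D^-1 B D^-1 X)
.trPdiag <- function(st, Xs, w) {
  S <- crossprod(Xs, Xs * (w / st$d^2))
  G <- backsolve(st$Rx, forwardsolve(t(st$Rx), S))
  sum(w / st$d) - sum(diag(as.matrix(G)))
}

#' Fit the univariate GREML model by EM-then-AI REML
#'
#' Maximizes the restricted likelihood of
#' \eqn{y = X\beta + g + e}, \eqn{g \sim N(0, A\sigma_g^2)},
#' \eqn{e \sim N(0, I\sigma_e^2)}. Starting from an equal split of the OLS
#' residual variance, one expectation-maximization update is applied (EM
#' never decreases the restricted likelihood), followed by
#' average-information (AI) updates with step-halving whenever a proposed
#' step lowers the likelihood or leaves the parameter space; variances are
#' floored at \code{1e-8} times the phenotypic variance. Iteration stops when
#' the likelihood gain drops below \code{tol}. Fixed effects are re-estimated
#' by GLS at the current variances each iteration. Internally the model is
#' rotated onto the eigenbasis of A, which leaves the restricted likelihood
#' unchanged while making each iteration linear in n (see the methods
#' vignette).
#'
#' The standard error of h2 is obtained by the delta method from the inverse
#' AI matrix at the optimum.
#'
#' @param y numeric response vector.
#' @param X design matrix (with intercept); full column rank required.
#' @param A \linkS4class{GRMatrix} or symmetric matrix.
#' @param maxIter iteration cap, default 100.
#' @param tol convergence tolerance on the likelihood gain, default 1e-6.
#' @param eigenA optional precomputed \code{eigen(A, symmetric = TRUE)},
#'   reusable across fits on the same GRM.
#' @return a \linkS4class{UnivariateGREML}. Non-convergence returns the fit
#'   with \code{converged = FALSE} and a warning.
#' @examples
#' set.seed(1)
#' n <- 150; m <- 400
#' Z <- scale(matrix(rbinom(n * m, 2, 0.3), n, m))
#' A <- tcrossprod(Z) / m; dimnames(A) <- list(1:n, 1:n)
#' y <- drop(Z %*% rnorm(m, 0, sqrt(0.6 / m))) + rnorm(n, 0, sqrt(0.4))
#' fit <- fitUnivariateGREML(y, cbind(1, rnorm(n)), A)
#' heritability(fit)
#' @export
fitUnivariateGREML <- function(y, X, A, maxIter = 100L, tol = 1e-6,
                               eigenA = NULL) {
  M <- 0L
  if (is(A, "GRMatrix")) {
    M <- nMarkers(A)
    A <- grmMatrix(A)
  }
  X <- as.matrix(X)
  n <- length(y)
  L <- ncol(X)
  stopIf(n < L + 2L, "need at least L + 2 observations")
  stopIf(qr(X)$rank < L, "design matrix is rank deficient")
  stopifnot(nrow(A) == n, nrow(X) == n)

  if (is.null(eigenA)) eigenA <- eigen(A, symmetric = TRUE)
  lam <- eigenA$values
  U <- eigenA$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)

  if (sd(lam) < 1e-10)
    warning("GRM is (numerically) proportional to the identity; genetic and ",
            "residual variance are not separately identifiable")

  varP <- var(y)
  floorv <- 1e-8 * varP
  res0 <- drop(y - X %*% qr.solve(X, y))
  sg2 <- se2 <- max(var(res0) / 2, floorv)

  st <- .remlRotated(sg2, se2, lam, ys, Xs)
  stopIf(is.null(st), "initial variance matrix is not positive definite")
  trace <- st$ll
  converged <- FALSE
  ones <- rep(1, n)
  AI <- diag(2)

  derivs <- function(st) {
    Py <- st$Py
    vg <- lam * Py
    trPA <- .trPdiag(st, Xs, lam)
    trP <- .trPdiag(st, Xs, ones)
    yPAPy <- sum(vg * Py)
    yPPy <- sum(Py * Py)
    Pvg <- .applyP(st, Xs, vg)
    PPy <- .applyP(st, Xs, Py)
    AI <- 0.5 * matrix(c(sum(vg * Pvg), sum(Py * Pvg),
                         sum(Py * Pvg), sum(Py * PPy)), 2L, 2L)
    grad <- -0.5 * c(trPA - yPAPy, trP - yPPy)
    list(grad = grad, AI = AI, trPA = trPA, trP = trP,
         yPAPy = yPAPy, yPPy = yPPy)
  }

  nIter <- 0L
  for (iter in seq_len(maxIter)) {
    nIter <- iter
    dv <- derivs(st)
    AI <- dv$AI
    if (iter == 1L) {
      # EM-REML update: sigma_i^2 + sigma_i^4 (y'P B_i P y - tr(P B_i)) / n
      delta <- c(sg2^2 * (dv$yPAPy - dv$trPA),
                 se2^2 * (dv$yPPy - dv$trP)) / n
    } else {
      delta <- tryCatch(drop(solve(AI, dv$grad)),
                        error = function(e) dv$grad / n)
    }
    accepted <- FALSE
    for (h in 0:30) {
      prop <- pmax(c(sg2, se2) + delta / 2^h, floorv)
      stNew <- .remlRotated(prop[1], prop[2], lam, ys, Xs)
      if (!is.null(stNew) && stNew$ll >= st$ll - 1e-10) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) { converged <- TRUE; break }   # no uphill step exists
    gain <- stNew$ll - st$ll
    sg2 <- prop[1]; se2 <- prop[2]; st <- stNew
    trace <- c(trace, st$ll)
    if (iter >= 2L && abs(gain) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("REML did not converge in ", maxIter, " iterations")

  dv <- derivs(st)
  vc <- tryCatch(solve(dv$AI), error = function(e)
    matrix(NA_real_, 2L, 2L))
  tot <- sg2 + se2
  h2 <- sg2 / tot
  gh <- c(se2, -sg2) / tot^2
  seH2 <- if (anyNA(vc)) NA_real_ else sqrt(max(0, drop(t(gh) %*% vc %*% gh)))
  beta <- setNames(st$beta, colnames(X) %||% paste0("b", seq_len(L)))

  new("UnivariateGREML", sigmaG2 = sg2, sigmaE2 = se2, h2 = h2, seH2 = seH2,
      vcov = vc, beta = beta, loglik = trace, nIter = nIter,
      converged = converged, n = as.integer(n), M = as.integer(M))
}

#' BLUP of total additive genetic effects
#'
#' Evaluates \eqn{g = \sigma_g^2 A V^{-1} (y - X\beta)} at the fitted
#' variances and GLS fixed effects.
#'
#' @param fit a \linkS4class{UnivariateGREML}.
#' @param y,X,A the data the model was fitted to.
#' @return named numeric vector of predicted additive effects.
#' @export
blupAdditive <- function(fit, y, X, A) {
  if (is(A, "GRMatrix")) A <- grmMatrix(A)
  X <- as.matrix(X)
  n <- length(y)
  stopIf(nrow(A) != n || nrow(X) != n || length(fit@beta) != ncol(X),
         "dimension mismatch between fit and data")
  if (fit@sigmaG2 <= 0) return(setNames(rep(0, n), rownames(A)))
  resid <- drop(y - X %*% fit@beta)
  V <- A * fit@sigmaG2 + diag(fit@sigmaE2, n)
  g <- fit@sigmaG2 * drop(A %*% solve(V, resid))
  setNames(g, rownames(A))
}

#' BLUP of per-SNP effects
#'
#' Evaluates \eqn{a = \sigma_u^2 Z' V^{-1} (y - X\beta)} with
#' \eqn{\sigma_u^2 = \sigma_g^2 / M}; by construction the SNP effects satisfy
#' \eqn{Z a = g}, the total additive effects of [blupAdditive()].
#'
#' @param fit a \linkS4class{UnivariateGREML}.
#' @param Z \linkS4class{StandardizedGenotypes} (or samples x SNPs matrix)
#'   consistent with the GRM the model was fitted to.
#' @param y,X the data the model was fitted to.
#' @param A optional GRM used in the fit; when supplied, consistency
#'   \eqn{A = ZZ'/M} is verified and a mismatch is an error.
#' @return named numeric vector of SNP effects.
#' @export
blupSnpEffects <- function(fit, Z, y, X, A = NULL) {
  if (is(Z, "StandardizedGenotypes")) Z <- Z@z
  X <- as.matrix(X)
  n <- length(y)
  M <- ncol(Z)
  stopIf(nrow(Z) != n || nrow(X) != n, "dimension mismatch")
  AZ <- tcrossprod(Z) / M
  if (!is.null(A)) {
    if (is(A, "GRMatrix")) A <- grmMatrix(A)
    stopIf(max(abs(A - AZ)) > 1e-6,
           "Z is inconsistent with the GRM used in the fit (A != ZZ'/M)")
  }
  sigmaU2 <- fit@sigmaG2 / M
  resid <- drop(y - X %*% fit@beta)
  V <- AZ * fit@sigmaG2 + diag(fit@sigmaE2, n)
  a <- sigmaU2 * drop(crossprod(Z, solve(V, resid)))
  setNames(a, colnames(Z))
}
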