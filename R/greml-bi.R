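#' Genetic, environmental and phenotypic correlations from (co)variance components
#'
#' \eqn{r_G = \sigma_{g_1 g_2} / \sqrt{\sigma_{g_1}^2 \sigma_{g_2}^2}},
#' \eqn{r_E} analogously from the residual components, and
#' \eqn{r_P = (\sigma_{g_1 g_2} + \sigma_{e_1 e_2}) /
#'   \sqrt{(\sigma_{g_1}^2 + \sigma_{e_1}^2)(\sigma_{g_2}^2 + \sigma_{e_2}^2)}}.
#'
#' @param sigmaG1,sigmaG2,sigmaG12 genetic variances and covariance.
#' @param sigmaE1,sigmaE2,sigmaE12 residual variances and covariance.
#' @return named vector \code{c(rG, rE, rP)}.
#' @examples
#' correlationsFromComponents(0.599, 0.036, 0.1302, 0.401, 0.964, 0.1013)
#' @export
correlationsFromComponents <- function(sigmaG1, sigmaG2, sigmaG12,
                                       sigmaE1, sigmaE2, sigmaE12) {
  stopIf(any(c(sigmaG1, sigmaG2, sigmaE1, sigmaE2) <= 0),
         "variance components must be positive")
  c(rG = unname(sigmaG12 / sqrt(sigmaG1 * sigmaG2)),
    rE = unname(sigmaE12 / sqrt(sigmaE1 * sigmaE2)),
    rP = unname((sigmaG12 + sigmaE12) /
                  sqrt((sigmaG1 + sigmaE1) * (sigmaG2 + sigmaE2))))
}

# dense REML state for the bivariate model; B is the list of structure
# matrices so that V = sum_k theta_k B[[k]]
.biState <- function(theta, B, y, X) {
  nt <- length(y)
  V <- matrix(0, nt, nt)
  for (k in seq_along(theta)) if (theta[k] != 0) V <- V + theta[k] * B[[k]]
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Vi <- chol2inv(R)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  Rx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(Rx)) return(NULL)
  Viy <- drop(Vi %*% y)
  XtViy <- crossprod(X, Viy)
  beta <- drop(backsolve(Rx, forwardsolve(t(Rx), XtViy)))
  Py <- drop(Viy - ViX %*% beta)
  P <- Vi - ViX %*% chol2inv(Rx) %*% t(ViX)
  ll <- -0.5 * (2 * sum(log(diag(R))) + 2 * sum(log(diag(Rx))) +
                  sum(y * Py))
  list(P = P, Py = Py, beta = beta, ll = ll)
}

#' Fit the bivariate GREML model
#'
#' REML fit of the two-trait mixed model with genetic covariance structure
#' \deqn{var(g) = \begin{pmatrix} A_1\sigma_{g_1}^2 & A_{12}\sigma_{g_1g_2} \\
#'  A_{12}'\sigma_{g_1g_2} & A_2\sigma_{g_2}^2 \end{pmatrix}}
#' and residual covariance \eqn{\sigma_{e_1e_2}} applied only over pairs of
#' records belonging to the same individual (the overlap map). Per-trait
#' variances are initialized from univariate fits and a damped
#' average-information step, followed by full AI iterations with
#' step-halving; proposals with a non-positive-semidefinite genetic or
#' residual covariance matrix are rejected by the same halving. When the two
#' traits are measured on disjoint individuals the residual covariance is not
#' identifiable and is fixed at zero.
#'
#' @param y1,y2 response vectors for trait 1 and 2.
#' @param X1,X2 per-trait design matrices (with intercepts).
#' @param A a \linkS4class{GRMatrix} or matrix: the GRM of the trait-1
#'   individuals (and, by default, of the trait-2 individuals and of the
#'   cross block, the common case where every individual carries both
#'   traits).
#' @param A2,A12 optional GRM blocks for trait 2 and the cross block.
#' @param overlap two-column matrix of (trait-1 index, trait-2 index) pairs
#'   marking records of the same individual; \code{NULL} with equal trait
#'   sample sizes means complete overlap in order.
#' @param maxIter,tol iteration cap and likelihood-gain tolerance.
#' @return a \linkS4class{BivariateGREML}.
#' @export
fitBivariateGREML <- function(y1, y2, X1, X2, A, A2 = NULL, A12 = NULL,
                              overlap = NULL, maxIter = 100L, tol = 1e-6) {
  if (is(A, "GRMatrix")) A <- grmMatrix(A)
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  n1 <- length(y1); n2 <- length(y2)
  A1 <- A
  A2 <- if (is.null(A2)) A1 else if (is(A2, "GRMatrix")) grmMatrix(A2) else A2
  A12 <- if (is.null(A12)) {
    stopIf(n1 != n2, "A12 must be given when trait sample sizes differ")
    A1
  } else A12
  stopifnot(nrow(A1) == n1, nrow(A2) == n2,
            nrow(A12) == n1, ncol(A12) == n2,
            nrow(X1) == n1, nrow(X2) == n2)
  stopIf(qr(X1)$rank < ncol(X1) || qr(X2)$rank < ncol(X2),
         "design matrices must be full rank")

  I12 <- matrix(0, n1, n2)
  if (is.null(overlap)) {
    if (n1 == n2) diag(I12) <- 1
  } else {
    overlap <- as.matrix(overlap)
    stopIf(anyDuplicated(overlap[, 1]) || anyDuplicated(overlap[, 2]),
           "each record may appear at most once per side of the overlap map")
    I12[overlap] <- 1
  }
  hasOverlap <- sum(I12) > 0

  zero11 <- matrix(0, n1, n1); zero22 <- matrix(0, n2, n2)
  zero12 <- matrix(0, n1, n2)
  blk <- function(tl, tr, br) rbind(cbind(tl, tr), cbind(t(tr), br))
  B <- list(
    sigmaG1  = blk(A1, zero12, zero22),
    sigmaG2  = blk(zero11, zero12, A2),
    sigmaG12 = blk(zero11, A12, zero22),
    sigmaE1  = blk(diag(n1), zero12, zero22),
    sigmaE2  = blk(zero11, zero12, diag(n2)),
    sigmaE12 = blk(zero11, I12, zero22))
  y <- c(y1, y2)
  X <- rbind(cbind(X1, matrix(0, n1, ncol(X2))),
             cbind(matrix(0, n2, ncol(X1)), X2))

  # initialize from per-trait univariate fits and moment covariances
  f1 <- suppressWarnings(fitUnivariateGREML(y1, X1, A1, maxIter = 30L))
  f2 <- suppressWarnings(fitUnivariateGREML(y2, X2, A2, maxIter = 30L))
  covP <- if (hasOverlap) {
    ij <- which(I12 == 1, arr.ind = TRUE)
    cov(y1[ij[, 1]], y2[ij[, 2]])
  } else 0
  capG <- 0.9 * sqrt(f1@sigmaG2 * f2@sigmaG2)
  capE <- 0.9 * sqrt(f1@sigmaE2 * f2@sigmaE2)
  theta <- c(sigmaG1 = f1@sigmaG2, sigmaG2 = f2@sigmaG2,
             sigmaG12 = max(-capG, min(capG, covP / 2)),
             sigmaE1 = f1@sigmaE2, sigmaE2 = f2@sigmaE2,
             sigmaE12 = if (hasOverlap) max(-capE, min(capE, covP / 2)) else 0)
  active <- c(TRUE, TRUE, TRUE, TRUE, TRUE, hasOverlap)
  floorv <- 1e-8 * c(var(y1), var(y2), Inf, var(y1), var(y2), Inf)

  okTheta <- function(th) {
    th["sigmaG1"] > 0 && th["sigmaG2"] > 0 &&
      th["sigmaE1"] > 0 && th["sigmaE2"] > 0 &&
      th["sigmaG12"]^2 <= th["sigmaG1"] * th["sigmaG2"] * (1 + 1e-10) &&
      th["sigmaE12"]^2 <= th["sigmaE1"] * th["sigmaE2"] * (1 + 1e-10)
  }
  st <- .biState(theta, B, y, X)
  stopIf(is.null(st), "initial covariance matrix is not positive definite")
  trace <- st$ll
  converged <- FALSE
  ka <- which(active)

  derivs <- function(st) {
    Py <- st$Py
    vk <- lapply(B[ka], function(Bk) drop(Bk %*% Py))
    grad <- vapply(seq_along(ka), function(i)
      -0.5 * (sum(st$P * B[[ka[i]]]) - sum(vk[[i]] * Py)), 0)
    Pv <- lapply(vk, function(v) drop(st$P %*% v))
    AI <- matrix(0, length(ka), length(ka))
    for (i in seq_along(ka)) for (j in i:length(ka)) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(vk[[i]] * Pv[[j]])
    }
    list(grad = grad, AI = AI)
  }

  nIter <- 0L
  AIfin <- NULL
  for (iter in seq_len(maxIter)) {
    nIter <- iter
    dv <- derivs(st)
    AIfin <- dv$AI
    delta <- tryCatch(drop(solve(dv$AI, dv$grad)),
                      error = function(e) dv$grad / length(y))
    if (iter == 1L) delta <- 0.3 * delta    # damped first step
    accepted <- FALSE
    for (h in 0:30) {
      prop <- theta
      prop[ka] <- theta[ka] + delta / 2^h
      prop <- pmax(prop, -Inf)
      for (v in c("sigmaG1", "sigmaG2", "sigmaE1", "sigmaE2"))
        prop[v] <- max(prop[v], floorv[match(v, names(theta))])
      if (!okTheta(prop)) next
      stNew <- .biState(prop, B, y, X)
      if (!is.null(stNew) && stNew$ll >= st$ll - 1e-10) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) { converged <- TRUE; break }
    gain <- stNew$ll - st$ll
    theta <- prop; st <- stNew
    trace <- c(trace, st$ll)
    if (iter >= 2L && abs(gain) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("bivariate REML did not converge in ", maxIter, " iterations")

  dv <- derivs(st)
  vcA <- tryCatch(solve(dv$AI), error = function(e)
    matrix(NA_real_, length(ka), length(ka)))
  vc <- matrix(0, 6L, 6L, dimnames = list(names(theta), names(theta)))
  vc[ka, ka] <- vcA

  g1 <- theta["sigmaG1"]; g2 <- theta["sigmaG2"]; g12 <- theta["sigmaG12"]
  e1 <- theta["sigmaE1"]; e2 <- theta["sigmaE2"]; e12 <- theta["sigmaE12"]
  cors <- correlationsFromComponents(g1, g2, g12, e1, e2, e12)
  clamp <- function(x) max(-1, min(1, x))
  P1 <- g1 + e1; P2 <- g2 + e2

  dseSE <- function(gr) {
    v <- drop(t(gr) %*% vc %*% gr)
    if (is.na(v) || v < 0) NA_real_ else sqrt(v)
  }
  rG <- unname(cors["rG"]); rE <- unname(cors["rE"]); rP <- unname(cors["rP"])
  gRG <- c(-rG / (2 * g1), -rG / (2 * g2), 1 / sqrt(g1 * g2), 0, 0, 0)
  gRE <- c(0, 0, 0, -rE / (2 * e1), -rE / (2 * e2), 1 / sqrt(e1 * e2))
  gRP <- c(-rP / (2 * P1), -rP / (2 * P2), 1 / sqrt(P1 * P2),
           -rP / (2 * P1), -rP / (2 * P2), 1 / sqrt(P1 * P2))
  gH1 <- c(e1 / P1^2, 0, 0, -g1 / P1^2, 0, 0)
  gH2 <- c(0, e2 / P2^2, 0, 0, -g2 / P2^2, 0)

  new("BivariateGREML",
      varcomp = theta, vcov = vc,
      rG = clamp(rG), rE = clamp(rE), rP = clamp(rP),
      seRG = dseSE(gRG), seRE = dseSE(gRE), seRP = dseSE(gRP),
      h2 = unname(c(g1 / P1, g2 / P2)),
      seH2 = c(dseSE(gH1), dseSE(gH2)),
      beta1 = st$beta[seq_len(ncol(X1))],
      beta2 = st$beta[ncol(X1) + seq_len(ncol(X2))],
      loglik = trace, nIter = nIter, converged = converged)
}
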