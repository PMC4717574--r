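# shared fixtures, generated in code and cached per test run

.cohortCache <- new.env(parent = emptyenv())

testCohort <- function(nCouples = 250, nSnps = 800, h2Height = 0.6,
                       targetRp = 0.26, seed = 42, ...) {
  key <- paste(nCouples, nSnps, h2Height, targetRp, seed,
               paste(unlist(list(...)), collapse = "_"), sep = "|")
  if (!is.null(.cohortCache[[key]])) return(.cohortCache[[key]])
  par <- simParams(nCouples = nCouples, nSnps = nSnps, h2Height = h2Height,
                   targetRp = targetRp, seed = seed, ...)
  cohort <- simulateCohort(par)
  cohort$params <- par
  cohort$Z <- standardizeGenotypes(cohort$geno)
  cohort$grm <- computeGRM(cohort$Z)
  .cohortCache[[key]] <- cohort
  cohort
}

coupleHeightCor <- function(phenos, couples) {
  idx <- setNames(seq_len(nrow(phenos)), phenos$sample_id)
  cor(phenos$height[idx[couples$female_id]],
      phenos$height[idx[couples$male_id]])
}

# independent HWE oracle: conditional distribution of the heterozygote count
# given the allele count, obtained by normalizing multinomial HWE
# probabilities over all genotype configurations with that allele count
hweOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  p <- nA / (2 * n)
  hets <- seq(min(nA, 2 * n - nA) %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    stats::dmultinom(c(aa, h, bb), prob = c(p^2, 2 * p * (1 - p), (1 - p)^2))
  }, 0)
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# small dense GREML instance built straight from a standardized matrix
gremlInstance <- function(n, m, h2, seed, L = 2) {
  set.seed(seed)
  Z <- matrix(rbinom(n * m, 2, 0.3), n, m)
  Z <- scale(Z)
  Z[is.na(Z)] <- 0
  A <- tcrossprod(Z) / m
  A <- (A + t(A)) / 2
  dimnames(A) <- list(sprintf("i%04d", 1:n), sprintf("i%04d", 1:n))
  g <- drop(Z %*% rnorm(m, 0, sqrt(h2 / m)))
  g <- g * sqrt(h2) / sd(g)
  y <- g + rnorm(n, 0, sqrt(1 - h2))
  X <- cbind(1, matrix(rnorm(n * (L - 1)), n, L - 1))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(L - 1)))
  list(y = y, X = X, A = A, Z = Z, g = g)
}

# REML log-likelihood via the error-contrast route: density of K'y with K an
# orthonormal basis of the null space of X'. Differences across variance
# values match the profile form up to a theta-free constant.
remlContrastLogLik <- function(sg2, se2, y, X, A) {
  n <- length(y)
  K <- qr.Q(qr(X), complete = TRUE)[, (qr(X)$rank + 1):n, drop = FALSE]
  V <- A * sg2 + diag(se2, n)
  W <- crossprod(K, V) %*% K
  ky <- drop(crossprod(K, y))
  -0.5 * (determinant(W, logarithm = TRUE)$modulus +
            sum(ky * solve(W, ky)))
}

# build a GenotypeData from an explicit samples x SNPs dosage matrix
makeGeno <- function(dos, platform = NULL) {
  n <- nrow(dos); m <- ncol(dos)
  colnames(dos) <- NULL
  if (is.null(platform)) platform <- rep("p1", n)
  rd <- S4Vectors::DataFrame(chrom = rep(1L, m), pos = seq_len(m),
                             a1 = "A", a2 = "G",
                             freq = colMeans(dos, na.rm = TRUE) / 2,
                             row.names = sprintf("snp%03d", seq_len(m)))
  ids <- rownames(dos)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  cd <- S4Vectors::DataFrame(platform = platform, row.names = ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = t(dos)), rowData = rd, colData = cd)
  new("GenotypeData", se)
}
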