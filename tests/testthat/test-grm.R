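test_that("standardization applies (d - 2p)/sqrt(2p(1-p)) with mean imputation", {
  dos <- rbind(c(2, 0, 1), c(0, 2, 1), c(1, 1, NA), c(1, 1, 1))
  g <- makeGeno(dos)
  Z <- standardizeGenotypes(g)
  p <- colMeans(dos, na.rm = TRUE) / 2
  expect_equal(unname(Z@freqs), unname(p))
  expect_equal(Z@z[1, 1], (2 - 2 * p[1]) / sqrt(2 * p[1] * (1 - p[1])))
  expect_equal(Z@z[3, 3], 0)                       # missing -> mean imputed
  # hand evaluation at p = 0.5: dosage 2 maps to 1/sqrt(0.5)
  g5 <- makeGeno(rbind(c(2), c(0), c(2), c(0)))
  expect_equal(standardizeGenotypes(g5)@z[1, 1], 1 / sqrt(0.5))
  # monomorphic column is an error naming the SNP
  gm <- makeGeno(cbind(c(1, 0, 2, 1), c(0, 0, 0, 0)))
  expect_error(standardizeGenotypes(gm), "snp002")
})

test_that("GRM has unit diagonal and 1/sqrt(M)-scale off-diagonals", {
  co <- testCohort(nCouples = 150, nSnps = 2000, seed = 41)
  A <- grmMatrix(co$grm)
  expect_equal(mean(diag(A)), 1, tolerance = 0.02)
  off <- A[upper.tri(A)]
  expect_equal(mean(off), 0, tolerance = 0.01)
  expect_equal(sd(off), 1 / sqrt(2000), tolerance = 0.3 / sqrt(2000))
  expect_identical(A, t(A))

  # duplicated sample rows: off-diagonal equals the two diagonals
  z <- co$Z@z[1:5, 1:500]
  z <- rbind(z, z[1, ])
  rownames(z) <- sprintf("d%d", 1:6)
  Ad <- grmMatrix(computeGRM(new("StandardizedGenotypes",
                                 z = z, freqs = co$Z@freqs[1:500])))
  expect_equal(Ad[1, 6], Ad[1, 1])
  expect_equal(Ad[6, 6], Ad[1, 1])
})

test_that("LD pruning keeps independent SNPs and drops later correlated ones", {
  set.seed(42)
  n <- 300
  base <- matrix(rbinom(n * 30, 2, 0.4), n, 30)
  dup <- base[, 5]                                  # perfect copy of SNP 5
  partial <- base[, 10]
  flip <- sample(n, n %/% 3)
  partial[flip] <- rbinom(length(flip), 2, 0.4)     # correlated, r2 ~ 0.45
  dos <- cbind(base[, 1:10], dup, partial, base[, 11:30])
  g <- makeGeno(dos)
  ids <- rownames(g)
  kept <- ldPrune(g, window = 15, step = 5, r2Max = 0.2)
  expect_false(ids[11] %in% kept)                   # duplicate removed
  expect_true(ids[5] %in% kept)                     # earlier member kept
  expect_false(ids[12] %in% kept)                   # r2 = 0.45 pair: later out
  expect_true(ids[10] %in% kept)

  # mutually independent SNPs are all retained
  gInd <- makeGeno(matrix(rbinom(n * 20, 2, 0.3), n, 20))
  expect_equal(ldPrune(gInd, window = 10, step = 5, r2Max = 0.2),
               rownames(gInd))
  # deterministic
  expect_identical(kept, ldPrune(g, window = 15, step = 5, r2Max = 0.2))
})

test_that("grmPCA returns orthonormal descending eigenpairs that solve A v = lambda v", {
  co <- testCohort(nCouples = 100, nSnps = 500, seed = 43)
  pcs <- grmPCA(co$grm, k = 20)
  expect_equal(ncol(pcs@vectors), 20)
  expect_equal(crossprod(pcs@vectors), diag(20), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pcs@values) <= 1e-10))
  A <- grmMatrix(co$grm)
  for (j in c(1, 5, 20)) {
    res <- A %*% pcs@vectors[, j] - pcs@values[j] * pcs@vectors[, j]
    expect_lt(max(abs(res)) / max(abs(pcs@values[j]), 1), 1e-8)
  }
  expect_error(grmPCA(co$grm, k = 1000), "exceed")
})

test_that("PC1 separates two diverged simulated clusters", {
  set.seed(44)
  n <- 120; m <- 800
  p1 <- runif(m, 0.1, 0.5)
  shift <- runif(m, -0.15, 0.15)
  p2 <- pmin(0.95, pmax(0.05, p1 + shift))
  dos <- rbind(
    matrix(rbinom(n / 2 * m, 2, rep(p1, each = n / 2)), n / 2, m),
    matrix(rbinom(n / 2 * m, 2, rep(p2, each = n / 2)), n / 2, m))
  g <- makeGeno(dos)
  pcs <- grmPCA(computeGRM(standardizeGenotypes(g)), k = 5)
  pc1 <- pcs@vectors[, 1]
  grp <- rep(c(1, 2), each = n / 2)
  # loadings have the same sign within a cluster, opposite between
  expect_true(abs(mean(sign(pc1[grp == 1])) - mean(sign(pc1[grp == 2]))) > 1.8)
})

test_that("ethnic core filter keeps matching labels within 3 SD on all PCs", {
  set.seed(45)
  n <- 200
  vecs <- qr.Q(qr(matrix(rnorm(n * 20), n, 20)))
  rownames(vecs) <- sprintf("S%03d", 1:n)
  # push one sample to 3.5 SD on PC2
  target <- 3.5 * sd(vecs[, 2])
  vecs[7, 2] <- mean(vecs[, 2]) + target
  pcs <- new("GenomicPCs", values = sort(runif(20), decreasing = TRUE),
             vectors = vecs)
  labels <- setNames(rep("white_british", n), rownames(vecs))
  labels[c("S010", "S011")] <- "other"
  kept <- ethnicCoreFilter(pcs, labels)
  expect_false("S007" %in% kept)                 # PC outlier excluded
  expect_false(any(c("S010", "S011") %in% kept)) # label mismatch excluded
  expect_true("S050" %in% kept)                  # central sample retained
})

test_that("couple relatedness filter drops couples at r >= 0.0625", {
  ids <- sprintf("S%02d", 1:8)
  A <- diag(8); dimnames(A) <- list(ids, ids)
  A[1, 2] <- A[2, 1] <- 0.07    # excluded
  A[3, 4] <- A[4, 3] <- 0.05    # retained
  A[5, 6] <- A[6, 5] <- 0.30    # excluded (e.g. siblings paired)
  grm <- new("GRMatrix", grm = A, nMarkers = 100L)
  couples <- data.frame(household_id = c("H1", "H2", "H3", "H4"),
                        female_id = c("S01", "S03", "S05", "S07"),
                        male_id = c("S02", "S04", "S06", "S99"))
  expect_warning(out <- coupleRelatednessFilter(couples, grm), "absent")
  expect_identical(out$household_id, "H2")
  expect_equal(out$relatedness, 0.05)
  # related individuals stay in the GRM sample even when their couple is cut
  expect_true(all(c("S05", "S06") %in% sampleIds(grm)))
})
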