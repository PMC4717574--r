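test_that("HWE exact test matches the conditional enumeration oracle", {
  cases <- list(c(25, 50, 25), c(30, 40, 30), c(5, 5, 90), c(12, 1, 2),
                c(0, 10, 90), c(40, 20, 40))
  for (cs in cases) {
    expect_equal(hweExactTest(cs[1], cs[2], cs[3]),
                 hweOracle(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  }
  expect_gt(hweExactTest(25, 50, 25), 0.9)
  expect_lt(hweExactTest(50, 0, 50), 1e-20)
  expect_equal(hweExactTest(80, 0, 0), 1)   # monomorphic: single outcome
  expect_error(hweExactTest(0, 0, 0), "zero")
  expect_error(hweExactTest(-1, 2, 3), "non-negative")
})

test_that("HWE exact test tracks the chi-square test at large counts", {
  # counts >= 1000, genotype frequencies moderately off HWE (p-values away
  # from 0 and 1, where the chi-square approximation is meaningful)
  cases <- list(c(1830, 2520, 900), c(780, 2480, 1740), c(4600, 4300, 1100))
  for (cs in cases) {
    n <- sum(cs)
    p <- (2 * cs[1] + cs[2]) / (2 * n)
    expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    chi <- sum((cs - expected)^2 / expected)
    pChi <- pchisq(chi, df = 1, lower.tail = FALSE)
    pEx <- hweExactTest(cs[1], cs[2], cs[3])
    expect_lt(abs(pEx - pChi), 0.1 * max(pEx, pChi))
  }
})

test_that("platform missingness Fisher test behaves at both extremes", {
  expect_equal(platformMissingnessTest(5, 95, 5, 95), 1)
  expect_lt(platformMissingnessTest(0, 100, 50, 50), 1e-12)
  expect_error(platformMissingnessTest(0, 0, 5, 95), "platforms")
  # agrees with stats::fisher.test on a moderate table
  expect_equal(platformMissingnessTest(10, 90, 25, 75),
               fisher.test(matrix(c(10, 90, 25, 75), 2, byrow = TRUE))$p.value)
})

test_that("snpQC applies missingness, platform, HWE and MAF filters in order", {
  set.seed(31)
  n <- 2000
  good <- rbinom(n, 2, 0.3)
  highMiss <- good; highMiss[seq_len(0.03 * n)] <- NA   # 3 % missing
  lowMaf <- rbinom(n, 2, 0.04)
  offHwe <- c(rep(2, n / 2), rep(0, n / 2))             # no heterozygotes
  platBias <- rbinom(n, 2, 0.3)
  platBias[1:40] <- NA            # exactly 2 % missing, all on platform 1
  dos <- cbind(good, highMiss, lowMaf, offHwe, platBias)
  colnames(dos) <- NULL
  platform <- c(rep("p1", 600), rep("p2", 1400))
  g <- makeGeno(dos, platform)

  res <- snpQC(g, qcThresholds(platformFisherPMin = 1e-10))
  kept <- rownames(res$geno)
  expect_identical(kept, "snp001")
  expect_equal(unname(dosages(res$geno)[, 1]), good, ignore_attr = TRUE)

  cts <- res$report@counts
  expect_true(all(cts$n_input == cts$n_excluded + cts$n_retained))
  expect_equal(cts$n_excluded[cts$filter == "snp_missingness"], 1)
  expect_equal(cts$n_excluded[cts$filter == "platform_bias"], 1)
  expect_equal(cts$n_excluded[cts$filter == "hwe"], 1)
  expect_equal(cts$n_excluded[cts$filter == "maf"], 1)

  # idempotence
  res2 <- snpQC(res$geno, qcThresholds(platformFisherPMin = 1e-10))
  expect_identical(dosages(res2$geno), dosages(res$geno))
})

test_that("a borderline MAF SNP is excluded at 0.04 and kept at 0.05", {
  set.seed(32)
  n <- 4000
  dos <- cbind(rbinom(n, 2, 0.3),
               rep(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1), n / 10) * 0)
  # construct exact-frequency columns: 4 % and 6 % carriers
  maf04 <- c(rep(1, round(2 * n * 0.04)), rep(0, n - round(2 * n * 0.04)))
  maf06 <- c(rep(1, round(2 * n * 0.06)), rep(0, n - round(2 * n * 0.06)))
  g <- makeGeno(cbind(dos[, 1], sample(maf04), sample(maf06)))
  kept <- rownames(snpQC(g, qcThresholds(hwePMin = 0))$geno)
  expect_false("snp002" %in% kept)
  expect_true("snp003" %in% kept)
})

test_that("sampleQC removes high-missingness and heterozygosity outliers", {
  set.seed(33)
  n <- 100; m <- 400
  dos <- matrix(rbinom(n * m, 2, 0.3), n, m)
  dos[1, seq_len(0.06 * m)] <- NA                  # 6 % missing
  dos[2, ] <- 1                                    # all-heterozygous sample
  g <- makeGeno(dos)
  res <- sampleQC(g)
  expect_false("S001" %in% colnames(res$geno))
  expect_false("S002" %in% colnames(res$geno))
  expect_true("S003" %in% colnames(res$geno))
  cts <- res$report@counts
  expect_true(all(cts$n_input == cts$n_excluded + cts$n_retained))
})

test_that("phenotype filter removes strict 3-SD gender outliers only", {
  # with a large gender group, one added point barely moves the mean/SD, so
  # a point placed just inside 3 SD stays and one just outside goes: the
  # decision boundary is strict at 3
  set.seed(34)
  hM <- rnorm(10000, 175, 6)
  xIn <- mean(hM) + 2.97 * sd(hM)
  xOut <- mean(hM) + 3.03 * sd(hM)
  hM <- c(hM, xIn, xOut)
  hF <- rnorm(400, 162, 6)
  xFar <- mean(hF) + 10 * sd(hF)
  hF <- c(hF, xFar)
  ph <- data.frame(
    sample_id = sprintf("P%05d", seq_len(length(hM) + length(hF))),
    sex = c(rep("male", length(hM)), rep("female", length(hF))),
    height = c(hM, hF), stringsAsFactors = FALSE)
  res <- phenotypeOutlierFilter(ph)
  kept <- res$phenos
  expect_true(xIn %in% kept$height)                   # inside 3 SD retained
  expect_false(xOut %in% kept$height)                 # outside 3 SD removed
  expect_false(xFar %in% kept$height)                 # 10 SD removed
  expect_equal(res$report@counts$n_input,
               res$report@counts$n_excluded + res$report@counts$n_retained)

  # a gender with fewer than 2 records passes through with a warning
  tiny <- data.frame(sample_id = c("a", "b", "c"),
                     sex = c("male", "female", "female"),
                     height = c(300, 160, 165))
  expect_warning(res2 <- phenotypeOutlierFilter(tiny), "fewer than 2")
  expect_true("a" %in% res2$phenos$sample_id)

  # empty input passes through
  empty <- ph[0, ]
  expect_equal(nrow(phenotypeOutlierFilter(empty)$phenos), 0)
})
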