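test_that("swapMales follows the sort-and-swap rule exactly", {
  ph <- data.frame(
    sample_id = c("F1", "F2", "F3", "F4", "M1", "M2", "M3", "M4"),
    height = c(150, 155, 160, 165, 160, 170, 165, 180))
  couples <- data.frame(household_id = paste0("H", 1:4),
                        female_id = paste0("F", 1:4),
                        male_id = paste0("M", 1:4))
  sw <- swapMales(couples, ph)
  # (F150,M160),(F155,M170),(F160,M165),(F165,M180) ->
  # (F150,M170),(F155,M160),(F160,M180),(F165,M165)
  expect_identical(sw$permuted$male_id, c("M2", "M1", "M4", "M3"))
  expect_identical(sw$permuted$female_id, couples$female_id)
  expect_setequal(sw$permuted$male_id, couples$male_id)

  # a single couple is unchanged
  one <- swapMales(couples[1, ], ph)
  expect_identical(one$permuted, couples[1, ])

  # odd couple count: the last sorted couple keeps its male
  sw3 <- swapMales(couples[1:3, ], ph)
  expect_identical(sw3$permuted$male_id[3], "M3")
  expect_identical(sort(sw3$permuted$male_id), sort(couples$male_id[1:3]))

  expect_error(swapMales(couples, ph[-1, ]), "missing height")
})

test_that("swapping preserves marginals and nearly preserves assortment", {
  set.seed(61)
  nc <- 2000
  hF <- rnorm(nc, 162, 6.5)
  hM <- 0.26 * scale(hF) * 6.5 + 175 + rnorm(nc, 0, 6.5 * sqrt(1 - 0.26^2))
  ph <- data.frame(sample_id = c(sprintf("F%04d", 1:nc), sprintf("M%04d", 1:nc)),
                   height = c(hF, hM))
  couples <- data.frame(household_id = sprintf("H%04d", 1:nc),
                        female_id = sprintf("F%04d", 1:nc),
                        male_id = sprintf("M%04d", 1:nc))
  h <- setNames(ph$height, ph$sample_id)
  rp0 <- cor(h[couples$female_id], h[couples$male_id])
  sw <- swapMales(couples, ph)
  rp1 <- cor(h[sw$permuted$female_id], h[sw$permuted$male_id])
  expect_setequal(sw$permuted$male_id, couples$male_id)   # marginal exact
  expect_lt(abs(rp1 - rp0), 0.02)
  # swap of the swap: same couple correlation again
  sw2 <- swapMales(sw$permuted, ph)
  rp2 <- cor(h[sw2$permuted$female_id], h[sw2$permuted$male_id])
  expect_lt(abs(rp2 - rp0), 0.02)
})

test_that("mutual information diagnostics hit their degenerate values", {
  set.seed(62)
  nc <- 400
  region <- sample(letters[1:4], nc, replace = TRUE)
  ph <- data.frame(
    sample_id = c(sprintf("F%03d", 1:nc), sprintf("M%03d", 1:nc)),
    region = c(region, region),                    # identical for partners
    flat = rep("x", 2 * nc),
    stringsAsFactors = FALSE)
  couples <- data.frame(household_id = sprintf("H%03d", 1:nc),
                        female_id = sprintf("F%03d", 1:nc),
                        male_id = sprintf("M%03d", 1:nc))
  rep <- covariateDependenceTests(couples, ph, c("region", "flat"),
                                  types = c(region = "categorical",
                                            flat = "categorical"),
                                  nPerm = 1000, seed = 3)
  # identical covariate: MI equals the marginal entropy, p at its minimum
  tab <- table(region) / nc
  expect_equal(rep$statistic[rep$covariate == "region"],
               -sum(tab * log(tab)), tolerance = 1e-10)
  expect_equal(rep$p_value[rep$covariate == "region"], 1 / 1001)
  # constant covariate: statistic 0, p 1
  expect_equal(rep$statistic[rep$covariate == "flat"], 0)
  expect_equal(rep$p_value[rep$covariate == "flat"], 1)
})

test_that("permutation p-values are valid under independence", {
  set.seed(63)
  nc <- 60
  couples <- data.frame(household_id = sprintf("H%03d", 1:nc),
                        female_id = sprintf("F%03d", 1:nc),
                        male_id = sprintf("M%03d", 1:nc))
  pvals <- vapply(1:60, function(r) {
    ph <- data.frame(
      sample_id = c(couples$female_id, couples$male_id),
      cat = sample(letters[1:3], 2 * nc, replace = TRUE),
      stringsAsFactors = FALSE)
    covariateDependenceTests(couples, ph, "cat",
                             types = c(cat = "categorical"),
                             nPerm = 99, seed = r)$p_value
  }, 0)
  alpha <- 0.2
  slack <- 1 / 100 + 3 * sqrt(alpha * (1 - alpha) / 60)
  expect_lte(mean(pvals <= alpha), alpha + slack)
  expect_gte(min(pvals), 1 / 100)
})

test_that("the swap destroys within-couple covariate dependence", {
  co <- testCohort(nCouples = 500, nSnps = 60, seed = 64)
  ph <- co$phenos
  ph$region <- paste0("c", round(ph$birth_east / 2e5))  # coarse geography
  sw <- swapMales(co$couples, ph)
  obs <- covariateDependenceTests(sw$original, ph, c("age", "region"),
                                  types = c(age = "continuous",
                                            region = "categorical"),
                                  nPerm = 300, seed = 1)
  per <- covariateDependenceTests(sw$permuted, ph, c("age", "region"),
                                  types = c(age = "continuous",
                                            region = "categorical"),
                                  nPerm = 300, seed = 2)
  # observed couples: strong age correlation and regional MI
  expect_gt(obs$statistic[obs$covariate == "age"], 0.8)
  expect_lt(obs$p_value[obs$covariate == "age"], 1e-10)
  expect_lt(obs$p_value[obs$covariate == "region"], 0.01)
  # swapped couples: dependence severely reduced
  expect_lt(abs(per$statistic[per$covariate == "age"]),
            obs$statistic[obs$covariate == "age"] / 3)
  expect_gt(per$p_value[per$covariate == "region"], 0.01)
})

test_that("relatedness declines with birthplace distance and flattens after swap", {
  # two genetically diverged clusters living in two places: couples form
  # within clusters, so close birthplaces go with high relatedness
  set.seed(65)
  nc <- 150; m <- 600
  p1 <- runif(m, 0.1, 0.5)
  p2 <- pmin(0.9, pmax(0.05, p1 + runif(m, -0.2, 0.2)))
  mkpop <- function(p, n) matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  # couples 1-50 within cluster 1, 51-100 cross-cluster, 101-150 within 2
  clF <- c(rep(1, 100), rep(2, 50))
  clM <- c(rep(1, 50), rep(2, 100))
  mkind <- function(cl) {
    out <- matrix(0L, length(cl), m)
    out[cl == 1, ] <- mkpop(p1, sum(cl == 1))
    out[cl == 2, ] <- mkpop(p2, sum(cl == 2))
    out
  }
  all <- rbind(mkind(clF), mkind(clM))
  rownames(all) <- c(sprintf("F%03d", 1:nc), sprintf("M%03d", 1:nc))
  g <- makeGeno(all)
  grm <- computeGRM(standardizeGenotypes(g))
  east <- 4e5 * (c(clF, clM) - 1) + rnorm(2 * nc, 0, 2e4)
  ph <- data.frame(sample_id = sampleIds(g), height = rnorm(2 * nc, 170, 6),
                   birth_east = east, birth_north = rnorm(2 * nc, 0, 2e4),
                   stringsAsFactors = FALSE)
  couples <- data.frame(household_id = sprintf("H%03d", 1:nc),
                        female_id = sprintf("F%03d", 1:nc),
                        male_id = sprintf("M%03d", 1:nc))
  obs <- relatednessDistanceRegression(couples, grm, ph)
  expect_lt(obs["slope"], 0)
  expect_lt(obs["p_value"], 0.05)

  sw <- swapMales(couples, ph)
  per <- relatednessDistanceRegression(sw$permuted, grm, ph)
  expect_lt(abs(per["slope"]), abs(obs["slope"]))

  # degenerate inputs
  expect_error(relatednessDistanceRegression(couples[1:2, ], grm, ph),
               "three couples")
  Aconst <- grm
  Aconst@grm[] <- 0; diag(Aconst@grm) <- 1
  flat <- relatednessDistanceRegression(couples, Aconst, ph)
  expect_equal(unname(flat["slope"]), 0)
})
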