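#' Construct simulation parameters for a synthetic couple cohort
#'
#' The generator emulates the statistical structure the mate-choice analysis
#' assumes: biallelic SNPs in Hardy-Weinberg equilibrium with a minor-allele
#' frequency floor, an additive polygenic architecture for height, male-female
#' couples whose heights correlate through phenotype-driven assortment, and
#' household/geography/age/deprivation covariates exhibiting within-couple
#' dependence for the permutation control to destroy.
#'
#' @param nCouples number of couples (cohort size is \code{2 * nCouples}).
#' @param nSnps number of biallelic SNPs.
#' @param mafLow,mafHigh per-SNP allele frequencies are drawn uniformly on
#'   \code{[mafLow, mafHigh]}; bounds must lie in (0, 0.5].
#' @param h2Height narrow-sense heritability of height in [0, 1].
#' @param causalFraction fraction of SNPs carrying a nonzero effect.
#' @param targetRp target within-couple height correlation in [0, 1).
#' @param sexMeanShift male height advantage in cm (default 13, the
#'   approximate UK male-female difference).
#' @param heightSD within-sex phenotypic SD of height in cm.
#' @param geoClusters number of birthplace clusters on a planar grid.
#' @param ageCorr within-couple age correlation (couples tend to be
#'   age-matched; 0.9 is typical of real cohorts).
#' @param missingRate per-genotype missing rate, default 0.
#' @param seed integer seed driving all randomness of the generator.
#' @return A validated \linkS4class{SimParams} object.
#' @examples
#' simParams(nCouples = 100, nSnps = 500, seed = 1)
#' @export
simParams <- function(nCouples, nSnps, mafLow = 0.05, mafHigh = 0.5,
                      h2Height = 0.8, causalFraction = 0.1, targetRp = 0.26,
                      sexMeanShift = 13, heightSD = 6.5, geoClusters = 25L,
                      ageCorr = 0.9, missingRate = 0, seed = 1L) {
  new("SimParams", nCouples = as.integer(nCouples), nSnps = as.integer(nSnps),
      mafLow = mafLow, mafHigh = mafHigh, h2Height = h2Height,
      causalFraction = causalFraction, targetRp = targetRp,
      sexMeanShift = sexMeanShift, heightSD = heightSD,
      geoClusters = as.integer(geoClusters), ageCorr = ageCorr,
      missingRate = missingRate, seed = as.integer(seed))
}

#' Simulate biallelic SNP genotypes in Hardy-Weinberg equilibrium
#'
#' Each SNP's allele frequency p is drawn from Uniform(mafLow, mafHigh) and
#' dosages are Binomial(2, p) per individual, i.e. the population is
#' panmictic at the marker level. Missing genotypes (if \code{missingRate > 0})
#' are injected uniformly at random. The result is deterministic given
#' \code{params@seed}.
#'
#' @param params a \linkS4class{SimParams} object.
#' @return A \linkS4class{GenotypeData} (SNPs x samples) whose rowData holds
#'   SNP id, chromosome, position, alleles and the generating frequency, and
#'   whose colData holds the per-sample genotyping platform label.
#' @export
simulateGenotypes <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  n <- 2L * params@nCouples
  m <- params@nSnps
  set.seed(childSeed(params@seed, 101L))
  p <- runif(m, params@mafLow, params@mafHigh)
  # samples x SNPs, column j ~ Binomial(2, p_j)
  dos <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
  if (params@missingRate > 0) {
    nmiss <- rbinom(1L, n * m, params@missingRate)
    if (nmiss > 0) dos[sample.int(n * m, nmiss)] <- NA_integer_
  }
  sampleId <- sprintf("S%06d", seq_len(n))
  snpId <- sprintf("snp%06d", seq_len(m))
  rowData <- S4Vectors::DataFrame(
    chrom = 1L + (seq_len(m) - 1L) %% 22L,
    pos = 10000L + 1000L * seq_len(m),
    a1 = "A", a2 = "G", freq = p, row.names = snpId)
  colData <- S4Vectors::DataFrame(
    platform = ifelse(seq_len(n) <= n %/% 3L, "array_a", "array_b"),
    row.names = sampleId)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = t(dos)), rowData = rowData, colData = colData)
  new("GenotypeData", se)
}

#' Simulate heights under the standard additive genetic model
#'
#' Phenotypes follow P = A + E: the additive value A of each individual is a
#' weighted sum of standardized dosages over the causal SNP set, rescaled so
#' the realized variance ratio var(A)/var(P) equals \code{h2Height}; E is
#' independent normal. Sexes are assigned alternately and males receive the
#' constant \code{sexMeanShift}. The true A is retained for downstream
#' checks of the assortment theory.
#'
#' @param geno a \linkS4class{GenotypeData} from [simulateGenotypes()].
#' @param params the same \linkS4class{SimParams}.
#' @return data.frame with columns \code{sample_id}, \code{sex}
#'   ("female"/"male"), \code{height} (cm) and \code{additive} (the latent
#'   true additive value, cm).
#' @export
simulateHeights <- function(geno, params) {
  stopifnot(is(geno, "GenotypeData"), is(params, "SimParams"))
  stopIf(params@h2Height > 1, "h2Height must not exceed 1")
  n <- ncol(geno)
  m <- nrow(geno)
  stopIf(n == 0L || m == 0L, "empty genotype matrix")
  set.seed(childSeed(params@seed, 202L))
  nCausal <- max(1L, ceiling(params@causalFraction * m))
  causal <- sort(sample.int(m, nCausal))
  eff <- rnorm(nCausal)
  dos <- dosages(geno)[, causal, drop = FALSE]
  p <- snpInfo(geno)$freq[causal]
  zc <- sweep(dos, 2L, 2 * p, "-")
  zc <- sweep(zc, 2L, sqrt(2 * p * (1 - p)), "/")
  zc[is.na(zc)] <- 0
  a <- drop(zc %*% eff)
  varP <- params@heightSD^2
  if (params@h2Height == 0) {
    a <- rep(0, n)
  } else {
    sda <- sd(a)
    stopIf(sda == 0, "degenerate additive values (no causal variation)")
    a <- a * sqrt(params@h2Height * varP) / sda
  }
  e <- if (params@h2Height >= 1) rep(0, n) else
    rnorm(n, 0, sqrt((1 - params@h2Height) * varP))
  sex <- rep_len(c("female", "male"), n)
  height <- 162 + ifelse(sex == "male", params@sexMeanShift, 0) + a + e
  data.frame(sample_id = sampleIds(geno), sex = sex, height = height,
             additive = a, stringsAsFactors = FALSE)
}

#' Pair males and females by noisy height rank to a target couple correlation
#'
#' Each sex receives a matching score: the within-sex standardized height plus
#' Gaussian noise of variance sigma^2 = (1 - r)/r; the sexes are sorted by
#' score and paired by rank, which yields a couple height correlation close to
#' r. Because the realized correlation on a finite cohort fluctuates, a short
#' calibration loop rescales the working r until the realized correlation is
#' within 0.02 of \code{targetRp}. \code{targetRp = 0} falls back to uniform
#' random pairing. Pairing depends on phenotype only, so the ante-dependence
#' assumption (genes affect own height, own height drives partner choice)
#' holds by construction.
#'
#' @param phenos data.frame from [simulateHeights()].
#' @param params the \linkS4class{SimParams}.
#' @return data.frame (couple table) with columns \code{household_id},
#'   \code{female_id}, \code{male_id}.
#' @export
formCouples <- function(phenos, params) {
  stopifnot(all(c("sample_id", "sex", "height") %in% names(phenos)))
  stopIf(params@targetRp >= 1, "targetRp must be below 1")
  fem <- phenos[phenos$sex == "female", ]
  mal <- phenos[phenos$sex == "male", ]
  stopIf(nrow(fem) != nrow(mal), "equal numbers of males and females required")
  nc <- nrow(fem)
  zf <- zscore(fem$height)
  zm <- zscore(mal$height)
  target <- params@targetRp

  pairAt <- function(r, iter) {
    set.seed(childSeed(params@seed, 300L + iter))
    if (r <= 0) {
      list(f = sample.int(nc), m = sample.int(nc))
    } else {
      sig <- sqrt((1 - r) / r)
      sf <- zf + rnorm(nc, 0, sig)
      sm <- zm + rnorm(nc, 0, sig)
      list(f = order(sf), m = order(sm))
    }
  }

  r <- target
  best <- pairAt(r, 1L)
  if (target > 0 && nc > 2) {
    for (iter in seq_len(25L)) {
      ord <- pairAt(r, iter)
      realized <- cor(fem$height[ord$f], mal$height[ord$m])
      best <- ord
      if (abs(realized - target) <= 0.02) break
      r <- min(0.999, max(1e-4, r * target / max(realized, 1e-3)))
    }
  }
  data.frame(household_id = sprintf("H%06d", seq_len(nc)),
             female_id = fem$sample_id[best$f],
             male_id = mal$sample_id[best$m],
             stringsAsFactors = FALSE)
}

#' Attach structured covariates shared within couples
#'
#' Adds the covariates whose within-couple dependence the swap permutation is
#' meant to destroy: a shared \code{household_id}; birthplaces drawn around a
#' shared geographic cluster centre (planar metres, within-cluster scatter
#' 20 km over a ~600 km grid); ages correlated at \code{ageCorr} within
#' couples (mean 55, SD 8); and a Townsend deprivation score shared at the
#' household level plus individual noise.
#'
#' @param phenos data.frame of phenotype records.
#' @param couples couple table from [formCouples()].
#' @param params the \linkS4class{SimParams}.
#' @return \code{phenos} augmented with \code{household_id}, \code{age},
#'   \code{townsend}, \code{birth_east}, \code{birth_north}.
#' @export
attachCovariates <- function(phenos, couples, params) {
  nc <- nrow(couples)
  set.seed(childSeed(params@seed, 404L))
  centers <- matrix(runif(2L * params@geoClusters, 0, 6e5),
                    ncol = 2L, dimnames = list(NULL, c("east", "north")))
  cl <- sample.int(params@geoClusters, nc, replace = TRUE)
  rho <- params@ageCorr
  z0 <- rnorm(nc); z1 <- rnorm(nc); z2 <- rnorm(nc)
  sgn <- sign(rho)
  ageF <- 55 + 8 * (sqrt(abs(rho)) * z0 + sqrt(1 - abs(rho)) * z1)
  ageM <- 55 + 8 * (sgn * sqrt(abs(rho)) * z0 + sqrt(1 - abs(rho)) * z2)
  town <- rnorm(nc, 0, 3)

  idx <- setNames(seq_len(nrow(phenos)), phenos$sample_id)
  phenos$household_id <- NA_character_
  phenos$age <- NA_real_
  phenos$townsend <- NA_real_
  phenos$birth_east <- NA_real_
  phenos$birth_north <- NA_real_
  fi <- idx[couples$female_id]
  mi <- idx[couples$male_id]
  phenos$household_id[fi] <- couples$household_id
  phenos$household_id[mi] <- couples$household_id
  phenos$age[fi] <- ageF
  phenos$age[mi] <- ageM
  phenos$townsend[fi] <- town + rnorm(nc, 0, 0.5)
  phenos$townsend[mi] <- town + rnorm(nc, 0, 0.5)
  scatter <- 2e4
  phenos$birth_east[fi] <- centers[cl, "east"] + rnorm(nc, 0, scatter)
  phenos$birth_north[fi] <- centers[cl, "north"] + rnorm(nc, 0, scatter)
  phenos$birth_east[mi] <- centers[cl, "east"] + rnorm(nc, 0, scatter)
  phenos$birth_north[mi] <- centers[cl, "north"] + rnorm(nc, 0, scatter)
  phenos
}

#' Simulate a complete assortatively-mating cohort
#'
#' Convenience wrapper chaining [simulateGenotypes()], [simulateHeights()],
#' [formCouples()] and [attachCovariates()].
#'
#' @param params a \linkS4class{SimParams}.
#' @return list with elements \code{geno} (\linkS4class{GenotypeData}),
#'   \code{phenos} (data.frame) and \code{couples} (data.frame).
#' @examples
#' cohort <- simulateCohort(simParams(nCouples = 50, nSnps = 200, seed = 7))
#' str(cohort$couples)
#' @export
simulateCohort <- function(params) {
  geno <- simulateGenotypes(params)
  phenos <- simulateHeights(geno, params)
  couples <- formCouples(phenos, params)
  phenos <- attachCovariates(phenos, couples, params)
  list(geno = geno, phenos = phenos, couples = couples)
}
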