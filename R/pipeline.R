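#' Identify couples from household sharing
#'
#' Keeps households with exactly two opposite-sex members. In
#' \code{"prediction_pairs"} mode — used for partner prediction where only
#' one member is genotyped, so relatedness cannot be checked from genotypes —
#' couples must additionally have an age difference below \code{maxAgeGap}
#' years, and, when the columns are present, a cohabitation flag
#' (\code{cohabiting}) and differing reported parental ages
#' (\code{mother_age}/\code{father_age}).
#'
#' @param phenos phenotype data.frame with \code{sample_id}, \code{sex} and
#'   \code{household_id} (plus \code{age} in prediction mode).
#' @param mode \code{"genotyped_pairs"} (default) or
#'   \code{"prediction_pairs"}.
#' @param maxAgeGap age-difference ceiling in years for prediction mode.
#' @return couple table (household_id, female_id, male_id).
#' @export
identifyCouples <- function(phenos, mode = c("genotyped_pairs",
                                             "prediction_pairs"),
                            maxAgeGap = 10) {
  mode <- match.arg(mode)
  ph <- phenos[!is.na(phenos$household_id), , drop = FALSE]
  sizes <- table(ph$household_id)
  two <- names(sizes)[sizes == 2L]
  out <- data.frame()
  for (h in two) {
    mem <- ph[ph$household_id == h, ]
    if (!setequal(mem$sex, c("female", "male"))) next
    f <- mem[mem$sex == "female", ]; m <- mem[mem$sex == "male", ]
    if (mode == "prediction_pairs") {
      if (abs(f$age - m$age) >= maxAgeGap) next
      if (!is.null(mem$cohabiting) && !all(mem$cohabiting)) next
      if (!is.null(mem$mother_age) && !is.null(mem$father_age) &&
          isTRUE(f$mother_age == m$mother_age &&
                   f$father_age == m$father_age)) next
    }
    out <- rbind(out, data.frame(household_id = h,
                                 female_id = f$sample_id,
                                 male_id = m$sample_id,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Build a fixed-effects design matrix
#'
#' Intercept plus the configured covariates, taken from \code{data} by name;
#' character or factor covariates are expanded to treatment contrasts.
#' Duplicate covariates and rank-deficient designs are errors naming the
#' offending columns.
#'
#' @param data data.frame holding the covariates.
#' @param covariates character vector of column names (may be empty).
#' @return numeric design matrix with an \code{"(Intercept)"} first column.
#' @export
buildDesign <- function(data, covariates = character()) {
  stopIf(anyDuplicated(covariates) > 0, "duplicate covariate(s): ",
         paste(unique(covariates[duplicated(covariates)]), collapse = ", "))
  missing <- setdiff(covariates, names(data))
  stopIf(length(missing) > 0, "covariate(s) not found: ",
         paste(missing, collapse = ", "))
  if (length(covariates) == 0L)
    return(matrix(1, nrow(data), 1L, dimnames = list(NULL, "(Intercept)")))
  fml <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  X <- model.matrix(fml, data = data)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qrx$rank)]
    stop("collinear design column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  X
}

#' Expand couples to focal records
#'
#' Each couple contributes two focal records: every member once as the focal
#' individual, carrying their own covariates, their own height
#' (\code{own_height}) and their partner's height (\code{partner_height},
#' the mate-choice trait).
#'
#' @param phenos phenotype data.frame.
#' @param couples couple table.
#' @return data.frame of 2 x nrow(couples) focal records.
#' @export
focalRecords <- function(phenos, couples) {
  idx <- setNames(seq_len(nrow(phenos)), phenos$sample_id)
  fi <- idx[couples$female_id]; mi <- idx[couples$male_id]
  stopIf(anyNA(fi) || anyNA(mi), "couple member absent from phenotype table")
  foc <- rbind(phenos[fi, , drop = FALSE], phenos[mi, , drop = FALSE])
  foc$own_height <- foc$height
  foc$partner_height <- c(phenos$height[mi], phenos$height[fi])
  rownames(foc) <- NULL
  foc
}

# align a GRM (and optional eigen decomposition) to a set of sample ids
.subsetGRM <- function(grm, ids) {
  A <- grmMatrix(grm)
  stopIf(!all(ids %in% rownames(A)), "sample absent from the GRM")
  new("GRMatrix", grm = A[ids, ids], nMarkers = nMarkers(grm))
}

#' Univariate GREML of mate-height choice
#'
#' Fits partner height, treated as the focal individual's own trait, on all
#' focal individuals (both members of every couple), with the configured
#' fixed effects.
#'
#' @param phenos,couples the cohort.
#' @param grm \linkS4class{GRMatrix} covering all couple members.
#' @param covariates fixed-effect column names (intercept always included).
#' @param ... passed to [fitUnivariateGREML()].
#' @return a \linkS4class{UnivariateGREML}.
#' @export
runMateChoiceUnivariate <- function(phenos, couples, grm,
                                    covariates = "sex", ...) {
  foc <- focalRecords(phenos, couples)
  X <- buildDesign(foc, covariates)
  A <- .subsetGRM(grm, foc$sample_id)
  fitUnivariateGREML(foc$partner_height, X, A, ...)
}

#' Bivariate GREML of own height and mate-height choice
#'
#' Joint fit of (own height, partner height) on the focal records, sharing
#' one GRM (every individual carries both traits, so all three genetic
#' relationship blocks coincide and the residual overlap map is the
#' identity).
#'
#' @inheritParams runMateChoiceUnivariate
#' @param ... passed to [fitBivariateGREML()].
#' @return a \linkS4class{BivariateGREML}.
#' @export
runMateChoiceBivariate <- function(phenos, couples, grm,
                                   covariates = "sex", ...) {
  foc <- focalRecords(phenos, couples)
  X <- buildDesign(foc, covariates)
  A <- .subsetGRM(grm, foc$sample_id)
  fitBivariateGREML(foc$own_height, foc$partner_height, X, X, A, ...)
}

#' Format a bivariate mate-choice fit as the five-row summary table
#'
#' @param fit a \linkS4class{BivariateGREML} from
#'   [runMateChoiceBivariate()].
#' @return data.frame with rows h2_Height, h2_Height_choice, r_G, r_E, r_P
#'   and columns estimate, se.
#' @export
bivariateSummaryTable <- function(fit) {
  data.frame(
    row.names = c("h2_Height", "h2_Height_choice", "r_G", "r_E", "r_P"),
    estimate = c(fit@h2[1], fit@h2[2], fit@rG, fit@rE, fit@rP),
    se = c(fit@seH2[1], fit@seH2[2], fit@seRG, fit@seRE, fit@seRP))
}

#' Predict partner height from the focal individual's genotype
#'
#' Computes the BLUP additive effect for own height of holdout individuals
#' from a training-set fit, and correlates this polygenic score with the
#' holdout partners' measured heights. The holdout genotypes are
#' standardized with the training allele frequencies; the holdout partners
#' must not be part of the training GRM.
#'
#' @param fit \linkS4class{UnivariateGREML} of own height on the training
#'   set.
#' @param zTrain \linkS4class{StandardizedGenotypes} (or matrix) of the
#'   training samples, the ones the fit used.
#' @param yTrain,XTrain training response and design.
#' @param zHoldout standardized genotypes of the holdout (genotyped) members,
#'   standardized with the training frequencies.
#' @param partnerHeight heights of the holdout members' partners.
#' @param h2Choice heritability of mate-height choice used for the
#'   theoretical-maximum denominator \eqn{\sqrt{h^2_{choice}}}.
#' @return named vector \code{c(accuracy, ratio_to_max)}; the ratio is on
#'   the percent scale.
#' @export
predictPartnerHeight <- function(fit, zTrain, yTrain, XTrain, zHoldout,
                                 partnerHeight, h2Choice) {
  if (is(zTrain, "StandardizedGenotypes")) zTrain <- zTrain@z
  if (is(zHoldout, "StandardizedGenotypes")) zHoldout <- zHoldout@z
  stopIf(fit@sigmaG2 <= 0, "training fit has zero genetic variance; ",
         "the polygenic score is undefined")
  M <- ncol(zTrain)
  resid <- drop(yTrain - as.matrix(XTrain) %*% fit@beta)
  V <- tcrossprod(zTrain) / M * fit@sigmaG2 + diag(fit@sigmaE2, length(yTrain))
  # g_new = sigma_g^2 A_{new,train} V^{-1} resid with A_{new,train} = Zh Zt'/M
  w <- solve(V, resid)
  g <- fit@sigmaG2 * drop(zHoldout %*% crossprod(zTrain, w)) / M
  stopIf(sd(g) == 0, "zero-variance polygenic score")
  acc <- cor(g, partnerHeight)
  c(accuracy = acc, ratio_to_max = 100 * acc / sqrt(h2Choice))
}

#' Greedy unrelated subset of a GRM
#'
#' Iteratively drops the sample with the largest number of relatedness ties
#' above \code{rMax} until no pair exceeds the ceiling.
#'
#' @param grm a \linkS4class{GRMatrix}.
#' @param rMax relatedness ceiling, default 0.0625.
#' @return character vector of retained sample ids.
#' @export
unrelatedSubset <- function(grm, rMax = 0.0625) {
  A <- grmMatrix(grm)
  diag(A) <- 0
  keep <- rep(TRUE, nrow(A))
  repeat {
    ties <- rowSums(A[keep, keep, drop = FALSE] > rMax)
    if (!length(ties) || max(ties) == 0L) break
    worst <- names(ties)[which.max(ties)]
    keep[match(worst, rownames(A))] <- FALSE
  }
  rownames(A)[keep]
}

#' Correlation of GWAS effects for height and mate-height choice
#'
#' On the unrelated focal subset, runs two single-marker association scans —
#' one for own height, one for partner height — with the covariates
#' projected out of both the phenotype and each SNP (ordinary least
#' squares), and returns the Pearson correlation of the two per-SNP effect
#' vectors.
#'
#' @param geno \linkS4class{GenotypeData} of the focal individuals.
#' @param phenos,couples the cohort.
#' @param grm \linkS4class{GRMatrix} for the relatedness screen.
#' @param covariates fixed-effect column names.
#' @param rMax relatedness ceiling for the unrelated subset.
#' @return Pearson correlation of per-SNP effects across traits.
#' @export
gwasEffectCorrelation <- function(geno, phenos, couples, grm,
                                  covariates = "sex", rMax = 0.0625) {
  foc <- focalRecords(phenos, couples)
  unrel <- unrelatedSubset(.subsetGRM(grm, foc$sample_id), rMax)
  foc <- foc[foc$sample_id %in% unrel, , drop = FALSE]
  X <- buildDesign(foc, covariates)
  dos <- dosages(geno)[foc$sample_id, , drop = FALSE]
  for (j in seq_len(ncol(dos))) {
    na <- is.na(dos[, j])
    if (any(na)) dos[na, j] <- mean(dos[, j], na.rm = TRUE)
  }
  Q <- qr(X)
  ry1 <- qr.resid(Q, foc$own_height)
  ry2 <- qr.resid(Q, foc$partner_height)
  rx <- qr.resid(Q, dos)
  xx <- colSums(rx^2)
  xx[xx == 0] <- NA
  b1 <- colSums(rx * ry1) / xx
  b2 <- colSums(rx * ry2) / xx
  cor(b1, b2, use = "complete.obs")
}

#' Run the full mate-choice analysis on a synthetic cohort
#'
#' Simulation, genotype/sample/phenotype QC, GRM and principal components
#' (PCA on the GRM of an LD-pruned marker set), couple identification and
#' relatedness filtering, univariate and bivariate mate-choice GREML,
#' partner-height prediction on a held-out couple fraction, the couple-swap
#' permutation diagnostics, the GWAS effect correlation, and the closed-form
#' theory quantities evaluated at the realized cohort parameters. Fully
#' reproducible from \code{params@seed}.
#'
#' @param params a \linkS4class{SimParams}.
#' @param covariates fixed-effect columns for the GREML fits (PCs are added
#'   when \code{nPCs > 0}).
#' @param nPCs number of genomic PCs to include as fixed effects.
#' @param holdoutFraction fraction of couples held out for prediction.
#' @param nPerm permutations for the covariate dependence tests.
#' @return named list: \code{params}, \code{qc} (reports), \code{grm},
#'   \code{pcs}, \code{couples}, \code{realizedRp}, \code{univariate},
#'   \code{bivariate}, \code{bivariateTable}, \code{prediction},
#'   \code{permutation}, \code{gwasEffectCor}, \code{theory}.
#' @export
runFullPipeline <- function(params, covariates = c("sex", "age", "townsend"),
                            nPCs = 20L, holdoutFraction = 0.2,
                            nPerm = 200L) {
  cohort <- simulateCohort(params)
  geno <- cohort$geno
  phenos <- cohort$phenos

  sq <- snpQC(geno)
  smq <- sampleQC(sq$geno)
  geno <- smq$geno
  phq <- phenotypeOutlierFilter(phenos[phenos$sample_id %in%
                                         sampleIds(geno), , drop = FALSE])
  phenos <- phq$phenos

  geno <- geno[, colnames(geno) %in% phenos$sample_id]
  Z <- standardizeGenotypes(geno)
  grm <- computeGRM(Z)

  pruned <- ldPrune(geno)
  grmPruned <- computeGRM(standardizeGenotypes(geno[pruned, ]))
  k <- min(nPCs, ncol(geno) - 1L)
  pcs <- grmPCA(grmPruned, k = k)
  core <- ethnicCoreFilter(pcs, setNames(rep("white_british", ncol(geno)),
                                         sampleIds(geno)))
  phenos <- phenos[phenos$sample_id %in% core, , drop = FALSE]

  couples <- identifyCouples(phenos)
  couples <- coupleRelatednessFilter(couples, grm)
  stopIf(nrow(couples) < 10L, "pipeline aborted at couple identification: ",
         "fewer than 10 couples survive filtering")

  pcdf <- as.data.frame(pcs@vectors)
  pcdf$sample_id <- rownames(pcs@vectors)
  phenos <- merge(phenos, pcdf, by = "sample_id", sort = FALSE)
  covs <- c(covariates, if (k > 0) paste0("PC", seq_len(k)))

  idx <- setNames(seq_len(nrow(phenos)), phenos$sample_id)
  realizedRp <- cor(phenos$height[idx[couples$female_id]],
                    phenos$height[idx[couples$male_id]])

  set.seed(childSeed(params@seed, 505L))
  nHold <- max(1L, round(holdoutFraction * nrow(couples)))
  holdIdx <- sample.int(nrow(couples), nHold)
  train <- couples[-holdIdx, , drop = FALSE]
  hold <- couples[holdIdx, , drop = FALSE]

  uni <- runMateChoiceUnivariate(phenos, train, grm, covariates = covs)
  bi <- runMateChoiceBivariate(phenos, train, grm, covariates = covs)

  # own-height fit on the training females for partner prediction
  trainIds <- phenos$sample_id[idx[train$female_id]]
  trainPh <- phenos[match(trainIds, phenos$sample_id), , drop = FALSE]
  Xtr <- buildDesign(trainPh, setdiff(covs, "sex"))
  ztr <- Z@z[trainIds, , drop = FALSE]
  Atr <- .subsetGRM(grm, trainIds)
  ownFit <- fitUnivariateGREML(trainPh$height, Xtr, Atr)
  zho <- Z@z[hold$female_id, , drop = FALSE]
  partnerH <- phenos$height[idx[hold$male_id]]
  pred <- predictPartnerHeight(ownFit, ztr, trainPh$height, Xtr, zho,
                               partnerH, h2Choice = max(uni@h2, 1e-6))

  sw <- swapMales(couples, phenos)
  depCovs <- intersect(c("age", "townsend", "birth_east", "birth_north"),
                       names(phenos))
  depObs <- covariateDependenceTests(sw$original, phenos, depCovs,
                                     nPerm = nPerm,
                                     seed = childSeed(params@seed, 606L))
  depSwap <- covariateDependenceTests(sw$permuted, phenos, depCovs,
                                      nPerm = nPerm,
                                      seed = childSeed(params@seed, 707L))
  regObs <- relatednessDistanceRegression(sw$original, grm, phenos)
  regSwap <- relatednessDistanceRegression(sw$permuted, grm, phenos)

  gwasCor <- gwasEffectCorrelation(geno, phenos, couples, grm,
                                   covariates = covs)

  h2Own <- bi@h2[1]
  m <- expectedBreedingValueCorrelation(realizedRp, h2Own)
  theory <- theoryTable(h2Own, m, realizedRp)

  list(params = params,
       qc = list(snp = sq$report, sample = smq$report, phenotype = phq$report),
       grm = grm, pcs = pcs, couples = couples, realizedRp = realizedRp,
       univariate = uni, bivariate = bi,
       bivariateTable = bivariateSummaryTable(bi),
       prediction = pred,
       permutation = list(swap = sw$mapping, dependenceObserved = depObs,
                          dependenceSwapped = depSwap,
                          relatednessDistanceObserved = regObs,
                          relatednessDistanceSwapped = regSwap),
       gwasEffectCor = gwasCor,
       theory = theory)
}

#' Replicate mate-choice heritability estimation over synthetic cohorts
#'
#' For each seed: simulate a cohort (genotypes, heights, noisy-rank couple
#' formation), build the GRM over all couple members, and fit the univariate
#' GREML of partner height with sex as fixed effect on all focal
#' individuals. This is the simulation counterpart of the headline
#' mate-choice heritability estimate; under phenotype-driven assortment the
#' estimates average close to \eqn{r_p^2 h^2}.
#'
#' @param seeds integer vector of simulation seeds, one replicate each.
#' @param nCouples,nSnps,h2Height,targetRp generating conditions (defaults:
#'   2,000 couples, 5,000 SNPs, own-height SNP heritability 0.60, couple
#'   height correlation 0.26).
#' @return data.frame with one row per replicate: seed, h2, se, realizedRp.
#' @export
mateChoiceH2Replicates <- function(seeds, nCouples = 2000L, nSnps = 5000L,
                                   h2Height = 0.6, targetRp = 0.26) {
  out <- data.frame()
  for (s in seeds) {
    par <- simParams(nCouples = nCouples, nSnps = nSnps,
                     h2Height = h2Height, targetRp = targetRp, seed = s)
    geno <- simulateGenotypes(par)
    phenos <- simulateHeights(geno, par)
    couples <- formCouples(phenos, par)
    grm <- computeGRM(standardizeGenotypes(geno))
    fit <- runMateChoiceUnivariate(phenos, couples, grm, covariates = "sex")
    idx <- setNames(seq_len(nrow(phenos)), phenos$sample_id)
    rp <- cor(phenos$height[idx[couples$female_id]],
              phenos$height[idx[couples$male_id]])
    out <- rbind(out, data.frame(seed = s, h2 = fit@h2, se = fit@seH2,
                                 realizedRp = rp))
    rm(geno, phenos, couples, grm, fit)
    gc(verbose = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Correlation of mates' true breeding values in a synthetic cohort
#'
#' Simulates couples at the given heritability and target couple
#' correlation and returns the Pearson correlation between the female and
#' male partners' latent additive genetic values, together with the
#' realized couple height correlation. Expected value under phenotypic
#' assortment: \eqn{r_p h^2}.
#'
#' @param nCouples,nSnps,h2Height,targetRp generating conditions.
#' @param seed simulation seed.
#' @return named vector \code{c(breedingValueCor, realizedRp)}.
#' @export
breedingValueCorrelation <- function(nCouples = 10000L, nSnps = 500L,
                                     h2Height = 0.8, targetRp = 0.26,
                                     seed = 1L) {
  par <- simParams(nCouples = nCouples, nSnps = nSnps, h2Height = h2Height,
                   targetRp = targetRp, seed = seed)
  geno <- simulateGenotypes(par)
  phenos <- simulateHeights(geno, par)
  couples <- formCouples(phenos, par)
  idx <- setNames(seq_len(nrow(phenos)), phenos$sample_id)
  fi <- idx[couples$female_id]; mi <- idx[couples$male_id]
  c(breedingValueCor = cor(phenos$additive[fi], phenos$additive[mi]),
    realizedRp = cor(phenos$height[fi], phenos$height[mi]))
}
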