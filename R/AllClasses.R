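#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats var cor sd rnorm rbinom runif setNames coef lm pchisq
#'   pnorm pt qnorm dhyper fisher.test cor.test model.matrix quantile
#'   complete.cases rmultinom
#' @importFrom utils head read.table write.table
NULL

#' Simulation parameters for a synthetic assortatively-mating cohort
#'
#' Container for every knob of the synthetic cohort generator: cohort and
#' marker panel size, allele-frequency bounds, the additive architecture of
#' height, the strength of phenotype-driven assortment, and the structured
#' covariates (household, geography, age, deprivation) that the couple-swap
#' permutation is designed to destroy.
#'
#' @slot nCouples number of male-female couples to simulate.
#' @slot nSnps number of biallelic autosomal SNPs.
#' @slot mafLow,mafHigh allele-frequency bounds, drawn per SNP from
#'   \code{Uniform(mafLow, mafHigh)}; both must lie in (0, 0.5].
#' @slot h2Height narrow-sense heritability of height in [0, 1].
#' @slot causalFraction fraction of SNPs with nonzero additive effect, (0, 1].
#' @slot targetRp desired within-couple height correlation in [0, 1).
#' @slot sexMeanShift mean height advantage of males, cm.
#' @slot heightSD within-sex phenotypic standard deviation of height, cm.
#' @slot geoClusters number of birthplace clusters.
#' @slot ageCorr within-couple age correlation.
#' @slot missingRate per-genotype missingness rate (default 0), used to
#'   exercise quality control.
#' @slot seed integer seed; all randomness in the generator flows from it.
#'
#' @seealso [simParams()], [simulateCohort()]
#' @export
setClass("SimParams", representation(
  nCouples = "integer", nSnps = "integer",
  mafLow = "numeric", mafHigh = "numeric",
  h2Height = "numeric", causalFraction = "numeric",
  targetRp = "numeric", sexMeanShift = "numeric", heightSD = "numeric",
  geoClusters = "integer", ageCorr = "numeric",
  missingRate = "numeric", seed = "integer"
))

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@nCouples < 1L) msg <- c(msg, "nCouples must be >= 1")
  if (object@nSnps < 1L) msg <- c(msg, "nSnps must be >= 1")
  if (!(object@mafLow > 0 && object@mafLow <= object@mafHigh &&
        object@mafHigh <= 0.5))
    msg <- c(msg, "require 0 < mafLow <= mafHigh <= 0.5")
  if (object@h2Height < 0 || object@h2Height > 1)
    msg <- c(msg, "h2Height must lie in [0, 1]")
  if (object@causalFraction <= 0 || object@causalFraction > 1)
    msg <- c(msg, "causalFraction must lie in (0, 1]")
  if (object@targetRp < 0 || object@targetRp >= 1)
    msg <- c(msg, "targetRp must lie in [0, 1)")
  if (object@ageCorr < -1 || object@ageCorr > 1)
    msg <- c(msg, "ageCorr must lie in [-1, 1]")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Genotype matrix with SNP and sample annotation
#'
#' A \linkS4class{SummarizedExperiment} holding one assay, \code{"dosage"}:
#' SNPs as rows, samples as columns, values in \{0, 1, 2, NA\} counting copies
#' of the A1 allele. \code{rowData} carries per-SNP chromosome, position,
#' alleles and generating allele frequency; \code{colData} carries the
#' per-sample genotyping platform label.
#'
#' @seealso [simulateGenotypes()], [dosages()], [snpInfo()]
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    return("dosage values must be 0, 1, 2 or NA")
  if (anyDuplicated(colnames(object)))
    return("sample ids must be unique")
  TRUE
})

#' Column-standardized genotypes
#'
#' Genotypes transformed to z = (dosage - 2p) / sqrt(2 p (1 - p)) with p the
#' sample allele frequency; missing dosages are mean-imputed to z = 0.
#' Samples are rows here (the orientation of the GRM algebra Z Z'/M).
#'
#' @slot z numeric samples x SNPs matrix.
#' @slot freqs allele frequencies used for centering and scaling.
#' @export
setClass("StandardizedGenotypes",
         representation(z = "matrix", freqs = "numeric"))

setValidity("StandardizedGenotypes", function(object) {
  if (ncol(object@z) != length(object@freqs))
    return("one frequency per SNP column required")
  TRUE
})

#' Genomic relationship matrix
#'
#' Realized genetic similarity A = Z Z' / M among samples, with Z the
#' column-standardized genotypes and M the marker count.
#'
#' @slot grm symmetric samples x samples matrix with sample ids as dimnames.
#' @slot nMarkers number of markers M used.
#' @export
setClass("GRMatrix", representation(grm = "matrix", nMarkers = "integer"))

setValidity("GRMatrix", function(object) {
  A <- object@grm
  if (nrow(A) != ncol(A)) return("GRM must be square")
  if (is.null(rownames(A)) || !identical(rownames(A), colnames(A)))
    return("GRM needs matching row/column sample ids")
  if (max(abs(A - t(A))) > 1e-8) return("GRM must be symmetric")
  TRUE
})

#' Principal components of a genomic relationship matrix
#'
#' @slot values eigenvalues, non-increasing.
#' @slot vectors orthonormal eigenvectors (samples x k), sample ids as
#'   rownames; the sign of each vector is fixed so its largest-magnitude
#'   loading is positive.
#' @export
setClass("GenomicPCs", representation(values = "numeric", vectors = "matrix"))

setValidity("GenomicPCs", function(object) {
  if (length(object@values) != ncol(object@vectors))
    return("one eigenvalue per eigenvector required")
  if (is.unsorted(rev(object@values)))
    return("eigenvalues must be non-increasing")
  TRUE
})

#' Quality-control report
#'
#' @slot step label of the QC stage.
#' @slot counts data.frame with one row per filter: \code{filter},
#'   \code{n_input}, \code{n_excluded}, \code{n_retained}.
#' @slot kept ids surviving the stage.
#' @export
setClass("QCReport", representation(step = "character", counts = "data.frame",
                                    kept = "character"))

setValidity("QCReport", function(object) {
  cts <- object@counts
  need <- c("filter", "n_input", "n_excluded", "n_retained")
  if (!all(need %in% names(cts))) return("counts must have filter/n_* columns")
  if (nrow(cts) && any(cts$n_input != cts$n_excluded + cts$n_retained))
    return("excluded + retained must equal input for every filter")
  TRUE
})

#' Univariate GREML fit
#'
#' REML estimates of the genetic and residual variance for a single trait
#' under var(y) = A sigma_g^2 + I sigma_e^2, with fixed effects estimated by
#' generalized least squares at the fitted variances.
#'
#' @slot sigmaG2,sigmaE2 variance-component estimates.
#' @slot h2 sigmaG2 / (sigmaG2 + sigmaE2).
#' @slot seH2 delta-method standard error of h2 from the inverse
#'   average-information matrix.
#' @slot vcov 2x2 asymptotic covariance of (sigmaG2, sigmaE2).
#' @slot beta fixed-effect estimates (GLS).
#' @slot loglik restricted log-likelihood trace, one entry per iteration.
#' @slot nIter iterations used.
#' @slot converged logical convergence flag.
#' @slot n,M sample and marker counts (M is 0 when the GRM's marker count is
#'   unknown; sigma_u^2 = sigmaG2 / M needs M > 0).
#' @export
setClass("UnivariateGREML", representation(
  sigmaG2 = "numeric", sigmaE2 = "numeric", h2 = "numeric", seH2 = "numeric",
  vcov = "matrix", beta = "numeric", loglik = "numeric", nIter = "integer",
  converged = "logical", n = "integer", M = "integer"
))

#' Bivariate GREML fit
#'
#' REML estimates of the six (co)variance components of a two-trait mixed
#' model with genetic covariance structure A_12 sigma_g1g2 and residual
#' covariance applied over the trait-overlap map, plus the derived genetic,
#' environmental and phenotypic correlations.
#'
#' @slot varcomp named vector (sigmaG1, sigmaG2, sigmaG12, sigmaE1, sigmaE2,
#'   sigmaE12).
#' @slot vcov 6x6 asymptotic covariance from the inverse average-information
#'   matrix.
#' @slot rG,rE,rP correlations derived from the components.
#' @slot seRG,seRE,seRP delta-method standard errors.
#' @slot h2 per-trait heritabilities (length 2) with \code{seH2}.
#' @slot beta1,beta2 fixed-effect estimates per trait.
#' @slot loglik restricted log-likelihood trace.
#' @slot nIter,converged iteration count and convergence flag.
#' @export
setClass("BivariateGREML", representation(
  varcomp = "numeric", vcov = "matrix",
  rG = "numeric", rE = "numeric", rP = "numeric",
  seRG = "numeric", seRE = "numeric", seRP = "numeric",
  h2 = "numeric", seH2 = "numeric",
  beta1 = "numeric", beta2 = "numeric",
  loglik = "numeric", nIter = "integer", converged = "logical"
))
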