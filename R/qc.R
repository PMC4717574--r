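#' Quality-control thresholds
#'
#' Defaults are the filters used throughout the analysis: SNPs are dropped at
#' overall missingness > 2 %, platform-specific missingness bias with Fisher
#' exact p < 1e-100, Hardy-Weinberg exact p < 1e-50, or minor allele
#' frequency < 0.05; samples are dropped at missingness > 5 % or an autosomal
#' heterozygosity rate more than 3 SD from the sample mean; phenotypes more
#' than 3 SD from their gender mean are removed.
#'
#' @param snpMissingMax,platformFisherPMin,hwePMin,mafMin,sampleMissingMax,hetSdMax,phenoSdMax
#'   see description.
#' @return named list of thresholds.
#' @export
qcThresholds <- function(snpMissingMax = 0.02, platformFisherPMin = 1e-100,
                         hwePMin = 1e-50, mafMin = 0.05,
                         sampleMissingMax = 0.05, hetSdMax = 3,
                         phenoSdMax = 3) {
  th <- list(snpMissingMax = snpMissingMax,
             platformFisherPMin = platformFisherPMin,
             hwePMin = hwePMin, mafMin = mafMin,
             sampleMissingMax = sampleMissingMax, hetSdMax = hetSdMax,
             phenoSdMax = phenoSdMax)
  probs <- unlist(th[c("snpMissingMax", "platformFisherPMin", "hwePMin",
                       "mafMin", "sampleMissingMax")])
  stopIf(any(probs < 0 | probs > 1), "probability thresholds must be in [0,1]")
  stopIf(hetSdMax <= 0 || phenoSdMax <= 0, "SD thresholds must be positive")
  th
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, enumerates every possible
#' heterozygote count of matching parity, computes its probability under
#' random union of gametes in log space (stable down to the p < 1e-50
#' regime), and sums the probabilities not exceeding that of the observed
#' configuration. No mid-p correction is applied.
#'
#' @param nAA,nAa,naa genotype counts.
#' @return two-sided exact p-value in [0, 1]; a monomorphic site returns 1.
#' @examples
#' hweExactTest(25, 50, 25)   # close to HWE proportions
#' hweExactTest(50, 0, 50)    # extreme heterozygote deficit
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  stopIf(any(c(nAA, nAa, naa) < 0), "genotype counts must be non-negative")
  n <- nAA + nAa + naa
  stopIf(n == 0, "all genotype counts are zero")
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  # heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(nAa = h | allele counts) up to a common constant:
  #   n! / (nAA! nAa! naa!) * 2^nAa / C(2n, nA)
  hAA <- (nA - hets) / 2
  haa <- (na - hets) / 2
  logp <- hets * log(2) - lgamma(hAA + 1) - lgamma(hets + 1) - lgamma(haa + 1)
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  pObs <- pr[match(nAa, hets)]
  min(1, sum(pr[pr <= pObs * (1 + 1e-12)]))
}

#' Fisher exact test for platform-specific missingness bias
#'
#' Two-sided Fisher exact test on the 2x2 table of (missing, genotyped) by
#' genotyping platform for one SNP.
#'
#' @param miss1,ok1 missing and genotyped counts on platform 1.
#' @param miss2,ok2 same for platform 2.
#' @return two-sided p-value.
#' @export
platformMissingnessTest <- function(miss1, ok1, miss2, ok2) {
  counts <- c(miss1, ok1, miss2, ok2)
  stopIf(any(counts < 0), "counts must be non-negative")
  stopIf(miss1 + ok1 == 0 || miss2 + ok2 == 0,
         "both platforms must have samples")
  if (miss1 + miss2 == 0 || ok1 + ok2 == 0) return(1)
  fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
}

#' SNP-level quality control
#'
#' Applies, in order: overall missingness, platform missingness bias,
#' Hardy-Weinberg exact test, and minor allele frequency (computed on the
#' analysis subset, i.e. the samples present in \code{geno}). The order of
#' surviving SNPs is preserved and their dosages are unchanged.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param thresholds from [qcThresholds()].
#' @return list with elements \code{geno} (filtered) and \code{report}
#'   (\linkS4class{QCReport}).
#' @export
snpQC <- function(geno, thresholds = qcThresholds()) {
  dos <- SummarizedExperiment::assay(geno, "dosage")  # SNPs x samples
  m0 <- nrow(dos)
  stopIf(m0 == 0, "empty genotype matrix")
  counts <- data.frame()
  keep <- rep(TRUE, m0)

  missRate <- rowMeans(is.na(dos))
  fail <- keep & missRate > thresholds$snpMissingMax
  counts <- rbind(counts, qcCountsRow("snp_missingness", sum(keep), sum(fail)))
  keep <- keep & !fail

  platform <- SummarizedExperiment::colData(geno)$platform
  fail <- rep(FALSE, m0)
  if (length(unique(platform)) == 2L) {
    pl <- platform == unique(platform)[1]
    for (j in which(keep & missRate > 0)) {
      na <- is.na(dos[j, ])
      p <- platformMissingnessTest(sum(na & pl), sum(!na & pl),
                                   sum(na & !pl), sum(!na & !pl))
      if (p < thresholds$platformFisherPMin) fail[j] <- TRUE
    }
  }
  counts <- rbind(counts, qcCountsRow("platform_bias", sum(keep), sum(fail & keep)))
  keep <- keep & !fail

  fail <- rep(FALSE, m0)
  for (j in which(keep)) {
    g <- dos[j, ]
    g <- g[!is.na(g)]
    p <- hweExactTest(sum(g == 2), sum(g == 1), sum(g == 0))
    if (p < thresholds$hwePMin) fail[j] <- TRUE
  }
  counts <- rbind(counts, qcCountsRow("hwe", sum(keep), sum(fail & keep)))
  keep <- keep & !fail

  freq <- rowMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  fail <- keep & (is.na(maf) | maf < thresholds$mafMin)
  counts <- rbind(counts, qcCountsRow("maf", sum(keep), sum(fail)))
  keep <- keep & !fail

  if (!any(keep)) warning("no SNPs survive QC")
  out <- geno[keep, ]
  list(geno = out,
       report = makeQCReport("snp_qc", counts, rownames(out)))
}

#' Sample-level quality control
#'
#' Removes samples whose genotype missingness exceeds
#' \code{sampleMissingMax} and samples whose autosomal heterozygosity rate
#' lies more than \code{hetSdMax} SDs from the sample mean (both directions;
#' excess heterozygosity indicates contamination, a strong deficit
#' inbreeding or genotyping failure).
#'
#' @inheritParams snpQC
#' @return list with \code{geno} and \code{report}.
#' @export
sampleQC <- function(geno, thresholds = qcThresholds()) {
  dos <- SummarizedExperiment::assay(geno, "dosage")
  n0 <- ncol(dos)
  stopIf(n0 == 0, "empty genotype matrix")
  counts <- data.frame()
  keep <- rep(TRUE, n0)

  missRate <- colMeans(is.na(dos))
  fail <- missRate > thresholds$sampleMissingMax
  counts <- rbind(counts, qcCountsRow("sample_missingness", n0, sum(fail)))
  keep <- keep & !fail

  het <- colMeans(dos == 1, na.rm = TRUE)
  mu <- mean(het[keep]); s <- sd(het[keep])
  fail <- rep(FALSE, n0)
  if (is.finite(s) && s > 0)
    fail <- keep & abs(het - mu) > thresholds$hetSdMax * s
  counts <- rbind(counts, qcCountsRow("heterozygosity", sum(keep), sum(fail)))
  keep <- keep & !fail

  out <- geno[, keep]
  list(geno = out,
       report = makeQCReport("sample_qc", counts, colnames(out)))
}

#' Remove height outliers per gender
#'
#' Single pass: gender means and SDs are computed on the input set, and
#' records strictly more than \code{sdMax} SD from their own gender mean are
#' removed. A gender with fewer than two records is passed through unchanged
#' with a warning (its SD is undefined).
#'
#' @param phenos phenotype data.frame with \code{sex} and \code{height}.
#' @param sdMax SD cut, default 3.
#' @return list with \code{phenos} (filtered) and \code{report}.
#' @export
phenotypeOutlierFilter <- function(phenos, sdMax = 3) {
  stopifnot(all(c("sex", "height") %in% names(phenos)))
  n0 <- nrow(phenos)
  keep <- rep(TRUE, n0)
  for (s in unique(phenos$sex)) {
    i <- which(phenos$sex == s)
    if (length(i) < 2L) {
      warning("gender '", s, "' has fewer than 2 records; not filtered")
      next
    }
    z <- abs(phenos$height[i] - mean(phenos$height[i])) / sd(phenos$height[i])
    keep[i] <- z <= sdMax
  }
  counts <- qcCountsRow("height_outlier", n0, sum(!keep))
  list(phenos = phenos[keep, , drop = FALSE],
       report = makeQCReport("phenotype_qc", counts,
                             phenos$sample_id[keep] %||% which(keep)))
}
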