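#' Standardize genotypes by sample allele frequency
#'
#' z = (dosage - 2 p) / sqrt(2 p (1 - p)) with p the sample allele frequency
#' of the A1 allele; missing dosages are set to 0 after centering, i.e.
#' imputed at the mean. Monomorphic SNPs cannot be standardized and raise an
#' error naming the offending SNP.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @return a \linkS4class{StandardizedGenotypes} (samples x SNPs).
#' @export
standardizeGenotypes <- function(geno) {
  dos <- dosages(geno)                       # samples x SNPs
  p <- colMeans(dos, na.rm = TRUE) / 2
  bad <- !is.finite(p) | p <= 0 | p >= 1
  stopIf(any(bad), "monomorphic or all-missing SNP(s): ",
         paste(head(colnames(dos)[bad], 5), collapse = ", "))
  z <- sweep(dos, 2L, 2 * p, "-")
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), "/")
  z[is.na(z)] <- 0
  new("StandardizedGenotypes", z = z, freqs = p)
}

#' Compute the genomic relationship matrix A = Z Z' / M
#'
#' @param Z a \linkS4class{StandardizedGenotypes}.
#' @return a \linkS4class{GRMatrix}; exact symmetry is enforced.
#' @export
computeGRM <- function(Z) {
  stopifnot(is(Z, "StandardizedGenotypes"))
  M <- ncol(Z@z)
  stopIf(M < 1, "at least one marker required")
  A <- tcrossprod(Z@z) / M
  A <- (A + t(A)) / 2
  dimnames(A) <- list(rownames(Z@z), rownames(Z@z))
  new("GRMatrix", grm = A, nMarkers = as.integer(M))
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of \code{window} SNPs (advanced by \code{step}), any
#' pair of retained SNPs with squared dosage correlation above \code{r2Max}
#' loses its later member. Deterministic: the earlier SNP is always kept.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param window window size in SNPs (>= 2), default 50.
#' @param step window increment, default 5.
#' @param r2Max squared-correlation threshold, default 0.2.
#' @return character vector of retained SNP ids, in input order.
#' @export
ldPrune <- function(geno, window = 50L, step = 5L, r2Max = 0.2) {
  stopIf(window < 2L, "window must be >= 2")
  dos <- dosages(geno)
  m <- ncol(dos)
  for (j in seq_len(m)) {
    na <- is.na(dos[, j])
    if (any(na)) dos[na, j] <- mean(dos[, j], na.rm = TRUE)
  }
  keep <- rep(TRUE, m)
  starts <- unique(c(seq(1L, max(1L, m - window + 1L), by = step)))
  for (s in starts) {
    idx <- s:min(s + window - 1L, m)
    idx <- idx[keep[idx]]
    if (length(idx) < 2L) next
    cc <- suppressWarnings(cor(dos[, idx, drop = FALSE]))
    cc[is.na(cc)] <- 0
    for (a in seq_along(idx)) {
      if (!keep[idx[a]]) next
      for (b in seq_along(idx)) {
        if (b <= a || !keep[idx[b]]) next
        if (cc[a, b]^2 > r2Max) keep[idx[b]] <- FALSE
      }
    }
  }
  colnames(dos)[keep]
}

#' Principal components of a GRM
#'
#' Top-k eigenpairs of the genomic relationship matrix. Eigenvectors are
#' unit-norm, mutually orthogonal, and sign-fixed so each vector's
#' largest-magnitude loading is positive.
#'
#' @param grm a \linkS4class{GRMatrix}.
#' @param k number of components, at most the sample count.
#' @return a \linkS4class{GenomicPCs}.
#' @export
grmPCA <- function(grm, k = 20L) {
  A <- grmMatrix(grm)
  n <- nrow(A)
  stopIf(k > n, "k must not exceed the sample count")
  e <- eigen(A, symmetric = TRUE)
  vals <- e$values[seq_len(k)]
  vecs <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- rownames(A)
  colnames(vecs) <- paste0("PC", seq_len(k))
  new("GenomicPCs", values = vals, vectors = vecs)
}

#' Retain the ethnically homogeneous core of the cohort
#'
#' Among samples whose self-reported label matches \code{label}, keeps those
#' whose projection on every one of the leading PCs lies within \code{sdMax}
#' standard deviations of that PC's mean (mean and SD computed on the
#' matching-label subset). Samples with a different self-report are excluded
#' regardless of their projections.
#'
#' @param pcs a \linkS4class{GenomicPCs} (computed with k = 20 in the default
#'   analysis).
#' @param selfReport character vector of self-reported labels, aligned with
#'   (or named by) the samples in \code{pcs}.
#' @param label the core label, default \code{"white_british"}.
#' @param sdMax per-PC SD cut, default 3.
#' @return character vector of retained sample ids.
#' @export
ethnicCoreFilter <- function(pcs, selfReport, label = "white_british",
                             sdMax = 3) {
  ids <- sampleIds(pcs)
  if (!is.null(names(selfReport))) selfReport <- selfReport[ids]
  stopIf(length(selfReport) != length(ids),
         "one self-report label per sample required")
  match_lab <- selfReport == label
  V <- pcs@vectors[match_lab, , drop = FALSE]
  mu <- colMeans(V)
  s <- apply(V, 2L, sd)
  s[s == 0] <- Inf
  z <- abs(sweep(sweep(V, 2L, mu, "-"), 2L, s, "/"))
  ok <- rowSums(z > sdMax) == 0L
  ids[match_lab][ok]
}

#' Drop couples more related than the relatedness ceiling
#'
#' Couples whose GRM relatedness is at or above \code{rMax} (default 0.0625,
#' first cousins once removed) are removed; couples with a member absent from
#' the GRM are dropped with a warning. Related individuals in different
#' households are unaffected (this filters couples, not samples).
#'
#' @param couples couple table.
#' @param grm a \linkS4class{GRMatrix}.
#' @param rMax relatedness ceiling, default 0.0625.
#' @return the couple table restricted to couples with r < rMax, with a
#'   \code{relatedness} column appended.
#' @export
coupleRelatednessFilter <- function(couples, grm, rMax = 0.0625) {
  A <- grmMatrix(grm)
  present <- couples$female_id %in% rownames(A) &
    couples$male_id %in% rownames(A)
  if (any(!present))
    warning(sum(!present), " couple(s) with a member absent from the GRM dropped")
  couples <- couples[present, , drop = FALSE]
  r <- A[cbind(match(couples$female_id, rownames(A)),
               match(couples$male_id, rownames(A)))]
  couples$relatedness <- r
  couples[r < rMax, , drop = FALSE]
}
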