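#' Accessors for AssortMate objects
#'
#' Small accessor family: \code{dosages} returns the samples x SNPs dosage
#' matrix of a \linkS4class{GenotypeData}; \code{snpInfo} its per-SNP
#' annotation; \code{sampleIds} the sample identifiers of genotype, GRM or PC
#' objects; \code{grmMatrix} and \code{nMarkers} the matrix and marker count
#' of a \linkS4class{GRMatrix}; \code{heritability} and
#' \code{varianceComponents} the estimates of a GREML fit.
#'
#' @param x,object an AssortMate S4 object.
#' @return See each method; accessors never expose slots for writing.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))

#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname accessors
#' @export
setGeneric("heritability", function(object) standardGeneric("heritability"))

#' @rdname accessors
#' @export
setGeneric("varianceComponents",
           function(object) standardGeneric("varianceComponents"))

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeData", function(x) {
  t(SummarizedExperiment::assay(x, "dosage"))
})

#' @rdname accessors
#' @export
setMethod("snpInfo", "GenotypeData", function(x) {
  SummarizedExperiment::rowData(x)
})

#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypeData", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("sampleIds", "GRMatrix", function(x) rownames(x@grm))

#' @rdname accessors
#' @export
setMethod("sampleIds", "GenomicPCs", function(x) rownames(x@vectors))

#' @rdname accessors
#' @export
setMethod("grmMatrix", "GRMatrix", function(x) x@grm)

#' @rdname accessors
#' @export
setMethod("nMarkers", "GRMatrix", function(x) x@nMarkers)

#' @rdname accessors
#' @export
setMethod("heritability", "UnivariateGREML", function(object) {
  c(h2 = object@h2, se = object@seH2)
})

#' @rdname accessors
#' @export
setMethod("heritability", "BivariateGREML", function(object) {
  setNames(c(object@h2, object@seH2),
           c("h2_trait1", "h2_trait2", "se_trait1", "se_trait2"))
})

#' @rdname accessors
#' @export
setMethod("varianceComponents", "UnivariateGREML", function(object) {
  c(sigmaG2 = object@sigmaG2, sigmaE2 = object@sigmaE2)
})

#' @rdname accessors
#' @export
setMethod("varianceComponents", "BivariateGREML", function(object) {
  object@varcomp
})

setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@nCouples, "couples x", object@nSnps, "SNPs\n")
  cat(sprintf("  MAF U(%.2f, %.2f), h2 = %.2f, causal fraction %.2f\n",
              object@mafLow, object@mafHigh, object@h2Height,
              object@causalFraction))
  cat(sprintf("  target couple correlation %.2f, seed %d\n",
              object@targetRp, object@seed))
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object), "SNPs x", ncol(object), "samples\n")
  d <- SummarizedExperiment::assay(object, "dosage")
  cat(sprintf("  missing rate %.4f\n", mean(is.na(d))))
})

setMethod("show", "GRMatrix", function(object) {
  cat("GRMatrix:", nrow(object@grm), "samples,", object@nMarkers, "markers\n")
  cat(sprintf("  diagonal mean %.3f\n", mean(diag(object@grm))))
})

setMethod("show", "GenomicPCs", function(object) {
  cat("GenomicPCs:", ncol(object@vectors), "components over",
      nrow(object@vectors), "samples\n")
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport [", object@step, "]\n", sep = "")
  print(object@counts, row.names = FALSE)
})

setMethod("show", "UnivariateGREML", function(object) {
  cat("Univariate GREML fit (n =", object@n, ")\n")
  cat(sprintf("  sigma_g^2 = %.4f  sigma_e^2 = %.4f\n",
              object@sigmaG2, object@sigmaE2))
  cat(sprintf("  h2 = %.4f (SE %.4f)\n", object@h2, object@seH2))
  cat(sprintf("  logLik %.4f after %d iterations; converged: %s\n",
              object@loglik[length(object@loglik)], object@nIter,
              object@converged))
})

setMethod("show", "BivariateGREML", function(object) {
  cat("Bivariate GREML fit\n")
  v <- object@varcomp
  cat(sprintf("  G: var1 %.4f var2 %.4f cov %.4f | E: var1 %.4f var2 %.4f cov %.4f\n",
              v["sigmaG1"], v["sigmaG2"], v["sigmaG12"],
              v["sigmaE1"], v["sigmaE2"], v["sigmaE12"]))
  cat(sprintf("  h2: %.4f (SE %.4f), %.4f (SE %.4f)\n",
              object@h2[1], object@seH2[1], object@h2[2], object@seH2[2]))
  cat(sprintf("  rG %.3f (SE %.3f)  rE %.3f (SE %.3f)  rP %.3f (SE %.3f)\n",
              object@rG, object@seRG, object@rE, object@seRE,
              object@rP, object@seRP))
  cat(sprintf("  converged: %s after %d iterations\n", object@converged,
              object@nIter))
})
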