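# GCTA binary GRM triple: <prefix>.grm.bin (float32 lower triangle, row-major,
# diagonal included), <prefix>.grm.N.bin (float32 marker counts, same order),
# <prefix>.grm.id (two-column FID IID text).

#' Write a GRM in GCTA binary format
#'
#' @param grm a \linkS4class{GRMatrix}.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
writeGRM <- function(grm, prefix) {
  A <- grmMatrix(grm)
  n <- nrow(A)
  lower <- A[upper.tri(A, diag = TRUE)]      # column-major upper == row-major lower
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4L)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(nMarkers(grm)), length(lower)), con, size = 4L)
  close(con)
  ids <- sampleIds(grm)
  write.table(data.frame(ids, ids), paste0(prefix, ".grm.id"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GRM from GCTA binary format
#'
#' @param prefix path prefix of a \code{.grm.bin/.grm.N.bin/.grm.id} triple.
#' @return a \linkS4class{GRMatrix}; the marker count is the rounded mean of
#'   the per-pair counts in \code{.grm.N.bin}.
#' @export
readGRM <- function(prefix) {
  ids <- read.table(paste0(prefix, ".grm.id"), header = FALSE,
                    stringsAsFactors = FALSE)$V2
  n <- length(ids)
  nPairs <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = nPairs, size = 4L)
  stopIf(length(vals) != nPairs, "truncated .grm.bin")
  Nvals <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = nPairs,
                   size = 4L)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[upper.tri(A, diag = TRUE)] <- vals
  A <- A + t(A) - diag(diag(A))
  new("GRMatrix", grm = A, nMarkers = as.integer(round(mean(Nvals))))
}
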