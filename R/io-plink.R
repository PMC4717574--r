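# PLINK 1 binary (.bed/.bim/.fam) and cohort TSV input/output.
#
# .bed layout (v1, SNP-major): magic bytes 0x6C 0x1B 0x01, then for each SNP
# ceiling(n/4) bytes, two bits per sample in sample order within each byte
# (least significant pair first): 00 = A1/A1 (dosage 2), 01 = missing,
# 10 = het, 11 = A2/A2 (dosage 0).

.bedMagic <- as.raw(c(0x6C, 0x1B, 0x01))

# dosage -> 2-bit code
.dosageToCode <- function(d) {
  code <- integer(length(d))
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 2] <- 0L
  code[!is.na(d) & d == 1] <- 2L
  code[!is.na(d) & d == 0] <- 3L
  code
}

# 256 x 4 lookup: dosage of each 2-bit field of a byte
.bedByteLookup <- local({
  tab <- matrix(NA_integer_, nrow = 256L, ncol = 4L)
  dec <- c(2L, NA_integer_, 1L, 0L)
  for (b in 0:255) {
    v <- b
    for (k in 1:4) {
      tab[b + 1L, k] <- dec[(v %% 4L) + 1L]
      v <- v %/% 4L
    }
  }
  tab
})

#' Write a synthetic cohort to PLINK binary plus TSV files
#'
#' Emits \code{<prefix>.bed} (SNP-major PLINK v1 binary), \code{.bim},
#' \code{.fam}, a phenotype table \code{<prefix>_phenotypes.tsv} (columns
#' IID, sex, age, height, townsend, household_id, birth_east, birth_north,
#' platform) and a couple table \code{<prefix>_couples.tsv} (household_id,
#' female_IID, male_IID). Reading the files back with [readCohort()]
#' round-trips the dosage matrix exactly.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param phenos phenotype data.frame covering the same samples.
#' @param couples couple table.
#' @param prefix output path prefix (directory must exist).
#' @return \code{prefix}, invisibly.
#' @export
writeCohort <- function(geno, phenos, couples, prefix) {
  stopIf(!setequal(sampleIds(geno), phenos$sample_id),
         "genotype and phenotype sample sets differ")
  stopIf(!all(c(couples$female_id, couples$male_id) %in% phenos$sample_id),
         "couple member absent from phenotype table")
  dir <- dirname(prefix)
  stopIf(!dir.exists(dir), "output directory does not exist: ", dir)

  dos <- dosages(geno)                    # samples x SNPs
  n <- nrow(dos); m <- ncol(dos)
  nBytes <- ceiling(n / 4)
  code <- matrix(.dosageToCode(dos), nrow = n)
  pad <- matrix(0L, nrow = 4L * nBytes, ncol = m)
  pad[seq_len(n), ] <- code
  dim(pad) <- c(4L, nBytes * m)
  bytes <- as.raw(pad[1L, ] + 4L * pad[2L, ] + 16L * pad[3L, ] + 64L * pad[4L, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(.bedMagic, con)
  writeBin(bytes, con)

  info <- as.data.frame(snpInfo(geno))
  bim <- data.frame(chrom = info$chrom, id = rownames(info), cm = 0,
                    pos = info$pos, a1 = info$a1, a2 = info$a2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  ord <- match(sampleIds(geno), phenos$sample_id)
  fam <- data.frame(fid = sampleIds(geno), iid = sampleIds(geno),
                    pat = 0, mat = 0,
                    sex = ifelse(phenos$sex[ord] == "male", 1L, 2L),
                    pheno = -9)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  platform <- SummarizedExperiment::colData(geno)$platform
  ptab <- data.frame(IID = phenos$sample_id, sex = phenos$sex,
                     age = phenos$age %||% NA, height = phenos$height,
                     townsend = phenos$townsend %||% NA,
                     household_id = phenos$household_id %||% NA,
                     birth_east = phenos$birth_east %||% NA,
                     birth_north = phenos$birth_north %||% NA,
                     platform = platform[match(phenos$sample_id,
                                               sampleIds(geno))])
  write.table(ptab, paste0(prefix, "_phenotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ctab <- data.frame(household_id = couples$household_id,
                     female_IID = couples$female_id,
                     male_IID = couples$male_id)
  write.table(ctab, paste0(prefix, "_couples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read PLINK binary genotypes
#'
#' @param prefix path prefix of a \code{.bed/.bim/.fam} triple.
#' @param platform optional per-sample platform labels (in .fam order);
#'   defaults to a single label.
#' @return a \linkS4class{GenotypeData}; rowData \code{freq} holds the sample
#'   allele frequency of A1 computed from the non-missing dosages.
#' @export
readPlink <- function(prefix, platform = NULL) {
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                    stringsAsFactors = FALSE)
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  nBytes <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3L + as.numeric(nBytes) * m)
  stopIf(length(raw) < 3L || !identical(raw[1:3], .bedMagic),
         "not a PLINK v1 SNP-major .bed file")
  body <- as.integer(raw[-(1:3)])
  stopIf(length(body) != nBytes * m, "truncated .bed file")
  # decode all bytes at once via the 256 x 4 lookup
  dec <- .bedByteLookup[body + 1L, , drop = FALSE]  # (nBytes*m) x 4
  dos <- matrix(t(dec), nrow = 4L * nBytes)[seq_len(n), , drop = FALSE]
  dim(dos) <- c(n, m)
  freq <- colMeans(dos, na.rm = TRUE) / 2
  rowData <- S4Vectors::DataFrame(chrom = bim$chrom, pos = bim$pos,
                                  a1 = bim$a1, a2 = bim$a2, freq = freq,
                                  row.names = bim$id)
  colData <- S4Vectors::DataFrame(
    platform = platform %||% rep("unknown", n), row.names = fam$V2)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = t(dos)), rowData = rowData, colData = colData)
  new("GenotypeData", se)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param prefix the prefix passed to [writeCohort()].
#' @return list with \code{geno}, \code{phenos}, \code{couples}.
#' @export
readCohort <- function(prefix) {
  phenos <- read.table(paste0(prefix, "_phenotypes.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
  couples <- read.table(paste0(prefix, "_couples.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
  names(couples)[names(couples) == "female_IID"] <- "female_id"
  names(couples)[names(couples) == "male_IID"] <- "male_id"
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  platform <- phenos$platform[match(fam$V2, phenos$IID)]
  geno <- readPlink(prefix, platform = platform)
  names(phenos)[names(phenos) == "IID"] <- "sample_id"
  list(geno = geno, phenos = phenos, couples = couples)
}
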