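#' Swap males between height-matched couples
#'
#' The permutation control: couples are sorted lexicographically by (female
#' height, male height) and the male partners of successive couples are
#' exchanged — male 1 with 2, 3 with 4, and so on; with an odd number of
#' couples the last sorted couple is left unchanged. Because successive
#' couples in the sort have nearly equal heights, the couple height
#' correlation is essentially preserved while any within-couple genetic or
#' environmental structure (shared geography, age, deprivation) is destroyed.
#'
#' @param couples couple table with \code{female_id} and \code{male_id}.
#' @param heights named numeric vector of heights (names are sample ids), or
#'   a phenotype data.frame with \code{sample_id} and \code{height}.
#' @return list with \code{original}, \code{permuted} (couple tables, the
#'   permuted one in the same row order as the input) and \code{mapping}
#'   (data.frame household_id, male_before, male_after).
#' @export
swapMales <- function(couples, heights) {
  stopIf(nrow(couples) < 1L, "at least one couple required")
  if (is.data.frame(heights))
    heights <- setNames(heights$height, heights$sample_id)
  hf <- heights[couples$female_id]
  hm <- heights[couples$male_id]
  stopIf(anyNA(hf) || anyNA(hm), "missing height for a couple member")
  ord <- order(hf, hm)
  maleSorted <- couples$male_id[ord]
  swapped <- maleSorted
  nc <- length(ord)
  if (nc >= 2L) {
    pairs <- seq_len(nc %/% 2L)
    a <- 2L * pairs - 1L
    b <- 2L * pairs
    swapped[a] <- maleSorted[b]
    swapped[b] <- maleSorted[a]
  }
  permuted <- couples
  permuted$male_id[ord] <- swapped
  list(original = couples, permuted = permuted,
       mapping = data.frame(household_id = couples$household_id[ord],
                            male_before = maleSorted, male_after = swapped,
                            stringsAsFactors = FALSE))
}

# plug-in mutual information (natural log) of a two-way contingency table
.mutualInformation <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  if (n == 0) return(0)
  p <- tab / n
  pr <- rowSums(p); pc <- colSums(p)
  e <- outer(pr, pc)
  i <- p > 0
  sum(p[i] * log(p[i] / e[i]))
}

#' Within-couple covariate dependence diagnostics
#'
#' For each covariate, measures the dependence between the two partners'
#' values: the Pearson correlation with its analytic two-sided p-value for
#' continuous covariates, and the plug-in mutual information (natural log,
#' no bias correction: the permutation null absorbs the plug-in bias) with a
#' permutation p-value \eqn{(1 + \#\{MI_{perm} \ge MI_{obs}\})/(n_{perm}+1)}
#' from permutations of the female values for categorical covariates. A
#' constant covariate yields statistic 0 and p = 1.
#'
#' @param couples couple table.
#' @param phenos phenotype data.frame with \code{sample_id} and the
#'   covariate columns.
#' @param covariates character vector of covariate column names.
#' @param types named character vector, \code{"continuous"} or
#'   \code{"categorical"} per covariate; defaults to continuous for numeric
#'   columns.
#' @param nPerm number of permutations for categorical covariates.
#' @param seed RNG seed for the permutations.
#' @return data.frame with columns covariate, type, statistic, p_value,
#'   n_perm.
#' @export
covariateDependenceTests <- function(couples, phenos, covariates,
                                     types = NULL, nPerm = 1000L, seed = 1L) {
  idx <- setNames(seq_len(nrow(phenos)), phenos$sample_id)
  out <- data.frame()
  for (cv in covariates) {
    f <- phenos[[cv]][idx[couples$female_id]]
    m <- phenos[[cv]][idx[couples$male_id]]
    type <- if (!is.null(types) && !is.na(types[cv])) types[[cv]] else
      if (is.numeric(f)) "continuous" else "categorical"
    ok <- !(is.na(f) | is.na(m))
    f <- f[ok]; m <- m[ok]
    if (length(unique(f)) < 2L || length(unique(m)) < 2L) {
      out <- rbind(out, data.frame(covariate = cv, type = type, statistic = 0,
                                   p_value = 1, n_perm = NA_integer_))
      next
    }
    if (type == "continuous") {
      ct <- cor.test(f, m)
      out <- rbind(out, data.frame(covariate = cv, type = type,
                                   statistic = unname(ct$estimate),
                                   p_value = ct$p.value,
                                   n_perm = NA_integer_))
    } else {
      obs <- .mutualInformation(f, m)
      set.seed(childSeed(seed, match(cv, covariates)))
      ge <- 0L
      for (b in seq_len(nPerm)) {
        if (.mutualInformation(sample(f), m) >= obs) ge <- ge + 1L
      }
      out <- rbind(out, data.frame(covariate = cv, type = type,
                                   statistic = obs,
                                   p_value = (1 + ge) / (nPerm + 1),
                                   n_perm = as.integer(nPerm)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Regression of within-couple relatedness on birthplace distance
#'
#' Ordinary least squares of the couple's GRM relatedness on the planar
#' Euclidean distance between the partners' birthplaces, with the two-sided
#' p-value for a zero slope. A negative slope indicates geographic genetic
#' structure among couples; after [swapMales()] the slope should attenuate
#' toward zero.
#'
#' @param couples couple table.
#' @param grm a \linkS4class{GRMatrix} covering both members.
#' @param phenos phenotype data.frame with \code{sample_id},
#'   \code{birth_east}, \code{birth_north}.
#' @return named vector \code{c(slope, p_value)}.
#' @export
relatednessDistanceRegression <- function(couples, grm, phenos) {
  stopIf(nrow(couples) < 3L, "at least three couples required")
  A <- grmMatrix(grm)
  idx <- setNames(seq_len(nrow(phenos)), phenos$sample_id)
  fi <- idx[couples$female_id]; mi <- idx[couples$male_id]
  d <- sqrt((phenos$birth_east[fi] - phenos$birth_east[mi])^2 +
              (phenos$birth_north[fi] - phenos$birth_north[mi])^2)
  r <- A[cbind(match(couples$female_id, rownames(A)),
               match(couples$male_id, rownames(A)))]
  stopIf(anyNA(d) || anyNA(r), "missing coordinates or relatedness")
  if (sd(r) == 0) return(c(slope = 0, p_value = 1))
  fit <- summary(lm(r ~ d))
  c(slope = unname(fit$coefficients["d", "Estimate"]),
    p_value = unname(fit$coefficients["d", "Pr(>|t|)"]))
}
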