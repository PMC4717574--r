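#' Closed-form assortative-mating theory
#'
#' Scalar quantitative-genetics results for phenotype-driven assortment on a
#' standardized trait P = A + E, where one's additive value A affects one's
#' own phenotype, which in turn drives the partner's phenotype (the
#' ante-dependence chain A -> P -> P_partner, so cov(A, P_partner | P) = 0).
#'
#' \describe{
#'   \item{\code{expectedMateChoiceH2(rp, h2)}}{Expected heritability of the
#'     partner's phenotype treated as one's own trait: \eqn{r_p^2 h^2}. The
#'     partner's phenotype is \eqn{b P + E'} with \eqn{b = r_p} for
#'     standardized traits, so the genetic variance transmitted through one's
#'     own phenotype is \eqn{r_p^2 h^2} of the (equal) phenotypic variance.}
#'   \item{\code{randomMatingH2(h2, m)}}{Heritability the trait would have
#'     under random mating, given the equilibrium heritability \eqn{h^2}
#'     under assortment and the breeding-value correlation among mates
#'     \eqn{m}: removing the assortment-generated (directional LD) share of
#'     the additive variance, \eqn{V_{A0} = (1 - m) V_{A,eq}} at constant
#'     environmental variance, gives
#'     \eqn{h_0^2 = h^2 (1 - m) / (1 - m h^2)}.}
#'   \item{\code{heritabilityIncreasePct(h2Eq, h2Random)}}{Percent increase
#'     of the equilibrium over the random-mating heritability,
#'     \eqn{100 (h^2_{eq} - h^2_0)/h^2_0}.}
#'   \item{\code{expectedBreedingValueCorrelation(rp, h2)}}{Expected
#'     correlation of mates' breeding values under phenotypic assortment:
#'     \eqn{m = r_p h^2} (each partner's A correlates \eqn{\sqrt{h^2}} with
#'     their own P, and the two phenotypes correlate \eqn{r_p}).}
#' }
#'
#' @param rp phenotypic correlation among mates, in [-1, 1].
#' @param h2,h2Eq heritability (equilibrium, under assortment), in [0, 1].
#' @param m breeding-value correlation among mates, in [0, 1).
#' @param h2Random heritability under random mating, > 0.
#' @return a scalar; see each function.
#' @examples
#' expectedMateChoiceH2(0.232, 0.8)          # ~0.043
#' randomMatingH2(0.8, 0.2)                  # ~0.76
#' heritabilityIncreasePct(0.8, randomMatingH2(0.8, 0.2))  # ~5 %
#' expectedBreedingValueCorrelation(0.26, 0.8)             # ~0.21
#' @name assortmentTheory
NULL

#' @rdname assortmentTheory
#' @export
expectedMateChoiceH2 <- function(rp, h2) {
  stopIf(abs(rp) > 1, "rp must lie in [-1, 1]")
  stopIf(h2 < 0 || h2 > 1, "h2 must lie in [0, 1]")
  rp^2 * h2
}

#' @rdname assortmentTheory
#' @export
randomMatingH2 <- function(h2, m) {
  stopIf(h2 < 0 || h2 > 1, "h2 must lie in [0, 1]")
  stopIf(m < 0 || m >= 1, "m must lie in [0, 1)")
  h2 * (1 - m) / (1 - m * h2)
}

#' @rdname assortmentTheory
#' @export
heritabilityIncreasePct <- function(h2Eq, h2Random) {
  stopIf(h2Random <= 0, "h2Random must be positive")
  100 * (h2Eq - h2Random) / h2Random
}

#' @rdname assortmentTheory
#' @export
expectedBreedingValueCorrelation <- function(rp, h2) {
  stopIf(abs(rp) > 1, "rp must lie in [-1, 1]")
  stopIf(h2 < 0 || h2 > 1, "h2 must lie in [0, 1]")
  rp * h2
}

#' Tabulate the four assortative-mating theory quantities
#'
#' @param h2 equilibrium heritability of the trait.
#' @param m breeding-value correlation among mates.
#' @param rp phenotypic correlation among mates.
#' @return data.frame with one row per quantity (value unrounded).
#' @export
theoryTable <- function(h2, m, rp) {
  h0 <- randomMatingH2(h2, m)
  data.frame(
    quantity = c("expected_mate_choice_h2", "random_mating_h2",
                 "heritability_increase_pct", "breeding_value_correlation"),
    value = c(expectedMateChoiceH2(rp, h2), h0,
              heritabilityIncreasePct(h2, h0),
              expectedBreedingValueCorrelation(rp, h2)),
    stringsAsFactors = FALSE)
}
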