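#' Gametophytic transmission efficiency of a T-DNA insertion
#'
#' From a reciprocal out-cross of a hemizygous insertion line to wild type,
#' the transmission efficiency through the tested gamete is the ratio of
#' insertion-carrying (marker-resistant) to non-carrying (sensitive) F1
#' progeny, as a percentage: TE = 100 * resistant / sensitive. 100% means
#' the insertion allele competes equally with the wild-type allele; values
#' below 100% indicate reduced transmission through that gametophyte.
#'
#' @param nResistant count of F1 progeny carrying the insertion.
#' @param nSensitive count lacking it; must be positive (TE is undefined,
#'   not infinite, when no sensitive progeny are scored).
#' @return TE as a percentage.
#' @examples
#' transmissionEfficiency(50, 50)   # 100
#' transmissionEfficiency(44, 50)   # 88
#' @export
transmissionEfficiency <- function(nResistant, nSensitive) {
  stopifnot(length(nResistant) == 1L, length(nSensitive) == 1L)
  if (is.na(nResistant) || is.na(nSensitive) ||
      nResistant < 0 || nSensitive < 0 ||
      nResistant != round(nResistant) || nSensitive != round(nSensitive))
    stop("counts must be non-negative integers")
  if (nSensitive == 0)
    stop("transmission efficiency undefined: no sensitive progeny scored")
  100 * nResistant / nSensitive
}

#' Expected genotype fractions among selfed progeny
#'
#' For a hemizygous insertion line selfed, with relative transmission of
#' the insertion allele through male gametes \code{m} and female gametes
#' \code{f} (fractions of the wild-type allele's success, 1 = fully
#' competitive), gamete pools are (insert : wild-type) = (m : 1) male and
#' (f : 1) female. Zygote classes are therefore proportional to m*f
#' (homozygous insert), m + f (heterozygous) and 1 (wild type). With
#' \code{zygoticLethal = TRUE} the homozygous-insert class dies and the
#' survivors are renormalized — the pattern behind an insertion line that
#' transmits through both gametophytes yet never yields homozygotes.
#'
#' @param m,f relative transmission in [0, 1].
#' @param zygoticLethal does the homozygous insertion class die?
#' @return named numeric vector \code{c(homozygous_insert, heterozygous,
#'   wild_type)} summing to 1.
#' @examples
#' selfingGenotypeExpectation(1, 1)                       # 0.25 0.50 0.25
#' selfingGenotypeExpectation(1, 1, zygoticLethal = TRUE) # 0 2/3 1/3
#' selfingGenotypeExpectation(0.705, 0.88, zygoticLethal = TRUE)
#' @export
selfingGenotypeExpectation <- function(m, f, zygoticLethal = FALSE) {
  stopifnot(length(m) == 1L, length(f) == 1L)
  if (is.na(m) || is.na(f) || m < 0 || m > 1 || f < 0 || f > 1)
    stop("m and f must lie in [0, 1]")
  w <- c(homozygous_insert = m * f,
         heterozygous = m + f,
         wild_type = 1)
  if (isTRUE(zygoticLethal)) w["homozygous_insert"] <- 0
  w / sum(w)
}
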