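#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
NULL

#' MotifCatalog: a set of IUPAC motif definitions
#'
#' A catalog of named degenerate nucleotide patterns to scan promoters with.
#' Each entry carries a strand policy (\code{"both"} scans the pattern and its
#' reverse complement; \code{"forward_only"} scans the pattern as given) and a
#' \code{min_copies} threshold used by downstream filters (e.g. the G-box
#' entry defaults to 2, the pass boundary for candidate promoters).
#'
#' @slot table a \link[S4Vectors]{DataFrame} with columns \code{name},
#'   \code{pattern}, \code{strand_policy}, \code{min_copies}.
#' @seealso [defaultMotifCatalog()], [scanMotif()], [annotateElements()]
#' @exportClass MotifCatalog
setClass("MotifCatalog", representation(table = "DataFrame"))

setValidity("MotifCatalog", function(object) {
  tb <- object@table
  need <- c("name", "pattern", "strand_policy", "min_copies")
  if (!all(need %in% colnames(tb)))
    return(paste("catalog table must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(tb$name))
    return("duplicate motif names in catalog")
  if (any(!nzchar(tb$pattern)))
    return("empty motif pattern")
  bad <- vapply(tb$pattern, function(p) {
    ch <- strsplit(toupper(p), "")[[1]]
    any(!ch %in% names(IUPAC_SETS))
  }, logical(1))
  if (any(bad))
    return(paste("invalid IUPAC pattern(s):", paste(tb$pattern[bad], collapse = ", ")))
  if (!all(tb$strand_policy %in% c("both", "forward_only")))
    return("strand_policy must be 'both' or 'forward_only'")
  if (any(tb$min_copies < 0))
    return("min_copies must be >= 0")
  TRUE
})

#' DivergentPairSet: accepted head-to-head gene pairs
#'
#' Result container for [findDivergentPairs()]. One row per accepted
#' (reverse-strand gene, forward-strand gene) pair, with the two
#' transcription start sites, the exclusive interior length between them
#' (\code{len_tss}), the start-codon distance when both transcripts carry a
#' CDS (\code{len_atg}, \code{NA} otherwise), the 1-based inclusive interior
#' interval and, after [extractIntergenic()], the plus-strand intergenic
#' sequence.
#'
#' @slot pairs a \link[S4Vectors]{DataFrame}, one row per pair.
#' @slot params list of scan parameters (minDist, maxDist, requireNoIntervening).
#' @seealso [findDivergentPairs()], [interiorRanges()], [extractIntergenic()]
#' @exportClass DivergentPairSet
setClass("DivergentPairSet",
         representation(pairs = "DataFrame", params = "list"))

setValidity("DivergentPairSet", function(object) {
  p <- object@pairs
  need <- c("chrom", "rv_gene", "fw_gene", "rv_tx", "fw_tx",
            "tss_rv", "tss_fw", "len_tss", "len_atg",
            "interior_start", "interior_end", "sequence")
  if (!all(need %in% colnames(p)))
    return(paste("pairs table must have columns:", paste(need, collapse = ", ")))
  if (nrow(p) == 0L) return(TRUE)
  if (any(p$tss_rv >= p$tss_fw))
    return("tss_rv must be < tss_fw for every divergent pair")
  if (any(p$len_tss != p$tss_fw - p$tss_rv - 1L))
    return("len_tss must equal tss_fw - tss_rv - 1")
  if (any(p$interior_start != p$tss_rv + 1L) || any(p$interior_end != p$tss_fw - 1L))
    return("interior interval must be (tss_rv+1, tss_fw-1)")
  w <- object@params
  if (!is.null(w$minDist) &&
      any(p$len_tss < w$minDist | p$len_tss > w$maxDist))
    return("accepted len_tss outside the configured window")
  TRUE
})

#' CandidateSet: Table-1-style candidate bidirectional promoters
#'
#' One row per divergent pair passing the multi-G-box filter, carrying the
#' intergenic length, G-box and ACGT-core counts, DRE/CE3 presence flags and
#' optional per-gene functional annotation and subcellular localization
#' labels. Motif hit tables (one per record) are kept alongside for BED
#' export and spacing analysis.
#'
#' @slot records a \link[S4Vectors]{DataFrame}, one row per candidate pair.
#' @slot hits list of per-record motif hit data frames (may be empty).
#' @seealso [buildCandidateTable()], [loadTable1Fixture()],
#'   [writeCandidateTSV()]
#' @exportClass CandidateSet
setClass("CandidateSet",
         representation(records = "DataFrame", hits = "list"))

setValidity("CandidateSet", function(object) {
  r <- object@records
  need <- c("fw_gene", "rv_gene", "len", "gbox_n", "dre", "ce3", "acgt_n",
            "fw_annotation", "rv_annotation", "fw_location", "rv_location")
  if (!all(need %in% colnames(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(r) == 0L) return(TRUE)
  if (!is.logical(r$dre) || !is.logical(r$ce3))
    return("dre and ce3 must be logical")
  if (any(r$len <= 0, na.rm = TRUE))
    return("len must be positive")
  if (any(r$gbox_n < 0, na.rm = TRUE))
    return("gbox_n must be non-negative")
  if (length(object@hits) && length(object@hits) != nrow(r))
    return("hits list length must match record count")
  TRUE
})

setMethod("show", "MotifCatalog", function(object) {
  tb <- object@table
  cat(sprintf("MotifCatalog with %d motif(s)\n", nrow(tb)))
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-6s %-14s strand=%s min_copies=%d\n",
                tb$name[i], tb$pattern[i], tb$strand_policy[i], tb$min_copies[i]))
})

setMethod("show", "DivergentPairSet", function(object) {
  p <- object@pairs
  cat(sprintf("DivergentPairSet with %d pair(s)", nrow(p)))
  w <- object@params
  if (!is.null(w$minDist))
    cat(sprintf(" (TSS window %d-%d bp, intervening features %s)",
                w$minDist, w$maxDist,
                if (isTRUE(w$requireNoIntervening)) "excluded" else "allowed"))
  cat("\n")
  if (nrow(p))
    print(utils::head(as.data.frame(
      p[, c("chrom", "rv_gene", "fw_gene", "tss_rv", "tss_fw", "len_tss")]), 6))
  if (nrow(p) > 6) cat(sprintf("  ... and %d more\n", nrow(p) - 6L))
})

setMethod("show", "CandidateSet", function(object) {
  r <- object@records
  cat(sprintf("CandidateSet with %d candidate pair(s)\n", nrow(r)))
  if (nrow(r)) {
    cat(sprintf("  len range: %d-%d bp; DRE: %d; CE3: %d; both: %d\n",
                min(r$len), max(r$len), sum(r$dre), sum(r$ce3),
                sum(r$dre & r$ce3)))
    print(utils::head(as.data.frame(
      r[, c("fw_gene", "rv_gene", "len", "gbox_n", "dre", "ce3")]), 6))
    if (nrow(r) > 6) cat(sprintf("  ... and %d more\n", nrow(r) - 6L))
  }
})

#' @describeIn DivergentPairSet-class number of accepted pairs
#' @param x a DivergentPairSet
#' @export
setMethod("length", "DivergentPairSet", function(x) nrow(x@pairs))

#' @describeIn CandidateSet-class number of candidate records
#' @param x a CandidateSet
#' @export
setMethod("length", "CandidateSet", function(x) nrow(x@records))

#' Coerce a DivergentPairSet to a data.frame
#' @param x a DivergentPairSet
#' @param ... ignored
#' @export
as.data.frame.DivergentPairSet <- function(x, ...) as.data.frame(x@pairs)

#' Coerce a CandidateSet to a data.frame
#' @param x a CandidateSet
#' @param ... ignored
#' @export
as.data.frame.CandidateSet <- function(x, ...) as.data.frame(x@records)

#' Access the motif catalog table
#' @param x a MotifCatalog
#' @return a data.frame with columns name, pattern, strand_policy, min_copies
#' @export
catalogTable <- function(x) {
  stopifnot(is(x, "MotifCatalog"))
  as.data.frame(x@table)
}

#' Intergenic sequences stored on a pair set
#' @param x a DivergentPairSet after [extractIntergenic()]
#' @return named character vector (names \code{rv_gene|fw_gene}); \code{NA}
#'   where no sequence has been extracted yet
#' @export
pairSequences <- function(x) {
  stopifnot(is(x, "DivergentPairSet"))
  stats::setNames(x@pairs$sequence, paste0(x@pairs$rv_gene, "|", x@pairs$fw_gene))
}

#' Per-record motif hits of a candidate set
#' @param x a CandidateSet
#' @return list of data.frames (motif, start, strand, matched, flanks),
#'   one per record, positions 1-based within the intergenic region
#' @export
candidateHits <- function(x) {
  stopifnot(is(x, "CandidateSet"))
  x@hits
}
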