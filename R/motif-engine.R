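# IUPAC degenerate nucleotide codes; U is folded to T at compile time.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# complement of each IUPAC code (degenerate codes map to the code whose
# base set is the complement of theirs)
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Compile an IUPAC nucleotide pattern into a matcher
#'
#' Validates the pattern and precomputes, for each position, the set of
#' plain bases (A/C/G/T) the degenerate code allows. \code{U} is treated as
#' \code{T}. The result is consumed by [scanMotif()] but can be inspected
#' directly.
#'
#' @param pattern a single IUPAC nucleotide string, e.g. \code{"CACGTG"} or
#'   \code{"RYCGAC"}.
#' @return an object of class \code{iupacMatcher}: a list with the
#'   normalized \code{pattern}, its length \code{k}, the per-position
#'   allowed-base sets \code{allowed}, the reverse-complement pattern
#'   \code{revcomp} and a \code{palindrome} flag.
#' @examples
#' m <- compileIUPAC("RY")
#' m$allowed   # position 1: A,G; position 2: C,T
#' @export
compileIUPAC <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern) ||
      !nzchar(pattern))
    stop("pattern must be a single non-empty string")
  pat <- chartr("U", "T", toupper(pattern))
  ch <- strsplit(pat, "")[[1]]
  bad <- which(!ch %in% names(IUPAC_SETS))
  if (length(bad))
    stop(sprintf("invalid IUPAC code '%s' at position %d in pattern '%s'",
                 ch[bad[1]], bad[1], pattern))
  rc <- paste(rev(unname(IUPAC_COMPLEMENT[ch])), collapse = "")
  structure(
    list(pattern = pat, k = length(ch),
         allowed = IUPAC_SETS[ch],
         revcomp = rc, palindrome = identical(pat, rc)),
    class = "iupacMatcher")
}

# all start positions (1-based) where the compiled pattern matches chv
# (a character vector of single bases). nAny: subject 'N' matches any code.
.match_starts <- function(chv, matcher, nAny = FALSE) {
  k <- matcher$k
  n <- length(chv) - k + 1L
  if (n < 1L) return(integer(0))
  ok <- rep(TRUE, n)
  for (j in seq_len(k)) {
    win <- chv[j:(j + n - 1L)]
    hit <- win %in% matcher$allowed[[j]]
    if (nAny) hit <- hit | win == "N"
    ok <- ok & hit
  }
  which(ok)
}

#' Scan a sequence for an IUPAC motif
#'
#' Tests every start position; overlapping occurrences are all reported.
#' With \code{strandPolicy = "both"} the reverse complement of the pattern
#' is also scanned, and minus-strand hits are reported at the forward-strand
#' start of their leftmost base, with \code{matched} given as read on the
#' plus strand. A palindromic pattern (equal to its own reverse complement,
#' e.g. the G-box CACGTG) is reported once per position with strand
#' \code{"+"}, so "copies" are counted at the position level.
#'
#' @param seq a single string over A/C/G/T/N (case-insensitive).
#' @param pattern an IUPAC pattern string or a compiled [compileIUPAC()]
#'   matcher.
#' @param strandPolicy \code{"both"} (default) or \code{"forward_only"}.
#' @param flankK number of flanking bases to report on each side (default 2;
#'   clipped, never padded, at sequence ends).
#' @param nPolicy how an \code{N} in the subject behaves: \code{"never"}
#'   (default, matches no code) or \code{"any"} (matches every code).
#' @param motifName label used in the \code{motif} column.
#' @return a data.frame with columns \code{motif}, \code{start} (1-based),
#'   \code{strand}, \code{matched}, \code{left_flank}, \code{right_flank},
#'   sorted by start position.
#' @examples
#' scanMotif("TTCACGTGTT", "CACGTG")           # one hit, start 3, "+"
#' scanMotif("TTGTCGGTT", "CCGAC")             # reverse-complement hit, "-"
#' @export
scanMotif <- function(seq, pattern, strandPolicy = c("both", "forward_only"),
                      flankK = 2L, nPolicy = c("never", "any"),
                      motifName = NULL) {
  strandPolicy <- match.arg(strandPolicy)
  nPolicy <- match.arg(nPolicy)
  m <- if (inherits(pattern, "iupacMatcher")) pattern else compileIUPAC(pattern)
  if (is.null(motifName)) motifName <- m$pattern
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  chv <- strsplit(s, "")[[1]]
  nAny <- nPolicy == "any"

  fw <- .match_starts(chv, m, nAny)
  starts <- fw
  strands <- rep("+", length(fw))
  if (strandPolicy == "both" && !m$palindrome) {
    rcm <- compileIUPAC(m$revcomp)
    rv <- .match_starts(chv, rcm, nAny)
    starts <- c(starts, rv)
    strands <- c(strands, rep("-", length(rv)))
  }
  if (length(starts) == 0L)
    return(data.frame(motif = character(0), start = integer(0),
                      strand = character(0), matched = character(0),
                      left_flank = character(0), right_flank = character(0),
                      stringsAsFactors = FALSE))
  o <- order(starts, strands)
  starts <- starts[o]; strands <- strands[o]
  k <- m$k
  lf <- substring(s, pmax(1L, starts - flankK), starts - 1L)
  rf <- substring(s, starts + k, pmin(nchar(s), starts + k + flankK - 1L))
  data.frame(motif = rep(motifName, length(starts)),
             start = as.integer(starts), strand = strands,
             matched = substring(s, starts, starts + k - 1L),
             left_flank = lf, right_flank = rf,
             stringsAsFactors = FALSE)
}

#' Count G-box (CACGTG) occurrences
#'
#' Number of distinct start positions matching the palindromic G-box
#' hexamer. The candidate-promoter filter passes when this count is at
#' least two.
#'
#' @inheritParams scanMotif
#' @return integer count
#' @export
countGbox <- function(seq, nPolicy = c("never", "any")) {
  nrow(scanMotif(seq, "CACGTG", nPolicy = match.arg(nPolicy),
                 motifName = "GBOX"))
}

#' Construct a motif catalog
#'
#' @param name character vector of motif names
#' @param pattern IUPAC patterns (validated)
#' @param strand_policy \code{"both"} or \code{"forward_only"}, recycled
#' @param min_copies integer thresholds for downstream filters, recycled
#' @return a [MotifCatalog-class] object
#' @export
MotifCatalog <- function(name, pattern, strand_policy = "both",
                         min_copies = 1L) {
  n <- length(name)
  tb <- DataFrame(name = as.character(name),
                  pattern = toupper(as.character(pattern)),
                  strand_policy = rep_len(strand_policy, n),
                  min_copies = as.integer(rep_len(min_copies, n)))
  new("MotifCatalog", table = tb)
}

#' Default cis-element catalog for ABA-responsive promoter annotation
#'
#' The four element classes used for candidate annotation: the palindromic
#' G-box ABRE (CACGTG, filter threshold 2 copies), the DRE/CRT core (CCGAC,
#' both strands), a CE3 coupling element (default the barley HVA1 CE3
#' consensus; the exact string is configurable because CE3 consensus
#' definitions vary between studies), and the bare ACGT ABRE core.
#'
#' @param ce3 the CE3 pattern to use (default \code{"ACGCGTGTCCTC"}).
#' @return a [MotifCatalog-class]
#' @export
defaultMotifCatalog <- function(ce3 = "ACGCGTGTCCTC") {
  MotifCatalog(name = c("GBOX", "DRE", "CE3", "ACGT"),
               pattern = c("CACGTG", "CCGAC", ce3, "ACGT"),
               strand_policy = "both",
               min_copies = c(2L, 1L, 1L, 1L))
}

#' Annotate a promoter sequence with a motif catalog
#'
#' Scans every catalog motif under its strand policy and derives the summary
#' used for candidate tables: G-box and ACGT-core counts plus DRE/CE3
#' presence flags.
#'
#' @param seq a single A/C/G/T/N string (the intergenic region).
#' @param catalog a [MotifCatalog-class]; must be non-empty.
#' @param flankK,nPolicy passed to [scanMotif()].
#' @return a list with \code{hits} (named list of per-motif hit frames),
#'   \code{gbox_n}, \code{acgt_n}, \code{dre}, \code{ce3}.
#' @export
annotateElements <- function(seq, catalog = defaultMotifCatalog(),
                             flankK = 2L, nPolicy = c("never", "any")) {
  stopifnot(is(catalog, "MotifCatalog"))
  nPolicy <- match.arg(nPolicy)
  tb <- catalog@table
  if (nrow(tb) == 0L) stop("empty motif catalog")
  hits <- lapply(seq_len(nrow(tb)), function(i)
    scanMotif(seq, tb$pattern[i],
              strandPolicy = tb$strand_policy[i],
              flankK = flankK, nPolicy = nPolicy, motifName = tb$name[i]))
  names(hits) <- tb$name
  nOf <- function(nm) if (nm %in% names(hits)) nrow(hits[[nm]]) else 0L
  list(hits = hits,
       gbox_n = nOf("GBOX"),
       acgt_n = nOf("ACGT"),
       dre = nOf("DRE") > 0L,
       ce3 = nOf("CE3") > 0L)
}

#' Spacing between two motif hit lists on the same sequence
#'
#' For each hit of motif B, finds the nearest upstream hit of motif A and
#' reports the gap: the number of bases strictly between the end of A and
#' the start of B. Overlaps give negative gaps. The canonical geometry
#' looked for here is a coupling element a few bases downstream of a G-box
#' (e.g. CE3 five bases after one G-box).
#'
#' @param hitsA,hitsB hit data.frames from [scanMotif()] on the same
#'   sequence.
#' @return a data.frame with one row per B hit that has an upstream A hit:
#'   \code{a_start}, \code{a_strand}, \code{b_start}, \code{b_strand},
#'   \code{gap}.
#' @examples
#' a <- scanMotif("TTCACGTGTTTTTACGCGTGTCCTCTT", "CACGTG", motifName = "GBOX")
#' b <- scanMotif("TTCACGTGTTTTTACGCGTGTCCTCTT", "ACGCGTGTCCTC", motifName = "CE3")
#' elementSpacing(a, b)   # gap 5
#' @export
elementSpacing <- function(hitsA, hitsB) {
  out <- data.frame(a_start = integer(0), a_strand = character(0),
                    b_start = integer(0), b_strand = character(0),
                    gap = integer(0), stringsAsFactors = FALSE)
  if (nrow(hitsA) == 0L || nrow(hitsB) == 0L) return(out)
  for (i in seq_len(nrow(hitsB))) {
    b <- hitsB[i, ]
    up <- hitsA[hitsA$start < b$start, , drop = FALSE]
    if (nrow(up) == 0L) next
    up <- up[up$start == max(up$start), , drop = FALSE]
    up <- up[order(up$strand), , drop = FALSE][1, ]   # "+" preferred on ties
    a_end <- up$start + nchar(up$matched) - 1L
    out <- rbind(out, data.frame(
      a_start = up$start, a_strand = up$strand,
      b_start = b$start, b_strand = b$strand,
      gap = as.integer(b$start - a_end - 1L), stringsAsFactors = FALSE))
  }
  out
}

#' Binomial background model for motif depletion/enrichment
#'
#' Quantifies how surprising an observed motif count is in a sequence of
#' length \code{L} under an independent-base background. The per-position
#' match probability is the product over pattern positions of the summed
#' background frequencies of the allowed bases; the count is modelled as
#' Binomial(L - k + 1, p). Overlaps between potential match positions are
#' deliberately ignored — a documented approximation that is conservative
#' for the short, non-self-overlapping elements considered here. The
#' lower-tail probability P(X <= observed) is small when the motif is
#' depleted relative to background.
#'
#' @param L sequence length in bp.
#' @param pattern IUPAC pattern string or compiled matcher.
#' @param background named base frequencies \code{c(A=,C=,G=,T=)} summing
#'   to 1 (tolerance 1e-9); default uniform.
#' @param observed observed motif count.
#' @param motifName label for the result.
#' @return a list of class \code{depletionResult}: \code{motif}, \code{L},
#'   \code{k}, \code{n_slots}, \code{p}, \code{expected}, \code{observed},
#'   \code{p_lower}.
#' @examples
#' # constructed so that n_slots * p = 1 exactly
#' motifDepletionStat(4101, "CACGTG", observed = 0)
#' @export
motifDepletionStat <- function(L, pattern,
                               background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                               observed, motifName = NULL) {
  m <- if (inherits(pattern, "iupacMatcher")) pattern else compileIUPAC(pattern)
  if (is.null(motifName)) motifName <- m$pattern
  if (!all(c("A", "C", "G", "T") %in% names(background)))
    stop("background must be named A, C, G, T")
  if (abs(sum(background) - 1) > 1e-9)
    stop(sprintf("background frequencies sum to %.12f, not 1", sum(background)))
  if (L < m$k) stop("L must be at least the pattern length")
  stopifnot(observed >= 0)
  p <- prod(vapply(m$allowed, function(a) sum(background[a]), numeric(1)))
  n_slots <- as.integer(L - m$k + 1L)
  if (observed > n_slots) stop("observed count exceeds the number of slots")
  structure(
    list(motif = motifName, L = as.integer(L), k = m$k, n_slots = n_slots,
         p = p, expected = n_slots * p, observed = as.integer(observed),
         p_lower = stats::pbinom(observed, n_slots, p)),
    class = "depletionResult")
}

#' @export
print.depletionResult <- function(x, ...) {
  cat(sprintf(
    "Motif depletion: %s | L=%d k=%d slots=%d p=%.3g E=%.4g observed=%d P(X<=x)=%.4g\n",
    x$motif, x$L, x$k, x$n_slots, x$p, x$expected, x$observed, x$p_lower))
  invisible(x)
}

#' Reverse complement of a plain or degenerate nucleotide string
#' @param x a single IUPAC string
#' @return its reverse complement (degeneracy preserved)
#' @export
revcompIUPAC <- function(x) {
  ch <- strsplit(chartr("U", "T", toupper(x)), "")[[1]]
  bad <- which(!ch %in% names(IUPAC_COMPLEMENT))
  if (length(bad))
    stop(sprintf("invalid IUPAC code '%s' at position %d", ch[bad[1]], bad[1]))
  paste(rev(unname(IUPAC_COMPLEMENT[ch])), collapse = "")
}
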