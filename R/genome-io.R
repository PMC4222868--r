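#' Read a genome FASTA into a DNAStringSet
#'
#' Sequence names are truncated at the first whitespace (the chromosome
#' token). Sequences are uppercased; any letter outside A/C/G/T/N is mapped
#' to N with a warning, so ambiguity codes in real assemblies never abort a
#' scan.
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @return a \link[Biostrings]{DNAStringSet}, one entry per chromosome.
#' @export
#' @importFrom Biostrings readBStringSet DNAStringSet
readGenomeFASTA <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no sequences in FASTA: ", path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm))
    stop("duplicate chromosome name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  ch <- toupper(as.character(x))
  if (any(!nzchar(ch)))
    stop("empty sequence record(s): ", paste(nm[!nzchar(ch)], collapse = ", "))
  bad <- grepl("[^ACGTN]", ch)
  if (any(bad)) {
    warning(sprintf("non-ACGTN letters in %d sequence(s) mapped to N",
                    sum(bad)))
    ch[bad] <- gsub("[^ACGTN]", "N", ch[bad])
  }
  out <- Biostrings::DNAStringSet(ch)
  names(out) <- nm
  out
}

# fail fast, with a line number, on structurally broken GFF3 bodies —
# rtracklayer's error messages do not localize the offending line
.check_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) {
      if (identical(ln, "##FASTA")) break
      next
    }
    if (startsWith(ln, ">")) break   # embedded FASTA section
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (nf != 9L)
      stop(sprintf("GFF3 parse error at line %d: expected 9 tab-separated columns, found %d",
                   i, nf))
  }
  invisible(TRUE)
}

#' Read transcript models from a GFF3 file
#'
#' Parses mRNA/transcript features into a \link[GenomicRanges]{GRanges}
#' with one range per transcript and metadata columns \code{tx_id},
#' \code{gene_id}, \code{cds_start}, \code{cds_end}. The CDS span is the
#' min/max over a transcript's CDS features (\code{NA} when it has none).
#' A transcript without a parent gene attribute adopts its own id as
#' \code{gene_id}, so minimal hand-written annotations stay usable.
#' Coordinates are kept 1-based inclusive throughout.
#'
#' @param path GFF3 file with gene/mRNA (or transcript) features; CDS
#'   features optional.
#' @param genome optional \link[Biostrings]{DNAStringSet}; when supplied,
#'   every transcript must lie within its chromosome's length.
#' @return a GRanges, one range per transcript, in file order.
#' @export
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom rtracklayer import
readTranscriptsGFF3 <- function(path, genome = NULL) {
  .check_gff3_lines(path)
  g <- rtracklayer::import(path, format = "gff3")
  type <- as.character(g$type)
  is_tx <- type %in% c("mRNA", "transcript")
  tx <- g[is_tx]
  if (length(tx) == 0L)
    return(GenomicRanges::GRanges(
      tx_id = character(0), gene_id = character(0),
      cds_start = integer(0), cds_end = integer(0)))
  tx_id <- as.character(tx$ID)
  if (anyNA(tx_id) || any(!nzchar(tx_id)))
    stop("transcript feature(s) without an ID attribute")
  if (anyDuplicated(tx_id))
    stop("duplicate transcript ID(s): ",
         paste(unique(tx_id[duplicated(tx_id)]), collapse = ", "))
  str <- as.character(GenomicRanges::strand(tx))
  if (any(str == "*"))
    stop("rejected transcript record(s) lacking a strand: ",
         paste(tx_id[str == "*"], collapse = ", "))
  parent <- if (is.null(tx$Parent)) rep(NA_character_, length(tx)) else
    vapply(tx$Parent, function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
  gene_id <- ifelse(is.na(parent) | !nzchar(parent), tx_id, parent)

  cds_start <- rep(NA_integer_, length(tx))
  cds_end <- rep(NA_integer_, length(tx))
  cds <- g[type == "CDS"]
  if (length(cds)) {
    cp <- as.character(unlist(cds$Parent))
    cs <- rep(GenomicRanges::start(cds), lengths(cds$Parent))
    ce <- rep(GenomicRanges::end(cds), lengths(cds$Parent))
    agg_min <- tapply(cs, cp, min)
    agg_max <- tapply(ce, cp, max)
    hit <- tx_id %in% names(agg_min)
    cds_start[hit] <- as.integer(agg_min[tx_id[hit]])
    cds_end[hit] <- as.integer(agg_max[tx_id[hit]])
  }
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(tx),
    ranges = IRanges::IRanges(GenomicRanges::start(tx),
                              GenomicRanges::end(tx)),
    strand = str)
  mcols(out)$tx_id <- tx_id
  mcols(out)$gene_id <- gene_id
  mcols(out)$cds_start <- cds_start
  mcols(out)$cds_end <- cds_end
  bad_cds <- !is.na(cds_start) &
    (cds_start < GenomicRanges::start(out) |
       cds_end > GenomicRanges::end(out) | cds_start > cds_end)
  if (any(bad_cds))
    stop("CDS span outside transcript span for: ",
         paste(tx_id[bad_cds], collapse = ", "))
  if (!is.null(genome)) {
    chr <- as.character(GenomicRanges::seqnames(out))
    unknown <- !chr %in% names(genome)
    if (any(unknown))
      stop("transcript(s) on chromosome absent from genome: ",
           paste(tx_id[unknown], collapse = ", "))
    len <- Biostrings::width(genome)[match(chr, names(genome))]
    oob <- GenomicRanges::end(out) > len | GenomicRanges::start(out) < 1L
    if (any(oob))
      stop("transcript(s) outside chromosome bounds: ",
           paste(tx_id[oob], collapse = ", "))
  }
  out
}

#' Strand-aware transcription start sites
#'
#' The 5' end of each transcript: the leftmost coordinate on the plus
#' strand, the rightmost (annotated transcript end) on the minus strand.
#'
#' @param tx transcript GRanges from [readTranscriptsGFF3()].
#' @return integer vector of 1-based TSS positions, named by \code{tx_id}.
#' @export
tssOf <- function(tx) {
  str <- as.character(GenomicRanges::strand(tx))
  if (any(!str %in% c("+", "-")))
    stop("transcript(s) without a definite strand")
  out <- ifelse(str == "+", GenomicRanges::start(tx), GenomicRanges::end(tx))
  stats::setNames(as.integer(out), mcols(tx)$tx_id)
}

#' Strand-aware start-codon positions
#'
#' The 5' end of each transcript's CDS span: leftmost CDS coordinate on the
#' plus strand, rightmost on the minus strand.
#'
#' @param tx transcript GRanges from [readTranscriptsGFF3()].
#' @return integer vector of 1-based positions, named by \code{tx_id}.
#' @export
startCodonOf <- function(tx) {
  cs <- mcols(tx)$cds_start
  ce <- mcols(tx)$cds_end
  if (anyNA(cs))
    stop("no CDS annotated for transcript(s): ",
         paste(mcols(tx)$tx_id[is.na(cs)], collapse = ", "))
  str <- as.character(GenomicRanges::strand(tx))
  if (any(!str %in% c("+", "-")))
    stop("transcript(s) without a definite strand")
  stats::setNames(as.integer(ifelse(str == "+", cs, ce)), mcols(tx)$tx_id)
}
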