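#' Find divergent (head-to-head) transcript pairs
#'
#' Scans an annotation for opposite-strand transcript pairs on the same
#' chromosome transcribed away from each other, with the number of bases
#' strictly between their transcription start sites inside
#' \code{[minDist, maxDist]} (default 100-600 bp, the window used for
#' compact plant genomes). Divergence requires the minus-strand TSS to lie
#' left of the plus-strand TSS, so convergent and overlapping arrangements
#' are rejected. By default a pair is also rejected when any other
#' transcript's span intersects the interior interval (an intervening gene
#' means the two genes do not share a promoter). Transcript pairs are then
#' collapsed to unique gene pairs, keeping the transcript combination with
#' the smallest TSS distance — the most conservative promoter span.
#'
#' @param tx transcript GRanges from [readTranscriptsGFF3()] (or the
#'   synthetic generator).
#' @param minDist,maxDist inclusive bounds (bp) on the interior TSS
#'   distance.
#' @param requireNoIntervening reject pairs whose interior interval is
#'   touched by another transcript (default TRUE).
#' @return a [DivergentPairSet-class], sorted by chromosome then by the
#'   minus-strand TSS, ties broken by gene ids.
#' @export
#' @importFrom IRanges IRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
findDivergentPairs <- function(tx, minDist = 100L, maxDist = 600L,
                               requireNoIntervening = TRUE) {
  if (minDist > maxDist)
    stop("configuration error: minDist (", minDist,
         ") exceeds maxDist (", maxDist, ")")
  if (minDist < 0L) stop("minDist must be non-negative")

  empty <- DataFrame(
    chrom = character(0), rv_gene = character(0), fw_gene = character(0),
    rv_tx = character(0), fw_tx = character(0),
    tss_rv = integer(0), tss_fw = integer(0),
    len_tss = integer(0), len_atg = integer(0),
    interior_start = integer(0), interior_end = integer(0),
    sequence = character(0))
  params <- list(minDist = as.integer(minDist), maxDist = as.integer(maxDist),
                 requireNoIntervening = isTRUE(requireNoIntervening))
  if (length(tx) == 0L)
    return(new("DivergentPairSet", pairs = empty, params = params))

  chr <- as.character(GenomicRanges::seqnames(tx))
  str <- as.character(GenomicRanges::strand(tx))
  tss <- ifelse(str == "+", GenomicRanges::start(tx), GenomicRanges::end(tx))
  rows <- list()
  for (cc in unique(chr)) {
    on_c <- which(chr == cc)
    rv <- on_c[str[on_c] == "-"]
    fw <- on_c[str[on_c] == "+"]
    if (!length(rv) || !length(fw)) next
    # fw TSS must land in (tss_rv + minDist + 1) .. (tss_rv + maxDist + 1)
    # so that len_tss = tss_fw - tss_rv - 1 lies in [minDist, maxDist]
    win <- IRanges::IRanges(tss[rv] + minDist + 1L, tss[rv] + maxDist + 1L)
    pts <- IRanges::IRanges(tss[fw], width = 1L)
    ov <- IRanges::findOverlaps(pts, win)
    if (!length(ov)) next
    i_fw <- fw[S4Vectors::queryHits(ov)]
    i_rv <- rv[S4Vectors::subjectHits(ov)]
    for (j in seq_along(i_fw)) {
      a <- i_rv[j]; b <- i_fw[j]
      t_rv <- tss[a]; t_fw <- tss[b]
      int_s <- t_rv + 1L; int_e <- t_fw - 1L
      if (requireNoIntervening) {
        others <- setdiff(on_c, c(a, b))
        if (length(others)) {
          hit <- GenomicRanges::start(tx)[others] <= int_e &
            GenomicRanges::end(tx)[others] >= int_s
          if (any(hit)) next
        }
      }
      m <- mcols(tx)
      la <- NA_integer_
      if (!is.na(m$cds_start[a]) && !is.na(m$cds_start[b])) {
        codon_rv <- m$cds_end[a]     # minus strand: 5' CDS end is rightmost
        codon_fw <- m$cds_start[b]
        la <- as.integer(codon_fw - codon_rv - 1L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cc,
        rv_gene = m$gene_id[a], fw_gene = m$gene_id[b],
        rv_tx = m$tx_id[a], fw_tx = m$tx_id[b],
        tss_rv = as.integer(t_rv), tss_fw = as.integer(t_fw),
        len_tss = as.integer(t_fw - t_rv - 1L), len_atg = la,
        interior_start = as.integer(int_s), interior_end = as.integer(int_e),
        sequence = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(new("DivergentPairSet", pairs = empty, params = params))
  df <- do.call(rbind, rows)

  # collapse isoform combinations to one row per (rv_gene, fw_gene),
  # keeping the smallest len_tss; ties broken by transcript ids
  key <- paste(df$rv_gene, df$fw_gene, sep = "\r")
  df <- df[order(key, df$len_tss, df$rv_tx, df$fw_tx), , drop = FALSE]
  df <- df[!duplicated(paste(df$rv_gene, df$fw_gene, sep = "\r")), ,
           drop = FALSE]
  df <- df[order(df$chrom, df$tss_rv, df$rv_gene, df$fw_gene), , drop = FALSE]
  rownames(df) <- NULL
  new("DivergentPairSet", pairs = as(df, "DataFrame"), params = params)
}

#' Interior intervals of a pair set as GRanges
#'
#' The 1-based inclusive interval strictly between the two TSSs of each
#' pair — the putative bidirectional promoter. A zero-width range marks the
#' degenerate adjacent-TSS case.
#'
#' @param x a [DivergentPairSet-class]
#' @return a GRanges named \code{rv_gene|fw_gene}
#' @export
interiorRanges <- function(x) {
  stopifnot(is(x, "DivergentPairSet"))
  p <- x@pairs
  gr <- GenomicRanges::GRanges(
    seqnames = p$chrom,
    ranges = IRanges::IRanges(start = p$interior_start, width = p$len_tss))
  names(gr) <- paste0(p$rv_gene, "|", p$fw_gene)
  gr
}

#' Extract intergenic promoter sequences for a pair set
#'
#' Slices the plus-strand sequence of every interior interval out of the
#' genome and stores it on the pair set. The degenerate adjacent-TSS case
#' yields the empty string.
#'
#' @param x a [DivergentPairSet-class]
#' @param genome a \link[Biostrings]{DNAStringSet} covering every interior
#' @return \code{x} with the \code{sequence} column filled
#' @export
extractIntergenic <- function(x, genome) {
  stopifnot(is(x, "DivergentPairSet"))
  p <- x@pairs
  if (nrow(p) == 0L) return(x)
  seqs <- character(nrow(p))
  for (i in seq_len(nrow(p))) {
    cc <- p$chrom[i]
    if (!cc %in% names(genome))
      stop(sprintf("coordinate error for pair %s|%s: chromosome '%s' not in genome",
                   p$rv_gene[i], p$fw_gene[i], cc))
    if (p$len_tss[i] == 0L) { seqs[i] <- ""; next }
    if (p$interior_start[i] < 1L ||
        p$interior_end[i] > Biostrings::width(genome)[match(cc, names(genome))])
      stop(sprintf("coordinate error for pair %s|%s: interior %d-%d outside chromosome '%s'",
                   p$rv_gene[i], p$fw_gene[i],
                   p$interior_start[i], p$interior_end[i], cc))
    seqs[i] <- as.character(Biostrings::subseq(
      genome[[cc]], p$interior_start[i], p$interior_end[i]))
  }
  p$sequence <- seqs
  x@pairs <- p
  validObject(x)
  x
}

#' Interior distance between the two TSSs
#' @param x a [DivergentPairSet-class]
#' @return integer vector of bp counts strictly between the TSSs
#' @export
lenTSS <- function(x) {
  stopifnot(is(x, "DivergentPairSet"))
  x@pairs$len_tss
}

#' Interior distance between the two start codons
#'
#' The alternative promoter-length convention: bases strictly between the
#' 5' CDS ends of the two transcripts. \code{NA} (not an error) when either
#' transcript lacks a CDS.
#'
#' @param x a [DivergentPairSet-class]
#' @return integer vector, \code{NA} where a CDS is missing
#' @export
startCodonDistance <- function(x) {
  stopifnot(is(x, "DivergentPairSet"))
  x@pairs$len_atg
}
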