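.BASES <- c("A", "C", "G", "T")

#' AT-rich background base frequencies
#'
#' A preset emulating the base composition of Arabidopsis intergenic DNA
#' (roughly 64% A+T).
#' @return named numeric vector over A/C/G/T summing to 1
#' @export
atRichBackground <- function() c(A = 0.32, C = 0.18, G = 0.18, T = 0.32)

#' Specification for a synthetic plant-like genome
#'
#' Describes a multi-chromosome genome with single-exon gene models planted
#' in controlled arrangements: qualifying divergent pairs (TSS gap inside
#' the scan window, two or more G-boxes, optional DRE and CE3 with a stated
#' G-box-to-CE3 spacing) plus decoy arrangements designed to be rejected
#' for exactly one reason each — TSS gap below/above the window, same
#' strand, convergent orientation, a single G-box, or an intervening gene.
#' Intergenic regions are rejection-sampled so they contain no catalog
#' motif beyond the planted ones; gene bodies and inter-unit buffers are
#' unconstrained background (the scan never reads them). The ubiquitous
#' ACGT core is deliberately not sanitized: every G-box contains one and
#' chance occurrences carry no weight in the filter.
#'
#' @param nQualifying number of planted qualifying pairs. The first one
#'   carries three G-boxes plus a DRE and a CE3 placed \code{ce3Gap} bases
#'   downstream of its first G-box (the coupled-element geometry of
#'   characterized ABA-responsive bidirectional promoters); later ones
#'   alternate 2/3 G-boxes and every third carries a DRE.
#' @param decoys named integer vector with (a subset of) names
#'   \code{too_close}, \code{too_far}, \code{same_strand},
#'   \code{convergent}, \code{single_gbox}, \code{intervening}.
#' @param nChromosomes,chromLength genome shape; generation aborts before
#'   emitting anything if the units do not fit.
#' @param background base frequencies (default uniform; see
#'   [atRichBackground()]).
#' @param minGap,maxGap the TSS window the qualifying pairs are drawn in.
#' @param geneLength inclusive range of gene model lengths (bp).
#' @param utr5 5' UTR length separating TSS from start codon, so the
#'   TSS-distance and start-codon-distance conventions are distinguishable.
#' @param ce3Gap bases between the first G-box and the CE3 element.
#' @param ce3 CE3 pattern planted and sanitized against.
#' @param maxRedraws rejection-sampling bound per region.
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   output.
#' @return a list of class \code{syntheticGenomeSpec}
#' @export
syntheticGenomeSpec <- function(nQualifying = 3L,
                                decoys = c(too_close = 1L, too_far = 1L,
                                           same_strand = 1L, convergent = 1L,
                                           single_gbox = 1L, intervening = 1L),
                                nChromosomes = 3L, chromLength = 9000L,
                                background = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25),
                                minGap = 100L, maxGap = 600L,
                                geneLength = c(300L, 500L), utr5 = 50L,
                                ce3Gap = 5L, ce3 = "ACGCGTGTCCTC",
                                maxRedraws = 10000L, seed = 1L) {
  known <- c("too_close", "too_far", "same_strand", "convergent",
             "single_gbox", "intervening")
  if (length(decoys) && (is.null(names(decoys)) ||
                         !all(names(decoys) %in% known)))
    stop("decoy classes must be among: ", paste(known, collapse = ", "))
  if (abs(sum(background) - 1) > 1e-9)
    stop("background frequencies must sum to 1")
  if (minGap < 30L || minGap > maxGap)
    stop("need 30 <= minGap <= maxGap")
  structure(list(
    nQualifying = as.integer(nQualifying),
    decoys = vapply(decoys, as.integer, integer(1)),
    nChromosomes = as.integer(nChromosomes),
    chromLength = as.integer(chromLength),
    background = background[.BASES],
    minGap = as.integer(minGap), maxGap = as.integer(maxGap),
    geneLength = as.integer(geneLength), utr5 = as.integer(utr5),
    ce3Gap = as.integer(ce3Gap), ce3 = toupper(ce3),
    maxRedraws = as.integer(maxRedraws), seed = as.integer(seed)),
    class = "syntheticGenomeSpec")
}

# catalog used to sanitize intergenic regions (ACGT core intentionally
# excluded: it occurs inside every G-box)
.scan_region <- function(s, ce3) {
  rbind(scanMotif(s, "CACGTG", motifName = "GBOX"),
        scanMotif(s, "CCGAC", motifName = "DRE"),
        scanMotif(s, ce3, motifName = "CE3"))
}

.rbases <- function(n, bg) sample(.BASES, n, replace = TRUE, prob = bg)

# layout blocks of planted motifs for one region and rejection-sample the
# background around them until the region contains exactly the planted hits
.plant_region <- function(L, gbox_n, dre, dre_strand, ce3_here, ce3_gap,
                          ce3_pattern, bg, maxRedraws, limit = L) {
  blocks <- list()
  if (ce3_here) {
    w <- 6L + ce3_gap + nchar(ce3_pattern)
    blocks[[length(blocks) + 1L]] <- list(
      width = w,
      motifs = data.frame(motif = c("GBOX", "CE3"),
                          off = c(0L, 6L + ce3_gap),
                          strand = "+",
                          literal = c("CACGTG", ce3_pattern),
                          stringsAsFactors = FALSE))
    gbox_rest <- gbox_n - 1L
  } else gbox_rest <- gbox_n
  for (i in seq_len(max(0L, gbox_rest)))
    blocks[[length(blocks) + 1L]] <- list(
      width = 6L,
      motifs = data.frame(motif = "GBOX", off = 0L, strand = "+",
                          literal = "CACGTG", stringsAsFactors = FALSE))
  if (dre)
    blocks[[length(blocks) + 1L]] <- list(
      width = 5L,
      motifs = data.frame(motif = "DRE", off = 0L, strand = dre_strand,
                          literal = if (dre_strand == "+") "CCGAC" else "GTCGG",
                          stringsAsFactors = FALSE))

  nb <- length(blocks)
  margin <- 3L; bbgap <- 8L
  planted <- data.frame(motif = character(0), start = integer(0),
                        strand = character(0), literal = character(0),
                        stringsAsFactors = FALSE)
  if (nb > 0L) {
    totw <- sum(vapply(blocks, `[[`, integer(1), "width"))
    slack <- limit - 2L * margin - totw - (nb - 1L) * bbgap
    if (slack < 0L)
      stop(sprintf("generation error: region of %d bp cannot host %d planted block(s)",
                   L, nb))
    gaps <- as.vector(stats::rmultinom(1, slack, rep(1, nb + 1L)))
    pos <- margin + gaps[1] + 1L
    for (i in seq_len(nb)) {
      b <- blocks[[i]]
      planted <- rbind(planted, data.frame(
        motif = b$motifs$motif, start = pos + b$motifs$off,
        strand = b$motifs$strand, literal = b$motifs$literal,
        stringsAsFactors = FALSE))
      pos <- pos + b$width + bbgap + gaps[i + 1L]
    }
  }
  want <- planted[order(planted$start, planted$motif),
                  c("motif", "start", "strand")]
  rownames(want) <- NULL
  for (try in seq_len(maxRedraws)) {
    chv <- .rbases(L, bg)
    for (i in seq_len(nrow(planted))) {
      lit <- strsplit(planted$literal[i], "")[[1]]
      chv[planted$start[i]:(planted$start[i] + length(lit) - 1L)] <- lit
    }
    s <- paste(chv, collapse = "")
    got <- .scan_region(s, ce3_pattern)
    got <- got[order(got$start, got$motif), c("motif", "start", "strand")]
    rownames(got) <- NULL
    if (identical(got$motif, want$motif) &&
        identical(got$start, want$start) &&
        identical(got$strand, want$strand))
      return(list(seq = s, motifs = planted))
  }
  stop(sprintf("generation error: region not sanitized after %d redraws",
               maxRedraws))
}

#' Generate a synthetic genome with planted divergent pairs and decoys
#'
#' Builds FASTA-ready chromosome sequences, single-exon gene/mRNA/exon/CDS
#' models and a ground-truth manifest from a [syntheticGenomeSpec()].
#' Identical spec and seed reproduce the output byte for byte. Each unit is
#' separated from its neighbours by enough buffer that no cross-unit TSS
#' pair can fall inside the scan window.
#'
#' @param spec a \code{syntheticGenomeSpec}
#' @param outDir optional directory; when given, \code{genome.fa},
#'   \code{genes.gff3} and \code{truth.json} are written there.
#' @return list with \code{genome} (DNAStringSet), \code{transcripts}
#'   (GRanges as from [readTranscriptsGFF3()]) and \code{manifest} (list
#'   with \code{seed}, \code{spec}, \code{units}, \code{motifs}).
#' @export
generateSyntheticGenome <- function(spec, outDir = NULL) {
  stopifnot(inherits(spec, "syntheticGenomeSpec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  bg <- spec$background
  gl <- function() sample(spec$geneLength[1]:spec$geneLength[2], 1L)
  classes <- c(rep("qualifying", spec$nQualifying),
               rep(names(spec$decoys), spec$decoys))
  nU <- length(classes)
  if (nU == 0L) {
    genome <- Biostrings::DNAStringSet(vapply(
      seq_len(spec$nChromosomes),
      function(i) paste(.rbases(spec$chromLength, bg), collapse = ""),
      character(1)))
    names(genome) <- paste0("chr", seq_len(spec$nChromosomes))
    tx <- GenomicRanges::GRanges()
    mcols(tx)$tx_id <- character(0); mcols(tx)$gene_id <- character(0)
    mcols(tx)$cds_start <- integer(0); mcols(tx)$cds_end <- integer(0)
    manifest <- list(seed = spec$seed, spec = unclass(spec),
                     units = data.frame(), motifs = data.frame())
    res <- list(genome = genome, transcripts = tx, manifest = manifest)
    if (!is.null(outDir)) .write_synth(res, outDir)
    return(res)
  }
  chrom_of <- paste0("chr", ((seq_len(nU) - 1L) %% spec$nChromosomes) + 1L)

  segs <- stats::setNames(vector("list", spec$nChromosomes),
                          paste0("chr", seq_len(spec$nChromosomes)))
  cursor <- stats::setNames(rep(1L, spec$nChromosomes), names(segs))
  txrec <- list()
  units <- list()
  motifs <- list()
  qual_i <- 0L

  emit <- function(cc, s) {
    segs[[cc]][[length(segs[[cc]]) + 1L]] <<- s
    cursor[cc] <<- cursor[cc] + nchar(s)
  }
  add_tx <- function(cc, start, end, strand, gid, tid, cs, ce) {
    txrec[[length(txrec) + 1L]] <<- data.frame(
      chrom = cc, start = start, end = end, strand = strand,
      gene_id = gid, tx_id = tid, cds_start = cs, cds_end = ce,
      stringsAsFactors = FALSE)
  }

  for (u in seq_len(nU)) {
    cls <- classes[u]
    cc <- chrom_of[u]
    # inter-unit buffer wider than the scan window, so no cross-unit TSS
    # pair can ever satisfy the distance predicate
    emit(cc, paste(.rbases(sample((spec$maxGap + 50L):(spec$maxGap + 200L),
                                  1L), bg), collapse = ""))

    gid <- function(tag) sprintf("SYNG%02d%s", u, tag)
    tid <- function(tag) sprintf("SYNT%02d%s", u, tag)

    if (cls %in% c("qualifying", "too_close", "too_far",
                   "single_gbox", "intervening")) {
      L <- switch(cls,
        too_close = sample(30:(spec$minGap - 1L), 1L),
        too_far = sample((spec$maxGap + 1L):(spec$maxGap + 300L), 1L),
        intervening = sample(max(spec$minGap, 450L):spec$maxGap, 1L),
        sample(spec$minGap:spec$maxGap, 1L))
      if (cls == "qualifying") {
        qual_i <- qual_i + 1L
        gbox_n <- if (qual_i == 1L) 3L else 2L + (qual_i %% 2L)
        ce3_here <- qual_i == 1L
        dre <- ce3_here || qual_i %% 3L == 0L
      } else {
        gbox_n <- if (cls == "single_gbox") 1L else 2L
        ce3_here <- FALSE
        dre <- FALSE
      }
      dre_strand <- if (u %% 2L == 1L) "+" else "-"
      inner_rel <- NA_integer_
      limit <- L
      if (cls == "intervening") {
        inner_rel <- (L - 100L) %/% 2L + 1L
        limit <- inner_rel - 10L
      }
      reg <- .plant_region(L, gbox_n, dre, dre_strand, ce3_here,
                           spec$ce3Gap, spec$ce3, bg, spec$maxRedraws,
                           limit = limit)
      gl1 <- gl(); gl2 <- gl()
      rv_s <- cursor[cc]; rv_e <- rv_s + gl1 - 1L
      emit(cc, paste(.rbases(gl1, bg), collapse = ""))
      reg_s <- cursor[cc]
      emit(cc, reg$seq)
      fw_s <- cursor[cc]; fw_e <- fw_s + gl2 - 1L
      emit(cc, paste(.rbases(gl2, bg), collapse = ""))

      add_tx(cc, rv_s, rv_e, "-", gid("A"), tid("A"),
             rv_s + 30L, rv_e - spec$utr5)
      add_tx(cc, fw_s, fw_e, "+", gid("B"), tid("B"),
             fw_s + spec$utr5, fw_e - 30L)
      inner_gene <- NA_character_
      if (cls == "intervening") {
        ia <- reg_s + inner_rel - 1L
        inner_gene <- gid("I")
        # minus strand: the inner gene can then never pair divergently with
        # the planted G-boxes on its left (same strand as gene A), and its
        # own divergent pairing with gene B sees only motif-free sequence
        add_tx(cc, ia, ia + 99L, "-", inner_gene, tid("I"),
               ia + 20L, ia + 79L)
      }
      units[[u]] <- data.frame(
        unit = u, class = cls, qualifying = cls == "qualifying",
        chrom = cc, gene_a = gid("A"), gene_b = gid("B"),
        strand_a = "-", strand_b = "+",
        tss_a = rv_e, tss_b = fw_s,
        region_start = reg_s, region_end = reg_s + L - 1L, region_len = L,
        gbox_n = gbox_n, dre = dre, ce3 = ce3_here,
        ce3_gap = if (ce3_here) spec$ce3Gap else NA_integer_,
        len_atg = L + 2L * spec$utr5,
        inner_gene = inner_gene, stringsAsFactors = FALSE)
      motifs[[u]] <- cbind(unit = u, chrom = cc, reg$motifs,
                           start_abs = reg_s + reg$motifs$start - 1L)
    } else if (cls == "same_strand") {
      L <- sample(spec$minGap:spec$maxGap, 1L)
      reg <- .plant_region(L, 2L, FALSE, "+", FALSE, spec$ce3Gap, spec$ce3,
                           bg, spec$maxRedraws)
      gl1 <- gl(); gl2 <- gl()
      a_s <- cursor[cc]; a_e <- a_s + gl1 - 1L
      emit(cc, paste(.rbases(gl1, bg), collapse = ""))
      reg_s <- cursor[cc]; emit(cc, reg$seq)
      b_s <- cursor[cc]; b_e <- b_s + gl2 - 1L
      emit(cc, paste(.rbases(gl2, bg), collapse = ""))
      add_tx(cc, a_s, a_e, "+", gid("A"), tid("A"),
             a_s + spec$utr5, a_e - 30L)
      add_tx(cc, b_s, b_e, "+", gid("B"), tid("B"),
             b_s + spec$utr5, b_e - 30L)
      units[[u]] <- data.frame(
        unit = u, class = cls, qualifying = FALSE, chrom = cc,
        gene_a = gid("A"), gene_b = gid("B"),
        strand_a = "+", strand_b = "+", tss_a = a_s, tss_b = b_s,
        region_start = reg_s, region_end = reg_s + L - 1L, region_len = L,
        gbox_n = 2L, dre = FALSE, ce3 = FALSE, ce3_gap = NA_integer_,
        len_atg = NA_integer_, inner_gene = NA_character_,
        stringsAsFactors = FALSE)
      motifs[[u]] <- cbind(unit = u, chrom = cc, reg$motifs,
                           start_abs = reg_s + reg$motifs$start - 1L)
    } else if (cls == "convergent") {
      # short genes facing each other: opposite strands, TSS spacing inside
      # the window, but transcription is inward, not outward
      gl1 <- 120L; gl2 <- 120L
      # choose the mid gap so the (convergent) TSS spacing lands in the
      # window: spacing = gl1 + L + gl2 - 2
      lo <- max(30L, spec$minGap - gl1 - gl2 + 2L)
      hi <- spec$maxGap - gl1 - gl2 + 2L
      if (hi < lo)
        stop("generation error: window too narrow for a convergent decoy")
      L <- sample(lo:hi, 1L)
      reg <- .plant_region(L, 2L, FALSE, "+", FALSE, spec$ce3Gap, spec$ce3,
                           bg, spec$maxRedraws)
      a_s <- cursor[cc]; a_e <- a_s + gl1 - 1L
      emit(cc, paste(.rbases(gl1, bg), collapse = ""))
      reg_s <- cursor[cc]; emit(cc, reg$seq)
      b_s <- cursor[cc]; b_e <- b_s + gl2 - 1L
      emit(cc, paste(.rbases(gl2, bg), collapse = ""))
      add_tx(cc, a_s, a_e, "+", gid("A"), tid("A"),
             a_s + spec$utr5, a_e - 10L)
      add_tx(cc, b_s, b_e, "-", gid("B"), tid("B"),
             b_s + 10L, b_e - spec$utr5)
      units[[u]] <- data.frame(
        unit = u, class = cls, qualifying = FALSE, chrom = cc,
        gene_a = gid("A"), gene_b = gid("B"),
        strand_a = "+", strand_b = "-", tss_a = a_s, tss_b = b_e,
        region_start = reg_s, region_end = reg_s + L - 1L, region_len = L,
        gbox_n = 2L, dre = FALSE, ce3 = FALSE, ce3_gap = NA_integer_,
        len_atg = NA_integer_, inner_gene = NA_character_,
        stringsAsFactors = FALSE)
      motifs[[u]] <- cbind(unit = u, chrom = cc, reg$motifs,
                           start_abs = reg_s + reg$motifs$start - 1L)
    } else stop("unknown unit class: ", cls)
  }

  for (cc in names(segs)) {
    used <- cursor[cc] - 1L
    if (used > spec$chromLength)
      stop(sprintf("generation error: %s needs %d bp but chromLength is %d",
                   cc, used, spec$chromLength))
    if (used < spec$chromLength)
      emit(cc, paste(.rbases(spec$chromLength - used, bg), collapse = ""))
  }

  genome <- Biostrings::DNAStringSet(vapply(
    segs, function(x) paste(unlist(x), collapse = ""), character(1)))
  names(genome) <- names(segs)
  txdf <- do.call(rbind, txrec)
  tx <- GenomicRanges::GRanges(txdf$chrom,
                               IRanges::IRanges(txdf$start, txdf$end),
                               strand = txdf$strand)
  mcols(tx)$tx_id <- txdf$tx_id
  mcols(tx)$gene_id <- txdf$gene_id
  mcols(tx)$cds_start <- txdf$cds_start
  mcols(tx)$cds_end <- txdf$cds_end

  mo <- do.call(rbind, motifs)
  rownames(mo) <- NULL
  names(mo)[names(mo) == "start"] <- "start_rel"
  manifest <- list(seed = spec$seed, spec = unclass(spec),
                   units = do.call(rbind, units), motifs = mo)
  res <- list(genome = genome, transcripts = tx, manifest = manifest)
  if (!is.null(outDir)) .write_synth(res, outDir)
  res
}

.write_synth <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeGenomeFASTA(res$genome, file.path(outDir, "genome.fa"))
  writeTranscriptsGFF3(res$transcripts, file.path(outDir, "genes.gff3"))
  jsonlite::write_json(res$manifest, file.path(outDir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  invisible(outDir)
}

#' Write a genome as FASTA
#' @param genome a DNAStringSet
#' @param path output file
#' @param width line wrap width
#' @return \code{path}, invisibly
#' @export
writeGenomeFASTA <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(genome, path, width = width)
  invisible(path)
}

#' Write transcript models as GFF3
#'
#' Emits one gene/mRNA/exon/CDS block per transcript (single-exon models),
#' 1-based inclusive coordinates, deterministic attribute order — so the
#' same input always produces identical bytes.
#'
#' @param tx transcript GRanges (as returned by [readTranscriptsGFF3()] or
#'   the generator)
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeTranscriptsGFF3 <- function(tx, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  m <- mcols(tx)
  for (i in seq_along(tx)) {
    cc <- as.character(GenomicRanges::seqnames(tx))[i]
    s <- GenomicRanges::start(tx)[i]; e <- GenomicRanges::end(tx)[i]
    st <- as.character(GenomicRanges::strand(tx))[i]
    g <- m$gene_id[i]; t <- m$tx_id[i]
    ln <- function(type, a, b, attr, phase = ".")
      sprintf("%s\tBidiProm\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              cc, type, a, b, st, phase, attr)
    writeLines(c(
      ln("gene", s, e, sprintf("ID=%s", g)),
      ln("mRNA", s, e, sprintf("ID=%s;Parent=%s", t, g)),
      ln("exon", s, e, sprintf("ID=%s.exon1;Parent=%s", t, t))), con)
    if (!is.na(m$cds_start[i]))
      writeLines(ln("CDS", m$cds_start[i], m$cds_end[i],
                    sprintf("ID=%s.cds;Parent=%s", t, t), phase = "0"), con)
  }
  invisible(path)
}

#' Verify a synthetic genome against its ground-truth manifest
#'
#' Re-scans every manifest region and confirms (i) each planted motif
#' matches its recorded literal at its recorded offset, (ii) no unplanted
#' catalog motif occurs in any sanitized region, and (iii) every recorded
#' TSS agrees with the transcript models. Discrepancies are report content,
#' not errors.
#'
#' @param genome DNAStringSet
#' @param transcripts transcript GRanges
#' @param manifest the generator's manifest list
#' @return list with \code{ok} (logical) and \code{discrepancies}
#'   (data.frame: unit, check, detail; first row is the first discrepancy)
#' @export
verifyGroundTruth <- function(genome, transcripts, manifest) {
  ce3 <- manifest$spec$ce3
  un <- manifest$units
  mo <- manifest$motifs
  disc <- list()
  note <- function(unit, check, detail)
    disc[[length(disc) + 1L]] <<- data.frame(
      unit = unit, check = check, detail = detail, stringsAsFactors = FALSE)
  tss <- if (length(transcripts)) tssOf(transcripts) else integer(0)
  gmap <- if (length(transcripts))
    stats::setNames(tss, mcols(transcripts)$gene_id) else integer(0)

  for (i in seq_len(NROW(un))) {
    u <- un$unit[i]
    s <- as.character(Biostrings::subseq(genome[[un$chrom[i]]],
                                         un$region_start[i],
                                         un$region_end[i]))
    pm <- mo[mo$unit == u, , drop = FALSE]
    for (j in seq_len(nrow(pm))) {
      lit <- pm$literal[j]
      got <- substr(s, pm$start_rel[j], pm$start_rel[j] + nchar(lit) - 1L)
      if (!identical(got, lit))
        note(u, "planted_literal",
             sprintf("%s at offset %d reads %s, expected %s",
                     pm$motif[j], pm$start_rel[j], got, lit))
    }
    got <- .scan_region(s, ce3)
    key <- function(d) paste(d$motif, d$start, d$strand)
    kg <- key(got)
    kp <- paste(pm$motif, pm$start_rel, pm$strand)
    for (k in setdiff(kp, kg))
      note(u, "missing_planted", sprintf("planted hit absent: %s", k))
    for (k in setdiff(kg, kp))
      note(u, "unplanted_hit", sprintf("unexpected hit: %s", k))
    for (g in c("gene_a", "gene_b")) {
      gg <- un[[g]][i]
      want <- if (g == "gene_a") un$tss_a[i] else un$tss_b[i]
      if (!gg %in% names(gmap))
        note(u, "missing_gene", gg)
      else if (gmap[[gg]] != want)
        note(u, "tss_mismatch",
             sprintf("%s TSS %d, manifest says %d", gg, gmap[[gg]], want))
    }
  }
  disc <- if (length(disc)) do.call(rbind, disc) else
    data.frame(unit = integer(0), check = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  list(ok = nrow(disc) == 0L, discrepancies = disc)
}
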