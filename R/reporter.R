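.tsv_cols <- c("FWgene", "RVgene", "len", "DRE", "CE3", "gbox_n", "acgt_n",
               "FWannotation", "RVannotation", "FWlocation", "RVlocation")

.fixture_cols <- c("FWgene", "RVgene", "len", "DRE", "CE3",
                   "FWannotation", "RVannotation", "FWlocation", "RVlocation")

.join_gene_table <- function(tab, what) {
  if (is.null(tab)) return(NULL)
  tab <- as.data.frame(tab)
  if (!"gene_id" %in% colnames(tab))
    stop(what, " table must have a 'gene_id' column")
  dup <- unique(tab$gene_id[duplicated(tab$gene_id)])
  if (length(dup))
    stop(what, " table has duplicate gene id(s): ",
         paste(dup, collapse = ", "))
  tab
}

.lookup <- function(tab, col, ids) {
  if (is.null(tab) || !col %in% colnames(tab))
    return(rep(NA_character_, length(ids)))
  as.character(tab[[col]])[match(ids, tab$gene_id)]
}

#' Build the candidate bidirectional-promoter table
#'
#' Runs every divergent pair through the cis-element filter: the intergenic
#' sequence is extracted, scanned with the motif catalog, and retained when
#' it carries at least the catalog's G-box copy threshold (default 2).
#' Surviving pairs become candidate records with G-box/ACGT counts and
#' DRE/CE3 presence flags, optionally joined to user-supplied per-gene
#' annotation and subcellular localization tables.
#'
#' @param pairs a [DivergentPairSet-class] from [findDivergentPairs()].
#' @param genome a \link[Biostrings]{DNAStringSet}.
#' @param catalog a [MotifCatalog-class]; its \code{GBOX} entry's
#'   \code{min_copies} is the filter threshold.
#' @param annotations optional data.frame with columns \code{gene_id},
#'   \code{annotation} and/or \code{location}; duplicate gene ids are an
#'   error.
#' @return a [CandidateSet-class], in the pair set's order.
#' @export
buildCandidateTable <- function(pairs, genome, catalog = defaultMotifCatalog(),
                                annotations = NULL) {
  stopifnot(is(pairs, "DivergentPairSet"), is(catalog, "MotifCatalog"))
  pairs <- extractIntergenic(pairs, genome)
  p <- pairs@pairs
  ann <- .join_gene_table(annotations, "annotation")
  ct <- catalog@table
  min_gbox <- if ("GBOX" %in% ct$name) ct$min_copies[ct$name == "GBOX"] else 2L

  keep <- logical(nrow(p))
  res <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    res[[i]] <- annotateElements(p$sequence[i], catalog)
    keep[i] <- res[[i]]$gbox_n >= min_gbox
  }
  p <- p[keep, , drop = FALSE]
  res <- res[keep]
  rec <- DataFrame(
    fw_gene = p$fw_gene, rv_gene = p$rv_gene,
    len = p$len_tss,
    gbox_n = vapply(res, function(r) r$gbox_n, integer(1)),
    dre = vapply(res, function(r) r$dre, logical(1)),
    ce3 = vapply(res, function(r) r$ce3, logical(1)),
    acgt_n = vapply(res, function(r) r$acgt_n, integer(1)),
    fw_annotation = .lookup(ann, "annotation", p$fw_gene),
    rv_annotation = .lookup(ann, "annotation", p$rv_gene),
    fw_location = .lookup(ann, "location", p$fw_gene),
    rv_location = .lookup(ann, "location", p$rv_gene),
    chrom = p$chrom,
    interior_start = p$interior_start, interior_end = p$interior_end)
  hits <- lapply(res, function(r) do.call(rbind, unname(r$hits)))
  new("CandidateSet", records = rec, hits = hits)
}

#' Write a candidate table as TSV
#'
#' Fixed column order \code{FWgene RVgene len DRE CE3 gbox_n acgt_n
#' FWannotation RVannotation FWlocation RVlocation}; the DRE/CE3 flags are
#' serialized in the y/blank dialect used by the published candidate
#' tables.
#'
#' @param x a [CandidateSet-class]
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeCandidateTSV <- function(x, path) {
  stopifnot(is(x, "CandidateSet"))
  r <- as.data.frame(x@records)
  out <- data.frame(
    FWgene = r$fw_gene, RVgene = r$rv_gene, len = r$len,
    DRE = ifelse(r$dre, "y", ""), CE3 = ifelse(r$ce3, "y", ""),
    gbox_n = r$gbox_n, acgt_n = r$acgt_n,
    FWannotation = ifelse(is.na(r$fw_annotation), "", r$fw_annotation),
    RVannotation = ifelse(is.na(r$rv_annotation), "", r$rv_annotation),
    FWlocation = ifelse(is.na(r$fw_location), "", r$fw_location),
    RVlocation = ifelse(is.na(r$rv_location), "", r$rv_location),
    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a candidate table written by [writeCandidateTSV()]
#' @param path TSV file
#' @return a [CandidateSet-class] (without motif hit detail)
#' @export
readCandidateTSV <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  if (!identical(colnames(d), .tsv_cols))
    stop("unexpected candidate TSV schema in ", path)
  blank_na <- function(x) ifelse(nzchar(x), x, NA_character_)
  rec <- DataFrame(
    fw_gene = d$FWgene, rv_gene = d$RVgene, len = as.integer(d$len),
    gbox_n = as.integer(d$gbox_n),
    dre = d$DRE == "y", ce3 = d$CE3 == "y",
    acgt_n = as.integer(d$acgt_n),
    fw_annotation = blank_na(d$FWannotation),
    rv_annotation = blank_na(d$RVannotation),
    fw_location = blank_na(d$FWlocation),
    rv_location = blank_na(d$RVlocation))
  new("CandidateSet", records = rec, hits = list())
}

#' Export candidate motif hits as BED6
#'
#' One BED record per motif hit across all candidate pairs, converted to
#' 0-based half-open genome coordinates; name \code{motif:rv_gene|fw_gene},
#' score 0, strand from the hit.
#'
#' @param x a [CandidateSet-class] built by [buildCandidateTable()] (hit
#'   detail required)
#' @param path output BED file
#' @return \code{path}, invisibly
#' @export
#' @importFrom rtracklayer export
writeHitsBED <- function(x, path) {
  stopifnot(is(x, "CandidateSet"))
  if (!length(x@hits))
    stop("candidate set carries no motif hit detail (read from TSV?)")
  r <- x@records
  rows <- list()
  for (i in seq_len(nrow(r))) {
    h <- x@hits[[i]]
    if (is.null(h) || nrow(h) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = r$chrom[i],
      start = r$interior_start[i] + h$start - 1L,
      end = r$interior_start[i] + h$start - 1L + nchar(h$matched) - 1L,
      name = paste0(h$motif, ":", r$rv_gene[i], "|", r$fw_gene[i]),
      strand = h$strand, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  mcols(gr)$name <- df$name
  mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Load the packaged 70-pair Arabidopsis candidate table
#'
#' The published genome-wide scan of Arabidopsis (TSS window 100-600 bp,
#' two or more G-boxes) yielded 70 divergent gene pairs; this fixture is a
#' transcription of that table (gene ids, intergenic length, DRE/CE3 flags,
#' functional annotations and predicted localizations), shipped with the
#' package so downstream summaries run with no download. G-box/ACGT counts
#' were not printed in the source table and load as \code{NA}.
#'
#' @return a [CandidateSet-class] with 70 records
#' @export
loadTable1Fixture <- function() {
  path <- system.file("extdata", "arabidopsis_70_pairs.tsv",
                      package = "BidiProm", mustWork = TRUE)
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  if (!identical(colnames(d), .fixture_cols))
    stop("fixture integrity error: unexpected column schema")
  if (nrow(d) != 70L)
    stop("fixture integrity error: expected 70 rows, found ", nrow(d))
  if (!all(d$DRE %in% c("y", "")) || !all(d$CE3 %in% c("y", "")))
    stop("fixture integrity error: DRE/CE3 must be 'y' or blank")
  rec <- DataFrame(
    fw_gene = d$FWgene, rv_gene = d$RVgene, len = as.integer(d$len),
    gbox_n = NA_integer_,
    dre = d$DRE == "y", ce3 = d$CE3 == "y",
    acgt_n = NA_integer_,
    fw_annotation = d$FWannotation, rv_annotation = d$RVannotation,
    fw_location = d$FWlocation, rv_location = d$RVlocation)
  new("CandidateSet", records = rec, hits = list())
}

#' Summarize subcellular localization labels over a candidate table
#'
#' Counts every gene (two per pair) by its verbatim localization label and,
#' optionally, by a user-supplied label-to-group map (e.g. collapsing
#' ER/golgi/membrane labels into an endomembrane group — grouping rules
#' differ between prediction tools, so they are configuration, not code).
#' Genes without a label are counted under \code{"unspecified"}.
#'
#' @param x a [CandidateSet-class]
#' @param groupMap optional named character vector mapping verbatim labels
#'   to group names; unmapped labels keep their own name.
#' @return a list with data.frames \code{by_label} and (when a map is
#'   given) \code{by_group}, each with columns \code{label}, \code{count},
#'   \code{proportion} (proportions sum to 1).
#' @export
summarizeLocalizations <- function(x, groupMap = NULL) {
  stopifnot(is(x, "CandidateSet"))
  r <- x@records
  labs <- c(as.character(r$fw_location), as.character(r$rv_location))
  if (length(labs) == 0L)
    return(list(by_label = data.frame(label = character(0),
                                      count = integer(0),
                                      proportion = numeric(0))))
  labs[is.na(labs) | !nzchar(labs)] <- "unspecified"
  tab <- function(v) {
    tt <- sort(table(v), decreasing = TRUE)
    data.frame(label = names(tt), count = as.integer(tt),
               proportion = as.integer(tt) / length(v),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- list(by_label = tab(labs))
  if (!is.null(groupMap)) {
    g <- ifelse(labs %in% names(groupMap), groupMap[labs], labs)
    out$by_group <- tab(unname(g))
  }
  out
}

#' Pearson co-expression of a divergent gene pair
#'
#' Correlation of the two genes' expression vectors over shared samples —
#' a quantitative stand-in for eyeballing expression-atlas profiles when
#' judging whether a shared promoter drives coordinated expression.
#'
#' @param expr numeric matrix or data.frame, genes in rows (rownames are
#'   gene ids, or a first column named \code{gene_id}), samples in columns.
#' @param geneA,geneB gene ids; both must be present.
#' @return Pearson correlation in [-1, 1]; \code{NA} with a warning when
#'   either vector has zero variance.
#' @export
coexpressionScore <- function(expr, geneA, geneB) {
  if (is.data.frame(expr) && "gene_id" %in% colnames(expr)) {
    rn <- expr$gene_id
    expr <- as.matrix(expr[, setdiff(colnames(expr), "gene_id"), drop = FALSE])
    rownames(expr) <- rn
  }
  expr <- as.matrix(expr)
  missing <- setdiff(c(geneA, geneB), rownames(expr))
  if (length(missing))
    stop("gene(s) not in expression matrix: ", paste(missing, collapse = ", "))
  a <- as.numeric(expr[geneA, ])
  b <- as.numeric(expr[geneB, ])
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L)
    stop("fewer than 3 shared samples for ", geneA, " / ", geneB)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    warning("zero-variance expression vector; co-expression undefined")
    return(NA_real_)
  }
  stats::cor(a[ok], b[ok])
}
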