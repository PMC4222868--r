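# Independent oracles for property tests. These deliberately re-derive
# semantics from scratch (own IUPAC table, regex engine, exhaustive loops)
# rather than calling back into the package's scanning code.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A",
                 R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                 B = "V", D = "H", H = "D", V = "B", N = "N")

oracle_revcomp <- function(p)
  paste(rev(unname(ORACLE_COMP[strsplit(p, "")[[1]]])), collapse = "")

# truly naive matcher: loop over every offset, check every position
naive_starts <- function(seq, pattern) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  k <- length(p); n <- length(s) - k + 1L
  out <- integer(0)
  for (i in seq_len(max(0L, n))) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!s[i + j - 1L] %in% ORACLE_IUPAC[[p[j]]]) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, i)
  }
  out
}

naive_scan <- function(seq, pattern, strandPolicy = "both") {
  rc <- oracle_revcomp(pattern)
  fw <- naive_starts(seq, pattern)
  df <- data.frame(start = fw, strand = rep("+", length(fw)))
  if (strandPolicy == "both" && !identical(pattern, rc)) {
    rv <- naive_starts(seq, rc)
    df <- rbind(df, data.frame(start = rv, strand = rep("-", length(rv))))
  }
  df[order(df$start, df$strand), , drop = FALSE]
}

# PCRE lookahead matcher: an independent engine, fast enough for big sweeps
regex_starts <- function(seq, pattern) {
  cls <- vapply(strsplit(pattern, "")[[1]], function(ch)
    paste0("[", paste(ORACLE_IUPAC[[ch]], collapse = ""), "]"), character(1))
  m <- gregexpr(paste0("(?=", paste(cls, collapse = ""), ")"), seq,
                perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

regex_scan <- function(seq, pattern, strandPolicy = "both") {
  rc <- oracle_revcomp(pattern)
  fw <- regex_starts(seq, pattern)
  df <- data.frame(start = fw, strand = rep("+", length(fw)))
  if (strandPolicy == "both" && !identical(pattern, rc)) {
    rv <- regex_starts(seq, rc)
    df <- rbind(df, data.frame(start = rv, strand = rep("-", length(rv))))
  }
  df[order(df$start, df$strand), , drop = FALSE]
}

rand_seq <- function(n, prob = rep(0.25, 4))
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")

# exhaustive all-pairs divergent-pair filter over a transcript table
# (chrom, start, end, strand, tx_id, gene_id, cds_start, cds_end)
brute_force_pairs <- function(df, minDist = 100, maxDist = 600,
                              requireNoIntervening = TRUE) {
  tss <- ifelse(df$strand == "+", df$start, df$end)
  hits <- list()
  for (a in seq_len(nrow(df))) for (b in seq_len(nrow(df))) {
    if (a == b) next
    if (df$strand[a] != "-" || df$strand[b] != "+") next
    if (df$chrom[a] != df$chrom[b]) next
    if (tss[a] >= tss[b]) next
    len <- tss[b] - tss[a] - 1L
    if (len < minDist || len > maxDist) next
    if (requireNoIntervening) {
      blocked <- FALSE
      for (o in seq_len(nrow(df))) {
        if (o %in% c(a, b) || df$chrom[o] != df$chrom[a]) next
        if (df$start[o] <= tss[b] - 1L && df$end[o] >= tss[a] + 1L) {
          blocked <- TRUE; break
        }
      }
      if (blocked) next
    }
    hits[[length(hits) + 1L]] <- data.frame(
      rv_gene = df$gene_id[a], fw_gene = df$gene_id[b],
      rv_tx = df$tx_id[a], fw_tx = df$tx_id[b],
      len_tss = len, stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(rv_gene = character(0), fw_gene = character(0),
                      len_tss = integer(0)))
  h <- do.call(rbind, hits)
  # gene-level collapse: keep smallest len_tss, ties by transcript ids
  h <- h[order(h$rv_gene, h$fw_gene, h$len_tss, h$rv_tx, h$fw_tx), ]
  h[!duplicated(paste(h$rv_gene, h$fw_gene)), ]
}

# four-way gamete enumeration for selfing genotype expectations
enumerate_selfing <- function(m, f, lethal = FALSE) {
  male <- c(ins = m, wt = 1) / (m + 1)
  female <- c(ins = f, wt = 1) / (f + 1)
  geno <- c(homozygous_insert = 0, heterozygous = 0, wild_type = 0)
  for (gm in names(male)) for (gf in names(female)) {
    w <- male[[gm]] * female[[gf]]
    cls <- if (gm == "ins" && gf == "ins") "homozygous_insert"
           else if (gm == "wt" && gf == "wt") "wild_type"
           else "heterozygous"
    geno[cls] <- geno[cls] + w
  }
  if (lethal) geno["homozygous_insert"] <- 0
  geno / sum(geno)
}

# minimal transcript GRanges builder for toy annotations
toy_tx <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$tx_id <- df$tx_id
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$cds_start <-
    if ("cds_start" %in% names(df)) df$cds_start else NA_integer_
  S4Vectors::mcols(gr)$cds_end <-
    if ("cds_end" %in% names(df)) df$cds_end else NA_integer_
  gr
}
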