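test_that("a clean head-to-head pair inside the window is accepted", {
  tx <- toy_tx(data.frame(
    chrom = "chr1", start = c(500L, 1300L), end = c(1000L, 1800L),
    strand = c("-", "+"), tx_id = c("r1", "f1"), gene_id = c("gr", "gf"),
    cds_start = c(550L, 1350L), cds_end = c(950L, 1750L)))
  dp <- findDivergentPairs(tx)
  expect_equal(length(dp), 1L)
  p <- as.data.frame(dp)
  expect_equal(p$tss_rv, 1000L)
  expect_equal(p$tss_fw, 1300L)
  expect_equal(p$len_tss, 299L)
  expect_equal(p$interior_start, 1001L)
  expect_equal(p$interior_end, 1299L)
  # start-codon distance uses the same exclusive convention
  expect_equal(startCodonDistance(dp), 1350L - 950L - 1L)
})

test_that("window boundaries are inclusive and violations excluded", {
  mk <- function(tss_fw) toy_tx(data.frame(
    chrom = "chr1", start = c(500L, tss_fw), end = c(1000L, tss_fw + 400L),
    strand = c("-", "+"), tx_id = c("r", "f"), gene_id = c("r", "f")))
  expect_equal(length(findDivergentPairs(mk(1100L))), 0L)  # len 99
  expect_equal(length(findDivergentPairs(mk(1101L))), 1L)  # len 100
  expect_equal(length(findDivergentPairs(mk(1601L))), 1L)  # len 600
  expect_equal(length(findDivergentPairs(mk(1602L))), 0L)  # len 601
  expect_error(findDivergentPairs(mk(1200L), minDist = 500, maxDist = 100),
               "configuration")
})

test_that("same-strand and convergent arrangements are never paired", {
  same <- toy_tx(data.frame(
    chrom = "chr1", start = c(100L, 700L), end = c(500L, 1100L),
    strand = c("+", "+"), tx_id = c("a", "b"), gene_id = c("a", "b")))
  expect_equal(length(findDivergentPairs(same)), 0L)
  conv <- toy_tx(data.frame(
    chrom = "chr1", start = c(100L, 500L), end = c(300L, 700L),
    strand = c("+", "-"), tx_id = c("a", "b"), gene_id = c("a", "b")))
  expect_equal(length(findDivergentPairs(conv)), 0L)
  # opposite chromosomes never pair
  twochr <- toy_tx(data.frame(
    chrom = c("chr1", "chr2"), start = c(500L, 1300L), end = c(1000L, 1700L),
    strand = c("-", "+"), tx_id = c("r", "f"), gene_id = c("r", "f")))
  expect_equal(length(findDivergentPairs(twochr)), 0L)
})

test_that("an intervening transcript vetoes the pair unless allowed", {
  tx <- toy_tx(data.frame(
    chrom = "chr1",
    start = c(500L, 1300L, 1100L), end = c(1000L, 1800L, 1200L),
    strand = c("-", "+", "+"),
    tx_id = c("r", "f", "mid"), gene_id = c("r", "f", "mid")))
  expect_equal(length(findDivergentPairs(tx)), 0L)
  dp <- findDivergentPairs(tx, requireNoIntervening = FALSE)
  expect_true("r" %in% as.data.frame(dp)$rv_gene)
})

test_that("scan equals the exhaustive all-pairs oracle on a 12-transcript toy", {
  set.seed(99)
  df <- data.frame(
    chrom = rep(c("chr1", "chr2"), each = 6),
    start = c(100, 900, 1500, 2600, 3100, 4200,
              50, 700, 820, 2100, 2700, 3900),
    end = c(700, 1400, 2300, 3000, 3900, 4800,
            600, 800, 1700, 2600, 3600, 4500),
    strand = c("-", "+", "-", "+", "-", "+",
               "-", "-", "+", "-", "+", "+"),
    tx_id = sprintf("t%02d", 1:12), gene_id = sprintf("g%02d", 1:12))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  tx <- toy_tx(df)
  for (noInt in c(TRUE, FALSE)) {
    got <- as.data.frame(findDivergentPairs(tx, requireNoIntervening = noInt))
    want <- brute_force_pairs(df, requireNoIntervening = noInt)
    expect_setequal(paste(got$rv_gene, got$fw_gene, got$len_tss),
                    paste(want$rv_gene, want$fw_gene, want$len_tss))
  }
})

test_that("pair scan matches the brute-force oracle on random annotations", {
  set.seed(123)
  for (rep in 1:15) {
    n <- sample(6:14, 1)
    starts <- sort(sample.int(8000, n))
    df <- data.frame(
      chrom = sample(c("chrA", "chrB"), n, replace = TRUE),
      start = starts, end = starts + sample(200:800, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      tx_id = sprintf("t%02d", seq_len(n)),
      gene_id = sprintf("g%02d", seq_len(n)))
    tx <- toy_tx(df)
    got <- as.data.frame(findDivergentPairs(tx))
    want <- brute_force_pairs(df)
    expect_setequal(paste(got$rv_gene, got$fw_gene, got$len_tss),
                    paste(want$rv_gene, want$fw_gene, want$len_tss))
    # all accepted lengths inside the window
    if (nrow(got))
      expect_true(all(got$len_tss >= 100 & got$len_tss <= 600))
  }
})

test_that("isoform combinations collapse to the tightest gene pair", {
  tx <- toy_tx(data.frame(
    chrom = "chr1",
    start = c(500L, 500L, 1300L), end = c(1000L, 1100L, 1800L),
    strand = c("-", "-", "+"),
    tx_id = c("rA.1", "rA.2", "f.1"), gene_id = c("gr", "gr", "gf")))
  dp <- findDivergentPairs(tx)
  p <- as.data.frame(dp)
  expect_equal(nrow(p), 1L)
  expect_equal(p$rv_tx, "rA.2")      # TSS 1100, len 199 < len 299
  expect_equal(p$len_tss, 199L)
})

test_that("output order is deterministic: chrom, then minus-strand TSS", {
  df <- data.frame(
    chrom = c("chr2", "chr2", "chr1"),
    start = c(3000L, 500L, 500L), end = c(3500L, 1000L, 1000L),
    strand = c("-", "-", "-"),
    tx_id = c("r3", "r2", "r1"), gene_id = c("r3", "r2", "r1"))
  fw <- data.frame(
    chrom = c("chr2", "chr2", "chr1"),
    start = c(3800L, 1300L, 1300L), end = c(4200L, 1700L, 1700L),
    strand = "+", tx_id = c("f3", "f2", "f1"), gene_id = c("f3", "f2", "f1"))
  tx <- toy_tx(rbind(df, fw))
  p <- as.data.frame(findDivergentPairs(tx))
  expect_equal(p$chrom, c("chr1", "chr2", "chr2"))
  expect_equal(p$tss_rv, c(1000L, 1000L, 3500L))
  # identical input, identical output
  p2 <- as.data.frame(findDivergentPairs(tx))
  expect_identical(p, p2)
})

test_that("interior extraction slices the plus strand and flags bad coordinates", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAAACGTGGG"))
  tx <- toy_tx(data.frame(
    chrom = "chr1", start = c(2L, 8L), end = c(4L, 10L),
    strand = c("-", "+"), tx_id = c("r", "f"), gene_id = c("r", "f")))
  dp <- findDivergentPairs(tx, minDist = 0, maxDist = 10)
  dp <- extractIntergenic(dp, genome)
  expect_equal(unname(pairSequences(dp)), "CGT")   # interval (5,7)
  expect_equal(Biostrings::width(interiorRanges(dp)), 3L)

  # interval escaping the chromosome is a coordinate error naming the pair
  tx2 <- toy_tx(data.frame(
    chrom = "chr1", start = c(2L, 12L), end = c(4L, 20L),
    strand = c("-", "+"), tx_id = c("r", "f"), gene_id = c("r", "f")))
  dp2 <- findDivergentPairs(tx2, minDist = 0, maxDist = 10)
  expect_error(extractIntergenic(dp2, genome), "r\\|f")
})

test_that("adjacent TSSs give an empty interior and empty sequence", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 30)))
  tx <- toy_tx(data.frame(
    chrom = "chr1", start = c(2L, 11L), end = c(10L, 20L),
    strand = c("-", "+"), tx_id = c("r", "f"), gene_id = c("r", "f")))
  dp <- findDivergentPairs(tx, minDist = 0, maxDist = 5)
  expect_equal(lenTSS(dp), 0L)
  dp <- extractIntergenic(dp, genome)
  expect_equal(unname(pairSequences(dp)), "")
  # missing CDS: distance absent, not an error
  expect_true(is.na(startCodonDistance(dp)))
})

test_that("interior length always equals the extracted sequence length", {
  g <- generateSyntheticGenome(syntheticGenomeSpec(seed = 5))
  dp <- extractIntergenic(findDivergentPairs(g$transcripts), g$genome)
  expect_equal(nchar(unname(pairSequences(dp))), lenTSS(dp))
})
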