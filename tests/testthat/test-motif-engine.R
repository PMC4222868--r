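test_that("IUPAC compilation expands degenerate codes and rejects bad ones", {
  m <- compileIUPAC("CACGTG")
  expect_equal(m$k, 6L)
  expect_true(m$palindrome)
  expect_equal(m$allowed, ORACLE_IUPAC[strsplit("CACGTG", "")[[1]]],
               ignore_attr = TRUE)

  ry <- compileIUPAC("RY")
  combos <- expand.grid(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"),
                        stringsAsFactors = FALSE)
  hit <- vapply(seq_len(nrow(combos)), function(i)
    nrow(scanMotif(paste0(combos$a[i], combos$b[i]), ry,
                   strandPolicy = "forward_only")) > 0, logical(1))
  expect_setequal(paste0(combos$a, combos$b)[hit], c("AC", "AT", "GC", "GT"))

  expect_error(compileIUPAC("CAXGTG"), "'X' at position 3")
  expect_error(compileIUPAC(""), "non-empty")
  expect_equal(compileIUPAC("u")$pattern, "T")
})

test_that("scanning finds overlapping, strand-aware, palindrome-deduplicated hits", {
  h <- scanMotif("TTCACGTGTT", "CACGTG")
  expect_equal(h$start, 3L)
  expect_equal(h$strand, "+")
  expect_equal(h$matched, "CACGTG")
  expect_equal(h$left_flank, "TT")
  expect_equal(h$right_flank, "TT")

  # self-overlapping pattern: every offset reported
  h <- scanMotif("CCGACCGAC", "CCGAC")
  expect_equal(h$start, c(1L, 5L))
  expect_equal(h$strand, c("+", "+"))

  # reverse-complement hit reported at forward offset of its leftmost base
  h <- scanMotif("TTGTCGGTT", "CCGAC")
  expect_equal(h$start, 3L)
  expect_equal(h$strand, "-")
  expect_equal(h$matched, "GTCGG")

  # palindromes are counted once per offset
  h <- scanMotif("ACACGTGT", "CACGTG")
  expect_equal(nrow(h), 1L)

  # flanks are clipped, never padded
  h <- scanMotif("CACGTGA", "CACGTG")
  expect_equal(h$left_flank, "")
  expect_equal(h$right_flank, "A")

  # N in the subject matches nothing by default, anything when asked
  expect_equal(nrow(scanMotif("CACGNG", "CACGTG")), 0L)
  expect_equal(nrow(scanMotif("CACGNG", "CACGTG", nPolicy = "any")), 1L)
})

test_that("scan agrees with a naive position-by-position matcher", {
  pats <- c("CACGTG", "CCGAC", "ACGCGTGTCCTC", "ACGT", "RYCGW")
  set.seed(42)
  for (rep in 1:60) {
    s <- rand_seq(300)
    for (p in pats) {
      got <- scanMotif(s, p)[, c("start", "strand")]
      want <- naive_scan(s, p)
      expect_equal(got$start, want$start, info = p)
      expect_equal(got$strand, want$strand, info = p)
    }
  }
})

test_that("palindrome symmetry and strand duality hold", {
  set.seed(7)
  rc <- function(s) paste(rev(unname(ORACLE_COMP[strsplit(s, "")[[1]]])),
                          collapse = "")
  for (rep in 1:40) {
    s <- rand_seq(500, prob = c(0.32, 0.18, 0.18, 0.32))
    # palindromic pattern: hit count invariant under reverse complement
    expect_equal(nrow(scanMotif(s, "CACGTG")),
                 nrow(scanMotif(rc(s), "CACGTG")))
    # non-palindromic: minus hits mirror plus hits on the revcomp sequence
    h <- scanMotif(s, "CCGAC")
    minus <- h$start[h$strand == "-"]
    h2 <- scanMotif(rc(s), "CCGAC")
    plus2 <- h2$start[h2$strand == "+"]
    expect_equal(sort(nchar(s) - (minus + 5L - 1L) + 1L), sort(plus2))
  }
})

test_that("G-box counting feeds the two-or-more filter", {
  expect_equal(countGbox("TTTTTTTT"), 0L)
  set.seed(1)
  filler <- gsub("CACGTG", "ATATAT", rand_seq(50))
  two <- paste0("CACGTG", filler, "CACGTG")
  expect_equal(countGbox(two), 2L)
  expect_true(countGbox(two) >= 2L)     # the candidate filter boundary
  expect_equal(countGbox(paste0("AAA", "CACGTG", "AAA")), 1L)
})

test_that("catalog annotation sets flags and counts", {
  ann <- annotateElements("TTTCCGACTTT")
  expect_true(ann$dre); expect_false(ann$ce3)
  expect_equal(ann$gbox_n, 0L)

  ann <- annotateElements(paste0("TT", "ACGCGTGTCCTC", "TT"))
  expect_true(ann$ce3)

  ann <- annotateElements("TTACGTTT")
  expect_equal(ann$acgt_n, 1L)
  expect_false(ann$dre); expect_false(ann$ce3)
  expect_equal(ann$gbox_n, 0L)

  expect_error(annotateElements("ACGT", MotifCatalog(character(0),
                                                     character(0))),
               "empty")
  expect_error(MotifCatalog("BAD", "CAXGTG"), "invalid IUPAC")
})

test_that("element spacing measures bases strictly between elements", {
  # G-box at 1-based 11..16, CE3 starting at 22: gap 5 (the coupled
  # ABRE/CE3 geometry)
  s <- paste0(strrep("T", 10), "CACGTG", strrep("T", 5), "ACGCGTGTCCTC", "TT")
  sp <- elementSpacing(scanMotif(s, "CACGTG", motifName = "GBOX"),
                       scanMotif(s, "ACGCGTGTCCTC", motifName = "CE3"))
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$gap, 5L)

  # immediately adjacent: gap 0
  s0 <- paste0("TT", "CACGTG", "ACGCGTGTCCTC", "TT")
  sp0 <- elementSpacing(scanMotif(s0, "CACGTG"), scanMotif(s0, "ACGCGTGTCCTC"))
  expect_equal(sp0$gap, 0L)

  # overlap reported as negative; empty inputs give empty output
  a <- data.frame(motif = "A", start = 5L, strand = "+", matched = "CACGTG",
                  left_flank = "", right_flank = "")
  b <- data.frame(motif = "B", start = 8L, strand = "+", matched = "CCGAC",
                  left_flank = "", right_flank = "")
  expect_equal(elementSpacing(a, b)$gap, -3L)
  expect_equal(nrow(elementSpacing(a[0, ], b)), 0L)
})

test_that("depletion model matches closed forms and frozen exact tails", {
  # constructed so n_slots * p = 1 exactly
  d <- motifDepletionStat(4101, "CACGTG", observed = 0)
  expect_identical(d$n_slots, 4096L)
  expect_equal(d$p, 4^-6, tolerance = 1e-15)
  expect_equal(d$expected, 1.0, tolerance = 1e-12)
  # exact rational evaluations, frozen (25 significant digits at source)
  expect_equal(d$p_lower, 0.3678345294443461, tolerance = 1e-10)
  expect_equal(motifDepletionStat(4101, "CACGTG", observed = 2)$p_lower,
               0.9197210615337386, tolerance = 1e-10)
  expect_equal(motifDepletionStat(4101, "CACGTG", observed = 5)$p_lower,
               0.9994073110978844, tolerance = 1e-10)
  # full support: tail is exactly 1
  expect_equal(motifDepletionStat(4101, "CACGTG", observed = 4096)$p_lower, 1.0)

  # non-uniform background: p is the product of allowed-base sums
  bg <- c(A = 0.32, C = 0.18, G = 0.18, T = 0.32)
  d2 <- motifDepletionStat(1000, "CACGTG", background = bg, observed = 0)
  expect_equal(d2$p, 26244 / 244140625, tolerance = 1e-15)
  expect_equal(d2$expected, 0.10695794688, tolerance = 1e-12)
  expect_equal(d2$p_lower, 0.8985582936252771, tolerance = 1e-10)
  expect_equal(motifDepletionStat(1000, "CACGTG", background = bg,
                                  observed = 1)$p_lower,
               0.9946765761389659, tolerance = 1e-10)

  # degenerate positions sum their base frequencies
  d3 <- motifDepletionStat(100, "RY", background = bg, observed = 0)
  expect_equal(d3$p, (0.32 + 0.18) * (0.18 + 0.32), tolerance = 1e-15)

  expect_error(motifDepletionStat(100, "ACGT", background = c(A = 0.3, C = 0.3,
                                                              G = 0.3, T = 0.3),
                                  observed = 0), "sum")
  expect_error(motifDepletionStat(3, "CACGTG", observed = 0), "at least")
})
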