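test_that("parse_halfsite decodes bracket-form consensus text", {
  p <- parse_halfsite("[GA]GGT[TC]A")
  expect_s3_class(p, "iupac_pattern")
  expect_equal(p$length, 6L)
  expect_equal(p$sets, list(c("A", "G"), "G", "G", "T", c("C", "T"), "A"))

  q <- parse_halfsite("ACGT")
  expect_equal(q$sets, list("A", "C", "G", "T"))

  expect_equal(parse_halfsite("N")$sets, list(c("A", "C", "G", "T")))

  expect_error(parse_halfsite("[]A"), "empty alternative")
  expect_error(parse_halfsite("[GA"), "unbalanced")
  expect_error(parse_halfsite("AC]G"), "unbalanced")
  expect_error(parse_halfsite("AXG"), "illegal character")
  expect_error(parse_halfsite("[GX]A"), "illegal character")
})

test_that("patterns round-trip through their bracket text form", {
  set.seed(11)
  for (i in 1:25) {
    p <- parse_halfsite(random_halfsite())
    expect_equal(parse_halfsite(bracket_form(p))$sets, p$sets)
  }
})

test_that("compile_element derives the second half-site from the geometry", {
  ir1 <- compile_element("[GA]GGT[TC]A", "IR", 1)
  expect_equal(ir1$full$length, 13L)
  expect_true(ir1$self_rc)
  # the IR right half reproduces the printed right half of the consensus
  expect_equal(ir1$right$sets, parse_halfsite("T[AG]ACC[TC]")$sets)
  # spacer position fully degenerate
  expect_equal(ir1$full$sets[[7]], c("A", "C", "G", "T"))

  aa <- compile_element("A", "DR", 0)
  expect_equal(bracket_form(aa$full), "AA")

  dr4 <- compile_element("[GA]GGT[TC]A", "DR", 4)
  expect_equal(dr4$full$length, 16L)
  expect_false(dr4$self_rc)

  # ER: left half is the reverse complement, right half is direct
  er2 <- compile_element("AGGTCA", "ER", 2)
  expect_equal(bracket_form(er2$left), "TGACCT")
  expect_equal(bracket_form(er2$right), "AGGTCA")
})

test_that("self_rc flag agrees with direct set-list comparison", {
  set.seed(12)
  for (i in 1:30) {
    e <- random_element()
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    rc <- rev(lapply(e$full$sets, function(s) sort(unname(comp[s]))))
    direct <- length(rc) == length(e$full$sets) &&
      all(mapply(setequal, lapply(e$full$sets, sort), rc))
    expect_identical(e$self_rc, direct)
  }
})

test_that("mismatches_at scores the printed elements as reported", {
  ir1 <- ir1_element()
  expect_equal(mismatches_at("GGGTTAGTGACCC", 0, ir1), 0L)  # conserved NDRG2 element
  expect_equal(mismatches_at("AGGTTGATGACCC", 0, ir1), 1L)  # second, IR1-like element
  expect_equal(mismatches_at("GGGTGAATAACCT", 0, ir1), 1L)  # IBABP element
  expect_error(mismatches_at("GGGTTAGTGACCC", 1, ir1), "out of range")
})

test_that("ambiguity characters mismatch at constrained positions, never at the spacer", {
  ir1 <- ir1_element()
  expect_equal(mismatches_at("NGGTTAGTGACCC", 0, ir1), 1L)
  expect_equal(mismatches_at("GGGTTANTGACCC", 0, ir1), 0L)  # N at spacer is free
  expect_equal(mismatches_at("GGGTTAXTGACCC", 0, ir1), 0L)
})

test_that("scan_motif reproduces the reporter-insert hit structure", {
  ir1 <- ir1_element()
  h0 <- scan_motif(ndrg2_re_wt, ir1, max_mm = 0)
  expect_equal(nrow(h0), 1L)
  expect_equal(h0$start, 15L)
  expect_equal(h0$matched, "GGGTTAGTGACCC")
  expect_equal(h0$start1, 16L)
  expect_equal(h0$end1, 28L)

  h1 <- scan_motif(ndrg2_re_wt, ir1, max_mm = 1)
  expect_equal(h1$start, c(15L, 32L))
  expect_equal(h1$mismatches, c(0L, 1L))

  expect_equal(nrow(scan_motif(ndrg2_re_mut, ir1, max_mm = 1)), 0L)
  expect_equal(nrow(scan_motif("", ir1, max_mm = 2)), 0L)
})

test_that("scan_motif matches the naive per-position oracle", {
  set.seed(13)
  for (i in 1:40) {
    e <- random_element()
    s <- random_seq(sample(50:400, 1))
    for (k in 0:2) {
      got <- scan_motif(s, e, max_mm = k)
      exp <- oracle_scan(s, e, max_mm = k)
      expect_equal(got$start, exp$start)
      expect_equal(got$strand, exp$strand)
      expect_equal(got$mismatches, exp$mismatches)
    }
  }
})

test_that("scan_motif agrees with Biostrings ambiguity matching on the plus strand", {
  iupac_of <- function(sets) {
    codes <- Biostrings::IUPAC_CODE_MAP
    paste(vapply(sets, function(s) {
      names(codes)[vapply(codes, function(x)
        setequal(strsplit(x, "")[[1]], s), TRUE)][1]
    }, ""), collapse = "")
  }
  set.seed(14)
  for (i in 1:15) {
    e <- random_element()
    s <- random_seq(500)
    for (k in 0:1) {
      ref <- Biostrings::matchPattern(iupac_of(e$full$sets), Biostrings::DNAString(s),
                                      max.mismatch = k, fixed = "subject")
      got <- scan_motif(s, e, max_mm = k, strands = "plus")
      expect_equal(got$start, Biostrings::start(ref) - 1L)
    }
  }
})

test_that("hits are monotone in the mismatch budget", {
  set.seed(15)
  for (i in 1:15) {
    e <- random_element()
    s <- random_seq(300)
    prev <- scan_motif(s, e, max_mm = 0)
    for (k in 1:3) {
      cur <- scan_motif(s, e, max_mm = k)
      key <- function(h) paste(h$start, h$strand)
      expect_true(all(key(prev) %in% key(cur)))
      prev <- cur
    }
  }
})

test_that("self-RC scans are strand invariant and canonicalised to plus", {
  ir1 <- ir1_element()
  set.seed(16)
  for (i in 1:15) {
    s <- random_seq(1000)
    fwd <- scan_motif(s, ir1, max_mm = 1, strands = "both")
    expect_true(all(fwd$strand == "+"))  # one report per physical site
    rev <- scan_motif(revcomp(s), ir1, max_mm = 1, strands = "both")
    expect_equal(sort(rev$start), sort(1000L - 13L - fwd$start))
    expect_equal(nrow(rev), nrow(fwd))
  }
})

test_that("the IR1 full pattern admits exactly 64 distinct words", {
  expect_equal(pattern_word_count(ir1_element()), 64)
})
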