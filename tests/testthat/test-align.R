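test_that("global_align reproduces the worked identity examples", {
  al <- global_align(aa_seq("a", "ACDE"), aa_seq("b", "ACDE"))
  expect_equal(al$identity_pct, 100)
  expect_false(grepl("-", al$aligned_a))

  # gapless optimum for ACDE vs ACDA (confirmed by the linear-gap DP oracle
  # and by enumeration over the 4-column alignments)
  al <- global_align(aa_seq("a", "ACDE"), aa_seq("b", "ACDA"))
  expect_equal(al$match_count, 3L)
  expect_equal(al$aligned_columns, 4L)
  expect_equal(percent_identity(al), 75.0)

  al <- global_align(aa_seq("a", "A"), aa_seq("b", "G"))
  expect_equal(al$aligned_columns, 1L)
  expect_equal(al$identity_pct, 0)

  expect_error(global_align(aa_seq("a", "ACDE"), aa_seq("b", "X")),
               NA)  # X is alignable
})

test_that("empty sequences are rejected", {
  a <- aa_seq("a", "ACDE")
  b <- a; b$residues <- ""
  expect_error(global_align(a, b), class = "petasetyper_input_error")
})

test_that("alignment score matches the linear-gap DP oracle on short pairs", {
  set.seed(101)
  B <- blosum62()
  for (r in 1:60) {
    a <- random_aa(sample(1:8, 1))
    b <- random_aa(sample(1:8, 1))
    g <- sample(c(1, 3, 6), 1)
    got <- global_align(aa_seq("a", a), aa_seq("b", b),
                        gap_open = 0, gap_extend = g)$score
    expect_equal(got, bf_linear_score(a, b, B, g), tolerance = 1e-9)
  }
})

test_that("affine scores agree with an independent aligner", {
  set.seed(202)
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  for (r in 1:25) {
    a <- random_aa(sample(5:50, 1))
    b <- random_aa(sample(5:50, 1))
    got <- global_align(aa_seq("a", a), aa_seq("b", b))$score
    ref <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = env$BLOSUM62, gapOpening = 10,
      gapExtension = 0.5, type = "global", scoreOnly = TRUE)
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("score and identity are symmetric under input swap", {
  set.seed(303)
  for (r in 1:20) {
    a <- aa_seq("a", random_aa(sample(5:40, 1)))
    b <- aa_seq("b", random_aa(sample(5:40, 1)))
    f <- global_align(a, b); g <- global_align(b, a)
    expect_equal(f$score, g$score)
    expect_equal(f$identity_pct, g$identity_pct)
  }
})

test_that("aligned strings degap to their inputs", {
  set.seed(404)
  a <- aa_seq("a", random_aa(30)); b <- aa_seq("b", random_aa(25))
  al <- global_align(a, b)
  expect_equal(gsub("-", "", al$aligned_a), a$residues)
  expect_equal(gsub("-", "", al$aligned_b), b$residues)
  expect_equal(nchar(al$aligned_a), nchar(al$aligned_b))
})

test_that("percent_identity uses the aligned-column denominator", {
  fake <- structure(list(aligned_a = "AC--", aligned_b = "--AC",
                         match_count = 0L, aligned_columns = 4L),
                    class = "aa_alignment")
  expect_equal(percent_identity(fake), 0)
  fake$aligned_columns <- 0L
  expect_error(percent_identity(fake),
               class = "petasetyper_undefined_identity")
})

test_that("progressive_msa handles the canonical small cases", {
  s3 <- lapply(c("i1", "i2", "i3"), function(id) aa_seq(id, "MKWVTFIS"))
  m <- progressive_msa(s3)
  expect_equal(m$column_count, 8L)
  expect_false(any(grepl("-", m$rows)))

  m <- progressive_msa(list(aa_seq("x", "ACDE"), aa_seq("y", "ACE")))
  expect_equal(sort(m$rows), sort(c("ACDE", "AC-E")))  # gap at the D column

  expect_error(progressive_msa(list(aa_seq("x", "ACDE"))),
               class = "petasetyper_input_error")
  expect_error(progressive_msa(list(aa_seq("x", "ACDE"), aa_seq("x", "ACD"))),
               class = "petasetyper_input_error")
})

test_that("progressive_msa rows degap to their inputs (residue conservation)", {
  set.seed(505)
  for (r in 1:5) {
    n <- sample(3:6, 1)
    base <- random_aa(40)
    seqs <- lapply(seq_len(n), function(i) {
      s <- mutate_seq(aa_seq(sprintf("s%d", i), base), rate = 0.2)
      s
    })
    m <- progressive_msa(seqs)
    for (i in seq_len(n))
      expect_equal(gsub("-", "", m$rows[match(seqs[[i]]$id, m$ids)]),
                   seqs[[i]]$residues)
  }
})

test_that("column_frequencies counts non-gap residues and gap fraction", {
  msa <- aa_msa(c("a", "b", "c", "d"), c("AA", "AA", "GA", "-A"))
  cf <- column_frequencies(msa)
  expect_equal(cf$freq["A", 1], 2 / 3)
  expect_equal(cf$freq["G", 1], 1 / 3)
  expect_equal(unname(cf$gap_fraction[1]), 1 / 4)
  expect_equal(cf$freq["A", 2], 1)
  expect_equal(colSums(cf$freq), c(`1` = 1, `2` = 1))

  expect_error(column_frequencies(msa, columns = 5),
               class = "petasetyper_range_error")
  expect_error(column_frequencies(aa_msa(character(0), character(0))),
               class = "petasetyper_empty_input")
})

test_that("strictly conserved columns report a single residue at frequency 1", {
  set.seed(606)
  base <- random_aa(60)
  seqs <- lapply(1:5, function(i)
    mutate_seq(aa_seq(sprintf("h%d", i), base), rate = 0.1,
               protect = c(10L, 25L, 40L)))
  m <- progressive_msa(seqs)
  cf <- column_frequencies(m)
  # protected positions align to conserved columns with one residue at 1.0
  chars <- strsplit(base, "")[[1]]
  for (p in c(10L, 25L, 40L)) {
    hits <- which(cf$freq[chars[p], ] == 1)
    expect_true(length(hits) >= 1L)
  }
})

test_that("read_score_matrix parses NCBI-format text", {
  f <- tempfile()
  writeLines(c("# tiny demo matrix", "   A  C", "A  4 -2", "C -2  9"), f)
  m <- read_score_matrix(f)
  expect_equal(m["A", "C"], -2)
  expect_equal(m["C", "C"], 9)
  writeLines(c("   A  C", "A  4 -2", "C  1  9"), f)
  expect_error(read_score_matrix(f), class = "petasetyper_format_error")
})
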