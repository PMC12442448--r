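test_that("archetypes carry their type's gating features by construction", {
  fix <- make_reference_set(2)
  halo <- fix$sequences$synthetic_HaloPETase1_like_typeIII
  expect_equal(substr(halo$residues, 154, 158), "GHSQG")
  expect_equal(residue_at(halo, c(64, 126, 273, 276)), rep("C", 4))
  expect_equal(residue_at(halo, 88), "T")        # non-aromatic clamp anchor 1
  expect_equal(residue_at(halo, 206), "D")
  expect_equal(residue_at(halo, 236), "H")
  # exactly the four planted cysteines
  expect_equal(sum(strsplit(halo$residues, "")[[1]] == "C"), 4L)

  lcc <- fix$sequences$synthetic_LCC_like_typeI
  expect_equal(sum(strsplit(lcc$residues, "")[[1]] == "C"), 2L)
  expect_equal(nchar(lcc$residues), 311L)        # extended loop removed

  iib <- fix$sequences$synthetic_IsPETase_like_typeIIb
  expect_equal(substr(iib$residues, 158, 162), "GWSMG")
  expect_equal(residue_at(iib, c(203, 239, 273, 289)), rep("C", 4))
})

test_that("generation is deterministic under a fixed seed", {
  a <- make_stand_ins(7)
  b <- make_stand_ins(7)
  for (id in names(a$sequences))
    expect_identical(a$sequences[[id]]$residues, b$sequences[[id]]$residues)
  expect_identical(a$pmc$residues, b$pmc$residues)
})

test_that("mutate_seq respects rate, protection and exact counts", {
  s <- aa_seq("s", random_aa(260))
  expect_identical(mutate_seq(s, rate = 0, seed = 1)$residues, s$residues)

  # observed substitution count behaves binomially at rate 0.05
  counts <- vapply(1:50, function(i) {
    m <- mutate_seq(s, rate = 0.05, seed = i)
    sum(strsplit(m$residues, "")[[1]] != strsplit(s$residues, "")[[1]])
  }, numeric(1))
  expect_equal(mean(counts), 13, tolerance = 0.25)
  q <- stats::qbinom(c(0.005, 0.995), 260, 0.05)
  expect_true(all(counts >= q[1] & counts <= q[2]))

  # protected positions never change
  m <- mutate_seq(s, rate = 1, protect = c(10L, 20L, 30L), seed = 3)
  expect_equal(residue_at(m, c(10, 20, 30)), residue_at(s, c(10, 20, 30)))

  m <- mutate_seq(s, rate = 0, exact_count = 17L, seed = 4)
  expect_equal(sum(strsplit(m$residues, "")[[1]] !=
                   strsplit(s$residues, "")[[1]]), 17L)
})

test_that("the PmC-like stand-in is planted at 62.4% identity", {
  al <- global_align(HALO, FIX$pmc)
  expect_equal(percent_identity(al), 62.4, tolerance = 0.05)
  # gapless: both stand-ins are equal length with no planted indels
  expect_false(grepl("-", al$aligned_a))
})

test_that("toy structures reproduce the planted geometry exactly", {
  fix <- make_reference_set(3)
  halo <- fix$sequences$synthetic_HaloPETase1_like_typeIII
  p <- make_toy_structure(halo, triad_positions = c(156L, 236L, 206L),
                          cys_pairs = rbind(c(64L, 126L), c(273L, 276L)))
  m <- read_pdb(p)
  ds <- detect_disulfides(m)
  expect_equal(ds$res_a, c(64L, 273L))
  expect_equal(ds$res_b, c(126L, 276L))
  tc <- detect_triad(m)
  expect_equal(c(tc$ser, tc$his, tc$asp), c(156L, 236L, 206L))
  # the chain sequence round-trips through the coordinates
  expect_equal(pdb_chain_seq(m)$residues, halo$residues)

  # SG atoms pushed to 4 A are no longer bonded
  p4 <- make_toy_structure(halo, cys_pairs = rbind(c(64L, 126L)),
                           sg_dist = 4.0)
  expect_equal(nrow(detect_disulfides(read_pdb(p4))), 0L)

  # infeasible request: triad letters that do not match the sequence
  expect_error(make_toy_structure(halo, triad_positions = c(10L, 11L, 12L)),
               class = "petasetyper_construction_error")
})

test_that("triad detection is independent of residue insertion order", {
  fix <- make_reference_set(4)
  halo <- fix$sequences$synthetic_HaloPETase1_like_typeIII
  p <- make_toy_structure(halo, triad_positions = c(156L, 236L, 206L))
  lines <- readLines(p)
  atoms <- grep("^ATOM", lines)
  shuffled <- lines
  shuffled[atoms] <- lines[sample(atoms)]
  p2 <- tempfile(fileext = ".pdb")
  writeLines(shuffled, p2)
  a <- detect_triad(read_pdb(p))
  b <- detect_triad(read_pdb(p2))
  expect_equal(c(a$ser, a$his, a$asp), c(b$ser, b$his, b$asp))
})

test_that("profile samples outscore length-matched random sequences", {
  set.seed(51)
  # composition-balanced seed family (three copies of every letter) so the
  # MSA-frequency null model matches the uniform random baseline
  alphabet <- rownames(blosum62())[1:20]
  base <- paste(sample(rep(alphabet, 3)), collapse = "")
  seed_seqs <- lapply(1:5, function(i)
    mutate_seq(aa_seq(sprintf("seed%d", i), base), rate = 0.05))
  hmm <- build_profile(progressive_msa(seed_seqs))

  expect_length(sample_from_profile(hmm, 0), 0L)
  s1 <- sample_from_profile(hmm, 5, seed = 9)
  s2 <- sample_from_profile(hmm, 5, seed = 9)
  expect_identical(vapply(s1, `[[`, character(1), "residues"),
                   vapply(s2, `[[`, character(1), "residues"))

  draws <- sample_from_profile(hmm, 30, seed = 10)
  bits_model <- vapply(draws, function(s) score_forward(hmm, s)$bits,
                       numeric(1))
  bits_rand <- vapply(draws, function(s)
    score_forward(hmm, aa_seq("r", random_aa(nchar(s$residues))))$bits,
    numeric(1))
  expect_gt(mean(bits_model), mean(bits_rand))
})

test_that("classification accuracy is perfect at rate 0 and non-increasing", {
  rates <- c(0, 0.02, 0.05, 0.1)
  n_rep <- 8L
  acc <- vapply(rates, function(rate) {
    hits <- 0L
    for (r in seq_len(n_rep)) {
      for (id in names(FIX$sequences)) {
        q <- mutate_seq(FIX$sequences[[id]], rate = rate,
                        protect = FIX$feature_positions[[id]],
                        seed = r * 1000L + nchar(id) + round(rate * 1000))
        cl <- classify_petase(build_report(q, IIB_REF_SEQ, IIB_ANN))
        if (cl$call == FIX$truth[[id]]) hits <- hits + 1L
      }
    }
    hits / (n_rep * 4L)
  }, numeric(1))
  expect_equal(acc[1], 1)
  expect_true(all(diff(acc) <= 1e-9 + 0))
})

test_that("the shipped annotation TSVs match the generator constants", {
  for (tp in c("I", "IIa", "IIb", "III")) {
    a <- archetype_annotation(tp)
    f <- system.file("extdata", paste0(a$ref_id, "_annotation.tsv"),
                     package = "petasetyper")
    expect_true(nzchar(f), label = a$ref_id)
    b <- read_annotation(f)
    expect_equal(b$triad, a$triad, label = a$ref_id)
    expect_equal(b$loop_windows, a$loop_windows)
    expect_equal(b$canonical_disulfides, a$canonical_disulfides)
    expect_equal(b$extended_loop, a$extended_loop)
  }
})

test_that("the fixture suite writes files that parse cleanly", {
  dir <- file.path(tempdir(), "fixture_suite")
  files <- write_fixture_suite(dir, seed = 6)
  seqs <- read_fasta(files[["archetypes"]])
  expect_length(seqs, 4L)
  expect_silent(m <- read_pdb(files[["structure"]]))
  expect_equal(nrow(detect_disulfides(m)), 2L)
  ann <- read_annotation(files[["annotation"]])
  expect_equal(ann$triad[["ser"]], 160L)
  halo_ann <- read_annotation(files[["halo_annotation"]])
  expect_equal(halo_ann$triad[["ser"]], 156L)
  # regeneration with the same seed is byte-identical
  dir2 <- file.path(tempdir(), "fixture_suite2")
  files2 <- write_fixture_suite(dir2, seed = 6)
  for (k in names(files))
    expect_identical(readLines(files[[k]]), readLines(files2[[k]]))
})
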