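test_that("lipase-box extraction labels the known variants", {
  s <- aa_seq("q", "AAAGHSQGVVV")
  lb <- extract_lipase_box(s, 6)
  expect_equal(lb$motif, "GHSQG")
  expect_equal(lb$label, "GHSQG")

  s <- aa_seq("q", "AAAGWSMGVVV")
  expect_equal(extract_lipase_box(s, 6)$label, "GWSMG")

  s <- aa_seq("q", "AAAGASTGVVV")   # G-X-S-X-G but not a named variant
  expect_equal(extract_lipase_box(s, 6)$label, "other")

  s <- aa_seq("q", "AAAGHTQGVVV")   # center not serine
  expect_equal(extract_lipase_box(s, 6)$label, "nonconforming")

  expect_error(extract_lipase_box(aa_seq("q", "GHSQG"), 2),
               class = "petasetyper_range_error")
})

test_that("map_positions on self is the identity map", {
  m <- map_positions(IIB_REF_SEQ, IIB_REF_SEQ)
  expect_equal(m$ref_pos, m$query_pos)
})

test_that("the type III archetype maps the published anchor offsets", {
  m <- map_positions(HALO, IIB_REF_SEQ)
  get <- function(p) m$query_pos[m$ref_pos == p]
  expect_equal(get(87L), 88L)     # clamp anchor 1: IsPETase 87 -> T88
  expect_equal(get(160L), 156L)   # catalytic serine -> S156
  expect_equal(get(161L), 157L)   # oxyanion partner -> Q157
  expect_equal(get(206L), 206L)   # D206 aligned
  expect_equal(get(237L), 236L)   # H236
  # reference position 119 sits in the deleted loop-2 stretch: unalignable
  expect_true(is.na(get(119L)))
  # the mapped residues carry the planted letters
  expect_equal(residue_at(HALO, get(87L)), "T")
  expect_equal(residue_at(HALO, get(93L)), "T")   # subsite II T94 signature
})

test_that("position maps round-trip query -> reference -> query", {
  m_fwd <- map_positions(HALO, IIB_REF_SEQ)
  m_rev <- map_positions(IIB_REF_SEQ, HALO)
  mapped <- m_fwd[!is.na(m_fwd$query_pos), ]
  back <- m_rev$query_pos[match(mapped$query_pos, m_rev$ref_pos)]
  expect_equal(back, mapped$ref_pos)
})

test_that("clamp status follows the mapped anchor residues", {
  ann <- IIB_ANN
  m_self <- map_positions(IIB_REF_SEQ, IIB_REF_SEQ)
  cl <- check_clamp(IIB_REF_SEQ, m_self, ann)
  expect_true(cl$present)                       # Y87 / W185
  expect_equal(cl$residues, c("Y", "W"))

  m_halo <- map_positions(HALO, IIB_REF_SEQ)
  cl <- check_clamp(HALO, m_halo, ann)
  expect_false(cl$present)                      # T at anchor 1
  expect_equal(cl$residues[1], "T")

  # synthetic F/W variant counts as a clamp
  v <- IIB_REF_SEQ
  v$residues <- paste0(substr(v$residues, 1, 86), "F",
                       substr(v$residues, 88, nchar(v$residues)))
  cl <- check_clamp(v, map_positions(v, IIB_REF_SEQ), ann)
  expect_true(cl$present)

  # unalignable anchor -> undetermined
  fake_map <- data.frame(ref_pos = ann$clamp_anchors,
                         query_pos = c(NA_integer_, 100L))
  cl <- check_clamp(HALO, fake_map, ann)
  expect_equal(cl$status, "undetermined")
  expect_true(is.na(cl$present))
})

test_that("loop deltas recover the planted +5/-5 signature", {
  al <- global_align(HALO, IIB_REF_SEQ)
  ld <- measure_loops(HALO, IIB_REF_SEQ, IIB_ANN, al)
  expect_equal(unname(ld["loop2"]), -5)
  expect_equal(unname(ld["loop3"]), +5)
  expect_equal(unname(ld["loop1"]), 0)

  al_self <- global_align(IIB_REF_SEQ, IIB_REF_SEQ)
  expect_equal(unname(measure_loops(IIB_REF_SEQ, IIB_REF_SEQ, IIB_ANN, al_self)),
               c(0, 0, 0))
})

test_that("loop deltas against the reverse direction negate", {
  halo_ann <- halopetase1_annotation()
  al_fwd <- global_align(HALO, IIB_REF_SEQ)
  al_rev <- global_align(IIB_REF_SEQ, HALO)
  fwd <- measure_loops(HALO, IIB_REF_SEQ, IIB_ANN, al_fwd)
  rev <- measure_loops(IIB_REF_SEQ, HALO, halo_ann, al_rev)
  expect_equal(unname(fwd[c("loop2", "loop3")]),
               -unname(rev[c("loop2", "loop3")]))
})

test_that("sequence-inferred disulfides carry the canonical flags", {
  # the IIb reference itself: both pairs canonical
  m <- map_positions(IIB_REF_SEQ, IIB_REF_SEQ)
  inf <- infer_disulfides_from_sequence(IIB_REF_SEQ, m, IIB_ANN)
  expect_equal(nrow(inf$pairs), 2L)
  expect_true(all(inf$pairs$canonical))
  expect_equal(inf$pairs$pos_a, c(203L, 273L))

  # the type III archetype: both pairs present but non-canonical
  m <- map_positions(HALO, IIB_REF_SEQ)
  inf <- infer_disulfides_from_sequence(HALO, m, IIB_ANN)
  expect_equal(nrow(inf$pairs), 2L)
  expect_false(any(inf$pairs$canonical))
  expect_equal(inf$pairs$pos_a, c(64L, 273L))
  expect_equal(inf$pairs$pos_b, c(126L, 276L))

  # odd cysteine count: unpaired listed, no error
  odd <- HALO
  odd$residues <- paste0(substr(odd$residues, 1, 9), "C",
                         substr(odd$residues, 11, nchar(odd$residues)))
  inf <- infer_disulfides_from_sequence(odd, map_positions(odd, IIB_REF_SEQ),
                                        IIB_ANN)
  expect_length(inf$unpaired, 1L)
})

test_that("build_report assembles the full evidence and structure overrides", {
  rep_seq <- build_report(HALO, IIB_REF_SEQ, IIB_ANN)
  expect_equal(rep_seq$lipase_box$label, "GHSQG")
  expect_false(rep_seq$clamp$present)
  expect_true(rep_seq$extended_loop_present)
  expect_equal(rep_seq$disulfide_source, "sequence-inferred")
  expect_equal(unname(rep_seq$loop_deltas["loop3"]), 5)
  expect_equal(rep_seq$catalytic_ser, 156L)

  # with coordinates, the geometric triad and bonds supersede
  pdb <- make_toy_structure(HALO, triad_positions = c(156L, 236L, 206L),
                            cys_pairs = rbind(c(64L, 126L), c(273L, 276L)))
  rep_str <- build_report(HALO, IIB_REF_SEQ, IIB_ANN,
                          structure = read_pdb(pdb))
  expect_equal(rep_str$disulfide_source, "structure")
  expect_equal(rep_str$triad_source, "structure")
  expect_equal(rep_str$triad$ser, 156L)
  expect_equal(nrow(rep_str$disulfide_pairs), 2L)
  expect_false(any(rep_str$disulfide_pairs$canonical))

  # a type I archetype report matches its generating features
  lcc <- FIX$sequences$synthetic_LCC_like_typeI
  rep1 <- build_report(lcc, IIB_REF_SEQ, IIB_ANN)
  expect_equal(rep1$lipase_box$label, "GHSMG")
  expect_equal(nrow(rep1$disulfide_pairs), 1L)
  expect_true(rep1$disulfide_pairs$canonical)
  expect_true(rep1$clamp$present)
  expect_false(rep1$extended_loop_present)
})

test_that("annotation TSV round-trips", {
  f <- tempfile(fileext = ".tsv")
  write_annotation(IIB_ANN, f)
  back <- read_annotation(f)
  expect_equal(back$triad, IIB_ANN$triad)
  expect_equal(back$clamp_anchors, IIB_ANN$clamp_anchors)
  expect_equal(back$loop_windows, IIB_ANN$loop_windows)
  expect_equal(back$canonical_disulfides, IIB_ANN$canonical_disulfides)
  expect_equal(back$subsite2, IIB_ANN$subsite2)
})
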