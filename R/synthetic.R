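# Seeded synthetic-fixture generator. Archetype sequences carry exactly the
# gating features of the four PETase types at annotated positions; derived
# stand-ins (labelled "synthetic_*") emulate the published feature geometry
# of the real proteins (triad and disulfide author numbers, loop-length
# signatures, the 62.4% HaloPETase1-PmC identity) without using any deposited
# data. Toy structures are geometric scaffolds: all structure operations in
# this package are local-geometry predicates, so no realistic fold is needed.

random_residues <- function(n) paste(sample(AA_BACKGROUND, n, replace = TRUE),
                                     collapse = "")

plant <- function(chars, pos, letters) {
  L <- str_chars(letters)
  if (length(pos) == 1L && length(L) > 1L) pos <- pos + seq_along(L) - 1L
  stopifnot(length(pos) == length(L))
  chars[pos] <- L
  chars
}

# --- edit scripts with ground-truth correspondence ------------------------

# ops: list of list(type = "ins"|"del", at = ref position, len = n).
# "ins" inserts len random residues after ref position `at`; "del" deletes
# ref positions at..(at+len-1). Returns query chars plus the true map
# ref index -> query index (NA where deleted).
apply_edits <- function(ref_chars, ops) {
  n <- length(ref_chars)
  del <- logical(n)
  ins_after <- integer(n + 1L)        # ins_after[i+1] = residues inserted after ref i
  for (op in ops) {
    if (op$type == "del") del[op$at:(op$at + op$len - 1L)] <- TRUE
    else ins_after[op$at + 1L] <- ins_after[op$at + 1L] + op$len
  }
  q <- character(0)
  map <- rep(NA_integer_, n)
  inserted <- integer(0)
  if (ins_after[1L] > 0L) {
    q <- c(q, str_chars(random_residues(ins_after[1L])))
    inserted <- seq_along(q)
  }
  for (i in seq_len(n)) {
    if (!del[i]) {
      q <- c(q, ref_chars[i])
      map[i] <- length(q)
    }
    if (ins_after[i + 1L] > 0L) {
      new <- str_chars(random_residues(ins_after[i + 1L]))
      inserted <- c(inserted, length(q) + seq_along(new))
      q <- c(q, new)
    }
  }
  list(query = q, map = map, inserted = inserted)
}

#' Mutate a sequence with protected feature positions
#'
#' Point substitutions (always to a different residue, drawn from the
#' cysteine-free background alphabet) everywhere except the protected author
#' positions. With `exact_count` set, exactly that many unprotected sites
#' are substituted (sampled without replacement) instead of per-site
#' Bernoulli draws.
#'
#' @param seq an [aa_seq()].
#' @param rate per-site substitution probability.
#' @param protect author positions never touched.
#' @param seed integer seed (NULL = use the current RNG state).
#' @param exact_count optional exact number of substitutions.
#' @return the mutated [aa_seq()].
#' @export
mutate_seq <- function(seq, rate, protect = integer(0), seed = NULL,
                       exact_count = NULL) {
  stopifnot(inherits(seq, "aa_seq"), rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  chars <- str_chars(seq$residues)
  idx_protect <- unique(protect - seq$numbering_offset + 1L)
  free <- setdiff(seq_along(chars), idx_protect)
  hit <- if (!is.null(exact_count)) sample(free, exact_count)
         else free[stats::runif(length(free)) < rate]
  for (i in hit) {
    alt <- setdiff(AA_BACKGROUND, chars[i])
    chars[i] <- sample(alt, 1L)
  }
  out <- seq
  out$residues <- paste(chars, collapse = "")
  out
}

# --- the packaged reference geometry (author positions, seed-independent) --

# IIb-like reference ("synthetic_IsPETase_like"): feature positions follow
# the published IsPETase numbering where the literature cites it
# (Y87, S93, Q119, G158-W159-S160-M161-G162, W185, D206, H237).
IIB_REF <- list(
  length = 320L,
  triad = c(ser = 160L, his = 237L, asp = 206L),
  clamp = c(87L, 185L),
  oxyanion = c(87L, 161L),
  subsite1 = c(87L, 119L, 185L),
  subsite2 = c(93L, 94L, 95L, 100L),
  extended_loop = 244:252,
  loop_windows = rbind(loop1 = c(84L, 90L), loop2 = c(115L, 124L),
                       loop3 = c(163L, 172L)),
  disulfides = rbind(c(203L, 239L), c(273L, 289L))
)

# residues planted on the reference; subsite-II / extended-loop letters are
# the IIb-scored variant
iib_plant <- function(chars) {
  chars <- plant(chars, 87L, "Y")
  chars <- plant(chars, 93L, "S")
  chars <- plant(chars, 94L, "N")
  chars <- plant(chars, 95L, "Q")
  chars <- plant(chars, 100L, "T")
  chars <- plant(chars, 119L, "Q")
  chars <- plant(chars, 158L, "GWSMG")
  chars <- plant(chars, 185L, "W")
  chars <- plant(chars, 206L, "D")
  chars <- plant(chars, 237L, "H")
  chars <- plant(chars, c(203L, 239L, 273L, 289L), "CCCC")
  chars <- plant(chars, 245L, "PVGN")       # 245 P shared, 246-248 IIb letters
  chars
}

iib_protect <- function() {
  p <- c(87L, 93:95, 100L, 119L, 158:162, 185L, 203L, 206L, 237L, 239L,
         245:248, 273L, 289L)
  sort(unique(c(p - 1L, p, p + 1L)))
}

#' Annotation of the synthetic IIb reference
#' @return the [ref_annotation()] all feature mapping is anchored to.
#' @export
iib_reference_annotation <- function() {
  ref_annotation(ref_id = "synthetic_IsPETase_like_typeIIb",
                 triad = IIB_REF$triad, clamp_anchors = IIB_REF$clamp,
                 oxyanion = IIB_REF$oxyanion, subsite1 = IIB_REF$subsite1,
                 subsite2 = IIB_REF$subsite2,
                 extended_loop = IIB_REF$extended_loop,
                 loop_windows = IIB_REF$loop_windows,
                 canonical_disulfides = IIB_REF$disulfides)
}

# type III edit script: reproduces the published numbering offsets between
# HaloPETase1 and the IIb reference (87->88, 160->156, 206->206, 237->236)
# plus the loop-2 five-residue deletion and loop-3 five-residue insertion.
# Indels are kept far apart so a sequence aligner can recover each of them
# (the clamp anchor 185 therefore lands on query 186, not the published 180;
# see the methods vignette).
III_EDITS <- list(list(type = "ins", at = 80L, len = 1L),
                  list(type = "del", at = 118L, len = 5L),
                  list(type = "ins", at = 166L, len = 5L),
                  list(type = "del", at = 196L, len = 1L),
                  list(type = "del", at = 219L, len = 1L))

# query-position plants for the type III archetype (HaloPETase1 numbering)
III_PLANTS <- list(list(64L, "C"), list(88L, "T"), list(94L, "T"),
                   list(95L, "S"), list(96L, "G"), list(126L, "C"),
                   list(154L, "GHSQG"), list(163L, "L"), list(186L, "Y"),
                   list(206L, "D"), list(236L, "H"), list(239L, "P"),
                   list(241L, "G"), list(273L, "C"), list(276L, "C"))
# reference cysteines that must disappear in the query (query positions
# under the edit script: 203, 238, 272, 288)
III_KILL_CYS <- c(203L, 238L, 272L, 288L)

iii_protect <- function() {
  p <- unlist(lapply(III_PLANTS, function(x) x[[1]] + seq_len(nchar(x[[2]])) - 1L))
  sort(unique(c(p - 2L, p - 1L, p, p + 1L, p + 2L)))
}

#' Annotation of the synthetic HaloPETase1-like archetype (its own numbering)
#' @return a [ref_annotation()].
#' @export
halopetase1_annotation <- function() {
  ref_annotation(ref_id = "synthetic_HaloPETase1_like_typeIII",
                 triad = c(ser = 156L, his = 236L, asp = 206L),
                 clamp_anchors = c(88L, 186L), oxyanion = c(88L, 157L),
                 subsite1 = c(88L, 163L, 186L),
                 subsite2 = c(94L, 95L, 96L, 101L),
                 extended_loop = 243:251,
                 loop_windows = rbind(loop1 = c(85L, 91L),
                                      loop2 = c(116L, 120L),
                                      loop3 = c(159L, 173L)),
                 canonical_disulfides = rbind(c(64L, 126L), c(273L, 276L)))
}

#' Annotation table for one synthetic archetype
#'
#' Feature positions in the archetype's own author numbering. The IIa
#' archetype shares the reference geometry; the type I archetype lacks the
#' extended loop (deleted) and keeps only the distal disulfide, which the
#' deletion shifts to 264-280.
#'
#' @param type_label `"I"`, `"IIa"`, `"IIb"` or `"III"`.
#' @return a [ref_annotation()].
#' @export
archetype_annotation <- function(type_label) {
  switch(type_label,
    "IIb" = iib_reference_annotation(),
    "III" = halopetase1_annotation(),
    "IIa" = {
      a <- iib_reference_annotation()
      a$ref_id <- "synthetic_PEH_like_typeIIa"
      a
    },
    "I" = {
      a <- iib_reference_annotation()
      a$ref_id <- "synthetic_LCC_like_typeI"
      a$extended_loop <- integer(0)
      a$canonical_disulfides <- matrix(c(264L, 280L), ncol = 2L)
      a
    },
    pt_abort("unknown archetype label", "petasetyper_input_error"))
}

#' Generate the synthetic archetype reference set
#'
#' Four type-consistent archetype sequences, one per PETase type, each
#' carrying exactly its type's gating features at annotated positions, all
#' derived from one seeded IIb-like backbone:
#' * `synthetic_LCC_like_typeI` — one canonical disulfide, extended loop
#'   deleted, GHSMG lipase box, clamp present;
#' * `synthetic_PEH_like_typeIIa` — two canonical disulfides, extended loop,
#'   GWSMG, IIa subsite-II/extended-loop residues;
#' * `synthetic_IsPETase_like_typeIIb` — the reference backbone itself;
#' * `synthetic_HaloPETase1_like_typeIII` — GHSQG, T/Y clamp anchors (clamp
#'   absent), two non-canonical disulfides at 64-126 and 273-276, loop-2
#'   five residues shorter and loop-3 five residues longer than the
#'   reference, triad S156/D206/H236.
#'
#' Background divergence of the derived archetypes is a generator default
#' (see the methods vignette); the planted features and their positions are
#' seed-independent.
#'
#' @param seed integer seed.
#' @return list with `sequences` (named list of [aa_seq()]), `annotation`
#'   (the IIb reference [ref_annotation()]), `truth` (named character of
#'   generating types), `iii_map` (ground-truth reference-to-query
#'   correspondence of the type III archetype), and `feature_positions`
#'   (per archetype, the planted positions a mutation step must preserve).
#' @export
make_reference_set <- function(seed = 1L) {
  set.seed(seed)
  ref_chars <- iib_plant(str_chars(random_residues(IIB_REF$length)))
  iib <- aa_seq("synthetic_IsPETase_like_typeIIb", paste(ref_chars, collapse = ""))

  # type I: drop the extended loop and the active-site-distal disulfide
  e1 <- apply_edits(ref_chars, list(list(type = "del", at = 244L, len = 9L)))
  q1 <- e1$query
  q1 <- plant(q1, 203L, sample(AA_BACKGROUND, 1L))
  q1 <- plant(q1, 239L, sample(AA_BACKGROUND, 1L))
  q1 <- plant(q1, 159L, "H")                     # GHSMG
  q1 <- plant(q1, c(94L, 95L, 100L), "ALV")      # type I scored letters
  prot1 <- stats::na.omit(e1$map[iib_protect()])   # protection in query numbering
  typeI <- mutate_seq(aa_seq("synthetic_LCC_like_typeI", paste(q1, collapse = "")),
                      rate = 0.25, protect = prot1)

  # type IIa: same geometry as the reference, IIa scored letters
  q2 <- plant(ref_chars, c(94L, 95L, 100L), "GAG")
  q2 <- plant(q2, 246L, "ASD")
  typeIIa <- mutate_seq(aa_seq("synthetic_PEH_like_typeIIa", paste(q2, collapse = "")),
                        rate = 0.2, protect = iib_protect())

  # type III: published indel/offset geometry, then plants, then divergence
  e3 <- apply_edits(ref_chars, III_EDITS)
  q3 <- e3$query
  for (k in III_KILL_CYS) q3 <- plant(q3, k, sample(AA_BACKGROUND, 1L))
  for (p in III_PLANTS) q3 <- plant(q3, p[[1]] + seq_len(nchar(p[[2]])) - 1L, p[[2]])
  typeIII <- mutate_seq(aa_seq("synthetic_HaloPETase1_like_typeIII",
                               paste(q3, collapse = "")),
                        rate = 0.35, protect = iii_protect())

  seqs <- list(typeI, typeIIa, iib, typeIII)
  names(seqs) <- vapply(seqs, `[[`, character(1), "id")
  truth <- stats::setNames(c("I", "IIa", "IIb", "III"), names(seqs))
  feature_positions <- list(as.integer(prot1), iib_protect(), iib_protect(),
                            iii_protect())
  names(feature_positions) <- names(seqs)
  list(sequences = seqs, annotation = iib_reference_annotation(),
       truth = truth, iii_map = e3$map,
       feature_positions = feature_positions)
}

#' Synthetic stand-ins for the named comparison proteins
#'
#' The PmC-like stand-in is derived from the HaloPETase1-like archetype by
#' substituting an exact count of unprotected sites so the planted pairwise
#' identity is 62.4% of aligned columns (120 substitutions over 319
#' residues), matching the reported HaloPETase1-PmC identity. It keeps the
#' GHSQG box and the type III disulfide/loop geometry.
#'
#' @param seed integer seed.
#' @return list with the archetype set plus `pmc` (an [aa_seq()]).
#' @export
make_stand_ins <- function(seed = 1L) {
  fix <- make_reference_set(seed)
  halo <- fix$sequences$synthetic_HaloPETase1_like_typeIII
  n <- nchar(halo$residues)
  k <- round(n * (1 - 0.624))
  pmc <- mutate_seq(halo, rate = 0, protect = iii_protect(),
                    seed = seed + 1L, exact_count = k)
  pmc$id <- "synthetic_PmC_like"
  c(fix, list(pmc = pmc))
}

# --- toy coordinate scaffolds ---------------------------------------------

#' Write a toy structure with exact triad and disulfide geometry
#'
#' Extended-chain C-alpha trace (3.8 A spacing along x) with side-chain
#' pseudo-atoms placed so the requested geometry holds exactly: Ser OG -
#' His NE2 = `d_og_ne2`, His ND1 - Asp OD2 = `d_nd1_od2`, SG - SG =
#' `sg_dist` per cysteine pair. Residue names follow the sequence letters.
#' These are geometric scaffolds, not folds.
#'
#' @param seq an [aa_seq()]; letters at `triad_positions` must be S, H, D and
#'   at `cys_pairs` positions C.
#' @param triad_positions author positions `c(ser, his, asp)`, or NULL for no
#'   triad atoms.
#' @param cys_pairs n x 2 matrix of author position pairs, or NULL.
#' @param path output PDB path (default a tempfile).
#' @param sg_dist,d_og_ne2,d_nd1_od2 planted distances in Angstrom.
#' @return the path, invisibly readable via [read_pdb()].
#' @export
make_toy_structure <- function(seq, triad_positions = NULL, cys_pairs = NULL,
                               path = tempfile(fileext = ".pdb"),
                               sg_dist = 2.05, d_og_ne2 = 3.0, d_nd1_od2 = 2.8) {
  stopifnot(inherits(seq, "aa_seq"))
  chars <- str_chars(seq$residues)
  check_letter <- function(pos, want, what) {
    got <- residue_at(seq, pos)
    if (any(got != want))
      pt_abort(sprintf("%s position(s) %s are %s, expected %s", what,
                       paste(pos, collapse = ","), paste(got, collapse = ","),
                       paste(want, collapse = ",")),
               "petasetyper_construction_error")
  }
  if (!is.null(triad_positions)) check_letter(triad_positions, c("S", "H", "D"), "triad")
  if (!is.null(cys_pairs)) check_letter(as.vector(cys_pairs), "C", "cysteine")

  rows <- list()
  serial <- 0L
  add <- function(elety, resno, x, y, z) {
    serial <<- serial + 1L
    i <- resno - seq$numbering_offset + 1L
    resid <- bio3d::aa123(chars[i])
    elem <- substr(elety, 1L, 1L)
    rows[[length(rows) + 1L]] <<-
      sprintf("ATOM  %5d %s%3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              serial, formatC(paste0(" ", elety), width = -5L), resid, resno,
              x, y, z, 1.00, 20.00, elem)
  }
  authors <- index_to_author(seq, seq_along(chars))
  for (a in authors) add("CA", a, 3.8 * (a - seq$numbering_offset), 0, 0)
  if (!is.null(triad_positions)) {
    base <- c(0, 50, 50)
    add("OG",  triad_positions[1L], base[1L], base[2L], base[3L])
    add("NE2", triad_positions[2L], base[1L] + d_og_ne2, base[2L], base[3L])
    add("ND1", triad_positions[2L], base[1L] + d_og_ne2 + 2.2, base[2L], base[3L])
    add("OD2", triad_positions[3L], base[1L] + d_og_ne2 + 2.2 + d_nd1_od2,
        base[2L], base[3L])
  }
  if (!is.null(cys_pairs)) {
    cys_pairs <- matrix(as.integer(cys_pairs), ncol = 2L)
    for (j in seq_len(nrow(cys_pairs))) {
      y <- 60 + 8 * j
      add("SG", cys_pairs[j, 1L], 0, y, 0)
      add("SG", cys_pairs[j, 2L], sg_dist, y, 0)
    }
  }
  writeLines(c(unlist(rows), "TER", "END"), path)
  invisible(path)
}

#' Sample sequences from a profile HMM
#'
#' Follows the model's seeded transitions and emissions from Begin to End.
#'
#' @param hmm a [build_profile()] model.
#' @param n number of sequences.
#' @param seed integer seed.
#' @param id_prefix id prefix for the samples.
#' @return list of [aa_seq()] (empty for `n = 0`).
#' @export
sample_from_profile <- function(hmm, n, seed = 1L, id_prefix = "sample") {
  stopifnot(inherits(hmm, "profile_hmm"), is_count(n))
  set.seed(seed)
  K <- hmm$match_count
  out <- vector("list", n)
  for (s in seq_len(n)) {
    res <- character(0)
    type <- "M"; k <- 0L
    repeat {
      pr <- hmm$transitions[[type]][k + 1L, ]
      if (k == K) pr[["D"]] <- 0      # no delete state beyond the last match
      nxt <- sample(c("M", "I", "D"), 1L, prob = pr)
      if (nxt == "M" && k == K) break          # End
      if (nxt == "I") {
        res <- c(res, sample(AA_ALPHABET, 1L, prob = hmm$insert_emissions[k + 1L, ]))
        type <- "I"
      } else {
        k <- k + 1L
        if (nxt == "M")
          res <- c(res, sample(AA_ALPHABET, 1L, prob = hmm$match_emissions[k, ]))
        type <- nxt
      }
    }
    out[[s]] <- aa_seq(sprintf("%s_%03d", id_prefix, s), paste(res, collapse = ""))
  }
  out
}

#' Write the full fixture suite to a directory
#'
#' Single seeded entry point: archetype and stand-in FASTA files, the toy
#' HaloPETase1-like structure (PDB), and the reference annotation TSVs.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return invisible character vector of the files written.
#' @export
write_fixture_suite <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fix <- make_stand_ins(seed)
  files <- c(
    archetypes = file.path(dir, "synthetic_archetypes.fasta"),
    pmc = file.path(dir, "synthetic_pmc_like.fasta"),
    structure = file.path(dir, "synthetic_halopetase1_like.pdb"),
    annotation = file.path(dir, "synthetic_iib_reference_annotation.tsv"),
    halo_annotation = file.path(dir, "synthetic_halopetase1_annotation.tsv"))
  write_fasta(fix$sequences, files[["archetypes"]])
  write_fasta(fix$pmc, files[["pmc"]])
  halo <- fix$sequences$synthetic_HaloPETase1_like_typeIII
  make_toy_structure(halo, triad_positions = c(156L, 236L, 206L),
                     cys_pairs = rbind(c(64L, 126L), c(273L, 276L)),
                     path = files[["structure"]])
  write_annotation(iib_reference_annotation(), files[["annotation"]])
  write_annotation(halopetase1_annotation(), files[["halo_annotation"]])
  invisible(files)
}
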