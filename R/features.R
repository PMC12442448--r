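# Classification evidence extracted from a query sequence (and optionally a
# structure), anchored to an annotated reference by global alignment:
# lipase-box motif variant, pi-stacking clamp, subsite residues, disulfide
# positions, loop-length deltas.

#' Reference annotation for feature mapping
#'
#' Author-numbered feature positions on one reference protein. All positions
#' are in the reference's author numbering.
#'
#' @param ref_id reference protein id.
#' @param triad named integer vector `c(ser=, his=, asp=)`.
#' @param clamp_anchors two positions of the aromatic-clamp anchors (e.g. the
#'   equivalents of IsPETase 87 and 185).
#' @param oxyanion two positions whose backbone amides form the oxyanion hole.
#' @param subsite1,subsite2 positions of the two substrate-binding subsites.
#' @param extended_loop positions of the extended loop region.
#' @param loop_windows 3 x 2 matrix (rows `loop1`..`loop3`) of author-numbered
#'   `(start, end)` windows for the active-site loops.
#' @param canonical_disulfides n x 2 matrix of canonical disulfide position
#'   pairs.
#' @return object of class `ref_annotation`.
#' @export
ref_annotation <- function(ref_id, triad, clamp_anchors, oxyanion,
                           subsite1, subsite2, extended_loop,
                           loop_windows, canonical_disulfides) {
  stopifnot(length(triad) == 3L, all(c("ser", "his", "asp") %in% names(triad)),
            length(clamp_anchors) == 2L, length(oxyanion) == 2L,
            nrow(loop_windows) == 3L, ncol(loop_windows) == 2L)
  loop_windows <- matrix(as.integer(loop_windows), ncol = 2L,
                         dimnames = list(c("loop1", "loop2", "loop3"),
                                         c("start", "end")))
  if (any(loop_windows[, "end"] < loop_windows[, "start"]))
    pt_abort("loop windows must have start <= end", "petasetyper_annotation_error")
  structure(list(ref_id = ref_id,
                 triad = vapply(triad[c("ser", "his", "asp")], as.integer, integer(1)),
                 clamp_anchors = as.integer(clamp_anchors),
                 oxyanion = as.integer(oxyanion),
                 subsite1 = as.integer(subsite1),
                 subsite2 = as.integer(subsite2),
                 extended_loop = as.integer(extended_loop),
                 loop_windows = loop_windows,
                 canonical_disulfides = matrix(as.integer(canonical_disulfides),
                                               ncol = 2L)),
            class = "ref_annotation")
}

#' Read / write a reference annotation as TSV
#'
#' Three columns: `feature`, `label`, `positions` (comma-separated author
#' positions). The editable on-disk form of [ref_annotation()].
#'
#' @param path file path.
#' @return `read_annotation` returns a `ref_annotation`.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("feature", "label", "positions") %in% names(tab)))
    pt_abort("annotation TSV needs columns feature/label/positions",
             "petasetyper_annotation_error")
  pos <- function(feature, label = NULL) {
    rows <- tab$feature == feature
    if (!is.null(label)) rows <- rows & tab$label == label
    as.integer(unlist(strsplit(tab$positions[rows], ",")))
  }
  lw <- rbind(pos("loop_window", "loop1"), pos("loop_window", "loop2"),
              pos("loop_window", "loop3"))
  ds <- do.call(rbind, lapply(tab$positions[tab$feature == "disulfide"],
                              function(p) as.integer(strsplit(p, ",")[[1L]])))
  ref_annotation(ref_id = tab$label[tab$feature == "ref_id"][1L],
                 triad = c(ser = pos("triad", "ser"), his = pos("triad", "his"),
                           asp = pos("triad", "asp")),
                 clamp_anchors = c(pos("clamp", "anchor1"), pos("clamp", "anchor2")),
                 oxyanion = c(pos("oxyanion", "pos1"), pos("oxyanion", "pos2")),
                 subsite1 = pos("subsite1"), subsite2 = pos("subsite2"),
                 extended_loop = pos("extended_loop"),
                 loop_windows = lw, canonical_disulfides = ds)
}

#' @rdname read_annotation
#' @param annotation a `ref_annotation` to write.
#' @export
write_annotation <- function(annotation, path) {
  a <- annotation
  rows <- rbind(
    c("ref_id", a$ref_id, ""),
    c("triad", "ser", a$triad[["ser"]]),
    c("triad", "his", a$triad[["his"]]),
    c("triad", "asp", a$triad[["asp"]]),
    c("clamp", "anchor1", a$clamp_anchors[1L]),
    c("clamp", "anchor2", a$clamp_anchors[2L]),
    c("oxyanion", "pos1", a$oxyanion[1L]),
    c("oxyanion", "pos2", a$oxyanion[2L]),
    c("subsite1", ".", paste(a$subsite1, collapse = ",")),
    c("subsite2", ".", paste(a$subsite2, collapse = ",")),
    c("extended_loop", ".", paste(a$extended_loop, collapse = ",")),
    t(vapply(1:3, function(i) c("loop_window", rownames(a$loop_windows)[i],
                                paste(a$loop_windows[i, ], collapse = ",")),
             character(3))),
    t(vapply(seq_len(nrow(a$canonical_disulfides)),
             function(i) c("disulfide", paste0("pair", i),
                           paste(a$canonical_disulfides[i, ], collapse = ",")),
             character(3))))
  tab <- data.frame(feature = rows[, 1L], label = rows[, 2L],
                    positions = rows[, 3L], stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

annotated_positions <- function(annotation) {
  sort(unique(c(annotation$triad, annotation$clamp_anchors, annotation$oxyanion,
                annotation$subsite1, annotation$subsite2,
                annotation$extended_loop,
                as.vector(annotation$canonical_disulfides))))
}

#' Map reference positions onto a query by global alignment
#'
#' Aligns query and reference and reports, for each requested reference
#' author position, the aligned query author position, or `NA` when the
#' reference position sits opposite a gap ("unalignable").
#'
#' @param query,reference [aa_seq()] objects.
#' @param positions reference author positions to map (default: every
#'   reference position).
#' @param alignment optional precomputed [global_align()] result
#'   (query as `a`, reference as `b`).
#' @inheritParams global_align
#' @return data.frame `ref_pos`, `query_pos` (NA = unalignable), plus the
#'   alignment as attribute `"alignment"`.
#' @export
map_positions <- function(query, reference, positions = NULL, alignment = NULL,
                          matrix = blosum62(), gap_open = 10, gap_extend = 0.5) {
  if (is.null(alignment))
    alignment <- global_align(query, reference, matrix, gap_open, gap_extend)
  qa <- str_chars(alignment$aligned_a); ra <- str_chars(alignment$aligned_b)
  qidx <- cumsum(qa != GAP_CHAR); qidx[qa == GAP_CHAR] <- NA
  ridx <- cumsum(ra != GAP_CHAR); ridx[ra == GAP_CHAR] <- NA
  if (is.null(positions))
    positions <- index_to_author(reference, seq_len(nchar(reference$residues)))
  ref_index <- author_to_index(reference, positions)
  cols <- match(ref_index, ridx)
  qpos <- ifelse(is.na(cols), NA_integer_,
                 ifelse(is.na(qidx[cols]), NA_integer_,
                        index_to_author(query, ifelse(is.na(qidx[cols]), 1L, qidx[cols]))))
  out <- data.frame(ref_pos = as.integer(positions), query_pos = as.integer(qpos))
  attr(out, "alignment") <- alignment
  out
}

map_lookup <- function(map, ref_pos) {
  map$query_pos[match(ref_pos, map$ref_pos)]
}

#' Extract the lipase-box pentapeptide around the catalytic serine
#'
#' Returns the 5-mer centered on the given serine position together with a
#' variant label: `GHSMG` (type-I-associated), `GWSMG` (type-II-associated),
#' `GHSQG` (type-III-associated), `other` for any other G-X-S-X-G, or
#' `nonconforming` when the window does not fit the pattern.
#'
#' @param seq an [aa_seq()].
#' @param ser_pos author position of the catalytic serine.
#' @return list `motif` (5-letter string), `label`.
#' @export
extract_lipase_box <- function(seq, ser_pos) {
  idx <- author_to_index(seq, ser_pos)
  if (idx - 2L < 1L || idx + 2L > nchar(seq$residues))
    pt_abort("lipase-box window out of range", "petasetyper_range_error")
  motif <- substr(seq$residues, idx - 2L, idx + 2L)
  label <- if (substr(motif, 3L, 3L) != "S") "nonconforming"
           else if (motif %in% c("GHSMG", "GWSMG", "GHSQG")) motif
           else if (grepl("^G.S.G$", motif)) "other"
           else "nonconforming"
  list(motif = motif, label = label)
}

#' Check the pi-stacking clamp
#'
#' The clamp is present when both mapped anchor residues are aromatic
#' (F, Y or W). If an anchor is unalignable the status is `"undetermined"`.
#'
#' @param query an [aa_seq()].
#' @param map a [map_positions()] result covering the anchors.
#' @param annotation a [ref_annotation()].
#' @param clamp_alphabet residues counted as aromatic.
#' @return list `present` (TRUE/FALSE/NA), `status`, `residues` (letters at
#'   the mapped anchors), `positions` (query author positions).
#' @export
check_clamp <- function(query, map, annotation, clamp_alphabet = c("F", "Y", "W")) {
  qpos <- map_lookup(map, annotation$clamp_anchors)
  if (anyNA(qpos))
    return(list(present = NA, status = "undetermined",
                residues = c(NA_character_, NA_character_), positions = qpos))
  res <- residue_at(query, qpos)
  list(present = all(res %in% clamp_alphabet), status = "determined",
       residues = res, positions = qpos)
}

#' Loop-length deltas relative to the reference
#'
#' For each annotated loop window, the signed difference between the number
#' of query residues aligned within the window's alignment columns and the
#' number of reference residues in the window. Positive values are
#' insertions in the query.
#'
#' @inheritParams check_clamp
#' @param reference the reference [aa_seq()].
#' @param alignment a [global_align()] result (query as `a`).
#' @param annotation a [ref_annotation()].
#' @return named numeric vector `loop1`, `loop2`, `loop3` (NA when a window
#'   is not covered by the alignment).
#' @export
measure_loops <- function(query, reference, annotation, alignment) {
  qa <- str_chars(alignment$aligned_a); ra <- str_chars(alignment$aligned_b)
  ridx <- cumsum(ra != GAP_CHAR); ridx[ra == GAP_CHAR] <- NA
  out <- stats::setNames(numeric(3), rownames(annotation$loop_windows))
  for (i in 1:3) {
    w <- annotation$loop_windows[i, ]
    ii <- author_to_index(reference, w["start"]:w["end"])
    hit <- which(!is.na(ridx) & ridx >= ii[1L] & ridx <= ii[length(ii)])
    if (!length(hit)) { out[i] <- NA_real_; next }
    cols <- range(hit)
    qcount <- sum(qa[cols[1L]:cols[2L]] != GAP_CHAR)
    out[i] <- qcount - length(ii)
  }
  out
}

#' Infer disulfide pairs from the sequence
#'
#' Pairs the query cysteines and flags a pair as canonical when both members
#' map within +/- 2 positions of a reference canonical pair. Cysteines not
#' consumed by a canonical pair are paired consecutively along the sequence;
#' an odd cysteine is listed as unpaired. Structure-derived bonds (from
#' [detect_disulfides()]) should override this inference when coordinates
#' exist (see [build_report()]).
#'
#' @inheritParams check_clamp
#' @param tolerance window (alignment positions) for the canonical flag.
#' @return list `pairs` (data.frame `pos_a`, `pos_b`, `canonical`),
#'   `unpaired` (integer positions).
#' @export
infer_disulfides_from_sequence <- function(query, map, annotation, tolerance = 2L) {
  chars <- str_chars(query$residues)
  cys <- index_to_author(query, which(chars == "C"))
  used <- logical(length(cys))
  pairs <- list()
  for (i in seq_len(nrow(annotation$canonical_disulfides))) {
    qp <- map_lookup(map, annotation$canonical_disulfides[i, ])
    if (anyNA(qp)) next
    a <- which(!used & abs(cys - qp[1L]) <= tolerance)
    b <- which(!used & abs(cys - qp[2L]) <= tolerance)
    b <- setdiff(b, a[1L])
    if (length(a) && length(b)) {
      used[c(a[1L], b[1L])] <- TRUE
      pairs[[length(pairs) + 1L]] <-
        data.frame(pos_a = min(cys[a[1L]], cys[b[1L]]),
                   pos_b = max(cys[a[1L]], cys[b[1L]]), canonical = TRUE)
    }
  }
  rest <- cys[!used]
  while (length(rest) >= 2L) {
    pairs[[length(pairs) + 1L]] <-
      data.frame(pos_a = rest[1L], pos_b = rest[2L], canonical = FALSE)
    rest <- rest[-(1:2)]
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(pos_a = integer(0), pos_b = integer(0),
                           canonical = logical(0))
  list(pairs = pairs[order(pairs$pos_a), , drop = FALSE], unpaired = rest)
}

# canonical flag for structure-derived bonds, same +/- tolerance rule
flag_canonical <- function(pairs, map, annotation, tolerance = 2L) {
  canonical <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    for (k in seq_len(nrow(annotation$canonical_disulfides))) {
      qp <- map_lookup(map, annotation$canonical_disulfides[k, ])
      if (anyNA(qp)) next
      if ((abs(pairs$pos_a[i] - qp[1L]) <= tolerance &&
           abs(pairs$pos_b[i] - qp[2L]) <= tolerance) ||
          (abs(pairs$pos_a[i] - qp[2L]) <= tolerance &&
           abs(pairs$pos_b[i] - qp[1L]) <= tolerance)) {
        canonical[i] <- TRUE
        break
      }
    }
  }
  pairs$canonical <- canonical
  pairs
}

#' Build the full feature report for one query
#'
#' Runs the whole evidence-extraction chain against an annotated reference:
#' position map, lipase-box motif, clamp status, oxyanion and subsite
#' residues, loop deltas, extended-loop presence, disulfide pairs. When a
#' structure is supplied its geometric triad and disulfides supersede the
#' sequence-inferred ones; otherwise the sequence-derived fields are flagged
#' `"sequence-inferred"`.
#'
#' @param query an [aa_seq()].
#' @param reference the annotated reference [aa_seq()].
#' @param annotation the reference's [ref_annotation()].
#' @param structure optional `pdb_model` of the query.
#' @inheritParams global_align
#' @param extended_loop_min_cover fraction of extended-loop positions that
#'   must map for the loop to count as present.
#' @return object of class `petase_features`.
#' @export
build_report <- function(query, reference, annotation, structure = NULL,
                         matrix = blosum62(), gap_open = 10, gap_extend = 0.5,
                         extended_loop_min_cover = 0.5) {
  map <- map_positions(query, reference, annotated_positions(annotation),
                       matrix = matrix, gap_open = gap_open, gap_extend = gap_extend)
  alignment <- attr(map, "alignment")

  triad <- NULL; triad_source <- "sequence-inferred"
  ser_pos <- map_lookup(map, annotation$triad[["ser"]])
  if (!is.null(structure)) {
    triad <- tryCatch(detect_triad(structure), petasetyper_no_triad = function(e) NULL)
    if (!is.null(triad)) { ser_pos <- triad$ser; triad_source <- "structure" }
  }
  blocked <- is.na(ser_pos)
  lipase_box <- if (!blocked) extract_lipase_box(query, ser_pos)
                else list(motif = NA_character_, label = "undetermined")

  clamp <- check_clamp(query, map, annotation)
  oxy_pos <- map_lookup(map, annotation$oxyanion)
  sub1 <- map_lookup(map, annotation$subsite1)
  sub2 <- map_lookup(map, annotation$subsite2)
  get_res <- function(p) ifelse(is.na(p), NA_character_, residue_at_safe(query, p))

  loop_deltas <- measure_loops(query, reference, annotation, alignment)
  el_map <- map_lookup(map, annotation$extended_loop)
  extended_loop_present <- mean(!is.na(el_map)) >= extended_loop_min_cover

  if (!is.null(structure)) {
    ds <- detect_disulfides(structure)
    pairs <- data.frame(pos_a = ds$res_a, pos_b = ds$res_b)
    pairs <- flag_canonical(pairs, map, annotation)
    unpaired <- integer(0)
    ds_source <- "structure"
  } else {
    inf <- infer_disulfides_from_sequence(query, map, annotation)
    pairs <- inf$pairs; unpaired <- inf$unpaired
    ds_source <- "sequence-inferred"
  }

  all_pos <- annotated_positions(annotation)
  mapped <- map_lookup(map, all_pos)
  mapped_residues <- stats::setNames(get_res(mapped), all_pos)

  structure(list(query_id = query$id,
                 ref_id = annotation$ref_id,
                 lipase_box = lipase_box,
                 catalytic_ser = ser_pos,
                 triad = triad, triad_source = triad_source,
                 clamp = clamp,
                 oxyanion_residues = stats::setNames(get_res(oxy_pos),
                                                     annotation$oxyanion),
                 subsite1_residues = stats::setNames(get_res(sub1),
                                                     annotation$subsite1),
                 subsite2_residues = stats::setNames(get_res(sub2),
                                                     annotation$subsite2),
                 disulfide_pairs = pairs, unpaired_cys = unpaired,
                 disulfide_source = ds_source,
                 extended_loop_present = extended_loop_present,
                 loop_deltas = loop_deltas,
                 mapped_residues = mapped_residues,
                 blocked = blocked,
                 identity_pct = percent_identity(alignment)),
            class = "petase_features")
}

# residue_at that tolerates a vector and out-of-range NA
residue_at_safe <- function(seq, pos) {
  vapply(pos, function(p) {
    if (is.na(p)) return(NA_character_)
    idx <- p - seq$numbering_offset + 1L
    if (idx < 1L || idx > nchar(seq$residues)) return(NA_character_)
    substr(seq$residues, idx, idx)
  }, character(1))
}

#' @export
print.petase_features <- function(x, ...) {
  cat(sprintf("<petase_features> %s vs %s\n", x$query_id, x$ref_id))
  cat(sprintf("  lipase box: %s (%s)\n", x$lipase_box$motif, x$lipase_box$label))
  cat(sprintf("  clamp: %s (%s)\n",
              if (is.na(x$clamp$present)) "undetermined"
              else if (x$clamp$present) "present" else "absent",
              paste(x$clamp$residues, collapse = "/")))
  cat(sprintf("  disulfides (%s): %s\n", x$disulfide_source,
              if (nrow(x$disulfide_pairs))
                paste(sprintf("%d-%d%s", x$disulfide_pairs$pos_a,
                              x$disulfide_pairs$pos_b,
                              ifelse(x$disulfide_pairs$canonical, "*", "")),
                      collapse = ", ")
              else "none"))
  cat(sprintf("  extended loop: %s; loop deltas: %s\n",
              if (x$extended_loop_present) "present" else "absent",
              paste(sprintf("%s %+.0f", names(x$loop_deltas), x$loop_deltas),
                    collapse = ", ")))
  invisible(x)
}
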