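# Coordinate handling and the geometric classification evidence: disulfide
# detection, catalytic-triad detection, iterative least-squares superposition.
# PDB parsing is delegated to bio3d; this layer applies the model-1 /
# highest-occupancy-altloc policy and exposes a plain atom table.

#' Read a PDB coordinate file
#'
#' Only the first MODEL is kept; for atoms with alternate locations the
#' highest-occupancy altloc wins (ties: first altloc letter). Waters and other
#' heteroatoms are retained but flagged in the `het` column.
#'
#' @param path PDB file (wwPDB v3.3 columns).
#' @return object of class `pdb_model`: `id` and `atoms`, a data.frame with
#'   columns `chain`, `resno`, `insert`, `resid`, `elety`, `x`, `y`, `z`,
#'   `o`, `het`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path))
    pt_abort(sprintf("file not found: %s", path), "petasetyper_io_error")
  lines <- readLines(path)
  endm <- grep("^ENDMDL", lines)
  if (length(endm)) {                 # truncate to MODEL 1
    keep <- c(seq_len(endm[1L] - 1L), grep("^(END|CONECT|MASTER)", lines))
    lines <- lines[sort(unique(keep))]
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    on.exit(unlink(path))
  }
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE)),
                  error = function(e)
                    pt_abort(sprintf("cannot parse PDB file: %s", conditionMessage(e)),
                             "petasetyper_format_error"))
  at <- pdb$atom
  if (is.null(at) || !nrow(at) || !any(at$type == "ATOM"))
    pt_abort("no ATOM records in file", "petasetyper_empty_structure")
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    pt_abort("non-finite coordinates in PDB file", "petasetyper_format_error")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # highest-occupancy altloc per (chain, resno, insert, atom name)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, ]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "|")), ]
  at <- at[order(match(at$chain, unique(at$chain)), at$resno, at$insert), ]
  atoms <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                      resid = at$resid, elety = at$elety,
                      x = at$x, y = at$y, z = at$z, o = at$o,
                      het = at$type != "ATOM",
                      stringsAsFactors = FALSE)
  structure(list(id = sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path)),
                 atoms = atoms),
            class = "pdb_model")
}

#' @export
print.pdb_model <- function(x, ...) {
  cat(sprintf("<pdb_model> %s: %d atoms, %d residues, chains %s\n",
              x$id, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$insert))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Amino-acid sequence of one chain of a structure
#'
#' One-letter sequence of the polymer residues, with `numbering_offset` set
#' from the first residue's author number (gaps in author numbering are not
#' modeled; residues are taken in author order).
#'
#' @param model a `pdb_model`.
#' @param chain chain identifier; default the first chain.
#' @return an [aa_seq()].
#' @export
pdb_chain_seq <- function(model, chain = NULL) {
  at <- model$atoms[!model$atoms$het, ]
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain == chain, ]
  res <- at[!duplicated(paste(at$resno, at$insert)), ]
  letters1 <- bio3d::aa321(res$resid)
  letters1[letters1 == "X" | is.na(letters1)] <- "X"
  aa_seq(paste0(model$id, "_", chain), paste(letters1, collapse = ""),
         numbering_offset = res$resno[1L])
}

atom_xyz <- function(atoms, sel) as.matrix(atoms[sel, c("x", "y", "z")])

dist3 <- function(p, q) sqrt(sum((p - q)^2))

#' Detect disulfide bonds from SG-SG distances
#'
#' All cysteine pairs whose SG-SG distance is at most `max_sg_dist` (default
#' 2.3 A; the canonical bond is ~2.05 A). Each cysteine joins at most one
#' bond; assignment is greedy by ascending distance.
#'
#' @param model a `pdb_model`.
#' @param max_sg_dist maximum SG-SG distance in Angstrom.
#' @return data.frame with one row per bond: `chain_a`, `res_a`, `chain_b`,
#'   `res_b`, `sg_distance`, ordered with `res_a < res_b` and sorted by
#'   `res_a`. Zero rows when no cysteines pair up.
#' @export
detect_disulfides <- function(model, max_sg_dist = 2.3) {
  stopifnot(inherits(model, "pdb_model"))
  at <- model$atoms
  sg <- which(at$resid == "CYS" & at$elety == "SG")
  empty <- data.frame(chain_a = character(0), res_a = integer(0),
                      chain_b = character(0), res_b = integer(0),
                      sg_distance = numeric(0))
  if (length(sg) < 2L) return(empty)
  cand <- NULL
  for (i in seq_len(length(sg) - 1L)) for (j in seq.int(i + 1L, length(sg))) {
    d <- dist3(atom_xyz(at, sg[i]), atom_xyz(at, sg[j]))
    if (d <= max_sg_dist)
      cand <- rbind(cand, data.frame(i = sg[i], j = sg[j], d = d))
  }
  if (is.null(cand)) return(empty)
  cand <- cand[order(cand$d, at$resno[cand$i], at$resno[cand$j]), , drop = FALSE]
  used <- integer(0)
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (i %in% used || j %in% used) next
    used <- c(used, i, j)
    a <- i; b <- j
    if (at$resno[b] < at$resno[a]) { a <- j; b <- i }
    rows[[length(rows) + 1L]] <-
      data.frame(chain_a = at$chain[a], res_a = at$resno[a],
                 chain_b = at$chain[b], res_b = at$resno[b],
                 sg_distance = cand$d[r], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$res_a, out$res_b), , drop = FALSE]
}

#' Detect a Ser-His-Asp(/Glu) catalytic triad
#'
#' Over all (Ser, His, Asp/Glu) triples, returns the one minimizing
#' `ser_his_dist + his_asp_dist` subject to Ser OG - His NE2 <= `d1` and
#' His ND1 - Asp OD1/OD2 (or Glu OE1/OE2) <= `d2`. These thresholds cover the
#' hydrogen-bond range of a charge-relay system.
#'
#' @param model a `pdb_model`.
#' @param d1 maximum Ser OG - His NE2 distance (Angstrom).
#' @param d2 maximum His ND1 - acid carboxylate oxygen distance (Angstrom).
#' @return list of class `triad_call`: `ser`, `his`, `asp` (author residue
#'   numbers), `ser_his_dist`, `his_asp_dist`, `acid_is_glu`.
#' @export
detect_triad <- function(model, d1 = 3.5, d2 = 3.5) {
  stopifnot(inherits(model, "pdb_model"))
  at <- model$atoms
  og  <- which(at$resid == "SER" & at$elety == "OG")
  ne2 <- which(at$resid == "HIS" & at$elety == "NE2")
  nd1 <- which(at$resid == "HIS" & at$elety == "ND1")
  acid <- which((at$resid == "ASP" & at$elety %in% c("OD1", "OD2")) |
                (at$resid == "GLU" & at$elety %in% c("OE1", "OE2")))
  best <- NULL
  for (h in ne2) {
    hres <- at$resno[h]; hch <- at$chain[h]
    hd1 <- nd1[at$resno[nd1] == hres & at$chain[nd1] == hch]
    if (!length(hd1)) next
    for (s in og) {
      dsh <- dist3(atom_xyz(at, s), atom_xyz(at, h))
      if (dsh > d1) next
      for (a in acid) {
        dha <- dist3(atom_xyz(at, hd1[1L]), atom_xyz(at, a))
        if (dha > d2) next
        tot <- dsh + dha
        if (is.null(best) || tot < best$total) {
          best <- list(ser = at$resno[s], his = hres, asp = at$resno[a],
                       ser_his_dist = dsh, his_asp_dist = dha,
                       acid_is_glu = at$resid[a] == "GLU", total = tot)
        }
      }
    }
  }
  if (is.null(best))
    pt_abort("no Ser-His-Asp/Glu triple satisfies the distance thresholds",
             "petasetyper_no_triad")
  best$total <- NULL
  structure(best, class = "triad_call")
}

#' @export
print.triad_call <- function(x, ...) {
  cat(sprintf("<triad_call> Ser%d-His%d-%s%d (OG-NE2 %.2f A, ND1-O %.2f A)\n",
              x$ser, x$his, if (x$acid_is_glu) "Glu" else "Asp", x$asp,
              x$ser_his_dist, x$his_asp_dist))
  invisible(x)
}

kabsch <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2L, cm); B <- sweep(target, 2L, ct)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  # row-vector convention: y = x %*% t(R) + tr
  rot <- t(R)
  tr <- ct - as.numeric(cm %*% rot)
  list(rotation = rot, translation = tr)
}

#' Iterative least-squares superposition of paired coordinates
#'
#' Optimal rotation by the SVD (Kabsch) method with reflection correction.
#' After each cycle all pairs deviating more than `reject_cutoff` are dropped
#' at once and the fit repeated, up to `cycles` times or until no pair is
#' dropped; the protocol mirrors structure-viewer `align`-style refinement
#' (default 5 cycles, 2 A rejection).
#'
#' @param mobile,target n x 3 coordinate matrices of corresponding atoms
#'   (n >= 3), typically C-alpha pairs from a sequence alignment.
#' @param cycles maximum refinement cycles.
#' @param reject_cutoff per-pair deviation cutoff in Angstrom.
#' @return list of class `superposition`: `rotation` (3 x 3, proper),
#'   `translation` (length 3), `rmsd` (over retained pairs), `retained`
#'   (logical per input pair), `retained_pairs`, `cycles_run`. The fitted
#'   mobile coordinates are `mobile %*% rotation + translation` (row vectors).
#' @export
superpose <- function(mobile, target, cycles = 5L, reject_cutoff = 2.0) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3L, ncol(target) == 3L,
            nrow(mobile) == nrow(target))
  n <- nrow(mobile)
  if (n < 3L)
    pt_abort("superposition needs at least 3 pairs", "petasetyper_degenerate_fit")
  keep <- rep(TRUE, n)
  cycles_run <- 0L
  fit <- NULL
  repeat {
    if (sum(keep) < 3L)
      pt_abort("fewer than 3 pairs remain after outlier rejection",
               "petasetyper_degenerate_fit")
    fit <- kabsch(mobile[keep, , drop = FALSE], target[keep, , drop = FALSE])
    moved <- sweep(mobile %*% fit$rotation, 2L, fit$translation, `+`)
    dev <- sqrt(rowSums((moved - target)^2))
    cycles_run <- cycles_run + 1L
    drop_now <- keep & dev > reject_cutoff
    if (!any(drop_now) || cycles_run >= cycles) break
    keep <- keep & !drop_now
  }
  rmsd <- sqrt(mean(dev[keep]^2))
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = rmsd, retained = keep,
                 retained_pairs = sum(keep), cycles_run = cycles_run),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.3f A over %d pairs (%d cycles)\n",
              x$rmsd, x$retained_pairs, x$cycles_run))
  invisible(x)
}
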