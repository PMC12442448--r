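#' Protein sequence with author numbering
#'
#' Lightweight container for a named amino-acid sequence. Residue letters are
#' restricted to the 20 canonical amino acids plus `X` (unknown).
#' `numbering_offset` maps string positions to "author numbering" (the residue
#' numbers used in structure papers): author position of string index `i` is
#' `i + numbering_offset - 1`, so reports can cite residues the way the
#' literature does (S156, D206, ...) even after signal-peptide trimming.
#'
#' @param id record identifier.
#' @param residues character scalar of residue letters (upper case enforced).
#' @param signal_len number of N-terminal signal-peptide residues still
#'   present in `residues` (0 if none or unknown).
#' @param numbering_offset author residue number of the first letter.
#' @return An object of class `aa_seq`.
#' @export
aa_seq <- function(id, residues, signal_len = 0L, numbering_offset = 1L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  residues <- gsub("\\*+$", "", residues)
  chars <- str_chars(residues)
  bad <- which(!chars %in% AA_EXTENDED)
  if (length(bad))
    pt_abort(sprintf("record '%s': invalid residue '%s' at position %d",
                     id, chars[bad[1L]], bad[1L]),
             "petasetyper_alphabet_error")
  if (!is_count(signal_len) || signal_len >= nchar(residues))
    pt_abort(sprintf("record '%s': signal_len must be a count < sequence length", id),
             "petasetyper_range_error")
  structure(list(id = id, residues = residues,
                 signal_len = as.integer(signal_len),
                 numbering_offset = as.integer(numbering_offset)),
            class = "aa_seq")
}

#' @export
print.aa_seq <- function(x, ...) {
  cat(sprintf("<aa_seq> %s: %d aa (signal %d, numbering from %d)\n",
              x$id, nchar(x$residues), x$signal_len, x$numbering_offset))
  invisible(x)
}

#' @export
length.aa_seq <- function(x) nchar(x$residues)

#' Convert between author numbering and string index
#'
#' @param seq an [aa_seq()].
#' @param pos author residue number(s) (`author_to_index`) or string
#'   index(es) (`index_to_author`).
#' @return integer vector of the converted positions.
#' @export
author_to_index <- function(seq, pos) {
  idx <- as.integer(pos) - seq$numbering_offset + 1L
  if (any(idx < 1L | idx > nchar(seq$residues)))
    pt_abort(sprintf("record '%s': author position out of range", seq$id),
             "petasetyper_range_error")
  idx
}

#' @rdname author_to_index
#' @export
index_to_author <- function(seq, pos) as.integer(pos) + seq$numbering_offset - 1L

#' Residue letter(s) at author position(s)
#' @inheritParams author_to_index
#' @export
residue_at <- function(seq, pos) {
  idx <- author_to_index(seq, pos)
  vapply(idx, function(i) substr(seq$residues, i, i), character(1))
}

#' Remove an N-terminal signal peptide
#'
#' Drops the first `n` residues and shifts `numbering_offset` so the retained
#' residues keep their original author numbers. The default used by the
#' structure-model alignment workflow is 40 residues.
#'
#' @param seq an [aa_seq()].
#' @param n number of N-terminal residues to drop (`0 <= n < length`).
#' @return the mature [aa_seq()].
#' @export
trim_signal <- function(seq, n) {
  stopifnot(inherits(seq, "aa_seq"))
  if (!is_count(n) || n >= nchar(seq$residues))
    pt_abort(sprintf("record '%s': cannot trim %s residues from a %d-residue sequence",
                     seq$id, format(n), nchar(seq$residues)),
             "petasetyper_range_error")
  n <- as.integer(n)
  if (n == 0L) return(seq)
  out <- seq
  out$residues <- substr(seq$residues, n + 1L, nchar(seq$residues))
  out$numbering_offset <- seq$numbering_offset + n
  out$signal_len <- max(0L, seq$signal_len - n)
  out
}
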