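# FASTA and aligned-FASTA I/O. Parsing is delegated to Biostrings (which is
# gzip-transparent); records are then validated against the package alphabet.

#' Read protein sequences from a FASTA file
#'
#' @param path path to a FASTA file (plain or gzip).
#' @param id_from_first_token use only the first whitespace-delimited token of
#'   each header as the record id (default `TRUE`).
#' @return list of [aa_seq()] in file order. Lower-case letters are upper-cased
#'   and trailing `*` terminators stripped; any other non-amino-acid letter
#'   raises an alphabet error naming the record and position.
#' @export
read_fasta <- function(path, id_from_first_token = TRUE) {
  if (!file.exists(path))
    pt_abort(sprintf("file not found: %s", path), "petasetyper_io_error")
  set <- tryCatch(Biostrings::readBStringSet(path), error = function(e) NULL)
  if (is.null(set) || length(set) == 0L)
    pt_abort(sprintf("no FASTA records in %s", path), "petasetyper_empty_input")
  ids <- names(set)
  if (id_from_first_token) ids <- sub("\\s.*$", "", ids)
  out <- vector("list", length(set))
  for (i in seq_along(set))
    out[[i]] <- aa_seq(ids[i], as.character(set[[i]]))
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs list of [aa_seq()] (or a single one).
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "aa_seq")) seqs <- list(seqs)
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, character(1), "residues"))
  names(set) <- vapply(seqs, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Multiple sequence alignment container
#'
#' Rows are gapped strings of identical length over the residue alphabet plus
#' `-`. Degapping a row reproduces the source sequence.
#'
#' @param ids character vector of row ids (unique).
#' @param rows character vector of aligned strings, same length as `ids`.
#' @return object of class `aa_msa` with fields `ids`, `rows`, `column_count`.
#' @export
aa_msa <- function(ids, rows) {
  stopifnot(is.character(ids), is.character(rows), length(ids) == length(rows))
  if (anyDuplicated(ids))
    pt_abort("duplicate row ids in alignment", "petasetyper_input_error")
  ids <- unname(ids)
  rows <- unname(toupper(rows))
  nc <- unique(nchar(rows))
  if (length(nc) > 1L)
    pt_abort("alignment rows have unequal lengths", "petasetyper_format_error")
  if (length(nc) == 0L) nc <- 0L
  ok <- c(AA_EXTENDED, GAP_CHAR)
  for (i in seq_along(rows)) {
    chars <- str_chars(rows[i])
    bad <- which(!chars %in% ok)
    if (length(bad))
      pt_abort(sprintf("row '%s': invalid character '%s' at column %d",
                       ids[i], chars[bad[1L]], bad[1L]),
               "petasetyper_alphabet_error")
  }
  structure(list(ids = ids, rows = rows, column_count = as.integer(nc)),
            class = "aa_msa")
}

#' @export
print.aa_msa <- function(x, ...) {
  cat(sprintf("<aa_msa> %d rows x %d columns\n", length(x$ids), x$column_count))
  invisible(x)
}

#' Degap one alignment row back to its source sequence
#' @param msa an [aa_msa()].
#' @param i row index or id.
#' @return an [aa_seq()].
#' @export
msa_row_seq <- function(msa, i) {
  if (is.character(i)) i <- match(i, msa$ids)
  aa_seq(msa$ids[i], gsub(GAP_CHAR, "", msa$rows[i], fixed = TRUE))
}

#' Read / write an alignment in aligned-FASTA format
#'
#' Reading enforces equal row lengths (a format error otherwise); write
#' followed by read is the identity.
#'
#' @param path file path.
#' @return `read_msa_fasta` returns an [aa_msa()].
#' @export
read_msa_fasta <- function(path) {
  if (!file.exists(path))
    pt_abort(sprintf("file not found: %s", path), "petasetyper_io_error")
  set <- tryCatch(Biostrings::readBStringSet(path), error = function(e) NULL)
  if (is.null(set)) {
    if (isTRUE(file.size(path) == 0)) return(aa_msa(character(0), character(0)))
    pt_abort(sprintf("cannot parse aligned FASTA: %s", path), "petasetyper_format_error")
  }
  if (length(set) == 0L) return(aa_msa(character(0), character(0)))
  aa_msa(sub("\\s.*$", "", names(set)), as.character(set))
}

#' @rdname read_msa_fasta
#' @param msa an [aa_msa()] to write.
#' @export
write_msa_fasta <- function(msa, path) {
  stopifnot(inherits(msa, "aa_msa"))
  set <- Biostrings::BStringSet(msa$rows)
  names(set) <- msa$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
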