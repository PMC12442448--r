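# Pairwise and progressive alignment. The affine-gap dynamic program lives in
# src/align.cpp; this file builds the position-score matrices, runs the
# traceback, and derives identity statistics.

#' BLOSUM62 substitution matrix over the package alphabet
#'
#' Taken from the matrix shipped with Biostrings and restricted to the 20
#' canonical residues plus `X`.
#'
#' @return symmetric integer matrix with dimnames over the alphabet.
#' @export
blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA_EXTENDED, AA_EXTENDED]
  storage.mode(m) <- "double"
  m
}

#' Read a substitution matrix in NCBI text format
#'
#' Lines starting with `#` are comments; the first non-comment row lists the
#' column letters, subsequent rows start with the row letter.
#'
#' @param path file path.
#' @return symmetric numeric matrix with letter dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  rows <- vapply(body, `[`, character(1), 1L)
  vals <- t(vapply(body, function(x) as.numeric(x[-1L]), numeric(length(cols))))
  dimnames(vals) <- list(rows, cols)
  if (!isTRUE(all.equal(vals[cols, cols], t(vals[cols, cols]))))
    pt_abort("substitution matrix is not symmetric", "petasetyper_format_error")
  vals
}

check_score_matrix <- function(matrix) {
  if (is.null(dimnames(matrix)) ||
      !all(AA_ALPHABET %in% rownames(matrix)) ||
      !all(AA_ALPHABET %in% colnames(matrix)))
    pt_abort("substitution matrix must cover the 20 canonical residues",
             "petasetyper_input_error")
  invisible(matrix)
}

encode_seq <- function(residues) {
  m <- match(str_chars(residues), AA_EXTENDED)
  m
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch over the full sequence lengths (end gaps penalized). A gap
#' of length `k` costs `gap_open + k * gap_extend`. Traceback ties are broken
#' deterministically, preferring diagonal over up (gap in `b`) over left.
#'
#' @param a,b [aa_seq()] objects (non-empty).
#' @param matrix substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend gap penalties (positive costs).
#' @return object of class `aa_alignment`: `aligned_a`, `aligned_b` (gapped
#'   strings), `score`, `identity_pct`, `aligned_columns`, `match_count`.
#' @export
global_align <- function(a, b, matrix = blosum62(), gap_open = 10, gap_extend = 0.5) {
  stopifnot(inherits(a, "aa_seq"), inherits(b, "aa_seq"))
  if (nchar(a$residues) == 0L || nchar(b$residues) == 0L)
    pt_abort("cannot align an empty sequence", "petasetyper_input_error")
  check_score_matrix(matrix)
  ca <- str_chars(a$residues); cb <- str_chars(b$residues)
  S <- matrix[ca, cb, drop = FALSE]
  res <- nw_core(S, gap_open, gap_extend)
  moves <- res$moves
  out_a <- character(length(moves)); out_b <- character(length(moves))
  i <- 0L; j <- 0L
  for (k in seq_along(moves)) {
    if (moves[k] == 1L) { i <- i + 1L; j <- j + 1L; out_a[k] <- ca[i]; out_b[k] <- cb[j] }
    else if (moves[k] == 2L) { i <- i + 1L; out_a[k] <- ca[i]; out_b[k] <- GAP_CHAR }
    else { j <- j + 1L; out_a[k] <- GAP_CHAR; out_b[k] <- cb[j] }
  }
  aligned_a <- paste(out_a, collapse = "")
  aligned_b <- paste(out_b, collapse = "")
  match_count <- sum(out_a == out_b & out_a != GAP_CHAR)
  cols <- length(moves)
  structure(list(id_a = a$id, id_b = b$id,
                 aligned_a = aligned_a, aligned_b = aligned_b,
                 score = res$score,
                 identity_pct = 100 * match_count / cols,
                 aligned_columns = cols, match_count = match_count,
                 seq_a = a, seq_b = b),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("<aa_alignment> %s vs %s: score %.1f, identity %.1f%% (%d/%d columns)\n",
              x$id_a, x$id_b, x$score, x$identity_pct, x$match_count,
              x$aligned_columns))
  invisible(x)
}

#' Percent identity of an alignment
#'
#' Matches divided by aligned columns (columns with at least one non-gap row),
#' times 100, reported to 0.1. Note the denominator convention: aligned
#' columns, not the shorter sequence length.
#'
#' @param res an `aa_alignment`.
#' @return numeric percent in `[0, 100]`.
#' @export
percent_identity <- function(res) {
  stopifnot(inherits(res, "aa_alignment"))
  if (res$aligned_columns == 0L)
    pt_abort("identity undefined for a zero-column alignment",
             "petasetyper_undefined_identity")
  round(100 * res$match_count / res$aligned_columns, 1)
}

# frequency profile of an alignment block: (A+1) x ncol matrix over
# AA_EXTENDED plus gap, as plain column proportions over all rows
block_profile <- function(rows) {
  chars <- do.call(rbind, lapply(rows, str_chars))
  nc <- ncol(chars)
  lev <- c(AA_EXTENDED, GAP_CHAR)
  prof <- matrix(0, nrow = length(lev), ncol = nc, dimnames = list(lev, NULL))
  for (j in seq_len(nc)) {
    tab <- table(factor(chars[, j], levels = lev))
    prof[, j] <- as.numeric(tab) / nrow(chars)
  }
  prof
}

# expected substitution score between two profile columns; gaps contribute 0
profile_col_scores <- function(profA, profB, matrix) {
  a <- profA[AA_EXTENDED, , drop = FALSE]
  b <- profB[AA_EXTENDED, , drop = FALSE]
  t(a) %*% matrix[AA_EXTENDED, AA_EXTENDED] %*% b
}

merge_profiles <- function(rowsA, rowsB, matrix, gap_open, gap_extend) {
  S <- profile_col_scores(block_profile(rowsA), block_profile(rowsB), matrix)
  moves <- nw_core(S, gap_open, gap_extend)$moves
  splitA <- lapply(rowsA, str_chars)
  splitB <- lapply(rowsB, str_chars)
  outA <- matrix("", nrow = length(rowsA), ncol = length(moves))
  outB <- matrix("", nrow = length(rowsB), ncol = length(moves))
  i <- 0L; j <- 0L
  for (k in seq_along(moves)) {
    if (moves[k] != 3L) i <- i + 1L
    if (moves[k] != 2L) j <- j + 1L
    outA[, k] <- if (moves[k] == 3L) GAP_CHAR else vapply(splitA, `[`, character(1), i)
    outB[, k] <- if (moves[k] == 2L) GAP_CHAR else vapply(splitB, `[`, character(1), j)
  }
  c(apply(outA, 1L, paste, collapse = ""), apply(outB, 1L, paste, collapse = ""))
}

#' Progressive multiple sequence alignment
#'
#' Deterministic progressive scheme: pairwise identity distances feed a UPGMA
#' guide tree; profiles are merged bottom-up by profile-profile
#' Needleman-Wunsch with the same affine gap model as [global_align()]. Gaps,
#' once inserted, are never removed.
#'
#' @param seqs list of at least two [aa_seq()] with unique ids.
#' @inheritParams global_align
#' @return an [aa_msa()] whose rows degap to the inputs (input order).
#' @export
progressive_msa <- function(seqs, matrix = blosum62(), gap_open = 10, gap_extend = 0.5) {
  if (length(seqs) < 2L)
    pt_abort("progressive_msa needs at least two sequences", "petasetyper_input_error")
  ids <- vapply(seqs, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    pt_abort("duplicate sequence ids", "petasetyper_input_error")
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    al <- global_align(seqs[[i]], seqs[[j]], matrix, gap_open, gap_extend)
    D[i, j] <- D[j, i] <- 1 - al$identity_pct / 100
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  blocks <- lapply(seqs, function(s) stats::setNames(s$residues, s$id))
  merged <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    pick <- function(k) if (k < 0) blocks[[-k]] else merged[[k]]
    A <- pick(hc$merge[step, 1L]); B <- pick(hc$merge[step, 2L])
    rows <- merge_profiles(unname(A), unname(B), matrix, gap_open, gap_extend)
    merged[[step]] <- stats::setNames(rows, c(names(A), names(B)))
  }
  final <- merged[[n - 1L]]
  aa_msa(ids, unname(final[ids]))
}

#' Per-column residue frequencies of an alignment
#'
#' For each column: frequency of each residue among non-gap rows (summing to
#' 1) plus the gap fraction over all rows. This is the table behind sequence
#' logos.
#'
#' @param msa an [aa_msa()] with at least one row.
#' @param columns optional integer vector of columns (default all).
#' @return list with `freq` (residues x columns matrix) and `gap_fraction`
#'   (numeric per column).
#' @export
column_frequencies <- function(msa, columns = NULL) {
  stopifnot(inherits(msa, "aa_msa"))
  if (length(msa$ids) == 0L)
    pt_abort("empty alignment", "petasetyper_empty_input")
  if (is.null(columns)) columns <- seq_len(msa$column_count)
  if (any(columns < 1L | columns > msa$column_count))
    pt_abort("column index out of range", "petasetyper_range_error")
  chars <- do.call(rbind, lapply(msa$rows, str_chars))
  freq <- matrix(0, nrow = length(AA_EXTENDED), ncol = length(columns),
                 dimnames = list(AA_EXTENDED, columns))
  gap_fraction <- numeric(length(columns))
  for (k in seq_along(columns)) {
    col <- chars[, columns[k]]
    gap_fraction[k] <- mean(col == GAP_CHAR)
    res <- col[col != GAP_CHAR]
    if (length(res))
      freq[, k] <- as.numeric(table(factor(res, levels = AA_EXTENDED))) / length(res)
  }
  list(freq = freq, gap_fraction = stats::setNames(gap_fraction, columns))
}
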