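# Simplified profile hidden Markov model for homolog mining. Laplace
# pseudocounts and a glocal (Begin -> all match states -> End) path set; bit
# scores are log2 odds against an i.i.d. background and live on this model's
# own scale (no numeric parity with other HMM packages is claimed). The DP
# recursions are compiled (src/phmm.cpp).

#' Build a profile HMM from a seed alignment
#'
#' Columns whose gap fraction is below `match_gap_frac` become match states.
#' Match emissions are Laplace-smoothed column counts,
#' `(counts + pseudocount) / (n + 20 * pseudocount)`; transition probabilities
#' are smoothed likewise over the three successors of each state; insert
#' states emit from the null model. The null model is the overall residue
#' frequency of the alignment with the same pseudocounts.
#'
#' @param msa an [aa_msa()] with at least two rows.
#' @param match_gap_frac gap-fraction threshold below which a column is a
#'   match column.
#' @param pseudocount Laplace pseudocount weight.
#' @return object of class `profile_hmm` with fields `match_count`,
#'   `match_emissions` (K x 20), `insert_emissions` ((K+1) x 20),
#'   `transitions` (list `M`, `I`, `D`, each (K+1) x 3 over successors
#'   M/I/D), `null_model` (length 20), `match_columns`.
#' @export
build_profile <- function(msa, match_gap_frac = 0.5, pseudocount = 1.0) {
  stopifnot(inherits(msa, "aa_msa"))
  if (length(msa$ids) < 2L)
    pt_abort("profile needs an alignment with >= 2 rows", "petasetyper_input_error")
  chars <- do.call(rbind, lapply(msa$rows, str_chars))
  nrow_ <- nrow(chars); ncol_ <- ncol(chars)
  gap_frac <- colMeans(chars == GAP_CHAR)
  match_cols <- which(gap_frac < match_gap_frac)
  K <- length(match_cols)
  if (K == 0L)
    pt_abort("no column qualifies as a match state", "petasetyper_degenerate_model")

  A <- length(AA_ALPHABET)
  count_col <- function(col) {
    res <- col[col != GAP_CHAR & col != "X"]
    as.numeric(table(factor(res, levels = AA_ALPHABET)))
  }
  match_emissions <- matrix(0, K, A, dimnames = list(NULL, AA_ALPHABET))
  for (k in seq_len(K)) {
    cnt <- count_col(chars[, match_cols[k]])
    match_emissions[k, ] <- (cnt + pseudocount) / (sum(cnt) + A * pseudocount)
  }
  all_cnt <- count_col(as.vector(chars))
  null_model <- (all_cnt + pseudocount) / (sum(all_cnt) + A * pseudocount)
  names(null_model) <- AA_ALPHABET
  insert_emissions <- matrix(null_model, K + 1L, A, byrow = TRUE,
                             dimnames = list(NULL, AA_ALPHABET))

  # per-row state paths -> transition counts; states indexed k = 0..K
  is_match <- logical(ncol_); is_match[match_cols] <- TRUE
  col_state_idx <- cumsum(is_match)        # match-state index at each column
  tc <- list(M = matrix(0, K + 1L, 3L), I = matrix(0, K + 1L, 3L),
             D = matrix(0, K + 1L, 3L))
  succ <- c(M = 1L, I = 2L, D = 3L)
  for (r in seq_len(nrow_)) {
    prev_type <- "M"; prev_k <- 0L   # Begin behaves as M_0
    for (j in seq_len(ncol_)) {
      ch <- chars[r, j]
      if (is_match[j]) {
        type <- if (ch == GAP_CHAR) "D" else "M"
        k <- col_state_idx[j]
      } else {
        if (ch == GAP_CHAR) next
        type <- "I"; k <- col_state_idx[j]
      }
      tc[[prev_type]][prev_k + 1L, succ[[type]]] <-
        tc[[prev_type]][prev_k + 1L, succ[[type]]] + 1
      prev_type <- type; prev_k <- k
    }
    # exit to End, booked in the M successor slot of state K
    tc[[prev_type]][prev_k + 1L, succ[["M"]]] <-
      tc[[prev_type]][prev_k + 1L, succ[["M"]]] + 1
  }
  transitions <- lapply(tc, function(m) {
    p <- (m + pseudocount) / (rowSums(m) + 3 * pseudocount)
    colnames(p) <- c("M", "I", "D")
    p
  })

  structure(list(match_count = K,
                 match_emissions = match_emissions,
                 insert_emissions = insert_emissions,
                 transitions = transitions,
                 null_model = null_model,
                 match_columns = match_cols),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm> %d match states\n", x$match_count))
  invisible(x)
}

phmm_score <- function(hmm, seq, forward) {
  stopifnot(inherits(hmm, "profile_hmm"), inherits(seq, "aa_seq"))
  if (nchar(seq$residues) == 0L)
    pt_abort("cannot score an empty sequence", "petasetyper_input_error")
  chars <- str_chars(seq$residues)
  code <- match(chars, AA_ALPHABET)
  if (any(is.na(code) & chars != "X"))
    pt_abort(sprintf("record '%s': residue outside the scoring alphabet", seq$id),
             "petasetyper_alphabet_error")
  code[is.na(code)] <- 0L            # X -> -1 after 0-base shift
  logp <- phmm_logprob(log(hmm$match_emissions), log(hmm$insert_emissions),
                       log(hmm$transitions$M), log(hmm$transitions$I),
                       log(hmm$transitions$D), code - 1L, forward)
  lognull <- sum(log(hmm$null_model[chars[chars != "X"]]))
  (logp - lognull) / log(2)
}

#' Score a sequence against a profile HMM (bits)
#'
#' Log2 odds of the sequence under the model versus the i.i.d. null model,
#' computed in log space. `score_forward` sums over all paths;
#' `score_viterbi` takes the single best path, so forward bits are always at
#' least the Viterbi bits.
#'
#' @param hmm a [build_profile()] model.
#' @param seq an [aa_seq()].
#' @return one-row data.frame: `seq_id`, `bits`, `algorithm`.
#' @export
score_forward <- function(hmm, seq) {
  data.frame(seq_id = seq$id, bits = phmm_score(hmm, seq, TRUE),
             algorithm = "forward", stringsAsFactors = FALSE)
}

#' @rdname score_forward
#' @export
score_viterbi <- function(hmm, seq) {
  data.frame(seq_id = seq$id, bits = phmm_score(hmm, seq, FALSE),
             algorithm = "viterbi", stringsAsFactors = FALSE)
}

#' Score many sequences
#' @param hmm a [build_profile()] model.
#' @param seqs list of [aa_seq()].
#' @param algorithm `"forward"` (default) or `"viterbi"`.
#' @return data.frame of per-sequence scores.
#' @export
score_sequences <- function(hmm, seqs, algorithm = c("forward", "viterbi")) {
  algorithm <- match.arg(algorithm)
  f <- if (algorithm == "forward") score_forward else score_viterbi
  do.call(rbind, lapply(seqs, f, hmm = hmm))
}

#' Apply the mining thresholds and split hits into score groups
#'
#' Hits must score strictly above `hit_threshold` bits; hits below
#' `group_boundary` form the low group and hits at or above it the high group
#' (boundary membership goes to the high group).
#'
#' @param scores data.frame with columns `seq_id`, `bits` (as produced by
#'   [score_sequences()]).
#' @param hit_threshold minimum bit score, strict.
#' @param group_boundary low/high group boundary in bits.
#' @return list with data.frames `hits`, `low_group`, `high_group`; `hits`
#'   gains a `group` column.
#' @export
filter_and_group <- function(scores, hit_threshold = 100, group_boundary = 200) {
  stopifnot(is.data.frame(scores), all(c("seq_id", "bits") %in% names(scores)))
  hits <- scores[scores$bits > hit_threshold, , drop = FALSE]
  hits$group <- ifelse(hits$bits >= group_boundary, "high", "low")
  list(hits = hits,
       low_group = hits[hits$group == "low", setdiff(names(hits), "group"), drop = FALSE],
       high_group = hits[hits$group == "high", setdiff(names(hits), "group"), drop = FALSE])
}

#' Write / read a profile HMM as plain text
#'
#' Documented line-oriented format: a header (`petasetyper_phmm`, version,
#' match-state count), the null model, then per-state emission and transition
#' rows, all tab-separated.
#'
#' @param hmm a `profile_hmm`.
#' @param path file path.
#' @export
write_phmm <- function(hmm, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("petasetyper_phmm 1",
               paste("K", hmm$match_count),
               paste(c("NULL", format(hmm$null_model, digits = 17)), collapse = "\t")),
             con)
  for (k in seq_len(hmm$match_count))
    writeLines(paste(c(sprintf("MAT %d", k),
                       format(hmm$match_emissions[k, ], digits = 17)), collapse = "\t"), con)
  for (k in seq_len(hmm$match_count + 1L))
    writeLines(paste(c(sprintf("INS %d", k - 1L),
                       format(hmm$insert_emissions[k, ], digits = 17)), collapse = "\t"), con)
  for (tp in c("M", "I", "D"))
    for (k in seq_len(hmm$match_count + 1L))
      writeLines(paste(c(sprintf("TR%s %d", tp, k - 1L),
                         format(hmm$transitions[[tp]][k, ], digits = 17)), collapse = "\t"), con)
  writeLines(paste(c("MATCHCOLS", hmm$match_columns), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_phmm
#' @return `read_phmm` returns the `profile_hmm`.
#' @export
read_phmm <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "petasetyper_phmm"))
    pt_abort("not a petasetyper profile-HMM file", "petasetyper_format_error")
  K <- as.integer(strsplit(lines[2L], " ")[[1L]][2L])
  fields <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  tag <- vapply(fields, `[`, character(1), 1L)
  nums <- lapply(fields, function(f) as.numeric(f[-1L]))
  grab <- function(prefix, n) {
    idx <- which(startsWith(tag, prefix))
    m <- do.call(rbind, nums[idx])
    stopifnot(nrow(m) == n)
    m
  }
  A <- length(AA_ALPHABET)
  null_model <- stats::setNames(nums[[which(tag == "NULL")]], AA_ALPHABET)
  me <- grab("MAT ", K); colnames(me) <- AA_ALPHABET
  ie <- grab("INS ", K + 1L); colnames(ie) <- AA_ALPHABET
  tr <- lapply(c(M = "TRM ", I = "TRI ", D = "TRD "), function(p) {
    m <- grab(p, K + 1L); colnames(m) <- c("M", "I", "D"); m
  })
  mc <- as.integer(nums[[which(tag == "MATCHCOLS")]])
  structure(list(match_count = K, match_emissions = me, insert_emissions = ie,
                 transitions = tr, null_model = null_model, match_columns = mc),
            class = "profile_hmm")
}
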