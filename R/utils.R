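# Shared helpers: structured error conditions and the amino-acid alphabet.

# 20 canonical residues; 'X' is tolerated as "unknown".
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_EXTENDED <- c(AA_ALPHABET, "X")
GAP_CHAR <- "-"

# background alphabet for random fixture residues: no Cys, so disulfide
# evidence stays entirely under generator control
AA_BACKGROUND <- AA_ALPHABET[AA_ALPHABET != "C"]

pt_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "petasetyper_error")))
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == as.integer(x)
}

# split a residue string into single letters
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
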