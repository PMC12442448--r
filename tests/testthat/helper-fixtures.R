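# Shared fixtures and independent oracles, built once per test run.

FIX <- make_stand_ins(1)
IIB_REF_SEQ <- FIX$sequences$synthetic_IsPETase_like_typeIIb
IIB_ANN <- FIX$annotation
HALO <- FIX$sequences$synthetic_HaloPETase1_like_typeIII

random_aa <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H", "I",
                                      "K", "L", "M", "N", "P", "Q", "R", "S",
                                      "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# plain (non-affine) global alignment DP: the linear-gap score oracle
bf_linear_score <- function(a, b, mat, g) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  F <- matrix(-Inf, n + 1, m + 1)
  F[1, ] <- -g * (0:m); F[, 1] <- -g * (0:n)
  for (i in 1:n) for (j in 1:m)
    F[i + 1, j + 1] <- max(F[i, j] + mat[ca[i], cb[j]],
                           F[i, j + 1] - g, F[i + 1, j] - g)
  F[n + 1, m + 1]
}

# hand-built toy profile HMM over an {A, C} emission support
toy_hmm <- function(K, pA = 0.7, tmm = 0.8, tmi = 0.1) {
  A <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  me <- matrix(0, K, 20, dimnames = list(NULL, A))
  me[, "A"] <- pA; me[, "C"] <- 1 - pA
  ie <- matrix(0, K + 1, 20, dimnames = list(NULL, A))
  ie[, "A"] <- 0.5; ie[, "C"] <- 0.5
  tr <- function() matrix(rep(c(tmm, tmi, 1 - tmm - tmi), each = K + 1),
                          K + 1, 3, dimnames = list(NULL, c("M", "I", "D")))
  null <- stats::setNames(rep(1 / 20, 20), A)
  structure(list(match_count = K, match_emissions = me, insert_emissions = ie,
                 transitions = list(M = tr(), I = tr(), D = tr()),
                 null_model = null, match_columns = seq_len(K)),
            class = "profile_hmm")
}

# random valid toy model: Dirichlet-ish draws over the {A, C} support
random_toy_hmm <- function(K) {
  h <- toy_hmm(K)
  rnd3 <- function(n) {
    m <- matrix(stats::rexp(3 * n), n, 3)
    m / rowSums(m)
  }
  for (tp in c("M", "I", "D")) {
    m <- rnd3(K + 1)
    colnames(m) <- c("M", "I", "D")
    h$transitions[[tp]] <- m
  }
  pa <- stats::runif(K, 0.1, 0.9)
  h$match_emissions[, "A"] <- pa; h$match_emissions[, "C"] <- 1 - pa
  h
}

# exhaustive path-sum oracle for P(seq | model), independent of the DP
enum_prob <- function(hmm, chars) {
  K <- hmm$match_count
  rec <- function(type, k, i) {
    pr <- hmm$transitions[[type]][k + 1, ]
    tot <- 0
    if (k == K && i > length(chars)) tot <- tot + pr[["M"]]
    if (k < K && i <= length(chars))
      tot <- tot + pr[["M"]] * hmm$match_emissions[k + 1, chars[i]] *
        rec("M", k + 1, i + 1)
    if (i <= length(chars))
      tot <- tot + pr[["I"]] * hmm$insert_emissions[k + 1, chars[i]] *
        rec("I", k, i + 1)
    if (k < K) tot <- tot + pr[["D"]] * rec("D", k + 1, i)
    tot
  }
  unname(rec("M", 0, 1))
}

# model probability of a sequence reconstructed from the public bit score
forward_prob <- function(hmm, s) {
  chars <- strsplit(s, "")[[1]]
  2^score_forward(hmm, aa_seq("t", s))$bits * prod(hmm$null_model[chars])
}

# minimal hand-written PDB ATOM line
pdb_atom_line <- function(serial, elety, resid, resno, x, y, z,
                          occ = 1.00, alt = " ", chain = "A") {
  sprintf("ATOM  %5d %s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, formatC(paste0(" ", elety), width = -4L), alt, resid, chain,
          resno, x, y, z, occ, 20.00, substr(elety, 1L, 1L))
}

write_pdb_lines <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

# random proper rotation from a fixed axis-angle construction
random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0.1, pi - 0.1)
  Kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
}
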