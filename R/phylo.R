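# Distance-based phylogeny: uncorrected p-distances from an alignment,
# neighbor joining (Saitou-Nei, via ape), column-resampling bootstrap
# support, Newick export. Negative NJ branch lengths are clamped to zero
# with the deficit recorded.

#' Pairwise p-distances from an alignment
#'
#' `d(i, j) = 1 - identity`, identity computed over columns where neither row
#' is gapped. An error is raised for a pair with no comparable column.
#'
#' @param msa an [aa_msa()] with at least three rows.
#' @param correction `"none"` (uncorrected p-distance, default) or
#'   `"kimura"` (Kimura's 1983 protein-distance correction).
#' @return symmetric numeric matrix with zero diagonal and row/col labels.
#' @export
distances_from_msa <- function(msa, correction = c("none", "kimura")) {
  stopifnot(inherits(msa, "aa_msa"))
  correction <- match.arg(correction)
  n <- length(msa$ids)
  if (n < 3L)
    pt_abort("need at least three rows for a distance matrix",
             "petasetyper_size_error")
  chars <- do.call(rbind, lapply(msa$rows, str_chars))
  D <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    ok <- chars[i, ] != GAP_CHAR & chars[j, ] != GAP_CHAR
    if (!any(ok))
      pt_abort(sprintf("rows '%s' and '%s' share no comparable column",
                       msa$ids[i], msa$ids[j]),
               "petasetyper_incomparable_pair")
    p <- 1 - mean(chars[i, ok] == chars[j, ok])
    if (correction == "kimura") {
      arg <- 1 - p - 0.2 * p^2
      if (arg <= 0)
        pt_abort("p-distance too large for the Kimura correction",
                 "petasetyper_incomparable_pair")
      p <- -log(arg)
    }
    D[i, j] <- D[j, i] <- p
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix (standard Q-criterion,
#' as implemented in ape). Negative branch lengths are clamped to zero;
#' the clamped deficit is attached as attribute `"clamped_total"`.
#'
#' @param dm symmetric distance matrix with labels (>= 3 taxa).
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L)
    pt_abort("neighbor joining needs at least 3 taxa", "petasetyper_size_error")
  if (max(abs(dm - t(dm))) > 1e-8 || any(diag(dm) != 0))
    pt_abort("distance matrix must be symmetric with zero diagonal",
             "petasetyper_input_error")
  # deterministic taxon order: ape's NJ resolves ties by input order
  ord <- order(rownames(dm))
  tree <- ape::nj(dm[ord, ord])
  neg <- tree$edge.length < 0
  clamped <- -sum(tree$edge.length[neg])
  tree$edge.length[neg] <- 0
  attr(tree, "clamped_total") <- clamped
  tree
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the full-data tree the
#' fraction of replicates containing the same bipartition. Seeded and
#' reproducible.
#'
#' @param msa an [aa_msa()].
#' @param replicates number of bootstrap replicates (>= 1); the reference
#'   analysis convention is 1000.
#' @param seed integer seed.
#' @param correction passed to [distances_from_msa()].
#' @return the full-data NJ tree with `node.label` set to support fractions
#'   (root label empty).
#' @export
bootstrap_support <- function(msa, replicates = 1000L, seed = 1L,
                              correction = "none") {
  stopifnot(inherits(msa, "aa_msa"))
  if (!is_count(replicates) || replicates < 1L)
    pt_abort("replicates must be a positive integer", "petasetyper_parameter_error")
  ref <- nj_tree(distances_from_msa(msa, correction))
  set.seed(seed)
  nrep <- as.integer(replicates)
  boot <- vector("list", nrep)
  for (r in seq_len(nrep)) {
    cols <- sample.int(msa$column_count, msa$column_count, replace = TRUE)
    rows <- vapply(msa$rows,
                   function(x) paste(str_chars(x)[cols], collapse = ""),
                   character(1))
    bmsa <- aa_msa(msa$ids, unname(rows))
    boot[[r]] <- nj_tree(distances_from_msa(bmsa, correction))
  }
  counts <- ape::prop.clades(ref, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- counts / nrep
  ref$node.label <- as.character(support)
  ref$node.label[1L] <- ""      # root of the unrooted representation
  attr(ref, "support") <- support
  ref
}

newick_quote <- function(labels) {
  needs <- grepl("[][ ():;,']", labels)
  labels[needs] <- paste0("'", gsub("'", "''", labels[needs]), "'")
  labels
}

#' Write a tree in Newick format
#'
#' Branch lengths are kept; node labels (e.g. bootstrap supports) become
#' internal labels. Labels containing Newick metacharacters are quoted.
#'
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  # ape mangles labels containing metacharacters; route them through
  # placeholders and restore the quoted form afterwards
  needs <- grepl("[][ ():;,']", tree$tip.label)
  placeholders <- sprintf("PTQUOTE%dPT", seq_along(tree$tip.label))
  orig <- tree$tip.label
  tree$tip.label[needs] <- placeholders[needs]
  txt <- ape::write.tree(tree)
  for (i in which(needs))
    txt <- sub(placeholders[i], newick_quote(orig[i]), txt, fixed = TRUE)
  writeLines(txt, path)
  invisible(path)
}

#' Read a Newick tree
#' @param path file path.
#' @return an `ape::phylo`.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  quoted <- grepl("^'.*'$", tree$tip.label)
  tree$tip.label[quoted] <-
    gsub("''", "'", sub("^'(.*)'$", "\\1", tree$tip.label[quoted]))
  tree
}

#' Write a distance matrix (PHYLIP square or TSV)
#' @param dm labelled distance matrix.
#' @param path output path.
#' @param format `"phylip"` or `"tsv"`.
#' @export
write_distance_matrix <- function(dm, path, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(dm, path, sep = "\t", quote = FALSE, col.names = NA)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("%5d", nrow(dm)), con)
    for (i in seq_len(nrow(dm)))
      writeLines(paste(c(formatC(rownames(dm)[i], width = -10),
                         formatC(dm[i, ], format = "f", digits = 6)),
                       collapse = "  "), con)
  }
  invisible(path)
}
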