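.aln_matrix <- function(aligned) {
  m <- matrix(unlist(strsplit(aligned, "", fixed = TRUE), use.names = FALSE),
              nrow = length(aligned), byrow = TRUE)
  rownames(m) <- names(aligned)
  m
}

.named_seqs <- function(sequences) {
  .assert_peptide(sequences, "sequences")
  if (is.null(names(sequences))) names(sequences) <- sequences
  if (anyDuplicated(names(sequences))) stop("sequence ids must be unique")
  sequences
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch with affine gaps (a gap of length g costs
#' `gap_open + (g - 1) * gap_extend`) and a deterministic traceback that
#' prefers match over deletion over insertion on score ties.
#'
#' @param a,b Non-empty peptide strings.
#' @param substitution 20 x 20 scoring matrix in the internal residue order
#'   (default BLOSUM62).
#' @param gap_open,gap_extend Positive gap penalties.
#' @return List with gapped strings `a`, `b` and the alignment `score`.
#' @export
pairwise_align <- function(a, b, substitution = blosum62_matrix(),
                           gap_open = 10, gap_extend = 0.5) {
  .assert_peptide(c(a, b))
  cpp_pairwise_align(a, b, substitution, gap_open, gap_extend)
}

#' UPGMA guide tree over pairwise identity distances
#'
#' Distances are `1 - sequence_identity`; the tree is average-linkage (UPGMA)
#' agglomeration, computed by `stats::hclust`. Determinism comes from the
#' total input order (abundance rank with lexicographic tie-break upstream):
#' identical input order gives an identical tree.
#'
#' @param sequences Named character vector (>= 2; a single sequence yields a
#'   trivial one-leaf tree object).
#' @return `guide_tree`: list with the `hclust` object, `labels`, `sequences`.
#' @export
build_guide_tree <- function(sequences) {
  sequences <- .named_seqs(sequences)
  n <- length(sequences)
  if (n < 2L) {
    return(structure(list(hclust = NULL, labels = names(sequences),
                          sequences = sequences), class = "guide_tree"))
  }
  d <- cpp_identity_dist(unname(sequences), 2, 1)
  attributes(d) <- list(Size = n, Labels = names(sequences), Diag = FALSE,
                        Upper = FALSE, method = "identity", class = "dist")
  structure(list(hclust = hclust(d, method = "average"),
                 labels = names(sequences), sequences = sequences),
            class = "guide_tree")
}

#' Newick export of a guide tree
#'
#' @param tree A `guide_tree`.
#' @return Newick string.
#' @export
guide_tree_newick <- function(tree) {
  stopifnot(inherits(tree, "guide_tree"))
  if (is.null(tree$hclust)) return(sprintf("(%s);", tree$labels[1L]))
  ape::write.tree(ape::as.phylo(tree$hclust))
}

#' Progressive multiple sequence alignment
#'
#' Profile-profile progressive alignment up a UPGMA guide tree, BLOSUM62 with
#' gap open 10 / extend 0.5 by default. The d-initiator `y` is scored as `Y`
#' but preserved in the output rows. Removing gaps from any row reproduces
#' its input sequence exactly.
#'
#' @param sequences Named character vector of peptides.
#' @param tree Optional `guide_tree`; built from `sequences` when `NULL`.
#' @param substitution,gap_open,gap_extend Scoring, as [pairwise_align()].
#' @return An `alignment_profile`: list with `aligned` (named gapped rows),
#'   `conservation` (per column), `consensus`, `tree`.
#' @export
progressive_align <- function(sequences, tree = NULL,
                              substitution = blosum62_matrix(),
                              gap_open = 10, gap_extend = 0.5) {
  sequences <- .named_seqs(sequences)
  if (is.null(tree)) tree <- build_guide_tree(sequences)
  stopifnot(identical(tree$labels, names(sequences)))
  if (length(sequences) == 1L) {
    aligned <- sequences
  } else {
    aligned <- setNames(
      as.character(cpp_progressive_align(unname(sequences), tree$hclust$merge,
                                         substitution, gap_open, gap_extend)),
      names(sequences))
  }
  cons <- column_conservation(aligned)
  structure(list(aligned = aligned,
                 conservation = cons,
                 consensus = consensus_sequence(aligned),
                 tree = tree),
            class = "alignment_profile")
}

#' @export
print.alignment_profile <- function(x, ...) {
  cat(sprintf("alignment profile: %d sequences x %d columns\n",
              length(x$aligned), nchar(x$aligned[[1L]])))
  cat("consensus:", x$consensus, "\n")
  invisible(x)
}

.as_aligned <- function(x) {
  if (inherits(x, "alignment_profile")) x$aligned else x
}

#' Per-column conservation score
#'
#' `1 - H / ln(20)` where `H` is the Shannon entropy (natural log) of the
#' non-gap residue frequencies in the column; columns with more than 50% gaps
#' are defined unconserved (score 0). All-identical columns score exactly 1,
#' uniform-over-20 columns score 0.
#'
#' @param x An `alignment_profile` or a character vector of equal-length
#'   gapped rows.
#' @return Numeric vector, one score in `[0, 1]` per column.
#' @export
column_conservation <- function(x) {
  m <- .aln_matrix(.as_aligned(x))
  m[m == "y"] <- "Y"
  apply(m, 2L, function(col) {
    gaps <- col == "-"
    if (mean(gaps) > 0.5) return(0)
    p <- table(col[!gaps])
    p <- p / sum(p)
    h <- -sum(p * log(p))
    max(0, 1 - h / log(20))
  })
}

#' Majority-rule consensus of an alignment
#'
#' Per column: gap if gaps hold the strict majority, otherwise the most
#' frequent residue (ties broken alphabetically, deterministic).
#'
#' @inheritParams column_conservation
#' @return Consensus string over residues and `-`.
#' @export
consensus_sequence <- function(x) {
  aligned <- .as_aligned(x)
  if (length(aligned) == 1L) return(unname(aligned[1L]))
  m <- .aln_matrix(aligned)
  n <- nrow(m)
  W <- ncol(m)
  lv <- c(sort(AA20), "y", "-")          # alphabetical tie-break, d-init last
  mm <- match(m, lv)
  cnt <- matrix(tabulate(mm + (rep(seq_len(W), each = n) - 1L) * length(lv),
                         nbins = length(lv) * W),
                length(lv), W)
  gap <- cnt[length(lv), ]
  res <- cnt[-length(lv), , drop = FALSE]
  out <- lv[max.col(t(res), ties.method = "first")]
  out[gap > n / 2] <- "-"
  paste(out, collapse = "")
}

#' Position-by-residue frequency matrix (sequence logo input)
#'
#' @inheritParams column_conservation
#' @return Numeric matrix, columns the 20 residues, rows alignment positions;
#'   frequencies over non-gap characters (rows of all-gap columns are 0).
#' @export
logo_matrix <- function(x) {
  m <- .aln_matrix(.as_aligned(x))
  m[m == "y"] <- "Y"
  out <- t(apply(m, 2L, function(col) {
    res <- col[col != "-"]
    if (!length(res)) return(setNames(numeric(20), AA20))
    tab <- table(factor(res, levels = AA20))
    as.numeric(tab) / length(res)
  }))
  colnames(out) <- AA20
  out
}

#' @rdname logo_matrix
#' @param path TSV output path.
#' @export
write_logo_matrix <- function(x, path) {
  lm <- logo_matrix(x)
  write.table(data.table(position = seq_len(nrow(lm)), lm), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract conserved families from an alignment
#'
#' Single-linkage grouping of alignment rows by gapped identity (identical
#' residues in shared non-gap columns over the shorter ungapped length) at or
#' above `threshold`. Families partition the rows; each gets a majority-rule
#' consensus. Rows with no neighbour stay singleton families — exactly the
#' situation of an isolated representative whose homologues were hidden
#' deeper in the pool.
#'
#' @param profile An `alignment_profile` (or gapped rows).
#' @param threshold Linkage threshold on gapped identity, default 0.6.
#' @return A `family_assignment`: list with `families` (named list of member
#'   ids), `membership` (named integer), `consensus` (per family),
#'   `threshold`.
#' @export
extract_families <- function(profile, threshold = 0.6) {
  aligned <- .as_aligned(profile)
  n <- length(aligned)
  ids <- names(aligned)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (n > 1L) {
    e <- cpp_aln_edges(unname(aligned), threshold)
    for (k in seq_along(e$i)) {
      a <- find(e$i[k]); b <- find(e$j[k])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  fam_ids <- unique(root)                      # ordered by first member row
  membership <- match(root, fam_ids)
  families <- lapply(seq_along(fam_ids), function(f) ids[membership == f])
  names(families) <- sprintf("F%d", seq_along(fam_ids))
  memb_list <- split(seq_len(n), membership)
  consensus <- vapply(seq_along(fam_ids), function(f) {
    rows <- memb_list[[as.character(f)]]
    if (length(rows) == 1L) unname(aligned[rows]) else consensus_sequence(aligned[rows])
  }, character(1))
  structure(list(families = families,
                 membership = setNames(membership, ids),
                 consensus = setNames(consensus, names(families)),
                 threshold = threshold),
            class = "family_assignment")
}

#' @export
print.family_assignment <- function(x, ...) {
  sizes <- lengths(x$families)
  cat(sprintf("family assignment: %d rows -> %d families (linkage %.2f); sizes: %s\n",
              sum(sizes), length(sizes), x$threshold,
              paste(utils::head(sort(sizes, decreasing = TRUE), 10L), collapse = " ")))
  invisible(x)
}

#' Write an alignment as FASTA or Clustal
#'
#' @param profile `alignment_profile` or gapped rows.
#' @param path Output path.
#' @export
write_alignment_fasta <- function(profile, path) {
  aligned <- .as_aligned(profile)
  writeLines(as.vector(rbind(paste0(">", names(aligned)), unname(aligned))), path)
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @export
write_alignment_clustal <- function(profile, path) {
  aligned <- .as_aligned(profile)
  w <- max(nchar(names(aligned))) + 3L
  lines <- c("CLUSTAL W multiple sequence alignment (rapidmine)", "")
  len <- nchar(aligned[[1L]])
  for (s in seq(1L, len, by = 60L)) {
    blk <- substr(aligned, s, min(s + 59L, len))
    lines <- c(lines, sprintf("%-*s%s", w, names(aligned), blk), "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname column_conservation
#' @param path TSV output path for per-column conservation.
#' @export
write_conservation <- function(x, path) {
  cons <- if (inherits(x, "alignment_profile")) x$conservation else column_conservation(x)
  write.table(data.table(column = seq_along(cons), conservation = cons), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname extract_families
#' @param families A `family_assignment`.
#' @param path JSON output path.
#' @export
write_families <- function(families, path) {
  jsonlite::write_json(list(threshold = families$threshold,
                            families = families$families,
                            consensus = as.list(families$consensus)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
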