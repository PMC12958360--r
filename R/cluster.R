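#' Pairwise sequence identity
#'
#' Identity in the sense of greedy high-identity clustering tools: the number
#' of identical aligned positions under a global alignment that maximises
#' matches (match +1, mismatch 0, affine gaps; a gap of length g costs
#' `gap_open + (g - 1) * gap_extend`), divided by the length of the shorter
#' sequence. For equal-length ungapped peptides this reduces to one minus the
#' Hamming fraction.
#'
#' @param a,b Non-empty peptide strings.
#' @param gap_open,gap_extend Positive gap costs for the identity alignment.
#' @return Fraction in `[0, 1]`.
#' @examples
#' sequence_identity("ACDEFGHIK", "ACDEFGHIR")  # 8/9
#' @export
sequence_identity <- function(a, b, gap_open = 2, gap_extend = 1) {
  .assert_peptide(c(a, b))
  cpp_seq_identity(a, b, gap_open, gap_extend)
}

#' Short-word prefilter
#'
#' Conservative screen used before the identity alignment: `FALSE` only when
#' the number of shared k-words (multiset intersection) provably cannot
#' support `sequence_identity(a, b) >= threshold`. Never rejects a pair that
#' would reach the threshold; enabling or disabling it cannot change a
#' clustering, only its runtime.
#'
#' @param a,b Peptide strings.
#' @param k Word length (1-3; 2 is appropriate for short macrocycle peptides).
#' @param threshold Identity threshold the pair is being screened for.
#' @return Logical: may this pair reach `threshold`?
#' @export
word_prefilter <- function(a, b, k = 2L, threshold = 0.9) {
  .assert_peptide(c(a, b))
  need <- cpp_word_bound(min(nchar(a), nchar(b)), max(nchar(a), nchar(b)),
                         as.integer(k), threshold)
  if (need <= 0L) return(TRUE)
  cpp_shared_words(a, b, as.integer(k)) >= need
}

#' Greedy incremental identity clustering
#'
#' Condenses a round's unique peptides into clusters of near-duplicates:
#' sequences are scanned in descending abundance order (ties lexicographic);
#' each joins the first existing cluster whose representative has identity
#' `>= threshold`, else founds a new cluster and becomes its representative.
#' Representatives are therefore always the most abundant member of their
#' cluster, and cluster indices count creation order from 1. An inverted
#' k-word index prefilters candidate representatives; the prefilter is
#' conservative and does not affect the partition.
#'
#' @param peptides Character vector of unique peptides. If `counts` is given
#'   the input is (re)ordered by descending count with lexicographic
#'   tie-break; otherwise the given order is trusted as the abundance order.
#' @param counts Optional integer counts parallel to `peptides`.
#' @param threshold Identity threshold in (0, 1]; 0.90 merges single-mutation
#'   variants of 17-mers.
#' @param word_k Prefilter word length.
#' @param prefilter Use the word prefilter?
#' @return A `peptide_clustering`: list with `members` (`data.table`:
#'   `peptide`, `count`, `rank`, `cluster`, `identity`, `is_representative`),
#'   `representatives` (character, by cluster index), `threshold`, `word_k`.
#' @export
greedy_cluster <- function(peptides, counts = NULL, threshold = 0.9,
                           word_k = 2L, prefilter = TRUE) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (length(peptides) == 0L) {
    return(structure(list(members = data.table(peptide = character(),
                                               count = integer(),
                                               rank = integer(),
                                               cluster = integer(),
                                               identity = numeric(),
                                               is_representative = logical()),
                          representatives = character(),
                          threshold = threshold, word_k = as.integer(word_k)),
                     class = "peptide_clustering"))
  }
  .assert_peptide(peptides)
  if (anyDuplicated(peptides)) stop("peptides must be unique (aggregate counts first)")
  if (!is.null(counts)) {
    stopifnot(length(counts) == length(peptides))
    o <- order(-counts, peptides)
    peptides <- peptides[o]
    counts <- as.integer(counts[o])
  } else {
    counts <- rep(NA_integer_, length(peptides))
  }
  res <- cpp_greedy_cluster(peptides, threshold, as.integer(word_k),
                            isTRUE(prefilter), 2, 1)
  members <- data.table(peptide = peptides,
                        count = counts,
                        rank = seq_along(peptides),
                        cluster = res$cluster,
                        identity = res$identity,
                        is_representative = seq_along(peptides) %in% res$representatives)
  structure(list(members = members,
                 representatives = peptides[res$representatives],
                 threshold = threshold,
                 word_k = as.integer(word_k)),
            class = "peptide_clustering")
}

#' @export
print.peptide_clustering <- function(x, ...) {
  cat(sprintf("greedy identity clustering: %d peptides -> %d clusters (threshold %.2f, k = %d)\n",
              nrow(x$members), length(x$representatives), x$threshold, x$word_k))
  invisible(x)
}

#' Write a clustering as a .clstr-compatible file
#'
#' Text format of the classic greedy clustering tool: `>Cluster i` headers
#' (0-based in the file, as the original tool writes them), member lines with
#' sequence length, id, `*` on the representative and the identity percentage
#' (one decimal) on every other member. Optionally also writes the
#' representatives as FASTA with headers encoding library, cluster index
#' (1-based), abundance rank and count.
#'
#' @param clustering A `peptide_clustering`.
#' @param clstr_path Output path for the cluster file.
#' @param fasta_path Optional path for the representatives FASTA.
#' @param library_tag Tag used in FASTA headers.
#' @export
write_clusters <- function(clustering, clstr_path, fasta_path = NULL,
                           library_tag = "L") {
  m <- clustering$members
  lines <- character(0)
  for (cl in seq_along(clustering$representatives)) {
    sub <- m[m$cluster == cl, ]
    lines <- c(lines, sprintf(">Cluster %d", cl - 1L))
    for (i in seq_len(nrow(sub))) {
      if (sub$is_representative[i]) {
        lines <- c(lines, sprintf("%d\t%daa, >%s... *", i - 1L,
                                  nchar(sub$peptide[i]), sub$peptide[i]))
      } else {
        lines <- c(lines, sprintf("%d\t%daa, >%s... at %.1f%%", i - 1L,
                                  nchar(sub$peptide[i]), sub$peptide[i],
                                  100 * sub$identity[i]))
      }
    }
  }
  writeLines(lines, clstr_path)
  if (!is.null(fasta_path)) {
    reps <- m[m$is_representative == TRUE, ]
    hdr <- sprintf(">%s%d-%d count=%s", library_tag, reps$cluster, reps$rank,
                   ifelse(is.na(reps$count), "NA", reps$count))
    writeLines(as.vector(rbind(hdr, reps$peptide)), fasta_path)
  }
  invisible(clstr_path)
}

#' Parse a .clstr-compatible cluster file
#'
#' @param path Path written by [write_clusters()] (or the original tool, with
#'   peptide strings as sequence ids).
#' @return `data.table` with `cluster` (1-based), `peptide`, `identity`,
#'   `is_representative`.
#' @export
read_clusters <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>Cluster", lines)
  cl <- cumsum(hdr)
  mem <- lines[!hdr]
  clm <- cl[!hdr]
  pep <- sub("^.*>\\s*", "", mem)
  pep <- sub("\\.{3}.*$", "", pep)
  isrep <- grepl("\\*\\s*$", mem)
  idp <- rep(NA_real_, length(mem))
  has <- grepl("at\\s+[0-9.]+%", mem)
  idp[has] <- as.numeric(sub("^.*at\\s+([0-9.]+)%.*$", "\\1", mem[has])) / 100
  idp[isrep] <- 1.0
  data.table(cluster = clm, peptide = pep, identity = idp,
             is_representative = isrep)
}
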