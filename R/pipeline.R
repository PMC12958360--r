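#' Full-dataset mining of one selection round
#'
#' The complete downstream workflow on an already-counted round, with no
#' abundance cut-off: greedy identity clustering of every unique peptide in
#' rank order, UPGMA-guided progressive alignment of the cluster
#' representatives, single-linkage family extraction on the alignment, and a
#' per-family hit report. The analysis round defaults to the
#' penultimate-diversity round (round 3 of a 5-round selection) when present.
#'
#' @param counts A `peptide_counts` table for one library.
#' @param round Analysis round; default 3 when counted, else the last round.
#' @param cluster_id Identity threshold for clustering (default 0.90).
#' @param family_id Gapped-identity linkage threshold for families (0.6).
#' @param word_k Prefilter word length.
#' @param from_round Baseline round for enrichment ratios in the report.
#' @param substitution,gap_open,gap_extend MSA scoring.
#' @param max_representatives Optional cap on representatives carried into
#'   the MSA (rank order); `Inf` analyses all of them.
#' @return A `selection_analysis`: list with `round`, `clustering`,
#'   `profile`, `families`, `report`.
#' @export
mine_selection <- function(counts, round = NULL, cluster_id = 0.9,
                           family_id = 0.6, word_k = 2L, from_round = 1L,
                           substitution = blosum62_matrix(),
                           gap_open = 10, gap_extend = 0.5,
                           max_representatives = Inf) {
  present <- sort(unique(counts$round))
  if (is.null(round)) round <- if (3L %in% present) 3L else max(present)
  x <- .round_slice(counts, round)
  x <- x[order(x$rank)]
  clustering <- greedy_cluster(x$peptide, x$count, threshold = cluster_id,
                               word_k = word_k)
  reps <- clustering$representatives
  if (is.finite(max_representatives) && length(reps) > max_representatives)
    reps <- reps[seq_len(max_representatives)]
  profile <- progressive_align(setNames(reps, reps),
                               substitution = substitution,
                               gap_open = gap_open, gap_extend = gap_extend)
  families <- extract_families(profile, threshold = family_id)
  if (!is.null(from_round) && !from_round %in% present) from_round <- NULL
  report <- family_report(families, counts, clustering, profile,
                          round = round, from_round = from_round)
  structure(list(round = round, clustering = clustering, profile = profile,
                 families = families, report = report),
            class = "selection_analysis")
}

#' @export
print.selection_analysis <- function(x, ...) {
  cat(sprintf("selection analysis, round %d\n", x$round))
  print(x$clustering)
  cat(sprintf("  %d families from %d aligned representatives\n",
              length(x$families$families), length(x$profile$aligned)))
  cat("top families:\n")
  print(head(x$report[, c("hit_name", "representative", "members",
                          "summed_freq", "consensus", "truncate_to_cycle")], 5L))
  invisible(x)
}
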