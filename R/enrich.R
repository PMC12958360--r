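#' Count unique peptides in one selection round
#'
#' One record per distinct peptide string; counts are multiplicities in the
#' input stream, frequencies are `count / total`, and ranks are assigned by
#' descending count with a lexicographic tie-break on the peptide string
#' (making the ordering total and the whole downstream pipeline reproducible
#' under input permutation).
#'
#' @param peptides Character vector of accepted peptides (one entry per read).
#' @param round Round index (positive integer).
#' @param library_tag `"L"` or `"D"`.
#' @return A `peptide_counts` `data.table` with columns `peptide`, `library`,
#'   `round`, `count`, `freq`, `rank`.
#' @examples
#' count_unique(c("P1", "P1", "P2"), round = 1, library_tag = "L")
#' @export
count_unique <- function(peptides, round = 1L, library_tag = "L") {
  round <- as.integer(round)
  stopifnot(length(round) == 1L, !is.na(round), round >= 1L)
  if (length(peptides) == 0L) {
    out <- data.table(peptide = character(), library = character(),
                      round = integer(), count = integer(),
                      freq = numeric(), rank = integer())
    setattr(out, "class", c("peptide_counts", class(out)))
    return(out)
  }
  dt <- data.table(peptide = as.character(peptides))
  dt <- dt[, .(count = .N), by = peptide]
  dt[, `:=`(library = library_tag, round = round, freq = count / sum(count))]
  setorder(dt, -count, peptide)
  dt[, rank := seq_len(.N)]
  setcolorder(dt, c("peptide", "library", "round", "count", "freq", "rank"))
  setattr(dt, "class", c("peptide_counts", class(dt)))
  dt[]
}

#' Tally several rounds into one count table
#'
#' @param rounds Named list `round index -> character vector of accepted
#'   peptides` (names coerced to integers) or a list in round order.
#' @param library_tag Library of all rounds.
#' @return A `peptide_counts` table covering all rounds.
#' @export
tally_rounds <- function(rounds, library_tag = "L") {
  idx <- if (!is.null(names(rounds))) as.integer(names(rounds)) else seq_along(rounds)
  out <- rbindlist(lapply(seq_along(rounds), function(i)
    count_unique(rounds[[i]], idx[i], library_tag)))
  setattr(out, "class", c("peptide_counts", "data.table", "data.frame"))
  out[]
}

.round_slice <- function(counts, round) {
  # pre-evaluate the filter: the argument name collides with the column name,
  # and data.table would otherwise resolve `round` to the column
  keep <- which(counts[["round"]] == round & counts[["count"]] > 0L)
  if (length(keep) == 0L) stop("no records for round ", round, call. = FALSE)
  counts[keep]
}

#' Re-rank records for a round
#'
#' Ranks are recomputed by descending count, ties broken lexicographically by
#' peptide string, starting at 1. Normally already done by [count_unique()];
#' exposed for tables assembled by other means.
#'
#' @param counts A `peptide_counts` table.
#' @param round Round to re-rank (default: all rounds present).
#' @return The table, re-ranked by reference and returned invisibly-visible.
#' @export
rank_sequences <- function(counts, round = NULL) {
  rs <- if (is.null(round)) unique(counts$round) else round
  for (r in rs) {
    i <- which(counts$round == r)
    o <- order(-counts$count[i], counts$peptide[i])
    set(counts, i[o], "rank", seq_along(i))
  }
  counts[]
}

#' Summed frequency of the top n peptides
#'
#' The convergence statistic of a selection: the fraction of a round's reads
#' held by its `n` most abundant unique peptides. Non-decreasing in `n`.
#'
#' @param counts A `peptide_counts` table.
#' @param round Round index.
#' @param n Number of top peptides (vectorised).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
top_n_fraction <- function(counts, round, n) {
  x <- .round_slice(counts, round)
  fr <- x$freq[order(x$rank)]
  cs <- cumsum(fr)
  vapply(n, function(k) cs[min(k, length(cs))], numeric(1))
}

#' Per-round convergence summary
#'
#' @param counts A `peptide_counts` table.
#' @param round Round index.
#' @param n Top-n values to report.
#' @return `round_summary` list: `round`, `total_reads`, `unique_peptides`,
#'   `top_n_fraction` (named numeric).
#' @export
round_summary <- function(counts, round, n = c(1L, 5L, 10L, 20L, 50L, 100L, 200L)) {
  x <- .round_slice(counts, round)
  structure(list(round = round,
                 total_reads = sum(x$count),
                 unique_peptides = nrow(x),
                 top_n_fraction = setNames(top_n_fraction(counts, round, n),
                                           as.character(n))),
            class = "round_summary")
}

#' @export
print.round_summary <- function(x, ...) {
  cat(sprintf("round %d: %d reads, %d unique peptides\n",
              x$round, x$total_reads, x$unique_peptides))
  cat("  top-n read fraction:",
      paste(sprintf("n=%s %.3f", names(x$top_n_fraction), x$top_n_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' @rdname round_summary
#' @param summary A `round_summary`.
#' @param path JSON output path.
#' @export
write_round_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Per-peptide enrichment between two rounds
#'
#' Ratio of a peptide's frequency at `to_round` over `from_round`. Peptides
#' unseen in the earlier round receive the pseudo-frequency
#' `0.5 / total_reads(from_round)` so ratios stay finite.
#'
#' @param counts A `peptide_counts` table.
#' @param from_round,to_round Round indices (both must be present).
#' @return Named numeric vector of ratios for every peptide with nonzero
#'   count at `to_round`.
#' @export
enrichment_trajectory <- function(counts, from_round, to_round) {
  to <- .round_slice(counts, to_round)
  from <- .round_slice(counts, from_round)
  pseudo <- 0.5 / sum(from$count)
  f0 <- setNames(from$freq, from$peptide)[to$peptide]
  f0[is.na(f0)] <- pseudo
  setNames(to$freq / f0, to$peptide)
}

#' Top-k peptides of a round
#'
#' @param counts A `peptide_counts` table.
#' @param round Round index.
#' @param k Number of peptides.
#' @return Character vector of peptides, rank order; all records (with a
#'   warning) if fewer than `k` are present.
#' @export
select_top_k <- function(counts, round, k) {
  x <- .round_slice(counts, round)
  x <- x[order(x$rank)]
  if (nrow(x) < k)
    warning(sprintf("only %d unique peptides in round %d (k = %d); returning all",
                    nrow(x), round, k))
  head(x$peptide, k)
}

#' Write the per-round count table as TSV
#'
#' Wide layout: `peptide`, `library`, `count_r<i>` per round, plus frequency
#' and rank at the stated analysis round.
#'
#' @param counts A `peptide_counts` table.
#' @param path TSV output path.
#' @param analysis_round Round whose frequency/rank columns are included.
#' @export
write_count_table <- function(counts, path, analysis_round = max(counts$round)) {
  wide <- dcast(as.data.table(counts), peptide + library ~ round,
                value.var = "count", fill = 0L)
  setnames(wide, as.character(unique(sort(counts$round))),
           sprintf("count_r%d", unique(sort(counts$round))))
  ar <- counts[counts$round == analysis_round,
               .(peptide, freq, rank)]
  setnames(ar, c("freq", "rank"),
           sprintf(c("freq_r%d", "rank_r%d"), analysis_round))
  wide <- merge(wide, ar, by = "peptide", all.x = TRUE)
  setorderv(wide, sprintf("rank_r%d", analysis_round), na.last = TRUE)
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export top-k peptides as FASTA
#'
#' Plain 2-line records (`writeLines`; the lowercase d-initiator must survive,
#' which rules out AAStringSet).
#'
#' @param counts A `peptide_counts` table.
#' @param round Round index.
#' @param k Number of peptides.
#' @param path FASTA output path.
#' @export
write_top_fasta <- function(counts, round, k, path) {
  x <- .round_slice(counts, round)
  x <- x[order(x$rank)][seq_len(min(k, nrow(x)))]
  lines <- as.vector(rbind(
    sprintf(">%s_r%d_rank%d count=%d", x$library, round, x$rank, x$count),
    x$peptide))
  writeLines(lines, path)
  invisible(path)
}
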