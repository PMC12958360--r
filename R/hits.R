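#' Hit names: "[library][cluster]-[rank]"
#'
#' A hit is named by its library tag, the (1-based) cluster it represents and
#' its abundance rank among all unique sequences of the analysis round — e.g.
#' `L21-34` is the l-library, 21st cluster, 34th most abundant sequence.
#'
#' @param library_tag `"L"` or `"D"`.
#' @param cluster_index,abundance_rank Positive integers.
#' @return The rendered name (character scalar).
#' @examples
#' name_hit("L", 21, 34)
#' parse_hit_name("D28-36")
#' @export
name_hit <- function(library_tag, cluster_index, abundance_rank) {
  if (!library_tag %in% c("L", "D")) stop("library_tag must be 'L' or 'D'")
  cluster_index <- as.integer(cluster_index)
  abundance_rank <- as.integer(abundance_rank)
  if (is.na(cluster_index) || cluster_index < 1L ||
      is.na(abundance_rank) || abundance_rank < 1L)
    stop("cluster_index and abundance_rank must be positive integers")
  sprintf("%s%d-%d", library_tag, cluster_index, abundance_rank)
}

#' @rdname name_hit
#' @param name A rendered hit name.
#' @export
parse_hit_name <- function(name) {
  m <- regmatches(name, regexec("^([LD])([0-9]+)-([0-9]+)$", name))[[1L]]
  if (length(m) != 4L) stop("not a valid hit name: ", name)
  out <- list(library_tag = m[2L],
              cluster_index = as.integer(m[3L]),
              abundance_rank = as.integer(m[4L]))
  if (out$cluster_index < 1L || out$abundance_rank < 1L)
    stop("not a valid hit name: ", name)
  out
}

#' Split a lariat peptide into macrocycle and tail
#'
#' The thioether ring closes between the chloroacetyl initiator and the first
#' cysteine thiol; residues after that cysteine form the linear tail. Later
#' cysteines are tail residues.
#'
#' @param peptide Peptide string containing at least one `C`.
#' @return List with 1-based inclusive spans `cycle_span` and `tail_span`
#'   (`NULL` when the peptide is a pure macrocycle).
#' @examples
#' split_macrocycle_tail("yLWFQGRPCAHNMKTSE")
#' @export
split_macrocycle_tail <- function(peptide) {
  .assert_peptide(peptide)
  pos <- regexpr("C", peptide, fixed = TRUE)
  if (pos < 0L) {
    cond <- simpleError(paste0("no_cysteine: peptide '", peptide,
                               "' cannot cyclise"))
    class(cond) <- c("no_cysteine", class(cond))
    stop(cond)
  }
  len <- nchar(peptide)
  list(cycle_span = c(1L, as.integer(pos)),
       tail_span = if (pos < len) c(as.integer(pos) + 1L, len) else NULL)
}

#' Propose a macrocycle-only truncation from conservation
#'
#' Compares mean per-column conservation over the macrocycle span against the
#' tail span of one aligned peptide (columns where this row is gapped are
#' skipped). A highly conserved ring next to a poorly conserved tail suggests
#' the tail is dispensable and the macrocycle can be synthesised alone.
#'
#' @param profile An `alignment_profile` containing the peptide.
#' @param id Row id in the profile.
#' @param gap_threshold Minimum conservation difference (cycle - tail) to
#'   suggest truncation; with the default 0.3 only a clear contrast triggers.
#'   Equality at `gap_threshold = 0` suggests truncation (`>=` convention).
#' @return `truncation_suggestion` list: spans, mean conservations (empty
#'   tail scores 0 and never suggests), and `suggest_cycle_only`.
#' @export
suggest_truncation <- function(profile, id, gap_threshold = 0.3) {
  stopifnot(inherits(profile, "alignment_profile"))
  if (!id %in% names(profile$aligned)) stop("id not in profile: ", id)
  row <- profile$aligned[[id]]
  chars <- strsplit(row, "", fixed = TRUE)[[1L]]
  cols <- which(chars != "-")              # column of each residue
  peptide <- paste(chars[chars != "-"], collapse = "")
  spans <- split_macrocycle_tail(peptide)
  cyc_cols <- cols[spans$cycle_span[1L]:spans$cycle_span[2L]]
  cycle_cons <- mean(profile$conservation[cyc_cols])
  if (is.null(spans$tail_span)) {
    tail_cons <- 0
    suggest <- FALSE
  } else {
    tail_cols <- cols[spans$tail_span[1L]:spans$tail_span[2L]]
    tail_cons <- mean(profile$conservation[tail_cols])
    suggest <- (cycle_cons - tail_cons) >= gap_threshold
  }
  structure(list(id = id, peptide = peptide,
                 cycle_span = spans$cycle_span, tail_span = spans$tail_span,
                 cycle_conservation = cycle_cons,
                 tail_conservation = tail_cons,
                 suggest_cycle_only = suggest,
                 gap_threshold = gap_threshold),
            class = "truncation_suggestion")
}

#' @export
print.truncation_suggestion <- function(x, ...) {
  cat(sprintf("%s: cycle %d-%d cons %.3f | tail %s cons %.3f -> %s\n",
              x$id, x$cycle_span[1L], x$cycle_span[2L], x$cycle_conservation,
              if (is.null(x$tail_span)) "(none)"
              else sprintf("%d-%d", x$tail_span[1L], x$tail_span[2L]),
              x$tail_conservation,
              if (x$suggest_cycle_only) "synthesise macrocycle only"
              else "keep full length"))
  invisible(x)
}

#' Per-family hit report
#'
#' One row per extracted family, combining abundance, enrichment and
#' conservation: the family representative (most abundant member at the
#' analysis round), its hit name, the number of aligned members, the summed
#' round frequency over every peptide condensed into the family's clusters,
#' the family enrichment ratio versus `from_round` (pseudo-frequency for
#' families unseen there), the family consensus, and the truncation flag for
#' the representative. Sorted by summed frequency, descending.
#'
#' @param families A `family_assignment` over cluster representatives.
#' @param counts The round's `peptide_counts`.
#' @param clustering The `peptide_clustering` whose representatives were
#'   aligned.
#' @param profile The `alignment_profile` the families came from.
#' @param round Analysis round.
#' @param from_round Baseline round for the enrichment ratio (default 1; set
#'   `NULL` to skip when only one round was counted).
#' @param gap_threshold Passed to [suggest_truncation()].
#' @return `data.table`, one row per family.
#' @export
family_report <- function(families, counts, clustering, profile,
                          round, from_round = 1L, gap_threshold = 0.3) {
  stopifnot(inherits(families, "family_assignment"),
            inherits(clustering, "peptide_clustering"),
            inherits(profile, "alignment_profile"))
  x <- .round_slice(counts, round)
  lib <- unique(x$library)
  stopifnot(length(lib) == 1L)
  cnt <- setNames(x$count, x$peptide)
  frq <- setNames(x$freq, x$peptide)
  rnk <- setNames(x$rank, x$peptide)
  mem <- clustering$members
  have_from <- !is.null(from_round) && from_round %in% counts$round
  if (have_from) {
    fr <- .round_slice(counts, from_round)
    frq0 <- setNames(fr$freq, fr$peptide)
    pseudo <- 0.5 / sum(fr$count)
  }

  # peptides of each cluster, for rolling members up to families
  cl_of <- setNames(mem$cluster, mem$peptide)
  pep_by_cl <- split(mem$peptide, mem$cluster)
  nf <- length(families$families)
  representative <- character(nf); hit_name <- character(nf)
  members <- integer(nf); peptides <- integer(nf)
  summed_freq <- numeric(nf); enrichment <- rep(NA_real_, nf)
  cyc <- numeric(nf); tl <- numeric(nf); trunc <- logical(nf)
  for (f in seq_len(nf)) {
    reps <- families$families[[f]]               # aligned row ids = representatives
    cl_idx <- unname(cl_of[reps])
    all_pep <- unlist(pep_by_cl[as.character(cl_idx)], use.names = FALSE)
    rep_pep <- reps[which.max(cnt[reps])]
    summed_freq[f] <- sum(frq[all_pep], na.rm = TRUE)
    if (have_from) {
      f0 <- frq0[all_pep]
      f0[is.na(f0)] <- pseudo
      enrichment[f] <- summed_freq[f] / sum(f0)
    }
    tr <- suggest_truncation(profile, rep_pep, gap_threshold)
    representative[f] <- rep_pep
    hit_name[f] <- name_hit(lib, cl_idx[match(rep_pep, reps)], unname(rnk[rep_pep]))
    members[f] <- length(reps)
    peptides[f] <- length(all_pep)
    cyc[f] <- tr$cycle_conservation
    tl[f] <- tr$tail_conservation
    trunc[f] <- tr$suggest_cycle_only
  }
  out <- data.table(family = names(families$families),
                    representative = representative,
                    hit_name = hit_name,
                    members = members,
                    peptides = peptides,
                    summed_freq = summed_freq,
                    enrichment = enrichment,
                    consensus = unname(families$consensus),
                    cycle_conservation = cyc,
                    tail_conservation = tl,
                    truncate_to_cycle = trunc)
  setorder(out, -summed_freq)
  out[]
}

#' @rdname family_report
#' @param report A report table.
#' @param path Output path (`.tsv` or `.json` by extension).
#' @export
write_family_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
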