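REJECT_LEVELS <- c("none", "anchor_not_found", "ambiguous_base", "internal_stop",
                   "length_mismatch", "nnk_violation_discarded")

# locate the upstream anchor in each read; -1 where absent
find_anchor <- function(reads, arch) {
  if (arch$max_flank_mismatches == 0L) {
    as.integer(regexpr(arch$upstream_anchor, reads, fixed = TRUE))
  } else {
    hits <- Biostrings::vmatchPattern(arch$upstream_anchor,
                                      Biostrings::DNAStringSet(reads),
                                      max.mismatch = arch$max_flank_mismatches)
    vapply(Biostrings::startIndex(hits),
           function(s) if (length(s)) s[[1L]] else -1L, integer(1))
  }
}

revcomp_chr <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Decode amplicon reads into library peptides
#'
#' Locates the constant 5' flank (trying the reverse complement when the
#' forward strand fails), translates initiator + random region under the
#' reprogrammed code, and verifies the cysteine anchor codon immediately after
#' the random region. Every read yields either an accepted peptide of length
#' `random_codon_count + 2` (initiator symbol, random region, `C`) or exactly
#' one rejection reason, assigned in the order `anchor_not_found`,
#' `ambiguous_base`, `internal_stop`, `length_mismatch`. A cysteine codon
#' found shifted by up to ±2 codons from its expected position is classified
#' as `length_mismatch` (an indel in the random region); one absent from that
#' window as `anchor_not_found`.
#'
#' NNK violations at the wobble position are counted per read but do not
#' reject unless `strict_nnk = TRUE` (sequencing error routinely breaks the K
#' constraint); internal stop codons reject unless `keep_internal_stops =
#' TRUE`, since a prematurely terminated peptide cannot cyclise onto the
#' downstream cysteine.
#'
#' @param reads Character vector of DNA reads (cDNA sense strand).
#' @param arch A [library_architecture()].
#' @param strict_nnk Reject reads whose random region violates NNK.
#' @param keep_internal_stops Retain reads with in-frame stops in the random
#'   region (diagnostics only; they remain flagged).
#' @return A `data.table` with columns `read_id`, `peptide`,
#'   `dna_random_region`, `library_tag`, `accepted`, `reject_reason`
#'   (factor over the reason enum) and `nnk_violations`.
#' @export
decode_reads <- function(reads, arch = library_architecture(),
                         strict_nnk = FALSE, keep_internal_stops = FALSE) {
  stopifnot(inherits(arch, "library_architecture"))
  ids <- names(reads)
  reads <- as.character(reads)
  n <- length(reads)
  if (is.null(ids) || !all(nzchar(ids))) ids <- sprintf("read%d", seq_len(n))
  if (n == 0L)
    return(data.table(read_id = character(), peptide = character(),
                      dna_random_region = character(), library_tag = character(),
                      accepted = logical(),
                      reject_reason = factor(character(), levels = REJECT_LEVELS),
                      nnk_violations = integer()))

  pos <- find_anchor(reads, arch)
  miss <- pos < 0L
  if (any(miss)) {
    rc <- revcomp_chr(reads[miss])
    pos2 <- find_anchor(rc, arch)
    flip <- pos2 > 0L
    reads[miss][flip] <- rc[flip]
    pos[miss] <- pos2
  }

  reason <- rep(NA_character_, n)
  reason[pos < 0L] <- "anchor_not_found"

  ncod <- arch$random_codon_count
  width <- 3L * (ncod + 2L)              # initiator + random + Cys anchor
  start <- pos + nchar(arch$upstream_anchor)
  ok <- is.na(reason)
  short <- ok & (nchar(reads) - start + 1L < width)
  reason[short] <- "anchor_not_found"    # read ends inside the footprint
  ok <- is.na(reason)

  window <- rep(NA_character_, n)
  window[ok] <- substr(reads[ok], start[ok], start[ok] + width - 1L)

  # cysteine anchor at the expected position, else scan +/- 2 codons
  cys_at <- function(w, off) substr(w, width - 2L + 3L * off, width + 3L * off)
  expected <- ok & !is.na(window) & cys_at(window, 0L) == arch$anchor_codon
  # note: positive offsets run past `window`; scan on the full read
  shifted <- rep(FALSE, n)
  chk <- ok & !expected
  if (any(chk)) {
    for (off in c(-2L, -1L, 1L, 2L)) {
      at <- start[chk] + width - 3L + 3L * off
      cod <- substr(reads[chk], at, at + 2L)
      shifted[chk] <- shifted[chk] | (cod == arch$anchor_codon & at > 0L)
    }
  }
  reason[chk & !shifted] <- "anchor_not_found"
  ok <- is.na(reason)

  # the initiator codon is part of the constant region: a mismatch there is a
  # flank failure, reported before base-level problems inside the window
  init_cod <- substr(window, 1L, 3L)
  mismatch_init <- ok & init_cod != arch$initiator_codon
  reason[mismatch_init] <- "anchor_not_found"
  ok <- is.na(reason)

  amb <- ok & grepl("[^ACGT]", window)
  reason[amb] <- "ambiguous_base"
  ok <- is.na(reason)

  starts <- 3L * seq_len(ncod) + 1L
  codons <- matrix(NA_character_, n, ncod)
  if (any(ok)) {
    w <- window[ok]
    for (j in seq_len(ncod))
      codons[ok, j] <- substr(w, starts[j], starts[j] + 2L)
  }
  is_stop <- matrix(FALSE, n, ncod)
  is_stop[ok, ] <- matrix(codons[ok, ] %in% arch$stop_codons, sum(ok), ncod)
  has_stop <- rowSums(is_stop) > 0L
  if (!keep_internal_stops) {
    reason[ok & has_stop] <- "internal_stop"
    ok <- is.na(reason)
  }

  reason[ok & shifted] <- "length_mismatch"
  ok <- is.na(reason)

  nnk_viol <- integer(n)
  if (any(ok)) {
    third <- substr(codons[ok, , drop = FALSE], 3L, 3L)
    viol <- matrix(!(third %in% c("G", "T")), sum(ok), ncod)
    nnk_viol[ok] <- as.integer(rowSums(viol))
  }
  if (strict_nnk) {
    reason[ok & nnk_viol > 0L] <- "nnk_violation_discarded"
    ok <- is.na(reason)
  }

  code <- genetic_code(arch$initiator_symbol, arch$initiator_codon)
  peptide <- rep(NA_character_, n)
  region <- rep(NA_character_, n)
  if (any(ok)) {
    aa <- translate_codons(as.vector(codons[ok, , drop = FALSE]), code)
    aa <- matrix(aa, sum(ok), ncod)
    mid <- do.call(paste0, as.data.frame(aa, stringsAsFactors = FALSE))
    peptide[ok] <- paste0(arch$initiator_symbol, mid,
                          translate_codon(arch$anchor_codon, code))
    region[ok] <- substr(window[ok], 4L, 3L + 3L * ncod)
  }
  reason[is.na(reason)] <- "none"

  data.table(read_id = ids,
             peptide = peptide,
             dna_random_region = region,
             library_tag = arch$library_tag,
             accepted = reason == "none",
             reject_reason = factor(reason, levels = REJECT_LEVELS),
             nnk_violations = nnk_viol)
}

#' Decode a single read
#'
#' Scalar convenience wrapper over [decode_reads()].
#'
#' @inheritParams decode_reads
#' @param read A single DNA string.
#' @return A one-row list with fields `peptide`, `dna_random_region`,
#'   `library_tag`, `accepted`, `reject_reason`, `nnk_violations`.
#' @export
decode_read <- function(read, arch = library_architecture(), ...) {
  stopifnot(length(read) == 1L)
  as.list(decode_reads(read, arch, ...)[1L, -"read_id"])
}

#' Decode a FASTQ file
#'
#' Reads a (possibly gzip-compressed) FASTQ via Biostrings and decodes every
#' read. Base qualities are ignored (quality-aware filtering is out of scope).
#'
#' @param path FASTQ path, optionally `.gz`.
#' @inheritParams decode_reads
#' @return As [decode_reads()].
#' @export
decode_fastq <- function(path, arch = library_architecture(), ...) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  reads <- as.character(seqs)
  names(reads) <- sub("\\s.*$", "", names(seqs))
  decode_reads(reads, arch, ...)
}

#' Tally rejection reasons
#'
#' @param decoded Output of [decode_reads()].
#' @return `data.table` with `reject_reason` and `reads` counts (all enum
#'   levels present, zero-filled).
#' @export
rejection_tally <- function(decoded) {
  tab <- table(decoded$reject_reason)
  data.table(reject_reason = names(tab), reads = as.integer(tab))
}

#' @rdname rejection_tally
#' @param path Output TSV path.
#' @export
write_rejection_tally <- function(decoded, path) {
  write.table(rejection_tally(decoded), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
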