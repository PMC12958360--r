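#' mRNA-display library architecture
#'
#' Describes the fixed layout of an amplicon read from a RaPID-style selection:
#' a constant 5' region (`upstream_anchor`) ending immediately before the
#' initiator codon, the initiator codon itself (reassigned to a chloroacetyl
#' amino acid that later cyclises onto the downstream cysteine), a random
#' region of `random_codon_count` NNK codons, the cysteine anchor codon, a
#' flexible Gly/Ser spacer and a stop codon. The initiator is rendered in the
#' decoded peptide as `initiator_symbol`: `"Y"` for the l-library and the
#' single lowercase `"y"` for the d-library (stereochemistry, not identity).
#'
#' @param upstream_anchor Constant 5' DNA ending at the initiator codon.
#' @param initiator_codon Length-3 DNA codon, default `"ATG"`.
#' @param random_codon_count Number of NNK codons in the random region.
#' @param anchor_codon Downstream cysteine codon, default `"TGC"`.
#' @param spacer_nucleotides Constant spacer DNA after the anchor codon
#'   (default encodes G-S-G-S-G-S).
#' @param stop_codons Character vector of stop codons; the first is used when
#'   the simulator writes reads.
#' @param initiator_symbol Single peptide character for the initiator.
#' @param library_tag `"L"` or `"D"`.
#' @param max_flank_mismatches Mismatches tolerated when locating
#'   `upstream_anchor` (default 0, exact).
#' @return An object of class `library_architecture`.
#' @examples
#' arch <- library_architecture()
#' arch$random_codon_count
#' @export
library_architecture <- function(upstream_anchor = "TTAACTTTAAGAAGGAGATATACAT",
                                 initiator_codon = "ATG",
                                 random_codon_count = 15L,
                                 anchor_codon = "TGC",
                                 spacer_nucleotides = "GGTAGTGGTAGTGGTAGT",
                                 stop_codons = c("TAA", "TAG", "TGA"),
                                 initiator_symbol = "Y",
                                 library_tag = "L",
                                 max_flank_mismatches = 0L) {
  .assert_dna <- function(x, arg) {
    if (!is.character(x) || length(x) != 1L || grepl("[^ACGT]", x) || !nzchar(x))
      stop(arg, " must be a non-empty string over {A,C,G,T}", call. = FALSE)
  }
  .assert_dna(upstream_anchor, "upstream_anchor")
  .assert_dna(initiator_codon, "initiator_codon")
  .assert_dna(anchor_codon, "anchor_codon")
  .assert_dna(spacer_nucleotides, "spacer_nucleotides")
  if (nchar(initiator_codon) != 3L || nchar(anchor_codon) != 3L)
    stop("initiator_codon and anchor_codon must have length 3", call. = FALSE)
  for (s in stop_codons) .assert_dna(s, "stop_codons")
  if (any(nchar(stop_codons) != 3L)) stop("stop codons must have length 3", call. = FALSE)
  random_codon_count <- as.integer(random_codon_count)
  if (is.na(random_codon_count) || random_codon_count < 1L)
    stop("random_codon_count must be a positive integer", call. = FALSE)
  if (!is.character(initiator_symbol) || nchar(initiator_symbol) != 1L)
    stop("initiator_symbol must be exactly one character", call. = FALSE)
  if (!library_tag %in% c("L", "D")) stop("library_tag must be 'L' or 'D'", call. = FALSE)
  max_flank_mismatches <- as.integer(max_flank_mismatches)
  if (is.na(max_flank_mismatches) || max_flank_mismatches < 0L)
    stop("max_flank_mismatches must be a non-negative integer", call. = FALSE)
  structure(
    list(upstream_anchor = upstream_anchor,
         initiator_codon = initiator_codon,
         random_codon_count = random_codon_count,
         anchor_codon = anchor_codon,
         spacer_nucleotides = spacer_nucleotides,
         stop_codons = unique(stop_codons),
         initiator_symbol = initiator_symbol,
         library_tag = library_tag,
         max_flank_mismatches = max_flank_mismatches),
    class = "library_architecture")
}

#' @export
print.library_architecture <- function(x, ...) {
  cat(sprintf(
    "mRNA-display library architecture [%s library]\n  5' anchor: %s\n  %s + %d x NNK + %s (Cys) + spacer + stop\n  initiator symbol: '%s'\n",
    x$library_tag, x$upstream_anchor, x$initiator_codon, x$random_codon_count,
    x$anchor_codon, x$initiator_symbol))
  invisible(x)
}

#' Read or write a library architecture as JSON
#'
#' @param arch A `library_architecture`.
#' @param path File path.
#' @return `read_architecture` returns a `library_architecture`.
#' @export
write_architecture <- function(arch, path) {
  stopifnot(inherits(arch, "library_architecture"))
  jsonlite::write_json(unclass(arch), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(library_architecture, x)
}

#' Genetic code with a reprogrammed initiator
#'
#' The standard genetic code (64 codons, stops as `"*"`) with the initiator
#' codon reassigned: in RaPID translation the start codon is charged with a
#' chloroacetyl amino acid by flexizyme, so at the initiator position it
#' decodes to `initiator_symbol` rather than Met.
#'
#' @param initiator_symbol Peptide character emitted at the initiator position.
#' @param initiator_codon The reassigned codon (default `"ATG"`).
#' @return Object of class `genetic_code`: list with `codon_to_residue`
#'   (named character, 64 codons) and `initiator_override`.
#' @export
genetic_code <- function(initiator_symbol = "Y", initiator_codon = "ATG") {
  if (nchar(initiator_symbol) != 1L)
    stop("initiator_symbol must be exactly one character", call. = FALSE)
  tab <- Biostrings::GENETIC_CODE
  structure(list(codon_to_residue = setNames(as.character(tab), names(tab)),
                 initiator_override = setNames(initiator_symbol, initiator_codon)),
            class = "genetic_code")
}

#' Translate a single codon
#'
#' @param codon Length-3 DNA string over `{A,C,G,T}`.
#' @param code A [genetic_code()].
#' @param is_initiator If `TRUE` and the codon is the reassigned initiator,
#'   the initiator symbol is returned.
#' @return One peptide character, or `"*"` for a stop codon at a
#'   non-initiator position.
#' @examples
#' translate_codon("TGC", genetic_code())                 # "C"
#' translate_codon("ATG", genetic_code("y"), TRUE)        # "y"
#' @export
translate_codon <- function(codon, code = genetic_code(), is_initiator = FALSE) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L)
    stop("codon must be a single string of length 3", call. = FALSE)
  if (grepl("[^ACGT]", codon))
    stop("ambiguous_base: codon '", codon, "' contains a base outside {A,C,G,T}",
         call. = FALSE)
  if (is_initiator && codon %in% names(code$initiator_override))
    return(unname(code$initiator_override[codon]))
  unname(code$codon_to_residue[codon])
}

# vectorised internal translation; returns NA for codons with ambiguous bases
translate_codons <- function(codons, code) {
  out <- code$codon_to_residue[codons]
  unname(out)
}

#' Is a codon NNK?
#'
#' NNK degenerate codons have any base at positions 1-2 and G or T (K) at the
#' wobble position; the scheme covers all 20 residues with a single stop (TAG).
#'
#' @param codon Character vector of length-3 codons.
#' @return Logical vector: third base in `{G, T}`.
#' @examples
#' check_nnk(c("TTG", "TTA"))
#' @export
check_nnk <- function(codon) {
  if (any(nchar(codon) != 3L)) stop("codons must have length 3", call. = FALSE)
  substr(codon, 3L, 3L) %in% c("G", "T")
}

#' All NNK codons
#'
#' @param coding_only Drop the NNK stop codon (TAG)?
#' @return Character vector of codons with a `residue` attribute giving the
#'   standard-code translation.
#' @export
nnk_codons <- function(coding_only = FALSE) {
  b <- c("A", "C", "G", "T")
  cods <- as.vector(outer(outer(b, b, paste0), c("G", "T"), paste0))
  cods <- sort(cods)
  res <- unname(Biostrings::GENETIC_CODE[cods])
  if (coding_only) {
    keep <- res != "*"
    cods <- cods[keep]
    res <- res[keep]
  }
  attr(cods, "residue") <- res
  cods
}

#' Residue distribution implied by NNK codon sampling
#'
#' Exact census of the 32 NNK codons. With `include_stop = FALSE` the single
#' NNK stop (TAG) is excluded and probabilities renormalised — this is the
#' distribution produced by rejection sampling in the simulator's background.
#'
#' @param include_stop Keep the stop codon as `"*"`?
#' @return Named numeric vector of probabilities.
#' @export
nnk_residue_distribution <- function(include_stop = FALSE) {
  cods <- nnk_codons(coding_only = !include_stop)
  tab <- table(attr(cods, "residue"))
  p <- as.numeric(tab) / length(cods)
  setNames(p, names(tab))
}
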