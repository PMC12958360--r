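# Shared fixtures and independent oracles. Everything is generated in code
# under fixed seeds set inside each test.

AA <- rapidmine:::AA20

rnd_pep <- function(n, len) {
  vapply(seq_len(n), function(i) paste(sample(AA, len, TRUE), collapse = ""),
         character(1))
}

# arbitrary NNK-compatible codon per residue (random among the options)
NNK_BY_RES <- split(nnk_codons(coding_only = TRUE),
                    attr(nnk_codons(coding_only = TRUE), "residue"))

encode_nnk <- function(peptide) {
  res <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  paste(vapply(res, function(r) sample(NNK_BY_RES[[r]], 1L), character(1)),
        collapse = "")
}

build_read <- function(region_dna, arch = library_architecture()) {
  paste0(arch$upstream_anchor, arch$initiator_codon, region_dna,
         arch$anchor_codon, arch$spacer_nucleotides, arch$stop_codons[1L])
}

# independent per-codon translation oracle (Biostrings table, no package code)
naive_translate <- function(region_dna, initiator_symbol = "Y") {
  cods <- substring(region_dna, seq(1, nchar(region_dna), 3),
                    seq(3, nchar(region_dna), 3))
  paste0(initiator_symbol,
         paste(unname(Biostrings::GENETIC_CODE[cods]), collapse = ""), "C")
}

# prefilter-free greedy clustering oracle: plain R loop over pairwise
# sequence_identity, first-cluster-wins in creation order
brute_greedy <- function(peptides, threshold) {
  reps <- integer(0)
  assign_to <- integer(length(peptides))
  for (q in seq_along(peptides)) {
    hit <- 0L
    for (r in seq_along(reps)) {
      if (sequence_identity(peptides[q], peptides[reps[r]]) >= threshold - 1e-9) {
        hit <- r
        break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, q)
      hit <- length(reps)
    }
    assign_to[q] <- hit
  }
  list(cluster = assign_to, representatives = reps)
}

# exhaustive global alignment score, linear gap cost (oracle for toy scoring)
enum_align_score <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  la <- nchar(a); lb <- nchar(b)
  rec <- function(i, j) {
    if (i > la && j > lb) return(0)
    best <- -Inf
    if (i <= la && j <= lb) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L))
    }
    if (i <= la) best <- max(best, gap + rec(i + 1L, j))
    if (j <= lb) best <- max(best, gap + rec(i, j + 1L))
    best
  }
  rec(1L, 1L)
}

# fixture family around a printed consensus motif: random-length random flanks
motif_fixture <- function(n = 20, motif = "FWTLYGPI", max_flank = 3) {
  out <- vapply(seq_len(n), function(i) {
    nf <- sample(0:max_flank, 1L)
    nb <- sample(0:max_flank, 1L)
    paste0(paste(sample(AA, nf, TRUE), collapse = ""), motif,
           paste(sample(AA, nb, TRUE), collapse = ""))
  }, character(1))
  setNames(out, sprintf("s%02d", seq_len(n)))
}

mutate_pep <- function(peptide, k) {
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(AA, chars[p]), 1L)
  paste(chars, collapse = "")
}

# truth map peptide -> planted family for a selection_sim
truth_families <- function(sim) {
  tr <- unique(data.table::rbindlist(
    lapply(sim$rounds, function(r) r[, list(peptide, family)])))
  setNames(tr$family, tr$peptide)
}
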