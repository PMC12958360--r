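test_that("translate_codon: standard code, reprogrammed initiator, stop, ambiguity", {
  code_l <- genetic_code("Y")
  code_d <- genetic_code("y")
  expect_identical(translate_codon("TGC", code_l), "C")
  expect_identical(translate_codon("TAA", code_l), "*")
  expect_identical(translate_codon("ATG", code_d, is_initiator = TRUE), "y")
  expect_identical(translate_codon("ATG", code_d, is_initiator = FALSE), "M")
  expect_identical(translate_codon("ATG", code_l, is_initiator = TRUE), "Y")
  expect_error(translate_codon("ANG", code_l), "ambiguous_base")
  expect_error(translate_codon("AT", code_l))
})

test_that("check_nnk: wobble rule and the 32/64 census", {
  expect_true(check_nnk("TTG"))
  expect_false(check_nnk("TTA"))
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  expect_identical(sum(check_nnk(all64)), 32L)       # enumeration oracle
  expect_length(nnk_codons(), 32L)
  expect_length(nnk_codons(coding_only = TRUE), 31L) # single NNK stop (TAG)
})

test_that("nnk residue census matches hand-counted codon multiplicities", {
  p <- nnk_residue_distribution(include_stop = TRUE)
  expect_equal(unname(p[c("L", "R", "S")]), rep(3 / 32, 3))
  expect_equal(unname(p[c("M", "W")]), rep(1 / 32, 2))
  expect_equal(unname(p["*"]), 1 / 32)
  expect_equal(sum(p), 1)
  expect_equal(sum(nnk_residue_distribution(include_stop = FALSE)), 1)
})

test_that("library_architecture validates its invariants", {
  expect_error(library_architecture(initiator_codon = "AT"), "length 3")
  expect_error(library_architecture(random_codon_count = 0), "positive")
  expect_error(library_architecture(initiator_symbol = "yy"), "one character")
  expect_error(library_architecture(upstream_anchor = "ACGN"), "A,C,G,T")
  arch <- library_architecture(initiator_symbol = "y", library_tag = "D")
  expect_s3_class(arch, "library_architecture")
})

test_that("decode/encode round trip over arbitrary NNK codon choices", {
  set.seed(11)
  arch <- library_architecture()
  for (i in 1:40) {
    pep <- rnd_pep(1, arch$random_codon_count)
    region <- encode_nnk(pep)
    got <- decode_read(build_read(region, arch), arch)
    expect_true(got$accepted)
    expect_identical(got$peptide, paste0("Y", pep, "C"))
    expect_identical(got$peptide, naive_translate(region))   # oracle
    expect_identical(got$dna_random_region, region)
  }
})

test_that("decode handles the reverse-complement orientation", {
  set.seed(12)
  arch <- library_architecture()
  pep <- rnd_pep(1, 15)
  read <- build_read(encode_nnk(pep), arch)
  rc <- rapidmine:::revcomp_chr(read)
  got <- decode_read(rc, arch)
  expect_true(got$accepted)
  expect_identical(got$peptide, paste0("Y", pep, "C"))
})

test_that("rejection reasons are single, ordered, and exhaustive", {
  set.seed(13)
  arch <- library_architecture()
  pep <- rnd_pep(1, 15)
  region <- encode_nnk(pep)
  good <- build_read(region, arch)

  # upstream anchor destroyed
  noanchor <- sub(arch$upstream_anchor, strrep("A", nchar(arch$upstream_anchor)),
                  good, fixed = TRUE)
  expect_identical(as.character(decode_read(noanchor, arch)$reject_reason),
                   "anchor_not_found")

  # read truncated inside the footprint
  short <- substr(good, 1, nchar(arch$upstream_anchor) + 20)
  expect_identical(as.character(decode_read(short, arch)$reject_reason),
                   "anchor_not_found")

  # ambiguous base inside the random region
  nread <- good
  substr(nread, nchar(arch$upstream_anchor) + 10, nchar(arch$upstream_anchor) + 10) <- "N"
  expect_identical(as.character(decode_read(nread, arch)$reject_reason),
                   "ambiguous_base")

  # internal stop in the random region
  stopregion <- paste0("TAA", substr(region, 4, nchar(region)))
  stopread <- build_read(stopregion, arch)
  expect_identical(as.character(decode_read(stopread, arch)$reject_reason),
                   "internal_stop")
  expect_identical(as.character(decode_read(stopread, arch,
                                            keep_internal_stops = TRUE)$reject_reason),
                   "none")

  # whole-codon deletion: Cys anchor shifted by one codon -> length_mismatch
  indel <- build_read(substr(region, 4, nchar(region)), arch)
  expect_identical(as.character(decode_read(indel, arch)$reject_reason),
                   "length_mismatch")

  # Cys anchor replaced -> anchor_not_found (absent at and around the
  # expected position)
  nocys <- paste0(arch$upstream_anchor, arch$initiator_codon, region, "GGA",
                  arch$spacer_nucleotides, arch$stop_codons[1])
  expect_identical(as.character(decode_read(nocys, arch)$reject_reason),
                   "anchor_not_found")

  # every read yields accepted xor exactly one reason
  batch <- decode_reads(c(good, noanchor, nread, stopread, indel, nocys), arch)
  expect_identical(batch$accepted, batch$reject_reason == "none")
  expect_false(anyNA(batch$reject_reason))
})

test_that("NNK violations are counted, and rejected only in strict mode", {
  arch <- library_architecture()
  region <- paste0("TTA", strrep("GCT", 14))   # Leu with A wobble + 14 NNK Ala
  read <- build_read(region, arch)
  lax <- decode_read(read, arch)
  expect_true(lax$accepted)
  expect_identical(lax$nnk_violations, 1L)
  strict <- decode_read(read, arch, strict_nnk = TRUE)
  expect_identical(as.character(strict$reject_reason), "nnk_violation_discarded")
})

test_that("decode_reads is a pure function of (read, arch)", {
  set.seed(14)
  arch <- library_architecture()
  reads <- vapply(rnd_pep(25, 15), function(p) build_read(encode_nnk(p), arch),
                  character(1))
  reads <- c(reads, "ACGTACGTACGT")
  expect_identical(decode_reads(reads, arch), decode_reads(reads, arch))
})

test_that("decode_fastq reads plain and gzipped files", {
  set.seed(15)
  cfg <- selection_sim_config(seed = 21, rounds = 1, reads_per_round = 150,
                              pool_size = 400, per_base_error = 0)
  sim <- simulate_selection(cfg)
  fq <- tempfile(fileext = ".fastq")
  fqgz <- tempfile(fileext = ".fastq.gz")
  emit_fastq(sim, 1, fq)
  emit_fastq(sim, 1, fqgz)
  d1 <- decode_fastq(fq, cfg$arch)
  d2 <- decode_fastq(fqgz, cfg$arch)
  expect_identical(d1$peptide, d2$peptide)
  expect_identical(nrow(d1), 150L)
  expect_true(all(d1$accepted))
  expect_identical(sort(d1$read_id), sort(sim$rounds[[1]]$read_id))
})

test_that("rejection tally covers all enum levels", {
  arch <- library_architecture()
  tal <- rejection_tally(decode_reads(c("ACGT"), arch))
  expect_setequal(tal$reject_reason, rapidmine:::REJECT_LEVELS)
  expect_identical(sum(tal$reads), 1L)
})
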