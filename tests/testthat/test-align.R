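test_that("pairwise_align: identical sequences, toy enumeration oracle, symmetry", {
  sub <- blosum62_matrix()
  pa <- pairwise_align("ACDEFG", "ACDEFG")
  expect_identical(pa$a, "ACDEFG")
  expect_identical(pa$b, "ACDEFG")
  expect_equal(pa$score, sum(diag(sub[strsplit("ACDEFG", "")[[1]],
                                      strsplit("ACDEFG", "")[[1]]])))

  # toy matrix, linear gaps: compare against exhaustive enumeration
  toy <- rapidmine:::score_matrix(1, -1)
  set.seed(51)
  cases <- list(c("ACG", "AG"), c("WW", "WAW"), c("ACDE", "CDE"), c("AC", "CA"))
  for (cs in cases) {
    got <- pairwise_align(cs[1], cs[2], toy, gap_open = 1, gap_extend = 1)
    expect_equal(got$score, enum_align_score(cs[1], cs[2]))
    expect_identical(gsub("-", "", got$a), cs[1])
    expect_identical(gsub("-", "", got$b), cs[2])
    expect_identical(nchar(got$a), nchar(got$b))
  }
  got <- pairwise_align("ACG", "AG", toy, gap_open = 1, gap_extend = 1)
  expect_equal(got$score, 1)                     # two matches, one gap
  expect_identical(lengths(regmatches(got$b, gregexpr("-", got$b)))[[1]], 1L)

  for (i in 1:10) {
    a <- rnd_pep(1, sample(5:12, 1)); b <- rnd_pep(1, sample(5:12, 1))
    expect_equal(pairwise_align(a, b)$score, pairwise_align(b, a)$score)
  }
  expect_error(pairwise_align("", "AA"))
})

test_that("build_guide_tree reproduces a hand-computed 3-taxon UPGMA", {
  seqs <- c(A = "AAAAAAAAAA", B = "AAAAAAAAAW", C = "WWWWWWAAAA")
  d <- 1 - outer(seqs, seqs, Vectorize(sequence_identity))
  tr <- build_guide_tree(seqs)$hclust
  # closest pair (A, B) joins first at half its distance...
  expect_setequal(tr$merge[1, ], c(-1, -2))
  expect_equal(tr$height[1], d["A", "B"])
  # ...then C at the average of its distances to A and B (UPGMA by hand;
  # hclust reports merge heights as cluster distances)
  expect_equal(tr$height[2], mean(c(d["A", "C"], d["B", "C"])))
})

test_that("ultrametric distances are reproduced by cophenetic distances", {
  # build sequences whose identity distances are ultrametric by construction:
  # two tight pairs far from each other
  seqs <- c(a1 = "AAAAAAAAAA", a2 = "AAAAAAAAAW",
            b1 = "CCCCCCCCCC", b2 = "CCCCCCCCCW")
  tr <- build_guide_tree(seqs)$hclust
  co <- as.matrix(stats::cophenetic(tr))
  d <- 1 - outer(seqs, seqs, Vectorize(sequence_identity))
  # within-pair and between-block distances are reproduced exactly
  expect_equal(co["a1", "a2"], d["a1", "a2"])
  expect_equal(co["b1", "b2"], d["b1", "b2"])
  expect_equal(co["a1", "b1"], mean(d[c("a1", "a2"), c("b1", "b2")]))
  expect_match(guide_tree_newick(build_guide_tree(seqs)), "^\\(")
})

test_that("progressive_align: gapless on identical input, full conservation", {
  seqs <- setNames(rep("YFWTLYGPIC", 4), paste0("s", 1:4))
  pr <- progressive_align(seqs)
  expect_identical(unname(pr$aligned), unname(seqs))
  expect_equal(pr$conservation, rep(1, 10))
  expect_identical(pr$consensus, "YFWTLYGPIC")
})

test_that("a single-residue insertion yields exactly one gap column", {
  seqs <- c(x = "YFWTLYGPC", y = "YFWTLYGPC", z = "YFWTALYGPC")
  pr <- progressive_align(seqs)
  expect_identical(nchar(pr$aligned[["x"]]), 10L)
  expect_identical(sum(strsplit(pr$aligned[["x"]], "")[[1]] == "-"), 1L)
  expect_identical(sum(strsplit(pr$aligned[["y"]], "")[[1]] == "-"), 1L)
  expect_false(grepl("-", pr$aligned[["z"]]))
})

test_that("gap removal reproduces inputs on random profiles (property)", {
  set.seed(52)
  for (rep in 1:8) {
    n <- sample(3:7, 1)
    seqs <- rnd_pep(n, 14)
    # lengths vary per sequence
    seqs <- vapply(seqs, function(s) substr(s, 1, sample(6:nchar(s), 1)), character(1))
    names(seqs) <- sprintf("q%d", seq_len(n))
    pr <- progressive_align(seqs)
    expect_identical(vapply(pr$aligned, function(r) gsub("-", "", r), character(1),
                            USE.NAMES = FALSE),
                     unname(seqs))
    expect_identical(length(unique(nchar(pr$aligned))), 1L)
    expect_true(all(pr$conservation >= 0 & pr$conservation <= 1))
  }
})

test_that("on pairs, progressive alignment reduces to pairwise alignment", {
  set.seed(53)
  for (i in 1:6) {
    a <- rnd_pep(1, sample(8:14, 1)); b <- rnd_pep(1, sample(8:14, 1))
    pr <- progressive_align(c(p = a, q = b))
    pa <- pairwise_align(a, b)
    expect_identical(unname(pr$aligned[["p"]]), pa$a)
    expect_identical(unname(pr$aligned[["q"]]), pa$b)
  }
})

test_that("column_conservation arithmetic", {
  expect_equal(column_conservation(c(r1 = "W", r2 = "W", r3 = "W")), 1)
  expect_equal(column_conservation(setNames(AA, AA)), 0)
  expect_equal(column_conservation(c(a = "A", b = "A", c = "G", d = "G")),
               1 - log(2) / log(20))
  # gap-majority rule: > 50% gaps scores 0
  expect_equal(column_conservation(c(a = "W", b = "-", c = "-")), 0)
  # lowercase d-initiator is scored as Tyr
  expect_equal(column_conservation(c(a = "y", b = "Y")), 1)
})

test_that("consensus: majority residue, gap majority, deterministic ties", {
  rows <- c(a = "AW-", b = "AW-", c = "GWA")
  expect_identical(consensus_sequence(rows), "AW-")
  # tie A vs G resolved alphabetically
  expect_identical(consensus_sequence(c(a = "A", b = "G")), "A")
})

test_that("consensus of a motif family contains the motif", {
  set.seed(54)
  seqs <- motif_fixture(20, "FWTLYGPI")
  pr <- progressive_align(seqs)
  expect_match(gsub("-", "", pr$consensus), "FWTLYGPI")
})

test_that("extract_families recovers planted structure", {
  set.seed(55)
  sA <- rnd_pep(1, 12); sB <- rnd_pep(1, 12)
  while (sequence_identity(sA, sB) > 0.3) sB <- rnd_pep(1, 12)
  fam <- c(setNames(vapply(rep(sA, 8), mutate_pep, character(1), k = 1),
                    sprintf("A%d", 1:8)),
           setNames(vapply(rep(sB, 8), mutate_pep, character(1), k = 1),
                    sprintf("B%d", 1:8)))
  pr <- progressive_align(fam)
  fa <- extract_families(pr, threshold = 0.6)
  expect_length(fa$families, 2L)
  got <- lapply(fa$families, sort)
  expect_setequal(vapply(got, paste, character(1), collapse = ","),
                  c(paste(sprintf("A%d", 1:8), collapse = ","),
                    paste(sprintf("B%d", 1:8), collapse = ",")))

  # all-identical rows collapse to one family
  same <- setNames(rep("YWFACDEG", 5), sprintf("s%d", 1:5))
  expect_length(extract_families(progressive_align(same))$families, 1L)

  # a lone distant row stays a singleton family
  lone <- rnd_pep(1, 12)
  while (sequence_identity(lone, sA) > 0.3 || sequence_identity(lone, sB) > 0.3)
    lone <- rnd_pep(1, 12)
  pr2 <- progressive_align(c(fam, LONE = lone))
  fa2 <- extract_families(pr2, threshold = 0.6)
  expect_length(fa2$families, 3L)
  expect_true("LONE" %in% unlist(fa2$families[lengths(fa2$families) == 1]))
})

test_that("logo matrix rows are frequency distributions", {
  set.seed(56)
  pr <- progressive_align(motif_fixture(10))
  lm <- logo_matrix(pr)
  expect_identical(ncol(lm), 20L)
  sums <- rowSums(lm)
  expect_true(all(abs(sums[sums > 0] - 1) < 1e-9))
})

test_that("alignment writers emit readable files", {
  pr <- progressive_align(c(u = "YFWTLYGPC", v = "YFWTLYAPC"))
  fa <- tempfile(fileext = ".afa"); cw <- tempfile(fileext = ".aln")
  write_alignment_fasta(pr, fa)
  write_alignment_clustal(pr, cw)
  lines <- readLines(fa)
  expect_identical(lines[1], ">u")
  expect_identical(gsub("-", "", lines[2]), "YFWTLYGPC")
  expect_match(readLines(cw)[1], "CLUSTAL")
})
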