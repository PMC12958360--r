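test_that("config validation enforces the stated world", {
  expect_error(selection_sim_config(1, families = list(
    list(seed = "AAAAA", mutation_rate = 0, fitness = 1, fraction_r1 = 0.1))),
    "length")
  expect_error(selection_sim_config(1, families = list(
    list(seed = strrep("A", 15), mutation_rate = 0, fitness = 1, fraction_r1 = 0.7),
    list(seed = strrep("G", 15), mutation_rate = 0, fitness = 1, fraction_r1 = 0.7))),
    "exceed")
  cfg <- selection_sim_config(1, families = list(
    list(seed = strrep("A", 15), mutation_rate = 0.1, fitness = 2, fraction_r1 = 0.2)))
  expect_equal(cfg$background_fraction_r1, 0.8)
})

test_that("sim config JSON round trip", {
  cfg <- headline_sim_config(seed = 5, reads_per_round = 100)
  f <- tempfile(fileext = ".json")
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  expect_equal(back$families, cfg$families)
  expect_identical(back$pool_size, cfg$pool_size)
  expect_identical(back$arch$upstream_anchor, cfg$arch$upstream_anchor)
})

test_that("zero mutation rate reproduces the seed exactly", {
  cfg <- selection_sim_config(2, rounds = 1, reads_per_round = 50, pool_size = 200,
                              families = list(list(seed = strrep("W", 15),
                                                   mutation_rate = 0, fitness = 1,
                                                   fraction_r1 = 0.5)),
                              per_base_error = 0)
  pool <- sample_library(cfg)
  expect_true(all(pool$peptide[pool$family == 1] == strrep("W", 15)))
})

test_that("advance_round follows the closed-form fitness update", {
  expect_equal(advance_round(c(0.3, 0.7), c(2, 2)), c(0.3, 0.7))
  expect_equal(advance_round(c(0.5, 0.5), c(10, 1)), c(10 / 11, 1 / 11))
  # four updates from p = (0.01, 0.99), w = (10, 1): closed-form iteration
  p <- c(0.01, 0.99)
  for (i in 1:4) p <- advance_round(p, c(10, 1))
  expect_equal(p[1], 0.01 * 1e4 / (0.01 * 1e4 + 0.99))
  expect_error(advance_round(c(1, 0), c(0, 0)), "all-zero")
  # expected_frequencies agrees with repeated updates
  cfg <- headline_sim_config(seed = 1, reads_per_round = 10)
  ef <- expected_frequencies(cfg)
  p <- ef[, 1]
  w <- c(cfg$background_fitness,
         vapply(cfg$families, `[[`, numeric(1), "fitness"))
  for (r in 2:cfg$rounds) {
    p <- advance_round(p, w)
    expect_equal(unname(p), unname(ef[, r]))
  }
})

test_that("round-1 family fraction matches the config within sampling error", {
  cfg <- selection_sim_config(3, rounds = 1, reads_per_round = 20000,
                              pool_size = 40000,
                              families = list(list(seed = strrep("W", 15),
                                                   mutation_rate = 0.05, fitness = 1,
                                                   fraction_r1 = 0.1)),
                              per_base_error = 0)
  sim <- simulate_selection(cfg)
  obs <- mean(sim$rounds[[1]]$family == 1)
  se <- sqrt(0.1 * 0.9 / 20000)
  expect_lt(abs(obs - 0.1), 4 * se)
})

test_that("zero-error emission round-trips through decoding, counts = truth", {
  cfg <- selection_sim_config(4, rounds = 2, reads_per_round = 1500,
                              pool_size = 3000,
                              families = list(list(seed = strrep("A", 15),
                                                   mutation_rate = 0.1, fitness = 3,
                                                   fraction_r1 = 0.05)),
                              per_base_error = 0)
  sim <- simulate_selection(cfg)
  dec <- decode_reads(sim$rounds[[2]]$dna, cfg$arch)
  expect_true(all(dec$accepted))
  expect_identical(dec$peptide, sim$rounds[[2]]$peptide)
  pc <- count_unique(dec$peptide, round = 2)
  truth <- sim_round_counts(sim, 2)
  setkey(truth, peptide)
  expect_identical(truth[pc$peptide, count], pc$count)   # oracle: simulator tally
})

test_that("substitution errors appear at the configured binomial rate", {
  cfg <- selection_sim_config(6, rounds = 1, reads_per_round = 5000,
                              pool_size = 10000, per_base_error = 0.002)
  sim <- simulate_selection(cfg)
  rd <- sim$rounds[[1]]
  mism <- sum(vapply(seq_len(nrow(rd)), function(i) {
    a <- strsplit(rd$dna[i], "")[[1]]
    b <- strsplit(rd$dna_clean[i], "")[[1]]
    sum(a != b)
  }, numeric(1)))
  total <- sum(nchar(rd$dna_clean))
  expected <- total * 0.002
  expect_lt(abs(mism - expected), 3 * sqrt(total * 0.002 * 0.998))
})

test_that("same seed gives byte-identical FASTQ; SimTruth export is complete", {
  cfg <- selection_sim_config(7, rounds = 2, reads_per_round = 300,
                              pool_size = 900, per_base_error = 0.005)
  f1 <- tempfile(fileext = ".fastq.gz"); f2 <- tempfile(fileext = ".fastq.gz")
  emit_fastq(simulate_selection(cfg), 2, f1)
  emit_fastq(simulate_selection(cfg), 2, f2)
  expect_identical(readLines(f1), readLines(f2))

  sim <- simulate_selection(cfg)
  tf <- tempfile(fileext = ".tsv")
  write_sim_truth(sim, tf)
  tr <- read.table(tf, header = TRUE, sep = "\t")
  expect_identical(nrow(tr), 600L)
  expect_setequal(unique(tr$round), 1:2)
})

test_that("background residue draws follow the stop-conditioned NNK census", {
  set.seed(71)
  peps <- rapidmine:::sample_nnk_peptides(2000, 15)
  res <- unlist(strsplit(peps, ""), use.names = FALSE)
  n <- length(res)
  p <- nnk_residue_distribution(include_stop = FALSE)
  obs <- table(factor(res, levels = names(p))) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(as.numeric(obs) - p) <= 4 * se))
})
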