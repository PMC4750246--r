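test_that("the worked two-read bubble is found exactly once", {
  g <- fig2_graph()
  for (mode in c("strict", "relaxed")) {
    b <- find_snp_bubbles(g, mode)
    expect_equal(nrow(b), 1L)
    expect_equal(nchar(b$path_a), 7L)  # 2k - 1
    expect_equal(b$center, 3L)         # k - 1
    # the reported pair is the canonical form of (CTGACCT, CTGTCCT)
    expect_equal(ora_pair_key(b$path_a, b$path_b),
                 ora_pair_key("CTGACCT", "CTGTCCT"))
    d <- mapply(function(p, q) {
      sum(strsplit(p, "")[[1]] != strsplit(q, "")[[1]])
    }, b$path_a, b$path_b)
    expect_equal(unname(d), 1L)
    # both paths are made of solid windows only
    wins <- c(ora_windows(b$path_a, 4L), ora_windows(b$path_b, 4L))
    expect_true(all(solid_contains(g$solid, wins)))
  }
})

test_that("a variant-free genome yields no bubbles", {
  set.seed(20)
  g <- graph_from_reads(rand_dna(2000), 15L)
  expect_equal(nrow(find_snp_bubbles(g)), 0L)
})

test_that("relaxed detection equals the exhaustive string-level oracle", {
  set.seed(21)
  cases <- list(list(k = 5L, len = 300L), list(k = 5L, len = 400L),
                list(k = 7L, len = 800L), list(k = 7L, len = 1200L))
  for (cs in cases) {
    genome <- rand_dna(cs$len)
    alt <- mutate_positions(genome, 3L)
    g <- graph_from_reads(c(genome, alt), cs$k)
    b <- find_snp_bubbles(g, "relaxed")
    keys <- sort(mapply(ora_pair_key, b$path_a, b$path_b, USE.NAMES = FALSE))
    expect_equal(keys, oracle_bubbles(solid_members(g$solid), cs$k))
  }
})

test_that("bubble calling is strand-invariant", {
  set.seed(22)
  genome <- rand_dna(3000)
  pl <- plant_snps(genome, 4L, 15L, seed = 221)
  reads <- c(genome, pl$alt_genome)
  g_f <- graph_from_reads(reads, 15L)
  g_r <- graph_from_reads(reverse_complement(reads), 15L)
  b_f <- find_snp_bubbles(g_f)
  b_r <- find_snp_bubbles(g_r)
  expect_equal(b_f$path_a, b_r$path_a)
  expect_equal(b_f$path_b, b_r$path_b)
})

test_that("every reported bubble window meets the solidity threshold", {
  set.seed(23)
  genome <- rand_dna(5000)
  pl <- plant_snps(genome, 5L, 15L, seed = 231)
  r1 <- simulate_reads(genome, 8, 60, 0, 232)
  r2 <- simulate_reads(pl$alt_genome, 8, 60, 0, 233)
  c_thr <- 3L
  tab <- count_kmers(list(r1, r2), kmer_spec(15L))
  g <- dbg_graph(build_solid_set(tab, c_thr))
  b <- find_snp_bubbles(g)
  expect_gt(nrow(b), 0L)
  for (i in seq_len(nrow(b))) {
    wins <- c(ora_windows(b$path_a[i], 15L), ora_windows(b$path_b[i], 15L))
    expect_true(all(kmer_count(tab, wins) >= c_thr))
  }
})

test_that("flanks reconstruct the genome and stop at neighboring forks", {
  g <- fig2_graph()
  b <- extend_flanks(g, find_snp_bubbles(g))
  expect_equal(b$left_contig, "")   # toy bubble has no context
  expect_equal(b$right_contig, "")

  set.seed(24)
  genome <- rand_dna(2000)
  k <- 15L
  pl <- plant_snps(genome, 1L, k, seed = 241)
  g1 <- graph_from_reads(c(genome, pl$alt_genome), k)
  b1 <- extend_flanks(g1, find_snp_bubbles(g1))
  expect_equal(nrow(b1), 1L)
  full <- paste0(b1$left_contig, b1$path_a, b1$right_contig)
  fullb <- paste0(b1$left_contig, b1$path_b, b1$right_contig)
  # one flanked allele is a genome substring, the other carries the SNP
  # (possibly both reverse-complemented: compare canonically)
  hit <- function(s, gen) grepl(s, gen, fixed = TRUE) ||
    grepl(ora_rc(s), gen, fixed = TRUE)
  expect_true(hit(full, genome) || hit(full, pl$alt_genome))
  expect_true(hit(fullb, genome) || hit(fullb, pl$alt_genome))
  expect_true(xor(hit(full, genome), hit(fullb, genome)))
  # flanks span all context up to the genome ends (single SNP, no forks)
  expect_equal(nchar(full), nchar(genome))
})

test_that("a second bubble truncates the flank at its fork", {
  set.seed(25)
  k <- 15L
  # two SNPs ~3k apart: flank of one stops before the other's fork
  genome <- rand_dna(3000)
  repeat {
    pl <- plant_snps(genome, 2L, k, seed = sample.int(1e6, 1))
    gap <- diff(pl$truth$position)
    if (gap >= 2 * k && gap <= 4 * k) break
  }
  g <- graph_from_reads(c(genome, pl$alt_genome), k)
  b <- extend_flanks(g, find_snp_bubbles(g))
  expect_equal(nrow(b), 2L)
  # no flanked sequence may span both SNP positions
  for (i in 1:2) {
    flanked <- paste0(b$left_contig[i], b$path_a[i], b$right_contig[i])
    expect_lt(nchar(flanked), nchar(genome))
  }
})

test_that("bubble FASTA round-trips losslessly, with and without counts", {
  set.seed(26)
  genome <- rand_dna(20000)
  k <- 21L
  pl <- plant_snps(genome, 8L, k, seed = 261)
  sets <- list(hapA = simulate_reads(genome, 6, 80, 0, 262),
               hapB = simulate_reads(pl$alt_genome, 6, 80, 0, 263))
  g <- graph_from_reads(c(sets$hapA$seq, sets$hapB$seq), k)
  b <- extend_flanks(g, find_snp_bubbles(g))
  f <- tempfile(fileext = ".fa")
  expect_equal(write_bubbles_fasta(b, f), 2L * nrow(b))
  back <- read_bubbles_fasta(f, k)
  expect_equal(back$path_a, b$path_a)
  expect_equal(back$path_b, b$path_b)
  expect_equal(back$left_contig, b$left_contig)
  expect_equal(back$right_contig, b$right_contig)

  q <- rank_bubbles(quantify_bubbles(b, sets, k))
  write_bubbles_fasta(q, f)
  back2 <- read_bubbles_fasta(f, k)
  expect_equal(back2$count_a_hapA, q$count_a_hapA)
  expect_equal(back2$count_b_hapB, q$count_b_hapB)
  expect_equal(back2$phi, q$phi, tolerance = 1e-5)

  # empty set round-trips too
  empty <- b[0, ]
  class(empty) <- c("snp_bubbles", "data.frame")
  f0 <- tempfile(fileext = ".fa")
  expect_equal(write_bubbles_fasta(empty, f0), 0L)
  expect_equal(nrow(read_bubbles_fasta(f0, k)), 0L)
})

test_that("full-coverage error-free reads recover every planted SNP", {
  set.seed(27)
  genome <- random_genome(20000, 0.5, 271)
  k <- 21L
  pl <- plant_snps(genome, 10L, k, seed = 272)
  r1 <- simulate_reads(genome, 15, 80, 0, 273)
  r2 <- simulate_reads(pl$alt_genome, 15, 80, 0, 274)
  tab <- count_kmers(list(r1, r2), kmer_spec(k))
  g <- dbg_graph(build_solid_set(tab, 2L))
  b <- find_snp_bubbles(g, "strict")
  ev <- evaluate_snps(b, pl$truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
})
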