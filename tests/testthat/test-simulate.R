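test_that("random genomes are deterministic with controlled composition", {
  expect_error(random_genome(0), "length")
  expect_equal(nchar(random_genome(1, seed = 1)), 1L)
  expect_equal(random_genome(500, seed = 7), random_genome(500, seed = 7))
  expect_false(random_genome(500, seed = 7) == random_genome(500, seed = 8))
  g <- random_genome(1e5, gc = 0.5, seed = 9)
  gc_obs <- mean(strsplit(g, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.5), 3 * sqrt(0.25 / 1e5))
  g2 <- random_genome(1e5, gc = 0.7, seed = 10)
  gc2 <- mean(strsplit(g2, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc2 - 0.7), 3 * sqrt(0.21 / 1e5))
  expect_error(random_genome(100, gc = 0), "gc")
})

test_that("planted SNPs are where the truth says, and nowhere else", {
  k <- 15L
  genome <- random_genome(10000, 0.5, 70)
  expect_identical(plant_snps(genome, 0L, k)$alt_genome, genome)
  pl <- plant_snps(genome, 8L, k, seed = 71)
  gv <- strsplit(genome, "")[[1]]
  av <- strsplit(pl$alt_genome, "")[[1]]
  diffs <- which(gv != av) - 1L  # 0-based
  expect_equal(sort(diffs), sort(pl$truth$position))
  expect_equal(gv[pl$truth$position + 1L], pl$truth$ref)
  expect_equal(av[pl$truth$position + 1L], pl$truth$alt)
  expect_true(all(diff(sort(pl$truth$position)) >= 2L * k))
  # each truth window's k-mers occur exactly once across both genomes
  wins <- unlist(lapply(c(pl$truth$ref_window, pl$truth$alt_window),
                        ora_windows, k = k))
  census <- table(ora_canon_vec(unlist(lapply(list(genome, pl$alt_genome),
                                              ora_windows, k = k))))
  expect_true(all(census[ora_canon_vec(wins)] == 1L))
  # capacity guard
  expect_error(plant_snps(rand_dna(100), 5L, k, seed = 72), "capacity")
})

test_that("planted inversions reverse-complement their segments with sound truth", {
  k <- 15L
  genome <- random_genome(20000, 0.5, 73)
  expect_identical(plant_inversions(genome, 0L, 50L, 100L, k)$alt_genome,
                   genome)
  pl <- plant_inversions(genome, 5L, 60L, 200L, k, seed = 74)
  tr <- pl$truth
  expect_equal(nrow(tr), 5L)
  for (i in 1:5) {
    seg <- substr(genome, tr$start[i] + 1L, tr$end[i])
    expect_equal(substr(pl$alt_genome, tr$start[i] + 1L, tr$end[i]),
                 ora_rc(seg))
  }
  # outside the segments the genomes agree
  gv <- strsplit(genome, "")[[1]]
  av <- strsplit(pl$alt_genome, "")[[1]]
  inside <- unlist(mapply(function(s, e) (s + 1L):e, tr$start, tr$end))
  expect_equal(gv[-inside], av[-inside])
  # each breakpoint word occurs in exactly one of the two genomes
  # (on either strand)
  occurs <- function(w, g) grepl(w, g, fixed = TRUE) ||
    grepl(ora_rc(w), g, fixed = TRUE)
  for (w in c(tr$bp_au, tr$bp_vb, tr$bp_avp, tr$bp_upb)) {
    expect_equal(occurs(w, genome) + occurs(w, pl$alt_genome), 1L)
  }
})

test_that("simulated reads are genome substrings with calibrated errors", {
  genome <- random_genome(5000, 0.5, 75)
  r <- simulate_reads(genome, 1, nchar(genome), 0, 751)
  expect_true(all(r$seq == genome | r$seq == ora_rc(genome)))

  r2 <- simulate_reads(genome, 3, 80, 0, 752)
  expect_equal(nrow(r2), ceiling(3 * 5000 / 80))
  expect_true(all(vapply(r2$seq, function(s) {
    grepl(s, genome, fixed = TRUE) || grepl(ora_rc(s), genome, fixed = TRUE)
  }, logical(1))))
  expect_equal(unique(nchar(r2$seq)), 80L)
  expect_equal(unique(nchar(r2$qual)), 80L)

  # determinism under a fixed seed
  expect_identical(simulate_reads(genome, 2, 60, 0.01, 753),
                   simulate_reads(genome, 2, 60, 0.01, 753))

  # observed substitution rate within 3 binomial SDs of the target
  err <- 0.01
  r3 <- simulate_reads(genome, 20, 100, err, 754)
  # same seed, zero error rate: identical layout, so mismatches = errors
  r0 <- simulate_reads(genome, 20, 100, 0, 754)
  same_layout <- nchar(r0$seq) == nchar(r3$seq)
  expect_true(all(same_layout))
  mism <- sum(mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, r0$seq, r3$seq))
  total <- sum(nchar(r3$seq))
  expect_lt(abs(mism / total - err), 3 * sqrt(err * (1 - err) / total))

  expect_error(simulate_reads(genome, 2, 10000), "read_len")
})

test_that("evaluation matches pairs canonically and handles edge rules", {
  k <- 15L
  genome <- random_genome(10000, 0.5, 76)
  pl <- plant_snps(genome, 6L, k, seed = 761)
  # predictions identical to truth -> perfect metrics
  pred <- data.frame(bubble_id = 1:6, path_a = pl$truth$ref_window,
                     path_b = pl$truth$alt_window, stringsAsFactors = FALSE)
  class(pred) <- c("snp_bubbles", "data.frame")
  ev <- evaluate_snps(pred, pl$truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  # reverse-complemented, shuffled, duplicated predictions: unchanged
  pred2 <- pred[c(3, 1, 2, 4, 5, 6, 1, 2), ]
  pred2$path_a <- ora_rc_vec(pred2$path_b)  # note: rc swaps pair roles
  pred2$path_b <- ora_rc_vec(pred[c(3, 1, 2, 4, 5, 6, 1, 2), ]$path_a)
  class(pred2) <- c("snp_bubbles", "data.frame")
  ev2 <- evaluate_snps(pred2, pl$truth)
  expect_equal(ev2$recall, 1)
  expect_equal(ev2$precision, 1)
  # empty predictions
  ev0 <- evaluate_snps(pred[0, ], pl$truth)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$precision, 1)
  # a junk prediction costs precision but not recall
  junk <- pred[1, ]
  junk$path_a <- strrep("A", 2 * k - 1)
  junk$path_b <- paste0(strrep("A", k - 1), "C", strrep("A", k - 1))
  ev3 <- evaluate_snps(rbind(pred, junk), pl$truth)
  expect_equal(ev3$recall, 1)
  expect_equal(ev3$precision, 6 / 7)
})

test_that("inversion evaluation is invariant over the tuple orbit", {
  k <- 15L
  genome <- random_genome(20000, 0.5, 77)
  pl <- plant_inversions(genome, 4L, 60L, 150L, k, seed = 771)
  tr <- pl$truth
  pred <- data.frame(a = tr$a, u = tr$u, v = tr$v, b = tr$b,
                     stringsAsFactors = FALSE)
  expect_equal(evaluate_inversions(pred, tr)$recall, 1)
  # present each event in a different equivalent form
  pred2 <- data.frame(a = ora_rc_vec(tr$b), u = ora_rc_vec(tr$v),
                      v = ora_rc_vec(tr$u), b = ora_rc_vec(tr$a),
                      stringsAsFactors = FALSE)
  ev2 <- evaluate_inversions(pred2, tr)
  expect_equal(ev2$recall, 1)
  expect_equal(ev2$precision, 1)
  expect_equal(evaluate_inversions(pred[0, ], tr)$recall, 0)
  expect_equal(evaluate_inversions(pred[0, ], tr)$precision, 1)
})
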