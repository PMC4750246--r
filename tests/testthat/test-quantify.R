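test_that("map_read honors identity, the center rule and the anchor rule", {
  set.seed(30)
  k <- 11L
  target <- rand_dna(80)
  center <- 40L
  expect_true(map_read(target, target, center, k, 0L))
  # a read covering only the left of the target never reaches the center
  expect_false(map_read(substr(target, 1, 30), target, center, k, 0L))
  # reverse-complement reads map too
  expect_true(map_read(ora_rc(substr(target, 20, 60)), target, center, k, 0L))
})

test_that("map_read agrees with the exhaustive all-offsets oracle", {
  set.seed(31)
  k <- 7L
  n_agree <- 0L
  for (i in 1:200) {
    target <- rand_dna(sample(20:60, 1))
    center <- sample(seq_len(nchar(target)), 1) - 1L
    read <- if (runif(1) < 0.5) {
      # related read: a (possibly mutated, possibly flipped) slice
      lo <- sample(seq_len(nchar(target) - 10), 1)
      s <- substr(target, lo, min(nchar(target), lo + sample(10:40, 1)))
      s <- mutate_positions(s, sample(0:2, 1))
      if (runif(1) < 0.5) ora_rc(s) else s
    } else {
      rand_dna(sample(15:40, 1))
    }
    mm <- sample(0:2, 1)
    got <- map_read(read, target, center, k, mm)
    want <- oracle_map_read(read, target, center, k, mm)
    expect_identical(got, want)
    n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, 200L)
})

make_two_allele_bubbles <- function(k = 11L, seed = 32) {
  set.seed(seed)
  genome <- rand_dna(4000)
  pl <- plant_snps(genome, 3L, k, seed = seed + 1L)
  g <- graph_from_reads(c(genome, pl$alt_genome), k)
  b <- extend_flanks(g, find_snp_bubbles(g))
  list(bubbles = b, genome = genome, alt = pl$alt_genome, k = k)
}

test_that("quantification counts allele-specific reads and drops ambiguous ones", {
  fx <- make_two_allele_bubbles()
  b <- fx$bubbles
  expect_equal(nrow(b), 3L)
  pa <- paste0(b$left_contig, b$path_a, b$right_contig)
  pb <- paste0(b$left_contig, b$path_b, b$right_contig)
  # trim to a window around the center so reads stay read-sized
  ctr <- nchar(b$left_contig) + b$center
  win <- function(s, c0) substr(s, pmax(1, c0 - 25), pmin(nchar(s), c0 + 26))
  ra <- win(pa[1], ctr[1] + 1)
  rb <- win(pb[1], ctr[1] + 1)
  sets <- list(s1 = rep(ra, 10), s2 = rep(rb, 10))
  q <- quantify_bubbles(b, sets, fx$k, max_mismatch = 1L)
  expect_equal(q$count_a_s1[1], 10L)
  expect_equal(q$count_b_s1[1], 0L)
  expect_equal(q$count_a_s2[1], 0L)
  expect_equal(q$count_b_s2[1], 10L)
  expect_equal(q$phi[1], 1)
  # other bubbles see none of these reads
  expect_equal(q$count_a_s1[2:3], c(0L, 0L))

  # a read equal to the shared left contig covers no center: counted nowhere
  lc <- substr(pa[1], 1, nchar(b$left_contig[1]))
  q2 <- quantify_bubbles(b, list(s1 = lc), fx$k)
  expect_true(all(q2$count_a_s1 == 0L & q2$count_b_s1 == 0L))

  # a read carrying a third base at the SNP ties both alleles: ambiguous
  c0 <- ctr[1] + 1L
  off <- c0 - max(1L, c0 - 25L) + 1L  # center's offset inside the trimmed read
  third <- setdiff(ACGT, c(substr(ra, off, off), substr(rb, off, off)))[1]
  amb <- ra
  substr(amb, off, off) <- third
  q3 <- quantify_bubbles(b, list(s1 = amb), fx$k, max_mismatch = 2L)
  expect_equal(q3$count_a_s1[1], 0L)
  expect_equal(q3$count_b_s1[1], 0L)
})

test_that("a heterozygous sample splits reads between the alleles", {
  fx <- make_two_allele_bubbles(k = 15L, seed = 33)
  set.seed(34)
  het <- rbind(simulate_reads(fx$genome, 15, 60, 0, 341),
               simulate_reads(fx$alt, 15, 60, 0, 342))
  q <- quantify_bubbles(fx$bubbles, list(het = het), 15L)
  # both alleles covered; each count near 15 (central Poisson mass)
  expect_true(all(q$count_a_het >= 4 & q$count_a_het <= 33))
  expect_true(all(q$count_b_het >= 4 & q$count_b_het <= 33))
  expect_true(all(q$phi < 0.5))  # one sample cannot discriminate
})

test_that("phi matches its worked values and the chi-squared oracle", {
  expect_equal(phi_score(rbind(c(10, 0), c(0, 10))), 1)
  expect_equal(phi_score(rbind(c(5, 5), c(5, 5))), 0)
  expect_equal(phi_score(rbind(c(8, 2), c(2, 8))), 0.6)  # sqrt(7.2/20)
  expect_equal(phi_score(rbind(c(8, 2), c(2, 8))),
               ora_phi(rbind(c(8, 2), c(2, 8))))
  set.seed(35)
  for (i in 1:50) {
    m <- matrix(rpois(2 * sample(2:5, 1), 5), nrow = 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(phi_score(m), ora_phi(m), tolerance = 1e-12)
  }
})

test_that("phi invariances and degenerate rules hold", {
  set.seed(36)
  for (i in 1:50) {
    m <- matrix(rpois(8, 4), nrow = 2)
    p <- phi_score(m)
    expect_gte(p, 0); expect_lte(p, 1)
    expect_equal(phi_score(m[, sample(ncol(m))]), p)      # column permutation
    expect_equal(phi_score(m[2:1, ]), p)                  # row swap
    expect_equal(phi_score(3L * m), p)                    # integer scaling
  }
  # S = 2 closed form |ad-bc|/sqrt((a+b)(c+d)(a+c)(b+d))
  for (i in 1:50) {
    m <- matrix(rpois(4, 6) + 1L, nrow = 2)
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    closed <- abs(a * d - b * c) /
      sqrt((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(phi_score(m), min(1, closed), tolerance = 1e-12)
  }
  expect_equal(phi_score(matrix(0L, 2, 3)), 0)
  expect_equal(phi_score(rbind(c(5, 5), c(0, 0))), 0)     # one allele absent
  expect_equal(phi_score(rbind(c(5, 0), c(3, 0))), 0)     # single live column
  expect_error(phi_score(rbind(c(-1, 1), c(1, 1))), "non-negative")
})

test_that("ranking is by descending phi with id tie-breaks", {
  b <- data.frame(bubble_id = 1:4, path_a = "A", path_b = "C",
                  center = 0L, left_contig = "", right_contig = "",
                  phi = c(0.2, 0.9, 0.2, 0.5), stringsAsFactors = FALSE)
  class(b) <- c("snp_bubbles", "data.frame")
  r <- rank_bubbles(b)
  expect_equal(r$bubble_id, c(2L, 4L, 1L, 3L))
  b$phi <- rep(0.3, 4)
  expect_equal(rank_bubbles(b)$bubble_id, 1:4)
  set.seed(37)
  b$phi <- runif(4)
  expect_setequal(rank_bubbles(b)$bubble_id, 1:4)
  expect_true(!is.unsorted(rev(rank_bubbles(b)$phi)))
})
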