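test_that("starter validation reflects the solid fraction", {
  set.seed(50)
  k <- 15L
  genome <- rand_dna(3000)
  solid <- solid_from_reads(genome, k)
  v <- validate_starter(substr(genome, 1001, 1080), solid)
  expect_true(v$accepted)
  expect_equal(v$solid_fraction, 1)

  v2 <- validate_starter(rand_dna(80), solid)
  expect_false(v2$accepted)
  expect_lt(v2$solid_fraction, 0.1)

  # one substitution knocks out min(k, windows) of the windows
  st <- substr(genome, 1001, 1080)
  mid <- 40L
  substr(st, mid, mid) <- setdiff(ACGT, substr(st, mid, mid))[1]
  v3 <- validate_starter(st, solid)
  nwin <- nchar(st) - k + 1L
  expect_equal(v3$solid_fraction, 1 - min(k, nwin) / nwin)

  expect_error(validate_starter("ACGT", solid), "shorter than k")
})

test_that("linear extension reconstructs a repeat-free genome from a starter", {
  set.seed(51)
  k <- 15L
  genome <- rand_dna(2000)
  g <- graph_from_reads(genome, k)
  starter <- substr(genome, 900, 980)
  ext <- extend_linear(g, starter)
  expect_equal(paste0(ext$left, starter, ext$right), genome)
  expect_equal(extend_linear(g, starter, max_len = 0L),
               list(left = "", right = ""))
  # a non-solid terminal k-mer warns and yields no extension on that side
  bad <- paste0(rand_dna(k), substr(genome, 900, 980))
  expect_warning(extl <- extend_linear(g, bad), "not solid")
  expect_equal(extl$left, "")
})

test_that("extension stops exactly at a planted SNP fork", {
  set.seed(52)
  k <- 15L
  genome <- rand_dna(4000)
  sd <- 521
  repeat {  # need room upstream of the SNP for the starter
    pl <- plant_snps(genome, 1L, k, seed = sd)
    if (pl$truth$position >= 600) break
    sd <- sd + 1L
  }
  pos <- pl$truth$position  # 0-based
  g <- graph_from_reads(c(genome, pl$alt_genome), k)
  starter <- substr(genome, pos - 400, pos - 300)  # upstream of the SNP
  ext <- extend_linear(g, starter)
  asm <- paste0(ext$left, starter, ext$right)
  # right extension halts at the fork opening the bubble: the assembly
  # covers everything up to, but not including, the SNP base
  expect_equal(asm, substr(genome, 1, pos))
})

test_that("the neighborhood graph shows the SNP bubble with per-set coverage", {
  set.seed(53)
  k <- 15L
  genome <- rand_dna(4000)
  sd <- 531
  repeat {
    pl <- plant_snps(genome, 1L, k, seed = sd)
    if (pl$truth$position >= 600) break
    sd <- sd + 1L
  }
  pos <- pl$truth$position
  spec <- kmer_spec(k)
  setA <- simulate_reads(genome, 10, 60, 0, 532, "A")
  setB <- simulate_reads(pl$alt_genome, 10, 60, 0, 533, "B")
  tabA <- count_kmers(setA, spec)
  tabB <- count_kmers(setB, spec)
  tab <- count_kmers(list(setA, setB), spec)
  g <- dbg_graph(build_solid_set(tab, 2L))
  starter <- substr(genome, pos - 200, pos - 100)
  expect_true(validate_starter(starter, g$solid)$accepted)
  nb <- build_neighborhood_graph(g, starter, list(A = tabA, B = tabB))
  expect_equal(sum(nb$nodes$is_starter), 1L)
  # a bubble: two nodes sharing predecessor and successor
  ek <- paste(nb$edges$from, nb$edges$to)
  pair_found <- FALSE
  for (i in seq_len(nrow(nb$nodes))) {
    for (j in seq_len(nrow(nb$nodes))) {
      if (i >= j) next
      pi <- nb$edges$from[nb$edges$to == i]
      pj <- nb$edges$from[nb$edges$to == j]
      si <- nb$edges$to[nb$edges$from == i]
      sj <- nb$edges$to[nb$edges$from == j]
      if (length(intersect(pi, pj)) && length(intersect(si, sj))) {
        # allele nodes: haplotype-specific coverage separates the sets
        cvA <- nb$nodes[c(i, j), "cov_A"]
        cvB <- nb$nodes[c(i, j), "cov_B"]
        if ((cvA[1] > 2 && cvB[1] < 0.5 && cvB[2] > 2 && cvA[2] < 0.5) ||
            (cvA[2] > 2 && cvB[2] < 0.5 && cvB[1] > 2 && cvA[1] < 0.5))
          pair_found <- TRUE
      }
    }
  }
  expect_true(pair_found)
  # every edge is a k-1 overlap consistent with orientation
  for (e in seq_len(nrow(nb$edges))) {
    sfrom <- nb$nodes$seq[nb$edges$from[e]]
    sto <- nb$nodes$seq[nb$edges$to[e]]
    expect_equal(substr(sfrom, nchar(sfrom) - k + 2, nchar(sfrom)),
                 substr(sto, 1, k - 1))
  }
})

test_that("graph JSON round-trips and matches the shipped schema", {
  set.seed(54)
  k <- 15L
  genome <- rand_dna(1500)
  spec <- kmer_spec(k)
  tab <- count_kmers(genome, spec)
  g <- dbg_graph(build_solid_set(tab, 1L))
  nb <- build_neighborhood_graph(g, substr(genome, 700, 760), list(x = tab))
  f <- tempfile(fileext = ".json")
  write_graph_json(nb, f)
  doc <- jsonlite::read_json(f)

  schema <- jsonlite::read_json(system.file("extdata",
                                            "neighborhood-graph-schema.json",
                                            package = "dbgvar"))
  expect_setequal(intersect(names(doc), unlist(schema$required)),
                  unlist(schema$required))
  for (nd in doc$nodes) {
    expect_true(all(unlist(schema$properties$nodes$items$required) %in%
                      names(nd)))
    expect_match(nd$seq, "^[ACGTN]+$")
  }
  for (e in doc$edges) expect_true(all(c("from", "to") %in% names(e)))

  back <- read_graph_json(f)
  expect_equal(back$nodes, nb$nodes)
  expect_equal(back$edges, nb$edges)
  expect_equal(back$k, nb$k)
  expect_equal(back$starter, nb$starter)
})

test_that("graph content is independent of read order", {
  set.seed(55)
  k <- 15L
  genome <- rand_dna(3000)
  pl <- plant_snps(genome, 1L, k, seed = 551)
  reads <- c(simulate_reads(genome, 8, 60, 0, 552)$seq,
             simulate_reads(pl$alt_genome, 8, 60, 0, 553)$seq)
  spec <- kmer_spec(k)
  starter <- substr(genome, 1400, 1480)
  make <- function(rs) {
    tab <- count_kmers(list(rs), spec)
    g <- dbg_graph(build_solid_set(tab, 2L))
    build_neighborhood_graph(g, starter, list(all = tab))
  }
  nb1 <- make(reads)
  nb2 <- make(rev(reads))
  expect_equal(nb1$nodes, nb2$nodes)
  expect_equal(nb1$edges, nb2$edges)
})
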