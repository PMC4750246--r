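# Independent reference implementations used as oracles. Everything here
# is plain string-level R, deliberately sharing no code with the
# package's C++ kernel.

ACGT <- c("A", "C", "G", "T")

ora_rc <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

ora_rc_vec <- function(x) vapply(x, ora_rc, character(1), USE.NAMES = FALSE)

ora_canon <- function(s) {
  r <- ora_rc(s)
  if (s <= r) s else r
}

ora_canon_vec <- function(x) vapply(x, ora_canon, character(1), USE.NAMES = FALSE)

ora_windows <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

# canonical k-mers with count >= c, by plain table() counting
ora_solid <- function(reads, k, c = 1L) {
  wins <- unlist(lapply(reads, ora_windows, k = k))
  wins <- wins[!grepl("[^ACGT]", wins)]
  tab <- table(ora_canon_vec(wins))
  sort(names(tab)[tab >= c])
}

ora_ham <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])

rand_dna <- function(n) paste(sample(ACGT, n, replace = TRUE), collapse = "")

# n random substitutions, no placement constraints (for oracle tests at
# small k where window uniqueness is unattainable)
mutate_positions <- function(genome, n) {
  v <- strsplit(genome, "")[[1]]
  for (p in sample(seq_along(v), n)) v[p] <- sample(setdiff(ACGT, v[p]), 1)
  paste(v, collapse = "")
}

# full lookup tables of reverse complement / canonical form over all
# 4^k k-mers; only sensible for the small k the oracles run at
.kmer_tab_cache <- new.env(parent = emptyenv())
kmer_tables <- function(k) {
  key <- as.character(k)
  if (!is.null(.kmer_tab_cache[[key]])) return(.kmer_tab_cache[[key]])
  stopifnot(k <= 8)
  all_k <- do.call(paste0, expand.grid(rep(list(ACGT), k),
                                       stringsAsFactors = FALSE))
  rc <- ora_rc_vec(all_k)
  names(rc) <- all_k
  canon <- ifelse(all_k <= rc, all_k, rc)
  names(canon) <- all_k
  .kmer_tab_cache[[key]] <- list(rc = rc, canon = canon)
  .kmer_tab_cache[[key]]
}

# ---- bubble oracle -----------------------------------------------------

# reverse-complement-canonical serialization of an unordered path pair
ora_pair_key <- function(p, q) {
  if (q < p) { t <- p; p <- q; q <- t }
  rp <- ora_rc(p); rq <- ora_rc(q)
  if (rq < rp) { t <- rp; rp <- rq; rq <- t }
  if (rp < p || (rp == p && rq < q)) paste(rp, rq, sep = "|")
  else paste(p, q, sep = "|")
}

# exhaustive enumeration: every (2k-1)-string whose k-windows are all
# canonical-solid, paired with the strings differing only at the center,
# keeping vertex-disjoint pairs (all 2k windows canonically distinct)
oracle_bubbles <- function(solid, k) {
  tabs <- kmer_tables(k)
  frontier <- unique(c(solid, unname(tabs$rc[solid])))
  for (step in seq_len(k - 1)) {
    cand <- as.vector(outer(frontier, ACGT, paste0))
    last <- substring(cand, nchar(cand) - k + 1, nchar(cand))
    frontier <- cand[unname(tabs$canon[last]) %in% solid]
  }
  if (length(frontier) == 0) return(character(0))
  grp <- paste0(substr(frontier, 1, k - 1), "#",
                substr(frontier, k + 1, 2 * k - 1))
  keys <- character(0)
  for (g in unique(grp[duplicated(grp)])) {
    strs <- sort(unique(frontier[grp == g]))
    if (length(strs) < 2) next
    for (i in seq_len(length(strs) - 1)) {
      for (j in (i + 1):length(strs)) {
        wins <- unname(tabs$canon[c(ora_windows(strs[i], k),
                                    ora_windows(strs[j], k))])
        if (anyDuplicated(wins)) next
        keys <- c(keys, ora_pair_key(strs[i], strs[j]))
      }
    }
  }
  sort(unique(keys))
}

# ---- dBG neighbor oracle ----------------------------------------------

oracle_successors <- function(solid, node, k) {
  oriented <- unique(c(solid, ora_rc_vec(solid)))
  sort(oriented[substr(oriented, 1, k - 1) == substr(node, 2, k)])
}

oracle_predecessors <- function(solid, node, k) {
  oriented <- unique(c(solid, ora_rc_vec(solid)))
  sort(oriented[substr(oriented, 2, k) == substr(node, 1, k - 1)])
}

# TRUE when the genome's k-mer path has no folds: every window's only
# neighbor (per the string-level oracle) is the adjacent genome window
genome_is_clean_unitig <- function(genome, k) {
  wins <- ora_windows(genome, k)
  solidv <- unique(ora_canon_vec(wins))
  if (length(solidv) < length(wins)) return(FALSE)
  n <- length(wins)
  for (i in seq_len(n)) {
    succ <- oracle_successors(solidv, wins[i], k)
    want <- if (i < n) wins[i + 1] else character(0)
    if (!identical(succ, want)) return(FALSE)
    pred <- oracle_predecessors(solidv, wins[i], k)
    want_p <- if (i > 1) wins[i - 1] else character(0)
    if (!identical(pred, want_p)) return(FALSE)
  }
  TRUE
}

# ---- map-back oracle ---------------------------------------------------

ora_map_one_strand <- function(read, target, center0, k, mm) {
  lr <- nchar(read); lt <- nchar(target)
  rv <- strsplit(read, "")[[1]]; tv <- strsplit(target, "")[[1]]
  for (off in (-(lr - 1)):(lt - 1)) {
    lo <- max(0L, off); hi <- min(lt, off + lr)   # target coords, half-open
    if (hi - lo < k) next
    if (center0 < lo || center0 >= hi) next
    m <- tv[(lo + 1):hi] == rv[(lo - off + 1):(hi - off)]
    if (sum(!m) > mm) next
    r <- rle(m)
    if (any(r$values & r$lengths >= k)) return(TRUE)  # exact k-mer anchor
  }
  FALSE
}

oracle_map_read <- function(read, target, center0, k, mm) {
  ora_map_one_strand(read, target, center0, k, mm) ||
    ora_map_one_strand(ora_rc(read), target, center0, k, mm)
}

# ---- inversion oracle --------------------------------------------------

ora_event_key <- function(a, u, v, b) {
  ap <- ora_rc(a); up <- ora_rc(u); vp <- ora_rc(v); bp <- ora_rc(b)
  forms <- list(c(a, u, v, b), c(a, vp, up, b), c(bp, vp, up, ap),
                c(bp, u, v, ap))
  forms <- c(forms, lapply(forms, function(f) f[c(3, 4, 1, 2)]))
  sort(vapply(forms, paste, character(1), collapse = "|"))[1]
}

ora_event_distinct <- function(a, u, v, b) {
  cn <- ora_canon_vec(c(a, u, v, b))
  for (x in 1:3) for (y in (x + 1):4) {
    if (x == 2 && y == 3) next  # u/v exemption for palindromic events
    if (cn[x] == cn[y]) return(FALSE)
  }
  TRUE
}

# all 4-tuples of solid k-mers satisfying the four-breakpoint-word
# condition, pruned by the a-fork requirement
oracle_inversions <- function(solid, k, min_fork_distance = 3L) {
  tabs <- kmer_tables(k)
  canon <- tabs$canon
  rc <- tabs$rc
  oriented <- unique(c(solid, unname(rc[solid])))
  word_all_solid <- function(words) {
    ok <- rep(TRUE, length(words))
    for (s in seq_len(k + 1)) {
      win <- substring(words, s, s + k - 1L)
      ok <- ok & (unname(canon[win]) %in% solid)
    }
    ok
  }
  is_fork <- vapply(oriented, function(a) {
    sum(unname(canon[paste0(substr(a, 2, k), ACGT)]) %in% solid) >= 2L
  }, logical(1), USE.NAMES = FALSE)
  keys <- character(0)
  for (a in oriented[is_fork]) {
    U <- oriented[word_all_solid(paste0(a, oriented))]
    if (length(U) == 0) next
    ub_mask <- lapply(U, function(u) {
      word_all_solid(paste0(unname(rc[u]), oriented))
    })
    names(ub_mask) <- U
    for (vprime in U) {
      v <- unname(rc[vprime])
      vb_mask <- word_all_solid(paste0(v, oriented))
      for (u in U) {
        if (ora_ham(u, vprime) < min_fork_distance) next
        if (min_fork_distance > 0 &&
            substr(u, 1, 1) == substr(vprime, 1, 1)) next
        a_prime0 <- chartr("ACGT", "TGCA", substr(a, k, k))
        for (b in oriented[vb_mask & ub_mask[[u]]]) {
          if (min_fork_distance > 0 && substr(b, 1, 1) == a_prime0) next
          if (!ora_event_distinct(a, u, v, b)) next
          keys <- c(keys, ora_event_key(a, u, v, b))
        }
      }
    }
  }
  sort(unique(keys))
}

# ---- phi oracle --------------------------------------------------------

ora_phi <- function(counts) {
  N <- sum(counts)
  keep <- colSums(counts) > 0
  m <- counts[, keep, drop = FALSE]
  chi2 <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$statistic)
  min(1, max(0, sqrt(unname(chi2) / N)))
}

# ---- fixtures ----------------------------------------------------------

fig2_graph <- function() {
  spec <- suppressWarnings(kmer_spec(4L))
  tab <- count_kmers(list(c("CTGACCT", "CTGTCCT")), spec)
  dbg_graph(build_solid_set(tab, 1L))
}

solid_from_reads <- function(reads, k, c = 1L) {
  build_solid_set(count_kmers(list(reads), suppressWarnings(kmer_spec(k))), c)
}

graph_from_reads <- function(reads, k, c = 1L) {
  dbg_graph(solid_from_reads(reads, k, c))
}
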