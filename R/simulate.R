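#' Random genome sequence
#'
#' I.i.d. bases with `P(G) + P(C) = gc`, split evenly within each pair;
#' deterministic for a given seed.
#'
#' @param length genome length in bases (at least 1).
#' @param gc GC fraction, strictly between 0 and 1.
#' @param seed integer seed (optional; `NULL` uses the current RNG
#'   state).
#' @return a single DNA string.
#' @export
random_genome <- function(length, gc = 0.5, seed = NULL) {
  if (length < 1) stop("length must be >= 1")
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
}

#' Plant isolated SNPs in a genome
#'
#' Substitutes `n` bases at positions at least 2k apart and 2k from the
#' genome ends, then verifies that every k-mer of each affected
#' (2k-1)-window is unique across the two genomes (so each planted SNP
#' is guaranteed to form exactly one clean bubble at full coverage);
#' positions are resampled as a whole, up to `max_rounds` times, until
#' the uniqueness holds.
#'
#' @param genome reference genome string.
#' @param n number of SNPs to plant.
#' @param k the k-mer length the callers will use.
#' @param seed integer seed.
#' @param max_rounds resampling budget before a capacity error.
#' @return list with `alt_genome` and `truth`, a data.frame with
#'   columns `kind`, `position` (0-based), `ref`, `alt`, `ref_window`,
#'   `alt_window`.
#' @export
plant_snps <- function(genome, n, k, seed = NULL, max_rounds = 50L) {
  L <- nchar(genome)
  if (n == 0L) {
    return(list(alt_genome = genome,
                truth = data.frame(kind = character(0), position = integer(0),
                                   ref = character(0), alt = character(0),
                                   ref_window = character(0),
                                   alt_window = character(0),
                                   stringsAsFactors = FALSE)))
  }
  lo <- 2L * k
  hi <- L - 1L - 2L * k
  if (hi - lo + 1L < n * 2L * k)
    stop("capacity error: genome too short for ", n, " SNPs at separation 2k")
  bases <- c("A", "C", "G", "T")
  gvec <- strsplit(genome, "", fixed = TRUE)[[1]]
  with_seed(seed, {
    for (round in seq_len(max_rounds)) {
      pos <- sort(sample(lo:hi, n))
      if (n > 1L && any(diff(pos) < 2L * k)) next
      pos1 <- pos + 1L  # 1-based
      ref <- gvec[pos1]
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1),
                    USE.NAMES = FALSE)
      avec <- gvec
      avec[pos1] <- alt
      alt_genome <- paste(avec, collapse = "")
      # every k-mer of every affected window must be unique in the pair
      tab <- count_kmers(list(genome, alt_genome),
                         suppressWarnings(kmer_spec(k)))
      ok <- TRUE
      win_ref <- substring(genome, pos1 - (k - 1L), pos1 + (k - 1L))
      win_alt <- substring(alt_genome, pos1 - (k - 1L), pos1 + (k - 1L))
      for (w in c(win_ref, win_alt)) {
        st <- seq_len(k)
        if (any(kmer_count(tab, substring(w, st, st + k - 1L)) != 1L)) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      truth <- data.frame(kind = "snp", position = pos, ref = ref, alt = alt,
                          ref_window = win_ref, alt_window = win_alt,
                          stringsAsFactors = FALSE)
      return(list(alt_genome = alt_genome, truth = truth))
    }
    stop("capacity error: could not place ", n,
         " SNPs with unique windows after ", max_rounds, " rounds")
  })
}

#' Plant inversions in a genome
#'
#' Reverse-complements `n` non-overlapping segments of length in
#' `[min_len, max_len]`, separated by at least 2k and 2k from the ends.
#' Each event's flanks a, b and segment terminals u, v are resampled
#' (by moving the segment) until its two k-forks genuinely branch
#' (`u[1] != v'[1]` and `v[k] != u'[k]`), `Hamming(u, v') >= 3` clears
#' the caller's default repeat guard, and every junction-spanning k-mer
#' of the four breakpoint words is unique across the two genomes. These
#' conditions make full recovery at full coverage a construction
#' guarantee rather than a hope.
#'
#' @param genome reference genome string.
#' @param n number of inversions.
#' @param min_len,max_len segment length bounds (`min_len >= 2k`).
#' @param k the k-mer length the caller will use.
#' @param seed integer seed.
#' @param max_rounds resampling budget before a capacity error.
#' @return list with `alt_genome` and `truth`, a data.frame with
#'   columns `kind`, `start`, `end` (0-based half-open), `a`, `u`, `v`,
#'   `b` (canonical event form) and the four breakpoint sequences.
#' @export
plant_inversions <- function(genome, n, min_len, max_len, k, seed = NULL,
                             max_rounds = 100L) {
  L <- nchar(genome)
  empty_truth <- data.frame(kind = character(0), start = integer(0),
                            end = integer(0), a = character(0),
                            u = character(0), v = character(0),
                            b = character(0), bp_au = character(0),
                            bp_vb = character(0), bp_avp = character(0),
                            bp_upb = character(0), stringsAsFactors = FALSE)
  if (n == 0L) return(list(alt_genome = genome, truth = empty_truth))
  if (min_len < 2L * k) stop("min_len must be >= 2k")
  with_seed(seed, {
    seg_ok <- function(start, len) {
      # local branch conditions at the candidate segment [start, start+len)
      seg <- substr(genome, start + 1L, start + len)
      u <- substr(seg, 1L, k)
      v <- substr(seg, len - k + 1L, len)
      vp <- reverse_complement(v)
      up <- reverse_complement(u)
      if (substr(u, 1L, 1L) == substr(vp, 1L, 1L)) return(FALSE)
      if (substr(v, k, k) == substr(up, k, k)) return(FALSE)
      # no breakpoint micro-homology: if the base left of the segment
      # complements the base right of it, a second, shifted copy of the
      # motif exists in the data and the breakpoint is ambiguous
      left_base <- substr(genome, start, start)        # 1-based = 0-based start-1
      right_base <- substr(genome, start + len + 1L, start + len + 1L)
      if (left_base == chartr("ACGT", "TGCA", right_base)) return(FALSE)
      ham <- sum(strsplit(u, "")[[1]] != strsplit(vp, "")[[1]])
      ham >= 3L
    }
    for (round in seq_len(max_rounds)) {
      # place segments left to right, nudging each until its forks branch
      lens <- sample(min_len:max_len, n, replace = TRUE)
      if (L - 4L * k - sum(lens) - (n - 1L) * 2L * k < n)
        stop("capacity error: genome too short for the inversions")
      starts <- integer(n)
      cur <- 2L * k
      placed <- TRUE
      for (i in seq_len(n)) {
        reserve <- if (i < n) sum(lens[(i + 1L):n] + 2L * k) else 0L
        hi <- L - 2L * k - reserve - lens[i]
        if (hi < cur) { placed <- FALSE; break }
        # keep draws near the cursor so later segments still fit
        lim <- min(hi, cur + max(1L, (hi - cur) %/% (n - i + 1L)))
        found <- FALSE
        for (try in 1:100) {
          cand <- if (lim > cur) sample(cur:lim, 1L) else cur
          if (seg_ok(cand, lens[i])) {
            starts[i] <- cand
            cur <- cand + lens[i] + 2L * k
            found <- TRUE
            break
          }
        }
        if (!found) { placed <- FALSE; break }
      }
      if (!placed) next
      ends <- starts + lens  # half-open, 0-based
      seg <- substring(genome, starts + 1L, ends)
      a <- substring(genome, starts - k + 1L, starts)
      b <- substring(genome, ends + 1L, ends + k)
      u <- substr(seg, 1L, k)
      v <- substring(seg, lens - k + 1L, lens)
      vp <- reverse_complement(v)
      up <- reverse_complement(u)
      # alternative genome with the segments reverse-complemented
      pieces <- character(0)
      prev <- 0L
      segrc <- reverse_complement(seg)
      for (i in seq_len(n)) {
        pieces <- c(pieces, substring(genome, prev + 1L, starts[i]), segrc[i])
        prev <- ends[i]
      }
      pieces <- c(pieces, substring(genome, prev + 1L, L))
      alt_genome <- paste(pieces, collapse = "")
      # junction-spanning k-mers of each breakpoint word unique in the pair
      tab <- count_kmers(list(genome, alt_genome),
                         suppressWarnings(kmer_spec(k)))
      words <- c(paste0(a, u), paste0(v, b), paste0(a, vp), paste0(up, b))
      ok <- TRUE
      for (w in words) {
        st <- 2:k  # windows crossing the junction
        if (any(kmer_count(tab, substring(w, st, st + k - 1L)) != 1L)) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      canon <- t(mapply(function(a, u, v, b) canonicalize_event(a, u, v, b),
                        a, u, v, b))
      truth <- data.frame(kind = "inversion", start = starts, end = ends,
                          a = canon[, 1], u = canon[, 2], v = canon[, 3],
                          b = canon[, 4],
                          bp_au = paste0(canon[, 1], canon[, 2]),
                          bp_vb = paste0(canon[, 3], canon[, 4]),
                          bp_avp = paste0(canon[, 1],
                                          reverse_complement(canon[, 3])),
                          bp_upb = paste0(reverse_complement(canon[, 2]),
                                          canon[, 4]),
                          stringsAsFactors = FALSE)
      return(list(alt_genome = alt_genome, truth = truth))
    }
    stop("capacity error: could not place ", n, " inversions after ",
         max_rounds, " rounds")
  })
}

#' Simulate substitution-error short reads
#'
#' `N = ceiling(coverage * L / read_len)` reads with uniform start
#' positions, a fair strand coin, and i.i.d. per-base substitutions at
#' `err_rate` to a uniformly chosen different base. Qualities are a
#' constant `I`. Substitution-only errors are deliberate: the callers
#' in this package model substitution-induced graph motifs, not indels.
#'
#' @param genome template genome string.
#' @param coverage fold coverage (> 0).
#' @param read_len read length (at most the genome length).
#' @param err_rate per-base substitution probability in `[0, 1)`.
#' @param seed integer seed.
#' @param set_name prefix for read identifiers.
#' @return a record data.frame (`id`, `seq`, `qual`) suitable for
#'   [write_fastq()] and every counting function.
#' @export
simulate_reads <- function(genome, coverage, read_len, err_rate = 0,
                           seed = NULL, set_name = "reads") {
  L <- nchar(genome)
  if (read_len > L) stop("read_len exceeds genome length")
  if (coverage <= 0) stop("coverage must be > 0")
  if (err_rate < 0 || err_rate >= 1) stop("err_rate must be in [0, 1)")
  with_seed(seed, {
    N <- ceiling(coverage * L / read_len)
    starts <- sample.int(L - read_len + 1L, N, replace = TRUE)
    seqs <- substring(genome, starts, starts + read_len - 1L)
    rev <- stats::runif(N) < 0.5
    if (any(rev)) seqs[rev] <- cpp_revcomp(seqs[rev])
    if (err_rate > 0) seqs <- cpp_mutate_seqs(seqs, err_rate)
    data.frame(id = paste0(set_name, "_", seq_len(N)), seq = seqs,
               qual = strrep("I", read_len), stringsAsFactors = FALSE)
  })
}

# reverse-complement-canonical serialization of a bubble path pair
bubble_pair_key <- function(p, q) {
  mapply(function(p, q) {
    if (q < p) { tmp <- p; p <- q; q <- tmp }
    rp <- cpp_revcomp(p)
    rq <- cpp_revcomp(q)
    if (rq < rp) { tmp <- rp; rp <- rq; rq <- tmp }
    if (rp < p || (rp == p && rq < q)) paste(rp, rq, sep = "|")
    else paste(p, q, sep = "|")
  }, p, q, USE.NAMES = FALSE)
}

#' Score SNP predictions against planted truth
#'
#' A truth record is recovered when some predicted bubble's path pair
#' equals its (ref window, alt window) pair up to reverse-complement
#' canonicalization. Predictions are deduplicated before matching, and
#' each prediction can match at most one truth record. Recall is
#' recovered / truth; precision is matched / predictions, defined as 1
#' for an empty prediction set.
#'
#' @param predicted a [find_snp_bubbles()] result.
#' @param truth the truth data.frame from [plant_snps()].
#' @param k the k-mer length (unused placeholder kept for symmetry with
#'   callers that only know k; pair matching is length-agnostic).
#' @return list with `recall`, `precision` and `matched_ids` (bubble
#'   ids of the matching predictions).
#' @export
evaluate_snps <- function(predicted, truth, k = NULL) {
  truth_keys <- unique(bubble_pair_key(truth$ref_window, truth$alt_window))
  if (nrow(predicted) == 0L) {
    return(list(recall = if (length(truth_keys) == 0L) 1 else 0,
                precision = 1, matched_ids = integer(0)))
  }
  pred_keys <- bubble_pair_key(predicted$path_a, predicted$path_b)
  keep <- !duplicated(pred_keys)
  recall <- if (length(truth_keys) == 0L) 1
            else mean(truth_keys %in% pred_keys)
  precision <- mean(pred_keys[keep] %in% truth_keys)
  list(recall = recall, precision = precision,
       matched_ids = predicted$bubble_id[pred_keys %in% truth_keys])
}

#' Score inversion predictions against planted truth
#'
#' Events match by equality of their canonical (a, u, v, b)
#' representative, which is invariant over the four equivalent tuple
#' forms. Metrics follow [evaluate_snps()].
#'
#' @param predicted a [find_inversions()] result.
#' @param truth the truth data.frame from [plant_inversions()].
#' @return list with `recall` and `precision`.
#' @export
evaluate_inversions <- function(predicted, truth) {
  ev_key <- function(a, u, v, b) {
    if (length(a) == 0L) return(character(0))
    apply(t(mapply(function(a, u, v, b) canonicalize_event(a, u, v, b),
                   a, u, v, b)), 1L, paste, collapse = "|")
  }
  truth_keys <- unique(ev_key(truth$a, truth$u, truth$v, truth$b))
  if (nrow(predicted) == 0L) {
    return(list(recall = if (length(truth_keys) == 0L) 1 else 0,
                precision = 1))
  }
  pred_keys <- ev_key(predicted$a, predicted$u, predicted$v, predicted$b)
  keep <- !duplicated(pred_keys)
  recall <- if (length(truth_keys) == 0L) 1 else mean(truth_keys %in% pred_keys)
  precision <- mean(pred_keys[keep] %in% truth_keys)
  list(recall = recall, precision = precision)
}
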