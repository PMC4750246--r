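#' Detect inversion breakpoints from the de Bruijn graph
#'
#' An inverted segment I between flanks a and b (aIb in one genome,
#' aI'b in the other, with ' the reverse complement) leaves four 2k
#' breakpoint words in the joint k-mer content: au, vb, av', u'b, where
#' u and v are the first and last k-mers of I. The motif is two k-forks
#' joining a, u, v and b in a pseudo-cycle. The search roots at every
#' solid k-mer with at least two successors, enumerates its length-k
#' solid extensions (abandoning forks whose partial-path count exceeds
#' `max_paths`, which bounds blowup in repeat regions), pairs extensions
#' into (u, v') candidates, and completes each pair with the k-mers b
#' for which both vb and u'b are fully solid.
#'
#' Repeats and palindromes mimic the motif, so a repeat guard (active
#' whenever `min_fork_distance > 0`) suppresses candidates with
#' `Hamming(u, v') < min_fork_distance` and candidates whose junctions
#' do not genuinely branch at their first base (`u[1] = v'[1]` or
#' `b[1] = a'[1]`) - the latter catches folds through chance
#' palindromes and breakpoint micro-homology, where the breakpoint
#' position is ambiguous. A detected event with u equal to v' is
#' flagged palindromic (only reachable with `min_fork_distance = 0`,
#' which disables the guard). This local-dissimilarity guard is this
#' package's interpretation of repeat filtering; the upstream tools use
#' their own local-complexity test.
#'
#' @param g a [dbg_graph()].
#' @param max_paths abandon a fork whose extension enumeration exceeds
#'   this many partial paths (default 100).
#' @param min_fork_distance minimum Hamming distance between u and v'
#'   (default 3; 0 disables the repeat guard).
#' @return a data.frame of class `inversion_events` with columns
#'   `event_id`, `a`, `u`, `v`, `b`, `palindromic` and the four
#'   breakpoint sequences `bp_au`, `bp_vb`, `bp_avp`, `bp_upb` (each of
#'   length 2k). Events are canonical representatives, deduplicated and
#'   sorted.
#' @export
find_inversions <- function(g, max_paths = 100L, min_fork_distance = 3L) {
  stopifnot(inherits(g, "dbg"))
  df <- cpp_find_inversions(g$solid$ptr, as.integer(max_paths),
                            as.integer(min_fork_distance))
  out <- data.frame(
    event_id = seq_len(nrow(df)),
    a = df$a, u = df$u, v = df$v, b = df$b,
    palindromic = df$palindromic,
    stringsAsFactors = FALSE)
  out$bp_au <- paste0(out$a, out$u)
  out$bp_vb <- paste0(out$v, out$b)
  out$bp_avp <- paste0(out$a, reverse_complement(out$v))
  out$bp_upb <- paste0(reverse_complement(out$u), out$b)
  if (nrow(out) == 0L) {
    out$bp_au <- out$bp_vb <- out$bp_avp <- out$bp_upb <- character(0)
  }
  class(out) <- c("inversion_events", "data.frame")
  attr(out, "k") <- g$k
  out
}

#' Canonical representative of an inversion event
#'
#' The breakpoint word set `{au, vb, av', u'b}` is unchanged (modulo
#' reverse complement) by exchanging `u <-> v'` together with
#' `u' <-> v`, by reverse-complementing the whole event, and by
#' swapping the two halves `(a,u,v,b) -> (v,b,a,u)`; the eight
#' resulting descriptions denote the same event, and the
#' representative is the one with the lexicographically smallest
#' `a|u|v|b` serialization. The map is idempotent, so events from a
#' genome and from its reverse complement canonicalize identically.
#'
#' @param a,u,v,b the four k-mers of the event.
#' @return a named character vector with elements `a`, `u`, `v`, `b`.
#' @export
canonicalize_event <- function(a, u, v, b) {
  e <- cpp_canonicalize_event(a, u, v, b)
  stats::setNames(e, c("a", "u", "v", "b"))
}

#' Write / read inversion events as FASTA
#'
#' Four records per event, one per breakpoint sequence, with headers
#' `>INV_<id>|au|palindromic=<0/1>` (labels `au`, `vb`, `avp`, `upb`;
#' `p` stands for the prime / reverse complement).
#'
#' @param events a [find_inversions()] result.
#' @param path file path.
#' @return the number of records written, invisibly.
#' @export
write_inversions <- function(events, path) {
  stopifnot(inherits(events, "inversion_events"))
  if (nrow(events) == 0L) {
    file.create(path)
    return(invisible(0L))
  }
  labels <- c("au", "vb", "avp", "upb")
  cols <- c("bp_au", "bp_vb", "bp_avp", "bp_upb")
  ids <- character(0)
  seqs <- character(0)
  for (i in seq_len(nrow(events))) {
    for (j in seq_along(labels)) {
      ids <- c(ids, sprintf("INV_%d|%s|palindromic=%d", events$event_id[i],
                            labels[j], as.integer(events$palindromic[i])))
      seqs <- c(seqs, events[[cols[j]]][i])
    }
  }
  write_fasta(data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE), path)
}

#' @rdname write_inversions
#' @param k the k-mer length used when the file was produced.
#' @return `read_inversions` returns the reconstructed
#'   `inversion_events` data.frame.
#' @export
read_inversions <- function(path, k) {
  empty <- data.frame(event_id = integer(0), a = character(0),
                      u = character(0), v = character(0), b = character(0),
                      palindromic = logical(0), bp_au = character(0),
                      bp_vb = character(0), bp_avp = character(0),
                      bp_upb = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("inversion_events", "data.frame")
  attr(empty, "k") <- as.integer(k)
  if (file.size(path) == 0L) return(empty)
  rec <- read_sequences(path)
  parts <- strsplit(rec$id, "|", fixed = TRUE)
  lab <- vapply(parts, `[`, character(1), 2L)
  idx_au <- which(lab == "au")
  n <- length(idx_au)
  if (n == 0L) return(empty)
  out <- empty[rep(1L, 0L), ]
  for (j in seq_len(n)) {
    i <- idx_au[j]
    au <- rec$seq[i]
    vb <- rec$seq[i + 1L]  # record order within an event is au, vb, avp, upb
    a <- substr(au, 1L, k)
    u <- substr(au, k + 1L, 2L * k)
    v <- substr(vb, 1L, k)
    b <- substr(vb, k + 1L, 2L * k)
    row <- data.frame(
      event_id = as.integer(sub("^INV_", "", parts[[i]][1L])),
      a = a, u = u, v = v, b = b,
      palindromic = sub("^palindromic=", "", parts[[i]][3L]) == "1",
      bp_au = au, bp_vb = vb,
      bp_avp = paste0(a, reverse_complement(v)),
      bp_upb = paste0(reverse_complement(u), b),
      stringsAsFactors = FALSE)
    out <- rbind(out, row)
  }
  class(out) <- c("inversion_events", "data.frame")
  attr(out, "k") <- as.integer(k)
  out
}
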