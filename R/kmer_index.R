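#' k-mer specification
#'
#' Fixes the word length `k` used by every downstream structure. All
#' membership is on canonical k-mers (the lexicographic minimum of a
#' word and its reverse complement), so the graph is strand-neutral.
#'
#' @param k k-mer length in bases, between 3 and 31 (a k-mer is packed
#'   two bits per base into one machine word). Odd `k` is recommended:
#'   even `k` admits self-reverse-complement words and triggers a
#'   warning.
#' @return an object of class `kmer_spec`.
#' @export
kmer_spec <- function(k = 31L) {
  k <- as.integer(k)
  if (is.na(k) || k < 3L || k > 31L) stop("k must be an integer in [3, 31]")
  if (k %% 2L == 0L)
    warning("even k admits self-reverse-complement k-mers; odd k is recommended")
  structure(list(k = k), class = "kmer_spec")
}

#' @export
print.kmer_spec <- function(x, ...) {
  cat("k-mer spec: k =", x$k, "(canonical)\n")
  invisible(x)
}

#' Reverse complement of DNA sequences
#'
#' @param seq character vector of sequences over `A`, `C`, `G`, `T`.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("CTGA")  # "TCAG"
#' @export
reverse_complement <- function(seq) {
  cpp_revcomp(as.character(seq))
}

#' Canonical form of k-mers
#'
#' The lexicographic minimum of a k-mer and its reverse complement;
#' idempotent and strand-neutral.
#'
#' @param kmer character vector of k-mers (ACGT only).
#' @return character vector of canonical k-mers.
#' @export
canonical_kmer <- function(kmer) {
  cpp_canonical(as.character(kmer))
}

#' Enumerate k-mer windows of a sequence
#'
#' Yields every length-`k` window in position order; windows containing
#' any non-ACGT character are skipped wholesale.
#'
#' @param seq a single sequence.
#' @param spec a [kmer_spec()].
#' @return a data.frame with columns `pos` (0-based start) and `kmer`
#'   (oriented, as read).
#' @export
iter_kmers <- function(seq, spec) {
  stopifnot(inherits(spec, "kmer_spec"))
  k <- spec$k
  n <- nchar(seq)
  if (n < k) return(data.frame(pos = integer(0), kmer = character(0)))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", kmers)
  data.frame(pos = starts[ok] - 1L, kmer = kmers[ok],
             stringsAsFactors = FALSE)
}

#' Count canonical k-mers across read sets
#'
#' Scans every k-window of every read in every set and tallies canonical
#' k-mer occurrences. Counts saturate at 2^16 - 1 (solidity thresholds
#' are small, so saturation is harmless).
#'
#' @param readsets a read set or list of read sets; each set may be a
#'   character vector of sequences, a record data.frame from
#'   [read_sequences()], or a file path.
#' @param spec a [kmer_spec()].
#' @return an object of class `count_table`.
#' @export
count_kmers <- function(readsets, spec) {
  stopifnot(inherits(spec, "kmer_spec"))
  if (!is.list(readsets) || is.data.frame(readsets)) readsets <- list(readsets)
  ptr <- cpp_new_count_table(spec$k)
  for (rs in readsets) cpp_count_add(ptr, as_read_seqs(rs))
  structure(list(ptr = ptr, k = spec$k), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count table: k =", x$k, "|", format(cpp_count_size(x$ptr), big.mark = ","),
      "distinct canonical k-mers |", format(cpp_count_windows(x$ptr), big.mark = ","),
      "windows scanned\n")
  invisible(x)
}

#' Look up counts of specific k-mers
#'
#' @param table a [count_kmers()] table.
#' @param kmers character vector of k-mers (any orientation).
#' @return integer vector of canonical counts (0 for absent or invalid).
#' @export
kmer_count <- function(table, kmers) {
  stopifnot(inherits(table, "count_table"))
  cpp_count_get(table$ptr, as.character(kmers))
}

#' @method as.data.frame count_table
#' @export
as.data.frame.count_table <- function(x, ...) {
  cpp_count_entries(x$ptr)
}

#' Build the exact solid k-mer set
#'
#' Keeps the canonical k-mers with count at least `c` (the solidity
#' threshold). Membership queries against this set are exact; it is the
#' source of truth for every graph algorithm in the package.
#'
#' @param table a [count_kmers()] table.
#' @param c solidity threshold, at least 1.
#' @return an object of class `solid_set`.
#' @export
build_solid_set <- function(table, c = 3L) {
  stopifnot(inherits(table, "count_table"))
  c <- as.integer(c)
  if (is.na(c) || c < 1L) stop("solidity threshold c must be >= 1")
  structure(list(ptr = cpp_solid_build(table$ptr, c), k = table$k, c = c),
            class = "solid_set")
}

#' Build a solid set directly from explicit k-mers
#'
#' Canonicalises and deduplicates the given words. Used for indexes
#' where every k-mer counts (e.g. read-set comparison at c = 1) and in
#' tests.
#'
#' @param kmers character vector of length-`k` ACGT words.
#' @param k the k-mer length.
#' @return an object of class `solid_set`.
#' @export
solid_from_kmers <- function(kmers, k) {
  structure(list(ptr = cpp_solid_from_kmers(as.character(kmers), as.integer(k)),
                 k = as.integer(k), c = 1L),
            class = "solid_set")
}

#' @export
length.solid_set <- function(x) as.integer(cpp_solid_size(x$ptr))

#' @export
print.solid_set <- function(x, ...) {
  cat("solid set: k =", x$k, "| c =", x$c, "|",
      format(cpp_solid_size(x$ptr), big.mark = ","), "canonical k-mers\n")
  invisible(x)
}

#' Exact membership query against a solid set
#'
#' @param solid a [build_solid_set()] result.
#' @param kmers character vector of k-mers (any orientation).
#' @return logical vector; invalid words are `FALSE`.
#' @export
solid_contains <- function(solid, kmers) {
  stopifnot(inherits(solid, "solid_set"))
  cpp_solid_contains(solid$ptr, as.character(kmers))
}

#' All members of a solid set
#'
#' Canonical k-mers in ascending order. Intended for small sets.
#'
#' @param solid a solid set.
#' @return character vector.
#' @export
solid_members <- function(solid) {
  stopifnot(inherits(solid, "solid_set"))
  cpp_solid_members(solid$ptr)
}

#' Persist / restore a solid set
#'
#' Binary format: magic `DBGVSS1`, then `k`, `c`, the member count and
#' the packed canonical k-mers in ascending order. Lets command-line
#' stages share one index.
#'
#' @param solid a solid set.
#' @param path file path.
#' @return `save_solid_set` returns `path` invisibly; `load_solid_set`
#'   returns the restored `solid_set`.
#' @export
save_solid_set <- function(solid, path) {
  stopifnot(inherits(solid, "solid_set"))
  cpp_solid_save(solid$ptr, path)
  invisible(path)
}

#' @rdname save_solid_set
#' @export
load_solid_set <- function(path) {
  ptr <- cpp_solid_load(path)
  structure(list(ptr = ptr, k = cpp_solid_k(ptr), c = cpp_solid_c(ptr)),
            class = "solid_set")
}

#' Build a bloom filter over a solid set
#'
#' A plain bit vector of `m = bits_per_elem * |solid|` bits; each k-mer
#' sets `h` addresses derived by double hashing. Querying an inserted
#' k-mer is always true (no false negatives); a never-inserted k-mer is
#' reported present with probability about `(1 - exp(-h n / m))^h`. The
#' filter is an optional prefilter: algorithmic truth in this package is
#' always the exact solid set.
#'
#' @param solid a solid set.
#' @param bits_per_elem bits allocated per member (default 16).
#' @param h number of hash addresses per item (default 7).
#' @return an object of class `bloom_filter`.
#' @export
build_bloom <- function(solid, bits_per_elem = 16L, h = 7L) {
  stopifnot(inherits(solid, "solid_set"))
  bits_per_elem <- as.integer(bits_per_elem)
  h <- as.integer(h)
  if (is.na(bits_per_elem) || bits_per_elem < 1L)
    stop("bits_per_elem must be >= 1")
  if (is.na(h) || h < 1L || h > 16L) stop("h must be in [1, 16]")
  structure(list(ptr = cpp_bloom_build(solid$ptr, bits_per_elem, h),
                 k = solid$k),
            class = "bloom_filter")
}

#' Probabilistic membership query against a bloom filter
#'
#' @param bloom a [build_bloom()] filter.
#' @param kmers character vector of k-mers (any orientation).
#' @return logical vector (may contain false positives, never false
#'   negatives).
#' @export
bloom_contains <- function(bloom, kmers) {
  stopifnot(inherits(bloom, "bloom_filter"))
  cpp_bloom_contains(bloom$ptr, as.character(kmers))
}

#' Bloom filter parameters
#'
#' @param bloom a bloom filter.
#' @return list with `k`, `m` (bits), `h`, `n_inserted`.
#' @export
bloom_params <- function(bloom) {
  stopifnot(inherits(bloom, "bloom_filter"))
  cpp_bloom_params(bloom$ptr)
}

#' @export
print.bloom_filter <- function(x, ...) {
  p <- bloom_params(x)
  cat("bloom filter: k =", p$k, "| m =", format(p$m, big.mark = ","),
      "bits | h =", p$h, "|", format(p$n_inserted, big.mark = ","),
      "inserted\n")
  invisible(x)
}
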