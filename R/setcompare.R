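#' Mark reads of a query set similar to an indexed set
#'
#' Read i of the query gets bit 1 when it contains at least `t`
#' k-windows (canonical) present in the index; reads shorter than k get
#' bit 0. The index is either an exact solid set or a bloom filter over
#' one - with a bloom index false positives can only add window hits,
#' so the exact-index bits are always a subset of the bloom-index bits.
#'
#' The `>= t` shared-k-mer rule (overlapping windows allowed, default
#' `t = 2`) is this package's read-similarity criterion; it is exposed
#' as a parameter because different projects draw the line differently.
#'
#' @param reads query read set (vector, record data.frame or file
#'   path).
#' @param index a `solid_set` or `bloom_filter` built from the target
#'   set with the same k.
#' @param t minimum number of shared k-mers (default 2).
#' @param set_name,against_name optional labels stored on the result.
#' @return an object of class `shared_bits`: list with `bits` (logical,
#'   read order), `n_reads`, `set_name`, `against_name`, `k`, `t`,
#'   `expr`.
#' @export
mark_shared <- function(reads, index, t = 2L, set_name = "query",
                        against_name = "target") {
  t <- as.integer(t)
  if (is.na(t) || t < 1L) stop("t must be >= 1")
  seqs <- as_read_seqs(reads)
  if (inherits(index, "solid_set")) {
    bits <- cpp_mark_shared_solid(index$ptr, seqs, t)
  } else if (inherits(index, "bloom_filter")) {
    bits <- cpp_mark_shared_bloom(index$ptr, seqs, t)
  } else {
    stop("index must be a solid_set or a bloom_filter")
  }
  structure(list(bits = bits, n_reads = length(seqs), set_name = set_name,
                 against_name = against_name, k = index$k, t = t,
                 expr = paste0(set_name, "~", against_name)),
            class = "shared_bits")
}

#' @export
print.shared_bits <- function(x, ...) {
  cat("shared-read bit vector:", x$expr, "|", sum(x$bits), "/", x$n_reads,
      "reads marked | k =", x$k, ", t =", x$t, "\n")
  invisible(x)
}

#' Logical algebra on shared-read bit vectors
#'
#' Combines subsets of one read set. `NOT` is unary and ignores `y`;
#' the other operations require two vectors over the same read set
#' (same `set_name` and length). The `expr` field records the
#' combination.
#'
#' @param x,y `shared_bits` objects.
#' @param op one of `"AND"`, `"OR"`, `"NOT"`, `"ANDNOT"`.
#' @return a new `shared_bits` object.
#' @export
combine_bits <- function(x, y = NULL, op = c("AND", "OR", "NOT", "ANDNOT")) {
  op <- match.arg(op)
  stopifnot(inherits(x, "shared_bits"))
  if (op == "NOT") {
    bits <- !x$bits
    expr <- paste0("NOT(", x$expr, ")")
  } else {
    stopifnot(inherits(y, "shared_bits"))
    if (x$n_reads != y$n_reads || x$set_name != y$set_name)
      stop("bit vectors cover different read sets")
    bits <- switch(op,
                   AND = x$bits & y$bits,
                   OR = x$bits | y$bits,
                   ANDNOT = x$bits & !y$bits)
    expr <- paste0(op, "(", x$expr, ",", y$expr, ")")
  }
  structure(list(bits = bits, n_reads = x$n_reads, set_name = x$set_name,
                 against_name = NA_character_, k = x$k, t = x$t, expr = expr),
            class = "shared_bits")
}

#' Persist / restore a shared-read bit vector
#'
#' Binary format, versioned: magic `KVBV1`, then k, t, the two names,
#' the read count and the packed bits. The packed form is the compact
#' representation of a read subset that downstream logical operations
#' work on.
#'
#' @param x a `shared_bits` object.
#' @param path file path.
#' @return `write_bit_vector` returns `path` invisibly;
#'   `read_bit_vector` returns the restored object.
#' @export
write_bit_vector <- function(x, path) {
  stopifnot(inherits(x, "shared_bits"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("KVBV1", con, nchars = 5L, eos = NULL)
  writeBin(c(as.integer(x$k), as.integer(x$t)), con, size = 4L)
  for (s in c(x$set_name, x$against_name, x$expr)) {
    s <- as.character(s)
    writeBin(nchar(s), con, size = 4L)
    writeChar(s, con, nchars = nchar(s), eos = NULL)
  }
  writeBin(as.integer(x$n_reads), con, size = 4L)
  writeBin(packBits(c(x$bits, rep(FALSE, (8L - x$n_reads %% 8L) %% 8L)), "raw"),
           con)
  invisible(path)
}

#' @rdname write_bit_vector
#' @export
read_bit_vector <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 5L, useBytes = TRUE)
  if (!identical(magic, "KVBV1")) stop("'", path, "' is not a bit-vector file")
  kt <- readBin(con, "integer", n = 2L, size = 4L)
  strs <- character(3)
  for (i in 1:3) {
    n <- readBin(con, "integer", n = 1L, size = 4L)
    strs[i] <- readChar(con, n, useBytes = TRUE)
  }
  n_reads <- readBin(con, "integer", n = 1L, size = 4L)
  raw <- readBin(con, "raw", n = ceiling(n_reads / 8))
  bits <- as.logical(rawToBits(raw))[seq_len(n_reads)]
  structure(list(bits = bits, n_reads = n_reads, set_name = strs[1],
                 against_name = strs[2], k = kt[1], t = kt[2], expr = strs[3]),
            class = "shared_bits")
}

#' All-against-all read-set similarity
#'
#' For every ordered pair, `pct(A -> B)` is the percentage of A's reads
#' marked similar to B's k-mer index (an exact all-k-mer index of B,
#' i.e. solidity c = 1). The symmetric similarity is
#' `100 (shared(A->B) + shared(B->A)) / (|A| + |B|)`, with 100 on the
#' diagonal.
#'
#' @param readsets list of at least two read sets; names become labels.
#' @param k k-mer length.
#' @param t minimum shared k-mers per read (default 2).
#' @param set_names optional labels overriding `names(readsets)`.
#' @return an object of class `similarity_matrix`: list with `directed`
#'   and `symmetric` S-by-S matrices and `names`.
#' @export
similarity_matrix <- function(readsets, k, t = 2L, set_names = NULL) {
  if (!is.list(readsets) || is.data.frame(readsets)) readsets <- list(readsets)
  if (length(readsets) < 2L) stop("need at least 2 read sets")
  if (is.null(set_names)) set_names <- names(readsets)
  if (is.null(set_names)) set_names <- paste0("set", seq_along(readsets))
  seqs <- lapply(readsets, as_read_seqs)
  if (any(vapply(seqs, length, integer(1)) == 0L)) stop("empty read set")
  spec <- kmer_spec(k)
  idx <- lapply(seqs, function(s) build_solid_set(count_kmers(s, spec), 1L))
  S <- length(seqs)
  directed <- matrix(0, S, S, dimnames = list(set_names, set_names))
  shared <- matrix(0, S, S)
  for (a in seq_len(S)) {
    for (b in seq_len(S)) {
      n <- sum(mark_shared(seqs[[a]], idx[[b]], t)$bits)
      shared[a, b] <- n
      directed[a, b] <- 100 * n / length(seqs[[a]])
    }
  }
  sym <- matrix(0, S, S, dimnames = list(set_names, set_names))
  for (a in seq_len(S)) {
    for (b in seq_len(S)) {
      sym[a, b] <- 100 * (shared[a, b] + shared[b, a]) /
        (length(seqs[[a]]) + length(seqs[[b]]))
    }
  }
  diag(sym) <- 100
  structure(list(directed = directed, symmetric = sym, names = set_names,
                 k = as.integer(k), t = as.integer(t)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("read-set similarity (k =", x$k, ", t =", x$t, ")\n")
  print(round(x$symmetric, 1))
  invisible(x)
}

#' Average-linkage dendrogram of read sets
#'
#' Hierarchical clustering on the distance `100 - symmetric similarity`
#' with average linkage (UPGMA). Input order (set-name order) fixes tie
#' breaking, so the result is deterministic.
#'
#' @param m a [similarity_matrix()] result.
#' @return a list with `newick` (tree text with branch lengths),
#'   `leaf_order`, and the underlying `hclust` object.
#' @export
cluster_dendrogram <- function(m) {
  stopifnot(inherits(m, "similarity_matrix"))
  if (length(m$names) < 2L) stop("need at least 2 sets to cluster")
  d <- as.dist(100 - m$symmetric)
  hc <- hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  list(newick = ape::write.tree(phy), leaf_order = hc$labels[hc$order],
       hclust = hc)
}
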