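#' Implicit de Bruijn graph over solid canonical k-mers
#'
#' The node set is the solid set; arcs are the exact (k-1)-overlaps
#' between k-mers. Edges are never materialised: successors and
#' predecessors are computed by at most four membership queries each.
#' Traversal works on oriented k-mers while membership is tested on
#' canonical forms, realising the bidirected graph implicitly.
#'
#' @param solid a [build_solid_set()] result (the exact node set).
#' @param bloom optional [build_bloom()] filter over the same set, kept
#'   for footprint experiments; never used as algorithmic truth.
#' @return an object of class `dbg`.
#' @export
dbg_graph <- function(solid, bloom = NULL) {
  stopifnot(inherits(solid, "solid_set"))
  if (!is.null(bloom)) {
    stopifnot(inherits(bloom, "bloom_filter"))
    if (bloom$k != solid$k) stop("bloom filter and solid set disagree on k")
  }
  structure(list(solid = solid, bloom = bloom, k = solid$k), class = "dbg")
}

#' @export
print.dbg <- function(x, ...) {
  cat("de Bruijn graph: k =", x$k, "|", length(x$solid), "nodes (implicit edges)",
      if (!is.null(x$bloom)) "| bloom prefilter attached" else "", "\n")
  invisible(x)
}

#' Neighbors of an oriented k-mer
#'
#' A successor of `node` is `substr(node, 2, k)` plus one base whose
#' canonical form is solid; predecessors mirror this on the left. The
#' result is sorted by the appended/prepended base and has 0-4 entries.
#'
#' @param g a [dbg_graph()].
#' @param node an oriented k-mer (length `k`, ACGT).
#' @return character vector of oriented neighbor k-mers.
#' @export
dbg_successors <- function(g, node) {
  stopifnot(inherits(g, "dbg"))
  cpp_successors(g$solid$ptr, node)
}

#' @rdname dbg_successors
#' @export
dbg_predecessors <- function(g, node) {
  stopifnot(inherits(g, "dbg"))
  cpp_predecessors(g$solid$ptr, node)
}

#' Unambiguous unitig extension
#'
#' Walks from `start` while the current node has exactly one neighbor in
#' the walk direction and that neighbor has exactly one neighbor looking
#' back (the standard both-sides-unique unitig rule, which stops contigs
#' at bubble entrances). Halts on a branch, a dead end, a revisited node
#' (loop guard) or after `max_len` bases.
#'
#' @param g a [dbg_graph()].
#' @param start an oriented solid k-mer.
#' @param direction `"right"` (append) or `"left"` (prepend).
#' @param max_len maximum number of extension bases (default 10000;
#'   flanks are context, not assemblies).
#' @return the extension bases only (excluding `start`), in genome
#'   order.
#' @export
extend_unitig <- function(g, start, direction = c("right", "left"),
                          max_len = 10000L) {
  stopifnot(inherits(g, "dbg"))
  direction <- match.arg(direction)
  cpp_extend_unitig(g$solid$ptr, start, direction == "right",
                    as.integer(max_len))
}
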