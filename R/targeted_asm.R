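#' Validate a starter sequence against the solid k-mer content
#'
#' A starter anchors a targeted assembly; it is only worth extending if
#' enough of its k-windows are solid in the reads. The solid fraction is
#' the share of the starter's valid k-windows present in the solid set.
#'
#' @param starter starter sequence (length at least `k`).
#' @param solid a [build_solid_set()] result.
#' @param min_fraction acceptance threshold on the solid fraction
#'   (default 0.7).
#' @return a list with `accepted` (flag) and `solid_fraction`.
#' @export
validate_starter <- function(starter, solid, min_fraction = 0.7) {
  stopifnot(inherits(solid, "solid_set"))
  k <- solid$k
  if (nchar(starter) < k) stop("starter shorter than k")
  starts <- seq_len(nchar(starter) - k + 1L)
  wins <- substring(starter, starts, starts + k - 1L)
  frac <- mean(solid_contains(solid, wins))
  list(accepted = frac >= min_fraction, solid_fraction = frac)
}

#' Linear targeted extension of a starter
#'
#' Extends the starter from both ends with the unambiguous unitig rule:
#' the sequence is cut as soon as two choices occur (or at a dead end,
#' loop, or `max_len`). A terminal k-mer that is not solid yields an
#' empty extension on that side, with a warning.
#'
#' @param g a [dbg_graph()].
#' @param starter an accepted starter sequence.
#' @param max_len maximum extension length per side.
#' @return a list with `left` and `right` extension strings; the
#'   assembled sequence is `paste0(left, starter, right)`.
#' @export
extend_linear <- function(g, starter, max_len = 10000L) {
  stopifnot(inherits(g, "dbg"))
  k <- g$k
  if (nchar(starter) < k) stop("starter shorter than k")
  if (max_len == 0L) return(list(left = "", right = ""))
  lk <- substr(starter, 1L, k)
  rk <- substr(starter, nchar(starter) - k + 1L, nchar(starter))
  left <- right <- ""
  if (isTRUE(solid_contains(g$solid, lk))) {
    left <- extend_unitig(g, lk, "left", max_len)
  } else {
    warning("left terminal k-mer of starter is not solid; no left extension")
  }
  if (isTRUE(solid_contains(g$solid, rk))) {
    right <- extend_unitig(g, rk, "right", max_len)
  } else {
    warning("right terminal k-mer of starter is not solid; no right extension")
  }
  list(left = left, right = right)
}

#' Neighborhood graph of a starter
#'
#' Breadth-first exploration of compacted simple paths (unitig nodes)
#' from both ends of the starter, up to `max_depth` branch levels or
#' `max_nodes` nodes. Bubbles in this graph witness polymorphisms next
#' to the starter. Each node carries, per read set, the mean count of
#' its k-windows in that set's count table (the coverage proxy used for
#' node coloring); exploration order is deterministic (branches sorted
#' by base).
#'
#' @param g a [dbg_graph()].
#' @param starter an accepted starter sequence.
#' @param tables list of per-read-set [count_kmers()] tables (same k).
#' @param set_names labels for the coverage columns; defaults to
#'   `names(tables)`.
#' @param max_nodes node budget (default 200).
#' @param max_depth branch levels explored from the starter (default 5).
#' @return an object of class `neighborhood_graph`: a list with `k`,
#'   `starter` (node id), `nodes` (data.frame: `id`, `seq`,
#'   `is_starter`, one `cov_<set>` column per set) and `edges`
#'   (data.frame: `from`, `to`; overlap is always k-1).
#' @export
build_neighborhood_graph <- function(g, starter, tables, set_names = NULL,
                                     max_nodes = 200L, max_depth = 5L) {
  stopifnot(inherits(g, "dbg"))
  k <- g$k
  if (!is.list(tables) || inherits(tables, "count_table")) tables <- list(tables)
  if (is.null(set_names)) set_names <- names(tables)
  if (is.null(set_names)) set_names <- paste0("set", seq_along(tables))
  node_seqs <- character(0)
  node_key <- character(0)   # oriented sequence, for dedup on rejoin
  edges_from <- integer(0)
  edges_to <- integer(0)
  add_node <- function(seq) {
    node_seqs[length(node_seqs) + 1L] <<- seq
    length(node_seqs)
  }
  starter_id <- add_node(starter)
  node_key[starter_id] <- starter
  # frontier entries: node id, boundary oriented k-mer, direction
  frontier <- list(list(id = starter_id,
                        km = substr(starter, nchar(starter) - k + 1L, nchar(starter)),
                        dir = "right"),
                   list(id = starter_id,
                        km = substr(starter, 1L, k),
                        dir = "left"))
  depth <- 0L
  while (length(frontier) > 0L && depth < max_depth &&
         length(node_seqs) < max_nodes) {
    depth <- depth + 1L
    nxt <- list()
    for (fr in frontier) {
      nbrs <- if (fr$dir == "right") dbg_successors(g, fr$km)
              else dbg_predecessors(g, fr$km)
      for (nb in nbrs) {
        if (length(node_seqs) >= max_nodes) break
        ext <- extend_unitig(g, nb, fr$dir, 10000L)
        seq <- if (fr$dir == "right") paste0(nb, ext) else paste0(ext, nb)
        key <- paste0(fr$dir, ":", seq)
        hit <- match(key, node_key)
        if (!is.na(hit)) {
          id <- hit
        } else {
          id <- add_node(seq)
          node_key[id] <- key
          boundary <- if (fr$dir == "right")
            substr(seq, nchar(seq) - k + 1L, nchar(seq))
          else substr(seq, 1L, k)
          nxt[[length(nxt) + 1L]] <- list(id = id, km = boundary, dir = fr$dir)
        }
        if (fr$dir == "right") {
          edges_from <- c(edges_from, fr$id); edges_to <- c(edges_to, id)
        } else {
          edges_from <- c(edges_from, id); edges_to <- c(edges_to, fr$id)
        }
      }
    }
    frontier <- nxt
  }
  nodes <- data.frame(id = seq_along(node_seqs), seq = node_seqs,
                      is_starter = seq_along(node_seqs) == starter_id,
                      stringsAsFactors = FALSE)
  for (j in seq_along(tables)) {
    stopifnot(inherits(tables[[j]], "count_table"))
    nodes[[paste0("cov_", set_names[j])]] <- vapply(node_seqs, function(s) {
      wc <- cpp_window_counts(tables[[j]]$ptr, s)
      wc <- wc[wc >= 0L]
      if (length(wc) == 0L) return(0)
      mean(wc)
    }, numeric(1), USE.NAMES = FALSE)
  }
  edges <- unique(data.frame(from = edges_from, to = edges_to))
  rownames(edges) <- NULL
  structure(list(k = k, starter = starter_id, set_names = set_names,
                 nodes = nodes, edges = edges),
            class = "neighborhood_graph")
}

#' @export
print.neighborhood_graph <- function(x, ...) {
  cat("neighborhood graph: k =", x$k, "|", nrow(x$nodes), "nodes |",
      nrow(x$edges), "edges | starter node", x$starter, "\n")
  invisible(x)
}

#' Write a neighborhood graph as JSON
#'
#' Schema (shipped in `inst/extdata/neighborhood-graph-schema.json`):
#' `{"k", "starter", "nodes": [{"id", "seq", "cov": [...], "is_starter"}],`
#' `"edges": [{"from", "to"}]}` with stable key order; parse-back is
#' lossless.
#'
#' @param graph a [build_neighborhood_graph()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "neighborhood_graph"))
  covcols <- paste0("cov_", graph$set_names)
  nodes <- lapply(seq_len(nrow(graph$nodes)), function(i) {
    list(id = graph$nodes$id[i],
         seq = graph$nodes$seq[i],
         cov = as.numeric(unlist(graph$nodes[i, covcols, drop = TRUE])),
         is_starter = graph$nodes$is_starter[i])
  })
  edges <- lapply(seq_len(nrow(graph$edges)), function(i) {
    list(from = graph$edges$from[i], to = graph$edges$to[i])
  })
  doc <- list(k = graph$k, starter = graph$starter,
              sets = as.list(graph$set_names), nodes = nodes, edges = edges)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_graph_json
#' @return `read_graph_json` returns the reconstructed
#'   `neighborhood_graph`.
#' @export
read_graph_json <- function(path) {
  doc <- jsonlite::read_json(path)
  set_names <- unlist(doc$sets)
  nodes <- data.frame(
    id = vapply(doc$nodes, function(n) as.integer(n$id), integer(1)),
    seq = vapply(doc$nodes, function(n) n$seq, character(1)),
    is_starter = vapply(doc$nodes, function(n) isTRUE(n$is_starter), logical(1)),
    stringsAsFactors = FALSE)
  for (j in seq_along(set_names)) {
    nodes[[paste0("cov_", set_names[j])]] <-
      vapply(doc$nodes, function(n) as.numeric(n$cov[[j]]), numeric(1))
  }
  edges <- data.frame(
    from = vapply(doc$edges, function(e) as.integer(e$from), integer(1)),
    to = vapply(doc$edges, function(e) as.integer(e$to), integer(1)))
  structure(list(k = as.integer(doc$k), starter = as.integer(doc$starter),
                 set_names = set_names, nodes = nodes, edges = edges),
            class = "neighborhood_graph")
}
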