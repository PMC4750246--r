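#' Map one read onto a predicted variant sequence
#'
#' A read matches when some ungapped placement of it (either strand),
#' anchored by at least one exact shared k-mer with the target, covers
#' the target's center position and has at most `max_mismatch`
#' mismatches over the overlap.
#'
#' @param read read sequence.
#' @param target predicted variant sequence (length at least `k`).
#' @param center 0-based index of the variant position within `target`.
#' @param k anchor k-mer length (the global k).
#' @param max_mismatch mismatch budget over the overlap (default 1).
#' @return `TRUE` or `FALSE`.
#' @export
map_read <- function(read, target, center, k, max_mismatch = 1L) {
  cpp_map_read(read, target, as.integer(center), as.integer(k),
               as.integer(max_mismatch))
}

#' Map reads back onto bubbles and count per-allele per-set support
#'
#' For every bubble, reads of every set are mapped (see [map_read()])
#' onto the two flanked allele sequences. A read is counted for the
#' allele it matches strictly better; a read whose best placements tie
#' between the two alleles is ambiguous and counted for neither. The phi
#' score of the resulting 2-by-S table is computed as well.
#'
#' @param bubbles a flanked [find_snp_bubbles()] result.
#' @param readsets list of read sets (vectors, record data.frames or
#'   file paths); element names become the set labels.
#' @param k the k-mer length used to build the graph.
#' @param max_mismatch mismatch budget per read placement.
#' @param set_names optional labels overriding `names(readsets)`.
#' @return `bubbles` with integer columns `count_a_<set>`,
#'   `count_b_<set>` and a numeric `phi` column.
#' @export
quantify_bubbles <- function(bubbles, readsets, k, max_mismatch = 1L,
                             set_names = NULL) {
  stopifnot(inherits(bubbles, "snp_bubbles"))
  if (!is.list(readsets) || is.data.frame(readsets)) readsets <- list(readsets)
  if (is.null(set_names)) set_names <- names(readsets)
  if (is.null(set_names)) set_names <- paste0("set", seq_along(readsets))
  seqs <- lapply(readsets, as_read_seqs)
  if (nrow(bubbles) == 0L) {
    for (s in set_names) {
      bubbles[[paste0("count_a_", s)]] <- integer(0)
      bubbles[[paste0("count_b_", s)]] <- integer(0)
    }
    bubbles$phi <- numeric(0)
    return(bubbles)
  }
  q <- cpp_quantify(seqs, flanked_seq(bubbles, "a"), flanked_seq(bubbles, "b"),
                    as.integer(flanked_center(bubbles)), as.integer(k),
                    as.integer(max_mismatch))
  for (j in seq_along(set_names)) {
    bubbles[[paste0("count_a_", set_names[j])]] <- q$count_a[, j]
    bubbles[[paste0("count_b_", set_names[j])]] <- q$count_b[, j]
  }
  bubbles$phi <- vapply(seq_len(nrow(bubbles)), function(i) {
    phi_score(rbind(q$count_a[i, ], q$count_b[i, ]))
  }, numeric(1))
  bubbles
}

#' Phi score of a 2-by-S allele-count table
#'
#' A normalized chi-squared statistic in `[0, 1]` ranking how
#' discriminant a variant's allele counts are across read sets. With
#' `N` the table total, `chi2` the classical Pearson statistic over the
#' cells whose expected value is positive (zero-marginal columns are
#' skipped), the score is `sqrt(chi2 / N)`, clamped to `[0, 1]` - the
#' Cramer's V of a 2-row table. Degenerate tables (empty, one allele
#' absent everywhere, no column mass) score 0. For two read sets this
#' equals the absolute classical phi coefficient
#' `|ad - bc| / sqrt((a+b)(c+d)(a+c)(b+d))`.
#'
#' @param counts a 2-row matrix: rows = alleles A/B, columns = read
#'   sets; non-negative integers.
#' @return a number in `[0, 1]`.
#' @examples
#' phi_score(rbind(c(10, 0), c(0, 10)))  # 1
#' phi_score(rbind(c(5, 5), c(5, 5)))    # 0
#' phi_score(rbind(c(8, 2), c(2, 8)))    # 0.6
#' @export
phi_score <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L) stop("counts must have exactly 2 rows (alleles)")
  if (any(counts < 0)) stop("counts must be non-negative")
  N <- sum(counts)
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (N == 0 || any(rs == 0) || all(cs == 0)) return(0)
  keep <- cs > 0
  chi2 <- 0
  for (j in which(keep)) {
    for (i in 1:2) {
      E <- rs[i] * cs[j] / N
      chi2 <- chi2 + (counts[i, j] - E)^2 / E
    }
  }
  min(1, max(0, sqrt(chi2 / N)))
}

#' Rank bubbles by phi score
#'
#' Descending phi, ties broken by ascending `bubble_id`; stable and
#' deterministic.
#'
#' @param bubbles a quantified [quantify_bubbles()] result with a `phi`
#'   column.
#' @return the same data.frame, reordered.
#' @export
rank_bubbles <- function(bubbles) {
  stopifnot(inherits(bubbles, "snp_bubbles"))
  if (is.null(bubbles$phi)) stop("bubbles have no phi column; run quantify_bubbles() first")
  out <- bubbles[order(-bubbles$phi, bubbles$bubble_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the quantified bubble table as TSV
#'
#' Columns: `bubble_id`, `phi`, then the per-set allele counts. The
#' file starts with `#` comment lines recording the configuration.
#'
#' @param bubbles a quantified bubble set.
#' @param path output path.
#' @param config optional named list echoed into the `#` header.
#' @return `path`, invisibly.
#' @export
write_bubble_table <- function(bubbles, path, config = list()) {
  stopifnot(inherits(bubbles, "snp_bubbles"))
  cols <- c("bubble_id", "phi",
            grep("^count_[ab]_", names(bubbles), value = TRUE))
  cols <- intersect(cols, names(bubbles))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header("bubble quantification table", config), con)
  write.table(bubbles[, cols, drop = FALSE], con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
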