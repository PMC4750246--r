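#' Detect isolated-SNP bubbles in the de Bruijn graph
#'
#' An isolated SNP shows up as a pair of k-vertex paths spelling two
#' (2k-1)-length sequences that differ at exactly the center position.
#' Detection seeds on two oriented solid k-mers identical except at
#' their last base and extends both simultaneously for k-1 steps, each
#' step requiring the appended base to keep both paths solid. In
#' `strict` mode (the default, the conservative choice) a step must
#' admit exactly one such base or the candidate is discarded; `relaxed`
#' mode enumerates every admissible extension. Output is deduplicated to
#' the reverse-complement-canonical pair form, sorted by
#' `(path_a, path_b)` with `path_a < path_b`, and ids assigned in that
#' order.
#'
#' @param g a [dbg_graph()].
#' @param branching `"strict"` or `"relaxed"`.
#' @return a data.frame of class `snp_bubbles` with columns `bubble_id`,
#'   `path_a`, `path_b`, `center` (0-based index `k - 1`),
#'   `left_contig`, `right_contig` (empty until [extend_flanks()]).
#' @examples
#' spec <- suppressWarnings(kmer_spec(4L))
#' tab <- count_kmers(c("CTGACCT", "CTGTCCT"), spec)
#' g <- dbg_graph(build_solid_set(tab, 1L))
#' find_snp_bubbles(g)
#' @export
find_snp_bubbles <- function(g, branching = c("strict", "relaxed")) {
  stopifnot(inherits(g, "dbg"))
  branching <- match.arg(branching)
  df <- cpp_find_bubbles(g$solid$ptr, branching == "strict")
  out <- data.frame(
    bubble_id = seq_len(nrow(df)),
    path_a = df$path_a,
    path_b = df$path_b,
    center = rep(g$k - 1L, nrow(df)),
    left_contig = rep("", nrow(df)),
    right_contig = rep("", nrow(df)),
    stringsAsFactors = FALSE)
  class(out) <- c("snp_bubbles", "data.frame")
  attr(out, "k") <- g$k
  out
}

#' Attach flanking contigs to bubbles
#'
#' Both paths of a bubble share their first and last k-1 bases, so the
#' flanks are common to the two alleles. The left contig is the
#' unambiguous unitig extension of the unique solid predecessor of the
#' shared prefix (empty if that predecessor is absent or ambiguous);
#' the right contig mirrors this. Extension stops at the first branch,
#' so a second nearby bubble truncates the flank rather than producing
#' a chimeric contig.
#'
#' @param g a [dbg_graph()].
#' @param bubbles a [find_snp_bubbles()] result.
#' @param max_len maximum flank length per side.
#' @return `bubbles` with `left_contig` / `right_contig` filled in.
#' @export
extend_flanks <- function(g, bubbles, max_len = 10000L) {
  stopifnot(inherits(g, "dbg"), inherits(bubbles, "snp_bubbles"))
  if (nrow(bubbles) == 0L) return(bubbles)
  fl <- cpp_bubble_flanks(g$solid$ptr, bubbles$path_a, as.integer(max_len))
  bubbles$left_contig <- fl$left
  bubbles$right_contig <- fl$right
  bubbles
}

# flanked allele sequence and the center's index within it
flanked_seq <- function(bubbles, allele = c("a", "b")) {
  allele <- match.arg(allele)
  path <- if (allele == "a") bubbles$path_a else bubbles$path_b
  paste0(bubbles$left_contig, path, bubbles$right_contig)
}

flanked_center <- function(bubbles) {
  nchar(bubbles$left_contig) + bubbles$center
}

#' Write bubbles as a paired-path multi-FASTA
#'
#' Every consecutive pair of records is the two paths of one SNP, each
#' flanked by the shared contigs. Headers follow
#' `>SNP_<id>|P_A|left=<len>|right=<len>` with optional `|C_<set>=<n>`
#' per-set allele counts and `|phi=<score>` when quantification has
#' run; [read_bubbles_fasta()] parses them back losslessly.
#'
#' @param bubbles a [find_snp_bubbles()] result (optionally flanked,
#'   quantified and scored).
#' @param path output FASTA path.
#' @return the number of records written, invisibly.
#' @export
write_bubbles_fasta <- function(bubbles, path) {
  stopifnot(inherits(bubbles, "snp_bubbles"))
  csets <- grep("^count_[ab]_", names(bubbles), value = TRUE)
  recs <- character(0)
  ids <- character(0)
  for (i in seq_len(nrow(bubbles))) {
    for (al in c("a", "b")) {
      hdr <- sprintf("SNP_%d|P_%s|left=%d|right=%d",
                     bubbles$bubble_id[i], toupper(al),
                     nchar(bubbles$left_contig[i]),
                     nchar(bubbles$right_contig[i]))
      mine <- grep(paste0("^count_", al, "_"), csets, value = TRUE)
      for (col in mine) {
        hdr <- paste0(hdr, "|C_", sub(paste0("^count_", al, "_"), "", col),
                      "=", bubbles[[col]][i])
      }
      if (!is.null(bubbles$phi))
        hdr <- paste0(hdr, "|phi=", format(bubbles$phi[i], digits = 6))
      ids <- c(ids, hdr)
      recs <- c(recs, flanked_seq(bubbles[i, , drop = FALSE], al))
    }
  }
  if (length(recs) == 0L) {
    file.create(path)
    return(invisible(0L))
  }
  write_fasta(data.frame(id = ids, seq = recs, stringsAsFactors = FALSE), path)
}

#' @rdname write_bubbles_fasta
#' @param k the k-mer length used when the file was produced.
#' @return `read_bubbles_fasta` returns the reconstructed `snp_bubbles`
#'   data.frame.
#' @export
read_bubbles_fasta <- function(path, k) {
  if (file.size(path) == 0L) {
    out <- data.frame(bubble_id = integer(0), path_a = character(0),
                      path_b = character(0), center = integer(0),
                      left_contig = character(0), right_contig = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("snp_bubbles", "data.frame")
    attr(out, "k") <- as.integer(k)
    return(out)
  }
  rec <- read_sequences(path)
  parts <- strsplit(rec$id, "|", fixed = TRUE)
  get_field <- function(p, key) {
    hit <- grep(paste0("^", key, "="), p, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    sub(paste0("^", key, "="), "", hit[1L])
  }
  a_rows <- seq(1L, nrow(rec), by = 2L)
  n <- length(a_rows)
  out <- data.frame(bubble_id = integer(n), path_a = character(n),
                    path_b = character(n), center = rep(k - 1L, n),
                    left_contig = character(n), right_contig = character(n),
                    stringsAsFactors = FALSE)
  counts <- list()
  phi <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    ia <- a_rows[j]; ib <- ia + 1L
    pa <- parts[[ia]]; pb <- parts[[ib]]
    out$bubble_id[j] <- as.integer(sub("^SNP_", "", pa[1L]))
    l <- as.integer(get_field(pa, "left"))
    r <- as.integer(get_field(pa, "right"))
    sa <- rec$seq[ia]; sb <- rec$seq[ib]
    out$left_contig[j] <- substr(sa, 1L, l)
    out$right_contig[j] <- substr(sa, nchar(sa) - r + 1L, nchar(sa))
    out$path_a[j] <- substr(sa, l + 1L, nchar(sa) - r)
    out$path_b[j] <- substr(sb, l + 1L, nchar(sb) - r)
    for (al in c("a", "b")) {
      p <- if (al == "a") pa else pb
      chits <- grep("^C_", p, value = TRUE)
      for (h in chits) {
        set <- sub("=.*$", "", sub("^C_", "", h))
        col <- paste0("count_", al, "_", set)
        if (is.null(counts[[col]])) counts[[col]] <- rep(NA_integer_, n)
        counts[[col]][j] <- as.integer(sub("^.*=", "", h))
      }
    }
    ph <- get_field(pa, "phi")
    if (!is.na(ph)) phi[j] <- as.numeric(ph)
  }
  for (col in names(counts)) out[[col]] <- counts[[col]]
  if (!all(is.na(phi))) out$phi <- phi
  class(out) <- c("snp_bubbles", "data.frame")
  attr(out, "k") <- as.integer(k)
  out
}
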