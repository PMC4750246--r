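#' Read sequences from FASTA or FASTQ, plain or gzipped
#'
#' The format is auto-detected from the first byte of the (decompressed)
#' stream: `>` for FASTA, `@` for FASTQ; gzip is detected from its magic
#' bytes, never from the file extension. Sequences are uppercased and any
#' letter outside `A`, `C`, `G`, `T` is normalised to `N`; record
#' identifiers are truncated at the first whitespace. Qualities are
#' carried verbatim for FASTQ input and never interpreted.
#'
#' @param path path to a FASTA or FASTQ file, optionally gzip-compressed.
#' @return a data.frame with columns `id`, `seq` and `qual` (`NA` for
#'   FASTA input), one row per record, in file order.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ACgt"), f)
#' read_sequences(f)
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  first <- readBin(con, "raw", n = 1L)
  close(con)
  if (length(first) == 0L) stop("empty file: ", path)
  ch <- rawToChar(first)
  if (ch == ">") {
    x <- Biostrings::readBStringSet(path, format = "fasta")
    qual <- rep(NA_character_, length(x))
  } else if (ch == "@") {
    x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
  } else {
    stop("cannot detect format of '", path, "': first byte is not '>' or '@'")
  }
  seqs <- gsub("[^ACGTN]", "N", toupper(as.character(x)))
  if (any(!nzchar(seqs))) {
    stop("format error: empty sequence at record ", which(!nzchar(seqs))[1L],
         " of '", path, "'")
  }
  ids <- sub("\\s.*$", "", names(x))
  data.frame(id = ids, seq = unname(seqs), qual = unname(qual),
             stringsAsFactors = FALSE)
}

#' Write sequence records as FASTA
#'
#' @param records a data.frame with columns `id` and `seq` (as returned
#'   by [read_sequences()]), or a named character vector of sequences.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param line_width bases per sequence line; `0` writes each sequence on
#'   a single line.
#' @return the number of records written, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 0L) {
  records <- as_records(records)
  if (line_width < 0L) stop("line_width must be >= 0")
  x <- Biostrings::BStringSet(records$seq)
  names(x) <- records$id
  width <- if (line_width == 0L) max(nchar(records$seq), 1L) else line_width
  Biostrings::writeXStringSet(x, path, format = "fasta", width = width,
                              compress = grepl("\\.gz$", path))
  invisible(nrow(records))
}

#' Write sequence records as FASTQ
#'
#' Records lacking a quality string get a constant `I` quality.
#'
#' @inheritParams write_fasta
#' @return the number of records written, invisibly.
#' @export
write_fastq <- function(records, path) {
  records <- as_records(records)
  qual <- records$qual
  if (is.null(qual)) qual <- rep(NA_character_, nrow(records))
  miss <- is.na(qual)
  qual[miss] <- vapply(nchar(records$seq[miss]),
                       function(n) strrep("I", n), character(1))
  if (any(nchar(qual) != nchar(records$seq)))
    stop("format error: quality length differs from sequence length")
  x <- Biostrings::BStringSet(records$seq)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(nrow(records))
}

# coerce sequences in any accepted shape to the record data.frame
as_records <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "seq") %in% names(x)))
    return(x)
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(data.frame(id = ids, seq = unname(x), stringsAsFactors = FALSE))
  }
  stop("cannot interpret input as sequence records")
}

# sequences from: character vector, record data.frame, or file path
as_read_seqs <- function(x) {
  if (is.data.frame(x)) return(x$seq)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(read_sequences(x)$seq)
  if (is.character(x)) return(unname(x))
  stop("cannot interpret input as a read set")
}
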