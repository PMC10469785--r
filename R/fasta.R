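# FASTA reading and writing.
#
# Sequences travel through the package as named character vectors
# (names = record ids, values = normalized IUPAC strings). Reading performs
# a strict validation pass so malformed files fail with a line number;
# writing delegates to Biostrings with a fixed 70-column wrap.

#' Read a FASTA file into a named character vector
#'
#' Accepts plain or gzipped multi-record FASTA, LF or CRLF line endings.
#' Sequences are uppercased, U is normalized to T, and any character outside
#' the IUPAC nucleotide alphabet is an error. Malformed structure (text
#' before the first header, empty id, record without sequence) is reported
#' with the offending line number.
#'
#' @param path path to a FASTA file (".gz" accepted).
#' @return named character vector of normalized sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- sub("\r$", "", lines)

  ids <- character(0)
  seqs <- character(0)
  cur_id <- NULL
  cur_chunks <- character(0)
  cur_header_line <- NA_integer_

  flush_record <- function() {
    if (is.null(cur_id)) return()
    s <- paste(cur_chunks, collapse = "")
    if (nchar(s) == 0L)
      stop("FASTA parse error: record '", cur_id, "' (line ",
           cur_header_line, ") has no sequence")
    ids[length(ids) + 1L] <<- cur_id
    seqs[length(seqs) + 1L] <<- s
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      flush_record()
      cur_id <- trimws(substring(ln, 2L))
      if (nchar(cur_id) == 0L)
        stop("FASTA parse error: empty record id at line ", i)
      cur_chunks <- character(0)
      cur_header_line <- i
    } else if (nchar(trimws(ln)) == 0L) {
      next
    } else {
      if (is.null(cur_id))
        stop("FASTA parse error: sequence data before first header at line ", i)
      chunk <- gsub("[[:space:]]", "", ln)
      norm <- tryCatch(normalize_seq(chunk, "FASTA record"),
                       error = function(e) stop(conditionMessage(e),
                                                " at line ", i, call. = FALSE))
      cur_chunks[length(cur_chunks) + 1L] <- norm
    }
  }
  flush_record()
  if (length(ids) == 0L) stop("FASTA parse error: no records in ", path)
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' Lines are wrapped at 70 columns; a ".gz" path is written gzip-compressed.
#' \code{read_fasta(write_fasta(x, p))} restores identical id/sequence pairs.
#'
#' @param records named character vector of IUPAC sequences.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (length(records) == 0L) stop("no records to write")
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("every record needs a non-empty id")
  records <- vapply(records, normalize_seq, character(1))
  x <- Biostrings::DNAStringSet(records)
  Biostrings::writeXStringSet(x, filepath = path, width = 70L,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
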