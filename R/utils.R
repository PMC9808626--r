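# Internal helpers shared across modules.

#' @import data.table
NULL

.datatable.aware <- TRUE

PHRED_OFFSET <- 33L
# printable Phred char lookup, index = Q + 1 (Q in 0..93)
.QCHARS <- vapply(0:93, function(q) rawToChar(as.raw(q + PHRED_OFFSET)),
                  character(1))

.qual_to_int <- function(qual) {
  # vector of quality strings -> integer vector (concatenated) of Phred scores
  if (length(qual) == 0L) return(integer(0))
  as.integer(charToRaw(paste(qual, collapse = ""))) - PHRED_OFFSET
}

.int_to_qual_chars <- function(q) .QCHARS[pmax(pmin(q, 93L), 0L) + 1L]

# split a character vector of equal-length strings into an m x w matrix of
# single characters (row = string)
.char_matrix <- function(x, width) {
  if (length(x) == 0L) return(matrix(character(0), nrow = 0L, ncol = width))
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = width, byrow = TRUE)
}

# collapse an m x w character matrix back to m strings
.collapse_rows <- function(mat) {
  if (nrow(mat) == 0L) return(character(0))
  if (ncol(mat) == 1L) return(as.vector(mat))
  do.call(paste0, lapply(seq_len(ncol(mat)), function(j) mat[, j]))
}

.revcomp <- function(x) {
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz])))
  }
  out
}

.reverse_str <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

.stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

#' Read a FASTQ file into a data frame
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning the
#' three-column layout (`id`, `seq`, `qual`) used throughout the package.
#'
#' @param path path to a FASTQ file (optionally gzipped).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Write a data frame of reads to FASTQ
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              compress = grepl("\\.gz$", path),
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}
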