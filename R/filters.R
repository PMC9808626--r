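# Post-alignment filters for single-end alignments of deconvolved reads.
# Records are plain data.frames with the columns of a SAM record plus the
# optional integer tags AS (best alignment score), XS (second-best) and the
# XM methylation-call string. Applied in the fixed order: unique-mapping,
# duplicate marking, XM tagging, non-conversion filtering.

.require_cols <- function(records, cols) {
  miss <- setdiff(cols, names(records))
  if (length(miss))
    stop(sprintf("alignment records lack column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
}

#' Keep uniquely mapping records
#'
#' A record maps uniquely when it carries only an AS tag, or when its AS
#' score differs from its XS (second-best) score. Records with AS equal to
#' XS, and unmapped records, are removed. A record carrying XS without AS is
#' malformed.
#'
#' @param records alignment data.frame with columns `qname`, `rname`, `pos`
#'   and optional `AS`, `XS` (NA = tag absent).
#' @return list with `records` (kept rows) and `n_removed`.
#' @export
mark_unique <- function(records) {
  .require_cols(records, c("qname", "rname", "pos"))
  if (is.null(records$AS)) records$AS <- NA_integer_
  if (is.null(records$XS)) records$XS <- NA_integer_
  mapped <- !is.na(records$rname) & !is.na(records$pos)
  if (!is.null(records$flag))
    mapped <- mapped & bitwAnd(records$flag, 4L) == 0L
  bad <- mapped & !is.na(records$XS) & is.na(records$AS)
  if (any(bad))
    stop(sprintf("record(s) with XS but no AS tag: %s",
                 paste(utils::head(records$qname[bad], 3), collapse = ", ")),
         call. = FALSE)
  keep <- mapped & !is.na(records$AS) &
    (is.na(records$XS) | records$AS != records$XS)
  list(records = records[keep, , drop = FALSE],
       n_removed = sum(!keep))
}

.mean_qual <- function(qual) {
  vapply(qual, function(q) mean(.qual_to_int(q)), numeric(1),
         USE.NAMES = FALSE)
}

#' Mark and remove PCR duplicates
#'
#' Duplicates are records aligned to the same position (5' end of the
#' oriented read) on the same strand with the same sequence. Within each
#' duplicate group the record with the highest mean base quality is kept
#' (ties broken by read id).
#'
#' @param records alignment data.frame with `qname`, `rname`, `pos`,
#'   `strand`, `seq`, `qual`.
#' @return list with `records` (deduplicated, original order) and
#'   `n_duplicates`.
#' @export
mark_duplicates <- function(records) {
  .require_cols(records, c("qname", "rname", "pos", "strand", "seq", "qual"))
  if (!nrow(records)) return(list(records = records, n_duplicates = 0L))
  pos5 <- ifelse(records$strand == "-",
                 records$pos + nchar(records$seq) - 1L, records$pos)
  key <- paste(records$rname, pos5, records$strand, records$seq, sep = "\r")
  mq <- .mean_qual(records$qual)
  ord <- order(key, -mq, records$qname)
  first <- !duplicated(key[ord])
  keep_idx <- sort(ord[first])
  list(records = records[keep_idx, , drop = FALSE],
       n_duplicates = nrow(records) - length(keep_idx))
}

.XM_SYMBOL <- c("CpG.methylated" = "Z", "CpG.unmethylated" = "z",
                "CHG.methylated" = "X", "CHG.unmethylated" = "x",
                "CHH.methylated" = "H", "CHH.unmethylated" = "h",
                "Unknown.methylated" = "U", "Unknown.unmethylated" = "u")

#' Attach XM methylation tags to alignment records
#'
#' Builds the per-base methylation-call string of each read from the
#' deconvolution methylation report and attaches it as the `XM` column.
#' For minus-strand alignments the string is reversed so that XM position i
#' annotates mapped base i of the stored (reverse-complemented) sequence.
#'
#' @param records alignment data.frame with `qname`, `strand`, `seq`.
#' @param report methylation report from [methylation_report()].
#' @return `records` with an `XM` character column.
#' @export
add_xm_tag <- function(records, report) {
  .require_cols(records, c("qname", "strand", "seq"))
  missing_ids <- setdiff(records$qname, report$id)
  # reads without any cytosine legitimately have no report rows only if the
  # report was built per-call; treat absence as all-'.' only when the read
  # has no C at all
  lens <- nchar(records$seq)
  xm <- strrep(".", lens)
  if (nrow(report)) {
    rep_use <- report[report$id %in% records$qname, , drop = FALSE]
    if (nrow(rep_use)) {
      sym <- .XM_SYMBOL[paste(rep_use$context, rep_use$state, sep = ".")]
      row <- match(rep_use$id, records$qname)
      # offsets are in read orientation; stored seq of minus-strand records
      # is reverse-complemented, handled by reversing the final string
      for (r in unique(row)) {
        sel <- row == r
        ch <- strsplit(xm[r], "", fixed = TRUE)[[1]]
        ch[rep_use$offset[sel] + 1L] <- sym[sel]
        xm[r] <- paste(ch, collapse = "")
      }
    }
  }
  minus <- records$strand == "-"
  xm[minus] <- .reverse_str(xm[minus])
  n_c <- nchar(gsub("[^C]", "", ifelse(minus, .revcomp(records$seq),
                                       records$seq)))
  unreported <- records$qname %in% missing_ids & n_c > 0L
  if (any(unreported))
    stop(sprintf("read id(s) absent from the methylation report: %s",
                 paste(utils::head(records$qname[unreported], 3),
                       collapse = ", ")), call. = FALSE)
  records$XM <- xm
  records
}

#' Remove reads with incomplete bisulfite conversion
#'
#' A read whose XM string carries `min_non_cpg_meth` or more methylated
#' non-CpG calls (symbols X or H) most likely escaped conversion and is
#' removed.
#'
#' @param records alignment data.frame with an `XM` column.
#' @param min_non_cpg_meth removal threshold (default 3, the default of the
#'   standard non-conversion filter).
#' @return list with `records` (kept) and `n_removed`.
#' @export
filter_non_conversion <- function(records, min_non_cpg_meth = 3L) {
  .require_cols(records, "XM")
  if (any(is.na(records$XM)))
    stop("record(s) without XM tag", call. = FALSE)
  n_bad <- nchar(gsub("[^XH]", "", records$XM))
  keep <- n_bad < min_non_cpg_meth
  list(records = records[keep, , drop = FALSE], n_removed = sum(!keep))
}

#' Construct alignments of simulated reads from ground truth
#'
#' Builds single-end alignment records for deconvolved simulated reads from
#' the simulator's per-read truth table (a perfect aligner on synthetic
#' data; no external aligner is involved). Minus-strand reads are stored
#' reverse-complemented with reversed qualities, as in a SAM file.
#'
#' @param deconv a `DeconvolutionResult` for the simulated pairs.
#' @param reads per-read truth table from [simulate_read_pairs()].
#' @param drop_rejected drop pairs not flagged `deconvolved` (default TRUE).
#' @return alignment data.frame (`qname`, `flag`, `rname`, `pos`, `strand`,
#'   `seq`, `qual`, `AS`, `XS`, `XM`).
#' @export
truth_alignments <- function(deconv, reads, drop_rejected = TRUE) {
  d <- deconv$reads
  if (drop_rejected) d <- d[d$status == "deconvolved", , drop = FALSE]
  tr <- reads[match(d$id, reads$id), , drop = FALSE]
  minus <- tr$strand == "-"
  seq <- d$seq; qual <- d$qual; xm <- d$xm
  seq[minus] <- .revcomp(seq[minus])
  qual[minus] <- .reverse_str(qual[minus])
  xm[minus] <- .reverse_str(xm[minus])
  data.frame(qname = d$id, flag = ifelse(minus, 16L, 0L),
             rname = tr$contig, pos = tr$start + 1L, strand = tr$strand,
             mapq = 42L, seq = seq, qual = qual,
             AS = 0L, XS = NA_integer_, XM = xm,
             stringsAsFactors = FALSE)
}

#' Read single-end alignments from SAM/BAM
#'
#' Parses alignments through Rsamtools (SAM files are converted with
#' `asBam()` first) into the plain data.frame layout used by the filter
#' functions.
#'
#' @param path SAM or BAM file.
#' @return alignment data.frame with `qname`, `flag`, `rname`, `pos`,
#'   `strand`, `mapq`, `seq`, `qual`, `AS`, `XS`, `XM`.
#' @export
read_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading SAM/BAM requires the Rsamtools package", call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "mapq", "seq",
             "qual"),
    tag = c("AS", "XS", "XM"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  data.frame(qname = x$qname, flag = x$flag,
             rname = as.character(x$rname), pos = x$pos,
             strand = as.character(x$strand), mapq = x$mapq,
             seq = as.character(x$seq), qual = as.character(x$qual),
             AS = if (is.null(x$tag$AS)) NA_integer_ else x$tag$AS,
             XS = if (is.null(x$tag$XS)) NA_integer_ else x$tag$XS,
             XM = if (is.null(x$tag$XM)) NA_character_ else x$tag$XM,
             stringsAsFactors = FALSE)
}

#' Write alignment records as SAM
#'
#' Emits a minimal SAM file (with @SQ header lines from `contig_lengths`)
#' carrying the AS, XS and XM tags.
#'
#' @param records alignment data.frame.
#' @param path output path.
#' @param contig_lengths named integer vector of reference lengths.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, contig_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                     as.integer(contig_lengths)), con)
  if (nrow(records)) {
    tags <- character(nrow(records))
    add_tag <- function(tags, val, fmt)
      ifelse(is.na(val), tags, paste0(tags, sprintf(fmt, val)))
    tags <- add_tag(tags, records$AS, "\tAS:i:%d")
    if (!is.null(records$XS)) tags <- add_tag(tags, records$XS, "\tXS:i:%d")
    if (!is.null(records$XM)) tags <- add_tag(tags, records$XM, "\tXM:Z:%s")
    mapq <- if (is.null(records$mapq)) 42L else records$mapq
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s%s",
                       records$qname, records$flag, records$rname,
                       records$pos, mapq, nchar(records$seq), records$seq,
                       records$qual, tags), con)
  }
  invisible(path)
}
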