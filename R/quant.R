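# Per-site methylation pileups, conversion-rate estimation, region (CpG
# island) methylation and allele-specific read splitting.

#' Pile up methylation calls from XM-tagged alignments
#'
#' Every CpG/CHG/CHH symbol of each XM string contributes one call at its
#' mapped genomic coordinate (record position + string offset; XM strings
#' are stored in mapped orientation). Uppercase symbols increment both the
#' methylated count X and the total N, lowercase only N. Unknown-context
#' calls (U/u) are excluded.
#'
#' @param records alignment data.frame with `qname`, `rname`, `pos`,
#'   `strand`, `seq`, `XM`.
#' @return data.frame (`contig`, `pos` 1-based, `strand`, `context`, `X`,
#'   `N`) with one row per covered cytosine, sorted by coordinate.
#' @export
pileup_methylation <- function(records) {
  .require_cols(records, c("rname", "pos", "strand", "XM"))
  empty <- data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      X = integer(0), N = integer(0))
  if (!nrow(records)) return(empty)
  if (!is.null(records$seq) &&
      any(nchar(records$XM) != nchar(records$seq)))
    stop("XM length differs from sequence length for some record(s)",
         call. = FALSE)
  sym <- unlist(strsplit(records$XM, "", fixed = TRUE), use.names = FALSE)
  row <- rep(seq_len(nrow(records)), nchar(records$XM))
  off <- sequence(nchar(records$XM)) - 1L
  keep <- sym %in% c("Z", "z", "X", "x", "H", "h")
  if (!any(keep)) return(empty)
  sym <- sym[keep]; row <- row[keep]; off <- off[keep]
  dt <- data.table::data.table(
    contig = records$rname[row],
    pos = records$pos[row] + off,
    strand = records$strand[row],
    context = c(Z = "CpG", z = "CpG", X = "CHG", x = "CHG",
                H = "CHH", h = "CHH")[sym],
    meth = sym %in% c("Z", "X", "H"))
  agg <- dt[, list(X = sum(meth), N = .N),
            by = c("contig", "pos", "strand", "context")]
  data.table::setorderv(agg, c("contig", "pos", "strand"))
  as.data.frame(agg)
}

#' Estimate the bisulfite conversion rate
#'
#' Computes 100 * sum(N - X) / sum(N) over a selected subset of the pileup:
#' either all calls on designated unmethylated control contigs (spike-in
#' mode) or all CHG+CHH calls genome-wide (context mode).
#'
#' @param pileup result of [pileup_methylation()].
#' @param contigs optional character vector of control contig names.
#' @param contexts optional character vector of contexts (e.g.
#'   `c("CHG", "CHH")`).
#' @return conversion rate in percent.
#' @export
conversion_rate <- function(pileup, contigs = NULL, contexts = NULL) {
  sel <- rep(TRUE, nrow(pileup))
  if (!is.null(contigs)) sel <- sel & pileup$contig %in% contigs
  if (!is.null(contexts)) sel <- sel & pileup$context %in% contexts
  N <- sum(pileup$N[sel]); X <- sum(pileup$X[sel])
  if (N == 0)
    stop("no methylation calls in the selected subset; cannot estimate a conversion rate",
         call. = FALSE)
  100 * (N - X) / N
}

#' Compute per-region methylation levels
#'
#' Region methylation = (number of methylated CpG calls in the region) /
#' (number of CpG calls in the region); regions whose CpG-call coverage is
#' below `min_coverage` are reported but flagged `filtered`, with `NA`
#' level when they contain no calls at all.
#'
#' @param pileup result of [pileup_methylation()].
#' @param regions data.frame with `contig`, `start`, `end` (0-based
#'   half-open) and optional `name`.
#' @param min_coverage minimum CpG-call coverage for a region to pass
#'   (default 50, kept when coverage >= 50).
#' @param contexts contexts counted (default CpG only).
#' @return data.frame (`name`, `contig`, `start`, `end`, `coverage`,
#'   `level`, `filtered`).
#' @export
region_methylation <- function(pileup, regions, min_coverage = 50L,
                               contexts = "CpG") {
  stopifnot(all(c("contig", "start", "end") %in% names(regions)))
  if (any(!(regions$start < regions$end)))
    stop("malformed region interval: start must be < end", call. = FALSE)
  if (is.null(regions$name))
    regions$name <- sprintf("region_%d", seq_len(nrow(regions)))
  p <- pileup[pileup$context %in% contexts, , drop = FALSE]
  out <- regions[, c("name", "contig", "start", "end")]
  out$coverage <- 0L
  out$level <- NA_real_
  for (i in seq_len(nrow(regions))) {
    sel <- p$contig == regions$contig[i] &
      (p$pos - 1L) >= regions$start[i] & (p$pos - 1L) < regions$end[i]
    N <- sum(p$N[sel])
    out$coverage[i] <- N
    if (N > 0) out$level[i] <- sum(p$X[sel]) / N
  }
  out$filtered <- out$coverage < min_coverage
  out
}

#' Define a heterozygous SNP
#'
#' @param contig contig name.
#' @param pos 1-based position.
#' @param ref,alt single-nucleotide REF/ALT alleles (must differ).
#' @return a `HetSNP` list.
#' @export
het_snp <- function(contig, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) != 1L || nchar(alt) != 1L ||
      !all(c(ref, alt) %in% c("A", "C", "G", "T")))
    stop("REF and ALT must be single nucleotides", call. = FALSE)
  if (ref == alt) stop("REF and ALT must differ", call. = FALSE)
  structure(list(contig = contig, pos = as.integer(pos), ref = ref,
                 alt = alt), class = "HetSNP")
}

#' Split alignments by the allele carried at a heterozygous SNP
#'
#' Reads covering the SNP position are assigned to the REF or ALT group by
#' the read base observed there (deconvolved reads are four-base, so the
#' comparison is direct); any other base, or N, leaves the read unassigned.
#' The three groups partition the covering reads.
#'
#' @param records alignment data.frame (`rname`, `pos`, `seq`, ...).
#' @param snp a [het_snp()].
#' @return list with `ref`, `alt`, `unassigned` (data.frames) and
#'   `n_overlapping`.
#' @export
split_by_allele <- function(records, snp) {
  stopifnot(inherits(snp, "HetSNP"))
  .require_cols(records, c("rname", "pos", "seq"))
  off <- snp$pos - records$pos            # 0-based offset into mapped seq
  covers <- records$rname == snp$contig & off >= 0L & off < nchar(records$seq)
  if (!any(covers))
    warning(sprintf("no read covers %s:%d", snp$contig, snp$pos))
  base <- rep(NA_character_, nrow(records))
  base[covers] <- substring(records$seq[covers], off[covers] + 1L,
                            off[covers] + 1L)
  list(ref = records[covers & base == snp$ref, , drop = FALSE],
       alt = records[covers & base == snp$alt, , drop = FALSE],
       unassigned = records[covers & !(base %in% c(snp$ref, snp$alt)), ,
                            drop = FALSE],
       n_overlapping = sum(covers))
}

#' Export allele-split methylation tables
#'
#' Piles up CpG methylation separately for the REF and ALT read groups of
#' [split_by_allele()] and returns the four-column per-site tables (`chr`,
#' `pos`, `N`, `X`) consumed by downstream differential-methylation tools,
#' together with the recommended test thresholds (delta = 0.1,
#' p.threshold = 0.05) passed through for the caller's configuration.
#'
#' @param ref_group,alt_group XM-tagged alignment data.frames.
#' @param contexts contexts to export (default CpG).
#' @return list with `ref`, `alt` (data.frames `chr`, `pos`, `N`, `X`) and
#'   `dss_params`.
#' @export
allele_methylation_tables <- function(ref_group, alt_group,
                                      contexts = "CpG") {
  to_table <- function(g) {
    if (!nrow(g))
      return(data.frame(chr = character(0), pos = integer(0),
                        N = integer(0), X = integer(0)))
    p <- pileup_methylation(g)
    p <- p[p$context %in% contexts, , drop = FALSE]
    data.frame(chr = p$contig, pos = p$pos, N = p$N, X = p$X,
               stringsAsFactors = FALSE)
  }
  list(ref = to_table(ref_group), alt = to_table(alt_group),
       dss_params = list(delta = 0.1, p.threshold = 0.05))
}

#' Write a per-site methylation table in DSS input format
#'
#' @param table data.frame `chr`, `pos`, `N`, `X`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_dss_table <- function(table, path) {
  utils::write.table(table[, c("chr", "pos", "N", "X")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pileup as bedGraph (0-based starts, methylation percent)
#'
#' @param pileup result of [pileup_methylation()].
#' @param path output path.
#' @param contexts contexts to export (default CpG).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(pileup, path, contexts = "CpG") {
  p <- pileup[pileup$context %in% contexts, , drop = FALSE]
  df <- data.frame(chrom = p$contig, start = p$pos - 1L, end = p$pos,
                   value = round(100 * p$X / p$N, 2))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read regions from a BED file
#'
#' @param path BED file (0-based half-open intervals).
#' @return data.frame `contig`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading BED requires the rtracklayer package", call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || all(is.na(nm)))
    nm <- sprintf("region_%d", seq_along(gr))
  out <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,   # back to 0-based
                    end = GenomicRanges::end(gr),
                    name = nm, stringsAsFactors = FALSE)
  if (any(!(out$start < out$end)))
    stop("malformed BED interval: start must be < end", call. = FALSE)
  out
}

#' Read heterozygous SNVs from a VCF file
#'
#' Keeps biallelic single-nucleotide variants with a heterozygous genotype
#' (0/1 or 0|1) in the first sample.
#'
#' @param path VCF path.
#' @return data.frame `contig`, `pos`, `ref`, `alt`.
#' @export
read_het_snps <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fix))
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  gt <- if (!is.null(v@gt) && ncol(v@gt) >= 2L) {
    sub(":.*$", "", vcfR::extract.gt(v, element = "GT")[, 1L])
  } else rep("0/1", nrow(fix))
  keep <- nchar(fix$REF) == 1L & !is.na(fix$ALT) & nchar(fix$ALT) == 1L &
    gt %in% c("0/1", "1/0", "0|1", "1|0")
  data.frame(contig = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
             ref = toupper(fix$REF[keep]), alt = toupper(fix$ALT[keep]),
             stringsAsFactors = FALSE)
}
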