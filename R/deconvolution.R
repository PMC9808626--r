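# Hairpin read-pair deconvolution.
#
# Read1 is the bisulfite-converted original strand, Read2 the unconverted
# copy strand, sequenced cycle-for-cycle from the same fragment end. At each
# cycle: C/C means a methylated C, T/C an unmethylated C, agreement on any
# other base is the true base, and any other combination is a mismatch
# (sequencing error on one mate). The deconvolved read is the recovered
# four-base sequence; methylation calls are reported in the Bismark XM
# alphabet (Z/z CpG, X/x CHG, H/h CHH, U/u unknown context, '.' non-C).

#' Published 46-nt hairpin adapter (U read as T after amplification)
#' @export
HAIRPIN_ADAPTER <- "CCACGACGACGACGACGAGCGTTAGGCTCGTCGTCGTCGTCGTGGT"

#' Illumina TruSeq adapter prefix used for 3'-end trimming
#' @export
ILLUMINA_ADAPTER <- "AGATCGGAAGAGC"

#' Trimming configuration for hairpin bisulfite pairs
#'
#' @param hairpin hairpin adapter sequence (U is treated as T).
#' @param illumina Illumina adapter sequence.
#' @param min_length minimum retained read length after trimming; shorter
#'   pairs are dropped.
#' @param max_mismatch_frac mismatch tolerance of the adapter match.
#' @param min_overlap minimum 3'-anchored overlap to call an adapter match.
#' @param max_len_diff maximum allowed trimmed-length difference between
#'   mates before a pair is rejected in deconvolution.
#' @return a `HairpinConfig` object.
#' @export
hairpin_config <- function(hairpin = HAIRPIN_ADAPTER,
                           illumina = ILLUMINA_ADAPTER,
                           min_length = 30L, max_mismatch_frac = 0.10,
                           min_overlap = 3L, max_len_diff = 0L) {
  hairpin <- chartr("U", "T", toupper(hairpin))
  illumina <- chartr("U", "T", toupper(illumina))
  if (!nzchar(hairpin) || !nzchar(illumina) ||
      grepl("[^ACGT]", hairpin) || grepl("[^ACGT]", illumina))
    stop("adapter sequences must be non-empty ACGT(U) strings", call. = FALSE)
  structure(list(hairpin = hairpin, illumina = illumina,
                 min_length = as.integer(min_length),
                 max_mismatch_frac = max_mismatch_frac,
                 min_overlap = as.integer(min_overlap),
                 max_len_diff = as.integer(max_len_diff)),
            class = "HairpinConfig")
}

# 3'-anchored adapter scan: earliest start i (1-based) such that the read
# suffix matches the adapter prefix with <= max_mismatch_frac mismatches
# over an overlap of >= min_overlap; returns trimmed length (i - 1), or
# nchar(seq) when no match
.trim_one <- function(chars, adapters, max_mm_frac, min_ov) {
  L <- length(chars)
  for (i in seq_len(max(L - min_ov + 1L, 0L))) {
    for (ad in adapters) {
      ov <- min(L - i + 1L, length(ad))
      if (ov < min_ov) next
      mm <- sum(chars[i:(i + ov - 1L)] != ad[seq_len(ov)])
      if (mm <= floor(max_mm_frac * ov)) return(i - 1L)
    }
  }
  L
}

#' Trim hairpin and Illumina adapters from read pairs
#'
#' Removes 3'-anchored adapter occurrences from each mate, then truncates
#' both mates to the shorter mate's length. Pairs retaining less than
#' `config$min_length` bases are dropped.
#'
#' @param r1,r2 data.frames with columns `id`, `seq`, `qual` (mate 1 =
#'   converted strand, mate 2 = copy strand), row-matched.
#' @param config a [hairpin_config()].
#' @return list with `pairs` (data.frame `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`) and `n_dropped`.
#' @export
trim_pairs <- function(r1, r2, config = hairpin_config()) {
  stopifnot(nrow(r1) == nrow(r2), all(r1$id == r2$id))
  if (any(nchar(r1$seq) != nchar(r1$qual)) ||
      any(nchar(r2$seq) != nchar(r2$qual)))
    stop(sprintf(
      "malformed FASTQ record (sequence/quality length mismatch), e.g. '%s'",
      c(r1$id[nchar(r1$seq) != nchar(r1$qual)],
        r2$id[nchar(r2$seq) != nchar(r2$qual)])[1]), call. = FALSE)
  adapters <- lapply(c(config$hairpin, config$illumina),
                     function(a) strsplit(a, "", fixed = TRUE)[[1]])
  trim_len <- function(seqs) {
    ch <- strsplit(toupper(seqs), "", fixed = TRUE)
    vapply(ch, .trim_one, integer(1), adapters = adapters,
           max_mm_frac = config$max_mismatch_frac,
           min_ov = config$min_overlap)
  }
  l1 <- trim_len(r1$seq)
  l2 <- trim_len(r2$seq)
  keep_len <- pmin(l1, l2)
  kept <- keep_len >= config$min_length
  pairs <- data.frame(id = r1$id[kept],
                      seq1 = toupper(substring(r1$seq[kept], 1L, keep_len[kept])),
                      qual1 = substring(r1$qual[kept], 1L, keep_len[kept]),
                      seq2 = toupper(substring(r2$seq[kept], 1L, keep_len[kept])),
                      qual2 = substring(r2$qual[kept], 1L, keep_len[kept]),
                      stringsAsFactors = FALSE)
  list(pairs = pairs, n_dropped = sum(!kept))
}

#' Classify one sequencing cycle of a read pair
#'
#' Total partition of the 25 (Read1, Read2) base combinations: `AMBIGUOUS`
#' (either base N), `METH_C` (C/C), `UNMETH_C` (T/C), `AGREE` (equal non-C
#' bases) and `MISMATCH` (everything else).
#'
#' @param b1,b2 equal-length character vectors of Read1/Read2 bases
#'   (A/C/G/T/N).
#' @return character vector of class labels.
#' @export
classify_position <- function(b1, b2) {
  b1 <- toupper(b1); b2 <- toupper(b2)
  if (length(b1) != length(b2))
    stop("b1 and b2 must have equal length", call. = FALSE)
  ok <- c("A", "C", "G", "T", "N")
  if (!all(b1 %in% ok) || !all(b2 %in% ok))
    stop("bases must be one of A, C, G, T, N", call. = FALSE)
  out <- rep("MISMATCH", length(b1))
  out[b1 == b2 & b1 != "C"] <- "AGREE"
  out[b1 == "C" & b2 == "C"] <- "METH_C"
  out[b1 == "T" & b2 == "C"] <- "UNMETH_C"
  out[b1 == "N" | b2 == "N"] <- "AMBIGUOUS"
  out
}

# context symbols from a deconvolved-base character matrix; returns XM
# matrix. `state` TRUE = methylated (uppercase). Positions not flagged in
# `is_call` stay '.'.
.xm_matrix <- function(base_mat, is_call, state_mat, uncalled_c) {
  m <- nrow(base_mat); w <- ncol(base_mat)
  xm <- matrix(".", m, w)
  if (m == 0L || w == 0L) return(xm)
  pad <- matrix("N", m, 2L)
  nx1 <- cbind(base_mat[, -1L, drop = FALSE], pad[, 1L, drop = FALSE])
  nx2 <- if (w >= 2L) cbind(base_mat[, -(1:2), drop = FALSE], pad) else
    pad[, 1L, drop = FALSE]
  near_end <- matrix(rep(seq_len(w) > w - 2L, each = m), m, w)
  unknown <- near_end | nx1 == "N" | (nx1 != "G" & nx2 == "N")
  sym <- matrix("", m, w)
  sym[is_call] <- ifelse(unknown[is_call], "u",
                    ifelse(nx1[is_call] == "G", "z",
                      ifelse(nx2[is_call] == "G", "x", "h")))
  up <- is_call & state_mat
  sym[up] <- toupper(sym[up])
  xm[is_call] <- sym[is_call]
  xm[uncalled_c] <- "u"
  xm
}

# core batch deconvolution over equal-length pairs (character matrices)
.deconvolve_group <- function(ids, s1, q1, s2, q2, L, reject_frac,
                              calibration, ref) {
  m <- length(ids)
  b1 <- .char_matrix(s1, L); b2 <- .char_matrix(s2, L)
  qi1 <- matrix(.qual_to_int(q1), m, L, byrow = TRUE)
  qi2 <- matrix(.qual_to_int(q2), m, L, byrow = TRUE)

  amb <- b1 == "N" | b2 == "N"
  meth <- !amb & b1 == "C" & b2 == "C"
  unmeth <- !amb & b1 == "T" & b2 == "C"
  agree <- !amb & b1 == b2 & b1 != "C"
  mism <- !(amb | meth | unmeth | agree)

  base <- b1
  base[meth | unmeth] <- "C"
  base[amb] <- "N"

  q <- pmin(qi1, qi2)
  q[amb] <- 0L
  if (is.null(calibration)) {
    q[mism] <- 0L
  } else {
    idx <- which(mism)
    cyc <- ((idx - 1L) %/% m)            # 0-based cycle
    rb <- if (is.null(ref)) rep(NA_character_, length(idx)) else {
      .char_matrix(ref, L)[idx]
    }
    q[idx] <- calibration_q(calibration, a = b1[idx], b = b2[idx],
                            cycle = cyc, r = rb)
  }

  is_call <- meth | unmeth
  uncalled_c <- mism & b1 == "C"         # deconvolved base is C, state unknown
  xm <- .xm_matrix(base, is_call, meth, uncalled_c)

  mism_frac <- rowSums(mism) / L
  status <- ifelse(mism_frac > reject_frac, "rejected", "deconvolved")

  mlist <- which(mism, arr.ind = TRUE)
  mismatches <- data.frame(id = ids[mlist[, 1L]],
                           cycle = mlist[, 2L] - 1L,
                           b1 = b1[mlist], b2 = b2[mlist],
                           stringsAsFactors = FALSE)

  list(reads = data.frame(id = ids, seq = .collapse_rows(base),
                          qual = .collapse_rows(
                            matrix(.int_to_qual_chars(q), m, L)),
                          xm = .collapse_rows(xm),
                          status = status, mismatch_frac = mism_frac,
                          stringsAsFactors = FALSE),
       mismatches = mismatches,
       tallies = c(AGREE = sum(agree), METH_C = sum(meth),
                   UNMETH_C = sum(unmeth), MISMATCH = sum(mism),
                   AMBIGUOUS = sum(amb)))
}

#' Deconvolve trimmed read pairs
#'
#' Applies the per-cycle pairing rules to every pair and assembles the
#' deconvolved read, its adjusted quality string and its XM methylation
#' string. In reference-free mode mismatch positions keep the Read1 base
#' with quality 0; with a [build_calibration_table()] result the empirical
#' posterior quality is assigned instead. Pairs whose mismatch fraction
#' exceeds `reject_frac` are marked `rejected` (undeconvolvable).
#'
#' Cytosine context is read from the deconvolved sequence itself (next base
#' G: CpG; base after next G: CHG; else CHH); cytosines within 2 nt of the
#' read end, or with N in their context window, are reported as unknown
#' (U/u). A mismatch position whose retained Read1 base is C is annotated
#' 'u' (cytosine of unknown state) so that every C carries one symbol.
#'
#' @param pairs data.frame `id`, `seq1`, `qual1`, `seq2`, `qual2` (from
#'   [trim_pairs()] or the simulator).
#' @param reject_frac mismatch-fraction threshold above which a pair is
#'   rejected (default 0.10).
#' @param calibration optional `CalibrationTable` for reference-dependent
#'   quality adjustment.
#' @param ref optional character vector of reference sequences in read
#'   orientation (one per pair) giving the aligned reference base per cycle;
#'   when absent, calibrated lookups marginalize over the reference base.
#' @param max_len_diff maximum tolerated mate length difference; pairs
#'   beyond it are rejected.
#' @return a `DeconvolutionResult`: list with `reads` (data.frame `id`,
#'   `seq`, `qual`, `xm`, `status`, `mismatch_frac`), `mismatches`
#'   (data.frame `id`, `cycle`, `b1`, `b2` of mismatch positions) and
#'   `summary`.
#' @export
deconvolve_pairs <- function(pairs, reject_frac = 0.10, calibration = NULL,
                             ref = NULL, max_len_diff = 0L) {
  stopifnot(all(c("id", "seq1", "qual1", "seq2", "qual2") %in% names(pairs)))
  n1 <- nchar(pairs$seq1); n2 <- nchar(pairs$seq2)
  bad_len <- abs(n1 - n2) > max_len_diff
  L <- pmin(n1, n2)

  groups <- split(seq_len(nrow(pairs))[!bad_len], L[!bad_len])
  reads <- list(); mismatches <- list()
  tallies <- c(AGREE = 0, METH_C = 0, UNMETH_C = 0, MISMATCH = 0,
               AMBIGUOUS = 0)
  for (g in groups) {
    Lg <- L[g[1L]]
    if (Lg == 0L) next
    res <- .deconvolve_group(
      ids = pairs$id[g],
      s1 = substring(pairs$seq1[g], 1L, Lg),
      q1 = substring(pairs$qual1[g], 1L, Lg),
      s2 = substring(pairs$seq2[g], 1L, Lg),
      q2 = substring(pairs$qual2[g], 1L, Lg),
      L = Lg, reject_frac = reject_frac, calibration = calibration,
      ref = if (is.null(ref)) NULL else substring(ref[g], 1L, Lg))
    reads[[length(reads) + 1L]] <- res$reads
    mismatches[[length(mismatches) + 1L]] <- res$mismatches
    tallies <- tallies + res$tallies
  }
  if (any(bad_len)) {
    reads[[length(reads) + 1L]] <- data.frame(
      id = pairs$id[bad_len], seq = "", qual = "", xm = "",
      status = "rejected", mismatch_frac = NA_real_,
      stringsAsFactors = FALSE)
  }
  reads <- if (length(reads)) do.call(rbind, reads) else
    data.frame(id = character(0), seq = character(0), qual = character(0),
               xm = character(0), status = character(0),
               mismatch_frac = numeric(0))
  reads <- reads[match(pairs$id, reads$id), , drop = FALSE]
  rownames(reads) <- NULL
  mismatches <- if (length(mismatches)) do.call(rbind, mismatches) else
    data.frame(id = character(0), cycle = integer(0), b1 = character(0),
               b2 = character(0))
  out <- list(reads = reads, mismatches = mismatches,
              summary = list(total = nrow(pairs),
                             deconvolved = sum(reads$status == "deconvolved"),
                             rejected = sum(reads$status == "rejected"),
                             position_tallies = as.list(tallies)))
  class(out) <- "DeconvolutionResult"
  out
}

#' Deconvolve a single read pair
#'
#' Convenience scalar interface over [deconvolve_pairs()].
#'
#' @param seq1,seq2 mate sequences (equal length after trimming).
#' @param qual1,qual2 quality strings; default constant Q37.
#' @param ... passed to [deconvolve_pairs()] (`reject_frac`, `calibration`,
#'   `ref`, ...).
#' @return list with `sequence`, `quality`, `methylation`, `status`,
#'   `mismatch_frac`.
#' @examples
#' deconvolve_pair("TACGT", "CACGT")$methylation  # "h.Z.."
#' @export
deconvolve_pair <- function(seq1, seq2, qual1 = NULL, qual2 = NULL, ...) {
  if (is.null(qual1)) qual1 <- strrep(.QCHARS[38L], nchar(seq1))
  if (is.null(qual2)) qual2 <- strrep(.QCHARS[38L], nchar(seq2))
  res <- deconvolve_pairs(data.frame(id = "pair", seq1 = toupper(seq1),
                                     qual1 = qual1, seq2 = toupper(seq2),
                                     qual2 = qual2,
                                     stringsAsFactors = FALSE), ...)
  r <- res$reads[1L, ]
  list(sequence = r$seq, quality = r$qual, methylation = r$xm,
       status = r$status, mismatch_frac = r$mismatch_frac)
}

#' Deconvolve a single pair with calibrated mismatch qualities
#'
#' Identical to [deconvolve_pair()] except that mismatch positions receive
#' the empirical posterior quality from `table` instead of 0.
#'
#' @inheritParams deconvolve_pair
#' @param table a `CalibrationTable`.
#' @param ref optional reference sequence in read orientation.
#' @export
calibrate_pair <- function(seq1, seq2, table, qual1 = NULL, qual2 = NULL,
                           ref = NULL, ...) {
  deconvolve_pair(seq1, seq2, qual1 = qual1, qual2 = qual2,
                  calibration = table, ref = ref, ...)
}

#' Extract the per-read methylation report
#'
#' @param deconv a `DeconvolutionResult`.
#' @return data.frame `id`, `offset` (0-based position in the deconvolved
#'   read), `context` (`CpG`, `CHG`, `CHH`, `Unknown`), `state`
#'   (`methylated`/`unmethylated`) for every called cytosine of accepted
#'   reads.
#' @export
methylation_report <- function(deconv) {
  reads <- deconv$reads[deconv$reads$status == "deconvolved", , drop = FALSE]
  if (!nrow(reads))
    return(data.frame(id = character(0), offset = integer(0),
                      context = character(0), state = character(0)))
  sym <- unlist(strsplit(reads$xm, "", fixed = TRUE), use.names = FALSE)
  row <- rep(seq_len(nrow(reads)), nchar(reads$xm))
  off <- sequence(nchar(reads$xm)) - 1L
  keep <- sym != "."
  sym <- sym[keep]; row <- row[keep]; off <- off[keep]
  ctx <- c(Z = "CpG", z = "CpG", X = "CHG", x = "CHG",
           H = "CHH", h = "CHH", U = "Unknown", u = "Unknown")[sym]
  data.frame(id = reads$id[row], offset = off, context = unname(ctx),
             state = ifelse(sym %in% c("Z", "X", "H", "U"),
                            "methylated", "unmethylated"),
             stringsAsFactors = FALSE)
}

#' Summarize a deconvolution batch
#'
#' @param deconv a `DeconvolutionResult`.
#' @param trim optional result of [trim_pairs()] contributing the
#'   dropped-in-trim count.
#' @return list of counts: `total`, `deconvolved`, `rejected`,
#'   `dropped_in_trim`, `position_tallies`.
#' @export
deconvolution_summary <- function(deconv, trim = NULL) {
  s <- deconv$summary
  s$dropped_in_trim <- if (is.null(trim)) 0L else trim$n_dropped
  s$total <- s$total + s$dropped_in_trim
  s
}

# ---- reference-dependent quality calibration --------------------------------

.as_contigs <- function(genome) {
  if (inherits(genome, "SimGenome")) return(genome$contigs)
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome); names(out) <- names(genome); return(out)
  }
  if (is.character(genome) && !is.null(names(genome))) return(toupper(genome))
  stop("`genome` must be a SimGenome, DNAStringSet or named character vector",
       call. = FALSE)
}

#' Build an empirical base-quality calibration table
#'
#' For every mismatch position of every aligned deconvolved read, the
#' stratum (reference base r, Read1 base a, Read2 base b, cycle bin c) is
#' incremented, counting a success when the Read1 base equals the reference
#' base. The posterior probability that Read1 can be trusted is the
#' Beta(1,1) posterior mean p = (x+1)/(N+2), reported as an adjusted Phred
#' score Q = round(-10 log10(1-p)) capped at 41. A stratum never observed
#' falls back to the prior (p = 1/2, Q = 3). A companion table marginalized
#' over the reference base serves lookups made before alignment.
#'
#' @param deconv a `DeconvolutionResult` (its `mismatches` element is used).
#' @param alignments data.frame of uniquely aligned reads: `qname`, `rname`,
#'   `pos` (1-based leftmost), `strand` (`+`/`-`).
#' @param genome reference sequences (`SimGenome`, `DNAStringSet`, or named
#'   character vector).
#' @param bin_width sequencing-cycle bin width (default 10).
#' @return a `CalibrationTable`.
#' @export
build_calibration_table <- function(deconv, alignments, genome,
                                    bin_width = 10L) {
  contigs <- .as_contigs(genome)
  mm <- deconv$mismatches
  rl <- nchar(deconv$reads$seq)[match(mm$id, deconv$reads$id)]
  al <- alignments[match(mm$id, alignments$qname), , drop = FALSE]
  keep <- !is.na(al$pos)
  mm <- mm[keep, , drop = FALSE]; al <- al[keep, , drop = FALSE]
  rl <- rl[keep]
  missing_ctg <- setdiff(unique(al$rname), names(contigs))
  if (length(missing_ctg))
    stop(sprintf("reference contig(s) not found: %s",
                 paste(missing_ctg, collapse = ", ")), call. = FALSE)
  refpos <- ifelse(al$strand == "-", al$pos + (rl - 1L - mm$cycle),
                   al$pos + mm$cycle)                      # 1-based
  rbase <- substring(contigs[al$rname], refpos, refpos)
  rbase <- ifelse(al$strand == "-",
                  chartr("ACGT", "TGCA", rbase), rbase)    # read orientation
  ok <- rbase %in% c("A", "C", "G", "T")
  dt <- data.table::data.table(r = rbase[ok], a = mm$b1[ok], b = mm$b2[ok],
                               bin = mm$cycle[ok] %/% as.integer(bin_width),
                               success = mm$b1[ok] == rbase[ok])
  agg <- dt[, list(x = sum(success), N = .N), by = c("r", "a", "b", "bin")]
  agg[, c("p", "Q") := {
    p <- (x + 1) / (N + 2)
    list(p, pmin(as.integer(round(-10 * log10(1 - p))), 41L))
  }]
  marg <- dt[, list(x = sum(success), N = .N), by = c("a", "b", "bin")]
  marg[, c("p", "Q") := {
    p <- (x + 1) / (N + 2)
    list(p, pmin(as.integer(round(-10 * log10(1 - p))), 41L))
  }]
  data.table::setkeyv(agg, c("r", "a", "b", "bin"))
  data.table::setkeyv(marg, c("a", "b", "bin"))
  structure(list(strata = agg, marginal = marg,
                 bin_width = as.integer(bin_width)),
            class = "CalibrationTable")
}

#' Look up calibrated mismatch qualities
#'
#' @param table a `CalibrationTable`.
#' @param a,b Read1/Read2 bases at the mismatch.
#' @param cycle 0-based sequencing cycle.
#' @param r reference base in read orientation, or `NA` to use the
#'   marginal table.
#' @return integer vector of Phred scores (3 for unobserved strata).
#' @export
calibration_q <- function(table, a, b, cycle, r = NA) {
  stopifnot(inherits(table, "CalibrationTable"))
  n <- max(length(a), length(b), length(cycle), length(r))
  a <- rep_len(a, n); b <- rep_len(b, n)
  bin <- rep_len(as.integer(cycle), n) %/% table$bin_width
  r <- rep_len(r, n)
  q <- rep(3L, n)
  has_r <- !is.na(r)
  if (any(has_r)) {
    key <- data.table::data.table(r = r[has_r], a = a[has_r], b = b[has_r],
                                  bin = bin[has_r])
    hit <- table$strata[key, on = c("r", "a", "b", "bin")]$Q
    q[has_r][!is.na(hit)] <- hit[!is.na(hit)]
  }
  if (any(!has_r)) {
    key <- data.table::data.table(a = a[!has_r], b = b[!has_r],
                                  bin = bin[!has_r])
    hit <- table$marginal[key, on = c("a", "b", "bin")]$Q
    q[!has_r][!is.na(hit)] <- hit[!is.na(hit)]
  }
  q
}
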