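# Protocol-faithful simulator for hairpin-linked bisulfite read pairs.
#
# Each simulated fragment yields a Read1 (bisulfite-converted strand) and a
# Read2 (four-base copy strand) emitted cycle-for-cycle from the same
# fragment end, so that position i of Read1 and position i of Read2 report
# the same original base. Ground truth (per-site methylation and per-read
# fragment coordinates) is returned alongside the reads.

#' Generate a random genome
#'
#' Draws an i.i.d. nucleotide sequence with a target GC content. Used as the
#' substrate for simulation; user-supplied sequences can be wrapped with
#' [sim_genome()].
#'
#' @param length contig length in bp (> 0).
#' @param gc target GC fraction in `[0, 1]`.
#' @param seed integer seed; identical calls reproduce the same contig.
#' @param name contig name.
#' @return a `SimGenome` object (list with `contigs`, a named character
#'   vector, and `origin`).
#' @examples
#' g <- generate_genome(1000, gc = 0.5, seed = 1)
#' nchar(g$contigs)
#' @export
generate_genome <- function(length, gc = 0.5, seed = 1L, name = "contig1") {
  if (!is.numeric(length) || length(length) != 1L || length <= 0)
    stop("`length` must be a positive number", call. = FALSE)
  .stopifnot_prob(gc, "gc")
  set.seed(as.integer(seed))
  bases <- sample(c("A", "C", "G", "T"), size = as.integer(length),
                  replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  seqs <- paste(bases, collapse = "")
  names(seqs) <- name
  sim_genome(seqs, origin = "random")
}

#' Wrap nucleotide sequences as a simulation genome
#'
#' @param contigs named character vector of ACGT sequences.
#' @param origin `"random"` or `"user-supplied"`.
#' @return a `SimGenome` object.
#' @export
sim_genome <- function(contigs, origin = "user-supplied") {
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    names(contigs) <- paste0("contig", seq_along(contigs))
  contigs <- toupper(contigs)
  if (any(nchar(contigs) == 0L))
    stop("contig sequences must be non-empty", call. = FALSE)
  if (any(grepl("[^ACGT]", contigs)))
    stop("contig alphabet restricted to A/C/G/T", call. = FALSE)
  structure(list(contigs = contigs, origin = origin), class = "SimGenome")
}

#' Combine the contigs of several simulation genomes
#'
#' @param ... `SimGenome` objects with distinct contig names.
#' @return a single `SimGenome`.
#' @export
combine_genomes <- function(...) {
  gs <- list(...)
  contigs <- do.call(c, lapply(gs, `[[`, "contigs"))
  if (anyDuplicated(names(contigs)))
    stop("contig names must be distinct when combining genomes", call. = FALSE)
  sim_genome(contigs, origin = "user-supplied")
}

#' Write a simulation genome to FASTA
#'
#' @param genome a `SimGenome`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Specify a methylation model
#'
#' Two modes are supported. `"rate"` emulates vertebrate CpG methylation:
#' each CpG cytosine is methylated independently with probability
#' `cpg_rate`. By default methylation is applied symmetrically to both
#' cytosines of a CpG dyad (`symmetric = TRUE`), matching the palindromic
#' maintenance methylation of real genomes; `symmetric = FALSE` restricts
#' it to top-strand cytosines. `"motif"` emulates prokaryotic
#' methyltransferases: every occurrence of each IUPAC motif, on either
#' strand, is methylated at the stated cytosine offset with the stated
#' efficiency.
#'
#' @param mode `"rate"` or `"motif"`.
#' @param cpg_rate per-CpG methylation probability (rate mode).
#' @param motifs data.frame with columns `pattern` (IUPAC string), `offset`
#'   (0-based index of the methylated C within the pattern) and
#'   `efficiency` (probability in `[0, 1]`); motif mode.
#' @param symmetric rate mode only: methylate both strands of each CpG dyad.
#' @return a `MethylationModel` object.
#' @examples
#' methylation_model("rate", cpg_rate = 0.453)
#' methylation_model("motif",
#'   motifs = data.frame(pattern = "CCWGG", offset = 1, efficiency = 1))
#' @export
methylation_model <- function(mode = c("rate", "motif"), cpg_rate = 0,
                              motifs = NULL, symmetric = TRUE) {
  mode <- match.arg(mode)
  if (mode == "rate") {
    .stopifnot_prob(cpg_rate, "cpg_rate")
  } else {
    if (is.null(motifs) || nrow(motifs) == 0L)
      stop("motif mode requires a non-empty `motifs` data.frame",
           call. = FALSE)
    stopifnot(all(c("pattern", "offset", "efficiency") %in% names(motifs)))
    for (i in seq_len(nrow(motifs))) {
      pat <- toupper(motifs$pattern[i])
      off <- motifs$offset[i]
      if (off < 0 || off >= nchar(pat))
        stop("motif offset out of range", call. = FALSE)
      code <- substr(pat, off + 1L, off + 1L)
      if (!grepl("C", Biostrings::IUPAC_CODE_MAP[[code]], fixed = TRUE))
        stop(sprintf(
          "motif offset %d of '%s' is '%s', whose IUPAC code does not include C",
          off, pat, code), call. = FALSE)
      .stopifnot_prob(motifs$efficiency[i], "efficiency")
      motifs$pattern[i] <- pat
    }
  }
  structure(list(mode = mode, cpg_rate = cpg_rate, motifs = motifs,
                 symmetric = isTRUE(symmetric)),
            class = "MethylationModel")
}

.empty_truth <- function() {
  data.frame(contig = character(0), pos = integer(0), strand = character(0),
             methylated = logical(0), stringsAsFactors = FALSE)
}

#' Assign ground-truth methylation states to a genome
#'
#' Returns the set of methylated cytosines under a [methylation_model()];
#' every cytosine not listed is unmethylated. Positions are 0-based.
#' `strand` gives the strand whose base is the methylated C (`"-"` rows sit
#' on a top-strand G).
#'
#' @param genome a `SimGenome`.
#' @param model a `MethylationModel`.
#' @param seed integer seed for the Bernoulli draws.
#' @return data.frame (`contig`, `pos`, `strand`, `methylated`) with one row
#'   per methylated cytosine.
#' @export
assign_methylation <- function(genome, model, seed = 1L) {
  stopifnot(inherits(genome, "SimGenome"), inherits(model, "MethylationModel"))
  set.seed(as.integer(seed))
  rows <- list()
  for (ctg in names(genome$contigs)) {
    s <- Biostrings::DNAString(genome$contigs[[ctg]])
    if (model$mode == "rate") {
      if (model$cpg_rate > 0) {
        cg <- Biostrings::start(Biostrings::matchPattern("CG", s))
        if (length(cg)) {
          top <- cg - 1L                      # 0-based C on the plus strand
          keep <- stats::runif(length(top)) < model$cpg_rate
          if (any(keep))
            rows[[length(rows) + 1L]] <- data.frame(
              contig = ctg, pos = top[keep], strand = "+", methylated = TRUE,
              stringsAsFactors = FALSE)
          if (model$symmetric) {
            keep2 <- stats::runif(length(top)) < model$cpg_rate
            if (any(keep2))
              rows[[length(rows) + 1L]] <- data.frame(
                contig = ctg, pos = top[keep2] + 1L, strand = "-",
                methylated = TRUE, stringsAsFactors = FALSE)
          }
        }
      }
    } else {
      chars <- strsplit(as.character(s), "", fixed = TRUE)[[1]]
      for (i in seq_len(nrow(model$motifs))) {
        pat <- model$motifs$pattern[i]
        off <- as.integer(model$motifs$offset[i])
        eff <- model$motifs$efficiency[i]
        w <- nchar(pat)
        fwd <- Biostrings::start(
          Biostrings::matchPattern(pat, s, fixed = FALSE))
        pos_f <- fwd - 1L + off
        pos_f <- pos_f[chars[pos_f + 1L] == "C"]
        rcp <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(pat)))
        rev <- Biostrings::start(
          Biostrings::matchPattern(rcp, s, fixed = FALSE))
        pos_r <- rev - 1L + (w - 1L - off)
        pos_r <- pos_r[chars[pos_r + 1L] == "G"]   # C on the minus strand
        add <- function(pos, strand) {
          if (!length(pos)) return(NULL)
          keep <- stats::runif(length(pos)) < eff
          if (!any(keep)) return(NULL)
          data.frame(contig = ctg, pos = pos[keep], strand = strand,
                     methylated = TRUE, stringsAsFactors = FALSE)
        }
        rows[[length(rows) + 1L]] <- add(pos_f, "+")
        rows[[length(rows) + 1L]] <- add(pos_r, "-")
      }
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.empty_truth())
  out <- do.call(rbind, rows)
  out <- unique(out)
  out[order(out$contig, out$pos, out$strand), , drop = FALSE]
}

#' Simulation configuration
#'
#' @param n_fragments number of fragments to draw.
#' @param fragment_mean,fragment_sd fragment length distribution (bp);
#'   lengths are normal, rounded, and truncated below at `read_length`.
#' @param read_length read length in bp.
#' @param conversion_rate probability that an unmethylated C on the original
#'   strand is read as T (bisulfite conversion efficiency).
#' @param methylated_retention probability that a methylated C survives
#'   conversion (1 minus the inappropriate-conversion rate).
#' @param seq_error_rate per-base substitution error probability applied to
#'   both mates.
#' @param r1_error_rate,r2_error_rate optional per-mate overrides of
#'   `seq_error_rate`.
#' @param adapter_readthrough when a fragment is shorter than the read
#'   length, continue reading into the hairpin (then Illumina) adapter
#'   instead of emitting a short read.
#' @param undeconvolvable_fraction probability that a pair is emitted as a
#'   conventional (non-hairpin) bisulfite pair, which downstream
#'   deconvolution should reject.
#' @param seed integer seed governing all randomness of the simulator.
#' @return a `SimConfig` object.
#' @export
sim_config <- function(n_fragments = 10000L, fragment_mean = 300,
                       fragment_sd = 50, read_length = 100L,
                       conversion_rate = 0.975, methylated_retention = 1.0,
                       seq_error_rate = 0, r1_error_rate = NULL,
                       r2_error_rate = NULL, adapter_readthrough = FALSE,
                       undeconvolvable_fraction = 0, seed = 1L) {
  .stopifnot_prob(conversion_rate, "conversion_rate")
  .stopifnot_prob(methylated_retention, "methylated_retention")
  .stopifnot_prob(seq_error_rate, "seq_error_rate")
  .stopifnot_prob(undeconvolvable_fraction, "undeconvolvable_fraction")
  if (is.null(r1_error_rate)) r1_error_rate <- seq_error_rate
  if (is.null(r2_error_rate)) r2_error_rate <- seq_error_rate
  .stopifnot_prob(r1_error_rate, "r1_error_rate")
  .stopifnot_prob(r2_error_rate, "r2_error_rate")
  structure(list(n_fragments = as.integer(n_fragments),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 read_length = as.integer(read_length),
                 conversion_rate = conversion_rate,
                 methylated_retention = methylated_retention,
                 seq_error_rate = seq_error_rate,
                 r1_error_rate = r1_error_rate, r2_error_rate = r2_error_rate,
                 adapter_readthrough = isTRUE(adapter_readthrough),
                 undeconvolvable_fraction = undeconvolvable_fraction,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# per-contig, per-strand logical vectors marking methylated cytosines
.truth_index <- function(genome, truth) {
  idx <- lapply(genome$contigs, function(s) {
    n <- nchar(s)
    list("+" = logical(n), "-" = logical(n))
  })
  if (nrow(truth)) {
    for (strand in c("+", "-")) {
      t2 <- truth[truth$strand == strand & truth$methylated, , drop = FALSE]
      if (!nrow(t2)) next
      for (ctg in unique(t2$contig))
        idx[[ctg]][[strand]][t2$pos[t2$contig == ctg] + 1L] <- TRUE
    }
  }
  idx
}

# bisulfite-convert a character matrix in place: unmethylated C -> T with
# prob `conv`, methylated C -> T with prob 1 - retention; `genomic` masks
# adapter fill, which is never converted
.convert_matrix <- function(mat, meth, conv, retention, genomic = NULL) {
  is_c <- mat == "C"
  if (!is.null(genomic)) is_c <- is_c & genomic
  u <- matrix(stats::runif(length(mat)), nrow = nrow(mat))
  flip <- is_c & ((!meth & u < conv) | (meth & u >= retention))
  mat[flip] <- "T"
  mat
}

# inject substitution errors; returns list(mat, err) where err marks changes
.inject_errors <- function(mat, rate) {
  if (rate <= 0 || length(mat) == 0L)
    return(list(mat = mat, err = matrix(FALSE, nrow(mat), ncol(mat))))
  err <- matrix(stats::runif(length(mat)) < rate, nrow = nrow(mat))
  if (any(err)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG", N = "ACGT")
    orig <- mat[err]
    pick <- ceiling(stats::runif(sum(err)) * 3)
    mat[err] <- substring(alt[orig], pick, pick)
  }
  list(mat = mat, err = err)
}

#' Simulate hairpin bisulfite read pairs with ground truth
#'
#' Fragments are drawn uniformly from the genome (both strands). For each
#' fragment, Read2 reports the first `read_length` bases of the fragment
#' verbatim (the copy strand) and Read1 reports the same bases after
#' bisulfite conversion of the original strand, so the two mates are
#' cycle-aligned. A configurable fraction of pairs is instead emitted as
#' conventional bisulfite pairs (both mates converted, second mate from the
#' opposite fragment end), emulating the undeconvolvable molecules that
#' escape hairpin ligation.
#'
#' Base qualities are a constant Q37 baseline with Q11 at injected
#' sequencing-error positions.
#'
#' @param genome a `SimGenome`.
#' @param truth methylation truth from [assign_methylation()] (may be empty
#'   for a fully unmethylated genome).
#' @param config a `SimConfig`.
#' @return list with elements `r1`, `r2` (data.frames `id`, `seq`, `qual`),
#'   `reads` (per-read truth: `id`, `contig`, `start` 0-based leftmost
#'   genome position of the covered segment, `strand`, `width`, `frag_len`,
#'   `undeconvolvable`) and `n_skipped` (fragments skipped on short
#'   contigs).
#' @export
simulate_read_pairs <- function(genome, truth, config) {
  stopifnot(inherits(genome, "SimGenome"), inherits(config, "SimConfig"))
  set.seed(config$seed)
  rl <- config$read_length
  clen <- nchar(genome$contigs)
  usable <- clen >= rl
  if (!all(usable))
    warning(sprintf("skipping %d contig(s) shorter than the read length",
                    sum(!usable)))
  if (!any(usable)) stop("no contig is at least one read length long",
                         call. = FALSE)
  cnames <- names(genome$contigs)[usable]
  clen <- clen[usable]

  n <- config$n_fragments
  ctg_i <- sample.int(length(cnames), n, replace = TRUE, prob = clen)
  # fragments shorter than a read are only allowed when adapter read-through
  # is modelled; otherwise lengths are truncated below at the read length
  floor_len <- if (config$adapter_readthrough) min(rl, 20L) else rl
  frag_len <- pmax(floor_len, as.integer(round(
    stats::rnorm(n, config$fragment_mean, config$fragment_sd))))
  skip <- frag_len > clen[ctg_i]
  n_skipped <- sum(skip)
  if (n_skipped > 0L) {
    warning(sprintf(
      "skipped %d fragment(s) longer than their sampled contig", n_skipped))
    ctg_i <- ctg_i[!skip]; frag_len <- frag_len[!skip]
  }
  m <- length(ctg_i)
  if (m == 0L)
    return(list(r1 = data.frame(id = character(0), seq = character(0),
                                qual = character(0)),
                r2 = data.frame(id = character(0), seq = character(0),
                                qual = character(0)),
                reads = data.frame(), n_skipped = n_skipped))

  start <- as.integer(floor(stats::runif(m) * (clen[ctg_i] - frag_len + 1)))
  strand <- c("+", "-")[1L + (stats::runif(m) < 0.5)]
  undec <- stats::runif(m) < config$undeconvolvable_fraction
  width <- pmin(rl, frag_len)

  ctg <- cnames[ctg_i]
  frag_plus <- substring(genome$contigs[ctg], start + 1L, start + frag_len)
  frag <- frag_plus
  minus <- strand == "-"
  frag[minus] <- .revcomp(frag[minus])

  meths <- .truth_index(genome, truth)
  w <- rl

  # copy-strand readout; short fragments run into the hairpin, then the
  # Illumina adapter (adapter read-through)
  filler <- strrep(paste0(HAIRPIN_ADAPTER, ILLUMINA_ADAPTER, HAIRPIN_ADAPTER),
                   ceiling(w / 46))
  read2 <- substring(paste0(substring(frag, 1L, width), filler), 1L, w)
  mat2 <- .char_matrix(read2, w)

  # genome position of cycle j (0-based): plus -> start + j;
  # minus -> start + frag_len - 1 - j; adapter fill masked out
  col0 <- matrix(rep(0:(w - 1L), each = m), m, w)
  genomic <- col0 < width
  gpos <- start + col0
  if (any(minus))
    gpos[minus, ] <- start[minus] + frag_len[minus] - 1L -
      col0[minus, , drop = FALSE]
  gpos[!genomic] <- 0L
  meth_mat <- matrix(FALSE, m, w)
  for (cg in unique(ctg)) {
    for (sd_ in c("+", "-")) {
      sel <- ctg == cg & strand == sd_
      if (!any(sel)) next
      meth_mat[sel, ] <- matrix(
        meths[[cg]][[sd_]][gpos[sel, , drop = FALSE] + 1L], sum(sel))
    }
  }
  meth_mat[!genomic] <- FALSE

  mat1 <- .convert_matrix(mat2, meth_mat, config$conversion_rate,
                          config$methylated_retention, genomic)

  # undeconvolvable pairs: mate 2 becomes a conventional bisulfite read from
  # the opposite fragment end (opposite strand), itself converted
  if (any(undec)) {
    oi <- which(undec)
    ofrag <- .revcomp(frag[oi])                    # opposite strand, 5'->3'
    oread <- substring(paste0(substring(ofrag, 1L, width[oi]), filler), 1L, w)
    omat <- .char_matrix(oread, w)
    ocol <- col0[oi, , drop = FALSE]
    ogenomic <- ocol < width[oi]
    # cycle j of the opposite mate walks the fragment from its other end
    ogpos <- start[oi] + frag_len[oi] - 1L - ocol
    om <- minus[oi]
    if (any(om))
      ogpos[om, ] <- start[oi][om] + ocol[om, , drop = FALSE]
    ogpos[!ogenomic] <- 0L
    ometh <- matrix(FALSE, length(oi), w)
    ostrand <- ifelse(minus[oi], "+", "-")
    for (cg in unique(ctg[oi])) {
      for (sd_ in c("+", "-")) {
        sel <- ctg[oi] == cg & ostrand == sd_
        if (!any(sel)) next
        ometh[sel, ] <- matrix(
          meths[[cg]][[sd_]][ogpos[sel, , drop = FALSE] + 1L], sum(sel))
      }
    }
    ometh[!ogenomic] <- FALSE
    omat <- .convert_matrix(omat, ometh, config$conversion_rate,
                            config$methylated_retention, ogenomic)
    mat2[oi, ] <- omat
  }

  e1 <- .inject_errors(mat1, config$r1_error_rate)
  e2 <- .inject_errors(mat2, config$r2_error_rate)

  q1 <- matrix(.QCHARS[38L], m, w); q1[e1$err] <- .QCHARS[12L]  # Q37 / Q11
  q2 <- matrix(.QCHARS[38L], m, w); q2[e2$err] <- .QCHARS[12L]

  ids <- sprintf("read_%06d", seq_len(m))
  r1 <- data.frame(id = ids, seq = .collapse_rows(e1$mat),
                   qual = .collapse_rows(q1), stringsAsFactors = FALSE)
  r2 <- data.frame(id = ids, seq = .collapse_rows(e2$mat),
                   qual = .collapse_rows(q2), stringsAsFactors = FALSE)

  left0 <- ifelse(minus, start + frag_len - width, start)
  reads <- data.frame(id = ids, contig = ctg, start = as.integer(left0),
                      strand = strand, width = as.integer(width),
                      frag_len = as.integer(frag_len),
                      undeconvolvable = undec, stringsAsFactors = FALSE)
  list(r1 = r1, r2 = r2, reads = reads, n_skipped = n_skipped)
}
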