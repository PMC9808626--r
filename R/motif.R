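# Reference-free methyltransferase-specificity discovery.
#
# From a random subsample of deconvolved reads, every cytosine call is
# expanded into its 8-mer sequence context (3 bases upstream, the C, 4
# downstream). Per distinct 8-mer, k methylated occurrences out of n total
# feed an upper-tail binomial test against the global average methylation
# level P0, Bonferroni-corrected. Significant 8-mers are clustered by
# Hamming distance (average linkage) and summarized as IUPAC consensus
# motifs with position frequency matrices.

#' Randomly subsample reads
#'
#' Bernoulli subsampling: each read is kept independently with probability
#' `fraction`; deterministic for a given seed.
#'
#' @param reads data.frame of reads (any columns).
#' @param fraction keep probability in (0, 1].
#' @param seed integer seed.
#' @return the sampled subset of `reads`.
#' @export
sample_reads <- function(reads, fraction = 0.02, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  if (fraction == 1) return(reads)
  set.seed(as.integer(seed))
  reads[stats::runif(nrow(reads)) < fraction, , drop = FALSE]
}

#' Extract cytosine-context k-mers from deconvolved reads
#'
#' For each cytosine call with at least `up` read bases upstream and `down`
#' downstream, emits the (up + 1 + down)-mer centered on the C together
#' with its methylation state. Reads carrying more than one methylated call
#' are excluded entirely (they confound motif attribution); k-mers
#' containing N are skipped.
#'
#' @param seq character vector of deconvolved read sequences.
#' @param xm matching XM methylation strings.
#' @param up,down context window (default 3 upstream, 4 downstream: 8-mers).
#' @return data.frame (`kmer`, `methylated`).
#' @export
extract_context_kmers <- function(seq, xm, up = 3L, down = 4L) {
  if (length(seq) != length(xm) || any(nchar(seq) != nchar(xm)))
    stop("`seq` and `xm` must match in length, element by element",
         call. = FALSE)
  empty <- data.frame(kmer = character(0), methylated = logical(0))
  if (!length(seq)) return(empty)
  n_meth <- nchar(gsub("[^ZXHU]", "", xm))
  keep <- n_meth <= 1L
  seq <- seq[keep]; xm <- xm[keep]
  if (!length(seq)) return(empty)
  hits <- gregexpr("[ZzXxHhUu]", xm)
  cnt <- vapply(hits, function(h) if (h[1L] == -1L) 0L else length(h),
                integer(1))
  row <- rep(seq_along(seq), cnt)
  pos <- unlist(hits[cnt > 0L], use.names = FALSE)       # 1-based C position
  if (!length(row)) return(empty)
  # consistency: every call must sit on a C of the sequence
  if (any(substring(seq[row], pos, pos) != "C"))
    stop("methylation string inconsistent with sequence (call not on a C)",
         call. = FALSE)
  L <- nchar(seq)[row]
  ok <- pos - up >= 1L & pos + down <= L
  row <- row[ok]; pos <- pos[ok]
  if (!length(row)) return(empty)
  kmer <- substring(seq[row], pos - up, pos + down)
  state <- substring(xm[row], pos, pos) %in% c("Z", "X", "H", "U")
  no_n <- !grepl("N", kmer, fixed = TRUE)
  data.frame(kmer = kmer[no_n], methylated = state[no_n],
             stringsAsFactors = FALSE)
}

#' Tally k-mer methylation counts
#'
#' @param stream data.frame from [extract_context_kmers()].
#' @return data.frame (`kmer`, `k` methylated occurrences, `n` total
#'   occurrences), sorted by `kmer`.
#' @export
count_kmers <- function(stream) {
  if (!nrow(stream))
    return(data.frame(kmer = character(0), k = integer(0), n = integer(0)))
  dt <- data.table::as.data.table(stream)
  agg <- dt[, list(k = sum(methylated), n = .N), by = "kmer"]
  data.table::setorderv(agg, "kmer")
  as.data.frame(agg)
}

#' Binomial enrichment test over k-mer counts
#'
#' The background P0 is the average methylation level sum(k)/sum(n) over
#' all counted k-mers. Each k-mer observed at least `min_n` times is tested
#' with the upper-tail binomial P-value 1 - BinomCDF(k; n, P0), i.e. the
#' probability of strictly more than k methylated occurrences under the
#' background (`tail = "paper"`); `tail = "geq"` gives the conventional
#' P(X >= k). Significance is Bonferroni-controlled at `alpha / m`, where m
#' counts the tested k-mers.
#'
#' @param counts data.frame from [count_kmers()].
#' @param alpha family-wise significance level (default 0.0001).
#' @param min_n minimum occurrences for a k-mer to be tested (default 5).
#' @param tail `"paper"` (strictly greater than k) or `"geq"`.
#' @return list with `kmers` (data.frame `kmer`, `k`, `n`, `p_value`,
#'   `tested`, `significant`), `P0`, `alpha`, `m`.
#' @export
enrichment_test <- function(counts, alpha = 1e-4, min_n = 5L,
                            tail = c("paper", "geq")) {
  tail <- match.arg(tail)
  if (!nrow(counts) || sum(counts$n) == 0)
    stop("no k-mer occurrences to test", call. = FALSE)
  P0 <- sum(counts$k) / sum(counts$n)
  tested <- counts$n >= min_n
  m <- sum(tested)
  p <- rep(NA_real_, nrow(counts))
  kk <- if (tail == "paper") counts$k[tested] else counts$k[tested] - 1L
  p[tested] <- 1 - stats::pbinom(kk, counts$n[tested], P0)
  sig <- tested & !is.na(p) & m > 0 & p < alpha / max(m, 1L)
  list(kmers = data.frame(kmer = counts$kmer, k = counts$k, n = counts$n,
                          p_value = p, tested = tested, significant = sig,
                          stringsAsFactors = FALSE),
       P0 = P0, alpha = alpha, m = m)
}

# pairwise mismatch distance; with ic_weight, a mismatch at column j costs
# 1 + IC_j, where IC_j = 2 - Shannon entropy (bits) of the column over the
# k-mers themselves: every mismatch still counts (separating unrelated
# motif families), while mismatches at discriminating, low-entropy columns
# (e.g. a 2-letter wobble) outweigh those at uniform flanking columns
.kmer_dist <- function(kmers, ic_weight = TRUE, weights = NULL) {
  w <- nchar(kmers[1L])
  mat <- .char_matrix(kmers, w)
  if (is.null(weights)) weights <- rep(1, length(kmers))
  colw <- rep(1, w)
  if (ic_weight) {
    for (j in seq_len(w)) {
      f <- vapply(c("A", "C", "G", "T"),
                  function(b) sum(weights[mat[, j] == b]), numeric(1))
      p <- f / sum(f)
      p <- p[p > 0]
      colw[j] <- 1 + 2 + sum(p * log2(p))
    }
  }
  D <- matrix(0, length(kmers), length(kmers))
  for (j in seq_len(w))
    D <- D + colw[j] * outer(mat[, j], mat[, j], "!=")
  D
}

#' Cluster significant k-mers by pairwise sequence difference
#'
#' Average-linkage agglomerative clustering on pairwise mismatch distances,
#' cut into exactly `n_clusters` groups. By default a mismatch at column j
#' costs 1 plus the column's information content over the input k-mers
#' (`ic_weight = TRUE`): all mismatches count (keeping unrelated motif
#' families apart), while discriminating low-entropy columns — a
#' two-letter wobble such as the W of CCWGG — outweigh near-uniform
#' flanking columns. With `ic_weight = FALSE` the distance is the plain
#' Hamming count, which cannot resolve a single-position wobble inside an
#' otherwise symmetric k-mer set (every flanking column then competes
#' equally with the wobble). Input k-mers are sorted lexicographically
#' first, making the result deterministic.
#'
#' @param kmers character vector of equal-length k-mers.
#' @param n_clusters number of clusters to report.
#' @param weights optional per-k-mer weights (e.g. methylated counts k)
#'   used for the column information content and carried into each cluster
#'   for consensus building.
#' @param ic_weight weight column mismatches by information content.
#' @return list of `MotifCluster` objects: `members`, `weights`.
#' @export
cluster_kmers <- function(kmers, n_clusters, weights = NULL,
                          ic_weight = TRUE) {
  if (length(kmers) < n_clusters)
    stop(sprintf("need at least %d k-mers to form %d clusters (have %d)",
                 n_clusters, n_clusters, length(kmers)), call. = FALSE)
  if (length(unique(nchar(kmers))) > 1L)
    stop("k-mers must have equal length", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(kmers))
  ord <- order(kmers)
  kmers <- kmers[ord]; weights <- weights[ord]
  grp <- if (length(kmers) == 1L) 1L else {
    hc <- stats::hclust(stats::as.dist(
      .kmer_dist(kmers, ic_weight = ic_weight, weights = weights)),
      method = "average")
    stats::cutree(hc, k = n_clusters)
  }
  lapply(seq_len(n_clusters), function(g) {
    structure(list(members = kmers[grp == g], weights = weights[grp == g]),
              class = "MotifCluster")
  })
}

.IUPAC_FROM_SET <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  keys <- vapply(strsplit(m, ""), function(x) paste(sort(x), collapse = ""),
                 character(1))
  stats::setNames(names(m), keys)
})

#' IUPAC consensus and position frequency matrix of a k-mer cluster
#'
#' The PFM column for each position is the base frequency among member
#' k-mers, weighted by each member's weight (typically its methylated
#' count). The consensus letter is the IUPAC code of all bases reaching a
#' column frequency of at least `threshold`; the reported core trims fully
#' degenerate (N) positions from both flanks.
#'
#' @param cluster a `MotifCluster` (or list with `members` and optional
#'   `weights`).
#' @param threshold per-column inclusion frequency (default 0.2).
#' @return list with `consensus` (full-length IUPAC string), `core`
#'   (N-trimmed), `pfm` (4 x width matrix, columns sum to 1).
#' @export
consensus_motif <- function(cluster, threshold = 0.2) {
  members <- cluster$members
  if (!length(members)) stop("empty cluster", call. = FALSE)
  weights <- cluster$weights
  if (is.null(weights) || all(weights == 0)) weights <- rep(1, length(members))
  w <- nchar(members[1L])
  mat <- .char_matrix(members, w)
  pfm <- vapply(seq_len(w), function(j) {
    f <- vapply(c("A", "C", "G", "T"),
                function(b) sum(weights[mat[, j] == b]), numeric(1))
    f / sum(f)
  }, numeric(4))
  rownames(pfm) <- c("A", "C", "G", "T")
  letters <- vapply(seq_len(w), function(j) {
    bases <- rownames(pfm)[pfm[, j] >= threshold]
    if (!length(bases)) bases <- rownames(pfm)[which.max(pfm[, j])]
    .IUPAC_FROM_SET[[paste(sort(bases), collapse = "")]]
  }, character(1))
  consensus <- paste(letters, collapse = "")
  core <- sub("^N+", "", sub("N+$", "", consensus))
  list(consensus = consensus, core = core, pfm = pfm)
}

#' Test whether a consensus motif matches an IUPAC pattern
#'
#' A consensus recovered from finite data is typically a refinement of the
#' true recognition motif (e.g. core `GCDHGC` for a GCNNGC
#' methyltransferase, since D and H are subsets of N). The consensus
#' matches the pattern when some alignment window exists in which every
#' consensus letter's base set is contained in the corresponding pattern
#' letter's base set.
#'
#' @param consensus IUPAC consensus string (e.g. a [consensus_motif()]
#'   core).
#' @param pattern expected IUPAC recognition motif.
#' @return TRUE if the consensus contains a window refining the pattern.
#' @examples
#' motif_matches("WDGCDHGC", "GCNNGC")  # TRUE
#' motif_matches("CCAGG", "CCTGG")      # FALSE
#' @export
motif_matches <- function(consensus, pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  cs <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  ps <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  if (length(cs) < length(ps)) return(FALSE)
  refines <- function(a, b)
    all(strsplit(map[[a]], "")[[1]] %in% strsplit(map[[b]], "")[[1]])
  for (i in 0:(length(cs) - length(ps))) {
    if (all(mapply(refines, cs[i + seq_along(ps)], ps))) return(TRUE)
  }
  FALSE
}

#' Reference-free motif discovery pipeline
#'
#' Chains [sample_reads()], [extract_context_kmers()], [count_kmers()],
#' [enrichment_test()], [cluster_kmers()] and [consensus_motif()].
#'
#' @param reads data.frame with `seq` and `xm` columns (deconvolved reads).
#' @param n_clusters number of motif clusters to report.
#' @param fraction read subsample fraction (default 0.02).
#' @param alpha,min_n,tail passed to [enrichment_test()].
#' @param up,down context window (default 8-mers).
#' @param seed subsampling seed.
#' @return list with `enrichment` (the [enrichment_test()] result),
#'   `clusters` (list of `MotifCluster`), `motifs` (list of
#'   [consensus_motif()] results) and `cores` (character vector).
#' @export
discover_motifs <- function(reads, n_clusters, fraction = 0.02,
                            alpha = 1e-4, min_n = 5L, tail = "paper",
                            up = 3L, down = 4L, seed = 1L) {
  sub <- sample_reads(reads, fraction = fraction, seed = seed)
  stream <- extract_context_kmers(sub$seq, sub$xm, up = up, down = down)
  counts <- count_kmers(stream)
  enr <- enrichment_test(counts, alpha = alpha, min_n = min_n, tail = tail)
  sig <- enr$kmers[enr$kmers$significant, , drop = FALSE]
  clusters <- cluster_kmers(sig$kmer, n_clusters, weights = sig$k)
  motifs <- lapply(clusters, consensus_motif)
  list(enrichment = enr, clusters = clusters, motifs = motifs,
       cores = vapply(motifs, `[[`, "", "core"))
}

#' Write motif PFMs in MEME minimal format
#'
#' @param motifs list of [consensus_motif()] results.
#' @param path output path.
#' @param background optional length-4 background frequencies (A, C, G, T).
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path,
                              background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       background[1], background[2], background[3],
                       background[4]), ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$core), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       ncol(m$pfm)), con)
    for (j in seq_len(ncol(m$pfm)))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", m$pfm["A", j],
                         m$pfm["C", j], m$pfm["G", j], m$pfm["T", j]), con)
    writeLines("", con)
  }
  invisible(path)
}
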