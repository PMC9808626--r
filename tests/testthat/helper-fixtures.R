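# Shared fixtures and independent oracles, all built in code at test time.

# bind simulator output into the pair layout consumed by deconvolve_pairs()
sim_pairs <- function(sim) {
  data.frame(id = sim$r1$id, seq1 = sim$r1$seq, qual1 = sim$r1$qual,
             seq2 = sim$r2$seq, qual2 = sim$r2$qual,
             stringsAsFactors = FALSE)
}

# fragment sequences (read portion, read orientation) from truth + genome
true_fragments <- function(genome, reads) {
  frag <- unname(substring(genome$contigs[reads$contig], reads$start + 1L,
                           reads$start + reads$width))
  minus <- reads$strand == "-"
  if (any(minus))
    frag[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(frag[minus])))
  frag
}

# independent brute-force duplicate marking: exhaustive grouping, keep the
# highest mean quality (ties: smallest qname)
oracle_mark_duplicates <- function(records) {
  pos5 <- ifelse(records$strand == "-",
                 records$pos + nchar(records$seq) - 1L, records$pos)
  grp <- paste(records$rname, pos5, records$strand, records$seq)
  keep <- logical(nrow(records))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    mq <- sapply(idx, function(i)
      mean(utf8ToInt(records$qual[i]) - 33L))
    best <- idx[order(-mq, records$qname[idx])][1]
    keep[best] <- TRUE
  }
  records[keep, , drop = FALSE]
}

# independent unique-mapping rule: literal re-statement
oracle_mark_unique <- function(records) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    has_as <- !is.na(records$AS[i]); has_xs <- !is.na(records$XS[i])
    keep[i] <- (has_as && !has_xs) ||
      (has_as && has_xs && records$AS[i] != records$XS[i])
  }
  records[keep, , drop = FALSE]
}

# exact upper-tail binomial probability by direct summation of the pmf,
# P(X > k) = sum_{i=k+1}^{n} C(n,i) p^i (1-p)^(n-i)
oracle_binom_upper <- function(k, n, p) {
  if (k >= n) return(0)
  i <- (k + 1):n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

random_alignments <- function(n, seed) {
  set.seed(seed)
  seqs <- sapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = ""))
  quals <- sapply(seq_len(n), function(i)
    paste(sapply(sample(25:40, 8, replace = TRUE),
                 function(q) rawToChar(as.raw(q + 33L))), collapse = ""))
  data.frame(qname = sprintf("r%03d", seq_len(n)),
             rname = sample(c("c1", "c2"), n, replace = TRUE),
             pos = sample(1:5, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             seq = sample(seqs[1:4], n, replace = TRUE),
             qual = quals,
             AS = ifelse(runif(n) < 0.9, -sample(0:20, n, replace = TRUE),
                         NA_integer_),
             XS = NA_integer_,
             stringsAsFactors = FALSE)
}
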