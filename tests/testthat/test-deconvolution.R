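# Pair deconvolution: trimming, position classification, base/quality/XM
# assembly, rejection, and empirical quality calibration.

test_that("classify_position is a total partition of all 25 base pairs", {
  bases <- c("A", "C", "G", "T", "N")
  combos <- expand.grid(b1 = bases, b2 = bases, stringsAsFactors = FALSE)
  got <- classify_position(combos$b1, combos$b2)
  # independent re-derivation, case by case
  expected <- mapply(function(b1, b2) {
    if (b1 == "N" || b2 == "N") return("AMBIGUOUS")
    if (b1 == "C" && b2 == "C") return("METH_C")
    if (b1 == "T" && b2 == "C") return("UNMETH_C")
    if (b1 == b2) return("AGREE")
    "MISMATCH"
  }, combos$b1, combos$b2)
  expect_equal(got, unname(expected))
  # each combination lands in exactly one class (classify is a function)
  expect_equal(length(got), 25L)
  expect_error(classify_position("A", "Z"), "A, C, G, T, N")
})

test_that("deconvolution recovers sequence, quality and methylation string", {
  p <- deconvolve_pair("TACGT", "CACGT")
  expect_equal(p$sequence, "CACGT")
  expect_equal(p$methylation, "h.Z..")
  expect_equal(p$status, "deconvolved")

  # identical C-free mates pass through with an all-'.' string
  q <- deconvolve_pair("TAGGA", "TAGGA")
  expect_equal(q$sequence, "TAGGA")
  expect_equal(q$methylation, ".....")

  # mismatch keeps the Read1 base at quality 0 (reference-free mode)
  r <- deconvolve_pair("AACGT", "ACCGT")
  expect_equal(r$sequence, "AACGT")
  expect_equal(utf8ToInt(r$quality) - 33L, c(37L, 0L, 37L, 37L, 37L))

  # agreement quality is the minimum of the mate qualities
  s <- deconvolve_pair("TTTT", "TTTT", qual1 = "FF!!", qual2 = "!F,F")
  expect_equal(s$quality, "!F!!")

  # ambiguous positions give N at quality 0 with no methylation call
  t <- deconvolve_pair("TANGT", "TACGT")
  expect_equal(t$sequence, "TANGT")
  expect_equal(substr(t$methylation, 3, 3), ".")
  expect_equal(utf8ToInt(t$quality)[3] - 33L, 0L)
})

test_that("methylation string invariants hold on fuzzed pairs", {
  set.seed(42)
  for (i in 1:50) {
    L <- sample(5:80, 1)
    s1 <- paste(sample(c("A", "C", "G", "T", "N"), L, TRUE,
                       prob = c(.24, .24, .24, .24, .04)), collapse = "")
    s2 <- paste(sample(c("A", "C", "G", "T", "N"), L, TRUE,
                       prob = c(.24, .24, .24, .24, .04)), collapse = "")
    p <- deconvolve_pair(s1, s2, reject_frac = 1)  # never reject, check all
    expect_equal(nchar(p$sequence), nchar(p$quality))
    expect_equal(nchar(p$sequence), nchar(p$methylation))
    seq_ch <- strsplit(p$sequence, "")[[1]]
    xm_ch <- strsplit(p$methylation, "")[[1]]
    # every non-'.' symbol sits on a C; every C carries a symbol
    expect_true(all(seq_ch[xm_ch != "."] == "C"))
    expect_equal(sum(xm_ch != "."), sum(seq_ch == "C"))
  }
})

test_that("cytosine context is read from the deconvolved sequence", {
  # CpG, CHG, CHH and end-of-read unknowns, methylated and not
  p <- deconvolve_pair("CGCACCACC", "CGCACCACC")   # all C/C = methylated
  # pos0 C,next G -> Z; pos2 C next A then C -> H; pos4/5 CC: pos4 next C
  # then A -> H ... last two positions are within 2 nt of the end -> U
  expect_equal(p$methylation, "Z.H.HH.UU")
  u <- deconvolve_pair("TGTATTATT", "CGCACCACC") # same but unmethylated
  expect_equal(u$methylation, "z.h.hh.uu")
})

test_that("pairs over the mismatch threshold are rejected", {
  # 3 of 6 positions mismatch (50%) -> rejected at the 10% default
  p <- deconvolve_pair("AAAGGG", "AAACCC")
  expect_equal(p$status, "rejected")
  # just under the threshold passes: 1 mismatch in 12 positions
  q <- deconvolve_pair("AAAAAAAAAAAG", "AAAAAAAAAAAT")
  expect_equal(q$status, "deconvolved")
  # threshold is configurable
  r <- deconvolve_pair("AAAGGG", "AAACCC", reject_frac = 0.6)
  expect_equal(r$status, "deconvolved")
})

test_that("trimming removes 3'-anchored adapters and length-matches mates", {
  cfg <- hairpin_config()
  insert1 <- strrep("TGA", 20)                     # 60 nt, C-free
  insert2 <- strrep("TGA", 20)
  q60 <- strrep("F", 60); q106 <- strrep("F", 106)
  # full 46-nt hairpin read through at the 3' end
  r1 <- data.frame(id = "a", seq = paste0(insert1, HAIRPIN_ADAPTER),
                   qual = q106)
  r2 <- data.frame(id = "a", seq = paste0(insert2, HAIRPIN_ADAPTER),
                   qual = q106)
  tr <- trim_pairs(r1, r2, cfg)
  expect_equal(tr$pairs$seq1, insert1)
  expect_equal(tr$pairs$seq2, insert2)
  expect_equal(tr$n_dropped, 0)

  # no adapter occurrence: unchanged
  r3 <- data.frame(id = "b", seq = insert1, qual = q60)
  tr3 <- trim_pairs(r3, r3, cfg)
  expect_equal(tr3$pairs$seq1, insert1)

  # mates trimmed to 80 and 74 nt are both truncated to 74
  long1 <- paste0(strrep("TGA", 26), "TG", HAIRPIN_ADAPTER)   # 80 + hairpin
  long2 <- paste0(strrep("TGA", 24), "TG", HAIRPIN_ADAPTER,
                  strrep("A", 6))                              # 74 + hairpin
  r4 <- data.frame(id = "c", seq = long1, qual = strrep("F", nchar(long1)))
  r5 <- data.frame(id = "c", seq = long2, qual = strrep("F", nchar(long2)))
  tr4 <- trim_pairs(r4, r5, cfg)
  expect_equal(nchar(tr4$pairs$seq1), 74)
  expect_equal(nchar(tr4$pairs$seq2), 74)

  # pairs shorter than min_length after trimming are dropped and counted
  short <- data.frame(id = "d", seq = paste0("TGATGATGA", ILLUMINA_ADAPTER),
                      qual = strrep("F", 9 + nchar(ILLUMINA_ADAPTER)))
  tr5 <- trim_pairs(short, short, cfg)
  expect_equal(nrow(tr5$pairs), 0)
  expect_equal(tr5$n_dropped, 1)

  # malformed record (sequence/quality length mismatch) names the read
  bad <- data.frame(id = "oops", seq = "ACGT", qual = "FF")
  expect_error(trim_pairs(bad, bad, cfg), "oops")
})

test_that("trimming tolerates 10% adapter mismatches", {
  cfg <- hairpin_config()
  mut <- HAIRPIN_ADAPTER
  substr(mut, 10, 10) <- "T"; substr(mut, 30, 30) <- "A"   # 2/46 < 10%
  insert <- strrep("TGA", 20)
  r <- data.frame(id = "a", seq = paste0(insert, mut),
                  qual = strrep("F", 60 + 46))
  tr <- trim_pairs(r, r, cfg)
  expect_equal(tr$pairs$seq1, insert)
})

test_that("round trip: error-free simulated pairs deconvolve exactly", {
  g <- generate_genome(30000, gc = 0.45, seed = 20)
  tr <- assign_methylation(g, methylation_model("rate", cpg_rate = 0.5), 21)
  cfg <- sim_config(n_fragments = 800, read_length = 80,
                    conversion_rate = 1, seq_error_rate = 0, seed = 22)
  sim <- simulate_read_pairs(g, tr, cfg)
  dec <- deconvolve_pairs(sim_pairs(sim))
  expect_true(all(dec$reads$status == "deconvolved"))
  expect_identical(dec$reads$seq, true_fragments(g, sim$reads))

  # methylation calls equal truth at every covered cytosine
  al <- truth_alignments(dec, sim$reads)
  pu <- pileup_methylation(al)
  expect_true(all(pu$X == 0 | pu$X == pu$N))     # no site is mixed
  truth_key <- paste(tr$contig, tr$pos, tr$strand)
  pile_key <- paste(pu$contig, pu$pos - 1L, pu$strand)
  expect_true(all(pile_key[pu$X > 0] %in% truth_key))
  expect_false(any(pile_key[pu$X == 0] %in% truth_key))
})

test_that("deconvolution summary counts add up", {
  g <- generate_genome(20000, gc = 0.5, seed = 23)
  cfg <- sim_config(n_fragments = 400, read_length = 60,
                    undeconvolvable_fraction = 0.15, seed = 24)
  sim <- simulate_read_pairs(g, data.frame(), cfg)
  dec <- deconvolve_pairs(sim_pairs(sim))
  s <- deconvolution_summary(dec)
  expect_equal(s$deconvolved + s$rejected, s$total)
  expect_equal(sum(unlist(s$position_tallies)), 400 * 60)
  # rejected fraction tracks the undeconvolvable fraction
  expect_lt(abs(s$rejected / s$total - 0.15), 3 * sqrt(0.15 * 0.85 / 400))
  # clean input: 100% deconvolved
  cfg2 <- sim_config(n_fragments = 100, read_length = 60, seed = 25)
  sim2 <- simulate_read_pairs(g, data.frame(), cfg2)
  dec2 <- deconvolve_pairs(sim_pairs(sim2))
  expect_equal(deconvolution_summary(dec2)$deconvolved, 100)
  # empty batch: all zeros
  dec0 <- deconvolve_pairs(sim_pairs(list(
    r1 = data.frame(id = character(0), seq = character(0),
                    qual = character(0)),
    r2 = data.frame(id = character(0), seq = character(0),
                    qual = character(0)))))
  expect_equal(deconvolution_summary(dec0)$total, 0)
})

test_that("calibration posteriors match the closed form", {
  # build mismatch observations with known (x, N) per stratum via a toy
  # genome: reads of length 1 aligned at chosen reference bases
  mk_deconv <- function(b1s, b2s, ids) {
    pairs <- data.frame(id = ids, seq1 = b1s, qual1 = "F",
                        seq2 = b2s, qual2 = "F")
    deconvolve_pairs(pairs, reject_frac = 1)
  }
  # stratum (r=A, a=A, b=G, bin 0): 99 successes of 99 trials
  n1 <- 99
  d1 <- mk_deconv(rep("A", n1), rep("G", n1), sprintf("s%03d", 1:n1))
  al1 <- data.frame(qname = sprintf("s%03d", 1:n1), rname = "chr",
                    pos = 1L, strand = "+")
  tab1 <- build_calibration_table(d1, al1, c(chr = "A"), bin_width = 10)
  expect_equal(tab1$strata$x, 99)
  expect_equal(tab1$strata$p, 100 / 101)
  expect_equal(tab1$strata$Q, 20L)   # round(-10*log10(1/101))
  expect_equal(calibration_q(tab1, "A", "G", 0, "A"), 20L)

  # stratum with 0 successes of 8: p = 1/10, Q = round(-10*log10(0.9)) = 0
  n2 <- 8
  d2 <- mk_deconv(rep("A", n2), rep("G", n2), sprintf("t%03d", 1:n2))
  al2 <- data.frame(qname = sprintf("t%03d", 1:n2), rname = "chr",
                    pos = 1L, strand = "+")
  tab2 <- build_calibration_table(d2, al2, c(chr = "T"), bin_width = 10)
  expect_equal(tab2$strata$p, 1 / 10)
  expect_equal(tab2$strata$Q, 0L)

  # unobserved stratum falls back to the prior: p = 0.5, Q = 3
  expect_equal(calibration_q(tab1, "G", "T", 55, "C"), 3L)
  expect_equal(calibration_q(tab1, "G", "T", 55), 3L)
})

test_that("calibration equals a brute-force count on a mixed toy set", {
  set.seed(30)
  n <- 200
  b1 <- sample(c("A", "G"), n, TRUE)
  b2 <- sample(c("C", "T"), n, TRUE)
  refs <- sample(c("A", "C", "G", "T"), n, TRUE)
  ids <- sprintf("m%04d", seq_len(n))
  pairs <- data.frame(id = ids, seq1 = b1, qual1 = "F", seq2 = b2,
                      qual2 = "F")
  dec <- deconvolve_pairs(pairs, reject_frac = 1)
  genome <- c(chr = paste(refs, collapse = ""))
  al <- data.frame(qname = ids, rname = "chr", pos = seq_len(n),
                   strand = "+")
  tab <- build_calibration_table(dec, al, genome, bin_width = 10)
  # brute force: only true mismatches enter the table
  mism <- classify_position(b1, b2) == "MISMATCH"
  for (i in seq_len(nrow(tab$strata))) {
    st <- tab$strata[i]
    sel <- mism & refs == st$r & b1 == st$a & b2 == st$b
    expect_equal(st$N, sum(sel))
    expect_equal(st$x, sum(b1[sel] == refs[sel]))
    expect_equal(st$p, (st$x + 1) / (st$N + 2))
  }
  expect_equal(sum(tab$strata$N), sum(mism))
})

test_that("calibrated mode swaps mismatch qualities, and only those", {
  # table with a known stratum: r=A, a=G, b=T, cycle bin 0 -> Q=20
  n <- 99
  ids <- sprintf("c%03d", 1:n)
  d <- deconvolve_pairs(data.frame(id = ids, seq1 = "G", qual1 = "F",
                                   seq2 = "T", qual2 = "F"), reject_frac = 1)
  al <- data.frame(qname = ids, rname = "chr", pos = 1L, strand = "+")
  tab <- build_calibration_table(d, al, c(chr = "G"), bin_width = 10)

  p <- calibrate_pair("AAAAAAAAAAGA", "AAAAAAAAAATA", table = tab,
                      ref = "AAAAAAAAAAGA")
  expect_equal(utf8ToInt(p$quality)[11] - 33L,
               calibration_q(tab, "G", "T", 10, "G"))
  # positions without mismatch are untouched relative to reference-free mode
  free <- deconvolve_pair("AAAAAAAAAAGA", "AAAAAAAAAATA")
  expect_equal(substr(p$quality, 1, 10), substr(free$quality, 1, 10))
  # a pair with no mismatch is identical in both modes
  pm <- calibrate_pair("TACGT", "CACGT", table = tab)
  pf <- deconvolve_pair("TACGT", "CACGT")
  expect_identical(pm, pf)
})

test_that("calibrated qualities track which mate carries the errors", {
  g <- generate_genome(50000, gc = 0.5, seed = 31)
  base_cfg <- list(n_fragments = 1500, read_length = 80,
                   conversion_rate = 1, seed = 32)
  run <- function(r1e, r2e) {
    cfg <- do.call(sim_config, c(base_cfg, list(
      r1_error_rate = r1e, r2_error_rate = r2e)))
    sim <- simulate_read_pairs(g, data.frame(), cfg)
    dec <- deconvolve_pairs(sim_pairs(sim))
    al <- truth_alignments(dec, sim$reads)
    tab <- build_calibration_table(dec, al, g)
    # mean assigned Q over observed mismatch strata, weighted by N
    sum(tab$strata$Q * tab$strata$N) / sum(tab$strata$N)
  }
  q_r1_bad <- run(0.05, 0.001)   # Read1 errors dominate: distrust Read1
  q_r2_bad <- run(0.001, 0.05)   # Read2 errors dominate: Read1 usually right
  expect_lt(q_r1_bad, q_r2_bad)
})
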