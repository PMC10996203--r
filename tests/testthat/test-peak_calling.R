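ref_len_2kb <- c(ref = 2000L)

test_that("min_depth above the maximum coverage yields no peaks", {
  aln <- simulate_interval_reads(2000, 200, 36, seed = 1)
  pk <- call_peaks(aln, aln, peak_call_params(min_depth = 1e6), ref_len_2kb)
  expect_equal(nrow(pk), 0L)
})

test_that("an unknown reference id is rejected", {
  aln <- simulate_interval_reads(2000, 50, 36, seed = 1)
  expect_error(call_peaks(aln, aln, peak_call_params(), c(other = 500L)),
               "absent")
})

test_that("a planted site is recovered as a single well-localized peak", {
  site <- data.frame(start = 1000, end = 1059, factor = 10)
  hits <- 0L
  for (s in 1:10) {
    ip <- simulate_interval_reads(2000, 2800, 36, site, seed = s)
    input <- simulate_interval_reads(2000, 2800, 36, NULL, seed = s + 500)
    pk <- call_peaks(ip, input,
                     peak_call_params(min_depth = 150, seed = s), ref_len_2kb)
    if (nrow(pk) == 1L) {
      ov <- min(pk$end[1], 1059) - max(pk$start[1] + 1, 1000) + 1
      rec <- min(ov / 60, ov / (pk$end[1] - pk$start[1]))
      if (rec >= 0.5) hits <- hits + 1L
    }
  }
  expect_gte(hits, 9L)
})

test_that("stricter thresholds never increase the peak count and peaks stay disjoint", {
  site <- data.frame(start = c(400, 1400), end = c(459, 1459), factor = 10)
  ip <- simulate_interval_reads(2000, 2800, 36, site, seed = 4)
  input <- simulate_interval_reads(2000, 2800, 36, NULL, seed = 99)
  base <- call_peaks(ip, input, peak_call_params(min_depth = 120, seed = 1),
                     ref_len_2kb)
  strict_alpha <- call_peaks(ip, input,
                             peak_call_params(min_depth = 120, alpha = 0.01,
                                              seed = 1), ref_len_2kb)
  strict_enr <- call_peaks(ip, input,
                           peak_call_params(min_depth = 120,
                                            min_enrichment = 4, seed = 1),
                           ref_len_2kb)
  expect_lte(nrow(strict_alpha), nrow(base))
  expect_lte(nrow(strict_enr), nrow(base))
  if (nrow(base) > 1L) {
    b <- base[order(base$start), ]
    expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
})

test_that("null-candidate permutation p-values are not anticonservative", {
  # candidates from IP == Input generative model; collect all candidate p's
  ps <- c()
  for (s in 1:30) {
    ip <- simulate_interval_reads(800, 600, 36, NULL, seed = s)
    input <- simulate_interval_reads(800, 600, 36, NULL, seed = s + 1000)
    pk <- call_peaks(ip, input,
                     peak_call_params(min_depth = 25, alpha = 0.999,
                                      min_enrichment = 1,
                                      n_permutations = 100, seed = s),
                     c(ref = 800L))
    ps <- c(ps, pk$p)
  }
  expect_gt(length(ps), 10)
  frac <- mean(ps < 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / length(ps)))
})

test_that("summit categories follow the fixed priority", {
  # CDS beats everything (also antisense context would apply at geneB)
  pk <- annotate_peaks(make_peaks(c(200L, 300L, 120L, 660L, 850L, 1100L, 1950L),
                                  c("+", "+", "+", "+", "+", "+", "+")),
                       mini_ref)
  expect_equal(pk$category,
               c("CDS",          # 200: exon 1 of geneA, past the 5'UTR
                 "intron",       # 300: between geneA exons
                 "5UTR",         # 120: first 30 nt of geneA exon 1
                 "3UTR",         # 660: last 60 nt of geneA exon 2
                 "ncRNA-exon",   # 850: inside ncrna1
                 "antisense",    # 1100: inside geneB (-) with a + peak
                 "intergenic"))  # 1950: no feature
  d <- attr(pk, "distribution")
  expect_equal(sum(d$fraction), 1, tolerance = 1e-12)
  # a - strand peak at 1100 is sense to geneB -> exonic gene context
  pk2 <- annotate_peaks(make_peaks(1100L, "-"), mini_ref)
  expect_true(pk2$category %in% c("CDS", "5UTR", "3UTR"))
})

test_that("confident bound genes require peaks in both replicates", {
  p1 <- annotate_peaks(make_peaks(c(200L, 850L, 1100L), "+"), mini_ref)
  p2 <- annotate_peaks(make_peaks(c(250L, 860L), "+"), mini_ref)
  # geneA and ncrna1 in both; geneB (antisense hit) only in rep1
  expect_equal(confident_bound_genes(p1, p2), c("geneA", "ncrna1"))
})

test_that("maximal CA-run scanning counts units on both strands", {
  expect_equal(structrip:::max_ca_run("TTCACACACATT"), 4L)
  expect_equal(structrip:::max_ca_run("GGGG"), 0L)
  expect_equal(structrip:::max_ca_run("TGTGTGTG"), 4L)   # minus strand
  expect_equal(structrip:::max_ca_run("ACACAC"), 3L)     # AC phase
})

test_that("planted CA repeats are detected against the dinucleotide-shuffled null", {
  set.seed(21)
  mk <- function(n, len) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  seqs <- mk(40, 80)
  for (i in 1:20) {
    s <- seqs[i]
    substr(s, 30, 49) <- strrep("CA", 10)
    seqs[i] <- s
  }
  genome <- paste(seqs, collapse = "")
  fake_ref <- list(genome = c(chr1 = genome))
  peaks <- data.frame(start = (0:39) * 80L, end = (1:40) * 80L)
  res <- ca_repeat_enrichment(peaks, fake_ref, min_units = 5, seed = 1)
  expect_lt(res$p_empirical, 0.01)
  expect_gt(res$z, 3)
  # motif-free peaks: z stays near 0
  genome0 <- paste(mk(40, 80), collapse = "")
  res0 <- ca_repeat_enrichment(peaks, list(genome = c(chr1 = genome0)),
                               min_units = 5, seed = 1)
  expect_lt(abs(res0$z), 3)
})

test_that("peak extraction outside genome bounds errors", {
  fake_ref <- list(genome = c(chr1 = strrep("ACGT", 100)))
  expect_error(ca_repeat_enrichment(data.frame(start = 390L, end = 500L),
                                    fake_ref), "bounds")
})
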