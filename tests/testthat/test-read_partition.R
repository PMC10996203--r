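`%+%` <- function(a, b) paste0(a, b)

test_that("QC rules drop N-contaminated then short reads, with exact boundary", {
  reads <- data.frame(
    read_id = c("a", "b", "c", "d"),
    seq = c(strrep("A", 27) %+% "NNN",      # 30 nt, 3 N -> dropped
            strrep("A", 28) %+% "NN",       # 30 nt, 2 N -> kept
            strrep("G", 15),                # 15 nt -> dropped
            strrep("G", 16)),               # 16 nt -> kept (strict "less than")
    stringsAsFactors = FALSE)
  res <- qc_filter_reads(reads)
  expect_identical(res$kept$read_id, c("b", "d"))
  expect_equal(res$report$removed_n, 1L)
  expect_equal(res$report$removed_short, 1L)
})

test_that("QC counting is exact on a constructed 100-read set", {
  set.seed(11)
  mk <- function(n, len) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  good <- mk(88, 30)
  nbad <- vapply(mk(7, 30), function(s) {
    substr(s, 3, 5) <- "NNN"; s
  }, character(1), USE.NAMES = FALSE)
  short <- mk(5, 10)
  reads <- data.frame(read_id = sprintf("r%03d", 1:100),
                      seq = c(good, nbad, short), stringsAsFactors = FALSE)
  res <- qc_filter_reads(reads)
  expect_equal(nrow(res$kept), 88L)
  expect_equal(res$report$removed_n, 7L)
  expect_equal(res$report$removed_short, 5L)
})

test_that("QC of empty input returns an empty set and a zeroed report", {
  res <- qc_filter_reads(data.frame(read_id = character(0),
                                    seq = character(0)))
  expect_equal(nrow(res$kept), 0L)
  expect_equal(res$report$total, 0L)
  expect_equal(res$report$kept, 0L)
})

test_that("multiplicity partitions reads once per read id", {
  aln <- data.frame(
    read_id = c("m1", "m1", "m1", "u1", "u2"),
    ref = c("rDNA45S_1", "rDNA45S_2", "rDNA45S_3", "chr1", "chr1"),
    start = c(5L, 5L, 5L, 10L, 20L), end = c(40L, 40L, 40L, 46L, 56L),
    strand = "+", multiplicity = c(3L, 3L, 3L, 1L, 1L),
    stringsAsFactors = FALSE)
  p <- partition_by_multiplicity(aln)
  expect_equal(p$counts$multi, 1L)
  expect_equal(p$counts$unique, 2L)
  expect_equal(p$counts$total, 3L)
  # all multiplicities 1 -> empty multi set
  p1 <- partition_by_multiplicity(aln[aln$multiplicity == 1L, ])
  expect_equal(p1$counts$multi, 0L)
  expect_equal(p1$counts$unique, p1$counts$total)
})

test_that("inconsistent multiplicity across a read's records is an error", {
  aln <- data.frame(read_id = c("x", "x"), ref = c("a", "b"),
                    start = 0L, end = 10L, strand = "+",
                    multiplicity = c(2L, 3L), stringsAsFactors = FALSE)
  expect_error(partition_by_multiplicity(aln), "x")
})

test_that("class assignment is one class per read with fixed tie priority", {
  ct <- data.frame(ref_id = c("rDNA45S_1", "rDNA45S_2", "SNORA001"),
                   class = c("rRNA", "rRNA", "snoRNA"),
                   stringsAsFactors = FALSE)
  aln <- data.frame(
    read_id = c("a", "b", "b", "c", "c", "d"),
    ref = c("SNORA001", "rDNA45S_1", "rDNA45S_2", "SNORA001", "rDNA45S_1",
            "chrUn"),
    start = 0L, end = 30L, strand = "+", multiplicity = 2L,
    stringsAsFactors = FALSE)
  res <- assign_ncrna_class(aln, ct)
  got <- stats::setNames(res$assignments$class, res$assignments$read_id)
  expect_equal(got[["a"]], "snoRNA")       # only placement on a snoRNA
  expect_equal(got[["b"]], "rRNA")         # two identical copies, one count
  expect_equal(got[["c"]], "rRNA")         # tie broken by class priority
  expect_equal(got[["d"]], "unassigned")   # no structured reference
  expect_equal(sum(res$summary$count), 3L) # b, c, a assigned once each
  expect_equal(sum(res$summary$fraction), 1, tolerance = 1e-9)
})

test_that("a structured reference missing from the class table is a configuration error", {
  aln <- data.frame(read_id = "a", ref = "SNORD999", start = 0L, end = 30L,
                    strand = "+", multiplicity = 2L, stringsAsFactors = FALSE)
  ct <- data.frame(ref_id = "SNORA001", class = "snoRNA")
  expect_error(assign_ncrna_class(aln, ct, structured_refs = "SNORD999"),
               "SNORD999")
})

test_that("subregion assignment uses the read midpoint", {
  rd <- tiny_ref$rdna_table
  b58 <- rd[rd$name == "5.8S", ]
  # read spanning the 5.8S/ITS2 junction with midpoint in ITS2
  junction_read <- data.frame(read_id = "j", ref = "rDNA45S_1",
                              start = b58$end - 10L, end = b58$end + 26L,
                              strand = "+", multiplicity = 3L,
                              stringsAsFactors = FALSE)
  res <- assign_rdna_subregion(junction_read, rd)
  expect_equal(res$count[res$name == "ITS2"], 1L)
  expect_equal(sum(res$count), 1L)
  # read with midpoint in 28S
  r28 <- rd[rd$name == "28S", ]
  read28 <- data.frame(read_id = "k", ref = "rDNA45S_2",
                       start = r28$start + 99L, end = r28$start + 135L,
                       strand = "+", multiplicity = 3L,
                       stringsAsFactors = FALSE)
  res <- assign_rdna_subregion(read28, rd)
  expect_equal(res$count[res$name == "28S"], 1L)
})

test_that("planted subregion composition is recovered exactly from constructed reads", {
  rd <- tiny_ref$rdna_table
  mk <- function(sub, n, id0) {
    s <- rd$start[rd$name == sub] + seq_len(n) %% 50L
    data.frame(read_id = sprintf("%s%04d", id0, seq_len(n)),
               ref = "rDNA45S_1", start = s - 1L, end = s + 35L,
               strand = "+", multiplicity = 3L, stringsAsFactors = FALSE)
  }
  aln <- rbind(mk("28S", 300, "a"), mk("18S", 100, "b"))
  res <- assign_rdna_subregion(aln, rd)
  expect_equal(res$fraction[res$name == "28S"], 0.75)
  expect_equal(res$fraction[res$name == "18S"], 0.25)
  expect_equal(sum(res$fraction), 1, tolerance = 1e-9)
})

test_that("fractions are invariant under doubling a library", {
  aln <- tiny_sim$libraries$IP_1$alignments
  s1 <- read_class_summary(aln, tiny_ref$class_table, tiny_ref$rdna_table)
  doubled <- aln
  doubled$read_id <- paste0(doubled$read_id, "_dup")
  s2 <- read_class_summary(rbind(aln, doubled), tiny_ref$class_table,
                           tiny_ref$rdna_table)
  expect_equal(s2$counts$total, 2L * s1$counts$total)
  expect_equal(s2$subregion_summary$fraction, s1$subregion_summary$fraction,
               tolerance = 1e-12)
  expect_equal(s2$class_summary$fraction, s1$class_summary$fraction,
               tolerance = 1e-12)
  expect_equal(s2$rdna_fractions$fraction, s1$rdna_fractions$fraction,
               tolerance = 1e-12)
  # fraction vectors are proper distributions
  expect_equal(sum(s1$subregion_summary$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(s1$class_summary$fraction), 1, tolerance = 1e-9)
})

test_that("assigned multi fractions track the planted composition", {
  # multi reads come only from the multicopy rDNA units in the simulation
  s <- read_class_summary(tiny_sim$libraries$IP_1$alignments,
                          tiny_ref$class_table, tiny_ref$rdna_table)
  tc <- tiny_sim$libraries$IP_1$truth_counts
  planted_multi <- sum(tc$count[tc$source %in% c("45S", "5S")])
  expect_equal(s$counts$multi, planted_multi)
  frac <- s$counts$multi / s$counts$total
  p <- planted_multi / sum(tc$count)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / sum(tc$count)) + 1e-12)
})
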