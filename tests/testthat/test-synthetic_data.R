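test_that("rDNA copies are sequence-identical and the class table matches the layout", {
  refs <- tiny_ref$refs
  copies <- refs[grepl("^rDNA45S", names(refs))]
  expect_length(copies, 3L)
  expect_length(unique(unname(copies)), 1L)
  # genome carries the same unit sequence at each copy locus
  feats <- tiny_ref$features
  for (i in which(feats$kind == "rdna45S")) {
    expect_identical(substr(tiny_ref$genome[[1]], feats$start[i], feats$end[i]),
                     unname(copies[[1]]))
  }
  ct <- tiny_ref$class_table
  expect_equal(sum(ct$class == "snoRNA"), 8L + 6L)
  expect_equal(sum(ct$class == "scaRNA"), 3L)
  # every classified id exists in the annotation
  expect_true(all(ct$ref_id %in% feats$feature_id))
  # 45S subregions tile the unit
  rd <- tiny_ref$rdna_table
  expect_equal(rd$start[-1], rd$end[-nrow(rd)] + 1L)
})

test_that("identical seeds reproduce references and libraries exactly", {
  ref2 <- build_reference(tiny_spec)
  expect_identical(ref2$genome, tiny_ref$genome)
  expect_identical(ref2$features, tiny_ref$features)
  sim2 <- simulate_libraries(tiny_truth, library_sim(seed = 42), tiny_ref,
                             emit_reads = FALSE)
  for (lib in names(tiny_sim$libraries))
    expect_identical(sim2$libraries[[lib]]$alignments,
                     tiny_sim$libraries[[lib]]$alignments)
})

test_that("infeasible genome packing raises a sizing error", {
  sp <- genome_spec(n_coding_genes = 5, genome_length = 1000, seed = 1)
  expect_error(build_reference(sp), "infeasible packing")
})

test_that("truth referencing an unknown transcript is rejected", {
  bad <- binding_truth(c(nosuchgene = 50))
  expect_error(simulate_libraries(bad, library_sim(seed = 1), tiny_ref),
               "unknown transcript")
})

test_that("per-source counts follow the planted negative-binomial means", {
  # Monte-Carlo against the stated NB mean: baseline 100, IP enrichment 8
  tx <- tiny_ref$class_table$ref_id[tiny_ref$class_table$class == "snoRNA"][1]
  truth <- binding_truth(stats::setNames(100, tx),
                         stats::setNames(8, tx), nb_dispersion = 0.01)
  n_seeds <- 200
  ip_counts <- vapply(seq_len(n_seeds), function(s) {
    sim <- simulate_libraries(truth, library_sim(n_replicates = 1, seed = s),
                              tiny_ref, emit_reads = FALSE)
    sim$libraries$IP_1$truth_counts$count[1]
  }, numeric(1))
  se <- stats::sd(ip_counts) / sqrt(n_seeds)
  expect_lt(abs(mean(ip_counts) - 800), 3 * se)
})

test_that("truth counts equal the number of emitted fragments per library", {
  for (lib in names(tiny_sim$libraries)) {
    l <- tiny_sim$libraries[[lib]]
    expect_equal(sum(l$truth_counts$count),
                 length(unique(l$alignments$read_id)))
  }
})

test_that("the 28S binding window concentrates IP placements relative to Input", {
  rd <- tiny_ref$rdna_table
  off28 <- rd$start[rd$name == "28S"] - 1L
  w <- tiny_truth$rrna_binding_window
  frac_in_window <- function(lib) {
    a <- tiny_sim$libraries[[lib]]$alignments
    r45 <- a[grepl("^rDNA45S", a$ref), , drop = FALSE]
    r45 <- r45[!duplicated(r45$read_id), , drop = FALSE]
    local_start <- r45$start - off28 + 1L
    mean(local_start >= w$start & local_start <= w$end)
  }
  expect_gt(frac_in_window("IP_1"), frac_in_window("Input_1"))
  expect_gt(frac_in_window("IP_2"), frac_in_window("Input_2"))
})

test_that("raw-read emission includes the configured contaminant fractions", {
  simp <- library_sim(n_replicates = 1, frac_n_contaminated = 0.05,
                      frac_short = 0.04, seed = 9)
  sim <- simulate_libraries(tiny_truth, simp, tiny_ref, emit_reads = TRUE)
  l <- sim$libraries$IP_1
  n_clean <- length(unique(l$alignments$read_id))
  reads <- l$reads
  n_n <- sum(grepl("_nbad", reads$read_id))
  n_s <- sum(grepl("_short", reads$read_id))
  expect_equal(n_n, round(0.05 * n_clean))
  expect_equal(n_s, round(0.04 * n_clean))
  qc <- qc_filter_reads(reads)
  expect_equal(qc$report$removed_n, n_n)
  expect_equal(qc$report$removed_short, n_s)
  expect_equal(nrow(qc$kept), n_clean)
})

test_that("simulate_interval_reads up-weights placements inside sites", {
  sites <- data.frame(start = 901, end = 960, factor = 10)
  aln <- simulate_interval_reads(2000, 5000, 36, sites, seed = 3)
  inside <- mean(aln$start + 1 >= 901 & aln$start + 1 <= 960)
  # expected enrichment: 60 * 10 / (1965 - 60 + 600) of the mass
  expect_gt(inside, 3 * 60 / 1965)
  aln0 <- simulate_interval_reads(2000, 5000, 36, NULL, seed = 3)
  expect_lt(mean(aln0$start + 1 >= 901 & aln0$start + 1 <= 960), 2 * 60 / 1965)
})
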