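test_that("FPKM obeys its closed form and scaling invariance", {
  expect_identical(compute_fpkm(1000, 1000, 1e6), 1000)
  expect_identical(compute_fpkm(0, 500, 1e6), 0)
  # joint scaling of count and library total leaves FPKM unchanged
  for (k in c(2, 10, 137)) {
    expect_equal(compute_fpkm(480 * k, 1234, 2e6 * k),
                 compute_fpkm(480, 1234, 2e6))
  }
  expect_error(compute_fpkm(10, 0, 1e6), "length")
})

test_that("enrichment test handles empty evidence and matches the exact oracle", {
  res0 <- test_enrichment(0, 0, 1e5, 1e5)
  expect_equal(res0$fold_change, 1)
  expect_equal(res0$p, 1)
  # example table: 80 of 1e5 in IP, 10 of 1e5 in Input
  res <- test_enrichment(80, 10, 1e5, 1e5)
  expect_equal(res$p, fisher_oracle(80, 1e5 - 80, 10, 1e5 - 10),
               tolerance = 1e-10)
  expect_gt(res$fold_change, 2)
  # p is symmetric under swapping IP and Input
  res_sw <- test_enrichment(10, 80, 1e5, 1e5)
  expect_equal(res_sw$p, res$p, tolerance = 1e-12)
  expect_error(test_enrichment(10, 5, 8, 1e5), "exceeds")
})

test_that("Fisher p matches exhaustive enumeration on a grid of small tables", {
  for (a in 0:4) for (b in 0:4) for (c in 0:4) for (d in 0:4) {
    if (a + b == 0 || c + d == 0) next
    p_pkg <- test_enrichment(a, c, a + b, c + d)$p
    expect_equal(p_pkg, fisher_oracle(a, b, c, d), tolerance = 1e-12,
                 label = sprintf("table (%d,%d,%d,%d)", a, b, c, d))
  }
})

test_that("BH adjustment matches the hand-computed step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  p <- c(0.003, 0.04, 0.8, 0.012, 0.55)
  q <- bh_adjust(p)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p[perm]), q[perm])   # order equivariance
  expect_true(all(q >= p))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))    # monotone in sorted-p order
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("hypergeometric overlap matches enumeration and handles forced outcomes", {
  u <- sprintf("g%02d", 1:20)
  A <- u[1:10]
  B <- c(u[1:9], u[15])    # overlap 9
  res <- hypergeometric_overlap(A, B, u)
  expect_equal(res$overlap, 9L)
  expect_equal(res$p, hyper_tail_oracle(9, 20, 10, 10), tolerance = 1e-12)
  # A = B = universe forces overlap N and p = 1
  res_full <- hypergeometric_overlap(u, u, u)
  expect_equal(res_full$overlap, 20L)
  expect_equal(res_full$p, 1)
  # disjoint sets: p ~ 1 without underflow
  res_dis <- hypergeometric_overlap(u[1:5], u[6:10], u)
  expect_equal(res_dis$overlap, 0L)
  expect_equal(res_dis$p, 1, tolerance = 1e-12)
  expect_error(hypergeometric_overlap(c(A, "zz"), B, u), "outside")
})

test_that("top_abundant ranks by FPKM with lexicographic ties", {
  quant <- data.frame(transcript_id = c("c", "a", "b", "d"),
                      class = c("snoRNA", "snoRNA", "mRNA", "mRNA"),
                      ip_fpkm = c(5, 5, 9, 1), input_fpkm = c(1, 2, 3, 4),
                      stringsAsFactors = FALSE)
  top <- top_abundant(quant, n = 3)
  expect_equal(top$top$transcript_id, c("b", "a", "c"))
  expect_equal(top$composition$count[top$composition$class == "snoRNA"], 2L)
  expect_equal(nrow(top_abundant(quant, n = 0)$top), 0L)
  expect_warning(top_abundant(quant, n = 10), "only 4")
})

test_that("class enrichment summary computes fractions and box-type splits", {
  n <- 174
  quant <- data.frame(
    transcript_id = sprintf("s%03d", 1:n),
    class = "snoRNA",
    box_type = rep(c("H/ACA", "C/D"), length.out = n),
    input_fpkm = 5, enriched = c(rep(TRUE, 49), rep(FALSE, n - 49)),
    stringsAsFactors = FALSE)
  s <- class_enrichment_summary(quant)
  sno <- s[s$group == "snoRNA", ]
  expect_equal(sno$n_expressed, 174L)
  expect_equal(sno$n_enriched, 49L)
  expect_equal(sno$fraction, 49 / 174, tolerance = 1e-12)
  expect_equal(round(sno$fraction, 4), 0.2816)
  # box-type counts add up to the class total
  expect_equal(sum(s$n_enriched[s$group %in% c("snoRNA:H/ACA", "snoRNA:C/D")]),
               sno$n_enriched)
  # nothing expressed -> NA fraction
  quant$input_fpkm <- 0
  s0 <- class_enrichment_summary(quant)
  expect_true(is.na(s0$fraction[s0$group == "snoRNA"]))
})

test_that("a strongly planted transcript is flagged enriched in the full quant table", {
  tx <- tiny_ref$class_table$ref_id[tiny_ref$class_table$class == "snoRNA"]
  base <- stats::setNames(rep(60, length(tx)), tx)
  truth <- binding_truth(base, stats::setNames(8, tx[3]),
                         nb_dispersion = 0.01)
  sim <- simulate_libraries(truth, library_sim(seed = 5), tiny_ref,
                            emit_reads = FALSE)
  q <- quantify_transcripts(sim, tiny_ref)
  expect_true(q$enriched[q$transcript_id == tx[3]])
  expect_true(all(q$q >= q$p))
  expect_true(all(q$p >= 0 & q$p <= 1))
})

test_that("the global-null flag rate stays within the nominal level", {
  tx <- tiny_ref$class_table$ref_id[tiny_ref$class_table$class %in%
                                      c("snoRNA", "scaRNA")]
  base <- stats::setNames(rep(80, length(tx)), tx)
  truth <- binding_truth(base, nb_dispersion = 0.01)
  flagged <- 0L; total <- 0L
  for (s in 1:5) {
    sim <- simulate_libraries(truth, library_sim(seed = s), tiny_ref,
                              emit_reads = FALSE)
    q <- quantify_transcripts(sim, tiny_ref)
    q <- q[q$transcript_id %in% tx, ]
    flagged <- flagged + sum(q$enriched)
    total <- total + nrow(q)
  }
  expect_lte(flagged / total, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
})
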