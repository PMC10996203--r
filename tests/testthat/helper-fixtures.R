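# Shared fixtures and independent oracles, built in code at load time.

# small reference reused across tests (cheap to build, deterministic)
tiny_spec <- genome_spec(n_coding_genes = 10, gene_length_range = c(400, 1200),
                         exon_count_range = c(1, 3), n_rdna_copies = 3,
                         n_5s_copies = 2, n_snorna_haca = 8, n_snorna_cd = 6,
                         n_scarna = 3, n_mirna = 2, seed = 42)
tiny_ref <- build_reference(tiny_spec)

tiny_truth <- default_binding_truth(tiny_ref, n_enriched_snorna = 4,
                                    n_peak_sites = 4, seed = 42)
tiny_sim <- simulate_libraries(tiny_truth, library_sim(seed = 42), tiny_ref,
                               emit_reads = FALSE)

# hand-built reference with known annotation geometry, for category tests:
#   geneA (+): span 101-700, exons 101-250 and 401-700
#     -> 5'UTR 101-130, CDS 131-250 & 401-640, 3'UTR 641-700, intron 251-400
#   ncrna1 (+): 801-900
#   geneB (-): span 1001-1400, single exon
mini_ref <- local({
  feats <- data.frame(
    feature_id = c("geneA", "ncrna1", "geneB"),
    kind = c("coding", "ncRNA", "coding"),
    class = c("mRNA", "snoRNA", "mRNA"),
    box_type = c("none", "H/ACA", "none"),
    length = c(600L, 100L, 400L),
    chrom = "chr1",
    start = c(101L, 801L, 1001L),
    end = c(700L, 900L, 1400L),
    strand = c("+", "+", "-"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("geneA", "geneA", "geneB"),
    exon = c(1L, 2L, 1L),
    start = c(101L, 401L, 1001L),
    end = c(250L, 700L, 1400L),
    strand = c("+", "+", "-"),
    stringsAsFactors = FALSE)
  genome <- paste(rep("ACGT", 500), collapse = "")
  structure(list(genome = stats::setNames(genome, "chr1"),
                 refs = character(0), features = feats, exons = exons,
                 class_table = data.frame(ref_id = "ncrna1", class = "snoRNA",
                                          box_type = "H/ACA"),
                 rdna_table = default_rdna_subregions(),
                 domain_table = default_28s_domains(),
                 spec = NULL),
            class = "rip_reference")
})

make_peaks <- function(summits, strands = "+", ref = "chr1") {
  n <- length(summits)
  data.frame(ref = ref, start = summits - 10L, end = summits + 10L,
             summit = summits, ip_count = 50L, input_count = 5L,
             enrichment = 10, p = 0.001,
             strand = rep(strands, length.out = n),
             stringsAsFactors = FALSE)
}

# --- independent statistical oracles -------------------------------------

# exact table probability of a 2x2 table with fixed margins, via binomial
# coefficients (exact in double precision for small totals)
table_prob <- function(a, b, c, d) {
  choose(a + b, a) * choose(c + d, c) / choose(a + b + c + d, a + c)
}

# two-sided Fisher p by exhaustive enumeration of all tables with the same
# margins, summing those no more probable than the observed one (standard
# relative tolerance for floating-point ties). Small tables use exact
# binomial coefficients; larger ones the log-space hypergeometric mass.
fisher_oracle <- function(a, b, c, d) {
  k <- a + c
  lo <- max(0L, k - (c + d))
  hi <- min(k, a + b)
  xs <- lo:hi
  if (a + b + c + d <= 500) {
    probs <- vapply(xs, function(x) table_prob(x, a + b - x, k - x,
                                               c + d - k + x), numeric(1))
    pobs <- table_prob(a, b, c, d)
  } else {
    probs <- stats::dhyper(xs, a + b, c + d, k)
    pobs <- stats::dhyper(a, a + b, c + d, k)
  }
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# upper-tail hypergeometric by explicit summation over draw counts
hyper_tail_oracle <- function(k, N, m, n) {
  if (k > min(m, n)) return(0)
  js <- k:min(m, n)
  sum(vapply(js, function(j) choose(m, j) * choose(N - m, n - j),
             numeric(1))) / choose(N, n)
}
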