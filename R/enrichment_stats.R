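## Per-transcript abundance (FPKM), top-abundant extraction, IP-vs-Input
## enrichment testing, class-level summaries, and gene-set overlap
## statistics.

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = count / (length/1000) / (library_total/1e6)`; exact arithmetic,
#' invariant under joint scaling of count and library total.
#'
#' @param count fragment count (vectorized).
#' @param length effective transcript length in nt.
#' @param library_total total mapped fragments in the library.
#' @return numeric FPKM.
#' @export
compute_fpkm <- function(count, length, library_total) {
  assert_that(all(length > 0) && all(library_total > 0),
              "length and library_total must be > 0")
  count / (length / 1000) / (library_total / 1e6)
}

#' IP-vs-Input enrichment test for one transcript
#'
#' Fold change is the pseudocounted FPKM ratio
#' `(FPKM_IP + eps) / (FPKM_Input + eps)`; the p-value is a two-sided
#' Fisher's exact test on the 2x2 table
#' `[[ip, ip_total - ip], [input, input_total - input]]`.
#'
#' @param ip,input fragment counts for the transcript.
#' @param ip_total,input_total library totals (uniquely mapped fragments).
#' @param length transcript length in nt (cancels in the ratio except
#'   through the pseudocount).
#' @param eps pseudo-FPKM added to numerator and denominator.
#' @return list with `fold_change` and `p`.
#' @export
test_enrichment <- function(ip, input, ip_total, input_total,
                            length = 1000, eps = 0.01) {
  assert_that(ip <= ip_total && input <= input_total,
              "count exceeds library total")
  f_ip <- compute_fpkm(ip, length, ip_total)
  f_in <- compute_fpkm(input, length, input_total)
  fc <- (f_ip + eps) / (f_in + eps)
  p <- if (ip == 0 && input == 0) 1 else
    stats::fisher.test(matrix(c(ip, ip_total - ip, input, input_total - input),
                              nrow = 2, byrow = TRUE))$p.value
  list(fold_change = fc, p = p)
}

#' Benjamini-Hochberg adjustment with input validation
#'
#' Step-up BH with monotonicity enforcement; the input order is preserved.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  assert_that(all(is.finite(p)) && all(p >= 0) && all(p <= 1),
              "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Upper-tail hypergeometric overlap test
#'
#' For sets A, B drawn from a universe of size N, computes
#' `p = P[X >= |A intersect B|]` with `X ~ Hypergeom(N, |A|, |B|)` by exact
#' summation.
#'
#' @param setA,setB character vectors (subsets of `universe`).
#' @param universe character vector of all eligible elements.
#' @return list with `nA`, `nB`, `overlap`, `universe`, `p`, and the
#'   overlapping elements.
#' @export
hypergeometric_overlap <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  outside <- setdiff(c(setA, setB), universe)
  if (length(outside))
    stop("element(s) outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  k <- length(intersect(setA, setB))
  N <- length(universe); m <- length(setA); n <- length(setB)
  p <- stats::phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
  list(nA = m, nB = n, overlap = k, universe = N, p = p,
       elements = sort(intersect(setA, setB)))
}

#' Quantify transcripts and flag IP enrichment
#'
#' Builds the per-transcript quantification table from uniquely mapped
#' reads: pooled IP and Input counts, FPKM, pseudocounted fold change,
#' two-sided Fisher p, BH q, and the enriched flag
#' (`fold_change >= fc_cut & p < p_cut`).
#'
#' @param sim a `rip_simulation` (or any list of libraries with alignment
#'   data.frames named `IP_*` / `Input_*`).
#' @param ref the `rip_reference`.
#' @param fc_cut,p_cut enrichment cut-offs (defaults 2 and 0.05).
#' @param eps pseudo-FPKM for the fold change.
#' @return data.frame of class `rip_quant`, one row per transcript:
#'   `transcript_id`, `class`, `box_type`, `length`, `ip_count`,
#'   `input_count`, `ip_fpkm`, `input_fpkm`, `fold_change`, `p`, `q`,
#'   `enriched`.
#' @export
quantify_transcripts <- function(sim, ref, fc_cut = 2, p_cut = 0.05,
                                 eps = 0.01) {
  libs <- sim$libraries
  ip_names <- grep("^IP", names(libs), value = TRUE)
  in_names <- grep("^Input", names(libs), value = TRUE)
  count_unique <- function(lib) {
    part <- partition_by_multiplicity(lib$alignments)
    count_by_transcript(part$unique, ref)
  }
  ip_counts <- lapply(libs[ip_names], count_unique)
  in_counts <- lapply(libs[in_names], count_unique)
  feats <- ref$features
  single <- feats[!feats$kind %in% c("rdna45S", "rdna5S"), , drop = FALSE]
  ids <- single$feature_id
  pool <- function(lst) {
    m <- vapply(lst, function(cnt) {
      v <- cnt[ids]; v[is.na(v)] <- 0L; v
    }, numeric(length(ids)))
    rowSums(m)
  }
  ip <- pool(ip_counts); input <- pool(in_counts)
  ip_total <- sum(vapply(ip_counts, sum, numeric(1)))
  input_total <- sum(vapply(in_counts, sum, numeric(1)))
  len <- single$length
  ip_fpkm <- compute_fpkm(ip, len, max(ip_total, 1))
  input_fpkm <- compute_fpkm(input, len, max(input_total, 1))
  fc <- (ip_fpkm + eps) / (input_fpkm + eps)
  p <- vapply(seq_along(ids), function(i) {
    if (ip[i] == 0 && input[i] == 0) return(1)
    stats::fisher.test(matrix(c(ip[i], ip_total - ip[i],
                                input[i], input_total - input[i]),
                              nrow = 2, byrow = TRUE))$p.value
  }, numeric(1))
  q <- bh_adjust(p)
  quant <- data.frame(transcript_id = ids, class = single$class,
                      box_type = single$box_type, length = len,
                      ip_count = ip, input_count = input,
                      ip_fpkm = ip_fpkm, input_fpkm = input_fpkm,
                      fold_change = fc, p = p, q = q,
                      enriched = fc >= fc_cut & p < p_cut,
                      stringsAsFactors = FALSE, row.names = NULL)
  class(quant) <- c("rip_quant", "data.frame")
  attr(quant, "totals") <- c(ip = ip_total, input = input_total)
  attr(quant, "cuts") <- c(fc_cut = fc_cut, p_cut = p_cut)
  quant
}

# Count uniquely mapped reads per single-copy transcript. Reads on a
# standalone ncRNA reference count directly; genomic (chr1) reads are
# assigned to the coding gene whose span contains the read midpoint.
count_by_transcript <- function(aln, ref) {
  feats <- ref$features
  counts <- integer(0)
  tx <- aln[aln$ref != "chr1", , drop = FALSE]
  if (nrow(tx)) {
    tab <- table(tx$ref[!duplicated(tx$read_id)])
    counts <- stats::setNames(as.integer(tab), names(tab))
  }
  gen <- aln[aln$ref == "chr1", , drop = FALSE]
  if (nrow(gen)) {
    genes <- feats[feats$kind == "coding", , drop = FALSE]
    if (nrow(genes)) {
      genes <- genes[order(genes$start), , drop = FALSE]
      mid <- (gen$start + gen$end - 1L) %/% 2L + 1L
      idx <- findInterval(mid, genes$start)
      ok <- idx >= 1L & mid <= genes$end[pmax(idx, 1L)]
      tab <- table(genes$feature_id[idx[ok]])
      add <- stats::setNames(as.integer(tab), names(tab))
      counts <- c(counts, add[setdiff(names(add), names(counts))])
      both <- intersect(names(add), names(counts))
      counts[both] <- counts[both] + add[both]
    }
  }
  counts
}

#' Top abundant transcripts
#'
#' The `n` transcripts with the highest value of the ranking key (IP FPKM by
#' default), ties broken by transcript id, with a class-composition table.
#'
#' @param quant a `rip_quant` table.
#' @param n how many transcripts (default 100).
#' @param rank_by `"ip_fpkm"`, `"input_fpkm"` or `"mean_fpkm"`.
#' @return list with `top` (ordered subset of `quant`) and `composition`
#'   (per-class counts among the top n).
#' @export
top_abundant <- function(quant, n = 100, rank_by = "ip_fpkm") {
  assert_that(nrow(quant) > 0, "quant table is empty")
  key <- switch(rank_by,
                ip_fpkm = quant$ip_fpkm,
                input_fpkm = quant$input_fpkm,
                mean_fpkm = (quant$ip_fpkm + quant$input_fpkm) / 2,
                stop("unknown rank_by: ", rank_by, call. = FALSE))
  if (n > nrow(quant)) {
    warning("requested top ", n, " but only ", nrow(quant),
            " transcripts available")
    n <- nrow(quant)
  }
  ord <- order(-key, quant$transcript_id)
  top <- quant[ord[seq_len(n)], , drop = FALSE]
  rownames(top) <- NULL
  tab <- table(top$class)
  comp <- data.frame(class = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
  list(top = top, composition = comp)
}

#' Per-class enrichment summary
#'
#' For each ncRNA class (and each snoRNA box type) counts expressed
#' transcripts (Input FPKM above `expressed_floor`), enriched transcripts,
#' and the enriched fraction.
#'
#' @param quant a `rip_quant` table with the `enriched` flag set.
#' @param expressed_floor minimum Input FPKM to call a transcript expressed.
#' @return data.frame: `group`, `n_expressed`, `n_enriched`, `fraction`
#'   (`NA` when nothing in the group is expressed).
#' @export
class_enrichment_summary <- function(quant, expressed_floor = 1) {
  expressed <- quant$input_fpkm >= expressed_floor
  groups <- c(stats::setNames(nm = sort(unique(quant$class))),
              "snoRNA:H/ACA" = "snoRNA:H/ACA", "snoRNA:C/D" = "snoRNA:C/D")
  rows <- lapply(names(groups), function(g) {
    if (startsWith(g, "snoRNA:")) {
      box <- sub("^snoRNA:", "", g)
      sel <- quant$class == "snoRNA" & quant$box_type == box
    } else sel <- quant$class == g
    ne <- sum(sel & expressed)
    nf <- sum(sel & expressed & quant$enriched)
    data.frame(group = g, n_expressed = ne, n_enriched = nf,
               fraction = if (ne > 0) nf / ne else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Top enriched transcripts of a class
#'
#' Enriched transcripts of `class`, ranked by fold change (ties by p, then
#' id).
#'
#' @param quant a `rip_quant` table.
#' @param class transcript class to rank within.
#' @param n list length.
#' @return ordered subset of `quant`.
#' @export
top_enriched <- function(quant, class = "snoRNA", n = 20) {
  sel <- quant[quant$class == class & quant$enriched, , drop = FALSE]
  ord <- order(-sel$fold_change, sel$p, sel$transcript_id)
  out <- sel[ord[seq_len(min(n, nrow(sel)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}
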