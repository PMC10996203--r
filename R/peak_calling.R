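## Peak calling from uniquely mapped IP reads against Input, peak annotation
## with a fixed category priority, replicate-intersection bound genes, and a
## direct (CA)-repeat enrichment scan.

#' Peak-calling parameters
#'
#' @param min_depth minimum IP depth for a candidate position (reads).
#' @param merge_gap candidate runs separated by gaps of at most this many nt
#'   are merged.
#' @param n_permutations permutations for the empirical background (>= 100).
#' @param alpha significance level for the empirical p-value.
#' @param min_enrichment minimum Input-normalized fold enrichment.
#' @param pseudocount reads added to the Input window before computing
#'   enrichment (guards against Input-empty windows).
#' @param seed RNG seed for the permutation background.
#' @return object of class `peak_call_params`.
#' @export
peak_call_params <- function(min_depth = 10, merge_gap = 20,
                             n_permutations = 200, alpha = 0.05,
                             min_enrichment = 2, pseudocount = 1, seed = 1L) {
  assert_that(n_permutations >= 100, "n_permutations must be >= 100")
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  assert_that(min_enrichment >= 1, "min_enrichment must be >= 1")
  structure(list(min_depth = min_depth, merge_gap = as.integer(merge_gap),
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 min_enrichment = min_enrichment, pseudocount = pseudocount,
                 seed = as.integer(seed)),
            class = "peak_call_params")
}

# Null distribution of the maximum coverage depth when n reads (with the
# given lengths) are placed uniformly on a reference of length ref_len.
null_max_depth <- function(n_reads, read_lens, ref_len, n_perm) {
  vapply(seq_len(n_perm), function(b) {
    st <- sample.int(ref_len, n_reads, replace = TRUE) - 1L
    en <- pmin(st + read_lens, ref_len)
    max(interval_coverage(st, en, ref_len))
  }, numeric(1))
}

#' Call IP-enriched peaks against Input
#'
#' Candidate peaks are maximal runs of positions with IP depth >=
#' `min_depth`, merged across gaps <= `merge_gap`. Each candidate's
#' empirical p-value is the fraction of permutations -- the same number of
#' IP reads placed uniformly on the same reference -- whose maximum depth
#' reaches the candidate's maximum depth (with the add-one convention, so
#' p-values are super-uniform under the null). Enrichment is the
#' library-size-normalized IP/Input density ratio with a pseudocount on the
#' Input window. Peaks are kept iff p < alpha and enrichment >=
#' `min_enrichment`.
#'
#' @param ip alignment data.frame of uniquely mapped IP reads.
#' @param input alignment data.frame of Input reads.
#' @param params a [peak_call_params()].
#' @param ref_len named vector of reference lengths.
#' @return data.frame of peaks (class `rip_peaks`): `ref`, `start`, `end`
#'   (0-based half-open), `summit` (1-based), `ip_count`, `input_count`,
#'   `enrichment`, `p`, `strand`.
#' @export
call_peaks <- function(ip, input, params = peak_call_params(), ref_len) {
  validate_alignments(ip)
  missing_ref <- setdiff(unique(ip$ref), names(ref_len))
  if (length(missing_ref))
    stop("reference(s) absent from the annotation genome: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  ip_total <- length(unique(ip$read_id))
  input_total <- max(length(unique(input$read_id)), 1L)

  out <- list()
  for (rf in unique(ip$ref)) {
    L <- as.integer(ref_len[[rf]])
    ipr <- ip[ip$ref == rf, , drop = FALSE]
    inr <- input[input$ref == rf, , drop = FALSE]
    cov_ip <- interval_coverage(ipr$start, ipr$end, L)
    cand <- true_runs(cov_ip >= params$min_depth, params$merge_gap)
    if (nrow(cand) == 0L) next
    null_max <- with_seed(derive_seed(params$seed, match(rf, unique(ip$ref))),
                          null_max_depth(nrow(ipr), ipr$end - ipr$start, L,
                                         params$n_permutations))
    for (i in seq_len(nrow(cand))) {
      s <- cand[i, "start"]; e <- cand[i, "end"]   # 1-based closed
      seg <- cov_ip[s:e]
      peak_max <- max(seg)
      summit <- s + which.max(seg) - 1L            # leftmost max, 1-based
      p <- (1 + sum(null_max >= peak_max)) / (1 + params$n_permutations)
      ip_count <- sum(ipr$start < e & ipr$end > s - 1L)
      input_count <- if (nrow(inr)) sum(inr$start < e & inr$end > s - 1L) else 0L
      width <- e - s + 1L
      dens_ip <- ip_count / width / (ip_total / 1e6)
      dens_in <- (input_count + params$pseudocount) / width / (input_total / 1e6)
      enrich <- dens_ip / dens_in
      if (p < params$alpha && enrich >= params$min_enrichment) {
        str_tab <- table(ipr$strand[ipr$start < e & ipr$end > s - 1L])
        out[[length(out) + 1L]] <- data.frame(
          ref = rf, start = s - 1L, end = e, summit = summit,
          ip_count = ip_count, input_count = input_count,
          enrichment = enrich, p = p,
          strand = names(str_tab)[which.max(str_tab)],
          stringsAsFactors = FALSE)
      }
    }
  }
  peaks <- if (length(out)) do.call(rbind, out) else
    data.frame(ref = character(0), start = integer(0), end = integer(0),
               summit = integer(0), ip_count = integer(0),
               input_count = integer(0), enrichment = numeric(0),
               p = numeric(0), strand = character(0))
  rownames(peaks) <- NULL
  class(peaks) <- c("rip_peaks", "data.frame")
  attr(peaks, "params") <- params
  peaks
}

#' Annotate peaks to genomic features
#'
#' Each peak receives exactly one category, evaluated at its summit, by the
#' fixed priority CDS > 5'UTR > 3'UTR > ncRNA-exon > intron > antisense >
#' intergenic. `antisense` means the summit lies inside a gene on the
#' opposite strand only; unstranded peaks (`strand == "*"`) match features
#' on either strand and can therefore never be antisense.
#'
#' @param peaks a `rip_peaks` data.frame.
#' @param ref a `rip_reference` (supplies features and exon models).
#' @return the peaks with `category` and `gene_id` columns, plus a
#'   `distribution` attribute (category fractions summing to 1).
#' @export
annotate_peaks <- function(peaks, ref) {
  feats <- ref$features
  exons <- ref$exons
  genes <- feats[feats$kind == "coding", , drop = FALSE]
  nc <- feats[feats$kind %in% c("ncRNA", "rdna45S", "rdna5S"), , drop = FALSE]
  cat_out <- character(nrow(peaks))
  gene_out <- rep(NA_character_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    pos <- peaks$summit[i]
    pstrand <- peaks$strand[i]
    if (peaks$ref[i] != "chr1") {           # peak on a standalone ncRNA ref
      cat_out[i] <- "ncRNA-exon"
      gene_out[i] <- peaks$ref[i]
      next
    }
    same <- function(fstrand) pstrand == "*" | fstrand == pstrand
    hit_genes <- genes[genes$start <= pos & genes$end >= pos, , drop = FALSE]
    hit_nc <- nc[nc$start <= pos & nc$end >= pos, , drop = FALSE]
    sense_genes <- hit_genes[same(hit_genes$strand), , drop = FALSE]
    sense_nc <- hit_nc[same(hit_nc$strand), , drop = FALSE]
    cat <- "intergenic"; gid <- NA_character_
    if (nrow(sense_genes)) {
      g <- sense_genes[1L, ]
      ex <- exons[exons$gene_id == g$feature_id, , drop = FALSE]
      in_ex <- ex[ex$start <= pos & ex$end >= pos, , drop = FALSE]
      if (nrow(in_ex)) {
        # first/last exon edges carry the UTRs (20% of the terminal exons)
        first <- ex[1L, ]; last <- ex[nrow(ex), ]
        utr5_len <- max(10L, as.integer(0.2 * (first$end - first$start + 1L)))
        utr3_len <- max(10L, as.integer(0.2 * (last$end - last$start + 1L)))
        if (g$strand == "+") {
          in_utr5 <- pos <= first$start + utr5_len - 1L
          in_utr3 <- pos >= last$end - utr3_len + 1L
        } else {
          in_utr5 <- pos >= last$end - utr5_len + 1L
          in_utr3 <- pos <= first$start + utr3_len - 1L
        }
        cat <- if (in_utr5) "5UTR" else if (in_utr3) "3UTR" else "CDS"
      } else cat <- "intron"
      gid <- g$feature_id
    } else if (nrow(sense_nc)) {
      cat <- "ncRNA-exon"; gid <- sense_nc$feature_id[1L]
    } else if (nrow(hit_genes) || nrow(hit_nc)) {
      cat <- "antisense"
      gid <- c(hit_genes$feature_id, hit_nc$feature_id)[1L]
    }
    cat_out[i] <- cat; gene_out[i] <- gid
  }
  # priority order means CDS beats antisense etc. by construction above
  peaks$category <- cat_out
  peaks$gene_id <- gene_out
  lv <- c("CDS", "5UTR", "3UTR", "ncRNA-exon", "intron", "antisense",
          "intergenic")
  tab <- table(factor(cat_out, levels = lv))
  attr(peaks, "distribution") <-
    data.frame(category = lv, count = as.integer(tab),
               fraction = if (nrow(peaks)) as.integer(tab) / nrow(peaks) else
                 rep(NA_real_, length(lv)))
  peaks
}

#' Confident bound genes from replicate agreement
#'
#' Genes with at least one annotated peak (any category except intergenic)
#' in each of the two replicate peak sets.
#'
#' @param peaks1,peaks2 annotated peak sets from the two IP replicates.
#' @return sorted character vector of gene ids.
#' @export
confident_bound_genes <- function(peaks1, peaks2) {
  bound <- function(p) unique(p$gene_id[!is.na(p$gene_id) &
                                          p$category != "intergenic"])
  sort(intersect(bound(peaks1), bound(peaks2)))
}

# maximal (CA)n run length (in units) on both strands, allowing the AC phase
max_ca_run <- function(seq) {
  best <- 0L
  for (pat in c("(CA)+", "(AC)+", "(TG)+", "(GT)+")) {
    m <- gregexpr(pat, seq)[[1]]
    if (m[1] != -1L)
      best <- max(best, max(attr(m, "match.length")) %/% 2L)
  }
  best
}

# dinucleotide tile shuffle: permute the sequence's non-overlapping 2-mers
dinucleotide_shuffle <- function(seq) {
  n <- nchar(seq)
  tiles <- substring(seq, seq(1, n - 1, by = 2), pmin(seq(2, n, by = 2), n))
  paste(sample(tiles), collapse = "")
}

#' (CA)-repeat enrichment in peak sequences
#'
#' Scans each peak sequence for its maximal (CA)n run (n >= 3; both strands;
#' AC phase allowed). The statistic is the fraction of peaks containing a
#' run of at least `min_units` units; the null distribution is the same
#' statistic on dinucleotide-shuffled peak sequences.
#'
#' @param peaks annotated peaks on the genome.
#' @param ref a `rip_reference` (source of peak sequences).
#' @param min_units run-length threshold L (units of CA).
#' @param n_shuffles shuffle replicates for the null.
#' @param seed RNG seed.
#' @return list with `run_lengths`, `stat` (observed fraction), `null`
#'   (shuffled statistics), `z` and `p_empirical`.
#' @export
ca_repeat_enrichment <- function(peaks, ref, min_units = 5L,
                                 n_shuffles = 200L, seed = 1L) {
  glen <- nchar(ref$genome[[1]])
  if (any(peaks$start < 0L | peaks$end > glen))
    stop("peak outside genome bounds", call. = FALSE)
  seqs <- substring(ref$genome[[1]], peaks$start + 1L, peaks$end)
  runs <- vapply(seqs, max_ca_run, integer(1), USE.NAMES = FALSE)
  runs[runs < 3L] <- 0L                      # runs below n = 3 don't count
  stat <- mean(runs >= min_units)
  null <- with_seed(seed, vapply(seq_len(n_shuffles), function(b) {
    sh <- vapply(seqs, dinucleotide_shuffle, character(1), USE.NAMES = FALSE)
    r <- vapply(sh, max_ca_run, integer(1), USE.NAMES = FALSE)
    r[r < 3L] <- 0L
    mean(r >= min_units)
  }, numeric(1)))
  z <- (stat - mean(null)) / max(stats::sd(null), 1e-12)
  p_emp <- (1 + sum(null >= stat)) / (1 + n_shuffles)
  list(run_lengths = runs, stat = stat, null = null, z = z,
       p_empirical = p_emp)
}
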