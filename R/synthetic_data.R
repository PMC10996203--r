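## Synthetic reference + library generator with planted binding truth.
##
## The generator emulates the statistical structure of a structured-RNA
## RIP-seq experiment: two IP and two Input replicate libraries, a multicopy
## 45S rDNA transcription unit (identical copies, hence multi-mapped reads),
## single-copy snoRNA/scaRNA/miRNA genes, an IP-specific binding window on
## 28S rRNA domain II, count noise that is negative-binomial, and a small
## fraction of QC-failing raw reads (N-contaminated, too short).

#' Specification of a synthetic genome
#'
#' Describes the toy genome used by [build_reference()]: protein-coding genes
#' with exon/intron structure, a multicopy 45S rDNA unit
#' (5'ETS-18S-ITS1-5.8S-ITS2-28S-3'ETS), multicopy 5S rDNA, and single-copy
#' structured ncRNA genes (H/ACA and C/D box snoRNAs, scaRNAs, miRNAs).
#'
#' @param n_coding_genes number of protein-coding genes.
#' @param gene_length_range length range (nt) for coding-gene spans.
#' @param exon_count_range range of exon counts per coding gene.
#' @param n_rdna_copies number of sequence-identical 45S repeat copies;
#'   drives multi-mapping.
#' @param rdna_subregions data.frame with columns `name`, `length` giving the
#'   ordered subregions of the 45S unit. Defaults approximate the human unit.
#' @param n_5s_copies number of identical 5S rDNA copies.
#' @param n_snorna_haca,n_snorna_cd,n_scarna,n_mirna ncRNA gene counts.
#' @param intergenic_fraction fraction of the genome left intergenic.
#' @param genome_length optional explicit genome length (nt); an error is
#'   raised if the features do not fit.
#' @param seed RNG seed; identical seeds give byte-identical references.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(n_coding_genes = 80,
                        gene_length_range = c(500, 3000),
                        exon_count_range = c(1, 5),
                        n_rdna_copies = 3,
                        rdna_subregions = default_rdna_subregions(),
                        n_5s_copies = 3,
                        n_snorna_haca = 100,
                        n_snorna_cd = 74,
                        n_scarna = 20,
                        n_mirna = 10,
                        intergenic_fraction = 0.3,
                        genome_length = NULL,
                        seed = 1L) {
  counts <- c(n_coding_genes, n_rdna_copies, n_5s_copies, n_snorna_haca,
              n_snorna_cd, n_scarna, n_mirna)
  assert_that(all(counts >= 0), "all feature counts must be >= 0")
  assert_that(all(rdna_subregions$length >= 50),
              "rDNA subregion lengths must be >= 50 nt")
  assert_that(intergenic_fraction >= 0 && intergenic_fraction < 1,
              "intergenic_fraction must lie in [0, 1)")
  structure(list(n_coding_genes = as.integer(n_coding_genes),
                 gene_length_range = as.integer(gene_length_range),
                 exon_count_range = as.integer(exon_count_range),
                 n_rdna_copies = as.integer(n_rdna_copies),
                 rdna_subregions = rdna_subregions,
                 n_5s_copies = as.integer(n_5s_copies),
                 n_snorna_haca = as.integer(n_snorna_haca),
                 n_snorna_cd = as.integer(n_snorna_cd),
                 n_scarna = as.integer(n_scarna),
                 n_mirna = as.integer(n_mirna),
                 intergenic_fraction = intergenic_fraction,
                 genome_length = genome_length,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Default 45S rDNA subregion lengths
#'
#' Ordered subregions of the 45S transcription unit with lengths close to the
#' human unit (total 13,358 nt; 28S spans 5,070 nt).
#' @return data.frame with columns `name` and `length`.
#' @export
default_rdna_subregions <- function() {
  data.frame(name = c("5ETS", "18S", "ITS1", "5.8S", "ITS2", "28S", "3ETS"),
             length = c(3657L, 1869L, 1077L, 157L, 1167L, 5070L, 361L),
             stringsAsFactors = FALSE)
}

#' Default 28S secondary-structure domain intervals
#'
#' Six domains (I-VI) tiling the synthetic 5,070-nt 28S, in local 1-based
#' closed coordinates. Domain II contains the residues 1776-2242 used as the
#' default planted binding window, and the 2'-O-methylation sites 2388, 2409
#' and 2411.
#' @return data.frame with columns `name`, `start`, `end`.
#' @export
default_28s_domains <- function() {
  data.frame(name = c("I", "II", "III", "IV", "V", "VI"),
             start = c(1L, 1401L, 2801L, 3301L, 4101L, 4701L),
             end   = c(1400L, 2800L, 3300L, 4100L, 4700L, 5070L),
             stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
}

#' Build the synthetic reference bundle
#'
#' Lays out every feature of a [genome_spec()] on a single chromosome with
#' intergenic gaps, emitting the genome sequence, standalone structured-RNA
#' reference sequences (one per rDNA copy, all copies sequence-identical,
#' plus each ncRNA transcript), a feature table, an ncRNA class table, the
#' 45S subregion interval table and the 28S domain interval table.
#'
#' @param spec a [genome_spec()].
#' @return an object of class `rip_reference`: a list with elements
#'   `genome` (named character, chromosome sequences), `refs` (named
#'   character, structured reference sequences), `features` (data.frame of
#'   genomic features), `class_table`, `rdna_table` (45S subregions, local
#'   1-based closed), `domain_table` (28S domains), `exons` (per-gene exon
#'   model) and `spec`.
#' @export
build_reference <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, build_reference_impl(spec))
}

build_reference_impl <- function(spec) {
  rd <- spec$rdna_subregions
  len45 <- sum(rd$length)
  unit45 <- random_dna(len45)
  len5s <- 121L
  unit5s <- random_dna(len5s)

  ncrna <- function(prefix, n, lo, hi, class, box) {
    if (n == 0L) return(NULL)
    data.frame(feature_id = sprintf("%s%03d", prefix, seq_len(n)),
               kind = "ncRNA", class = class, box_type = box,
               length = sample(lo:hi, n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  feats <- list(
    if (spec$n_coding_genes > 0L)
      data.frame(feature_id = sprintf("gene%03d", seq_len(spec$n_coding_genes)),
                 kind = "coding", class = "mRNA", box_type = "none",
                 length = sample(spec$gene_length_range[1]:spec$gene_length_range[2],
                                 spec$n_coding_genes, replace = TRUE),
                 stringsAsFactors = FALSE),
    if (spec$n_rdna_copies > 0L)
      data.frame(feature_id = sprintf("rDNA45S_%d", seq_len(spec$n_rdna_copies)),
                 kind = "rdna45S", class = "rRNA", box_type = "none",
                 length = len45, stringsAsFactors = FALSE),
    if (spec$n_5s_copies > 0L)
      data.frame(feature_id = sprintf("rDNA5S_%d", seq_len(spec$n_5s_copies)),
                 kind = "rdna5S", class = "rRNA", box_type = "none",
                 length = len5s, stringsAsFactors = FALSE),
    ncrna("SNORA", spec$n_snorna_haca, 125L, 140L, "snoRNA", "H/ACA"),
    ncrna("SNORD", spec$n_snorna_cd, 70L, 95L, "snoRNA", "C/D"),
    ncrna("SCARNA", spec$n_scarna, 130L, 270L, "scaRNA", "none"),
    ncrna("MIR", spec$n_mirna, 60L, 85L, "miRNA", "none"))
  feats <- do.call(rbind, feats)
  total_feat <- sum(feats$length)

  glen <- spec$genome_length %||%
    as.integer(ceiling(total_feat / (1 - spec$intergenic_fraction)))
  if (total_feat > glen)
    stop(sprintf("infeasible packing: features need %d nt but genome length is %d nt",
                 total_feat, glen), call. = FALSE)

  ord <- sample.int(nrow(feats))
  feats <- feats[ord, , drop = FALSE]
  nfeat <- nrow(feats)
  slack <- glen - total_feat
  gaps <- if (slack > 0L)
    as.integer(stats::rmultinom(1L, slack, rep(1, nfeat + 1L))) else
    integer(nfeat + 1L)
  starts <- integer(nfeat)
  pos <- 1L + gaps[1L]
  for (i in seq_len(nfeat)) {
    starts[i] <- pos
    pos <- pos + feats$length[i] + gaps[i + 1L]
  }
  feats$chrom <- "chr1"
  feats$start <- starts                       # 1-based closed
  feats$end <- starts + feats$length - 1L
  feats$strand <- sample(c("+", "-"), nfeat, replace = TRUE)
  feats$strand[feats$kind %in% c("rdna45S", "rdna5S")] <- "+"

  genome <- random_dna(glen)
  # splice identical rDNA units (and every feature's standalone sequence)
  # into the chromosome
  seqs <- character(nfeat)
  for (i in seq_len(nfeat)) {
    s <- switch(feats$kind[i], rdna45S = unit45, rdna5S = unit5s,
                substr(genome, feats$start[i], feats$end[i]))
    seqs[i] <- s
    substr(genome, feats$start[i], feats$end[i]) <- s
  }

  # exon models for coding genes: ~50% exonic, exons evenly spread; first and
  # last exon carry the UTRs
  exons <- list()
  for (i in which(feats$kind == "coding")) {
    L <- feats$length[i]
    n_ex <- sample(spec$exon_count_range[1]:spec$exon_count_range[2], 1L)
    ex_total <- max(n_ex * 30L, as.integer(0.5 * L))
    ex_total <- min(ex_total, L)
    ex_len <- rep(ex_total %/% n_ex, n_ex)
    ex_len[1L] <- ex_len[1L] + ex_total %% n_ex
    gap_total <- L - ex_total
    ig <- if (n_ex > 1L) rep(gap_total %/% (n_ex - 1L), n_ex - 1L) else integer(0)
    if (n_ex > 1L) ig[1L] <- ig[1L] + gap_total %% (n_ex - 1L)
    p <- feats$start[i]
    es <- integer(n_ex); ee <- integer(n_ex)
    for (k in seq_len(n_ex)) {
      es[k] <- p; ee[k] <- p + ex_len[k] - 1L
      p <- ee[k] + 1L + if (k < n_ex) ig[k] else 0L
    }
    exons[[feats$feature_id[i]]] <-
      data.frame(gene_id = feats$feature_id[i], exon = seq_len(n_ex),
                 start = es, end = ee, strand = feats$strand[i],
                 stringsAsFactors = FALSE)
  }
  exons <- if (length(exons)) do.call(rbind, exons) else
    data.frame(gene_id = character(0), exon = integer(0), start = integer(0),
               end = integer(0), strand = character(0))
  rownames(exons) <- NULL

  refs <- seqs[feats$kind != "coding"]
  names(refs) <- feats$feature_id[feats$kind != "coding"]

  class_table <- data.frame(ref_id = feats$feature_id[feats$kind != "coding"],
                            class = feats$class[feats$kind != "coding"],
                            box_type = feats$box_type[feats$kind != "coding"],
                            stringsAsFactors = FALSE)

  rdna_table <- data.frame(name = rd$name,
                           start = cumsum(c(1L, rd$length[-nrow(rd)])),
                           end = cumsum(rd$length),
                           stringsAsFactors = FALSE)

  structure(list(genome = stats::setNames(genome, "chr1"),
                 refs = refs,
                 features = feats,
                 exons = exons,
                 class_table = class_table,
                 rdna_table = rdna_table,
                 domain_table = default_28s_domains(),
                 spec = spec),
            class = "rip_reference")
}

#' @export
print.rip_reference <- function(x, ...) {
  cat("Synthetic RIP-seq reference bundle\n")
  cat(sprintf("  genome: %s (%d nt)\n", names(x$genome), nchar(x$genome)))
  cat(sprintf("  features: %d (%d coding, %d rDNA copies, %d structured ncRNA)\n",
              nrow(x$features), sum(x$features$kind == "coding"),
              sum(x$features$kind %in% c("rdna45S", "rdna5S")),
              sum(x$features$kind == "ncRNA")))
  invisible(x)
}

#' Planted binding truth for the simulator
#'
#' @param baseline_expression named numeric vector: mean Input fragment count
#'   per source. Keys are feature ids, plus the special keys `"45S"`, `"5S"`
#'   (the multicopy units) and `"chr1"` (uniform genomic background used by
#'   the peak caller's Input model).
#' @param enriched_transcripts named numeric vector of IP enrichment factors
#'   (>= 1); sources absent from it have factor 1.
#' @param rrna_binding_window list with `start`, `end` (1-based closed, local
#'   to the 28S) and `factor`: IP fragment start positions inside the window
#'   are up-weighted by `factor` and renormalized.
#' @param peak_sites data.frame of planted genomic IP binding sites with
#'   columns `chrom`, `start`, `end` (1-based closed), `factor`, `strand`,
#'   `motif` (logical: carries a (CA)-repeat).
#' @param nb_dispersion negative-binomial dispersion shared by all counts
#'   (variance = mu + dispersion * mu^2).
#' @return object of class `binding_truth`.
#' @export
binding_truth <- function(baseline_expression,
                          enriched_transcripts = numeric(0),
                          rrna_binding_window = NULL,
                          peak_sites = NULL,
                          nb_dispersion = 0.01) {
  assert_that(all(baseline_expression > 0), "baseline means must be > 0")
  assert_that(length(enriched_transcripts) == 0 || all(enriched_transcripts >= 1),
              "enrichment factors must be >= 1")
  assert_that(nb_dispersion > 0, "nb_dispersion must be > 0")
  if (!is.null(rrna_binding_window)) {
    assert_that(rrna_binding_window$factor >= 1, "window factor must be >= 1")
    assert_that(rrna_binding_window$start >= 1 &&
                rrna_binding_window$end >= rrna_binding_window$start,
                "rrna_binding_window must be a valid 1-based interval")
  }
  structure(list(baseline_expression = baseline_expression,
                 enriched_transcripts = enriched_transcripts,
                 rrna_binding_window = rrna_binding_window,
                 peak_sites = peak_sites,
                 nb_dispersion = nb_dispersion),
            class = "binding_truth")
}

#' Default study-condition binding truth
#'
#' Emulates the experiment the package models: the 45S unit carries ~23% of
#' Input fragments' worth of rDNA at an 8-fold IP count enrichment (giving
#' ~40% multi-mapped IP reads and an IP 45S fraction several-fold above
#' Input), an 8-fold placement window on 28S residues 1776-2242 (domain II),
#' a set of planted IP-enriched H/ACA snoRNAs, and planted genomic peak
#' sites in CDS/intron/intergenic/antisense context.
#'
#' @param ref a `rip_reference`.
#' @param n_enriched_snorna number of planted enriched snoRNAs.
#' @param snorna_factor IP enrichment factor of planted snoRNAs.
#' @param enriched_box `"H/ACA"`, `"C/D"` or `"both"`: which box types are
#'   eligible for planting.
#' @param rrna_window_factor placement up-weighting of the 28S window.
#' @param rdna_ip_factor IP count enrichment factor of the whole 45S unit.
#' @param n_peak_sites number of planted genomic peak sites.
#' @param peak_factor placement up-weighting inside each planted site.
#' @param nb_dispersion shared negative-binomial dispersion.
#' @param seed RNG seed used to pick planted transcripts and site loci.
#' @return a [binding_truth()].
#' @export
default_binding_truth <- function(ref,
                                  n_enriched_snorna = 30,
                                  snorna_factor = 6,
                                  enriched_box = "H/ACA",
                                  rrna_window_factor = 8,
                                  rdna_ip_factor = 8,
                                  n_peak_sites = 12,
                                  peak_factor = 50,
                                  nb_dispersion = 0.01,
                                  seed = 1L) {
  stopifnot(inherits(ref, "rip_reference"))
  with_seed(seed, {
    feats <- ref$features
    base <- c("chr1" = 6000, "45S" = 3100, "5S" = 50)
    coding <- feats$feature_id[feats$kind == "coding"]
    if (length(coding))
      base[coding] <- round(stats::rlnorm(length(coding), log(120), 0.6))
    sno <- feats[feats$class == "snoRNA", ]
    if (nrow(sno))
      base[sno$feature_id] <- round(stats::rlnorm(nrow(sno), log(70), 0.5))
    sca <- feats$feature_id[feats$class == "scaRNA"]
    if (length(sca)) base[sca] <- round(stats::rlnorm(length(sca), log(45), 0.4))
    mir <- feats$feature_id[feats$class == "miRNA"]
    if (length(mir)) base[mir] <- round(stats::rlnorm(length(mir), log(25), 0.4))
    base <- pmax(base, 5)

    enr <- c("45S" = rdna_ip_factor)
    eligible <- switch(enriched_box,
                       "H/ACA" = sno$feature_id[sno$box_type == "H/ACA"],
                       "C/D" = sno$feature_id[sno$box_type == "C/D"],
                       sno$feature_id)
    planted <- sort(sample(eligible, min(n_enriched_snorna, length(eligible))))
    # planted snoRNAs get a boosted baseline so they sit among the abundant
    base[planted] <- pmax(base[planted], 50)
    enr[planted] <- snorna_factor

    win28 <- list(start = 1776L, end = 2242L, factor = rrna_window_factor)

    peak_sites <- pick_peak_sites(ref, n_peak_sites, peak_factor)
    binding_truth(baseline_expression = base,
                  enriched_transcripts = enr,
                  rrna_binding_window = win28,
                  peak_sites = peak_sites,
                  nb_dispersion = nb_dispersion)
  })
}

# Choose planted genomic peak sites in a mix of annotation contexts:
# CDS, intron, intergenic and antisense (inside a gene, opposite strand).
pick_peak_sites <- function(ref, n, factor, width = 60L) {
  feats <- ref$features
  glen <- nchar(ref$genome[[1]])
  coding <- feats[feats$kind == "coding", ]
  kinds <- rep(c("cds", "intron", "intergenic", "antisense"), length.out = n)
  out <- list()
  occupied <- feats[, c("start", "end")]
  for (i in seq_len(n)) {
    k <- kinds[i]
    if (k %in% c("cds", "intron", "antisense") && nrow(coding)) {
      g <- coding[sample.int(nrow(coding), 1L), ]
      ex <- ref$exons[ref$exons$gene_id == g$feature_id, ]
      if (k == "intron" && nrow(ex) > 1L) {
        s <- ex$end[1L] + 5L
      } else {
        s <- ex$start[1L] + max(5L, (ex$end[1L] - ex$start[1L]) %/% 3L)
      }
      e <- min(s + width - 1L, g$end)
      strand <- if (k == "antisense") setdiff(c("+", "-"), g$strand)[1] else g$strand
    } else {
      # intergenic: scan for a gap large enough
      gaps_start <- c(1L, sort(occupied$end) + 1L)
      gaps_end <- c(sort(occupied$start) - 1L, glen)
      ok <- which(gaps_end - gaps_start + 1L >= width + 10L)
      gi <- ok[sample.int(length(ok), 1L)]
      s <- gaps_start[gi] + 5L
      e <- s + width - 1L
      strand <- sample(c("+", "-"), 1L)
    }
    out[[i]] <- data.frame(chrom = "chr1", start = s, end = e,
                           factor = factor, strand = strand,
                           motif = i %% 2L == 1L, stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, out)
  sites[!duplicated(sites$start), , drop = FALSE]
}

#' Embed (CA)-repeat motifs at planted sites
#'
#' Writes a `(CA)n` run at the center of each site flagged `motif = TRUE`,
#' so motif-enrichment scans have planted signal to recover.
#'
#' @param ref a `rip_reference`.
#' @param sites peak-site data.frame (see [binding_truth()]).
#' @param n_units number of CA units to embed.
#' @return the modified `rip_reference`.
#' @export
plant_ca_repeats <- function(ref, sites, n_units = 10L) {
  stopifnot(inherits(ref, "rip_reference"))
  motif <- strrep("CA", n_units)
  g <- ref$genome[[1]]
  for (i in which(sites$motif)) {
    mid <- (sites$start[i] + sites$end[i]) %/% 2L
    s <- mid - nchar(motif) %/% 2L
    substr(g, s, s + nchar(motif) - 1L) <- motif
  }
  ref$genome[[1]] <- g
  ref
}

#' Library-simulation parameters
#'
#' @param n_fragments nominal fragments per Input library, or `NULL` to use
#'   the truth's baseline means as absolute counts (the default study scale).
#' @param read_length read length (nt), >= 16.
#' @param n_replicates replicate libraries per condition.
#' @param frac_n_contaminated fraction of extra raw reads carrying > 2 N
#'   bases (exercises the QC N-rule).
#' @param frac_short fraction of extra raw reads truncated below 16 nt.
#' @param seed RNG seed.
#' @return object of class `library_sim`.
#' @export
library_sim <- function(n_fragments = NULL, read_length = 36L,
                        n_replicates = 2L, frac_n_contaminated = 0.02,
                        frac_short = 0.02, seed = 1L) {
  assert_that(read_length >= 16L, "read_length must be >= 16")
  assert_that(frac_n_contaminated >= 0 && frac_n_contaminated <= 1 &&
              frac_short >= 0 && frac_short <= 1,
              "contamination fractions must lie in [0, 1]")
  structure(list(n_fragments = n_fragments, read_length = as.integer(read_length),
                 n_replicates = as.integer(n_replicates),
                 frac_n_contaminated = frac_n_contaminated,
                 frac_short = frac_short, seed = as.integer(seed)),
            class = "library_sim")
}

# Weighted fragment start sampling: w is a per-start weight vector of length
# L - rl + 1; windows up-weight starts inside them (renormalized by sample()).
weighted_starts <- function(n, L, rl, windows = NULL) {
  npos <- max(L - rl + 1L, 1L)
  if (is.null(windows) || nrow(windows) == 0L) {
    sample.int(npos, n, replace = TRUE) - 1L
  } else {
    w <- rep(1, npos)
    for (i in seq_len(nrow(windows))) {
      lo <- max(1L, windows$start[i])
      hi <- min(npos, windows$end[i])
      if (lo <= hi) w[lo:hi] <- w[lo:hi] * windows$factor[i]
    }
    sample.int(npos, n, replace = TRUE, prob = w) - 1L
  }
}

#' Simulate IP and Input libraries from planted truth
#'
#' Per library, per-source fragment counts are drawn from a negative binomial
#' with mean `baseline * enrichment` (enrichment applies to IP only) and
#' shared dispersion. Fragment start positions are uniform within the source
#' except inside enrichment windows (the 28S window for the 45S unit; planted
#' peak sites for the genomic background), where placement probability is
#' multiplied by the window factor and renormalized. Reads from multicopy
#' rDNA are recorded once per copy with the copy count as multiplicity.
#'
#' @param truth a [binding_truth()].
#' @param sim a [library_sim()].
#' @param ref a `rip_reference`.
#' @param emit_reads if `TRUE`, also generate raw read sequences (including
#'   the QC-failing contaminant reads) for each library.
#' @return object of class `rip_simulation`: list with `libraries` (named
#'   list, each with `alignments`, `truth_counts`, and optionally `reads`),
#'   `truth`, `sim`, and `ref_len` (named reference lengths).
#' @export
simulate_libraries <- function(truth, sim, ref, emit_reads = TRUE) {
  stopifnot(inherits(truth, "binding_truth"), inherits(sim, "library_sim"),
            inherits(ref, "rip_reference"))
  known <- c("chr1", "45S", "5S", ref$features$feature_id)
  unknown <- setdiff(names(truth$baseline_expression), known)
  if (length(unknown))
    stop("truth references unknown transcripts: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(truth$enriched_transcripts), known)
  if (length(unknown))
    stop("truth references unknown transcripts: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  scale <- if (is.null(sim$n_fragments)) 1 else
    sim$n_fragments / sum(truth$baseline_expression)
  libs <- c(paste0("IP_", seq_len(sim$n_replicates)),
            paste0("Input_", seq_len(sim$n_replicates)))
  out <- vector("list", length(libs))
  names(out) <- libs
  for (i in seq_along(libs)) {
    lib <- libs[i]
    is_ip <- startsWith(lib, "IP")
    out[[i]] <- with_seed(derive_seed(sim$seed, i),
                          simulate_one_library(lib, is_ip, truth, sim, ref,
                                               scale, emit_reads))
  }
  structure(list(libraries = out, truth = truth, sim = sim,
                 ref_len = reference_lengths(ref)),
            class = "rip_simulation")
}

reference_lengths <- function(ref) {
  c(stats::setNames(nchar(ref$genome), names(ref$genome)),
    stats::setNames(nchar(ref$refs), names(ref$refs)))
}

simulate_one_library <- function(lib, is_ip, truth, sim, ref, scale, emit_reads) {
  rl <- sim$read_length
  base <- truth$baseline_expression
  enr <- truth$enriched_transcripts
  feats <- ref$features
  size <- 1 / truth$nb_dispersion

  mu <- base * scale
  if (is_ip) {
    f <- enr[names(mu)]
    f[is.na(f)] <- 1
    mu <- mu * f
  }
  counts <- stats::rnbinom(length(mu), mu = mu, size = size)
  names(counts) <- names(mu)

  len45 <- sum(ref$rdna_table$end - ref$rdna_table$start + 1L)
  off28 <- ref$rdna_table$start[ref$rdna_table$name == "28S"]
  glen <- nchar(ref$genome[[1]])

  aln <- list(); seqsrc <- list()
  rid0 <- 0L
  add <- function(refid, start, len, strand, mult, src_ref, src_start) {
    n <- length(start)
    if (n == 0L) return(NULL)
    ids <- paste0(lib, "_r", rid0 + seq_len(n))
    rid0 <<- rid0 + n
    aln[[length(aln) + 1L]] <<- data.frame(
      read_id = ids, ref = refid, start = start, end = start + len,
      strand = strand, multiplicity = mult, stringsAsFactors = FALSE)
    seqsrc[[length(seqsrc) + 1L]] <<- data.frame(
      read_id = ids, src = src_ref, start = src_start, len = len,
      stringsAsFactors = FALSE)
    invisible(NULL)
  }

  for (src in names(counts)) {
    n <- counts[[src]]
    if (n == 0L) next
    if (src == "45S") {
      win <- NULL
      if (is_ip && !is.null(truth$rrna_binding_window)) {
        w <- truth$rrna_binding_window
        win <- data.frame(start = off28 + w$start - 1L, end = off28 + w$end - 1L,
                          factor = w$factor)
      }
      st <- weighted_starts(n, len45, rl, win)
      # one record per identical copy; multiplicity = copy count
      k <- ref$spec$n_rdna_copies
      copies <- sprintf("rDNA45S_%d", seq_len(k))
      for (cp in copies) {
        aln[[length(aln) + 1L]] <- data.frame(
          read_id = paste0(lib, "_r", rid0 + seq_len(n)), ref = cp,
          start = st, end = st + pmin(rl, len45 - st),
          strand = "+", multiplicity = k, stringsAsFactors = FALSE)
      }
      seqsrc[[length(seqsrc) + 1L]] <- data.frame(
        read_id = paste0(lib, "_r", rid0 + seq_len(n)), src = "rDNA45S_1",
        start = st, len = pmin(rl, len45 - st), stringsAsFactors = FALSE)
      rid0 <- rid0 + n
    } else if (src == "5S") {
      len5 <- nchar(ref$refs[["rDNA5S_1"]])
      st <- weighted_starts(n, len5, rl, NULL)
      k <- ref$spec$n_5s_copies
      for (cp in sprintf("rDNA5S_%d", seq_len(k))) {
        aln[[length(aln) + 1L]] <- data.frame(
          read_id = paste0(lib, "_r", rid0 + seq_len(n)), ref = cp,
          start = st, end = st + pmin(rl, len5 - st),
          strand = "+", multiplicity = k, stringsAsFactors = FALSE)
      }
      seqsrc[[length(seqsrc) + 1L]] <- data.frame(
        read_id = paste0(lib, "_r", rid0 + seq_len(n)), src = "rDNA5S_1",
        start = st, len = pmin(rl, len5 - st), stringsAsFactors = FALSE)
      rid0 <- rid0 + n
    } else if (src == "chr1") {
      win <- NULL
      if (is_ip && !is.null(truth$peak_sites) && nrow(truth$peak_sites))
        win <- truth$peak_sites[, c("start", "end", "factor")]
      st <- weighted_starts(n, glen, rl, win)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      if (is_ip && !is.null(truth$peak_sites)) {
        ps <- truth$peak_sites
        for (j in seq_len(nrow(ps))) {
          inside <- st + 1L >= ps$start[j] & st + 1L <= ps$end[j]
          strand[inside] <- ps$strand[j]
        }
      }
      add("chr1", st, pmin(rl, glen - st), strand, 1L, "chr1", st)
    } else {
      fi <- match(src, feats$feature_id)
      if (feats$kind[fi] == "coding") {
        # placement on the genomic gene span
        s0 <- feats$start[fi] - 1L
        span <- feats$length[fi]
        st <- s0 + weighted_starts(n, span, rl, NULL)
        add("chr1", st, pmin(rl, glen - st), feats$strand[fi], 1L, "chr1", st)
      } else {
        L <- nchar(ref$refs[[src]])
        st <- weighted_starts(n, L, rl, NULL)
        add(src, st, pmin(rl, L - st), "+", 1L, src, st)
      }
    }
  }

  aln <- if (length(aln)) do.call(rbind, aln) else
    data.frame(read_id = character(0), ref = character(0), start = integer(0),
               end = integer(0), strand = character(0), multiplicity = integer(0))
  rownames(aln) <- NULL

  reads <- NULL
  if (emit_reads) {
    ss <- do.call(rbind, seqsrc)
    seqs <- character(nrow(ss))
    for (src in unique(ss$src)) {
      idx <- ss$src == src
      template <- if (src == "chr1") ref$genome[[1]] else ref$refs[[src]]
      seqs[idx] <- substring(template, ss$start[idx] + 1L,
                             ss$start[idx] + ss$len[idx])
    }
    n_clean <- nrow(ss)
    n_nbad <- round(sim$frac_n_contaminated * n_clean)
    n_short <- round(sim$frac_short * n_clean)
    bad_n <- vapply(seq_len(n_nbad), function(i) {
      s <- strsplit(random_dna(rl), "")[[1]]
      s[sample.int(rl, 3L)] <- "N"
      paste(s, collapse = "")
    }, character(1))
    bad_short <- vapply(seq_len(n_short),
                        function(i) random_dna(sample(8:15, 1L)), character(1))
    reads <- data.frame(
      read_id = c(ss$read_id,
                  if (n_nbad) paste0(lib, "_nbad", seq_len(n_nbad)),
                  if (n_short) paste0(lib, "_short", seq_len(n_short))),
      seq = c(seqs, bad_n, bad_short),
      stringsAsFactors = FALSE)
  }

  list(alignments = aln,
       truth_counts = data.frame(source = names(counts),
                                 count = as.integer(counts),
                                 stringsAsFactors = FALSE),
       reads = reads)
}

#' Simulate reads on a single reference with optional enriched windows
#'
#' A minimal single-reference simulator used for peak-caller calibration and
#' recovery experiments: `n_reads` fragments placed uniformly on a reference
#' of length `ref_len`, except inside `sites` where placement probability is
#' multiplied by the site factor and renormalized.
#'
#' @param ref_len reference length (nt).
#' @param n_reads number of fragments.
#' @param read_length fragment length (nt).
#' @param sites optional data.frame with `start`, `end` (1-based closed) and
#'   `factor`.
#' @param ref_id reference name used in the output.
#' @param seed RNG seed.
#' @return alignment data.frame (`read_id`, `ref`, `start`, `end`, `strand`,
#'   `multiplicity`).
#' @export
simulate_interval_reads <- function(ref_len, n_reads, read_length = 36L,
                                    sites = NULL, ref_id = "ref", seed = 1L) {
  with_seed(seed, {
    st <- weighted_starts(n_reads, ref_len, read_length, sites)
    data.frame(read_id = paste0("r", seq_len(n_reads)), ref = ref_id,
               start = st, end = st + pmin(read_length, ref_len - st),
               strand = "+", multiplicity = 1L, stringsAsFactors = FALSE)
  })
}
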