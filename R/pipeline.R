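## End-to-end pipeline: simulate -> QC -> partition -> peaks -> enrichment
## -> 28S profile -> DEG overlap -> RTL-P, under one config and one seed.

#' Pipeline configuration
#'
#' All stage parameters in one validated list. Defaults mirror the
#' threshold conventions the package implements throughout: QC drops reads
#' with more than 2 N bases and reads shorter than 16 nt; enrichment uses
#' fold change >= 2 at p < 0.05; DEGs use fold change >= 2 (or <= 0.5) at
#' FDR < 0.05; the top-abundant list has 100 entries.
#'
#' @param out_dir output directory.
#' @param seed global RNG seed; all stage seeds derive from it.
#' @param genome arguments for [genome_spec()] (list).
#' @param truth arguments for [default_binding_truth()] (list).
#' @param sim arguments for [library_sim()] (list).
#' @param peaks arguments for [peak_call_params()] (list).
#' @param fc_cut,p_cut IP/Input enrichment cut-offs.
#' @param fdr_cut DEG FDR cut-off.
#' @param top_n top-abundant list length.
#' @param expressed_floor Input FPKM floor for "expressed".
#' @param rtlp arguments for [simulate_rtlp()] (list).
#' @param emit_reads generate raw reads (and run the QC stage).
#' @param write_files write stage outputs under `out_dir`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("structrip_run_"),
                            seed = 1L,
                            genome = list(), truth = list(), sim = list(),
                            peaks = list(), fc_cut = 2, p_cut = 0.05,
                            fdr_cut = 0.05, top_n = 100,
                            expressed_floor = 1, rtlp = list(),
                            emit_reads = TRUE, write_files = TRUE) {
  assert_that(fc_cut >= 1 && p_cut > 0 && p_cut < 1 && fdr_cut > 0 &&
              fdr_cut < 1, "thresholds outside valid ranges")
  structure(list(out_dir = out_dir, seed = as.integer(seed), genome = genome,
                 truth = truth, sim = sim, peaks = peaks, fc_cut = fc_cut,
                 p_cut = p_cut, fdr_cut = fdr_cut, top_n = top_n,
                 expressed_floor = expressed_floor, rtlp = rtlp,
                 emit_reads = emit_reads, write_files = write_files),
            class = "pipeline_config")
}

#' Write / read a pipeline config as YAML
#'
#' The config round-trips losslessly to disk.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full pipeline
#'
#' Stages in dependency order: build reference, plant truth, simulate
#' libraries, QC filter, partition and classify reads, call and annotate
#' peaks per IP replicate, intersect bound genes, scan for (CA) repeats,
#' quantify and test enrichment of structured RNAs, profile 28S domain
#' densities, run the DEG threshold test and its overlap with bound genes,
#' and compute the RTL-P methylation contrasts. Rerunning with an identical
#' config reproduces all output files byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report`: named list of stage outputs and
#'   key numbers.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  out_dir <- config$out_dir
  if (config$write_files)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ## stage 1: reference + truth
  gspec <- do.call(genome_spec,
                   utils::modifyList(list(seed = derive_seed(seed, 101L)),
                                     config$genome))
  ref <- build_reference(gspec)
  truth <- do.call(default_binding_truth,
                   utils::modifyList(list(ref = ref,
                                          seed = derive_seed(seed, 102L)),
                                     config$truth))
  ref <- plant_ca_repeats(ref, truth$peak_sites)
  if (config$write_files) write_reference(ref, file.path(out_dir, "reference"))

  ## stage 2: simulate libraries
  simp <- do.call(library_sim,
                  utils::modifyList(list(seed = derive_seed(seed, 103L)),
                                    config$sim))
  sim <- simulate_libraries(truth, simp, ref,
                            emit_reads = config$emit_reads)
  ref_len <- sim$ref_len

  ## stage 3: QC
  qc <- NULL
  if (config$emit_reads) {
    qc <- lapply(sim$libraries, function(l) qc_filter_reads(l$reads)$report)
    qc <- cbind(library = names(qc), do.call(rbind, qc))
    rownames(qc) <- NULL
    if (config$write_files) write_tsv(qc, file.path(out_dir, "qc_report.tsv"))
  }

  ## stage 4: partition + class/subregion summaries
  summaries <- lapply(names(sim$libraries), function(lib)
    read_class_summary(sim$libraries[[lib]]$alignments, ref$class_table,
                       ref$rdna_table, library_id = lib))
  names(summaries) <- names(sim$libraries)
  part_tab <- do.call(rbind, lapply(summaries, function(s)
    data.frame(library = s$library_id, s$counts,
               frac_multi = s$counts$multi / max(s$counts$total, 1),
               frac_45s = s$rdna_fractions$fraction[1])))
  rownames(part_tab) <- NULL
  if (config$write_files) {
    write_tsv(part_tab, file.path(out_dir, "partition_summary.tsv"))
    sub_tab <- do.call(rbind, lapply(summaries, function(s)
      cbind(library = s$library_id, s$subregion_summary)))
    write_tsv(sub_tab, file.path(out_dir, "rdna_subregion_fractions.tsv"))
  }

  ## stage 5: peaks per IP replicate against pooled Input
  pparams <- do.call(peak_call_params,
                     utils::modifyList(list(seed = derive_seed(seed, 104L)),
                                       config$peaks))
  input_aln <- do.call(rbind, lapply(
    sim$libraries[grep("^Input", names(sim$libraries))],
    function(l) l$alignments))
  input_chr <- input_aln[input_aln$ref == "chr1", , drop = FALSE]
  ip_names <- grep("^IP", names(sim$libraries), value = TRUE)
  peak_sets <- lapply(ip_names, function(lib) {
    part <- partition_by_multiplicity(sim$libraries[[lib]]$alignments)
    uniq_chr <- part$unique[part$unique$ref == "chr1", , drop = FALSE]
    annotate_peaks(call_peaks(uniq_chr, input_chr, pparams, ref_len), ref)
  })
  names(peak_sets) <- ip_names
  bound <- if (length(peak_sets) >= 2L)
    confident_bound_genes(peak_sets[[1L]], peak_sets[[2L]]) else
    unique(stats::na.omit(peak_sets[[1L]]$gene_id))
  motif <- if (nrow(peak_sets[[1L]]) > 0L)
    ca_repeat_enrichment(peak_sets[[1L]], ref,
                         seed = derive_seed(seed, 105L)) else NULL
  if (config$write_files) {
    for (lib in ip_names)
      write_peaks_bed(peak_sets[[lib]],
                      file.path(out_dir, paste0("peaks_", lib, ".bed")))
    writeLines(bound, file.path(out_dir, "confident_bound_genes.txt"))
  }

  ## stage 6: structured-RNA enrichment
  quant <- quantify_transcripts(sim, ref, fc_cut = config$fc_cut,
                                p_cut = config$p_cut)
  top <- top_abundant(quant, n = min(config$top_n, nrow(quant)))
  class_summary <- class_enrichment_summary(quant, config$expressed_floor)
  if (config$write_files) {
    write_tsv(quant, file.path(out_dir, "transcript_quant.tsv"))
    write_tsv(class_summary, file.path(out_dir, "class_enrichment.tsv"))
    write_tsv(top$composition, file.path(out_dir, "top_abundant_classes.tsv"))
  }

  ## stage 7: 28S domain profile
  prof <- profile_28s(sim, ref)
  if (config$write_files) {
    write_tsv(data.frame(position = seq_along(prof$profile_ip),
                         depth_ip = prof$profile_ip,
                         depth_input = prof$profile_input),
              file.path(out_dir, "profile_28s.tsv"))
    write_tsv(as.data.frame(prof$domains),
              file.path(out_dir, "domain_density.tsv"))
  }

  ## stage 8: DEG threshold test + overlap with bound genes
  coding <- ref$features$feature_id[ref$features$kind == "coding"]
  de_up <- with_seed(derive_seed(seed, 106L),
                     sample(coding, max(3L, length(coding) %/% 8L)))
  cm <- simulate_counts(n_genes = length(coding),
                        conditions = c("Ctrl", "Ctrl", "OE", "OE"),
                        fold_changes = list(OE = stats::setNames(
                          rep(4, length(de_up)), sprintf("g%04d", match(de_up, coding)))),
                        seed = derive_seed(seed, 107L))
  rownames(cm$counts) <- coding
  deg <- test_de(cm$counts, cm$conditions, "OE", "Ctrl",
                 fc_cut = config$fc_cut, fdr_cut = config$fdr_cut)
  overlap <- deg_overlap(deg, bound, coding)
  if (config$write_files) write_tsv(deg, file.path(out_dir, "deg_results.tsv"))

  ## stage 9: RTL-P
  rtlp_meas <- do.call(simulate_rtlp,
                       utils::modifyList(list(seed = derive_seed(seed, 108L)),
                                         config$rtlp))
  rtlp <- rtlp_index(rtlp_meas, site = "Am2388")
  if (config$write_files) {
    write_tsv(rtlp_meas, file.path(out_dir, "rtlp_ct.tsv"))
    write_tsv(rtlp$contrasts, file.path(out_dir, "rtlp_contrasts.tsv"))
  }

  report <- structure(list(
    config = config, reference = ref, truth = truth, sim = sim,
    qc = qc, partition = part_tab, summaries = summaries,
    peaks = peak_sets, bound_genes = bound, motif = motif,
    quant = quant, top_abundant = top, class_summary = class_summary,
    profile = prof, deg = deg, deg_overlap = overlap, rtlp = rtlp,
    key_numbers = list(
      n_reads = stats::setNames(part_tab$total, part_tab$library),
      frac_multi = stats::setNames(part_tab$frac_multi, part_tab$library),
      frac_45s = stats::setNames(part_tab$frac_45s, part_tab$library),
      n_peaks = vapply(peak_sets, nrow, numeric(1)),
      n_bound_genes = length(bound),
      n_enriched = sum(quant$enriched),
      max_domain = attr(prof$domains, "max_domain"),
      n_deg = sum(deg$direction != "ns"),
      deg_overlap_p = overlap$p,
      rtlp_contrasts = rtlp$contrasts)),
    class = "run_report")
  if (config$write_files) {
    yaml::write_yaml(report_summary_list(report),
                     file.path(out_dir, "run_report.yaml"))
  }
  report
}

report_summary_list <- function(r) {
  list(seed = r$config$seed,
       libraries = as.list(stats::setNames(as.integer(r$partition$total),
                                           r$partition$library)),
       frac_multi = as.list(stats::setNames(round(r$partition$frac_multi, 4),
                                            r$partition$library)),
       n_peaks = as.list(vapply(r$peaks, nrow, numeric(1))),
       n_bound_genes = length(r$bound_genes),
       n_enriched_transcripts = sum(r$quant$enriched),
       max_density_domain = attr(r$profile$domains, "max_domain"),
       n_deg = sum(r$deg$direction != "ns"),
       deg_overlap = list(overlap = r$deg_overlap$overlap,
                          p = r$deg_overlap$p),
       rtlp = lapply(seq_len(nrow(r$rtlp$contrasts)), function(i)
         list(condition = r$rtlp$contrasts$condition[i],
              contrast = round(r$rtlp$contrasts$contrast[i], 4),
              p = signif(r$rtlp$contrasts$p[i], 4))))
}

#' @export
print.run_report <- function(x, ...) {
  k <- x$key_numbers
  cat("structrip pipeline report\n")
  cat(sprintf("  libraries: %s\n",
              paste(sprintf("%s=%d", names(k$n_reads), k$n_reads),
                    collapse = ", ")))
  cat(sprintf("  multi-mapped fractions: %s\n",
              paste(sprintf("%s=%.3f", names(k$frac_multi), k$frac_multi),
                    collapse = ", ")))
  cat(sprintf("  peaks: %s; confident bound genes: %d\n",
              paste(sprintf("%s=%d", names(k$n_peaks), k$n_peaks),
                    collapse = ", "), k$n_bound_genes))
  cat(sprintf("  enriched transcripts: %d; max 28S density domain: %s\n",
              k$n_enriched, k$max_domain))
  cat(sprintf("  DEGs: %d; bound-gene overlap p = %.3g\n",
              k$n_deg, k$deg_overlap_p))
  if (!is.null(k$rtlp_contrasts))
    for (i in seq_len(nrow(k$rtlp_contrasts)))
      cat(sprintf("  RTL-P %s vs Ctrl: contrast %.3f (p = %.3g)\n",
                  k$rtlp_contrasts$condition[i],
                  k$rtlp_contrasts$contrast[i], k$rtlp_contrasts$p[i]))
  invisible(x)
}

#' Write called peaks as BED6+
#'
#' Standard BED columns plus enrichment, category and gene id; the score is
#' `-log10(p)`.
#'
#' @param peaks annotated `rip_peaks`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(chrom = peaks$ref, start = peaks$start, end = peaks$end,
                   name = sprintf("peak_%d", seq_len(nrow(peaks))),
                   score = round(-log10(pmax(peaks$p, 1e-300)), 3),
                   strand = peaks$strand,
                   enrichment = round(peaks$enrichment, 3),
                   category = peaks$category %||% NA,
                   gene = peaks$gene_id %||% NA)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
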