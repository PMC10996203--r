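## Readers and writers for the standard interchange formats: FASTA and FASTQ
## via Biostrings, GFF3 and BED via rtracklayer, SAM via Rsamtools (reading)
## and a plain text writer (writing), TSV tables via base R.

#' Write the reference bundle to disk
#'
#' Emits `genome.fa` (chromosome sequences), `structured_refs.fa` (the
#' standalone rDNA unit copies and ncRNA transcripts), `annotation.gff3`,
#' `class_table.tsv`, `rdna_subregions.tsv` and `domains_28s.tsv`.
#'
#' @param ref a `rip_reference`.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             refs = file.path(dir, "structured_refs.fa"),
             gff = file.path(dir, "annotation.gff3"),
             classes = file.path(dir, "class_table.tsv"),
             rdna = file.path(dir, "rdna_subregions.tsv"),
             domains = file.path(dir, "domains_28s.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$genome),
                              paths[["genome"]])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$refs),
                              paths[["refs"]])
  rtracklayer::export(annotation_granges(ref), paths[["gff"]],
                      format = "gff3")
  write_tsv(ref$class_table, paths[["classes"]])
  write_tsv(ref$rdna_table, paths[["rdna"]])
  write_tsv(ref$domain_table, paths[["domains"]])
  invisible(paths)
}

#' Annotation as a GRanges
#'
#' Gene, exon and ncRNA features of the reference as a `GRanges` suitable
#' for GFF3 export.
#'
#' @param ref a `rip_reference`.
#' @return a `GRanges` with `type`, `ID` and `Parent` metadata.
#' @export
annotation_granges <- function(ref) {
  feats <- ref$features
  ex <- ref$exons
  gene_type <- ifelse(feats$kind == "coding", "gene", "ncRNA_gene")
  g1 <- GenomicRanges::GRanges(
    seqnames = feats$chrom,
    ranges = IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand,
    type = gene_type, ID = feats$feature_id,
    Parent = IRanges::CharacterList(vector("list", nrow(feats))),
    class = feats$class)
  if (nrow(ex)) {
    g2 <- GenomicRanges::GRanges(
      seqnames = "chr1",
      ranges = IRanges::IRanges(ex$start, ex$end),
      strand = ex$strand,
      type = "exon", ID = paste0(ex$gene_id, ".e", ex$exon),
      Parent = IRanges::CharacterList(as.list(ex$gene_id)),
      class = "mRNA")
    g1 <- c(g1, g2)
  }
  g1
}

#' Write alignments as BED6
#'
#' Columns: reference, start, end (0-based half-open), read id, score =
#' multiplicity, strand.
#'
#' @param aln alignment data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_alignments_bed <- function(aln, path) {
  bed <- data.frame(chrom = aln$ref, start = aln$start, end = aln$end,
                    name = aln$read_id, score = aln$multiplicity,
                    strand = aln$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read alignments from BED6 or SAM
#'
#' BED is read through rtracklayer (score column = multiplicity). SAM is
#' converted through Rsamtools; multiplicity is taken from the NH tag
#' (default 1 when absent).
#'
#' @param path input file (`.bed` or `.sam`).
#' @return alignment data.frame (`read_id`, `ref`, `start`, `end`,
#'   `strand`, `multiplicity`).
#' @export
read_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    data.frame(read_id = gr$name, ref = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               multiplicity = as.integer(gr$score),
               stringsAsFactors = FALSE)
  } else if (ext == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    res <- Rsamtools::scanBam(bam,
      param = Rsamtools::ScanBamParam(
        what = c("qname", "rname", "pos", "qwidth", "strand"),
        tag = "NH"))[[1]]
    nh <- res$tag$NH %||% rep(1L, length(res$qname))
    nh[is.na(nh)] <- 1L
    data.frame(read_id = res$qname, ref = as.character(res$rname),
               start = res$pos - 1L, end = res$pos - 1L + res$qwidth,
               strand = as.character(res$strand),
               multiplicity = as.integer(nh), stringsAsFactors = FALSE)
  } else stop("unsupported alignment format: ", ext, call. = FALSE)
}

#' Write alignments as SAM with NH multiplicity tags
#'
#' Minimal unpaired SAM records (no stored sequence; CIGAR from the aligned
#' length) with `@SQ` headers for every reference.
#'
#' @param aln alignment data.frame.
#' @param ref_len named vector of reference lengths.
#' @param path output path (`.sam`).
#' @return invisibly, `path`.
#' @export
write_alignments_sam <- function(aln, ref_len, path) {
  refs <- unique(aln$ref)
  missing_ref <- setdiff(refs, names(ref_len))
  assert_that(length(missing_ref) == 0L,
              paste0("no length for reference(s): ",
                     paste(missing_ref, collapse = ", ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (rf in refs)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", rf, as.integer(ref_len[[rf]])), con)
  flag <- ifelse(aln$strand == "-", 16L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tNH:i:%d",
                 aln$read_id, flag, aln$ref, aln$start + 1L,
                 aln$end - aln$start, aln$multiplicity)
  writeLines(rec, con)
  invisible(path)
}

#' Write raw reads as FASTQ
#'
#' @param reads data.frame with `read_id` and `seq`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  qual <- Biostrings::BStringSet(vapply(nchar(reads$seq),
                                        function(n) strrep("I", n),
                                        character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read raw reads from FASTQ
#'
#' @param path FASTQ file.
#' @return data.frame with `read_id` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(x), seq = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
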