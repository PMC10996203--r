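## QC filtering, unique/multi partitioning, ncRNA class assignment and rDNA
## subregion assignment.

# class priority used to break ties when a multi-mapped read hits references
# of different classes
.class_priority <- c("rRNA", "snoRNA", "scaRNA", "snRNA", "tRNA", "miRNA",
                     "lincRNA", "other")

#' Quality-filter raw reads
#'
#' Applies the two read-level QC rules in fixed order: first discard reads
#' containing more than 2 N bases, then discard reads shorter than 16 nt.
#' A 16-nt read is kept ("shorter than" is strict).
#'
#' @param reads data.frame with columns `read_id` and `seq`.
#' @return list with `kept` (filtered data.frame) and `report` (counts
#'   removed per rule and totals).
#' @export
qc_filter_reads <- function(reads) {
  if (is.null(reads) || nrow(reads) == 0L) {
    return(list(kept = data.frame(read_id = character(0), seq = character(0),
                                  stringsAsFactors = FALSE),
                report = data.frame(total = 0L, removed_n = 0L,
                                    removed_short = 0L, kept = 0L)))
  }
  n_count <- nchar(reads$seq) - nchar(gsub("N", "", reads$seq, fixed = TRUE))
  pass_n <- n_count <= 2L
  after_n <- reads[pass_n, , drop = FALSE]
  pass_len <- nchar(after_n$seq) >= 16L
  kept <- after_n[pass_len, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept,
       report = data.frame(total = nrow(reads),
                           removed_n = sum(!pass_n),
                           removed_short = sum(!pass_len),
                           kept = nrow(kept)))
}

#' Partition alignments by mapping multiplicity
#'
#' A read id with multiplicity 1 is uniquely mapped; multiplicity > 1 is
#' multi-mapped. Reads are counted once per read id, not per placement.
#'
#' @param aln alignment data.frame (see [simulate_libraries()]).
#' @return list with `unique` and `multi` (alignment subsets) and `counts`
#'   (`total`, `unique`, `multi` read counts).
#' @export
partition_by_multiplicity <- function(aln) {
  validate_alignments(aln)
  n_ids <- sum(!duplicated(aln$read_id))
  n_pairs <- sum(!duplicated(paste0(aln$read_id, "\r", aln$multiplicity)))
  if (n_pairs > n_ids) {
    mult_range <- tapply(aln$multiplicity, aln$read_id,
                         function(x) max(x) - min(x))
    bad <- names(mult_range)[mult_range != 0]
    stop("inconsistent multiplicity for read(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  is_multi <- aln$multiplicity > 1L
  uniq <- aln[!is_multi, , drop = FALSE]
  multi <- aln[is_multi, , drop = FALSE]
  n_unique <- length(unique(uniq$read_id))
  n_multi <- length(unique(multi$read_id))
  list(unique = uniq, multi = multi,
       counts = data.frame(total = n_unique + n_multi,
                           unique = n_unique, multi = n_multi))
}

#' Assign multi-mapped reads to ncRNA classes
#'
#' Each multi-mapped read is assigned to exactly one class by its best
#' placement: placements are mapped to classes through the class table, ties
#' across classes are broken by the priority rRNA > snoRNA > scaRNA > snRNA >
#' tRNA > miRNA > lincRNA > other, then by the lexicographically smallest
#' reference id. Reads with no placement on a classified reference are
#' `unassigned`.
#'
#' @param multi alignment data.frame of multi-mapped reads.
#' @param class_table data.frame with columns `ref_id`, `class` (and
#'   optionally `box_type`).
#' @param structured_refs optional character vector naming the structured
#'   reference set; a placement on a structured reference that has no
#'   class-table row is a configuration error. Placements on references
#'   outside this set fall through to `unassigned`.
#' @return list with `assignments` (read_id, class, ref) and `summary`
#'   (per-class counts and fractions of assigned reads).
#' @export
assign_ncrna_class <- function(multi, class_table, structured_refs = NULL) {
  assert_that(all(c("ref_id", "class") %in% names(class_table)),
              "class table needs columns ref_id and class")
  if (!is.null(structured_refs)) {
    missing_cls <- setdiff(intersect(unique(multi$ref), structured_refs),
                           class_table$ref_id)
    if (length(missing_cls))
      stop("structured reference(s) missing from class table: ",
           paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  if (nrow(multi) == 0L) {
    return(list(assignments = data.frame(read_id = character(0),
                                         class = character(0),
                                         ref = character(0)),
                summary = data.frame(class = character(0), count = integer(0),
                                     fraction = numeric(0))))
  }
  cls <- class_table$class[match(multi$ref, class_table$ref_id)]
  prio <- match(cls, .class_priority)
  prio[is.na(prio)] <- length(.class_priority) + 1L
  ord <- order(multi$read_id, prio, multi$ref)
  m <- multi[ord, , drop = FALSE]
  first <- !duplicated(m$read_id)
  best <- m[first, , drop = FALSE]
  best_class <- class_table$class[match(best$ref, class_table$ref_id)]
  best_class[is.na(best_class)] <- "unassigned"
  assignments <- data.frame(read_id = best$read_id, class = best_class,
                            ref = best$ref, stringsAsFactors = FALSE)
  assigned <- assignments[assignments$class != "unassigned", , drop = FALSE]
  tab <- table(assigned$class)
  summary <- data.frame(class = names(tab), count = as.integer(tab),
                        fraction = as.numeric(tab) / max(sum(tab), 1L),
                        stringsAsFactors = FALSE)
  list(assignments = assignments, summary = summary)
}

#' Assign 45S reads to rDNA subregions
#'
#' Each read on the 45S unit is assigned to the subregion containing its
#' midpoint (midpoint rule avoids double-counting junction-spanning reads).
#' Coordinates are the unit-local coordinates carried by the rDNA copy
#' placements; multi-copy placements collapse to one count per read.
#'
#' @param aln alignment data.frame; rows on references named `rDNA45S_*` are
#'   used (one deduplicated record per read id).
#' @param rdna_table subregion intervals (columns `name`, `start`, `end`,
#'   1-based closed, tiling the unit without overlap).
#' @return data.frame per subregion: `name`, `count`, `fraction` (of 45S
#'   reads).
#' @export
assign_rdna_subregion <- function(aln, rdna_table) {
  r45 <- aln[grepl("^rDNA45S", aln$ref), , drop = FALSE]
  r45 <- r45[!duplicated(r45$read_id), , drop = FALSE]
  counts <- stats::setNames(integer(nrow(rdna_table)), rdna_table$name)
  if (nrow(r45)) {
    mid <- (r45$start + r45$end - 1L) %/% 2L + 1L  # 1-based midpoint
    idx <- findInterval(mid, rdna_table$start)
    if (any(idx < 1L) || any(mid > rdna_table$end[pmax(idx, 1L)]))
      stop("read midpoint outside the 45S unit; malformed interval table",
           call. = FALSE)
    tab <- table(factor(rdna_table$name[idx], levels = rdna_table$name))
    counts <- stats::setNames(as.integer(tab), names(tab))
  }
  data.frame(name = rdna_table$name, count = as.integer(counts),
             fraction = if (sum(counts) > 0) counts / sum(counts) else
               rep(NA_real_, length(counts)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-library read-class summary
#'
#' Combines multiplicity partitioning, ncRNA class assignment of the
#' multi-mapped set, and rDNA subregion assignment into one summary, the
#' shape of the per-class and per-subregion fraction tables typically
#' reported for RIP-seq libraries.
#'
#' @param aln alignment data.frame of one library.
#' @param class_table ncRNA class table.
#' @param rdna_table 45S subregion table.
#' @param library_id label carried into the output.
#' @return object of class `read_class_summary`: list with `library_id`,
#'   `counts` (total/unique/multi), `class_summary`, `subregion_summary`,
#'   and `rdna_fractions` (fractions of all reads on 45S and 5S).
#' @export
read_class_summary <- function(aln, class_table, rdna_table,
                               library_id = "library") {
  part <- partition_by_multiplicity(aln)
  cls <- assign_ncrna_class(part$multi, class_table)
  sub <- assign_rdna_subregion(aln, rdna_table)
  n45 <- length(unique(aln$read_id[grepl("^rDNA45S", aln$ref)]))
  n5 <- length(unique(aln$read_id[grepl("^rDNA5S", aln$ref)]))
  total <- part$counts$total
  structure(list(library_id = library_id, counts = part$counts,
                 class_summary = cls$summary, subregion_summary = sub,
                 rdna_fractions = data.frame(
                   unit = c("45S", "5S"),
                   count = c(n45, n5),
                   fraction = c(n45, n5) / max(total, 1L))),
            class = "read_class_summary")
}

#' @export
print.read_class_summary <- function(x, ...) {
  cat(sprintf("Read class summary for %s\n", x$library_id))
  cat(sprintf("  reads: %d total, %d unique (%.1f%%), %d multi (%.1f%%)\n",
              x$counts$total, x$counts$unique,
              100 * x$counts$unique / max(x$counts$total, 1),
              x$counts$multi, 100 * x$counts$multi / max(x$counts$total, 1)))
  cat(sprintf("  45S fraction: %.3f; 5S fraction: %.4f\n",
              x$rdna_fractions$fraction[1], x$rdna_fractions$fraction[2]))
  if (nrow(x$subregion_summary)) {
    s <- x$subregion_summary
    cat("  45S subregions: ",
        paste(sprintf("%s %.1f%%", s$name, 100 * s$fraction), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
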