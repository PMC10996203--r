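## Per-base coverage on an rRNA, per-domain density, binding-region calling
## and 2'-O-methylation site containment.

#' Per-base coverage profile on an rRNA
#'
#' `depth[i]` is the number of reads overlapping base `i` (1-based).
#' Multi-copy placements collapse to one count per read: identical rDNA
#' copies are profiled once, on the unit consensus.
#'
#' @param aln alignment data.frame; rows whose `ref` matches `ref_pattern`
#'   are used, deduplicated per read id.
#' @param ref_len length of the profiled reference (nt).
#' @param ref_pattern regular expression selecting the reference's
#'   placements (default: 45S copies).
#' @param offset local offset subtracted from coordinates before profiling
#'   (0-based); use the 28S offset within the 45S unit to profile the 28S.
#' @return integer depth vector of length `ref_len`.
#' @export
coverage_profile <- function(aln, ref_len, ref_pattern = "^rDNA45S",
                             offset = 0L) {
  sel <- aln[grepl(ref_pattern, aln$ref), , drop = FALSE]
  sel <- sel[!duplicated(sel$read_id), , drop = FALSE]
  if (nrow(sel) == 0L) return(integer(ref_len))
  st <- sel$start - offset
  en <- sel$end - offset
  if (offset == 0L && any(en > ref_len))
    stop("alignment beyond reference end", call. = FALSE)
  keep <- en > 0L & st < ref_len   # reads outside the profiled window drop
  st <- pmax(st[keep], 0L)
  en <- pmin(en[keep], ref_len)
  interval_coverage(st, en, ref_len)
}

#' Per-domain normalized binding density
#'
#' `density(d) = sum(depth over d) / length(d) / (library_size / 1e6)`:
#' reads-per-base per million mapped fragments. When both IP and Input
#' profiles are given, the IP/Input density ratio is also reported.
#'
#' @param profile_ip IP depth vector (1-based).
#' @param domain_table data.frame `name`, `start`, `end` (1-based closed,
#'   non-overlapping, within the profile).
#' @param ip_total IP library size (mapped fragments).
#' @param profile_input,input_total optional Input profile and library size.
#' @return object of class `domain_profile`: data.frame per domain with
#'   `name`, `length`, `ip_density`, optional `input_density` and `ratio`;
#'   attributes `max_domain` (by IP density; `NA` if all zero) and
#'   `max_domain_ratio`.
#' @export
domain_density <- function(profile_ip, domain_table, ip_total,
                           profile_input = NULL, input_total = NULL) {
  assert_that(all(domain_table$end >= domain_table$start),
              "empty domain interval in table")
  assert_that(all(domain_table$start >= 1) &&
              all(domain_table$end <= length(profile_ip)),
              "domain interval outside the profile")
  dens <- function(profile, total) vapply(seq_len(nrow(domain_table)),
    function(i) {
      d <- domain_table[i, ]
      sum(profile[d$start:d$end]) / (d$end - d$start + 1) / (total / 1e6)
    }, numeric(1))
  out <- data.frame(name = domain_table$name,
                    length = domain_table$end - domain_table$start + 1L,
                    ip_density = dens(profile_ip, ip_total),
                    stringsAsFactors = FALSE)
  if (!is.null(profile_input)) {
    out$input_density <- dens(profile_input, input_total)
    out$ratio <- out$ip_density / pmax(out$input_density, 1e-12)
  }
  class(out) <- c("domain_profile", "data.frame")
  attr(out, "max_domain") <- if (all(out$ip_density == 0)) NA_character_ else
    out$name[which.max(out$ip_density)]
  attr(out, "max_domain_ratio") <-
    if (!is.null(profile_input) && any(out$ip_density > 0))
      out$name[which.max(out$ratio)] else NA_character_
  out
}

#' @export
print.domain_profile <- function(x, ...) {
  cat("Per-domain binding density (reads/base per million mapped)\n")
  print.data.frame(x, digits = 4)
  cat("max IP-density domain:", attr(x, "max_domain"), "\n")
  invisible(x)
}

#' Call binding regions from a coverage profile
#'
#' Maximal runs of bases with depth >= `threshold * max(depth)`, merged
#' across gaps of at most `merge_gap` nt. Regions shrink setwise as the
#' threshold increases.
#'
#' @param profile depth vector (1-based).
#' @param threshold fraction of the maximum depth, in (0, 1].
#' @param merge_gap merge gap in nt.
#' @return data.frame `start`, `end` (1-based closed intervals).
#' @export
call_binding_region <- function(profile, threshold = 0.5, merge_gap = 20L) {
  assert_that(threshold > 0 && threshold <= 1,
              "threshold must lie in (0, 1]")
  mx <- max(profile)
  if (mx == 0) return(data.frame(start = integer(0), end = integer(0)))
  iv <- true_runs(profile >= threshold * mx, merge_gap)
  data.frame(start = iv[, "start"], end = iv[, "end"])
}

#' Check containment of modification sites in binding regions
#'
#' @param regions data.frame `start`, `end` (1-based closed).
#' @param sites data.frame `position` (1-based residue) and optional
#'   `label`.
#' @return `sites` with a logical `contained` column.
#' @export
check_modification_sites <- function(regions, sites) {
  sites$contained <- vapply(sites$position, function(p)
    any(regions$start <= p & regions$end >= p), logical(1))
  sites
}

#' Default 28S 2'-O-methylation sites of interest
#'
#' The three ribose-methylated residues (Am2388, Cm2409, Gm2411) that lie in
#' the domain II binding window.
#' @return data.frame `position`, `label`.
#' @export
default_modification_sites <- function() {
  data.frame(position = c(2388L, 2409L, 2411L),
             label = c("Am2388", "Cm2409", "Gm2411"),
             stringsAsFactors = FALSE)
}

#' Full 28S domain profile for a simulated experiment
#'
#' Convenience wrapper: builds pooled IP and Input 28S coverage profiles
#' (unit-local coordinates), per-domain densities, binding regions and
#' modification-site containment.
#'
#' @param sim a `rip_simulation`.
#' @param ref the `rip_reference`.
#' @param threshold,merge_gap see [call_binding_region()].
#' @return list with `profile_ip`, `profile_input`, `domains`
#'   (a `domain_profile`), `regions`, `sites`.
#' @export
profile_28s <- function(sim, ref, threshold = 0.5, merge_gap = 20L) {
  rd <- ref$rdna_table
  off <- rd$start[rd$name == "28S"] - 1L
  len28 <- rd$end[rd$name == "28S"] - rd$start[rd$name == "28S"] + 1L
  libs <- sim$libraries
  pool_profile <- function(pattern) {
    profs <- lapply(libs[grep(pattern, names(libs))], function(l)
      coverage_profile(l$alignments, len28, offset = off))
    Reduce(`+`, profs)
  }
  prof_ip <- pool_profile("^IP")
  prof_in <- pool_profile("^Input")
  n_reads <- function(pattern) sum(vapply(libs[grep(pattern, names(libs))],
    function(l) length(unique(l$alignments$read_id)), numeric(1)))
  dom <- domain_density(prof_ip, ref$domain_table, n_reads("^IP"),
                        prof_in, n_reads("^Input"))
  regions <- call_binding_region(prof_ip, threshold, merge_gap)
  sites <- check_modification_sites(regions, default_modification_sites())
  list(profile_ip = prof_ip, profile_input = prof_in, domains = dom,
       regions = regions, sites = sites)
}
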