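#' @keywords internal
"_PACKAGE"

# Run an expression under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage/per-library child seed from a global seed. Keeps all
# derived seeds inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2003L + as.integer(offset) %% 2003L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Validate an alignment table: read_id, ref, start, end (0-based half-open),
# strand, multiplicity.
validate_alignments <- function(aln) {
  need <- c("read_id", "ref", "start", "end", "strand", "multiplicity")
  miss <- setdiff(need, names(aln))
  assert_that(length(miss) == 0L,
              paste0("alignment table lacks columns: ", paste(miss, collapse = ", ")))
  assert_that(all(aln$start >= 0L) && all(aln$end > aln$start),
              "alignment coordinates must satisfy 0 <= start < end")
  assert_that(all(aln$multiplicity >= 1L), "multiplicity must be >= 1")
  invisible(aln)
}

# Coverage over [0, ref_len) from 0-based half-open intervals; returns an
# integer depth vector indexed 1..ref_len (base i = residue i, 1-based).
interval_coverage <- function(start, end, ref_len) {
  assert_that(all(end <= ref_len), "alignment extends beyond reference end")
  inc <- tabulate(start + 1L, nbins = ref_len + 1L)
  dec <- tabulate(end + 1L, nbins = ref_len + 1L)
  cumsum(inc - dec)[seq_len(ref_len)]
}

# Maximal runs where `keep` is TRUE, merging runs separated by gaps <= gap.
# Returns 1-based closed intervals as a two-column matrix.
true_runs <- function(keep, gap = 0L) {
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  if (length(idx) == 0L) return(cbind(start = integer(0), end = integer(0)))
  iv <- cbind(start = starts[idx], end = ends[idx])
  if (gap > 0L && nrow(iv) > 1L) {
    out <- list(iv[1L, ])
    for (i in 2L:nrow(iv)) {
      last <- out[[length(out)]]
      if (iv[i, "start"] - last["end"] - 1L <= gap) {
        last["end"] <- iv[i, "end"]
        out[[length(out)]] <- last
      } else out[[length(out) + 1L]] <- iv[i, ]
    }
    iv <- do.call(rbind, out)
  }
  iv
}
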