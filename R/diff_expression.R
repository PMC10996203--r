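## DEG threshold filtering on a count matrix with median-of-ratios
## normalization, a Fisher-on-pooled-counts per-gene test, and directional
## overlap with bound-gene sets.

#' Median-of-ratios size factors
#'
#' `factor_j = median over genes g (with nonzero counts in every library)
#' of count_gj / geomean_g`, the normalization used by standard RNA-seq
#' count models.
#'
#' @param mat integer count matrix, genes x libraries.
#' @return positive numeric vector of per-library scaling factors.
#' @export
size_factors <- function(mat) {
  mat <- as.matrix(mat)
  assert_that(all(mat >= 0), "counts must be >= 0")
  all_pos <- rowSums(mat == 0) == 0
  if (!any(all_pos))
    stop("no gene has nonzero counts in all libraries; consider pseudocounts",
         call. = FALSE)
  sub <- mat[all_pos, , drop = FALSE]
  geomean <- exp(rowMeans(log(sub)))
  apply(sub, 2, function(cnt) stats::median(cnt / geomean))
}

#' Simulate an RNA-seq count matrix with planted differential expression
#'
#' Negative-binomial counts with per-gene baseline means, per-library depth
#' factors and per-condition fold changes.
#'
#' @param n_genes number of genes.
#' @param conditions character vector of condition labels, one per library.
#' @param mean_range range for the log-uniform per-gene baseline mean.
#' @param fold_changes named list: condition -> named numeric vector of
#'   per-gene fold changes (genes absent have fold change 1).
#' @param depth_factors per-library depth multipliers (default all 1).
#' @param dispersion shared negative-binomial dispersion. The default
#'   (0.002) is the near-technical-replicate regime, matching the sampling
#'   assumptions of the count-based per-gene test in [test_de()]; raise it
#'   to emulate biological replicate variability (which that test does not
#'   model).
#' @param seed RNG seed.
#' @return list with `counts` (matrix with library:condition:replicate
#'   column names), `conditions`, `truth` (per-gene planted fold change per
#'   condition).
#' @export
simulate_counts <- function(n_genes = 1000, conditions = c("Ctrl", "Ctrl", "OE", "OE"),
                            mean_range = c(50, 500), fold_changes = list(),
                            depth_factors = NULL, dispersion = 0.002,
                            seed = 1L) {
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    mu0 <- exp(stats::runif(n_genes, log(mean_range[1]), log(mean_range[2])))
    names(mu0) <- genes
    nlib <- length(conditions)
    depth_factors <- depth_factors %||% rep(1, nlib)
    reps <- stats::ave(seq_len(nlib), conditions, FUN = seq_along)
    counts <- matrix(0L, n_genes, nlib,
                     dimnames = list(genes,
                                     paste0("lib", seq_len(nlib), ":",
                                            conditions, ":", reps)))
    for (j in seq_len(nlib)) {
      fc <- rep(1, n_genes); names(fc) <- genes
      planted <- fold_changes[[conditions[j]]]
      if (!is.null(planted)) fc[names(planted)] <- planted
      mu <- mu0 * fc * depth_factors[j]
      counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
    }
    truth <- do.call(cbind, lapply(unique(conditions), function(cond) {
      fc <- rep(1, n_genes); names(fc) <- genes
      planted <- fold_changes[[cond]]
      if (!is.null(planted)) fc[names(planted)] <- planted
      fc
    }))
    colnames(truth) <- unique(conditions)
    list(counts = counts, conditions = conditions, truth = truth)
  })
}

#' Differential-expression threshold test
#'
#' Normalizes by [size_factors()], computes the pseudocounted ratio of
#' normalized condition means, obtains a per-gene p-value from a two-sided
#' Fisher's exact test on condition-pooled raw counts versus pooled library
#' totals, adjusts by Benjamini-Hochberg, and assigns direction by the
#' threshold rule: `up` iff fold change >= `fc_cut` and FDR < `fdr_cut`,
#' `down` iff fold change <= 1/`fc_cut` and FDR < `fdr_cut`, otherwise `ns`.
#' The per-gene test is a deliberately simple stand-in for a full
#' negative-binomial GLM; the reproducible content is the threshold rule.
#'
#' @param mat count matrix, genes x libraries.
#' @param conditions condition label per library column.
#' @param condA,condB treated and control condition labels (fold change is
#'   A over B).
#' @param fc_cut,fdr_cut threshold rule cut-offs (defaults 2 and 0.05).
#' @param eps pseudo-mean added to both normalized means.
#' @return data.frame of class `deg_result`: `gene_id`, `base_mean`,
#'   `log2_fc`, `p`, `fdr`, `direction`.
#' @export
test_de <- function(mat, conditions, condA, condB, fc_cut = 2,
                    fdr_cut = 0.05, eps = 0.5) {
  mat <- as.matrix(mat)
  for (cond in c(condA, condB))
    if (!cond %in% conditions)
      stop("condition label not found: ", cond, call. = FALSE)
  sf <- size_factors(mat)
  norm <- sweep(mat, 2, sf, "/")
  selA <- conditions == condA
  selB <- conditions == condB
  meanA <- rowMeans(norm[, selA, drop = FALSE])
  meanB <- rowMeans(norm[, selB, drop = FALSE])
  fc <- (meanA + eps) / (meanB + eps)
  pooledA <- rowSums(mat[, selA, drop = FALSE])
  pooledB <- rowSums(mat[, selB, drop = FALSE])
  totA <- sum(pooledA); totB <- sum(pooledB)
  p <- vapply(seq_len(nrow(mat)), function(i) {
    if (pooledA[i] == 0 && pooledB[i] == 0) return(1)
    stats::fisher.test(matrix(c(pooledA[i], totA - pooledA[i],
                                pooledB[i], totB - pooledB[i]),
                              nrow = 2, byrow = TRUE))$p.value
  }, numeric(1))
  fdr <- bh_adjust(p)
  direction <- ifelse(fdr < fdr_cut & fc >= fc_cut, "up",
                      ifelse(fdr < fdr_cut & fc <= 1 / fc_cut, "down", "ns"))
  res <- data.frame(gene_id = rownames(mat),
                    base_mean = (meanA + meanB) / 2,
                    log2_fc = log2(fc), p = p, fdr = fdr,
                    direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("deg_result", "data.frame")
  attr(res, "contrast") <- c(A = condA, B = condB)
  res
}

#' @export
print.deg_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("Differential expression: %s vs %s (%d genes)\n",
              ct["A"], ct["B"], nrow(x)))
  cat(sprintf("  up: %d, down: %d, ns: %d\n", sum(x$direction == "up"),
              sum(x$direction == "down"), sum(x$direction == "ns")))
  invisible(x)
}

#' Overlap of a DEG set with a bound-gene (or second DEG) set
#'
#' Hypergeometric upper-tail overlap via [hypergeometric_overlap()], plus a
#' direction-split breakdown when both inputs carry directions.
#'
#' @param deg a `deg_result` or character vector of gene ids.
#' @param other character vector of gene ids, or a second `deg_result`.
#' @param universe universe of eligible gene ids.
#' @return list with the overlap test fields and, where available,
#'   `signed` (up/up and down/down overlap counts).
#' @export
deg_overlap <- function(deg, other, universe) {
  deg_ids <- function(x) if (inherits(x, "deg_result"))
    x$gene_id[x$direction != "ns"] else unique(x)
  A <- deg_ids(deg)
  B <- deg_ids(other)
  res <- hypergeometric_overlap(A, B, universe)
  if (inherits(deg, "deg_result") && inherits(other, "deg_result")) {
    dir_set <- function(x, d) x$gene_id[x$direction == d]
    res$signed <- c(up_up = length(intersect(dir_set(deg, "up"),
                                             dir_set(other, "up"))),
                    down_down = length(intersect(dir_set(deg, "down"),
                                                 dir_set(other, "down"))))
  }
  res
}
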