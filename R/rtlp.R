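## RTL-P quantification of ribose 2'-O-methylation from RT-qPCR Ct values,
## and the shared 2^-ddCt relative-quantification utility.
##
## RTL-P: reverse transcription at low dNTP concentration stalls at
## 2'-O-methylated residues, so the ratio of the read-through-dependent (FU)
## to read-through-independent (FD) amplicon, at low (LD) versus high (HD)
## dNTP, reports relative methylation. A lower LD/HD ratio-of-ratios means
## more stalling, i.e. higher inferred methylation.

#' Relative quantity by the 2^-ddCt method
#'
#' `2^-((Ct_target - Ct_reference) - (Ct_target_ctrl - Ct_reference_ctrl))`.
#' Invariant under adding a constant to all four Ct values.
#'
#' @param ct_target,ct_reference treated-sample Ct for the target and the
#'   reference (housekeeping) amplicon.
#' @param ct_target_ctrl,ct_reference_ctrl the same in the control sample.
#' @return relative quantity (1 when ddCt = 0).
#' @export
ddct <- function(ct_target, ct_reference, ct_target_ctrl, ct_reference_ctrl) {
  cts <- c(ct_target, ct_reference, ct_target_ctrl, ct_reference_ctrl)
  assert_that(all(is.finite(cts)), "all Ct values must be finite")
  2^-((ct_target - ct_reference) - (ct_target_ctrl - ct_reference_ctrl))
}

#' RTL-P methylation index and condition contrasts
#'
#' Per replicate, amplicon signals are `efficiency^-Ct`; the per-level
#' signal ratio is FU/FD; the methylation index is `ratio(LD) / ratio(HD)`
#' (HD anchors full read-through, so the index is unit-free; MD is reported
#' descriptively). Condition contrasts (treated over Ctrl) are ratios of
#' mean indices, with a paired Student's t-test on replicate-level
#' log2 indices.
#'
#' @param measurements data.frame with columns `condition`, `amplicon`
#'   (`FU`/`FD`), `dntp_level` (`LD`/`MD`/`HD`), `replicate`, `ct`.
#' @param site label carried into the result.
#' @param efficiency amplification efficiency base (2 = 100%).
#' @return object of class `rtlp_result`: list with `site`, `ratios`
#'   (per condition x level mean FU/FD signal ratio), `index` (per
#'   condition), `replicate_index` (per condition x replicate) and
#'   `contrasts` (condition, contrast ratio, paired-t p).
#' @export
rtlp_index <- function(measurements, site = "site", efficiency = 2) {
  m <- measurements
  need <- c("condition", "amplicon", "dntp_level", "replicate", "ct")
  miss <- setdiff(need, names(m))
  assert_that(length(miss) == 0L,
              paste0("measurement table lacks columns: ",
                     paste(miss, collapse = ", ")))
  conds <- unique(m$condition)
  for (cond in conds) for (amp in c("FU", "FD")) for (lev in c("LD", "HD")) {
    if (!any(m$condition == cond & m$amplicon == amp & m$dntp_level == lev))
      stop(sprintf("missing measurements: condition %s, amplicon %s, level %s",
                   cond, amp, lev), call. = FALSE)
  }
  m$signal <- efficiency^-m$ct
  agg <- stats::aggregate(signal ~ condition + amplicon + dntp_level,
                          data = m, FUN = mean)
  ratio_of <- function(cond, lev) {
    fu <- agg$signal[agg$condition == cond & agg$amplicon == "FU" &
                       agg$dntp_level == lev]
    fd <- agg$signal[agg$condition == cond & agg$amplicon == "FD" &
                       agg$dntp_level == lev]
    if (!length(fu) || !length(fd)) return(NA_real_)
    fu / fd
  }
  levels_present <- intersect(c("LD", "MD", "HD"), unique(m$dntp_level))
  ratios <- expand.grid(condition = conds, dntp_level = levels_present,
                        stringsAsFactors = FALSE)
  ratios$ratio <- mapply(ratio_of, ratios$condition, ratios$dntp_level)
  index <- vapply(conds, function(cond)
    ratio_of(cond, "LD") / ratio_of(cond, "HD"), numeric(1))
  names(index) <- conds

  # replicate-level indices for the paired test
  rep_index <- stats::aggregate(signal ~ condition + replicate + amplicon +
                                  dntp_level, data = m, FUN = mean)
  rep_idx_of <- function(cond, repl) {
    g <- function(amp, lev) {
      v <- rep_index$signal[rep_index$condition == cond &
                              rep_index$replicate == repl &
                              rep_index$amplicon == amp &
                              rep_index$dntp_level == lev]
      if (length(v)) v else NA_real_
    }
    (g("FU", "LD") / g("FD", "LD")) / (g("FU", "HD") / g("FD", "HD"))
  }
  reps <- sort(unique(m$replicate))
  replicate_index <- sapply(conds, function(cond)
    vapply(reps, function(r) rep_idx_of(cond, r), numeric(1)))
  replicate_index <- matrix(replicate_index, nrow = length(reps),
                            dimnames = list(reps, conds))

  contrasts <- NULL
  if ("Ctrl" %in% conds) {
    treated <- setdiff(conds, "Ctrl")
    contrasts <- do.call(rbind, lapply(treated, function(cond) {
      lr_t <- log2(replicate_index[, cond])
      lr_c <- log2(replicate_index[, "Ctrl"])
      p <- if (sum(is.finite(lr_t - lr_c)) >= 2 &&
               stats::sd(lr_t - lr_c) > 0)
        stats::t.test(lr_t, lr_c, paired = TRUE)$p.value else NA_real_
      data.frame(condition = cond,
                 contrast = index[[cond]] / index[["Ctrl"]],
                 p = p, stringsAsFactors = FALSE)
    }))
  }
  structure(list(site = site, ratios = ratios, index = index,
                 replicate_index = replicate_index, contrasts = contrasts),
            class = "rtlp_result")
}

#' @export
print.rtlp_result <- function(x, ...) {
  cat(sprintf("RTL-P methylation index at %s\n", x$site))
  for (cond in names(x$index))
    cat(sprintf("  index[%s] = %.4f\n", cond, x$index[[cond]]))
  if (!is.null(x$contrasts))
    for (i in seq_len(nrow(x$contrasts)))
      cat(sprintf("  %s vs Ctrl: contrast %.4f, paired-t p = %.4g\n",
                  x$contrasts$condition[i], x$contrasts$contrast[i],
                  x$contrasts$p[i]))
  invisible(x)
}

#' Simulate RTL-P RT-qPCR measurements
#'
#' Closed-form signal model: at low dNTP the read-through (FU) Ct increases
#' with the methylated fraction `m` by `-log2(1 - m * stall)` cycles (stall
#' efficiency `stall`); FD amplicons and the high-dNTP level are unaffected
#' by `m`; every Ct receives Gaussian replicate noise. With no noise the
#' planted index is exactly `1 - m * stall`.
#'
#' @param m named numeric vector: methylated fraction per condition (each in
#'   `[0, 1]`), e.g. `c(Ctrl = 0.5, OE = 0.9, KD = 0.1)`.
#' @param stall stall efficiency at a methylated site, in (0, 1].
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param n_replicates replicates per condition.
#' @param base_ct baseline Ct of the amplicons.
#' @param seed RNG seed.
#' @return data.frame of measurements as expected by [rtlp_index()].
#' @export
simulate_rtlp <- function(m = c(Ctrl = 0.5, OE = 0.9, KD = 0.1),
                          stall = 0.9, noise_sd = 0.1, n_replicates = 3L,
                          base_ct = 22, seed = 1L) {
  assert_that(all(m >= 0 & m <= 1), "methylated fractions must lie in [0, 1]")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  with_seed(seed, {
    grid <- expand.grid(condition = names(m), amplicon = c("FU", "FD"),
                        dntp_level = c("LD", "MD", "HD"),
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    shift <- function(cond, amp, lev) {
      if (amp != "FU") return(0)
      mm <- m[[cond]]
      if (lev == "LD") -log2(1 - mm * stall)
      else if (lev == "MD") -log2(1 - mm * stall * 0.3)
      else 0
    }
    grid$ct <- base_ct +
      mapply(shift, grid$condition, grid$amplicon, grid$dntp_level) +
      stats::rnorm(nrow(grid), 0, noise_sd)
    grid
  })
}
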