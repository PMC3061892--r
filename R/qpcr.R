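# Efficiency-corrected relative qPCR quantification.
#
# Per-run amplification efficiency E (per-cycle amplification factor) is
# estimated from the exponential phase of the amplification curve by a
# simplified LinRegPCR-style fit: after mean-baseline subtraction, the 4-6
# point log-linear window maximising r^2 is selected and E = 10^slope.
# Relative expression uses the Pfaffl ratio E_target^dCt(target) /
# E_ref^dCt(ref) with dCt = Ct(calibrator) - Ct(sample), normalised to a
# reference gene (GAPDH in the study) and calibrated to a baseline timepoint.

#' Estimate amplification efficiency from one curve
#'
#' @param curve list or data frame with `cycles` (strictly increasing
#'   integers, >= 8 points) and `fluorescence` (non-negative readings).
#' @param baseline_cycles number of initial cycles whose mean fluorescence is
#'   subtracted as baseline (default 5).
#' @param window_sizes candidate window lengths (consecutive above-baseline
#'   points) for the log-linear fit.
#' @return list with `efficiency` (clamped to `[1, 2.2]`, with a warning if
#'   clamping occurred), `window` (first and last cycle used) and `r2`.
#' @export
estimate_efficiency <- function(curve, baseline_cycles = 5L,
                                window_sizes = 4:6) {
  cyc <- curve$cycles
  f <- curve$fluorescence
  stopifnot(length(cyc) == length(f), length(cyc) >= 8L,
            !is.unsorted(cyc, strictly = TRUE), all(f >= 0))
  baseline <- mean(f[seq_len(min(baseline_cycles, length(f)))])
  adj <- f - baseline
  usable <- adj > 0
  best <- NULL
  for (w in window_sizes) {
    for (s in seq_len(length(cyc) - w + 1L)) {
      idx <- s:(s + w - 1L)
      if (!all(usable[idx])) next
      fit <- lm(log10(adj[idx]) ~ cyc[idx])
      r2 <- summary(fit)$r.squared
      if (is.null(best) || r2 > best$r2)
        best <- list(slope = coef(fit)[[2L]], r2 = r2,
                     window = c(cyc[idx[1L]], cyc[idx[w]]))
    }
  }
  if (is.null(best))
    stop("no amplification: no window of above-baseline points")
  eff <- 10^best$slope
  if (eff < 1 || eff > 2.2) {
    warning("estimated efficiency ", signif(eff, 4),
            " outside [1, 2.2]; clamped")
    eff <- min(max(eff, 1), 2.2)
  }
  list(efficiency = eff, window = best$window, r2 = best$r2)
}

#' Ct by linear interpolation at a fluorescence threshold
#'
#' Helper for synthetic curves; instruments report Ct directly for real runs.
#'
#' @inheritParams estimate_efficiency
#' @param threshold fluorescence threshold.
#' @return fractional cycle at which the curve first crosses the threshold.
#' @export
interpolate_ct <- function(curve, threshold) {
  cyc <- curve$cycles
  f <- curve$fluorescence
  above <- which(f >= threshold)
  if (!length(above) || above[1L] == 1L)
    stop("threshold not bracketed by the curve")
  i <- above[1L]
  cyc[i - 1L] + (threshold - f[i - 1L]) / (f[i] - f[i - 1L]) *
    (cyc[i] - cyc[i - 1L])
}

#' Pfaffl efficiency-corrected expression ratio
#'
#' ratio = E_target^dCt_target / E_ref^dCt_ref, with
#' dCt = Ct(calibrator) - Ct(sample). With both efficiencies equal to 2 this
#' reduces to the classic 2^ddCt.
#'
#' @param E_target,E_ref per-cycle amplification factors in `[1, 2.2]`.
#' @param dCt_target,dCt_ref Ct differences (calibrator minus sample).
#' @return the dimensionless expression ratio.
#' @export
pfaffl_ratio <- function(E_target, dCt_target, E_ref, dCt_ref) {
  if (E_target <= 0 || E_ref <= 0) stop("efficiencies must be positive")
  E_target^dCt_target / E_ref^dCt_ref
}

#' Timecourse relative expression with reference-gene normalisation
#'
#' For each gene, timepoint and biological repeat the Pfaffl ratio against
#' the calibrator timepoint is computed (using the gene's and the reference
#' gene's efficiencies), then summarised per timepoint as mean and standard
#' error (sd/sqrt(n)) over repeats. The calibrator timepoint has mean ratio
#' 1 by construction.
#'
#' @param ct_table data frame with columns `gene`, `timepoint`, `repeat_id`,
#'   `ct`.
#' @param efficiencies named numeric vector of per-gene efficiencies
#'   (must include every gene and the reference).
#' @param reference_gene gene used for normalisation (e.g. `"GAPDH"`).
#' @param calibrator_timepoint timepoint whose expression defines ratio 1.
#' @return data frame with `gene`, `timepoint`, `ratio` (mean over repeats),
#'   `se`, `n_repeats`; the reference gene itself is not reported.
#' @export
timecourse_expression <- function(ct_table, efficiencies, reference_gene,
                                  calibrator_timepoint) {
  need <- c("gene", "timepoint", "repeat_id", "ct")
  stopifnot(all(need %in% names(ct_table)))
  genes <- setdiff(unique(ct_table$gene), reference_gene)
  if (!reference_gene %in% ct_table$gene)
    stop("reference gene '", reference_gene, "' absent from table")
  missing_eff <- setdiff(c(genes, reference_gene), names(efficiencies))
  if (length(missing_eff))
    stop("no efficiency for gene(s): ", paste(missing_eff, collapse = ", "))
  lookup_ct <- function(g, tp, rep) {
    v <- ct_table$ct[ct_table$gene == g & ct_table$timepoint == tp &
                       ct_table$repeat_id == rep]
    if (length(v) != 1L || is.na(v))
      stop("missing Ct for gene=", g, " timepoint=", tp, " repeat=", rep)
    v
  }
  out <- NULL
  for (g in genes) {
    tps <- unique(ct_table$timepoint[ct_table$gene == g])
    if (!calibrator_timepoint %in% tps)
      stop("calibrator timepoint '", calibrator_timepoint,
           "' absent for gene ", g)
    for (tp in tps) {
      reps <- unique(ct_table$repeat_id[ct_table$gene == g &
                                          ct_table$timepoint == tp])
      ratios <- vapply(reps, function(r) {
        dct_t <- lookup_ct(g, calibrator_timepoint, r) - lookup_ct(g, tp, r)
        dct_r <- lookup_ct(reference_gene, calibrator_timepoint, r) -
          lookup_ct(reference_gene, tp, r)
        pfaffl_ratio(efficiencies[[g]], dct_t,
                     efficiencies[[reference_gene]], dct_r)
      }, numeric(1))
      out <- rbind(out, data.frame(
        gene = g, timepoint = tp, ratio = mean(ratios),
        se = if (length(ratios) > 1L) sd(ratios) / sqrt(length(ratios)) else 0,
        n_repeats = length(ratios), stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
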