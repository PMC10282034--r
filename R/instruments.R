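# Adaptive instrument selection, instrument-strength statistics and Steiger
# directionality filtering.

P_LADDER <- c(5e-8, 5e-7, 5e-6, 5e-5, 5e-4)

#' Select instruments by an adaptive p-value ladder
#'
#' Starts at genome-wide significance (p < 5e-8) and relaxes the threshold by
#' a factor of 10 per rung, up to 5e-4, until more than `min_count`
#' instruments survive clumping. If no rung yields enough instruments the
#' maximum-threshold set is returned with status `insufficient_instruments`.
#'
#' @param exposure Exposure summary statistics (canonical schema).
#' @param ld An `ld_reference` used for clumping at each rung.
#' @param start First threshold of the ladder.
#' @param factor Multiplicative step between rungs.
#' @param max_threshold Last rung.
#' @param min_count Instrument count that must be exceeded (strictly) for a
#'   rung to succeed; default 5, i.e. at least 6 instruments.
#' @param r2_max,window_kb Clumping parameters (see [clump()]).
#' @return List of class `instrument_selection`: `threshold`, `snv_ids`,
#'   `instruments` (the clumped exposure rows), `n_selected`, `status`.
#' @export
select_instruments <- function(exposure, ld, start = 5e-8, factor = 10,
                               max_threshold = 5e-4, min_count = 5L,
                               r2_max = 0.001, window_kb = 10000) {
  stopifnot(nrow(exposure) > 0L)
  ladder <- start * factor^(0:100)
  ladder <- ladder[ladder <= max_threshold * (1 + 1e-12)]
  sel <- NULL
  threshold <- NA_real_
  for (thr in ladder) {
    cand <- exposure[exposure$pval < thr, , drop = FALSE]
    if (nrow(cand) == 0L) next
    kept <- clump(cand, ld, r2_max = r2_max, window_kb = window_kb)
    sel <- kept
    threshold <- thr
    if (nrow(kept) > min_count) break
  }
  if (is.null(sel)) {
    sel <- exposure[0, , drop = FALSE]
    threshold <- ladder[length(ladder)]
  }
  status <- if (nrow(sel) > min_count) "ok" else "insufficient_instruments"
  structure(list(threshold = threshold, snv_ids = sel$snv_id,
                 instruments = sel, n_selected = nrow(sel), status = status),
            class = "instrument_selection")
}

#' Per-variant proportion of exposure variance explained
#'
#' Uses the t-statistic identity `r2 = t^2 / (t^2 + n - 2)` with
#' `t = beta / se`, which requires no trait-variance or allele-frequency
#' assumption and is exact for a standardised continuous exposure.
#'
#' @param beta,se,n Effect, standard error and sample size (vectorised).
#' @return Numeric vector of per-variant r2 values.
#' @export
per_variant_r2 <- function(beta, se, n) {
  if (any(n <= 2)) stop("sample size must exceed 2 for the r2 identity")
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Mean instrumental F statistic
#'
#' `F = ((N - 1 - k) / k) * (R2 / (1 - R2))` with `N` the exposure sample
#' size, `k` the instrument count and `R2` the total variance explained. A
#' mean F of 10 or below flags the instrument set as weak.
#'
#' @param r2_total Total proportion of variance explained, in \[0, 1).
#' @param n Exposure sample size.
#' @param k Number of instruments.
#' @return List: `f_mean`, `weak_instruments` (TRUE when `f_mean <= 10`),
#'   `r2_total`, `n`, `k`.
#' @export
mean_f_statistic <- function(r2_total, n, k) {
  stopifnot(k >= 1, n > k + 1)
  if (r2_total >= 1 || r2_total < 0) stop("r2_total must lie in [0, 1)")
  f <- ((n - 1 - k) / k) * (r2_total / (1 - r2_total))
  list(f_mean = f, weak_instruments = f <= 10, r2_total = r2_total,
       n = n, k = k)
}

#' Instrument-strength summary for a harmonised set
#'
#' @param set Harmonised instrument table (see [harmonise_pair()]).
#' @param n Exposure sample size.
#' @return As [mean_f_statistic()], with `r2_total` the sum of per-variant
#'   r2 values.
#' @export
instrument_strength <- function(set, n) {
  k <- nrow(set)
  r2 <- sum(per_variant_r2(set$gamma, set$se_gamma, n))
  mean_f_statistic(min(r2, 1 - 1e-12), n, k)
}

#' Steiger directionality filter
#'
#' Removes instruments that are more significant for the outcome than for
#' the exposure (strictly smaller outcome p-value), a guard against reverse
#' causation. Order is preserved.
#'
#' @param set Harmonised instrument table with `p_exposure` and `p_outcome`.
#' @return The filtered table with attribute `removed` (character vector of
#'   removed identifiers).
#' @export
steiger_filter <- function(set) {
  drop <- set$p_outcome < set$p_exposure
  out <- set[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- set$snv_id[drop]
  attr(out, "dropped") <- attr(set, "dropped")
  out
}
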