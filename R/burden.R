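# Gene-based rare-variant collapsing burden test: qualifying-variant
# selection and a single two-sided Fisher's exact test of carrier frequency
# in cases versus controls.

DELETERIOUS_CONSEQUENCES <- c("missense")

#' Select qualifying rare variants
#'
#' A variant qualifies when it is rare in both the study cohort and the
#' population reference (MAF strictly below `maf_max` in each), its
#' consequence changes the amino-acid sequence, and its REVEL pathogenicity
#' score strictly exceeds `revel_min`. Variants with a missing REVEL score
#' are excluded. The filter is pure: output rows are a subset of the input
#' and reapplication changes nothing.
#'
#' @param variants Variant data.frame (`variant_id, maf_cohort,
#'   maf_population, consequence, revel, ...`).
#' @param maf_max Rarity ceiling (default 0.001).
#' @param revel_min REVEL floor, exclusive (default 0.25).
#' @param deleterious Consequence labels counted as amino-acid-changing
#'   (default missense only).
#' @return The qualifying subset.
#' @export
qualifying_variants <- function(variants, maf_max = 0.001, revel_min = 0.25,
                                deleterious = DELETERIOUS_CONSEQUENCES) {
  keep <- variants$maf_cohort < maf_max &
    variants$maf_population < maf_max &
    variants$consequence %in% deleterious &
    !is.na(variants$revel) & variants$revel > revel_min
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher's exact test on a 2x2 burden table
#'
#' Conditional hypergeometric test: with all margins fixed, the two-sided
#' p-value is the total probability of tables whose probability does not
#' exceed the observed table's. The odds ratio is the cross-product
#' `(a d)/(b c)`; when a zero in `b` or `c` would make it undefined the
#' Haldane continuity correction (0.5 added to every cell) is applied and
#' flagged. A zero margin makes the test degenerate: `p = 1`, OR missing.
#'
#' @param a,b,c,d Cell counts: `a` carriers among cases, `b` carriers among
#'   controls, `c` non-carriers among cases, `d` non-carriers among
#'   controls.
#' @return List: `or, pval, haldane, degenerate`.
#' @export
fisher_exact <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0,
            a == round(a), b == round(b), c == round(c), d == round(d))
  n_cases <- a + c; n_controls <- b + d
  carriers <- a + b; total <- a + b + c + d
  if (carriers == 0L || carriers == total || n_cases == 0L || n_controls == 0L) {
    return(list(or = NA_real_, pval = 1, haldane = FALSE, degenerate = TRUE))
  }
  lo <- max(0L, carriers - n_controls)
  hi <- min(carriers, n_cases)
  support <- lo:hi
  probs <- stats::dhyper(support, carriers, total - carriers, n_cases)
  p_obs <- stats::dhyper(a, carriers, total - carriers, n_cases)
  pval <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  haldane <- (b == 0 || c == 0)
  or <- if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
        else (a * d) / (b * c)
  list(or = or, pval = pval, haldane = haldane, degenerate = FALSE)
}

#' Collapsing rare-variant burden test
#'
#' Qualifying variants are collapsed: the carrier count in each arm is the
#' sum of per-variant carrier counts (individuals are assumed to carry at
#' most one qualifying variant in the rare-variant regime; sums exceeding
#' the cohort size are capped and flagged). The resulting 2x2
#' carriers/non-carriers by cases/controls table is tested with a single
#' two-sided Fisher's exact test; nominal significance (`p < 0.05`) is
#' taken as association.
#'
#' @param variants Variant data.frame (see [qualifying_variants()]).
#' @param n_cases,n_controls Cohort sizes (positive).
#' @param maf_max,revel_min,deleterious Qualifying-variant thresholds.
#' @return List of class `burden_result`: `status` (`"ok"` or
#'   `"no_qualifying_variants"`), `table` (2x2 matrix), `or`, `pval`,
#'   `significant`, `n_qualifying`, `capped`, `haldane`, `degenerate`.
#' @export
burden_test <- function(variants, n_cases, n_controls, maf_max = 0.001,
                        revel_min = 0.25,
                        deleterious = DELETERIOUS_CONSEQUENCES) {
  stopifnot(n_cases >= 1L, n_controls >= 1L)
  qv <- qualifying_variants(variants, maf_max, revel_min, deleterious)
  if (nrow(qv) == 0L) {
    return(structure(list(status = "no_qualifying_variants", table = NULL,
                          or = NA_real_, pval = NA_real_, significant = FALSE,
                          n_qualifying = 0L, capped = FALSE, haldane = FALSE,
                          degenerate = FALSE),
                     class = "burden_result"))
  }
  cc <- sum(qv$carriers_cases)
  cn <- sum(qv$carriers_controls)
  capped <- cc > n_cases || cn > n_controls
  cc <- min(cc, n_cases); cn <- min(cn, n_controls)
  tab <- matrix(c(cc, cn, n_cases - cc, n_controls - cn), nrow = 2,
                byrow = TRUE,
                dimnames = list(c("carrier", "non_carrier"),
                                c("cases", "controls")))
  ft <- fisher_exact(cc, cn, n_cases - cc, n_controls - cn)
  structure(list(status = "ok", table = tab, or = ft$or, pval = ft$pval,
                 significant = is.finite(ft$pval) && ft$pval < 0.05,
                 n_qualifying = nrow(qv), capped = capped,
                 haldane = ft$haldane, degenerate = ft$degenerate),
            class = "burden_result")
}
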