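# Phenome-wide screen orchestration: catalogue filtering, duplicate-trait
# management, the per-trait pipeline, FDR correction, the five-way
# significance criterion and effect-size presentation.

#' Screen configuration
#'
#' @param nominal_alpha Nominal significance level for the robust-estimator
#'   concordance arm (default 0.05).
#' @param fdr_alpha FDR level applied to the MRE-IVW p-values (default 0.05).
#' @param ladder_start,ladder_factor,ladder_max,min_count Instrument-selection
#'   ladder (see [select_instruments()]).
#' @param palindrome_maf_max Palindromic MAF ceiling (see [harmonise_pair()]).
#' @param clump_r2,clump_window_kb Clumping parameters.
#' @param proxy_min_r2 Minimum LD r2 for proxy substitution.
#' @param radial_alpha Radial outlier flagging level; when
#'   `radial_bonferroni` is TRUE the level used is `radial_alpha / n_snv`.
#' @param radial_bonferroni Use the Bonferroni-divided radial level.
#' @param n_boot Bootstrap replicates for weighted median/mode.
#' @param bandwidth_factor Weighted-mode bandwidth multiplier.
#' @param seed Master seed; each trait gets a deterministic seed derived
#'   from it, so screen output is order-independent and reproducible.
#' @return A `screen_config` list.
#' @export
screen_config <- function(nominal_alpha = 0.05, fdr_alpha = 0.05,
                          ladder_start = 5e-8, ladder_factor = 10,
                          ladder_max = 5e-4, min_count = 5L,
                          palindrome_maf_max = 0.42,
                          clump_r2 = 0.001, clump_window_kb = 10000,
                          proxy_min_r2 = 0.9,
                          radial_alpha = 0.05, radial_bonferroni = FALSE,
                          n_boot = 1000L, bandwidth_factor = 1,
                          seed = 1L) {
  stopifnot(nominal_alpha > 0, nominal_alpha < 1, fdr_alpha > 0, fdr_alpha < 1)
  structure(list(nominal_alpha = nominal_alpha, fdr_alpha = fdr_alpha,
                 ladder_start = ladder_start, ladder_factor = ladder_factor,
                 ladder_max = ladder_max, min_count = as.integer(min_count),
                 palindrome_maf_max = palindrome_maf_max,
                 clump_r2 = clump_r2, clump_window_kb = clump_window_kb,
                 proxy_min_r2 = proxy_min_r2, radial_alpha = radial_alpha,
                 radial_bonferroni = radial_bonferroni,
                 n_boot = as.integer(n_boot),
                 bandwidth_factor = bandwidth_factor,
                 seed = as.integer(seed)),
            class = "screen_config")
}

#' Filter a trait catalogue for screen eligibility
#'
#' Drops imaging phenotypes, eQTL traits and traits from the "finn" cohort
#' (sample overlap with the outcome meta-analysis). Remaining traits are
#' assigned an outcome version: cohorts `ukb` and `met-d` (wholly
#' UK-Biobank-derived) use the overlap-free outcome subset, all others the
#' full outcome GWAS.
#'
#' @param catalogue Trait-metadata data.frame (see [read_trait_catalogue()]).
#' @return The eligible rows with an added `outcome_version` column
#'   (`"no_overlap_subset"` or `"full"`) and attribute `counts` (named vector
#'   of exclusion tallies).
#' @export
filter_trait_catalogue <- function(catalogue) {
  stopifnot(nrow(catalogue) > 0L)
  excl_imaging <- catalogue$is_imaging %in% TRUE
  excl_eqtl <- catalogue$is_eqtl %in% TRUE
  excl_finn <- catalogue$source_cohort == "finn"
  keep <- !(excl_imaging | excl_eqtl | excl_finn)
  out <- catalogue[keep, , drop = FALSE]
  out$outcome_version <- ifelse(out$source_cohort %in% c("ukb", "met-d"),
                                "no_overlap_subset", "full")
  rownames(out) <- NULL
  attr(out, "counts") <- c(excluded_imaging = sum(excl_imaging),
                           excluded_eqtl = sum(excl_eqtl),
                           excluded_finn = sum(excl_finn),
                           eligible = sum(keep))
  out
}

#' Choose the primary entry within duplicate-trait groups
#'
#' Traits sharing a label are duplicates of one another. Within each group
#' the primary analysis is the largest-sample-size study; same-population
#' ties on sample size break by larger mean F statistic (supplied
#' post-selection), and for binary traits remaining ties break by larger
#' case count. The ordering is fully deterministic (final tie-break by
#' trait identifier).
#'
#' @param catalogue Trait-metadata data.frame.
#' @param f_stat Optional named numeric vector of mean F statistics keyed by
#'   `trait_id` (used only to break exact sample-size ties).
#' @return The primary rows, one per label, with attribute
#'   `duplicates_removed` (character vector of non-primary trait ids).
#' @export
deduplicate_traits <- function(catalogue, f_stat = NULL) {
  f <- rep(-Inf, nrow(catalogue))
  if (!is.null(f_stat)) {
    m <- f_stat[catalogue$trait_id]
    f[!is.na(m)] <- m[!is.na(m)]
  }
  ncases <- ifelse(is.na(catalogue$n_cases), -Inf, catalogue$n_cases)
  ord <- order(catalogue$label, -catalogue$n_total, -f, -ncases,
               catalogue$trait_id)
  sorted <- catalogue[ord, , drop = FALSE]
  primary <- !duplicated(sorted$label)
  out <- sorted[primary, , drop = FALSE]
  out <- out[order(match(out$trait_id, catalogue$trait_id)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "duplicates_removed") <- setdiff(catalogue$trait_id, out$trait_id)
  out
}

#' Run the full per-trait MR pipeline
#'
#' Stages, in order: adaptive instrument selection (p-value ladder with
#' post-clump eligibility counts), LD-proxy substitution for instruments
#' missing from the outcome, clumping, harmonisation, Steiger filtering,
#' radial outlier removal, then the estimator battery with Cochran's Q,
#' MR-Egger intercept/I2_GX, leave-one-out and instrument-strength QC. Any
#' stage that reduces the instrument count below a method's minimum sets the
#' trait status and skips the remaining estimators; failures surface as
#' status codes, never exceptions, so a screen always completes.
#'
#' @param exposure,outcome Summary-statistic data.frames.
#' @param ld An `ld_reference`.
#' @param config A [screen_config()].
#' @param trait_id Trait identifier for the result.
#' @param seed Seed for the bootstrap estimators (defaults to
#'   `config$seed`).
#' @return A `trait_screen_result` list: `trait_id, status, selection,
#'   instrument_stats, fits, diagnostics, flags, harmonised, dropped,
#'   steiger_removed, outliers_removed`.
#' @export
run_trait <- function(exposure, outcome, ld, config = screen_config(),
                      trait_id = exposure$trait_id[1], seed = config$seed) {
  res <- list(trait_id = trait_id, status = "ok", selection = NULL,
              instrument_stats = NULL, fits = NULL, diagnostics = NULL,
              flags = list(weak_instruments = NA, egger_nome_warning = NA,
                           loo_all_nominal = NA, outliers_removed = 0L,
                           steiger_removed = 0L),
              harmonised = NULL, dropped = NULL)
  class(res) <- "trait_screen_result"

  sel <- select_instruments(exposure, ld, start = config$ladder_start,
                            factor = config$ladder_factor,
                            max_threshold = config$ladder_max,
                            min_count = config$min_count,
                            r2_max = config$clump_r2,
                            window_kb = config$clump_window_kb)
  res$selection <- sel
  if (sel$status != "ok") {
    res$status <- "insufficient_instruments"
    return(res)
  }

  inst <- substitute_proxies(sel$instruments, exposure, outcome$snv_id, ld,
                             min_r2 = config$proxy_min_r2)
  inst <- clump(inst, ld, r2_max = config$clump_r2,
                window_kb = config$clump_window_kb)

  hset <- harmonise_pair(inst, outcome,
                         palindrome_maf_max = config$palindrome_maf_max)
  res$dropped <- attr(hset, "dropped")
  if (nrow(hset) == 0L) {
    res$status <- "no_harmonisable_instruments"
    return(res)
  }

  hset <- steiger_filter(hset)
  res$flags$steiger_removed <- length(attr(hset, "removed"))

  if (nrow(hset) >= 3L) {
    alpha <- if (config$radial_bonferroni)
      config$radial_alpha / nrow(hset) else config$radial_alpha
    rad <- radial_outliers(hset, alpha = alpha)
    res$flags$outliers_removed <- length(rad$outliers)
    hset <- hset[!(hset$snv_id %in% rad$outliers), , drop = FALSE]
  }
  res$harmonised <- hset

  n <- nrow(hset)
  if (n == 0L) {
    res$status <- "insufficient_after_qc"
    return(res)
  }
  res$instrument_stats <- instrument_strength(hset, exposure$n[1])
  res$flags$weak_instruments <- res$instrument_stats$weak_instruments
  if (n == 1L) {
    res$status <- "single_instrument"
    res$fits <- list(wald_ratio = mr_wald_single(hset))
    return(res)
  }
  if (n == 2L) {
    res$status <- "insufficient_for_robust"
    res$fits <- list(ivw_mre = mr_ivw(hset, "mre"), ivw_fe = mr_ivw(hset, "fe"))
    return(res)
  }

  fits <- mr_all(hset, n_boot = config$n_boot, seed = seed,
                 bandwidth_factor = config$bandwidth_factor)
  res$diagnostics <- fits$diagnostics
  res$fits <- fits[setdiff(names(fits), "diagnostics")]
  res$flags$egger_nome_warning <- res$fits$egger$egger_nome_warning
  res$flags$loo_all_nominal <- attr(res$diagnostics$loo, "loo_all_nominal")
  res
}

#' Benjamini-Hochberg FDR adjustment over the whole screen
#'
#' Standard step-up with the denominator fixed at `m`, the total number of
#' traits entering the screen — traits whose pipeline failed contribute no
#' p-value but still count in `m`.
#'
#' @param pvals P-values in (0, 1].
#' @param m Total number of traits (at least `length(pvals)`).
#' @return Adjusted q-values in (0, 1].
#' @export
bh_fdr <- function(pvals, m = length(pvals)) {
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (m < length(pvals)) stop("m must be at least length(pvals)")
  stats::p.adjust(pvals, method = "BH", n = m)
}

#' Apply the five-way significance criterion
#'
#' A trait is called significant when (1) its MRE-IVW p-value survives FDR
#' correction, (2-4) the weighted median, weighted mode and MR-Egger
#' p-values are each nominally significant, and (5) every leave-one-out IVW
#' fit remains nominally significant. Traits passing the FDR and
#' leave-one-out arms but lacking full agreement among the robust
#' estimators are labelled `ivw_fdr_only` (weaker evidence); everything
#' else is `not_significant`.
#'
#' @param results Screen-results data.frame (one row per trait, as built by
#'   [run_screen()]); must carry `fdr_q_ivw`, the per-method p-values,
#'   `loo_all_nominal` and `status`.
#' @param config A [screen_config()].
#' @return `results` with `significant` (logical) and `call` (character)
#'   columns filled in.
#' @export
call_significant <- function(results, config = screen_config()) {
  ok <- results$status == "ok"
  q_pass <- ok & !is.na(results$fdr_q_ivw) &
    results$fdr_q_ivw < config$fdr_alpha
  loo_pass <- q_pass & results$loo_all_nominal %in% TRUE
  concord <- ok &
    !is.na(results$weighted_median_pval) &
    results$weighted_median_pval < config$nominal_alpha &
    !is.na(results$weighted_mode_pval) &
    results$weighted_mode_pval < config$nominal_alpha &
    !is.na(results$egger_pval) &
    results$egger_pval < config$nominal_alpha
  results$significant <- loo_pass & concord
  results$call <- ifelse(results$significant, "significant",
                         ifelse(loo_pass, "ivw_fdr_only", "not_significant"))
  results
}

#' Present a causal estimate on the odds-ratio scale
#'
#' Continuous exposures report the OR (per 1 SD of exposure) with its
#' confidence interval; binary exposures additionally report the log-odds
#' beta and carry a caveat flag, since the OR for a binary exposure
#' indicates direction but not an interpretable magnitude.
#'
#' @param fit An `mr_fit`.
#' @param exposure_is_binary Flag from the trait catalogue.
#' @param level Confidence level (default 0.95).
#' @return List: `or, ci_lower, ci_upper`, plus `beta` and
#'   `or_magnitude_caveat = TRUE` for binary exposures.
#' @export
format_effect <- function(fit, exposure_is_binary = FALSE, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- list(or = exp(fit$beta),
              ci_lower = exp(fit$beta - z * fit$se),
              ci_upper = exp(fit$beta + z * fit$se))
  if (exposure_is_binary) {
    out$beta <- fit$beta
    out$or_magnitude_caveat <- TRUE
  }
  out
}

#' Flatten a trait result to one screen-results row
#'
#' @param res A `trait_screen_result`.
#' @param outcome_version Outcome version used for the trait.
#' @return One-row data.frame in the screen-results schema (estimate fields
#'   empty unless the corresponding fit exists).
#' @export
screen_result_row <- function(res, outcome_version = "full") {
  row <- data.frame(trait_id = res$trait_id, status = res$status,
                    call = NA_character_, outcome_version = outcome_version,
                    stringsAsFactors = FALSE)
  sel <- res$selection
  row$threshold <- if (!is.null(sel)) sel$threshold else NA_real_
  row$n_selected <- if (!is.null(sel)) sel$n_selected else NA_integer_
  row$n_snv <- if (!is.null(res$harmonised)) nrow(res$harmonised) else NA_integer_
  for (m in c("ivw_mre", "ivw_fe", "egger", "weighted_median", "weighted_mode")) {
    f <- res$fits[[m]]
    row[[paste0(m, "_beta")]] <- if (!is.null(f)) f$beta else NA_real_
    row[[paste0(m, "_se")]] <- if (!is.null(f)) f$se else NA_real_
    row[[paste0(m, "_pval")]] <- if (!is.null(f)) f$pval else NA_real_
    row[[paste0(m, "_or")]] <- if (!is.null(f)) exp(f$beta) else NA_real_
  }
  eg <- res$fits$egger
  row$egger_intercept <- if (!is.null(eg)) eg$intercept else NA_real_
  row$egger_intercept_se <- if (!is.null(eg)) eg$intercept_se else NA_real_
  row$egger_intercept_pval <- if (!is.null(eg)) eg$intercept_pval else NA_real_
  row$i2_gx <- if (!is.null(eg)) eg$i2_gx else NA_real_
  di <- res$diagnostics
  row$q <- if (!is.null(di)) di$q else NA_real_
  row$q_df <- if (!is.null(di)) di$q_df else NA_real_
  row$q_pval <- if (!is.null(di)) di$q_pval else NA_real_
  row$sigma_hat <- if (!is.null(res$fits$ivw_mre)) res$fits$ivw_mre$sigma_hat
                   else NA_real_
  st <- res$instrument_stats
  row$r2_total <- if (!is.null(st)) st$r2_total else NA_real_
  row$f_mean <- if (!is.null(st)) st$f_mean else NA_real_
  fl <- res$flags
  row$weak_instruments <- fl$weak_instruments
  row$egger_nome_warning <- fl$egger_nome_warning
  row$loo_all_nominal <- fl$loo_all_nominal
  row$outliers_removed <- fl$outliers_removed
  row$steiger_removed <- fl$steiger_removed
  row$fdr_q_ivw <- NA_real_
  row$significant <- NA
  row
}

#' Run a phenome-wide screen
#'
#' Filters and deduplicates the catalogue, runs the per-trait pipeline for
#' every eligible primary trait (each with a deterministic seed derived from
#' the master seed, so results are order-independent), applies BH-FDR to
#' the MRE-IVW p-values with the denominator equal to the number of traits
#' entering the screen, and applies the five-way significance criterion.
#'
#' @param data Named list of per-trait inputs, each a list with elements
#'   `exposure`, `outcome`, `ld` (as produced by [simulate_phenome()]).
#' @param catalogue Trait-metadata data.frame covering `names(data)`.
#' @param config A [screen_config()].
#' @return List: `results` (screen-results data.frame, one row per screened
#'   trait, with `fdr_q_ivw`, `significant` and `call` filled), `details`
#'   (named list of `trait_screen_result`), `catalogue` (the filtered,
#'   deduplicated catalogue with `outcome_version`), `m` (FDR denominator).
#' @export
run_screen <- function(data, catalogue, config = screen_config()) {
  eligible <- filter_trait_catalogue(catalogue)
  primary <- deduplicate_traits(eligible)
  missing <- setdiff(primary$trait_id, names(data))
  if (length(missing)) stop("no data supplied for trait(s): ",
                            paste(missing, collapse = ", "))
  m <- nrow(primary)

  details <- vector("list", m)
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    tid <- primary$trait_id[i]
    d <- data[[tid]]
    seed_i <- derive_seed(config$seed, match(tid, sort(names(data))))
    res <- run_trait(d$exposure, d$outcome, d$ld, config, trait_id = tid,
                     seed = seed_i)
    details[[i]] <- res
    rows[[i]] <- screen_result_row(res, primary$outcome_version[i])
  }
  names(details) <- primary$trait_id
  results <- do.call(rbind, rows)

  has_p <- !is.na(results$ivw_mre_pval)
  results$fdr_q_ivw[has_p] <- bh_fdr(results$ivw_mre_pval[has_p], m = m)
  results <- call_significant(results, config)
  list(results = results, details = details, catalogue = primary, m = m)
}
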