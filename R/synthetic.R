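# Synthetic two-sample GWAS generator with known ground truth.
#
# The generator works directly on the summary-statistic scale: per-SNV
# exposure effects gamma_j (SD units) with sampling noise scaled to allele
# frequency and sample size, and outcome effects Gamma_j = theta * gamma_j +
# alpha_j on the log-odds scale, where alpha_j is a horizontal-pleiotropy
# term carried only by invalid instruments. LD is laid out in explicit
# blocks so clumping ground truth is enumerable; a configurable fraction of
# SNVs is palindromic and outcome rows can be randomly recoded (allele swap
# and/or strand complement) to exercise harmonisation.

#' Simulation configuration
#'
#' Defaults describe one exposure trait screened against a large binary
#' outcome GWAS: exposure sample size 1e5, outcome sample size 216,257
#' (16,677 cases + 199,580 controls), 50 SNVs jointly explaining 5% of
#' exposure variance.
#'
#' @param n_snv Number of SNVs.
#' @param n_blocks Number of LD blocks; SNVs are distributed evenly and
#'   blocks are mutually unlinked (between-block r2 exactly 0). Defaults to
#'   `n_snv` (no LD).
#' @param maf_range Interval in (0, 0.5] for the uniform minor-allele
#'   frequency draw.
#' @param n_exposure,n_outcome GWAS sample sizes; per-SNV standard errors are
#'   `(2 maf (1 - maf) n)^(-1/2)`.
#' @param theta True causal effect (log-OR of outcome per SD of exposure).
#' @param prop_invalid Fraction of SNVs carrying a pleiotropic direct effect.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the pleiotropic effect
#'   `alpha_j ~ N(mean, sd^2)` on invalid SNVs (directional when mean != 0,
#'   balanced when mean = 0). Pleiotropic effects act on the
#'   exposure-increasing allele, the frame in which the MR-Egger intercept
#'   estimates the mean directional effect.
#' @param prop_palindromic Fraction of SNVs given A/T or C/G allele pairs.
#' @param recode_prob Probability an outcome row is stored with discordant
#'   allele coding (allele swap, strand complement, or both).
#' @param r2_exposure Total exposure variance explained by the `n_snv` true
#'   effects.
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snv = 50L, n_blocks = n_snv,
                       maf_range = c(0.05, 0.5),
                       n_exposure = 1e5, n_outcome = 216257,
                       theta = 0, prop_invalid = 0,
                       pleiotropy_mean = 0, pleiotropy_sd = 0.05,
                       prop_palindromic = 0.2, recode_prob = 0.3,
                       r2_exposure = 0.05, seed = 1L) {
  cfg <- list(n_snv = as.integer(n_snv), n_blocks = as.integer(n_blocks),
              maf_range = as.numeric(maf_range),
              n_exposure = n_exposure, n_outcome = n_outcome,
              theta = theta, prop_invalid = prop_invalid,
              pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
              prop_palindromic = prop_palindromic, recode_prob = recode_prob,
              r2_exposure = r2_exposure, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @keywords internal
#' @noRd
validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_snv >= 1L, cfg$n_blocks >= 1L, cfg$n_blocks <= cfg$n_snv,
            cfg$n_exposure >= 2, cfg$n_outcome >= 2,
            length(cfg$maf_range) == 2L,
            cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
            cfg$maf_range[1] <= cfg$maf_range[2],
            cfg$r2_exposure > 0, cfg$r2_exposure < 1)
  for (f in c("prop_invalid", "prop_palindromic", "recode_prob")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  invisible(cfg)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Simulate one exposure/outcome summary-statistic pair
#'
#' @param config A [sim_config()].
#' @param trait_id Identifier used for the exposure rows and SNV id prefix.
#' @return List with elements `exposure` and `outcome` (summary-statistic
#'   data.frames in the canonical schema), `ld` (an `ld_reference` listing
#'   every within-block pair), and `truth` (a data.frame with `theta`
#'   attribute: per-SNV `gamma_true`, `alpha`, `valid_mask`,
#'   `Gamma_hat_pre` — the outcome estimate signed to the exposure effect
#'   allele before any recoding — `recode_type` and `is_palindromic`).
#' @export
simulate_trait_pair <- function(config = sim_config(), trait_id = "trait_1") {
  validate_sim_config(config)
  with_local_seed(config$seed, simulate_trait_pair_impl(config, trait_id))
}

#' @keywords internal
#' @noRd
simulate_trait_pair_impl <- function(cfg, trait_id) {
  J <- cfg$n_snv
  ids <- sprintf("rs%s_%04d", trait_id, seq_len(J))

  # genome layout: each block on its own 20-Mb-separated locus so blocks are
  # independent under any clumping window up to 20,000 kb
  block <- rep(seq_len(cfg$n_blocks), length.out = J)
  block <- sort(block)
  chrom <- as.character(((block - 1L) %% 22L) + 1L)
  locus_base <- 1e6 + ((block - 1L) %/% 22L) * 2e7
  within_idx <- stats::ave(seq_len(J), block, FUN = seq_along)
  pos <- as.integer(locus_base + (within_idx - 1L) * 1e4)

  maf <- stats::runif(J, cfg$maf_range[1], cfg$maf_range[2])

  # allele pairs: palindromic fraction first (A/T or C/G), rest non-palindromic
  n_pal <- round(cfg$prop_palindromic * J)
  is_pal <- seq_len(J) %in% sample.int(J, n_pal)
  ea <- character(J); oa <- character(J)
  pal_choice <- sample(c("AT", "CG"), J, replace = TRUE)
  ea[is_pal] <- ifelse(pal_choice[is_pal] == "AT", "A", "C")
  oa[is_pal] <- ifelse(pal_choice[is_pal] == "AT", "T", "G")
  npairs <- list(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))
  pick <- sample.int(4L, J, replace = TRUE)
  for (j in which(!is_pal)) {
    pr <- npairs[[pick[j]]]
    if (stats::runif(1) < 0.5) pr <- rev(pr)
    ea[j] <- pr[1]; oa[j] <- pr[2]
  }

  # true effects: magnitudes bounded away from zero (instruments are by
  # definition robustly exposure-associated; near-null effects would never
  # survive selection), random sign, rescaled so the summed per-SNV variance
  # explained (2 maf (1-maf) gamma^2) hits the configured r2 target
  g_raw <- sample(c(-1, 1), J, replace = TRUE) * (0.5 + abs(stats::rnorm(J)))
  v <- 2 * maf * (1 - maf)
  gamma_true <- g_raw * sqrt(cfg$r2_exposure / sum(v * g_raw^2))

  n_invalid <- round(cfg$prop_invalid * J)
  valid_mask <- rep(TRUE, J)
  if (n_invalid > 0) valid_mask[sample.int(J, n_invalid)] <- FALSE
  alpha <- numeric(J)
  alpha[!valid_mask] <- stats::rnorm(n_invalid, cfg$pleiotropy_mean,
                                     cfg$pleiotropy_sd)

  se_g <- 1 / sqrt(v * cfg$n_exposure)
  gamma_hat <- gamma_true + stats::rnorm(J, 0, se_g)
  # pleiotropic effects act on the exposure-increasing allele (the frame the
  # Egger intercept is defined in), so mu_alpha is directional after the
  # estimator orients instruments to non-negative exposure effects
  Gamma_true <- cfg$theta * gamma_true + sign(gamma_true) * alpha
  se_G <- 1 / sqrt(v * cfg$n_outcome)
  Gamma_hat <- Gamma_true + stats::rnorm(J, 0, se_G)

  exposure <- data.frame(
    trait_id = trait_id, snv_id = ids, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa, eaf = maf,
    beta = gamma_hat, se = se_g, pval = z_pval(gamma_hat, se_g),
    n = cfg$n_exposure, stringsAsFactors = FALSE
  )

  # outcome stored in the same frame, then randomly recoded
  eaf_out <- pmin(pmax(maf + stats::rnorm(J, 0, 0.002), 0.001), 0.999)
  outcome <- data.frame(
    trait_id = "outcome", snv_id = ids, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa, eaf = eaf_out,
    beta = Gamma_hat, se = se_G, pval = z_pval(Gamma_hat, se_G),
    n = cfg$n_outcome, stringsAsFactors = FALSE
  )

  recode_type <- rep("none", J)
  do_recode <- stats::runif(J) < cfg$recode_prob
  recode_type[do_recode] <- sample(c("swap", "flip", "both"),
                                   sum(do_recode), replace = TRUE)
  sw <- recode_type %in% c("swap", "both")
  fl <- recode_type %in% c("flip", "both")
  # allele swap: exchange EA/OA, flip beta sign, complement eaf
  tmp <- outcome$effect_allele[sw]
  outcome$effect_allele[sw] <- outcome$other_allele[sw]
  outcome$other_allele[sw] <- tmp
  outcome$beta[sw] <- -outcome$beta[sw]
  outcome$eaf[sw] <- 1 - outcome$eaf[sw]
  # strand complement: rename both alleles; effect direction and eaf refer to
  # the same (complemented) allele so beta and eaf are unchanged
  outcome$effect_allele[fl] <- unname(COMPLEMENT[outcome$effect_allele[fl]])
  outcome$other_allele[fl] <- unname(COMPLEMENT[outcome$other_allele[fl]])

  # within-block LD: every pair listed with r2 ~ U(0.2, 1)
  pair_a <- character(0); pair_b <- character(0)
  for (b in unique(block)) {
    members <- ids[block == b]
    if (length(members) >= 2L) {
      cmb <- utils::combn(members, 2L)
      pair_a <- c(pair_a, cmb[1, ]); pair_b <- c(pair_b, cmb[2, ])
    }
  }
  r2 <- if (length(pair_a)) stats::runif(length(pair_a), 0.2, 1) else numeric(0)
  ld <- ld_reference(
    pairs = data.frame(snp_a = pair_a, snp_b = pair_b, r2 = r2,
                       stringsAsFactors = FALSE),
    positions = data.frame(snv_id = ids, chrom = chrom, pos = pos,
                           stringsAsFactors = FALSE)
  )

  truth <- data.frame(
    snv_id = ids, gamma_true = gamma_true, alpha = alpha,
    valid_mask = valid_mask, gamma_hat = gamma_hat, Gamma_hat_pre = Gamma_hat,
    recode_type = recode_type, is_palindromic = is_pal, block = block,
    stringsAsFactors = FALSE
  )
  attr(truth, "theta") <- cfg$theta

  list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
}

#' Simulate a synthetic phenome for screen testing
#'
#' Generates a trait catalogue plus per-trait exposure/outcome/LD data with a
#' stated fraction of causal traits. The catalogue exercises every filtering
#' rule of the screen: `n_imaging`/`n_eqtl` flagged traits, `n_finn` traits
#' from the "finn" cohort, a mixture of `ukb`/`met-d`/`other` cohorts (which
#' drives outcome-version assignment), binary traits with case counts, and
#' `n_dup_groups` duplicate-label groups with differing sample sizes. Causal
#' status is assigned only to unflagged traits so ground truth survives
#' catalogue filtering. Per-trait seeds derive deterministically from
#' `base_config$seed`, so any single trait can be regenerated in isolation.
#'
#' @param n_traits Number of base traits.
#' @param prop_causal Fraction of base traits with `theta = theta_causal`.
#' @param base_config [sim_config()] template; per-trait seeds and `theta`
#'   are overridden.
#' @param theta_causal Causal effect (log-OR per SD) for causal traits.
#' @param n_dup_groups Number of duplicate-label groups (one smaller-n extra
#'   entry each).
#' @param n_imaging,n_eqtl,n_finn Number of traits flagged imaging / eQTL /
#'   "finn"-cohort.
#' @param prop_binary Fraction of traits marked binary (given `n_cases`).
#' @return List with `catalogue` (trait-metadata data.frame), `data` (named
#'   list of [simulate_trait_pair()] outputs per `trait_id`), and `truth`
#'   (data.frame `trait_id, label, theta, is_causal`).
#' @export
simulate_phenome <- function(n_traits, prop_causal = 0.05,
                             base_config = sim_config(),
                             theta_causal = log(2),
                             n_dup_groups = if (n_traits >= 10L) 2L else 0L,
                             n_imaging = if (n_traits >= 10L) 1L else 0L,
                             n_eqtl = if (n_traits >= 10L) 1L else 0L,
                             n_finn = if (n_traits >= 10L) 1L else 0L,
                             prop_binary = 0.3) {
  stopifnot(n_traits >= 1L)
  validate_sim_config(base_config)
  with_local_seed(base_config$seed, {
    n_causal <- round(prop_causal * n_traits)
    n_flag <- n_imaging + n_eqtl + n_finn
    stopifnot(n_flag + n_causal <= n_traits)

    trait_ids <- sprintf("t%04d", seq_len(n_traits))
    labels <- sprintf("trait %04d", seq_len(n_traits))
    perm <- sample.int(n_traits)
    flagged <- perm[seq_len(n_flag)]
    is_imaging <- seq_len(n_traits) %in% flagged[seq_len(n_imaging)]
    is_eqtl <- seq_len(n_traits) %in%
      flagged[n_imaging + seq_len(n_eqtl)]
    finn_idx <- flagged[n_imaging + n_eqtl + seq_len(n_finn)]
    causal <- perm[n_flag + seq_len(n_causal)]
    is_causal <- seq_len(n_traits) %in% causal

    cohort <- sample(c("ukb", "met-d", "other"), n_traits, replace = TRUE,
                     prob = c(0.3, 0.1, 0.6))
    cohort[finn_idx] <- "finn"
    is_binary <- stats::runif(n_traits) < prop_binary
    n_total <- round(stats::runif(n_traits, 2e4, 4e5))
    n_cases <- ifelse(is_binary,
                      pmax(500L, round(n_total * stats::runif(n_traits, 0.05, 0.4))),
                      NA_integer_)

    catalogue <- data.frame(
      trait_id = trait_ids, label = labels,
      population = "European", source_cohort = cohort,
      is_binary = is_binary, n_total = n_total, n_cases = n_cases,
      is_imaging = is_imaging, is_eqtl = is_eqtl,
      stringsAsFactors = FALSE
    )

    # duplicate groups: an extra smaller-n entry sharing an unflagged label
    dup_source <- setdiff(order(-n_total), c(flagged))
    dup_source <- dup_source[seq_len(min(n_dup_groups, length(dup_source)))]
    dup_rows <- lapply(seq_along(dup_source), function(i) {
      src <- dup_source[i]
      row <- catalogue[src, , drop = FALSE]
      row$trait_id <- sprintf("t%04d_dup", src)
      row$n_total <- round(row$n_total * stats::runif(1, 0.2, 0.8))
      if (!is.na(row$n_cases)) row$n_cases <- round(row$n_cases * 0.5)
      row
    })
    if (length(dup_rows)) catalogue <- rbind(catalogue, do.call(rbind, dup_rows))
    rownames(catalogue) <- NULL

    theta_vec <- ifelse(is_causal, theta_causal, 0)
    names(theta_vec) <- trait_ids
    dup_ids <- setdiff(catalogue$trait_id, trait_ids)
    theta_all <- c(theta_vec,
                   stats::setNames(theta_vec[sub("_dup$", "", dup_ids)], dup_ids))

    data <- lapply(seq_len(nrow(catalogue)), function(i) {
      tid <- catalogue$trait_id[i]
      cfg_i <- base_config
      cfg_i$theta <- unname(theta_all[tid])
      cfg_i$n_exposure <- catalogue$n_total[i]
      cfg_i$seed <- derive_seed(base_config$seed, i)
      simulate_trait_pair(cfg_i, trait_id = tid)
    })
    names(data) <- catalogue$trait_id

    truth <- data.frame(
      trait_id = catalogue$trait_id,
      label = catalogue$label,
      theta = unname(theta_all[catalogue$trait_id]),
      is_causal = unname(theta_all[catalogue$trait_id]) != 0,
      stringsAsFactors = FALSE
    )
    list(catalogue = catalogue, data = data, truth = truth)
  })
}

#' Simulate a rare-variant case/control cohort
#'
#' Emulates a gene's worth of rare variants with carrier counts in cases and
#' controls. Qualifying variants (missense, cohort and population MAF below
#' 0.001, REVEL above 0.25) jointly carry an odds ratio of `carrier_or` for
#' case status; all other variants are null. Carrier frequencies are small
#' enough that individuals carry at most one qualifying variant in
#' expectation, matching the collapsing assumption of the burden test.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param n_variants Number of variants (may be 0, giving an empty table).
#' @param carrier_or Odds ratio of qualifying-variant carriage, cases vs
#'   controls.
#' @param seed Integer seed.
#' @param base_carrier_freq Total qualifying-carrier frequency in controls.
#' @return `data.frame` with columns `variant_id, maf_cohort, maf_population,
#'   consequence, revel, carriers_cases, carriers_controls` and attribute
#'   `carrier_or`.
#' @export
simulate_burden_cohort <- function(n_cases, n_controls, n_variants,
                                   carrier_or = 1, seed = 1L,
                                   base_carrier_freq = 0.01) {
  stopifnot(n_cases >= 1L, n_controls >= 1L, n_variants >= 0L, carrier_or > 0)
  empty <- data.frame(variant_id = character(0), maf_cohort = numeric(0),
                      maf_population = numeric(0), consequence = character(0),
                      revel = numeric(0), carriers_cases = integer(0),
                      carriers_controls = integer(0), stringsAsFactors = FALSE)
  if (n_variants == 0L) return(structure(empty, carrier_or = carrier_or))
  with_local_seed(seed, {
    ids <- sprintf("var%04d", seq_len(n_variants))
    consequence <- sample(c("missense", "synonymous"), n_variants,
                          replace = TRUE, prob = c(0.6, 0.4))
    revel <- stats::runif(n_variants)
    # MAF mixture straddling the 0.001 qualifying threshold
    rare <- stats::runif(n_variants) < 0.7
    maf_cohort <- ifelse(rare, stats::runif(n_variants, 1e-5, 9e-4),
                         stats::runif(n_variants, 2e-3, 5e-2))
    maf_population <- pmin(pmax(maf_cohort * stats::runif(n_variants, 0.5, 1.5),
                                1e-6), 0.5)
    qual <- consequence == "missense" & maf_cohort < 0.001 &
      maf_population < 0.001 & revel > 0.25

    # control-side carrier probability per variant; qualifying variants share
    # base_carrier_freq, others use their own (possibly larger) MAF scale
    p0 <- numeric(n_variants)
    if (any(qual)) {
      w <- stats::runif(sum(qual), 0.5, 1.5)
      p0[qual] <- base_carrier_freq * w / sum(w)
    }
    p0[!qual] <- pmin(2 * maf_cohort[!qual], 0.1)
    odds0 <- p0 / (1 - p0)
    odds1 <- ifelse(qual, carrier_or, 1) * odds0
    p1 <- odds1 / (1 + odds1)

    out <- data.frame(
      variant_id = ids, maf_cohort = maf_cohort,
      maf_population = maf_population, consequence = consequence,
      revel = revel,
      carriers_cases = stats::rbinom(n_variants, n_cases, p1),
      carriers_controls = stats::rbinom(n_variants, n_controls, p0),
      stringsAsFactors = FALSE
    )
    structure(out, carrier_or = carrier_or)
  })
}
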