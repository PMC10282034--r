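make_catalogue <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    defaults <- list(trait_id = "t1", label = "trait", population = "European",
                     source_cohort = "other", is_binary = FALSE,
                     n_total = 1e5, n_cases = NA_integer_,
                     is_imaging = FALSE, is_eqtl = FALSE)
    defaults[names(r)] <- r
    as.data.frame(defaults, stringsAsFactors = FALSE)
  }))
}

test_that("catalogue filtering drops flagged traits and assigns outcome versions", {
  cat_df <- make_catalogue(
    list(trait_id = "t1", source_cohort = "finn"),
    list(trait_id = "t2", source_cohort = "ukb"),
    list(trait_id = "t3", source_cohort = "met-d"),
    list(trait_id = "t4", is_imaging = TRUE),
    list(trait_id = "t5", is_eqtl = TRUE),
    list(trait_id = "t6")
  )
  got <- filter_trait_catalogue(cat_df)
  expect_setequal(got$trait_id, c("t2", "t3", "t6"))
  expect_equal(got$outcome_version[got$trait_id == "t2"], "no_overlap_subset")
  expect_equal(got$outcome_version[got$trait_id == "t3"], "no_overlap_subset")
  expect_equal(got$outcome_version[got$trait_id == "t6"], "full")
  expect_equal(unname(attr(got, "counts")["excluded_finn"]), 1L)
})

test_that("duplicate-trait groups resolve by n, then F, then case count", {
  cat_df <- make_catalogue(
    list(trait_id = "a1", label = "A", n_total = 5e4),
    list(trait_id = "a2", label = "A", n_total = 2e4),
    list(trait_id = "b1", label = "B", n_total = 3e4),
    list(trait_id = "b2", label = "B", n_total = 3e4),
    list(trait_id = "c1", label = "C")
  )
  got <- deduplicate_traits(cat_df, f_stat = c(b1 = 12, b2 = 30))
  expect_setequal(got$trait_id, c("a1", "b2", "c1"))
  expect_setequal(attr(got, "duplicates_removed"), c("a2", "b1"))

  # binary tie resolves by case count
  cat_bin <- make_catalogue(
    list(trait_id = "d1", label = "D", is_binary = TRUE, n_total = 1e4,
         n_cases = 800L),
    list(trait_id = "d2", label = "D", is_binary = TRUE, n_total = 1e4,
         n_cases = 2000L)
  )
  expect_equal(deduplicate_traits(cat_bin)$trait_id, "d2")
})

test_that("BH adjustment matches the step-up oracle with screen-wide denominator", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03), m = 3), rep(0.03, 3))
  expect_equal(bh_fdr(0.04, m = 1), 0.04)
  expect_equal(bh_fdr(1e-10, m = 9661), 9661e-10)

  set.seed(3)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    p <- runif(n)
    m <- n + sample(0:20, 1)
    expect_equal(bh_fdr(p, m), oracle_bh(p, m), tolerance = 1e-14)
  }
  expect_error(bh_fdr(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.1, 0.2), m = 1), "at least")
})

test_that("the five-way criterion and its relaxations label traits correctly", {
  base <- data.frame(trait_id = c("sig", "fdr_only_egger", "loo_fail", "null",
                                  "failed"),
                     status = c("ok", "ok", "ok", "ok",
                                "insufficient_instruments"),
                     fdr_q_ivw = c(0.01, 0.01, 0.01, 0.5, NA),
                     weighted_median_pval = c(0.01, 0.01, 0.01, 0.5, NA),
                     weighted_mode_pval = c(0.02, 0.02, 0.02, 0.5, NA),
                     egger_pval = c(0.03, 0.3, 0.03, 0.5, NA),
                     loo_all_nominal = c(TRUE, TRUE, FALSE, TRUE, NA),
                     stringsAsFactors = FALSE)
  got <- call_significant(base, screen_config())
  expect_equal(got$call,
               c("significant", "ivw_fdr_only", "not_significant",
                 "not_significant", "not_significant"))
  expect_equal(got$significant, c(TRUE, FALSE, FALSE, FALSE, FALSE))

  # monotone: removing a criterion never shrinks the significant set
  relaxed <- base
  relaxed$egger_pval <- 0.001  # relax the failing Egger arm
  expect_gte(sum(call_significant(relaxed, screen_config())$significant),
             sum(got$significant))
})

test_that("empty results stay empty through the significance caller", {
  empty <- data.frame(trait_id = character(0), status = character(0),
                      fdr_q_ivw = numeric(0),
                      weighted_median_pval = numeric(0),
                      weighted_mode_pval = numeric(0),
                      egger_pval = numeric(0), loo_all_nominal = logical(0),
                      stringsAsFactors = FALSE)
  got <- call_significant(empty, screen_config())
  expect_equal(nrow(got), 0L)
})

test_that("effect sizes present ORs with the binary-exposure caveat", {
  f <- mr_fit_for_test(beta = 0, se = 0.1)
  expect_equal(format_effect(f)$or, 1)

  f2 <- mr_fit_for_test(beta = log(2.46), se = 0.1)
  expect_equal(format_effect(f2)$or, 2.46)

  f3 <- mr_fit_for_test(beta = 1.64, se = 0.2)
  got <- format_effect(f3, exposure_is_binary = TRUE)
  expect_equal(got$beta, 1.64)
  expect_equal(got$or, exp(1.64))
  expect_true(got$or_magnitude_caveat)
  expect_lt(got$ci_lower, got$or)
  expect_gt(got$ci_upper, got$or)
})

test_that("run_trait populates statuses along every degradation path", {
  cfg <- screen_config(n_boot = 50)
  # healthy causal trait
  sim <- simulate_trait_pair(sim_config(seed = 21, theta = log(2)))
  res <- run_trait(sim$exposure, sim$outcome, sim$ld, cfg, "tc", seed = 2)
  expect_equal(res$status, "ok")
  expect_true(all(c("ivw_mre", "ivw_fe", "egger", "weighted_median",
                    "weighted_mode") %in% names(res$fits)))
  expect_lt(res$fits$ivw_mre$pval, 0.05)
  expect_false(res$flags$weak_instruments)

  # too few strong SNVs anywhere on the ladder
  ex <- make_sumstats(sprintf("rs%d", 1:4), beta = 0.1, se = 0.01,
                      pval = rep(1e-9, 4))
  res2 <- run_trait(ex, ex, empty_ld(), cfg, "tweak", seed = 2)
  expect_equal(res2$status, "insufficient_instruments")
  expect_null(res2$fits)

  # determinism: identical seed, identical result
  res3 <- run_trait(sim$exposure, sim$outcome, sim$ld, cfg, "tc", seed = 2)
  expect_identical(screen_result_row(res3), screen_result_row(res))
})

test_that("a small screen runs end-to-end, reproducibly, with statuses populated", {
  ph <- simulate_phenome(12, prop_causal = 0.25,
                         base_config = sim_config(n_snv = 30, seed = 31),
                         n_dup_groups = 1, n_imaging = 1, n_eqtl = 1,
                         n_finn = 1)
  cfg <- screen_config(n_boot = 50, seed = 5)
  out <- run_screen(ph$data, ph$catalogue, cfg)

  expect_true(all(!is.na(out$results$status)))
  expect_true(all(out$results$call %in%
                    c("significant", "ivw_fdr_only", "not_significant")))
  # flagged traits never screened
  flagged <- ph$catalogue$trait_id[ph$catalogue$is_imaging |
                                     ph$catalogue$is_eqtl |
                                     ph$catalogue$source_cohort == "finn"]
  expect_false(any(flagged %in% out$results$trait_id))
  # the duplicate entry lost to its larger-n primary
  expect_true(all(!grepl("_dup$", out$results$trait_id)))
  expect_equal(out$m, nrow(out$results))

  out2 <- run_screen(ph$data, ph$catalogue, cfg)
  expect_identical(out$results, out2$results)

  # causal traits dominate the significant calls
  sig <- out$results$trait_id[out$results$significant]
  truth <- ph$truth$is_causal[match(out$results$trait_id, ph$truth$trait_id)]
  expect_gte(sum(out$results$significant & truth), 1L)
})
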