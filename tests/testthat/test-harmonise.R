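test_that("palindromic allele pairs are exactly {A,T} and {C,G}", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("T", "C"))
  expect_error(is_palindromic("A", "N"), "A, C, G, T")
})

test_that("outcome rows are aligned to the exposure effect allele", {
  ex <- make_sumstats(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.1, 0.1),
                      se = 0.01, ea = c("A", "A", "A"), oa = c("G", "G", "G"))
  ou <- ex
  ou$trait_id <- "out"
  ou$beta <- c(0.2, 0.2, 0.2)
  # rs1 aligned; rs2 swapped; rs3 strand-complemented
  ou$effect_allele[2] <- "G"; ou$other_allele[2] <- "A"
  ou$beta[2] <- 0.2; ou$eaf[2] <- 0.7
  ou$effect_allele[3] <- "T"; ou$other_allele[3] <- "C"
  h <- harmonise_pair(ex, ou)
  expect_equal(nrow(h), 3L)
  expect_equal(h$Gamma, c(0.2, -0.2, 0.2))
  expect_equal(h$effect_allele, rep("A", 3))
})

test_that("palindromic SNVs follow the MAF ceiling and frequency-side rule", {
  ex <- make_sumstats(c("p1", "p2", "p3"), beta = 0.1, se = 0.01,
                      ea = "A", oa = "T", eaf = c(0.45, 0.10, 0.10))
  ou <- ex
  ou$beta <- 0.3
  ou$eaf <- c(0.45, 0.12, 0.88)
  h <- harmonise_pair(ex, ou)
  # p1: MAF 0.45 > 0.42 in both -> dropped
  expect_false("p1" %in% h$snv_id)
  expect_equal(attr(h, "dropped")$reason[attr(h, "dropped")$snv_id == "p1"],
               "dropped_palindromic_maf")
  # p2: same frequency side -> sign kept
  expect_equal(h$Gamma[h$snv_id == "p2"], 0.3)
  # p3: opposite sides -> sign flipped
  expect_equal(h$Gamma[h$snv_id == "p3"], -0.3)

  # missing eaf on either side drops a palindromic SNV
  ex$eaf[2] <- NA
  h2 <- harmonise_pair(ex, ou)
  expect_equal(attr(h2, "dropped")$reason[attr(h2, "dropped")$snv_id == "p2"],
               "dropped_palindromic_no_eaf")
})

test_that("unreconcilable alleles and empty intersections carry status, not errors", {
  ex <- make_sumstats("rs1", 0.1, 0.01, ea = "A", oa = "G")
  ou <- make_sumstats("rs1", 0.2, 0.01, ea = "A", oa = "C")
  h <- harmonise_pair(ex, ou)
  expect_equal(nrow(h), 0L)
  expect_equal(attr(h, "dropped")$reason, "dropped_unreconcilable")

  ou2 <- make_sumstats("rsX", 0.2, 0.01)
  h2 <- harmonise_pair(ex, ou2)
  expect_equal(nrow(h2), 0L)
  expect_equal(attr(h2, "status"), "empty_intersection")
})

test_that("harmonisation recovers generator pre-recoding effects (round trip)", {
  for (seed in c(3, 14, 25)) {
    sim <- simulate_trait_pair(sim_config(n_snv = 60, seed = seed,
                                          recode_prob = 0.6, theta = 0.1))
    h <- harmonise_pair(sim$exposure, sim$outcome)
    tr <- sim$truth
    m <- match(h$snv_id, tr$snv_id)
    np <- !tr$is_palindromic[m]
    expect_identical(h$Gamma[np], tr$Gamma_hat_pre[m][np])
    # every SNV is either retained or accounted for in the drop log
    expect_setequal(c(h$snv_id, attr(h, "dropped")$snv_id), tr$snv_id)
    # no high-MAF palindromic SNV survives
    maf <- pmin(h$eaf, 1 - h$eaf)
    pal <- is_palindromic(h$effect_allele, h$other_allele)
    expect_true(all(maf[pal] <= 0.42))
  }
})

test_that("harmonisation output is a fixed point", {
  sim <- simulate_trait_pair(sim_config(n_snv = 30, seed = 8, recode_prob = 0.5))
  h <- harmonise_pair(sim$exposure, sim$outcome)
  # re-express the harmonised set as exposure/outcome tables and re-harmonise
  ex2 <- make_sumstats(h$snv_id, h$gamma, h$se_gamma, pval = h$p_exposure,
                       chrom = h$chrom, pos = h$pos, ea = h$effect_allele,
                       oa = h$other_allele, eaf = h$eaf)
  ou2 <- make_sumstats(h$snv_id, h$Gamma, h$se_Gamma, pval = h$p_outcome,
                       chrom = h$chrom, pos = h$pos, ea = h$effect_allele,
                       oa = h$other_allele, eaf = h$eaf)
  h2 <- harmonise_pair(ex2, ou2)
  expect_equal(h2$Gamma, h$Gamma)
  expect_equal(h2$gamma, h$gamma)
  expect_equal(h2$snv_id, h$snv_id)
})

test_that("proxy search honours the r2 floor and deterministic tie-breaks", {
  pos <- data.frame(snv_id = c("miss", "a", "b", "c", "d"), chrom = "1",
                    pos = c(1000L, 11000L, 51000L, 2000L, 3000L))
  mk <- function(pairs) ld_reference(pairs, pos)
  ids_all <- c("a", "b", "c", "d")

  ld <- mk(data.frame(snp_a = "miss", snp_b = c("a", "b"), r2 = c(0.95, 0.91)))
  expect_equal(find_proxy("miss", ids_all, ids_all, ld), "a")

  ld2 <- mk(data.frame(snp_a = "miss", snp_b = "a", r2 = 0.85))
  expect_true(is.na(find_proxy("miss", ids_all, ids_all, ld2)))

  # equal r2: nearer SNV wins (a at 10 kb vs b at 50 kb)
  ld3 <- mk(data.frame(snp_a = "miss", snp_b = c("a", "b"), r2 = c(0.95, 0.95)))
  expect_equal(find_proxy("miss", ids_all, ids_all, ld3), "a")

  # equal r2 and distance: lexicographic id (c at 1 kb vs d at 2 kb -> c wins
  # on distance; make distances equal via positions c=2000, d wins only if id)
  ld4 <- mk(data.frame(snp_a = "miss", snp_b = c("c", "d"), r2 = c(0.95, 0.95)))
  expect_equal(find_proxy("miss", ids_all, ids_all, ld4), "c")

  # candidate must be present in both datasets
  expect_true(is.na(find_proxy("miss", "b", "a", ld)))
  expect_equal(find_proxy("miss", c("a", "b"), c("a", "b"), ld), "a")
})

test_that("proxy substitution replaces missing instruments with the proxy's own rows", {
  ex <- make_sumstats(c("i1", "i2", "px"), beta = c(0.3, 0.2, 0.28),
                      se = 0.01, pos = c(1e6, 2e6, 1.01e6))
  inst <- ex[1:2, ]
  ld <- ld_reference(data.frame(snp_a = "i1", snp_b = "px", r2 = 0.95),
                     data.frame(snv_id = ex$snv_id, chrom = "1", pos = ex$pos))
  out_ids <- c("i2", "px")
  got <- substitute_proxies(inst, ex, out_ids, ld)
  expect_setequal(got$snv_id, c("px", "i2"))
  expect_true(got$proxy_used[got$snv_id == "px"])
  expect_equal(got$proxy_source[got$snv_id == "px"], "i1")
  expect_equal(got$beta[got$snv_id == "px"], 0.28)

  # no proxy available -> instrument dropped with reason
  got2 <- substitute_proxies(inst, ex, "i2", ld)
  expect_equal(attr(got2, "dropped_no_proxy"), "i1")
  expect_equal(got2$snv_id, "i2")
})

test_that("clumping applies the r2/window rule greedily by p-value", {
  mkrec <- function(ids, pos, pval) {
    make_sumstats(ids, beta = 0.1, se = 0.01, pval = pval, pos = pos)
  }
  ld <- function(r2) ld_reference(
    data.frame(snp_a = "s1", snp_b = "s2", r2 = r2),
    data.frame(snv_id = c("s1", "s2"), chrom = "1", pos = c(1e6, 1e6 + 5e6))
  )
  # 5,000 kb apart, r2 0.5: only the smaller p retained
  rec <- mkrec(c("s1", "s2"), c(1e6, 1e6 + 5e6), c(1e-12, 1e-8))
  got <- clump(rec, ld(0.5))
  expect_equal(got$snv_id, "s1")
  expect_equal(attr(got, "dropped")$reason, "dropped_ld_prune")

  # 12,000 kb apart: outside the window, both retained
  rec2 <- mkrec(c("s1", "s2"), c(1e6, 1e6 + 1.2e7), c(1e-12, 1e-8))
  ld2 <- ld_reference(data.frame(snp_a = "s1", snp_b = "s2", r2 = 0.5),
                      data.frame(snv_id = c("s1", "s2"), chrom = "1",
                                 pos = c(1e6, 1e6 + 1.2e7)))
  expect_equal(nrow(clump(rec2, ld2)), 2L)

  # single SNV is retained unchanged
  expect_equal(clump(rec[1, ], ld(0.5))$snv_id, "s1")

  # missing position excluded with reason
  rec3 <- rec; rec3$pos[2] <- NA
  got3 <- clump(rec3, ld(0.5))
  expect_equal(attr(got3, "dropped")$reason, "dropped_no_position")
})

test_that("clumping is idempotent and output is pairwise independent", {
  for (seed in c(2, 9)) {
    sim <- simulate_trait_pair(sim_config(n_snv = 40, n_blocks = 8,
                                          seed = seed))
    c1 <- clump(sim$exposure, sim$ld)
    c2 <- clump(c1, sim$ld)
    expect_equal(c2$snv_id, c1$snv_id)
    ids <- c1$snv_id
    if (length(ids) >= 2) {
      prs <- combn(seq_along(ids), 2)
      for (k in seq_len(ncol(prs))) {
        i <- prs[1, k]; j <- prs[2, k]
        same_chr <- c1$chrom[i] == c1$chrom[j]
        close_by <- same_chr && abs(c1$pos[i] - c1$pos[j]) <= 1e7
        if (close_by) expect_lte(ld_r2(sim$ld, ids[i], ids[j]), 0.001)
      }
    }
  }
})
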