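# Shared fixtures and independent oracles used across the suite.

# Minimal harmonised instrument table from raw vectors.
make_hset <- function(gamma, Gamma, se_Gamma, se_gamma = rep(0.01, length(gamma)),
                      p_exposure = NULL, p_outcome = NULL,
                      ids = sprintf("rs%03d", seq_along(gamma))) {
  data.frame(
    snv_id = ids, chrom = "1", pos = seq_along(gamma) * 1000L,
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    gamma = gamma, se_gamma = se_gamma,
    p_exposure = p_exposure %||% 2 * pnorm(-abs(gamma / se_gamma)),
    Gamma = Gamma, se_Gamma = se_Gamma,
    p_outcome = p_outcome %||% 2 * pnorm(-abs(Gamma / se_Gamma)),
    proxy_used = FALSE, proxy_source = NA_character_,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Summary-statistic data.frame in the canonical in-memory schema.
make_sumstats <- function(ids, beta, se, pval = 2 * pnorm(-abs(beta / se)),
                          chrom = "1", pos = seq_along(ids) * 1e6,
                          ea = "A", oa = "G", eaf = 0.3, n = 1e5,
                          trait_id = "tx") {
  data.frame(trait_id = trait_id, snv_id = ids,
             chrom = rep_len(chrom, length(ids)),
             pos = as.integer(rep_len(pos, length(ids))),
             effect_allele = rep_len(ea, length(ids)),
             other_allele = rep_len(oa, length(ids)),
             eaf = rep_len(eaf, length(ids)),
             beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}

# Write a canonical summary-statistic TSV and return its path.
write_sumstat_file <- function(df, path = tempfile(fileext = ".tsv")) {
  hdr <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  out <- data.frame(SNP = df$snv_id, CHR = df$chrom, POS = df$pos,
                    EA = df$effect_allele, OA = df$other_allele,
                    EAF = df$eaf, BETA = df$beta, SE = df$se, P = df$pval,
                    N = df$n)
  names(out) <- hdr
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}

empty_ld <- function(positions = data.frame(snv_id = character(0),
                                            chrom = character(0),
                                            pos = integer(0))) {
  ld_reference(pairs = data.frame(snp_a = character(0), snp_b = character(0),
                                  r2 = numeric(0)),
               positions = positions)
}

# ---- independent oracles ------------------------------------------------

# Generalized-least-squares oracle for IVW (no intercept) and Egger (with
# intercept), via R's QR-based weighted fitter — independent of the
# closed-form implementation under test.
oracle_ivw <- function(g, G, se_G) {
  fit <- lm.wfit(x = matrix(g, ncol = 1), y = G, w = 1 / se_G^2)
  unname(fit$coefficients[1])
}

oracle_egger <- function(g, G, se_G) {
  flip <- ifelse(g < 0, -1, 1)
  fit <- lm.wfit(x = cbind(1, g * flip), y = G * flip, w = 1 / se_G^2)
  unname(fit$coefficients)
}

oracle_q <- function(g, G, se_G, beta) sum(((G - beta * g) / se_G)^2)

# Brute-force BH step-up with denominator m.
oracle_bh <- function(p, m) {
  n <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(ord)]
}

# Full-enumeration two-sided Fisher p-value over all tables with the
# observed margins, using exact log-factorial table probabilities.
oracle_fisher_p <- function(a, b, c, d) {
  K <- a + b; n1 <- a + c; N <- a + b + c + d
  lo <- max(0, K - (N - n1)); hi <- min(K, n1)
  logp <- function(x) {
    lchoose(n1, x) + lchoose(N - n1, K - x) - lchoose(N, K)
  }
  probs <- exp(sapply(lo:hi, logp))
  p_obs <- exp(logp(a))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A bare mr_fit-like object for presentation tests.
mr_fit_for_test <- function(beta, se) {
  structure(list(method = "ivw_mre", beta = beta, se = se,
                 pval = 2 * pnorm(-abs(beta / se)), n_snv = 10L),
            class = "mr_fit")
}
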