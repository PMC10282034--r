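# Two-sample MR estimators and diagnostics: Wald ratios, IVW (fixed and
# multiplicative random effects), MR-Egger with intercept test and I2_GX,
# weighted median, weighted mode, radial outlier detection, Cochran's Q and
# leave-one-out.
#
# Throughout, gamma / se_gamma are the instrument-exposure effects and
# Gamma / se_Gamma the instrument-outcome effects of a harmonised set, all
# signed to the same effect allele.

#' @keywords internal
#' @noRd
mr_fit <- function(method, beta, se, pval, n_snv, ...) {
  structure(c(list(method = method, beta = beta, se = se, pval = pval,
                   n_snv = n_snv), list(...)), class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("MR fit [%s]: beta = %.4g (SE %.4g), p = %.3g, nSNV = %d\n",
              x$method, x$beta, x$se, x$pval, x$n_snv))
  invisible(x)
}

#' @keywords internal
#' @noRd
check_n_snv <- function(set, min, method) {
  if (nrow(set) < min) {
    stop("insufficient instruments for ", method, ": ", nrow(set),
         " SNV(s), need at least ", min, call. = FALSE)
  }
}

#' Per-variant Wald ratios
#'
#' `beta_j = Gamma_j / gamma_j` with first-order standard error
#' `se_j = se_Gamma_j / |gamma_j|`. Variants with `gamma_j = 0` are excluded
#' with a reason code since their ratio is undefined.
#'
#' @param set Harmonised instrument table.
#' @return `data.frame` with `snv_id, ratio, se, weight` (inverse-variance,
#'   unnormalised) and attribute `excluded_zero_gamma`.
#' @export
wald_ratios <- function(set) {
  zero <- set$gamma == 0
  s <- set[!zero, , drop = FALSE]
  out <- data.frame(snv_id = s$snv_id,
                    ratio = s$Gamma / s$gamma,
                    se = s$se_Gamma / abs(s$gamma),
                    stringsAsFactors = FALSE)
  out$weight <- 1 / out$se^2
  attr(out, "excluded_zero_gamma") <- set$snv_id[zero]
  out
}

#' Inverse-variance-weighted estimator
#'
#' Weighted regression of the outcome effects on the exposure effects
#' through the origin with weights `1/se_Gamma^2`. The fixed-effects (FE)
#' standard error is `(sum gamma^2 / se_Gamma^2)^(-1/2)`; the multiplicative
#' random effects (MRE) variant inflates it by the residual scale
#' `sigma_hat = sqrt(Q / (n_snv - 1))`, bounded below at 1 so it never
#' deflates below FE. P-values are two-sided normal.
#'
#' @param set Harmonised instrument table (at least 2 SNVs; a single SNV is
#'   handled by [mr_wald_single()]).
#' @param mode `"mre"` (default) or `"fe"`.
#' @return An `mr_fit` with extras `sigma_hat`, `q`, `q_df`, `q_pval`.
#' @export
mr_ivw <- function(set, mode = c("mre", "fe")) {
  mode <- match.arg(mode)
  check_n_snv(set, 2L, "IVW")
  w <- 1 / set$se_Gamma^2
  sw_g2 <- sum(w * set$gamma^2)
  beta <- sum(w * set$gamma * set$Gamma) / sw_g2
  se_fe <- 1 / sqrt(sw_g2)
  q <- sum(w * (set$Gamma - beta * set$gamma)^2)
  df <- nrow(set) - 1L
  sigma_hat <- sqrt(q / df)
  se <- if (mode == "mre") se_fe * max(1, sigma_hat) else se_fe
  mr_fit(paste0("ivw_", mode), beta, se, z_pval(beta, se), nrow(set),
         sigma_hat = sigma_hat, q = q, q_df = df,
         q_pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Single-instrument Wald fallback
#'
#' @param set Harmonised table with exactly one SNV.
#' @return An `mr_fit` labelled `wald_ratio`; such fits are ineligible for
#'   the five-way significance call (no Egger/median/mode available).
#' @export
mr_wald_single <- function(set) {
  stopifnot(nrow(set) == 1L)
  beta <- set$Gamma / set$gamma
  se <- set$se_Gamma / abs(set$gamma)
  mr_fit("wald_ratio", beta, se, z_pval(beta, se), 1L)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum((Gamma_j - beta_hat * gamma_j)^2 / se_Gamma_j^2)` with a
#' chi-square reference on `n_snv - 1` degrees of freedom. Inflated Q signals
#' heterogeneity among variant-specific causal estimates, an indicator of
#' horizontal pleiotropy.
#'
#' @param set Harmonised instrument table.
#' @param beta_hat Causal estimate the residuals are taken about (typically
#'   the IVW estimate).
#' @return List `q, q_df, q_pval`.
#' @export
cochran_q <- function(set, beta_hat) {
  check_n_snv(set, 2L, "Cochran's Q")
  q <- sum((set$Gamma - beta_hat * set$gamma)^2 / set$se_Gamma^2)
  df <- nrow(set) - 1L
  list(q = q, q_df = df, q_pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects WITH an intercept,
#' after orienting every SNV so its exposure effect is non-negative (both
#' signs flipped together). The intercept estimates the average directional
#' pleiotropic effect; under InSIDE the slope remains a consistent causal
#' estimate. The residual scale is bounded below at 1 and multiplies both
#' standard errors; p-values use a t reference with `n_snv - 2` degrees of
#' freedom. `I2_GX = (Q_GX - (n_snv - 1)) / Q_GX` measures regression
#' dilution from exposure-side measurement error (NOME violation); values
#' below 0.9 — or an undefined `Q_GX = 0` — raise `egger_nome_warning`.
#'
#' @param set Harmonised instrument table (at least 3 SNVs).
#' @return An `mr_fit` with extras `intercept, intercept_se, intercept_pval,
#'   i2_gx, egger_nome_warning, sigma_hat, q, q_df`.
#' @export
mr_egger <- function(set) {
  check_n_snv(set, 3L, "MR-Egger")
  flip <- sign(set$gamma)
  flip[flip == 0] <- 1
  g <- set$gamma * flip
  G <- set$Gamma * flip
  w <- 1 / set$se_Gamma^2
  X <- cbind(1, g)
  XtWX <- crossprod(X, w * X)
  df <- nrow(set) - 2L

  wg <- 1 / set$se_gamma^2
  gbar <- sum(wg * g) / sum(wg)
  q_gx <- sum(wg * (g - gbar)^2)
  i2_gx <- if (q_gx > 0) (q_gx - (nrow(set) - 1L)) / q_gx else NA_real_
  nome_warn <- is.na(i2_gx) || i2_gx < 0.9

  if (rcond(XtWX) < 1e-12) {
    # constant exposure effects: intercept and slope are not separable
    return(mr_fit("egger", beta = NA_real_, se = NA_real_, pval = NA_real_,
                  n_snv = nrow(set), intercept = NA_real_,
                  intercept_se = NA_real_, intercept_pval = NA_real_,
                  i2_gx = i2_gx, egger_nome_warning = TRUE,
                  sigma_hat = NA_real_, q = NA_real_, q_df = df,
                  status = "degenerate_design"))
  }
  coef <- as.numeric(solve(XtWX, crossprod(X, w * G)))
  resid <- G - as.numeric(X %*% coef)
  q <- sum(w * resid^2)
  sigma_hat <- sqrt(q / df)
  scale <- max(1, sigma_hat)
  ses <- sqrt(diag(solve(XtWX))) * scale
  tstat <- coef / ses
  pvals <- pmax(2 * stats::pt(-abs(tstat), df), .Machine$double.xmin)

  mr_fit("egger", beta = coef[2], se = unname(ses[2]),
         pval = pvals[2], n_snv = nrow(set),
         intercept = coef[1], intercept_se = unname(ses[1]),
         intercept_pval = pvals[1], i2_gx = i2_gx,
         egger_nome_warning = nome_warn, sigma_hat = sigma_hat,
         q = q, q_df = df)
}

# Weighted median of values b with weights w: order by b, form standardised
# cumulative weights s_j = (cumsum(w) - w/2) / sum(w), interpolate b across
# s at 0.5.
#' @keywords internal
#' @noRd
weighted_median_value <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  stats::approx(s, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' Median of the inverse-variance-weighted empirical distribution of the
#' per-variant Wald ratios; consistent when instruments carrying more than
#' half the weight are valid, and robust to outlying variants. The standard
#' error comes from a parametric bootstrap: each replicate redraws
#' `ratio_j* ~ N(ratio_j, se_j)` and recomputes the weighted median; the SE
#' is the standard deviation over replicates.
#'
#' @param set Harmonised instrument table (at least 3 SNVs).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap (local RNG stream).
#' @return An `mr_fit` with extra `n_boot`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000L, seed = 1L) {
  check_n_snv(set, 3L, "weighted median")
  wr <- wald_ratios(set)
  est <- weighted_median_value(wr$ratio, wr$weight)
  se <- with_local_seed(seed, {
    J <- nrow(wr)
    draws <- matrix(stats::rnorm(J * n_boot, wr$ratio, wr$se), nrow = J)
    stats::sd(apply(draws, 2, weighted_median_value, w = wr$weight))
  })
  mr_fit("weighted_median", est, se, z_pval(est, se), nrow(set),
         n_boot = n_boot)
}

# Mode of a weighted kernel-smoothed density of b (normal kernel, bandwidth
# h), located on a 512-point grid spanning the data plus 3 bandwidths.
#' @keywords internal
#' @noRd
weighted_mode_value <- function(b, w, h) {
  if (max(b) - min(b) <= .Machine$double.eps * max(1, abs(b[1]))) return(b[1])
  d <- stats::density(b, weights = w / sum(w), bw = h, kernel = "gaussian",
                      n = 512L, from = min(b) - 3 * h, to = max(b) + 3 * h)
  d$x[which.max(d$y)]
}

# Bandwidth: a normal-consistent scale estimate built from the median
# absolute pairwise deviation of the ratios.
#' @keywords internal
#' @noRd
mode_bandwidth <- function(b, bandwidth_factor) {
  pd <- abs(as.numeric(stats::dist(b)))
  s <- 1.4826 * stats::median(pd) / sqrt(2)
  if (!is.finite(s) || s <= 0) s <- stats::mad(b)
  if (s <= 0) s <- 1e-8
  bandwidth_factor * s
}

# Batched mode extraction for the bootstrap: every replicate (column of
# `draws`) is linearly binned onto one shared 512-point grid and smoothed
# with its own Gaussian bandwidth through a single mvfft pass — the same
# binned-KDE algorithm stats::density uses, vectorised across replicates.
#' @keywords internal
#' @noRd
batch_weighted_modes <- function(draws, w, bandwidth_factor) {
  J <- nrow(draws); B <- ncol(draws)
  w <- w / sum(w)
  pair_i <- utils::combn(J, 2L)
  pd <- abs(draws[pair_i[1, ], , drop = FALSE] -
              draws[pair_i[2, ], , drop = FALSE])
  h <- bandwidth_factor * 1.4826 *
    apply(pd, 2, stats::median) / sqrt(2)
  h[!is.finite(h) | h <= 0] <- 1e-8

  n <- 512L; L <- 2L * n
  lo <- min(draws) - 3 * max(h)
  up <- max(draws) + 3 * max(h)
  dx <- (up - lo) / (n - 1L)
  # linear binning of each replicate's weighted ratios
  pos <- (draws - lo) / dx
  i0 <- pmin(pmax(floor(pos), 0), n - 1L)
  frac <- pos - i0
  y <- matrix(0, L, B)
  colix <- rep(seq_len(B), each = J)
  idx1 <- as.integer(i0) + 1L + (colix - 1L) * L
  idx2 <- pmin(as.integer(i0) + 2L, n) + (colix - 1L) * L
  wrep <- rep(w, times = B)
  y[idx1] <- y[idx1] + wrep * (1 - as.numeric(frac))
  y[idx2] <- y[idx2] + wrep * as.numeric(frac)
  # Gaussian smoothing in the frequency domain, one column per replicate
  kseq <- c(0:(L / 2L), -(L / 2L - 1L):-1L)
  omega <- 2 * pi * kseq / (L * dx)
  damp <- exp(-0.5 * outer(omega^2, h^2))
  sm <- Re(stats::mvfft(stats::mvfft(y) * damp, inverse = TRUE)) / L
  grid <- lo + (0:(n - 1L)) * dx
  flat <- apply(draws, 2, function(b)
    max(b) - min(b) <= .Machine$double.eps * max(1, abs(b[1])))
  out <- grid[max.col(t(sm[seq_len(n), , drop = FALSE]), "first")]
  out[flat] <- draws[1, flat]
  out
}

#' Weighted-mode estimator
#'
#' Kernel-smoothed weighted density of the per-variant Wald ratios; the
#' estimate is the density argmax. Consistent under plurality validity: the
#' largest group of instruments sharing a ratio identifies the causal
#' effect, even if most instruments are invalid. Bootstrap SE as in
#' [mr_weighted_median()].
#'
#' @param set Harmonised instrument table (at least 3 SNVs).
#' @param bandwidth_factor Multiplier on the pairwise-deviation bandwidth
#'   (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return An `mr_fit` with extras `bandwidth`, `n_boot`.
#' @export
mr_weighted_mode <- function(set, bandwidth_factor = 1, n_boot = 1000L,
                             seed = 1L) {
  check_n_snv(set, 3L, "weighted mode")
  wr <- wald_ratios(set)
  w <- wr$weight / sum(wr$weight)
  h <- mode_bandwidth(wr$ratio, bandwidth_factor)
  est <- weighted_mode_value(wr$ratio, w, h)
  se <- with_local_seed(seed, {
    J <- nrow(wr)
    draws <- matrix(stats::rnorm(J * n_boot, wr$ratio, wr$se), nrow = J)
    stats::sd(batch_weighted_modes(draws, w, bandwidth_factor))
  })
  mr_fit("weighted_mode", est, se, z_pval(est, se), nrow(set),
         bandwidth = h, n_boot = n_boot)
}

# One radial IVW fit with modified second-order weights, iterated from the
# first-order IVW estimate until the estimate moves by less than 1e-8.
#' @keywords internal
#' @noRd
radial_fit <- function(gamma, Gamma, se_gamma, se_Gamma) {
  ratio <- Gamma / gamma
  w <- gamma^2 / se_Gamma^2
  beta <- sum(w * ratio) / sum(w)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(100L)) {
    iterations <- it
    w <- gamma^2 / (se_Gamma^2 + beta^2 * se_gamma^2)
    beta_new <- sum(w * ratio) / sum(w)
    if (abs(beta_new - beta) < 1e-8) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  w <- gamma^2 / (se_Gamma^2 + beta^2 * se_gamma^2)
  list(beta = beta, q_contrib = w * (ratio - beta)^2,
       converged = converged, iterations = iterations)
}

#' Radial MR outlier detection
#'
#' Radial IVW with modified second-order weights
#' `w_j = gamma_j^2 / (se_Gamma_j^2 + beta_hat^2 se_gamma_j^2)`, started
#' from the first-order IVW estimate and refitted until the estimate moves
#' by less than 1e-8 (at most 100 iterations). Each variant's contribution
#' to the radial Q, `Q_j = w_j (ratio_j - beta_radial)^2`, is referred to a
#' chi-square(1) upper tail. Outliers are removed greedily one at a time
#' (worst contribution first, while its tail probability is below `alpha`)
#' with the radial fit recomputed after each removal, so a gross outlier
#' cannot drag the reference estimate and implicate clean variants. Used
#' for outlier identification only, not as a causal estimator.
#'
#' @param set Harmonised instrument table (at least 3 SNVs).
#' @param alpha Per-variant flagging level; `0.05 / n_snv` gives the
#'   Bonferroni variant. `alpha = 0` never flags.
#' @return List: `outliers` (ids, in removal order), `beta` (radial estimate
#'   on the retained variants), `q_radial`, `q_contrib` (per retained
#'   variant), `converged`, `iterations`.
#' @export
radial_outliers <- function(set, alpha = 0.05) {
  check_n_snv(set, 3L, "radial MR")
  keep <- seq_len(nrow(set))
  outliers <- character(0)
  repeat {
    s <- set[keep, , drop = FALSE]
    fit <- radial_fit(s$gamma, s$Gamma, s$se_gamma, s$se_Gamma)
    pj <- stats::pchisq(fit$q_contrib, 1L, lower.tail = FALSE)
    worst <- which.min(pj)
    if (pj[worst] < alpha && length(keep) > 3L) {
      outliers <- c(outliers, s$snv_id[worst])
      keep <- keep[-worst]
    } else break
  }
  if (!fit$converged) warning("radial MR did not converge after 100 ",
                              "iterations; using last iterate")
  list(outliers = outliers, beta = fit$beta,
       q_radial = sum(fit$q_contrib),
       q_contrib = stats::setNames(fit$q_contrib, set$snv_id[keep]),
       converged = fit$converged, iterations = fit$iterations)
}

#' Leave-one-out IVW analysis
#'
#' Refits the MRE IVW estimator `n_snv` times, omitting one variant each
#' time, to check whether any single variant drives the result.
#'
#' @param set Harmonised instrument table (at least 3 SNVs).
#' @return `data.frame` with `omitted, beta, se, pval` and attribute
#'   `loo_all_nominal` (TRUE when every omission keeps `p < 0.05`).
#' @export
leave_one_out <- function(set) {
  check_n_snv(set, 3L, "leave-one-out")
  fits <- lapply(seq_len(nrow(set)), function(j) {
    f <- mr_ivw(set[-j, , drop = FALSE], mode = "mre")
    data.frame(omitted = set$snv_id[j], beta = f$beta, se = f$se,
               pval = f$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  attr(out, "loo_all_nominal") <- all(out$pval < 0.05)
  out
}

#' Run the full estimator battery
#'
#' @param set Harmonised instrument table.
#' @param n_boot Bootstrap replicates for median/mode.
#' @param seed Integer seed for the bootstraps.
#' @param bandwidth_factor Weighted-mode bandwidth multiplier.
#' @return Named list of `mr_fit` objects (`ivw_mre, ivw_fe, egger,
#'   weighted_median, weighted_mode`) plus `diagnostics` (Cochran's Q about
#'   the MRE IVW estimate and the leave-one-out table).
#' @export
mr_all <- function(set, n_boot = 1000L, seed = 1L, bandwidth_factor = 1) {
  ivw_mre <- mr_ivw(set, "mre")
  list(
    ivw_mre = ivw_mre,
    ivw_fe = mr_ivw(set, "fe"),
    egger = mr_egger(set),
    weighted_median = mr_weighted_median(set, n_boot, seed),
    weighted_mode = mr_weighted_mode(set, bandwidth_factor, n_boot,
                                     seed + 1L),
    diagnostics = c(cochran_q(set, ivw_mre$beta), list(loo = leave_one_out(set)))
  )
}
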