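# Multivariable MR: joint instrument pooling with automated threshold
# relaxation, multivariable IVW, conditional F statistics and adjusted
# Cochran's Q under configurable phenotypic correlation between the
# exposure samples.

#' Construct a multivariable MR input
#'
#' @param gamma J x K matrix of instrument effects on the K exposures.
#' @param se_gamma J x K matrix of their standard errors (all positive).
#' @param Gamma,se_Gamma Outcome effects and standard errors (length J).
#' @param rho Assumed phenotypic correlation between the exposure samples,
#'   applied pairwise between overlapping-cohort exposures; use 0 for
#'   non-overlapping cohorts. The conventional sensitivity pair is
#'   `c(0.1, 0.9)`.
#' @param snv_id Optional identifiers.
#' @return An `mvmr_input` list.
#' @export
mvmr_input <- function(gamma, se_gamma, Gamma, se_Gamma, rho = 0,
                       snv_id = NULL) {
  gamma <- as.matrix(gamma); se_gamma <- as.matrix(se_gamma)
  stopifnot(ncol(gamma) >= 2L, all(dim(gamma) == dim(se_gamma)),
            nrow(gamma) == length(Gamma), length(Gamma) == length(se_Gamma),
            all(se_gamma > 0), all(se_Gamma > 0),
            rho >= -1, rho <= 1)
  structure(list(gamma = gamma, se_gamma = se_gamma,
                 Gamma = as.numeric(Gamma), se_Gamma = as.numeric(se_Gamma),
                 rho = rho,
                 snv_id = snv_id %||% sprintf("snv%04d", seq_along(Gamma))),
            class = "mvmr_input")
}

#' Multivariable IVW estimator
#'
#' Weighted multiple regression of the outcome effects on the K columns of
#' exposure effects without intercept, weights `1/se_Gamma^2`. Standard
#' errors come from the weighted-least-squares covariance scaled by
#' `max(1, sigma_hat)` exactly as in the univariable multiplicative
#' random-effects IVW; p-values are two-sided normal.
#'
#' @param input An [mvmr_input()] (needs at least K + 2 SNVs).
#' @return List of class `mvmr_result`: per-exposure `beta, se, pval`,
#'   plus `sigma_hat`, `n_snv`, `k`, `status` (`"ok"`, or
#'   `"collinear_exposures"` when the design is rank deficient — identified
#'   coefficients are still estimated, aliased ones are `NA`).
#' @export
mvmr_ivw <- function(input) {
  X <- input$gamma
  J <- nrow(X); K <- ncol(X)
  if (J < K + 2L) stop("multivariable IVW needs at least K + 2 SNVs")
  w <- 1 / input$se_Gamma^2
  # pivoted QR identifies aliased (collinear or all-zero) exposure columns;
  # identified coefficients are still estimated, aliased ones reported NA
  qrx <- qr(sqrt(w) * X)
  rank <- qrx$rank
  used <- sort(qrx$pivot[seq_len(rank)])
  Xu <- X[, used, drop = FALSE]
  XtWX <- crossprod(Xu, w * Xu)
  beta <- rep(NA_real_, K); se <- rep(NA_real_, K)
  beta[used] <- solve(XtWX, crossprod(Xu, w * input$Gamma))[, 1]
  resid <- input$Gamma - as.numeric(Xu %*% beta[used])
  sigma_hat <- sqrt(sum(w * resid^2) / (J - rank))
  se[used] <- sqrt(diag(solve(XtWX))) * max(1, sigma_hat)
  names(beta) <- names(se) <- colnames(X)
  structure(list(beta = beta, se = se,
                 pval = ifelse(is.na(beta), NA_real_, z_pval(beta, se)),
                 sigma_hat = sigma_hat, n_snv = J, k = K,
                 status = if (rank < K) "collinear_exposures" else "ok"),
            class = "mvmr_result")
}

#' Conditional instrument-strength F statistic
#'
#' Measures how strongly the instruments predict exposure `k` beyond what
#' the other exposures explain. Exposure k's effects are regressed on the
#' other exposures' effects (no intercept) by iterated weighted least
#' squares, with per-SNV weights equal to the inverse variance of the
#' residual `gamma_jk - sum(delta * gamma_jk')` accounting for the
#' cross-exposure sampling covariance `rho * se_jk * se_jk'`. The
#' conditional F is `Q_k / (n_snv - K + 1)` where `Q_k` is the weighted
#' residual sum of squares; values at or below 10 indicate conditionally
#' weak instruments.
#'
#' @param input An [mvmr_input()].
#' @param k Exposure index.
#' @param rho Phenotypic correlation (defaults to `input$rho`).
#' @return The conditional F statistic, with attributes `q` and `delta`.
#' @export
conditional_f <- function(input, k, rho = input$rho) {
  X <- input$gamma
  J <- nrow(X); K <- ncol(X)
  if (J < K + 1L) stop("conditional F needs at least K + 1 SNVs")
  y <- X[, k]
  se_y <- input$se_gamma[, k]
  Z <- X[, -k, drop = FALSE]
  se_z <- input$se_gamma[, -k, drop = FALSE]
  Kz <- ncol(Z)

  resid_var <- function(delta) {
    v <- se_y^2
    for (a in seq_len(Kz)) {
      v <- v + delta[a]^2 * se_z[, a]^2 - 2 * delta[a] * rho * se_y * se_z[, a]
      if (a < Kz) for (b in seq((a + 1L), Kz)) {
        v <- v + 2 * delta[a] * delta[b] * rho * se_z[, a] * se_z[, b]
      }
    }
    pmax(v, 1e-12)
  }

  fit_delta <- function(w) {
    qz <- qr(sqrt(w) * Z)
    d <- qr.coef(qz, sqrt(w) * y)
    d[is.na(d)] <- 0
    d
  }

  delta <- fit_delta(rep(1, J))
  for (it in seq_len(50L)) {
    w <- 1 / resid_var(delta)
    delta_new <- fit_delta(w)
    if (max(abs(delta_new - delta)) < 1e-10) { delta <- delta_new; break }
    delta <- delta_new
  }
  w <- 1 / resid_var(delta)
  q_k <- sum(w * (y - as.numeric(Z %*% delta))^2)
  structure(q_k / (J - K + 1L), q = q_k, delta = delta)
}

#' Adjusted Cochran's Q for multivariable MR
#'
#' Heterogeneity about the fitted multivariable model with a denominator
#' that propagates exposure-side sampling error and its cross-exposure
#' correlation:
#' `Q_A = sum_j (Gamma_j - sum_k beta_k gamma_jk)^2 / (se_Gamma_j^2 +
#' sum_k beta_k^2 se_jk^2 + 2 sum_{k<k'} beta_k beta_k' rho se_jk se_jk')`,
#' referred to chi-square with `n_snv - K` degrees of freedom.
#'
#' @param input An [mvmr_input()].
#' @param betas Fitted direct effects (length K).
#' @param rho Phenotypic correlation (defaults to `input$rho`).
#' @return List `q_a, df, pval`.
#' @export
adjusted_q <- function(input, betas, rho = input$rho) {
  X <- input$gamma
  J <- nrow(X); K <- ncol(X)
  stopifnot(length(betas) == K)
  resid <- input$Gamma - as.numeric(X %*% betas)
  denom <- input$se_Gamma^2
  for (a in seq_len(K)) {
    denom <- denom + betas[a]^2 * input$se_gamma[, a]^2
    if (a < K) for (b in seq((a + 1L), K)) {
      denom <- denom + 2 * betas[a] * betas[b] * rho *
        input$se_gamma[, a] * input$se_gamma[, b]
    }
  }
  q_a <- sum(resid^2 / denom)
  df <- J - K
  list(q_a = q_a, df = df, pval = stats::pchisq(q_a, df, lower.tail = FALSE))
}

#' Pool instruments for multivariable MR with automated relaxation
#'
#' Each exposure starts at genome-wide significance; the pooled instrument
#' set is the union of per-exposure selections, clumped jointly (ranking by
#' each SNV's best p-value across exposures) and restricted to SNVs present
#' in every exposure and the outcome. Any exposure whose conditional F
#' statistic (minimum over the configured `rho` values) is 10 or below has
#' its threshold relaxed by a factor of 10 and the pool is rebuilt, capped
#' at 5e-4 with a weak-instrument flag.
#'
#' @param exposures List of >= 2 exposure summary-statistic data.frames.
#' @param outcome Outcome summary statistics.
#' @param ld An `ld_reference`.
#' @param rho Phenotypic correlation(s) assumed between exposure samples;
#'   both 0.1 and 0.9 by default, reported per value.
#' @param start,factor,max_threshold Ladder parameters.
#' @param min_cond_f Conditional-F bar that must be exceeded (default 10).
#' @param clump_r2,window_kb Clumping parameters.
#' @return List: `input` (an [mvmr_input()] built at the final thresholds,
#'   with `rho` set to the first configured value), `thresholds`
#'   (per-exposure), `cond_f` (matrix exposure x rho), `weak_flag`,
#'   `status` (`"ok"` or `"insufficient_instruments"`).
#' @export
select_mvmr_instruments <- function(exposures, outcome, ld,
                                    rho = c(0.1, 0.9),
                                    start = 5e-8, factor = 10,
                                    max_threshold = 5e-4, min_cond_f = 10,
                                    clump_r2 = 0.001, window_kb = 10000) {
  K <- length(exposures)
  stopifnot(K >= 2L)
  thresholds <- rep(start, K)

  build_pool <- function(thresholds) {
    sel_ids <- unique(unlist(lapply(seq_len(K), function(k) {
      ex <- exposures[[k]]
      ex$snv_id[ex$pval < thresholds[k]]
    })))
    # present in every exposure and the outcome
    for (k in seq_len(K)) sel_ids <- intersect(sel_ids, exposures[[k]]$snv_id)
    sel_ids <- intersect(sel_ids, outcome$snv_id)
    if (length(sel_ids) == 0L) return(NULL)
    base <- exposures[[1]][match(sel_ids, exposures[[1]]$snv_id), , drop = FALSE]
    best_p <- Reduce(pmin, lapply(exposures, function(ex)
      ex$pval[match(sel_ids, ex$snv_id)]))
    base$pval <- best_p
    kept <- clump(base, ld, r2_max = clump_r2, window_kb = window_kb)
    kept$snv_id
  }

  make_input <- function(ids, rho1) {
    g <- sapply(exposures, function(ex) ex$beta[match(ids, ex$snv_id)])
    sg <- sapply(exposures, function(ex) ex$se[match(ids, ex$snv_id)])
    oi <- match(ids, outcome$snv_id)
    mvmr_input(g, sg, outcome$beta[oi], outcome$se[oi], rho = rho1,
               snv_id = ids)
  }

  repeat {
    ids <- build_pool(thresholds)
    if (is.null(ids) || length(ids) < K + 2L) {
      at_cap <- all(thresholds >= max_threshold * (1 - 1e-12))
      if (at_cap) {
        return(list(input = NULL, thresholds = thresholds, cond_f = NULL,
                    weak_flag = TRUE, status = "insufficient_instruments"))
      }
      thresholds <- pmin(thresholds * factor, max_threshold)
      next
    }
    inp <- make_input(ids, rho[1])
    cf <- sapply(rho, function(r)
      sapply(seq_len(K), function(k) as.numeric(conditional_f(inp, k, rho = r))))
    cf <- matrix(cf, nrow = K,
                 dimnames = list(paste0("exposure", seq_len(K)),
                                 paste0("rho", rho)))
    weak <- apply(cf, 1, min) <= min_cond_f
    can_relax <- weak & thresholds < max_threshold * (1 - 1e-12)
    if (!any(can_relax)) {
      return(list(input = inp, thresholds = thresholds, cond_f = cf,
                  weak_flag = any(weak), status = "ok"))
    }
    thresholds[can_relax] <- pmin(thresholds[can_relax] * factor, max_threshold)
  }
}
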