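# Allele harmonisation, palindromic-variant handling, LD-proxy substitution
# and PLINK-style clumping.

#' Is an allele pair palindromic?
#'
#' A palindromic pair reads the same on the forward and reverse strands
#' (A/T or C/G), making strand orientation ambiguous from the alleles alone.
#'
#' @param effect_allele,other_allele Single-base alleles (A/C/G/T),
#'   vectorised.
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele); oa <- toupper(other_allele)
  if (any(!(ea %in% BASES) | !(oa %in% BASES))) {
    stop("alleles must be one of A, C, G, T")
  }
  unname(COMPLEMENT[ea] == oa)
}

HARMONISE_REASONS <- c("dropped_palindromic_maf", "dropped_palindromic_no_eaf",
                       "dropped_unreconcilable")

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele. SNVs present in
#' both datasets are retained; outcome rows with swapped effect/other alleles
#' have their beta sign flipped and allele frequency complemented; rows coded
#' on the opposite strand are complemented and re-matched. Palindromic SNVs
#' cannot be strand-resolved from their alleles: those whose minor-allele
#' frequency exceeds `palindrome_maf_max` in either dataset are dropped, and
#' the remainder are aligned by comparing which side of 0.5 the effect-allele
#' frequency falls on in each dataset (missing frequency on either side drops
#' the SNV). Unreconcilable allele pairs are dropped. Every drop carries a
#' reason code in the `dropped` attribute; nothing is dropped silently.
#'
#' @param exposure,outcome Summary-statistic data.frames (canonical schema);
#'   `exposure` rows are the selected instruments.
#' @param palindrome_maf_max Palindromic minor-allele-frequency ceiling
#'   (default 0.42).
#' @return A harmonised data.frame with columns `snv_id, chrom, pos,
#'   effect_allele, other_allele, eaf, gamma, se_gamma, p_exposure, Gamma,
#'   se_Gamma, p_outcome, proxy_used, proxy_source`, attributes `dropped`
#'   (data.frame `snv_id, reason`) and `status` (`"ok"` or
#'   `"empty_intersection"`).
#' @export
harmonise_pair <- function(exposure, outcome, palindrome_maf_max = 0.42) {
  common <- intersect(exposure$snv_id, outcome$snv_id)
  dropped <- data.frame(snv_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (length(common) == 0L) {
    out <- empty_harmonised()
    attr(out, "dropped") <- dropped
    attr(out, "status") <- "empty_intersection"
    return(out)
  }
  ex <- exposure[match(common, exposure$snv_id), , drop = FALSE]
  ou <- outcome[match(common, outcome$snv_id), , drop = FALSE]

  ea_x <- ex$effect_allele; oa_x <- ex$other_allele
  ea_y <- ou$effect_allele; oa_y <- ou$other_allele
  pal <- is_palindromic(ea_x, oa_x)

  Gamma <- ou$beta
  eaf_out <- ou$eaf
  keep <- rep(TRUE, length(common))
  reason <- rep(NA_character_, length(common))

  exact <- ea_y == ea_x & oa_y == oa_x
  swapped <- ea_y == oa_x & oa_y == ea_x
  comp <- COMPLEMENT[ea_y] == ea_x & COMPLEMENT[oa_y] == oa_x
  comp_swapped <- COMPLEMENT[ea_y] == oa_x & COMPLEMENT[oa_y] == ea_x

  # non-palindromic: allele letters identify the orientation uniquely
  np <- !pal
  flip <- np & !exact & (swapped | comp_swapped)
  ok_np <- np & (exact | swapped | comp | comp_swapped)
  Gamma[flip] <- -Gamma[flip]
  eaf_out[flip] <- 1 - eaf_out[flip]
  keep[np & !ok_np] <- FALSE
  reason[np & !ok_np] <- "dropped_unreconcilable"

  # palindromic: the same letters on both strands; only an allele pair that
  # is not {A,T}/{C,G}-compatible is unreconcilable, orientation comes from
  # the allele-frequency side
  pal_pairable <- pal & (exact | swapped | comp | comp_swapped)
  keep[pal & !pal_pairable] <- FALSE
  reason[pal & !pal_pairable] <- "dropped_unreconcilable"

  maf_x <- pmin(ex$eaf, 1 - ex$eaf)
  maf_y <- pmin(ou$eaf, 1 - ou$eaf)
  pal_no_eaf <- pal_pairable & (is.na(ex$eaf) | is.na(ou$eaf))
  keep[pal_no_eaf] <- FALSE
  reason[pal_no_eaf] <- "dropped_palindromic_no_eaf"
  pal_high <- pal_pairable & !pal_no_eaf &
    (maf_x > palindrome_maf_max | maf_y > palindrome_maf_max)
  keep[pal_high] <- FALSE
  reason[pal_high] <- "dropped_palindromic_maf"

  pal_ok <- pal_pairable & !pal_no_eaf & !pal_high
  opposite <- pal_ok & ((ex$eaf < 0.5) != (ou$eaf < 0.5))
  Gamma[opposite] <- -Gamma[opposite]
  eaf_out[opposite] <- 1 - eaf_out[opposite]

  out <- data.frame(
    snv_id = common, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ea_x, other_allele = oa_x, eaf = ex$eaf,
    gamma = ex$beta, se_gamma = ex$se, p_exposure = ex$pval,
    Gamma = Gamma, se_Gamma = ou$se, p_outcome = ou$pval,
    proxy_used = if (!is.null(ex$proxy_used)) ex$proxy_used else FALSE,
    proxy_source = if (!is.null(ex$proxy_source)) ex$proxy_source
                   else NA_character_,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(snv_id = common[!keep],
                                     reason = reason[!keep],
                                     stringsAsFactors = FALSE)
  attr(out, "status") <- "ok"
  out
}

#' @keywords internal
#' @noRd
empty_harmonised <- function() {
  data.frame(snv_id = character(0), chrom = character(0), pos = integer(0),
             effect_allele = character(0), other_allele = character(0),
             eaf = numeric(0), gamma = numeric(0), se_gamma = numeric(0),
             p_exposure = numeric(0), Gamma = numeric(0), se_Gamma = numeric(0),
             p_outcome = numeric(0), proxy_used = logical(0),
             proxy_source = character(0), stringsAsFactors = FALSE)
}

#' Find an LD proxy for a missing variant
#'
#' When an instrument is absent from the outcome dataset, searches the LD
#' reference for the most strongly linked variant (r2 at or above `min_r2`)
#' that is present in both datasets. Ties on r2 break by smaller base-pair
#' distance, then lexicographic identifier, so the choice is deterministic.
#'
#' @param missing_id Instrument absent from the outcome.
#' @param exposure_ids,outcome_ids Identifiers present in each dataset.
#' @param ld An `ld_reference`.
#' @param min_r2 Minimum r2 (default 0.9).
#' @return The proxy identifier, or `NA_character_` if no candidate
#'   qualifies.
#' @export
find_proxy <- function(missing_id, exposure_ids, outcome_ids, ld,
                       min_r2 = 0.9) {
  cand <- ld_partners(ld, missing_id, min_r2 = min_r2)
  cand <- cand[cand$snv_id %in% exposure_ids & cand$snv_id %in% outcome_ids, ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(NA_character_)
  pos <- ld$positions
  p0 <- pos$pos[match(missing_id, pos$snv_id)]
  pc <- pos$pos[match(cand$snv_id, pos$snv_id)]
  dist <- abs(pc - p0)
  dist[is.na(dist)] <- Inf
  ord <- order(-cand$r2, dist, cand$snv_id)
  cand$snv_id[ord[1]]
}

#' Substitute proxies for instruments missing from the outcome
#'
#' For each instrument with no outcome row, [find_proxy()] is consulted; if a
#' proxy exists, the proxy's own exposure row replaces the instrument (so its
#' exposure and outcome effects refer to the same variant, with no phasing
#' across the pair). Instruments without a proxy are dropped with reason
#' `no_proxy`.
#'
#' @param instruments Exposure rows of the selected instruments.
#' @param exposure Full exposure summary statistics (source of proxy rows).
#' @param outcome_ids Identifiers present in the outcome dataset.
#' @param ld An `ld_reference`.
#' @param min_r2 Proxy r2 threshold.
#' @return Instrument data.frame with `proxy_used`/`proxy_source` columns and
#'   attribute `dropped_no_proxy` (character vector of unresolvable ids).
#' @export
substitute_proxies <- function(instruments, exposure, outcome_ids, ld,
                               min_r2 = 0.9) {
  instruments$proxy_used <- FALSE
  instruments$proxy_source <- NA_character_
  missing <- setdiff(instruments$snv_id, outcome_ids)
  dropped <- character(0)
  for (id in missing) {
    proxy <- find_proxy(id, setdiff(exposure$snv_id, instruments$snv_id),
                        outcome_ids, ld, min_r2 = min_r2)
    i <- match(id, instruments$snv_id)
    if (is.na(proxy)) {
      dropped <- c(dropped, id)
      instruments <- instruments[-i, , drop = FALSE]
    } else {
      row <- exposure[match(proxy, exposure$snv_id), , drop = FALSE]
      row$proxy_used <- TRUE
      row$proxy_source <- id
      instruments[i, ] <- row[, names(instruments)]
    }
  }
  rownames(instruments) <- NULL
  attr(instruments, "dropped_no_proxy") <- dropped
  instruments
}

#' Clump instruments to approximate independence
#'
#' Greedy PLINK-style pruning: SNVs are visited in ascending p-value order
#' (ties broken by identifier) and accepted unless they lie within
#' `window_kb` of an already-accepted SNV on the same chromosome with
#' reference r2 above `r2_max`. Records without a position are excluded with
#' reason `dropped_no_position`.
#'
#' @param records Data.frame with `snv_id, chrom, pos, pval` (any extra
#'   columns pass through).
#' @param ld An `ld_reference`.
#' @param r2_max LD ceiling between retained SNVs (default 0.001).
#' @param window_kb Distance window in kilobases (default 10,000).
#' @return The retained rows, in the original row order, with attribute
#'   `dropped` (data.frame `snv_id, reason` covering both LD-pruned and
#'   position-less records).
#' @export
clump <- function(records, ld, r2_max = 0.001, window_kb = 10000) {
  no_pos <- is.na(records$pos) | is.na(records$chrom)
  excluded <- records$snv_id[no_pos]
  rec <- records[!no_pos, , drop = FALSE]
  ord <- order(rec$pval, rec$snv_id)
  accepted <- integer(0)
  pruned <- character(0)
  window_bp <- window_kb * 1000
  for (i in ord) {
    conflict <- FALSE
    for (a in accepted) {
      if (rec$chrom[i] == rec$chrom[a] &&
          abs(rec$pos[i] - rec$pos[a]) <= window_bp &&
          ld_r2(ld, rec$snv_id[i], rec$snv_id[a]) > r2_max) {
        conflict <- TRUE
        break
      }
    }
    if (conflict) pruned <- c(pruned, rec$snv_id[i]) else accepted <- c(accepted, i)
  }
  out <- rec[sort(accepted), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(
    snv_id = c(excluded, pruned),
    reason = c(rep("dropped_no_position", length(excluded)),
               rep("dropped_ld_prune", length(pruned))),
    stringsAsFactors = FALSE
  )
  out
}
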