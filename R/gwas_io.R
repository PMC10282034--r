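# Reading and writing GWAS summary statistics, LD references, trait
# catalogues and screen results in the package's canonical tab-separated
# dialects.

SUMSTAT_COLS <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
BASES <- c("A", "C", "G", "T")

#' Read GWAS summary statistics
#'
#' Reads a tab-separated summary-statistic file in the canonical dialect
#' (columns `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N`; optionally
#' gzip-compressed). Rows violating the record invariants (non-ACGT or equal
#' alleles, `SE <= 0`, `P` outside (0, 1], `EAF` outside \[0, 1\], `POS < 1`,
#' `N <= 0`, or non-finite `BETA`) are dropped with a logged count, never
#' silently. When the same `SNP` identifier appears more than once, the row
#' with the smallest p-value is kept.
#'
#' @param path Path to the file.
#' @param trait_id Identifier attached to every returned row.
#' @param quiet Suppress the per-file INFO messages about dropped rows.
#' @return A `data.frame` with columns `trait_id, snv_id, chrom, pos,
#'   effect_allele, other_allele, eaf, beta, se, pval, n`. Missing
#'   effect-allele frequency is `NA` and is propagated, never imputed.
#' @export
read_summary_stats <- function(path, trait_id, quiet = FALSE) {
  if (!file.exists(path)) stop("summary-statistic file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("SNP", "CHR", "EA", "OA")),
                          na.strings = c("", "NA"), showProgress = FALSE)
  missing_cols <- setdiff(SUMSTAT_COLS, names(dt))
  if (length(missing_cols)) {
    stop("summary-statistic file ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(dt) == 0L) stop("summary-statistic file ", path, " contains no rows")

  df <- data.frame(
    trait_id = trait_id,
    snv_id = as.character(dt$SNP),
    chrom = as.character(dt$CHR),
    pos = suppressWarnings(as.integer(dt$POS)),
    effect_allele = toupper(as.character(dt$EA)),
    other_allele = toupper(as.character(dt$OA)),
    eaf = suppressWarnings(as.numeric(dt$EAF)),
    beta = suppressWarnings(as.numeric(dt$BETA)),
    se = suppressWarnings(as.numeric(dt$SE)),
    pval = suppressWarnings(as.numeric(dt$P)),
    n = suppressWarnings(as.numeric(dt$N)),
    stringsAsFactors = FALSE
  )

  ok <- valid_sumstat_rows(df)
  n_dropped <- sum(!ok)
  df <- df[ok, , drop = FALSE]

  # duplicate identifiers: keep the smallest-p row (ties by file order)
  n_dup <- 0L
  if (anyDuplicated(df$snv_id)) {
    ord <- order(df$snv_id, df$pval)
    first <- !duplicated(df$snv_id[ord])
    keep <- sort(ord[first])
    n_dup <- nrow(df) - length(keep)
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  if (!quiet && (n_dropped > 0L || n_dup > 0L)) {
    message(sprintf("INFO [%s] %s: dropped %d invalid row(s), resolved %d duplicate id(s)",
                    trait_id, basename(path), n_dropped, n_dup))
  }
  df
}

# Vectorised invariant check used by the reader (and by tests as a predicate).
#' @keywords internal
#' @noRd
valid_sumstat_rows <- function(df) {
  !is.na(df$snv_id) & nzchar(df$snv_id) &
    !is.na(df$chrom) & nzchar(df$chrom) &
    !is.na(df$pos) & df$pos >= 1L &
    df$effect_allele %in% BASES & df$other_allele %in% BASES &
    df$effect_allele != df$other_allele &
    (is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1)) &
    is.finite(df$beta) &
    !is.na(df$se) & df$se > 0 &
    !is.na(df$pval) & df$pval > 0 & df$pval <= 1 &
    !is.na(df$n) & df$n > 0
}

#' Write GWAS summary statistics
#'
#' Inverse of [read_summary_stats()]: writes the canonical tab-separated
#' dialect. Numeric fields are written with 12 significant digits so a
#' write/read cycle preserves them to relative error below 1e-9.
#'
#' @param stats A summary-statistic `data.frame` as returned by
#'   [read_summary_stats()] or [simulate_trait_pair()].
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  out <- data.table::data.table(
    SNP = stats$snv_id, CHR = stats$chrom, POS = stats$pos,
    EA = stats$effect_allele, OA = stats$other_allele,
    EAF = signif(stats$eaf, 12), BETA = signif(stats$beta, 12),
    SE = signif(stats$se, 12), P = signif(stats$pval, 12), N = stats$n
  )
  data.table::fwrite(out, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read a local LD reference
#'
#' Reads a pairwise linkage-disequilibrium table (`SNP_A, SNP_B, R2`) plus a
#' position table (`SNP, CHR, POS`), the package's local stand-in for a
#' reference-panel LD server. Lookups are symmetric, `r2(x, x) = 1`, and an
#' absent pair has `r2 = 0` by contract.
#'
#' @param pairs_path Tab-separated pair table with columns `SNP_A, SNP_B, R2`.
#' @param positions_path Tab-separated position table with columns
#'   `SNP, CHR, POS`.
#' @return An object of class `ld_reference` with `$r2(a, b)` lookup served by
#'   [ld_r2()] and a `$positions` data.frame.
#' @export
read_ld_reference <- function(pairs_path, positions_path) {
  pr <- data.table::fread(pairs_path, sep = "\t", header = TRUE,
                          showProgress = FALSE)
  need <- setdiff(c("SNP_A", "SNP_B", "R2"), names(pr))
  if (length(need)) stop("LD pair table missing column(s): ",
                         paste(need, collapse = ", "))
  if (nrow(pr) && (any(!is.finite(pr$R2)) || any(pr$R2 < 0 | pr$R2 > 1))) {
    stop("LD pair table contains R2 values outside [0, 1]")
  }
  po <- data.table::fread(positions_path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("SNP", "CHR")),
                          showProgress = FALSE)
  need <- setdiff(c("SNP", "CHR", "POS"), names(po))
  if (length(need)) stop("LD position table missing column(s): ",
                         paste(need, collapse = ", "))
  ld_reference(
    pairs = data.frame(snp_a = as.character(pr$SNP_A),
                       snp_b = as.character(pr$SNP_B),
                       r2 = as.numeric(pr$R2), stringsAsFactors = FALSE),
    positions = data.frame(snv_id = as.character(po$SNP),
                           chrom = as.character(po$CHR),
                           pos = as.integer(po$POS), stringsAsFactors = FALSE)
  )
}

#' Construct an LD reference from in-memory tables
#'
#' @param pairs `data.frame` with columns `snp_a, snp_b, r2`.
#' @param positions `data.frame` with columns `snv_id, chrom, pos`.
#' @return An `ld_reference` object.
#' @export
ld_reference <- function(pairs, positions) {
  key <- ld_pair_key(pairs$snp_a, pairs$snp_b)
  r2 <- pairs$r2
  # symmetric duplicates collapse to the maximum recorded r2
  if (anyDuplicated(key)) {
    agg <- tapply(r2, key, max)
    key <- names(agg)
    r2 <- as.numeric(agg)
  }
  structure(list(pairs = pairs, positions = positions,
                 .map = stats::setNames(r2, key)),
            class = "ld_reference")
}

#' @keywords internal
#' @noRd
ld_pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Query pairwise LD
#'
#' @param ld An `ld_reference`.
#' @param a,b SNV identifiers (vectorised, recycled).
#' @return Numeric vector of r2 values; `1` when `a == b`, `0` for pairs not
#'   present in the reference.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_reference"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  out <- unname(ld$.map[ld_pair_key(a, b)])
  out[is.na(out)] <- 0
  out[a == b] <- 1
  out
}

#' Neighbours of a SNV in the LD reference
#'
#' @param ld An `ld_reference`.
#' @param id SNV identifier.
#' @param min_r2 Minimum r2 to report.
#' @return `data.frame` with columns `snv_id, r2` (partners of `id`).
#' @export
ld_partners <- function(ld, id, min_r2 = 0) {
  p <- ld$pairs
  hit <- (p$snp_a == id | p$snp_b == id) & p$r2 >= min_r2
  partner <- ifelse(p$snp_a[hit] == id, p$snp_b[hit], p$snp_a[hit])
  keep <- partner != id
  data.frame(snv_id = partner[keep], r2 = p$r2[hit][keep],
             stringsAsFactors = FALSE)
}

#' Read a trait catalogue
#'
#' Tab-separated catalogue mirroring the trait-metadata schema: columns
#' `trait_id, label, population, source_cohort, is_binary, n_total, n_cases,
#' is_imaging, is_eqtl`.
#'
#' @param path Path to the catalogue file.
#' @return `data.frame` with those columns; flags logical, `n_cases` `NA` when
#'   absent.
#' @export
read_trait_catalogue <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("", "NA"), showProgress = FALSE)
  need <- setdiff(c("trait_id", "label", "population", "source_cohort",
                    "is_binary", "n_total", "n_cases", "is_imaging", "is_eqtl"),
                  names(dt))
  if (length(need)) stop("trait catalogue missing column(s): ",
                         paste(need, collapse = ", "))
  cat_df <- as.data.frame(dt, stringsAsFactors = FALSE)
  for (f in c("is_binary", "is_imaging", "is_eqtl")) cat_df[[f]] <- as.logical(cat_df[[f]])
  bad <- !is.na(cat_df$n_cases) & cat_df$n_cases > cat_df$n_total
  if (any(bad)) stop("trait catalogue has n_cases > n_total for: ",
                     paste(cat_df$trait_id[bad], collapse = ", "))
  cat_df
}

#' Write a trait catalogue
#' @param catalogue Catalogue `data.frame` (see [read_trait_catalogue()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_catalogue <- function(catalogue, path) {
  data.table::fwrite(data.table::as.data.table(catalogue), path, sep = "\t",
                     na = "", quote = FALSE)
  invisible(path)
}

# Columns of the per-trait screen-results table. Every estimator contributes
# beta/se/p plus the derived odds ratio; QC and status fields follow.
SCREEN_NUMERIC_COLS <- local({
  methods <- c("ivw_mre", "ivw_fe", "egger", "weighted_median", "weighted_mode")
  c(paste0(rep(methods, each = 4), "_", c("beta", "se", "pval", "or")),
    "fdr_q_ivw", "egger_intercept", "egger_intercept_se", "egger_intercept_pval",
    "i2_gx", "q", "q_df", "q_pval", "sigma_hat", "threshold", "r2_total",
    "f_mean")
})

SCREEN_INT_COLS <- c("n_snv", "n_selected", "outliers_removed", "steiger_removed")
SCREEN_FLAG_COLS <- c("weak_instruments", "egger_nome_warning", "loo_all_nominal",
                      "significant")
SCREEN_CHR_COLS <- c("trait_id", "status", "call", "outcome_version")

#' Write screen results
#'
#' One row per trait with every estimator's beta, SE, p-value and odds ratio,
#' the FDR-adjusted IVW p, QC fields and status flags. Numeric fields are
#' written with 12 significant digits and round-trip through
#' [read_screen_results()] to relative error below 1e-9. Traits whose status
#' is not `"ok"` keep their status string but have empty estimate fields.
#'
#' @param results `data.frame` of per-trait screen rows (see
#'   [screen_result_row()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0L) stop("no screen results to write")
  cols <- c(SCREEN_CHR_COLS, SCREEN_INT_COLS, SCREEN_FLAG_COLS, SCREEN_NUMERIC_COLS)
  for (cl in setdiff(cols, names(results))) results[[cl]] <- NA
  out <- results[, cols]
  for (cl in SCREEN_NUMERIC_COLS) out[[cl]] <- signif(as.numeric(out[[cl]]), 12)
  ok <- tryCatch({
    data.table::fwrite(data.table::as.data.table(out), path, sep = "\t",
                       na = "", quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write screen results to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read screen results
#'
#' @param path Path written by [write_screen_results()].
#' @return `data.frame` with the screen-results schema.
#' @export
read_screen_results <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("", "NA"), showProgress = FALSE)
  df <- as.data.frame(dt, stringsAsFactors = FALSE)
  for (cl in intersect(SCREEN_FLAG_COLS, names(df))) df[[cl]] <- as.logical(df[[cl]])
  for (cl in intersect(SCREEN_NUMERIC_COLS, names(df))) df[[cl]] <- as.numeric(df[[cl]])
  df
}

#' Read a screen configuration
#'
#' YAML front end over [screen_config()]: keys matching its arguments
#' override the defaults.
#'
#' @param path YAML file.
#' @return A `screen_config` list.
#' @export
read_screen_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(screen_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown configuration key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(screen_config, vals)
}
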