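#' @include AllClasses.R conditions.R
NULL

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.isPalindromic <- function(ea, oa) unname(.COMPLEMENT[ea]) == oa

#' Construct a SummaryDataset from a records data.frame
#'
#' Thin validated constructor; most users will go through
#' [readSummaryTsv()] or the synthetic generator instead.
#'
#' @param traitId trait identifier.
#' @param records data.frame with the canonical columns.
#' @param traitType `"binary"` or `"continuous"`.
#' @param tally named numeric of QC drop counts (bookkeeping only).
#' @return A [SummaryDataset-class].
#' @export
summaryDataset <- function(traitId, records, traitType = "continuous",
                           tally = numeric(0)) {
  records <- as.data.frame(records)[, .CANONICAL_COLS]
  rownames(records) <- NULL
  new("SummaryDataset", traitId = as.character(traitId),
      traitType = traitType, records = records, tally = tally)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated summary-statistics file (plain or gzip), maps
#' dialect column names onto the canonical schema, uppercases alleles,
#' drops rows violating the record invariants (tallying each reason) and
#' resolves duplicate variant ids by keeping the smallest p-value.
#'
#' @param path file path; gzip is handled transparently.
#' @param columnMap optional named character vector mapping canonical field
#'   names to the file's column headers, e.g.
#'   `c(variant_id = "rsid", pval = "p_value")`. Unmapped canonical names
#'   are looked up verbatim.
#' @param traitId trait identifier; defaults to the file name without
#'   extensions.
#' @param traitType `"binary"` or `"continuous"`.
#' @return A [SummaryDataset-class]; `qcTally()` reports rows dropped as
#'   `invalid_se`, `invalid_pval`, `invalid_alleles`, `invalid_eaf`,
#'   `invalid_beta` or `duplicate`.
#' @export
readSummaryTsv <- function(path, columnMap = NULL, traitId = NULL,
                           traitType = "continuous") {
  if (!file.exists(path))
    .mrError(sprintf("file not found: %s", path), "mrIOError")
  df <- tryCatch(
    utils::read.delim(gzfile(path), header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e)
      .mrError(sprintf("cannot read %s: %s", path, conditionMessage(e)),
               "mrEmptyInputError"))
  if (nrow(df) == 0L)
    .mrError(sprintf("no data rows in %s", path), "mrEmptyInputError")

  if (!is.null(columnMap)) {
    for (canon in names(columnMap)) {
      src <- columnMap[[canon]]
      if (!src %in% names(df))
        .mrError(sprintf("mapped column '%s' (for %s) absent from %s",
                         src, canon, path), "mrConfigError")
      names(df)[names(df) == src] <- canon
    }
  }
  mandatory <- setdiff(.CANONICAL_COLS, c("eaf", "n"))
  absent <- setdiff(mandatory, names(df))
  if (length(absent))
    .mrError(sprintf("missing mandatory column(s): %s",
                     paste(absent, collapse = ", ")), "mrConfigError")
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_real_
  df <- df[, .CANONICAL_COLS]

  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))

  tally <- c(invalid_se = 0, invalid_pval = 0, invalid_alleles = 0,
             invalid_eaf = 0, invalid_beta = 0, duplicate = 0)
  ok_allele <- df$effect_allele %in% names(.COMPLEMENT) &
    df$other_allele %in% names(.COMPLEMENT) &
    df$effect_allele != df$other_allele
  bad <- rep("", nrow(df))
  bad[!ok_allele] <- "invalid_alleles"
  bad[bad == "" & (is.na(df$se) | df$se <= 0)] <- "invalid_se"
  bad[bad == "" & (is.na(df$pval) | df$pval <= 0 | df$pval > 1)] <- "invalid_pval"
  bad[bad == "" & is.na(df$beta)] <- "invalid_beta"
  bad[bad == "" & !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)] <- "invalid_eaf"
  for (reason in names(tally)) tally[reason] <- sum(bad == reason)
  df <- df[bad == "", , drop = FALSE]

  if (anyDuplicated(df$variant_id)) {
    # keep the smallest p-value per id (ties: first occurrence)
    ord <- order(df$pval, seq_len(nrow(df)))
    df <- df[ord, , drop = FALSE]
    dup <- duplicated(df$variant_id)
    tally["duplicate"] <- sum(dup)
    df <- df[!dup, , drop = FALSE]
    df <- df[order(match(df$variant_id, unique(df$variant_id))), , drop = FALSE]
  }

  if (is.null(traitId))
    traitId <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  summaryDataset(traitId, df, traitType = traitType, tally = tally)
}

#' Write a SummaryDataset to the canonical TSV
#'
#' Inverse of [readSummaryTsv()]: numeric columns are serialized at full
#' precision so a write/read round trip is bit-exact.
#'
#' @param dataset a [SummaryDataset-class].
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
writeSummaryTsv <- function(dataset, path) {
  df <- records(dataset)
  out <- df
  for (col in c("eaf", "beta", "se", "pval", "n"))
    out[[col]] <- .fullPrecision(df[[col]])
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.fullPrecision <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# Orientation of one dataset's rows relative to reference alleles.
# Returns integer: +1 keep, -1 flip, 0 mismatch, NA palindromic-ambiguous.
# refEaf/eaf used only for palindromic variants.
.orient <- function(ea, oa, refEa, refOa, eaf, refEaf, window) {
  n <- length(ea)
  out <- integer(n)
  pal <- .isPalindromic(refEa, refOa)
  comp_ea <- unname(.COMPLEMENT[ea])
  comp_oa <- unname(.COMPLEMENT[oa])
  same <- ea == refEa & oa == refOa
  swap <- ea == refOa & oa == refEa
  csame <- comp_ea == refEa & comp_oa == refOa
  cswap <- comp_ea == refOa & comp_oa == refEa
  out[same | csame] <- 1L
  out[swap | cswap] <- -1L   # for palindromes swap==csame; resolved below
  out[!(same | swap | csame | cswap)] <- 0L

  if (any(pal)) {
    i <- which(pal & out != 0L)
    if (length(i)) {
      ambiguous <- is.na(eaf[i]) | is.na(refEaf[i]) |
        (eaf[i] >= window[1] & eaf[i] <= window[2]) |
        (refEaf[i] >= window[1] & refEaf[i] <= window[2])
      # allele labels cannot fix strand for palindromes; use frequency.
      # nominal eaf applies when labels match the reference effect allele,
      # otherwise the complement-coded frequency.
      nominal <- ifelse(ea[i] == refEa[i], eaf[i], 1 - eaf[i])
      flip <- (nominal < 0.5) != (refEaf[i] < 0.5)
      out[i] <- ifelse(ambiguous, NA_integer_, ifelse(flip, -1L, 1L))
    }
  }
  out
}

#' Harmonize an exposure-outcome pair of summary datasets
#'
#' Aligns the overlapping variants of two GWAS so that both effect sizes
#' refer to the exposure's effect allele. Swapped allele codings flip the
#' outcome beta sign and complement its allele frequency; strand flips
#' (A<->T, C<->G complements) are recognized and aligned. Palindromic (A/T,
#' C/G) variants cannot be strand-resolved from labels: they are oriented
#' by allele-frequency concordance, and dropped as ambiguous when either
#' frequency is missing or falls inside `palindromeEafWindow` (inclusive).
#'
#' @param exposure,outcome [SummaryDataset-class] objects.
#' @param palindromeEafWindow frequency interval within which palindromic
#'   variants are considered ambiguous.
#' @return A [HarmonizedSet-class] in exposure order; `dropped()` lists the
#'   exposure variants not carried through with their reasons.
#' @export
harmonize <- function(exposure, outcome,
                      palindromeEafWindow = c(0.42, 0.58)) {
  if (nVariants(exposure) == 0L || nVariants(outcome) == 0L)
    .mrError("both datasets must be non-empty", "mrEmptyInputError")
  re <- records(exposure)
  ro <- records(outcome)
  idx <- match(re$variant_id, ro$variant_id)
  if (all(is.na(idx)))
    .mrError(sprintf("no overlapping variants between %s and %s",
                     traitId(exposure), traitId(outcome)),
             "mrEmptyOverlapError")

  present <- !is.na(idx)
  reason <- rep(NA_character_, nrow(re))
  reason[!present] <- "missing_in_outcome"

  i <- which(present)
  o <- ro[idx[i], ]
  orient <- .orient(o$effect_allele, o$other_allele,
                    re$effect_allele[i], re$other_allele[i],
                    o$eaf, re$eaf[i], palindromeEafWindow)
  reason[i[!is.na(orient) & orient == 0L]] <- "allele_mismatch"
  reason[i[is.na(orient)]] <- "palindromic_ambiguous"

  keep <- i[!is.na(orient) & orient != 0L]
  sgn <- orient[!is.na(orient) & orient != 0L]
  if (!length(keep))
    .mrError(sprintf("no variants survived harmonization of %s vs %s",
                     traitId(exposure), traitId(outcome)),
             "mrEmptyOverlapError")

  droppedDf <- data.frame(variant_id = re$variant_id[!is.na(reason)],
                          reason = reason[!is.na(reason)],
                          stringsAsFactors = FALSE)
  new("HarmonizedSet",
      exposureId = traitId(exposure), outcomeId = traitId(outcome),
      variantIds = re$variant_id[keep],
      bx = re$beta[keep], seX = re$se[keep],
      by = sgn * ro$beta[idx[keep]], seY = ro$se[idx[keep]],
      dropped = droppedDf)
}

#' Write MR or mediation results to a TSV
#'
#' One row per (pair, method). Numeric columns are serialized at full
#' precision; display columns round the odds ratio and confidence limits to
#' 3 decimals and the p-value to 3 decimals, the convention of published
#' forest-plot tables.
#'
#' @param results a list of [MRSuiteResult-class] or
#'   [MediationEstimate-class] objects (a single object is accepted).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeResultsTsv <- function(results, path) {
  if (is(results, "MRSuiteResult") || is(results, "MediationEstimate"))
    results <- list(results)
  if (!length(results))
    .mrError("results must be non-empty", "mrEmptyInputError")
  tabs <- lapply(results, function(r) {
    if (is(r, "MRSuiteResult")) suiteTable(r)
    else if (is(r, "MediationEstimate")) mediationTable(r)
    else .mrError("results must be MRSuiteResult or MediationEstimate",
                  "mrConfigError")
  })
  common <- Reduce(union, lapply(tabs, names))
  tabs <- lapply(tabs, function(t) {
    t[setdiff(common, names(t))] <- NA
    t[common]
  })
  df <- do.call(rbind, tabs)
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], .fullPrecision)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    .mrError(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
             "mrIOError")
  invisible(path)
}

#' @describeIn writeResultsTsv Flat table of one MR suite, with display
#'   columns (`or_display`, `ci_display`, `p_display`).
#' @param x an [MRSuiteResult-class] or [MediationEstimate-class].
#' @export
suiteTable <- function(x) {
  est <- x@estimates
  df <- data.frame(
    exposure_id = x@exposureId, outcome_id = x@outcomeId,
    direction = x@direction,
    method = vapply(est, function(e) e@method, character(1)),
    k = x@k,
    beta = vapply(est, function(e) e@beta, numeric(1)),
    se = vapply(est, function(e) e@se, numeric(1)),
    pval = vapply(est, function(e) e@pval, numeric(1)),
    or = vapply(est, function(e) e@or, numeric(1)),
    ci_low = vapply(est, function(e) e@ciLow, numeric(1)),
    ci_high = vapply(est, function(e) e@ciHigh, numeric(1)),
    q = x@q@Q, q_df = x@q@df, q_pval = x@q@pval,
    egger_intercept =
      if (is.null(x@eggerIntercept)) NA_real_ else x@eggerIntercept@intercept,
    egger_intercept_pval =
      if (is.null(x@eggerIntercept)) NA_real_ else x@eggerIntercept@pval,
    stringsAsFactors = FALSE)
  df$or_display <- sprintf("%.3f", df$or)
  df$ci_display <- sprintf("%.3f–%.3f", df$ci_low, df$ci_high)
  df$p_display <- sprintf("%.3f", df$pval)
  rownames(df) <- NULL
  df
}

#' @describeIn writeResultsTsv Flat table of one mediation estimate.
#' @export
mediationTable <- function(x) {
  data.frame(
    exposure_id = x@exposureId, mediator_id = x@mediatorId,
    outcome_id = x@outcomeId, method = x@method,
    beta_total = x@betaTotal, beta_xm = x@betaXm, beta_my = x@betaMy,
    indirect = x@indirect, indirect_se = x@indirectSe, direct = x@direct,
    prop_mediated = x@propMediated, prop_se = x@propSe,
    pval_indirect = x@pvalIndirect,
    sign_consistent = x@signConsistent, prop_undefined = x@propUndefined,
    prop_display = if (x@propUndefined) "NA"
                   else sprintf("%.2f%%", 100 * x@propMediated),
    stringsAsFactors = FALSE)
}

#' Write the harmonization drop log
#'
#' @param h a [HarmonizedSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDropsTsv <- function(h, path) {
  utils::write.table(dropped(h), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
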