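#' @include AllClasses.R conditions.R gwas-io.R
NULL

#' Select variants by association p-value
#'
#' Retains exactly the records with `pval < pThreshold` (strict), in the
#' original order. The conventional relaxed instrument threshold for
#' molecular-trait exposures is 5e-5.
#'
#' @param dataset a [SummaryDataset-class].
#' @param pThreshold significance threshold in (0, 1].
#' @return A [SummaryDataset-class] (possibly empty).
#' @export
selectByPvalue <- function(dataset, pThreshold = 5e-5) {
  r <- records(dataset)
  summaryDataset(traitId(dataset), r[r$pval < pThreshold, , drop = FALSE],
                 traitType = traitType(dataset), tally = qcTally(dataset))
}

#' Remove variants on a confounder exclusion list
#'
#' Static stand-in for confounder lookups (e.g. a PhenoScanner export):
#' variants whose id appears in `exclusionIds` are removed. Listed ids
#' absent from the dataset trigger a classed warning.
#'
#' @param dataset a [SummaryDataset-class].
#' @param exclusionIds character vector of variant ids to drop.
#' @return A [SummaryDataset-class].
#' @export
excludeSnps <- function(dataset, exclusionIds = character(0)) {
  if (!length(exclusionIds)) return(dataset)
  r <- records(dataset)
  absent <- setdiff(exclusionIds, r$variant_id)
  if (length(absent))
    .mrWarning(sprintf("%d exclusion id(s) not present in %s",
                       length(absent), traitId(dataset)),
               "mrAbsentExclusionWarning")
  summaryDataset(traitId(dataset),
                 r[!r$variant_id %in% exclusionIds, , drop = FALSE],
                 traitType = traitType(dataset), tally = qcTally(dataset))
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining variant with the smallest p-value as an
#' index (ties broken lexicographically on `variant_id`) and removes every
#' remaining variant whose r-squared with the index exceeds `clumpR2` AND
#' whose position lies strictly within `clumpWindowKb` of the index on the
#' same chromosome. With no LD matrix, variants are treated as independent
#' and returned unchanged.
#'
#' @param dataset a [SummaryDataset-class].
#' @param ld an [LDMatrix-class] covering all dataset variants, or NULL.
#' @param criteria an [InstrumentCriteria-class].
#' @return A [SummaryDataset-class] of retained index variants, original
#'   order preserved.
#' @export
ldClump <- function(dataset, ld = NULL, criteria = instrumentCriteria()) {
  r <- records(dataset)
  if (is.null(ld) || nrow(r) == 0L) return(dataset)
  miss <- setdiff(r$variant_id, ld@variantIds)
  if (length(miss))
    .mrError(sprintf("LD matrix lacks %d dataset variant(s), e.g. %s",
                     length(miss), miss[1]), "mrConfigError")
  m <- ld@r2[match(r$variant_id, ld@variantIds),
             match(r$variant_id, ld@variantIds), drop = FALSE]
  n <- nrow(r)
  ord <- order(r$pval, r$variant_id)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  windowBp <- criteria@clumpWindowKb * 1000
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    conflict <- alive &
      r$chrom == r$chrom[i] &
      abs(r$pos - r$pos[i]) < windowBp &
      m[i, ] > criteria@clumpR2
    alive[conflict] <- FALSE
  }
  summaryDataset(traitId(dataset), r[keep, , drop = FALSE],
                 traitType = traitType(dataset), tally = qcTally(dataset))
}

#' Instrument-strength F filter
#'
#' Computes the per-variant F statistic as the squared Wald z,
#' `F = (beta/se)^2`, and retains records with `F > fMin` strictly. The
#' conventional weak-instrument bound is F > 10.
#'
#' @param dataset a [SummaryDataset-class].
#' @param fMin minimum F statistic.
#' @return A list with `dataset` (the filtered [SummaryDataset-class]) and
#'   `f` (named numeric of all input variants' F values, for reporting).
#' @export
fFilter <- function(dataset, fMin = 10) {
  r <- records(dataset)
  f <- (r$beta / r$se)^2
  names(f) <- r$variant_id
  list(dataset = summaryDataset(traitId(dataset),
                                r[f > fMin, , drop = FALSE],
                                traitType = traitType(dataset),
                                tally = qcTally(dataset)),
       f = f)
}

#' Read an LD r-squared matrix
#'
#' Accepts either a long-format TSV with columns `id_a`, `id_b`, `r2`
#' (missing pairs default to 0, the diagonal to 1) or a square matrix file
#' whose header row holds the variant ids.
#'
#' @param path file path.
#' @return An [LDMatrix-class].
#' @export
readLdMatrix <- function(path) {
  if (!file.exists(path))
    .mrError(sprintf("file not found: %s", path), "mrIOError")
  df <- utils::read.delim(gzfile(path), header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("id_a", "id_b", "r2") %in% names(df))) {
    ids <- sort(unique(c(df$id_a, df$id_b)))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    for (i in seq_len(nrow(df))) {
      m[df$id_a[i], df$id_b[i]] <- df$r2[i]
      m[df$id_b[i], df$id_a[i]] <- df$r2[i]
    }
  } else {
    ids <- names(df)
    m <- as.matrix(df)
    dimnames(m) <- list(ids, ids)
  }
  new("LDMatrix", variantIds = ids, r2 = unname(m))
}

#' Read a confounder exclusion list (one variant id per line)
#'
#' @param path file path.
#' @return Character vector of variant ids.
#' @export
readExclusionList <- function(path) {
  if (!file.exists(path))
    .mrError(sprintf("file not found: %s", path), "mrIOError")
  ids <- readLines(gzfile(path), warn = FALSE)
  ids[nzchar(trimws(ids))]
}

#' Construct an LDMatrix in code
#'
#' @param variantIds character vector of ids.
#' @param r2 square symmetric matrix of squared correlations.
#' @return An [LDMatrix-class].
#' @export
ldMatrix <- function(variantIds, r2) {
  new("LDMatrix", variantIds = as.character(variantIds),
      r2 = as.matrix(r2))
}
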