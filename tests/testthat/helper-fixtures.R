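# builders for in-code fixtures

makeRecords <- function(n = 3, ids = sprintf("rs%03d", seq_len(n)),
                        chrom = "1", pos = seq_len(n) * 1e6L,
                        ea = "A", oa = "G", eaf = 0.3,
                        beta = 0.1, se = 0.02, pval = NULL, nSamp = 10000) {
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)),
                                  .Machine$double.xmin)
  data.frame(variant_id = rep_len(ids, n), chrom = rep_len(chrom, n),
             pos = as.integer(rep_len(pos, n)),
             effect_allele = rep_len(ea, n), other_allele = rep_len(oa, n),
             eaf = rep_len(eaf, n), beta = rep_len(beta, n),
             se = rep_len(se, n), pval = rep_len(pval, n),
             n = rep_len(nSamp, n), stringsAsFactors = FALSE)
}

makeDataset <- function(..., traitId = "trait", traitType = "continuous") {
  summaryDataset(traitId, makeRecords(...), traitType = traitType)
}

makeHarmonized <- function(bx, by, seY, seX = rep(0.01, length(bx)),
                           ids = sprintf("rs%03d", seq_along(bx))) {
  new("HarmonizedSet", exposureId = "X", outcomeId = "Y",
      variantIds = ids, bx = bx, seX = seX, by = by, seY = seY,
      dropped = data.frame(variant_id = character(0),
                           reason = character(0)))
}

writeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# matched exposure/outcome pair with per-variant true ratio `theta`
makePair <- function(k = 30, theta = 0.3, seOut = 0.01, seed = 1,
                     noise = TRUE) {
  set.seed(seed)
  bx <- runif(k, 0.05, 0.15)
  seX <- rep(0.002, k)
  by <- theta * bx + if (noise) rnorm(k, 0, seOut) else 0
  ids <- sprintf("rs%03d", seq_len(k))
  exposure <- summaryDataset("X", makeRecords(
    n = k, ids = ids, beta = bx, se = seX))
  outcome <- summaryDataset("Y", makeRecords(
    n = k, ids = ids, beta = by, se = seOut), traitType = "binary")
  list(exposure = exposure, outcome = outcome)
}

# independent exhaustive clumping oracle: enumerate all subsets and find the
# one where membership equals "no kept conflicting variant precedes me" in
# (p, id) order; asserts uniqueness before returning.
clumpOracle <- function(records, r2, clumpR2, windowKb) {
  n <- nrow(records)
  ord <- order(records$pval, records$variant_id)
  rank <- match(seq_len(n), ord)  # position in precedence order
  conflict <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    i != j && records$chrom[i] == records$chrom[j] &&
      abs(records$pos[i] - records$pos[j]) < windowKb * 1000 &&
      r2[i, j] > clumpR2
  }))
  valid <- list()
  for (mask in 0:(2^n - 1)) {
    keep <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    okAll <- TRUE
    for (v in seq_len(n)) {
      blocked <- any(keep & conflict[, v] & rank < rank[v])
      if (keep[v] == blocked) { okAll <- FALSE; break }
    }
    if (okAll) valid[[length(valid) + 1]] <- keep
  }
  stopifnot(length(valid) == 1)
  records$variant_id[valid[[1]]]
}
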