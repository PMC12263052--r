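test_that("reading keeps valid rows, drops and tallies invalid ones", {
  df <- makeRecords(n = 3)
  d <- readSummaryTsv(writeTsv(df), traitId = "t")
  expect_s4_class(d, "SummaryDataset")
  expect_equal(nVariants(d), 3L)
  expect_equal(sum(qcTally(d)), 0)

  df2 <- makeRecords(n = 3)
  df2$se[2] <- 0
  d2 <- readSummaryTsv(writeTsv(df2), traitId = "t")
  expect_equal(nVariants(d2), 2L)
  expect_equal(unname(qcTally(d2)["invalid_se"]), 1)

  df3 <- makeRecords(n = 4)
  df3$pval[1] <- 0
  df3$effect_allele[2] <- "G"   # equals other allele
  df3$eaf[3] <- 1.4
  d3 <- readSummaryTsv(writeTsv(df3), traitId = "t")
  expect_equal(nVariants(d3), 1L)
  expect_equal(unname(qcTally(d3)[c("invalid_pval", "invalid_alleles",
                                    "invalid_eaf")]), c(1, 1, 1))
})

test_that("duplicate variant ids keep the smallest p-value", {
  df <- makeRecords(n = 2, ids = c("rs1", "rs1"),
                    beta = c(0.2, 0.1), pval = c(1e-3, 1e-6))
  d <- readSummaryTsv(writeTsv(df), traitId = "t")
  expect_equal(nVariants(d), 1L)
  expect_equal(records(d)$beta, 0.1)
  expect_equal(unname(qcTally(d)["duplicate"]), 1)
})

test_that("column maps rename dialect headers; missing columns error", {
  df <- makeRecords(n = 2)
  names(df)[names(df) == "variant_id"] <- "rsid"
  names(df)[names(df) == "pval"] <- "p_value"
  path <- writeTsv(df)
  d <- readSummaryTsv(path, columnMap = c(variant_id = "rsid",
                                          pval = "p_value"))
  expect_equal(nVariants(d), 2L)
  expect_error(readSummaryTsv(path), class = "mrConfigError")
  expect_error(readSummaryTsv(path, columnMap = c(variant_id = "nope")),
               class = "mrConfigError")
  empty <- tempfile(fileext = ".tsv")
  file.create(empty)
  expect_error(readSummaryTsv(empty), class = "mrEmptyInputError")
})

test_that("summary TSVs are gzip-transparent and round-trip bit-exactly", {
  cfg <- simConfig(nSnps = 10, seed = 5)
  x <- simulateTriplet(cfg)$exposure
  gz <- tempfile(fileext = ".tsv.gz")
  writeSummaryTsv(x, gz)
  back <- readSummaryTsv(gz, traitId = traitId(x))
  expect_identical(records(back)$beta, records(x)$beta)
  expect_identical(records(back)$se, records(x)$se)
  expect_identical(records(back)$pval, records(x)$pval)
})

test_that("harmonization flips swapped alleles and aligns strand flips", {
  exposure <- makeDataset(n = 1, ids = "rs1", ea = "A", oa = "G",
                          beta = 0.1, traitId = "X")
  outcome <- makeDataset(n = 1, ids = "rs1", ea = "G", oa = "A",
                         beta = 0.05, traitId = "Y")
  h <- harmonize(exposure, outcome)
  expect_equal(h@by, -0.05)

  # strand flip: exposure G/T vs outcome C/A are complements, same orientation
  e2 <- makeDataset(n = 1, ids = "rs1", ea = "G", oa = "T", traitId = "X")
  o2 <- makeDataset(n = 1, ids = "rs1", ea = "C", oa = "A", beta = 0.2,
                    traitId = "Y")
  expect_equal(harmonize(e2, o2)@by, 0.2)

  # strand flip + swap
  o3 <- makeDataset(n = 1, ids = "rs1", ea = "A", oa = "C", beta = 0.2,
                    traitId = "Y")
  expect_equal(harmonize(e2, o3)@by, -0.2)
})

test_that("ambiguous palindromic variants drop; clear ones orient by frequency", {
  e <- makeDataset(n = 2, ids = c("rs1", "rs2"), ea = "A", oa = "T",
                   eaf = c(0.50, 0.10), beta = 0.1, traitId = "X")
  o <- makeDataset(n = 2, ids = c("rs1", "rs2"), ea = "A", oa = "T",
                   eaf = c(0.50, 0.85), beta = 0.3, traitId = "Y")
  h <- harmonize(e, o)
  expect_equal(dropped(h)$variant_id, "rs1")
  expect_equal(dropped(h)$reason, "palindromic_ambiguous")
  # rs2: exposure eaf 0.10 vs outcome 0.85 -> opposite orientation
  expect_equal(h@by, -0.3)

  # missing eaf on either side is ambiguous
  e2 <- makeDataset(n = 1, ids = "rs1", ea = "C", oa = "G",
                    eaf = NA_real_, traitId = "X")
  o2 <- makeDataset(n = 1, ids = "rs1", ea = "C", oa = "G", eaf = 0.2,
                    traitId = "Y")
  expect_error(harmonize(e2, o2), class = "mrEmptyOverlapError")
})

test_that("overlap accounting: k plus non-missing drops equals the overlap", {
  e <- makeDataset(n = 4, ids = c("rs1", "rs2", "rs3", "rs4"),
                   ea = c("A", "A", "C", "A"), oa = c("G", "T", "G", "G"),
                   eaf = c(0.3, 0.5, 0.3, 0.3), traitId = "X")
  o <- makeDataset(n = 3, ids = c("rs1", "rs2", "rs3"),
                   ea = c("A", "A", "C"), oa = c("G", "T", "T"),
                   eaf = c(0.3, 0.5, 0.3), traitId = "Y")
  h <- harmonize(e, o)   # rs2 palindromic-ambiguous, rs3 mismatch, rs4 missing
  overlap <- length(intersect(variantIds(e), variantIds(o)))
  nonMissingDrops <- sum(dropped(h)$reason != "missing_in_outcome")
  expect_equal(nVariants(h) + nonMissingDrops, overlap)
  expect_error(harmonize(makeDataset(n = 1, ids = "rsA", traitId = "X"),
                         makeDataset(n = 1, ids = "rsB", traitId = "Y")),
               class = "mrEmptyOverlapError")
})

test_that("harmonization is idempotent and invariant to exposure recoding", {
  cfg <- simConfig(nSnps = 40, seed = 11)
  trip <- simulateTriplet(cfg)
  h1 <- harmonize(trip$exposure, trip$outcome)

  # rebuild an outcome already aligned to the exposure coding and re-harmonize
  re <- records(trip$exposure)
  aligned <- re[match(variantIds(h1), re$variant_id), ]
  aligned$beta <- h1@by
  aligned$se <- h1@seY
  o2 <- summaryDataset("Y", aligned, traitType = "binary")
  h2 <- harmonize(trip$exposure, o2)
  expect_equal(h2@by[match(variantIds(h1), variantIds(h2))], h1@by)
  expect_equal(nVariants(h2), nVariants(h1))

  # flip the allele coding of every 3rd exposure variant
  flip <- seq(1, nrow(re), by = 3)
  re2 <- re
  re2$effect_allele[flip] <- re$other_allele[flip]
  re2$other_allele[flip] <- re$effect_allele[flip]
  re2$beta[flip] <- -re$beta[flip]
  re2$eaf[flip] <- 1 - re$eaf[flip]
  h3 <- harmonize(summaryDataset("X", re2), trip$outcome)
  # both effects now refer to the new exposure allele: jointly negated where
  # flipped, so every orientation-invariant quantity is unchanged
  expect_equal(h3@bx * h3@by, h1@bx * h1@by)
  expect_equal(abs(h3@bx), abs(h1@bx))
  expect_equal(h3@seY, h1@seY)
  expect_equal(mrIvw(h3)$estimate@beta, mrIvw(h1)$estimate@beta)
})

test_that("results TSVs carry rounded display columns and exact numerics", {
  h <- makeHarmonized(bx = c(0.2, 0.4, 0.3), by = c(0, 0, 0),
                      seY = c(0.1, 0.1, 0.1))
  suite <- new("MRSuiteResult", exposureId = "X", outcomeId = "Y",
               direction = "forward", k = 3L,
               estimates = list(ivw_random = mrIvw(h)$estimate),
               skipped = character(0), q = mrIvw(h)$q,
               eggerIntercept = NULL, fStats = numeric(0),
               tally = numeric(0), harmonized = h)
  path <- tempfile(fileext = ".tsv")
  writeResultsTsv(suite, path)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(or_display = "character"))
  expect_equal(tab$or_display, "1.000")     # beta 0 -> OR prints 1.000
  expect_identical(as.numeric(tab$beta), 0) # full-precision round trip

  est <- mrchain:::.mkEstimate("ivw_random", 5L, log(1.134), 0.0431)
  suite@estimates <- list(ivw_random = est)
  writeResultsTsv(suite, path)
  tab2 <- read.delim(path, colClasses = c(or_display = "character"))
  expect_equal(tab2$or_display, "1.134")
  expect_identical(as.numeric(tab2$beta), log(1.134))
})
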