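#' @include AllClasses.R conditions.R gwas-io.R screening.R mediation.R
NULL

#' StudyConfig: configuration of a full causal-chain study
#'
#' Paths to the exposure and mediator panel manifests (TSV with columns
#' `trait_id`, `path`, `trait_type`) and the outcome summary statistics,
#' plus the instrument criteria, screening level, bootstrap size, study
#' seed and output directory.
#' @export
setClass("StudyConfig",
  representation(exposureManifest = "character",
                 mediatorManifest = "character",
                 outcomePath = "character",
                 criteria = "InstrumentCriteria",
                 alpha = "numeric", nBoot = "numeric",
                 seed = "integer", outputDir = "character"))

#' @describeIn StudyConfig-class Constructor.
#' @param exposureManifest,mediatorManifest,outcomePath input file paths.
#' @param criteria an [InstrumentCriteria-class].
#' @param alpha screening significance level.
#' @param nBoot bootstrap draws for median/mode SEs.
#' @param seed mandatory study-level seed; all component seeds derive from
#'   it.
#' @param outputDir directory for result tables and logs.
#' @export
studyConfig <- function(exposureManifest, mediatorManifest, outcomePath,
                        criteria = instrumentCriteria(), alpha = 0.05,
                        nBoot = 1000, seed, outputDir) {
  if (missing(seed)) .mrError("seed is mandatory", "mrConfigError")
  new("StudyConfig", exposureManifest = exposureManifest,
      mediatorManifest = mediatorManifest, outcomePath = outcomePath,
      criteria = criteria, alpha = alpha, nBoot = nBoot,
      seed = as.integer(seed), outputDir = outputDir)
}

#' Read a panel manifest
#'
#' @param path TSV with columns `trait_id`, `path`, `trait_type`; relative
#'   dataset paths are resolved against the manifest's directory.
#' @return Named list of [SummaryDataset-class].
#' @export
readManifest <- function(path) {
  if (!file.exists(path))
    .mrError(sprintf("manifest not found: %s", path), "mrIOError")
  mf <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trait_id", "path", "trait_type")
  if (!all(need %in% names(mf)))
    .mrError(sprintf("manifest %s must have columns %s", path,
                     paste(need, collapse = ", ")), "mrConfigError")
  out <- list()
  for (i in seq_len(nrow(mf))) {
    p <- mf$path[i]
    if (!file.exists(p)) p <- file.path(dirname(path), mf$path[i])
    out[[mf$trait_id[i]]] <- readSummaryTsv(p, traitId = mf$trait_id[i],
                                            traitType = mf$trait_type[i])
  }
  out
}

.configDigest <- function(config) {
  txt <- paste(deparse(lapply(slotNames(config), function(s)
    slot(config, s))), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the complete causal-chain study
#'
#' Executes, in order: the forward exposure panel against the outcome; the
#' reverse panel (outcome as exposure against each exposure); direction
#' classification with exclusion of bidirectional exposures; mediator
#' screening (X -> M and M -> Y panels with two-step gating); and mediation
#' estimation by both the product and difference methods. Writes result
#' TSVs, a QC/drops log, a structured event log and a run manifest to the
#' output directory. Deterministic: equal configs give byte-identical
#' outputs.
#'
#' @param config a [StudyConfig-class].
#' @return A bundle (list of class `mrStudyBundle`) with components
#'   `forward`, `reverse`, `direction`, `mediation`, `paths`, `log`.
#' @export
runStudy <- function(config) {
  for (p in c(config@exposureManifest, config@mediatorManifest,
              config@outcomePath))
    if (!file.exists(p))
      .mrError(sprintf("input not readable: %s", p), "mrIOError")
  dir.create(config@outputDir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  note <- function(...) {
    log <<- c(log, paste0("event=", sprintf(...)))
    invisible(NULL)
  }

  exposures <- readManifest(config@exposureManifest)
  mediators <- readManifest(config@mediatorManifest)
  outcome <- readSummaryTsv(config@outcomePath, traitType = "binary")
  note("load exposures=%d mediators=%d outcome=%s",
       length(exposures), length(mediators), traitId(outcome))

  fwd <- runPanel(exposures, outcome, config@criteria,
                  alpha = config@alpha, nBoot = config@nBoot,
                  seed = config@seed, direction = "forward")
  note("forward_panel results=%d significant=%d errors=%d",
       length(fwd$results), length(fwd$significant), length(fwd$errors))

  rev <- list()
  revErrors <- character(0)
  for (xid in names(fwd$results)) {
    r <- tryCatch(
      reverseMr(outcome, exposures[[xid]], config@criteria,
                nBoot = config@nBoot, seed = config@seed, methods = "ivw"),
      mrchainError = function(e) e)
    if (is(r, "MRSuiteResult")) rev[[xid]] <- r
    else revErrors[xid] <- conditionMessage(r)
  }
  note("reverse_panel results=%d errors=%d", length(rev), length(revErrors))

  direction <- list()
  for (xid in names(rev))
    direction[[xid]] <- classifyDirection(fwd$results[[xid]], rev[[xid]],
                                          config@alpha)
  eligible <- intersect(
    fwd$significant,
    names(direction)[vapply(direction, function(d) d@mediationEligible,
                            logical(1))])
  excluded <- names(direction)[vapply(direction, function(d)
    d@label == "bidirectional", logical(1))]
  note("direction eligible=%d bidirectional_excluded=%d",
       length(eligible), length(excluded))

  med <- screenMediators(exposures[eligible], mediators, outcome,
                         config@criteria, alpha = config@alpha,
                         nBoot = config@nBoot, seed = config@seed)
  note("mediation estimates=%d skipped=%d",
       length(med$estimates), nrow(med$skipped))

  paths <- c(forward = file.path(config@outputDir, "results_forward.tsv"),
             reverse = file.path(config@outputDir, "results_reverse.tsv"),
             direction = file.path(config@outputDir, "direction.tsv"),
             mediation = file.path(config@outputDir, "mediation.tsv"),
             drops = file.path(config@outputDir, "qc_drops.tsv"),
             manifest = file.path(config@outputDir, "run_manifest.txt"),
             log = file.path(config@outputDir, "study.log"))

  if (length(fwd$results)) {
    tab <- panelTable(fwd, config@alpha)
    utils::write.table(.formatNumerics(tab), paths["forward"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (length(rev)) writeResultsTsv(unname(rev), paths["reverse"])

  dirDf <- do.call(rbind, lapply(direction, function(d) data.frame(
    pair_id = d@pairId, forward_sig = d@forwardSig,
    reverse_sig = d@reverseSig, label = d@label,
    mediation_eligible = d@mediationEligible, stringsAsFactors = FALSE)))
  if (!is.null(dirDf))
    utils::write.table(dirDf, paths["direction"], sep = "\t", quote = FALSE,
                       row.names = FALSE)

  if (length(med$estimates))
    writeResultsTsv(unname(med$estimates), paths["mediation"])

  dropsDf <- do.call(rbind, lapply(names(fwd$results), function(xid) {
    d <- dropped(fwd$results[[xid]]@harmonized)
    if (nrow(d)) cbind(exposure_id = xid, d) else NULL
  }))
  if (is.null(dropsDf))
    dropsDf <- data.frame(exposure_id = character(0),
                          variant_id = character(0), reason = character(0))
  utils::write.table(dropsDf, paths["drops"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  writeLines(c(
    sprintf("config_digest: %s", .configDigest(config)),
    sprintf("seed: %d", config@seed),
    sprintf("alpha: %g", config@alpha),
    sprintf("package: mrchain %s",
            as.character(utils::packageVersion("mrchain"))),
    sprintf("inputs: %s | %s | %s", config@exposureManifest,
            config@mediatorManifest, config@outcomePath)),
    paths["manifest"])
  writeLines(log, paths["log"])

  structure(list(forward = fwd, reverse = rev, direction = direction,
                 mediation = med, paths = paths, log = log,
                 alpha = config@alpha),
            class = "mrStudyBundle")
}

.formatNumerics <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .fullPrecision)
  df
}

#' Format an odds ratio with its confidence interval
#'
#' @param or,ciLow,ciHigh numbers on the odds-ratio scale.
#' @return String like `"1.000 (0.822–1.217)"`.
#' @export
formatOrCi <- function(or, ciLow, ciHigh) {
  sprintf("%.3f (%.3f–%.3f)", or, ciLow, ciHigh)
}

#' Format a proportion mediated as a percentage
#'
#' @param prop proportion (0.246 prints as `"24.60%"`).
#' @return String.
#' @export
formatProportion <- function(prop) sprintf("%.2f%%", 100 * prop)

#' Render a plain-text study report
#'
#' Per-direction association tables sorted by p-value with OR (CI) strings
#' to three decimals, the direction classification, and mediation
#' proportions as percentages to two decimals.
#'
#' @param bundle result of [runStudy()].
#' @return Character vector of report lines, invisibly printed.
#' @export
renderReport <- function(bundle) {
  lines <- c("Causal-chain MR study report",
             strrep("=", 28), "")
  if (!length(bundle$forward$results) && !length(bundle$reverse)) {
    .mrWarning("empty bundle: nothing to report", "mrEmptyReportWarning")
    return(c(lines, "No results."))
  }
  fmtSuite <- function(r) {
    e <- estimate(r, .HEADLINE)
    sprintf("  %-12s -> %-12s  OR %s  p=%.3f  k=%d",
            r@exposureId, r@outcomeId,
            formatOrCi(e@or, e@ciLow, e@ciHigh), e@pval, r@k)
  }
  lines <- c(lines, "Forward MR (sorted by IVW p):",
             vapply(bundle$forward$results, fmtSuite, character(1)))
  sig <- bundle$forward$significant
  lines <- c(lines, "",
             if (length(sig))
               sprintf("Significant at alpha=%g: %s", bundle$alpha,
                       paste(sig, collapse = ", "))
             else "Zero significant forward findings.")
  if (length(bundle$reverse)) {
    ord <- order(vapply(bundle$reverse, function(r)
      estimate(r, .HEADLINE)@pval, numeric(1)))
    lines <- c(lines, "", "Reverse MR:",
               vapply(bundle$reverse[ord], fmtSuite, character(1)))
  }
  if (length(bundle$direction)) {
    lines <- c(lines, "", "Direction classification:",
               vapply(bundle$direction, function(d)
                 sprintf("  %-25s %s%s", d@pairId, d@label,
                         if (d@label == "bidirectional")
                           " [mediation ineligible]" else ""),
                 character(1)))
  }
  meds <- bundle$mediation$estimates
  lines <- c(lines, "", "Mediation:")
  if (length(meds)) {
    lines <- c(lines, vapply(meds, function(m) {
      prop <- if (m@propUndefined) "undefined"
              else formatProportion(m@propMediated)
      sprintf("  %s -> %s -> %s  [%s]  indirect=%.4f  proportion=%s%s",
              m@exposureId, m@mediatorId, m@outcomeId, m@method,
              m@indirect, prop,
              if (!m@signConsistent) "  [sign-inconsistent]" else "")
    }, character(1)))
  } else {
    lines <- c(lines, "  Zero mediation findings.")
  }
  unname(lines)
}
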