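#' Build an analysis configuration
#'
#' Describes a full study: which exposures (instrument sets) are tested
#' against which outcomes, with which estimators, and under which
#' thresholds. [runAnalysis()] executes it.
#'
#' @param exposures list of exposure descriptors; each a list with
#'   \code{name}, and either \code{set} (an [InstrumentSet-class]) or
#'   \code{path} (+ optional \code{columnMap}) pointing at a summary
#'   table; optional \code{unitLabel} and \code{exclusions} (character
#'   vector of SNP ids or a path to an exclusion-list file).
#' @param outcomes list of outcome descriptors; each a list with
#'   \code{label}, either \code{data} (canonical summary table) or
#'   \code{path} (+ optional \code{columnMap}); \code{scale}
#'   (\code{"log_odds"} or \code{"linear"}); and \code{transform} for the
#'   presentation scale (\code{"exp_or"}, \code{"lifespan_decade"} or
#'   \code{"identity"}).
#' @param methods named logical toggles: \code{ivw}, \code{weighted_median},
#'   \code{egger}, \code{presso}, \code{leave_one_out}. Missing entries
#'   default to TRUE for the estimator battery.
#' @param alpha two-sided significance level used for flagging (default
#'   0.05; no multiple-testing correction across exposures).
#' @param palindromePolicy,eafWindow harmonization settings, see
#'   [harmonize()].
#' @param presso list of MR-PRESSO settings: \code{nSim} (default 5000)
#'   and \code{outlierAlpha} (default 0.05).
#' @param nBoot weighted-median bootstrap replicates (default 1000).
#' @param seed integer master seed; every stochastic step derives its own
#'   reproducible sub-seed from it.
#' @return a validated configuration object (list with class
#'   \code{"mr_analysis_config"}).
#' @export
analysisConfig <- function(exposures, outcomes,
                           methods = list(),
                           alpha = 0.05,
                           palindromePolicy = "infer_by_eaf",
                           eafWindow = 0.08,
                           presso = list(),
                           nBoot = 1000L,
                           seed = 1L) {
  if (!length(exposures)) stop("config needs at least one exposure")
  if (!length(outcomes)) stop("config needs at least one outcome")
  m_def <- list(ivw = TRUE, weighted_median = TRUE, egger = TRUE,
                presso = TRUE, leave_one_out = TRUE)
  unknown <- setdiff(names(methods), names(m_def))
  if (length(unknown)) stop("unknown method toggle(s): ",
                            paste(unknown, collapse = ", "))
  m_def[names(methods)] <- methods
  p_def <- list(nSim = 5000L, outlierAlpha = 0.05)
  p_def[names(presso)] <- presso
  for (i in seq_along(exposures)) {
    e <- exposures[[i]]
    if (is.null(e$name)) stop("exposure ", i, " lacks a name")
    if (is.null(e$set) && is.null(e$path))
      stop("exposure '", e$name, "' needs 'set' or 'path'")
  }
  for (i in seq_along(outcomes)) {
    o <- outcomes[[i]]
    if (is.null(o$label)) stop("outcome ", i, " lacks a label")
    if (is.null(o$data) && is.null(o$path))
      stop("outcome '", o$label, "' needs 'data' or 'path'")
    scale <- if (is.null(o$scale)) "log_odds" else o$scale
    if (!scale %in% c("log_odds", "linear"))
      stop("outcome '", o$label, "': unknown scale '", scale, "'")
    transform <- if (is.null(o$transform)) "identity" else o$transform
    if (!transform %in% c("exp_or", "lifespan_decade", "identity"))
      stop("outcome '", o$label, "': unknown transform '", transform, "'")
    if (transform == "exp_or" && scale != "log_odds")
      stop("outcome '", o$label,
           "': exp_or transform requires the log_odds scale")
    if (transform == "lifespan_decade" && scale != "linear")
      stop("outcome '", o$label,
           "': lifespan_decade transform requires the linear scale")
    outcomes[[i]]$scale <- scale
    outcomes[[i]]$transform <- transform
  }
  structure(list(exposures = exposures, outcomes = outcomes,
                 methods = m_def, alpha = alpha,
                 palindromePolicy = palindromePolicy,
                 eafWindow = eafWindow, presso = p_def,
                 nBoot = as.integer(nBoot), seed = as.integer(seed)),
            class = "mr_analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' The YAML mirrors [analysisConfig()]'s arguments; file paths inside it
#' are resolved relative to the YAML file's directory.
#'
#' @param path YAML file path.
#' @return configuration object, as from [analysisConfig()].
#' @export
readAnalysisConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix_path <- function(item) {
    if (!is.null(item$path) && !file.exists(item$path))
      item$path <- file.path(base, item$path)
    item
  }
  y$exposures <- lapply(y$exposures, fix_path)
  y$outcomes <- lapply(y$outcomes, fix_path)
  do.call(analysisConfig, y)
}

.loadExposure <- function(e) {
  set <- if (!is.null(e$set)) e$set
  else {
    tab <- readSummaryTable(e$path, columnMap = e$columnMap)
    InstrumentSet(e$name, tab,
                  unitLabel = if (is.null(e$unitLabel)) "" else e$unitLabel,
                  sampleSize = if (is.null(e$sampleSize)) NA_real_ else
                    e$sampleSize,
                  varianceExplained = if (is.null(e$varianceExplained))
                    NA_real_ else e$varianceExplained)
  }
  if (!is.null(e$exclusions) && length(e$exclusions))
    set <- applyExclusions(set, e$exclusions)
  set
}

.loadOutcome <- function(o) {
  if (!is.null(o$data)) o$data
  else readSummaryTable(o$path, columnMap = o$columnMap)
}

.naRow <- function(exposure, outcome, method, n_snps, reason) {
  data.frame(exposure = exposure, outcome = outcome, method = method,
             n_snps = n_snps, estimate = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, pvalue = NA_real_,
             heterogeneity_p = NA_real_, egger_intercept = NA_real_,
             egger_intercept_p = NA_real_,
             presso_outlier_count = NA_integer_,
             presso_corrected_estimate = NA_real_,
             reason = reason, stringsAsFactors = FALSE)
}

.estRow <- function(exposure, outcome, method, est, transform,
                    het_p = NA_real_, eg_int = NA_real_,
                    eg_int_p = NA_real_, pr_count = NA_integer_,
                    pr_corr = NA_real_) {
  pres <- transformPresentation(est, transform)
  data.frame(exposure = exposure, outcome = outcome, method = method,
             n_snps = nSnps(est), estimate = pres$estimate,
             ci_low = pres$ci_low, ci_high = pres$ci_high,
             pvalue = pres$pvalue, heterogeneity_p = het_p,
             egger_intercept = eg_int, egger_intercept_p = eg_int_p,
             presso_outlier_count = pr_count,
             presso_corrected_estimate = pr_corr,
             reason = "ok", stringsAsFactors = FALSE)
}

#' Run the configured analysis battery
#'
#' For every exposure x outcome pair: loads the tables, applies
#' exclusions, harmonizes, and runs each enabled estimator, emitting one
#' result row per method on the outcome's presentation scale. Methods
#' needing more instruments than are available (weighted median and
#' MR-Egger need 3, MR-PRESSO needs 4) yield \code{NA} rows with a
#' machine-readable \code{reason} — nothing is skipped silently. The
#' estimator battery always runs in a fixed internal order with sub-seeds
#' derived per pair and method, so toggling methods on or off never
#' changes another method's estimate, and rerunning with the same seed
#' reproduces every row.
#'
#' @param config configuration from [analysisConfig()] or
#'   [readAnalysisConfig()].
#' @return \code{data.frame} of result rows: exposure, outcome, method,
#'   n_snps, estimate, ci_low, ci_high, pvalue, heterogeneity_p,
#'   egger_intercept, egger_intercept_p, presso_outlier_count,
#'   presso_corrected_estimate, reason.
#' @export
runAnalysis <- function(config) {
  stopifnot(inherits(config, "mr_analysis_config"))
  rows <- list()
  for (e in config$exposures) {
    set <- .loadExposure(e)
    for (o in config$outcomes) {
      out_tab <- .loadOutcome(o)
      hs <- harmonize(set, out_tab,
                      palindromePolicy = config$palindromePolicy,
                      eafWindow = config$eafWindow,
                      outcomeLabel = o$label, scale = o$scale)
      rows[[length(rows) + 1L]] <-
        .analyzePair(hs, e$name, o$label, o$transform, config)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

.analyzePair <- function(hs, exp_name, out_label, transform, config) {
  m <- config$methods
  J <- nSnps(hs)
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r

  if (J < 1L) {
    for (meth in names(m)[unlist(m)])
      add(.naRow(exp_name, out_label, meth, 0L, "no_instruments_after_harmonization"))
    return(do.call(rbind, rows))
  }

  ivw_fit <- mrIVW(hs)
  if (isTRUE(m$ivw)) {
    het_p <- if (J >= 2L) pValue(heterogeneity(ivw_fit)) else NA_real_
    method_label <- if (J == 1L) "wald_ratio" else "ivw_mre"
    add(.estRow(exp_name, out_label, method_label, ivw_fit@estimate,
                transform, het_p = het_p))
  }
  if (isTRUE(m$weighted_median)) {
    if (J >= 3L) {
      wm <- mrWeightedMedian(hs, nBoot = config$nBoot,
                             seed = .deriveSeed(config$seed, exp_name,
                                                out_label, "wm"))
      add(.estRow(exp_name, out_label, "weighted_median", wm, transform))
    } else add(.naRow(exp_name, out_label, "weighted_median", J,
                      "needs_3_instruments"))
  }
  if (isTRUE(m$egger)) {
    if (J >= 3L) {
      eg <- mrEgger(hs)
      add(.estRow(exp_name, out_label, "egger_slope", eg@slope, transform,
                  eg_int = estimate(eg@intercept),
                  eg_int_p = pValue(eg@intercept)))
    } else add(.naRow(exp_name, out_label, "egger_slope", J,
                      "needs_3_instruments"))
  }
  if (isTRUE(m$presso)) {
    if (J >= 4L) {
      pr <- mrPresso(hs, nSim = config$presso$nSim,
                     outlierAlpha = config$presso$outlierAlpha,
                     seed = .deriveSeed(config$seed, exp_name, out_label,
                                        "presso"))
      n_out <- length(outliers(pr))
      corr <- if (n_out) correctedEstimate(pr) else ivw_fit@estimate
      pres_corr <- transformPresentation(corr, transform)
      row <- .estRow(exp_name, out_label, "presso", corr, transform,
                     pr_count = n_out, pr_corr = pres_corr$estimate)
      row$heterogeneity_p <- globalPvalue(pr)
      add(row)
    } else add(.naRow(exp_name, out_label, "presso", J,
                      "needs_4_instruments"))
  }
  if (isTRUE(m$leave_one_out)) {
    if (J >= 3L) {
      loo <- mrLeaveOneOut(hs)
      rng <- range(vapply(loo, estimate, numeric(1)))
      full <- loo[["(all)"]]
      row <- .estRow(exp_name, out_label, "leave_one_out", full, transform)
      row$reason <- sprintf("loo_range=[%.6g,%.6g]", rng[1], rng[2])
      add(row)
    } else add(.naRow(exp_name, out_label, "leave_one_out", J,
                      "needs_3_instruments"))
  }
  do.call(rbind, rows)
}

#' Transform an estimate onto its presentation scale
#'
#' \describe{
#'   \item{\code{exp_or}}{exponentiates a log-odds estimate and its CI to
#'     an odds ratio (errors on linear-scale estimates);}
#'   \item{\code{lifespan_decade}}{multiplies a linear estimate and CI by
#'     ten — lifespan years per 10-fold (decadic) exposure increase;}
#'   \item{\code{identity}}{returns the estimate unchanged.}
#' }
#' The p-value is never touched (the transforms are monotone).
#'
#' @param est an [MREstimate-class].
#' @param transform \code{"exp_or"}, \code{"lifespan_decade"} or
#'   \code{"identity"}.
#' @return list: \code{estimate}, \code{ci_low}, \code{ci_high},
#'   \code{pvalue}.
#' @export
transformPresentation <- function(est,
    transform = c("identity", "exp_or", "lifespan_decade")) {
  transform <- match.arg(transform)
  b <- estimate(est); ci <- confInt(est)
  if (transform == "exp_or") {
    if (effectScale(est) != "log_odds")
      stop("exp_or transform requires a log_odds-scale estimate")
    b <- exp(b); ci <- exp(ci)
  } else if (transform == "lifespan_decade") {
    if (effectScale(est) != "linear")
      stop("lifespan_decade transform requires a linear-scale estimate")
    b <- 10 * b; ci <- 10 * ci
  }
  list(estimate = b, ci_low = ci[1], ci_high = ci[2], pvalue = pValue(est))
}

#' IVW-only panel across longevity risk factors
#'
#' Runs the exposures against a panel of risk-factor outcomes (years of
#' education, smoking initiation, type 2 diabetes, BMI, LDL-c, HDL-c,
#' hypertension — any subset) using the IVW estimator only, reporting on
#' the beta scale. One row per exposure x risk factor.
#'
#' @param config configuration whose outcomes are the risk factors.
#' @return result \code{data.frame} as from [runAnalysis()], IVW rows only.
#' @export
riskFactorPanel <- function(config) {
  stopifnot(inherits(config, "mr_analysis_config"))
  config$methods <- list(ivw = TRUE, weighted_median = FALSE,
                         egger = FALSE, presso = FALSE,
                         leave_one_out = FALSE)
  runAnalysis(config)
}

#' Write a result table as TSV
#'
#' @param results result \code{data.frame} from [runAnalysis()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeResultTable <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
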