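#' @import methods
NULL

## Canonical column set for a table of SNP-trait summary associations.
## eaf, pval and n may be NA (several source GWASs omit them).
.SUMMARY_COLS <- c("snp", "effect_allele", "other_allele", "eaf",
                   "beta", "se", "pval", "n")
.SUMMARY_MANDATORY <- c("snp", "effect_allele", "other_allele", "beta", "se")

#' InstrumentSet: genetic instruments for one exposure
#'
#' Container for the SNPs instrumenting a single exposure (for example,
#' circulating lycopene), together with metadata about the source GWAS:
#' sample size, ancestry, the significance threshold used to select
#' instruments, and the fraction of exposure variance the instruments
#' explain (R-squared).
#'
#' @slot exposure exposure label.
#' @slot unitLabel free-text description of one exposure unit
#'   (e.g. \code{"ln-transformed"}, \code{"1 mmol/l"}, \code{"log10 units"}).
#' @slot snps \code{data.frame} of summary associations with columns
#'   \code{snp}, \code{effect_allele}, \code{other_allele}, \code{eaf},
#'   \code{beta}, \code{se}, \code{pval}, \code{n}.
#' @slot sampleSize exposure GWAS sample size (may be \code{NA}).
#' @slot ancestry ancestry label (may be \code{NA}).
#' @slot pThreshold instrument-selection significance threshold (may be \code{NA}).
#' @slot varianceExplained fraction of exposure variance explained, in (0,1),
#'   or \code{NA} when the source GWAS does not report one.
#'
#' @seealso [InstrumentSet()] constructor, [applyExclusions()], [harmonize()]
#' @export
setClass("InstrumentSet",
  representation(
    exposure = "character",
    unitLabel = "character",
    snps = "data.frame",
    sampleSize = "numeric",
    ancestry = "character",
    pThreshold = "numeric",
    varianceExplained = "numeric"
  )
)

setValidity("InstrumentSet", function(object) {
  msg <- character()
  snps <- object@snps
  missing_cols <- setdiff(.SUMMARY_COLS, names(snps))
  if (length(missing_cols))
    msg <- c(msg, paste("snps table lacks columns:",
                        paste(missing_cols, collapse = ", ")))
  else {
    if (nrow(snps) < 1L) msg <- c(msg, "instrument set must contain at least 1 SNP")
    if (anyDuplicated(snps$snp))
      msg <- c(msg, "duplicated SNP identifiers within instrument set")
    if (any(!is.na(snps$se) & snps$se <= 0))
      msg <- c(msg, "all standard errors must be positive")
    if (any(!is.na(snps$eaf) & (snps$eaf < 0 | snps$eaf > 1)))
      msg <- c(msg, "effect-allele frequencies must lie in [0,1]")
  }
  ve <- object@varianceExplained
  if (!is.na(ve) && (ve <= 0 || ve >= 1))
    msg <- c(msg, "varianceExplained must lie strictly in (0,1)")
  if (length(msg)) msg else TRUE
})

#' HarmonizedSet: exposure/outcome effects aligned to a shared effect allele
#'
#' Result of [harmonize()]. Every exposure SNP appears exactly once with
#' an \code{action} recording how (or whether) it was aligned:
#' \code{aligned}, \code{flipped}, \code{dropped_palindromic},
#' \code{dropped_missing} or \code{dropped_incompatible}. Estimators use
#' only the retained rows (\code{aligned}/\code{flipped}).
#'
#' @slot exposure exposure label carried from the instrument set.
#' @slot outcome outcome label.
#' @slot scale outcome effect scale, \code{"log_odds"} or \code{"linear"}.
#' @slot data \code{data.frame} with columns \code{snp}, \code{beta_exp},
#'   \code{se_exp}, \code{beta_out}, \code{se_out}, \code{eaf_exp},
#'   \code{eaf_out}, \code{action}.
#' @export
setClass("HarmonizedSet",
  representation(
    exposure = "character",
    outcome = "character",
    scale = "character",
    data = "data.frame"
  )
)

setValidity("HarmonizedSet", function(object) {
  msg <- character()
  d <- object@data
  need <- c("snp", "beta_exp", "se_exp", "beta_out", "se_out",
            "eaf_exp", "eaf_out", "action")
  if (!all(need %in% names(d)))
    msg <- c(msg, "harmonized data lacks required columns")
  else {
    keep <- d$action %in% c("aligned", "flipped")
    if (any(keep & (is.na(d$se_exp) | d$se_exp <= 0)))
      msg <- c(msg, "retained rows must have positive exposure SE")
    if (any(keep & (is.na(d$se_out) | d$se_out <= 0)))
      msg <- c(msg, "retained rows must have positive outcome SE")
    ok_actions <- c("aligned", "flipped", "dropped_palindromic",
                    "dropped_missing", "dropped_incompatible")
    if (!all(d$action %in% ok_actions))
      msg <- c(msg, "unknown harmonization action")
  }
  if (!object@scale %in% c("log_odds", "linear"))
    msg <- c(msg, "scale must be 'log_odds' or 'linear'")
  if (length(msg)) msg else TRUE
})

#' MREstimate: a causal-effect estimate with its uncertainty
#'
#' @slot method estimator label: one of \code{wald_ratio}, \code{ivw_mre},
#'   \code{weighted_median}, \code{egger_slope}, \code{egger_intercept},
#'   \code{presso_corrected}.
#' @slot beta causal estimate (outcome units per exposure unit; log-odds
#'   for binary outcomes).
#' @slot se standard error (> 0).
#' @slot ciLow,ciHigh normal-theory 95\% confidence bounds.
#' @slot pvalue two-sided normal p-value (chi-square for heterogeneity
#'   results, which use their own class).
#' @slot nSnps number of instruments contributing.
#' @slot scale \code{"log_odds"} or \code{"linear"}.
#' @export
setClass("MREstimate",
  representation(
    method = "character",
    beta = "numeric",
    se = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    pvalue = "numeric",
    nSnps = "integer",
    scale = "character"
  )
)

setValidity("MREstimate", function(object) {
  msg <- character()
  if (!is.na(object@se) && object@se <= 0) msg <- c(msg, "se must be positive")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      object@ciLow > object@ciHigh)
    msg <- c(msg, "confidence bounds out of order")
  if (!object@scale %in% c("log_odds", "linear"))
    msg <- c(msg, "scale must be 'log_odds' or 'linear'")
  if (length(msg)) msg else TRUE
})

#' HeterogeneityResult: Cochran's Q test
#'
#' @slot q Cochran's Q statistic (>= 0).
#' @slot df degrees of freedom (number of instruments minus one).
#' @slot pvalue upper-tail chi-square probability.
#' @export
setClass("HeterogeneityResult",
  representation(q = "numeric", df = "integer", pvalue = "numeric")
)

setValidity("HeterogeneityResult", function(object) {
  msg <- character()
  if (object@q < 0) msg <- c(msg, "Q must be nonnegative")
  if (object@df < 1L) msg <- c(msg, "df must be >= 1")
  if (length(msg)) msg else TRUE
})

#' IVWResult: pooled IVW estimate plus its heterogeneity test
#'
#' @slot estimate the pooled [MREstimate-class].
#' @slot heterogeneity the accompanying [HeterogeneityResult-class].
#' @export
setClass("IVWResult",
  representation(estimate = "MREstimate", heterogeneity = "HeterogeneityResult")
)

#' EggerResult: MR-Egger slope and intercept
#'
#' @slot slope pleiotropy-corrected causal estimate.
#' @slot intercept average directional pleiotropy per instrument.
#' @export
setClass("EggerResult",
  representation(slope = "MREstimate", intercept = "MREstimate")
)

#' PressoResult: MR-PRESSO global, outlier and distortion tests
#'
#' @slot rssObserved observed residual sum of squares.
#' @slot globalPvalue Monte-Carlo global heterogeneity p-value; bounded
#'   below by 1/(nSim + 1).
#' @slot outlierPvalues named per-SNP Bonferroni-adjusted outlier p-values.
#' @slot outliers SNP identifiers flagged as outliers.
#' @slot corrected [MREstimate-class] after outlier removal, or \code{NULL}
#'   when no outlier was flagged.
#' @slot distortionPvalue distortion-test p-value (\code{NA} when no
#'   outlier was flagged).
#' @slot nSim number of null simulations.
#' @slot seed RNG seed used.
#' @export
setClass("PressoResult",
  representation(
    rssObserved = "numeric",
    globalPvalue = "numeric",
    outlierPvalues = "numeric",
    outliers = "character",
    corrected = "ANY",
    distortionPvalue = "numeric",
    nSim = "integer",
    seed = "integer"
  )
)

setValidity("PressoResult", function(object) {
  msg <- character()
  if (object@globalPvalue < 1 / (object@nSim + 1) - 1e-12)
    msg <- c(msg, "globalPvalue below its Monte-Carlo floor")
  has_out <- length(object@outliers) > 0L
  if (has_out && is.null(object@corrected))
    msg <- c(msg, "corrected estimate must be present when outliers are flagged")
  if (!has_out && !is.null(object@corrected))
    msg <- c(msg, "corrected estimate must be absent when no outlier is flagged")
  if (length(msg)) msg else TRUE
})

#' SimulationScenario: ground-truth configuration for synthetic summary data
#'
#' @slot nSnps number of instruments (>= 2).
#' @slot theta true causal effect of the exposure on the outcome.
#' @slot exposureN,outcomeN GWAS sample sizes.
#' @slot mafRange minor-allele-frequency interval within (0, 0.5].
#' @slot betaXScale per-allele exposure effect magnitude (SD of the
#'   half-normal draw).
#' @slot pleiotropy list describing the pleiotropy regime; see
#'   [simulationScenario()].
#' @slot outcomeScale list: \code{type} (\code{"linear"}/\code{"log_odds"})
#'   and \code{caseFraction} for binary outcomes.
#' @slot seed integer seed governing the whole scenario.
#' @export
setClass("SimulationScenario",
  representation(
    nSnps = "integer",
    theta = "numeric",
    exposureN = "numeric",
    outcomeN = "numeric",
    mafRange = "numeric",
    betaXScale = "numeric",
    pleiotropy = "list",
    outcomeScale = "list",
    seed = "integer"
  )
)

setValidity("SimulationScenario", function(object) {
  msg <- character()
  if (object@nSnps < 2L) msg <- c(msg, "nSnps must be >= 2")
  r <- object@mafRange
  if (length(r) != 2L || r[1] <= 0 || r[2] > 0.5 || r[1] > r[2])
    msg <- c(msg, "mafRange must be an interval within (0, 0.5]")
  pl <- object@pleiotropy
  if (!pl$type %in% c("none", "balanced", "directional", "outliers"))
    msg <- c(msg, "unknown pleiotropy type")
  if (pl$type %in% c("balanced", "directional") && pl$tau < 0)
    msg <- c(msg, "tau must be nonnegative")
  if (pl$type == "outliers" && !is.null(pl$fraction) &&
      (pl$fraction <= 0 || pl$fraction >= 1))
    msg <- c(msg, "outlier fraction must lie in (0,1)")
  os <- object@outcomeScale
  if (!os$type %in% c("linear", "log_odds"))
    msg <- c(msg, "outcome scale must be 'linear' or 'log_odds'")
  if (os$type == "log_odds" &&
      (is.null(os$caseFraction) || os$caseFraction <= 0 || os$caseFraction >= 1))
    msg <- c(msg, "log-odds outcomes need caseFraction in (0,1)")
  if (length(msg)) msg else TRUE
})
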