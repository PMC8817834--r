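#' Accessors for MR estimates and diagnostic results
#'
#' @param object an [MREstimate-class], [IVWResult-class],
#'   [HeterogeneityResult-class] or [PressoResult-class].
#' @return the corresponding scalar (or two-element vector for
#'   \code{confInt}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("estimate", "MREstimate", function(object) object@beta)
#' @rdname accessors
#' @export
setMethod("stdError", "MREstimate", function(object) object@se)
#' @rdname accessors
#' @export
setMethod("pValue", "MREstimate", function(object) object@pvalue)
#' @rdname accessors
#' @export
setMethod("confInt", "MREstimate",
          function(object) c(object@ciLow, object@ciHigh))
#' @rdname accessors
#' @export
setMethod("nSnps", "MREstimate", function(object) object@nSnps)
#' @rdname accessors
#' @export
setMethod("effectScale", "MREstimate", function(object) object@scale)
#' @rdname accessors
#' @export
setMethod("methodLabel", "MREstimate", function(object) object@method)

#' @rdname accessors
#' @export
setMethod("estimate", "IVWResult", function(object) estimate(object@estimate))
#' @rdname accessors
#' @export
setMethod("stdError", "IVWResult", function(object) stdError(object@estimate))
#' @rdname accessors
#' @export
setMethod("pValue", "IVWResult", function(object) pValue(object@estimate))
#' @rdname accessors
#' @export
setMethod("confInt", "IVWResult", function(object) confInt(object@estimate))
#' @rdname accessors
#' @export
setMethod("nSnps", "IVWResult", function(object) nSnps(object@estimate))
#' @rdname mrIVW
#' @export
setMethod("heterogeneity", "IVWResult", function(object) object@heterogeneity)

#' @rdname accessors
#' @export
setMethod("pValue", "HeterogeneityResult", function(object) object@pvalue)

#' Accessors for instrument sets
#'
#' @param object an [InstrumentSet-class].
#' @return the exposure label, unit label, SNP summary table or
#'   instrument count.
#' @name instrumentset-accessors
NULL

#' @rdname instrumentset-accessors
#' @export
setMethod("exposureName", "InstrumentSet", function(object) object@exposure)
#' @rdname instrumentset-accessors
#' @export
setMethod("unitLabel", "InstrumentSet", function(object) object@unitLabel)
#' @rdname instrumentset-accessors
#' @export
setMethod("snpTable", "InstrumentSet", function(object) object@snps)
#' @rdname instrumentset-accessors
#' @export
setMethod("nSnps", "InstrumentSet", function(object) nrow(object@snps))

#' @rdname harmonize
#' @export
setMethod("nSnps", "HarmonizedSet", function(object)
  sum(object@data$action %in% c("aligned", "flipped")))

#' @rdname mrPresso
#' @export
setMethod("globalPvalue", "PressoResult", function(object) object@globalPvalue)
#' @rdname mrPresso
#' @export
setMethod("outliers", "PressoResult", function(object) object@outliers)
#' @rdname mrPresso
#' @export
setMethod("correctedEstimate", "PressoResult", function(object) object@corrected)
#' @rdname mrPresso
#' @export
setMethod("distortionPvalue", "PressoResult",
          function(object) object@distortionPvalue)

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s] (%s scale, %d SNPs)\n",
              object@method, object@scale, object@nSnps))
  cat(sprintf("  beta = %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              object@beta, object@se, object@ciLow, object@ciHigh,
              object@pvalue))
})

setMethod("show", "IVWResult", function(object) {
  show(object@estimate)
  h <- object@heterogeneity
  cat(sprintf("  Cochran's Q = %.4g on %d df, p = %.3g\n",
              h@q, h@df, h@pvalue))
})

setMethod("show", "EggerResult", function(object) {
  cat("MR-Egger regression\n")
  cat(sprintf("  slope:     %.4g (SE %.4g), p = %.3g\n",
              object@slope@beta, object@slope@se, object@slope@pvalue))
  cat(sprintf("  intercept: %.4g (SE %.4g), p = %.3g\n",
              object@intercept@beta, object@intercept@se,
              object@intercept@pvalue))
})

setMethod("show", "HeterogeneityResult", function(object) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g\n",
              object@q, object@df, object@pvalue))
})

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf("InstrumentSet '%s' (%s): %d SNPs\n",
              object@exposure, object@unitLabel, nrow(object@snps)))
  if (!is.na(object@sampleSize))
    cat(sprintf("  source GWAS n = %s", format(object@sampleSize, big.mark = ",")))
  if (!is.na(object@varianceExplained))
    cat(sprintf(", variance explained = %.1f%%", 100 * object@varianceExplained))
  cat("\n")
})

setMethod("show", "HarmonizedSet", function(object) {
  tab <- table(object@data$action)
  cat(sprintf("HarmonizedSet: %s -> %s (%s scale)\n",
              object@exposure, object@outcome, object@scale))
  cat("  actions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("MR-PRESSO (%d simulations, seed %d)\n",
              object@nSim, object@seed))
  cat(sprintf("  RSS = %.4g, global p = %.4g\n",
              object@rssObserved, object@globalPvalue))
  if (length(object@outliers)) {
    cat("  outliers:", paste(object@outliers, collapse = ", "), "\n")
    cat(sprintf("  corrected beta = %.4g (p = %.3g), distortion p = %.3g\n",
                object@corrected@beta, object@corrected@pvalue,
                object@distortionPvalue))
  } else {
    cat("  no outliers detected\n")
  }
})

setMethod("show", "SimulationScenario", function(object) {
  cat(sprintf(
    "SimulationScenario: %d SNPs, theta = %.3g, n_exp = %s, n_out = %s\n",
    object@nSnps, object@theta,
    format(object@exposureN, big.mark = ","),
    format(object@outcomeN, big.mark = ",")))
  cat(sprintf("  pleiotropy: %s; outcome scale: %s; seed %d\n",
              object@pleiotropy$type, object@outcomeScale$type, object@seed))
})
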