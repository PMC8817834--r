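#' Variance explained by one SNP
#'
#' For a biallelic SNP with standardized per-allele effect \eqn{\beta} on
#' an exposure with unit variance, the fraction of exposure variance
#' explained is \deqn{R^2 = 2 \beta^2 \, MAF (1 - MAF),} i.e. the effect
#' squared times the genotype variance under Hardy-Weinberg equilibrium.
#'
#' @param beta standardized per-allele effect on the exposure.
#' @param maf minor-allele frequency, in (0, 0.5].
#' @return the variance fraction (vectorized over both arguments).
#' @export
snpR2 <- function(beta, maf) {
  if (any(maf <= 0 | maf > 0.5))
    stop("maf must lie in (0, 0.5]")
  2 * beta^2 * maf * (1 - maf)
}

#' F statistic for instrument strength
#'
#' \deqn{F = \frac{R^2 (n - k - 1)}{k (1 - R^2)}} where \eqn{R^2} is the
#' exposure variance explained by the k instruments jointly and n is the
#' exposure GWAS sample size. Values above 10 conventionally indicate that
#' weak-instrument bias is small; anything lower triggers a warning.
#'
#' @param r2 variance explained, in (0,1).
#' @param n exposure GWAS sample size (must exceed k + 1).
#' @param k number of instruments (>= 1).
#' @param warnWeak warn when F < 10 (default TRUE).
#' @return the F statistic.
#' @export
fStatistic <- function(r2, n, k, warnWeak = TRUE) {
  if (any(r2 <= 0 | r2 >= 1)) stop("r2 must lie strictly in (0,1)")
  if (any(k < 1)) stop("k must be >= 1")
  if (any(n <= k + 1)) stop("n must exceed k + 1")
  f <- r2 * (n - k - 1) / (k * (1 - r2))
  if (warnWeak && any(f < 10))
    warning("F statistic below 10: possible weak-instrument bias")
  f
}

#' Instrument-strength report for an InstrumentSet
#'
#' Uses the set-level variance explained when the source GWAS reports one;
#' otherwise sums per-SNP \eqn{R^2} values from [snpR2()] (instruments are
#' assumed uncorrelated, i.e. LD-pruned at source — the standard selection
#' practice).
#'
#' @param instruments an [InstrumentSet-class]; needs \code{sampleSize}
#'   and either \code{varianceExplained} or per-SNP beta and eaf.
#' @return list with components \code{r2}, \code{f_stat}, \code{n},
#'   \code{k}, and \code{per_snp_r2} (NULL when the set-level value was
#'   used directly).
#' @export
strengthReport <- function(instruments) {
  stopifnot(is(instruments, "InstrumentSet"))
  n <- instruments@sampleSize
  if (is.na(n)) stop("missing field: sampleSize")
  k <- nrow(instruments@snps)
  per_snp <- NULL
  r2 <- instruments@varianceExplained
  if (is.na(r2)) {
    tab <- instruments@snps
    if (any(is.na(tab$eaf)))
      stop("missing field: eaf (needed to compute per-SNP R2)")
    maf <- pmin(tab$eaf, 1 - tab$eaf)
    per_snp <- snpR2(tab$beta, maf)
    r2 <- sum(per_snp)
  }
  list(r2 = r2, f_stat = fStatistic(r2, n, k), n = n, k = k,
       per_snp_r2 = per_snp)
}

#' Strength and power report table for an instrument set
#'
#' One row per hypothesized effect size: the set's variance explained,
#' F statistic, and IVW power against the given outcome.
#'
#' @param instruments an [InstrumentSet-class] (see [strengthReport()]).
#' @param effects vector of hypothesized causal effects.
#' @param nOutcome outcome GWAS sample size.
#' @param outcomeLabel outcome label for the table.
#' @param alpha two-sided level.
#' @param caseFraction case fraction for binary outcomes, or \code{NULL}.
#' @return \code{data.frame}: exposure, r2, n, k, f_stat, outcome,
#'   effect, power. Write it with \code{write.table(..., sep = "\t")}.
#' @export
strengthPowerTable <- function(instruments, effects, nOutcome,
                               outcomeLabel = "outcome", alpha = 0.05,
                               caseFraction = NULL) {
  rep <- strengthReport(instruments)
  pw <- vapply(effects, function(e)
    powerIVW(rep$r2, e, nOutcome, alpha, caseFraction)$power, numeric(1))
  data.frame(exposure = exposureName(instruments), r2 = rep$r2,
             n = rep$n, k = rep$k, f_stat = rep$f_stat,
             outcome = outcomeLabel, effect = effects, power = pw,
             stringsAsFactors = FALSE)
}

#' Statistical power of the IVW analysis
#'
#' Noncentrality approximation behind the standard two-sample MR power
#' calculators: the IVW z statistic is approximately normal with mean
#' \eqn{\sqrt{n \, R^2}\,|\theta|} (continuous outcomes), giving
#' \deqn{power = \Phi(\sqrt{n R^2}\,|\theta| - z_{1-\alpha/2}) +
#'       \Phi(-\sqrt{n R^2}\,|\theta| - z_{1-\alpha/2}).}
#' For binary outcomes \eqn{|\theta|} is the log odds ratio scaled by
#' \eqn{\sqrt{cf(1-cf)}} with cf the case fraction, reflecting the reduced
#' information of a binary response.
#'
#' @param r2 exposure variance explained by the instruments, in (0,1).
#' @param effect hypothesized causal effect (outcome units, or log-OR for
#'   binary outcomes, per exposure unit).
#' @param nOutcome outcome GWAS sample size.
#' @param alpha two-sided significance level (default 0.05).
#' @param caseFraction case fraction for binary outcomes; \code{NULL}
#'   (default) means a continuous outcome. Binary calls without it are an
#'   error.
#' @param binary treat the outcome as binary (default: TRUE iff
#'   \code{caseFraction} is given).
#' @return list with components \code{power}, \code{alpha}, \code{effect},
#'   \code{n_outcome}, \code{case_fraction}.
#' @references Brion MJ, Shakhbazov K, Visscher PM (2013) Calculating
#'   statistical power in Mendelian randomization studies. Int J Epidemiol
#'   42:1497-1501.
#' @export
powerIVW <- function(r2, effect, nOutcome, alpha = 0.05,
                     caseFraction = NULL, binary = !is.null(caseFraction)) {
  if (any(r2 <= 0 | r2 >= 1)) stop("r2 must lie strictly in (0,1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  b <- abs(effect)
  if (binary) {
    if (is.null(caseFraction))
      stop("missing field: caseFraction (required for binary outcomes)")
    if (caseFraction <= 0 || caseFraction >= 1)
      stop("caseFraction must lie in (0,1)")
    b <- b * sqrt(caseFraction * (1 - caseFraction))
  }
  z <- stats::qnorm(1 - alpha / 2)
  ncp <- sqrt(nOutcome * r2) * b
  pw <- stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
  list(power = pw, alpha = alpha, effect = effect, n_outcome = nOutcome,
       case_fraction = if (binary) caseFraction else NA_real_)
}
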