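#' Wald ratio estimate from a single instrument
#'
#' The per-SNP causal estimate: the SNP-outcome effect divided by the
#' SNP-exposure effect. The default standard error is the first-order
#' delta-method approximation \eqn{\sigma_Y / |\beta_X|}, which ignores
#' exposure-side uncertainty and matches the weighting the IVW pooling
#' uses; \code{secondOrder = TRUE} adds the exposure-side term
#' \eqn{\sqrt{\sigma_Y^2/\beta_X^2 + \beta_Y^2\sigma_X^2/\beta_X^4}}.
#'
#' @param inst one harmonized instrument: a single-row data.frame (or
#'   [HarmonizedSet-class] with exactly one retained SNP) carrying
#'   \code{beta_exp}, \code{se_exp}, \code{beta_out}, \code{se_out}.
#' @param secondOrder use the second-order delta-method SE.
#' @param scale outcome scale label carried into the estimate.
#' @return an [MREstimate-class] with method \code{"wald_ratio"}.
#' @export
waldRatio <- function(inst, secondOrder = FALSE, scale = NULL) {
  d <- .mrData(inst, scale)
  if (length(d$bx) != 1L)
    stop("waldRatio expects exactly one instrument; got ", length(d$bx))
  if (d$bx == 0) stop("beta_exp is zero: Wald ratio undefined")
  theta <- d$by / d$bx
  se <- if (secondOrder)
    sqrt(d$sy^2 / d$bx^2 + d$by^2 * d$sx^2 / d$bx^4)
  else d$sy / abs(d$bx)
  .newEstimate("wald_ratio", theta, se, 1L, d$scale)
}

#' Inverse-variance weighted estimate (multiplicative random effects)
#'
#' Pools per-SNP Wald ratios \eqn{\theta_j = \beta_{Yj}/\beta_{Xj}} with
#' first-order inverse-variance weights \eqn{w_j = \beta_{Xj}^2/\sigma_{Yj}^2}:
#' \deqn{\hat\theta = \sum w_j \theta_j / \sum w_j,}
#' equivalent to the zero-intercept weighted regression of outcome on
#' exposure effects. Cochran's Q, \eqn{Q = \sum w_j(\theta_j - \hat\theta)^2},
#' measures heterogeneity; under the multiplicative random-effects model the
#' fixed-effect SE \eqn{(\sum w_j)^{-1/2}} is inflated by
#' \eqn{\max(1, \sqrt{Q/(J-1)})} — overdispersion widens the interval,
#' underdispersion never narrows it.
#'
#' With a single instrument the function degrades to the Wald ratio with a
#' logged notice.
#'
#' @param insts a [HarmonizedSet-class] or data.frame of harmonized
#'   instruments.
#' @param scale optional outcome scale override.
#' @return an [IVWResult-class] holding the pooled [MREstimate-class]
#'   (method \code{"ivw_mre"}) and the [HeterogeneityResult-class].
#' @references Burgess S, Butterworth A, Thompson SG (2013) Mendelian
#'   randomization analysis with multiple genetic variants using summarized
#'   data. Genet Epidemiol 37:658-665.
#' @export
mrIVW <- function(insts, scale = NULL) {
  d <- .mrData(insts, scale)
  J <- length(d$bx)
  if (J < 1L) stop("no usable instruments")
  if (J == 1L) {
    message("single instrument: IVW degrades to the Wald ratio")
    est <- waldRatio(data.frame(beta_exp = d$bx, se_exp = d$sx,
                                beta_out = d$by, se_out = d$sy),
                     scale = d$scale)
    het <- new("HeterogeneityResult", q = 0, df = 1L, pvalue = NA_real_)
    return(new("IVWResult", estimate = est, heterogeneity = het))
  }
  w <- d$bx^2 / d$sy^2
  if (!any(is.finite(w) & w > 0)) stop("all IVW weights zero or non-finite")
  theta_j <- d$by / d$bx
  theta <- sum(w * theta_j) / sum(w)
  se_fe <- 1 / sqrt(sum(w))
  q <- sum(w * (theta_j - theta)^2)
  scale_mre <- max(1, sqrt(q / (J - 1)))
  est <- .newEstimate("ivw_mre", theta, se_fe * scale_mre, J, d$scale)
  het <- new("HeterogeneityResult", q = q, df = J - 1L,
             pvalue = stats::pchisq(q, J - 1, lower.tail = FALSE))
  new("IVWResult", estimate = est, heterogeneity = het)
}

#' Cochran's Q heterogeneity test for an instrument set
#'
#' @inheritParams mrIVW
#' @return a [HeterogeneityResult-class].
#' @export
cochranQ <- function(insts, scale = NULL) heterogeneity(mrIVW(insts, scale))

## weighted-median point estimate on precomputed ratios/weights:
## linear interpolation of the order statistics at standardized
## midpoint cumulative weight 0.5
.weightedMedianPoint <- function(theta_j, w) {
  o <- order(theta_j)
  th <- theta_j[o]; wo <- w[o]
  s <- (cumsum(wo) - wo / 2) / sum(wo)
  if (0.5 <= s[1]) return(th[1])
  k <- max(which(s < 0.5))
  if (k == length(th)) return(th[length(th)])
  th[k] + (th[k + 1] - th[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Weighted median estimate
#'
#' Consistent when instruments contributing more than half the total weight
#' are valid. Ratio estimates are sorted; the estimate is the linear
#' interpolation of the order statistics at standardized midpoint
#' cumulative weight 0.5, with inverse-variance weights
#' \eqn{w_j = \beta_{Xj}^2/\sigma_{Yj}^2}. The standard error comes from a
#' seeded parametric bootstrap: exposure and outcome effects are resampled
#' from normal distributions centred on their estimates and the median
#' recomputed.
#'
#' @inheritParams mrIVW
#' @param nBoot bootstrap replicates (default 1000; fewer than 100 warns).
#' @param seed integer RNG seed (mandatory: the bootstrap must be
#'   reproducible).
#' @return an [MREstimate-class] with method \code{"weighted_median"}.
#' @references Bowden J, Davey Smith G, Haycock PC, Burgess S (2016)
#'   Consistent estimation in Mendelian randomization with some invalid
#'   instruments using a weighted median estimator. Genet Epidemiol
#'   40:304-314.
#' @export
mrWeightedMedian <- function(insts, nBoot = 1000L, seed, scale = NULL) {
  if (missing(seed)) stop("a seed is required for the bootstrap SE")
  d <- .mrData(insts, scale)
  J <- length(d$bx)
  if (J < 3L) stop("weighted median needs at least 3 instruments")
  if (nBoot < 100L) warning("nBoot < 100: bootstrap SE will be unstable")
  w <- d$bx^2 / d$sy^2
  point <- .weightedMedianPoint(d$by / d$bx, w)
  boot <- withr_seed(seed, {
    vapply(seq_len(nBoot), function(b) {
      bx <- stats::rnorm(J, d$bx, d$sx)
      by <- stats::rnorm(J, d$by, d$sy)
      .weightedMedianPoint(by / bx, bx^2 / d$sy^2)
    }, numeric(1))
  })
  .newEstimate("weighted_median", point, stats::sd(boot), J, d$scale)
}

## evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with an
#' unconstrained intercept (weights \eqn{1/\sigma_{Yj}^2}). The slope is a
#' pleiotropy-corrected causal estimate; the intercept estimates the average
#' directional pleiotropy per instrument — an intercept compatible with zero
#' is evidence against directional pleiotropy. Instruments are first
#' oriented so every exposure effect is nonnegative (negating both effects
#' where needed), which the intercept's interpretation requires. Standard
#' errors are inflated by the multiplicative residual scale
#' \eqn{\max(1, \sqrt{RSS_w/(J-2)})}.
#'
#' @inheritParams mrIVW
#' @return an [EggerResult-class] with \code{slope} (method
#'   \code{"egger_slope"}) and \code{intercept} (method
#'   \code{"egger_intercept"}; its \code{scale} is that of the outcome
#'   effects).
#' @references Bowden J, Davey Smith G, Burgess S (2015) Mendelian
#'   randomization with invalid instruments: effect estimation and bias
#'   detection through Egger regression. Int J Epidemiol 44:512-525.
#' @export
mrEgger <- function(insts, scale = NULL) {
  d <- .mrData(insts, scale)
  J <- length(d$bx)
  if (J < 3L) stop("MR-Egger needs at least 3 instruments")
  sgn <- ifelse(d$bx < 0, -1, 1)
  bx <- d$bx * sgn
  by <- d$by * sgn
  if (max(bx) - min(bx) <= 0)
    stop("no spread in exposure effects: Egger slope unidentifiable")
  w <- 1 / d$sy^2
  ## weighted normal equations, solved directly
  W <- sum(w); Wx <- sum(w * bx); Wxx <- sum(w * bx^2)
  Wy <- sum(w * by); Wxy <- sum(w * bx * by)
  det <- W * Wxx - Wx^2
  slope <- (W * Wxy - Wx * Wy) / det
  inter <- (Wxx * Wy - Wx * Wxy) / det
  resid <- by - inter - slope * bx
  rss_w <- sum(w * resid^2)
  sigma <- max(1, sqrt(rss_w / (J - 2)))
  se_slope <- sigma * sqrt(W / det)
  se_inter <- sigma * sqrt(Wxx / det)
  new("EggerResult",
      slope = .newEstimate("egger_slope", slope, se_slope, J, d$scale),
      intercept = .newEstimate("egger_intercept", inter, se_inter, J, d$scale))
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate omitting each SNP in turn, flagging single
#' instruments with undue influence on the pooled effect. The last element
#' is the all-SNP estimate (labelled \code{"(all)"}).
#'
#' @inheritParams mrIVW
#' @return a named list of [MREstimate-class] objects of length J + 1:
#'   one per omitted SNP plus the full estimate.
#' @export
mrLeaveOneOut <- function(insts, scale = NULL) {
  d <- .mrData(insts, scale)
  J <- length(d$bx)
  if (J < 3L) stop("leave-one-out needs at least 3 instruments")
  df <- data.frame(beta_exp = d$bx, se_exp = d$sx,
                   beta_out = d$by, se_out = d$sy)
  out <- lapply(seq_len(J), function(j)
    mrIVW(df[-j, , drop = FALSE], scale = d$scale)@estimate)
  names(out) <- d$snp
  out[["(all)"]] <- mrIVW(df, scale = d$scale)@estimate
  out
}
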