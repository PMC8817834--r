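#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based framework detecting horizontal pleiotropy through the
#' residual sum of squares of the IVW fit. The observed statistic is
#' \deqn{RSS = \sum_j w_j (\beta_{Yj} - \hat\theta_{(-j)} \beta_{Xj})^2,}
#' with \eqn{w_j = 1/\sigma_{Yj}^2} and \eqn{\hat\theta_{(-j)}} the IVW
#' estimate computed without SNP j. A null distribution is built by drawing
#' \code{nSim} synthetic instrument sets with both effect sides resampled
#' from normals — \eqn{\hat\beta_{Xj} \sim N(\beta_{Xj}, \sigma_{Xj})},
#' \eqn{\hat\beta_{Yj} \sim N(\hat\theta_{(-j)}\beta_{Xj}, \sigma_{Yj})} —
#' and recomputing the statistic on each draw.
#'
#' Three tests are reported:
#' \itemize{
#'   \item global: Monte-Carlo p-value
#'     \eqn{(1 + \#\{RSS_{sim} \ge RSS_{obs}\})/(nSim + 1)};
#'   \item per-SNP outlier: each SNP's observed residual contribution
#'     against its simulated distribution, Bonferroni-corrected across the
#'     J instruments; SNPs below \code{outlierAlpha} are flagged and an
#'     outlier-corrected IVW estimate on the remainder is reported;
#'   \item distortion: the observed difference between corrected and
#'     uncorrected estimates against differences obtained by removing
#'     random same-sized inlier subsets.
#' }
#' The distortion test is reported for inspection only and never gates
#' which estimate the pipeline surfaces — both are returned.
#'
#' @param insts a [HarmonizedSet-class] or data.frame of harmonized
#'   instruments; at least 4.
#' @param nSim null simulations (default 5000; below 1000 warns — tail
#'   p-values become unstable).
#' @param outlierAlpha significance threshold for the Bonferroni-adjusted
#'   per-SNP outlier test (default 0.05).
#' @param seed integer RNG seed (mandatory; identical seed and input give
#'   identical results).
#' @param scale optional outcome scale override.
#' @return a [PressoResult-class].
#' @references Verbanck M, Chen CY, Neale B, Do R (2018) Detection of
#'   widespread horizontal pleiotropy in causal relationships inferred from
#'   Mendelian randomization between complex traits and diseases. Nat Genet
#'   50:693-698.
#' @export
mrPresso <- function(insts, nSim = 5000L, outlierAlpha = 0.05, seed,
                     scale = NULL) {
  if (missing(seed)) stop("a seed is required for the null simulation")
  d <- .mrData(insts, scale)
  J <- length(d$bx)
  if (J < 4L) stop("MR-PRESSO needs at least 4 instruments")
  if (nSim < 1000L) warning("nSim < 1000: tail p-values will be unstable")
  nSim <- as.integer(nSim)

  w_res <- 1 / d$sy^2                     # residual weights
  rss <- .pressoRss(d$bx, d$by, d$sy)
  rss_obs <- sum(rss)

  sim <- withr_seed(.deriveSeed(seed, "presso-null"), {
    bx_sim <- matrix(stats::rnorm(nSim * J, mean = rep(d$bx, each = nSim),
                                  sd = rep(d$sx, each = nSim)), nSim, J)
    theta_loo <- .looIvw(d$bx, d$by, d$sy)
    by_sim <- matrix(stats::rnorm(nSim * J,
                                  mean = rep(theta_loo * d$bx, each = nSim),
                                  sd = rep(d$sy, each = nSim)), nSim, J)
    .pressoRssMatrix(bx_sim, by_sim, d$sy)
  })
  rss_sim <- rowSums(sim)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (nSim + 1)

  p_raw <- (1 + colSums(sweep(sim, 2, rss, ">="))) / (nSim + 1)
  p_adj <- pmin(1, p_raw * J)
  names(p_adj) <- d$snp
  out_ids <- d$snp[p_adj < outlierAlpha]
  if (length(out_ids) == J) stop("every SNP flagged as an outlier")

  corrected <- NULL
  distortion_p <- NA_real_
  if (length(out_ids)) {
    keep <- !(d$snp %in% out_ids)
    df_keep <- data.frame(beta_exp = d$bx[keep], se_exp = d$sx[keep],
                          beta_out = d$by[keep], se_out = d$sy[keep])
    corrected_ivw <- mrIVW(df_keep, scale = d$scale)@estimate
    corrected <- .newEstimate("presso_corrected", corrected_ivw@beta,
                              corrected_ivw@se, sum(keep), d$scale)
    theta_all <- mrIVW(data.frame(beta_exp = d$bx, se_exp = d$sx,
                                  beta_out = d$by, se_out = d$sy),
                       scale = d$scale)@estimate@beta
    d_obs <- corrected@beta - theta_all
    n_in <- sum(keep); n_out <- length(out_ids)
    if (n_in > n_out + 1L) {
      nd <- min(nSim, 1000L)
      d_sim <- withr_seed(.deriveSeed(seed, "presso-distortion"), {
        idx_in <- which(keep)
        vapply(seq_len(nd), function(b) {
          drop <- sample(idx_in, n_out)
          sub <- data.frame(beta_exp = d$bx[-drop], se_exp = d$sx[-drop],
                            beta_out = d$by[-drop], se_out = d$sy[-drop])
          mrIVW(sub, scale = d$scale)@estimate@beta - theta_all
        }, numeric(1))
      })
      distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (nd + 1)
    }
  }

  new("PressoResult", rssObserved = rss_obs, globalPvalue = global_p,
      outlierPvalues = p_adj, outliers = out_ids, corrected = corrected,
      distortionPvalue = distortion_p, nSim = nSim,
      seed = as.integer(seed))
}

#' Flatten a PressoResult to a single serializable row
#'
#' @param object a [PressoResult-class].
#' @return one-row \code{data.frame}: \code{global_p}, \code{n_outliers},
#'   \code{outlier_ids} (comma-joined), \code{corrected_beta},
#'   \code{corrected_se}, \code{distortion_p}, \code{n_sim}, \code{seed}.
#' @export
pressoSummaryRow <- function(object) {
  stopifnot(is(object, "PressoResult"))
  has_out <- length(object@outliers) > 0L
  data.frame(
    global_p = object@globalPvalue,
    n_outliers = length(object@outliers),
    outlier_ids = paste(object@outliers, collapse = ","),
    corrected_beta = if (has_out) object@corrected@beta else NA_real_,
    corrected_se = if (has_out) object@corrected@se else NA_real_,
    distortion_p = object@distortionPvalue,
    n_sim = object@nSim, seed = object@seed,
    stringsAsFactors = FALSE)
}

## leave-one-out IVW estimates, vectorized: theta_(-j) for every j
.looIvw <- function(bx, by, sy) {
  v <- bx^2 / sy^2
  theta_j <- by / bx
  (sum(v * theta_j) - v * theta_j) / (sum(v) - v)
}

## per-SNP weighted residual contributions w_j (by_j - theta_(-j) bx_j)^2
.pressoRss <- function(bx, by, sy) {
  theta_loo <- .looIvw(bx, by, sy)
  (by - theta_loo * bx)^2 / sy^2
}

## same, rows = simulations (sy fixed across simulations)
.pressoRssMatrix <- function(bx, by, sy) {
  sy2 <- matrix(sy^2, nrow(bx), ncol(bx), byrow = TRUE)
  v <- bx^2 / sy2
  theta_j <- by / bx
  S <- rowSums(v * theta_j)
  V <- rowSums(v)
  theta_loo <- (S - v * theta_j) / (V - v)
  (by - theta_loo * bx)^2 / sy2
}
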