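#' Construct a simulation scenario for synthetic summary statistics
#'
#' Defines the ground truth from which [simulateSummaryStats()] draws
#' two-sample GWAS summary statistics under the linear MR causal model:
#' per SNP j, a minor-allele frequency on \code{mafRange}, a true exposure
#' effect \eqn{\beta_{Xj}} drawn as \eqn{|N(0, betaXScale^2)|} with random
#' sign, a pleiotropic effect \eqn{\alpha_j} per regime, and a true outcome
#' effect \eqn{\beta_{Yj} = \theta \beta_{Xj} + \alpha_j}.
#'
#' Pleiotropy regimes (\code{pleiotropy}):
#' \describe{
#'   \item{\code{list(type = "none")}}{all instruments valid
#'     (\eqn{\alpha_j = 0}).}
#'   \item{\code{list(type = "balanced", tau = )}}{\eqn{\alpha_j \sim
#'     N(0, \tau^2)} — violates exclusion restriction but averages out.}
#'   \item{\code{list(type = "directional", mu_alpha = , tau = )}}{
#'     \eqn{\alpha_j \sim N(\mu_\alpha, \tau^2)} — biases the IVW estimate.}
#'   \item{\code{list(type = "outliers", fraction = , offset_scale = ,
#'     indices = )}}{a subset of SNPs receives a fixed offset
#'     \code{offset_scale} times its outcome SE; membership is Bernoulli
#'     (\code{fraction}) per SNP, or exactly \code{indices} when given.}
#' }
#'
#' @param nSnps number of instruments (2-24 covers the source-GWAS range).
#' @param theta true causal effect.
#' @param exposureN,outcomeN GWAS sample sizes.
#' @param mafRange interval for the uniform MAF draw, within (0, 0.5].
#' @param betaXScale SD of the half-normal exposure-effect draw.
#' @param pleiotropy pleiotropy regime (see Details).
#' @param outcomeScale \code{list(type = "linear")} or
#'   \code{list(type = "log_odds", caseFraction = )}.
#' @param seed integer seed governing the whole scenario.
#' @return a [SimulationScenario-class].
#' @export
simulationScenario <- function(nSnps, theta, exposureN, outcomeN,
                               mafRange = c(0.1, 0.5), betaXScale = 0.1,
                               pleiotropy = list(type = "none"),
                               outcomeScale = list(type = "linear"),
                               seed = 1L) {
  new("SimulationScenario", nSnps = as.integer(nSnps), theta = theta,
      exposureN = as.numeric(exposureN), outcomeN = as.numeric(outcomeN),
      mafRange = as.numeric(mafRange), betaXScale = betaXScale,
      pleiotropy = pleiotropy, outcomeScale = outcomeScale,
      seed = as.integer(seed))
}

## large-sample per-allele SE of a GWAS regression coefficient for a trait
## with unit variance: 1 / sqrt(2 maf (1-maf) n); binary (log-odds) traits
## lose a factor sqrt(cf (1-cf)) of information
.gwasSe <- function(maf, n, caseFraction = NULL) {
  se <- 1 / sqrt(2 * maf * (1 - maf) * n)
  if (!is.null(caseFraction)) se <- se / sqrt(caseFraction * (1 - caseFraction))
  se
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Draws observed exposure- and outcome-side effect estimates
#' independently (the two-sample property) around the scenario's true
#' effects, with standard errors from the large-sample per-allele variance
#' approximation, so realized instrument F statistics are consistent with
#' [fStatistic()].
#'
#' Each SNP uses its own deterministic RNG sub-stream derived from the
#' scenario seed, so enlarging \code{nSnps} never reshuffles the draws of
#' earlier SNPs, and identical seeds give bit-identical output.
#'
#' @param scenario a [SimulationScenario-class].
#' @return list with components:
#'   \describe{
#'     \item{exposure}{an [InstrumentSet-class] of observed exposure
#'       associations;}
#'     \item{outcome}{canonical summary table of observed outcome
#'       associations (same TSV dialect [readSummaryTable()] reads);}
#'     \item{truth}{list: \code{theta}, per-SNP \code{maf},
#'       \code{beta_x_true}, \code{beta_y_true}, \code{alpha},
#'       \code{outlier_ids}, realized \code{r2}.}
#'   }
#' @export
simulateSummaryStats <- function(scenario) {
  stopifnot(is(scenario, "SimulationScenario"))
  validObject(scenario)
  J <- scenario@nSnps
  pl <- scenario@pleiotropy
  os <- scenario@outcomeScale
  cf <- if (os$type == "log_odds") os$caseFraction else NULL

  maf <- beta_x <- alpha <- se_x <- se_y <- bx_obs <- by_obs <- numeric(J)
  is_outlier <- logical(J)
  fixed_idx <- if (pl$type == "outliers" && !is.null(pl$indices))
    as.integer(pl$indices) else NULL

  for (j in seq_len(J)) {
    draws <- withr_seed(.deriveSeed(scenario@seed, "snp", j), {
      m <- stats::runif(1, scenario@mafRange[1], scenario@mafRange[2])
      bx <- abs(stats::rnorm(1, 0, scenario@betaXScale)) *
        sample(c(-1, 1), 1)
      a <- switch(pl$type,
        none = 0,
        balanced = stats::rnorm(1, 0, pl$tau),
        directional = stats::rnorm(1, pl$mu_alpha, pl$tau),
        outliers = 0)   # offset applied below, needs se_y
      flag <- if (pl$type == "outliers") {
        if (!is.null(fixed_idx)) j %in% fixed_idx
        else stats::runif(1) < pl$fraction
      } else FALSE
      ex <- stats::rnorm(1); ey <- stats::rnorm(1)
      list(m = m, bx = bx, a = a, flag = flag, ex = ex, ey = ey)
    })
    maf[j] <- draws$m
    beta_x[j] <- draws$bx
    se_x[j] <- .gwasSe(draws$m, scenario@exposureN)
    se_y[j] <- .gwasSe(draws$m, scenario@outcomeN, cf)
    ## pleiotropy is defined on the exposure-increasing allele, so a
    ## directional mean or outlier offset stays directional after the
    ## orientation step estimators apply; reported-allele sign carries it
    alpha[j] <- sign(draws$bx) *
      (draws$a + if (draws$flag) pl$offset_scale * se_y[j] else 0)
    is_outlier[j] <- draws$flag
    by_true <- scenario@theta * beta_x[j] + alpha[j]
    bx_obs[j] <- beta_x[j] + draws$ex * se_x[j]
    by_obs[j] <- by_true + draws$ey * se_y[j]
  }

  snp_ids <- sprintf("rs%04d", seq_len(J))
  exp_tab <- data.frame(
    snp = snp_ids, effect_allele = "A", other_allele = "G",
    eaf = maf, beta = bx_obs, se = se_x,
    pval = .zPvalue(bx_obs, se_x), n = scenario@exposureN,
    stringsAsFactors = FALSE)
  out_tab <- data.frame(
    snp = snp_ids, effect_allele = "A", other_allele = "G",
    eaf = maf, beta = by_obs, se = se_y,
    pval = .zPvalue(by_obs, se_y), n = scenario@outcomeN,
    stringsAsFactors = FALSE)

  r2 <- sum(snpR2(beta_x, maf))
  list(
    exposure = InstrumentSet("synthetic_exposure", exp_tab,
                             unitLabel = "SD units",
                             sampleSize = scenario@exposureN,
                             varianceExplained = if (r2 < 1) r2 else NA_real_),
    outcome = out_tab,
    truth = list(theta = scenario@theta, maf = maf, beta_x_true = beta_x,
                 beta_y_true = scenario@theta * beta_x + alpha,
                 alpha = alpha, outlier_ids = snp_ids[is_outlier],
                 se_x = se_x, se_y = se_y, r2 = r2,
                 scale = if (os$type == "log_odds") "log_odds" else "linear")
  )
}

#' Harmonized instruments straight from a scenario
#'
#' Convenience wrapper: simulate, then pair exposure and outcome rows
#' (alleles are constructed concordant, so harmonization is the identity).
#'
#' @param scenario a [SimulationScenario-class].
#' @return list with \code{data} (harmonized instrument data.frame),
#'   \code{truth}, and \code{scale}.
#' @export
simulateHarmonized <- function(scenario) {
  sim <- simulateSummaryStats(scenario)
  ex <- snpTable(sim$exposure)
  list(data = data.frame(snp = ex$snp,
                         beta_exp = ex$beta, se_exp = ex$se,
                         beta_out = sim$outcome$beta,
                         se_out = sim$outcome$se,
                         stringsAsFactors = FALSE),
       truth = sim$truth, scale = sim$truth$scale)
}

## Source-GWAS inventory used for calibrated scenarios: exposure sample
## size, instrument count and reported variance explained for the nine
## antioxidant exposures (absolute circulating levels and blood
## metabolites).
.SOURCE_GWAS <- data.frame(
  name = c("ascorbate", "lycopene", "selenium", "beta_carotene", "retinol",
           "ascorbate_metabolite", "alpha_tocopherol", "gamma_tocopherol",
           "retinol_metabolite"),
  exposure_n = c(15087, 441, 4162, 2344, 5006, 2063, 7276, 5822, 1957),
  n_snps = c(10L, 5L, 4L, 3L, 2L, 14L, 11L, 13L, 24L),
  r2 = c(0.0187, 0.301, 0.059, 0.090, 0.023, 0.186, 0.033, 0.150, 0.048),
  stringsAsFactors = FALSE
)

#' Scenario calibrated to a real exposure's source GWAS
#'
#' Builds a [SimulationScenario-class] whose instrument count, exposure
#' sample size and expected realized variance explained match the source
#' GWAS of one of the nine antioxidant exposures. \code{betaXScale} is set
#' so that the expected total \eqn{R^2 = \sum_j 2\beta_{Xj}^2 MAF_j(1-MAF_j)}
#' equals the reported value: with \eqn{E[\beta_X^2] = betaXScale^2} and
#' MAF uniform on \code{mafRange}, \code{betaXScale =
#' sqrt(r2 / (k E[2 MAF (1-MAF)]))}.
#'
#' The outcome defaults to the binary longevity contrast (survival to the
#' 90th vs 60th percentile age; 11,262 cases, 25,483 controls, log-odds
#' scale) or, with \code{outcome = "linear"}, to the parental-lifespan
#' trait (n = 1,012,240, continuous).
#'
#' @param exposureName one of \code{"ascorbate"}, \code{"lycopene"},
#'   \code{"selenium"}, \code{"beta_carotene"}, \code{"retinol"},
#'   \code{"ascorbate_metabolite"}, \code{"alpha_tocopherol"},
#'   \code{"gamma_tocopherol"}, \code{"retinol_metabolite"}.
#' @param theta true causal effect (default 0).
#' @param outcome \code{"log_odds"} (default) or \code{"linear"}.
#' @param mafRange MAF interval (default c(0.1, 0.5)).
#' @param pleiotropy pleiotropy regime (default none).
#' @param seed integer seed.
#' @return a [SimulationScenario-class].
#' @export
scenarioFromSource <- function(exposureName, theta = 0,
                               outcome = c("log_odds", "linear"),
                               mafRange = c(0.1, 0.5),
                               pleiotropy = list(type = "none"),
                               seed = 1L) {
  outcome <- match.arg(outcome)
  row <- .SOURCE_GWAS[.SOURCE_GWAS$name == exposureName, ]
  if (!nrow(row))
    stop("unknown exposure '", exposureName, "'; valid names: ",
         paste(.SOURCE_GWAS$name, collapse = ", "))
  a <- mafRange[1]; b <- mafRange[2]
  mean_m <- (a + b) / 2
  e_m2 <- (b - a)^2 / 12 + mean_m^2
  e_var <- 2 * (mean_m - e_m2)        # E[2 MAF (1-MAF)] under uniform MAF
  bx_scale <- sqrt(row$r2 / (row$n_snps * e_var))
  os <- if (outcome == "log_odds")
    list(type = "log_odds", caseFraction = 11262 / (11262 + 25483))
  else list(type = "linear")
  outN <- if (outcome == "log_odds") 11262 + 25483 else 1012240
  simulationScenario(nSnps = row$n_snps, theta = theta,
                     exposureN = row$exposure_n, outcomeN = outN,
                     mafRange = mafRange, betaXScale = bx_scale,
                     pleiotropy = pleiotropy, outcomeScale = os, seed = seed)
}

#' Write a simulated scenario to disk in the standard TSV dialect
#'
#' Emits \code{exposure.tsv}, \code{outcome.tsv} (both readable by
#' [readSummaryTable()]) and \code{truth.tsv}.
#'
#' @param scenario a [SimulationScenario-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
writeScenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulateSummaryStats(scenario)
  writeSummaryTable(snpTable(sim$exposure), file.path(dir, "exposure.tsv"))
  writeSummaryTable(sim$outcome, file.path(dir, "outcome.tsv"))
  tr <- sim$truth
  truth_tab <- data.frame(
    snp = snpTable(sim$exposure)$snp, maf = tr$maf,
    beta_x_true = tr$beta_x_true, beta_y_true = tr$beta_y_true,
    alpha = tr$alpha, theta = tr$theta,
    outlier = snpTable(sim$exposure)$snp %in% tr$outlier_ids,
    stringsAsFactors = FALSE)
  utils::write.table(truth_tab, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
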