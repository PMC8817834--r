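# Shared fixtures, all generated in code.

# Random harmonized-instrument table (no pleiotropy unless alpha given).
randInstruments <- function(J, seed, theta = 0.2, alpha = rep(0, J)) {
  set.seed(seed)
  bx <- runif(J, 0.05, 0.5) * sample(c(-1, 1), J, replace = TRUE)
  sx <- runif(J, 0.01, 0.05)
  sy <- runif(J, 0.02, 0.1)
  by <- theta * bx + alpha + rnorm(J, 0, sy)
  data.frame(snp = sprintf("rs%03d", seq_len(J)),
             beta_exp = bx, se_exp = sx, beta_out = by, se_out = sy,
             stringsAsFactors = FALSE)
}

# Minimal canonical summary table for IO tests.
demoSummaryTable <- function() {
  data.frame(
    snp = c("rs0001", "rs0002", "rs0003"),
    effect_allele = c("A", "C", "T"),
    other_allele = c("G", "T", "C"),
    eaf = c(0.25, 0.6, 0.1),
    beta = c(0.12, -0.05, 0.3),
    se = c(0.02, 0.01, 0.07),
    pval = c(2e-9, 6e-7, 2e-5),
    n = c(1000, 1000, 1000),
    stringsAsFactors = FALSE)
}

# Independent WLS oracle via lm(): zero-intercept for IVW, intercept for
# Egger. Returns coef and (for Egger) intercept with model-based SEs.
wlsOracleIVW <- function(d) {
  fit <- lm(beta_out ~ 0 + beta_exp, data = d, weights = 1 / d$se_out^2)
  unname(coef(fit)[1])
}

wlsOracleEgger <- function(d) {
  sgn <- ifelse(d$beta_exp < 0, -1, 1)
  dd <- data.frame(x = d$beta_exp * sgn, y = d$beta_out * sgn)
  fit <- lm(y ~ x, data = dd, weights = 1 / d$se_out^2)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}
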