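## two-sided normal p from an estimate and its SE
.zPvalue <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

.Z95 <- stats::qnorm(0.975)

## Deterministic sub-seed derivation: mixes a base seed with string labels /
## integers so independent analysis arms get reproducible, non-clashing
## streams. Arithmetic in double precision, reduced mod 2^31 - 1 so the
## result is a valid 32-bit seed.
.deriveSeed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(paste(x, collapse = ""))) else as.numeric(x)
  }))
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (p in parts) h <- (h * 69069 + p * 2654435761) %% m
  as.integer(h %% (m - 1) + 1)
}

.newEstimate <- function(method, beta, se, nSnps, scale) {
  new("MREstimate",
      method = method,
      beta = beta,
      se = se,
      ciLow = beta - .Z95 * se,
      ciHigh = beta + .Z95 * se,
      pvalue = .zPvalue(beta, se),
      nSnps = as.integer(nSnps),
      scale = scale)
}

## Extract the (beta_exp, se_exp, beta_out, se_out, snp) vectors an
## estimator needs, from a HarmonizedSet (retained rows) or a plain
## data.frame already carrying those columns.
.mrData <- function(x, scale = NULL) {
  if (is(x, "HarmonizedSet")) {
    d <- x@data[x@data$action %in% c("aligned", "flipped"), , drop = FALSE]
    list(snp = d$snp, bx = d$beta_exp, sx = d$se_exp,
         by = d$beta_out, sy = d$se_out,
         scale = if (is.null(scale)) x@scale else scale)
  } else if (is.data.frame(x)) {
    need <- c("beta_exp", "se_exp", "beta_out", "se_out")
    if (!all(need %in% names(x)))
      stop("data.frame input needs columns: ", paste(need, collapse = ", "))
    snp <- if ("snp" %in% names(x)) as.character(x$snp) else
      paste0("snp", seq_len(nrow(x)))
    list(snp = snp, bx = x$beta_exp, sx = x$se_exp,
         by = x$beta_out, sy = x$se_out,
         scale = if (is.null(scale)) "linear" else scale)
  } else {
    stop("expected a HarmonizedSet or a data.frame of harmonized instruments")
  }
}
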