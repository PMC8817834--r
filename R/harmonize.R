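.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.complement <- function(allele) {
  ok <- allele %in% names(.COMPLEMENT)
  out <- rep(NA_character_, length(allele))
  out[ok] <- unname(.COMPLEMENT[allele[ok]])
  out
}

.isPalindromic <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) & .complement(a1) == a2
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome association of every exposure SNP onto the exposure's
#' effect allele, so that each instrument carries a consistent
#' (beta_exp, beta_out) pair — the input every two-sample MR estimator
#' consumes. Non-palindromic allele mismatches are resolved by strand
#' complementation and/or allele swap (swapping negates the outcome beta and
#' reflects its allele frequency). Palindromic SNPs (A/T, C/G), whose strand
#' cannot be resolved from allele letters, are handled per
#' \code{palindromePolicy}:
#' \describe{
#'   \item{\code{infer_by_eaf}}{(default) use allele frequencies to infer
#'     orientation; drop the SNP when either frequency is missing or lies
#'     within \code{eafWindow} of 0.5 (uninformative).}
#'   \item{\code{drop}}{always drop palindromic SNPs.}
#'   \item{\code{keep}}{trust the reported alleles as being on the same
#'     strand (appropriate for pre-harmonized source tables).}
#' }
#'
#' SNPs absent from the outcome table are retained in the output with
#' action \code{dropped_missing}; nothing is dropped silently.
#'
#' @param exposure an [InstrumentSet-class].
#' @param outcome canonical summary table of outcome associations (see
#'   [readSummaryTable()]).
#' @param palindromePolicy one of \code{"infer_by_eaf"}, \code{"drop"},
#'   \code{"keep"}.
#' @param eafWindow half-width of the frequency window around 0.5 within
#'   which a palindromic SNP is considered uninformative (default 0.08,
#'   i.e. drop when eaf is in [0.42, 0.58]).
#' @param outcomeLabel label for the outcome trait.
#' @param scale outcome effect scale: \code{"log_odds"} or \code{"linear"}.
#' @return a [HarmonizedSet-class].
#' @export
harmonize <- function(exposure, outcome,
                      palindromePolicy = c("infer_by_eaf", "drop", "keep"),
                      eafWindow = 0.08,
                      outcomeLabel = "outcome", scale = "log_odds") {
  stopifnot(is(exposure, "InstrumentSet"))
  palindromePolicy <- match.arg(palindromePolicy)
  exp_tab <- exposure@snps
  idx <- match(exp_tab$snp, outcome$snp)

  n <- nrow(exp_tab)
  res <- data.frame(
    snp = exp_tab$snp,
    beta_exp = exp_tab$beta, se_exp = exp_tab$se,
    beta_out = NA_real_, se_out = NA_real_,
    eaf_exp = exp_tab$eaf, eaf_out = NA_real_,
    action = NA_character_,
    alleles_exp = paste0(exp_tab$effect_allele, "/", exp_tab$other_allele),
    alleles_out = NA_character_,
    stringsAsFactors = FALSE
  )

  for (i in seq_len(n)) {
    j <- idx[i]
    if (is.na(j)) { res$action[i] <- "dropped_missing"; next }
    a1 <- exp_tab$effect_allele[i]; a2 <- exp_tab$other_allele[i]
    b1 <- toupper(outcome$effect_allele[j]); b2 <- toupper(outcome$other_allele[j])
    res$alleles_out[i] <- paste0(b1, "/", b2)
    by <- outcome$beta[j]; sy <- outcome$se[j]; fy <- outcome$eaf[j]

    same <- !is.na(b1) && b1 == a1 && b2 == a2
    swap <- !is.na(b1) && b1 == a2 && b2 == a1
    cb1 <- .complement(b1); cb2 <- .complement(b2)
    csame <- !is.na(cb1) && cb1 == a1 && cb2 == a2
    cswap <- !is.na(cb1) && cb1 == a2 && cb2 == a1

    if (.isPalindromic(a1, a2)) {
      if (palindromePolicy == "drop") { res$action[i] <- "dropped_palindromic"; next }
      if (!(same || swap)) { res$action[i] <- "dropped_incompatible"; next }
      ## nominal letter alignment (strand unresolvable for palindromes)
      flip <- swap
      if (palindromePolicy == "infer_by_eaf") {
        fx <- exp_tab$eaf[i]
        fy_nominal <- if (flip) 1 - fy else fy
        uninformative <- function(f)
          is.na(f) || abs(f - 0.5) <= eafWindow
        if (uninformative(fx) || uninformative(fy_nominal)) {
          res$action[i] <- "dropped_palindromic"; next
        }
        ## frequencies disagreeing after nominal alignment mean the
        ## reported outcome allele sits on the opposite strand, i.e. it is
        ## really the exposure's other allele: undo/extend the flip
        if ((fx - 0.5) * (fy_nominal - 0.5) < 0) flip <- !flip
      }
      if (flip) { by <- -by; fy <- 1 - fy }
      res$action[i] <- if (flip) "flipped" else "aligned"
    } else {
      if (same || csame) {
        res$action[i] <- "aligned"
      } else if (swap || cswap) {
        by <- -by; fy <- if (is.na(fy)) NA_real_ else 1 - fy
        res$action[i] <- "flipped"
      } else {
        res$action[i] <- "dropped_incompatible"; next
      }
    }
    res$beta_out[i] <- by; res$se_out[i] <- sy; res$eaf_out[i] <- fy
  }

  new("HarmonizedSet", exposure = exposure@exposure, outcome = outcomeLabel,
      scale = scale, data = res)
}

#' @describeIn harmonize Harmonized instrument table. \code{keep =
#'   "retained"} (default) returns only rows usable by estimators
#'   (actions \code{aligned}/\code{flipped}); \code{"all"} includes
#'   dropped rows.
#' @param object a [HarmonizedSet-class].
#' @param keep \code{"retained"} or \code{"all"}.
#' @export
setMethod("harmonizedData", "HarmonizedSet", function(object,
    keep = c("retained", "all")) {
  keep <- match.arg(keep)
  d <- object@data[, c("snp", "beta_exp", "se_exp", "beta_out", "se_out",
                       "eaf_exp", "eaf_out", "action")]
  if (keep == "retained")
    d <- d[d$action %in% c("aligned", "flipped"), , drop = FALSE]
  rownames(d) <- NULL
  d
})

#' @describeIn harmonize Audit table (one row per exposure SNP: action,
#'   pre/post alleles and betas), suitable for writing as TSV.
#' @export
setMethod("harmonizationAudit", "HarmonizedSet", function(object) {
  d <- object@data
  data.frame(snp = d$snp, action = d$action,
             alleles_exposure = d$alleles_exp,
             alleles_outcome = d$alleles_out,
             beta_exp = d$beta_exp, beta_out = d$beta_out,
             eaf_exp = d$eaf_exp, eaf_out = d$eaf_out,
             stringsAsFactors = FALSE)
})

#' Write the harmonization audit table as TSV
#'
#' @param object a [HarmonizedSet-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeHarmonizationAudit <- function(object, path) {
  utils::write.table(harmonizationAudit(object), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
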