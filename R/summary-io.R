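#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file (tab- or comma-separated, detected from the
#' header line) of SNP-trait summary associations, maps its columns onto the
#' canonical fields and validates every row. Validation is total: each input
#' row is either accepted or appears in the rejection report with a reason.
#' Alleles are upper-cased on ingestion.
#'
#' The canonical fields are \code{snp}, \code{effect_allele},
#' \code{other_allele}, \code{eaf}, \code{beta}, \code{se}, \code{pval},
#' \code{n}. The first three plus \code{beta} and \code{se} are mandatory;
#' \code{eaf}, \code{pval} and \code{n} may be absent or missing per row
#' (several published GWASs omit them), in which case downstream operations
#' that need them fail with a named-field error.
#'
#' Row-level rules: \code{se > 0}; \code{eaf} in [0,1] when present;
#' \code{pval} in (0,1] when present; effect and other alleles must differ
#' (case-insensitively); unparseable numerics reject the row. When a
#' p-value is present it is compared with the two-sided normal p implied by
#' beta/se; a z-score disagreement beyond 10\% relative tolerance is only a
#' warning (published tables are rounded), recorded in the report.
#'
#' @param path file path to a delimited text table with a header row.
#' @param columnMap named character vector mapping canonical field names to
#'   column names in the file, e.g. \code{c(snp = "rsid", beta = "b")}.
#'   Fields not named fall back to the default dialect (canonical names).
#' @param sep field separator; \code{NULL} (default) auto-detects tab vs
#'   comma from the header line.
#' @return a \code{data.frame} of accepted rows in canonical columns, with
#'   attributes \code{"rejections"} (data.frame: row, snp, reason) and
#'   \code{"warnings"} (data.frame: row, snp, message) — retrieve them with
#'   [validationReport()].
#' @seealso [writeSummaryTable()], [InstrumentSet()], [validationReport()]
#' @export
readSummaryTable <- function(path, columnMap = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  map <- c(snp = "snp", effect_allele = "effect_allele",
           other_allele = "other_allele", eaf = "eaf", beta = "beta",
           se = "se", pval = "pval", n = "n")
  if (!is.null(columnMap)) map[names(columnMap)] <- columnMap

  for (f in .SUMMARY_MANDATORY)
    if (!map[[f]] %in% names(raw))
      stop("mandatory column missing: '", map[[f]], "' (field ", f, ")")

  get_col <- function(f) {
    if (map[[f]] %in% names(raw)) raw[[map[[f]]]] else rep(NA_character_, nrow(raw))
  }
  out <- data.frame(
    snp = get_col("snp"),
    effect_allele = toupper(get_col("effect_allele")),
    other_allele = toupper(get_col("other_allele")),
    eaf = get_col("eaf"), beta = get_col("beta"), se = get_col("se"),
    pval = get_col("pval"), n = get_col("n"),
    stringsAsFactors = FALSE
  )

  rejections <- data.frame(row = integer(), snp = character(),
                           reason = character(), stringsAsFactors = FALSE)
  warns <- data.frame(row = integer(), snp = character(),
                      message = character(), stringsAsFactors = FALSE)
  reject <- function(i, why) {
    rejections <<- rbind(rejections, data.frame(
      row = i, snp = out$snp[i], reason = why, stringsAsFactors = FALSE))
  }
  num <- function(x) suppressWarnings(as.numeric(x))

  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    beta <- num(out$beta[i]); se <- num(out$se[i])
    eaf <- num(out$eaf[i]); pv <- num(out$pval[i]); n <- num(out$n[i])
    if (is.na(out$snp[i]) || !nzchar(out$snp[i])) {
      reject(i, "missing SNP identifier"); keep[i] <- FALSE; next
    }
    if ((is.na(beta) && nzchar(out$beta[i]) && !is.na(out$beta[i])) ||
        is.na(beta)) {
      reject(i, "unparseable or missing beta"); keep[i] <- FALSE; next
    }
    if (is.na(se)) { reject(i, "unparseable or missing SE"); keep[i] <- FALSE; next }
    if (se <= 0) { reject(i, "nonpositive SE"); keep[i] <- FALSE; next }
    if (!is.na(eaf) && (eaf < 0 || eaf > 1)) {
      reject(i, "EAF outside [0,1]"); keep[i] <- FALSE; next
    }
    if (!is.na(pv) && (pv <= 0 || pv > 1)) {
      reject(i, "p-value outside (0,1]"); keep[i] <- FALSE; next
    }
    if (!is.na(n) && n <= 0) { reject(i, "nonpositive sample size"); keep[i] <- FALSE; next }
    if (toupper(out$effect_allele[i]) == toupper(out$other_allele[i])) {
      reject(i, "effect and other allele identical"); keep[i] <- FALSE; next
    }
    if (!is.na(pv)) {
      z_obs <- abs(beta / se)
      z_imp <- stats::qnorm(pv / 2, lower.tail = FALSE)
      if (is.finite(z_imp) && z_obs > 0 &&
          abs(z_obs - z_imp) / z_obs > 0.10) {
        warns <- rbind(warns, data.frame(
          row = i, snp = out$snp[i],
          message = sprintf(
            "p-value inconsistent with beta/se (z %.3g vs implied %.3g)",
            z_obs, z_imp),
          stringsAsFactors = FALSE))
      }
    }
  }

  acc <- out[keep, , drop = FALSE]
  res <- data.frame(
    snp = acc$snp,
    effect_allele = acc$effect_allele,
    other_allele = acc$other_allele,
    eaf = num(acc$eaf), beta = num(acc$beta), se = num(acc$se),
    pval = num(acc$pval), n = num(acc$n),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "rejections") <- rejections
  attr(res, "warnings") <- warns
  res
}

#' Retrieve the validation report attached by [readSummaryTable()]
#'
#' @param x a table returned by [readSummaryTable()].
#' @return list with components \code{rejections} and \code{warnings}.
#' @export
validationReport <- function(x) {
  list(rejections = attr(x, "rejections"),
       warnings = attr(x, "warnings"))
}

#' Write the validation report as a structured text log
#'
#' @param x a table returned by [readSummaryTable()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeValidationReport <- function(x, path) {
  rep <- validationReport(x)
  lines <- c(sprintf("accepted_rows\t%d", nrow(x)),
             sprintf("rejected_rows\t%d", nrow(rep$rejections)))
  if (nrow(rep$rejections))
    lines <- c(lines, sprintf("reject\trow=%d\tsnp=%s\treason=%s",
                              rep$rejections$row, rep$rejections$snp,
                              rep$rejections$reason))
  if (!is.null(rep$warnings) && nrow(rep$warnings))
    lines <- c(lines, sprintf("warn\trow=%d\tsnp=%s\tmessage=%s",
                              rep$warnings$row, rep$warnings$snp,
                              rep$warnings$message))
  writeLines(lines, path)
  invisible(path)
}

#' Write a summary-statistics table as TSV
#'
#' Numerics are written at full double precision so that a write/read
#' round-trip reproduces every field.
#'
#' @param x canonical summary table (as from [readSummaryTable()]).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSummaryTable <- function(x, path) {
  y <- x[, intersect(.SUMMARY_COLS, names(x)), drop = FALSE]
  for (cl in c("eaf", "beta", "se", "pval", "n"))
    if (cl %in% names(y))
      y[[cl]] <- vapply(y[[cl]], function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 17), character(1))
  utils::write.table(y, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Construct an InstrumentSet
#'
#' @param exposure exposure label.
#' @param snps canonical summary table of the instrument SNPs (see
#'   [readSummaryTable()]).
#' @param unitLabel text describing one exposure unit.
#' @param sampleSize,ancestry,pThreshold,varianceExplained source-GWAS
#'   metadata; all optional.
#' @return an [InstrumentSet-class].
#' @export
InstrumentSet <- function(exposure, snps, unitLabel = "",
                          sampleSize = NA_real_, ancestry = NA_character_,
                          pThreshold = NA_real_,
                          varianceExplained = NA_real_) {
  for (cl in setdiff(.SUMMARY_COLS, names(snps)))
    snps[[cl]] <- NA_real_
  snps <- snps[, .SUMMARY_COLS, drop = FALSE]
  new("InstrumentSet", exposure = exposure, unitLabel = unitLabel,
      snps = snps, sampleSize = as.numeric(sampleSize),
      ancestry = as.character(ancestry), pThreshold = as.numeric(pThreshold),
      varianceExplained = as.numeric(varianceExplained))
}

#' Read an instrument exclusion list (one rsID per line)
#'
#' @param path text file, one SNP identifier per line; blank lines and
#'   lines starting with \code{#} are ignored.
#' @return character vector of SNP identifiers.
#' @export
readExclusionList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Remove excluded SNPs from an instrument set
#'
#' Instruments known to act through pleiotropic pathways (for example
#' rs174547 in \emph{FADS1} for ascorbate) are removed before analysis.
#' Exclusion identifiers not present in the set produce a warning; removing
#' every SNP is an error.
#'
#' @param instruments an [InstrumentSet-class].
#' @param exclusions character vector of SNP identifiers to drop (or a file
#'   path readable by [readExclusionList()]).
#' @return the filtered [InstrumentSet-class]; the identifiers actually
#'   removed are attached as attribute \code{"excluded"}.
#' @export
applyExclusions <- function(instruments, exclusions) {
  stopifnot(is(instruments, "InstrumentSet"))
  if (length(exclusions) == 1L && !grepl("^rs", exclusions) &&
      file.exists(exclusions))
    exclusions <- readExclusionList(exclusions)
  if (!length(exclusions)) return(instruments)
  snps <- instruments@snps
  absent <- setdiff(exclusions, snps$snp)
  if (length(absent))
    warning("exclusion identifiers not present in set: ",
            paste(absent, collapse = ", "))
  hit <- intersect(exclusions, snps$snp)
  if (length(hit) == nrow(snps))
    stop("exclusions would remove every SNP from '",
         instruments@exposure, "'")
  if (length(hit)) {
    message(sprintf("excluded %d SNP(s) from '%s': %s",
                    length(hit), instruments@exposure,
                    paste(hit, collapse = ", ")))
    instruments@snps <- snps[!snps$snp %in% hit, , drop = FALSE]
    rownames(instruments@snps) <- NULL
    validObject(instruments)
  }
  attr(instruments, "excluded") <- hit
  instruments
}
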