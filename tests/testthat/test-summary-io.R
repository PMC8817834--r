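test_that("write/read round-trip reproduces every field", {
  tab <- demoSummaryTable()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSummaryTable(tab, path)
  back <- readSummaryTable(path)
  expect_equal(nrow(back), 3L)
  expect_equal(nrow(validationReport(back)$rejections), 0L)
  for (cl in names(tab)) expect_equal(back[[cl]], tab[[cl]], ignore_attr = TRUE)

  # second round trip is exact too
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeSummaryTable(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("validation is total: every row accepted or rejected with a reason", {
  tab <- demoSummaryTable()
  tab$se[2] <- 0                       # nonpositive SE
  extra <- tab[1, ]; extra$snp <- "rs0004"; extra$beta <- "oops"
  tab <- rbind(tab, extra)
  tab2 <- tab[1, ]; tab2$snp <- "rs0005"
  tab2$other_allele <- "a"; tab2$effect_allele <- "A"  # identical alleles
  tab <- rbind(tab, tab2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)

  got <- readSummaryTable(path)
  rej <- validationReport(got)$rejections
  expect_equal(nrow(got) + nrow(rej), nrow(tab))
  expect_equal(rej$reason[rej$snp == "rs0002"], "nonpositive SE")
  expect_match(rej$reason[rej$snp == "rs0004"], "beta")
  expect_match(rej$reason[rej$snp == "rs0005"], "allele")
  expect_true(all(got$effect_allele == toupper(got$effect_allele)))

  logf <- withr::local_tempfile(fileext = ".log")
  writeValidationReport(got, logf)
  expect_true(any(grepl("nonpositive SE", readLines(logf))))
})

test_that("column mapping, separators, and mandatory-column errors", {
  tab <- demoSummaryTable()
  names(tab) <- c("rsid", "A1", "A2", "freq", "b", "stderr", "p", "N")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  got <- readSummaryTable(path, columnMap = c(
    snp = "rsid", effect_allele = "A1", other_allele = "A2",
    eaf = "freq", beta = "b", se = "stderr", pval = "p", n = "N"))
  expect_equal(got$beta, demoSummaryTable()$beta)

  expect_error(readSummaryTable(path), "mandatory column missing.*snp")

  # eaf/n columns may be absent entirely; rows stay valid with NA fields
  slim <- demoSummaryTable()[, c("snp", "effect_allele", "other_allele",
                                 "beta", "se")]
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(slim, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  got2 <- readSummaryTable(p2)
  expect_equal(nrow(got2), 3L)
  expect_true(all(is.na(got2$eaf)))
})

test_that("rounded p-values inconsistent with beta/se only warn", {
  tab <- demoSummaryTable()
  tab$pval[1] <- 0.5                   # wildly off the z-implied p
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- readSummaryTable(path)
  expect_equal(nrow(got), 3L)          # row kept
  w <- validationReport(got)$warnings
  expect_equal(w$snp, "rs0001")
  expect_match(w$message, "inconsistent")
})

test_that("exclusions shrink the set, warn on absent ids, refuse emptying", {
  snps <- do.call(rbind, lapply(1:11, function(i) {
    r <- demoSummaryTable()[1, ]; r$snp <- paste0("rs17454", i - 1); r
  }))
  snps$snp[8] <- "rs174547"
  set <- InstrumentSet("ascorbate", snps, unitLabel = "1 mmol/l",
                       sampleSize = 15087)
  expect_equal(nSnps(set), 11L)

  slim <- suppressMessages(applyExclusions(set, "rs174547"))
  expect_equal(nSnps(slim), 10L)
  expect_false("rs174547" %in% snpTable(slim)$snp)
  expect_identical(attr(slim, "excluded"), "rs174547")

  expect_identical(snpTable(applyExclusions(set, character())),
                   snpTable(set))
  expect_warning(applyExclusions(set, "rs999999"), "not present")
  expect_error(suppressWarnings(
    applyExclusions(set, snps$snp)), "every SNP")

  # exclusion list file, one rsID per line
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# pleiotropic", "rs174547", ""), f)
  expect_identical(readExclusionList(f), "rs174547")
})

test_that("InstrumentSet validity rejects broken inputs", {
  tab <- demoSummaryTable()
  expect_error(InstrumentSet("x", tab[0, ]), "at least 1")
  dup <- rbind(tab, tab[1, ])
  expect_error(InstrumentSet("x", dup), "duplicated")
  expect_error(InstrumentSet("x", tab, varianceExplained = 1.2),
               "varianceExplained")
})
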