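# Build a one-SNP exposure/outcome pair with chosen alleles/frequencies.
pairSet <- function(ea_x, oa_x, eaf_x, ea_y, oa_y, eaf_y,
                    beta_x = 0.1, beta_y = 0.2) {
  exp_tab <- data.frame(snp = "rs1", effect_allele = ea_x,
                        other_allele = oa_x, eaf = eaf_x, beta = beta_x,
                        se = 0.02, pval = NA_real_, n = NA_real_,
                        stringsAsFactors = FALSE)
  out_tab <- data.frame(snp = "rs1", effect_allele = ea_y,
                        other_allele = oa_y, eaf = eaf_y, beta = beta_y,
                        se = 0.05, pval = NA_real_, n = NA_real_,
                        stringsAsFactors = FALSE)
  list(set = InstrumentSet("x", exp_tab), out = out_tab)
}

test_that("identity, swap, and strand-complement alignments", {
  p <- pairSet("A", "G", 0.2, "A", "G", 0.2)
  h <- harmonizedData(harmonize(p$set, p$out), keep = "all")
  expect_equal(h$action, "aligned")
  expect_equal(h$beta_out, 0.2)

  p <- pairSet("A", "G", 0.2, "G", "A", 0.8)
  h <- harmonizedData(harmonize(p$set, p$out), keep = "all")
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_out, -0.2)
  expect_equal(h$eaf_out, 0.2)

  # other strand, same orientation: T/C complements A/G
  p <- pairSet("A", "G", 0.2, "T", "C", 0.2)
  h <- harmonizedData(harmonize(p$set, p$out), keep = "all")
  expect_equal(h$action, "aligned")
  expect_equal(h$beta_out, 0.2)

  # other strand, swapped: C/T
  p <- pairSet("A", "G", 0.2, "C", "T", 0.8)
  h <- harmonizedData(harmonize(p$set, p$out), keep = "all")
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_out, -0.2)
})

test_that("missing and incompatible SNPs are dropped with recorded actions", {
  p <- pairSet("A", "G", 0.2, "A", "G", 0.2)
  p$out$snp <- "rs2"
  h <- harmonizedData(harmonize(p$set, p$out), keep = "all")
  expect_equal(h$action, "dropped_missing")

  p <- pairSet("A", "G", 0.2, "A", "C", 0.2)
  h <- harmonizedData(harmonize(p$set, p$out), keep = "all")
  expect_equal(h$action, "dropped_incompatible")
  expect_equal(nrow(harmonizedData(harmonize(p$set, p$out))), 0L)
})

test_that("palindrome handling matches an enumeration oracle", {
  # Independent rule, from first principles: under infer_by_eaf a
  # palindromic SNP is dropped when either frequency is uninformative
  # (within the window of 0.5, after nominal letter alignment) and
  # otherwise oriented so minor/major status agrees across studies.
  oracle <- function(ea_y, eaf_x, eaf_y, window = 0.08) {
    swap <- ea_y == "T"               # vs exposure A/T
    f_nominal <- if (swap) 1 - eaf_y else eaf_y
    if (is.na(eaf_x) || abs(eaf_x - 0.5) <= window ||
        is.na(f_nominal) || abs(f_nominal - 0.5) <= window)
      return("dropped_palindromic")
    flip <- xor(swap, (eaf_x - 0.5) * (f_nominal - 0.5) < 0)
    if (flip) "flipped" else "aligned"
  }
  grid <- expand.grid(ea_y = c("A", "T"),
                      eaf_x = c(NA, 0.10, 0.30, 0.44, 0.50, 0.58, 0.70, 0.95),
                      eaf_y = c(NA, 0.10, 0.30, 0.44, 0.50, 0.58, 0.70, 0.95),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- pairSet("A", "T", g$eaf_x, g$ea_y, setdiff(c("A", "T"), g$ea_y),
                 g$eaf_y)
    h <- harmonizedData(harmonize(p$set, p$out), keep = "all")
    expect_equal(h$action, oracle(g$ea_y, g$eaf_x, g$eaf_y),
                 info = paste(g, collapse = " / "))
    if (h$action == "flipped") expect_equal(h$beta_out, -0.2)
    if (h$action == "aligned") expect_equal(h$beta_out, 0.2)
  }

  # policy = drop always drops; policy = keep trusts letters
  p <- pairSet("A", "T", 0.1, "A", "T", 0.1)
  expect_equal(harmonizedData(harmonize(p$set, p$out, "drop"),
                              keep = "all")$action, "dropped_palindromic")
  expect_equal(harmonizedData(harmonize(p$set, p$out, "keep"),
                              keep = "all")$action, "aligned")
})

test_that("double harmonization is idempotent", {
  sim <- simulateSummaryStats(
    simulationScenario(8, 0.1, 5e4, 5e4, seed = 11))
  exp_tab <- snpTable(sim$exposure)
  # make some SNPs palindromic and some swapped/complemented in the outcome
  exp_tab$effect_allele[1:2] <- "A"; exp_tab$other_allele[1:2] <- "T"
  out_tab <- sim$outcome
  out_tab$effect_allele[1:2] <- "A"; out_tab$other_allele[1:2] <- "T"
  out_tab$effect_allele[3] <- "G"; out_tab$other_allele[3] <- "A"
  out_tab$beta[3] <- -out_tab$beta[3]; out_tab$eaf[3] <- 1 - out_tab$eaf[3]
  out_tab$effect_allele[4] <- "T"; out_tab$other_allele[4] <- "C"
  set1 <- InstrumentSet("x", exp_tab)

  h1 <- harmonizedData(harmonize(set1, out_tab), keep = "all")
  # feed the harmonized pairs back in as exposure/outcome on shared alleles
  keep <- h1$action %in% c("aligned", "flipped")
  exp2 <- data.frame(snp = h1$snp[keep], effect_allele = "A",
                     other_allele = "G", eaf = h1$eaf_exp[keep],
                     beta = h1$beta_exp[keep], se = h1$se_exp[keep],
                     pval = NA_real_, n = NA_real_)
  out2 <- data.frame(snp = h1$snp[keep], effect_allele = "A",
                     other_allele = "G", eaf = h1$eaf_out[keep],
                     beta = h1$beta_out[keep], se = h1$se_out[keep],
                     pval = NA_real_, n = NA_real_)
  h2 <- harmonizedData(harmonize(InstrumentSet("x", exp2), out2))
  expect_equal(h2$beta_out, h1$beta_out[keep])
  expect_equal(h2$beta_exp, h1$beta_exp[keep])
  expect_true(all(h2$action == "aligned"))
})

test_that("audit table records actions and alleles for every SNP", {
  p <- pairSet("A", "G", 0.2, "G", "A", 0.8)
  hs <- harmonize(p$set, p$out)
  aud <- harmonizationAudit(hs)
  expect_equal(nrow(aud), 1L)
  expect_equal(aud$action, "flipped")
  expect_equal(aud$alleles_exposure, "A/G")
  expect_equal(aud$alleles_outcome, "G/A")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeHarmonizationAudit(hs, path)
  expect_equal(nrow(read.delim(path)), 1L)
})
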