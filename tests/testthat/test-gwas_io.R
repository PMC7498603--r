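test_that("summary statistics read applies the dialect and validates rows", {
  df <- toy_summary_df(3)
  names(df) <- c("SNP", "CHR", "BP", "A1", "A2", "FREQ", "BETA", "SE", "P", "N")
  path <- write_tsv(df)
  dialect <- summary_dialect("BMI", "continuous", "kg/m^2",
                             columns = c(rsid = "SNP", chr = "CHR", pos = "BP",
                                         effect_allele = "A1",
                                         other_allele = "A2", eaf = "FREQ",
                                         beta = "BETA", se = "SE", p = "P",
                                         n = "N"))
  tab <- read_summary_stats(path, dialect)
  expect_s3_class(tab, "summary_stats")
  expect_equal(nrow(tab), 3)
  expect_identical(attr(tab, "trait_name"), "BMI")
  expect_identical(attr(tab, "unit"), "kg/m^2")

  # missing mandatory column is a configuration error
  bad_dialect <- summary_dialect("BMI", columns = c(rsid = "nope", chr = "CHR",
                                                    pos = "BP",
                                                    effect_allele = "A1",
                                                    other_allele = "A2",
                                                    beta = "BETA", se = "SE",
                                                    p = "P"))
  expect_error(read_summary_stats(path, bad_dialect), "nope")
})

test_that("invariant-violating rows are rejected with reasons, others kept", {
  df <- toy_summary_df(5)
  df$se[2] <- 0                       # se > 0 violated
  df$effect_allele[3] <- "a"          # lower case, still valid
  df$other_allele[3] <- "g"
  df$p[4] <- 0                        # p outside (0,1]
  tab <- summary_stats(df, "X")
  rej <- attr(tab, "rejected")
  expect_equal(nrow(tab) + nrow(rej), 5)
  expect_equal(nrow(rej), 2)
  expect_match(rej$reason[rej$rsid == "rs2"], "se>0")
  expect_identical(tab$effect_allele[tab$rsid == "rs3"], "A")
  expect_identical(tab$other_allele[tab$rsid == "rs3"], "G")

  df$rsid[5] <- "rs1"
  expect_error(summary_stats(df, "X"), "duplicate rsid.*rs1")
})

test_that("summary-stats write/read round trip is bit-exact", {
  set.seed(99)
  df <- toy_summary_df(20, beta = rnorm(20, sd = 0.03),
                       se = runif(20, 0.001, 0.02),
                       p = runif(20, 1e-300, 1), eaf = runif(20, 0.01, 0.99))
  tab <- summary_stats(df, "X", "binary", "log-odds")
  path <- tempfile(fileext = ".tsv")
  write_summary_stats(tab, path)
  back <- read_summary_stats(path, summary_dialect("X", "binary", "log-odds"))
  for (col in c("pos", "eaf", "beta", "se", "p", "n"))
    expect_identical(back[[col]], tab[[col]], label = col)
  expect_identical(back$rsid, tab$rsid)
})

test_that("LD lookup is symmetric, self-pairs are 1, bounds are enforced", {
  ld <- ld_table(data.frame(rsid_a = "rs1", rsid_b = "rs2", r2 = 0.8))
  expect_equal(ld_r2(ld, "rs1", "rs2"), 0.8)
  expect_equal(ld_r2(ld, "rs2", "rs1"), 0.8)
  expect_equal(ld_r2(ld, "rs1", "rs1"), 1)
  expect_true(is.na(ld_r2(ld, "rs1", "rs9")))
  expect_error(ld_table(data.frame(rsid_a = "rs1", rsid_b = "rs2", r2 = 1.3)),
               "r2 outside")
})

test_that("MR report emits TSV and text blocks per outcome type", {
  h_bin <- make_harmonized(bx = c(0.1, 0.12, 0.09, 0.11),
                           sx = rep(0.01, 4),
                           by = c(0.02, 0.025, 0.017, 0.022),
                           sy = rep(0.008, 4), binary = TRUE)
  est <- run_estimator_suite(h_bin, config = list(seed = 1, n_boot = 200))
  prefix <- tempfile()
  files <- write_mr_report(est, prefix,
                           diagnostics = mr_diagnostics(h_bin),
                           harmonization_log = data.frame(
                             rsid = h_bin$rsid, action = "none",
                             reason = NA_character_))
  expect_true(all(file.exists(files)))
  tsv <- read.delim(paste0(prefix, "_estimates.tsv"))
  expect_equal(nrow(tsv), 5)
  ok <- !is.na(tsv$beta)
  expect_equal(tsv$or[ok], exp(tsv$beta[ok]), tolerance = 1e-12)

  # continuous outcome: OR column empty
  h_cont <- make_harmonized(bx = c(0.1, 0.12, 0.09), sx = rep(0.01, 3),
                            by = c(0.02, 0.025, 0.017), sy = rep(0.008, 3))
  est2 <- run_estimator_suite(h_cont, config = list(seed = 1, n_boot = 200))
  prefix2 <- tempfile()
  write_mr_report(est2, prefix2)  # no diagnostics: still written
  tsv2 <- read.delim(paste0(prefix2, "_estimates.tsv"))
  expect_true(all(is.na(tsv2$or)))
  txt <- readLines(paste0(prefix2, "_report.txt"))
  expect_true(any(grepl("diagnostics: absent", txt)))
  expect_error(write_mr_report(est2[0, ], tempfile()), "at least one")
})
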