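# Readers and writers: fixtures, alias resolution, validation, round trips.

test_that("the packaged instrument fixture parses to 12 validated records", {
  d <- chb_instruments()
  expect_equal(nrow(d), 12)
  r <- d[d$rsid == "rs12614", ]
  expect_equal(r$chrom, "6")
  expect_equal(r$eaf, 0.92)
  expect_equal(r$beta, 0.637)
  expect_equal(r$se, 0.053)
  expect_equal(r$n, 18371)
  expect_equal(sum(d$chrom == "6"), 11)
  expect_false(any(is_palindromic(d$effect_allele, d$other_allele)))
})

test_that("exposure reader errors name the missing column and flag bad numerics", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tChr\tPosition\tEAF\tEA\tOA\tBeta\tSE",
               "rs1\t1\t100\t0.2\tA\tG\t0.1\t0.05"), f)
  expect_error(read_exposure_instruments(f), "p")
  writeLines(c("SNP\tChr\tPosition\tEAF\tEA\tOA\tBeta\tSE\tp",
               "rs1\t1\t100\t0.2\tA\tG\tnot_a_number\t0.05\t0.01"), f)
  expect_error(read_exposure_instruments(f), "row 1")
})

test_that("a header-only exposure file yields an empty table with a warning", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("SNP\tChr\tPosition\tEAF\tEA\tOA\tBeta\tSE\tp", f)
  expect_warning(d <- read_exposure_instruments(f), "no rows")
  expect_equal(nrow(d), 0)
})

test_that("typeset scientific notation with unicode signs is normalized", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tChr\tPosition\tEAF\tEA\tOA\tBeta\tSE\tp",
               "rs1\t6\t100\t0.9\tC\tT\t0.637\t0.053\t1.28 × 10−2"),
             f)
  d <- read_exposure_instruments(f)
  expect_equal(d$pvalue, 1.28e-2)
})

test_that("outcome reader resolves GWAS-Catalog aliases order-independently", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("standard_error\thm_effect_allele\tp_value\thm_rsid\thm_other_allele\thm_beta",
               "0.05\tA\t0.3\trs1\tG\t0.12",
               "0.07\tT\t0.4\trs2\tC\t-0.05"), f)
  d <- read_outcome_summary(f, label = "AS")
  expect_equal(nrow(d), 2)
  expect_equal(d$beta, c(0.12, -0.05))
  expect_equal(attr(d, "label"), "AS")
})

test_that("an odds-ratio column with no beta is converted to log scale", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tEA\tOA\tOR\tSE\tp",
               "rs1\tA\tG\t1.5\t0.05\t0.3"), f)
  d <- read_outcome_summary(f)
  expect_equal(d$beta, log(1.5))
})

test_that("rsid filtering drops absent variants silently, not exceptionally", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tEA\tOA\tbeta\tSE\tp",
               "rs1\tA\tG\t0.1\t0.05\t0.3",
               "rs2\tT\tC\t0.2\t0.05\t0.2"), f)
  d <- read_outcome_summary(f, rsid_filter = c("rs1", "rs2853953"))
  expect_equal(d$rsid, "rs1")
  expect_false("rs2853953" %in% d$rsid)
  expect_warning(read_outcome_summary(f, rsid_filter = "rs_none"),
                 "no outcome records")
})

test_that("LD matrix validation enforces symmetry, unit diagonal and bounds", {
  rs <- c("rs1", "rs2", "rs3", "rs4")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(identity_ld(rs), f)
  m <- read_ld_matrix(f)
  expect_equal(unname(m), diag(4))
  expect_equal(rownames(m), rs)

  bad <- identity_ld(rs); bad["rs1", "rs2"] <- 0.5; bad["rs2", "rs1"] <- 0.4
  write_ld_matrix(bad, f)
  expect_error(read_ld_matrix(f), "asymmetric")

  bad <- identity_ld(rs); bad["rs2", "rs2"] <- 0.99
  write_ld_matrix(bad, f)
  expect_error(read_ld_matrix(f), "diagonal")

  bad <- identity_ld(rs); bad["rs1", "rs2"] <- bad["rs2", "rs1"] <- 1.2
  write_ld_matrix(bad, f)
  expect_error(read_ld_matrix(f), "\\[-1, 1\\]")
})

test_that("estimates writer emits the forest-table layout and round-trips", {
  ests <- list(mr_estimate("ivw_canonical", 4, -0.137, 0.0529, 0.01),
               mr_estimate("weighted_median", 4, 0, 0.05, 1))
  d <- do.call(rbind, lapply(ests, as.data.frame))
  d <- cbind(outcome = "LAS", d)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_estimates_table(d, f)
  back <- read_estimates_table(f)
  expect_equal(names(back),
               c("outcome", "method", "n_snp", "logOR", "SE", "OR",
                 "CI_low", "CI_high", "p"))
  expect_equal(back$logOR, d$logOR, tolerance = 1e-12)
  expect_equal(back$OR[2], 1.0)
  expect_equal(back$SE, d$SE, tolerance = 1e-12)

  expect_warning(write_estimates_table(d[0, ], f), "header-only")
  expect_equal(nrow(read_estimates_table(f)), 0)
})

test_that("association-table and LD round trips preserve 12 significant digits", {
  st <- simulate_two_sample(sim_config(n_variants = 6, theta = 0.1,
    ld_blocks = list(list(size = 3, type = "ar1", rho = 0.6),
                     list(size = 3, type = "compound", rho = 0.3))),
    seed = 11)
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  ex <- read_exposure_instruments(paths$exposure)
  expect_equal(ex$beta, st$exposure$beta, tolerance = 1e-12)
  expect_equal(ex$se, st$exposure$se, tolerance = 1e-12)
  expect_equal(ex$pvalue, st$exposure$pvalue, tolerance = 1e-12)
  ld <- read_ld_matrix(paths$ld)
  expect_equal(ld, st$ld, tolerance = 1e-12)
})
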