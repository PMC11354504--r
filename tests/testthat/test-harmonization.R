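# Allele alignment: swaps, strand complements, palindromes, missing
# variants, and the audit-trail accounting invariant.

make_exposure <- function() {
  variant_association(
    rsid = c("rs_same", "rs_swap", "rs_comp", "rs_compswap", "rs_pal"),
    chrom = "1", pos = c(1e6, 2e6, 3e6, 4e6, 5e6),
    effect_allele = c("G", "G", "G", "G", "A"),
    other_allele = c("A", "A", "A", "A", "T"),
    eaf = c(0.3, 0.3, 0.3, 0.3, 0.2),
    beta = c(0.419, 0.419, 0.419, 0.419, 0.3),
    se = rep(0.02, 5), pvalue = rep(1e-10, 5), n = 18371
  )
}

make_outcome <- function(pal_eaf = 0.25) {
  variant_association(
    rsid = c("rs_same", "rs_swap", "rs_comp", "rs_compswap", "rs_pal"),
    chrom = "1", pos = c(1e6, 2e6, 3e6, 4e6, 5e6),
    effect_allele = c("G", "A", "C", "T", "A"),
    other_allele = c("A", "G", "T", "C", "T"),
    eaf = c(0.3, 0.7, 0.3, 0.7, pal_eaf),
    beta = c(0.1, 0.1, 0.1, 0.1, 0.1),
    se = rep(0.05, 5), pvalue = rep(0.01, 5), n = 1e5
  )
}

test_that("swaps and strand complements are aligned with the right signs", {
  h <- harmonize(make_exposure(), make_outcome())
  expect_equal(h$rsids,
               c("rs_same", "rs_swap", "rs_comp", "rs_compswap", "rs_pal"))
  expect_equal(h$beta_y, c(0.1, -0.1, 0.1, -0.1, 0.1))
  expect_equal(h$eaf_y, c(0.3, 0.3, 0.3, 0.3, 0.25))
  acts <- setNames(h$audit$action, h$audit$rsid)
  expect_equal(unname(acts[c("rs_same", "rs_swap", "rs_comp",
                             "rs_compswap", "rs_pal")]),
               c("kept", "flipped", "complemented", "complemented", "kept"))
  # SEs never altered
  expect_equal(h$se_y, rep(0.05, 5))
})

test_that("missing outcome variants are dropped with audit, never imputed", {
  ex <- make_exposure()
  out <- make_outcome()[-2, ]
  h <- harmonize(ex, out)
  expect_equal(length(h$rsids), 4)
  expect_false("rs_swap" %in% h$rsids)
  expect_equal(h$audit$action[h$audit$rsid == "rs_swap"], "dropped_missing")
})

test_that("palindrome policies behave as documented", {
  ex <- make_exposure()
  # ambiguous frequency near 0.5 under infer_by_eaf -> dropped
  h <- harmonize(ex, make_outcome(pal_eaf = 0.50), eaf_ambiguity_band = 0.08)
  expect_equal(h$audit$action[h$audit$rsid == "rs_pal"],
               "dropped_palindromic")
  # frequencies on opposite sides of 0.5 -> flipped sign
  h2 <- harmonize(ex, make_outcome(pal_eaf = 0.8))
  expect_equal(h2$beta_y[h2$rsids == "rs_pal"], -0.1)
  expect_equal(h2$eaf_y[h2$rsids == "rs_pal"], 0.2)
  # policy drop removes all palindromic variants
  h3 <- harmonize(ex, make_outcome(), palindrome_policy = "drop")
  expect_equal(h3$audit$action[h3$audit$rsid == "rs_pal"],
               "dropped_palindromic")
  # policy keep trusts the reported orientation
  h4 <- harmonize(ex, make_outcome(pal_eaf = 0.5),
                  palindrome_policy = "keep")
  expect_true("rs_pal" %in% h4$rsids)
})

test_that("irreconcilable alleles drop the variant with a warning, not an error", {
  ex <- make_exposure()[1, ]
  out <- make_outcome()[1, ]
  out$effect_allele <- "GT"
  out$other_allele <- "A"
  expect_warning(h <- harmonize(ex, out), "irreconcilable")
  expect_equal(length(h$rsids), 0)
  expect_equal(h$audit$action, "dropped_mismatch")
})

test_that("the fixture instruments against an outcome lacking rs2853953 keep 11", {
  st <- reference_study(seed = 42)
  h <- harmonize(st$exposure, st$outcome)
  expect_equal(length(h$rsids), 11)
  expect_equal(h$audit$action[h$audit$rsid == "rs2853953"],
               "dropped_missing")
})

test_that("harmonization is idempotent and self-inverse under double flips", {
  ex <- make_exposure()
  out <- make_outcome()
  h1 <- harmonize(ex, out)
  # re-harmonize the already-aligned set: exposure alleles on both sides
  realigned <- variant_association(
    rsid = h1$rsids, chrom = h1$chrom, pos = h1$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    eaf = h1$eaf_y, beta = h1$beta_y, se = h1$se_y,
    pvalue = 0.5, n = 1e5
  )
  h2 <- harmonize(ex, realigned)
  expect_equal(h2$beta_y, h1$beta_y)
  expect_true(all(h2$audit$action == "kept"))
  # swapping EA/OA of every outcome record negates twice = original
  swapped <- out
  swapped$effect_allele <- out$other_allele
  swapped$other_allele <- out$effect_allele
  swapped$beta <- -out$beta
  swapped$eaf <- 1 - out$eaf
  h3 <- harmonize(ex, swapped)
  expect_equal(h3$beta_y, h1$beta_y)
})

test_that("audit covers every exposure variant exactly once", {
  for (seed in 1:5) {
    st <- simulate_two_sample(sim_config(n_variants = 8, theta = 0.1),
                              seed = seed)
    # remove a random outcome variant to exercise dropped_missing
    out <- st$outcome[-sample.int(8, 1), ]
    h <- harmonize(st$exposure, out)
    expect_equal(sort(h$audit$rsid), sort(st$exposure$rsid))
    expect_equal(length(h$rsids) +
                   sum(startsWith(h$audit$action, "dropped")), 8)
  }
})
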