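#!/usr/bin/env Rscript
# Step 1 — build the study inputs.
#
# Two input sets are produced under results/inputs/:
#   reference/  exposure = the packaged 12-variant chronic hepatitis B
#                instrument table; outcome = synthetic LAS-scale summary
#                statistics (1735 cases / 237,242 controls) omitting
#                rs2853953; LD = the synthetic East-Asian-like block matrix
#   synthetic/   a fully synthetic 12-variant study with a known protective
#                effect theta = log(0.872) and correlated HLA-like blocks
#
# Both are plain files readable by the package's readers, so every later
# step runs from disk exactly as it would on real downloads.

suppressPackageStartupMessages(library(chbstroke))

seed <- 20240810

st_ref <- reference_study(seed = seed, theta = log(0.872))
paths <- write_study(st_ref, "results/inputs/reference")
cat("reference study:", nrow(st_ref$exposure), "exposure variants,",
    nrow(st_ref$outcome), "outcome variants (rs2853953 absent),",
    "true theta =", format(st_ref$truth$theta, digits = 3), "\n")

cfg <- sim_config(
  n_variants = 12, theta = log(0.872),
  n_outcome = effective_n(1735, 237242),
  ld_blocks = list(list(size = 9, type = "compound", rho = 0.8),
                   list(size = 1, type = "ar1", rho = 0),
                   list(size = 1, type = "ar1", rho = 0),
                   list(size = 1, type = "ar1", rho = 0))
)
st_syn <- simulate_two_sample(cfg, seed = seed + 1)
write_study(st_syn, "results/inputs/synthetic")
cat("synthetic study: instrument F range",
    paste(round(range(instrument_strength(st_syn$exposure)$f_stat), 1),
          collapse = "-"), "\n")
cat("inputs written under results/inputs/\n")
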