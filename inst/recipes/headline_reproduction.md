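# Reproducing the published headline estimate (requires external data)

The packaged fixtures are desk-scale: the exposure instrument table is
shipped verbatim, but the stroke outcome summary statistics and a real
East Asian LD reference are external downloads. With those in hand the
pipeline reproduces the published large-artery atherosclerotic stroke
(LAS) result — canonical IVW odds ratio 0.872 (95% CI 0.786–0.967,
p = 0.010) over the clumped instruments, and a canonical-set Cochran's Q
of 3.148 — within rounding.

## 1. Outcome summary statistics

Download the five East Asian stroke outcome files from the GWAS Catalog,
accessions **GCST90104544–GCST90104548** (any stroke, any ischemic
stroke, and the TOAST subtypes: large-artery atherosclerotic,
small-vessel, cardioembolic):

```
https://www.ebi.ac.uk/gwas/downloads/summary-statistics
```

The Catalog does not encode the outcome label in the accession metadata
uniformly, so the outcome-label-to-file mapping must be given explicitly
(check each file's `trait` header). Save them uncompressed as
tab-separated text; the harmonised-format headers (`hm_rsid`,
`hm_effect_allele`, `standard_error`, `p_value`, ...) are recognized
as-is by `read_outcome_summary()`.

## 2. LD reference

Compute the signed pairwise LD correlations (r, not r²) between the 12
instrument variants from an East Asian reference panel (e.g. the 1000
Genomes EAS samples) with external tooling, and write them as a
tab-separated square matrix with rsid header row and first column (the
shape produced by `write_ld_matrix()`). The package deliberately does
not compute LD from genotype panels; the shipped
`extdata/ld_eas_synthetic.tsv` is a synthetic stand-in whose block
structure reproduces the published clumping retention pattern for
testing, not real LD.

## 3. Run

```r
library(chbstroke)
cfg <- study_config(
  exposure_path = system.file("extdata", "chb_instruments.tsv",
                              package = "chbstroke"),
  outcome_paths = c(AS  = "GCST_any_stroke.tsv",
                    AIS = "GCST_any_ischemic.tsv",
                    CES = "GCST_cardioembolic.tsv",
                    LAS = "GCST_large_artery.tsv",
                    SVS = "GCST_small_vessel.tsv"),
  ld_path = "ld_eas_real.tsv",
  seed = 1
)
res <- run_full_analysis(cfg, out_dir = "results/headline")
subset(res$estimates, outcome == "LAS" & method == "ivw_canonical")
subset(res$sensitivity, outcome == "LAS")
```

Expected: the LAS canonical IVW row shows OR 0.872 (0.786–0.967),
p = 0.010 and is flagged Bonferroni-significant at 0.05/5 = 0.01; the
LAS canonical sensitivity row shows Q = 3.148 (p = 0.369) on 3 degrees
of freedom. Residual differences at the third decimal can arise from
the LD panel and from the variance model (`variance_model = "fixed"`
versus the default multiplicative random-effects model).
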