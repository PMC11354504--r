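#' Construct a table of per-variant summary associations
#'
#' The basic record of the pipeline: one row per variant with its summary
#' association to a trait (alleles, effect-allele frequency, effect size on
#' the log-odds scale for binary traits, standard error, p-value, sample
#' size, genomic coordinates). All readers and the synthetic generator
#' return this shape; all downstream operations consume it.
#'
#' @param rsid character vector of variant identifiers.
#' @param chrom chromosome labels (character; "6", "20", "X", ...).
#' @param pos 1-based base-pair positions.
#' @param effect_allele,other_allele allele strings; must differ per row.
#' @param eaf effect-allele frequency in [0, 1] (NA allowed).
#' @param beta per-allele effect on the trait (log-odds for binary traits).
#' @param se standard error of `beta`, strictly positive.
#' @param pvalue association p-value in (0, 1].
#' @param n sample size (>= 3); may be a single shared value.
#' @return A `data.frame` with one row per variant, validated.
#' @export
variant_association <- function(rsid, chrom = NA_character_, pos = NA_integer_,
                                effect_allele, other_allele,
                                eaf = NA_real_, beta, se, pvalue = NA_real_,
                                n = NA_real_) {
  J <- length(rsid)
  chrom <- rep_len(chrom, J); pos <- rep_len(pos, J)
  eaf <- rep_len(eaf, J); pvalue <- rep_len(pvalue, J)
  n <- rep_len(n, J)
  d <- data.frame(
    rsid = as.character(rsid),
    chrom = as.character(chrom),
    pos = as.numeric(pos),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    eaf = as.numeric(eaf),
    beta = as.numeric(beta),
    se = as.numeric(se),
    pvalue = as.numeric(pvalue),
    n = as.numeric(n),
    stringsAsFactors = FALSE
  )
  validate_variant_table(d)
}

#' Validate a variant association table
#'
#' Checks the row-level invariants: alleles differ, `se > 0`,
#' `eaf` in [0, 1] where present, `n >= 3` where present.
#'
#' @param d a data.frame as produced by [variant_association()].
#' @return `d`, invisibly unchanged, or an error describing the first
#'   violated invariant.
#' @export
validate_variant_table <- function(d) {
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    stop("variant table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(d) == 0) return(d)
  bad <- which(d$effect_allele == d$other_allele)
  if (length(bad) > 0) {
    stop("effect and other allele identical for ", d$rsid[bad[1]],
         call. = FALSE)
  }
  if (any(!is.finite(d$se) | d$se <= 0)) {
    stop("standard errors must be finite and > 0", call. = FALSE)
  }
  if (any(!is.na(d$eaf) & (d$eaf < 0 | d$eaf > 1))) {
    stop("effect-allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.na(d$n) & d$n < 3)) {
    stop("sample sizes must be >= 3", call. = FALSE)
  }
  d
}

#' Reverse-complement an allele string
#'
#' @param allele character vector of allele strings over A/C/G/T.
#' @return the complementary allele string(s) (A<->T, C<->G per base).
#' @export
complement_allele <- function(allele) {
  vapply(strsplit(toupper(allele), ""), function(bases) {
    comp <- c(A = "T", T = "A", C = "G", G = "C")[bases]
    if (anyNA(comp)) return(NA_character_)
    paste(rev(comp), collapse = "")
  }, character(1))
}

#' Is an allele pair palindromic (strand-ambiguous)?
#'
#' A/T and C/G pairs are their own reverse complements, so strand cannot be
#' resolved from allele labels alone.
#'
#' @param a1,a2 allele strings.
#' @return logical vector.
#' @export
is_palindromic <- function(a1, a2) {
  !is.na(ca <- complement_allele(a1)) & toupper(a2) == ca
}
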