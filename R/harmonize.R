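# Allele harmonization: align outcome effects to the exposure's effect
# allele, handling swapped alleles, strand complements, palindromes and
# missing variants, with a per-variant audit trail.

#' Construct a harmonized exposure/outcome set
#'
#' Usually produced by [harmonize()]; the constructor is exported so that
#' estimators can be fed synthetic aligned effects directly.
#'
#' @param rsids variant identifiers of the aligned variants.
#' @param beta_x,se_x exposure effect and SE per variant.
#' @param beta_y,se_y outcome effect and SE per variant, aligned to the
#'   exposure effect allele.
#' @param eaf_x,eaf_y aligned effect-allele frequencies (optional).
#' @param chrom,pos genomic coordinates (optional; needed for clumping).
#' @param audit data.frame with columns `rsid, action, reason` covering
#'   every input variant (aligned and dropped).
#' @return an object of class `harmonized_set`.
#' @export
harmonized_set <- function(rsids, beta_x, se_x, beta_y, se_y,
                           eaf_x = rep(NA_real_, length(rsids)),
                           eaf_y = rep(NA_real_, length(rsids)),
                           chrom = rep(NA_character_, length(rsids)),
                           pos = rep(NA_real_, length(rsids)),
                           audit = NULL) {
  J <- length(rsids)
  recycle <- function(v) if (length(v) == 1 && J > 1) rep(v, J) else v
  beta_x <- recycle(beta_x); se_x <- recycle(se_x)
  beta_y <- recycle(beta_y); se_y <- recycle(se_y)
  eaf_x <- recycle(eaf_x); eaf_y <- recycle(eaf_y)
  chrom <- recycle(chrom); pos <- recycle(pos)
  lens <- c(length(beta_x), length(se_x), length(beta_y), length(se_y))
  if (any(lens != J)) {
    stop("beta_x, se_x, beta_y, se_y must all have length ", J,
         call. = FALSE)
  }
  if (J > 0 && (any(se_x <= 0) || any(se_y <= 0))) {
    stop("standard errors must be > 0", call. = FALSE)
  }
  if (is.null(audit)) {
    audit <- data.frame(rsid = rsids, action = rep("kept", J),
                        reason = rep("constructed aligned", J),
                        stringsAsFactors = FALSE)
  }
  structure(
    list(rsids = as.character(rsids), beta_x = as.numeric(beta_x),
         se_x = as.numeric(se_x), beta_y = as.numeric(beta_y),
         se_y = as.numeric(se_y), eaf_x = as.numeric(eaf_x),
         eaf_y = as.numeric(eaf_y), chrom = as.character(chrom),
         pos = as.numeric(pos), audit = audit),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized exposure/outcome set:", length(x$rsids),
      "aligned variants\n")
  tab <- table(x$audit$action)
  cat("  audit:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.harmonized_set <- function(x, ...) {
  data.frame(rsid = x$rsids, chrom = x$chrom, pos = x$pos,
             beta_x = x$beta_x, se_x = x$se_x, beta_y = x$beta_y,
             se_y = x$se_y, eaf_x = x$eaf_x, eaf_y = x$eaf_y,
             stringsAsFactors = FALSE)
}

#' Number of aligned variants
#' @param h a `harmonized_set`.
#' @return integer count.
#' @export
n_snp <- function(h) length(h$rsids)

#' Restrict a harmonized set to a subset of variants
#'
#' @param h a `harmonized_set`.
#' @param rsids identifiers to keep; order of `h` is preserved.
#' @return a `harmonized_set` over the intersection.
#' @export
subset_harmonized <- function(h, rsids) {
  keep <- h$rsids %in% rsids
  harmonized_set(h$rsids[keep], h$beta_x[keep], h$se_x[keep],
                 h$beta_y[keep], h$se_y[keep], h$eaf_x[keep],
                 h$eaf_y[keep], h$chrom[keep], h$pos[keep],
                 audit = h$audit[h$audit$rsid %in% h$rsids[keep], ,
                                 drop = FALSE])
}

#' Harmonize outcome effects to the exposure effect allele
#'
#' For each exposure variant the matching outcome record (by rsid) is
#' aligned so both effects refer to the same allele:
#' \itemize{
#'   \item absent from the outcome: dropped (`dropped_missing`), never
#'     imputed by LD proxy;
#'   \item alleles equal: kept as is;
#'   \item effect/other alleles swapped: outcome beta negated and outcome
#'     frequency complemented (`flipped`);
#'   \item alleles matching only after strand complement (A<->T, C<->G per
#'     base): complemented, then the same swap logic (`complemented`);
#'   \item palindromic pairs (A/T or C/G), where allele labels cannot
#'     resolve strand, handled per `palindrome_policy`;
#'   \item irreconcilable allele sets: dropped with a warning
#'     (`dropped_mismatch`), not an error.
#' }
#' Standard errors are never altered; only signs and frequencies change.
#'
#' @param exposure variant association table with unique rsids.
#' @param outcome variant association table (or the result of
#'   [read_outcome_summary()]).
#' @param palindrome_policy `"infer_by_eaf"` aligns palindromic variants by
#'   comparing both frequencies to 0.5, dropping the variant when either
#'   frequency lies within `eaf_ambiguity_band` of 0.5; `"drop"` removes
#'   all palindromic variants; `"keep"` treats them as already aligned.
#' @param eaf_ambiguity_band half-width of the ambiguous frequency zone
#'   around 0.5 (default 0.08, i.e. drop when EAF is in [0.42, 0.58]).
#' @return a `harmonized_set`; its `audit` covers every exposure variant
#'   exactly once.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer_by_eaf", "drop", "keep"),
                      eaf_ambiguity_band = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (anyDuplicated(exposure$rsid)) {
    stop("exposure rsids must be unique", call. = FALSE)
  }
  out_idx <- match(exposure$rsid, outcome$rsid)

  J <- nrow(exposure)
  action <- character(J)
  reason <- character(J)
  beta_y <- se_y <- eaf_y <- rep(NA_real_, J)

  for (j in seq_len(J)) {
    i <- out_idx[j]
    if (is.na(i)) {
      action[j] <- "dropped_missing"
      reason[j] <- "variant absent from outcome summary statistics"
      next
    }
    ea_x <- exposure$effect_allele[j]; oa_x <- exposure$other_allele[j]
    ea_y <- outcome$effect_allele[i];  oa_y <- outcome$other_allele[i]
    b_y <- outcome$beta[i]; s_y <- outcome$se[i]; f_y <- outcome$eaf[i]

    if (is_palindromic(ea_x, oa_x)) {
      if (palindrome_policy == "drop") {
        action[j] <- "dropped_palindromic"
        reason[j] <- "palindromic allele pair, policy drop"
        next
      }
      if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
        action[j] <- "dropped_mismatch"
        reason[j] <- sprintf("outcome alleles %s/%s irreconcilable with %s/%s",
                             ea_y, oa_y, ea_x, oa_x)
        warning("alleles irreconcilable for ", exposure$rsid[j],
                "; variant dropped")
        next
      }
      if (palindrome_policy == "keep") {
        # labels are strand-ambiguous; trust the reported orientation
        if (ea_y != ea_x) { b_y <- -b_y; f_y <- 1 - f_y }
        action[j] <- "kept"
        reason[j] <- "palindromic, policy keep (label orientation trusted)"
      } else { # infer_by_eaf
        f_x <- exposure$eaf[j]
        if (is.na(f_x) || is.na(f_y) ||
            abs(f_x - 0.5) < eaf_ambiguity_band ||
            abs(f_y - 0.5) < eaf_ambiguity_band) {
          action[j] <- "dropped_palindromic"
          reason[j] <- "palindromic with frequency too close to 0.5 to orient"
          next
        }
        # align by frequency: same side of 0.5 means same allele
        if ((f_x < 0.5) != (f_y < 0.5)) { b_y <- -b_y; f_y <- 1 - f_y }
        action[j] <- "kept"
        reason[j] <- "palindromic, oriented by allele frequency"
      }
    } else {
      cea_y <- complement_allele(ea_y); coa_y <- complement_allele(oa_y)
      if (ea_y == ea_x && oa_y == oa_x) {
        action[j] <- "kept"
        reason[j] <- "alleles already aligned"
      } else if (ea_y == oa_x && oa_y == ea_x) {
        b_y <- -b_y; f_y <- 1 - f_y
        action[j] <- "flipped"
        reason[j] <- "effect/other alleles swapped; beta negated"
      } else if (!is.na(cea_y) && cea_y == ea_x && coa_y == oa_x) {
        action[j] <- "complemented"
        reason[j] <- "outcome on opposite strand; complemented"
      } else if (!is.na(cea_y) && cea_y == oa_x && coa_y == ea_x) {
        b_y <- -b_y; f_y <- 1 - f_y
        action[j] <- "complemented"
        reason[j] <- "opposite strand and swapped; complemented and negated"
      } else {
        action[j] <- "dropped_mismatch"
        reason[j] <- sprintf("outcome alleles %s/%s irreconcilable with %s/%s",
                             ea_y, oa_y, ea_x, oa_x)
        warning("alleles irreconcilable for ", exposure$rsid[j],
                "; variant dropped")
        next
      }
    }
    beta_y[j] <- b_y; se_y[j] <- s_y; eaf_y[j] <- f_y
  }

  audit <- data.frame(rsid = exposure$rsid, action = action,
                      reason = reason, stringsAsFactors = FALSE)
  keep <- !startsWith(action, "dropped")
  harmonized_set(
    rsids = exposure$rsid[keep],
    beta_x = exposure$beta[keep], se_x = exposure$se[keep],
    beta_y = beta_y[keep], se_y = se_y[keep],
    eaf_x = exposure$eaf[keep], eaf_y = eaf_y[keep],
    chrom = exposure$chrom[keep], pos = exposure$pos[keep],
    audit = audit
  )
}
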