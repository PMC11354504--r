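# Full-study orchestration: per outcome — harmonize, clump to the
# canonical instrument set, produce the five estimates, run the
# sensitivity diagnostics on both instrument sets, and apply Bonferroni
# control across outcomes. Output is a pure function of (inputs, config,
# seed).

#' Study configuration
#'
#' Defaults are the published analysis parameters: clumping at
#' r-squared < 0.01 with a 10,000 kb distance cutoff, family-wise alpha
#' 0.05 over the five stroke outcomes, exposure sample size 18,371.
#'
#' @param exposure_path path to the exposure instrument table.
#' @param outcome_paths named character vector, outcome label -> path.
#' @param ld_path optional path to the signed LD correlation matrix; when
#'   absent the correlated-instrument methods are skipped with a warning.
#' @param exposure_n exposure sample size attached to instrument records.
#' @param clump_r2 squared-correlation clumping cutoff.
#' @param clump_window_kb pairwise clumping distance cutoff in kb.
#' @param variance_model `"multiplicative_random"` or `"fixed"`.
#' @param palindrome_policy,eaf_ambiguity_band see [harmonize()].
#' @param n_boot weighted-median bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @param alpha family-wise error level.
#' @param family_size Bonferroni family size; defaults to the number of
#'   outcomes.
#' @return list of class `study_config`.
#' @export
study_config <- function(exposure_path, outcome_paths, ld_path = NULL,
                         exposure_n = 18371, clump_r2 = 0.01,
                         clump_window_kb = 10000,
                         variance_model = c("multiplicative_random",
                                            "fixed"),
                         palindrome_policy = "infer_by_eaf",
                         eaf_ambiguity_band = 0.08,
                         n_boot = 1000, seed = 1, alpha = 0.05,
                         family_size = NULL) {
  variance_model <- match.arg(variance_model)
  if (is.null(names(outcome_paths)) || any(names(outcome_paths) == "")) {
    stop("outcome_paths must be a named vector (label = path)",
         call. = FALSE)
  }
  if (is.null(family_size)) family_size <- length(outcome_paths)
  if (family_size < 1) stop("family_size must be >= 1", call. = FALSE)
  structure(
    list(exposure_path = exposure_path, outcome_paths = outcome_paths,
         ld_path = ld_path, exposure_n = exposure_n, clump_r2 = clump_r2,
         clump_window_kb = clump_window_kb, variance_model = variance_model,
         palindrome_policy = palindrome_policy,
         eaf_ambiguity_band = eaf_ambiguity_band, n_boot = n_boot,
         seed = seed, alpha = alpha, family_size = family_size),
    class = "study_config"
  )
}

# Canonical forest ordering: the five stroke outcomes first, in the
# published block order, then any user-defined labels alphabetically.
.order_outcomes <- function(labels) {
  canon <- c("AS", "AIS", "CES", "LAS", "SVS")
  c(intersect(canon, labels), sort(setdiff(labels, canon)))
}

#' Run the full Mendelian randomization study
#'
#' For each outcome: harmonize to the exposure effect alleles, derive the
#' canonical instrument set by greedy LD clumping and the all-variant set,
#' then produce the five estimates — IVW and MR-Egger on the clumped set,
#' their LD-aware correlated forms on the all-variant set, and the
#' weighted median on the clumped set — plus sensitivity reports for both
#' sets and Bonferroni significance flags at `alpha / family_size` on the
#' canonical IVW p-values. Missing LD downgrades gracefully: the two
#' correlated methods are skipped with a warning. Fewer than three
#' clumped variants skips Egger and the weighted median with a warning.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, `estimates.tsv`,
#'   `sensitivity.tsv` and `audit.log` are written there.
#' @return list with `estimates` (data.frame, one row per outcome/method,
#'   with Bonferroni flags on the canonical IVW rows), `sensitivity`
#'   (data.frame, one row per outcome/instrument set) and `audit`
#'   (data.frame of harmonization and clumping events).
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  exposure <- read_exposure_instruments(config$exposure_path,
                                        n = config$exposure_n)
  ld <- if (!is.null(config$ld_path)) read_ld_matrix(config$ld_path)
  labels <- .order_outcomes(names(config$outcome_paths))

  est_rows <- list()
  sens_rows <- list()
  audit_rows <- list()
  thr <- bonferroni_threshold(config$alpha, config$family_size)

  for (k in seq_along(labels)) {
    label <- labels[k]
    outcome <- read_outcome_summary(config$outcome_paths[[label]],
                                    rsid_filter = exposure$rsid,
                                    label = label)
    h_all <- harmonize(exposure, outcome,
                       palindrome_policy = config$palindrome_policy,
                       eaf_ambiguity_band = config$eaf_ambiguity_band)
    audit_rows[[length(audit_rows) + 1]] <- data.frame(
      outcome = rep(label, nrow(h_all$audit)), stage = "harmonization",
      rsid = h_all$audit$rsid, action = h_all$audit$action,
      detail = h_all$audit$reason, stringsAsFactors = FALSE
    )
    if (n_snp(h_all) == 0) {
      warning("no variants aligned for ", label, "; outcome skipped")
      next
    }

    # canonical set: clump the harmonized variants on exposure statistics
    exp_h <- exposure[exposure$rsid %in% h_all$rsids, , drop = FALSE]
    if (!is.null(ld)) {
      kept <- ld_clump(exp_h, ld, r2_threshold = config$clump_r2,
                       window_kb = config$clump_window_kb)
      creport <- attr(kept, "report")
      audit_rows[[length(audit_rows) + 1]] <- data.frame(
        outcome = label, stage = "clumping", rsid = creport$rsid,
        action = creport$status,
        detail = ifelse(is.na(creport$index_rsid), "",
                        sprintf("index=%s r2=%.4g dist_bp=%.0f",
                                creport$index_rsid, creport$r2_to_index,
                                creport$distance_bp)),
        stringsAsFactors = FALSE
      )
      h_can <- subset_harmonized(h_all, as.character(kept))
    } else {
      warning("no LD matrix: clumping skipped, canonical set = all ",
              "variants for ", label)
      h_can <- h_all
    }

    add <- function(fit) {
      row <- cbind(data.frame(outcome = label, stringsAsFactors = FALSE),
                   as.data.frame(fit))
      est_rows[[length(est_rows) + 1]] <<- row
    }

    fit_ivw <- mr_ivw(h_can, config$variance_model)
    add(fit_ivw)
    if (!is.null(ld)) {
      add(mr_ivw_correlated(h_all, ld, config$variance_model))
    } else {
      warning("LD matrix missing: correlated-instrument methods skipped ",
              "for ", label)
    }
    if (n_snp(h_can) >= 3) {
      add(mr_egger(h_can, config$variance_model))
    } else {
      warning("fewer than 3 canonical instruments: Egger skipped for ",
              label)
    }
    if (!is.null(ld) && n_snp(h_all) >= 3) {
      add(mr_egger_correlated(h_all, ld, config$variance_model))
    }
    if (n_snp(h_can) >= 3) {
      add(mr_weighted_median(h_can, n_boot = config$n_boot,
                             seed = config$seed + k))
    } else {
      warning("fewer than 3 canonical instruments: weighted median ",
              "skipped for ", label)
    }

    if (n_snp(h_can) >= 2) {
      sens_rows[[length(sens_rows) + 1]] <-
        sensitivity_report(h_can, ld = NULL, outcome = label,
                           instrument_set = "canonical",
                           variance_model = config$variance_model)
    }
    if (!is.null(ld) && n_snp(h_all) >= 2) {
      sens_rows[[length(sens_rows) + 1]] <-
        sensitivity_report(h_all, ld = ld, outcome = label,
                           instrument_set = "all_snps",
                           variance_model = config$variance_model)
    }
  }

  estimates <- do.call(rbind, est_rows)
  rownames(estimates) <- NULL
  estimates$bonferroni_significant <-
    estimates$method == "ivw_canonical" & is_significant(estimates$p, thr)
  sensitivity <- do.call(rbind, sens_rows)
  rownames(sensitivity) <- NULL
  audit <- do.call(rbind, audit_rows)
  rownames(audit) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_estimates_table(estimates, file.path(out_dir, "estimates.tsv"))
    write_sensitivity_table(sensitivity,
                            file.path(out_dir, "sensitivity.tsv"))
    write_audit_log(audit, file.path(out_dir, "audit.log"))
  }
  list(estimates = estimates, sensitivity = sensitivity, audit = audit,
       bonferroni_threshold = thr)
}
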