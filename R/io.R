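# Readers and writers for the tabular artifacts: exposure instrument tables,
# outcome GWAS summary statistics, LD correlation matrices and result tables.
# All files are tab-separated UTF-8 text with a header row. Numbers are
# written with 15 significant digits so a write/read round trip preserves
# values to at least 12 significant digits.

.num_fmt <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.15g", x))
}

# Normalize typeset scientific notation ("1.28 × 10−34", unicode minus and
# multiplication sign) to parseable numerics.
.parse_numeric <- function(x) {
  x <- gsub("−", "-", x)                               # unicode minus
  x <- gsub("[[:space:]]*[x×][[:space:]]*10\\^?", "e", x)  # "× 10^" -> e
  x <- gsub("\\^|[[:space:]]", "", x)
  suppressWarnings(as.numeric(x))
}

# Resolve one logical column among its accepted aliases, order-independently.
.find_col <- function(header, aliases) {
  hit <- which(tolower(header) %in% tolower(aliases))
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Read an exposure instrument table
#'
#' Reads a tab-separated instrument table with header columns
#' `SNP, Chr, Position, EAF, EA, OA, Beta, SE, p` and optionally `N`.
#' When the file carries no `N` column the shared exposure sample size is
#' attached to every record via `n`.
#'
#' @param path file path.
#' @param n shared exposure sample size used when the file has no `N`
#'   column. Defaults to 18371 (9114 cases + 9257 controls of the chronic
#'   hepatitis B discovery GWAS).
#' @return a validated variant association table, row order preserved.
#' @export
read_exposure_instruments <- function(path, n = 18371) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  header <- names(raw)
  cols <- c(rsid = "SNP", chrom = "Chr", pos = "Position", eaf = "EAF",
            effect_allele = "EA", other_allele = "OA", beta = "Beta",
            se = "SE", pvalue = "p")
  idx <- vapply(cols, function(a) .find_col(header, a), integer(1))
  if (anyNA(idx)) {
    stop("exposure table missing required column(s): ",
         paste(cols[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("exposure table ", path, " has a header but no rows")
    return(variant_association(character(0), effect_allele = character(0),
                               other_allele = character(0),
                               beta = numeric(0), se = numeric(0)))
  }
  num <- function(field) {
    v <- .parse_numeric(raw[[idx[field]]])
    bad <- which(is.na(v) & !(raw[[idx[field]]] %in% c("NA", "")))
    if (field %in% c("beta", "se") && length(bad) > 0) {
      stop("non-numeric ", field, " at data row ", bad[1], " of ", path,
           call. = FALSE)
    }
    v
  }
  n_idx <- .find_col(header, c("N", "n", "sample_size"))
  n_vec <- if (is.na(n_idx)) rep(n, nrow(raw)) else .parse_numeric(raw[[n_idx]])
  variant_association(
    rsid = raw[[idx["rsid"]]], chrom = raw[[idx["chrom"]]],
    pos = num("pos"), effect_allele = raw[[idx["effect_allele"]]],
    other_allele = raw[[idx["other_allele"]]], eaf = num("eaf"),
    beta = num("beta"), se = num("se"), pvalue = num("pvalue"), n = n_vec
  )
}

#' Load the packaged chronic hepatitis B instrument table
#'
#' The 12 genome-wide-significant variants from the Chinese chronic
#' hepatitis B GWAS (9114 cases, 9257 controls), shipped as a plain-text
#' fixture. Eleven lie in the HLA region on chromosome 6; rs1883832 is on
#' chromosome 20.
#'
#' @param n exposure sample size attached to each record.
#' @return a variant association table of 12 rows.
#' @export
chb_instruments <- function(n = 18371) {
  read_exposure_instruments(
    system.file("extdata", "chb_instruments.tsv", package = "chbstroke",
                mustWork = TRUE),
    n = n
  )
}

#' Default column aliases for outcome summary-statistics files
#'
#' Covers plain names, capitalized GWAS conventions, and GWAS-Catalog
#' harmonised headers (`hm_rsid`, `hm_effect_allele`, `standard_error`,
#' `p_value`, ...).
#'
#' @return named list mapping logical fields to accepted header aliases.
#' @export
outcome_column_aliases <- function() {
  list(
    rsid = c("rsid", "SNP", "snp", "hm_rsid", "variant_id", "markername"),
    chrom = c("chrom", "chr", "Chr", "chromosome", "hm_chrom"),
    pos = c("pos", "position", "Position", "base_pair_location", "hm_pos"),
    effect_allele = c("effect_allele", "EA", "ea", "hm_effect_allele",
                      "allele1"),
    other_allele = c("other_allele", "OA", "oa", "hm_other_allele",
                     "allele2"),
    eaf = c("eaf", "EAF", "effect_allele_frequency",
            "hm_effect_allele_frequency", "freq1"),
    beta = c("beta", "Beta", "hm_beta", "b"),
    or = c("or", "OR", "odds_ratio", "hm_odds_ratio"),
    se = c("se", "SE", "standard_error", "stderr"),
    pvalue = c("p", "pvalue", "p_value", "P", "pval"),
    n = c("n", "N", "sample_size")
  )
}

#' Read outcome GWAS summary statistics
#'
#' Reads a tab-separated outcome file, resolving column names through a
#' configurable alias table. Files carrying an odds-ratio column and no
#' beta column have effects converted to the log scale at parse time; all
#' internal effects are log-odds. Variants absent from the file are simply
#' absent from the result (the caller decides how to handle them).
#'
#' @param path file path.
#' @param rsid_filter optional character vector; when given, records are
#'   restricted to these identifiers.
#' @param label outcome name attached to the result (e.g. "LAS").
#' @param aliases column-alias table, see [outcome_column_aliases()].
#' @return a variant association table with attribute `label`.
#' @export
read_outcome_summary <- function(path, rsid_filter = NULL, label = "outcome",
                                 aliases = outcome_column_aliases()) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  header <- names(raw)
  idx <- vapply(aliases, function(a) .find_col(header, a), integer(1))
  required <- c("rsid", "effect_allele", "other_allele", "se", "pvalue")
  if (any(is.na(idx[required]))) {
    stop("outcome file missing unmappable required column(s): ",
         paste(required[is.na(idx[required])], collapse = ", "),
         call. = FALSE)
  }
  if (is.na(idx["beta"]) && is.na(idx["or"])) {
    stop("outcome file has neither a beta nor an odds-ratio column",
         call. = FALSE)
  }
  get <- function(field, default = NA) {
    if (is.na(idx[field])) rep(default, nrow(raw)) else raw[[idx[field]]]
  }
  beta <- if (!is.na(idx["beta"])) {
    .parse_numeric(raw[[idx["beta"]]])
  } else {
    log(.parse_numeric(raw[[idx["or"]]]))
  }
  d <- variant_association(
    rsid = get("rsid"), chrom = get("chrom", NA_character_),
    pos = .parse_numeric(get("pos")),
    effect_allele = get("effect_allele"), other_allele = get("other_allele"),
    eaf = .parse_numeric(get("eaf")), beta = beta,
    se = .parse_numeric(get("se")),
    pvalue = .parse_numeric(get("pvalue")),
    n = .parse_numeric(get("n"))
  )
  if (!is.null(rsid_filter)) {
    d <- d[d$rsid %in% rsid_filter, , drop = FALSE]
    if (nrow(d) == 0) {
      warning("no outcome records remain after rsid filtering for ", label)
    }
    rownames(d) <- NULL
  }
  attr(d, "label") <- label
  d
}

#' Read an LD correlation matrix
#'
#' Reads a tab-separated square matrix of signed pairwise correlations
#' (r, not r-squared) with variant identifiers as header row and first
#' column. The matrix is validated (symmetry within 1e-8 then symmetrized,
#' unit diagonal, entries bounded by 1 in magnitude).
#'
#' @param path file path.
#' @return a numeric matrix with rsid dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  validate_ld_matrix(m)
}

#' Validate an LD correlation matrix
#'
#' @param m square numeric matrix with identical row/column names.
#' @param tol symmetry tolerance; asymmetry beyond it is an error, within
#'   it the matrix is symmetrized as (m + t(m)) / 2.
#' @return the validated, symmetrized matrix.
#' @export
validate_ld_matrix <- function(m, tol = 1e-8) {
  if (nrow(m) != ncol(m)) stop("LD matrix is not square", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m))) {
    stop("LD matrix row and column names must be identical rsids",
         call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop("LD matrix asymmetric beyond tolerance ", tol, call. = FALSE)
  }
  m <- (m + t(m)) / 2
  if (any(abs(diag(m) - 1) > tol)) {
    stop("LD matrix diagonal entries must equal 1", call. = FALSE)
  }
  diag(m) <- 1
  if (any(abs(m) > 1 + tol)) {
    stop("LD matrix entries must lie in [-1, 1]", call. = FALSE)
  }
  m[m > 1] <- 1
  m[m < -1] <- -1
  m
}

#' Write an LD matrix
#'
#' @param m LD matrix with rsid dimnames.
#' @param path destination path.
#' @export
write_ld_matrix <- function(m, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("rsid", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], .num_fmt(m[i, ])), collapse = "\t"),
               con)
  }
  invisible(NULL)
}

#' Write a variant association table
#'
#' Inverse of [read_exposure_instruments()]: writes the standard exposure
#' header so synthetic studies can be exported and re-read.
#'
#' @param d variant association table.
#' @param path destination path.
#' @export
write_association_table <- function(d, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("SNP", "Chr", "Position", "EAF", "EA", "OA", "Beta",
                     "SE", "p", "N"), collapse = "\t"), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(d$rsid[i], d$chrom[i], .num_fmt(d$pos[i]),
                       .num_fmt(d$eaf[i]), d$effect_allele[i],
                       d$other_allele[i], .num_fmt(d$beta[i]),
                       .num_fmt(d$se[i]), .num_fmt(d$pvalue[i]),
                       .num_fmt(d$n[i])), collapse = "\t"), con)
  }
  invisible(NULL)
}

#' Write an estimates table
#'
#' One row per (outcome, method) pair with columns
#' `outcome, method, n_snp, logOR, SE, OR, CI_low, CI_high, p`, mirroring
#' the forest-table layout of the five-method analysis.
#'
#' @param estimates a data.frame as returned by [run_full_analysis()], or a
#'   list of `mr_estimate` objects (then `outcome` must label them via an
#'   `outcome` element).
#' @param path destination path.
#' @export
write_estimates_table <- function(estimates, path) {
  if (!is.data.frame(estimates)) {
    estimates <- do.call(rbind, lapply(estimates, as.data.frame))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  cols <- c("outcome", "method", "n_snp", "logOR", "SE", "OR", "CI_low",
            "CI_high", "p")
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(estimates) == 0) {
    warning("writing a header-only estimates table")
    return(invisible(NULL))
  }
  for (i in seq_len(nrow(estimates))) {
    r <- estimates[i, ]
    writeLines(paste(c(r$outcome, r$method, r$n_snp, .num_fmt(r$logOR),
                       .num_fmt(r$SE), .num_fmt(r$OR), .num_fmt(r$CI_low),
                       .num_fmt(r$CI_high), .num_fmt(r$p)),
                     collapse = "\t"), con)
  }
  invisible(NULL)
}

#' Read back an estimates table
#'
#' @param path file written by [write_estimates_table()].
#' @return data.frame with numeric columns restored.
#' @export
read_estimates_table <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("n_snp", "logOR", "SE", "OR", "CI_low", "CI_high", "p")) {
    d[[col]] <- as.numeric(d[[col]])
  }
  d
}

#' Write a sensitivity table in the pleiotropy/heterogeneity layout
#'
#' Long form: one row per (outcome, instrument set) with the Egger
#' intercept triple and the Cochran's Q triple, the two column groups of
#' the canonical/all-variant sensitivity summary.
#'
#' @param sens data.frame of sensitivity rows (see [run_full_analysis()]).
#' @param path destination path.
#' @export
write_sensitivity_table <- function(sens, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  cols <- c("outcome", "instrument_set", "n_snp", "egger_intercept",
            "egger_intercept_se", "egger_intercept_p", "q_stat", "q_df",
            "q_p")
  writeLines(paste(cols, collapse = "\t"), con)
  for (i in seq_len(nrow(sens))) {
    r <- sens[i, ]
    writeLines(paste(c(r$outcome, r$instrument_set, r$n_snp,
                       .num_fmt(r$egger_intercept),
                       .num_fmt(r$egger_intercept_se),
                       .num_fmt(r$egger_intercept_p), .num_fmt(r$q_stat),
                       r$q_df, .num_fmt(r$q_p)), collapse = "\t"), con)
  }
  invisible(NULL)
}

#' Write a harmonization/clumping audit log
#'
#' Machine-readable tab-separated event log with columns
#' `outcome, stage, rsid, action, detail`.
#'
#' @param audit data.frame of audit rows.
#' @param path destination path.
#' @export
write_audit_log <- function(audit, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("outcome", "stage", "rsid", "action", "detail"),
                   collapse = "\t"), con)
  for (i in seq_len(nrow(audit))) {
    writeLines(paste(unlist(audit[i, c("outcome", "stage", "rsid", "action",
                                       "detail")]), collapse = "\t"), con)
  }
  invisible(NULL)
}
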