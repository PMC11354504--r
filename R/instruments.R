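# Instrument-strength screening (variance explained and F-statistic) and
# greedy LD clumping of summary statistics to an independent instrument set.

#' Variance in the exposure explained by one variant
#'
#' Two standard approximations are available:
#' \describe{
#'   \item{eaf}{\eqn{R^2 = 2 f (1-f) \beta^2} with `f` the effect-allele
#'     frequency; assumes a standardized trait.}
#'   \item{zscore}{\eqn{R^2 = z^2 / (z^2 + N - 2)} with
#'     \eqn{z = \beta / SE}; needs only the reported effect, its SE and the
#'     sample size, and is the package default because it recovers the
#'     published instrument F-statistics most closely.}
#' }
#'
#' @param v a one-row variant association table (or a list with fields
#'   `beta`, `se`, `eaf`, `n`).
#' @param mode `"zscore"` (default) or `"eaf"`.
#' @return the explained variance, in [0, 1).
#' @export
explained_variance <- function(v, mode = c("zscore", "eaf")) {
  mode <- match.arg(mode)
  if (mode == "eaf") {
    if (is.null(v$eaf) || is.na(v$eaf)) {
      stop("mode 'eaf' requires the effect-allele frequency", call. = FALSE)
    }
    r2 <- 2 * v$eaf * (1 - v$eaf) * v$beta^2
  } else {
    if (is.null(v$n) || is.na(v$n) || is.na(v$se)) {
      stop("mode 'zscore' requires se and n", call. = FALSE)
    }
    z <- v$beta / v$se
    r2 <- z^2 / (z^2 + v$n - 2)
  }
  if (any(r2 >= 1)) {
    stop("explained variance >= 1: degenerate input", call. = FALSE)
  }
  r2
}

#' Instrument-strength F-statistic
#'
#' \eqn{F = R^2 (N - 2) / (1 - R^2)}. F > 10 is the conventional screen
#' against weak-instrument bias.
#'
#' @param r2 variance explained, in [0, 1).
#' @param n exposure sample size, > 2.
#' @return the F value, >= 0.
#' @export
f_statistic <- function(r2, n) {
  if (any(r2 < 0) || any(r2 >= 1)) {
    stop("r2 must lie in [0, 1)", call. = FALSE)
  }
  if (any(n <= 2)) stop("n must exceed 2", call. = FALSE)
  r2 * (n - 2) / (1 - r2)
}

#' Instrument strength for every variant of a table
#'
#' @param d variant association table.
#' @param mode passed to [explained_variance()].
#' @return data.frame with columns `rsid, r2, f_stat, mode`.
#' @export
instrument_strength <- function(d, mode = c("zscore", "eaf")) {
  mode <- match.arg(mode)
  r2 <- vapply(seq_len(nrow(d)),
               function(i) explained_variance(d[i, ], mode), numeric(1))
  data.frame(rsid = d$rsid, r2 = r2, f_stat = f_statistic(r2, d$n),
             mode = mode, stringsAsFactors = FALSE)
}

#' Greedy LD clumping to an independent instrument set
#'
#' Variants are ranked by association p-value (ascending; ties broken by
#' chromosome then position). The best remaining variant is kept and all
#' remaining variants on the same chromosome within `window_kb` of it whose
#' squared correlation with it is at least `r2_threshold` are removed;
#' this repeats until no variants remain. Variants on different
#' chromosomes are never pruned against each other, and variants absent
#' from the LD matrix are treated as uncorrelated with all others (logged
#' in the report).
#'
#' @param variants variant association table with `rsid, chrom, pos,
#'   pvalue`.
#' @param ld signed LD correlation matrix covering (a superset of) the
#'   variants.
#' @param r2_threshold squared-correlation cutoff in (0, 1]; default 0.01.
#' @param window_kb pairwise distance cutoff in kilobases between index
#'   and candidate; default 10000 (10 Mb).
#' @return character vector of retained rsids in the original input order,
#'   with attribute `report`: a data.frame
#'   `rsid, status, index_rsid, r2_to_index, distance_bp`.
#' @export
ld_clump <- function(variants, ld, r2_threshold = 0.01, window_kb = 10000) {
  if (r2_threshold <= 0 || r2_threshold > 1) {
    stop("r2_threshold must lie in (0, 1]", call. = FALSE)
  }
  d <- variants
  in_ld <- d$rsid %in% rownames(ld)
  rho <- function(a, b) {
    if (!(a %in% rownames(ld)) || !(b %in% rownames(ld))) return(0)
    ld[a, b]
  }
  # canonical ranking: p ascending, ties by chromosome then position
  ord <- order(d$pvalue, d$chrom, d$pos)
  ranked <- d$rsid[ord]
  status <- stats::setNames(rep(NA_character_, nrow(d)), d$rsid)
  index_of <- stats::setNames(rep(NA_character_, nrow(d)), d$rsid)
  r2_to <- stats::setNames(rep(NA_real_, nrow(d)), d$rsid)
  dist_to <- stats::setNames(rep(NA_real_, nrow(d)), d$rsid)

  remaining <- ranked
  while (length(remaining) > 0) {
    idx <- remaining[1]
    remaining <- remaining[-1]
    status[idx] <- "kept"
    if (length(remaining) == 0) break
    ii <- match(idx, d$rsid)
    cand <- match(remaining, d$rsid)
    same_chr <- d$chrom[cand] == d$chrom[ii]
    dist_bp <- abs(d$pos[cand] - d$pos[ii])
    near <- same_chr & !is.na(dist_bp) & dist_bp < window_kb * 1000
    r2 <- vapply(remaining, function(r) rho(idx, r)^2, numeric(1))
    prune <- near & r2 >= r2_threshold
    for (r in remaining[prune]) {
      status[r] <- "removed"
      index_of[r] <- idx
      r2_to[r] <- r2[match(r, remaining)]
      dist_to[r] <- dist_bp[match(r, remaining)]
    }
    remaining <- remaining[!prune]
  }

  report <- data.frame(
    rsid = d$rsid, status = status[d$rsid],
    index_rsid = index_of[d$rsid], r2_to_index = r2_to[d$rsid],
    distance_bp = dist_to[d$rsid],
    in_ld_matrix = in_ld, stringsAsFactors = FALSE
  )
  kept <- d$rsid[status[d$rsid] == "kept"]
  structure(kept, report = report)
}
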