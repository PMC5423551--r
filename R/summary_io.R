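#' Convert an odds ratio to a log-odds effect size
#'
#' MR pooling is carried out on the additive (log-odds) scale, while GWAS
#' consortia typically report odds ratios. This is the natural-log transform
#' with domain checking.
#'
#' @param odds_ratio Numeric vector of odds ratios, all strictly positive.
#' @return Numeric vector of log-odds effects, `log(odds_ratio)`.
#' @examples
#' beta_from_or(1.03)
#' @export
beta_from_or <- function(odds_ratio) {
  if (!is.numeric(odds_ratio) || any(!is.finite(odds_ratio)) ||
      any(odds_ratio <= 0)) {
    stop("`odds_ratio` must be finite and strictly positive", call. = FALSE)
  }
  log(odds_ratio)
}

#' Recover a standard error from a reported confidence interval
#'
#' Summary tables often print an effect with its confidence interval but not
#' its standard error. Assuming normal sampling error, the SE is the CI width
#' divided by twice the standard-normal quantile at `(1 + level) / 2`. For
#' `scale = "log_odds"` the bounds are odds ratios and the width is taken on
#' the log scale; for `scale = "linear"` the bounds are used as given.
#'
#' The full-precision quantile (1.959964... at 95%) is used rather than the
#' conventional 1.96; the difference is below reporting precision.
#'
#' @param lower,upper Numeric vectors of confidence bounds, `lower < upper`.
#' @param level Confidence level of the interval, in (0, 1). Default 0.95.
#' @param scale `"log_odds"` (ratio bounds, must be positive) or `"linear"`.
#' @return Numeric vector of positive standard errors.
#' @examples
#' se_from_ci(0.97, 1.01)                      # odds-ratio bounds
#' se_from_ci(-0.23, 0.19, scale = "linear")   # additive bounds
#' @export
se_from_ci <- function(lower, upper, level = 0.95,
                       scale = c("log_odds", "linear")) {
  scale <- match.arg(scale)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("`level` must be a single probability in (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("confidence bounds must be finite", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("`lower` must be strictly below `upper`", call. = FALSE)
  }
  z <- stats::qnorm((1 + level) / 2)
  if (scale == "log_odds") {
    if (any(lower <= 0)) {
      stop("odds-ratio confidence bounds must be positive", call. = FALSE)
    }
    (log(upper) - log(lower)) / (2 * z)
  } else {
    (upper - lower) / (2 * z)
  }
}

# Canonical column set of the tab-separated dialect. Effect columns may be
# given either as (beta, se), (beta, ci_lower, ci_upper) or
# (or, ci_lower, ci_upper); everything except rsid/effect columns is optional.
.st_columns <- c("rsid", "effect_allele", "other_allele", "eaf",
                 "beta", "se", "or", "ci_lower", "ci_upper", "p", "n")
.st_numeric <- c("eaf", "beta", "se", "or", "ci_lower", "ci_upper", "p", "n")

.new_study_table <- function(records, study_id, trait, scale) {
  stopifnot(is.data.frame(records))
  structure(records,
            study_id = study_id, trait = trait, scale = scale,
            class = c("study_table", "data.frame"))
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated UTF-8 table with a header into a `study_table` (a
#' data frame with one row per SNP and attributes `study_id`, `trait` and
#' `scale`). Effects may be supplied as `beta` + `se`, as `beta` +
#' `ci_lower`/`ci_upper` (additive bounds), or as `or` + `ci_lower`/`ci_upper`
#' (ratio bounds, converted to log-odds via [beta_from_or()] and
#' [se_from_ci()]). If both a beta and an odds-ratio column set are present
#' the beta set takes precedence and a warning is issued. Row order is
#' preserved; `p`, `n`, `eaf` and `other_allele` are optional.
#'
#' @param path Path to the file.
#' @param study_id Label for the contributing study or meta-analysis.
#' @param trait Label for the trait the effects refer to.
#' @param scale Effect scale: `"log_odds"` for binary traits, `"linear"` for
#'   continuous traits. Ignored (forced to `"log_odds"`) when effects are
#'   read from an odds-ratio column set.
#' @param level Confidence level of any `ci_lower`/`ci_upper` columns.
#' @return A `study_table` data frame with columns
#'   `rsid, effect_allele, other_allele, eaf, beta, se, p, n`.
#' @seealso [write_summary_table()], [harmonize_tables()]
#' @export
read_summary_table <- function(path, study_id, trait,
                               scale = c("log_odds", "linear"),
                               level = 0.95) {
  scale <- match.arg(scale)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = c("NA", ""))
  if (!"rsid" %in% names(raw)) {
    stop("required column missing from ", basename(path), ": rsid",
         call. = FALSE)
  }
  has <- function(cols) all(cols %in% names(raw))
  has_beta_se <- has(c("beta", "se"))
  has_beta_ci <- has(c("beta", "ci_lower", "ci_upper"))
  has_or_ci <- has(c("or", "ci_lower", "ci_upper"))
  if (!has_beta_se && !has_beta_ci && !has_or_ci) {
    stop("required effect columns missing from ", basename(path),
         ": need (beta, se), (beta, ci_lower, ci_upper) or ",
         "(or, ci_lower, ci_upper)", call. = FALSE)
  }

  num <- function(col) {
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s', row %d of %s",
                   x[bad[1]], col, bad[1], basename(path)), call. = FALSE)
    }
    out
  }
  chr <- function(col) {
    if (col %in% names(raw)) as.character(raw[[col]])
    else rep(NA_character_, nrow(raw))
  }

  rsid <- chr("rsid")
  if (anyDuplicated(rsid)) {
    stop("duplicate rsid in ", basename(path), ": ",
         paste(unique(rsid[duplicated(rsid)]), collapse = ", "),
         call. = FALSE)
  }

  if (nrow(raw) == 0) {
    rec <- data.frame(rsid = character(), effect_allele = character(),
                      other_allele = character(), eaf = numeric(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      n = numeric(), stringsAsFactors = FALSE)
    return(.new_study_table(rec, study_id, trait, scale))
  }

  if ((has_beta_se || has_beta_ci) && has_or_ci && "or" %in% names(raw) &&
      any(!is.na(num("or")))) {
    warning("both beta and odds-ratio effect columns present in ",
            basename(path), "; beta columns take precedence", call. = FALSE)
  }

  if (has_beta_se) {
    beta <- num("beta"); se <- num("se")
  } else if (has_beta_ci) {
    beta <- num("beta")
    se <- se_from_ci(num("ci_lower"), num("ci_upper"), level, "linear")
  } else {
    or <- num("or")
    beta <- beta_from_or(or)
    se <- se_from_ci(num("ci_lower"), num("ci_upper"), level, "log_odds")
    scale <- "log_odds"
  }
  if (any(!is.na(beta) & (is.na(se) | se <= 0))) {
    stop("every beta requires a positive standard error (", basename(path),
         ")", call. = FALSE)
  }
  p <- num("p")
  if (any(!is.na(p) & (p <= 0 | p > 1))) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  eaf <- num("eaf")
  if (any(!is.na(eaf) & (eaf <= 0 | eaf >= 1))) {
    stop("effect-allele frequencies must lie in (0, 1)", call. = FALSE)
  }

  rec <- data.frame(rsid = rsid,
                    effect_allele = chr("effect_allele"),
                    other_allele = chr("other_allele"),
                    eaf = eaf, beta = beta, se = se, p = p, n = num("n"),
                    stringsAsFactors = FALSE)
  .new_study_table(rec, study_id, trait, scale)
}

#' Write a summary-statistics table in the package's tab-separated dialect
#'
#' Numeric values are written with enough digits that reading the file back
#' with [read_summary_table()] reproduces the records exactly.
#'
#' @param x A `study_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(x, path) {
  stopifnot(inherits(x, "study_table"))
  out <- as.data.frame(x)
  for (col in intersect(names(out), .st_numeric)) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA,
                         sprintf("%.17g", out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s on %s (%s scale), %d SNP%s\n",
              attr(x, "study_id"), attr(x, "trait"), attr(x, "scale"),
              nrow(x), if (nrow(x) == 1) "" else "s"))
  print(as.data.frame(x), ...)
  invisible(x)
}

.complement <- function(allele) chartr("ACGT", "TGCA", toupper(allele))

.is_palindromic <- function(a, b) {
  !is.na(a) && !is.na(b) && identical(.complement(a), toupper(b))
}

#' Harmonize an exposure/outcome record pair to a common effect allele
#'
#' Two-sample MR requires the SNP-outcome effect to be expressed for the same
#' allele as the SNP-exposure effect. If the outcome record reports the
#' opposite allele, its effect sign is flipped and its allele frequency
#' complemented. Palindromic SNPs (A/T or C/G) with both allele frequencies
#' near 0.5 (both in (0.42, 0.58)) cannot be strand-resolved and raise an
#' error.
#'
#' @param exposure,outcome Single-row data frames (or lists) with at least
#'   `rsid`, `effect_allele`, `beta`; optionally `other_allele`, `eaf`, `se`.
#' @return A list of class `harmonized_pair` with elements `rsid`,
#'   `exposure`, `outcome` (possibly flipped) and `flipped`.
#' @export
harmonize_pair <- function(exposure, outcome) {
  exposure <- as.list(exposure); outcome <- as.list(outcome)
  if (!identical(as.character(exposure$rsid), as.character(outcome$rsid))) {
    stop("exposure and outcome records refer to different SNPs (",
         exposure$rsid, " vs ", outcome$rsid, ")", call. = FALSE)
  }
  ea_x <- toupper(as.character(exposure$effect_allele))
  oa_x <- if (is.null(exposure$other_allele)) NA_character_ else
    toupper(as.character(exposure$other_allele))
  ea_y <- toupper(as.character(outcome$effect_allele))
  oa_y <- if (is.null(outcome$other_allele)) NA_character_ else
    toupper(as.character(outcome$other_allele))

  if (.is_palindromic(ea_x, oa_x)) {
    eaf_x <- exposure$eaf; eaf_y <- outcome$eaf
    if (!is.null(eaf_x) && !is.null(eaf_y) &&
        !is.na(eaf_x) && !is.na(eaf_y) &&
        eaf_x > 0.42 && eaf_x < 0.58 && eaf_y > 0.42 && eaf_y < 0.58) {
      stop("palindromic SNP ", exposure$rsid, " with allele frequencies ",
           "near 0.5: strand cannot be resolved", call. = FALSE)
    }
  }

  # try the outcome alleles as given, then strand-complemented; in either
  # orientation the full allele pair must be consistent with the exposure's
  orient <- function(ea, oa) {
    ok <- function(a, b) is.na(a) || is.na(b) || identical(a, b)
    if (ok(ea, ea_x) && ok(oa, oa_x) && !is.na(ea)) return(FALSE)
    if (ok(ea, oa_x) && ok(oa, ea_x) && !is.na(ea) && !is.na(oa_x)) {
      return(TRUE)
    }
    NA
  }
  flipped <- orient(ea_y, oa_y)
  if (is.na(flipped)) flipped <- orient(.complement(ea_y), .complement(oa_y))
  if (is.na(flipped)) {
    stop("allele sets incompatible for ", exposure$rsid, ": exposure ",
         ea_x, "/", oa_x, ", outcome ", ea_y, "/", oa_y, call. = FALSE)
  }

  if (flipped) {
    outcome$beta <- -outcome$beta
    if (!is.null(outcome$eaf) && !is.na(outcome$eaf)) {
      outcome$eaf <- 1 - outcome$eaf
    }
    outcome$effect_allele <- ea_x
    outcome$other_allele <- oa_x
  }
  structure(list(rsid = as.character(exposure$rsid), exposure = exposure,
                 outcome = outcome, flipped = flipped),
            class = "harmonized_pair")
}

#' Harmonize whole exposure and outcome tables
#'
#' Applies [harmonize_pair()] SNP by SNP and returns one data frame ready for
#' Wald-ratio estimation. Every exposure SNP must be present in the outcome
#' table; missing SNPs are reported together in the error.
#'
#' @param exposure,outcome `study_table` objects sharing rsids.
#' @return Data frame with columns `rsid, effect_allele, beta_x, se_x,
#'   beta_y, se_y, flipped`, in exposure-table order.
#' @export
harmonize_tables <- function(exposure, outcome) {
  missing <- setdiff(exposure$rsid, outcome$rsid)
  if (length(missing)) {
    stop("instrument/outcome rsid mismatch; missing from outcome table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(exposure)), function(i) {
    j <- match(exposure$rsid[i], outcome$rsid)
    hp <- harmonize_pair(exposure[i, , drop = FALSE],
                         outcome[j, , drop = FALSE])
    data.frame(rsid = hp$rsid,
               effect_allele = as.character(hp$exposure$effect_allele),
               beta_x = hp$exposure$beta,
               se_x = if (is.null(hp$exposure$se)) NA_real_ else hp$exposure$se,
               beta_y = hp$outcome$beta,
               se_y = hp$outcome$se,
               flipped = hp$flipped,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Substitute a proxy SNP for an unavailable target SNP
#'
#' When an instrument is absent from an outcome GWAS, the association of a
#' proxy variant in (near-)perfect linkage disequilibrium can stand in for
#' it. The proxy's record is re-keyed under the target rsid and the
#' substitution is appended to the table's provenance attribute.
#'
#' @param table A `study_table` containing `proxy_rsid`.
#' @param target_rsid rsid the record should be keyed under.
#' @param proxy_rsid rsid of the measured proxy variant.
#' @param r2 Linkage-disequilibrium r-squared between proxy and target.
#' @param min_r2 Minimum acceptable r-squared (default 1: perfect proxies
#'   only).
#' @return The modified `study_table`; `attr(, "proxy_log")` lists all
#'   substitutions applied.
#' @export
substitute_proxy <- function(table, target_rsid, proxy_rsid, r2,
                             min_r2 = 1.0) {
  stopifnot(inherits(table, "study_table"))
  if (!is.numeric(r2) || length(r2) != 1 || r2 < 0 || r2 > 1) {
    stop("`r2` must be a single value in [0, 1]", call. = FALSE)
  }
  if (r2 < min_r2) {
    stop(sprintf("proxy %s has r2 = %g, below the required minimum %g",
                 proxy_rsid, r2, min_r2), call. = FALSE)
  }
  i <- match(proxy_rsid, table$rsid)
  if (is.na(i)) {
    stop("proxy rsid not present in table: ", proxy_rsid, call. = FALSE)
  }
  table$rsid[i] <- target_rsid
  log_entry <- data.frame(target = target_rsid, proxy = proxy_rsid, r2 = r2,
                          stringsAsFactors = FALSE)
  attr(table, "proxy_log") <- rbind(attr(table, "proxy_log"), log_entry)
  table
}
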