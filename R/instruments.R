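#' Instrument-strength F-statistic from summary data
#'
#' The squared ratio of the SNP-exposure effect to its standard error,
#' i.e. the single-SNP regression F. Values well above 10 indicate that
#' weak-instrument bias is unlikely to be material.
#'
#' @param beta_x,se_x SNP-exposure effect and its positive SE.
#' @return Nonnegative F-statistic, `(beta_x / se_x)^2`.
#' @export
f_statistic <- function(beta_x, se_x) {
  if (any(!is.finite(se_x) | se_x <= 0)) {
    stop("`se_x` must be positive", call. = FALSE)
  }
  (beta_x / se_x)^2
}

#' Convert between the F-statistic and variance explained
#'
#' For a single regressor, `R2 = F / (F + n - 2)`; `f_from_r2` is the exact
#' inverse, `F = R2 * (n - 2) / (1 - R2)`.
#'
#' @param f Nonnegative F-statistic.
#' @param r2 Fraction of exposure variance explained, in [0, 1).
#' @param n Sample size, greater than 2.
#' @return A fraction (`r2_from_f`) or F-statistic (`f_from_r2`).
#' @export
r2_from_f <- function(f, n) {
  if (any(n <= 2)) stop("`n` must exceed 2", call. = FALSE)
  if (any(f < 0)) stop("`f` must be nonnegative", call. = FALSE)
  f / (f + n - 2)
}

#' @rdname r2_from_f
#' @export
f_from_r2 <- function(r2, n) {
  if (any(n <= 2)) stop("`n` must exceed 2", call. = FALSE)
  if (any(r2 < 0 | r2 >= 1)) stop("`r2` must lie in [0, 1)", call. = FALSE)
  r2 * (n - 2) / (1 - r2)
}

#' Bonferroni-corrected confounder screen for MR instruments
#'
#' Tests whether any instrument is associated with a measured confounder of
#' the exposure-outcome relation. With `m` instruments, significance is
#' declared at `p <= 0.05 / m` (inclusive boundary); the instrument set
#' passes the screen when no association reaches that threshold.
#'
#' @param assocs Data frame with columns `rsid`, `confounder`, `p`.
#' @param m Number of instruments used for the correction; defaults to the
#'   number of distinct rsids in `assocs`.
#' @param alpha Family-wise error rate before correction.
#' @return Object of class `confounder_screen`: list with `m`, `threshold`,
#'   `entries` (the input plus a `significant` flag) and `pass`.
#' @export
confounder_screen <- function(assocs, m = length(unique(assocs$rsid)),
                              alpha = 0.05) {
  stopifnot(is.data.frame(assocs),
            all(c("rsid", "confounder", "p") %in% names(assocs)))
  if (!is.numeric(m) || length(m) != 1 || m < 1) {
    stop("`m` must be a positive integer", call. = FALSE)
  }
  if (any(!is.finite(assocs$p) | assocs$p <= 0 | assocs$p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  threshold <- alpha / m
  entries <- assocs
  entries$significant <- entries$p <= threshold
  structure(list(m = m, threshold = threshold, entries = entries,
                 pass = !any(entries$significant)),
            class = "confounder_screen")
}

#' @export
print.confounder_screen <- function(x, ...) {
  cat(sprintf("Confounder screen: %d instruments, threshold p <= %.4g\n",
              x$m, x$threshold))
  cat(if (x$pass) "PASS: no instrument-confounder association\n"
      else "FAIL: significant associations flagged below\n")
  flagged <- x$entries[x$entries$significant, , drop = FALSE]
  if (nrow(flagged)) print(flagged, row.names = FALSE)
  invisible(x)
}

#' Pairwise linkage-disequilibrium independence check
#'
#' IVW pooling assumes independent instruments; correlated instruments
#' double-count evidence. Given user-supplied pairwise r-squared values
#' (from a reference panel), the set is declared independent when every pair
#' satisfies `r2 <= max_allowed`.
#'
#' @param pairs Data frame with columns `rsid_a`, `rsid_b`, `r2`. An empty
#'   data frame (a single SNP) is vacuously independent.
#' @param max_allowed Largest admissible pairwise r-squared (default 0.01).
#' @return Object of class `ld_report`: list with `pairs`, `max_allowed`,
#'   `independent`, and `offending` (the failing pairs).
#' @export
ld_independence <- function(pairs, max_allowed = 0.01) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) && !all(c("rsid_a", "rsid_b", "r2") %in% names(pairs))) {
    stop("`pairs` needs columns rsid_a, rsid_b, r2", call. = FALSE)
  }
  if (nrow(pairs) && any(!is.finite(pairs$r2) | pairs$r2 < 0 |
                         pairs$r2 > 1)) {
    stop("r2 values must lie in [0, 1]", call. = FALSE)
  }
  offending <- if (nrow(pairs)) pairs[pairs$r2 > max_allowed, , drop = FALSE]
    else pairs
  structure(list(pairs = pairs, max_allowed = max_allowed,
                 independent = nrow(offending) == 0,
                 offending = offending),
            class = "ld_report")
}

#' @export
print.ld_report <- function(x, ...) {
  cat(sprintf("LD independence (max pairwise r2 allowed: %g): %s\n",
              x$max_allowed,
              if (x$independent) "independent" else "NOT independent"))
  if (nrow(x$offending)) print(x$offending, row.names = FALSE)
  invisible(x)
}

# Locus -> vitamin D pathway. DHCR7 (7-dehydrocholesterol reductase) and
# CYP2R1 (hepatic 25-hydroxylase) act in 25OHD synthesis; GC (the binding
# protein) and CYP24A1 (the catabolic hydroxylase) in its metabolism.
.pathway_map <- c(DHCR7 = "synthesis", CYP2R1 = "synthesis",
                  GC = "metabolism", CYP24A1 = "metabolism")

#' Classify a vitamin D locus into the synthesis or metabolism pathway
#'
#' @param locus Character vector of gene labels; each must be one of
#'   `GC`, `DHCR7`, `CYP2R1`, `CYP24A1`.
#' @return Character vector with values `"synthesis"` or `"metabolism"`.
#' @export
classify_pathway <- function(locus) {
  out <- .pathway_map[as.character(locus)]
  if (anyNA(out)) {
    stop("unknown locus: ",
         paste(unique(locus[is.na(out)]), collapse = ", "),
         "; expected one of ", paste(names(.pathway_map), collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}
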