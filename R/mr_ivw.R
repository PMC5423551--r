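#' Wald ratio estimate of a causal effect for a single instrument
#'
#' The ratio of the SNP-outcome effect to the SNP-exposure effect estimates
#' the causal effect of the exposure on the outcome per unit of exposure,
#' under the instrumental-variable assumptions. The default first-order
#' delta-method SE treats the exposure effect as fixed (`se_y / |beta_x|`),
#' the usual choice in two-sample MR where the exposure GWAS is much better
#' powered; the second-order SE additionally propagates `se_x`:
#' `sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)`.
#'
#' @param beta_y,se_y SNP-outcome effect and its positive SE.
#' @param beta_x SNP-exposure effect; must be nonzero.
#' @param se_x SNP-exposure SE, required for `method = "second_order"`.
#' @param method `"first_order"` (default) or `"second_order"`.
#' @return Data frame with columns `estimate`, `se`, `method`, one row per
#'   instrument.
#' @examples
#' wald_ratio(log(0.99), 0.010309, -0.052)
#' @export
wald_ratio <- function(beta_y, se_y, beta_x, se_x = NULL,
                       method = c("first_order", "second_order")) {
  method <- match.arg(method)
  if (any(!is.finite(beta_y)) || any(!is.finite(beta_x))) {
    stop("effects must be finite", call. = FALSE)
  }
  if (any(!is.finite(se_y) | se_y <= 0)) {
    stop("`se_y` must be positive", call. = FALSE)
  }
  if (any(beta_x == 0)) {
    stop("weak instrument: `beta_x` must be nonzero", call. = FALSE)
  }
  estimate <- beta_y / beta_x
  if (method == "first_order") {
    se <- se_y / abs(beta_x)
  } else {
    if (is.null(se_x) || any(is.na(se_x))) {
      stop("second-order SE requires `se_x` for every instrument",
           call. = FALSE)
    }
    se <- sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  }
  data.frame(estimate = estimate, se = se, method = method,
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted fixed-effects pooling
#'
#' Combines per-instrument estimates with weights equal to their inverse
#' squared standard errors: the pooled estimate is `sum(w * e) / sum(w)` with
#' `w = 1 / se^2`, and its SE is `1 / sqrt(sum(w))`. Equivalent to the slope
#' of a weighted least-squares regression through the origin of the outcome
#' effects on the exposure effects.
#'
#' @param estimate Numeric vector of estimates, or a data frame with columns
#'   `estimate` and `se` (as returned by [wald_ratio()]).
#' @param se Positive standard errors (ignored when `estimate` is a data
#'   frame).
#' @return List with elements `estimate`, `se`, `k`, `weights`.
#' @export
ivw_pool <- function(estimate, se = NULL) {
  if (is.data.frame(estimate)) {
    se <- estimate$se
    estimate <- estimate$estimate
  }
  if (length(estimate) < 1) {
    stop("at least one estimate is required", call. = FALSE)
  }
  if (any(!is.finite(estimate))) {
    stop("estimates must be finite", call. = FALSE)
  }
  if (length(se) != length(estimate) || any(!is.finite(se) | se <= 0)) {
    stop("standard errors must be positive and match the estimates",
         call. = FALSE)
  }
  w <- 1 / se^2
  list(estimate = sum(w * estimate) / sum(w),
       se = 1 / sqrt(sum(w)),
       k = length(estimate),
       weights = w / sum(w))
}

#' Cochran's Q and the I-squared heterogeneity statistic
#'
#' `Q = sum(w * (e - pooled)^2)` with IVW weights, and
#' `I2 = max(0, (Q - (k - 1)) / Q)`, the fraction of variability across
#' instruments beyond what chance alone explains. The confidence interval for
#' I-squared is obtained by the Q-profile method: the generalized Q statistic
#' is profiled over the between-instrument variance tau-squared against
#' chi-squared quantiles, and the tau-squared bounds are mapped to the
#' I-squared scale using the typical within-instrument variance. With few
#' instruments this interval is wide, which is the honest statement.
#'
#' @param estimate,se Per-instrument estimates and positive SEs (or a data
#'   frame with those columns as first argument); at least two instruments.
#' @param level Confidence level for the I-squared interval.
#' @return List with `q`, `df`, `p` (chi-squared tail), `i2` and `i2_ci`
#'   (length-2 vector, truncated to [0, 1)).
#' @export
heterogeneity <- function(estimate, se = NULL, level = 0.95) {
  if (is.data.frame(estimate)) {
    se <- estimate$se
    estimate <- estimate$estimate
  }
  k <- length(estimate)
  if (k < 2) {
    stop("heterogeneity is undefined for fewer than two instruments",
         call. = FALSE)
  }
  if (any(!is.finite(se) | se <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  w <- 1 / se^2
  pooled <- sum(w * estimate) / sum(w)
  q <- sum(w * (estimate - pooled)^2)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) else 0

  # Q-profile: generalized Q is decreasing in tau2; invert against the
  # chi-squared(k - 1) quantiles, then translate tau2 to the I2 scale via the
  # typical within-instrument variance s2 (Higgins-Thompson).
  gen_q <- function(tau2) {
    wt <- 1 / (se^2 + tau2)
    mu <- sum(wt * estimate) / sum(wt)
    sum(wt * (estimate - mu)^2)
  }
  s2 <- (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))
  alpha <- 1 - level
  tau2_bound <- function(target) {
    if (gen_q(0) <= target) return(0)
    upper <- s2
    while (gen_q(upper) > target) upper <- upper * 4
    stats::uniroot(function(t) gen_q(t) - target, c(0, upper),
                   tol = 1e-12)$root
  }
  t_lo <- tau2_bound(stats::qchisq(1 - alpha / 2, k - 1))
  t_hi <- tau2_bound(stats::qchisq(alpha / 2, k - 1))
  i2_ci <- c(t_lo / (t_lo + s2), t_hi / (t_hi + s2))
  i2_ci <- pmin(pmax(i2_ci, 0), 1 - 1e-12)

  list(q = q, df = k - 1, p = stats::pchisq(q, k - 1, lower.tail = FALSE),
       i2 = i2, i2_ci = i2_ci)
}

#' Two-sided p-value from a normal Wald test
#'
#' @param estimate,se Estimate and its positive SE.
#' @return `2 * pnorm(-abs(estimate / se))`.
#' @export
two_sided_p <- function(estimate, se) {
  if (any(!is.finite(se) | se <= 0)) {
    stop("`se` must be positive", call. = FALSE)
  }
  2 * stats::pnorm(-abs(estimate / se))
}

#' Rescale a pooled per-unit estimate to "per SD decrease" of the exposure
#'
#' The pooled IVW estimate is per unit of the exposure; multiplying by
#' `-sigma` (the SD of the exposure) re-expresses it per one-SD *decrease*,
#' the reporting convention for exposures where deficiency is the
#' hypothesized risk state. For binary outcomes the estimate and CI are also
#' exponentiated to odds ratios.
#'
#' @param pooled List with `estimate` and `se` (per exposure unit), as from
#'   [ivw_pool()].
#' @param sigma Positive SD of the exposure distribution.
#' @param or_scale Report odds ratios (`TRUE` for log-odds outcome effects).
#' @param level Confidence level.
#' @param direction `"decrease"` (default) or `"increase"`.
#' @return List with `estimate`, `se`, `ci_lower`, `ci_upper`, `p` on the
#'   additive per-SD scale, plus `or`, `or_ci` when `or_scale`, and the
#'   `sigma`, `level`, `direction` used.
#' @export
per_sd_decrease <- function(pooled, sigma = 0.47, or_scale = TRUE,
                            level = 0.95, direction = c("decrease",
                                                        "increase")) {
  direction <- match.arg(direction)
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a single positive number", call. = FALSE)
  }
  sgn <- if (direction == "decrease") -1 else 1
  est <- sgn * sigma * pooled$estimate
  se <- sigma * pooled$se
  z <- stats::qnorm((1 + level) / 2)
  ci <- c(est - z * se, est + z * se)
  out <- list(estimate = est, se = se, ci_lower = ci[1], ci_upper = ci[2],
              p = two_sided_p(est, se), sigma = sigma, level = level,
              direction = direction, or_scale = or_scale)
  if (or_scale) {
    out$or <- exp(est)
    out$or_ci <- exp(ci)
  }
  out
}

#' Fixed-effects meta-analysis of one SNP's effect across studies
#'
#' Pools per-study (beta, se) estimates for a single variant with
#' inverse-variance weights, e.g. to merge an asthma association measured in
#' two non-overlapping GWAS before MR. Identical arithmetic to [ivw_pool()],
#' applied across studies rather than across instruments.
#'
#' @param beta,se Per-study effects and positive SEs.
#' @return List with `beta`, `se`, `p`, `k`.
#' @export
ivw_meta_studies <- function(beta, se) {
  pooled <- ivw_pool(beta, se)
  list(beta = pooled$estimate, se = pooled$se,
       p = two_sided_p(pooled$estimate, pooled$se), k = pooled$k)
}

# Named instrument subsets used in the sensitivity analyses. Each function
# takes a locus vector and returns a keep mask.
.mr_subsets <- list(
  all = function(locus) rep(TRUE, length(locus)),
  exclude_DHCR7 = function(locus) locus != "DHCR7",
  exclude_CYP2R1 = function(locus) locus != "CYP2R1",
  exclude_CYP2R1_CYP24A1 = function(locus) !locus %in% c("CYP2R1", "CYP24A1"),
  synthesis_only = function(locus) classify_pathway(locus) == "synthesis",
  metabolism_only = function(locus) classify_pathway(locus) == "metabolism"
)

#' Names of the built-in sensitivity subsets
#' @return Character vector of subset labels accepted by [mr_ivw()].
#' @export
mr_subsets <- function() names(.mr_subsets)

#' Fit a two-sample Mendelian randomization model
#'
#' The main fitting function. Harmonizes the exposure and outcome summary
#' tables to a common effect allele, forms one Wald ratio per instrument,
#' pools them by inverse-variance-weighted fixed effects, quantifies
#' heterogeneity (Cochran's Q, I-squared with a Q-profile CI), and rescales
#' the pooled estimate to the effect of a one-SD change in the exposure.
#'
#' @param exposure `study_table` of SNP-exposure effects (the instruments).
#' @param outcome `study_table` of SNP-outcome effects for the same SNPs.
#' @param sigma SD of the exposure distribution, used to rescale the pooled
#'   per-unit estimate. Default 0.47, the SD of natural-log 25OHD underlying
#'   the packaged vitamin D analysis.
#' @param subset One of [mr_subsets()], or a character vector of rsids to
#'   keep. Locus-based subsets require locus annotation (see `instruments`).
#' @param instruments Optional data frame mapping `rsid` to `locus`; defaults
#'   to the packaged vitamin D instrument metadata when the rsids match.
#' @param wald_method SE method for [wald_ratio()].
#' @param level Confidence level for intervals.
#' @param direction Report per SD `"decrease"` (default) or `"increase"` of
#'   the exposure.
#' @return Object of class `mr_ivw`: a list with the per-instrument ratio
#'   table (`ratios`), pooled per-unit estimate (`estimate_per_unit`,
#'   `se_per_unit`), the per-SD summary (`estimate`, `se`, `ci_lower`,
#'   `ci_upper`, `p`, and `or`/`or_ci` for binary outcomes), heterogeneity
#'   (`q`, `i2`, `i2_ci`), and metadata (`outcome`, `subset`, `sigma`, `k`,
#'   ...). Methods: `print`, `summary`, `coef`, `confint`, `weights`,
#'   `plot`.
#' @examples
#' tabs <- vitd_study_tables()
#' fit <- mr_ivw(tabs$exposure, tabs$asthma)
#' fit
#' coef(fit)
#' confint(fit)
#' @export
mr_ivw <- function(exposure, outcome, sigma = 0.47,
                   subset = "all", instruments = NULL,
                   wald_method = c("first_order", "second_order"),
                   level = 0.95,
                   direction = c("decrease", "increase")) {
  wald_method <- match.arg(wald_method)
  direction <- match.arg(direction)
  cl <- match.call()
  if (nrow(exposure) == 0) {
    stop("exposure table contains no instruments", call. = FALSE)
  }
  harm <- harmonize_tables(exposure, outcome)

  if (is.null(instruments)) instruments <- vitd_instruments()
  locus <- instruments$locus[match(harm$rsid, instruments$rsid)]

  subset_label <- if (length(subset) == 1 && subset %in% names(.mr_subsets))
    subset else "custom"
  keep <- if (subset_label != "custom") {
    if (subset != "all" && anyNA(locus)) {
      stop("locus annotation required for subset '", subset, "' but missing",
           " for: ", paste(harm$rsid[is.na(locus)], collapse = ", "),
           call. = FALSE)
    }
    .mr_subsets[[subset]](locus)
  } else {
    harm$rsid %in% subset
  }
  if (!any(keep)) {
    stop("subset '", subset_label, "' leaves no instruments", call. = FALSE)
  }
  harm <- harm[keep, , drop = FALSE]
  locus <- locus[keep]

  wr <- wald_ratio(harm$beta_y, harm$se_y, harm$beta_x,
                   se_x = harm$se_x, method = wald_method)
  pooled <- ivw_pool(wr)
  het <- if (pooled$k >= 2) heterogeneity(wr, level = level) else
    list(q = NA_real_, df = NA_integer_, p = NA_real_, i2 = NA_real_,
         i2_ci = c(NA_real_, NA_real_))
  or_scale <- identical(attr(outcome, "scale"), "log_odds")
  sd_est <- per_sd_decrease(pooled, sigma = sigma, or_scale = or_scale,
                            level = level, direction = direction)

  ratios <- data.frame(rsid = harm$rsid, locus = locus,
                       beta_x = harm$beta_x, beta_y = harm$beta_y,
                       se_y = harm$se_y,
                       estimate = wr$estimate, se = wr$se,
                       weight = pooled$weights,
                       stringsAsFactors = FALSE)

  structure(list(
    outcome = attr(outcome, "trait"), study_id = attr(outcome, "study_id"),
    subset = subset_label,
    subset_rsids = harm$rsid,
    ratios = ratios,
    estimate_per_unit = pooled$estimate, se_per_unit = pooled$se,
    estimate = sd_est$estimate, se = sd_est$se,
    ci_lower = sd_est$ci_lower, ci_upper = sd_est$ci_upper,
    p = sd_est$p, or = sd_est$or, or_ci = sd_est$or_ci,
    or_scale = or_scale,
    q = het$q, q_p = het$p, i2 = het$i2, i2_ci = het$i2_ci,
    k = pooled$k, sigma = sigma, level = level,
    wald_method = wald_method, direction = direction,
    call = cl), class = "mr_ivw")
}

#' Sensitivity-subset MR analysis
#'
#' Convenience wrapper around [mr_ivw()] that refits the model on a named
#' instrument subset (see [mr_subsets()]), as done when instruments are
#' excluded for suspected pleiotropy or population stratification, or when
#' biological pathways are analyzed separately.
#'
#' @inheritParams mr_ivw
#' @param subset Subset label or rsid vector.
#' @return An `mr_ivw` fit on the restricted instrument set.
#' @export
subset_analysis <- function(exposure, outcome, subset, ...) {
  mr_ivw(exposure, outcome, subset = subset, ...)
}

.fmt_est <- function(x, digits = 2) {
  if (x$or_scale) {
    sprintf("OR %.*f (%.*f-%.*f)", digits, x$or, digits, x$or_ci[1],
            digits, x$or_ci[2])
  } else {
    sprintf("beta %.*f (%.*f to %.*f)", digits, x$estimate, digits,
            x$ci_lower, digits, x$ci_upper)
  }
}

#' @export
print.mr_ivw <- function(x, digits = 2, ...) {
  cat("Two-sample MR, IVW fixed effects\n")
  cat(sprintf("Outcome: %s   instruments: %d (%s)\n",
              x$outcome, x$k, x$subset))
  cat(sprintf("Per SD %s of exposure: %s, p = %.2f\n",
              x$direction, .fmt_est(x, digits), x$p))
  if (x$k >= 2) {
    cat(sprintf("Heterogeneity: Q = %.2f (df %d), I2 = %.0f%% (%.0f%%-%.0f%%)\n",
                x$q, x$k - 1, 100 * x$i2, 100 * x$i2_ci[1],
                100 * x$i2_ci[2]))
  }
  invisible(x)
}

#' @export
summary.mr_ivw <- function(object, ...) {
  structure(object, class = c("summary.mr_ivw", "mr_ivw"))
}

#' @export
print.summary.mr_ivw <- function(x, digits = 2, ...) {
  print.mr_ivw(x, digits = digits, ...)
  cat(sprintf("sigma = %g, %s Wald SEs, %g%% CIs\n", x$sigma,
              gsub("_", "-", x$wald_method), 100 * x$level))
  cat("\nPer-instrument Wald ratios (per exposure unit):\n")
  tab <- x$ratios
  tab$weight <- sprintf("%.1f%%", 100 * tab$weight)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.mr_ivw <- function(object, ...) {
  stats::setNames(object$estimate,
                  sprintf("per_sd_%s", object$direction))
}

#' @export
confint.mr_ivw <- function(object, parm, level = NULL, ...) {
  if (!is.null(level) && !isTRUE(all.equal(level, object$level))) {
    z <- stats::qnorm((1 + level) / 2)
    ci <- object$estimate + c(-1, 1) * z * object$se
  } else {
    ci <- c(object$ci_lower, object$ci_upper)
    level <- object$level
  }
  m <- matrix(ci, nrow = 1,
              dimnames = list(sprintf("per_sd_%s", object$direction),
                              sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                         (1 + level) / 2))))
  m
}

#' @export
weights.mr_ivw <- function(object, ...) {
  stats::setNames(object$ratios$weight, object$ratios$rsid)
}
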