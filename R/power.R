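#' Analytic power for a two-sample MR Wald test
#'
#' Normal-approximation power for the two-sided test of no causal effect.
#' The IVW estimator behaves asymptotically like a regression of the outcome
#' on the genetically predicted exposure, giving non-centrality parameter
#' `NCP = n * r2 * effect^2`, where `r2` is the fraction of exposure variance
#' explained by the instrument set and `effect` is the causal effect per SD
#' of the exposure (log-OR for binary outcomes, outcome units for continuous
#' ones). Power is
#' `pnorm(sqrt(NCP) - z) + pnorm(-sqrt(NCP) - z)` with `z` the two-sided
#' critical value, hence symmetric in the sign of `effect` and equal to
#' `alpha` at `effect = 0`.
#'
#' For binary outcomes the `"case_control_scaled"` variant multiplies the
#' NCP by `case_fraction * (1 - case_fraction)`, the binomial information
#' factor appropriate when `effect` is a log-odds ratio and the outcome
#' regression is logistic. The `"plain"` variant (default) omits it.
#'
#' @param n Outcome-study sample size.
#' @param r2 Exposure variance explained by the instruments, in (0, 1).
#' @param effect Causal effect per SD of exposure (log-OR if binary).
#' @param alpha Two-sided type-I error rate.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param case_fraction Case proportion, required for the
#'   `"case_control_scaled"` variant of a binary outcome.
#' @param variant `"plain"` (default) or `"case_control_scaled"`.
#' @return Power, a probability.
#' @examples
#' mr_power(12853, 0.0036, 0.43, outcome_type = "continuous")
#' @export
mr_power <- function(n, r2, effect, alpha = 0.05,
                     outcome_type = c("binary", "continuous"),
                     case_fraction = NULL,
                     variant = c("plain", "case_control_scaled")) {
  outcome_type <- match.arg(outcome_type)
  variant <- match.arg(variant)
  if (any(n < 1)) stop("`n` must be positive", call. = FALSE)
  if (any(r2 <= 0 | r2 >= 1)) stop("`r2` must lie in (0, 1)", call. = FALSE)
  if (any(alpha <= 0 | alpha >= 1)) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  ncp <- n * r2 * effect^2
  if (variant == "case_control_scaled") {
    if (outcome_type != "binary") {
      stop("case-control scaling applies to binary outcomes only",
           call. = FALSE)
    }
    if (is.null(case_fraction) ||
        any(case_fraction <= 0 | case_fraction >= 1)) {
      stop("`case_fraction` in (0, 1) is required for the ",
           "case_control_scaled variant", call. = FALSE)
    }
    ncp <- ncp * case_fraction * (1 - case_fraction)
  }
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(sqrt(ncp) - z) + stats::pnorm(-sqrt(ncp) - z)
}

#' Minimal detectable effect at a target power
#'
#' Inverts [mr_power()] in `|effect|` by bisection: the smallest effect per
#' SD of exposure that the design detects with probability `target_power`.
#' Power is strictly increasing in `|effect|`, so the root is unique.
#'
#' @inheritParams mr_power
#' @param target_power Desired power, in `(alpha, 1)`.
#' @param tol Bisection tolerance on the effect scale.
#' @return Named numeric vector: `effect`, plus `or = exp(effect)` for
#'   binary outcomes.
#' @examples
#' minimal_detectable_effect(144243, 0.0036, target_power = 0.8)
#' @export
minimal_detectable_effect <- function(n, r2, alpha = 0.05,
                                      target_power = 0.8,
                                      outcome_type = c("binary",
                                                       "continuous"),
                                      case_fraction = NULL,
                                      variant = c("plain",
                                                  "case_control_scaled"),
                                      tol = 1e-10) {
  outcome_type <- match.arg(outcome_type)
  variant <- match.arg(variant)
  if (target_power <= alpha || target_power >= 1) {
    stop("`target_power` must lie in (alpha, 1)", call. = FALSE)
  }
  pw <- function(b) mr_power(n, r2, b, alpha, outcome_type, case_fraction,
                             variant)
  upper <- 1
  while (pw(upper) < target_power) {
    upper <- upper * 2
    if (upper > 1e6) stop("target power unattainable", call. = FALSE)
  }
  effect <- stats::uniroot(function(b) pw(b) - target_power,
                           c(0, upper), tol = tol)$root
  if (outcome_type == "binary") c(effect = effect, or = exp(effect))
  else c(effect = effect)
}

#' Power summary for the four packaged study designs
#'
#' Evaluates [mr_power()] at each outcome study's published sample size
#' against its clinically motivated reference effect, and the 80%-power
#' minimal detectable effect, using the summed instrument variance explained
#' (0.36% by default, the sum of the packaged per-SNP values).
#'
#' @param r2 Instrument-set variance explained.
#' @param alpha Two-sided type-I error rate.
#' @param target_power Power level for the minimal detectable effect.
#' @return Data frame with one row per outcome design.
#' @export
study_power_table <- function(r2 = 0.0036, alpha = 0.05,
                              target_power = 0.8) {
  designs <- data.frame(
    outcome = c("asthma", "childhood asthma", "atopic dermatitis",
                "ln IgE"),
    n = c(144243, 15008, 40835, 12853),
    outcome_type = c("binary", "binary", "binary", "continuous"),
    reference_effect = c(log(1.6), log(1.6), log(1.5), 0.43),
    stringsAsFactors = FALSE
  )
  designs$power_at_reference <- mapply(function(n, type, eff)
    mr_power(n, r2, eff, alpha, outcome_type = type),
    designs$n, designs$outcome_type, designs$reference_effect)
  designs$mde <- mapply(function(n, type)
    minimal_detectable_effect(n, r2, alpha, target_power,
                              outcome_type = type)[["effect"]],
    designs$n, designs$outcome_type)
  designs$mde_or <- ifelse(designs$outcome_type == "binary",
                           exp(designs$mde), NA_real_)
  designs
}
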