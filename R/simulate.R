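#' Configuration for the genotype-exposure-outcome simulator
#'
#' Describes the assumed causal structure: independent biallelic variants
#' affect a continuous exposure; a latent confounder may affect both
#' exposure and outcome; the (standardized) exposure affects the outcome
#' with causal effect `theta`; optional direct variant-outcome (pleiotropic)
#' effects bypass the exposure. Defaults mirror the packaged vitamin D
#' setting: four variants with the published allele frequencies and
#' per-allele effects on natural-log 25OHD, residual exposure SD 0.47, and a
#' binary outcome with 17% prevalence (the asthma case fraction).
#'
#' @param n Number of individuals.
#' @param eaf Effect-allele frequencies, one per variant, each in (0, 1).
#' @param beta_x Per-allele effects on the exposure (exposure units).
#' @param sigma_resid Residual SD of the exposure.
#' @param theta Causal effect of the exposure, per SD of exposure (log-OR
#'   for binary outcomes, outcome units for continuous ones).
#' @param gamma Confounder effect on the exposure.
#' @param delta Confounder effect on the outcome (log-OR / outcome units).
#' @param pleiotropy Direct variant effects on the outcome, one per variant.
#' @param prevalence Population outcome prevalence (binary outcomes).
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param rsid Variant labels.
#' @param seed Optional integer seed stored with the configuration.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n = 10000,
                       eaf = c(0.62, 0.27, 0.30, 0.19),
                       beta_x = c(-0.052, -0.056, -0.047, -0.027),
                       sigma_resid = 0.47,
                       theta = 0, gamma = 0, delta = 0,
                       pleiotropy = rep(0, length(eaf)),
                       prevalence = 0.17,
                       outcome_type = c("binary", "continuous"),
                       rsid = c("rs10741657", "rs12785878", "rs2282679",
                                "rs6013897")[seq_along(eaf)],
                       seed = NULL) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(n >= 10, length(beta_x) == length(eaf),
            length(pleiotropy) == length(eaf),
            length(rsid) == length(eaf))
  if (any(eaf <= 0 | eaf >= 1)) stop("`eaf` must lie in (0, 1)",
                                     call. = FALSE)
  if (sigma_resid <= 0) stop("`sigma_resid` must be positive",
                             call. = FALSE)
  if (outcome_type == "binary" && (prevalence <= 0 || prevalence >= 1)) {
    stop("`prevalence` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(n = as.integer(n), eaf = eaf, beta_x = beta_x,
                 sigma_resid = sigma_resid, theta = theta, gamma = gamma,
                 delta = delta, pleiotropy = pleiotropy,
                 prevalence = prevalence, outcome_type = outcome_type,
                 rsid = rsid, seed = seed),
            class = "sim_config")
}

#' Simulate an individual-level cohort
#'
#' Genotypes are drawn independently per variant as Binomial(2, eaf); the
#' confounder is standard normal; the exposure is the genetic score plus
#' `gamma` times the confounder plus Normal(0, sigma_resid) noise. The
#' exposure is standardized within the simulated cohort so that `theta` is
#' interpretable per SD of exposure. For binary outcomes the logistic
#' intercept is solved by bisection so that the cohort-averaged event
#' probability equals `prevalence` to within 1e-8; for continuous outcomes
#' unit-variance Gaussian noise is added.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to the seed stored in `config`.
#'   Cohorts are bit-reproducible given the seed.
#' @return Object of class `sim_cohort`: list with `genotypes` (n x m
#'   matrix), `confounder`, `exposure`, `exposure_std`, `outcome`,
#'   `intercept`, and the `config`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  m <- length(config$eaf)
  g <- vapply(config$eaf, function(q) stats::rbinom(n, 2L, q),
              integer(n))
  colnames(g) <- config$rsid
  confounder <- stats::rnorm(n)
  exposure <- drop(g %*% config$beta_x) + config$gamma * confounder +
    stats::rnorm(n, sd = config$sigma_resid)
  z <- (exposure - mean(exposure)) / stats::sd(exposure)
  lp <- config$theta * z + config$delta * confounder +
    drop(g %*% config$pleiotropy)

  if (config$outcome_type == "binary") {
    # cohort-averaged logistic mean is monotone in the intercept
    target <- config$prevalence
    f <- function(a) mean(stats::plogis(a + lp)) - target
    lo <- stats::qlogis(target) - max(lp) - 1
    hi <- stats::qlogis(target) - min(lp) + 1
    if (f(lo) > 0 || f(hi) < 0) {
      stop("prevalence intercept could not be bracketed", call. = FALSE)
    }
    intercept <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    if (abs(f(intercept)) > 1e-8) {
      stop("prevalence intercept solve did not converge", call. = FALSE)
    }
    outcome <- stats::rbinom(n, 1L, stats::plogis(intercept + lp))
  } else {
    intercept <- 0
    outcome <- lp + stats::rnorm(n)
  }
  structure(list(genotypes = g, confounder = confounder,
                 exposure = exposure, exposure_std = z, outcome = outcome,
                 intercept = intercept, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: n = %d, %d variants, %s outcome\n",
              x$config$n, ncol(x$genotypes), x$config$outcome_type))
  if (x$config$outcome_type == "binary") {
    cat(sprintf("case fraction %.4f (target %.4f)\n", mean(x$outcome),
                x$config$prevalence))
  }
  invisible(x)
}

# per-SNP simple linear regression: slope, SE, two-sided t p-value
.slr <- function(y, g) {
  n <- length(y)
  gc <- g - mean(g)
  sxx <- sum(gc^2)
  if (sxx == 0) return(c(beta = NA_real_, se = NA_real_, p = NA_real_))
  beta <- sum(gc * y) / sxx
  res <- y - mean(y) - beta * gc
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  c(beta = beta, se = se,
    p = 2 * stats::pt(-abs(beta / se), n - 2))
}

# per-SNP univariable logistic regression via glm.fit
.logit <- function(y, g) {
  if (stats::var(g) == 0) return(c(beta = NA_real_, se = NA_real_,
                                   p = NA_real_))
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, g), y, family = stats::binomial()))
  cov <- chol2inv(qr.R(structure(fit$qr, class = "qr")))
  beta <- fit$coefficients[2]
  se <- sqrt(cov[2, 2])
  c(beta = unname(beta), se = se, p = two_sided_p(beta, se))
}

#' Derive two-sample GWAS summary statistics from a simulated cohort
#'
#' Emulates the two-sample design: SNP-exposure associations are estimated
#' by per-variant linear regression in one subsample, SNP-outcome
#' associations by per-variant logistic (binary) or linear (continuous)
#' regression in a disjoint subsample. Monomorphic variants within a
#' subsample are dropped with a warning.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param split_a,split_b Disjoint row index vectors for the exposure and
#'   outcome subsamples; default first and second halves.
#' @return List with `study_table` objects `exposure` and `outcome`, plus
#'   `sd_exposure` (the exposure SD in the exposure subsample, the natural
#'   `sigma` for per-SD rescaling).
#' @export
summarize_gwas <- function(cohort,
                           split_a = seq_len(floor(cohort$config$n / 2)),
                           split_b = seq.int(floor(cohort$config$n / 2) + 1,
                                             cohort$config$n)) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (length(split_a) == 0 || length(split_b) == 0) {
    stop("both subsamples must be non-empty", call. = FALSE)
  }
  if (length(intersect(split_a, split_b))) {
    stop("two-sample design requires disjoint subsamples", call. = FALSE)
  }
  m <- ncol(cohort$genotypes)
  rsid <- colnames(cohort$genotypes)

  assoc <- function(idx, y, fun) {
    res <- t(vapply(seq_len(m),
                    function(j) fun(y[idx], cohort$genotypes[idx, j]),
                    numeric(3)))
    keep <- !is.na(res[, 1])
    if (any(!keep)) {
      warning("dropping monomorphic variant(s): ",
              paste(rsid[!keep], collapse = ", "), call. = FALSE)
    }
    eaf <- colMeans(cohort$genotypes[idx, keep, drop = FALSE]) / 2
    data.frame(rsid = rsid[keep], effect_allele = "A", other_allele = "G",
               eaf = pmin(pmax(eaf, 1e-12), 1 - 1e-12),
               beta = res[keep, 1], se = res[keep, 2], p = res[keep, 3],
               n = length(idx), stringsAsFactors = FALSE)
  }

  exp_tab <- .new_study_table(assoc(split_a, cohort$exposure, .slr),
                              "sim/A", "exposure", "linear")
  binary <- cohort$config$outcome_type == "binary"
  out_tab <- .new_study_table(
    assoc(split_b, cohort$outcome, if (binary) .logit else .slr),
    "sim/B", "outcome", if (binary) "log_odds" else "linear")
  list(exposure = exp_tab, outcome = out_tab,
       sd_exposure = stats::sd(cohort$exposure[split_a]))
}

#' Naive observational estimate of the exposure-outcome association
#'
#' Regresses the outcome on the standardized exposure in the full cohort
#' without adjusting for the confounder — the estimate an observational
#' study reports. Under confounding (`gamma * delta != 0`) it is biased
#' in the direction of `sign(gamma * delta)` even when the causal effect is
#' null, which is the contrast MR is designed to escape.
#'
#' @param cohort A [simulate_cohort()] result.
#' @return List with `beta`, `se`, `p` (per SD of exposure).
#' @export
observational_estimate <- function(cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (cohort$config$outcome_type == "binary") {
    r <- .logit(cohort$outcome, cohort$exposure_std)
  } else {
    r <- .slr(cohort$outcome, cohort$exposure_std)
  }
  list(beta = unname(r["beta"]), se = unname(r["se"]), p = unname(r["p"]))
}

# one simulated two-sample MR replicate: per-SD-increase estimate + CI + p
.mr_replicate <- function(config, seed, level = 0.95) {
  cohort <- simulate_cohort(config, seed = seed)
  gw <- summarize_gwas(cohort)
  harm <- harmonize_tables(gw$exposure, gw$outcome)
  wr <- wald_ratio(harm$beta_y, harm$se_y, harm$beta_x)
  pooled <- ivw_pool(wr)
  per_sd_decrease(pooled, sigma = gw$sd_exposure, or_scale = FALSE,
                  level = level, direction = "increase")
}

#' Replicated simulation experiments over a grid of configurations
#'
#' Runs the full pipeline (simulate, split, summarize, MR) `replicates`
#' times per configuration and aggregates rejection rate, mean and SD of
#' the per-SD estimate, and CI coverage of the true `theta`. Per-replicate
#' seeds are drawn once from the master seed (`sample.int` after
#' `set.seed(seed)`), so the whole table is reproducible from `seed` and
#' results do not depend on evaluation order.
#'
#' @param configs A [sim_config()] or list of them (the grid).
#' @param replicates Replicates per configuration, at least 1.
#' @param seed Master integer seed.
#' @param alpha Nominal test size for the rejection rate.
#' @param level CI level for the coverage column.
#' @return Data frame of class `mr_experiment`: one row per configuration
#'   with columns `cell`, `theta`, `n`, `replicates`, `reject_rate`,
#'   `mean_est`, `sd_est`, `coverage`.
#' @export
run_experiment <- function(configs, replicates, seed = 1, alpha = 0.05,
                           level = 0.95) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  stopifnot(length(configs) >= 1, replicates >= 1)
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1,
                             length(configs) * replicates),
                  nrow = replicates)
  cells <- lapply(seq_along(configs), function(i) {
    config <- configs[[i]]
    est <- p <- lo <- hi <- numeric(replicates)
    for (r in seq_len(replicates)) {
      fit <- .mr_replicate(config, seed = seeds[r, i], level = level)
      est[r] <- fit$estimate; p[r] <- fit$p
      lo[r] <- fit$ci_lower; hi[r] <- fit$ci_upper
    }
    data.frame(cell = if (!is.null(names(configs)[i]) &&
                          nzchar(names(configs)[i])) names(configs)[i]
               else sprintf("cell%d", i),
               theta = config$theta, n = config$n,
               replicates = replicates,
               reject_rate = mean(p < alpha),
               mean_est = mean(est), sd_est = stats::sd(est),
               coverage = mean(lo <= config$theta & config$theta <= hi),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, cells),
            class = c("mr_experiment", "data.frame"), seed = seed)
}
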