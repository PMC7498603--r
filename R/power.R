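#' Analytic MR power
#'
#' Power of the two-sample MR Wald test via the non-centrality parameter
#' (NCP) of a 1-df chi-square, following the summary-statistic approach of
#' the standard web power calculator for MR designs: the causal effect and
#' the variance explained by the instruments determine the NCP, and power is
#' the upper-tail probability of the noncentral chi-square beyond the
#' central `1 - alpha` quantile. For a binary outcome the odds ratio is
#' consumed per unit of the exposure as measured, with the instrument R2 on
#' the same scale.
#'
#' @name power
NULL

#' Specify an MR power calculation
#'
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param n Outcome-sample size.
#' @param r2_xz Proportion of exposure variance explained by the instruments
#'   (in (0, 1)).
#' @param effect True causal effect: an odds ratio per unit exposure for a
#'   binary outcome, or a regression coefficient (outcome units per exposure
#'   unit) for a continuous outcome. May be `NA` when the spec is used for
#'   [minimum_detectable_effect()].
#' @param alpha Two-sided type-1 error rate (default 0.05).
#' @param case_fraction Case fraction K in (0, 1); binary outcome only.
#' @param var_x,var_y Exposure and outcome variances; continuous outcome
#'   only.
#' @param observational_effect Optional observed exposure-outcome
#'   coefficient used to seed power curves; informative only.
#' @return List of class `"power_spec"`.
#' @export
power_spec <- function(outcome_type = c("binary", "continuous"), n, r2_xz,
                       effect = NA_real_, alpha = 0.05, case_fraction = NULL,
                       var_x = NULL, var_y = NULL,
                       observational_effect = NULL) {
  outcome_type <- match.arg(outcome_type)
  if (!(r2_xz > 0 && r2_xz < 1)) stop("r2_xz must lie in (0,1)")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0,1)")
  if (n < 1) stop("n must be at least 1")
  if (outcome_type == "binary") {
    if (is.null(case_fraction) || !(case_fraction > 0 && case_fraction < 1))
      stop("binary outcome requires case_fraction in (0,1)")
  } else {
    if (is.null(var_x) || is.null(var_y) || var_x <= 0 || var_y <= 0)
      stop("continuous outcome requires positive var_x and var_y")
  }
  structure(list(outcome_type = outcome_type, n = n, r2_xz = r2_xz,
                 effect = effect, alpha = alpha,
                 case_fraction = case_fraction, var_x = var_x, var_y = var_y,
                 observational_effect = observational_effect),
            class = "power_spec")
}

ncp_binary <- function(spec, or = spec$effect) {
  if (any(or <= 0)) stop("odds ratio must be positive")
  k <- spec$case_fraction
  b <- k * (or / (1 + k * (or - 1)) - 1)   # approximate risk-difference slope
  v <- (k * (1 - k) - b^2) / (spec$n * spec$r2_xz)
  b^2 / v
}

ncp_continuous <- function(spec, beta = spec$effect) {
  if (spec$var_y <= 0) stop("var_y must be positive")
  spec$n * spec$r2_xz * beta^2 * spec$var_x / spec$var_y
}

power_from_ncp <- function(ncp, alpha) {
  crit <- stats::qchisq(1 - alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Analytic power for a binary outcome
#'
#' The odds ratio is converted to an approximate risk-difference slope
#' `b = K (OR / (1 + K (OR - 1)) - 1)`; the variance of the MR estimator is
#' `v = (K(1-K) - b^2) / (n R2)`; the NCP is `b^2 / v`, and power is the
#' noncentral chi-square (1 df) upper tail beyond the central `1 - alpha`
#' quantile. At the null (OR = 1) the power equals `alpha` exactly.
#'
#' @param spec A [power_spec()] with `outcome_type = "binary"`.
#' @return Power probability, with the NCP as attribute `"ncp"`.
#' @export
power_binary_outcome <- function(spec) {
  stopifnot(inherits(spec, "power_spec"), spec$outcome_type == "binary")
  ncp <- ncp_binary(spec)
  structure(power_from_ncp(ncp, spec$alpha), ncp = ncp)
}

#' Analytic power for a continuous outcome
#'
#' `NCP = n R2 beta^2 var_x / var_y`; power is the noncentral chi-square
#' (1 df) upper tail beyond the central `1 - alpha` quantile.
#'
#' @param spec A [power_spec()] with `outcome_type = "continuous"`.
#' @return Power probability, with the NCP as attribute `"ncp"`.
#' @export
power_continuous_outcome <- function(spec) {
  stopifnot(inherits(spec, "power_spec"), spec$outcome_type == "continuous")
  ncp <- ncp_continuous(spec)
  structure(power_from_ncp(ncp, spec$alpha), ncp = ncp)
}

#' Analytic MR power (dispatch on outcome type)
#'
#' @param spec A [power_spec()].
#' @return Power probability, with the NCP as attribute `"ncp"`.
#' @export
mr_power <- function(spec) {
  if (spec$outcome_type == "binary") power_binary_outcome(spec)
  else power_continuous_outcome(spec)
}

#' Minimum detectable effect at a target power
#'
#' Bisection on the monotone power function, on the OR > 1 branch for a
#' binary outcome and the beta > 0 branch for a continuous outcome, until
#' the achieved power is within 1e-6 of the target.
#'
#' @param spec A [power_spec()]; its `effect` field is ignored.
#' @param target_power Target power in (0, 1).
#' @return The effect size (odds ratio or regression coefficient) reaching
#'   `target_power`.
#' @export
minimum_detectable_effect <- function(spec, target_power) {
  if (!(target_power > 0 && target_power < 1))
    stop("target_power must lie in (0,1)")
  if (target_power <= spec$alpha)
    return(if (spec$outcome_type == "binary") 1 else 0)
  pw <- function(effect) {
    s <- spec; s$effect <- effect
    as.numeric(mr_power(s))
  }
  # effect parameterized additively: log(OR) for binary, beta for continuous
  to_effect <- if (spec$outcome_type == "binary") exp else identity
  lo <- 0; hi <- 1
  while (pw(to_effect(hi)) < target_power) {
    hi <- hi * 2
    if (hi > 1e6) stop("target power not bracketable")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    p <- pw(to_effect(mid))
    if (abs(p - target_power) <= 1e-6) break
    if (p < target_power) lo <- mid else hi <- mid
  }
  to_effect(mid)
}

#' Simulation oracle for MR power
#'
#' Estimates power by simulating the sampling distribution of the
#' two-sample MR test at the spec's sample size: an instrument score
#' explaining `r2_xz` of the exposure is drawn per subject, the outcome is
#' generated from the causal model (a logistic disease model with the
#' spec's odds ratio and marginal case fraction for a binary outcome; a
#' linear model with the spec's variances for a continuous outcome), and
#' the score-outcome association is tested at level `alpha`. The exposure
#' side is treated as precisely estimated, matching the NOME assumption of
#' the analytic formula. The rejection fraction over `n_reps` replicates
#' estimates power.
#'
#' @param spec A [power_spec()].
#' @param n_reps Number of replicates (default 5000).
#' @param seed Integer RNG seed.
#' @return Empirical power, with attribute `"mc_se"` (binomial Monte-Carlo
#'   standard error).
#' @export
simulate_power <- function(spec, n_reps = 5000, seed = 1) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  n <- spec$n
  zcrit <- stats::qnorm(1 - spec$alpha / 2)
  reject <- logical(n_reps)
  if (spec$outcome_type == "binary") {
    b <- log(spec$effect)
    # intercept giving the marginal case fraction over a standard-normal exposure
    quad <- stats::qnorm(seq(0.0005, 0.9995, length.out = 2000))
    a <- stats::uniroot(function(a0)
      mean(stats::plogis(a0 + b * quad)) - spec$case_fraction,
      c(-30, 30))$root
    for (i in seq_len(n_reps)) {
      s <- stats::rnorm(n)
      x <- sqrt(spec$r2_xz) * s + sqrt(1 - spec$r2_xz) * stats::rnorm(n)
      y <- stats::rbinom(n, 1, stats::plogis(a + b * x))
      fit <- stats::glm.fit(cbind(1, s), y, family = stats::binomial())
      cf <- fit$coefficients[2]
      # Wald SE from the weighted information of the converged fit
      wmat <- fit$weights
      xtwx <- crossprod(cbind(1, s), cbind(1, s) * wmat)
      se <- sqrt(solve(xtwx)[2, 2])
      reject[i] <- abs(cf / se) > zcrit
    }
  } else {
    slope <- spec$effect * sqrt(spec$r2_xz * spec$var_x)
    resid_sd <- sqrt(spec$var_y - slope^2)
    for (i in seq_len(n_reps)) {
      s <- stats::rnorm(n)
      y <- slope * s + stats::rnorm(n, sd = resid_sd)
      vs <- sum((s - mean(s))^2)
      bhat <- sum((s - mean(s)) * y) / vs
      rv <- sum((y - mean(y) - bhat * (s - mean(s)))^2) / (n - 2)
      se <- sqrt(rv / vs)
      reject[i] <- abs(bhat / se) > zcrit
    }
  }
  p <- mean(reject)
  structure(p, mc_se = sqrt(p * (1 - p) / n_reps))
}
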