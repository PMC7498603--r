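#' Causal-effect estimators
#'
#' Per-SNP Wald ratios and the multi-SNP estimators: inverse-variance
#' weighted (IVW) meta-analysis with multiplicative random effects, maximum
#' likelihood under a joint normal measurement model, the weighted median,
#' and MR-Egger regression with its intercept test for directional
#' pleiotropy.
#'
#' @name estimators
NULL

new_mr_estimate <- function(method, n_snps, beta, se, p_value,
                            q_statistic = NA_real_, intercept = NA_real_,
                            intercept_se = NA_real_, intercept_p = NA_real_,
                            binary_outcome = FALSE, status = "ok") {
  ci_low <- beta - 1.96 * se
  ci_high <- beta + 1.96 * se
  data.frame(method = method, n_snps = n_snps, beta = beta, se = se,
             ci_low = ci_low, ci_high = ci_high, p_value = p_value,
             or = if (binary_outcome) exp(beta) else NA_real_,
             or_ci_low = if (binary_outcome) exp(ci_low) else NA_real_,
             or_ci_high = if (binary_outcome) exp(ci_high) else NA_real_,
             q_statistic = q_statistic, intercept = intercept,
             intercept_se = intercept_se, intercept_p = intercept_p,
             status = status, stringsAsFactors = FALSE)
}

is_binary_outcome <- function(data)
  identical(attr(data, "outcome_trait_type"), "binary")

#' Per-SNP Wald ratio with delta-method standard error
#'
#' The ratio is the SNP-outcome effect divided by the SNP-exposure effect.
#' The first-order delta-method SE is `se_y / |beta_x|`; the second-order SE
#' additionally propagates the exposure-side uncertainty,
#' `sqrt(se_y^2/beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)`.
#'
#' @param beta_x,se_x SNP-exposure effect and its SE (> 0).
#' @param beta_y,se_y SNP-outcome effect and its SE (> 0).
#' @param se_order `"first"` (default) or `"second"`.
#' @return List with `ratio`, `se` and inverse-variance `weight = 1/se^2`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y,
                       se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  if (any(beta_x == 0)) stop("undefined ratio: beta_x = 0")
  if (any(se_x <= 0) || any(se_y <= 0)) stop("standard errors must be > 0")
  ratio <- beta_y / beta_x
  se <- if (se_order == "first") se_y / abs(beta_x)
        else sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  list(ratio = ratio, se = se, weight = 1 / se^2)
}

#' Per-SNP ratio table for a harmonized dataset
#'
#' @param data A `harmonized_data` object.
#' @param se_order Delta-method order, see [wald_ratio()].
#' @return Data frame with columns `rsid`, `ratio`, `se`, `weight`.
#' @export
ratio_estimates <- function(data, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  w <- wald_ratio(data$beta_exposure, data$se_exposure,
                  data$beta_outcome, data$se_outcome, se_order)
  data.frame(rsid = data$rsid, ratio = w$ratio, se = w$se, weight = w$weight,
             stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimate
#'
#' Weighted mean of the per-SNP Wald ratios with weights `1/se^2`. The
#' fixed-effects SE is `1/sqrt(sum(w))`; the multiplicative random-effects
#' model inflates it by `max(1, sqrt(Q/(k-1)))` where `Q` is Cochran's
#' heterogeneity statistic (the residual scale is never allowed to deflate
#' the SE). With a single instrument the estimate is the Wald ratio itself
#' and the random-effects request falls back to fixed effects with a
#' warning. P-values are two-sided standard normal; the CI is
#' `beta +/- 1.96 se`.
#'
#' @param data A `harmonized_data` object.
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @param se_order Delta-method order for the per-SNP SEs.
#' @param method_label Method name recorded in the result row.
#' @return One-row data frame of class `mr_result` fields (see
#'   [run_estimator_suite()]).
#' @export
ivw_estimate <- function(data,
                         effects_model = c("multiplicative_random", "fixed"),
                         se_order = c("first", "second"),
                         method_label = "ivw") {
  effects_model <- match.arg(effects_model)
  r <- ratio_estimates(data, se_order)
  k <- nrow(r)
  if (k < 1) stop("at least one instrument is required")
  w <- r$weight
  beta <- sum(w * r$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (r$ratio - beta)^2)
  if (k == 1 && effects_model == "multiplicative_random") {
    warning("single instrument: falling back to fixed-effects IVW")
    effects_model <- "fixed"
  }
  se <- if (effects_model == "multiplicative_random")
    se_fixed * max(1, sqrt(q / (k - 1))) else se_fixed
  p <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate(method_label, k, beta, se, p, q_statistic = q,
                  binary_outcome = is_binary_outcome(data))
}

# Profile -2 log-likelihood (up to a constant) of the joint normal
# measurement model, with the per-SNP exposure means profiled out.
ml_profile_objective <- function(beta, bx, sx, by, sy)
  sum((by - beta * bx)^2 / (sy^2 + beta^2 * sx^2))

#' Maximum-likelihood estimate
#'
#' Maximizes the joint likelihood over the causal effect and the per-SNP true
#' exposure effects, where the observed exposure/outcome effects are
#' independent normals with means `(gamma_j, beta * gamma_j)` and SDs equal
#' to their reported standard errors. The per-SNP means are profiled out in
#' closed form, leaving a one-dimensional optimization initialized at the
#' IVW estimate; the SE of the causal effect comes from the inverse of the
#' observed-information matrix of the full joint likelihood at the optimum.
#' With a single SNP the estimate reduces to the Wald ratio.
#'
#' @param data A `harmonized_data` object.
#' @return One-row estimate data frame (see [run_estimator_suite()]).
#' @export
max_likelihood_estimate <- function(data) {
  bx <- data$beta_exposure; sx <- data$se_exposure
  by <- data$beta_outcome; sy <- data$se_outcome
  k <- length(bx)
  if (k < 1) stop("at least one instrument is required")
  init <- ivw_estimate(data, effects_model = "fixed")
  width <- max(1, 50 * init$se, abs(init$beta))
  lo <- init$beta - width; hi <- init$beta + width
  opt <- NULL
  for (attempt in 1:12) {
    opt <- stats::optimize(ml_profile_objective, c(lo, hi), bx = bx, sx = sx,
                           by = by, sy = sy, tol = 1e-10)
    margin <- 1e-6 * (hi - lo)
    if (opt$minimum > lo + margin && opt$minimum < hi - margin) break
    lo <- lo - (hi - lo); hi <- hi + (hi - lo)
    opt <- NULL
  }
  if (is.null(opt))
    stop("maximum-likelihood optimizer failed to locate an interior optimum ",
         "(last bracket ", format(lo), " to ", format(hi), ")")
  beta <- opt$minimum
  # profiled per-SNP exposure means and the observed information blocks
  g <- (bx / sx^2 + beta * by / sy^2) / (1 / sx^2 + beta^2 / sy^2)
  i_bb <- sum(g^2 / sy^2)
  i_bg <- (2 * beta * g - by) / sy^2
  i_gg <- 1 / sx^2 + beta^2 / sy^2
  info <- i_bb - sum(i_bg^2 / i_gg)
  if (info <= 0)
    stop("observed information is not positive at the optimum")
  se <- sqrt(1 / info)
  p <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("max_likelihood", k, beta, se, p,
                  binary_outcome = is_binary_outcome(data))
}

# interpolated weighted median of `x` with weights `w`: the point where the
# standardized cumulative weight s_j = sum_{i<=j} w_i - w_j/2 crosses 1/2
weighted_median_value <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(x[1])
  if (s[length(s)] < 0.5) return(x[length(s)])
  below <- max(which(s < 0.5))
  x[below] + (x[below + 1] - x[below]) *
    (0.5 - s[below]) / (s[below + 1] - s[below])
}

#' Weighted median estimate
#'
#' The inverse-variance weighted median of the per-SNP Wald ratios: with
#' ratios sorted ascending and weights normalized, the estimate is the
#' linearly interpolated ratio at the cumulative-weight midpoint, so that
#' half the weight comes from ratio estimates at or below it. Consistent
#' when at least 50% of the weight comes from valid instruments. The SE is a
#' parametric bootstrap: each ratio is resampled from a normal with its
#' delta-method SE, the weighted median recomputed `n_boot` times, and the
#' SD of the bootstrap estimates taken (RNG seeded for reproducibility; the
#' caller's RNG state is restored).
#'
#' @param data A `harmonized_data` object with at least 3 instruments.
#' @param n_boot Number of bootstrap replicates (default 1000; fewer than
#'   100 draws a warning).
#' @param seed Integer seed for the bootstrap (required).
#' @param se_order Delta-method order for the per-SNP SEs.
#' @return One-row estimate data frame (see [run_estimator_suite()]).
#' @export
weighted_median_estimate <- function(data, n_boot = 1000, seed,
                                     se_order = c("first", "second")) {
  if (missing(seed)) stop("a bootstrap seed is required for reproducibility")
  r <- ratio_estimates(data, se_order)
  k <- nrow(r)
  if (k < 3) stop("weighted median requires at least 3 instruments")
  if (n_boot < 100) warning("n_boot < 100 gives an unstable bootstrap SE")
  beta <- weighted_median_value(r$ratio, r$weight)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  draws <- matrix(stats::rnorm(k * n_boot, mean = r$ratio, sd = r$se),
                  nrow = k)
  boot <- apply(draws, 2, weighted_median_value, w = r$weight)
  se <- stats::sd(boot)
  p <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("weighted_median", k, beta, se, p,
                  binary_outcome = is_binary_outcome(data))
}

#' MR-Egger regression estimate and intercept test
#'
#' Instruments are first oriented so every SNP-exposure effect is
#' non-negative (both betas negated where needed), which makes the intercept
#' interpretable as average directional pleiotropy. The SNP-outcome effects
#' are then regressed on the SNP-exposure effects by weighted least squares
#' (weights `1/se_outcome^2`) with a free intercept: the slope is the causal
#' estimate under the InSIDE assumption and the intercept estimates
#' directional pleiotropy. Under the multiplicative random-effects model
#' both SEs are inflated by `max(1, residual scale)`. P-values are two-sided
#' from the t distribution with `k - 2` degrees of freedom.
#'
#' @param data A `harmonized_data` object with at least 3 instruments.
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return One-row estimate data frame with `intercept`, `intercept_se`,
#'   `intercept_p` populated (see [run_estimator_suite()]).
#' @export
egger_estimate <- function(data,
                           effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  k <- nrow(data)
  if (k < 3) stop("insufficient for Egger: at least 3 instruments required")
  s <- ifelse(data$beta_exposure < 0, -1, 1)
  bx <- data$beta_exposure * s
  by <- data$beta_outcome * s
  w <- 1 / data$se_outcome^2
  X <- cbind(1, bx)
  xtwx <- crossprod(X, X * w)
  coef <- solve(xtwx, crossprod(X, by * w))
  fitted <- X %*% coef
  rss_w <- sum(w * (by - fitted)^2)
  sigma2 <- rss_w / (k - 2)
  cov_known <- solve(xtwx)   # variance with the reported SEs taken at face value
  se_known <- sqrt(diag(cov_known))
  scale <- if (effects_model == "multiplicative_random")
    max(1, sqrt(sigma2)) else 1
  se <- se_known * scale
  tval <- coef / se
  pval <- 2 * stats::pt(-abs(tval), df = k - 2)
  new_mr_estimate("egger", k, beta = coef[2], se = se[2], p_value = pval[2],
                  q_statistic = rss_w, intercept = coef[1],
                  intercept_se = se[1], intercept_p = pval[1],
                  binary_outcome = is_binary_outcome(data))
}

#' Run the full estimator suite
#'
#' Computes IVW (multiplicative random effects), the modified IVW on the
#' confounder-filtered dataset when supplied, maximum likelihood, weighted
#' median and MR-Egger. A failing method is reported as a row with status
#' `"failed: <reason>"` rather than aborting the suite; when no filtered set
#' is supplied the modified IVW row is marked `"skipped"`. OR columns are
#' populated (as `exp(beta)`) when the outcome trait is binary.
#'
#' @param data A `harmonized_data` object.
#' @param confounder_filtered Optional `harmonized_data` restricted to
#'   instruments surviving confounder exclusion.
#' @param config List of estimator options: `effects_model`, `se_order`,
#'   `n_boot`, `seed` (defaults `"multiplicative_random"`, `"first"`, 1000,
#'   42).
#' @return Data frame of class `"mr_result"`, one row per method, columns
#'   `method`, `n_snps`, `beta`, `se`, `ci_low`, `ci_high`, `p_value`, `or`,
#'   `or_ci_low`, `or_ci_high`, `q_statistic`, `intercept`, `intercept_se`,
#'   `intercept_p`, `status`.
#' @export
run_estimator_suite <- function(data, confounder_filtered = NULL,
                                config = list()) {
  if (is.null(data) || nrow(data) == 0) stop("data must be non-empty")
  cfg <- utils::modifyList(list(effects_model = "multiplicative_random",
                                se_order = "first", n_boot = 1000,
                                seed = 42), config)
  binary <- is_binary_outcome(data)
  failed_row <- function(method, e)
    new_mr_estimate(method, NA_integer_, NA_real_, NA_real_, NA_real_,
                    binary_outcome = FALSE,
                    status = paste0("failed: ", conditionMessage(e)))
  run <- function(method, expr)
    tryCatch(expr, error = function(e) failed_row(method, e))
  rows <- list(
    run("ivw", ivw_estimate(data, cfg$effects_model, cfg$se_order)),
    if (is.null(confounder_filtered)) {
      r <- new_mr_estimate("ivw_modified", NA_integer_, NA_real_, NA_real_,
                           NA_real_, status = "skipped")
      r
    } else run("ivw_modified",
               ivw_estimate(confounder_filtered, cfg$effects_model,
                            cfg$se_order, method_label = "ivw_modified")),
    run("max_likelihood", max_likelihood_estimate(data)),
    run("weighted_median",
        weighted_median_estimate(data, n_boot = cfg$n_boot, seed = cfg$seed,
                                 se_order = cfg$se_order)),
    run("egger", egger_estimate(data, cfg$effects_model)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, direction_label = attr(data, "direction_label"),
            outcome_trait_type = attr(data, "outcome_trait_type"),
            class = c("mr_result", "data.frame"))
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR estimates: %s\n", attr(x, "direction_label")))
  df <- as.data.frame(x)
  show <- df[, c("method", "n_snps", "beta", "se", "ci_low", "ci_high",
                 "p_value", "or", "status")]
  print(format(show, digits = 3), row.names = FALSE)
  invisible(x)
}
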