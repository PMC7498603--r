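#' Synthetic two-sample GWAS generator
#'
#' Generates exposure and outcome summary-statistic tables with known ground
#' truth — the causal effect, per-SNP instrument effects, a configurable
#' pleiotropy regime, and outcome-side missingness that forces LD-proxy
#' lookup — so that every pipeline stage and estimator property can be
#' tested offline. Per-SNP true outcome effects obey
#' `Gamma_j = true_beta * gamma_j + alpha_j` exactly.
#'
#' @name synthdata
NULL

SCENARIO_PRESETS <- c("bmi_to_ad_like", "ad_to_bmi_like", "null",
                      "balanced_pleiotropy", "directional_pleiotropy")

#' Build a synthetic-scenario configuration
#'
#' Presets:
#' \describe{
#'   \item{bmi_to_ad_like}{941 instruments explaining R2 = 0.06 of a
#'     continuous exposure handled on its standardized (unit-variance)
#'     scale, exposure GWAS n = 681,275; binary outcome GWAS with 21,000
#'     cases / 95,000 controls; true log-OR log(1.08) per exposure unit;
#'     one instrument missing from the outcome table with an r2 = 1 proxy.}
#'   \item{ad_to_bmi_like}{24 instruments explaining R2 = 0.026 of a binary
#'     exposure (case fraction 21,000/116,000); continuous outcome of
#'     variance 16 with GWAS n = 681,275; true effect 0; 14 instruments
#'     missing from the outcome table, 10 of them proxiable at r2 in
#'     [0.67, 1] and 4 with no adequate proxy.}
#'   \item{null}{300 strong instruments, continuous traits, true effect 0,
#'     no pleiotropy — the type-I-error calibration scenario.}
#'   \item{balanced_pleiotropy}{100 instruments, direct SNP-outcome effects
#'     drawn with mean zero.}
#'   \item{directional_pleiotropy}{100 instruments, direct effects with
#'     positive mean and the InSIDE condition holding
#'     (`inside_violation = 0`).}
#' }
#'
#' @param name Preset name: `"bmi_to_ad_like"`, `"ad_to_bmi_like"`,
#'   `"null"`, `"balanced_pleiotropy"` or `"directional_pleiotropy"`.
#' @param ... Field overrides applied on top of the preset (e.g. `seed`,
#'   `n_snps`, `true_beta`, `pleiotropy = list(type, mu, tau, fraction)`,
#'   `inside_violation`, `maf_range`, `target_r2`,
#'   `missing_outcome_fraction`, `no_proxy_fraction`, `proxy_r2_range`,
#'   `palindromic_fraction`).
#' @return List of class `"mr_scenario"`.
#' @export
make_scenario <- function(name, ...) {
  if (!name %in% SCENARIO_PRESETS)
    stop("unknown preset '", name, "'; available presets: ",
         paste(SCENARIO_PRESETS, collapse = ", "))
  base <- list(
    name = name, n_snps = 100, true_beta = 0,
    exposure_type = "continuous", outcome_type = "continuous",
    var_x = 1, var_y = 1,
    n_exposure = 3e5, n_outcome = 3e5,
    case_fraction_exposure = NULL, case_fraction_outcome = NULL,
    target_r2 = 0.05,
    pleiotropy = list(type = "none", mu = 0, tau = 0, fraction = 1),
    inside_violation = 0,
    maf_range = c(0.05, 0.40), palindromic_fraction = 0.1,
    gamma_dist = "halfnormal",
    missing_outcome_fraction = 0, no_proxy_fraction = 0,
    proxy_r2_range = c(0.8, 1), seed = 1L)
  preset <- switch(name,
    bmi_to_ad_like = list(
      n_snps = 941, true_beta = log(1.08),
      exposure_type = "continuous", outcome_type = "binary",
      var_x = 1, n_exposure = 681275, n_outcome = 116000,
      case_fraction_outcome = 21000 / 116000, target_r2 = 0.06,
      missing_outcome_fraction = 1 / 941, no_proxy_fraction = 0,
      proxy_r2_range = c(1, 1)),
    ad_to_bmi_like = list(
      n_snps = 24, true_beta = 0,
      exposure_type = "binary", outcome_type = "continuous",
      var_y = 16, n_exposure = 116000, n_outcome = 681275,
      case_fraction_exposure = 21000 / 116000, target_r2 = 0.026,
      missing_outcome_fraction = 14 / 24, no_proxy_fraction = 4 / 14,
      proxy_r2_range = c(0.67, 1)),
    null = list(n_snps = 300, true_beta = 0, n_exposure = 5e5,
                n_outcome = 5e5, target_r2 = 0.05),
    balanced_pleiotropy = list(
      true_beta = 0.1, gamma_dist = "uniform",
      pleiotropy = list(type = "balanced", mu = 0, tau = 0.002,
                        fraction = 1)),
    directional_pleiotropy = list(
      true_beta = 0.1, gamma_dist = "uniform",
      n_exposure = 3e6, n_outcome = 3e6,
      pleiotropy = list(type = "directional", mu = 0.002, tau = 0.001,
                        fraction = 1),
      inside_violation = 0))
  sc <- utils::modifyList(base, preset)
  sc <- utils::modifyList(sc, list(...))
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  stopifnot(sc$n_snps >= 1,
            sc$maf_range[1] > 0, sc$maf_range[2] <= 0.5,
            sc$maf_range[1] <= sc$maf_range[2],
            sc$missing_outcome_fraction >= 0,
            sc$missing_outcome_fraction < 1,
            sc$target_r2 > 0, sc$target_r2 < 1)
  if (sc$exposure_type == "binary" && is.null(sc$case_fraction_exposure))
    stop("binary exposure requires case_fraction_exposure")
  if (sc$outcome_type == "binary" && is.null(sc$case_fraction_outcome))
    stop("binary outcome requires case_fraction_outcome")
  structure(sc, class = "mr_scenario")
}

# per-allele GWAS standard error approximations given allele frequency and n
gwas_se <- function(maf, n, type, trait_var = 1, case_fraction = NULL) {
  if (type == "continuous") sqrt(trait_var / (2 * maf * (1 - maf) * n))
  else 1 / sqrt(2 * maf * (1 - maf) * n *
                  case_fraction * (1 - case_fraction))
}

NONPAL_PAIRS <- local({
  p <- expand.grid(ea = VALID_BASES, oa = VALID_BASES,
                   stringsAsFactors = FALSE)
  p[p$ea != p$oa & p$oa != chartr("ACGT", "TGCA", p$ea), ]
})
PAL_PAIRS <- data.frame(ea = c("A", "T", "C", "G"),
                        oa = c("T", "A", "G", "C"),
                        stringsAsFactors = FALSE)

#' Simulate a two-sample GWAS summary-statistic dataset
#'
#' MAFs are drawn uniformly in `maf_range`; per-SNP exposure effects are
#' drawn normal and rescaled so the explained variance equals `target_r2`
#' exactly (on the trait scale for a continuous exposure; on the observed
#' 0/1 scale, with effects in log-odds, for a binary exposure). Direct
#' pleiotropic outcome effects follow the configured regime, with the
#' InSIDE-violating correlation applied to the affected SNPs. Observed
#' effects are the truths plus normal noise at per-SNP standard errors from
#' the standard GWAS approximations for the configured sample sizes. Outcome
#' allele presentation is randomly scrambled (swapped, strand-flipped, or
#' both) to exercise harmonization; a configured fraction of instruments is
#' removed from the outcome table, each given at most one LD proxy with r2
#' drawn from `proxy_r2_range` (a `no_proxy_fraction` of them gets either a
#' sub-threshold proxy or none). Fully reproducible from `scenario$seed`.
#'
#' @param scenario An [make_scenario()] configuration.
#' @return List of class `"synthetic_mr_data"` with elements `exposure` and
#'   `outcome` ([summary_stats()] tables), `ld` ([ld_table()]), `truth`
#'   (data frame `rsid`, `gamma`, `alpha`, `big_gamma` with attribute
#'   `true_beta`) and `scenario`.
#' @export
simulate_two_sample_gwas <- function(scenario) {
  sc <- validate_scenario(scenario)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(sc$seed)

  L <- sc$n_snps
  rsid <- sprintf("rs1%06d", seq_len(L))
  chr <- as.character(sample.int(22, L, replace = TRUE))
  pos <- sample.int(2.4e8, L, replace = TRUE)
  maf <- stats::runif(L, sc$maf_range[1], sc$maf_range[2])
  n_pal <- round(sc$palindromic_fraction * L)
  pal <- seq_len(L) %in% sample.int(L, n_pal)
  pair_idx <- sample.int(nrow(NONPAL_PAIRS), L, replace = TRUE)
  ea <- ifelse(pal, PAL_PAIRS$ea[(pair_idx %% 4) + 1], NONPAL_PAIRS$ea[pair_idx])
  oa <- ifelse(pal, PAL_PAIRS$oa[(pair_idx %% 4) + 1], NONPAL_PAIRS$oa[pair_idx])

  het <- 2 * maf * (1 - maf)
  target_sum <- if (sc$exposure_type == "continuous")
    sc$target_r2 * sc$var_x
  else sc$target_r2 / (sc$case_fraction_exposure *
                         (1 - sc$case_fraction_exposure))
  # instrument effects oriented to the exposure-increasing allele (the
  # convention under which directional pleiotropy is defined); half-normal
  # by default, or uniform bounded away from zero (the benchmark design for
  # pleiotropy scenarios, where near-null instruments would otherwise be
  # noise-mis-oriented and break InSIDE by construction)
  raw <- if (identical(sc$gamma_dist, "uniform")) stats::runif(L, 0.5, 1.5)
         else abs(stats::rnorm(L))
  gamma <- raw * sqrt(target_sum / sum(het * raw^2))

  alpha <- numeric(L)
  pl <- sc$pleiotropy
  if (pl$type != "none") {
    n_aff <- round(pl$fraction * L)
    aff <- sample.int(L, n_aff)
    mu <- if (pl$type == "balanced") 0 else pl$mu
    rho <- sc$inside_violation
    g_std <- if (stats::sd(gamma[aff]) > 0)
      (gamma[aff] - mean(gamma[aff])) / stats::sd(gamma[aff]) else 0
    alpha[aff] <- mu + pl$tau * (rho * g_std +
                                   sqrt(1 - rho^2) * stats::rnorm(n_aff))
  }
  big_gamma <- sc$true_beta * gamma + alpha

  se_x <- gwas_se(maf, sc$n_exposure, sc$exposure_type, sc$var_x,
                  sc$case_fraction_exposure)
  se_y <- gwas_se(maf, sc$n_outcome, sc$outcome_type, sc$var_y,
                  sc$case_fraction_outcome)
  bx <- gamma + stats::rnorm(L, sd = se_x)
  by <- big_gamma + stats::rnorm(L, sd = se_y)
  pfun <- function(b, s) pmax(2 * stats::pnorm(-abs(b / s)), 1e-300)

  exposure <- summary_stats(
    data.frame(rsid = rsid, chr = chr, pos = pos, effect_allele = ea,
               other_allele = oa, eaf = maf, beta = bx, se = se_x,
               p = pfun(bx, se_x), n = sc$n_exposure,
               stringsAsFactors = FALSE),
    trait_name = paste0(sc$name, "_exposure"),
    trait_type = sc$exposure_type)

  # outcome presentation scrambling: swap and/or strand-flip the record
  mode <- sample.int(4, L, replace = TRUE)   # 1 as-is, 2 swap, 3 flip, 4 both
  o_ea <- ea; o_oa <- oa; o_b <- by; o_eaf <- maf
  swp <- mode %in% c(2, 4); flp <- mode %in% c(3, 4)
  tmp <- o_ea[swp]; o_ea[swp] <- o_oa[swp]; o_oa[swp] <- tmp
  o_b[swp] <- -o_b[swp]; o_eaf[swp] <- 1 - o_eaf[swp]
  o_ea[flp] <- complement_alleles(o_ea[flp])
  o_oa[flp] <- complement_alleles(o_oa[flp])

  n_miss <- round(sc$missing_outcome_fraction * L)
  miss <- sort(sample.int(L, n_miss))
  n_noproxy <- round(sc$no_proxy_fraction * n_miss)
  noproxy <- miss[seq_len(n_noproxy)]
  proxiable <- setdiff(miss, noproxy)
  # among the unproxiable, half get a sub-threshold proxy, half none at all
  lowproxy <- noproxy[seq_len(ceiling(n_noproxy / 2))]

  out_keep <- setdiff(seq_len(L), miss)
  out_df <- data.frame(rsid = rsid, chr = chr, pos = pos,
                       effect_allele = o_ea, other_allele = o_oa,
                       eaf = o_eaf, beta = o_b, se = se_y,
                       p = pfun(o_b, se_y), n = sc$n_outcome,
                       stringsAsFactors = FALSE)[out_keep, , drop = FALSE]

  ld_rows <- list()
  proxy_targets <- c(proxiable, lowproxy)
  if (length(proxy_targets)) {
    for (j in seq_along(proxy_targets)) {
      i <- proxy_targets[j]
      r2 <- if (i %in% proxiable)
        stats::runif(1, sc$proxy_r2_range[1], sc$proxy_r2_range[2])
      else stats::runif(1, 0.10, 0.55)
      prs <- sprintf("rs9%06d", j)
      ppair <- NONPAL_PAIRS[sample.int(nrow(NONPAL_PAIRS), 1), ]
      pmaf <- maf[i]
      pse <- gwas_se(pmaf, sc$n_outcome, sc$outcome_type, sc$var_y,
                     sc$case_fraction_outcome)
      # proxy's marginal outcome effect attenuated by the LD correlation
      ptrue <- sqrt(r2) * big_gamma[i]
      aligned <- stats::runif(1) < 0.5   # proxy effect allele tags index ea?
      pb <- (if (aligned) ptrue else -ptrue) + stats::rnorm(1, sd = pse)
      peaf <- if (aligned) pmaf else 1 - pmaf
      out_df <- rbind(out_df, data.frame(
        rsid = prs, chr = chr[i], pos = pos[i] + 5000L,
        effect_allele = ppair$ea, other_allele = ppair$oa,
        eaf = peaf, beta = pb, se = pse, p = pfun(pb, pse),
        n = sc$n_outcome, stringsAsFactors = FALSE))
      ld_rows[[j]] <- data.frame(
        rsid_a = rsid[i], rsid_b = prs, r2 = r2,
        allele_a = ea[i],
        allele_b = if (aligned) ppair$ea else ppair$oa,
        stringsAsFactors = FALSE)
    }
  }
  outcome <- summary_stats(out_df,
                           trait_name = paste0(sc$name, "_outcome"),
                           trait_type = sc$outcome_type)
  ld <- ld_table(if (length(ld_rows)) do.call(rbind, ld_rows)
                 else data.frame(rsid_a = character(0), rsid_b = character(0),
                                 r2 = numeric(0), allele_a = character(0),
                                 allele_b = character(0),
                                 stringsAsFactors = FALSE))
  truth <- data.frame(rsid = rsid, gamma = gamma, alpha = alpha,
                      big_gamma = big_gamma, stringsAsFactors = FALSE)
  attr(truth, "true_beta") <- sc$true_beta
  structure(list(exposure = exposure, outcome = outcome, ld = ld,
                 truth = truth, scenario = sc),
            class = "synthetic_mr_data")
}

#' @export
print.synthetic_mr_data <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("Synthetic two-sample GWAS ('%s'): %d instruments, true beta %.4f\n",
              sc$name, sc$n_snps, sc$true_beta))
  cat(sprintf("  exposure: %s n=%g; outcome: %s n=%g; %d outcome records, %d LD pairs\n",
              sc$exposure_type, sc$n_exposure, sc$outcome_type, sc$n_outcome,
              nrow(x$outcome), nrow(x$ld$entries)))
  invisible(x)
}

#' Operating characteristics of the estimators over replicated scenarios
#'
#' Runs simulate -> harmonize -> estimate `n_reps` times with per-replicate
#' seeds derived from `seed` by a counter scheme, and aggregates bias,
#' empirical SE, RMSE, 95% CI coverage and rejection rate (p < 0.05) per
#' method against the scenario's true causal effect. A failing estimator in
#' a single replicate is recorded, not fatal.
#'
#' @param scenario An [make_scenario()] configuration.
#' @param n_reps Number of replicates (at least 100 for stable summaries).
#' @param methods Character vector among `"ivw"`, `"max_likelihood"`,
#'   `"weighted_median"`, `"egger"`.
#' @param seed Master integer seed.
#' @param config Estimator options (see [run_estimator_suite()]); the
#'   weighted-median bootstrap uses the per-replicate seed.
#' @return Data frame with one row per method (`bias`, `mean_estimate`,
#'   `empirical_se`, `rmse`, `coverage`, `rejection_rate`, `n_ok`), with the
#'   per-replicate estimate matrix in attribute `"estimates"`.
#' @export
evaluate_operating_characteristics <- function(scenario, n_reps = 200,
                                               methods = c("ivw",
                                                           "max_likelihood",
                                                           "weighted_median",
                                                           "egger"),
                                               seed = 1,
                                               config = list()) {
  if (n_reps < 100) warning("n_reps < 100 gives unstable summaries")
  cfg <- utils::modifyList(list(effects_model = "multiplicative_random",
                                se_order = "first", n_boot = 200), config)
  true_beta <- scenario$true_beta
  est <- matrix(NA_real_, n_reps, length(methods),
                dimnames = list(NULL, methods))
  cover <- rej <- est
  for (rep in seq_len(n_reps)) {
    sc <- scenario
    sc$seed <- (seed + rep) %% 2147483647L
    sim <- simulate_two_sample_gwas(sc)
    h <- tryCatch(harmonize_dataset(sim$exposure, sim$outcome, sim$ld),
                  error = function(e) NULL)
    if (is.null(h)) next
    for (m in methods) {
      r <- tryCatch(switch(m,
        ivw = ivw_estimate(h, cfg$effects_model, cfg$se_order),
        max_likelihood = max_likelihood_estimate(h),
        weighted_median = weighted_median_estimate(h, n_boot = cfg$n_boot,
                                                   seed = sc$seed,
                                                   se_order = cfg$se_order),
        egger = egger_estimate(h, cfg$effects_model),
        stop("unknown method: ", m)), error = function(e) NULL)
      if (is.null(r)) next
      est[rep, m] <- r$beta
      cover[rep, m] <- r$ci_low <= true_beta && true_beta <= r$ci_high
      rej[rep, m] <- r$p_value < 0.05
    }
  }
  out <- do.call(rbind, lapply(methods, function(m) {
    e <- est[, m]
    ok <- !is.na(e)
    data.frame(method = m, true_beta = true_beta,
               mean_estimate = mean(e[ok]),
               bias = mean(e[ok]) - true_beta,
               empirical_se = stats::sd(e[ok]),
               rmse = sqrt(mean((e[ok] - true_beta)^2)),
               coverage = mean(cover[ok, m]),
               rejection_rate = mean(rej[ok, m]),
               n_ok = sum(ok), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, estimates = est, scenario_name = scenario$name)
}
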