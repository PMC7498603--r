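#' Instrument-strength and NOME diagnostics
#'
#' Measurement error in the SNP-exposure estimates (departure from the "NO
#' Measurement Error", NOME, assumption) attenuates MR estimates. For IVW
#' the attenuation is governed by the mean instrument F statistic through
#' `(F - 1)/F`; for MR-Egger by the I2_GX statistic, the fraction of the
#' dispersion of the SNP-exposure estimates attributable to true effect
#' heterogeneity rather than estimation noise.
#'
#' @name diagnostics
NULL

exposure_effects <- function(data) {
  if (inherits(data, "harmonized_data"))
    list(rsid = data$rsid, beta = data$beta_exposure, se = data$se_exposure)
  else if (inherits(data, "summary_stats"))
    list(rsid = data$rsid, beta = data$beta, se = data$se)
  else stop("expected harmonized_data or summary_stats input")
}

#' Per-SNP F statistics and mean-F NOME attenuation
#'
#' The per-SNP F is the squared z statistic of the SNP-exposure association,
#' `(beta/se)^2` — the standard single-SNP instrument-strength F at large
#' sample size. The mean F is a simple average by default; an
#' inverse-variance weighted mean (weights `1/se^2`) is selectable. The
#' expected relative attenuation of the IVW estimate under NOME departure is
#' `(mean_F - 1)/mean_F`.
#'
#' @param data A `harmonized_data` object or exposure `summary_stats` /
#'   `instrument_set`.
#' @param mean_type `"simple"` (default) or `"inverse_variance"`.
#' @return List of class `"mr_diagnostics"` with `per_snp_f` (named vector),
#'   `mean_f`, `attenuation`, and `i2_gx` fields left `NA`.
#' @export
instrument_strength <- function(data, mean_type = c("simple",
                                                    "inverse_variance")) {
  mean_type <- match.arg(mean_type)
  e <- exposure_effects(data)
  if (length(e$beta) < 1 || any(e$se <= 0))
    stop("at least one SNP with positive SE is required")
  f <- (e$beta / e$se)^2
  names(f) <- e$rsid
  mean_f <- if (mean_type == "simple") mean(f)
            else sum(f / e$se^2) / sum(1 / e$se^2)
  structure(list(per_snp_f = f, mean_f = mean_f,
                 attenuation = (mean_f - 1) / mean_f,
                 q_gx = NA_real_, i2_gx = NA_real_),
            class = "mr_diagnostics")
}

#' I2_GX statistic for MR-Egger NOME attenuation
#'
#' Instruments are oriented to non-negative exposure effects (as for Egger),
#' then `Q_GX` is the Cochran heterogeneity of the SNP-exposure estimates
#' about their inverse-variance weighted mean, and
#' `I2_GX = max(0, (Q_GX - (k-1))/Q_GX)`. Values near 1 indicate that
#' measurement error in the exposure estimates barely attenuates the Egger
#' slope; small values flag the Egger estimate as unreliable.
#'
#' @param data A `harmonized_data` object (or exposure table) with at least
#'   2 SNPs.
#' @return List of class `"mr_diagnostics"` with `q_gx` and `i2_gx` set.
#' @export
i_squared_gx <- function(data) {
  e <- exposure_effects(data)
  k <- length(e$beta)
  if (k < 2) stop("I2_GX requires at least 2 SNPs")
  b <- abs(e$beta)
  w <- 1 / e$se^2
  bw <- sum(w * b) / sum(w)
  q <- sum(w * (b - bw)^2)
  i2 <- if (q <= 0) 0 else max(0, (q - (k - 1)) / q)
  structure(list(per_snp_f = NULL, mean_f = NA_real_,
                 attenuation = NA_real_, q_gx = q, i2_gx = i2),
            class = "mr_diagnostics")
}

#' Combined instrument-strength diagnostics report
#'
#' @inheritParams instrument_strength
#' @return List of class `"mr_diagnostics"` with `per_snp_f`, `mean_f`,
#'   `attenuation`, `q_gx` and `i2_gx` all populated (I2 fields are `NA`
#'   for a single instrument).
#' @export
mr_diagnostics <- function(data, mean_type = c("simple", "inverse_variance")) {
  f <- instrument_strength(data, mean_type)
  if (length(f$per_snp_f) >= 2) {
    i2 <- i_squared_gx(data)
    f$q_gx <- i2$q_gx
    f$i2_gx <- i2$i2_gx
  }
  f
}

#' @export
print.mr_diagnostics <- function(x, ...) {
  cat("Instrument-strength diagnostics\n")
  if (!is.na(x$mean_f))
    cat(sprintf("  mean F = %.2f over %d SNPs; NOME attenuation (F-1)/F = %.2f%%\n",
                x$mean_f, length(x$per_snp_f), 100 * x$attenuation))
  if (!is.na(x$i2_gx))
    cat(sprintf("  Q_GX = %.2f; I2_GX = %.1f%%\n", x$q_gx, 100 * x$i2_gx))
  invisible(x)
}
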