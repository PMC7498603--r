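#' Allele harmonization
#'
#' Places each exposure/outcome association pair on a common effect allele,
#' resolves palindromic (A/T, C/G) variants, substitutes LD proxies for
#' instruments absent from the outcome table, and logs every action.
#' Harmonization never changes the magnitude of any effect or any standard
#' error; only signs, allele labels and effect-allele-frequency sides.
#'
#' @name harmonize
NULL

#' Base-complement of allele letters
#' @param a Character vector of A/C/G/T letters.
#' @return The complementary bases.
#' @export
complement_alleles <- function(a) chartr("ACGT", "TGCA", a)

is_palindromic <- function(ea, oa) oa == complement_alleles(ea)

#' Classify the relationship between two allele pairs
#'
#' Vectorized over its four arguments. The relationship is `match` when the
#' pairs are equal; `swap` when effect/other are exchanged; `strand_flip`
#' when the outcome pair is the base-complement of the exposure pair;
#' `swap_and_flip` when complemented and exchanged; `palindromic_ambiguous`
#' when the exposure pair is complementary to itself (A/T or C/G), so that
#' strand cannot be resolved from alleles alone; and `incompatible`
#' otherwise.
#'
#' @param exp_effect,exp_other Exposure effect/other alleles.
#' @param out_effect,out_other Outcome effect/other alleles.
#' @return Character vector of relationships.
#' @export
classify_alleles <- function(exp_effect, exp_other, out_effect, out_other) {
  all4 <- c(exp_effect, exp_other, out_effect, out_other)
  if (any(!(toupper(all4) %in% VALID_BASES)))
    stop("alleles must be single bases A/C/G/T")
  ea <- toupper(exp_effect); oa <- toupper(exp_other)
  eb <- toupper(out_effect); ob <- toupper(out_other)
  n <- max(length(ea), length(oa), length(eb), length(ob))
  ea <- rep_len(ea, n); oa <- rep_len(oa, n)
  eb <- rep_len(eb, n); ob <- rep_len(ob, n)
  cea <- complement_alleles(ea); coa <- complement_alleles(oa)
  out <- rep("incompatible", n)
  out[eb == cea & ob == coa] <- "strand_flip"
  out[eb == coa & ob == cea] <- "swap_and_flip"
  out[eb == oa & ob == ea] <- "swap"
  out[eb == ea & ob == oa] <- "match"
  pal <- is_palindromic(ea, oa)
  out[pal & out != "incompatible"] <- "palindromic_ambiguous"
  out
}

# Vectorized harmonization core over a joined exposure/outcome frame with
# columns rsid, ea_x, oa_x, beta_x, se_x, eaf_x, ea_y, oa_y, beta_y, se_y,
# eaf_y (and optionally proxy_rsid, proxy_r2). Returns the frame with
# harmonized outcome fields plus `action`, `palindromic`, `drop_reason`.
harmonize_core <- function(df, palindrome_policy = "align_by_eaf",
                           eaf_ambiguity_band = 0.08) {
  n <- nrow(df)
  if (n == 0) {
    df$action <- character(0); df$palindromic <- logical(0)
    df$drop_reason <- character(0)
    return(df)
  }
  rel <- classify_alleles(df$ea_x, df$oa_x, df$ea_y, df$oa_y)
  action <- rep("none", n)
  drop_reason <- rep(NA_character_, n)
  palindromic <- rel == "palindromic_ambiguous"

  negate <- rel %in% c("swap", "swap_and_flip")
  action[rel == "swap"] <- "swap"
  action[rel == "strand_flip"] <- "strand_flip"
  action[rel == "swap_and_flip"] <- "swap_and_flip"
  drop_reason[rel == "incompatible"] <- "incompatible"

  # Palindromic variants: nominally orient by allele labels first (effect
  # alleles equal => as-is, exchanged => swap), then resolve strand per policy.
  pal <- which(palindromic)
  if (length(pal)) {
    pal_swap <- df$ea_y[pal] != df$ea_x[pal]
    negate[pal] <- pal_swap
    if (palindrome_policy == "drop") {
      drop_reason[pal] <- "palindromic"
    } else if (palindrome_policy == "keep") {
      action[pal] <- ifelse(pal_swap, "swap", "none")
    } else if (palindrome_policy == "align_by_eaf") {
      eaf_y_nominal <- ifelse(pal_swap, 1 - df$eaf_y[pal], df$eaf_y[pal])
      no_eaf <- is.na(df$eaf_x[pal]) | is.na(df$eaf_y[pal])
      ambig <- !no_eaf &
        (abs(df$eaf_x[pal] - 0.5) <= eaf_ambiguity_band |
           abs(eaf_y_nominal - 0.5) <= eaf_ambiguity_band)
      opposite <- !no_eaf & !ambig &
        ((df$eaf_x[pal] < 0.5) != (eaf_y_nominal < 0.5))
      drop_reason[pal][no_eaf] <- "palindromic_no_eaf"
      drop_reason[pal][ambig] <- "palindromic_ambiguous_eaf"
      # opposite frequency sides: the outcome record is on the other strand,
      # so the nominal orientation must additionally be reversed
      negate[pal][opposite] <- !negate[pal][opposite]
      act <- ifelse(pal_swap,
                    ifelse(opposite, "strand_flip", "swap"),
                    ifelse(opposite, "swap_and_flip", "none"))
      act[!no_eaf & opposite & !pal_swap] <- "swap_and_flip"
      action[pal] <- act
    } else stop("unknown palindrome_policy: ", palindrome_policy)
  }

  flip_eaf <- negate & is.na(drop_reason)
  df$beta_y <- ifelse(negate & is.na(drop_reason), -df$beta_y, df$beta_y)
  df$eaf_y <- ifelse(flip_eaf, 1 - df$eaf_y, df$eaf_y)
  # present outcome alleles on the exposure's labels once harmonized
  df$ea_y <- ifelse(is.na(drop_reason), df$ea_x, df$ea_y)
  df$oa_y <- ifelse(is.na(drop_reason), df$oa_x, df$oa_y)
  df$action <- action
  df$palindromic <- palindromic
  df$drop_reason <- drop_reason
  df
}

as_snp_record <- function(x) {
  if (is.data.frame(x)) as.list(x[1, , drop = FALSE]) else as.list(x)
}

#' Harmonize one exposure/outcome association pair
#'
#' For `swap`/`swap_and_flip` relationships the outcome effect is negated and
#' its effect-allele frequency replaced by `1 - eaf`; for `strand_flip` the
#' alleles are complemented with effect and frequency unchanged. Palindromic
#' variants are resolved per `palindrome_policy`: `align_by_eaf` orients by
#' agreement of the frequency sides (both below or both above 0.5), dropping
#' the variant when either frequency lies within `eaf_ambiguity_band` of 0.5
#' or is absent; `drop` removes all palindromic variants; `keep` retains them
#' in their nominal orientation. Standard errors are never altered.
#'
#' @param exp,out Single records (one-row data frames or lists) with fields
#'   `rsid`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`; the same
#'   rsid on both sides.
#' @param palindrome_policy `"align_by_eaf"` (default), `"drop"` or `"keep"`.
#' @param eaf_ambiguity_band Half-width of the ambiguity band around 0.5.
#' @return A one-row data frame with columns `rsid`, `beta_exposure`,
#'   `se_exposure`, `eaf_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_outcome`, `action`, `palindromic`; or, for a dropped pair, the same
#'   frame with a non-`NA` `drop_reason` column.
#' @export
harmonize_pair <- function(exp, out, palindrome_policy = "align_by_eaf",
                           eaf_ambiguity_band = 0.08) {
  e <- as_snp_record(exp); o <- as_snp_record(out)
  if (!identical(as.character(e$rsid), as.character(o$rsid)))
    stop("exposure and outcome records must share the same rsid")
  df <- data.frame(rsid = as.character(e$rsid),
                   ea_x = e$effect_allele, oa_x = e$other_allele,
                   beta_x = e$beta, se_x = e$se,
                   eaf_x = if (is.null(e$eaf)) NA_real_ else e$eaf,
                   ea_y = o$effect_allele, oa_y = o$other_allele,
                   beta_y = o$beta, se_y = o$se,
                   eaf_y = if (is.null(o$eaf)) NA_real_ else o$eaf,
                   stringsAsFactors = FALSE)
  h <- harmonize_core(df, palindrome_policy, eaf_ambiguity_band)
  data.frame(rsid = h$rsid, beta_exposure = h$beta_x, se_exposure = h$se_x,
             eaf_exposure = h$eaf_x, beta_outcome = h$beta_y,
             se_outcome = h$se_y, eaf_outcome = h$eaf_y, action = h$action,
             palindromic = h$palindromic, drop_reason = h$drop_reason,
             stringsAsFactors = FALSE)
}

#' Choose LD proxies for instruments missing from the outcome table
#'
#' For each missing rsid the outcome-present partner with maximal r2 at or
#' above `min_r2` is chosen (ties broken by lexicographically smallest proxy
#' rsid). When the LD table carries no allele-phase map for the chosen pair,
#' the proxy is used only if it is non-palindromic and its effect-allele
#' frequency lies away from 0.5 (so it can be oriented by frequency);
#' otherwise the rsid is dropped with a reason.
#'
#' @param missing_rsids Character vector of instrument rsids absent from the
#'   outcome table.
#' @param ld An [ld_table()].
#' @param outcome The outcome [summary_stats()] table.
#' @param min_r2 Minimum acceptable r2 (default 0.6).
#' @param eaf_ambiguity_band Band around 0.5 within which a phase-less proxy
#'   is considered non-orientable.
#' @return List with `mapping` (data frame: `rsid`, `proxy_rsid`, `r2`,
#'   `allele_index`, `allele_proxy`, plus the proxy's outcome record fields)
#'   and `dropped` (data frame: `rsid`, `reason`).
#' @export
substitute_proxies <- function(missing_rsids, ld, outcome, min_r2 = 0.6,
                               eaf_ambiguity_band = 0.08) {
  if (min_r2 < 0 || min_r2 > 1) stop("min_r2 must lie in [0,1]")
  out_df <- as.data.frame(outcome)
  map <- list(); dropped <- list()
  for (rs in missing_rsids) {
    cand <- ld_partners(ld, rs)
    cand <- cand[cand$proxy %in% out_df$rsid & cand$r2 >= min_r2, , drop = FALSE]
    if (nrow(cand) == 0) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(rsid = rs, reason = "no_proxy", stringsAsFactors = FALSE)
      next
    }
    cand <- cand[order(-cand$r2, cand$proxy), , drop = FALSE]
    best <- cand[1, ]
    prec <- out_df[out_df$rsid == best$proxy, , drop = FALSE][1, ]
    has_phase <- !is.na(best$allele_index) && !is.na(best$allele_proxy)
    if (!has_phase) {
      orientable <- !is_palindromic(prec$effect_allele, prec$other_allele) &&
        !is.na(prec$eaf) && abs(prec$eaf - 0.5) > eaf_ambiguity_band
      if (!orientable) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(rsid = rs, reason = "proxy_unorientable",
                     stringsAsFactors = FALSE)
        next
      }
    }
    map[[length(map) + 1L]] <- data.frame(
      rsid = rs, proxy_rsid = best$proxy, r2 = best$r2,
      allele_index = best$allele_index, allele_proxy = best$allele_proxy,
      proxy_effect_allele = prec$effect_allele,
      proxy_other_allele = prec$other_allele,
      proxy_eaf = prec$eaf, proxy_beta = prec$beta, proxy_se = prec$se,
      stringsAsFactors = FALSE)
  }
  empty_map <- data.frame(rsid = character(0), proxy_rsid = character(0),
                          r2 = numeric(0), allele_index = character(0),
                          allele_proxy = character(0),
                          proxy_effect_allele = character(0),
                          proxy_other_allele = character(0),
                          proxy_eaf = numeric(0), proxy_beta = numeric(0),
                          proxy_se = numeric(0), stringsAsFactors = FALSE)
  list(mapping = if (length(map)) do.call(rbind, map) else empty_map,
       dropped = if (length(dropped)) do.call(rbind, dropped)
                 else data.frame(rsid = character(0), reason = character(0),
                                 stringsAsFactors = FALSE))
}

# Express a proxy's outcome record on the index SNP's alleles. The phase map
# states that `allele_proxy` of the proxy tags `allele_index` of the index
# SNP; without a phase map the orientation is inferred from agreement of the
# effect-allele-frequency sides (valid because r2 is high). The proxy's beta
# and SE stand in unchanged for the missing SNP (no r2 attenuation
# correction), as in standard two-sample practice.
translate_proxy <- function(m, index_ea, index_oa, index_eaf,
                            eaf_ambiguity_band = 0.08) {
  has_phase <- !is.na(m$allele_index) && !is.na(m$allele_proxy) &&
    m$allele_index %in% c(index_ea, index_oa) &&
    m$allele_proxy %in% c(m$proxy_effect_allele, m$proxy_other_allele)
  if (has_phase) {
    # which index allele does the proxy's *effect* allele tag?
    tagged <- if (m$proxy_effect_allele == m$allele_proxy) m$allele_index
              else setdiff(c(index_ea, index_oa), m$allele_index)
    flip <- tagged != index_ea
  } else {
    if (is.na(index_eaf) || abs(index_eaf - 0.5) <= eaf_ambiguity_band ||
        is.na(m$proxy_eaf) || abs(m$proxy_eaf - 0.5) <= eaf_ambiguity_band)
      return(NULL)
    flip <- (m$proxy_eaf < 0.5) != (index_eaf < 0.5)
  }
  data.frame(effect_allele = index_ea, other_allele = index_oa,
             beta = if (flip) -m$proxy_beta else m$proxy_beta,
             se = m$proxy_se,
             eaf = if (flip) 1 - m$proxy_eaf else m$proxy_eaf,
             stringsAsFactors = FALSE)
}

new_harmonized_data <- function(df, direction_label, exposure_trait,
                                outcome_trait, outcome_trait_type, log) {
  rownames(df) <- NULL
  structure(df, direction_label = direction_label,
            exposure_trait = exposure_trait, outcome_trait = outcome_trait,
            outcome_trait_type = outcome_trait_type, log = log,
            class = c("harmonized_data", "data.frame"))
}

#' Harmonization log
#' @param data A `harmonized_data` object.
#' @return List with counts and the per-SNP action/disposition tables.
#' @export
harmonization_log <- function(data) attr(data, "log")

#' Harmonize an instrument set against an outcome table
#'
#' Per-SNP pipeline: locate the instrument in the outcome table (else find an
#' LD proxy at `r2 >= proxy_min_r2`, else drop) then classify and harmonize
#' alleles per [harmonize_pair()]. Output rows keep the input instrument
#' order. The attached log accounts for every input instrument exactly once
#' (used / proxied / dropped-with-reason).
#'
#' @param instruments An `instrument_set` or `summary_stats` table for the
#'   exposure.
#' @param outcome The outcome [summary_stats()] table.
#' @param ld Optional [ld_table()] used for proxy lookup.
#' @param options List of policies: `palindrome_policy`, `eaf_ambiguity_band`,
#'   `proxy_min_r2` (defaults `"align_by_eaf"`, 0.08, 0.6).
#' @return A `harmonized_data` data frame with columns `rsid`,
#'   `beta_exposure`, `se_exposure`, `eaf_exposure`, `beta_outcome`,
#'   `se_outcome`, `eaf_outcome`, `action`, `palindromic`.
#' @export
harmonize_dataset <- function(instruments, outcome, ld = NULL,
                              options = list()) {
  stopifnot(inherits(instruments, "summary_stats"),
            inherits(outcome, "summary_stats"))
  if (nrow(instruments) == 0) stop("instrument set is empty")
  opt <- utils::modifyList(list(palindrome_policy = "align_by_eaf",
                                eaf_ambiguity_band = 0.08,
                                proxy_min_r2 = 0.6), options)
  exp_df <- as.data.frame(instruments)
  out_df <- as.data.frame(outcome)
  idx <- match(exp_df$rsid, out_df$rsid)
  present <- !is.na(idx)

  missing_rsids <- exp_df$rsid[!present]
  proxied <- data.frame(rsid = character(0), proxy_rsid = character(0),
                        r2 = numeric(0), stringsAsFactors = FALSE)
  dropped <- data.frame(rsid = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  # outcome-side fields aligned to exposure rows
  ocols <- data.frame(ea_y = rep(NA_character_, nrow(exp_df)),
                      oa_y = NA_character_, beta_y = NA_real_,
                      se_y = NA_real_, eaf_y = NA_real_,
                      proxy_rsid = NA_character_, stringsAsFactors = FALSE)
  ocols$ea_y[present] <- out_df$effect_allele[idx[present]]
  ocols$oa_y[present] <- out_df$other_allele[idx[present]]
  ocols$beta_y[present] <- out_df$beta[idx[present]]
  ocols$se_y[present] <- out_df$se[idx[present]]
  ocols$eaf_y[present] <- out_df$eaf[idx[present]]

  if (length(missing_rsids)) {
    if (is.null(ld)) {
      dropped <- rbind(dropped, data.frame(rsid = missing_rsids,
                                           reason = "no_outcome_record",
                                           stringsAsFactors = FALSE))
    } else {
      sub <- substitute_proxies(missing_rsids, ld, outcome,
                                min_r2 = opt$proxy_min_r2,
                                eaf_ambiguity_band = opt$eaf_ambiguity_band)
      dropped <- rbind(dropped, sub$dropped)
      if (nrow(sub$mapping)) for (i in seq_len(nrow(sub$mapping))) {
        m <- sub$mapping[i, ]
        row <- which(exp_df$rsid == m$rsid)
        tr <- translate_proxy(m, exp_df$effect_allele[row],
                              exp_df$other_allele[row], exp_df$eaf[row],
                              opt$eaf_ambiguity_band)
        if (is.null(tr)) {
          dropped <- rbind(dropped,
                           data.frame(rsid = m$rsid,
                                      reason = "proxy_unorientable",
                                      stringsAsFactors = FALSE))
          next
        }
        ocols$ea_y[row] <- tr$effect_allele
        ocols$oa_y[row] <- tr$other_allele
        ocols$beta_y[row] <- tr$beta
        ocols$se_y[row] <- tr$se
        ocols$eaf_y[row] <- tr$eaf
        ocols$proxy_rsid[row] <- m$proxy_rsid
        proxied <- rbind(proxied, data.frame(rsid = m$rsid,
                                             proxy_rsid = m$proxy_rsid,
                                             r2 = m$r2,
                                             stringsAsFactors = FALSE))
      }
    }
  }

  have <- !is.na(ocols$beta_y)
  df <- data.frame(rsid = exp_df$rsid,
                   ea_x = exp_df$effect_allele, oa_x = exp_df$other_allele,
                   beta_x = exp_df$beta, se_x = exp_df$se, eaf_x = exp_df$eaf,
                   stringsAsFactors = FALSE)[have, , drop = FALSE]
  df <- cbind(df, ocols[have, , drop = FALSE])
  h <- harmonize_core(df, opt$palindrome_policy, opt$eaf_ambiguity_band)
  bad <- !is.na(h$drop_reason)
  if (any(bad))
    dropped <- rbind(dropped, data.frame(rsid = h$rsid[bad],
                                         reason = h$drop_reason[bad],
                                         stringsAsFactors = FALSE))
  h <- h[!bad, , drop = FALSE]
  if (nrow(h) == 0) stop("no usable instruments after harmonization")

  action <- ifelse(is.na(h$proxy_rsid), h$action,
                   paste0("proxy:", h$proxy_rsid))
  out <- data.frame(rsid = h$rsid, beta_exposure = h$beta_x,
                    se_exposure = h$se_x, eaf_exposure = h$eaf_x,
                    beta_outcome = h$beta_y, se_outcome = h$se_y,
                    eaf_outcome = h$eaf_y, action = action,
                    palindromic = h$palindromic, stringsAsFactors = FALSE)
  disposition <- data.frame(
    rsid = c(out$rsid, dropped$rsid),
    status = c(ifelse(is.na(h$proxy_rsid), "used", "proxied"),
               rep("dropped", nrow(dropped))),
    detail = c(action, dropped$reason), stringsAsFactors = FALSE)
  disposition <- disposition[match(exp_df$rsid, disposition$rsid), , drop = FALSE]
  rownames(disposition) <- NULL
  log <- list(n_input = nrow(exp_df), n_retained = nrow(out),
              n_dropped = nrow(dropped),
              n_swapped = sum(h$action %in% c("swap", "swap_and_flip")),
              n_strand_flipped = sum(h$action %in%
                                       c("strand_flip", "swap_and_flip")),
              n_proxied = nrow(proxied), n_palindromic = sum(h$palindromic),
              proxied = proxied, dropped = dropped, disposition = disposition)
  new_harmonized_data(out,
                      direction_label = paste(attr(instruments, "trait_name"),
                                              "->", attr(outcome, "trait_name")),
                      exposure_trait = attr(instruments, "trait_name"),
                      outcome_trait = attr(outcome, "trait_name"),
                      outcome_trait_type = attr(outcome, "trait_type"),
                      log = log)
}

#' @export
print.harmonized_data <- function(x, ...) {
  log <- harmonization_log(x)
  cat(sprintf("Harmonized data: %s\n", attr(x, "direction_label")))
  cat(sprintf("  %d of %d instruments retained (%d proxied, %d dropped, %d effect-swapped)\n",
              log$n_retained, log$n_input, log$n_proxied, log$n_dropped,
              log$n_swapped))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Scatter of instrument effects with fitted MR lines
#'
#' Plots SNP-outcome against SNP-exposure effects (oriented to non-negative
#' exposure effects) with the IVW line through the origin and the MR-Egger
#' line with free intercept.
#'
#' @param x A `harmonized_data` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.harmonized_data <- function(x, ...) {
  s <- sign(x$beta_exposure)
  bx <- x$beta_exposure * s; by <- x$beta_outcome * s
  graphics::plot(bx, by, xlab = "SNP-exposure effect",
                 ylab = "SNP-outcome effect",
                 main = attr(x, "direction_label"), pch = 19,
                 col = "grey30", ...)
  ivw <- ivw_estimate(x)
  graphics::abline(0, ivw$beta, col = "firebrick", lwd = 2)
  if (nrow(x) >= 3) {
    eg <- egger_estimate(x)
    graphics::abline(eg$intercept, eg$beta, col = "steelblue", lwd = 2,
                     lty = 2)
    graphics::legend("topleft", legend = c("IVW", "MR-Egger"),
                     col = c("firebrick", "steelblue"), lty = c(1, 2),
                     lwd = 2, bty = "n")
  }
  invisible(x)
}
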