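#' Instrument selection and pruning
#'
#' An instrument set is a summary-statistics table restricted to the variants
#' used as instrumental variables, carrying a provenance log of every
#' selection step (threshold used, counts before/after, per-SNP exclusion
#' reasons).
#'
#' @name instruments
NULL

new_instrument_set <- function(df, trait_name, trait_type, unit, provenance) {
  structure(as.data.frame(df),
            trait_name = trait_name, trait_type = trait_type, unit = unit,
            rejected = attr(df, "rejected"),
            provenance = provenance,
            class = c("instrument_set", "summary_stats", "data.frame"))
}

#' Provenance log of an instrument set
#'
#' @param set An `instrument_set`.
#' @return List of selection steps, each with counts before/after and the
#'   dropped rsids with reasons.
#' @export
instrument_provenance <- function(set) attr(set, "provenance")

#' Select genome-wide-significant instruments
#'
#' Retains records with p-value strictly below `p_threshold`.
#'
#' @param table A [summary_stats()] table for the exposure trait.
#' @param p_threshold Significance threshold in (0, 1); conventional choices
#'   are 5e-8 and the stricter 1e-8.
#' @return An `instrument_set`.
#' @export
filter_genome_wide <- function(table, p_threshold = 1e-8) {
  stopifnot(inherits(table, "summary_stats"))
  if (!is.numeric(p_threshold) || length(p_threshold) != 1 ||
      p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must lie strictly inside (0,1)")
  keep <- table$p < p_threshold
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    warning("no SNP passes p < ", format(p_threshold), "; empty instrument set")
  step <- list(step = "p_threshold", threshold = p_threshold,
               n_before = nrow(table), n_after = nrow(out),
               dropped = data.frame(rsid = table$rsid[!keep],
                                    reason = rep(sprintf("p >= %g", p_threshold),
                                                 sum(!keep)),
                                    stringsAsFactors = FALSE))
  new_instrument_set(out, attr(table, "trait_name"), attr(table, "trait_type"),
                     attr(table, "unit"), provenance = list(step))
}

#' Prune instruments by LD and/or physical distance
#'
#' Greedy pruning in ascending p-value order (ties broken by chromosome then
#' position): a record is kept unless it violates (a) `r2 > r2_threshold`
#' with an already-kept record on the same chromosome within `window_bp`, or
#' (b) distance `< min_distance_bp` from an already-kept record on the same
#' chromosome. LD pairs absent from the table are treated as independent
#' (r2 = 0); this assumption is recorded in the provenance step, since
#' supplied LD tables are sparse by nature.
#'
#' @param set An `instrument_set`.
#' @param ld An [ld_table()]; may be `NULL` when only distance pruning is
#'   requested.
#' @param r2_threshold Maximum tolerated pairwise r2, or `NULL` to skip the
#'   LD rule.
#' @param window_bp Window (bp) within which the LD rule applies; `NULL`
#'   means any distance on the same chromosome.
#' @param min_distance_bp Minimum distance (bp) between kept records, or
#'   `NULL` to skip distance pruning.
#' @return The pruned `instrument_set`, with a provenance step logging every
#'   drop together with the kept partner and the rule violated.
#' @export
prune_instruments <- function(set, ld = NULL, r2_threshold = NULL,
                              window_bp = NULL, min_distance_bp = NULL) {
  stopifnot(inherits(set, "instrument_set"))
  if (is.null(r2_threshold) && is.null(min_distance_bp))
    stop("supply at least one of r2_threshold or min_distance_bp")
  if (!is.null(r2_threshold) &&
      (r2_threshold < 0 || r2_threshold > 1))
    stop("r2_threshold must lie in [0,1]")
  df <- as.data.frame(set)
  if (nrow(df) == 0) return(set)
  if (any(is.na(df$pos)) || any(is.na(df$chr)))
    stop("records must carry chromosome and position for pruning")
  ord <- order(df$p, df$chr, df$pos)
  kept_idx <- integer(0)
  drop_rsid <- character(0); drop_partner <- character(0); drop_rule <- character(0)
  missing_ld_pairs <- 0L
  win <- if (is.null(window_bp)) Inf else window_bp
  for (i in ord) {
    same_chr <- kept_idx[df$chr[kept_idx] == df$chr[i]]
    violated <- FALSE
    for (j in same_chr) {
      d <- abs(df$pos[i] - df$pos[j])
      if (!is.null(min_distance_bp) && d < min_distance_bp) {
        violated <- TRUE
        drop_rsid <- c(drop_rsid, df$rsid[i])
        drop_partner <- c(drop_partner, df$rsid[j])
        drop_rule <- c(drop_rule, sprintf("distance < %g bp", min_distance_bp))
        break
      }
      if (!is.null(r2_threshold) && d <= win) {
        r2 <- if (is.null(ld)) NA_real_ else ld_r2(ld, df$rsid[i], df$rsid[j])
        if (is.na(r2)) { missing_ld_pairs <- missing_ld_pairs + 1L; r2 <- 0 }
        if (r2 > r2_threshold) {
          violated <- TRUE
          drop_rsid <- c(drop_rsid, df$rsid[i])
          drop_partner <- c(drop_partner, df$rsid[j])
          drop_rule <- c(drop_rule, sprintf("r2 > %g within %g bp",
                                            r2_threshold, win))
          break
        }
      }
    }
    if (!violated) kept_idx <- c(kept_idx, i)
  }
  keep <- sort(kept_idx)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  step <- list(step = "prune",
               r2_threshold = r2_threshold, window_bp = window_bp,
               min_distance_bp = min_distance_bp,
               n_before = nrow(df), n_after = nrow(out),
               missing_ld_pairs_assumed_independent = missing_ld_pairs,
               dropped = data.frame(rsid = drop_rsid, kept_partner = drop_partner,
                                    reason = drop_rule, stringsAsFactors = FALSE))
  new_instrument_set(out, attr(set, "trait_name"), attr(set, "trait_type"),
                     attr(set, "unit"),
                     provenance = c(instrument_provenance(set), list(step)))
}

#' Exclude instruments annotated to potential confounders
#'
#' Drops every SNP carrying at least one annotation whose trait label matches
#' any of the supplied patterns. The default is case-insensitive substring
#' matching, since annotation trait labels are free text; exact matching is
#' available. SNPs absent from the annotation table are retained. The
#' filtered set feeds the "modified IVW" analysis.
#'
#' @param set An `instrument_set`.
#' @param annotations An [annotation_table()].
#' @param confounder_labels Non-empty character vector of trait-label
#'   patterns (e.g. `c("smoking", "education")`).
#' @param match `"substring"` (default) or `"exact"`; both case-insensitive.
#' @return The filtered `instrument_set`, with provenance listing dropped
#'   rsids and the labels that matched.
#' @export
exclude_confounded <- function(set, annotations, confounder_labels,
                               match = c("substring", "exact")) {
  stopifnot(inherits(set, "instrument_set"))
  match <- match.arg(match)
  if (length(confounder_labels) == 0)
    stop("confounder_labels must be non-empty")
  ann <- as.data.frame(annotations)
  hit <- rep(FALSE, nrow(ann))
  for (pat in confounder_labels) {
    hit <- hit | if (match == "substring")
      grepl(pat, ann$trait, ignore.case = TRUE, fixed = FALSE)
    else tolower(ann$trait) == tolower(pat)
  }
  bad <- ann[hit, , drop = FALSE]
  drop <- set$rsid %in% bad$rsid
  labels <- vapply(set$rsid[drop], function(r)
    paste(unique(bad$trait[bad$rsid == r]), collapse = "; "), character(1))
  out <- as.data.frame(set)[!drop, , drop = FALSE]
  rownames(out) <- NULL
  step <- list(step = "confounder_exclusion", patterns = confounder_labels,
               match = match, n_before = nrow(set), n_after = nrow(out),
               dropped = data.frame(rsid = set$rsid[drop],
                                    matched_labels = unname(labels),
                                    stringsAsFactors = FALSE))
  new_instrument_set(out, attr(set, "trait_name"), attr(set, "trait_type"),
                     attr(set, "unit"),
                     provenance = c(instrument_provenance(set), list(step)))
}

#' @export
print.instrument_set <- function(x, ...) {
  prov <- instrument_provenance(x)
  cat(sprintf("Instrument set for %s: %d SNPs after %d selection step(s)\n",
              attr(x, "trait_name"), nrow(x), length(prov)))
  for (s in prov)
    cat(sprintf("  %-22s %d -> %d\n", s$step, s$n_before, s$n_after))
  invisible(x)
}
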