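#' bimr: bidirectional two-sample Mendelian randomization
#'
#' Summary-statistic MR with instrument selection, harmonization (including
#' LD-proxy substitution and palindromic-variant resolution), five causal
#' estimators, instrument-strength diagnostics, analytic power, and a
#' synthetic two-sample GWAS generator with known ground truth.
#'
#' Positions are 1-based base-pair coordinates throughout, as in common GWAS
#' summary exports.
#'
#' @keywords internal
"_PACKAGE"

VALID_BASES <- c("A", "C", "G", "T")

# Native column set of the headered-TSV dialect.
NATIVE_COLUMNS <- c(rsid = "rsid", chr = "chr", pos = "pos",
                    effect_allele = "effect_allele",
                    other_allele = "other_allele",
                    eaf = "eaf", beta = "beta", se = "se", p = "p", n = "n")

MANDATORY_FIELDS <- c("rsid", "chr", "pos", "effect_allele", "other_allele",
                      "beta", "se", "p")

#' Describe the layout and trait metadata of a summary-statistics file
#'
#' GWAS summary files in the wild disagree on column names; a dialect maps
#' the file's headers onto the fields used internally and attaches the trait
#' metadata that the file itself does not carry.
#'
#' @param trait_name Name of the trait the file describes.
#' @param trait_type `"continuous"` or `"binary"` (effects are trait units
#'   per allele, respectively log-odds per allele).
#' @param unit Measurement unit of the trait (e.g. `"kg/m^2"`); informative
#'   only.
#' @param columns Named character vector/list mapping internal field names
#'   (`rsid`, `chr`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `p`, `n`) to the file's column headers. Defaults to the native
#'   headers (identical names). `eaf` and `n` are optional fields.
#' @return A list of class `"summary_dialect"`.
#' @export
summary_dialect <- function(trait_name, trait_type = c("continuous", "binary"),
                            unit = "", columns = NATIVE_COLUMNS) {
  trait_type <- match.arg(trait_type)
  columns <- as.list(columns)
  unknown <- setdiff(names(columns), names(NATIVE_COLUMNS))
  if (length(unknown))
    stop("unknown summary-statistics fields in dialect: ",
         paste(unknown, collapse = ", "))
  missing_map <- setdiff(MANDATORY_FIELDS, names(columns))
  if (length(missing_map))
    stop("dialect does not map mandatory fields: ",
         paste(missing_map, collapse = ", "))
  structure(list(trait_name = trait_name, trait_type = trait_type,
                 unit = unit, columns = columns),
            class = "summary_dialect")
}

#' Construct a validated summary-statistics table
#'
#' Rows violating the per-record invariants (single distinct A/C/G/T alleles,
#' `se > 0`, `p` in (0, 1], `eaf` strictly inside (0, 1) when present, finite
#' `beta`) are rejected; the rejections, with one reason string per row, are
#' kept in the `"rejected"` attribute. Allele letters are upper-cased.
#'
#' @param df Data frame with columns `rsid`, `chr`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `p` and optionally `eaf`, `n`.
#' @param trait_name,trait_type,unit Trait metadata (see [summary_dialect()]).
#' @return A data frame of class `"summary_stats"` with attributes
#'   `trait_name`, `trait_type`, `unit` and `rejected`.
#' @export
summary_stats <- function(df, trait_name, trait_type = c("continuous", "binary"),
                          unit = "") {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(MANDATORY_FIELDS, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_real_
  df <- df[, names(NATIVE_COLUMNS)]
  df$rsid <- as.character(df$rsid)
  df$chr <- as.character(df$chr)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "p", "n"))
    df[[col]] <- as.numeric(df[[col]])

  dup <- unique(df$rsid[duplicated(df$rsid)])
  if (length(dup))
    stop("duplicate rsid in summary statistics: ",
         paste(utils::head(dup, 5), collapse = ", "))

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  flag(!(df$effect_allele %in% VALID_BASES) |
         !(df$other_allele %in% VALID_BASES), "allele not one of A/C/G/T")
  flag(df$effect_allele == df$other_allele, "effect and other allele identical")
  flag(is.na(df$beta) | !is.finite(df$beta), "beta missing or non-finite")
  flag(is.na(df$se) | df$se <= 0, "se>0 violated")
  flag(is.na(df$p) | df$p <= 0 | df$p > 1, "p not in (0,1]")
  flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1),
       "eaf not strictly inside (0,1)")

  rejected <- data.frame(row = which(!is.na(reason)),
                         rsid = df$rsid[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  out <- df[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, trait_name = trait_name, trait_type = trait_type,
            unit = unit, rejected = rejected,
            class = c("summary_stats", "data.frame"))
}

#' Read GWAS summary statistics from a delimited file
#'
#' @param path Path to a tab-delimited, headered file.
#' @param dialect A [summary_dialect()] describing the column layout and the
#'   trait metadata.
#' @inherit summary_stats return
#' @export
read_summary_stats <- function(path, dialect) {
  if (!inherits(dialect, "summary_dialect"))
    stop("`dialect` must be created with summary_dialect()")
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  absent <- setdiff(unlist(dialect$columns[MANDATORY_FIELDS]), names(raw))
  if (length(absent))
    stop("file lacks mapped column(s): ", paste(absent, collapse = ", "))
  cols <- list()
  for (field in names(dialect$columns)) {
    src <- dialect$columns[[field]]
    if (src %in% names(raw)) cols[[field]] <- raw[[src]]
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  summary_stats(df, trait_name = dialect$trait_name,
                trait_type = dialect$trait_type, unit = dialect$unit)
}

# Format numerics at 17 significant digits so a write/read round trip
# reproduces doubles bit-exactly.
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a summary-statistics table as headered TSV
#'
#' Numeric fields are written at full double precision so that reading the
#' file back reproduces every value bit-exactly.
#'
#' @param x A `summary_stats` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "summary_stats"))
  df <- as.data.frame(x)
  for (col in c("pos", "eaf", "beta", "se", "p", "n"))
    df[[col]] <- .fmt_num(df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("Summary statistics: %s (%s%s), %d SNPs (%d rejected on read)\n",
              attr(x, "trait_name"), attr(x, "trait_type"),
              if (nzchar(attr(x, "unit"))) paste0(", ", attr(x, "unit")) else "",
              nrow(x), nrow(attr(x, "rejected"))))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Construct a pairwise LD table
#'
#' Lookup is symmetric in the two variants and self-pairs have r2 = 1.
#' The optional phase columns record which allele of `rsid_b` tags which
#' allele of `rsid_a` (for aligning proxy effect alleles).
#'
#' @param entries Data frame with columns `rsid_a`, `rsid_b`, `r2` and
#'   optionally `allele_a`, `allele_b` (the phase map).
#' @return An object of class `"ld_table"`.
#' @export
ld_table <- function(entries) {
  need <- c("rsid_a", "rsid_b", "r2")
  if (!all(need %in% names(entries)))
    stop("LD table needs columns rsid_a, rsid_b, r2")
  entries$rsid_a <- as.character(entries$rsid_a)
  entries$rsid_b <- as.character(entries$rsid_b)
  entries$r2 <- as.numeric(entries$r2)
  if (any(is.na(entries$r2) | entries$r2 < 0 | entries$r2 > 1))
    stop("r2 outside [0,1] in LD table")
  if (!"allele_a" %in% names(entries)) entries$allele_a <- NA_character_
  if (!"allele_b" %in% names(entries)) entries$allele_b <- NA_character_
  entries$allele_a <- toupper(as.character(entries$allele_a))
  entries$allele_b <- toupper(as.character(entries$allele_b))
  rownames(entries) <- NULL
  structure(list(entries = entries), class = "ld_table")
}

#' Read a pairwise LD table from a delimited file
#'
#' @param path Tab-delimited, headered file with columns `rsid_a`, `rsid_b`,
#'   `r2` and optionally `allele_a`, `allele_b`.
#' @inherit ld_table return
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ld_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Query pairwise r2
#'
#' Symmetric in `(a, b)`; a self-pair returns 1; an absent pair returns `NA`.
#'
#' @param ld An [ld_table()].
#' @param a,b rsids.
#' @return Numeric r2 (or `NA` when the pair is not recorded).
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_table"))
  if (a == b) return(1)
  e <- ld$entries
  hit <- (e$rsid_a == a & e$rsid_b == b) | (e$rsid_a == b & e$rsid_b == a)
  if (!any(hit)) return(NA_real_)
  max(e$r2[hit])
}

# All LD partners of `rsid`, with the phase map oriented so allele_index is
# the allele of `rsid` tagged by allele_proxy of the partner.
ld_partners <- function(ld, rsid) {
  e <- ld$entries
  fwd <- e[e$rsid_a == rsid & e$rsid_b != rsid, , drop = FALSE]
  rev <- e[e$rsid_b == rsid & e$rsid_a != rsid, , drop = FALSE]
  data.frame(
    proxy = c(fwd$rsid_b, rev$rsid_a),
    r2 = c(fwd$r2, rev$r2),
    allele_index = c(fwd$allele_a, rev$allele_b),
    allele_proxy = c(fwd$allele_b, rev$allele_a),
    stringsAsFactors = FALSE)
}

#' Construct a SNP-to-trait annotation table
#'
#' One row per published association; rsids may repeat.
#'
#' @param records Data frame with columns `rsid`, `trait` and optionally
#'   `source`.
#' @return An object of class `"annotation_table"`.
#' @export
annotation_table <- function(records) {
  if (!all(c("rsid", "trait") %in% names(records)))
    stop("annotation table needs columns rsid, trait")
  records$rsid <- as.character(records$rsid)
  records$trait <- as.character(records$trait)
  if (!"source" %in% names(records))
    records$source <- rep(NA_character_, nrow(records))
  rownames(records) <- NULL
  structure(records, class = c("annotation_table", "data.frame"))
}

#' Read a SNP-to-trait annotation table (PhenoScanner-style export)
#'
#' @param path Tab-delimited, headered file with columns `rsid`, `trait` and
#'   optionally `source`.
#' @inherit annotation_table return
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  annotation_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write the MR report
#'
#' Emits a machine-readable TSV (one row per method, OR columns populated by
#' exponentiating log-odds estimates for binary outcomes) and a human-readable
#' text table with one block per direction, mirroring the usual two-block
#' summary layout of MR studies (OR block for a binary outcome, beta block
#' for a continuous outcome).
#'
#' @param estimates Data frame of estimates as returned by
#'   [run_estimator_suite()], optionally with a `direction` column.
#' @param path_prefix Path prefix; `<prefix>_estimates.tsv` and
#'   `<prefix>_report.txt` are written (plus `<prefix>_harmonization.tsv`
#'   when a log is supplied).
#' @param diagnostics Optional [mr_diagnostics()] result (or a named list of
#'   them, one per direction).
#' @param harmonization_log Optional harmonization action log (data frame
#'   with columns `rsid`, `action`, `reason`).
#' @return Character vector of files written, invisibly.
#' @export
write_mr_report <- function(estimates, path_prefix, diagnostics = NULL,
                            harmonization_log = NULL) {
  if (is.null(estimates) || nrow(estimates) == 0)
    stop("at least one estimate is required")
  est <- as.data.frame(estimates)
  if (!"direction" %in% names(est)) est$direction <- "direction 1"
  tsv <- paste0(path_prefix, "_estimates.tsv")
  out <- est
  for (col in names(out))
    if (is.numeric(out[[col]])) out[[col]] <- .fmt_num(out[[col]])
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  files <- tsv

  txt <- paste0(path_prefix, "_report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines("Mendelian randomization summary", con)
  writeLines(strrep("=", 60), con)
  for (dir in unique(est$direction)) {
    blk <- est[est$direction == dir, , drop = FALSE]
    writeLines(c("", dir, strrep("-", 60)), con)
    binary <- any(!is.na(blk$or))
    for (i in seq_len(nrow(blk))) {
      r <- blk[i, ]
      if (!is.na(r$status) && r$status != "ok") {
        writeLines(sprintf("  %-22s %s", r$method, r$status), con)
        next
      }
      if (binary) {
        writeLines(sprintf("  %-22s OR %5.2f (%.2f to %.2f)  p = %.3g",
                           r$method, r$or, r$or_ci_low, r$or_ci_high,
                           r$p_value), con)
      } else {
        writeLines(sprintf("  %-22s beta %6.2f (%.2f to %.2f)  p = %.3g",
                           r$method, r$beta, r$ci_low, r$ci_high,
                           r$p_value), con)
      }
      if (identical(r$method, "egger") && !is.na(r$intercept))
        writeLines(sprintf("  %-22s intercept %.3f (se %.3f, p = %.3g)",
                           "", r$intercept, r$intercept_se, r$intercept_p),
                   con)
    }
    diag_i <- if (is.null(diagnostics)) NULL
      else if (inherits(diagnostics, "mr_diagnostics")) diagnostics
      else diagnostics[[dir]]
    writeLines("", con)
    if (is.null(diag_i)) {
      writeLines("  diagnostics: absent", con)
    } else {
      writeLines(sprintf(
        "  mean F = %.1f; NOME attenuation (F-1)/F = %.1f%%; I2_GX = %.1f%%",
        diag_i$mean_f, 100 * diag_i$attenuation,
        100 * ifelse(is.na(diag_i$i2_gx), NA, diag_i$i2_gx)), con)
    }
  }
  files <- c(files, txt)

  if (!is.null(harmonization_log)) {
    htsv <- paste0(path_prefix, "_harmonization.tsv")
    utils::write.table(harmonization_log, htsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    files <- c(files, htsv)
  }
  invisible(files)
}
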