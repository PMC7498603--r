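#' Bidirectional analysis pipeline
#'
#' Orchestrates the full bidirectional MR analysis from one configuration:
#' instrument selection, harmonization with proxy substitution, the
#' estimator suite (including the modified IVW on the confounder-excluded
#' set), instrument-strength diagnostics, pruning-ladder sensitivity reruns,
#' and power evaluation, with a consolidated report bundle and logs.
#'
#' @name pipeline
NULL

resolve_summary_stats <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "summary_stats")) return(x)
  if (is.list(x) && !is.null(x$path)) {
    d <- x$dialect
    dialect <- summary_dialect(
      trait_name = d$trait_name,
      trait_type = if (is.null(d$trait_type)) "continuous" else d$trait_type,
      unit = if (is.null(d$unit)) "" else d$unit,
      columns = if (is.null(d$columns)) NATIVE_COLUMNS else d$columns)
    return(read_summary_stats(x$path, dialect))
  }
  stop("cannot interpret summary-statistics entry; supply a summary_stats ",
       "object or a list(path=, dialect=)")
}

resolve_ld <- function(x) {
  if (is.null(x) || inherits(x, "ld_table")) return(x)
  if (is.character(x)) return(read_ld_table(x))
  stop("cannot interpret LD entry")
}

resolve_annotations <- function(x) {
  if (is.null(x) || inherits(x, "annotation_table")) return(x)
  if (is.character(x)) return(read_annotations(x))
  stop("cannot interpret annotation entry")
}

#' Read an analysis configuration from YAML
#'
#' The YAML mirrors the list accepted by [run_bidirectional_mr()]:
#' a `directions` map (each with `exposure`/`outcome` file entries carrying
#' `path` and `dialect`, optional `ld`, `annotations`, `p_threshold`,
#' `confounders`, `pruning_ladder`), shared `options`, optional `power`
#' specs, and `out_dir`.
#'
#' @param path Path to a YAML file.
#' @return Configuration list.
#' @export
read_analysis_config <- function(path) yaml::read_yaml(path)

run_one_direction <- function(dircfg, label, opts) {
  exposure <- resolve_summary_stats(dircfg$exposure)
  outcome <- resolve_summary_stats(dircfg$outcome)
  ld <- resolve_ld(dircfg$ld)
  ann <- resolve_annotations(dircfg$annotations)
  p_thr <- if (is.null(dircfg$p_threshold)) 1e-8 else dircfg$p_threshold

  instruments <- filter_genome_wide(exposure, p_thr)
  hopts <- opts[c("palindrome_policy", "eaf_ambiguity_band", "proxy_min_r2")]
  harmonized <- harmonize_dataset(instruments, outcome, ld, hopts)

  filtered <- NULL
  if (!is.null(ann) && length(dircfg$confounders)) {
    fset <- exclude_confounded(instruments, ann, dircfg$confounders)
    filtered <- tryCatch(harmonize_dataset(fset, outcome, ld, hopts),
                         error = function(e) NULL)
  }
  estimates <- run_estimator_suite(harmonized, filtered, config = opts)
  diagnostics <- mr_diagnostics(harmonized)

  ladder <- NULL
  if (length(dircfg$pruning_ladder)) {
    rows <- lapply(dircfg$pruning_ladder, function(stp) {
      setting <- paste(
        c(if (!is.null(stp$r2_threshold)) sprintf("r2<=%g", stp$r2_threshold),
          if (!is.null(stp$window_bp)) sprintf("window %g bp", stp$window_bp),
          if (!is.null(stp$min_distance_bp))
            sprintf("distance >= %g bp", stp$min_distance_bp)),
        collapse = ", ")
      pruned <- prune_instruments(instruments, ld,
                                  r2_threshold = stp$r2_threshold,
                                  window_bp = stp$window_bp,
                                  min_distance_bp = stp$min_distance_bp)
      sub <- harmonized[harmonized$rsid %in% pruned$rsid, , drop = FALSE]
      attributes(sub)[c("direction_label", "outcome_trait_type")] <-
        attributes(harmonized)[c("direction_label", "outcome_trait_type")]
      class(sub) <- class(harmonized)
      est <- ivw_estimate(sub, opts$effects_model, opts$se_order)
      cbind(setting = setting, est, stringsAsFactors = FALSE)
    })
    ladder <- do.call(rbind, rows)
    rownames(ladder) <- NULL
  }
  list(label = label, estimates = estimates, diagnostics = diagnostics,
       ladder = ladder, harmonization = harmonization_log(harmonized),
       provenance = instrument_provenance(instruments),
       n_instruments = nrow(instruments), harmonized = harmonized,
       error = NULL)
}

#' Run the bidirectional MR analysis
#'
#' For each configured direction: select instruments at the direction's
#' p-value threshold, harmonize against the outcome table (with LD-proxy
#' substitution), run the estimator suite (modified IVW on the
#' confounder-excluded set when annotations are supplied), compute
#' diagnostics, re-estimate IVW over each pruning-ladder step, and evaluate
#' any power specs. A failing direction is reported as such; the other
#' direction still completes. When `config$out_dir` is set the bundle is
#' written as TSV + text report + JSON sidecar of all counts.
#'
#' @param config Configuration list (see [read_analysis_config()]) or a
#'   path to a YAML file.
#' @return A list of class `"mr_report_bundle"`: per-direction results
#'   (`estimates`, `diagnostics`, `ladder`, `harmonization`, `provenance`),
#'   a `power` table, and the echoed `config`.
#' @export
run_bidirectional_mr <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  opts <- utils::modifyList(
    list(palindrome_policy = "align_by_eaf", eaf_ambiguity_band = 0.08,
         proxy_min_r2 = 0.6, effects_model = "multiplicative_random",
         se_order = "first", n_boot = 1000, seed = 42),
    if (is.null(config$options)) list() else config$options)
  if (is.null(config$directions) || !length(config$directions))
    stop("config$directions must name at least one direction")

  directions <- lapply(names(config$directions), function(lab)
    tryCatch(run_one_direction(config$directions[[lab]], lab, opts),
             error = function(e)
               list(label = lab, error = conditionMessage(e))))
  names(directions) <- names(config$directions)

  power <- NULL
  if (length(config$power)) {
    rows <- lapply(seq_along(config$power), function(i) {
      ps <- config$power[[i]]
      lab <- if (!is.null(ps$label)) ps$label else sprintf("power_%d", i)
      ps$label <- NULL
      spec <- do.call(power_spec, ps)
      pw <- mr_power(spec)
      data.frame(label = lab, outcome_type = spec$outcome_type, n = spec$n,
                 r2_xz = spec$r2_xz, effect = spec$effect,
                 alpha = spec$alpha, ncp = attr(pw, "ncp"),
                 power = as.numeric(pw), stringsAsFactors = FALSE)
    })
    power <- do.call(rbind, rows)
  }

  bundle <- structure(list(directions = directions, power = power,
                           config = config, options = opts),
                      class = "mr_report_bundle")
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' Emits the estimates TSV, the human-readable report text, per-direction
#' harmonization logs, the pruning-ladder table, the power table, and a
#' machine-readable JSON sidecar of all counts.
#'
#' @param bundle An `mr_report_bundle`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- Filter(function(d) is.null(d$error), bundle$directions)
  if (length(ok)) {
    est <- do.call(rbind, lapply(ok, function(d)
      cbind(direction = d$label, as.data.frame(d$estimates),
            stringsAsFactors = FALSE)))
    diags <- lapply(ok, function(d) d$diagnostics)
    names(diags) <- vapply(ok, function(d) d$label, character(1))
    hlog <- do.call(rbind, lapply(ok, function(d)
      cbind(direction = d$label, d$harmonization$disposition,
            stringsAsFactors = FALSE)))
    write_mr_report(est, file.path(out_dir, "mr"), diagnostics = diags,
                    harmonization_log = hlog)
    ladders <- Filter(Negate(is.null), lapply(ok, function(d)
      if (!is.null(d$ladder)) cbind(direction = d$label, d$ladder)))
    if (length(ladders))
      utils::write.table(do.call(rbind, ladders),
                         file.path(out_dir, "mr_pruning_ladder.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$power))
    utils::write.table(bundle$power, file.path(out_dir, "mr_power.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- lapply(bundle$directions, function(d) {
    if (!is.null(d$error)) return(list(error = d$error))
    h <- d$harmonization
    list(n_instruments = d$n_instruments, n_retained = h$n_retained,
         n_proxied = h$n_proxied, n_dropped = h$n_dropped,
         n_swapped = h$n_swapped, n_palindromic = h$n_palindromic)
  })
  jsonlite::write_json(counts, file.path(out_dir, "mr_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.mr_report_bundle <- function(x, ...) {
  cat("Bidirectional MR report bundle\n")
  for (d in x$directions) {
    cat("\n== direction:", d$label, "==\n")
    if (!is.null(d$error)) {
      cat("  FAILED:", d$error, "\n")
      next
    }
    h <- d$harmonization
    cat(sprintf("  %d instruments; %d harmonized (%d proxied, %d dropped)\n",
                d$n_instruments, h$n_retained, h$n_proxied, h$n_dropped))
    print(d$estimates)
    print(d$diagnostics)
    if (!is.null(d$ladder)) {
      cat("  pruning-ladder IVW reruns:\n")
      print(format(as.data.frame(d$ladder)[, c("setting", "n_snps", "beta",
                                               "se", "p_value")],
                   digits = 3), row.names = FALSE)
    }
  }
  if (!is.null(x$power)) {
    cat("\n== power ==\n")
    print(format(x$power, digits = 3), row.names = FALSE)
  }
  invisible(x)
}
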