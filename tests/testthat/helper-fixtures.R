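# fixtures built in code: tiny summary-stat tables and harmonized datasets

toy_summary_df <- function(n = 3, beta = seq(0.05, by = 0.01, length.out = n),
                           se = rep(0.01, n), p = rep(1e-10, n),
                           eaf = seq(0.2, 0.4, length.out = n),
                           chr = rep("1", n),
                           pos = seq(1e6, by = 1e6, length.out = n),
                           ea = rep("A", n), oa = rep("G", n)) {
  data.frame(rsid = sprintf("rs%d", seq_len(n)), chr = chr, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta,
             se = se, p = p, n = 1e5, stringsAsFactors = FALSE)
}

toy_summary_stats <- function(..., trait_name = "trait",
                              trait_type = "continuous", unit = "") {
  summary_stats(toy_summary_df(...), trait_name, trait_type, unit)
}

# construct a harmonized_data object directly from effect vectors
make_harmonized <- function(bx, sx, by, sy, binary = FALSE,
                            rsid = sprintf("rs%d", seq_along(bx))) {
  df <- data.frame(rsid = rsid, beta_exposure = bx, se_exposure = sx,
                   beta_outcome = by, se_outcome = sy,
                   eaf_exposure = 0.3, eaf_outcome = 0.3,
                   action = "none", palindromic = FALSE,
                   stringsAsFactors = FALSE)
  structure(df, direction_label = "test",
            exposure_trait = "X", outcome_trait = "Y",
            outcome_trait_type = if (binary) "binary" else "continuous",
            log = list(n_input = length(bx), n_retained = length(bx),
                       n_dropped = 0),
            class = c("harmonized_data", "data.frame"))
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
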