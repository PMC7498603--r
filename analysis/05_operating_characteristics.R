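#!/usr/bin/env Rscript
# Operating characteristics of the estimators over replicated synthetic
# scenarios: type-I error under the null, parameter recovery on the
# 941-instrument design, and the directional-pleiotropy benchmark in which
# MR-Egger stays consistent while IVW is biased. Replicate counts are kept
# moderate here so the script runs in about two minutes; the full-size runs
# live in the test suite. Writes results/operating_characteristics/.

library(bimr)

out_dir <- "results/operating_characteristics"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cat("Type-I error (null scenario, 500 replicates):\n")
oc_null <- evaluate_operating_characteristics(make_scenario("null"),
                                              n_reps = 500, methods = "ivw",
                                              seed = 1)
print(oc_null[, c("method", "rejection_rate", "coverage")], row.names = FALSE)

cat("\nRecovery of log(1.08) on the 941-instrument design (100 replicates):\n")
oc_fwd <- evaluate_operating_characteristics(
  make_scenario("bmi_to_ad_like"), n_reps = 100,
  methods = c("ivw", "max_likelihood", "weighted_median"), seed = 2,
  config = list(n_boot = 100))
print(oc_fwd[, c("method", "true_beta", "mean_estimate", "bias",
                 "empirical_se", "coverage")], row.names = FALSE)

cat("\nDirectional pleiotropy benchmark (150 replicates):\n")
oc_dir <- evaluate_operating_characteristics(
  make_scenario("directional_pleiotropy"), n_reps = 150,
  methods = c("ivw", "egger"), seed = 3)
print(oc_dir[, c("method", "true_beta", "mean_estimate", "bias",
                 "coverage")], row.names = FALSE)
cat("\nIVW absorbs the directional pleiotropy into its slope; the Egger\n")
cat("intercept soaks it up and the Egger slope stays on the truth.\n")

for (nm in c("oc_null", "oc_fwd", "oc_dir")) {
  obj <- get(nm)
  attr(obj, "estimates") <- NULL
  write.table(obj, file.path(out_dir, paste0(nm, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
cat("\nTables written under results/operating_characteristics/.\n")
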