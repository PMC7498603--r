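# independent oracle: enumerate the four presentation transforms of the
# exposure pair and see which reproduces the outcome pair
oracle_classify <- function(ea, oa, eb, ob) {
  comp <- function(x) chartr("ACGT", "TGCA", x)
  cands <- list(match = c(ea, oa), swap = c(oa, ea),
                strand_flip = comp(c(ea, oa)), swap_and_flip = comp(c(oa, ea)))
  hits <- names(cands)[vapply(cands, function(p)
    identical(p, c(eb, ob)), logical(1))]
  if (length(hits) == 0) return("incompatible")
  if (oa == comp(ea)) return("palindromic_ambiguous")
  hits[1]
}

test_that("allele classification agrees with brute-force enumeration", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(ea = bases, oa = bases, eb = bases, ob = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ea != grid$oa & grid$eb != grid$ob, ]
  got <- classify_alleles(grid$ea, grid$oa, grid$eb, grid$ob)
  want <- mapply(oracle_classify, grid$ea, grid$oa, grid$eb, grid$ob)
  expect_identical(unname(got), unname(want))
  # for a non-palindromic exposure pair the matching transform is unique
  nonpal <- grid$oa != chartr("ACGT", "TGCA", grid$ea)
  n_hits <- mapply(function(ea, oa, eb, ob) {
    comp <- function(x) chartr("ACGT", "TGCA", x)
    sum(vapply(list(c(ea, oa), c(oa, ea), comp(c(ea, oa)), comp(c(oa, ea))),
               identical, logical(1), y = c(eb, ob)))
  }, grid$ea[nonpal], grid$oa[nonpal], grid$eb[nonpal], grid$ob[nonpal])
  expect_true(all(n_hits <= 1))
  expect_error(classify_alleles("A", "G", "N", "T"), "A/C/G/T")
})

snp <- function(rsid = "rs1", ea = "A", oa = "G", beta = 0.05, se = 0.01,
                eaf = 0.3)
  list(rsid = rsid, effect_allele = ea, other_allele = oa, beta = beta,
       se = se, eaf = eaf)

test_that("pairwise harmonization swaps, flips and preserves magnitudes", {
  # identical alleles: untouched
  h <- harmonize_pair(snp(), snp(beta = 0.02, se = 0.004))
  expect_identical(h$action, "none")
  expect_equal(h$beta_outcome, 0.02)

  # swapped alleles: effect and frequency switch direction
  h <- harmonize_pair(snp(), snp(ea = "G", oa = "A", beta = 0.02, eaf = 0.3))
  expect_identical(h$action, "swap")
  expect_equal(h$beta_outcome, -0.02)
  expect_equal(h$eaf_outcome, 0.7)
  expect_equal(h$se_outcome, 0.01)   # SEs are never altered

  # strand flip: complemented labels, effect unchanged
  h <- harmonize_pair(snp(), snp(ea = "T", oa = "C", beta = 0.02))
  expect_identical(h$action, "strand_flip")
  expect_equal(h$beta_outcome, 0.02)

  # swap + flip
  h <- harmonize_pair(snp(), snp(ea = "C", oa = "T", beta = 0.02, eaf = 0.25))
  expect_identical(h$action, "swap_and_flip")
  expect_equal(h$beta_outcome, -0.02)
  expect_equal(h$eaf_outcome, 0.75)

  # incompatible pairs are dropped with a reason
  h <- harmonize_pair(snp(), snp(ea = "A", oa = "C", beta = 0.02))
  expect_identical(h$drop_reason, "incompatible")
  expect_error(harmonize_pair(snp(), snp(rsid = "rs2")), "same rsid")
})

test_that("palindromic variants are resolved by frequency agreement", {
  pal_exp <- snp(ea = "A", oa = "T", eaf = 0.10)
  # frequencies on the same side: same orientation
  h <- harmonize_pair(pal_exp, snp(ea = "A", oa = "T", beta = 0.02, eaf = 0.12))
  expect_true(h$palindromic)
  expect_true(is.na(h$drop_reason))
  expect_equal(h$beta_outcome, 0.02)
  # opposite sides: the outcome record is on the other strand => sign flip
  h <- harmonize_pair(pal_exp, snp(ea = "A", oa = "T", beta = 0.02, eaf = 0.88))
  expect_equal(h$beta_outcome, -0.02)
  expect_equal(h$eaf_outcome, 0.12)
  # frequency in the ambiguity band: dropped
  h <- harmonize_pair(pal_exp, snp(ea = "A", oa = "T", beta = 0.02, eaf = 0.46))
  expect_identical(h$drop_reason, "palindromic_ambiguous_eaf")
  # absent frequency under align_by_eaf: dropped
  h <- harmonize_pair(pal_exp, snp(ea = "A", oa = "T", beta = 0.02, eaf = NA))
  expect_identical(h$drop_reason, "palindromic_no_eaf")
  # drop policy removes palindromic variants outright
  h <- harmonize_pair(pal_exp, snp(ea = "A", oa = "T", beta = 0.02, eaf = 0.12),
                      palindrome_policy = "drop")
  expect_identical(h$drop_reason, "palindromic")
  # keep policy retains the nominal orientation
  h <- harmonize_pair(pal_exp, snp(ea = "T", oa = "A", beta = 0.02, eaf = 0.88),
                      palindrome_policy = "keep")
  expect_equal(h$beta_outcome, -0.02)
})

test_that("palindromic resolution matches the orientation-hypothesis oracle", {
  # brute force: of the four (swap, strand) hypotheses, the eaf-consistent
  # ones determine the sign applied to the outcome effect
  set.seed(7)
  for (i in 1:200) {
    maf <- runif(1, 0.05, 0.40)
    swapped <- runif(1) < 0.5
    flipped <- runif(1) < 0.5
    beta_y <- rnorm(1)
    # presented record after the true (swap, flip) transformations
    eaf_pres <- if (swapped) 1 - maf else maf
    beta_pres <- if (swapped) -beta_y else beta_y
    ea_pres <- if (swapped) "T" else "A"  # flip of A/T relabels the same pair
    if (flipped) ea_pres <- chartr("AT", "TA", ea_pres)
    h <- harmonize_pair(snp(ea = "A", oa = "T", eaf = maf),
                        snp(ea = ea_pres,
                            oa = chartr("AT", "TA", ea_pres),
                            beta = beta_pres, eaf = eaf_pres))
    expect_true(is.na(h$drop_reason))
    expect_equal(h$beta_outcome, beta_y)
    expect_equal(h$eaf_outcome, maf)
  }
})

test_that("proxy choice maximizes r2 above the floor with stable ties", {
  outcome <- toy_summary_stats(3, beta = c(0.01, 0.02, 0.03),
                               ea = c("A", "C", "A"), oa = c("G", "T", "C"))
  ld <- ld_table(data.frame(
    rsid_a = c("rsX", "rsX", "rsY", "rsZ"),
    rsid_b = c("rs1", "rs2", "rs3", "rs1"),
    r2 = c(0.9, 0.8, 0.5, 1.0),
    allele_a = c("A", "A", "A", "A"),
    allele_b = c("A", "C", "A", "G")))
  sub <- substitute_proxies(c("rsX", "rsY", "rsW"), ld, outcome, min_r2 = 0.6)
  expect_identical(sub$mapping$proxy_rsid, "rs1")       # 0.9 beats 0.8
  expect_equal(sub$mapping$r2, 0.9)
  expect_setequal(sub$dropped$rsid, c("rsY", "rsW"))    # 0.5 < 0.6; no entry
  expect_true(all(sub$dropped$reason == "no_proxy"))

  # exact r2 tie: lexicographically smallest proxy rsid wins
  ld2 <- ld_table(data.frame(rsid_a = c("rsX", "rsX"),
                             rsid_b = c("rs2", "rs1"), r2 = c(0.8, 0.8),
                             allele_a = "A", allele_b = c("C", "A")))
  sub2 <- substitute_proxies("rsX", ld2, outcome, min_r2 = 0.6)
  expect_identical(sub2$mapping$proxy_rsid, "rs1")

  # no phase map and a palindromic/eaf-ambiguous proxy: dropped with reason
  out_pal <- toy_summary_stats(1, ea = "A", oa = "T", eaf = 0.5)
  ld3 <- ld_table(data.frame(rsid_a = "rsX", rsid_b = "rs1", r2 = 0.9))
  sub3 <- substitute_proxies("rsX", ld3, out_pal, min_r2 = 0.6)
  expect_identical(sub3$dropped$reason, "proxy_unorientable")
})

test_that("dataset harmonization proxies missing SNPs and accounts for all", {
  exp_tab <- toy_summary_stats(4, beta = c(0.05, 0.06, 0.04, 0.05))
  # outcome lacks rs2 (proxied via rsP) and rs4 (unproxiable)
  out_df <- toy_summary_df(4, beta = c(0.01, 0.012, 0.009, 0.011))
  out_df <- out_df[c(1, 3), ]
  out_df <- rbind(out_df, data.frame(rsid = "rsP", chr = "1", pos = 2.1e6,
                                     effect_allele = "C", other_allele = "T",
                                     eaf = 0.25, beta = -0.012, se = 0.01,
                                     p = 0.02, n = 1e5))
  outcome <- summary_stats(out_df, "Y")
  ld <- ld_table(data.frame(rsid_a = "rs2", rsid_b = "rsP", r2 = 0.9,
                            allele_a = "A", allele_b = "T"))
  h <- harmonize_dataset(filter_genome_wide(exp_tab, 1e-6), outcome, ld)
  log <- harmonization_log(h)
  expect_equal(log$n_retained, 3)
  expect_equal(log$n_proxied, 1)
  expect_equal(log$n_dropped, 1)
  expect_identical(h$rsid, c("rs1", "rs2", "rs3"))      # input order kept
  # rsP's effect allele T tags rs2's other allele G => flipped onto A
  expect_identical(h$action[2], "proxy:rsP")
  expect_equal(h$beta_outcome[2], 0.012)
  expect_equal(h$eaf_outcome[2], 0.75)
  # disposition covers every input instrument exactly once
  expect_identical(log$disposition$rsid, exp_tab$rsid)
  expect_identical(log$disposition$status,
                   c("used", "proxied", "used", "dropped"))

  expect_error(harmonize_dataset(filter_genome_wide(exp_tab, 1e-6),
                                 summary_stats(toy_summary_df(1,
                                   ea = "C", oa = "A"), "Y")),
               "no usable instruments")
})

test_that("harmonization is an involution and magnitudes are invariant", {
  for (i in 1:200) {
    sc <- make_scenario("balanced_pleiotropy", n_snps = 25, seed = 5000 + i,
                        missing_outcome_fraction = 0)
    sim <- simulate_two_sample_gwas(sc)
    h1 <- harmonize_dataset(sim$exposure, sim$outcome)
    # pre-swap every outcome record: exchange alleles, negate beta, 1 - eaf
    od <- as.data.frame(sim$outcome)
    od[, c("effect_allele", "other_allele")] <-
      od[, c("other_allele", "effect_allele")]
    od$beta <- -od$beta
    od$eaf <- 1 - od$eaf
    out2 <- summary_stats(od, attr(sim$outcome, "trait_name"),
                          attr(sim$outcome, "trait_type"))
    h2 <- harmonize_dataset(sim$exposure, out2)
    num <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
    expect_identical(as.data.frame(h1)[num], as.data.frame(h2)[num])
    # frequencies agree to roundoff (1 - (1 - eaf) costs one ulp)
    expect_equal(h1$eaf_outcome, h2$eaf_outcome, tolerance = 1e-14)
    # magnitudes and SEs are those of the inputs
    expect_equal(sort(abs(h1$beta_outcome)), sort(abs(od$beta)))
    expect_identical(sort(h1$se_outcome), sort(od$se))
    # double harmonization is the identity
    hd <- as.data.frame(h1)
    again <- summary_stats(data.frame(
      rsid = hd$rsid, chr = "1", pos = seq_len(nrow(hd)),
      effect_allele = as.data.frame(sim$exposure)$effect_allele[
        match(hd$rsid, sim$exposure$rsid)],
      other_allele = as.data.frame(sim$exposure)$other_allele[
        match(hd$rsid, sim$exposure$rsid)],
      eaf = hd$eaf_outcome, beta = hd$beta_outcome, se = hd$se_outcome,
      p = 0.5, n = 1e5), "Y", attr(sim$outcome, "trait_type"))
    h3 <- harmonize_dataset(sim$exposure, again)
    expect_true(all(h3$action == "none"))
    expect_identical(h3$beta_outcome, h1$beta_outcome)
  }
})
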