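test_that("generated datasets have the configured scale and are seed-deterministic", {
  m <- build_model("3-dicho+mig")
  cfg <- synthetic_config(m, recovery_truth(), n_snps = 300, seed = 42)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$gm$geno, ds2$gm$geno)
  expect_identical(ds1$gm$coverage, ds2$gm$coverage)
  expect_equal(nrow(ds1$gm$geno), 300)
  # field sampling design: 3 + 4 + 8 sites, 3-4 diploids each
  expect_equal(length(unique(ds1$gm$sites)), 15)
  expect_equal(ncol(ds1$gm$geno), 11 + 16 + 30)
  expect_identical(ds1$truth$params, recovery_truth())
  ds3 <- generate_dataset(synthetic_config(m, recovery_truth(),
                                           n_snps = 300, seed = 43))
  expect_false(identical(ds1$gm$geno, ds3$gm$geno))
})

test_that("per-genotype missingness and coverage behave as configured", {
  m <- build_model("3-dicho")
  truth <- recovery_truth()[names(build_model("3-dicho")$params)]
  cfg <- synthetic_config(m, truth, n_snps = 2000, missing_rate = 0.2,
                          coverage_mean = 18, seed = 7)
  gm <- generate_dataset(cfg)$gm
  expect_equal(mean(is.na(gm$geno)), 0.2, tolerance = 0.01)
  expect_equal(mean(gm$coverage, na.rm = TRUE), 18, tolerance = 0.5)
  expect_true(all(is.na(gm$coverage[is.na(gm$geno)])))
  expect_true(all(!is.na(gm$coverage[!is.na(gm$geno)])))
})

test_that("a loss-free dataset passes the filters except undecidable-MAF SNPs", {
  m <- build_model("3-dicho")
  truth <- recovery_truth()[names(build_model("3-dicho")$params)]
  cfg <- synthetic_config(m, truth, n_snps = 500, missing_rate = 0,
                          coverage_mean = 60, seed = 13)
  gm <- generate_dataset(cfg)$gm
  red <- filter_reduced(gm)
  rej <- attr(red, "rejections")
  expect_true(all(rej$rule == "maf_half"))
  expect_equal(nrow(red$geno) + nrow(rej), 500)
})

test_that("total missingness empties the reduced dataset with a warning", {
  m <- build_model("3-dicho")
  truth <- recovery_truth()[names(build_model("3-dicho")$params)]
  cfg <- synthetic_config(m, truth, n_snps = 50, missing_rate = 1, seed = 2)
  gm <- generate_dataset(cfg)$gm
  expect_warning(red <- filter_reduced(gm), "no SNPs")
  expect_equal(nrow(red$geno), 0)
})

test_that("datasets round-trip through VCF + popmap unchanged", {
  m <- build_model("3-dicho+mig")
  cfg <- synthetic_config(m, recovery_truth(), n_snps = 120,
                          missing_rate = 0.1, seed = 31)
  ds <- generate_dataset(cfg)
  paths <- write_dataset(ds, tempdir(), prefix = "rt_test")
  gm2 <- read_vcf_genotypes(paths["vcf"], paths["popmap"])
  expect_identical(unname(gm2$geno), unname(ds$gm$geno))
  expect_identical(gm2$samples, ds$gm$samples)
  expect_identical(gm2$sites, ds$gm$sites)
  expect_identical(gm2$demes, ds$gm$demes)
  expect_identical(gm2$loci, ds$gm$loci)
  cov_match <- gm2$coverage == ds$gm$coverage
  expect_true(all(cov_match | is.na(cov_match)))
  # permissive thresholds keep every SNP: one SNP per locus already
  perm <- filter_thresholds(max_missing_fraction = 1, max_obs_het = 1,
                            min_coverage = 1, min_individuals_per_site = 1)
  kept <- select_random_snp_per_locus(gm2, max_snps = 10, seed = 1,
                                      th = perm)
  singletons <- attr(kept, "rejections")
  expect_equal(nrow(kept$geno) + nrow(singletons), 120)
})

test_that("pseudoreplicate spectra conserve totals and reproduce probabilities", {
  toy <- toy_two_deme(n1 = 4, n2 = 4, N1 = 4000, N2 = 4000,
                      t_merge = 6000, N_anc = 4000)
  ps <- pseudoreplicate_sfs(toy$model, toy$params, n_snps = 3000, seed = 6,
                            n_sims = 50000)
  expect_equal(sum(ps[[1]]$counts), 3000)
  ps2 <- pseudoreplicate_sfs(toy$model, toy$params, n_snps = 3000, seed = 6,
                             n_sims = 50000)
  expect_identical(ps, ps2)
  # large-sample relative frequencies match the generating distribution
  big <- pseudoreplicate_sfs(toy$model, toy$params, n_snps = 100000,
                             seed = 8, n_sims = 200000)[[1]]
  e <- expected_pair_sfs(toy$model, toy$params, 200000, seed = 8)[[1]]
  un <- !big$mask
  obs_p <- big$counts[un] / sum(big$counts[un])
  keep <- e$prob[un] > 0.005
  expect_lt(max(abs(obs_p[keep] - e$prob[un][keep])), 0.01)
  # direct per-SNP simulation also conserves totals
  sim <- pseudoreplicate_sfs(toy$model, toy$params, n_snps = 500, seed = 3,
                             method = "simulate")
  expect_equal(sum(sim[[1]]$counts) , 500)
})

test_that("site-level dropout stresses the presence filter beyond independent missingness", {
  m <- build_model("3-dicho")
  truth <- recovery_truth()[names(build_model("3-dicho")$params)]
  base <- generate_dataset(synthetic_config(m, truth, n_snps = 400,
                                            missing_rate = 0, seed = 3))$gm
  drop <- generate_dataset(synthetic_config(m, truth, n_snps = 400,
                                            missing_rate = 0,
                                            site_dropout_rate = 0.2,
                                            seed = 3))$gm
  expect_gt(mean(is.na(drop$geno)), mean(is.na(base$geno)))
  r_base <- suppressWarnings(filter_reduced(base))
  r_drop <- suppressWarnings(filter_reduced(drop))
  n_pres <- function(gm) sum(attr(gm, "rejections")$rule == "site_presence")
  expect_gt(n_pres(r_drop), n_pres(r_base))
  # dropped blocks are whole sites: every affected (SNP, site) pair is
  # either fully present or fully absent
  for (s in unique(drop$sites)) {
    sub <- drop$geno[, drop$sites == s, drop = FALSE]
    n_na <- rowSums(is.na(sub))
    expect_true(all(n_na == 0 | n_na == ncol(sub)))
  }
})
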