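# rows are SNPs, columns samples; 0 hom-ref, 1 het, 2 hom-alt, NA missing

test_that("per-SNP complete-dataset rules drop the intended genotypic patterns", {
  # 10 samples; each row violates exactly one rule (or none)
  g <- rbind(
    pass      = c(0, 0, 0, 1, 1, 2, 0, 0, 0, 0),
    het6of10  = c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0),   # Hobs = 0.6
    singleton = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1),   # alt in one individual
    boundary  = c(NA, NA, NA, NA, NA, 0, 0, 1, 1, 2)  # 50% missing, Hobs 0.4
  )
  gm <- tiny_gm(g)
  out <- filter_complete(gm, seed = 5)
  expect_setequal(sub(":.*", "", out$snp_ids), c("L1", "L4"))
  rej <- attr(out, "rejections")
  expect_equal(rej$rule[rej$snp == gm$snp_ids[2]], "heterozygosity")
  expect_equal(rej$rule[rej$snp == gm$snp_ids[3]], "singleton")
})

test_that("hom-alt singletons and 50% heterozygosity boundaries behave inclusively", {
  g <- rbind(
    hom_alt_single = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 2),  # minor allele, 1 carrier
    het_exactly_half = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), # Hobs = 0.5: retained
    two_carriers = c(0, 0, 0, 0, 0, 0, 0, 0, 1, 1)
  )
  out <- filter_complete(tiny_gm(g), seed = 1)
  expect_setequal(sub(":.*", "", out$snp_ids), c("L2", "L3"))
})

test_that("loci with more than max_snps SNPs are dropped entirely", {
  g <- matrix(rep(c(0, 0, 1, 1, 2, 0, 0, 0, 1, 0), 13), nrow = 13,
              byrow = TRUE)
  loci <- c(rep("big", 11), "small", "small")
  out <- select_random_snp_per_locus(tiny_gm(g, loci = loci), seed = 3)
  expect_equal(unique(out$loci), "small")
  expect_equal(nrow(out$geno), 1)
  rej <- attr(out, "rejections")
  expect_equal(sum(rej$rule == "locus_excess_snps"), 11)
})

test_that("a locus with one qualifying SNP keeps it for any seed", {
  g <- rbind(c(0, 0, 1, 1, 2, 0, 0, 0, 1, 0),
             c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1))  # second is a singleton
  gm <- tiny_gm(g, loci = c("L", "L"))
  for (s in c(1, 99, 123456))
    expect_equal(select_random_snp_per_locus(gm, seed = s)$snp_ids,
                 gm$snp_ids[1])
})

test_that("random SNP choice within a locus is uniform over seeds", {
  g <- matrix(rep(c(0, 0, 1, 1, 2, 0, 0, 0, 1, 0), 3), nrow = 3,
              byrow = TRUE)
  gm <- tiny_gm(g, loci = rep("L", 3))
  picks <- vapply(1:10000, function(s)
    select_random_snp_per_locus(gm, seed = s)$snp_ids, character(1))
  freq <- table(factor(picks, levels = gm$snp_ids)) / 10000
  expect_true(all(abs(freq - 1 / 3) <= 0.02))
})

test_that("missing locus annotation is a hard error naming the SNP", {
  g <- rbind(c(0, 1, 0, 2), c(0, 1, 1, 0))
  gm <- tiny_gm(g, sites = rep("s1", 4), demes = rep("A", 4),
                loci = c("L1", "L2"))
  gm$loci[2] <- NA
  expect_error(select_random_snp_per_locus(gm), gm$snp_ids[2])
})

test_that("reduced filter: coverage masking, per-site presence, exact-0.5 MAF", {
  sites <- rep(c("s1", "s2"), each = 4)
  g <- rbind(
    pass      = c(0, 1, 0, 0,  0, 0, 1, 0),
    low_cov   = c(0, 1, 0, 0,  0, 0, 1, 0),   # all depths 5
    one_at_s2 = c(0, 1, 0, 0,  2, NA, NA, NA),
    maf_half  = c(2, 2, 0, 0,  2, 2, 0, 0)    # 8 alt of 16 alleles
  )
  cov <- matrix(30, nrow(g), ncol(g))
  cov[2, ] <- 5
  cov[is.na(g)] <- NA
  gm <- tiny_gm(g, coverage = cov, sites = sites, demes = rep("A", 8))
  out <- filter_reduced(gm)
  expect_equal(sub(":.*", "", out$snp_ids), "L1")
  rej <- attr(out, "rejections")
  expect_equal(rej$rule[rej$snp == gm$snp_ids[2]], "coverage")
  expect_equal(rej$rule[rej$snp == gm$snp_ids[3]], "site_presence")
  expect_equal(rej$rule[rej$snp == gm$snp_ids[4]], "maf_half")
})

test_that("24 ref + 24 alt alleles over all calls is removed as undecidable", {
  g <- matrix(c(rep(1, 24), rep(NA, 0)), nrow = 1)  # 24 hets: 24 ref, 24 alt
  cov <- matrix(30, 1, 24)
  gm <- tiny_gm(g, coverage = cov, sites = rep(c("s1", "s2"), each = 12),
                demes = rep("A", 24))
  out <- suppressWarnings(filter_reduced(gm))
  expect_equal(nrow(out$geno), 0)
  expect_equal(attr(out, "rejections")$rule, "maf_half")
})

test_that("a site that can never satisfy the presence rule is a hard error", {
  g <- rbind(c(0, 1, 0))
  gm <- tiny_gm(g, coverage = matrix(30, 1, 3),
                sites = c("s1", "s1", "lonely"), demes = rep("A", 3))
  expect_error(filter_reduced(gm), "lonely")
})

test_that("filters are idempotent and preserve sample order and SNP subsetting", {
  set.seed(7)
  n_snp <- 60
  g <- matrix(sample(c(0L, 0L, 0L, 1L, 2L, NA), n_snp * 8, replace = TRUE),
              nrow = n_snp)
  cov <- matrix(rpois(n_snp * 8, 15), n_snp)
  cov[is.na(g)] <- NA
  gm <- tiny_gm(g, coverage = cov, sites = rep(c("s1", "s2"), each = 4),
                demes = rep("A", 8), loci = paste0("L", rep(1:20, 3)))
  c1 <- suppressWarnings(filter_complete(gm, seed = 2))
  c2 <- suppressWarnings(filter_complete(c1, seed = 9))
  expect_identical(c2$geno, c1$geno)        # second pass changes nothing
  r1 <- suppressWarnings(filter_reduced(c1))
  r2 <- suppressWarnings(filter_reduced(r1))
  expect_identical(r2$geno, r1$geno)
  expect_identical(r1$samples, gm$samples)  # sample order preserved
  expect_true(all(r1$snp_ids %in% c1$snp_ids))
  expect_true(all(c1$snp_ids %in% gm$snp_ids))
})

test_that("a matrix violating one rule per SNP is rejected for exactly those rules", {
  sites <- rep(c("s1", "s2"), each = 5)
  g <- rbind(
    keepers   = c(0, 1, 0, 0, 2,  0, 0, 1, 0, 0),
    missing60 = c(NA, NA, NA, NA, NA, NA, 0, 1, 1, 0),
    het_high  = c(1, 1, 1, 1, 1,  1, 1, 0, 0, 0),
    singleton = c(0, 0, 0, 0, 0,  0, 0, 0, 0, 1),
    presence  = c(0, 1, 0, 1, 0,  2, NA, NA, NA, NA),
    maf_half  = c(2, 2, 0, 1, 1,  2, 0, 0, 1, 1)
  )
  cov <- matrix(30, nrow(g), ncol(g))
  cov[is.na(g)] <- NA
  gm <- tiny_gm(g, coverage = cov, sites = sites, demes = rep("A", 10))
  comp <- filter_complete(gm, seed = 4)
  red <- filter_reduced(comp)
  rej <- attr(red, "rejections")
  lookup <- setNames(rej$rule, sub(":.*", "", rej$snp))
  expect_equal(unname(lookup[c("L2", "L3", "L4", "L5", "L6")]),
               c("missingness", "heterozygosity", "singleton",
                 "site_presence", "maf_half"))
  expect_equal(sub(":.*", "", red$snp_ids), "L1")
})
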