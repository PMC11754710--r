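test_that("site downsampling keeps identity pools and rejects short pools", {
  # pool of exactly 4 present alleles {0,0,1,1}: returned unchanged
  for (s in c(1, 7, 500))
    expect_equal(sort(downsample_site(c(1, 1, NA), k = 4, seed = s)),
                 c(0, 0, 1, 1))
  # pool of 3 present alleles: unusable
  expect_null(downsample_site(c(1, NA, NA), k = 4))
  expect_null(downsample_site(c(0, NA), k = 4, seed = 1))
  expect_error(downsample_site(c(0, 0, 1), k = 0), "positive")
})

test_that("downsampling is hypergeometric-unbiased", {
  # pool of 6 alleles {0,0,0,1,1,1}: mean alt frequency after drawing 4
  # must match the pool frequency 0.5 (law of large numbers over seeds)
  alt <- vapply(1:20000, function(s)
    sum(downsample_site(c(1, 1, 1), k = 4, seed = s)), numeric(1))
  expect_equal(mean(alt) / 4, 0.5, tolerance = 0.01)
  # exhaustive enumeration for pools up to 8: expected draw frequency
  # equals the pool frequency exactly under the hypergeometric law
  for (pool_n in c(6, 8)) {
    for (pool_alt in 1:(pool_n - 1)) {
      ev <- sum(0:4 * dhyper(0:4, pool_alt, pool_n - pool_alt, 4)) / 4
      expect_equal(ev, pool_alt / pool_n, tolerance = 1e-12)
    }
  }
  # the vectorised per-site path follows the same hypergeometric law
  g <- matrix(1L, 5000, 3)  # 3 het individuals: pool {0,0,0,1,1,1}
  set.seed(1)
  cc <- rangecoal:::.downsample_site_counts(g, 4L)
  expect_equal(mean(cc) / 4, 0.5, tolerance = 0.01)
})

test_that("folding stores patterns at the pair minor allele with lexicographic ties", {
  f <- rangecoal:::.fold_pair
  # already minor: kept
  expect_equal(unlist(f(10, 3, 12, 16)), c(i = 10, j = 3))
  # majority-derived: complement-folded
  expect_equal(unlist(f(11, 6, 12, 16)), c(i = 1, j = 10))
  # exact 50% tie: lexicographically smaller image
  expect_equal(unlist(f(10, 4, 12, 16)), c(i = 2, j = 12))
  expect_equal(unlist(f(2, 12, 12, 16)), c(i = 2, j = 12))
  # involution: folding a folded pattern is the identity
  set.seed(2)
  for (r in 1:200) {
    ca <- sample(0:12, 1); cb <- sample(0:16, 1)
    f1 <- f(ca, cb, 12, 16)
    f2 <- f(f1$i, f1$j, 12, 16)
    expect_identical(c(f2$i, f2$j), c(f1$i, f1$j))
  }
})

test_that("masks cover monomorphic corners, pair singletons and unreachable cells", {
  mask <- rangecoal:::.sfs_mask(4, 4)
  expect_true(mask[1, 1])        # (0,0)
  expect_true(mask[1, 2] && mask[2, 1])  # i + j = 1
  expect_true(mask[5, 5])        # (n_a, n_b)
  # all cells beyond half the pooled sample size are fold-unreachable
  ij <- expand.grid(i = 0:4, j = 0:4)
  beyond <- ij$i + ij$j > 4
  expect_true(all(mask[cbind(ij$i + 1, ij$j + 1)][beyond]))
  expect_false(mask[2, 2])       # (1,1) is a scored shared polymorphism
})

test_that("pair spectra conserve SNPs and share the downsampling draw across pairs", {
  truth <- recovery_truth()
  m <- build_model("3-dicho+mig")
  cfg <- synthetic_config(m, truth, n_snps = 400, missing_rate = 0.1,
                          seed = 21)
  gm <- generate_dataset(cfg)$gm
  sfs <- all_pair_sfs(gm, seed = 77)
  expect_length(sfs, 3)   # C(3,2)
  for (s in sfs)
    expect_equal(sum(s$counts) + s$skipped, 400)
  # deterministic under the seed
  sfs2 <- all_pair_sfs(gm, seed = 77)
  expect_identical(sfs, sfs2)
  expect_false(identical(sfs, all_pair_sfs(gm, seed = 78)))
  # haploid sample sizes are 4 x number of sites per deme
  expect_equal(sfs[["Pgal|Pnig"]]$n_a, 4 * 3)
  expect_equal(sfs[["Pgal|Pnig"]]$n_b, 4 * 4)
  expect_equal(sfs[["Pnig|Pspi"]]$n_b, 4 * 8)
  # a pairwise spectrum built alone from the same blocks matches the
  # shared-draw version
  one <- build_folded_2d_sfs(gm, "Pgal", "Pnig", seed = 77)
  expect_equal(one$n_a, sfs[["Pgal|Pnig"]]$n_a)
})

test_that("the four-deme layout yields six spectra with the field sample sizes", {
  truth <- c(N_PGAL = 2e4, N_PNIG = 2e4, N_PSPE = 4e4, N_PSPW = 1e4,
             N_ANC_GAL = 2e4, N_ANC_SPW = 4e4, N_ANC = 4e4,
             TDIV_GAL = 15000, TDIV_SPW = 8000, TDIV_ANC = 52000,
             MIG_NIG_SPI = 1e-6, MIG_SPI_NIG = 1e-6,
             MIG_SPW_SPE = 1e-6, MIG_SPE_SPW = 1e-6)
  m <- build_model("4-dicho", submodel = "a")
  cfg <- synthetic_config(m, truth, n_snps = 200, missing_rate = 0,
                          seed = 5)
  gm <- generate_dataset(cfg)$gm
  sfs <- all_pair_sfs(gm, seed = 3)
  expect_length(sfs, 6)   # C(4,2)
  ns <- vapply(sfs, function(s) c(s$n_a, s$n_b), numeric(2))
  sizes <- c(Pgal = 12, Pnig = 16, PspE = 24, PspW = 8)
  for (nm in names(sfs)) {
    ab <- strsplit(nm, "|", fixed = TRUE)[[1]]
    expect_equal(unname(ns[, nm]), unname(sizes[ab]))
  }
})

test_that("observed-SFS files round-trip through the joint-MAF dialect", {
  truth <- recovery_truth()
  m <- build_model("3-dicho+mig")
  cfg <- synthetic_config(m, truth, n_snps = 150, seed = 9)
  gm <- generate_dataset(cfg)$gm
  sfs <- all_pair_sfs(gm, seed = 1)[[1]]
  path <- file.path(tempdir(), "pair_test.obs")
  write_pair_obs(sfs, path, seed = 1)
  back <- read_pair_obs(path)
  expect_equal(back$counts, sfs$counts)
  expect_equal(back$mask, sfs$mask)
  expect_equal(back$n_a, sfs$n_a)
  expect_equal(readLines(path, n = 1), "1 observations")
})

test_that("averaging over downsampling draws conserves mass and stays deterministic", {
  truth <- recovery_truth()
  m <- build_model("3-dicho+mig")
  cfg <- synthetic_config(m, truth, n_snps = 300, missing_rate = 0.1,
                          seed = 12)
  gm <- generate_dataset(cfg)$gm
  avg <- all_pair_sfs(gm, seed = 5, n_draws = 4)
  one <- all_pair_sfs(gm, seed = 5, n_draws = 1)
  for (s in avg) expect_equal(sum(s$counts) + s$skipped, 300)
  expect_identical(avg, all_pair_sfs(gm, seed = 5, n_draws = 4))
  # averaged spectra feed the likelihood machinery unchanged
  expect_lte(max_observed_log10_likelihood(avg), 0)
  # with a single draw the two paths agree exactly
  expect_equal(one, all_pair_sfs(gm, seed = 5))
})
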