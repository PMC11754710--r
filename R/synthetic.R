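#' Configuration for the synthetic RAD-like dataset generator
#'
#' Defaults emulate the reduced coalescent-modelling dataset of the study
#' system: 12,486 biallelic SNPs over 4 demes with the field sampling
#' design (Pgal 3 sites of 3/4/4 diploids, Pnig 4 sites of 4, PspE 6
#' sites of 3/4/4/4/4/4, PspW 2 sites of 3/4; the 3-deme layout pools the
#' two spicatum lineages into 8 Pspi sites), per-genotype Bernoulli
#' missingness and overdispersed (negative-binomial) read coverage.
#'
#' @param model a `demographic_model` giving the generating demography.
#' @param true_params named parameter vector for `model`.
#' @param n_snps number of segregating SNPs to simulate (default 12,486).
#' @param diploids_per_site named list: per deme, an integer vector of
#'   diploid counts per sampling site. Defaults as above.
#' @param missing_rate per-genotype missingness probability.
#' @param site_dropout_rate per-(site, SNP) probability that a whole
#'   sampling site drops out at that SNP (correlated locus dropout; a
#'   stress mode for the per-site presence filter, default 0).
#' @param coverage_mean,coverage_size negative-binomial read-depth mean
#'   and dispersion.
#' @param snps_per_locus SNPs grouped under one RAD-locus ID (grouping is
#'   for exercising the locus filters; SNPs remain unlinked).
#' @param seed integer seed; the generator is deterministic under it.
#' @export
synthetic_config <- function(model, true_params, n_snps = 12486,
                             diploids_per_site = NULL,
                             missing_rate = 0.15,
                             site_dropout_rate = 0,
                             coverage_mean = 20, coverage_size = 5,
                             snps_per_locus = 1, seed = 1) {
  stopifnot(n_snps > 0, missing_rate >= 0, missing_rate <= 1,
            site_dropout_rate >= 0, site_dropout_rate <= 1,
            coverage_mean > 0, snps_per_locus >= 1)
  if (is.null(diploids_per_site)) {
    defaults <- list(Pgal = c(3L, 4L, 4L), Pnig = c(4L, 4L, 4L, 4L),
                     PspE = c(3L, 4L, 4L, 4L, 4L, 4L), PspW = c(3L, 4L),
                     Pspi = c(3L, 4L, 4L, 4L, 4L, 4L, 3L, 4L))
    diploids_per_site <- defaults[model$demes]
    if (anyNA(names(diploids_per_site)))
      stop("no default site layout for demes ",
           paste(setdiff(model$demes, names(defaults)), collapse = ", "),
           "; supply diploids_per_site")
  }
  structure(list(model = model, true_params = true_params, n_snps = n_snps,
                 diploids_per_site = diploids_per_site[model$demes],
                 missing_rate = missing_rate,
                 site_dropout_rate = site_dropout_rate,
                 coverage_mean = coverage_mean,
                 coverage_size = coverage_size,
                 snps_per_locus = as.integer(snps_per_locus),
                 seed = seed),
            class = "synthetic_config")
}

#' Generate a synthetic genotype dataset with known truth
#'
#' Simulates `n_snps` unlinked segregating SNPs under the configured
#' demography (two haplotypes per diploid), pairs haplotypes into diploid
#' genotypes, assigns individuals to sampling sites, and overlays
#' independent per-genotype missingness and negative-binomial read
#' coverage. The generating parameters and seed are returned as a truth
#' record.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `gm` (a [genotype_matrix()]) and `truth`
#'   (model name, parameters, seed, SNP count).
#' @export
generate_dataset <- function(cfg) {
  model <- cfg$model
  dip <- cfg$diploids_per_site
  hap_n <- vapply(dip, function(x) 2L * sum(x), integer(1))
  model$sample_n <- stats::setNames(as.integer(hap_n), model$demes)
  flat <- instantiate_model(model, cfg$true_params)
  res <- .sim_snp_haplotypes_cpp(flat, as.integer(cfg$n_snps),
                                 as.double(cfg$seed))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  # SNPs fall on genealogies proportionally to total branch length
  hap <- res$patterns[sample.int(cfg$n_snps, cfg$n_snps, replace = TRUE,
                                 prob = res$weights), , drop = FALSE]
  # haplotype columns are in deme-block order; adjacent pairs = one diploid
  geno <- hap[, seq(1, ncol(hap), 2), drop = FALSE] +
    hap[, seq(2, ncol(hap), 2), drop = FALSE]
  storage.mode(geno) <- "integer"
  sites <- character(0); demes <- character(0); samples <- character(0)
  for (d in model$demes) {
    for (s in seq_along(dip[[d]])) {
      nd <- dip[[d]][s]
      sites <- c(sites, rep(sprintf("%s-%d", d, s), nd))
      demes <- c(demes, rep(d, nd))
      samples <- c(samples, sprintf("%s-%d_%d", d, s, seq_len(nd)))
    }
  }
  stopifnot(length(samples) == ncol(geno))
  n_cell <- length(geno)
  miss <- matrix(stats::runif(n_cell) < cfg$missing_rate,
                 nrow(geno), ncol(geno))
  geno[miss] <- NA_integer_
  if (cfg$site_dropout_rate > 0) {
    # correlated dropout: a whole sampling site loses a SNP at once
    for (s in unique(sites)) {
      gone <- stats::runif(nrow(geno)) < cfg$site_dropout_rate
      geno[gone, sites == s] <- NA_integer_
    }
  }
  cov <- matrix(stats::rnbinom(n_cell, mu = cfg$coverage_mean,
                               size = cfg$coverage_size),
                nrow(geno), ncol(geno))
  cov[is.na(geno)] <- NA_real_
  loci <- paste0("L", ceiling(seq_len(nrow(geno)) / cfg$snps_per_locus))
  gm <- genotype_matrix(geno, cov, samples = samples, sites = sites,
                        demes = demes, loci = loci)
  list(gm = gm,
       truth = list(model = model$name, params = cfg$true_params,
                    seed = cfg$seed, n_snps = cfg$n_snps))
}

#' Write a synthetic dataset as VCF + popmap + truth JSON
#' @param ds result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named vector of the paths written.
#' @export
write_dataset <- function(ds, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- write_vcf_genotypes(ds$gm, file.path(dir, paste0(prefix, ".vcf")))
  pop <- write_popmap(ds$gm, file.path(dir, paste0(prefix, ".popmap.tsv")))
  truth <- file.path(dir, paste0(prefix, ".truth.json"))
  jsonlite::write_json(ds$truth, truth, auto_unbox = TRUE, digits = NA)
  c(vcf = vcf, popmap = pop, truth = truth)
}

#' Simulate pseudoreplicate observed spectra under known parameters
#'
#' Either draws `n_snps` SNPs per pair from the model's expected masked
#' spectrum (multinomial over unmasked cells; the default, matching how
#' the composite likelihood treats cells) or simulates `n_snps` site
#' patterns directly and tabulates them per pair.
#'
#' @param model a `demographic_model`.
#' @param params named parameter vector.
#' @param n_snps SNPs per pair (single number or vector over pairs).
#' @param seed integer seed.
#' @param method `"multinomial"` or `"simulate"`.
#' @param n_sims simulations for the expected spectrum
#'   (`method = "multinomial"` only).
#' @return named list of `folded2dsfs` count spectra, one per unordered
#'   deme pair.
#' @export
pseudoreplicate_sfs <- function(model, params, n_snps, seed = 1,
                                method = c("multinomial", "simulate"),
                                n_sims = 200000) {
  method <- match.arg(method)
  pairs <- t(utils::combn(model$demes, 2))
  n_snps <- rep_len(n_snps, nrow(pairs))
  if (method == "simulate") {
    pat <- simulate_site_patterns(model, params, max(n_snps), seed)
    out <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      out[[i]] <- .tabulate_pair_sfs(pat[seq_len(n_snps[i]), a],
                                     pat[seq_len(n_snps[i]), b],
                                     model$sample_n[[a]],
                                     model$sample_n[[b]], a, b)
    }
  } else {
    exp_sfs <- expected_pair_sfs(model, params, n_sims, seed, pairs = pairs)
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    out <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      e <- exp_sfs[[i]]
      un <- !e$mask
      counts <- matrix(0, nrow(e$counts), ncol(e$counts),
                       dimnames = dimnames(e$counts))
      counts[un] <- stats::rmultinom(1, n_snps[i], e$prob[un])[, 1]
      out[[i]] <- .new_folded2dsfs(counts, e$mask, e$deme_a, e$deme_b,
                                   e$n_a, e$n_b,
                                   n_snps_used = n_snps[i])
    }
  }
  names(out) <- paste(pairs[, 1], pairs[, 2], sep = "|")
  out
}
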