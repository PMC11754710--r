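#' SNP-retention thresholds
#'
#' Bundles the thresholds of the retention cascade: at most
#' `max_snps_per_locus` SNPs per RAD locus, per-SNP missingness and
#' observed heterozygosity at most 50%, minor allele in at least two
#' individuals, per-genotype coverage at least six, and presence in at
#' least two individuals per sampling site. All bounds are inclusive.
#'
#' @param max_snps_per_locus integer, default 10.
#' @param max_missing_fraction proportion in \[0, 1\], default 0.50.
#' @param max_obs_het proportion in \[0, 1\], default 0.50.
#' @param min_coverage integer read depth, default 6.
#' @param min_individuals_per_site integer, default 2.
#' @export
filter_thresholds <- function(max_snps_per_locus = 10L,
                              max_missing_fraction = 0.50,
                              max_obs_het = 0.50,
                              min_coverage = 6L,
                              min_individuals_per_site = 2L) {
  stopifnot(max_snps_per_locus >= 1, min_coverage >= 1,
            min_individuals_per_site >= 1,
            max_missing_fraction >= 0, max_missing_fraction <= 1,
            max_obs_het >= 0, max_obs_het <= 1)
  structure(list(max_snps_per_locus = as.integer(max_snps_per_locus),
                 max_missing_fraction = max_missing_fraction,
                 max_obs_het = max_obs_het,
                 min_coverage = as.integer(min_coverage),
                 min_individuals_per_site = as.integer(min_individuals_per_site)),
            class = "filter_thresholds")
}

# per-SNP complete-dataset criteria; returns the first failed rule per SNP
# ("" = passes)
.per_snp_rule <- function(gm, th) {
  g <- gm$geno
  n_samp <- ncol(g)
  called <- !is.na(g)
  n_called <- rowSums(called)
  miss_frac <- 1 - n_called / n_samp
  n_het <- rowSums(g == 1L, na.rm = TRUE)
  hobs <- ifelse(n_called > 0, n_het / n_called, 1)
  # minor allele must be carried by >= 2 distinct individuals
  alt_cnt <- rowSums(g, na.rm = TRUE)
  tot_cnt <- 2L * n_called
  alt_minor <- 2L * alt_cnt <= tot_cnt    # ties: alt treated as minor
  carriers_alt <- rowSums(g >= 1L, na.rm = TRUE)
  carriers_ref <- rowSums(g <= 1L, na.rm = TRUE)
  carriers_minor <- ifelse(alt_minor, carriers_alt, carriers_ref)
  rule <- rep("", nrow(g))
  rule[n_called > 0 & carriers_minor < 2] <- "singleton"
  rule[hobs > th$max_obs_het] <- "heterozygosity"
  rule[miss_frac > th$max_missing_fraction] <- "missingness"
  rule[n_called == 0] <- "missingness"
  rule
}

.log_rejections <- function(gm, snp, rule) {
  rej <- attr(gm, "rejections")
  if (is.null(rej))
    rej <- data.frame(snp = character(), rule = character(),
                      stringsAsFactors = FALSE)
  if (length(snp) > 0)
    rej <- rbind(rej, data.frame(snp = snp, rule = rule,
                                 stringsAsFactors = FALSE))
  rej
}

#' Keep one random qualifying SNP per RAD locus
#'
#' Loci carrying more than `max_snps` SNPs are dropped entirely. Among
#' each remaining locus's SNPs that individually pass the complete-dataset
#' per-SNP criteria (missingness at most 50%, observed heterozygosity at
#' most 50%, minor allele in at least two individuals), exactly one is
#' chosen uniformly at random; loci with no qualifying SNP are dropped.
#'
#' @param gm a [genotype_matrix()].
#' @param max_snps maximum SNPs per locus before the whole locus is
#'   discarded (default 10).
#' @param seed integer seed governing the random choice (recorded in the
#'   output's `seed` attribute).
#' @param th thresholds for the per-SNP criteria ([filter_thresholds()]).
#' @return filtered `genotype_matrix` with at most one SNP per locus and a
#'   `rejections` attribute (`snp`, `rule`) covering every removed SNP.
#' @export
select_random_snp_per_locus <- function(gm, max_snps = 10L, seed = 1L,
                                        th = filter_thresholds()) {
  if (anyNA(gm$loci) || any(gm$loci == "")) {
    bad <- which(is.na(gm$loci) | gm$loci == "")[1]
    stop("SNP '", gm$snp_ids[bad], "' has no locus annotation")
  }
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  locus_n <- table(gm$loci)
  big <- names(locus_n)[locus_n > max_snps]
  rule <- rep("", nrow(gm$geno))
  rule[gm$loci %in% big] <- "locus_excess_snps"
  snp_rule <- .per_snp_rule(gm, th)
  fresh <- rule == "" & snp_rule != ""
  rule[fresh] <- snp_rule[fresh]
  keep <- logical(nrow(gm$geno))
  for (loc in setdiff(unique(gm$loci), big)) {
    idx <- which(gm$loci == loc & rule == "")
    if (length(idx) == 0) next
    pick <- if (length(idx) == 1) idx else idx[sample.int(length(idx), 1)]
    keep[pick] <- TRUE
    rule[setdiff(idx, pick)] <- "not_selected"
  }
  out <- .gm_subset(gm, keep)
  attr(out, "rejections") <- .log_rejections(gm, gm$snp_ids[!keep],
                                             rule[!keep])
  attr(out, "seed") <- seed
  out
}

#' Complete-dataset SNP filter
#'
#' Retains SNPs with missing fraction at most 50%, observed heterozygosity
#' (het calls / non-missing calls) at most 50%, and minor allele carried by
#' at least two distinct individuals, then keeps a single random qualifying
#' SNP per RAD locus (delegating to [select_random_snp_per_locus()]).
#'
#' @inheritParams select_random_snp_per_locus
#' @param th a [filter_thresholds()].
#' @return filtered `genotype_matrix` with rejection log and seed attributes.
#' @export
filter_complete <- function(gm, th = filter_thresholds(), seed = 1L) {
  out <- select_random_snp_per_locus(gm, max_snps = th$max_snps_per_locus,
                                     seed = seed, th = th)
  if (nrow(out$geno) == 0)
    warning("no SNPs survive the complete-dataset filter")
  out
}

#' Reduced-dataset SNP filter
#'
#' Applies the coalescent-modelling filters on top of a complete-dataset
#' matrix: genotypes below the coverage threshold are set missing, every
#' sampling site must then retain at least two genotyped individuals per
#' SNP, and SNPs whose overall alternate-allele frequency is exactly
#' 0.5 are removed (their minor allele is undefined; equality is tested on
#' integer allele counts).
#'
#' @param gm a [genotype_matrix()] that already passed [filter_complete()].
#' @param th a [filter_thresholds()].
#' @param coverage_rule how the coverage threshold is applied:
#'   `"genotype"` (default) masks individual genotypes with depth below
#'   `min_coverage`; `"locus_mean"` drops whole SNPs whose mean depth over
#'   called genotypes is below it.
#' @return filtered `genotype_matrix` (low-coverage genotypes masked) with
#'   rejection log.
#' @export
filter_reduced <- function(gm, th = filter_thresholds(),
                           coverage_rule = c("genotype", "locus_mean")) {
  coverage_rule <- match.arg(coverage_rule)
  site_sizes <- table(gm$sites)
  small <- names(site_sizes)[site_sizes < th$min_individuals_per_site]
  if (length(small) > 0)
    stop("sampling site(s) with fewer than ", th$min_individuals_per_site,
         " samples can never satisfy the presence rule: ",
         paste(small, collapse = ", "))
  g <- gm$geno
  rule <- rep("", nrow(g))
  called_before <- !is.na(g)
  if (coverage_rule == "genotype") {
    low <- !is.na(g) & !is.na(gm$coverage) & gm$coverage < th$min_coverage
    g[low] <- NA_integer_
    cov <- gm$coverage
    cov[low] <- NA_real_
  } else {
    mean_cov <- rowMeans(ifelse(is.na(g), NA, gm$coverage), na.rm = TRUE)
    rule[is.finite(mean_cov) & mean_cov < th$min_coverage] <- "coverage"
    cov <- gm$coverage
  }
  # presence rule: >= 2 genotyped individuals in every sampling site;
  # failures introduced purely by the depth masking are logged as
  # "coverage", pre-existing ones as "site_presence"
  called <- !is.na(g)
  for (s in unique(gm$sites)) {
    cols <- gm$sites == s
    n_here <- rowSums(called[, cols, drop = FALSE])
    n_before <- rowSums(called_before[, cols, drop = FALSE])
    fail <- rule == "" & n_here < th$min_individuals_per_site
    rule[fail & n_before >= th$min_individuals_per_site] <- "coverage"
    rule[fail & n_before < th$min_individuals_per_site] <- "site_presence"
  }
  # after masking, SNPs whose every call vanished are also presence failures
  all_gone <- rule == "" & rowSums(called) == 0
  rule[all_gone & rowSums(called_before) > 0] <- "coverage"
  rule[all_gone & rowSums(called_before) == 0] <- "site_presence"
  # exactly-0.5 overall alternate-allele frequency (integer-count test)
  alt_cnt <- rowSums(g, na.rm = TRUE)
  tot_cnt <- 2L * rowSums(called)
  rule[rule == "" & tot_cnt > 0 & 2L * alt_cnt == tot_cnt] <- "maf_half"
  keep <- rule == ""
  out <- gm
  out$geno <- g
  out$coverage <- cov
  out <- .gm_subset(out, keep)
  attr(out, "rejections") <- .log_rejections(gm, gm$snp_ids[!keep],
                                             rule[!keep])
  if (nrow(out$geno) == 0)
    warning("no SNPs survive the reduced-dataset filter")
  out
}

#' Write the rejection log of a filtered genotype matrix
#' @param gm filtered `genotype_matrix`.
#' @param path output TSV path (columns `snp`, `rule`).
#' @export
write_rejection_log <- function(gm, path) {
  rej <- attr(gm, "rejections")
  if (is.null(rej)) rej <- data.frame(snp = character(), rule = character())
  utils::write.table(rej, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
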