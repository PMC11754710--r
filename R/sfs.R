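#' Folded pairwise site frequency spectra
#'
#' A `folded2dsfs` stores, for one deme pair, a matrix of SNP counts
#' indexed by folded (pair-pooled minor) allele counts `(i, j)` with
#' `0 <= i <= n_a`, `0 <= j <= n_b`, together with a logical mask of cells
#' ignored in likelihood computations: the pair-monomorphic corners
#' `(0,0)` and `(n_a,n_b)`, the pair singletons `i + j = 1`, and all cells
#' unreachable after folding (`i + j` above half the pooled sample size,
#' or the lexicographically larger image of an exactly-50% tie).
#'
#' @name folded2dsfs
NULL

# fold a pattern on the pair's pooled minor allele (vectorised);
# exact-50% ties go to the lexicographically smaller image
.fold_pair <- function(ca, cb, na, nb) {
  tot2 <- 2L * (ca + cb)
  h <- na + nb
  ia <- na - ca
  ib <- nb - cb
  flip <- tot2 > h | (tot2 == h & (ia < ca | (ia == ca & ib < cb)))
  list(i = ifelse(flip, ia, ca), j = ifelse(flip, ib, cb))
}

.sfs_mask <- function(na, nb) {
  i <- matrix(0:na, na + 1, nb + 1)
  j <- matrix(0:nb, na + 1, nb + 1, byrow = TRUE)
  f <- .fold_pair(as.vector(i), as.vector(j), na, nb)
  unreachable <- matrix(f$i != as.vector(i) | f$j != as.vector(j),
                        na + 1, nb + 1)
  mask <- unreachable | (i + j <= 1) | (i == na & j == nb)
  dimnames(mask) <- list(paste0("d0_", 0:na), paste0("d1_", 0:nb))
  mask
}

.new_folded2dsfs <- function(counts, mask, deme_a, deme_b, na, nb,
                             n_snps_used = sum(counts), skipped = 0L) {
  structure(list(deme_a = deme_a, deme_b = deme_b, n_a = na, n_b = nb,
                 counts = counts, mask = mask, n_snps_used = n_snps_used,
                 skipped = skipped),
            class = "folded2dsfs")
}

# fold + tabulate per-pair derived counts into a count matrix
.tabulate_pair_sfs <- function(ca, cb, na, nb, deme_a, deme_b,
                               skipped = 0L) {
  f <- .fold_pair(ca, cb, na, nb)
  idx <- f$i * (nb + 1L) + f$j + 1L
  counts <- matrix(tabulate(idx, nbins = (na + 1L) * (nb + 1L)),
                   na + 1L, nb + 1L, byrow = TRUE)
  dimnames(counts) <- list(paste0("d0_", 0:na), paste0("d1_", 0:nb))
  .new_folded2dsfs(counts, .sfs_mask(na, nb), deme_a, deme_b, na, nb,
                   n_snps_used = length(ca), skipped = skipped)
}

# attach renormalised, floored probabilities over unmasked cells
.sfs_counts_to_probs <- function(sfs, floor) {
  un <- !sfs$mask
  tot <- sum(sfs$counts[un])
  p <- matrix(0, nrow(sfs$counts), ncol(sfs$counts),
              dimnames = dimnames(sfs$counts))
  p[un] <- if (tot > 0) sfs$counts[un] / tot else 1 / sum(un)
  p[un] <- pmax(p[un], floor)
  p[un] <- p[un] / sum(p[un])
  sfs$prob <- p
  sfs
}

#' @export
print.folded2dsfs <- function(x, ...) {
  cat(sprintf("Folded 2D SFS %s (n=%d) x %s (n=%d): %d SNPs (%d skipped)\n",
              x$deme_a, x$n_a, x$deme_b, x$n_b,
              x$n_snps_used, x$skipped))
  invisible(x)
}

## ---- downsampling ----------------------------------------------------------

#' Downsample one sampling site to a fixed haploid block
#'
#' Draws `k` alleles uniformly without replacement from the pool of present
#' (non-missing) haploid alleles of one sampling site at one SNP, so the
#' resulting block has no missing data. Each non-missing diploid call
#' contributes two alleles to the pool.
#'
#' @param calls integer vector of diploid genotypes at one SNP for the
#'   site's individuals (0 = hom-ref, 1 = het, 2 = hom-alt, `NA` missing).
#' @param k block size (haploid genotypes to draw), default 4.
#' @param seed optional integer seed.
#' @return integer vector of `k` alleles in `{0, 1}`, or `NULL` when the
#'   pool holds fewer than `k` alleles.
#' @export
downsample_site <- function(calls, k = 4, seed = NULL) {
  if (k <= 0) stop("k must be positive")
  calls <- calls[!is.na(calls)]
  pool <- rep(c(0L, 1L), c(2L * length(calls) - sum(calls), sum(calls)))
  if (length(pool) < k) return(NULL)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  pool[sample.int(length(pool), k)]
}

# vectorised equivalent of downsample_site over all SNPs of one site:
# drawing k alleles without replacement and keeping only the derived count
# is a hypergeometric draw from (n_alt, n_total - n_alt)
.downsample_site_counts <- function(geno_site, k = 4L) {
  called <- !is.na(geno_site)
  n_tot <- 2L * rowSums(called)
  n_alt <- rowSums(geno_site, na.rm = TRUE)
  out <- rep(NA_integer_, nrow(geno_site))
  ok <- n_tot >= k
  if (any(ok))
    out[ok] <- stats::rhyper(sum(ok), n_alt[ok], n_tot[ok] - n_alt[ok], k)
  out
}

## ---- observed spectra ------------------------------------------------------

# per-(site, SNP) downsampled derived counts for every site; one shared
# realisation feeds every deme pair
.site_blocks <- function(gm, k = 4L) {
  sites <- unique(gm$sites)
  blocks <- matrix(NA_integer_, nrow(gm$geno), length(sites),
                   dimnames = list(NULL, sites))
  for (s in sites) {
    cols <- gm$sites == s
    blocks[, s] <- .downsample_site_counts(
      gm$geno[, cols, drop = FALSE], k = k)
  }
  blocks
}

#' Folded 2D SFS of one deme pair from a genotype matrix
#'
#' For each SNP, four present haploid alleles are drawn per sampling site
#' ([downsample_site()]), derived counts are summed over the sites of each
#' deme, and the pattern is folded on the pair's pooled minor allele
#' (exact-50% ties stored at the lexicographically smaller image). SNPs
#' where any involved site has fewer than four present alleles are skipped
#' and counted in `skipped`.
#'
#' @param gm a [genotype_matrix()].
#' @param deme_a,deme_b deme labels present in `gm$demes`.
#' @param seed integer seed for the downsampling draw.
#' @param blocks optional precomputed site-block matrix (internal; lets
#'   [all_pair_sfs()] share one draw across pairs).
#' @return a `folded2dsfs`.
#' @export
build_folded_2d_sfs <- function(gm, deme_a, deme_b, seed = 1, blocks = NULL) {
  for (d in c(deme_a, deme_b))
    if (!d %in% gm$demes) stop("deme '", d, "' has zero sampling sites")
  if (is.null(blocks)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    blocks <- .site_blocks(gm)
  }
  site_deme <- gm$demes[match(colnames(blocks), gm$sites)]
  sa <- colnames(blocks)[site_deme == deme_a]
  sb <- colnames(blocks)[site_deme == deme_b]
  na <- 4L * length(sa)
  nb <- 4L * length(sb)
  ba <- blocks[, sa, drop = FALSE]
  bb <- blocks[, sb, drop = FALSE]
  usable <- rowSums(is.na(ba)) == 0 & rowSums(is.na(bb)) == 0
  ca <- rowSums(ba[usable, , drop = FALSE])
  cb <- rowSums(bb[usable, , drop = FALSE])
  .tabulate_pair_sfs(ca, cb, na, nb, deme_a, deme_b,
                     skipped = sum(!usable))
}

#' Folded 2D SFS for every unordered deme pair
#'
#' All pairs share a single per-(site, SNP) downsampling realisation, so
#' the same haploid block feeds every spectrum a site participates in.
#' One realisation is the default (matching how a single observed SFS is
#' reported); `n_draws > 1` averages the count matrices over independent
#' downsampling realisations, which smooths the downsampling noise at the
#' cost of non-integer cell counts.
#'
#' @param gm a [genotype_matrix()].
#' @param demes optional ordered deme subset (default: order of appearance
#'   in `gm$demes`); at least two.
#' @param seed integer seed.
#' @param n_draws number of downsampling realisations to average.
#' @return named list of `C(D, 2)` `folded2dsfs` objects
#'   (names `"A|B"`).
#' @export
all_pair_sfs <- function(gm, demes = NULL, seed = 1, n_draws = 1) {
  if (is.null(demes)) demes <- unique(gm$demes)
  if (length(demes) < 2) stop("need at least 2 demes")
  stopifnot(n_draws >= 1)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  pairs <- t(utils::combn(demes, 2))
  out <- NULL
  for (d in seq_len(n_draws)) {
    blocks <- .site_blocks(gm)
    draw <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs)))
      draw[[i]] <- build_folded_2d_sfs(gm, pairs[i, 1], pairs[i, 2],
                                       blocks = blocks)
    if (is.null(out)) out <- draw
    else for (i in seq_along(out)) {
      out[[i]]$counts <- out[[i]]$counts + draw[[i]]$counts
      out[[i]]$n_snps_used <- out[[i]]$n_snps_used + draw[[i]]$n_snps_used
      out[[i]]$skipped <- out[[i]]$skipped + draw[[i]]$skipped
    }
  }
  if (n_draws > 1) {
    for (i in seq_along(out)) {
      out[[i]]$counts <- out[[i]]$counts / n_draws
      out[[i]]$n_snps_used <- out[[i]]$n_snps_used / n_draws
      out[[i]]$skipped <- out[[i]]$skipped / n_draws
    }
  }
  names(out) <- paste(pairs[, 1], pairs[, 2], sep = "|")
  out
}

## ---- observed-SFS file dialect --------------------------------------------

#' Write a folded pairwise spectrum in the joint-MAF observed-SFS dialect
#'
#' Plain-text layout used by SFS-based coalescent fitters: a header line
#' `"1 observations"`, a tab-separated column-label line, then one labelled
#' row per entry of deme a. A JSON sidecar (`<path>.json`) records sample
#' sizes, the mask, SNP totals and the seed.
#'
#' @param sfs a `folded2dsfs`.
#' @param path output file path.
#' @param seed seed recorded in the sidecar.
#' @export
write_pair_obs <- function(sfs, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("1 observations", con)
  writeLines(paste(c("", colnames(sfs$counts)), collapse = "\t"), con)
  for (i in seq_len(nrow(sfs$counts)))
    writeLines(paste(c(rownames(sfs$counts)[i], sfs$counts[i, ]),
                     collapse = "\t"), con)
  sidecar <- list(deme_a = sfs$deme_a, deme_b = sfs$deme_b,
                  n_a = sfs$n_a, n_b = sfs$n_b,
                  n_snps_used = sfs$n_snps_used, skipped = sfs$skipped,
                  seed = seed, mask = sfs$mask)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read a folded pairwise spectrum written by [write_pair_obs()]
#' @param path file path.
#' @return a `folded2dsfs`.
#' @export
read_pair_obs <- function(path) {
  lines <- readLines(path)
  tab <- utils::read.table(text = lines[-1], sep = "\t", header = TRUE,
                           row.names = 1, check.names = FALSE)
  counts <- as.matrix(tab)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  na <- side$n_a; nb <- side$n_b
  stopifnot(nrow(counts) == na + 1, ncol(counts) == nb + 1)
  .new_folded2dsfs(counts, .sfs_mask(na, nb), side$deme_a, side$deme_b,
                   na, nb, n_snps_used = side$n_snps_used,
                   skipped = side$skipped)
}
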