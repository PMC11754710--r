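#' Diploid genotype matrix with site/deme labels and read coverage
#'
#' The container every SNP filter acts on: biallelic diploid calls coded
#' 0 (hom-ref), 1 (het), 2 (hom-alt), `NA` (missing), one row per SNP and
#' one column per sample, plus per-genotype read depth, per-SNP RAD-locus
#' IDs and per-sample sampling-site and deme labels.
#'
#' @param geno integer matrix (SNPs x samples) in `{0, 1, 2, NA}`.
#' @param coverage numeric matrix of read depths, same shape; must be
#'   non-missing wherever `geno` is non-missing.
#' @param samples sample IDs (column names).
#' @param sites per-sample sampling-site label.
#' @param demes per-sample deme label.
#' @param loci per-SNP RAD-locus ID.
#' @param snp_ids per-SNP identifier (default `locus:row`).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, coverage = NULL, samples = colnames(geno),
                            sites, demes, loci, snp_ids = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(geno)))
  stopifnot(length(samples) == ncol(geno),
            length(sites) == ncol(geno),
            length(demes) == ncol(geno),
            length(loci) == nrow(geno))
  if (!all(geno %in% c(0L, 1L, 2L) | is.na(geno)))
    stop("genotypes must be coded 0/1/2/NA (biallelic diploid)")
  if (is.null(coverage)) {
    coverage <- matrix(NA_real_, nrow(geno), ncol(geno))
    coverage[!is.na(geno)] <- Inf   # "coverage not recorded": never filtered
  }
  coverage <- as.matrix(coverage)
  stopifnot(all(dim(coverage) == dim(geno)))
  if (any(!is.na(geno) & is.na(coverage)))
    stop("coverage must be defined wherever the genotype is non-missing")
  if (is.null(snp_ids)) snp_ids <- paste0(loci, ":", seq_len(nrow(geno)))
  dimnames(geno) <- list(snp_ids, samples)
  dimnames(coverage) <- dimnames(geno)
  structure(list(geno = geno, coverage = coverage,
                 samples = samples,
                 sites = as.character(sites), demes = as.character(demes),
                 loci = as.character(loci), snp_ids = as.character(snp_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d SNPs x %d samples (%d loci, %d sites, %d demes)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$loci)),
              length(unique(x$sites)), length(unique(x$demes))))
  rej <- attr(x, "rejections")
  if (!is.null(rej)) cat("  rejection log:", nrow(rej), "entries\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

# row subset keeping labels and the rejection-log / seed attributes
.gm_subset <- function(gm, keep) {
  out <- gm
  out$geno <- gm$geno[keep, , drop = FALSE]
  out$coverage <- gm$coverage[keep, , drop = FALSE]
  out$loci <- gm$loci[keep]
  out$snp_ids <- gm$snp_ids[keep]
  attributes(out)$class <- "genotype_matrix"
  attr(out, "rejections") <- attr(gm, "rejections")
  attr(out, "seed") <- attr(gm, "seed")
  out
}

## ---- VCF + popmap I/O ------------------------------------------------------

#' Read a population map
#'
#' @param path 3-column headerless TSV: `sample<TAB>site<TAB>deme`.
#' @return data.frame with columns `sample`, `site`, `deme`.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample", "site", "deme"),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(pm$sample)) stop("duplicated samples in popmap")
  pm
}

#' Write a population map TSV
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @export
write_popmap <- function(gm, path) {
  utils::write.table(data.frame(gm$samples, gm$sites, gm$demes),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a multi-sample VCF plus popmap into a genotype matrix
#'
#' Reads biallelic SNPs (others are dropped with a message) through
#' `vcfR`, taking diploid calls from `GT` and per-genotype depth from
#' `DP`. The RAD-locus ID is parsed from the `ID` column (falling back to
#' `CHROM`) with a configurable regex whose first capture group is the
#' locus.
#'
#' @param vcf_path VCF file (`.vcf` or `.vcf.gz`).
#' @param popmap_path popmap TSV ([read_popmap()]).
#' @param locus_regex regex with one capture group extracting the locus ID.
#' @param id_source `"ID"` or `"CHROM"`.
#' @return a `genotype_matrix` restricted to (and ordered by) the popmap
#'   samples.
#' @export
read_vcf_genotypes <- function(vcf_path, popmap_path,
                               locus_regex = "^([^:]+)",
                               id_source = c("ID", "CHROM")) {
  id_source <- match.arg(id_source)
  pm <- read_popmap(popmap_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biall <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1
  if (!all(biall)) {
    message("dropping ", sum(!biall), " non-biallelic-SNP records")
    v <- v[biall, ]
    fix <- vcfR::getFIX(v)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  missing_samples <- setdiff(pm$sample, colnames(gt))
  if (length(missing_samples) > 0)
    stop("popmap samples absent from VCF: ",
         paste(missing_samples, collapse = ", "))
  gt <- gt[, pm$sample, drop = FALSE]
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt))
  geno[gt %in% c("0/0", "0|0")] <- 0L
  geno[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  geno[gt %in% c("1/1", "1|1")] <- 2L
  if (is.null(dp)) {
    dp <- matrix(NA_real_, nrow(geno), ncol(geno))
    dp[!is.na(geno)] <- Inf
  } else {
    dp <- dp[, pm$sample, drop = FALSE]
  }
  dp[is.na(dp) & !is.na(geno)] <- Inf  # depth absent: never depth-filtered
  raw_id <- if (id_source == "ID") fix[, "ID"] else fix[, "CHROM"]
  raw_id[is.na(raw_id) | raw_id == "."] <- fix[is.na(raw_id) | raw_id == ".",
                                               "CHROM"]
  loci <- sub(paste0(locus_regex, ".*$"), "\\1", raw_id)
  bad <- is.na(loci) | loci == ""
  if (any(bad))
    stop("missing locus annotation for SNP(s): ",
         paste(utils::head(raw_id[bad], 5), collapse = ", "))
  snp_ids <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  genotype_matrix(geno, dp, samples = pm$sample, sites = pm$site,
                  demes = pm$deme, loci = loci, snp_ids = snp_ids)
}

#' Write a genotype matrix as a VCF (GT:DP)
#'
#' @param gm a `genotype_matrix`.
#' @param path output path; `vcfR` writes gzipped VCF, so a `.vcf.gz`
#'   suffix is appended if absent.
#' @return the path written.
#' @export
write_vcf_genotypes <- function(gm, path) {
  if (!grepl("\\.vcf\\.gz$", path)) path <- paste0(path, ".vcf.gz")
  n_snp <- nrow(gm$geno)
  gt_str <- matrix("./.", n_snp, ncol(gm$geno))
  gt_str[gm$geno == 0L] <- "0/0"
  gt_str[gm$geno == 1L] <- "0/1"
  gt_str[gm$geno == 2L] <- "1/1"
  dp <- gm$coverage
  dp_str <- ifelse(is.na(dp) | is.infinite(dp), ".",
                   format(dp, trim = TRUE, scientific = FALSE))
  body <- matrix(paste(gt_str, dp_str, sep = ":"), n_snp, ncol(gm$geno))
  colnames(body) <- gm$samples
  fix <- cbind(CHROM = gm$loci,
               POS = as.character(seq_len(n_snp)),
               ID = gm$snp_ids, REF = "A", ALT = "T",
               QUAL = ".", FILTER = "PASS", INFO = ".")
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">")
  if (!is.null(attr(gm, "seed")))
    meta <- c(meta, paste0("##rangecoal_filter_seed=", attr(gm, "seed")))
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                    meta = meta,
                    fix = fix,
                    gt = cbind(FORMAT = rep("GT:DP", n_snp), body))
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
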