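# shared toy models and generating-parameter sets used across test files

toy_one_deme <- function(n = 4, N = 1000) {
  m <- demographic_model(
    "toy-1deme", demes = "A", sample_n = c(A = n), size = c(A = "N_A"),
    events = list(),
    params = list(param_spec("N_A", 100, 2e5, "log")))
  list(model = m, params = c(N_A = N))
}

toy_two_deme <- function(n1 = 4, n2 = 4, N1 = 5000, N2 = 5000,
                         m12 = 0, m21 = 0, t_merge = 4000, N_anc = 5000) {
  m <- demographic_model(
    "toy-2deme", demes = c("A", "B"),
    sample_n = c(A = n1, B = n2), size = c(A = "N_A", B = "N_B"),
    events = list(
      list(type = "merge", t = "T_AB", source = "B", dest = "A"),
      list(type = "resize", t = "T_AB", deme = "A", new_N = "N_ANC")),
    migration = list("A>B" = "M_AB", "B>A" = "M_BA"),
    params = list(
      param_spec("N_A", 100, 2e5, "log"),
      param_spec("N_B", 100, 2e5, "log"),
      param_spec("N_ANC", 100, 2e5, "log"),
      param_spec("T_AB", 100, 139000),
      param_spec("M_AB", 1e-8, 1e-3, "log", fixed = (m12 == 0), value = 0),
      param_spec("M_BA", 1e-8, 1e-3, "log", fixed = (m21 == 0), value = 0)))
  list(model = m,
       params = c(N_A = N1, N_B = N2, N_ANC = N_anc, T_AB = t_merge,
                  M_AB = m12, M_BA = m21))
}

# generating parameters used for the recovery / bootstrap experiments
recovery_truth <- function() {
  c(N_PGAL = 15000, N_PNIG = 30000, N_PSPI = 60000,
    N_ANC_GAL = 30000, N_ANC = 60000,
    TDIV_GAL = 17800, TDIV_ANC = 52000,
    MIG_NIG_SPI = 1e-5, MIG_SPI_NIG = 1e-5,
    MIG_GAL_SPI = 2e-5, MIG_SPI_GAL = 2e-5)
}

hybrid_truth <- function() {
  c(N_PGAL = 15000, N_PNIG = 30000, N_PSPI = 60000, N_ANC = 60000,
    ALPHA_GAL = 0.5, TDIV_GAL = 17800, TDIV_ANC = 52000,
    MIG_NIG_SPI = 1e-5, MIG_SPI_NIG = 1e-5)
}

# small genotype matrix builder: geno is SNPs x samples 0/1/2/NA
tiny_gm <- function(geno, coverage = NULL, sites = NULL, demes = NULL,
                    loci = NULL) {
  ns <- ncol(geno)
  if (is.null(sites)) sites <- rep("s1", ns)
  if (is.null(demes)) demes <- rep("A", ns)
  if (is.null(loci)) loci <- paste0("L", seq_len(nrow(geno)))
  genotype_matrix(geno, coverage, samples = paste0("ind", seq_len(ns)),
                  sites = sites, demes = demes, loci = loci)
}
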