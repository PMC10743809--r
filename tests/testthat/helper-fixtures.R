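# Shared fixtures, built in code. The full demo pipeline run is cached so
# several tests can inspect the same deterministic result.

.fixture_env <- new.env(parent = emptyenv())

demo_run <- function(seed = 1) {
  key <- paste0("run", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- run_pipeline(demo_config(seed = seed))
  .fixture_env[[key]]
}

small_geno <- function(seed = 7, n = 150, chrom = 3, m_per = 400) {
  key <- sprintf("g_%d_%d_%d_%d", seed, n, chrom, m_per)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_genotypes(
      genome_spec(n_chromosomes = chrom, chrom_length_bp = 2e7,
                  n_markers_per_chrom = m_per, seed = seed), n)
  .fixture_env[[key]]
}

# toy genotype object from an explicit dosage matrix (one chromosome,
# positions 1 kb apart unless given)
toy_geno <- function(dosage, pos = NULL) {
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  colnames(dosage) <- sprintf("Lu1_%d", pos)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("ACC%03d", seq_len(nrow(dosage)))
  geno_matrix(dosage, data.frame(marker = colnames(dosage), chrom = 1L,
                                 pos = pos))
}

# near-identity genetic correlation matrix with one planted trait pair
.default_gen_cor_for_test <- function(r_trl_rv) {
  tr <- base_traits()
  m <- diag(length(tr))
  dimnames(m) <- list(tr, tr)
  m["TRL", "RV"] <- m["RV", "TRL"] <- r_trl_rv
  m
}

# PSD Cholesky factor for drawing structured phenotypes from a GRM
chol_psd_for_test <- function(S) {
  ed <- eigen(S, symmetric = TRUE)
  t(ed$vectors %*% diag(sqrt(pmax(ed$values, 0))))
}

# balanced raw phenotype table for pheno tests
toy_raw <- function(n_acc = 4, n_rep = 3, seed = 1) {
  set.seed(seed)
  base <- c(TRL = 400, RV = 0.4, RT = 500, PDW = 100, SDW = 70, RDW = 30,
            shootN = 3, rootN = 1)
  grid <- expand.grid(accession = sprintf("A%02d", seq_len(n_acc)),
                      treatment = c("N+", "N-"),
                      replicate = seq_len(n_rep),
                      trait = names(base), stringsAsFactors = FALSE)
  grid$value <- base[grid$trait] * (1 + 0.1 * stats::rnorm(nrow(grid)))
  grid$value <- pmax(grid$value, 0.01)
  grid
}
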