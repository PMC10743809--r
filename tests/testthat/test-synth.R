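test_that("genotype simulation is deterministic and frequency-controlled", {
  spec <- genome_spec(n_chromosomes = 2, n_markers_per_chrom = 150,
                      maf_range = c(0.1, 0.5), seed = 3)
  g1 <- simulate_genotypes(spec, 80)
  g2 <- simulate_genotypes(spec, 80)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$map, g2$map)
  expect_true(all(marker_maf(g1$dosage) >= 0.1))
  expect_true(all(g1$dosage %in% 0:2))
  # positions strictly increasing within chromosome
  for (ch in unique(g1$map$chrom))
    expect_true(all(diff(g1$map$pos[g1$map$chrom == ch]) > 0))
})

test_that("a forced high-frequency draw yields markers near 0.5", {
  spec <- genome_spec(n_chromosomes = 1, n_markers_per_chrom = 200,
                      maf_range = c(0.45, 0.5), ld_block_len_bp = 1e3,
                      n_subpops = 1, fst = 0, seed = 5)
  g <- simulate_genotypes(spec, 300)
  expect_gt(mean(marker_maf(g$dosage)), 0.4)
})

test_that("an impossible MAF filter fails with a clear message", {
  spec <- genome_spec(n_chromosomes = 1, n_markers_per_chrom = 3,
                      maf_range = c(0.49, 0.5), n_subpops = 1, fst = 0.5,
                      seed = 11)
  # heavy drift pushes tiny panels out of the window often enough that
  # some seed gives zero survivors
  expect_error(
    {
      for (s in 1:50) {
        spec$seed <- s
        simulate_genotypes(spec, 10)
      }
    }, "MAF")
})

test_that("fst = 0 gives no subpopulation differentiation", {
  spec <- genome_spec(n_chromosomes = 1, n_markers_per_chrom = 220,
                      fst = 0, n_subpops = 2, ld_block_len_bp = 1e3,
                      seed = 9)
  g <- simulate_genotypes(spec, 200)
  sub <- g$subpop
  p1 <- colMeans(g$dosage[sub == "P1", ]) / 2
  p2 <- colMeans(g$dosage[sub == "P2", ]) / 2
  obs <- mean(abs(p1 - p2))
  # permutation null for the mean inter-subpopulation divergence
  set.seed(1)
  perm <- replicate(200, {
    sh <- sample(sub)
    mean(abs(colMeans(g$dosage[sh == "P1", ]) / 2 -
               colMeans(g$dosage[sh == "P2", ]) / 2))
  })
  expect_gt(mean(perm >= obs), 0.05)
})

test_that("markers in the same block are in much higher LD than distant ones", {
  r2_near <- r2_far <- numeric(0)
  for (s in 1:3) {
    spec <- genome_spec(n_chromosomes = 1, chrom_length_bp = 5e6,
                        n_markers_per_chrom = 300, ld_block_len_bp = 5e4,
                        seed = s)
    g <- simulate_genotypes(spec, 120)
    pr <- pairwise_r2(g, window = 40)
    r2_near <- c(r2_near, mean(pr$r2[pr$dist < 1e4]))
    r2_far <- c(r2_far, mean(pr$r2[pr$dist > 2e5]))
  }
  expect_gt(mean(r2_near), 3 * mean(r2_far))
})

test_that("phenotype simulation has exact additive dosage coding", {
  g <- small_geno(seed = 2, n = 60, chrom = 1, m_per = 50)
  mk <- g$map$marker[10]
  plan <- qtl_plan(effects = data.frame(marker = mk, trait = "TRL",
                                        effect = 1, treatment = "both"),
                   h2 = 1, gen_cv = 0)  # no polygenic term, no residual
  ph <- simulate_phenotypes(g, plan, n_reps = 1, seed = 4)
  trl <- ph[ph$trait == "TRL" & ph$treatment == "N+", ]
  v <- tapply(trl$value, trl$accession, mean)[rownames(g$dosage)]
  d2 <- names(v)[g$dosage[, mk] == 2]
  d0 <- names(v)[g$dosage[, mk] == 0]
  expect_gt(length(d2), 0)
  expect_gt(length(d0), 0)
  expect_equal(mean(v[d2]) - mean(v[d0]), 2, tolerance = 1e-10)
})

test_that("phenotypes are deterministic under seed and respond to treatment", {
  g <- small_geno(seed = 2, n = 60, chrom = 1, m_per = 50)
  plan <- qtl_plan()
  p1 <- simulate_phenotypes(g, plan, n_reps = 2, seed = 8)
  p2 <- simulate_phenotypes(g, plan, n_reps = 2, seed = 8)
  expect_identical(p1, p2)
  # size traits drop under N-, and derived R/S and NUE rise
  tt <- derive_traits(compute_blues(p1))
  expect_lt(mean(tt$SDW_Nm), mean(tt$SDW_Np))
  expect_lt(mean(tt$TRL_Nm), mean(tt$TRL_Np))
  expect_gt(mean(tt$RS_Nm), mean(tt$RS_Np))
  expect_gt(mean(tt$NUE_Nm), mean(tt$NUE_Np))
})

test_that("planted genetic correlation shows up in accession means", {
  g <- small_geno(seed = 13, n = 300, chrom = 2, m_per = 300)
  cormat <- .default_gen_cor_for_test(0.9)
  plan <- qtl_plan(h2 = 0.5, gen_cor = cormat)
  ph <- simulate_phenotypes(g, plan, n_reps = 3, seed = 21)
  trl <- tapply(ph$value[ph$trait == "TRL" & ph$treatment == "N+"],
                ph$accession[ph$trait == "TRL" & ph$treatment == "N+"], mean)
  rv <- tapply(ph$value[ph$trait == "RV" & ph$treatment == "N+"],
               ph$accession[ph$trait == "RV" & ph$treatment == "N+"], mean)
  expect_gte(cor(trl, rv[names(trl)]), 0.6)
})

test_that("count simulation is deterministic and null without planted DEGs", {
  plan <- counts_plan(n_genes = 300, dispersion = 0, sf_range = c(1, 1))
  c1 <- simulate_counts(plan, seed = 2)
  c2 <- simulate_counts(plan, seed = 2)
  expect_identical(c1$counts, c2$counts)
  expect_equal(dim(c1$counts), c(300, 16))
  # Poisson null: group means agree within sampling error
  sm <- c1$samples
  ln_m <- rowMeans(c1$counts[, sm$sample[sm$genotype == "LN" &
                                           sm$treatment == "N-"]])
  ln_p <- rowMeans(c1$counts[, sm$sample[sm$genotype == "LN" &
                                           sm$treatment == "N+"]])
  z <- (ln_m - ln_p) / sqrt((ln_m + ln_p) / 4)
  expect_lt(mean(abs(z[is.finite(z)]) > 4), 0.01)
})

test_that("planted fold change lands in the expected ratio band", {
  deg <- data.frame(gene = "Gene00001", genotype = "LN", log2fc = 2)
  ratios <- sapply(1:10, function(s) {
    plan <- counts_plan(n_genes = 50, dispersion = 0.1, deg_spec = deg,
                        baseline_meanlog = log(200), baseline_sdlog = 0)
    cc <- simulate_counts(plan, seed = s)
    norm <- normalize_counts(cc$counts)$normalized
    sm <- cc$samples
    mean(norm["Gene00001", sm$sample[sm$genotype == "LN" &
                                       sm$treatment == "N-"]]) /
      mean(norm["Gene00001", sm$sample[sm$genotype == "LN" &
                                         sm$treatment == "N+"]])
  })
  expect_true(all(ratios > 2.5 & ratios < 6.5))
})

test_that("annotation tiling covers the genome with valid intervals", {
  spec <- genome_spec(n_chromosomes = 1, chrom_length_bp = 1e6, seed = 1)
  ann <- make_annotation(spec, n_genes = 10, gene_len_bp = 1000)
  expect_equal(nrow(ann), 10)
  expect_true(all(ann$start >= 1 & ann$end <= 1e6))
  expect_true(all(ann$end - ann$start + 1 == 1000))
  # non-overlapping
  expect_true(all(diff(ann$start) > 1000))
  expect_error(make_annotation(spec, n_genes = 2000, gene_len_bp = 1000),
               "too short")
})
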