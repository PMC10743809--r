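test_that("Mann-Whitney exact p matches full enumeration (oracle)", {
  # enumeration oracle over all C(n1+n2, n1) label assignments
  exact_p <- function(a, b) {
    pool <- c(a, b)
    n1 <- length(a)
    idx <- utils::combn(length(pool), n1)
    u_obs <- sum(rank(pool)[seq_len(n1)]) - n1 * (n1 + 1) / 2
    u_all <- apply(idx, 2, function(i)
      sum(rank(pool)[i]) - n1 * (n1 + 1) / 2)
    mu <- n1 * (length(b)) / 2
    mean(abs(u_all - mu) >= abs(u_obs - mu))
  }
  cases <- list(list(c(1, 2), c(3, 4)),
                list(c(5, 1, 7), c(2, 9, 11, 4)),
                list(c(0.3, 0.9, 2.2, 1.4), c(0.1, 0.5, 0.7, 3.0)))
  for (cs in cases) {
    vals <- c(cs[[1]], cs[[2]])
    dos <- c(rep(0, length(cs[[1]])), rep(2, length(cs[[2]])))
    res <- allele_effect_test(vals, dos)
    expect_equal(res$p, exact_p(cs[[1]], cs[[2]]), tolerance = 1e-12)
  }
  # the canonical small case: {1,2} vs {3,4} has exact two-sided p = 1/3
  res <- allele_effect_test(c(1, 2, 3, 4), c(0, 0, 2, 2))
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  expect_equal(res$favorable_dosage, 2)
})

test_that("all-tied groups give p = 1 and tiny classes are untestable", {
  res <- allele_effect_test(rep(5, 6), c(0, 0, 0, 2, 2, 2))
  expect_equal(res$p, 1)
  res2 <- allele_effect_test(1:5, c(0, 2, 2, 2, 2))
  expect_false(res2$testable)
  expect_match(res2$reason, "< 2 members")
})

test_that("heterozygotes are excluded by default, pooled on request", {
  vals <- c(1, 2, 10, 11, 5, 6)
  dos <- c(0, 0, 2, 2, 1, 1)
  res <- allele_effect_test(vals, dos)
  expect_equal(res$n0 + res$n2, 4)
  res2 <- allele_effect_test(vals, dos, het = "pool")
  expect_equal(res2$n0 + res2$n2, 6)
})

test_that("QTN merging follows the link-distance rule and chains", {
  qtns <- data.frame(marker = c("a", "b"), chrom = 1,
                     pos = c(10000, 12000), trait = "T1",
                     effect = 1, lod = 4, p = 1e-4, r2 = c(5, 7),
                     models = "mlA", mw_p = 0.01, favorable_dosage = 2)
  dec <- structure(list(rho = NA, n = 100, method = "binned-median",
                        scope = "genome", max_dist = 2e5,
                        curve = data.frame(dist = c(13000, 14000),
                                           r2 = c(0.5, 0.2))),
                   class = "ld_decay")
  # decay_distance(0.3) = 14000 -> link distance 0.75 * 14000 = 10500
  qt <- merge_qtns(qtns, dec)
  expect_equal(nrow(qt$qtls), 1)
  qtns2 <- transform(qtns, pos = c(10000, 25000))
  qtns2$marker <- c("a", "b")
  qt2 <- merge_qtns(qtns2, dec)
  expect_equal(nrow(qt2$qtls), 2)
  # chain linkage: 0 / 9000 / 18000 with d_c = 10500 forms one QTL
  qtns3 <- data.frame(marker = c("a", "b", "c"), chrom = 1,
                      pos = c(1000, 10000, 19000), trait = "T1",
                      effect = 1, lod = 4, p = 1e-4, r2 = c(5, 9, 7),
                      models = "mlA", mw_p = 0.01, favorable_dosage = 2)
  qt3 <- merge_qtns(qtns3, dec)
  expect_equal(nrow(qt3$qtls), 1)
  expect_equal(qt3$qtls$rep_marker, "b")  # max R2 member
  expect_equal(qt3$qtls$qtl_id, "Lu1_10000")
})

test_that("merging recovers a constructed clustering exactly and is order-invariant", {
  set.seed(11)
  dc <- 10500  # from the binned profile above: 0.75 * 14000
  dec <- structure(list(rho = NA, n = 100, method = "binned-median",
                        scope = "genome", max_dist = 1e7,
                        curve = data.frame(dist = c(13000, 14000),
                                           r2 = c(0.5, 0.2))),
                   class = "ld_decay")
  # construct clusters with intra-gaps < dc and inter-gaps > dc
  n_clusters <- 40
  starts <- cumsum(c(1e4, rep(3e5, n_clusters - 1)))
  pos <- unlist(lapply(starts, function(s)
    s + cumsum(c(0, sample(2000:9000, sample(1:4, 1))))))
  qtns <- data.frame(marker = sprintf("m%03d", seq_along(pos)), chrom = 2,
                     pos = pos,
                     trait = sample(c("T1", "T2"), length(pos), TRUE),
                     effect = 1, lod = 4, p = 1e-4,
                     r2 = runif(length(pos), 1, 15), models = "mlA",
                     mw_p = 0.01, favorable_dosage = 2)
  qt <- merge_qtns(qtns, dec)
  expect_equal(nrow(qt$qtls), n_clusters)
  # every QTN belongs to exactly one QTL
  expect_equal(sort(qt$members$marker), sort(qtns$marker))
  expect_equal(anyDuplicated(qt$members$marker), 0)
  # representative R2 is the member maximum
  for (qid in qt$qtls$qtl_id)
    expect_equal(qt$qtls$rep_r2[qt$qtls$qtl_id == qid],
                 max(qt$members$r2[qt$members$qtl_id == qid]))
  # input order invariance
  qt_sh <- merge_qtns(qtns[sample(nrow(qtns)), ], dec)
  expect_equal(qt_sh$qtls, qt$qtls)
})

test_that("major and pleiotropic classification uses strict thresholds", {
  qtns <- data.frame(marker = c("a", "b", "c"), chrom = 1,
                     pos = c(1e4, 3e6, 3e6), trait = c("T1", "T1", "T2"),
                     effect = 1, lod = 4, p = 1e-4, r2 = c(10.0, 12, 3),
                     models = "mlA", mw_p = 0.01, favorable_dosage = 2)
  dec <- structure(list(rho = NA, n = 100, method = "binned-median",
                        scope = "genome", max_dist = 1e7,
                        curve = data.frame(dist = 1000, r2 = 0.1)),
                   class = "ld_decay")
  qt <- classify_qtls(merge_qtns(qtns, dec))
  q1 <- qt$qtls[qt$qtls$rep_pos == 1e4, ]
  expect_false(q1$major)       # R2 = 10.0 is not > 10 (strict)
  expect_false(q1$pleiotropic)
  q2 <- qt$qtls[qt$qtls$rep_pos == 3e6, ]
  expect_true(q2$major)
  expect_true(q2$pleiotropic)
})

test_that("QTL regression reproduces the adjusted-R2 formula", {
  set.seed(2)
  y <- rnorm(100)
  x <- y  # perfect predictor
  r <- qtl_regression(y, cbind(x))
  expect_equal(r$r2, 1, tolerance = 1e-12)
  expect_equal(r$adj_r2, 1, tolerance = 1e-12)
  # formula check at R2 = 0.5, n = 100, p = 1
  x2 <- rnorm(100)
  y2 <- x2 + rnorm(100)
  fit <- summary(lm(y2 ~ x2))
  r2 <- qtl_regression(y2, cbind(x2))
  expect_equal(r2$adj_r2, 1 - (1 - r2$r2) * 99 / 98, tolerance = 1e-12)
  expect_equal(r2$adj_r2, fit$adj.r.squared, tolerance = 1e-10)
  expect_error(qtl_regression(rnorm(5), matrix(rnorm(25), 5)), "prune")
})

test_that("favorable-allele counts behave and deciles round as 12/123", {
  g <- small_geno(seed = 12, n = 123, chrom = 1, m_per = 200)
  mks <- g$map$marker[c(20, 80, 140)]
  set.seed(5)
  y <- rowSums(g$dosage[, mks]) + rnorm(123, sd = 0.5)
  traits <- data.frame(accession = rownames(g$dosage), T1 = y)
  qtns <- data.frame(marker = mks, chrom = 1,
                     pos = g$map$pos[match(mks, g$map$marker)],
                     trait = "T1", effect = 1, lod = 5, p = 1e-5,
                     r2 = c(8, 9, 10), models = "mlA", mw_p = 0.01,
                     favorable_dosage = 2)
  dec <- structure(list(rho = NA, n = 123, method = "binned-median",
                        scope = "genome", max_dist = 1e7,
                        curve = data.frame(dist = 1000, r2 = 0.1)),
                   class = "ld_decay")
  qt <- classify_qtls(merge_qtns(qtns, dec))
  fav <- count_favorable_alleles(traits, qt, g, "T1")
  expect_equal(fav$decile_size, 12)
  expect_equal(nrow(fav$top), 12)
  # carriers of all favorable alleles count the full QTL tally
  all_fav <- rowSums(g$dosage[, mks] == 2) == 3
  if (any(all_fav))
    expect_true(all(fav$counts$n_favorable[all_fav] == nrow(qt$qtls)))
  # construction implies positive association
  ct <- cor.test(fav$counts$n_favorable, fav$counts$trait_value,
                 method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("validation removes untestable or non-significant QTNs monotonically", {
  run <- demo_run()
  expect_gte(nrow(run$qtns), nrow(run$qtns_valid))
  expect_gte(nrow(run$qtns_valid), nrow(run$qtl$qtls))
  expect_true(all(run$qtns_valid$mw_p < 0.05))
  removed <- attr(run$qtns_valid, "removed")
  if (nrow(removed)) expect_true(all(!is.na(removed$reason)))
})
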