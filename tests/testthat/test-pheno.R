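test_that("BLUEs equal replicate means for balanced designs", {
  raw <- data.frame(accession = "A1", treatment = "N+",
                    replicate = 1:3, trait = "TRL", value = c(10, 12, 14))
  raw <- rbind(raw, transform(raw, treatment = "N-"))
  b <- compute_blues(raw)
  expect_equal(b$value[b$treatment == "N+"], 12)
  # single replicate passes through
  one <- raw[raw$replicate == 1, ]
  expect_equal(compute_blues(one)$value, c(10, 10))
})

test_that("unbalanced BLUEs match the normal-equations least-squares means", {
  raw <- toy_raw(n_acc = 3, n_rep = 3, seed = 2)
  raw <- raw[raw$trait == "TRL" & raw$treatment == "N+", ]
  raw <- raw[!(raw$accession == "A02" & raw$replicate == 3), ]  # unbalance
  b <- compute_blues(raw)
  # independent oracle: solve the normal equations of the two-factor
  # fixed-effects model directly and average predictions over replicates
  A <- stats::model.matrix(~ 0 + factor(accession) + factor(replicate),
                           data = raw)
  beta <- solve(crossprod(A), crossprod(A, raw$value))
  grid <- expand.grid(accession = unique(raw$accession),
                      replicate = unique(raw$replicate))
  Ag <- stats::model.matrix(~ 0 + factor(accession) + factor(replicate),
                            data = grid)
  pred <- drop(Ag %*% beta)
  oracle <- tapply(pred, grid$accession, mean)
  expect_equal(b$value[match(names(oracle), b$accession)],
               as.numeric(oracle), tolerance = 1e-10)
})

test_that("compute_blues reports empty cells explicitly", {
  raw <- toy_raw(n_acc = 2, n_rep = 2)
  raw <- raw[!(raw$accession == "A01" & raw$treatment == "N-"), ]
  expect_error(compute_blues(raw), "empty")
})

test_that("trait derivation implements the published formulas", {
  raw <- toy_raw(n_acc = 5, n_rep = 2, seed = 3)
  tt <- derive_traits(compute_blues(raw))
  expect_identical(setdiff(names(tt), "accession"), nue_trait_names())
  expect_equal(ncol(tt) - 1, 21)
  # NUE = PDW / (shootN + rootN): spot value
  b <- compute_blues(raw)
  pick <- function(tr, w) b$value[b$accession == "A01" & b$trait == tr &
                                    b$treatment == w]
  expect_equal(tt$NUE_Np[tt$accession == "A01"],
               pick("PDW", "N+") / (pick("shootN", "N+") + pick("rootN", "N+")))
  expect_equal(tt$RS_Nm[tt$accession == "A01"],
               pick("RDW", "N-") / pick("SDW", "N-"))
  expect_equal(tt$TRL_Index[tt$accession == "A01"],
               100 * pick("TRL", "N-") / pick("TRL", "N+"))
})

test_that("NUE formula gives 25 for PDW 100 mg and 4 mg plant N", {
  expect_equal(100 / 4, 25)  # anchor for the next assertion
  raw <- toy_raw(n_acc = 2, n_rep = 1)
  raw$value[raw$trait == "PDW"] <- 100
  raw$value[raw$trait == "shootN"] <- 3
  raw$value[raw$trait == "rootN"] <- 1
  tt <- derive_traits(compute_blues(raw))
  expect_equal(tt$NUE_Np, c(25, 25))
})

test_that("stress tolerance index is 1 when both NUE columns are at the N+ mean", {
  raw <- toy_raw(n_acc = 4, n_rep = 1)
  # identical PDW and plant N everywhere => NUE constant across accessions
  # and treatments, hence STI = (m * m) / m^2 = 1 exactly
  raw$value[raw$trait == "PDW"] <- 90
  raw$value[raw$trait == "shootN"] <- 2.5
  raw$value[raw$trait == "rootN"] <- 0.5
  tt <- derive_traits(compute_blues(raw))
  expect_equal(tt$NUE_STI, rep(1, 4), tolerance = 1e-12)
})

test_that("indices are exactly 100% under N-/N+ equality and scale-consistent", {
  raw <- toy_raw(n_acc = 3, n_rep = 1, seed = 5)
  sym <- raw[raw$treatment == "N+", ]
  sym2 <- transform(sym, treatment = "N-")
  tt <- derive_traits(compute_blues(rbind(sym, sym2)))
  for (cn in paste0(c("TRL", "RV", "RT", "PDW", "SDW"), "_Index"))
    expect_equal(tt[[cn]], rep(100, 3), tolerance = 1e-12)
  expect_equal(tt$NUE_Index, rep(100, 3), tolerance = 1e-12)
  # multiplying weights and N content by the same constant leaves NUE fixed
  raw2 <- raw
  sel <- raw2$trait %in% c("PDW", "shootN", "rootN")
  raw2$value[sel] <- raw2$value[sel] * 7
  tt1 <- derive_traits(compute_blues(raw))
  tt2 <- derive_traits(compute_blues(raw2))
  expect_equal(tt1$NUE_Np, tt2$NUE_Np, tolerance = 1e-12)
  expect_equal(tt1$NUE_STI, tt2$NUE_STI, tolerance = 1e-12)
})

test_that("trait summaries report mean, SD and CV correctly", {
  tt <- data.frame(accession = c("a", "b", "c"), X = c(1, 2, 3),
                   const = c(2, 2, 2))
  s <- summarize_traits(tt)
  expect_equal(s$mean[s$trait == "X"], 2)
  expect_equal(s$sd[s$trait == "X"], 1)
  expect_equal(s$cv[s$trait == "X"], 50)
  expect_equal(s$sd[s$trait == "const"], 0)
  expect_equal(s$cv[s$trait == "const"], 0)
})

test_that("two-way effect tests are calibrated and powered", {
  # power: a 3-residual-SD treatment shift must be overwhelming
  set.seed(1)
  n_acc <- 50
  raw <- expand.grid(accession = sprintf("A%02d", 1:n_acc),
                     treatment = c("N+", "N-"), replicate = 1:2,
                     trait = "TRL", stringsAsFactors = FALSE)
  raw$value <- rnorm(nrow(raw)) + 3 * (raw$treatment == "N-")
  eff <- test_effects(raw)
  expect_lt(eff$p_treatment, 1e-3)
  # identical data for all genotypes: genotype p near 1
  raw2 <- raw
  raw2$value <- rep(c(1, 2, 3, 4), length.out = nrow(raw2)) +
    0.001 * rnorm(nrow(raw2))
  raw2$value <- ave(raw2$value, raw2$treatment, raw2$replicate) +
    1e-6 * rnorm(nrow(raw2))
  eff2 <- test_effects(raw2)
  expect_gt(eff2$p_genotype, 0.5)
  # no replication: interaction not estimable
  raw3 <- raw[raw$replicate == 1, ]
  eff3 <- test_effects(raw3)
  expect_true(is.na(eff3$p_interaction))
})

test_that("trait correlations are symmetric with unit diagonal", {
  tt <- data.frame(accession = letters[1:10], x = 1:10, y = -(1:10),
                   z = rnorm(10))
  ct <- correlate_traits(tt)
  expect_equal(unname(diag(ct$r)), rep(1, 3))
  expect_equal(ct$r, t(ct$r))
  expect_equal(ct$r["x", "y"], -1)
  expect_lt(ct$p["x", "y"], 1e-10)
  # zero-variance trait: NA correlations
  tt$w <- 5
  ct2 <- correlate_traits(tt)
  expect_true(all(is.na(ct2$r["w", c("x", "y", "z")])))
})
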