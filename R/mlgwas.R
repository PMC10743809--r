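#' REML variance components of the kinship mixed model
#'
#' Fits `y = X beta + g + e`, `g ~ N(0, sigma_g^2 G)`,
#' `e ~ N(0, sigma_e^2 I)` by restricted maximum likelihood, using a
#' spectral decomposition of `G` and one-dimensional optimization over
#' `log(delta)` with `delta = sigma_e^2 / sigma_g^2` (the EMMA approach).
#' Deterministic; no random starts.
#'
#' @param y numeric phenotype vector (no missing values).
#' @param G positive semi-definite relatedness matrix (e.g. from
#'   [vanraden_grm()]).
#' @param X fixed-effect design matrix; default intercept only.
#' @return object of class `vc_fit`: `sigma_g2`, `sigma_e2`, `delta`,
#'   `h2`, `loglik` (REML), `beta`, and the spectral pieces (`U`, `D`)
#'   for reuse by [scan_stage1()]. If `G` carries no relatedness signal
#'   (near-identical eigenvalues) the split is unidentifiable and flagged
#'   via `note`.
#' @export
fit_null_vc <- function(y, G, X = NULL) {
  n <- length(y)
  stopifnot(n >= 10, nrow(G) == n, ncol(G) == n, !anyNA(y))
  if (stats::var(y) == 0) stop("phenotype has zero variance")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- ncol(X)
  ed <- eigen(G, symmetric = TRUE)
  if (min(ed$values) < -1e-6 * max(abs(ed$values)))
    stop("G is not positive semi-definite")
  D <- pmax(ed$values, 0)
  U <- ed$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)

  reml <- function(log_delta) {
    w <- D + exp(log_delta)
    XtWX <- crossprod(Xs, Xs / w)
    beta <- solve(XtWX, crossprod(Xs, ys / w))
    r <- ys - Xs %*% beta
    rss <- sum(r^2 / w)
    sg2 <- rss / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * sg2) + 1) + sum(log(w)) +
              determinant(XtWX, logarithm = TRUE)$modulus[1])
  }
  opt <- stats::optimize(reml, c(-12, 12), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  w <- D + delta
  XtWX <- crossprod(Xs, Xs / w)
  beta <- solve(XtWX, crossprod(Xs, ys / w))
  rss <- sum((ys - Xs %*% beta)^2 / w)
  sg2 <- rss / (n - p)
  note <- if (diff(range(D)) < 1e-8 * max(1, max(D)))
    "G has no eigenvalue spread: sigma_g2/sigma_e2 split unidentifiable"
  else NA_character_
  # h2 = fraction of phenotypic variance that is genetic; the genetic
  # variance is sigma_g2 * tr(G)/n, not sigma_g2 itself, when the GRM
  # diagonal is inflated (e.g. inbred panels).
  trG <- mean(D)
  structure(list(sigma_g2 = sg2, sigma_e2 = sg2 * delta, delta = delta,
                 h2 = sg2 * trG / (sg2 * trG + sg2 * delta),
                 loglik = opt$objective,
                 beta = drop(beta), U = U, D = D, X = X, note = note),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("vc_fit: sigma_g2=%.4g sigma_e2=%.4g h2=%.3f REML logLik=%.2f\n",
              x$sigma_g2, x$sigma_e2, x$h2, x$loglik))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Stage-1 kinship-adjusted single-marker screen (P3D)
#'
#' Generalized-least-squares Wald test per marker, reusing the null-model
#' variance-component ratio for every marker (population parameters
#' previously determined). Monomorphic markers and markers collinear with
#' the covariates receive `NA` p-values.
#'
#' @param y phenotype vector aligned with `geno` accessions.
#' @param geno a `geno_matrix`.
#' @param vc null-model fit from [fit_null_vc()]; computed from `G` when
#'   omitted.
#' @param G relatedness matrix (required if `vc` is missing).
#' @param X covariate matrix (default intercept only).
#' @return data.frame: marker, chrom, pos, beta, se, p.
#' @export
scan_stage1 <- function(y, geno, vc = NULL, G = NULL, X = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (is.null(vc)) {
    if (is.null(G)) stop("supply either a vc_fit or G")
    vc <- fit_null_vc(y, G, X)
  }
  geno <- impute_dosages(geno)
  Z <- geno$dosage
  n <- nrow(Z)
  stopifnot(length(y) == n)
  U <- vc$U
  w <- vc$D + vc$delta
  Xs <- crossprod(U, vc$X)
  p_cov <- ncol(Xs)
  ys <- crossprod(U, y)
  Zs <- crossprod(U, Z)

  Xw <- Xs / w
  XtWX <- crossprod(Xs, Xw)
  Ainv <- solve(XtWX)
  Xty <- crossprod(Xs, ys / w)
  yWy <- sum(ys^2 / w)
  rss_null <- yWy - drop(crossprod(Xty, Ainv %*% Xty))

  B <- crossprod(Xs, Zs / w)                # p_cov x m
  czz <- colSums(Zs^2 / w)
  czy <- colSums(Zs * drop(ys) / w)
  AinvB <- Ainv %*% B
  S <- czz - colSums(B * AinvB)
  num <- czy - drop(crossprod(B, Ainv %*% Xty))
  ok <- S > 1e-10 * pmax(czz, 1)
  beta <- num / S
  rss <- pmax(rss_null - num^2 / S, 0)
  df <- n - p_cov - 1
  sigma2 <- rss / df
  se <- sqrt(sigma2 / S)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  pval[!ok] <- NA_real_
  beta[!ok] <- NA_real_
  se[!ok] <- NA_real_
  data.frame(marker = geno$map$marker, chrom = geno$map$chrom,
             pos = geno$map$pos, beta = beta, se = se, p = pval)
}

#' Multi-marker refinement by extended-BIC forward selection
#'
#' Fits all stage-1 candidate markers jointly: forward selection over the
#' candidate pool by extended BIC (`EBIC = n log(RSS/n) + k log(n) +
#' 2 gamma log C(M, k)`), then a likelihood-ratio test by single-term
#' deletion for each retained marker. `LOD = LRT / (2 ln 10)`; `p` from
#' the chi-squared distribution with 1 df; `R2` is the percentage of
#' phenotypic variance explained by the marker term. Only markers with
#' `LOD > lod_min` are reported.
#'
#' @param y phenotype vector.
#' @param geno a `geno_matrix`.
#' @param candidates character vector of candidate marker ids (stage-1
#'   survivors). May be empty.
#' @param X covariate matrix (default intercept only).
#' @param ebic_gamma extended-BIC gamma in \[0, 1\].
#' @param lod_min LOD retention threshold (default 3).
#' @return data.frame: marker, chrom, pos, effect, lod, p, r2.
#' @export
multilocus_refine <- function(y, geno, candidates, X = NULL,
                              ebic_gamma = 0.5, lod_min = 3) {
  stopifnot(inherits(geno, "geno_matrix"))
  empty <- data.frame(marker = character(), chrom = integer(),
                      pos = integer(), effect = numeric(), lod = numeric(),
                      p = numeric(), r2 = numeric())
  candidates <- intersect(candidates, geno$map$marker)
  if (!length(candidates)) return(empty)
  geno <- impute_dosages(geno)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  Zc <- geno$dosage[, candidates, drop = FALSE]
  n_cand <- length(candidates)
  # EBIC model space: size-k subsets of the genome-wide panel (the
  # candidates were screened from all markers, not just the pool)
  M <- ncol(geno$dosage)

  ebic <- function(rss, k)
    n * log(max(rss, 1e-300) / n) + k * log(n) + 2 * ebic_gamma * lchoose(M, k)

  sel <- integer(0)
  dropped <- character(0)
  cur <- X
  rss_cur <- sum(stats::lm.fit(cur, y)$residuals^2)
  crit_cur <- ebic(rss_cur, 0)
  repeat {
    remaining <- setdiff(seq_len(n_cand), sel)
    if (!length(remaining)) break
    rss_try <- rep(Inf, length(remaining))
    for (ii in seq_along(remaining)) {
      j <- remaining[ii]
      f <- stats::lm.fit(cbind(cur, Zc[, j]), y)
      # collinear additions change nothing: detect via rank deficiency
      if (f$rank < ncol(cur) + 1) next
      rss_try[ii] <- sum(f$residuals^2)
    }
    best <- which.min(rss_try)
    crit_new <- ebic(rss_try[best], length(sel) + 1)
    if (!is.finite(rss_try[best]) || crit_new >= crit_cur) break
    sel <- c(sel, remaining[best])
    cur <- cbind(cur, Zc[, remaining[best]])
    rss_cur <- rss_try[best]
    crit_cur <- crit_new
    if (rss_cur < 1e-12 * sum((y - mean(y))^2)) break  # perfect fit
  }
  if (!length(sel)) return(empty)

  mk <- candidates[sel]
  full <- stats::lm.fit(cbind(X, Zc[, sel, drop = FALSE]), y)
  if (full$rank < ncol(X) + length(sel)) {
    # drop aliased later-entered markers
    keep <- !is.na(full$coefficients[-(seq_len(ncol(X)))])
    dropped <- mk[!keep]
    sel <- sel[keep]; mk <- mk[keep]
    full <- stats::lm.fit(cbind(X, Zc[, sel, drop = FALSE]), y)
  }
  rss_full <- sum(full$residuals^2)
  vy <- stats::var(y) * (n - 1)
  eff <- full$coefficients[ncol(X) + seq_along(sel)]
  lrt <- lod <- pv <- r2 <- numeric(length(sel))
  for (ii in seq_along(sel)) {
    red <- stats::lm.fit(cbind(X, Zc[, sel[-ii], drop = FALSE]), y)
    rss_red <- sum(red$residuals^2)
    lrt[ii] <- if (rss_full <= 1e-300) Inf else n * log(rss_red / rss_full)
    r2[ii] <- 100 * stats::var(Zc[, sel[ii]] * eff[ii]) * (n - 1) / vy
  }
  lod <- lrt / (2 * log(10))
  pv <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  map <- geno$map[match(mk, geno$map$marker), ]
  res <- data.frame(marker = mk, chrom = map$chrom, pos = map$pos,
                    effect = unname(eff), lod = lod, p = pv, r2 = r2)
  res <- res[res$lod > lod_min, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped_collinear") <- dropped
  res
}

#' Default configuration variants for the multi-locus ensemble
#'
#' Three variants differing in stage-1 screening p-threshold and
#' extended-BIC gamma, whose union emulates an ensemble of multi-locus
#' mixed-model methods.
#' @return named list of lists with `stage1_p` and `ebic_gamma`.
#' @export
default_variants <- function() {
  list(mlA = list(stage1_p = 0.01, ebic_gamma = 0.5),
       mlB = list(stage1_p = 0.005, ebic_gamma = 1),
       mlC = list(stage1_p = 0.05, ebic_gamma = 0.5))
}

#' Multi-locus GWAS over traits and configuration variants
#'
#' For each trait and variant, runs the two-stage scan (kinship-adjusted
#' P3D screen at the variant's `stage1_p`, then extended-BIC multi-marker
#' refinement) and unions the resulting QTNs. Duplicate marker-trait
#' records are collapsed keeping the maximum-LOD record; the `models`
#' column lists every variant that found the QTN. Zero-variance traits are
#' skipped with a message.
#'
#' @param traits trait table (column `accession` + numeric trait columns),
#'   e.g. from [derive_traits()].
#' @param geno a `geno_matrix` whose accessions cover the trait table.
#' @param G relatedness matrix; [vanraden_grm()] of `geno` when omitted.
#' @param variants list of configuration variants, as
#'   [default_variants()].
#' @param X optional covariates.
#' @param lod_min LOD retention threshold (default 3).
#' @return object of class `qtn_table`: data.frame marker, chrom, pos,
#'   trait, effect, lod, p, r2, models.
#' @export
run_mlgwas <- function(traits, geno, G = NULL, variants = default_variants(),
                       X = NULL, lod_min = 3) {
  stopifnot(inherits(geno, "geno_matrix"), length(variants) >= 1)
  acc <- traits$accession
  stopifnot(!is.null(acc), all(acc %in% rownames(geno$dosage)))
  geno <- impute_dosages(geno)
  geno$dosage <- geno$dosage[match(acc, rownames(geno$dosage)), , drop = FALSE]
  if (is.null(G)) G <- vanraden_grm(geno)
  G <- G[acc, acc]
  trait_cols <- setdiff(names(traits), "accession")
  recs <- vector("list", 0)
  for (tr in trait_cols) {
    y <- traits[[tr]]
    if (anyNA(y) || stats::var(y) == 0) {
      message("run_mlgwas: skipping trait ", tr,
              " (missing values or zero variance)")
      next
    }
    vc <- fit_null_vc(y, G, X)
    s1 <- scan_stage1(y, geno, vc = vc, X = X)
    for (vn in names(variants)) {
      v <- variants[[vn]]
      cand <- s1$marker[!is.na(s1$p) & s1$p < v$stage1_p]
      q <- multilocus_refine(y, geno, cand, X = X,
                             ebic_gamma = v$ebic_gamma, lod_min = lod_min)
      if (nrow(q)) {
        q$trait <- tr
        q$models <- vn
        recs[[length(recs) + 1]] <- q
      }
    }
  }
  if (!length(recs)) {
    out <- data.frame(marker = character(), chrom = integer(),
                      pos = integer(), trait = character(),
                      effect = numeric(), lod = numeric(), p = numeric(),
                      r2 = numeric(), models = character())
    class(out) <- c("qtn_table", "data.frame")
    return(out)
  }
  all <- do.call(rbind, recs)
  key <- paste(all$marker, all$trait, sep = "\r")
  models <- vapply(split(all$models, key),
                   function(x) paste(sort(unique(x)), collapse = ","), "")
  best <- do.call(rbind, lapply(split(all, key), function(d)
    d[which.max(d$lod), , drop = FALSE]))
  best$models <- models[rownames(best)]
  best <- best[order(best$trait, best$chrom, best$pos),
               c("marker", "chrom", "pos", "trait", "effect", "lod", "p",
                 "r2", "models")]
  rownames(best) <- NULL
  class(best) <- c("qtn_table", "data.frame")
  best
}

#' @export
print.qtn_table <- function(x, ...) {
  cat("qtn_table:", nrow(x), "QTN records across",
      length(unique(x$trait)), "trait(s)\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
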