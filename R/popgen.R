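#' Pairwise LD (r-squared) within a sliding marker window
#'
#' For each marker, computes the squared Pearson correlation of dosage
#' vectors against the next `window` markers on the same chromosome
#' (window measured in markers, the convention of standard LD software).
#' Monomorphic markers are skipped; the number of skipped pairs is
#' recorded in the `"n_skipped"` attribute. Missing dosages are
#' mean-imputed first.
#'
#' @param geno a `geno_matrix`.
#' @param window number of downstream markers paired with each marker.
#' @return data.frame: chrom, pos_i, pos_j, dist, r2.
#' @export
pairwise_r2 <- function(geno, window = 50) {
  stopifnot(inherits(geno, "geno_matrix"), window >= 1)
  geno <- impute_dosages(geno)
  out <- vector("list", 0)
  n_skipped <- 0L
  for (ch in unique(geno$map$chrom)) {
    sel <- geno$map$chrom == ch
    if (sum(sel) < 2) next
    d <- geno$dosage[, sel, drop = FALSE]
    pos <- geno$map$pos[sel]
    n <- nrow(d)
    sds <- apply(d, 2, stats::sd)
    z <- d
    poly <- sds > 0
    z[, poly] <- scale(d[, poly, drop = FALSE])
    m <- ncol(z)
    for (k in seq_len(min(window, m - 1))) {
      i <- seq_len(m - k)
      j <- i + k
      r <- colSums(z[, i, drop = FALSE] * z[, j, drop = FALSE]) / (n - 1)
      ok <- poly[i] & poly[j]
      n_skipped <- n_skipped + sum(!ok)
      if (!any(ok)) next
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, pos_i = pos[i][ok], pos_j = pos[j][ok],
        dist = pos[j][ok] - pos[i][ok], r2 = (r^2)[ok])
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = integer(), pos_i = integer(), pos_j = integer(),
               dist = integer(), r2 = numeric())
  res <- res[order(res$chrom, res$pos_i, res$pos_j), ]
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

# Hill & Weir (1988) expectation of r2 at recombination "C" and sample size n
hill_weir_r2 <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit an LD-decay profile to distance-binned r2 pairs
#'
#' Fits the Hill-Weir expectation of r2 as a function of distance by
#' nonlinear least squares (parameter: recombination per bp, `rho`). If
#' the fit fails to converge, a binned-median interpolation fallback is
#' used and flagged.
#'
#' @param pairs LD pair table from [pairwise_r2()] (optionally subset to a
#'   chromosome for chromosome-specific decay).
#' @param n sample size (number of accessions) used in the Hill-Weir
#'   expectation.
#' @param scope label stored on the profile ("genome" or a chromosome id).
#' @param n_bins bins for the fallback median curve.
#' @return object of class `ld_decay` with elements `rho`, `n`, `method`
#'   ("hill-weir" or "binned-median"), `scope`, `max_dist` and the binned
#'   curve.
#' @export
fit_ld_decay <- function(pairs, n, scope = "genome", n_bins = 50) {
  if (nrow(pairs) < 50) stop("need >= 50 LD pairs to fit a decay profile")
  d <- pairs$dist
  r2 <- pairs$r2
  brk <- unique(stats::quantile(d, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(d, brk, include.lowest = TRUE)
  curve <- data.frame(dist = tapply(d, bin, stats::median),
                      r2 = tapply(r2, bin, stats::median))
  curve <- curve[stats::complete.cases(curve), ]
  fit <- tryCatch({
    df <- data.frame(d = d, r2 = r2)
    f <- minpack.lm::nlsLM(r2 ~ hill_weir_r2(rho * d, n), data = df,
                           start = list(rho = 1 / stats::median(d)),
                           lower = 1e-12, upper = 1,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(f)[["rho"]]
  }, error = function(e) NA_real_)
  method <- if (is.na(fit)) "binned-median" else "hill-weir"
  structure(list(rho = fit, n = n, method = method, scope = scope,
                 max_dist = max(d), curve = curve),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat(sprintf("ld_decay [%s] method=%s", x$scope, x$method))
  if (!is.na(x$rho)) cat(sprintf(" rho=%.3g/bp", x$rho))
  d01 <- decay_distance(x, 0.1)
  cat(sprintf("; decay_distance(0.1)=%s bp%s\n", format(round(d01)),
              if (isTRUE(attr(d01, "censored"))) " (right-censored)" else ""))
  invisible(x)
}

#' Distance at which the fitted expected r2 falls to a threshold
#'
#' @param profile an `ld_decay` profile.
#' @param threshold r2 threshold (e.g. 0.1 genome-wide, 0.3 for QTN
#'   merging).
#' @return distance in bp. If the curve never falls below the threshold
#'   within the observed range, the maximum observed distance is returned
#'   with attribute `censored = TRUE`.
#' @export
decay_distance <- function(profile, threshold) {
  stopifnot(inherits(profile, "ld_decay"), threshold > 0, threshold < 1)
  if (profile$method == "hill-weir") {
    f <- function(d) hill_weir_r2(profile$rho * d, profile$n) - threshold
    upper <- profile$max_dist
    if (f(upper) > 0)
      return(structure(profile$max_dist, censored = TRUE))
    if (f(1e-9) <= 0) return(structure(0, censored = FALSE))
    structure(stats::uniroot(f, c(1e-9, upper))$root, censored = FALSE)
  } else {
    cv <- profile$curve[order(profile$curve$dist), ]
    below <- which(cv$r2 <= threshold)
    if (!length(below))
      return(structure(profile$max_dist, censored = TRUE))
    structure(cv$dist[below[1]], censored = FALSE)
  }
}

#' Identity-by-state kinship matrix
#'
#' Entry (i, j) is the mean over markers of `1 - |d_i - d_j| / 2`, i.e.
#' average allele sharing; the diagonal is 1. Missing dosages are
#' mean-imputed and rounded to the nearest integer dosage first.
#'
#' @param geno a `geno_matrix`.
#' @return symmetric accession x accession matrix in \[0, 1\].
#' @export
ibs_kinship <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  d <- round(impute_dosages(geno)$dosage)
  m <- ncol(d)
  a0 <- (d == 0) + 0; a1 <- (d == 1) + 0; a2 <- (d == 2) + 0
  # |di-dj| summed over markers via indicator cross-products
  abs_sum <- 2 * (tcrossprod(a0, a2) + tcrossprod(a2, a0)) +
    tcrossprod(a1, a0 + a2) + tcrossprod(a0 + a2, a1)
  K <- 1 - abs_sum / (2 * m)
  dimnames(K) <- list(rownames(d), rownames(d))
  K
}

#' VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum(p_k (1 - p_k)))` with `Z` the dosage matrix
#' centered by twice the allele frequency. Monomorphic markers are
#' excluded (count in attribute `"n_excluded"`). Missing dosages are
#' mean-imputed.
#'
#' @param geno a `geno_matrix`.
#' @return symmetric positive semi-definite accession x accession matrix.
#' @export
vanraden_grm <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  d <- impute_dosages(geno)$dosage
  p <- colMeans(d) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all markers monomorphic; cannot build GRM")
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(d, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(d), rownames(d))
  attr(G, "n_excluded") <- sum(!keep)
  G
}
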