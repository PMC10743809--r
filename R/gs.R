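#' Build the five GS marker sets (M1-M5)
#'
#' * M1: seeded uniform random sample of `m1_size` genome-wide markers.
#' * M2: representative QTNs of QTLs associated with any trait measured
#'   under N deficiency (trait suffix `_Nm`).
#' * M3: representative QTNs of QTLs associated with the target trait.
#' * M4: representative QTNs of QTLs for traits significantly positively
#'   correlated with the target (Pearson r > 0; the p < 0.05 gate can be
#'   dropped via `correlation_gate = "none"`). The target itself is
#'   included.
#' * M5: M4 restricted to QTLs whose window contains at least one DEG.
#'
#' @param geno a `geno_matrix`.
#' @param qtl_table classified `qtl_table`.
#' @param trait_cor correlation object from [correlate_traits()].
#' @param coloc colocalization result from [colocalize()] (required for
#'   M5).
#' @param target target trait (default "NUE_STI").
#' @param m1_size size of the random genome-wide set.
#' @param seed seed for the M1 draw.
#' @param correlation_gate `"p0.05"` (default) or `"none"`.
#' @return named list of marker-id character vectors, class `marker_sets`.
#' @export
build_marker_sets <- function(geno, qtl_table, trait_cor, coloc,
                              target = "NUE_STI", m1_size = 1000,
                              seed = 1, correlation_gate = c("p0.05", "none")) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(qtl_table, "qtl_table"))
  correlation_gate <- match.arg(correlation_gate)
  q <- qtl_table$qtls
  trait_list <- strsplit(q$traits, ",", fixed = TRUE)

  set.seed(seed)
  m1 <- sort(sample(geno$map$marker, min(m1_size, nrow(geno$map))))

  has_trait <- function(pred) q$rep_marker[vapply(trait_list,
                                                  function(t) any(pred(t)),
                                                  TRUE)]
  m2 <- has_trait(function(t) endsWith(t, "_Nm"))
  m3 <- has_trait(function(t) t == target)

  rvec <- trait_cor$r[target, ]
  pvec <- trait_cor$p[target, ]
  pos <- names(rvec)[!is.na(rvec) & rvec > 0 &
                       (correlation_gate == "none" |
                          (!is.na(pvec) & pvec < 0.05))]
  pos <- union(pos, target)
  m4 <- has_trait(function(t) t %in% pos)

  qtl_with_deg <- coloc$hits$qtl_id[coloc$hits$n_degs > 0]
  m4_ids <- q$qtl_id[q$rep_marker %in% m4]
  m5 <- q$rep_marker[q$qtl_id %in% intersect(m4_ids, qtl_with_deg)]

  sets <- list(M1 = m1, M2 = unique(m2), M3 = unique(m3), M4 = unique(m4),
               M5 = unique(m5))
  for (nm in names(sets))
    if (!length(sets[[nm]])) stop("marker set ", nm, " is empty")
  structure(sets, class = c("marker_sets", "list"))
}

#' @export
print.marker_sets <- function(x, ...) {
  cat("marker_sets:",
      paste(sprintf("%s=%d", names(x), lengths(x)), collapse = " "), "\n")
  invisible(x)
}

#' Encode markers as favorable/alternative allele codes in \{1, -1\}
#'
#' The favorable homozygote is coded 1, the alternative homozygote -1 and
#' heterozygotes 0. For markers without an allele-effect test (e.g. the
#' random genome-wide set), `allow_fallback = TRUE` codes the major-allele
#' homozygote as 1 with a warning; the sign convention does not affect
#' GBLUP, whose relationship matrix is invariant to column sign flips.
#'
#' @param geno a `geno_matrix`.
#' @param markers marker ids to encode.
#' @param favorable named numeric vector: favorable dosage (0 or 2) per
#'   marker, from [validate_qtns()]/[allele_effect_test()].
#' @param allow_fallback allow frequency-based orientation for markers
#'   missing from `favorable`.
#' @return accessions x markers matrix with entries in \{-1, 0, 1\}.
#' @export
encode_markers <- function(geno, markers, favorable = NULL,
                           allow_fallback = FALSE) {
  stopifnot(inherits(geno, "geno_matrix"),
            all(markers %in% geno$map$marker))
  d <- round(impute_dosages(geno)$dosage[, markers, drop = FALSE])
  fav <- rep(NA_real_, length(markers))
  names(fav) <- markers
  if (!is.null(favorable)) {
    hit <- intersect(markers, names(favorable))
    fav[hit] <- favorable[hit]
  }
  if (anyNA(fav)) {
    if (!allow_fallback)
      stop("no favorable-allele call for marker(s): ",
           paste(utils::head(markers[is.na(fav)], 5), collapse = ", "))
    warning("orienting ", sum(is.na(fav)),
            " marker(s) by major-allele frequency")
    maj <- ifelse(colMeans(d[, is.na(fav), drop = FALSE]) >= 1, 2, 0)
    fav[is.na(fav)] <- maj
  }
  W <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  favm <- matrix(rep(fav, each = nrow(d)), nrow(d))
  W[d == favm] <- 1
  W[d == (2 - favm)] <- -1
  W
}

#' GBLUP with repeated k-fold cross-validation
#'
#' Builds `G = W W' / m` from the coded marker matrix; for each random
#' fold partition, variance components are re-estimated by REML on the
#' training accessions and test genetic values are predicted as
#' `g_test = G\[test, train\] (G\[train, train\] + delta I)^-1
#' (y_train - mu)`. Accuracy is the Pearson correlation between predicted
#' genetic values and observed phenotypes in the held-out fold.
#' Deterministic under `seed`. Singular training systems receive a 1e-8
#' ridge jitter.
#'
#' @param y phenotype vector (no missing).
#' @param W coded marker matrix from [encode_markers()] (rows aligned
#'   with `y`).
#' @param k folds (default 5).
#' @param repeats partition repetitions (default 100).
#' @param seed integer seed.
#' @param set_id optional label stored in the result.
#' @return data.frame of class `cv_result`: set, rep, fold, r, n_test.
#'   Folds whose held-out phenotype is constant give `NA` accuracy (count
#'   in attribute `"n_constant"`).
#' @export
gblup_cv <- function(y, W, k = 5, repeats = 100, seed = 1, set_id = "set") {
  n <- length(y)
  stopifnot(nrow(W) == n, n >= 5 * k, !anyNA(y))
  G <- tcrossprod(W) / ncol(W)
  set.seed(seed)
  out <- vector("list", repeats * k)
  n_constant <- 0L
  idx <- 0L
  for (rp in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(k), n))
    for (fd in seq_len(k)) {
      test <- fold == fd
      train <- !test
      vc <- fit_null_vc(y[train], G[train, train, drop = FALSE])
      mu <- vc$beta[1]
      A <- G[train, train, drop = FALSE]
      diag(A) <- diag(A) + vc$delta
      sol <- tryCatch(solve(A, y[train] - mu), error = function(e) {
        diag(A) <- diag(A) + 1e-8
        solve(A, y[train] - mu)
      })
      ghat <- drop(G[test, train, drop = FALSE] %*% sol)
      r <- if (stats::sd(y[test]) == 0 || stats::sd(ghat) == 0) {
        n_constant <- n_constant + 1L
        NA_real_
      } else stats::cor(ghat, y[test])
      idx <- idx + 1L
      out[[idx]] <- data.frame(set = set_id, rep = rp, fold = fd, r = r,
                               n_test = sum(test))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cv_result", "data.frame")
  attr(res, "n_constant") <- n_constant
  res
}

#' Compare marker sets by ANOVA and Tukey HSD
#'
#' One-way ANOVA of fold-level accuracy by marker set, Tukey honest
#' significant differences, and a compact letter display (sets sharing a
#' letter are not significantly different at `alpha`).
#'
#' @param cv row-bound `cv_result` tables for >= 2 sets.
#' @param alpha significance level for the letter display (default 0.05).
#' @return list of class `set_comparison`: `means` (set, mean_r, sd_r, n,
#'   letter), `anova_p`, `anova_F`, `tukey` (pairwise table),
#'   `degenerate` flag (zero within-group variance).
#' @export
compare_sets <- function(cv, alpha = 0.05) {
  cv <- cv[!is.na(cv$r), , drop = FALSE]
  cv$set <- factor(cv$set)
  if (nlevels(cv$set) < 2) stop("need >= 2 marker sets")
  means <- data.frame(
    set = levels(cv$set),
    mean_r = as.numeric(tapply(cv$r, cv$set, mean)),
    sd_r = as.numeric(tapply(cv$r, cv$set, stats::sd)),
    n = as.integer(table(cv$set)))
  fit <- stats::aov(r ~ set, data = cv)
  an <- summary(fit)[[1]]
  within_ms <- an["Residuals", "Mean Sq"]
  degenerate <- !is.finite(within_ms) || within_ms < 1e-300
  if (degenerate) {
    # no within-set variance: sets differ iff their means differ
    key <- match(means$mean_r, sort(unique(means$mean_r), decreasing = TRUE))
    means$letter <- letters[key]
    return(structure(list(means = means, anova_p = NA_real_,
                          anova_F = NA_real_, tukey = NULL,
                          degenerate = TRUE), class = "set_comparison"))
  }
  tk <- stats::TukeyHSD(fit)$set
  pmat <- matrix(1, nlevels(cv$set), nlevels(cv$set),
                 dimnames = list(levels(cv$set), levels(cv$set)))
  for (nm in rownames(tk)) {
    ab <- strsplit(nm, "-", fixed = TRUE)[[1]]
    pmat[ab[1], ab[2]] <- pmat[ab[2], ab[1]] <- tk[nm, "p adj"]
  }
  means$letter <- .letter_display(means$set[order(-means$mean_r)],
                                  pmat, alpha)[means$set]
  structure(list(means = means,
                 anova_p = an["set", "Pr(>F)"],
                 anova_F = an["set", "F value"],
                 tukey = as.data.frame(tk), degenerate = FALSE),
            class = "set_comparison")
}

# insert-and-absorb compact letter display; `ord` = sets sorted by mean desc
.letter_display <- function(ord, pmat, alpha) {
  ord <- as.character(ord)
  groups <- list()
  for (s in ord) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (all(pmat[s, groups[[gi]]] >= alpha)) {
        groups[[gi]] <- c(groups[[gi]], s)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- s
  }
  # absorb subset groups
  keep <- rep(TRUE, length(groups))
  for (i in seq_along(groups)) for (j in seq_along(groups))
    if (i != j && keep[i] && keep[j] &&
        all(groups[[i]] %in% groups[[j]])) keep[i] <- FALSE
  groups <- groups[keep]
  lab <- stats::setNames(rep("", length(ord)), ord)
  for (gi in seq_along(groups))
    for (s in groups[[gi]]) lab[s] <- paste0(lab[s], letters[gi])
  lab
}

#' @export
print.set_comparison <- function(x, ...) {
  cat("marker-set comparison (one-way ANOVA of CV accuracy)\n")
  if (!x$degenerate)
    cat(sprintf("  F = %.3f, p = %.3g\n", x$anova_F, x$anova_p))
  else cat("  degenerate: zero within-set variance\n")
  print.data.frame(x$means, digits = 3)
  invisible(x)
}
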