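#' Mann-Whitney allele-effect test for one QTN
#'
#' Splits trait values by homozygous allele class (heterozygotes excluded
#' under the inbred-line assumption, or pooled with the minor class via
#' `het = "pool"`) and applies a two-sided Mann-Whitney U test: exact when
#' the smaller class has at most 8 members and there are no ties, normal
#' approximation with tie and continuity correction otherwise. The
#' favorable allele is the class with the larger trait mean.
#'
#' @param values numeric trait values per accession.
#' @param dosages dosage vector in \{0, 1, 2\} aligned with `values`.
#' @param het `"exclude"` (default) or `"pool"` heterozygotes with the
#'   minor homozygous class.
#' @return one-row data.frame: n0, n2, U, p, favorable_dosage (0 or 2,
#'   `NA` when untestable), testable, reason.
#' @export
allele_effect_test <- function(values, dosages, het = c("exclude", "pool")) {
  het <- match.arg(het)
  stopifnot(length(values) == length(dosages))
  ok <- !is.na(values) & !is.na(dosages)
  values <- values[ok]; dosages <- round(dosages[ok])
  g0 <- values[dosages == 0]
  g2 <- values[dosages == 2]
  if (het == "pool") {
    gh <- values[dosages == 1]
    if (length(g0) <= length(g2)) g0 <- c(g0, gh) else g2 <- c(g2, gh)
  }
  n0 <- length(g0); n2 <- length(g2)
  if (min(n0, n2) < 2)
    return(data.frame(n0 = n0, n2 = n2, U = NA_real_, p = NA_real_,
                      favorable_dosage = NA_real_, testable = FALSE,
                      reason = "homozygous class with < 2 members"))
  wt <- suppressWarnings(stats::wilcox.test(
    g0, g2, exact = min(n0, n2) <= 8, correct = TRUE))
  pv <- wt$p.value
  if (!is.finite(pv)) pv <- 1  # fully tied groups carry no evidence
  fav <- if (mean(g2) > mean(g0)) 2 else 0
  data.frame(n0 = n0, n2 = n2, U = unname(wt$statistic), p = pv,
             favorable_dosage = fav, testable = TRUE, reason = NA_character_)
}

#' Validate QTNs by allele-effect testing
#'
#' Runs [allele_effect_test()] for every QTN record against its trait and
#' removes QTNs whose allele effect is not significant (false positives)
#' or untestable. The removed records, with reasons, are kept in the
#' `"removed"` attribute.
#'
#' @param qtns `qtn_table` from [run_mlgwas()].
#' @param traits trait table (column `accession` + trait columns).
#' @param geno a `geno_matrix`.
#' @param alpha Mann-Whitney significance threshold (default 0.05).
#' @param het heterozygote handling, see [allele_effect_test()].
#' @return validated `qtn_table` with columns `mw_p` and
#'   `favorable_dosage` appended.
#' @export
validate_qtns <- function(qtns, traits, geno, alpha = 0.05,
                          het = "exclude") {
  stopifnot(inherits(geno, "geno_matrix"))
  if (!nrow(qtns)) {
    qtns$mw_p <- numeric(0); qtns$favorable_dosage <- numeric(0)
    attr(qtns, "removed") <- qtns
    return(qtns)
  }
  d <- impute_dosages(geno)$dosage[traits$accession, , drop = FALSE]
  tests <- do.call(rbind, lapply(seq_len(nrow(qtns)), function(i)
    allele_effect_test(traits[[qtns$trait[i]]], d[, qtns$marker[i]],
                       het = het)))
  qtns$mw_p <- tests$p
  qtns$favorable_dosage <- tests$favorable_dosage
  pass <- tests$testable & tests$p < alpha
  removed <- qtns[!pass, , drop = FALSE]
  removed$reason <- ifelse(tests$testable[!pass],
                           "allele effect not significant", tests$reason[!pass])
  out <- qtns[pass, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("qtn_table", "data.frame")
  attr(out, "removed") <- removed
  out
}

#' Merge validated QTNs into QTL blocks by LD distance
#'
#' Per chromosome, clusters QTN positions (across all traits) by single
#' linkage with link distance `d_c = factor * decay_distance(r2
#' threshold)` from the chromosome-specific LD-decay profile (genome-wide
#' fallback). Each cluster becomes one QTL named
#' `Lu{chrom}_{representative position}`; the representative QTN is the
#' member with the largest R2 (ties broken by smallest position), and the
#' QTL's trait set is the union of member traits.
#'
#' @param qtns validated `qtn_table` from [validate_qtns()].
#' @param decay either a single `ld_decay` profile (genome-wide) or a list
#'   of profiles named by chromosome, with optional element `"genome"` as
#'   fallback.
#' @param factor fraction of the decay distance used as link distance
#'   (default 0.75).
#' @param r2_threshold r2 level defining the decay distance (default 0.3,
#'   the QTN-grouping criterion).
#' @return object of class `qtl_table`: list with `qtls` (one row per
#'   QTL: qtl_id, chrom, rep_pos, rep_marker, rep_r2, n_members,
#'   n_traits, traits, major, pleiotropic, members) and `members` (QTN
#'   rows with their qtl_id).
#' @export
merge_qtns <- function(qtns, decay, factor = 0.75, r2_threshold = 0.3) {
  stopifnot(nrow(qtns) >= 1)
  get_dc <- function(ch) {
    prof <- if (inherits(decay, "ld_decay")) decay
    else decay[[as.character(ch)]] %||% decay[["genome"]]
    if (is.null(prof))
      stop("no LD-decay profile for chromosome ", ch,
           " and no genome-wide fallback")
    factor * as.numeric(decay_distance(prof, r2_threshold))
  }
  qtns <- qtns[order(qtns$chrom, qtns$pos, qtns$trait), , drop = FALSE]
  qtl_rows <- vector("list", 0)
  members <- vector("list", 0)
  for (ch in unique(qtns$chrom)) {
    dc <- get_dc(ch)
    q <- qtns[qtns$chrom == ch, , drop = FALSE]
    upos <- sort(unique(q$pos))
    grp <- cumsum(c(1, diff(upos) > dc))
    grp_of <- grp[match(q$pos, upos)]
    for (g in unique(grp_of)) {
      mem <- q[grp_of == g, , drop = FALSE]
      rep_i <- order(-mem$r2, mem$pos)[1]
      qid <- sprintf("Lu%s_%d", as.character(ch), mem$pos[rep_i])
      mem$qtl_id <- qid
      traits <- sort(unique(mem$trait))
      qtl_rows[[length(qtl_rows) + 1]] <- data.frame(
        qtl_id = qid, chrom = ch, rep_pos = mem$pos[rep_i],
        rep_marker = mem$marker[rep_i], rep_r2 = mem$r2[rep_i],
        n_members = nrow(mem), n_traits = length(traits),
        traits = paste(traits, collapse = ","),
        members = paste(unique(mem$marker), collapse = ","))
      members[[length(members) + 1]] <- mem
    }
  }
  qtls <- do.call(rbind, qtl_rows)
  qtls <- qtls[order(qtls$chrom, qtls$rep_pos), ]
  rownames(qtls) <- NULL
  mem <- do.call(rbind, members)
  rownames(mem) <- NULL
  structure(list(qtls = qtls, members = mem), class = "qtl_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.qtl_table <- function(x, ...) {
  cat("qtl_table:", nrow(x$qtls), "QTLs from", nrow(x$members),
      "member QTNs\n")
  if ("major" %in% names(x$qtls))
    cat("  major (R2 > 10%):", sum(x$qtls$major),
        "; pleiotropic (>= 2 traits):", sum(x$qtls$pleiotropic), "\n")
  invisible(x)
}

#' Flag major and pleiotropic QTLs
#'
#' A QTL is major when its representative R2 strictly exceeds 10% of the
#' phenotypic variance, and pleiotropic when its members associate with at
#' least two distinct traits.
#'
#' @param qtl_table a `qtl_table` from [merge_qtns()].
#' @return the same object with logical columns `major` and `pleiotropic`.
#' @export
classify_qtls <- function(qtl_table) {
  stopifnot(inherits(qtl_table, "qtl_table"))
  qtl_table$qtls$major <- qtl_table$qtls$rep_r2 > 10
  qtl_table$qtls$pleiotropic <- qtl_table$qtls$n_traits >= 2
  qtl_table
}

#' Regression of a trait on its representative QTN dosages
#'
#' Ordinary least squares of the trait on all representative-QTN dosage
#' columns associated with it; reports multiple R2 and adjusted R2
#' (`adjR2 = 1 - (1 - R2)(n - 1)/(n - p - 1)`).
#'
#' @param y trait vector.
#' @param X_qtl matrix of representative-QTN dosages (columns).
#' @return list: r2, adj_r2, n, p.
#' @export
qtl_regression <- function(y, X_qtl) {
  X_qtl <- as.matrix(X_qtl)
  n <- length(y)
  p <- ncol(X_qtl)
  if (p >= n - 1)
    stop("p >= n - 1 predictors: prune markers before regression")
  fit <- stats::lm.fit(cbind(1, X_qtl), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  p_eff <- fit$rank - 1  # aliased columns do not consume df
  adj <- 1 - (1 - r2) * (n - 1) / (n - p_eff - 1)
  list(r2 = r2, adj_r2 = adj, n = n, p = p_eff)
}

#' Favorable-allele counts per accession and decile contrast
#'
#' For a target trait, counts per accession the QTLs at which it carries
#' the favorable homozygous class (heterozygous or non-favorable calls
#' count zero). The favorable class per QTL is taken from the validated
#' member QTN for that trait with the largest R2. Accessions are also
#' ranked into top and bottom deciles by trait value
#' (`round(0.1 * n)` accessions each).
#'
#' @param traits trait table (column `accession` + trait columns).
#' @param qtl_table classified `qtl_table`.
#' @param geno a `geno_matrix`.
#' @param trait target trait name.
#' @return list: `counts` (accession, trait_value, n_favorable),
#'   `decile_size`, `top`, `bottom` (subsets of `counts`),
#'   `mean_top`, `mean_bottom` (mean favorable counts).
#' @export
count_favorable_alleles <- function(traits, qtl_table, geno, trait) {
  stopifnot(inherits(qtl_table, "qtl_table"), inherits(geno, "geno_matrix"))
  mem <- qtl_table$members
  mem <- mem[mem$trait == trait & !is.na(mem$favorable_dosage), , drop = FALSE]
  if (!nrow(mem)) stop("no validated QTLs for trait ", trait)
  pick <- do.call(rbind, lapply(split(mem, mem$qtl_id), function(d)
    d[which.max(d$r2), , drop = FALSE]))
  d <- impute_dosages(geno)$dosage[traits$accession, pick$marker,
                                   drop = FALSE]
  fav <- matrix(rep(pick$favorable_dosage, each = nrow(d)), nrow(d))
  counts <- rowSums(round(d) == fav)
  res <- data.frame(accession = traits$accession,
                    trait_value = traits[[trait]],
                    n_favorable = counts)
  n <- nrow(res)
  k <- round(0.1 * n)
  ord <- order(-res$trait_value)
  top <- res[ord[seq_len(k)], ]
  bottom <- res[rev(ord)[seq_len(k)], ]
  list(counts = res, decile_size = k, top = top, bottom = bottom,
       mean_top = mean(top$n_favorable), mean_bottom = mean(bottom$n_favorable))
}
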