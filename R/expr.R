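#' Median-of-ratios library-size normalization
#'
#' Size factor per sample = median over genes (positive in every sample)
#' of the ratio of the count to the gene's geometric mean across samples.
#'
#' @param counts genes x samples integer matrix.
#' @return list: `size_factors` (per sample) and `normalized`
#'   (counts divided by their size factor).
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples")
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use))
    stop("no gene has positive counts in every sample; ",
         "a pseudo-reference would be required")
  sf <- apply(counts, 2, function(cnt)
    exp(stats::median(log(cnt[use]) - log_geo[use])))
  list(size_factors = sf, normalized = sweep(counts, 2, sf, "/"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement, as provided by
#' [stats::p.adjust()].
#'
#' @param p vector of p-values in \[0, 1\] (`NA` allowed).
#' @return adjusted values.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression test (N+ vs N- within one genotype)
#'
#' Per gene, fits a negative-binomial GLM (log link) of counts on the
#' treatment indicator with log size factors as offset. The NB dispersion
#' is estimated per gene by the method of moments on normalized counts,
#' with a floor of 1e-8, and a Wald test is applied to the treatment
#' coefficient. P-values are BH-adjusted across tested genes.
#' Orientation: the reported log2 fold change is N+ relative to the N-
#' baseline, so "up" means higher expression under optimum N. A gene is
#' significant when `|log2FC| >= lfc_min` and `FDR < fdr_max`. All-zero
#' genes are excluded (count in attribute `"n_excluded"`).
#'
#' @param counts genes x samples matrix.
#' @param samples sample sheet with columns `sample`, `genotype`,
#'   `treatment` matching `colnames(counts)`.
#' @param genotype contrast genotype ("HN" or "LN").
#' @param lfc_min absolute log2-fold-change gate (default 1).
#' @param fdr_max FDR gate (default 0.05).
#' @param dispersion_floor lower bound for the moment estimate.
#' @return data.frame: gene, contrast, base_mean, log2fc, p, fdr,
#'   significant, direction ("up"/"down" under N+).
#' @export
de_test <- function(counts, samples, genotype, lfc_min = 1, fdr_max = 0.05,
                    dispersion_floor = 1e-8) {
  stopifnot(all(c("sample", "genotype", "treatment") %in% names(samples)),
            all(samples$sample %in% colnames(counts)))
  sel <- samples[samples$genotype == genotype, ]
  if (nrow(sel) < 4 || length(unique(sel$treatment)) < 2)
    stop("need both treatments for genotype ", genotype)
  if (min(table(sel$treatment)) < 2)
    stop("need >= 2 replicates per group")
  cnt <- as.matrix(counts[, sel$sample, drop = FALSE])
  # N- is the baseline level; coefficient = effect of N+
  grp <- factor(sel$treatment, levels = c("N-", "N+"))
  nz <- rowSums(cnt) > 0
  n_excluded <- sum(!nz)
  cnt <- cnt[nz, , drop = FALSE]
  norm <- normalize_counts(cnt)
  sf <- norm$size_factors
  k <- norm$normalized
  res <- data.frame(gene = rownames(cnt), contrast = genotype,
                    base_mean = rowMeans(k), log2fc = NA_real_,
                    p = NA_real_)
  off <- log(sf)
  for (i in seq_len(nrow(cnt))) {
    ki <- k[i, ]
    mu_g <- tapply(ki, grp, mean)
    v_g <- tapply(ki, grp, stats::var)
    mu_bar <- mean(ki)
    alpha <- max(dispersion_floor,
                 (stats::weighted.mean(v_g, table(grp)) - mu_bar) / mu_bar^2,
                 na.rm = TRUE)
    fit <- tryCatch(
      suppressWarnings(stats::glm(
        cnt[i, ] ~ grp + offset(off),
        family = MASS::negative.binomial(theta = 1 / alpha))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    co <- summary(fit)$coefficients
    if (nrow(co) < 2) next
    res$log2fc[i] <- co[2, 1] / log(2)
    res$p[i] <- co[2, 4]
  }
  res$fdr <- bh_fdr(res$p)
  res$significant <- !is.na(res$fdr) & abs(res$log2fc) >= lfc_min &
    res$fdr < fdr_max
  res$direction <- ifelse(is.na(res$log2fc), NA_character_,
                          ifelse(res$log2fc >= 0, "up", "down"))
  rownames(res) <- NULL
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Colocalize differentially expressed genes with QTL windows
#'
#' Builds a window of `rep_pos +/- half_window` bp (clipped at the
#' chromosome start, and end when chromosome lengths are supplied) around
#' each QTL's representative QTN and intersects it with gene intervals
#' (1-based, closed). Genes flagged significant in `degs` are counted per
#' window.
#'
#' @param qtl_table a `qtl_table`.
#' @param annotation gene annotation data.frame (gene_id, chrom, start,
#'   end), as from [make_annotation()].
#' @param degs DEG table from [de_test()] (possibly several contrasts
#'   row-bound); only rows with `significant == TRUE` count as DEGs.
#' @param half_window half window width in bp (default 100 kb, the
#'   genome-wide LD decay range).
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   right clipping.
#' @return list: `hits` (qtl_id, chrom, win_start, win_end, n_genes,
#'   n_degs, deg_genes), `summary` (n_qtls, n_qtls_with_deg,
#'   n_deg_total, n_deg_in_windows, frac_deg_in_windows,
#'   mean_degs_per_hit, sd_degs_per_hit).
#' @export
colocalize <- function(qtl_table, annotation, degs, half_window = 1e5,
                       chrom_lengths = NULL) {
  stopifnot(inherits(qtl_table, "qtl_table"))
  q <- qtl_table$qtls
  bad <- setdiff(unique(q$chrom), unique(annotation$chrom))
  if (length(bad))
    stop("QTL chromosomes absent from annotation: ",
         paste(bad, collapse = ", "))
  sig_genes <- unique(degs$gene[degs$significant])
  hits <- data.frame(qtl_id = q$qtl_id, chrom = q$chrom,
                     win_start = pmax(1, q$rep_pos - half_window),
                     win_end = q$rep_pos + half_window,
                     n_genes = 0L, n_degs = 0L, deg_genes = "")
  if (!is.null(chrom_lengths))
    hits$win_end <- pmin(hits$win_end,
                         chrom_lengths[as.character(hits$chrom)])
  deg_in_any <- character(0)
  for (i in seq_len(nrow(hits))) {
    g <- annotation[annotation$chrom == hits$chrom[i] &
                      annotation$start <= hits$win_end[i] &
                      annotation$end >= hits$win_start[i], ]
    hits$n_genes[i] <- nrow(g)
    dg <- intersect(g$gene_id, sig_genes)
    hits$n_degs[i] <- length(dg)
    hits$deg_genes[i] <- paste(dg, collapse = ",")
    deg_in_any <- union(deg_in_any, dg)
  }
  with_deg <- hits$n_degs > 0
  summary <- data.frame(
    n_qtls = nrow(hits),
    n_qtls_with_deg = sum(with_deg),
    n_deg_total = length(sig_genes),
    n_deg_in_windows = length(deg_in_any),
    frac_deg_in_windows = if (length(sig_genes))
      length(deg_in_any) / length(sig_genes) else NA_real_,
    mean_degs_per_hit = if (any(with_deg)) mean(hits$n_degs[with_deg])
      else NA_real_,
    sd_degs_per_hit = if (sum(with_deg) > 1) stats::sd(hits$n_degs[with_deg])
      else NA_real_)
  list(hits = hits, summary = summary)
}
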