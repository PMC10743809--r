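#' Names of the 21 derived NUE-related traits
#'
#' Six base traits under each nitrogen treatment (suffix `_Np` for optimum
#' N, `_Nm` for N deficiency), five N-/N+ stability indices, NUE under each
#' treatment, the NUE index and the NUE stress tolerance index.
#' @return character vector of length 21.
#' @export
nue_trait_names <- function() {
  c(paste0(rep(c("TRL", "RV", "RT", "PDW", "SDW", "RS"), each = 2),
           c("_Np", "_Nm")),
    paste0(c("TRL", "RV", "RT", "PDW", "SDW"), "_Index"),
    "NUE_Np", "NUE_Nm", "NUE_Index", "NUE_STI")
}

.check_raw <- function(raw) {
  need <- c("accession", "treatment", "replicate", "trait", "value")
  if (!all(need %in% names(raw)))
    stop("raw phenotypes need columns: ", paste(need, collapse = ", "))
  if (!all(raw$treatment %in% c("N+", "N-")))
    stop("treatment must be 'N+' or 'N-'")
  if (any(!is.finite(raw$value))) stop("non-finite phenotype values")
  invisible(raw)
}

#' Best linear unbiased estimates of accession x treatment cell means
#'
#' Per trait and treatment, fits a fixed-effect model with accession and
#' replicate factors and returns the least-squares accession means
#' (averaged over replicate levels). For a balanced completely randomized
#' design this equals the arithmetic replicate mean.
#'
#' @param raw long replicate-level phenotype table (accession, treatment,
#'   replicate, trait, value).
#' @return long data.frame: accession, treatment, trait, value (the BLUE).
#' @export
compute_blues <- function(raw) {
  .check_raw(raw)
  cells <- unique(raw[c("accession", "treatment", "trait")])
  full <- expand.grid(accession = unique(raw$accession),
                      treatment = unique(raw$treatment),
                      trait = unique(raw$trait), stringsAsFactors = FALSE)
  missing_cells <- full[!interaction(full) %in% interaction(cells), ]
  if (nrow(missing_cells))
    stop("empty accession x treatment x trait cell(s): ",
         paste(utils::head(apply(missing_cells, 1, paste, collapse = "/"), 5),
               collapse = ", "))
  out <- vector("list", 0)
  for (w in unique(raw$treatment)) for (tr in unique(raw$trait)) {
    d <- raw[raw$treatment == w & raw$trait == tr, ]
    d$accession <- factor(d$accession)
    d$replicate <- factor(d$replicate)
    if (nlevels(d$replicate) > 1 &&
        nrow(d) > nlevels(d$accession) + nlevels(d$replicate) - 1) {
      fit <- stats::lm(value ~ accession + replicate, data = d)
      grid <- expand.grid(accession = levels(d$accession),
                          replicate = levels(d$replicate))
      pr <- stats::predict(fit, newdata = grid)
      blue <- tapply(pr, grid$accession, mean)
    } else {
      blue <- tapply(d$value, d$accession, mean)
    }
    out[[length(out) + 1]] <- data.frame(
      accession = names(blue), treatment = w, trait = tr,
      value = as.numeric(blue))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Derive the 21 NUE-related traits from base-trait BLUEs
#'
#' Computes, per accession: root/shoot ratio RS = RDW/SDW under each
#' treatment; NUE = PDW / plant N content (mg/mg) with plant N = shoot N +
#' root N; stability indices `100 * x_N- / x_N+` for TRL, RV, RT, PDW, SDW
#' and NUE; and the Fernandez stress tolerance index
#' `NUE_STI = (NUE_N+ * NUE_N-) / mean(NUE_N+)^2`.
#' Accessions with a zero denominator (a zero N+ trait value or zero plant
#' N) are excluded, with the count recorded in the `"excluded"` attribute.
#'
#' @param blues long accession x treatment x trait table as returned by
#'   [compute_blues()]; base traits TRL, RV, RT, PDW, SDW, RDW, shootN,
#'   rootN must be present under both treatments.
#' @return data.frame with column `accession` plus the 21 trait columns of
#'   [nue_trait_names()].
#' @export
derive_traits <- function(blues) {
  base <- c("TRL", "RV", "RT", "PDW", "SDW", "RDW", "shootN", "rootN")
  miss <- setdiff(base, unique(blues$trait))
  if (length(miss)) stop("missing base traits: ", paste(miss, collapse = ", "))
  wide <- function(w) {
    d <- blues[blues$treatment == w & blues$trait %in% base, ]
    m <- stats::reshape(d[c("accession", "trait", "value")],
                        idvar = "accession", timevar = "trait",
                        direction = "wide")
    names(m) <- sub("^value\\.", "", names(m))
    m
  }
  p <- wide("N+"); s <- wide("N-")
  m <- merge(p, s, by = "accession", suffixes = c("_Np", "_Nm"))

  plantN_p <- m$shootN_Np + m$rootN_Np
  plantN_m <- m$shootN_Nm + m$rootN_Nm
  bad <- plantN_p <= 0 | plantN_m <= 0 | m$SDW_Np <= 0 | m$SDW_Nm <= 0 |
    m$TRL_Np <= 0 | m$RV_Np <= 0 | m$RT_Np <= 0 | m$PDW_Np <= 0
  n_excluded <- sum(bad)
  if (n_excluded) {
    message("derive_traits: excluded ", n_excluded,
            " accession(s) with zero denominators")
    m <- m[!bad, ]; plantN_p <- plantN_p[!bad]; plantN_m <- plantN_m[!bad]
  }
  out <- data.frame(accession = m$accession)
  for (b in c("TRL", "RV", "RT", "PDW", "SDW")) {
    out[[paste0(b, "_Np")]] <- m[[paste0(b, "_Np")]]
    out[[paste0(b, "_Nm")]] <- m[[paste0(b, "_Nm")]]
  }
  out$RS_Np <- m$RDW_Np / m$SDW_Np
  out$RS_Nm <- m$RDW_Nm / m$SDW_Nm
  for (b in c("TRL", "RV", "RT", "PDW", "SDW"))
    out[[paste0(b, "_Index")]] <-
      100 * m[[paste0(b, "_Nm")]] / m[[paste0(b, "_Np")]]
  out$NUE_Np <- m$PDW_Np / plantN_p
  out$NUE_Nm <- m$PDW_Nm / plantN_m
  out$NUE_Index <- 100 * out$NUE_Nm / out$NUE_Np
  out$NUE_STI <- (out$NUE_Np * out$NUE_Nm) / mean(out$NUE_Np)^2
  out <- out[c("accession", nue_trait_names())]
  attr(out, "excluded") <- n_excluded
  out
}

#' Per-trait summary statistics (mean, SD, range, CV%)
#'
#' @param traits trait table from [derive_traits()] (column `accession`
#'   plus numeric trait columns).
#' @return data.frame: trait, mean, sd, min, max, cv (percent; `NA` when
#'   the mean is zero).
#' @export
summarize_traits <- function(traits) {
  num <- traits[setdiff(names(traits), "accession")]
  if (nrow(num) < 2) stop("need at least 2 accessions")
  data.frame(
    trait = names(num),
    mean = vapply(num, mean, 0),
    sd = vapply(num, stats::sd, 0),
    min = vapply(num, min, 0),
    max = vapply(num, max, 0),
    cv = vapply(num, function(x) {
      m <- mean(x)
      if (m == 0) NA_real_ else 100 * stats::sd(x) / m
    }, 0),
    row.names = NULL)
}

#' Two-way fixed-effects tests for treatment, genotype and interaction
#'
#' Per trait, fits `value ~ treatment * accession` on replicate-level data
#' and reports ANOVA p-values. With balanced data this coincides with the
#' classical two-way ANOVA (and with a REML fit treating genotype as
#' fixed). Without replication the interaction is not estimable and is
#' reported as `NA` (an additive model is used).
#'
#' @param raw long replicate-level phenotype table.
#' @return data.frame: trait, p_treatment, p_genotype, p_interaction.
#' @export
test_effects <- function(raw) {
  .check_raw(raw)
  out <- lapply(unique(raw$trait), function(tr) {
    d <- raw[raw$trait == tr, ]
    d$accession <- factor(d$accession)
    d$treatment <- factor(d$treatment)
    n_cells <- nrow(unique(d[c("accession", "treatment")]))
    has_reps <- nrow(d) > n_cells
    form <- if (has_reps) value ~ treatment * accession
            else value ~ treatment + accession
    an <- stats::anova(stats::lm(form, data = d))
    p <- an[["Pr(>F)"]]
    names(p) <- rownames(an)
    data.frame(trait = tr,
               p_treatment = unname(p["treatment"]),
               p_genotype = unname(p["accession"]),
               p_interaction = if (has_reps)
                 unname(p["treatment:accession"]) else NA_real_)
  })
  do.call(rbind, out)
}

#' Pairwise Pearson correlations between derived traits
#'
#' Pairwise-complete Pearson r with two-sided p-values from the t
#' distribution. Zero-variance traits yield `NA` for their pairs.
#'
#' @param traits trait table from [derive_traits()].
#' @return list with matrices `r`, `p` and `n` (complete pairs).
#' @export
correlate_traits <- function(traits) {
  num <- as.matrix(traits[setdiff(names(traits), "accession")])
  k <- ncol(num)
  ok <- !is.na(num)
  n <- crossprod(ok)
  if (any(n[upper.tri(n)] < 3)) stop("need >= 3 complete pairs")
  r <- suppressWarnings(stats::cor(num, use = "pairwise.complete.obs"))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  p[!is.finite(r)] <- NA_real_
  list(r = r, p = p, n = n)
}
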