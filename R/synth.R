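#' Genome specification for the genotype simulator
#'
#' Describes the marker panel to simulate: chromosome layout, marker density,
#' haplotype-block length governing linkage disequilibrium (LD) decay, the
#' minor-allele-frequency (MAF) window of the ancestral frequency draw, and
#' the population-structure model (number of subpopulations and their
#' Balding-Nichols differentiation Fst).
#'
#' Accessions are treated as (mostly) inbred lines: with probability
#' `inbreeding` an accession's two haplotypes are identical copies, giving
#' the high homozygosity typical of selfing crops such as flax.
#'
#' @param n_chromosomes number of chromosomes (default 15, the flax karyotype).
#' @param chrom_length_bp chromosome length in bp; recycled to
#'   `n_chromosomes`.
#' @param n_markers_per_chrom markers simulated per chromosome (before the
#'   MAF filter); recycled.
#' @param ld_block_len_bp expected haplotype-block length in bp; the
#'   per-interval probability of switching founder haplotype is
#'   `1 - exp(-d / ld_block_len_bp)` for an inter-marker distance `d`.
#' @param maf_range length-2 numeric, ancestral MAF draw bounds in
#'   (0, 0.5]. The hard post-simulation filter keeps markers with sample
#'   MAF >= `maf_range[1]`.
#' @param n_subpops number of subpopulations.
#' @param fst Balding-Nichols differentiation in \[0, 1).
#' @param inbreeding probability that an accession is fully homozygous.
#' @param missing_rate per-call missing-genotype rate injected before
#'   filtering (default 0).
#' @param n_founders latent founder haplotypes per subpopulation.
#' @param seed integer seed; identical spec implies identical output.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 15, chrom_length_bp = 2e7,
                        n_markers_per_chrom = 200, ld_block_len_bp = 1e5,
                        maf_range = c(0.05, 0.5), n_subpops = 2, fst = 0.1,
                        inbreeding = 0.95, missing_rate = 0,
                        n_founders = 30, seed = 1) {
  stopifnot(n_chromosomes >= 1, n_subpops >= 1, fst >= 0, fst < 1,
            inbreeding >= 0, inbreeding <= 1,
            missing_rate >= 0, missing_rate < 1, n_founders >= 2)
  if (length(maf_range) != 2 || maf_range[1] <= 0 ||
      maf_range[1] > maf_range[2] || maf_range[2] > 0.5)
    stop("maf_range must satisfy 0 < min <= max <= 0.5")
  spec <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = rep_len(as.numeric(chrom_length_bp), n_chromosomes),
    n_markers_per_chrom = rep_len(as.integer(n_markers_per_chrom),
                                  n_chromosomes),
    ld_block_len_bp = as.numeric(ld_block_len_bp),
    maf_range = as.numeric(maf_range),
    n_subpops = as.integer(n_subpops),
    fst = as.numeric(fst),
    inbreeding = as.numeric(inbreeding),
    missing_rate = as.numeric(missing_rate),
    n_founders = as.integer(n_founders),
    seed = as.integer(seed))
  class(spec) <- "genome_spec"
  spec
}

#' Simulate a diploid dosage matrix with block LD and population structure
#'
#' Markers are placed at random positions on each chromosome. Ancestral
#' allele frequencies are drawn from `maf_range` (random allele
#' orientation); subpopulation frequencies follow the Balding-Nichols model
#' parameterized by `fst`. Haplotypes are built by a copying scheme: each
#' haplotype walks along the chromosome and, with probability
#' `1 - exp(-d / ld_block_len_bp)` per inter-marker gap, switches to a new
#' random founder haplotype of its subpopulation, producing tunable LD decay
#' without coalescent machinery. Markers with sample MAF below
#' `maf_range[1]` are removed, mirroring the usual resequencing-panel
#' MAF filter.
#'
#' @param spec a [genome_spec()].
#' @param n_accessions number of accessions (default 123).
#' @return a `geno_matrix`: list with `dosage` (accessions x markers matrix
#'   in \{0,1,2\}, `NA` where missing), `map` (marker, chrom, pos), and
#'   `subpop` (accession labels).
#' @export
simulate_genotypes <- function(spec, n_accessions = 123) {
  stopifnot(inherits(spec, "genome_spec"), n_accessions >= 2)
  set.seed(spec$seed)
  n_sub <- spec$n_subpops
  sub_of <- rep_len(seq_len(n_sub), n_accessions)
  acc <- sprintf("ACC%03d", seq_len(n_accessions))
  inbred <- stats::runif(n_accessions) < spec$inbreeding

  dos_list <- vector("list", spec$n_chromosomes)
  map_list <- vector("list", spec$n_chromosomes)
  for (ch in seq_len(spec$n_chromosomes)) {
    m <- spec$n_markers_per_chrom[ch]
    len <- spec$chrom_length_bp[ch]
    pos <- sort(sample.int(len, m))
    maf <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
    p_anc <- ifelse(stats::runif(m) < 0.5, maf, 1 - maf)
    # Balding-Nichols subpopulation frequencies
    pf <- matrix(0, n_sub, m)
    for (s in seq_len(n_sub)) {
      if (spec$fst > 0) {
        a <- p_anc * (1 - spec$fst) / spec$fst
        b <- (1 - p_anc) * (1 - spec$fst) / spec$fst
        pf[s, ] <- stats::rbeta(m, a, b)
      } else pf[s, ] <- p_anc
    }
    # Founder haplotype pools per subpopulation. Founder alleles are
    # correlated along the chromosome (latent Gaussian AR(1) with
    # autocorrelation exp(-d / ld_block_len_bp), thresholded at the
    # subpopulation frequency) so that markers within a haplotype block
    # are in strong LD while the pool stays frequency-controlled.
    # Founder allele correlation decays three times slower than the
    # copying switch rate, so the haplotype-copying recombination (rate
    # 1/ld_block_len_bp) dominates the realized LD decay.
    ar <- exp(-diff(pos) / (3 * spec$ld_block_len_bp))
    make_pool <- function(s) {
      z <- matrix(0, spec$n_founders, m)
      z[, 1] <- stats::rnorm(spec$n_founders)
      for (k in seq_len(m - 1))
        z[, k + 1] <- ar[k] * z[, k] +
          sqrt(1 - ar[k]^2) * stats::rnorm(spec$n_founders)
      thr <- stats::qnorm(pf[s, ])
      (z < rep(thr, each = spec$n_founders)) + 0L
    }
    # fst = 0 means no differentiation at all: one shared pool, so
    # founder-sampling drift cannot masquerade as structure
    founders <- if (spec$fst > 0) lapply(seq_len(n_sub), make_pool)
                else rep(list(make_pool(1L)), n_sub)
    # per-gap founder-switch probability
    p_switch <- c(1, 1 - exp(-diff(pos) / spec$ld_block_len_bp))
    draw_hap <- function(s) {
      seg <- cumsum(stats::runif(m) < p_switch)
      if (seg[1] == 0L) seg <- seg + 1L  # guard: always start a segment
      idx <- sample.int(spec$n_founders, max(seg), replace = TRUE)
      founders[[s]][cbind(idx[seg], seq_len(m))]
    }
    dos <- matrix(0L, n_accessions, m)
    for (i in seq_len(n_accessions)) {
      h1 <- draw_hap(sub_of[i])
      h2 <- if (inbred[i]) h1 else draw_hap(sub_of[i])
      dos[i, ] <- h1 + h2
    }
    dos_list[[ch]] <- dos
    map_list[[ch]] <- data.frame(
      marker = sprintf("Lu%d_%d", ch, pos), chrom = ch, pos = pos)
  }
  dosage <- do.call(cbind, dos_list)
  map <- do.call(rbind, map_list)
  rownames(dosage) <- acc
  colnames(dosage) <- map$marker

  if (spec$missing_rate > 0) {
    miss <- stats::runif(length(dosage)) < spec$missing_rate
    dosage[miss] <- NA_integer_
  }
  keep <- marker_maf(dosage) >= spec$maf_range[1]
  keep[is.na(keep)] <- FALSE
  if (!any(keep))
    stop("no markers survive the MAF filter (MAF >= ", spec$maf_range[1], ")")
  geno_matrix(dosage[, keep, drop = FALSE], map[keep, , drop = FALSE],
              subpop = paste0("P", sub_of))
}

#' Construct a genotype-matrix object
#'
#' @param dosage accessions x markers matrix of diploid dosages in
#'   \{0, 1, 2\} (`NA` = missing), with row and column names.
#' @param map data.frame with columns `marker`, `chrom`, `pos` matching
#'   `colnames(dosage)`.
#' @param subpop optional accession subpopulation labels.
#' @return object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, map, subpop = NULL) {
  stopifnot(is.matrix(dosage), ncol(dosage) == nrow(map),
            all(colnames(dosage) == map$marker))
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in {0, 1, 2}")
  ord <- order(map$chrom, map$pos)
  if (is.unsorted(ord)) { map <- map[ord, ]; dosage <- dosage[, ord] }
  if (any(duplicated(map[c("chrom", "pos")])))
    stop("marker positions must be unique within a chromosome")
  rownames(map) <- NULL
  structure(list(dosage = dosage, map = map, subpop = subpop),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$dosage), "accessions x", ncol(x$dosage),
      "markers on", length(unique(x$map$chrom)), "chromosome(s)\n")
  maf <- marker_maf(x$dosage)
  cat(sprintf("  MAF range %.3f-%.3f; missing calls: %d\n",
              min(maf, na.rm = TRUE), max(maf, na.rm = TRUE),
              sum(is.na(x$dosage))))
  invisible(x)
}

#' Per-marker minor allele frequency
#' @param dosage dosage matrix (accessions x markers).
#' @return numeric vector of MAFs (NA for all-missing markers).
#' @export
marker_maf <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Mean-impute missing dosages per marker
#' @param geno a `geno_matrix`.
#' @return the same object with `NA` dosages replaced by the marker mean.
#' @export
impute_dosages <- function(geno) {
  d <- geno$dosage
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
    geno$dosage <- d
  }
  geno
}

# ---- phenotype simulation ---------------------------------------------------

#' Base traits measured by the phenotyping protocol (per treatment)
#' @export
base_traits <- function() c("TRL", "RV", "RT", "SDW", "RDW", "shootN", "rootN")

.default_trait_means <- c(TRL = 469.2, RV = 0.464, RT = 533.7, SDW = 77.1,
                          RDW = 28.6, shootN = 3.1, rootN = 1.03)
# N- multipliers: size traits shrink, roots shrink less than shoots (raising
# root/shoot), and N content drops more than biomass (raising NUE).
.default_nminus_mult <- c(TRL = 0.868, RV = 0.838, RT = 0.839, SDW = 0.777,
                          RDW = 0.935, shootN = 0.70, rootN = 0.86)

.default_gen_cor <- function() {
  tr <- base_traits()
  k <- length(tr)
  r <- matrix(0.3, k, k, dimnames = list(tr, tr))
  root <- c("TRL", "RV", "RT")
  r[root, root] <- 0.6
  r[c("SDW", "RDW"), c("SDW", "RDW")] <- 0.6
  r["shootN", "SDW"] <- r["SDW", "shootN"] <- 0.6
  r["rootN", "RDW"] <- r["RDW", "rootN"] <- 0.6
  diag(r) <- 1
  r
}

#' Planted-QTL plan for the phenotype simulator
#'
#' @param effects data.frame with columns `marker` (marker id, or integer
#'   index into the simulated panel), `trait` (one of [base_traits()]),
#'   `effect` (additive per-dosage effect in trait units) and `treatment`
#'   (`"both"`, `"N+"` or `"N-"`). May have zero rows.
#' @param h2 per-trait narrow-sense heritability in (0, 1\]; a single value
#'   is recycled. Heritability is defined at the single-observation level.
#' @param gen_cor genetic correlation matrix across the base traits
#'   (symmetric PSD, unit diagonal).
#' @param trait_means per-trait population means under N+ (trait units).
#' @param nminus_mult per-trait multiplicative mean shift under N-.
#' @param gen_cv genetic coefficient of variation of the polygenic
#'   component, per trait (recycled).
#' @param nminus_noise_mult factor inflating residual SD under N-
#'   (produces the larger trait CVs seen under nitrogen deficiency).
#' @return object of class `qtl_plan`.
#' @export
qtl_plan <- function(effects = data.frame(marker = character(),
                                          trait = character(),
                                          effect = numeric(),
                                          treatment = character()),
                     h2 = 0.5, gen_cor = .default_gen_cor(),
                     trait_means = .default_trait_means,
                     nminus_mult = .default_nminus_mult,
                     gen_cv = 0.25, nminus_noise_mult = 1.3) {
  tr <- base_traits()
  stopifnot(all(effects$trait %in% tr),
            all(effects$treatment %in% c("both", "N+", "N-")),
            all(tr %in% names(trait_means)), all(tr %in% names(nminus_mult)))
  h2 <- rep_len(h2, length(tr)); names(h2) <- tr
  if (any(h2 <= 0 | h2 > 1)) stop("h2 must lie in (0, 1]")
  gen_cv <- rep_len(gen_cv, length(tr)); names(gen_cv) <- tr
  if (!isTRUE(all.equal(gen_cor, t(gen_cor))) ||
      !isTRUE(all.equal(unname(diag(gen_cor)), rep(1, nrow(gen_cor)))))
    stop("gen_cor must be symmetric with unit diagonal")
  ev <- eigen(gen_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("genetic correlation matrix is not positive semi-definite")
  structure(list(effects = effects, h2 = h2, gen_cor = gen_cor,
                 trait_means = trait_means[tr], nminus_mult = nminus_mult[tr],
                 gen_cv = gen_cv, nminus_noise_mult = nminus_noise_mult),
            class = "qtl_plan")
}

#' Simulate replicate-level phenotypes with planted QTLs
#'
#' For each base trait, the accession-level genetic value is the sum of the
#' planted additive QTL contributions and a polygenic term built from all
#' markers (so its covariance follows the realized genomic relationship),
#' correlated across traits via `gen_cor`. The residual variance is scaled
#' so that the per-observation heritability equals `h2`. Under N-, trait
#' means are multiplied by `nminus_mult` and residual SDs by
#' `nminus_noise_mult`. Plant dry weight is recorded as SDW + RDW per
#' replicate. Negative draws are truncated at zero.
#'
#' @param geno a `geno_matrix` (missing dosages are mean-imputed).
#' @param plan a [qtl_plan()]; all planted markers must exist in `geno`.
#' @param n_reps biological replicates per accession x treatment.
#' @param seed integer seed.
#' @return long data.frame: accession, treatment ("N+"/"N-"), replicate,
#'   trait (base traits plus PDW), value.
#' @export
simulate_phenotypes <- function(geno, plan, n_reps = 3, seed = 1) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(plan, "qtl_plan"),
            n_reps >= 1)
  plan$effects$marker <- resolve_markers(geno, plan$effects$marker)
  miss <- setdiff(plan$effects$marker, geno$map$marker)
  if (length(miss))
    stop("planted markers absent from genotype matrix: ",
         paste(miss, collapse = ", "))
  set.seed(seed)
  geno <- impute_dosages(geno)
  d <- geno$dosage
  n <- nrow(d)
  tr <- base_traits()
  k <- length(tr)

  # polygenic values: marker effects correlated across traits
  sds <- apply(d, 2, stats::sd)
  use <- sds > 0
  zs <- scale(d[, use, drop = FALSE])
  m <- ncol(zs)
  B <- matrix(stats::rnorm(m * k), m, k) %*% chol_psd(plan$gen_cor)
  U <- zs %*% B / sqrt(m)
  U <- scale(U)  # unit-variance polygenic score per trait
  colnames(U) <- tr

  gvals <- matrix(0, n, k, dimnames = list(rownames(d), tr))
  planted <- array(0, c(n, k, 2),
                   dimnames = list(rownames(d), tr, c("N+", "N-")))
  for (t in tr) {
    sg <- plan$gen_cv[t] * plan$trait_means[t]
    gvals[, t] <- U[, t] * sg
  }
  if (nrow(plan$effects)) {
    for (i in seq_len(nrow(plan$effects))) {
      e <- plan$effects[i, ]
      x <- d[, e$marker]
      trts <- if (e$treatment == "both") c("N+", "N-") else e$treatment
      for (w in trts) planted[, e$trait, w] <-
          planted[, e$trait, w] + e$effect * x
    }
  }

  out <- vector("list", 2L * n_reps)
  idx <- 0L
  for (w in c("N+", "N-")) {
    mult <- if (w == "N+") rep(1, k) else unname(plan$nminus_mult)
    nm <- if (w == "N+") 1 else plan$nminus_noise_mult
    gen <- sweep(gvals, 2, mult, "*") + planted[, , w]
    vg <- apply(gen, 2, stats::var)
    ve <- ifelse(vg > 0, vg * (1 - plan$h2) / plan$h2,
                 (plan$gen_cv * plan$trait_means)^2 *
                   (1 - plan$h2) / plan$h2)
    se <- sqrt(ve) * nm
    mu <- plan$trait_means * mult
    for (r in seq_len(n_reps)) {
      eps <- matrix(stats::rnorm(n * k), n, k) %*% diag(se, k)
      val <- sweep(gen + eps, 2, mu, "+")
      val <- pmax(val, 0)
      colnames(val) <- tr
      df <- data.frame(accession = rep(rownames(d), k + 1L),
                       treatment = w, replicate = r,
                       trait = rep(c(tr, "PDW"), each = n),
                       value = c(val, val[, "SDW"] + val[, "RDW"]))
      idx <- idx + 1L
      out[[idx]] <- df
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Resolve marker references against a genotype panel
#'
#' Marker references may be ids (character), integer indices into the
#' (post-filter) panel, or fractions in (0, 1\] interpreted as relative
#' positions along the panel — convenient when planting QTLs before the
#' MAF filter determines the surviving marker count.
#' @param geno a `geno_matrix`.
#' @param marker character, integer or fractional references.
#' @return character marker ids.
#' @export
resolve_markers <- function(geno, marker) {
  if (!length(marker) || is.character(marker)) return(marker)
  m <- nrow(geno$map)
  idx <- if (all(marker <= 1)) pmax(1, round(marker * m))
         else as.integer(marker)
  if (any(idx < 1 | idx > m))
    stop("marker index out of range (panel has ", m, " markers)")
  geno$map$marker[idx]
}

# Cholesky factor tolerant of semi-definite matrices
chol_psd <- function(S) {
  ed <- eigen(S, symmetric = TRUE)
  v <- pmax(ed$values, 0)
  t(ed$vectors %*% diag(sqrt(v), length(v)))
}

# ---- RNA-seq count simulation ----------------------------------------------

#' Negative-binomial counts plan
#'
#' @param n_genes number of genes.
#' @param n_reps biological replicates per genotype x treatment (default 4).
#' @param dispersion NB dispersion alpha (> 0; variance = mu + alpha mu^2).
#'   Values below 1e-12 produce Poisson counts.
#' @param deg_spec data.frame (`gene`, `genotype` in \{"HN","LN"\},
#'   `log2fc`): planted fold change applied to the N- samples of that
#'   genotype.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline mean.
#' @param sf_range library-size-factor draw bounds.
#' @param placement optional data.frame (`gene`, `chrom`, `start`, `end`)
#'   mapping genes to genomic intervals.
#' @return object of class `counts_plan`.
#' @export
counts_plan <- function(n_genes, n_reps = 4, dispersion = 0.1,
                        deg_spec = data.frame(gene = character(),
                                              genotype = character(),
                                              log2fc = numeric()),
                        baseline_meanlog = log(150), baseline_sdlog = 1,
                        sf_range = c(0.7, 1.3), placement = NULL) {
  stopifnot(n_genes >= 1, n_reps >= 2, dispersion >= 0,
            all(deg_spec$genotype %in% c("HN", "LN")))
  if (!is.null(placement)) {
    stopifnot(all(c("gene", "chrom", "start", "end") %in% names(placement)),
              all(placement$start >= 1), all(placement$end >= placement$start))
  }
  structure(list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
                 dispersion = dispersion, deg_spec = deg_spec,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, sf_range = sf_range,
                 placement = placement),
            class = "counts_plan")
}

#' Simulate an RNA-seq count matrix with planted DEGs
#'
#' Counts are negative-binomial with gene-specific baselines, sample
#' library-size factors, and planted log2 fold changes applied to the N-
#' samples of the specified genotype. The design crosses two genotypes
#' (HN, LN) with two nitrogen treatments (N+, N-).
#'
#' @param plan a [counts_plan()].
#' @param seed integer seed.
#' @return list with `counts` (genes x samples integer matrix), `samples`
#'   (sample sheet: sample, genotype, treatment, replicate) and
#'   `size_factors` (true simulated factors).
#' @export
simulate_counts <- function(plan, seed = 1) {
  stopifnot(inherits(plan, "counts_plan"))
  set.seed(seed)
  genes <- if (!is.null(plan$placement)) as.character(plan$placement$gene)
           else sprintf("Gene%05d", seq_len(plan$n_genes))
  if (length(genes) != plan$n_genes)
    stop("placement must map every gene exactly once")
  samples <- expand.grid(replicate = seq_len(plan$n_reps),
                         treatment = c("N+", "N-"),
                         genotype = c("HN", "LN"),
                         stringsAsFactors = FALSE)[, 3:1]
  samples$sample <- sprintf("%s_%s_%d", samples$genotype,
                            ifelse(samples$treatment == "N+", "Np", "Nm"),
                            samples$replicate)
  base <- stats::rlnorm(plan$n_genes, plan$baseline_meanlog,
                        plan$baseline_sdlog)
  sf <- stats::runif(nrow(samples), plan$sf_range[1], plan$sf_range[2])
  lfc <- matrix(0, plan$n_genes, nrow(samples),
                dimnames = list(genes, samples$sample))
  if (nrow(plan$deg_spec)) {
    for (i in seq_len(nrow(plan$deg_spec))) {
      dg <- plan$deg_spec[i, ]
      j <- which(samples$genotype == dg$genotype & samples$treatment == "N-")
      lfc[as.character(dg$gene), j] <- dg$log2fc
    }
  }
  mu <- base * 2^lfc
  mu <- sweep(mu, 2, sf, "*")
  counts <- if (plan$dispersion < 1e-12) {
    matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / plan$dispersion),
           nrow(mu), ncol(mu))
  }
  dimnames(counts) <- dimnames(lfc)
  list(counts = counts, samples = samples[c("sample", "genotype",
                                            "treatment", "replicate")],
       size_factors = stats::setNames(sf, samples$sample))
}

# ---- gene annotation ---------------------------------------------------------

#' Tile non-overlapping genes uniformly across the genome
#'
#' Genes are distributed across chromosomes proportionally to chromosome
#' length and tiled at regular intervals, 1-based inclusive coordinates.
#'
#' @param spec a [genome_spec()] (chromosome lengths).
#' @param n_genes total genes to place.
#' @param gene_len_bp gene length in bp.
#' @return data.frame: gene_id, chrom, start, end, strand.
#' @export
make_annotation <- function(spec, n_genes, gene_len_bp = 2000) {
  stopifnot(inherits(spec, "genome_spec"), n_genes >= 1, gene_len_bp >= 1)
  lens <- spec$chrom_length_bp
  per <- pmax(1L, round(n_genes * lens / sum(lens)))
  # adjust to hit n_genes exactly
  while (sum(per) != n_genes) {
    i <- if (sum(per) > n_genes) which.max(per) else which.min(per / lens)
    per[i] <- per[i] + sign(n_genes - sum(per))
  }
  out <- vector("list", length(lens))
  for (ch in seq_along(lens)) {
    k <- per[ch]
    if (k * gene_len_bp > lens[ch])
      stop("chromosome ", ch, " too short for ", k, " genes of ",
           gene_len_bp, " bp")
    gap <- (lens[ch] - k * gene_len_bp) / (k + 1)
    start <- floor(gap + (seq_len(k) - 1) * (gene_len_bp + gap)) + 1
    out[[ch]] <- data.frame(
      gene_id = sprintf("Gene_%02d_%04d", ch, seq_len(k)),
      chrom = ch, start = start, end = start + gene_len_bp - 1,
      strand = "+")
  }
  res <- do.call(rbind, out)
  stopifnot(all(res$end <= rep(lens, per)))
  rownames(res) <- NULL
  res
}
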