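#' Read a genotype matrix from VCF or CSV
#'
#' VCF 4.x files are parsed with \pkg{vcfR}; diploid GT fields (`0/0`,
#' `0|1`, ...) become dosages 0/1/2 (`./.` = missing, non-diploid GT is an
#' error). CSV input expects accessions in rows (first column = accession
#' id), marker ids in the header, and a sidecar map file (marker, chrom,
#' pos). Markers are filtered at call rate > `call_rate` then MAF >
#' `maf`; the before/after counts are reported in a message and the
#' `"filter_log"` attribute.
#'
#' @param path genotype file.
#' @param format "auto" (by extension), "vcf" or "csv".
#' @param map_path sidecar marker map (CSV input only; defaults to
#'   `<path>.map.csv`).
#' @param maf MAF filter threshold (strict >; default 0.05).
#' @param call_rate call-rate threshold (strict >; default 0.95).
#' @return a `geno_matrix` (missing dosages kept as `NA`).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "csv"),
                           map_path = NULL, maf = 0.05, call_rate = 0.95) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "csv"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    gt_clean <- gsub("|", "/", gt, fixed = TRUE)
    dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    known <- is.na(gt_clean) | gt_clean %in% c("./.", ".")
    dos[gt_clean == "0/0"] <- 0L
    dos[gt_clean %in% c("0/1", "1/0")] <- 1L
    dos[gt_clean == "1/1"] <- 2L
    bad <- !known & is.na(dos)
    if (any(bad))
      stop("non-diploid or unsupported GT value(s), first at record ",
           which(bad)[1], ": ", gt_clean[which(bad)[1]])
    dosage <- t(dos)
    map <- data.frame(marker = v@fix[, "ID"],
                      chrom = utils::type.convert(v@fix[, "CHROM"],
                                                  as.is = TRUE),
                      pos = as.integer(v@fix[, "POS"]))
  } else {
    tab <- utils::read.csv(path, check.names = FALSE)
    dosage <- as.matrix(tab[, -1, drop = FALSE])
    rownames(dosage) <- tab[[1]]
    if (is.null(map_path)) map_path <- paste0(path, ".map.csv")
    map <- utils::read.csv(map_path)
    stopifnot(all(c("marker", "chrom", "pos") %in% names(map)))
    map <- map[match(colnames(dosage), map$marker), ]
  }
  m0 <- ncol(dosage)
  cr <- colMeans(!is.na(dosage))
  dosage <- dosage[, cr > call_rate, drop = FALSE]
  map <- map[cr > call_rate, , drop = FALSE]
  m1 <- ncol(dosage)
  mafv <- marker_maf(dosage)
  keep <- !is.na(mafv) & mafv > maf
  dosage <- dosage[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]
  log <- sprintf("markers: %d read, %d after call-rate > %g, %d after MAF > %g",
                 m0, m1, call_rate, ncol(dosage), maf)
  message("read_genotypes: ", log)
  g <- geno_matrix(dosage, map)
  attr(g, "filter_log") <- log
  g
}

#' Write a genotype matrix as VCF 4.2
#'
#' One sample column per accession, GT field only (0/0, 0/1, 1/1, ./.),
#' alleles written as placeholder REF=A / ALT=T.
#'
#' @param geno a `geno_matrix`.
#' @param path output path.
#' @export
write_genotypes_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "geno_matrix"))
  d <- geno$dosage
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow(d), ncol(d))
  gt[is.na(d)] <- "./."
  hdr <- c("##fileformat=VCFv4.2",
           "##source=flaxnue",
           sprintf("##contig=<ID=%s>", unique(geno$map$chrom)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  body <- paste(geno$map$chrom, geno$map$pos, geno$map$marker, "A", "T",
                ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a genotype matrix as CSV plus a marker-map sidecar
#' @param geno a `geno_matrix`.
#' @param path output CSV; the map is written to `<path>.map.csv`.
#' @export
write_genotypes_csv <- function(geno, path) {
  stopifnot(inherits(geno, "geno_matrix"))
  df <- data.frame(accession = rownames(geno$dosage), geno$dosage,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(geno$map, paste0(path, ".map.csv"), row.names = FALSE)
  invisible(path)
}

#' Read/write a gene annotation as GFF3
#'
#' Uses \pkg{rtracklayer}; coordinates are 1-based inclusive.
#'
#' @param annotation data.frame (gene_id, chrom, start, end, strand).
#' @param path GFF3 file.
#' @return `write_annotation_gff3` the path; `read_annotation_gff3` the
#'   annotation data.frame.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(annotation$chrom),
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand)
  GenomicRanges::mcols(gr)$type <- "gene"
  GenomicRanges::mcols(gr)$ID <- annotation$gene_id
  GenomicRanges::mcols(gr)$source <- "flaxnue"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    gene_id = gr$ID,
    chrom = utils::type.convert(as.character(GenomicRanges::seqnames(gr)),
                                as.is = TRUE),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  df[order(df$chrom, df$start), ]
}

#' Pipeline run configuration
#'
#' Collects the filter thresholds, GWAS/QTL/DE/GS parameters and the
#' synthetic-data blocks used by [run_pipeline()], with the study's
#' canonical defaults: MAF > 0.05 and call rate > 0.95 for genotype
#' filtering, LOD > 3.0 for QTN retention, Mann-Whitney alpha 0.05,
#' QTL merging at 75% of the r2 = 0.3 LD-decay distance, +/- 100 kb
#' colocalization windows, |log2FC| >= 1 and FDR < 0.05 for DEGs, and
#' fivefold cross-validation repeated 100 times for GS.
#'
#' @param ... overrides of the defaults listed above; unknown keys are an
#'   error.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(maf = 0.05, call_rate = 0.95, lod_min = 3.0, mw_alpha = 0.05,
              merge_factor = 0.75, merge_r2 = 0.3, window_bp = 1e5,
              de_lfc = 1.0, de_fdr = 0.05,
              k_folds = 5, repeats = 100, m1_size = 1000, seed = 1,
              n_accessions = 123, n_reps = 3,
              genome = genome_spec(), qtl_plan = qtl_plan(),
              counts_plan = NULL, n_genes = 500, gene_len_bp = 2000,
              deg_in_qtl_windows = 20, deg_elsewhere = 20, deg_log2fc = 2,
              gs_target = "NUE_STI", ld_window = 50,
              out_dir = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$maf >= 0, cfg$maf < 0.5, cfg$call_rate > 0,
            cfg$call_rate <= 1, cfg$lod_min >= 0, cfg$mw_alpha > 0,
            cfg$mw_alpha < 1, cfg$merge_factor > 0, cfg$merge_r2 > 0,
            cfg$merge_r2 < 1, cfg$window_bp > 0, cfg$de_lfc >= 0,
            cfg$de_fdr > 0, cfg$de_fdr < 1, cfg$k_folds >= 2,
            cfg$repeats >= 1, length(cfg$seed) == 1)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Scalar keys override [run_config()] defaults; `genome` and `qtl_plan`
#' blocks are passed to [genome_spec()] and [qtl_plan()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$genome)) y$genome <- do.call(genome_spec, y$genome)
  if (!is.null(y$qtl_plan)) {
    if (!is.null(y$qtl_plan$effects))
      y$qtl_plan$effects <- as.data.frame(y$qtl_plan$effects)
    y$qtl_plan <- do.call(qtl_plan, y$qtl_plan)
  }
  do.call(run_config, y)
}

# Default RNA-seq plan for the pipeline: genes tiled by the annotation,
# DEGs planted preferentially in the windows of the planted QTL markers
# (so colocalization has true positives to find) plus some elsewhere.
.default_counts_plan <- function(config, plan, geno, annot) {
  set.seed(config$seed + 5L)
  near <- character(0)
  if (nrow(plan$effects)) {
    mks <- unique(plan$effects$marker)
    mks <- mks[seq_len(min(length(mks), config$deg_in_qtl_windows))]
    for (mk in mks) {
      i <- match(mk, geno$map$marker)
      cand <- annot[annot$chrom == geno$map$chrom[i], ]
      near <- c(near, cand$gene_id[
        which.min(abs((cand$start + cand$end) / 2 - geno$map$pos[i]))])
    }
    near <- unique(near)
  }
  far <- sample(setdiff(annot$gene_id, near),
                min(config$deg_elsewhere,
                    nrow(annot) - length(near)))
  genes <- c(near, far)
  deg <- data.frame(
    gene = genes,
    genotype = sample(c("LN", "HN"), length(genes), TRUE, prob = c(0.85, 0.15)),
    log2fc = config$deg_log2fc * sample(c(1, -1), length(genes), TRUE,
                                        prob = c(0.4, 0.6)))
  counts_plan(n_genes = nrow(annot), deg_spec = deg,
              baseline_meanlog = log(200), baseline_sdlog = 0.8,
              placement = data.frame(gene = annot$gene_id,
                                     chrom = annot$chrom,
                                     start = annot$start, end = annot$end))
}

#' Study-conditions pipeline configuration
#'
#' The bundled reference scenario: 150 accessions genotyped at 3000
#' markers on three chromosomes (two subpopulations, Fst 0.1, 100 kb LD
#' blocks), an oligogenic architecture in which 16 planted QTLs of
#' graded effect drive plant dry weight and hence NUE and its stress
#' tolerance index, a handful of root-trait QTLs, and RNA-seq counts
#' with differentially expressed genes planted inside QTL windows.
#' Cross-validation uses 20 repeats of fivefold partitioning.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param repeats CV partition repetitions (default 20).
#' @return a [run_config()].
#' @export
demo_config <- function(seed = 1, repeats = 20) {
  qtl_frac <- seq(0.02, 0.98, length.out = 16)
  sdw_eff <- c(rep(7, 4), rep(4.5, 6), rep(2, 6))
  effects <- rbind(
    data.frame(marker = qtl_frac, trait = "SDW", effect = sdw_eff,
               treatment = "both"),
    data.frame(marker = qtl_frac, trait = "RDW", effect = 0.35 * sdw_eff,
               treatment = "both"),
    data.frame(marker = seq(0.07, 0.93, length.out = 3),
               trait = "TRL", effect = 45, treatment = "both"),
    data.frame(marker = seq(0.12, 0.88, length.out = 2),
               trait = "RV", effect = 0.08, treatment = "N-"),
    data.frame(marker = seq(0.17, 0.83, length.out = 2),
               trait = "RT", effect = 60, treatment = "both"))
  run_config(
    seed = as.integer(seed),
    n_accessions = 150, n_reps = 3,
    genome = genome_spec(n_chromosomes = 3, chrom_length_bp = 2e7,
                         n_markers_per_chrom = 1000, ld_block_len_bp = 1e5,
                         n_subpops = 2, fst = 0.1, seed = seed),
    qtl_plan = qtl_plan(effects = effects, h2 = 0.6, gen_cv = 0.12),
    n_genes = 600, gene_len_bp = 2000,
    repeats = repeats, m1_size = 1000)
}

# tiny polynomial rolling hash of a serialized object, for manifests
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes, in dependency order: synthetic-data generation (genotypes,
#' replicate-level phenotypes, gene annotation, RNA-seq counts), trait
#' derivation, LD decay, multi-locus GWAS, QTN validation and QTL
#' merging, differential expression, QTL-window colocalization, and
#' GWAS-assisted GBLUP cross-validation over the five marker sets. The
#' returned manifest records the config hash, seed and per-stage record
#' counts (the detected -> validated -> merged accounting). With
#' `out_dir` set, stage tables are written as CSV/TSV/VCF/GFF3.
#'
#' @param config a [run_config()].
#' @param stages subset of c("simulate", "derive", "ld", "gwas", "qtl",
#'   "de", "coloc", "gs") or "all"; later stages require earlier ones.
#' @return list with the stage results and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), stages = "all") {
  all_stages <- c("simulate", "derive", "ld", "gwas", "qtl", "de", "coloc",
                  "gs")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  need <- function(s, what) if (!(s %in% stages))
    stop("stage '", what, "' requires stage '", s, "'")
  res <- list()
  manifest <- list(config_hash = config_hash(
    unclass(config)[setdiff(names(config), "out_dir")]),
                   seed = config$seed, counts = list())

  if ("simulate" %in% stages) {
    spec <- config$genome
    spec$seed <- config$seed
    geno <- simulate_genotypes(spec, n_accessions = config$n_accessions)
    plan <- config$qtl_plan
    plan$effects$marker <- resolve_markers(geno, plan$effects$marker)
    pheno <- simulate_phenotypes(geno, plan, n_reps = config$n_reps,
                                 seed = config$seed + 1L)
    annot <- make_annotation(spec, config$n_genes, config$gene_len_bp)
    cplan <- config$counts_plan %||%
      .default_counts_plan(config, plan, geno, annot)
    cnt <- simulate_counts(cplan, seed = config$seed + 2L)
    res$qtl_plan <- plan
    res$geno <- geno; res$pheno <- pheno; res$annotation <- annot
    res$rnaseq <- cnt
    manifest$counts$n_accessions <- nrow(geno$dosage)
    manifest$counts$n_markers <- ncol(geno$dosage)
    manifest$counts$n_genes <- nrow(annot)
  }
  if ("derive" %in% stages) {
    need("simulate", "derive")
    blues <- compute_blues(res$pheno)
    res$traits <- derive_traits(blues)
    res$trait_summary <- summarize_traits(res$traits)
    res$trait_cor <- correlate_traits(res$traits)
    manifest$counts$n_traits <- length(nue_trait_names())
  }
  if ("ld" %in% stages) {
    need("simulate", "ld")
    pairs <- pairwise_r2(res$geno, window = config$ld_window)
    res$ld_pairs <- pairs
    res$ld_decay <- list(genome = fit_ld_decay(pairs,
                                               n = nrow(res$geno$dosage)))
    for (ch in unique(pairs$chrom)) {
      sub <- pairs[pairs$chrom == ch, ]
      if (nrow(sub) >= 50)
        res$ld_decay[[as.character(ch)]] <-
          fit_ld_decay(sub, n = nrow(res$geno$dosage),
                       scope = as.character(ch))
    }
    manifest$counts$ld_decay_bp_r2_0.1 <-
      as.numeric(decay_distance(res$ld_decay$genome, 0.1))
  }
  if ("gwas" %in% stages) {
    need("derive", "gwas")
    res$grm <- vanraden_grm(res$geno)
    res$qtns <- run_mlgwas(res$traits, res$geno, G = res$grm,
                           lod_min = config$lod_min)
    manifest$counts$n_qtn_detected <- nrow(res$qtns)
  }
  if ("qtl" %in% stages) {
    need("gwas", "qtl"); need("ld", "qtl")
    res$qtns_valid <- validate_qtns(res$qtns, res$traits, res$geno,
                                    alpha = config$mw_alpha)
    if (nrow(res$qtns_valid)) {
      res$qtl <- classify_qtls(merge_qtns(res$qtns_valid, res$ld_decay,
                                          factor = config$merge_factor,
                                          r2_threshold = config$merge_r2))
      manifest$counts$n_qtl <- nrow(res$qtl$qtls)
      manifest$counts$n_major_qtl <- sum(res$qtl$qtls$major)
      manifest$counts$n_pleiotropic_qtl <- sum(res$qtl$qtls$pleiotropic)
    }
    manifest$counts$n_qtn_validated <- nrow(res$qtns_valid)
  }
  if ("de" %in% stages) {
    need("simulate", "de")
    res$degs <- rbind(
      de_test(res$rnaseq$counts, res$rnaseq$samples, "HN",
              lfc_min = config$de_lfc, fdr_max = config$de_fdr),
      de_test(res$rnaseq$counts, res$rnaseq$samples, "LN",
              lfc_min = config$de_lfc, fdr_max = config$de_fdr))
    manifest$counts$n_deg <- length(unique(res$degs$gene[res$degs$significant]))
  }
  if ("coloc" %in% stages) {
    need("qtl", "coloc"); need("de", "coloc")
    lens <- stats::setNames(config$genome$chrom_length_bp,
                            seq_along(config$genome$chrom_length_bp))
    res$coloc <- colocalize(res$qtl, res$annotation, res$degs,
                            half_window = config$window_bp,
                            chrom_lengths = lens)
    manifest$counts$n_qtl_with_deg <- res$coloc$summary$n_qtls_with_deg
    manifest$counts$n_deg_in_windows <- res$coloc$summary$n_deg_in_windows
  }
  if ("gs" %in% stages) {
    need("coloc", "gs")
    res$marker_sets <- build_marker_sets(
      res$geno, res$qtl, res$trait_cor, res$coloc,
      target = config$gs_target, m1_size = config$m1_size,
      seed = config$seed + 3L)
    fav <- stats::setNames(res$qtns_valid$favorable_dosage,
                           res$qtns_valid$marker)
    fav <- fav[!duplicated(names(fav))]
    y <- res$traits[[config$gs_target]]
    cvs <- lapply(names(res$marker_sets), function(nm) {
      W <- suppressWarnings(encode_markers(
        res$geno, res$marker_sets[[nm]], favorable = fav,
        allow_fallback = nm == "M1"))
      W <- W[res$traits$accession, , drop = FALSE]
      gblup_cv(y, W, k = config$k_folds, repeats = config$repeats,
               seed = config$seed + 4L, set_id = nm)
    })
    res$cv <- do.call(rbind, cvs)
    res$set_comparison <- compare_sets(res$cv)
    manifest$counts$mean_r_by_set <-
      stats::setNames(res$set_comparison$means$mean_r,
                      res$set_comparison$means$set)
  }
  res$manifest <- manifest
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

#' Write pipeline stage tables to an output directory
#'
#' Plain-text formats only: VCF + CSV genotypes, long phenotype CSV, GFF3
#' annotation, counts TSV + sample sheet, trait/QTN/QTL/DEG/CV tables as
#' TSV, and the manifest as YAML. Every table carries the config hash in
#' a comment-free sidecar (`manifest.yaml`).
#'
#' @param res result list from [run_pipeline()].
#' @param out_dir directory (created if needed).
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  wtsv <- function(x, f) utils::write.table(
    x, fp(f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$geno)) {
    write_genotypes_vcf(res$geno, fp("genotypes.vcf"))
    write_genotypes_csv(res$geno, fp("genotypes.csv"))
  }
  if (!is.null(res$pheno))
    utils::write.csv(res$pheno, fp("phenotypes.csv"), row.names = FALSE)
  if (!is.null(res$annotation))
    write_annotation_gff3(res$annotation, fp("annotation.gff3"))
  if (!is.null(res$rnaseq)) {
    wtsv(data.frame(gene = rownames(res$rnaseq$counts), res$rnaseq$counts,
                    check.names = FALSE), "counts.tsv")
    utils::write.csv(res$rnaseq$samples, fp("samples.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$traits)) wtsv(res$traits, "traits.tsv")
  if (!is.null(res$trait_summary)) wtsv(res$trait_summary,
                                        "trait_summary.tsv")
  if (!is.null(res$qtns)) wtsv(as.data.frame(res$qtns), "qtns.tsv")
  if (!is.null(res$qtns_valid)) wtsv(as.data.frame(res$qtns_valid),
                                     "qtns_validated.tsv")
  if (!is.null(res$qtl)) {
    wtsv(res$qtl$qtls, "qtls.tsv")
    wtsv(res$qtl$members, "qtl_members.tsv")
  }
  if (!is.null(res$degs)) wtsv(res$degs, "degs.tsv")
  if (!is.null(res$coloc)) {
    wtsv(res$coloc$hits, "coloc_hits.tsv")
    wtsv(res$coloc$summary, "coloc_summary.tsv")
  }
  if (!is.null(res$cv)) wtsv(as.data.frame(res$cv), "cv_results.tsv")
  if (!is.null(res$set_comparison)) wtsv(res$set_comparison$means,
                                         "set_comparison.tsv")
  yaml::write_yaml(res$manifest, fp("manifest.yaml"))
  invisible(out_dir)
}
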