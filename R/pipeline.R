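#' @include io.R
NULL

#' Default pipeline configuration
#'
#' All parameters of the end-to-end synthetic pipeline with their
#' documented ranges. Values are validated by [validateConfig()] before
#' any stage runs.
#'
#' @param ... overrides for any default entry.
#' @return named list.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = tempfile("toxqtl_run_"),
    # simulation scale
    n_riails = 250L, n_wild = 150L, n_markers = 500L,
    n_subpopulations = 3L, fst_like_divergence = 0.2,
    qtl_ve = 0.20, n_intercross_generations = 10L,
    # mapping parameters
    n_perm = 1000L, alpha = 0.05, drop = 1.5, maf = 0.05,
    roi_width = 50L, window_snvs = 300L, step_snvs = 100L,
    # enrichment scenario
    edit_fraction_pre = 0.001, relative_fitness_edited = 1.75,
    n_generations = 10, depth = 1e6)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every parameter against its documented range; any violation
#' aborts before compute starts.
#'
#' @param config named list (see [defaultConfig()]).
#' @return `config`, invisibly, or an error.
#' @export
validateConfig <- function(config) {
  chk <- function(ok, msg) if (!ok) stop("config: ", msg, call. = FALSE)
  chk(is.numeric(config$seed) && length(config$seed) == 1, "seed must be one integer")
  chk(config$alpha > 0 && config$alpha < 1, "alpha must lie in (0, 1)")
  chk(config$maf >= 0 && config$maf < 0.5, "maf must lie in [0, 0.5)")
  chk(config$n_perm >= 100, "n_perm must be >= 100")
  chk(config$drop > 0, "drop must be > 0")
  chk(config$roi_width >= 0, "roi_width must be >= 0")
  chk(config$window_snvs >= 1 && config$step_snvs >= 1,
      "window/step must be >= 1")
  chk(config$n_riails >= 10, "n_riails must be >= 10")
  chk(config$n_wild >= 10, "n_wild must be >= 10")
  chk(config$qtl_ve > 0 && config$qtl_ve < 1, "qtl_ve must lie in (0, 1)")
  chk(config$fst_like_divergence >= 0 && config$fst_like_divergence < 1,
      "fst_like_divergence must lie in [0, 1)")
  chk(config$edit_fraction_pre > 0 && config$edit_fraction_pre < 1,
      "edit_fraction_pre must lie in (0, 1)")
  chk(config$depth > 0, "depth must be > 0")
  invisible(config)
}

stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes, in order: simulation of RIAIL and wild panels with a planted
#' QTL, linkage scan with permutation threshold and LOD-drop intervals,
#' kinship-corrected association scan with regions of interest, Spearman
#' fine mapping in the region, sliding-window Tajima's D, and pooled
#' CRISPR enrichment statistics. Every artifact is written under
#' `config$out_dir` and stamped (in `run.json`) with the seed and a hash
#' of the parameters; identical configurations give identical artifacts.
#'
#' @param config validated configuration list (see [defaultConfig()]).
#' @return named list of artifact paths and headline results, invisibly.
#' @export
runPipeline <- function(config = defaultConfig()) {
  validateConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  art <- list()

  stageLog("simulate", "markers=%d riails=%d wild=%d",
           config$n_markers, config$n_riails, config$n_wild)
  mm <- elegansMarkerMap(config$n_markers)
  riails <- simulateRiailGenotypes(config$n_riails, mm,
                                   config$n_intercross_generations,
                                   seed = seed)
  wild <- simulateWildPanel(config$n_wild, mm, config$n_subpopulations,
                            config$fst_like_divergence, seed = seed + 1L)
  qtl_marker <- markerMap(riails)$marker_id[
    which(markerMap(riails)$chromosome == "II")[
      ceiling(sum(markerMap(riails)$chromosome == "II") * 0.75)]]
  qtls <- data.frame(marker_id = qtl_marker,
                     variance_explained = config$qtl_ve)
  trait_riail <- simulatePhenotypes(riails, qtls, seed = seed + 2L,
                                    trait = "length")
  trait_wild <- simulatePhenotypes(wild, qtls, polygenic_h2 = 0.2,
                                   seed = seed + 3L, trait = "length")
  art$genotypes_tsv <- writeGenotypesTsv(
    riails, file.path(config$out_dir, "riail_genotypes.tsv"))
  art$genotypes_vcf <- writeGenotypesVcf(
    wild, file.path(config$out_dir, "wild_genotypes.vcf"))

  stageLog("linkage", "n_perm=%d alpha=%g", config$n_perm, config$alpha)
  scan <- genomeScan(riails, trait_riail)
  thr <- permutationThreshold(
    riails, matrix(trait_riail$value, ncol = 1,
                   dimnames = list(trait_riail$strain, "length")),
    n_perm = config$n_perm, alpha = config$alpha, seed = seed + 4L)
  scan@thresholdMode <- "max-lod-quantile"
  scan <- lodDropIntervals(scan, drop = config$drop, h2 = NULL,
                           threshold = as.numeric(thr))
  art$scan_tsv <- writeScanTsv(scan, file.path(config$out_dir,
                                               "linkage_scan.tsv"))

  stageLog("gwas", "maf=%g", config$maf)
  K <- computeKinship(wild)
  gwa <- gwaScan(wild, trait_wild, K = K, min_maf = config$maf,
                 alpha = config$alpha)
  gwa <- defineRoi(gwa, width_in_snvs = config$roi_width)
  write.table(gwaTable(gwa),
              file.path(config$out_dir, "gwa_scan.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  art$gwa_tsv <- file.path(config$out_dir, "gwa_scan.tsv")
  if (nrow(regions(gwa)) > 0)
    art$roi_bed <- writeRegionsBed(gwa, file.path(config$out_dir,
                                                  "regions.bed"))

  stageLog("finemap", "regions=%d", nrow(regions(gwa)))
  finemap <- NULL
  if (nrow(regions(gwa)) > 0) {
    corrected <- correctPhenotypeForKinship(trait_wild, K)
    reg <- regions(gwa)[1, ]
    mmw <- markerMap(wild)
    inroi <- mmw$chromosome == reg$chromosome &
      mmw$position_bp >= reg$left_bp & mmw$position_bp <= reg$right_bp
    calls <- genotypeCalls(wild)[, inroi, drop = FALSE]
    variants <- cbind(
      data.frame(variant_id = mmw$marker_id[inroi],
                 chromosome = mmw$chromosome[inroi],
                 position_bp = mmw$position_bp[inroi],
                 gene = "synthetic_gene",
                 effect_class = rep_len(c("MODERATE", "HIGH"), sum(inroi))),
      as.data.frame(t(calls)))
    finemap <- variantCorrelation(variants, corrected)
    write.table(finemap, file.path(config$out_dir, "finemap.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    art$finemap_tsv <- file.path(config$out_dir, "finemap.tsv")
  }

  stageLog("tajima", "window=%d step=%d", config$window_snvs,
           config$step_snvs)
  taj <- suppressWarnings(
    slidingTajimasD(wild, window_snvs = config$window_snvs,
                    step_snvs = config$step_snvs))
  write.table(taj, file.path(config$out_dir, "tajima.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  art$tajima_tsv <- file.path(config$out_dir, "tajima.tsv")

  stageLog("enrich", "pre=%g fitness=%g", config$edit_fraction_pre,
           config$relative_fitness_edited)
  rc <- simulatePooledReadcounts(config$edit_fraction_pre,
                                 config$relative_fitness_edited,
                                 config$n_generations, config$depth,
                                 seed = seed + 5L)
  enr <- enrichmentFromTable(rc)
  art$readcounts_csv <- writeReadCounts(rc, file.path(config$out_dir,
                                                      "readcounts.csv"))
  write.csv(enr, file.path(config$out_dir, "enrichment.csv"),
            row.names = FALSE)
  art$enrichment_csv <- file.path(config$out_dir, "enrichment.csv")

  stamp <- list(seed = seed,
                parameter_hash = paste0("sum", sum(utf8ToInt(paste(
                  names(config), vapply(config, paste, character(1),
                                        collapse = ","), collapse = ";")))),
                parameters = config[setdiff(names(config), "out_dir")])
  jsonlite::write_json(stamp, file.path(config$out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA)
  art$run_json <- file.path(config$out_dir, "run.json")

  invisible(list(artifacts = art, scan = scan, gwa = gwa,
                 finemap = finemap, tajima = taj, enrichment = enr,
                 qtl_marker = qtl_marker))
}
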