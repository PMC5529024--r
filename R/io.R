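#' @include crispr.R
NULL

#' Read and write genotype matrices
#'
#' Two on-disk formats, both with 1-based marker positions:
#' \describe{
#'   \item{TSV}{genotype table with a `strain` column and one 0/1 column
#'     per marker, plus a sidecar map at `<path>.map` (columns
#'     `marker_id`, `chromosome`, `position_bp`, `genetic_pos_cM`), in the
#'     spirit of PLINK's ped/map split. Shuffled marker columns are
#'     re-sorted deterministically by (chromosome, position) on read.}
#'   \item{VCF}{minimal VCFv4.2 with homozygous GT fields: `0/0` maps to
#'     0, `1/1` to 1, and `0/1` (policy: heterozygotes are not expected
#'     in inbred panels, logged with a warning) or `./.` to missing.
#'     Multi-allelic sites are skipped with a count. The genetic position
#'     is carried in the `CM` INFO key; when absent, 1 cM/Mb from the
#'     chromosome's first marker is assumed.}
#' }
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"` (default: guessed from the
#'   extension).
#' @param genotypes a [GenotypeMatrix-class] (writers).
#' @return readers return a [GenotypeMatrix-class]; writers return
#'   `path` invisibly.
#' @name genotype-io
NULL

#' @rdname genotype-io
#' @export
writeGenotypesTsv <- function(genotypes, path) {
  calls <- genotypeCalls(genotypes)
  df <- data.frame(strain = rownames(calls), calls, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(markerMap(genotypes), paste0(path, ".map"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname genotype-io
#' @export
writeGenotypesVcf <- function(genotypes, path) {
  calls <- genotypeCalls(genotypes)
  mm <- markerMap(genotypes)
  gt <- matrix(c("0/0", "1/1")[calls + 1L], nrow(calls), ncol(calls))
  gt[is.na(calls)] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic position in cM\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(calls)), collapse = "\t")), con)
  body <- cbind(mm$chromosome, mm$position_bp, mm$marker_id, "A", "T", ".",
                "PASS", sprintf("CM=%g", mm$genetic_pos_cM), "GT", t(gt))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname genotype-io
#' @export
readGenotypes <- function(path, format = c("guess", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE)
    mappath <- paste0(path, ".map")
    if (!file.exists(mappath))
      stop("marker map sidecar not found: ", mappath)
    mm <- read.delim(mappath)
    calls <- as.matrix(df[, setdiff(names(df), "strain"), drop = FALSE])
    rownames(calls) <- df$strain
    return(GenotypeMatrix(calls, mm))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    message(sum(multi), " multi-allelic site(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  norm <- gsub("\\|", "/", gt)
  calls <- matrix(NA_integer_, nrow(norm), ncol(norm),
                  dimnames = dimnames(norm))
  calls[norm == "0/0"] <- 0L
  calls[norm == "1/1"] <- 1L
  nhet <- sum(norm %in% c("0/1", "1/0"), na.rm = TRUE)
  if (nhet > 0)
    warning(nhet, " heterozygous call(s) set to missing")
  info <- if ("INFO" %in% colnames(fix)) fix[, "INFO"] else rep(".", nrow(fix))
  cm <- suppressWarnings(as.numeric(sub("^.*CM=([-0-9.eE+]+).*$", "\\1", info)))
  pos <- as.integer(fix[, "POS"])
  chrom <- fix[, "CHROM"]
  if (anyNA(cm)) {
    # 1 cM/Mb fallback from each chromosome's first marker
    for (ch in unique(chrom)) {
      i <- chrom == ch
      cm[i] <- (pos[i] - min(pos[i])) / 1e6
    }
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- sprintf("%s_%d", chrom, pos)[
    is.na(ids) | ids == "."]
  mm <- data.frame(marker_id = ids, chromosome = chrom, position_bp = pos,
                   genetic_pos_cM = cm)
  GenotypeMatrix(t(calls), mm)
}

#' Write a genome scan as TSV plus a JSON sidecar
#'
#' The TSV carries one row per marker (`marker_id`, `chromosome`,
#' `position_bp` 1-based, `lod`, `n`); thresholds, peaks and intervals go
#' to `<path>.json`.
#'
#' @param scan a [ScanResult-class].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
writeScanTsv <- function(scan, path) {
  write.table(scan@scanTable, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  side <- list(trait = scan@trait, threshold = scan@threshold,
               threshold_mode = scan@thresholdMode, peaks = scan@peaks,
               intervals = scan@intervals)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Export regions of interest as BED
#'
#' Regions are stored 1-based inclusive; BED is 0-based half-open. The
#' conversion is delegated to \pkg{rtracklayer} via a `GRanges`
#' round-trip, so `left_bp = 100, right_bp = 200` becomes the BED line
#' `chrom 99 200`.
#'
#' @param regions regions data.frame (`chromosome`, `left_bp`,
#'   `right_bp`, optional `peak_marker` used as the BED name) or a
#'   [GwaResult-class].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
writeRegionsBed <- function(regions, path) {
  if (is(regions, "GwaResult")) regions <- regions(regions)
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chromosome,
    ranges = IRanges::IRanges(start = regions$left_bp,
                              end = regions$right_bp),
    name = if ("peak_marker" %in% names(regions)) regions$peak_marker
    else paste0("region", seq_len(nrow(regions))))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Import a BED file as 1-based regions
#'
#' Inverse of [writeRegionsBed()]: BED's 0-based half-open intervals come
#' back 1-based inclusive.
#'
#' @param path BED path.
#' @return data.frame `chromosome`, `left_bp`, `right_bp`, `name`.
#' @export
readRegionsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
             left_bp = GenomicRanges::start(gr),
             right_bp = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_)
}

#' Read and write well records as CSV
#'
#' The list column `animal_lengths` is serialized as a
#' semicolon-separated string.
#'
#' @param wells well records data.frame.
#' @param path CSV path.
#' @return reader: well records data.frame; writer: `path` invisibly.
#' @name well-io
NULL

#' @rdname well-io
#' @export
writeWellRecords <- function(wells, path) {
  out <- wells
  out$animal_lengths <- vapply(wells$animal_lengths, paste,
                               collapse = ";", FUN.VALUE = character(1))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname well-io
#' @export
readWellRecords <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$animal_lengths <- I(lapply(strsplit(as.character(df$animal_lengths),
                                         ";", fixed = TRUE), as.numeric))
  if (!"exclude" %in% names(df)) df$exclude <- FALSE
  df
}

#' Read and write pooled read-count tables as CSV
#'
#' Columns: `locus`, `condition`, `timepoint`, `wildtype_reads`,
#' `edited_reads`.
#'
#' @param readcounts read-count table.
#' @param path CSV path.
#' @return reader: read-count data.frame; writer: `path` invisibly.
#' @name readcount-io
NULL

#' @rdname readcount-io
#' @export
writeReadCounts <- function(readcounts, path) {
  write.csv(readcounts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readcount-io
#' @export
readReadCounts <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus", "condition", "timepoint", "wildtype_reads",
            "edited_reads")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("read-count table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  bad <- df$wildtype_reads + df$edited_reads <= 0
  if (any(bad)) stop("rows with zero total reads: ", sum(bad))
  df
}

#' Read annotated variants from a flat TSV
#'
#' Expected columns: `variant_id`, `chromosome`, `position_bp`, `gene`,
#' `effect_class` (HIGH/MODERATE/LOW/MODIFIER), then one 0/1/NA genotype
#' column per strain. Effect classes are consumed as provided — no effect
#' prediction is performed.
#'
#' @param path TSV path.
#' @return annotated variant data.frame (see [variantCorrelation()]).
#' @export
readAnnotatedVariants <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("variant_id", "chromosome", "position_bp", "gene",
            "effect_class")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("variant table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Read a dose-response phenotype table
#'
#' CSV with one row per replicate measurement: columns `strain`, `drug`,
#' `concentration`, `phenotype` (additional columns pass through).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readDoseResponse <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "drug", "concentration", "phenotype")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("dose-response table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Broad-sense heritability per drug and concentration
#'
#' Applies [estimateHeritability()] to every drug x concentration cell of
#' a dose-response table.
#'
#' @param dose_response data.frame as returned by [readDoseResponse()].
#' @return data.frame: `drug`, `concentration`, `H2`, `var_strain`,
#'   `var_resid`, `n_strains`, `n_obs`.
#' @export
heritabilityByDose <- function(dose_response) {
  cells <- unique(dose_response[c("drug", "concentration")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- dose_response[dose_response$drug == cells$drug[i] &
                           dose_response$concentration ==
                           cells$concentration[i], ]
    h <- estimateHeritability(data.frame(strain = sub$strain,
                                         value = sub$phenotype))
    data.frame(drug = cells$drug[i], concentration = cells$concentration[i],
               H2 = h@H2, var_strain = h@varStrain, var_resid = h@varResid,
               n_strains = length(unique(sub$strain)), n_obs = nrow(sub))
  })
  do.call(rbind, rows)
}
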