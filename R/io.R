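# Canonical file formats: the long genotype TSV dialect, VCF import, and
# bundle export.
#
# Genotype TSV dialect: UTF-8, tab-separated, mandatory header, columns
# dataset_id, family_id, individual_id, generation (F0A|F0B|F1|F2|F3),
# environment (lab|pond), marker_id, chromosome, allele_1, allele_2,
# coverage, length_mm; missing values encoded "NA"; one row per
# individual x marker. A long format subsumes microsatellite, SNP-array,
# and GBS panels alike; physical positions are not used by any statistic,
# so chromosome is an opaque label.

#' Read a long-format genotype TSV
#'
#' Parses and validates the canonical genotype dialect (see Details in
#' [write_genotype_tsv()]). Unknown extra columns are preserved as opaque
#' metadata. Structural problems (missing mandatory columns, unknown
#' generation labels, half-missing allele pairs, duplicate calls) raise
#' structured errors naming the offending lines; an empty file with a valid
#' header yields an empty table with a warning.
#'
#' @param path Path to a TSV file.
#' @return A validated `cross_genotypes` tibble.
#' @export
read_genotype_tsv <- function(path) {
  if (!file.exists(path)) {
    abort_exhet(paste0("File not found: ", path), "file_not_found")
  }
  parsers <- list(
    dataset_id = readr::col_character(),
    family_id = readr::col_character(),
    individual_id = readr::col_character(),
    generation = readr::col_character(),
    environment = readr::col_character(),
    marker_id = readr::col_character(),
    chromosome = readr::col_character(),
    allele_1 = readr::col_character(),
    allele_2 = readr::col_character(),
    coverage = readr::col_integer(),
    length_mm = readr::col_double()
  )
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  spec <- do.call(readr::cols,
                  c(parsers[intersect(names(parsers), header)],
                    .default = list(readr::col_character())))
  raw <- readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                         progress = FALSE, col_types = spec)
  missing_cols <- setdiff(genotype_columns, names(raw))
  if (length(missing_cols) > 0) {
    abort_exhet(paste0("Missing mandatory column(s): ",
                       paste(missing_cols, collapse = ", ")), "bad_columns")
  }
  if (nrow(raw) == 0) {
    warn_exhet("Genotype file has a valid header but no records.", "empty_file")
    return(new_cross_genotypes(raw))
  }
  validate_cross_genotypes(raw)
}

#' Write a genotype table in the canonical TSV dialect
#'
#' @param cross A `cross_genotypes` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(cross, path) {
  cross <- validate_cross_genotypes(cross)
  readr::write_tsv(cross, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Import genotypes from a VCF file
#'
#' Converts biallelic VCF records into the canonical long genotype format
#' using REF/ALT nucleotides as allele tokens; the `DP` FORMAT field, when
#' present, is mapped to per-call coverage. Multiallelic sites and
#' half-missing genotypes are set missing, with counts reported in
#' attributes `multiallelic_sites` and `half_missing_calls`.
#'
#' @param path Path to a VCF (4.x) file.
#' @param pedigree_map A data frame assigning every VCF sample to the
#'   pedigree: columns `sample_id`, `dataset_id`, `family_id`, `generation`,
#'   `environment`, and optionally `individual_id` (defaults to the sample
#'   id) and `length_mm`.
#' @return A validated `cross_genotypes` tibble.
#' @export
import_vcf <- function(path, pedigree_map) {
  if (!file.exists(path)) {
    abort_exhet(paste0("File not found: ", path), "file_not_found")
  }
  need <- c("sample_id", "dataset_id", "family_id", "generation", "environment")
  missing_cols <- setdiff(need, names(pedigree_map))
  if (length(missing_cols) > 0) {
    abort_exhet(paste0("pedigree_map lacks column(s): ",
                       paste(missing_cols, collapse = ", ")), "bad_pedigree_map")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  unmapped <- setdiff(samples, pedigree_map$sample_id)
  if (length(unmapped) > 0) {
    abort_exhet(paste0("VCF sample(s) absent from pedigree_map: ",
                       paste(unmapped, collapse = ", ")), "unmapped_samples")
  }
  fixed <- tibble::as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))
  biallelic <- vcfR::is.biallelic(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- tryCatch(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)

  marker_id <- fixed$ID
  fallback <- is.na(marker_id) | marker_id == "."
  marker_id[fallback] <- paste0(fixed$CHROM, "_", fixed$POS)[fallback]

  n_sites <- nrow(fixed)
  long <- tidyr::expand_grid(site = seq_len(n_sites), sample = samples)
  g <- gt[cbind(long$site, match(long$sample, samples))]
  # normalize separators and split
  g <- gsub("|", "/", g, fixed = TRUE)
  parts <- strsplit(ifelse(is.na(g), "./.", g), "/", fixed = TRUE)
  a1i <- vapply(parts, function(p) p[1] %||% ".", character(1))
  a2i <- vapply(parts, function(p) if (length(p) > 1) p[2] else ".", character(1))
  half_missing <- xor(a1i == ".", a2i == ".")
  a1i[half_missing] <- "."
  a2i[half_missing] <- "."
  not_biallelic <- !biallelic[long$site]

  tok <- function(idx, site) {
    out <- rep(NA_character_, length(idx))
    ref <- fixed$REF[site]
    alt <- fixed$ALT[site]
    out[idx == "0"] <- ref[idx == "0"]
    out[idx == "1"] <- alt[idx == "1"]
    out
  }
  allele_1 <- tok(a1i, long$site)
  allele_2 <- tok(a2i, long$site)
  allele_1[not_biallelic] <- NA_character_
  allele_2[not_biallelic] <- NA_character_
  drop_pair <- is.na(allele_1) | is.na(allele_2)
  allele_1[drop_pair] <- NA_character_
  allele_2[drop_pair] <- NA_character_

  ped <- tibble::as_tibble(pedigree_map)
  if (!"individual_id" %in% names(ped)) ped$individual_id <- ped$sample_id
  if (!"length_mm" %in% names(ped)) ped$length_mm <- NA_real_
  pi <- match(long$sample, ped$sample_id)

  out <- tibble::tibble(
    dataset_id = ped$dataset_id[pi],
    family_id = ped$family_id[pi],
    individual_id = ped$individual_id[pi],
    generation = ped$generation[pi],
    environment = ped$environment[pi],
    marker_id = marker_id[long$site],
    chromosome = fixed$CHROM[long$site],
    allele_1 = allele_1,
    allele_2 = allele_2,
    coverage = if (is.null(dp)) NA_integer_ else
      as.integer(dp[cbind(long$site, match(long$sample, samples))]),
    length_mm = ped$length_mm[pi]
  )
  out <- validate_cross_genotypes(out)
  attr(out, "multiallelic_sites") <- sum(!biallelic)
  attr(out, "half_missing_calls") <- sum(half_missing)
  out
}

#' Write a simulated study bundle to disk
#'
#' Emits the pooled genotype TSV, the dataset manifest TSV, and a YAML
#' sidecar echoing the full generator configuration and seed.
#'
#' @param bundle A `study_bundle` from [generate_study_bundle()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!inherits(bundle, "study_bundle")) {
    abort_exhet("`bundle` must be a study_bundle.", "bad_bundle")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotype_tsv(bundle$genotypes, file.path(dir, "genotypes.tsv"))
  readr::write_tsv(bundle$manifest, file.path(dir, "manifest.tsv"), na = "NA",
                   progress = FALSE)
  cfg <- bundle$config
  cfg$selection <- if (is.null(cfg$selection)) NULL else unclass(cfg$selection)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
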