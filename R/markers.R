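#' Select ancestry-diagnostic markers for a cross
#'
#' A marker is diagnostic when (a) the side-A founders and side-B founders
#' share no alleles (their allele-set unions are disjoint, so every allele's
#' ancestry is unambiguous -- for multi-founder designs the rule is applied to
#' the unions across all same-side founders), (b) every genotyped F1 hybrid
#' carries exactly one allele from each side, and (c) the marker is not on
#' the sex chromosome. Calls whose read depth is at or below `min_coverage`
#' (GBS data) are treated as missing before the rules are evaluated; the
#' depth rule is strict ("more than 20x" retains a call).
#'
#' The returned panel also records, as attribute `f1_validation_rate`, the
#' fraction of non-missing F1 calls at side-disjoint markers that are
#' cross-side heterozygous -- a genotyping-quality check that equals 1 in a
#' clean cross.
#'
#' @param cross A `cross_genotypes` table for a single dataset.
#' @param sex_chrom_label Chromosome label excluded from analysis
#'   (default `"19"`, the stickleback sex chromosome).
#' @param min_coverage Depth threshold; calls with `coverage <= min_coverage`
#'   are masked before evaluation. Default 20.
#' @return A `marker_panel` tibble: `marker_id`, `chromosome`,
#'   `side_A_alleles`, `side_B_alleles` (list columns), `diagnostic`,
#'   `rejection_reason` (`NA` for diagnostic markers; otherwise the first
#'   failed rule among `shared_alleles`, `no_f0_calls`,
#'   `f1_not_heterozygous`, `sex_chromosome`).
#' @export
select_diagnostic_markers <- function(cross, sex_chrom_label = "19",
                                      min_coverage = 20) {
  cross <- validate_cross_genotypes(cross)
  if (dplyr::n_distinct(cross$dataset_id) > 1) {
    abort_exhet(
      "`cross` spans multiple datasets; select markers one dataset at a time.",
      "multiple_datasets")
  }
  gens <- unique(cross$generation)
  if (!all(c("F0A", "F0B") %in% gens)) {
    abort_exhet("Cross has no F0A or no F0B founders.", "missing_founders")
  }
  if (!"F1" %in% gens) {
    abort_exhet("Cross has no F1 individuals.", "missing_f1")
  }

  cross <- mask_low_coverage(cross, min_coverage)

  marker_tab <- dplyr::distinct(cross, .data$marker_id, .data$chromosome)
  called <- dplyr::filter(cross, !is.na(.data$allele_1))

  side_sets <- function(gen) {
    f0 <- dplyr::filter(called, .data$generation == gen)
    tokens <- tapply(c(f0$allele_1, f0$allele_2), rep(f0$marker_id, 2),
                     function(x) sort(unique(x)), simplify = FALSE)
    tokens
  }
  a_sets <- side_sets("F0A")
  b_sets <- side_sets("F0B")

  ids <- marker_tab$marker_id
  side_a <- a_sets[ids]
  side_b <- b_sets[ids]
  names(side_a) <- names(side_b) <- ids
  no_f0 <- vapply(ids, function(m) {
    is.null(side_a[[m]]) || is.null(side_b[[m]])
  }, logical(1))
  shared <- vapply(ids, function(m) {
    if (no_f0[[m]]) return(FALSE)
    length(intersect(side_a[[m]], side_b[[m]])) > 0
  }, logical(1))
  disjoint <- !no_f0 & !shared

  f1 <- dplyr::filter(called, .data$generation == "F1",
                      .data$marker_id %in% ids[disjoint])
  if (nrow(f1) > 0) {
    # per-marker side membership of each F1 allele, via (marker, token) keys
    key_a <- paste(rep(f1$marker_id, 2), c(f1$allele_1, f1$allele_2))
    pool_a <- unlist(lapply(ids[disjoint], function(m) paste(m, side_a[[m]])))
    pool_b <- unlist(lapply(ids[disjoint], function(m) paste(m, side_b[[m]])))
    m1 <- matrix(key_a %in% pool_a, ncol = 2)
    m2 <- matrix(key_a %in% pool_b, ncol = 2)
    f1_ok <- (rowSums(m1) == 1) & (rowSums(m2) == 1)
    f1_rate <- mean(f1_ok)
    bad_f1_markers <- unique(f1$marker_id[!f1_ok])
  } else {
    f1_rate <- NA_real_
    bad_f1_markers <- character(0)
  }

  reason <- rep(NA_character_, length(ids))
  reason[shared] <- "shared_alleles"
  reason[no_f0] <- "no_f0_calls"
  reason[is.na(reason) & ids %in% bad_f1_markers] <- "f1_not_heterozygous"
  reason[is.na(reason) & marker_tab$chromosome == sex_chrom_label] <- "sex_chromosome"

  panel <- tibble::tibble(
    marker_id = ids,
    chromosome = marker_tab$chromosome,
    side_A_alleles = unname(lapply(side_a, function(x) x %||% character(0))),
    side_B_alleles = unname(lapply(side_b, function(x) x %||% character(0))),
    diagnostic = is.na(reason),
    rejection_reason = reason
  )
  if (!any(panel$diagnostic)) {
    warn_exhet("No diagnostic markers retained for this cross.", "empty_panel")
  }
  attr(panel, "f1_validation_rate") <- f1_rate
  attr(panel, "min_coverage") <- min_coverage
  attr(panel, "sex_chrom_label") <- sex_chrom_label
  class(panel) <- c("marker_panel", class(panel))
  panel
}

mask_low_coverage <- function(cross, min_coverage) {
  low <- !is.na(cross$coverage) & cross$coverage <= min_coverage
  cross$allele_1[low] <- NA_character_
  cross$allele_2[low] <- NA_character_
  cross
}
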