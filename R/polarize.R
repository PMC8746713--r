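#' Polarize genotype calls to ancestry dosages
#'
#' Converts allele calls at diagnostic markers into counts of side-B ancestry
#' alleles: 0 (homozygous side-A), 1 (ancestry heterozygote), or 2
#' (homozygous side-B). Calls containing any token found in neither founder
#' side set (e.g. a novel mutation or genotyping artifact) are set missing
#' and counted in the `novel_calls` attribute. Calls below the panel's
#' coverage threshold are masked exactly as during marker selection.
#'
#' @param cross The `cross_genotypes` table the panel was built from.
#' @param panel A `marker_panel` from [select_diagnostic_markers()].
#' @return An `ancestry_matrix`: list with `dosage` (individuals x diagnostic
#'   markers integer matrix with `NA` for missing), `individuals`, and
#'   `markers` metadata tibbles.
#' @export
polarize_to_ancestry <- function(cross, panel) {
  if (!inherits(panel, "marker_panel")) {
    abort_exhet("`panel` must come from select_diagnostic_markers().", "bad_panel")
  }
  cross <- validate_cross_genotypes(cross)
  diag_panel <- panel[panel$diagnostic, ]
  missing_markers <- setdiff(diag_panel$marker_id, unique(cross$marker_id))
  if (length(missing_markers) > 0) {
    abort_exhet(paste0("Panel marker(s) absent from cross: ",
                       paste(head(missing_markers, 5), collapse = ", ")),
                "marker_not_in_cross")
  }
  cross <- mask_low_coverage(cross, attr(panel, "min_coverage") %||% 20)
  calls <- dplyr::filter(cross, .data$marker_id %in% diag_panel$marker_id)

  pool_key <- function(col) {
    unlist(lapply(seq_len(nrow(diag_panel)), function(i) {
      paste(diag_panel$marker_id[i], diag_panel[[col]][[i]])
    }))
  }
  pool_a <- pool_key("side_A_alleles")
  pool_b <- pool_key("side_B_alleles")
  k1 <- paste(calls$marker_id, calls$allele_1)
  k2 <- paste(calls$marker_id, calls$allele_2)
  b1 <- k1 %in% pool_b
  b2 <- k2 %in% pool_b
  known1 <- b1 | (k1 %in% pool_a)
  known2 <- b2 | (k2 %in% pool_a)
  called <- !is.na(calls$allele_1)
  novel <- called & !(known1 & known2)
  dosage_vec <- ifelse(called & !novel, as.integer(b1) + as.integer(b2),
                       NA_integer_)

  individuals <- calls |>
    dplyr::distinct(.data$individual_id, .data$dataset_id, .data$family_id,
                    .data$generation, .data$environment, .data$length_mm)
  if (anyDuplicated(individuals$individual_id)) {
    individuals <- dplyr::distinct(individuals, .data$individual_id,
                                   .keep_all = TRUE)
  }
  # order generations founders-first for readability
  gen_rank <- match(individuals$generation, all_generations)
  individuals <- individuals[order(gen_rank, individuals$individual_id), ]

  ri <- match(calls$individual_id, individuals$individual_id)
  ci <- match(calls$marker_id, diag_panel$marker_id)
  dosage <- matrix(NA_integer_, nrow(individuals), nrow(diag_panel))
  dosage[cbind(ri, ci)] <- dosage_vec

  markers <- tibble::tibble(marker_id = diag_panel$marker_id,
                            chromosome = diag_panel$chromosome)
  out <- new_ancestry_matrix(dosage, individuals, markers)
  attr(out, "novel_calls") <- sum(novel)
  attr(out, "side_A_alleles") <- diag_panel$side_A_alleles
  attr(out, "side_B_alleles") <- diag_panel$side_B_alleles
  out
}
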