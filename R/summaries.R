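#' Per-individual ancestry heterozygosity summaries
#'
#' For each recombinant (F2/F3) individual, over its non-missing diagnostic
#' loci: the hybrid index \eqn{h} (frequency of side-B ancestry alleles,
#' i.e. dosage sum over `2 * n_loci`), observed ancestry heterozygosity
#' \eqn{p_{AB}} (fraction of heterozygous loci), expected heterozygosity
#' \eqn{2 p_A p_B = 2h(1-h)} computed from the individual's own genome-wide
#' ancestry frequencies, and the excess
#' \eqn{p_{AB} - 2 p_A p_B}. Positive excess indicates enrichment of
#' ancestry heterozygotes beyond the Hardy-Weinberg expectation, the
#' genome-wide signature of selection against hybrid incompatibilities.
#'
#' @param matrix An `ancestry_matrix`, normally after
#'   [apply_matrix_filters()].
#' @param statistic Which quantity to expose as the `response` column for
#'   downstream models: `"excess"` (default) or `"observed"` (a robustness
#'   variant using raw observed heterozygosity).
#' @param correction `"none"` (default) or `"small_sample"`, which multiplies
#'   the expected heterozygosity by \eqn{2N/(2N-1)} with \eqn{N} the number
#'   of genotyped loci, removing the finite-loci downward bias of
#'   \eqn{2h(1-h)}.
#' @return A tibble with one row per recombinant: `individual_id`,
#'   `dataset_id`, `family_id`, `environment`, `generation`, `length_mm`,
#'   `n_loci`, `hybrid_index`, `observed_het`, `expected_het`, `excess_het`,
#'   `response`.
#' @export
summarize_individuals <- function(matrix, statistic = c("excess", "observed"),
                                  correction = c("none", "small_sample")) {
  statistic <- match.arg(statistic)
  correction <- match.arg(correction)
  if (!inherits(matrix, "ancestry_matrix")) {
    abort_exhet("`matrix` must be an ancestry_matrix.", "bad_matrix")
  }
  rec <- recombinant_rows(matrix)
  if (length(rec) == 0) {
    abort_exhet("No recombinant (F2/F3) individuals to summarize.", "no_recombinants")
  }
  d <- unname(matrix$dosage[rec, , drop = FALSE])
  n_loci <- rowSums(!is.na(d))
  if (any(n_loci == 0)) {
    abort_exhet("Individual(s) with zero genotyped loci; filter the matrix first.",
                "zero_loci")
  }
  observed <- rowSums(d == 1, na.rm = TRUE) / n_loci
  h <- rowSums(d, na.rm = TRUE) / (2 * n_loci)
  expected <- 2 * h * (1 - h)
  if (correction == "small_sample") {
    expected <- expected * (2 * n_loci) / (2 * n_loci - 1)
  }
  out <- dplyr::bind_cols(
    matrix$individuals[rec, c("individual_id", "dataset_id", "family_id",
                              "environment", "generation", "length_mm")],
    tibble::tibble(
      n_loci = n_loci,
      hybrid_index = h,
      observed_het = observed,
      expected_het = expected,
      excess_het = observed - expected
    )
  )
  out$response <- if (statistic == "excess") out$excess_het else out$observed_het
  attr(out, "statistic") <- statistic
  attr(out, "correction") <- correction
  out
}

#' Per-locus ancestry heterozygosity summaries
#'
#' Mirror of [summarize_individuals()] with the roles of rows and columns
#' swapped: each diagnostic marker is summarized over the recombinant
#' individuals genotyped at it, using the locus's own ancestry frequency
#' \eqn{p_B} for the expected heterozygosity.
#'
#' @inheritParams summarize_individuals
#' @return A tibble with one row per marker: `marker_id`, `chromosome`,
#'   `n_individuals`, `ancestry_freq`, `observed_het`, `expected_het`,
#'   `excess_het`, `response`.
#' @export
summarize_loci <- function(matrix, statistic = c("excess", "observed"),
                           correction = c("none", "small_sample")) {
  statistic <- match.arg(statistic)
  correction <- match.arg(correction)
  if (!inherits(matrix, "ancestry_matrix")) {
    abort_exhet("`matrix` must be an ancestry_matrix.", "bad_matrix")
  }
  rec <- recombinant_rows(matrix)
  if (length(rec) == 0) {
    abort_exhet("No recombinant (F2/F3) individuals to summarize.", "no_recombinants")
  }
  d <- unname(matrix$dosage[rec, , drop = FALSE])
  n_ind <- colSums(!is.na(d))
  if (any(n_ind == 0)) {
    abort_exhet("Marker(s) with zero genotyped recombinants; filter the matrix first.",
                "zero_individuals")
  }
  observed <- colSums(d == 1, na.rm = TRUE) / n_ind
  p_b <- colSums(d, na.rm = TRUE) / (2 * n_ind)
  expected <- 2 * p_b * (1 - p_b)
  if (correction == "small_sample") {
    expected <- expected * (2 * n_ind) / (2 * n_ind - 1)
  }
  out <- dplyr::bind_cols(
    matrix$markers[, c("marker_id", "chromosome")],
    tibble::tibble(
      n_individuals = n_ind,
      ancestry_freq = p_b,
      observed_het = observed,
      expected_het = expected,
      excess_het = observed - expected
    )
  )
  out$response <- if (statistic == "excess") out$excess_het else out$observed_het
  attr(out, "statistic") <- statistic
  attr(out, "correction") <- correction
  out
}

#' Mean excess ancestry heterozygosity per chromosome
#'
#' Unweighted mean of locus-level excess heterozygosity over the markers on
#' each chromosome, with the standard error of that mean (`NA` for
#' single-marker chromosomes). The sex chromosome is absent by construction
#' when the locus summaries derive from a diagnostic panel.
#'
#' @param loci A locus summary tibble from [summarize_loci()].
#' @return A tibble: `chromosome`, `mean_excess_het`, `se`, `n_loci`.
#' @export
chromosome_means <- function(loci) {
  if (nrow(loci) == 0) {
    abort_exhet("Empty locus summary.", "empty_input")
  }
  loci |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(
      mean_excess_het = mean(.data$excess_het),
      se = if (dplyr::n() > 1) sd(.data$excess_het) / sqrt(dplyr::n()) else NA_real_,
      n_loci = dplyr::n(),
      .groups = "drop"
    )
}
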