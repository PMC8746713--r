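#' Apply the reciprocal individual/locus genotyping-success filters
#'
#' Recombinant (F2/F3) individuals genotyped at fewer than `min_loci`
#' diagnostic markers are dropped, then markers genotyped in fewer than
#' `min_individuals` retained recombinants are dropped, and the two rules are
#' iterated to a fixed point so the result does not depend on the order of
#' application. Founder and F1 rows are control material: they are retained
#' unconditionally and never counted toward the locus threshold.
#'
#' @param matrix An `ancestry_matrix` from [polarize_to_ancestry()].
#' @param min_loci Minimum non-missing loci per recombinant (default 20,
#'   "at least 20 loci genotyped").
#' @param min_individuals Minimum non-missing recombinants per marker
#'   (default 20).
#' @return The filtered `ancestry_matrix`, with a `filter_report` attribute
#'   (individuals and markers dropped, iterations to fixed point).
#' @export
apply_matrix_filters <- function(matrix, min_loci = 20, min_individuals = 20) {
  if (!inherits(matrix, "ancestry_matrix")) {
    abort_exhet("`matrix` must be an ancestry_matrix.", "bad_matrix")
  }
  if (nrow(matrix$dosage) == 0 || ncol(matrix$dosage) == 0) {
    abort_exhet("Cannot filter an empty ancestry matrix.", "empty_matrix")
  }
  n_ind0 <- nrow(matrix$dosage)
  n_mark0 <- ncol(matrix$dosage)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    rec <- recombinant_rows(matrix)
    if (length(rec) == 0) {
      abort_exhet(
        sprintf("All recombinant individuals dropped (binding constraint: min_loci = %d).",
                min_loci), "all_individuals_dropped")
    }
    loci_per_ind <- rowSums(!is.na(matrix$dosage[rec, , drop = FALSE]))
    drop_ind <- rec[loci_per_ind < min_loci]
    if (length(drop_ind) > 0) {
      keep <- setdiff(seq_len(nrow(matrix$dosage)), drop_ind)
      matrix <- matrix[keep, ]
    }
    rec <- recombinant_rows(matrix)
    if (length(rec) == 0) {
      abort_exhet(
        sprintf("All recombinant individuals dropped (binding constraint: min_loci = %d).",
                min_loci), "all_individuals_dropped")
    }
    ind_per_marker <- colSums(!is.na(matrix$dosage[rec, , drop = FALSE]))
    drop_mark <- which(ind_per_marker < min_individuals)
    if (length(drop_mark) > 0) {
      if (length(drop_mark) == ncol(matrix$dosage)) {
        abort_exhet(
          sprintf("All markers dropped (binding constraint: min_individuals = %d).",
                  min_individuals), "all_markers_dropped")
      }
      matrix <- matrix[, setdiff(seq_len(ncol(matrix$dosage)), drop_mark)]
    }
    if (length(drop_ind) == 0 && length(drop_mark) == 0) break
  }
  attr(matrix, "filter_report") <- list(
    individuals_dropped = n_ind0 - nrow(matrix$dosage),
    markers_dropped = n_mark0 - ncol(matrix$dosage),
    iterations = iterations,
    min_loci = min_loci,
    min_individuals = min_individuals
  )
  matrix
}
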