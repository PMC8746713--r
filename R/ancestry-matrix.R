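# Containers: the canonical long genotype table and the individuals-by-
# markers ancestry dosage matrix.

genotype_columns <- c("dataset_id", "family_id", "individual_id", "generation",
                      "environment", "marker_id", "chromosome", "allele_1",
                      "allele_2", "coverage", "length_mm")

new_cross_genotypes <- function(x) {
  x <- tibble::as_tibble(x)
  class(x) <- unique(c("cross_genotypes", class(x)))
  x
}

#' Validate a long-format genotype table
#'
#' Checks the structural invariants of the canonical genotype dialect:
#' mandatory columns, known generation and environment labels, allele
#' pairing (`allele_1` is missing iff `allele_2` is missing), and uniqueness
#' of `(individual_id, marker_id)` within each dataset.
#'
#' @param cross A `cross_genotypes` tibble (or any data frame with the
#'   canonical columns).
#' @return The validated table, invisibly classed as `cross_genotypes`.
#' @export
validate_cross_genotypes <- function(cross) {
  missing_cols <- setdiff(genotype_columns, names(cross))
  if (length(missing_cols) > 0) {
    abort_exhet(paste0("Missing mandatory column(s): ",
                       paste(missing_cols, collapse = ", ")), "bad_columns")
  }
  bad_gen <- !cross$generation %in% all_generations
  if (any(bad_gen)) {
    abort_exhet(sprintf(
      "Unknown generation label(s) %s at line(s) %s.",
      paste(unique(cross$generation[bad_gen]), collapse = ", "),
      paste(head(which(bad_gen), 5), collapse = ", ")), "bad_generation")
  }
  bad_env <- !cross$environment %in% c("lab", "pond")
  if (any(bad_env)) {
    abort_exhet(sprintf("Unknown environment label(s) at line(s) %s.",
                        paste(head(which(bad_env), 5), collapse = ", ")),
                "bad_environment")
  }
  half <- xor(is.na(cross$allele_1), is.na(cross$allele_2))
  if (any(half)) {
    abort_exhet(sprintf(
      "allele_1/allele_2 must be missing together; offending line(s): %s.",
      paste(head(which(half), 5), collapse = ", ")), "half_missing_call")
  }
  dup <- duplicated(cross[, c("dataset_id", "individual_id", "marker_id")])
  if (any(dup)) {
    abort_exhet(sprintf(
      "Duplicate (individual_id, marker_id) within a dataset; line(s): %s.",
      paste(head(which(dup), 5), collapse = ", ")), "duplicate_call")
  }
  invisible(new_cross_genotypes(cross))
}

new_ancestry_matrix <- function(dosage, individuals, markers) {
  stopifnot(nrow(dosage) == nrow(individuals), ncol(dosage) == nrow(markers))
  rownames(dosage) <- individuals$individual_id
  colnames(dosage) <- markers$marker_id
  structure(list(dosage = dosage, individuals = individuals, markers = markers),
            class = "ancestry_matrix")
}

#' @export
print.ancestry_matrix <- function(x, ...) {
  n_rec <- sum(x$individuals$generation %in% recombinant_generations)
  cat(sprintf(
    "<ancestry_matrix> %d individuals (%d recombinant) x %d diagnostic markers; %.1f%% missing\n",
    nrow(x$dosage), n_rec, ncol(x$dosage), 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
`[.ancestry_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  new_ancestry_matrix(x$dosage[i, j, drop = FALSE],
                      x$individuals[i, , drop = FALSE],
                      x$markers[j, , drop = FALSE])
}

#' @export
dim.ancestry_matrix <- function(x) dim(x$dosage)

recombinant_rows <- function(matrix) {
  which(matrix$individuals$generation %in% recombinant_generations)
}
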