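#' Inject conservative genotyping error into recombinant calls
#'
#' Implements the worst-case error model for heterozygosity inference: every
#' error converts a true homozygote into a called heterozygote. Each
#' non-missing homozygous F2/F3 call is independently replaced, with
#' probability `e`, by a cross-side heterozygous call (one original allele
#' retained plus one random opposite-side founder allele). Heterozygous
#' calls, missing calls, and all F0/F1 calls are untouched, so errors can
#' only inflate observed ancestry heterozygosity.
#'
#' @param cross A `cross_genotypes` table containing founder rows (needed to
#'   resolve which side each allele belongs to).
#' @param e Error probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The perturbed `cross_genotypes` table.
#' @export
inject_genotyping_error <- function(cross, e, seed = 1) {
  if (!is_prob(e)) {
    abort_exhet("`e` must be a probability in [0, 1].", "bad_error_rate")
  }
  cross <- validate_cross_genotypes(cross)
  if (e == 0) return(cross)

  f0a <- dplyr::filter(cross, .data$generation == "F0A", !is.na(.data$allele_1))
  f0b <- dplyr::filter(cross, .data$generation == "F0B", !is.na(.data$allele_1))
  a_tokens <- tapply(c(f0a$allele_1, f0a$allele_2),
                     paste(rep(f0a$dataset_id, 2), rep(f0a$marker_id, 2)),
                     unique, simplify = FALSE)
  b_tokens <- tapply(c(f0b$allele_1, f0b$allele_2),
                     paste(rep(f0b$dataset_id, 2), rep(f0b$marker_id, 2)),
                     unique, simplify = FALSE)

  key <- paste(cross$dataset_id, cross$marker_id)
  hom <- !is.na(cross$allele_1) & cross$allele_1 == cross$allele_2 &
    cross$generation %in% recombinant_generations
  with_seed(seed, {
    flip <- hom & runif(nrow(cross)) < e
    idx <- which(flip)
    for (i in idx) {
      a_set <- a_tokens[[key[i]]]
      b_set <- b_tokens[[key[i]]]
      if (is.null(a_set) || is.null(b_set)) next
      if (cross$allele_1[i] %in% a_set) {
        cross$allele_2[i] <- b_set[sample.int(length(b_set), 1)]
      } else if (cross$allele_1[i] %in% b_set) {
        cross$allele_1[i] <- a_set[sample.int(length(a_set), 1)]
      }
    }
  })
  cross
}

#' Apply viability selection to a cohort of recombinant hybrids
#'
#' Each recombinant survives with probability proportional to its fitness
#' under the chosen genetic architecture (see [selection_spec()] for the
#' fitness definitions), scaled so the fittest cohort member survives with
#' probability one; founders and F1s always survive. The proportionality
#' constant affects only how many fish survive, never the genotype
#' composition of the survivors, which is what every downstream statistic
#' measures. Selection changes cohort
#' membership only -- survivor genotypes are bit-identical to their input
#' rows -- so elevated heterozygosity among survivors is purely a sampling
#' effect of differential viability, as in a pond cohort sampled after
#' mortality.
#'
#' @param matrix An `ancestry_matrix`.
#' @param spec A [selection_spec()].
#' @param seed Integer seed.
#' @return The `ancestry_matrix` restricted to survivors. With `s = 0` the
#'   input is returned unchanged.
#' @export
apply_viability_selection <- function(matrix, spec, seed = 1) {
  if (!inherits(matrix, "ancestry_matrix")) {
    abort_exhet("`matrix` must be an ancestry_matrix.", "bad_matrix")
  }
  if (!inherits(spec, "selection_spec")) {
    abort_exhet("`spec` must be a selection_spec().", "bad_selection")
  }
  if (nrow(matrix$dosage) == 0) {
    abort_exhet("Cannot select on an empty matrix.", "empty_matrix")
  }
  if (spec$s == 0) return(matrix)
  rec <- recombinant_rows(matrix)
  w <- fitness_from_dosage(matrix$dosage[rec, , drop = FALSE], spec,
                           fgm_seed = mix_seed(seed, 777L))
  survived <- with_seed(seed, runif(length(rec)) < w / max(w))
  if (all(survived)) return(matrix)
  keep <- sort(c(setdiff(seq_len(nrow(matrix$dosage)), rec), rec[survived]))
  matrix[keep, ]
}
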