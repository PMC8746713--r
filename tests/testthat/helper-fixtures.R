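# Shared fixtures: small bundle configs and a hand-built toy cross.

small_config <- function(..., seed = 1) {
  sim_bundle_config(
    n_datasets_lab = 2, n_datasets_pond = 2, f2_per_family = 80,
    n_chromosomes = 5, markers_per_chromosome = 7, sex_chromosome = "5",
    seed = seed, ...
  )
}

# Hand-built 5-marker cross: founders share an allele at marker m3, one F1 is
# homozygous at m5, and m4 sits on the sex chromosome in some tests.
toy_cross <- function(sex_marker_chrom = c(m1 = "1", m2 = "1", m3 = "2",
                                           m4 = "2", m5 = "3")) {
  markers <- names(sex_marker_chrom)
  geno <- function(individual, generation, alleles) {
    tibble::tibble(
      dataset_id = "toy", family_id = "fam1", individual_id = individual,
      generation = generation, environment = "lab",
      marker_id = markers, chromosome = unname(sex_marker_chrom),
      allele_1 = vapply(alleles, `[`, "", 1),
      allele_2 = vapply(alleles, `[`, "", 2),
      coverage = NA_integer_, length_mm = NA_real_
    )
  }
  dplyr::bind_rows(
    geno("p_a", "F0A", list(c("A", "A"), c("A", "A"), c("A", "A"),
                            c("A", "A"), c("A", "A"))),
    geno("p_b", "F0B", list(c("G", "G"), c("G", "G"), c("A", "G"),
                            c("G", "G"), c("G", "G"))),
    geno("f1_1", "F1", list(c("A", "G"), c("A", "G"), c("A", "G"),
                            c("A", "G"), c("A", "G"))),
    geno("f1_2", "F1", list(c("A", "G"), c("A", "G"), c("A", "G"),
                            c("A", "G"), c("A", "A"))),
    geno("f2_1", "F2", list(c("A", "G"), c("A", "A"), c("A", "G"),
                            c("G", "G"), c("A", "G"))),
    geno("f2_2", "F2", list(c("G", "G"), c("A", "G"), c("A", "A"),
                            c("A", "G"), c("A", "A")))
  )
}

# ancestry matrix built directly from a dosage matrix (recombinants only)
matrix_from_dosage <- function(d, environment = "pond", dataset_id = "ds1",
                               generation = "F2") {
  n <- nrow(d)
  individuals <- tibble::tibble(
    individual_id = sprintf("ind_%04d", seq_len(n)),
    dataset_id = dataset_id, family_id = "fam1",
    generation = generation, environment = environment,
    length_mm = NA_real_
  )
  markers <- tibble::tibble(
    marker_id = sprintf("m_%03d", seq_len(ncol(d))),
    chromosome = as.character(rep_len(seq_len(max(1, ncol(d) %/% 5)), ncol(d)))
  )
  exhet:::new_ancestry_matrix(d, individuals, markers)
}
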