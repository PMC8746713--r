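# Synthetic pedigreed cross generator.
#
# Each dataset carries its own marker panel: side-A and side-B founder
# lineages have disjoint allele sets at every candidate marker (fixed
# differences), so ancestry is polarizable by construction. F2 dosages are
# drawn i.i.d. 1:2:1 per marker (unlinked loci; the heterozygosity statistic
# and its null expectation do not depend on linkage). F3s are formed by
# random union of one recombination-free gamete per marker from two randomly
# chosen surviving F2 parents.

microsat_token_pool <- as.character(seq(100, 198, by = 2))

# Dataset-level marker panel: ids, chromosomes, and per-side allele sets
# (two tokens per side for microsatellites, one nucleotide per side for
# SNP-array/GBS panels). Seeded by (seed, dataset_index) only, so all
# families within a dataset share the panel, like population-level fixed
# differences.
sim_dataset_markers <- function(config, dataset_index) {
  platform <- config$platform[dataset_index]
  L <- config$n_chromosomes * config$markers_per_chromosome
  chrom <- rep(config$chromosomes, each = config$markers_per_chromosome)
  marker_id <- sprintf("ds%02d_c%s_m%02d", dataset_index,
                       formatC(chrom, width = 2, flag = "0"),
                       rep(seq_len(config$markers_per_chromosome),
                           times = config$n_chromosomes))
  with_seed(mix_seed(config$seed, dataset_index, 0L), {
    if (platform == "microsatellite") {
      tok <- t(vapply(seq_len(L), function(i) sample(microsat_token_pool, 4L),
                      character(4)))
      side_a <- tok[, 1:2, drop = FALSE]
      side_b <- tok[, 3:4, drop = FALSE]
    } else {
      nt <- t(vapply(seq_len(L), function(i) sample(c("A", "C", "G", "T"), 2L),
                     character(2)))
      side_a <- nt[, c(1, 1), drop = FALSE]
      side_b <- nt[, c(2, 2), drop = FALSE]
    }
    list(marker_id = marker_id, chromosome = chrom,
         side_a = side_a, side_b = side_b, platform = platform)
  })
}

# Viability fitness of recombinants from their ancestry-dosage matrix.
# Missing dosages are treated as heterozygous (neutral midpoint) so that
# fitness is defined for every individual.
fitness_from_dosage <- function(dosage, spec, fgm_seed = 1L) {
  L <- ncol(dosage)
  s <- spec$s
  switch(spec$architecture,
    heterozygote_advantage = {
      k <- spec$k_loci %||% L
      if (k > L) {
        abort_exhet(sprintf(
          "Architecture needs %d loci but only %d are available.", k, L),
          "selection_insufficient_loci")
      }
      n_hom <- rowSums(dosage[, seq_len(k), drop = FALSE] != 1, na.rm = TRUE)
      (1 - s)^n_hom
    },
    pairwise_dmi = {
      kp <- spec$k_pairs %||% (L %/% 2L)
      if (2L * kp > L) {
        abort_exhet(sprintf(
          "Architecture needs %d loci (for %d pairs) but only %d are available.",
          2L * kp, kp, L), "selection_insufficient_loci")
      }
      i1 <- seq(1L, by = 2L, length.out = kp)
      d1 <- dosage[, i1, drop = FALSE]
      d2 <- dosage[, i1 + 1L, drop = FALSE]
      opp <- (d1 == 0 & d2 == 2) | (d1 == 2 & d2 == 0)
      n_pair <- rowSums(opp, na.rm = TRUE)
      (1 - s)^n_pair
    },
    fgm_mismatch = {
      effects <- with_seed(fgm_seed, matrix(rnorm(L * 2, 0, 0.15), L, 2))
      d <- dosage
      d[is.na(d)] <- 1
      pheno <- (d / 2) %*% effects
      axis <- colSums(effects)  # derived-parent phenotype minus ancestor (0,0)
      axis_len2 <- sum(axis^2)
      if (axis_len2 == 0) {
        abort_exhet("Degenerate effect axis: parents share a phenotype.",
                    "selection_degenerate_axis")
      }
      proj <- as.vector(pheno %*% axis) / sqrt(axis_len2)
      d_perp2 <- pmax(0, rowSums(pheno^2) - proj^2)
      exp(-s * spec$sigma_scale * d_perp2)
    },
    abort_exhet("Unknown selection architecture.", "bad_selection")
  )
}

# realize allele pairs from ancestry dosages, drawing tokens from the
# founder genotypes (each side may be heterozygous for two same-side tokens)
alleles_from_dosage <- function(dosage_vec, marker_idx, f0a_geno, f0b_geno) {
  n <- length(dosage_vec)
  pick_a1 <- f0a_geno[cbind(marker_idx, sample(1:2, n, TRUE))]
  pick_a2 <- f0a_geno[cbind(marker_idx, sample(1:2, n, TRUE))]
  pick_b1 <- f0b_geno[cbind(marker_idx, sample(1:2, n, TRUE))]
  pick_b2 <- f0b_geno[cbind(marker_idx, sample(1:2, n, TRUE))]
  allele_1 <- ifelse(dosage_vec == 2, pick_b1, pick_a1)
  allele_2 <- ifelse(dosage_vec == 0, pick_a2, pick_b2)
  list(allele_1 = allele_1, allele_2 = allele_2)
}

#' Simulate one pedigreed intercross family
#'
#' Generates founder (F0A, F0B), F1, and recombinant (F2 and optionally F3)
#' genotype records for a single family of a configured dataset. Founders
#' carry disjoint allele sets at every marker, F1s carry one allele from each
#' side, and each F2 ancestry dosage is drawn independently per marker with
#' probabilities 0.25/0.5/0.25 (the 1:2:1 intercross expectation, which holds
#' regardless of how eggs and sperm were united). Viability selection (when
#' the dataset's environment is targeted by `config$selection`) removes F2
#' individuals before F3s are bred and before missingness and genotyping
#' error are layered on. Deterministic for fixed `(seed, indices)`.
#'
#' @param config A [sim_bundle_config()].
#' @param dataset_index Dataset index within the bundle (lab datasets first).
#' @param family_index Family index within the dataset.
#' @return A `cross_genotypes` tibble in the canonical long format (see
#'   [read_genotype_tsv()] for the column dialect).
#' @export
generate_f2_family <- function(config, dataset_index, family_index = 1) {
  if (!inherits(config, "sim_bundle_config")) {
    abort_exhet("`config` must be a sim_bundle_config().", "bad_config")
  }
  n_datasets <- config$n_datasets_lab + config$n_datasets_pond
  if (!is_count(dataset_index) || dataset_index > n_datasets) {
    abort_exhet("`dataset_index` is out of range for this config.", "bad_config")
  }
  if (!is_count(family_index) || family_index > config$families_per_dataset) {
    abort_exhet("`family_index` is out of range for this config.", "bad_config")
  }
  info <- dataset_info(config)[dataset_index, ]
  panel <- sim_dataset_markers(config, dataset_index)
  L <- length(panel$marker_id)
  if (L == 0) abort_exhet("Configuration yields zero markers.", "no_markers")
  gbs <- panel$platform == "gbs"

  selected_here <- !is.null(config$selection) && config$selection$s > 0 &&
    config$selection$target_environment %in% c(info$environment, "both")

  subseed <- mix_seed(config$seed, dataset_index, family_index)
  with_seed(subseed, {
    f0a_geno <- matrix(panel$side_a[cbind(rep(seq_len(L), 2),
                                          sample(1:2, 2L * L, TRUE))], L, 2)
    f0b_geno <- matrix(panel$side_b[cbind(rep(seq_len(L), 2),
                                          sample(1:2, 2L * L, TRUE))], L, 2)

    n_f1 <- config$f1_per_family
    f1_a1 <- matrix(f0a_geno[cbind(rep(seq_len(L), n_f1),
                                   sample(1:2, L * n_f1, TRUE))], L, n_f1)
    f1_a2 <- matrix(f0b_geno[cbind(rep(seq_len(L), n_f1),
                                   sample(1:2, L * n_f1, TRUE))], L, n_f1)

    n_f2 <- config$f2_per_family
    if (!selected_here) {
      dosage_f2 <- matrix(sample(0:2, n_f2 * L, TRUE, prob = c(0.25, 0.5, 0.25)),
                          n_f2, L)
    } else {
      # cohorts under viability selection are sampled post-mortality, as a
      # field study genotypes the fish it recaptures: simulate birth batches,
      # keep survivors, until the configured sample size is reached
      fgm_seed <- mix_seed(config$seed, dataset_index, 7777L)
      survivors <- vector("list", 0L)
      n_kept <- 0L
      n_births <- 0L
      batch <- max(2L * n_f2, 200L)
      max_births <- 2e6
      repeat {
        births <- matrix(sample(0:2, batch * L, TRUE, prob = c(0.25, 0.5, 0.25)),
                         batch, L)
        w <- fitness_from_dosage(births, config$selection, fgm_seed = fgm_seed)
        keep <- runif(batch) < w / max(w)
        n_births <- n_births + batch
        if (any(keep)) {
          survivors[[length(survivors) + 1L]] <- births[keep, , drop = FALSE]
          n_kept <- n_kept + sum(keep)
        }
        if (n_kept >= n_f2 || n_births >= max_births) break
        # scale the next batch to the observed survival rate
        rate <- max(n_kept / n_births, 1 / n_births)
        batch <- as.integer(min(ceiling(1.5 * (n_f2 - n_kept) / rate),
                                max_births - n_births))
      }
      if (n_kept < n_f2) {
        abort_exhet(
          "Viability selection is too strong to sample the configured cohort; lower `s`.",
          "selection_extinction")
      }
      dosage_f2 <- do.call(rbind, survivors)[seq_len(n_f2), , drop = FALSE]
    }

    gens <- list()
    if ("F2" %in% config$generations) gens$F2 <- dosage_f2
    if ("F3" %in% config$generations) {
      if (n_f2 < 2) {
        abort_exhet("F3 breeding needs at least two surviving F2 parents.",
                    "too_few_parents")
      }
      n_f3 <- config$f2_per_family
      p1 <- sample(n_f2, n_f3, TRUE)
      p2 <- sample(n_f2, n_f3, TRUE)
      g1 <- matrix(rbinom(n_f3 * L, 1, dosage_f2[p1, , drop = FALSE] / 2), n_f3, L)
      g2 <- matrix(rbinom(n_f3 * L, 1, dosage_f2[p2, , drop = FALSE] / 2), n_f3, L)
      gens$F3 <- g1 + g2
    }

    fam <- sprintf("ds%02d_fam%02d", dataset_index, family_index)
    rec <- list()

    add_rows <- function(ids, generation, a1, a2, length_mm) {
      tibble::tibble(
        dataset_id = info$dataset_id,
        family_id = fam,
        individual_id = rep(ids, each = L),
        generation = generation,
        environment = info$environment,
        marker_id = rep(panel$marker_id, length(ids)),
        chromosome = rep(panel$chromosome, length(ids)),
        allele_1 = a1,
        allele_2 = a2,
        coverage = NA_integer_,
        length_mm = rep(rep_len(length_mm, length(ids)), each = L)
      )
    }

    rec$f0a <- add_rows(paste0(fam, "_F0A"), "F0A", f0a_geno[, 1], f0a_geno[, 2],
                        NA_real_)
    rec$f0b <- add_rows(paste0(fam, "_F0B"), "F0B", f0b_geno[, 1], f0b_geno[, 2],
                        NA_real_)
    rec$f1 <- add_rows(sprintf("%s_F1_%02d", fam, seq_len(n_f1)), "F1",
                       as.vector(f1_a1), as.vector(f1_a2), NA_real_)

    for (g in names(gens)) {
      dd <- gens[[g]]
      n <- nrow(dd)
      ids <- sprintf("%s_%s_%04d", fam, g, seq_len(n))
      dv <- as.vector(t(dd))  # individual-major to match rep(ids, each = L)
      al <- alleles_from_dosage(dv, rep(seq_len(L), n), f0a_geno, f0b_geno)
      lengths <- rnorm(n, 45, 5)
      rows <- add_rows(ids, g, al$allele_1, al$allele_2, lengths)
      if (config$missing_rate > 0) {
        drop <- runif(nrow(rows)) < config$missing_rate
        rows$allele_1[drop] <- NA_character_
        rows$allele_2[drop] <- NA_character_
      }
      if (config$error_rate > 0) {
        rows <- flip_homozygotes(rows, config$error_rate, f0a_geno, f0b_geno,
                                 panel$marker_id)
      }
      rec[[g]] <- rows
    }

    out <- dplyr::bind_rows(rec)
    if (gbs) {
      out$coverage <- as.integer(rnbinom(nrow(out), mu = config$coverage_mean,
                                         size = config$coverage_dispersion))
    }
    new_cross_genotypes(out)
  })
}

# conservative error model: a true homozygote is mis-called heterozygous
# (one existing allele retained, one random opposite-side allele added);
# heterozygous, missing, F0 and F1 calls are never touched. Assumes the
# current RNG stream.
flip_homozygotes <- function(rows, e, f0a_geno, f0b_geno, marker_ids) {
  mi <- match(rows$marker_id, marker_ids)
  hom <- !is.na(rows$allele_1) & rows$allele_1 == rows$allele_2 &
    rows$generation %in% recombinant_generations
  flip <- hom & runif(nrow(rows)) < e
  if (!any(flip)) return(rows)
  idx <- which(flip)
  on_a <- rows$allele_1[idx] == f0a_geno[mi[idx], 1] |
    rows$allele_1[idx] == f0a_geno[mi[idx], 2]
  opp <- ifelse(on_a,
                f0b_geno[cbind(mi[idx], sample(1:2, length(idx), TRUE))],
                f0a_geno[cbind(mi[idx], sample(1:2, length(idx), TRUE))])
  rows$allele_2[idx] <- ifelse(on_a, opp, rows$allele_2[idx])
  rows$allele_1[idx] <- ifelse(on_a, rows$allele_1[idx], opp)
  rows
}

#' Simulate a full multi-dataset study bundle
#'
#' Generates every configured dataset (lab datasets first, then pond), applies
#' any configured viability selection to cohorts in the targeted environment,
#' and assembles a manifest of dataset-level metadata. Reproducible: the same
#' config (including its seed) always yields an identical bundle.
#'
#' @param config A [sim_bundle_config()].
#' @return A `study_bundle`: list with `genotypes` (pooled `cross_genotypes`
#'   tibble), `manifest` (one row per dataset: dataset_id, environment,
#'   cross_type, lake, platform, n_fish, n_markers), and `config`.
#' @export
generate_study_bundle <- function(config) {
  if (!inherits(config, "sim_bundle_config")) {
    abort_exhet("`config` must be a sim_bundle_config().", "bad_config")
  }
  info <- dataset_info(config)
  if (anyDuplicated(info$dataset_id)) {
    abort_exhet("Duplicate dataset ids in configuration.", "duplicate_dataset")
  }
  parts <- vector("list", nrow(info) * config$families_per_dataset)
  k <- 0
  for (di in info$dataset_index) {
    for (fi in seq_len(config$families_per_dataset)) {
      k <- k + 1
      parts[[k]] <- generate_f2_family(config, di, fi)
    }
  }
  genotypes <- new_cross_genotypes(dplyr::bind_rows(parts))
  counts <- genotypes |>
    dplyr::filter(.data$generation %in% recombinant_generations) |>
    dplyr::group_by(.data$dataset_id) |>
    dplyr::summarise(n_fish = dplyr::n_distinct(.data$individual_id),
                     n_markers = dplyr::n_distinct(.data$marker_id),
                     .groups = "drop")
  manifest <- dplyr::left_join(
    dplyr::select(info, -"dataset_index"), counts, by = "dataset_id")
  structure(list(genotypes = genotypes, manifest = manifest, config = config),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("<study_bundle>\n")
  print(x$manifest)
  invisible(x)
}
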