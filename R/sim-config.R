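#' Configure a synthetic cross-data bundle
#'
#' Describes a collection of pedigreed intercross datasets with the structure
#' of a lab-versus-field hybrid study: each dataset is a benthic x limnetic
#' (`"BxL"`) or marine x freshwater (`"MxF"`) cross raised either in
#' aquaria (`"lab"`) or in experimental ponds (`"pond"`), genotyped on one of
#' three platforms. Diagnostic markers segregate 1:2:1 in F2s; ponds may
#' additionally impose viability selection (see [selection_spec()]).
#'
#' Per-dataset arguments (`cross_type`, `lake`, `platform`) are recycled to
#' `n_datasets_lab + n_datasets_pond` entries, lab datasets first. Defaults
#' give all-microsatellite lab datasets and SNP-array pond datasets, matching
#' the typical platform split of such studies.
#'
#' @param n_datasets_lab,n_datasets_pond Number of lab / pond datasets.
#' @param cross_type Per-dataset cross label, `"BxL"` or `"MxF"`.
#' @param lake Per-dataset lake of origin for BxL crosses (`"Paxton"` or
#'   `"Priest"`); ignored with `NA` for MxF datasets.
#' @param families_per_dataset Number of biparental F2 families per dataset.
#' @param f2_per_family Recombinant individuals simulated per family and
#'   generation.
#' @param f1_per_family Number of F1 hybrids genotyped per family.
#' @param generations Subset of `c("F2", "F3")`. F3s are produced by random
#'   union of gametes from (surviving) simulated F2s.
#' @param n_chromosomes Number of chromosome labels (`"1" ...`).
#' @param sex_chromosome Label of the chromosome treated as the sex
#'   chromosome (excluded from analysis downstream). Default `"19"`, or the
#'   last chromosome when fewer than 19 are simulated.
#' @param markers_per_chromosome Diagnostic marker candidates per chromosome.
#' @param platform Per-dataset genotyping platform: `"microsatellite"`,
#'   `"snp_array"`, or `"gbs"`.
#' @param missing_rate Probability that a recombinant's genotype call is
#'   missing (F0/F1 calls are never masked by this rate).
#' @param coverage_mean,coverage_dispersion Mean and dispersion of the
#'   negative-binomial per-call read depth simulated for GBS datasets.
#' @param error_rate Genotyping error rate applied to recombinant calls via
#'   the conservative homozygote-to-heterozygote model
#'   (see [inject_genotyping_error()]).
#' @param selection Optional [selection_spec()] applied to the configured
#'   target environment, or `NULL` for neutral bundles.
#' @param seed Integer seed; all randomness in the generator derives from it.
#' @return A `sim_bundle_config` object (a validated list).
#' @seealso [generate_study_bundle()], [generate_f2_family()]
#' @export
sim_bundle_config <- function(n_datasets_lab = 2,
                              n_datasets_pond = 2,
                              cross_type = "BxL",
                              lake = c("Paxton", "Priest"),
                              families_per_dataset = 1,
                              f2_per_family = 100,
                              f1_per_family = 2,
                              generations = "F2",
                              n_chromosomes = 20,
                              sex_chromosome = NULL,
                              markers_per_chromosome = 6,
                              platform = NULL,
                              missing_rate = 0,
                              coverage_mean = 60,
                              coverage_dispersion = 5,
                              error_rate = 0,
                              selection = NULL,
                              seed = 1) {
  n_datasets <- n_datasets_lab + n_datasets_pond
  for (nm in c("n_datasets_lab", "n_datasets_pond", "families_per_dataset",
               "f2_per_family", "f1_per_family", "n_chromosomes",
               "markers_per_chromosome")) {
    val <- get(nm)
    if (nm %in% c("n_datasets_lab", "n_datasets_pond")) {
      ok <- length(val) == 1L && is.numeric(val) && val >= 0 && val == floor(val)
    } else {
      ok <- is_count(val)
    }
    if (!ok) abort_exhet(paste0("`", nm, "` must be a positive count."), "bad_config")
  }
  if (n_datasets < 1) {
    abort_exhet("At least one dataset (lab or pond) must be configured.", "bad_config")
  }
  for (nm in c("missing_rate", "error_rate")) {
    if (!is_prob(get(nm))) {
      abort_exhet(paste0("`", nm, "` must be a probability in [0, 1]."), "bad_config")
    }
  }
  if (!is.numeric(coverage_mean) || coverage_mean <= 0 ||
      !is.numeric(coverage_dispersion) || coverage_dispersion <= 0) {
    abort_exhet("Coverage mean and dispersion must be positive.", "bad_config")
  }

  environment_of <- rep(c("lab", "pond"), c(n_datasets_lab, n_datasets_pond))
  cross_type <- rep_len(cross_type, n_datasets)
  if (!all(cross_type %in% c("BxL", "MxF"))) {
    abort_exhet("`cross_type` labels must be \"BxL\" or \"MxF\".", "bad_config")
  }
  lake <- rep_len(lake, n_datasets)
  if (!all(lake[cross_type == "BxL"] %in% c("Paxton", "Priest"))) {
    abort_exhet("`lake` must be \"Paxton\" or \"Priest\" for BxL datasets.", "bad_config")
  }
  lake[cross_type == "MxF"] <- NA_character_
  if (is.null(platform)) {
    platform <- ifelse(environment_of == "lab", "microsatellite", "snp_array")
  }
  platform <- rep_len(platform, n_datasets)
  if (!all(platform %in% c("microsatellite", "snp_array", "gbs"))) {
    abort_exhet(
      "`platform` must be one of \"microsatellite\", \"snp_array\", \"gbs\".",
      "bad_platform"
    )
  }
  generations <- unique(generations)
  if (length(generations) == 0 || !all(generations %in% recombinant_generations)) {
    abort_exhet("`generations` must be a non-empty subset of c(\"F2\", \"F3\").", "bad_config")
  }
  chromosomes <- as.character(seq_len(n_chromosomes))
  sex_chromosome <- sex_chromosome %||% if (n_chromosomes >= 19) "19" else chromosomes[n_chromosomes]
  sex_chromosome <- as.character(sex_chromosome)
  if (sum(chromosomes == sex_chromosome) != 1L) {
    abort_exhet("Exactly one chromosome must carry the sex-chromosome label.", "bad_config")
  }
  if (!is.null(selection) && !inherits(selection, "selection_spec")) {
    abort_exhet("`selection` must be NULL or a selection_spec().", "bad_config")
  }
  if (!is_count(seed + 1)) {
    abort_exhet("`seed` must be a single integer.", "bad_config")
  }

  structure(
    list(
      n_datasets_lab = as.integer(n_datasets_lab),
      n_datasets_pond = as.integer(n_datasets_pond),
      environment_of = environment_of,
      cross_type = cross_type,
      lake = lake,
      families_per_dataset = as.integer(families_per_dataset),
      f2_per_family = as.integer(f2_per_family),
      f1_per_family = as.integer(f1_per_family),
      generations = generations,
      n_chromosomes = as.integer(n_chromosomes),
      chromosomes = chromosomes,
      sex_chromosome = sex_chromosome,
      markers_per_chromosome = as.integer(markers_per_chromosome),
      platform = platform,
      missing_rate = missing_rate,
      coverage_mean = coverage_mean,
      coverage_dispersion = coverage_dispersion,
      error_rate = error_rate,
      selection = selection,
      seed = as.integer(seed)
    ),
    class = "sim_bundle_config"
  )
}

#' @export
print.sim_bundle_config <- function(x, ...) {
  cat("<sim_bundle_config>\n")
  cat(sprintf("  datasets: %d lab + %d pond\n", x$n_datasets_lab, x$n_datasets_pond))
  cat(sprintf("  markers: %d chromosomes x %d (sex chromosome \"%s\" excluded downstream)\n",
              x$n_chromosomes, x$markers_per_chromosome, x$sex_chromosome))
  cat(sprintf("  cohort: %d family(ies) x %d fish, generations %s\n",
              x$families_per_dataset, x$f2_per_family,
              paste(x$generations, collapse = "+")))
  cat(sprintf("  missing %.3f, error %.3f, selection %s, seed %d\n",
              x$missing_rate, x$error_rate,
              if (is.null(x$selection)) "none" else x$selection$architecture,
              x$seed))
  invisible(x)
}

#' Specify a viability-selection regime for simulated pond cohorts
#'
#' Three genetic architectures span the mechanisms that can elevate ancestry
#' heterozygosity among survivors: per-locus heterozygote advantage,
#' pairwise Dobzhansky-Muller incompatibilities, and polygenic selection
#' against phenotypic mismatch under a Fisher-geometric trait model.
#'
#' Fitness of a recombinant with ancestry dosages \eqn{d_1 \ldots d_L}:
#' \describe{
#'   \item{`heterozygote_advantage`}{\eqn{w = (1-s)^{n_{hom}}} where
#'     \eqn{n_{hom}} counts homozygous dosages among the first `k_loci`
#'     designated loci.}
#'   \item{`pairwise_dmi`}{\eqn{w = (1-s)^{n_{pair}}} where \eqn{n_{pair}}
#'     counts designated locus pairs homozygous for opposite ancestries.}
#'   \item{`fgm_mismatch`}{\eqn{w = \exp(-s \cdot \sigma_{scale} \cdot
#'     d_\perp^2)} where \eqn{d_\perp} is the perpendicular phenotypic
#'     distance from the inter-parent axis under an additive
#'     Fisher-geometric effect model over the loci.}
#' }
#'
#' @param architecture One of `"heterozygote_advantage"`, `"pairwise_dmi"`,
#'   `"fgm_mismatch"`.
#' @param s Selection strength, `>= 0` (and `<= 1` for the two
#'   `(1-s)`-exponent architectures).
#' @param k_loci Number of designated loci under selection
#'   (`heterozygote_advantage`); `NULL` means all loci.
#' @param k_pairs Number of designated incompatible locus pairs
#'   (`pairwise_dmi`); `NULL` means `floor(L/2)`.
#' @param sigma_scale Positive scale multiplier for the `fgm_mismatch`
#'   fitness exponent.
#' @param target_environment Environment(s) whose cohorts are subjected to
#'   selection in [generate_study_bundle()]: `"pond"`, `"lab"`, or `"both"`.
#' @return A `selection_spec` object.
#' @export
selection_spec <- function(architecture = c("heterozygote_advantage",
                                            "pairwise_dmi", "fgm_mismatch"),
                           s = 0,
                           k_loci = NULL,
                           k_pairs = NULL,
                           sigma_scale = 1,
                           target_environment = c("pond", "lab", "both")) {
  architecture <- match.arg(architecture)
  target_environment <- match.arg(target_environment)
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s < 0) {
    abort_exhet("`s` must be a single non-negative number.", "bad_selection")
  }
  if (architecture %in% c("heterozygote_advantage", "pairwise_dmi") && s > 1) {
    abort_exhet("`s` must be <= 1 for multiplicative (1 - s) architectures.", "bad_selection")
  }
  if (!is.null(k_loci) && !is_count(k_loci)) {
    abort_exhet("`k_loci` must be a positive count.", "bad_selection")
  }
  if (!is.null(k_pairs) && !is_count(k_pairs)) {
    abort_exhet("`k_pairs` must be a positive count.", "bad_selection")
  }
  if (!is.numeric(sigma_scale) || sigma_scale <= 0) {
    abort_exhet("`sigma_scale` must be positive.", "bad_selection")
  }
  structure(
    list(architecture = architecture, s = s,
         k_loci = if (is.null(k_loci)) NULL else as.integer(k_loci),
         k_pairs = if (is.null(k_pairs)) NULL else as.integer(k_pairs),
         sigma_scale = sigma_scale,
         target_environment = target_environment),
    class = "selection_spec"
  )
}

#' @export
print.selection_spec <- function(x, ...) {
  cat(sprintf("<selection_spec> %s, s = %g, target = %s\n",
              x$architecture, x$s, x$target_environment))
  invisible(x)
}

# Per-dataset metadata implied by a bundle config.
dataset_info <- function(config) {
  n <- config$n_datasets_lab + config$n_datasets_pond
  env <- config$environment_of
  id <- sprintf("%s_%02d", env, stats::ave(seq_len(n), env, FUN = seq_along))
  tibble::tibble(
    dataset_index = seq_len(n),
    dataset_id = id,
    environment = env,
    cross_type = config$cross_type,
    lake = config$lake,
    platform = config$platform
  )
}
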