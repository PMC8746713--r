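#' Configure an end-to-end analysis run
#'
#' A run takes exactly one input source: either paths to genotype TSV files
#' (one per dataset, plus an optional manifest TSV) or a
#' [sim_bundle_config()] to generate data in place. Filter thresholds and
#' analysis toggles mirror the pipeline stages.
#'
#' @param input_paths Character vector of genotype TSV paths, or `NULL`.
#' @param manifest_path Optional manifest TSV path accompanying
#'   `input_paths`.
#' @param simulation A [sim_bundle_config()], or `NULL`.
#' @param out_dir Output directory for result tables and metadata.
#' @param sex_chrom_label,min_coverage,min_loci,min_individuals Filtering
#'   thresholds (see [select_diagnostic_markers()] and
#'   [apply_matrix_filters()]).
#' @param statistic,correction Passed to [summarize_individuals()].
#' @param fit_model,run_correlations,run_bootstrap,run_resampling,run_error_sim,run_selection_sim,run_fgm
#'   Stage toggles.
#' @param seed Integer seed governing all stochastic stages.
#' @param log_level `"info"` or `"quiet"`; logging never alters results.
#' @return A `run_config` object.
#' @export
run_config <- function(input_paths = NULL, manifest_path = NULL,
                       simulation = NULL, out_dir = tempfile("exhet_run_"),
                       sex_chrom_label = "19", min_coverage = 20,
                       min_loci = 20, min_individuals = 20,
                       statistic = "excess", correction = "none",
                       fit_model = TRUE, run_correlations = TRUE,
                       run_bootstrap = FALSE, run_resampling = FALSE,
                       run_error_sim = FALSE, run_selection_sim = FALSE,
                       run_fgm = FALSE, seed = 1, log_level = "info") {
  if (is.null(input_paths) == is.null(simulation)) {
    abort_exhet("Set exactly one of `input_paths` or `simulation`.",
                "bad_run_config")
  }
  for (nm in c("min_coverage", "min_loci", "min_individuals")) {
    if (!is_count(get(nm))) {
      abort_exhet(paste0("`", nm, "` must be a positive integer."),
                  "bad_run_config")
    }
  }
  if (!log_level %in% c("info", "quiet")) {
    abort_exhet("`log_level` must be \"info\" or \"quiet\".", "bad_run_config")
  }
  structure(
    list(input_paths = input_paths, manifest_path = manifest_path,
         simulation = simulation, out_dir = out_dir,
         sex_chrom_label = as.character(sex_chrom_label),
         min_coverage = min_coverage, min_loci = min_loci,
         min_individuals = min_individuals,
         statistic = statistic, correction = correction,
         fit_model = fit_model, run_correlations = run_correlations,
         run_bootstrap = run_bootstrap, run_resampling = run_resampling,
         run_error_sim = run_error_sim, run_selection_sim = run_selection_sim,
         run_fgm = run_fgm, seed = as.integer(seed), log_level = log_level),
    class = "run_config"
  )
}

#' Run the full excess-heterozygosity pipeline
#'
#' Executes the analysis stages in order -- diagnostic-marker selection,
#' ancestry polarization, reciprocal filtering, individual and locus
#' summaries, then the enabled analyses -- and writes tidy TSV result
#' tables, a filter report, a YAML metadata sidecar (seed, configuration
#' hash, stage log), and a human-readable summary to the output directory.
#' Every written table carries the run's configuration hash in a
#' `config_hash` column, so outputs from different configurations cannot be
#' mixed undetected. Identical configurations (including seed) produce
#' byte-identical result tables.
#'
#' @param config A [run_config()].
#' @return A `pipeline_result` list (summaries, locus summaries, filter
#'   report, model, analyses, paths), invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    abort_exhet("`config` must be a run_config().", "bad_run_config")
  }
  t0 <- Sys.time()
  log_msg <- function(...) {
    if (config$log_level == "info") message("[exhet] ", sprintf(...))
  }
  # hash the scientific configuration only: where results are written and
  # how chatty the run is must not change what is computed
  cfg_hash <- rlang::hash(config[setdiff(names(config),
                                         c("out_dir", "log_level"))])
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- "input"
  result <- tryCatch({
    if (!is.null(config$simulation)) {
      log_msg("generating synthetic bundle (seed %d)", config$simulation$seed)
      bundle <- generate_study_bundle(config$simulation)
      genotypes <- bundle$genotypes
      manifest <- bundle$manifest
    } else {
      log_msg("reading %d genotype file(s)", length(config$input_paths))
      genotypes <- new_cross_genotypes(
        dplyr::bind_rows(lapply(config$input_paths, read_genotype_tsv)))
      manifest <- if (!is.null(config$manifest_path)) {
        readr::read_tsv(config$manifest_path, show_col_types = FALSE,
                        progress = FALSE)
      } else {
        NULL
      }
    }

    stage <- "markers"
    datasets <- split(genotypes, genotypes$dataset_id)
    panels <- lapply(datasets, function(cr) {
      select_diagnostic_markers(new_cross_genotypes(cr),
                                config$sex_chrom_label, config$min_coverage)
    })
    filter_report <- dplyr::bind_rows(lapply(names(panels), function(ds) {
      p <- panels[[ds]]
      tibble::tibble(
        dataset_id = ds,
        n_markers = nrow(p),
        n_diagnostic = sum(p$diagnostic),
        f1_validation_rate = attr(p, "f1_validation_rate") %||% NA_real_,
        shared_alleles = sum(p$rejection_reason %in% "shared_alleles"),
        f1_not_heterozygous = sum(p$rejection_reason %in% "f1_not_heterozygous"),
        sex_chromosome = sum(p$rejection_reason %in% "sex_chromosome"),
        no_f0_calls = sum(p$rejection_reason %in% "no_f0_calls")
      )
    }))

    stage <- "polarize+filter"
    mats <- lapply(names(datasets), function(ds) {
      mat <- polarize_to_ancestry(new_cross_genotypes(datasets[[ds]]),
                                  panels[[ds]])
      apply_matrix_filters(mat, config$min_loci, config$min_individuals)
    })
    names(mats) <- names(datasets)

    stage <- "summaries"
    summaries <- dplyr::bind_rows(lapply(mats, function(m) {
      summarize_individuals(m, statistic = config$statistic,
                            correction = config$correction)
    }))
    loci <- dplyr::bind_rows(lapply(mats, function(m) {
      dplyr::mutate(
        summarize_loci(m, statistic = config$statistic,
                       correction = config$correction),
        dataset_id = m$individuals$dataset_id[1], .before = 1)
    }))
    chrom <- chromosome_means(loci)
    log_msg("summarized %d recombinants, %d loci", nrow(summaries), nrow(loci))

    analyses <- list()
    model <- NULL
    if (config$fit_model && dplyr::n_distinct(summaries$environment) > 1) {
      stage <- "model"
      model <- fit_environment_model(summaries, manifest)
      log_msg("environment contrast(s): %s",
              paste(sprintf("%s %+0.4f", model$contrasts$cross_type,
                            model$contrasts$estimate), collapse = ", "))
    }
    if (config$run_correlations) {
      stage <- "correlations"
      analyses$correlations <- lapply(
        stats::setNames(nm = intersect(c("lab", "pond"),
                                       unique(summaries$environment))),
        function(env) {
          tryCatch(hybrid_index_deviation_correlation(summaries, env),
                   exhet_error = function(e) NULL)
        })
    }
    if (config$run_bootstrap &&
        all(c("lab", "pond") %in% summaries$environment)) {
      stage <- "bootstrap"
      analyses$bootstrap <- bootstrap_correlation_difference(
        summaries[summaries$environment == "pond", ],
        summaries[summaries$environment == "lab", ],
        seed = mix_seed(config$seed, 11L))
    }
    if (config$run_resampling) {
      stage <- "resampling"
      analyses$resampling <- single_marker_resampling(
        list(matrices = mats, manifest = manifest),
        seed = mix_seed(config$seed, 12L))
    }
    if (config$run_error_sim) {
      stage <- "error_sim"
      analyses$error_sim <- genotyping_error_threshold(
        seed = mix_seed(config$seed, 13L))
    }
    if (config$run_selection_sim) {
      stage <- "selection_sim"
      analyses$selection_sim <- selection_strength_required(
        "heterozygote_advantage", seed = mix_seed(config$seed, 14L))
    }
    if (config$run_fgm) {
      stage <- "fgm"
      walk <- adaptive_walk(fgm_config(seed = mix_seed(config$seed, 15L)))
      cohort <- make_f2_cohort(walk)
      analyses$fgm <- list(walk = walk, cohort = cohort,
                           relation = cohort_relation(cohort))
    }

    stage <- "write"
    stamp <- function(df) dplyr::mutate(df, config_hash = cfg_hash)
    wr <- function(df, name) {
      readr::write_tsv(stamp(df), file.path(config$out_dir, name), na = "NA",
                       progress = FALSE)
    }
    wr(summaries, "individual_summaries.tsv")
    wr(loci, "locus_summaries.tsv")
    wr(chrom, "chromosome_means.tsv")
    wr(filter_report, "filter_report.tsv")
    if (!is.null(model)) {
      wr(model$contrasts, "model_contrasts.tsv")
      if (!is.null(model$group_means)) wr(model$group_means, "group_means.tsv")
    }
    if (!is.null(manifest)) wr(manifest, "manifest.tsv")

    meta <- list(
      config_hash = cfg_hash,
      seed = config$seed,
      package_version = as.character(utils::packageVersion("exhet")),
      n_individuals = nrow(summaries),
      n_loci = nrow(loci),
      model_method = if (is.null(model)) NA else model$method,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    yaml::write_yaml(meta, file.path(config$out_dir, "metadata.yaml"))

    summary_lines <- c(
      "excess ancestry heterozygosity pipeline",
      sprintf("config hash: %s", cfg_hash),
      sprintf("individuals: %d, loci: %d", nrow(summaries), nrow(loci)),
      if (!is.null(model)) {
        sprintf("pond - lab contrast (%s): %+.4f +/- %.4f (z = %.2f, P = %.3g)",
                model$contrasts$cross_type, model$contrasts$estimate,
                model$contrasts$se, model$contrasts$z, model$contrasts$p_value)
      }
    )
    writeLines(summary_lines, file.path(config$out_dir, "summary.txt"))

    structure(
      list(summaries = summaries, loci = loci, chromosome_means = chrom,
           filter_report = filter_report, model = model, analyses = analyses,
           manifest = manifest, matrices = mats, config_hash = cfg_hash,
           out_dir = config$out_dir),
      class = "pipeline_result"
    )
  }, exhet_error = function(e) {
    abort_exhet(sprintf("Pipeline failed at stage `%s`: %s", stage,
                        conditionMessage(e)), "pipeline_stage", parent = e)
  })
  log_msg("done in %.1fs", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$out_dir, "\n")
  cat(sprintf("  %d individuals, %d loci, %d datasets\n", nrow(x$summaries),
              nrow(x$loci), dplyr::n_distinct(x$summaries$dataset_id)))
  if (!is.null(x$model)) print(x$model)
  invisible(x)
}

#' Violin plot of excess heterozygosity by environment
#'
#' Simple diagnostic export mirroring the structure of the main
#' lab-versus-pond comparison: per-individual excess ancestry
#' heterozygosity by environment, faceted by cross type when available.
#'
#' @param summaries Individual summaries (pooled).
#' @param manifest Optional manifest supplying `cross_type`.
#' @return A ggplot object.
#' @export
plot_environment_contrast <- function(summaries, manifest = NULL) {
  df <- summaries
  if (!is.null(manifest) && !has_col(df, "cross_type")) {
    keep <- intersect(c("dataset_id", "cross_type"), names(manifest))
    df <- dplyr::left_join(df, dplyr::distinct(manifest[, keep]),
                           by = "dataset_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$environment,
                                        y = .data$excess_het,
                                        fill = .data$environment)) +
    ggplot2::geom_violin(alpha = 0.5, colour = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 0.4, alpha = 0.4) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_cl_normal, geom = "pointrange") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "excess ancestry heterozygosity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (has_col(df, "cross_type") && dplyr::n_distinct(df$cross_type) > 1) {
    p <- p + ggplot2::facet_wrap(~cross_type)
  }
  p
}
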