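# Robustness analyses: single-marker resampling, the genotyping-error
# threshold simulation, and the selection-strength-required simulation.

# fast neutral F2 cohort at the dosage level (1:2:1 per locus, unlinked)
neutral_dosage_cohort <- function(n_fish, n_loci) {
  matrix(sample(0:2, n_fish * n_loci, TRUE, prob = c(0.25, 0.5, 0.25)),
         n_fish, n_loci)
}

# individual-level excess ancestry heterozygosity from a complete dosage matrix
excess_from_dosage <- function(d) {
  n_loci <- ncol(d)
  observed <- rowMeans(d == 1)
  h <- rowSums(d) / (2 * n_loci)
  observed - 2 * h * (1 - h)
}

#' Sign stability of the environment contrast under single-marker resampling
#'
#' A methodological robustness check: in each replicate, every dataset is
#' thinned to one randomly chosen diagnostic marker per chromosome
#' (uniformly and independently per dataset, chromosome, and replicate), the
#' individual summaries and the environment contrast are recomputed, and the
#' sign of the resampled main effect is compared with the full-data sign.
#' Individuals are summarized over however many chromosomes remain (the
#' minimum-loci filter is not reapplied at one marker per chromosome), and
#' the fast fixed-effects fit is used for the per-replicate contrast.
#'
#' @param bundle A `study_bundle`, or a list with elements `matrices` (named
#'   list of filtered `ancestry_matrix` objects per dataset) and `manifest`.
#' @param n_reps Number of resampling replicates (default 1000).
#' @param seed Integer seed.
#' @param sex_chrom_label,min_coverage Passed to marker selection when a raw
#'   bundle is supplied.
#' @return A list: `fraction_same_direction`, `se` (binomial), `n_reps`,
#'   `full_estimate`.
#' @export
single_marker_resampling <- function(bundle, n_reps = 1000, seed = 1,
                                     sex_chrom_label = "19", min_coverage = 20) {
  prepared <- prepare_bundle_matrices(bundle, sex_chrom_label, min_coverage,
                                      apply_filters = TRUE)
  mats <- prepared$matrices
  manifest <- prepared$manifest

  summarize_cols <- function(mat, cols) {
    sub <- mat[, cols]
    summarize_individuals(sub)
  }
  full <- dplyr::bind_rows(lapply(mats, summarize_individuals))
  full_fit <- fit_environment_model(full, manifest, method = "lm")
  full_est <- environment_main_effect(full, manifest)

  chrom_groups <- lapply(mats, function(mat) {
    split(seq_len(ncol(mat$dosage)), mat$markers$chromosome)
  })
  same <- logical(n_reps)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      pieces <- lapply(names(mats), function(ds) {
        groups <- chrom_groups[[ds]]
        cols <- vapply(groups, function(ix) {
          if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
        }, integer(1))
        summarize_cols(mats[[ds]], unname(cols))
      })
      est <- environment_main_effect(dplyr::bind_rows(pieces), manifest)
      same[r] <- sign(est) == sign(full_est)
    }
  })
  frac <- mean(same)
  list(fraction_same_direction = frac,
       se = sqrt(frac * (1 - frac) / n_reps),
       n_reps = n_reps,
       full_estimate = full_est,
       full_model = full_fit)
}

# pooled environment main effect (pond - lab) from a fast fixed-effects fit
environment_main_effect <- function(summaries, manifest = NULL) {
  df <- summaries
  if (!is.null(manifest)) {
    keep <- intersect(c("dataset_id", "cross_type"), names(manifest))
    df <- dplyr::left_join(df, dplyr::distinct(manifest[, keep]),
                           by = "dataset_id")
  }
  y <- response_of(df)
  x <- as.numeric(df$environment == "pond")
  if (has_col(df, "cross_type") && dplyr::n_distinct(df$cross_type) > 1) {
    fit <- stats::lm(y ~ x + factor(df$cross_type))
  } else {
    fit <- stats::lm(y ~ x)
  }
  unname(stats::coef(fit)["x"])
}

prepare_bundle_matrices <- function(bundle, sex_chrom_label, min_coverage,
                                    apply_filters = TRUE,
                                    min_loci = 20, min_individuals = 20) {
  if (inherits(bundle, "study_bundle")) {
    manifest <- bundle$manifest
    datasets <- split(bundle$genotypes, bundle$genotypes$dataset_id)
    mats <- lapply(datasets, function(cr) {
      panel <- select_diagnostic_markers(new_cross_genotypes(cr),
                                         sex_chrom_label, min_coverage)
      mat <- polarize_to_ancestry(new_cross_genotypes(cr), panel)
      if (apply_filters) mat <- apply_matrix_filters(mat, min_loci, min_individuals)
      mat
    })
    list(matrices = mats, manifest = manifest)
  } else if (is.list(bundle) && !is.null(bundle$matrices)) {
    list(matrices = bundle$matrices, manifest = bundle$manifest)
  } else {
    abort_exhet("`bundle` must be a study_bundle or a prepared matrix list.",
                "bad_bundle")
  }
}

#' Genotyping-error rate needed to mimic the observed excess heterozygosity
#'
#' Simulates neutral F2 cohorts (1:2:1 unlinked dosages), applies the
#' conservative homozygote-to-heterozygote error model at each rate on a
#' grid, and records the mean individual excess ancestry heterozygosity.
#' The threshold is the smallest grid rate whose mean excess reaches
#' `target_excess`; because roughly half of neutral F2 calls are homozygous
#' and each conversion raises observed heterozygosity by one locus's worth,
#' the mean excess grows like `e / 2` for small `e`, so reproducing a 3%
#' excess requires an error rate well above any plausible genotyping error.
#'
#' @param n_fish,n_loci Cohort dimensions (defaults 500 x 100).
#' @param n_reps Replicate cohorts per grid point (default 20).
#' @param grid Error rates to scan (default 0 to 0.10 by 0.005).
#' @param target_excess Excess-heterozygosity target (default 0.03).
#' @param seed Integer seed.
#' @return A `sim_report` list: `results` (per-rate tibble of mean excess,
#'   Monte Carlo SE, and replicate count), `threshold` (smallest rate
#'   reaching the target, or `NA` if unattained), `bracket` (the grid pair
#'   straddling the target), and the simulation parameters.
#' @export
genotyping_error_threshold <- function(n_fish = 500, n_loci = 100,
                                       n_reps = 20,
                                       grid = seq(0, 0.10, by = 0.005),
                                       target_excess = 0.03, seed = 1) {
  if (any(grid < 0 | grid > 1)) {
    abort_exhet("`grid` rates must lie in [0, 1].", "bad_grid")
  }
  grid <- sort(unique(grid))
  rows <- lapply(seq_along(grid), function(gi) {
    e <- grid[gi]
    rep_means <- vapply(seq_len(n_reps), function(r) {
      with_seed(mix_seed(seed, gi, r), {
        d <- neutral_dosage_cohort(n_fish, n_loci)
        if (e > 0) {
          hom <- d != 1
          flip <- hom & matrix(runif(length(d)) < e, nrow(d))
          d[flip] <- 1L
        }
        mean(excess_from_dosage(d))
      })
    }, numeric(1))
    tibble::tibble(error_rate = e,
                   mean_excess_het = mean(rep_means),
                   mc_se = sd(rep_means) / sqrt(n_reps),
                   n_replicates = n_reps)
  })
  results <- dplyr::bind_rows(rows)
  reached <- which(results$mean_excess_het >= target_excess)
  threshold <- if (length(reached)) results$error_rate[min(reached)] else NA_real_
  bracket <- if (length(reached) && min(reached) > 1) {
    c(results$error_rate[min(reached) - 1], threshold)
  } else {
    c(NA_real_, threshold)
  }
  structure(
    list(results = results, threshold = threshold, bracket = bracket,
         target_excess = target_excess,
         params = list(n_fish = n_fish, n_loci = n_loci, n_reps = n_reps,
                       seed = seed)),
    class = "sim_report"
  )
}

#' @export
print.sim_report <- function(x, ...) {
  cat("<sim_report>\n")
  if (!is.null(x$results)) {
    print(x$results, n = Inf)
    cat(sprintf("  threshold for target %.3f: %s\n", x$target_excess,
                if (is.na(x$threshold)) "not reached" else format(x$threshold)))
  }
  if (!is.null(x$s_star)) {
    cat(sprintf("  %s: s* = %.5f (achieved excess %.4f, target %.3f)\n",
                x$architecture, x$s_star, x$achieved_excess, x$target_excess))
  }
  invisible(x)
}

#' Selection strength required to produce a target excess heterozygosity
#'
#' Finds, by bisection, the selection strength `s` at which viability
#' selection under a given genetic architecture leaves survivors of a
#' neutral F2 cohort with a target mean excess ancestry heterozygosity.
#' Common random numbers (the same base cohorts and survival draws across
#' `s` values) make the survivor mean monotone in `s`, so the bisection is
#' well behaved. Comparing the returned `s_star` across architectures shows
#' that the strength of selection consistent with a given excess varies by
#' orders of magnitude with the assumed architecture.
#'
#' @param architecture Selection architecture (see [selection_spec()]).
#' @param target_excess Target survivor mean excess heterozygosity
#'   (default 0.03).
#' @param n_fish,n_loci Cohort dimensions (defaults 2000 x 100).
#' @param k_loci,k_pairs,sigma_scale Architecture parameters forwarded to
#'   [selection_spec()].
#' @param n_reps Cohort replicates averaged per evaluation (default 3).
#' @param tol Bisection tolerance on the mean excess (default 0.002).
#' @param seed Integer seed.
#' @param s_upper Initial upper bracket for `s` (capped at 1 for the
#'   multiplicative architectures; expanded automatically for
#'   `fgm_mismatch`).
#' @param max_expand Maximum number of upper-bracket doublings.
#' @return A `sim_report` list: `s_star`, `achieved_excess`, `evaluations`
#'   (tibble of every `(s, mean excess)` pair visited), and parameters.
#' @export
selection_strength_required <- function(architecture, target_excess = 0.03,
                                        n_fish = 2000, n_loci = 100,
                                        k_loci = NULL, k_pairs = NULL,
                                        sigma_scale = 1, n_reps = 3,
                                        tol = 0.002, seed = 1, s_upper = NULL,
                                        max_expand = 20) {
  multiplicative <- architecture %in% c("heterozygote_advantage", "pairwise_dmi")
  s_upper <- s_upper %||% if (multiplicative) 1 - 1e-6 else 64
  cohorts <- lapply(seq_len(n_reps), function(r) {
    with_seed(mix_seed(seed, 101L, r), {
      list(d = neutral_dosage_cohort(n_fish, n_loci), u = runif(n_fish))
    })
  })
  eval_s <- function(s) {
    spec <- selection_spec(architecture, s = s, k_loci = k_loci,
                           k_pairs = k_pairs, sigma_scale = sigma_scale)
    vals <- vapply(cohorts, function(co) {
      w <- fitness_from_dosage(co$d, spec, fgm_seed = mix_seed(seed, 777L))
      keep <- co$u < w / max(w)
      if (!any(keep)) return(NA_real_)
      mean(excess_from_dosage(co$d[keep, , drop = FALSE]))
    }, numeric(1))
    if (all(is.na(vals))) {
      # total extinction: only maximally heterozygous genotypes could survive,
      # so the survivor excess limit lies above any attainable target
      return(Inf)
    }
    mean(vals, na.rm = TRUE)
  }
  evals <- list()
  record <- function(s, value) {
    evals[[length(evals) + 1]] <<- tibble::tibble(s = s, mean_excess_het = value)
  }
  lo <- 0
  f_lo <- eval_s(lo)
  record(lo, f_lo)
  if (f_lo >= target_excess) {
    abort_exhet("Target excess is already met without selection.", "target_trivial")
  }
  hi <- s_upper
  f_hi <- eval_s(hi)
  record(hi, f_hi)
  expansions <- 0
  while (f_hi < target_excess && !multiplicative && expansions < max_expand) {
    hi <- hi * 2
    f_hi <- eval_s(hi)
    record(hi, f_hi)
    expansions <- expansions + 1
  }
  if (f_hi < target_excess) {
    abort_exhet(sprintf(
      "Target excess %.3f unattainable under `%s` with %d loci (max reached %.4f).",
      target_excess, architecture, n_loci, f_hi), "target_unattainable")
  }
  f_mid <- NA_real_
  mid <- hi
  for (iter in seq_len(60)) {
    mid <- (lo + hi) / 2
    f_mid <- eval_s(mid)
    record(mid, f_mid)
    if (abs(f_mid - target_excess) <= tol || (hi - lo) < 1e-6 * max(1, hi)) break
    if (f_mid < target_excess) lo <- mid else hi <- mid
  }
  structure(
    list(s_star = mid, achieved_excess = f_mid,
         evaluations = dplyr::bind_rows(evals),
         target_excess = target_excess, architecture = architecture,
         params = list(n_fish = n_fish, n_loci = n_loci, n_reps = n_reps,
                       k_loci = k_loci, k_pairs = k_pairs,
                       sigma_scale = sigma_scale, seed = seed, tol = tol)),
    class = "sim_report"
  )
}
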