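# Secondary analyses: heterosis-vs-incompatibility correlation, group-mean
# comparisons, and the body-size regression.

spearman_hybrid_dev <- function(h, y) {
  x <- abs(h - 0.5)
  if (sd(x) == 0 || sd(y) == 0) {
    abort_exhet("Constant input vector; rank correlation undefined.",
                "constant_input")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Correlation between hybrid-index deviation and excess heterozygosity
#'
#' Heterosis (within-locus heterozygote advantage) predicts no relationship
#' between genome-wide ancestry proportion and excess heterozygosity,
#' whereas between-locus incompatibilities predict that the benefit of
#' heterozygosity declines as the hybrid index deviates from 0.5. This
#' computes the Spearman rank correlation between `|h - 0.5|` and the
#' summary response (excess heterozygosity by default), pooling across cross
#' types, with ties handled by average ranks and `P` from the large-sample
#' approximation.
#'
#' @param summaries Individual summaries (pooled across datasets).
#' @param group Optional environment label (`"lab"` or `"pond"`) to restrict
#'   to before correlating.
#' @return A list: `rho`, `p_value`, `n`.
#' @export
hybrid_index_deviation_correlation <- function(summaries, group = NULL) {
  df <- summaries
  if (!is.null(group)) df <- df[df$environment == group, ]
  if (nrow(df) < 3) {
    abort_exhet("Need at least 3 individuals in the group.", "too_few")
  }
  y <- response_of(df)
  spearman_hybrid_dev(df$hybrid_index, y)
}

#' Bootstrap test for a difference between two rank correlations
#'
#' Resamples individuals with replacement within each group, recomputes the
#' hybrid-index-deviation correlation of [hybrid_index_deviation_correlation()]
#' in both, and summarizes the distribution of
#' `delta_rho = rho_A - rho_B` with a percentile confidence interval and a
#' two-sided `P` using the `(k + 1) / (B + 1)` continuity convention (so `P`
#' is never exactly zero). Replicates in which a resampled vector is
#' constant are skipped and counted.
#'
#' @param group_a,group_b Individual-summary tibbles for the two groups.
#' @param n_boot Number of bootstrap replicates (a warning is raised below
#'   100).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param conf Confidence level for the percentile interval (default 0.95).
#' @return A list: `delta_rho` (point estimate), `ci` (percentile bounds),
#'   `p_value`, `n_boot_used`, `n_skipped`.
#' @export
bootstrap_correlation_difference <- function(group_a, group_b, n_boot = 1000,
                                             seed = 1, conf = 0.95) {
  if (nrow(group_a) < 3 || nrow(group_b) < 3) {
    abort_exhet("Both groups need at least 3 individuals.", "too_few")
  }
  if (n_boot < 100) {
    warn_exhet("Fewer than 100 bootstrap replicates; estimates will be crude.",
               "few_replicates")
  }
  rho_of <- function(df) spearman_hybrid_dev(df$hybrid_index, response_of(df))$rho
  point <- rho_of(group_a) - rho_of(group_b)
  deltas <- rep(NA_real_, n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      ra <- group_a[sample.int(nrow(group_a), replace = TRUE), ]
      rb <- group_b[sample.int(nrow(group_b), replace = TRUE), ]
      da <- tryCatch(rho_of(ra), exhet_constant_input = function(e) NA_real_)
      db <- tryCatch(rho_of(rb), exhet_constant_input = function(e) NA_real_)
      deltas[b] <- da - db
    }
  })
  used <- deltas[!is.na(deltas)]
  k_low <- sum(used <= 0)
  k_high <- sum(used >= 0)
  bb <- length(used)
  p <- min(1, 2 * min((k_low + 1) / (bb + 1), (k_high + 1) / (bb + 1)))
  alpha <- 1 - conf
  ci <- unname(stats::quantile(used, c(alpha / 2, 1 - alpha / 2)))
  list(delta_rho = point, ci = ci, p_value = p,
       n_boot_used = bb, n_skipped = n_boot - bb)
}

#' One-way comparison of mean excess heterozygosity between groups
#'
#' Fixed-effects one-way comparison (ANOVA F test) of the summary response
#' across the levels of a grouping column. Covers the inbred-versus-outbred,
#' F2-versus-F3, among-study homogeneity, and a-priori phenotype-group
#' analyses, depending on which column is passed. For two-level groupings
#' the signed difference (second level minus first) and its standard error
#' are also reported.
#'
#' @param summaries Individual summaries.
#' @param grouping Name of the grouping column (e.g. `"generation"`,
#'   `"dataset_id"`, or a user-added label column).
#' @return A list: `difference`, `difference_se` (two-level groupings, else
#'   `NA`), `f_statistic`, `df`, `p_value`, `group_means`.
#' @export
compare_group_means <- function(summaries, grouping) {
  if (!grouping %in% names(summaries)) {
    abort_exhet(sprintf("Grouping column `%s` not found.", grouping),
                "bad_grouping")
  }
  g <- factor(summaries[[grouping]])
  if (nlevels(g) < 2) {
    abort_exhet("Grouping must have at least 2 levels.", "single_level")
  }
  counts <- table(g)
  if (any(counts < 2)) {
    abort_exhet(sprintf("Group level(s) with fewer than 2 individuals: %s.",
                        paste(names(counts)[counts < 2], collapse = ", ")),
                "tiny_group")
  }
  y <- response_of(summaries)
  fit <- stats::lm(y ~ g)
  an <- stats::anova(fit)
  diff_est <- diff_se <- NA_real_
  if (nlevels(g) == 2) {
    diff_est <- unname(stats::coef(fit)[2])
    diff_se <- sqrt(diag(stats::vcov(fit)))[2]
  }
  list(
    difference = diff_est,
    difference_se = unname(diff_se),
    f_statistic = an$`F value`[1],
    df = c(an$Df[1], an$Df[2]),
    p_value = an$`Pr(>F)`[1],
    group_means = tapply(y, g, mean)
  )
}

#' Within-family regression of body size on ancestry heterozygosity
#'
#' Tests for hybrid vigor expressed as growth: standard length is
#' standardized to zero mean and unit variance within each family (removing
#' family-level environmental and parental effects), then regressed on
#' observed ancestry heterozygosity by least squares. Families with fewer
#' than 3 measured fish or zero length variance are excluded with a warning.
#'
#' @param summaries Individual summaries carrying `length_mm` and
#'   `family_id`.
#' @return A list: `slope`, `slope_se`, `f_statistic`, `p_value`,
#'   `r_squared`, `n`, `n_families_used`.
#' @export
within_family_size_regression <- function(summaries) {
  df <- summaries[!is.na(summaries$length_mm), ]
  if (nrow(df) == 0) {
    abort_exhet("No individuals with measured length.", "no_lengths")
  }
  stats_by_fam <- df |>
    dplyr::group_by(.data$family_id) |>
    dplyr::mutate(fam_n = dplyr::n(),
                  fam_sd = sd(.data$length_mm),
                  fam_mean = mean(.data$length_mm)) |>
    dplyr::ungroup()
  bad <- stats_by_fam$fam_n < 3 | stats_by_fam$fam_sd == 0
  if (any(bad)) {
    warn_exhet(sprintf(
      "%d family(ies) excluded (fewer than 3 fish or zero length variance).",
      dplyr::n_distinct(stats_by_fam$family_id[bad])), "families_excluded")
  }
  use <- stats_by_fam[!bad, ]
  if (nrow(use) < 3) {
    abort_exhet("Too few usable individuals after family exclusions.", "too_few")
  }
  use$std_length <- (use$length_mm - use$fam_mean) / use$fam_sd
  fit <- stats::lm(std_length ~ observed_het, data = use)
  sm <- summary(fit)
  list(
    slope = unname(stats::coef(fit)[2]),
    slope_se = sm$coefficients[2, 2],
    f_statistic = unname(sm$fstatistic[1]),
    p_value = stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                        lower.tail = FALSE),
    r_squared = sm$r.squared,
    n = nrow(use),
    n_families_used = dplyr::n_distinct(use$family_id)
  )
}
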