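# The statistical layer: environment model, correlations, group
# comparisons, body-size regression, and the robustness simulations.

# synthetic individual summaries with a known environment effect and
# dataset-level intercepts
fake_summaries <- function(n_per_dataset = 150, delta = 0, dataset_sd = 0,
                           sd = 0.05, n_lab = 2, n_pond = 2, seed = 1,
                           cross_type = "BxL") {
  withr::with_seed(seed, {
    envs <- rep(c("lab", "pond"), c(n_lab, n_pond))
    ids <- sprintf("%s_%02d", envs, stats::ave(seq_along(envs), envs,
                                               FUN = seq_along))
    rows <- lapply(seq_along(ids), function(i) {
      mu <- (envs[i] == "pond") * delta + rnorm(1, 0, dataset_sd)
      h <- 0.5 + rnorm(n_per_dataset, 0, 0.05)
      tibble::tibble(
        individual_id = sprintf("%s_i%03d", ids[i], seq_len(n_per_dataset)),
        dataset_id = ids[i], family_id = paste0(ids[i], "_fam"),
        environment = envs[i], generation = "F2",
        length_mm = rnorm(n_per_dataset, 45, 5),
        n_loci = 100L, hybrid_index = h,
        observed_het = NA_real_,
        expected_het = 2 * h * (1 - h),
        excess_het = mu + rnorm(n_per_dataset, 0, sd)
      )
    })
    out <- dplyr::bind_rows(rows)
    out$observed_het <- out$excess_het + out$expected_het
    out$response <- out$excess_het
    out
  })
}

fake_manifest <- function(summaries, cross_type = "BxL") {
  ds <- dplyr::distinct(summaries, dataset_id, environment)
  ds$cross_type <- cross_type
  ds$lake <- ifelse(ds$cross_type == "BxL",
                    rep_len(c("Paxton", "Priest"), nrow(ds)), NA)
  ds
}

test_that("the environment model recovers a known pond elevation", {
  s <- fake_summaries(delta = 0.03, dataset_sd = 0.003, seed = 4)
  m <- fit_environment_model(s, fake_manifest(s))
  ct <- m$contrasts
  expect_equal(nrow(ct), 1)
  expect_lt(abs(ct$estimate - 0.03), 2.5 * ct$se + 0.005)
  expect_true(ct$p_value < 0.05)
  expect_true(all(m$fixed$se > 0))
})

test_that("the per-cross contrasts are recomputable from the fixed effects", {
  s1 <- fake_summaries(delta = 0.03, seed = 8)
  s2 <- fake_summaries(delta = 0.01, seed = 9)
  s2$dataset_id <- paste0("mxf_", s2$dataset_id)
  s2$individual_id <- paste0("mxf_", s2$individual_id)
  man <- dplyr::bind_rows(fake_manifest(s1, "BxL"), fake_manifest(s2, "MxF"))
  m <- fit_environment_model(dplyr::bind_rows(s1, s2), man)
  expect_equal(m$contrasts$cross_type, c("BxL", "MxF"))
  beta <- stats::setNames(m$fixed$estimate, m$fixed$term)
  expect_equal(m$contrasts$estimate[1], unname(beta["environmentpond"]))
  expect_equal(m$contrasts$estimate[2],
               unname(beta["environmentpond"] +
                        beta["environmentpond:cross_typeMxF"]))
  # contrasts equal differences of model-implied group means
  gm <- m$group_means
  for (cr in c("BxL", "MxF")) {
    diff_means <- gm$emmean[gm$environment == "pond" & gm$cross_type == cr] -
      gm$emmean[gm$environment == "lab" & gm$cross_type == cr]
    expect_equal(m$contrasts$estimate[m$contrasts$cross_type == cr],
                 diff_means, tolerance = 1e-8)
  }
})

test_that("a single environment is a structured error", {
  s <- fake_summaries(n_lab = 2, n_pond = 0, seed = 2)
  expect_error(fit_environment_model(s), class = "exhet_single_environment")
})

test_that("boundary variance components degrade to the fixed-effects fit with a note", {
  s <- fake_summaries(delta = 0, dataset_sd = 0, seed = 3)
  m <- suppressMessages(fit_environment_model(s, fake_manifest(s)))
  if (m$method == "lm") expect_match(paste(m$note, collapse = " "), "boundary")
  # forcing lm always works
  m2 <- fit_environment_model(s, fake_manifest(s), method = "lm")
  expect_equal(m2$method, "lm")
  expect_equal(m$contrasts$estimate, m2$contrasts$estimate, tolerance = 1e-6)
})

test_that("hybrid-index deviation correlation recovers exact monotone structure", {
  s <- fake_summaries(seed = 5, n_lab = 1, n_pond = 1, n_per_dataset = 50)
  # excess constructed as exactly -|h - 0.5| -> rho = -1
  s$response <- s$excess_het <- -abs(s$hybrid_index - 0.5)
  r <- hybrid_index_deviation_correlation(s)
  expect_equal(r$rho, -1)

  # x = [0.1, 0.2, 0.3] as |h - 0.5|, y = [3, 2, 1] -> rho = -1
  tiny <- tibble::tibble(environment = "pond",
                         hybrid_index = 0.5 + c(0.1, 0.2, 0.3),
                         excess_het = c(3, 2, 1))
  expect_equal(hybrid_index_deviation_correlation(tiny)$rho, -1)

  # constant response errors
  s$excess_het <- s$response <- 0.1
  expect_error(hybrid_index_deviation_correlation(s),
               class = "exhet_constant_input")
})

test_that("neutral data show no hybrid-index deviation correlation", {
  s <- fake_summaries(n_per_dataset = 500, seed = 6, n_lab = 1, n_pond = 1)
  r <- hybrid_index_deviation_correlation(s, group = "pond")
  expect_lt(abs(r$rho), 0.1)
  expect_gt(r$p_value, 0.01)
})

test_that("the bootstrap correlation difference is calibrated and deterministic", {
  s <- fake_summaries(n_per_dataset = 120, seed = 7, n_lab = 1, n_pond = 1)
  a <- s[s$environment == "pond", ]
  b1 <- bootstrap_correlation_difference(a, a, n_boot = 300, seed = 12)
  expect_true(b1$ci[1] <= 0 && 0 <= b1$ci[2])
  expect_gt(b1$p_value, 0.05)
  b2 <- bootstrap_correlation_difference(a, a, n_boot = 300, seed = 12)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$p_value > 0 && b1$p_value <= 1)

  # power: a strong negative correlation versus none is detected
  strong <- a
  strong$excess_het <- strong$response <-
    -abs(strong$hybrid_index - 0.5) + rnorm(nrow(a), 0, 0.02)
  b3 <- bootstrap_correlation_difference(strong, a, n_boot = 500, seed = 13)
  expect_true(b3$ci[2] < 0)
  expect_lt(b3$p_value, 0.05)
  expect_warning(bootstrap_correlation_difference(a, a, n_boot = 50, seed = 1),
                 class = "exhet_few_replicates")
})

test_that("group-mean comparisons behave under identity, symmetry, and effects", {
  s <- fake_summaries(seed = 14, n_lab = 1, n_pond = 1, n_per_dataset = 200)
  # two identical groups: F near 0, difference exactly 0
  twin <- dplyr::bind_rows(
    dplyr::mutate(s, grp = "g1"),
    dplyr::mutate(s, grp = "g2")
  )
  r <- compare_group_means(twin, "grp")
  expect_equal(r$difference, 0, tolerance = 1e-12)
  expect_lt(r$f_statistic, 1e-10)

  # known difference of 0.05 with sd 0.1 at n = 200/group
  withr::with_seed(15, {
    sim <- tibble::tibble(
      excess_het = c(rnorm(200, 0, 0.1), rnorm(200, 0.05, 0.1)),
      grp = rep(c("a", "b"), each = 200)
    )
  })
  r2 <- compare_group_means(sim, "grp")
  expect_true(r2$difference > 0.03 && r2$difference < 0.07)
  expect_equal(r2$df[2], 398)

  # F is invariant to permuting labels of three groups
  withr::with_seed(16, {
    sim3 <- tibble::tibble(excess_het = rnorm(90),
                           grp = rep(c("x", "y", "z"), each = 30))
  })
  f1 <- compare_group_means(sim3, "grp")$f_statistic
  sim3$grp <- c(x = "z", y = "x", z = "y")[sim3$grp]
  expect_equal(compare_group_means(sim3, "grp")$f_statistic, f1)

  expect_error(compare_group_means(dplyr::mutate(s, g = "one"), "g"),
               class = "exhet_single_level")
  tiny <- dplyr::bind_rows(s, dplyr::mutate(s[1, ], grp2 = "rare"))
  tiny$grp2[is.na(tiny$grp2 %||% NA)] <- "common"
  expect_error(compare_group_means(tiny, "grp2"), class = "exhet_tiny_group")
})

test_that("the within-family size regression handles exact and degenerate cases", {
  s <- fake_summaries(seed = 17, n_lab = 1, n_pond = 1, n_per_dataset = 100)
  s$observed_het <- 0.5 + rnorm(nrow(s), 0, 0.05)

  # lengths an exact linear function of heterozygosity -> R^2 = 1 within a
  # family (after standardization the slope is the reciprocal within-family
  # heterozygosity spread)
  exact <- s[s$family_id == s$family_id[1], ]
  exact$length_mm <- 2 * exact$observed_het + 10
  r <- within_family_size_regression(exact)
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  expect_equal(r$slope, 1 / sd(exact$observed_het), tolerance = 1e-6)
  expect_lt(r$p_value, 1e-10)

  # standardization makes the slope invariant to shifting all lengths
  single <- exact[exact$family_id == exact$family_id[1], ]
  r1 <- within_family_size_regression(single)
  single$length_mm <- single$length_mm + 1000
  r2 <- within_family_size_regression(single)
  expect_equal(r1$slope, r2$slope, tolerance = 1e-9)

  # lengths independent of heterozygosity: no association
  r3 <- within_family_size_regression(s)
  expect_gt(r3$p_value, 0.01)

  # zero-variance family excluded with a warning
  flat <- s
  flat$length_mm[flat$family_id == flat$family_id[1]] <- 50
  expect_warning(within_family_size_regression(flat),
                 class = "exhet_families_excluded")
})

test_that("single-marker resampling is exact with one marker per chromosome", {
  cfg <- sim_bundle_config(
    n_datasets_lab = 1, n_datasets_pond = 1, f2_per_family = 60,
    n_chromosomes = 21, markers_per_chromosome = 1, seed = 51)
  b <- generate_study_bundle(cfg)
  r <- single_marker_resampling(b, n_reps = 20, seed = 2)
  expect_equal(r$fraction_same_direction, 1.0)
})

test_that("resampling sign agreement tracks the true effect size", {
  # neutral bundle: agreement hovers near one half
  cfg0 <- sim_bundle_config(
    n_datasets_lab = 1, n_datasets_pond = 1, f2_per_family = 100,
    n_chromosomes = 11, markers_per_chromosome = 4, sex_chromosome = "11",
    seed = 52)
  r0 <- single_marker_resampling(generate_study_bundle(cfg0), n_reps = 200,
                                 seed = 3)
  expect_gt(r0$fraction_same_direction, 0.25)
  expect_lt(r0$fraction_same_direction, 0.75)

  # strong selection: nearly every replicate agrees
  cfg1 <- sim_bundle_config(
    n_datasets_lab = 1, n_datasets_pond = 1, f2_per_family = 100,
    n_chromosomes = 11, markers_per_chromosome = 4, sex_chromosome = "11",
    selection = selection_spec("heterozygote_advantage", s = 0.3), seed = 53)
  r1 <- single_marker_resampling(generate_study_bundle(cfg1), n_reps = 200,
                                 seed = 4)
  expect_gte(r1$fraction_same_direction, 0.95)
})

test_that("the error-threshold simulation matches its analytic small-e slope", {
  rep <- genotyping_error_threshold(n_fish = 300, n_loci = 100, n_reps = 10,
                                    grid = c(0, 0.01, 0.02, 0.04), seed = 61)
  res <- rep$results
  bias <- 1 / (4 * 100)  # finite-loci bias of the uncorrected expectation
  # e = 0: mean excess within Monte Carlo error of the neutral bias
  expect_lt(abs(res$mean_excess_het[1] - bias), 4 * res$mc_se[1] + 1e-3)
  # small-e slope: mean excess ~ e/2 above the neutral baseline
  for (i in 2:4) {
    predicted <- res$error_rate[i] / 2 + bias
    expect_lt(abs(res$mean_excess_het[i] - predicted),
              4 * res$mc_se[i] + 2e-3)
  }
  # monotone nondecreasing within Monte Carlo error
  expect_true(all(diff(res$mean_excess_het) > -2 * max(res$mc_se)))
})

test_that("required selection strength is ordered in target and architecture", {
  s_small <- selection_strength_required("heterozygote_advantage",
                                         target_excess = 0.02, n_fish = 1500,
                                         n_loci = 60, n_reps = 2, seed = 71)
  s_large <- selection_strength_required("heterozygote_advantage",
                                         target_excess = 0.04, n_fish = 1500,
                                         n_loci = 60, n_reps = 2, seed = 71)
  expect_gt(s_large$s_star, s_small$s_star)

  # concentrating selection on one locus demands an order of magnitude more
  # selection than spreading it genome-wide
  s_one <- selection_strength_required("heterozygote_advantage",
                                       target_excess = 0.012, n_loci = 50,
                                       k_loci = 1, n_fish = 2000, n_reps = 2,
                                       seed = 72)
  s_all <- selection_strength_required("heterozygote_advantage",
                                       target_excess = 0.012, n_loci = 50,
                                       k_loci = 50, n_fish = 2000, n_reps = 2,
                                       seed = 72)
  expect_gte(s_one$s_star / s_all$s_star, 10)

  # s = 0 achieves nothing: s* is strictly positive for positive targets
  expect_gt(s_small$s_star, 0)
  # an unreachable target is a structured error: mismatch selection on many
  # small-effect loci saturates far below a 5% excess
  expect_error(
    selection_strength_required("fgm_mismatch", target_excess = 0.05,
                                n_fish = 1000, n_loci = 100, n_reps = 2,
                                seed = 73, max_expand = 6),
    class = "exhet_target_unattainable")
})
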