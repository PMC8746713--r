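# Marker filtering, polarization, reciprocal filters, and the
# heterozygosity summaries.

test_that("diagnostic rules reject shared-allele, bad-F1, and sex-chromosome markers", {
  cross <- toy_cross()
  panel <- select_diagnostic_markers(cross, sex_chrom_label = "none")
  expect_setequal(panel$marker_id[panel$diagnostic], c("m1", "m2", "m4"))
  expect_equal(panel$rejection_reason[panel$marker_id == "m3"], "shared_alleles")
  expect_equal(panel$rejection_reason[panel$marker_id == "m5"],
               "f1_not_heterozygous")

  # the same cross with m4's chromosome declared the sex chromosome
  panel2 <- select_diagnostic_markers(cross, sex_chrom_label = "2")
  expect_false(panel2$diagnostic[panel2$marker_id == "m4"])
  expect_equal(panel2$rejection_reason[panel2$marker_id == "m4"],
               "sex_chromosome")
  # F1 validation rate: among side-disjoint markers (m1, m2, m4, m5),
  # 8 F1 calls, 1 homozygous
  expect_equal(attr(panel, "f1_validation_rate"), 7 / 8)
})

test_that("clean simulated crosses validate all F1 calls as heterozygous", {
  cfg <- small_config(seed = 19)
  fam <- generate_f2_family(cfg, 1, 1)
  panel <- select_diagnostic_markers(fam, sex_chrom_label = "5")
  expect_equal(attr(panel, "f1_validation_rate"), 1.0)
})

test_that("marker selection requires founders and F1s", {
  cross <- toy_cross()
  expect_error(
    select_diagnostic_markers(dplyr::filter(cross, generation != "F1")),
    class = "exhet_missing_f1")
  expect_error(
    select_diagnostic_markers(dplyr::filter(cross, generation != "F0A")),
    class = "exhet_missing_founders")
})

test_that("low-coverage calls are masked before the diagnostic rules run", {
  cross <- toy_cross()
  # bury the F0B call at m3 (the shared-allele marker) below the depth cutoff:
  # with it masked the F0 sets remain disjoint... but F0B then has no calls
  cross$coverage <- NA_integer_
  i <- cross$individual_id == "p_b" & cross$marker_id == "m3"
  cross$coverage[i] <- 10L
  panel <- select_diagnostic_markers(cross, sex_chrom_label = "none",
                                     min_coverage = 20)
  expect_equal(panel$rejection_reason[panel$marker_id == "m3"], "no_f0_calls")
  # a depth just above the threshold keeps the call (strict "> 20x")
  cross$coverage[i] <- 21L
  panel2 <- select_diagnostic_markers(cross, sex_chrom_label = "none",
                                      min_coverage = 20)
  expect_equal(panel2$rejection_reason[panel2$marker_id == "m3"],
               "shared_alleles")
})

test_that("polarization maps founders to 0/2, F1s to 1, and novel alleles to missing", {
  cross <- toy_cross()
  # give f2_2 a token seen in neither founder at m1
  cross$allele_1[cross$individual_id == "f2_2" & cross$marker_id == "m1"] <- "T"
  panel <- select_diagnostic_markers(cross, sex_chrom_label = "none")
  mat <- polarize_to_ancestry(cross, panel)
  d <- mat$dosage
  expect_true(all(d["p_a", ] == 0))
  expect_true(all(d["p_b", ] == 2))
  expect_true(all(d["f1_1", ] == 1))
  expect_true(is.na(d["f2_2", "m1"]))
  expect_equal(attr(mat, "novel_calls"), 1L)
  # f2_1 at m1 is A/G -> dosage 1; at m4 G/G -> dosage 2
  expect_equal(unname(d["f2_1", "m1"]), 1L)
  expect_equal(unname(d["f2_1", "m4"]), 2L)
})

test_that("polarization round-trips through side allele sets", {
  cfg <- small_config(seed = 23, platform = "microsatellite")
  fam <- generate_f2_family(cfg, 2, 1)
  panel <- select_diagnostic_markers(fam, sex_chrom_label = "5")
  mat <- polarize_to_ancestry(fam, panel)
  diag_panel <- panel[panel$diagnostic, ]
  # re-derive each call's side memberships from its dosage and check against
  # the original alleles
  calls <- dplyr::filter(fam, marker_id %in% diag_panel$marker_id,
                         !is.na(allele_1))
  ci <- match(calls$marker_id, diag_panel$marker_id)
  ri <- match(calls$individual_id, mat$individuals$individual_id)
  dos <- mat$dosage[cbind(ri, ci)]
  in_b_1 <- mapply(function(a, i) a %in% diag_panel$side_B_alleles[[i]],
                   calls$allele_1, ci)
  in_b_2 <- mapply(function(a, i) a %in% diag_panel$side_B_alleles[[i]],
                   calls$allele_2, ci)
  expect_equal(dos, as.integer(in_b_1) + as.integer(in_b_2))
})

test_that("panel markers missing from the cross raise a structured error", {
  cross <- toy_cross()
  panel <- select_diagnostic_markers(cross, sex_chrom_label = "none")
  expect_error(
    polarize_to_ancestry(dplyr::filter(cross, marker_id != "m1"), panel),
    class = "exhet_marker_not_in_cross")
})

test_that("matrix filters enforce the at-least-20 boundary and iterate to a fixed point", {
  # 25 individuals x 30 markers, complete; then punch holes
  d <- matrix(1L, 25, 30)
  mat <- matrix_from_dosage(d)
  # individual 1: exactly 19 non-missing -> dropped; individual 2: exactly 20
  mat$dosage[1, 20:30] <- NA_integer_
  mat$dosage[2, 21:30] <- NA_integer_
  out <- apply_matrix_filters(mat)
  kept <- out$individuals$individual_id
  expect_false("ind_0001" %in% kept)
  expect_true("ind_0002" %in% kept)

  # a matrix already satisfying both thresholds is returned unchanged
  full <- matrix_from_dosage(matrix(1L, 21, 21))
  out2 <- apply_matrix_filters(full)
  expect_identical(out2$dosage, full$dosage)

  # adversarial cascade: dropping an individual starves a marker.
  # 21 x 21 complete, except: marker 21 is missing for individual 21, and
  # individual 21 is the only carrier that keeps marker 21 at 20 genotyped
  # individuals once individual 1 (19 loci) is dropped.
  d3 <- matrix(1L, 21, 21)
  d3[1, 1:2] <- NA_integer_   # 19 loci -> dropped on pass 1
  d3[2, 21] <- NA_integer_    # marker 21: 19 genotyped after ind 1 goes
  mat3 <- matrix_from_dosage(d3)
  out3 <- apply_matrix_filters(mat3)
  expect_false("m_021" %in% out3$markers$marker_id)
  expect_equal(attr(out3, "filter_report")$iterations, 2L)
  # exhaustive recount oracle: every survivor meets both thresholds
  expect_true(all(rowSums(!is.na(out3$dosage)) >= 20))
  expect_true(all(colSums(!is.na(out3$dosage)) >= 20))
})

test_that("filtering is monotone and errors when everything is dropped", {
  d <- matrix(1L, 30, 30)
  d[, 1:5] <- NA_integer_
  mat <- matrix_from_dosage(d)
  out <- apply_matrix_filters(mat)
  expect_lte(ncol(out$dosage), ncol(mat$dosage))
  expect_lte(nrow(out$dosage), nrow(mat$dosage))
  tiny <- matrix_from_dosage(matrix(1L, 5, 30))
  expect_error(apply_matrix_filters(tiny),
               class = "exhet_all_markers_dropped")
  sparse <- matrix_from_dosage(matrix(NA_integer_, 25, 25))
  expect_error(apply_matrix_filters(sparse),
               class = "exhet_all_individuals_dropped")
})

test_that("individual summaries match hand arithmetic and the exact identity", {
  # all loci heterozygous: h = 0.5, observed 1, expected 0.5, excess +0.5
  m_het <- matrix_from_dosage(matrix(1L, 3, 4))
  s <- summarize_individuals(m_het)
  expect_equal(s$hybrid_index, rep(0.5, 3))
  expect_equal(s$observed_het, rep(1, 3))
  expect_equal(s$excess_het, rep(0.5, 3))

  # all dosage 0: everything 0
  s0 <- summarize_individuals(matrix_from_dosage(matrix(0L, 3, 4)))
  expect_equal(s0$hybrid_index, rep(0, 3))
  expect_equal(s0$excess_het, rep(0, 3))

  # dosages [0, 1, 1, 2]: observed 0.5, h 0.5, expected 0.5, excess 0
  s1 <- summarize_individuals(matrix_from_dosage(matrix(c(0L, 1L, 1L, 2L), 1)))
  expect_equal(s1$observed_het, 0.5)
  expect_equal(s1$hybrid_index, 0.5)
  expect_equal(s1$excess_het, 0)

  # identity excess = p_AB - 2h(1-h), against the brute-force oracle,
  # including matrices with missing cells
  set.seed(99)
  d <- matrix(sample(c(0:2, NA), 200 * 40, TRUE, prob = c(.24, .49, .24, .03)),
              200, 40)
  s2 <- summarize_individuals(matrix_from_dosage(d))
  expect_equal(s2$excess_het, unname(brute_excess(d)), tolerance = 1e-12)
  expect_true(all(s2$excess_het >= -0.5 & s2$excess_het <= 0.5))
})

test_that("the small-sample correction scales expected heterozygosity by 2N/(2N-1)", {
  d <- matrix(sample(0:2, 50 * 25, TRUE, prob = c(.25, .5, .25)), 50, 25)
  plain <- summarize_individuals(matrix_from_dosage(d))
  corr <- summarize_individuals(matrix_from_dosage(d),
                                correction = "small_sample")
  expect_equal(corr$expected_het,
               plain$expected_het * (2 * plain$n_loci) / (2 * plain$n_loci - 1))
  # corrected expected heterozygosity is unbiased under neutrality, so the
  # corrected excess is on average below the uncorrected one
  expect_lt(mean(corr$excess_het), mean(plain$excess_het))
})

test_that("statistic = observed exposes raw heterozygosity as the response", {
  d <- matrix(sample(0:2, 30 * 25, TRUE), 30, 25)
  s <- summarize_individuals(matrix_from_dosage(d), statistic = "observed")
  expect_equal(s$response, s$observed_het)
})

test_that("locus summaries mirror individuals with roles swapped", {
  # locus with dosage counts (25, 50, 25): p_B = 0.5, observed 0.5, excess 0
  d <- matrix(rep(c(rep(0L, 25), rep(1L, 50), rep(2L, 25)), 2), ncol = 2)
  ls <- summarize_loci(matrix_from_dosage(d))
  expect_equal(ls$ancestry_freq, c(0.5, 0.5))
  expect_equal(ls$observed_het, c(0.5, 0.5))
  expect_equal(ls$excess_het, c(0, 0))

  # all heterozygous: excess +0.5; monomorphic dosage 2: excess 0
  d2 <- cbind(rep(1L, 100), rep(2L, 100))
  ls2 <- summarize_loci(matrix_from_dosage(d2))
  expect_equal(ls2$excess_het, c(0.5, 0))

  # only recombinants count: founders and F1s are excluded
  cfg <- small_config(seed = 31)
  fam <- generate_f2_family(cfg, 1, 1)
  mat <- polarize_to_ancestry(fam, select_diagnostic_markers(fam, "5"))
  ls3 <- summarize_loci(mat)
  expect_true(all(ls3$n_individuals == 80))
})

test_that("chromosome means average loci with SE undefined for singletons", {
  loci <- tibble::tibble(
    marker_id = c("a", "b", "c"),
    chromosome = c("1", "1", "2"),
    excess_het = c(0.1, -0.1, 0.07)
  )
  cm <- chromosome_means(loci)
  expect_equal(cm$mean_excess_het[cm$chromosome == "1"], 0)
  expect_true(is.na(cm$se[cm$chromosome == "2"]))
  expect_equal(cm$n_loci, c(2L, 1L))

  # neutral simulated dataset: every chromosome mean within 4 SE of the
  # finite-loci bias band around zero
  cfg <- sim_bundle_config(
    n_datasets_lab = 1, n_datasets_pond = 0, f2_per_family = 400,
    n_chromosomes = 6, markers_per_chromosome = 12, sex_chromosome = "6",
    seed = 71)
  fam <- generate_f2_family(cfg, 1, 1)
  mat <- apply_matrix_filters(
    polarize_to_ancestry(fam, select_diagnostic_markers(fam, "6")))
  cm2 <- chromosome_means(summarize_loci(mat))
  expect_true(all(abs(cm2$mean_excess_het) < 4 * cm2$se + 0.01))
  expect_false("6" %in% cm2$chromosome)
})
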