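#' Configure a Fisher-geometric-model adaptive-walk simulation
#'
#' Phenotypes are points in an `m`-trait Euclidean space; fitness declines as
#' a Gaussian function of squared distance from the optimum. A derived
#' population adapts from the ancestral phenotype to a displaced optimum via
#' an origin-fixation walk (mutations are rare enough to sweep one at a
#' time), after which F2 hybrids between the two populations are formed from
#' the fixed mutations.
#'
#' @param m Number of traits (2 by default; 10 reproduces the
#'   high-dimensional variant in which only trait 1 is under divergent
#'   selection).
#' @param alpha Mutation-effect standard deviation per trait (default 0.15).
#' @param sigma Strength of stabilizing selection (default 10).
#' @param N Effective population size (default 1000).
#' @param p0 Initial frequency of a new mutation (default `1/N`).
#' @param n_mutations Number of mutations proposed during the walk
#'   (default 1000, sufficient for the population to reach the optimum).
#' @param z0 Ancestral phenotype (default the origin).
#' @param z_opt Optimum of the adapting population: `c(1, 1)` for `m = 2`;
#'   for `m > 2`, 1 for trait 1 and 0 for the non-selected traits.
#' @param n_hybrids F2 cohort size for [make_f2_cohort()] (default 500).
#' @param seed Integer seed.
#' @return An `fgm_config` object.
#' @export
fgm_config <- function(m = 2, alpha = 0.15, sigma = 10, N = 1000,
                       p0 = 1 / N, n_mutations = 1000, z0 = NULL,
                       z_opt = NULL, n_hybrids = 500, seed = 1) {
  if (!is_count(m)) abort_exhet("`m` must be a positive count.", "bad_fgm_config")
  if (!is.numeric(alpha) || alpha <= 0) {
    abort_exhet("`alpha` must be positive.", "bad_fgm_config")
  }
  if (!is.numeric(sigma) || sigma < 0) {
    abort_exhet("`sigma` must be non-negative.", "bad_fgm_config")
  }
  if (!is_count(N) || N < 2) abort_exhet("`N` must be >= 2.", "bad_fgm_config")
  if (!is.numeric(p0) || p0 <= 0 || p0 > 1) {
    abort_exhet("`p0` must be in (0, 1].", "bad_fgm_config")
  }
  if (!is_count(n_mutations) || !is_count(n_hybrids)) {
    abort_exhet("`n_mutations` and `n_hybrids` must be positive counts.",
                "bad_fgm_config")
  }
  z0 <- z0 %||% rep(0, m)
  z_opt <- z_opt %||% if (m == 2) c(1, 1) else c(1, rep(0, m - 1))
  if (length(z0) != m || length(z_opt) != m) {
    abort_exhet("`z0` and `z_opt` must have length `m`.", "bad_fgm_config")
  }
  structure(
    list(m = as.integer(m), alpha = alpha, sigma = sigma, N = as.integer(N),
         p0 = p0, n_mutations = as.integer(n_mutations), z0 = z0,
         z_opt = z_opt, n_hybrids = as.integer(n_hybrids),
         seed = as.integer(seed)),
    class = "fgm_config"
  )
}

#' Gaussian fitness in phenotype space
#'
#' \eqn{w = \exp(-\sigma \, \lVert z - o \rVert^2)}: fitness declines with the
#' squared Euclidean distance between a phenotype and the optimum.
#'
#' @param z Phenotype vector, or a matrix with one phenotype per row.
#' @param optimum Optimum phenotype vector of the same trait dimension.
#' @param sigma Non-negative selection strength.
#' @return Fitness value(s) in `(0, 1]`.
#' @export
fgm_fitness <- function(z, optimum, sigma) {
  if (is.matrix(z)) {
    if (ncol(z) != length(optimum)) {
      abort_exhet("`z` and `optimum` disagree in trait dimension.", "dim_mismatch")
    }
    d2 <- rowSums(sweep(z, 2, optimum)^2)
  } else {
    if (length(z) != length(optimum)) {
      abort_exhet("`z` and `optimum` disagree in trait dimension.", "dim_mismatch")
    }
    d2 <- sum((z - optimum)^2)
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0) {
    abort_exhet("`sigma` must be a single non-negative number.", "bad_sigma")
  }
  exp(-sigma * d2)
}

#' Diffusion fixation probability of a new mutation
#'
#' \eqn{\pi = \frac{1 - e^{-2Nsp}}{1 - e^{-2Ns}}}, the classical diffusion
#' approximation for a mutation at frequency `p` with selection coefficient
#' `s` in a population of size `N`. The neutral limit (`|2Ns|` below 1e-8)
#' returns `p` by continuous extension; evaluation is log-stable for
#' strongly deleterious mutations, and the result is clamped to `[0, 1]`.
#'
#' @param N Population size (`>= 2`).
#' @param s Selection coefficient (any sign).
#' @param p Current allele frequency in `(0, 1]`.
#' @return Fixation probability in `[0, 1]`.
#' @export
fixation_probability <- function(N, s, p) {
  if (!is.numeric(N) || any(N < 2)) abort_exhet("`N` must be >= 2.", "bad_n")
  if (!is.numeric(p) || any(p <= 0) || any(p > 1)) {
    abort_exhet("`p` must be in (0, 1].", "bad_p")
  }
  a <- -2 * N * s  # pi = expm1(a * p) / expm1(a)
  pi_val <- ifelse(
    abs(a) < 1e-8,
    p,
    ifelse(
      a > 50,
      # deleterious tail: expm1 overflows, use exp(a p - a) * (1 - e^{-ap})
      exp(pmin(a * p, 700) - a) * -expm1(-a * p),
      expm1(a * p) / expm1(a)
    )
  )
  pmin(pmax(pi_val, 0), 1)
}

#' Simulate an origin-fixation adaptive walk
#'
#' Proposes `n_mutations` phenotypic mutations, each a vector of `m`
#' independent Normal(0, alpha^2) trait effects. A proposal's selection
#' coefficient is the fitness ratio minus one,
#' \eqn{s = w_{mut}/w_{wt} - 1}, and it fixes with probability
#' \eqn{\pi(N, s, p_0)} from [fixation_probability()]; fixed effects add to
#' the population phenotype. Deleterious fixations are possible (drift), but
#' accepted proposals have systematically higher `s` than rejected ones.
#'
#' @param config An [fgm_config()].
#' @return An `adaptive_walk`: list with `effects` (fixed-mutation matrix,
#'   one row per fixed locus), `proposals` (per-proposal tibble of `s`,
#'   `pi`, `accepted`), `z_A` (ancestral phenotype), `z_P` (derived-parent
#'   phenotype, equal to `z_A + colSums(effects)`), and `config`.
#' @export
adaptive_walk <- function(config) {
  if (!inherits(config, "fgm_config")) {
    abort_exhet("`config` must be an fgm_config().", "bad_fgm_config")
  }
  m <- config$m
  with_seed(config$seed, {
    z <- config$z0
    effects <- matrix(numeric(0), 0, m)
    s_vec <- pi_vec <- numeric(config$n_mutations)
    acc <- logical(config$n_mutations)
    for (i in seq_len(config$n_mutations)) {
      delta <- rnorm(m, 0, config$alpha)
      w_wt <- fgm_fitness(z, config$z_opt, config$sigma)
      w_mut <- fgm_fitness(z + delta, config$z_opt, config$sigma)
      s <- w_mut / w_wt - 1
      pi_i <- fixation_probability(config$N, s, config$p0)
      fixed <- runif(1) < pi_i
      if (fixed) {
        z <- z + delta
        effects <- rbind(effects, delta)
      }
      s_vec[i] <- s
      pi_vec[i] <- pi_i
      acc[i] <- fixed
    }
    rownames(effects) <- NULL
    structure(
      list(effects = effects,
           proposals = tibble::tibble(s = s_vec, pi = pi_vec, accepted = acc),
           z_A = config$z0, z_P = z, config = config),
      class = "adaptive_walk"
    )
  })
}

#' @export
print.adaptive_walk <- function(x, ...) {
  cat(sprintf(
    "<adaptive_walk> %d traits, %d/%d proposals fixed, final distance to optimum %.4f\n",
    x$config$m, nrow(x$effects), x$config$n_mutations,
    sqrt(sum((x$z_P - x$config$z_opt)^2))))
  invisible(x)
}

#' Generate an F2 hybrid cohort from an adaptive walk
#'
#' Hybrids between the derived population and its ancestor inherit, at each
#' fixed locus independently (free recombination), homozygous-ancestral,
#' heterozygous, or homozygous-derived ancestry with probabilities
#' 0.25/0.5/0.25. Phenotypes are additive:
#' \eqn{z = z_A + \sum_i (d_i / 2)\, \Delta_i}. Each hybrid's trait mismatch
#' is its perpendicular distance from the axis connecting the two realized
#' parent phenotypes; for `m > 2` the distance over the non-selected traits
#' is also reported.
#'
#' @param walk An [adaptive_walk()] with at least one fixed mutation.
#' @param n_hybrids Cohort size (defaults to the walk config's value).
#' @param seed Integer seed (defaults to the walk config's seed).
#' @return A `hybrid_cohort` tibble: per hybrid `hybrid_index`,
#'   `heterozygosity`, `excess_het`, `mismatch`, phenotype columns `z1..zm`,
#'   and (for `m > 2`) `mismatch_nonselected`; the dosage matrix and walk are
#'   attached as attributes `dosage` and `walk`.
#' @export
make_f2_cohort <- function(walk, n_hybrids = NULL, seed = NULL) {
  if (!inherits(walk, "adaptive_walk")) {
    abort_exhet("`walk` must come from adaptive_walk().", "bad_walk")
  }
  L <- nrow(walk$effects)
  if (L == 0) {
    abort_exhet("The walk fixed zero mutations; no loci to segregate.",
                "no_fixed_mutations")
  }
  n_hybrids <- n_hybrids %||% walk$config$n_hybrids
  seed <- seed %||% mix_seed(walk$config$seed, 424242L)
  m <- walk$config$m
  with_seed(seed, {
    dosage <- matrix(sample(0:2, n_hybrids * L, TRUE, prob = c(0.25, 0.5, 0.25)),
                     n_hybrids, L)
    phenotype <- sweep((dosage / 2) %*% walk$effects, 2, walk$z_A, `+`)
    h <- rowSums(dosage) / (2 * L)
    het <- rowMeans(dosage == 1)
    cohort <- tibble::tibble(
      hybrid_index = h,
      heterozygosity = het,
      excess_het = het - 2 * h * (1 - h),
      mismatch = trait_mismatch(phenotype, walk, mode = "perpendicular")
    )
    if (m > 2) {
      cohort$mismatch_nonselected <-
        trait_mismatch(phenotype, walk, mode = "nonselected_distance")
    }
    colnames(phenotype) <- paste0("z", seq_len(m))
    cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(phenotype))
    attr(cohort, "dosage") <- dosage
    attr(cohort, "walk") <- walk
    class(cohort) <- c("hybrid_cohort", class(cohort))
    cohort
  })
}

#' Trait mismatch of hybrid phenotypes
#'
#' `"perpendicular"`: shortest distance from a phenotype to the infinite
#' line through the two realized parent phenotypes (the axis of divergence);
#' zero for any phenotype on the segment, in particular for the additive
#' midpoint of a fully heterozygous hybrid. `"nonselected_distance"` (for
#' `m > 2`): Euclidean norm of the phenotype over the non-selected traits
#' `2..m`, i.e. maladaptive displacement orthogonal to the selected trait.
#'
#' @param z A phenotype vector or a matrix of phenotypes (rows).
#' @param walk The [adaptive_walk()] defining the parental axis.
#' @param mode `"perpendicular"` or `"nonselected_distance"`.
#' @return Non-negative mismatch value(s).
#' @export
trait_mismatch <- function(z, walk,
                           mode = c("perpendicular", "nonselected_distance")) {
  mode <- match.arg(mode)
  if (!is.matrix(z)) z <- matrix(z, 1)
  m <- walk$config$m
  if (ncol(z) != m) {
    abort_exhet("Phenotype dimension does not match the walk.", "dim_mismatch")
  }
  if (mode == "nonselected_distance") {
    if (m <= 2) {
      abort_exhet("`nonselected_distance` requires more than 2 traits.",
                  "bad_mode")
    }
    return(sqrt(rowSums(z[, -1, drop = FALSE]^2)))
  }
  axis <- walk$z_P - walk$z_A
  len2 <- sum(axis^2)
  if (len2 == 0) {
    abort_exhet("Parent phenotypes coincide; the inter-parent axis is undefined.",
                "degenerate_axis")
  }
  u <- sweep(z, 2, walk$z_A)
  # residual-vector form: subtracting the axis projection before taking the
  # norm keeps on-axis points at mismatch zero (the Pythagorean form
  # |u|^2 - proj^2 loses that exactness to cancellation)
  coef <- as.vector(u %*% axis) / len2
  resid <- u - outer(coef, axis)
  sqrt(rowSums(resid^2))
}

#' Rank correlation between excess heterozygosity and mismatch
#'
#' Spearman correlation of per-hybrid excess ancestry heterozygosity against
#' trait mismatch in an F2 cohort. Under divergent adaptation followed by
#' hybridization the correlation is negative: more heterozygous hybrids have
#' phenotypes closer to the inter-parent axis.
#'
#' @param cohort A `hybrid_cohort` from [make_f2_cohort()].
#' @param mismatch_col Which mismatch column to use (default `"mismatch"`).
#' @return A list: `rho`, `p_value`, `n`.
#' @export
cohort_relation <- function(cohort, mismatch_col = "mismatch") {
  if (nrow(cohort) < 3) {
    abort_exhet("Need at least 3 hybrids.", "too_few")
  }
  x <- cohort$excess_het
  y <- cohort[[mismatch_col]]
  if (is.null(y)) abort_exhet("Mismatch column not found.", "bad_column")
  if (sd(y) == 0 || sd(x) == 0) {
    abort_exhet("Constant excess heterozygosity or mismatch; correlation undefined.",
                "constant_input")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(cohort))
}
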