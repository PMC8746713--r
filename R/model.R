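#' Fit the lab-versus-pond excess-heterozygosity model
#'
#' Linear mixed model for pooled individual summaries: the response (excess
#' ancestry heterozygosity by default) is modeled with environment (lab or
#' pond), cross type, their interaction, and lake of origin (a contrast that
#' only exists within benthic x limnetic crosses) as fixed effects, and data
#' source (`dataset_id`) as a random intercept, fitted by REML. Terms whose
#' factors have a single level in the data are dropped automatically. When
#' the random-intercept variance is estimated at the boundary (a singular
#' fit) or fewer than two data sources are present, fitting degrades
#' gracefully to the fixed-effects model and the `note` field records it.
#'
#' The quantity of interest is the per-cross environment contrast
#' (pond minus lab), reported with its standard error, Wald `z`, and
#' two-sided `P`; it is a linear combination of the fixed effects, so it can
#' be recomputed from `fixed` and the fitted model's covariance.
#'
#' @param summaries Pooled tibble from [summarize_individuals()] across
#'   datasets; must carry `dataset_id` and `environment`.
#' @param manifest Optional dataset manifest carrying `dataset_id`,
#'   `cross_type`, and `lake` (as produced by [generate_study_bundle()]).
#'   Without cross information all rows are treated as one cross.
#' @param method `"auto"` (REML with fixed-effects fallback), `"reml"`, or
#'   `"lm"` (fixed effects only; useful for fast resampling).
#' @return An `env_model` object: list with `contrasts` (per-cross tibble),
#'   `group_means` (estimated marginal means per environment x cross),
#'   `fixed`, `method`, `note`, `fit`, `n_obs`.
#' @export
fit_environment_model <- function(summaries, manifest = NULL,
                                  method = c("auto", "reml", "lm")) {
  method <- match.arg(method)
  df <- tibble::as_tibble(summaries)
  if (!all(c("dataset_id", "environment") %in% names(df))) {
    abort_exhet("Summaries must carry `dataset_id` and `environment`.",
                "bad_summaries")
  }
  if (!is.null(manifest)) {
    keep <- intersect(c("dataset_id", "cross_type", "lake"), names(manifest))
    df <- dplyr::left_join(df, dplyr::distinct(manifest[, keep]),
                           by = "dataset_id")
  }
  if (!has_col(df, "response") && !has_col(df, "excess_het")) {
    abort_exhet("Summaries carry neither `response` nor `excess_het`.",
                "bad_summaries")
  }
  df$y <- response_of(df)
  envs <- unique(df$environment)
  if (length(envs) < 2) {
    abort_exhet("Both environments (lab and pond) are required for the contrast.",
                "single_environment")
  }
  df$environment <- factor(df$environment, levels = c("lab", "pond"))
  if (!has_col(df, "cross_type")) df$cross_type <- "all"
  crosses <- sort(unique(df$cross_type))
  df$cross_type <- factor(df$cross_type, levels = crosses)
  two_crosses <- length(crosses) > 1

  use_lake <- has_col(df, "lake") && dplyr::n_distinct(df$lake[!is.na(df$lake)]) > 1
  if (use_lake) {
    df$lake_priest <- as.numeric(!is.na(df$lake) & df$lake == "Priest")
  }

  rhs <- "environment"
  if (two_crosses) rhs <- paste(rhs, "+ cross_type + environment:cross_type")
  if (use_lake) rhs <- paste(rhs, "+ lake_priest")
  fixed_formula <- stats::as.formula(paste("y ~", rhs))

  n_datasets <- dplyr::n_distinct(df$dataset_id)
  note <- character(0)
  fit <- NULL
  used <- "lm"
  if (method != "lm" && n_datasets >= 2) {
    mixed_formula <- stats::as.formula(paste("y ~", rhs, "+ (1 | dataset_id)"))
    fit_try <- tryCatch(
      lme4::lmer(mixed_formula, data = df, REML = TRUE),
      error = function(e) e
    )
    if (inherits(fit_try, "error")) {
      if (method == "reml") {
        abort_exhet(paste0("Mixed model failed to converge: ",
                           conditionMessage(fit_try)), "non_convergence")
      }
      note <- c(note, paste0("mixed model failed (", conditionMessage(fit_try),
                             "); fixed-effects fallback"))
    } else if (lme4::isSingular(fit_try, tol = 1e-5) && method == "auto") {
      note <- c(note,
                "random-intercept variance at boundary (0); fixed-effects fallback")
    } else {
      fit <- fit_try
      used <- "reml"
    }
  } else if (method != "lm" && n_datasets < 2) {
    note <- c(note, "single data source; fixed-effects model used")
  }
  if (is.null(fit)) {
    fit <- stats::lm(fixed_formula, data = df)
    used <- "lm"
  }

  beta <- if (used == "reml") lme4::fixef(fit) else stats::coef(fit)
  vc <- as.matrix(stats::vcov(fit))
  term_env <- "environmentpond"
  contrast_rows <- lapply(crosses, function(cr) {
    cvec <- stats::setNames(numeric(length(beta)), names(beta))
    cvec[term_env] <- 1
    if (two_crosses && cr != crosses[1]) {
      inter <- paste0("environmentpond:cross_type", cr)
      if (inter %in% names(beta)) cvec[inter] <- 1
    }
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% vc %*% cvec))
    z <- est / se
    tibble::tibble(cross_type = cr, estimate = est, se = se, z = z,
                   p_value = 2 * pnorm(-abs(z)),
                   lower = est - qnorm(0.975) * se,
                   upper = est + qnorm(0.975) * se)
  })
  contrasts <- dplyr::bind_rows(contrast_rows)

  group_means <- tryCatch({
    spec <- if (two_crosses) ~environment * cross_type else ~environment
    em <- suppressMessages(if (used == "reml") {
      emmeans::emmeans(fit, spec, lmer.df = "asymptotic")
    } else {
      emmeans::emmeans(fit, spec)
    })
    tibble::as_tibble(as.data.frame(em))
  }, error = function(e) NULL)

  structure(
    list(contrasts = contrasts, group_means = group_means,
         fixed = tibble::tibble(term = names(beta), estimate = unname(beta),
                                se = sqrt(diag(vc))),
         method = used, note = note, fit = fit, n_obs = nrow(df),
         n_datasets = n_datasets),
    class = "env_model"
  )
}

#' @export
print.env_model <- function(x, ...) {
  cat(sprintf("<env_model> %s fit, %d individuals from %d data sources\n",
              toupper(x$method), x$n_obs, x$n_datasets))
  if (length(x$note)) cat("  note:", paste(x$note, collapse = "; "), "\n")
  cat("  pond - lab contrasts:\n")
  for (i in seq_len(nrow(x$contrasts))) {
    r <- x$contrasts[i, ]
    cat(sprintf("    %s: %+.4f +/- %.4f (z = %.2f, P = %.3g)\n",
                r$cross_type, r$estimate, r$se, r$z, r$p_value))
  }
  invisible(x)
}
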