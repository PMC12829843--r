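#' Pairwise collinearity screen for numeric covariates
#'
#' Flags every pair of numeric covariates whose absolute Pearson correlation
#' exceeds the threshold (default 0.70, i.e. 70%); an empty result means the
#' covariate set passes. A constant column makes the correlation undefined
#' and is an error rather than a silent pass.
#'
#' @param covariates Data frame of numeric columns.
#' @param threshold Absolute-correlation cutoff (strict).
#' @return A tibble `var1`, `var2`, `r` of offending pairs (0 rows = pass).
#' @export
collinearity_screen <- function(covariates, threshold = 0.70) {
  covariates <- as.data.frame(covariates)
  num <- covariates[vapply(covariates, is.numeric, logical(1))]
  stopifnot(ncol(num) >= 2L)
  sds <- vapply(num, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop(sprintf("constant column(s), correlation undefined: %s",
                 paste(names(num)[sds == 0], collapse = ", ")))
  }
  r <- stats::cor(num, method = "pearson")
  idx <- which(abs(r) > threshold & upper.tri(r), arr.ind = TRUE)
  tibble::tibble(
    var1 = rownames(r)[idx[, 1]],
    var2 = colnames(r)[idx[, 2]],
    r = r[idx]
  )
}

.default_fixed <- c("genetics", "n_authors", "n_types", "n_species_in_paper",
                    "n_trips", "genus_richness")

#' Assemble the model frame for the description-time models
#'
#' Joins the per-species covariates with the lag decomposition and builds the
#' response `log_description_y = log(description_y)`; genetics is coded 0/1.
#'
#' @param records A [new_records()] object.
#' @param lags The tibble returned by [compute_lags()] on the same records.
#' @return A tibble with response, covariates and grouping factors.
#' @export
build_model_frame <- function(records, lags) {
  df <- dplyr::inner_join(
    records$species, lags[, c("species", "description_y", "n_trips")],
    by = "species"
  )
  stopifnot(all(df$description_y > 0))
  tibble::tibble(
    species = df$species,
    log_description_y = log(df$description_y),
    genetics = as.numeric(df$genetics),
    n_authors = as.numeric(df$n_authors),
    n_types = as.numeric(df$n_types),
    n_species_in_paper = as.numeric(df$n_species_in_paper),
    n_trips = as.numeric(df$n_trips),
    genus_richness = as.numeric(df$genus_richness),
    genus = factor(df$genus),
    region = factor(df$region)
  )
}

#' Fit the Gaussian mixed model for log description time
#'
#' Fits `log(description_y)` on the abiotic covariates with random intercepts
#' for genus (and, in the global scope, region), Gaussian family with an
#' identity link, by maximum likelihood (not REML) so that likelihoods and
#' AICs are comparable across the null-versus-full model test. Covariates
#' constant within the scope are dropped with a message. A single-level
#' random grouping is dropped (its variance pinned at zero), in which case
#' the fit reduces to ordinary least squares.
#'
#' @param frame Model frame from [build_model_frame()] (or any data frame
#'   with the same columns).
#' @param scope `"global"` (random intercepts genus + region) or a region
#'   name (rows filtered to that region; random intercept genus only).
#' @param fixed Character vector of fixed-effect covariates; `character(0)`
#'   gives the null model (random effects only).
#' @param scale_covariates If `TRUE`, z-scale the continuous covariates
#'   (off by default; the analysis runs on the raw scales).
#' @return An object of class `taxalag_fit`: list with the underlying model
#'   (`model`), `coefficients` tibble (term, estimate, se), `varcomp` named
#'   vector of random-intercept and residual variances, `logLik`, `AIC`,
#'   `n`, `converged`, `spec`.
#' @export
fit_lmm <- function(frame, scope = "global", fixed = .default_fixed,
                    scale_covariates = FALSE) {
  df <- tibble::as_tibble(frame)
  random <- c("genus", "region")
  if (!identical(scope, "global")) {
    df <- df[df$region == scope, , drop = FALSE]
    if (!nrow(df)) stop(sprintf("no rows for region '%s'", scope))
    random <- "genus"
  }
  if (scale_covariates) {
    cont <- intersect(fixed, c("n_authors", "n_types", "n_species_in_paper",
                               "n_trips", "genus_richness"))
    for (v in cont) df[[v]] <- as.numeric(scale(df[[v]]))
  }
  constant <- fixed[vapply(fixed, function(v) stats::sd(df[[v]]) == 0, logical(1))]
  if (length(constant)) {
    message("dropping covariate(s) constant within scope: ",
            paste(constant, collapse = ", "))
    fixed <- setdiff(fixed, constant)
  }
  single <- random[vapply(random, function(v) nlevels(droplevels(df[[v]])) < 2L, logical(1))]
  if (length(single)) {
    message("dropping single-level random effect(s), variance pinned at 0: ",
            paste(single, collapse = ", "))
    random <- setdiff(random, single)
  }
  fixed_part <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  if (length(random)) {
    form <- stats::as.formula(paste(
      "log_description_y ~", fixed_part, "+",
      paste(sprintf("(1 | %s)", random), collapse = " + ")
    ))
    model <- lme4::lmer(form, data = df, REML = FALSE,
                        control = lme4::lmerControl(calc.derivs = FALSE))
    msgs <- unlist(model@optinfo$conv$lme4$messages)
    # a boundary (singular) fit is a valid ML optimum with a variance at 0,
    # not a convergence failure
    real <- msgs[!grepl("singular|boundary", msgs, ignore.case = TRUE)]
    converged <- !length(real)
    if (!converged) warning("mixed-model fit did not converge cleanly: ",
                            paste(real, collapse = "; "))
    fe <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
    vc <- as.data.frame(lme4::VarCorr(model))
    varcomp <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual", vc$grp))
  } else {
    form <- stats::as.formula(paste("log_description_y ~", fixed_part))
    model <- stats::lm(form, data = df)
    converged <- TRUE
    fe <- stats::coef(model)
    se <- sqrt(diag(stats::vcov(model)))
    n <- nrow(df)
    varcomp <- c(residual = sum(stats::resid(model)^2) / n)  # ML variance
  }
  ll <- as.numeric(stats::logLik(model))
  k <- attr(stats::logLik(model), "df")
  structure(
    list(
      model = model,
      coefficients = tibble::tibble(term = names(fe), estimate = unname(fe), se = unname(se)),
      varcomp = varcomp,
      logLik = ll,
      AIC = 2 * k - 2 * ll,
      df = k,
      n = nrow(df),
      converged = converged,
      spec = list(scope = scope, fixed = fixed, random = random,
                  response = "log_description_y")
    ),
    class = "taxalag_fit"
  )
}

#' @export
print.taxalag_fit <- function(x, ...) {
  cat(sprintf(
    "<taxalag_fit> scope %s | n = %d | fixed: %s | random: %s\n  logLik %.2f, AIC %.2f, converged: %s\n",
    x$spec$scope, x$n,
    if (length(x$spec$fixed)) paste(x$spec$fixed, collapse = ", ") else "(null)",
    if (length(x$spec$random)) paste(x$spec$random, collapse = ", ") else "(none)",
    x$logLik, x$AIC, x$converged
  ))
  invisible(x)
}

#' Type-II Wald chi-square tests per fixed-effect term
#'
#' Tests each fixed-effect term jointly over its columns, adjusted for every
#' other term, so the influence of a predictor is assessed without regard to
#' factor-level parameterization. For a single-coefficient term the
#' statistic reduces to (estimate / se)^2 on 1 degree of freedom.
#'
#' @param fit A [fit_lmm()] object with at least one fixed effect.
#' @return A tibble `term`, `chisq`, `df`, `p`.
#' @export
wald_anova <- function(fit) {
  stopifnot(inherits(fit, "taxalag_fit"))
  if (!fit$converged) warning("Wald tests from a fit that did not converge cleanly")
  if (!length(fit$spec$fixed)) stop("null model has no fixed-effect terms to test")
  if (inherits(fit$model, "merMod")) {
    a <- car::Anova(fit$model, type = 2, test.statistic = "Chisq")
    keep <- rownames(a) != "Residuals"
    return(tibble::tibble(
      term = rownames(a)[keep],
      chisq = a[["Chisq"]][keep],
      df = a[["Df"]][keep],
      p = a[[grep("^Pr", colnames(a), value = TRUE)[1]]][keep]
    ))
  }
  # OLS fallback (all random effects dropped): joint Wald chi-square per
  # term over its model-matrix columns, adjusted for all other terms
  V <- as.matrix(stats::vcov(fit$model))
  b <- stats::coef(fit$model)
  asgn <- attr(stats::model.matrix(fit$model), "assign")
  labels <- attr(stats::terms(fit$model), "term.labels")
  rows <- lapply(seq_along(labels), function(j) {
    idx <- which(asgn == j)
    ok <- idx[!is.na(b[idx])]
    if (!length(ok)) {
      return(tibble::tibble(term = labels[j], chisq = NA_real_,
                            df = NA_integer_, p = NA_real_))
    }
    stat <- tryCatch(
      drop(t(b[ok]) %*% solve(V[ok, ok, drop = FALSE], b[ok])),
      error = function(e) NA_real_
    )
    tibble::tibble(
      term = labels[j], chisq = stat, df = length(ok),
      p = if (is.na(stat)) NA_real_ else
        stats::pchisq(stat, df = length(ok), lower.tail = FALSE)
    )
  })
  dplyr::bind_rows(rows)
}

#' Compare a fitted model against its null (random-effects-only) model
#'
#' Likelihood-ratio test of the fixed effects: both models must be ML fits
#' on the same data with the null's fixed part nested in the full's. Also
#' reports the AIC difference and which model the AIC prefers.
#'
#' @param fit,null_fit [fit_lmm()] objects on the same rows; `null_fit`
#'   nested in `fit`.
#' @return A list: `lr` statistic, `df`, `p`, `aic_delta`
#'   (AIC full - AIC null), `preferred` (`"full"` or `"null"`).
#' @export
compare_null <- function(fit, null_fit) {
  stopifnot(inherits(fit, "taxalag_fit"), inherits(null_fit, "taxalag_fit"))
  if (fit$n != null_fit$n) stop("models were fitted to different numbers of observations")
  if (!all(null_fit$spec$fixed %in% fit$spec$fixed)) {
    stop("null model's fixed effects are not nested in the full model's")
  }
  df <- fit$df - null_fit$df
  if (df < 0) stop("null model has more parameters than the full model")
  lr <- 2 * (fit$logLik - null_fit$logLik)
  p <- if (df == 0) NA_real_ else stats::pchisq(lr, df = df, lower.tail = FALSE)
  aic_delta <- fit$AIC - null_fit$AIC
  list(
    lr = lr, df = df, p = p, aic_delta = aic_delta,
    preferred = if (aic_delta < 0) "full" else if (aic_delta > 0) "null" else "tie"
  )
}

#' Simulation-based scaled-quantile residual diagnostics
#'
#' For each observation, simulates `n_sim` new responses from the fitted
#' model — drawing fresh random-effect and residual deviates — and scores
#' the observation by the fraction of simulated values below it (mid-rank
#' handling of ties), yielding residuals that are approximately Uniform(0,1)
#' when the model is correctly specified. Three tests summarize deviations:
#' a Kolmogorov-Smirnov test of uniformity, a two-sided empirical dispersion
#' test comparing the observed residual variance with the distribution of
#' simulated residual variances, and a binomial outlier test counting
#' observations outside the range of all their simulations.
#'
#' @param fit A converged [fit_lmm()] object.
#' @param n_sim Number of simulated response vectors (>= 50).
#' @param seed Integer seed; identical seed and data give bit-identical
#'   output.
#' @param response Optional numeric vector to diagnose against the fitted
#'   model in place of the model's own response (same length and order as
#'   the fitted data) — the hook for checking how a fit behaves when the
#'   observed data are misspecified relative to it.
#' @return An object of class `taxalag_residuals`: list with `residuals`
#'   (in \[0, 1\]), `n_sim`, `uniformity` (`statistic`, `p`), `dispersion`
#'   (`statistic` = observed/mean simulated variance ratio, `p`),
#'   `outliers` (`count`, `p`).
#' @export
simulate_residuals <- function(fit, n_sim = 250L, seed = 1L, response = NULL) {
  stopifnot(inherits(fit, "taxalag_fit"), n_sim >= 50L)
  if (!fit$converged) stop("residual simulation requires a converged fit")
  sims <- stats::simulate(fit$model, nsim = n_sim, seed = seed)
  sims <- as.matrix(sims)
  y <- response %||% observed_response(fit$model)
  stopifnot(length(y) == nrow(sims))
  scaled <- vapply(seq_along(y), function(i) {
    s <- sims[i, ]
    (sum(s < y[i]) + 0.5 * sum(s == y[i])) / n_sim
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(scaled, "punif"))
  mu <- unconditional_fitted(fit$model)
  obs_var <- stats::var(y - mu)
  sim_var <- apply(sims - mu, 2, stats::var)
  p_lo <- (1 + sum(sim_var <= obs_var)) / (1 + n_sim)
  p_hi <- (1 + sum(sim_var >= obs_var)) / (1 + n_sim)
  disp_p <- min(1, 2 * min(p_lo, p_hi))
  lo <- apply(sims, 1, min)
  hi <- apply(sims, 1, max)
  n_out <- sum(y < lo | y > hi)
  out_p <- stats::binom.test(n_out, length(y), p = 2 / (n_sim + 1))$p.value
  structure(
    list(
      residuals = scaled,
      n_sim = as.integer(n_sim),
      uniformity = list(statistic = unname(ks$statistic), p = ks$p.value),
      dispersion = list(statistic = obs_var / mean(sim_var), p = disp_p),
      outliers = list(count = n_out, p = out_p)
    ),
    class = "taxalag_residuals"
  )
}

observed_response <- function(model) {
  if (inherits(model, "merMod")) {
    unname(lme4::getME(model, "y"))
  } else {
    unname(stats::model.response(stats::model.frame(model)))
  }
}

unconditional_fitted <- function(model) {
  if (inherits(model, "merMod")) {
    unname(stats::predict(model, re.form = NA))
  } else {
    unname(stats::fitted(model))
  }
}

#' @export
print.taxalag_residuals <- function(x, ...) {
  cat(sprintf(
    "<taxalag_residuals> n = %d, n_sim = %d\n  uniformity KS D = %.3f (p = %.3f)\n  dispersion ratio = %.3f (p = %.3f)\n  outliers = %d (p = %.3f)\n",
    length(x$residuals), x$n_sim,
    x$uniformity$statistic, x$uniformity$p,
    x$dispersion$statistic, x$dispersion$p,
    x$outliers$count, x$outliers$p
  ))
  invisible(x)
}

#' Serialize a model fit (plus companions) to JSON
#'
#' Machine-readable twin of the model-results tables: specification,
#' coefficient table, variance components, likelihood and AIC, Wald tests,
#' null-model comparison and residual diagnostics.
#'
#' @param fit A [fit_lmm()] object.
#' @param path Output JSON path.
#' @param anova Optional [wald_anova()] tibble.
#' @param null_comparison Optional [compare_null()] list.
#' @param diagnostics Optional [simulate_residuals()] object.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path, anova = NULL, null_comparison = NULL,
                             diagnostics = NULL) {
  payload <- list(
    spec = fit$spec,
    n = fit$n,
    converged = fit$converged,
    coefficients = fit$coefficients,
    varcomp = as.list(fit$varcomp),
    logLik = fit$logLik,
    AIC = fit$AIC
  )
  if (!is.null(anova)) payload$anova <- anova
  if (!is.null(null_comparison)) payload$null_comparison <- null_comparison
  if (!is.null(diagnostics)) {
    payload$diagnostics <- list(
      n_sim = diagnostics$n_sim,
      uniformity = diagnostics$uniformity,
      dispersion = diagnostics$dispersion,
      outliers = diagnostics$outliers
    )
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
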